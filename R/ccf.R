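#' Cancer cell fraction from a VAF
#'
#' Inverts the peak equation for the cancer cell fraction of a mutation with
#' multiplicity `m` on an `nA:nB` segment:
#' \deqn{c_m(\pi, v) = v[(n_A + n_B - 2)\pi + 2] / (m\pi).}
#' Per-mutation CCFs inherit the binomial read-count noise of the VAF and are
#' deliberately *not* clipped to \[0, 1\]: clonal mutations spread around
#' `c = 1` (for a pure diploid tumor `c = 2v`). `NA` multiplicities propagate
#' to `NA` CCFs.
#'
#' @param v VAF in \[0, 1\].
#' @param m Multiplicity (1 or 2, possibly `NA`).
#' @param nA,nB Segment allele counts.
#' @param purity Tumor purity in (0, 1].
#' @return Numeric CCF (can exceed 1).
#' @examples
#' ccf_from_vaf(0.5, 1, 1, 1, purity = 1)  # 1
#' @export
ccf_from_vaf <- function(v, m, nA, nB, purity) {
  check_purity(purity)
  v * ((nA + nB - 2) * purity + 2) / (m * purity)
}

#' Phase mutation multiplicity with the entropy method
#'
#' For amplified simple states (2:0, 2:1, 2:2) mutations can carry one or two
#' copies; the method builds a two-component binomial mixture anchored at the
#' theoretical peaks `v1`, `v2` (trials fixed at the median coverage, mixing
#' proportions from the mutation counts inside the central 1--99% quantile
#' range of each component), computes each mutation's responsibility pair
#' `z = (z1, z2)` and its entropy `H(z)`. Where the two binomials overlap the
#' entropy spikes; the VAF range `[h1, h2]` bracketing the spike (where the
#' entropy profile falls back to half of its `ln 2` maximum) is declared
#' unassignable: mutations inside it get `m = NA` and an `NA` CCF, the rest
#' are assigned by largest responsibility and converted through
#' [ccf_from_vaf()]. For 1:0 and 1:1 every mutation has `m = 1`.
#'
#' @param mutations Tibble with `nv`, `dp` (and `vaf`).
#' @param nA,nB Allele counts of the (simple) karyotype.
#' @param purity Tumor purity.
#' @param grid_step VAF grid step for the entropy profile.
#' @return A `vafqc_ccf` object: tibble of per-mutation estimates (`m`, `z1`,
#'   `z2`, `entropy`, `ccf`, `method`, `outlier` flag for CCF > 1.5) with
#'   attributes `na_range` (`c(h1, h2)` or `NULL`) and `karyotype`.
#' @export
phase_entropy <- function(mutations, nA, nB, purity, grid_step = 0.001) {
  mutations <- validate_mutations(mutations)
  key <- paste0(max(nA, nB), ":", min(nA, nB))
  if (key %in% c("1:0", "1:1")) {
    est <- dplyr::mutate(mutations,
      m = 1L, z1 = 1, z2 = 0, entropy = 0,
      ccf = ccf_from_vaf(.data$vaf, 1, nA, nB, purity),
      method = "entropy")
    return(new_ccf(est, NULL, key))
  }
  if (!key %in% c("2:0", "2:1", "2:2")) {
    stop("CCF phasing supports simple karyotypes only.", call. = FALSE)
  }

  mix <- ccf_mixture(mutations, nA, nB, purity)
  z <- responsibilities(mutations$nv, mutations$dp, mix)
  H <- entropy2(z)

  # entropy profile over a VAF grid at the median coverage
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  zg <- responsibilities(round(grid * mix$trials), rep(mix$trials, length(grid)), mix)
  Hg <- entropy2(zg)
  na_range <- entropy_spike_range(grid, Hg, mix$v1, mix$v2)

  in_na <- !is.na(na_range[1]) &
    mutations$vaf >= na_range[1] & mutations$vaf <= na_range[2]
  m <- ifelse(in_na, NA_integer_, ifelse(z[, 1] >= z[, 2], 1L, 2L))
  est <- dplyr::mutate(mutations,
    m = m, z1 = z[, 1], z2 = z[, 2], entropy = H,
    ccf = ccf_from_vaf(.data$vaf, m, nA, nB, purity),
    method = "entropy")
  if (all(is.na(est$m))) {
    warning("Binomial components overlap so widely that no mutation is assignable.")
  }
  new_ccf(est, na_range, key)
}

#' Phase mutation multiplicity with the rough midpoint cut
#'
#' Computes the weighted midpoint `o = v1 + (v2 - v1) * w1` between the two
#' theoretical peaks (`w1` the mixing proportion of the single-copy
#' component) and assigns `m = 1` below the cut and `m = 2` at or above it.
#' Every mutation is assigned -- the method carries no uncertainty, so its QC
#' status is always a pass.
#'
#' @inheritParams phase_entropy
#' @return A `vafqc_ccf` object (no NA range).
#' @export
phase_rough <- function(mutations, nA, nB, purity) {
  mutations <- validate_mutations(mutations)
  key <- paste0(max(nA, nB), ":", min(nA, nB))
  if (key %in% c("1:0", "1:1")) {
    est <- dplyr::mutate(mutations,
      m = 1L, z1 = 1, z2 = 0, entropy = 0,
      ccf = ccf_from_vaf(.data$vaf, 1, nA, nB, purity),
      method = "rough")
    return(new_ccf(est, NULL, key))
  }
  mix <- ccf_mixture(mutations, nA, nB, purity)
  o <- mix$v1 + (mix$v2 - mix$v1) * mix$w1
  m <- ifelse(mutations$vaf < o, 1L, 2L)
  est <- dplyr::mutate(mutations,
    m = m, z1 = as.numeric(m == 1L), z2 = as.numeric(m == 2L), entropy = 0,
    ccf = ccf_from_vaf(.data$vaf, m, nA, nB, purity),
    method = "rough")
  out <- new_ccf(est, NULL, key)
  attr(out, "midpoint") <- o
  out
}

#' QC status of a set of CCF estimates
#'
#' The entropy method abstains on unassignable mutations; the karyotype
#' fails QC when the fraction of `NA` multiplicities exceeds `na_cutoff`
#' (strictly greater than the default 10%). The rough method never abstains
#' and therefore always passes.
#'
#' @param estimates A `vafqc_ccf` object or its tibble of estimates.
#' @param na_cutoff Maximum tolerated NA fraction.
#' @return A one-row tibble: `karyotype`, `n`, `n_na`, `prop_na`, `status`.
#' @export
ccf_qc <- function(estimates, na_cutoff = 0.10) {
  karyotype <- attr(estimates, "karyotype") %||% NA_character_
  est <- if (inherits(estimates, "vafqc_ccf")) estimates$estimates else estimates
  prop_na <- mean(is.na(est$m))
  tibble::tibble(
    karyotype = karyotype, n = nrow(est), n_na = sum(is.na(est$m)),
    prop_na = prop_na,
    status = if (prop_na > na_cutoff) "FAIL" else "PASS"
  )
}

# ---- internals --------------------------------------------------------------

ccf_mixture <- function(mutations, nA, nB, purity) {
  v1 <- expected_vaf(1, nA, nB, purity)
  v2 <- expected_vaf(2, nA, nB, purity)
  trials <- round(stats::median(mutations$dp))
  # central 1-99% quantile range of each binomial component, in VAF units
  r1 <- stats::qbinom(c(0.01, 0.99), trials, v1) / trials
  r2 <- stats::qbinom(c(0.01, 0.99), trials, v2) / trials
  n1 <- sum(mutations$vaf >= r1[1] & mutations$vaf <= r1[2])
  n2 <- sum(mutations$vaf >= r2[1] & mutations$vaf <= r2[2])
  if (n1 + n2 == 0) { n1 <- n2 <- 1 }   # neither range populated: even split
  list(v1 = v1, v2 = v2, trials = trials,
       w1 = n1 / (n1 + n2), w2 = n2 / (n1 + n2))
}

responsibilities <- function(nv, dp, mix) {
  l1 <- mix$w1 * stats::dbinom(nv, dp, mix$v1)
  l2 <- mix$w2 * stats::dbinom(nv, dp, mix$v2)
  tot <- l1 + l2
  tot[tot == 0] <- .Machine$double.xmin
  cbind(l1, l2) / tot
}

entropy2 <- function(z) {
  z <- pmin(pmax(z, 1e-300), 1)
  -rowSums(z * log(z))
}

# bracket the central entropy spike: the grid position of maximal entropy
# between the two peaks, extended left/right until H falls to ln(2)/2
entropy_spike_range <- function(grid, H, v1, v2) {
  inside <- grid > v1 & grid < v2
  if (!any(inside)) return(c(NA_real_, NA_real_))
  spike <- which(inside)[which.max(H[inside])]
  cut <- log(2) / 2
  left <- spike
  while (left > 1 && H[left - 1] >= cut && grid[left - 1] > v1) left <- left - 1
  right <- spike
  while (right < length(grid) && H[right + 1] >= cut && grid[right + 1] < v2) right <- right + 1
  h <- c(grid[left], grid[right])
  h[1] <- max(h[1], v1 + .Machine$double.eps)
  h[2] <- min(h[2], v2 - .Machine$double.eps)
  h
}

new_ccf <- function(estimates, na_range, karyotype) {
  estimates$outlier <- !is.na(estimates$ccf) & estimates$ccf > 1.5
  out <- list(estimates = estimates, na_range = na_range, karyotype = karyotype)
  class(out) <- "vafqc_ccf"
  attr(out, "karyotype") <- karyotype
  out
}

#' @export
print.vafqc_ccf <- function(x, ...) {
  qc <- ccf_qc(x)
  cat(sprintf("CCF estimates (%s method) for %s: %d mutations, %.1f%% NA -> %s\n",
              x$estimates$method[1], x$karyotype, qc$n, 100 * qc$prop_na, qc$status))
  if (!is.null(x$na_range) && !anyNA(x$na_range)) {
    cat(sprintf("  unassignable VAF range [%.3f, %.3f]\n",
                x$na_range[1], x$na_range[2]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
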