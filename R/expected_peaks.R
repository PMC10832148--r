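#' Theoretical VAF peak for a clonal or subclonal mutation
#'
#' For a bulk sample that mixes tumor cells (purity `pi`) with diploid normal
#' cells, a mutation carried by `m` copies of an `nA:nB` segment and present
#' in a fraction `c` of tumor cells is expected to peak at
#' \deqn{v_m(\pi, c) = \frac{m \pi c}{2(1-\pi) + \pi(n_A + n_B)}.}
#' All peak-based QC in this package derives from this map between purity and
#' VAF space.
#'
#' @param m Mutation multiplicity, integer >= 1 (number of tumor-genome copies
#'   carrying the mutation).
#' @param nA,nB Major and minor allele copies of the segment (`nA >= nB >= 0`).
#' @param purity Tumor purity in (0, 1].
#' @param ccf Cancer cell fraction of the mutation in (0, 1]; 1 for clonal
#'   mutations.
#'
#' @return Expected VAF, a numeric vector (vectorized over all arguments).
#' @examples
#' expected_vaf(1, 1, 1, purity = 1)        # 0.5
#' expected_vaf(1:2, 2, 2, purity = 1)      # 0.25, 0.5
#' @export
expected_vaf <- function(m, nA, nB, purity, ccf = 1) {
  check_purity(purity)
  if (any(ccf <= 0 | ccf > 1)) stop("`ccf` must lie in (0, 1].", call. = FALSE)
  if (any(m < 1 | m != round(m))) stop("`m` must be a positive integer.", call. = FALSE)
  check_allele_counts(nA, nB)
  denom <- 2 * (1 - purity) + purity * (nA + nB)
  if (any(denom <= 0)) {
    stop("Undefined peak: segment with zero copies in a pure tumor.", call. = FALSE)
  }
  m * purity * ccf / denom
}

#' Expected clonal peaks for one karyotype
#'
#' Enumerates the theoretical clonal VAF peaks of a segment with allele counts
#' `nA:nB`. Simple states use the multiplicities that single-step evolution
#' allows: `{1}` for 1:0 and 1:1, `{1, 2}` for 2:0, 2:1 and 2:2 (mutations
#' before/after the amplification step). Complex states are scanned with
#' multiplicities 1 to `max(nA, nB)`.
#'
#' @inheritParams expected_vaf
#' @return A tibble with columns `karyotype`, `m`, `vaf`, `origin`, sorted by
#'   increasing multiplicity (peaks are strictly increasing in `m`).
#' @examples
#' peaks_for_karyotype(2, 1, purity = 1)  # 1/3 and 2/3
#' @export
peaks_for_karyotype <- function(nA, nB, purity) {
  check_allele_counts(nA, nB)
  m_set <- multiplicity_set(nA, nB)
  tibble::tibble(
    karyotype = paste0(nA, ":", nB),
    m = m_set,
    vaf = expected_vaf(m_set, nA, nB, purity),
    origin = "clonal"
  )
}

multiplicity_set <- function(nA, nB) {
  key <- paste0(max(nA, nB), ":", min(nA, nB))
  if (key %in% c("1:0", "1:1")) return(1L)
  if (key %in% c("2:0", "2:1", "2:2")) return(c(1L, 2L))
  seq_len(max(nA, nB))
}

#' First-order VAF error from a purity error
#'
#' Propagates a purity tolerance `epsilon` to VAF space by linearizing the
#' peak equation around `purity`:
#' \deqn{\Delta v_m(\pi, \epsilon) \approx 2 m \epsilon / [2(1-\pi) + \pi p]^2}
#' with `p = nA + nB` the segment ploidy.
#'
#' @param m Mutation multiplicity.
#' @param p Segment ploidy `nA + nB`.
#' @param purity Tumor purity in (0, 1].
#' @param epsilon Purity error (> 0, in purity units).
#' @return VAF half-width (first order).
#' @examples
#' vaf_error_from_purity_error(1, 3, 0.9, 0.05)  # ~0.0119
#' @export
vaf_error_from_purity_error <- function(m, p, purity, epsilon) {
  if (any(epsilon < 0)) stop("`epsilon` must be non-negative.", call. = FALSE)
  2 * m * epsilon / (2 * (1 - purity) + purity * p)^2
}

#' Purity implied by a VAF peak, and its first-order error
#'
#' Inverts the clonal peak equation for a peak observed at `v` with
#' multiplicity `m` on ploidy-`p` segments:
#' \deqn{\pi(v_m) = 2 v_m / [m + (2 - p) v_m]}
#' `purity_error_from_vaf_error()` is the matching first-order propagation
#' \deqn{\Delta\pi \approx 2 m \Delta v_m / [m + v_m (2 - p)]^2.}
#' Composing the two propagations returns the original purity error exactly.
#'
#' @param v VAF peak position.
#' @param m Mutation multiplicity.
#' @param p Segment ploidy.
#' @return Implied purity.
#' @examples
#' purity_from_vaf(0.5, 1, 2)  # 1
#' @export
purity_from_vaf <- function(v, m, p) {
  denom <- m + (2 - p) * v
  if (any(abs(denom) < .Machine$double.eps)) {
    stop("Degenerate configuration: zero denominator in purity inversion.", call. = FALSE)
  }
  2 * v / denom
}

#' @rdname purity_from_vaf
#' @param dv VAF offset or half-width to propagate.
#' @export
purity_error_from_vaf_error <- function(v, dv, m, p) {
  denom <- m + v * (2 - p)
  if (any(abs(denom) < .Machine$double.eps)) {
    stop("Degenerate configuration: zero denominator in error propagation.", call. = FALSE)
  }
  2 * m * dv / denom^2
}

#' Accepted VAF band for an expected peak under a purity tolerance
#'
#' Half-width of the VAF interval accepted around an expected peak when the
#' input purity may be wrong by up to `epsilon` on either side. This is the
#' exact image of the two-sided purity band under the peak equation,
#' \deqn{\Delta = v_m(\pi + \epsilon) - v_m(\pi - \epsilon),}
#' which to first order equals twice [vaf_error_from_purity_error()]. For a
#' diploid segment at purity 0.60 with `epsilon = 0.025` the accepted band is
#' `[0.275, 0.325]`, i.e. implied purity in `[0.55, 0.65]`.
#'
#' @inheritParams expected_vaf
#' @param epsilon Purity tolerance (purity units).
#' @return VAF half-width of the acceptance interval.
#' @export
vaf_acceptance_halfwidth <- function(m, nA, nB, purity, epsilon) {
  hi <- pmin(purity + epsilon, 1)
  lo <- pmax(purity - epsilon, .Machine$double.eps)
  expected_vaf(m, nA, nB, hi) - expected_vaf(m, nA, nB, lo)
}

#' Expected peaks of a two-subclone segment under an evolution model
#'
#' Given an evolution model (see [enumerate_evolution_models()]) relating two
#' subclones with allele states `nA1:nB1` and `nA2:nB2` present at proportions
#' `rho1` and `rho2 = 1 - rho1` of the tumor, shared mutations with
#' multiplicity pair `(m1, m2)` peak at
#' \deqn{v_{\{m_1,m_2\}} = \frac{(m_1\rho_1 + m_2\rho_2)\pi}
#'   {2(1-\pi) + \pi(\rho_1 p_1 + \rho_2 p_2)}}
#' and mutations private to subclone `i` with multiplicity `m` peak at
#' \deqn{v_{m_i} = \frac{m\rho_i\pi}{2(1-\pi) + \pi(\rho_1 p_1 + \rho_2 p_2)}}
#' with `p_i` the subclone ploidies. Peaks landing at the same position are
#' collapsed, keeping the provenance of every contributing mutation class.
#'
#' @param model One evolution model, a row-list as returned by
#'   [enumerate_evolution_models()] (fields `state1`, `state2`,
#'   `shared_multiplicities`, `private1`, `private2`).
#' @param rho1,rho2 Subclone proportions, summing to 1.
#' @param purity Tumor purity in (0, 1].
#' @return A tibble with columns `vaf`, `origin`
#'   (`shared`/`private_clone1`/`private_clone2`), `m1`, `m2`, `label`.
#' @export
subclonal_expected_peaks <- function(model, rho1, rho2, purity) {
  if (is.data.frame(model)) {
    stopifnot(nrow(model) == 1)
    model <- list(state1 = model$state1, state2 = model$state2,
                  shared_multiplicities = model$shared_multiplicities[[1]],
                  private1 = model$private1[[1]], private2 = model$private2[[1]])
  }
  if (abs(rho1 + rho2 - 1) > 1e-6) stop("`rho1 + rho2` must equal 1.", call. = FALSE)
  if (rho1 <= 0 || rho1 >= 1) stop("`rho1` must lie in (0, 1).", call. = FALSE)
  check_purity(purity)
  p1 <- sum(parse_karyotype(model$state1))
  p2 <- sum(parse_karyotype(model$state2))
  denom <- 2 * (1 - purity) + purity * (rho1 * p1 + rho2 * p2)

  shared <- model$shared_multiplicities
  rows <- list()
  if (!is.null(shared) && nrow(shared) > 0) {
    rows[[1]] <- tibble::tibble(
      vaf = (shared$m1 * rho1 + shared$m2 * rho2) * purity / denom,
      origin = "shared", m1 = shared$m1, m2 = shared$m2
    )
  }
  if (length(model$private1) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      vaf = model$private1 * rho1 * purity / denom,
      origin = "private_clone1", m1 = model$private1, m2 = 0L
    )
  }
  if (length(model$private2) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      vaf = model$private2 * rho2 * purity / denom,
      origin = "private_clone2", m1 = 0L, m2 = model$private2
    )
  }
  peaks <- dplyr::bind_rows(rows)
  peaks <- peaks[peaks$vaf > 0, , drop = FALSE]
  peaks$label <- paste0(peaks$origin, "(", peaks$m1, ",", peaks$m2, ")")
  # collapse positionally duplicate peaks, keep provenance
  peaks |>
    dplyr::mutate(.pos = round(.data$vaf, 10)) |>
    dplyr::group_by(.data$.pos) |>
    dplyr::summarise(
      vaf = .data$vaf[1],
      origin = paste(unique(.data$origin), collapse = "+"),
      m1 = .data$m1[1], m2 = .data$m2[1],
      label = paste(.data$label, collapse = "; "),
      .groups = "drop"
    ) |>
    dplyr::select(-".pos") |>
    dplyr::arrange(.data$vaf)
}

# ---- shared validators ------------------------------------------------------

check_purity <- function(purity) {
  if (any(!is.finite(purity) | purity <= 0 | purity > 1)) {
    stop("`purity` must lie in (0, 1].", call. = FALSE)
  }
  invisible(purity)
}

check_allele_counts <- function(nA, nB) {
  if (any(nA < 0 | nB < 0 | nA != round(nA) | nB != round(nB))) {
    stop("Allele counts must be non-negative integers.", call. = FALSE)
  }
  invisible(NULL)
}

parse_karyotype <- function(x) {
  parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(parts) != 2 || anyNA(parts)) stop("Malformed karyotype string: ", x, call. = FALSE)
  parts
}
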