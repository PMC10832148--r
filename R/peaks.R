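#' Detect VAF peaks by kernel density estimation
#'
#' Smooths the VAF distribution with a fixed-bandwidth Gaussian kernel and
#' returns local density maxima whose height reaches at least
#' `min_rel_height` of the tallest peak (the empirical 1/20 cut suppresses
#' spurious bumps from stray mutations).
#'
#' @param vafs Numeric vector of VAFs in \[0, 1\].
#' @param bandwidth Kernel bandwidth in VAF units; the 0.01 default matches
#'   the 0.01-wide support-counting bins and resolves peaks a few
#'   coverage-standard-deviations apart at typical WGS depth.
#' @param min_rel_height Minimum peak height relative to the tallest peak.
#' @param min_prominence Minimum topographic prominence of a peak relative
#'   to its own height; prunes sampling wiggles riding on a genuine peak
#'   (shallow dips) while keeping well-separated modes.
#' @param n_grid Density evaluation grid size.
#' @return A tibble of peaks: `position`, `height`, `support` (mutations in
#'   the 0.01 bin containing the peak), `method = "kde"`, sorted by position.
#' @export
kde_peaks <- function(vafs, bandwidth = 0.01, min_rel_height = 1 / 20,
                      min_prominence = 0.25, n_grid = 1024) {
  vafs <- vafs[is.finite(vafs)]
  if (length(vafs) == 0) stop("No VAFs to detect peaks from.", call. = FALSE)
  if (diff(range(vafs)) < .Machine$double.eps) {
    return(tibble::tibble(position = vafs[1], height = Inf,
                          support = length(vafs), method = "kde"))
  }
  d <- stats::density(vafs, bw = bandwidth, n = n_grid,
                      from = max(0, min(vafs) - 3 * bandwidth),
                      to = min(1, max(vafs) + 3 * bandwidth))
  y <- d$y
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  # grid ends count when the density keeps rising into the boundary
  # (e.g. a mass of homozygous mutations at VAF 1)
  is_max[1] <- y[1] > y[2]
  is_max[length(y)] <- y[length(y)] > y[length(y) - 1]
  idx <- which(is_max)
  pos <- d$x[idx]
  height <- y[idx]
  prom <- vapply(seq_along(idx), function(i) peak_prominence(y, idx[i]), numeric(1))
  keep <- height >= min_rel_height * max(height) &
    prom >= min_prominence * height
  tibble::tibble(
    position = pos[keep], height = height[keep],
    support = vapply(pos[keep], function(p) count_support(vafs, p), integer(1)),
    method = "kde"
  ) |> dplyr::arrange(.data$position)
}

# topographic prominence: drop from the peak to the highest saddle
# separating it from higher ground (full height for the global maximum)
peak_prominence <- function(y, i) {
  h <- y[i]
  side_min <- function(range) {
    if (length(range) == 0) return(0)          # no higher ground: sea level
    higher <- which(y[range] > h)
    if (length(higher) == 0) return(0)
    min(y[range[seq_len(min(higher) - 1)]], h)
  }
  left <- side_min(rev(seq_len(i - 1)))
  right <- side_min(seq(i + 1, length(y), length.out = max(0, length(y) - i)))
  h - max(left, right)
}

#' Count mutations supporting a peak
#'
#' The VAF axis is binned into 100 bins of width 0.01 (`[k/100, (k+1)/100)`,
#' last bin right-closed); the support of a peak is the number of mutations
#' in the bin containing its position.
#'
#' @param vafs Numeric vector of VAFs.
#' @param position Peak position in \[0, 1\].
#' @return Integer mutation count.
#' @export
count_support <- function(vafs, position) {
  k <- min(floor(position * 100), 99)
  lo <- k / 100
  hi <- (k + 1) / 100
  if (k == 99) sum(vafs >= lo & vafs <= hi) else sum(vafs >= lo & vafs < hi)
}

#' Fit a finite binomial mixture to read counts
#'
#' Models alt-read counts as a mixture of up to `max_w` binomial components
#' (successes `nv` out of `dp` trials), fitted by expectation-maximization
#' for each component count and selected by the integrated classification
#' likelihood (ICL): the BIC plus twice the total responsibility entropy, so
#' that overlapping, poorly separated components are penalized. Components
#' are initialized on spread quantiles of the VAFs plus random restarts under
#' a fixed master seed, so the fit is deterministic.
#'
#' @param nv,dp Paired integer vectors of alt reads and depths (`nv <= dp`).
#' @param max_w Largest number of components tried (default 4).
#' @param n_restarts Random restarts per component count.
#' @param seed Master seed for the restarts.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An object of class `binmix_fit`: a list with `w`, `p` (component
#'   success probabilities), `weight` (mixing proportions), `icl`, `loglik`,
#'   `responsibilities`, and a `peaks` tibble (one row per component with
#'   `position`, `height`, `support`, `method = "mixture"`).
#' @export
fit_binomial_mixture <- function(nv, dp, max_w = 4, n_restarts = 3,
                                 seed = 42, max_iter = 150, tol = 1e-6) {
  stopifnot(length(nv) == length(dp))
  if (any(nv > dp | nv < 0 | dp < 1)) stop("Need 0 <= nv <= dp, dp >= 1.", call. = FALSE)
  n <- length(nv)
  if (n == 0) stop("No data.", call. = FALSE)
  degenerate <- all(nv == 0)
  if (degenerate) warning("All alt counts are zero; returning a single-component fit.")

  vaf <- nv / dp
  fits <- list()
  ws <- if (degenerate) 1L else seq_len(max_w)
  for (w in ws) {
    best <- NULL
    # quantile-spread init plus seeded random restarts
    inits <- list(stats::quantile(vaf, probs = (seq_len(w) - 0.5) / w, names = FALSE))
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed + w)
    for (r in seq_len(n_restarts)) {
      inits[[length(inits) + 1]] <- stats::runif(w, 0.02, 0.98)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    for (p0 in inits) {
      f <- binmix_em(nv, dp, sort(pmin(pmax(p0, 1e-3), 1 - 1e-3)), max_iter, tol)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    ent <- -sum(best$z * log(pmax(best$z, 1e-300)))
    npar <- 2 * w - 1
    best$icl <- -2 * best$loglik + npar * log(n) + 2 * ent
    best$w <- w
    fits[[w]] <- best
  }
  icls <- vapply(fits, function(f) f$icl, numeric(1))
  # tie-break: best ICL, then fewest components
  fit <- fits[[which.min(icls)]]
  support <- vapply(fit$p, function(pp) count_support(vaf, pp), integer(1))
  out <- list(
    w = fit$w, p = fit$p, weight = fit$weight,
    loglik = fit$loglik, icl = fit$icl,
    responsibilities = fit$z,
    icl_path = icls,
    peaks = tibble::tibble(position = fit$p, height = fit$weight,
                           support = support, method = "mixture") |>
      dplyr::arrange(.data$position)
  )
  class(out) <- "binmix_fit"
  out
}

binmix_em <- function(nv, dp, p, max_iter, tol) {
  w <- length(p)
  weight <- rep(1 / w, w)
  n <- length(nv)
  ll_old <- -Inf
  z <- matrix(1 / w, n, w)
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(w), function(i) {
      stats::dbinom(nv, dp, p[i], log = TRUE) + log(weight[i])
    }, numeric(n))
    logd <- matrix(logd, nrow = n)
    mx <- logd[, 1]
    if (w > 1) for (i in 2:w) mx <- pmax(mx, logd[, i])
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    z <- exp(logd - lse)
    weight <- colMeans(z)
    p <- colSums(z * nv) / pmax(colSums(z * dp), 1e-300)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    if (is.finite(ll) && ll - ll_old < tol && it > 2) break
    ll_old <- ll
  }
  list(p = p, weight = weight, loglik = ll, z = z)
}

#' @export
print.binmix_fit <- function(x, ...) {
  cat("Binomial mixture fit: w =", x$w, "components\n")
  cat("  p      =", paste(sprintf("%.4f", x$p), collapse = ", "), "\n")
  cat("  weight =", paste(sprintf("%.4f", x$weight), collapse = ", "), "\n")
  cat("  ICL    =", sprintf("%.2f", x$icl), "\n")
  invisible(x)
}

#' Detected data peaks for a set of mutations
#'
#' Convenience wrapper dispatching to [kde_peaks()] or
#' [fit_binomial_mixture()] and returning peaks in the common tibble form.
#'
#' @param mutations Mutation tibble with `vaf` (and `nv`, `dp` for the
#'   mixture method).
#' @param method `"kde"` or `"mixture"`.
#' @param ... Passed to the underlying detector.
#' @return A tibble of peaks (`position`, `height`, `support`, `method`).
#' @export
detect_peaks <- function(mutations, method = c("kde", "mixture"), ...) {
  method <- match.arg(method)
  if (method == "kde") {
    kde_peaks(mutations$vaf, ...)
  } else {
    fit_binomial_mixture(mutations$nv, mutations$dp, ...)$peaks
  }
}
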