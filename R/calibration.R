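#' Build a false-positive-rate grid for purity-tolerance calibration
#'
#' For every cell of a purity-by-coverage grid and every tolerance `epsilon`,
#' simulates tumors at the true purity and runs QC with an input purity of
#' `purity + epsilon + phi`, `phi ~ U[0, 0.03]` -- a borderline-bad input the
#' tool should fail (the error always exceeds the tolerance). The fraction
#' of such runs that nevertheless pass is the false positive rate (FPR) of
#' that cell.
#'
#' The default grid is a scaled-down design (5 purities x 5 coverages x 10
#' tolerances); replicate counts and genome size are configurable for
#' full-scale regeneration.
#'
#' @param purities,coverages,epsilons Grid axes.
#' @param reps Simulated tumors per cell.
#' @param seed Master seed; the grid is reproduced bit-exactly from it.
#' @param n_chrom,mutations_per_mb Genome size knobs passed to the simulator.
#' @return A `fpr_grid` object: tibble `grid` (purity, coverage, epsilon,
#'   fpr, pass, reps) plus the axes, seed and simulator settings.
#' @export
build_fpr_grid <- function(purities = c(0.15, 0.35, 0.55, 0.75, 0.9),
                           coverages = c(20, 45, 70, 95, 120),
                           epsilons = seq(0.01, 0.1, by = 0.01),
                           reps = 10, seed = 20260101,
                           n_chrom = 4, mutations_per_mb = 3) {
  if (reps < 1) stop("`reps` must be at least 1.", call. = FALSE)
  cells <- tidyr::expand_grid(purity = purities, coverage = coverages,
                              epsilon = epsilons)
  res <- purrr::pmap_dfr(cells, function(purity, coverage, epsilon) {
    pass <- 0L
    for (r in seq_len(reps)) {
      rep_seed <- (seed + 7919L * r +
                     round(1e4 * (purity * 100 + coverage + epsilon * 1000))) %% .Machine$integer.max
      sim <- simulate_tumor(sim_config(purity = purity, coverage = coverage,
                                       n_chrom = n_chrom,
                                       mutations_per_mb = mutations_per_mb,
                                       seed = rep_seed))
      set.seed(rep_seed + 1L)
      phi <- stats::runif(1, 0, 0.03)
      input_purity <- suppressWarnings(corrupt_purity(purity, epsilon + phi))
      mapped <- map_mutations(sim$mutations, sim$segments)
      rep_qc <- qc_sample(mapped, input_purity, epsilon)
      if (identical(rep_qc$status, "PASS")) pass <- pass + 1L
    }
    tibble::tibble(purity = purity, coverage = coverage, epsilon = epsilon,
                   pass = pass, reps = reps, fpr = pass / reps)
  })
  structure(list(grid = res, purities = purities, coverages = coverages,
                 epsilons = epsilons, reps = reps, seed = seed,
                 n_chrom = n_chrom, mutations_per_mb = mutations_per_mb,
                 version = 1L),
            class = "fpr_grid")
}

#' Load the frozen calibration grid shipped with the package
#'
#' A pre-computed [build_fpr_grid()] result (stored as versioned JSON) so
#' that [suggest_epsilon()] works without on-the-fly simulation; it can be
#' regenerated bit-exactly from the stored seed and settings.
#'
#' @return An `fpr_grid` object.
#' @export
frozen_fpr_grid <- function() {
  path <- system.file("extdata", "fpr_grid.json", package = "vafqc")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(grid = tibble::as_tibble(obj$grid),
              purities = obj$purities, coverages = obj$coverages,
              epsilons = obj$epsilons, reps = obj$reps, seed = obj$seed,
              n_chrom = obj$n_chrom, mutations_per_mb = obj$mutations_per_mb,
              version = obj$version)
  class(out) <- "fpr_grid"
  out
}

#' Suggest the purity tolerance for a target false positive rate
#'
#' Per grid cell, a binomial GLM (logit link) of pass/fail on `epsilon` is
#' inverted to find the largest tolerance whose predicted FPR stays at or
#' below `max_fpr`; the per-cell values, capped to `eps_bounds`, are then
#' interpolated to the query point with a tensor-product Akima non-smoothing
#' spline (bilinear fallback when `pracma` is unavailable, reported in the
#' output). Queries outside the training hull raise an error -- there is no
#' extrapolation.
#'
#' @param purity,coverage Query point.
#' @param max_fpr Highest acceptable FPR (default 10%).
#' @param eps_bounds Allowed tolerance range (caps the inversion).
#' @param grid An `fpr_grid`; defaults to the frozen one.
#' @return List with `epsilon` (the suggestion), `cell_values` (per-node
#'   inversions) and `interpolation` (`"akima"` or `"bilinear"`).
#' @export
suggest_epsilon <- function(purity, coverage, max_fpr = 0.10,
                            eps_bounds = c(0.01, 0.1),
                            grid = frozen_fpr_grid()) {
  stopifnot(inherits(grid, "fpr_grid"))
  if (purity < min(grid$purities) || purity > max(grid$purities) ||
      coverage < min(grid$coverages) || coverage > max(grid$coverages)) {
    stop("Query outside the calibration training range; no extrapolation.",
         call. = FALSE)
  }
  cells <- grid$grid |>
    dplyr::group_by(.data$purity, .data$coverage) |>
    dplyr::summarise(
      eps_star = invert_fpr_glm(.data$epsilon, .data$pass, .data$reps,
                                max_fpr, eps_bounds),
      .groups = "drop")
  node_vals <- tidyr::pivot_wider(cells, names_from = "coverage",
                                  values_from = "eps_star") |>
    dplyr::arrange(.data$purity)
  z <- as.matrix(node_vals[, -1])          # purity x coverage
  px <- node_vals$purity
  cx <- sort(grid$coverages)
  z <- z[, order(as.numeric(colnames(z))), drop = FALSE]

  have_akima <- requireNamespace("pracma", quietly = TRUE) &&
    length(cx) >= 3 && length(px) >= 3
  if (have_akima) {
    # tensor-product 1D Akima: along coverage per purity row, then along purity
    row_vals <- vapply(seq_along(px), function(i) {
      interp_1d_akima(cx, z[i, ], coverage)
    }, numeric(1))
    eps <- interp_1d_akima(px, row_vals, purity)
    method <- "akima"
  } else {
    eps <- interp_bilinear(cx, px, z, coverage, purity)
    method <- "bilinear"
  }
  eps <- min(max(eps, eps_bounds[1]), eps_bounds[2])
  list(epsilon = eps, cell_values = cells, interpolation = method)
}

invert_fpr_glm <- function(eps, pass, reps, max_fpr, eps_bounds) {
  fail <- reps - pass
  fit <- suppressWarnings(
    stats::glm(cbind(pass, fail) ~ eps, family = stats::binomial()))
  a <- stats::coef(fit)[1]; b <- stats::coef(fit)[2]
  target <- stats::qlogis(min(max(max_fpr, 1e-6), 1 - 1e-6))
  eps_star <- if (!is.finite(b) || abs(b) < 1e-9) {
    # flat FPR: take the largest tolerance if acceptable, else the floor
    if (stats::plogis(a) <= max_fpr) max(eps) else eps_bounds[1]
  } else if (b > 0) {
    (target - a) / b
  } else {
    # decreasing FPR in tolerance: any large epsilon acceptable if tail is
    if (stats::plogis(a + b * max(eps)) <= max_fpr) max(eps) else eps_bounds[1]
  }
  unname(min(max(eps_star, eps_bounds[1]), eps_bounds[2]))
}

interp_bilinear <- function(x, y, z, xi, yi) {
  # z indexed [row = y, col = x]
  j <- min(max(findInterval(xi, x), 1), length(x) - 1)
  i <- min(max(findInterval(yi, y), 1), length(y) - 1)
  tx <- (xi - x[j]) / (x[j + 1] - x[j])
  ty <- (yi - y[i]) / (y[i + 1] - y[i])
  (1 - ty) * ((1 - tx) * z[i, j] + tx * z[i, j + 1]) +
    ty * ((1 - tx) * z[i + 1, j] + tx * z[i + 1, j + 1])
}

interp_1d_akima <- function(x, y, xi) {
  if (xi <= min(x)) xi <- min(x)
  if (xi >= max(x)) xi <- max(x)
  if (any(xi == x)) return(y[which(x == xi)[1]])   # interpolation exactness
  pracma::akimaInterp(x, y, xi)
}
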