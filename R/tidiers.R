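#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a QC report into one row per expected peak
#'
#' @param x A `vafqc_report`.
#' @param ... Unused.
#' @return Tibble with karyotype, multiplicity, expected and matched peak
#'   positions, offsets (VAF and purity units), match status and weights.
#' @method tidy vafqc_report
#' @export
tidy.vafqc_report <- function(x, ...) {
  if (nrow(x$peaks %||% tibble::tibble()) == 0) return(tibble::tibble())
  dplyr::select(x$peaks, "karyotype", "m", expected = "vaf", "d_star",
                "offset", "offset_purity", "band", "matched", "support",
                "weight", "status")
}

#' One-row summary of a QC report
#'
#' @param x A `vafqc_report`.
#' @param ... Unused.
#' @return Tibble with `status`, `lambda`, `purity`, `suggested_purity`,
#'   `epsilon`, mutation and karyotype counts.
#' @method glance vafqc_report
#' @export
glance.vafqc_report <- function(x, ...) {
  tibble::tibble(
    status = x$status, lambda = x$lambda, purity = x$purity,
    suggested_purity = x$suggested_purity, epsilon = x$epsilon,
    n_mutations = x$n_mutations,
    n_karyotypes = nrow(x$karyotypes %||% tibble::tibble()),
    n_peaks_matched = sum(x$peaks$matched %||% logical(0)),
    n_peaks = nrow(x$peaks %||% tibble::tibble())
  )
}

#' Tidy per-mutation CCF estimates
#'
#' @param x A `vafqc_ccf`.
#' @param ... Unused.
#' @return The per-mutation estimate tibble.
#' @method tidy vafqc_ccf
#' @export
tidy.vafqc_ccf <- function(x, ...) x$estimates

#' One-row summary of CCF estimates
#'
#' @param x A `vafqc_ccf`.
#' @param ... Passed to [ccf_qc()].
#' @return The [ccf_qc()] row plus the NA range bounds.
#' @method glance vafqc_ccf
#' @export
glance.vafqc_ccf <- function(x, ...) {
  out <- ccf_qc(x, ...)
  out$h1 <- if (is.null(x$na_range)) NA_real_ else x$na_range[1]
  out$h2 <- if (is.null(x$na_range)) NA_real_ else x$na_range[2]
  out
}

#' Plot the VAF histogram of a QC run with expected-peak overlays
#'
#' Diagnostic view: per-karyotype VAF histograms with vertical lines at the
#' expected peaks (solid when matched, dashed when not).
#'
#' @param mutations Mapped mutation tibble used for the QC run.
#' @param report The matching `vafqc_report`.
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_peaks <- function(mutations, report, binwidth = 0.01) {
  stopifnot(inherits(report, "vafqc_report"))
  peaks <- report$peaks
  dat <- dplyr::filter(mutations, .data$karyotype %in% unique(peaks$karyotype))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$vaf)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70") +
    ggplot2::geom_vline(
      data = peaks,
      ggplot2::aes(xintercept = .data$vaf, linetype = .data$matched),
      colour = "firebrick") +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"), name = "matched") +
    ggplot2::facet_wrap(~karyotype, scales = "free_y") +
    ggplot2::labs(x = "VAF", y = "mutations",
                  title = sprintf("Peak QC: %s (lambda %+.3f)",
                                  report$status, report$lambda)) +
    ggplot2::theme_minimal()
}

#' @method autoplot vafqc_report
#' @export
autoplot.vafqc_report <- function(object, mutations = NULL, ...) {
  if (is.null(mutations)) {
    # peak-level summary when raw mutations are not supplied
    peaks <- object$peaks
    return(
      ggplot2::ggplot(peaks, ggplot2::aes(x = .data$vaf, y = .data$support)) +
        ggplot2::geom_segment(ggplot2::aes(xend = .data$d_star,
                                           yend = .data$support,
                                           colour = .data$matched)) +
        ggplot2::geom_point(ggplot2::aes(colour = .data$matched)) +
        ggplot2::facet_wrap(~karyotype) +
        ggplot2::labs(x = "expected VAF peak", y = "support") +
        ggplot2::theme_minimal()
    )
  }
  plot_peaks(mutations, object, ...)
}

#' Plot the entropy profile and NA range of a CCF phasing
#'
#' @param object A `vafqc_ccf` from [phase_entropy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vafqc_ccf
#' @export
autoplot.vafqc_ccf <- function(object, ...) {
  est <- object$estimates
  gg <- ggplot2::ggplot(est, ggplot2::aes(x = .data$vaf, y = .data$entropy)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$m)), size = 0.8) +
    ggplot2::labs(x = "VAF", y = "H(z)", colour = "multiplicity") +
    ggplot2::theme_minimal()
  if (!is.null(object$na_range) && !anyNA(object$na_range)) {
    gg <- gg + ggplot2::annotate("rect", xmin = object$na_range[1],
                                 xmax = object$na_range[2],
                                 ymin = -Inf, ymax = Inf, alpha = 0.15,
                                 fill = "firebrick")
  }
  gg
}

#' Plot a calibration FPR grid
#'
#' @param object An `fpr_grid`.
#' @param ... Unused.
#' @return A ggplot object: FPR against tolerance, one panel per cell.
#' @method autoplot fpr_grid
#' @export
autoplot.fpr_grid <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$epsilon, y = .data$fpr)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(purity ~ coverage,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "purity tolerance", y = "false positive rate") +
    ggplot2::theme_minimal()
}
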