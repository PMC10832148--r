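#' Label segments as short or long relative to their arm
#'
#' A segment covering at least a fraction `mu` of its chromosome arm is
#' `"long"`, otherwise `"short"` (boundary counts as long). Segments spanning
#' the centromere are split at the arm boundary by [assign_arms()] before
#' labelling.
#'
#' @param segments Segment data frame (clonal).
#' @param mu Long/short cut as a fraction of arm length (default 0.2).
#' @param build Genome build for arm coordinates.
#' @return Arm-assigned tibble with `seg_length`, `rel_length` and
#'   `length_class` columns.
#' @export
classify_fragment_lengths <- function(segments, mu = 0.2, build = "GRCh38") {
  if (mu <= 0) stop("`mu` must be positive.", call. = FALSE)
  assign_arms(segments, build) |>
    dplyr::mutate(
      seg_length = .data$to - .data$from + 1,
      rel_length = .data$seg_length / .data$arm_length,
      length_class = ifelse(.data$rel_length >= mu, "long", "short")
    )
}

#' Arm-level ploidy jump statistic
#'
#' Sum of absolute differences between the total ploidy (`major + minor`) of
#' consecutive segments on one arm; 0 for a single segment. Arms without
#' copy number activity (small jumps) are not worth testing for
#' over-fragmentation.
#'
#' @param ploidies Integer vector of segment ploidies in genomic order.
#' @return Non-negative jump statistic.
#' @examples
#' ploidy_jump(c(2, 3, 2))  # 2
#' @export
ploidy_jump <- function(ploidies) {
  if (length(ploidies) < 2) return(0)
  sum(abs(diff(ploidies)))
}

#' Exact binomial test for arm over-fragmentation
#'
#' Under the null, each of the `k` segments on an arm is short with
#' probability `mu`; the p-value is the upper tail `P(X >= s)` for the
#' observed number of short segments `s`, with `X ~ Binomial(k, mu)`.
#' Significance is controlled family-wise by Bonferroni: `p < alpha /
#' n_tests`.
#'
#' @param k Number of segments on the arm.
#' @param s Number of short segments.
#' @param mu Null short-segment probability.
#' @param n_tests Number of arms tested (Bonferroni divisor).
#' @param alpha Desired family-wise error rate.
#' @return A one-row tibble: `k`, `s`, `p`, `significant`.
#' @examples
#' arm_fragmentation_test(10, 10, 0.2, n_tests = 1)  # p = 0.2^10
#' @export
arm_fragmentation_test <- function(k, s, mu = 0.2, n_tests = 1, alpha = 0.05) {
  stopifnot(k >= 0, s >= 0, s <= k)
  p <- if (k == 0) NA_real_ else stats::pbinom(s - 1, k, mu, lower.tail = FALSE)
  tibble::tibble(k = k, s = s, p = p,
                 significant = !is.na(p) & p < alpha / n_tests)
}

#' Genome-wide over-fragmentation screen
#'
#' Smooths the segmentation (optional, on by default), assigns segments to
#' chromosome arms, labels them short/long, filters arms by a minimum
#' segment count and a minimum ploidy jump, and runs the one-tailed binomial
#' test per arm with Bonferroni control over the arms actually tested.
#' Over-fragmented arms are a triage signal for chromothripsis-like
#' patterns; the test does not replace dedicated callers.
#'
#' @param segments Clonal segment data frame.
#' @param mu Short-fraction parameter (see [classify_fragment_lengths()]).
#' @param alpha Family-wise error rate.
#' @param min_segments Minimum segments per arm to test (default 10).
#' @param min_jump Minimum arm ploidy jump to test (default 1).
#' @param smooth Merge equal-state contiguous segments first.
#' @param build Genome build.
#' @return Tibble with one row per arm: `arm`, `k`, `s`, `jump`, `tested`,
#'   `p`, `significant`.
#' @export
fragmentation_test <- function(segments, mu = 0.2, alpha = 0.05,
                               min_segments = 10, min_jump = 1,
                               smooth = TRUE, build = "GRCh38") {
  if (smooth) segments <- smooth_segments(segments)
  labelled <- classify_fragment_lengths(segments, mu, build)
  per_arm <- labelled |>
    dplyr::arrange(.data$arm, .data$from) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      k = dplyr::n(),
      s = sum(.data$length_class == "short"),
      jump = ploidy_jump(.data$major + .data$minor),
      .groups = "drop"
    ) |>
    dplyr::mutate(tested = .data$k >= min_segments & .data$jump >= min_jump)
  n_tests <- sum(per_arm$tested)
  per_arm |>
    dplyr::rowwise() |>
    dplyr::mutate(
      p = ifelse(.data$tested,
                 arm_fragmentation_test(.data$k, .data$s, mu, 1, alpha)$p,
                 NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$tested & !is.na(.data$p) &
                    .data$p < alpha / max(n_tests, 1))
}
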