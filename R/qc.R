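#' Match expected peaks to detected data peaks
#'
#' Every expected peak is paired with a data peak according to `strategy`:
#' `"closest"` minimizes the geometric distance, `"right_only"` considers
#' only data peaks to the right of the expected position (useful when
#' hunting miscalled breakpoints, e.g. a diploid call stretching over an LOH
#' region). The expected peak carries a VAF acceptance band -- the image of
#' the two-sided purity tolerance `epsilon` under the peak equation (see
#' [vaf_acceptance_halfwidth()]) -- and the data peak a band of half-width
#' `sigma` (given in purity units and converted through the first-order
#' propagation with the peak's own multiplicity and ploidy). The peak is
#' matched when the two intervals overlap.
#'
#' @param expected Tibble of expected peaks with columns `m`, `vaf` and the
#'   segment allele counts `nA`, `nB`.
#' @param data_peaks Tibble of detected peaks (`position`, `support`).
#' @param purity Input tumor purity.
#' @param epsilon Purity tolerance (> 0).
#' @param sigma Data-peak tolerance in purity units (default 0.02).
#' @param strategy `"closest"` or `"right_only"`.
#' @return `expected` with columns `d_star`, `offset` (`d_star - vaf`),
#'   `band` (expected half-width), `sigma_vaf`, `matched`, `support`,
#'   `offset_purity` (offset converted to purity units).
#' @export
match_peaks <- function(expected, data_peaks, purity, epsilon, sigma = 0.02,
                        strategy = c("closest", "right_only")) {
  strategy <- match.arg(strategy)
  if (epsilon <= 0) stop("`epsilon` must be positive.", call. = FALSE)
  if (nrow(data_peaks) == 0) {
    warning("No data peaks detected; all expected peaks unmatched.")
    return(dplyr::mutate(expected, d_star = NA_real_, offset = NA_real_,
                         band = NA_real_, sigma_vaf = NA_real_,
                         matched = FALSE, support = 0L,
                         offset_purity = NA_real_))
  }
  p <- expected$nA + expected$nB
  res <- purrr::pmap_dfr(
    list(expected$m, expected$vaf, expected$nA, expected$nB),
    function(m, v, nA, nB) {
      cand <- data_peaks$position
      if (strategy == "right_only") cand <- cand[cand > v]
      if (length(cand) == 0) {
        return(tibble::tibble(d_star = NA_real_, support = 0L))
      }
      d <- cand[which.min(abs(cand - v))]
      tibble::tibble(
        d_star = d,
        support = data_peaks$support[match(d, data_peaks$position)]
      )
    }
  )
  expected |>
    dplyr::mutate(
      d_star = res$d_star,
      support = res$support,
      offset = .data$d_star - .data$vaf,
      band = vaf_acceptance_halfwidth(.data$m, .data$nA, .data$nB, purity, epsilon),
      sigma_vaf = vaf_error_from_purity_error(.data$m, p, purity, sigma),
      matched = !is.na(.data$d_star) &
        (.data$d_star - .data$sigma_vaf) <= (.data$vaf + .data$band) &
        (.data$d_star + .data$sigma_vaf) >= (.data$vaf - .data$band),
      offset_purity = ifelse(
        is.na(.data$d_star), NA_real_,
        purity_error_from_vaf_error(.data$vaf, .data$offset, .data$m, p))
    )
}

# Sharpen detected peak positions with the local binomial ML estimate:
# the density argmax is quantized by the read-count lattice, while the
# pooled alt/total ratio of the mutations under the peak converges at the
# usual root-n rate. The window is the smaller of half the distance to the
# neighbouring peak and two binomial standard deviations at the median depth.
# Pooling is only valid when the VAF lattice (spacing 1/depth) is fine
# relative to the kernel bandwidth; on coarser data the window straddles
# resolved read-count atoms and the pooled ratio is biased by up to the
# lattice spacing, so the raw density modes are kept instead.
refine_peak_positions <- function(data_peaks, mutations, min_support = 10L,
                                  bandwidth = 0.01) {
  if (nrow(data_peaks) == 0 || !all(c("nv", "dp") %in% names(mutations))) {
    return(data_peaks)
  }
  med_dp <- max(1, round(stats::median(mutations$dp)))
  if (1 / med_dp > 2 * bandwidth) return(data_peaks)
  pos <- data_peaks$position
  for (i in seq_along(pos)) {
    gap <- if (length(pos) > 1) min(abs(pos[-i] - pos[i])) / 2 else Inf
    r <- min(gap, 2 * sqrt(pos[i] * (1 - pos[i]) / med_dp), 0.1)
    sel <- abs(mutations$vaf - pos[i]) <= r
    if (sum(sel) >= min_support) {
      data_peaks$position[i] <- sum(mutations$nv[sel]) / sum(mutations$dp[sel])
    }
  }
  dplyr::arrange(data_peaks, .data$position)
}

#' QC one simple clonal karyotype
#'
#' Pools the mutations of one simple copy state, detects their VAF peaks,
#' matches every expected multiplicity peak and votes the karyotype status by
#' the peak carrying the most mutations (majority voting weighted by
#' mutation counts).
#'
#' @param mutations Mutation tibble (needs `vaf`; `nv`, `dp` for the mixture
#'   detector).
#' @param nA,nB Allele counts of the karyotype.
#' @param purity,epsilon,sigma See [match_peaks()].
#' @param min_mutations Minimum mutations required to attempt QC.
#' @param peak_method `"kde"` or `"mixture"`.
#' @param strategy Matching strategy.
#' @return A tibble of per-peak rows with `karyotype`, `n_k` (mutations in
#'   the karyotype) and `status` (`"PASS"`/`"FAIL"`), or a zero-row tibble
#'   with attribute `skipped = TRUE` when there are too few mutations.
#' @export
qc_karyotype <- function(mutations, nA, nB, purity, epsilon, sigma = 0.02,
                         min_mutations = 20, peak_method = "kde",
                         strategy = "closest") {
  n_k <- nrow(mutations)
  if (n_k < min_mutations) {
    out <- tibble::tibble()
    attr(out, "skipped") <- TRUE
    return(out)
  }
  expected <- peaks_for_karyotype(nA, nB, purity) |>
    dplyr::mutate(nA = nA, nB = nB)
  data_peaks <- detect_peaks(mutations, method = peak_method)
  data_peaks <- refine_peak_positions(data_peaks, mutations)
  matches <- match_peaks(expected, data_peaks, purity, epsilon, sigma,
                         strategy = strategy)
  # support for the vote: mutations in the 0.01 bin of the matched data peak
  matches$support <- vapply(
    seq_len(nrow(matches)),
    function(i) if (is.na(matches$d_star[i])) 0L
                else count_support(mutations$vaf, matches$d_star[i]),
    integer(1))
  status <- if (matches$matched[which.max(matches$support)]) "PASS" else "FAIL"
  dplyr::mutate(matches, n_k = n_k, status = status)
}

#' Sample-level QC of purity and simple clonal copy number calls
#'
#' Runs [qc_karyotype()] on every simple clonal copy state with enough
#' mutations and assembles the sample score
#' \deqn{\lambda = \sum_{k \in pass} \lambda_k^{PASS} +
#'       \sum_{k \in fail} \lambda_k^{FAIL},}
#' a weighted mean of signed peak offsets converted to purity units (weights
#' are normalized mutation counts per karyotype, split evenly over the
#' karyotype's peaks). The sample passes when the mutation mass carried by
#' pass-status karyotypes is at least the fail-status mass *and* the purity
#' correction `lambda` lies within the tolerance, `|lambda| <= epsilon`; on
#' failure the suggested purity is `purity + lambda`.
#'
#' @param mutations Mapped mutations (see [map_mutations()]); rows with
#'   `class == "simple_clonal"` are used.
#' @param purity Input purity in (0, 1].
#' @param epsilon Purity tolerance.
#' @param sigma Data-peak tolerance in purity units.
#' @param min_mutations Minimum mutations per karyotype.
#' @param peak_method,strategy Passed to [qc_karyotype()].
#' @param by_chromosome When `TRUE`, mutations are pooled per chromosome
#'   instead of genome-wide and a report is returned for each chromosome.
#' @return A `vafqc_report` object (or a named list of them when
#'   `by_chromosome = TRUE`): fields `peaks` (per-peak table), `karyotypes`
#'   (per-state status and scores), `lambda`, `status` (`"PASS"`, `"FAIL"`,
#'   or `"CANNOT_QC"`), `suggested_purity`, `purity`, `epsilon`.
#' @export
qc_sample <- function(mutations, purity, epsilon, sigma = 0.02,
                      min_mutations = 20, peak_method = "kde",
                      strategy = "closest", by_chromosome = FALSE) {
  check_purity(purity)
  if (by_chromosome) {
    chroms <- unique(mutations$chrom)
    out <- lapply(chroms, function(ch) {
      qc_sample(mutations[mutations$chrom == ch, , drop = FALSE],
                purity, epsilon, sigma, min_mutations, peak_method, strategy)
    })
    names(out) <- chroms
    return(out)
  }

  simple <- mutations |>
    dplyr::filter(!is.na(.data$class), .data$class == "simple_clonal")
  karyos <- simple |> dplyr::count(.data$karyotype, .data$major, .data$minor)

  per_k <- purrr::pmap(karyos, function(karyotype, major, minor, n) {
    qc_karyotype(simple[simple$karyotype == karyotype, , drop = FALSE],
                 major, minor, purity, epsilon, sigma,
                 min_mutations, peak_method, strategy)
  })
  skipped <- vapply(per_k, function(x) isTRUE(attr(x, "skipped")), logical(1))
  peaks <- dplyr::bind_rows(per_k[!skipped])

  report <- list(purity = purity, epsilon = epsilon, sigma = sigma,
                 n_mutations = nrow(simple),
                 skipped_karyotypes = karyos$karyotype[skipped])
  if (nrow(peaks) == 0) {
    report$peaks <- tibble::tibble()
    report$karyotypes <- tibble::tibble()
    report$lambda <- NA_real_
    report$status <- "CANNOT_QC"
    report$suggested_purity <- NA_real_
    class(report) <- "vafqc_report"
    return(report)
  }

  total_n <- sum(unique(peaks[, c("karyotype", "n_k")])$n_k)
  peaks <- peaks |>
    dplyr::group_by(.data$karyotype) |>
    dplyr::mutate(weight = (.data$n_k / total_n) / dplyr::n()) |>
    dplyr::ungroup()

  karyotypes <- peaks |>
    dplyr::group_by(.data$karyotype) |>
    dplyr::summarise(
      n = .data$n_k[1],
      status = .data$status[1],
      lambda_pass = sum((.data$weight * .data$offset_purity)[.data$matched],
                        na.rm = TRUE),
      lambda_fail = sum((.data$weight * .data$offset_purity)[!.data$matched],
                        na.rm = TRUE),
      .groups = "drop"
    )
  # Eq-style aggregation: pass karyotypes contribute their matched-peak
  # offsets, fail karyotypes their unmatched-peak offsets
  lam_terms <- peaks |>
    dplyr::mutate(use = (.data$status == "PASS") == .data$matched) |>
    dplyr::filter(.data$use, !is.na(.data$offset_purity))
  lambda <- sum(lam_terms$weight * lam_terms$offset_purity)

  # pass/fail comparison by mutation mass: each karyotype contributes its
  # normalized mutation weight to the side given by its own (majority-vote)
  # status, and the larger side wins
  mass_pass <- sum(peaks$weight[peaks$status == "PASS"])
  mass_fail <- sum(peaks$weight[peaks$status == "FAIL"])
  status <- if (mass_pass >= mass_fail && abs(lambda) <= epsilon) "PASS" else "FAIL"

  report$peaks <- peaks
  report$karyotypes <- karyotypes
  report$lambda <- lambda
  report$score_mass <- c(pass = mass_pass, fail = mass_fail)
  report$status <- status
  report$suggested_purity <- if (status == "FAIL") min(max(purity + lambda, 0), 1) else purity
  class(report) <- "vafqc_report"
  report
}

#' @export
print.vafqc_report <- function(x, ...) {
  cat("VAF-peak QC report\n")
  cat(sprintf("  purity %.3f | epsilon %.3f | %d mutations\n",
              x$purity, x$epsilon, x$n_mutations))
  if (x$status == "CANNOT_QC") {
    cat("  status CANNOT_QC (no karyotype with enough mutations)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$karyotypes))) {
    k <- x$karyotypes[i, ]
    cat(sprintf("  %-5s n=%5d %s\n", k$karyotype, k$n, k$status))
  }
  cat(sprintf("  lambda %+0.4f -> %s", x$lambda, x$status))
  if (x$status == "FAIL") cat(sprintf(" (suggested purity %.3f)", x$suggested_purity))
  cat("\n")
  invisible(x)
}

#' QC a complex clonal karyotype
#'
#' Complex states (`nA:nB` outside the simple set) are screened with the KDE
#' peak detector alone: expected peaks for multiplicities 1 to `max(nA, nB)`
#' are matched with the closest strategy, using the purity tolerance directly
#' as a VAF-space distance cut (no purity-unit conversion). The result is a
#' peak table and the fraction of matched peaks; complex states never
#' contribute to the sample score.
#'
#' @inheritParams qc_karyotype
#' @param tolerance Raw VAF-space matching tolerance.
#' @param min_mutations Minimum mutations (default 150).
#' @return List with `peaks` (one row per multiplicity, `matched` flag) and
#'   `prop_matched`; `NULL` (with attribute `skipped`) when under-powered.
#' @export
qc_complex <- function(mutations, nA, nB, purity, tolerance,
                       min_mutations = 150) {
  if (nrow(mutations) < min_mutations) {
    out <- list(peaks = tibble::tibble(), prop_matched = NA_real_)
    attr(out, "skipped") <- TRUE
    return(out)
  }
  expected <- peaks_for_karyotype(nA, nB, purity)
  data_peaks <- kde_peaks(mutations$vaf)
  expected$d_star <- vapply(expected$vaf, function(v) {
    if (nrow(data_peaks) == 0) return(NA_real_)
    data_peaks$position[which.min(abs(data_peaks$position - v))]
  }, numeric(1))
  expected$offset <- expected$d_star - expected$vaf
  expected$matched <- !is.na(expected$d_star) & abs(expected$offset) <= tolerance
  list(peaks = expected,
       prop_matched = if (nrow(data_peaks) == 0) 0 else mean(expected$matched))
}

#' QC a two-subclone segment against its evolution models
#'
#' Enumerates every linear and branching evolution model compatible with the
#' two simple copy states (see [enumerate_evolution_models()]), predicts each
#' model's shared and private VAF peaks, and matches them against the KDE
#' peaks of the segment's mutations with a raw VAF-space tolerance. The model
#' with the highest fraction of matched peaks is selected; models predicting
#' identical peak sets are reported jointly as `"indistinguishable"`, a tie
#' between genuinely different peak sets is `"ambiguous"`, and if no model
#' matches at least half of its peaks the call is `"none"`.
#'
#' @param mutations Mutations on the subclonal segment.
#' @param state1,state2 Simple copy states of the two clones.
#' @param rho1 Proportion of clone 1 (clone 2 has `1 - rho1`).
#' @param purity Tumor purity.
#' @param tolerance Raw VAF matching tolerance.
#' @param min_mutations Minimum mutations (default 150).
#' @param ancestor Ancestral state for model enumeration.
#' @return List with `models` (per-model table: description, topology,
#'   `prop_matched`, peak table in a list-column), `best` (row indices of the
#'   winning model(s)) and `status` (`"selected"`, `"indistinguishable"`,
#'   `"ambiguous"`, `"none"`, or `"skipped"`).
#' @export
qc_subclonal <- function(mutations, state1, state2, rho1, purity,
                         tolerance = 0.03, min_mutations = 150,
                         ancestor = "1:1") {
  if (nrow(mutations) < min_mutations) {
    return(list(models = tibble::tibble(), best = integer(), status = "skipped"))
  }
  models <- enumerate_evolution_models(state1, state2, ancestor)
  if (nrow(models) == 0) {
    return(list(models = tibble::tibble(), best = integer(), status = "none"))
  }
  data_peaks <- kde_peaks(mutations$vaf)
  evals <- purrr::map(seq_len(nrow(models)), function(i) {
    pk <- subclonal_expected_peaks(models[i, ], rho1, 1 - rho1, purity)
    pk$d_star <- vapply(pk$vaf, function(v) {
      if (nrow(data_peaks) == 0) return(NA_real_)
      data_peaks$position[which.min(abs(data_peaks$position - v))]
    }, numeric(1))
    pk$matched <- !is.na(pk$d_star) & abs(pk$d_star - pk$vaf) <= tolerance
    pk
  })
  models$peak_table <- evals
  models$prop_matched <- vapply(evals, function(p) mean(p$matched), numeric(1))
  best_prop <- max(models$prop_matched)
  best <- which(models$prop_matched == best_prop)
  status <- if (best_prop < 0.5) {
    "none"
  } else if (length(best) == 1) {
    "selected"
  } else {
    # tied models with identical peak positions are one equivalence class
    sets <- lapply(best, function(i) sort(round(models$peak_table[[i]]$vaf, 6)))
    if (all(vapply(sets, identical, logical(1), sets[[1]]))) "indistinguishable"
    else "ambiguous"
  }
  list(models = models, best = best, status = status)
}
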