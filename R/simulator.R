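#' Configuration for the synthetic tumor simulator
#'
#' Captures the generative design used throughout testing and calibration:
#' per-chromosome segment counts are Poisson (mean 6), allele-specific copy
#' states are drawn with concentration weights 1, 1, 6, 2, 1 over
#' 1:0, 2:0, 1:1, 2:1, 2:2 (the relative frequencies of simple states in
#' large pan-cancer cohorts), read depth is Poisson around the target
#' coverage and alt counts are binomial at the theoretical clonal peak for a
#' uniformly drawn legal multiplicity.
#'
#' @param purity True tumor purity.
#' @param coverage Mean sequencing depth.
#' @param segs_per_chrom Poisson mean of segments per chromosome.
#' @param karyotype_weights Named weights over the simple states.
#' @param mutations_per_mb Mutation rate per megabase.
#' @param n_chrom Number of autosomes simulated (1..22, real GRCh38 lengths);
#'   scale down for fast simulation studies.
#' @param min_alt_reads Detection floor: simulated mutations with fewer alt
#'   reads are dropped, mimicking a variant caller's minimum read support
#'   (no real call set contains variants with 0--1 supporting reads).
#' @param subclonal Optional list describing one two-subclone segment:
#'   fields `state1`, `state2`, `rho1`, `model` (row index into
#'   [enumerate_evolution_models()] output or a one-row model), `n_mutations`
#'   (total on the segment), `chrom` (chromosome it replaces).
#' @param seed Integer seed; the output is byte-identical for equal seeds.
#' @return A `sim_config` list.
#' @export
sim_config <- function(purity = 0.8, coverage = 90, segs_per_chrom = 6,
                       karyotype_weights = c("1:0" = 1, "2:0" = 1, "1:1" = 6,
                                             "2:1" = 2, "2:2" = 1),
                       mutations_per_mb = 1, n_chrom = 22,
                       min_alt_reads = 2L, subclonal = NULL, seed = 1) {
  check_purity(purity)
  stopifnot(coverage > 0, segs_per_chrom > 0, mutations_per_mb > 0,
            n_chrom >= 1, n_chrom <= 22, all(karyotype_weights > 0),
            min_alt_reads >= 0)
  structure(list(purity = purity, coverage = coverage,
                 segs_per_chrom = segs_per_chrom,
                 karyotype_weights = karyotype_weights,
                 mutations_per_mb = mutations_per_mb, n_chrom = n_chrom,
                 min_alt_reads = as.integer(min_alt_reads),
                 subclonal = subclonal, seed = seed),
            class = "sim_config")
}

#' Simulate a synthetic tumor (read counts + segments)
#'
#' Draws a clonal allele-specific segmentation and somatic mutation read
#' counts under the model of [sim_config()]. Each mutation's alt count is
#' `Binomial(dp, v_m)` with `v_m` the clonal peak of its segment state and
#' multiplicity; an optional two-subclone segment places shared and private
#' mutations at the peaks implied by its evolution model.
#'
#' @param config A [sim_config()] object.
#' @return List with `mutations` (tibble: chrom, pos, ref, alt, nv, dp, vaf,
#'   true multiplicity `m_true`), `segments` (tibble), and `purity`.
#' @export
simulate_tumor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  purity <- config$purity
  chrom_lengths <- grch38_autosome_lengths()[seq_len(config$n_chrom)]
  states <- names(config$karyotype_weights)
  probs <- config$karyotype_weights / sum(config$karyotype_weights)

  seg_list <- list(); mut_list <- list()
  for (ci in seq_along(chrom_lengths)) {
    chrom <- names(chrom_lengths)[ci]
    len <- chrom_lengths[[ci]]
    sub <- config$subclonal
    if (!is.null(sub) && identical(sub$chrom, chrom)) {
      out <- simulate_subclonal_chrom(chrom, len, sub, purity, config$coverage)
      seg_list[[ci]] <- out$segments; mut_list[[ci]] <- out$mutations
      next
    }
    n_seg <- max(1L, stats::rpois(1, config$segs_per_chrom))
    bp <- sort(sample.int(len - 1, n_seg - 1))
    from <- c(1, bp + 1); to <- c(bp, len)
    st <- sample(states, n_seg, replace = TRUE, prob = probs)
    ab <- do.call(rbind, lapply(st, parse_karyotype))
    segs <- tibble::tibble(chrom = chrom, from = from, to = to,
                           major = ab[, 1], minor = ab[, 2])
    seg_list[[ci]] <- segs
    muts <- purrr::pmap_dfr(segs, function(chrom, from, to, major, minor) {
      n_mut <- stats::rpois(1, (to - from + 1) / 1e6 * config$mutations_per_mb)
      if (n_mut == 0) return(tibble::tibble())
      m <- sample(multiplicity_set(major, minor), n_mut, replace = TRUE)
      v <- expected_vaf(m, major, minor, purity)
      dp <- pmax(1L, stats::rpois(n_mut, config$coverage))
      tibble::tibble(
        chrom = chrom,
        pos = sort(sample(from:to, n_mut, replace = FALSE)),
        ref = "N", alt = "A",
        nv = stats::rbinom(n_mut, dp, v), dp = dp, m_true = m
      )
    })
    mut_list[[ci]] <- muts
  }
  segments <- dplyr::bind_rows(seg_list)
  mutations <- dplyr::bind_rows(mut_list)
  # detection floor: a caller never emits variants with too few alt reads
  floor_reads <- config$min_alt_reads %||% 2L
  mutations <- mutations[mutations$nv >= floor_reads, , drop = FALSE]
  mutations$vaf <- mutations$nv / mutations$dp
  # flag configurations whose peaks drop under the detection floor
  all_states <- unique(segments[, c("major", "minor")])
  min_peak <- min(expected_vaf(1, all_states$major, all_states$minor, purity))
  if (min_peak < 0.03) {
    warning(sprintf("Lowest expected peak %.3f is under the 0.03 detection floor.",
                    min_peak))
  }
  list(mutations = mutations, segments = segments, purity = purity)
}

simulate_subclonal_chrom <- function(chrom, len, sub, purity, coverage) {
  models <- enumerate_evolution_models(sub$state1, sub$state2)
  model <- if (is.numeric(sub$model)) models[sub$model, ] else sub$model
  peaks <- subclonal_expected_peaks(model, sub$rho1, 1 - sub$rho1, purity)
  s1 <- parse_karyotype(sub$state1); s2 <- parse_karyotype(sub$state2)
  segs <- tibble::tibble(chrom = chrom, from = 1, to = len,
                         major = s1[1], minor = s1[2],
                         major2 = s2[1], minor2 = s2[2], ccf1 = sub$rho1)
  n_per_peak <- pmax(1L, round(sub$n_mutations / nrow(peaks)))
  mut <- purrr::pmap_dfr(peaks, function(vaf, ...) {
    dp <- pmax(1L, stats::rpois(n_per_peak, coverage))
    tibble::tibble(ref = "N", alt = "A",
                   nv = stats::rbinom(n_per_peak, dp, vaf), dp = dp,
                   m_true = NA_integer_)
  })
  mut$chrom <- chrom
  mut$pos <- sort(sample.int(len, nrow(mut)))
  list(segments = segs, mutations = mut[, c("chrom", "pos", "ref", "alt",
                                            "nv", "dp", "m_true")])
}

#' Corrupt a purity estimate by a known error
#'
#' @param purity True purity.
#' @param phi Additive error.
#' @return `purity + phi` clipped to (0.01, 1\] (with a warning on clipping).
#' @examples
#' corrupt_purity(0.8, -0.1)  # 0.7
#' @export
corrupt_purity <- function(purity, phi) {
  out <- purity + phi
  if (out > 1 || out <= 0.01) {
    warning("Corrupted purity clipped into (0.01, 1].")
    out <- min(max(out, 0.01), 1)
  }
  out
}

grch38_autosome_lengths <- function() {
  arms <- readr::read_tsv(
    system.file("extdata", "arms_grch38.tsv", package = "vafqc"),
    show_col_types = FALSE)
  arms <- arms[arms$chrom %in% paste0("chr", 1:22), ]
  stats::setNames(as.list(arms$length), arms$chrom)
}
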