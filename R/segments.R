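#' Classify allele-specific segments into the QC taxonomy
#'
#' Segments are grouped by how their VAF peaks can be validated:
#' * `simple_clonal` -- clonal states reachable from diploid 1:1 in one
#'   evolutionary step: 1:0, 1:1, 2:0, 2:1, 2:2. These drive the sample-level
#'   purity score.
#' * `complex_clonal` -- any other clonal `nA:nB` state (e.g. 3:2, 4:0, 6:1).
#' * `subclonal_simple` -- two-subclone rows where both clones carry simple
#'   states.
#' * `unsupported` -- subclonal rows with any clone outside the simple set.
#'
#' @param segments A data frame with columns `chrom`, `from`, `to`, `major`,
#'   `minor`, and optionally `major2`, `minor2`, `ccf1` for two-subclone rows
#'   (clone proportions `ccf1` and `1 - ccf1`).
#' @return The input as a tibble with added columns `karyotype` (e.g.
#'   `"2:1"`, or `"1:1-2:1"` for subclonal rows) and `class`.
#' @examples
#' classify_segments(data.frame(chrom = "chr1", from = 1, to = 1e7,
#'                              major = 2, minor = 1))
#' @export
classify_segments <- function(segments) {
  segments <- validate_segments(segments)
  simple <- c("1:0", "1:1", "2:0", "2:1", "2:2")
  k1 <- paste0(segments$major, ":", segments$minor)
  subclonal <- !is.na(segments$major2)
  k2 <- ifelse(subclonal, paste0(segments$major2, ":", segments$minor2), NA)
  segments$karyotype <- ifelse(subclonal, paste0(k1, "-", k2), k1)
  segments$class <- dplyr::case_when(
    !subclonal & k1 %in% simple ~ "simple_clonal",
    !subclonal ~ "complex_clonal",
    k1 %in% simple & k2 %in% simple ~ "subclonal_simple",
    TRUE ~ "unsupported"
  )
  segments
}

validate_segments <- function(segments) {
  segments <- tibble::as_tibble(segments)
  req <- c("chrom", "from", "to", "major", "minor")
  missing <- setdiff(req, names(segments))
  if (length(missing) > 0) {
    stop("Segments are missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"major2" %in% names(segments)) segments$major2 <- NA_integer_
  if (!"minor2" %in% names(segments)) segments$minor2 <- NA_integer_
  if (!"ccf1" %in% names(segments)) segments$ccf1 <- NA_real_
  with(segments, {
    check_allele_counts(major, minor)
    sub <- !is.na(major2)
    if (any(sub)) check_allele_counts(major2[sub], minor2[sub])
    if (any(major < minor)) stop("Segments must satisfy major >= minor.", call. = FALSE)
    if (any(from > to)) stop("Segments must satisfy from <= to.", call. = FALSE)
    if (any(sub & (is.na(ccf1[sub]) | ccf1[sub] <= 0 | ccf1[sub] >= 1))) {
      stop("Subclonal rows need clone proportion ccf1 in (0, 1).", call. = FALSE)
    }
  })
  if (!"segment_id" %in% names(segments)) {
    segments$segment_id <- paste0("seg_", seq_len(nrow(segments)))
  }
  # overlapping segmentations are a caller error, not silently resolved
  by_chr <- split(segments, segments$chrom)
  for (s in by_chr) {
    s <- s[order(s$from), , drop = FALSE]
    if (nrow(s) > 1 && any(s$from[-1] <= s$to[-nrow(s)])) {
      stop("Overlapping segments on ", s$chrom[1], "; fix the segmentation.", call. = FALSE)
    }
  }
  segments
}

#' Map somatic mutations onto copy number segments
#'
#' Assigns every mutation to the segment whose 1-based, fully closed span
#' `[from, to]` contains its position (boundary positions included).
#' Mutations outside all segments are kept and flagged unassigned.
#'
#' @param mutations A data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `nv` (alt-supporting reads), `dp` (total depth); `vaf` is (re)computed
#'   as `nv / dp`.
#' @param segments A segment data frame (see [classify_segments()]).
#' @return The mutations as a tibble with `segment_id`, `karyotype`, `class`
#'   (NA when unassigned).
#' @export
map_mutations <- function(mutations, segments) {
  mutations <- validate_mutations(mutations)
  segments <- classify_segments(segments)
  seg_cols <- segments[, c("chrom", "from", "to", "segment_id", "karyotype", "class",
                           "major", "minor", "major2", "minor2", "ccf1")]
  hit <- dplyr::left_join(
    mutations, seg_cols,
    by = dplyr::join_by("chrom", "pos" >= "from", "pos" <= "to")
  )
  hit$from <- NULL; hit$to <- NULL
  stopifnot(nrow(hit) == nrow(mutations))   # non-overlap guarantees uniqueness
  hit
}

validate_mutations <- function(mutations) {
  mutations <- tibble::as_tibble(mutations)
  req <- c("chrom", "pos", "ref", "alt", "nv", "dp")
  missing <- setdiff(req, names(mutations))
  if (length(missing) > 0) {
    stop("Mutations are missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- with(mutations, nv > dp | nv < 0 | dp < 1 | pos < 1)
  if (any(bad)) {
    stop(sum(bad), " mutation row(s) violate nv <= dp, nv >= 0, dp >= 1, pos >= 1 ",
         "(first bad row: ", which(bad)[1], ").", call. = FALSE)
  }
  mutations$vaf <- mutations$nv / mutations$dp   # counts are the source of truth
  mutations
}

#' Merge contiguous clonal segments with identical allele-specific state
#'
#' Copy number callers often break a constant stretch of genome into several
#' segments without any change in the called `major:minor` state; those extra
#' breakpoints inflate the over-fragmentation test. Smoothing merges adjacent
#' same-chromosome clonal segments with identical `(major, minor)` whenever
#' the gap between them does not exceed `max_gap` (default 1 Mb). The ploidy
#' profile over covered bases is unchanged and the operation is idempotent.
#'
#' @param segments Clonal segment data frame.
#' @param max_gap Maximum inter-segment gap (bases) to merge across.
#' @return Smoothed tibble of segments.
#' @export
smooth_segments <- function(segments, max_gap = 1e6) {
  segments <- validate_segments(segments)
  if (any(!is.na(segments$major2))) {
    stop("smooth_segments() applies to clonal segments only.", call. = FALSE)
  }
  segments |>
    dplyr::arrange(.data$chrom, .data$from) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      new_run = dplyr::row_number() == 1 |
        .data$major != dplyr::lag(.data$major) |
        .data$minor != dplyr::lag(.data$minor) |
        (.data$from - dplyr::lag(.data$to) - 1) > max_gap,
      run = cumsum(.data$new_run)
    ) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(
      from = min(.data$from), to = max(.data$to),
      major = .data$major[1], minor = .data$minor[1],
      .groups = "drop"
    ) |>
    dplyr::select(-"run") |>
    validate_segments()
}

#' Decompose a fractional copy number call into two integer subclones
#'
#' Some callers report fractional (non-integer) minor and total copy numbers
#' on putatively heterogeneous segments, together with an integer solution
#' (`mCN1`, `CN1`) and the segment's minor allele frequency (MAF). Assuming a
#' two-subclone mixture, each candidate integer minor copy number `mCN2` on a
#' grid implies a clone-1 proportion
#' \deqn{\rho_1 = (mCNF - mCN_1) / (mCN_2 - mCN_1),}
#' a second total copy number
#' \deqn{CN_2 = [CNF - (1 - \rho_1) CN_1] / \rho_1,}
#' and a MAF error
#' \deqn{|MAF - \pi(\rho_1\eta_1 + (1-\rho_1)\eta_2) - (1-\pi)/2|,
#'   \quad \eta_i = mCN_i / CN_i.}
#' Candidates with `rho1` outside (0, 1), with `CN2 < 2 mCN2` (minor above
#' half the total), or with MAF error at or above `err_tol` are discarded;
#' the surviving candidate with minimal MAF error is returned.
#'
#' @param mCNF,CNF Fractional minor and total copy number from the caller.
#' @param MAF Minor allele frequency of the segment.
#' @param mCN1,CN1 Integer minor and total copy number of subclone 1.
#' @param purity Tumor purity in (0, 1].
#' @param grid_max Largest candidate `mCN2` (grid is 0:grid_max, skipping
#'   `mCN1`, which would divide by zero).
#' @param err_tol MAF-error acceptance threshold.
#' @return A one-row tibble `mCN2`, `CN2`, `rho1`, `maf_err` for the selected
#'   solution, or a zero-row tibble when no candidate survives. The full
#'   candidate grid is attached as attribute `"grid"`.
#' @export
decompose_fractional_cn <- function(mCNF, CNF, MAF, mCN1, CN1, purity,
                                    grid_max = 10, err_tol = 0.1) {
  check_purity(purity)
  if (CN1 == 0) stop("CN1 must be positive.", call. = FALSE)
  if (grid_max < 1) stop("Degenerate mCN2 grid.", call. = FALSE)
  grid <- setdiff(0:grid_max, mCN1)
  cand <- tibble::tibble(mCN2 = grid) |>
    dplyr::mutate(
      rho1 = (mCNF - mCN1) / (.data$mCN2 - mCN1),
      CN2 = (CNF - (1 - .data$rho1) * CN1) / .data$rho1,
      eta1 = mCN1 / CN1,
      eta2 = .data$mCN2 / .data$CN2,
      maf_err = abs(MAF - purity * (.data$rho1 * .data$eta1 +
                                      (1 - .data$rho1) * .data$eta2) -
                      (1 - purity) * 0.5),
      valid = .data$rho1 > 0 & .data$rho1 < 1 &
        .data$CN2 >= 2 * .data$mCN2 & .data$maf_err < err_tol
    )
  ok <- cand[cand$valid, , drop = FALSE]
  sol <- if (nrow(ok) == 0) {
    ok[, c("mCN2", "CN2", "rho1", "maf_err")]
  } else {
    ok[which.min(ok$maf_err), c("mCN2", "CN2", "rho1", "maf_err")]
  }
  attr(sol, "grid") <- cand
  sol
}

#' Chromosome arm coordinates for a genome build
#'
#' Returns the bundled arm table (UCSC chromosome lengths with approximate
#' centromere spans) used to assign segments to arms.
#'
#' @param build `"GRCh38"` or `"hg19"`.
#' @return A tibble with `chrom`, `length`, `centromere_start`,
#'   `centromere_end`, plus derived `p_from`, `p_to`, `q_from`, `q_to`.
#' @export
arm_coordinates <- function(build = c("GRCh38", "hg19")) {
  build <- match.arg(build)
  path <- system.file("extdata",
                      paste0("arms_", tolower(build), ".tsv"), package = "vafqc")
  readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::mutate(
      p_from = 1, p_to = .data$centromere_start - 1,
      q_from = .data$centromere_end + 1, q_to = .data$length
    )
}

#' Split segments at arm boundaries and label them with arm ids
#'
#' Segments spanning the centromere are split at the arm boundary; each piece
#' is labelled `1p`, `1q`, etc. Coordinates are 1-based and fully closed.
#'
#' @param segments Segment data frame.
#' @param build Genome build for [arm_coordinates()].
#' @return Tibble of (possibly split) segments with columns `arm` and
#'   `arm_length` added.
#' @export
assign_arms <- function(segments, build = "GRCh38") {
  segments <- validate_segments(segments)
  arms <- arm_coordinates(build)
  long <- dplyr::bind_rows(
    dplyr::transmute(arms, chrom = .data$chrom,
                     arm = paste0(sub("^chr", "", .data$chrom), "p"),
                     arm_from = .data$p_from, arm_to = .data$p_to),
    dplyr::transmute(arms, chrom = .data$chrom,
                     arm = paste0(sub("^chr", "", .data$chrom), "q"),
                     arm_from = .data$q_from, arm_to = .data$q_to)
  )
  out <- dplyr::inner_join(segments, long, by = "chrom",
                           relationship = "many-to-many") |>
    dplyr::filter(.data$from <= .data$arm_to, .data$to >= .data$arm_from) |>
    dplyr::mutate(
      from = pmax(.data$from, .data$arm_from),
      to = pmin(.data$to, .data$arm_to),
      arm_length = .data$arm_to - .data$arm_from + 1
    ) |>
    dplyr::select(-"arm_from", -"arm_to")
  out
}
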