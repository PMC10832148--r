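#' Read somatic mutations from VCF or TSV
#'
#' TSV input needs the header `chrom,pos,ref,alt,NV,DP` (tab-separated). VCF
#' input takes alt/total read counts from the `AD` FORMAT field (ref,alt
#' depths; depth is their sum) or from `NV` + `DP`; multi-allelic records
#' are split into one row per alternate allele. VAF is always recomputed
#' from the counts. Indels (`nchar(ref) != nchar(alt)`) are flagged so they
#' can be excluded -- VAFs of indels are prone to alignment noise and peak
#' QC is best run on SNVs.
#'
#' @param path File path (`.vcf`, `.vcf.gz`, or tabular).
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @param sample For multi-sample VCFs, the sample column to use (default:
#'   first).
#' @return Validated mutation tibble with `chrom`, `pos`, `ref`, `alt`,
#'   `nv`, `dp`, `vaf`, `is_indel`.
#' @export
read_mutations <- function(path, format = c("auto", "vcf", "tsv"),
                           sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  out <- if (format == "vcf") read_mutations_vcf(path, sample) else read_mutations_tsv(path)
  out$is_indel <- nchar(out$ref) != nchar(out$alt)
  validate_mutations(out)
}

read_mutations_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  names(tab) <- tolower(names(tab))
  req <- c("chrom", "pos", "ref", "alt", "nv", "dp")
  if (!all(req %in% names(tab))) {
    stop("Mutation TSV needs columns chrom, pos, ref, alt, NV, DP.", call. = FALSE)
  }
  bad <- which(tab$nv > tab$dp | tab$nv < 0 | tab$dp < 1)
  if (length(bad) > 0) {
    stop("Rejected ", length(bad), " malformed mutation row(s) (NV > DP or DP < 1): ",
         "data lines ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "", call. = FALSE)
  }
  tab[, req]
}

read_mutations_vcf <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("Reading VCF requires the vcfR package.", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  has_ad <- "AD" %in% fmt_keys
  has_nvdp <- all(c("NV", "DP") %in% fmt_keys)
  if (!has_ad && !has_nvdp) {
    stop("VCF lacks read-count FORMAT fields: need AD, or NV and DP.", call. = FALSE)
  }
  pick <- function(key) {
    m <- vcfR::extract.gt(v, element = key)
    if (is.null(sample)) m[, 1] else m[, sample]
  }
  rows <- list()
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  if (has_ad) {
    ad <- strsplit(pick("AD"), ",", fixed = TRUE)
    for (i in seq_len(nrow(fix))) {
      depths <- suppressWarnings(as.integer(ad[[i]]))
      for (j in seq_along(alts[[i]])) {       # split multi-allelic records
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[[i]][j],
          nv = depths[j + 1], dp = sum(depths, na.rm = TRUE))
      }
    }
  } else {
    nv <- suppressWarnings(as.integer(pick("NV")))
    dp <- suppressWarnings(as.integer(pick("DP")))
    for (i in seq_len(nrow(fix))) {
      for (j in seq_along(alts[[i]])) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[[i]][j], nv = nv[i], dp = dp[i])
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Read allele-specific segments from TSV
#'
#' Expects the header `chrom,from,to,Major,minor` with optional
#' `Major2,minor2,ccf1` columns for two-subclone rows. Coordinates are
#' 1-based, fully closed.
#'
#' @param path File path.
#' @return Validated segment tibble.
#' @export
read_segments <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  names(tab) <- tolower(names(tab))
  validate_segments(tab)
}

#' Write mutation / segment tables in the dialects the readers consume
#'
#' @param x Mutation or segment tibble.
#' @param path Output file.
#' @name write_tables
#' @return `path`, invisibly.
#' @export
write_mutations <- function(x, path) {
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(x), chrom = "chrom", pos = "pos",
                  ref = "ref", alt = "alt", NV = "nv", DP = "dp"), path)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_segments <- function(x, path) {
  x <- tibble::as_tibble(x)
  cols <- c(chrom = "chrom", from = "from", to = "to",
            Major = "major", minor = "minor")
  if ("major2" %in% names(x) && any(!is.na(x$major2))) {
    cols <- c(cols, Major2 = "major2", minor2 = "minor2", ccf1 = "ccf1")
  }
  readr::write_tsv(dplyr::select(x, dplyr::all_of(cols)), path)
  invisible(path)
}

#' Write a machine-readable QC report
#'
#' Serializes a [qc_sample()] report (plus optional CCF estimates and
#' fragmentation table) to JSON with a schema version; statuses and the
#' purity-correction score are rounded to 4 decimals. The companion exit
#' code for pipeline integration is 0 (pass), 3 (fail) or 2 (cannot QC).
#'
#' @param report A `vafqc_report`.
#' @param path Output JSON path.
#' @param ccf Optional `vafqc_ccf` object or list of them.
#' @param fragmentation Optional [fragmentation_test()] tibble.
#' @param config Optional run configuration list to embed.
#' @return The exit code, invisibly.
#' @export
write_report <- function(report, path, ccf = NULL, fragmentation = NULL,
                         config = NULL) {
  stopifnot(inherits(report, "vafqc_report"))
  obj <- list(
    schema_version = "1.0",
    status = report$status,
    purity = report$purity,
    epsilon = report$epsilon,
    lambda = if (is.na(report$lambda)) NULL else round(report$lambda, 4),
    suggested_purity = if (is.na(report$suggested_purity)) NULL
                       else round(report$suggested_purity, 4),
    n_mutations = report$n_mutations,
    karyotypes = report$karyotypes,
    peaks = if (nrow(report$peaks %||% tibble::tibble()) > 0) {
      dplyr::mutate(report$peaks, dplyr::across(dplyr::where(is.numeric),
                                                ~ round(.x, 4)))
    } else NULL,
    skipped_karyotypes = report$skipped_karyotypes,
    config = config
  )
  if (!is.null(ccf)) {
    if (inherits(ccf, "vafqc_ccf")) ccf <- list(ccf)
    obj$ccf <- lapply(ccf, function(cc) list(
      karyotype = cc$karyotype,
      qc = ccf_qc(cc),
      na_range = cc$na_range))
  }
  if (!is.null(fragmentation)) obj$fragmentation <- fragmentation
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(switch(report$status, PASS = 0L, FAIL = 3L, CANNOT_QC = 2L))
}

#' Write per-mutation CCF estimates as TSV
#'
#' @param ccf A `vafqc_ccf` object.
#' @param path Output path.
#' @param na_cutoff QC cutoff passed to [ccf_qc()].
#' @return `path`, invisibly.
#' @export
write_ccf <- function(ccf, path, na_cutoff = 0.10) {
  stopifnot(inherits(ccf, "vafqc_ccf"))
  status <- ccf_qc(ccf, na_cutoff)$status
  kary <- ccf$karyotype
  est <- ccf$estimates |>
    dplyr::mutate(mutation_id = paste0(.data$chrom, ":", .data$pos, "_",
                                       .data$ref, ">", .data$alt),
                  karyotype = kary, qc_status = status) |>
    dplyr::select("mutation_id", "karyotype", "m", "z1", "z2",
                  H = "entropy", "ccf", "method", "qc_status")
  readr::write_tsv(est, path)
  invisible(path)
}
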