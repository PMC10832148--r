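# small shared fixtures built in code

tiny_segments <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    from = c(1, 201, 1),
    to = c(200, 500, 300),
    major = c(1, 2, 2),
    minor = c(1, 1, 0)
  )
}

tiny_mutations <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
    pos = c(100, 200, 300, 150, 50),
    ref = "A", alt = "T",
    nv = c(40, 50, 30, 60, 10),
    dp = c(100, 100, 100, 100, 100)
  )
}

# binomial draws around one or more expected peaks
peaky_mutations <- function(peaks, n_per_peak, coverage = 100, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(peaks, function(p) {
    dp <- pmax(1L, stats::rpois(n_per_peak, coverage))
    tibble::tibble(chrom = "chr1", ref = "N", alt = "A",
                   nv = stats::rbinom(n_per_peak, dp, p), dp = dp)
  }) |>
    dplyr::mutate(pos = dplyr::row_number(), vaf = nv / dp)
}
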