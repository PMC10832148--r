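test_that("segments are classified into the QC taxonomy", {
  segs <- tibble::tibble(
    chrom = paste0("chr", 1:4), from = 1, to = 100,
    major = c(2, 3, 1, 2), minor = c(1, 2, 1, 1),
    major2 = c(NA, NA, 2, 3), minor2 = c(NA, NA, 1, 2),
    ccf1 = c(NA, NA, 0.6, 0.5)
  )
  out <- classify_segments(segs)
  expect_equal(out$class,
               c("simple_clonal", "complex_clonal", "subclonal_simple",
                 "unsupported"))
  expect_equal(out$karyotype[1], "2:1")
  expect_equal(out$karyotype[3], "1:1-2:1")
  expect_error(classify_segments(dplyr::mutate(segs, major = c(-1, 3, 1, 2))),
               "non-negative integers")
  expect_error(classify_segments(dplyr::mutate(segs, minor = major + 1)),
               "major >= minor")
})

test_that("mutation mapping respects closed intervals and conserves counts", {
  mapped <- map_mutations(tiny_mutations(), tiny_segments())
  expect_equal(nrow(mapped), nrow(tiny_mutations()))
  expect_equal(mapped$karyotype, c("1:1", "1:1", "2:1", "2:0", NA))
  # boundary position pos == to is assigned (inclusive span)
  expect_false(is.na(mapped$segment_id[2]))
  # unassigned mutations flagged, not dropped
  expect_true(is.na(mapped$segment_id[5]))
  expect_equal(sum(!is.na(mapped$segment_id)) + sum(is.na(mapped$segment_id)),
               nrow(tiny_mutations()))
})

test_that("overlapping segmentations are rejected", {
  segs <- tibble::tibble(chrom = "chr1", from = c(1, 150), to = c(200, 400),
                         major = c(1, 2), minor = c(1, 1))
  expect_error(map_mutations(tiny_mutations(), segs), "Overlapping")
})

test_that("mutation records are validated and VAF recomputed from counts", {
  bad <- dplyr::mutate(tiny_mutations(), nv = c(40, 150, 30, 60, 10))
  expect_error(map_mutations(bad, tiny_segments()), "nv <= dp")
  withvaf <- dplyr::mutate(tiny_mutations(), vaf = 99)
  expect_equal(map_mutations(withvaf, tiny_segments())$vaf[1], 0.4)
})

test_that("smoothing merges equal-state neighbours within the gap", {
  segs <- tibble::tibble(
    chrom = "chr1", from = c(1, 150, 400), to = c(100, 300, 500),
    major = c(1, 1, 2), minor = c(1, 1, 1))
  sm <- smooth_segments(segs, max_gap = 1e6)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$from[1], 1)
  expect_equal(sm$to[1], 300)
  # different state: unchanged
  segs2 <- tibble::tibble(chrom = "chr1", from = c(1, 150), to = c(100, 300),
                          major = c(1, 2), minor = c(1, 1))
  expect_equal(nrow(smooth_segments(segs2)), 2)
  # gap above the cut: unchanged
  segs3 <- tibble::tibble(chrom = "chr1", from = c(1, 2e6), to = c(100, 3e6),
                          major = 1, minor = 1)
  expect_equal(nrow(smooth_segments(segs3, max_gap = 1e6)), 2)
})

test_that("smoothing preserves covered bases per state and is idempotent", {
  set.seed(7)
  n <- 30
  bp <- sort(sample.int(1e6, 2 * n))
  segs <- tibble::tibble(chrom = "chr1",
                         from = bp[seq(1, 2 * n, 2)], to = bp[seq(2, 2 * n, 2)],
                         major = sample(1:2, n, TRUE), minor = 1)
  covered <- function(s) {
    s |> dplyr::group_by(.data$major, .data$minor) |>
      dplyr::summarise(bases = sum(to - from + 1), .groups = "drop") |>
      dplyr::arrange(.data$major)
  }
  sm1 <- smooth_segments(segs, max_gap = 0)   # merge only exact neighbours
  expect_equal(covered(sm1), covered(segs))
  sm2 <- smooth_segments(sm1, max_gap = 0)
  expect_equal(sm1, sm2)
})

test_that("fractional copy number decomposes into the documented grid", {
  sol <- decompose_fractional_cn(mCNF = 1.8, CNF = 4.2, MAF = 0.4,
                                 mCN1 = 1, CN1 = 3, purity = 1,
                                 grid_max = 6)
  grid <- attr(sol, "grid")
  sub <- grid[grid$mCN2 %in% 2:6, ]
  expect_equal(round(sub$rho1, 3), c(0.8, 0.4, 0.267, 0.2, 0.16))
  expect_equal(sub$CN2[sub$mCN2 == 3], 6)
  # CN2 < 2*mCN2 discards the mCN2 >= 4 candidates; lowest MAF error wins
  expect_equal(sol$mCN2, 3)
  expect_equal(sol$rho1, 0.4)
  expect_true(sol$maf_err < 0.1)
})

test_that("clonal segments do not produce spurious subclones", {
  sol <- decompose_fractional_cn(mCNF = 1, CNF = 2, MAF = 0.5,
                                 mCN1 = 1, CN1 = 2, purity = 1)
  expect_equal(nrow(sol), 0)   # rho1 = 0 for every candidate: no second clone
  expect_error(decompose_fractional_cn(1.8, 4.2, 0.4, 1, 0, 1), "CN1")
})

test_that("arm tables cover both builds and assign segments to arms", {
  for (build in c("GRCh38", "hg19")) {
    arms <- arm_coordinates(build)
    expect_equal(nrow(arms), 24)
    expect_true(all(arms$centromere_start < arms$centromere_end))
    expect_true(all(arms$centromere_end < arms$length))
  }
  # a segment spanning the centromere is split at the boundary
  arms <- arm_coordinates("GRCh38")
  c1 <- arms[arms$chrom == "chr1", ]
  seg <- tibble::tibble(chrom = "chr1", from = c1$centromere_start - 100,
                        to = c1$centromere_end + 100, major = 2, minor = 1)
  out <- assign_arms(seg)
  expect_equal(sort(out$arm), c("1p", "1q"))
  expect_equal(out$to[out$arm == "1p"], c1$centromere_start - 1)
  expect_equal(out$from[out$arm == "1q"], c1$centromere_end + 1)
})
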