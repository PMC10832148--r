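expected_tbl <- function(nA, nB, purity) {
  dplyr::mutate(peaks_for_karyotype(nA, nB, purity), nA = nA, nB = nB)
}

test_that("peak matching uses interval overlap with the purity band", {
  exp <- expected_tbl(1, 1, 0.6)           # diploid peak at 0.30
  dp <- tibble::tibble(position = c(0.276, 0.324, 0.33), support = c(5L, 5L, 5L))
  # sigma = 0: accepted band is exactly [0.275, 0.325]
  m1 <- match_peaks(exp, dp[1, ], 0.6, epsilon = 0.025, sigma = 0)
  expect_true(m1$matched)
  m2 <- match_peaks(exp, dp[3, ], 0.6, epsilon = 0.025, sigma = 0)
  expect_false(m2$matched)
  m3 <- match_peaks(exp, tibble::tibble(position = 0.30, support = 1L),
                    0.6, epsilon = 0.025, sigma = 0)
  expect_equal(m3$offset, 0)
  expect_true(m3$matched)
})

test_that("right-only matching ignores closer peaks on the left", {
  exp <- expected_tbl(2, 1, 0.9)[1, ]      # v_1 ~ 0.31
  dp <- tibble::tibble(position = c(0.27, 0.36), support = c(10L, 10L))
  m_closest <- match_peaks(exp, dp, 0.9, 0.05, strategy = "closest")
  expect_equal(m_closest$d_star, 0.27)
  m_right <- match_peaks(exp, dp, 0.9, 0.05, strategy = "right_only")
  expect_equal(m_right$d_star, 0.36)
})

test_that("no data peaks yields an unmatched warning, not an error", {
  exp <- expected_tbl(1, 1, 0.8)
  expect_warning(m <- match_peaks(exp, tibble::tibble(position = numeric(0),
                                                      support = integer(0)),
                                  0.8, 0.05), "unmatched")
  expect_false(m$matched)
})

test_that("karyotype status is a mutation-weighted majority vote", {
  # two peaks; the supported one matches, the sparse one does not
  mut <- dplyr::bind_rows(
    peaky_mutations(2 / 3, 500, coverage = 200, seed = 21),
    dplyr::mutate(peaky_mutations(0.25, 60, coverage = 200, seed = 22),
                  pos = pos + 1000)   # displaced m=1 peak (true at 1/3)
  )
  res <- qc_karyotype(mut, 2, 1, purity = 1, epsilon = 0.02, sigma = 0.01)
  expect_equal(unique(res$status), "PASS")
  m2 <- res[res$m == 2, ]
  expect_true(m2$matched)
  expect_gt(m2$support, res$support[res$m == 1])
})

test_that("karyotypes with too few mutations are skipped, not failed", {
  mut <- peaky_mutations(0.5, 10, seed = 23)
  res <- qc_karyotype(mut, 1, 1, 1, 0.03)
  expect_true(isTRUE(attr(res, "skipped")))
  rep <- qc_sample(dplyr::mutate(mut, karyotype = "1:1", major = 1, minor = 1,
                                 class = "simple_clonal"),
                   1, 0.03)
  expect_equal(rep$status, "CANNOT_QC")
  expect_equal(rep$skipped_karyotypes, "1:1")
})

test_that("a clean simulated tumor passes at its true purity", {
  sim <- simulate_tumor(sim_config(purity = 0.8, coverage = 90, n_chrom = 6,
                                   seed = 31))
  mapped <- map_mutations(sim$mutations, sim$segments)
  rep <- qc_sample(mapped, 0.8, 0.03)
  expect_equal(rep$status, "PASS")
  expect_lt(abs(rep$lambda), 0.02)
  expect_equal(rep$suggested_purity, 0.8)
})

test_that("a purity error is failed with a corrective lambda", {
  sim <- simulate_tumor(sim_config(purity = 0.8, coverage = 90, n_chrom = 8,
                                   mutations_per_mb = 1.5, seed = 32))
  mapped <- map_mutations(sim$mutations, sim$segments)
  rep <- qc_sample(mapped, 0.87, 0.03)
  expect_equal(rep$status, "FAIL")
  # suggested adjustment ~ -0.07, within +/-0.02
  expect_lt(abs(rep$lambda - (-0.07)), 0.02)
  expect_equal(rep$suggested_purity, 0.87 + rep$lambda)
})

test_that("lambda changes sign when data peaks are mirrored", {
  exp <- expected_tbl(1, 1, 0.8)           # peak at 0.4
  up <- tibble::tibble(position = 0.43, support = 10L)
  down <- tibble::tibble(position = 0.37, support = 10L)
  m_up <- match_peaks(exp, up, 0.8, 0.05)
  m_down <- match_peaks(exp, down, 0.8, 0.05)
  expect_equal(m_up$offset_purity, -m_down$offset_purity, tolerance = 1e-12)
  expect_gt(m_up$offset_purity, 0)
})

test_that("enlarging the tolerance is monotone: passes stay passes", {
  sim <- simulate_tumor(sim_config(purity = 0.7, coverage = 60, n_chrom = 5,
                                   seed = 33))
  mapped <- map_mutations(sim$mutations, sim$segments)
  eps_grid <- c(0.01, 0.02, 0.04, 0.08)
  status <- vapply(eps_grid, function(e) qc_sample(mapped, 0.73, e)$status,
                   character(1))
  passed <- status == "PASS"
  expect_true(all(passed[which(passed)[1]:length(passed)]) || !any(passed))
})

test_that("chromosome-level mode localizes a miscalled chromosome", {
  sim <- simulate_tumor(sim_config(purity = 0.9, coverage = 120, n_chrom = 4,
                                   mutations_per_mb = 2,
                                   karyotype_weights = c("1:1" = 1), seed = 34))
  segments <- sim$segments
  mutations <- sim$mutations
  # miscall chr1 as triploid: its mutations were generated diploid
  segments$major[segments$chrom == "chr1"] <- 2
  segments$minor[segments$chrom == "chr1"] <- 1
  mapped <- map_mutations(mutations, segments)
  reps <- qc_sample(mapped, 0.9, 0.03, by_chromosome = TRUE)
  expect_equal(reps[["chr1"]]$status, "FAIL")
  others <- vapply(reps[names(reps) != "chr1"], function(r) r$status,
                   character(1))
  expect_true(all(others == "PASS"))
})

test_that("complex karyotypes are screened with raw VAF tolerance", {
  mut <- peaky_mutations(c(1, 2, 3) / 3, 200, coverage = 150, seed = 35)
  res <- qc_complex(mut, 3, 0, purity = 1, tolerance = 0.03)
  expect_equal(nrow(res$peaks), 3)
  expect_equal(res$prop_matched, 1)

  res42 <- qc_complex(peaky_mutations(1:4 / 6, 200, coverage = 300, seed = 36),
                      4, 2, purity = 0.99999, tolerance = 0.03)
  expect_equal(nrow(res42$peaks), 4)   # multiplicities 1..4 tested

  small <- qc_complex(peaky_mutations(0.5, 20, seed = 37), 3, 0, 1, 0.03)
  expect_true(isTRUE(attr(small, "skipped")))
})

test_that("subclonal QC recovers the generating evolution model", {
  cfg <- sim_config(purity = 0.8, coverage = 150, n_chrom = 4,
                    subclonal = list(state1 = "2:1", state2 = "2:0",
                                     rho1 = 0.75, model = 3,  # linear
                                     n_mutations = 600, chrom = "chr4"),
                    seed = 41)
  sim <- simulate_tumor(cfg)
  sub_mut <- sim$mutations[sim$mutations$chrom == "chr4", ]
  res <- qc_subclonal(sub_mut, "2:1", "2:0", 0.75, 0.8)
  expect_true(res$status %in% c("selected", "indistinguishable"))
  expect_true(all(res$models$topology[res$best] == "linear"))
})

test_that("mirrored triploid subclones select the mirrored branching model", {
  m <- enumerate_evolution_models("2:1", "1:2")
  mirrored_idx <- which(vapply(seq_len(nrow(m)), function(i) {
    sh <- m$shared_multiplicities[[i]]
    m$topology[i] == "branching" && any(sh$m1 != sh$m2)
  }, logical(1)))
  # the mirrored shared peaks (0.473 / 0.527) are ~1.5 binomial sd apart at
  # 150x and physically merge; resolving them needs high-coverage data
  cfg <- sim_config(purity = 1, coverage = 600, n_chrom = 4,
                    subclonal = list(state1 = "2:1", state2 = "1:2",
                                     rho1 = 0.58, model = mirrored_idx[1],
                                     n_mutations = 700, chrom = "chr4"),
                    seed = 42)
  sim <- simulate_tumor(cfg)
  sub_mut <- sim$mutations[sim$mutations$chrom == "chr4", ]
  res <- qc_subclonal(sub_mut, "2:1", "1:2", 0.58, 1)
  expect_true(res$status %in% c("selected", "indistinguishable"))
  best_models <- res$models[res$best, ]
  expect_true(any(vapply(seq_len(nrow(best_models)), function(i) {
    sh <- best_models$shared_multiplicities[[i]]
    best_models$topology[i] == "branching" && any(sh$m1 != sh$m2)
  }, logical(1))))
})

test_that("ties between peak-identical models are reported as indistinguishable", {
  cfg <- sim_config(purity = 0.9, coverage = 150, n_chrom = 4,
                    subclonal = list(state1 = "1:1", state2 = "1:0",
                                     rho1 = 0.7, model = 1,
                                     n_mutations = 500, chrom = "chr4"),
                    seed = 43)
  sim <- simulate_tumor(cfg)
  sub_mut <- sim$mutations[sim$mutations$chrom == "chr4", ]
  res <- qc_subclonal(sub_mut, "1:1", "1:0", 0.7, 0.9)
  expect_equal(res$status, "indistinguishable")
  small <- qc_subclonal(sub_mut[1:20, ], "1:1", "1:0", 0.7, 0.9)
  expect_equal(small$status, "skipped")
})
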