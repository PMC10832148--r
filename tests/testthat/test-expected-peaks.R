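test_that("clonal peak equation reproduces canonical configurations", {
  expect_equal(expected_vaf(1, 1, 1, purity = 1), 0.5)
  expect_equal(expected_vaf(1, 2, 2, purity = 1), 0.25)
  expect_equal(expected_vaf(2, 2, 2, purity = 1), 0.5)
  expect_equal(expected_vaf(1, 2, 1, purity = 1), 1 / 3)
  expect_equal(expected_vaf(2, 2, 1, purity = 1), 2 / 3)
  expect_equal(expected_vaf(1, 2, 1, purity = 0.9), 0.9 / 2.9)
  # subclonal dilution through the ccf argument
  expect_equal(expected_vaf(1, 1, 1, purity = 1, ccf = 0.5), 0.25)
})

test_that("peak equation is monotone and validates inputs", {
  purities <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(expected_vaf(1, 2, 1, purities)) > 0))
  expect_true(all(diff(expected_vaf(1:3, 3, 1, 0.7)) > 0))
  ccfs <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(expected_vaf(1, 1, 1, 0.8, ccfs)) > 0))
  expect_equal(expected_vaf(1, 1, 1, 0.64), 0.32)  # pi/2 for diploid het
  expect_error(expected_vaf(1, 0, 0, purity = 1), "zero copies")
  expect_error(expected_vaf(0, 1, 1, purity = 1), "positive integer")
  expect_error(expected_vaf(1, 1, 1, purity = 0), "purity")
})

test_that("multiplicity sets follow the karyotype taxonomy", {
  expect_equal(peaks_for_karyotype(1, 0, 1)$m, 1L)
  expect_equal(peaks_for_karyotype(1, 1, 1)$m, 1L)
  expect_equal(peaks_for_karyotype(2, 0, 1)$m, c(1L, 2L))
  expect_equal(peaks_for_karyotype(2, 1, 1)$m, c(1L, 2L))
  expect_equal(peaks_for_karyotype(2, 2, 1)$m, c(1L, 2L))
  p42 <- peaks_for_karyotype(4, 2, 0.8)
  expect_equal(p42$m, 1:4)
  expect_true(all(diff(p42$vaf) > 0))
  expect_equal(peaks_for_karyotype(2, 1, 1)$vaf, c(1 / 3, 2 / 3))
  expect_equal(peaks_for_karyotype(1, 0, 1)$vaf, 1)
})

test_that("purity error propagates to VAF space per the first-order rule", {
  expect_equal(vaf_error_from_purity_error(1, 3, 0.9, 0.05), 0.0119, tolerance = 1e-2)
  expect_equal(round(vaf_error_from_purity_error(1, 3, 0.9, 0.05), 2), 0.01)
  expect_equal(round(vaf_error_from_purity_error(2, 3, 0.9, 0.05), 2), 0.02)
  expect_equal(vaf_error_from_purity_error(1, 2, 0.7, 0), 0)
})

test_that("purity inversion and the error round-trip are exact", {
  expect_equal(purity_from_vaf(0.5, 1, 2), 1)
  expect_equal(purity_from_vaf(0.45, 1, 2), 0.9)
  # composing forward and backward propagation returns epsilon exactly
  grid <- tidyr::expand_grid(m = 1:3, p = 1:5, purity = seq(0.2, 0.95, by = 0.15),
                             eps = c(0.01, 0.03, 0.05, 0.1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$m > g$p) next
    v <- g$m * g$purity / (2 * (1 - g$purity) + g$purity * g$p)
    dv <- vaf_error_from_purity_error(g$m, g$p, g$purity, g$eps)
    expect_equal(purity_error_from_vaf_error(v, dv, g$m, g$p), g$eps,
                 tolerance = 1e-12)
    expect_equal(purity_from_vaf(v, g$m, g$p), g$purity, tolerance = 1e-12)
  }
})

test_that("acceptance band is the image of the two-sided purity interval", {
  # diploid at purity 0.60 with 2.5% tolerance accepts [0.275, 0.325]
  hw <- vaf_acceptance_halfwidth(1, 1, 1, 0.6, 0.025)
  expect_equal(hw, 0.025)
  v <- expected_vaf(1, 1, 1, 0.6)
  expect_equal(c(v - hw, v + hw), c(0.275, 0.325))
  # implied purity interval is the two-sided band
  expect_equal(purity_from_vaf(0.275, 1, 2), 0.55)
  expect_equal(purity_from_vaf(0.325, 1, 2), 0.65)
})

test_that("subclonal peaks reproduce the 2:1/2:0 worked models", {
  m <- enumerate_evolution_models("2:1", "2:0")
  peaks_of <- function(desc) {
    i <- grep(desc, m$description, fixed = TRUE)[1]
    subclonal_expected_peaks(m[i, ], 0.75, 0.25, 0.8)
  }
  b1 <- peaks_of("AAB | BB")   # mirrored branching: one shared peak
  expect_equal(sort(round(b1$vaf, 2)), c(0.08, 0.15, 0.23, 0.38, 0.46))
  shared1 <- b1[grepl("shared", b1$origin) & b1$m1 == 1, ]
  expect_equal(round(shared1$vaf, 2), 0.38)

  b2 <- peaks_of("AAB | AA")   # same-allele branching: (2,2) shared peak
  sh22 <- b2[grepl("shared", b2$origin), ]
  expect_equal(sh22$vaf[which.max(sh22$vaf)], 1.6 / 2.6)  # prints as 0.61

  lin <- peaks_of("AAB -> AA")
  expect_equal(nrow(lin), 4)
  expect_equal(sort(round(lin$vaf, 2)), c(0.08, 0.23, 0.31, 0.62))
})

test_that("mirrored and same-allele triploid subclones give the printed peaks", {
  m <- enumerate_evolution_models("2:1", "1:2")
  mirrored <- m[m$topology == "branching" &
                  grepl("AAB | ABB", m$description, fixed = TRUE), ]
  pk <- subclonal_expected_peaks(mirrored[1, ], 0.58, 0.42, 1)
  sh <- pk[grepl("shared", pk$origin), ]
  expect_equal(round(sort(sh$vaf), 2), c(0.47, 0.53))
  expect_equal(sh$vaf[sh$m1 == 1 & sh$m2 == 2], (0.58 + 2 * 0.42) / 3)

  same <- m[grepl("AAB | AAB", m$description, fixed = TRUE) &
              m$topology == "branching", ]
  pk2 <- subclonal_expected_peaks(same[1, ], 0.58, 0.42, 1)
  sh2 <- pk2[grepl("shared", pk2$origin), ]
  expect_equal(sort(sh2$vaf), c(1 / 3, 2 / 3), tolerance = 1e-12)
})

test_that("subclonal peaks converge to clonal peaks as rho1 -> 1", {
  m <- enumerate_evolution_models("2:1", "2:0")
  lin <- m[m$topology == "linear", ]
  for (purity in c(0.6, 1)) {
    pk <- subclonal_expected_peaks(lin[1, ], 1 - 1e-9, 1e-9, purity)
    clonal <- peaks_for_karyotype(2, 1, purity)
    # every clonal 2:1 peak is a limit of some subclonal peak
    for (v in clonal$vaf) expect_true(min(abs(pk$vaf - v)) < 1e-6)
  }
})
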