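test_that("CCF conversion inverts the peak equation", {
  # pure diploid tumor: c = 2v
  expect_equal(ccf_from_vaf(0.5, 1, 1, 1, 1), 1)
  expect_equal(ccf_from_vaf(0.55, 1, 1, 1, 1), 1.1)   # not clipped
  expect_equal(ccf_from_vaf(1 / 3, 1, 2, 1, 1), 1)
  expect_true(is.na(ccf_from_vaf(0.4, NA, 2, 1, 0.8)))
  # exact round trip through the forward equation on a grid
  grid <- tidyr::expand_grid(m = 1:2, nA = 1:2, purity = c(0.3, 0.7, 1),
                             ccf = c(0.2, 0.6, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    v <- expected_vaf(g$m, g$nA, 1, g$purity, g$ccf)
    expect_equal(ccf_from_vaf(v, g$m, g$nA, 1, g$purity), g$ccf,
                 tolerance = 1e-12)
  }
})

test_that("responsibility entropy peaks at the density crossing", {
  mut <- peaky_mutations(c(1 / 3, 2 / 3), 300, coverage = 60, seed = 51)
  est <- phase_entropy(mut, 2, 1, 1)
  e <- est$estimates
  # at the component modes: confident assignment, near-zero entropy
  near1 <- which.min(abs(e$vaf - 1 / 3))
  expect_gt(e$z1[near1], 0.99)
  expect_lt(e$entropy[near1], 0.1)
  expect_equal(e$m[near1], 1L)
  # entropy is bounded by ln 2 and maximal near equal responsibilities
  expect_true(all(e$entropy <= log(2) + 1e-9))
  mid <- which.min(abs(e$z1 - 0.5))
  expect_gt(e$entropy[mid], 0.9 * log(2))
  # NA range lies strictly between the theoretical peaks
  expect_true(est$na_range[1] > 1 / 3 & est$na_range[2] < 2 / 3)
})

test_that("uncertainty shrinks with coverage and purity", {
  na_frac <- function(coverage, purity, seed = 52) {
    set.seed(seed)
    m <- sample(1:2, 500, TRUE)
    dp <- pmax(1L, rpois(500, coverage))
    v <- expected_vaf(m, 2, 1, purity)
    mut <- tibble::tibble(chrom = "c", pos = 1:500, ref = "N", alt = "A",
                          nv = rbinom(500, dp, v), dp = dp)
    mean(is.na(phase_entropy(mut, 2, 1, purity)$estimates$m))
  }
  grid <- tidyr::expand_grid(purity = c(0.5, 0.9), coverage = c(30, 60, 100))
  fracs <- matrix(purrr::pmap_dbl(grid, function(purity, coverage)
    na_frac(coverage, purity)), nrow = 3)   # rows: coverage, cols: purity
  # non-increasing along coverage at each purity, and in purity at each coverage
  expect_true(all(diff(fracs[, 1]) <= 1e-9))
  expect_true(all(diff(fracs[, 2]) <= 1e-9))
  expect_true(all(fracs[, 2] <= fracs[, 1] + 1e-9))
  expect_lt(fracs[3, 2], fracs[1, 1])
})

test_that("the rough method is the entropy cut without abstention", {
  mut <- peaky_mutations(c(1 / 3, 2 / 3), 400, coverage = 50, seed = 53)
  rough <- phase_rough(mut, 2, 1, 1)
  ent <- phase_entropy(mut, 2, 1, 1)
  expect_false(any(is.na(rough$estimates$m)))
  expect_equal(ccf_qc(rough)$status, "PASS")
  # agreement outside the abstention range
  ok <- !is.na(ent$estimates$m)
  expect_true(mean(rough$estimates$m[ok] == ent$estimates$m[ok]) > 0.98)
  # midpoint with equal clusters sits halfway
  eq <- attr(phase_rough(peaky_mutations(c(0.33, 0.66), 500, coverage = 1000,
                                         seed = 54), 2, 1, 1), "midpoint")
  expect_lt(abs(eq - 0.495), 0.02)
  # all mutations below the cut are single copy
  low <- peaky_mutations(1 / 3, 100, coverage = 400, seed = 55)
  expect_true(all(phase_rough(low, 2, 1, 1)$estimates$m == 1L))
})

test_that("CCF QC fails only above the NA cutoff", {
  fake <- function(prop_na, n = 100) {
    tibble::tibble(m = c(rep(NA_integer_, round(n * prop_na)),
                         rep(1L, n - round(n * prop_na))))
  }
  expect_equal(ccf_qc(fake(0.14))$status, "FAIL")
  expect_equal(ccf_qc(fake(0))$status, "PASS")
  expect_equal(ccf_qc(fake(0.10))$status, "PASS")   # strict inequality
  expect_equal(ccf_qc(fake(0.11))$status, "FAIL")
})

test_that("1:0 and 1:1 phase trivially to single copy", {
  mut <- peaky_mutations(0.5, 50, seed = 56)
  est <- phase_entropy(mut, 1, 1, 1)
  expect_true(all(est$estimates$m == 1L))
  expect_true(all(est$estimates$ccf == 2 * est$estimates$vaf))
  expect_error(phase_entropy(mut, 3, 2, 1), "simple karyotypes")
})
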