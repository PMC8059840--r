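test_that("isotropic weight has the exact edge/corner closed-form values", {
  w <- pp_window(678, 506)
  # interior circle: no correction
  expect_equal(isotropic_weight(300, 250, 25, w), 1)
  # midpoint of an edge, circle cut by that edge only: half inside
  expect_equal(isotropic_weight(0, 253, 10, w), 2)
  expect_equal(isotropic_weight(339, 0, 10, w), 2)
  # corner, quarter circle inside
  expect_equal(isotropic_weight(0, 0, 10, w), 4)
  expect_equal(isotropic_weight(678, 506, 10, w), 4)
  expect_error(isotropic_weight(300, 250, 0, w), "positive")
  expect_error(isotropic_weight(-1, 250, 10, w), "outside")
})

test_that("closed-form weight agrees with numeric arc integration to 1e-9", {
  w <- pp_window(678, 506)
  set.seed(42)
  for (i in 1:25) {
    # concentrate near edges and corners where the correction is active
    x <- sample(c(runif(1, 0, 40), runif(1, 0, 678)), 1)
    y <- sample(c(runif(1, 0, 40), runif(1, 0, 506)), 1)
    r <- runif(1, 1, 60)
    expect_equal(isotropic_weight(x, y, r, w),
                 isotropic_weight_numeric(x, y, r, w),
                 tolerance = 1e-9)
  }
})

test_that("weights are bounded between 1 and 4 inside the rectangle", {
  w <- pp_window(678, 506)
  set.seed(7)
  x <- runif(500, 0, 678); y <- runif(500, 0, 506)
  wt <- isotropic_weight(x, y, 25, w)
  expect_true(all(wt >= 1))
  expect_true(all(wt <= 4 + 1e-12))
})

test_that("cross_k reproduces the hand-computed two-target example", {
  w <- pp_window(200, 200)
  p <- marked_point_pattern(data.frame(
    x = c(100, 100, 100), y = c(100, 110, 140),
    cell_class = c("tumor", "other", "other"), cd68 = c(0, 1, 1)), w)
  est <- cross_k(p, "tumor", "cd68", radii = 25)
  # one pair within 25 um at distance 10 (circle fully interior, weight 1)
  expect_equal(est$k[1], 40000 / (1 * 2) * 1)
  expect_equal(est$nk[1], 20000 / (pi * 625), tolerance = 1e-12)
  expect_equal(round(est$nk[1], 3), 10.186)
  expect_equal(nk25(p, "tumor", "cd68"), est$nk[1])
  # no target within r -> K = 0
  est0 <- cross_k(p, "tumor", "cd68", radii = 5)
  expect_equal(est0$k[1], 0)
  expect_equal(est0$nk[1], 0)
})

test_that("cross_k equals the naive double loop exactly on interior-only patterns", {
  for (seed in 1:5) {
    p <- interior_pattern(40, 30, r = 25, seed = seed)
    expect_equal(cross_k(p, "tumor", "cd68", radii = 25)$k[1],
                 naive_cross_k(p, "tumor", "cd68", 25), tolerance = 1e-12)
    # univariate case: n(n-1) divisor, self-pairs excluded
    expect_equal(cross_k(p, "tumor", "tumor", radii = 25)$k[1],
                 naive_cross_k(p, "tumor", "tumor", 25), tolerance = 1e-12)
  }
})

test_that("K is nondecreasing in r and marker/class selections are honoured", {
  set.seed(3)
  p <- simulate_csr(c(tumor = 8e-4, cd68 = 5e-4), seed = 31)
  est <- cross_k(p, "tumor", "cd68", radii = seq(5, 50, by = 5))
  expect_true(all(diff(est$k) >= 0))
  expect_equal(est$nk, est$k / (pi * est$radii^2))
  df <- as.data.frame(est)
  expect_equal(names(df), c("roi_id", "ref_type", "target_type", "r_um",
                            "k", "nk", "n_ref", "n_target"))
})

test_that("cross_k errors on empty selections with an eligibility hint", {
  w <- pp_window(100, 100)
  p <- marked_point_pattern(
    data.frame(x = c(10, 20), y = c(10, 20), cell_class = "tumor"), w)
  expect_error(cross_k(p, "tumor", "cd68", 25), "eligibility")
  expect_error(cross_k(p, "stroma", "tumor", 25), "eligibility")
  expect_error(cross_k(p, "tumor", "tumor", radii = c(10, 5)), "increasing")
})

test_that("duplicate coordinates contribute pairs with the interior-limit weight", {
  w <- pp_window(200, 200)
  p <- marked_point_pattern(data.frame(
    x = c(100, 100), y = c(100, 100),
    cell_class = c("tumor", "other"), cd68 = c(0, 1)), w)
  # distinct records at distance 0: one pair, weight 1
  expect_equal(cross_k(p, "tumor", "cd68", radii = 25)$k[1], 40000)
  # a CD68+ tumor cell is a self-pair for tumor->cd68 and is excluded
  p2 <- marked_point_pattern(data.frame(
    x = 100, y = 100, cell_class = "tumor", cd68 = 1), w)
  expect_error(cross_k(p2, "tumor", "cd68", 25), NA)
  expect_equal(cross_k(p2, "tumor", "cd68", 25)$k[1], 0)
})

test_that("normalize_k applies K/(pi r^2) with its range contract", {
  expect_equal(normalize_k(pi * 625, 25), 1)
  expect_equal(normalize_k(0, 25), 0)
  # nK = 1.30 reads as 30% excess over the CSR expectation
  expect_equal(normalize_k(1.30 * pi * 25^2, 25), 1.30)
  expect_error(normalize_k(10, 0), "positive")
  expect_error(normalize_k(-1, 25), "nonnegative")
})

test_that("CSR patterns give nK(25) near 1 and co-located targets inflate it", {
  set.seed(8)
  v <- replicate(40, nk25(simulate_csr(c(tumor = 1e-3, cd68 = 1e-3)),
                          "tumor", "cd68"))
  expect_lt(abs(mean(v) - 1), 0.05)
  # univariate CSR likewise
  p <- simulate_csr(c(tumor = 2e-3), seed = 5)
  expect_lt(abs(nk25(p, "tumor", "tumor") - 1), 0.25)
  # sparse refs with targets planted 5 um away: strong clustering
  set.seed(9)
  rx <- runif(12, 50, 628); ry <- runif(12, 50, 456)
  p2 <- marked_point_pattern(data.frame(
    x = c(rx, rx + 5), y = c(ry, ry),
    cell_class = rep(c("tumor", "other"), each = 12),
    cd68 = rep(c(0L, 1L), each = 12)), pp_window())
  expect_gt(nk25(p2, "tumor", "cd68"), 10)
})
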