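test_that("Kaplan-Meier product-limit arithmetic on small cohorts", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  km2 <- km_estimate(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # duplicating every observation leaves the curve unchanged
  km3 <- km_estimate(rep(c(1, 2, 3), 2), rep(1, 6))
  expect_equal(km3$surv, km$surv)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank test matches the hand O-E/V tabulation", {
  # perfectly separated groups on n = 6
  tt <- c(1, 2, 3, 10, 11, 12)
  ee <- rep(1, 6)
  gg <- rep(c("A", "B"), each = 3)
  res <- log_rank(gg, tt, ee)
  hand <- hand_log_rank(gg, tt, ee)
  expect_equal(res$chi2, hand$chi2, tolerance = 1e-9)
  expect_equal(res$p_value, hand$p_value, tolerance = 1e-9)
  expect_lt(res$p_value, 0.05)
  # label swap leaves chi2 unchanged
  expect_equal(log_rank(rev(gg), tt, ee)$chi2, res$chi2)
  # identical groups: no signal
  tie <- log_rank(rep(c("A", "B"), 3), rep(c(4, 4, 9, 9, 15, 15)), rep(1, 6))
  expect_lt(tie$chi2, 1e-9)
  expect_error(log_rank(rep("A", 4), 1:4, rep(1, 4)), "two")
  # randomized instances with censoring and ties
  set.seed(19)
  for (i in 1:10) {
    n <- sample(8:40, 1)
    tt <- sample(1:12, n, replace = TRUE)
    ee <- rbinom(n, 1, 0.7); ee[1:2] <- 1
    gg <- rbinom(n, 1, 0.5); gg[1:2] <- 0:1
    expect_equal(log_rank(gg, tt, ee)$chi2, hand_log_rank(gg, tt, ee)$chi2,
                 tolerance = 1e-9)
  }
})

test_that("optimal cut-point picks the exhaustive-scan split on the toy example", {
  res <- optimal_cutpoint(c(1, 2, 9, 10), c(10, 9, 1, 2), rep(1, 4))
  expect_equal(res$cutpoint, 2)
  expect_equal(res$n_low, 2)
  expect_equal(res$n_high, 2)
  oracle <- brute_cutpoint(c(1, 2, 9, 10), c(10, 9, 1, 2), rep(1, 4))
  expect_equal(res$p_value, oracle$p_value, tolerance = 1e-10)
  expect_error(optimal_cutpoint(rep(3, 5), 1:5, rep(1, 5)), "distinct")
})

test_that("optimal cut-point equals the brute-force scan on random instances", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(12:60, 1)
    v <- round(rnorm(n), 2)
    tt <- round(rexp(n, 0.1) + 0.1, 3)
    ee <- rbinom(n, 1, 0.75); if (sum(ee) == 0) ee[1] <- 1
    res <- optimal_cutpoint(v, tt, ee)
    oracle <- brute_cutpoint(v, tt, ee)
    expect_equal(res$cutpoint, oracle$cutpoint)
    expect_equal(res$p_value, oracle$p_value, tolerance = 1e-9)
    expect_equal(res$chi2, oracle$chi2, tolerance = 1e-9)
  }
})

test_that("cut-point recovery on a monotone hazard simulation, with group floor", {
  set.seed(29)
  n <- 200
  v <- runif(n)
  rate <- ifelse(v > 0.5, 0.2, 0.05)  # generating threshold at 0.5
  tt <- rexp(n, rate)
  ee <- as.integer(tt <= 30); tt <- pmin(tt, 30)
  res <- optimal_cutpoint(v, tt, ee, min_group_frac = 0.10,
                          min_group_size = 3)
  expect_lt(abs(res$cutpoint - 0.5), 0.12)
  expect_gte(res$n_low, 20)
  expect_gte(res$n_high, 20)
  # the permutation-adjusted p is no smaller than the raw minimized p
  res2 <- optimal_cutpoint(v[1:40], tt[1:40], ee[1:40], n_perm = 30)
  expect_gte(res2$p_adjusted, res2$p_value)
})

test_that("Cox wrapper recovers a two-group hazard ratio of 2 and the null", {
  set.seed(31)
  n <- 500
  grp <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05 * 2^grp)
  ee <- as.integer(tt <= 40); tt <- pmin(tt, 40)
  df <- data.frame(os_months = tt, event = ee, grp = grp,
                   noise = rnorm(n))
  fit <- cox_fit(df, c("grp", "noise"))
  co <- fit$coefficients
  expect_gt(co$ci_upper[co$term == "grp"], 2 * 0.8)
  expect_lt(co$ci_lower[co$term == "grp"], 2 * 1.2)
  # null covariate: CI covers 1
  expect_lt(co$ci_lower[co$term == "noise"], 1)
  expect_gt(co$ci_upper[co$term == "noise"], 1)
  expect_equal(fit$n_events, sum(ee))
  # IMDC enters as a factor with level "1" as reference
  df$imdc <- sample(c("1", "2", "3+"), n, replace = TRUE)
  fit2 <- cox_fit(df, c("grp", "imdc"))
  expect_setequal(fit2$coefficients$term, c("grp", "imdc2", "imdc3+"))
  expect_error(cox_fit(df, "absent"), "missing column")
  expect_error(cox_fit(transform(df, event = 0), "grp"), "events|0/1")
  expect_error(cox_fit(transform(df, grp = 1), "grp"), "constant")
})

test_that("Cox Wald p-values are near-uniform under the null", {
  set.seed(37)
  p_vals <- replicate(300, {
    n <- 60
    tt <- rexp(n, 0.1)
    ee <- as.integer(tt <= 15); tt <- pmin(tt, 15)
    df <- data.frame(os_months = tt, event = ee, x = rnorm(n))
    if (sum(ee) < 2) return(NA_real_)
    cox_fit(df, "x")$coefficients$p_value
  })
  ks <- ks.test(p_vals[!is.na(p_vals)], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("minimum detectable HR reproduces its closed form and monotonicity", {
  expect_equal(round(minimum_detectable_hr(35, 0.80), 1), 1.7)
  expect_equal(minimum_detectable_hr(100, 1.0),
               exp((qnorm(0.975) + qnorm(0.80)) / 10), tolerance = 1e-12)
  expect_equal(round(minimum_detectable_hr(100, 1.0), 4), 1.3233)
  # strictly decreasing in n, p_event and power
  expect_gt(minimum_detectable_hr(35, 0.8), minimum_detectable_hr(70, 0.8))
  expect_gt(minimum_detectable_hr(35, 0.5), minimum_detectable_hr(35, 0.9))
  expect_gt(minimum_detectable_hr(35, 0.8, power = 0.9),
            minimum_detectable_hr(35, 0.8, power = 0.8))
  # n -> Inf drives the MDHR to 1
  expect_lt(minimum_detectable_hr(1e8, 1) - 1, 1e-3)
  # round-trip: events required to detect the MDHR is what we started with
  mdhr <- minimum_detectable_hr(35, 0.8)
  events_needed <- ((qnorm(0.975) + qnorm(0.8)) / log(mdhr))^2
  expect_lte(events_needed, 35 * 0.8 + 1e-9)
  expect_error(minimum_detectable_hr(1, 0.2), "event")
})
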