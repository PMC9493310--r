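test_that("noiseless detection is certain above the limit, zero below", {
  cfg <- pheno_gen_config(noise_sd = 0, true_sensitivity = 0.05)
  s <- sensitivity_analysis(c(0.5, 1, 2, 5), reps = 20, gen_cfg = cfg,
                            seed = 3)
  expect_equal(s$sensitivity, c(0, 100, 100, 100))
  u <- uncertainty_analysis(c(2, 5), reps = 20, boot = 100, gen_cfg = cfg,
                            seed = 3)
  expect_equal(u$uncertainty, c(0, 0))
  # below the limit every forcing is suppressed: flagged undefined
  u0 <- uncertainty_analysis(0.5, reps = 20, boot = 100, gen_cfg = cfg,
                             seed = 3)
  expect_true(is.na(u0$uncertainty))
})

test_that("sensitivity matches a brute-force re-simulation of the same stream", {
  grid <- c(1, 3, 6)
  reps <- 50
  gen_cfg <- pheno_gen_config(noise_sd = 2, true_sensitivity = 0.05)
  tol <- 0.1
  s <- sensitivity_analysis(grid, reps, gen_cfg, tolerance = tol, seed = 9)

  # independent re-simulation: same seed derivation, direct arithmetic
  set.seed(9)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, reps * length(grid)),
                  nrow = reps)
  for (g in seq_along(grid)) {
    hits <- 0
    for (r in seq_len(reps)) {
      cfg <- gen_cfg
      cfg$cei <- grid[g]
      cfg$seed <- seeds[r, g]
      ps <- generate_phenology_shifts(cfg)
      fp <- grid[g]^2 * n_phenophases(ps) * 100 / sum_delta_p(ps)
      fstar <- grid[g] / gen_cfg$true_sensitivity
      if (grid[g] >= 1 && sum_delta_p(ps) > 0 &&
          abs(fp - fstar) <= tol * fstar)
        hits <- hits + 1
    }
    expect_equal(s$sensitivity[g], 100 * hits / reps)
  }
})

test_that("verification runs are deterministic and noise never helps", {
  grid <- c(1, 2, 4, 8)
  a <- sensitivity_analysis(grid, reps = 100, seed = 5)
  b <- sensitivity_analysis(grid, reps = 100, seed = 5)
  expect_identical(a, b)
  ua <- uncertainty_analysis(grid, reps = 100, boot = 200, seed = 5)
  expect_identical(ua, uncertainty_analysis(grid, reps = 100, boot = 200,
                                            seed = 5))
  # doubling the shift noise does not increase sensitivity nor decrease
  # uncertainty at any grid point
  lo <- pheno_gen_config(noise_sd = 1)
  hi <- pheno_gen_config(noise_sd = 2)
  s_lo <- sensitivity_analysis(grid, reps = 300, gen_cfg = lo, seed = 6)
  s_hi <- sensitivity_analysis(grid, reps = 300, gen_cfg = hi, seed = 6)
  expect_true(all(s_hi$sensitivity <= s_lo$sensitivity + 3))
  u_lo <- uncertainty_analysis(grid, reps = 300, boot = 200, gen_cfg = lo,
                               seed = 6)
  u_hi <- uncertainty_analysis(grid, reps = 300, boot = 200, gen_cfg = hi,
                               seed = 6)
  expect_true(all(u_hi$uncertainty >= u_lo$uncertainty - 0.005))
})

test_that("meta summary reproduces the inverse-variance closed forms", {
  m <- meta_summary(c(1, 3), c(1, 1))
  expect_equal(m$pooled, 2)
  expect_equal(m$q, 2)
  expect_equal(m$weights, c(0.5, 0.5))
  expect_equal(m$i2, 50)  # (2 - 1) / 2 * 100

  # homogeneous effects: no heterogeneity, pooled equals the common value
  m0 <- meta_summary(c(2, 2, 2), c(0.5, 1, 2))
  expect_equal(m0$q, 0)
  expect_equal(m0$i2, 0)
  expect_equal(m0$pooled, 2)

  # general fixed-effect closed form on random fixtures
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(3:10, 1)
    e <- rnorm(k)
    v <- runif(k, 0.2, 3)
    m <- meta_summary(e, v)
    w <- (1 / v) / sum(1 / v)
    expect_equal(sum(m$weights), 1, tolerance = 1e-12)
    expect_equal(m$pooled, sum(w * e), tolerance = 1e-10)
    expect_equal(m$q, sum((1 / v) * (e - sum(w * e))^2), tolerance = 1e-10)
    expect_true(m$ci_low <= m$pooled && m$pooled <= m$ci_high)
    expect_gte(m$q, 0)
    expect_true(m$i2 >= 0 && m$i2 <= 100)
  }
  expect_error(meta_summary(c(1, 2), c(1, 0)), "positive")
  expect_error(meta_summary(1, 1), "at least 2")
})

test_that("random effects collapse to fixed when Q is small, widen otherwise", {
  # homogeneous: tau2 truncates to 0 -> identical pooled estimate
  e <- c(1.0, 1.1, 0.9)
  v <- rep(1, 3)
  fx <- meta_summary(e, v, model = "fixed")
  rnd <- meta_summary(e, v, model = "random")
  expect_equal(rnd$tau2, 0)
  expect_equal(rnd$pooled, fx$pooled)
  # heterogeneous: tau2 > 0 and the interval widens
  e <- c(-2, 0, 2, 4)
  v <- rep(0.1, 4)
  fx <- meta_summary(e, v, model = "fixed")
  rnd <- meta_summary(e, v, model = "random")
  expect_gt(rnd$tau2, 0)
  expect_gt(rnd$ci_high - rnd$ci_low, fx$ci_high - fx$ci_low)
})

test_that("funnel coordinates put the apex at the pooled effect", {
  m <- meta_summary(c(1, 2, 3), c(1, 0.5, 2))
  fc <- funnel_coordinates(m)
  expect_equal(fc$points$se, sqrt(c(1, 0.5, 2)))
  apex <- fc$guides[fc$guides$se == 0, ]
  expect_equal(apex$lower, m$pooled)
  expect_equal(apex$upper, m$pooled)
  # symmetric effects around the pooled value split evenly at the apex line
  ms <- meta_summary(c(-1, -0.5, 0.5, 1), rep(1, 4))
  fcs <- funnel_coordinates(ms)
  expect_equal(sum(fcs$points$effect < fcs$pooled),
               sum(fcs$points$effect > fcs$pooled))
})

test_that("the full verification wrapper returns a coherent curve and meta", {
  v <- verify_forcing_model(grid = c(1, 2, 4, 6), reps = 80, boot = 120,
                            seed = 13)
  expect_named(v$curve, c("cei", "sensitivity", "uncertainty"))
  expect_true(all(v$curve$sensitivity >= 0 & v$curve$sensitivity <= 100))
  expect_true(all(v$curve$uncertainty >= 0, na.rm = TRUE))
  expect_s3_class(v$meta, "meta_summary")
  # simulated forcing is unbiased: pooled log-ratio CI should straddle 0
  expect_true(v$meta$ci_low < 0.05 && v$meta$ci_high > -0.05)
})
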