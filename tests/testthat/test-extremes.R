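test_that("extreme magnitude follows the anomaly-times-magnitude form", {
  # E = (X_Avr - X) * X / 100, zero iff X is at the reference mean
  ref <- weather_series(as.Date("2020-01-01") + 0:4,
                        tmax = c(28, 30, 32, 30, 30), tmin = rep(10, 5),
                        precip = rep(1, 5), wind = rep(60, 5))
  ev <- weather_series(as.Date("2020-01-01") + 0:1,
                       tmax = c(30, 40), tmin = rep(10, 2),
                       precip = rep(1, 2), wind = c(100, 60))
  m <- extreme_magnitude(ev, ref, "HT")
  expect_equal(m$x_avr, 30)
  expect_equal(m$values, c(0, (30 - 40) * 40 / 100))  # 0 and -4
  w <- extreme_magnitude(ev, ref, "W")
  expect_equal(w$x_avr, 60)
  expect_equal(w$values, c((100 - 60) * 100 / 100, 0))  # 40 and 0
})

test_that("the extreme-decile threshold matches a sort-based oracle", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(20:400, 1)
    p <- sample(c(5, 10, 25), 1)
    e <- rnorm(n) * runif(1, 0.1, 50)
    th <- phenoforce:::extreme_threshold(e, p)
    expect_identical(th$threshold, oracle_threshold(e, p))
    k <- max(1, ceiling(n * p / 100))
    expect_equal(th$e_10p, mean(sort(abs(e), decreasing = TRUE)[1:k]))
    # exactly k records sit at or beyond the threshold (continuous draws)
    expect_equal(sum(abs(e) >= th$threshold), k)
  }
})

test_that("normalized subclass CEI is the percentage of records beyond the threshold", {
  ref <- tiny_weather(n = 200, seed = 5)
  ev <- tiny_weather(n = 10, seed = 6)
  m <- extreme_magnitude(ev, ref, "HT")
  # brute-force count over all records
  expected <- 100 * sum(abs(m$values) >= m$threshold) / length(m$values)
  expect_equal(subclass_cei(m), expected)
  expect_true(subclass_cei(m) >= 0 && subclass_cei(m) <= 100)

  # constructed 3-of-10 case
  m$values <- c(rep(m$threshold + 1, 3), rep(0, 7))
  expect_equal(subclass_cei(m), 30)
  m$values <- rep(0, 10)
  expect_equal(subclass_cei(m), 0)
  m$values <- rep(m$threshold, 10)
  expect_equal(subclass_cei(m), 100)
})

test_that("literal mode evaluates the deviation sum and guards denominators", {
  ref <- tiny_weather(n = 200, seed = 5)
  ev <- tiny_weather(n = 50, seed = 6)
  m <- extreme_magnitude(ev, ref, "HT")
  ae <- abs(m$values)
  idx <- ae >= m$threshold
  expect_equal(subclass_cei(m, mode = "literal"),
               sum((m$e_10p - ae[idx]) / ae[idx]))
  m$values <- c(m$threshold + 1, 0)
  m$threshold <- 0  # forces the zero record into the extreme set
  expect_error(subclass_cei(m, mode = "literal"), "epsilon")
})

test_that("combining the six sub-indices preserves the printed bounds", {
  six0 <- setNames(rep(0, 6), subclass_ids())
  six100 <- setNames(rep(100, 6), subclass_ids())
  expect_equal(combine_cei(six0), 0)
  expect_equal(combine_cei(six100), 100)
  one <- setNames(c(100, 0, 0, 0, 0, 0), subclass_ids())
  expect_equal(combine_cei(one), 100 / 6)
  expect_equal(combine_cei(one, mode = "literal"), 100)
  expect_error(combine_cei(six0[1:5]), "missing subclass")
})

test_that("normalized CEI is monotone in the number of extreme records", {
  ref <- tiny_weather(n = 300, seed = 8)
  ev <- tiny_weather(n = 40, seed = 9)
  m <- extreme_magnitude(ev, ref, "W")
  base <- subclass_cei(m)
  # appending one extreme record never lowers the count-based index
  m2 <- m
  m2$values <- c(m$values, m$threshold * 2)
  grown <- subclass_cei(m2) * length(m2$values) / 100  # extreme count
  expect_gte(grown, subclass_cei(m) * length(m$values) / 100)
  expect_gte(subclass_cei(m2) * (length(m$values) + 1),
             base * length(m$values))
})

test_that("drought profile run-length encodes dry spells and categorizes them", {
  # all wet: no drought
  p <- drought_profile(precip_series(rep(5, 40)))
  expect_length(p$dry_spells, 0)
  expect_equal(p$category, "near normal")

  # hand-counted runs {3, 4}, 7 dry days in the month
  p <- drought_profile(precip_series(c(0, 0, 0, 5, 0, 0, 0, 0)))
  expect_equal(p$dry_spells, c(3L, 4L))
  expect_equal(sum(p$dd), 7)

  # 70 consecutive dry days: 10 full weeks -> extreme
  p <- drought_profile(precip_series(c(rep(5, 5), rep(0, 70), rep(5, 5))))
  expect_equal(p$weeks_under_drought, 10L)
  expect_equal(p$category, "extreme")

  # cutoff boundaries: 2 weeks near normal, 3 mild-moderate, 6 severe
  expect_equal(drought_profile(precip_series(c(rep(0, 20), 5)))$category,
               "near normal")
  expect_equal(drought_profile(precip_series(c(rep(0, 21), 5)))$category,
               "mild to moderate")
  expect_equal(drought_profile(precip_series(c(rep(0, 42), 5)))$category,
               "severe")
  # sum of run lengths never exceeds the series length
  set.seed(3)
  for (rep in 1:20) {
    pr <- ifelse(runif(50) < 0.5, 0, 5)
    expect_lte(sum(drought_profile(precip_series(pr))$dry_spells), 50)
  }
})

test_that("CEI results serialize to JSON with stable keys and read back", {
  gen <- generate_weather(weather_gen_config(n_days = 120, seed = 31))
  r <- compute_cei(gen$eval, gen$ref)
  path <- withr::local_tempfile(fileext = ".json")
  cei_to_json(r, path)
  obj <- jsonlite::fromJSON(path)
  expect_named(obj, c("cei_ht", "cei_lt", "cei_hp", "cei_lp", "cei_d",
                      "cei_w", "cei", "mode", "percentile"),
               ignore.order = TRUE)
  back <- cei_from_json(path)
  expect_equal(back$per_subclass, r$per_subclass)
  expect_equal(back$combined, r$combined)
})
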