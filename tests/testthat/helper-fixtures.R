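# Small in-code fixtures shared across tests.

tiny_weather <- function(n = 10, seed = 1, start = as.Date("2020-01-01")) {
  set.seed(seed)
  tmin <- rnorm(n, 16, 4)
  tmax <- tmin + rgamma(n, shape = 16, scale = 0.75)
  wet <- runif(n) < 0.6
  precip <- ifelse(wet, rgamma(n, 2, scale = 5), 0)
  weather_series(start + seq_len(n) - 1, tmax, tmin, precip,
                 rgamma(n, 9, scale = 5 / 3))
}

# weather series with explicitly chosen precipitation (temps/wind benign)
precip_series <- function(precip, start = as.Date("2020-01-01")) {
  n <- length(precip)
  weather_series(start + seq_len(n) - 1, rep(25, n), rep(15, n), precip,
                 rep(10, n))
}

write_tmp_weather_csv <- function(ws) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  write_weather_csv(ws, path)
  path
}

# independent sort-based percentile oracle: value of the k-th most extreme
# |e|, k = ceiling(n * p / 100), via ascending sort and back-indexing
oracle_threshold <- function(e, p = 10) {
  a <- sort(abs(e))
  n <- length(a)
  k <- max(1, ceiling(n * p / 100))
  a[n - k + 1]
}
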