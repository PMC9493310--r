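#' Synthetic weather generator configuration
#'
#' Describes the base climate a synthetic site is drawn from and, per
#' extreme sub-category, the fraction of records to plant beyond the
#' reference extreme threshold. Defaults emulate a warm-temperate maize
#' site: daily minima around 16 degrees C (sd 4), maxima around 28 (sd 4,
#' never below the same day's minimum), zero-inflated gamma precipitation
#' (wet-day probability 0.6, mean wet-day depth 10 mm) and gamma wind
#' around 15 km/h.
#'
#' @param n_days Series length, days (>= 30).
#' @param seed Integer seed; generation is a pure function of the config.
#' @param start First calendar date.
#' @param tmax_mean,tmax_sd Daily maximum temperature, degrees C.
#' @param tmin_mean,tmin_sd Daily minimum temperature, degrees C.
#' @param wet_prob Probability a day is wet.
#' @param precip_shape,precip_scale Gamma parameters of wet-day depth, mm.
#' @param wind_mean,wind_sd Wind speed moments, km/h (gamma-matched).
#' @param extreme_fraction Named vector over [subclass_ids()]: fraction of
#'   records (windows, for drought) planted beyond the reference threshold.
#'   A fraction of 0 leaves that subclass untouched (natural base rate).
#' @param dry_threshold A day is dry iff precip <= this, mm.
#' @param percentile Screening level used when planting, percent.
#' @return A list of class `weather_gen_config`.
#' @export
weather_gen_config <- function(n_days = 365, seed = 1,
                               start = as.Date("2001-01-01"),
                               tmax_mean = 28, tmax_sd = 4,
                               tmin_mean = 16, tmin_sd = 4,
                               wet_prob = 0.6,
                               precip_shape = 2, precip_scale = 5,
                               wind_mean = 15, wind_sd = 5,
                               extreme_fraction = c(HT = 0, LT = 0, HP = 0,
                                                    LP = 0, D = 0, W = 0),
                               dry_threshold = 0, percentile = 10) {
  ef <- c(HT = 0, LT = 0, HP = 0, LP = 0, D = 0, W = 0)
  ef[names(extreme_fraction)] <- extreme_fraction
  if (any(!names(extreme_fraction) %in% subclass_ids()))
    stop("unknown subclass in extreme_fraction", call. = FALSE)
  if (any(ef < 0 | ef > 1)) stop("extreme fractions must lie in [0, 1]",
                                 call. = FALSE)
  if (n_days < 30) stop("n_days must be >= 30", call. = FALSE)
  structure(list(n_days = as.integer(n_days), seed = as.integer(seed),
                 start = as.Date(start),
                 tmax_mean = tmax_mean, tmax_sd = tmax_sd,
                 tmin_mean = tmin_mean, tmin_sd = tmin_sd,
                 wet_prob = wet_prob, precip_shape = precip_shape,
                 precip_scale = precip_scale,
                 wind_mean = wind_mean, wind_sd = wind_sd,
                 extreme_fraction = ef, dry_threshold = dry_threshold,
                 percentile = percentile),
            class = "weather_gen_config")
}

# Solve (a - x) * x = -100 * m for the branch above a (used for HT/LT/HP/W
# magnitudes) or below (low branch, used to push minima down):
# x^2 - a*x - 100*m = 0.
displace_beyond <- function(a, m, branch = c("high", "low")) {
  branch <- match.arg(branch)
  d <- sqrt(a^2 + 400 * m)
  if (branch == "high") (a + d) / 2 else (a - d) / 2
}

draw_base_weather <- function(cfg) {
  n <- cfg$n_days
  tmin <- stats::rnorm(n, cfg$tmin_mean, cfg$tmin_sd)
  tmax <- stats::rnorm(n, cfg$tmax_mean, cfg$tmax_sd)
  tmax <- pmax(tmax, tmin + 0.5)
  wet <- stats::runif(n) < cfg$wet_prob
  precip <- numeric(n)
  precip[wet] <- stats::rgamma(sum(wet), shape = cfg$precip_shape,
                               scale = cfg$precip_scale)
  wshape <- (cfg$wind_mean / cfg$wind_sd)^2
  wind <- stats::rgamma(n, shape = wshape, scale = cfg$wind_mean / wshape)
  list(tmin = tmin, tmax = tmax, precip = precip, wind = wind)
}

#' Generate a reference and an evaluation weather series
#'
#' The reference series is drawn from the configured base climate. The
#' evaluation series follows the same law, except that for every subclass
#' with `extreme_fraction > 0` the planting is exact: `round(f * n)`
#' records (or monthly windows for drought) are displaced beyond the
#' reference extreme-decile threshold and every other record is, if
#' necessary, pulled inside it, so the normalized per-subclass CEI equals
#' `100 * round(f * n) / n` by construction. A fraction of exactly 0
#' leaves the subclass untouched, so its CEI sits near the screening base
#' rate (10 at the default level). Drought planting converts wet days to
#' dry but always leaves a few wet days per displaced month so that the
#' precipitation subclasses stay screenable.
#'
#' @param cfg A [weather_gen_config()].
#' @return A list with `eval` and `ref` [weather_series()], the `config`,
#'   and `truth`: per-subclass planted counts, class sizes and the exact
#'   normalized CEI implied by the planting (`NA` for untouched
#'   subclasses).
#' @export
generate_weather <- function(cfg) {
  stopifnot(inherits(cfg, "weather_gen_config"))
  set.seed(cfg$seed)
  ref_raw <- draw_base_weather(cfg)
  eval_raw <- draw_base_weather(cfg)
  dates <- cfg$start + seq_len(cfg$n_days) - 1L
  ref <- weather_series(dates, ref_raw$tmax, ref_raw$tmin, ref_raw$precip,
                        ref_raw$wind, site_id = "synthetic-ref",
                        role = "reference")
  ev <- eval_raw
  dt <- cfg$dry_threshold
  truth <- list()

  ref_stats <- function(x_ref, kind) {
    a <- mean(x_ref)
    e <- extreme_e(x_ref, a, kind)
    th <- extreme_threshold(e, cfg$percentile)
    list(a = a, thr = th$threshold)
  }
  pick <- function(n, f) {
    k <- round(f * n)
    list(k = k, idx = if (k > 0) sample.int(n, k) else integer(0))
  }

  # --- drought: monthly windows (before the precip subclasses, which
  # screen whatever wet days remain) -----------------------------------
  f <- cfg$extreme_fraction[["D"]]
  mon <- format(dates, "%Y-%m")
  if (f > 0) {
    rs <- ref_stats(as.numeric(tapply(ref_raw$precip <= dt, mon, sum)), "D")
    umon <- unique(mon)
    sel <- pick(length(umon), f)
    for (j in seq_along(umon)) {
      di <- which(mon == umon[j])
      ndays <- length(di)
      dd <- sum(ev$precip[di] <= dt)
      if (j %in% sel$idx) {
        target <- displace_beyond(rs$a, rs$thr * stats::runif(1, 1.3, 1.8))
        target <- min(round(target), ndays - 3L)
        if (abs(extreme_e(target, rs$a, "D")) < rs$thr) target <- ndays
      } else {
        target <- round(rs$a) + sample(-1:1, 1)
        target <- max(0L, min(target, ndays))
        if (abs(extreme_e(target, rs$a, "D")) >= rs$thr) target <- round(rs$a)
        if (abs(extreme_e(dd, rs$a, "D")) < rs$thr) target <- dd  # already fine
      }
      if (target > dd) {          # convert wet days to dry
        wet_i <- di[ev$precip[di] > dt]
        conv <- sample(wet_i, target - dd)
        ev$precip[conv] <- 0
      } else if (target < dd) {   # convert dry days to wet
        dry_i <- di[ev$precip[di] <= dt]
        conv <- sample(dry_i, dd - target)
        ev$precip[conv] <- dt + stats::rgamma(length(conv),
                                              shape = cfg$precip_shape,
                                              scale = cfg$precip_scale)
      }
    }
    truth$D <- list(k = sel$k, n = length(umon))
  }

  # --- high / low precipitation: wet days split at the reference wet
  # median --------------------------------------------------------------
  ref_wet <- ref_raw$precip[ref_raw$precip > dt]
  wet_med <- stats::median(ref_wet)
  for (kind in c("HP", "LP")) {
    f <- cfg$extreme_fraction[[kind]]
    if (f <= 0) next
    x_ref <- if (kind == "HP") ref_wet[ref_wet > wet_med]
             else ref_wet[ref_wet <= wet_med]
    rs <- ref_stats(x_ref, kind)
    cls <- if (kind == "HP")
      which(ev$precip > dt & ev$precip > wet_med)
    else
      which(ev$precip > dt & ev$precip <= wet_med)
    n <- length(cls)
    if (n == 0L) { truth[[kind]] <- list(k = 0L, n = 0L); next }
    sel <- pick(n, f)
    sel_i <- cls[sel$idx]
    oth_i <- setdiff(cls, sel_i)
    if (kind == "HP") {
      m <- rs$thr * stats::runif(length(sel_i), 1.3, 1.8)
      ev$precip[sel_i] <- displace_beyond(rs$a, m)
      # pull non-selected extremes back near the class mean
      e_oth <- abs(extreme_e(ev$precip[oth_i], rs$a, kind))
      fix <- oth_i[e_oth >= rs$thr]
      ev$precip[fix] <- rs$a * stats::runif(length(fix), 0.95, 1.05)
    } else {
      # |E| is maximised inside the class domain at the wet median or at
      # a/2; either dominates every reference record, hence the threshold
      cand <- c(wet_med, rs$a / 2)
      cand <- cand[cand > dt & cand <= wet_med]
      xstar <- cand[which.max(abs(extreme_e(cand, rs$a, kind)))]
      ev$precip[sel_i] <- xstar
      e_oth <- abs(extreme_e(ev$precip[oth_i], rs$a, kind))
      fix <- oth_i[e_oth >= rs$thr]
      ev$precip[fix] <- rs$a
    }
    truth[[kind]] <- list(k = sel$k, n = n)
  }

  # --- temperatures and wind ------------------------------------------
  plant_column <- function(x_eval, x_ref, kind, push) {
    rs <- ref_stats(x_ref, kind)
    n <- length(x_eval)
    sel <- pick(n, cfg$extreme_fraction[[kind]])
    m <- rs$thr * stats::runif(sel$k, 1.3, 1.8)
    x_eval[sel$idx] <- displace_beyond(rs$a, m, branch = push)
    oth <- setdiff(seq_len(n), sel$idx)
    e_oth <- abs(extreme_e(x_eval[oth], rs$a, kind))
    fix <- oth[e_oth >= rs$thr]
    delta <- min(50 * rs$thr / max(abs(rs$a), 1), 0.25 * max(abs(rs$a), 1))
    x_eval[fix] <- rs$a + stats::runif(length(fix), -delta, delta)
    list(x = x_eval, k = sel$k, n = n, a = rs$a, thr = rs$thr)
  }
  if (cfg$extreme_fraction[["HT"]] > 0) {
    p <- plant_column(ev$tmax, ref_raw$tmax, "HT", "high")
    ev$tmax <- p$x
    # keep tmax >= tmin without re-crossing the threshold
    clash <- which(ev$tmax < ev$tmin)
    ev$tmin[clash] <- ev$tmax[clash] - 0.5
    truth$HT <- list(k = p$k, n = p$n)
  }
  if (cfg$extreme_fraction[["LT"]] > 0) {
    p <- plant_column(ev$tmin, ref_raw$tmin, "LT", "low")
    ev$tmin <- p$x
    clash <- which(ev$tmin > ev$tmax)
    ev$tmin[clash] <- pmin(ev$tmin[clash], ev$tmax[clash] - 0.5)
    bad <- clash[abs(extreme_e(ev$tmin[clash], p$a, "LT")) >= p$thr]
    ev$tmin[bad] <- pmin(p$a, ev$tmax[bad] - 0.5)
    truth$LT <- list(k = p$k, n = p$n)
  }
  if (cfg$extreme_fraction[["W"]] > 0) {
    p <- plant_column(ev$wind, ref_raw$wind, "W", "high")
    ev$wind <- pmax(p$x, 0)
    truth$W <- list(k = p$k, n = p$n)
  }
  ev$tmax <- pmax(ev$tmax, ev$tmin)

  eval_ws <- weather_series(dates, ev$tmax, ev$tmin, ev$precip, ev$wind,
                            site_id = "synthetic-eval", role = "evaluation")
  planted_cei <- vapply(subclass_ids(), function(s) {
    t <- truth[[s]]
    if (is.null(t) || t$n == 0L) NA_real_ else 100 * t$k / t$n
  }, numeric(1))
  list(eval = eval_ws, ref = ref, config = cfg,
       truth = list(per_subclass = truth, planted_cei = planted_cei))
}

#' Synthetic phenophase-shift generator configuration
#'
#' Ground truth for sensitivity recovery: the generator inverts
#' `P_Si = S* x CEI` and spreads the implied total shift
#' `sum(delta_p) = S* x CEI x 100 x Np` equally over the phenophases, then
#' adds independent Gaussian noise (sd `noise_sd`, in percentage points of
#' `delta_p`, truncated at 0). With `noise_sd = 0` the composed recovery
#' `phenology_sensitivity(phenology_shift_index(.), cei)` returns `S*`
#' exactly.
#'
#' @param n_p Number of phenophases (ignored when `templates` given).
#' @param true_sensitivity Ground-truth sensitivity S* (dimensionless).
#' @param cei Climate extreme index the shifts respond to, percent.
#' @param noise_sd Gaussian noise on each `delta_p`, percentage points.
#' @param seed Integer seed.
#' @param templates Optional `data.frame` with columns `phenophase`,
#'   `baseline_duration_days` and optionally `shift_cap_pct` (a biological
#'   ceiling on `delta_p`, percent of duration; capping breaks the exact
#'   inversion and is meant for realistic demo scenarios).
#' @return A list of class `pheno_gen_config`.
#' @export
pheno_gen_config <- function(n_p = 4, true_sensitivity = 0.05, cei = 10,
                             noise_sd = 0, seed = 1, templates = NULL) {
  if (!is.null(templates)) {
    stopifnot(is.data.frame(templates),
              all(c("phenophase", "baseline_duration_days") %in%
                    names(templates)))
    n_p <- nrow(templates)
  }
  if (n_p < 1) stop("n_p must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cei < 0) stop("cei must be >= 0", call. = FALSE)
  if (true_sensitivity < 0) stop("true_sensitivity must be >= 0", call. = FALSE)
  structure(list(n_p = as.integer(n_p), true_sensitivity = true_sensitivity,
                 cei = cei, noise_sd = noise_sd, seed = as.integer(seed),
                 templates = templates),
            class = "pheno_gen_config")
}

#' Generate a phenophase shift set with known sensitivity
#'
#' @param cfg A [pheno_gen_config()].
#' @return A [phenology_shift_set()] whose noiseless sensitivity recovery is
#'   exact (see [pheno_gen_config()]). Shifts alternate advance/delay in
#'   sign; `delta_p` is sign-invariant.
#' @examples
#' cfg <- pheno_gen_config(n_p = 4, true_sensitivity = 0.05, cei = 10)
#' ps <- generate_phenology_shifts(cfg)
#' phenology_sensitivity(phenology_shift_index(ps), 10)  # 0.05
#' @export
generate_phenology_shifts <- function(cfg) {
  stopifnot(inherits(cfg, "pheno_gen_config"))
  np <- cfg$n_p
  if (is.null(cfg$templates)) {
    name <- paste0("phenophase_", seq_len(np))
    dur <- rep(c(10, 20, 30, 40), length.out = np)
    cap <- rep(Inf, np)
  } else {
    name <- as.character(cfg$templates$phenophase)
    dur <- as.numeric(cfg$templates$baseline_duration_days)
    cap <- if ("shift_cap_pct" %in% names(cfg$templates))
      as.numeric(cfg$templates$shift_cap_pct) else rep(Inf, np)
  }
  delta_p <- rep(cfg$true_sensitivity * cfg$cei * 100, np)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    delta_p <- pmax(0, delta_p + stats::rnorm(np, 0, cfg$noise_sd))
  }
  delta_p <- pmin(delta_p, cap)
  sgn <- rep_len(c(1, -1), np)
  phenology_shift_set(name, dur, sgn * delta_p * dur / 100)
}

#' Maize demonstration scenario
#'
#' Bundled presets for a four-phenophase maize crop. The low-temperature
#' shift ceilings follow the documented maize response: seedling emergence
#' may be prolonged by up to 32 percent of its duration and silking by up
#' to 17 percent, while the terminal stages (emergence and maturity) can
#' shift by more than 15 percent of their duration under almost every
#' extreme sub-category.
#'
#' @return A list with `phenophases` (template `data.frame` with
#'   `phenophase`, `baseline_duration_days`, `shift_cap_pct`), `pheno_cfg`
#'   (a ready [pheno_gen_config()] using the templates) and `psd` (a
#'   deterministic demonstration [psd_timeseries()] of a low-temperature
#'   emergence response over an eight-month season).
#' @export
maize_scenario <- function() {
  templates <- data.frame(
    phenophase = c("seedling emergence", "silking", "grain filling",
                   "maturity"),
    baseline_duration_days = c(12, 18, 38, 30),
    shift_cap_pct = c(32, 17, 12, 18))
  cfg <- pheno_gen_config(true_sensitivity = 0.05, cei = 5, noise_sd = 2,
                          seed = 1, templates = templates)
  # deterministic logistic adoption of the shift across a 100-plant stand
  times <- 1:8
  n_shifted <- round(100 * stats::plogis((times - 3.5) / 0.9))
  shifted <- t(vapply(n_shifted,
                      function(k) seq_len(100) <= k, logical(100)))
  psd <- psd_timeseries(shifted, times, subclass = "LT",
                        phenophase = "seedling emergence")
  list(phenophases = templates, pheno_cfg = cfg, psd = psd)
}
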