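#' Monte-Carlo sensitivity analysis of the forcing model
#'
#' For each climate extreme index on the grid, `reps` phenophase-shift sets
#' are simulated from `gen_cfg` (noise included), the forcing index is
#' computed, and a *detection* is scored when the forcing is nonzero
#' (i.e., the minimum impact limit passed) and within `tolerance` relative
#' of the ground truth `F* = CEI / S*`. The sensitivity index at a grid
#' point is the detection percentage. With additive shift noise the curve
#' rises over small CEI — where the noise is large relative to the planted
#' shift — and plateaus once the signal dominates.
#'
#' @param grid Strictly increasing CEI values (>= 0).
#' @param reps Replicates per grid point.
#' @param gen_cfg A [pheno_gen_config()]; its `cei` field is overridden by
#'   each grid value and its `seed` by the stream derived from `seed`.
#' @param tolerance Relative detection tolerance on `f_p` (default 0.1).
#' @param mil Minimum impact limit passed to [phenology_forcing()].
#' @param seed Integer seed for the replicate stream.
#' @return `data.frame` of class `sensitivity_curve`: columns `cei`,
#'   `sensitivity` (percent in \[0, 100\]).
#' @export
sensitivity_analysis <- function(grid, reps = 200,
                                 gen_cfg = pheno_gen_config(noise_sd = 2),
                                 tolerance = 0.1, mil = 1.0, seed = 1) {
  check_grid(grid)
  stopifnot(reps >= 1, inherits(gen_cfg, "pheno_gen_config"),
            gen_cfg$true_sensitivity > 0)
  fp <- simulate_forcing_reps(grid, reps, gen_cfg, mil, seed)
  f_star <- grid / gen_cfg$true_sensitivity
  sens <- vapply(seq_along(grid), function(g) {
    v <- fp[, g]
    hit <- is.finite(v) & v > 0 & abs(v - f_star[g]) <= tolerance * f_star[g]
    100 * mean(hit)
  }, numeric(1))
  structure(data.frame(cei = grid, sensitivity = sens),
            reps = reps, seed = seed, tolerance = tolerance,
            class = c("sensitivity_curve", "data.frame"))
}

check_grid <- function(grid) {
  if (length(grid) == 0L || any(grid < 0) ||
      (length(grid) > 1L && is.unsorted(grid, strictly = TRUE)))
    stop("grid must be strictly increasing and non-negative", call. = FALSE)
}

# One forcing draw per (rep, grid point); reproducible: the seed stream is
# a fixed function of `seed` alone, so a brute-force re-simulation with the
# same derivation reproduces every draw.
simulate_forcing_reps <- function(grid, reps, gen_cfg, mil, seed) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, reps * length(grid)),
                  nrow = reps)
  vapply(seq_along(grid), function(g) {
    vapply(seq_len(reps), function(r) {
      cfg <- gen_cfg
      cfg$cei <- grid[g]
      cfg$seed <- seeds[r, g]
      phenology_forcing(grid[g], generate_phenology_shifts(cfg), mil)$f_p
    }, numeric(1))
  }, numeric(reps))
}

#' Bootstrap uncertainty analysis of the forcing model
#'
#' For each grid CEI, `reps` forcing indices are simulated as in
#' [sensitivity_analysis()]; the uncertainty index is the bootstrap
#' coefficient of variation of the forcing index: the mean over `boot`
#' resamples of `sd(resample) / mean(resample)`. Noiseless generation gives
#' 0 everywhere; a grid point whose mean forcing is 0 (fully suppressed by
#' the minimum impact limit) is flagged undefined (`NA`).
#'
#' @inheritParams sensitivity_analysis
#' @param boot Bootstrap resamples per grid point (>= 100).
#' @return `data.frame` of class `sensitivity_curve`: columns `cei`,
#'   `uncertainty`.
#' @export
uncertainty_analysis <- function(grid, reps = 200, boot = 500,
                                 gen_cfg = pheno_gen_config(noise_sd = 2),
                                 mil = 1.0, seed = 1) {
  check_grid(grid)
  stopifnot(boot >= 100, inherits(gen_cfg, "pheno_gen_config"))
  fp <- simulate_forcing_reps(grid, reps, gen_cfg, mil, seed)
  unc <- vapply(seq_along(grid), function(g) {
    v <- fp[, g]
    v <- v[is.finite(v)]
    if (length(v) == 0L || mean(v) == 0) return(NA_real_)
    cvs <- vapply(seq_len(boot), function(b) {
      s <- v[sample.int(length(v), replace = TRUE)]
      m <- mean(s)
      if (m == 0) return(NA_real_)
      stats::sd(s) / m
    }, numeric(1))
    mean(cvs, na.rm = TRUE)
  }, numeric(1))
  structure(data.frame(cei = grid, uncertainty = unc),
            reps = reps, boot = boot, seed = seed,
            class = c("sensitivity_curve", "data.frame"))
}

#' Full verification run: sensitivity + uncertainty + meta-summary
#'
#' Convenience wrapper reproducing the whole verification protocol on one
#' seed: the sensitivity and uncertainty curves over a CEI grid, and a
#' meta-analytic summary in which each grid point is one "study" whose
#' effect is the mean log-ratio of simulated to ground-truth forcing
#' (log OR-style scale; 0 = perfect agreement) with its Monte-Carlo
#' variance.
#'
#' @inheritParams uncertainty_analysis
#' @param tolerance Relative detection tolerance for the sensitivity index.
#' @param model Meta-analysis model, `"fixed"` or `"random"`.
#' @return A list with `curve` (`data.frame`: `cei`, `sensitivity`,
#'   `uncertainty`) and `meta` (a [meta_summary()]).
#' @export
verify_forcing_model <- function(grid = 1:15, reps = 200, boot = 500,
                                 gen_cfg = pheno_gen_config(noise_sd = 2),
                                 tolerance = 0.1, mil = 1.0, model = "fixed",
                                 seed = 1) {
  sens <- sensitivity_analysis(grid, reps, gen_cfg, tolerance, mil, seed)
  unc <- uncertainty_analysis(grid, reps, boot, gen_cfg, mil, seed)
  curve <- data.frame(cei = grid, sensitivity = sens$sensitivity,
                      uncertainty = unc$uncertainty)
  fp <- simulate_forcing_reps(grid, reps, gen_cfg, mil, seed)
  f_star <- grid / gen_cfg$true_sensitivity
  eff <- var <- rep(NA_real_, length(grid))
  for (g in seq_along(grid)) {
    lr <- log(fp[, g][is.finite(fp[, g]) & fp[, g] > 0] / f_star[g])
    if (length(lr) >= 2L) {
      eff[g] <- mean(lr)
      var[g] <- stats::var(lr) / length(lr)
    }
  }
  ok <- is.finite(eff) & is.finite(var) & var > 0
  meta <- if (sum(ok) >= 2L) meta_summary(eff[ok], var[ok], model = model)
          else NULL
  list(curve = structure(curve, reps = reps, boot = boot, seed = seed,
                         class = c("sensitivity_curve", "data.frame")),
       meta = meta)
}

#' Inverse-variance meta-analytic summary
#'
#' Pools per-study effect sizes (log odds-ratio scale or any other
#' symmetric effect) with inverse-variance weights, as used by the
#' forest/funnel verification of the forcing model. Fixed-effect weights
#' are proportional to `1/v_i`; the random-effects model adds the
#' DerSimonian-Laird `tau^2` to every variance (and collapses to the
#' fixed-effect fit when Cochran's Q is at most k-1, where `tau^2`
#' truncates to 0). Heterogeneity is summarized by Q and
#' `I^2 = max(0, (Q - (k-1)) / Q) * 100`; the 95 percent confidence
#' interval is normal-theory based.
#'
#' @param effects Numeric effect sizes, one per study (k >= 2).
#' @param variances Positive per-study variances.
#' @param model `"fixed"` or `"random"`.
#' @return An object of class `meta_summary`: list with `effects`,
#'   `variances`, `weights` (normalized, sum 1), `pooled`, `se`, `ci_low`,
#'   `ci_high`, `q`, `i2`, `tau2`, `model`.
#' @examples
#' meta_summary(c(1, 3), c(1, 1))  # pooled 2, Q = 2, weights 0.5/0.5
#' @export
meta_summary <- function(effects, variances, model = c("fixed", "random")) {
  model <- match.arg(model)
  if (length(effects) < 2L)
    stop("meta-analysis needs at least 2 studies", call. = FALSE)
  if (length(variances) != length(effects))
    stop("effects and variances must have equal length", call. = FALSE)
  if (any(!is.finite(variances) | variances <= 0))
    stop("all variances must be positive", call. = FALSE)
  fit <- metafor::rma(yi = effects, vi = variances,
                      method = if (model == "fixed") "FE" else "DL")
  k <- length(effects)
  q <- as.numeric(fit$QE)
  i2 <- max(0, (q - (k - 1)) / q) * 100
  if (!is.finite(i2)) i2 <- 0
  tau2 <- if (model == "random") as.numeric(fit$tau2) else 0
  w <- 1 / (variances + tau2)
  structure(list(effects = effects, variances = variances,
                 weights = w / sum(w),
                 pooled = as.numeric(fit$b), se = as.numeric(fit$se),
                 ci_low = as.numeric(fit$ci.lb),
                 ci_high = as.numeric(fit$ci.ub),
                 q = q, i2 = i2, tau2 = tau2, model = model),
            class = "meta_summary")
}

#' @export
print.meta_summary <- function(x, ...) {
  cat(sprintf("<meta_summary> %s-effect pooling of %d studies\n",
              x$model, length(x$effects)))
  cat(sprintf("  pooled = %.4g [%.4g, %.4g] (95%% CI), Q = %.4g, I2 = %.3g%%, tau2 = %.4g\n",
              x$pooled, x$ci_low, x$ci_high, x$q, x$i2, x$tau2))
  invisible(x)
}

#' Serialize a meta summary to JSON
#' @param x A [meta_summary()].
#' @param path Optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
meta_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "meta_summary"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Funnel-plot coordinates
#'
#' Per-study (effect, standard error) pairs together with the 95 percent
#' pseudo-confidence guide lines `pooled +/- 1.96 * SE` over the observed
#' SE range; the funnel apex (SE = 0) sits at the pooled effect.
#'
#' @param summary A [meta_summary()].
#' @param n_guide Number of points per guide line.
#' @return A list with `points` (`data.frame`: `effect`, `se`), `guides`
#'   (`data.frame`: `se`, `lower`, `upper`) and `pooled`.
#' @export
funnel_coordinates <- function(summary, n_guide = 50) {
  stopifnot(inherits(summary, "meta_summary"))
  se <- sqrt(summary$variances)
  gse <- seq(0, max(se), length.out = n_guide)
  z <- stats::qnorm(0.975)
  list(points = data.frame(effect = summary$effects, se = se),
       guides = data.frame(se = gse,
                           lower = summary$pooled - z * gse,
                           upper = summary$pooled + z * gse),
       pooled = summary$pooled)
}

#' Verification plots
#'
#' ggplot2 renderings of the forest plot, funnel plot and the dual
#' sensitivity/uncertainty curve. ggplot2 must be installed.
#'
#' @param x A [meta_summary()] (forest/funnel) or the `curve` element of
#'   [verify_forcing_model()].
#' @return A ggplot object.
#' @export
plot_forest <- function(x) {
  need_ggplot()
  stopifnot(inherits(x, "meta_summary"))
  z <- stats::qnorm(0.975)
  df <- data.frame(study = factor(seq_along(x$effects)),
                   effect = x$effects,
                   lo = x$effects - z * sqrt(x$variances),
                   hi = x$effects + z * sqrt(x$variances),
                   w = x$weights)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$study)) +
    ggplot2::geom_vline(xintercept = x$pooled, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$w), shape = 15) +
    ggplot2::labs(x = "effect (log ratio)", y = "study",
                  size = "weight",
                  title = sprintf("Pooled %.3g [%.3g, %.3g]",
                                  x$pooled, x$ci_low, x$ci_high)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_forest
#' @export
plot_funnel <- function(x) {
  need_ggplot()
  fc <- funnel_coordinates(x)
  ggplot2::ggplot(fc$points, ggplot2::aes(x = .data$effect, y = .data$se)) +
    ggplot2::geom_line(data = fc$guides,
                       ggplot2::aes(x = .data$lower, y = .data$se),
                       linetype = "dotted") +
    ggplot2::geom_line(data = fc$guides,
                       ggplot2::aes(x = .data$upper, y = .data$se),
                       linetype = "dotted") +
    ggplot2::geom_vline(xintercept = fc$pooled, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "effect (log ratio)", y = "standard error") +
    ggplot2::theme_minimal()
}

#' @rdname plot_forest
#' @export
plot_verification_curve <- function(x) {
  need_ggplot()
  stopifnot(all(c("cei", "sensitivity", "uncertainty") %in% names(x)))
  scale <- max(x$sensitivity, na.rm = TRUE) /
    max(x$uncertainty, na.rm = TRUE)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$cei)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sensitivity), color = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$uncertainty * scale),
                       color = "orange") +
    ggplot2::scale_y_continuous(
      name = "sensitivity index (%)",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "uncertainty index")) +
    ggplot2::labs(x = "climate extreme index (CEI)") +
    ggplot2::theme_minimal()
}

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}
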