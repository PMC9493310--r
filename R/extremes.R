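#' Extreme environmental event sub-categories
#'
#' The six sub-categories of extreme environmental events screened by the
#' climate extreme index: high temperature (HT, daily maxima), low
#' temperature (LT, daily minima), high precipitation (HP, wet days above
#' the reference wet-day median), low precipitation (LP, wet days at or
#' below it), drought (D, monthly dry-day counts) and wind (W, daily wind
#' speed).
#'
#' @return Character vector of the six subclass identifiers.
#' @export
subclass_ids <- function() c("HT", "LT", "HP", "LP", "D", "W")

# Per-record screened variable X for one subclass, plus the variables the
# split/aggregation needs from the reference. Dry days (precip <= dry
# threshold) belong to the drought subclass and are excluded from the
# HP/LP precipitation screening.
subclass_variable <- function(series, subclass, ref_wet_median = NULL,
                              dry_threshold = 0) {
  switch(subclass,
    HT = series$tmax,
    LT = series$tmin,
    W  = series$wind,
    HP = {
      wet <- series$precip > dry_threshold
      series$precip[wet & series$precip > ref_wet_median]
    },
    LP = {
      wet <- series$precip > dry_threshold
      series$precip[wet & series$precip <= ref_wet_median]
    },
    D  = monthly_dry_days(series, dry_threshold),
    stop("unknown subclass: ", subclass, call. = FALSE)
  )
}

monthly_dry_days <- function(series, dry_threshold = 0) {
  mon <- format(series$date, "%Y-%m")
  as.numeric(tapply(series$precip <= dry_threshold, mon, sum))
}

# E = (X_Avr - X) * X / 100 for HT/LT/HP/LP/D; wind uses the anomaly the
# other way round, E = (WS - WS') * WS / 100; screening is on |E| so the
# sign convention only affects reported signs.
extreme_e <- function(x, x_avr, subclass) {
  if (subclass == "W") (x - x_avr) * x / 100 else (x_avr - x) * x / 100
}

#' Per-record extreme magnitudes for one subclass
#'
#' Computes the dimensionless extreme magnitude E for every screened record
#' of the evaluation series, together with the reference-period extreme
#' threshold. E is the product of the anomaly from the reference mean and
#' the record's own magnitude, divided by 100 (`E = (X_Avr - X) * X / 100`;
#' wind uses `(WS - WS') * WS / 100`), so large departures on large values
#' score highest. The threshold is the boundary of the most-extreme
#' `percentile` percent of |E| over the reference series ("tenth percentile
#' of the period of record" counted from the extreme end), and `e_10p` is
#' the mean |E| of that extreme tail.
#'
#' @param eval_series Evaluation [weather_series()].
#' @param ref_series Reference (climatology) [weather_series()]; defaults to
#'   the evaluation series itself when no separate climatology exists (in
#'   that case a series cannot be 100 percent extreme by construction).
#' @param subclass One of [subclass_ids()].
#' @param percentile Screening level, percent (default 10 = top decile of |E|).
#' @param dry_threshold A day is dry iff `precip <= dry_threshold` (mm).
#' @return An object of class `extreme_magnitudes`: list with `subclass`,
#'   `values` (eval E, one per screened record/window), `ref_values`,
#'   `threshold`, `e_10p`, `x_avr`, `percentile`.
#' @export
extreme_magnitude <- function(eval_series, ref_series = eval_series, subclass,
                              percentile = 10, dry_threshold = 0) {
  stopifnot(inherits(eval_series, "weather_series"),
            inherits(ref_series, "weather_series"))
  subclass <- match.arg(subclass, subclass_ids())
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]", call. = FALSE)

  ref_wet_median <- NULL
  if (subclass %in% c("HP", "LP")) {
    wet <- ref_series$precip[ref_series$precip > dry_threshold]
    if (length(wet) == 0L)
      stop("reference series has no wet days; cannot screen ", subclass,
           call. = FALSE)
    ref_wet_median <- stats::median(wet)
  }
  x_ref <- subclass_variable(ref_series, subclass, ref_wet_median, dry_threshold)
  if (length(x_ref) == 0L)
    stop("reference series has no records in subclass ", subclass, call. = FALSE)
  x_avr <- mean(x_ref)
  e_ref <- extreme_e(x_ref, x_avr, subclass)
  x_eval <- subclass_variable(eval_series, subclass, ref_wet_median, dry_threshold)
  e_eval <- extreme_e(x_eval, x_avr, subclass)

  thr <- extreme_threshold(e_ref, percentile)
  structure(list(subclass = subclass, values = e_eval, ref_values = e_ref,
                 threshold = thr$threshold, e_10p = thr$e_10p,
                 x_avr = x_avr, percentile = percentile),
            class = "extreme_magnitudes")
}

# Threshold = k-th largest |E| over the reference, k = ceiling(n * p / 100):
# exactly the k most extreme reference records satisfy |E| >= threshold
# (modulo ties). e_10p is the mean |E| of those k records.
extreme_threshold <- function(e_ref, percentile) {
  a <- sort(abs(e_ref), decreasing = TRUE)
  k <- max(1L, ceiling(length(a) * percentile / 100))
  list(threshold = a[k], e_10p = mean(a[seq_len(k)]))
}

#' @export
print.extreme_magnitudes <- function(x, ...) {
  cat(sprintf("<extreme_magnitudes> %s: %d eval records, threshold |E| >= %.4g (top %g%% of reference), e_10p = %.4g\n",
              x$subclass, length(x$values), x$threshold, x$percentile, x$e_10p))
  invisible(x)
}

#' Per-subclass climate extreme index
#'
#' In `normalized` mode (the default) CEI_X is the percentage of evaluation
#' records whose |E| reaches the reference-period extreme threshold — 0 when
#' no record is extreme, 100 when all are. `literal` mode evaluates the
#' printed deviation-from-the-tail-mean sum
#' `CEI_X = sum over extreme records of (e_10p - |E_i|) / |E_i|`,
#' which is unbounded and requires every extreme |E_i| to exceed `epsilon`.
#'
#' @param mags An [extreme_magnitude()] result.
#' @param mode `"normalized"` or `"literal"`.
#' @param epsilon Degenerate-denominator guard for literal mode.
#' @return CEI_X (percent in normalized mode; unbounded in literal mode).
#' @export
subclass_cei <- function(mags, mode = c("normalized", "literal"),
                         epsilon = 1e-9) {
  stopifnot(inherits(mags, "extreme_magnitudes"))
  mode <- match.arg(mode)
  ae <- abs(mags$values)
  n <- length(ae)
  if (n == 0L) return(0)
  extreme <- ae >= mags$threshold
  if (mode == "normalized") return(100 * sum(extreme) / n)
  if (!any(extreme)) return(0)
  if (any(ae[extreme] <= epsilon))
    stop("literal-mode CEI undefined: |E| <= epsilon in the extreme decile",
         call. = FALSE)
  sum((mags$e_10p - ae[extreme]) / ae[extreme])
}

#' Combine per-subclass indices into the total climate extreme index
#'
#' The six sub-indices are aggregated into one CEI. In `normalized` mode
#' the aggregate is their arithmetic mean, preserving the 0–100 bounds
#' (100 = the whole record extreme in every sub-category); `literal` mode
#' returns the plain sum.
#'
#' @param per_subclass Named numeric vector with one CEI_X per subclass id.
#' @param mode `"normalized"` or `"literal"`.
#' @return The combined CEI.
#' @export
combine_cei <- function(per_subclass, mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  miss <- setdiff(subclass_ids(), names(per_subclass))
  if (length(miss))
    stop("missing subclass indices: ", paste(miss, collapse = ", "),
         call. = FALSE)
  v <- as.numeric(per_subclass[subclass_ids()])
  if (mode == "normalized") mean(v) else sum(v)
}

#' Climate extreme index of a weather series
#'
#' End-to-end CEI computation: screens all six extreme sub-categories of the
#' evaluation series against the reference climatology and aggregates them.
#'
#' @inheritParams extreme_magnitude
#' @param mode `"normalized"` (percent of records in the extreme tail,
#'   bounded 0–100) or `"literal"` (printed deviation sum, unbounded).
#' @param epsilon Literal-mode denominator guard.
#' @return An object of class `cei_result`: list with `per_subclass` (named
#'   vector over [subclass_ids()]), `combined`, `mode`, `percentile`.
#' @examples
#' gen <- generate_weather(weather_gen_config(n_days = 120, seed = 7))
#' compute_cei(gen$eval, gen$ref)
#' @export
compute_cei <- function(eval_series, ref_series = eval_series,
                        mode = c("normalized", "literal"), percentile = 10,
                        dry_threshold = 0, epsilon = 1e-9) {
  mode <- match.arg(mode)
  per <- vapply(subclass_ids(), function(s) {
    m <- extreme_magnitude(eval_series, ref_series, s,
                           percentile = percentile,
                           dry_threshold = dry_threshold)
    subclass_cei(m, mode = mode, epsilon = epsilon)
  }, numeric(1))
  structure(list(per_subclass = per,
                 combined = combine_cei(per, mode = mode),
                 mode = mode, percentile = percentile),
            class = "cei_result")
}

#' @export
print.cei_result <- function(x, ...) {
  cat(sprintf("<cei_result> mode = %s, screening level = %g%%\n",
              x$mode, x$percentile))
  print(round(x$per_subclass, 3))
  cat(sprintf("combined CEI = %.3f\n", x$combined))
  invisible(x)
}

#' Serialize a CEI result to JSON
#'
#' Stable lower-case keys: `cei_ht, cei_lt, cei_hp, cei_lp, cei_d, cei_w,
#' cei, mode, percentile`.
#'
#' @param x A `cei_result`.
#' @param path Optional file path; when given, JSON is written there.
#' @return The JSON string (invisibly when `path` is given).
#' @export
cei_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cei_result"))
  obj <- c(as.list(stats::setNames(x$per_subclass,
                                   paste0("cei_", tolower(subclass_ids())))),
           list(cei = x$combined, mode = x$mode, percentile = x$percentile))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a CEI result back from JSON
#' @param path File written by [cei_to_json()].
#' @return A `cei_result`.
#' @export
cei_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  per <- vapply(paste0("cei_", tolower(subclass_ids())), function(k) {
    if (is.null(obj[[k]])) stop("CEI JSON missing key ", k, call. = FALSE)
    as.numeric(obj[[k]])
  }, numeric(1))
  names(per) <- subclass_ids()
  structure(list(per_subclass = per, combined = as.numeric(obj$cei),
                 mode = obj$mode, percentile = as.numeric(obj$percentile)),
            class = "cei_result")
}

#' Drought profile of a daily series
#'
#' Drought intensity is measured by dry-day duration: consecutive runs of
#' days without precipitation, monthly dry-day counts, and a categorical
#' intensity derived from the number of whole weeks spent under the longest
#' unbroken drought. Default category cutoffs (weeks under drought):
#' up to 2 near normal, 3–5 mild to moderate, 6–9 severe, 10 and more
#' extreme.
#'
#' @param series [weather_series()] to profile.
#' @param ref_series Reference series for the mean monthly dry-day count.
#' @param dry_threshold A day is dry iff `precip <= dry_threshold` (mm).
#' @param cutoffs Named numeric vector `c(near_normal=, mild_moderate=,
#'   severe=)`: upper bounds (weeks) of the first three categories.
#' @return An object of class `drought_profile`: list with `dry_spells`
#'   (run lengths, days), `dd` (dry days per calendar month), `dd_avr`
#'   (reference mean monthly dry days), `weeks_under_drought`, `category`.
#' @export
drought_profile <- function(series, ref_series = series, dry_threshold = 0,
                            cutoffs = c(near_normal = 2, mild_moderate = 5,
                                        severe = 9)) {
  stopifnot(inherits(series, "weather_series"), dry_threshold >= 0)
  dry <- series$precip <= dry_threshold
  r <- rle(dry)
  spells <- r$lengths[r$values]
  if (length(spells) == 0L) spells <- integer(0)
  weeks <- if (length(spells)) max(spells) %/% 7L else 0L
  category <- if (weeks <= cutoffs[["near_normal"]]) "near normal"
    else if (weeks <= cutoffs[["mild_moderate"]]) "mild to moderate"
    else if (weeks <= cutoffs[["severe"]]) "severe"
    else "extreme"
  structure(list(dry_spells = as.integer(spells),
                 dd = monthly_dry_days(series, dry_threshold),
                 dd_avr = mean(monthly_dry_days(ref_series, dry_threshold)),
                 weeks_under_drought = as.integer(weeks),
                 category = category, cutoffs = cutoffs),
            class = "drought_profile")
}

#' @export
print.drought_profile <- function(x, ...) {
  cat(sprintf("<drought_profile> %d dry spells (longest %d d), %d full weeks under drought: %s\n",
              length(x$dry_spells),
              if (length(x$dry_spells)) max(x$dry_spells) else 0L,
              x$weeks_under_drought, x$category))
  invisible(x)
}
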