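#' Daily weather series
#'
#' Construct and validate a daily weather series: one row per calendar day
#' with daily maximum and minimum temperature (degrees C), precipitation (mm)
#' and wind speed (km/h). This is the common input container for all extreme
#' index computations; a series is used either as the climatology
#' *reference* (the period of record that defines what counts as extreme) or
#' as the *evaluation* series being screened.
#'
#' @param date `Date` vector (or ISO-8601 text coercible to `Date`).
#' @param tmax,tmin Daily maximum / minimum temperature, degrees Celsius.
#' @param precip Daily precipitation, mm; must be non-negative.
#' @param wind Daily wind speed, km/h (direction is ignored); non-negative.
#' @param site_id Free-text site label.
#' @param role Either `"reference"` or `"evaluation"`.
#'
#' @return A `data.frame` of class `weather_series` with columns
#'   `date`, `tmax`, `tmin`, `precip`, `wind`, sorted by date, and
#'   attributes `site_id` and `role`.
#' @examples
#' ws <- weather_series(as.Date("2020-01-01") + 0:2,
#'                      tmax = c(10, 12, 9), tmin = c(2, 3, 1),
#'                      precip = c(0, 4.2, 0), wind = c(12, 8, 30))
#' ws
#' @export
weather_series <- function(date, tmax, tmin, precip, wind,
                           site_id = "site", role = c("evaluation", "reference")) {
  role <- match.arg(role)
  date <- as.Date(date)
  df <- data.frame(date = date, tmax = as.numeric(tmax), tmin = as.numeric(tmin),
                   precip = as.numeric(precip), wind = as.numeric(wind))
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  validate_weather(df)
  structure(df, site_id = site_id, role = role,
            class = c("weather_series", "data.frame"))
}

validate_weather <- function(df) {
  if (nrow(df) == 0L) stop("weather series must be non-empty", call. = FALSE)
  bad_row <- function(cond, field, msg) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("invalid weather record: row %d, field '%s': %s",
                   i[1L], field, msg), call. = FALSE)
  }
  bad_row(is.na(df$date), "date", "unparseable or missing date")
  bad_row(duplicated(df$date), "date", "duplicate date")
  bad_row(!is.finite(df$tmax), "tmax_c", "non-numeric value")
  bad_row(!is.finite(df$tmin), "tmin_c", "non-numeric value")
  bad_row(!is.finite(df$precip), "precip_mm", "non-numeric value")
  bad_row(!is.finite(df$wind), "wind_kmh", "non-numeric value")
  bad_row(df$precip < 0, "precip_mm", "negative precipitation")
  bad_row(df$wind < 0, "wind_kmh", "negative wind speed")
  bad_row(df$tmax < df$tmin, "tmax_c", "tmax below tmin")
  invisible(df)
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> site '%s' (%s), %d days: %s .. %s\n",
              attr(x, "site_id"), attr(x, "role"), nrow(x),
              format(min(x$date)), format(max(x$date))))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read / write a daily weather CSV
#'
#' The on-disk format is a plain comma-separated file with a mandatory
#' header `date,tmax_c,tmin_c,precip_mm,wind_kmh`, ISO-8601 dates and "."
#' decimal separators. Validation failures name the offending row and field.
#'
#' @param path File path.
#' @param site_id,role Passed to [weather_series()].
#' @return `read_weather_csv` returns a validated [weather_series()];
#'   `write_weather_csv` invisibly returns `path`.
#' @export
read_weather_csv <- function(path, site_id = basename(path),
                             role = c("evaluation", "reference")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("date", "tmax_c", "tmin_c", "precip_mm", "wind_kmh")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("weather CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- as.Date(as.character(raw$date), format = "%Y-%m-%d")
  if (anyNA(d))
    stop(sprintf("invalid weather record: row %d, field 'date': unparseable date '%s'",
                 which(is.na(d))[1L], raw$date[which(is.na(d))[1L]]), call. = FALSE)
  weather_series(d, raw$tmax_c, raw$tmin_c, raw$precip_mm, raw$wind_kmh,
                 site_id = site_id, role = match.arg(role))
}

#' @rdname read_weather_csv
#' @param ws A [weather_series()].
#' @export
write_weather_csv <- function(ws, path) {
  stopifnot(inherits(ws, "weather_series"))
  # %.17g keeps doubles bit-exact through the write-read round trip
  out <- data.frame(date = format(ws$date, "%Y-%m-%d"),
                    tmax_c = num17(ws$tmax), tmin_c = num17(ws$tmin),
                    precip_mm = num17(ws$precip), wind_kmh = num17(ws$wind))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

num17 <- function(x) sprintf("%.17g", x)

#' Phenophase shift set
#'
#' A table of observed phenophase shifts for one crop/site: each phenophase
#' (e.g., seedling emergence, silking, maturity) has a baseline duration in
#' days and a signed shift in days (negative = advance, positive = delay).
#' The derived column `delta_p` is the shift magnitude as a percentage of
#' the phenophase's baseline duration, the quantity summed in the phenology
#' shift index: both advances and delays count as shift, so `delta_p` uses
#' the absolute shift.
#'
#' @param phenophase Character labels, one per phenophase.
#' @param baseline_duration Baseline phenophase durations, days (> 0).
#' @param shift Signed shifts, days.
#' @return A `data.frame` of class `phenology_shift_set` with columns
#'   `phenophase`, `baseline_duration`, `shift`, `delta_p`.
#' @examples
#' ps <- phenology_shift_set(c("emergence", "silking"), c(10, 20), c(3.2, -3.4))
#' sum_delta_p(ps)  # 49
#' @export
phenology_shift_set <- function(phenophase, baseline_duration, shift) {
  df <- data.frame(phenophase = as.character(phenophase),
                   baseline_duration = as.numeric(baseline_duration),
                   shift = as.numeric(shift))
  if (nrow(df) == 0L) stop("phenology shift set must be non-empty", call. = FALSE)
  bad <- which(!is.finite(df$baseline_duration) | df$baseline_duration <= 0)
  if (length(bad))
    stop(sprintf("invalid phenology record: row %d: baseline_duration must be > 0",
                 bad[1L]), call. = FALSE)
  bad <- which(!is.finite(df$shift))
  if (length(bad))
    stop(sprintf("invalid phenology record: row %d: non-numeric shift", bad[1L]),
         call. = FALSE)
  df$delta_p <- 100 * abs(df$shift) / df$baseline_duration
  structure(df, class = c("phenology_shift_set", "data.frame"))
}

#' @rdname phenology_shift_set
#' @param x A `phenology_shift_set`.
#' @export
n_phenophases <- function(x) {
  stopifnot(inherits(x, "phenology_shift_set"))
  nrow(x)
}

#' @rdname phenology_shift_set
#' @export
sum_delta_p <- function(x) {
  stopifnot(inherits(x, "phenology_shift_set"))
  sum(x$delta_p)
}

#' @export
print.phenology_shift_set <- function(x, ...) {
  cat(sprintf("<phenology_shift_set> Np = %d, sum(delta_p) = %.4g%%\n",
              nrow(x), sum(x$delta_p)))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' Read / write a phenophase shift CSV
#'
#' Columns: `phenophase,baseline_duration_days,shift_days`. The percentage
#' shift `delta_p` is derived on read, never stored.
#'
#' @param path File path.
#' @return `read_phenology_csv` returns a [phenology_shift_set()].
#' @export
read_phenology_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("phenophase", "baseline_duration_days", "shift_days")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("phenology CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) stop("phenology CSV is empty", call. = FALSE)
  phenology_shift_set(raw$phenophase, raw$baseline_duration_days, raw$shift_days)
}

#' @rdname read_phenology_csv
#' @param ps A [phenology_shift_set()].
#' @export
write_phenology_csv <- function(ps, path) {
  stopifnot(inherits(ps, "phenology_shift_set"))
  out <- data.frame(phenophase = ps$phenophase,
                    baseline_duration_days = num17(ps$baseline_duration),
                    shift_days = num17(ps$shift))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
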