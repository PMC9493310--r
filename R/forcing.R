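#' Phenology shift index
#'
#' Aggregate shift of a set of phenophases:
#' `P_Si = sum(delta_p) / (100 * Np)`, where `delta_p` are the per-phenophase
#' shift magnitudes in percent of baseline duration and `Np` is the number of
#' phenophases. `P_Si` is 0 iff no phenophase shifted and equals 1 when the
#' average phenophase shifted by its full duration.
#'
#' @param shifts A [phenology_shift_set()].
#' @return Dimensionless `p_si >= 0`.
#' @examples
#' ps <- phenology_shift_set(c("emergence", "silking"), c(10, 20), c(3.2, -3.4))
#' phenology_shift_index(ps)  # 49 / 200 = 0.245
#' @export
phenology_shift_index <- function(shifts) {
  stopifnot(inherits(shifts, "phenology_shift_set"))
  sum_delta_p(shifts) / (100 * n_phenophases(shifts))
}

#' Phenology sensitivity
#'
#' Shift per unit of climate extremity: `S_CEI = P_Si / CEI`. Defined for
#' any positive CEI (combined or a single subclass); a zero CEI leaves the
#' sensitivity undefined and is an error, never a silent division by zero.
#'
#' @param p_si Phenology shift index (see [phenology_shift_index()]).
#' @param cei Climate extreme index, percent; must be > 0.
#' @return Dimensionless `s_cei`; 0 iff `p_si` is 0.
#' @export
phenology_sensitivity <- function(p_si, cei) {
  stopifnot(is.numeric(p_si), is.numeric(cei), p_si >= 0)
  if (cei <= 0)
    stop("phenology sensitivity is undefined for CEI <= 0", call. = FALSE)
  p_si / cei
}

#' Phenology forcing index
#'
#' The tendency of an extreme-climate state to force a phenophase shift:
#' `F^p = CEI / S_CEI`, equivalently `F^p = CEI^2 * Np * 100 / sum(delta_p)`.
#' Both algebraic forms are evaluated and asserted equal to 1e-9 relative;
#' the ratio form is returned. Forcing below the minimum impact limit (MIL,
#' default CEI >= 1.0, inclusive) is treated as negligible and reported as
#' 0. A shift set with zero total shift under a CEI at or above the MIL
#' leaves the forcing undefined (infinite); the result is flagged rather
#' than raised, so batch runs survive degenerate rows.
#'
#' @param cei Climate extreme index, percent; must be >= 0.
#' @param shifts A [phenology_shift_set()].
#' @param mil Minimum impact limit in CEI units (default 1.0, inclusive).
#' @return An object of class `forcing_result`: list with `p_si`, `s_cei`,
#'   `f_p`, `cei`, `mil`, `mil_passed`, `undefined`, `n_p`, `sum_delta_p`.
#'   Below the MIL, `f_p = 0`, `mil_passed = FALSE` and `s_cei` is `NA`
#'   when CEI is 0.
#' @examples
#' ps <- phenology_shift_set(paste0("p", 1:4), rep(30, 4), rep(15, 4))  # sum delta_p = 200
#' phenology_forcing(2, ps)   # f_p = 8
#' phenology_forcing(0.5, ps) # suppressed below the MIL
#' @export
phenology_forcing <- function(cei, shifts, mil = 1.0) {
  stopifnot(inherits(shifts, "phenology_shift_set"), is.numeric(cei),
            length(cei) == 1L, is.numeric(mil), mil >= 0)
  if (!is.finite(cei) || cei < 0)
    stop("CEI must be a finite non-negative number", call. = FALSE)
  np <- n_phenophases(shifts)
  sdp <- sum_delta_p(shifts)
  p_si <- phenology_shift_index(shifts)
  s_cei <- if (cei > 0) p_si / cei else NA_real_

  res <- list(p_si = p_si, s_cei = s_cei, f_p = 0, cei = cei, mil = mil,
              mil_passed = FALSE, undefined = FALSE, n_p = np,
              sum_delta_p = sdp)
  if (cei < mil) return(structure(res, class = "forcing_result"))
  res$mil_passed <- TRUE
  if (sdp <= 0) {
    res$f_p <- Inf
    res$undefined <- TRUE
    return(structure(res, class = "forcing_result"))
  }
  f_ratio <- cei / s_cei
  f_expanded <- cei^2 * np * 100 / sdp
  if (abs(f_ratio - f_expanded) > 1e-9 * max(abs(f_ratio), abs(f_expanded)))
    stop("internal error: the two forcing forms disagree", call. = FALSE)
  res$f_p <- f_ratio
  structure(res, class = "forcing_result")
}

#' @export
print.forcing_result <- function(x, ...) {
  cat(sprintf("<forcing_result> CEI = %.4g (MIL %.4g, %s)\n", x$cei, x$mil,
              if (x$mil_passed) "passed" else "suppressed"))
  cat(sprintf("  P_Si = %.6g, S_CEI = %.6g, F^p = %.6g%s\n", x$p_si, x$s_cei,
              x$f_p, if (x$undefined) " [undefined: zero total shift]" else ""))
  invisible(x)
}

#' Serialize a forcing result to JSON
#'
#' Keys: `p_si, s_cei, f_p, cei, mil, mil_passed, n_p, sum_delta_p`
#' (plus `undefined`). An infinite forcing is serialized as the string
#' `"Inf"`.
#'
#' @param x A `forcing_result`.
#' @param path Optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
forcing_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "forcing_result"))
  obj <- x[c("p_si", "s_cei", "f_p", "cei", "mil", "mil_passed",
             "undefined", "n_p", "sum_delta_p")]
  if (!is.finite(obj$f_p)) obj$f_p <- "Inf"
  if (!is.finite(obj$s_cei)) obj$s_cei <- NA
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Phenophase shift density over time
#'
#' PSD is the fraction of a plant population whose phenophase has shifted at
#' each observation time. With absorbing shifts (default) an individual once
#' shifted stays shifted within the season, so the curve is nondecreasing;
#' the non-absorbing mode keeps the raw per-time fractions, allowing curves
#' that plateau and fall.
#'
#' @param shifted Logical matrix, one row per time point, one column per
#'   individual: `TRUE` where the individual's phenophase is shifted.
#' @param times Numeric time points (months), strictly increasing; default
#'   `1:nrow(shifted)`.
#' @param subclass Optional [subclass_ids()] label for reporting.
#' @param phenophase Optional phenophase label for reporting.
#' @param absorbing Treat shifts as absorbing (default `TRUE`).
#' @return A `data.frame` of class `psd_series` with columns `time_month`
#'   and `psd` (fractions in \[0, 1\]).
#' @export
psd_timeseries <- function(shifted, times = seq_len(nrow(shifted)),
                           subclass = NULL, phenophase = NULL,
                           absorbing = TRUE) {
  if (!is.matrix(shifted) || !is.logical(shifted))
    stop("'shifted' must be a logical matrix (times x individuals)",
         call. = FALSE)
  if (ncol(shifted) == 0L) stop("empty population", call. = FALSE)
  if (nrow(shifted) == 0L) stop("empty time grid", call. = FALSE)
  if (length(times) != nrow(shifted) || is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing with one value per row",
         call. = FALSE)
  if (absorbing && nrow(shifted) > 1L)
    shifted <- apply(shifted, 2L, function(col) cummax(col) > 0)
  structure(data.frame(time_month = times, psd = rowMeans(shifted)),
            subclass = subclass, phenophase = phenophase,
            absorbing = absorbing,
            class = c("psd_series", "data.frame"))
}
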