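# Canonical units: activity MBq, time hours, dose Gy, body mass kg,
# organ/lesion mass g. S values carry an explicit unit tag; the only
# conversion needed is mGy/(MBq.s) <-> Gy/(MBq.h), an exact factor of 3.6.

#' Physical half-life of 131I
#'
#' 8.0252 days expressed in hours, used for decay correction of phantom
#' and stock activities.
#'
#' @format A length-one numeric (hours).
#' @export
I131_HALF_LIFE_H <- 8.0252 * 24

S_UNIT_TAGS <- c("Gy/(MBq.h)", "mGy/(MBq.s)")

#' Decay-correct an activity
#'
#' @param activity_MBq activity at the reference time (MBq).
#' @param dt_h elapsed time in hours; positive values decay the activity
#'   forward in time, negative values correct back to an earlier time.
#' @param half_life_h physical half-life in hours (default 131I).
#' @return activity after `dt_h` hours (MBq).
#' @examples
#' decay_correct(100, I131_HALF_LIFE_H)  # one half-life -> 50 MBq
#' @export
decay_correct <- function(activity_MBq, dt_h, half_life_h = I131_HALF_LIFE_H) {
  stopifnot(half_life_h > 0)
  activity_MBq * 2^(-dt_h / half_life_h)
}

#' Construct an S value
#'
#' An S value is the mean absorbed dose rate to a target region per unit
#' activity in a source region (here always region self-dose). The object
#' carries the numeric value, a unit tag, the provenance of the value and
#' the region mass it was evaluated for.
#'
#' @param value positive S value.
#' @param units `"Gy/(MBq.h)"` or `"mGy/(MBq.s)"`.
#' @param source one of `"wb_power_law"`, `"sphere_power_law"`,
#'   `"user_table"`.
#' @param mass region mass the value corresponds to (kg for whole body,
#'   g for organs/lesions); `NA` if unknown.
#' @param sigma optional standard uncertainty of the value (same units).
#' @return an object of class `s_value`.
#' @export
s_value <- function(value, units = c("Gy/(MBq.h)", "mGy/(MBq.s)"),
                    source = "user_table", mass = NA_real_, sigma = 0) {
  units <- match.arg(units)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop("S value must be a single positive finite number")
  }
  if (sigma < 0) stop("sigma must be non-negative")
  structure(
    list(value = value, units = units, source = source, mass = mass,
         sigma = sigma),
    class = "s_value"
  )
}

#' @export
print.s_value <- function(x, ...) {
  cat(sprintf("S value: %.4g %s", x$value, x$units))
  if (x$sigma > 0) cat(sprintf(" (sigma %.2g)", x$sigma))
  if (!is.na(x$mass)) cat(sprintf(" at mass %.4g", x$mass))
  cat(sprintf(" [%s]\n", x$source))
  invisible(x)
}

#' Convert an S value between unit systems
#'
#' The conversion between `mGy/(MBq.s)` and `Gy/(MBq.h)` is exact:
#' 1 mGy/(MBq.s) = 3.6 Gy/(MBq.h).
#'
#' @param s an [s_value].
#' @param target_units target unit tag.
#' @return an [s_value] in the target units.
#' @examples
#' convert_s_units(s_value(7.8e-4, "mGy/(MBq.s)"), "Gy/(MBq.h)")
#' @export
convert_s_units <- function(s, target_units = c("Gy/(MBq.h)", "mGy/(MBq.s)")) {
  if (!inherits(s, "s_value")) stop("s must be an s_value object")
  target_units <- match.arg(target_units)
  if (!s$units %in% S_UNIT_TAGS) stop("unknown unit tag: ", s$units)
  if (identical(s$units, target_units)) return(s)
  # mGy/s -> Gy/h: 1e-3 Gy per mGy, 3600 s per h
  factor <- if (s$units == "mGy/(MBq.s)") 3.6 else 1 / 3.6
  s_value(s$value * factor, target_units, source = s$source, mass = s$mass,
          sigma = s$sigma * factor)
}

# internal: coerce any s_value (or bare number assumed Gy/(MBq.h)) to Gy/(MBq.h)
as_s_gy_per_mbq_h <- function(s) {
  if (inherits(s, "s_value")) {
    convert_s_units(s, "Gy/(MBq.h)")
  } else {
    stop("S value must carry a unit tag; use s_value()")
  }
}
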