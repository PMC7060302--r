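# MIRD absorbed-dose calculation, mass-scaled S-value models, fractionated
# activity planning and first-order uncertainty propagation.

#' Mass power-law S-value model
#'
#' Represents a self-dose S value scaling with region mass as
#' `S(m) = a * m^b` with `b < 0` (S decreases with mass).
#'
#' @param a positive coefficient.
#' @param b exponent (typically negative).
#' @param units unit tag of the evaluated S value.
#' @param mass_unit `"kg"` or `"g"`.
#' @param source provenance tag.
#' @return an object of class `power_law_s`.
#' @export
power_law_s <- function(a, b, units = c("Gy/(MBq.h)", "mGy/(MBq.s)"),
                        mass_unit = c("kg", "g"), source = "user_table") {
  units <- match.arg(units)
  mass_unit <- match.arg(mass_unit)
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b), length(b) == 1L, is.finite(b))
  structure(list(a = a, b = b, units = units, mass_unit = mass_unit,
                 source = source),
            class = "power_law_s")
}

#' @export
print.power_law_s <- function(x, ...) {
  cat(sprintf("S(m) = %.4g * m^%.4g %s (m in %s) [%s]\n",
              x$a, x$b, x$units, x$mass_unit, x$source))
  invisible(x)
}

#' Evaluate a power-law S model at a mass
#'
#' @param object a [power_law_s] model.
#' @param mass region mass in the model's mass unit; must be positive.
#' @param ... unused.
#' @return an [s_value] at that mass.
#' @export
predict.power_law_s <- function(object, mass, ...) {
  if (!is.numeric(mass) || any(mass <= 0)) stop("mass must be positive")
  value <- object$a * mass^object$b
  if (length(mass) == 1L) {
    s_value(value, object$units, source = object$source, mass = mass)
  } else {
    value
  }
}

#' Whole-body self-dose S value from patient mass
#'
#' Empirical whole-body self-dose power law for 131I,
#' `S = 1.34e-4 * m^-0.921` Gy/(MBq.h) with the patient mass `m` in kg,
#' obtained by interpolating newborn, 1-year, 5-year and adult phantom
#' S values. Valid over roughly the newborn-to-adult range; masses outside
#' 1--150 kg trigger an extrapolation warning.
#'
#' @param mass_kg patient mass in kg.
#' @return an [s_value] in Gy/(MBq.h) with source `"wb_power_law"`.
#' @examples
#' s_wb_from_mass(17.5)  # 9.60e-6 Gy/(MBq.h)
#' @export
s_wb_from_mass <- function(mass_kg) {
  if (!is.numeric(mass_kg) || length(mass_kg) != 1L || mass_kg <= 0) {
    stop("mass_kg must be a single positive number")
  }
  if (mass_kg < 1 || mass_kg > 150) {
    warning("mass outside the 1-150 kg phantom interpolation range")
  }
  law <- wb_s_power_law()
  s <- predict(law, mass_kg)
  s$source <- "wb_power_law"
  s
}

#' Whole-body S-value power law for 131I
#'
#' @return the [power_law_s] underlying [s_wb_from_mass()].
#' @export
wb_s_power_law <- function() {
  power_law_s(1.34e-4, -0.921, "Gy/(MBq.h)", "kg", source = "wb_power_law")
}

#' Fit a mass power law to (mass, S) data
#'
#' Ordinary least squares on the log-log scale, the standard way S values
#' for unit-density spheres and phantom organs are condensed into a
#' mass-scaling law usable at arbitrary lesion/organ masses.
#'
#' @param masses region masses (all positive, distinct; same mass unit).
#' @param s_values S values at those masses (all positive).
#' @param units unit tag of `s_values`.
#' @param mass_unit mass unit of `masses`.
#' @return a [power_law_s] with source `"sphere_power_law"`; the fit's
#'   log-scale residual standard error and coefficient covariance are
#'   attached as attributes `sigma_log` and `cov_log`.
#' @export
fit_s_power_law <- function(masses, s_values,
                            units = c("mGy/(MBq.s)", "Gy/(MBq.h)"),
                            mass_unit = c("g", "kg")) {
  units <- match.arg(units)
  mass_unit <- match.arg(mass_unit)
  if (length(masses) < 3L) stop("at least 3 (mass, S) points required")
  if (length(masses) != length(s_values)) stop("length mismatch")
  if (any(masses <= 0) || any(s_values <= 0)) {
    stop("masses and S values must be positive")
  }
  if (anyDuplicated(masses)) stop("masses must be distinct")
  fit <- lm(log(s_values) ~ log(masses))
  cf <- coef(fit)
  out <- power_law_s(exp(cf[[1L]]), cf[[2L]], units, mass_unit,
                     source = "sphere_power_law")
  # suppress the perfect-fit chatter on exact data
  attr(out, "sigma_log") <- suppressWarnings(summary(fit)$sigma)
  attr(out, "cov_log") <- suppressWarnings(vcov(fit))
  out
}

#' MIRD mean absorbed dose
#'
#' `D = A_tilde * S`: the mean absorbed dose over a dose-integration period
#' is the time-integrated activity in the region multiplied by the region
#' self-dose S value. Units are normalised internally (result in Gy when
#' the time-integrated activity is in MBq.h).
#'
#' @param tia_MBq_h time-integrated activity in MBq.h (non-negative).
#' @param s an [s_value].
#' @param sigma_tia_MBq_h optional standard uncertainty of the
#'   time-integrated activity.
#' @return a list with `dose_Gy`, `sigma_Gy` (first-order, uncorrelated)
#'   and the normalised S used.
#' @examples
#' absorbed_dose(164500, s_wb_from_mass(17.5))$dose_Gy  # 1.58 Gy
#' @export
absorbed_dose <- function(tia_MBq_h, s, sigma_tia_MBq_h = 0) {
  if (!is.numeric(tia_MBq_h) || tia_MBq_h < 0) {
    stop("time-integrated activity must be non-negative")
  }
  s_h <- as_s_gy_per_mbq_h(s)
  dose <- tia_MBq_h * s_h$value
  sigma <- propagate_product_uncertainty(tia_MBq_h, sigma_tia_MBq_h,
                                         s_h$value, s_h$sigma)
  list(dose_Gy = dose, sigma_Gy = sigma, s = s_h)
}

#' Dose per unit administered activity
#'
#' @param dose_Gy absorbed dose (Gy).
#' @param activity_MBq administered activity (MBq), positive.
#' @return Gy/GBq.
#' @examples
#' dose_per_unit_activity(1.58, 6893)  # 0.23 Gy/GBq
#' @export
dose_per_unit_activity <- function(dose_Gy, activity_MBq) {
  if (activity_MBq <= 0) stop("activity must be positive")
  1000 * dose_Gy / activity_MBq
}

#' Plan remaining treatment fractions from the first fraction's dose
#'
#' For a fractionated schedule targeting a total whole-body absorbed dose,
#' the activity for each remaining administration is
#' `A_i = (A1 / D1) * (D_target - D1) / (N - 1)`,
#' i.e. the dose still to deliver, shared equally over the remaining
#' `N - 1` fractions, converted to activity with the dose-per-activity
#' observed in fraction 1 (assumed to hold for later fractions).
#'
#' @param A1_MBq administered activity of the first fraction.
#' @param D1_Gy measured whole-body absorbed dose of the first fraction;
#'   must be positive and below the target.
#' @param target_Gy total whole-body dose target.
#' @param N planned total number of administrations (>= 2).
#' @return activity per remaining fraction in MBq.
#' @examples
#' plan_next_fractions(6893, 1.58, 4, 2)  # ~10,560 MBq
#' @export
plan_next_fractions <- function(A1_MBq, D1_Gy, target_Gy, N) {
  if (N < 2) stop("N must be at least 2")
  if (A1_MBq <= 0) stop("A1 must be positive")
  if (D1_Gy <= 0) stop("D1 must be positive")
  if (D1_Gy >= target_Gy) stop("target dose already met by fraction 1")
  (A1_MBq / D1_Gy) * (target_Gy - D1_Gy) / (N - 1)
}

#' Red-marrow dose surrogate from whole-body dose
#'
#' The whole-body absorbed dose divided by the empirical whole-body to
#' red-marrow dose ratio (mean 1.6 in children treated for neuroblastoma
#' and adults with neuroendocrine tumours).
#'
#' @param D_wb_Gy whole-body absorbed dose (Gy).
#' @param ratio whole-body/red-marrow dose ratio (> 0; default 1.6).
#' @return estimated red-marrow dose (Gy).
#' @export
estimate_red_marrow_dose <- function(D_wb_Gy, ratio = 1.6) {
  if (ratio <= 0) stop("ratio must be positive")
  D_wb_Gy / ratio
}

#' Weight-based first-fraction activity
#'
#' @param mass_kg patient mass (kg).
#' @param MBq_per_kg activity prescription per kg (e.g. 444 MBq/kg without
#'   stem-cell rescue, 666 MBq/kg with stored stem cells).
#' @return activity in MBq.
#' @export
weight_based_first_activity <- function(mass_kg, MBq_per_kg = 444) {
  if (mass_kg <= 0 || MBq_per_kg <= 0) stop("inputs must be positive")
  mass_kg * MBq_per_kg
}

#' First-order uncertainty of a product
#'
#' Standard uncertainty of `x * y` by first-order propagation:
#' `sigma^2 = (y sx)^2 + (x sy)^2 + 2 corr x y sx sy`.
#'
#' @param x,y values.
#' @param sx,sy standard uncertainties (non-negative).
#' @param corr correlation coefficient in `[-1, 1]` (default 0).
#' @return standard uncertainty of the product.
#' @export
propagate_product_uncertainty <- function(x, sx, y, sy, corr = 0) {
  if (sx < 0 || sy < 0) stop("uncertainties must be non-negative")
  if (corr < -1 || corr > 1) stop("corr must be in [-1, 1]")
  v <- (y * sx)^2 + (x * sy)^2 + 2 * corr * x * y * sx * sy
  sqrt(max(v, 0))
}

#' S-value uncertainty from mass uncertainty
#'
#' First-order propagation of a mass uncertainty through a power-law S
#' model: `sigma_S = |b| * (sigma_m / m) * S(m)`.
#'
#' @param power_law a [power_law_s].
#' @param mass region mass (model's mass unit).
#' @param sigma_mass standard uncertainty of the mass.
#' @return standard uncertainty of S (model's units).
#' @export
s_uncertainty_from_mass <- function(power_law, mass, sigma_mass) {
  if (mass <= 0) stop("mass must be positive")
  if (sigma_mass < 0) stop("sigma_mass must be non-negative")
  s <- power_law$a * mass^power_law$b
  abs(power_law$b) * (sigma_mass / mass) * s
}
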