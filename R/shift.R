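## Upshifting a fitted gamma drinking distribution so that population
## exposure matches adult per-capita consumption. Only the gamma family is
## shifted: its fitted mean equals the empirical mean, and its parameters
## are elementary functions of (mean, sd), so a distribution with a
## prescribed mean and regression-predicted sd is immediate. There is no
## comparably simple recipe for the Weibull or log-normal.

## SD-regression coefficients recovered by least squares (through the
## origin) from the 40-stratum published US reference table shipped in
## inst/extdata; see sd_regression() and the methods vignette. sd in
## grams/day = slope * shifted mean + sex_coef * sex (men 0, women 1).
.sd_coef_defaults <- c(slope = 1.1740004567, sex = 1.0032064331)

#' Default shifted-SD regression coefficients
#'
#' @return Named numeric vector with elements `slope` (dimensionless) and
#'   `sex` (grams/day added for women).
#' @seealso [sd_regression()] for how they are recovered.
#' @export
default_sd_coefs <- function() .sd_coef_defaults

#' Convert adult per-capita consumption to grams of ethanol per day
#'
#' @param liters liters of pure alcohol per adult per year (>= 0).
#' @param density grams of ethanol per liter (default 789.24 g/L at 20 C).
#' @param days_per_year days (default 365).
#' @return Grams of ethanol per adult per day.
#' @examples
#' percapita_gpd(8.75)  # ~18.92 g/day
#' @export
percapita_gpd <- function(liters, density = 789.24, days_per_year = 365) {
  if (any(!is.finite(liters)) || any(liters < 0)) {
    stop("per-capita liters must be non-negative", call. = FALSE)
  }
  stopifnot(density > 0, days_per_year > 0)
  liters * density / days_per_year
}

#' Survey coverage rate against per-capita consumption
#'
#' Coverage is the survey-derived total volume of exposure divided by adult
#' per-capita consumption, computed over the whole adult sample: abstainers
#' and former drinkers contribute zero grams/day.
#'
#' @param gpd grams/day for every adult respondent (zeros included), or a
#'   survey data frame with a `grams_per_day` column (see [read_survey()]).
#' @param percapita adult per-capita consumption in grams/day (> 0), e.g.
#'   from [percapita_gpd()].
#' @param weights optional survey weights (taken from the data frame's
#'   `weight` column when present).
#' @return The coverage fraction (0.529 means the survey captures 52.9% of
#'   per-capita consumption).
#' @export
coverage_rate <- function(gpd, percapita, weights = NULL) {
  if (is.data.frame(gpd)) {
    if (is.null(weights) && "weight" %in% names(gpd)) weights <- gpd$weight
    gpd <- gpd$grams_per_day
  }
  gpd <- as.numeric(gpd)
  gpd[is.na(gpd)] <- 0           # missing volume = no reported consumption
  if (!is.finite(percapita) || percapita <= 0) {
    stop("per-capita consumption must be positive", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(gpd))
  .wmean(gpd, weights) / percapita
}

#' Configuration of the upshifting step
#'
#' @param coverage survey coverage fraction in (0, ~1.5]; the single constant
#'   applied to every stratum (constant-undercoverage assumption).
#' @param target_fraction fraction of per-capita consumption to shift to:
#'   1 (default), with 0.9 and 0.8 as the conventional sensitivity levels.
#' @param sd_slope,sd_sex_coef coefficients of the shifted-SD regression
#'   `sd = sd_slope * mean + sd_sex_coef * sex`, sex coded 0 for men and 1
#'   for women. Defaults from [default_sd_coefs()].
#' @return A list of class `"shift_config"`.
#' @export
shift_config <- function(coverage, target_fraction = 1,
                         sd_slope = .sd_coef_defaults[["slope"]],
                         sd_sex_coef = .sd_coef_defaults[["sex"]]) {
  if (!is.finite(coverage) || coverage <= 0) {
    stop("coverage must be positive", call. = FALSE)
  }
  if (!is.finite(target_fraction) || target_fraction <= 0 ||
      target_fraction > 1) {
    stop("target_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(coverage = coverage, target_fraction = target_fraction,
                 sd_slope = sd_slope, sd_sex_coef = sd_sex_coef),
            class = "shift_config")
}

#' @export
print.shift_config <- function(x, ...) {
  cat(sprintf(paste0("shift config: coverage %.4f, target fraction %.2f, ",
                     "sd = %.4f*mean + %.4f*sex\n"),
              x$coverage, x$target_fraction, x$sd_slope, x$sd_sex_coef))
  invisible(x)
}

#' Shifted mean of a drinker stratum
#'
#' The same multiplicative constant `target_fraction / coverage` is applied
#' to every stratum's drinker mean.
#'
#' @param mean stratum drinker mean in grams/day (> 0).
#' @param config a [shift_config()].
#' @return Shifted mean in grams/day.
#' @export
shift_mean <- function(mean, config) {
  stopifnot(inherits(config, "shift_config"))
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    stop("stratum mean must be positive", call. = FALSE)
  }
  mean * config$target_fraction / config$coverage
}

#' Predict the standard deviation of a shifted distribution
#'
#' @param mean_shifted shifted mean in grams/day.
#' @param sex 0 for men, 1 for women.
#' @param config a [shift_config()].
#' @return Predicted standard deviation in grams/day (strictly positive, or
#'   an error).
#' @export
predict_shifted_sd <- function(mean_shifted, sex, config) {
  stopifnot(inherits(config, "shift_config"))
  if (!all(sex %in% c(0, 1))) stop("sex must be coded 0 (men) or 1 (women)",
                                   call. = FALSE)
  if (any(!is.finite(mean_shifted)) || any(mean_shifted <= 0)) {
    stop("shifted mean must be positive", call. = FALSE)
  }
  sd <- config$sd_slope * mean_shifted + config$sd_sex_coef * sex
  if (any(sd <= 0)) stop("predicted sd is non-positive; check coefficients",
                         call. = FALSE)
  sd
}

#' Upshift a fitted gamma distribution to the per-capita level
#'
#' Divides the fitted drinker mean by the coverage rate (times the target
#' fraction), predicts the shifted standard deviation from the shifted mean
#' and sex, and converts back to gamma shape/scale via the moment relations
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`.
#'
#' @param fit a gamma `"drinkfit"` or `"drinkdist"` (other families are an
#'   error: they cannot be shifted this way).
#' @param sex 0 for men, 1 for women.
#' @param config a [shift_config()].
#' @return An object of class `"stratum_shift"`: list with `original` and
#'   `shifted` gamma `"drinkdist"`s and the original/shifted moments.
#' @examples
#' fit <- gamma_from_moments(21.0, 30.9)
#' shift_distribution(fit, sex = 0, shift_config(coverage = 0.529))
#' @export
shift_distribution <- function(fit, sex, config) {
  stopifnot(inherits(config, "shift_config"))
  if (!inherits(fit, "drinkdist") || fit$family != "gamma") {
    stop("only the gamma family can be shifted: its mean matches the ",
         "empirical mean and its parameters follow from (mean, sd)",
         call. = FALSE)
  }
  m <- dist_moments(fit)
  m_sh <- shift_mean(m[["mean"]], config)
  sd_sh <- predict_shifted_sd(m_sh, sex, config)
  shifted <- gamma_from_moments(m_sh, sd_sh)
  structure(list(
    sex = sex,
    original = consumption_dist("gamma", shape = fit$params[["shape"]],
                                scale = fit$params[["scale"]]),
    shifted = shifted,
    original_mean = m[["mean"]], original_sd = m[["sd"]],
    shifted_mean = m_sh, shifted_sd = sd_sh,
    config = config
  ), class = "stratum_shift")
}

#' @export
print.stratum_shift <- function(x, ...) {
  cat(sprintf("gamma upshift (%s, coverage %.4f, target %.2f)\n",
              if (x$sex == 0) "men" else "women",
              x$config$coverage, x$config$target_fraction))
  cat(sprintf("  original: shape %.3f, scale %.3f (mean %.3f, sd %.3f)\n",
              x$original$params[["shape"]], x$original$params[["scale"]],
              x$original_mean, x$original_sd))
  cat(sprintf("  shifted:  shape %.3f, scale %.3f (mean %.3f, sd %.3f)\n",
              x$shifted$params[["shape"]], x$shifted$params[["scale"]],
              x$shifted_mean, x$shifted_sd))
  invisible(x)
}

#' Published US reference table of original and upshifted gamma parameters
#'
#' Forty strata (sex x ethnicity x age, including all-ages rows) from the
#' published US 2001-2002 application of the triangulation method to the
#' NESARC survey: the original fitted gamma parameters and the upshifted
#' mean, standard deviation, shape and scale. Used to recover the shifted-SD
#' regression coefficients and to validate the moment relations.
#'
#' @return A data frame with columns `sex`, `ethnicity`, `age`, `k`, `theta`
#'   (original fit), `mean_shifted`, `sd_shifted`, `k_shifted`,
#'   `theta_shifted`.
#' @export
upshift_reference <- function() {
  path <- system.file("extdata", "us_shifted_gamma_reference.csv",
                      package = "upshift", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Recover the shifted-SD regression from a reference table
#'
#' Least squares of the shifted standard deviation on the shifted mean and a
#' sex indicator (men 0, women 1), through the origin: in the reference
#' table the male SD/mean ratio is one constant and the female excess
#' `sd - slope*mean` another, so no intercept is identified (adding one
#' yields an estimate indistinguishable from zero).
#'
#' @param ref a data frame shaped like [upshift_reference()].
#' @return List with `coefficients` (named `slope`, `sex`), `r_squared`,
#'   `max_rel_err` (largest relative deviation of a predicted SD from the
#'   table), and the underlying `"lm"` fit.
#' @export
sd_regression <- function(ref = upshift_reference()) {
  stopifnot(all(c("sex", "mean_shifted", "sd_shifted") %in% names(ref)))
  sexn <- ifelse(ref$sex %in% c("women", "female", "1"), 1, 0)
  fit <- lm(sd_shifted ~ 0 + mean_shifted + sexn,
            data = data.frame(sd_shifted = ref$sd_shifted,
                              mean_shifted = ref$mean_shifted, sexn = sexn))
  co <- setNames(coef(fit), c("slope", "sex"))
  pred <- fitted(fit)
  ss_tot <- sum((ref$sd_shifted - mean(ref$sd_shifted))^2)
  r2 <- 1 - sum((ref$sd_shifted - pred)^2) / ss_tot
  list(coefficients = co, r_squared = r2,
       max_rel_err = max(abs(pred - ref$sd_shifted) / ref$sd_shifted),
       fit = fit)
}
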