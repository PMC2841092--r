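## Nonparametric bootstrap of the full per-stratum estimation chain:
## resample respondents, recompute abstention proportions, refit the gamma,
## reapply the shift, recompute the AAF. The coverage constant and the
## SD-regression coefficients are held fixed across replicates: they come
## from external aggregate statistics (per-capita totals, the reference
## regression), not from the stratum sample.

#' Bootstrap confidence interval for a stratum AAF
#'
#' Resamples respondents with replacement within one stratum and recomputes
#' the whole chain (status proportions -> gamma MLE -> upshift -> continuous
#' AAF) per replicate. The standard error is the standard deviation of the
#' replicate AAFs; the confidence interval uses the percentile method.
#' Replicates whose resample cannot be fitted (fewer than two current
#' drinkers, or zero variance among drinker volumes) are dropped and
#' counted; more than 1% dropped is an error.
#'
#' Reproducibility: replicate `r` is driven by its own sub-seed drawn once
#' from `seed`, so results are bitwise identical for the same data and seed
#' regardless of run order.
#'
#' @param status character vector of drinking status per respondent:
#'   `"lifetime_abstainer"`, `"former"` or `"current"`.
#' @param gpd grams/day per respondent (positive for current drinkers,
#'   0 otherwise).
#' @param sex 0 for men, 1 for women (one stratum, one value).
#' @param risk a [risk_function()].
#' @param config a [shift_config()]; coverage and SD coefficients are fixed
#'   across replicates.
#' @param n_reps number of bootstrap replicates (the reference analysis used
#'   10,000).
#' @param seed integer seed (mandatory: every stochastic step is seeded).
#' @param cap,upper,step passed to [aaf_continuous()].
#' @param conf confidence level (default 0.95).
#' @return An object of class `"bootstrap_aaf"`: list with `point` (full-
#'   sample AAF), `se`, `ci_low`, `ci_high`, `n_reps`, `n_dropped`, `seed`,
#'   `replicates` (the replicate AAFs).
#' @export
bootstrap_aaf <- function(status, gpd, sex, risk, config,
                          n_reps = 10000, seed,
                          cap = NULL, upper = 300, step = 0.01,
                          conf = 0.95) {
  stopifnot(inherits(risk, "risk_function"), inherits(config, "shift_config"))
  if (missing(seed) || !is.finite(seed)) {
    stop("a seed is mandatory for the bootstrap", call. = FALSE)
  }
  status <- as.character(status)
  gpd <- as.numeric(gpd)
  n <- length(status)
  if (n < 30) stop("stratum has fewer than 30 respondents", call. = FALSE)
  if (length(gpd) != n) stop("status and gpd lengths differ", call. = FALSE)
  ok_status <- c("lifetime_abstainer", "former", "current")
  if (!all(status %in% ok_status)) {
    stop("unknown drinking status: ",
         paste(unique(setdiff(status, ok_status)), collapse = ", "),
         call. = FALSE)
  }

  # grid and RR values are constant across replicates: prepare them once
  top <- if (!is.null(cap)) cap else upper
  prep <- .prep_excess(risk, top, step)
  ctrl <- fit_control()
  mult <- config$target_fraction / config$coverage

  one_pass <- function(st, vol) {
    cur <- st == "current"
    drink <- vol[cur]
    if (sum(cur) < 2 || length(unique(drink)) < 2) return(NA_real_)
    p_form <- mean(st == "former")
    p_cur <- mean(cur)
    fit <- .fit_gamma(drink, rep(1, length(drink)), ctrl)
    m_sh <- fit$params[["shape"]] * fit$params[["scale"]] * mult
    sd_sh <- config$sd_slope * m_sh + config$sd_sex_coef * sex
    shifted <- gamma_from_moments(m_sh, sd_sh)
    excess <- .excess_from_prep(prep, shifted) +
      (1 - .fam_p(shifted, top)) * prep$g_top
    S <- p_form * (risk$rr_former - 1) + p_cur * excess
    S / (1 + S)
  }

  point <- one_pass(status, gpd)
  if (is.na(point)) {
    stop("stratum cannot be fitted (needs >= 2 distinct drinker volumes)",
         call. = FALSE)
  }

  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, n_reps)
  reps <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(sub_seeds[r])
    idx <- sample.int(n, n, replace = TRUE)
    reps[r] <- one_pass(status[idx], gpd[idx])
  }
  dropped <- sum(is.na(reps))
  if (dropped > 0.01 * n_reps) {
    stop(dropped, " of ", n_reps, " bootstrap replicates (>1%) were ",
         "degenerate resamples", call. = FALSE)
  }
  reps_ok <- reps[!is.na(reps)]
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(reps_ok, c(alpha, 1 - alpha), type = 7))
  structure(list(point = point, se = sd(reps_ok),
                 ci_low = ci[1], ci_high = ci[2],
                 n_reps = n_reps, n_dropped = dropped,
                 seed = as.integer(seed), conf = conf,
                 replicates = reps),
            class = "bootstrap_aaf")
}

#' @export
print.bootstrap_aaf <- function(x, ...) {
  cat(sprintf("bootstrap AAF: %.4f, se %.4f, %g%% CI [%.4f, %.4f]\n",
              x$point, x$se, 100 * x$conf, x$ci_low, x$ci_high))
  cat(sprintf("  %d replicates (%d dropped), seed %d\n",
              x$n_reps, x$n_dropped, x$seed))
  invisible(x)
}
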