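## Parametric models for grams/day of ethanol among current drinkers.
## All three families have support (0, Inf); consumption of exactly zero
## belongs to the abstainer categories, not to these models.

.families <- c("gamma", "lognormal", "weibull")

.check_family <- function(family) {
  family <- match.arg(family, .families)
  family
}

.check_params <- function(family, params) {
  bad <- switch(family,
    gamma     = params[["shape"]] <= 0 || params[["scale"]] <= 0,
    lognormal = params[["sdlog"]] <= 0,
    weibull   = params[["shape"]] <= 0 || params[["scale"]] <= 0
  )
  if (!all(is.finite(params)) || isTRUE(bad)) {
    stop("invalid ", family, " parameters: ",
         paste(names(params), signif(params, 6), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  invisible(params)
}

#' Consumption distribution objects
#'
#' Construct a parametric model of daily ethanol intake (grams/day) among
#' current drinkers. Three right-skewed two-parameter families are supported,
#' each in its standard shape/scale (or meanlog/sdlog) parameterization:
#' `"gamma"` (`shape`, `scale`), `"lognormal"` (`meanlog`, `sdlog`) and
#' `"weibull"` (`shape`, `scale`).
#'
#' @param family one of `"gamma"`, `"lognormal"`, `"weibull"`.
#' @param shape,scale shape and scale parameters (gamma, Weibull). The scale
#'   is in grams/day.
#' @param meanlog,sdlog mean and standard deviation of log-consumption
#'   (log-normal).
#' @return An object of class `"drinkdist"`: a list with elements `family`
#'   and `params` (named numeric vector).
#' @seealso [fit_consumption()] to estimate a `drinkdist` from data,
#'   [gamma_from_moments()] for the moment parameterization used in shifting.
#' @examples
#' d <- consumption_dist("gamma", shape = 0.726, scale = 55.5)
#' dist_moments(d)
#' predict(d, c(10, 50), type = "cdf")
#' @export
consumption_dist <- function(family, shape = NULL, scale = NULL,
                             meanlog = NULL, sdlog = NULL) {
  family <- .check_family(family)
  params <- switch(family,
    gamma     = c(shape = shape, scale = scale),
    lognormal = c(meanlog = meanlog, sdlog = sdlog),
    weibull   = c(shape = shape, scale = scale)
  )
  if (length(params) != 2 || is.null(names(params))) {
    stop("family '", family, "' needs both of its parameters", call. = FALSE)
  }
  params <- vapply(params, as.numeric, numeric(1))
  .check_params(family, params)
  structure(list(family = family, params = params), class = "drinkdist")
}

#' Gamma distribution from mean and standard deviation
#'
#' The moment relations `shape = (mean/sd)^2`, `scale = sd^2/mean` are the
#' backbone of the upshifting procedure: the shifted distribution is defined
#' by its mean (tied to per-capita consumption) and a regression-predicted
#' standard deviation.
#'
#' @param mean,sd mean and standard deviation in grams/day; both > 0.
#' @return A gamma `"drinkdist"`.
#' @examples
#' gamma_from_moments(40.268, 47.275)  # shape ~0.726, scale ~55.5
#' @export
gamma_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || !is.finite(sd) || mean <= 0 || sd <= 0) {
    stop("mean and sd must be positive and finite", call. = FALSE)
  }
  consumption_dist("gamma", shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Analytic mean and standard deviation of a consumption distribution
#'
#' @param dist a `"drinkdist"` (or fitted `"drinkfit"`).
#' @return Named numeric vector `c(mean, sd)` in grams/day.
#' @export
dist_moments <- function(dist) {
  stopifnot(inherits(dist, "drinkdist"))
  p <- dist$params
  switch(dist$family,
    gamma = c(mean = p[["shape"]] * p[["scale"]],
              sd   = sqrt(p[["shape"]]) * p[["scale"]]),
    lognormal = {
      m <- exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2)
      c(mean = m, sd = m * sqrt(exp(p[["sdlog"]]^2) - 1))
    },
    weibull = {
      g1 <- gamma(1 + 1 / p[["shape"]])
      g2 <- gamma(1 + 2 / p[["shape"]])
      c(mean = p[["scale"]] * g1,
        sd   = p[["scale"]] * sqrt(g2 - g1^2))
    }
  )
}

## density / cdf / quantile / random dispatch onto stats
.fam_d <- function(dist, x, log = FALSE) {
  p <- dist$params
  switch(dist$family,
    gamma     = dgamma(x, shape = p[["shape"]], scale = p[["scale"]], log = log),
    lognormal = dlnorm(x, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]], log = log),
    weibull   = dweibull(x, shape = p[["shape"]], scale = p[["scale"]], log = log)
  )
}

.fam_p <- function(dist, q) {
  p <- dist$params
  switch(dist$family,
    gamma     = pgamma(q, shape = p[["shape"]], scale = p[["scale"]]),
    lognormal = plnorm(q, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    weibull   = pweibull(q, shape = p[["shape"]], scale = p[["scale"]])
  )
}

.fam_q <- function(dist, pr) {
  p <- dist$params
  switch(dist$family,
    gamma     = qgamma(pr, shape = p[["shape"]], scale = p[["scale"]]),
    lognormal = qlnorm(pr, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    weibull   = qweibull(pr, shape = p[["shape"]], scale = p[["scale"]])
  )
}

.fam_r <- function(dist, n) {
  p <- dist$params
  switch(dist$family,
    gamma     = rgamma(n, shape = p[["shape"]], scale = p[["scale"]]),
    lognormal = rlnorm(n, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    weibull   = rweibull(n, shape = p[["shape"]], scale = p[["scale"]])
  )
}

#' Evaluate a consumption distribution
#'
#' @param object a `"drinkdist"` or `"drinkfit"`.
#' @param newdata numeric vector: grams/day for `type = "density"` (must be
#'   > 0) or `type = "cdf"` (must be >= 0), probabilities for
#'   `type = "quantile"`.
#' @param type `"density"`, `"cdf"` or `"quantile"`.
#' @param ... unused.
#' @return Numeric vector of the same length as `newdata`.
#' @export
predict.drinkdist <- function(object, newdata,
                              type = c("density", "cdf", "quantile"), ...) {
  type <- match.arg(type)
  x <- as.numeric(newdata)
  if (anyNA(x)) stop("newdata contains missing values", call. = FALSE)
  switch(type,
    density = {
      if (any(x <= 0)) stop("density is defined for x > 0 only", call. = FALSE)
      .fam_d(object, x)
    },
    cdf = {
      if (any(x < 0)) stop("cdf is defined for x >= 0 only", call. = FALSE)
      .fam_p(object, x)
    },
    quantile = {
      if (any(x < 0 | x > 1)) stop("quantile needs probabilities in [0, 1]",
                                   call. = FALSE)
      .fam_q(object, x)
    }
  )
}

#' @export
print.drinkdist <- function(x, ...) {
  m <- dist_moments(x)
  cat(sprintf("%s consumption distribution (%s)\n", x$family,
              paste(names(x$params), signif(x$params, 5),
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  mean %.3f g/day, sd %.3f g/day\n", m[["mean"]], m[["sd"]]))
  invisible(x)
}

#' Simulate drinker consumption
#'
#' @param object a `"drinkdist"` or `"drinkfit"`.
#' @param nsim number of draws.
#' @param seed optional integer seed; when supplied the RNG state is restored
#'   afterwards.
#' @param ... unused.
#' @return Numeric vector of `nsim` grams/day values.
#' @export
simulate.drinkdist <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  .fam_r(object, nsim)
}

#' @export
mean.drinkdist <- function(x, ...) dist_moments(x)[["mean"]]

## ---- maximum likelihood fitting -------------------------------------------

#' Control parameters for maximum-likelihood fitting
#'
#' @param tol relative parameter-change convergence tolerance for the
#'   Newton-Raphson iterations.
#' @param maxit maximum Newton iterations before falling back to a bounded
#'   derivative-free search.
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(tol = 1e-8, maxit = 200) {
  stopifnot(tol > 0, maxit >= 1)
  structure(list(tol = tol, maxit = maxit), class = "fit_control")
}

.wmean <- function(x, w) sum(w * x) / sum(w)

## log-likelihood of a family given sufficient data (weighted)
.fam_loglik <- function(dist, x, w) sum(w * .fam_d(dist, x, log = TRUE))

## Newton-Raphson for the gamma shape on the profile likelihood.
## With scale profiled out (scale = xbar/k), the score in k reduces to
## log(k) - digamma(k) = log(xbar) - mean(log x) =: s, s > 0 by Jensen.
.fit_gamma <- function(x, w, control) {
  xbar <- .wmean(x, w)
  mlog <- .wmean(log(x), w)
  s <- log(xbar) - mlog
  if (s <= 0) stop("gamma fit did not converge: zero sample variance",
                   call. = FALSE)
  v <- .wmean((x - xbar)^2, w)
  k <- max(xbar^2 / v, 1e-8)          # method-of-moments start
  converged <- FALSE
  for (i in seq_len(control$maxit)) {
    g  <- log(k) - digamma(k) - s
    gp <- 1 / k - trigamma(k)         # < 0 for k > 0
    step <- g / gp
    k_new <- k - step
    while (k_new <= 0) { step <- step / 2; k_new <- k - step }
    if (abs(k_new - k) <= control$tol * max(k, 1)) {
      k <- k_new; converged <- TRUE; break
    }
    k <- k_new
  }
  if (!converged) {
    # bounded fallback on the profile log-likelihood
    prof <- function(kk) {
      th <- xbar / kk
      sum(w * dgamma(x, shape = kk, scale = th, log = TRUE))
    }
    opt <- optimize(prof, interval = c(1e-6, 1e4), maximum = TRUE,
                    tol = control$tol)
    k <- opt$maximum
  }
  consumption_dist("gamma", shape = k, scale = xbar / k)
}

## closed-form weighted MLE for the log-normal
.fit_lognormal <- function(x, w, control) {
  lx <- log(x)
  mu <- .wmean(lx, w)
  s2 <- .wmean((lx - mu)^2, w)
  if (s2 <= 0) stop("lognormal fit did not converge: zero sample variance",
                    call. = FALSE)
  consumption_dist("lognormal", meanlog = mu, sdlog = sqrt(s2))
}

## Newton-Raphson for the Weibull shape on the profile likelihood.
## With scale^shape profiled out, the score is
##   h(g) = 1/g + mean(log x) - sum(w x^g log x)/sum(w x^g), decreasing in g.
.fit_weibull <- function(x, w, control) {
  lx <- log(x)
  mlog <- .wmean(lx, w)
  if (.wmean((lx - mlog)^2, w) <= 0) {
    stop("weibull fit did not converge: zero sample variance", call. = FALSE)
  }
  sdl <- sqrt(.wmean((lx - mlog)^2, w))
  g <- 1.2 / sdl                       # standard starting value
  converged <- FALSE
  for (i in seq_len(control$maxit)) {
    xg  <- w * x^g
    A   <- sum(xg)
    B   <- sum(xg * lx)
    C   <- sum(xg * lx^2)
    h   <- 1 / g + mlog - B / A
    hp  <- -1 / g^2 - (C * A - B^2) / A^2
    step <- h / hp
    g_new <- g - step
    while (g_new <= 0) { step <- step / 2; g_new <- g - step }
    if (!is.finite(g_new)) break
    if (abs(g_new - g) <= control$tol * max(g, 1)) {
      g <- g_new; converged <- TRUE; break
    }
    g <- g_new
  }
  if (!converged) {
    prof <- function(gg) {
      th <- (sum(w * x^gg) / sum(w))^(1 / gg)
      sum(w * dweibull(x, shape = gg, scale = th, log = TRUE))
    }
    opt <- optimize(prof, interval = c(1e-3, 100), maximum = TRUE,
                    tol = control$tol)
    g <- opt$maximum
  }
  theta <- (sum(w * x^g) / sum(w))^(1 / g)
  consumption_dist("weibull", shape = g, scale = theta)
}

#' Method-of-moments parameter estimates
#'
#' Used as Newton-Raphson starting values and as a likelihood floor in tests:
#' the MLE must attain at least the moment-matched log-likelihood.
#'
#' @inheritParams fit_consumption
#' @return A `"drinkdist"`.
#' @export
fit_moments <- function(x, family, weights = NULL) {
  family <- .check_family(family)
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  m <- .wmean(x, w)
  v <- .wmean((x - m)^2, w)
  if (v <= 0) stop("zero sample variance", call. = FALSE)
  switch(family,
    gamma = consumption_dist("gamma", shape = m^2 / v, scale = v / m),
    lognormal = {
      s2 <- log(1 + v / m^2)
      consumption_dist("lognormal", meanlog = log(m) - s2 / 2,
                       sdlog = sqrt(s2))
    },
    weibull = {
      cv2 <- v / m^2
      f <- function(g) gamma(1 + 2 / g) / gamma(1 + 1 / g)^2 - 1 - cv2
      g <- uniroot(f, c(0.05, 50), tol = 1e-10)$root
      consumption_dist("weibull", shape = g, scale = m / gamma(1 + 1 / g))
    }
  )
}

#' Fit a consumption distribution by maximum likelihood
#'
#' Fits one of the three supported families to positive drinker volumes
#' (grams of ethanol per day). The log-normal MLE is closed form; gamma and
#' Weibull shapes are found by Newton-Raphson on the profile log-likelihood
#' (quadratic convergence from method-of-moments starting values), with a
#' bounded golden-section fallback if the iteration stalls. A fitted gamma
#' preserves the (weighted) sample mean exactly: `shape * scale = mean(x)`.
#'
#' @param x numeric vector of positive volumes (grams/day). Missing values
#'   are an error: callers drop them (with logging) before fitting, see
#'   [read_survey()].
#' @param family `"gamma"`, `"lognormal"` or `"weibull"`.
#' @param weights optional positive frequency-style weights (default all 1).
#' @param control a [fit_control()] list.
#' @return An object of classes `"drinkfit"` and `"drinkdist"` with elements
#'   `family`, `params`, `n_obs`, `loglik`, `mean`, `sd` and `data` (the
#'   fitted volumes, kept for plotting and goodness-of-fit).
#' @examples
#' set.seed(1)
#' x <- rgamma(2000, shape = 0.45, scale = 50)
#' fit <- fit_consumption(x, "gamma")
#' fit
#' coef(fit)
#' @export
fit_consumption <- function(x, family = c("gamma", "lognormal", "weibull"),
                            weights = NULL, control = fit_control()) {
  family <- match.arg(family)
  x <- as.numeric(x)
  if (anyNA(x)) stop("x contains missing values; drop them before fitting",
                     call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(x <= 0)) {
    stop("all volumes must be positive; zeros belong to abstainer ",
         "categories, not the drinker distribution", call. = FALSE)
  }
  if (is.null(weights)) {
    w <- rep(1, length(x))
  } else {
    w <- as.numeric(weights)
    if (length(w) != length(x) || any(!is.finite(w)) || any(w <= 0)) {
      stop("weights must be positive, finite and match x in length",
           call. = FALSE)
    }
  }
  if (max(x) == min(x)) {
    stop(family, " fit did not converge: all values identical (zero variance)",
         call. = FALSE)
  }
  dist <- switch(family,
    gamma     = .fit_gamma(x, w, control),
    lognormal = .fit_lognormal(x, w, control),
    weibull   = .fit_weibull(x, w, control)
  )
  ll <- .fam_loglik(dist, x, w)
  if (!is.finite(ll)) stop(family, " fit did not converge: non-finite ",
                           "log-likelihood", call. = FALSE)
  m <- dist_moments(dist)
  structure(
    list(family = family, params = dist$params, n_obs = length(x),
         loglik = ll, mean = m[["mean"]], sd = m[["sd"]],
         weights = if (is.null(weights)) NULL else w, data = x),
    class = c("drinkfit", "drinkdist")
  )
}

#' @export
coef.drinkfit <- function(object, ...) object$params

#' @export
logLik.drinkfit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n_obs, class = "logLik")
}

#' @export
print.drinkfit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood %s fit, n = %d\n", x$family, x$n_obs))
  cat(sprintf("  %s\n", paste(names(x$params), signif(x$params, 5),
                              sep = " = ", collapse = ", ")))
  cat(sprintf("  mean %.3f g/day, sd %.3f g/day, logLik %.2f\n",
              x$mean, x$sd, x$loglik))
  invisible(x)
}

#' @export
summary.drinkfit <- function(object, ...) {
  emp_mean <- if (is.null(object$weights)) mean(object$data)
              else .wmean(object$data, object$weights)
  out <- list(family = object$family, params = object$params,
              n_obs = object$n_obs, loglik = object$loglik,
              fitted_mean = object$mean, fitted_sd = object$sd,
              empirical_mean = emp_mean)
  class(out) <- "summary.drinkfit"
  out
}

#' @export
print.summary.drinkfit <- function(x, ...) {
  cat(sprintf("%s fit to %d drinker volumes\n", x$family, x$n_obs))
  cat(sprintf("  parameters: %s\n",
              paste(names(x$params), signif(x$params, 6),
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  fitted mean %.4f (empirical %.4f), fitted sd %.4f\n",
              x$fitted_mean, x$empirical_mean, x$fitted_sd))
  cat(sprintf("  log-likelihood %.3f\n", x$loglik))
  invisible(x)
}

#' Quantile residuals of a fitted consumption distribution
#'
#' @param object a `"drinkfit"`.
#' @param ... unused.
#' @return `qnorm(cdf(x))`: standard normal under a correct model.
#' @export
residuals.drinkfit <- function(object, ...) {
  qnorm(pmin(pmax(.fam_p(object, object$data), 1e-12), 1 - 1e-12))
}

#' Histogram of the data with the fitted density
#'
#' @param x a `"drinkfit"`.
#' @param breaks passed to [graphics::hist()].
#' @param xlim upper plotting limit in grams/day (default the 99.5th
#'   percentile of the data).
#' @param ... further arguments for `hist()`.
#' @export
plot.drinkfit <- function(x, breaks = 50, xlim = NULL, ...) {
  up <- if (is.null(xlim)) quantile(x$data, 0.995) else xlim[2]
  graphics::hist(x$data[x$data <= up], breaks = breaks, freq = FALSE,
                 xlab = "grams ethanol / day",
                 main = sprintf("%s fit (n = %d)", x$family, x$n_obs), ...)
  xs <- seq(min(x$data), up, length.out = 512)
  graphics::lines(xs, .fam_d(x, xs), lwd = 2)
  invisible(x)
}
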