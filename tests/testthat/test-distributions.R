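# Parametric consumption models: densities, CDFs, moments, MLE.

test_that("densities and CDFs match their analytic special cases", {
  # gamma with shape 1 is exponential
  d <- consumption_dist("gamma", shape = 1, scale = 10)
  expect_equal(predict(d, 1e-9, type = "density"), 0.1, tolerance = 1e-6)
  # standard log-normal at its median
  ln <- consumption_dist("lognormal", meanlog = 0, sdlog = 1)
  expect_equal(predict(ln, 1, type = "density"), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  # Weibull with shape 1 is exponential
  w <- consumption_dist("weibull", shape = 1, scale = 10)
  expect_equal(predict(w, 10, type = "cdf"), 1 - exp(-1), tolerance = 1e-12)
  # normalization limit
  g <- consumption_dist("gamma", shape = 0.5, scale = 2)
  expect_equal(predict(g, 1e6, type = "cdf"), 1)
})

test_that("all three densities integrate to 1 by the package's quadrature", {
  dists <- list(
    consumption_dist("gamma", shape = 0.436, scale = 48.132),
    consumption_dist("lognormal", meanlog = 2.0, sdlog = 1.2),
    consumption_dist("weibull", shape = 0.65, scale = 16),
    consumption_dist("gamma", shape = 2, scale = 20)
  )
  for (d in dists) {
    expect_equal(quad_cdf(d, 5000, n = 2e6), 1, tolerance = 1e-6)
  }
})

test_that("cdf agrees with trapezoidal integration of the density", {
  d <- consumption_dist("gamma", shape = 0.436, scale = 48.132)
  expect_equal(predict(d, 10, type = "cdf"), quad_cdf(d, 10),
               tolerance = 1e-6)
})

test_that("domain violations are errors", {
  d <- consumption_dist("gamma", shape = 1, scale = 10)
  expect_error(predict(d, -1, type = "density"), "x > 0")
  expect_error(predict(d, 0, type = "density"), "x > 0")
  expect_error(predict(d, -0.5, type = "cdf"), "x >= 0")
  expect_error(consumption_dist("gamma", shape = -1, scale = 10), "invalid")
  expect_error(consumption_dist("lognormal", meanlog = 0, sdlog = 0),
               "invalid")
})

test_that("gamma moment relations round-trip to machine precision", {
  set.seed(5)
  for (i in 1:25) {
    m <- runif(1, 2, 80)
    s <- runif(1, 2, 100)
    d <- gamma_from_moments(m, s)
    mm <- dist_moments(d)
    expect_equal(mm[["mean"]], m, tolerance = 1e-10)
    expect_equal(mm[["sd"]], s, tolerance = 1e-10)
  }
})

test_that("lognormal MLE is the closed-form log-moment estimate", {
  x <- gamma_sample(400)
  f <- fit_consumption(x, "lognormal")
  expect_equal(unname(coef(f)[["meanlog"]]), mean(log(x)), tolerance = 1e-12)
  expect_equal(unname(coef(f)[["sdlog"]]),
               sqrt(mean((log(x) - mean(log(x)))^2)), tolerance = 1e-12)
})

test_that("gamma MLE preserves the sample mean", {
  for (seed in 1:5) {
    x <- gamma_sample(1000, shape = runif(1, 0.3, 2),
                      scale = runif(1, 5, 80), seed = seed)
    f <- fit_consumption(x, "gamma")
    expect_lt(abs(coef(f)[["shape"]] * coef(f)[["scale"]] - mean(x)) /
                mean(x), 1e-6)
  }
})

test_that("MLE recovers generating parameters at large n", {
  set.seed(42)
  x <- rgamma(50000, shape = 0.44, scale = 48)
  f <- fit_consumption(x, "gamma")
  expect_gt(coef(f)[["shape"]], 0.42)
  expect_lt(coef(f)[["shape"]], 0.46)
  expect_gt(coef(f)[["scale"]], 45)
  expect_lt(coef(f)[["scale"]], 51)
})

test_that("MLE log-likelihood is at least the method-of-moments one", {
  x <- gamma_sample(2000, shape = 0.6, scale = 30, seed = 12)
  for (fam in c("gamma", "lognormal", "weibull")) {
    fit <- fit_consumption(x, fam)
    mom <- fit_moments(x, fam)
    ll_mom <- sum(predict(mom, x, type = "density") |> log())
    expect_gte(fit$loglik, ll_mom - 1e-8)
  }
})

test_that("MLE agrees with an independent fitting routine", {
  skip_if_not_installed("fitdistrplus")
  x <- gamma_sample(3000, seed = 33)
  for (fam in c("gamma", "weibull", "lognormal")) {
    ours <- coef(fit_consumption(x, fam))
    ref <- fitdistrplus::fitdist(
      x, switch(fam, gamma = "gamma", weibull = "weibull",
                lognormal = "lnorm"))
    ref_par <- ref$estimate
    if (fam == "gamma") ref_par["scale"] <- 1 / ref_par[["rate"]]
    for (nm in names(ours)) {
      expect_equal(unname(ours[[nm]]), unname(ref_par[[nm]]),
                   tolerance = 1e-3, label = paste(fam, nm))
    }
  }
})

test_that("degenerate and invalid inputs fail loudly", {
  expect_error(fit_consumption(c(10, 10, 10), "gamma"), "zero variance")
  expect_error(fit_consumption(c(10, 10, 10), "weibull"), "zero variance")
  expect_error(fit_consumption(c(1, -2, 3), "gamma"), "positive")
  expect_error(fit_consumption(c(1, 0, 3), "gamma"), "positive")
  expect_error(fit_consumption(c(1, NA, 3), "gamma"), "missing")
  expect_error(fit_consumption(5, "gamma"), "at least 2")
})

test_that("weighted fits treat weights as frequencies", {
  x <- c(5, 5, 5, 20, 20, 40)
  f_rep <- fit_consumption(x, "gamma")
  f_w <- fit_consumption(c(5, 20, 40), "gamma", weights = c(3, 2, 1))
  expect_equal(coef(f_w), coef(f_rep), tolerance = 1e-7)
})

test_that("simulate is reproducible and predict quantile inverts cdf", {
  d <- consumption_dist("gamma", shape = 0.726, scale = 55.5)
  s1 <- simulate(d, 100, seed = 4)
  s2 <- simulate(d, 100, seed = 4)
  expect_identical(s1, s2)
  q <- predict(d, 0.9, type = "quantile")
  expect_equal(predict(d, q, type = "cdf"), 0.9, tolerance = 1e-10)
})
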