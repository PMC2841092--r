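# Shared fixtures, built in code.

# a moderate drinker sample from a gamma resembling a male US stratum
gamma_sample <- function(n = 5000, shape = 0.45, scale = 48, seed = 101) {
  set.seed(seed)
  rgamma(n, shape = shape, scale = scale)
}

# one synthetic stratum at the generator's default-style conditions
small_stratum <- function(n = 2000, seed = 7, underreport = 0.53) {
  stratum_spec("men", "18-34", "white", n = n, p_abs = 0.2, p_form = 0.2,
               shape = 0.436, scale = 48, underreport = underreport)
}

illustrative_risk <- function() rr_loglinear(0.01, rr_former = 1.3)

# Independent quadrature oracle: integral of the density over (0, upper]
# by the package's trapezoid rule. Gamma/Weibull densities with shape < 1
# diverge at the origin, where the plain rule cannot converge; substituting
# u = x^shape makes the integrand bounded and smooth there.
quad_cdf <- function(dist, upper, n = 2e5) {
  shape <- if (dist$family %in% c("gamma", "weibull")) {
    dist$params[["shape"]]
  } else NA_real_
  if (!is.na(shape) && shape < 1) {
    g <- function(u) {
      x <- u^(1 / shape)
      predict(dist, x, type = "density") * x / (shape * u)
    }
    trap_integrate(g, 1e-12, upper^shape, n)
  } else {
    trap_integrate(function(x) predict(dist, x, type = "density"),
                   1e-12, upper, n)
  }
}
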