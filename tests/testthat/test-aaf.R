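# Attributable fractions: integration, continuous and categorical forms.

test_that("trapezoid rule is exact for linear f and O(h^2) otherwise", {
  expect_equal(trap_integrate(function(x) x, 0, 1, 1), 0.5)
  expect_equal(trap_integrate(function(x) x, 0, 1, 7), 0.5)
  # halving the step reduces the x^2 error ~4x
  err <- function(n) abs(trap_integrate(function(x) x^2, 0, 1, n) - 1 / 3)
  expect_equal(err(50) / err(100), 4, tolerance = 0.01)
  # normalization of a smooth gamma density
  expect_equal(trap_integrate(function(x) dgamma(x, 2, scale = 1), 0, 50,
                              1e5), 1, tolerance = 1e-6)
  expect_error(trap_integrate(function(x) 1 / x, 0, 1, 10), "non-finite")
})

test_that("population structure validates proportions", {
  p <- population_structure(0.3, 0.2, 0.5)
  expect_equal(p$p_abs + p$p_form + p$p_cur, 1)
  expect_error(population_structure(0.5, 0.2, 0.5), "sum to 1")
  expect_error(population_structure(-0.1, 0.6, 0.5), "\\[0, 1\\]")
})

test_that("no excess risk means zero AAF", {
  pop <- population_structure(0.3, 0.2, 0.5)
  d <- gamma_from_moments(40, 47)
  expect_equal(aaf_continuous(pop, rr_constant(1), d)$aaf, 0)
  sch <- category_scheme(c(20, 40), rr = c(1, 1, 1), rr_former = 1)
  expect_equal(aaf_categorical(pop, sch, d)$aaf, 0)
})

test_that("constant RR reproduces the Levin closed form exactly", {
  d <- gamma_from_moments(40.268, 47.275)
  for (p_cur in c(0.1, 0.5, 0.9)) {
    for (r in c(1.2, 2, 5)) {
      pop <- population_structure(1 - p_cur, 0, p_cur)
      got <- aaf_continuous(pop, rr_constant(r), d)$aaf
      expect_equal(got, p_cur * (r - 1) / (1 + p_cur * (r - 1)),
                   tolerance = 1e-10)
    }
  }
})

test_that("linear RR matches the analytic k/(1+k) form", {
  # RR(x) = 1 + x/scale gives E[RR - 1] = shape, so AAF = k/(1+k)
  d <- gamma_from_moments(40.268, 47.275)
  k <- d$params[["shape"]]
  sc <- d$params[["scale"]]
  got <- aaf_continuous(population_structure(0, 0, 1),
                        risk_function(function(x) 1 + x / sc),
                        d, upper = 2000, step = 0.01)$aaf
  expect_equal(got, k / (1 + k), tolerance = 1e-4)
})

test_that("categorical and continuous AAFs agree for step risk functions", {
  pop <- population_structure(0.3, 0.2, 0.5)
  for (dist in list(gamma_from_moments(40.3, 47.3),
                    gamma_from_moments(12.5, 15.7),
                    consumption_dist("weibull", shape = 0.8, scale = 20))) {
    sch <- category_scheme(c(20, 40, 60), rr = c(1.2, 2.5, 4.8, 9.1),
                           rr_former = 1.3)
    cat_aaf <- aaf_categorical(pop, sch, dist)$aaf
    cont_aaf <- aaf_continuous(pop, as_risk_function(sch), dist)$aaf
    expect_equal(cont_aaf, cat_aaf, tolerance = 1e-6)
  }
})

test_that("a single all-covering category equals constant continuous RR", {
  pop <- population_structure(0.4, 0.1, 0.5)
  d <- gamma_from_moments(30, 35)
  sch <- category_scheme(1e-12, rr = c(2, 2), rr_former = 1.5)
  expect_equal(aaf_categorical(pop, sch, d)$aaf,
               aaf_continuous(pop, rr_constant(2, rr_former = 1.5), d)$aaf,
               tolerance = 1e-9)
})

test_that("AAF increases with pointwise RR and vanishes without drinkers", {
  d <- gamma_from_moments(40, 47)
  pop <- population_structure(0.3, 0.2, 0.5)
  a1 <- aaf_continuous(pop, rr_loglinear(0.005), d)$aaf
  a2 <- aaf_continuous(pop, rr_loglinear(0.008), d)$aaf
  expect_gt(a2, a1)
  none <- population_structure(1, 0, 0)
  expect_equal(aaf_continuous(none, rr_loglinear(0.01, rr_former = 2),
                              d)$aaf, 0)
})

test_that("upshifting never lowers the AAF for convex nondecreasing RR", {
  risk <- illustrative_risk()
  cfg <- shift_config(0.529)
  pop <- population_structure(0.3, 0.2, 0.5)
  ref <- upshift_reference()
  for (i in c(1, 8, 21, 36)) {
    orig <- consumption_dist("gamma", shape = ref$k[i], scale = ref$theta[i])
    sh <- shift_distribution(orig, as.integer(ref$sex[i] == "women"), cfg)
    expect_gte(aaf_continuous(pop, risk, sh$shifted)$aaf,
               aaf_continuous(pop, risk, sh$original)$aaf)
  }
})

test_that("capping consumption cannot raise the AAF of a nondecreasing RR", {
  pop <- population_structure(0.3, 0.2, 0.5)
  d <- gamma_from_moments(40.3, 47.3)
  risk <- illustrative_risk()
  uncapped <- aaf_continuous(pop, risk, d, upper = 1000)$aaf
  capped <- aaf_continuous(pop, risk, d, cap = 150)$aaf
  expect_lte(capped, uncapped)
  # capped mass is retained: a constant RR is unaffected by the cap
  expect_equal(aaf_continuous(pop, rr_constant(3), d, cap = 150)$aaf,
               aaf_continuous(pop, rr_constant(3), d)$aaf, tolerance = 1e-12)
  # truncation mode conditions on X <= cap instead
  trunc <- aaf_continuous(pop, risk, d, cap = 150, cap_mode = "truncate")$aaf
  expect_lte(trunc, capped)
})

test_that("risk function constructors validate and evaluate", {
  expect_error(rr_step(c(20, 40), c(1, 2)), "length")
  expect_error(category_scheme(c(40, 20), c(1, 2, 3)), "increasing")
  rt <- rr_table(c(10, 50), c(2, 6))
  expect_equal(rt$rr(30), 4)     # linear interpolation
  expect_equal(rt$rr(0), 1)      # anchored at the RR(0) = 1 reference
  expect_equal(rt$rr(100), 6)    # constant beyond the last point
  rs <- rr_step(c(20, 40), c(1.1, 2, 3))
  expect_equal(rs$rr(c(5, 20, 39.9, 40, 80)), c(1.1, 2, 2, 3, 3))
  # divergent/non-finite RR is caught and names the grid point
  bad <- risk_function(function(x) ifelse(x > 100, Inf, 1))
  d <- gamma_from_moments(40, 47)
  expect_error(aaf_continuous(population_structure(0, 0, 1), bad, d),
               "non-finite")
})
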