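test_that("linear predictor follows the model formula and drops absent terms", {
  d <- long_count_data(c(1, 1, 2, 2), c(1, 2, 1, 2), c(0, 3, 0, 3),
                       c(0, 0, 1, 1), c(1, 2, 3, 4))
  spec_full <- model_spec("poisson", "I", "main_interaction")
  z <- linear_predictor(list(beta = rep(0, 4), b0 = c(0, 0)), d, spec_full)
  expect_equal(z, rep(0, 4))

  # beta = (1, -0.19, 0, -0.17), x = 1, t = 3 -> 1 - 0.57 - 0.51 = -0.08
  eta <- linear_predictor(list(beta = c(1, -0.19, 0, -0.17), b0 = c(0, 0)),
                          d, spec_full)
  expect_equal(eta[4], -0.08)

  # pre_study formula has no group main effect
  spec_pre <- model_spec("poisson", "I", "pre_study")
  eta2 <- linear_predictor(list(beta = c(1, -0.19, -0.17), b0 = c(0, 0)),
                           d, spec_pre)
  expect_equal(eta2[4], -0.08)

  # IS with b1 = 0 reduces exactly to I
  spec_is <- model_spec("poisson", "IS", "main_interaction")
  st <- list(beta = c(0.4, -0.2, 0.1, -0.1), b0 = c(0.3, -0.2))
  expect_equal(linear_predictor(c(st, list(b1 = c(0, 0))), d, spec_is),
               linear_predictor(st, d, spec_full))
  # and a nonzero slope enters multiplied by time
  eta_is <- linear_predictor(c(st, list(b1 = c(0.5, 0))), d, spec_is)
  expect_equal(eta_is - linear_predictor(st, d, spec_full),
               c(0, 1.5, 0, 0))

  expect_error(linear_predictor(list(beta = rep(0, 3), b0 = c(0, 0)), d,
                                spec_full), "beta")
  expect_error(linear_predictor(list(beta = rep(0, 4), b0 = 0), d,
                                spec_full), "b0")
})

test_that("observation log-likelihoods match their closed forms", {
  sp <- function(f) model_spec(f, "I")
  # Poisson at y = 0, mu = 1
  expect_equal(loglik_obs(list(), 0, 0, sp("poisson")), -1)
  # NB with k = 1 is geometric: pmf(0) = 1/(1 + mu)
  mu <- 2.5
  expect_equal(loglik_obs(list(k = 1), 0, log(mu), sp("nb")),
               log(1 / (1 + mu)))
  # ZIP zero mass: pi0 + (1 - pi0) e^-mu
  expect_equal(exp(loglik_obs(list(pi0 = 0.09), 0, log(2), sp("zip"))),
               0.09 + 0.91 * exp(-2))
  # NMM is a Gaussian density on the transformed scale
  expect_equal(loglik_obs(list(sigma_eps = 0.5), 1.2, 1.0,
                          sp("nmm_arcsinh")),
               stats::dnorm(1.2, 1.0, 0.5, log = TRUE))
  expect_error(loglik_obs(list(), 1.5, 0, sp("poisson")), "integer")
})

test_that("NB pmf converges to the Poisson pmf as k grows", {
  y <- 0:50
  d <- abs(exp(loglik_obs(list(k = 1e6), y, log(4), model_spec("nb", "I"))) -
             stats::dpois(y, 4))
  expect_lt(max(d), 1e-4)
})

test_that("count pmfs are proper and NB moments match the stated identities", {
  set.seed(42)
  for (f in c("poisson", "nb", "zip", "zinb")) {
    st <- list(k = 2.3, pi0 = 0.25)
    p <- exp(loglik_obs(st, 0:400, log(6), model_spec(f, "I")))
    expect_lt(abs(sum(p) - 1), 1e-8)
  }
  for (i in 1:5) {
    k <- stats::runif(1, 0.5, 20); mu <- stats::runif(1, 1, 15)
    y <- 0:3000
    p <- exp(loglik_obs(list(k = k), y, log(mu), model_spec("nb", "I")))
    m1 <- sum(y * p); m2 <- sum(y^2 * p) - m1^2
    expect_equal(m1, mu, tolerance = 1e-6)
    expect_equal(m2, mu + mu^2 / k, tolerance = 1e-6)
    # p = k/(k+mu) gives mean k(1-p)/p
    pp <- k / (k + mu)
    expect_equal(k * (1 - pp) / pp, mu)
  }
  # zero-inflated pmf with pi0 = 0 equals the base pmf element-wise
  y <- 0:30
  expect_equal(loglik_obs(list(pi0 = 0), y, log(3), model_spec("zip", "I")),
               loglik_obs(list(), y, log(3), model_spec("poisson", "I")))
  expect_equal(loglik_obs(list(pi0 = 0, k = 2), y, log(3),
                          model_spec("zinb", "I")),
               loglik_obs(list(k = 2), y, log(3), model_spec("nb", "I")))
})

test_that("arcsinh transform has the right values and inverse", {
  expect_equal(arcsinh_transform(0), 0)
  expect_equal(arcsinh_transform(1), log(1 + sqrt(2)))
  for (y in c(0, 3, 25))
    expect_equal(arcsinh_inverse(arcsinh_transform(y)), y, tolerance = 1e-12)
  expect_error(arcsinh_transform(-1))
})

test_that("NB variance stabilizer matches quadrature and the Poisson limit", {
  expect_equal(vst_negbin(0, 1), 0)
  expect_equal(vst_negbin(0, 0), 0)
  for (case in list(c(4, 1), c(9, 0.2), c(2.5, 3))) {
    q <- stats::integrate(function(u) 1 / sqrt(u * (case[2] * u + 1)),
                          0, case[1], rel.tol = 1e-12)$value
    expect_lt(abs(vst_negbin(case[1], case[2]) - q), 1e-8)
  }
  # near z = 0 the stabilizer is proportional to sqrt(y)
  r <- sapply(c(1, 4, 9), function(y) vst_negbin(y, 1e-8) / sqrt(y))
  expect_equal(signif(r, 4), rep(signif(r[1], 4), 3))
  expect_equal(vst_negbin(9, 0), 2 * sqrt(9))
  expect_error(vst_negbin(1, -0.1), "non-negative")
})

test_that("Gamma prior derivation inverts the marginal t range", {
  b <- derive_gamma_prior(0.6, 0.5)["b"]
  # doubling the range quadruples the rate
  expect_equal(unname(derive_gamma_prior(1.2, 0.5)["b"]), unname(4 * b))
  # independent quantile oracle: invert the t CDF numerically at a = 1
  tq <- stats::uniroot(function(x) stats::pt(x, df = 2) - 0.975,
                       c(1, 100), tol = 1e-12)$root
  expect_equal(unname(derive_gamma_prior(0.6, 1)["b"]), (0.6 / tq)^2,
               tolerance = 1e-9)
})

test_that("prior and model specs validate their hyperparameters", {
  expect_error(prior_spec(wishart_r = 1), "wishart_r")
  expect_error(prior_spec(beta_precision = 0))
  expect_error(model_spec("weibull"), "arg")
  s <- model_spec("zinb", "IS")
  expect_s3_class(s, "model_spec")
  expect_output(print(s), "zinb")
})
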