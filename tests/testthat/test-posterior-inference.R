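test_that("fits are seed-deterministic and reusable", {
  f1 <- tiny_fit("poisson")
  f2 <- suppressWarnings(
    fit_mcmc(model_spec("poisson", "I"), tiny_data(), quick_control()))
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$loglik, f2$loglik)
  expect_true(all(is.finite(f1$loglik)))
  expect_equal(nrow(f1$loglik), 800)  # 2 chains x (800 - 400 burn-in)
  expect_true(all(c("rhat", "ess") %in% names(f1$diagnostics)))
})

test_that("posterior matches the conjugate Gaussian closed form when the
           hierarchy is pinned", {
  # NMM with the random-intercept and residual precisions pinned by very
  # concentrated Gamma priors reduces to Bayesian linear regression of the
  # arcsinh response with known error SD 0.5.
  d <- tiny_data()
  pr <- prior_spec(beta_precision = 0.001,
                   intercept_prec_shape = 1e8, intercept_prec_rate = 100,
                   resid_prec_shape = 1e8, resid_prec_rate = 1e8 / 4)
  spec <- model_spec("nmm_arcsinh", "I", priors = pr)
  fit <- suppressWarnings(
    fit_mcmc(spec, d, mcmc_control(chains = 2, iter = 3000, seed = 7)))
  X <- cbind(1, d$time, d$group * d$time)
  tau <- 4
  P <- 0.001 * diag(3) + tau * crossprod(X)
  Sig <- solve(P)
  mu <- drop(Sig %*% (tau * crossprod(X, asinh(d$count))))
  sds <- sqrt(diag(Sig))
  ess <- pmax(fit$diagnostics$ess[1:3], 50)
  for (j in 1:3) {
    expect_lt(abs(colMeans(fit$draws$beta)[j] - mu[j]),
              3 * sds[j] / sqrt(ess[j]) + 0.02 * sds[j])
    expect_equal(stats::sd(fit$draws$beta[, j]), sds[j], tolerance = 0.15)
  }
  # non-hierarchical in effect: p_D is about the number of fixed effects
  dic <- compute_dic(fit)
  expect_lt(abs(dic$pD - 3), 1)
})

test_that("degenerate all-zero data fits without crashing", {
  d <- long_count_data(rep(1:4, each = 3), rep(1:3, 4), rep(0:2, 4),
                       rep(c(0, 1), each = 6), rep(0, 12))
  fit <- suppressWarnings(
    fit_mcmc(model_spec("poisson", "I"), d, quick_control()))
  expect_true(all(is.finite(fit$draws$beta)))
  expect_true(all(is.finite(fit$loglik)))
})

test_that("posterior summaries are stable under subject relabeling", {
  d <- tiny_data()
  perm <- rev(sort(unique(d$subject_id)))
  d2 <- long_count_data(perm[match(d$subject_id, sort(unique(d$subject_id)))],
                        d$visit, d$time, d$group, d$count)
  d2 <- d2[order(d2$subject_id, d2$visit), ]
  f1 <- tiny_fit("nb")
  f2 <- suppressWarnings(
    fit_mcmc(model_spec("nb", "I"), d2, quick_control()))
  expect_lt(max(abs(colMeans(f1$draws$beta) - colMeans(f2$draws$beta))), 0.1)
  expect_lt(abs(mean(f1$draws$k) - mean(f2$draws$k)), 0.6)
})

test_that("plug-in deviance equals an independent likelihood recomputation", {
  fit <- tiny_fit("nb")
  pm <- fit$posterior_means
  X <- cbind(1, fit$data$time, fit$data$group * fit$data$time)
  subj <- match(fit$data$subject_id, sort(unique(fit$data$subject_id)))
  eta <- drop(X %*% pm$beta) + pm$b0[subj]
  oracle <- -2 * sum(stats::dnbinom(fit$data$count, size = pm$k,
                                    mu = exp(eta), log = TRUE))
  expect_equal(plug_in_deviance(fit), oracle, tolerance = 1e-10)
})

test_that("a point-mass posterior gives pD = 0 and DIC = D(theta-bar)", {
  d <- tiny_data()
  fit <- suppressWarnings(
    fit_mcmc(model_spec("nb", "I"), d,
             mcmc_control(chains = 1, iter = 401, burn = 400, seed = 3)))
  expect_equal(nrow(fit$loglik), 1)
  dic <- compute_dic(fit)
  expect_equal(dic$pD, 0, tolerance = 1e-6)
  expect_equal(dic$DIC, dic$Dhat, tolerance = 1e-6)
})

test_that("harmonic-mean CPO reduces to the likelihood for a single draw and
           stays in (0, 1] for discrete families", {
  d <- tiny_data()
  fit1 <- suppressWarnings(
    fit_mcmc(model_spec("poisson", "I"), d,
             mcmc_control(chains = 1, iter = 401, burn = 400, seed = 3)))
  cp <- ghost_cpo(fit1, ghost = FALSE)
  expect_equal(cp$cpo, exp(fit1$loglik[1, ]))
  cp2 <- ghost_cpo(tiny_fit("poisson"), ghost = FALSE)
  expect_true(all(cp2$cpo > 0 & cp2$cpo <= 1))
  cp3 <- ghost_cpo(tiny_fit("poisson"), ghost = TRUE, M = 10)
  expect_true(all(cp3$cpo > 0 & cp3$cpo <= 1))
})

test_that("the leave-one-out predictive from an exact refit is proper", {
  d <- tiny_data()
  ex <- suppressWarnings(
    exact_refit_cpo(model_spec("poisson", "I"), d, index = 7,
                    control = quick_control(), want_pit = TRUE))
  pmf <- loo_predictive_pmf(ex$fit, 7, ymax = 400)
  expect_lt(abs(sum(pmf) - 1), 1e-6)
  # the refit CPO is the predictive mass at the observed count
  expect_equal(ex$cpo, pmf[d$count[7] + 1], tolerance = 1e-12)
  expect_true(ex$pit >= 0 && ex$pit <= 1)
})
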