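test_that("generator is deterministic, structurally valid, and substream-stable", {
  cfg <- dgp_config(k = 2, n_per_group = 6, seed = 99)
  d1 <- generate_nb_longitudinal(cfg)
  d2 <- generate_nb_longitudinal(cfg)
  expect_identical(d1, d2)
  expect_s3_class(d1, "long_count_data")
  expect_equal(nrow(d1), 2 * 6 * 4)
  expect_true(all(d1$count >= 0 & d1$count == round(d1$count)))
  expect_true(all(tapply(d1$group, d1$subject_id,
                         function(g) length(unique(g))) == 1))
  expect_false(any(duplicated(d1[, c("subject_id", "visit")])))
  # counter-based substreams: growing the design never reshuffles draws of
  # subjects that keep their group assignment
  big <- generate_nb_longitudinal(dgp_config(k = 2, n_per_group = 12,
                                             seed = 99))
  expect_identical(d1$count[d1$subject_id <= 6],
                   big$count[big$subject_id <= 6])
})

test_that("NB sampling has the stated moments and limits", {
  # Poisson limit: sigma_a = 0, huge k, t = 0 -> mean exp(alpha) = e^3
  d <- generate_nb_longitudinal(dgp_config(sigma_a = 0, k = 1e6,
                                           n_per_group = 3000,
                                           times = c(0, 0), seed = 3))
  expect_lt(abs(mean(d$count) - exp(3)), 0.2)
  # variance/mean ratio within 5% of 1 in the Poisson limit
  expect_lt(abs(stats::var(d$count) / mean(d$count) - 1), 0.05)

  # overdispersion by construction at moderate k
  d2 <- generate_nb_longitudinal(dgp_config(k = 5, n_per_group = 200,
                                            seed = 4))
  base <- d2[d2$time == 0, ]
  expect_gt(stats::var(base$count), mean(base$count))
  # lognormal random-intercept mixing: E[Y | t=0] = exp(alpha + sigma_a^2/2)
  d3 <- generate_nb_longitudinal(dgp_config(k = 5, n_per_group = 300,
                                            seed = 8))
  expect_lt(abs(mean(d3$count[d3$time == 0]) - exp(3 + 0.3^2 / 2)), 2.5)
})

test_that("group-wise log-mean trajectories recover the true slopes", {
  cfg <- dgp_config(k = 10, n_per_group = 200, seed = 12)
  d <- generate_nb_longitudinal(cfg)
  for (g in 0:1) {
    lm_means <- log(tapply(d$count[d$group == g], d$time[d$group == g], mean))
    slope <- stats::coef(stats::lm(lm_means ~ as.numeric(names(lm_means))))[2]
    truth <- if (g == 1) cfg$beta2 else cfg$beta1
    expect_lt(abs(slope - truth), 0.12)
  }
})

test_that("zero inflation masks after the base draw and hits the zero formula", {
  cfg0 <- dgp_config(family = "zip", pi0 = 0, n_per_group = 8, seed = 21)
  base <- generate_nb_longitudinal(dgp_config(family = "poisson",
                                              n_per_group = 8, seed = 21))
  expect_identical(generate_zero_inflated(cfg0)$count, base$count)

  # P(Y = 0) = pi0 + (1 - pi0) exp(-mu) for the ZIP with fixed small mu
  cfg <- dgp_config(alpha = 0.5, sigma_a = 0, family = "zip", pi0 = 0.5,
                    times = c(0, 0), n_per_group = 1000, seed = 22)
  d <- generate_zero_inflated(cfg)
  p0 <- 0.5 + 0.5 * exp(-exp(0.5))
  expect_lt(abs(mean(d$count == 0) - p0), 0.035)

  # near-total inflation: zero fraction approaches pi0 + (1-pi0) f(0)
  cfg2 <- dgp_config(alpha = 2, sigma_a = 0, family = "zinb", k = 1,
                     pi0 = 0.95, times = c(0, 0), n_per_group = 1000,
                     seed = 23)
  d2 <- generate_zero_inflated(cfg2)
  p02 <- 0.95 + 0.05 * stats::dnbinom(0, size = 1, mu = exp(2))
  expect_lt(abs(mean(d2$count == 0) - p02), 0.02)

  expect_error(dgp_config(pi0 = 1), "pi0")
  expect_error(dgp_config(pi0 = -0.1), "pi0")
  expect_error(generate_zero_inflated(dgp_config(family = "nb")), "zip")
})

test_that("vertigo-like generator matches the pre-study design shape", {
  d <- generate_vertigo_like(50, 62, seed = 17)
  expect_equal(length(unique(d$subject_id)), 112)
  expect_equal(nrow(d), 560)
  expect_equal(sort(unique(d$time)), c(0, 3, 6, 9, 12))
  expect_identical(d, generate_vertigo_like(50, 62, seed = 17))
  expect_false(identical(d$count, generate_vertigo_like(50, 62, seed = 18)$count))

  # MCAR dropout keeps baseline and thins later visits
  dm <- generate_vertigo_like(40, 40, seed = 2, p_miss = 0.5)
  expect_true(all(tapply(dm$visit, dm$subject_id, function(v) 1 %in% v)))
  expect_lt(nrow(dm), 400)

  # zero random-effect variances: empirical group means follow the common
  # expected trajectory exp(beta0 + (beta_time + beta_inter * g) t)
  d0 <- generate_vertigo_like(300, 300, seed = 9, sd_b0 = 0, sd_b1 = 0)
  for (g in 0:1) {
    sel <- d0$group == g
    emp <- tapply(d0$count[sel], d0$time[sel], mean)
    tt <- as.numeric(names(emp))
    expected <- exp(1.6 + (-0.19 - 0.17 * g) * tt)
    se <- sqrt(expected / 300)
    expect_true(all(abs(emp - expected) < 4 * se))
  }
})

test_that("overflowing linear predictors fail loudly, naming the subject", {
  expect_error(
    generate_nb_longitudinal(dgp_config(alpha = 500, beta1 = 400, beta2 = 400,
                                        n_per_group = 2, seed = 1)),
    "subject")
})

test_that("long count data round-trips through CSV", {
  d <- tiny_data()
  f <- withr::local_tempfile(fileext = ".csv")
  write_long_count(d, f)
  d2 <- read_long_count(f)
  expect_equal(as.data.frame(d), as.data.frame(d2))
})

test_that("container invariants are enforced", {
  expect_error(long_count_data(c(1, 1), c(1, 1), c(0, 1), c(0, 0), c(1, 2)),
               "duplicated")
  expect_error(long_count_data(c(1, 1), c(1, 2), c(1, 0), c(0, 0), c(1, 2)),
               "non-decreasing")
  expect_error(long_count_data(c(1, 1), c(1, 2), c(0, 1), c(0, 1), c(1, 2)),
               "constant")
  expect_error(long_count_data(1, 1, 0, 0, -1), "non-negative")
  expect_error(long_count_data(1, 1, 0, 0, 1.5), "non-negative")
})
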