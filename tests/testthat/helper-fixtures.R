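# Shared fixtures, memoised so expensive fits are computed once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

tiny_data <- function() memo("tiny_data",
  generate_nb_longitudinal(dgp_config(k = 3, n_per_group = 6, seed = 5)))

quick_control <- function(seed = 2) mcmc_control(chains = 2, iter = 800,
                                                 seed = seed)

tiny_fit <- function(family = "poisson", structure = "I") {
  key <- paste0("fit_", family, "_", structure)
  memo(key, suppressWarnings(
    fit_mcmc(model_spec(family, structure), tiny_data(), quick_control())))
}

# Hand-built posterior "fit" with fixed draws, for predictive edge cases.
fixed_poisson_fit <- function(data, beta, S = 4) {
  spec <- model_spec("poisson", "I")
  draws <- list(beta = matrix(rep(beta, each = S), S, length(beta)),
                b0 = matrix(0, S, length(unique(data$subject_id))),
                b1 = NULL,
                sigma_mat = cbind(rep(0.01, S), 0, NA),
                tau_b0 = rep(100, S), k = rep(1, S), pi0 = rep(0, S),
                sigma_eps = rep(1, S))
  eta <- drop(cbind(1, data$time, data$group * data$time) %*% beta)
  ll <- matrix(rep(stats::dpois(data$count, exp(eta), log = TRUE), each = S),
               S, nrow(data))
  structure(list(spec = spec, data = data, draws = draws, loglik = ll,
                 exclude = NULL,
                 control = mcmc_control(chains = 1, iter = 2, burn = 1)),
            class = "posterior_fit")
}
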