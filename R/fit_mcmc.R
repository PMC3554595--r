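#' MCMC settings
#'
#' @param chains number of independent chains.
#' @param iter iterations per chain (including burn-in).
#' @param burn burn-in iterations per chain (default half), during which the
#'   proposal scales adapt; post-burn-in draws are retained.
#' @param thin thinning interval.
#' @param seed integer seed for the whole fit.
#' @param rhat_threshold split-chain convergence threshold above which a
#'   warning is issued.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 2, iter = 2000, burn = floor(iter / 2),
                         thin = 1, seed = 1L, rhat_threshold = 1.05) {
  stopifnot(chains >= 1, iter > burn, burn >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn = as.integer(burn), thin = as.integer(thin),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold),
            class = "mcmc_control")
}

fam_code <- function(family) {
  match(family, c("poisson", "nb", "zip", "zinb", "nmm_arcsinh")) - 1L
}

prior_list <- function(priors) {
  list(prec_beta = priors$beta_precision,
       a_tau = priors$intercept_prec_shape,
       b_tau = priors$intercept_prec_rate,
       wishart_r = priors$wishart_r,
       wishart_R = priors$wishart_R,
       k_a = priors$k_shape, k_b = priors$k_rate,
       pi_a = priors$pi0_shape1, pi_b = priors$pi0_shape2,
       eps_a = priors$resid_prec_shape, eps_b = priors$resid_prec_rate)
}

default_inits <- function(spec, data, jitter_sd = 0) {
  y <- data$count
  N <- length(unique(data$subject_id))
  p <- ncol(fixed_design(spec, data))
  if (spec$family == "nmm_arcsinh") {
    z <- asinh(y)
    beta <- c(mean(z), rep(0, p - 1))
  } else {
    beta <- c(log(mean(y) + 0.5), rep(0, p - 1))
  }
  m <- mean(y); v <- stats::var(y)
  k0 <- if (v > m + 1e-8) max(m^2 / (v - m), 0.05) else 10
  list(beta = beta + stats::rnorm(p, 0, jitter_sd),
       b0 = rep(0, N), b1 = rep(0, N),
       tau0 = 10, k = k0, pi0 = 0.1, tau_eps = 1)
}

split_rhat <- function(x, chain) {
  # split each chain in half; standard potential-scale-reduction statistic
  halves <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- floor(length(v) / 2)
    if (h < 2) return(NA_real_)
    halves <- c(halves, list(v[seq_len(h)]), list(v[(h + 1):(2 * h)]))
  }
  m <- length(halves); nn <- length(halves[[1]])
  mu <- vapply(halves, mean, 0); s2 <- vapply(halves, stats::var, 0)
  W <- mean(s2); B <- nn * stats::var(mu)
  if (W < 1e-300) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_basic <- function(x, chain) {
  # initial-positive-sequence autocorrelation estimator, per chain, summed
  tot <- 0
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    nn <- length(v)
    if (nn < 2 || !is.finite(stats::var(v)) || stats::var(v) < 1e-300) {
      tot <- tot + nn
      next
    }
    ac <- stats::acf(v, lag.max = min(nn - 1, 200), plot = FALSE)$acf[-1]
    s <- 0
    for (l in seq_along(ac)) {
      if (ac[l] < 0.05) break
      s <- s + ac[l]
    }
    tot <- tot + nn / (1 + 2 * s)
  }
  tot
}

#' Fit a Bayesian GLMM by adaptive MCMC
#'
#' Draws from the posterior of a [model_spec()] applied to a
#' [long_count_data()] using an adaptive Metropolis-within-Gibbs sampler
#' (componentwise random-walk updates for fixed effects and subject random
#' effects; conjugate Gibbs updates for the random-effect precision or its
#' Wishart-prior precision matrix; log-scale random walk for the NB size k and
#' logit-scale for the zero-inflation probability). The arcsinh normal mixed
#' model is fully conjugate and sampled by plain Gibbs; its response is
#' transformed internally. The per-draw per-observation conditional
#' log-likelihood matrix needed by the predictive criteria is stored with the
#' fit.
#'
#' @param spec a [model_spec()].
#' @param data a [long_count_data()].
#' @param control an [mcmc_control()].
#' @param exclude optional single row index of `data` to omit from the
#'   likelihood (used for exact leave-one-out refits); the omitted
#'   observation's log-likelihood is still evaluated and stored per draw.
#' @return A list of class `posterior_fit`: posterior draws, the
#'   S x n log-likelihood matrix, componentwise posterior means
#'   (`posterior_means`), split-chain convergence diagnostics, and metadata.
#'   A warning is raised (and `converged` set to `FALSE`) if any monitored
#'   scalar exceeds the convergence threshold.
#' @export
fit_mcmc <- function(spec, data, control = mcmc_control(), exclude = NULL) {
  stopifnot(inherits(spec, "model_spec"), nrow(data) > 0)
  validate_long_count_data(data, "count")
  X <- fixed_design(spec, data)
  subj <- match(data$subject_id, sort(unique(data$subject_id))) - 1L
  fam <- fam_code(spec$family)
  yy <- if (spec$family == "nmm_arcsinh") asinh(data$count) else
    as.numeric(data$count)
  excl <- if (is.null(exclude)) -1L else as.integer(exclude) - 1L
  slope <- spec$random_structure == "IS"
  pl <- prior_list(spec$priors)

  set.seed(control$seed)
  res <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    inits <- default_inits(spec, data, jitter_sd = if (ch == 1) 0 else 0.15)
    res[[ch]] <- mcmc_glmm_cpp(yy, X, subj, data$time, fam, slope, pl, inits,
                               control$iter, control$burn, control$thin, excl)
  }
  S_ch <- nrow(res[[1]]$beta)
  chain_id <- rep(seq_len(control$chains), each = S_ch)
  bindm <- function(f) do.call(rbind, lapply(res, `[[`, f))
  bindv <- function(f) do.call(c, lapply(res, `[[`, f))
  draws <- list(beta = bindm("beta"), b0 = bindm("b0"),
                b1 = if (slope) bindm("b1") else NULL,
                sigma_mat = bindm("sigma_mat"),
                tau_b0 = bindv("tau0"), k = bindv("k"), pi0 = bindv("pi0"),
                sigma_eps = bindv("sigma_eps"))
  colnames(draws$beta) <- colnames(X)
  loglik <- bindm("loglik")

  # monitored scalars: fixed effects + family hyperparameters
  mon <- as.data.frame(draws$beta)
  mon$sd_b0 <- sqrt(draws$sigma_mat[, 1])
  if (slope) {
    mon$sd_b1 <- sqrt(draws$sigma_mat[, 3])
    mon$rho <- draws$sigma_mat[, 2] /
      sqrt(draws$sigma_mat[, 1] * draws$sigma_mat[, 3])
  }
  if (spec$family %in% c("nb", "zinb")) mon$k <- draws$k
  if (spec$family %in% c("zip", "zinb")) mon$pi0 <- draws$pi0
  if (spec$family == "nmm_arcsinh") mon$sigma_eps <- draws$sigma_eps
  diagnostics <- data.frame(
    param = names(mon),
    rhat = vapply(mon, split_rhat, 0, chain = chain_id),
    ess = vapply(mon, ess_basic, 0, chain = chain_id))
  converged <- all(is.na(diagnostics$rhat) |
                     diagnostics$rhat < control$rhat_threshold)
  if (!converged)
    warning("convergence diagnostic above ", control$rhat_threshold,
            " for: ", paste(diagnostics$param[
              !is.na(diagnostics$rhat) &
                diagnostics$rhat >= control$rhat_threshold], collapse = ", "))

  pm_sig <- colMeans(draws$sigma_mat)
  posterior_means <- list(
    beta = colMeans(draws$beta), b0 = colMeans(draws$b0),
    b1 = if (slope) colMeans(draws$b1) else NULL,
    tau_b0 = 1 / pm_sig[1],
    tau_b1 = if (slope) 1 / pm_sig[3] else NULL,
    rho = if (slope) pm_sig[2] / sqrt(pm_sig[1] * pm_sig[3]) else NULL,
    k = mean(draws$k), pi0 = mean(draws$pi0),
    sigma_eps = mean(draws$sigma_eps))

  structure(list(spec = spec, data = data, draws = draws, loglik = loglik,
                 posterior_means = posterior_means, diagnostics = diagnostics,
                 converged = converged, chain_id = chain_id,
                 accept = lapply(res, `[[`, "accept"),
                 exclude = exclude, control = control),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("posterior_fit: %s, %d draws (%d chains), %d observations\n",
              model_label(x$spec), nrow(x$loglik), x$control$chains,
              ncol(x$loglik)))
  cat(sprintf("  converged: %s (max rhat %.3f)\n", x$converged,
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Deviance at the posterior means
#'
#' Evaluates \eqn{D(\bar\theta) = -2 \sum \log f(y_{ij} | \bar\theta)} with the
#' standardizing term fixed to zero, where \eqn{\bar\theta} collects the
#' componentwise posterior means of *all* latent quantities, including the
#' subject random effects (observation-level likelihood focus).
#'
#' @param fit a [posterior_fit()][fit_mcmc].
#' @return The plug-in deviance, a single number.
#' @export
plug_in_deviance <- function(fit) {
  pm <- fit$posterior_means
  eta <- linear_predictor(pm, fit$data, fit$spec)
  y <- if (fit$spec$family == "nmm_arcsinh") asinh(fit$data$count) else
    fit$data$count
  keep <- rep(TRUE, nrow(fit$data))
  if (!is.null(fit$exclude)) keep[fit$exclude] <- FALSE
  -2 * sum(loglik_obs(pm, y, eta, fit$spec)[keep])
}
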