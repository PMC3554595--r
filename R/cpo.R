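# Leave-one-out predictive machinery: CPO and the predictive CDF components
# shared with the PIT, via full-data estimators or exact single-case refits.

# Per-draw linear predictor matrix (S x n) from stored draws.
draw_eta <- function(fit) {
  X <- fixed_design(fit$spec, fit$data)
  subj <- match(fit$data$subject_id, sort(unique(fit$data$subject_id)))
  eta <- fit$draws$beta %*% t(X) + fit$draws$b0[, subj, drop = FALSE]
  if (fit$spec$random_structure == "IS")
    eta <- eta + fit$draws$b1[, subj, drop = FALSE] *
      matrix(fit$data$time, nrow(eta), ncol(eta), byrow = TRUE)
  eta
}

# Strict predictive CDF P(Y < y) per draw (S x n), count families, and
# P(Z <= z) for the NMM.
draw_cdf_lt <- function(fit) {
  S <- nrow(fit$loglik); n <- ncol(fit$loglik)
  eta <- draw_eta(fit)
  fam <- fit$spec$family
  if (fam == "nmm_arcsinh") {
    z <- matrix(asinh(fit$data$count), S, n, byrow = TRUE)
    return(stats::pnorm(z, eta, fit$draws$sigma_eps))
  }
  mu <- exp(eta)
  ym1 <- matrix(fit$data$count - 1, S, n, byrow = TRUE)
  Fv <- switch(fam,
    poisson = stats::ppois(ym1, mu),
    nb = stats::pnbinom(ym1, size = fit$draws$k, mu = mu),
    zip = fit$draws$pi0 + (1 - fit$draws$pi0) * stats::ppois(ym1, mu),
    zinb = fit$draws$pi0 + (1 - fit$draws$pi0) *
      stats::pnbinom(ym1, size = fit$draws$k, mu = mu))
  Fv[ym1 < 0] <- 0
  Fv
}

#' Leave-one-out CPO from a single full-data fit
#'
#' Estimates the conditional predictive ordinate
#' \eqn{CPO_{ij} = \pi(y_{ij} | y_{-ij})} for every observation from the
#' full-data posterior draws, without refitting.
#'
#' With `ghost = TRUE` (default) the full-data mixed approach is used: for
#' each draw, fresh "ghost" random effects for the subject are drawn from
#' their prior given the drawn hyperparameters and importance-weighted by the
#' subject's remaining observations, which marginalizes the left-out subject
#' term out of the conditional predictive; a harmonic mean over draws then
#' corrects for the left-out observation's influence on fixed effects and
#' hyperparameters. With `ghost = FALSE` the plain harmonic-mean
#' (importance-weighting) identity \eqn{CPO^{-1} = E[1/f(y_{ij}|\theta)]} is
#' applied to the stored per-draw likelihoods.
#'
#' Observations whose importance weights are unstable (relative Monte Carlo
#' standard error of \eqn{1/CPO} above `flag_threshold`) are flagged; for
#' those, [exact_refit_cpo()] is the reliable fallback.
#'
#' @param fit a [posterior_fit()][fit_mcmc].
#' @param ghost use ghost sampling (default) or the plain harmonic mean.
#' @param M ghost draws per subject-draw (ghost mode).
#' @param want_pit also compute the leave-one-out predictive CDF components
#'   needed by [compute_pit()].
#' @param flag_threshold relative MC-SE of 1/CPO above which an observation is
#'   flagged unreliable.
#' @param draw_thin use every `draw_thin`-th posterior draw in the ghost
#'   estimator (the ghost re-draws already average over the random-effect
#'   dimension, so modest thinning costs little precision).
#' @return A `data.frame` with columns `cpo`, `rel_se`, `flag`, and (if
#'   requested) `pit`.
#' @export
ghost_cpo <- function(fit, ghost = TRUE, M = 20, want_pit = FALSE,
                      flag_threshold = 0.2, draw_thin = 1) {
  stopifnot(inherits(fit, "posterior_fit"))
  fam <- fit$spec$family
  if (ghost) {
    X <- fixed_design(fit$spec, fit$data)
    subj <- match(fit$data$subject_id, sort(unique(fit$data$subject_id))) - 1L
    yy <- if (fam == "nmm_arcsinh") asinh(fit$data$count) else
      as.numeric(fit$data$count)
    ss <- seq(1, nrow(fit$draws$beta), by = draw_thin)
    g <- ghost_predict_cpp(yy, X, subj, fit$data$time, fam_code(fam),
                           fit$spec$random_structure == "IS",
                           fit$draws$beta[ss, , drop = FALSE],
                           fit$draws$k[ss], fit$draws$pi0[ss],
                           fit$draws$sigma_eps[ss],
                           fit$draws$sigma_mat[ss, , drop = FALSE],
                           as.integer(M), want_pit)
    out <- data.frame(cpo = g$cpo, rel_se = g$rel_se)
    if (want_pit)
      out$pit <- if (fam == "nmm_arcsinh") g$pit_lt else
        pmin(g$pit_lt + 0.5 * g$cpo, 1)
  } else {
    inv <- exp(-fit$loglik)
    mi <- colMeans(inv)
    cpo <- 1 / mi
    vr <- pmax(colMeans(inv^2) - mi^2, 0)
    out <- data.frame(cpo = cpo,
                      rel_se = sqrt(vr / nrow(inv)) / mi)
    if (want_pit) {
      Flt <- draw_cdf_lt(fit)
      pit_lt <- colSums(Flt * inv) / colSums(inv)
      out$pit <- if (fam == "nmm_arcsinh") pit_lt else
        pmin(pit_lt + 0.5 * cpo, 1)
    }
  }
  out$flag <- !is.finite(out$cpo) | out$rel_se > flag_threshold
  out
}

#' Exact leave-one-out CPO by single-case refit
#'
#' Removes observation `index` from the likelihood, refits the model, and
#' evaluates the posterior predictive mass (density for the NMM) at the
#' observed value: the Monte Carlo average over refit draws of
#' \eqn{f(y_{ij} | \theta_s)}, which is exact in the limit of many draws
#' because the refit posterior no longer depends on \eqn{y_{ij}}. Intended for
#' desk-scale data and as the fallback for observations flagged by
#' [ghost_cpo()].
#'
#' @param spec a [model_spec()].
#' @param data a [long_count_data()].
#' @param index row index of the observation to leave out.
#' @param control an [mcmc_control()].
#' @param want_pit also return the adjusted PIT for the left-out observation.
#' @return A list with `cpo`, optionally `pit`, and the refit `fit`.
#' @export
exact_refit_cpo <- function(spec, data, index, control = mcmc_control(),
                            want_pit = FALSE) {
  stopifnot(index >= 1, index <= nrow(data))
  fit <- fit_mcmc(spec, data, control, exclude = index)
  cpo <- mean(exp(fit$loglik[, index]))
  out <- list(cpo = cpo, fit = fit)
  if (want_pit) {
    Flt <- draw_cdf_lt(fit)[, index]
    out$pit <- if (spec$family == "nmm_arcsinh") mean(Flt) else
      min(mean(Flt) + 0.5 * cpo, 1)
  }
  out
}

#' Leave-one-out predictive pmf over a count grid
#'
#' For a fit with one observation excluded, returns the posterior predictive
#' mass function of that observation over `0:ymax` (the mean over draws of the
#' family pmf at each grid value). Useful for checking that the leave-one-out
#' predictive is a proper distribution.
#'
#' @param fit a [posterior_fit()][fit_mcmc] created with `exclude = index`.
#' @param index the excluded row index.
#' @param ymax upper end of the count grid.
#' @return Numeric vector of length `ymax + 1` of predictive masses.
#' @export
loo_predictive_pmf <- function(fit, index, ymax = 100) {
  stopifnot(!is.null(fit$exclude), fit$exclude == index,
            fit$spec$family != "nmm_arcsinh")
  eta <- draw_eta(fit)[, index]
  mu <- exp(eta)
  fam <- fit$spec$family
  vapply(0:ymax, function(yv) {
    pm <- switch(fam,
      poisson = stats::dpois(yv, mu),
      nb = stats::dnbinom(yv, size = fit$draws$k, mu = mu),
      zip = (yv == 0) * fit$draws$pi0 +
        (1 - fit$draws$pi0) * stats::dpois(yv, mu),
      zinb = (yv == 0) * fit$draws$pi0 +
        (1 - fit$draws$pi0) * stats::dnbinom(yv, size = fit$draws$k, mu = mu))
    mean(pm)
  }, 0)
}
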