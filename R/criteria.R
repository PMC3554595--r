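#' Deviance information criterion
#'
#' Computes the posterior mean deviance \eqn{\bar D}, the plug-in deviance
#' \eqn{D(\bar\theta)} (posterior means of all latent quantities, including
#' random effects), the effective number of parameters
#' \eqn{p_D = \bar D - D(\bar\theta)}, and
#' \eqn{DIC = \bar D + p_D = 2\bar D - D(\bar\theta) = D(\bar\theta) + 2 p_D}.
#' The standardizing term of the deviance is fixed to zero, so only DIC
#' *differences* across models fitted to the same data are meaningful.
#'
#' @param fit a [posterior_fit()][fit_mcmc].
#' @return Named list with `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
compute_dic <- function(fit) {
  keep <- rep(TRUE, ncol(fit$loglik))
  if (!is.null(fit$exclude)) keep[fit$exclude] <- FALSE
  Dbar <- mean(-2 * rowSums(fit$loglik[, keep, drop = FALSE]))
  Dhat <- plug_in_deviance(fit)
  pD <- Dbar - Dhat
  list(Dbar = Dbar, Dhat = Dhat, pD = pD, DIC = Dbar + pD)
}

#' Logarithmic scores from CPO values
#'
#' The logarithmic score of an observation is \eqn{LS_{ij} = -\log CPO_{ij}};
#' models are ranked by the unweighted mean score over all observations
#' (lower is better). A zero CPO yields an infinite score, reported as such.
#'
#' @param cpo per-observation CPO values.
#' @return List with per-observation `ls` and `mean_ls`.
#' @export
compute_log_scores <- function(cpo) {
  if (any(cpo < 0, na.rm = TRUE)) stop("CPO values must be non-negative")
  ls <- -log(cpo)
  list(ls = ls, mean_ls = mean(ls))
}

#' Leave-one-out probability integral transform
#'
#' For count families, the non-randomized adjusted PIT
#' \eqn{PIT_{ij} = \Pr(y^{new} < y_{ij} | y_{-ij}) + 0.5 \Pr(y^{new} = y_{ij}
#' | y_{-ij})}; for the continuous arcsinh NMM, the plain
#' \eqn{\Pr(y^{new} \le y_{ij} | y_{-ij})}. Computed from the same
#' leave-one-out predictive machinery as the CPO ([ghost_cpo()]). Under a
#' well-calibrated model the pooled values are approximately uniform on
#' [0, 1].
#'
#' @inheritParams ghost_cpo
#' @return A `data.frame` with columns `pit`, `cpo`, `rel_se`, `flag`.
#' @export
compute_pit <- function(fit, ghost = TRUE, M = 20, flag_threshold = 0.2) {
  out <- ghost_cpo(fit, ghost = ghost, M = M, want_pit = TRUE,
                   flag_threshold = flag_threshold)
  out[, c("pit", "cpo", "rel_se", "flag")]
}

#' PIT histogram data
#'
#' Bins PIT values into `n_bins` equal-width bins on [0, 1] (half-open
#' `[l, u)`, with the final bin closed so that a PIT of exactly 1 lands in
#' it) and returns relative frequencies together with the reference height
#' `1/n_bins` corresponding to perfect calibration.
#'
#' @param pit PIT values in [0, 1].
#' @param n_bins number of bins (at least 2; default 10).
#' @return List with `breaks`, `freq` (summing to 1), and `reference`.
#' @export
pit_histogram <- function(pit, n_bins = 10) {
  stopifnot(n_bins >= 2, all(pit >= 0 & pit <= 1))
  br <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(findInterval(pit, br, rightmost.closed = TRUE), n_bins)
  freq <- tabulate(idx, nbins = n_bins) / length(pit)
  list(breaks = br, freq = freq, reference = 1 / n_bins)
}

#' Back-transform an arcsinh-scale mean log score to the count scale
#'
#' Scores of the arcsinh NMM are densities on the transformed scale. By the
#' change of variables \eqn{z = g(y) = \mathrm{arcsinh}(y)}, the mean log
#' score on the original scale equals the transformed-scale mean minus the
#' sample mean of \eqn{\log g'(y)} with \eqn{g'(y) = 1/\sqrt{1+y^2}}:
#' the correction adds \eqn{\frac{1}{n}\sum \log\sqrt{1+y_{ij}^2}}. Only the
#' *mean* score can be moved between scales, not individual observation-level
#' scores, which is why permutation tests against count-family models are not
#' applicable for the NMM.
#'
#' @param mean_ls_arcsinh mean logarithmic score computed on the arcsinh
#'   scale.
#' @param y the original (untransformed) counts.
#' @return Mean log score comparable to count-scale models.
#' @export
backtransform_mean_ls <- function(mean_ls_arcsinh, y) {
  mean_ls_arcsinh + mean(0.5 * log1p(y^2))
}

#' Full predictive assessment of one fitted model
#'
#' Bundles the per-observation CPO, logarithmic scores, optional adjusted
#' PIT, reliability flags, DIC components, and the mean log score. For the
#' arcsinh NMM the observation-level scores are on the transformed scale and
#' only `mean_ls_comparable` (back-transformed via [backtransform_mean_ls()])
#' can be compared with count-family models; its DIC is likewise marked
#' non-comparable.
#'
#' @param fit a [posterior_fit()][fit_mcmc].
#' @param ghost,M,flag_threshold,draw_thin passed to [ghost_cpo()].
#' @param pit compute adjusted PIT values as well (default `FALSE`; they cost
#'   predictive-CDF evaluations).
#' @return An object of class `assessment`.
#' @export
assess <- function(fit, ghost = TRUE, M = 20, pit = FALSE,
                   flag_threshold = 0.2, draw_thin = 1) {
  cp <- ghost_cpo(fit, ghost = ghost, M = M, want_pit = pit,
                  flag_threshold = flag_threshold, draw_thin = draw_thin)
  sc <- compute_log_scores(cp$cpo)
  is_nmm <- fit$spec$family == "nmm_arcsinh"
  structure(list(
    model = model_label(fit$spec), spec = fit$spec,
    cpo = cp$cpo, ls = sc$ls, pit = if (pit) cp$pit else NULL,
    flags = cp$flag, rel_se = cp$rel_se,
    mean_ls = sc$mean_ls,
    mean_ls_comparable = if (is_nmm)
      backtransform_mean_ls(sc$mean_ls, fit$data$count) else sc$mean_ls,
    dic = compute_dic(fit),
    dic_comparable = !is_nmm,
    scale = if (is_nmm) "arcsinh_backtransformed" else "original",
    n_obs = length(cp$cpo), data_digest = data_digest(fit$data)),
    class = "assessment")
}

#' @export
print.assessment <- function(x, ...) {
  cat(sprintf("assessment of %s: mean LS = %.4f%s, DIC = %.1f%s, %d flagged\n",
              x$model, x$mean_ls_comparable,
              if (x$scale != "original") " (back-transformed)" else "",
              x$dic$DIC, if (!x$dic_comparable) " (not comparable)" else "",
              sum(x$flags)))
  invisible(x)
}

# cheap fingerprint to refuse cross-dataset comparisons
data_digest <- function(data) {
  c(n = nrow(data), sum_y = sum(data$count), sum_t = sum(data$time),
    sum_g = sum(data$group))
}
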