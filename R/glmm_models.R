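#' Prior specification for a Bayesian count GLMM
#'
#' Fixed effects get independent zero-mean Gaussian priors with a fixed small
#' precision. For the random-intercept-only structure the intercept precision
#' \eqn{\sigma_b^{-2}} gets a Gamma(a, b) prior; integrating it out gives a
#' marginal Student-t for the intercept, which is how [derive_gamma_prior()]
#' turns a plausible 95% range into (a, b). For the correlated
#' intercept-plus-slope structure the 2x2 precision matrix Q gets a
#' Wishart(r, R^-1) hyperprior (r > 1 for propriety). The NB size k gets a
#' diffuse Gamma prior (nearly flat on log k), the zero-inflation probability
#' a Beta prior (default uniform), and the NMM residual precision a diffuse
#' Gamma prior.
#'
#' @param beta_precision prior precision of each fixed effect (default 0.001).
#' @param intercept_prec_shape,intercept_prec_rate Gamma(a, b) on the random
#'   intercept precision; defaults are the values implied by a 95% intercept
#'   range of [-0.6, 0.6] with a = 0.5 (marginal Cauchy).
#' @param wishart_r,wishart_R Wishart degrees of freedom (> 1) and 2x2 scale
#'   matrix R for the intercept+slope precision matrix.
#' @param k_shape,k_rate diffuse Gamma prior on the NB size k.
#' @param pi0_shape1,pi0_shape2 Beta prior on the zero-inflation probability.
#' @param resid_prec_shape,resid_prec_rate Gamma prior on the NMM residual
#'   precision.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(beta_precision = 0.001,
                       intercept_prec_shape = 0.5,
                       intercept_prec_rate = derive_gamma_prior(0.6, 0.5)["b"],
                       wishart_r = 4, wishart_R = diag(2),
                       k_shape = 0.01, k_rate = 0.01,
                       pi0_shape1 = 1, pi0_shape2 = 1,
                       resid_prec_shape = 0.01, resid_prec_rate = 0.01) {
  stopifnot(beta_precision > 0, intercept_prec_shape > 0,
            intercept_prec_rate > 0, wishart_r > 1,
            isSymmetric(unname(wishart_R)), all(eigen(wishart_R)$values > 0),
            k_shape > 0, k_rate > 0, pi0_shape1 > 0, pi0_shape2 > 0)
  structure(list(beta_precision = beta_precision,
                 intercept_prec_shape = intercept_prec_shape,
                 intercept_prec_rate = unname(intercept_prec_rate),
                 wishart_r = wishart_r, wishart_R = wishart_R,
                 k_shape = k_shape, k_rate = k_rate,
                 pi0_shape1 = pi0_shape1, pi0_shape2 = pi0_shape2,
                 resid_prec_shape = resid_prec_shape,
                 resid_prec_rate = resid_prec_rate),
            class = "prior_spec")
}

#' Candidate model specification
#'
#' One candidate GLMM is a response family, a random-effects structure, and a
#' fixed-effects formula. Families: `"poisson"`, `"nb"` (negative binomial,
#' mean mu and size k), `"zip"`/`"zinb"` (zero-inflated mixtures with
#' structural-zero probability pi0), and `"nmm_arcsinh"` (normal mixed model on
#' the arcsinh-transformed response). Random structures: `"I"` (subject
#' intercepts only) and `"IS"` (correlated subject intercepts and slopes).
#' Fixed formulas: `"main_interaction"` (intercept, time, group, group x time)
#' and `"pre_study"` (no group main effect, appropriate when groups share a
#' common baseline by design).
#'
#' @param family response family (see Details).
#' @param random_structure `"I"` or `"IS"`.
#' @param fixed_formula `"pre_study"` (default) or `"main_interaction"`.
#' @param priors a [prior_spec()].
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("poisson", "nb", "zip", "zinb", "nmm_arcsinh"),
                       random_structure = c("I", "IS"),
                       fixed_formula = c("pre_study", "main_interaction"),
                       priors = prior_spec()) {
  family <- match.arg(family)
  random_structure <- match.arg(random_structure)
  fixed_formula <- match.arg(fixed_formula)
  stopifnot(inherits(priors, "prior_spec"))
  structure(list(family = family, random_structure = random_structure,
                 fixed_formula = fixed_formula, priors = priors),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %s (%s), fixed formula '%s'\n",
              x$family, x$random_structure, x$fixed_formula))
  invisible(x)
}

model_label <- function(spec) sprintf("%s(%s)", spec$family, spec$random_structure)

# Fixed-effect design matrix for a model_spec.
fixed_design <- function(spec, data) {
  t <- data$time; x <- data$group
  if (spec$fixed_formula == "main_interaction")
    cbind(intercept = 1, time = t, group = x, group_time = x * t)
  else
    cbind(intercept = 1, time = t, group_time = x * t)
}

#' Linear predictor of a candidate GLMM
#'
#' Computes \eqn{\eta_{ij} = (\beta_0+b_{0i}) + (\beta_1+b_{1i}) t_{ij} +
#' \beta_2 x_i + \beta_3 x_i t_{ij}} per observation, dropping the terms
#' absent from the model: the `"pre_study"` formula has no group main effect
#' \eqn{\beta_2 x_i}, and the `"I"` structure has no random slope
#' \eqn{b_{1i}}.
#'
#' @param state a named list with `beta` (length matching the fixed formula),
#'   `b0` (per-subject intercepts) and, for `"IS"`, `b1` (per-subject slopes).
#' @param data a [long_count_data()].
#' @param spec a [model_spec()].
#' @return Numeric vector of linear-predictor values, one per row of `data`.
#' @export
linear_predictor <- function(state, data, spec) {
  X <- fixed_design(spec, data)
  if (length(state$beta) != ncol(X))
    stop("beta has length ", length(state$beta), ", expected ", ncol(X))
  subj <- match(data$subject_id, sort(unique(data$subject_id)))
  nsub <- max(subj)
  if (length(state$b0) != nsub)
    stop("b0 has length ", length(state$b0), ", expected ", nsub)
  eta <- drop(X %*% state$beta) + state$b0[subj]
  if (spec$random_structure == "IS") {
    if (length(state$b1) != nsub)
      stop("b1 has length ", length(state$b1), ", expected ", nsub)
    eta <- eta + state$b1[subj] * data$time
  }
  eta
}

#' Per-observation log-likelihood
#'
#' Log density/mass of one observation given the linear predictor. Count
#' families use the log link, \eqn{\mu = e^\eta}: Poisson
#' \eqn{e^{-\mu}\mu^y/y!}; NB with size k parameterized so that the mean is
#' \eqn{\mu} (success probability \eqn{p = k/(k+\mu)}, variance
#' \eqn{\mu + \mu^2/k}); ZIP/ZINB the structural-zero mixture
#' \eqn{\pi_0 I[y=0] + (1-\pi_0) f_D(y)}. The arcsinh NMM is Gaussian on the
#' transformed scale: `y` must already be arcsinh-transformed and the value is
#' a log *density* on that scale.
#'
#' @param state named list carrying the needed parameters: `k` for nb/zinb,
#'   `pi0` for zip/zinb, `sigma_eps` for the NMM.
#' @param y observed value(s): non-negative integers for count families, reals
#'   (arcsinh scale) for the NMM.
#' @param eta linear predictor value(s), recycled against `y`.
#' @param spec a [model_spec()] (only `family` is used).
#' @return Log-likelihood value(s).
#' @export
loglik_obs <- function(state, y, eta, spec) {
  fam <- spec$family
  if (fam != "nmm_arcsinh" && any(y < 0 | y != round(y)))
    stop("count families require non-negative integer y")
  mu <- exp(eta)
  switch(fam,
    poisson = stats::dpois(y, mu, log = TRUE),
    nb = stats::dnbinom(y, size = state$k, mu = mu, log = TRUE),
    zip = dzi(y, stats::dpois(y, mu), state$pi0),
    zinb = dzi(y, stats::dnbinom(y, size = state$k, mu = mu), state$pi0),
    nmm_arcsinh = stats::dnorm(y, eta, state$sigma_eps, log = TRUE))
}

# log of the zero-inflated mixture pmf given the base pmf values
dzi <- function(y, base_pmf, pi0) {
  log(ifelse(y == 0, pi0 + (1 - pi0) * base_pmf, (1 - pi0) * base_pmf))
}

#' Inverse hyperbolic sine transform and its inverse
#'
#' \eqn{\mathrm{arcsinh}(y) = \log(y + \sqrt{y^2+1})}, a variance-stabilizing
#' transform for non-negative counts; the inverse is
#' \eqn{g^{-1}(z) = (e^z - e^{-z})/2}.
#'
#' @param y non-negative real value(s).
#' @param z real value(s) on the transformed scale.
#' @return Transformed values.
#' @export
arcsinh_transform <- function(y) {
  stopifnot(all(y >= 0))
  asinh(y)
}

#' @rdname arcsinh_transform
#' @export
arcsinh_inverse <- function(z) sinh(z)

#' Variance-stabilizing transform for negative binomial counts
#'
#' Closed form of \eqn{T(y) = \int_0^y v(u)^{-1/2} du} with the NB variance
#' function \eqn{v(u) = u(zu+1)}, where \eqn{z = 1/k} is the overdispersion:
#' \eqn{T(y) = (2/\sqrt{z})\,\mathrm{arcsinh}(\sqrt{zy})}. At \eqn{z = 0} this
#' reduces to the Poisson stabilizer \eqn{2\sqrt{y}}.
#'
#' @param y non-negative count value(s).
#' @param z overdispersion \eqn{1/k \ge 0}.
#' @return Transformed value(s).
#' @export
vst_negbin <- function(y, z) {
  stopifnot(all(y >= 0))
  if (z < 0) stop("overdispersion z must be non-negative")
  if (z < 1e-12) return(2 * sqrt(y))
  2 / sqrt(z) * asinh(sqrt(z * y))
}

#' Derive a Gamma prior on a random-effect precision from a 95% range
#'
#' With precision \eqn{\tau \sim} Gamma(a, b) and effect \eqn{u|\tau \sim
#' N(0, 1/\tau)}, the marginal of \eqn{u} is Student-t with 2a degrees of
#' freedom and scale \eqn{\sqrt{b/a}}. Given a plausible symmetric 95% range
#' \eqn{[-q, q]} for the effect, the rate solving
#' \eqn{t_{0.975, 2a}\sqrt{b/a} = q} is \eqn{b = a (q / t_{0.975, 2a})^2}.
#' With a = 0.5 the marginal is Cauchy; q = 0.6 then gives b = 0.001115 and
#' marginal scale b/a = 0.00223.
#'
#' @param range95 half-width q of the marginal 95% range.
#' @param a Gamma shape.
#' @return Named vector `c(a, b)`.
#' @export
#' @examples
#' derive_gamma_prior(0.6, 0.5)
derive_gamma_prior <- function(range95, a = 0.5) {
  stopifnot(range95 > 0, a > 0)
  tq <- stats::qt(0.975, df = 2 * a)
  c(a = a, b = a * (range95 / tq)^2)
}
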