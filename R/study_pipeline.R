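# End-to-end studies: the simulation of discriminatory power across an
# (overdispersion k) x (group size n) grid, and the pilot-data case-study
# workflow (fit a menu of candidate models, assess, rank, recommend).

# Replicate seeds are derived by hashing (master seed, k, n, replicate), so a
# grid subset re-creates the identical datasets and all candidate models see
# the same data within a replicate (the paired design the AUC assumes).
scenario_seed <- function(master_seed, k, n, rep) {
  substream_seed(substream_seed(master_seed, round(1000 * k)),
                 n * 100003 + rep)
}

#' Simulation scenario grid
#'
#' @param n_values subjects per group (default 20, 50, 100).
#' @param k_values NB overdispersion values (default 0.5, 1, 5, 10, 20, 50;
#'   the default grid has 18 scenarios).
#' @param r replicates per scenario (100 for the full study; smaller values
#'   give a scaled-down replication and are recorded as such).
#' @param models candidate model families fitted to every replicate.
#' @param master_seed integer seed from which all replicate seeds derive.
#' @return List of class `scenario_grid`.
#' @export
scenario_grid <- function(n_values = c(20, 50, 100),
                          k_values = c(0.5, 1, 5, 10, 20, 50), r = 100,
                          models = c("nb", "poisson", "zip", "zinb",
                                     "nmm_arcsinh"),
                          master_seed = 1L) {
  stopifnot(r >= 2, length(n_values) >= 1, length(k_values) >= 1)
  structure(list(n_values = n_values, k_values = k_values, r = as.integer(r),
                 models = models, master_seed = as.integer(master_seed)),
            class = "scenario_grid")
}

# Candidate model menu for the simulation study: intercept-only structures
# matching the random-intercept DGP, no group main effect (groups share a
# baseline by design), and the Ga(0.5, 0.001115) intercept-precision prior
# derived from a 95% random-intercept range of [-0.6, 0.6].
sim_model_spec <- function(family) {
  model_spec(family = family, random_structure = "I",
             fixed_formula = "pre_study", priors = prior_spec())
}

#' Run one simulation scenario
#'
#' For each of `r` replicates: simulate NB random-intercept data with the
#' given overdispersion `k` and group size `n` ([dgp_config()] defaults:
#' alpha = 3, sigma_a = 0.3, slopes -0.3 / -0.5, four visits at t = 0..3),
#' fit every candidate model (random intercepts only, matching the DGP),
#' and record per-replicate mean logarithmic scores (the arcsinh NMM's mean
#' back-transformed to the count scale) and DICs. AUC summaries of each wrong
#' model against the true NB model follow from the per-replicate scores.
#' Replicate failures are recorded and excluded, never silent.
#'
#' @param n subjects per group.
#' @param k NB overdispersion of the data-generating process.
#' @param r number of replicates.
#' @param models character vector of candidate families; include `"nb"` to
#'   obtain AUC summaries against the true model.
#' @param seed master seed.
#' @param control [mcmc_control()] for the per-replicate fits (its `seed` is
#'   overridden per fit).
#' @param ghost,M CPO estimator settings, see [ghost_cpo()].
#' @return List of class `scenario_result`: matrices `mean_ls` and `dic`
#'   (replicates x models), `auc` (list of [auc_discrimination()] results per
#'   wrong model), `failures`, and provenance.
#' @export
run_scenario <- function(n, k, r = 30,
                         models = c("nb", "poisson", "zip", "zinb",
                                    "nmm_arcsinh"),
                         seed = 1L,
                         control = mcmc_control(chains = 2, iter = 1500),
                         ghost = FALSE, M = 20, draw_thin = 3) {
  mean_ls <- dic <- matrix(NA_real_, r, length(models),
                           dimnames = list(NULL, models))
  failures <- character(0)
  for (rep in seq_len(r)) {
    rs <- scenario_seed(seed, k, n, rep)
    dat <- generate_nb_longitudinal(
      dgp_config(k = k, n_per_group = n, family = "nb", seed = rs))
    for (mi in seq_along(models)) {
      ctl <- control
      ctl$seed <- substream_seed(rs, mi)
      res <- tryCatch({
        fit <- suppressWarnings(
          fit_mcmc(sim_model_spec(models[mi]), dat, ctl))
        a <- assess(fit, ghost = ghost, M = M, draw_thin = draw_thin)
        c(a$mean_ls_comparable, a$dic$DIC)
      }, error = function(e) {
        failures <<- c(failures,
                       sprintf("rep %d model %s: %s", rep, models[mi],
                               conditionMessage(e)))
        c(NA_real_, NA_real_)
      })
      mean_ls[rep, mi] <- res[1]
      dic[rep, mi] <- res[2]
    }
  }
  auc <- list()
  if ("nb" %in% models) {
    ok <- stats::complete.cases(mean_ls)
    for (m in setdiff(models, "nb"))
      auc[[m]] <- auc_discrimination(mean_ls[ok, m], mean_ls[ok, "nb"])
  }
  structure(list(n = n, k = k, r = r, models = models, mean_ls = mean_ls,
                 dic = dic, auc = auc, failures = failures, seed = seed,
                 control = control),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario n=%d per group, k=%g, r=%d (%d failures)\n",
              x$n, x$k, x$r, length(x$failures)))
  if (length(x$auc))
    for (m in names(x$auc))
      cat(sprintf("  AUC(%s vs nb) = %.3f\n", m, x$auc[[m]]$auc))
  invisible(x)
}

#' Run the full simulation study over a scenario grid
#'
#' Executes [run_scenario()] for every (k, n) cell of the grid and assembles
#' an AUC matrix (rows: k x wrong model; columns: n) plus per-scenario
#' summaries of the DIC and mean-log-score distributions. Partial grids give
#' partial outputs.
#'
#' @param grid a [scenario_grid()].
#' @param control,ghost,M,draw_thin as in [run_scenario()].
#' @return List of class `study_result` with `scenarios` (named list of
#'   [run_scenario()] results), `auc_table` (long-format data frame), and
#'   `summary` (median mean-LS and DIC per scenario and model).
#' @export
run_full_study <- function(grid = scenario_grid(),
                           control = mcmc_control(chains = 2, iter = 1500),
                           ghost = FALSE, M = 20, draw_thin = 3) {
  scenarios <- list()
  auc_rows <- list()
  summ_rows <- list()
  for (k in grid$k_values) for (n in grid$n_values) {
    key <- sprintf("k%g_n%d", k, n)
    sc <- run_scenario(n, k, grid$r, grid$models, grid$master_seed, control,
                       ghost = ghost, M = M, draw_thin = draw_thin)
    scenarios[[key]] <- sc
    for (m in names(sc$auc))
      auc_rows[[length(auc_rows) + 1]] <-
        data.frame(k = k, model = m, n = n, auc = sc$auc[[m]]$auc)
    for (m in sc$models)
      summ_rows[[length(summ_rows) + 1]] <- data.frame(
        k = k, n = n, model = m,
        median_mean_ls = stats::median(sc$mean_ls[, m], na.rm = TRUE),
        iqr_mean_ls = stats::IQR(sc$mean_ls[, m], na.rm = TRUE),
        median_dic = stats::median(sc$dic[, m], na.rm = TRUE),
        iqr_dic = stats::IQR(sc$dic[, m], na.rm = TRUE))
  }
  structure(list(grid = grid, scenarios = scenarios,
                 auc_table = do.call(rbind, auc_rows),
                 summary = do.call(rbind, summ_rows)),
            class = "study_result")
}

#' Case-study workflow on pilot data
#'
#' Fits a menu of candidate models to one longitudinal count dataset,
#' assesses each (CPO / log score / PIT / DIC), ranks them, and runs paired
#' permutation tests of every count-family model against the best
#' (lowest-mean-LS) count-family model. Models for the arcsinh-transformed
#' outcome are ranked by their back-transformed mean score but get no
#' permutation test (observation-level scores live on a different scale);
#' their p-value is reported as `NA`.
#'
#' @param data a [long_count_data()].
#' @param menu list of [model_spec()]s (at least 2).
#' @param control an [mcmc_control()]; per-model seeds derive from its seed.
#' @param n_perm permutations for the pairwise tests.
#' @param ghost,M CPO estimator settings.
#' @return List of class `case_study`: `ranking` (from [rank_models()] plus a
#'   p-value column), `posterior_summary` (fixed-effect means and 95%
#'   credible intervals per model), `pit` (named list of [pit_histogram()]
#'   data), `assessments`, and `recommendation` (best model and the models
#'   statistically indistinguishable from it at the 5% level).
#' @export
run_case_study <- function(data, menu, control = mcmc_control(),
                           n_perm = 9999, ghost = TRUE, M = 20) {
  stopifnot(length(menu) >= 2)
  labels <- vapply(menu, model_label, "")
  fits <- assessments <- vector("list", length(menu))
  names(fits) <- names(assessments) <- labels
  post_rows <- list()
  for (i in seq_along(menu)) {
    ctl <- control
    ctl$seed <- substream_seed(control$seed, i)
    fits[[i]] <- suppressWarnings(fit_mcmc(menu[[i]], data, ctl))
    assessments[[i]] <- assess(fits[[i]], ghost = ghost, M = M, pit = TRUE)
    bd <- fits[[i]]$draws$beta
    post_rows[[i]] <- data.frame(
      model = labels[i], parameter = colnames(bd),
      mean = colMeans(bd),
      q2.5 = apply(bd, 2, stats::quantile, 0.025),
      q97.5 = apply(bd, 2, stats::quantile, 0.975), row.names = NULL)
  }
  ranking <- rank_models(assessments)

  count_models <- ranking$model[
    vapply(ranking$model, function(m)
      assessments[[m]]$spec$family != "nmm_arcsinh", TRUE)]
  ref <- count_models[1]
  pvals <- setNames(rep(NA_real_, nrow(ranking)), ranking$model)
  for (m in count_models) {
    if (m == ref) next
    pt <- permutation_test_paired_ls(
      assessments[[m]]$ls, assessments[[ref]]$ls, n_perm = n_perm,
      seed = substream_seed(control$seed, 7777 + match(m, ranking$model)))
    pvals[m] <- pt$p_value
  }
  ranking$p_vs_best <- ifelse(ranking$model == ref, NA, pvals[ranking$model])

  indist <- count_models[
    count_models != ref & !is.na(pvals[count_models]) &
      pvals[count_models] > 0.05]
  recommendation <- list(
    best = ref,
    indistinguishable = indist,
    text = paste0(
      sprintf("Best predictive model by mean logarithmic score: %s.", ref),
      if (length(indist))
        sprintf(" Statistically indistinguishable at the 5%% level: %s.",
                paste(indist, collapse = ", "))
      else " All other count-family models scored significantly worse."))

  pits <- lapply(assessments, function(a) pit_histogram(a$pit))
  structure(list(ranking = ranking,
                 posterior_summary = do.call(rbind, post_rows),
                 pit = pits, assessments = assessments,
                 recommendation = recommendation),
            class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  print(x$ranking, digits = 4)
  cat("\n", x$recommendation$text, "\n", sep = "")
  invisible(x)
}
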