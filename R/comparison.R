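#' Paired Monte Carlo permutation test for mean score differences
#'
#' Tests whether the mean logarithmic scores of two rival models differ, using
#' the paired observation-level scores. The test statistic is the difference
#' of means (model A minus model B); the null distribution is generated by
#' independent random sign flips of the paired differences, which is the exact
#' permutation group for paired data. The two-sided Monte Carlo p-value uses
#' the add-one convention (the identity permutation counts in numerator and
#' denominator), so `p` is never exactly 0 and `ls_a == ls_b` gives `p = 1`.
#'
#' Scores within a subject may be correlated; `block` (a subject id per score)
#' switches to flipping whole subjects jointly.
#'
#' @param ls_a,ls_b per-observation log scores of the two models, aligned on
#'   identical observations.
#' @param n_perm number of random permutations (default 9999).
#' @param seed integer seed.
#' @param block optional grouping vector for block-wise sign flips.
#' @return List of class `permutation_test` with `observed_diff`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
permutation_test_paired_ls <- function(ls_a, ls_b, n_perm = 9999, seed = 1L,
                                       block = NULL) {
  if (length(ls_a) != length(ls_b))
    stop("score vectors must have equal length (paired observations)")
  d <- ls_a - ls_b
  obs <- mean(d)
  set.seed(seed)
  if (is.null(block)) {
    n <- length(d)
    null_stats <- vapply(seq_len(n_perm), function(r)
      mean(d * sample(c(-1, 1), n, replace = TRUE)), 0)
  } else {
    ub <- unique(block)
    bi <- match(block, ub)
    null_stats <- vapply(seq_len(n_perm), function(r)
      mean(d * sample(c(-1, 1), length(ub), replace = TRUE)[bi]), 0)
  }
  # two-sided by doubling the smaller tail, capped at 1; add-one correction
  lo <- (1 + sum(null_stats <= obs)) / (n_perm + 1)
  hi <- (1 + sum(null_stats >= obs)) / (n_perm + 1)
  structure(list(observed_diff = obs, p_value = min(1, 2 * min(lo, hi)),
                 n_perm = n_perm, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("paired permutation test: diff = %.4f, p = %.4f (%d perms)\n",
              x$observed_diff, x$p_value, x$n_perm))
  invisible(x)
}

#' AUC for score separation between a wrong and the true model
#'
#' Probability that a randomly chosen replicate mean log score of the wrong
#' model exceeds that of the true model across all cross pairs, with half
#' credit for ties (the rank-sum statistic divided by the number of pairs).
#' 1 means the mean score discriminates perfectly; 0.5 means random
#' discrimination — in particular, two identical score distributions give
#' exactly 0.5 under the tie rule.
#'
#' @param mean_ls_wrong,mean_ls_true per-replicate mean log scores.
#' @return List of class `auc_result` with `auc`, `n_wrong`, `n_true`,
#'   `tie_count`.
#' @export
auc_discrimination <- function(mean_ls_wrong, mean_ls_true) {
  stopifnot(length(mean_ls_wrong) > 0, length(mean_ls_true) > 0)
  r <- rank(c(mean_ls_wrong, mean_ls_true))
  nw <- length(mean_ls_wrong); nt <- length(mean_ls_true)
  U <- sum(r[seq_len(nw)]) - nw * (nw + 1) / 2
  ties <- sum(outer(mean_ls_wrong, mean_ls_true, `==`))
  structure(list(auc = U / (nw * nt), n_wrong = nw, n_true = nt,
                 tie_count = ties),
            class = "auc_result")
}

#' Rank candidate models by predictive criteria
#'
#' Orders a set of [assess()]ments of the same dataset by mean logarithmic
#' score (ascending; back-transformed for the arcsinh NMM so all models are
#' on the count scale) and tabulates DIC alongside. The NMM's DIC is masked
#' (`NA`) because a transformed-outcome deviance is not comparable to
#' count-scale deviances. `delta_DIC` differences of 3-5 are conventionally
#' the smallest noteworthy ones; the `noteworthy` column marks differences
#' above 5, with `"borderline"` for 3-5.
#'
#' @param assessments list of `assessment` objects on the same data.
#' @return A `data.frame`, one row per model, ordered by mean LS.
#' @export
rank_models <- function(assessments) {
  stopifnot(length(assessments) >= 2,
            all(vapply(assessments, inherits, TRUE, "assessment")))
  dg <- lapply(assessments, `[[`, "data_digest")
  if (!all(vapply(dg, identical, TRUE, dg[[1]])))
    stop("assessments were computed on different datasets")
  tab <- data.frame(
    model = vapply(assessments, `[[`, "", "model"),
    Dbar = vapply(assessments, function(a) a$dic$Dbar, 0),
    Dhat = vapply(assessments, function(a) a$dic$Dhat, 0),
    pD = vapply(assessments, function(a) a$dic$pD, 0),
    DIC = vapply(assessments, function(a)
      if (a$dic_comparable) a$dic$DIC else NA_real_, 0),
    mean_ls = vapply(assessments, `[[`, 0, "mean_ls_comparable"))
  tab <- tab[order(tab$mean_ls), ]
  tab$delta_ls <- tab$mean_ls - tab$mean_ls[1]
  best_dic <- min(tab$DIC, na.rm = TRUE)
  tab$delta_DIC <- tab$DIC - best_dic
  tab$noteworthy <- ifelse(is.na(tab$delta_DIC), NA,
                           ifelse(tab$delta_DIC > 5, "yes",
                                  ifelse(tab$delta_DIC >= 3, "borderline",
                                         "no")))
  rownames(tab) <- NULL
  tab
}
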