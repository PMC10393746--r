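# Supervised analysis: outcome dichotomization, random-forest
# classification with out-of-bag AUC, (joint) permutation variable
# importance with outcome-direction signs, and Kaplan-Meier/log-rank
# survival comparisons.

#' Dichotomize survival into poor/good outcome at a cutoff
#'
#' Event before the cutoff is poor outcome; event-free follow-up reaching
#' the cutoff is good; patients censored before the cutoff are excluded
#' (`NA`), since their class is undetermined.
#'
#' @param records Data frame with `patient_id`, `time_months`, `event`
#'   (1 = event, 0 = censored).
#' @param cutoff Months (default 12).
#' @return Factor with levels `good`, `poor`, named by patient; `NA` for
#'   excluded patients.
#' @export
dichotomize_outcome <- function(records, cutoff = 12) {
  if (cutoff <= 0) stop_("cutoff must be positive")
  if (any(records$time_months <= 0))
    stop_("non-positive survival time(s)")
  lab <- ifelse(records$event == 1 & records$time_months < cutoff, "poor",
         ifelse(records$time_months >= cutoff, "good", NA))
  n_excl <- sum(is.na(lab))
  if (n_excl > 0)
    message(sprintf("%d patient(s) censored before %g months excluded",
                    n_excl, cutoff))
  setNames(factor(lab, levels = c("good", "poor")), records$patient_id)
}

# rank-based AUC with midranks for ties; positive class = 1
.auc_rank <- function(prob, y) {
  ok <- !is.na(prob)
  prob <- prob[ok]; y <- y[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random-forest classification with out-of-bag evaluation
#'
#' Binary classification by a bagged forest of CART trees (gini splits,
#' bootstrap sampling with replacement, `mtry` candidate features per
#' node, grown to purity). Predictive performance is the AUC of the
#' out-of-bag class probabilities (midrank statistic), so no patient's
#' prediction ever uses a tree that sampled that patient.
#'
#' @param mat Patient x feature matrix, no missing values.
#' @param labels Factor of two levels aligned with `rownames(mat)` (the
#'   second level is the positive class); `NA` labels are dropped.
#' @param n_trees Number of trees (default 100000; a few thousand suffice
#'   at cohort sizes of ~100).
#' @param mtry Features tried per split, default `floor(sqrt(p))`.
#' @param node_size Minimum node size (default 1: grow to purity).
#' @param seed Seed.
#' @return Object of class `tme_rf`: `oob_prob` (per patient), `auc`,
#'   `labels`, `fit` (internal forest), `settings`.
#' @export
rf_oob_classify <- function(mat, labels, n_trees = 100000,
                            mtry = NULL, node_size = 1, seed = NULL) {
  labels <- labels[rownames(mat)]
  keep <- !is.na(labels)
  mat <- mat[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  if (nlevels(labels) != 2L)
    stop_("need exactly 2 classes present, got %d", nlevels(labels))
  y <- as.integer(labels == levels(labels)[2])
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(mat))))
  fit <- with_seed(seed,
    cpp_rf_fit(mat, y, as.integer(n_trees), as.integer(mtry),
               as.integer(node_size)))
  oob <- setNames(cpp_rf_prob(fit, mat, TRUE), rownames(mat))
  structure(list(
    oob_prob = oob, auc = .auc_rank(oob, y), labels = labels, y = y,
    positive = levels(labels)[2], mat = mat, fit = fit,
    settings = list(n_trees = n_trees, mtry = mtry,
                    node_size = node_size, seed = seed)),
    class = "tme_rf")
}

#' @export
print.tme_rf <- function(x, ...) {
  cat(sprintf("tme_rf: %d trees, mtry %d, %d patients, OOB AUC %.3f\n",
              x$settings$n_trees, x$settings$mtry, nrow(x$mat), x$auc))
  invisible(x)
}

#' Joint permutation importance of feature groups
#'
#' Importance of a feature group is the mean drop in out-of-bag AUC when
#' the group's columns are jointly permuted (one shared row permutation
#' per draw, preserving within-group dependence), averaged over `n_perm`
#' draws. Singleton groups give per-feature importance.
#'
#' @param rf A [rf_oob_classify()] result.
#' @param groups Named list: group name -> character vector of feature
#'   names (or column indices). Default: one singleton group per feature.
#' @param n_perm Permutation draws per group (default 10).
#' @param seed Seed.
#' @return Data frame `group`, `importance` (mean AUC drop), `se`.
#' @export
group_permutation_importance <- function(rf, groups = NULL, n_perm = 10,
                                         seed = NULL) {
  mat <- rf$mat
  groups <- groups %||% setNames(as.list(colnames(mat)), colnames(mat))
  if (any(lengths(groups) == 0L)) stop_("empty feature group")
  base_auc <- rf$auc
  with_seed(seed, {
    res <- lapply(names(groups), function(g) {
      cols <- groups[[g]]
      drops <- vapply(seq_len(n_perm), function(b) {
        perm <- sample.int(nrow(mat))
        pm <- mat
        pm[, cols] <- mat[perm, cols, drop = FALSE]
        base_auc - .auc_rank(cpp_rf_prob(rf$fit, pm, TRUE), rf$y)
      }, numeric(1))
      data.frame(group = g, importance = mean(drops),
                 se = sd(drops) / sqrt(n_perm), stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}

#' Attach outcome-direction signs to feature importances
#'
#' Sign is +1 when the feature's mean in poor-outcome patients exceeds its
#' mean in good-outcome patients, -1 when lower, 0 when equal; magnitude
#' is the permutation importance.
#'
#' @param mat Patient x feature matrix.
#' @param labels good/poor factor aligned with rows.
#' @param importance Named numeric importances (names = feature keys), or
#'   the data frame from [group_permutation_importance()] restricted to
#'   singleton groups.
#' @return Named numeric of signed importances.
#' @export
signed_feature_direction <- function(mat, labels, importance) {
  if (is.data.frame(importance))
    importance <- setNames(importance$importance, importance$group)
  labels <- labels[rownames(mat)]
  if (!all(c("good", "poor") %in% levels(labels)) ||
      !all(table(labels) > 0))
    stop_("both outcome classes must be present")
  feats <- names(importance)
  mp <- colMeans(mat[labels == "poor", feats, drop = FALSE])
  mg <- colMeans(mat[labels == "good", feats, drop = FALSE])
  sign(mp - mg) * abs(importance)
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' @param groups Group labels named by patient (factor or character).
#' @param records Survival data frame (`patient_id`, `time_months`,
#'   `event`).
#' @param times Optional time points (months) for the number-at-risk
#'   table.
#' @return List: `fit` (a [survival::survfit] object), `chisq`, `df`,
#'   `p_value`, and `at_risk` (data frame) when `times` is given.
#' @export
km_logrank <- function(groups, records, times = NULL) {
  g <- groups[records$patient_id]
  if (anyNA(g)) {
    records <- records[!is.na(g), , drop = FALSE]
    g <- g[!is.na(g)]
  }
  g <- droplevels(factor(g))
  if (nlevels(g) < 2L) stop_("need >= 2 non-empty groups")
  if (any(table(g) == 0L)) stop_("group with zero records")
  df_surv <- data.frame(time = records$time_months, event = records$event,
                        group = g)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = df_surv)
  df <- length(sd_$n) - 1L
  p <- pchisq(sd_$chisq, df, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = df_surv)
  out <- list(fit = fit, chisq = unname(sd_$chisq), df = df, p_value = p)
  if (!is.null(times)) {
    sm <- summary(fit, times = times, extend = TRUE)
    out$at_risk <- data.frame(group = sm$strata, time = sm$time,
                              n_risk = sm$n.risk)
  }
  out
}
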