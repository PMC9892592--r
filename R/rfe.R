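#' Pre-filter daily features by missingness and variance
#'
#' Drops feature columns whose missing fraction exceeds `max_missing_frac`
#' (imputation of mostly-missing columns would inject bias) or whose variance
#' over observed values falls below `min_variance` (no information content).
#'
#' @param X data.frame/matrix of candidate feature columns.
#' @param max_missing_frac maximum tolerated missing fraction.
#' @param min_variance minimum variance over observed values.
#' @return list with `keep` (retained column names) and `report` (data.frame
#'   of dropped columns with reasons).
#' @export
kd_prefilter_features <- function(X, max_missing_frac = 0.3,
                                  min_variance = 1e-8) {
  check_scalar_prob(max_missing_frac, "max_missing_frac")
  if (min_variance < 0) stop_config("min_variance must be >= 0")
  X <- as.data.frame(X)
  miss <- vapply(X, function(x) mean(is.na(x)), numeric(1))
  v <- vapply(X, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) 0 else stats::var(x)
  }, numeric(1))
  drop_miss <- miss > max_missing_frac
  drop_var <- !drop_miss & v < min_variance
  keep <- names(X)[!(drop_miss | drop_var)]
  if (!length(keep)) stop_config("all candidate features were dropped")
  report <- data.frame(
    feature = names(X)[drop_miss | drop_var],
    reason = ifelse(drop_miss[drop_miss | drop_var], "missingness", "low_variance"),
    missing_frac = miss[drop_miss | drop_var],
    variance = v[drop_miss | drop_var],
    row.names = NULL
  )
  list(keep = keep, report = report)
}

# Grouped k-fold assignment: groups (not rows) are dealt round-robin after a
# seeded shuffle, so every fold's test rows come from held-out groups only.
group_kfold <- function(groups, k, seed = 1L) {
  ug <- unique(groups)
  if (length(ug) < k) stop_config("need at least k groups for group k-fold")
  with_seed(seed, {
    shuffled <- sample(ug)
    fold_of_group <- stats::setNames(rep(seq_len(k), length.out = length(ug)),
                                     shuffled)
    unname(fold_of_group[as.character(groups)])
  })
}

# Mean AUC over grouped CV folds for one feature subset and one estimator.
cv_auc <- function(X, y, fold, estimator, seed) {
  aucs <- c()
  for (f in sort(unique(fold))) {
    tr <- fold != f
    ytr <- y[tr]; yte <- y[!tr]
    if (length(unique(ytr)) < 2L || length(unique(yte)) < 2L) {
      warning("skipping single-class fold in grouped CV", call. = FALSE)
      next
    }
    fit <- kd_fit_classifier(estimator, X[tr, , drop = FALSE], ytr, seed = seed)
    p <- kd_predict_prob(fit, X[!tr, , drop = FALSE])
    aucs <- c(aucs, kd_auc(p, yte))
  }
  if (!length(aucs)) return(NA_real_)
  mean(aucs)
}

# Feature importance for backward elimination: |coefficient| for the logistic
# model, impurity importance for the forest, otherwise a single-permutation
# AUC drop on the training data.
feature_importance <- function(estimator, X, y, seed) {
  if (estimator == "lr") {
    fit <- kd_fit_classifier("lr", X, y, seed = seed)
    co <- stats::coef(fit$model)[-1]
    imp <- abs(co)
    names(imp) <- colnames(X)
    imp[is.na(imp)] <- 0
    return(imp)
  }
  if (estimator == "rf") {
    m <- ranger::ranger(x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
                        probability = TRUE, num.trees = 300L,
                        importance = "impurity", seed = as.integer(seed),
                        num.threads = 1L)
    return(m$variable.importance[colnames(X)])
  }
  fit <- kd_fit_classifier(estimator, X, y, seed = seed)
  base <- kd_auc(kd_predict_prob(fit, X), y)
  with_seed(seed, {
    vapply(seq_len(ncol(X)), function(j) {
      Xp <- X
      Xp[, j] <- sample(Xp[, j])
      base - kd_auc(kd_predict_prob(fit, Xp), y)
    }, numeric(1)) -> drops
    stats::setNames(drops, colnames(X))
  })
}

#' Recursive feature elimination with cross-classifier consensus
#'
#' For each estimator, greedy backward elimination removes the least
#' important feature one at a time, recording the mean grouped k-fold
#' cross-validated AUC-ROC at every subset size (the AUC-versus-size trace).
#' Each estimator's best subset is the one maximising its CV AUC (ties broken
#' toward smaller subsets). The consensus set has the size maximising the
#' mean trace across estimators and contains the features most recurrent
#' across the estimators' best subsets (ties broken by how late a feature was
#' eliminated on average).
#'
#' @param X complete numeric feature matrix.
#' @param y 0/1 labels.
#' @param groups group (subject) id per row for the grouped CV.
#' @param estimators estimator names; the default five span the pipeline's
#'   classifier menus.
#' @param k number of grouped CV folds.
#' @param seed integer seed.
#' @return list with `selected` (consensus feature names), `traces` (matrix
#'   size x estimator of mean CV AUC), `best_subsets`, `counts`.
#' @export
kd_rfe_consensus <- function(X, y, groups,
                             estimators = c("lr", "rf", "qda", "gnb", "svm"),
                             k = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  p <- ncol(X)
  if (p < 1L) stop_config("no candidate features")
  if (p == 1L) {
    return(list(selected = colnames(X), traces = NULL,
                best_subsets = NULL, counts = NULL))
  }
  fold <- group_kfold(groups, k, seed)
  sizes <- seq_len(p)
  traces <- matrix(NA_real_, nrow = p, ncol = length(estimators),
                   dimnames = list(sizes, estimators))
  best_subsets <- list()
  elim_step <- matrix(NA_real_, nrow = p, ncol = length(estimators),
                      dimnames = list(colnames(X), estimators))
  for (e in seq_along(estimators)) {
    est <- estimators[e]
    feats <- colnames(X)
    subsets <- vector("list", p)
    while (length(feats) >= 1L) {
      s <- length(feats)
      subsets[[s]] <- feats
      traces[s, e] <- cv_auc(X[, feats, drop = FALSE], y, fold, est,
                             seed = seed + 100L * e + s)
      if (s == 1L) break
      imp <- feature_importance(est, X[, feats, drop = FALSE], y,
                                seed = seed + 100L * e + s)
      worst <- feats[which.min(imp)]
      elim_step[worst, e] <- s
      feats <- setdiff(feats, worst)
    }
    elim_step[feats, e] <- 0  # survivor
    best_size <- which(traces[, e] >= max(traces[, e], na.rm = TRUE) - 1e-12)[1]
    best_subsets[[est]] <- subsets[[best_size]]
  }
  counts <- table(unlist(best_subsets))
  mean_trace <- rowMeans(traces, na.rm = TRUE)
  s_star <- which(mean_trace >= max(mean_trace, na.rm = TRUE) - 1e-12)[1]
  # rank candidates: recurrence first, then average elimination step (later
  # elimination = more important; survivors count as step 0)
  avg_elim <- rowMeans(elim_step, na.rm = TRUE)
  cand <- names(sort(avg_elim))  # low step first = strongest first
  cnt <- stats::setNames(rep(0L, p), colnames(X))
  cnt[names(counts)] <- as.integer(counts)
  ord <- order(-cnt[cand], seq_along(cand))
  selected <- cand[ord][seq_len(s_star)]
  list(selected = selected, traces = traces, best_subsets = best_subsets,
       counts = cnt, mean_trace = mean_trace, consensus_size = s_star)
}
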