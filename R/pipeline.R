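# Shared fold machinery: given candidate window day-rows (raw daily feature
# columns), fit fold-local composites + stage 1 + ensemble on the training
# subjects and score the test subjects' windows.

fit_fold <- function(candidate, train_ids, cluster_fit_specs, menu, seed,
                     select_features = FALSE, rfe_estimators = NULL) {
  tr <- candidate[candidate$subject_id %in% train_ids]
  if (length(unique(tr$label)) < 2L) {
    stop_config("single-class training labels in fold")
  }
  cfit <- kd_fit_composites(tr, cluster_fit_specs)
  make_X <- function(rows) {
    comp <- kd_transform_composites(cfit, rows)
    as.matrix(as.data.frame(comp)[, setdiff(names(comp), c("subject_id", "day")),
                                  drop = FALSE])
  }
  Xtr <- make_X(tr)
  # fold-level variance guard: constant columns (e.g. a saturated count
  # feature) carry no information and cannot be standardized
  v <- apply(Xtr, 2L, function(x) stats::var(x[!is.na(x)]))
  keep_var <- !is.na(v) & v > 1e-12
  if (!any(keep_var)) stop_config("no informative feature columns in fold")
  Xtr <- Xtr[, keep_var, drop = FALSE]
  stage1 <- kd_fit_stage1(Xtr)
  Ztr <- kd_transform_stage1(stage1, Xtr)
  feats <- colnames(Ztr)
  if (select_features && ncol(Ztr) >= 2L) {
    sel <- kd_rfe_consensus(Ztr, tr$label, groups = tr$subject_id,
                            estimators = rfe_estimators %||% c("lr", "rf", "qda", "gnb", "svm"),
                            seed = seed)
    feats <- sel$selected
    Ztr <- Ztr[, feats, drop = FALSE]
  }
  ens <- kd_fit_ensemble(Ztr, tr$label, menu = menu, seed = seed)
  list(cfit = cfit, stage1 = stage1, ensemble = ens, feats = feats,
       make_X = make_X)
}

predict_fold <- function(fold, rows) {
  if (!nrow(rows)) return(data.table())
  X <- fold$make_X(rows)
  Z <- kd_transform_stage1(fold$stage1, X)[, fold$feats, drop = FALSE]
  p <- kd_predict_ensemble(fold$ensemble, Z)
  dt <- data.table(subject_id = rows$subject_id, visit = rows$visit,
                   label = rows$label, p_day = p)
  dt[, .(label = label[1], prob = mean(p_day), n_days = .N),
     by = .(subject_id, visit)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Labelled visits + candidate window rows for one target, before any
# fold-specific cutoff is applied. Returns NULL label scores for diagnosis.
target_visits <- function(clinical, demographics, spec, subjects) {
  if (spec$name == "diagnosis") {
    d <- as.data.table(demographics)[subject_id %in% subjects]
    vis <- d[, .(subject_id, visit = "m00", visit_day = 0L,
                 score = NA_real_, label0 = as.integer(group == "MS"))]
  } else {
    score_col <- c(edss = "edss", nhpt = "nhpt_s", sdmt = "sdmt")[[spec$name]]
    cl <- as.data.table(clinical)[subject_id %in% subjects]
    cl <- cl[!is.na(cl[[score_col]])]
    vis <- cl[, .(subject_id, visit, visit_day)]
    vis[, score := cl[[score_col]]]
    vis[, label0 := NA_integer_]
  }
  vis
}

apply_cutoff <- function(vis, spec, fit_ids) {
  if (spec$name == "diagnosis") {
    return(list(labels = vis$label0, cutoff = NA_real_))
  }
  cutoff <- if (identical(spec$cutoff, "median_split")) {
    stats::median(vis$score[vis$subject_id %in% fit_ids])
  } else as.numeric(spec$cutoff)
  labels <- switch(spec$name,
                   edss = as.integer(vis$score > cutoff),
                   nhpt = as.integer(vis$score > cutoff),
                   sdmt = as.integer(vis$score <= cutoff))
  list(labels = labels, cutoff = cutoff)
}

#' Leave-one-subject-out cross-validation of the three-stage pipeline
#'
#' Runs the full classification pipeline under a leave-one-group-out scheme:
#' for every subject, a model is fitted on all remaining subjects — including
#' the median-split cutoff, composite standardisation, the stage-1
#' normalisation/imputation, optional recursive feature elimination, and the
#' soft-voting ensemble — and the held-out subject's visits are predicted by
#' averaging their per-day probabilities. No preprocessing statistic ever
#' sees the held-out subject.
#'
#' @param daily daily feature table from [kd_featurize()].
#' @param clinical clinical visit table (ignored for `diagnosis`).
#' @param demographics demographics table (used for `diagnosis` labels).
#' @param spec a [kd_target_spec()].
#' @param cluster_specs composite cluster specs; pruned once (label-free) on
#'   the input table.
#' @param subjects optional subject id subset (e.g. the training split).
#' @param seed integer seed.
#' @param select_features run RFE-consensus feature selection inside every
#'   fold (expensive; the default composite feature space is small enough
#'   that selection is usually unnecessary).
#' @param prune prune composite clusters by correlation first.
#' @param rfe_estimators estimator names for the in-fold RFE consensus
#'   (default: the five-estimator list of [kd_rfe_consensus()]).
#' @return `data.table` of out-of-fold predictions (`subject_id, visit,
#'   label, prob, n_days`) with attributes `auc` and `n_subjects`.
#' @export
kd_logocv <- function(daily, clinical = NULL, demographics = NULL, spec,
                      cluster_specs = kd_cluster_specs(), subjects = NULL,
                      seed = 1L, select_features = FALSE, prune = TRUE,
                      rfe_estimators = NULL) {
  stopifnot(inherits(spec, "kd_target_spec"))
  daily <- as.data.table(daily)
  subjects <- subjects %||% unique(daily$subject_id)
  daily <- daily[subject_id %in% subjects]
  vis <- target_visits(clinical, demographics, spec, subjects)
  if (prune) {
    cluster_specs[] <- lapply(cluster_specs,
                              function(sp) kd_prune_by_correlation(daily, sp))
  }
  vis[, label := 0L]  # placeholder; real labels set per fold
  candidate <- kd_assemble_windows(daily, vis, spec$w_d, spec$tau_d,
                                   anchor = spec$anchor)
  ids <- sort(intersect(unique(candidate$subject_id), vis$subject_id))
  if (length(ids) < 3L) stop_config("need at least 3 predictable subjects")
  preds <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    test_id <- ids[i]
    train_ids <- setdiff(ids, test_id)
    cut <- apply_cutoff(vis, spec, train_ids)
    lab_map <- vis[, .(subject_id, visit)]
    lab_map[, label := cut$labels]
    cand_f <- merge(candidate[, !"label"], lab_map,
                    by = c("subject_id", "visit"))
    fold <- fit_fold(cand_f, train_ids, cluster_specs, spec$classifiers,
                     seed = seed + i, select_features = select_features,
                     rfe_estimators = rfe_estimators)
    preds[[i]] <- predict_fold(fold, cand_f[subject_id == test_id])
    preds[[i]][, cutoff := cut$cutoff]
  }
  out <- data.table::rbindlist(preds)
  auc <- if (length(unique(out$label)) == 2L) kd_auc(out$prob, out$label) else NA_real_
  data.table::setattr(out, "auc", auc)
  data.table::setattr(out, "n_subjects", length(ids))
  out[]
}

#' Grid search over the window hyper-parameters (w_d, tau_d)
#'
#' Runs [kd_logocv()] for every pair on the grid and records the mean
#' cross-validated AUC-ROC as a heatmap. The best pair maximises the AUC;
#' ties are broken toward larger `tau_d` (stricter day quality), then
#' smaller `w_d` (tighter window). Cells for which fewer than 2 subjects are
#' predictable, or whose AUC is undefined, are marked invalid and excluded
#' from the argmax.
#'
#' @inheritParams kd_logocv
#' @param w_grid,tau_grid numeric grids.
#' @return list with `best` (named vector `w_d`, `tau_d`), `heatmap` (matrix
#'   w x tau of AUCs).
#' @export
kd_grid_search_wd_tau <- function(daily, clinical = NULL, demographics = NULL,
                                  spec, w_grid, tau_grid, seed = 1L, ...) {
  if (!length(w_grid) || !length(tau_grid)) stop_config("empty grid")
  heat <- matrix(NA_real_, length(w_grid), length(tau_grid),
                 dimnames = list(w_grid, tau_grid))
  for (i in seq_along(w_grid)) {
    for (j in seq_along(tau_grid)) {
      sp <- spec
      sp$w_d <- as.integer(w_grid[i]); sp$tau_d <- as.numeric(tau_grid[j])
      auc <- tryCatch({
        res <- kd_logocv(daily, clinical, demographics, sp, seed = seed, ...)
        if (attr(res, "n_subjects") < 2L) NA_real_ else attr(res, "auc")
      }, error = function(e) NA_real_)
      heat[i, j] <- auc
    }
  }
  if (all(is.na(heat))) stop_config("no valid grid cell")
  best_val <- max(heat, na.rm = TRUE)
  cand <- which(heat >= best_val - 1e-12, arr.ind = TRUE)
  cand <- cand[order(-tau_grid[cand[, 2]], w_grid[cand[, 1]]), , drop = FALSE]
  list(best = c(w_d = w_grid[cand[1, 1]], tau_d = tau_grid[cand[1, 2]]),
       heatmap = heat)
}

#' Train on a grouped 80/20 split and evaluate the hold-out set
#'
#' Splits subjects into training and hold-out sets (subject-disjoint,
#' stratified by subject-level class), optionally runs LOGOCV inside the
#' training set, then fits the final pipeline on all training subjects and
#' scores the hold-out subjects. Reports AUC with a grouped bootstrap CI and
#' threshold metrics.
#'
#' @inheritParams kd_logocv
#' @param holdout_fraction hold-out fraction of subjects.
#' @param run_logocv also compute LOGOCV predictions within the training set.
#' @param B bootstrap resamples for the CV AUC confidence interval.
#' @return list with `split`, `cv` (LOGOCV predictions or NULL), `cv_auc`,
#'   `cv_ci`, `holdout` (predictions), `holdout_auc`, `holdout_metrics`,
#'   `cutoff`.
#' @export
kd_train_evaluate <- function(daily, clinical = NULL, demographics = NULL,
                              spec, cluster_specs = kd_cluster_specs(),
                              holdout_fraction = 0.2, seed = 1L,
                              run_logocv = TRUE, B = 1000L,
                              select_features = FALSE, prune = TRUE) {
  daily <- as.data.table(daily)
  vis <- target_visits(clinical, demographics, spec, unique(daily$subject_id))
  # subject-level label for stratification: full-sample rule
  cut_all <- apply_cutoff(vis, spec, unique(vis$subject_id))
  vis[, lab_all := cut_all$labels]
  subj_lab <- vis[, .(lab = as.integer(mean(lab_all) >= 0.5)), by = subject_id]
  split <- kd_split_holdout(subj_lab$subject_id, subj_lab$lab,
                            fraction = holdout_fraction, seed = seed)
  if (prune) {
    cluster_specs[] <- lapply(cluster_specs,
                              function(sp) kd_prune_by_correlation(daily[subject_id %in% split$train], sp))
  }
  cv <- NULL; cv_auc <- NA_real_; cv_ci <- NULL
  if (run_logocv) {
    cv <- kd_logocv(daily, clinical, demographics, spec,
                    cluster_specs = cluster_specs, subjects = split$train,
                    seed = seed, select_features = select_features,
                    prune = FALSE)
    cv_auc <- attr(cv, "auc")
    cv_ci <- kd_bootstrap_auc_ci(cv$prob, cv$label, cv$subject_id, B = B,
                                 seed = seed)
  }
  # final fit on the full training split
  cut <- apply_cutoff(vis, spec, split$train)
  lab_map <- vis[, .(subject_id, visit)]
  lab_map[, label := cut$labels]
  vis2 <- merge(vis, lab_map, by = c("subject_id", "visit"))
  candidate <- kd_assemble_windows(daily, vis2, spec$w_d, spec$tau_d,
                                   anchor = spec$anchor)
  fold <- fit_fold(candidate, split$train, cluster_specs, spec$classifiers,
                   seed = seed, select_features = select_features)
  holdout_pred <- predict_fold(fold,
                               candidate[subject_id %in% split$holdout])
  holdout_auc <- if (length(unique(holdout_pred$label)) == 2L) {
    kd_auc(holdout_pred$prob, holdout_pred$label)
  } else NA_real_
  holdout_metrics <- if (!is.na(holdout_auc)) {
    kd_confusion_metrics(holdout_pred$prob, holdout_pred$label)
  } else NULL
  list(split = split, cv = cv, cv_auc = cv_auc, cv_ci = cv_ci,
       holdout = holdout_pred, holdout_auc = holdout_auc,
       holdout_metrics = holdout_metrics, cutoff = cut$cutoff,
       model = fold)
}
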