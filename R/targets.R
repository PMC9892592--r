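#' Target specification for a binary classification pipeline
#'
#' Encodes, per clinical target, the binarization rule, the classifier menu
#' and the window hyper-parameters:
#' \itemize{
#'   \item `diagnosis`: positive iff the subject is in the MS group; trailing
#'     window of `w_d` days anchored at each subject's first observed day
#'     (controls have no clinical visits); menu RF + LR.
#'   \item `edss`: positive (high disease severity) iff EDSS > cutoff
#'     (median split by default); menu RF + LR + QDA.
#'   \item `nhpt`: positive (low fine motor skill) iff NHPT > cutoff (median
#'     split); menu LR + GNB + SVM.
#'   \item `sdmt`: positive (cognitive deficit) iff SDMT <= 55; menu
#'     LR + KNN + SVM.
#' }
#' For the severity targets the window of `2 * w_d + 1` days is centred on
#' each clinical visit, and only days with at least `tau_d` keystroke events
#' contribute.
#'
#' @param name target name.
#' @param cutoff `"median_split"`, or a fixed numeric cutoff (e.g. the
#'   published full-sample medians EDSS 3.5 / NHPT 20.40), or `NULL` for the
#'   target's default.
#' @param w_d window half-width in days (window length for `diagnosis`).
#' @param tau_d minimum daily event count for a day to contribute.
#' @param classifiers optional override of the ensemble menu.
#' @return object of class `kd_target_spec`.
#' @export
kd_target_spec <- function(name = c("diagnosis", "edss", "nhpt", "sdmt"),
                           cutoff = NULL, w_d = NULL, tau_d = NULL,
                           classifiers = NULL) {
  name <- match.arg(name)
  defaults <- list(
    diagnosis = list(cutoff = NA_real_, w_d = 11L, tau_d = 100,
                     classifiers = c("rf", "lr"), anchor = "trailing"),
    edss = list(cutoff = "median_split", w_d = 10L, tau_d = 125,
                classifiers = c("rf", "lr", "qda"), anchor = "centered"),
    nhpt = list(cutoff = "median_split", w_d = 12L, tau_d = 125,
                classifiers = c("lr", "gnb", "svm"), anchor = "centered"),
    sdmt = list(cutoff = 55, w_d = 4L, tau_d = 150,
                classifiers = c("lr", "knn", "svm"), anchor = "centered")
  )[[name]]
  spec <- list(
    name = name,
    cutoff = if (is.null(cutoff)) defaults$cutoff else cutoff,
    w_d = as.integer(if (is.null(w_d)) defaults$w_d else w_d),
    tau_d = as.numeric(if (is.null(tau_d)) defaults$tau_d else tau_d),
    classifiers = if (is.null(classifiers)) defaults$classifiers else classifiers,
    anchor = defaults$anchor
  )
  if (spec$w_d < 0L || spec$tau_d < 0) stop_config("w_d and tau_d must be >= 0")
  structure(spec, class = "kd_target_spec")
}

#' Binarize clinical outcomes into per-visit labels
#'
#' Applies the target's rule: SDMT is positive (impaired) iff `sdmt <= 55`;
#' NHPT is positive iff `nhpt_s > cutoff`; EDSS is positive iff
#' `edss > cutoff`; `diagnosis` labels subjects by group. Median-split
#' cutoffs are estimated over the visits of `fit_ids` only (the training
#' split), which keeps label construction leakage-safe; a fixed numeric
#' `cutoff` in the spec freezes the rule instead. Visits with a missing score
#' are dropped with a warning.
#'
#' @param clinical clinical visit table (`subject_id, visit, visit_day,
#'   edss, nhpt_s, sdmt`).
#' @param spec a [kd_target_spec()].
#' @param fit_ids subject ids whose visits define a median-split cutoff.
#' @param demographics required for `diagnosis` (uses `subject_id`, `group`).
#' @return `data.table` with `subject_id, visit, visit_day, label` and the
#'   resolved cutoff as attribute `"cutoff"`.
#' @export
kd_binarize_targets <- function(clinical, spec, fit_ids = NULL,
                                demographics = NULL) {
  stopifnot(inherits(spec, "kd_target_spec"))
  if (spec$name == "diagnosis") {
    if (is.null(demographics)) stop_config("diagnosis labels need demographics")
    d <- as.data.table(demographics)
    out <- d[, .(subject_id, visit = "m00", visit_day = 0L,
                 label = as.integer(group == "MS"))]
    data.table::setattr(out, "cutoff", NA_real_)
    return(out[])
  }
  cl <- as.data.table(clinical)
  score_col <- c(edss = "edss", nhpt = "nhpt_s", sdmt = "sdmt")[[spec$name]]
  score <- cl[[score_col]]
  if (anyNA(score)) {
    warning(sprintf("dropping %d visit(s) with missing %s", sum(is.na(score)),
                    score_col), call. = FALSE)
    cl <- cl[!is.na(score)]
    score <- cl[[score_col]]
  }
  if (identical(spec$cutoff, "median_split")) {
    fit_scores <- if (is.null(fit_ids)) score else score[cl$subject_id %in% fit_ids]
    if (!length(fit_scores)) stop_config("no visits available to estimate the median cutoff")
    cutoff <- stats::median(fit_scores)
  } else {
    cutoff <- as.numeric(spec$cutoff)
  }
  label <- switch(spec$name,
                  edss = as.integer(score > cutoff),
                  nhpt = as.integer(score > cutoff),
                  sdmt = as.integer(score <= cutoff))
  out <- cl[, .(subject_id, visit, visit_day)]
  out[, label := label]
  data.table::setattr(out, "cutoff", cutoff)
  out[]
}

#' Grouped, stratified train/hold-out split of subjects
#'
#' Splits subject ids into a training and hold-out set with no subject in
#' both, stratified by subject-level class so each split contains both
#' classes.
#'
#' @param ids subject ids.
#' @param labels subject-level 0/1 labels aligned with `ids`.
#' @param fraction hold-out fraction.
#' @param seed integer seed.
#' @return list with `train` and `holdout` id vectors.
#' @export
kd_split_holdout <- function(ids, labels, fraction = 0.2, seed = 1L) {
  if (length(ids) < 5L) stop_config("need at least 5 subjects to split")
  if (length(ids) != length(labels)) stop_config("ids and labels differ in length")
  labels <- as.integer(labels)
  with_seed(seed, {
    hold <- character(0)
    for (cls in unique(labels)) {
      members <- ids[labels == cls]
      n_h <- max(1L, round(fraction * length(members)))
      if (n_h >= length(members)) {
        stop_config("class %s would be absent from the training split", cls)
      }
      hold <- c(hold, sample(members, n_h))
    }
    train <- setdiff(ids, hold)
    for (cls in unique(labels)) {
      if (!any(labels[ids %in% train] == cls) || !any(labels[ids %in% hold] == cls)) {
        stop_config("class %s absent from one split", cls)
      }
    }
    list(train = train, holdout = hold)
  })
}

#' Assemble per-visit day windows from a composite-score table
#'
#' For every labelled subject-visit, collects the composite-score rows whose
#' day lies in the visit window (`visit_day - w_d .. visit_day + w_d` for
#' centred targets; the first `w_d` observed days for the trailing diagnosis
#' anchor) and masks days with fewer than `tau_d` events. Windows left with
#' zero qualifying days are excluded and reported in the `"dropped"`
#' attribute.
#'
#' @param composites composite-score table from [kd_transform_composites()].
#' @param visits labelled visit table from [kd_binarize_targets()].
#' @param w_d,tau_d window half-width / minimum daily event count.
#' @param anchor `"centered"` or `"trailing"`.
#' @return `data.table` of qualifying day rows with columns `subject_id`,
#'   `visit`, `label`, `day` and the feature columns.
#' @export
kd_assemble_windows <- function(composites, visits, w_d, tau_d,
                                anchor = c("centered", "trailing")) {
  anchor <- match.arg(anchor)
  comp <- as.data.table(composites)
  vis <- data.table::copy(as.data.table(visits))
  if (anchor == "trailing") {
    first_day <- comp[, .(first_day = min(day)), by = subject_id]
    vis <- merge(vis, first_day, by = "subject_id")
    vis[, `:=`(lo = first_day, hi = first_day + pmax(w_d - 1L, 0L))]
  } else {
    vis[, `:=`(lo = visit_day - w_d, hi = visit_day + w_d)]
  }
  if (nrow(vis)) {
    len <- vis$hi - vis$lo + 1L
    cand <- vis[rep(seq_len(nrow(vis)), len),
                .(subject_id, visit, label)]
    cand[, day := unlist(Map(seq.int, vis$lo, vis$hi))]
    out <- merge(cand, comp[event_count >= tau_d], by = c("subject_id", "day"))
  } else {
    out <- cbind(comp[0], data.table(visit = character(), label = integer()))
  }
  data.table::setcolorder(out, c("subject_id", "visit", "label", "day"))
  dropped <- merge(vis[, .(subject_id, visit)],
                   unique(out[, .(subject_id, visit, got = TRUE)]),
                   by = c("subject_id", "visit"), all.x = TRUE)[is.na(got),
                                                               .(subject_id, visit)]
  data.table::setattr(out, "dropped", dropped)
  out[]
}

#' Average per-day ensemble probabilities into a subject-visit prediction
#'
#' The third pipeline stage: each qualifying day row of a window is mapped
#' through the fitted stage-1 transformer and the ensemble, giving per-day
#' probabilities; the subject-visit prediction is their arithmetic mean, and
#' the hard label calls it positive at `threshold`. A window with zero
#' qualifying days yields an abstention (`prob = NA`, `abstained = TRUE`),
#' never a silent 0.5.
#'
#' @param window day-row table for one subject-visit (feature columns only
#'   are used).
#' @param stage1 a fitted [kd_fit_stage1()].
#' @param ensemble a fitted [kd_fit_ensemble()].
#' @param threshold decision threshold on the averaged probability.
#' @return list with `prob`, `per_day`, `label`, `abstained`.
#' @export
kd_predict_subject <- function(window, stage1, ensemble, threshold = 0.5) {
  X <- window_matrix(window, stage1$features)
  if (nrow(X) == 0L) {
    return(list(prob = NA_real_, per_day = numeric(0), label = NA_integer_,
                abstained = TRUE))
  }
  Z <- kd_transform_stage1(stage1, X)
  per_day <- kd_predict_ensemble(ensemble, Z)
  prob <- mean(per_day)
  list(prob = prob, per_day = per_day, label = as.integer(prob >= threshold),
       abstained = FALSE)
}

window_matrix <- function(window, features) {
  df <- as.data.frame(window)
  cols <- intersect(features, names(df))
  as.matrix(df[, cols, drop = FALSE])
}
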