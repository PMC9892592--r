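#' Default composite-score cluster specification
#'
#' Composite scores collapse the daily feature table into a handful of
#' interpretable scores by averaging standardized, highly inter-correlated
#' cluster members. The default clusters follow the hypothesis that
#' timing-related sequences (PPL, RRL, HT, FT) reflect fine motor skill while
#' error-related (PreCS, PostCS) and paralinguistic (APP) sequences reflect
#' cognitive processing:
#' \itemize{
#'   \item `fmcs_central`: central-tendency statistics (mean, median) of
#'     PPL/RRL/HT/FT — the central value of the fine motor score;
#'   \item `fmcs_dispersion`: dispersion statistics (sd, iqr) of the same —
#'     fine motor variability;
#'   \item `ccs_central` and `ccs_dispersion`: the analogous statistics of
#'     PreCS/PostCS/APP — the cognition composite scores.
#' }
#' Count features (total events, backspace and suggestion counts) pass
#' through unclustered.
#'
#' @param min_abs_correlation pruning threshold on the mean absolute pairwise
#'   correlation of a member with the rest of its cluster.
#' @return named list of cluster specs (class `kd_cluster_specs`), each with
#'   `members` and `min_abs_correlation`.
#' @export
kd_cluster_specs <- function(min_abs_correlation = 0.5) {
  check_scalar_prob(min_abs_correlation, "min_abs_correlation")
  fm <- c("PPL", "RRL", "HT", "FT")
  cc <- c("PreCS", "PostCS", "APP")
  mk <- function(seqs, stats) {
    list(members = as.vector(outer(seqs, stats, paste, sep = "_")),
         min_abs_correlation = min_abs_correlation)
  }
  structure(list(
    fmcs_central    = mk(fm, c("mean", "median")),
    fmcs_dispersion = mk(fm, c("sd", "iqr")),
    ccs_central     = mk(cc, c("mean", "median")),
    ccs_dispersion  = mk(cc, c("sd", "iqr"))
  ), class = "kd_cluster_specs")
}

#' Prune a cluster to its highly inter-correlated members
#'
#' Keeps members whose mean absolute pairwise Pearson correlation with the
#' other members (complete pairwise observations) reaches the cluster's
#' threshold. The best-connected member is always retained, so a cluster is
#' never emptied; members with no observed values are excluded with a
#' warning. Single-member clusters are returned unchanged.
#'
#' @param daily daily feature table from [kd_featurize()].
#' @param spec a single cluster spec (`members`, `min_abs_correlation`).
#' @return the spec with `members` reduced to the retained set.
#' @export
kd_prune_by_correlation <- function(daily, spec) {
  members <- spec$members
  missing_cols <- setdiff(members, names(daily))
  if (length(missing_cols)) {
    stop_config("cluster member(s) absent from daily table: %s",
                paste(missing_cols, collapse = ", "))
  }
  if (length(members) < 2L) return(spec)
  m <- as.matrix(as.data.frame(daily)[, members, drop = FALSE])
  all_na <- colSums(!is.na(m)) == 0L
  if (any(all_na)) {
    warning(sprintf("excluding all-missing cluster member(s): %s",
                    paste(members[all_na], collapse = ", ")), call. = FALSE)
    members <- members[!all_na]
    m <- m[, members, drop = FALSE]
    if (length(members) < 2L) { spec$members <- members; return(spec) }
  }
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(cm) <- NA_real_
  connectivity <- rowMeans(abs(cm), na.rm = TRUE)
  keep <- connectivity >= spec$min_abs_correlation
  keep[which.max(connectivity)] <- TRUE
  spec$members <- members[keep]
  spec
}

#' Fit composite-score standardisation parameters
#'
#' Estimates, on a fitting split only, the per-member mean and standard
#' deviation used to z-score cluster members before averaging. Members with
#' zero variance on the fitting split are skipped with a warning (a constant
#' carries no score information and cannot be standardized).
#'
#' @param daily daily feature table restricted to the fitting split.
#' @param specs cluster specs, e.g. [kd_cluster_specs()], optionally pruned
#'   via [kd_prune_by_correlation()].
#' @param prune if `TRUE`, prune each cluster by correlation first.
#' @return object of class `kd_composite_fit`.
#' @export
kd_fit_composites <- function(daily, specs = kd_cluster_specs(), prune = FALSE) {
  if (prune) specs[] <- lapply(specs, function(sp) kd_prune_by_correlation(daily, sp))
  df <- as.data.frame(daily)
  fit <- lapply(specs, function(sp) {
    members <- sp$members
    mu <- vapply(members, function(cn) mean(df[[cn]], na.rm = TRUE), numeric(1))
    sigma <- vapply(members, function(cn) stats::sd(df[[cn]], na.rm = TRUE), numeric(1))
    bad <- !is.finite(sigma) | sigma <= 0
    if (any(bad)) {
      warning(sprintf("skipping zero-variance member(s): %s",
                      paste(members[bad], collapse = ", ")), call. = FALSE)
      members <- members[!bad]; mu <- mu[!bad]; sigma <- sigma[!bad]
    }
    list(members = members, mu = mu, sigma = sigma)
  })
  structure(list(clusters = fit), class = "kd_composite_fit")
}

#' Build the composite-score table from fitted parameters
#'
#' Each composite is the unweighted mean of its z-scored members available
#' that day (standardisation parameters come from the fit, never from the
#' data being transformed); a composite is missing only when all its members
#' are missing. Count features pass through.
#'
#' @param fit a [kd_fit_composites()] object.
#' @param daily daily feature table to transform.
#' @return `data.table` with `subject_id`, `day`, one column per composite,
#'   and the count columns.
#' @export
kd_transform_composites <- function(fit, daily) {
  stopifnot(inherits(fit, "kd_composite_fit"))
  df <- as.data.frame(daily)
  out <- data.table(subject_id = df$subject_id, day = df$day)
  for (nm in names(fit$clusters)) {
    cl <- fit$clusters[[nm]]
    if (!length(cl$members)) { out[, (nm) := NA_real_]; next }
    z <- sweep(sweep(as.matrix(df[, cl$members, drop = FALSE]), 2L, cl$mu),
               2L, cl$sigma, "/")
    comp <- rowMeans(z, na.rm = TRUE)
    comp[is.nan(comp)] <- NA_real_
    out[, (nm) := comp]
  }
  for (cn in c("event_count", "backspace_count", "suggestion_count")) {
    if (cn %in% names(df)) out[, (cn) := df[[cn]]]
  }
  out[]
}

#' Fit and apply composites in one step
#'
#' Convenience wrapper: fits standardisation parameters on `fit_rows` (all
#' rows by default) and transforms the full table.
#'
#' @inheritParams kd_fit_composites
#' @param fit_rows logical/integer row index of the fitting split.
#' @return composite score table.
#' @export
kd_build_composites <- function(daily, specs = kd_cluster_specs(),
                                prune = FALSE, fit_rows = NULL) {
  fit_data <- if (is.null(fit_rows)) daily else as.data.table(daily)[fit_rows]
  fit <- kd_fit_composites(fit_data, specs, prune = prune)
  kd_transform_composites(fit, daily)
}
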