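#' Exact Shapley values by subset enumeration
#'
#' Attributes a model's output for one instance to its features with exact
#' Shapley values under the interventional (marginal) value function: for a
#' coalition S, v(S) is the mean model output over the background rows with
#' the features in S replaced by the instance's values. For each feature i,
#' \deqn{\phi_i = \sum_{S \not\ni i} \frac{|S|! (f - |S| - 1)!}{f!}
#'       \left[v(S \cup \{i\}) - v(S)\right].}
#' All `2^f` coalitions are enumerated, so the attribution satisfies the
#' efficiency, symmetry and null-player axioms to numerical precision; the
#' enumeration is limited to 15 features.
#'
#' @param predict_fun function mapping a numeric matrix to model outputs
#'   (e.g. ensemble probabilities).
#' @param instance named numeric vector, the row to explain.
#' @param background numeric matrix of background rows (the reference
#'   distribution; at most a few hundred training rows is typical).
#' @return object of class `kd_shapley`: list with `values` (named numeric),
#'   `base_value` (mean model output over the background) and `prediction`.
#' @export
kd_exact_shapley <- function(predict_fun, instance, background) {
  background <- as.matrix(background)
  f <- length(instance)
  if (f > 15L) {
    stop_config("exact enumeration supports at most 15 features (2^f coalitions); use a sampling approximation for larger sets")
  }
  if (nrow(background) == 0L) stop_config("background must be non-empty")
  if (is.null(names(instance))) names(instance) <- colnames(background)
  n_sub <- bitwShiftL(1L, f)
  # v(S) for every coalition mask, batched into one predict call
  big <- matrix(rep(t(background), n_sub), ncol = f, byrow = TRUE)
  colnames(big) <- colnames(background)
  nb <- nrow(background)
  for (j in seq_len(f)) {
    masks <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) > 0L
    rows <- rep(masks, each = nb)
    big[rows, j] <- instance[j]
  }
  out <- predict_fun(big)
  v <- rowMeans(matrix(out, nrow = n_sub, byrow = TRUE))
  sizes <- vapply(seq_len(n_sub) - 1L, function(m) sum(bitwAnd(m, bitwShiftL(1L, seq_len(f) - 1L)) > 0L), numeric(1))
  lf <- lfactorial(f)
  w <- exp(lfactorial(sizes) + lfactorial(f - sizes - 1) - lf)  # weight of S by |S|
  phi <- numeric(f)
  for (j in seq_len(f)) {
    bit <- bitwShiftL(1L, j - 1L)
    has <- bitwAnd(seq_len(n_sub) - 1L, bit) > 0L
    s_mask <- which(!has)
    phi[j] <- sum(w[s_mask] * (v[s_mask + bit] - v[s_mask]))
  }
  structure(list(values = stats::setNames(phi, names(instance)),
                 base_value = v[1L], prediction = v[n_sub]),
            class = "kd_shapley")
}

#' Global feature importance from a set of Shapley explanations
#'
#' Averages the absolute Shapley values per feature across explanations
#' (e.g. across the daily samples of a cohort) and returns them in
#' descending order.
#'
#' @param explanations list of `kd_shapley` objects.
#' @return named numeric vector of mean absolute Shapley values, descending.
#' @export
kd_global_importance <- function(explanations) {
  if (!length(explanations)) stop_config("need at least one explanation")
  vals <- vapply(explanations, function(e) abs(e$values),
                 numeric(length(explanations[[1]]$values)))
  if (is.null(dim(vals))) {
    vals <- matrix(vals, nrow = 1L,
                   dimnames = list(names(explanations[[1]]$values), NULL))
  }
  sort(rowMeans(vals), decreasing = TRUE)
}

#' Explain per-day predictions of a fitted pipeline stage
#'
#' Computes exact Shapley explanations for a set of (stage-1 transformed)
#' day rows against a background sample, plus the pooled global importance.
#'
#' @param ensemble a fitted [kd_fit_ensemble()].
#' @param rows standardized day-row matrix to explain.
#' @param background standardized background matrix (subsampled to
#'   `max_background` rows).
#' @param max_background cap on background rows.
#' @param seed seed for the background subsample.
#' @return list with `explanations` (list of `kd_shapley`) and `importance`.
#' @export
kd_explain_days <- function(ensemble, rows, background, max_background = 100L,
                            seed = 1L) {
  rows <- as.matrix(rows); background <- as.matrix(background)
  if (nrow(background) > max_background) {
    background <- with_seed(seed, background[sample.int(nrow(background), max_background), , drop = FALSE])
  }
  pf <- function(X) kd_predict_ensemble(ensemble, X)
  expl <- lapply(seq_len(nrow(rows)), function(i) {
    kd_exact_shapley(pf, rows[i, ], background)
  })
  list(explanations = expl, importance = kd_global_importance(expl))
}
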