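#' Fit the stage-1 transformer: z-score normalisation + chained-equation
#' imputation
#'
#' The first pipeline stage standardizes every feature using training-split
#' means and standard deviations, then fills missing entries with an
#' iterative (chained-equation) imputer: starting from mean imputation (zero
#' on the z scale), each feature with missing values is regressed on all
#' other features over the observed rows, missing entries are replaced by the
#' regression predictions, and the cycle repeats until the largest update
#' falls below `tol` or `max_iter` rounds have run. The final-round
#' regression coefficients are stored so that transforming new data never
#' refits anything.
#'
#' @param X numeric matrix of training rows (may contain `NA`).
#' @param max_iter maximum imputation rounds.
#' @param tol convergence tolerance on the largest absolute change of an
#'   imputed (z-scaled) value.
#' @param eps variance guard: features with SD below `eps` raise an error.
#' @return object of class `kd_stage1`.
#' @export
kd_fit_stage1 <- function(X, max_iter = 10L, tol = 1e-3, eps = 1e-12) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_config("need at least 2 training rows")
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    stop_config("feature(s) with no observed values: %s",
                paste(colnames(X)[all_missing], collapse = ", "))
  }
  mu <- colMeans(X, na.rm = TRUE)
  sigma <- apply(X, 2L, stats::sd, na.rm = TRUE)
  sigma[is.na(sigma)] <- 0
  if (any(sigma <= eps)) {
    stop_config("constant feature(s) cannot be standardized: %s",
                paste(colnames(X)[sigma <= eps], collapse = ", "))
  }
  Z <- sweep(sweep(X, 2L, mu), 2L, sigma, "/")
  na_mask <- is.na(Z)
  Zf <- Z; Zf[na_mask] <- 0
  p <- ncol(Z)
  n_rounds <- 0L
  if (any(na_mask) && p >= 2L) {
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (j in seq_len(p)) {
        mj <- na_mask[, j]
        if (!any(mj)) next
        obs <- !mj
        fitj <- impute_lm(Zf[obs, -j, drop = FALSE], Zf[obs, j])
        pred <- drop(cbind(1, Zf[mj, -j, drop = FALSE]) %*% fitj)
        delta <- max(delta, max(abs(pred - Zf[mj, j])))
        Zf[mj, j] <- pred
      }
      n_rounds <- it
      if (delta < tol) break
    }
  }
  # final-round coefficients for every feature, reused at transform time
  coefs <- if (p >= 2L) {
    lapply(seq_len(p), function(j) {
      obs <- !na_mask[, j]
      impute_lm(Zf[obs, -j, drop = FALSE], Zf[obs, j])
    })
  } else list()
  structure(list(mu = mu, sigma = sigma, coefs = coefs,
                 n_rounds = max(n_rounds, 1L), p = p,
                 features = colnames(X)),
            class = "kd_stage1")
}

# Least-squares fit with a tiny ridge for rank-deficiency protection.
impute_lm <- function(X, y) {
  Xd <- cbind(1, X)
  A <- crossprod(Xd) + diag(1e-8, ncol(Xd))
  drop(solve(A, crossprod(Xd, y)))
}

#' Apply a fitted stage-1 transformer
#'
#' Standardizes with the stored training parameters and imputes missing
#' entries by running the stored chained-equation regressions for the fitted
#' number of rounds. Rows with no missing values pass through the imputer
#' unchanged.
#'
#' @param object a [kd_fit_stage1()] fit.
#' @param X matrix of rows to transform (columns matching the fit).
#' @return complete standardized numeric matrix.
#' @export
kd_transform_stage1 <- function(object, X) {
  stopifnot(inherits(object, "kd_stage1"))
  X <- as.matrix(X)
  if (!is.null(object$features) && !is.null(colnames(X))) {
    X <- X[, object$features, drop = FALSE]
  }
  Z <- sweep(sweep(X, 2L, object$mu), 2L, object$sigma, "/")
  na_mask <- is.na(Z)
  Z[na_mask] <- 0
  if (any(na_mask) && object$p >= 2L) {
    for (it in seq_len(object$n_rounds)) {
      for (j in seq_len(object$p)) {
        mj <- na_mask[, j]
        if (!any(mj)) next
        Z[mj, j] <- drop(cbind(1, Z[mj, -j, drop = FALSE]) %*% object$coefs[[j]])
      }
    }
  }
  Z
}
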