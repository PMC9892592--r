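#' Exact test of independence for an r x c contingency table
#'
#' Two-sided exact test with fixed margins: for 2x2 tables the classic
#' hypergeometric test, for larger tables the Freeman-Halton extension. The
#' two-sided p-value is the probability-ordering sum — the total conditional
#' probability of all tables (with the observed margins) no more probable
#' than the observed one — the convention that reproduces standard exact-test
#' output. The enumeration is delegated to the exact network algorithm in
#' [stats::fisher.test()].
#'
#' @param tab matrix of non-negative integer counts.
#' @return list with `p_value` and the input table.
#' @export
kd_fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_config("contingency table must hold non-negative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in contingency table: p = 1", call. = FALSE)
    return(list(p_value = 1, table = tab))
  }
  p <- stats::fisher.test(tab, workspace = 2e7)$p.value
  list(p_value = min(p, 1), table = tab)
}

#' Two-sample t-test from summary statistics
#'
#' Independent two-sample t-test computed from group means, standard
#' deviations and sizes, as needed to re-analyse published cohort tables.
#' Both the pooled-variance (Student) and unequal-variance (Welch,
#' Satterthwaite degrees of freedom) variants are provided.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @param variant `"welch"` or `"pooled"`.
#' @return list with `t`, `df`, `p_value` (two-sided).
#' @export
kd_t_test_summary <- function(m1, s1, n1, m2, s2, n2,
                              variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop_config("each group needs n >= 2")
  if (s1 <= 0 || s2 <= 0) stop_config("standard deviations must be positive")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  if (variant == "welch") {
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Logistic association test between subject status and model predictions
#'
#' Regresses the binarized subject status on the subject-level prediction
#' probability, demographics (age, sex, education) and the average daily
#' keystroke count, all standardized, and reports coefficients with Wald
#' p-values. Education is coded ordinally (low < middle < high) as 0/1/2
#' before standardisation; sex is coded F = 0, M = 1. If the fit does not
#' converge or the data are separable, a weakly ridge-penalized refit is
#' returned with a flag (no Wald p-values are reported for a penalized fit).
#'
#' @param data data.frame with columns `status` (0/1), `prediction`, `age`,
#'   `sex`, `education`, `daily_keystroke`.
#' @return list with `coefficients` (data.frame: term, estimate, p_value),
#'   `converged`, `penalized`.
#' @export
kd_association_logistic <- function(data) {
  df <- as.data.frame(data)
  req <- c("status", "prediction", "age", "sex", "education", "daily_keystroke")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop_config("missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) < 20L) stop_config("need at least 20 subjects")
  edu <- match(df$education, c("low", "middle", "high")) - 1L
  if (anyNA(edu)) stop_config("education must be low/middle/high")
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  X <- data.frame(
    age = zs(df$age),
    education = zs(edu),
    gender = zs(as.integer(df$sex == "M")),
    daily_keystroke = zs(df$daily_keystroke),
    prediction = zs(df$prediction)
  )
  y <- as.integer(df$status)
  fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, X),
                                     family = stats::binomial()))
  separable <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8) ||
    any(abs(stats::coef(fit)[-1]) > 15)
  if (fit$converged && !separable) {
    sm <- summary(fit)$coefficients
    co <- data.frame(term = rownames(sm)[-1],
                     estimate = sm[-1, "Estimate"],
                     p_value = sm[-1, "Pr(>|z|)"],
                     row.names = NULL)
    return(list(coefficients = co, converged = TRUE, penalized = FALSE))
  }
  warning("separation or non-convergence: returning ridge-penalized refit",
          call. = FALSE)
  co <- ridge_logistic(as.matrix(X), y, lambda = 1)
  list(coefficients = data.frame(term = names(co), estimate = unname(co),
                                 p_value = NA_real_, row.names = NULL),
       converged = FALSE, penalized = TRUE)
}

# Ridge-penalized logistic regression by IRLS (intercept unpenalized);
# returns the slope coefficients.
ridge_logistic <- function(X, y, lambda = 1, max_iter = 100L, tol = 1e-8) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xd, Xd * w) + pen
    beta_new <- drop(solve(H, crossprod(Xd, w * z)))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  stats::setNames(beta[-1], colnames(X))
}

#' Pairwise correlogram with significance mask
#'
#' Pairwise Pearson correlations (complete pairwise observations) between
#' numeric columns, with per-cell p-values and a significance mask at the
#' chosen alpha. Cells with fewer than 3 complete pairs are marked missing.
#'
#' @param data data.frame of numeric columns.
#' @param alpha significance level for the mask.
#' @return list with matrices `r`, `p` and logical `significant`.
#' @export
kd_correlogram <- function(data, alpha = 0.05) {
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, logical(1))
  df <- df[, num, drop = FALSE]
  k <- ncol(df)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(df), names(df)))
  diag(r) <- 1; diag(p) <- 0
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        ok <- stats::complete.cases(df[[i]], df[[j]])
        if (sum(ok) >= 3L) {
          ct <- stats::cor.test(df[[i]][ok], df[[j]][ok])
          r[i, j] <- r[j, i] <- unname(ct$estimate)
          p[i, j] <- p[j, i] <- ct$p.value
        }
      }
    }
  }
  list(r = r, p = p, significant = !is.na(p) & p <= alpha)
}

#' Baseline keystroke volume per subject
#'
#' Average daily event count within a window centred on a given day (default
#' two weeks centred at baseline), for use in the correlogram and the
#' logistic association test.
#'
#' @param daily daily feature (or composite) table with `subject_id`, `day`,
#'   `event_count`.
#' @param center_day centre of the window.
#' @param half_width window half-width in days.
#' @return `data.table` with `subject_id`, `daily_keystroke`.
#' @export
kd_baseline_keystroke <- function(daily, center_day = 0L, half_width = 7L) {
  dt <- as.data.table(daily)
  dt[day >= center_day - half_width & day <= center_day + half_width,
     .(daily_keystroke = mean(event_count)), by = subject_id]
}
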