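test_that("2x2 exact test agrees with a direct hypergeometric-sum oracle", {
  set.seed(110)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8) + 1, 2, 2)
    p <- kd_fisher_exact(tab)$p_value
    # oracle: sum over the support of probabilities <= that of the observed
    rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
    lo <- max(0, cs[1] - rs[2]); hi <- min(rs[1], cs[1])
    probs <- dhyper(lo:hi, rs[1], rs[2], cs[1])
    p_obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
    p_oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    expect_equal(p, min(p_oracle, 1), tolerance = 1e-10)
  }
})

test_that("r x c exact test matches a Freeman-Halton enumeration oracle", {
  set.seed(111)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 6) + 1, 3, 2)
    expect_equal(kd_fisher_exact(tab)$p_value, freeman_halton_rx2(tab),
                 tolerance = 1e-8)
  }
  # identical row proportions: the observed table is the mode, p = 1
  expect_equal(kd_fisher_exact(matrix(c(10, 20, 10, 20), 2, 2))$p_value, 1)
  expect_warning(p0 <- kd_fisher_exact(matrix(c(0, 0, 3, 5), 2, 2, byrow = TRUE)),
                 "margin")
  expect_equal(p0$p_value, 1)
  expect_error(kd_fisher_exact(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
})

test_that("summary t-test reproduces hand-computed pooled and Welch results", {
  r <- kd_t_test_summary(5, 1, 10, 7, 1, 10, variant = "pooled")
  expect_equal(r$t, -4.472136, tolerance = 1e-6)
  expect_equal(r$df, 18)
  ident <- kd_t_test_summary(5, 2, 12, 5, 2, 12)
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)
  expect_error(kd_t_test_summary(1, 0, 10, 2, 1, 10), "positive")
  expect_error(kd_t_test_summary(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("summary t-test agrees with t.test on raw data with matching summaries", {
  set.seed(112)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.5)
    w <- kd_t_test_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    ref <- t.test(x, y)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
    p <- kd_t_test_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                           variant = "pooled")
    refp <- t.test(x, y, var.equal = TRUE)
    expect_equal(p$p_value, refp$p.value, tolerance = 1e-10)
  }
})

test_that("logistic association recovers an informative predictor", {
  set.seed(113)
  n <- 150
  status <- rbinom(n, 1, 0.5)
  df <- data.frame(
    status = status,
    prediction = status + rnorm(n, 0, 0.7),
    age = rnorm(n, 45, 10),
    sex = sample(c("F", "M"), n, TRUE),
    education = sample(c("low", "middle", "high"), n, TRUE),
    daily_keystroke = rnorm(n, 120, 30)
  )
  a <- kd_association_logistic(df)
  expect_true(a$converged)
  co <- a$coefficients
  pred_row <- co[co$term == "prediction", ]
  expect_gt(pred_row$estimate, 0)
  expect_lt(pred_row$p_value, 0.001)
})

test_that("logistic association matches an independent IRLS oracle", {
  set.seed(114)
  n <- 120
  status <- rbinom(n, 1, 0.5)
  df <- data.frame(status = status, prediction = status + rnorm(n),
                   age = rnorm(n), sex = sample(c("F", "M"), n, TRUE),
                   education = sample(c("low", "middle", "high"), n, TRUE),
                   daily_keystroke = rnorm(n))
  a <- kd_association_logistic(df)
  # oracle: direct Newton-Raphson on the standardized design
  zs <- function(x) (x - mean(x)) / sd(x)
  X <- cbind(1, age = zs(df$age),
             education = zs(match(df$education, c("low", "middle", "high")) - 1),
             gender = zs(as.integer(df$sex == "M")),
             daily_keystroke = zs(df$daily_keystroke),
             prediction = zs(df$prediction))
  beta <- rep(0, ncol(X))
  for (it in 1:50) {
    mu <- 1 / (1 + exp(-drop(X %*% beta)))
    W <- mu * (1 - mu)
    beta <- beta + solve(crossprod(X, X * W), crossprod(X, status - mu))
  }
  got <- a$coefficients$estimate[match(colnames(X)[-1], a$coefficients$term)]
  expect_equal(got, unname(beta[-1]), tolerance = 1e-6)
})

test_that("pure-noise covariates reach nominal type-I error rates", {
  set.seed(115)
  hits <- 0L; n_sim <- 150L
  for (i in seq_len(n_sim)) {
    n <- 60
    df <- data.frame(status = rbinom(n, 1, 0.5), prediction = rnorm(n),
                     age = rnorm(n), sex = sample(c("F", "M"), n, TRUE),
                     education = sample(c("low", "middle", "high"), n, TRUE),
                     daily_keystroke = rnorm(n))
    a <- suppressWarnings(kd_association_logistic(df))
    if (a$converged) {
      p <- a$coefficients$p_value[a$coefficients$term == "prediction"]
      hits <- hits + (p < 0.05)
    }
  }
  expect_gt(hits / n_sim, 0.01)
  expect_lt(hits / n_sim, 0.11)
})

test_that("separation triggers the flagged penalized refit", {
  n <- 40
  df <- data.frame(status = rep(c(0, 1), each = n / 2),
                   prediction = rep(c(-3, 3), each = n / 2),
                   age = rnorm(n), sex = sample(c("F", "M"), n, TRUE),
                   education = sample(c("low", "middle", "high"), n, TRUE),
                   daily_keystroke = rnorm(n))
  expect_warning(a <- kd_association_logistic(df), "separation|converge")
  expect_false(a$converged)
  expect_true(a$penalized)
  expect_gt(a$coefficients$estimate[a$coefficients$term == "prediction"], 0)
})

test_that("correlogram is symmetric with unit diagonal and masks by p-value", {
  set.seed(116)
  n <- 500
  df <- data.frame(a = rnorm(n))
  df$b <- df$a + rnorm(n, 0, 0.5)
  df$c <- rnorm(n)
  cg <- kd_correlogram(df)
  expect_equal(cg$r, t(cg$r))
  expect_equal(unname(diag(cg$r)), rep(1, 3))
  expect_true(cg$significant["a", "b"])
  expect_lt(abs(cg$r["a", "c"]), 0.12)
  expect_lt(abs(cg$r["b", "c"]), 0.12)
})

test_that("baseline keystroke volume averages the two-week window around m00", {
  daily <- data.frame(subject_id = rep("S1", 30), day = 0:29,
                      event_count = c(rep(100, 8), rep(200, 22)))
  b <- kd_baseline_keystroke(daily, center_day = 0, half_width = 7)
  expect_equal(b$daily_keystroke, 100)
})
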