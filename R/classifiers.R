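# Classifier menu behind the ensemble: each entry knows how to fit on a
# standardized numeric matrix with 0/1 labels (optionally with balanced class
# weights) and how to return P(class = 1). Margin classifiers (SVM) get a
# Platt-style sigmoid calibration fitted on the training decision values.

KD_CLASSIFIERS <- c("lr", "rf", "qda", "gnb", "svm", "knn")

balanced_weights <- function(y) {
  n <- length(y)
  w1 <- n / (2 * sum(y == 1L))
  w0 <- n / (2 * sum(y == 0L))
  ifelse(y == 1L, w1, w0)
}

#' Fit a single member classifier
#'
#' @param name one of `"lr"` (logistic regression), `"rf"` (random forest),
#'   `"qda"` (quadratic discriminant analysis), `"gnb"` (Gaussian naive
#'   Bayes), `"svm"` (support-vector machine with Platt-calibrated
#'   probabilities), `"knn"` (k-nearest neighbours).
#' @param X numeric feature matrix (complete, standardized).
#' @param y 0/1 labels.
#' @param balanced use class weights (or balanced priors) inversely
#'   proportional to class frequency.
#' @param seed integer seed for the stochastic members.
#' @return object of class `kd_classifier`.
#' @export
kd_fit_classifier <- function(name, X, y, balanced = TRUE, seed = 1L) {
  name <- match.arg(name, KD_CLASSIFIERS)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_config("training labels contain one class")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  w <- if (balanced) balanced_weights(y) else rep(1, length(y))
  model <- switch(
    name,
    lr = {
      df <- data.frame(y = y, X, check.names = FALSE)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial(),
                                  weights = w))
    },
    rf = {
      ranger::ranger(x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = 300L,
                     case.weights = w, seed = as.integer(seed),
                     num.threads = 1L)
    },
    qda = {
      MASS::qda(X, grouping = factor(y, levels = c(0, 1)),
                prior = if (balanced) c(0.5, 0.5) else table(y) / length(y))
    },
    gnb = {
      fit <- e1071::naiveBayes(x = as.data.frame(X),
                               y = factor(y, levels = c(0, 1)))
      list(fit = fit, prior_train = mean(y == 1L), balanced = balanced)
    },
    svm = {
      fit <- with_seed(seed, e1071::svm(
        x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
        scale = FALSE,
        class.weights = if (balanced) {
          n <- length(y)
          c("0" = n / (2 * sum(y == 0L)), "1" = n / (2 * sum(y == 1L)))
        } else NULL))
      dv <- drop(attr(stats::predict(fit, X, decision.values = TRUE),
                      "decision.values"))
      # sign so that larger decision value means class 1
      r <- suppressWarnings(stats::cor(dv, y))
      sgn <- if (is.finite(r) && r < 0) -1 else 1
      platt <- suppressWarnings(stats::glm(y ~ dv,
                                           data = data.frame(y = y, dv = sgn * dv),
                                           family = stats::binomial()))
      list(fit = fit, platt = stats::coef(platt), sgn = sgn)
    },
    knn = {
      list(X = X, y = y, k = min(11L, length(y) - 1L))
    }
  )
  structure(list(name = name, model = model, features = colnames(X)),
            class = "kd_classifier")
}

#' Predict class-1 probabilities from a fitted member classifier
#'
#' @param object a `kd_classifier`.
#' @param X numeric matrix of rows to score.
#' @return numeric vector of probabilities in [0, 1].
#' @export
kd_predict_prob <- function(object, X) {
  stopifnot(inherits(object, "kd_classifier"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- object$features
  X <- X[, object$features, drop = FALSE]
  m <- object$model
  p <- switch(
    object$name,
    lr = {
      as.numeric(stats::predict(m, newdata = as.data.frame(X), type = "response"))
    },
    rf = stats::predict(m, data = as.data.frame(X),
                        num.threads = 1L)$predictions[, "1"],
    qda = stats::predict(m, X)$posterior[, "1"],
    gnb = {
      post <- stats::predict(m$fit, as.data.frame(X), type = "raw")[, "1"]
      if (m$balanced) {
        pi1 <- m$prior_train
        num <- post / pi1
        den <- num + (1 - post) / (1 - pi1)
        num / den
      } else post
    },
    svm = {
      dv <- m$sgn * drop(attr(stats::predict(m$fit, X, decision.values = TRUE),
                              "decision.values"))
      1 / (1 + exp(-(m$platt[1] + m$platt[2] * dv)))
    },
    knn = {
      pr <- class::knn(train = m$X, test = X,
                       cl = factor(m$y, levels = c(0, 1)), k = m$k, prob = TRUE)
      vote <- attr(pr, "prob")
      ifelse(pr == "1", vote, 1 - vote)
    }
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Fit a soft-voting ensemble
#'
#' Trains each member of the menu independently and combines them by
#' unweighted averaging of predicted probabilities (soft voting). Members are
#' trained with balanced class weights by default to counteract class
#' imbalance.
#'
#' @param X,y,balanced,seed as in [kd_fit_classifier()].
#' @param menu character vector of member names.
#' @return object of class `kd_ensemble`.
#' @export
kd_fit_ensemble <- function(X, y, menu = c("lr", "gnb", "svm"),
                            balanced = TRUE, seed = 1L) {
  if (!length(menu)) stop_config("classifier menu must be non-empty")
  members <- lapply(seq_along(menu), function(i) {
    kd_fit_classifier(menu[i], X, y, balanced = balanced, seed = seed + i)
  })
  structure(list(members = members, menu = menu), class = "kd_ensemble")
}

#' Soft-voting ensemble probabilities
#'
#' @param object a `kd_ensemble`.
#' @param X matrix of rows to score.
#' @return per-row mean of member probabilities.
#' @export
kd_predict_ensemble <- function(object, X) {
  stopifnot(inherits(object, "kd_ensemble"))
  probs <- sapply(object$members, function(mem) kd_predict_prob(mem, X))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}
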