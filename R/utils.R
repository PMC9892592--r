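#' @importFrom stats median sd quantile rnorm runif rbeta rpois rgeom rlnorm
#'   rbinom glm binomial coef predict var cor complete.cases pnorm pt qnorm
#'   fisher.test cor.test setNames lm.fit
#' @importFrom utils head tail
#' @import data.table
#' @importFrom Rcpp evalCpp
#' @useDynLib keydyn, .registration = TRUE
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded pipeline stages never interfere.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config("`%s` must be a single probability in [0, 1]", name)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_config("`%s` must be a single positive number", name)
  }
  invisible(x)
}

#' Summary-statistic registry for daily aggregation
#'
#' Named list of summary statistics applied to each keystroke sequence when
#' aggregating to the subject-day level. The default set covers central
#' tendency (mean, median), dispersion (standard deviation, interquartile
#' range) and the upper tail (maximum, 95th percentile). Any named list of
#' functions mapping a numeric vector to a scalar can be supplied instead, so
#' alternative statistic sets are reproducible by configuration.
#'
#' @param stats optional character vector selecting a subset of the default
#'   statistics by name.
#' @return named list of functions.
#' @export
kd_stat_registry <- function(stats = NULL) {
  reg <- list(
    mean   = function(x) mean(x),
    median = function(x) stats::median(x),
    sd     = function(x) stats::sd(x),
    iqr    = function(x) stats::quantile(x, 0.75, names = FALSE) -
                         stats::quantile(x, 0.25, names = FALSE),
    max    = function(x) max(x),
    p95    = function(x) stats::quantile(x, 0.95, names = FALSE)
  )
  if (is.null(stats)) return(reg)
  unknown <- setdiff(stats, names(reg))
  if (length(unknown)) {
    stop_config("unknown statistic name(s): %s", paste(unknown, collapse = ", "))
  }
  reg[stats]
}

KD_KEY_CLASSES <- c("alphanumeric", "backspace", "punctuation", "space", "suggestion")
KD_SEQUENCES <- c("HT", "FT", "PPL", "RRL", "APP", "PreCS", "PostCS")
MS_PER_DAY <- 86400000
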