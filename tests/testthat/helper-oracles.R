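# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (loops, enumeration) so they share no code with the
# package's vectorised implementations.

# Random single-session-or-multi-session event stream with known structure.
random_stream <- function(n, seed = NULL, gap_prob = 0.05,
                          classes = c("alphanumeric", "backspace",
                                      "punctuation", "space")) {
  if (!is.null(seed)) set.seed(seed)
  ht <- runif(n, 40, 300)
  gap <- runif(n - 1, 20, 800)
  long <- runif(n - 1) < gap_prob
  gap[long] <- runif(sum(long), 61000, 120000)  # session breaks
  press <- numeric(n)
  press[1] <- runif(1, 0, 1000)
  for (i in seq_len(n - 1)) press[i + 1] <- press[i] + ht[i] + gap[i]
  data.frame(
    t_press_ms = press,
    t_release_ms = press + ht,
    key_class = sample(classes, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Naive per-index scan computing the seven sequences straight from the
# defining differences, breaking chains at gaps > gap_ms.
scan_sequences <- function(ev, gap_ms = 60000) {
  ev <- ev[ev$key_class != "suggestion", ]
  n <- nrow(ev)
  out <- list(HT = numeric(0), FT = numeric(0), PPL = numeric(0),
              RRL = numeric(0), APP = numeric(0), PreCS = numeric(0),
              PostCS = numeric(0))
  for (i in seq_len(n)) out$HT <- c(out$HT, ev$t_release_ms[i] - ev$t_press_ms[i])
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      ft <- ev$t_press_ms[i + 1] - ev$t_release_ms[i]
      if (ft > gap_ms) next
      out$FT <- c(out$FT, ft)
      out$PPL <- c(out$PPL, ev$t_press_ms[i + 1] - ev$t_press_ms[i])
      out$RRL <- c(out$RRL, ev$t_release_ms[i + 1] - ev$t_release_ms[i])
      if (ev$key_class[i] == "punctuation") out$APP <- c(out$APP, ft)
      if (ev$key_class[i + 1] == "backspace") out$PreCS <- c(out$PreCS, ft)
      if (ev$key_class[i] == "backspace") out$PostCS <- c(out$PostCS, ft)
    }
  }
  out
}

# Brute-force AUC: count concordant pairs, ties as 1/2.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Freeman-Halton enumeration for r x 2 tables with fixed margins:
# two-sided p = sum of probabilities of tables no more probable than observed.
freeman_halton_rx2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(ncol(tab) == 2)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  logp <- function(first_col) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
      sum(lgamma(first_col + 1)) - sum(lgamma(rs - first_col + 1))
  }
  grids <- lapply(rs, function(r) 0:r)
  combos <- expand.grid(grids)
  keep <- rowSums(combos) == cs[1]
  combos <- combos[keep, , drop = FALSE]
  lp <- apply(combos, 1, function(x) logp(as.numeric(x)))
  lp_obs <- logp(tab[, 1])
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}

# Shapley values via the permutation definition (all f! orders).
permutation_shapley <- function(f, x, background) {
  d <- length(x)
  v <- function(S) {
    M <- background
    for (j in S) M[, j] <- x[j]
    mean(f(M))
  }
  perms <- matrix(unlist(all_perms(seq_len(d))), ncol = d, byrow = TRUE)
  phi <- numeric(d)
  for (r in seq_len(nrow(perms))) {
    S <- integer(0)
    for (j in perms[r, ]) {
      phi[j] <- phi[j] + v(c(S, j)) - v(S)
      S <- c(S, j)
    }
  }
  phi / nrow(perms)
}

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Tiny cohort configuration used to keep pipeline tests fast.
micro_config <- function(...) {
  kd_cohort_config(n_hc = 8, n_ms = 16, study_days = 100,
                   visit_days = c(0L, 30L, 60L, 90L), hc_followup_mean = 50,
                   ...)
}
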