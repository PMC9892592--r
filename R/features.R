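#' Derive the four timing sequences from an ordered keystroke stream
#'
#' For `N` keys pressed in an interval, with press/release timestamps
#' \eqn{t_n^p, t_n^r}:
#' \deqn{HT_n = t_n^r - t_n^p,\quad n = 1..N}
#' \deqn{FT_n = t_{n+1}^p - t_n^r,\quad PPL_n = t_{n+1}^p - t_n^p,\quad
#'       RRL_n = t_{n+1}^r - t_n^r,\quad n = 1..N-1}
#' Session boundaries (a gap longer than `session_gap_ms` between a release
#' and the next press) break the chain: FT/PPL/RRL are never computed across
#' sessions. Suggestion-button taps are not typing-rhythm keys and are
#' excluded before any sequence is formed.
#'
#' @param events data.frame/data.table with columns `t_press_ms`,
#'   `t_release_ms`, `key_class`, ordered by press time.
#' @param session_gap_ms release-to-press gap starting a new session.
#' @return list of class `kd_sequences` with elements `HT`, `FT`, `PPL`,
#'   `RRL`, `APP`, `PreCS`, `PostCS` (numeric vectors, ms) and `n_keys`.
#' @export
kd_derive_sequences <- function(events, session_gap_ms = 60000) {
  ev <- as.data.table(events)
  if (nrow(ev) == 0L) {
    return(structure(c(setNames(rep(list(numeric()), 7L), KD_SEQUENCES),
                       list(n_keys = 0L)), class = "kd_sequences"))
  }
  required <- c("t_press_ms", "t_release_ms", "key_class")
  missing_cols <- setdiff(required, names(ev))
  if (length(missing_cols)) {
    stop_config("event table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (is.unsorted(ev$t_press_ms)) {
    stop_config("events must be ordered by press time")
  }
  if (any(ev$t_release_ms < ev$t_press_ms)) {
    stop_config("release time before press time")
  }
  ev <- ev[key_class != "suggestion"]
  n <- nrow(ev)
  if (n == 0L) {
    return(structure(c(setNames(rep(list(numeric()), 7L), KD_SEQUENCES),
                       list(n_keys = 0L)), class = "kd_sequences"))
  }
  ht <- ev$t_release_ms - ev$t_press_ms
  if (n == 1L) {
    out <- c(list(HT = ht), setNames(rep(list(numeric()), 6L), KD_SEQUENCES[-1]),
             list(n_keys = 1L))
    return(structure(out, class = "kd_sequences"))
  }
  ft  <- ev$t_press_ms[-1L] - ev$t_release_ms[-n]
  ppl <- ev$t_press_ms[-1L] - ev$t_press_ms[-n]
  rrl <- ev$t_release_ms[-1L] - ev$t_release_ms[-n]
  same_session <- ft <= session_gap_ms
  prev_class <- ev$key_class[-n]
  next_class <- ev$key_class[-1L]
  structure(list(
    HT = ht,
    FT = ft[same_session],
    PPL = ppl[same_session],
    RRL = rrl[same_session],
    APP = ft[same_session & prev_class == "punctuation"],
    PreCS = ft[same_session & next_class == "backspace"],
    PostCS = ft[same_session & prev_class == "backspace"],
    n_keys = n
  ), class = "kd_sequences")
}

#' Derive only the event-conditioned flight-time sequences
#'
#' Convenience accessor returning the After Punctuation Pause (flight time
#' following a punctuation key), Pre-Correction Slowing (flight time
#' immediately before a backspace) and Post-Correction Slowing (flight time
#' immediately after a backspace).
#'
#' @inheritParams kd_derive_sequences
#' @return list with elements `APP`, `PreCS`, `PostCS`.
#' @export
kd_conditional_sequences <- function(events, session_gap_ms = 60000) {
  s <- kd_derive_sequences(events, session_gap_ms)
  s[c("APP", "PreCS", "PostCS")]
}

#' Outlier filter configuration for keystroke sequences
#'
#' Per-sequence inclusive `[min, max]` retention bounds in milliseconds.
#' Defaults keep hold times in (0, 2000] and flight times (and therefore the
#' flight-time-derived conditional sequences) in [0, 5000]; negative flight
#' times (key rollover) are dropped, as are press-press/release-release
#' latencies outside [0, 7000]. Long gaps from an on-screen idle keyboard fall
#' outside these bounds and are removed before aggregation.
#'
#' @param ht,ft,ppl,rrl numeric length-2 bounds for the respective sequences;
#'   conditional sequences inherit the `ft` bounds.
#' @return object of class `kd_filter_config`.
#' @export
kd_filter_config <- function(ht = c(1e-9, 2000), ft = c(0, 5000),
                             ppl = c(0, 7000), rrl = c(0, 7000)) {
  bounds <- list(HT = ht, FT = ft, PPL = ppl, RRL = rrl,
                 APP = ft, PreCS = ft, PostCS = ft)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !is.numeric(b) || b[1] > b[2]) {
      stop_config("invalid bounds for %s: min must be <= max", nm)
    }
  }
  structure(bounds, class = "kd_filter_config")
}

#' Remove out-of-bounds values from keystroke sequences
#'
#' Applies the `[min, max]` retention bounds of a [kd_filter_config()] to each
#' sequence; conditional sequences are governed by the flight-time bounds, so
#' a filtered-out flight time never survives as an APP/PreCS/PostCS value.
#' The operation is idempotent. Counts of removed values are attached as the
#' `"removed"` attribute.
#'
#' @param seqs a `kd_sequences` list.
#' @param rules a [kd_filter_config()].
#' @return filtered `kd_sequences`.
#' @export
kd_filter_outliers <- function(seqs, rules = kd_filter_config()) {
  stopifnot(inherits(seqs, "kd_sequences"))
  if (!inherits(rules, "kd_filter_config")) {
    stop_config("`rules` must be a kd_filter_config")
  }
  removed <- integer(0)
  out <- seqs
  for (nm in KD_SEQUENCES) {
    b <- rules[[nm]]
    x <- seqs[[nm]]
    keep <- x >= b[1] & x <= b[2]
    out[[nm]] <- x[keep]
    removed[nm] <- sum(!keep)
  }
  attr(out, "removed") <- removed
  out
}

# Per-group (integer subject-day key) summary statistics of one sequence's
# values. Statistics named like the defaults are computed vectorised (grouped
# mean/median/sd/max plus order-statistic quantiles on the sorted table);
# any unrecognised statistic name falls back to a generic per-group apply.
aggregate_one_sequence <- function(skey, value, stats, prefix,
                                   sorted = !is.unsorted(skey)) {
  fast_names <- c("mean", "median", "sd", "iqr", "max", "p95")
  if (all(names(stats) %in% fast_names) && sorted) {
    res <- .group_seq_stats(value, skey)
    agg <- data.table::setDT(res[c("skey", names(stats))])
  } else {
    dt <- data.table(skey = skey, value = value)
    agg <- dt[, {
      vals <- lapply(stats, function(f) as.numeric(f(value)))
      names(vals) <- names(stats)
      vals
    }, by = skey]
  }
  data.table::setnames(agg, names(stats), paste(prefix, names(stats), sep = "_"))
  agg
}

#' Aggregate a keystroke event log into daily features
#'
#' The main feature-engineering entry point: derives the seven keystroke
#' sequences per subject-day (sessions never crossing the configured idle
#' gap), filters outliers, and aggregates each sequence with every statistic
#' of the registry, alongside count features (total events, backspaces,
#' suggestion-button uses). One row is emitted per subject-day with any
#' events; the statistic of an empty sequence is missing (`NA`), never zero.
#'
#' @param events event log (`subject_id, day, t_press_ms, t_release_ms,
#'   key_class`), e.g. from [kd_simulate_cohort()] or read from CSV.
#' @param filter a [kd_filter_config()].
#' @param stats a statistic registry from [kd_stat_registry()].
#' @param session_gap_ms idle gap defining session boundaries.
#' @return `data.table` with one row per subject-day: `subject_id`, `day`,
#'   `<sequence>_<stat>` columns, `event_count`, `backspace_count`,
#'   `suggestion_count`.
#' @export
kd_featurize <- function(events, filter = kd_filter_config(),
                         stats = kd_stat_registry(), session_gap_ms = 60000) {
  if (!length(stats)) stop_config("statistic registry must be non-empty")
  ev <- as.data.table(events)
  feat_cols <- as.vector(outer(KD_SEQUENCES, names(stats), paste, sep = "_"))
  if (nrow(ev) == 0L) {
    empty <- data.table(subject_id = character(), day = integer())
    for (cn in feat_cols) empty[, (cn) := numeric()]
    empty[, `:=`(event_count = integer(), backspace_count = integer(),
                 suggestion_count = integer())]
    return(empty)
  }
  if (data.table::is.data.table(events)) ev <- data.table::copy(ev)
  data.table::setorder(ev, subject_id, t_press_ms)
  # single integer subject-day key for the hot aggregation path
  subjects <- unique(ev$subject_id)
  kmul <- max(ev$day) + 1L
  ev[, skey := (data.table::chmatch(subject_id, subjects) - 1L) * kmul + day]
  counts <- ev[, .(event_count = .N,
                   backspace_count = sum(key_class == "backspace"),
                   suggestion_count = sum(key_class == "suggestion")),
               by = skey]
  out <- counts
  typing <- ev[key_class != "suggestion"]
  if (nrow(typing)) {
    is_punct <- typing$key_class == "punctuation"
    is_bksp <- typing$key_class == "backspace"
    typing[, ht := t_release_ms - t_press_ms]
    typing[, bk := is_bksp]
    typing[, `:=`(
      ft  = data.table::shift(t_press_ms, -1L) - t_release_ms,
      ppl = data.table::shift(t_press_ms, -1L) - t_press_ms,
      rrl = data.table::shift(t_release_ms, -1L) - t_release_ms,
      pre_bksp = data.table::shift(bk, -1L)
    ), by = subject_id]
    typing[!is.na(ft) & ft > session_gap_ms,
           c("ft", "ppl", "rrl") := NA_real_]
    in_pair <- !is.na(typing$ft)
    pick <- list(
      HT = list(col = "ht", sel = NULL),
      FT = list(col = "ft", sel = in_pair),
      PPL = list(col = "ppl", sel = in_pair),
      RRL = list(col = "rrl", sel = in_pair),
      APP = list(col = "ft", sel = in_pair & is_punct),
      PreCS = list(col = "ft", sel = in_pair & typing$pre_bksp),
      PostCS = list(col = "ft", sel = in_pair & is_bksp)
    )
    for (nm in KD_SEQUENCES) {
      b <- filter[[nm]]
      v <- typing[[pick[[nm]]$col]]
      keep <- v >= b[1] & v <= b[2]
      if (!is.null(pick[[nm]]$sel)) keep <- keep & pick[[nm]]$sel
      keep[is.na(keep)] <- FALSE
      if (!any(keep)) next
      out <- merge(out,
                   aggregate_one_sequence(typing$skey[keep], v[keep], stats, nm,
                                          sorted = TRUE),
                   by = "skey", all.x = TRUE)
    }
  }
  out[, `:=`(subject_id = subjects[skey %/% kmul + 1L], day = skey %% kmul)]
  out[, skey := NULL]
  for (cn in setdiff(feat_cols, names(out))) out[, (cn) := NA_real_]
  data.table::setcolorder(out, c("subject_id", "day", feat_cols,
                                 "event_count", "backspace_count",
                                 "suggestion_count"))
  data.table::setorder(out, subject_id, day)
  out[]
}
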