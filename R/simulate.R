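#' Cohort configuration for the synthetic keystroke generator
#'
#' Defines the statistical structure of a simulated remote-monitoring cohort:
#' group sizes, follow-up schedule, the latency model linking a latent
#' disability severity trait to typing timings, session/volume structure, and
#' the noise models tying the same trait to the clinical outcome scales
#' (EDSS, NHPT, SDMT).
#'
#' The latency model is log-normal: for a subject with latent severity
#' \eqn{s \in [0,1]}, the subject-level log-mean of hold (flight) times is
#' shifted by `effect_hold * sdlog_hold * s` (`effect_flight * sdlog_flight *
#' s`) relative to the population baseline, plus an idiosyncratic subject
#' offset with standard deviation `subject_sd` and a per-day offset with
#' standard deviation `day_sd`. Setting both effects to zero yields a null
#' cohort in which typing carries no information about severity or group.
#'
#' @param n_hc,n_ms number of healthy controls / people with MS.
#' @param study_days length of follow-up for pwMS in days.
#' @param visit_days day indices of the five 3-monthly clinical visits (pwMS
#'   only).
#' @param hc_followup_mean mean number of observed days for controls.
#' @param base_hold_ms,base_flight_ms population median hold / flight time in
#'   milliseconds at severity 0.
#' @param sdlog_hold,sdlog_flight log-scale standard deviation of single-key
#'   hold / flight times.
#' @param effect_hold,effect_flight severity effect on the log-mean, in units
#'   of the corresponding log-scale SD per unit severity.
#' @param subject_sd,day_sd idiosyncratic subject-level and day-level
#'   log-mean standard deviations.
#' @param sessions_per_day_mean Poisson mean number of typing sessions per
#'   active day.
#' @param session_len_mean,min_session_len mean and minimum number of keys per
#'   session (geometric tail above the minimum).
#' @param active_day_prob probability that a subject types at all on a given
#'   day (the source of day-level missingness).
#' @param punctuation_rate,backspace_rate,space_rate,suggestion_rate expected
#'   key-class proportions; the remainder is alphanumeric.
#' @param nhpt_base,nhpt_slope,nhpt_sd NHPT (seconds) at severity 0, its
#'   increase per unit severity, and visit-level noise SD.
#' @param sdmt_max,sdmt_slope,sdmt_sd SDMT score at severity 0, its decrease
#'   per unit severity, and visit-level noise SD.
#' @param edss_base,edss_slope,edss_sd EDSS at severity 0, increase per unit
#'   severity, and visit-level noise SD (result rounded to the half-point
#'   scale and clipped to [0, 7]).
#' @return object of class `kd_cohort_config`.
#' @export
kd_cohort_config <- function(n_hc = 24L, n_ms = 102L,
                             study_days = 365L,
                             visit_days = c(0L, 91L, 182L, 273L, 364L),
                             hc_followup_mean = 88,
                             base_hold_ms = 180, base_flight_ms = 250,
                             sdlog_hold = 0.35, sdlog_flight = 0.6,
                             effect_hold = 0.25, effect_flight = 0.25,
                             subject_sd = 0.03, day_sd = 0.04,
                             sessions_per_day_mean = 4,
                             session_len_mean = 20, min_session_len = 5L,
                             active_day_prob = 0.85,
                             punctuation_rate = 0.08, backspace_rate = 0.08,
                             space_rate = 0.15, suggestion_rate = 0.03,
                             nhpt_base = 17, nhpt_slope = 8, nhpt_sd = 0.8,
                             sdmt_max = 68, sdmt_slope = 25, sdmt_sd = 5,
                             edss_base = 1, edss_slope = 6, edss_sd = 0.7) {
  if (!is.numeric(n_hc) || !is.numeric(n_ms) || n_hc < 0 || n_ms < 0) {
    stop_config("group sizes must be non-negative")
  }
  if (n_hc + n_ms > 0) check_positive(study_days, "study_days")
  check_positive(base_hold_ms, "base_hold_ms")
  check_positive(base_flight_ms, "base_flight_ms")
  check_scalar_prob(active_day_prob, "active_day_prob")
  for (nm in c("punctuation_rate", "backspace_rate", "space_rate", "suggestion_rate")) {
    check_scalar_prob(get(nm), nm)
  }
  if (punctuation_rate + backspace_rate + space_rate + suggestion_rate >= 1) {
    stop_config("key-class rates must sum to less than 1")
  }
  if (session_len_mean < min_session_len) {
    stop_config("session_len_mean must be >= min_session_len")
  }
  cfg <- as.list(environment())
  cfg <- cfg[!vapply(cfg, is.function, logical(1))]
  cfg$n_hc <- as.integer(n_hc)
  cfg$n_ms <- as.integer(n_ms)
  cfg$study_days <- as.integer(study_days)
  cfg$visit_days <- as.integer(visit_days)
  structure(cfg, class = "kd_cohort_config")
}

#' Construct a subject typing profile
#'
#' A profile bundles everything the per-day event simulator needs for one
#' subject: group, latent severity, subject-specific base latencies,
#' key-class usage rates, session structure and demographics.
#'
#' @param subject_id character id.
#' @param group `"HC"` or `"MS"`.
#' @param latent_severity severity trait in [0, 1] (controls sit in the low
#'   stratum).
#' @param base_hold_ms,base_flight_ms subject-level median latencies (already
#'   including any severity effect).
#' @param sdlog_hold,sdlog_flight,day_sd log-normal shape parameters, see
#'   [kd_cohort_config()].
#' @param punctuation_rate,backspace_rate,space_rate,suggestion_rate key-class
#'   rates.
#' @param sessions_per_day_mean,session_len_mean,min_session_len session
#'   structure.
#' @param active_day_prob probability of any typing on a day.
#' @param age,sex,education demographics (`sex` in `{"F","M"}`, `education`
#'   in `{"low","middle","high"}`).
#' @return object of class `kd_subject_profile`.
#' @export
kd_subject_profile <- function(subject_id, group = c("MS", "HC"),
                               latent_severity = 0,
                               base_hold_ms = 180, base_flight_ms = 250,
                               sdlog_hold = 0.35, sdlog_flight = 0.6,
                               day_sd = 0.04,
                               punctuation_rate = 0.08, backspace_rate = 0.08,
                               space_rate = 0.15, suggestion_rate = 0.03,
                               sessions_per_day_mean = 5,
                               session_len_mean = 25, min_session_len = 5L,
                               active_day_prob = 0.85,
                               age = 45, sex = "F", education = "middle") {
  group <- match.arg(group)
  check_scalar_prob(latent_severity, "latent_severity")
  check_positive(base_hold_ms, "base_hold_ms")
  check_positive(base_flight_ms, "base_flight_ms")
  check_scalar_prob(active_day_prob, "active_day_prob")
  p <- as.list(environment())
  structure(p, class = "kd_subject_profile")
}

# Vectorised event generation for one subject over a vector of candidate day
# indices; uses the current RNG stream. Returns a data.table in event-log
# schema (possibly zero rows).
gen_subject_events <- function(profile, days, apply_active_prob = TRUE) {
  p <- profile
  days <- as.integer(days)
  if (length(days) == 0L) return(empty_event_log())
  if (apply_active_prob) {
    days <- days[stats::runif(length(days)) < p$active_day_prob]
  }
  if (length(days) == 0L) return(empty_event_log())
  ns <- stats::rpois(length(days), p$sessions_per_day_mean)
  keep <- ns > 0L
  days <- days[keep]; ns <- ns[keep]
  if (length(days) == 0L) return(empty_event_log())
  day_eff <- stats::rnorm(length(days), 0, p$day_sd)

  sess_day <- rep(days, ns)
  sess_day_eff <- rep(day_eff, ns)
  n_sess <- length(sess_day)
  geo_extra <- p$session_len_mean - p$min_session_len
  len <- p$min_session_len +
    if (geo_extra > 0) stats::rgeom(n_sess, 1 / (geo_extra + 1)) else 0L
  n_keys <- sum(len)

  sess_id <- rep(seq_len(n_sess), len)
  key_day_eff <- rep(sess_day_eff, len)
  mu_h <- log(p$base_hold_ms) + key_day_eff
  mu_f <- log(p$base_flight_ms) + key_day_eff
  ht <- stats::rlnorm(n_keys, mu_h, p$sdlog_hold)
  ft <- stats::rlnorm(n_keys, mu_f, p$sdlog_flight)  # gap following each key

  probs <- c(p$punctuation_rate, p$backspace_rate, p$space_rate,
             p$suggestion_rate)
  probs <- c(1 - sum(probs), probs)
  key_class <- sample(c("alphanumeric", "punctuation", "backspace", "space",
                        "suggestion"), n_keys, replace = TRUE, prob = probs)

  dt <- data.table(sess = sess_id, ht = ht, ft = ft)
  dt[, off := cumsum(data.table::shift(ht + ft, fill = 0)), by = sess]
  dur <- dt[, .(dur = off[.N] + ht[.N]), by = sess]$dur

  # Sessions are laid out sequentially within each day: a morning offset plus
  # inter-session gaps (>= 61 s so the featurizer's session detector, with its
  # 60 s rule, recovers the generated sessions).
  sess_dt <- data.table(day = sess_day, dur = dur)
  sess_dt[, gap := 61000 + stats::rexp(.N, 1 / 3600000)]
  sess_dt[, start0 := stats::runif(1, 0, 7200000) +
            cumsum(data.table::shift(dur + gap, fill = 0)), by = day]
  start_abs <- sess_dt$day * MS_PER_DAY + sess_dt$start0

  press <- rep(start_abs, len) + dt$off
  release <- press + dt$ht
  out <- data.table(
    subject_id = p$subject_id,
    day = as.integer(press %/% MS_PER_DAY),
    t_press_ms = press,
    t_release_ms = release,
    key_class = key_class
  )
  data.table::setorder(out, t_press_ms)
  out[]
}

# Batched event generation for a whole cohort whose subjects share the
# config's key-class rates and session structure; only the base latencies
# differ per subject. Statistically identical to calling the per-subject
# generator day by day, but one vectorised pass over all keys.
gen_cohort_events <- function(config, ids, base_h, base_f, followup) {
  n <- length(ids)
  sub_day <- data.table(si = rep(seq_len(n), followup),
                        day = unlist(lapply(followup, function(f) seq_len(f) - 1L)))
  sub_day <- sub_day[stats::runif(nrow(sub_day)) < config$active_day_prob]
  if (!nrow(sub_day)) return(empty_event_log())
  sub_day[, ns := stats::rpois(.N, config$sessions_per_day_mean)]
  sub_day <- sub_day[ns > 0L]
  if (!nrow(sub_day)) return(empty_event_log())
  sub_day[, day_eff := stats::rnorm(.N, 0, config$day_sd)]
  sub_day[, gkey := .I]

  sess <- sub_day[rep(seq_len(.N), ns)]
  n_sess <- nrow(sess)
  geo_extra <- config$session_len_mean - config$min_session_len
  sess[, len := config$min_session_len +
         if (geo_extra > 0) stats::rgeom(.N, 1 / (geo_extra + 1)) else 0L]

  key <- sess[rep(seq_len(.N), len), .(si, day, day_eff, gkey)]
  key[, sess_id := rep(seq_len(n_sess), sess$len)]
  n_keys <- nrow(key)
  ht <- stats::rlnorm(n_keys, log(base_h[key$si]) + key$day_eff, config$sdlog_hold)
  ft <- stats::rlnorm(n_keys, log(base_f[key$si]) + key$day_eff, config$sdlog_flight)
  probs <- c(config$punctuation_rate, config$backspace_rate, config$space_rate,
             config$suggestion_rate)
  probs <- c(1 - sum(probs), probs)
  key_class <- sample(c("alphanumeric", "punctuation", "backspace", "space",
                        "suggestion"), n_keys, replace = TRUE, prob = probs)

  key[, c("ht", "ftg") := list(ht, ft)]
  key[, off := cumsum(data.table::shift(ht + ftg, fill = 0)), by = sess_id]
  sess[, dur := key[, .(d = off[.N] + ht[.N]), by = sess_id]$d]
  sess[, gap := 61000 + stats::rexp(.N, 1 / 3600000)]
  sess[, start0 := stats::runif(1, 0, 7200000) +
         cumsum(data.table::shift(dur + gap, fill = 0)), by = gkey]
  start_abs <- sess$day * MS_PER_DAY + sess$start0

  press <- start_abs[key$sess_id] + key$off
  out <- data.table(
    subject_id = ids[key$si],
    day = as.integer(press %/% MS_PER_DAY),
    t_press_ms = press,
    t_release_ms = press + key$ht,
    key_class = key_class
  )
  out
}

empty_event_log <- function() {
  data.table(subject_id = character(), day = integer(),
             t_press_ms = numeric(), t_release_ms = numeric(),
             key_class = character())
}

#' Simulate one subject-day of keystroke events
#'
#' Draws the typing sessions of a single calendar day for one subject. With
#' probability `1 - active_day_prob` the day is empty. Within a session press
#' times are strictly increasing and every release follows its press.
#'
#' @param profile a [kd_subject_profile()].
#' @param day non-negative integer day index.
#' @return a `data.table` in event-log schema (possibly zero rows) with
#'   columns `subject_id, day, t_press_ms, t_release_ms, key_class`.
#' @export
kd_simulate_subject_day <- function(profile, day) {
  stopifnot(inherits(profile, "kd_subject_profile"))
  if (!is.numeric(day) || length(day) != 1L || day < 0) {
    stop_config("`day` must be a single non-negative integer")
  }
  gen_subject_events(profile, as.integer(day))
}

#' Generate clinical visit outcomes for one pwMS profile
#'
#' Maps latent severity to the three clinical scales with additive visit-level
#' noise: NHPT increases and SDMT decreases in severity in expectation; EDSS
#' is rounded to the half-point scale and clipped to [0, 7]. Healthy controls
#' have no clinical assessments, so calling this on an HC profile is an error.
#'
#' @param profile a [kd_subject_profile()] with `group == "MS"`.
#' @param visit_days integer day indices of the visits.
#' @param config a [kd_cohort_config()] providing the outcome noise models.
#' @return `data.table` with columns
#'   `subject_id, visit, visit_day, edss, nhpt_s, sdmt`.
#' @export
kd_generate_outcomes <- function(profile, visit_days, config = kd_cohort_config()) {
  stopifnot(inherits(profile, "kd_subject_profile"))
  if (profile$group != "MS") {
    stop_config("clinical outcomes are only generated for MS subjects")
  }
  s <- profile$latent_severity
  k <- length(visit_days)
  nhpt <- config$nhpt_base + config$nhpt_slope * s + stats::rnorm(k, 0, config$nhpt_sd)
  nhpt <- pmax(nhpt, 5)
  sdmt <- round(config$sdmt_max - config$sdmt_slope * s + stats::rnorm(k, 0, config$sdmt_sd))
  sdmt <- pmin(pmax(sdmt, 0), 105)
  edss <- config$edss_base + config$edss_slope * s + stats::rnorm(k, 0, config$edss_sd)
  edss <- pmin(pmax(round(edss * 2) / 2, 0), 7)
  data.table(
    subject_id = profile$subject_id,
    visit = sprintf("m%02d", 3L * (seq_len(k) - 1L)),
    visit_day = as.integer(visit_days),
    edss = edss, nhpt_s = nhpt, sdmt = as.integer(sdmt)
  )
}

#' Simulate a full synthetic keystroke cohort
#'
#' Generates, from a seed, a cohort of healthy controls and people with MS:
#' a raw keystroke event log, a clinical visit table (pwMS only, five
#' 3-monthly visits), and a demographics table. Identical `(config, seed)`
#' pairs reproduce identical output.
#'
#' Controls are observed for roughly `hc_followup_mean` days from baseline;
#' pwMS for the full study. Latent severity is drawn from a low Beta stratum
#' for HC and a symmetric Beta for pwMS, shifts the log-mean typing latencies
#' per the configured effect sizes, and drives the clinical outcomes.
#'
#' @param config a [kd_cohort_config()].
#' @param seed integer seed.
#' @return list of class `kd_cohort` with elements `events`, `clinical`,
#'   `demographics` and `profiles`.
#' @export
kd_simulate_cohort <- function(config = kd_cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "kd_cohort_config"))
  with_seed(seed, {
    n <- config$n_hc + config$n_ms
    if (n == 0L) {
      return(structure(list(events = empty_event_log(),
                            clinical = kd_generate_outcomes_empty(),
                            demographics = empty_demographics(),
                            profiles = list()),
                       class = "kd_cohort"))
    }
    group <- c(rep("HC", config$n_hc), rep("MS", config$n_ms))
    ids <- sprintf("S%03d", seq_len(n))
    sev <- ifelse(group == "HC",
                  stats::rbeta(n, 1.5, 15),
                  stats::rbeta(n, 2, 2))
    subj_off_h <- stats::rnorm(n, 0, config$subject_sd)
    subj_off_f <- stats::rnorm(n, 0, config$subject_sd)
    base_h <- exp(log(config$base_hold_ms) +
                  config$effect_hold * config$sdlog_hold * sev + subj_off_h)
    base_f <- exp(log(config$base_flight_ms) +
                  config$effect_flight * config$sdlog_flight * sev + subj_off_f)
    age <- ifelse(group == "HC",
                  round(stats::rnorm(n, 42, 15)),
                  round(40 + 12 * sev + stats::rnorm(n, 0, 9)))
    age <- pmin(pmax(age, 18), 65)
    sex <- ifelse(stats::runif(n) < ifelse(group == "HC", 0.54, 0.74), "F", "M")
    edu_p_hc <- c(0.21, 0.46, 0.33)
    edu_p_ms <- c(0.36, 0.45, 0.19)
    education <- vapply(seq_len(n), function(i) {
      sample(c("low", "middle", "high"), 1L,
             prob = if (group[i] == "HC") edu_p_hc else edu_p_ms)
    }, character(1))

    profiles <- lapply(seq_len(n), function(i) {
      kd_subject_profile(
        subject_id = ids[i], group = group[i], latent_severity = sev[i],
        base_hold_ms = base_h[i], base_flight_ms = base_f[i],
        sdlog_hold = config$sdlog_hold, sdlog_flight = config$sdlog_flight,
        day_sd = config$day_sd,
        punctuation_rate = config$punctuation_rate,
        backspace_rate = config$backspace_rate,
        space_rate = config$space_rate,
        suggestion_rate = config$suggestion_rate,
        sessions_per_day_mean = config$sessions_per_day_mean,
        session_len_mean = config$session_len_mean,
        min_session_len = config$min_session_len,
        active_day_prob = config$active_day_prob,
        age = age[i], sex = sex[i], education = education[i]
      )
    })

    followup <- ifelse(group == "HC",
                       pmax(30L, as.integer(round(stats::rnorm(n, config$hc_followup_mean, 10)))),
                       config$study_days)
    followup <- pmin(followup, config$study_days)

    events <- gen_cohort_events(config, ids, base_h, base_f, followup)
    if (nrow(events)) data.table::setorder(events, subject_id, t_press_ms)

    clinical <- data.table::rbindlist(lapply(which(group == "MS"), function(i) {
      kd_generate_outcomes(profiles[[i]], config$visit_days, config)
    }))
    if (!nrow(clinical)) clinical <- kd_generate_outcomes_empty()

    demographics <- data.table(subject_id = ids, group = group, age = age,
                               sex = sex, education = education,
                               latent_severity = sev)
    structure(list(events = events, clinical = clinical,
                   demographics = demographics, profiles = profiles),
              class = "kd_cohort")
  })
}

kd_generate_outcomes_empty <- function() {
  data.table(subject_id = character(), visit = character(),
             visit_day = integer(), edss = numeric(), nhpt_s = numeric(),
             sdmt = integer())
}

empty_demographics <- function() {
  data.table(subject_id = character(), group = character(), age = numeric(),
             sex = character(), education = character(),
             latent_severity = numeric())
}

#' Write the tables of a simulated cohort as CSV files
#'
#' @param cohort a `kd_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
kd_write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "kd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("events.csv", "clinical.csv", "demographics.csv"))
  data.table::fwrite(cohort$events, paths[1])
  data.table::fwrite(cohort$clinical, paths[2])
  data.table::fwrite(cohort$demographics[, !"latent_severity"], paths[3])
  invisible(paths)
}
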