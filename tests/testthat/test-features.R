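test_that("timing sequences match their definitions on a worked example", {
  ev <- data.frame(t_press_ms = c(0, 200), t_release_ms = c(80, 300),
                   key_class = c("alphanumeric", "alphanumeric"))
  s <- kd_derive_sequences(ev)
  expect_equal(s$HT, c(80, 100))
  expect_equal(s$FT, 120)
  expect_equal(s$PPL, 200)
  expect_equal(s$RRL, 220)
})

test_that("a single key yields one hold time and empty pair sequences", {
  ev <- data.frame(t_press_ms = 10, t_release_ms = 95, key_class = "space")
  s <- kd_derive_sequences(ev)
  expect_equal(s$HT, 85)
  expect_length(s$FT, 0)
  expect_length(s$PPL, 0)
  expect_length(s$RRL, 0)
})

test_that("latency identities PPL = HT + FT and RRL = FT + HT(next) hold on random streams", {
  set.seed(20)
  for (i in 1:50) {
    ev <- random_stream(sample(2:60, 1), gap_prob = 0)
    s <- kd_derive_sequences(ev)
    n <- length(s$HT)
    expect_equal(s$PPL, s$HT[-n] + s$FT)
    expect_equal(s$RRL, s$FT + s$HT[-1])
    expect_length(s$FT, n - 1)
  }
})

test_that("derived sequences agree with a naive scan oracle, sessions included", {
  set.seed(21)
  for (i in 1:25) {
    ev <- random_stream(sample(5:80, 1), gap_prob = 0.1)
    s <- kd_derive_sequences(ev)
    o <- scan_sequences(ev)
    for (nm in c("HT", "FT", "PPL", "RRL", "APP", "PreCS", "PostCS")) {
      expect_equal(s[[nm]], o[[nm]], info = nm)
    }
  }
})

test_that("conditional sequences respect their defining key classes", {
  ev <- data.frame(
    t_press_ms = c(0, 300, 600, 900),
    t_release_ms = c(100, 400, 700, 1000),
    key_class = c("alphanumeric", "punctuation", "alphanumeric", "alphanumeric")
  )
  cs <- kd_conditional_sequences(ev)
  expect_equal(cs$APP, 200)  # flight time after the punctuation key
  expect_length(cs$PreCS, 0)
  expect_length(cs$PostCS, 0)
  ev$key_class <- c("alphanumeric", "backspace", "alphanumeric", "alphanumeric")
  cs <- kd_conditional_sequences(ev)
  expect_equal(cs$PreCS, 200)
  expect_equal(cs$PostCS, 200)
})

test_that("suggestion taps are excluded from timing sequences", {
  ev <- data.frame(
    t_press_ms = c(0, 300, 600),
    t_release_ms = c(100, 400, 700),
    key_class = c("alphanumeric", "suggestion", "alphanumeric")
  )
  s <- kd_derive_sequences(ev)
  expect_length(s$HT, 2)
  expect_equal(s$FT, 600 - 100)
})

test_that("unordered or invalid input is rejected", {
  ev <- data.frame(t_press_ms = c(200, 0), t_release_ms = c(300, 80),
                   key_class = c("alphanumeric", "alphanumeric"))
  expect_error(kd_derive_sequences(ev), "ordered")
  ev2 <- data.frame(t_press_ms = 100, t_release_ms = 50, key_class = "space")
  expect_error(kd_derive_sequences(ev2), "release")
})

test_that("outlier filtering removes out-of-bounds values and is idempotent", {
  ev <- random_stream(100, seed = 30)
  s <- kd_derive_sequences(ev)
  s$FT <- c(s$FT, 90000)
  rules <- kd_filter_config(ft = c(0, 5000))
  f1 <- kd_filter_outliers(s, rules)
  expect_false(any(f1$FT > 5000))
  expect_equal(attr(f1, "removed")[["FT"]], 1L)
  f2 <- kd_filter_outliers(f1, rules)
  expect_equal(unclass(f2)[1:7], unclass(f1)[1:7])
  # wide-open bounds are the identity
  wide <- kd_filter_config(ht = c(0, Inf), ft = c(-Inf, Inf),
                           ppl = c(-Inf, Inf), rrl = c(-Inf, Inf))
  expect_equal(kd_filter_outliers(s, wide)$FT, s$FT)
  expect_error(kd_filter_config(ft = c(10, 5)), "min")
})

test_that("daily aggregation matches a groupwise summary oracle", {
  co <- kd_simulate_cohort(micro_config(), seed = 44)
  daily <- kd_featurize(co$events)
  ev <- co$events
  picks <- unique(daily[!is.na(daily$APP_sd), c("subject_id", "day")])
  picks <- picks[seq_len(min(8, nrow(picks))), ]
  for (i in seq_len(nrow(picks))) {
    sub <- ev[ev$subject_id == picks$subject_id[i] & ev$day == picks$day[i], ]
    s <- kd_filter_outliers(kd_derive_sequences(sub[order(sub$t_press_ms), ]))
    row <- daily[daily$subject_id == picks$subject_id[i] & daily$day == picks$day[i], ]
    expect_equal(row$HT_mean, mean(s$HT))
    expect_equal(row$FT_median, median(s$FT))
    expect_equal(row$RRL_iqr, unname(diff(quantile(s$RRL, c(.25, .75)))))
    expect_equal(row$PPL_max, max(s$PPL))
    expect_equal(row$APP_p95, unname(quantile(s$APP, .95)))
    expect_equal(row$event_count, nrow(sub))
    expect_equal(row$backspace_count, sum(sub$key_class == "backspace"))
    expect_equal(row$suggestion_count, sum(sub$key_class == "suggestion"))
  }
})

test_that("daily aggregation is invariant to event-row permutation and leaves empty stats missing", {
  co <- kd_simulate_cohort(kd_cohort_config(n_hc = 2, n_ms = 4, study_days = 20,
                                            visit_days = c(0L, 15L),
                                            punctuation_rate = 0.01), seed = 5)
  ev <- co$events
  set.seed(1)
  shuffled <- ev[sample(nrow(ev)), ]
  d1 <- kd_featurize(ev)
  d2 <- kd_featurize(shuffled)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  # statistic of an empty sequence is NA, never zero
  no_punct_days <- d1[is.na(d1$APP_mean), ]
  expect_gt(nrow(no_punct_days), 0)
  expect_true(all(is.na(no_punct_days$APP_max)))
})

test_that("custom statistic registries are applied and unknown names rejected", {
  expect_error(kd_stat_registry(c("mean", "mode")), "unknown")
  ev <- random_stream(50, seed = 31)
  ev$subject_id <- "S1"; ev$day <- 0L
  reg <- kd_stat_registry(c("mean", "max"))
  d <- kd_featurize(ev, stats = reg)
  expect_true(all(c("HT_mean", "HT_max") %in% names(d)))
  expect_false("HT_median" %in% names(d))
  expect_error(kd_featurize(ev, stats = list()), "non-empty")
})

test_that("an empty event log produces an empty daily table with full schema", {
  d <- kd_featurize(data.frame(subject_id = character(), day = integer(),
                               t_press_ms = numeric(), t_release_ms = numeric(),
                               key_class = character()))
  expect_equal(nrow(d), 0L)
  expect_true(all(c("HT_mean", "event_count") %in% names(d)))
})
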