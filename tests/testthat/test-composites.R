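test_that("correlation pruning keeps correlated members and drops noise", {
  set.seed(60)
  n <- 500
  base <- rnorm(n)
  daily <- data.frame(
    a = base + rnorm(n, 0, 0.3), b = base + rnorm(n, 0, 0.3),
    c = base + rnorm(n, 0, 0.3), d = base + rnorm(n, 0, 0.3),
    noise = rnorm(n)
  )
  spec <- list(members = c("a", "b", "c", "d", "noise"),
               min_abs_correlation = 0.6)
  pruned <- kd_prune_by_correlation(daily, spec)
  expect_setequal(pruned$members, c("a", "b", "c", "d"))
  # two perfectly correlated members survive any threshold below 1
  spec2 <- list(members = c("a", "a2"), min_abs_correlation = 0.5)
  daily$a2 <- daily$a
  expect_setequal(kd_prune_by_correlation(daily, spec2)$members, c("a", "a2"))
  # single member: unchanged
  spec3 <- list(members = "a", min_abs_correlation = 0.9)
  expect_equal(kd_prune_by_correlation(daily, spec3)$members, "a")
  # unknown member is an error; all-missing member a warning
  expect_error(kd_prune_by_correlation(daily, list(members = c("a", "zz"),
                                                   min_abs_correlation = .5)),
               "absent")
  daily$allna <- NA_real_
  expect_warning(
    pr <- kd_prune_by_correlation(daily, list(members = c("a", "b", "allna"),
                                              min_abs_correlation = .5)),
    "all-missing")
  expect_false("allna" %in% pr$members)
})

test_that("composites equal a standardize-then-rowmean oracle on a toy table", {
  set.seed(61)
  daily <- data.frame(subject_id = rep("S1", 10), day = 0:9,
                      m1 = rnorm(10, 100, 10), m2 = rnorm(10, 200, 30),
                      m3 = rnorm(10, 50, 5), event_count = 100L)
  specs <- structure(list(comp = list(members = c("m1", "m2", "m3"),
                                      min_abs_correlation = 0)),
                     class = "kd_cluster_specs")
  fit <- kd_fit_composites(daily, specs)
  out <- kd_transform_composites(fit, daily)
  z <- scale(daily[, c("m1", "m2", "m3")])
  expect_equal(out$comp, rowMeans(z), ignore_attr = TRUE)
  # fitted-split composite has mean ~ 0
  expect_lt(abs(mean(out$comp)), 1e-10)
})

test_that("missing members are averaged over what remains; all-missing stays missing", {
  daily <- data.frame(subject_id = "S1", day = 0:3,
                      m1 = c(1, NA, NA, 4), m2 = c(2, 3, NA, 5),
                      event_count = 10L)
  specs <- structure(list(comp = list(members = c("m1", "m2"),
                                      min_abs_correlation = 0)),
                     class = "kd_cluster_specs")
  fit <- kd_fit_composites(daily, specs)
  out <- kd_transform_composites(fit, daily)
  z1 <- (daily$m1 - mean(daily$m1, na.rm = TRUE)) / sd(daily$m1, na.rm = TRUE)
  z2 <- (daily$m2 - mean(daily$m2, na.rm = TRUE)) / sd(daily$m2, na.rm = TRUE)
  expect_equal(out$comp[2], z2[2])        # only m2 observed that day
  expect_true(is.na(out$comp[3]))          # both missing
  expect_equal(out$comp[1], mean(c(z1[1], z2[1])))
})

test_that("a constant z-shift of every member shifts the composite by that amount", {
  set.seed(62)
  daily <- data.frame(subject_id = "S1", day = 0:49,
                      m1 = rnorm(50), m2 = rnorm(50), event_count = 10L)
  specs <- structure(list(comp = list(members = c("m1", "m2"),
                                      min_abs_correlation = 0)),
                     class = "kd_cluster_specs")
  fit <- kd_fit_composites(daily, specs)
  out1 <- kd_transform_composites(fit, daily)
  shifted <- daily
  shifted$m1 <- shifted$m1 + sd(daily$m1) * 0.7
  shifted$m2 <- shifted$m2 + sd(daily$m2) * 0.7
  out2 <- kd_transform_composites(fit, shifted)
  expect_equal(out2$comp, out1$comp + 0.7, tolerance = 1e-10)
})

test_that("zero-variance members are skipped with a warning", {
  daily <- data.frame(subject_id = "S1", day = 0:9, m1 = rnorm(10),
                      m2 = rep(5, 10), event_count = 1L)
  specs <- structure(list(comp = list(members = c("m1", "m2"),
                                      min_abs_correlation = 0)),
                     class = "kd_cluster_specs")
  expect_warning(fit <- kd_fit_composites(daily, specs), "zero-variance")
  expect_equal(fit$clusters$comp$members, "m1")
})

test_that("default clusters standardize to near-zero mean on a synthetic cohort", {
  co <- kd_simulate_cohort(micro_config(), seed = 66)
  daily <- kd_featurize(co$events)
  comp <- kd_build_composites(daily, prune = TRUE)
  for (nm in c("fmcs_central", "fmcs_dispersion", "ccs_central")) {
    expect_lt(abs(mean(comp[[nm]], na.rm = TRUE)), 0.05)
  }
})
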