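# Excursion metrics, EMG effort, paired t-tests, summaries, confusion tables.

# hand-built pose trace: enters the window once, with a decoy extreme outside
fake_trial <- function() {
  list(trial_id = "fx",
       theta_abd = c(70, 75, 85, 90, 95, 85, 75, 70),
       theta_h = c(30, 40, 50, 80, 70, 60, 90, 30),   # 90 occurs out-of-window
       phi_e = c(120, 20, 60, 40, 50, 70, 110, 120),  # 20 occurs out-of-window
       fs = 1)
}

test_that("excursion metrics use only in-window samples", {
  m <- excursion_metrics(fake_trial())
  expect_true(m$valid)
  expect_equal(m$elbow_metric, 40)      # not the out-of-window 20
  expect_equal(m$shoulder_metric, 80)   # not the out-of-window 90
  low <- fake_trial()
  low$theta_abd <- rep(75, 8)           # never enters the window
  m2 <- excursion_metrics(low)
  expect_false(m2$valid)
  expect_true(is.na(m2$elbow_metric))
})

test_that("envelope of a constant-amplitude signal settles at that amplitude", {
  x <- rep(c(2, -2), 500)
  env <- emg_envelope(x, fs = 1000)
  expect_equal(env[201:1000], rep(2, 800))
  expect_length(env, 1000)
})

test_that("normalization yields unit session maxima and scale-invariant sums", {
  prof <- fx_profile()
  mk <- function(seed, gain = 1) {
    r <- generate_class_emg(prof, "abduction", duration_s = 1, seed = seed)
    list(emg = gain * r$samples, fs = 1000, trial_id = seed,
         theta_abd = rep(90, 1000), theta_h = rep(50, 1000),
         phi_e = rep(90, 1000))
  }
  trials <- list(mk(1), mk(2))
  smax <- session_channel_max(trials)
  norm_env <- sapply(seq_along(smax), function(j)
    max(sapply(trials, function(tr)
      max(emg_envelope(tr$emg[, j], 1000)))) / smax[j])
  expect_equal(unname(norm_env), rep(1, 12))
  e1 <- emg_effort(trials, smax)
  doubled <- list(mk(1, 2), mk(2, 2))
  e2 <- emg_effort(doubled, session_channel_max(doubled))
  expect_equal(e1$total, e2$total, tolerance = 1e-12)
})

test_that("zero-maximum channels are excluded with a warning", {
  tr <- list(emg = matrix(0, 100, 12,
                          dimnames = list(NULL, default_channel_names())),
             fs = 1000)
  tr$emg[, "mid_delt"] <- rnorm(100)
  smax <- session_channel_max(list(tr))
  expect_warning(out <- emg_effort(list(tr), smax), "zero session maximum")
  expect_true(is.finite(out$total))
})

test_that("paired one-sided t matches hand values and the reference oracle", {
  # identical vectors: t = 0, one-sided p = 0.5
  r <- paired_one_sided_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)
  expect_match(r$flag, "zero variance")
  # agreement with the independent reference implementation
  set.seed(13)
  for (k in 1:100) {
    n <- sample(3:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    mine <- paired_one_sided_t(a, b, "less")
    ref <- stats::t.test(a, b, paired = TRUE, alternative = "less")
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("condition summary: cell and group statistics", {
  # five participant means, one per cell
  df <- data.frame(participant = 1:5, condition = "no_support",
                   value = c(86, 63, 50, 49, 61))
  cs <- condition_summary(df)
  expect_equal(cs$group$mean, 61.8)
  expect_equal(round(cs$group$sd, 1), 14.9)
  # all-identical trials: zero cell SD; single participant: NA group SD
  df2 <- data.frame(participant = 1, condition = "force", value = c(40, 40, 40))
  cs2 <- condition_summary(df2)
  expect_equal(cs2$cells$sd, 0)
  expect_true(is.na(cs2$group$sd))
})

test_that("confusion rows sum to 100 and high-SNR no-movement is recognised", {
  model <- fx_small_model()
  prof <- fx_profile()
  recs <- list(
    horiz_addabd = generate_class_emg(prof, "horiz_addabd", duration_s = 2,
                                      seed = 51),
    elbow_flexext = generate_class_emg(prof, "elbow_flexext", duration_s = 2,
                                       seed = 52))
  tab <- unrelated_movement_confusion(model, recs,
                                      support_condition = "limb_weight")
  expect_equal(unname(rowSums(as.matrix(tab))), rep(100, 3), tolerance = 0.5)
  expect_identical(attr(tab, "support_condition"), "limb_weight")
  # a trial generated exactly from the trained no-movement pattern
  nm <- generate_class_emg(prof, "no_movement", duration_s = 2, seed = 53)
  tab2 <- unrelated_movement_confusion(model, list(rest = nm))
  expect_gte(tab2["rest", "no_movement"], 95)
})

test_that("confusion averaging reproduces printed-style average rows exactly", {
  tab <- rbind(c(78, 6, 16), c(70, 15, 15), c(96, 3, 1), c(84, 16, 1))
  expect_equal(unname(confusion_average(tab)), c(82, 10, 8))
  # unrounded arithmetic is exposed when digits = NULL
  expect_equal(unname(confusion_average(tab, digits = NULL))[3], 8.25)
})
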