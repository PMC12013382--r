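# Synthetic stroke-subject EMG generation, training protocol, user policy,
# and closed-loop trials.

test_that("generation is seed-reproducible and intensity-0 is noise only", {
  prof <- fx_profile()
  r1 <- generate_class_emg(prof, "abduction", duration_s = 1, seed = 41)
  r2 <- generate_class_emg(prof, "abduction", duration_s = 1, seed = 41)
  expect_identical(r1$samples, r2$samples)
  r0 <- generate_class_emg(prof, "abduction", intensity = 0, duration_s = 2,
                           seed = 42)
  expect_equal(apply(r0$samples, 2, sd), rep(prof$noise_sd, 12),
               tolerance = 0.1, ignore_attr = TRUE)
})

test_that("per-channel MAV tracks the synergy-coupled activation pattern", {
  prof <- fx_profile()
  r <- generate_class_emg(prof, "abduction", duration_s = 10, seed = 43)
  amp <- as.numeric(prof$coupling %*% prof$activation_patterns["abduction", ])
  mv <- colMeans(abs(r$samples))
  pred <- sqrt(2 / pi) * sqrt(amp^2 + prof$noise_sd^2)
  strong <- amp > 0.1   # relative error meaningful above the noise floor
  expect_true(all(abs(mv[strong] / pred[strong] - 1) < 0.10))
})

test_that("synergy coupling bleeds abduction drive into the flexor channels", {
  clean <- subject_profile(k_syn = 0)
  syn <- subject_profile(k_syn = 1)
  obs0 <- (clean$coupling %*% clean$activation_patterns["abduction", ])[, 1]
  obs1 <- (syn$coupling %*% syn$activation_patterns["abduction", ])[, 1]
  expect_equal(obs0["biceps"],
               clean$activation_patterns["abduction", "biceps"],
               ignore_attr = TRUE)          # k_syn = 0: independent joints
  expect_gt(obs1["biceps"], obs0["biceps"])
  expect_gt(obs1["wrist_flex1"], obs0["wrist_flex1"])
})

test_that("training protocol composition matches the study design", {
  prof <- fx_profile()
  both <- build_training_protocol(prof, "both", duration_s = 2, seed = 44)
  expect_length(both, 28)
  pos <- build_training_protocol(prof, "position", duration_s = 2, seed = 44)
  expect_length(pos, 23)
  labels <- vapply(pos, function(t) t$label, character(1))
  expect_equal(sum(labels == "no_movement"), 11)
  expect_equal(sum(labels == "abduction"), 6)
  frc <- build_training_protocol(prof, "force", duration_s = 2, seed = 44)
  expect_length(frc, 23)
  postures <- vapply(both[1:18], function(t) t$posture, numeric(1))
  expect_equal(sort(unique(postures)), c(0, 45, 90))
})

test_that("policy: full support removes lift intent; synergy limits extension", {
  prof <- fx_profile()
  arm <- fx_arm()
  pose <- list(theta_abd = 75, theta_h = 30, phi_e = 130)
  # static full support: no abduction drive needed
  pol <- user_policy("lift", pose, F_robot = arm$W, prof, "limb_weight", arm)
  expect_equal(pol$shoulder_effort, 0)
  # no support: full anti-gravity drive
  pol_ns <- user_policy("lift", pose, 0, prof, "no_support", arm)
  expect_equal(pol_ns$shoulder_effort, 1)
  # synergy: more shoulder effort -> less attainable elbow extension
  reach_ns <- user_policy("reach", pose, 0, prof, "no_support", arm)
  reach_lw <- user_policy("reach", pose, arm$W, prof, "limb_weight", arm)
  expect_gt(reach_ns$phi_e_target, reach_lw$phi_e_target)
  # k_syn = 0: attainable extension independent of support
  p0 <- subject_profile(k_syn = 0)
  r1 <- user_policy("reach", pose, 0, p0, "no_support", arm)
  r2 <- user_policy("reach", pose, arm$W, p0, "limb_weight", arm)
  expect_equal(r1$phi_e_target, r2$phi_e_target)
})

test_that("closed-loop trials: determinism, no-support forces, window entry", {
  prof <- fx_profile()
  t1 <- simulate_trial(prof, "no_support", seed = 45, max_s = 15)
  t2 <- simulate_trial(prof, "no_support", seed = 45, max_s = 15)
  expect_identical(t1$emg, t2$emg)
  expect_identical(t1$z, t2$z)
  expect_true(all(t1$F_applied == 0))
  expect_true(t1$flags$window_entered)
  expect_false(t1$flags$truncated)
  lw <- simulate_trial(prof, "limb_weight", seed = 46, max_s = 15)
  expect_true(all(lw$F_applied == lw$F_applied[1]))   # constant support
  expect_equal(lw$F_applied[1], fx_arm()$W)
})

test_that("position-control trials press down on the rigid support during reach", {
  prof <- fx_profile()
  model <- fx_small_model()
  tr <- simulate_trial(prof, "position", model, fx_state("position", model),
                       seed = 47, max_s = 18)
  expect_true(tr$flags$window_entered)
  in_win <- tr$theta_abd >= 80 & tr$theta_abd <= 100
  expect_lt(mean(tr$F_sensed[in_win]), 0)   # sustained negative loading
  expect_gt(nrow(tr$decisions), 0)
})
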