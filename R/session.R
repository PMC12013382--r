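# Closed-loop lift - reach - return - lower trials: the synthetic subject's
# policy generates EMG, the classifier/controller (for the real-time
# conditions) commands the robot, and the 1-DOF vertical dynamics respond.
#
# Integration runs at 1 ms with commands held between the 25 ms decisions.
# All randomness is drawn up front from the trial seed, so a fixed seed gives
# a bit-identical trial.

# causal conditioning of a short sample block (matrix) from zero state
.condition_block <- function(m, filt) {
  apply(m, 2, function(x) {
    x <- .iir_filter(x, filt$bp$b, filt$bp$a)
    .iir_filter(x, filt$bs$b, filt$bs$a)
  })
}

#' Simulate one closed-loop lift-reach-return-lower trial
#'
#' Runs the scripted user policy against the configured support condition.
#' For the `position` and `force` conditions the EMG stream is windowed,
#' classified and fed to the incremental controller every 25 ms (first
#' decision at 200 ms, each using the preceding 200 ms of causally
#' conditioned EMG); the static conditions apply their constant support.
#'
#' @param profile A [subject_profile()].
#' @param condition One of the five support-condition tags, see
#'   [make_condition()].
#' @param model An `emg_classifier` (required for real-time conditions).
#' @param state A `controller_state` (required for real-time conditions).
#' @param arm An [arm_model()].
#' @param seed Integer seed for the trial's EMG randomness.
#' @param max_s Trial timeout (s); a timed-out trial is truncated and flagged.
#' @param trial_id Identifier stored on the record.
#' @return Object of class `trial_record`: 1 kHz series of pose
#'   (`theta_abd`, `theta_h`, `phi_e`), `z`, `F_applied`, `F_sensed`, the raw
#'   EMG matrix, the decision log, and flags (`truncated`,
#'   `ceiling_contact`, `window_entered`).
#' @export
simulate_trial <- function(profile, condition, model = NULL, state = NULL,
                           arm = arm_model(), seed = NULL, max_s = 20,
                           trial_id = condition) {
  env <- make_condition(condition, arm)
  if (env$controller_driven && (is.null(model) || is.null(state)))
    stop("condition '", condition, "' needs a trained model and controller state")
  fs <- 1000
  blk <- 25L
  n_max <- round(max_s * fs)
  nch <- ncol(profile$activation_patterns)
  p <- profile$policy
  filt <- emg_filters(fs)

  rng <- .with_seed(seed, list(
    carrier = .carrier(n_max, nch, fs),
    mod = .slow_modulation(n_max, nch, fs),
    noise = matrix(stats::rnorm(n_max * nch, sd = profile$noise_sd), n_max, nch),
    kin_jitter = stats::rnorm(2, sd = 1.5)))   # deg, trial-to-trial variability
  carrier <- rng$carrier; mod <- rng$mod; noise <- rng$noise

  # state
  z <- if (condition == "table") 0 else env$z_floor
  z_ref <- z                       # rate-limited self-paced vertical target
  v_ref <- (env$z_ceiling - env$z_floor) / p$lift_s
  zdot <- 0
  phase <- if (condition == "table") "reach" else "lift"
  phase_t <- 0
  theta_h <- p$theta_h_start
  phi_e <- p$phi_rest
  F_robot <- if (env$controller_driven && state$mode == "force") state$F
             else if (is.na(env$F_robot_const)) 0 else env$F_robot_const
  if (env$controller_driven && state$mode == "position") state$z <- z

  emg <- matrix(0, n_max, nch,
                dimnames = list(NULL, colnames(profile$activation_patterns)))
  log_z <- log_fa <- log_fs_ <- log_ta <- log_th <- log_pe <- numeric(n_max)
  dec_t <- numeric(0); dec_cl <- character(0); dec_pc <- numeric(0)
  flags <- list(truncated = FALSE, ceiling_contact = FALSE,
                window_entered = FALSE)
  t_samp <- 0L

  while (t_samp < n_max && phase != "done") {
    pose <- list(theta_abd = height_to_abduction(z, arm),
                 theta_h = theta_h, phi_e = phi_e)
    pol <- user_policy(phase, pose, F_robot, profile, condition, arm)

    # EMG block from current intents (plus resting baseline)
    a <- .observed_amplitude(profile, c(list(no_movement = 1), pol$intents))
    idx <- t_samp + seq_len(blk)
    emg[idx, ] <- sweep(carrier[idx, , drop = FALSE] *
                          mod[idx, , drop = FALSE], 2, a, "*") +
                  noise[idx, , drop = FALSE]

    # decision (real-time conditions, once a full window exists)
    if (env$controller_driven && t_samp + blk >= 200L) {
      lo <- max(1L, t_samp + blk - 300L + 1L)
      w <- .condition_block(emg[lo:(t_samp + blk), , drop = FALSE], filt)
      w <- w[(nrow(w) - 200L + 1L):nrow(w), , drop = FALSE]
      fv <- extract_features(w, thresholds = model$thresholds)
      d <- classify_window(model, fv)
      state <- if (state$mode == "position") position_step(state, d)
               else force_step(state, d)
      if (state$mode == "force") F_robot <- state$F
      dec_t <- c(dec_t, t_samp + blk)
      dec_cl <- c(dec_cl, d$class)
      dec_pc <- c(dec_pc, d$pc)
    }

    # vertical response over the 25 ms block
    syn <- min(1, profile$k_syn * pol$shoulder_effort)
    # effortful movement against gravity load is slower (self-paced task)
    pace <- 1 + p$slow_load * min(1, pol$shoulder_effort)
    if (condition == "table" ||
        (env$controller_driven && state$mode == "position")) {
      z <- if (condition == "table") env$z_lock else state$z
      F_user <- if (phase == "reach") -p$press_frac * arm$W * syn else 0
      log_z[idx] <- z
      log_fs_[idx] <- F_user - arm$W
      log_fa[idx] <- 0
      zdot <- 0
    } else {
      z_tgt <- if (phase %in% c("lift", "reach", "return")) 0 else env$z_floor
      g_ff <- if (phase %in% c("lift", "reach", "return")) 1 else 0
      for (s in seq_len(blk)) {
        # self-paced: the user tracks a rate-limited reference, not a step
        z_ref <- z_ref + sign(z_tgt - z_ref) *
                 min(abs(z_tgt - z_ref), v_ref / pace / fs)
        F_user <- g_ff * max(0, arm$W - F_robot) +
                  p$kp * (z_ref - z) - p$kd * zdot
        F_user <- min(max(F_user, -1.5 * arm$W), 1.5 * arm$W)
        st <- vertical_dynamics_step(z, zdot, F_robot, F_user, arm, 1e-3)
        z <- st$z; zdot <- st$zdot
        j <- t_samp + s
        log_z[j] <- z
        log_fs_[j] <- st$F_sensed
        log_fa[j] <- F_robot
      }
    }

    # horizontal kinematics (first-order approach toward policy targets)
    dtb <- blk / fs
    if (phase == "reach") {
      th_t <- pol$theta_h_target + rng$kin_jitter[1]
      pe_t <- max(0, pol$phi_e_target + rng$kin_jitter[2])
      theta_h <- theta_h + (th_t - theta_h) * dtb / (p$tau_h * pace)
      phi_e <- phi_e + (pe_t - phi_e) * dtb / (p$tau_h * pace)
    } else if (phase == "return") {
      theta_h <- theta_h + (p$theta_h_start - theta_h) * dtb / (p$tau_h * pace)
      phi_e <- phi_e + (p$phi_rest - phi_e) * dtb / (p$tau_h * pace)
    }
    log_ta[idx] <- height_to_abduction(z, arm)
    log_th[idx] <- theta_h
    log_pe[idx] <- phi_e

    theta_now <- height_to_abduction(z, arm)
    if (theta_now >= 80 && theta_now <= 100) flags$window_entered <- TRUE
    if (theta_now >= arm$theta_limits[2] - 0.01) flags$ceiling_contact <- TRUE

    # phase transitions
    phase_t <- phase_t + dtb
    new_phase <- phase
    if (phase == "lift" && theta_now >= 82) new_phase <- "reach"
    else if (phase == "reach" && phase_t >= p$reach_s * pace) new_phase <- "return"
    else if (phase == "return" &&
             (theta_h <= p$theta_h_start + 5 || phase_t >= 4)) {
      new_phase <- if (condition == "table") "done" else "lower"
    } else if (phase == "lower" && theta_now <= 72) new_phase <- "done"
    if (new_phase != phase) { phase <- new_phase; phase_t <- 0 }

    t_samp <- t_samp + blk
  }
  if (phase != "done") flags$truncated <- TRUE

  n <- t_samp
  keep <- seq_len(n)
  structure(list(
    condition = condition, trial_id = trial_id, fs = fs,
    time_ms = keep - 1,
    theta_abd = log_ta[keep], theta_h = log_th[keep], phi_e = log_pe[keep],
    z = log_z[keep], F_applied = log_fa[keep], F_sensed = log_fs_[keep],
    emg = emg[keep, , drop = FALSE],
    decisions = data.frame(time_ms = dec_t, class = dec_cl, pc = dec_pc),
    flags = flags),
    class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("trial_record '%s' (%s): %.2f s, %d decisions%s\n",
              x$trial_id, x$condition, length(x$z) / x$fs,
              nrow(x$decisions),
              if (x$flags$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Simulate a session of closed-loop trials under one support condition
#'
#' Runs `n_trials` complete lift-reach-return-lower trials. For the
#' real-time conditions a fresh controller state (with [default_gains()]) is
#' created per trial unless one is supplied.
#'
#' @inheritParams simulate_trial
#' @param n_trials Number of trials (the study protocol used 10).
#' @param seed Session seed; each trial derives its own sub-stream.
#' @return List of `trial_record`s.
#' @export
simulate_session <- function(profile, condition, model = NULL, state = NULL,
                             arm = arm_model(), n_trials = 10, seed = 1,
                             max_s = 20) {
  env <- make_condition(condition, arm)
  lapply(seq_len(n_trials), function(i) {
    st <- state
    if (env$controller_driven && is.null(st)) {
      mode <- condition
      st <- controller_state(
        mode = mode, gains = default_gains(model, arm, mode),
        z = env$z_floor, z_limits = c(env$z_floor, env$z_ceiling),
        F = 0, F_limits = c(0, arm$W))
    }
    simulate_trial(profile, condition, model, st, arm,
                   seed = .sub_seed(seed, i), max_s = max_s,
                   trial_id = sprintf("%s_%02d", condition, i))
  })
}
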