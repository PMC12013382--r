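# Incremental vertical support controllers.
#
# Every 25 ms a (class, PC) decision updates either the commanded vertical
# position (a velocity proportional to PC applied across the decision window)
# or the commanded vertical support force (an increment proportional to PC).
# Between decisions the robot holds the command rigidly. Limits are enforced
# by silent (logged) clamping.

#' Controller state for incremental vertical support
#'
#' @param mode `"position"` or `"force"`.
#' @param gains List with `up` and `down` gains: m/s per PC unit in position
#'   mode, N per decision per PC unit in force mode. Separate up/down gains
#'   are used, as tuned per participant in practice.
#' @param z Initial vertical position (m).
#' @param z_limits `(z_floor, z_ceiling)` in metres, from the 70/100-degree
#'   abduction virtual surfaces.
#' @param F Initial support force (N, up).
#' @param F_limits `(0, F_max)`; `F_max` defaults to the limb weight — the
#'   gold-standard support is 100% of limb weight, beyond which the robot
#'   would lift the arm passively.
#' @param decision_period_ms Decision cadence (ms), default 25.
#' @return Object of class `controller_state`.
#' @export
controller_state <- function(mode = c("position", "force"),
                             gains = list(up = 0.05, down = 0.05),
                             z = 0, z_limits = c(-0.103, 0.052),
                             F = 0, F_limits = c(0, 30),
                             decision_period_ms = 25) {
  mode <- match.arg(mode)
  stopifnot(gains$up >= 0, gains$down >= 0,
            z_limits[1] <= z_limits[2], F_limits[1] <= F_limits[2],
            decision_period_ms > 0)
  structure(list(mode = mode, gains = gains,
                 z = min(max(z, z_limits[1]), z_limits[2]),
                 z_limits = z_limits,
                 F = min(max(F, F_limits[1]), F_limits[2]),
                 F_limits = F_limits,
                 decision_period_ms = decision_period_ms,
                 clamped = FALSE),
            class = "controller_state")
}

#' Default controller gains from a trained classifier and arm model
#'
#' Position gains are chosen so a sustained center-effort abduction (PC at
#' the class-center MAVs) traverses the full 70-to-100-degree vertical range
#' in about 3 s; force gains load the full limb weight in about 2 s.
#'
#' @param model An `emg_classifier`.
#' @param arm An [arm_model()].
#' @param mode `"position"` or `"force"`.
#' @return Gains list with `up` and `down`.
#' @export
default_gains <- function(model, arm, mode = c("position", "force")) {
  mode <- match.arg(mode)
  pc_ref <- function(cl) proportional_control(model$S[cl, ], model, cl)
  z_range <- abduction_to_height(arm$theta_limits[2], arm) -
             abduction_to_height(arm$theta_limits[1], arm)
  if (mode == "position") {
    list(up = z_range / (3 * pc_ref("abduction")),
         down = z_range / (3 * pc_ref("adduction")))
  } else {
    per_s <- 1000 / 25                      # decisions per second
    list(up = arm$W / (2 * per_s * pc_ref("abduction")),
         down = arm$W / (2 * per_s * pc_ref("adduction")))
  }
}

#' One position-mode decision update
#'
#' Abduction applies an upward velocity `gain_up * PC` across the decision
#' window, adduction a downward one; `no_movement` leaves the position
#' untouched. The result is clamped to the virtual-surface limits.
#'
#' @param state A `controller_state` with `mode = "position"`.
#' @param decision A decision list with `class` and `pc` (from
#'   [classify_window()]).
#' @return Updated state; `$clamped` records whether the limit clamp engaged.
#' @export
position_step <- function(state, decision) {
  stopifnot(state$mode == "position")
  dt <- state$decision_period_ms / 1000
  dz <- switch(decision$class,
               abduction = state$gains$up * decision$pc * dt,
               adduction = -state$gains$down * decision$pc * dt,
               0)
  znew <- state$z + dz
  state$clamped <- znew < state$z_limits[1] || znew > state$z_limits[2]
  state$z <- min(max(znew, state$z_limits[1]), state$z_limits[2])
  state
}

#' One force-mode decision update
#'
#' Abduction increments the support force by `gain_up * PC`, adduction
#' decrements it by `gain_down * PC`; `no_movement` leaves it untouched.
#' The result is clamped to `[0, F_max]`.
#'
#' @inheritParams position_step
#' @return Updated state.
#' @export
force_step <- function(state, decision) {
  stopifnot(state$mode == "force")
  dF <- switch(decision$class,
               abduction = state$gains$up * decision$pc,
               adduction = -state$gains$down * decision$pc,
               0)
  Fnew <- state$F + dF
  state$clamped <- Fnew < state$F_limits[1] || Fnew > state$F_limits[2]
  state$F <- min(max(Fnew, state$F_limits[1]), state$F_limits[2])
  state
}

#' Participant-specific gain adaptation heuristic
#'
#' Lift gain is lowered (x 0.8) when the arm consistently slams into the
#' ceiling limit, and raised (x 1.25) when the arm lags or the elbow lifts
#' off the load cell, bounded within `[g_min, g_max]`.
#'
#' @param trial_summary List with logical flags `ceiling_slam` and `arm_lag`.
#' @param gains Gains list with `up` and `down`.
#' @param bounds `(g_min, g_max)` multiplicative bounds on each gain.
#' @return Adjusted gains.
#' @export
adapt_gains <- function(trial_summary, gains, bounds = c(1e-4, 10)) {
  g <- gains
  if (isTRUE(trial_summary$ceiling_slam)) g$up <- g$up * 0.8
  if (isTRUE(trial_summary$arm_lag)) g$up <- g$up * 1.25
  g$up <- min(max(g$up, bounds[1]), bounds[2])
  g$down <- min(max(g$down, bounds[1]), bounds[2])
  g
}

#' Run the decision loop over a fixed EMG stream (open loop)
#'
#' Conditions the stream causally, emits the first decision at
#' `window_ms` (200 ms) and one every `step_ms` (25 ms) thereafter, each
#' using exactly the preceding window of conditioned EMG, and applies each
#' decision to the controller. With a `force`-mode state and an arm model the
#' vertical dynamics are integrated between decisions (no user lift force);
#' in position mode the robot holds the commanded z rigidly.
#'
#' @param recording An [emg_recording()] of at least one window length.
#' @param model An `emg_classifier`.
#' @param state A `controller_state`.
#' @param arm Optional [arm_model()] for force-mode dynamics.
#' @param window_ms,step_ms Decision windowing (defaults 200/25 ms).
#' @return List with the final `state` and a `decisions` data frame
#'   (`time_ms`, `class`, `pc`, `z`, `F`, `clamped`).
#' @export
run_decision_loop <- function(recording, model, state, arm = NULL,
                              window_ms = 200, step_ms = 25) {
  cond <- condition_signal(recording, "causal")
  fx <- extract_features_recording(cond, window_ms, step_ms,
                                   thresholds = model$thresholds)
  n <- nrow(fx$features)
  if (n == 0L) stop("stream shorter than one analysis window")
  dec <- classify_features(model, fx$features, fx$mav)
  time_ms <- fx$start_ms + window_ms
  z <- F <- numeric(n)
  clamped <- logical(n)
  zdot <- 0
  for (k in seq_len(n)) {
    d <- list(class = dec$class[k], pc = dec$pc[k])
    state <- if (state$mode == "position") position_step(state, d)
             else force_step(state, d)
    if (state$mode == "force" && !is.null(arm)) {
      zz <- state$z
      for (s in seq_len(round(step_ms))) {  # 1 ms substeps
        st <- vertical_dynamics_step(zz, zdot, state$F, 0, arm, 1e-3)
        zz <- st$z; zdot <- st$zdot
      }
      state$z <- zz
    }
    z[k] <- state$z; F[k] <- state$F; clamped[k] <- state$clamped
  }
  list(state = state,
       decisions = data.frame(time_ms = time_ms, class = dec$class,
                              pc = dec$pc, z = z, F = F, clamped = clamped))
}
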