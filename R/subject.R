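# Synthetic stroke-subject model: class-conditioned EMG generation, the
# 28-trial training protocol, and a closed-loop user policy with abnormal
# flexion-synergy coupling.
#
# The EMG carrier is band-limited (20-350 Hz) Gaussian noise, the standard
# surface-EMG amplitude model: each channel is a unit-RMS carrier amplitude-
# modulated by the (synergy-coupled) activation level plus additive sensor
# noise. MAV of such a signal is sqrt(2/pi) times its amplitude, so relative
# channel amplitudes map directly onto relative MAVs.

# run code under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derived sub-stream seed, kept within 32-bit integer range
.sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + k * 7919) %% 2147483562) + 1L
}

# default per-class mean channel activations (normalized units, config not
# claims): movement classes mirror the electrode montage, unrelated-movement
# patterns are emitted for evaluation only and never trained on
.default_patterns <- function() {
  ch <- default_channel_names()
  p <- rbind(
    no_movement   = c(0.03, 0.03, 0.03, 0.03, 0.03, 0.03, 0.03, 0.03,
                      0.03, 0.03, 0.03, 0.03),
    abduction     = c(0.80, 0.90, 0.60, 0.70, 0.08, 0.80, 0.25, 0.15,
                      0.06, 0.06, 0.06, 0.06),
    adduction     = c(0.10, 0.10, 0.20, 0.10, 0.90, 0.10, 0.65, 0.30,
                      0.06, 0.06, 0.10, 0.10),
    reach         = c(0.30, 0.15, 0.10, 0.15, 0.15, 0.10, 0.20, 0.40,
                      0.25, 0.25, 0.30, 0.30),
    horiz_addabd  = c(0.45, 0.25, 0.35, 0.25, 0.55, 0.15, 0.45, 0.20,
                      0.10, 0.10, 0.15, 0.15),
    int_ext_rot   = c(0.20, 0.15, 0.25, 0.20, 0.40, 0.35, 0.55, 0.15,
                      0.10, 0.10, 0.12, 0.12),
    elbow_flexext = c(0.10, 0.08, 0.08, 0.10, 0.10, 0.06, 0.10, 0.55,
                      0.35, 0.35, 0.30, 0.30),
    hand_openclose = c(0.08, 0.06, 0.06, 0.08, 0.08, 0.06, 0.08, 0.20,
                      0.45, 0.45, 0.45, 0.45))
  colnames(p) <- ch
  p
}

# synergy leak matrix: shoulder-abductor drive bleeds into elbow/wrist
# flexor channels (abnormal flexion synergy after stroke)
.default_leak <- function() {
  ch <- default_channel_names()
  L <- matrix(0, 12, 12, dimnames = list(ch, ch))
  L["biceps", "ant_delt"] <- 0.30
  L["biceps", "mid_delt"] <- 0.30
  L["wrist_flex1", "ant_delt"] <- 0.15
  L["wrist_flex1", "mid_delt"] <- 0.20
  L["wrist_flex2", "ant_delt"] <- 0.15
  L["wrist_flex2", "mid_delt"] <- 0.20
  L["pect_major", "mid_delt"] <- 0.10
  L
}

#' Synthetic stroke-subject profile
#'
#' Bundles the per-class channel activation patterns, the abnormal-synergy
#' coupling, noise level and behavioural policy parameters that define one
#' simulated participant.
#'
#' The policy constants encode the qualitative behaviour reported for this
#' task: sustained full anti-gravity effort without support, intermittent
#' command effort plus post-stroke co-activation under real-time control, and
#' near-baseline shoulder effort under static full support.
#'
#' @param activation_patterns Matrix `classes x 12 channels` of mean
#'   activations (>= 0); defaults cover the three trained classes, reach, and
#'   four unrelated movements.
#' @param k_syn Abnormal-synergy strength (>= 0). Couples shoulder-abduction
#'   effort into elbow/wrist flexor channels and reduces attainable elbow
#'   extension; 0 restores independent joints.
#' @param synergy_leak 12 x 12 non-negative leak matrix; observed activation
#'   is `(I + k_syn * leak) %*% intended`.
#' @param noise_sd Additive sensor noise SD (normalized units).
#' @param mvc_scale Overall amplitude scale.
#' @param posture_factor Relative pattern perturbation per 45 degrees of
#'   horizontal-adduction posture change.
#' @param policy Named list of behavioural constants; see Details source.
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(activation_patterns = .default_patterns(),
                            k_syn = 0.5,
                            synergy_leak = .default_leak(),
                            noise_sd = 0.02, mvc_scale = 1,
                            posture_factor = 0.03,
                            policy = list()) {
  stopifnot(all(activation_patterns >= 0), k_syn >= 0,
            all(synergy_leak >= 0), noise_sd >= 0, mvc_scale > 0)
  defaults <- list(
    ns_intensity = 1.0,     # no-support anti-gravity abduction intensity
    rt_lift = 0.9,          # real-time abduction command intensity (lift)
    rt_stab = 0.45,         # real-time sustained stabilization (reach/return)
    static_stab = 0.1,      # residual shoulder drive under static support
    lower_ns = 0.6,         # eccentric abductor intensity lowering (no support)
    lower_rt = 0.9,         # adduction command intensity lowering (real time)
    lift_s = 2.5,           # self-paced vertical transit time, floor to 90 deg
    reach_intensity = 0.6,  # reach-pattern drive during reach/return
    press_frac = 0.2,       # fraction of W pressed down via extension synergy
    phi_rest = 130,         # resting elbow flexion (deg)
    phi_range = 110,        # elbow range recruitable at zero shoulder effort
    theta_h_start = 30,     # starting horizontal adduction (deg)
    h_syn = 35,             # horizontal-reach loss (deg) at full synergy drive
    tau_h = 0.8,            # horizontal first-order time constant (s)
    reach_s = 3,            # reach-phase dwell (s)
    slow_load = 0.6,        # pace slowing per unit shoulder effort (gravity load)
    kp = 150, kd = 40)      # user vertical PD effort (N/m, N s/m)
  policy <- utils::modifyList(defaults, policy)
  M <- diag(ncol(activation_patterns)) + k_syn * synergy_leak
  dimnames(M) <- dimnames(synergy_leak)
  structure(list(activation_patterns = activation_patterns,
                 k_syn = k_syn, synergy_leak = synergy_leak, coupling = M,
                 noise_sd = noise_sd, mvc_scale = mvc_scale,
                 posture_factor = posture_factor, policy = policy),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("subject_profile: %d patterns x %d channels, k_syn = %g, noise_sd = %g\n",
              nrow(x$activation_patterns), ncol(x$activation_patterns),
              x$k_syn, x$noise_sd))
  invisible(x)
}

# unit-RMS band-limited (20-350 Hz) Gaussian carrier, n x nch
.carrier <- function(n, nch, fs) {
  filt <- emg_filters(fs)
  g <- matrix(stats::rnorm(n * nch), n, nch)
  g <- apply(g, 2, function(x) .iir_filter(x, filt$bp$b, filt$bp$a))
  sweep(g, 2, sqrt(colMeans(g^2)), "/")
}

# slow (>= 250 ms) multiplicative amplitude modulation around 1
.slow_modulation <- function(n, nch, fs, depth = 0.1) {
  w <- max(1L, round(0.25 * fs))
  m <- matrix(stats::rnorm(n * nch), n, nch)
  kern <- rep(1 / w, w)
  m <- apply(m, 2, function(x)
    as.numeric(stats::filter(c(rep(x[1], w - 1), x), kern, sides = 1))[w - 1 + seq_len(n)])
  m <- sweep(m, 2, apply(m, 2, stats::sd), "/")
  m[] <- pmax(0, 1 + depth * m)   # pmax would drop the dim attribute
  m
}

# observed per-channel amplitude for a named intent intensity vector
.observed_amplitude <- function(profile, intents, posture = 45) {
  drive <- numeric(ncol(profile$activation_patterns))
  for (cl in names(intents))
    drive <- drive + intents[[cl]] * profile$activation_patterns[cl, ]
  a <- as.numeric(profile$coupling %*% drive) * profile$mvc_scale
  # deterministic small posture perturbation, alternating sign per channel
  pert <- rep_len(c(1, -1), length(a))
  a * (1 + profile$posture_factor * (posture - 45) / 45 * pert)
}

#' Generate a class-conditioned multi-channel EMG trial
#'
#' Each channel is band-limited Gaussian noise amplitude-modulated by the
#' synergy-coupled activation `coupling %*% (intensity * pattern[class])`,
#' with slow (>= 250 ms) amplitude fluctuation and additive sensor noise.
#' Reproducible for a fixed seed.
#'
#' @param profile A [subject_profile()].
#' @param class Row name of the activation-pattern matrix.
#' @param intensity Drive intensity (>= 0); 0 leaves only sensor noise.
#' @param duration_s Trial duration in seconds.
#' @param posture Horizontal-adduction posture tag (deg); perturbs patterns
#'   by the profile's small posture factor.
#' @param fs Sampling rate (Hz).
#' @param seed Optional integer seed.
#' @param label Class label stored on the recording (defaults to `class`).
#' @return An [emg_recording()].
#' @export
generate_class_emg <- function(profile, class, intensity = 1, duration_s = 10,
                               posture = 45, fs = 1000, seed = NULL,
                               label = class) {
  stopifnot(inherits(profile, "subject_profile"), intensity >= 0,
            duration_s > 0, class %in% rownames(profile$activation_patterns))
  n <- round(duration_s * fs)
  nch <- ncol(profile$activation_patterns)
  a <- .observed_amplitude(profile,
                           stats::setNames(list(intensity), class), posture)
  .with_seed(seed, {
    sig <- .carrier(n, nch, fs) * .slow_modulation(n, nch, fs)
    sig <- sweep(sig, 2, a, "*") +
      matrix(stats::rnorm(n * nch, sd = profile$noise_sd), n, nch)
    emg_recording(sig, fs, colnames(profile$activation_patterns),
                  label = label, posture = posture)
  })
}

#' Build the training protocol of labeled EMG trials
#'
#' Three horizontal-adduction postures (0, 45, 90 degrees) x 2 trials x
#' 3 classes (abduction, adduction, no movement) = 18 ten-second trials,
#' plus 5 tabletop-supported and 5 limb-weight-supported reach trials labeled
#' `no_movement` (supported reaching is included so the classifier separates
#' reaching from vertical intent). Mode `"both"` emits all 28 trials;
#' `"position"` and `"force"` use the 18 plus their 5 matching reach trials
#' (23 in total, 11 of them labeled `no_movement`).
#'
#' @param profile A [subject_profile()].
#' @param mode `"both"`, `"position"`, or `"force"`.
#' @param duration_s Per-trial duration (s), default 10.
#' @param seed Integer seed; every trial derives its own sub-stream.
#' @return List of [emg_recording()]s with a `composition` attribute.
#' @export
build_training_protocol <- function(profile, mode = c("both", "position", "force"),
                                    duration_s = 10, seed = 1) {
  mode <- match.arg(mode)
  trials <- list()
  k <- 0L
  for (posture in c(0, 45, 90)) {
    for (rep in 1:2) {
      for (cl in c("abduction", "adduction", "no_movement")) {
        k <- k + 1L
        r <- generate_class_emg(profile, cl, intensity = 1,
                                duration_s = duration_s, posture = posture,
                                seed = .sub_seed(seed, k))
        r$trial_id <- sprintf("train_%02d_%s_p%02d_r%d", k, cl, posture, rep)
        trials[[k]] <- r
      }
    }
  }
  reach_sets <- list(table = "position", limb_weight = "force")
  for (support in names(reach_sets)) {
    if (mode != "both" && reach_sets[[support]] != mode) next
    for (rep in 1:5) {
      k <- k + 1L
      r <- generate_class_emg(profile, "reach",
                              intensity = profile$policy$reach_intensity / 0.6 * 0.8,
                              duration_s = duration_s, posture = 90,
                              seed = .sub_seed(seed, k), label = "no_movement")
      r$trial_id <- sprintf("train_%02d_reach_%s_r%d", k, support, rep)
      trials[[k]] <- r
    }
  }
  structure(trials,
            composition = table(vapply(trials, function(t) t$label, character(1))))
}

#' Train a classifier from a training protocol
#'
#' Conditions each trial causally (matching the real-time loop), derives the
#' default ZC/SSC amplitude gates as 0.01 x per-channel conditioned-training
#' RMS, extracts windowed features, and fits the classifier.
#'
#' @param protocol Output of [build_training_protocol()].
#' @param lambda Covariance shrinkage, see [train_classifier()].
#' @param window_ms,step_ms Windowing (defaults 200/25 ms).
#' @param eq1_variant Proportional-control form.
#' @return An `emg_classifier`.
#' @export
train_from_protocol <- function(protocol, lambda = 0.1, window_ms = 200,
                                step_ms = 25, eq1_variant = "s_mav_sq") {
  cond <- lapply(protocol, condition_signal, mode = "causal")
  rms <- sqrt(Reduce(`+`, lapply(cond, function(r) colMeans(r$samples^2))) /
                length(cond))
  thresholds <- 0.01 * sqrt(rms)
  labels <- vapply(protocol, function(t) t$label, character(1))
  feats <- lapply(cond, extract_features_recording, window_ms = window_ms,
                  step_ms = step_ms, thresholds = thresholds)
  by_class <- function(part) {
    out <- list()
    for (cl in intersect(.CLASSES, unique(labels)))
      out[[cl]] <- do.call(rbind, lapply(feats[labels == cl], `[[`, part))
    out
  }
  train_classifier(by_class("features"), by_class("mav"), lambda = lambda,
                   thresholds = thresholds, eq1_variant = eq1_variant)
}

#' User intent and effort policy for one task phase
#'
#' Encodes the scripted lift - reach - return - lower behaviour. During lift
#' the abduction intent scales with the unsupported fraction of limb weight
#' `max(0, W - F_robot) / W`; under real-time control a sustained
#' stabilization drive persists through reach and return (post-stroke
#' co-activation plus command maintenance). The attainable elbow extension
#' during reach is limited by the abnormal synergy:
#' `phi_e_min = phi_rest - phi_range * (1 - k_syn * shoulder_effort)`,
#' clamped at 0 - more shoulder effort means less elbow extension. The
#' horizontal-adduction target is reduced symmetrically.
#'
#' @param phase One of `"lift"`, `"reach"`, `"return"`, `"lower"`, `"done"`.
#' @param pose List with `theta_abd`, `theta_h`, `phi_e` (deg).
#' @param F_robot Current robot support force (N).
#' @param profile A [subject_profile()].
#' @param condition Support-condition tag (changes effort strategy).
#' @param arm An [arm_model()] (for the limb weight).
#' @return List with `intents` (named intensity list over pattern rows),
#'   `shoulder_effort` (scalar drive entering the synergy model),
#'   `phi_e_target`, `theta_h_target`.
#' @export
user_policy <- function(phase, pose, F_robot, profile, condition,
                        arm = arm_model()) {
  p <- profile$policy
  rt <- condition %in% c("position", "force")
  unsupported <- max(0, (arm$W - F_robot)) / arm$W
  intents <- list()
  effort <- 0
  if (phase == "lift") {
    effort <- if (rt) max(p$rt_stab, p$rt_lift * unsupported)
              else p$ns_intensity * unsupported
    if (effort > 0) intents$abduction <- effort
  } else if (phase %in% c("reach", "return")) {
    effort <- if (rt) p$rt_stab
              else if (condition == "no_support") p$ns_intensity
              else p$static_stab * unsupported + 0.02
    if (effort > 0) intents$abduction <- effort
    intents$reach <- p$reach_intensity
  } else if (phase == "lower") {
    if (rt) {
      intents$adduction <- p$lower_rt
    } else if (condition == "no_support") {
      effort <- p$lower_ns
      intents$abduction <- effort            # eccentric abductor control
    } else {
      intents$adduction <- 0.15
    }
  }
  syn <- min(1, profile$k_syn * effort)
  phi_e_target <- max(0, p$phi_rest - p$phi_range * (1 - syn))
  theta_h_target <- 90 - p$h_syn * syn
  list(intents = intents, shoulder_effort = effort,
       phi_e_target = phi_e_target, theta_h_target = theta_h_target)
}
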