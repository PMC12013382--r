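# Shared, lazily built fixtures. Expensive objects (trained models, sessions)
# are memoized so multiple test files reuse them within one run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

fx_profile <- function() fixture("profile", subject_profile())

fx_arm <- function() fixture("arm", arm_model())

# short-trial protocol + model: cheap enough for unit tests
fx_small_protocol <- function() fixture("small_protocol",
  build_training_protocol(fx_profile(), mode = "position", duration_s = 2,
                          seed = 11))

fx_small_model <- function() fixture("small_model",
  train_from_protocol(fx_small_protocol()))

# full-length (10 s trial) mode-specific models, study defaults
fx_model_position <- function() fixture("model_position",
  train_from_protocol(build_training_protocol(fx_profile(), mode = "position",
                                              seed = 21)))

fx_model_force <- function() fixture("model_force",
  train_from_protocol(build_training_protocol(fx_profile(), mode = "force",
                                              seed = 22)))

# default closed-loop sessions (10 trials each) under four conditions
fx_sessions <- function() fixture("sessions", {
  prof <- fx_profile()
  list(no_support = simulate_session(prof, "no_support", n_trials = 10,
                                     seed = 101),
       limb_weight = simulate_session(prof, "limb_weight", n_trials = 10,
                                      seed = 102),
       position = simulate_session(prof, "position", fx_model_position(),
                                   n_trials = 10, seed = 103),
       force = simulate_session(prof, "force", fx_model_force(),
                                n_trials = 10, seed = 104))
})

# controller state at the study limits
fx_state <- function(mode, model, arm = fx_arm()) {
  zf <- abduction_to_height(arm$theta_limits[1], arm)
  zc <- abduction_to_height(arm$theta_limits[2], arm)
  controller_state(mode, default_gains(model, arm, mode),
                   z = zf, z_limits = c(zf, zc), F = 0,
                   F_limits = c(0, arm$W))
}

# hand-built classifier with chosen means and identity pooled covariance,
# used as a scaffold for distance-rule oracles
manual_classifier <- function(means, classes = rownames(means)) {
  nf <- ncol(means)
  structure(list(
    classes = classes, class_means = means,
    pooled_covariance = diag(nf), chol = diag(nf), lambda = 0,
    S = matrix(1, length(classes), 2,
               dimnames = list(classes, c("a", "b"))),
    C = stats::setNames(rep(2, length(classes)), classes),
    n_channels = 2, feature_order = colnames(means),
    thresholds = 0, eq1_variant = "s_mav_sq"),
    class = "emg_classifier")
}
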