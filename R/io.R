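# File formats and the command-line surface: EMG trial CSVs with JSON
# sidecars, trial-record CSVs, run configuration, and a thin CLI dispatcher.

.sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write an EMG recording to CSV with a JSON metadata sidecar
#'
#' CSV header `time_ms,ch01,...,chNN`, one row per sample; the sidecar
#' carries fs, channel names, label, posture and identifiers.
#'
#' @param recording An [emg_recording()].
#' @param path Output CSV path; the sidecar goes to the same path with a
#'   `.json` extension.
#' @export
write_emg_csv <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  n <- nrow(recording$samples)
  df <- data.frame(time_ms = (seq_len(n) - 1) * 1000 / recording$fs,
                   recording$samples)
  names(df) <- c("time_ms", sprintf("ch%02d", seq_len(ncol(recording$samples))))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = recording$fs, channel_names = recording$channel_names,
               label = recording$label, posture = recording$posture,
               trial_id = recording$trial_id, session_id = recording$session_id)
  jsonlite::write_json(meta, .sidecar_path(path), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read an EMG recording from CSV (+ JSON sidecar)
#'
#' Validates the header layout, time monotonicity, completeness and, when
#' requested, the channel count.
#'
#' @param path CSV path written in the `time_ms,ch01,...` layout.
#' @param expect_channels Optional required channel count; a mismatch is an
#'   error naming both counts.
#' @return An [emg_recording()].
#' @export
read_emg_csv <- function(path, expect_channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_ms" ||
      !all(grepl("^ch[0-9]+$", names(df)[-1])))
    stop("unexpected header in ", path,
         ": want time_ms,ch01,...,chNN, got ",
         paste(utils::head(names(df), 4), collapse = ","))
  nch <- ncol(df) - 1L
  if (!is.null(expect_channels) && nch != expect_channels)
    stop("channel count mismatch in ", path, ": file has ", nch,
         ", configuration demands ", expect_channels)
  if (anyNA(df)) stop("missing values in ", path)
  t <- df$time_ms
  if (any(diff(t) <= 0)) stop("non-monotonic time column in ", path)
  meta <- list()
  sc <- .sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  fs <- if (!is.null(meta$fs)) meta$fs else 1000 / stats::median(diff(t))
  emg_recording(as.matrix(df[, -1, drop = FALSE]), fs = fs,
                channel_names = meta$channel_names %||% NULL,
                label = meta$label %||% NA_character_,
                posture = meta$posture %||% NA_real_,
                trial_id = meta$trial_id %||% NA_character_,
                session_id = meta$session_id %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trial record to CSV (+ JSON sidecar)
#'
#' Columns `time_ms, theta_abd, theta_h, phi_e, z, F_applied, F_sensed,
#' env01..envNN` where the env columns are the per-channel 200 ms rectified
#' moving-average EMG envelopes.
#'
#' @param trial A `trial_record`.
#' @param path Output CSV path.
#' @export
write_trial_csv <- function(trial, path) {
  env <- apply(trial$emg, 2, emg_envelope, fs = trial$fs)
  df <- data.frame(time_ms = trial$time_ms, theta_abd = trial$theta_abd,
                   theta_h = trial$theta_h, phi_e = trial$phi_e,
                   z = trial$z, F_applied = trial$F_applied,
                   F_sensed = trial$F_sensed, env)
  names(df) <- c("time_ms", "theta_abd", "theta_h", "phi_e", "z",
                 "F_applied", "F_sensed",
                 sprintf("env%02d", seq_len(ncol(trial$emg))))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(condition = trial$condition,
                            trial_id = trial$trial_id, fs = trial$fs,
                            flags = trial$flags),
                       .sidecar_path(path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a trial record CSV written by [write_trial_csv()]
#'
#' The env columns hold precomputed envelopes, not raw EMG, so the result
#' supports excursion and envelope-based effort analysis but not
#' re-classification.
#'
#' @param path Trial CSV path.
#' @return List of class `trial_record_csv` with the pose/force series and
#'   an `envelope` matrix.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- list()
  sc <- .sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  env_cols <- grep("^env[0-9]+$", names(df))
  structure(list(condition = meta$condition %||% NA_character_,
                 trial_id = meta$trial_id %||% basename(path),
                 fs = meta$fs %||% 1000 / stats::median(diff(df$time_ms)),
                 time_ms = df$time_ms, theta_abd = df$theta_abd,
                 theta_h = df$theta_h, phi_e = df$phi_e, z = df$z,
                 F_applied = df$F_applied, F_sensed = df$F_sensed,
                 envelope = as.matrix(df[, env_cols, drop = FALSE]),
                 flags = meta$flags),
            class = "trial_record_csv")
}

#' Default run configuration
#'
#' @return Named list of pipeline settings (sampling, windowing, classifier,
#'   controller, arm) with the study defaults.
#' @export
default_run_config <- function() {
  list(fs = 1000, n_channels = 12, window_ms = 200, step_ms = 25,
       band_pass_hz = c(20, 350), band_stop_hz = c(50, 70),
       lambda = 0.1, eq1_variant = "s_mav_sq",
       controller = list(mode = "position"),
       arm = list(L_u = 0.30, L_f = 0.35, W = 30),
       n_trials = 10, seed = 1)
}

#' Read a JSON run configuration, merged over the defaults
#' @param path JSON file; missing entries fall back to
#'   [default_run_config()].
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(default_run_config(),
                           jsonlite::read_json(path, simplifyVector = TRUE))
  if (cfg$window_ms <= cfg$step_ms || cfg$step_ms <= 0)
    stop("invalid windowing: need window_ms > step_ms > 0")
  cfg
}

.cli_args <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[[i]], "--")) {
      flags[[substring(args[[i]], 3)]] <- args[[i + 1L]]
      i <- i + 2L
    } else i <- i + 1L
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands used by the `inst/cli/myoreach.R`
#' wrapper script:
#' \describe{
#'   \item{simulate-data}{`--out DIR [--seed N] [--mode both]` writes a
#'     training protocol of EMG trial CSVs plus a manifest.}
#'   \item{train}{`--data DIR --out MODEL.json [--mode both]` trains the
#'     classifier from a protocol directory.}
#'   \item{run-session}{`--model MODEL.json --condition TAG --out DIR
#'     [--seed N] [--trials N]` runs closed-loop trials and writes trial
#'     CSVs.}
#'   \item{evaluate}{`--session DIR... --out DIR` (comma-separated session
#'     directories) writes excursion and effort summary CSVs.}
#' }
#'
#' @param args Character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the primary output path.
#' @export
cli_main <- function(args) {
  if (length(args) < 1L)
    stop("usage: myoreach <simulate-data|train|run-session|evaluate> [--flags]")
  cmd <- args[[1]]
  fl <- .cli_args(args[-1])
  seed <- as.integer(fl$seed %||% 1)
  switch(cmd,
    "simulate-data" = {
      out <- fl$out %||% stop("simulate-data needs --out DIR")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      prof <- subject_profile()
      prot <- build_training_protocol(prof, mode = fl$mode %||% "both",
                                      seed = seed)
      for (r in prot)
        write_emg_csv(r, file.path(out, paste0(r$trial_id, ".csv")))
      jsonlite::write_json(
        list(n_trials = length(prot), seed = seed,
             mode = fl$mode %||% "both",
             trials = vapply(prot, `[[`, character(1), "trial_id")),
        file.path(out, "manifest.json"), auto_unbox = TRUE)
      message("wrote ", length(prot), " training trials to ", out)
      invisible(out)
    },
    "train" = {
      data_dir <- fl$data %||% stop("train needs --data DIR")
      out <- fl$out %||% stop("train needs --out MODEL.json")
      files <- list.files(data_dir, pattern = "^train_.*\\.csv$",
                          full.names = TRUE)
      if (!length(files)) stop("no training trial CSVs in ", data_dir)
      prot <- lapply(files, read_emg_csv)
      model <- train_from_protocol(prot)
      save_classifier(model, out)
      message("trained on ", length(prot), " trials -> ", out)
      invisible(out)
    },
    "run-session" = {
      model <- load_classifier(fl$model %||% stop("run-session needs --model"))
      cond <- fl$condition %||% stop("run-session needs --condition")
      out <- fl$out %||% stop("run-session needs --out DIR")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      n <- as.integer(fl$trials %||% 10)
      trials <- simulate_session(subject_profile(), cond, model,
                                 n_trials = n, seed = seed)
      for (tr in trials)
        write_trial_csv(tr, file.path(out, paste0(tr$trial_id, ".csv")))
      jsonlite::write_json(list(condition = cond, n_trials = n, seed = seed),
                           file.path(out, "manifest.json"), auto_unbox = TRUE)
      message("wrote ", n, " ", cond, " trials to ", out)
      invisible(out)
    },
    "evaluate" = {
      dirs <- strsplit(fl$session %||% stop("evaluate needs --session DIR[,DIR...]"),
                       ",")[[1]]
      out <- fl$out %||% stop("evaluate needs --out DIR")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      sessions <- lapply(dirs, function(d)
        lapply(list.files(d, pattern = "\\.csv$", full.names = TRUE),
               read_trial_csv))
      names(sessions) <- vapply(sessions, function(s)
        s[[1]]$condition %||% "unknown", character(1))
      exc <- do.call(rbind, lapply(names(sessions), function(cond) {
        mets <- lapply(sessions[[cond]], excursion_metrics)
        ok <- vapply(mets, `[[`, logical(1), "valid")
        data.frame(condition = cond,
                   elbow = mean(vapply(mets[ok], `[[`, numeric(1),
                                       "elbow_metric")),
                   shoulder = mean(vapply(mets[ok], `[[`, numeric(1),
                                          "shoulder_metric")))
      }))
      # envelope-based effort: shoulder channels 1:3 (deltoids) + 6 (supraspin)
      all_env <- do.call(rbind, lapply(unlist(sessions, recursive = FALSE),
                                       `[[`, "envelope"))
      smax <- apply(all_env, 2, max)
      shoulder <- c(1, 2, 3, 6)
      eff <- vapply(names(sessions), function(cond)
        sum(vapply(sessions[[cond]], function(tr)
          sum(sweep(tr$envelope[, shoulder, drop = FALSE], 2,
                    smax[shoulder], "/")), numeric(1))), numeric(1))
      utils::write.csv(exc, file.path(out, "excursion.csv"), row.names = FALSE)
      utils::write.csv(data.frame(condition = names(eff), effort = eff),
                       file.path(out, "effort.csv"), row.names = FALSE)
      message("wrote excursion.csv and effort.csv to ", out)
      invisible(out)
    },
    stop("unknown command '", cmd, "'"))
}
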