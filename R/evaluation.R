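# Reach-excursion metrics, normalized EMG effort, paired one-sided t-tests,
# condition summary tables, and unrelated-movement confusion tables.

#' Reach-excursion metrics of one trial within the vertical target window
#'
#' Masks the trial to samples where shoulder abduction lies in the 80-100
#' degree target window and reports the minimum elbow-flexion angle (smaller
#' = more extension = better reach) and the maximum horizontal-adduction
#' angle (larger = further reach) over the mask. Extremes attained outside
#' the window are ignored.
#'
#' @param trial A `trial_record` (or any list with `theta_abd`, `theta_h`,
#'   `phi_e` series).
#' @param window Abduction window in degrees, default `c(80, 100)`.
#' @return List with `trial_id`, `elbow_metric` (deg), `shoulder_metric`
#'   (deg), and `valid` (`FALSE`, with `NA` metrics, when the window is never
#'   entered).
#' @export
excursion_metrics <- function(trial, window = c(80, 100)) {
  mask <- trial$theta_abd >= window[1] & trial$theta_abd <= window[2]
  if (!any(mask)) {
    return(list(trial_id = trial$trial_id, elbow_metric = NA_real_,
                shoulder_metric = NA_real_, valid = FALSE))
  }
  list(trial_id = trial$trial_id,
       elbow_metric = min(trial$phi_e[mask]),
       shoulder_metric = max(trial$theta_h[mask]),
       valid = TRUE)
}

#' Rectified moving-average EMG envelope
#'
#' Rectifies the signal and applies a causal 200 ms moving average; the
#' initial partial windows average over the samples available so far.
#'
#' @param x Numeric vector (one channel).
#' @param fs Sampling rate (Hz).
#' @param window_ms Moving-average length (ms), default 200.
#' @return Envelope vector, same length as `x`.
#' @export
emg_envelope <- function(x, fs, window_ms = 200) {
  w <- max(1L, round(window_ms * fs / 1000))
  cs <- cumsum(abs(x))
  n <- length(x)
  full <- if (n > w) (cs[(w + 1):n] - cs[1:(n - w)]) / w else numeric(0)
  c(cs[seq_len(min(w, n))] / seq_len(min(w, n)), full)
}

#' Per-channel session-wide envelope maximum
#'
#' @param trials List of `trial_record`s (typically all trials of all
#'   conditions of one session).
#' @param window_ms Envelope moving-average length (ms).
#' @return Named numeric vector, one maximum per channel.
#' @export
session_channel_max <- function(trials, window_ms = 200) {
  maxima <- sapply(trials, function(tr)
    apply(tr$emg, 2, function(x) max(emg_envelope(x, tr$fs, window_ms))))
  apply(rbind(maxima), 1, max)
}

#' Summed normalized shoulder-EMG effort of a condition
#'
#' For each trial, each channel's rectified 200 ms moving-average envelope is
#' divided by that channel's session-wide maximum, then summed across the
#' selected shoulder channels, across time, and across all trials of the
#' condition. The default channel set (three deltoid heads plus
#' supraspinatus) is the one used for the cumulative statistic; the heatmap
#' set substitutes upper trapezius for supraspinatus.
#'
#' @param trials List of `trial_record`s of one condition.
#' @param session_max Per-channel maxima from [session_channel_max()]
#'   computed over the whole session (all conditions).
#' @param channels Channel names to sum; zero-maximum channels are excluded
#'   with a warning.
#' @param window_ms Envelope moving-average length (ms).
#' @return List with `total` (scalar summed normalized effort) and
#'   `per_trial` (vector).
#' @export
emg_effort <- function(trials, session_max,
                       channels = c("ant_delt", "mid_delt", "post_delt",
                                    "supraspin"),
                       window_ms = 200) {
  chs <- channels
  bad <- chs[session_max[chs] == 0 | is.na(session_max[chs])]
  if (length(bad)) {
    warning("excluding channel(s) with zero session maximum: ",
            paste(bad, collapse = ", "))
    chs <- setdiff(chs, bad)
  }
  per_trial <- vapply(trials, function(tr) {
    sum(vapply(chs, function(ch)
      sum(emg_envelope(tr$emg[, ch], tr$fs, window_ms)) / session_max[[ch]],
      numeric(1)))
  }, numeric(1))
  list(total = sum(per_trial), per_trial = per_trial)
}

#' Paired one-sided t-test
#'
#' Classical paired t statistic on `a - b` with `n - 1` degrees of freedom
#' and a one-sided p-value in the stated direction (`"less"`: mean of `a`
#' below mean of `b`). Zero variance of the differences is flagged and gives
#' p of 0.5 (all-zero differences) or 0/1 by the sign convention.
#'
#' @param a,b Paired per-subject values, equal length >= 2.
#' @param alternative `"less"` or `"greater"` (direction of `a` vs `b`).
#' @return List with `t`, `df`, `p`, and `flag` (degenerate-variance note,
#'   `NULL` otherwise).
#' @export
paired_one_sided_t <- function(a, b, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    m <- mean(d)
    p <- if (m == 0) 0.5
         else if ((m < 0) == (alternative == "less")) 0 else 1
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = n - 1, p = p,
                flag = "zero variance of paired differences"))
  }
  t <- mean(d) / (s / sqrt(n))
  p <- if (alternative == "less") stats::pt(t, n - 1)
       else stats::pt(t, n - 1, lower.tail = FALSE)
  list(t = t, df = n - 1, p = p, flag = NULL)
}

#' Mean (SD) summary per participant-by-condition cell and per condition
#'
#' Per-cell mean and sample SD across trials, and a group row per condition:
#' mean and sample SD across participant means. A single-participant group SD
#' is undefined and flagged as `NA`.
#'
#' @param data Data frame with columns `participant`, `condition`, `value`
#'   (one row per trial, or per participant when already aggregated).
#' @return List with `cells` (participant x condition mean/SD) and `group`
#'   (per-condition mean/SD across participant means).
#' @export
condition_summary <- function(data) {
  stopifnot(all(c("participant", "condition", "value") %in% names(data)))
  agg <- stats::aggregate(value ~ participant + condition, data,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  cells <- data.frame(participant = agg$participant,
                      condition = agg$condition,
                      mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  grp <- do.call(rbind, lapply(split(cells, cells$condition), function(d)
    data.frame(condition = d$condition[1], n = nrow(d),
               mean = mean(d$mean),
               sd = if (nrow(d) > 1) stats::sd(d$mean) else NA_real_)))
  rownames(grp) <- NULL
  list(cells = cells, group = grp)
}

#' Unweighted average row of a confusion table
#'
#' The per-class unweighted mean over tasks, the operation producing the
#' "average - all tasks" row of an unrelated-movement confusion table.
#'
#' @param tab Numeric matrix or data frame, rows = tasks, columns = classes
#'   (percentages).
#' @param digits Rounding for the printed style (integers); `NULL` keeps full
#'   precision.
#' @return Named numeric vector of per-class averages.
#' @export
confusion_average <- function(tab, digits = 0) {
  m <- as.matrix(tab)
  avg <- colMeans(m)
  if (!is.null(digits)) avg <- round(avg, digits)
  avg
}

#' Offline confusion table of unrelated movements
#'
#' Windows and featurizes each unrelated-movement recording identically to
#' training (causal conditioning, 200/25 ms windows, the model's ZC/SSC
#' gates), classifies every window with the fixed three-class model, and
#' tabulates the percentage of windows per class. An `average` row holds the
#' unweighted mean over tasks.
#'
#' @param model An `emg_classifier`.
#' @param recordings_by_task Named list: task -> [emg_recording()] or list of
#'   recordings.
#' @param window_ms,step_ms Windowing (defaults 200/25 ms).
#' @param support_condition Tag stored on the result.
#' @return Data frame (rows: tasks + `average`; columns: the three classes)
#'   of percentages; attribute `support_condition`.
#' @export
unrelated_movement_confusion <- function(model, recordings_by_task,
                                         window_ms = 200, step_ms = 25,
                                         support_condition = NA_character_) {
  rows <- lapply(recordings_by_task, function(recs) {
    if (inherits(recs, "emg_recording")) recs <- list(recs)
    cls <- unlist(lapply(recs, function(r) {
      fx <- extract_features_recording(condition_signal(r, "causal"),
                                       window_ms, step_ms,
                                       thresholds = model$thresholds)
      classify_features(model, fx$features)$class
    }))
    100 * vapply(model$classes, function(cl) mean(cls == cl), numeric(1))
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, average = confusion_average(tab, digits = NULL))
  structure(as.data.frame(tab), support_condition = support_condition)
}

#' Session-level excursion and effort analysis
#'
#' Convenience wrapper reproducing the study's analyses on simulated
#' sessions: per-condition excursion metrics (trial means) and summed
#' normalized shoulder effort.
#'
#' @param sessions Named list: condition tag -> list of `trial_record`s.
#' @param channels Shoulder channel set for the effort sum.
#' @return List with `excursion` (data frame: condition, mean elbow and
#'   shoulder metrics) and `effort` (named vector of summed normalized
#'   effort per condition).
#' @export
analyze_sessions <- function(sessions,
                             channels = c("ant_delt", "mid_delt", "post_delt",
                                          "supraspin")) {
  smax <- session_channel_max(unlist(sessions, recursive = FALSE))
  exc <- do.call(rbind, lapply(names(sessions), function(cond) {
    mets <- lapply(sessions[[cond]], excursion_metrics)
    ok <- vapply(mets, `[[`, logical(1), "valid")
    data.frame(condition = cond,
               elbow = mean(vapply(mets[ok], `[[`, numeric(1), "elbow_metric")),
               shoulder = mean(vapply(mets[ok], `[[`, numeric(1),
                                      "shoulder_metric")),
               n_valid = sum(ok))
  }))
  eff <- vapply(names(sessions), function(cond)
    emg_effort(sessions[[cond]], smax, channels)$total, numeric(1))
  list(excursion = exc, effort = eff)
}
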