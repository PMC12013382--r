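# Three-class minimum-Mahalanobis-distance classifier with class-wise
# proportional control.
#
# The classifier is LDA-style: per-class feature means with one pooled,
# shrinkage-regularized covariance. The class of a window is the one whose
# mean is nearest in Mahalanobis distance; the proportional-control magnitude
# is computed from the window's per-channel MAV sub-vector against stored
# training centers.

.CLASSES <- c("no_movement", "abduction", "adduction")

#' Per-class, per-channel training MAV centers
#'
#' `S[i, j]` is the mean over all training windows of class `i` of the MAV of
#' channel `j`.
#'
#' @param mav_by_class Named list, one matrix (`windows x channels`) per class.
#' @return Matrix `n_classes x n_channels` of centers.
#' @export
compute_centers <- function(mav_by_class) {
  stopifnot(is.list(mav_by_class), !is.null(names(mav_by_class)))
  rows <- lapply(names(mav_by_class), function(cl) {
    m <- as.matrix(mav_by_class[[cl]])
    if (nrow(m) < 1L)
      stop("no training windows for class '", cl, "'")
    mu <- colMeans(m)
    silent <- which(mu == 0)
    if (length(silent))
      warning("class '", cl, "': silent channel(s) ",
              paste(silent, collapse = ", "), " (all-zero training MAV)")
    mu
  })
  S <- do.call(rbind, rows)
  rownames(S) <- names(mav_by_class)
  S
}

#' Per-class proportional-control normalization factors
#'
#' `C[i]` is the channel-sum of squared centers for class `i`.
#'
#' @param S Center matrix from [compute_centers()] (or one row of it).
#' @return Numeric vector of factors, one per class; a zero factor flags the
#'   class unusable for proportional control (warning).
#' @export
compute_normalization <- function(S) {
  S <- rbind(S)
  C <- rowSums(S^2)
  if (any(C == 0))
    warning("class(es) ", paste(rownames(S)[C == 0], collapse = ", "),
            " have zero normalization: unusable for proportional control")
  C
}

#' Proportional-control magnitude for one class
#'
#' The default (literal) form is
#' `PC_i = (1 / C_i) * sum_j S[i, j] * MAV_j^2`. The alternative `"dot"`
#' variant `PC_i = (1 / C_i) * sum_j S[i, j] * MAV_j` evaluates to 1 when the
#' current MAVs equal the class centers.
#'
#' @param mav_vector Per-channel MAV of the current window.
#' @param model An [train_classifier()] model (or any list with `S` and `C`).
#' @param class Class name or index.
#' @param variant `"s_mav_sq"` (default, literal) or `"dot"`.
#' @return Non-negative scalar; 0 with a warning when `C_i = 0`.
#' @export
proportional_control <- function(mav_vector, model, class,
                                 variant = c("s_mav_sq", "dot")) {
  variant <- if (missing(variant) && !is.null(model$eq1_variant))
    model$eq1_variant else match.arg(variant)
  i <- if (is.character(class)) match(class, rownames(model$S)) else class
  S_i <- model$S[i, ]
  C_i <- unname(model$C[i])
  stopifnot(length(mav_vector) == length(S_i))
  if (C_i == 0) {
    warning("zero normalization factor for class ", class,
            "; proportional control unavailable")
    return(0)
  }
  if (variant == "dot") sum(S_i * mav_vector) / C_i
  else sum(S_i * mav_vector^2) / C_i
}

# pooled within-class covariance, (sum_c (n_c - 1) * cov_c) / (N - g)
.pooled_covariance <- function(feature_list) {
  N <- sum(vapply(feature_list, nrow, integer(1)))
  g <- length(feature_list)
  acc <- 0
  for (m in feature_list) acc <- acc + (nrow(m) - 1) * stats::cov(m)
  acc / (N - g)
}

#' Train the three-class minimum-Mahalanobis classifier
#'
#' Computes per-class feature means, a shrinkage-regularized pooled
#' covariance `(1 - lambda) * Sigma + lambda * diag(Sigma)`, and the
#' proportional-control centers `S` and normalization factors `C`.
#'
#' @param features_by_class Named list of feature matrices
#'   (`windows x n_features`), one per class, in class order
#'   `no_movement, abduction, adduction` (any consistent order is accepted
#'   and preserved).
#' @param mav_by_class Named list of per-window MAV matrices
#'   (`windows x n_channels`), same classes.
#' @param lambda Shrinkage weight in `[0, 1]`; default 0.1. The 120-dim
#'   feature space with limited windows makes the raw pooled covariance
#'   ill-conditioned.
#' @param thresholds Per-channel ZC/SSC amplitude gates used at feature time
#'   (stored so deployment matches training).
#' @param eq1_variant Proportional-control form, see [proportional_control()].
#' @return Object of class `emg_classifier`.
#' @export
train_classifier <- function(features_by_class, mav_by_class, lambda = 0.1,
                             thresholds = 0, eq1_variant = "s_mav_sq") {
  stopifnot(is.list(features_by_class), length(features_by_class) >= 2L,
            identical(names(features_by_class), names(mav_by_class)),
            lambda >= 0, lambda <= 1)
  features_by_class <- lapply(features_by_class, as.matrix)
  nf <- unique(vapply(features_by_class, ncol, integer(1)))
  if (length(nf) != 1L) stop("inconsistent feature length across classes")
  if (any(vapply(features_by_class, nrow, integer(1)) < 2L))
    stop("every class needs at least 2 training windows")
  means <- do.call(rbind, lapply(features_by_class, colMeans))
  sigma <- .pooled_covariance(features_by_class)
  sigma_l <- (1 - lambda) * sigma + lambda * diag(diag(sigma), nf)
  R <- tryCatch(chol(sigma_l), error = function(e)
    stop("pooled covariance singular even after shrinkage (lambda = ", lambda,
         "); try a larger lambda", call. = FALSE))
  S <- compute_centers(mav_by_class)
  C <- compute_normalization(S)
  structure(list(
    classes = names(features_by_class),
    class_means = means,
    pooled_covariance = sigma_l,
    chol = R,
    lambda = lambda,
    S = S, C = C,
    n_channels = ncol(S),
    feature_order = colnames(features_by_class[[1]]),
    thresholds = thresholds,
    eq1_variant = eq1_variant),
    class = "emg_classifier")
}

#' @export
print.emg_classifier <- function(x, ...) {
  cat(sprintf("emg_classifier: %d classes (%s), %d features, lambda = %g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              ncol(x$class_means), x$lambda))
  invisible(x)
}

# Mahalanobis distances of rows of X to each class mean under the pooled
# covariance; returns a n_windows x n_classes matrix
.class_distances <- function(model, X) {
  X <- rbind(X)
  d <- sapply(seq_along(model$classes), function(i) {
    V <- forwardsolve(t(model$chol), t(X) - model$class_means[i, ])
    sqrt(colSums(V^2))
  })
  d <- rbind(d)
  colnames(d) <- model$classes
  d
}

# winner index with the safety tie-break: ties including no_movement go to
# no_movement; other ties go to the lower class index
.decide <- function(d, classes) {
  hit <- which(d <= min(d) + 0)            # exact ties
  nm <- match("no_movement", classes)
  if (!is.na(nm) && nm %in% hit) nm else min(hit)
}

#' Classify one analysis window
#'
#' Assigns the class whose training mean is nearest in Mahalanobis distance
#' under the pooled covariance, with a deterministic tie-break preferring
#' `no_movement` (ambiguous intent must not move the robot), else the lower
#' class index. The proportional-control magnitude is computed for the
#' winning class from the window's MAV sub-vector.
#'
#' @param model An `emg_classifier`.
#' @param features Feature vector from [extract_features()] (its `"mav"`
#'   attribute is used unless `mav_vector` is given).
#' @param mav_vector Optional explicit per-channel MAV sub-vector.
#' @return List with `class`, `class_index`, `pc`, and per-class `distances`.
#' @export
classify_window <- function(model, features, mav_vector = NULL) {
  stopifnot(inherits(model, "emg_classifier"))
  if (length(features) != ncol(model$class_means))
    stop("feature length (", length(features), ") does not match model (",
         ncol(model$class_means), ")")
  if (is.null(mav_vector)) mav_vector <- attr(features, "mav")
  d <- .class_distances(model, matrix(features, 1))[1, ]
  i <- .decide(d, model$classes)
  pc <- if (is.null(mav_vector)) NA_real_
        else proportional_control(mav_vector, model, i)
  list(class = model$classes[i], class_index = i, pc = pc, distances = d)
}

#' Classify many windows at once
#'
#' @param model An `emg_classifier`.
#' @param features Matrix `n_windows x n_features`.
#' @param mav Optional matrix `n_windows x n_channels` of MAV sub-vectors.
#' @return Data frame with `class`, `pc`, and one distance column per class.
#' @export
classify_features <- function(model, features, mav = NULL) {
  features <- rbind(features)
  d <- .class_distances(model, features)
  idx <- apply(d, 1, .decide, classes = model$classes)
  pc <- rep(NA_real_, nrow(features))
  if (!is.null(mav)) {
    mav <- rbind(mav)
    for (k in seq_len(nrow(features)))
      pc[k] <- proportional_control(mav[k, ], model, idx[k])
  }
  out <- data.frame(class = model$classes[idx], pc = pc)
  cbind(out, as.data.frame(d))
}

#' Serialize a classifier to a portable JSON model file
#' @param model An `emg_classifier`.
#' @param path Output path.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "emg_classifier"))
  obj <- list(
    format = "myoreach-classifier", version = 1L,
    classes = model$classes,
    lambda = model$lambda,
    eq1_variant = model$eq1_variant,
    feature_order = model$feature_order,
    channel_names = colnames(model$S),
    thresholds = model$thresholds,
    class_means = model$class_means,
    pooled_covariance = model$pooled_covariance,
    S = model$S, C = unname(model$C))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a classifier from a JSON model file
#' @param path Path written by [save_classifier()].
#' @return An `emg_classifier`.
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "myoreach-classifier"))
    stop("not a myoreach classifier model file: ", path)
  means <- as.matrix(obj$class_means)
  sigma <- as.matrix(obj$pooled_covariance)
  S <- as.matrix(obj$S)
  rownames(means) <- rownames(S) <- obj$classes
  colnames(S) <- obj$channel_names
  colnames(means) <- colnames(sigma) <- obj$feature_order
  structure(list(
    classes = obj$classes, class_means = means, pooled_covariance = sigma,
    chol = chol(sigma), lambda = obj$lambda,
    S = S, C = stats::setNames(obj$C, obj$classes),
    n_channels = ncol(S), feature_order = obj$feature_order,
    thresholds = obj$thresholds, eq1_variant = obj$eq1_variant),
    class = "emg_classifier")
}
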