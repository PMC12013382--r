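# Minimum-Mahalanobis classification and proportional control.

test_that("centers are per-cell training MAV means", {
  mavs <- list(no_movement = matrix(c(1, 2, 3, 0, 0, 0), 3, 2),
               abduction = matrix(c(5, 5, 2, 4), 2, 2))
  expect_warning(S <- compute_centers(mavs), "silent channel")
  expect_equal(S["no_movement", ], c(2, 0), ignore_attr = TRUE)
  expect_equal(S["abduction", ], c(5, 3), ignore_attr = TRUE)
  expect_error(compute_centers(list(a = matrix(numeric(0), 0, 2))),
               "no training windows for class 'a'")
})

test_that("normalization is the channel-sum of squared centers", {
  expect_equal(unname(compute_normalization(rbind(x = c(3, 4)))), 25)
  expect_equal(unname(compute_normalization(rbind(x = rep(1, 12)))), 12)
  expect_warning(C0 <- compute_normalization(rbind(x = c(0, 0))),
                 "zero normalization")
  expect_equal(unname(C0), 0)
})

test_that("proportional control follows the literal center-weighted square", {
  m <- list(S = rbind(abduction = 2), C = c(abduction = 4),
            eq1_variant = "s_mav_sq")
  expect_equal(proportional_control(2, m, "abduction"), 2.0)   # (1/4)*2*4
  expect_equal(proportional_control(0, m, "abduction"), 0.0)
  # doubling every MAV quadruples PC (squared term)
  m12 <- list(S = rbind(abduction = runif(12)), eq1_variant = "s_mav_sq")
  m12$C <- c(abduction = sum(m12$S^2))
  mv <- runif(12)
  expect_equal(proportional_control(2 * mv, m12, "abduction"),
               4 * proportional_control(mv, m12, "abduction"))
  # dot variant: PC = 1 exactly at the class centers
  expect_equal(proportional_control(as.numeric(m12$S), m12, "abduction",
                                    variant = "dot"), 1)
  mz <- list(S = rbind(abduction = c(0, 0)), C = c(abduction = 0),
             eq1_variant = "s_mav_sq")
  expect_warning(pc <- proportional_control(c(1, 1), mz, "abduction"),
                 "zero normalization")
  expect_equal(pc, 0)
})

test_that("training reproduces hand-computed means and brute-force pooled scatter", {
  f <- list(no_movement = rbind(c(1, 2), c(3, 4), c(5, 0)),
            abduction = rbind(c(10, 10), c(12, 14)),
            adduction = rbind(c(0, 9), c(2, 7), c(4, 8), c(6, 4)))
  mv <- lapply(f, function(m) abs(m))
  model <- train_classifier(f, mv, lambda = 0)
  expect_equal(model$class_means["no_movement", ], c(3, 2), ignore_attr = TRUE)
  expect_equal(model$class_means["abduction", ], c(11, 12), ignore_attr = TRUE)
  # brute-force two-loop pooled within-class scatter
  N <- sum(vapply(f, nrow, integer(1)))
  acc <- matrix(0, 2, 2)
  for (cl in names(f)) {
    mu <- colMeans(f[[cl]])
    for (r in seq_len(nrow(f[[cl]]))) {
      d <- f[[cl]][r, ] - mu
      acc <- acc + outer(d, d)
    }
  }
  expect_equal(unname(model$pooled_covariance), acc / (N - 3))
})

test_that("far-separated synthetic classes classify perfectly on resubstitution", {
  set.seed(3)
  nf <- 8
  mk <- function(center) sweep(matrix(rnorm(40 * nf, sd = 0.3), 40, nf),
                               2, center, "+")
  f <- list(no_movement = mk(rep(0, nf)), abduction = mk(rep(5, nf)),
            adduction = mk(rep(-5, nf)))
  mv <- lapply(f, function(m) abs(m[, 1:2]))
  model <- train_classifier(f, mv)
  for (cl in names(f))
    expect_true(all(classify_features(model, f[[cl]])$class == cl))
})

test_that("a window at a class mean has zero distance to it", {
  set.seed(4)
  means <- rbind(no_movement = rnorm(5), abduction = rnorm(5) + 4,
                 adduction = rnorm(5) - 4)
  m <- manual_classifier(means)
  d <- classify_window(m, means["abduction", ], mav_vector = c(1, 1))
  expect_equal(d$class, "abduction")
  expect_equal(unname(d$distances["abduction"]), 0)
})

test_that("identity covariance reduces to the nearest-Euclidean-mean rule", {
  set.seed(5)
  nf <- 6
  means <- rbind(no_movement = rnorm(nf), abduction = rnorm(nf),
                 adduction = rnorm(nf))
  m <- manual_classifier(means)
  X <- matrix(rnorm(100 * nf, sd = 2), 100, nf)
  got <- classify_features(m, X)$class
  oracle <- apply(X, 1, function(x) {
    d2 <- apply(means, 1, function(mu) sum((x - mu)^2))
    rownames(means)[which.min(d2)]
  })
  expect_identical(got, unname(oracle))
})

test_that("exact ties prefer no_movement, else the lower class index", {
  mu <- c(1, 1, 1)
  m <- manual_classifier(rbind(no_movement = mu, abduction = mu,
                               adduction = mu))
  expect_equal(classify_window(m, mu, mav_vector = c(1, 1))$class,
               "no_movement")
  m2 <- manual_classifier(rbind(alpha = mu, beta = mu), c("alpha", "beta"))
  expect_equal(classify_window(m2, mu, mav_vector = c(1, 1))$class, "alpha")
})

test_that("decisions are invariant to consistent diagonal feature re-scaling", {
  set.seed(6)
  nf <- 10
  mk <- function(center) sweep(matrix(rnorm(30 * nf), 30, nf), 2, center, "+")
  f <- list(no_movement = mk(rep(0, nf)), abduction = mk(rep(2, nf)),
            adduction = mk(rep(-2, nf)))
  mv <- lapply(f, function(m) abs(m[, 1:3]))
  m1 <- train_classifier(f, mv, lambda = 0.05)
  for (rep in 1:5) {
    D <- diag(exp(runif(nf, -2, 2)))
    fs <- lapply(f, function(m) m %*% D)
    m2 <- train_classifier(fs, mv, lambda = 0.05)
    X <- matrix(rnorm(50 * nf), 50, nf)
    d1 <- classify_features(m1, X)
    d2 <- classify_features(m2, X %*% D)
    expect_identical(d1$class, d2$class)
    expect_equal(d1$no_movement, d2$no_movement, tolerance = 1e-8)
  }
})

test_that("PC is monotone non-decreasing in each channel MAV", {
  set.seed(8)
  m <- list(S = rbind(abduction = runif(12)), eq1_variant = "s_mav_sq")
  m$C <- c(abduction = sum(m$S^2))
  mv <- runif(12)
  base <- proportional_control(mv, m, "abduction")
  for (j in 1:12) {
    up <- mv; up[j] <- up[j] + 0.5
    expect_gte(proportional_control(up, m, "abduction"), base)
  }
})

test_that("shrinkage keeps the covariance usable where lambda = 0 fails", {
  set.seed(9)
  # more features than windows: raw pooled covariance is singular
  nf <- 30
  mk <- function(center) sweep(matrix(rnorm(8 * nf), 8, nf), 2, center, "+")
  f <- list(no_movement = mk(rep(0, nf)), abduction = mk(rep(3, nf)))
  mv <- lapply(f, function(m) abs(m[, 1:2]))
  expect_error(train_classifier(f, mv, lambda = 0), "singular")
  expect_s3_class(train_classifier(f, mv, lambda = 0.1), "emg_classifier")
})

test_that("serialization round-trips to identical decisions", {
  model <- fx_small_model()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  save_classifier(model, path)
  back <- load_classifier(path)
  expect_identical(back$classes, model$classes)
  set.seed(10)
  X <- matrix(rnorm(1000 * ncol(model$class_means), sd = 0.3), 1000)
  X <- sweep(X, 2, model$class_means["abduction", ], "+")
  d1 <- classify_features(model, X)
  d2 <- classify_features(back, X)
  expect_identical(d1$class, d2$class)
  expect_equal(d1$no_movement, d2$no_movement, tolerance = 1e-12)
})
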