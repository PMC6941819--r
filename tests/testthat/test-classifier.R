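## two well-separated training clusters
separable_features <- function(n = 30L, seed = 1L) {
  set.seed(seed)
  data.frame(
    x_bias = c(rnorm(n, 10, 1), rnorm(n, 0.2, 0.1)),
    x_clip = c(rnorm(n, 0.5, 0.05), pmax(rnorm(n, 0.05, 0.02), 0)),
    label = rep(c("artifact", "genuine"), each = n))
}

test_that("feature transform maps KS p to -log10 with the zero guard", {
  f <- noise_features(c(1, 0.01, 0), c(0, 0.5, 1))
  expect_equal(f$x_bias[1L], -log10(1 + 1e-300))
  expect_equal(f$x_bias[2L], -log10(0.01 + 1e-300))
  expect_true(is.finite(f$x_bias[3L]))  # p = 0 stays finite
  expect_error(noise_features(2, 0), "ks_p")
})

test_that("separable clusters train to sensitivity = specificity = 1 with a finite fallback fit", {
  f <- separable_features()
  expect_warning(m <- fit_noise_model(f), "separable")
  expect_true(all(is.finite(coef(m))))
  expect_equal(m$training$sensitivity, 1)
  expect_equal(m$training$specificity, 1)
  expect_equal(m$training$auroc, 1)
  ## an unambiguously clean point classifies as signal
  expect_equal(predict(m, data.frame(x_bias = 0, x_clip = 0), type = "class"),
               "signal")
})

test_that("single-class or undersized training data is rejected", {
  f <- separable_features()
  expect_error(fit_noise_model(f[f$label == "artifact", ]), "both classes")
  expect_error(fit_noise_model(f[c(1:5, 31:35), ]), "per class")
})

test_that("known logistic coefficients are recovered within 3 standard errors", {
  set.seed(2024)
  n <- 2000L
  truth <- c(-3, 0.8, 6)
  x_bias <- rexp(n, rate = 0.5)
  x_clip <- runif(n)
  p <- plogis(truth[1L] + truth[2L] * x_bias + truth[3L] * x_clip)
  lab <- ifelse(runif(n) < p, "artifact", "genuine")
  m <- fit_noise_model(data.frame(x_bias = x_bias, x_clip = x_clip, label = lab))
  expect_false(m$separable)
  expect_true(all(abs(coef(m) - truth) <= 3 * m$se))
})

test_that("shuffled labels give chance-level AUROC", {
  set.seed(99)
  n <- 500L
  f <- data.frame(x_bias = rexp(n), x_clip = runif(n),
                  label = sample(c("artifact", "genuine"), n, replace = TRUE))
  m <- fit_noise_model(f)
  expect_lt(abs(m$training$auroc - 0.5), 0.08)
})

test_that("choose_threshold equals the exhaustive sweep oracle, ties to the larger cut", {
  set.seed(12)
  for (i in 1:10) {
    n <- 60L
    f <- data.frame(x_bias = rexp(n, 0.3), x_clip = runif(n),
                    label = sample(c("artifact", "genuine"), n,
                                   replace = TRUE, prob = c(.4, .6)))
    m0 <- structure(list(coefficients = c(`(Intercept)` = -1, x_bias = 0.7,
                                          x_clip = 2),
                         threshold = 0.5), class = "noise_model")
    t_pkg <- choose_threshold(m0, f)
    p <- predict(m0, f, type = "prob")
    sw <- sweep_threshold(p, f$label == "artifact")
    expect_equal(t_pkg, sw$best_t)
    sens <- sum(p >= t_pkg & f$label == "artifact") / sum(f$label == "artifact")
    spec <- sum(p < t_pkg & f$label == "genuine") / sum(f$label == "genuine")
    expect_equal(sens + spec, sw$best_score)
  }
})

test_that("degenerate threshold choice: all probabilities equal", {
  m0 <- structure(list(coefficients = c(0, 0, 0), threshold = NA_real_),
                  class = "noise_model")
  f <- data.frame(x_bias = c(1, 2, 3, 4), x_clip = c(0, 0, 0, 0),
                  label = c("artifact", "artifact", "genuine", "genuine"))
  t <- choose_threshold(m0, f)
  expect_equal(t, 0.5)  # the single candidate; sens + spec = 1 there
})

test_that("classification is deterministic, boundary-inclusive and monotone in the features", {
  f <- separable_features()
  m <- suppressWarnings(fit_noise_model(f))
  ## boundary convention: a point with p exactly at threshold is noise
  b <- coef(m)
  x_on <- data.frame(x_bias = 5, x_clip = (qlogis(m$threshold) - b[1L] - 5 * b[2L]) / b[3L])
  p_on <- predict(m, x_on, type = "prob")
  if (abs(p_on - m$threshold) < 1e-12) {
    expect_equal(predict(m, x_on, type = "class"), "noise")
  }
  ## monotone: increasing x_clip (b_clip > 0) never flips noise -> signal
  expect_gt(b[3L], 0)
  grid <- data.frame(x_bias = 3, x_clip = seq(0, 1, 0.05))
  cls <- predict(m, grid, type = "class")
  expect_true(all(diff(cls == "noise") >= 0))
  expect_error(predict(m, data.frame(x_bias = NA_real_, x_clip = 0)), "missing")
})

test_that("AUROC is a rank statistic and matches pROC", {
  set.seed(77)
  scores <- runif(40)
  labels <- sample(c("artifact", "genuine"), 40, replace = TRUE)
  a <- auroc(scores, labels)
  ## invariance under a strictly monotone transform
  expect_equal(auroc(qlogis(scores / 2 + 0.25), labels), a)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("genuine", "artifact"),
    direction = "<", quiet = TRUE)))
  expect_equal(a, ref)
})

test_that("roc_points spans (0,1) endpoints and separable data reach AUROC 1", {
  f <- separable_features()
  m <- suppressWarnings(fit_noise_model(f))
  p <- predict(m, f, type = "prob")
  rc <- roc_points(p, f$label)
  expect_equal(rc$sensitivity[1L], 1)   # threshold -Inf: everything noise
  expect_equal(rc$specificity[1L], 0)
  expect_equal(rc$sensitivity[nrow(rc)], 0)
  expect_equal(rc$specificity[nrow(rc)], 1)
  expect_equal(auroc(p, f$label), 1)
})

test_that("models survive a JSON round trip", {
  f <- separable_features()
  m <- suppressWarnings(fit_noise_model(f))
  path <- withr::local_tempfile(fileext = ".json")
  write_noise_model(m, path)
  m2 <- read_noise_model(path)
  expect_equal(coef(m2), coef(m))
  expect_equal(m2$threshold, m$threshold)
  newx <- data.frame(x_bias = c(0, 2, 8), x_clip = c(0, 0.2, 0.6))
  expect_equal(predict(m2, newx, type = "prob"),
               predict(m, newx, type = "prob"))
})
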