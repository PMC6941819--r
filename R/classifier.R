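## noise_classifier: stage 2.  A logistic regression of artifact status on
## the positional-bias score x_bias = -log10(KS p) and the soft-clipped read
## ratio x_clip, with the probability threshold chosen to maximize
## sensitivity + specificity (the Youden-style optimum).  The decision
## boundary is a straight line in (x_bias, x_clip) space.

BIAS_EPS <- 1e-300  # guards -log10 against exact p = 0

#' Assemble classifier features
#'
#' @param ks_p KS positional-bias p-values in \[0, 1\].
#' @param clip_ratio soft-clipped read ratios in \[0, 1\].
#' @param label optional training labels, `"artifact"` or `"genuine"`.
#' @return `data.frame` with `x_bias = -log10(ks_p + 1e-300)`, `x_clip`, and
#'   `label` when given.
#' @export
noise_features <- function(ks_p, clip_ratio, label = NULL) {
  stopifnot(all(ks_p >= 0 & ks_p <= 1), all(clip_ratio >= 0 & clip_ratio <= 1))
  out <- data.frame(x_bias = -log10(ks_p + BIAS_EPS), x_clip = clip_ratio)
  if (!is.null(label)) {
    stopifnot(all(label %in% c("artifact", "genuine")))
    out$label <- label
  }
  out
}

## ridge-penalized IRLS fallback for perfectly separated training data
.ridge_logistic <- function(X, y, lambda = 1e-6, tol = 1e-10, maxit = 200L) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1L, 1L] <- 0  # intercept unpenalized
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Fit the logistic noise model
#'
#' Maximum-likelihood logistic regression of P(artifact | x_bias, x_clip),
#' followed by threshold selection maximizing sensitivity + specificity on
#' the training data.  Perfectly separated data (where the MLE diverges)
#' triggers a warning and a ridge-penalized fit (penalty 1e-6) so that
#' coefficients stay finite.
#'
#' @param features training `data.frame` from [noise_features()] with a
#'   `label` column, or with `ks_p`/`clip_ratio` columns plus `label`.
#' @param min_per_class minimum training examples per class (default 10).
#' @return object of class `noise_model`: `coefficients` (intercept,
#'   `x_bias`, `x_clip`), `threshold`, `se` (NA for the ridge fallback),
#'   `training` summary (n per class, sensitivity, specificity, auroc),
#'   `separable` flag.
#' @seealso [choose_threshold()], [classify_noise()], [roc_points()]
#' @export
fit_noise_model <- function(features, min_per_class = 10L) {
  if (!"x_bias" %in% names(features) && "ks_p" %in% names(features)) {
    features <- cbind(noise_features(features$ks_p, features$clip_ratio),
                      label = features$label)
  }
  stopifnot(all(c("x_bias", "x_clip", "label") %in% names(features)))
  y <- as.integer(features$label == "artifact")
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  if (min(sum(y), sum(1 - y)) < min_per_class) {
    stop(sprintf("need >= %d training examples per class", min_per_class))
  }
  X <- cbind(`(Intercept)` = 1, x_bias = features$x_bias, x_clip = features$x_clip)
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100L)),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- coef(fit)
  mu <- fit$fitted.values
  separable <- !fit$converged || any(abs(beta) > 1e3) ||
    all(mu < 1e-8 | mu > 1 - 1e-8)
  se <- rep(NA_real_, 3L)
  if (separable) {
    warning("training classes are (near-)separable; using ridge-penalized fit")
    beta <- .ridge_logistic(X, y)
  } else {
    ## standard errors from the Fisher information at the MLE
    info <- crossprod(X, X * (mu * (1 - mu)))
    se <- tryCatch(sqrt(diag(solve(info))), error = function(e) se)
  }
  names(beta) <- names(se) <- colnames(X)
  model <- structure(list(
    coefficients = beta, se = se, separable = separable,
    transform = list(bias = "-log10(ks_p + 1e-300)", clip = "identity"),
    threshold = NA_real_, training = NULL
  ), class = "noise_model")
  model$threshold <- choose_threshold(model, features)
  p <- predict(model, features, type = "prob")
  pred_noise <- p >= model$threshold
  model$training <- list(
    n_artifact = sum(y), n_genuine = sum(1 - y),
    sensitivity = sum(pred_noise & y == 1) / sum(y),
    specificity = sum(!pred_noise & y == 0) / sum(1 - y),
    auroc = auroc(p, features$label))
  model
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model> logistic artifact classifier\n")
  cat(sprintf("  logit P(artifact) = %.4g %+.4g*x_bias %+.4g*x_clip\n",
              x$coefficients[1L], x$coefficients[2L], x$coefficients[3L]))
  cat(sprintf("  threshold t = %.4g on P(artifact)%s\n", x$threshold,
              if (x$separable) "  [ridge fallback: separable training data]" else ""))
  if (!is.null(x$training)) {
    cat(sprintf("  training: %d artifact / %d genuine; sens %.3f spec %.3f AUROC %.3f\n",
                x$training$n_artifact, x$training$n_genuine,
                x$training$sensitivity, x$training$specificity, x$training$auroc))
  }
  invisible(x)
}

#' @export
summary.noise_model <- function(object, ...) {
  print(object)
  if (!all(is.na(object$se))) {
    cat("  coefficient standard errors:\n")
    print(round(object$se, 4L))
  }
  b <- object$coefficients
  if (abs(b[3L]) > 0) {
    cat(sprintf("  decision boundary: x_clip = %.4g %+.4g * x_bias\n",
                (stats::qlogis(object$threshold) - b[1L]) / b[3L], -b[2L] / b[3L]))
  }
  invisible(object)
}

#' @export
coef.noise_model <- function(object, ...) object$coefficients

#' Predict artifact probabilities or classes
#'
#' @param object a `noise_model`.
#' @param newdata `data.frame` with `x_bias`/`x_clip` (or `ks_p`/`clip_ratio`).
#' @param type `"prob"` for P(artifact) or `"class"` for `noise`/`signal`
#'   (noise iff probability >= threshold).
#' @param ... unused.
#' @export
predict.noise_model <- function(object, newdata,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!"x_bias" %in% names(newdata) && "ks_p" %in% names(newdata)) {
    newdata <- noise_features(newdata$ks_p, newdata$clip_ratio)
  }
  if (anyNA(newdata$x_bias) || anyNA(newdata$x_clip)) {
    stop("missing classifier features")
  }
  eta <- object$coefficients[1L] +
    object$coefficients[2L] * newdata$x_bias +
    object$coefficients[3L] * newdata$x_clip
  p <- stats::plogis(unname(eta))
  if (type == "prob") p else ifelse(p >= object$threshold, "noise", "signal")
}

#' Threshold maximizing sensitivity + specificity
#'
#' Sweeps every distinct predicted probability as a candidate cut (noise iff
#' p >= t) and returns the one maximizing sensitivity + specificity; ties
#' are broken toward the largest threshold (fewest removals).
#'
#' @param model a `noise_model` (threshold need not be set yet).
#' @param features labeled feature `data.frame`.
#' @return the chosen threshold in (0, 1\].
#' @export
choose_threshold <- function(model, features) {
  p <- predict.noise_model(model, features, type = "prob")
  y <- features$label == "artifact"
  cand <- sort(unique(p))
  score <- vapply(cand, function(t) {
    sum(p >= t & y) / sum(y) + sum(p < t & !y) / sum(!y)
  }, numeric(1L))
  best <- max(score)
  max(cand[score >= best - 1e-12])
}

#' Classify variants as noise or signal
#'
#' @param model a fitted `noise_model`.
#' @param features feature `data.frame` (see [predict.noise_model()]).
#' @return character vector, `"noise"` or `"signal"`.
#' @export
classify_noise <- function(model, features) {
  predict(model, features, type = "class")
}

#' ROC curve over all cut points
#'
#' @param scores predicted artifact probabilities (or any monotone score).
#' @param labels `"artifact"`/`"genuine"` labels.
#' @return `data.frame` with `threshold`, `sensitivity`, `specificity`,
#'   one row per distinct score plus the trivial endpoints.
#' @export
roc_points <- function(scores, labels) {
  y <- labels == "artifact"
  cand <- c(-Inf, sort(unique(scores)), Inf)
  data.frame(
    threshold = cand,
    sensitivity = vapply(cand, function(t) sum(scores >= t & y) / sum(y), 0),
    specificity = vapply(cand, function(t) sum(scores < t & !y) / sum(!y), 0))
}

#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney rank statistic (ties count 1/2).
#'
#' @inheritParams roc_points
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- labels == "artifact"
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Plot the training feature space and decision boundary
#'
#' @param x a `noise_model`.
#' @param features labeled feature `data.frame` to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.noise_model <- function(x, features, ...) {
  col <- ifelse(features$label == "artifact", "#d62728", "#1f77b4")
  graphics::plot(features$x_bias, features$x_clip, col = col, pch = 16L,
                 cex = 0.6, xlab = "-log10 KS p (positional bias)",
                 ylab = "soft-clipped read ratio", ...)
  b <- x$coefficients
  if (abs(b[3L]) > 1e-12) {
    graphics::abline(a = (stats::qlogis(x$threshold) - b[1L]) / b[3L],
                     b = -b[2L] / b[3L])
  } else if (abs(b[2L]) > 1e-12) {
    graphics::abline(v = (stats::qlogis(x$threshold) - b[1L]) / b[2L])
  }
  graphics::legend("topright", legend = c("artifact", "genuine"),
                   col = c("#d62728", "#1f77b4"), pch = 16L, bty = "n")
  invisible(x)
}

#' Serialize / restore a noise model
#'
#' Models are stored as a small JSON text file (coefficients, threshold,
#' transform metadata, training summary).
#'
#' @param model a `noise_model`.
#' @param path file path.
#' @return `read_noise_model()` returns a `noise_model`.
#' @export
write_noise_model <- function(model, path) {
  obj <- list(coefficients = as.list(model$coefficients),
              se = as.list(model$se),
              threshold = model$threshold,
              separable = model$separable,
              transform = model$transform,
              training = model$training)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_noise_model
#' @export
read_noise_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coefficients = unlist(obj$coefficients),
    se = unlist(obj$se),
    separable = isTRUE(obj$separable),
    transform = obj$transform,
    threshold = obj$threshold,
    training = obj$training
  ), class = "noise_model")
}
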