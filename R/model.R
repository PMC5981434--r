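#' @title Discriminant classification with noise-injected forward selection
#' @name model
#' @description
#' Classification of night-comparison observations with Gaussian
#' discriminant analysis: LDA (shared covariance, linear boundary) or QDA
#' (per-class covariance, quadratic boundary), both with a relative ridge
#' on the covariance because difference features can be collinear. Feature
#' selection is a greedy sequential forward search scored by validation
#' balanced accuracy; to blunt selection-stage overfitting the training set
#' is augmented with a Gaussian-noise copy of itself during the search.
NULL

obs_values <- function(obs) if (inherits(obs, "comparison_set")) obs$values else as.matrix(obs)
obs_labels <- function(obs) obs$label

#' Augment observations with a noisy copy
#'
#' Appends to the set one copy of every observation with independent
#' Gaussian noise added: feature \code{k} receives noise with SD
#' \code{strength} times that feature's SD over the input set. Labels and
#' provenance are duplicated; the output has twice the rows of the input.
#'
#' @param obs A \code{comparison_set}.
#' @param strength Noise level as a fraction of each feature's SD;
#'   \code{0} duplicates exactly.
#' @param seed Integer seed.
#' @return A \code{comparison_set} with \code{2 * n} observations.
#' @export
inject_noise <- function(obs, strength = 0.1, seed = 1) {
  if (strength < 0) stop("noise strength must be >= 0", call. = FALSE)
  x <- obs_values(obs)
  n <- nrow(x)
  if (n == 0) return(obs)
  set.seed(seed)
  sds <- apply(x, 2, stats::sd)
  sds[!is.finite(sds)] <- 0
  noise <- matrix(stats::rnorm(n * ncol(x)), n, ncol(x)) *
    rep(strength * sds, each = n)
  structure(list(values = rbind(x, x + noise),
                 label = c(obs$label, obs$label),
                 left_night_id = c(obs$left_night_id, obs$left_night_id),
                 right_night_id = c(obs$right_night_id, obs$right_night_id),
                 sign = c(obs$sign, obs$sign)),
            class = "comparison_set")
}

# class order puts the non-migraine class first so that ties in the
# discriminant scores resolve to it (which.max takes the first maximum)
ordered_classes <- function(labels) {
  cl <- sort(unique(labels))
  pref <- cl[grepl("^non_migraine", cl)]
  c(pref, setdiff(cl, pref))
}

regularize <- function(S, lambda) {
  d <- nrow(S)
  tr <- sum(diag(S))
  S + diag(if (tr > 0) lambda * tr / d else 1e-8, d)
}

#' Fit a regularized linear or quadratic discriminant model
#'
#' Class means are sample means; the covariance is the pooled sample
#' covariance (LDA) or per-class sample covariances (QDA), each stabilized
#' with a relative ridge \code{lambda * (trace(S)/d) * I}. Priors are the
#' empirical class frequencies. The discriminant score of class \code{c} is
#' \deqn{\delta_c(x) = -\tfrac12 \log|\Sigma_c|
#'   - \tfrac12 (x-\mu_c)^T \Sigma_c^{-1} (x-\mu_c) + \log \pi_c,}
#' with a shared \eqn{\Sigma} for LDA.
#'
#' @param obs A \code{comparison_set}, or a numeric matrix via
#'   \code{labels}.
#' @param kind \code{"lda"} or \code{"qda"}.
#' @param lambda Relative ridge on the covariance.
#' @param features Optional character vector restricting (and ordering) the
#'   feature columns used.
#' @param labels Class labels, taken from \code{obs$label} when omitted.
#' @return A list of class \code{discriminant_model}.
#' @export
fit_discriminant <- function(obs, kind = c("qda", "lda"), lambda = 1e-6,
                             features = NULL, labels = NULL) {
  kind <- match.arg(kind)
  x <- obs_values(obs)
  if (is.null(labels)) labels <- obs_labels(obs)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  classes <- ordered_classes(labels)
  if (length(classes) < 2) stop("need at least 2 classes to fit", call. = FALSE)
  counts <- table(factor(labels, classes))
  if (any(counts < 2)) {
    stop("every class needs at least 2 observations", call. = FALSE)
  }
  d <- ncol(x)
  means <- lapply(classes, function(cl) colMeans(x[labels == cl, , drop = FALSE]))
  covs <- lapply(classes, function(cl) stats::cov(x[labels == cl, , drop = FALSE]))
  if (kind == "lda") {
    pooled <- Reduce(`+`, Map(function(S, n) S * (n - 1), covs, as.list(as.numeric(counts)))) /
      (sum(counts) - length(classes))
    covs <- rep(list(pooled), length(classes))
  }
  covs <- lapply(covs, regularize, lambda = lambda)
  chols <- lapply(covs, chol)
  structure(list(kind = kind, classes = classes, means = means,
                 covariances = covs, chols = chols,
                 log_priors = log(as.numeric(counts) / sum(counts)),
                 log_dets = vapply(chols, function(R) 2 * sum(log(diag(R))), 0),
                 lambda = lambda,
                 features = colnames(x)),
            class = "discriminant_model")
}

discriminant_scores <- function(model, x) {
  scores <- matrix(0, nrow(x), length(model$classes))
  for (k in seq_along(model$classes)) {
    centered <- x - rep(model$means[[k]], each = nrow(x))
    z <- backsolve(model$chols[[k]], t(centered), transpose = TRUE)
    scores[, k] <- -0.5 * model$log_dets[k] - 0.5 * colSums(z^2) + model$log_priors[k]
  }
  scores
}

#' Predict class labels for observations
#'
#' Argmax of the class discriminant scores; exact ties resolve
#' deterministically to the non-migraine class.
#'
#' @param model A \code{discriminant_model}.
#' @param obs A \code{comparison_set} or numeric matrix whose columns cover
#'   the model's features (matched by name when named).
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(model, obs) {
  x <- obs_values(obs)
  if (!is.null(colnames(x))) {
    missing <- setdiff(model$features, colnames(x))
    if (length(missing) > 0) {
      stop("observations are missing model features: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- x[, model$features, drop = FALSE]
  } else if (ncol(x) != length(model$features)) {
    stop("unnamed observation matrix must match model dimensionality", call. = FALSE)
  }
  model$classes[max.col(discriminant_scores(model, x), ties.method = "first")]
}

obs_balanced_accuracy <- function(truth, predicted) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl) mean(predicted[truth == cl] == cl), 0))
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: at each step the candidate feature whose
#' addition maximizes the validation balanced accuracy (at the observation
#' level) of the refitted discriminant model is added; the search stops
#' when the best improvement falls below \code{epsilon} or
#' \code{max_features} is reached. If no feature improves on the empty
#' model, the single best feature is still returned. Noise injection (see
#' \code{\link{inject_noise}}) is expected to have been applied to
#' \code{train} beforehand.
#'
#' @param train,validation \code{comparison_set}s.
#' @param kind \code{"lda"} or \code{"qda"}.
#' @param lambda Covariance ridge passed to \code{\link{fit_discriminant}}.
#' @param epsilon Minimum balanced-accuracy improvement to continue.
#' @param max_features Selection size cap.
#' @return Character vector of selected feature names, in selection order.
#' @export
sfs_select <- function(train, validation, kind = c("qda", "lda"),
                       lambda = 1e-6, epsilon = 0.001, max_features = 15) {
  kind <- match.arg(kind)
  xt <- obs_values(train)
  xv <- obs_values(validation)
  lt <- obs_labels(train)
  lv <- obs_labels(validation)
  all_features <- colnames(xt)
  selected <- character(0)
  current <- 0.5   # empty model: majority vote, chance balanced accuracy
  repeat {
    remaining <- setdiff(all_features, selected)
    if (length(remaining) == 0 || length(selected) >= max_features) break
    scores <- vapply(remaining, function(f) {
      cols <- c(selected, f)
      tryCatch({
        m <- fit_discriminant(xt[, cols, drop = FALSE], kind = kind,
                              lambda = lambda, labels = lt)
        obs_balanced_accuracy(lv, predict_labels(m, xv[, cols, drop = FALSE]))
      }, error = function(e) -Inf)
    }, 0)
    # exact validation ties resolve to the earliest feature in registry
    # order; scoring ties by training accuracy was tried and rejected, it
    # degrades null calibration by rewarding selection-stage overfit
    best <- which.max(scores)
    if (!is.finite(scores[best])) break
    if (scores[best] - current < epsilon) {
      if (length(selected) == 0) selected <- remaining[best]
      break
    }
    selected <- c(selected, remaining[best])
    current <- scores[best]
  }
  selected
}

#' Serialize a discriminant model to JSON
#' @param model A \code{discriminant_model}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
save_model <- function(model, path) {
  out <- list(kind = model$kind, classes = model$classes,
              features = model$features, lambda = model$lambda,
              log_priors = model$log_priors,
              means = lapply(model$means, unname),
              covariances = lapply(model$covariances, unname))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a discriminant model from JSON
#' @param path Path written by \code{\link{save_model}}.
#' @return A \code{discriminant_model}.
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- lapply(seq_along(raw$classes), function(k) {
    S <- as.matrix(if (is.list(raw$covariances)) raw$covariances[[k]] else raw$covariances[k, , ])
    dimnames(S) <- NULL
    S
  })
  means <- lapply(seq_along(raw$classes), function(k) {
    m <- if (is.list(raw$means)) raw$means[[k]] else raw$means[k, ]
    stats::setNames(as.numeric(m), raw$features)
  })
  chols <- lapply(covs, chol)
  structure(list(kind = raw$kind, classes = raw$classes, means = means,
                 covariances = covs, chols = chols,
                 log_priors = as.numeric(raw$log_priors),
                 log_dets = vapply(chols, function(R) 2 * sum(log(diag(R))), 0),
                 lambda = raw$lambda, features = raw$features),
            class = "discriminant_model")
}
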