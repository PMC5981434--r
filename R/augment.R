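#' @title Night-comparison augmentation
#' @name augment
#' @description
#' A cohort of a few dozen nights, with few pre-migraine nights among them,
#' is too small and too imbalanced to train a classifier on nights
#' directly. The night-comparison construction expands a set of
#' \code{n_mig} pre-migraine and \code{n_non} non-migraine nightly feature
#' vectors into \code{n_mig * n_non + n_non * (n_non - 1) / 2} labelled
#' difference observations: every (pre-migraine, non-migraine) pair yields
#' \code{m - n} labelled as a migraine comparison, and every unordered pair
#' of non-migraine nights yields \code{s * (n_i - n_j)} with the sign
#' \code{s} drawn uniformly from \{+1, -1\} (each unordered pair is used
#' once; computing both directions would leak the same information twice).
#' Pre-migraine nights are never differenced against each other.
NULL

#' Closed-form count of comparison observations
#'
#' @param n_mig Number of pre-migraine nights.
#' @param n_non Number of non-migraine nights.
#' @return \code{n_mig * n_non + n_non * (n_non - 1) / 2}.
#' @export
count_observations <- function(n_mig, n_non) {
  if (n_mig < 0 || n_non < 0) stop("night counts must be nonnegative", call. = FALSE)
  n_mig * n_non + n_non * (n_non - 1) / 2
}

#' Build the night-comparison observation matrix
#'
#' @param features A feature table (one row per night with columns
#'   \code{night_id}, \code{label}, and feature columns; see
#'   \code{\link{nightly_feature_table}}) for a single subject, or a list of
#'   \code{night_features}.
#' @param seed Integer seed for the non-migraine pair sign draws. Pairs are
#'   ordered lexicographically by night id before the draws, so the map
#'   from seed to matrix is deterministic.
#' @return A list of class \code{comparison_set}: \code{values} (matrix,
#'   one row per observation), \code{label}
#'   (\code{"migraine_comparison"}/\code{"non_migraine_comparison"}),
#'   \code{left_night_id}, \code{right_night_id}, \code{sign}. A migraine
#'   night only ever appears as the left member.
#' @export
build_comparison_matrix <- function(features, seed = 1) {
  if (is.list(features) && !is.data.frame(features)) {
    features <- do.call(rbind, lapply(features, function(f) {
      cbind(data.frame(subject_id = f$subject_id, night_id = f$night_id,
                       label = f$label, stringsAsFactors = FALSE),
            as.data.frame(t(f$values)))
    }))
  }
  meta_cols <- intersect(c("subject_id", "night_id", "label"), names(features))
  x <- as.matrix(features[, setdiff(names(features), meta_cols), drop = FALSE])
  ids <- features$night_id
  mig <- which(features$label == "pre_migraine")
  non <- which(features$label == "non_migraine")
  if (!(length(non) >= 2 || (length(mig) >= 1 && length(non) >= 1))) {
    stop("need at least two non-migraine nights, or one of each class", call. = FALSE)
  }
  mig <- mig[order(ids[mig])]
  non <- non[order(ids[non])]

  n_obs <- count_observations(length(mig), length(non))
  values <- matrix(0, n_obs, ncol(x), dimnames = list(NULL, colnames(x)))
  left <- right <- character(n_obs)
  lab <- character(n_obs)
  sgn <- integer(n_obs)
  k <- 0L
  for (i in mig) {
    for (j in non) {
      k <- k + 1L
      values[k, ] <- x[i, ] - x[j, ]
      left[k] <- ids[i]; right[k] <- ids[j]
      lab[k] <- "migraine_comparison"; sgn[k] <- 1L
    }
  }
  set.seed(seed)
  if (length(non) >= 2) {
    for (a in seq_len(length(non) - 1)) {
      for (b in seq.int(a + 1, length(non))) {
        k <- k + 1L
        s <- sample(c(1L, -1L), 1)
        i <- non[a]; j <- non[b]
        values[k, ] <- s * (x[i, ] - x[j, ])
        left[k] <- ids[i]; right[k] <- ids[j]
        lab[k] <- "non_migraine_comparison"; sgn[k] <- s
      }
    }
  }
  structure(list(values = values, label = lab, left_night_id = left,
                 right_night_id = right, sign = sgn),
            class = "comparison_set")
}

#' Number of observations in a comparison set
#' @param x A \code{comparison_set}.
#' @return Integer count.
#' @export
n_comparisons <- function(x) length(x$label)

#' Comparison set as a data.frame with provenance columns
#' @param x A \code{comparison_set}.
#' @param ... Unused.
#' @return data.frame with \code{label}, \code{left_night_id},
#'   \code{right_night_id}, \code{sign}, then the feature columns.
#' @export
as.data.frame.comparison_set <- function(x, ...) {
  cbind(data.frame(label = x$label, left_night_id = x$left_night_id,
                   right_night_id = x$right_night_id, sign = x$sign,
                   stringsAsFactors = FALSE),
        as.data.frame(x$values))
}
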