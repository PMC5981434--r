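#' @title Nightly feature extraction: the 110-feature vector
#' @name features
#' @description
#' Each night is summarised by 110 named features computed from the 64 Hz
#' resampled block and the raw inter-beat event list:
#' \itemize{
#'   \item full-night statistics (46): SD and mean of \{acc_mag, bvp, temp,
#'     hr, eda, hrv\} where "hrv" is the raw inter-beat interval series;
#'     minimum of \{acc_mag, bvp, temp, hr\} (EDA minimum is excluded — it
#'     is uninformative at the skin-conductance floor); maximum, median and
#'     5th/25th/75th/95th percentiles of \{acc_mag, bvp, temp, hr, eda\};
#'   \item quarter-comparison features (44): the night is cut into four
#'     equal parts and, for the same statistic/signal sets (minus hrv),
#'     last-quarter value minus first-quarter value;
#'   \item inter-signal Pearson correlations (14): all 15 unordered pairs of
#'     the six resampled columns minus the (hr, ibi_interp) pair, which is
#'     deterministically redundant;
#'   \item time-domain HRV summaries (6): RMSSD, mean and SD of successive
#'     inter-beat differences, beat count, NN50, and total spectral power of
#'     the inter-beat series.
#' }
NULL

FEATURE_SIGNALS <- c("acc_mag", "bvp", "temp", "hr", "eda")
CORR_COLUMNS <- c("acc_mag", "bvp", "temp", "hr", "eda", "ibi_interp")

stat_funs <- list(
  std = stats::sd,
  mean = mean,
  min = min,
  max = max,
  median = stats::median,
  p5 = function(x) unname(stats::quantile(x, 0.05)),
  p25 = function(x) unname(stats::quantile(x, 0.25)),
  p75 = function(x) unname(stats::quantile(x, 0.75)),
  p95 = function(x) unname(stats::quantile(x, 0.95))
)

stat_signal_set <- function(stat, with_hrv) {
  if (stat == "min") return(c("acc_mag", "bvp", "temp", "hr"))
  if (with_hrv && stat %in% c("std", "mean")) return(c(FEATURE_SIGNALS, "hrv"))
  FEATURE_SIGNALS
}

corr_pairs <- function() {
  pairs <- utils::combn(CORR_COLUMNS, 2)
  drop <- apply(pairs, 2, function(p) all(p %in% c("hr", "ibi_interp")))
  pairs[, !drop, drop = FALSE]
}

#' The feature registry: names, categories and source signals
#'
#' The registry order is fixed; every feature vector and feature table uses
#' exactly this order.
#'
#' @return A data.frame with columns \code{name}, \code{category},
#'   \code{signal}; 110 rows.
#' @export
feature_registry <- function() {
  rows <- list()
  for (stat in names(stat_funs)) {
    for (sig in stat_signal_set(stat, with_hrv = TRUE)) {
      rows[[length(rows) + 1L]] <- c(paste(stat, sig, sep = "_"), paste0("night_", stat), sig)
    }
  }
  for (stat in names(stat_funs)) {
    for (sig in stat_signal_set(stat, with_hrv = FALSE)) {
      rows[[length(rows) + 1L]] <- c(paste("qdiff", stat, sig, sep = "_"),
                                     paste0("quarter_", stat), sig)
    }
  }
  cp <- corr_pairs()
  for (j in seq_len(ncol(cp))) {
    rows[[length(rows) + 1L]] <- c(paste("corr", cp[1, j], cp[2, j], sep = "_"),
                                   "correlation", paste(cp[, j], collapse = "+"))
  }
  for (nm in c("rmssd", "sdiff_mean", "sdiff_sd", "n_beats", "nn50", "total_power")) {
    rows[[length(rows) + 1L]] <- c(paste0("hrv_", nm), "hrv", "ibi")
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("name", "category", "signal")
  out
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# all nine segment statistics with a single order-statistics pass
stats9 <- function(x) {
  q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  c(std = stats::sd(x), mean = mean(x), min = min(x), max = max(x),
    median = q[3], p5 = q[1], p25 = q[2], p75 = q[4], p95 = q[5])
}

#' Quarter-comparison features (last quarter minus first quarter)
#'
#' The night is divided into four equal-size parts by sample count
#' (\code{floor(N/4)} samples per quarter, remainder truncated); for each
#' statistic/signal combination the feature is the statistic over the last
#' quarter minus the statistic over the first quarter.
#'
#' @param block A \code{resampled_block} with at least 4 samples.
#' @return Named numeric vector of 44 features.
#' @export
compute_quarter_diffs <- function(block) {
  n <- block_length(block)
  if (n < 4) stop("block must contain at least 4 samples", call. = FALSE)
  q <- n %/% 4
  first <- seq_len(q)
  last <- seq.int(n - q + 1, n)
  diffs <- lapply(FEATURE_SIGNALS, function(sig) {
    stats9(block[[sig]][last]) - stats9(block[[sig]][first])
  })
  names(diffs) <- FEATURE_SIGNALS
  out <- numeric(0)
  for (stat in names(stat_funs)) {
    for (sig in stat_signal_set(stat, with_hrv = FALSE)) {
      out[paste("qdiff", stat, sig, sep = "_")] <- diffs[[sig]][[stat]]
    }
  }
  out
}

#' Inter-signal Pearson correlations
#'
#' Correlations of the 15 unordered pairs of the six resampled columns,
#' minus the (hr, ibi_interp) pair: heart rate is computed from the
#' inter-beat series, so that pair is deterministically near minus one and
#' carries no information. A zero-variance column yields correlation 0.
#'
#' @param block A \code{resampled_block} with at least 2 samples.
#' @return Named numeric vector of 14 correlations.
#' @export
compute_signal_correlations <- function(block) {
  if (block_length(block) < 2) stop("need at least 2 samples", call. = FALSE)
  cp <- corr_pairs()
  out <- numeric(ncol(cp))
  names(out) <- paste("corr", cp[1, ], cp[2, ], sep = "_")
  for (j in seq_len(ncol(cp))) {
    out[j] <- safe_cor(block[[cp[1, j]]], block[[cp[2, j]]])
  }
  out
}

# Welch PSD: mean modified periodogram over 50%-overlapping Hann segments.
# Returns total power (sum of PSD * df) over [0, band_hi].
welch_total_power <- function(x, rate, seg_len = 256, band_hi = 2) {
  n <- length(x)
  if (n < 8) return(0)
  seg_len <- min(seg_len, n)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  step <- max(seg_len %/% 2, 1)
  starts <- seq(1, n - seg_len + 1, by = step)
  psd <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * w
    psd <- psd + Mod(stats::fft(seg))^2 / (sum(w^2) * rate)
  }
  psd <- psd / length(starts)
  freq <- (seq_len(seg_len) - 1) * rate / seg_len
  keep <- freq <= band_hi & freq <= rate / 2
  sum(psd[keep]) * rate / seg_len
}

#' Time-domain HRV summary features
#'
#' From the raw inter-beat intervals (seconds): RMSSD (root mean square of
#' successive differences), mean and SD of successive differences, beat
#' count, NN50 (successive pairs differing by more than 50 ms), and total
#' spectral power of the interval series (Welch periodogram of the series
#' linearly resampled to \code{resample_hz}, summed over 0-2 Hz).
#'
#' @param ibi Numeric vector of inter-beat intervals, seconds.
#' @param resample_hz Resampling rate for the spectral estimate.
#' @return Named numeric vector of 6 features. With fewer than 3 intervals
#'   the difference-based features and power are reported as 0 with a
#'   warning; the beat count stays exact.
#' @export
compute_hrv_features <- function(ibi, resample_hz = 4) {
  if (length(ibi) < 3) {
    warning("fewer than 3 inter-beat intervals; HRV features reported as 0",
            call. = FALSE)
    return(c(hrv_rmssd = 0, hrv_sdiff_mean = 0, hrv_sdiff_sd = 0,
             hrv_n_beats = length(ibi), hrv_nn50 = 0, hrv_total_power = 0))
  }
  d <- diff(ibi)
  t <- cumsum(ibi)
  grid <- seq(t[1], t[length(t)], by = 1 / resample_hz)
  xr <- stats::approx(t, ibi, xout = grid, rule = 2)$y
  c(hrv_rmssd = sqrt(mean(d^2)),
    hrv_sdiff_mean = mean(d),
    hrv_sdiff_sd = stats::sd(d),
    hrv_n_beats = length(ibi),
    hrv_nn50 = sum(abs(d) > 0.050),
    hrv_total_power = welch_total_power(xr, resample_hz))
}

#' Extract the 110-feature vector for one night
#'
#' @param night A \code{night_recording} (see
#'   \code{\link{segment_label_nights}}).
#' @return A list of class \code{night_features}: \code{night_id},
#'   \code{subject_id}, \code{label}, and \code{values}, a named numeric
#'   vector of exactly 110 finite features in registry order.
#' @export
extract_night_features <- function(night) {
  block <- night$block
  n <- block_length(block)
  if (n < 4) stop("night block must contain at least 4 samples", call. = FALSE)
  ibi <- block$ibi_events[, "interval"]

  sig_stats <- lapply(FEATURE_SIGNALS, function(sig) stats9(block[[sig]]))
  names(sig_stats) <- FEATURE_SIGNALS
  hrv_stats <- c(std = if (length(ibi) >= 2) stats::sd(ibi) else 0,
                 mean = if (length(ibi) >= 1) mean(ibi) else 0)
  full <- numeric(0)
  for (stat in names(stat_funs)) {
    for (sig in stat_signal_set(stat, with_hrv = TRUE)) {
      full[paste(stat, sig, sep = "_")] <-
        if (sig == "hrv") hrv_stats[[stat]] else sig_stats[[sig]][[stat]]
    }
  }
  values <- c(full,
              compute_quarter_diffs(block),
              compute_signal_correlations(block),
              suppressWarnings(compute_hrv_features(ibi)))
  values <- values[feature_registry()$name]
  stopifnot(length(values) == 110, all(is.finite(values)))
  structure(list(night_id = night$night_id, subject_id = night$subject_id,
                 label = night$label, values = values),
            class = "night_features")
}

#' Build the nightly feature table for a set of nights
#'
#' @param nights List of \code{night_recording} objects.
#' @return A data.frame with columns \code{subject_id}, \code{night_id},
#'   \code{label}, then the 110 features in registry order; one row per
#'   night.
#' @export
nightly_feature_table <- function(nights) {
  fv <- lapply(nights, extract_night_features)
  meta <- data.frame(
    subject_id = vapply(fv, `[[`, "", "subject_id"),
    night_id = vapply(fv, `[[`, "", "night_id"),
    label = vapply(fv, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  vals <- do.call(rbind, lapply(fv, `[[`, "values"))
  if (is.null(vals)) vals <- matrix(numeric(0), 0, 110,
                                    dimnames = list(NULL, feature_registry()$name))
  cbind(meta, as.data.frame(vals))
}
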