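#' @title Preprocessing: magnitude, 64 Hz resampling, sleep detection
#' @name preprocess
NULL

#' Euclidean magnitude of a 3-axis acceleration signal
#'
#' @param acc n-by-3 numeric matrix of acceleration samples (any consistent
#'   unit; the norm is returned in the same unit).
#' @return Numeric vector of per-sample magnitudes.
#' @export
compute_acc_magnitude <- function(acc) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3) stop("acceleration must have exactly 3 axes", call. = FALSE)
  sqrt(acc[, 1]^2 + acc[, 2]^2 + acc[, 3]^2)
}

#' Resample all channels of a session onto a common 64 Hz grid
#'
#' The grid spans the intersection of the channel time spans at the blood
#' volume pulse rate (64 Hz, the fastest channel). Slower regular channels
#' are up-sampled by zero-order hold (sample-and-hold), which adds no
#' intra-sample structure; the irregular inter-beat events are linearly
#' interpolated onto the grid as \code{ibi_interp}. Raw acceleration is
#' converted from 1/64 g units to g and collapsed to its magnitude.
#'
#' @param session An \code{e4_session}; the IBI channel is required here
#'   because the correlation and HRV features need it.
#' @param rate Target grid rate in Hz (the BVP rate).
#' @return A list of class \code{resampled_block}: \code{start_time},
#'   \code{rate} (64), equal-length numeric columns \code{acc_mag} (g),
#'   \code{bvp}, \code{temp}, \code{hr}, \code{eda}, \code{ibi_interp} (s),
#'   plus \code{ibi_events}, the raw (time, interval) event matrix.
#' @export
resample_channels <- function(session, rate = 64) {
  ch <- session$channels
  if (is.null(ch$IBI)) stop("resampling requires an IBI channel", call. = FALSE)
  reg <- ch[E4_REQUIRED_CHANNELS]
  starts <- vapply(reg, `[[`, 0, "start_time")
  ends <- vapply(reg, function(x) x$start_time + channel_duration(x), 0)
  t0 <- max(starts)
  t1 <- min(ends)
  n <- floor((t1 - t0) * rate)
  if (n < 1) stop("channels share no overlapping time span", call. = FALSE)
  tt <- t0 + (seq_len(n) - 1) / rate

  hold <- function(x) {
    idx <- floor((tt - x$start_time) * x$sample_rate) + 1
    idx[idx < 1] <- 1L
    idx[idx > n_samples(x)] <- n_samples(x)
    idx
  }
  acc_g <- ch$ACC$samples / 64
  ibi_t <- ch$IBI$start_time + ch$IBI$samples[, "offset"]
  ibi_v <- ch$IBI$samples[, "interval"]
  ibi_interp <- if (length(ibi_v) >= 2) {
    stats::approx(ibi_t, ibi_v, xout = tt, rule = 2)$y
  } else rep(if (length(ibi_v) == 1) ibi_v else 0, n)

  structure(list(
    start_time = t0, rate = rate,
    acc_mag = compute_acc_magnitude(acc_g)[hold(ch$ACC)],
    bvp = ch$BVP$samples[hold(ch$BVP)],
    temp = ch$TEMP$samples[hold(ch$TEMP)],
    hr = ch$HR$samples[hold(ch$HR)],
    eda = ch$EDA$samples[hold(ch$EDA)],
    ibi_interp = ibi_interp,
    ibi_events = cbind(time = ibi_t, interval = ibi_v)
  ), class = "resampled_block")
}

block_length <- function(block) length(block$acc_mag)

# O(n) centered rolling SD via cumulative sums.
rolling_sd <- function(x, window) {
  n <- length(x)
  half <- window %/% 2
  s1 <- cumsum(c(0, x))
  s2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  k <- hi - lo + 1
  m <- (s1[hi + 1] - s1[lo]) / k
  v <- pmax((s2[hi + 1] - s2[lo]) / k - m^2, 0)
  sqrt(v * k / pmax(k - 1, 1))
}

#' Sleep-detector parameters
#'
#' Conventional actigraphy-style defaults: movement is quantified as the
#' rolling SD of the acceleration magnitude over \code{window_s}; samples
#' below \code{threshold_g} count as still; still runs separated by less
#' than \code{bridge_s} are merged; the longest merged run of at least
#' \code{min_sleep_s} is the night's sleep interval.
#'
#' @param window_s Rolling-SD window, seconds.
#' @param threshold_g Stillness threshold on the rolling SD, g.
#' @param bridge_s Maximum movement gap bridged inside sleep, seconds.
#' @param min_sleep_s Minimum acceptable sleep duration, seconds.
#' @return A list of class \code{sleep_params}.
#' @export
sleep_params <- function(window_s = 60, threshold_g = 0.01,
                         bridge_s = 300, min_sleep_s = 3 * 3600) {
  structure(list(window_s = window_s, threshold_g = threshold_g,
                 bridge_s = bridge_s, min_sleep_s = min_sleep_s),
            class = "sleep_params")
}

#' Detect the night's sleep interval from the acceleration magnitude
#'
#' Automates the visual actigraphy criterion of "noticeably less movement":
#' returns the boundaries of the longest low-movement interval (see
#' \code{\link{sleep_params}}).
#'
#' @param block A \code{resampled_block}.
#' @param params A \code{\link{sleep_params}}.
#' @return Named numeric vector \code{c(sleep_start, sleep_end)} in POSIX
#'   seconds.
#' @export
detect_sleep_period <- function(block, params = sleep_params()) {
  n <- block_length(block)
  w <- max(round(params$window_s * block$rate), 2)
  still <- rolling_sd(block$acc_mag, w) < params$threshold_g
  r <- rle(still)
  # bridge short movement gaps that are flanked by stillness
  if (length(r$lengths) > 2) {
    inner <- 2:(length(r$lengths) - 1)
    gap <- !r$values[inner] & r$lengths[inner] < params$bridge_s * block$rate
    r$values[inner][gap] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & r$lengths >= params$min_sleep_s * block$rate
  if (!any(ok)) {
    stop("no low-movement interval of at least ", params$min_sleep_s,
         " s found; night skipped", call. = FALSE)
  }
  best <- which(ok)[which.max(r$lengths[ok])]
  c(sleep_start = block$start_time + (starts[best] - 1) / block$rate,
    sleep_end = block$start_time + ends[best] / block$rate)
}

restrict_block <- function(block, from, to) {
  i0 <- max(floor((from - block$start_time) * block$rate) + 1, 1)
  i1 <- min(floor((to - block$start_time) * block$rate), block_length(block))
  idx <- i0:i1
  ev <- block$ibi_events
  ev <- ev[ev[, "time"] >= from & ev[, "time"] < to, , drop = FALSE]
  structure(list(start_time = block$start_time + (i0 - 1) / block$rate,
                 rate = block$rate,
                 acc_mag = block$acc_mag[idx], bvp = block$bvp[idx],
                 temp = block$temp[idx], hr = block$hr[idx],
                 eda = block$eda[idx], ibi_interp = block$ibi_interp[idx],
                 ibi_events = ev),
            class = "resampled_block")
}

#' Segment sessions into labelled sleep-interval recordings
#'
#' For each session: resample, detect the sleep interval, restrict the block
#' to it, and label the night with the diary status of the calendar day the
#' subject wakes into (\code{pre_migraine} if that day is a migraine day).
#' Nights with no detectable sleep, or waking into a day absent from the
#' diary, are dropped with a warning.
#'
#' @param sessions List of \code{e4_session} objects.
#' @param diary A \code{diary_labels} data.frame.
#' @param params A \code{\link{sleep_params}}.
#' @param tz_offset Local-time offset from UTC in seconds, used to assign
#'   the waking timestamp to a calendar day.
#' @return List of \code{night_recording} objects: \code{subject_id},
#'   \code{night_id}, \code{sleep_start}, \code{sleep_end}, \code{label}
#'   (\code{"pre_migraine"} or \code{"non_migraine"}), \code{block}.
#' @export
segment_label_nights <- function(sessions, diary, params = sleep_params(),
                                 tz_offset = 0) {
  nights <- list()
  for (s in sessions) {
    bounds <- tryCatch({
      block <- resample_channels(s)
      detect <- detect_sleep_period(block, params)
      list(block = block, detect = detect)
    }, error = function(e) {
      warning("night ", s$session_id, " dropped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(bounds)) next
    wake_day <- as.Date(as.POSIXct(bounds$detect[["sleep_end"]] + tz_offset,
                                   origin = "1970-01-01", tz = "UTC"))
    hit <- which(diary$date == wake_day)
    if (length(hit) == 0) {
      warning("night ", s$session_id, " dropped: waking day ", format(wake_day),
              " not in diary", call. = FALSE)
      next
    }
    nights[[length(nights) + 1L]] <- structure(list(
      subject_id = s$subject_id, night_id = s$session_id,
      sleep_start = bounds$detect[["sleep_start"]],
      sleep_end = bounds$detect[["sleep_end"]],
      label = if (diary$migraine[hit]) "pre_migraine" else "non_migraine",
      block = restrict_block(bounds$block, bounds$detect[["sleep_start"]],
                             bounds$detect[["sleep_end"]])
    ), class = "night_recording")
  }
  nights
}
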