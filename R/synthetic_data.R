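#' @title Seeded synthetic E4 cohort generator
#' @name synthetic_data
#' @description
#' Generates multi-day, multi-subject wrist-sensor datasets in the E4 export
#' dialect, with an explicit sleep/wake movement structure and configurable
#' pre-migraine physiological shifts, so the whole pipeline can be exercised
#' and calibrated without any recorded data. The generator is a pure
#' function of (profile, effect, seed). All emitted sample values are
#' rounded to six decimals, the precision of the CSV dialect, so sessions
#' round-trip bit-exactly through \code{\link{write_e4_session}}.
NULL

#' Subject profile for the synthetic generator
#'
#' Baseline means are night-level expectations; the SDs are *between-night*
#' standard deviations, the scale on which \code{\link{effect_spec}} shifts
#' are expressed.
#'
#' @param subject_id Subject identifier.
#' @param n_days Number of diary days (and candidate nights).
#' @param n_migraine_days Number of migraine days among them.
#' @param temp_mean,temp_sd Nocturnal wrist temperature, deg C.
#' @param eda_mean,eda_sd Nocturnal electrodermal level, microsiemens.
#' @param hr_mean,hr_sd Nocturnal heart rate, beats/min.
#' @param rmssd_mean,rmssd_sd RMSSD of inter-beat intervals, seconds.
#' @param movement_rate Brief movement arousals per hour of sleep.
#' @param sleep_onset_hour,sleep_offset_hour Mean clock time (h, 24h+ for
#'   past-midnight) of falling asleep / waking; both jittered by
#'   \code{sleep_jitter_sd} hours between nights.
#' @param sleep_jitter_sd Between-night SD of onset/offset clock times, h.
#' @param wake_pad_min Minutes of awake (high-movement) recording kept on
#'   each side of the sleep interval.
#' @param missing_prob Probability that a whole night is missing (device
#'   off: charging, showering, sauna).
#' @param start_date First diary date (ISO string or Date).
#' @return A list of class \code{subject_profile}.
#' @export
subject_profile <- function(subject_id = "S1", n_days = 28, n_migraine_days = 8,
                            temp_mean = 35.5, temp_sd = 0.30,
                            eda_mean = 0.60, eda_sd = 0.20,
                            hr_mean = 58, hr_sd = 3.0,
                            rmssd_mean = 0.045, rmssd_sd = 0.010,
                            movement_rate = 4,
                            sleep_onset_hour = 23.0, sleep_offset_hour = 31.0,
                            sleep_jitter_sd = 0.5, wake_pad_min = 20,
                            missing_prob = 0.05, start_date = "2024-03-01") {
  if (n_migraine_days < 0 || n_migraine_days > n_days) {
    stop("need 0 <= n_migraine_days <= n_days", call. = FALSE)
  }
  sds <- c(temp_sd, eda_sd, hr_sd, rmssd_sd, sleep_jitter_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (missing_prob < 0 || missing_prob > 1) stop("missing_prob must be in [0,1]", call. = FALSE)
  if (sleep_offset_hour <= sleep_onset_hour) {
    stop("sleep_offset_hour must exceed sleep_onset_hour", call. = FALSE)
  }
  structure(list(subject_id = subject_id, n_days = as.integer(n_days),
                 n_migraine_days = as.integer(n_migraine_days),
                 temp_mean = temp_mean, temp_sd = temp_sd,
                 eda_mean = eda_mean, eda_sd = eda_sd,
                 hr_mean = hr_mean, hr_sd = hr_sd,
                 rmssd_mean = rmssd_mean, rmssd_sd = rmssd_sd,
                 movement_rate = movement_rate,
                 sleep_onset_hour = sleep_onset_hour,
                 sleep_offset_hour = sleep_offset_hour,
                 sleep_jitter_sd = sleep_jitter_sd,
                 wake_pad_min = wake_pad_min,
                 missing_prob = missing_prob,
                 start_date = as.Date(start_date)),
            class = "subject_profile")
}

#' Pre-migraine effect specification
#'
#' Shifts applied to nights preceding a migraine day, each in multiples of
#' the subject's between-night SD of that quantity. \code{trend} adds a
#' within-night linear drift (first-to-last-quarter differential, again in
#' between-night SDs) to temperature and EDA on pre-migraine nights. A zero
#' effect makes the two night classes identically distributed.
#'
#' @param temp,eda,hr,rmssd Night-mean shifts in SD units.
#' @param movement Shift of the movement-arousal rate, in SD units where one
#'   SD is taken as half the baseline rate.
#' @param trend Within-night drift term in SD units.
#' @return A list of class \code{effect_spec}.
#' @export
effect_spec <- function(temp = 1, eda = 1, hr = 0.5, rmssd = -1,
                        movement = 0.5, trend = 0) {
  vals <- c(temp = temp, eda = eda, hr = hr, rmssd = rmssd,
            movement = movement, trend = trend)
  if (any(!is.finite(vals))) stop("effect sizes must be finite", call. = FALSE)
  structure(as.list(vals), class = "effect_spec")
}

#' Zero (null) effect — classes identically distributed
#' @return An \code{effect_spec} with every shift 0.
#' @export
null_effect <- function() effect_spec(0, 0, 0, 0, 0, 0)

round6 <- function(x) round(x, 6)

#' Synthesize a blood-volume-pulse waveform from inter-beat intervals
#'
#' Concatenates one single-peak pulse template per interval, each template
#' stretched to the interval's duration, producing a waveform of exactly
#' \code{round(sum(ibi) * rate)} samples with one peak per beat.
#'
#' @param ibi Numeric vector of inter-beat intervals, seconds (all > 0).
#' @param rate Output sampling rate, Hz.
#' @return Numeric waveform in arbitrary PPG units.
#' @export
synthesize_bvp_from_ibi <- function(ibi, rate = 64) {
  if (length(ibi) == 0) return(numeric(0))
  if (any(ibi <= 0)) stop("inter-beat intervals must be positive", call. = FALSE)
  edges <- round(cumsum(c(0, ibi)) * rate)
  counts <- diff(edges)
  # phase in [0,1) within each beat; systolic peak at 0.3 of the cycle
  phase <- unlist(lapply(counts, function(n) if (n > 0) seq_len(n) / (n + 1) else numeric(0)),
                  use.names = FALSE)
  100 * exp(-((phase - 0.3) / 0.12)^2) - 20 * phase
}

# AR(1) inter-beat series whose successive-difference SD hits target_rmssd.
# For x_t = mu + phi (x_{t-1} - mu) + e: Var(x_t - x_{t-1}) = 2 sigma_x^2 (1 - phi).
sim_ibi_ar1 <- function(duration_s, mean_ibi, target_rmssd, phi = 0.9) {
  n <- ceiling(duration_s / mean_ibi) + 16
  sigma_x <- target_rmssd / sqrt(2 * (1 - phi))
  e <- stats::rnorm(n, 0, sigma_x * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma_x)
  for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
  ibi <- pmax(mean_ibi + x, 0.3)
  keep <- cumsum(ibi) <= duration_s
  ibi[keep]
}

# Smooth low-frequency drift: sum of two random-phase sinusoids + slow noise.
slow_drift <- function(n, rate, amplitude) {
  t <- seq_len(n) / rate
  span <- max(t)
  a <- stats::runif(2, 0.5, 1) * amplitude
  ph <- stats::runif(2, 0, 2 * pi)
  per <- stats::runif(2, span / 3, span)
  a[1] * sin(2 * pi * t / per[1] + ph[1]) + a[2] * sin(2 * pi * t / per[2] + ph[2])
}

# Movement bursts for sleep: Poisson arousals of 5-30 s at `per_hour` rate.
movement_mask <- function(n, rate, per_hour) {
  mask <- logical(n)
  hours <- n / rate / 3600
  k <- stats::rpois(1, max(per_hour, 0) * hours)
  if (k > 0) {
    starts <- sort(stats::runif(k, 0, n / rate))
    lens <- stats::runif(k, 5, 30)
    for (i in seq_len(k)) {
      idx <- seq(floor(starts[i] * rate) + 1, min(n, floor((starts[i] + lens[i]) * rate)))
      mask[idx] <- TRUE
    }
  }
  mask
}

acc_segment <- function(n, sd_g) {
  # gravity along z plus zero-mean movement, in raw 1/64 g units
  cbind(stats::rnorm(n, 0, sd_g * 64),
        stats::rnorm(n, 0, sd_g * 64),
        64 + stats::rnorm(n, 0, sd_g * 64))
}

#' Generate one synthetic night session
#'
#' Produces a session spanning evening to morning: high-movement awake
#' padding on both sides, a low-movement sleep interval, an AR(1) inter-beat
#' series realizing the night's target RMSSD, HR as 60 over a rolling mean
#' of the inter-beat series at 1 Hz, BVP from the beat sequence at 64 Hz,
#' and temperature/EDA as 4 Hz slow drifts plus noise. Pre-migraine nights
#' receive the \code{effect_spec} shifts on their night-level means.
#'
#' @param profile A \code{\link{subject_profile}}.
#' @param is_pre_migraine Logical: is this the night before a migraine day?
#' @param effect An \code{\link{effect_spec}}.
#' @param seed Integer seed; the night is a pure function of its arguments.
#' @param night_id Identifier for the session.
#' @param start_time Session start, POSIX seconds UTC.
#' @return An \code{e4_session} with attributes \code{sleep_start} and
#'   \code{sleep_end} (ground-truth boundaries, POSIX seconds).
#' @export
generate_night <- function(profile, is_pre_migraine, effect = effect_spec(),
                           seed = 1, night_id = "night1", start_time = NULL) {
  set.seed(seed)
  sh <- if (is_pre_migraine) effect else null_effect()

  onset_h <- stats::rnorm(1, profile$sleep_onset_hour, profile$sleep_jitter_sd)
  offset_h <- stats::rnorm(1, profile$sleep_offset_hour, profile$sleep_jitter_sd)
  sleep_s <- (offset_h - onset_h) * 3600
  if (sleep_s <= 0) sleep_s <- (profile$sleep_offset_hour - profile$sleep_onset_hour) * 3600
  pad_s <- profile$wake_pad_min * 60
  if (pad_s <= 0 || sleep_s <= 0) stop("nonpositive durations", call. = FALSE)
  total_s <- round(sleep_s + 2 * pad_s)
  sleep_s <- total_s - 2 * pad_s
  if (is.null(start_time)) {
    start_time <- as.numeric(as.POSIXct(profile$start_date, tz = "UTC")) +
      round((onset_h - pad_s / 3600) * 3600)
  }

  # night-level draws (between-night variability + class shift)
  temp_n <- stats::rnorm(1, profile$temp_mean + sh$temp * profile$temp_sd, profile$temp_sd)
  eda_n <- max(stats::rnorm(1, profile$eda_mean + sh$eda * profile$eda_sd, profile$eda_sd), 0.05)
  hr_n <- stats::rnorm(1, profile$hr_mean + sh$hr * profile$hr_sd, profile$hr_sd)
  rmssd_n <- max(stats::rnorm(1, profile$rmssd_mean + sh$rmssd * profile$rmssd_sd,
                              profile$rmssd_sd), 0.005)
  move_n <- max(profile$movement_rate * (1 + 0.5 * sh$movement) +
                  stats::rnorm(1, 0, 0.25 * profile$movement_rate), 0)

  # accelerometer: awake pads are high-movement, sleep quiet + arousals
  n_pad <- round(pad_s * 32)
  n_slp <- round(sleep_s * 32)
  acc_sleep <- acc_segment(n_slp, 0.004)
  burst <- movement_mask(n_slp, 32, move_n)
  if (any(burst)) acc_sleep[burst, ] <- acc_segment(sum(burst), 0.06)
  acc <- rbind(acc_segment(n_pad, 0.25), acc_sleep, acc_segment(n_pad, 0.25))

  # beats over the whole session; sleep-level HR during pads is acceptable
  ibi <- sim_ibi_ar1(total_s, 60 / hr_n, rmssd_n)
  beat_t <- cumsum(ibi)
  bvp <- synthesize_bvp_from_ibi(ibi, 64) + stats::rnorm(round(sum(ibi) * 64), 0, 1)
  n64 <- total_s * 64
  bvp <- if (length(bvp) >= n64) bvp[seq_len(n64)] else c(bvp, numeric(n64 - length(bvp)))

  # HR at 1 Hz: 60 / rolling 10-beat mean of the inter-beat series
  roll <- as.numeric(stats::filter(ibi, rep(1 / 10, 10), sides = 1))
  roll[is.na(roll)] <- mean(ibi[seq_len(min(10, length(ibi)))])
  hr <- 60 / stats::approx(beat_t, roll, xout = seq_len(total_s) - 0.5, rule = 2)$y

  # temperature / EDA at 4 Hz: night level + slow drift + sensor noise
  n4 <- total_s * 4
  ramp <- (seq_len(n4) - 1) / max(n4 - 1, 1)   # 0..1 across the session
  temp <- temp_n + slow_drift(n4, 4, 0.10) + stats::rnorm(n4, 0, 0.02) +
    sh$trend * profile$temp_sd * ramp
  eda <- pmax(eda_n + slow_drift(n4, 4, 0.15 * eda_n) + stats::rnorm(n4, 0, 0.01) +
                sh$trend * profile$eda_sd * ramp, 0)

  session <- e4_session(night_id, profile$subject_id, list(
    e4_channel("ACC", start_time, 32, round6(acc)),
    e4_channel("BVP", start_time, 64, round6(bvp)),
    e4_channel("EDA", start_time, 4, round6(eda)),
    e4_channel("HR", start_time, 1, round6(hr)),
    e4_channel("TEMP", start_time, 4, round6(temp)),
    e4_channel("IBI", start_time, NA, round6(cbind(beat_t, ibi)))
  ))
  attr(session, "sleep_start") <- start_time + pad_s
  attr(session, "sleep_end") <- start_time + pad_s + sleep_s
  session
}

#' Generate a full multi-day dataset for one subject
#'
#' Draws the subject's migraine days uniformly at random (no adjacency
#' constraint), generates one night session waking into each diary day, and
#' drops whole nights with the profile's missing-night probability. The
#' diary always covers every day; a night preceding a migraine day carries
#' the pre-migraine physiology regardless of whether it survives the
#' missingness draw.
#'
#' @param profile A \code{\link{subject_profile}}.
#' @param effect An \code{\link{effect_spec}}.
#' @param seed Integer master seed for the subject.
#' @return A list with elements \code{sessions} (list of
#'   \code{e4_session}) and \code{diary} (a \code{diary_labels} data.frame).
#' @export
generate_subject_dataset <- function(profile, effect = effect_spec(), seed = 1) {
  set.seed(seed)
  days <- profile$start_date + seq_len(profile$n_days) - 1
  mig_days <- sort(sample.int(profile$n_days, profile$n_migraine_days))
  migraine <- seq_len(profile$n_days) %in% mig_days
  keep <- stats::runif(profile$n_days) >= profile$missing_prob
  night_seeds <- sample.int(.Machine$integer.max - 1, profile$n_days)

  sessions <- list()
  for (d in which(keep)) {
    start_time <- as.numeric(as.POSIXct(days[d] - 1, tz = "UTC"))  # evening of day d-1
    sessions[[length(sessions) + 1L]] <- generate_night(
      profile, is_pre_migraine = migraine[d], effect = effect,
      seed = night_seeds[d],
      night_id = sprintf("%s_n%03d", profile$subject_id, d),
      start_time = start_time + round(profile$sleep_onset_hour * 3600) -
        profile$wake_pad_min * 60)
  }
  diary <- data.frame(date = days, migraine = migraine,
                      note = ifelse(migraine, "migraine attack", ""),
                      stringsAsFactors = FALSE)
  attr(diary, "subject_id") <- profile$subject_id
  class(diary) <- c("diary_labels", class(diary))
  list(sessions = sessions, diary = diary)
}
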