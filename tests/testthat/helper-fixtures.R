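# Shared fixtures, generated in code. Synthetic nights use short sleep
# intervals at the native sampling rates so the suite stays fast; the
# statistics under test act on between-night variation, which is
# unaffected by night length.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# profile with a ~20-minute sleep interval waking shortly after 1 am
short_profile <- function(subject_id = "S1", n_days = 8, n_migraine_days = 3,
                          sleep_min = 20, missing_prob = 0, ...) {
  subject_profile(subject_id, n_days = n_days, n_migraine_days = n_migraine_days,
                  sleep_onset_hour = 25, sleep_offset_hour = 25 + sleep_min / 60,
                  sleep_jitter_sd = 0.01, wake_pad_min = 3,
                  missing_prob = missing_prob, ...)
}

short_sleep_params <- function() sleep_params(min_sleep_s = 5 * 60)

# one segmented + featurized subject, reused across test files
tiny_subject_features <- function() {
  cached("tiny_subject_features", {
    ds <- generate_subject_dataset(short_profile(), effect_spec(), seed = 401)
    nights <- segment_label_nights(ds$sessions, ds$diary, short_sleep_params())
    nightly_feature_table(nights)
  })
}

tiny_night <- function() {
  cached("tiny_night", {
    ds <- generate_subject_dataset(short_profile(n_days = 1, n_migraine_days = 0),
                                   seed = 402)
    segment_label_nights(ds$sessions, ds$diary, short_sleep_params())[[1]]
  })
}

# a synthetic resampled block built directly (no generator), for
# closed-form feature checks
constant_block <- function(n = 400, acc = 1, bvp = 5, temp = 36, hr = 60,
                           eda = 0.5, ibi = 1) {
  structure(list(start_time = 0, rate = 64,
                 acc_mag = rep(acc, n), bvp = rep(bvp, n),
                 temp = rep(temp, n), hr = rep(hr, n), eda = rep(eda, n),
                 ibi_interp = rep(ibi, n),
                 ibi_events = cbind(time = cumsum(rep(ibi, 10)),
                                    interval = rep(ibi, 10))),
            class = "resampled_block")
}

as_night <- function(block, label = "non_migraine", night_id = "n1",
                     subject_id = "S1") {
  structure(list(subject_id = subject_id, night_id = night_id,
                 sleep_start = block$start_time,
                 sleep_end = block$start_time + length(block$acc_mag) / block$rate,
                 label = label, block = block),
            class = "night_recording")
}

# feature table with given class structure and arbitrary numeric content;
# feature columns are iid normals so discriminant fits stay well-posed
dummy_feature_table <- function(n_mig, n_non, n_features = 5, seed = 1,
                                subject_id = "S1") {
  set.seed(seed)
  n <- n_mig + n_non
  if (n == 0) {
    return(cbind(data.frame(subject_id = character(0), night_id = character(0),
                            label = character(0), stringsAsFactors = FALSE),
                 as.data.frame(matrix(numeric(0), 0, n_features,
                                      dimnames = list(NULL, paste0("f", seq_len(n_features)))))))
  }
  vals <- matrix(rnorm(n * n_features), n, n_features,
                 dimnames = list(NULL, paste0("f", seq_len(n_features))))
  cbind(data.frame(subject_id = subject_id,
                   night_id = sprintf("%s_n%03d", subject_id, seq_len(n)),
                   label = rep(c("pre_migraine", "non_migraine"), c(n_mig, n_non)),
                   stringsAsFactors = FALSE),
        as.data.frame(vals))
}

random_session <- function(seed = 1, with_ibi = TRUE, n_seconds = 5) {
  set.seed(seed)
  start <- 1700000000
  r6 <- function(x) round(x, 6)
  chans <- list(
    e4_channel("ACC", start, 32, r6(matrix(rnorm(n_seconds * 32 * 3, 0, 30), ncol = 3))),
    e4_channel("BVP", start, 64, r6(rnorm(n_seconds * 64, 0, 50))),
    e4_channel("EDA", start, 4, r6(runif(n_seconds * 4, 0, 2))),
    e4_channel("HR", start, 1, r6(runif(n_seconds, 50, 90))),
    e4_channel("TEMP", start, 4, r6(runif(n_seconds * 4, 33, 37))))
  if (with_ibi) {
    ibi <- r6(runif(8, 0.7, 1.1))
    chans <- c(chans, list(e4_channel("IBI", start, NA, cbind(r6(cumsum(ibi)), ibi))))
  }
  e4_session(paste0("sess", seed), "SX", chans)
}
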