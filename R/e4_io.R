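#' @title Empatica E4 session containers and CSV dialect I/O
#' @name e4_io
#' @description
#' The E4 wristband exports one CSV file per channel. Every file starts with
#' the session start time in POSIX seconds (UTC); regularly sampled channels
#' carry the sampling rate in Hz on the second row, followed by one sample
#' per row (three comma-separated values per row for the 3-axis
#' accelerometer). The inter-beat-interval file (IBI.csv) instead lists
#' irregular events: the start time on the first row, then
#' \code{offset_seconds, interval_seconds} rows.
#'
#' Channels and units: ACC in raw 1/64 g units at 32 Hz, BVP in arbitrary
#' photoplethysmography units at 64 Hz, EDA in microsiemens at 4 Hz, TEMP in
#' degrees Celsius at 4 Hz, HR in beats/min at 1 Hz, IBI in seconds.
NULL

E4_REQUIRED_CHANNELS <- c("ACC", "BVP", "EDA", "HR", "TEMP")
E4_DEFAULT_RATES <- c(ACC = 32, BVP = 64, EDA = 4, HR = 1, TEMP = 4)

#' Construct one E4 signal channel
#'
#' @param name Channel identifier: one of \code{"ACC"}, \code{"BVP"},
#'   \code{"EDA"}, \code{"HR"}, \code{"TEMP"}, \code{"IBI"}.
#' @param start_time Session start, POSIX seconds UTC.
#' @param sample_rate Sampling rate in Hz; must be \code{NA} for IBI.
#' @param samples Numeric vector (BVP/EDA/HR/TEMP), an n-by-3 matrix of raw
#'   1/64 g values (ACC), or an n-by-2 matrix of
#'   \code{(offset_seconds, interval_seconds)} events (IBI).
#' @return An object of class \code{e4_channel}.
#' @export
e4_channel <- function(name, start_time, sample_rate, samples) {
  name <- match.arg(name, c("ACC", "BVP", "EDA", "HR", "TEMP", "IBI"))
  if (name == "IBI") {
    if (!is.na(sample_rate)) stop("IBI channel has no sampling rate", call. = FALSE)
    samples <- matrix(as.numeric(samples), ncol = 2,
                      dimnames = list(NULL, c("offset", "interval")))
    if (nrow(samples) > 1 && any(diff(samples[, "offset"]) <= 0)) {
      stop("IBI offsets must be strictly increasing", call. = FALSE)
    }
  } else {
    if (!is.numeric(sample_rate) || sample_rate <= 0) {
      stop("sample_rate must be > 0 for channel ", name, call. = FALSE)
    }
    if (name == "ACC") {
      samples <- matrix(as.numeric(samples), ncol = 3,
                        dimnames = list(NULL, c("x", "y", "z")))
    } else {
      samples <- as.numeric(samples)
    }
  }
  structure(list(name = name, start_time = as.numeric(start_time),
                 sample_rate = as.numeric(sample_rate), samples = samples),
            class = "e4_channel")
}

n_samples <- function(ch) if (is.matrix(ch$samples)) nrow(ch$samples) else length(ch$samples)

#' Duration of a channel in seconds
#' @param ch An \code{e4_channel}.
#' @return Seconds covered by the channel (for IBI: last offset).
#' @export
channel_duration <- function(ch) {
  if (ch$name == "IBI") {
    if (nrow(ch$samples) == 0) return(0)
    return(ch$samples[nrow(ch$samples), "offset"])
  }
  n_samples(ch) / ch$sample_rate
}

#' Construct a wear session from channels
#'
#' @param session_id Opaque session identifier.
#' @param subject_id Opaque subject identifier.
#' @param channels List of \code{e4_channel} objects; ACC, BVP, EDA, HR and
#'   TEMP are required, IBI is optional.
#' @return An object of class \code{e4_session}.
#' @export
e4_session <- function(session_id, subject_id, channels) {
  names(channels) <- vapply(channels, `[[`, "", "name")
  missing <- setdiff(E4_REQUIRED_CHANNELS, names(channels))
  if (length(missing) > 0) {
    stop("session is missing required channels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(session_id = as.character(session_id),
                 subject_id = as.character(subject_id),
                 channels = channels[order(names(channels))]),
            class = "e4_session")
}

#' @export
print.e4_session <- function(x, ...) {
  cat("<e4_session>", x$session_id, "subject", x$subject_id, "\n")
  for (ch in x$channels) {
    cat(sprintf("  %-4s %8d samples  %s\n", ch$name, n_samples(ch),
                if (is.na(ch$sample_rate)) "(event list)" else paste0(ch$sample_rate, " Hz")))
  }
  invisible(x)
}

fmt_num <- function(x) formatC(x, format = "f", digits = 6, drop0trailing = TRUE)

#' Write a session in the E4 CSV export dialect
#'
#' Emits one CSV per channel into \code{path}: first row the start time
#' (repeated across the three ACC columns), second row the sampling rate,
#' then samples. IBI.csv gets the header row \code{"<start>, IBI"} followed
#' by \code{offset,interval} rows, and is omitted when the session has no
#' IBI channel.
#'
#' @param session An \code{e4_session}.
#' @param path Directory to write into (created if absent).
#' @return Invisibly, \code{path}.
#' @export
write_e4_session <- function(session, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (ch in session$channels) {
    file <- file.path(path, paste0(ch$name, ".csv"))
    if (ch$name == "IBI") {
      header <- paste0(fmt_num(ch$start_time), ", IBI")
      body <- if (nrow(ch$samples) > 0) {
        paste(fmt_num(ch$samples[, "offset"]), fmt_num(ch$samples[, "interval"]), sep = ",")
      } else character(0)
    } else if (ch$name == "ACC") {
      header <- c(paste(rep(fmt_num(ch$start_time), 3), collapse = ","),
                  paste(rep(fmt_num(ch$sample_rate), 3), collapse = ","))
      body <- if (nrow(ch$samples) > 0) {
        paste(fmt_num(ch$samples[, 1]), fmt_num(ch$samples[, 2]),
              fmt_num(ch$samples[, 3]), sep = ",")
      } else character(0)
    } else {
      header <- c(fmt_num(ch$start_time), fmt_num(ch$sample_rate))
      body <- if (length(ch$samples) > 0) fmt_num(ch$samples) else character(0)
    }
    writeLines(c(header, body), file)
  }
  invisible(path)
}

read_csv_lines <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

parse_rows <- function(lines, width, what) {
  if (length(lines) == 0) return(matrix(numeric(0), ncol = width))
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(parts) < width)) {
    stop("malformed ", what, ": expected ", width, " values per row", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  if (anyNA(vals)) stop("malformed ", what, ": non-numeric sample row", call. = FALSE)
  matrix(vals, ncol = width, byrow = TRUE)
}

#' Read a session directory in the E4 CSV export dialect
#'
#' @param path Directory containing ACC.csv, BVP.csv, EDA.csv, HR.csv,
#'   TEMP.csv and optionally IBI.csv.
#' @param session_id Session identifier to attach; defaults to the directory
#'   base name.
#' @param subject_id Subject identifier to attach; default \code{"unknown"}.
#' @return An \code{e4_session}.
#' @export
read_e4_session <- function(path, session_id = basename(path), subject_id = "unknown") {
  missing <- E4_REQUIRED_CHANNELS[!file.exists(file.path(path, paste0(E4_REQUIRED_CHANNELS, ".csv")))]
  if (length(missing) > 0) {
    stop("E4 directory ", path, " is missing: ",
         paste(paste0(missing, ".csv"), collapse = ", "), call. = FALSE)
  }
  present <- c(E4_REQUIRED_CHANNELS,
               if (file.exists(file.path(path, "IBI.csv"))) "IBI")
  channels <- lapply(present, function(name) {
    lines <- read_csv_lines(file.path(path, paste0(name, ".csv")))
    if (length(lines) < 1) stop("malformed ", name, ".csv: empty file", call. = FALSE)
    start <- suppressWarnings(as.numeric(strsplit(lines[1], ",", fixed = TRUE)[[1]][1]))
    if (is.na(start)) stop("malformed ", name, ".csv: bad start-time row", call. = FALSE)
    if (name == "IBI") {
      return(e4_channel("IBI", start, NA, parse_rows(lines[-1], 2, "IBI.csv")))
    }
    if (length(lines) < 2) stop("malformed ", name, ".csv: missing rate row", call. = FALSE)
    rate <- suppressWarnings(as.numeric(strsplit(lines[2], ",", fixed = TRUE)[[1]][1]))
    if (is.na(rate) || rate <= 0) stop("malformed ", name, ".csv: bad rate row", call. = FALSE)
    width <- if (name == "ACC") 3L else 1L
    vals <- parse_rows(lines[-(1:2)], width, paste0(name, ".csv"))
    e4_channel(name, start, rate, if (width == 1L) as.numeric(vals) else vals)
  })
  e4_session(session_id, subject_id, channels)
}

#' Read a migraine diary file
#'
#' The diary is a CSV with columns \code{date} (ISO-8601), \code{migraine}
#' (0/1) and an optional free-text \code{note}. Each calendar day may appear
#' at most once; days absent from the file are simply unknown and are never
#' imputed.
#'
#' @param path Path to the diary CSV.
#' @param subject_id Subject the diary belongs to.
#' @return A data.frame of class \code{diary_labels} with columns
#'   \code{date} (\code{Date}), \code{migraine} (logical), \code{note}
#'   (character) and attribute \code{subject_id}.
#' @export
read_diary <- function(path, subject_id = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(date = "character"))
  if (nrow(df) == 0) {
    out <- data.frame(date = as.Date(character(0)), migraine = logical(0),
                      note = character(0), stringsAsFactors = FALSE)
  } else {
    dates <- as.Date(df$date, format = "%Y-%m-%d")
    if (anyNA(dates)) {
      stop("diary contains unparseable dates: ",
           paste(df$date[is.na(dates)], collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(dates)) {
      stop("diary contains duplicate dates: ",
           paste(unique(format(dates[duplicated(dates)])), collapse = ", "),
           call. = FALSE)
    }
    out <- data.frame(date = dates, migraine = as.logical(as.integer(df$migraine)),
                      note = if ("note" %in% names(df)) as.character(df$note) else "",
                      stringsAsFactors = FALSE)
    out <- out[order(out$date), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "subject_id") <- subject_id
  class(out) <- c("diary_labels", class(out))
  out
}

#' Write a diary file
#' @param diary A \code{diary_labels} data.frame.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_diary <- function(diary, path) {
  utils::write.csv(data.frame(date = format(diary$date, "%Y-%m-%d"),
                              migraine = as.integer(diary$migraine),
                              note = diary$note),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
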