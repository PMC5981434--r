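#' @title Pipeline wiring: simulate -> ingest -> featurize -> evaluate
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param out_dir Directory for stage artifacts.
#' @param profiles List of \code{\link{subject_profile}}s (simulate stage).
#' @param effect An \code{\link{effect_spec}} (simulate stage).
#' @param seed Master seed for every stage.
#' @param sleep A \code{\link{sleep_params}}.
#' @param mode,classifier,reps Evaluation settings
#'   (\code{\link{run_repeated_experiment}}).
#' @param noise_strength,epsilon,max_features,lambda Model settings.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, profiles = list(subject_profile()),
                            effect = effect_spec(), seed = 1,
                            sleep = sleep_params(), mode = "personal",
                            classifier = "qda", reps = 20,
                            noise_strength = 0.1, epsilon = 0.001,
                            max_features = 15, lambda = 1e-6) {
  if (reps < 1) stop("repetitions must be >= 1", call. = FALSE)
  structure(list(out_dir = out_dir, profiles = profiles, effect = effect,
                 seed = seed, sleep = sleep, mode = mode,
                 classifier = classifier, reps = reps,
                 noise_strength = noise_strength, epsilon = epsilon,
                 max_features = max_features, lambda = lambda),
            class = "pipeline_config")
}

write_manifest <- function(dir, stage, config, files) {
  jsonlite::write_json(
    list(stage = stage, seed = config$seed,
         package_version = as.character(utils::packageVersion("migranight")),
         files = files),
    file.path(dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA)
}

#' Run the pipeline stages
#'
#' Stages run in the fixed order \code{simulate} (write synthetic E4
#' datasets + diaries), \code{featurize} (read sessions, detect sleep,
#' extract the nightly feature table), \code{evaluate} (repeated
#' experiment). Each stage writes its artifacts plus a JSON manifest under
#' \code{config$out_dir}; rerunning with an identical config reproduces
#' identical artifacts.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param stages Character subset of
#'   \code{c("simulate", "featurize", "evaluate")}; an empty vector runs
#'   nothing.
#' @return Invisibly, a list with the artifacts produced (paths, the
#'   feature table and/or the \code{evaluation_report}).
#' @export
run_pipeline <- function(config, stages = c("simulate", "featurize", "evaluate")) {
  out <- list()
  if (length(stages) == 0) return(invisible(out))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  subject_seeds <- derive_seeds(config$seed, length(config$profiles))

  if ("simulate" %in% stages) {
    files <- character(0)
    for (i in seq_along(config$profiles)) {
      p <- config$profiles[[i]]
      ds <- generate_subject_dataset(p, config$effect, seed = subject_seeds[i])
      sdir <- file.path(config$out_dir, "raw", p$subject_id)
      for (s in ds$sessions) {
        write_e4_session(s, file.path(sdir, s$session_id))
      }
      write_diary(ds$diary, file.path(sdir, "diary.csv"))
      files <- c(files, sdir)
    }
    write_manifest(config$out_dir, "simulate", config, files)
    out$raw_dir <- file.path(config$out_dir, "raw")
  }

  if ("featurize" %in% stages) {
    raw <- file.path(config$out_dir, "raw")
    if (!dir.exists(raw)) stop("featurize: no raw data under ", raw, call. = FALSE)
    nights <- list()
    for (sdir in list.dirs(raw, recursive = FALSE)) {
      subject <- basename(sdir)
      diary <- read_diary(file.path(sdir, "diary.csv"), subject_id = subject)
      sessions <- lapply(list.dirs(sdir, recursive = FALSE), read_e4_session,
                         subject_id = subject)
      nights <- c(nights, segment_label_nights(sessions, diary, config$sleep))
    }
    features <- nightly_feature_table(nights)
    feat_path <- file.path(config$out_dir, "features.csv")
    utils::write.csv(features, feat_path, row.names = FALSE)
    jsonlite::write_json(feature_registry(),
                         file.path(config$out_dir, "feature_registry.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(config$out_dir, "featurize", config, feat_path)
    out$features <- features
    out$features_path <- feat_path
  }

  if ("evaluate" %in% stages) {
    features <- out$features
    if (is.null(features)) {
      feat_path <- file.path(config$out_dir, "features.csv")
      if (!file.exists(feat_path)) stop("evaluate: no feature table at ", feat_path, call. = FALSE)
      features <- utils::read.csv(feat_path, stringsAsFactors = FALSE)
    }
    report <- run_repeated_experiment(
      features, mode = config$mode, kind = config$classifier,
      reps = config$reps, seed = config$seed, lambda = config$lambda,
      noise_strength = config$noise_strength, epsilon = config$epsilon,
      max_features = config$max_features)
    rep_path <- file.path(config$out_dir, "evaluation_report.json")
    jsonlite::write_json(list(mode = report$mode, kind = report$kind,
                              reps = report$reps, seed = report$seed,
                              per_rep = report$per_rep, summary = report$summary,
                              overall = as.list(report$overall)),
                         rep_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(report$per_rep,
                     file.path(config$out_dir, "per_repetition_metrics.csv"),
                     row.names = FALSE)
    write_manifest(config$out_dir, "evaluate", config, rep_path)
    out$report <- report
    out$report_path <- rep_path
  }
  invisible(out)
}
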