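#' @title Evaluation protocol: personal and leave-one-subject-out
#' @name evaluate
#' @description
#' Personal models are evaluated with a split that honours the provenance
#' of the comparison observations: two pre-migraine nights are drawn and
#' *all* comparisons built from them go to the test set together (so no
#' pre-migraine night is shared between train and test), plus a random 20%
#' of the non-migraine comparisons; the remainder is partitioned into five
#' observation-level folds, four for training and one for validation of the
#' feature search. User-independent models use leave-one-subject-out. Test
#' predictions are aggregated to nights by majority vote, and performance
#' is the balanced accuracy over night labels, reported as mean and SD over
#' repeated runs with freshly drawn comparison matrices.
NULL

#' Build the personal train/validation/test split
#'
#' @param comp A \code{comparison_set} for one subject.
#' @param seed Integer seed.
#' @param n_test_migraine_nights Pre-migraine nights whose comparisons are
#'   all held out (2, per protocol).
#' @param test_non_fraction Fraction of non-migraine comparisons held out
#'   (rounded to nearest, minimum 1).
#' @param n_folds Number of folds over the remaining observations.
#' @return A list of class \code{split_plan}: \code{mode}, \code{test}
#'   (indices), \code{folds} (list of index vectors, sizes differing by at
#'   most 1), \code{validation_fold}, \code{test_migraine_nights}.
#' @export
make_personal_split <- function(comp, seed = 1, n_test_migraine_nights = 2,
                                test_non_fraction = 0.2, n_folds = 5) {
  mig_idx <- which(comp$label == "migraine_comparison")
  non_idx <- which(comp$label == "non_migraine_comparison")
  mig_nights <- unique(comp$left_night_id[mig_idx])
  if (length(mig_nights) < n_test_migraine_nights + 1) {
    stop("split needs at least ", n_test_migraine_nights + 1,
         " pre-migraine nights, found ", length(mig_nights), call. = FALSE)
  }
  if (length(non_idx) < n_folds) {
    stop("split needs at least ", n_folds, " non-migraine comparisons, found ",
         length(non_idx), call. = FALSE)
  }
  set.seed(seed)
  test_nights <- sample(mig_nights, n_test_migraine_nights)
  test_mig <- mig_idx[comp$left_night_id[mig_idx] %in% test_nights]
  n_test_non <- max(round(test_non_fraction * length(non_idx)), 1)
  test_non <- sample(non_idx, n_test_non)
  test <- c(test_mig, test_non)
  rest <- setdiff(seq_along(comp$label), test)
  fold_of <- sample(rep(seq_len(n_folds), length.out = length(rest)))
  plan <- structure(list(mode = "personal", test = test,
                         folds = split(rest, fold_of), validation_fold = 1L,
                         test_migraine_nights = test_nights),
                    class = "split_plan")
  check_no_leakage(plan, comp)
  plan
}

#' Build one leave-one-subject-out split
#'
#' @param comp_by_subject Named list of \code{comparison_set}s, one per
#'   subject.
#' @param held_out Subject id used as the independent test set.
#' @param seed Integer seed for the fold assignment.
#' @param n_folds Number of folds over the other subjects' observations.
#' @return A \code{split_plan} over the pooled observation set (see
#'   \code{\link{pool_comparisons}}), with \code{held_out} recorded.
#' @export
make_loso_split <- function(comp_by_subject, held_out, seed = 1, n_folds = 5) {
  if (length(comp_by_subject) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (!held_out %in% names(comp_by_subject)) {
    stop("unknown subject: ", held_out, call. = FALSE)
  }
  sizes <- vapply(comp_by_subject, n_comparisons, 0L)
  subject_of <- rep(names(comp_by_subject), sizes)
  test <- which(subject_of == held_out)
  rest <- which(subject_of != held_out)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(n_folds), length.out = length(rest)))
  structure(list(mode = "loso", test = test, folds = split(rest, fold_of),
                 validation_fold = 1L, test_migraine_nights = character(0),
                 held_out = held_out),
            class = "split_plan")
}

#' Pool per-subject comparison sets into one observation set
#' @param comp_by_subject Named list of \code{comparison_set}s.
#' @return A single \code{comparison_set} with a \code{subject_id} field.
#' @export
pool_comparisons <- function(comp_by_subject) {
  sizes <- vapply(comp_by_subject, n_comparisons, 0L)
  structure(list(values = do.call(rbind, lapply(comp_by_subject, `[[`, "values")),
                 label = unlist(lapply(comp_by_subject, `[[`, "label"), use.names = FALSE),
                 left_night_id = unlist(lapply(comp_by_subject, `[[`, "left_night_id"), use.names = FALSE),
                 right_night_id = unlist(lapply(comp_by_subject, `[[`, "right_night_id"), use.names = FALSE),
                 sign = unlist(lapply(comp_by_subject, `[[`, "sign"), use.names = FALSE),
                 subject_id = rep(names(comp_by_subject), sizes)),
            class = "comparison_set")
}

subset_comparisons <- function(comp, idx) {
  structure(list(values = comp$values[idx, , drop = FALSE],
                 label = comp$label[idx],
                 left_night_id = comp$left_night_id[idx],
                 right_night_id = comp$right_night_id[idx],
                 sign = comp$sign[idx]),
            class = "comparison_set")
}

#' Verify the migraine-night leakage invariant of a split
#'
#' No comparison built from a held-out pre-migraine night may appear in the
#' training or validation folds. Called automatically on every personal
#' split; exported so audits can re-check plans.
#'
#' @param plan A \code{split_plan}.
#' @param comp The \code{comparison_set} the plan indexes.
#' @return Invisibly \code{TRUE}; stops on violation.
#' @export
check_no_leakage <- function(plan, comp) {
  rest <- unlist(plan$folds, use.names = FALSE)
  rest_mig_nights <- comp$left_night_id[rest][comp$label[rest] == "migraine_comparison"]
  bad <- intersect(plan$test_migraine_nights, rest_mig_nights)
  if (length(bad) > 0) {
    stop("leakage: test migraine night(s) ", paste(bad, collapse = ", "),
         " appear in train/validation", call. = FALSE)
  }
  invisible(TRUE)
}

#' Aggregate observation predictions to night labels by majority vote
#'
#' A migraine comparison's vote accrues to its left (pre-migraine) night; a
#' non-migraine comparison's vote accrues to both member nights. A
#' prediction of \code{migraine_comparison} is a \code{pre_migraine} vote.
#' The night label is the modal vote; ties go to \code{pre_migraine}
#' (alert-favoring). Nights with no test votes are absent from the output.
#'
#' @param comp The \code{comparison_set} the predictions refer to.
#' @param idx Indices of the predicted (test) observations.
#' @param predicted Predicted labels for \code{comp[idx]}.
#' @return data.frame with \code{night_id}, \code{truth},
#'   \code{predicted}, \code{n_votes}.
#' @export
aggregate_night_predictions <- function(comp, idx, predicted) {
  if (length(idx) == 0) {
    return(data.frame(night_id = character(0), truth = character(0),
                      predicted = character(0), n_votes = integer(0)))
  }
  vote <- ifelse(predicted == "migraine_comparison", "pre_migraine", "non_migraine")
  is_mig <- comp$label[idx] == "migraine_comparison"
  night <- c(comp$left_night_id[idx],                 # every comparison votes left
             comp$right_night_id[idx][!is_mig])       # non-migraine ones also vote right
  truth <- c(ifelse(is_mig, "pre_migraine", "non_migraine"),
             rep("non_migraine", sum(!is_mig)))
  vote <- c(vote, vote[!is_mig])
  out <- do.call(rbind, lapply(split(seq_along(night), night), function(i) {
    pro <- sum(vote[i] == "pre_migraine")
    data.frame(night_id = night[i[1]], truth = truth[i[1]],
               predicted = if (pro >= length(i) - pro) "pre_migraine" else "non_migraine",
               n_votes = length(i), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Balanced accuracy, sensitivity and specificity over night labels
#'
#' Balanced accuracy is the mean of the two per-class true positive rates.
#' Sensitivity is the TPR of non-migraine nights and specificity the TPR of
#' pre-migraine nights (the orientation under which these models tend to
#' recognize non-migraine nights more reliably).
#'
#' @param truth,predicted Aligned night-label vectors; both classes must be
#'   present in \code{truth}.
#' @return Named numeric vector \code{c(balanced_accuracy, sensitivity,
#'   specificity)}.
#' @export
balanced_accuracy <- function(truth, predicted) {
  if (length(truth) == 0 || length(truth) != length(predicted)) {
    stop("need aligned nonempty label vectors", call. = FALSE)
  }
  classes <- c("non_migraine", "pre_migraine")
  if (!all(classes %in% truth)) {
    stop("both classes must be present in the truth labels", call. = FALSE)
  }
  tpr <- vapply(classes, function(cl) mean(predicted[truth == cl] == cl), 0)
  c(balanced_accuracy = mean(tpr),
    sensitivity = tpr[["non_migraine"]],
    specificity = tpr[["pre_migraine"]])
}

eval_one_split <- function(comp, plan, kind, lambda, noise_strength, sfs_opts,
                           refit_noise_free, seed) {
  check_no_leakage(plan, comp)
  val_idx <- plan$folds[[plan$validation_fold]]
  train_idx <- unlist(plan$folds[-plan$validation_fold], use.names = FALSE)
  train <- subset_comparisons(comp, train_idx)
  validation <- subset_comparisons(comp, val_idx)
  noisy_train <- inject_noise(train, strength = noise_strength, seed = seed)
  selected <- sfs_select(noisy_train, validation, kind = kind, lambda = lambda,
                         epsilon = sfs_opts$epsilon,
                         max_features = sfs_opts$max_features)
  final_train <- if (refit_noise_free) {
    subset_comparisons(comp, c(train_idx, val_idx))
  } else noisy_train
  model <- fit_discriminant(final_train, kind = kind, lambda = lambda,
                            features = selected)
  predicted <- predict_labels(model, subset_comparisons(comp, plan$test))
  nights <- aggregate_night_predictions(comp, plan$test, predicted)
  list(metrics = balanced_accuracy(nights$truth, nights$predicted),
       nights = nights, selected = selected)
}

derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1, n)
}

#' Run the repeated evaluation experiment
#'
#' For each repetition a fresh comparison matrix is built (the sign draws
#' of the non-migraine pairs differ between runs), split, feature-selected
#' with a noise-augmented training set, refit, and scored at the night
#' level. Personal mode evaluates every subject separately; LOSO mode
#' holds each subject out in turn against a model trained on the others.
#' Repetitions whose split preconditions fail are recorded as
#' not-evaluable with a warning, never imputed.
#'
#' @param features Nightly feature table
#'   (\code{\link{nightly_feature_table}}).
#' @param mode \code{"personal"} or \code{"loso"}.
#' @param kind Classifier, \code{"qda"} or \code{"lda"}.
#' @param reps Number of repetitions (20, per protocol).
#' @param seed Master seed; per-repetition seeds are derived from it.
#' @param lambda,noise_strength,epsilon,max_features Model and selection
#'   settings (see \code{\link{fit_discriminant}},
#'   \code{\link{inject_noise}}, \code{\link{sfs_select}}).
#' @param refit_noise_free Refit the final model on the un-noised
#'   train+validation data after selection (default) instead of the noisy
#'   training set.
#' @return A list of class \code{evaluation_report}: \code{per_rep} (one
#'   row per subject and repetition), \code{summary} (per-subject mean and
#'   SD), \code{overall} (grand mean and SD of subject means), and the
#'   configuration.
#' @export
run_repeated_experiment <- function(features, mode = c("personal", "loso"),
                                    kind = c("qda", "lda"), reps = 20,
                                    seed = 1, lambda = 1e-6,
                                    noise_strength = 0.1, epsilon = 0.001,
                                    max_features = 15,
                                    refit_noise_free = TRUE) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  if (reps < 1) stop("need at least one repetition", call. = FALSE)
  subjects <- unique(features$subject_id)
  sfs_opts <- list(epsilon = epsilon, max_features = max_features)
  seeds <- matrix(derive_seeds(seed, 3 * reps * length(subjects)),
                  nrow = length(subjects))
  rows <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    for (r in seq_len(reps)) {
      seed3 <- seeds[si, (3 * r - 2):(3 * r)]
      res <- tryCatch({
        if (mode == "personal") {
          comp <- build_comparison_matrix(features[features$subject_id == s, ],
                                          seed = seed3[1])
          plan <- make_personal_split(comp, seed = seed3[2])
        } else {
          comp_by <- lapply(stats::setNames(subjects, subjects), function(u) {
            build_comparison_matrix(features[features$subject_id == u, ],
                                    seed = seed3[1] + match(u, subjects))
          })
          comp <- pool_comparisons(comp_by)
          plan <- make_loso_split(comp_by, held_out = s, seed = seed3[2])
        }
        eval_one_split(comp, plan, kind, lambda, noise_strength, sfs_opts,
                       refit_noise_free, seed = seed3[3])
      }, error = function(e) {
        warning("subject ", s, " repetition ", r, " not evaluable: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, rep = r,
        balanced_accuracy = res$metrics[["balanced_accuracy"]],
        sensitivity = res$metrics[["sensitivity"]],
        specificity = res$metrics[["specificity"]],
        n_selected = length(res$selected),
        selected = paste(res$selected, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  per_rep <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(subject_id = character(0), rep = integer(0),
               balanced_accuracy = numeric(0), sensitivity = numeric(0),
               specificity = numeric(0), n_selected = integer(0),
               selected = character(0))
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$subject_id), function(d) {
    data.frame(subject_id = d$subject_id[1], n_reps = nrow(d),
               mean_balanced_accuracy = mean(d$balanced_accuracy),
               sd_balanced_accuracy = stats::sd(d$balanced_accuracy),
               mean_sensitivity = mean(d$sensitivity),
               mean_specificity = mean(d$specificity),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  overall <- if (!is.null(summ) && nrow(summ) > 0) {
    c(mean_balanced_accuracy = mean(summ$mean_balanced_accuracy),
      sd_balanced_accuracy = stats::sd(summ$mean_balanced_accuracy))
  } else c(mean_balanced_accuracy = NA_real_, sd_balanced_accuracy = NA_real_)
  structure(list(mode = mode, kind = kind, reps = reps, seed = seed,
                 per_rep = per_rep, summary = summ, overall = overall),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s %s, %d repetitions\n",
              x$mode, toupper(x$kind), x$reps))
  if (!is.null(x$summary) && nrow(x$summary) > 0) {
    for (i in seq_len(nrow(x$summary))) {
      cat(sprintf("  %-10s balanced accuracy %.1f%% (%.1f)  [%d reps]\n",
                  x$summary$subject_id[i],
                  100 * x$summary$mean_balanced_accuracy[i],
                  100 * x$summary$sd_balanced_accuracy[i],
                  x$summary$n_reps[i]))
    }
    cat(sprintf("  overall    %.1f%% (%.1f)\n",
                100 * x$overall[["mean_balanced_accuracy"]],
                100 * x$overall[["sd_balanced_accuracy"]]))
  } else cat("  (no evaluable repetitions)\n")
  invisible(x)
}
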