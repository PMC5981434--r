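test_that("personal split reproduces the protocol arithmetic on a 17/12 cohort", {
  ft <- dummy_feature_table(17, 12, seed = 1)
  comp <- build_comparison_matrix(ft, seed = 2)
  expect_equal(n_comparisons(comp), 270)
  plan <- make_personal_split(comp, seed = 3)
  test_labels <- comp$label[plan$test]
  expect_equal(sum(test_labels == "migraine_comparison"), 2 * 12)
  expect_equal(sum(test_labels == "non_migraine_comparison"), round(0.2 * 66))
  sizes <- lengths(plan$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(unname(sort(c(plan$test, unlist(plan$folds)))), seq_len(270))
})

test_that("no test migraine night leaks into train or validation", {
  ft <- dummy_feature_table(6, 10, seed = 4)
  comp <- build_comparison_matrix(ft, seed = 5)
  for (s in 1:25) {
    plan <- make_personal_split(comp, seed = s)
    rest <- unlist(plan$folds)
    rest_mig <- comp$left_night_id[rest][comp$label[rest] == "migraine_comparison"]
    expect_length(intersect(plan$test_migraine_nights, rest_mig), 0)
    expect_true(check_no_leakage(plan, comp))
  }
})

test_that("split preconditions are reported by name", {
  ft <- dummy_feature_table(2, 10, seed = 6)   # only 2 migraine nights
  comp <- build_comparison_matrix(ft, seed = 7)
  expect_error(make_personal_split(comp), "pre-migraine nights")
  ft2 <- dummy_feature_table(4, 2, seed = 8)   # one non-migraine pair
  comp2 <- build_comparison_matrix(ft2, seed = 9)
  expect_error(make_personal_split(comp2), "non-migraine comparisons")
})

test_that("LOSO plans hold each subject out completely", {
  comp_by <- lapply(c(A = 10, B = 20, C = 30), function(s) {
    build_comparison_matrix(dummy_feature_table(3, 5, seed = s,
                                                subject_id = paste0("S", s)),
                            seed = s)
  })
  pooled <- pool_comparisons(comp_by)
  for (held in names(comp_by)) {
    plan <- make_loso_split(comp_by, held, seed = 1)
    expect_equal(unname(sort(c(plan$test, unlist(plan$folds)))),
                 seq_len(n_comparisons(pooled)))
    expect_true(all(pooled$subject_id[plan$test] == held))
    expect_false(held %in% pooled$subject_id[unlist(plan$folds)])
  }
  expect_error(make_loso_split(comp_by, "nope"), "unknown subject")
  expect_error(make_loso_split(comp_by["A"], "A"), "2 subjects")
})

test_that("night aggregation follows the vote and tie rules", {
  comp <- structure(list(
    values = matrix(0, 5, 1),
    label = c("migraine_comparison", "migraine_comparison", "migraine_comparison",
              "non_migraine_comparison", "non_migraine_comparison"),
    left_night_id = c("m1", "m1", "m1", "n1", "n2"),
    right_night_id = c("n1", "n2", "n3", "n2", "n3"),
    sign = c(1L, 1L, 1L, 1L, -1L)), class = "comparison_set")
  # m1 votes [mig, mig, non] -> mig; n1 votes [mig(from m1? no) ...]
  pred <- c("migraine_comparison", "migraine_comparison", "non_migraine_comparison",
            "non_migraine_comparison", "migraine_comparison")
  out <- aggregate_night_predictions(comp, 1:5, pred)
  get <- function(id) out$predicted[out$night_id == id]
  expect_equal(get("m1"), "pre_migraine")          # majority 2 of 3
  # n1: one vote (non, from the n1-n2 comparison) -> non_migraine
  expect_equal(get("n1"), "non_migraine")
  # n2: votes [non, mig] -> tie -> pre_migraine (alert-favoring)
  expect_equal(get("n2"), "pre_migraine")
  # n3 receives no vote from migraine comparisons beyond m1's left accrual,
  # but is a member of the n2-n3 comparison -> one mig vote
  expect_equal(get("n3"), "pre_migraine")
  expect_equal(out$n_votes[out$night_id == "m1"], 3)
  # subsetting to no observations yields an empty frame
  expect_equal(nrow(aggregate_night_predictions(comp, integer(0), character(0))), 0)
})

test_that("balanced accuracy is the mean of the per-class TPRs", {
  truth <- rep(c("pre_migraine", "non_migraine"), c(5, 10))
  expect_equal(unname(balanced_accuracy(truth, truth)["balanced_accuracy"]), 1)
  flipped <- ifelse(truth == "pre_migraine", "non_migraine", "pre_migraine")
  half <- c(truth[1:5], flipped[6:15])
  expect_equal(unname(balanced_accuracy(truth, half)["balanced_accuracy"]), 0.5)
  # TPRs 0.8 (non) and 0.6 (mig) -> 0.7
  pred <- truth
  pred[1:2] <- "non_migraine"   # 3/5 migraine correct
  pred[6:7] <- "pre_migraine"   # 8/10 non correct
  ba <- balanced_accuracy(truth, pred)
  expect_equal(unname(ba["balanced_accuracy"]), 0.7)
  expect_equal(unname(ba["sensitivity"]), 0.8)
  expect_equal(unname(ba["specificity"]), 0.6)
  expect_error(balanced_accuracy(rep("pre_migraine", 3), rep("pre_migraine", 3)),
               "both classes")
})

test_that("the repeated experiment is deterministic and returns sane metrics", {
  ft <- dummy_feature_table(5, 9, n_features = 6, seed = 10)
  r1 <- run_repeated_experiment(ft, mode = "personal", kind = "lda", reps = 3, seed = 21)
  r2 <- run_repeated_experiment(ft, mode = "personal", kind = "lda", reps = 3, seed = 21)
  expect_identical(r1$per_rep, r2$per_rep)
  expect_equal(nrow(r1$per_rep), 3)
  expect_true(all(r1$per_rep$balanced_accuracy >= 0 & r1$per_rep$balanced_accuracy <= 1))
  expect_true(all(c("mean_balanced_accuracy", "sd_balanced_accuracy") %in% names(r1$summary)))
})

test_that("subjects failing split preconditions are reported, not imputed", {
  ft <- dummy_feature_table(2, 8, n_features = 4, seed = 11)  # 2 migraine nights
  expect_warning(r <- run_repeated_experiment(ft, mode = "personal", reps = 1, seed = 5),
                 "not evaluable")
  expect_equal(nrow(r$per_rep), 0)
})
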