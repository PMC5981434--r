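make_obs <- function(x, labels) {
  structure(list(values = x, label = labels,
                 left_night_id = paste0("L", seq_len(nrow(x))),
                 right_night_id = paste0("R", seq_len(nrow(x))),
                 sign = rep(1L, nrow(x))),
            class = "comparison_set")
}

gauss_obs <- function(n, mu1, mu2, sd1 = 1, sd2 = 1, d = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d, mu1, sd1), n, d),
             matrix(rnorm(n * d, mu2, sd2), n, d))
  colnames(x) <- paste0("f", seq_len(d))
  make_obs(x, rep(c("non_migraine_comparison", "migraine_comparison"), each = n))
}

test_that("noise injection doubles the set and scales with feature SD", {
  obs <- gauss_obs(50, 0, 2, seed = 2)
  out <- inject_noise(obs, strength = 0, seed = 3)
  expect_equal(n_comparisons(out), 200)
  expect_identical(out$values[101:200, ], out$values[1:100, ])
  expect_identical(out$label[101:200], obs$label)

  big <- make_obs(matrix(rnorm(10000, 0, 3), ncol = 1,
                         dimnames = list(NULL, "f1")),
                  rep(c("a", "b"), 5000))
  noisy <- inject_noise(big, strength = 0.3, seed = 4)
  deltas <- noisy$values[10001:20000, 1] - big$values[, 1]
  expect_lt(abs(sd(deltas) / (0.3 * sd(big$values[, 1])) - 1), 0.05)

  empty <- make_obs(matrix(numeric(0), 0, 2), character(0))
  expect_equal(n_comparisons(inject_noise(empty, 0.1, 1)), 0)
  expect_error(inject_noise(big, -0.1, 1), ">= 0")
})

test_that("1-D LDA places the boundary midway between equal-variance classes", {
  obs <- gauss_obs(10000, 0, 2, seed = 5)
  m <- fit_discriminant(obs, kind = "lda")
  grid <- matrix(seq(-1, 3, by = 0.001), ncol = 1, dimnames = list(NULL, "f1"))
  pred <- predict_labels(m, grid)
  boundary <- grid[max(which(pred == "non_migraine_comparison")), 1]
  expect_lt(abs(boundary - 1.0), 0.1)
})

test_that("QDA boundaries match the closed-form roots for unequal variances", {
  obs <- gauss_obs(10000, 0, 0, sd1 = 1, sd2 = 3, seed = 6)
  m <- fit_discriminant(obs, kind = "qda")
  # delta_1 = delta_2 at x^2 = 2 log(s2/s1) / (1/s1^2 - 1/s2^2)
  root <- sqrt(2 * log(3) / (1 - 1 / 9))
  set.seed(7)
  x <- matrix(rnorm(10000, 0, 2), ncol = 1, dimnames = list(NULL, "f1"))
  oracle <- ifelse(abs(x[, 1]) < root, "non_migraine_comparison", "migraine_comparison")
  expect_lt(mean(predict_labels(m, x) != oracle), 0.01)
})

test_that("separable clusters are reclassified perfectly; mean maps to its class", {
  obs <- gauss_obs(100, 0, 10, d = 3, seed = 8)
  m <- fit_discriminant(obs, kind = "qda")
  expect_equal(mean(predict_labels(m, obs) == obs$label), 1)
  mu <- matrix(m$means[[2]], 1, dimnames = list(NULL, m$features))
  expect_equal(predict_labels(m, mu), m$classes[2])
})

test_that("prediction is invariant to input feature order and ties go non-migraine", {
  obs <- gauss_obs(200, 0, 1.5, d = 4, seed = 9)
  m <- fit_discriminant(obs, kind = "lda")
  x <- obs$values
  expect_identical(predict_labels(m, x[, c(3, 1, 4, 2)]), predict_labels(m, x))
  expect_error(predict_labels(m, x[, 1:2, drop = FALSE]), "missing model features")

  # identical class-conditional data -> identical scores -> documented tie rule
  xx <- rbind(x[1:50, ], x[1:50, ])
  tied <- fit_discriminant(make_obs(xx, rep(c("non_migraine_comparison",
                                              "migraine_comparison"), each = 50)))
  expect_true(all(predict_labels(tied, x) == "non_migraine_comparison"))
})

test_that("fit preconditions: two classes, two observations each", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_error(fit_discriminant(make_obs(x, rep("a", 10))), "2 classes")
  expect_error(fit_discriminant(make_obs(x, c("a", rep("b", 9)))), "at least 2 obs")
})

test_that("QDA agrees with LDA when covariances are truly equal", {
  obs <- gauss_obs(10000, 0, 1, d = 2, seed = 10)
  lda <- fit_discriminant(obs, kind = "lda", lambda = 1e-10)
  qda <- fit_discriminant(obs, kind = "qda", lambda = 1e-10)
  expect_lt(mean(predict_labels(lda, obs) != predict_labels(qda, obs)), 0.01)
})

test_that("decisions are invariant under affine rescaling of one feature", {
  # in the small-ridge regime; the trace-relative ridge itself is not
  # scale-equivariant, so the property is checked at negligible lambda
  obs <- gauss_obs(500, 0, 1.2, d = 3, seed = 11)
  p0 <- predict_labels(fit_discriminant(obs, kind = "qda", lambda = 1e-12), obs)
  scaled <- obs
  scaled$values[, 2] <- scaled$values[, 2] * 1000
  p1 <- predict_labels(fit_discriminant(scaled, kind = "qda", lambda = 1e-12), scaled)
  expect_lt(mean(p0 != p1), 0.005)
})

test_that("predictions agree with an independent discriminant implementation", {
  skip_if_not_installed("MASS")
  obs <- gauss_obs(300, 0, 1.5, d = 3, seed = 12)
  df <- data.frame(obs$values, y = obs$label)
  ours <- predict_labels(fit_discriminant(obs, kind = "qda", lambda = 0), obs)
  ref <- as.character(predict(MASS::qda(y ~ f1 + f2 + f3, df))$class)
  expect_gt(mean(ours == ref), 0.99)
  ours_l <- predict_labels(fit_discriminant(obs, kind = "lda", lambda = 0), obs)
  ref_l <- as.character(predict(MASS::lda(y ~ f1 + f2 + f3, df))$class)
  expect_gt(mean(ours_l == ref_l), 0.99)
})

test_that("forward selection finds the one informative feature", {
  first_pick <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 120
    x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
    lab <- rep(c("non_migraine_comparison", "migraine_comparison"), each = n / 2)
    x[lab == "migraine_comparison", 3] <- x[lab == "migraine_comparison", 3] + 6
    obs <- make_obs(x, lab)
    idx <- sample(n)
    train <- migranight:::subset_comparisons(obs, idx[1:80])
    val <- migranight:::subset_comparisons(obs, idx[81:n])
    sfs_select(inject_noise(train, 0.1, s), val, kind = "lda")[1]
  }, "")
  expect_gte(mean(first_pick == "f3"), 0.95)
})

test_that("selection caps at max_features and skips redundant duplicates", {
  obs <- gauss_obs(200, 0, 2, d = 5, seed = 13)
  dup <- cbind(obs$values, f1_copy = obs$values[, 1])
  obs2 <- make_obs(dup, obs$label)
  sel <- sfs_select(obs2, obs2, kind = "lda", max_features = 1)
  expect_length(sel, 1)
  sel_full <- sfs_select(obs2, obs2, kind = "lda", max_features = 6)
  expect_false(all(c("f1", "f1_copy") %in% sel_full))
})

test_that("models serialize to JSON and back without changing decisions", {
  obs <- gauss_obs(150, 0, 1.5, d = 3, seed = 14)
  m <- fit_discriminant(obs, kind = "qda")
  path <- file.path(withr::local_tempdir(), "model.json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_labels(m2, obs), predict_labels(m, obs))
  expect_equal(m2$log_priors, m$log_priors)
})
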