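test_that("default base configurations carry the fixed hyperparameters", {
  cfg <- default_base_configs()
  expect_named(cfg, c("gbm", "svm", "ert"))
  expect_equal(cfg$ert$params$n_trees, 100L)
  expect_equal(cfg$ert$params$min_split, 2L)
  expect_equal(cfg$ert$params$min_leaf, 1L)
  expect_equal(cfg$gbm$params$learning_rate, 0.05)
  expect_equal(cfg$gbm$params$n_estimators, 400L)
  expect_equal(cfg$gbm$params$max_depth, 7L)
  expect_equal(cfg$gbm$params$subsample, 0.8)
  expect_equal(cfg$svm$params$gamma, 0.018)
  expect_equal(cfg$svm$params$cost, 19)
  expect_error(base_config("svm_rbf", trees = 5), "unknown hyperparameters")
})

test_that("folds are disjoint, exhaustive, near-equal and deterministic", {
  ids <- sprintf("s%03d", 1:100)
  f <- make_folds(ids, k = 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 10L))
  expect_identical(names(f), ids)

  f23 <- make_folds(sprintf("t%d", 1:23), k = 10, seed = 2)
  expect_true(all(table(f23) %in% 2:3))
  expect_equal(length(f23), 23L)

  expect_identical(make_folds(ids, k = 10, seed = 3),
                   make_folds(ids, k = 10, seed = 3))
  expect_error(make_folds(ids[1:5], k = 10), "at least k")

  y <- rep(0:1, 50)
  fs <- make_folds(ids, k = 10, seed = 4, labels = y)
  for (fold in 1:10)
    expect_equal(sum(y[fs == fold] == 1L), 5L)  # stratified: 5 per class
})

test_that("out-of-fold probabilities are leakage-free probabilities", {
  ft <- signal_table(n = 30, d = 5, n_signal = 3, effect = 2, seed = 1)
  folds <- make_folds(ft$ids, k = 5, seed = 2, labels = ft$labels)
  cfg <- light_configs()
  oof <- generate_oof(ft, cfg, folds, seed = 3)
  expect_equal(dim(oof), c(30L, 3L))
  expect_identical(colnames(oof), c("gbm", "svm", "ert"))
  expect_true(all(oof >= 0 & oof <= 1))

  # definition restated: retraining base m without fold(i) reproduces (i, m)
  i <- 7L
  f <- folds[i]
  tr <- folds != f
  for (m in 1:3) {
    fit <- pssmstack:::.fit_base(cfg[[m]], ft$x[tr, , drop = FALSE],
                                 ft$labels[tr], seed = 3 + 1000L * f + m)
    expect_equal(unname(fit$predict_prob(ft$x[i, , drop = FALSE])),
                 unname(oof[i, m]), tolerance = 1e-10)
  }

  # flipping sample i's label must not move sample i's OOF row
  ft2 <- ft
  ft2$labels[i] <- 1L - ft2$labels[i]
  oof2 <- generate_oof(ft2, cfg, folds, seed = 3)
  expect_equal(oof2[i, ], oof[i, ], tolerance = 1e-12)

  # a fold whose removal leaves one class errors with advice
  y_bad <- c(rep(1L, 29), 0L)
  ft_bad <- feature_table(ft$x, ft$ids, y_bad)
  folds_bad <- make_folds(ft$ids, k = 5, seed = 2)  # unstratified
  expect_error(generate_oof(ft_bad, cfg, folds_bad, seed = 3),
               "single-class|undersample")
})

test_that("separable data gives accurate OOF columns and a stack at least as good", {
  ft <- signal_table(n = 60, d = 6, n_signal = 4, effect = 5, seed = 4)
  cfg <- light_configs()
  cfg$gbm <- base_config("gbm", n_estimators = 150L, max_depth = 3L)
  st <- fit_stack(ft, configs = cfg, k = 5, seed = 5)
  base_acc <- vapply(colnames(st$oof), function(m)
    mean((st$oof[, m] >= 0.5) == (ft$labels == 1L)), numeric(1))
  expect_true(all(base_acc > 0.95))
  stack_acc <- mean((fitted(st) >= 0.5) == (ft$labels == 1L))
  expect_gte(stack_acc, max(base_acc) - 0.02)
})

test_that("fit_stack is deterministic and rejects n < k", {
  ft <- signal_table(n = 25, d = 4, n_signal = 2, effect = 2, seed = 6)
  s1 <- fit_stack(ft, configs = light_configs(), k = 5, seed = 7)
  s2 <- fit_stack(ft, configs = light_configs(), k = 5, seed = 7)
  expect_equal(coef(s1), coef(s2), tolerance = 1e-8)
  expect_identical(s1$folds, s2$folds)
  expect_equal(s1$oof, s2$oof, tolerance = 1e-12)
  expect_error(fit_stack(ft_rows(ft, 1:8), k = 10), "at least k")
})

test_that("predict aligns features by name and rejects mismatches", {
  ft <- signal_table(n = 30, d = 5, n_signal = 3, effect = 2, seed = 8)
  st <- fit_stack(ft, configs = light_configs(), k = 5, seed = 9)
  p <- predict(st, ft)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(predict(st, ft, type = "label"), 30L)
  expect_true(all(predict(st, ft, type = "label") %in% 0:1))

  # shuffled column order must give identical predictions
  shuf <- feature_table(ft$x[, rev(colnames(ft$x))], ft$ids, ft$labels)
  expect_equal(predict(st, shuf), p, tolerance = 1e-12)

  missing <- feature_table(ft$x[, -2], ft$ids, ft$labels)
  expect_error(predict(st, missing), "missing: f02")
  extra_x <- cbind(ft$x, zz = rnorm(30))
  expect_error(predict(st, feature_table(extra_x, ft$ids)), "unexpected: zz")

  r <- residuals(st)
  expect_equal(r, ft$labels - fitted(st), tolerance = 1e-12)
})

test_that("vote_combine: agreement, majority, and the soft/hard disagreement case", {
  P <- rbind(c(0.9, 0.8, 0.7),    # all positive
             c(0.1, 0.2, 0.3),    # all negative
             c(0.9, 0.8, 0.2),    # 2-1 hard positive
             c(0.9, 0.45, 0.45))  # soft positive (mean 0.6), hard negative
  expect_equal(as.integer(vote_combine(P, "hard")), c(1L, 0L, 1L, 0L))
  soft <- vote_combine(P, "soft")
  expect_equal(as.integer(soft), c(1L, 0L, 1L, 1L))
  expect_equal(attr(soft, "prob")[4], 0.6, tolerance = 1e-12)
})

test_that("voting baseline predicts sensibly on held-out separable data", {
  ft <- signal_table(n = 80, d = 5, n_signal = 3, effect = 3, seed = 10)
  sp <- stratified_split(ft, 0.25, seed = 11)
  for (mode in c("hard", "soft")) {
    v <- voting_predict(sp$train, sp$test, light_configs(), mode = mode,
                        seed = 12)
    expect_length(v$label, nrow(sp$test$x))
    expect_gte(mean(v$label == sp$test$labels), 0.9)
    expect_equal(dim(v$base_probs), c(nrow(sp$test$x), 3L))
  }
})

test_that("grid search is exhaustive, seeded and prefers the stronger config", {
  ft <- signal_table(n = 50, d = 5, n_signal = 3, effect = 3, seed = 13)
  single <- list(base_config("extra_trees", n_trees = 20L))
  gs1 <- grid_search(single, ft, cv = 4, seed = 14)
  expect_identical(gs1$best, single[[1]])

  space <- list(base_config("extra_trees", n_trees = 1L),
                base_config("extra_trees", n_trees = 60L))
  gs <- grid_search(space, ft, cv = 4, seed = 14)
  expect_equal(gs$best$params$n_trees, 60L)
  gs2 <- grid_search(space, ft, cv = 4, seed = 14)
  expect_equal(gs$results, gs2$results, tolerance = 1e-12)
})

test_that("a saved and reloaded stack predicts identically", {
  ft <- signal_table(n = 30, d = 4, n_signal = 2, effect = 2, seed = 15)
  st <- fit_stack(ft, configs = light_configs(), k = 5, seed = 16)
  f <- withr::local_tempfile(fileext = ".rds")
  save_stack(st, f)
  st2 <- load_stack(f)
  expect_equal(predict(st2, ft), predict(st, ft), tolerance = 1e-12)
  expect_equal(coef(st2), coef(st))

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something_else"), bad)
  expect_error(load_stack(bad), "not a stack archive")
})

test_that("held-out accuracy is non-decreasing in class separation", {
  accs <- vapply(c(0, 1.5, 4), function(eff) {
    ft <- signal_table(n = 80, d = 5, n_signal = 3, effect = eff, seed = 17)
    sp <- stratified_split(ft, 0.3, seed = 18)
    st <- fit_stack(sp$train, configs = light_configs(), k = 5, seed = 19)
    mean(predict(st, sp$test, type = "label") == sp$test$labels)
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))  # monotone up to small noise
  expect_gt(accs[3], accs[1])
})
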