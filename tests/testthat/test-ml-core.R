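# Small but real feature encodings keep these tests representative and fast.
ml_fixture <- function(n = 400, seed = 51) {
  peps <- unique(random_peptides(n + 50, seed = seed))[seq_len(n)]
  x <- encode_table(peps, test_scales, energies = numeric(n))
  list(peptides = peps, x = x)
}

test_that("prediction metrics match closed-form arithmetic", {
  m <- evaluate_predictions(c(1, 2, 3), c(2, 2, 5))
  # by hand: centred cross product 3, ss_x 2, ss_y 6 -> r = 3/sqrt(12);
  # squared errors (1, 0, 4) -> rmse = sqrt(5/3)
  expect_equal(m$r, 3 / sqrt(12))
  expect_equal(m$rmse, sqrt(5 / 3))
  expect_true(m$r_defined)

  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$rmse, 0)
  inv <- evaluate_predictions(c(1, 2, 3), c(-1, -2, -3))
  expect_equal(inv$r, -1)
  flat <- evaluate_predictions(c(1, 1, 1), c(1, 2, 3))
  expect_false(flat$r_defined)
  expect_true(is.na(flat$r))
})

test_that("cross-validated forest recovers a noiseless single-feature target", {
  fx <- ml_fixture(500)
  y <- 2 * fx$x[, "z3_4"] + 1
  cfg <- tep_model_config(n_trees = 300, grid = data.frame(mtry = 52), seed = 2)
  m <- tep_train(fx$x, y, cfg)
  expect_gt(m$pooled_r, 0.95)
  # fold partition: disjoint and exhaustive
  expect_identical(sort(unique(m$folds)), 1:5)
  expect_identical(length(m$folds), nrow(fx$x))
  expect_identical(as.integer(table(m$folds)), rep(100L, 5))
})

test_that("a constant response yields zero RMSE and an undefined correlation flag", {
  fx <- ml_fixture(60)
  y <- rep(1.5, 60)
  m <- tep_train(fx$x, y, tep_model_config(n_trees = 50, grid = data.frame(mtry = 13),
                                           seed = 3))
  expect_false(m$r_defined)
  expect_true(is.na(m$pooled_r))
  expect_equal(m$pooled_rmse, 0, tolerance = 1e-12)
})

test_that("training and prediction are reproducible given the seed", {
  fx <- ml_fixture(120)
  set.seed(61)
  y <- fx$x[, "T3"] + rnorm(120, sd = 0.1)
  cfg <- tep_model_config(n_trees = 100, seed = 7)  # default mtry grid
  m1 <- tep_train(fx$x, y, cfg)
  m2 <- tep_train(fx$x, y, cfg)
  expect_identical(m1$oof, m2$oof)
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(predict(m1, fx$x), predict(m2, fx$x))
  expect_identical(predict(m1, fx$x), predict(m1, fx$x))
})

test_that("forest predictions stay within the training response range", {
  fx <- ml_fixture(200)
  set.seed(71)
  y <- exp(fx$x[, "z1_2"] / 4) + rnorm(200, sd = 0.05)
  m <- tep_train(fx$x, y, tep_model_config(n_trees = 100,
                                           grid = data.frame(mtry = 52), seed = 5))
  p <- predict(m, encode_table(random_peptides(500, seed = 72), test_scales,
                               energies = numeric(500)))
  expect_true(all(p >= min(y) - 1e-9 & p <= max(y) + 1e-9))
})

test_that("schema mismatches are rejected with offending columns named", {
  fx <- ml_fixture(60)
  m <- tep_train(fx$x, seq_len(60) / 60,
                 tep_model_config(n_trees = 20, grid = data.frame(mtry = 13),
                                  seed = 1))
  bad <- fx$x[, -3]
  expect_error(predict(m, bad), colnames(fx$x)[3])
  swapped <- fx$x[, c(2, 1, 3:157)]
  expect_error(predict(m, swapped), "order")
})

test_that("importance is a normalized ranking that recovers a planted signal", {
  fx <- ml_fixture(400)
  y <- 3 * fx$x[, "z5_1"]
  m <- tep_train(fx$x, y, tep_model_config(n_trees = 300,
                                           grid = data.frame(mtry = 52), seed = 9))
  imp <- m$importance
  expect_identical(nrow(imp), 157L)
  expect_equal(sum(imp$importance), 1)
  expect_true(all(imp$importance >= 0))
  expect_identical(imp$rank, seq_len(157L))
  # the driving feature or its sequence-average alias must rank near the top
  expect_true(any(imp$feature[1:3] %in% c("z5_1", "z5")))
})

test_that("gradient boosting backend trains, predicts deterministically and ranks features", {
  fx <- ml_fixture(200)
  y <- 2 * fx$x[, "z3_4"] + 1
  cfg <- tep_model_config("xgboost", seed = 4,
                          grid = expand.grid(eta = 0.1, max_depth = c(2L, 4L),
                                             gamma = 0, colsample_bytree = 0.8,
                                             min_child_weight = 1, subsample = 0.8,
                                             nrounds = 150L))
  m <- tep_train(fx$x, y, cfg)
  expect_gt(m$pooled_r, 0.9)
  expect_identical(predict(m, fx$x), predict(m, fx$x))
  expect_equal(sum(m$importance$importance), 1)
  expect_identical(nrow(m$importance), 157L)
  m2 <- tep_train(fx$x, y, cfg)
  expect_identical(m$oof, m2$oof)
})

test_that("model methods summarize without error", {
  fx <- ml_fixture(80)
  y <- fx$x[, "z1"]
  m <- tep_train(fx$x, y, tep_model_config(n_trees = 50,
                                           grid = data.frame(mtry = 13), seed = 6))
  expect_output(print(m), "pooled out-of-fold")
  expect_output(summary(m), "Per-fold")
  expect_length(residuals(m), 80L)
  expect_equal(residuals(m), y - m$oof)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(m))
})
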