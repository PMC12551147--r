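# A deterministic lookup oracle over the reduced space.
lookup_oracle <- function(space, values) {
  function(peptides, seed = 0L, round = 0L) {
    as_tbl <- activity_table(peptides,
                             relative_intensity = values[match(peptides, space)],
                             source = "synthetic", round = round)
    attr(as_tbl, "normalized") <- TRUE
    as_tbl
  }
}

test_that("a pure top-k policy returns exactly the k highest-predicted unseen peptides", {
  space <- small_space()
  x <- small_features(space)
  set.seed(81)
  preds <- stats::runif(length(space))
  pol <- selection_policy(batch_size = 50, n_top = 50, n_cluster_reps = 0,
                          n_random = 0, seed = 1)
  got <- select_candidates(space, preds, x, pol)
  expect_identical(got$peptide, space[order(-preds, space)][1:50])
  expect_true(all(got$stratum == "top"))

  # exclusion first: already-measured peptides can never be selected
  seen <- space[order(-preds, space)][1:30]
  got2 <- select_candidates(space, preds, x, pol, exclude = seen)
  expect_identical(got2$peptide, setdiff(space[order(-preds, space)], seen)[1:50])
  expect_length(intersect(got2$peptide, seen), 0L)
})

test_that("forced selection and capacity limits behave at the boundary", {
  space <- small_space()
  x <- small_features(space)
  preds <- seq_along(space) / length(space)
  pol <- selection_policy(batch_size = 10, pool_size = 10, n_top = 10,
                          n_cluster_reps = 0, n_random = 0, seed = 1)
  keep <- space[c(5, 50, 500, 900, 1000, 1100, 1200, 1290, 1293, 1296)]
  got <- select_candidates(space, preds, x, pol, exclude = setdiff(space, keep))
  expect_setequal(got$peptide, keep)
  expect_error(select_candidates(space, preds, x, pol,
                                 exclude = setdiff(space, keep[1:9])),
               "exhausted")
})

test_that("cluster representatives cover well-separated planted clusters", {
  # 10 planted blobs in a synthetic 5-feature embedding + an energy column
  set.seed(91)
  n_per <- 60
  centers <- matrix(stats::rnorm(10 * 5, sd = 30), 10, 5)
  emb <- do.call(rbind, lapply(1:10, function(k) {
    sweep(matrix(stats::rnorm(n_per * 5, sd = 0.5), n_per, 5), 2,
          centers[k, ], "+")
  }))
  colnames(emb) <- paste0("f", 1:5)
  feats <- cbind(emb, energy = 0)
  ids <- sprintf("P%03d", seq_len(nrow(feats)))  # labels, not real peptides
  preds <- stats::runif(nrow(feats))
  truth <- rep(1:10, each = n_per)
  pol <- selection_policy(batch_size = 10, pool_size = nrow(feats), n_top = 0,
                          n_cluster_reps = 10, n_random = 0, seed = 3)
  got <- select_candidates(ids, preds, feats, pol)
  covered <- unique(truth[match(got$peptide, ids)])
  expect_gte(length(covered), 8L)
  expect_identical(anyDuplicated(got$peptide), 0L)
})

test_that("rounds grow the training table by the batch accounting and stay disjoint", {
  space <- small_space()
  x <- small_features(space)
  set.seed(101)
  truth <- exp(0.4 * scale(x[, "z3_4"] + 0.5 * x[, "ST5_2"])[, 1])
  oracle <- lookup_oracle(space, truth)
  set.seed(102)
  start <- sample(space, 158)
  initial <- oracle(start, round = 1)
  cfg <- tep_model_config(n_trees = 100, grid = data.frame(mtry = 52), seed = 5)
  pol <- selection_policy(seed = 7)
  camp <- run_campaign(initial, oracle, n_rounds = 3, policy = pol, config = cfg,
                       space = space, features = x, batch_sizes = c(50, 40))
  expect_identical(camp$history$n_train, c(158L, 208L, 248L))
  expect_identical(nrow(camp$history), 3L)
  expect_identical(anyDuplicated(camp$table$peptide), 0L)
  for (k in 1:2) {
    batch <- camp$rounds[[k]]$batch
    expect_identical(nrow(batch), c(50L, 40L)[k])
    trained_before <- camp$table$peptide[camp$table$round <= k]
    expect_length(intersect(batch$peptide, trained_before), 0L)
  }
  # final round trains and scores but selects nothing
  expect_null(camp$rounds[[3]]$batch)
  expect_identical(length(camp$predictions), length(space))

  camp2 <- run_campaign(initial, oracle, n_rounds = 3, policy = pol, config = cfg,
                        space = space, features = x, batch_sizes = c(50, 40))
  expect_identical(camp$history, camp2$history)
  expect_identical(camp$predictions, camp2$predictions)
})

test_that("a zero-size batch leaves the training table untouched", {
  space <- small_space()
  x <- small_features(space)
  truth <- stats::setNames(seq_along(space) / length(space), space)
  oracle <- lookup_oracle(space, unname(truth))
  initial <- oracle(space[1:20], round = 1)
  state <- list(table = initial, round = 1L, history = NULL)
  pol <- selection_policy()
  pol$batch_size <- 0L
  cfg <- tep_model_config(n_trees = 30, grid = data.frame(mtry = 13), seed = 2)
  st2 <- run_round(state, oracle, pol, cfg, space, x)
  expect_identical(st2$round, 2L)
  expect_identical(as.data.frame(st2$table), as.data.frame(initial))
  expect_identical(st2$history$n_train, 20L)
})

test_that("a measured-table oracle refuses unmeasured peptides", {
  t <- activity_table(c("SKIK", "AAAA"), relative_intensity = c(1, 0.4))
  attr(t, "normalized") <- TRUE
  f <- oracle_from_table(t)
  got <- f(c("AAAA", "SKIK"), round = 2)
  expect_equal(got$relative_intensity, c(0.4, 1))
  expect_identical(got$round, c(2L, 2L))
  expect_error(f("CCCC"), "CCCC")
})
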