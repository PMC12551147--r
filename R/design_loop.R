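#' Diversity-aware candidate selection policy
#'
#' A batch is assembled from three strata: the `n_top` highest-predicted
#' unseen peptides, one representative from each of `k_clusters` k-means
#' clusters computed in descriptor-feature space over the `pool_size`
#' highest-predicted peptides (the representative is the cluster's
#' highest-predicted member not already chosen), and `n_random` uniform draws
#' from the remaining unseen space. The strata must add up to `batch_size`.
#'
#' @param batch_size Total candidates per round (default 50).
#' @param pool_size Size of the top-prediction pool used for clustering
#'   (default 5000).
#' @param n_top,n_cluster_reps,n_random Stratum sizes (defaults 30/10/10).
#' @param k_clusters Number of k-means clusters (default `n_cluster_reps`).
#' @param seed Seed for clustering and random draws.
#' @return A list of class `selection_policy`.
#' @export
selection_policy <- function(batch_size = 50L, pool_size = 5000L,
                             n_top = 30L, n_cluster_reps = 10L,
                             n_random = 10L, k_clusters = n_cluster_reps,
                             seed = 1L) {
  stopifnot(n_top + n_cluster_reps + n_random == batch_size,
            pool_size >= batch_size, n_top >= 0, n_cluster_reps >= 0,
            n_random >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 pool_size = as.integer(pool_size),
                 n_top = as.integer(n_top),
                 n_cluster_reps = as.integer(n_cluster_reps),
                 n_random = as.integer(n_random),
                 k_clusters = as.integer(k_clusters),
                 seed = as.integer(seed)),
            class = "selection_policy")
}

#' Select a diverse candidate batch from full-space predictions
#'
#' @param peptides Character vector covering the design space.
#' @param predictions Predicted activity, aligned with `peptides`.
#' @param features Feature matrix over `peptides` (the `energy` column is
#'   excluded from the clustering embedding).
#' @param policy A [selection_policy()].
#' @param exclude Previously measured peptides, removed before any selection.
#' @return Data frame `peptide`, `predicted`, `stratum` of exactly
#'   `policy$batch_size` distinct candidates.
#' @export
select_candidates <- function(peptides, predictions, features,
                              policy = selection_policy(),
                              exclude = character(0)) {
  stopifnot(length(peptides) == length(predictions),
            nrow(features) == length(peptides))
  keep <- !peptides %in% exclude
  if (sum(keep) < policy$batch_size) {
    stop("design space exhausted: ", sum(keep), " unseen peptides left for a ",
         policy$batch_size, "-candidate batch")
  }
  peptides <- peptides[keep]
  predictions <- predictions[keep]
  features <- features[keep, , drop = FALSE]
  ord <- order(-predictions, peptides)  # ties broken lexicographically

  chosen <- character(0)
  stratum <- character(0)
  if (policy$n_top > 0) {
    chosen <- peptides[ord[seq_len(policy$n_top)]]
    stratum <- rep("top", policy$n_top)
  }
  if (policy$n_cluster_reps > 0) {
    pool_idx <- ord[seq_len(min(policy$pool_size, length(ord)))]
    emb <- features[pool_idx, setdiff(colnames(features), "energy"),
                    drop = FALSE]
    set.seed(derive_seed(policy$seed, 41L))
    km <- suppressWarnings(stats::kmeans(emb, centers = policy$k_clusters,
                                         nstart = 10L, iter.max = 50L))
    pool_pep <- peptides[pool_idx]
    pool_pred <- predictions[pool_idx]
    # per cluster, best-predicted member; clusters visited by descending best
    reps <- character(0)
    for (cl in unique(km$cluster[order(-pool_pred, pool_pep)])) {
      members <- which(km$cluster == cl)
      members <- members[order(-pool_pred[members], pool_pep[members])]
      pick <- pool_pep[members][!pool_pep[members] %in% c(chosen, reps)]
      if (length(pick)) reps <- c(reps, pick[1])
      if (length(reps) == policy$n_cluster_reps) break
    }
    # clusters exhausted (all members already chosen): fall back to next-best
    if (length(reps) < policy$n_cluster_reps) {
      extra <- peptides[ord][!peptides[ord] %in% c(chosen, reps)]
      reps <- c(reps, extra[seq_len(policy$n_cluster_reps - length(reps))])
    }
    chosen <- c(chosen, reps)
    stratum <- c(stratum, rep("cluster", policy$n_cluster_reps))
  }
  if (policy$n_random > 0) {
    remaining <- setdiff(peptides, chosen)
    set.seed(derive_seed(policy$seed, 43L))
    rnd <- sample(remaining, policy$n_random)
    chosen <- c(chosen, rnd)
    stratum <- c(stratum, rep("random", policy$n_random))
  }
  stopifnot(!anyDuplicated(chosen), length(chosen) == policy$batch_size)
  data.frame(peptide = chosen,
             predicted = predictions[match(chosen, peptides)],
             stratum = stratum, stringsAsFactors = FALSE)
}

#' Run one active-learning round
#'
#' Trains on the current table, scores the full space, selects a candidate
#' batch disjoint from everything already measured, queries the oracle, and
#' returns the augmented state. With `batch_size = 0` the state is unchanged
#' except for the round index and refreshed model.
#'
#' @param state List with elements `table` (an [activity_table()]),
#'   `round`, and optionally `history`.
#' @param oracle A measurement oracle: either a `tep_oracle` or a function
#'   `f(peptides, seed, round)` returning an `activity_table`.
#' @param policy A [selection_policy()].
#' @param config A [tep_model_config()].
#' @param space Character vector of all candidate peptides.
#' @param features Feature matrix over `space` (157 canonical columns).
#' @return Updated state with `model`, `batch`, `predictions` and an appended
#'   `history` row.
#' @export
run_round <- function(state, oracle, policy, config, space, features) {
  stopifnot(inherits(state$table, "activity_table"))
  idx <- match(state$table$peptide, space)
  if (anyNA(idx)) stop("training peptide(s) outside the design space: ",
                       paste(utils::head(state$table$peptide[is.na(idx)], 3),
                             collapse = ", "))
  round_seed <- derive_seed(config$seed, 100L + state$round)
  cfg <- config
  cfg$seed <- round_seed
  model <- tep_train(features[idx, , drop = FALSE],
                     state$table$relative_intensity, cfg)
  preds <- predict(model, features)
  new_round <- state$round + 1L
  batch <- NULL
  if (policy$batch_size > 0) {
    pol <- policy
    pol$seed <- derive_seed(policy$seed, 200L + state$round)
    batch <- select_candidates(space, preds, features, pol,
                               exclude = state$table$peptide)
    measured <- if (inherits(oracle, "tep_oracle")) {
      measure(oracle, batch$peptide, seed = derive_seed(config$seed, 300L + state$round),
              round = new_round)
    } else {
      oracle(batch$peptide, seed = derive_seed(config$seed, 300L + state$round),
             round = new_round)
    }
    stopifnot(inherits(measured, "activity_table"))
    tbl <- rbind(as.data.frame(state$table)[, c("peptide", "raw_intensity",
                                                "relative_intensity",
                                                "replicate_sd", "source", "round")],
                 as.data.frame(measured)[, c("peptide", "raw_intensity",
                                             "relative_intensity",
                                             "replicate_sd", "source", "round")])
    state$table <- as_activity_table(tbl, normalized = TRUE)
  }
  hist_row <- data.frame(round = state$round, n_train = model$n_train,
                         pooled_r = model$pooled_r,
                         pooled_rmse = model$pooled_rmse)
  state$history <- rbind(state$history, hist_row)
  state$model <- model
  state$predictions <- preds
  state$batch <- batch
  state$round <- new_round
  state
}

#' Run an iterative design campaign
#'
#' The full loop: train on the initial table, score all 160,000 tetrapeptides,
#' select a diverse batch, measure it with the oracle, augment the training
#' data, and repeat. Mirrors the three-round experimental campaign in which
#' 158 starting measurements grew by 50 and then 40 peptides.
#'
#' @param initial An initial normalized [activity_table()].
#' @param oracle Measurement oracle (see [run_round()]).
#' @param n_rounds Number of training rounds (>= 1; round 1 uses only the
#'   initial data, so `n_rounds - 1` batches are measured).
#' @param policy A [selection_policy()]; `batch_sizes` may override its
#'   batch size per round.
#' @param config A [tep_model_config()].
#' @param scales Descriptor scales (used if `features` is missing).
#' @param codon_table Codon table for the energy feature (idem).
#' @param energy_model [rna_energy_model()] for the energy feature (idem).
#' @param space,features Optionally precomputed design space and its feature
#'   matrix; computing the 160,000 x 157 matrix once and passing it in makes
#'   repeated campaigns much faster.
#' @param batch_sizes Optional integer vector of per-round batch sizes for
#'   rounds 2..n_rounds (default `policy$batch_size` each; e.g. `c(50, 40)`
#'   replicates the 158 -> 208 -> 248 accounting).
#' @return An object of class `tep_campaign`: `history` (per-round n and
#'   pooled metrics), `rounds` (list of round records with model, batch and
#'   top-100 logo), `final_model`, `table` (final training table),
#'   `space`, `predictions` (final full-space predictions).
#' @export
run_campaign <- function(initial, oracle, n_rounds = 3L,
                         policy = selection_policy(),
                         config = tep_model_config(),
                         scales = load_scales(),
                         codon_table = load_codon_table(),
                         energy_model = rna_energy_model(),
                         space = NULL, features = NULL,
                         batch_sizes = NULL) {
  stopifnot(n_rounds >= 1L)
  if (is.null(space)) space <- enumerate_tetrapeptides()
  if (is.null(features)) {
    features <- encode_table(space, scales,
                             energies = ensemble_energy(space, codon_table,
                                                        energy_model))
  }
  if (is.null(batch_sizes)) batch_sizes <- rep(policy$batch_size, max(n_rounds - 1L, 0L))
  batch_sizes <- rep_len(batch_sizes, max(n_rounds - 1L, 0L))
  state <- list(table = initial, round = 1L, history = NULL)
  rounds <- vector("list", n_rounds)
  for (k in seq_len(n_rounds)) {
    pol <- policy
    if (k < n_rounds) {
      bs <- as.integer(batch_sizes[k])
      if (bs != pol$batch_size) {
        # rescale strata proportionally, keeping the sum exact
        frac <- c(pol$n_top, pol$n_cluster_reps, pol$n_random) / pol$batch_size
        parts <- floor(frac * bs)
        parts[1] <- bs - sum(parts[-1])
        pol <- selection_policy(batch_size = bs, pool_size = pol$pool_size,
                                n_top = parts[1], n_cluster_reps = parts[2],
                                n_random = parts[3],
                                k_clusters = min(pol$k_clusters, max(parts[2], 1L)),
                                seed = pol$seed)
      }
    } else {
      pol$batch_size <- 0L  # final round: train and score only
    }
    state <- run_round(state, oracle, pol, config, space, features)
    top100 <- space[order(-state$predictions, space)][seq_len(min(100L, length(space)))]
    rounds[[k]] <- list(round = k, model = state$model, batch = state$batch,
                        top100 = top100,
                        pfm = position_frequency_matrix(top100))
  }
  out <- list(history = state$history, rounds = rounds,
              final_model = state$model, table = state$table,
              space = space, predictions = state$predictions)
  class(out) <- "tep_campaign"
  out
}

#' @export
print.tep_campaign <- function(x, ...) {
  cat("Iterative design campaign,", nrow(x$history), "rounds\n")
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tep_campaign <- function(object, ...) {
  print(object)
  last <- object$rounds[[length(object$rounds)]]
  cat("\nFinal-round top 10 features:\n")
  print(utils::head(last$model$importance, 10), row.names = FALSE)
  cat("\nTop 10 predicted peptides:\n")
  print(utils::head(last$top100, 10))
  invisible(object)
}

#' Pooled-r trajectory plot of a campaign
#'
#' @param x A `tep_campaign`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tep_campaign <- function(x, ...) {
  graphics::plot(x$history$round, x$history$pooled_r, type = "b",
                 xlab = "round", ylab = "pooled out-of-fold r",
                 ylim = range(0, 1, x$history$pooled_r), ...)
  invisible(x)
}

#' Wrap a measured activity table as a lookup oracle
#'
#' Turns a CSV/table of measured activities into the oracle interface used by
#' [run_campaign()], so laboratory measurements and the synthetic oracle are
#' interchangeable.
#'
#' @param table A normalized [activity_table()].
#' @return A function `f(peptides, seed, round)` returning the matching rows.
#' @export
oracle_from_table <- function(table) {
  stopifnot(inherits(table, "activity_table"))
  function(peptides, seed = 0L, round = 0L) {
    idx <- match(peptides, table$peptide)
    if (anyNA(idx)) {
      stop("no measurement available for: ",
           paste(utils::head(peptides[is.na(idx)], 5), collapse = ", "))
    }
    out <- table[idx, , drop = FALSE]
    out$round <- as.integer(round)
    as_activity_table(as.data.frame(out), normalized = TRUE)
  }
}
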