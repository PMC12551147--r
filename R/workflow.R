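config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    scales_dir = system.file("extdata", "scales", package = "teploop"),
    codon_table = system.file("extdata", "ecoli_codon_usage.tsv",
                              package = "teploop"),
    activity_file = NULL,
    n_rounds = 3L,
    batch_sizes = c(50L, 40L),
    model = list(algorithm = "random_forest", n_trees = 1000L, n_folds = 5L),
    policy = list(batch_size = 50L, pool_size = 5000L, n_top = 30L,
                  n_cluster_reps = 10L, n_random = 10L),
    landscape = list(sparsity = 0.05, weight_scale = 1, noise_sd = 0.1,
                     replicates = 3L, skew = 0.5, reference_quantile = 0.9,
                     bonus = list(residue = "D", position = 4L, effect = 0.6))
  )
}

#' Validate a campaign configuration file
#'
#' Reads a YAML (or JSON) campaign configuration, fills documented defaults,
#' rejects unknown keys, and checks that every referenced file exists. All
#' violations are reported in a single error message.
#'
#' @param file Path to a YAML/JSON configuration file, or a list.
#' @return The completed configuration list, of class `tep_campaign_config`.
#' @export
validate_config <- function(file) {
  cfg <- if (is.list(file)) file else yaml::read_yaml(file)
  if (is.null(cfg)) cfg <- list()
  defaults <- config_defaults()
  problems <- character(0)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  for (nm in c("model", "policy", "landscape")) {
    if (!is.null(cfg[[nm]])) {
      bad <- setdiff(names(cfg[[nm]]), names(defaults[[nm]]))
      if (length(bad)) {
        problems <- c(problems, paste0("unknown key(s) under ", nm, ": ",
                                       paste(bad, collapse = ", ")))
      }
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], cfg[[nm]])
    }
  }
  for (nm in setdiff(names(defaults), c("model", "policy", "landscape"))) {
    if (!is.null(cfg[[nm]])) defaults[[nm]] <- cfg[[nm]]
  }
  for (nm in c("scales_dir", "codon_table", "activity_file")) {
    p <- defaults[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      problems <- c(problems, paste0(nm, " does not exist: ", p))
    }
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  defaults$seed <- as.integer(defaults$seed)
  class(defaults) <- c("tep_campaign_config", "list")
  defaults
}

#' Write a configuration back to YAML
#'
#' @param config A `tep_campaign_config`.
#' @param file Output path.
#' @return Invisibly `file`; `validate_config(emit_config(cfg))` round-trips.
#' @export
emit_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' Self-contained demonstration campaign on a synthetic landscape
#'
#' Runs the full three-round loop end to end with no external input: builds
#' the default aspartate-at-position-4 landscape, measures a 158-peptide
#' starting set (157 random library peptides plus the SKIK reference), then
#' trains, scores the 160,000-peptide space, selects and "measures" batches of
#' 50 and 40, retraining each round. Writes plain-text artifacts (metrics
#' JSON, per-round logo and importance tables, predicted-versus-observed CSV),
#' each stamped with the seed.
#'
#' @param seed Global seed.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param config Optional `tep_campaign_config` (defaults are used otherwise).
#' @param n_trees,grid Model-size overrides passed to [tep_model_config()]
#'   (the defaults follow the main campaign configuration).
#' @return The `tep_campaign` object, invisibly, with the oracle and the
#'   written file list attached as attributes.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, config = validate_config(list()),
                     n_trees = config$model$n_trees, grid = NULL) {
  seed <- as.integer(seed)
  scales <- load_scales(config$scales_dir)
  codon_table <- load_codon_table(config$codon_table)
  space <- enumerate_tetrapeptides()
  features <- encode_table(space, scales,
                           energies = ensemble_energy(space, codon_table))
  spec <- landscape_spec(sparsity = config$landscape$sparsity,
                         weight_scale = config$landscape$weight_scale,
                         bonus = config$landscape$bonus,
                         skew = config$landscape$skew,
                         reference_quantile = config$landscape$reference_quantile,
                         noise_sd = config$landscape$noise_sd,
                         replicates = config$landscape$replicates,
                         seed = derive_seed(seed, 1L))
  oracle <- make_landscape(spec, scales, peptides = space, features = features)
  set.seed(derive_seed(seed, 2L))
  start <- unique(c(sample(space, 157L), "SKIK"))
  while (length(start) < 158L) {
    start <- unique(c(start, sample(space, 158L - length(start))))
  }
  initial <- measure(oracle, start, seed = derive_seed(seed, 3L), round = 1L)
  mcfg <- tep_model_config(algorithm = config$model$algorithm,
                           n_trees = n_trees, grid = grid,
                           n_folds = config$model$n_folds,
                           seed = derive_seed(seed, 4L))
  pol <- selection_policy(batch_size = config$policy$batch_size,
                          pool_size = config$policy$pool_size,
                          n_top = config$policy$n_top,
                          n_cluster_reps = config$policy$n_cluster_reps,
                          n_random = config$policy$n_random,
                          seed = derive_seed(seed, 5L))
  campaign <- run_campaign(initial, oracle, n_rounds = config$n_rounds,
                           policy = pol, config = mcfg,
                           space = space, features = features,
                           batch_sizes = config$batch_sizes)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    metrics <- list(seed = seed, history = campaign$history)
    f <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(metrics, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- f
    for (k in seq_along(campaign$rounds)) {
      rd <- campaign$rounds[[k]]
      f1 <- file.path(out_dir, sprintf("round%d_logo.tsv", k))
      write_matrix_tsv(rd$pfm, f1)
      f2 <- file.path(out_dir, sprintf("round%d_importance.csv", k))
      utils::write.csv(rd$model$importance, f2, row.names = FALSE)
      f3 <- file.path(out_dir, sprintf("round%d_pred_obs.csv", k))
      utils::write.csv(data.frame(seed = seed,
                                  predicted = rd$model$oof,
                                  observed = rd$model$y),
                       f3, row.names = FALSE)
      files <- c(files, f1, f2, f3)
    }
    f4 <- file.path(out_dir, "training_table.csv")
    write_activity_csv(campaign$table, f4)
    files <- c(files, f4)
  }
  attr(campaign, "oracle") <- oracle
  attr(campaign, "files") <- files
  attr(campaign, "seed") <- seed
  invisible(campaign)
}
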