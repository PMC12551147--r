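# Derive a module-level seed from a global one, kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 69069 + offset) %% 2147483647)
}

#' Specification of a synthetic activity landscape
#'
#' Describes the hidden ground truth that stands in for cell-free protein
#' synthesis measurements: a sparse linear score over the 156 amino-acid
#' descriptor features, an additive positional bonus (by default +0.6 score
#' units for aspartate at the fourth residue, mimicking the D-at-position-4
#' enrichment seen among strong translation enhancers), an exponential
#' right-skewing transform (so highly active peptides are rare), normalization
#' to the SKIK reference = 1, and a replicate noise model.
#'
#' @param sparsity Fraction of the 156 descriptor features with nonzero
#'   ground-truth weight (default 0.05, i.e. 8 features).
#' @param weight_scale SD of the nonzero weights.
#' @param bonus List with `residue`, `position` (1-4 over the variable
#'   residues) and `effect` (score units added after standardization).
#' @param skew Exponential skew strength applied to the standardized score.
#' @param reference Reference peptide (activity fixed to 1).
#' @param reference_quantile Quantile of the true-score distribution at which
#'   the reference peptide is pinned (default 0.9): the reference is a known
#'   strong enhancer, so most random tetrapeptides fall below it, matching
#'   the rarity of highly active peptides in the screen.
#' @param noise_sd Measurement SD per replicate, in relative units.
#' @param replicates Replicates per measurement.
#' @param seed Seed fixing the hidden weights.
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(sparsity = 0.05, weight_scale = 1,
                           bonus = list(residue = "D", position = 4, effect = 0.6),
                           skew = 0.5, reference = "SKIK",
                           reference_quantile = 0.9, noise_sd = 0.1,
                           replicates = 3L, seed = 1L) {
  stopifnot(sparsity > 0, sparsity <= 1, noise_sd >= 0, replicates >= 1L,
            skew > 0, reference_quantile > 0, reference_quantile < 1)
  structure(list(sparsity = sparsity, weight_scale = weight_scale,
                 bonus = bonus, skew = skew, reference = reference,
                 reference_quantile = reference_quantile,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Build a synthetic activity oracle over the tetrapeptide space
#'
#' Constructs the hidden true-activity function
#' `a(p) = exp(skew * (z(p) + bonus))`, where `z` is the standardized sparse
#' linear score over the descriptor features, normalized so that
#' `a(reference) = 1`. The oracle is fully determined by `(spec, scales)`.
#'
#' @param spec A [landscape_spec()].
#' @param scales A `descriptor_scales` object.
#' @param peptides The design space (default: all 160,000 tetrapeptides).
#' @param features Optional precomputed feature matrix over `peptides`
#'   (157 canonical columns); the energy column is ignored by the ground
#'   truth and may be zero.
#' @return A list of class `tep_oracle` with `true` (named activity vector
#'   over the space), `spec`, and `measure(peptides, seed, round)`.
#' @export
make_landscape <- function(spec = landscape_spec(), scales = load_scales(),
                           peptides = enumerate_tetrapeptides(),
                           features = NULL) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (is.null(features)) {
    features <- encode_table(peptides, scales,
                             energies = numeric(length(peptides)))
  }
  stopifnot(nrow(features) == length(peptides))
  desc <- features[, setdiff(colnames(features), "energy"), drop = FALSE]
  n_active <- max(1L, round(spec$sparsity * ncol(desc)))
  set.seed(derive_seed(spec$seed, 11L))
  # Background weights avoid position-specific features of the bonus position,
  # so the injected positional effect is the only signal tied to it and
  # recovery of that signature is attributable to the bonus alone.
  eligible <- seq_len(ncol(desc))
  if (!is.null(spec$bonus)) {
    eligible <- which(!grepl(paste0("_", spec$bonus$position, "$"),
                             colnames(desc)))
  }
  active <- sample(eligible, n_active)
  w <- stats::rnorm(n_active, sd = spec$weight_scale)
  score <- as.numeric(desc[, active, drop = FALSE] %*% w)
  score <- (score - mean(score)) / stats::sd(score)
  # Soft-saturate the linear part (scale: 3 SD) so the landscape shows
  # diminishing returns and no single descriptor direction can dominate the
  # extreme tail; this keeps planted positional effects visible among the
  # most active peptides.
  score <- score / sqrt(1 + (score / 3)^2)
  if (!is.null(spec$bonus) && spec$bonus$effect != 0) {
    hit <- substr(peptides, spec$bonus$position, spec$bonus$position) ==
      spec$bonus$residue
    score[hit] <- score[hit] + spec$bonus$effect
  }
  ref_i <- match(spec$reference, peptides)
  if (is.na(ref_i)) stop("reference peptide not in the design space")
  # Pin the reference at an upper quantile of the score distribution: it is a
  # known strong enhancer, so most random tetrapeptides score below it.
  score[ref_i] <- stats::quantile(score, spec$reference_quantile, names = FALSE)
  a <- exp(spec$skew * score)
  if (a[ref_i] <= 0) stop("reference activity is zero under this spec")
  a <- a / a[ref_i]
  names(a) <- peptides
  oracle <- list(true = a, spec = spec,
                 weights = stats::setNames(w, colnames(desc)[active]))
  oracle$measure <- function(peptides, seed = 0L, round = 0L) {
    measure(oracle, peptides, seed = seed, round = round)
  }
  class(oracle) <- "tep_oracle"
  oracle
}

#' @export
print.tep_oracle <- function(x, ...) {
  cat("Synthetic activity oracle over", length(x$true), "peptides;",
      "reference", x$spec$reference, "= 1;",
      "noise SD", x$spec$noise_sd, "x", x$spec$replicates, "replicates\n")
  invisible(x)
}

#' Simulate noisy activity measurements from an oracle
#'
#' Draws `spec$replicates` replicate measurements per peptide (true activity
#' plus Gaussian noise), reports their mean (truncated at zero) and standard
#' deviation, mimicking triplicate fluorescence assays.
#'
#' @param oracle A `tep_oracle`.
#' @param peptides Peptides to measure.
#' @param seed Seed for the measurement noise.
#' @param round Round label stored in the result.
#' @return A normalized [activity_table()] with `source = "synthetic"`.
#' @export
measure <- function(oracle, peptides, seed = 0L, round = 0L) {
  stopifnot(inherits(oracle, "tep_oracle"))
  truth <- oracle$true[peptides]
  if (anyNA(truth)) {
    stop("oracle has no activity for peptide(s): ",
         paste(utils::head(peptides[is.na(truth)], 5), collapse = ", "))
  }
  set.seed(derive_seed(seed, 23L))
  k <- oracle$spec$replicates
  reps <- matrix(stats::rnorm(length(peptides) * k, mean = rep(truth, each = k),
                              sd = oracle$spec$noise_sd),
                 nrow = k)
  m <- pmax(colMeans(reps), 0)
  s <- if (k > 1) apply(reps, 2, stats::sd) else rep(NA_real_, length(peptides))
  as_activity_table(
    data.frame(peptide = peptides, raw_intensity = NA_real_,
               relative_intensity = m, replicate_sd = s,
               source = "synthetic", round = as.integer(round),
               stringsAsFactors = FALSE),
    normalized = TRUE)
}

#' Simulate NNK amplicon reads for a peptide pool
#'
#' Emits single-end reads (default 81 bp) of the library amplicon: the
#' upstream primer region ending in the start codon, an NNK-conformant
#' 12-nt randomized region encoding the sampled peptide (codons drawn
#' uniformly among the NNK codons of each residue), and the downstream
#' SecM arrest-peptide context, padded with a fixed synthetic filler to the
#' 161-bp amplicon length. Optional uniform substitution errors.
#'
#' @param pool Character vector of peptides.
#' @param abundance Relative abundances (default uniform).
#' @param n_reads Number of reads.
#' @param read_len Read length (default 81).
#' @param error_rate Per-base substitution probability.
#' @param seed Seed.
#' @param file Optional FASTQ output path; plain or gzip by extension.
#' @return Invisibly a data frame `id`, `sequence`; written as FASTQ when
#'   `file` is given.
#' @export
simulate_reads <- function(pool, abundance = NULL, n_reads = 1000L,
                           read_len = 81L, error_rate = 0, seed = 1L,
                           file = NULL) {
  stopifnot(length(pool) >= 1L, n_reads >= 0L, error_rate >= 0, error_rate < 1)
  check_peptides(pool)
  if (is.null(abundance)) abundance <- rep(1, length(pool))
  stopifnot(length(abundance) == length(pool), all(abundance > 0))
  up <- "AAGAAGGAGATATACATATG"      # forward amplicon primer, ends in ATG
  down <- paste0(ORF_DOWNSTREAM, "ATAAG")
  filler <- paste(rep("GCATTCGGTACTGAGCTTGACGTA", 5), collapse = "")  # synthetic pad
  nnk <- nnk_codon_set()
  codons_by_aa <- split(names(nnk$translation)[nnk$translation != "*"],
                        nnk$translation[nnk$translation != "*"])
  set.seed(derive_seed(seed, 37L))
  if (n_reads == 0L) {
    reads <- data.frame(id = character(0), sequence = character(0))
  } else {
    picks <- sample(length(pool), n_reads, replace = TRUE,
                    prob = abundance / sum(abundance))
    res <- strsplit(pool[picks], "")
    regions <- vapply(res, function(r) {
      paste(vapply(r, function(a) {
        cs <- codons_by_aa[[a]]
        cs[sample.int(length(cs), 1L)]
      }, character(1)), collapse = "")
    }, character(1))
    amplicon <- paste0(up, regions, down)
    amplicon <- substr(paste0(amplicon, filler), 1L, 161L)
    seqs <- substr(amplicon, 1L, read_len)
    if (error_rate > 0) {
      chars <- strsplit(seqs, "")
      seqs <- vapply(chars, function(cc) {
        hit <- stats::runif(length(cc)) < error_rate
        if (any(hit)) {
          cc[hit] <- vapply(cc[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, character(1))
        }
        paste(cc, collapse = "")
      }, character(1))
    }
    reads <- data.frame(id = sprintf("sim_%06d", seq_len(n_reads)),
                        sequence = seqs, stringsAsFactors = FALSE)
  }
  if (!is.null(file)) {
    x <- Biostrings::DNAStringSet(reads$sequence)
    names(x) <- reads$id
    Biostrings::writeXStringSet(
      x, file, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(reads$sequence))),
      compress = grepl("\\.gz$", file))
  }
  invisible(reads)
}
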