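# Cache of computed ensemble energies, keyed by model hash + DNA string.
.energy_cache <- new.env(parent = emptyenv())

#' A simple nucleic-acid secondary-structure energy model
#'
#' Defines the energy model of the built-in partition-function backend:
#' one free energy per pair type (G-C, A-U, G-U wobble, in kcal/mol), an
#' optional stacking bonus added whenever a pair sits directly inside another,
#' a minimum hairpin-loop size, and the thermal energy RT. The defaults
#' (G-C -3, A-U -2, G-U -1 kcal/mol, no stacking, loop >= 3 nt,
#' RT = 0.616 kcal/mol i.e. 310 K) give a consistent, documented proxy for
#' the ensemble free-energy feature; full nearest-neighbour parameter sets
#' are deliberately out of scope and external values can be supplied through
#' the `precomputed` backend of [ensemble_energy()].
#'
#' @param e_gc,e_au,e_gu Pair free energies in kcal/mol (must be finite).
#' @param e_stack Additional free energy per stacked pair (kcal/mol).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop (>= 3).
#' @param rt Thermal energy RT in kcal/mol (> 0).
#' @param allow_gu Allow G-U wobble pairs?
#' @return A list of class `rna_energy_model`.
#' @export
rna_energy_model <- function(e_gc = -3, e_au = -2, e_gu = -1, e_stack = 0,
                             min_loop = 3L, rt = 0.616, allow_gu = TRUE) {
  stopifnot(is.finite(e_gc), is.finite(e_au), is.finite(e_gu),
            is.finite(e_stack), min_loop >= 3L, rt > 0)
  m <- list(e_gc = e_gc, e_au = e_au, e_gu = e_gu, e_stack = e_stack,
            min_loop = as.integer(min_loop), rt = rt, allow_gu = allow_gu)
  class(m) <- "rna_energy_model"
  m
}

model_key <- function(m) {
  paste(format(c(m$e_gc, m$e_au, m$e_gu, m$e_stack, m$rt), digits = 17),
        m$min_loop, m$allow_gu, collapse = "|")
}

#' Partition function over pseudoknot-free secondary structures
#'
#' Computes `Z = sum over structures of exp(-E/RT)` by a McCaskill-style
#' interval dynamic programme. The open chain contributes 1, so `Z >= 1`
#' always. `T` is read as `U` (coding-strand DNA is transcribed in place).
#'
#' @param seqs Character vector of RNA/DNA sequences over A, C, G, U/T
#'   (each of length <= 200).
#' @param model An [rna_energy_model()].
#' @return Numeric vector of partition-function values, one per sequence.
#' @examples
#' partition_function("AAAAAAAAAA")  # 1: no complementary pairs
#' @export
partition_function <- function(seqs, model = rna_energy_model()) {
  stopifnot(inherits(model, "rna_energy_model"))
  if (length(seqs) == 0L) return(numeric(0))
  if (any(nchar(seqs) > 200L)) stop("sequence longer than 200 nt")
  partition_function_cpp(seqs, model$e_gc, model$e_au, model$e_gu,
                         model$e_stack, model$min_loop, model$rt,
                         model$allow_gu)
}

# Boltzmann pair factor lookup used by the brute-force oracle.
pair_energy_fun <- function(model) {
  function(a, b) {
    ab <- paste0(a, b)
    if (ab %in% c("GC", "CG")) return(model$e_gc)
    if (ab %in% c("AU", "UA")) return(model$e_au)
    if (model$allow_gu && ab %in% c("GU", "UG")) return(model$e_gu)
    NA_real_
  }
}

#' Brute-force partition function (test oracle)
#'
#' Exhaustively enumerates every pseudoknot-free set of base pairs (minimum
#' hairpin loop respected) and sums the Boltzmann factors directly. Intended
#' as an independent oracle for [partition_function()] on short sequences.
#'
#' @param seq A single sequence of length <= 20.
#' @inheritParams partition_function
#' @return The partition-function value.
#' @export
brute_force_partition <- function(seq, model = rna_energy_model()) {
  stopifnot(length(seq) == 1L)
  if (nchar(seq) > 20L) stop("brute-force oracle limited to length <= 20")
  bases <- chartr("Tt", "Uu", toupper(strsplit(seq, "")[[1]]))
  if (!all(bases %in% c("A", "C", "G", "U"))) stop("invalid character in sequence")
  n <- length(bases)
  ef <- pair_energy_fun(model)
  # All structures on [i, j] as lists of pair matrices (2-column: i, j).
  structures <- function(i, j) {
    if (j - i < model$min_loop + 1L) return(list(matrix(integer(0), 0, 2)))
    out <- structures(i + 1L, j)  # i unpaired
    for (k in seq.int(i + model$min_loop + 1L, j)) {
      if (is.na(ef(bases[i], bases[k]))) next
      left <- structures(i + 1L, k - 1L)
      right <- if (k < j) structures(k + 1L, j) else list(matrix(integer(0), 0, 2))
      for (l in left) for (r in right) {
        out[[length(out) + 1L]] <- rbind(c(i, k), l, r)
      }
    }
    out
  }
  ss <- structures(1L, n)
  z <- 0
  for (s in ss) {
    e <- 0
    if (nrow(s) > 0) {
      e <- sum(mapply(function(a, b) ef(bases[a], bases[b]), s[, 1], s[, 2]))
      if (model$e_stack != 0 && nrow(s) > 1) {
        key <- paste(s[, 1], s[, 2])
        stacked <- sum(paste(s[, 1] + 1L, s[, 2] - 1L) %in% key)
        e <- e + model$e_stack * stacked
      }
    }
    z <- z + exp(-e / model$rt)
  }
  z
}

#' Ensemble free energy of the 11-codon ORF prefix
#'
#' The `energy` feature: `-RT * ln Z` (kcal/mol, always <= 0) of the 33-nt
#' ORF prefix built by [build_orf_prefix()]. Results are cached per
#' (DNA, model) so repeated encodings are cheap.
#'
#' @inheritParams build_orf_prefix
#' @param model An [rna_energy_model()].
#' @param backend `"builtin"` (partition-function DP) or `"precomputed"`
#'   (look energies up in a user-supplied table, e.g. from an external
#'   folding program).
#' @param precomputed For the `precomputed` backend: a data frame with
#'   columns `dna` and `energy` covering every ORF prefix queried.
#' @param cache Use the package-level energy cache?
#' @return Numeric vector of ensemble free energies (kcal/mol), one per
#'   peptide.
#' @export
ensemble_energy <- function(peptides, codon_table = load_codon_table(),
                            model = rna_energy_model(),
                            backend = c("builtin", "precomputed"),
                            precomputed = NULL, dna_override = NULL,
                            cache = TRUE) {
  backend <- match.arg(backend)
  dna <- build_orf_prefix(peptides, codon_table, dna_override = dna_override)
  if (backend == "precomputed") {
    if (is.null(precomputed) || !all(c("dna", "energy") %in% names(precomputed))) {
      stop("precomputed backend needs a data frame with columns 'dna' and ",
           "'energy'; use backend = \"builtin\" to fall back to the ",
           "built-in partition function")
    }
    idx <- match(dna, precomputed$dna)
    if (anyNA(idx)) {
      stop("precomputed table lacks ", sum(is.na(idx)), " ORF prefix(es), ",
           "e.g. ", dna[which(is.na(idx))[1]], "; recompute the table or ",
           "use backend = \"builtin\"")
    }
    return(as.numeric(precomputed$energy[idx]))
  }
  key_prefix <- model_key(model)
  keys <- paste0(key_prefix, ":", dna)
  out <- rep(NA_real_, length(dna))
  if (cache) {
    hit <- vapply(keys, exists, logical(1), envir = .energy_cache,
                  inherits = FALSE)
    out[hit] <- unlist(mget(keys[hit], envir = .energy_cache), use.names = FALSE)
  } else {
    hit <- rep(FALSE, length(dna))
  }
  if (any(!hit)) {
    todo <- which(!hit)
    uq <- !duplicated(dna[todo])
    z <- partition_function(dna[todo][uq], model)
    e <- -model$rt * log(z)
    names(e) <- dna[todo][uq]
    out[todo] <- e[dna[todo]]
    if (cache) {
      for (i in todo[uq]) assign(keys[i], out[i], envir = .energy_cache)
    }
  }
  out
}

#' Clear the ensemble-energy cache
#' @return Invisibly `NULL`.
#' @export
clear_energy_cache <- function() {
  rm(list = ls(.energy_cache), envir = .energy_cache)
  invisible(NULL)
}
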