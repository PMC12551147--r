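# Fixed downstream context of the randomized region: the first six SecM
# arrest-peptide codons (F-S-T-P-V-W), 18 nt, taken verbatim from the
# library-construction primer.
ORF_DOWNSTREAM <- "TTCAGCACGCCCGTCTGG"

#' The 20-letter amino-acid alphabet
#'
#' One-letter codes of the 20 standard amino acids in alphabetical order.
#' This ordering fixes the enumeration order of the design space and all
#' downstream tie-breaking.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Enumerate the tetrapeptide design space
#'
#' Generates every peptide of length `length` over `alphabet` exactly once,
#' in lexicographic order. With the defaults this is the full design space of
#' 20^4 = 160,000 tetrapeptides.
#'
#' @param alphabet Character vector of residue one-letter codes.
#' @param length Peptide length (default 4).
#' @return Character vector of peptides in lexicographic order.
#' @examples
#' length(enumerate_tetrapeptides())  # 160000
#' enumerate_tetrapeptides(c("A", "D"), 2)
#' @export
enumerate_tetrapeptides <- function(alphabet = aa_alphabet(), length = 4L) {
  stopifnot(length >= 1L, length(alphabet) >= 1L, !anyDuplicated(alphabet))
  grids <- rep(list(alphabet), length)
  # expand.grid varies the first factor fastest; reverse so position 1 is the
  # slowest-moving digit and the result is lexicographically sorted.
  g <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  do.call(paste0, rev(g))
}

#' Validate peptide sequences
#'
#' @param peptides Character vector.
#' @param length Required length (default 4).
#' @return Invisibly `peptides`; errors on invalid input.
#' @export
check_peptides <- function(peptides, length = 4L) {
  if (length(peptides) == 0L) return(invisible(peptides))
  bad_len <- nchar(peptides) != length
  if (any(bad_len)) {
    stop("peptide(s) not of length ", length, ": ",
         paste(utils::head(peptides[bad_len], 5), collapse = ", "))
  }
  ok <- grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"), peptides)
  if (!all(ok)) {
    stop("peptide(s) contain invalid residues: ",
         paste(utils::head(peptides[!ok], 5), collapse = ", "))
  }
  invisible(peptides)
}

#' Translate DNA codons with the standard genetic code
#'
#' @param dna Character vector of DNA sequences whose lengths are multiples
#'   of 3.
#' @return Character vector of amino-acid sequences; stop codons appear
#'   as `*`.
#' @export
translate_dna <- function(dna) {
  if (length(dna) == 0L) return(character(0))
  if (any(nchar(dna) %% 3L != 0L)) {
    stop("sequence length is not a multiple of 3")
  }
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     no.init.codon = TRUE))
}

#' The NNK degenerate codon set
#'
#' Enumerates the 32 codons with any base at positions 1-2 and G or T at
#' position 3, the degeneracy scheme used to build the randomized tetrapeptide
#' library. Reports which amino acids the set encodes and which stop codons it
#' contains (TAG only).
#'
#' @return A list of class `nnk_set` with elements `codons` (32 codons),
#'   `amino_acids` (encoded residues), `stop_codons`, and `translation`
#'   (named character vector codon -> residue/`*`).
#' @export
nnk_codon_set <- function() {
  n <- c("A", "C", "G", "T")
  k <- c("G", "T")
  codons <- as.vector(outer(outer(n, n, paste0), k, paste0))
  codons <- sort(codons)
  tr <- translate_dna(codons)
  names(tr) <- codons
  out <- list(
    codons = codons,
    amino_acids = sort(unique(tr[tr != "*"])),
    stop_codons = codons[tr == "*"],
    translation = tr
  )
  class(out) <- "nnk_set"
  out
}

#' @export
print.nnk_set <- function(x, ...) {
  cat("NNK codon set:", length(x$codons), "codons,",
      length(x$amino_acids), "amino acids covered,",
      "stop codon(s):", paste(x$stop_codons, collapse = ", "), "\n")
  invisible(x)
}

#' Load a codon-usage table
#'
#' Reads a codon-usage table (codon, amino acid, frequency per 1000) and
#' computes the relative adaptiveness weight of each codon, `w = freq / max
#' freq among synonymous codons`, as used by the codon adaptation index.
#' The bundled default is an E. coli K-12 table.
#'
#' @param file Path to a TSV with columns `codon`, `aa`, `per1000`.
#' @return A data frame of class `codon_table` with columns `codon`, `aa`,
#'   `per1000`, `weight`.
#' @export
load_codon_table <- function(file = system.file("extdata", "ecoli_codon_usage.tsv",
                                                package = "teploop")) {
  t <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "aa", "per1000") %in% names(t)))
  if (!all(grepl("^[ACGT]{3}$", t$codon))) stop("invalid codon in table")
  if (anyDuplicated(t$codon)) stop("duplicated codon in table")
  missing_aa <- setdiff(aa_alphabet(), t$aa)
  if (length(missing_aa)) {
    stop("codon table lacks amino acid(s): ", paste(missing_aa, collapse = ", "))
  }
  mistranslated <- translate_dna(t$codon) != t$aa
  if (any(mistranslated)) {
    stop("codon/amino-acid mismatch: ", paste(t$codon[mistranslated], collapse = ", "))
  }
  t$weight <- t$per1000 / stats::ave(t$per1000, t$aa, FUN = max)
  class(t) <- c("codon_table", "data.frame")
  t
}

#' Reverse-translate a peptide with CAI-optimal codons
#'
#' Maps each residue to its maximum-weight (most adaptive) codon in the
#' usage table. Ties are broken alphabetically by codon, so the mapping is
#' deterministic.
#'
#' @param peptides Character vector of peptides.
#' @param codon_table A `codon_table` from [load_codon_table()].
#' @return Character vector of DNA sequences (3 nt per residue).
#' @examples
#' ct <- load_codon_table()
#' reverse_translate_cai("SKIK", ct)
#' @export
reverse_translate_cai <- function(peptides, codon_table = load_codon_table()) {
  check_peptides(peptides, length = unique(nchar(peptides)))
  ord <- order(codon_table$aa, -codon_table$weight, codon_table$codon)
  best <- codon_table[ord, ][!duplicated(codon_table$aa[ord]), ]
  opt <- stats::setNames(best$codon, best$aa)
  res <- strsplit(peptides, "")
  vapply(res, function(r) {
    if (any(!r %in% names(opt))) {
      stop("no codon available for residue(s): ",
           paste(setdiff(r, names(opt)), collapse = ", "))
    }
    paste0(opt[r], collapse = "")
  }, character(1))
}

#' Build the 11-codon ORF prefix used for the mRNA energy feature
#'
#' Concatenates the start codon, the CAI-optimal reverse translation of the
#' tetrapeptide, and the fixed 18-nt downstream context (the first six SecM
#' arrest-peptide codons, F-S-T-P-V-W), yielding the 33-nt / 11-codon prefix
#' whose ensemble free energy is used as the `energy` feature.
#'
#' @inheritParams reverse_translate_cai
#' @param dna_override Optional 12-nt DNA sequences to use for the randomized
#'   region instead of CAI reverse translation (e.g. NNK codons actually
#'   observed by sequencing); must translate to `peptides`.
#' @return Character vector of 33-nt DNA sequences.
#' @export
build_orf_prefix <- function(peptides, codon_table = load_codon_table(),
                             dna_override = NULL) {
  check_peptides(peptides)
  if (is.null(dna_override)) {
    region <- reverse_translate_cai(peptides, codon_table)
  } else {
    stopifnot(length(dna_override) == length(peptides),
              all(nchar(dna_override) == 12L))
    if (!all(translate_dna(dna_override) == peptides)) {
      stop("dna_override does not translate to the given peptides")
    }
    region <- dna_override
  }
  paste0("ATG", region, ORF_DOWNSTREAM)
}

#' Write peptides as one-sequence-per-line text or protein FASTA
#'
#' @param peptides Character vector of peptides.
#' @param file Output path.
#' @param format `"txt"` (one per line) or `"fasta"`.
#' @return Invisibly `file`.
#' @export
write_peptides <- function(peptides, file, format = c("txt", "fasta")) {
  format <- match.arg(format)
  if (format == "txt") {
    writeLines(peptides, file)
  } else {
    x <- Biostrings::AAStringSet(peptides)
    names(x) <- if (is.null(names(peptides))) peptides else names(peptides)
    Biostrings::writeXStringSet(x, file)
  }
  invisible(file)
}

#' Read peptides from text or FASTA
#'
#' @param file Input path; FASTA is detected from a leading `>`.
#' @return Character vector of peptides.
#' @export
read_peptides <- function(file) {
  first <- readLines(file, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    as.character(Biostrings::readAAStringSet(file))
  } else {
    x <- trimws(readLines(file))
    x[nzchar(x)]
  }
}
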