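#' Read single-end amplicon reads from FASTQ
#'
#' @param file FASTQ path (optionally gzip-compressed).
#' @return A data frame with columns `id` and `sequence`.
#' @export
read_fastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  data.frame(id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract the randomized 12-nt region from amplicon reads
#'
#' Finds the upstream anchor (default `CATATG`, ending in the start codon),
#' takes the following 12 nt, and requires the downstream anchor (default
#' `TTCAGCACG`, the start of the SecM arrest-peptide context) immediately
#' after it. Failures are reported as statuses, never errors:
#' `flank_missing`, `bad_length` (anchors found but not 12 nt apart),
#' `ambiguous_base`, or `ok`.
#'
#' @param reads Data frame from [read_fastq()] or a character vector of read
#'   sequences.
#' @param up_flank,down_flank Anchor sequences.
#' @param max_mismatch Allowed mismatches per anchor (0 = exact, the default;
#'   1 enables tolerant matching).
#' @return A data frame with columns `id`, `status`, `dna_region`, `peptide`.
#' @export
extract_randomized_region <- function(reads, up_flank = "CATATG",
                                      down_flank = "TTCAGCACG",
                                      max_mismatch = 0L) {
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("read", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  }
  n <- nrow(reads)
  status <- rep("flank_missing", n)
  region <- rep(NA_character_, n)
  seqs <- toupper(reads$sequence)
  if (max_mismatch == 0L) {
    up_end <- regexpr(up_flank, seqs, fixed = TRUE)
    up_end <- ifelse(up_end > 0, up_end + nchar(up_flank) - 1L, NA_integer_)
    down_start <- rep(NA_integer_, n)
    has_up <- !is.na(up_end)
    if (any(has_up)) {
      # search the downstream anchor only after the upstream one
      tail_part <- substr(seqs[has_up], up_end[has_up] + 1L, nchar(seqs[has_up]))
      d <- regexpr(down_flank, tail_part, fixed = TRUE)
      down_start[has_up] <- ifelse(d > 0, up_end[has_up] + d, NA_integer_)
    }
  } else {
    sset <- Biostrings::DNAStringSet(seqs)
    up_hits <- Biostrings::vmatchPattern(up_flank, sset, max.mismatch = max_mismatch)
    down_hits <- Biostrings::vmatchPattern(down_flank, sset, max.mismatch = max_mismatch)
    up_end <- vapply(seq_len(n), function(i) {
      e <- BiocGenerics::end(up_hits[[i]])
      if (length(e)) min(e) else NA_integer_
    }, integer(1))
    down_start <- vapply(seq_len(n), function(i) {
      s <- BiocGenerics::start(down_hits[[i]])
      s <- s[s > ifelse(is.na(up_end[i]), 0L, up_end[i])]
      if (length(s)) min(s) else NA_integer_
    }, integer(1))
  }
  found <- !is.na(up_end) & !is.na(down_start)
  gap <- down_start - up_end - 1L
  bad_len <- found & gap != 12L
  status[bad_len] <- "bad_length"
  ok <- found & gap == 12L
  region[ok] <- substr(seqs[ok], up_end[ok] + 1L, down_start[ok] - 1L)
  amb <- ok & !grepl("^[ACGT]{12}$", region)
  status[amb] <- "ambiguous_base"
  ok <- ok & !amb
  status[ok] <- "ok"
  out <- data.frame(id = reads$id, status = status, dna_region = region,
                    peptide = NA_character_, stringsAsFactors = FALSE)
  if (any(ok)) {
    tr <- translate_region(out$dna_region[ok])
    stopped <- is.na(tr)
    out$status[ok][stopped] <- "contains_stop"
    out$peptide[ok][!stopped] <- tr[!stopped]
  }
  out$dna_region[out$status %in% c("flank_missing")] <- NA_character_
  out
}

#' Translate a 12-nt randomized region to a tetrapeptide
#'
#' @param dna Character vector of DNA regions; lengths must be multiples
#'   of 3.
#' @return Character vector of peptides; `NA` where a stop codon occurs.
#' @export
translate_region <- function(dna) {
  if (any(nchar(dna) %% 3L != 0L)) {
    stop("region length is not a multiple of 3")
  }
  aa <- translate_dna(dna)
  ifelse(grepl("*", aa, fixed = TRUE), NA_character_, aa)
}

#' Tally extracted peptides
#'
#' Counts reads per recovered peptide (sorted by descending count, then
#' lexicographically) and summarizes extraction failures. Counts plus
#' failures always add up to the number of input reads.
#'
#' @param results Data frame from [extract_randomized_region()].
#' @return A list of class `peptide_tally` with `counts` (data frame
#'   `peptide`, `reads`) and `failures` (named integer vector by status).
#' @export
tally_peptides <- function(results) {
  ok <- results$status == "ok"
  counts <- table(results$peptide[ok])
  cd <- data.frame(peptide = as.character(names(counts)),
                   reads = as.integer(counts), stringsAsFactors = FALSE)
  cd <- cd[order(-cd$reads, cd$peptide), , drop = FALSE]
  rownames(cd) <- NULL
  fail <- table(results$status[!ok])
  out <- list(counts = cd,
              failures = stats::setNames(as.integer(fail), names(fail)),
              n_reads = nrow(results))
  class(out) <- "peptide_tally"
  out
}

#' @export
print.peptide_tally <- function(x, ...) {
  cat("Peptide tally:", nrow(x$counts), "distinct peptides from",
      x$n_reads, "reads\n")
  if (length(x$failures)) {
    cat("Failures:", paste(names(x$failures), x$failures, sep = "=",
                           collapse = ", "), "\n")
  }
  print(utils::head(x$counts, 10))
  invisible(x)
}

#' Write a peptide tally as TSV
#' @param x A `peptide_tally`.
#' @param file Path.
#' @return Invisibly `file`.
#' @export
write_tally <- function(x, file) {
  utils::write.table(x$counts, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
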