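#' Load the amino-acid descriptor scales
#'
#' Reads the four bundled descriptor tables: Z-scale (5 components), T-scale
#' (5), ST-scale (8) and VHSE-scale (8), 26 components per residue in total.
#' Each table is validated: exactly the 20 standard residues, consistent
#' component counts, finite values.
#'
#' @param dir Directory holding `zscale.tsv`, `tscale.tsv`, `stscale.tsv`,
#'   `vhse.tsv` (defaults to the copies shipped with the package).
#' @return A named list of class `descriptor_scales`; each element is a
#'   20 x k numeric matrix with residue rownames and component colnames.
#' @examples
#' sc <- load_scales()
#' sapply(sc, ncol)  # 5 5 8 8
#' @export
load_scales <- function(dir = system.file("extdata", "scales", package = "teploop")) {
  expected <- c(zscale = 5L, tscale = 5L, stscale = 8L, vhse = 8L)
  scales <- lapply(names(expected), function(nm) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(f)) stop("missing scale file: ", f)
    t <- utils::read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
    if (names(t)[1] != "aa") stop(nm, ": first column must be 'aa'")
    m <- as.matrix(t[, -1, drop = FALSE])
    rownames(m) <- t$aa
    if (ncol(m) != expected[[nm]]) {
      stop(nm, ": expected ", expected[[nm]], " components, found ", ncol(m))
    }
    missing_aa <- setdiff(aa_alphabet(), rownames(m))
    extra_aa <- setdiff(rownames(m), aa_alphabet())
    if (length(missing_aa)) stop(nm, ": missing residue(s) ", paste(missing_aa, collapse = ", "))
    if (length(extra_aa)) stop(nm, ": unknown residue(s) ", paste(extra_aa, collapse = ", "))
    if (anyDuplicated(rownames(m))) stop(nm, ": duplicated residue rows")
    if (!all(is.finite(m))) stop(nm, ": non-finite descriptor value")
    m[aa_alphabet(), , drop = FALSE]
  })
  names(scales) <- names(expected)
  class(scales) <- "descriptor_scales"
  scales
}

#' @export
print.descriptor_scales <- function(x, ...) {
  cat("Descriptor scales:",
      paste(sprintf("%s (%d)", names(x), vapply(x, ncol, 0L)), collapse = ", "),
      "-", sum(vapply(x, ncol, 0L)), "components per residue\n")
  invisible(x)
}

# 20 x 26 matrix of all components, residue rows.
scale_block <- function(scales) {
  do.call(cbind, lapply(unclass(scales), identity))
}

#' Canonical feature names
#'
#' The 157 feature names in canonical column order: for each of the 26 scale
#' components, the five positional values `c_0` .. `c_4` (position 0 is the
#' initiator methionine) followed by the unsuffixed sequence average `c`;
#' `energy` (the mRNA ensemble free energy of the 11-codon ORF prefix) comes
#' last.
#'
#' @param scales A `descriptor_scales` object.
#' @return Character vector of length 157.
#' @export
feature_names <- function(scales = load_scales()) {
  comp <- colnames(scale_block(scales))
  c(as.vector(vapply(comp, function(cc) c(paste0(cc, "_", 0:4), cc),
                     character(6))), "energy")
}

#' Encode peptides as 157-dimensional descriptor feature vectors
#'
#' Builds the full feature matrix: each of the 26 descriptor components
#' evaluated at the five residue positions (initiator Met = position 0, then
#' the four variable residues) and as the arithmetic mean over the five
#' positions (130 + 26 = 156 amino-acid-based features), plus the `energy`
#' column. Position-0 features are constant across peptides (always Met) and
#' are retained, matching the 157-feature convention.
#'
#' @param peptides Character vector of tetrapeptides.
#' @param scales A `descriptor_scales` object.
#' @param energies Numeric vector of ensemble free energies (kcal/mol), one
#'   per peptide.
#' @return Numeric matrix `length(peptides)` x 157 with canonical column
#'   names and `peptides` as rownames.
#' @examples
#' sc <- load_scales()
#' x <- encode_table("SKIK", sc, energies = -1.5)
#' dim(x)  # 1 157
#' @export
encode_table <- function(peptides, scales, energies) {
  if (length(energies) != length(peptides)) {
    stop("length mismatch: ", length(peptides), " peptides vs ",
         length(energies), " energies")
  }
  nm <- feature_names(scales)
  if (length(peptides) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = length(nm),
                  dimnames = list(NULL, nm)))
  }
  check_peptides(peptides)
  if (any(!is.finite(energies))) stop("non-finite energy value")
  block <- scale_block(scales)          # 20 x 26
  n <- length(peptides)
  res <- matrix(unlist(strsplit(peptides, ""), use.names = FALSE),
                nrow = n, byrow = TRUE) # n x 4 residues
  out <- matrix(NA_real_, n, length(nm), dimnames = list(peptides, nm))
  met <- block["M", ]
  for (ci in seq_len(ncol(block))) {
    cc <- colnames(block)[ci]
    pos <- cbind(met[ci], matrix(block[res, ci], n, 4))  # n x 5
    out[, paste0(cc, "_", 0:4)] <- pos
    out[, cc] <- rowMeans(pos)
  }
  out[, "energy"] <- energies
  out
}

#' @rdname encode_table
#' @param peptide A single peptide.
#' @param energy Its energy value.
#' @return `encode_peptide` returns a named numeric vector of length 157.
#' @export
encode_peptide <- function(peptide, scales, energy) {
  stopifnot(length(peptide) == 1L, length(energy) == 1L)
  encode_table(peptide, scales, energy)[1, ]
}

#' Write / read a feature matrix as CSV
#'
#' @param x Feature matrix from [encode_table()].
#' @param file Path.
#' @return `write_features` invisibly returns `file`; `read_features` returns
#'   the matrix with peptide rownames.
#' @export
write_features <- function(x, file) {
  utils::write.csv(data.frame(peptide = rownames(x), x, check.names = FALSE),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_features
#' @export
read_features <- function(file) {
  t <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(t[, -1, drop = FALSE])
  rownames(m) <- t$peptide
  m
}
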