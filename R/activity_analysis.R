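#' Position frequency matrix of equal-length peptides
#'
#' Relative residue frequencies per position over the four variable positions
#' (the constant initiator methionine is not included, matching 4-column
#' logos).
#'
#' @param peptides Non-empty character vector of equal-length peptides.
#' @return A 20 x L matrix of class `tep_pfm` (rows = residues, columns =
#'   positions, each column summing to 1) with attribute `n`.
#' @export
position_frequency_matrix <- function(peptides) {
  if (length(peptides) == 0L) stop("no peptides given")
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("peptides must have equal length")
  check_peptides(peptides, length = L)
  res <- matrix(unlist(strsplit(peptides, ""), use.names = FALSE),
                ncol = L, byrow = TRUE)
  pfm <- vapply(seq_len(L), function(j) {
    tab <- table(factor(res[, j], levels = aa_alphabet()))
    as.numeric(tab) / length(peptides)
  }, numeric(20L))
  dimnames(pfm) <- list(aa_alphabet(), paste0("pos", seq_len(L)))
  attr(pfm, "n") <- length(peptides)
  class(pfm) <- c("tep_pfm", class(pfm))
  pfm
}

#' Information content per logo position
#'
#' `IC_j = log2(20) + sum_a f_aj * log2(f_aj)` (bits), with `0 * log 0 = 0`.
#' Zero for a uniform column, `log2(20)` (~4.32 bits) for a point mass.
#' An optional small-sample correction subtracts `(20 - 1) / (2 n ln 2)`.
#'
#' @param pfm A `tep_pfm`.
#' @param correct Apply the small-sample correction?
#' @return Numeric vector of bits per position.
#' @export
information_content <- function(pfm, correct = FALSE) {
  stopifnot(inherits(pfm, "tep_pfm"))
  f <- unclass(pfm)
  plogp <- ifelse(f > 0, f * log2(f), 0)
  ic <- log2(nrow(f)) + colSums(plogp)
  if (correct) {
    n <- attr(pfm, "n")
    ic <- pmax(ic - (nrow(f) - 1) / (2 * n * log(2)), 0)
  }
  ic
}

#' Sequence logo plot
#'
#' Draws a simple base-graphics logo: residue letters stacked per position,
#' letter height proportional to `frequency * information content`.
#'
#' @param x A `tep_pfm`.
#' @param ... Unused.
#' @export
plot.tep_pfm <- function(x, ...) {
  ic <- information_content(x)
  L <- ncol(x)
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(0, log2(nrow(x))),
                 xlab = "position", ylab = "bits", xaxt = "n")
  graphics::axis(1, at = seq_len(L), labels = seq_len(L))
  for (j in seq_len(L)) {
    h <- unclass(x)[, j] * ic[j]
    ord <- order(h)
    y0 <- 0
    for (i in ord) {
      if (h[i] <= 0) next
      graphics::text(j, y0 + h[i] / 2, rownames(x)[i],
                     cex = max(0.3, min(3, h[i] * 3)))
      y0 <- y0 + h[i]
    }
  }
  invisible(x)
}

#' Counts of ordered adjacent residue pairs
#'
#' Counts each ordered dipeptide over the adjacent position pairs (1,2),
#' (2,3), (3,4) of tetrapeptides, the quantity visualized by Sankey-style
#' adjacency diagrams. The total count is `3 * length(peptides)`.
#'
#' @param peptides Non-empty character vector of tetrapeptides.
#' @return A 20 x 20 integer matrix (rows = first residue, columns = second).
#' @export
dipeptide_adjacency <- function(peptides) {
  if (length(peptides) == 0L) stop("no peptides given")
  check_peptides(peptides)
  res <- matrix(unlist(strsplit(peptides, ""), use.names = FALSE),
                ncol = 4L, byrow = TRUE)
  m <- matrix(0L, 20L, 20L, dimnames = list(aa_alphabet(), aa_alphabet()))
  for (j in 1:3) {
    t <- table(factor(res[, j], levels = aa_alphabet()),
               factor(res[, j + 1], levels = aa_alphabet()))
    m <- m + as.integer(t)
  }
  m
}

#' Top ordered dipeptide pairs
#'
#' @param adj Matrix from [dipeptide_adjacency()].
#' @param n Number of pairs to return.
#' @return Data frame `pair`, `count`, sorted by descending count then pair.
#' @export
top_dipeptides <- function(adj, n = 10L) {
  d <- data.frame(pair = paste0(rep(rownames(adj), times = ncol(adj)),
                                rep(colnames(adj), each = nrow(adj))),
                  count = as.vector(adj), stringsAsFactors = FALSE)
  d <- d[order(-d$count, d$pair), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, n)
}

#' Write a PFM or adjacency matrix as TSV
#' @param m Matrix.
#' @param file Path.
#' @return Invisibly `file`.
#' @export
write_matrix_tsv <- function(m, file) {
  utils::write.table(as.data.frame(unclass(m)), file, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(file)
}

#' Regression of variant activity on a residue property
#'
#' Ordinary least squares of relative intensity against a per-residue
#' physicochemical property across single-position variants (e.g. the fourth
#' residue of an otherwise fixed tetrapeptide). Used to ask whether a
#' side-chain property is (inversely) correlated with translation-enhancing
#' activity.
#'
#' @param activity Named numeric vector: residue -> relative intensity.
#' @param property Named numeric vector: residue -> property value. Only
#'   residues present in both are used (>= 3 required).
#' @return A list of class `residue_regression`: `slope`, `intercept`,
#'   `r_squared`, `n`, `residues`, `degenerate` (TRUE when the property has
#'   zero variance; estimates are `NA` in that case), and `fit` (the `lm`).
#' @examples
#' prop <- c(A = 1, D = -2, K = 0.5, S = 0)
#' act <- -2 * prop + 5
#' residue_property_regression(act, prop)$r_squared  # 1
#' @export
residue_property_regression <- function(activity, property) {
  shared <- intersect(names(activity), names(property))
  shared <- shared[is.finite(activity[shared]) & is.finite(property[shared])]
  if (length(shared) < 3L) stop("need at least 3 shared residues")
  x <- property[shared]
  y <- activity[shared]
  if (stats::sd(x) == 0) {
    out <- list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                n = length(shared), residues = shared, degenerate = TRUE,
                fit = NULL)
  } else {
    fit <- stats::lm(y ~ x)
    out <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                r_squared = summary(fit)$r.squared,
                n = length(shared), residues = shared, degenerate = FALSE,
                fit = fit)
  }
  class(out) <- "residue_regression"
  out
}

#' @export
print.residue_regression <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate fit: property has zero variance over", x$n, "residues\n")
  } else {
    cat(sprintf("slope = %.4g, intercept = %.4g, R^2 = %.3f (n = %d residues)\n",
                x$slope, x$intercept, x$r_squared, x$n))
  }
  invisible(x)
}

#' Load a per-residue property table
#'
#' Reads a two-column TSV (`aa`, property value). The bundled default is the
#' Kyte-Doolittle hydropathy index, shipped purely as a demonstration
#' property (see the file header).
#'
#' @param file TSV path.
#' @return Named numeric vector over residues.
#' @export
load_property_table <- function(file = system.file("extdata", "hydropathy_demo.tsv",
                                                   package = "teploop")) {
  t <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(t[[2]]), t[[1]])
}
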