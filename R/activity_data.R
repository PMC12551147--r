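#' Construct a peptide activity table
#'
#' The central tabular container: one row per measurement with the peptide
#' (or a reference label such as `"SKIK"` or `"no_peptide"`), raw fluorescence
#' intensity, SKIK-normalized relative intensity, replicate standard
#' deviation, data source and design-loop round.
#'
#' @param peptide Character vector of peptides or reference labels.
#' @param raw_intensity Raw fluorescence (arbitrary units, >= 0); may be `NA`
#'   when only relative values are known.
#' @param relative_intensity Relative fluorescence (reference = 1); may be
#'   `NA` before normalization.
#' @param replicate_sd Replicate standard deviation (same units).
#' @param source One of `"in_vivo"`, `"in_vitro"`, `"synthetic"`.
#' @param round Design-loop round (integer >= 0).
#' @return A data frame of class `activity_table` with attribute
#'   `normalized`.
#' @export
activity_table <- function(peptide, raw_intensity = NA_real_,
                           relative_intensity = NA_real_,
                           replicate_sd = NA_real_, source = "in_vitro",
                           round = 0L) {
  n <- length(peptide)
  t <- data.frame(peptide = as.character(peptide),
                  raw_intensity = rep_len(as.numeric(raw_intensity), n),
                  relative_intensity = rep_len(as.numeric(relative_intensity), n),
                  replicate_sd = rep_len(as.numeric(replicate_sd), n),
                  source = rep_len(as.character(source), n),
                  round = rep_len(as.integer(round), n),
                  stringsAsFactors = FALSE)
  if (any(t$raw_intensity < 0, na.rm = TRUE)) stop("raw_intensity must be >= 0")
  if (any(t$relative_intensity < 0, na.rm = TRUE)) stop("relative_intensity must be >= 0")
  bad <- !t$source %in% c("in_vivo", "in_vitro", "synthetic")
  if (any(bad)) stop("unknown source: ", paste(unique(t$source[bad]), collapse = ", "))
  attr(t, "normalized") <- all(is.finite(t$relative_intensity))
  class(t) <- c("activity_table", "data.frame")
  t
}

as_activity_table <- function(t, normalized = NA) {
  stopifnot(is.data.frame(t))
  out <- activity_table(t$peptide, t$raw_intensity, t$relative_intensity,
                        t$replicate_sd, t$source, t$round)
  if (!is.na(normalized)) attr(out, "normalized") <- normalized
  out
}

#' Normalize activities to a reference peptide
#'
#' Divides every raw intensity by the raw intensity of the reference record
#' (default SKIK), so the reference gets relative intensity exactly 1.
#' Idempotent: renormalizing a normalized table is a no-op.
#'
#' @param t An `activity_table`.
#' @param reference Reference label (default `"SKIK"`).
#' @return The table with `relative_intensity` (and scaled `replicate_sd`)
#'   filled in.
#' @examples
#' t <- activity_table(c("no_peptide", "SKIK"), raw_intensity = c(16, 86))
#' normalize_to_reference(t)$relative_intensity  # 16/86, 1
#' @export
normalize_to_reference <- function(t, reference = "SKIK") {
  stopifnot(inherits(t, "activity_table"))
  if (isTRUE(attr(t, "normalized")) && all(is.finite(t$relative_intensity))) {
    ref <- t$relative_intensity[t$peptide == reference]
    if (length(ref) == 1L && isTRUE(all.equal(ref, 1))) return(t)
  }
  i <- which(t$peptide == reference)
  if (length(i) != 1L) {
    stop("normalization requires exactly one '", reference, "' record, found ",
         length(i))
  }
  denom <- t$raw_intensity[i]
  if (!is.finite(denom) || denom <= 0) {
    stop("reference '", reference, "' has non-positive raw intensity")
  }
  t$relative_intensity <- t$raw_intensity / denom
  t$replicate_sd <- t$replicate_sd / denom
  attr(t, "normalized") <- TRUE
  t
}

#' Average duplicate peptide records
#'
#' Collapses records of the same peptide into one row whose relative intensity
#' is the mean of the duplicates; the number of pooled records is kept in an
#' `n_obs` column. `mode = "composition"` pools peptides with identical
#' residue multisets (anagrams) instead of identical sequences; the default is
#' sequence-level pooling, which preserves positional information.
#'
#' @param t A normalized `activity_table`.
#' @param mode `"sequence"` (default) or `"composition"`.
#' @return An `activity_table` with unique keys and an `n_obs` column.
#' @export
deduplicate_average <- function(t, mode = c("sequence", "composition")) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "activity_table"))
  if (!all(is.finite(t$relative_intensity))) stop("table must be normalized first")
  key <- if (mode == "sequence") t$peptide else
    vapply(strsplit(t$peptide, ""), function(r) paste(sort(r), collapse = ""),
           character(1))
  first <- !duplicated(key)
  agg <- tapply(t$relative_intensity, key, mean)
  cnt <- tapply(rep(1L, nrow(t)), key, sum)
  out <- t[first, , drop = FALSE]
  k <- key[first]
  out$relative_intensity <- as.numeric(agg[k])
  out$n_obs <- as.integer(cnt[k])
  out$raw_intensity <- NA_real_
  out$replicate_sd <- NA_real_
  rownames(out) <- NULL
  attr(out, "normalized") <- TRUE
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Classify records as positive relative to the reference
#'
#' A record is positive when its relative intensity strictly exceeds the
#' reference level of 1 ("surpassed" read as strict; equality is negative).
#'
#' @param t A normalized `activity_table`.
#' @return Logical vector, one per row.
#' @export
classify_positive <- function(t) {
  stopifnot(inherits(t, "activity_table"))
  if (nrow(t) == 0L) return(logical(0))
  if (!all(is.finite(t$relative_intensity))) stop("table must be normalized first")
  t$relative_intensity > 1.0
}

#' Read / write activity tables as CSV
#'
#' The fixed column schema is `peptide, raw_intensity, relative_intensity,
#' replicate_sd, source, round`; the header is validated on read and the
#' round trip is lossless.
#'
#' @param t An `activity_table`.
#' @param file Path.
#' @return `read_activity_csv` returns an `activity_table`;
#'   `write_activity_csv` invisibly returns `file`.
#' @export
write_activity_csv <- function(t, file) {
  stopifnot(inherits(t, "activity_table"))
  utils::write.csv(as.data.frame(t)[, c("peptide", "raw_intensity",
                                        "relative_intensity", "replicate_sd",
                                        "source", "round")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_activity_csv
#' @export
read_activity_csv <- function(file) {
  t <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("peptide", "raw_intensity", "relative_intensity", "replicate_sd",
            "source", "round")
  missing <- setdiff(need, names(t))
  if (length(missing)) {
    stop("activity CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  activity_table(t$peptide, t$raw_intensity, t$relative_intensity,
                 t$replicate_sd, t$source, t$round)
}
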