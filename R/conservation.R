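## Per-column conservation of a multiple sequence alignment relative to a
## reference row, digit binning, and per-region variant density.

#' Read an aligned FASTA file as an alignment matrix
#' @param path aligned FASTA (equal-length rows, gaps as `-`).
#' @return named character vector of aligned rows.
#' @export
read_alignment <- function(path) {
  s <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(s)), names(s))
}

#' Per-column conservation relative to a reference row
#'
#' For each non-gap column of the reference row, the percent of rows whose
#' character equals the reference character; gaps and ambiguity codes count
#' as non-matching. By default the reference row itself is included in the
#' denominator (so minimum conservation is 1/N, not 0).
#'
#' @param alignment named character vector of equal-length aligned rows.
#' @param reference_id name of the reference row.
#' @param include_reference include the reference row in the denominator.
#' @return `ConservationProfile` data.frame: `ref_pos` (1-based ungapped
#'   reference position), `ref_char`, `percent`, `digit`.
#' @export
column_conservation <- function(alignment, reference_id,
                                include_reference = TRUE) {
  if (!reference_id %in% names(alignment)) stop("reference row not present")
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) stop("ragged alignment")
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(mat) <- names(alignment)
  ref <- mat[reference_id, ]
  cols <- which(ref != "-")
  if (length(cols) == 0L) stop("reference row is all gaps")
  rows <- if (include_reference) rownames(mat) else
    setdiff(rownames(mat), reference_id)
  sub <- mat[rows, cols, drop = FALSE]
  matches <- sub == matrix(ref[cols], nrow = length(rows), ncol = length(cols),
                           byrow = TRUE)
  percent <- 100 * colSums(matches) / length(rows)
  out <- data.frame(ref_pos = seq_along(cols), ref_char = ref[cols],
                    percent = as.numeric(percent),
                    digit = conservation_digit(percent),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ConservationProfile", "data.frame")
  out
}

#' Conservation digit bin
#'
#' `floor(percent / 10)` capped at 9, so 90-100 percent all map to digit 9
#' (the bins are closed at the top).
#'
#' @param percent numeric in `[0, 100]` (vectorised).
#' @return integer digits in 0..9.
#' @export
conservation_digit <- function(percent) {
  if (any(percent < 0 | percent > 100)) stop("percent outside [0,100]")
  pmin(as.integer(floor(percent / 10)), 9L)
}

#' Unique-variant density over a region
#'
#' Counts distinct (position, ref, alt) variants whose position falls inside
#' the 0-based half-open `region`, divided by the region length.
#'
#' @param region length-2 vector `c(start, end)`.
#' @param variants list of `VariantRecord`s or data.frame with `position`,
#'   `ref`, `alt`.
#' @return variants per base.
#' @export
variant_density <- function(region, variants) {
  len <- region[2] - region[1]
  if (len <= 0) stop("region length must be positive")
  if (is.data.frame(variants)) {
    df <- variants
  } else {
    df <- do.call(rbind, lapply(variants, function(v) data.frame(
      position = v$position, ref = v$ref, alt = v$alt,
      stringsAsFactors = FALSE)))
  }
  if (is.null(df) || nrow(df) == 0L) return(0)
  df <- unique(df[, c("position", "ref", "alt")])
  sum(df$position >= region[1] & df$position < region[2]) / len
}

#' Write a conservation profile TSV
#' @param profile a `ConservationProfile`.
#' @param path output path.
#' @export
write_conservation_tsv <- function(profile, path) {
  write_tsv_report(as.data.frame(profile), path,
                   c("ref_pos", "ref_char", "percent", "digit"))
}
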