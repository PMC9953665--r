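## Fusion junction probes: extraction, uniqueness screening against a
## background transcriptome, and junction-spanning read counting.

#' Extract a junction probe from a fused transcript
#'
#' The probe is `sequence[junction_offset - flank : junction_offset + flank]`
#' (0-based half-open): `flank` bases of donor followed by `flank` bases of
#' acceptor sequence.
#'
#' @param fused_sequence fused transcript sequence.
#' @param junction_offset transcript coordinate of the junction (first
#'   acceptor base).
#' @param flank bases per side (default 20).
#' @param fused_transcript_id identifier carried on the probe.
#' @return object of class `JunctionProbe` with `uniqueness = "unknown"`.
#' @export
extract_probe <- function(fused_sequence, junction_offset, flank = 20L,
                          fused_transcript_id = NA_character_) {
  n <- nchar(fused_sequence)
  if (flank > junction_offset || flank > n - junction_offset)
    stop("flank exceeds distance from junction to a transcript end")
  probe <- substr(fused_sequence, junction_offset - flank + 1L,
                  junction_offset + flank)
  structure(list(fused_transcript_id = fused_transcript_id,
                 junction_offset = as.integer(junction_offset),
                 flank = as.integer(flank), probe_sequence = probe,
                 uniqueness = "unknown", hits = NULL),
            class = "JunctionProbe")
}

#' Screen probe uniqueness against a background transcriptome
#'
#' Scans every window of every background sequence (both strands) for a
#' Hamming distance of at most `max_mismatches` to the probe. The probe is
#' unique when all hits fall on the fusion transcript itself (matched by
#' sequence name).
#'
#' @param probe a `JunctionProbe`.
#' @param background named character vector of background transcript
#'   sequences (may include the fusion transcript under its own id).
#' @param max_mismatches Hamming threshold (default 2).
#' @return the probe with `hits` (data.frame: `sequence_id`, `offset`,
#'   `strand`, `mismatches`) and `uniqueness` filled in.
#' @export
screen_uniqueness <- function(probe, background, max_mismatches = 2L) {
  if (length(background) == 0L) stop("background transcript set is empty")
  hits <- cpp_hamming_hits(probe$probe_sequence, unname(toupper(background)),
                           max_mismatches)
  hits$sequence_id <- names(background)[hits$seq_index]
  hits <- hits[, c("sequence_id", "offset", "strand", "mismatches")]
  probe$hits <- hits
  foreign <- hits$sequence_id != probe$fused_transcript_id
  probe$uniqueness <- if (any(foreign)) "non-unique" else "unique"
  probe
}

#' Count junction-spanning reads
#'
#' A read counts when some ungapped placement of the probe (either read
#' orientation) covers at least `min_overlap` read bases on each side of the
#' junction with at most `max_mismatches` mismatches over the overlap. Each
#' read is counted at most once.
#'
#' @param reads character vector of reads, or a FASTQ path.
#' @param probe a `JunctionProbe` (a warning is issued when its uniqueness is
#'   not `"unique"`).
#' @param min_overlap bases required on each side (default 10).
#' @param max_mismatches mismatch budget (default 0).
#' @return list with `count` and `hits` (per-read placements).
#' @export
count_junction_reads <- function(reads, probe, min_overlap = 10L,
                                 max_mismatches = 0L) {
  if (min_overlap > probe$flank)
    stop("min_overlap exceeds the probe flank")
  if (!identical(probe$uniqueness, "unique"))
    warning("probe uniqueness is ", probe$uniqueness,
            "; junction counts may include off-target reads")
  if (length(reads) == 1L && !is_dna(reads[1L]) && file.exists(reads[1L]))
    reads <- read_fastq(reads)
  if (length(reads) == 0L)
    return(list(count = 0L, hits = data.frame(read_index = integer(0),
                                              offset = integer(0),
                                              strand = character(0),
                                              mismatches = integer(0))))
  cpp_count_junction_reads(unname(toupper(reads)), probe$probe_sequence,
                           probe$flank, min_overlap, max_mismatches)
}

#' Write a probe report TSV
#' @param probes list of screened `JunctionProbe`s.
#' @param path output path.
#' @export
write_probe_tsv <- function(probes, path) {
  df <- do.call(rbind, lapply(probes, function(p) data.frame(
    fused_transcript_id = p$fused_transcript_id,
    junction_offset = p$junction_offset, flank = p$flank,
    probe_sequence = p$probe_sequence, uniqueness = p$uniqueness,
    n_hits = if (is.null(p$hits)) NA_integer_ else nrow(p$hits),
    stringsAsFactors = FALSE)))
  write_tsv_report(df, path, c("fused_transcript_id", "junction_offset",
                               "flank", "probe_sequence", "uniqueness", "n_hits"))
}
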