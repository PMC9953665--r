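## Transcript models, coordinate projection, consequence classification,
## readthrough fusion construction, ORF translation and decay rules.
## All internal coordinates are 0-based half-open; GTF/VCF conversion happens
## at I/O only.

#' Construct a genome sequence object
#'
#' @param contig_id contig name.
#' @param sequence plus-strand nucleotide string (A/C/G/T/N).
#' @return object of class `GenomeSequence`.
#' @export
genome_sequence <- function(contig_id, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty genome sequence")
  if (!is_dna(sequence)) stop("genome alphabet restricted to A/C/G/T/N")
  structure(list(contig_id = contig_id, sequence = sequence),
            class = "GenomeSequence")
}

#' Construct a transcript model
#'
#' Exons are genomic intervals in 0-based half-open coordinates, sorted by
#' genome coordinate and non-overlapping regardless of strand. `cds_span` is
#' transcript-relative (0-based half-open, 5'->3' in transcript orientation).
#'
#' @param transcript_id,gene_id,contig_id identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame of exon start/end.
#' @param cds_span optional length-2 integer vector.
#' @param cds_partial flag allowing a CDS whose length is not a codon multiple.
#' @return object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig_id, strand, exons,
                             cds_span = NULL, cds_partial = FALSE) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon")
  if (is.unsorted(exons[, 1], strictly = TRUE) && nrow(exons) > 1L)
    stop("exons must be sorted by genome coordinate")
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop("exons overlap")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  len <- sum(exons[, 2] - exons[, 1])
  if (!is.null(cds_span)) {
    cds_span <- as.integer(cds_span)
    if (cds_span[1] < 0L || cds_span[2] > len || cds_span[2] <= cds_span[1])
      stop("cds_span outside transcript")
    if ((cds_span[2] - cds_span[1]) %% 3L != 0L && !cds_partial)
      stop("CDS length not divisible by 3 (set cds_partial = TRUE to allow)")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 contig_id = contig_id, strand = strand, exons = exons,
                 cds_span = cds_span, cds_partial = cds_partial),
            class = "TranscriptModel")
}

#' Transcript length (sum of exon lengths)
#' @param tx a `TranscriptModel`.
#' @export
tx_length <- function(tx) sum(tx$exons[, 2] - tx$exons[, 1])

#' Exon-exon junction positions in transcript coordinates
#'
#' Returns the transcript-relative positions immediately after each junction
#' (i.e. cumulative exon lengths, excluding the transcript end). Single-exon
#' transcripts return an empty vector.
#' @param tx a `TranscriptModel`.
#' @export
tx_junctions <- function(tx) {
  lens <- exon_lengths_tx_order(tx)
  if (length(lens) < 2L) return(integer(0))
  cumsum(lens)[-length(lens)]
}

# exon lengths in transcript (5'->3') order
exon_lengths_tx_order <- function(tx) {
  lens <- tx$exons[, 2] - tx$exons[, 1]
  if (tx$strand == "-") rev(lens) else lens
}

#' Extract the spliced transcript sequence
#'
#' @param genome a `GenomeSequence`.
#' @param tx a `TranscriptModel` on the same contig.
#' @return transcript sequence, 5'->3' in transcript orientation.
#' @export
extract_transcript_sequence <- function(genome, tx) {
  if (genome$contig_id != tx$contig_id) stop("contig mismatch")
  glen <- nchar(genome$sequence)
  if (any(tx$exons[, 1] < 0L) || any(tx$exons[, 2] > glen))
    stop("exon out of contig bounds")
  pieces <- substring(genome$sequence, tx$exons[, 1] + 1L, tx$exons[, 2])
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

#' Project a genomic position into transcript coordinates
#'
#' @param tx a `TranscriptModel`.
#' @param gpos 0-based genomic position of a single base.
#' @return 0-based transcript position, or `NA` when the base is not exonic.
#' @export
genome_to_tx <- function(tx, gpos) {
  vapply(gpos, function(g) {
    hit <- which(g >= tx$exons[, 1] & g < tx$exons[, 2])
    if (length(hit) == 0L) return(NA_integer_)
    before <- if (hit > 1L) sum(tx$exons[seq_len(hit - 1L), 2] -
                                tx$exons[seq_len(hit - 1L), 1]) else 0L
    plus_off <- as.integer(before + (g - tx$exons[hit, 1]))
    if (tx$strand == "+") plus_off else tx_length(tx) - 1L - plus_off
  }, integer(1))
}

#' Project a transcript position onto the genome
#' @param tx a `TranscriptModel`.
#' @param tpos 0-based transcript position(s).
#' @return 0-based genomic position(s).
#' @export
tx_to_genome <- function(tx, tpos) {
  len <- tx_length(tx)
  vapply(tpos, function(p) {
    if (p < 0L || p >= len) stop("transcript position out of range")
    plus_off <- if (tx$strand == "+") p else len - 1L - p
    for (i in seq_len(nrow(tx$exons))) {
      w <- tx$exons[i, 2] - tx$exons[i, 1]
      if (plus_off < w) return(as.integer(tx$exons[i, 1] + plus_off))
      plus_off <- plus_off - w
    }
    stop("unreachable")
  }, integer(1))
}

#' Construct a variant record
#'
#' Positions are 0-based internally; `ref`/`alt` follow the anchored VCF
#' allele convention (non-empty, ref matching the genome).
#'
#' @param contig_id contig.
#' @param position 0-based genomic position of the first ref base.
#' @param ref,alt alleles.
#' @param variant_id optional identifier (e.g. an rsID).
#' @param population_frequencies optional named numeric in `[0,1]`.
#' @param annotation_scores optional named numeric of ingested scores.
#' @return object of class `VariantRecord`.
#' @export
variant_record <- function(contig_id, position, ref, alt, variant_id = NA_character_,
                           population_frequencies = NULL, annotation_scores = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) == 0L || nchar(alt) == 0L) stop("alleles must be non-empty")
  if (!is_dna(ref) || !is_dna(alt)) stop("alleles must be DNA")
  if (!is.null(population_frequencies) &&
      any(population_frequencies < 0 | population_frequencies > 1))
    stop("population frequencies must lie in [0,1]")
  structure(list(contig_id = contig_id, position = as.integer(position),
                 ref = ref, alt = alt, variant_id = variant_id,
                 population_frequencies = population_frequencies,
                 annotation_scores = annotation_scores),
            class = "VariantRecord")
}

check_ref_allele <- function(variant, genome) {
  obs <- substr(genome$sequence, variant$position + 1L,
                variant$position + nchar(variant$ref))
  if (obs != variant$ref)
    stop(sprintf("ref allele mismatch at %s:%d (genome %s, variant %s)",
                 variant$contig_id, variant$position, obs, variant$ref))
  invisible(TRUE)
}

#' Project a variant into transcript coordinates
#'
#' Returns the transcript-relative position of the (strand-adjusted) ref
#' allele and the alleles in transcript orientation, or `NULL` when the
#' variant is not fully exonic in this transcript.
#'
#' @param variant a `VariantRecord`.
#' @param tx a `TranscriptModel` on the same contig.
#' @return list with `position`, `ref`, `alt`, or `NULL`.
#' @export
project_variant <- function(variant, tx) {
  if (variant$contig_id != tx$contig_id) stop("contig mismatch")
  gspan <- variant$position + seq_len(nchar(variant$ref)) - 1L
  tpos <- genome_to_tx(tx, gspan)
  if (anyNA(tpos)) return(NULL)
  # a multi-base ref must be contiguous in transcript space
  if (length(tpos) > 1L && any(abs(diff(sort(tpos))) != 1L)) return(NULL)
  if (tx$strand == "+") {
    list(position = min(tpos), ref = variant$ref, alt = variant$alt)
  } else {
    list(position = min(tpos), ref = revcomp(variant$ref),
         alt = revcomp(variant$alt))
  }
}

CONSEQUENCE_PRIORITY <- c(
  "splice_site", "frameshift", "stop_gained", "stop_lost", "missense",
  "inframe_indel", "synonymous", "splice_region", "five_prime_UTR",
  "three_prime_UTR", "intronic", "noncoding_transcript",
  "upstream_gene", "downstream_gene")

#' Classify the consequence of a variant on one transcript
#'
#' A single consequence is chosen by fixed priority (splice_site > frameshift >
#' stop_gained > stop_lost > missense > inframe_indel > synonymous >
#' splice_region > five_prime_UTR > three_prime_UTR > intronic >
#' noncoding_transcript; upstream/downstream only without transcript overlap).
#' Splice windows: 2 intronic bases (splice_site); 3 exonic + 8 intronic
#' (splice_region).
#'
#' @param variant a `VariantRecord`.
#' @param tx a `TranscriptModel`.
#' @param genome the `GenomeSequence` (used for ref validation and codons).
#' @param window upstream/downstream window in bases (default 5000).
#' @return list with `transcript_id`, `consequence`, `protein_change`, or
#'   `NULL` when the variant is outside the window.
#' @export
classify_consequence <- function(variant, tx, genome, window = 5000L) {
  check_ref_allele(variant, genome)
  v_lo <- variant$position
  v_hi <- variant$position + nchar(variant$ref)  # half-open
  t_lo <- min(tx$exons[, 1]); t_hi <- max(tx$exons[, 2])

  call <- function(consequence, protein_change = NA_character_) {
    list(transcript_id = tx$transcript_id, consequence = consequence,
         protein_change = protein_change)
  }

  if (v_hi <= t_lo || v_lo >= t_hi) {   # outside the transcript body
    if (v_hi <= t_lo) {
      if (t_lo - v_hi >= window) return(NULL)
      return(call(if (tx$strand == "+") "upstream_gene" else "downstream_gene"))
    }
    if (v_lo - t_hi >= window) return(NULL)
    return(call(if (tx$strand == "+") "downstream_gene" else "upstream_gene"))
  }

  candidates <- character(0)

  # splice windows at internal exon boundaries (strand-symmetric)
  n <- nrow(tx$exons)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      dstart <- tx$exons[i, 2]       # intron start after exon i
      dend <- tx$exons[i + 1L, 1]    # intron end before exon i+1
      site <- rbind(c(dstart, dstart + 2L), c(dend - 2L, dend))
      regio <- rbind(c(tx$exons[i, 2] - 3L, tx$exons[i, 2]),          # exonic
                     c(tx$exons[i + 1L, 1], tx$exons[i + 1L, 1] + 3L),
                     c(dstart + 2L, dstart + 8L),                     # intronic
                     c(dend - 8L, dend - 2L))
      overlaps <- function(m) any(v_lo < m[, 2] & v_hi > m[, 1])
      if (overlaps(site)) candidates <- c(candidates, "splice_site")
      if (overlaps(regio)) candidates <- c(candidates, "splice_region")
    }
  }

  proj <- project_variant(variant, tx)
  protein_change <- NA_character_
  if (is.null(proj)) {
    exonic <- any(v_lo < tx$exons[, 2] & v_hi > tx$exons[, 1])
    if (exonic && !"splice_site" %in% candidates) {
      # partially exonic indel straddling a junction: treat as splice_site
      candidates <- c(candidates, "splice_site")
    }
    if (!exonic) candidates <- c(candidates, "intronic")
  } else if (is.null(tx$cds_span)) {
    candidates <- c(candidates, "noncoding_transcript")
  } else {
    cs <- tx$cds_span
    p_lo <- proj$position
    p_hi <- proj$position + nchar(proj$ref)
    if (p_hi <= cs[1]) {
      candidates <- c(candidates, "five_prime_UTR")
    } else if (p_lo >= cs[2]) {
      candidates <- c(candidates, "three_prime_UTR")
    } else if (nchar(proj$ref) != nchar(proj$alt)) {
      shift <- abs(nchar(proj$ref) - nchar(proj$alt))
      candidates <- c(candidates,
                      if (shift %% 3L == 0L) "inframe_indel" else "frameshift")
      if (shift %% 3L != 0L) {
        codon_i <- (p_lo - cs[1]) %/% 3L
        txseq <- extract_transcript_sequence(genome, tx)
        ref_codon <- substr(txseq, cs[1] + 3L * codon_i + 1L, cs[1] + 3L * codon_i + 3L)
        protein_change <- sprintf("p.%s%dfs",
                                  translate_dna(ref_codon), codon_i + 1L)
      }
    } else {
      # same-length substitution within the CDS; classify via codons
      txseq <- extract_transcript_sequence(genome, tx)
      alt_txseq <- inject_haplotype(txseq, data.frame(
        pos = proj$position, ref = proj$ref, alt = proj$alt,
        stringsAsFactors = FALSE))
      cds_ref <- substr(txseq, cs[1] + 1L, cs[2])
      cds_alt <- substr(alt_txseq, cs[1] + 1L, cs[2])
      aa_ref <- translate_dna(cds_ref)
      aa_alt <- translate_dna(cds_alt)
      diff_at <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
      if (length(diff_at) == 0L) {
        candidates <- c(candidates, "synonymous")
      } else {
        i <- diff_at[1]
        r <- substr(aa_ref, i, i); a <- substr(aa_alt, i, i)
        if (a == "*") {
          candidates <- c(candidates, "stop_gained")
        } else if (r == "*") {
          candidates <- c(candidates, "stop_lost")
        } else {
          candidates <- c(candidates, "missense")
        }
        protein_change <- sprintf("p.%s%d%s", r, i, a)
      }
    }
  }

  if (length(candidates) == 0L) candidates <- "intronic"
  chosen <- CONSEQUENCE_PRIORITY[min(match(candidates, CONSEQUENCE_PRIORITY))]
  coding_altering <- chosen %in% c("missense", "stop_gained", "stop_lost", "frameshift")
  call(chosen, if (coding_altering) protein_change else NA_character_)
}

#' Apply transcript-relative allele edits to a sequence
#'
#' Edits are validated against the sequence and applied right-to-left so that
#' indels do not shift the coordinates of yet-unapplied edits.
#'
#' @param tx_sequence nucleotide string.
#' @param edits data.frame with columns `pos` (0-based), `ref`, `alt`.
#' @return edited sequence.
#' @export
inject_haplotype <- function(tx_sequence, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(tx_sequence)
  edits <- edits[order(edits$pos), , drop = FALSE]
  hi <- edits$pos + nchar(edits$ref)
  if (nrow(edits) > 1L && any(edits$pos[-1L] < hi[-nrow(edits)]))
    stop("overlapping edits")
  for (i in rev(seq_len(nrow(edits)))) {
    pos <- edits$pos[i]; ref <- toupper(edits$ref[i]); alt <- toupper(edits$alt[i])
    obs <- substr(tx_sequence, pos + 1L, pos + nchar(ref))
    if (obs != ref)
      stop(sprintf("ref mismatch at position %d: sequence has %s, edit says %s",
                   pos, obs, ref))
    tx_sequence <- paste0(substr(tx_sequence, 1L, pos), alt,
                          substr(tx_sequence, pos + nchar(ref) + 1L,
                                 nchar(tx_sequence)))
  }
  tx_sequence
}

# genomic exon intervals covering transcript range [from, to)
tx_range_to_exons <- function(tx, from, to) {
  lens <- exon_lengths_tx_order(tx)
  offs <- c(0L, cumsum(lens))
  exons_tx_order <- if (tx$strand == "-") tx$exons[rev(seq_len(nrow(tx$exons))), ,
                                                   drop = FALSE] else tx$exons
  out <- NULL
  for (i in seq_along(lens)) {
    lo <- max(from, offs[i]); hi <- min(to, offs[i + 1L])
    if (hi <= lo) next
    o1 <- lo - offs[i]; o2 <- hi - offs[i]   # offsets within exon, tx order
    if (tx$strand == "+") {
      g <- c(exons_tx_order[i, 1] + o1, exons_tx_order[i, 1] + o2)
    } else {
      g <- c(exons_tx_order[i, 2] - o2, exons_tx_order[i, 2] - o1)
    }
    out <- rbind(out, g)
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  colnames(out) <- c("start", "end")
  rownames(out) <- NULL
  out
}

#' Build a readthrough fusion transcript
#'
#' The fused sequence is `donor[0:donor_break] + acceptor[acceptor_start:]`
#' (transcript coordinates). Donor and acceptor must lie on the same strand of
#' the same contig. The junction position and the updated exon-junction list
#' are recorded on the fused model for decay classification.
#'
#' @param donor,acceptor `TranscriptModel`s.
#' @param donor_seq,acceptor_seq their transcript sequences.
#' @param donor_break,acceptor_start transcript-relative coordinates.
#' @param transcript_id,gene_id identifiers for the fused transcript.
#' @return list with `model`, `sequence`, `junction_offset`.
#' @export
build_readthrough_transcript <- function(donor, acceptor, donor_seq, acceptor_seq,
                                         donor_break, acceptor_start,
                                         transcript_id = paste0(donor$transcript_id,
                                                                "--", acceptor$transcript_id),
                                         gene_id = paste0(donor$gene_id, "--",
                                                          acceptor$gene_id)) {
  if (donor$contig_id != acceptor$contig_id || donor$strand != acceptor$strand)
    stop("cross-contig or cross-strand join is unsupported")
  if (donor_break < 1L || donor_break > tx_length(donor) ||
      acceptor_start < 0L || acceptor_start >= tx_length(acceptor))
    stop("join coordinates outside transcript lengths")
  ex <- rbind(tx_range_to_exons(donor, 0L, donor_break),
              tx_range_to_exons(acceptor, acceptor_start, tx_length(acceptor)))
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  if (nrow(ex) > 1L && any(ex[-1L, 1] < ex[-nrow(ex), 2]))
    stop("donor and acceptor segments overlap on the genome")
  model <- transcript_model(transcript_id, gene_id, donor$contig_id,
                            donor$strand, ex)
  seq <- paste0(substr(donor_seq, 1L, donor_break),
                substr(acceptor_seq, acceptor_start + 1L, nchar(acceptor_seq)))
  stopifnot(nchar(seq) == tx_length(model))
  list(model = model, sequence = seq, junction_offset = donor_break)
}

#' Find and translate an open reading frame
#'
#' With `cds_span` the given span is translated; otherwise the longest
#' ATG-initiated ORF is chosen (ties to the 5'-most). Translation stops at the
#' first in-frame stop codon; whether a stop was reached is recorded.
#'
#' @param tx_sequence nucleotide string.
#' @param cds_span optional 0-based half-open transcript span.
#' @param cds_partial allow a span that is not a codon multiple.
#' @param transcript_id carried through to the record.
#' @return a `ProteinRecord` list: `sequence`, `source_transcript_id`,
#'   `orf_span`, `stop_reached`, `decay_class` (`NA` until classified).
#' @export
find_orf_translate <- function(tx_sequence, cds_span = NULL, cds_partial = FALSE,
                               transcript_id = NA_character_) {
  tx_sequence <- toupper(tx_sequence)
  if (nchar(tx_sequence) == 0L) stop("empty sequence")
  translate_from <- function(start) {
    # returns c(n_aa, stop_reached) for ORF starting at 0-based `start`
    sub <- substr(tx_sequence, start + 1L, nchar(tx_sequence))
    aa <- translate_dna(sub)
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0L) c(stop_at - 1L, 1L) else c(nchar(aa), 0L)
  }
  if (!is.null(cds_span)) {
    len <- cds_span[2] - cds_span[1]
    if (len %% 3L != 0L && !cds_partial)
      stop("cds_span length not divisible by 3")
    aa <- translate_dna(substr(tx_sequence, cds_span[1] + 1L, cds_span[2]))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0L) {
      protein <- substr(aa, 1L, stop_at - 1L)
      span <- c(cds_span[1], cds_span[1] + 3L * stop_at)
      stop_reached <- TRUE
    } else {
      protein <- aa
      span <- c(cds_span[1], cds_span[1] + 3L * nchar(aa))
      stop_reached <- FALSE
    }
  } else {
    starts <- as.integer(gregexpr("ATG", tx_sequence, fixed = TRUE)[[1L]]) - 1L
    if (length(starts) == 1L && starts[1] == -1L)
      return(structure(list(sequence = "", source_transcript_id = transcript_id,
                            orf_span = c(0L, 0L), stop_reached = FALSE,
                            decay_class = NA_character_),
                       class = "ProteinRecord"))
    best <- NULL
    for (s in starts) {
      r <- translate_from(s)
      if (is.null(best) || r[1] > best$n) best <- list(start = s, n = r[1],
                                                       stop = r[2] == 1L)
    }
    protein <- translate_dna(substr(tx_sequence, best$start + 1L,
                                    best$start + 3L * best$n))
    span <- c(best$start,
              best$start + 3L * (best$n + if (best$stop) 1L else 0L))
    stop_reached <- best$stop
  }
  structure(list(sequence = protein, source_transcript_id = transcript_id,
                 orf_span = as.integer(span), stop_reached = stop_reached,
                 decay_class = NA_character_),
            class = "ProteinRecord")
}

#' Classify transcript decay (NMD / nonstop / normal)
#'
#' `nmd_predicted` when the stop codon ends more than `nmd_threshold` nt
#' upstream of the final exon-exon junction; `nonstop_predicted` when no
#' in-frame stop is reached before the transcript end; otherwise `normal`.
#'
#' @param tx a `TranscriptModel` (source of the junction list).
#' @param orf_span 0-based half-open transcript span of the ORF including the
#'   stop codon when present.
#' @param stop_reached whether the ORF reached an in-frame stop.
#' @param nmd_threshold distance rule in nt (default 50).
#' @return one of `"normal"`, `"nmd_predicted"`, `"nonstop_predicted"`.
#' @export
classify_decay <- function(tx, orf_span, stop_reached = TRUE, nmd_threshold = 50L) {
  if (!stop_reached) return("nonstop_predicted")
  j <- tx_junctions(tx)
  if (length(j) == 0L) return("normal")
  if (max(j) - orf_span[2] > nmd_threshold) "nmd_predicted" else "normal"
}

#' Re-translate through a stop-loss edit into the 3'UTR
#'
#' The edit must overlap the stop codon of `orf_span` and abolish it.
#' Translation restarts at the (former) stop codon and proceeds until the next
#' in-frame stop or the transcript end, producing the HGVS extension name
#' `p.Ter{N}{Aa}extTer{M}` with `M - 1` added residues; when no stop is
#' reached the open form `p.Ter{N}{Aa}ext*?` is used and the decay class
#' becomes `nonstop_predicted`.
#'
#' @param tx_sequence transcript sequence.
#' @param orf_span ORF span including the stop codon.
#' @param edit list or one-row data.frame with `pos`, `ref`, `alt`
#'   (transcript-relative).
#' @return list with `protein` (extended `ProteinRecord`), `name`,
#'   `added_residues`.
#' @export
apply_stop_loss_retranslate <- function(tx_sequence, orf_span, edit) {
  edit <- as.data.frame(edit, stringsAsFactors = FALSE)
  stop_lo <- orf_span[2] - 3L
  e_lo <- edit$pos; e_hi <- edit$pos + nchar(edit$ref)
  if (e_hi <= stop_lo || e_lo >= orf_span[2])
    stop("edit does not overlap the stop codon: not a stop-loss")
  old_stop <- substr(tx_sequence, stop_lo + 1L, stop_lo + 3L)
  if (!old_stop %in% STOP_CODONS) stop("orf_span does not end in a stop codon")
  edited <- inject_haplotype(tx_sequence, edit)
  new_codon <- substr(edited, stop_lo + 1L, stop_lo + 3L)
  if (new_codon %in% STOP_CODONS)
    stop("edit does not abolish the stop codon: not a stop-loss")
  n_prot <- (orf_span[2] - orf_span[1]) %/% 3L - 1L  # residues before stop
  ter_pos <- n_prot + 1L
  tail_aa <- translate_dna(substr(edited, stop_lo + 1L, nchar(edited)))
  stop_at <- regexpr("*", tail_aa, fixed = TRUE)
  original <- translate_dna(substr(tx_sequence, orf_span[1] + 1L, stop_lo))
  if (stop_at > 0L) {
    added <- as.integer(stop_at) - 1L
    ext <- substr(tail_aa, 1L, added)
    name <- sprintf("p.Ter%d%sextTer%d", ter_pos, aa1to3(substr(ext, 1L, 1L)),
                    added + 1L)
    span <- c(orf_span[1], stop_lo + 3L * (added + 1L))
    decay <- "normal"
    stop_reached <- TRUE
  } else {
    added <- nchar(tail_aa)
    ext <- tail_aa
    name <- sprintf("p.Ter%d%sext*?", ter_pos, aa1to3(substr(ext, 1L, 1L)))
    span <- c(orf_span[1], stop_lo + 3L * added)
    decay <- "nonstop_predicted"
    stop_reached <- FALSE
  }
  protein <- structure(list(sequence = paste0(original, ext),
                            source_transcript_id = NA_character_,
                            orf_span = as.integer(span),
                            stop_reached = stop_reached, decay_class = decay),
                       class = "ProteinRecord")
  list(protein = protein, name = name, added_residues = added)
}

#' Parse an HGVS stop-loss extension name
#'
#' @param name e.g. `"p.Ter201GlyextTer29"` or the open form
#'   `"p.Ter201Glyext*?"`.
#' @return list with `stop_position`, `new_aa` (three-letter), `ext_ter`
#'   (`NA` for the open form) and `added_residues` (`ext_ter - 1`).
#' @export
parse_hgvs_ext <- function(name) {
  m <- regmatches(name, regexec("^p\\.Ter([0-9]+)([A-Za-z]{3})extTer([0-9]+)$", name))[[1L]]
  if (length(m) == 4L) {
    return(list(stop_position = as.integer(m[2]), new_aa = m[3],
                ext_ter = as.integer(m[4]), added_residues = as.integer(m[4]) - 1L))
  }
  m <- regmatches(name, regexec("^p\\.Ter([0-9]+)([A-Za-z]{3})ext\\*\\?$", name))[[1L]]
  if (length(m) == 3L)
    return(list(stop_position = as.integer(m[2]), new_aa = m[3],
                ext_ter = NA_integer_, added_residues = NA_integer_))
  stop("not a recognised HGVS extension name: ", name)
}
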