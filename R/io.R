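## GTF and VCF conversion. Internal coordinates are 0-based half-open;
## both formats are 1-based inclusive on disk.

#' Write transcript models to a GTF file
#'
#' Emits transcript, exon and CDS features; CDS spans are projected from the
#' transcript-relative `cds_span` onto the genome.
#'
#' @param models list of `TranscriptModel`s.
#' @param path output GTF path.
#' @export
write_gtf <- function(models, path) {
  rows <- list()
  for (tx in models) {
    add <- function(type, start0, end0, phase = NA_integer_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        seqnames = tx$contig_id, start = start0 + 1L, end = end0,
        strand = tx$strand, type = type, gene_id = tx$gene_id,
        transcript_id = tx$transcript_id, phase = phase,
        stringsAsFactors = FALSE)
    }
    add("transcript", min(tx$exons[, 1]), max(tx$exons[, 2]))
    for (i in seq_len(nrow(tx$exons))) add("exon", tx$exons[i, 1], tx$exons[i, 2])
    if (!is.null(tx$cds_span)) {
      cds_ex <- tx_range_to_exons(tx, tx$cds_span[1], tx$cds_span[2])
      ord <- if (tx$strand == "-") rev(seq_len(nrow(cds_ex))) else
        seq_len(nrow(cds_ex))
      before <- 0L
      for (i in ord) {
        add("CDS", cds_ex[i, 1], cds_ex[i, 2], phase = (3L - before %% 3L) %% 3L)
        before <- before + (cds_ex[i, 2] - cds_ex[i, 1])
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand, type = df$type, gene_id = df$gene_id,
    transcript_id = df$transcript_id, phase = df$phase)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Uses exon features to build each model and CDS features (when present) to
#' reconstruct the transcript-relative `cds_span`.
#'
#' @param path GTF file.
#' @return named list of `TranscriptModel`s.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  models <- list()
  for (txid in unique(df$transcript_id[df$type == "exon"])) {
    ex <- df[df$type == "exon" & df$transcript_id == txid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    exons <- cbind(start = ex$start - 1L, end = ex$end)
    tx <- transcript_model(txid, ex$gene_id[1L], as.character(ex$seqnames[1L]),
                           as.character(ex$strand[1L]), exons)
    cds <- df[df$type == "CDS" & df$transcript_id == txid, , drop = FALSE]
    if (nrow(cds) > 0L) {
      bases <- unlist(lapply(seq_len(nrow(cds)),
                             function(i) seq(cds$start[i] - 1L, cds$end[i] - 1L)))
      tpos <- genome_to_tx(tx, bases)
      tx <- transcript_model(txid, tx$gene_id, tx$contig_id, tx$strand, exons,
                             cds_span = c(min(tpos), max(tpos) + 1L),
                             cds_partial = TRUE)
      # restore the strict codon check when the span is a codon multiple
      if ((tx$cds_span[2] - tx$cds_span[1]) %% 3L == 0L) tx$cds_partial <- FALSE
    }
    models[[txid]] <- tx
  }
  models
}

#' Left-align and anchor an indel against the genome
#'
#' Trims shared trailing bases, shifts the representation left while the
#' alleles end with the same base, and guarantees the anchored (non-empty
#' ref and alt) representation used throughout the package.
#'
#' @param genome a `GenomeSequence`.
#' @param position 0-based position.
#' @param ref,alt alleles.
#' @return list with normalized `position`, `ref`, `alt`.
#' @export
normalize_variant <- function(genome, position, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  last <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L && last(ref) == last(alt) &&
        !(nchar(ref) == 1L && nchar(alt) == 1L)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    } else if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (position == 0L) stop("cannot left-align past the contig start")
      prev <- substr(genome$sequence, position, position)  # base at position-1
      ref <- paste0(prev, ref); alt <- paste0(prev, alt)
      position <- position - 1L
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    position <- position + 1L
  }
  list(position = as.integer(position), ref = ref, alt = alt)
}

#' Write variant records to a VCF 4.2 file
#'
#' Minimal writer: CHROM/POS/ID/REF/ALT plus an `AF` INFO field when a
#' population frequency named `AF` is present.
#'
#' @param variants list of `VariantRecord`s.
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (v in variants) {
    af <- if (!is.null(v$population_frequencies) &&
              "AF" %in% names(v$population_frequencies))
      sprintf("AF=%g", v$population_frequencies[["AF"]]) else "."
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s", v$contig_id,
                       v$position + 1L,
                       ifelse(is.na(v$variant_id), ".", v$variant_id),
                       v$ref, v$alt, af), con)
  }
  invisible(path)
}

#' Read variant records from a VCF file
#'
#' Backed by `VariantAnnotation::readVcf`; multi-allelic rows are expanded to
#' one record per alternate allele. An `AF` INFO field, when present, is
#' stored under `population_frequencies$AF`.
#'
#' @param path VCF file.
#' @return list of `VariantRecord`s.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF files")
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  info <- VariantAnnotation::info(vcf)
  ids <- names(rr)
  out <- vector("list", length(rr))
  for (i in seq_along(rr)) {
    af <- NULL
    if ("AF" %in% names(info)) {
      a <- info$AF[[i]]
      if (length(a) >= 1L && !is.na(a[1L])) af <- c(AF = as.numeric(a[1L]))
    }
    out[[i]] <- variant_record(
      as.character(GenomicRanges::seqnames(rr)[i]),
      GenomicRanges::start(rr)[i] - 1L, ref[i], alt[i],
      variant_id = if (is.null(ids) || ids[i] == "") NA_character_ else ids[i],
      population_frequencies = af)
  }
  out
}

#' Write a table as TSV with fixed column order
#'
#' UTF-8, LF line endings, header row, no quoting or row names. An empty
#' table produces a header-only file.
#'
#' @param df data.frame.
#' @param path output path.
#' @param columns optional character vector fixing column order (must all be
#'   present in `df`).
#' @export
write_tsv_report <- function(df, path, columns = NULL) {
  if (!is.null(columns)) {
    if (!all(columns %in% names(df))) stop("table does not match report schema")
    df <- df[, columns, drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write per-variant consequence calls as TSV
#'
#' Columns: variant_id, transcript_id, consequence, protein_change.
#' @param calls data.frame of consequence calls.
#' @param path output path.
#' @export
write_consequence_tsv <- function(calls, path) {
  write_tsv_report(calls, path,
                   c("variant_id", "transcript_id", "consequence", "protein_change"))
}
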