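## Seeded generators for every pipeline input: a toy two-gene locus with a
## readthrough fusion, variants, stranded single-end reads, an MSA with known
## per-column conservation, and toy multi-chain coordinates with a known
## contact graph. Every generator is a pure function of (config, seed); the
## global seed fans out to per-generator substreams.

# fixed layout of the toy locus (0-based half-open genomic coordinates).
# Gene A: three isoforms -- A-201 (primary), A-202 (extra 3'UTR exon =>
# NMD-structured), A-203 (shortened middle exon => frameshift, stop-free).
# Gene B downstream on the same strand; FUS-201 is the A->B readthrough
# fusion whose junction lands in B's 5'UTR in a shifted frame.
locus_layout <- function() {
  list(
    contig = "chrT", genome_length = 3100L,
    exons = list(
      "A-201" = rbind(c(100L, 300L), c(400L, 700L), c(800L, 1100L)),
      "A-202" = rbind(c(100L, 300L), c(400L, 700L), c(800L, 1000L),
                      c(1100L, 1250L)),
      "A-203" = rbind(c(100L, 300L), c(400L, 650L), c(800L, 1100L)),
      "B-201" = rbind(c(2000L, 2200L), c(2300L, 2600L), c(2700L, 2900L))),
    gene = c("A-201" = "GENEA", "A-202" = "GENEA", "A-203" = "GENEA",
             "B-201" = "GENEB"),
    cds = list("A-201" = c(150L, 630L), "A-202" = c(150L, 630L),
               "A-203" = c(150L, 750L),   # stop-free, runs to transcript end
               "B-201" = c(250L, 550L)),
    cds_partial = c("A-201" = FALSE, "A-202" = FALSE, "A-203" = TRUE,
                    "B-201" = FALSE),
    fusion = list(id = "FUS-201", gene = "GENEA--GENEB", donor = "A-201",
                  acceptor = "B-201", donor_break = 480L,
                  acceptor_start = 101L, cds = c(150L, 933L)))
}

#' Default simulation configuration
#'
#' The stated world of the simulators: isoform proportions
#' (0.50, 0.25, 0.15, 0.07, 0.03) over the five locus transcripts with the
#' primary isoform dominant, 100-nt single-end reads at a 0.5% per-base
#' error rate, a heterozygous (0.5) alternate-allele ratio on the primary
#' isoform's 3'UTR variant pair, a 200-row MSA with a fixed per-column
#' conservation pattern, and a three-chain toy structure with two interface
#' contacts and one Zn site.
#'
#' @param seed integer master seed; each generator derives its own substream.
#' @param ... named overrides merged into the defaults (nested lists are
#'   replaced per-field).
#' @return `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    proportions = c("A-201" = 0.50, "A-202" = 0.25, "A-203" = 0.15,
                    "B-201" = 0.07, "FUS-201" = 0.03),
    variants = list(
      v_5utr = list(gpos = 160L),          # gene A 5'UTR
      v_3utr_a = list(gpos = 940L),        # gene A 3'UTR (phase pair, 10 bp)
      v_3utr_b = list(gpos = 950L),
      v_cds = list(gpos = 505L),           # inside gene A CDS
      v_splice_region = list(gpos = 304L), # 5th intronic base after exon 1
      v_splice_site = list(gpos = 301L),   # 2nd intronic base after exon 1
      v_intronic = list(gpos = 360L)),
    reads = list(n_reads = 20000L, read_length = 100L, error_rate = 0.005,
                 # the 3'UTR het is genomic, so every gene-A isoform
                 # containing the site carries it on the alternate haplotype
                 haplotypes = list(
                   list(transcript = "A-201", variants = c("v_3utr_a"),
                        alt_ratio = 0.5),
                   list(transcript = "A-202", variants = c("v_3utr_a"),
                        alt_ratio = 0.5),
                   list(transcript = "A-203", variants = c("v_3utr_a"),
                        alt_ratio = 0.5))),
    msa = list(n_rows = 200L, n_cols = 60L,
               probabilities = rep(c(1, 0.95, 0.9, 0.8, 0.5), length.out = 60L)),
    structure = list(
      chains = list(A = 8L, B = 8L, C = 8L),
      contacts = list(c("A", 2L, "B", 3L), c("B", 5L, "C", 1L)),
      metal = list(element = "ZN", chain = "A",
                   residues = c(4L, 6L, 7L))))
  # one-level merge: named fields of a block are replaced wholesale (a
  # recursive modifyList would silently skip unnamed lists like `haplotypes`)
  override <- list(...)
  for (nm in names(override)) {
    if (is.list(cfg[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      for (k in names(override[[nm]])) cfg[[nm]][k] <- list(override[[nm]][[k]])
    } else cfg[[nm]] <- override[[nm]]
  }
  stopifnot(abs(sum(cfg$proportions) - 1) < 1e-12,
            cfg$reads$error_rate >= 0, cfg$reads$error_rate <= 0.2,
            cfg$reads$n_reads > 0L)
  structure(cfg, class = "SimulationConfig")
}

substream <- function(seed, offset) (as.integer(seed) * 97L + offset) %% .Machine$integer.max

# genomic position of the middle base of a stop codon found at transcript
# codon-start `tpos` of `model`
destroy_stop_edit <- function(model, tpos) tx_to_genome(model, tpos + 1L)

#' Simulate the toy two-gene locus
#'
#' Generates a random genome, then stamps start/stop codons and repairs stray
#' in-frame stops so that, for any seed: the primary isoform translates a
#' clean ORF ending in the last exon (normal), the extra-3'UTR-exon isoform
#' is NMD-structured, the frameshifted isoform reaches the transcript end
#' without a stop (nonstop), gene B translates a clean ORF, and the fusion
#' ORF crosses the junction in a frame shifted from gene B's and stops in the
#' last exon. Repairs replace the middle base of an offending stop codon
#' with C, which can never create a stop codon in any frame.
#'
#' @param cfg a `SimulationConfig`.
#' @return list with `genome`, `models` (named `TranscriptModel` list,
#'   fusion included), `sequences`, `variants` (named `VariantRecord` list),
#'   `fusion` (junction bookkeeping), `decay_truth`.
#' @export
simulate_locus <- function(cfg) {
  lay <- locus_layout()
  set.seed(substream(cfg$seed, 1L))
  g <- paste(sample(c("A", "C", "G", "T"), lay$genome_length, replace = TRUE),
             collapse = "")
  put <- function(s, pos0, what) {  # overwrite bases at 0-based pos0
    paste0(substr(s, 1L, pos0), what, substr(s, pos0 + nchar(what) + 1L, nchar(s)))
  }
  # start codons, designed stops, and C guards flanking each stop so that no
  # other-frame codon overlapping a stop can itself be a stop
  g <- put(g, 250L, "ATG")              # gene A CDS start (tx 150 on A-201)
  g <- put(g, 2350L, "ATG")             # gene B CDS start (tx 250)
  g <- put(g, 926L, "C"); g <- put(g, 927L, "TAA"); g <- put(g, 930L, "C")
  g <- put(g, 2746L, "C"); g <- put(g, 2747L, "TAA"); g <- put(g, 2750L, "C")
  g <- put(g, 2751L, "TGA"); g <- put(g, 2754L, "C")

  build_models <- function(genome) {
    models <- list()
    for (id in names(lay$exons)) {
      models[[id]] <- transcript_model(id, lay$gene[[id]], lay$contig, "+",
                                       lay$exons[[id]],
                                       cds_span = lay$cds[[id]],
                                       cds_partial = lay$cds_partial[[id]])
    }
    seqs <- vapply(models, function(m) extract_transcript_sequence(genome, m),
                   character(1))
    fus <- build_readthrough_transcript(
      models[[lay$fusion$donor]], models[[lay$fusion$acceptor]],
      seqs[[lay$fusion$donor]], seqs[[lay$fusion$acceptor]],
      lay$fusion$donor_break, lay$fusion$acceptor_start,
      transcript_id = lay$fusion$id, gene_id = lay$fusion$gene)
    fus_model <- transcript_model(lay$fusion$id, lay$fusion$gene, lay$contig,
                                  "+", fus$model$exons,
                                  cds_span = lay$fusion$cds)
    models[[lay$fusion$id]] <- fus_model
    seqs[[lay$fusion$id]] <- fus$sequence
    list(models = models, seqs = seqs)
  }

  # constraints: (transcript, no-stop codon-start range [from, to) in tx coords)
  constraints <- list(
    list(id = "A-201", from = 150L, to = 627L),
    list(id = "B-201", from = 250L, to = 547L),
    list(id = "A-203", from = 150L, to = 750L),
    list(id = "FUS-201", from = 150L, to = 930L))
  for (pass in 1:10) {
    built <- build_models(genome_sequence(lay$contig, g))
    edits <- integer(0)
    for (cn in constraints) {
      seq <- built$seqs[[cn$id]]
      starts <- seq(cn$from, cn$to - 3L, by = 3L)
      codons <- substring(seq, starts + 1L, starts + 3L)
      bad <- starts[codons %in% STOP_CODONS]
      for (b in bad) edits <- c(edits, destroy_stop_edit(built$models[[cn$id]], b))
    }
    if (length(edits) == 0L) break
    for (e in unique(edits)) g <- put(g, e, "C")
  }
  if (length(edits) != 0L) stop("stop-codon repair did not converge")
  genome <- genome_sequence(lay$contig, g)
  built <- build_models(genome)

  # variants: alt allele is the cyclic successor of the reference base
  succ <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  variants <- list()
  for (nm in names(cfg$variants)) {
    p <- cfg$variants[[nm]]$gpos
    ref <- substr(g, p + 1L, p + 1L)
    variants[[nm]] <- variant_record(lay$contig, p, ref, succ[[ref]],
                                     variant_id = nm)
  }

  decay_truth <- c("A-201" = "normal", "A-202" = "nmd_predicted",
                   "A-203" = "nonstop_predicted", "B-201" = "normal",
                   "FUS-201" = "normal")
  list(genome = genome, models = built$models, sequences = built$seqs,
       variants = variants,
       fusion = list(transcript_id = lay$fusion$id,
                     junction_offset = lay$fusion$donor_break,
                     donor = lay$fusion$donor, acceptor = lay$fusion$acceptor,
                     acceptor_start = lay$fusion$acceptor_start),
       decay_truth = decay_truth, layout = lay)
}

#' Simulate stranded single-end reads with ground truth
#'
#' Reads are drawn over isoforms with weight proportional to
#' `proportion * (length - read_length + 1)` (the number of valid start
#' positions, i.e. the same effective-length measure the quantifier uses),
#' start positions uniform, alternate-haplotype membership Bernoulli at the
#' configured ratio, and i.i.d. per-base substitution errors.
#'
#' @param cfg a `SimulationConfig`.
#' @param locus output of [simulate_locus()].
#' @return list with `reads` (named character vector), `truth` (data.frame:
#'   `read_id`, `transcript`, `start`, `haplotype`), `proportions`,
#'   `haplotype_sequences` (ref/alt sequence pairs for transcripts carrying
#'   variants).
#' @export
simulate_reads <- function(cfg, locus) {
  set.seed(substream(cfg$seed, 2L))
  L <- cfg$reads$read_length
  props <- cfg$proportions
  seqs <- locus$sequences[names(props)]
  if (any(nchar(seqs) < L)) stop("read length exceeds a transcript length")

  hap <- list()   # per transcript: list(alt_seq, alt_ratio)
  for (h in cfg$reads$haplotypes) {
    tx <- locus$models[[h$transcript]]
    edits <- do.call(rbind, lapply(h$variants, function(vn) {
      pv <- project_variant(locus$variants[[vn]], tx)
      if (is.null(pv)) stop("haplotype variant not exonic on ", h$transcript)
      data.frame(pos = pv$position, ref = pv$ref, alt = pv$alt,
                 stringsAsFactors = FALSE)
    }))
    hap[[h$transcript]] <- list(
      alt_seq = inject_haplotype(seqs[[h$transcript]], edits),
      alt_ratio = h$alt_ratio)
  }

  w <- props * (nchar(seqs) - L + 1)
  w <- w / sum(w)
  n <- cfg$reads$n_reads
  src <- sample(names(props), n, replace = TRUE, prob = w)
  starts <- integer(n)
  is_alt <- logical(n)
  out <- character(n)
  for (id in names(props)) {
    sel <- which(src == id)
    if (length(sel) == 0L) next
    starts[sel] <- sample.int(nchar(seqs[[id]]) - L + 1L, length(sel),
                              replace = TRUE) - 1L
    if (!is.null(hap[[id]]))
      is_alt[sel] <- runif(length(sel)) < hap[[id]]$alt_ratio
    ref_part <- substring(seqs[[id]], starts[sel] + 1L, starts[sel] + L)
    if (!is.null(hap[[id]])) {
      alt_part <- substring(hap[[id]]$alt_seq, starts[sel] + 1L, starts[sel] + L)
      out[sel] <- ifelse(is_alt[sel], alt_part, ref_part)
    } else out[sel] <- ref_part
  }
  e <- cfg$reads$error_rate
  if (e > 0) {
    chars <- strsplit(out, "")
    others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
    out <- vapply(chars, function(cc) {
      hit <- which(runif(length(cc)) < e)
      for (i in hit) cc[i] <- sample(others[[cc[i]]], 1L)
      paste(cc, collapse = "")
    }, character(1))
  }
  ids <- sprintf("read%06d", seq_len(n))
  truth <- data.frame(read_id = ids, transcript = src, start = starts,
                      haplotype = ifelse(is_alt, "alt", "ref"),
                      stringsAsFactors = FALSE)
  list(reads = setNames(out, ids), truth = truth, proportions = props,
       haplotype_sequences = hap)
}

#' Ground-truth junction-spanning read count
#'
#' Number of reads whose source interval overlaps the junction by at least
#' `min_overlap` bases on each side, computed from simulation truth.
#'
#' @param truth the `truth` data.frame from [simulate_reads()].
#' @param fusion_id fusion transcript id.
#' @param junction_offset junction position in fusion transcript coordinates.
#' @param read_length read length.
#' @param min_overlap required overlap per side.
#' @return integer count.
#' @export
true_junction_spanning <- function(truth, fusion_id, junction_offset,
                                   read_length, min_overlap = 10L) {
  f <- truth[truth$transcript == fusion_id, , drop = FALSE]
  sum(f$start <= junction_offset - min_overlap &
      f$start + read_length >= junction_offset + min_overlap)
}

#' Simulate a multiple sequence alignment with known column conservation
#'
#' The reference row is random; every other row matches the reference at
#' column j with probability p_j and otherwise draws uniformly from the
#' three alternative bases.
#'
#' @param cfg a `SimulationConfig`.
#' @return list with `alignment` (named rows, reference first, named
#'   `"ref"`), `probabilities`.
#' @export
simulate_msa <- function(cfg) {
  set.seed(substream(cfg$seed, 3L))
  p <- cfg$msa$probabilities
  nc <- cfg$msa$n_cols
  stopifnot(length(p) == nc, all(p >= 0 & p <= 1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nc, replace = TRUE)
  rows <- list(ref = paste(ref, collapse = ""))
  for (r in seq_len(cfg$msa$n_rows - 1L)) {
    keep <- runif(nc) < p
    row <- ref
    for (j in which(!keep)) row[j] <- sample(setdiff(bases, ref[j]), 1L)
    rows[[sprintf("sp%03d", r)]] <- paste(row, collapse = "")
  }
  list(alignment = unlist(rows), probabilities = p)
}

#' Simulate toy multi-chain coordinates with a known contact graph
#'
#' Residues are one-CA-atom beads on a coarse grid (all pairwise distances
#' >= 6 A). Each configured contact pair is relocated to a dedicated site
#' with the two beads 3.5 A apart; the optional metal site places a Zn
#' HETATM with an extra N donor atom at 2.1 A for each designated residue of
#' a single chain. A residue may appear in at most one contact pair
#' (generation error otherwise -- documented limit).
#'
#' @param cfg a `SimulationConfig`.
#' @return list with `pdb_lines`, `true_contacts` (data.frame `chain_i`,
#'   `resnum_i`, `chain_j`, `resnum_j`), `true_coordination` (data.frame
#'   `chain`, `resnum`).
#' @export
simulate_structure <- function(cfg) {
  sc <- cfg$structure
  used <- character(0)
  for (ct in sc$contacts) {
    keys <- c(paste(ct[[1]], ct[[2]]), paste(ct[[3]], ct[[4]]))
    if (any(keys %in% used))
      stop("infeasible geometry: a residue may join at most one contact pair")
    used <- c(used, keys)
  }
  pos <- list()  # chain|resnum -> c(x,y,z) of the CA bead
  for (ci in seq_along(sc$chains)) {
    ch <- names(sc$chains)[ci]
    for (r in seq_len(sc$chains[[ci]]))
      pos[[paste(ch, r)]] <- c(ci * 50, r * 10, 0)
  }
  for (pi in seq_along(sc$contacts)) {
    ct <- sc$contacts[[pi]]
    base <- c(1000 + pi * 50, 0, 0)
    pos[[paste(ct[[1]], ct[[2]])]] <- base
    pos[[paste(ct[[3]], ct[[4]])]] <- base + c(3.5, 0, 0)
  }
  lines <- character(0)
  serial <- 0L
  fmt <- "%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  emit <- function(rec, atom, resname, chain, resnum, xyz, element) {
    serial <<- serial + 1L
    lines <<- c(lines, sprintf(fmt, rec, serial, atom, resname, chain, resnum,
                               xyz[1], xyz[2], xyz[3], 1, 0, element))
  }
  for (ci in seq_along(sc$chains)) {
    ch <- names(sc$chains)[ci]
    for (r in seq_len(sc$chains[[ci]]))
      emit("ATOM", "CA", "GLY", ch, r, pos[[paste(ch, r)]], "C")
  }
  true_coord <- data.frame(chain = character(0), resnum = integer(0))
  if (!is.null(sc$metal)) {
    zn <- c(-500, 0, 0)   # stays within the fixed-width coordinate field
    dirs <- list(c(2.1, 0, 0), c(0, 2.1, 0), c(0, 0, 2.1), c(-2.1, 0, 0))
    if (length(sc$metal$residues) > length(dirs))
      stop("infeasible geometry: at most ", length(dirs), " metal donors")
    for (i in seq_along(sc$metal$residues))
      emit("ATOM", "ND1", "HIS", sc$metal$chain, sc$metal$residues[i],
           zn + dirs[[i]], "N")
    emit("HETATM", "ZN", "ZN", "Z", 999L, zn, sc$metal$element)
    true_coord <- data.frame(chain = sc$metal$chain,
                             resnum = as.integer(sc$metal$residues),
                             stringsAsFactors = FALSE)
  }
  lines <- c(lines, "END")
  true_contacts <- do.call(rbind, lapply(sc$contacts, function(ct) {
    a <- data.frame(chain_i = ct[[1]], resnum_i = as.integer(ct[[2]]),
                    chain_j = ct[[3]], resnum_j = as.integer(ct[[4]]),
                    stringsAsFactors = FALSE)
    # canonical order
    if (a$chain_j < a$chain_i) a[, ] <- a[, c(3, 4, 1, 2)]
    a
  }))
  if (is.null(true_contacts))
    true_contacts <- data.frame(chain_i = character(0), resnum_i = integer(0),
                                chain_j = character(0), resnum_j = integer(0))
  list(pdb_lines = lines, true_contacts = true_contacts,
       true_coordination = true_coord)
}
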