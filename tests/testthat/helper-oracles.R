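# Independent brute-force oracles. These deliberately avoid the package's
# compiled code paths and k-mer machinery: plain R loops and string ops only.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# standard genetic code as a plain named vector (independent of Biostrings)
ORACLE_CODE <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)
  aa <- c(
    AAA = "K", AAC = "N", AAG = "K", AAT = "N", ACA = "T", ACC = "T",
    ACG = "T", ACT = "T", AGA = "R", AGC = "S", AGG = "R", AGT = "S",
    ATA = "I", ATC = "I", ATG = "M", ATT = "I", CAA = "Q", CAC = "H",
    CAG = "Q", CAT = "H", CCA = "P", CCC = "P", CCG = "P", CCT = "P",
    CGA = "R", CGC = "R", CGG = "R", CGT = "R", CTA = "L", CTC = "L",
    CTG = "L", CTT = "L", GAA = "E", GAC = "D", GAG = "E", GAT = "D",
    GCA = "A", GCC = "A", GCG = "A", GCT = "A", GGA = "G", GGC = "G",
    GGG = "G", GGT = "G", GTA = "V", GTC = "V", GTG = "V", GTT = "V",
    TAA = "*", TAC = "Y", TAG = "*", TAT = "Y", TCA = "S", TCC = "S",
    TCG = "S", TCT = "S", TGA = "*", TGC = "C", TGG = "W", TGT = "C",
    TTA = "L", TTC = "F", TTG = "L", TTT = "F")
  aa[codons]
})

oracle_translate <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  paste(ORACLE_CODE[substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))],
        collapse = "")
}

# exhaustive ATG-initiated ORF scan over all start positions
oracle_longest_orf <- function(s) {
  best <- NULL
  for (p in seq_len(nchar(s) - 2L)) {
    if (substr(s, p, p + 2L) != "ATG") next
    aa <- oracle_translate(substr(s, p, nchar(s)))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    n_aa <- if (stop_at > 0L) stop_at - 1L else nchar(aa)
    has_stop <- stop_at > 0L
    if (is.null(best) || n_aa > best$n_aa)
      best <- list(start = p - 1L, n_aa = n_aa, has_stop = has_stop,
                   protein = substr(aa, 1L, n_aa))
  }
  best
}

# left-to-right haplotype application with explicit offset bookkeeping
oracle_inject <- function(seq, edits) {
  edits <- edits[order(edits$pos), , drop = FALSE]
  shift <- 0L
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i] + shift
    stopifnot(substr(seq, p + 1L, p + nchar(edits$ref[i])) == edits$ref[i])
    seq <- paste0(substr(seq, 1L, p), edits$alt[i],
                  substr(seq, p + nchar(edits$ref[i]) + 1L, nchar(seq)))
    shift <- shift + nchar(edits$alt[i]) - nchar(edits$ref[i])
  }
  seq
}

oracle_kmers <- function(s, k) {
  if (nchar(s) < k) return(character(0))
  substring(s, seq_len(nchar(s) - k + 1L), seq_len(nchar(s) - k + 1L) + k - 1L)
}

oracle_decay <- function(junctions, stop_end, stop_reached, threshold = 50L) {
  if (!stop_reached) return("nonstop_predicted")
  if (length(junctions) == 0L) return("normal")
  if (max(junctions) - stop_end > threshold) "nmd_predicted" else "normal"
}

oracle_hamming_scan <- function(probe, subjects, max_mm) {
  m <- nchar(probe)
  pv <- strsplit(probe, "")[[1L]]
  rv <- strsplit(oracle_revcomp(probe), "")[[1L]]
  hits <- 0L
  details <- list()
  for (s in seq_along(subjects)) {
    sv <- strsplit(subjects[[s]], "")[[1L]]
    n <- length(sv)
    for (o in 0:(n - m)) {
      win <- sv[(o + 1):(o + m)]
      mmF <- sum(win != pv); mmR <- sum(win != rv)
      if (mmF <= max_mm)
        details[[length(details) + 1L]] <- c(s, o, 1L, mmF)
      if (mmR <= max_mm)
        details[[length(details) + 1L]] <- c(s, o, 2L, mmR)
    }
  }
  if (length(details) == 0L)
    return(data.frame(seq_index = integer(0), offset = integer(0),
                      strand = character(0), mismatches = integer(0)))
  d <- do.call(rbind, details)
  data.frame(seq_index = d[, 1], offset = d[, 2],
             strand = c("+", "-")[d[, 3]], mismatches = d[, 4])
}

oracle_junction_count <- function(reads, probe, flank, min_overlap, max_mm) {
  m <- nchar(probe)
  count <- 0L
  for (rd in reads) {
    counted <- FALSE
    for (seq in c(rd, oracle_revcomp(rd))) {
      n <- nchar(seq)
      for (o in (-(m - 1L)):(n - 1L)) {
        lo <- max(0L, -o); hi <- min(m, n - o)
        if (hi <= lo) next
        donor <- max(0L, min(hi, flank) - lo)
        acceptor <- max(0L, hi - max(lo, flank))
        if (donor < min_overlap || acceptor < min_overlap) next
        read_part <- substr(seq, o + lo + 1L, o + hi)
        probe_part <- substr(probe, lo + 1L, hi)
        mm <- sum(strsplit(read_part, "")[[1L]] != strsplit(probe_part, "")[[1L]])
        if (mm <= max_mm) { counted <- TRUE; break }
      }
      if (counted) break
    }
    if (counted) count <- count + 1L
  }
  count
}

# all-pairs inter-chain residue contacts from an atom table
oracle_contacts <- function(atoms, cutoff) {
  atoms <- atoms[atoms$element != "H" & !atoms$het, , drop = FALSE]
  out <- character(0)
  n <- nrow(atoms)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (atoms$chain[i] == atoms$chain[j]) next
    d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
              (atoms$z[i] - atoms$z[j])^2)
    if (d <= cutoff) {
      a <- c(atoms$chain[i], atoms$resnum[i]); b <- c(atoms$chain[j], atoms$resnum[j])
      if (b[1] < a[1]) { tmp <- a; a <- b; b <- tmp }
      out <- c(out, paste(a[1], a[2], b[1], b[2]))
    }
  }
  sort(unique(out))
}

contact_keys <- function(ct) {
  if (nrow(ct) == 0L) return(character(0))
  sort(unique(paste(ct$chain_i, ct$resnum_i, ct$chain_j, ct$resnum_j)))
}

# random DNA of length n
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
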