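## Lightweight k-mer equivalence-class EM quantifier, allele fractions,
## genotype classes, phase checks and gene-level rollups.

#' Build a k-mer index over a transcript set
#'
#' Every transcript of length >= k contributes length - k + 1 k-mer
#' occurrences; shorter sequences are dropped with a warning. Effective
#' length is `max(length - mean_fragment_length + 1, 1)`; when
#' `mean_fragment_length` is `NA` it is taken from the mean read length at
#' assignment time.
#'
#' @param sequences named character vector of transcript sequences
#'   (haplotype-injected duplicates must carry distinct names).
#' @param k k-mer length (default 31, must be <= 32).
#' @param mean_fragment_length fragment length for effective lengths.
#' @return object of class `KmerIndex`.
#' @export
build_index <- function(sequences, k = 31L, mean_fragment_length = NA_real_) {
  stopifnot(k >= 1L, k <= 32L)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names")
  sequences <- toupper(sequences)
  short <- nchar(sequences) < k
  if (any(short)) {
    warning("dropping ", sum(short), " sequence(s) shorter than k")
    sequences <- sequences[!short]
  }
  if (length(sequences) == 0L) stop("no sequence of length >= k")
  structure(list(k = as.integer(k), tx_ids = names(sequences),
                 sequences = unname(sequences),
                 lengths = unname(nchar(sequences)),
                 mean_fragment_length = mean_fragment_length),
            class = "KmerIndex")
}

#' Effective transcript lengths of an index
#' @param index a `KmerIndex`.
#' @param mean_fragment_length overrides the index value when given.
#' @return named numeric vector.
#' @export
effective_lengths <- function(index, mean_fragment_length = NULL) {
  mfl <- if (!is.null(mean_fragment_length)) mean_fragment_length
         else index$mean_fragment_length
  if (is.na(mfl)) stop("mean fragment length unknown; pass it explicitly")
  setNames(pmax(index$lengths - mfl + 1, 1), index$tx_ids)
}

#' k-mer to transcript-set map (inspection helper)
#'
#' Materialises the full k-mer map as a data.frame; intended for small
#' fixtures and tests, not for full-size runs.
#' @param index a `KmerIndex`.
#' @return data.frame with columns `kmer` and `transcripts` (comma-joined ids).
#' @export
kmer_transcript_map <- function(index) {
  df <- cpp_kmer_transcript_map(index$sequences, index$k)
  df$transcripts <- vapply(strsplit(df$transcripts, ","), function(i)
    paste(index$tx_ids[as.integer(i)], collapse = ","), character(1))
  df
}

#' Assign reads to transcript equivalence classes
#'
#' A read is compatible with a transcript when at least `compat_fraction` of
#' its k-mers occur in that transcript; both the read and its reverse
#' complement are evaluated and the better orientation kept. The equivalence
#' class of a read is its compatible transcript set; the empty set is counted
#' as unassigned.
#'
#' @param reads character vector of read sequences, or a FASTQ path.
#' @param index a `KmerIndex`.
#' @param compat_fraction compatibility threshold (default 0.8).
#' @return object of class `EquivalenceClassCounts`: `classes` (list of
#'   transcript-id vectors), `counts`, `unassigned`, `n_reads`,
#'   `mean_read_length`.
#' @export
assign_reads <- function(reads, index, compat_fraction = 0.8) {
  if (length(reads) == 1L && !is_dna(reads[1L]) && file.exists(reads[1L]))
    reads <- read_fastq(reads)
  if (length(reads) == 0L) {
    return(structure(list(classes = list(), counts = integer(0),
                          unassigned = 0L, n_reads = 0L,
                          mean_read_length = NA_real_),
                     class = "EquivalenceClassCounts"))
  }
  res <- cpp_assign_reads(index$sequences, unname(toupper(reads)), index$k,
                          compat_fraction)
  classes <- lapply(res$classes, function(i) index$tx_ids[i])
  structure(list(classes = classes, counts = res$counts,
                 unassigned = res$unassigned, n_reads = res$n_reads,
                 mean_read_length = mean(nchar(reads))),
            class = "EquivalenceClassCounts")
}

#' EM abundance estimation over equivalence classes
#'
#' Equivalence-class EM with uniform initialisation; converged when the
#' largest absolute change of any transcript proportion falls below `tol`
#' (default 1e-8) or after `max_iter` iterations. With
#' `position_weights = TRUE` (the default) each transcript's probability of
#' generating each class is computed exactly by assigning all of its
#' error-free read-length windows through the same compatibility rule,
#' which removes the bias of the plain class-share EM on heavily shared
#' transcript sets; plain alpha-share EM (`position_weights = FALSE`)
#' behaves identically on symmetric classes. TPM is computed from rates
#' `count / effective_length` normalised to 1e6; per-gene percent usage is
#' TPM-proportional within each gene.
#'
#' @param counts an `EquivalenceClassCounts`.
#' @param index the `KmerIndex` the reads were assigned against.
#' @param gene_ids optional named vector mapping transcript id -> gene id
#'   (default: single gene `"gene"`).
#' @param mean_fragment_length effective-length fragment size; defaults to
#'   the observed mean read length.
#' @param position_weights use exact per-transcript class-generation
#'   probabilities (see above).
#' @param compat_fraction compatibility threshold used for the window
#'   assignment when `position_weights = TRUE`.
#' @param max_iter,tol convergence controls.
#' @return `AbundanceTable`: data.frame with `transcript_id`, `est_count`,
#'   `tpm`, `gene_id`, `pct_usage`; attributes `gene_tpm`, `loglik` (per
#'   iteration), `n_iter`.
#' @export
em_abundance <- function(counts, index, gene_ids = NULL,
                         mean_fragment_length = NULL, position_weights = TRUE,
                         compat_fraction = 0.8, max_iter = 1000L,
                         tol = 1e-8) {
  if (length(counts$counts) == 0L || sum(counts$counts) == 0L)
    stop("all reads unassigned: no abundance to estimate")
  tx <- index$tx_ids
  nt <- length(tx)
  if (is.null(gene_ids)) gene_ids <- setNames(rep("gene", nt), tx)
  mfl <- if (!is.null(mean_fragment_length)) mean_fragment_length
         else if (!is.na(index$mean_fragment_length)) index$mean_fragment_length
         else counts$mean_read_length
  eff <- pmax(index$lengths - mfl + 1, 1)

  cls <- lapply(counts$classes, function(ids) match(ids, tx))
  n_c <- as.numeric(counts$counts)
  N <- sum(n_c)

  # W[c, t]: probability that an error-free read of transcript t falls in
  # class c, from exhaustive window assignment; classes never produced by
  # windows of any member transcript fall back to uniform weights.
  W <- matrix(0, nrow = length(cls), ncol = nt)
  if (position_weights) {
    L <- as.integer(round(mfl))
    key <- vapply(cls, paste, character(1), collapse = ",")
    for (t in seq_len(nt)) {
      n_t <- nchar(index$sequences[t])
      Lw <- min(L, n_t)
      starts <- seq_len(n_t - Lw + 1L)
      wins <- substring(index$sequences[t], starts, starts + Lw - 1L)
      res <- cpp_assign_reads(index$sequences, wins, index$k, compat_fraction)
      wkey <- vapply(res$classes, paste, character(1), collapse = ",")
      hit <- match(wkey, key)
      ok <- !is.na(hit)
      W[hit[ok], t] <- res$counts[ok] / length(wins)
    }
    for (ci in seq_along(cls)) {
      if (all(W[ci, cls[[ci]]] == 0)) W[ci, cls[[ci]]] <- 1 / eff[cls[[ci]]]
    }
  } else {
    for (ci in seq_along(cls)) W[ci, cls[[ci]]] <- 1
  }

  alpha <- rep(1 / nt, nt)
  loglik <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- as.numeric(W %*% alpha)
    loglik <- c(loglik, sum(n_c * log(denom)))
    new_alpha <- alpha * as.numeric(crossprod(W, n_c / denom))
    new_alpha <- new_alpha / sum(new_alpha)
    delta <- max(abs(new_alpha - alpha))
    alpha <- new_alpha
    if (delta < tol || iter >= max_iter) break
  }

  est_count <- alpha * N
  rate <- est_count / eff
  tpm <- rate / sum(rate) * 1e6
  gene <- unname(gene_ids[tx])
  gene_tpm <- tapply(tpm, gene, sum)
  pct <- 100 * tpm / as.numeric(gene_tpm[gene])
  pct[is.nan(pct)] <- 0
  out <- data.frame(transcript_id = tx, est_count = est_count, tpm = tpm,
                    gene_id = gene, pct_usage = pct, stringsAsFactors = FALSE)
  attr(out, "gene_tpm") <- gene_tpm
  attr(out, "loglik") <- loglik
  attr(out, "n_iter") <- iter
  class(out) <- c("AbundanceTable", "data.frame")
  out
}

# k-mers of `seq` whose window covers position `pos` (0-based), as characters
site_spanning_kmers <- function(seq, pos, k, width = 1L) {
  n <- nchar(seq)
  lo <- max(0L, pos + width - k)          # leftmost start covering the site
  hi <- min(pos, n - k)
  if (hi < lo) return(character(0))
  starts <- lo:hi
  substring(seq, starts + 1L, starts + k)
}

read_kmers <- function(read, k) {
  n <- nchar(read)
  if (n < k) return(character(0))
  starts <- 0:(n - k)
  substring(read, starts + 1L, starts + k)
}

#' Genotype label from an alt fraction
#'
#' @param alt_fraction fraction of informative reads supporting the alternate
#'   allele (`NA` when no informative reads).
#' @param thresholds named list: hom_ref (<=), het range, hom_alt (>=).
#' @return one of `"hom-ref"`, `"het"`, `"hom-alt"`, `"ambiguous"`,
#'   `"uninformative"`.
#' @export
genotype_label <- function(alt_fraction,
                           thresholds = list(hom_ref = 0.1, het = c(0.2, 0.8),
                                             hom_alt = 0.9)) {
  if (is.na(alt_fraction)) return("uninformative")
  if (alt_fraction <= thresholds$hom_ref) return("hom-ref")
  if (alt_fraction >= thresholds$hom_alt) return("hom-alt")
  if (alt_fraction >= thresholds$het[1] && alt_fraction <= thresholds$het[2])
    return("het")
  "ambiguous"
}

#' Combine per-variant genotype labels into a sample-level class
#'
#' Mirrors the sample classes of variant-combination tables: `"WT"` when
#' every variant is hom-ref, `"het-single"`/`"hom-single"` when exactly one
#' variant is non-reference, `"compound-het"` when two or more are.
#' Uninformative variants are ignored; any ambiguous call makes the sample
#' `"ambiguous"`.
#'
#' @param genotypes character vector of per-variant labels from
#'   [genotype_label()].
#' @return single class label.
#' @export
sample_genotype_class <- function(genotypes) {
  if (any(genotypes == "ambiguous")) return("ambiguous")
  g <- genotypes[genotypes != "uninformative"]
  nonref <- g[g != "hom-ref"]
  if (length(nonref) == 0L) return("WT")
  if (length(nonref) == 1L)
    return(if (nonref == "het") "het-single" else "hom-single")
  "compound-het"
}

#' Allele fraction of a variant from reads
#'
#' A read supports an allele when it contains (in either orientation) a
#' site-spanning k-mer found in exactly one of the two haplotype sequences;
#' reads matching k-mers of both haplotypes are ambiguous and excluded from
#' the fraction.
#'
#' @param reads character vector of read sequences.
#' @param ref_hap,alt_hap transcript sequences of the reference and alternate
#'   haplotypes.
#' @param position 0-based transcript position of the variant on the
#'   reference haplotype.
#' @param alt_position position on the alternate haplotype (defaults to
#'   `position`, correct when no upstream indel separates the haplotypes).
#' @param ref,alt alleles in transcript orientation (used for site width).
#' @param k k-mer length.
#' @param thresholds genotype thresholds, see [genotype_label()].
#' @return one-row data.frame: `ref_reads`, `alt_reads`, `ambiguous_reads`,
#'   `alt_fraction`, `genotype`.
#' @export
allele_fraction <- function(reads, ref_hap, alt_hap, position,
                            alt_position = position, ref = "N", alt = "N",
                            k = 31L,
                            thresholds = list(hom_ref = 0.1, het = c(0.2, 0.8),
                                              hom_alt = 0.9)) {
  if (position < 0 || position >= nchar(ref_hap))
    stop("variant position not on transcript")
  span_r <- site_spanning_kmers(ref_hap, position, k, max(1L, nchar(ref)))
  span_a <- site_spanning_kmers(alt_hap, alt_position, k, max(1L, nchar(alt)))
  ref_only <- setdiff(span_r, span_a)
  alt_only <- setdiff(span_a, span_r)
  hits <- cpp_kmer_set_hits(unname(toupper(reads)),
                            list(ref_only, alt_only), k)
  n_amb <- sum(hits[, 1] & hits[, 2])
  n_ref <- sum(hits[, 1] & !hits[, 2])
  n_alt <- sum(hits[, 2] & !hits[, 1])
  frac <- if (n_ref + n_alt > 0L) n_alt / (n_ref + n_alt) else NA_real_
  data.frame(ref_reads = n_ref, alt_reads = n_alt, ambiguous_reads = n_amb,
             alt_fraction = frac,
             genotype = genotype_label(frac, thresholds),
             stringsAsFactors = FALSE)
}

#' Phase two variants from reads
#'
#' Counts reads carrying each of the four allele combinations at two sites on
#' one transcript, using k-mers that span both sites and are unique to one
#' combination haplotype. Requires the sites to be fewer than `k - 1` bases
#' apart; wider pairs (or pairs no read covers) give the verdict
#' `"uninformative"`.
#'
#' @param reads character vector of reads.
#' @param tx_seq transcript (reference) sequence.
#' @param pos_a,pos_b 0-based positions of the two SNVs, `pos_a < pos_b`.
#' @param ref_a,alt_a,ref_b,alt_b single-base alleles.
#' @param k k-mer length.
#' @param min_cis_reads alt-alt reads needed for the `"cis-observed"` verdict.
#' @return list with `counts` (named ref-ref/ref-alt/alt-ref/alt-alt) and
#'   `verdict` (`"cis-observed"`, `"trans-only"`, `"uninformative"`).
#' @export
phase_pair <- function(reads, tx_seq, pos_a, pos_b, ref_a, alt_a, ref_b, alt_b,
                       k = 31L, min_cis_reads = 1L) {
  stopifnot(pos_a < pos_b)
  counts <- c("ref-ref" = 0L, "ref-alt" = 0L, "alt-ref" = 0L, "alt-alt" = 0L)
  if (pos_b - pos_a > k - 2L)
    return(list(counts = counts, verdict = "uninformative"))
  combos <- list(
    "ref-ref" = c(ref_a, ref_b), "ref-alt" = c(ref_a, alt_b),
    "alt-ref" = c(alt_a, ref_b), "alt-alt" = c(alt_a, alt_b))
  combo_kmers <- lapply(combos, function(al) {
    seq <- inject_haplotype(tx_seq, data.frame(
      pos = c(pos_a, pos_b), ref = c(ref_a, ref_b), alt = al,
      stringsAsFactors = FALSE))
    km_a <- site_spanning_kmers(seq, pos_a, k)
    km_b <- site_spanning_kmers(seq, pos_b, k)
    intersect(km_a, km_b)   # k-mers spanning both sites
  })
  all_km <- unlist(combo_kmers, use.names = FALSE)
  dup <- all_km[duplicated(all_km)]
  combo_unique <- lapply(combo_kmers, function(km) setdiff(km, dup))
  hits <- cpp_kmer_set_hits(unname(toupper(reads)), unname(combo_unique), k)
  single <- rowSums(hits) == 1L
  if (any(single)) {
    which_combo <- max.col(hits[single, , drop = FALSE])
    tab <- tabulate(which_combo, nbins = 4L)
    counts[] <- counts + tab
  }
  verdict <- if (sum(counts) == 0L) "uninformative"
             else if (counts[["alt-alt"]] >= min_cis_reads) "cis-observed"
             else "trans-only"
  list(counts = counts, verdict = verdict)
}

#' Gene-level metrics from an abundance table
#'
#' Computes the TPM ratio of two genes, flags samples whose designated
#' primary transcript falls below a usage threshold, and (when a two-column
#' per-sample matrix is supplied) the cross-sample R^2 of a least-squares fit
#' between two normalised gene values.
#'
#' @param abundance an `AbundanceTable`.
#' @param gene_a,gene_b gene ids (ratio is TPM(a)/TPM(b)).
#' @param primary_transcript transcript whose usage is checked.
#' @param usage_threshold percent-usage threshold (default 90).
#' @param samples optional data.frame/matrix with two columns of per-sample
#'   normalised values for the correlation.
#' @return list with `gene_ratio`, `ratio_defined`, `primary_usage`,
#'   `low_usage_flag`, and `r_squared` (`NA` without `samples`).
#' @export
gene_metrics <- function(abundance, gene_a, gene_b, primary_transcript = NULL,
                         usage_threshold = 90, samples = NULL) {
  gene_tpm <- attr(abundance, "gene_tpm")
  if (!all(c(gene_a, gene_b) %in% names(gene_tpm)))
    stop("gene not present in abundance table")
  ta <- as.numeric(gene_tpm[[gene_a]]); tb <- as.numeric(gene_tpm[[gene_b]])
  ratio_defined <- tb > 0
  ratio <- if (ratio_defined) ta / tb else NA_real_
  usage <- NA_real_; flag <- NA
  if (!is.null(primary_transcript)) {
    row <- abundance[abundance$transcript_id == primary_transcript, ]
    if (nrow(row) != 1L) stop("primary transcript not in table")
    usage <- row$pct_usage
    flag <- usage < usage_threshold
  }
  r2 <- NA_real_
  if (!is.null(samples)) {
    samples <- as.data.frame(samples)
    fit <- lm(samples[[2L]] ~ samples[[1L]])
    # exact collinearity is a legitimate input here; silence the lm warning
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  list(gene_ratio = ratio, ratio_defined = ratio_defined,
       primary_usage = usage, low_usage_flag = flag, r_squared = r2)
}
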