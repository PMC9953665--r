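make_counts <- function(classes, counts, n_reads = sum(counts),
                        mean_read_length = 100) {
  structure(list(classes = classes, counts = as.integer(counts),
                 unassigned = 0L, n_reads = n_reads,
                 mean_read_length = mean_read_length),
            class = "EquivalenceClassCounts")
}

test_that("build_index k-mer accounting matches brute-force enumeration", {
  set.seed(21)
  t1 <- rand_dna(120)
  idx <- build_index(c(t1 = t1), k = 31)
  km <- kmer_transcript_map(idx)
  # L - k + 1 k-mer positions (duplicates collapse in the map)
  expect_setequal(km$kmer, unique(oracle_kmers(t1, 31)))
  # a shared 50-nt block contributes its 20 internal k-mers to both
  block <- rand_dna(50)
  a <- paste0(rand_dna(70), block)
  b <- paste0(block, rand_dna(70))
  idx2 <- build_index(c(a = a, b = b), k = 31)
  km2 <- kmer_transcript_map(idx2)
  shared <- km2$kmer[km2$transcripts == "a,b"]
  expect_setequal(shared, intersect(oracle_kmers(a, 31), oracle_kmers(b, 31)))
  expect_equal(length(unique(oracle_kmers(block, 31))), 20L)
  expect_true(all(oracle_kmers(block, 31) %in% shared))
  # REF/ALT haplotypes differing by one interior SNV: exactly k
  # allele-discriminating k-mers per haplotype
  ref <- rand_dna(200)
  alt <- inject_haplotype(ref, data.frame(
    pos = 100, ref = substr(ref, 101, 101),
    alt = setdiff(c("A", "C", "G", "T"), substr(ref, 101, 101))[1]))
  idx3 <- build_index(c(ref = ref, alt = alt), k = 31)
  km3 <- kmer_transcript_map(idx3)
  expect_equal(sum(km3$transcripts == "ref"), 31L)
  expect_equal(sum(km3$transcripts == "alt"), 31L)
  # sequences shorter than k are dropped with a warning
  expect_warning(build_index(c(s = "ACGT", t1 = t1), k = 31), "shorter")
  expect_equal(suppressWarnings(effective_lengths(
    build_index(c(t1 = t1), k = 31, mean_fragment_length = 100))),
    c(t1 = 21))
})

test_that("assign_reads forms the expected equivalence classes", {
  set.seed(22)
  block <- rand_dna(150)
  t1 <- paste0(rand_dna(150), block)
  t2 <- paste0(block, rand_dna(150))
  idx <- build_index(c(t1 = t1, t2 = t2), k = 31)
  unique_read <- substr(t1, 11, 110)     # inside t1's unique prefix
  shared_read <- substr(block, 21, 120)  # inside the shared block
  ecc <- assign_reads(c(unique_read, shared_read, revcomp(shared_read)), idx)
  cls <- ecc$classes[order(lengths(ecc$classes))]
  expect_equal(cls[[1]], "t1")
  expect_equal(cls[[2]], c("t1", "t2"))
  expect_equal(sum(ecc$counts) + ecc$unassigned, 3L)
  # heavily corrupted read: oracle confirms < 0.8 of k-mers match anything
  bad <- unique_read
  for (p in seq(5, 95, by = 10)) {
    cur <- substr(bad, p, p)
    substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  frac <- max(mean(oracle_kmers(bad, 31) %in% oracle_kmers(t1, 31)),
              mean(oracle_kmers(bad, 31) %in% oracle_kmers(t2, 31)))
  expect_lt(frac, 0.8)
  ecc_bad <- assign_reads(bad, idx)
  expect_equal(ecc_bad$unassigned, 1L)
  # empty input is empty counts, not an error
  ecc0 <- assign_reads(character(0), idx)
  expect_equal(ecc0$n_reads, 0L)
})

test_that("EM reaches the closed-form fixed points", {
  set.seed(23)
  seqs <- c(t1 = rand_dna(200), t2 = rand_dna(200))
  idx <- build_index(seqs, k = 31, mean_fragment_length = 100)
  # all reads unique to t1
  ab <- em_abundance(make_counts(list("t1"), 100), idx)
  expect_equal(ab$pct_usage[ab$transcript_id == "t1"], 100)
  expect_equal(ab$tpm[ab$transcript_id == "t1"], 1e6)
  # symmetric 50/50 plus shared
  counts <- make_counts(list("t1", "t2", c("t1", "t2")), c(50, 50, 100))
  for (pw in c(TRUE, FALSE)) {
    ab <- em_abundance(counts, idx, position_weights = pw)
    expect_equal(ab$est_count, c(100, 100), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # 90/10 plus 100 shared: fixed point a = (90 + 100a)/200 -> 0.9
  counts <- make_counts(list("t1", "t2", c("t1", "t2")), c(90, 10, 100))
  for (pw in c(TRUE, FALSE)) {
    ab <- em_abundance(counts, idx, position_weights = pw)
    a <- ab$est_count[ab$transcript_id == "t1"] / sum(ab$est_count)
    expect_equal(a, 0.9, tolerance = 1e-6)
  }
  # all reads unassigned is an error
  expect_error(em_abundance(make_counts(list(), integer(0)), idx), "unassigned")
})

test_that("EM output satisfies the normalisation invariants", {
  cfg <- simulation_config(seed = 4, reads = list(n_reads = 4000L))
  loc <- simulate_locus(cfg)
  sim <- simulate_reads(cfg, loc)
  idx <- build_index(loc$sequences, k = 31)
  ecc <- assign_reads(sim$reads, idx)
  # conservation of reads
  expect_equal(sum(ecc$counts) + ecc$unassigned, length(sim$reads))
  gene_ids <- vapply(loc$models, function(m) m$gene_id, character(1))
  ab <- em_abundance(ecc, idx, gene_ids = gene_ids)
  expect_equal(sum(ab$tpm), 1e6, tolerance = 1e-6)
  for (g in unique(ab$gene_id))
    expect_equal(sum(ab$pct_usage[ab$gene_id == g]), 100, tolerance = 1e-9)
  expect_true(all(ab$est_count >= 0))
  # EM likelihood is non-decreasing across iterations
  ll <- attr(ab, "loglik")
  expect_true(all(diff(ll) >= -1e-9))
})

test_that("allele fractions and genotype labels follow the thresholds", {
  set.seed(24)
  ref <- rand_dna(200)
  alt_base <- setdiff(c("A", "C", "G", "T"), substr(ref, 101, 101))[1]
  alt <- inject_haplotype(ref, data.frame(pos = 100,
                                          ref = substr(ref, 101, 101),
                                          alt = alt_base))
  ref_reads <- substring(ref, 51, 150)
  alt_reads <- substring(alt, 51, 150)
  # all informative reads REF
  af <- allele_fraction(rep(ref_reads, 40), ref, alt, 100)
  expect_equal(af$alt_fraction, 0)
  expect_equal(af$genotype, "hom-ref")
  # 30 ALT / 70 REF
  af2 <- allele_fraction(c(rep(ref_reads, 70), rep(alt_reads, 30)), ref, alt, 100)
  expect_equal(af2$alt_fraction, 0.30)
  expect_equal(af2$genotype, "het")
  expect_equal(af2$ref_reads + af2$alt_reads, 100L)
  # reverse-complement reads are informative too
  af3 <- allele_fraction(revcomp(rep(alt_reads, 10)), ref, alt, 100)
  expect_equal(af3$alt_reads, 10L)
  # a variant off the transcript is a domain error
  expect_error(allele_fraction(ref_reads, ref, alt, 500), "not on transcript")
  # label thresholds
  expect_equal(genotype_label(0.05), "hom-ref")
  expect_equal(genotype_label(0.5), "het")
  expect_equal(genotype_label(0.95), "hom-alt")
  expect_equal(genotype_label(0.15), "ambiguous")
  expect_equal(genotype_label(NA_real_), "uninformative")
})

test_that("phase_pair classifies cis/trans/uninformative", {
  set.seed(25)
  tx <- rand_dna(300)
  pos_a <- 100L; pos_b <- 110L
  ref_a <- substr(tx, 101, 101); ref_b <- substr(tx, 111, 111)
  alt_a <- setdiff(c("A", "C", "G", "T"), ref_a)[1]
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  combo_read <- function(a, b) {
    edits <- data.frame(pos = c(pos_a, pos_b), ref = c(ref_a, ref_b),
                        alt = c(a, b), stringsAsFactors = FALSE)
    edits <- edits[edits$ref != edits$alt, , drop = FALSE]
    s <- inject_haplotype(tx, edits)
    substr(s, 61, 160)
  }
  # only ref-alt and alt-ref reads: trans-only
  reads <- c(rep(combo_read(ref_a, alt_b), 5), rep(combo_read(alt_a, ref_b), 5))
  ph <- phase_pair(reads, tx, pos_a, pos_b, ref_a, alt_a, ref_b, alt_b)
  expect_equal(ph$verdict, "trans-only")
  expect_equal(unname(ph$counts[c("ref-alt", "alt-ref")]), c(5L, 5L))
  expect_equal(unname(ph$counts[["alt-alt"]]), 0L)
  # a single alt-alt read flips the verdict at the default threshold
  ph2 <- phase_pair(c(reads, combo_read(alt_a, alt_b)), tx, pos_a, pos_b,
                    ref_a, alt_a, ref_b, alt_b)
  expect_equal(ph2$verdict, "cis-observed")
  # reads that cover neither site: uninformative
  far <- substring(tx, 201, 300)
  ph3 <- phase_pair(rep(far, 5), tx, pos_a, pos_b, ref_a, alt_a, ref_b, alt_b)
  expect_equal(ph3$verdict, "uninformative")
  # sites too far apart for site-spanning k-mers: uninformative
  ph4 <- phase_pair(reads, tx, 50L, 250L, substr(tx, 51, 51), "N",
                    substr(tx, 251, 251), "N")
  expect_equal(ph4$verdict, "uninformative")
})

test_that("gene_metrics computes ratios, flags and correlations", {
  ab <- data.frame(transcript_id = c("t1", "t2", "t3"),
                   est_count = c(850, 150, 100),
                   tpm = c(85e4, 15e4, 1e4) / 1.01,
                   gene_id = c("A", "A", "B"),
                   pct_usage = c(85, 15, 100), stringsAsFactors = FALSE)
  attr(ab, "gene_tpm") <- c(A = 100, B = 10)
  class(ab) <- c("AbundanceTable", "data.frame")
  m <- gene_metrics(ab, "A", "B", primary_transcript = "t1",
                    usage_threshold = 90)
  expect_equal(m$gene_ratio, 10)
  expect_true(m$low_usage_flag)    # 85% < 90%
  # perfectly proportional samples give R^2 = 1
  s <- data.frame(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_equal(gene_metrics(ab, "A", "B", samples = s)$r_squared, 1)
  # zero denominator flags the ratio undefined
  attr(ab, "gene_tpm") <- c(A = 100, B = 0)
  m2 <- gene_metrics(ab, "A", "B")
  expect_false(m2$ratio_defined)
  expect_true(is.na(m2$gene_ratio))
})

test_that("identical inputs and seed give byte-identical tables", {
  run <- function() {
    cfg <- simulation_config(seed = 9, reads = list(n_reads = 2000L))
    loc <- simulate_locus(cfg)
    sim <- simulate_reads(cfg, loc)
    idx <- build_index(loc$sequences, k = 31)
    em_abundance(assign_reads(sim$reads, idx), idx)
  }
  a <- run(); b <- run()
  expect_identical(a, b)
})
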