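test_that("extract_transcript_sequence splices and strand-flips correctly", {
  g <- genome_sequence("c1", "AAACCCGGGTTT")
  # identity: single plus-strand exon covering the contig
  tx <- transcript_model("t1", "g1", "c1", "+", rbind(c(0, 12)))
  expect_identical(extract_transcript_sequence(g, tx), "AAACCCGGGTTT")
  # minus strand, exons [0,3) and [6,9): revcomp of "AAAGGG"
  tx2 <- transcript_model("t2", "g1", "c1", "-", rbind(c(0, 3), c(6, 9)))
  expect_identical(extract_transcript_sequence(g, tx2), "CCCTTT")
  # out-of-bounds exon errors
  tx3 <- transcript_model("t3", "g1", "c1", "+", rbind(c(5, 20)))
  expect_error(extract_transcript_sequence(g, tx3), "bounds")
})

test_that("coordinate projection round-trips on both strands", {
  set.seed(11)
  for (strand in c("+", "-")) {
    tx <- transcript_model("t", "g", "c1", strand,
                           rbind(c(10, 40), c(60, 100), c(150, 170)))
    len <- tx_length(tx)
    tpos <- 0:(len - 1L)
    gpos <- tx_to_genome(tx, tpos)
    expect_identical(genome_to_tx(tx, gpos), tpos)
    expect_true(all(is.na(genome_to_tx(tx, c(0, 45, 120, 200)))))
  }
})

test_that("project_variant adjusts position and alleles by strand", {
  v <- variant_record("c1", 17L, "C", "T")
  tx_p <- transcript_model("t", "g", "c1", "+", rbind(c(10, 40)))
  expect_equal(project_variant(v, tx_p),
               list(position = 7L, ref = "C", alt = "T"))
  tx_m <- transcript_model("t", "g", "c1", "-", rbind(c(10, 40)))
  pm <- project_variant(v, tx_m)
  expect_equal(pm$position, 30L - 8L)  # mirrored offset
  expect_equal(pm$ref, "G"); expect_equal(pm$alt, "A")
  # intronic variant is absent
  tx2 <- transcript_model("t", "g", "c1", "+", rbind(c(0, 5), c(30, 40)))
  expect_null(project_variant(v, tx2))
})

# micro-locus for consequence tests: 5'UTR 6 nt, CDS 9 nt (ATG AAA TAA),
# 3'UTR 6 nt, two exons with an intron in the CDS-free 3'UTR
cons_fixture <- function() {
  #            0----5 6-------14 15--18 | intron | 19px
  exon1 <- "GGGGGG"               # 5'UTR
  cds <- "ATGAAATAA"
  utr3a <- "TTTT"; utr3b <- "CCCC"
  genome <- paste0(exon1, cds, utr3a, strrep("A", 50), utr3b,
                   strrep("G", 20))
  g <- genome_sequence("c1", genome)
  tx <- transcript_model("tx", "g", "c1", "+",
                         rbind(c(0, 19), c(69, 73)), cds_span = c(6, 15))
  list(g = g, tx = tx)
}

test_that("classify_consequence picks the right class by priority", {
  f <- cons_fixture()
  call <- function(pos, ref, alt)
    classify_consequence(variant_record("c1", pos, ref, alt), f$tx, f$g)
  expect_equal(call(2, "G", "C")$consequence, "five_prime_UTR")
  # CDS codon 2 AAA -> AGA: missense p.K2R
  cc <- call(10, "A", "G")
  expect_equal(cc$consequence, "missense")
  expect_equal(cc$protein_change, "p.K2R")
  # AAA -> AAG: synonymous
  expect_equal(call(11, "A", "G")$consequence, "synonymous")
  # stop codon TAA -> CAA: stop lost
  expect_equal(call(12, "T", "C")$consequence, "stop_lost")
  # AAA -> TAA: stop gained
  expect_equal(call(9, "A", "T")$consequence, "stop_gained")
  # 3'UTR exonic
  expect_equal(call(15, "T", "A")$consequence, "three_prime_UTR")
  # exonic tail of the exon overlaps the splice-region window
  expect_equal(call(16, "T", "A")$consequence, "splice_region")
  # frameshift deletion inside CDS
  fs <- classify_consequence(variant_record("c1", 9, "AA", "A"), f$tx, f$g)
  expect_equal(fs$consequence, "frameshift")
  # splice windows around the intron at [19, 69)
  expect_equal(call(19, "A", "C")$consequence, "splice_site")    # intron +1
  expect_equal(call(23, "A", "C")$consequence, "splice_region")  # intron +5
  expect_equal(call(40, "A", "C")$consequence, "intronic")
  expect_equal(call(68, "A", "C")$consequence, "splice_site")    # intron -1
  # downstream within/without the 5 kb window
  expect_equal(call(80, "G", "A")$consequence, "downstream_gene")
  g2 <- genome_sequence("c1", paste0(f$g$sequence, strrep("T", 6000)))
  expect_null(classify_consequence(variant_record("c1", 6090, "T", "A"),
                                   f$tx, g2))
  # ref mismatch is a validation error
  expect_error(call(2, "T", "C"), "mismatch")
})

test_that("strand symmetry: minus-strand call equals mirrored plus-strand call", {
  f <- cons_fixture()
  glen <- nchar(f$g$sequence)
  g_rc <- genome_sequence("c1", oracle_revcomp(f$g$sequence))
  mirror <- function(m) cbind(glen - m[, 2], glen - m[, 1])[rev(seq_len(nrow(m))), ,
                                                           drop = FALSE]
  tx_m <- transcript_model("tx", "g", "c1", "-", mirror(f$tx$exons),
                           cds_span = f$tx$cds_span)
  probes <- list(c(2, "G", "C"), c(10, "A", "G"), c(11, "A", "G"),
                 c(15, "T", "A"), c(23, "A", "C"), c(40, "A", "C"))
  for (p in probes) {
    pos <- as.integer(p[1])
    v_p <- variant_record("c1", pos, p[2], p[3])
    v_m <- variant_record("c1", glen - 1L - pos, oracle_revcomp(p[2]),
                          oracle_revcomp(p[3]))
    cp <- classify_consequence(v_p, f$tx, f$g)
    cm <- classify_consequence(v_m, tx_m, g_rc)
    expect_equal(cm$consequence, cp$consequence, info = paste(p, collapse = "/"))
  }
})

test_that("inject_haplotype matches the left-to-right offset oracle", {
  expect_identical(inject_haplotype("ACGT", NULL), "ACGT")
  expect_identical(
    inject_haplotype("AAAAACGGG", data.frame(pos = 5, ref = "C", alt = "T")),
    "AAAAATGGG")
  # deletion shifting a downstream SNV
  edits <- data.frame(pos = c(2L, 6L), ref = c("AA", "G"), alt = c("A", "T"),
                      stringsAsFactors = FALSE)
  s <- "AAAAACGGG"
  # substring(s, 7, 7) == "G"
  expect_identical(inject_haplotype(s, edits), oracle_inject(s, edits))
  expect_equal(nchar(inject_haplotype(s, edits)), nchar(s) - 1L)
  # randomised agreement with the oracle
  set.seed(42)
  for (i in 1:20) {
    s <- rand_dna(60)
    pos <- sort(sample(0:50, 3))
    if (any(diff(pos) < 4)) next
    edits <- data.frame(pos = pos,
                        ref = substring(s, pos + 1, pos + c(1, 2, 1)),
                        alt = c("T", "G", "ACGT"), stringsAsFactors = FALSE)
    edits$alt[edits$alt == edits$ref] <- "C"
    ok <- edits$ref != edits$alt
    edits <- edits[ok, , drop = FALSE]
    expect_identical(inject_haplotype(s, edits), oracle_inject(s, edits))
  }
  # SNV-only edits preserve length; a k-bp deletion shortens by k
  s <- rand_dna(40)
  snv <- data.frame(pos = c(3, 11), ref = substring(s, c(4, 12), c(4, 12)),
                    alt = c("N", "N"))
  expect_equal(nchar(inject_haplotype(s, snv)), 40L)
  del <- data.frame(pos = 5, ref = substr(s, 6, 10), alt = substr(s, 6, 6))
  expect_equal(nchar(inject_haplotype(s, del)), 40L - 4L)
  # overlapping edits and ref mismatches are rejected
  expect_error(inject_haplotype("AAAA", data.frame(
    pos = c(0, 1), ref = c("AA", "AA"), alt = c("A", "A"))), "overlap")
  expect_error(inject_haplotype("AAAA", data.frame(
    pos = 1, ref = "C", alt = "T")), "mismatch")
})

test_that("find_orf_translate finds and translates the longest ATG ORF", {
  pr <- find_orf_translate("ATGAAATAA")
  expect_identical(pr$sequence, "MK")
  expect_true(pr$stop_reached)
  expect_equal(pr$orf_span, c(0L, 9L))
  # two candidate ORFs, 4 vs 7 codons: the 7-codon one wins
  s <- paste0("CC", "ATG", strrep("GCA", 3), "TAA",   # 4 codons w/ start
              "TT", "ATG", strrep("GCA", 6), "TGA", "AA")
  pr2 <- find_orf_translate(s)
  expect_identical(pr2$sequence, paste0("M", strrep("A", 6)))
  # cds_span route, including the partial-codon validation error
  pr3 <- find_orf_translate("GGATGAAATAACC", cds_span = c(2, 11))
  expect_identical(pr3$sequence, "MK")
  expect_error(find_orf_translate("GGATGAAATAACC", cds_span = c(2, 10)),
               "divisible")
  # agreement with the exhaustive 3-frame oracle on random sequences
  set.seed(5)
  for (i in 1:40) {
    s <- rand_dna(120)
    if (!grepl("ATG", s, fixed = TRUE)) next
    o <- oracle_longest_orf(s)
    pr <- find_orf_translate(s)
    expect_identical(pr$sequence, o$protein)
    expect_equal(pr$stop_reached, o$has_stop)
  }
})

test_that("classify_decay applies the 50-nt junction rule", {
  single <- transcript_model("t", "g", "c", "+", rbind(c(0, 300)))
  expect_equal(classify_decay(single, c(10, 100), TRUE), "normal")
  # stop ending 60 nt upstream of the last junction
  tx <- transcript_model("t", "g", "c", "+", rbind(c(0, 100), c(200, 300)))
  # junction at 100; stop end 40 -> 60 upstream
  expect_equal(classify_decay(tx, c(0, 40), TRUE), "nmd_predicted")
  expect_equal(classify_decay(tx, c(0, 60), TRUE), "normal")  # 40 nt, inside rule
  expect_equal(classify_decay(tx, c(0, 150), FALSE), "nonstop_predicted")
  # 1,000 random synthetic transcripts agree with the brute-force rule
  set.seed(99)
  for (i in 1:1000) {
    n_ex <- sample(1:5, 1)
    lens <- sample(60:400, n_ex, replace = TRUE)
    gaps <- sample(50:200, max(n_ex - 1L, 0L), replace = TRUE)
    starts <- cumsum(c(0, head(lens, -1) + gaps))
    tx <- transcript_model("t", "g", "c", "+",
                           cbind(starts, starts + lens))
    total <- sum(lens)
    stop_end <- sample(3:total, 1)
    stop_reached <- runif(1) < 0.9
    junctions <- if (n_ex > 1) cumsum(lens)[-n_ex] else integer(0)
    expect_identical(classify_decay(tx, c(0L, stop_end), stop_reached),
                     oracle_decay(junctions, stop_end, stop_reached))
  }
})

test_that("stop-loss re-translation yields the HGVS extension name", {
  # toy CDS ATG AAA CCC GGG TAA with 3'UTR TTTTGA; stop TAA -> AGA (Arg)
  seq <- paste0("ATGAAACCCGGGTAA", "TTTTGA")
  res <- apply_stop_loss_retranslate(seq, c(0L, 15L),
                                     list(pos = 12L, ref = "TAA", alt = "AGA"))
  expect_equal(res$name, "p.Ter5ArgextTer3")
  expect_equal(res$added_residues, 2L)
  expect_identical(res$protein$sequence, "MKPGRF")
  expect_equal(res$protein$decay_class, "normal")
  # stop-free 3'UTR: open extension name and nonstop decay
  seq2 <- paste0("ATGAAACCCGGGTAA", "TTTTTT")
  res2 <- apply_stop_loss_retranslate(seq2, c(0L, 15L),
                                      list(pos = 12L, ref = "TAA", alt = "AGA"))
  expect_match(res2$name, "ext\\*\\?$")
  expect_equal(res2$protein$decay_class, "nonstop_predicted")
  # an edit that leaves a stop codon is rejected
  expect_error(apply_stop_loss_retranslate(seq, c(0L, 15L),
                                           list(pos = 12L, ref = "TAA",
                                                alt = "TGA")),
               "not a stop-loss")
  # an edit not overlapping the stop is rejected
  expect_error(apply_stop_loss_retranslate(seq, c(0L, 15L),
                                           list(pos = 3L, ref = "A", alt = "G")),
               "not a stop-loss")
})

test_that("HGVS extension parsing recovers the added-residue count", {
  p <- parse_hgvs_ext("p.Ter201GlyextTer29")
  expect_equal(p$stop_position, 201L)
  expect_equal(p$new_aa, "Gly")
  expect_equal(p$added_residues, 28L)
  open <- parse_hgvs_ext("p.Ter5Argext*?")
  expect_true(is.na(open$added_residues))
  expect_error(parse_hgvs_ext("p.G75D"), "not a recognised")
})

test_that("chain renumbering matches the published mappings and is a bijection", {
  expect_equal(prepro_to_chain(34)$region, "B")
  expect_equal(prepro_to_chain(34)$chain_index, 10L)
  expect_equal(prepro_to_chain(49)$chain_index, 25L)
  r91 <- prepro_to_chain(91)
  expect_equal(r91$region, "A"); expect_equal(r91$chain_index, 2L)
  expect_equal(prepro_to_chain(1)$region, "signal")
  expect_equal(prepro_to_chain(1)$chain_index, 1L)
  expect_error(prepro_to_chain(0), "outside")
  expect_error(prepro_to_chain(111), "outside")
  # bijection over 1..110
  m <- prepro_to_chain(1:110)
  back <- chain_to_prepro(m$region, m$chain_index)
  expect_identical(back, 1:110)
  expect_equal(anyDuplicated(paste(m$region, m$chain_index)), 0L)
})

test_that("dibasic sites and N-terminal prefixes behave", {
  expect_identical(find_dibasic_sites("MAGAGA"), integer(0))
  expect_identical(find_dibasic_sites("MKRAAKKA"), c(2L, 6L))
  expect_identical(find_dibasic_sites("KRR"), c(1L, 2L))  # overlapping pairs
  pp <- preproinsulin_sequence()
  expect_equal(nchar(pp), 110L)
  expect_identical(find_dibasic_sites(pp), c(55L, 88L))
  expect_equal(longest_common_nterminal_prefix("MKT", "MKT"), 3L)
  expect_equal(longest_common_nterminal_prefix("MKT", "MKA"), 2L)
  expect_equal(longest_common_nterminal_prefix("", "MK"), 0L)
})

test_that("GTF round trip preserves models and sequences", {
  cfg <- simulation_config(seed = 2)
  loc <- simulate_locus(cfg)
  path <- tempfile(fileext = ".gtf")
  suppressWarnings(write_gtf(loc$models, path))
  back <- read_gtf(path)
  expect_setequal(names(back), names(loc$models))
  for (id in names(loc$models)) {
    expect_equal(back[[id]]$exons, loc$models[[id]]$exons, info = id)
    expect_equal(back[[id]]$cds_span, loc$models[[id]]$cds_span, info = id)
    expect_identical(extract_transcript_sequence(loc$genome, back[[id]]),
                     loc$sequences[[id]], info = id)
  }
})

test_that("VCF writing and reading round-trips variant records", {
  skip_if_not_installed("VariantAnnotation")
  cfg <- simulation_config(seed = 2)
  loc <- simulate_locus(cfg)
  path <- tempfile(fileext = ".vcf")
  write_variants_vcf(loc$variants, path)
  back <- read_variants_vcf(path)
  expect_equal(length(back), length(loc$variants))
  for (i in seq_along(back)) {
    orig <- loc$variants[[i]]
    expect_equal(back[[i]]$position, orig$position)
    expect_equal(back[[i]]$ref, orig$ref)
    expect_equal(back[[i]]$alt, orig$alt)
  }
})

test_that("indel normalization left-aligns and anchors", {
  g <- genome_sequence("c", "GGTAAAAC")
  # deletion of one A inside the A-run, given right-aligned: shifts left
  n <- normalize_variant(g, 4L, "AA", "A")
  expect_equal(n$position, 2L)
  expect_equal(n$ref, "TA"); expect_equal(n$alt, "T")
  # SNV with redundant context collapses to a single base
  n2 <- normalize_variant(g, 2L, "TAA", "TCA")
  expect_equal(n2$position, 3L)
  expect_equal(n2$ref, "A"); expect_equal(n2$alt, "C")
})
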