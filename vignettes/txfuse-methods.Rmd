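---
title: "txfuse: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{txfuse: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

txfuse is an integrated toolkit for a locus with a readthrough fusion
transcript: isoform quantification that is aware of haplotype variants,
fusion junction detection, variant consequence and decay annotation,
alignment conservation, and variant-to-structure interface mapping. This
vignette explains the models behind each component, the tunable
parameters and their defaults, what the simulators emulate, and the
places where the design was genuinely open and a choice had to be made.

## The quantification model

Reads are not aligned. A read is *compatible* with a transcript when at
least `compat_fraction` (default 0.8) of its k-mers (default k = 31)
occur in that transcript; both the read and its reverse complement are
evaluated and the orientation with stronger k-mer support is kept. The
set of compatible transcripts is the read's equivalence class; the empty
class is counted as unassigned, so assigned + unassigned always equals
the input read count. Note that at k = 31 and 100-nt reads a single
central sequencing error already corrupts 31 of 70 k-mers, so the 0.8
threshold discards most error-carrying reads; this is a property of the
stated defaults, not a bug, and the loss is close to uniform across
transcripts.

Abundance is the maximum-likelihood estimate of read-origin proportions
$\alpha$ under the generative model: a read picks transcript $t$ with
probability $\alpha_t$, then falls into class $c$ with probability
$W_{c,t}$. The EM update is

$$\alpha_t \leftarrow \frac{1}{N}\sum_c n_c
  \frac{\alpha_t W_{c,t}}{\sum_{t'} \alpha_{t'} W_{c,t'}}$$

initialised uniformly (so fully symmetric classes resolve to equal
shares) and stopped when the largest change in any $\alpha_t$ falls
below `tol = 1e-8` or after 1000 iterations. The per-iteration
log-likelihood is recorded and is non-decreasing, which the tests
assert.

**Position-aware class weights.** The plain equivalence-class EM takes
$W_{c,t}$ constant for $t \in c$. On transcript sets with extreme
sharing — here the fusion transcript shares *all* of its sequence except
a 40-nt junction window with its two parents — that approximation is
visibly biased (we measured ~9 percentage points on the fusion isoform).
`em_abundance()` therefore computes $W_{c,t}$ exactly by pushing every
read-length window of every transcript through the same compatibility
rule and counting which class each window generates. This is the exact
likelihood under the simulator's uniform-start model, costs one extra
pass over the transcript sequences, and reduces to the familiar
closed-form fixed points on symmetric class structures (for unique
counts 90/10 plus 100 shared reads between two equal-length transcripts,
the fixed point $a = (90 + 100a)/200$ still gives 0.9 exactly, which the
acceptance suite checks at 1e-6). Classes never produced by any
error-free window (possible for error-bearing reads) fall back to
effective-length weights. Plain behaviour is available with
`position_weights = FALSE`.

TPM is `count / effective_length` normalised to sum to 1e6, with
`effective_length = max(length − mean_fragment_length + 1, 1)` and the
mean fragment length defaulting to the observed mean read length
(single-end protocol). Percent usage is TPM-proportional within a gene
and sums to 100 per gene by construction.

## Allele fractions and phase

A variant site on a transcript defines two haplotype sequences. K-mers
that span the site and occur in exactly one haplotype are
allele-discriminating; a read supports the allele whose discriminating
k-mers it contains (either orientation), reads matching both sets are
ambiguous and excluded from the fraction (the read-level percentages
this mirrors are computed over informative reads only). Genotype labels
are pure threshold rules — hom-ref ≤ 0.1, het within [0.2, 0.8],
hom-alt ≥ 0.9, otherwise ambiguous — all exposed in the configuration,
since the genotype classes being reproduced state no thresholds.
`sample_genotype_class()` rolls per-variant labels into the sample-level
classes (WT / het-single / hom-single / compound-het).

Phase between two nearby variants is read from k-mers spanning *both*
sites, unique to one of the four allele combinations. This requires the
sites to lie fewer than k − 1 bases apart — comfortably true for the
14-base pair the analysis was designed around — and wider pairs return
the verdict `uninformative` rather than an error. The `cis-observed`
verdict needs `min_cis_reads` (default 1) alt–alt reads; with non-zero
sequencing error a single spurious alt–alt read can flip the verdict, so
error-sensitive analyses should raise this threshold.

## Annotation rules

Consequence classification picks exactly one class per (variant,
transcript) by fixed priority: splice_site > frameshift > stop_gained >
stop_lost > missense > inframe_indel > synonymous > splice_region >
five_prime_UTR > three_prime_UTR > intronic > noncoding_transcript, with
upstream/downstream only when the variant does not overlap the
transcript and lies within a 5 kb window. Splice windows are 2 intronic
bases (splice_site) and 3 exonic + 8 intronic bases (splice_region) at
every internal junction. These mirror common annotator conventions; the
source data reported annotator categories without stating priorities, so
the ordering is a documented decision, not an imported fact. Coding SNVs
report `p.RefPosAlt` one-letter protein changes; frameshifts report
`p.Xnfs`.

Decay classes: `nmd_predicted` when the stop codon ends more than
`nmd_threshold` (default 50, configurable) nucleotides upstream of the
final exon–exon junction; `nonstop_predicted` when no in-frame stop is
reached before the transcript end; otherwise `normal`. Stop-loss
re-translation continues codon-by-codon into the 3'UTR and names the
result `p.Ter{N}{Aa}extTer{M}` with M − 1 added residues, matching the
printed extension style; a stop-free 3'UTR yields the open form
`p.Ter{N}{Aa}ext*?` and a nonstop prediction.

All coordinates are 0-based half-open internally and converted only at
GTF/VCF I/O, which eliminates off-by-one arithmetic in splicing code.
Indels are left-aligned and anchored at VCF I/O.

## Junction probes

A probe takes `flank` (default 20) bases on each side of the fusion
junction. Uniqueness is decided by an exhaustive Hamming scan of every
window of every background transcript and its reverse complement at
`max_mismatches` (default 2) — a deliberate replacement for BLAST-style
e-value screening, whose cutoffs in the source analysis were unspecified;
a mismatch count is reproducible and testable against a brute-force
oracle. A read counts toward the junction when some ungapped placement
of the probe covers at least `min_overlap` (default 10) read bases on
*each* side of the junction within `max_mismatches` (default 0); each
read counts once. Counting is monotone in reads and mismatches, and
anti-monotone in `min_overlap`, which the tests assert as properties.

## Conservation

Per-column conservation is the percent of alignment rows matching the
reference row's character, indexed on the ungapped reference; gaps and
ambiguity codes count as non-matching. The reference row itself is
included in the denominator by default (so the minimum is 1/N rather
than 0) — the source presentation does not say which convention it used,
so this is a documented, configurable choice. The digit bin is
`floor(percent/10)` capped at 9; the top bin is closed (90–100% → 9) per
the stated "100–90%" bin, and the second bin listed there as "9 =
80–90%" is treated as a typographical slip for 8. Variant density is
distinct (position, ref, alt) triples per base of a half-open region.

## Structure contacts

Coordinates are parsed from PDB-format text (first model by default,
highest-occupancy alternate conformers, elements inferred from atom
names when the element column is blank). Interface contacts are residue
pairs on different chains with any heavy-atom pair within 4.0 Å; metal
coordination requires a residue N/O/S atom within 2.8 Å of a metal
HETATM. Both cutoffs are configurable: the original analysis names its
visualisation tool but not its geometric criteria, so distance-only
definitions were chosen for reproducibility. Contact residues join to
variant positions through the preproinsulin chain map (signal 1–24,
B 25–54, linkers 55–56 and 88–89, C 57–87, A 90–110), producing
per-structure presence marks; residues absent from the numbering map
warn rather than fail.

## The synthetic world

The simulators are first-class, tested code, and their defaults are the
stated world of the whole test suite:

* **Locus** — a 3.1 kb contig with gene A (three isoforms: primary;
  one with an extra 3'UTR exon placing the stop 70 nt upstream of the
  final junction, hence NMD-structured; one with a shortened middle
  exon causing a frameshift and no stop before the transcript end,
  hence nonstop), downstream gene B on the same strand, and a fusion
  joining the primary isoform at transcript position 480 to gene B's
  5'UTR at position 101 — one base off codon phase, so the fusion ORF
  crosses into gene B in a shifted frame, as a readthrough fusion
  landing in a 5'UTR typically does. Start/stop codons are stamped and
  stray in-frame stops repaired by replacing the offending codon's
  middle base with C; since stop codons contain no C, these repairs can
  never create a stop in any frame, and guard C bases flanking each
  designed stop prevent cross-frame codons from overlapping it. The
  construction therefore holds for every seed, and the generator
  asserts it.
* **Reads** — 20,000 stranded single-end 100-nt reads by default at a
  0.5% per-base error rate; isoform proportions (0.50, 0.25, 0.15,
  0.07, 0.03) with the primary isoform dominant, mirroring a locus
  whose primary transcript carries most of the expression. Reads are
  drawn with weight proportional to `proportion × (length − read_length
  + 1)` — the number of valid start positions. This is the
  measure-consistent reading of "proportion × length" weighting: it
  matches the quantifier's effective length exactly, so molar
  proportions are recoverable rather than only approximately so. The
  3'UTR het variant sits on all three gene-A isoforms at ratio 0.5,
  because a genomic heterozygote affects every transcript containing
  the site. Qualities are constant `I`; no paired ends, no positional
  or GC bias, no empirical error profiles.
* **MSA** — 200 rows, 60 columns, a fixed repeating conservation
  pattern (1, 0.95, 0.9, 0.8, 0.5); each non-reference row matches the
  reference per column with the stated probability, else draws
  uniformly from the three alternatives.
* **Structure** — one-atom residue beads on a ≥ 6 Å grid, configured
  contact pairs placed at exactly 3.5 Å, a Zn site with donors at
  2.1 Å. Each residue may join at most one contact pair and metal
  donors must share a chain — documented feasibility limits, violated
  requests error.

A green recovery test on this world establishes that the estimators
invert the stated generative process at the stated sizes. It does not
establish robustness to real-data features the generators deliberately
omit: coverage bias, indel sequencing errors, unannotated transcripts,
alignment artefacts, or structural disorder.

## Numerical and degenerate-input choices

EM convergence is max-absolute-change < 1e-8 with a 1000-iteration cap;
ties break to equal shares via the uniform start. Reads shorter than k
are unassigned; index sequences shorter than k are dropped with a
warning. An all-unassigned sample is an explicit error rather than an
empty table. A zero-TPM denominator gene flags the ratio undefined. The
conservation profile of an all-gap reference, a probe whose flank
exceeds its distance to a transcript end, `min_overlap` beyond the
flank, and cross-contig or cross-strand fusion joins are all errors with
specific messages. Deterministic outputs are a contract: every
generator is a pure function of (config, seed) with per-generator
substreams, and the pipeline's reports are byte-identical across reruns
with the same seed.

## Known limitations

Phase calling is limited to variant pairs closer than k − 1 bases.
The quantifier has no bias correction and no multi-sample normalisation
beyond gene ratios. The consequence caller annotates single transcripts
(no canonical-transcript aggregation), does not compute deleteriousness
scores (external scores are ingested as annotation columns only), and
treats exon-boundary-straddling indels conservatively as splice_site.
Junction detection only counts user-specified junctions; there is no
novel-junction discovery and no spliced alignment. Structure analysis
is distance-geometric only — no electrostatics, hydrogen-bond geometry,
or energies.
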