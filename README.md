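# txfuse

Variant-aware transcript isoform quantification and readthrough-fusion
analysis for a two-gene locus, with the surrounding annotation a study of
such a locus needs: variant consequence calls, decay-class prediction,
fusion junction probes, alignment conservation, and protein interface
mapping. The package is built around the insulin locus problem — a gene
with several isoforms (one NMD-structured, one stop-free), a downstream
gene, and a readthrough fusion transcript whose splice junction lands in
the downstream gene's 5'UTR in a shifted reading frame — but every
component is generic and every input can be simulated, so the whole
pipeline runs from a single seed with no downloads.

It is intended for bioinformaticians who want a small, fully testable,
end-to-end reference implementation of this analysis style: each stage is
an exported R function with a documented contract, and seeded generators
provide ground truth for recovery tests.

## What it computes

**Quantification.** Reads are assigned to transcripts by k-mer
compatibility (a read is compatible with transcript *t* when ≥ 80% of its
*k*-mers, k = 31, occur in *t*; both orientations tried), giving
equivalence classes over the transcript set. Abundances come from an EM
on the class counts: with transcript read-origin proportions α and
per-transcript class-generation probabilities W (computed exactly from
all read-length windows of each transcript),

    alpha_t  <-  (1/N) * sum_c  n_c * alpha_t W[c,t] / sum_t' alpha_t' W[c,t']

iterated from a uniform start until the largest change is < 1e-8. TPM is
`count / effective_length` normalised to 1e6, with
`effective_length = length − mean_fragment_length + 1`; percent isoform
usage is TPM-proportional within each gene.

**Allele fractions and phase.** A read supports an allele when it
contains a site-spanning k-mer unique to one haplotype; the alt fraction
is computed over informative reads and thresholded into genotype classes
(hom-ref ≤ 0.1, het 0.2–0.8, hom-alt ≥ 0.9). Two-variant phase is read
off k-mers spanning both sites.

**Annotation.** One consequence per (variant, transcript) by fixed
priority (splice_site > frameshift > stop_gained > stop_lost > missense >
inframe_indel > synonymous > splice_region > UTRs > intronic), NMD
prediction by the 50-nt rule (stop ending > 50 nt upstream of the final
exon–exon junction), nonstop prediction when no in-frame stop is reached,
and HGVS stop-loss extension naming (`p.Ter{N}{Aa}extTer{M}`, M − 1 added
residues).

**Junction, conservation, structure.** Fusion junction probes (20 nt per
side) screened for uniqueness by exhaustive Hamming scan; junction-spanning
read counts requiring ≥ 10 read bases on each side; per-column MSA
conservation as percent identity to a reference row with the 0–9 digit
binning (`floor(percent/10)`, 90–100% → 9); inter-chain contacts
(heavy-atom pairs ≤ 4.0 Å) and metal coordination (N/O/S donors ≤ 2.8 Å
from a metal) from PDB-format coordinates, joined to variant positions via
preproinsulin chain numbering (signal 1–24, B 25–54, C 57–87, A 90–110).

## Worked example

```r
library(txfuse)

# preproinsulin position -> mature chain numbering
prepro_to_chain(c(34, 49, 91))
#>   position region chain_index
#> 1       34      B          10     # the Zn-coordinating His = B10
#> 2       49      B          25     # Phe of the B-chain core  = B25
#> 3       91      A           2     # Ile of the A-chain core  = A2

# stop-loss re-translation into the 3'UTR
apply_stop_loss_retranslate("ATGAAACCCGGGTAATTTTGA", c(0L, 15L),
                            list(pos = 12L, ref = "TAA", alt = "AGA"))$name
#> [1] "p.Ter5ArgextTer3"             # 2 residues (Arg, Phe) appended
parse_hgvs_ext("p.Ter201GlyextTer29")$added_residues
#> [1] 28

# simulate the locus and quantify it
cfg <- simulation_config(seed = 1)   # proportions 0.50/0.25/0.15/0.07/0.03
loc <- simulate_locus(cfg)
sim <- simulate_reads(cfg, loc)      # 20,000 stranded 100-nt reads
idx <- build_index(loc$sequences, k = 31)
em_abundance(assign_reads(sim$reads, idx), idx,
             gene_ids = sapply(loc$models, function(m) m$gene_id))
#>   transcript_id est_count    tpm      gene_id pct_usage
#> 1         A-201    6599.9 508680        GENEA     57.06
#> 2         A-202    3502.1 251946        GENEA     28.26
#> 3         A-203    1577.1 130888        GENEA     14.68
#> 4         B-201     689.5  61987        GENEB    100.00
#> 5       FUS-201     843.4  46499 GENEA--GENEB    100.00
```

The `tpm/1e6` column recovers the configured molar proportions (0.509,
0.252, 0.131, 0.062, 0.046 here at 20k reads with 0.5% errors; < 2
percentage points of error at 200k error-free reads). The heterozygous
3'UTR variant placed at ratio 0.5 is recovered as `alt_fraction 0.524,
genotype het` from 2,416 informative reads, and the 40-nt junction probe
(`GCAAAAAATCACCGGCAATC|AGGGTCTACTTCGATGACGT`) screens `unique` against
the transcriptome and counts 54 junction-spanning reads in this sample.

The full pipeline (simulate → annotate → quantify → junction → conserve →
contacts → report) runs behind one call or the bundled CLI:

```r
run_pipeline(default_pipeline_config(seed = 1, out_dir = "out"))
```

```sh
Rscript inst/cli/txfuse run-all --seed 1 --out-dir out
```

writing fixed-format TSV/JSON reports plus a run manifest; reruns with
the same seed are byte-identical.

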