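# oncocis

Cell-type-aware annotation and prioritization of candidate *cis*-regulatory
cancer mutations.

Most somatic mutations in a sequenced tumour genome are non-coding, and a
handful of them drive disease by rewiring gene regulation — the recurrent
TERT promoter mutations, which create an ETS factor binding site ~66 bp
upstream of the TERT TSS, are the textbook case. `oncocis` takes a list of
candidate mutations together with epigenome data for the relevant cell type
and annotates each one with the evidence a regulatory-genomics analyst
would assemble by hand:

* **open chromatin** — membership in a DNase I hypersensitive site (DHS);
* **flanking histone marks** — an H3K4me1 / H3K4me3 / H3K27ac peak in the
  150–500 bp annulus around the DHS centre (or the mutation, outside DHSs);
* **motif gain/loss** — transcription factor motifs created or removed,
  scored as `Score = log2 Π q(k, s_k) / p(s_k)` against JASPAR-style count
  matrices with uniform background, no pseudocounts, a strict > 5 bit
  cutoff, and a stringency filter that demands an exact match at every
  motif position where one base exceeds 80 % frequency;
* **target gene** — by enhancer–TSS association where available, else the
  nearest TSS within 1 Mbp, with signed distance (negative = upstream);
* **conservation** — mammalian phastCons-style score of the mutated base
  (mean over deleted bases; none for insertions) plus a ±20 bp background;
* **differential expression** — for DHS-resident, gene-assigned mutations
  with matched expression data: fold change of the mutant sample over the
  non-mutant median and a two-sided one-sample t-test of the non-mutant
  values against the mutant value, Bonferroni-adjusted by the number of
  DHS-associated records.

`prioritize_mutations()` keeps records passing all of: DHS, H3K4me1 or
H3K4me3, conservation > 0.8, ≥ 1 motif changed, adjusted p < 0.05.
`bootstrap_overlap()` tests whether a mutation subset overlaps an
annotation set more than random cohort draws (hypergeometric null, 1,000
replicates, one-sample t-test plus empirical p). `simulate_cohort()`
writes a fully synthetic, seeded input set with planted positives and
negatives for validation.

All user-facing functions take and return tibbles and chain with the pipe;
interval arithmetic runs on IRanges/GenomicRanges, sequences on Biostrings.

## Worked example

```r
library(oncocis)
library(dplyr)

dir <- file.path(tempdir(), "cohort")
simulate_cohort(dir, seed = 7)

rec <- annotate_mutations(
  read_mutations(file.path(dir, "mutations.tsv")),
  genome       = read_genome(file.path(dir, "genome.fa")),
  dhs          = read_bed(file.path(dir, "dhs.bed"), "DHS"),
  h3k4me1      = read_bed(file.path(dir, "h3k4me1.bed"), "H3K4me1"),
  h3k4me3      = read_bed(file.path(dir, "h3k4me3.bed"), "H3K4me3"),
  h3k27ac      = read_bed(file.path(dir, "h3k27ac.bed"), "H3K27ac"),
  motifs       = filter_motifs(read_motifs(file.path(dir, "motifs.pfm"))),
  conservation = read_conservation(file.path(dir, "conservation.bedGraph")),
  genes        = read_genes(file.path(dir, "genes.bed")),
  enhancer_tss = read_enhancer_tss(file.path(dir, "enhancer_tss.tsv")),
  expression   = read_expression(file.path(dir, "expression.tsv"),
                                 normal_ids = readLines(file.path(dir, "normal_samples.txt"))),
  coding_mask  = read_bed(file.path(dir, "coding_mask.bed"))
)

summarize_annotations(rec)
#>   n_mutations n_noncoding n_in_dhs n_h3k4me1 n_h3k4me3 n_h3k27ac n_motif_change n_prioritized
#> 1          46          45        4         3         1         1              4             1

prioritize_mutations(rec) |>
  select(chrom, pos, sample_id, gene, motifs_created, conservation, fold_change, adj_p_value)
#>   chrom   pos sample_id gene  motifs_created conservation fold_change adj_p_value
#> 1 chr1  10000 S01       GENE1 ETSF                   0.95        1.42     6.9e-18
```

Of 46 cohort mutations, four fall in a DHS and exactly the planted
positive survives every filter: it sits in open chromatin flanked by
H3K4me1, on a conserved base (0.95), creates the ETS-like fixture motif,
and its sample expresses the enhancer-linked gene far outside the
non-mutant distribution.

The TERT validation case, from the packaged gene model:

```r
g <- tert_gene_model()
distance_to_tss(tert_example_mutations()$pos, g$tss, g$strand)
#> [1] -66 -88
```

And an overlap-enrichment test on a universe with a known 50 % annotation
fraction:

```r
u <- tibble::tibble(annotated = rep(c(TRUE, FALSE), c(5000, 5000)))
glance(bootstrap_overlap(u, 100, "annotated", observed = 80, n_reps = 1000, seed = 1))
#>   observed  mean    sd p_value p_empirical ...
#> 1       80  49.8  4.69       0     0.002
```

The null mean (49.8) and sd (4.69) sit on the hypergeometric values
(50, 4.98); the observed overlap of 80 is far outside the null.

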