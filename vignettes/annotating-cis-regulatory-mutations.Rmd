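---
title: "Annotating cis-regulatory cancer mutations with oncocis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating cis-regulatory cancer mutations with oncocis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncocis)
library(dplyr)
```

## The problem

Whole-genome sequencing of tumours yields tens of thousands of somatic
mutations per cohort, the overwhelming majority non-coding. A small number
of them alter gene regulation in *cis* — the TERT promoter mutations, which
create an ETS factor binding site a few dozen bases upstream of the TERT
TSS, are the canonical example. Unlike germline SNP annotators, a somatic
annotator must work in a cell-type-specific frame: a mutation only matters
in chromatin that is open in the tumour's cell of origin, and its effect is
visible only in the expression of the sample that carries it.

`oncocis` annotates each candidate mutation with:

1. **Open chromatin** — does it fall inside a DNase I hypersensitive site
   (DHS) of the chosen cell type?
2. **Flanking histone marks** — is there an H3K4me1, H3K4me3 or H3K27ac
   peak in the annulus 150–500 bp either side of the anchor (the DHS peak
   centre when the mutation is in a DHS, the mutation itself otherwise)?
   Regulatory elements sit in nucleosome-depleted gaps between marked
   nucleosomes, which is why the core ±150 bp is excluded.
3. **Motif gain/loss** — which transcription factor binding motifs are
   created or removed by the mutation?
4. **Target gene** — via enhancer–TSS associations where available, else
   the nearest TSS within 1 Mbp, with a signed distance (negative =
   upstream in the gene's orientation).
5. **Conservation** — the mammalian phastCons-style score of the mutated
   base (mean across deleted bases for deletions; nothing for insertions,
   which have no mutated reference base), plus the mean over ±20 bp as
   local background.
6. **Differential expression** — is the gene's expression in the mutant
   sample an outlier against all non-mutant samples?

A prioritization filter then keeps mutations that tick every box, and a
bootstrap test assesses whether a mutation subset overlaps an annotation
set more than random draws from the cohort would.

## Motif model

Motifs are JASPAR-style count matrices. A window `s` of width `W` scores

$$\mathrm{Score} = \log_2 \prod_{k=1}^{W} \frac{q(k, s_k)}{p(s_k)}$$

with `q` the column frequency (counts divided by the column sum — **no
pseudocounts**, so a base never observed in the alignment gives probability
0 and the placement scores $-\infty$) and a uniform background
$p = 1/4$. A placement is a hit when the score strictly exceeds 5 bits
(the classical Possum default) **and** it passes a stringency filter: every
well-conserved motif position (one base at > 80 % column frequency) must
match exactly. Both strands are scanned — minus-strand placements score the
reverse complement — because regulatory sites are orientation-free; the
TERT-style ETS site on a minus-strand gene is only found this way. Hits are
reduced to TF names: a motif counts as *created* when it hits the mutant
window but not the wild-type window, *removed* in the opposite case, so
hits confined to the shared flanks cancel exactly. Motif collections are
first filtered to mammalian matrices supported by more than 20 aligned
sequences, the working set that keeps weakly-determined matrices out.

Windows span ±20 bp of the mutation. For indels the wild-type and mutant
windows differ in length and are scanned independently; TF-level
differencing absorbs the coordinate shift. For insertions the stated
window formula degenerates (there is no reference base), so the wild-type
window is the 41 bases centred on the anchor base and the insertion is
placed immediately after it. Windows containing non-ACGT bases simply
cannot produce hits covering those bases.

## Expression model

With a single mutant sample per mutation a two-group test is undefined, so
the test is read the only well-defined way: a one-sample two-sided t-test
of the non-mutant expression values against the mutant value as
hypothesized mean,

$$t = \frac{\bar{x}_\text{non} - x_\text{mut}}{s_\text{non}/\sqrt{n}},
\qquad \mathrm{df} = n - 1.$$

Samples are classified per DHS: every sample with *any* mutation inside
the DHS is mutant, everything else (user-supplied normal samples included)
is non-mutant. Fold change is the mutant value over the non-mutant median.
The Bonferroni family is the number of DHS-resident, gene-assigned
(mutation, gene) records in the run — the unit actually tested; when two
mutant samples share a DHS their records are separate tests. The adjusted
column is named `adj_p_value` and is a family-wise (Bonferroni) quantity,
whatever else one might want to call it. Degenerate inputs follow fixed
rules: fewer than 3 non-mutant values → no p-value; zero variance → p = 1
if the mutant equals the common value, else 0; missing expression cells
are dropped per comparison, never imputed.

## Bootstrap overlap test

`bootstrap_overlap()` draws `subset_size` mutations from the universe
without replacement per replicate and counts annotation members, so
replicate counts are hypergeometric with mean $kp$ and sd
$\sqrt{kp(1-p)(N-k)/(N-1)}$ — the tests assert exactly this calibration.
Significance of the observed overlap is a two-sided one-sample t-test of
the replicates against it, with an empirical rank p-value alongside
(the t-test p under a nearly-normal null with 1,000 replicates is
essentially 0 for any real enrichment; the empirical value is the honest
lower bound of resolution, 1/(n_reps+1)).

## Coordinate conventions and numerical choices

* Mutations are 1-based (`chr5:1,295,228` means the 1,295,228th base);
  BED inputs stay 0-based half-open; conversion happens only inside the
  interval-query helpers (IRanges underneath).
* Deletions are anchored at the first deleted base, insertions at the base
  after which the insertion occurs; anchor-padded VCF-style alleles are
  normalized by stripping the shared leading base.
* Chromosome names gain a `chr` prefix when missing, never lose it.
* The DHS anchor is `floor((start + end) / 2)` of the BED coordinates — a
  deterministic tie-break for odd-length peaks.
* A histone peak counts as flanking when it overlaps the annulus by ≥ 1
  base (peak-overlaps-annulus, not peak-centre-in-annulus): broad peaks
  would otherwise be missed. A peak entirely inside the ±150 core does not
  count — that is "within", not "flanking".
* Equidistant TSS ties break alphabetically by symbol — an arbitrary but
  deterministic rule.
* Conservation gaps are excluded from means rather than zero-filled, which
  would bias conservation downward; the ±20 bp background window includes
  the mutated base. Multi-base substitutions are averaged like deletions.
* Thresholds are strict inequalities throughout (score > 5, frequency
  > 0.8, conservation > 0.8, adjusted p < 0.05, n_sites > 20), matching
  the filter that reproduces the published 18-record candidate list
  exactly.

## The synthetic cohort

`simulate_cohort()` writes a complete toy input set: a 100 kb genome, 17
tumour + 3 normal samples, handcrafted motifs (a conserved ETS-like
`CCGGAA` motif, a GC-box, a uniform never-matching motif, and two motifs
that the taxon/evidence filter must remove), peaks, a conservation track
with plateaus and a gap, gene models on both strands, an enhancer–TSS
association and an expression matrix. One planted positive passes every
annotation stage by construction (its designed 51 bp neighbourhood is an
AC/TG repeat that cannot contain the motif consensus by accident, with a
T>A converting `CCGGTA` to the consensus); planted negatives each fail
exactly one criterion — outside DHS, low conservation, no motif change, no
expression effect (that sample is pinned to the non-mutant mean so its
t-statistic is exactly 0), or inside the coding mask. The planted
expression shift is 8 baseline standard deviations, far beyond the
analytic one-sample-t power knee, so recovery is deterministic across
seeds.

These sizes (100 kb, ~46 mutations, 20 expression samples, 1,000
bootstrap replicates) are the package's chosen validation scale: large
enough for the hypergeometric and power-curve checks to bind, small
enough to run in seconds. What passing them shows is that the machinery
implements the stated rules exactly; what they cannot show is performance
on real epigenomes — mappability artefacts, peak-caller idiosyncrasies,
expression normalization and copy-number confounding are all absent from
the generator.

## Worked example

```{r example}
dir <- file.path(tempdir(), "cohort")
fx <- simulate_cohort(dir, seed = 7)

rec <- annotate_mutations(
  read_mutations(file.path(dir, "mutations.tsv")),
  genome = read_genome(file.path(dir, "genome.fa")),
  dhs = read_bed(file.path(dir, "dhs.bed"), "DHS"),
  h3k4me1 = read_bed(file.path(dir, "h3k4me1.bed"), "H3K4me1"),
  h3k4me3 = read_bed(file.path(dir, "h3k4me3.bed"), "H3K4me3"),
  h3k27ac = read_bed(file.path(dir, "h3k27ac.bed"), "H3K27ac"),
  motifs = filter_motifs(read_motifs(file.path(dir, "motifs.pfm"))),
  conservation = read_conservation(file.path(dir, "conservation.bedGraph")),
  genes = read_genes(file.path(dir, "genes.bed")),
  enhancer_tss = read_enhancer_tss(file.path(dir, "enhancer_tss.tsv")),
  expression = read_expression(file.path(dir, "expression.tsv"),
                               normal_ids = readLines(file.path(dir, "normal_samples.txt"))),
  coding_mask = read_bed(file.path(dir, "coding_mask.bed"))
)

summarize_annotations(rec)
prioritize_mutations(rec) |>
  select(chrom, pos, sample_id, gene, motifs_created, conservation, adj_p_value)
```

And the TERT validation case:

```{r tert}
g <- tert_gene_model()
distance_to_tss(tert_example_mutations()$pos, g$tss, g$strand)
```

## Limitations

* Peak files are consumed as called; there is no signal-level analysis,
  alignment or peak calling.
* Nearest-TSS-within-1-Mbp stands in for full regulatory-domain logic;
  no chromatin-loop data beyond the user's enhancer–TSS table is used.
* One conservation track, one cell type per run; no built-in epigenome
  library — cell-type specificity is whichever peak files you pass.
* The expression test is an outlier test, not a count model: it assumes
  roughly normal non-mutant expression on whatever scale the matrix is in,
  and a single aberrant sample inflates neither dispersion estimation nor
  normalization because there is none.
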