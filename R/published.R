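#' Published worked example: TERT promoter mutation annotation
#'
#' The two recurrent TERT promoter mutations (chr5:1,295,228 G>A and
#' chr5:1,295,250 G>A) are the canonical validation case for cis-regulatory
#' mutation annotation: both sit upstream of the minus-strand TERT TSS,
#' inside a DHS flanking an H3K4me3 mark, and both create an ETS factor
#' binding site. This helper returns the published annotation record for
#' the pair; the TERT gene model is available via `tert_gene_model()`.
#'
#' @return A tibble with one row per mutation carrying the published
#'   annotation fields.
#' @examples
#' m <- tert_example_mutations()
#' g <- tert_gene_model()
#' distance_to_tss(m$pos, g$tss, g$strand)  # -66, -88
#' @export
tert_example_mutations <- function() {
  oc_mutations(
    chrom = c("chr5", "chr5"), pos = c(1295228L, 1295250L),
    ref = c("G", "G"), alt = c("A", "A"), sample_id = c("TERT1", "TERT2")
  )
}

#' @rdname tert_example_mutations
#' @export
tert_gene_model <- function() {
  tibble(symbol = "TERT", chrom = "chr5", tss = 1295162L, strand = "-")
}

#' @rdname tert_example_mutations
#' @export
tert_published_annotation <- function() {
  tibble(
    chrom = "chr5", pos = c(1295228L, 1295250L), ref = "G", alt = "A",
    kind = "substitution", sample_id = c("TERT1", "TERT2"),
    gene = "TERT", distance_to_tss = c(-66, -88),
    in_dhs = TRUE, h3k4me1 = FALSE, h3k4me3 = TRUE, h3k27ac = FALSE,
    conservation = c(0.008, 0),
    motifs_created = "ELK1;ELF1;FLI1;ELK4;GABPA",
    motifs_removed = c("TFAP2A", ""),
    fantom_promoter = TRUE, fantom_enhancer = FALSE
  )
}

#' Published candidate list: 18 prioritized breast-cancer mutations
#'
#' The annotation records of the 18 mutations from 17 whole-genome
#' sequenced breast cancer samples that met all four prioritization
#' criteria (DHS + H3K4me1/H3K4me3, conservation > 0.8, a motif created or
#' removed, adjusted differential-expression p < 0.05), as published.
#' Conservation printed as 1 is an exact phastCons 1.0; empty motif fields
#' are printed as `-` in the source table and encoded as `""` here. The
#' printed p-values are the Bonferroni-adjusted values used by criterion
#' (a).
#'
#' @return An 18-row annotation record tibble compatible with
#'   [prioritize_mutations()].
#' @export
breast_cancer_candidates <- function() {
  tibble::tribble(
    ~chrom, ~pos, ~sample_id, ~gene, ~distance_to_tss, ~fold_change, ~adj_p_value,
    ~in_dhs, ~h3k4me1, ~h3k4me3, ~h3k27ac, ~conservation, ~motifs_created, ~motifs_removed,
    ~fantom_promoter, ~fantom_enhancer,
    "chr6", 71108774L, "PD4006a", "COL9A1", -95988, 100.12, 1.39e-23,
    TRUE, TRUE, TRUE, TRUE, 1, "Hand1::Tcfe2a", "Klf1", TRUE, FALSE,
    "chr1", 160094923L, "PD4116a", "ATP1A2", -9404, 71.15, 2.99e-19,
    TRUE, TRUE, FALSE, TRUE, 0.981, "ELF1;Hltf", "SP1;ZEB1", TRUE, FALSE,
    "chr7", 92347495L, "PD4107a", "CDK6", 118446, 5.06, 7.75e-07,
    TRUE, TRUE, TRUE, TRUE, 1, "", "NFIC;THAP1", TRUE, FALSE,
    "chr9", 109651512L, "PD4006a", "ZNF462", -26135, 4.79, 2.27e-06,
    TRUE, TRUE, FALSE, TRUE, 0.993, "", "EHF;Erg;FLI1;PPARG::RXRA", FALSE, FALSE,
    "chr1", 208412585L, "PD4116a", "PLXNA2", 5080, 1.63, 4.17e-06,
    TRUE, TRUE, FALSE, TRUE, 0.993, "Nobox;Hltf", "", FALSE, TRUE,
    "chr4", 75560994L, "PD4103a", "BTC", 158888, 2.38, 7.39e-05,
    TRUE, TRUE, FALSE, FALSE, 0.938, "", "CREB1;Mafb", FALSE, FALSE,
    "chr5", 97643723L, "PD4109a", "RGMB", 461275, 2.50, 2.47e-04,
    TRUE, TRUE, FALSE, TRUE, 0.801, "", "ARID3A", FALSE, TRUE,
    "chr17", 2080270L, "PD4005a", "HIC1", -120667, 1.29, 4.02e-04,
    TRUE, TRUE, FALSE, TRUE, 1, "NFIC", "", FALSE, FALSE,
    "chr16", 57334425L, "PD4115a", "PLLP", -15841, 2.09, 8.51e-04,
    TRUE, TRUE, TRUE, TRUE, 1, "", "TFAP2C", TRUE, FALSE,
    "chr2", 219147431L, "PD4198a", "TMBIM1", 9849, 1.65, 2.23e-03,
    TRUE, TRUE, FALSE, TRUE, 0.973, "Foxd3", "NFATC2;Erg", TRUE, FALSE,
    "chr8", 100811550L, "PD4116a", "COX6C", 94692, 2.46, 2.63e-03,
    TRUE, TRUE, FALSE, FALSE, 1, "", "NFKB1;Stat4;Spi1;Bcl6", FALSE, FALSE,
    "chr14", 37612228L, "PD4115a", "SLC25A21", 29637, 1.54, 3.15e-03,
    TRUE, TRUE, FALSE, FALSE, 1, "Hand1::Tcfe2a", "RUNX1;RUNX2;FOXI1", FALSE, FALSE,
    "chr1", 185688035L, "PD4005a", "HMCN1", 15647, 0.61, 4.98e-03,
    TRUE, TRUE, FALSE, TRUE, 0.997, "FOXP1;FOXL1", "", FALSE, FALSE,
    "chr2", 208890286L, "PD3904a", "PLEKHM3", -2, 1.48, 1.09e-02,
    TRUE, TRUE, TRUE, TRUE, 0.998, "", "ELF5;GABPA;FLI1;ELK4;ELK1", TRUE, FALSE,
    "chr10", 93058182L, "PD4005a", "PCGF5", -77814, 0.65, 2.28e-02,
    TRUE, TRUE, FALSE, FALSE, 0.935, "", "Zfx", TRUE, FALSE,
    "chr7", 22617382L, "PD4107a", "IL6", -149383, 2.29, 2.62e-02,
    TRUE, TRUE, FALSE, TRUE, 1, "Hltf;CEBPA;CEBPB", "AR", TRUE, TRUE,
    "chr6", 26533145L, "PD4192a", "HMGN4", 5426, 0.49, 2.62e-02,
    TRUE, TRUE, FALSE, FALSE, 0.979, "", "Zfx", FALSE, TRUE,
    "chr22", 31644327L, "PD4103a", "LIMK2", -36078, 0.79, 3.43e-02,
    TRUE, TRUE, TRUE, TRUE, 0.989, "", "Klf4;SP2;SP1;KLF5;Klf1;ELK1", TRUE, FALSE
  )
}
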