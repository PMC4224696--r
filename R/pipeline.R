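#' Annotation run configuration
#'
#' Collects every tunable threshold of the annotation pipeline with its
#' default: motif score cutoff 5 bits, conserved-position frequency 0.8,
#' sequence window pad 20 bp, flanking-histone annulus 150-500 bp, maximum
#' TSS distance 1 Mbp, promoter/enhancer transcript extension 500 bp,
#' background conservation pad 20 bp, and the prioritization thresholds
#' (conservation > 0.8, adjusted p < 0.05).
#'
#' @param motif_cutoff Motif score cutoff in bits (exclusive).
#' @param conserved_threshold Conserved-position frequency (exclusive).
#' @param window_pad Sequence window half-width around the mutation (bp).
#' @param flank_inner,flank_outer Flanking-histone annulus bounds (bp).
#' @param max_gene_dist Maximum mutation-TSS distance (bp).
#' @param fantom_extension Promoter/enhancer transcript extension (bp).
#' @param background_pad Background conservation window half-width (bp).
#' @param min_conservation Prioritization conservation threshold (exclusive).
#' @param max_adj_p Prioritization adjusted-p threshold (exclusive).
#' @return A named list of class `oncocis_config`.
#' @export
oc_config <- function(motif_cutoff = 5, conserved_threshold = 0.8, window_pad = 20,
                      flank_inner = 150, flank_outer = 500, max_gene_dist = 1e6,
                      fantom_extension = 500, background_pad = 20,
                      min_conservation = 0.8, max_adj_p = 0.05) {
  cfg <- as.list(environment())
  stopifnot(all(purrr::map_lgl(cfg, function(v) is.numeric(v) && v >= 0)),
            flank_inner <= flank_outer)
  structure(cfg, class = "oncocis_config")
}

#' Annotate candidate mutations with their full cis-regulatory context
#'
#' Runs every annotation stage over a mutation table: DHS membership,
#' flanking histone marks (annulus anchored at the DHS centre when the
#' mutation is inside one, at the mutation otherwise), motif creation and
#' removal, target gene assignment with signed TSS distance, per-base and
#' background conservation, promoter/enhancer transcript overlap, and
#' mutation-linked differential expression (only for DHS-resident,
#' gene-assigned mutations with expression data). Stages whose inputs are
#' not supplied are skipped and their columns left `NA`.
#'
#' @param mutations Mutation tibble ([oc_mutations()], [read_mutations()]).
#' @param genome Genome [Biostrings::DNAStringSet] ([read_genome()]).
#' @param dhs DHS peak tibble.
#' @param h3k4me1,h3k4me3,h3k27ac Histone mark peak tibbles.
#' @param motifs Motif list ([read_motifs()], usually [filter_motifs()]ed).
#' @param conservation Conservation tibble ([read_conservation()]).
#' @param genes Gene model tibble ([read_genes()]).
#' @param enhancer_tss Enhancer-TSS association tibble.
#' @param fantom_promoters,fantom_enhancers Transcript interval tibbles.
#' @param expression Expression tibble ([read_expression()]).
#' @param coding_mask Optional coding-region interval tibble; mutations
#'   overlapping it are flagged `noncoding = FALSE`.
#' @param config Thresholds, see [oc_config()].
#' @return A tibble with one row per mutation-gene annotation record,
#'   ordered by chromosome, position, sample and gene.
#' @export
annotate_mutations <- function(mutations, genome = NULL, dhs = NULL,
                               h3k4me1 = NULL, h3k4me3 = NULL, h3k27ac = NULL,
                               motifs = NULL, conservation = NULL, genes = NULL,
                               enhancer_tss = NULL, fantom_promoters = NULL,
                               fantom_enhancers = NULL, expression = NULL,
                               coding_mask = NULL, config = oc_config()) {
  rec <- dhs_hit(mutations, dhs %||% tibble(chrom = character(), start = integer(),
                                            end = integer()))
  rec$noncoding <- TRUE
  if (!is.null(coding_mask) && nrow(coding_mask) > 0 && nrow(rec) > 0) {
    span_end <- rec$pos + pmax(nchar(rec$ref), 1L) - 1L
    hits <- interval_hits(coding_mask, rec$chrom, rec$pos, span_end)
    rec$noncoding[unique(hits$query)] <- FALSE
  }

  anchor <- flank_anchor(rec$pos, rec$dhs_start, rec$dhs_end)
  mark_flag <- function(peaks) {
    if (is.null(peaks)) return(rep(NA, nrow(rec)))
    histone_flanking(anchor, rec$chrom, peaks, config$flank_inner, config$flank_outer)
  }
  rec$h3k4me1 <- mark_flag(h3k4me1)
  rec$h3k4me3 <- mark_flag(h3k4me3)
  rec$h3k27ac <- mark_flag(h3k27ac)

  rec$motifs_created <- NA_character_
  rec$motifs_removed <- NA_character_
  if (!is.null(genome) && !is.null(motifs) && nrow(rec) > 0) {
    for (i in seq_len(nrow(rec))) {
      w <- build_windows(rec[i, ], genome, pad = config$window_pad)
      d <- diff_motifs(
        scan_motifs(w$wt, motifs, config$motif_cutoff, config$conserved_threshold),
        scan_motifs(w$mut, motifs, config$motif_cutoff, config$conserved_threshold)
      )
      rec$motifs_created[i] <- paste(d$created, collapse = ";")
      rec$motifs_removed[i] <- paste(d$removed, collapse = ";")
    }
  }

  if (!is.null(conservation)) {
    rec$conservation <- suppressWarnings(mutation_conservation(rec, conservation))
    rec$background_conservation <- suppressWarnings(
      background_conservation(rec, conservation, pad = config$background_pad)
    )
  } else {
    rec$conservation <- NA_real_
    rec$background_conservation <- NA_real_
  }

  ff <- fantom_flags(rec, fantom_promoters, fantom_enhancers,
                     extension = config$fantom_extension)
  rec$fantom_promoter <- ff$fantom_promoter
  rec$fantom_enhancer <- ff$fantom_enhancer

  if (!is.null(genes)) {
    assign <- map_to_gene(rec, genes, enhancer_tss, max_dist = config$max_gene_dist)
    rec <- rec[assign$mutation_row, , drop = FALSE]
    rec$gene <- assign$gene
    rec$gene_source <- assign$source
    rec$distance_to_tss <- assign$distance_to_tss
  } else {
    rec$gene <- NA_character_
    rec$gene_source <- "none"
    rec$distance_to_tss <- NA_real_
  }

  rec <- add_expression_stats(rec, mutations, expression)
  rec |>
    arrange(.data$chrom, .data$pos, .data$sample_id, .data$gene) |>
    select(
      "chrom", "pos", "ref", "alt", "kind", "sample_id", "noncoding",
      "gene", "gene_source", "distance_to_tss",
      "fold_change", "p_value", "adj_p_value", "n_non_mutant",
      "in_dhs", "dhs_start", "dhs_end", "h3k4me1", "h3k4me3", "h3k27ac",
      "conservation", "background_conservation",
      "motifs_created", "motifs_removed",
      "fantom_promoter", "fantom_enhancer"
    )
}

#' Prioritize candidate cis-regulatory mutations
#'
#' Retains annotation records satisfying all of: inside a DHS; flanking
#' H3K4me1 or H3K4me3; mutated-base conservation strictly above
#' `min_conservation`; at least one motif created or removed; adjusted
#' differential-expression p-value strictly below `max_adj_p`. H3K27ac is
#' annotated but not required.
#'
#' @param records Annotation record tibble ([annotate_mutations()]).
#' @param min_conservation Conservation threshold (exclusive), default 0.8.
#' @param max_adj_p Adjusted-p threshold (exclusive), default 0.05.
#' @return The retained records.
#' @export
prioritize_mutations <- function(records, min_conservation = 0.8, max_adj_p = 0.05) {
  has_motif <- !is.na(records$motifs_created) | !is.na(records$motifs_removed)
  has_motif <- has_motif &
    (dplyr::coalesce(records$motifs_created, "") != "" |
       dplyr::coalesce(records$motifs_removed, "") != "")
  keep <- records$in_dhs &
    (dplyr::coalesce(records$h3k4me1, FALSE) | dplyr::coalesce(records$h3k4me3, FALSE)) &
    !is.na(records$conservation) & records$conservation > min_conservation &
    has_motif &
    !is.na(records$adj_p_value) & records$adj_p_value < max_adj_p
  records[which(keep), , drop = FALSE]
}

#' Summarize an annotation run
#'
#' Counts are per mutation (a mutation annotated against two genes counts
#' once), except `n_prioritized` which is evaluated on records.
#'
#' @param records Annotation record tibble.
#' @param min_conservation,max_adj_p Prioritization thresholds, passed to
#'   [prioritize_mutations()].
#' @return A one-row tibble of counts: total mutations, non-coding, in DHS,
#'   flanking each mark, with any motif change, prioritized.
#' @export
summarize_annotations <- function(records, min_conservation = 0.8, max_adj_p = 0.05) {
  per_mut <- distinct(records, .data$chrom, .data$pos, .data$ref, .data$alt,
                      .data$sample_id, .keep_all = TRUE)
  cnt <- function(x) sum(x, na.rm = TRUE)
  has_motif <- dplyr::coalesce(per_mut$motifs_created, "") != "" |
    dplyr::coalesce(per_mut$motifs_removed, "") != ""
  prio <- prioritize_mutations(records, min_conservation, max_adj_p)
  tibble(
    n_mutations = nrow(per_mut),
    n_noncoding = cnt(per_mut$noncoding),
    n_in_dhs = cnt(per_mut$in_dhs),
    n_h3k4me1 = cnt(per_mut$h3k4me1),
    n_h3k4me3 = cnt(per_mut$h3k4me3),
    n_h3k27ac = cnt(per_mut$h3k27ac),
    n_motif_change = cnt(has_motif),
    n_prioritized = nrow(distinct(prio, .data$chrom, .data$pos, .data$ref,
                                  .data$alt, .data$sample_id))
  )
}

#' Write annotation records to a TSV file
#'
#' Logical flags are written as 0/1 and missing values as empty strings;
#' [read_annotations()] restores the original tibble.
#'
#' @param records Annotation record tibble.
#' @param path Output file.
#' @export
write_annotations <- function(records, path) {
  out <- mutate(records, across(dplyr::where(is.logical), as.integer))
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_annotations
#' @return `read_annotations()` returns the annotation record tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  d <- readr::read_tsv(
    path, na = "", progress = FALSE,
    col_types = readr::cols(
      chrom = "c", pos = "i", ref = "c", alt = "c", kind = "c", sample_id = "c",
      noncoding = "i", gene = "c", gene_source = "c", distance_to_tss = "d",
      fold_change = "d", p_value = "d", adj_p_value = "d", n_non_mutant = "i",
      in_dhs = "i", dhs_start = "i", dhs_end = "i",
      h3k4me1 = "i", h3k4me3 = "i", h3k27ac = "i",
      conservation = "d", background_conservation = "d",
      motifs_created = "c", motifs_removed = "c",
      fantom_promoter = "i", fantom_enhancer = "i"
    )
  )
  d |>
    mutate(
      across(c("noncoding", "in_dhs", "h3k4me1", "h3k4me3", "h3k27ac",
               "fantom_promoter", "fantom_enhancer"), as.logical),
      ref = dplyr::coalesce(.data$ref, ""),
      alt = dplyr::coalesce(.data$alt, ""),
      motifs_created = dplyr::coalesce(.data$motifs_created, ""),
      motifs_removed = dplyr::coalesce(.data$motifs_removed, "")
    )
}

#' Bar chart of annotation run counts
#'
#' @param object A summary tibble from [summarize_annotations()] or an
#'   annotation record tibble (summarized first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_annotation_summary <- function(object, ...) {
  if (!"n_mutations" %in% names(object)) object <- summarize_annotations(object)
  d <- tidyr::pivot_longer(object, dplyr::everything(),
                           names_to = "stage", values_to = "count") |>
    mutate(stage = factor(.data$stage, levels = rev(names(object))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mutations", y = NULL, title = "Annotation summary") +
    ggplot2::theme_minimal()
}
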