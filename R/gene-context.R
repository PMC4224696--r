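#' Signed distance from a mutation to a transcription start site
#'
#' Distances follow the gene's orientation: negative upstream of the TSS,
#' positive downstream, 0 at the TSS itself. For a `+` strand gene the
#' distance is `pos - tss`; for a `-` strand gene it is `tss - pos`.
#'
#' @param pos Mutation position(s), 1-based.
#' @param tss TSS coordinate(s), 1-based.
#' @param strand `"+"` or `"-"` per gene.
#' @param chrom,gene_chrom Optional chromosome names; when both are given,
#'   a mismatch raises an error.
#' @return Signed distance(s) in bp.
#' @examples
#' distance_to_tss(1295228, 1295162, "-")  # -66, upstream of a minus-strand TSS
#' @export
distance_to_tss <- function(pos, tss, strand, chrom = NULL, gene_chrom = NULL) {
  if (!is.null(chrom) && !is.null(gene_chrom) &&
      any(normalize_chrom(chrom) != normalize_chrom(gene_chrom))) {
    abort("mutation and gene are on different chromosomes")
  }
  n <- max(length(pos), length(tss), length(strand))
  pos <- rep_len(pos, n)
  tss <- rep_len(tss, n)
  strand <- rep_len(strand, n)
  ifelse(strand == "+", pos - tss, tss - pos)
}

#' Map mutations to their most likely target gene
#'
#' Enhancer-TSS associations take priority: a mutation inside an associated
#' enhancer maps to the linked gene (one output row per associated gene).
#' Otherwise the mutation maps to the gene with the nearest TSS on the same
#' chromosome within `max_dist` bp; ties are broken by smaller absolute
#' distance, then alphabetically by symbol. Mutations with no gene within
#' range get `source = "none"`.
#'
#' @param mutations Mutation tibble.
#' @param genes Gene model tibble ([read_genes()]).
#' @param enhancer_tss Optional association tibble ([read_enhancer_tss()]).
#' @param max_dist Maximum TSS distance in bp (default 1e6).
#' @return A tibble with one row per mutation-gene assignment: `mutation_row`
#'   (row index into `mutations`), `gene`, `source`
#'   (`enhancer_association` / `nearest_tss` / `none`) and `distance_to_tss`.
#' @export
map_to_gene <- function(mutations, genes, enhancer_tss = NULL, max_dist = 1e6) {
  n <- nrow(mutations)
  if (n == 0) {
    return(tibble(mutation_row = integer(), gene = character(),
                  source = character(), distance_to_tss = double()))
  }
  assigned <- vector("list", n)

  if (!is.null(enhancer_tss) && nrow(enhancer_tss) > 0) {
    hits <- interval_hits(enhancer_tss, mutations$chrom, mutations$pos)
    if (nrow(hits) > 0) {
      for (q in unique(hits$query)) {
        syms <- sort(unique(enhancer_tss$gene_symbol[hits$peak_row[hits$query == q]]))
        gm <- genes[match(syms, genes$symbol), , drop = FALSE]
        d <- ifelse(
          is.na(gm$tss) | normalize_chrom(gm$chrom %||% "") != mutations$chrom[q],
          NA_real_,
          distance_to_tss(mutations$pos[q], gm$tss, gm$strand)
        )
        assigned[[q]] <- tibble(
          mutation_row = q, gene = syms,
          source = "enhancer_association", distance_to_tss = d
        )
      }
    }
  }

  todo <- which(purrr::map_lgl(assigned, is.null))
  for (q in todo) {
    cand <- genes[genes$chrom == mutations$chrom[q], , drop = FALSE]
    if (nrow(cand) > 0) {
      d <- distance_to_tss(mutations$pos[q], cand$tss, cand$strand)
      cand <- cand[abs(d) <= max_dist, , drop = FALSE]
      d <- d[abs(d) <= max_dist]
    }
    if (nrow(cand) == 0) {
      assigned[[q]] <- tibble(mutation_row = q, gene = NA_character_,
                              source = "none", distance_to_tss = NA_real_)
    } else {
      ord <- order(abs(d), cand$symbol)
      assigned[[q]] <- tibble(
        mutation_row = q, gene = cand$symbol[ord[1]],
        source = "nearest_tss", distance_to_tss = d[ord[1]]
      )
    }
  }
  bind_rows(assigned) |> arrange(.data$mutation_row, .data$gene)
}

#' Flag overlap with (extended) promoter / enhancer transcript predictions
#'
#' CAGE-derived promoter and enhancer predictions locate the transcript
#' rather than the regulatory element, so each interval is extended
#' symmetrically by `extension` bp before testing whether the mutation
#' position falls inside.
#'
#' @param mutations Mutation tibble.
#' @param promoters,enhancers Interval tibbles ([read_bed()]); `NULL` yields
#'   all-`FALSE` flags.
#' @param extension Symmetric extension in bp (default 500).
#' @return A tibble with logical columns `fantom_promoter`, `fantom_enhancer`.
#' @export
fantom_flags <- function(mutations, promoters = NULL, enhancers = NULL, extension = 500) {
  flag_one <- function(peaks) {
    if (is.null(peaks) || nrow(peaks) == 0 || nrow(mutations) == 0) {
      return(rep(FALSE, nrow(mutations)))
    }
    ext <- mutate(peaks,
                  start = pmax(0L, .data$start - as.integer(extension)),
                  end = .data$end + as.integer(extension))
    hits <- interval_hits(ext, mutations$chrom, mutations$pos)
    out <- rep(FALSE, nrow(mutations))
    out[unique(hits$query)] <- TRUE
    out
  }
  tibble(fantom_promoter = flag_one(promoters), fantom_enhancer = flag_one(enhancers))
}
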