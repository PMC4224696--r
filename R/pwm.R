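#' Read JASPAR-style position frequency matrices
#'
#' Parses the JASPAR flat-file PFM format: a `>` header (matrix ID then TF
#' name) followed by four count rows in A, C, G, T order, with or without
#' the `A [ ... ]` row labels. Optional `key=value` tokens on the header
#' (e.g. `taxon=mammals`) are kept as metadata; `default_taxon` fills the
#' tag when a record carries none. The number of contributing sequences
#' (`n_sites`) is the maximum column sum of the counts.
#'
#' @param path PFM flat file.
#' @param default_taxon Taxon tag for records without one.
#' @return A list of `oncocis_pwm` objects, in file order.
#' @export
read_motifs <- function(path, default_taxon = NA_character_) {
  if (!file.exists(path)) abort(sprintf("motif file not found: %s", path))
  lines <- trimws(readr::read_lines(path))
  lines <- lines[nzchar(lines)]
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0) abort(sprintf("no PFM records in %s", path))
  purrr::map(seq_along(headers), function(i) {
    from <- headers[i] + 1L
    to <- if (i < length(headers)) headers[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 4) {
      abort(sprintf("PFM record %d in %s must have 4 count rows", i, path))
    }
    counts <- parse_pfm_rows(block, i, path)
    hdr <- strsplit(sub("^>\\s*", "", lines[headers[i]]), "\\s+")[[1]]
    kv <- grepl("=", hdr, fixed = TRUE)
    meta <- strsplit(hdr[kv], "=", fixed = TRUE)
    meta <- setNames(purrr::map_chr(meta, 2), purrr::map_chr(meta, 1))
    plain <- hdr[!kv]
    name <- if (length(plain) >= 2) plain[2] else plain[1]
    new_pwm(
      name = name,
      id = plain[1],
      counts = counts,
      taxon = unname(meta["taxon"] %|na|% default_taxon)
    )
  })
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

parse_pfm_rows <- function(block, rec, path) {
  rows <- purrr::map(block, function(line) {
    line <- sub("^[ACGTacgt]\\s*", "", line)
    line <- gsub("[][]", " ", line)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
    if (anyNA(vals)) abort(sprintf("non-numeric count in PFM record %d of %s", rec, path))
    vals
  })
  if (length(unique(lengths(rows))) != 1) {
    abort(sprintf("count rows of unequal width in PFM record %d of %s", rec, path))
  }
  counts <- do.call(rbind, rows)
  if (any(counts < 0)) abort(sprintf("negative count in PFM record %d of %s", rec, path))
  rownames(counts) <- c("A", "C", "G", "T")
  counts
}

new_pwm <- function(name, counts, id = name, taxon = NA_character_) {
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1, all(counts >= 0))
  rownames(counts) <- c("A", "C", "G", "T")
  colsum <- colSums(counts)
  if (any(colsum == 0)) abort(sprintf("motif %s has an all-zero column", name))
  structure(
    list(
      name = name, id = id, width = ncol(counts), counts = counts,
      # base probabilities straight from the counts: no pseudocounts, so a
      # base unseen in the alignment has probability exactly 0
      q = sweep(counts, 2, colsum, "/"),
      n_sites = max(colsum),
      taxon = taxon
    ),
    class = "oncocis_pwm"
  )
}

#' @export
print.oncocis_pwm <- function(x, ...) {
  cat(sprintf("<oncocis_pwm> %s (%s), width %d, n_sites %d, taxon %s\n",
              x$name, x$id, x$width, x$n_sites, x$taxon))
  print(round(x$q, 3))
  invisible(x)
}

#' Filter a motif collection by taxon and evidence depth
#'
#' Keeps motifs whose taxon tag is in `taxa` and whose number of
#' contributing sequences is strictly greater than `min_sites`, preserving
#' input order. With the JASPAR 2014 vertebrate set, `taxa = "mammals"` and
#' `min_sites = 20` reproduce the 171-motif mammalian working set used for
#' mutation annotation.
#'
#' @param motifs List of `oncocis_pwm` objects.
#' @param taxa Character vector of taxon tags to keep (`NULL` keeps all).
#' @param min_sites Minimum (exclusive) number of contributing sequences.
#' @return The filtered motif list.
#' @export
filter_motifs <- function(motifs, taxa = "mammals", min_sites = 20) {
  keep <- purrr::map_lgl(motifs, function(m) {
    (is.null(taxa) || (!is.na(m$taxon) && m$taxon %in% taxa)) && m$n_sites > min_sites
  })
  motifs[keep]
}

#' Score a sequence window against a motif
#'
#' The match score is the log2 likelihood ratio summed over motif columns,
#' `sum_k log2(q(k, s_k) / 0.25)`, with a uniform background of 1/4 per
#' base and no pseudocounts: any column where the observed base has count 0
#' drives the score to `-Inf`, as does any base outside A/C/G/T.
#'
#' @param motif An `oncocis_pwm`.
#' @param seq DNA string exactly `motif$width` long.
#' @return Score in bits (possibly `-Inf`).
#' @examples
#' m <- new_pwm("ex", matrix(c(10, 0, 0, 0), 4, 3))  # all-A motif
#' pssm_score(m, "AAA")  # 3 * log2(4) = 6 bits
#' @export
pssm_score <- function(motif, seq) {
  seq <- toupper(seq)
  if (nchar(seq) != motif$width) {
    abort(sprintf("sequence length %d != motif width %d", nchar(seq), motif$width))
  }
  bases <- strsplit(seq, "")[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(-Inf)
  probs <- motif$q[cbind(idx, seq_len(motif$width))]
  if (any(probs == 0)) return(-Inf)
  sum(log2(probs / 0.25))
}

#' Well-conserved positions of a motif
#'
#' A position is well conserved when one base accounts for strictly more
#' than `threshold` of the aligned sequences at that column.
#'
#' @param motif An `oncocis_pwm`.
#' @param threshold Frequency threshold (exclusive), default 0.8.
#' @return A tibble with columns `position` and `base`.
#' @export
conserved_positions <- function(motif, threshold = 0.8) {
  hits <- which(motif$q > threshold, arr.ind = TRUE)
  tibble(
    position = as.integer(hits[, "col"]),
    base = rownames(motif$q)[hits[, "row"]]
  ) |>
    arrange(.data$position)
}

#' Does a sequence match every well-conserved motif position?
#'
#' The stringency filter behind motif gain/loss calls: a window only counts
#' as a binding site when, besides clearing the score cutoff, it carries
#' the exact base at every well-conserved motif position. Motifs with no
#' conserved position always pass.
#'
#' @inheritParams pssm_score
#' @param threshold Conserved-position frequency threshold.
#' @return Logical flag.
#' @export
stringent_match <- function(motif, seq, threshold = 0.8) {
  cp <- conserved_positions(motif, threshold)
  if (nrow(cp) == 0) return(TRUE)
  bases <- strsplit(toupper(seq), "")[[1]]
  all(bases[cp$position] == cp$base)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a sequence window for qualifying motif matches
#'
#' Every placement of every motif on both strands is scored; a placement
#' qualifies when its score strictly exceeds `cutoff` (bits) and it passes
#' the conserved-position filter. Minus-strand placements score the reverse
#' complement of the covered subsequence.
#'
#' @param seq DNA window (character).
#' @param motifs List of `oncocis_pwm` objects.
#' @param cutoff Score cutoff in bits (exclusive), default 5.
#' @param threshold Conserved-position frequency threshold, default 0.8.
#' @return A tibble of qualifying placements with columns `tf`, `offset`
#'   (0-based within the window), `strand`, `score`.
#' @export
scan_motifs <- function(seq, motifs, cutoff = 5, threshold = 0.8) {
  seq <- toupper(seq)
  L <- nchar(seq)
  out <- purrr::map(motifs, function(m) {
    if (m$width > L) return(NULL)
    offs <- 0:(L - m$width)
    rows <- purrr::map(offs, function(o) {
      sub <- substr(seq, o + 1L, o + m$width)
      hits <- list()
      for (strand in c("+", "-")) {
        s <- if (strand == "+") sub else revcomp(sub)
        sc <- pssm_score(m, s)
        if (sc > cutoff && stringent_match(m, s, threshold)) {
          hits[[length(hits) + 1L]] <- tibble(
            tf = m$name, offset = o, strand = strand, score = sc
          )
        }
      }
      hits
    })
    bind_rows(purrr::flatten(rows))
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(tf = character(), offset = integer(),
                  strand = character(), score = double()))
  }
  res
}

#' Motifs created and removed by a mutation
#'
#' TF-name-level set difference of wild-type and mutant hit sets:
#' mutant-specific motifs are "created", wild-type-specific motifs are
#' "removed". Duplicate matrix versions sharing a TF name collapse to one
#' entry.
#'
#' @param wt_hits,mut_hits Hit tibbles from [scan_motifs()] (or character
#'   vectors of TF names).
#' @return A list with sorted character vectors `created` and `removed`.
#' @export
diff_motifs <- function(wt_hits, mut_hits) {
  tf_set <- function(x) {
    if (is.data.frame(x)) sort(unique(x$tf)) else sort(unique(as.character(x)))
  }
  wt <- tf_set(wt_hits)
  mut <- tf_set(mut_hits)
  list(created = setdiff(mut, wt), removed = setdiff(wt, mut))
}

#' Extract wild-type and mutant sequence windows around a mutation
#'
#' The wild-type window spans `pad` bases either side of the affected
#' reference bases; the mutant window swaps the reference allele for the
#' alternate, so the two windows share flanks but may differ in length for
#' indels. For insertions (empty reference allele) the wild-type window is
#' the `2*pad + 1` bases centred on the anchor base and the insertion is
#' placed immediately after the anchor. The reference allele is checked
#' against the genome.
#'
#' @param mutation One-row mutation tibble (see [oc_mutations()]).
#' @param genome A [Biostrings::DNAStringSet] from [read_genome()].
#' @param pad Flank width in bases, default 20.
#' @return A list with elements `wt` and `mut` (character windows) and
#'   `offset`, the 0-based position of the first affected base within `wt`.
#' @export
build_windows <- function(mutation, genome, pad = 20) {
  stopifnot(nrow(mutation) == 1)
  chrom <- mutation$chrom
  pos <- mutation$pos
  ref <- mutation$ref
  alt <- mutation$alt
  if (!chrom %in% names(genome)) abort(sprintf("chromosome %s absent from genome", chrom))
  chr_seq <- genome[[chrom]]
  L <- length(chr_seq)
  ref_len <- max(nchar(ref), 1L)
  from <- max(1L, pos - pad)
  to <- min(L, pos + ref_len - 1L + pad)
  window <- toupper(as.character(chr_seq[from:to]))
  at <- pos - from  # 0-based offset of the anchor base within the window
  if (nchar(ref) > 0) {
    seen <- substr(window, at + 1L, at + nchar(ref))
    if (seen != ref) {
      abort(sprintf("reference mismatch at %s:%d: genome has '%s', mutation claims '%s'",
                    chrom, pos, seen, ref))
    }
    mut <- paste0(substr(window, 1, at), alt,
                  substr(window, at + nchar(ref) + 1L, nchar(window)))
  } else {
    # insertion after the anchor base
    mut <- paste0(substr(window, 1, at + 1L), alt,
                  substr(window, at + 2L, nchar(window)))
  }
  list(wt = window, mut = mut, offset = at)
}
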