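#' Read a BED3+ peak file into an interval tibble
#'
#' Intervals keep the BED convention: 0-based, half-open. The 1-based
#' positions covered by a row `(start, end)` are `start+1 .. end`.
#' `track`/`browser` and `#` comment lines are skipped. Malformed rows
#' (fewer than 3 fields, non-integer or inverted coordinates) raise an
#' error naming the offending line.
#'
#' @param path BED file.
#' @param mark Optional label recorded in the `mark` column
#'   (e.g. `"DHS"`, `"H3K4me1"`).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `mark`.
#' @export
read_bed <- function(path, mark = "other") {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), mark = character()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED row at line %d of %s: fewer than 3 fields",
                  line_no[which(nf < 3)[1]], path))
  }
  start <- suppressWarnings(as.numeric(purrr::map_chr(fields, 2)))
  end <- suppressWarnings(as.numeric(purrr::map_chr(fields, 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    abort(sprintf("invalid interval (need 0 <= start < end) at line %d of %s",
                  line_no[which(bad)[1]], path))
  }
  tibble(
    chrom = normalize_chrom(purrr::map_chr(fields, 1)),
    start = as.integer(start),
    end = as.integer(end),
    name = purrr::map_chr(fields, function(f) if (length(f) >= 4) f[4] else NA_character_),
    mark = mark
  )
}

# IRanges-backed point/interval containment: which rows of `peaks` overlap the
# 1-based closed query [qstart, qend]? Returns a hits tibble (query, peak_row).
interval_hits <- function(peaks, chrom, qstart, qend = qstart) {
  stopifnot(length(chrom) == length(qstart), length(qstart) == length(qend))
  if (nrow(peaks) == 0 || length(chrom) == 0) {
    return(tibble(query = integer(), peak_row = integer()))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(qstart, qend))
  s <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  ov <- GenomicRanges::findOverlaps(q, s)
  tibble(query = S4Vectors::queryHits(ov), peak_row = S4Vectors::subjectHits(ov))
}

#' Read gene models from a BED6 file
#'
#' The transcription start site is strand-aware: for `+` genes the 1-based
#' TSS is `start + 1`, for `-` genes it is `end`.
#'
#' @param path BED6 file (chrom, start, end, symbol, score, strand).
#' @return A tibble with columns `symbol`, `chrom`, `tss`, `strand`.
#' @export
read_genes <- function(path) {
  b <- read_bed(path, mark = "gene")
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 6)) abort(sprintf("gene models require BED6 (strand column): %s", path))
  strand <- purrr::map_chr(fields, 6)
  if (!all(strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  tibble(
    symbol = b$name,
    chrom = b$chrom,
    tss = ifelse(strand == "+", b$start + 1L, b$end),
    strand = strand
  )
}

#' Read an enhancer-TSS association table
#'
#' Tab-separated with four columns: chrom, start, end (BED-style enhancer
#' interval) and the associated gene symbol.
#'
#' @param path Association file.
#' @return A tibble with columns `chrom`, `start`, `end`, `gene_symbol`.
#' @export
read_enhancer_tss <- function(path) {
  if (!file.exists(path)) abort(sprintf("association file not found: %s", path))
  d <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_symbol"),
                       col_types = "ciic", comment = "#", progress = FALSE)
  if (any(is.na(d$start) | is.na(d$end) | d$start >= d$end)) {
    abort(sprintf("invalid enhancer interval in %s", path))
  }
  d$chrom <- normalize_chrom(d$chrom)
  d
}

#' Read a genome FASTA file
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome (names
#'   normalized to the `chr` prefix, first whitespace token).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- normalize_chrom(sub("\\s.*$", "", names(g)))
  g
}

#' Read a per-base conservation track
#'
#' Accepts bedGraph (4 columns, 0-based half-open) or UCSC wiggle
#' (`fixedStep`/`variableStep`, parsed with \pkg{rtracklayer}). Scores must
#' lie in [0, 1] (phastCons-style posterior probabilities); overlapping
#' records are rejected. Bases not covered by any record have no score.
#'
#' @param path Track file.
#' @return A tibble with columns `chrom`, `start`, `end` (BED convention)
#'   and `score`.
#' @export
read_conservation <- function(path) {
  if (!file.exists(path)) abort(sprintf("conservation track not found: %s", path))
  head_lines <- readr::read_lines(path, n_max = 50)
  is_wig <- any(grepl("^(fixedStep|variableStep)", head_lines))
  if (is_wig) {
    gr <- rtracklayer::import(path, format = "wig")
    d <- tibble(
      chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      score = gr$score
    )
  } else {
    lines <- readr::read_lines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    line_no <- which(keep)
    fields <- strsplit(trimws(lines[keep]), "[ \t]+")
    if (any(lengths(fields) < 4)) {
      abort(sprintf("malformed bedGraph row at line %d of %s",
                    line_no[which(lengths(fields) < 4)[1]], path))
    }
    d <- tibble(
      chrom = normalize_chrom(purrr::map_chr(fields, 1)),
      start = as.integer(purrr::map_chr(fields, 2)),
      end = as.integer(purrr::map_chr(fields, 3)),
      score = as.numeric(purrr::map_chr(fields, 4))
    )
    bad <- is.na(d$start) | is.na(d$end) | d$start < 0 | d$start >= d$end
    if (any(bad)) {
      abort(sprintf("invalid interval at line %d of %s", line_no[which(bad)[1]], path))
    }
  }
  if (anyNA(d$score) || any(d$score < 0 | d$score > 1)) {
    abort(sprintf("conservation scores must lie in [0, 1]: %s", path))
  }
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1)) {
    abort(sprintf("overlapping records in conservation track %s", path))
  }
  d
}

# score of each 1-based position, NA where uncovered
conservation_at <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  if (is.null(track) || nrow(track) == 0 || length(pos) == 0) return(out)
  hits <- interval_hits(track, chrom, pos)
  out[hits$query] <- track$score[hits$peak_row]
  out
}

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated with a header row of sample IDs; first column holds gene
#' symbols. Cells may be `NA` (dropped from downstream statistics, never
#' imputed). Samples named in `normal_ids` are flagged as non-cancer
#' controls and always enter the non-mutant group.
#'
#' @param path Expression TSV.
#' @param normal_ids Optional character vector of normal (non-cancer)
#'   sample IDs; each must be a column of the matrix.
#' @return A long tibble with columns `gene`, `sample_id`, `value` and a
#'   `"normal_samples"` attribute.
#' @export
read_expression <- function(path, normal_ids = NULL) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  if (anyDuplicated(header[-1])) abort(sprintf("duplicate sample ID in %s", path))
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double(),
                                                     gene = readr::col_character()),
                       progress = FALSE)
  names(d)[1] <- "gene"
  samples <- names(d)[-1]
  if (anyDuplicated(d$gene)) abort(sprintf("duplicate gene symbol in %s", path))
  if (!is.null(normal_ids)) {
    missing <- setdiff(normal_ids, samples)
    if (length(missing) > 0) {
      abort(sprintf("normal sample(s) absent from expression matrix: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  long <- tidyr::pivot_longer(d, -"gene", names_to = "sample_id", values_to = "value")
  attr(long, "normal_samples") <- normal_ids %||% character()
  long
}

expression_samples <- function(expr) unique(expr$sample_id)

normal_samples <- function(expr) attr(expr, "normal_samples") %||% character()
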