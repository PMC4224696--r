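#' Build a validated mutation table
#'
#' Mutations are the unit of annotation: one candidate variant per row, with
#' the sample it was called in. Coordinates are 1-based; `pos` is the first
#' affected base. Deletions are anchored at the first deleted base
#' (`alt = ""`), insertions at the base after which the inserted sequence
#' lands (`ref = ""`). Anchor-padded alleles in the VCF style (`ref = "AT"`,
#' `alt = "A"`) are normalized by stripping the shared leading base and
#' shifting `pos` accordingly.
#'
#' @param chrom Chromosome names; a `chr` prefix is added when absent.
#' @param pos 1-based position of the first affected base.
#' @param ref Reference allele (`""` or `"-"` for a pure insertion).
#' @param alt Alternate allele (`""` or `"-"` for a pure deletion).
#' @param sample_id Sample label the mutation was observed in.
#'
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `sample_id`
#'   and a derived `kind` (`substitution`, `insertion` or `deletion`).
#' @examples
#' oc_mutations("chr5", 1295228, "G", "A", "S1")
#' @export
oc_mutations <- function(chrom, pos, ref, alt, sample_id) {
  m <- tibble(
    chrom = normalize_chrom(as.character(chrom)),
    pos = pos,
    ref = toupper(ifelse(is.na(ref) | ref %in% c("-", "."), "", as.character(ref))),
    alt = toupper(ifelse(is.na(alt) | alt %in% c("-", "."), "", as.character(alt))),
    sample_id = as.character(sample_id)
  )
  if (any(is.na(suppressWarnings(as.numeric(m$pos)))) ||
      any(as.numeric(m$pos) != floor(as.numeric(m$pos))) ||
      any(as.numeric(m$pos) < 1)) {
    abort("`pos` must contain positive integers (1-based coordinates)")
  }
  m$pos <- as.integer(round(as.numeric(m$pos)))

  # strip shared leading bases of anchor-padded indels ("AT" > "A" at pos 100
  # becomes a deletion of "T" at pos 101)
  norm <- purrr::pmap(list(m$pos, m$ref, m$alt), normalize_alleles)
  m$pos <- purrr::map_int(norm, "pos")
  m$ref <- purrr::map_chr(norm, "ref")
  m$alt <- purrr::map_chr(norm, "alt")

  bad <- which(m$ref == m$alt)
  if (length(bad) > 0) {
    abort(sprintf("ref and alt alleles are identical for mutation %d", bad[1]))
  }
  bad_base <- which(grepl("[^ACGTN]", m$ref) | grepl("[^ACGTN]", m$alt))
  if (length(bad_base) > 0) {
    abort(sprintf("non-nucleotide characters in alleles of mutation %d", bad_base[1]))
  }

  m$kind <- dplyr::case_when(
    m$ref == "" ~ "insertion",
    m$alt == "" ~ "deletion",
    nchar(m$ref) == nchar(m$alt) ~ "substitution",
    TRUE ~ NA_character_
  )
  if (anyNA(m$kind)) {
    i <- which(is.na(m$kind))[1]
    abort(sprintf(
      "mutation %d (%s:%d %s>%s) is a complex variant; only substitutions, insertions and deletions are supported",
      i, m$chrom[i], m$pos[i], m$ref[i], m$alt[i]
    ))
  }
  m
}

normalize_alleles <- function(pos, ref, alt) {
  stripped <- FALSE
  while (nchar(ref) > 0 && nchar(alt) > 0 && nchar(ref) != nchar(alt) &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
    stripped <- TRUE
  }
  # after stripping an anchor-padded insertion, pos points one past the base
  # after which the insertion occurs; step back so pos names that anchor base
  if (stripped && ref == "" && nchar(alt) > 0) pos <- pos - 1L
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Read candidate mutations from a TSV or VCF file
#'
#' The TSV dialect is whitespace/tab delimited with at least five columns:
#' chromosome, 1-based position, reference allele, alternate allele, sample
#' ID. A header line is detected (non-numeric second field) and skipped.
#' VCF input is parsed with \pkg{vcfR}; rows with multiple comma-separated
#' ALT alleles are expanded to one mutation each, and the sample label is
#' taken from the INFO key named by `sample_field` (falling back to the
#' genotype column name when exactly one genotype column is present).
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param sample_field INFO key carrying the sample label (VCF dialect).
#' @return A mutation tibble (see [oc_mutations()]).
#' @export
read_mutations <- function(path, dialect = c("tsv", "vcf"), sample_field = "SAMPLE") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("mutation file not found: %s", path))
  if (dialect == "vcf") {
    return(read_mutations_vcf(path, sample_field))
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(sprintf("no mutations in %s", path))
    return(oc_mutations(character(), integer(), character(), character(), character()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1]][2])))) start <- 2L
  if (start > length(fields)) {
    warn(sprintf("no mutations in %s", path))
    return(oc_mutations(character(), integer(), character(), character(), character()))
  }
  rows <- fields[start:length(fields)]
  nf <- lengths(rows)
  if (any(nf < 5)) {
    abad <- which(nf < 5)[1] + start - 1L
    abort(sprintf("malformed mutation row at line %d of %s: fewer than 5 fields", abad, path))
  }
  pos_chr <- purrr::map_chr(rows, 2)
  pos_num <- suppressWarnings(as.numeric(pos_chr))
  if (anyNA(pos_num) || any(pos_num < 1) || any(pos_num != floor(pos_num))) {
    abad <- which(is.na(pos_num) | pos_num < 1 | pos_num != floor(pos_num))[1] + start - 1L
    abort(sprintf("position is not a positive integer at line %d of %s", abad, path))
  }
  oc_mutations(
    chrom = purrr::map_chr(rows, 1),
    pos = pos_num,
    ref = purrr::map_chr(rows, 3),
    alt = purrr::map_chr(rows, 4),
    sample_id = purrr::map_chr(rows, 5)
  )
}

read_mutations_vcf <- function(path, sample_field) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    warn(sprintf("no mutations in %s", path))
    return(oc_mutations(character(), integer(), character(), character(), character()))
  }
  samp <- vcfR::extract.info(v, element = sample_field)
  if (all(is.na(samp))) {
    gt_samples <- colnames(v@gt)
    gt_samples <- setdiff(gt_samples, "FORMAT")
    if (length(gt_samples) == 1) {
      samp <- rep(gt_samples, nrow(fix))
    } else {
      warn("no sample label found in VCF; using 'unknown'")
      samp <- rep("unknown", nrow(fix))
    }
  }
  alt_split <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  oc_mutations(
    chrom = fix$CHROM[idx],
    pos = as.numeric(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alt_split),
    sample_id = samp[idx]
  )
}
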