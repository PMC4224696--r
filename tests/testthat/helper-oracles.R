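# Independent brute-force oracles used to cross-check the implementation.
# They deliberately use naive per-base / per-placement loops and a different
# arithmetic path (products instead of log sums) from the package code.

make_pwm <- function(name, counts, taxon = "mammals") {
  oncocis:::new_pwm(name, counts, taxon = taxon)
}

# all peak rows containing 1-based position `pos` (linear scan)
oracle_point_hits <- function(peaks, chrom, pos) {
  which(peaks$chrom == chrom & peaks$start + 1 <= pos & pos <= peaks$end)
}

# any peak base inside the annulus [anchor-outer, anchor-inner] U
# [anchor+inner, anchor+outer]? marks every base explicitly
oracle_flanking <- function(anchor, chrom, peaks, inner = 150, outer = 500) {
  annulus <- c(seq(anchor - outer, anchor - inner), seq(anchor + inner, anchor + outer))
  annulus <- annulus[annulus >= 1]
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != chrom) next
    covered <- seq(peaks$start[i] + 1, peaks$end[i])
    if (any(covered %in% annulus)) return(TRUE)
  }
  FALSE
}

# exhaustive motif scan: every placement x strand, probability product
oracle_scan_tfs <- function(seq, motifs, cutoff = 5, threshold = 0.8) {
  seq <- toupper(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- character()
  for (m in motifs) {
    W <- m$width
    if (W > nchar(seq)) next
    for (o in 0:(nchar(seq) - W)) {
      fwd <- strsplit(substr(seq, o + 1, o + W), "")[[1]]
      for (strand in c("+", "-")) {
        s <- if (strand == "+") fwd else rev(unname(comp[fwd]))
        if (any(is.na(s)) || any(!s %in% c("A", "C", "G", "T"))) next
        prod_q <- 1
        ok <- TRUE
        for (k in seq_len(W)) {
          qk <- m$counts[s[k], k] / sum(m$counts[, k])
          prod_q <- prod_q * qk
          best <- max(m$counts[, k]) / sum(m$counts[, k])
          if (best > threshold && m$counts[s[k], k] / sum(m$counts[, k]) <= threshold) ok <- FALSE
        }
        if (ok && prod_q > 0 && log2(prod_q / 0.25^W) > cutoff) hits <- c(hits, m$name)
      }
    }
  }
  sort(unique(hits))
}

# linear-scan nearest TSS within max_dist
oracle_nearest_gene <- function(chrom, pos, genes, max_dist = 1e6) {
  best <- NULL
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    d <- if (genes$strand[i] == "+") pos - genes$tss[i] else genes$tss[i] - pos
    if (abs(d) > max_dist) next
    if (is.null(best) || abs(d) < abs(best$d) ||
        (abs(d) == abs(best$d) && genes$symbol[i] < best$symbol)) {
      best <- list(symbol = genes$symbol[i], d = d)
    }
  }
  best
}

# shared toy motif set
fixture_motifs <- function() {
  cons_counts <- function(consensus, hi, lo) {
    idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
    m <- matrix(lo, 4, length(idx))
    m[cbind(idx, seq_along(idx))] <- hi
    m
  }
  list(
    make_pwm("ETSF", cons_counts("CCGGAA", 91, 3)),
    make_pwm("GCBOX", cons_counts("GGGCG", 44, 2)),
    make_pwm("UNIF6", matrix(10, 4, 6)),
    make_pwm("PAL6", cons_counts("ACGCGT", 46, 2))  # palindromic consensus
  )
}

# cohort fixture shared across test files (generated once per test run)
cohort_dir <- local({
  dir <- NULL
  function(seed = 7) {
    key <- file.path(tempdir(), sprintf("oncocis-cohort-%d", seed))
    if (!dir.exists(key)) simulate_cohort(key, seed = seed)
    key
  }
})

read_cohort <- function(dir) {
  list(
    mutations = read_mutations(file.path(dir, "mutations.tsv")),
    genome = read_genome(file.path(dir, "genome.fa")),
    dhs = read_bed(file.path(dir, "dhs.bed"), "DHS"),
    h3k4me1 = read_bed(file.path(dir, "h3k4me1.bed"), "H3K4me1"),
    h3k4me3 = read_bed(file.path(dir, "h3k4me3.bed"), "H3K4me3"),
    h3k27ac = read_bed(file.path(dir, "h3k27ac.bed"), "H3K27ac"),
    motifs = filter_motifs(read_motifs(file.path(dir, "motifs.pfm"))),
    conservation = read_conservation(file.path(dir, "conservation.bedGraph")),
    genes = read_genes(file.path(dir, "genes.bed")),
    enhancer_tss = read_enhancer_tss(file.path(dir, "enhancer_tss.tsv")),
    fantom_promoters = read_bed(file.path(dir, "fantom_promoters.bed")),
    fantom_enhancers = read_bed(file.path(dir, "fantom_enhancers.bed")),
    expression = read_expression(file.path(dir, "expression.tsv"),
                                 normal_ids = readLines(file.path(dir, "normal_samples.txt"))),
    coding_mask = read_bed(file.path(dir, "coding_mask.bed")),
    manifest = readr::read_tsv(file.path(dir, "manifest.tsv"), na = character(),
                               show_col_types = FALSE)
  )
}

annotate_cohort <- function(cx, expression = cx$expression) {
  annotate_mutations(
    cx$mutations, genome = cx$genome, dhs = cx$dhs,
    h3k4me1 = cx$h3k4me1, h3k4me3 = cx$h3k4me3, h3k27ac = cx$h3k27ac,
    motifs = cx$motifs, conservation = cx$conservation, genes = cx$genes,
    enhancer_tss = cx$enhancer_tss, fantom_promoters = cx$fantom_promoters,
    fantom_enhancers = cx$fantom_enhancers, expression = expression,
    coding_mask = cx$coding_mask
  )
}
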