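#' Generate a synthetic annotation cohort on disk
#'
#' Writes a complete, self-consistent toy input set for the annotation
#' pipeline: a 100 kb single-chromosome genome, DHS and histone peak BED
#' files, a JASPAR-style motif file, a bedGraph conservation track, gene
#' models, an enhancer-TSS association table, promoter/enhancer transcript
#' intervals, a coding-region mask, a cohort mutation table and a matched
#' gene-by-sample expression matrix. The cohort emulates the study design
#' of a whole-genome cancer series: `n_samples` tumour samples plus
#' `n_normals` expression-only normal samples, with one planted
#' cis-regulatory positive and a panel of planted negatives that each fail
#' exactly one prioritization criterion.
#'
#' Planted loci (ground truth recorded in the manifest):
#' * `P1` - in a DHS flanked by H3K4me1/H3K27ac, conservation 0.95,
#'   creates the ETS-like fixture motif, target gene linked by an
#'   enhancer-TSS association, expression shifted by `effect_sd` standard
#'   deviations in the mutant sample: prioritized.
#' * `N1` - outside any DHS.
#' * `N2` - like `P1` but conservation 0.3.
#' * `N3` - conserved DHS mutation with no motif change.
#' * `N4` - all chromatin/motif/conservation features but no expression
#'   effect.
#' * `C1` - inside the coding mask.
#' Background mutations are scattered over DHS-free regions.
#'
#' The motif file carries five matrices: a strongly conserved ETS-like
#' motif (consensus `CCGGAA`), a conserved GC-box, a uniform (never
#' matching) motif, one motif with too few contributing sequences and one
#' non-mammalian motif - the last two are removed by
#' `filter_motifs(taxa = "mammals", min_sites = 20)`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the directory is byte-identical across re-runs
#'   with the same seed and parameters.
#' @param n_samples Number of tumour samples (>= 5).
#' @param n_normals Number of expression-only normal samples.
#' @param n_background Number of random background mutations.
#' @param effect_sd Planted expression shift in baseline standard
#'   deviations.
#' @param genome_length Genome length in bases (>= 100000; the planted
#'   layout occupies the first 100 kb).
#' @return Invisibly, a list with `paths` (named file paths), `manifest`
#'   (ground-truth tibble) and the generation parameters.
#' @export
simulate_cohort <- function(dir, seed = 7, n_samples = 17, n_normals = 3,
                            n_background = 40, effect_sd = 8,
                            genome_length = 100000) {
  stopifnot(n_samples >= 5, n_normals >= 0, n_background >= 0,
            genome_length >= 100000)
  if (effect_sd < 0) abort("effect_sd must be non-negative")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  withr::with_seed(as.integer(seed), {
    samples <- sprintf("S%02d", seq_len(n_samples))
    normals <- if (n_normals > 0) sprintf("N%02d", seq_len(n_normals)) else character()

    ## genome: random background, designed segments overwritten
    base_mean <- 100
    base_sd <- 5
    g <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
    ac21 <- strsplit(strrep("AC", 11), "")[[1]][1:21]
    tg24 <- strsplit(strrep("TG", 12), "")[[1]][1:24]
    plant_gain <- function(start1) {
      # 51 bp designed segment: AC-repeat | CCGGTA | TG-repeat; the T at
      # start1 + 25 is the planted base, T>A yields the CCGGAA consensus
      g[start1:(start1 + 20)] <<- ac21
      g[(start1 + 21):(start1 + 26)] <<- c("C", "C", "G", "G", "T", "A")
      g[(start1 + 27):(start1 + 50)] <<- tg24
      start1 + 25L
    }
    pos_p1 <- plant_gain(9975L)   # 10000
    pos_n2 <- plant_gain(45025L)  # 45050
    pos_n4 <- plant_gain(75025L)  # 75050
    g[60025:60075] <- strsplit(strrep("AC", 26), "")[[1]][1:51]
    pos_n3 <- 60050L  # 26th char of the repeat = C; C>G changes no motif
    pos_n1 <- 35000L
    pos_c1 <- 80500L

    genome <- Biostrings::DNAStringSet(paste(g, collapse = ""))
    names(genome) <- "chr1"
    Biostrings::writeXStringSet(genome, p("genome.fa"), width = 80)

    write_bed <- function(d, f) {
      readr::write_tsv(d, p(f), col_names = FALSE)
      p(f)
    }
    dhs <- tibble(chrom = "chr1",
                  start = c(9900L, 44950L, 59950L, 74950L, 5000L, 92500L),
                  end = c(10100L, 45150L, 60150L, 75150L, 5200L, 92700L),
                  name = c("dhs_p1", "dhs_n2", "dhs_n3", "dhs_n4",
                           "dhs_decoy1", "dhs_decoy2"))
    write_bed(dhs, "dhs.bed")
    write_bed(tibble(chrom = "chr1", start = c(10200L, 45250L, 75250L),
                     end = c(10400L, 45400L, 75450L)), "h3k4me1.bed")
    write_bed(tibble(chrom = "chr1", start = 60250L, end = 60450L), "h3k4me3.bed")
    write_bed(tibble(chrom = "chr1", start = 9500L, end = 9700L), "h3k27ac.bed")
    write_bed(tibble(chrom = "chr1", start = 80000L, end = 81000L), "coding_mask.bed")
    write_bed(tibble(chrom = "chr1", start = 11800L, end = 12100L), "fantom_promoters.bed")
    write_bed(tibble(chrom = "chr1", start = 9600L, end = 9800L), "fantom_enhancers.bed")

    genes <- tibble(
      symbol = sprintf("GENE%d", 1:8),
      tss = c(12000L, 20000L, 30000L, 40000L, 52000L, 64000L, 76000L, 88000L),
      strand = c("+", "-", "+", "-", "+", "-", "+", "+")
    )
    write_bed(tibble(chrom = "chr1",
                     start = ifelse(genes$strand == "+", genes$tss - 1L, genes$tss - 200L),
                     end = ifelse(genes$strand == "+", genes$tss + 199L, genes$tss),
                     name = genes$symbol, score = 0L, strand = genes$strand),
              "genes.bed")
    readr::write_tsv(tibble(chrom = "chr1", start = 9900L, end = 10100L,
                            gene_symbol = "GENE1"),
                     p("enhancer_tss.tsv"), col_names = FALSE)

    ## conservation: 0.2 baseline, designed plateaus, one gap
    cons <- tibble(
      start = c(0L, 9970L, 10030L, 45020L, 45080L, 60020L, 60080L, 75020L, 75080L, 92000L),
      end = c(9970L, 10030L, 45020L, 45080L, 60020L, 60080L, 75020L, 75080L, 90000L, genome_length),
      score = c(0.2, 0.95, 0.2, 0.3, 0.2, 0.95, 0.2, 0.95, 0.2, 0.2)
    )
    readr::write_tsv(mutate(cons, chrom = "chr1")[, c("chrom", "start", "end", "score")],
                     p("conservation.bedGraph"), col_names = FALSE)

    write_pfm(p("motifs.pfm"))

    ## mutations: planted + background over DHS-free regions
    planted <- tibble(
      name = c("P1", "N1", "N2", "N3", "N4", "C1"),
      pos = c(pos_p1, pos_n1, pos_n2, pos_n3, pos_n4, pos_c1),
      sample_id = samples[1:6],
      alt_rule = c("A", NA, "A", "G", "A", NA)
    )
    pool <- c(15000:34000, 47000:58000, 62000:73000, 84000:89500)
    bg_pos <- if (n_background > 0) sort(sample(pool, n_background)) else integer()
    all_pos <- c(planted$pos, bg_pos)
    ref <- g[all_pos]
    next_base <- setNames(c("C", "G", "T", "A"), c("A", "C", "G", "T"))
    alt <- c(
      ifelse(is.na(planted$alt_rule), next_base[ref[1:6]], planted$alt_rule),
      unname(next_base[ref[-(1:6)]])
    )
    muts <- tibble(
      chrom = "chr1", pos = all_pos, ref = ref, alt = unname(alt),
      sample = c(planted$sample_id,
                 if (n_background > 0) sample(samples, n_background, replace = TRUE))
    )
    readr::write_tsv(muts, p("mutations.tsv"))

    ## expression: baseline noise, planted shifts in the mutant samples of
    ## P1 (GENE1), N2 (GENE4) and N3 (GENE6); N4's GENE7 stays at baseline
    all_ids <- c(samples, normals)
    expr <- matrix(rnorm(8 * length(all_ids), base_mean, base_sd),
                   nrow = 8, dimnames = list(genes$symbol, all_ids))
    expr["GENE1", planted$sample_id[1]] <- base_mean + effect_sd * base_sd
    expr["GENE4", planted$sample_id[3]] <- base_mean + effect_sd * base_sd
    expr["GENE6", planted$sample_id[4]] <- base_mean + effect_sd * base_sd
    # N4's sample sits exactly at the non-mutant mean: fold change ~ 1, p = 1
    expr["GENE7", planted$sample_id[5]] <-
      mean(expr["GENE7", setdiff(all_ids, planted$sample_id[5])])
    expr_df <- as_tibble(expr, rownames = "gene")
    readr::write_tsv(expr_df, p("expression.tsv"))
    readr::write_lines(normals, p("normal_samples.txt"))

    manifest <- tibble(
      name = planted$name, chrom = "chr1", pos = planted$pos,
      sample_id = planted$sample_id,
      expect_in_dhs = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
      expect_h3k4me1 = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
      expect_h3k4me3 = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
      expect_h3k27ac = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
      expect_motif_created = c("ETSF", "", "ETSF", "", "ETSF", ""),
      expect_gene = c("GENE1", "GENE3", "GENE4", "GENE6", "GENE7", "GENE7"),
      expect_conserved = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
      expect_expression_effect = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
      expect_noncoding = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      expect_prioritized = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
    )
    readr::write_tsv(manifest, p("manifest.tsv"))

    files <- c("genome.fa", "dhs.bed", "h3k4me1.bed", "h3k4me3.bed", "h3k27ac.bed",
               "motifs.pfm", "conservation.bedGraph", "genes.bed", "enhancer_tss.tsv",
               "fantom_promoters.bed", "fantom_enhancers.bed", "mutations.tsv",
               "expression.tsv", "normal_samples.txt", "coding_mask.bed", "manifest.tsv")
    invisible(list(
      paths = setNames(as.list(file.path(dir, files)),
                       sub("\\.[^.]*$", "", files)),
      manifest = manifest,
      params = list(seed = seed, n_samples = n_samples, n_normals = n_normals,
                    n_background = n_background, effect_sd = effect_sd,
                    genome_length = genome_length)
    ))
  })
}

write_pfm <- function(path) {
  fmt <- function(id, name, taxon, counts) {
    c(sprintf(">%s %s taxon=%s", id, name, taxon),
      sprintf("%s [ %s ]", c("A", "C", "G", "T"),
              apply(counts, 1, paste, collapse = " ")))
  }
  cons_counts <- function(consensus, hi, lo) {
    idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
    m <- matrix(lo, 4, length(idx))
    m[cbind(idx, seq_along(idx))] <- hi
    m
  }
  lines <- c(
    fmt("FX001", "ETSF", "mammals", cons_counts("CCGGAA", 91, 3)),
    fmt("FX002", "GCBOX", "mammals", cons_counts("GGGCG", 44, 2)),
    fmt("FX003", "UNIF6", "mammals", matrix(10, 4, 6)),
    fmt("FX004", "LOWN", "mammals", cons_counts("TATA", 9, 1)),
    fmt("FX005", "INSECTA", "insects", cons_counts("GATA", 27, 1))
  )
  readr::write_lines(lines, path)
}
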