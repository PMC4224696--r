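test_that("pssm scores are log2 likelihood ratios against a uniform background", {
  unif <- make_pwm("U", matrix(10, 4, 3))
  expect_equal(pssm_score(unif, "ACG"), 0)
  allA <- make_pwm("A", matrix(c(10, 0, 0, 0), 4, 3))
  expect_equal(pssm_score(allA, "AAA"), 6)  # 3 * log2(4)
  expect_equal(pssm_score(allA, "AAC"), -Inf)  # zero count, no pseudocounts
  expect_equal(pssm_score(unif, "ANC"), -Inf)  # non-ACGT base

  # width-4 example frozen from a hand-computed per-column log-ratio sum
  counts <- rbind(A = c(8, 0, 2, 4), C = c(0, 8, 2, 4),
                  G = c(2, 2, 4, 2), T = c(0, 0, 2, 0))
  m <- make_pwm("D", counts)
  expect_equal(pssm_score(m, "ACGG"), 3.7122876, tolerance = 1e-7)
})

test_that("conserved positions use a strict >80% frequency rule", {
  counts <- rbind(A = c(9, 8, 1), C = c(1, 2, 3), G = c(0, 0, 3), T = c(0, 0, 3))
  m <- make_pwm("M", counts)
  cp <- conserved_positions(m)
  expect_equal(cp$position, 1L)   # 0.9 > 0.8; 0.8 exactly is excluded
  expect_equal(cp$base, "A")
  expect_equal(nrow(conserved_positions(make_pwm("U", matrix(10, 4, 4)))), 0)
})

test_that("the stringency filter demands exact bases at conserved positions", {
  counts <- rbind(A = c(9, 2, 0), C = c(1, 3, 1), G = c(0, 3, 9), T = c(0, 2, 0))
  m <- make_pwm("M", counts)  # conserved: (1, A), (3, G)
  expect_true(stringent_match(m, "ATG"))
  expect_false(stringent_match(m, "CTG"))
  expect_true(stringent_match(make_pwm("U", matrix(10, 4, 3)), "TTT"))
})

test_that("sequence windows share flanks and differ only at the mutation", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 30), collapse = "")))
  sub <- oc_mutations("chr1", 60, "T", "A", "S1")
  w <- build_windows(sub, genome)
  expect_equal(nchar(w$wt), 41)
  expect_equal(nchar(w$mut), 41)
  expect_equal(substr(w$wt, 21, 21), "T")
  expect_equal(substr(w$mut, 21, 21), "A")
  expect_equal(substr(w$wt, 1, 20), substr(w$mut, 1, 20))

  del <- oc_mutations("chr1", 60, "TA", "", "S1")
  wd <- build_windows(del, genome)
  expect_equal(nchar(wd$wt), 42)
  expect_equal(nchar(wd$mut), 40)
  expect_equal(substr(wd$wt, 1, 20), substr(wd$mut, 1, 20))
  expect_equal(substr(wd$wt, 23, 42), substr(wd$mut, 21, 40))

  ins <- oc_mutations("chr1", 60, "", "GGG", "S1")
  wi <- build_windows(ins, genome)
  expect_equal(nchar(wi$wt), 41)
  expect_equal(nchar(wi$mut), 44)
  expect_equal(substr(wi$mut, 22, 24), "GGG")

  bad <- oc_mutations("chr1", 60, "G", "A", "S1")
  expect_error(build_windows(bad, genome), "reference mismatch.*chr1:60")
})

test_that("scan agrees with exhaustive placement x strand enumeration", {
  motifs <- fixture_motifs()
  withr::local_seed(3)
  for (rep in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T"), 45, replace = TRUE), collapse = "")
    expect_equal(sort(unique(scan_motifs(seq, motifs)$tf)), oracle_scan_tfs(seq, motifs),
                 info = seq)
  }
  # planted consensus at the window centre is found
  planted <- paste0(strrep("AC", 9), "CCGGAA", strrep("TG", 9))
  expect_true("ETSF" %in% scan_motifs(planted, motifs)$tf)
  expect_equal(sort(unique(scan_motifs(planted, motifs)$tf)),
               oracle_scan_tfs(planted, motifs))
})

test_that("all-N windows yield no hits and palindromes are reported once per strand pair", {
  motifs <- fixture_motifs()
  expect_equal(nrow(scan_motifs(strrep("N", 41), motifs)), 0)
  pal <- paste0(strrep("T", 10), "ACGCGT", strrep("T", 10))
  hits <- scan_motifs(pal, motifs)
  pal_hits <- hits[hits$tf == "PAL6", ]
  expect_setequal(pal_hits$strand, c("-", "+"))
  expect_equal(pal_hits$score[1], pal_hits$score[2])
  expect_equal(unique(pal_hits$offset), 10)
})

test_that("raising cutoff or conservation threshold never enlarges the hit set", {
  motifs <- fixture_motifs()
  withr::local_seed(9)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE,
                        prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    base <- unique(scan_motifs(seq, motifs, cutoff = 2, threshold = 0.9)$tf)
    expect_true(all(unique(scan_motifs(seq, motifs, cutoff = 5, threshold = 0.9)$tf) %in% base))
    expect_true(all(unique(scan_motifs(seq, motifs, cutoff = 2, threshold = 0.5)$tf) %in% base))
  }
})

test_that("consensus scores the analytic maximum over all sequences (exhaustive, W<=6)", {
  counts <- rbind(A = c(8, 1, 2), C = c(0, 7, 2), G = c(2, 2, 4), T = c(0, 0, 2))
  m <- make_pwm("M", counts)
  analytic_max <- sum(log2(apply(m$q, 2, max) / 0.25))
  all_seqs <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 3)))
  scores <- purrr::map_dbl(all_seqs, function(s) pssm_score(m, s))
  expect_equal(max(scores), analytic_max)
  consensus <- paste(rownames(m$q)[apply(m$q, 2, which.max)], collapse = "")
  expect_equal(pssm_score(m, consensus), analytic_max)
})

test_that("motif differencing is a TF-level set difference with empty intersection", {
  d <- diff_motifs(c("A", "B"), c("B", "C"))
  expect_equal(d, list(created = "C", removed = "A"))
  expect_equal(diff_motifs(c("A"), c("A")), list(created = character(), removed = character()))
  expect_length(intersect(d$created, d$removed), 0)
})

test_that("substitutions outside every hit leave created and removed empty", {
  motifs <- fixture_motifs()
  withr::local_seed(21)
  genome_str <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = genome_str))
  for (pos in seq(100, 1900, by = 60)) {
    ref <- substr(genome_str, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    w <- build_windows(oc_mutations("chr1", pos, ref, alt, "S"), genome)
    wt_hits <- scan_motifs(w$wt, motifs)
    mut_hits <- scan_motifs(w$mut, motifs)
    d <- diff_motifs(wt_hits, mut_hits)
    # every changed TF must have at least one hit covering the mutated base
    # (window offset 20); flank-only hits are identical in both windows
    for (tf in c(d$created, d$removed)) {
      h <- dplyr::bind_rows(wt_hits, mut_hits)
      h <- h[h$tf == tf, ]
      width <- motifs[[match(tf, purrr::map_chr(motifs, "name"))]]$width
      expect_true(any(h$offset <= 20 & 20 < h$offset + width), info = paste(pos, tf))
    }
    expect_length(intersect(d$created, d$removed), 0)
  }
})
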