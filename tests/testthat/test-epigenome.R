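test_that("DHS membership follows BED boundaries and covers deletions partially", {
  dhs <- tibble::tibble(chrom = "chr1", start = 900L, end = 1100L,
                        name = NA_character_, mark = "DHS")
  m <- oc_mutations(rep("chr1", 3), c(1000, 900, 1100), c("A", "A", "A"),
                    c("G", "G", "G"), "S1")
  r <- dhs_hit(m, dhs)
  expect_equal(r$in_dhs, c(TRUE, FALSE, TRUE))  # 900 is the base before the peak
  expect_equal(r$dhs_start[1], 900L)

  # deletion spanning the peak edge: any deleted base inside counts
  del <- oc_mutations("chr1", 1099, "AAA", "", "S1")
  expect_true(dhs_hit(del, dhs)$in_dhs)
  del2 <- oc_mutations("chr1", 1101, "AAA", "", "S1")
  expect_false(dhs_hit(del2, dhs)$in_dhs)
})

test_that("book-ended duplicate peaks resolve to the smallest start", {
  dhs <- tibble::tibble(chrom = "chr1", start = c(950L, 900L), end = c(1150L, 1100L),
                        name = NA, mark = "DHS")
  r <- dhs_hit(oc_mutations("chr1", 1000, "A", "G", "S1"), dhs)
  expect_equal(r$dhs_start, 900L)
})

test_that("flank anchor is the DHS midpoint (floor) inside a DHS, else the mutation", {
  expect_equal(flank_anchor(1234, 900L, 1100L), 1000L)
  expect_equal(flank_anchor(1234, 900L, 1101L), 1000L)  # odd length floors
  expect_equal(flank_anchor(5432, NA_integer_, NA_integer_), 5432L)
})

test_that("histone marks count only when a peak overlaps the flanking annulus", {
  peak <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e,
                                        name = NA, mark = "H3K4me1")
  expect_true(histone_flanking(10000L, "chr1", peak(10200L, 10400L)))
  # entirely inside the +/-150 core: not flanking
  expect_false(histone_flanking(10000L, "chr1", peak(9990L, 10010L)))
  # broad peak spanning core and both windows
  expect_true(histone_flanking(10000L, "chr1", peak(9000L, 11000L)))
  # just beyond the outer bound on the left
  expect_false(histone_flanking(10000L, "chr1", peak(9400L, 9499L)))
  expect_true(histone_flanking(10000L, "chr1", peak(9400L, 9500L)))
})

test_that("flanking flags match a per-base annulus oracle and its symmetries", {
  withr::local_seed(11)
  for (rep in 1:30) {
    anchor <- sample(2000:6000, 1)
    peaks <- tibble::tibble(
      chrom = "chr1",
      start = sample(0:8000, 8, replace = TRUE)
    )
    peaks$end <- peaks$start + sample(1:400, 8, replace = TRUE)
    peaks$name <- NA
    peaks$mark <- "H3K4me1"
    got <- histone_flanking(anchor, "chr1", peaks)
    expect_equal(got, oracle_flanking(anchor, "chr1", peaks))
    # reflecting all coordinates about the anchor preserves the flag
    refl <- tibble::tibble(chrom = "chr1",
                           start = 2 * anchor - peaks$end,
                           end = 2 * anchor - peaks$start,
                           name = NA, mark = "H3K4me1")
    expect_equal(histone_flanking(anchor, "chr1", refl), got)
    # zero-width annulus finds nothing; infinite outer equals co-occurrence
    expect_false(histone_flanking(anchor, "chr1", peaks, inner = 150, outer = 150) &&
                   !oracle_flanking(anchor, "chr1", peaks, 150, 150))
    expect_equal(histone_flanking(anchor, "chr1", peaks, inner = 0, outer = 1e7),
                 any(peaks$chrom == "chr1"))
  }
})
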