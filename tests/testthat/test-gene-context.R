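test_that("TSS distances are signed by gene orientation", {
  # minus-strand gene: upstream positions are numerically larger
  g <- tert_gene_model()
  expect_equal(distance_to_tss(c(1295228, 1295250), g$tss, g$strand), c(-66, -88))
  expect_equal(distance_to_tss(1000, 1000, "+"), 0)
  expect_equal(distance_to_tss(900, 1000, "+"), -100)
  expect_equal(distance_to_tss(900, 1000, "-"), 100)
  expect_error(distance_to_tss(900, 1000, "+", chrom = "chr1", gene_chrom = "chr2"),
               "different chromosomes")
})

test_that("flipping strand with fixed coordinates negates the distance", {
  withr::local_seed(5)
  pos <- sample(1e6, 50)
  tss <- sample(1e6, 50)
  expect_equal(distance_to_tss(pos, tss, "+"), -distance_to_tss(pos, tss, "-"))
})

test_that("enhancer associations outrank the nearest TSS", {
  genes <- tibble::tibble(symbol = c("GENE1", "GENE2"), chrom = "chr1",
                          tss = c(50000L, 10050L), strand = "+")
  assoc <- tibble::tibble(chrom = "chr1", start = 9900L, end = 10100L,
                          gene_symbol = "GENE1")
  m <- oc_mutations("chr1", 10000, "A", "G", "S1")
  a <- map_to_gene(m, genes, assoc)
  expect_equal(a$gene, "GENE1")  # association wins over GENE2's TSS 50 bp away
  expect_equal(a$source, "enhancer_association")
  # without the association the nearest TSS wins
  a2 <- map_to_gene(m, genes, NULL)
  expect_equal(a2$gene, "GENE2")
  expect_equal(a2$source, "nearest_tss")
  expect_equal(a2$distance_to_tss, -50)
})

test_that("mutations in several associated enhancers map to every linked gene", {
  genes <- tibble::tibble(symbol = c("GENE1", "GENE2"), chrom = "chr1",
                          tss = c(50000L, 90000L), strand = "+")
  assoc <- tibble::tibble(chrom = "chr1", start = c(9900L, 9950L), end = c(10100L, 10200L),
                          gene_symbol = c("GENE1", "GENE2"))
  a <- map_to_gene(oc_mutations("chr1", 10000, "A", "G", "S1"), genes, assoc)
  expect_equal(sort(a$gene), c("GENE1", "GENE2"))
})

test_that("the nearest-TSS fallback respects the distance cap and tie-breaks", {
  genes <- tibble::tibble(symbol = c("BBB", "AAA"), chrom = "chr1",
                          tss = c(2000000L, 3000000L), strand = "+")
  m <- oc_mutations("chr1", 500000, "A", "G", "S1")
  a <- map_to_gene(m, genes)
  expect_equal(a$source, "none")  # nearest TSS is 1.5 Mbp away
  expect_true(is.na(a$gene))
  # ties break alphabetically
  gt <- tibble::tibble(symbol = c("BBB", "AAA"), chrom = "chr1",
                       tss = c(900L, 1100L), strand = "+")
  at <- map_to_gene(oc_mutations("chr1", 1000, "A", "G", "S1"), gt)
  expect_equal(at$gene, "AAA")
  # max_dist 0 only matches a TSS coinciding with the mutation
  expect_equal(map_to_gene(oc_mutations("chr1", 900, "A", "G", "S1"), gt,
                           max_dist = 0)$gene, "BBB")
})

test_that("nearest-TSS assignment agrees with a linear-scan oracle", {
  withr::local_seed(13)
  for (rep in 1:10) {
    genes <- tibble::tibble(
      symbol = sprintf("G%03d", sample(999, 80)),
      chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
      tss = sample(3e6, 80),
      strand = sample(c("+", "-"), 80, replace = TRUE)
    )
    pos <- sample(3e6, 15)
    m <- oc_mutations(rep("chr1", 15), pos, "A", "G", "S1")
    a <- map_to_gene(m, genes)
    for (i in seq_len(15)) {
      want <- oracle_nearest_gene("chr1", pos[i], genes)
      row <- a[a$mutation_row == i, ]
      if (is.null(want)) {
        expect_equal(row$source, "none")
      } else {
        expect_equal(row$gene, want$symbol)
        expect_equal(row$distance_to_tss, want$d)
      }
    }
  }
})

test_that("promoter/enhancer transcript overlap honours the symmetric extension", {
  prom <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5200L,
                         name = NA, mark = "promoter")
  m <- oc_mutations(rep("chr1", 3), c(4600, 4400, 5100), "A", "G", "S1")
  ff <- fantom_flags(m, promoters = prom, extension = 500)
  expect_equal(ff$fantom_promoter, c(TRUE, FALSE, TRUE))
  expect_equal(ff$fantom_enhancer, rep(FALSE, 3))
  # extension 0 restores plain overlap
  ff0 <- fantom_flags(m, promoters = prom, extension = 0)
  expect_equal(ff0$fantom_promoter, c(FALSE, FALSE, TRUE))
})
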