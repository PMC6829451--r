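# hand-built toy genome with known region arithmetic:
# 0-100 intergenic | 100-400 CDS exon | 400-600 intron (with a nested
# 420-540 ORF) | 600-700 CDS exon | 700-800 intergenic | 800-900 rRNA |
# 900-1000 intergenic
toy_region_genome <- function() {
  set.seed(3)
  annotated_mitogenome("toyr", rand_seq(1000, at = 0.6), list(
    gene_feature("cox1", "CDS", rbind(c(100L, 400L), c(600L, 700L))),
    gene_feature("orfX", "ORF", c(420L, 540L)),
    gene_feature("rns", "rRNA", c(800L, 900L))))
}

test_that("region partition has known lengths and full coverage", {
  rp <- region_partition(toy_region_genome())
  expect_identical(unname(rp$lengths["protein_coding"]), 400L)
  expect_identical(unname(rp$lengths["intronic"]), 200L)
  expect_identical(unname(rp$lengths["rna"]), 100L)
  expect_identical(unname(rp$lengths["intergenic"]), 300L)
  expect_identical(sum(rp$lengths), 1000L)
  expect_equal(sum(rp$proportions), 100)
})

test_that("intron-encoded ORFs count as intronic, not protein-coding", {
  rp <- region_partition(toy_region_genome())
  # the 120 bp orfX lies inside the cox1 intron; intronic stays 200
  expect_identical(unname(rp$lengths["intronic"]), 200L)
  # and orfX/cox1 nesting is not reported as a gene overlap
  expect_false(any(rp$overlaps$gene_a == "orfX" |
                     rp$overlaps$gene_b == "orfX"))
})

test_that("partial gene overlaps are reported with their length", {
  set.seed(4)
  g <- annotated_mitogenome("ov", rand_seq(600, at = 0.6), list(
    gene_feature("cox3", "CDS", c(100L, 400L)),
    gene_feature("orf632", "CDS", c(315L, 550L))))
  rp <- region_partition(g)
  expect_identical(nrow(rp$overlaps), 1L)
  expect_identical(rp$overlaps$overlap_bp, 85L)
})

test_that("intergenic spans carry flanks and wrap the circular seam", {
  rp <- region_partition(toy_region_genome())
  sp <- rp$intergenic_spans
  expect_true(all(sp$length > 0))
  # seam span merges 900-1000 and 0-100 into one 200 bp gap
  expect_identical(sum(sp$length), 300L)
  expect_identical(max(sp$length), 200L)
  i <- which.max(sp$length)
  expect_identical(sp$left[i], "rns")
  expect_identical(sp$right[i], "cox1")
  s <- intergenic_summary(rp)
  expect_identical(s$total, 300L)
  expect_identical(s$longest_flanks, c("rns", "cox1"))
})

test_that("expansion decomposition sums to 100% and errors when equal", {
  pr <- shared_pair()
  pa <- region_partition(pr$a); pb <- region_partition(pr$b)
  d <- expansion_decomposition(pa, pb)
  expect_equal(sum(d$contributions), 100)
  expect_identical(d$size_difference,
                   nchar(pr$b$sequence) - nchar(pr$a$sequence))
  # intron gain dominates the expansion in the study design
  expect_identical(names(which.max(d$contributions)), "intronic")
  expect_error(expansion_decomposition(pa, pa), "same size")
})

test_that("partition conservation holds on random genomes", {
  set.seed(99)
  for (i in 1:20) {
    g <- random_genome(paste0("r", i), n_genes = sample(3:10, 1))
    rp <- region_partition(g)
    expect_identical(sum(rp$lengths), nchar(g$sequence))
    expect_equal(sum(rp$proportions), 100)
  }
})
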