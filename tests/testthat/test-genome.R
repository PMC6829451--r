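test_that("gene_feature validates intervals, kinds and strands", {
  expect_s3_class(gene_feature("cox1", "CDS", c(0L, 30L)), "gene_feature")
  expect_error(gene_feature("x", "gene", c(0L, 10L)))
  expect_error(gene_feature("x", "CDS", c(10L, 10L)), "start >= end")
  expect_error(gene_feature("x", "CDS", rbind(c(0L, 20L), c(15L, 30L))),
               "overlapping")
  expect_error(gene_feature("x", "CDS", rbind(c(30L, 40L), c(0L, 10L))),
               "not sorted")
  expect_error(gene_feature("x", "CDS", c(0L, 10L), strand = "x"))
})

test_that("annotated_mitogenome validates sequence and coordinates", {
  expect_error(annotated_mitogenome("g", "ACGU"), "outside")
  f <- gene_feature("cox1", "CDS", c(0L, 60L))
  expect_error(annotated_mitogenome("g", "ACGT", list(f)), "beyond")
  expect_error(
    annotated_mitogenome("g", strrep("ACGT", 40), list(f, f)),
    "more than once")
})

test_that("coding_sequence splices exons and honours strand", {
  s <- paste0("AAATTT", "GGGCCC", "ATATAT", "CCCGGG", "TTTAAA")
  g <- annotated_mitogenome("toy", s, list(
    gene_feature("plus", "CDS", rbind(c(0L, 6L), c(12L, 18L))),
    gene_feature("minus", "CDS", rbind(c(6L, 12L), c(18L, 24L)),
                 strand = "-")))
  expect_identical(coding_sequence(g, "plus"), "AAATTTATATAT")
  # minus strand: revcomp of concatenated exons in genome order
  expect_identical(coding_sequence(g, "minus"),
                   revcomp(paste0("GGGCCC", "CCCGGG")))
  expect_error(coding_sequence(g, "absent"), "not annotated")
})

test_that("origin-spanning features linearize and extract correctly", {
  n <- 40L
  s <- strrep("ACGT", 10)
  f <- gene_feature("wrap", "CDS", rbind(c(32L, 40L), c(0L, 4L)),
                    origin_span = TRUE)
  g <- annotated_mitogenome("circ", s, list(f))
  expect_identical(nchar(mitocompare:::feature_sequence(g, f)), 12L)
  expect_identical(mitocompare:::feature_sequence(g, f),
                   paste0(substr(s, 33, 40), substr(s, 1, 4)))
  lin <- mitocompare:::linearize_intervals(f, n)
  expect_identical(lin, mitocompare:::as_intervals(c(32L, 44L)))
})

test_that("rotate_genome preserves gene content and sequences", {
  pr <- shared_pair()
  a <- pr$a
  set.seed(42)
  off <- sample(nchar(a$sequence), 1)
  r <- rotate_genome(a, off)
  expect_identical(nchar(r$sequence), nchar(a$sequence))
  expect_identical(substr(r$sequence, 1, 50),
                   mitocompare:::sub0(a$sequence, off, off + 50L))
  for (nm in c("cox1", "cob", "nad5", "trnM1", "rnl"))
    expect_identical(coding_sequence(r, nm, kind = c("CDS", "rRNA", "tRNA")),
                     coding_sequence(a, nm, kind = c("CDS", "rRNA", "tRNA")),
                     label = nm)
  # rotating back restores the original sequence
  rr <- rotate_genome(r, nchar(a$sequence) - off)
  expect_identical(rr$sequence, a$sequence)
})

test_that("revcomp and helpers are involutions", {
  s <- "ACGTTGCAN"
  expect_identical(revcomp(revcomp(s)), s)
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(mitocompare:::complement_seq("AACG"), "TTGC")
})
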