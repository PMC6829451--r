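# toy genome: plus-strand gene with 2 introns, minus-strand gene with
# 1 intron, all coordinates known by construction
toy_intron_genome <- function() {
  set.seed(5)
  annotated_mitogenome("toyi", rand_seq(1500, at = 0.6), list(
    # exons 100-160, 220-280, 400-460 -> introns after 60 and 120 nt
    gene_feature("cox1", "CDS",
                 rbind(c(100L, 160L), c(220L, 280L), c(400L, 460L))),
    # minus strand: exons 600-660, 800-860; spliced CDS starts at 860
    # going left, so the intron sits after 60 nt of coding sequence
    gene_feature("nad5", "CDS", rbind(c(600L, 660L), c(800L, 860L)),
                 strand = "-")))
}

test_that("intron extraction gets coordinates, lengths and strand right", {
  g <- toy_intron_genome()
  tab <- extract_introns(g)
  expect_identical(nrow(tab), 3L)
  cx <- tab[tab$host == "cox1", ]
  expect_identical(cx$coordinate, c(60L, 120L))
  expect_identical(cx$length, c(60L, 120L))
  expect_identical(cx$sequence[1L],
                   substr(g$sequence, 161L, 220L))
  nd <- tab[tab$host == "nad5", ]
  expect_identical(nd$coordinate, 60L)
  expect_identical(nd$sequence,
                   revcomp(substr(g$sequence, 661L, 800L)))
})

test_that("explicit intron features give the same inventory", {
  g <- toy_intron_genome()
  # re-encode cox1 as one span plus explicit intron features
  g2 <- annotated_mitogenome("toyi2", g$sequence, list(
    gene_feature("cox1", "CDS", c(100L, 460L)),
    gene_feature("cox1.i1", "intron", c(160L, 220L)),
    gene_feature("cox1.i2", "intron", c(280L, 400L))))
  t1 <- extract_introns(g)
  t2 <- extract_introns(g2)
  cx1 <- t1[t1$host == "cox1", c("coordinate", "length", "sequence")]
  rownames(cx1) <- NULL
  cx2 <- t2[, c("coordinate", "length", "sequence")]
  rownames(cx2) <- NULL
  expect_identical(cx1, cx2)
})

test_that("intron extraction is invariant under genome rotation", {
  g <- toy_intron_genome()
  ref <- extract_introns(g)[, c("host", "coordinate", "length", "sequence")]
  for (off in c(130L, 450L, 820L, 1499L)) {
    r <- rotate_genome(g, off)
    got <- extract_introns(r)[, c("host", "coordinate", "length",
                                  "sequence")]
    rownames(ref) <- rownames(got) <- NULL
    expect_identical(got, ref, label = paste("offset", off))
  }
})

test_that("position classes split by host and coordinate", {
  g <- toy_intron_genome()
  ia <- extract_introns(g)
  ib <- ia[c(1L, 3L), ]          # second genome misses one cox1 intron
  ib$genome <- "other"
  p <- assign_pcls(ia, ib)
  expect_s3_class(p, "pcl_table")
  expect_identical(nrow(p), 3L)
  expect_identical(sum(p$shared), 2L)
  expect_true(all(p$identity[p$shared] == 1))
  expect_false(any(p$low_similarity, na.rm = TRUE))
  # every intron is a member of exactly one class
  expect_identical(sum(p$in_a), nrow(ia))
  expect_identical(sum(p$in_b), nrow(ib))
  expect_true(all(grepl("^cox1-p", p$pcl[p$host == "cox1"])))
  expect_identical(p$pcl[p$host == "nad5"], "nad5-1")
})

test_that("exemplar labels name cox1 classes", {
  g <- toy_intron_genome()
  ia <- extract_introns(g)
  ex <- data.frame(gene = "cox1", coordinate = 60L, label = "cox1-B")
  p <- assign_pcls(ia, ia, exemplars = ex)
  expect_identical(p$pcl[p$host == "cox1" & p$coordinate == 60L], "cox1-B")
  expect_identical(p$pcl[p$host == "cox1" & p$coordinate == 120L],
                   "cox1-p120")
})

test_that("low-similarity same-position pairs are flagged", {
  g <- toy_intron_genome()
  ia <- extract_introns(g)
  ib <- ia
  ib$genome <- "other"
  set.seed(6)
  ib$sequence[1L] <- rand_seq(ib$length[1L], at = 0.5)
  p <- assign_pcls(ia, ib, identity_threshold = 0.9)
  flagged <- p[p$host == "cox1" & p$coordinate == 60L, ]
  expect_true(flagged$shared)
  expect_true(flagged$low_similarity)
})

test_that("gain/loss table reproduces the planted fractions", {
  pr <- shared_pair()
  p <- assign_pcls(extract_introns(pr$a), extract_introns(pr$b))
  gl <- gain_loss_table(p)
  pct <- function(h) gl$pct_nonhomologous[gl$host == h]
  expect_equal(pct("cob"), 100 * 1 / 7, tolerance = 1e-10)
  expect_equal(pct("cox3"), 50)
  expect_equal(pct("nad5"), 60)
  expect_equal(pct("rnl"), 100)
  expect_equal(pct("nad1"), 100)
  expect_identical(sum(gl$total_introns), 40L)
  expect_identical(sum(gl$shared_pcls), 9L)
  # shared introns stay above the homology threshold
  expect_false(any(p$low_similarity, na.rm = TRUE))
})
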