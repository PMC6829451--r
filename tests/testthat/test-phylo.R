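test_that("supermatrix concatenation tracks partitions and padding", {
  al <- list(g1 = c(A = "AAAA", B = "AAAT", C = "AATT"),
             g2 = c(A = "GGG", B = "GGC"))
  sm <- concatenate_alignments(al)
  expect_identical(sm$width, 7L)
  expect_identical(sum(sm$partitions$end - sm$partitions$start + 1L),
                   sm$width)
  expect_identical(sm$rows[["C"]], "AATT---")
  expect_identical(sm$padded_taxa, "C")
  expect_error(concatenate_alignments(list(g = c(A = "AA", B = "AAA"))),
               "differ in length")
  expect_error(concatenate_alignments(list(g = c(A = "AA", A = "AA"))),
               "duplicate taxon")
})

test_that("k2p_matrix is symmetric with zero diagonal", {
  rows <- c(x = "ACGTACGTAA", y = "ACGTACGTAG", z = "ACGAACGTAA")
  m <- k2p_matrix(rows)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_equal(m["x", "y"], k2p_distance(rows["x"], rows["y"]))
})

test_that("NJ recovers 3-taxon branch lengths in closed form", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2L])], tr$tip.label)
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(bl["c"]), (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ recovers additive matrices exactly", {
  set.seed(31)
  for (i in 1:10) {
    tr <- random_additive_tree(sample(4:12, 1))
    m <- tree_distance_matrix(tr)
    est <- nj_tree(m)
    expect_identical(robinson_foulds(est, tr), 0L)
    dd <- ape::cophenetic.phylo(est)
    dd <- dd[rownames(m), colnames(m)]
    expect_equal(dd, m, tolerance = 1e-8)
  }
})

test_that("NJ validates its input", {
  m2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  expect_error(nj_tree(m2), "at least 3")
  m3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m3[1, 2] <- m3[2, 1] <- NA
  expect_error(nj_tree(m3), "NA")
})

test_that("robinson_foulds distinguishes the 4-taxon topologies", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_identical(robinson_foulds(t1, t1), 0L)
  expect_identical(robinson_foulds(t1, t2), 2L)
  # cross-check against the phangorn implementation
  expect_identical(robinson_foulds(t1, t2),
                   as.integer(phangorn::RF.dist(t1, t2)))
  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(robinson_foulds(t1, t3), "leaf sets")
})

test_that("bootstrap support is deterministic and saturates on 3 taxa", {
  al <- list(g = c(a = strrep("ACGT", 30), b = strrep("ACGT", 30),
                   c = strrep("ACGA", 30)))
  sm <- concatenate_alignments(al)
  b1 <- bootstrap_support(sm, replicates = 5, seed = 2)
  b2 <- bootstrap_support(sm, replicates = 5, seed = 2)
  expect_identical(b1$support, b2$support)
  # 3 taxa: only one unrooted topology, no non-trivial splits
  expect_length(b1$support, 0L)
})

test_that("sister taxa on a simulated supermatrix get full support", {
  tree <- "((A:0.02,B:0.02):0.08,(C:0.02,D:0.02):0.08);"
  rows <- simulate_alignment(tree, length = 4000, kappa = 2, seed = 3)
  sm <- concatenate_alignments(list(sim = rows))
  bs <- bootstrap_support(sm, replicates = 50, seed = 4)
  # single non-trivial split; canonical side omits the first taxon A
  expect_identical(names(bs$support), "C|D")
  expect_gte(unname(bs$support), 97)
})

test_that("NEXUS and Newick exports are well-formed and parseable", {
  al <- list(g1 = c("tax one" = "ACGTT", tax2 = "ACGTA"),
             g2 = c("tax one" = "GG", tax2 = "GC"))
  sm <- concatenate_alignments(al)
  nex <- withr::local_tempfile(fileext = ".nex")
  write_nexus(sm, nex)
  lines <- readLines(nex)
  expect_identical(lines[1L], "#NEXUS")
  expect_true(any(grepl("CHARSET g1 = 1-5;", lines)))
  expect_true(any(grepl("CHARSET g2 = 6-7;", lines)))
  expect_true(any(grepl("'tax one'", lines)))
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  tr$tip.label[1L] <- "tax one"
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, nwk)
  back <- ape::read.tree(nwk)
  # ape keeps the literal quotes on quoted labels
  expect_true("tax one" %in% gsub("^'|'$", "", back$tip.label))
})
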