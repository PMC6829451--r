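test_that("the generator is bit-reproducible under a fixed seed", {
  p1 <- generate_pair(generator_spec(seed = 123))
  p2 <- generate_pair(generator_spec(seed = 123))
  expect_identical(p1$a$sequence, p2$a$sequence)
  expect_identical(p1$b$sequence, p2$b$sequence)
  expect_identical(p1$truth, p2$truth)
  p3 <- generate_pair(generator_spec(seed = 124))
  expect_false(identical(p1$a$sequence, p3$a$sequence))
})

test_that("truth tables match the study-condition targets", {
  pr <- shared_pair()
  expect_lt(abs(pr$truth$sizes[["a"]] - 66700), 1500)
  expect_lt(abs(pr$truth$sizes[["b"]] - 77100), 1500)
  expect_identical(unname(pr$truth$n_introns), c(16L, 24L))
  expect_identical(pr$truth$n_shared_pcls, 9L)
  expect_identical(nrow(pr$truth$trna_mutations), 13L)
  expect_identical(
    as.integer(table(pr$truth$trna_mutations$domain)[
      c("acceptor_stem", "d_arm", "t_arm", "anticodon_arm")]),
    c(6L, 4L, 2L, 1L))
})

test_that("zero divergence with identical intron plans gives distance 0", {
  plan <- default_plan <- mitocompare:::default_intron_plan()
  plan$status[] <- "shared"
  plan$length_a[] <- plan$length_b[] <- 500L
  plan$identity[] <- 1
  div <- mitocompare:::default_divergence()
  div[] <- 0
  spec <- generator_spec(seed = 5, divergence = div, intron_plan = plan,
                         trna_plan = data.frame(trna = character(0),
                                                domain = character(0)))
  spec$intergenic_total_b <- spec$intergenic_total_a
  pr <- generate_pair(spec)
  tab <- core_gene_table(pr$a, pr$b)
  # shared intron sequences at identity 1 and zero substitutions:
  # every core gene identical except the planned indel genes
  same <- !tab$gene %in% c("nad3", "nad4", "rps3")
  expect_true(all(tab$k2p[same] == 0))
  expect_true(all(tab$ka[same] == 0))
  tr <- trna_variation_report(pr$a, pr$b)
  expect_identical(tr$n_variable_trnas, 0L)
})

test_that("generated annotations are internally consistent", {
  pr <- shared_pair()
  for (g in list(pr$a, pr$b)) {
    ss <- start_stop_table(g)
    gc4 <- mitocompare:::genetic_code4()
    for (gene in ss$gene) {
      cds <- coding_sequence(g, gene)
      expect_identical(nchar(cds) %% 3L, 0L, label = gene)
      aa <- mitocompare:::translate4(cds)
      # exactly one stop, at the end
      expect_identical(substr(aa, nchar(aa), nchar(aa)), "*", label = gene)
      expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)),
                   label = gene)
    }
  }
})

test_that("simulate_alignment respects branch lengths, kappa and seed", {
  tr0 <- "((A:0,B:0):0,C:0);"
  rows <- simulate_alignment(tr0, length = 500, seed = 1)
  expect_identical(unname(rows["A"]), unname(rows["B"]))
  expect_identical(unname(rows["A"]), unname(rows["C"]))
  r1 <- simulate_alignment("(A:0.1,B:0.1);", 2000, kappa = 2, seed = 9)
  r2 <- simulate_alignment("(A:0.1,B:0.1);", 2000, kappa = 2, seed = 9)
  expect_identical(r1, r2)
})

test_that("two-taxon K2P estimate recovers the simulated branch sum", {
  d <- 0.1
  n <- 10000L
  rows <- simulate_alignment(sprintf("(A:%f,B:%f);", d / 2, d / 2),
                             length = n, kappa = 2, seed = 11)
  est <- k2p_distance(rows[["A"]], rows[["B"]])
  se <- sqrt(d / n)    # conservative binomial-scale standard error
  expect_lt(abs(est - d), 3 * max(se, 0.004))
})

test_that("the K2P process produces the requested ti/tv ratio", {
  rows <- simulate_alignment("(A:0.15,B:0.15);", 30000, kappa = 2,
                             seed = 13)
  a <- chars(rows[["A"]]); b <- chars(rows[["B"]])
  diff <- which(a != b)
  ts <- sum((a[diff] %in% c("A", "G")) == (b[diff] %in% c("A", "G")))
  ratio <- ts / (length(diff) - ts)
  expect_lt(abs(ratio - 2), 0.35)
})
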