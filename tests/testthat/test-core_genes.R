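test_that("K2P distance matches the closed form", {
  # identical sequences
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)
  # 1 transition over 8 sites: P=1/8, Q=0
  d <- k2p_distance("ACGTACGT", "GCGTACGT")
  expect_equal(d, -0.5 * log((1 - 2 / 8) * sqrt(1)))
  set.seed(21)
  for (i in 1:25) {
    n <- sample(200:2000, 1)
    ts <- sample(0:round(n * 0.15), 1); tv <- sample(0:round(n * 0.1), 1)
    ref <- k2p_reference_pair(n, ts, tv)
    expect_equal(k2p_distance(ref$a, ref$b), ref$d, tolerance = 1e-12)
  }
})

test_that("K2P ignores gap/N columns and errors at saturation", {
  # pairwise deletion: gap and N columns dropped from the denominator
  expect_equal(k2p_distance("AC-TN", "ACGTA"), 0)
  expect_error(k2p_distance(strrep("A", 100), strrep("G", 100)),
               "saturat")
  expect_error(k2p_distance("ACG", "ACGT"), "length")
})

test_that("NG86 site counts match the oracle for every sense codon", {
  gc <- mitocompare:::genetic_code4()
  sense <- names(gc)[gc != "*"]
  expect_length(sense, 62L)
  for (cod in sense) {
    s <- mitocompare:::ng86_codon_sites(cod)   # synonymous sites
    o <- oracle_ng86_sites(cod)
    expect_true(s >= 0 && s <= 3, label = cod)
    expect_equal(s, unname(o["S"]), tolerance = 1e-12, label = cod)
  }
})

test_that("NG86 pathway averaging handles known cases", {
  # single synonymous third-position change
  d <- mitocompare:::ng86_codon_diffs("TTA", "TTG")   # both Leu
  expect_equal(unname(d["sd"]), 1)
  expect_equal(unname(d["nd"]), 0)
  # single nonsynonymous change
  d <- mitocompare:::ng86_codon_diffs("TTA", "TCA")   # Leu -> Ser
  expect_equal(unname(d["nd"]), 1)
  # two differences: averaged over both orderings
  d <- mitocompare:::ng86_codon_diffs("TTT", "GTA")   # Phe -> Val
  o <- oracle_ng86_diffs("TTT", "GTA")
  expect_equal(unname(d["sd"]), unname(o["sd"]))
  expect_equal(unname(d["sd"] + d["nd"]), 2)
})

test_that("ka_ks behaves at the boundaries", {
  a <- paste0("ATG", "CTT", "GGA")
  expect_warning(kk0 <- ka_ks(a, a), NA)
  expect_equal(kk0$ka, 0); expect_equal(kk0$ks, 0)
  expect_true(is.na(kk0$ka_ks))
  # purely synonymous change: Ka = 0, Ks > 0, ratio 0
  b <- paste0("ATG", "CTC", "GGA")
  kk <- ka_ks(a, b)
  expect_equal(kk$ka, 0)
  expect_gt(kk$ks, 0)
  expect_equal(kk$ka_ks, 0)
  # stop codons are excluded with a warning
  expect_warning(ka_ks(paste0(a, "TAA"), paste0(b, "TAA")), "skipped")
  expect_error(ka_ks("ATGCC", "ATGCC"), "divisible by 3")
})

test_that("codon-aware alignment produces codon-sized gaps", {
  a <- paste0("ATG", "AAA", "CCC", "GGG", "TTT", "TAA")
  b <- paste0("ATG", "AAA", "GGG", "TTT", "TAA")     # one codon deleted
  al <- mitocompare:::align_codon_aware(a, b)
  expect_identical(nchar(al[1L]), nchar(al[2L]))
  gaps <- gregexpr("-+", al[2L])[[1L]]
  expect_true(all(attr(gaps, "match.length") %% 3L == 0L))
})

test_that("core gene table reflects the planted divergence ordering", {
  pr <- shared_pair()
  tab <- core_gene_table(pr$a, pr$b)
  expect_identical(nrow(tab), 15L)
  expect_identical(tab$gene[which.max(tab$k2p)], "rps3")
  expect_identical(tab$gene[which.min(tab$k2p)], "atp9")
  # atp8 received only synonymous substitutions
  expect_equal(tab$ka[tab$gene == "atp8"], 0)
  expect_equal(tab$ka_ks[tab$gene == "atp8"], 0)
  expect_true(all(tab$k2p > 0))
  # nad3 length difference: 7 codons
  expect_identical(tab$length_a[tab$gene == "nad3"] -
                     tab$length_b[tab$gene == "nad3"], 21L)
})

test_that("alignment identity and global alignment are sane", {
  expect_equal(mitocompare:::alignment_identity("ACGT", "ACGT"), 1)
  id <- mitocompare:::alignment_identity("ACGTACGT", "ACGAACGT")
  expect_equal(id, 7 / 8)
})
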