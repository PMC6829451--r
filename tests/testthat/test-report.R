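test_that("pipeline_config validates inputs and thresholds", {
  expect_error(pipeline_config(), "genomes or paths")
  expect_error(pipeline_config(paths = "/no/such/file.gb"),
               "do not exist")
  pr <- shared_pair()
  expect_error(pipeline_config(genomes = list(pr$a, pr$b),
                               pcl_identity = 0), "pcl_identity")
})

test_that("run_all needs at least two genomes and names failing stages", {
  pr <- shared_pair()
  expect_error(run_all(pipeline_config(genomes = list(pr$a))),
               "at least 2")
  # cox1 copies differing by a transversion at every site saturate the
  # K2P estimate, so the core_genes stage fails with the module name
  # attached; earlier outputs are kept
  set.seed(17)
  s1 <- paste0(rand_seq(320, .6), strrep("AC", 45L), rand_seq(90, .6))
  s2 <- paste0(rand_seq(320, .6), strrep("CA", 45L), rand_seq(190, .6))
  bare <- annotated_mitogenome("bare1", s1, list(
    gene_feature("rns", "rRNA", c(10L, 300L)),
    gene_feature("cox1", "CDS", c(320L, 410L))))
  bare2 <- annotated_mitogenome("bare2", s2, list(
    gene_feature("rns", "rRNA", c(10L, 300L)),
    gene_feature("cox1", "CDS", c(320L, 410L))))
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(genomes = list(bare, bare2), out_dir = dir,
                         modules = c("composition", "regions",
                                     "core_genes"))
  expect_error(run_all(cfg), "module 'core_genes'")
  expect_true(file.exists(file.path(dir, "composition.tsv")))
  expect_true(file.exists(file.path(dir, "region_partition.tsv")))
})

test_that("identical genomes give zero divergence and N/A decomposition", {
  pr <- shared_pair()
  twin <- pr$a
  twin$id <- "synthetic_A2"
  res <- run_all(pipeline_config(
    genomes = list(pr$a, twin),
    modules = c("regions", "core_genes", "trna", "synteny")))
  expect_true(all(res$divergence$k2p == 0))
  expect_true(all(res$divergence$ka == 0))
  expect_true(all(is.na(res$divergence$ka_ks) | res$divergence$ka_ks == 0))
  expect_s3_class(res$decomposition, "expansion_na")
  expect_true(any(grepl("N/A \\(equal sizes\\)", res$summary)))
  expect_identical(res$trna$n_variable_trnas, 0L)
  expect_identical(res$breakpoints[1L, 2L], 0L)
})

test_that("run_all writes deterministic TSVs and a summary", {
  pr <- shared_pair()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  mods <- c("composition", "regions", "introns", "synteny")
  r1 <- run_all(pipeline_config(genomes = list(pr$a, pr$b),
                                out_dir = d1, seed = 3, modules = mods))
  r2 <- run_all(pipeline_config(genomes = list(pr$a, pr$b),
                                out_dir = d2, seed = 3, modules = mods))
  files <- sort(list.files(d1))
  expect_identical(sort(list.files(d2)), files)
  expect_true("summary.md" %in% files)
  expect_true("intron_position_classes.tsv" %in% files)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  expect_identical(r1$summary, r2$summary)
})

test_that("report numbers come straight from module outputs", {
  pr <- shared_pair()
  res <- run_all(pipeline_config(genomes = list(pr$a, pr$b),
                                 modules = c("composition", "introns")))
  expect_identical(res$composition$a$length, nchar(pr$a$sequence))
  line <- grep("introns;", res$summary, value = TRUE)
  expect_match(line, sprintf("%d introns", nrow(res$introns$a)))
})
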