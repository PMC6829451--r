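test_that("planted exact repeats are found with exact coordinates", {
  set.seed(8)
  unit <- rand_seq(50, at = 0.5)
  pal <- rand_seq(40, at = 0.5)
  s <- paste0(rand_seq(300, .5), unit, rand_seq(200, .5), unit,
              rand_seq(150, .5), pal, rand_seq(100, .5), rc(pal),
              rand_seq(80, .5))
  r <- exact_repeats(s, min_length = 30)
  fw <- r[r$orientation == "forward" & r$length >= 50, ]
  expect_gte(nrow(fw), 1L)
  expect_true(any(fw$start1 == 301L & fw$start2 == 551L))
  expect_identical(substr(s, fw$start1[1], fw$end1[1]),
                   substr(s, fw$start2[1], fw$end2[1]))
  pl <- r[r$orientation == "palindromic" & r$length >= 40, ]
  expect_gte(nrow(pl), 1L)
  expect_identical(substr(s, pl$start1[1], pl$end1[1]),
                   rc(substr(s, pl$start2[1], pl$end2[1])))
  expect_true(all(r$identity == 100))
})

test_that("exact repeats agree with the brute-force oracle", {
  set.seed(9)
  for (i in 1:15) {
    n <- sample(80:400, 1)
    s <- rand_seq(n, at = 0.72)      # AT-rich: repeats arise naturally
    ml <- sample(c(8L, 10L, 12L), 1)
    got <- exact_repeats(s, min_length = ml)
    want <- oracle_exact_repeats(s, ml)
    expect_identical(repeat_key(got), repeat_key(want),
                     label = paste("seq", i, "n =", n, "min =", ml))
  }
})

test_that("exact_repeats rejects tiny min_length", {
  expect_error(exact_repeats("ACGTACGTACGT", min_length = 4), ">= 8")
})

test_that("tandem repeats recover unit, copy number and consensus", {
  set.seed(10)
  unit <- rand_seq(17, at = 0.5)
  s <- paste0(rand_seq(200, .5), strrep(unit, 6), rand_seq(200, .5))
  tr <- tandem_repeats(s, min_unit = 11)
  hit <- tr[tr$period == 17, ]
  expect_identical(nrow(hit), 1L)
  expect_gte(hit$copies, 6)
  expect_identical(hit$consensus, unit)
  expect_gte(hit$start, 190L)
  expect_true(attr(tr, "coverage_pct") > 0)
})

test_that("tandem repeats report the primitive period only", {
  set.seed(12)
  unit <- rand_seq(12, at = 0.5)
  s <- paste0(rand_seq(150, .5), strrep(unit, 8), rand_seq(150, .5))
  tr <- tandem_repeats(s, min_unit = 11, max_period = 60)
  periods <- tr$period[tr$start > 140 & tr$start < 170]
  expect_true(12 %in% periods)
  expect_false(24 %in% periods)
})

test_that("tandem repeats tolerate up to 20% unit mismatches", {
  set.seed(13)
  unit <- rand_seq(20, at = 0.5)
  copies <- strrep(unit, 5)
  ch <- chars(copies)
  ch[c(30, 61)] <- setdiff(BASES, ch[c(30, 61)])[1:2]  # 2 mismatches
  s <- paste0(rand_seq(100, .5), paste(ch, collapse = ""),
              rand_seq(100, .5))
  tr <- tandem_repeats(s, min_unit = 11)
  expect_true(any(tr$period == 20 & tr$copies >= 4))
})

test_that("similarity hits exclude the self-diagonal and score E-values", {
  set.seed(14)
  block <- rand_seq(300, at = 0.5)
  s <- paste0(rand_seq(400, .5), block, rand_seq(300, .5), block,
              rand_seq(200, .5))
  h <- similarity_hits(list(g = s), list(g = s))
  expect_true(all(!(h$qstart == h$sstart & h$qend == h$send)))
  big <- h[h$length >= 250, ]
  expect_gte(nrow(big), 2L)           # the pair, in both directions
  expect_true(all(big$identity >= 99))
  expect_true(all(big$evalue < 1e-10))
})

test_that("diverged copies are found down to the identity floor", {
  set.seed(15)
  block <- rand_seq(810, at = 0.5)
  copy <- chars(block)
  idx <- sample(810, 60)              # ~92.6% identity
  for (i in idx) copy[i] <- sample(setdiff(BASES, copy[i]), 1)
  s <- paste0(rand_seq(300, .5), block, rand_seq(400, .5),
              paste(copy, collapse = ""), rand_seq(200, .5))
  h <- similarity_hits(list(g = s), list(g = s))
  big <- h[h$length >= 700, ]
  expect_gte(nrow(big), 1L)
  expect_true(all(big$identity >= 80 & big$identity <= 100))
  expect_true(all(big$evalue < 1e-10))
})

test_that("synthetic truth repeats are recovered", {
  pr <- shared_pair()
  sb <- pr$b$sequence
  tr <- tandem_repeats(sb)
  expect_true(any(tr$period == 12 & tr$copies >= 13))
  expect_true(any(tr$period == 29 & tr$copies >= 4))
  h <- similarity_hits(list(b = sb), list(b = sb))
  dup <- h[h$length >= 700 & h$length <= 950, ]
  expect_gte(nrow(dup), 1L)
  expect_true(all(dup$identity >= 90))
  ta <- tandem_repeats(pr$a$sequence)
  expect_true(any(ta$period == 17 & ta$copies >= 3))
})
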