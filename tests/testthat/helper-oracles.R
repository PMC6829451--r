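# Independent oracles used by unit and acceptance tests. These are
# deliberately written with different algorithms from the package
# implementations, so agreement is meaningful.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n, at = 0.5) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

rc <- function(s) chartr("ACGT", "TGCA",
                         paste(rev(chars(s)), collapse = ""))

# ---- K2P closed-form reference ------------------------------------------
# Builds a pair of sequences with exactly n_ts transitions and n_tv
# transversions over n sites, and returns the textbook closed form.
k2p_reference_pair <- function(n, n_ts, n_tv) {
  x <- sample(BASES, n, replace = TRUE)
  y <- x
  idx <- sample(n, n_ts + n_tv)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "G", T = "A")
  if (n_ts) for (i in idx[seq_len(n_ts)]) y[i] <- ts_map[[x[i]]]
  if (n_tv) for (i in idx[n_ts + seq_len(n_tv)]) y[i] <- tv_map[[x[i]]]
  P <- n_ts / n; Q <- n_tv / n
  list(a = paste(x, collapse = ""), b = paste(y, collapse = ""),
       d = -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)))
}

# ---- NG86 recursive-enumeration oracle ----------------------------------
oracle_code4 <- function() {
  gc <- Biostrings::getGeneticCode("4")
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

oracle_ng86_sites <- function(codon, gc = oracle_code4()) {
  cs <- chars(codon)
  syn <- 0
  for (p in 1:3) for (b in setdiff(BASES, cs[p])) {
    mut <- cs; mut[p] <- b
    m <- paste(mut, collapse = "")
    if (gc[[m]] != "*" && gc[[m]] == gc[[codon]]) syn <- syn + 1 / 3
  }
  c(S = syn, N = 3 - syn)
}

# recursive depth-first path enumeration (implementation uses an
# explicit permutation matrix instead)
oracle_ng86_diffs <- function(c1, c2, gc = oracle_code4()) {
  pos <- which(chars(c1) != chars(c2))
  if (!length(pos)) return(c(sd = 0, nd = 0))
  walk <- function(cur, remaining, skip_stops) {
    if (!length(remaining)) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (k in seq_along(remaining)) {
      p <- remaining[k]
      nxt <- chars(cur); nxt[p] <- chars(c2)[p]
      nxt <- paste(nxt, collapse = "")
      if (skip_stops && gc[[nxt]] == "*" && nxt != c2) next
      step <- if (gc[[cur]] == gc[[nxt]]) c(sd = 1, nd = 0) else
        c(sd = 0, nd = 1)
      for (tail in walk(nxt, remaining[-k], skip_stops))
        out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  paths <- walk(c1, pos, skip_stops = TRUE)
  if (!length(paths)) paths <- walk(c1, pos, skip_stops = FALSE)
  Reduce(`+`, paths) / length(paths)
}

# ---- brute-force maximal exact repeat oracle -----------------------------
# Maximal equal runs between strings s and t found by per-diagonal
# vectorized scanning (implementation uses a k-mer seed hash instead).
oracle_runs <- function(s, t, min_len, exclude_diag = FALSE) {
  x <- chars(s); y <- chars(t)
  n <- length(x); m <- length(y)
  out <- list()
  for (d in (-(n - min_len)):(m - min_len)) {
    i0 <- max(0L, -d); j0 <- i0 + d
    L <- min(n - i0, m - j0)
    if (L < min_len) next
    if (exclude_diag && d == 0L) next
    eq <- x[(i0 + 1L):(i0 + L)] == y[(j0 + 1L):(j0 + L)]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len))
      out[[length(out) + 1L]] <-
        c(i = i0 + starts[k] - 1L, j = j0 + starts[k] - 1L,
          len = r$lengths[k])
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0), len = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# full exact-repeat oracle mirroring the documented output contract
# (1-based inclusive, 4 orientations, i-before-j dedupe) but driven by
# oracle_runs
oracle_exact_repeats <- function(s, min_len) {
  n <- nchar(s)
  res <- list()
  add <- function(i, j, len, ori) {
    res[[length(res) + 1L]] <<- data.frame(
      start1 = i + 1L, end1 = i + len, start2 = j + 1L, end2 = j + len,
      length = len, orientation = ori)
  }
  fw <- oracle_runs(s, s, min_len, exclude_diag = TRUE)
  for (k in seq_len(nrow(fw)))
    if (fw$i[k] < fw$j[k]) add(fw$i[k], fw$j[k], fw$len[k], "forward")
  for (ori in c("reverse", "complemented", "palindromic")) {
    t <- switch(ori, reverse = paste(rev(chars(s)), collapse = ""),
                complemented = chartr("ACGT", "TGCA", s),
                palindromic = rc(s))
    r <- oracle_runs(s, t, min_len)
    for (k in seq_len(nrow(r))) {
      i <- r$i[k]; len <- r$len[k]
      j2 <- if (ori == "complemented") r$j[k] else n - r$j[k] - len
      if (ori == "complemented") { if (i < j2) add(i, j2, len, ori) }
      else if (i < j2) add(i, j2, len, ori)
    }
  }
  if (!length(res))
    return(data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      length = integer(0), orientation = character(0)))
  out <- do.call(rbind, res)
  out[order(out$orientation, out$start1, out$start2), , drop = FALSE]
}

repeat_key <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(sprintf("%s:%d-%d/%d-%d", df$orientation, df$start1, df$end1,
               df$start2, df$end2))
}

# ---- random additive trees for the NJ oracle -----------------------------
random_additive_tree <- function(n_taxa, min_edge = 0.05, max_edge = 1) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   tip.label = paste0("t", seq_len(n_taxa)))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_edge, max_edge)
  tr
}

tree_distance_matrix <- function(tr) {
  m <- ape::cophenetic.phylo(tr)
  m[order(rownames(m)), order(colnames(m))]
}

# ---- random annotated genomes for property tests ------------------------
# k features with random kinds/strands, some multi-exon, laid out left
# to right with random gaps so they are valid by construction
random_genome <- function(id = "rand", n_genes = 8, at = 0.6) {
  pos <- sample(50:300, 1)
  feats <- list()
  seq_len_total <- pos
  pieces <- list(rand_seq(pos, at))
  core_pool <- sample(mitocompare:::CORE_PCGS)
  used_core <- 0L
  for (g in seq_len(n_genes)) {
    kind <- sample(c("CDS", "tRNA", "rRNA", "ORF"), 1,
                   prob = c(.45, .25, .15, .15))
    strand <- sample(c("+", "-"), 1)
    if (kind == "CDS" && used_core < length(core_pool)) {
      used_core <- used_core + 1L
      nm <- core_pool[used_core]
    } else nm <- paste0(tolower(kind), g)
    n_ex <- if (kind %in% c("CDS", "rRNA")) sample(1:3, 1) else 1L
    ivs <- NULL
    for (e in seq_len(n_ex)) {
      ex_len <- sample(60:300, 1)
      ivs <- rbind(ivs, c(seq_len_total, seq_len_total + ex_len))
      pieces[[length(pieces) + 1L]] <- rand_seq(ex_len, at)
      seq_len_total <- seq_len_total + ex_len
      if (e < n_ex) {
        gap <- sample(40:150, 1)
        pieces[[length(pieces) + 1L]] <- rand_seq(gap, at)
        seq_len_total <- seq_len_total + gap
      }
    }
    feats[[length(feats) + 1L]] <-
      gene_feature(nm, kind, ivs, strand,
                   anticodon = if (kind == "tRNA") "CAT" else NA_character_)
    gap <- sample(20:200, 1)
    pieces[[length(pieces) + 1L]] <- rand_seq(gap, at)
    seq_len_total <- seq_len_total + gap
  }
  annotated_mitogenome(id, paste(unlist(pieces), collapse = ""), feats)
}

# small reusable synthetic pair shared across test files (generation
# takes a few seconds; compute once per test run)
shared_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_pair(generator_spec(seed = 7))
    cache
  }
})
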