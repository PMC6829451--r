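# Repeat detection: maximal exact repeated pairs in four orientations,
# tandem repeats with TRF-like mismatch tolerance, and interspersed
# similarity hits via seeded local alignment with Karlin-Altschul
# E-values.
#
# All coordinates in returned tables are 1-based inclusive.

# maximal common runs between s and t found by k-mer seeding: within a
# diagonal, seed starts are consecutive exactly along a common run, so
# merged seed runs are the maximal extensions. Returns 0-based starts.
maximal_common_runs <- function(s, t, min_len, exclude_diag = FALSE) {
  k <- min(min_len, 24L)
  ns <- nchar(s); nt <- nchar(t)
  if (ns < k || nt < k)
    return(data.frame(i = integer(0L), j = integer(0L), len = integer(0L)))
  kmers_s <- substring(s, 1:(ns - k + 1L), k:ns)
  kmers_t <- substring(t, 1:(nt - k + 1L), k:nt)
  pos_t <- split(seq_along(kmers_t) - 1L, kmers_t)
  idx <- which(kmers_s %in% names(pos_t))
  if (!length(idx))
    return(data.frame(i = integer(0L), j = integer(0L), len = integer(0L)))
  pairs_i <- integer(0L); pairs_j <- integer(0L)
  hits <- pos_t[kmers_s[idx]]
  reps <- lengths(hits)
  pairs_i <- rep.int(idx - 1L, reps)
  pairs_j <- unlist(hits, use.names = FALSE)
  if (exclude_diag) {
    keep <- pairs_i != pairs_j
    pairs_i <- pairs_i[keep]; pairs_j <- pairs_j[keep]
  }
  if (!length(pairs_i))
    return(data.frame(i = integer(0L), j = integer(0L), len = integer(0L)))
  diag <- pairs_j - pairs_i
  out_i <- integer(0L); out_j <- integer(0L); out_len <- integer(0L)
  for (d in unique(diag)) {
    st <- sort(pairs_i[diag == d])
    brk <- c(0L, which(diff(st) != 1L), length(st))
    for (b in seq_len(length(brk) - 1L)) {
      a <- st[brk[b] + 1L]; z <- st[brk[b + 1L]]
      len <- z - a + k
      if (len >= min_len) {
        out_i <- c(out_i, a); out_j <- c(out_j, a + d)
        out_len <- c(out_len, len)
      }
    }
  }
  data.frame(i = out_i, j = out_j, len = out_len)
}

#' Maximal exact repeats of a sequence
#'
#' Finds all maximal exact repeated pairs (not extendable left or
#' right) of length at least \code{min_length}, in four orientations:
#' forward (direct copy), reverse (reversed, not complemented),
#' complemented (complemented, not reversed) and palindromic (reverse
#' complemented). Each unordered locus pair is reported once;
#' identical-locus matches are excluded.
#'
#' @param seq DNA string.
#' @param min_length minimum repeat length (>= 8).
#' @param orientations subset of the four orientations to scan.
#' @return data.frame: start1, end1, start2, end2 (1-based inclusive),
#'   length, orientation, identity (always 100 for exact repeats).
#' @export
exact_repeats <- function(seq, min_length = 30L,
                          orientations = c("forward", "reverse",
                                           "complemented", "palindromic")) {
  if (min_length < 8L) stop("min_length must be >= 8")
  seq <- toupper(seq)
  n <- nchar(seq)
  res <- list()
  add <- function(s1, s2, len, ori) {
    res[[length(res) + 1L]] <<-
      data.frame(start1 = s1 + 1L, end1 = s1 + len,
                 start2 = s2 + 1L, end2 = s2 + len,
                 length = len, orientation = ori, identity = 100,
                 stringsAsFactors = FALSE)
  }
  if ("forward" %in% orientations) {
    r <- maximal_common_runs(seq, seq, min_length, exclude_diag = TRUE)
    r <- r[r$i < r$j, , drop = FALSE]      # each unordered pair once
    for (x in seq_len(nrow(r))) add(r$i[x], r$j[x], r$len[x], "forward")
  }
  if ("complemented" %in% orientations) {
    r <- maximal_common_runs(seq, complement_seq(seq), min_length)
    r <- r[r$i < r$j, , drop = FALSE]
    for (x in seq_len(nrow(r))) add(r$i[x], r$j[x], r$len[x], "complemented")
  }
  for (ori in intersect(orientations, c("reverse", "palindromic"))) {
    t <- if (ori == "reverse") reverse_seq(seq) else revcomp(seq)
    r <- maximal_common_runs(seq, t, min_length)
    if (nrow(r)) {
      # map t-coordinates back to seq: start2 = n - j - len
      r$j2 <- n - r$j - r$len
      r <- r[r$i < r$j2, , drop = FALSE]   # unordered pair, non-identical
      for (x in seq_len(nrow(r))) add(r$i[x], r$j2[x], r$len[x], ori)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(start1 = integer(0L), end1 = integer(0L),
               start2 = integer(0L), end2 = integer(0L),
               length = integer(0L), orientation = character(0L),
               identity = numeric(0L))
  out[order(out$orientation, out$start1, out$start2), , drop = FALSE]
}

#' Tandem repeats with mismatch tolerance
#'
#' Scans periods from \code{min_unit} upward for loci where
#' \code{seq[i] == seq[i + p]} holds over a stretch long enough for at
#' least \code{min_copies} copies, allowing up to 20% mismatching
#' positions (isolated mismatch gaps are bridged). A locus detected at
#' period p is suppressed at multiples of p, so repeats are reported at
#' their primitive period.
#'
#' @param seq DNA string.
#' @param min_unit minimum repeat-unit length; the default (11 bp)
#'   reports units longer than 10 bp.
#' @param min_copies minimum (possibly fractional) copy number.
#' @param max_period largest unit length scanned.
#' @param max_mismatch maximum tolerated fraction of mismatching
#'   positions within a locus.
#' @return data.frame: start, end (1-based inclusive), period, copies,
#'   consensus unit; attribute \code{coverage_pct} gives the percent of
#'   the sequence covered by all reported loci.
#' @export
tandem_repeats <- function(seq, min_unit = 11L, min_copies = 2,
                           max_period = 200L, max_mismatch = 0.2) {
  if (min_unit < 1L) stop("min_unit must be >= 1")
  seq <- toupper(seq)
  ch <- seq_chars(seq)
  n <- length(ch)
  max_period <- min(max_period, n %/% 2L)
  found <- list()
  for (p in seq(min_unit, length.out = max(0L, max_period - min_unit + 1L))) {
    m <- ch[seq_len(n - p)] == ch[seq_len(n - p) + p]
    if (!any(m)) next
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    # bridge short mismatch gaps between TRUE runs
    good <- which(r$values)
    if (!length(good)) next
    segs <- list(c(starts[good[1L]], ends[good[1L]],
                   0L))                     # start, end, mismatches
    if (length(good) > 1L) for (gidx in good[-1L]) {
      last <- segs[[length(segs)]]
      gap <- starts[gidx] - last[2L] - 1L
      newlen <- ends[gidx] - last[1L] + 1L
      if (gap <= max(2L, ceiling(0.1 * p)) &&
          (last[3L] + gap) / newlen <= max_mismatch) {
        segs[[length(segs)]] <- c(last[1L], ends[gidx], last[3L] + gap)
      } else segs[[length(segs) + 1L]] <- c(starts[gidx], ends[gidx], 0L)
    }
    for (sg in segs) {
      run <- sg[2L] - sg[1L] + 1L
      if (run < ceiling((min_copies - 1) * p)) next
      start <- sg[1L]; end <- sg[2L] + p    # 1-based inclusive locus
      copies <- (end - start + 1L) / p
      if (copies < min_copies) next
      # suppress harmonics of an already-reported primitive repeat
      dup <- FALSE
      for (f in found) {
        ovl <- min(end, f$end) - max(start, f$start) + 1L
        if (ovl > 0.5 * (end - start + 1L) &&
            (p %% f$period == 0L || p == f$period)) { dup <- TRUE; break }
      }
      if (dup) next
      units <- substring(seq, seq(start, end - p + 1L, by = p),
                         seq(start + p - 1L, end, by = p))
      consensus <- paste(apply(
        do.call(rbind, strsplit(units, "", fixed = TRUE)), 2L,
        function(col) names(which.max(table(col)))), collapse = "")
      found[[length(found) + 1L]] <-
        list(start = start, end = end, period = p,
             copies = round(copies, 1L), consensus = consensus)
    }
  }
  out <- if (length(found))
    do.call(rbind, lapply(found, function(f)
      data.frame(start = f$start, end = f$end, period = f$period,
                 copies = f$copies, consensus = f$consensus,
                 stringsAsFactors = FALSE)))
  else data.frame(start = integer(0L), end = integer(0L),
                  period = integer(0L), copies = numeric(0L),
                  consensus = character(0L))
  cov <- 0
  if (nrow(out)) {
    covered <- rep.int(FALSE, n)
    for (i in seq_len(nrow(out))) covered[out$start[i]:out$end[i]] <- TRUE
    cov <- 100 * sum(covered) / n
  }
  out <- out[order(out$start, out$period), , drop = FALSE]
  attr(out, "coverage_pct") <- cov
  out
}

# Karlin-Altschul parameters for ungapped DNA scoring +1/-2 at uniform
# base composition: lambda solves 0.25*e^l + 0.75*e^(-2l) = 1
KA_LAMBDA <- 1.3338
KA_K <- 0.621

#' Interspersed similarity hits between sequence sets
#'
#' Seeded (11-mer) local alignment: exact seed runs on each diagonal
#' are extended without gaps under +1/-2 scoring with an X-drop, then
#' refined by gapped local alignment (gap penalty -2). Hit significance
#' is a Karlin-Altschul E-value with database length equal to the total
#' subject length. When a query is compared against itself the
#' identical-diagonal self-hit is excluded. Both subject strands are
#' scanned; minus-strand hits are reported with orientation
#' \code{palindromic}.
#'
#' @param query_set,subject_set named character vectors of sequences.
#' @param min_identity minimum percent identity of reported hits.
#' @param max_e E-value threshold (default 1e-10).
#' @param word seed word size.
#' @return data.frame: query, subject, qstart, qend, sstart, send
#'   (1-based inclusive, on the subject plus strand), length, identity,
#'   score, evalue, orientation.
#' @export
similarity_hits <- function(query_set, subject_set, min_identity = 80,
                            max_e = 1e-10, word = 11L) {
  if (!length(query_set) || !length(subject_set) ||
      any(!nchar(query_set)) || any(!nchar(subject_set)))
    stop("query and subject sets must contain non-empty sequences")
  if (is.null(names(query_set)))
    names(query_set) <- paste0("query", seq_along(query_set))
  if (is.null(names(subject_set)))
    names(subject_set) <- paste0("subject", seq_along(subject_set))
  dblen <- sum(nchar(subject_set))
  hits <- list()
  for (qi in seq_along(query_set)) {
    q <- toupper(query_set[[qi]])
    for (si in seq_along(subject_set)) {
      su <- toupper(subject_set[[si]])
      self <- q == su && names(query_set)[qi] == names(subject_set)[si]
      for (ori in c("forward", "palindromic")) {
        subj <- if (ori == "forward") su else revcomp(su)
        runs <- maximal_common_runs(q, subj, word,
                                    exclude_diag = self && ori == "forward")
        if (!nrow(runs)) next
        # keep the longest few run cores per diagonal neighbourhood
        runs <- runs[order(-runs$len), , drop = FALSE]
        runs <- runs[runs$len >= max(word, 16L) | runs$len >= 0.9 *
                       max(runs$len), , drop = FALSE]
        runs <- utils::head(runs, 400L)
        for (x in seq_len(nrow(runs))) {
          h <- refine_hit(q, subj, runs$i[x], runs$j[x], runs$len[x])
          if (is.null(h)) next
          ev <- KA_K * nchar(q) * dblen * exp(-KA_LAMBDA * h$score)
          if (ev >= max_e || h$identity < min_identity) next
          if (ori == "palindromic") {
            ns <- nchar(su)
            tmp <- c(ns - h$send + 1L, ns - h$sstart + 1L)
            h$sstart <- tmp[1L]; h$send <- tmp[2L]
          }
          hits[[length(hits) + 1L]] <-
            data.frame(query = names(query_set)[qi],
                       subject = names(subject_set)[si],
                       qstart = h$qstart, qend = h$qend,
                       sstart = h$sstart, send = h$send,
                       length = h$length, identity = h$identity,
                       score = h$score, evalue = ev, orientation = ori,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query = character(0L), subject = character(0L),
               qstart = integer(0L), qend = integer(0L),
               sstart = integer(0L), send = integer(0L),
               length = integer(0L), identity = numeric(0L),
               score = numeric(0L), evalue = numeric(0L),
               orientation = character(0L))
  if (nrow(out) > 1L) out <- dedupe_hits(out)
  rownames(out) <- NULL
  out
}

# ungapped X-drop extension of a seed run, then gapped local refinement
# around the extended core. Returns 1-based inclusive coordinates on
# (q, subj) or NULL.
refine_hit <- function(q, subj, i, j, len, xdrop = 14) {
  qc <- seq_chars(q); sc <- seq_chars(subj)
  score_of <- function(match) sum(ifelse(match, 1, -2))
  # left extension
  li <- i; lj <- j; best <- 0; cur <- 0; bl <- 0L; step <- 0L
  while (li - step - 1L >= 1L && lj - step - 1L >= 1L) {
    step <- step + 1L
    cur <- cur + if (qc[li - step + 1L] == sc[lj - step + 1L]) 1 else -2
    if (cur > best) { best <- cur; bl <- step }
    if (cur < best - xdrop) break
  }
  # right extension
  ri <- i + len; rj <- j + len; bestr <- 0; cur <- 0; br <- 0L; step <- 0L
  while (ri + step + 1L <= length(qc) && rj + step + 1L <= length(sc)) {
    step <- step + 1L
    cur <- cur + if (qc[ri + step] == sc[rj + step]) 1 else -2
    if (cur > bestr) { bestr <- cur; br <- step }
    if (cur < bestr - xdrop) break
  }
  qs <- i - bl + 1L; qe <- ri + br
  ss <- j - bl + 1L; se <- rj + br
  # gapped refinement on a padded window
  pad <- 30L
  qw <- substr(q, max(1L, qs - pad), min(nchar(q), qe + pad))
  sw <- substr(subj, max(1L, ss - pad), min(nchar(subj), se + pad))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(qw), Biostrings::DNAString(sw), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  sc_al <- Biostrings::score(pa)
  if (sc_al <= 0) return(NULL)
  pq <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  ps <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  ident <- 100 * sum(pq == ps & pq != "-") / length(pq)
  list(qstart = max(1L, qs - pad) + Biostrings::start(
         Biostrings::pattern(pa)) - 1L,
       qend = max(1L, qs - pad) + Biostrings::end(
         Biostrings::pattern(pa)) - 1L,
       sstart = max(1L, ss - pad) + Biostrings::start(
         Biostrings::subject(pa)) - 1L,
       send = max(1L, ss - pad) + Biostrings::end(
         Biostrings::subject(pa)) - 1L,
       length = length(pq), identity = ident, score = sc_al)
}

# greedy removal of hits whose query AND subject loci largely overlap a
# higher-scoring kept hit
dedupe_hits <- function(h) {
  h <- h[order(-h$score), , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (h$query[i] != h$query[j] || h$subject[i] != h$subject[j]) next
      qo <- min(h$qend[i], h$qend[j]) - max(h$qstart[i], h$qstart[j]) + 1L
      so <- min(h$send[i], h$send[j]) - max(h$sstart[i], h$sstart[j]) + 1L
      if (qo > 0.5 * (h$qend[i] - h$qstart[i] + 1L) &&
          so > 0.5 * (h$send[i] - h$sstart[i] + 1L)) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  h[keep, , drop = FALSE]
}
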