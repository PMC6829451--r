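# Per-gene divergence between two genomes: Kimura 2-parameter distance
# and Nei-Gojobori (1986) Ka/Ks under the mold mitochondrial code.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transition <- function(x, y) {
  (x %in% PURINES & y %in% PURINES) |
    (x %in% PYRIMIDINES & y %in% PYRIMIDINES)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)) with P and Q the
#' transition and transversion proportions over compared sites.
#' Columns containing a gap or N in either sequence are excluded
#' (pairwise deletion).
#'
#' @param seq_a,seq_b aligned DNA strings of equal length (gaps as
#'   \code{-}).
#' @return distance in substitutions per site.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- seq_chars(toupper(seq_a)); b <- seq_chars(toupper(seq_b))
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable (ungapped, non-N) sites")
  diff <- a != b
  P <- sum(diff & is_transition(a, b)) / n
  Q <- sum(diff & !is_transition(a, b)) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined: sequences saturated (P=",
         signif(P, 3), ", Q=", signif(Q, 3), ")")
  -0.5 * log(w1 * sqrt(w2))
}

# ---- NG86 ----------------------------------------------------------------

# per-codon synonymous site count under code 4: at each position, the
# fraction of the three possible changes that preserve the amino acid;
# changes to stop codons count as nonsynonymous
ng86_codon_sites <- function(codon, gc = genetic_code4()) {
  aa <- gc[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (nb in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nb
      if (gc[[mut]] == aa && gc[[mut]] != "*") s <- s + 1 / 3
    }
  }
  s
}

# all codon-site counts, memoised at first use
ng86_site_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- genetic_code4()
      sense <- names(gc)[gc != "*"]
      tab <<- stats::setNames(vapply(sense, ng86_codon_sites, numeric(1L),
                                     gc = gc), sense)
    }
    tab
  }
})

# average synonymous/nonsynonymous differences between two codons over
# all minimal mutational pathways; pathways through stop codons are
# skipped (all-stop-blocked pairs fall back to unrestricted pathways)
ng86_codon_diffs <- function(c1, c2, gc = genetic_code4()) {
  pos <- which(seq_chars(c1) != seq_chars(c2))
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- permute_all(pos)
  count_path <- function(order) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*" && nxt != c2) return(NULL)   # blocked
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), apply(paths, 1L, count_path,
                                       simplify = FALSE))
  if (!length(res)) {               # every pathway passes a stop codon
    res <- apply(paths, 1L, function(order) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == gc[[cur]] && gc[[nxt]] != "*") sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }, simplify = FALSE)
  }
  Reduce(`+`, res) / length(res)
}

permute_all <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- permute_all(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Nei-Gojobori (1986) Ka and Ks under genetic code 4
#'
#' Synonymous and nonsynonymous site counts are averaged over the two
#' sequences; differences are averaged with equal weight over minimal
#' mutational pathways, skipping pathways through stop-codon
#' intermediates; proportions are Jukes-Cantor corrected
#' (d = -3/4 * ln(1 - 4p/3)).
#'
#' @param cds_a,cds_b in-frame coding sequences of equal length
#'   divisible by 3 (codon-aligned; gap codons \code{---} and codons
#'   containing N are skipped with a warning).
#' @return list: ka, ks, ka_ks (NA when ks is 0), and the underlying
#'   site/difference counts.
#' @export
ka_ks <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("coding sequences must be aligned to equal length")
  if (nchar(cds_a) %% 3L != 0L)
    stop("aligned length must be divisible by 3")
  ca <- codon_split(cds_a); cb <- codon_split(cds_b)
  usable <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  gc <- genetic_code4()
  usable <- usable & ca %in% names(gc) & cb %in% names(gc)
  usable[usable] <- gc[ca[usable]] != "*" & gc[cb[usable]] != "*"
  if (sum(!usable))
    warning(sum(!usable), " codon(s) skipped (gap, N or stop)")
  ca <- ca[usable]; cb <- cb[usable]
  if (!length(ca)) stop("no comparable codons")
  st <- ng86_site_table()
  S <- sum((st[ca] + st[cb]) / 2)
  N <- 3 * length(ca) - S
  diffs <- mapply(function(x, y) ng86_codon_diffs(x, y, gc), ca, cb)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  jc <- function(p, what) {
    if (p >= 0.75)
      stop(what, " proportion ", signif(p, 3),
           " >= 0.75: Jukes-Cantor correction undefined (saturation)")
    if (p == 0) return(0)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- if (S > 0) jc(Sd / S, "synonymous") else NA_real_
  ka <- if (N > 0) jc(Nd / N, "nonsynonymous") else NA_real_
  list(ka = ka, ks = ks,
       ka_ks = if (!is.na(ks) && ks > 0 && !is.na(ka)) ka / ks else NA_real_,
       S = S, N = N, Sd = Sd, Nd = Nd, codons = length(ca))
}

# ---- alignment helpers ---------------------------------------------------

# global nucleotide alignment, match +1 / mismatch -1 / gap -2 (linear)
align_global <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  c(as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)))
}

# fraction identical positions of a global alignment of two sequences
alignment_identity <- function(a, b) {
  if (a == b) return(1)
  al <- align_global(a, b)
  x <- seq_chars(al[1L]); y <- seq_chars(al[2L])
  sum(x == y) / length(x)
}

# codon-aware alignment: align translated proteins, then expand the
# protein gaps to codon gaps in the nucleotide sequences
align_codon_aware <- function(cds_a, cds_b) {
  cds_a <- substr(cds_a, 1L, 3L * (nchar(cds_a) %/% 3L))
  cds_b <- substr(cds_b, 1L, 3L * (nchar(cds_b) %/% 3L))
  # drop terminal stop codons before translating
  trim_stop <- function(s) {
    cod <- codon_split(s)
    if (length(cod) && !grepl("N", cod[length(cod)]) &&
        genetic_code4()[[cod[length(cod)]]] == "*")
      s <- substr(s, 1L, nchar(s) - 3L)
    s
  }
  cds_a <- trim_stop(cds_a); cds_b <- trim_stop(cds_b)
  if (nchar(cds_a) == nchar(cds_b)) return(c(cds_a, cds_b))
  aa_a <- translate4(cds_a); aa_b <- translate4(cds_b)
  alph <- unique(c(seq_chars(aa_a), seq_chars(aa_b), "X"))
  sm <- matrix(-1, length(alph), length(alph),
               dimnames = list(alph, alph))
  diag(sm) <- 2
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(aa_a), Biostrings::BString(aa_b), type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 3)
  pa_a <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  pa_b <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  expand <- function(aa_aln, cds) {
    cod <- codon_split(cds)
    out <- character(length(aa_aln)); j <- 0L
    for (i in seq_along(aa_aln)) {
      if (aa_aln[i] == "-") out[i] <- "---"
      else { j <- j + 1L; out[i] <- cod[j] }
    }
    paste(out, collapse = "")
  }
  c(expand(pa_a, cds_a), expand(pa_b, cds_b))
}

#' Per-core-gene divergence table between two genomes
#'
#' For every core protein-coding gene shared by the two genomes:
#' length, GC content and strand skews per genome, K2P distance (after
#' global nucleotide alignment when lengths differ), and NG86 Ka, Ks
#' and Ka/Ks (after codon-aware alignment).
#'
#' @param a,b \code{annotated_mitogenome} objects.
#' @param genes gene set to compare (default: core set shared by both).
#' @return data.frame of class \code{divergence_table}.
#' @export
core_gene_table <- function(a, b, genes = NULL) {
  present <- function(g, genome) !is.null(find_feature(genome, g, "CDS"))
  if (is.null(genes)) genes <- CORE_PCGS
  genes <- genes[vapply(genes, present, logical(1L), genome = a) &
                 vapply(genes, present, logical(1L), genome = b)]
  if (!length(genes)) stop("no shared core genes between ", a$id, " and ",
                           b$id)
  rows <- lapply(genes, function(g) {
    ca <- coding_sequence(a, g); cb <- coding_sequence(b, g)
    sa <- composition_stats(ca); sb <- composition_stats(cb)
    nuc <- if (nchar(ca) == nchar(cb)) c(ca, cb) else align_global(ca, cb)
    k2p <- k2p_distance(nuc[1L], nuc[2L])
    cod <- align_codon_aware(ca, cb)
    kk <- suppressWarnings(ka_ks(cod[1L], cod[2L]))
    data.frame(gene = g, length_a = nchar(ca), length_b = nchar(cb),
               gc_a = sa$gc_content, gc_b = sb$gc_content,
               at_skew_a = sa$at_skew, at_skew_b = sb$at_skew,
               gc_skew_a = sa$gc_skew, gc_skew_b = sb$gc_skew,
               k2p = k2p, ka = kk$ka, ks = kk$ks, ka_ks = kk$ka_ks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("divergence_table", class(out))
  attr(out, "genomes") <- c(a$id, b$id)
  out
}
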