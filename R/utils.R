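# Low-level sequence and interval helpers shared across modules.
# Sequences are plain uppercase character strings over {A,C,G,T,N};
# intervals are 0-based half-open [start, end) on the forward strand.

#' Reverse complement of a DNA string
#'
#' @param seq character scalar over \code{A,C,G,T,N} (case-insensitive).
#' @return reverse-complemented uppercase string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

complement_seq <- function(seq) chartr("ACGTNacgtn", "TGCANTGCAN", seq)

reverse_seq <- function(seq) {
  paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# substring on 0-based half-open coordinates
sub0 <- function(seq, start, end) substring(seq, start + 1L, end)

# total length of an interval matrix (columns start, end)
interval_len <- function(ivs) {
  if (is.null(ivs) || nrow(ivs) == 0L) return(0L)
  sum(ivs[, 2L] - ivs[, 1L])
}

# normalise an interval spec (vector, matrix or list of pairs) to an
# integer matrix with columns start, end
as_intervals <- function(x) {
  if (is.matrix(x)) {
    m <- matrix(as.integer(x), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  } else if (is.list(x)) {
    m <- do.call(rbind, lapply(x, function(p) as.integer(p[1:2])))
    colnames(m) <- c("start", "end")
  } else {
    m <- matrix(as.integer(x), ncol = 2L, byrow = TRUE,
                dimnames = list(NULL, c("start", "end")))
  }
  m
}

# extract (concatenated, forward-strand order) sequence of an interval set
extract_intervals <- function(seq, ivs) {
  paste(vapply(seq_len(nrow(ivs)),
               function(i) sub0(seq, ivs[i, 1L], ivs[i, 2L]), character(1L)),
        collapse = "")
}

# split a string into codons, dropping a trailing partial codon
codon_split <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0L))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# sample an AT-rich DNA string (iid bases); used by the generator
random_dna <- function(n, at = 0.785) {
  p <- c(A = at / 2, T = at / 2, C = (1 - at) / 2, G = (1 - at) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
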