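# Domain types: gene features and annotated mitogenomes.
#
# Internal coordinate convention: 0-based half-open intervals on the
# forward strand. Report output converts to 1-based inclusive (GenBank
# style). A feature spanning the origin of a circular genome is stored
# as two intervals with origin_span = TRUE; length arithmetic treats it
# as contiguous.

CORE_PCGS <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
               "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
               "rps3")

FEATURE_KINDS <- c("CDS", "intron", "tRNA", "rRNA", "ORF")

#' Construct a gene feature
#'
#' A typed annotation on a mitogenome: a (possibly multi-exon) CDS, an
#' intron, a tRNA, an rRNA or a free-standing ORF. Multi-interval CDS
#' and rRNA features encode introns implicitly as the gaps between
#' consecutive exon intervals.
#'
#' @param name gene symbol, e.g. \code{"cox1"}, \code{"rnl"},
#'   \code{"trnM"}, \code{"orf632"}.
#' @param kind one of \code{"CDS"}, \code{"intron"}, \code{"tRNA"},
#'   \code{"rRNA"}, \code{"ORF"}.
#' @param intervals interval set: matrix with columns start, end
#'   (0-based half-open, forward strand), a list of pairs, or a flat
#'   vector. Must be sorted and non-overlapping.
#' @param strand \code{"+"} or \code{"-"}.
#' @param product free-text product description.
#' @param anticodon 3-mer anticodon for tRNAs, else \code{NA}.
#' @param origin_span TRUE if the two intervals wrap the circular origin.
#' @return an object of class \code{gene_feature}.
#' @export
gene_feature <- function(name, kind, intervals, strand = "+",
                         product = NA_character_, anticodon = NA_character_,
                         origin_span = FALSE) {
  stopifnot(kind %in% FEATURE_KINDS, strand %in% c("+", "-"))
  ivs <- as_intervals(intervals)
  if (nrow(ivs) == 0L) stop("feature '", name, "': empty interval set")
  if (any(ivs[, 1L] >= ivs[, 2L]))
    stop("feature '", name, "': interval with start >= end")
  if (!origin_span && nrow(ivs) > 1L) {
    if (is.unsorted(ivs[, 1L]))
      stop("feature '", name, "': intervals not sorted")
    if (any(ivs[-nrow(ivs), 2L] > ivs[-1L, 1L]))
      stop("feature '", name, "': overlapping intervals")
  }
  structure(list(name = name, kind = kind, intervals = ivs,
                 strand = strand, product = product,
                 anticodon = anticodon, origin_span = isTRUE(origin_span)),
            class = "gene_feature")
}

#' @export
print.gene_feature <- function(x, ...) {
  loc <- paste(sprintf("%d..%d", x$intervals[, 1L] + 1L, x$intervals[, 2L]),
               collapse = ",")
  cat(sprintf("<%s %s [%s] %s%s>\n", x$kind, x$name, loc, x$strand,
              if (x$origin_span) " (origin-spanning)" else ""))
  invisible(x)
}

feature_length <- function(f) interval_len(f$intervals)

# full genomic extent of a feature (first start to last end); for an
# origin-spanning feature this is reported as the wrapped pair
feature_span <- function(f) {
  c(start = min(f$intervals[, 1L]), end = max(f$intervals[, 2L]))
}

#' Construct an annotated mitogenome
#'
#' @param id accession or label.
#' @param sequence DNA string over \code{A,C,G,T,N}; uppercased.
#' @param features list of \code{\link{gene_feature}} objects.
#' @param circular is the molecule circular (default TRUE).
#' @return an object of class \code{annotated_mitogenome}.
#' @export
annotated_mitogenome <- function(id, sequence, features = list(),
                                 circular = TRUE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  n <- nchar(sequence)
  for (f in features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature")
    if (any(f$intervals[, 2L] > n))
      stop("feature '", f$name, "' extends beyond sequence length ", n)
  }
  cds_core <- vapply(features, function(f)
    if (f$kind == "CDS" && f$name %in% CORE_PCGS) f$name else NA_character_,
    character(1L))
  dup <- unique(cds_core[!is.na(cds_core)][duplicated(cds_core[!is.na(cds_core)])])
  if (length(dup))
    stop("core gene annotated more than once as CDS: ",
         paste(dup, collapse = ", "))
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 features = features),
            class = "annotated_mitogenome")
}

#' @export
print.annotated_mitogenome <- function(x, ...) {
  kinds <- table(vapply(x$features, `[[`, character(1L), "kind"))
  cat(sprintf("annotated_mitogenome '%s': %d bp, %s\n", x$id,
              nchar(x$sequence),
              if (x$circular) "circular" else "linear"))
  if (length(kinds))
    cat("  features:", paste(sprintf("%s=%d", names(kinds), kinds),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Summarise an annotated mitogenome
#'
#' @param object an \code{annotated_mitogenome}.
#' @param ... unused.
#' @return a list with size, composition and feature counts, invisibly
#'   printed.
#' @export
summary.annotated_mitogenome <- function(object, ...) {
  comp <- composition_stats(object$sequence)
  kinds <- vapply(object$features, `[[`, character(1L), "kind")
  out <- list(id = object$id, length = comp$length,
              gc_content = comp$gc_content, at_skew = comp$at_skew,
              gc_skew = comp$gc_skew,
              n_cds = sum(kinds == "CDS"), n_trna = sum(kinds == "tRNA"),
              n_rrna = sum(kinds == "rRNA"), n_orf = sum(kinds == "ORF"),
              n_introns = nrow(extract_introns(object)))
  cat(sprintf(paste0("%s: %d bp | GC %.2f%% | AT skew %.2f | GC skew %.2f | ",
                     "%d CDS, %d tRNA, %d rRNA, %d ORF, %d introns\n"),
              out$id, out$length, out$gc_content, out$at_skew, out$gc_skew,
              out$n_cds, out$n_trna, out$n_rrna, out$n_orf, out$n_introns))
  invisible(out)
}

# lookup a feature by name (first match), optionally restricted by kind
find_feature <- function(genome, name, kind = NULL) {
  for (f in genome$features) {
    if (f$name == name && (is.null(kind) || f$kind %in% kind)) return(f)
  }
  NULL
}

features_of_kind <- function(genome, kinds) {
  Filter(function(f) f$kind %in% kinds, genome$features)
}

#' Extract the spliced coding sequence of a gene
#'
#' Exon intervals are concatenated in transcription order (and
#' reverse-complemented for minus-strand genes); intron gaps are
#' excluded.
#'
#' @param genome an \code{annotated_mitogenome}.
#' @param gene gene symbol; must be annotated as CDS (or ORF/rRNA with
#'   \code{kind}).
#' @param kind feature kinds to search (default CDS, then ORF).
#' @return DNA string of the spliced gene on its coding strand.
#' @export
coding_sequence <- function(genome, gene, kind = c("CDS", "ORF")) {
  f <- find_feature(genome, gene, kind = kind)
  if (is.null(f)) stop("gene '", gene, "' not annotated in ", genome$id)
  feature_sequence(genome, f)
}

# spliced, strand-oriented sequence of any feature
feature_sequence <- function(genome, f) {
  s <- extract_intervals(genome$sequence, f$intervals)
  if (f$strand == "-") revcomp(s) else s
}

# Intervals of a feature in "linearized" form: coordinates increase
# monotonically, with intervals past the origin seam shifted by +n and
# the seam-split exon re-joined into one run. Origin-spanning features
# store their intervals in genomic-linear order starting before the
# seam, so the seam is detectable as the first drop in start position.
linearize_intervals <- function(f, n) {
  ivs <- f$intervals
  if (!f$origin_span) return(ivs)
  shift <- 0L
  out <- list()
  for (i in seq_len(nrow(ivs))) {
    if (i > 1L && ivs[i, 1L] + shift < ivs[i - 1L, 1L] + prev_shift)
      shift <- n
    prev_shift <- shift
    out[[i]] <- ivs[i, ] + shift
  }
  m <- as_intervals(out)
  # re-join the exon split at the seam ([s, n) + [n, n + e))
  keep <- list(m[1L, ])
  for (i in seq_len(nrow(m))[-1L]) {
    last <- keep[[length(keep)]]
    if (m[i, 1L] == last[2L] && last[2L] == n) {
      keep[[length(keep)]] <- c(last[1L], m[i, 2L])
    } else keep[[length(keep) + 1L]] <- m[i, ]
  }
  as_intervals(keep)
}

# Inverse of linearize_intervals for a genome of length n: intervals may
# exceed n; the one crossing n is split at the seam, later ones shifted
# back. Returns list(intervals, origin_span).
delinearize_intervals <- function(lin, n) {
  out <- list(); wraps <- any(lin[, 2L] > n)
  for (i in seq_len(nrow(lin))) {
    s <- lin[i, 1L]; e <- lin[i, 2L]
    if (e <= n) {
      out[[length(out) + 1L]] <- c(s, e)
    } else if (s < n) {
      out[[length(out) + 1L]] <- c(s, n)
      out[[length(out) + 1L]] <- c(0L, e - n)
    } else {
      out[[length(out) + 1L]] <- c(s - n, e - n)
    }
  }
  list(intervals = as_intervals(out), origin_span = wraps)
}

#' Rotate a circular genome so a new origin is position 1
#'
#' Shifts the sequence left by \code{offset} bases and re-maps all
#' feature coordinates; features that come to span the new origin are
#' split into two intervals and flagged, and formerly origin-spanning
#' features that become contiguous are re-joined.
#'
#' @param genome circular \code{annotated_mitogenome}.
#' @param offset 0-based position that becomes the new first base.
#' @return rotated \code{annotated_mitogenome}.
#' @export
rotate_genome <- function(genome, offset) {
  stopifnot(genome$circular)
  n <- nchar(genome$sequence)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0L) return(genome)
  newseq <- paste0(sub0(genome$sequence, offset, n),
                   sub0(genome$sequence, 0L, offset))
  feats <- lapply(genome$features, function(f) {
    lin <- linearize_intervals(f, n)
    # shift into [0, n) on the first start, preserving monotonicity
    first <- ((lin[1L, 1L] - offset) %% n + n) %% n
    lin2 <- lin - lin[1L, 1L] + first
    d <- delinearize_intervals(lin2, n)
    gene_feature(f$name, f$kind, d$intervals, f$strand, f$product,
                 f$anticodon, origin_span = d$origin_span)
  })
  annotated_mitogenome(genome$id, newseq, feats, circular = TRUE)
}
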