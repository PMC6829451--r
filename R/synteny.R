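# Gene-order collinearity: signed circular gene orders and breakpoint
# distance.

#' Signed gene order of a genome
#'
#' Genes are sorted by start coordinate and signed by strand, then
#' normalized for circularity: the order is rotated (and, if the anchor
#' gene lies on the minus strand, reflected) so that the anchor comes
#' first with positive sign.
#'
#' @param genome an \code{annotated_mitogenome}.
#' @param shared gene symbols to include (default: core protein-coding
#'   genes plus rnl and rns present in the genome).
#' @param anchor anchor gene for rotation normalization.
#' @return object of class \code{gene_order}: character vector of
#'   signed gene symbols (e.g. \code{"-nad4"}).
#' @export
gene_order <- function(genome, shared = NULL, anchor = "cox1") {
  feats <- features_of_kind(genome, c("CDS", "rRNA"))
  nm <- vapply(feats, `[[`, character(1L), "name")
  if (is.null(shared)) shared <- intersect(c(CORE_PCGS, "rnl", "rns"), nm)
  if (any(duplicated(nm[nm %in% shared])))
    stop("duplicated shared gene in ", genome$id, ": ",
         paste(unique(nm[nm %in% shared][duplicated(nm[nm %in% shared])]),
               collapse = ", "))
  missing <- setdiff(shared, nm)
  if (length(missing))
    stop("shared genes absent from ", genome$id, ": ",
         paste(missing, collapse = ", "))
  keep <- which(nm %in% shared)
  starts <- vapply(feats[keep], function(f) min(f$intervals[, 1L]),
                   integer(1L))
  o <- keep[order(starts)]
  signs <- vapply(feats[o], function(f) if (f$strand == "+") "" else "-",
                  character(1L))
  order_vec <- paste0(signs, nm[o])
  normalize_gene_order(order_vec, anchor)
}

normalize_gene_order <- function(order_vec, anchor = "cox1") {
  genes <- sub("^-", "", order_vec)
  a <- match(anchor, genes)
  if (is.na(a)) a <- 1L                     # fall back to first gene
  n <- length(order_vec)
  rot <- order_vec[((seq_len(n) + a - 2L) %% n) + 1L]
  if (startsWith(rot[1L], "-")) {
    # reflect: reverse order and flip all signs
    rot <- rev(rot)
    rot <- ifelse(startsWith(rot, "-"), sub("^-", "", rot),
                  paste0("-", rot))
    rot <- rot[c(n, seq_len(n - 1L))]       # keep anchor first
  }
  structure(rot, class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

# circular signed adjacencies in canonical form: adjacency (a, b) is
# equivalent to (-b, -a); the lexicographically smaller rendering is
# kept
adjacency_set <- function(ord) {
  ord <- unclass(ord)
  n <- length(ord)
  nxt <- c(ord[-1L], ord[1L])
  flip <- function(g) ifelse(startsWith(g, "-"), sub("^-", "", g),
                             paste0("-", g))
  canon <- vapply(seq_len(n), function(i) {
    x <- paste(ord[i], nxt[i]); y <- paste(flip(nxt[i]), flip(ord[i]))
    if (x <= y) x else y
  }, character(1L))
  canon
}

#' Breakpoint distance between two gene orders
#'
#' Number of signed circular adjacencies present in \code{a} but not in
#' \code{b} (a symmetric count when both genomes carry each shared gene
#' exactly once).
#'
#' @param a,b \code{\link{gene_order}} objects over the same gene set.
#' @return integer breakpoint count.
#' @export
breakpoint_distance <- function(a, b) {
  ga <- sort(sub("^-", "", unclass(a)))
  gb <- sort(sub("^-", "", unclass(b)))
  if (!identical(ga, gb))
    stop("gene orders are over different gene sets")
  sum(!adjacency_set(a) %in% adjacency_set(b))
}

#' Pairwise breakpoint-distance matrix for a set of genomes
#'
#' @param genomes list of \code{annotated_mitogenome} objects.
#' @param shared gene set (default: genes shared by all genomes from
#'   the core + rRNA set).
#' @return symmetric integer matrix.
#' @export
breakpoint_matrix <- function(genomes, shared = NULL) {
  if (is.null(shared)) {
    sets <- lapply(genomes, function(g)
      vapply(features_of_kind(g, c("CDS", "rRNA")), `[[`, character(1L),
             "name"))
    shared <- Reduce(intersect, c(list(c(CORE_PCGS, "rnl", "rns")), sets))
  }
  ords <- lapply(genomes, gene_order, shared = shared)
  ids <- vapply(genomes, `[[`, character(1L), "id")
  m <- matrix(0L, length(genomes), length(genomes),
              dimnames = list(ids, ids))
  for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
    if (i < j) m[i, j] <- m[j, i] <- breakpoint_distance(ords[[i]],
                                                         ords[[j]])
  }
  m
}
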