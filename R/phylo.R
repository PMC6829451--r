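# Supermatrix construction and distance-based phylogeny: per-gene
# alignments are concatenated with gap padding for missing taxa, K2P
# distances (pairwise gap deletion) feed neighbor joining, and split
# support comes from column-resampling bootstrap.

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param alignments named list of alignments; each element is a named
#'   character vector of equal-length aligned sequences (taxon ->
#'   row), e.g. from \code{\link{read_fasta}}. Names give the gene
#'   (partition) names; unnamed lists are named gene1, gene2, ...
#' @return object of class \code{supermatrix}: taxa, rows (named
#'   character vector) and a partition table (gene, start, end,
#'   1-based inclusive columns).
#' @export
concatenate_alignments <- function(alignments) {
  if (is.null(names(alignments)))
    names(alignments) <- paste0("gene", seq_along(alignments))
  taxa <- unique(unlist(lapply(alignments, names)))
  if (is.null(taxa) || !length(taxa)) stop("alignments carry no taxon labels")
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list()
  col <- 0L
  padded <- character(0L)
  for (g in names(alignments)) {
    al <- alignments[[g]]
    if (any(duplicated(names(al))))
      stop("duplicate taxon within alignment '", g, "'")
    w <- unique(nchar(al))
    if (length(w) != 1L)
      stop("alignment '", g, "' rows differ in length")
    gap <- strrep("-", w)
    for (tx in taxa) {
      piece <- if (tx %in% names(al)) toupper(al[[tx]]) else {
        padded <- union(padded, tx); gap
      }
      rows[[tx]] <- paste0(rows[[tx]], piece)
    }
    parts[[length(parts) + 1L]] <-
      data.frame(gene = g, start = col + 1L, end = col + w,
                 stringsAsFactors = FALSE)
    col <- col + w
  }
  structure(list(taxa = taxa, rows = rows,
                 partitions = do.call(rbind, parts),
                 padded_taxa = padded, width = col),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d columns, %d partitions\n",
              length(x$taxa), x$width, nrow(x$partitions)))
  if (length(x$padded_taxa))
    cat("  gap-padded taxa:", paste(x$padded_taxa, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise K2P distance matrix of a supermatrix
#'
#' @param sm a \code{\link{concatenate_alignments}} supermatrix, or a
#'   named character vector of aligned sequences.
#' @return symmetric numeric matrix of K2P distances.
#' @export
k2p_matrix <- function(sm) {
  rows <- if (inherits(sm, "supermatrix")) sm$rows else sm
  taxa <- names(rows)
  m <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i < j)
      m[i, j] <- m[j, i] <- k2p_distance(rows[[i]], rows[[j]])
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic tie handling: taxa
#' are ordered by label before joining, so equal Q-criterion ties
#' resolve by label order. Negative branch-length estimates are clamped
#' to zero with a warning.
#'
#' @param m symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return an unrooted \code{ape::phylo} tree with branch lengths.
#' @export
nj_tree <- function(m) {
  if (any(is.na(m))) stop("distance matrix contains NA/NaN entries")
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  o <- order(rownames(m))
  m <- m[o, o]
  tr <- ape::nj(stats::as.dist(m))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# non-trivial splits of an unrooted tree as canonical strings: each
# split is the sorted side not containing the alphabetically first
# taxon
tree_splits <- function(tr) {
  tips <- sort(tr$tip.label)
  ref <- tips[1L]
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- character(0L)
  for (p in pp) {
    side <- sort(labs[p])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (ref %in% side) side <- sort(setdiff(tips, side))
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial splits.
#'
#' @param t1,t2 \code{ape::phylo} trees over the same leaf set.
#' @return integer count.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Bootstrap support for the splits of a reference NJ tree
#'
#' Columns of the supermatrix are resampled with replacement; each
#' replicate is re-analysed with K2P + neighbor joining and the
#' frequency of every non-trivial reference split is recorded.
#'
#' @param sm a \code{\link{concatenate_alignments}} supermatrix.
#' @param replicates number of bootstrap replicates.
#' @param seed integer seed; fixed seeds reproduce supports exactly.
#' @return list: \code{tree} (reference NJ tree), \code{support}
#'   (named percent support per split, names as
#'   \code{taxonA|taxonB|...} for the split side not containing the
#'   first taxon).
#' @export
bootstrap_support <- function(sm, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1L)
  rows <- vapply(sm$rows, identity, character(1L))
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(chars) <- names(sm$rows)
  ref <- nj_tree(k2p_matrix(sm))
  splits <- tree_splits(ref)
  hit <- stats::setNames(numeric(length(splits)), splits)
  set.seed(seed)
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
    boot_rows <- apply(chars[, cols, drop = FALSE], 1L, paste,
                       collapse = "")
    bt <- nj_tree(k2p_matrix(boot_rows))
    bs <- tree_splits(bt)
    hit[splits %in% bs] <- hit[splits %in% bs] + 1
  }
  list(tree = ref, support = 100 * hit / replicates)
}

#' Export a supermatrix as NEXUS with a partition block
#'
#' Writes a simple NEXUS DATA block plus a SETS block with one charset
#' per gene, ready for external Bayesian/ML analysis.
#'
#' @param sm a \code{\link{concatenate_alignments}} supermatrix.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_nexus <- function(sm, path) {
  con <- file(path, "w"); on.exit(close(con))
  quote_taxon <- function(x) ifelse(grepl("[[:space:]]", x),
                                    paste0("'", x, "'"), x)
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa),
                     sm$width), con)
  writeLines("  FORMAT DATATYPE=DNA MISSING=? GAP=-;", con)
  writeLines("  MATRIX", con)
  for (tx in sm$taxa)
    writeLines(sprintf("    %s %s", quote_taxon(tx), sm$rows[[tx]]), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  writeLines("BEGIN SETS;", con)
  for (i in seq_len(nrow(sm$partitions)))
    writeLines(sprintf("  CHARSET %s = %d-%d;", sm$partitions$gene[i],
                       sm$partitions$start[i], sm$partitions$end[i]), con)
  writeLines("END;", con)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' Taxon labels containing spaces are single-quoted.
#'
#' @param tree an \code{ape::phylo}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_newick <- function(tree, path) {
  labs <- tree$tip.label
  needs <- grepl("[][():;,[:space:]]", labs)
  labs[needs] <- paste0("'", gsub("'", "''", labs[needs]), "'")
  n <- length(labs)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  el <- tree$edge.length
  rec <- function(node) {
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      ch <- tree$edge[r, 2L]
      lab <- if (ch <= n) labs[ch] else rec(ch)
      if (!is.null(el)) paste0(lab, ":", sprintf("%.10g", el[r])) else lab
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  writeLines(paste0(rec(n + 1L), ";"), path)
  invisible(path)
}
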