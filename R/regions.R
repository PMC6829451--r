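# Genome region decomposition: protein-coding / intronic / RNA /
# intergenic, gene overlaps, intergenic spans, and attribution of the
# size difference between two genomes to the four region categories.

REGION_CATEGORIES <- c("protein_coding", "rna", "intronic", "intergenic")

# per-base category labels; priority protein_coding(exon) > rna >
# intronic > intergenic, applied by overwriting in increasing priority
region_labels <- function(genome) {
  n <- nchar(genome$sequence)
  lab <- rep.int(4L, n)             # intergenic
  paint <- function(ivs, code) {
    for (i in seq_len(nrow(ivs))) {
      if (ivs[i, 2L] > ivs[i, 1L])
        lab[(ivs[i, 1L] + 1L):ivs[i, 2L]] <<- code
    }
  }
  # intronic: explicit intron features + gaps between exon intervals
  for (f in genome$features) {
    if (f$kind == "intron") paint(f$intervals, 3L)
    if (f$kind %in% c("CDS", "rRNA", "tRNA") && nrow(f$intervals) > 1L) {
      lin <- linearize_intervals(f, n)
      if (nrow(lin) > 1L) {
        gaps <- cbind(lin[-nrow(lin), 2L], lin[-1L, 1L])
        d <- delinearize_intervals(gaps, n)
        paint(d$intervals, 3L)
      }
    }
  }
  for (f in features_of_kind(genome, c("tRNA", "rRNA")))
    paint(f$intervals, 2L)
  # standalone coding exons; intron-encoded ORFs stay intronic
  for (f in features_of_kind(genome, "CDS"))
    paint(f$intervals, 1L)
  lab
}

# full genomic extent of each feature as circle intervals (<= 2 rows)
feature_extents <- function(genome) {
  n <- nchar(genome$sequence)
  lapply(genome$features, function(f) {
    lin <- linearize_intervals(f, n)
    ext <- as_intervals(c(min(lin[, 1L]), max(lin[, 2L])))
    delinearize_intervals(ext, n)$intervals
  })
}

circle_overlap_len <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    tot <- tot + max(0L, min(a[i, 2L], b[j, 2L]) - max(a[i, 1L], b[j, 1L]))
  }
  tot
}

#' Partition a genome into region categories
#'
#' Every base is assigned exactly one of protein-coding, RNA, intronic
#' or intergenic (priority protein-coding exon > RNA > intronic >
#' intergenic), so category totals sum to the genome length. Also
#' reports pairwise gene overlaps (on full gene extents) and intergenic
#' spans with their flanking features; spans wrap the origin on
#' circular genomes.
#'
#' @param genome an \code{annotated_mitogenome}.
#' @return object of class \code{region_partition}.
#' @export
region_partition <- function(genome) {
  n <- nchar(genome$sequence)
  if (!length(genome$features))
    warning("genome '", genome$id, "' has no features; 100% intergenic")
  lab <- region_labels(genome)
  lengths <- vapply(1:4, function(k) sum(lab == k), integer(1L))
  names(lengths) <- REGION_CATEGORIES

  # ---- overlaps between gene extents (introns excluded as features) ----
  keep <- which(vapply(genome$features, function(f) f$kind != "intron",
                       logical(1L)))
  ext <- feature_extents(genome)[keep]
  nm <- vapply(genome$features[keep], `[[`, character(1L), "name")
  overlaps <- list()
  if (length(keep) > 1L) {
    for (i in seq_along(keep)[-length(keep)]) {
      for (j in seq(i + 1L, length(keep))) {
        ov <- circle_overlap_len(ext[[i]], ext[[j]])
        # nested features (intronic ORFs inside their host) are not
        # gene-boundary overlaps
        if (ov > 0L && ov < min(interval_len(ext[[i]]),
                                interval_len(ext[[j]])))
          overlaps[[length(overlaps) + 1L]] <-
            data.frame(gene_a = nm[i], gene_b = nm[j], overlap_bp = ov,
                       stringsAsFactors = FALSE)
      }
    }
  }
  overlaps <- if (length(overlaps)) do.call(rbind, overlaps) else
    data.frame(gene_a = character(0L), gene_b = character(0L),
               overlap_bp = integer(0L))

  # ---- intergenic spans (complement of gene extents on the circle) ----
  covered <- rep.int(FALSE, n)
  owner <- rep.int(NA_integer_, n)
  for (i in seq_along(keep)) {
    e <- ext[[i]]
    for (r in seq_len(nrow(e))) if (e[r, 2L] > e[r, 1L]) {
      idx <- (e[r, 1L] + 1L):e[r, 2L]
      covered[idx] <- TRUE
      owner[idx] <- keep[i]
    }
  }
  spans <- data.frame(left = character(0L), right = character(0L),
                      start = integer(0L), length = integer(0L))
  if (any(!covered) && any(covered)) {
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap_idx <- which(!r$values)
    gaps <- cbind(starts[gap_idx] - 1L, ends[gap_idx])  # 0-based half-open
    if (genome$circular && nrow(gaps) > 1L &&
        gaps[1L, 1L] == 0L && gaps[nrow(gaps), 2L] == n) {
      # merge the seam gap
      gaps[nrow(gaps), 2L] <- n + gaps[1L, 2L]
      gaps <- gaps[-1L, , drop = FALSE]
    }
    fname <- function(pos) {
      o <- owner[(pos %% n) + 1L]
      if (is.na(o)) NA_character_ else genome$features[[o]]$name
    }
    spans <- do.call(rbind, lapply(seq_len(nrow(gaps)), function(i) {
      s <- gaps[i, 1L]; e <- gaps[i, 2L]
      data.frame(left = fname(s - 1L), right = fname(e),
                 start = s %% n, length = e - s, stringsAsFactors = FALSE)
    }))
  } else if (all(!covered)) {
    spans <- data.frame(left = NA_character_, right = NA_character_,
                        start = 0L, length = n, stringsAsFactors = FALSE)
  }

  structure(list(id = genome$id, genome_length = n,
                 lengths = lengths,
                 proportions = 100 * lengths / n,
                 overlaps = overlaps, intergenic_spans = spans),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region_partition '%s' (%d bp):\n", x$id, x$genome_length))
  for (k in REGION_CATEGORIES)
    cat(sprintf("  %-15s %7d bp  %6.2f%%\n", k, x$lengths[[k]],
                x$proportions[[k]]))
  if (nrow(x$overlaps))
    cat(sprintf("  overlaps: %s\n",
                paste(sprintf("%s/%s (-%d bp)", x$overlaps$gene_a,
                              x$overlaps$gene_b, x$overlaps$overlap_bp),
                      collapse = ", ")))
  invisible(x)
}

#' Summarise intergenic spans of a partition
#'
#' @param partition a \code{\link{region_partition}}.
#' @return list: total bp, min bp, max bp, and the features flanking
#'   the longest span.
#' @export
intergenic_summary <- function(partition) {
  sp <- partition$intergenic_spans
  if (!nrow(sp))
    return(list(total = 0L, min = 0L, max = 0L,
                longest_flanks = c(NA_character_, NA_character_)))
  i <- which.max(sp$length)
  list(total = sum(sp$length), min = min(sp$length), max = max(sp$length),
       longest_flanks = c(sp$left[i], sp$right[i]))
}

#' Attribute a genome size difference to region categories
#'
#' For each category c, contribution(c) =
#' (len_c(b) - len_c(a)) / (size(b) - size(a)) * 100; the signed
#' contributions sum to 100% exactly.
#'
#' @param a,b \code{\link{region_partition}} objects of the smaller and
#'   larger genome respectively (any pair of unequal sizes works; the
#'   difference is b - a).
#' @return object of class \code{expansion_decomposition}.
#' @export
expansion_decomposition <- function(a, b) {
  d <- b$genome_length - a$genome_length
  if (d == 0L)
    stop("genomes are the same size; decomposition undefined")
  contrib <- 100 * (b$lengths - a$lengths) / d
  structure(list(a = a$id, b = b$id, size_difference = d,
                 contributions = contrib),
            class = "expansion_decomposition")
}

#' @export
print.expansion_decomposition <- function(x, ...) {
  cat(sprintf("size difference %s -> %s: %+d bp\n", x$a, x$b,
              x$size_difference))
  for (k in names(x$contributions))
    cat(sprintf("  %-15s %+8.2f%%\n", k, x$contributions[[k]]))
  invisible(x)
}
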