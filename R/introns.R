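# Intron inventory and position-class (Pcl) assignment.
#
# A Pcl groups introns inserted at the same nucleotide position of the
# host gene's coding sequence; members in both genomes with high
# pairwise identity are homologous (shared), supporting gain/loss
# inference between the genomes.

#' Extract intron records from an annotated genome
#'
#' Introns are the gaps between consecutive exon intervals of
#' multi-interval CDS/rRNA features. The insertion coordinate is the
#' number of coding-sequence nucleotides upstream of the intron
#' (1-based nt of the spliced sequence preceding the insertion),
#' measured on the coding strand.
#'
#' @param genome an \code{annotated_mitogenome}.
#' @return data.frame: host, genome, coordinate, length, sequence (one
#'   row per intron), ordered by host then coordinate.
#' @export
extract_introns <- function(genome) {
  n <- nchar(genome$sequence)
  rows <- list()
  for (f in genome$features) {
    if (!f$kind %in% c("CDS", "rRNA") || nrow(f$intervals) < 2L) next
    lin <- linearize_intervals(f, n)
    if (any(lin[-1L, 1L] < lin[-nrow(lin), 2L]))
      stop("inconsistent exon annotation in gene '", f$name, "'")
    widths <- lin[, 2L] - lin[, 1L]
    gaps <- cbind(lin[-nrow(lin), 2L], lin[-1L, 1L])
    for (i in seq_len(nrow(gaps))) {
      gseq <- extract_intervals(
        genome$sequence,
        delinearize_intervals(gaps[i, , drop = FALSE], n)$intervals)
      if (f$strand == "-") {
        coord <- sum(widths[seq(i + 1L, length(widths))])
        gseq <- revcomp(gseq)
      } else {
        coord <- sum(widths[seq_len(i)])
      }
      if (!nchar(gseq)) stop("empty intron in gene '", f$name, "'")
      rows[[length(rows) + 1L]] <-
        data.frame(host = f$name, genome = genome$id, coordinate = coord,
                   length = nchar(gseq), sequence = gseq,
                   stringsAsFactors = FALSE)
    }
  }
  # alternative encoding: host annotated as a single span with explicit
  # intron features inside it
  intron_feats <- features_of_kind(genome, "intron")
  if (length(intron_feats)) {
    hosts <- Filter(function(f) f$kind %in% c("CDS", "rRNA") &&
                      nrow(f$intervals) == 1L, genome$features)
    for (h in hosts) {
      hs <- h$intervals[1L, 1L]; he <- h$intervals[1L, 2L]
      inside <- Filter(function(g) g$intervals[1L, 1L] >= hs &&
                         g$intervals[nrow(g$intervals), 2L] <= he,
                       intron_feats)
      if (!length(inside)) next
      starts <- vapply(inside, function(g) g$intervals[1L, 1L], integer(1L))
      inside <- inside[order(starts)]
      ilens <- vapply(inside, feature_length, integer(1L))
      for (i in seq_along(inside)) {
        g <- inside[[i]]
        if (h$strand == "-") {
          downstream <- sum(ilens[seq_along(ilens) > i])
          coord <- (he - g$intervals[nrow(g$intervals), 2L]) - downstream
        } else {
          coord <- (g$intervals[1L, 1L] - hs) - sum(ilens[seq_len(i - 1L)])
        }
        gseq <- feature_sequence(genome, g)
        if (h$strand == "-" && g$strand == "+") gseq <- revcomp(gseq)
        rows[[length(rows) + 1L]] <-
          data.frame(host = h$name, genome = genome$id, coordinate = coord,
                     length = nchar(gseq), sequence = gseq,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(host = character(0L), genome = character(0L),
               coordinate = integer(0L), length = integer(0L),
               sequence = character(0L))
  out[order(out$host, out$coordinate), , drop = FALSE]
}

#' Assign introns of two genomes to position classes
#'
#' Introns are grouped by (host gene, insertion coordinate); matching
#' coordinates mean the same Pcl. Same-position pairs whose pairwise
#' global-alignment identity falls below \code{identity_threshold} are
#' kept in one Pcl but flagged as low-similarity. cox1 classes are
#' labelled with letters when a reference exemplar table (columns
#' gene, coordinate, label) is supplied; unassigned cox1 classes get
#' provisional \code{cox1-p<coordinate>} labels, and other host genes
#' are numbered by ascending coordinate.
#'
#' @param introns_a,introns_b intron tables from
#'   \code{\link{extract_introns}}.
#' @param identity_threshold homology threshold on aligned identity,
#'   in (0, 1]; default 0.70.
#' @param exemplars optional data.frame (gene, coordinate, label) of
#'   reference Pcl names.
#' @return data.frame of class \code{pcl_table}: pcl, host,
#'   coordinate, in_a, in_b, shared, identity, low_similarity.
#' @export
assign_pcls <- function(introns_a, introns_b, identity_threshold = 0.70,
                        exemplars = NULL) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  all_in <- rbind(introns_a, introns_b)
  if (!nrow(all_in))
    return(structure(data.frame(pcl = character(0L), host = character(0L),
                                coordinate = integer(0L), in_a = integer(0L),
                                in_b = integer(0L), shared = logical(0L),
                                identity = numeric(0L),
                                low_similarity = logical(0L)),
                     class = c("pcl_table", "data.frame")))
  ids <- unique(all_in$genome)
  id_a <- if (nrow(introns_a)) introns_a$genome[1L] else ids[1L]
  keys <- unique(all_in[, c("host", "coordinate")])
  keys <- keys[order(keys$host, keys$coordinate), , drop = FALSE]
  counter <- list()
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    h <- keys$host[i]; cc <- keys$coordinate[i]
    mem_a <- introns_a[introns_a$host == h & introns_a$coordinate == cc, ]
    mem_b <- introns_b[introns_b$host == h & introns_b$coordinate == cc, ]
    shared <- nrow(mem_a) > 0L && nrow(mem_b) > 0L
    ident <- NA_real_
    if (shared)
      ident <- alignment_identity(mem_a$sequence[1L], mem_b$sequence[1L])
    data.frame(host = h, coordinate = cc,
               in_a = nrow(mem_a), in_b = nrow(mem_b), shared = shared,
               identity = ident,
               low_similarity = shared && ident < identity_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # labels: letters for cox1 via exemplars, numbers elsewhere
  out$pcl <- NA_character_
  for (h in unique(out$host)) {
    idx <- which(out$host == h)
    idx <- idx[order(out$coordinate[idx])]
    if (h == "cox1") {
      for (k in idx) {
        lbl <- NULL
        if (!is.null(exemplars)) {
          hit <- exemplars$label[exemplars$gene == "cox1" &
                                 exemplars$coordinate == out$coordinate[k]]
          if (length(hit)) lbl <- hit[1L]
        }
        out$pcl[k] <- lbl %||% paste0("cox1-p", out$coordinate[k])
      }
    } else {
      out$pcl[idx] <- paste0(h, "-", seq_along(idx))
    }
  }
  out <- out[, c("pcl", "host", "coordinate", "in_a", "in_b", "shared",
                 "identity", "low_similarity")]
  attr(out, "genome_a") <- id_a
  class(out) <- c("pcl_table", class(out))
  out
}

#' Per-host-gene intron gain/loss summary
#'
#' @param pcls a \code{\link{assign_pcls}} table.
#' @return data.frame: host, n_pcls, shared_pcls, a_only, b_only,
#'   total_introns, and the fraction (percent) of member introns that
#'   are non-homologous (unshared) between the genomes.
#' @export
gain_loss_table <- function(pcls) {
  hosts <- unique(pcls$host)
  rows <- lapply(hosts, function(h) {
    p <- pcls[pcls$host == h, ]
    total <- sum(p$in_a) + sum(p$in_b)
    unshared <- sum(p$in_a[!p$shared]) + sum(p$in_b[!p$shared])
    data.frame(host = h, n_pcls = nrow(p), shared_pcls = sum(p$shared),
               a_only = sum(!p$shared & p$in_a > 0L),
               b_only = sum(!p$shared & p$in_b > 0L),
               total_introns = total,
               pct_nonhomologous = if (total) 100 * unshared / total else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
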