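# Base composition, strand skews and codon usage (genetic code 4).

#' Base composition and strand skew statistics
#'
#' AT skew = (A - T)/(A + T), GC skew = (G - C)/(G + C). N bases are
#' excluded from all denominators; a zero denominator yields a skew of
#' 0 with a warning.
#'
#' @param seq DNA string.
#' @return object of class \code{composition_stats}: length, base
#'   counts, gc/at content (percent) and both skews.
#' @export
composition_stats <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nchar(seq))
    stop("seq must be a non-empty DNA string")
  seq <- toupper(seq)
  ch <- seq_chars(seq)
  counts <- c(A = sum(ch == "A"), C = sum(ch == "C"),
              G = sum(ch == "G"), T = sum(ch == "T"))
  denom <- sum(counts)
  if (denom == 0L) stop("sequence contains no A/C/G/T bases")
  skew <- function(x, y, what) {
    if (x + y == 0L) {
      warning(what, " skew denominator is 0; reporting 0")
      return(0)
    }
    (x - y) / (x + y)
  }
  structure(list(
    length = nchar(seq),
    counts = counts,
    gc_content = 100 * (counts[["G"]] + counts[["C"]]) / denom,
    at_content = 100 * (counts[["A"]] + counts[["T"]]) / denom,
    at_skew = skew(counts[["A"]], counts[["T"]], "AT"),
    gc_skew = skew(counts[["G"]], counts[["C"]], "GC")
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "%d bp | GC %.2f%% AT %.2f%% | AT skew %.2f | GC skew %.2f\n",
    x$length, x$gc_content, x$at_content, x$at_skew, x$gc_skew))
  invisible(x)
}

# genetic code 4 (mold mitochondrial): TGA = Trp
genetic_code4 <- function() Biostrings::getGeneticCode("4")

translate4 <- function(cds) {
  codons <- codon_split(cds)
  gc <- genetic_code4()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"              # codons containing N
  paste(aa, collapse = "")
}

#' Codon usage table under the mold mitochondrial genetic code
#'
#' Counts codons in frame across the selected coding sequences (spliced
#' and strand-oriented); trailing partial codons are dropped. Frequency
#' is count over the pooled codon total.
#'
#' @param genome an \code{annotated_mitogenome}.
#' @param genes gene symbols to pool; default the core
#'   protein-coding set present in the genome.
#' @return object of class \code{codon_usage}: data.frame with codon,
#'   amino acid (code 4), count, frequency; plus per-gene start/stop
#'   codons.
#' @export
codon_usage <- function(genome, genes = NULL) {
  if (is.null(genes)) {
    present <- vapply(features_of_kind(genome, "CDS"), `[[`, character(1L),
                      "name")
    genes <- intersect(CORE_PCGS, present)
  }
  genes <- genes[vapply(genes, function(g)
    !is.null(find_feature(genome, g, c("CDS", "ORF"))), logical(1L))]
  if (!length(genes)) stop("no resolvable coding genes in ", genome$id)
  gc4 <- genetic_code4()
  all_codons <- names(gc4)
  counts <- stats::setNames(integer(64L), all_codons)
  per_gene <- vector("list", length(genes))
  names(per_gene) <- genes
  starts <- stops <- stats::setNames(character(length(genes)), genes)
  for (g in genes) {
    cds <- coding_sequence(genome, g)
    codons <- codon_split(cds)
    codons <- codons[!grepl("N", codons)]
    tab <- table(factor(codons, levels = all_codons))
    counts <- counts + as.integer(tab)
    per_gene[[g]] <- as.integer(tab)
    starts[[g]] <- if (length(codons)) codons[1L] else NA_character_
    stops[[g]] <- if (length(codons)) codons[length(codons)] else NA_character_
  }
  total <- sum(counts)
  tbl <- data.frame(codon = all_codons, aa = unname(gc4[all_codons]),
                    count = unname(counts),
                    frequency = if (total > 0) unname(counts) / total else 0,
                    stringsAsFactors = FALSE)
  structure(list(table = tbl, total_codons = total,
                 per_gene = do.call(cbind, per_gene),
                 starts = starts, stops = stops),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  top <- x$table[order(-x$table$count), ][1:6, ]
  cat(sprintf("codon_usage: %d codons pooled over %d genes\n",
              x$total_codons, length(x$starts)))
  cat("  top codons:",
      paste(sprintf("%s(%s)=%.3f", top$codon, top$aa, top$frequency),
            collapse = " "), "\n")
  invisible(x)
}

#' Per-gene start and stop codons with non-standard flags
#'
#' @param genome an \code{annotated_mitogenome}.
#' @param genes genes to report (default: core protein-coding genes
#'   present).
#' @return data.frame: gene, start, stop, nonstandard_start (not ATG),
#'   nonstandard_stop (not TAA).
#' @export
start_stop_table <- function(genome, genes = NULL) {
  if (is.null(genes)) {
    present <- vapply(features_of_kind(genome, "CDS"), `[[`, character(1L),
                      "name")
    genes <- intersect(CORE_PCGS, present)
  }
  if (!length(genes)) stop("no core CDS present in ", genome$id)
  rows <- lapply(genes, function(g) {
    cds <- coding_sequence(genome, g)
    if (nchar(cds) < 6L) stop("CDS of '", g, "' shorter than 6 nt")
    codons <- codon_split(cds)
    data.frame(gene = g, start = codons[1L], stop = codons[length(codons)],
               nonstandard_start = codons[1L] != "ATG",
               nonstandard_stop = codons[length(codons)] != "TAA",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
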