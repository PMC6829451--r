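# GenBank flat-file I/O.
#
# The reader handles LOCUS/FEATURES/ORIGIN blocks, join() and
# complement() locations (including joins across the origin of circular
# molecules), multi-line locations and quoted qualifiers. The writer
# produces records that round-trip through the reader.

GB_KEYS <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", intron = "intron")

# ---- location strings ----------------------------------------------------

# parse a GenBank location into list(intervals [0-based half-open],
# strand, origin_span); seqlen is needed to detect origin wraps
parse_location <- function(loc, seqlen, line = NA_integer_) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  ok <- grepl("^[0-9]+(\\.\\.[0-9]+)?$", parts)
  if (!length(parts) || !all(ok))
    stop("malformed location at line ", line, ": '", loc, "'")
  ivs <- t(vapply(parts, function(p) {
    se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    if (length(se) == 1L) se <- c(se, se)
    c(se[1L] - 1L, se[2L])          # to 0-based half-open
  }, integer(2L)))
  origin_span <- nrow(ivs) > 1L && any(diff(ivs[, 1L]) < 0)
  list(intervals = as_intervals(ivs), strand = strand,
       origin_span = origin_span)
}

format_location <- function(f) {
  ivs <- f$intervals
  parts <- sprintf("%d..%d", ivs[, 1L] + 1L, ivs[, 2L])
  loc <- if (length(parts) > 1L)
    paste0("join(", paste(parts, collapse = ","), ")") else parts
  if (f$strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

# ---- reader --------------------------------------------------------------

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Gene, CDS, tRNA, rRNA and intron features are captured with their
#' locations mapped to the internal 0-based half-open convention;
#' \code{join()} and \code{complement()} locations (including joins
#' across the origin of a circular record) are supported. CDS features
#' nested inside introns of other genes are tagged as intron-encoded
#' ORFs.
#'
#' @param path path to a GenBank flat file.
#' @return an \code{\link{annotated_mitogenome}}.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1L]))
    stop("malformed record at line 1: missing LOCUS line")
  toks <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  id <- toks[2L]
  seqlen <- suppressWarnings(as.integer(toks[3L]))
  circular <- any(grepl("circular", toks, ignore.case = TRUE))

  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) stop("missing ORIGIN block in ", path)
  origin_at <- origin_at[1L]
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[1L] else length(lines) + 1L
  seq_lines <- lines[seq(origin_at + 1L, end_at - 1L)]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines,
                                                        collapse = "")))
  if (!nchar(sequence)) stop("empty sequence in ORIGIN block of ", path)
  if (is.na(seqlen)) seqlen <- nchar(sequence)

  feat_at <- grep("^FEATURES", lines)
  raw <- list()
  if (length(feat_at)) {
    i <- feat_at[1L] + 1L
    cur <- NULL
    while (i < origin_at) {
      line <- lines[i]
      if (grepl("^ {5}[A-Za-z_']", line)) {        # new feature key
        if (!is.null(cur)) raw[[length(raw) + 1L]] <- cur
        key <- trimws(substr(line, 1L, 20L))
        cur <- list(key = key, loc = trimws(substring(line, 21L)),
                    line = i, quals = character(0L))
      } else if (!is.null(cur)) {
        txt <- trimws(line)
        if (startsWith(txt, "/")) {
          cur$quals <- c(cur$quals, txt)
        } else if (nchar(txt)) {
          # continuation of a location or of a quoted qualifier
          if (length(cur$quals)) {
            cur$quals[length(cur$quals)] <-
              paste0(cur$quals[length(cur$quals)], txt)
          } else cur$loc <- paste0(cur$loc, txt)
        }
      }
      i <- i + 1L
    }
    if (!is.null(cur)) raw[[length(raw) + 1L]] <- cur
  }

  qual_value <- function(quals, name) {
    hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    v <- sub(paste0("^/", name, "="), "", hit[1L])
    gsub("\"", "", v)
  }

  feats <- list()
  for (r in raw) {
    if (!r$key %in% names(GB_KEYS)) next
    loc <- parse_location(r$loc, seqlen, line = r$line)
    gene <- qual_value(r$quals, "gene")
    if (is.na(gene)) gene <- qual_value(r$quals, "label")
    product <- qual_value(r$quals, "product")
    if (is.na(gene)) gene <- if (!is.na(product)) product else r$key
    anticodon <- NA_character_
    if (r$key == "tRNA") {
      ac <- qual_value(r$quals, "anticodon")
      if (!is.na(ac)) {
        m <- regmatches(ac, regexpr("seq:[ACGTUacgtu]{3}", ac))
        anticodon <- toupper(sub("seq:", "",
                                 if (length(m)) m else ac))
        anticodon <- gsub("[^ACGTU]", "", anticodon)
        anticodon <- chartr("U", "T", substr(anticodon, 1L, 3L))
      }
    }
    kind <- GB_KEYS[[r$key]]
    note <- qual_value(r$quals, "note")
    if (kind == "CDS" && !is.na(note) && grepl("intron-encoded", note))
      kind <- "ORF"
    feats[[length(feats) + 1L]] <-
      gene_feature(gene, kind, loc$intervals, loc$strand,
                   product = product, anticodon = anticodon,
                   origin_span = loc$origin_span)
  }

  # tag CDS nested inside intron gaps of other features as ORFs
  feats <- tag_intronic_orfs(feats)
  annotated_mitogenome(id, sequence, feats, circular = circular)
}

# a CDS lying entirely within an intron (explicit intron feature, or a
# gap between consecutive exon intervals of another gene) is an
# intron-encoded ORF, not a standalone protein gene
tag_intronic_orfs <- function(feats) {
  gaps <- list()
  for (f in feats) {
    if (f$kind == "intron") {
      gaps[[length(gaps) + 1L]] <- f$intervals
    } else if (f$kind %in% c("CDS", "rRNA") && nrow(f$intervals) > 1L &&
               !f$origin_span) {
      ivs <- f$intervals
      gaps[[length(gaps) + 1L]] <-
        cbind(ivs[-nrow(ivs), 2L], ivs[-1L, 1L])
    }
  }
  if (!length(gaps)) return(feats)
  gaps <- do.call(rbind, gaps)
  lapply(feats, function(f) {
    if (f$kind != "CDS" || nrow(f$intervals) != 1L) return(f)
    s <- f$intervals[1L, 1L]; e <- f$intervals[1L, 2L]
    inside <- any(gaps[, 1L] <= s & e <= gaps[, 2L])
    if (inside) f$kind <- "ORF"
    f
  })
}

# ---- writer --------------------------------------------------------------

#' Write an annotated mitogenome as a GenBank flat file
#'
#' @param genome an \code{\link{annotated_mitogenome}}.
#' @param path output path.
#' @return invisibly, \code{path}. Reading the file back with
#'   \code{\link{read_genbank}} reproduces the feature table and
#'   sequence.
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$sequence)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to '", path, "'")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  # no date field: output must be byte-identical for identical input
  w("LOCUS       %s %d bp    DNA     %s   UNA",
    genome$id, n, if (genome$circular) "circular" else "linear")
  w("DEFINITION  %s mitochondrion.", genome$id)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", n)
  for (f in genome$features) {
    key <- if (f$kind == "ORF") "CDS" else f$kind
    w("     %-15s %s", key, format_location(f))
    w("                     /gene=\"%s\"", f$name)
    if (!is.na(f$product))
      w("                     /product=\"%s\"", f$product)
    if (f$kind == "ORF")
      w("                     /note=\"intron-encoded ORF\"")
    if (f$kind == "tRNA" && !is.na(f$anticodon))
      w("                     /anticodon=(seq:%s)", tolower(f$anticodon))
  }
  w("ORIGIN")
  s <- tolower(genome$sequence)
  for (start in seq(1L, n, by = 60L)) {
    chunk <- substring(s, start, min(start + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    w("%9d %s", start, paste(blocks, collapse = " "))
  }
  w("//")
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
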