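# tRNA comparison: pair shared tRNAs between genomes and localise
# variable sites to cloverleaf structural domains.

TRNA_DOMAINS <- c("acceptor_stem", "d_arm", "anticodon_arm",
                  "variable_region", "t_arm", "other")

#' Map tRNA positions to cloverleaf domains
#'
#' With a dot-bracket secondary structure the domains are derived from
#' the pairing pattern (acceptor stem = outer pairs; the three hairpins
#' in sequence order are the D arm, anticodon arm and T arm; unpaired
#' bases between the anticodon and T arms form the variable region).
#' Without a structure, a canonical positional template is used: 7 bp
#' acceptor stem at both ends, D arm at 10-25, anticodon arm at 27-43
#' with the anticodon at 34-36, T arm over the 17 bases preceding the
#' 3' acceptor stem, and the remainder as variable region.
#'
#' @param seq tRNA gene sequence (coding strand).
#' @param structure optional dot-bracket string of the same length.
#' @return object of class \code{trna_domain_map}: per-position domain
#'   labels and the anticodon position triplet.
#' @export
trna_domain_map <- function(seq, structure = NULL) {
  L <- nchar(seq)
  if (L < 54L) stop("sequence too short to be a tRNA (", L, " nt)")
  if (L < 71L || L > 88L)
    warning("tRNA length ", L, " nt outside the expected 71-88 nt range")
  if (!is.null(structure)) {
    lab <- domains_from_structure(structure)
  } else {
    lab <- rep("other", L)
    lab[1:7] <- "acceptor_stem"
    lab[10:25] <- "d_arm"
    lab[27:43] <- "anticodon_arm"
    if (L - 25L >= 44L) lab[44:(L - 25L)] <- "variable_region"
    lab[(L - 24L):(L - 8L)] <- "t_arm"
    lab[(L - 6L):L] <- "acceptor_stem"
  }
  ac <- which(lab == "anticodon_arm")
  anticodon_pos <- if (length(ac) >= 3L) {
    mid <- ac[ceiling(length(ac) / 2)]
    (mid - 1L):(mid + 1L)
  } else integer(0L)
  if (is.null(structure)) anticodon_pos <- 34:36
  structure(list(length = L, domains = lab,
                 anticodon_pos = anticodon_pos),
            class = "trna_domain_map")
}

# dot-bracket -> per-position domain labels
domains_from_structure <- function(db) {
  s <- seq_chars(db)
  L <- length(s)
  partner <- integer(L)
  stack <- integer(0L)
  for (i in seq_len(L)) {
    if (s[i] == "(") stack <- c(stack, i)
    else if (s[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket structure")
  lab <- rep("other", L)
  # hairpin loops: runs of dots flanked by a pair
  r <- rle(s == ".")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  loops <- list()
  for (k in which(r$values)) {
    l <- starts[k]; rr <- ends[k]
    if (l > 1L && rr < L && partner[l - 1L] == rr + 1L)
      loops[[length(loops) + 1L]] <- c(l, rr)
  }
  if (length(loops) != 3L)
    stop("expected 3 hairpin loops in cloverleaf, found ", length(loops))
  arm_names <- c("d_arm", "anticodon_arm", "t_arm")
  spans <- matrix(0L, 3L, 2L)
  for (k in 1:3) {
    l <- loops[[k]][1L]; rr <- loops[[k]][2L]
    lab[l:rr] <- arm_names[k]
    i <- l - 1L; j <- rr + 1L
    while (i >= 1L && j <= L) {
      if (partner[i] == j) {
        lab[i] <- lab[j] <- arm_names[k]; i <- i - 1L; j <- j + 1L
      } else if (s[i] == ".") { lab[i] <- arm_names[k]; i <- i - 1L
      } else if (s[j] == ".") { lab[j] <- arm_names[k]; j <- j + 1L
      } else break
    }
    spans[k, ] <- c(i + 1L, j - 1L)
  }
  # acceptor stem: pairs spanning all three hairpins
  for (i in which(s == "(")) {
    if (i < spans[1L, 1L] && partner[i] > spans[3L, 2L])
      lab[i] <- lab[partner[i]] <- "acceptor_stem"
  }
  # variable region: unpaired stretch between anticodon arm and T arm
  between <- seq_len(L) > spans[2L, 2L] & seq_len(L) < spans[3L, 1L]
  lab[between & lab == "other"] <- "variable_region"
  lab
}

# parse "trnM" / "trnS2" style names into the amino-acid letter part
trna_aa <- function(name) sub("^trn([A-Za-z]+)[0-9]*$", "\\1", name)

#' Match tRNA genes between two genomes
#'
#' Pairs are matched by (amino acid, anticodon); isodecoders (multiple
#' copies with the same anticodon) are matched by order of occurrence
#' along each genome.
#'
#' @param a,b \code{annotated_mitogenome} objects.
#' @return list: \code{pairs} data.frame (name, anticodon, index in
#'   each genome), \code{unmatched_a}, \code{unmatched_b}.
#' @export
match_trnas <- function(a, b) {
  tab <- function(g) {
    fs <- features_of_kind(g, "tRNA")
    fs <- fs[order(vapply(fs, function(f) f$intervals[1L, 1L], integer(1L)))]
    data.frame(name = vapply(fs, `[[`, character(1L), "name"),
               anticodon = vapply(fs, `[[`, character(1L), "anticodon"),
               idx = seq_along(fs), stringsAsFactors = FALSE)
  }
  ta <- tab(a); tb <- tab(b)
  key <- function(t) paste(trna_aa(t$name), t$anticodon)
  ta$key <- key(ta); tb$key <- key(tb)
  pairs <- list(); used_b <- logical(nrow(tb))
  for (i in seq_len(nrow(ta))) {
    j <- which(tb$key == ta$key[i] & !used_b)
    if (length(j)) {
      j <- j[1L]; used_b[j] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(name = ta$name[i], anticodon = ta$anticodon[i],
                   idx_a = ta$idx[i], idx_b = tb$idx[j],
                   stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(name = character(0L), anticodon = character(0L),
               idx_a = integer(0L), idx_b = integer(0L))
  list(pairs = pairs,
       unmatched_a = ta$name[!ta$key %in% tb$key],
       unmatched_b = tb$name[!used_b & !tb$key %in% ta$key])
}

#' Variable sites between one matched tRNA pair
#'
#' Equal-length pairs are compared position by position; unequal
#' lengths are globally aligned first. Each variable position is
#' attributed to the cloverleaf domain of the first sequence.
#'
#' @param seq_a,seq_b tRNA gene sequences (coding strand).
#' @param domains \code{\link{trna_domain_map}} for \code{seq_a}
#'   (computed from the template when NULL).
#' @return data.frame: position (in \code{seq_a}), base_a, base_b,
#'   domain.
#' @export
variable_sites <- function(seq_a, seq_b, domains = NULL) {
  if (is.null(domains)) domains <- trna_domain_map(seq_a)
  if (nchar(seq_a) == nchar(seq_b)) {
    x <- seq_chars(seq_a); y <- seq_chars(seq_b)
    pos <- which(x != y)
    return(data.frame(position = pos, base_a = x[pos], base_b = y[pos],
                      domain = domains$domains[pos],
                      stringsAsFactors = FALSE))
  }
  al <- align_global(seq_a, seq_b)
  x <- seq_chars(al[1L]); y <- seq_chars(al[2L])
  apos <- cumsum(x != "-")
  pos <- which(x != y)
  dom <- ifelse(x[pos] == "-", "other", domains$domains[apos[pos]])
  data.frame(position = ifelse(x[pos] == "-", NA_integer_, apos[pos]),
             base_a = x[pos], base_b = y[pos], domain = dom,
             stringsAsFactors = FALSE)
}

#' tRNA variation report between two genomes
#'
#' Matches tRNAs, finds variable sites per pair and totals them per
#' cloverleaf domain.
#'
#' @param a,b \code{annotated_mitogenome} objects.
#' @param structures optional named list of dot-bracket strings (by
#'   tRNA name, for genome \code{a}).
#' @return object of class \code{trna_variation_report}: per-tRNA site
#'   table, per-domain totals, and the number of tRNAs with at least
#'   one variable site.
#' @export
trna_variation_report <- function(a, b, structures = NULL) {
  m <- match_trnas(a, b)
  fa <- features_of_kind(a, "tRNA")
  fa <- fa[order(vapply(fa, function(f) f$intervals[1L, 1L], integer(1L)))]
  fb <- features_of_kind(b, "tRNA")
  fb <- fb[order(vapply(fb, function(f) f$intervals[1L, 1L], integer(1L)))]
  sites <- list()
  for (i in seq_len(nrow(m$pairs))) {
    p <- m$pairs[i, ]
    sa <- feature_sequence(a, fa[[p$idx_a]])
    sb <- feature_sequence(b, fb[[p$idx_b]])
    dm <- trna_domain_map(sa, structure = structures[[p$name]])
    v <- variable_sites(sa, sb, dm)
    if (nrow(v)) {
      v$trna <- p$name
      sites[[length(sites) + 1L]] <- v
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(position = integer(0L), base_a = character(0L),
               base_b = character(0L), domain = character(0L),
               trna = character(0L))
  domain_totals <- vapply(TRNA_DOMAINS, function(d) sum(sites$domain == d),
                          integer(1L))
  structure(list(pairs = m$pairs, unmatched_a = m$unmatched_a,
                 unmatched_b = m$unmatched_b, sites = sites,
                 domain_totals = domain_totals,
                 n_variable_trnas = length(unique(sites$trna)),
                 n_shared = nrow(m$pairs)),
            class = "trna_variation_report")
}

#' @export
print.trna_variation_report <- function(x, ...) {
  cat(sprintf(
    "trna_variation_report: %d shared tRNAs, %d with variable sites\n",
    x$n_shared, x$n_variable_trnas))
  tot <- x$domain_totals[x$domain_totals > 0]
  if (length(tot))
    cat("  variable sites by domain:",
        paste(sprintf("%s=%d", names(tot), tot), collapse = ", "), "\n")
  invisible(x)
}
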