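# Synthetic annotated-mitogenome generator.
#
# Builds a pair of circular AT-rich mitogenomes with fully known
# structure: 15 core protein genes + 2 rRNAs + 25 tRNAs + accessory
# ORFs, group-I-style introns planted at fixed coding-sequence
# coordinates (shared or genome-specific), overlapping gene pairs,
# tandem and interspersed repeats, domain-targeted tRNA mutations, and
# per-gene K2P-process divergence. Every planted quantity is recorded
# in truth tables so each pipeline stage has an exact oracle.

CORE_GENE_LENGTHS <- c(
  atp6 = 774L, atp8 = 147L, atp9 = 225L, cob = 1161L, cox1 = 1608L,
  cox2 = 750L, cox3 = 810L, nad1 = 984L, nad2 = 1734L, nad3 = 417L,
  nad4 = 1488L, nad4L = 270L, nad5 = 2016L, nad6 = 642L, rps3 = 1506L)

# amino acid -> anticodon for the 25-tRNA roster (2 isoacceptors for
# Ser/Leu/Arg, 3 Met isodecoders)
TRNA_ROSTER <- data.frame(
  name = c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
           "trnI", "trnK", "trnL1", "trnL2", "trnM1", "trnM2", "trnM3",
           "trnN", "trnP", "trnQ", "trnR1", "trnR2", "trnS1", "trnS2",
           "trnT", "trnV", "trnW", "trnY"),
  anticodon = c("TGC", "GCA", "GTC", "TTC", "GAA", "TCC", "GTG",
                "GAT", "TTT", "TAA", "TAG", "CAT", "CAT", "CAT",
                "GTT", "TGG", "TTG", "TCT", "ACG", "TGA", "GCT",
                "TGT", "TAC", "TCA", "GTA"),
  length = c(rep(73L, 9L), 85L, 85L, 73L, 73L, 73L,
             73L, 73L, 73L, 73L, 73L, 86L, 86L,
             73L, 73L, 73L, 73L),
  stringsAsFactors = FALSE)

# default intron plan: host, coordinate (nt of spliced CDS upstream of
# the insertion), presence, lengths and planted identity for shared
# introns. 16 introns in genome A, 24 in B, 9 shared position classes.
default_intron_plan <- function() {
  p <- function(host, coord, status) data.frame(
    host = host, coordinate = coord, status = status,
    stringsAsFactors = FALSE)
  plan <- rbind(
    p("cox1", 216L, "shared"), p("cox1", 393L, "shared"),
    p("cox1", 723L, "shared"), p("cox1", 1065L, "shared"),
    p("cox1", 510L, "a_only"), p("cox1", 888L, "a_only"),
    p("cox1", 300L, "b_only"), p("cox1", 450L, "b_only"),
    p("cox1", 600L, "b_only"), p("cox1", 810L, "b_only"),
    p("cox1", 951L, "b_only"), p("cox1", 1152L, "b_only"),
    p("cox1", 1251L, "b_only"), p("cox1", 1392L, "b_only"),
    p("cox2", 543L, "a_only"),
    p("cox3", 315L, "shared"), p("cox3", 510L, "a_only"),
    p("cox3", 603L, "b_only"),
    p("cob", 333L, "shared"), p("cob", 564L, "shared"),
    p("cob", 741L, "shared"), p("cob", 900L, "a_only"),
    p("nad1", 480L, "b_only"), p("nad1", 640L, "b_only"),
    p("nad1", 800L, "b_only"),
    p("nad5", 555L, "shared"), p("nad5", 1011L, "a_only"),
    p("nad5", 1335L, "b_only"), p("nad5", 1671L, "b_only"),
    p("rnl", 1200L, "a_only"), p("rnl", 2000L, "b_only"))
  plan$length_a <- ifelse(plan$status == "b_only", NA_integer_, 850L)
  plan$length_b <- ifelse(plan$status == "a_only", NA_integer_,
                          ifelse(plan$status == "shared", 850L, 1370L))
  plan$identity <- ifelse(plan$status == "shared", 0.90, NA_real_)
  plan
}

# per-core-gene substitution proportion between the two genomes; atp8
# receives only synonymous changes so its Ka is exactly 0
default_divergence <- function() {
  d <- c(atp6 = 0.05, atp8 = 0.03, atp9 = 0.010, cob = 0.05, cox1 = 0.04,
         cox2 = 0.05, cox3 = 0.10, nad1 = 0.05, nad2 = 0.06, nad3 = 0.06,
         nad4 = 0.05, nad4L = 0.04, nad5 = 0.05, nad6 = 0.12, rps3 = 0.14)
  d
}

# tRNA mutation plan: 13 tRNAs carry one variable site each; domain
# totals 6 acceptor stem, 4 D arm, 2 T arm, 1 anticodon arm
default_trna_plan <- function() {
  data.frame(
    trna = c("trnA", "trnD", "trnF", "trnH", "trnK", "trnN",
             "trnC", "trnE", "trnG", "trnI",
             "trnP", "trnQ", "trnT"),
    domain = c(rep("acceptor_stem", 6L), rep("d_arm", 4L),
               rep("t_arm", 2L), "anticodon_arm"),
    stringsAsFactors = FALSE)
}

#' Specification for a synthetic mitogenome pair
#'
#' The defaults emulate the empirical structure of a congeneric pair
#' of boletalean false-truffle mitogenomes: a ~66.7 kb and a ~77.1 kb
#' circular molecule at 78.5% AT; 16 vs 24 group-I introns in 9 shared
#' position classes; an 85 bp cox3/ORF overlap; planted tandem repeats
#' (including a 13-copy unit and a 116 bp four-copy unit), an 810 bp
#' interspersed duplicate at 95% identity; 13 mutated tRNAs with 6
#' acceptor-stem and 4 D-arm variable sites; per-gene substitution
#' proportions between 0.01 (atp9) and 0.14 (rps3) at
#' transition/transversion ratio 2, with purely synonymous change in
#' atp8.
#'
#' @param seed integer seed; the seed fully determines the output.
#' @param at_content target AT fraction.
#' @param kappa transition/transversion ratio of the substitution
#'   process.
#' @param divergence named per-gene substitution proportions.
#' @param intron_plan data.frame(host, coordinate, status in
#'   \{shared, a_only, b_only\}, length_a, length_b, identity).
#' @param trna_plan data.frame(trna, domain) of planted tRNA
#'   mutations.
#' @param intergenic_total_a,intergenic_total_b target intergenic
#'   totals (bp).
#' @return object of class \code{generator_spec}.
#' @export
generator_spec <- function(seed = 1L, at_content = 0.785, kappa = 2,
                           divergence = default_divergence(),
                           intron_plan = default_intron_plan(),
                           trna_plan = default_trna_plan(),
                           intergenic_total_a = 20700L,
                           intergenic_total_b = 15900L) {
  structure(list(seed = as.integer(seed), at_content = at_content,
                 kappa = kappa, divergence = divergence,
                 intron_plan = intron_plan, trna_plan = trna_plan,
                 intergenic_total_a = intergenic_total_a,
                 intergenic_total_b = intergenic_total_b),
            class = "generator_spec")
}

# ---- sequence builders ---------------------------------------------------

# Codon draws reject stop codons, which depresses realized AT below
# the per-base draw probability (TAA/TAG are AT-rich). Solve for the
# draw probability whose accepted-codon AT expectation equals the
# target; deterministic, no RNG.
calibrate_cds_at <- function(target) {
  accepted_at <- function(f) {
    p_taa <- (f / 2)^3
    p_tag <- (f / 2)^2 * (1 - f) / 2
    (3 * f - 3 * p_taa - 2 * p_tag) / (3 * (1 - p_taa - p_tag))
  }
  stats::uniroot(function(f) accepted_at(f) - target,
                 c(target, 1 - 1e-9), tol = 1e-10)$root
}

# random in-frame CDS of the given length (start, body without stops,
# terminal stop)
random_cds <- function(len, at, start_codon = "ATG", stop_codon = "TAA") {
  stopifnot(len %% 3L == 0L, len >= 9L)
  n_body <- len / 3L - 2L
  gc <- genetic_code4()
  body <- character(n_body)
  for (i in seq_len(n_body)) {
    repeat {
      cod <- random_dna(3L, at)
      if (gc[[cod]] != "*") break
    }
    body[i] <- cod
  }
  paste0(start_codon, paste(body, collapse = ""), stop_codon)
}

# cloverleaf-template tRNA gene: random bases with the anticodon
# placed at template positions 34-36
random_trna <- function(len, anticodon, at) {
  s <- seq_chars(random_dna(len, at))
  s[34:36] <- seq_chars(anticodon)
  paste(s, collapse = "")
}

# K2P-process substitution: p of the sites are changed; transitions
# chosen with probability kappa/(kappa+1), else one of the two
# transversions. For in-frame CDS the first/last codons are fixed and
# changes creating in-frame stops are resampled as transversions or
# skipped.
mutate_seq <- function(seq, p, kappa, in_frame = FALSE) {
  ch <- seq_chars(seq)
  n <- length(ch)
  eligible <- if (in_frame) 4:(n - 3L) else seq_len(n)
  k <- round(p * n)
  if (k == 0L) return(seq)
  sites <- sample(eligible, min(k, length(eligible)))
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  gc <- genetic_code4()
  for (s in sites) {
    old <- ch[s]
    cands <- if (stats::runif(1L) < kappa / (kappa + 1)) transition[[old]]
    else sample(transversions[[old]], 1L)
    for (nb in c(cands, setdiff(c("A", "C", "G", "T"), c(old, cands)))) {
      ch[s] <- nb
      if (!in_frame) break
      ci <- (s - 1L) %/% 3L
      cod <- paste(ch[(3L * ci + 1L):(3L * ci + 3L)], collapse = "")
      if (gc[[cod]] != "*") break
      ch[s] <- old
    }
  }
  paste(ch, collapse = "")
}

# substitute only synonymously: third positions whose change preserves
# the amino acid (transition preferred)
mutate_cds_synonymous <- function(seq, p, kappa) {
  ch <- seq_chars(seq)
  n <- length(ch)
  gc <- genetic_code4()
  k <- round(p * n)
  if (k == 0L) return(seq)
  codon_idx <- sample(2:(n / 3L - 1L))
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  done <- 0L
  for (ci in codon_idx) {
    if (done >= k) break
    pos <- 3L * ci                       # third codon position
    cod <- paste(ch[(pos - 2L):pos], collapse = "")
    old <- ch[pos]
    for (nb in c(transition[[old]], setdiff(c("A", "C", "G", "T"), old))) {
      mut <- cod
      substr(mut, 3L, 3L) <- nb
      if (gc[[mut]] == gc[[cod]] && gc[[mut]] != "*") {
        ch[pos] <- nb; done <- done + 1L; break
      }
    }
  }
  paste(ch, collapse = "")
}

# derive a diverged copy of an intron sequence at the target identity
mutate_to_identity <- function(seq, identity, kappa) {
  mutate_seq(seq, p = 1 - identity, kappa = kappa)
}

# ---- genome assembly -----------------------------------------------------

# assembler state: grows a sequence and a feature list with a cursor.
# overlap_bp > 0 starts the new gene inside the previous one (its
# first overlap_bp bases reuse existing sequence).
new_assembler <- function() {
  env <- new.env(parent = emptyenv())
  env$seq <- character(0L)      # chunks, concatenated at the end
  env$pos <- 0L
  env$features <- list()
  env
}

asm_append <- function(env, s) {
  env$seq[[length(env$seq) + 1L]] <- s
  env$pos <- env$pos + nchar(s)
}

asm_spacer <- function(env, s) asm_append(env, s)

# pieces: odd entries exons, even entries introns (coding orientation);
# intron_orfs: optional data.frame(index, offset, length) of
# intron-embedded ORFs
asm_gene <- function(env, name, kind, pieces, strand = "+",
                     product = NA_character_, anticodon = NA_character_,
                     overlap_bp = 0L, intron_orfs = NULL) {
  full_coding_order <- paste(pieces, collapse = "")
  gseq <- if (strand == "-") revcomp(full_coding_order) else
    full_coding_order
  glen <- nchar(gseq)
  start <- env$pos - overlap_bp
  if (overlap_bp > 0L) gseq <- substring(gseq, overlap_bp + 1L)
  asm_append(env, gseq)
  # piece intervals in genome order
  lens <- nchar(pieces)
  ord <- if (strand == "-") rev(seq_along(pieces)) else seq_along(pieces)
  offs <- cumsum(c(0L, lens[ord]))
  piece_iv <- cbind(start + offs[-length(offs)], start + offs[-1L])
  is_exon_genome_order <- (ord %% 2L) == 1L
  exon_iv <- piece_iv[is_exon_genome_order, , drop = FALSE]
  env$features[[length(env$features) + 1L]] <-
    gene_feature(name, kind, exon_iv, strand, product = product,
                 anticodon = anticodon)
  if (!is.null(intron_orfs) && nrow(intron_orfs)) {
    intron_rows <- which(!is_exon_genome_order)
    intron_coding_idx <- ord[intron_rows] / 2L   # intron number
    for (r in seq_len(nrow(intron_orfs))) {
      gi <- intron_rows[match(intron_orfs$index[r], intron_coding_idx)]
      if (is.na(gi)) next
      iv <- piece_iv[gi, ]
      s0 <- iv[1L] + intron_orfs$offset[r]
      env$features[[length(env$features) + 1L]] <-
        gene_feature(paste0(name, ".i", intron_orfs$index[r], "orf"),
                     "ORF", c(s0, s0 + intron_orfs$length[r]), strand,
                     product = "LAGLIDADG homing endonuclease")
    }
  }
  invisible(env)
}

asm_finish <- function(env, id) {
  annotated_mitogenome(id, paste(env$seq, collapse = ""), env$features,
                       circular = TRUE)
}

# splice introns into a coding sequence at the planned coordinates;
# returns the alternating exon/intron piece list
splice_plan <- function(cds, introns) {
  if (!nrow(introns)) return(cds)
  introns <- introns[order(introns$coordinate), , drop = FALSE]
  pieces <- character(0L)
  prev <- 0L
  for (i in seq_len(nrow(introns))) {
    pieces <- c(pieces, substring(cds, prev + 1L, introns$coordinate[i]),
                introns$sequence[i])
    prev <- introns$coordinate[i]
  }
  c(pieces, substring(cds, prev + 1L, nchar(cds)))
}

#' Generate a synthetic annotated mitogenome pair with truth tables
#'
#' Genome A is assembled gene by gene; genome B carries the same gene
#' complement with per-gene K2P-process substitutions (resampled when
#' they would create in-frame stops), planned codon indels in nad3,
#' nad4 and rps3, its own intron complement, accessory-ORF roster,
#' intergenic spacers and repeat insertions.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return list: \code{a}, \code{b} (annotated mitogenomes) and
#'   \code{truth} (list of data.frames describing every planted
#'   quantity).
#' @export
generate_pair <- function(spec = generator_spec()) {
  set.seed(spec$seed)
  at <- spec$at_content
  kap <- spec$kappa
  plan <- spec$intron_plan
  at_cds <- calibrate_cds_at(at)

  # The K2P substitution process pulls mutated components toward 50%
  # AT: an AT base struck by a substitution becomes G or C with
  # probability 5/6 at kappa = 2 (transition w.p. 2/3 plus the GC
  # transversion w.p. 1/6), and symmetrically for GC bases, so each
  # mutated site loses (5/6)(2f - 1) expected AT. Genome B's freshly
  # drawn non-coding material compensates for the total expected loss
  # so that both genomes land on the target genome-wide AT.
  flux <- 5 / 6 * (2 * at - 1)
  shared_rows <- spec$intron_plan$status == "shared"
  mutated_sites <-
    sum(CORE_GENE_LENGTHS * spec$divergence[names(CORE_GENE_LENGTHS)]) +
    (3200L + 1600L) * mean(spec$divergence) * 0.5 +
    sum(spec$intron_plan$length_a[shared_rows] *
          (1 - spec$intron_plan$identity[shared_rows])) +
    810L * 0.05
  deficit_bp <- mutated_sites * flux
  fresh_b_len <-
    sum(spec$intron_plan$length_b[spec$intron_plan$status == "b_only"]) +
    spec$intergenic_total_b +
    (810L + 2L * 163L + 4L * 29L + 13L * 12L + 2L * 60L + 2L * 40L)
  at_fresh_b <- min(at + deficit_bp / fresh_b_len, 0.98)

  # ---- shared gene sequences (genome A versions) ----
  core_a <- list()
  for (g in names(CORE_GENE_LENGTHS)) {
    core_a[[g]] <- random_cds(CORE_GENE_LENGTHS[[g]], at_cds,
                              start_codon = if (g == "cox1") "TTG" else "ATG",
                              stop_codon = if (g == "cob") "TAG" else "TAA")
  }
  rrna_a <- list(rnl = random_dna(3200L, at), rns = random_dna(1600L, at))
  trna_a <- list()
  for (i in seq_len(nrow(TRNA_ROSTER)))
    trna_a[[TRNA_ROSTER$name[i]]] <-
      random_trna(TRNA_ROSTER$length[i], TRNA_ROSTER$anticodon[i], at)

  # accessory ORFs: 9 in A (incl. orf632 overlapping cox3), 7 in B
  orf_lens_a <- c(orf632 = 1899L, dpo1 = 2400L, dpo2 = 2100L, dpo3 = 1800L,
                  orf300 = 903L, orf250 = 753L, orf200 = 603L,
                  orf150 = 453L, orf105 = 318L)
  orf_lens_b <- c(orf641 = 1926L, dpo1 = 2400L, dpo2 = 2100L,
                  orf232 = 699L, orf249 = 750L, orf438 = 1317L,
                  orf105 = 318L)
  orfs_a <- lapply(orf_lens_a, random_cds, at = at_cds)
  orfs_b_new <- lapply(orf_lens_b[c("orf641", "orf232", "orf249",
                                    "orf438")], random_cds, at = at_cds)

  # ---- genome B gene versions ----
  core_b <- list()
  for (g in names(core_a)) {
    p <- spec$divergence[[g]] %||% 0.05
    core_b[[g]] <- if (g == "atp8")
      mutate_cds_synonymous(core_a[[g]], p, kap)
    else mutate_seq(core_a[[g]], p, kap, in_frame = TRUE)
  }
  # planned codon indels (length variation): delete 7 codons from nad3,
  # 2 from nad4, insert 4 into rps3
  drop_codons <- function(s, from_codon, n_codons) {
    paste0(substr(s, 1L, 3L * (from_codon - 1L)),
           substring(s, 3L * (from_codon - 1L + n_codons) + 1L))
  }
  core_b$nad3 <- drop_codons(core_b$nad3, 60L, 7L)
  core_b$nad4 <- drop_codons(core_b$nad4, 200L, 2L)
  ins <- random_cds(24L, at_cds)   # borrow 4 interior codons
  core_b$rps3 <- paste0(substr(core_b$rps3, 1L, 300L),
                        substr(ins, 4L, 15L),
                        substring(core_b$rps3, 301L))
  # rRNAs diverge at half the mean protein-gene rate
  rrna_b <- lapply(rrna_a, mutate_seq, p = mean(spec$divergence) * 0.5,
                   kappa = kap)
  trna_b <- trna_a
  trna_truth <- spec$trna_plan
  trna_truth$position <- rep(NA_integer_, nrow(trna_truth))
  domain_positions <- function(dom, L) {
    tmpl <- trna_domain_map(random_dna(L, at))
    pos <- which(tmpl$domains == dom)
    setdiff(pos, 34:36)                 # never touch the anticodon
  }
  for (i in seq_len(nrow(trna_truth))) {
    nm <- trna_truth$trna[i]
    L <- nchar(trna_b[[nm]])
    pos <- sample(domain_positions(trna_truth$domain[i], L), 1L)
    ch <- seq_chars(trna_b[[nm]])
    ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1L)
    trna_b[[nm]] <- paste(ch, collapse = "")
    trna_truth$position[i] <- pos
  }

  # ---- intron sequences per plan ----
  plan$seq_a <- NA_character_
  plan$seq_b <- NA_character_
  for (i in seq_len(nrow(plan))) {
    if (plan$status[i] != "b_only") {
      plan$seq_a[i] <- random_dna(plan$length_a[i], at)
      if (plan$status[i] == "shared")
        plan$seq_b[i] <- mutate_to_identity(plan$seq_a[i],
                                            plan$identity[i], kap)
    } else {
      plan$seq_b[i] <- random_dna(plan$length_b[i], at_fresh_b)
    }
  }

  # ---- repeat plan ----
  tandem_unit_long <- random_dna(29L, at_fresh_b)  # 116 bp locus, 4 copies
  tandem_unit_many <- random_dna(12L, at_fresh_b)  # 13 copies
  tandem_a_unit <- random_dna(17L, at)             # 3 copies in genome A
  dup810 <- random_dna(810L, at_fresh_b)
  dup810_copy <- mutate_seq(dup810, p = 0.05, kappa = kap)
  dup163 <- random_dna(163L, at_fresh_b)
  exact60 <- random_dna(60L, at_fresh_b)
  pal40 <- random_dna(40L, at_fresh_b)

  # ---- intergenic spacers ----
  spacer_set <- function(n_gaps, total, fixed = integer(0L)) {
    rest <- n_gaps - length(fixed)
    raw <- stats::runif(rest, 0.4, 1.6)
    lens <- pmax(20L, round(raw / sum(raw) * (total - sum(fixed))))
    sample(c(fixed, lens))
  }

  intron_rows <- function(genome, host) {
    col <- if (genome == "a") "seq_a" else "seq_b"
    keep <- plan$host == host & !is.na(plan[[col]])
    out <- data.frame(coordinate = plan$coordinate[keep],
                      sequence = plan[[col]][keep],
                      stringsAsFactors = FALSE)
    out[order(out$coordinate), , drop = FALSE]
  }

  build <- function(which) {
    env <- new_assembler()
    core <- if (which == "a") core_a else core_b
    rrna <- if (which == "a") rrna_a else rrna_b
    trna <- if (which == "a") trna_a else trna_b
    minus <- c("nad2", "nad3", "atp8", "trnC", "trnE", "trnR2", "trnW")
    ov_orf <- if (which == "a") "orf632" else "orf641"
    ov_seq <- if (which == "a") orfs_a$orf632 else orfs_b_new$orf641
    orfs <- if (which == "a")
      orfs_a[setdiff(names(orfs_a), "orf632")]
    else c(orfs_b_new[c("orf232", "orf249", "orf438")],
           orfs_a[c("dpo1", "dpo2", "orf105")])
    # gene layout: tRNAs interleaved among the big genes
    layout <- c("trnM1", "rns", "trnA", "trnC", "cox1", "trnD", "nad1",
                "trnE", "orf105", "trnM2", "nad2", "trnF", "nad3",
                "trnG", "atp6", "trnH", "atp8", "trnI", "atp9", "trnK",
                if (which == "a") "orf200" else "orf201_gap",
                "cob", "trnL1", "nad4", "trnL2", "nad4L", "trnM3",
                "cox3|OV", "trnN", "nad5", "trnP", "rnl", "trnQ",
                "nad6", "trnR1", "cox2", "trnR2", "rps3", "trnS1",
                if (which == "a") "orf150" else "orf232",
                "trnS2", "dpo1", "trnT", "dpo2",
                if (which == "a") c("orf250", "orf300", "dpo3")
                else c("orf249", "orf438"),
                "trnV", "trnW", "trnY")
    layout <- layout[layout != "orf201_gap"]
    n_gaps <- length(layout)           # circular: one gap per block
    total <- if (which == "a") spec$intergenic_total_a else
      spec$intergenic_total_b
    gaps <- spacer_set(n_gaps, total, fixed = c(37L, 1500L))
    gap_seqs <- lapply(gaps, random_dna,
                       at = if (which == "b") at_fresh_b else at)
    # plant repeats inside genome-B (and a tandem in A) spacers
    if (which == "b") {
      gap_seqs[[2L]] <- paste0(gap_seqs[[2L]], dup810)
      gap_seqs[[20L]] <- paste0(gap_seqs[[20L]], dup810_copy)
      gap_seqs[[5L]] <- paste0(gap_seqs[[5L]], dup163)
      gap_seqs[[30L]] <- paste0(gap_seqs[[30L]], dup163)
      gap_seqs[[12L]] <- paste0(gap_seqs[[12L]],
                                strrep(tandem_unit_long, 4L))
      gap_seqs[[25L]] <- paste0(gap_seqs[[25L]],
                                strrep(tandem_unit_many, 13L))
      gap_seqs[[34L]] <- paste0(gap_seqs[[34L]], exact60)
      gap_seqs[[40L]] <- paste0(gap_seqs[[40L]], exact60)
      gap_seqs[[44L]] <- paste0(gap_seqs[[44L]], pal40)
      gap_seqs[[48L]] <- paste0(gap_seqs[[48L]], revcomp(pal40))
    } else {
      gap_seqs[[15L]] <- paste0(gap_seqs[[15L]],
                                strrep(tandem_a_unit, 3L))
    }
    for (bi in seq_along(layout)) {
      asm_spacer(env, gap_seqs[[bi]])
      blk <- layout[bi]
      overlap <- 0L
      if (blk == "cox3|OV") blk <- "cox3"
      nm <- blk
      if (nm %in% names(core)) {
        ir <- intron_rows(which, nm)
        pieces <- splice_plan(core[[nm]], ir)
        orf_tbl <- if (nrow(ir)) data.frame(
          index = seq_len(nrow(ir)),
          offset = 150L,
          length = 300L)[nchar(ir$sequence) >= 850L &
                           seq_len(nrow(ir)) %% 2L == 1L, , drop = FALSE]
        else NULL
        asm_gene(env, nm, "CDS", pieces,
                 strand = if (nm %in% minus) "-" else "+",
                 product = nm, intron_orfs = orf_tbl)
        if (nm == "cox3") {
          # overlapping accessory ORF: starts 85 bp before cox3 ends
          asm_gene(env, ov_orf, "CDS", ov_seq, strand = "+",
                   product = "hypothetical protein", overlap_bp = 85L)
        }
      } else if (nm %in% names(rrna)) {
        ir <- intron_rows(which, nm)
        pieces <- splice_plan(rrna[[nm]], ir)
        asm_gene(env, nm, "rRNA", pieces, strand = "+",
                 product = if (nm == "rnl") "large subunit ribosomal RNA"
                 else "small subunit ribosomal RNA")
      } else if (nm %in% names(trna)) {
        i <- match(nm, TRNA_ROSTER$name)
        asm_gene(env, nm, "tRNA", trna[[nm]],
                 strand = if (nm %in% minus) "-" else "+",
                 product = paste0("tRNA-", trna_aa(nm)),
                 anticodon = TRNA_ROSTER$anticodon[i])
      } else {
        asm_gene(env, nm, "CDS", orfs[[nm]], strand = "+",
                 product = if (startsWith(nm, "dpo"))
                   "B-type DNA polymerase" else "hypothetical protein")
      }
    }
    asm_finish(env, if (which == "a") "synthetic_A" else "synthetic_B")
  }

  a <- build("a")
  b <- build("b")

  truth <- list(
    sizes = c(a = nchar(a$sequence), b = nchar(b$sequence)),
    at_content = at,
    core_lengths = data.frame(
      gene = names(CORE_GENE_LENGTHS),
      length_a = vapply(core_a, nchar, integer(1L)),
      length_b = vapply(core_b, nchar, integer(1L)),
      divergence = unname(spec$divergence[names(CORE_GENE_LENGTHS)]),
      stringsAsFactors = FALSE),
    introns = plan[, c("host", "coordinate", "status", "identity")],
    n_introns = c(a = sum(plan$status != "b_only"),
                  b = sum(plan$status != "a_only")),
    n_shared_pcls = sum(plan$status == "shared"),
    trna_mutations = trna_truth,
    repeats = list(
      tandem_b = data.frame(period = c(29L, 12L), copies = c(4L, 13L)),
      tandem_a = data.frame(period = 17L, copies = 3L),
      dup810 = list(length = 810L, identity = 95),
      dup163 = list(length = 163L, identity = 100),
      exact_forward = 60L, exact_palindromic = 40L),
    kappa = kap)
  list(a = a, b = b, truth = truth)
}

#' Simulate a multiple alignment along a tree under a K2P process
#'
#' Sites are independent; branch lengths are expected substitutions
#' per site; \code{kappa} is the expected transition/transversion
#' ratio.
#'
#' @param tree an \code{ape::phylo} (or Newick string) with branch
#'   lengths.
#' @param length alignment columns.
#' @param kappa transition/transversion ratio.
#' @param seed integer seed.
#' @return named character vector of aligned sequences (one per tip).
#' @export
simulate_alignment <- function(tree, length, kappa = 2, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  set.seed(seed)
  # rate matrix order (ac, ag, at, cg, ct, gt): transition rates ag/ct
  # are 2*kappa so that the expected substitution count ratio is kappa
  sim <- phangorn::simSeq(tree, l = length,
                          Q = c(1, 2 * kappa, 1, 1, 2 * kappa, 1),
                          bf = rep(0.25, 4L), type = "DNA")
  m <- toupper(as.character(sim))
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}
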