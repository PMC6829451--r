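# Pipeline orchestration: run every comparative module on a genome
# pair, write per-module TSVs plus a Markdown summary, and return the
# collected results. Each number in the summary is taken directly from
# one module's output; the report layer never recomputes.

#' Pipeline configuration
#'
#' @param genomes list of \code{annotated_mitogenome} objects (>= 2),
#'   or NULL if \code{paths} is given.
#' @param paths character vector of GenBank file paths (used when
#'   \code{genomes} is NULL).
#' @param out_dir output directory for TSVs/summary; NULL writes
#'   nothing.
#' @param min_repeat_length exact-repeat minimum length (bp).
#' @param min_tandem_unit tandem-repeat minimum unit length (bp).
#' @param pcl_identity intron position-class homology threshold.
#' @param bootstrap_replicates bootstrap replicates for the phylogeny
#'   stage.
#' @param seed integer seed controlling all randomness.
#' @param modules character vector of stages to run (default: all).
#' @param alignments optional named list of per-gene multi-taxon
#'   alignments for the phylogeny stage; when absent, the supermatrix
#'   is built from the codon-aware alignments of the shared core genes
#'   of the two genomes (two taxa: exported for external analysis, no
#'   tree is estimated).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(genomes = NULL, paths = NULL, out_dir = NULL,
                            min_repeat_length = 30L, min_tandem_unit = 11L,
                            pcl_identity = 0.70,
                            bootstrap_replicates = 100L, seed = 1L,
                            modules = c("composition", "regions",
                                        "core_genes", "trna", "introns",
                                        "repeats", "synteny", "phylo"),
                            alignments = NULL) {
  if (is.null(genomes)) {
    if (is.null(paths)) stop("provide genomes or paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  stopifnot(min_repeat_length >= 8L, min_tandem_unit >= 1L,
            pcl_identity > 0, pcl_identity <= 1,
            bootstrap_replicates >= 1L)
  structure(list(genomes = genomes, paths = paths, out_dir = out_dir,
                 min_repeat_length = as.integer(min_repeat_length),
                 min_tandem_unit = as.integer(min_tandem_unit),
                 pcl_identity = pcl_identity,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 seed = as.integer(seed), modules = modules,
                 alignments = alignments),
            class = "pipeline_config")
}

write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

# run one stage; on error, re-throw with the module name attached so
# partial outputs written by earlier stages are retained on disk
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("module '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full comparative pipeline on a genome pair
#'
#' Executes composition, region-partition, core-gene divergence, tRNA
#' variation, intron/position-class, repeat, gene-order and phylogeny
#' stages on the first two genomes of the configuration, writes one
#' TSV per table plus \code{summary.md} to \code{out_dir}, and returns
#' everything invisibly as a \code{report_bundle}. Deterministic for a
#' fixed config and seed (byte-identical TSVs on re-run).
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{report_bundle}: named list of stage
#'   results plus \code{summary} (character lines).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genomes <- config$genomes %||% lapply(config$paths, read_genbank)
  if (length(genomes) < 2L) stop("run_all needs at least 2 genomes")
  a <- genomes[[1L]]; b <- genomes[[2L]]
  dir <- config$out_dir
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  res <- list(config = config, genome_ids = c(a$id, b$id))
  md <- c(sprintf("# Comparative mitogenome report: %s vs %s", a$id, b$id),
          "")
  fmt2 <- function(x) formatC(x, format = "f", digits = 2)

  if ("composition" %in% config$modules) run_stage("composition", {
    res$composition <- list(a = composition_stats(a$sequence),
                            b = composition_stats(b$sequence))
    res$codon_usage <- list(a = codon_usage(a), b = codon_usage(b))
    res$start_stop <- list(a = start_stop_table(a), b = start_stop_table(b))
    comp_df <- do.call(rbind, lapply(list(a = res$composition$a,
                                          b = res$composition$b),
      function(s) data.frame(length = s$length,
                             gc_content = fmt2(s$gc_content),
                             at_content = fmt2(s$at_content),
                             at_skew = fmt2(s$at_skew),
                             gc_skew = fmt2(s$gc_skew))))
    comp_df <- cbind(genome = c(a$id, b$id), comp_df)
    write_tsv(comp_df, dir, "composition")
    write_tsv(res$codon_usage$a$table, dir, paste0("codon_usage_", a$id))
    write_tsv(res$codon_usage$b$table, dir, paste0("codon_usage_", b$id))
    write_tsv(res$start_stop$a, dir, paste0("start_stop_", a$id))
    write_tsv(res$start_stop$b, dir, paste0("start_stop_", b$id))
    md <- c(md, "## Genome composition", "",
             sprintf("- %s: %d bp, GC %s%%, AT skew %s, GC skew %s",
                     a$id, res$composition$a$length,
                     fmt2(res$composition$a$gc_content),
                     fmt2(res$composition$a$at_skew),
                     fmt2(res$composition$a$gc_skew)),
             sprintf("- %s: %d bp, GC %s%%, AT skew %s, GC skew %s",
                     b$id, res$composition$b$length,
                     fmt2(res$composition$b$gc_content),
                     fmt2(res$composition$b$at_skew),
                     fmt2(res$composition$b$gc_skew)), "")
  })

  if ("regions" %in% config$modules) run_stage("regions", {
    res$regions <- list(a = region_partition(a), b = region_partition(b))
    res$intergenic <- list(a = intergenic_summary(res$regions$a),
                           b = intergenic_summary(res$regions$b))
    res$decomposition <- tryCatch(
      expansion_decomposition(res$regions$a, res$regions$b),
      error = function(e) structure(list(note = "N/A (equal sizes)"),
                                    class = "expansion_na"))
    reg_df <- rbind(
      cbind(genome = a$id, category = REGION_CATEGORIES,
            length = res$regions$a$lengths,
            percent = fmt2(res$regions$a$proportions)),
      cbind(genome = b$id, category = REGION_CATEGORIES,
            length = res$regions$b$lengths,
            percent = fmt2(res$regions$b$proportions)))
    write_tsv(as.data.frame(reg_df), dir, "region_partition")
    if (!inherits(res$decomposition, "expansion_na"))
      write_tsv(data.frame(category = REGION_CATEGORIES,
                           delta_bp = res$regions$b$lengths -
                             res$regions$a$lengths,
                           contribution_pct =
                             fmt2(res$decomposition$contributions)),
                dir, "expansion_decomposition")
    md <- c(md, "## Region partition (% of genome)", "",
             sprintf("- %s: %s", a$id,
                     paste(sprintf("%s %s%%", REGION_CATEGORIES,
                                   fmt2(res$regions$a$proportions)),
                           collapse = ", ")),
             sprintf("- %s: %s", b$id,
                     paste(sprintf("%s %s%%", REGION_CATEGORIES,
                                   fmt2(res$regions$b$proportions)),
                           collapse = ", ")),
             if (inherits(res$decomposition, "expansion_na"))
               "- Expansion decomposition: N/A (equal sizes)"
             else sprintf("- Size difference %+d bp; decomposition: %s",
                          res$decomposition$size_difference,
                          paste(sprintf("%s %s%%", REGION_CATEGORIES,
                                        fmt2(res$decomposition$contributions)),
                                collapse = ", ")),
             "")
  })

  if ("core_genes" %in% config$modules) run_stage("core_genes", {
    res$divergence <- core_gene_table(a, b)
    write_tsv(res$divergence, dir, "core_gene_divergence")
    kk <- res$divergence$ka_ks[!is.na(res$divergence$ka_ks)]
    md <- c(md, "## Core protein-coding genes", "",
             sprintf("- mean K2P across %d shared genes: %.4f",
                     nrow(res$divergence), mean(res$divergence$k2p)),
             if (length(kk))
               sprintf("- Ka/Ks range (defined ratios): %.2f-%.2f",
                       min(kk), max(kk))
             else "- Ka/Ks range: N/A (no defined ratios)", "")
  })

  if ("trna" %in% config$modules) run_stage("trna", {
    res$trna <- trna_variation_report(a, b)
    write_tsv(res$trna$sites, dir, "trna_variable_sites")
    dt <- res$trna$domain_totals
    md <- c(md, "## tRNA variation", "",
             sprintf("- %d shared tRNAs, %d with variable sites",
                     res$trna$n_shared, res$trna$n_variable_trnas),
             sprintf("- variable sites by domain: %s",
                     paste(sprintf("%s=%d", names(dt), dt),
                           collapse = ", ")), "")
  })

  if ("introns" %in% config$modules) run_stage("introns", {
    ia <- extract_introns(a); ib <- extract_introns(b)
    res$introns <- list(a = ia, b = ib)
    res$pcls <- assign_pcls(ia, ib,
                            identity_threshold = config$pcl_identity)
    res$gain_loss <- gain_loss_table(res$pcls)
    write_tsv(ia[, setdiff(names(ia), "sequence")], dir,
              paste0("introns_", a$id))
    write_tsv(ib[, setdiff(names(ib), "sequence")], dir,
              paste0("introns_", b$id))
    write_tsv(as.data.frame(res$pcls), dir, "intron_position_classes")
    write_tsv(res$gain_loss, dir, "intron_gain_loss")
    md <- c(md, "## Introns", "",
             sprintf("- %s: %d introns; %s: %d introns", a$id, nrow(ia),
                     b$id, nrow(ib)),
             sprintf("- %d position classes, %d shared",
                     nrow(res$pcls), sum(res$pcls$shared)), "")
  })

  if ("repeats" %in% config$modules) run_stage("repeats", {
    res$exact_repeats <- list(
      a = exact_repeats(a$sequence,
                        min_length = config$min_repeat_length),
      b = exact_repeats(b$sequence,
                        min_length = config$min_repeat_length))
    res$tandem_repeats <- list(
      a = tandem_repeats(a$sequence, min_unit = config$min_tandem_unit),
      b = tandem_repeats(b$sequence, min_unit = config$min_tandem_unit))
    res$similarity <- list(
      a = similarity_hits(stats::setNames(list(a$sequence), a$id),
                          stats::setNames(list(a$sequence), a$id)),
      b = similarity_hits(stats::setNames(list(b$sequence), b$id),
                          stats::setNames(list(b$sequence), b$id)))
    for (w in c("a", "b")) {
      id <- if (w == "a") a$id else b$id
      write_tsv(res$exact_repeats[[w]], dir, paste0("exact_repeats_", id))
      write_tsv(res$tandem_repeats[[w]], dir, paste0("tandem_repeats_", id))
      write_tsv(res$similarity[[w]], dir, paste0("similarity_hits_", id))
    }
    md <- c(md, "## Repeats", "",
             sprintf("- exact repeats >= %d bp: %d (%s), %d (%s)",
                     config$min_repeat_length,
                     nrow(res$exact_repeats$a), a$id,
                     nrow(res$exact_repeats$b), b$id),
             sprintf("- tandem loci: %d (%s, %.2f%% coverage), %d (%s, %.2f%% coverage)",
                     nrow(res$tandem_repeats$a), a$id,
                     attr(res$tandem_repeats$a, "coverage_pct"),
                     nrow(res$tandem_repeats$b), b$id,
                     attr(res$tandem_repeats$b, "coverage_pct")), "")
  })

  if ("synteny" %in% config$modules) run_stage("synteny", {
    res$gene_orders <- lapply(genomes, gene_order)
    res$breakpoints <- breakpoint_matrix(genomes)
    write_tsv(as.data.frame(res$breakpoints), dir, "breakpoint_matrix")
    md <- c(md, "## Gene order", "",
             sprintf("- breakpoint distance %s vs %s: %d", a$id, b$id,
                     res$breakpoints[a$id, b$id]), "")
  })

  if ("phylo" %in% config$modules) run_stage("phylo", {
    if (!is.null(config$alignments)) {
      sm <- concatenate_alignments(config$alignments)
    } else {
      shared <- intersect(
        intersect(CORE_PCGS,
                  vapply(features_of_kind(a, "CDS"), `[[`, character(1L),
                         "name")),
        vapply(features_of_kind(b, "CDS"), `[[`, character(1L), "name"))
      als <- lapply(shared, function(g) {
        al <- align_codon_aware(coding_sequence(a, g),
                                coding_sequence(b, g))
        stats::setNames(al, c(a$id, b$id))
      })
      sm <- concatenate_alignments(stats::setNames(als, shared))
    }
    res$supermatrix <- sm
    res$k2p_matrix <- k2p_matrix(sm)
    if (!is.null(dir)) write_nexus(sm, file.path(dir, "supermatrix.nex"))
    if (length(sm$taxa) >= 3L) {
      res$phylo <- bootstrap_support(sm, config$bootstrap_replicates,
                                     seed = config$seed)
      if (!is.null(dir))
        write_newick(res$phylo$tree, file.path(dir, "nj_tree.nwk"))
      md <- c(md, "## Phylogeny", "",
               sprintf("- NJ tree on %d taxa, %d columns; min split support %.0f%%",
                       length(sm$taxa), sm$width,
                       if (length(res$phylo$support))
                         min(res$phylo$support) else 100), "")
    } else {
      md <- c(md, "## Phylogeny", "",
               sprintf("- 2-taxon supermatrix (%d columns) exported for external analysis; K2P distance %.4f",
                       sm$width, res$k2p_matrix[1L, 2L]), "")
    }
  })

  res$summary <- md
  if (!is.null(dir)) writeLines(md, file.path(dir, "summary.md"))
  class(res) <- "report_bundle"
  invisible(res)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(x$summary, sep = "\n")
  invisible(x)
}
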