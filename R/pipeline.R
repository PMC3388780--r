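#' Run the full pan-genome pipeline
#'
#' Orchestrates the stages in order: similarity search (or ingested hits),
#' typed homology graph, Markov clustering, family labelling, pan-genome
#' partitioning, LSE classification, tandem-array and duplicated-block
#' detection, and optional signature screening and GO tabulation.
#'
#' @param proteins Named character vector of all protein sequences.
#' @param genes Gene table covering the same genes (see
#'   [read_gene_table()]).
#' @param hits Directed hit table, or `NULL` to compute hits with the
#'   built-in aligner ([all_vs_all()]).
#' @param evalue_cutoff BLASTP-style E-value cutoff (default `1e-5`).
#' @param inflation MCL inflation (default 1.5).
#' @param max_gap,min_anchors Block-detection parameters
#'   ([find_dup_blocks()]).
#' @param terminal_fraction Terminal-region proxy fraction
#'   ([flag_terminal()]).
#' @param outgroup_hits Optional outgroup hit table for signature screening
#'   of core families ([screen_signature()]).
#' @param annotations Optional gene-to-GO mapping ([read_gaf()]).
#' @param go_ids Optional GO ids to tabulate over core families.
#' @param sweep `TRUE` to also run the E-value-by-inflation sweep
#'   ([mcl_sweep()]) with default grids.
#' @param out_dir Optional output directory for [write_results()].
#' @param ... Further arguments to [all_vs_all()] (e.g. `prescreen`).
#' @return A `pan_pipeline` list: `hits`, `graph`, `clusters`, `families`,
#'   `copies`, `partition`, `core_pct`, `lse`, `lse_sizes`, `tandem_runs`,
#'   `dup_blocks`, `signature`, `go`, `sweep`, `summary` (headline counts).
#' @export
run_pipeline <- function(proteins, genes, hits = NULL,
                         evalue_cutoff = 1e-5, inflation = 1.5,
                         max_gap = 3L, min_anchors = 2L,
                         terminal_fraction = 0.1, outgroup_hits = NULL,
                         annotations = NULL, go_ids = NULL, sweep = FALSE,
                         out_dir = NULL, ...) {
  stopifnot(setequal(names(proteins), genes$gene_id))
  genome_of <- setNames(genes$genome_id, genes$gene_id)
  genome_ids <- sort(unique(genes$genome_id))
  genome_sizes <- table(genes$genome_id)[genome_ids]

  if (is.null(hits)) {
    hits <- all_vs_all(proteins, cutoff = evalue_cutoff, ...)
  }
  graph <- hits_to_graph(hits, genome_of, cutoff = evalue_cutoff)
  clusters <- mcl_cluster(graph, inflation = inflation,
                          nodes = names(proteins))
  families <- label_families(clusters, genome_of)
  copies <- copy_matrix(families, genome_ids)
  partition <- pan_partition(copies, genome_ids)
  core_pct <- core_fraction(partition, copies, genome_sizes)
  lse <- classify_lse(copies, partition, genome_sizes)
  lse_sizes <- lse_size_distribution(lse$calls)
  family_of <- setNames(families$family_id, families$gene_id)
  runs <- find_tandem_runs(genes, family_of)
  blocks <- find_dup_blocks(genes, family_of, max_gap = max_gap,
                            min_anchors = min_anchors)
  replicon_lengths <- table(genes$replicon_id)
  blocks <- flag_terminal(blocks, replicon_lengths, terminal_fraction)

  signature <- NULL
  if (!is.null(outgroup_hits)) {
    core_fams <- partition$table$family_id[partition$table$category ==
                                           "core"]
    core_members <- families[families$family_id %in% core_fams, ,
                             drop = FALSE]
    sig_fams <- screen_signature(core_members, outgroup_hits)
    sig_genes <- genes[genes$gene_id %in%
                       core_members$gene_id[core_members$family_id %in%
                                            sig_fams], , drop = FALSE]
    signature <- list(
      families = sig_fams,
      central_pct = central_fraction(sig_genes, replicon_lengths,
                                     terminal_fraction))
  }

  go <- NULL
  if (!is.null(annotations)) {
    fam_ann <- go_family_annotation(families, annotations)
    core_fams <- partition$table$family_id[partition$table$category ==
                                           "core"]
    core_ann <- go_family_annotation(
      families[families$family_id %in% core_fams, , drop = FALSE],
      annotations)
    go <- list(family_terms = fam_ann$terms,
               core_fraction_annotated = core_ann$fraction_annotated,
               core_n_annotated = core_ann$n_annotated)
    if (!is.null(go_ids)) {
      go$core_counts <- go_tabulate(fam_ann$terms, core_fams, go_ids)
    }
  }

  sweep_res <- NULL
  if (isTRUE(sweep)) {
    sweep_res <- mcl_sweep(hits, genome_of)
  }

  summary <- c(
    partition$totals,
    list(n_genes = nrow(genes),
         n_genomes = length(genome_ids),
         core_pct = as.list(core_pct),
         lse_summary = lse$summary,
         n_tandem_runs = nrow(runs),
         n_dup_blocks = nrow(blocks),
         n_terminal_blocks = sum(blocks$terminal_flag, na.rm = TRUE),
         evalue_cutoff = evalue_cutoff,
         inflation = inflation))
  if (!is.null(sweep_res)) {
    summary$sweep_min_groups <- min(sweep_res$matrix)
    summary$sweep_max_groups <- max(sweep_res$matrix)
  }

  result <- list(hits = hits, graph = graph, clusters = clusters,
                 families = families, copies = copies,
                 partition = partition, core_pct = core_pct, lse = lse,
                 lse_sizes = lse_sizes, tandem_runs = runs,
                 dup_blocks = blocks, signature = signature, go = go,
                 sweep = sweep_res, summary = summary)
  class(result) <- "pan_pipeline"
  if (!is.null(out_dir)) {
    write_results(families, partition, lse$calls, runs, blocks, out_dir)
  }
  result
}

#' @export
print.pan_pipeline <- function(x, ...) {
  s <- x$summary
  cat("pan-genome pipeline:", s$n_genes, "genes in", s$n_genomes,
      "genomes\n")
  print(x$partition)
  cat("tandem runs:", s$n_tandem_runs, "; duplicated blocks:",
      s$n_dup_blocks, "(", s$n_terminal_blocks, "terminal )\n")
  invisible(x)
}
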