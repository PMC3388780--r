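#' Compare a clustering against true family labels
#'
#' @param truth_labels Named character vector: true family label per gene.
#' @param clusters A `cluster_set`, long family table, or list of gene-id
#'   vectors covering exactly the same genes.
#' @return List: `ari` (adjusted Rand index over the two gene partitions),
#'   `precision` and `recall` of exactly recovered families (a predicted
#'   cluster counts when its gene set equals a true family's gene set),
#'   `n_true_families`, `n_predicted_families`.
#' @export
evaluate_clustering <- function(truth_labels, clusters) {
  pred_sets <- clustering_as_sets(clusters)
  pred_genes <- unlist(pred_sets, use.names = FALSE)
  if (anyDuplicated(pred_genes)) {
    stop("evaluate_clustering: gene in more than one cluster")
  }
  if (!setequal(pred_genes, names(truth_labels))) {
    stop("evaluate_clustering: clustering and truth cover different genes")
  }
  pred_labels <- rep(seq_along(pred_sets), lengths(pred_sets))
  names(pred_labels) <- pred_genes
  ari <- mclust::adjustedRandIndex(truth_labels,
                                   pred_labels[names(truth_labels)])
  true_sets <- split(names(truth_labels), truth_labels)
  canon <- function(sets) sort(vapply(sets, function(s)
    paste(sort(s), collapse = "\r"), ""))
  matches <- sum(canon(pred_sets) %in% canon(true_sets))
  list(ari = ari,
       precision = matches / length(pred_sets),
       recall = matches / length(true_sets),
       n_true_families = length(true_sets),
       n_predicted_families = length(pred_sets))
}

clustering_as_sets <- function(clusters) {
  if (inherits(clusters, "cluster_set")) return(clusters$clusters)
  if (is.data.frame(clusters)) {
    return(unname(split(clusters$gene_id, clusters$family_id)))
  }
  if (is.list(clusters)) return(clusters)
  stop("evaluate_clustering: unsupported clustering object")
}

#' Score expansion-pattern recovery against simulation truth
#'
#' Matches predicted tandem runs and duplicated blocks against the
#' simulator's ground truth.  A predicted tandem run matches a true run on
#' the same genome and replicon when the locus-interval overlap covers at
#' least `overlap_threshold` of both intervals; a predicted block matches a
#' true block of the same genome when the Jaccard index of their gene sets
#' (template plus copy vs. both intervals) is at least the threshold.
#' Matching is one-to-one and greedy in table order.
#'
#' @param truth `truth` element of [simulate_genomes()].
#' @param runs Predicted tandem run table ([find_tandem_runs()]).
#' @param blocks Predicted block table ([find_dup_blocks()]).
#' @param genes Gene table (to resolve block intervals to gene ids).
#' @param overlap_threshold Fraction in (0, 1].
#' @return List with per-type `precision`, `recall`, counts, and a
#'   `zero_prediction` flag per type (precision is reported as 1.0 when
#'   there are no predictions).  Tandem precision is judged against every
#'   true adjacency array (`truth$tandem_all`) while recall covers the
#'   lineage-specific arrays (`truth$tandem`) only, since ancestral arrays
#'   shared across genomes are legitimately split by the orthogroup rules.
#' @export
evaluate_expansions <- function(truth, runs, blocks, genes,
                                overlap_threshold = 0.5) {
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1)
  run_res <- match_runs(truth$tandem, runs, overlap_threshold,
                        all_true_runs = truth$tandem_all)
  blk_res <- match_blocks(truth$blocks, blocks, genes, overlap_threshold)
  list(tandem = run_res, block = blk_res)
}

# precision is judged against every true array (`all_true_runs`, when the
# truth distinguishes ancestral from lineage-specific arrays); recall is
# over the lineage-specific set `true_runs` only
match_runs <- function(true_runs, pred_runs, t, all_true_runs = NULL) {
  if (is.null(all_true_runs)) all_true_runs <- true_runs
  n_true <- nrow(all_true_runs)
  n_pred <- nrow(pred_runs)
  matched_true <- logical(n_true)
  matched_pred <- logical(n_pred)
  for (i in seq_len(n_pred)) {
    for (j in seq_len(n_true)) {
      if (matched_true[j]) next
      if (pred_runs$genome_id[i] != all_true_runs$genome_id[j] ||
          pred_runs$replicon_id[i] != all_true_runs$replicon_id[j]) next
      ov <- min(pred_runs$end_locus[i], all_true_runs$end_locus[j]) -
        max(pred_runs$start_locus[i], all_true_runs$start_locus[j]) + 1L
      if (ov <= 0) next
      len_p <- pred_runs$end_locus[i] - pred_runs$start_locus[i] + 1L
      len_t <- all_true_runs$end_locus[j] - all_true_runs$start_locus[j] +
        1L
      if (ov / len_p >= t && ov / len_t >= t) {
        matched_true[j] <- TRUE
        matched_pred[i] <- TRUE
        break
      }
    }
  }
  key <- function(df) paste(df$genome_id, df$replicon_id, df$start_locus,
                            df$end_locus)
  recall_idx <- key(all_true_runs) %in% key(true_runs)
  score_matching(matched_pred, matched_true[recall_idx])
}

match_blocks <- function(true_blocks, pred_blocks, genes, t) {
  n_true <- length(true_blocks)
  n_pred <- nrow(pred_blocks)
  pred_sets <- lapply(seq_len(n_pred), function(i)
    block_gene_set(pred_blocks[i, ], genes))
  true_sets <- lapply(true_blocks, function(b) c(b$template, b$copy))
  matched_true <- logical(n_true)
  matched_pred <- logical(n_pred)
  for (i in seq_len(n_pred)) {
    for (j in seq_len(n_true)) {
      if (matched_true[j]) next
      if (pred_blocks$genome_id[i] != true_blocks[[j]]$genome_id) next
      jac <- length(intersect(pred_sets[[i]], true_sets[[j]])) /
        length(union(pred_sets[[i]], true_sets[[j]]))
      if (jac >= t) {
        matched_true[j] <- TRUE
        matched_pred[i] <- TRUE
        break
      }
    }
  }
  score_matching(matched_pred, matched_true)
}

block_gene_set <- function(block, genes) {
  pick <- function(rep_id, lo, hi) {
    genes$gene_id[genes$replicon_id == rep_id &
                  genes$locus_index >= lo & genes$locus_index <= hi]
  }
  unique(c(pick(block$replicon_a, block$a_start, block$a_end),
           pick(block$replicon_b, block$b_start, block$b_end)))
}

score_matching <- function(matched_pred, matched_true) {
  n_pred <- length(matched_pred)
  n_true <- length(matched_true)
  list(precision = if (n_pred == 0) 1.0 else mean(matched_pred),
       recall = if (n_true == 0) 1.0 else mean(matched_true),
       n_predicted = n_pred, n_true = n_true,
       zero_prediction = n_pred == 0)
}
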