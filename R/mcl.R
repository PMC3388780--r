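#' Markov clustering of a similarity graph
#'
#' From-scratch sparse implementation of the MCL algorithm.  A
#' column-stochastic matrix is built from the graph's normalized edge
#' weights with per-node self-loops, then expansion (matrix squaring) and
#' inflation (entry-wise power followed by column renormalization) alternate
#' until the matrix stops changing.  Clusters are read off the attractor
#' structure of the converged matrix.
#'
#' @param graph A `similarity_graph` from [build_graph()], or any list with
#'   an `edges` data frame (`gene_a`, `gene_b`, `norm_weight`) and a `nodes`
#'   character vector.  Isolated nodes (in `nodes` but in no edge) come out
#'   as singleton clusters.
#' @param inflation Inflation exponent, >= 1.  Larger values give tighter,
#'   smaller clusters.
#' @param prune Entries below this value are zeroed after each inflation
#'   step (columns are then renormalized).
#' @param tol Convergence tolerance on the largest entry change per
#'   iteration.
#' @param max_iter Iteration cap; hitting it sets `converged = FALSE` on the
#'   result rather than failing.
#' @param nodes Optional explicit node universe (superset of the graph's
#'   nodes); extra ids become singletons.
#' @return A `cluster_set`: list with `clusters` (list of gene-id character
#'   vectors, sorted by decreasing size then first member), `parameters`,
#'   `converged`, `iterations` and `max_colsum_dev` (largest deviation of
#'   any column sum from 1 observed after an inflation step).
#' @details Self-loop weight is each node's maximum incident normalized
#'   weight (1 for isolated nodes).  Attractors are nodes with positive
#'   converged diagonal; attractor systems are connected components of the
#'   attractor-attractor support, and every other node joins the system of
#'   its highest-weight attractor (ties: the system containing the
#'   lexicographically smallest attractor id).
#' @export
mcl_cluster <- function(graph, inflation = 1.5, prune = 1e-5, tol = 1e-8,
                        max_iter = 100L, nodes = NULL) {
  stopifnot(inflation >= 1)
  edges <- graph$edges
  all_nodes <- sort(unique(c(graph$nodes, nodes,
                             edges$gene_a, edges$gene_b)))
  n <- length(all_nodes)
  if (n == 0) {
    return(new_cluster_set(list(), inflation, TRUE, 0L, 0))
  }
  if (nrow(edges) && any(edges$norm_weight < 0)) {
    stop("mcl_cluster: negative edge weight")
  }
  i <- match(edges$gene_a, all_nodes)
  j <- match(edges$gene_b, all_nodes)
  if (any(i == j)) stop("mcl_cluster: self-edge in input graph")
  w <- edges$norm_weight
  # symmetric adjacency with self-loops = max incident weight (1 if isolated)
  loop <- rep(1, n)
  if (length(w)) {
    mx <- tapply(c(w, w), c(i, j), max)
    loop[as.integer(names(mx))] <- mx
  }
  M <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)),
                            j = c(j, i, seq_len(n)),
                            x = c(w, w, loop), dims = c(n, n))
  M <- col_normalize(M)

  converged <- FALSE
  iter <- 0L
  max_dev <- 0
  while (iter < max_iter) {
    iter <- iter + 1L
    M_old <- M
    M <- M %*% M                      # expansion
    M <- inflate(M, inflation, prune) # inflation + prune + renormalize
    max_dev <- max(max_dev, max(abs(Matrix::colSums(M) - 1)))
    delta <- max(abs(M - M_old))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("mcl_cluster: no convergence after ", max_iter, " iterations")
  }
  clusters <- interpret_attractors(M, all_nodes, prune)
  new_cluster_set(clusters, inflation, converged, iter, max_dev)
}

col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

inflate <- function(M, inflation, prune) {
  M <- methods::as(M, "CsparseMatrix")
  M@x <- M@x^inflation
  M <- Matrix::drop0(M)
  if (length(M@x)) M@x[M@x < prune] <- 0
  M <- Matrix::drop0(M)
  col_normalize(M)
}

# Read clusters from the converged matrix.  M[i, j] > 0 means j flows to i.
interpret_attractors <- function(M, node_names, eps) {
  n <- length(node_names)
  d <- Matrix::diag(M)
  attractors <- which(d > eps)
  if (!length(attractors)) {
    # degenerate (should not happen with self-loops); everything by support
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      (M + Matrix::t(M)) > 0, mode = "undirected"))$membership
    return(split(node_names, comp))
  }
  # attractor systems: components of attractor-attractor support
  sub <- M[attractors, attractors, drop = FALSE]
  adj <- (sub + Matrix::t(sub)) > 0
  sys <- igraph::components(igraph::graph_from_adjacency_matrix(
    adj, mode = "undirected"))$membership
  # system label: lexicographically smallest member id, for deterministic ties
  sys_label <- tapply(node_names[attractors], sys, min)
  membership <- rep(NA_integer_, n)
  membership[attractors] <- sys
  others <- setdiff(seq_len(n), attractors)
  if (length(others)) {
    sub2 <- M[attractors, others, drop = FALSE]
    for (k in seq_along(others)) {
      col <- sub2[, k]
      pos <- which(col > eps)
      if (!length(pos)) pos <- which.max(col)
      cand_sys <- unique(sys[pos])
      if (length(cand_sys) == 1L) {
        membership[others[k]] <- cand_sys
      } else {
        # overlap: highest attraction weight wins, ties by smallest label
        wbest <- vapply(cand_sys, function(s) max(col[pos[sys[pos] == s]]),
                        0)
        best <- cand_sys[wbest == max(wbest)]
        membership[others[k]] <-
          best[order(sys_label[as.character(best)])][1]
      }
    }
  }
  out <- split(node_names, membership)
  lapply(unname(out), sort)
}

new_cluster_set <- function(clusters, inflation, converged, iterations,
                            max_dev, evalue_cutoff = NA_real_) {
  clusters <- lapply(clusters, sort)
  first <- vapply(clusters, function(x) if (length(x)) x[1] else "", "")
  ord <- order(-lengths(clusters), first)
  cs <- list(clusters = clusters[ord],
             parameters = list(evalue_cutoff = evalue_cutoff,
                               inflation = inflation),
             converged = converged, iterations = iterations,
             max_colsum_dev = max_dev)
  class(cs) <- "cluster_set"
  cs
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("cluster_set:", length(sizes), "clusters (",
      sum(sizes >= 2), "of size >= 2 ),", sum(sizes), "genes\n")
  invisible(x)
}

#' Number of multi-member groups in a clustering
#'
#' @param clusters A `cluster_set`.
#' @return Count of clusters with at least 2 members; singletons are
#'   reported separately throughout the package.
#' @export
n_groups <- function(clusters) {
  sum(lengths(clusters$clusters) >= 2)
}

#' E-value by inflation parameter sweep
#'
#' Rebuilds the homology graph at each E-value cutoff, clusters at each
#' inflation value, and reports the number of multi-member groups per grid
#' point.
#'
#' @param hits Directed hit table covering the loosest cutoff requested.
#' @param genome_of Named gene-to-genome mapping.
#' @param evalues Vector of E-value cutoffs (default: the 12-point ladder
#'   10, 1, 0.1, ..., 1e-10).
#' @param inflations Vector of inflation values (default 1.0, 1.5, 2.0).
#' @param ... Passed to [mcl_cluster()].
#' @return A `sweep_result`: list with `grid` (`data.frame`: `evalue_cutoff`,
#'   `inflation`, `n_groups`, `n_singletons`) and `matrix` (E-value by
#'   inflation group-count matrix).
#' @export
mcl_sweep <- function(hits, genome_of,
                      evalues = default_evalue_grid(),
                      inflations = c(1.0, 1.5, 2.0), ...) {
  stopifnot(length(evalues) > 0, length(inflations) > 0)
  rows <- list()
  for (ev in sort(evalues, decreasing = TRUE)) {
    graph <- hits_to_graph(hits, genome_of, cutoff = ev)
    for (inf in inflations) {
      cl <- mcl_cluster(graph, inflation = inf, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        evalue_cutoff = ev, inflation = inf,
        n_groups = n_groups(cl),
        n_singletons = sum(lengths(cl$clusters) == 1L))
    }
  }
  grid <- do.call(rbind, rows)
  mat <- matrix(grid$n_groups, nrow = length(evalues), byrow = TRUE,
                dimnames = list(format(sort(evalues, decreasing = TRUE)),
                                format(inflations)))
  structure(list(grid = grid, matrix = mat), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("MCL parameter sweep (groups of size >= 2):\n")
  print(x$matrix)
  cat("range:", min(x$matrix), "-", max(x$matrix), "\n")
  invisible(x)
}

#' The 12-point E-value cutoff ladder
#'
#' @return `c(10, 1, 0.1, 0.01, 1e-3, ..., 1e-10)`.
#' @export
default_evalue_grid <- function() {
  c(10, 1, 0.1, 0.01, 1e-3, 1e-4, 1e-5, 1e-6, 1e-7, 1e-8, 1e-9, 1e-10)
}

#' Build the typed homology graph directly from hits
#'
#' Convenience wrapper running [find_orthologs()], [find_inparalogs()],
#' [find_coorthologs()] and [build_graph()] at one cutoff.
#'
#' @inheritParams find_orthologs
#' @return A `similarity_graph`.
#' @export
hits_to_graph <- function(hits, genome_of, cutoff = 1e-5) {
  hits <- hits[hits$evalue <= cutoff, , drop = FALSE]
  ort <- find_orthologs(hits, genome_of, cutoff)
  inp <- find_inparalogs(hits, genome_of, cutoff)
  coo <- find_coorthologs(hits, genome_of, ort, inp, cutoff)
  g <- build_graph(hits, genome_of, ort, inp, coo)
  g$parameters <- list(evalue_cutoff = cutoff)
  g
}
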