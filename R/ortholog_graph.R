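#' Reciprocal-best ortholog pairs
#'
#' Identifies putative ortholog pairs between genomes from directed
#' similarity hits: `(a, b)` with `genome(a) != genome(b)` is an ortholog
#' pair iff `b` is among `a`'s best hits in `genome(b)` and `a` is among
#' `b`'s best hits in `genome(a)`.  "Best" means minimal E-value within the
#' target genome; co-best ties (E-values equal to 15 significant digits) are
#' all kept.
#'
#' @param hits Hit table (see [read_blast_tab()]), pre-filtered or not; rows
#'   with `evalue > cutoff` are ignored.
#' @param genome_of Named character vector mapping gene id to genome id.
#' @param cutoff E-value cutoff.
#' @return `data.frame` with columns `gene_a`, `gene_b` (unordered pairs,
#'   stored with `gene_a < gene_b`).
#' @export
find_orthologs <- function(hits, genome_of, cutoff = 1e-5) {
  hits <- filter_hits(hits, genome_of, cutoff)
  if (!nrow(hits)) return(empty_pairs())
  inter <- hits[hits$q_genome != hits$s_genome, , drop = FALSE]
  if (!nrow(inter)) return(empty_pairs())
  best <- best_hits_per_target_genome(inter)
  key <- paste(best$query_id, best$subject_id, sep = "\r")
  rkey <- paste(best$subject_id, best$query_id, sep = "\r")
  recip <- key[key %in% rkey]
  if (!length(recip)) return(empty_pairs())
  parts <- do.call(rbind, strsplit(recip, "\r", fixed = TRUE))
  canonical_pairs(parts[, 1], parts[, 2])
}

# rows that are (co-)best per (query, target genome): minimal evalue,
# equality judged at 15 significant digits
best_hits_per_target_genome <- function(hits) {
  grp <- paste(hits$query_id, hits$s_genome, sep = "\r")
  ev <- signif(hits$evalue, 15)
  best_ev <- stats::ave(ev, grp, FUN = min)
  hits[ev == best_ev, , drop = FALSE]
}

#' In-paralog pairs
#'
#' A within-genome pair `(a, a')` is called an in-paralog pair iff both
#' directed E-values are at or below `cutoff` and strictly smaller than the
#' worst (largest) E-value of any inter-genome hit of `a` or `a'` at the
#' cutoff.  Genes with no inter-genome hits use +Inf, so any mutual
#' within-genome hit qualifies for them.
#'
#' @inheritParams find_orthologs
#' @return Unordered pair table (`gene_a`, `gene_b`).
#' @export
find_inparalogs <- function(hits, genome_of, cutoff = 1e-5) {
  hits <- filter_hits(hits, genome_of, cutoff)
  if (!nrow(hits)) return(empty_pairs())
  intra <- hits[hits$q_genome == hits$s_genome &
                hits$query_id != hits$subject_id, , drop = FALSE]
  if (!nrow(intra)) return(empty_pairs())
  inter <- hits[hits$q_genome != hits$s_genome, , drop = FALSE]
  worst_inter <- tapply(inter$evalue, inter$query_id, max)
  thr <- function(g) {
    v <- worst_inter[g]
    ifelse(is.na(v), Inf, v)
  }
  key <- paste(intra$query_id, intra$subject_id, sep = "\r")
  rev_key <- paste(intra$subject_id, intra$query_id, sep = "\r")
  ev_rev <- intra$evalue[match(key, rev_key)]
  mutual <- !is.na(ev_rev)
  ok <- mutual &
    intra$evalue < pmin(thr(intra$query_id), thr(intra$subject_id)) &
    ev_rev < pmin(thr(intra$query_id), thr(intra$subject_id))
  cand <- intra[ok, , drop = FALSE]
  canonical_pairs(cand$query_id, cand$subject_id)
}

#' Co-ortholog pairs
#'
#' An inter-genome pair `(a, b)` that is not already an ortholog pair is a
#' co-ortholog pair iff `a` is linked by in-paralogy to some `a'` with
#' `(a', b)` orthologs (or symmetrically for `b`), and both directed hits
#' between `a` and `b` exist at the cutoff.
#'
#' @inheritParams find_orthologs
#' @param ortholog_pairs,inparalog_pairs Pair tables from
#'   [find_orthologs()] / [find_inparalogs()].
#' @return Unordered pair table (`gene_a`, `gene_b`).
#' @export
find_coorthologs <- function(hits, genome_of, ortholog_pairs,
                             inparalog_pairs, cutoff = 1e-5) {
  if (!nrow(inparalog_pairs) || !nrow(ortholog_pairs)) return(empty_pairs())
  hits <- filter_hits(hits, genome_of, cutoff)
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  has_both <- function(a, b) {
    paste(a, b, sep = "\r") %in% key & paste(b, a, sep = "\r") %in% key
  }
  # adjacency: in-paralog partners per gene, ortholog partners per gene
  inp <- rbind(setNames(inparalog_pairs, c("x", "y")),
               setNames(inparalog_pairs[2:1], c("x", "y")))
  ort <- rbind(setNames(ortholog_pairs, c("x", "y")),
               setNames(ortholog_pairs[2:1], c("x", "y")))
  # candidate (a, b): a in-paralog of a', a' ortholog of b
  cand <- merge(inp, ort, by.x = "y", by.y = "x")
  if (!nrow(cand)) return(empty_pairs())
  a <- cand$x
  b <- cand$y.y
  keep <- genome_of[a] != genome_of[b] & has_both(a, b)
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(empty_pairs())
  pairs <- canonical_pairs(a, b)
  okey <- paste(ortholog_pairs$gene_a, ortholog_pairs$gene_b, sep = "\r")
  pairs[!paste(pairs$gene_a, pairs$gene_b, sep = "\r") %in% okey, ,
        drop = FALSE]
}

#' Build the typed, weight-normalized homology graph
#'
#' Assembles ortholog, in-paralog and co-ortholog pairs into an undirected
#' weighted graph.  Each edge's `raw_weight` is the average of
#' `-log10(evalue)` over the two hit directions (E-value 0 capped at 316);
#' `norm_weight` divides the raw weight by the mean raw weight of same-type
#' edges for that genome pair (the genome itself for in-paralog edges), so
#' every non-empty (genome pair, type) class has mean normalized weight 1.
#'
#' @inheritParams find_coorthologs
#' @param coortholog_pairs Pair table from [find_coorthologs()].
#' @return A `similarity_graph`: list with `edges` (`data.frame`: `gene_a`,
#'   `gene_b`, `type`, `raw_weight`, `norm_weight`) and `nodes` (all gene
#'   ids seen in the edge set).
#' @export
build_graph <- function(hits, genome_of, ortholog_pairs, inparalog_pairs,
                        coortholog_pairs = empty_pairs()) {
  edges <- rbind(
    cbind(ortholog_pairs, type = rep("ortholog", nrow(ortholog_pairs))),
    cbind(inparalog_pairs, type = rep("inparalog", nrow(inparalog_pairs))),
    cbind(coortholog_pairs, type = rep("coortholog", nrow(coortholog_pairs)))
  )
  if (!nrow(edges)) {
    g <- list(edges = data.frame(gene_a = character(0), gene_b = character(0),
                                 type = character(0), raw_weight = numeric(0),
                                 norm_weight = numeric(0)),
              nodes = character(0))
    class(g) <- "similarity_graph"
    return(g)
  }
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  ev <- function(a, b) hits$evalue[match(paste(a, b, sep = "\r"), key)]
  e_ab <- ev(edges$gene_a, edges$gene_b)
  e_ba <- ev(edges$gene_b, edges$gene_a)
  if (anyNA(e_ab) || anyNA(e_ba)) {
    stop("build_graph: pair without both directed hits")
  }
  # -log10 evalue, capped at 316 for E = 0 and floored just above 0 so
  # edges admitted at loose cutoffs (E > 1) keep a positive weight
  nlog <- function(e) ifelse(e <= 0, 316,
                             pmin(pmax(-log10(e), 1e-3), 316))
  edges$raw_weight <- (nlog(e_ab) + nlog(e_ba)) / 2
  ga <- genome_of[edges$gene_a]
  gb <- genome_of[edges$gene_b]
  gp <- ifelse(ga < gb, paste(ga, gb, sep = "|"), paste(gb, ga, sep = "|"))
  cls <- paste(gp, edges$type, sep = "|")
  edges$norm_weight <- edges$raw_weight /
    stats::ave(edges$raw_weight, cls, FUN = mean)
  rownames(edges) <- NULL
  g <- list(edges = edges,
            nodes = sort(unique(c(edges$gene_a, edges$gene_b))))
  class(g) <- "similarity_graph"
  g
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  if (nrow(x$edges)) print(table(x$edges$type))
  invisible(x)
}

#' Export a similarity graph
#'
#' @param graph A `similarity_graph`.
#' @param path Output path.
#' @param format `"tsv"` for the five-column edge list, `"abc"` for MCL
#'   label input (`gene_a gene_b norm_weight`).
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("tsv", "abc")) {
  format <- match.arg(format)
  e <- graph$edges
  if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(e[c("gene_a", "gene_b", "norm_weight")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

filter_hits <- function(hits, genome_of, cutoff) {
  genes <- unique(c(hits$query_id, hits$subject_id))
  unknown <- genes[!genes %in% names(genome_of)]
  if (length(unknown)) {
    stop("gene with unknown genome: ", unknown[1])
  }
  hits <- hits[hits$evalue <= cutoff, , drop = FALSE]
  hits$q_genome <- unname(genome_of[hits$query_id])
  hits$s_genome <- unname(genome_of[hits$subject_id])
  hits
}

empty_pairs <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             stringsAsFactors = FALSE)
}

canonical_pairs <- function(a, b) {
  ga <- pmin(a, b)
  gb <- pmax(a, b)
  df <- unique(data.frame(gene_a = ga, gene_b = gb,
                          stringsAsFactors = FALSE))
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}
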