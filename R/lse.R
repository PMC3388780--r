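#' Classify lineage-specific expansions
#'
#' Every (family, genome) cell of the copy matrix with count >= 2 is an LSE
#' call: *lineage-unique* when the family occurs in that genome only,
#' *typical* when at least one other genome carries the family.
#'
#' @param copies Copy matrix from [copy_matrix()].
#' @param partition Matching `pan_partition`.
#' @param genome_sizes Named vector of total gene counts per genome, for the
#'   percentage column of the summary.
#' @return List with `calls` (`data.frame`: `family_id`, `genome_id`,
#'   `lse_type`, `copies`) and `summary` (per genome: lineage-unique family
#'   and gene counts, typical family count, total LSE gene count, and
#'   `pct_lse` = 100 x total LSE genes / genome genes).
#' @export
classify_lse <- function(copies, partition, genome_sizes = NULL) {
  stopifnot(identical(colnames(copies), partition$table$family_id))
  present <- colSums(copies >= 1)
  idx <- which(copies >= 2, arr.ind = TRUE)
  calls <- if (nrow(idx)) {
    data.frame(
      family_id = colnames(copies)[idx[, 2]],
      genome_id = rownames(copies)[idx[, 1]],
      lse_type = ifelse(present[idx[, 2]] == 1, "lineage-unique", "typical"),
      copies = copies[idx],
      stringsAsFactors = FALSE)
  } else empty_lse_calls()
  calls <- calls[order(calls$family_id, calls$genome_id), , drop = FALSE]
  rownames(calls) <- NULL

  genomes <- rownames(copies)
  summ <- data.frame(genome_id = genomes, stringsAsFactors = FALSE)
  per <- function(f) vapply(genomes, f, 0)
  summ$lineage_unique_families <- per(function(g)
    sum(calls$genome_id == g & calls$lse_type == "lineage-unique"))
  summ$lineage_unique_genes <- per(function(g)
    sum(calls$copies[calls$genome_id == g &
                     calls$lse_type == "lineage-unique"]))
  summ$typical_families <- per(function(g)
    sum(calls$genome_id == g & calls$lse_type == "typical"))
  summ$lse_genes <- per(function(g) sum(calls$copies[calls$genome_id == g]))
  if (!is.null(genome_sizes)) {
    summ$pct_lse <- round(100 * summ$lse_genes /
                          as.numeric(genome_sizes[genomes]), 2)
  }
  rownames(summ) <- NULL
  list(calls = calls, summary = summ)
}

empty_lse_calls <- function() {
  data.frame(family_id = character(0), genome_id = character(0),
             lse_type = character(0), copies = integer(0),
             stringsAsFactors = FALSE)
}

#' LSE family-size distribution
#'
#' Histogram of LSE family copy numbers per genome and LSE type, binned at
#' 2, 3, ..., 10 and ">=11", together with the fraction of two-copy
#' families.
#'
#' @param calls LSE call table from [classify_lse()].
#' @return List with `histogram` (`data.frame`: `genome_id`, `lse_type`,
#'   `bin`, `n_families`) and `two_copy_fraction` (named per-genome vector).
#' @export
lse_size_distribution <- function(calls) {
  bins <- c(as.character(2:10), ">=11")
  if (!nrow(calls)) {
    return(list(histogram = data.frame(genome_id = character(0),
                                       lse_type = character(0),
                                       bin = character(0),
                                       n_families = integer(0)),
                two_copy_fraction = numeric(0)))
  }
  bin_of <- ifelse(calls$copies >= 11, ">=11", as.character(calls$copies))
  grid <- expand.grid(genome_id = sort(unique(calls$genome_id)),
                      lse_type = sort(unique(calls$lse_type)),
                      bin = bins, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  counts <- table(paste(calls$genome_id, calls$lse_type, bin_of))
  grid$n_families <- as.integer(
    counts[paste(grid$genome_id, grid$lse_type, grid$bin)])
  grid$n_families[is.na(grid$n_families)] <- 0L
  two_copy <- vapply(sort(unique(calls$genome_id)), function(g) {
    gc <- calls$copies[calls$genome_id == g]
    sum(gc == 2) / length(gc)
  }, 0)
  list(histogram = grid, two_copy_fraction = two_copy)
}

#' Find tandem arrays (contiguous single-gene expansions)
#'
#' Maximal runs of >= 2 consecutive loci on one replicon whose genes all
#' belong to the same family.  Strand is ignored.
#'
#' @param genes Gene table (see [read_gene_table()]); `locus_index` must be
#'   consecutive within each replicon.
#' @param family_of Named gene-to-family mapping; genes missing from it
#'   never extend a run.
#' @return `data.frame`: `family_id`, `genome_id`, `replicon_id`,
#'   `start_locus`, `end_locus`, `length`, `gene_ids` (comma-separated, in
#'   locus order).
#' @export
find_tandem_runs <- function(genes, family_of) {
  out <- list()
  for (rep_id in sort(unique(genes$replicon_id))) {
    g <- genes[genes$replicon_id == rep_id, , drop = FALSE]
    g <- g[order(g$locus_index), , drop = FALSE]
    fam <- unname(family_of[g$gene_id])
    if (anyNA(fam)) fam[is.na(fam)] <- paste0(".orphan", which(is.na(fam)))
    r <- rle(fam)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$lengths >= 2L)
    for (k in keep) {
      loci <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        family_id = r$values[k],
        genome_id = g$genome_id[starts[k]],
        replicon_id = rep_id,
        start_locus = g$locus_index[starts[k]],
        end_locus = g$locus_index[ends[k]],
        length = r$lengths[k],
        gene_ids = paste(g$gene_id[loci], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_tandem_runs())
  res <- do.call(rbind, out)
  res <- res[order(res$genome_id, res$replicon_id, res$start_locus), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_tandem_runs <- function() {
  data.frame(family_id = character(0), genome_id = character(0),
             replicon_id = character(0), start_locus = integer(0),
             end_locus = integer(0), length = integer(0),
             gene_ids = character(0), stringsAsFactors = FALSE)
}

#' Find duplicated blocks within genomes
#'
#' Detects pairs of chromosomal intervals within one genome whose gene
#' orders match through same-family anchor pairs, in forward or inverted
#' orientation, allowing up to `max_gap` interleaved non-anchor genes
#' between consecutive anchors on each side.
#'
#' @param genes Gene table.
#' @param family_of Named gene-to-family mapping.
#' @param max_gap Maximum interleaved genes between consecutive anchors on
#'   either side of the chain.
#' @param min_anchors Minimum anchors per reported block.
#' @return `data.frame` with one row per block: `genome_id`, `replicon_a`,
#'   `a_start`, `a_end`, `replicon_b`, `b_start`, `b_end` (locus ranges,
#'   0-based inclusive), `orientation` (`forward`/`inverted`), `n_anchors`,
#'   `gaps` (interleaved non-anchor genes, both intervals combined),
#'   `anchors` (`;`-separated `geneA|geneB` pairs in chain order) and
#'   `terminal_flag` (`NA` until [flag_terminal()] is applied).
#' @details Anchors are within-genome gene pairs sharing a family; the two
#'   intervals of a block never overlap.  Chains are scored by anchor count
#'   and extracted greedily in descending score (ties: leftmost first
#'   interval, then leftmost second interval, forward before inverted); each
#'   gene is used by at most one extracted chain.  Chains that merely
#'   re-describe one tandem array (all anchors from one family and the whole
#'   span inside a single run) are suppressed — those are reported by
#'   [find_tandem_runs()].
#' @export
find_dup_blocks <- function(genes, family_of, max_gap = 3L,
                            min_anchors = 2L) {
  stopifnot(max_gap >= 0, min_anchors >= 2)
  out <- list()
  for (gen in sort(unique(genes$genome_id))) {
    g <- genes[genes$genome_id == gen, , drop = FALSE]
    out[[gen]] <- dup_blocks_one_genome(g, family_of, max_gap, min_anchors)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(empty_dup_blocks())
  rownames(res) <- NULL
  res
}

empty_dup_blocks <- function() {
  data.frame(genome_id = character(0), replicon_a = character(0),
             a_start = integer(0), a_end = integer(0),
             replicon_b = character(0), b_start = integer(0),
             b_end = integer(0), orientation = character(0),
             n_anchors = integer(0), gaps = integer(0),
             anchors = character(0), terminal_flag = logical(0),
             stringsAsFactors = FALSE)
}

dup_blocks_one_genome <- function(g, family_of, max_gap, min_anchors) {
  g <- g[order(g$replicon_id, g$locus_index), , drop = FALSE]
  anchors <- family_anchor_pairs(g, unname(family_of[g$gene_id]))
  if (!nrow(anchors)) return(empty_dup_blocks())
  runs <- find_tandem_runs(g, family_of)
  used <- character(0)
  blocks <- list()
  repeat {
    act <- !(anchors$a_gene %in% used) & !(anchors$b_gene %in% used)
    cand <- anchors[act, , drop = FALSE]
    if (nrow(cand) == 0L) break
    best <- best_chain(cand, max_gap)
    if (is.null(best) || nrow(best$chain) < min_anchors) break
    used <- c(used, best$chain$a_gene, best$chain$b_gene)
    if (!chain_is_tandem_echo(best$chain, runs)) {
      blocks[[length(blocks) + 1L]] <- chain_to_block(best, g)
    }
  }
  if (!length(blocks)) return(empty_dup_blocks())
  do.call(rbind, blocks)
}

# All within-genome same-family gene pairs as candidate anchors, the earlier
# gene (replicon, locus order) on the "a" side; sorted by first interval.
family_anchor_pairs <- function(g, fam) {
  ok <- which(!is.na(fam))
  idx <- split(ok, fam[ok])
  idx <- idx[lengths(idx) >= 2]
  if (!length(idx)) {
    return(data.frame(a_gene = character(0), b_gene = character(0),
                      family_id = character(0), a_rep = character(0),
                      b_rep = character(0), a_loc = integer(0),
                      b_loc = integer(0), stringsAsFactors = FALSE))
  }
  per_fam <- lapply(names(idx), function(f) {
    p <- utils::combn(idx[[f]], 2)
    data.frame(i = p[1, ], j = p[2, ], family_id = f,
               stringsAsFactors = FALSE)
  })
  pr <- do.call(rbind, per_fam)
  i <- pr$i; j <- pr$j
  swap <- (g$replicon_id[i] > g$replicon_id[j]) |
    (g$replicon_id[i] == g$replicon_id[j] &
     g$locus_index[i] > g$locus_index[j])
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  df <- data.frame(a_gene = g$gene_id[i], b_gene = g$gene_id[j],
                   family_id = pr$family_id,
                   a_rep = g$replicon_id[i], b_rep = g$replicon_id[j],
                   a_loc = g$locus_index[i], b_loc = g$locus_index[j],
                   stringsAsFactors = FALSE)
  df <- df[order(df$a_rep, df$a_loc, df$b_rep, df$b_loc), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Chains are compared by (anchor count descending, then the anchor index
# sequence lexicographically, indices in the sorted-anchor order, then
# forward before inverted).  Anchors are sorted by (a_rep, a_loc, b_rep,
# b_loc), so "earlier index sequence" realizes the leftmost-first-interval
# tie rule.  The exhaustive test oracle uses the identical comparator.
best_chain <- function(anchors, max_gap) {
  best <- NULL
  for (orient in c("forward", "inverted")) {
    res <- best_chain_oriented(anchors, max_gap, orient)
    if (is.null(res)) next
    cand <- list(chain = anchors[res$path, , drop = FALSE],
                 orientation = orient, path_key = res$key,
                 size = length(res$path))
    if (is.null(best) || chain_beats(cand, best)) best <- cand
  }
  best
}

chain_beats <- function(x, y) {
  if (x$size != y$size) return(x$size > y$size)
  if (x$path_key != y$path_key) return(x$path_key < y$path_key)
  x$orientation == "forward" && y$orientation == "inverted"
}

# Chains must keep the two intervals disjoint.  With anchors ordered a-side
# ascending: inverted chains (b descending) are always valid, because every
# same-replicon anchor has a_loc < b_loc by construction and the interval
# gap closes at the last anchor.  A forward chain is valid iff
# max(a_loc) < b_loc of its first anchor, so validity depends on the start:
# first try the unconstrained optimum (exact whenever it is valid, since
# restricting to valid chains can only do worse), then fall back to one
# constrained pass per start anchor, which covers every valid chain exactly.
best_chain_oriented <- function(anchors, max_gap, orient) {
  preds <- step_predecessors(anchors, max_gap, orient)
  res <- lex_longest_path(preds)
  if (is.null(res)) return(NULL)
  if (orient == "inverted" || forward_chain_valid(anchors, res$path)) {
    return(res)
  }
  n <- nrow(anchors)
  best <- NULL
  for (s in seq_len(n)) {
    adm <- anchors$a_rep != anchors$a_rep[s] |
      anchors$b_rep != anchors$b_rep[s] |
      anchors$a_loc < anchors$b_loc[s]
    adm[s] <- TRUE
    res_s <- lex_longest_path(preds, admissible = adm, start = s)
    if (is.null(res_s)) next
    if (is.null(best) || res_s$size > best$size ||
        (res_s$size == best$size && res_s$key < best$key)) {
      best <- res_s
    }
  }
  best
}

forward_chain_valid <- function(anchors, path) {
  ch <- anchors[path, , drop = FALSE]
  all(ch$a_rep != ch$b_rep) || max(ch$a_loc) < ch$b_loc[1]
}

# predecessor lists: preds[[k]] = indices p < k with a step p -> k allowed
# (same replicon pair, 0..max_gap interleaved genes on each side)
step_predecessors <- function(anchors, max_gap, orient) {
  n <- nrow(anchors)
  preds <- vector("list", n)
  if (n < 2) return(preds)
  for (k in seq_len(n)) {
    p <- seq_len(k - 1L)
    if (!length(p)) next
    ga <- anchors$a_loc[k] - anchors$a_loc[p] - 1L
    gb <- if (orient == "forward") {
      anchors$b_loc[k] - anchors$b_loc[p] - 1L
    } else {
      anchors$b_loc[p] - anchors$b_loc[k] - 1L
    }
    ok <- anchors$a_rep[p] == anchors$a_rep[k] &
      anchors$b_rep[p] == anchors$b_rep[k] &
      ga >= 0L & ga <= max_gap & gb >= 0L & gb <= max_gap
    preds[[k]] <- p[ok]
  }
  preds
}

# Longest path over the step DAG, tracking for every node the
# lexicographically smallest maximal-score index sequence (as a
# zero-padded string, so equal-score comparisons are positional).
lex_longest_path <- function(preds, admissible = NULL, start = NULL) {
  n <- length(preds)
  if (!n) return(NULL)
  score <- integer(n)
  key <- character(n)
  init <- if (is.null(start)) rep(TRUE, n) else seq_len(n) == start
  for (k in seq_len(n)) {
    if (!is.null(admissible) && !admissible[k]) next
    score[k] <- if (init[k]) 1L else 0L
    key[k] <- if (init[k]) sprintf("%06d", k) else ""
    for (p in preds[[k]]) {
      if (score[p] == 0L) next
      cand_score <- score[p] + 1L
      cand_key <- paste0(key[p], sprintf("%06d", k))
      if (cand_score > score[k] ||
          (cand_score == score[k] && cand_key < key[k])) {
        score[k] <- cand_score
        key[k] <- cand_key
      }
    }
  }
  if (max(score) == 0L) return(NULL)
  winners <- which(score == max(score))
  kbest <- winners[order(key[winners])][1]
  path <- as.integer(substring(key[kbest],
                               seq(1, nchar(key[kbest]), 6),
                               seq(6, nchar(key[kbest]), 6)))
  list(path = path, key = key[kbest], size = score[kbest])
}

chain_is_tandem_echo <- function(chain, runs) {
  fams <- unique(chain$family_id)
  if (length(fams) > 1L) return(FALSE)
  if (!all(chain$a_rep == chain$b_rep)) return(FALSE)
  lo <- min(chain$a_loc)
  hi <- max(chain$b_loc, chain$a_loc)
  any(runs$replicon_id == chain$a_rep[1] & runs$family_id == fams &
      runs$start_locus <= lo & runs$end_locus >= hi)
}

chain_to_block <- function(best, g) {
  chain <- best$chain
  data.frame(
    genome_id = g$genome_id[1],
    replicon_a = chain$a_rep[1],
    a_start = min(chain$a_loc), a_end = max(chain$a_loc),
    replicon_b = chain$b_rep[1],
    b_start = min(chain$b_loc), b_end = max(chain$b_loc),
    orientation = best$orientation,
    n_anchors = nrow(chain),
    gaps = (max(chain$a_loc) - min(chain$a_loc) + 1L - nrow(chain)) +
           (max(chain$b_loc) - min(chain$b_loc) + 1L - nrow(chain)),
    anchors = paste(paste(chain$a_gene, chain$b_gene, sep = "|"),
                    collapse = ";"),
    terminal_flag = NA,
    stringsAsFactors = FALSE)
}

#' Flag blocks in terminal chromosome regions
#'
#' Sets `terminal_flag` to `TRUE` for blocks with either interval lying
#' entirely within the first or last `terminal_fraction` of its replicon's
#' gene count (a proxy for the terminal inverted repeat regions of linear
#' chromosomes, where duplicated blocks accumulate).  Boundary-straddling
#' intervals are not flagged.
#'
#' @param blocks Block table from [find_dup_blocks()].
#' @param replicon_lengths Named vector: genes per replicon.
#' @param terminal_fraction Fraction of each replicon treated as terminal
#'   (0 < f < 0.5); window size is `floor(f * n)` loci at each end.
#' @return `blocks` with `terminal_flag` filled in.
#' @export
flag_terminal <- function(blocks, replicon_lengths, terminal_fraction = 0.1) {
  stopifnot(terminal_fraction > 0, terminal_fraction < 0.5)
  if (!nrow(blocks)) return(blocks)
  in_term <- function(rep_id, lo, hi) {
    n <- as.numeric(replicon_lengths[rep_id])
    w <- floor(terminal_fraction * n)
    (hi <= w - 1) | (lo >= n - w)
  }
  blocks$terminal_flag <-
    in_term(blocks$replicon_a, blocks$a_start, blocks$a_end) |
    in_term(blocks$replicon_b, blocks$b_start, blocks$b_end)
  blocks
}
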