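#' Smith-Waterman local alignment of two proteins
#'
#' Optimal local alignment with affine gap penalties, reported as the
#' statistics the downstream homology graph consumes.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param matrix Substitution matrix name (`"BLOSUM62"`, `"BLOSUM50"`, ...)
#'   or a numeric matrix in NCBI layout.
#' @param gap_open,gap_extend Gap opening / extension penalties (positive).
#' @param K,lambda Karlin-Altschul parameters used for the E-value estimate.
#' @return List with `score`, `pct_identity`, `aln_len`, `query_cov`
#'   (`aln_len / nchar(a)`) and `evalue`.
#' @details The score is symmetric in its arguments.  When no residue pair
#'   scores positive the optimal local alignment is empty: score 0,
#'   `aln_len` 0 and an E-value of `K * m * n`.  The E-value uses the raw
#'   Karlin-Altschul form on actual sequence lengths (see
#'   [estimate_evalue()]); it serves as a comparable ranking statistic, not a
#'   BLAST-calibrated significance.
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1, K = 0.041, lambda = 0.267) {
  if (!nzchar(a) || !nzchar(b)) stop("local_align: empty sequence")
  submat <- resolve_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  score <- Biostrings::score(pa)
  m <- nchar(a); n <- nchar(b)
  if (score <= 0) {
    return(list(score = 0, pct_identity = 0, aln_len = 0L, query_cov = 0,
                evalue = estimate_evalue(0, m, n, K, lambda)))
  }
  aln_len <- Biostrings::nchar(pa)
  n_ident <- Biostrings::nmatch(pa)
  list(score = score,
       pct_identity = 100 * n_ident / aln_len,
       aln_len = as.integer(aln_len),
       query_cov = aln_len / m,
       evalue = estimate_evalue(score, m, n, K, lambda))
}

resolve_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  get(data(list = matrix, package = "Biostrings",
           envir = environment()), envir = environment())
}

#' Karlin-Altschul E-value estimate
#'
#' \eqn{E = K m n e^{-\lambda S}} for a local alignment score \eqn{S} between
#' sequences of lengths \eqn{m} and \eqn{n}.
#'
#' @param score Alignment score (substitution-matrix units).
#' @param m,n Query and subject lengths (positive integers).
#' @param K,lambda Karlin-Altschul parameters (positive).
#' @return The E-value estimate, monotone decreasing in `score`.
#' @export
estimate_evalue <- function(score, m, n, K = 0.041, lambda = 0.267) {
  if (any(m <= 0) || any(n <= 0)) {
    stop("estimate_evalue: m and n must be positive")
  }
  if (any(K <= 0) || any(lambda <= 0)) {
    stop("estimate_evalue: K and lambda must be positive")
  }
  K * m * n * exp(-lambda * score)
}

#' All-versus-all protein similarity search
#'
#' Computes directed similarity hits among all proteins of a genome set with
#' the built-in Smith-Waterman aligner, in the shape of BLAST tabular input.
#' Intended for synthetic or toy data; at real scale, ingest external
#' aligner output with [read_blast_tab()] instead (a guard refuses more than
#' `max_sequences` proteins).
#'
#' @param proteins Named character vector of all protein sequences (names are
#'   gene ids, unique across genomes).
#' @param cutoff E-value cutoff; both directions of every pair with
#'   `evalue <= cutoff` are emitted.  Self-hits are excluded.
#' @param matrix,gap_open,gap_extend,K,lambda Passed to the aligner; see
#'   [local_align()].
#' @param prescreen If `TRUE` (default), only pairs sharing at least one
#'   exact `kmer`-mer are aligned.  Detectable homologs always share short
#'   exact words, so this prunes the quadratic pair set without losing them;
#'   set to `FALSE` for exhaustive alignment of every pair.
#' @param kmer Word size for the prescreen.
#' @param max_sequences Size guard for the quadratic stage.
#' @return Hit table as from [read_blast_tab()] (both directions per
#'   retained pair).
#' @export
all_vs_all <- function(proteins, cutoff = 1e-5, matrix = "BLOSUM62",
                       gap_open = 11, gap_extend = 1, K = 0.041,
                       lambda = 0.267, prescreen = TRUE, kmer = 4L,
                       max_sequences = 20000L) {
  n <- length(proteins)
  if (n > max_sequences) {
    stop("all_vs_all: ", n, " sequences exceeds the quadratic-work guard (",
         max_sequences, "); compute hits externally and use read_blast_tab()")
  }
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stop("all_vs_all: proteins must be uniquely named")
  }
  if (any(!nzchar(proteins))) stop("all_vs_all: empty sequence")
  if (n < 2) return(empty_hits())

  pairs <- if (prescreen) kmer_candidate_pairs(proteins, kmer) else
    all_unordered_pairs(n)
  if (!nrow(pairs)) return(empty_hits())

  submat <- resolve_matrix(matrix)
  ids <- names(proteins)
  lens <- nchar(proteins)
  # one alignment per unordered pair: score, identity and length are
  # direction-symmetric, and E = K*m*n*exp(-lambda*S) is too
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(proteins[pairs[, 1]]),
    Biostrings::AAStringSet(proteins[pairs[, 2]]),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  score <- Biostrings::score(pa)
  aln_len <- Biostrings::nchar(pa)
  n_ident <- Biostrings::nmatch(pa)
  m <- lens[pairs[, 1]]
  nn <- lens[pairs[, 2]]
  ev <- estimate_evalue(pmax(score, 0), m, nn, K, lambda)
  keep <- score > 0 & ev <= cutoff
  if (!any(keep)) return(empty_hits())
  i <- pairs[keep, 1]; j <- pairs[keep, 2]
  fwd <- data.frame(
    query_id = ids[i], subject_id = ids[j],
    pct_identity = 100 * n_ident[keep] / aln_len[keep],
    aln_len = as.integer(aln_len[keep]),
    evalue = ev[keep], bitscore = score[keep],
    query_cov = aln_len[keep] / m[keep],
    stringsAsFactors = FALSE)
  rev <- fwd
  rev$query_id <- fwd$subject_id
  rev$subject_id <- fwd$query_id
  rev$query_cov <- aln_len[keep] / nn[keep]
  out <- rbind(fwd, rev)
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

all_unordered_pairs <- function(n) {
  idx <- utils::combn(n, 2)
  cbind(idx[1, ], idx[2, ])
}

# indices (i < j) of sequence pairs sharing >= 1 exact k-mer
kmer_candidate_pairs <- function(proteins, kmer) {
  n <- length(proteins)
  words <- lapply(proteins, function(s) {
    L <- nchar(s)
    if (L < kmer) return(s)
    unique(substring(s, seq_len(L - kmer + 1L),
                     seq_len(L - kmer + 1L) + kmer - 1L))
  })
  idx <- rep.int(seq_len(n), lengths(words))
  w <- unlist(words, use.names = FALSE)
  by_word <- split(idx, w)
  pair_keys <- unlist(lapply(by_word, function(v) {
    if (length(v) < 2) return(integer(0))
    v <- sort.int(v)
    p <- utils::combn(v, 2)
    (p[1, ] - 1) * n + (p[2, ] - 1)
  }), use.names = FALSE)
  pair_keys <- unique(pair_keys)
  if (!length(pair_keys)) {
    return(matrix(integer(0), ncol = 2))
  }
  pair_keys <- sort(pair_keys)
  cbind(pair_keys %/% n + 1, pair_keys %% n + 1)
}
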