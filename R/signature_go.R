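#' Screening thresholds for signature proteins
#'
#' @param max_evalue Acceptable-hit E-value ceiling (strict `<`).
#' @param min_identity Acceptable-hit identity floor, percent (strict `>`).
#' @param min_coverage Acceptable-hit query-coverage floor, fraction
#'   (strict `>`).
#' @return Validated list of thresholds.
#' @export
screen_thresholds <- function(max_evalue = 1e-5, min_identity = 30,
                              min_coverage = 0.5) {
  stopifnot(max_evalue > 0, min_identity >= 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 1)
  list(max_evalue = max_evalue, min_identity = min_identity,
       min_coverage = min_coverage)
}

#' Screen families for genus signature proteins
#'
#' A hit against the outgroup set is *acceptable* iff
#' `evalue < max_evalue` and `pct_identity > min_identity` and
#' `query_cov > min_coverage` (all strict, per the printed `<`/`>` signs of
#' the screening criteria).  A family is a signature family iff none of its
#' members has an acceptable outgroup hit — including the vacuous case of no
#' outgroup hits at all.
#'
#' @param families Long family table restricted to the families to screen
#'   (typically core families).
#' @param outgroup_hits Hit table of family members queried against a
#'   non-genus protein set (`query_id` = member gene id).
#' @param thresholds From [screen_thresholds()].
#' @return Character vector of signature family ids (sorted).
#' @export
screen_signature <- function(families, outgroup_hits,
                             thresholds = screen_thresholds()) {
  if (!nrow(families)) stop("screen_signature: no families to screen")
  if (anyNA(families$gene_id) || any(!nzchar(families$gene_id))) {
    stop("screen_signature: family with missing members")
  }
  acc <- outgroup_hits$evalue < thresholds$max_evalue &
    outgroup_hits$pct_identity > thresholds$min_identity &
    outgroup_hits$query_cov > thresholds$min_coverage
  acc[is.na(acc)] <- FALSE
  hit_genes <- unique(outgroup_hits$query_id[acc])
  fam_hit <- unique(families$family_id[families$gene_id %in% hit_genes])
  sort(setdiff(unique(families$family_id), fam_hit))
}

#' Fraction of genes in the central chromosome region
#'
#' Percent of the given genes whose locus lies outside both terminal
#' windows of its replicon (the complement of [flag_terminal()]'s terminal
#' regions).
#'
#' @param genes Gene table rows for the genes of interest (e.g. signature
#'   family members).
#' @param replicon_lengths Named vector: genes per replicon.
#' @param terminal_fraction Terminal window fraction (0 < f < 0.5).
#' @return Percent in `[0, 100]`.
#' @export
central_fraction <- function(genes, replicon_lengths,
                             terminal_fraction = 0.1) {
  stopifnot(terminal_fraction > 0, terminal_fraction < 0.5)
  if (!nrow(genes)) return(NA_real_)
  n <- as.numeric(replicon_lengths[genes$replicon_id])
  w <- floor(terminal_fraction * n)
  central <- genes$locus_index > w - 1 & genes$locus_index < n - w
  100 * sum(central) / nrow(genes)
}

#' Aggregate GO annotations to family level
#'
#' Family terms are the union of direct member annotations; no ancestor
#' propagation is applied.
#'
#' @param families Long family table.
#' @param annotations Gene-to-GO mapping from [read_gaf()].
#' @return List with `terms` (named list: family id -> sorted character
#'   vector of GO ids), `n_annotated` and `fraction_annotated` (families
#'   with >= 1 term).
#' @export
go_family_annotation <- function(families, annotations) {
  fam_ids <- sort(unique(families$family_id))
  terms <- lapply(setNames(fam_ids, fam_ids), function(f) {
    members <- families$gene_id[families$family_id == f]
    sort(unique(unlist(annotations[members], use.names = FALSE)))
  })
  n_ann <- sum(lengths(terms) > 0)
  list(terms = terms, n_annotated = n_ann,
       fraction_annotated = n_ann / length(fam_ids))
}

#' Tabulate families per GO term
#'
#' @param family_terms `terms` element from [go_family_annotation()].
#' @param family_subset Family ids to count over (e.g. core families).
#' @param go_ids GO term ids to tabulate; terms carried by no family are
#'   reported with count 0, not omitted.
#' @return Named integer vector: term -> number of subset families whose
#'   term set contains it.  A family may count toward several terms.
#' @export
go_tabulate <- function(family_terms, family_subset, go_ids) {
  stopifnot(all(grepl("^GO:\\d{7}$", go_ids)))
  sub <- family_terms[names(family_terms) %in% family_subset]
  vapply(setNames(go_ids, go_ids), function(term) {
    sum(vapply(sub, function(ts) term %in% ts, TRUE))
  }, 0L)
}
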