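#' Label clusters as named gene families
#'
#' Assigns family labels of the form `"strep"` plus a zero-padded integer,
#' in descending cluster size (ties: lexicographically smallest member id),
#' starting at 1001.  Labels are 4 digits wide while the index fits, and
#' widen automatically beyond 9999.
#'
#' @param clusters A `cluster_set`, or a plain list of gene-id vectors.
#' @param genome_of Named gene-to-genome mapping.
#' @param prefix Label prefix.
#' @return Long family table: `data.frame` with `family_id`, `gene_id`,
#'   `genome_id`.
#' @export
label_families <- function(clusters, genome_of, prefix = "strep") {
  cl <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  if (!length(cl)) stop("label_families: no clusters")
  first <- vapply(cl, function(x) sort(x)[1], "")
  ord <- order(-lengths(cl), first)
  cl <- cl[ord]
  ids <- sprintf("%s%04d", prefix, seq_along(cl) + 1000L)
  df <- data.frame(
    family_id = rep(ids, lengths(cl)),
    gene_id = unlist(lapply(cl, sort), use.names = FALSE),
    stringsAsFactors = FALSE)
  df$genome_id <- unname(genome_of[df$gene_id])
  if (anyNA(df$genome_id)) {
    stop("label_families: gene with unknown genome: ",
         df$gene_id[is.na(df$genome_id)][1])
  }
  df
}

#' Genome-by-family copy-number matrix
#'
#' @param families Long family table from [label_families()].
#' @param genome_ids Genome universe (rows); defaults to the genomes seen.
#' @return Integer matrix, genomes as rows and families as columns.  Row
#'   sums are per-genome gene counts captured in families; column sums are
#'   family sizes.
#' @export
copy_matrix <- function(families, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- sort(unique(families$genome_id))
  fam_ids <- sort(unique(families$family_id))
  m <- table(factor(families$genome_id, levels = genome_ids),
             factor(families$family_id, levels = fam_ids))
  matrix(as.integer(m), nrow = length(genome_ids),
         dimnames = list(genome_ids, fam_ids))
}

#' Partition families into the pan-genome structure
#'
#' Families present (copy count >= 1) in every genome are *core*; families
#' present in exactly one genome are *unique* (subdivided into
#' *lineage-unique-LSE* when they hold >= 2 members and *singleton* when
#' exactly 1); everything else is *dispensable*.
#'
#' @param copies Copy matrix from [copy_matrix()] (genomes x families).
#' @param genome_ids Optional genome universe check; all rows of `copies`
#'   must be listed.
#' @return A `pan_partition`: list with `table` (`data.frame`: `family_id`,
#'   `category`, `subcategory`, `size`) and `totals` (named list:
#'   `pan`, `core`, `dispensable`, `unique`, `lineage_unique_lse`,
#'   `singleton`).
#' @export
pan_partition <- function(copies, genome_ids = NULL) {
  if (nrow(copies) < 2) {
    stop("pan_partition: need >= 2 genomes (core and unique coincide at 1)")
  }
  if (!is.null(genome_ids) && !all(rownames(copies) %in% genome_ids)) {
    stop("pan_partition: genome in copy matrix not in genome_ids")
  }
  present <- colSums(copies >= 1)
  size <- colSums(copies)
  category <- ifelse(present == nrow(copies), "core",
                     ifelse(present == 1, "unique", "dispensable"))
  subcategory <- rep(NA_character_, ncol(copies))
  subcategory[category == "unique" & size >= 2] <- "lineage-unique-LSE"
  subcategory[category == "unique" & size == 1] <- "singleton"
  tab <- data.frame(family_id = colnames(copies), category = category,
                    subcategory = subcategory, size = as.integer(size),
                    stringsAsFactors = FALSE)
  totals <- list(
    pan = ncol(copies),
    core = sum(category == "core"),
    dispensable = sum(category == "dispensable"),
    unique = sum(category == "unique"),
    lineage_unique_lse = sum(subcategory == "lineage-unique-LSE",
                             na.rm = TRUE),
    singleton = sum(subcategory == "singleton", na.rm = TRUE))
  structure(list(table = tab, totals = totals), class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  t <- x$totals
  cat("pan-genome:", t$pan, "families =", t$core, "core +", t$dispensable,
      "dispensable +", t$unique, "unique (", t$lineage_unique_lse,
      "lineage-unique LSE +", t$singleton, "singletons )\n")
  invisible(x)
}

#' Per-genome core-genome fraction
#'
#' @param partition A `pan_partition`.
#' @param copies Copy matrix from [copy_matrix()].
#' @param genome_sizes Named vector of total gene counts per genome
#'   (denominator); must cover every row of `copies`.
#' @return Named numeric vector: for each genome, 100 x (genes in core
#'   families) / (total genes), rounded to 2 decimals.
#' @export
core_fraction <- function(partition, copies, genome_sizes) {
  if (any(genome_sizes[rownames(copies)] <= 0) ||
      anyNA(genome_sizes[rownames(copies)])) {
    stop("core_fraction: missing or non-positive genome size")
  }
  core_fams <- partition$table$family_id[partition$table$category == "core"]
  core_genes <- rowSums(copies[, colnames(copies) %in% core_fams,
                               drop = FALSE])
  round(100 * core_genes / genome_sizes[rownames(copies)], 2)
}
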