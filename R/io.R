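#' Read a protein FASTA file
#'
#' Reads a protein multi-FASTA into a named character vector.  Record ids are
#' the first whitespace-delimited token of the header; sequences are
#' uppercased and line wraps are removed.
#'
#' @param path Path to a FASTA file.  An empty file yields an empty vector.
#' @return Named character vector of uppercase amino-acid sequences.
#' @details Sequences may contain the 20 standard amino-acid letters plus
#'   `X` (unknown residue) and `*` (stop, stripped on load).  Anything else,
#'   an empty id, or a duplicated id is a format error naming the offending
#'   record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  if (any(ids == "")) {
    stop("FASTA format error: empty id at record ", which(ids == "")[1])
  }
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate id '", ids[duplicated(ids)][1], "'")
  }
  bad <- grepl(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    stop("FASTA format error: non-amino-acid characters in record '",
         ids[bad][1], "'")
  }
  setNames(unname(seqs), ids)
}

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a gene coordinate table
#'
#' Loads per-gene coordinates from GFF3 (CDS features) or from a simple TSV
#' dialect, and assigns each gene an ordinal `locus_index` along its
#' replicon.
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"tsv"`.  The TSV dialect has a header with
#'   columns `gene_id`, `genome_id`, `replicon_id`, `start_bp`, `end_bp`,
#'   `strand` (tab-separated, 1-based inclusive coordinates).
#' @param genome_id Genome label applied to GFF3 records (GFF3 files carry no
#'   genome field); ignored for TSV input.
#' @return A gene table: `data.frame` with columns `gene_id`, `genome_id`,
#'   `replicon_id`, `locus_index` (0-based, consecutive within each
#'   replicon), `start_bp`, `end_bp`, `strand`.
#' @details `locus_index` is assigned by sorting on
#'   (`replicon_id`, `start_bp`, `end_bp`, `gene_id`) and restarts at 0 on
#'   each replicon.  For GFF3 the gene id is taken from the `ID` attribute,
#'   falling back to `locus_tag`.
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3"),
                            genome_id = "genome1") {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    ids <- as.character(gr$ID)
    if ("locus_tag" %in% names(S4Vectors::mcols(gr))) {
      lt <- as.character(gr$locus_tag)
      ids[is.na(ids)] <- lt[is.na(ids)]
    }
    if (anyNA(ids)) stop("GFF3 CDS feature without ID or locus_tag attribute")
    df <- data.frame(
      gene_id = ids,
      genome_id = genome_id,
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      start_bp = GenomicRanges::start(gr),
      end_bp = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    df$strand[df$strand == "*"] <- "+"
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("gene_id", "genome_id", "replicon_id", "start_bp", "end_bp",
              "strand")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("gene table format error: missing columns ",
           paste(miss, collapse = ", "))
    }
    df <- df[need]
    df$start_bp <- as.integer(df$start_bp)
    df$end_bp <- as.integer(df$end_bp)
  }
  validate_gene_table(df)
}

#' @keywords internal
validate_gene_table <- function(df) {
  if (!all(df$strand %in% c("+", "-"))) {
    bad <- unique(df$strand[!df$strand %in% c("+", "-")])
    stop("gene table format error: unknown strand symbol '", bad[1], "'")
  }
  if (any(df$start_bp > df$end_bp)) stop("gene table error: start_bp > end_bp")
  key <- paste(df$gene_id, df$replicon_id, df$start_bp, df$end_bp)
  if (anyDuplicated(key)) {
    stop("gene table error: duplicate gene '",
         df$gene_id[duplicated(key)][1], "' at identical coordinates")
  }
  if (anyDuplicated(df$gene_id)) {
    stop("gene table error: duplicate gene_id '",
         df$gene_id[duplicated(df$gene_id)][1], "'")
  }
  ord <- order(df$replicon_id, df$start_bp, df$end_bp, df$gene_id)
  df <- df[ord, , drop = FALSE]
  df$locus_index <- stats::ave(seq_len(nrow(df)), df$replicon_id,
                               FUN = function(i) seq_along(i) - 1L)
  rownames(df) <- NULL
  df[c("gene_id", "genome_id", "replicon_id", "locus_index",
       "start_bp", "end_bp", "strand")]
}

#' Write a gene table in the TSV dialect
#'
#' @param genes Gene table as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(
    genes[c("gene_id", "genome_id", "replicon_id", "start_bp", "end_bp",
            "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Parses 12-column BLAST tabular output into a hit table and collapses
#' multiple HSPs per (query, subject) pair to the single best row (lowest
#' E-value; ties broken by highest bitscore).
#'
#' @param path 12-column tab-separated file (`qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore`).
#' @param query_lengths Named integer vector of query sequence lengths, used
#'   to compute `query_cov = aln_len / query length`.  Queries missing from
#'   the vector get `NA` coverage.
#' @return Hit table: `data.frame` with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_len`, `evalue`, `bitscore`, `query_cov`.
#' @details A coverage above 1.5 (multi-segment over-count) raises a warning;
#'   values in (1, 1.5] are tolerated.
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 12L)) {
    stop("BLAST tabular format error: expected 12 columns, got ",
         ncols[ncols != 12L][1], " at line ", which(ncols != 12L)[1])
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  if (anyNA(evalue)) {
    stop("BLAST tabular format error: unparseable E-value at line ",
         which(is.na(evalue))[1])
  }
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
    evalue = evalue, bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  hits <- collapse_best_hsp(hits)
  if (!is.null(query_lengths)) {
    hits$query_cov <- hits$aln_len / as.numeric(query_lengths[hits$query_id])
    if (any(hits$query_cov > 1.5, na.rm = TRUE)) {
      warning("query coverage above 1.5 for ",
              sum(hits$query_cov > 1.5, na.rm = TRUE), " hits")
    }
  } else {
    hits$query_cov <- NA_real_
  }
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_len = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             query_cov = numeric(0), stringsAsFactors = FALSE)
}

# Best row per (query, subject): minimal evalue, ties by highest bitscore.
collapse_best_hsp <- function(hits) {
  ord <- order(hits$query_id, hits$subject_id, hits$evalue, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  keep <- !duplicated(paste(hits$query_id, hits$subject_id, sep = "\r"))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read GO annotations from a GAF 2.x file
#'
#' @param path GAF file; comment lines start with `!`.
#' @return Named list mapping gene id to a character vector of GO term ids.
#' @details Column 2 (DB object id) is the gene id and column 5 the GO id;
#'   rows whose qualifier (column 4) contains `NOT` are skipped, as are rows
#'   with malformed GO ids (counted in a single warning).
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  gene <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  qual <- vapply(parts, function(p) if (length(p) >= 4) p[4] else "", "")
  term <- vapply(parts, function(p) if (length(p) >= 5) p[5] else "", "")
  not <- vapply(strsplit(qual, "|", fixed = TRUE),
                function(q) "NOT" %in% q, TRUE)
  ok <- grepl("^GO:\\d{7}$", term) & !not & nzchar(gene)
  n_bad <- sum(!grepl("^GO:\\d{7}$", term) & nzchar(term) & !not)
  if (n_bad > 0) warning(n_bad, " rows skipped for malformed GO ids")
  split(term[ok], gene[ok])
}

#' Write pipeline result tables
#'
#' Serializes families, pan-genome partition, LSE calls, tandem runs and
#' duplicated blocks as TSV tables plus one JSON summary of headline counts.
#' Output is deterministic: re-running on the same results reproduces the
#' files byte for byte.
#'
#' @param families Long family table (`family_id`, `gene_id`, `genome_id`).
#' @param partition A pan-partition as returned by [pan_partition()].
#' @param lse_calls LSE call table from [classify_lse()] (may be `NULL`).
#' @param runs Tandem run table from [find_tandem_runs()] (may be `NULL`).
#' @param blocks Block table from [find_dup_blocks()] (may be `NULL`).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(families, partition, lse_calls = NULL, runs = NULL,
                          blocks = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  fam <- families[order(families$family_id, families$gene_id), , drop = FALSE]
  files <- c(families = wt(fam, "families.tsv"),
             partition = wt(partition$table, "partition.tsv"))
  if (is.null(lse_calls)) lse_calls <- empty_lse_calls()
  if (is.null(runs)) runs <- empty_tandem_runs()
  if (is.null(blocks)) blocks <- empty_dup_blocks()
  files <- c(files,
             lse = wt(lse_calls, "lse_calls.tsv"),
             runs = wt(runs, "tandem_runs.tsv"),
             blocks = wt(blocks, "dup_blocks.tsv"))
  summary <- c(partition$totals,
               list(n_lse_calls = nrow(lse_calls),
                    n_tandem_runs = nrow(runs),
                    n_dup_blocks = nrow(blocks)))
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, summary = json_path)
  invisible(files)
}
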