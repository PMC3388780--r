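#' Simulation configuration
#'
#' Parameters of the genome-evolution simulator.  An ancestral gene set
#' evolves down a rooted tree; on every branch each gene can be lost or
#' duplicated (tandem or dispersed), contiguous blocks can be duplicated
#' (forward or inverted copies), novel single-gene families arrive by
#' lateral transfer, and sequences accumulate point substitutions.
#'
#' @param n_genomes Number of leaf genomes (default 5).
#' @param n_ancestral_families Ancestral single-copy families (default 200).
#' @param tree `ape::phylo` tree whose tip labels name the genomes; default
#'   is a balanced 5-taxon tree with unit branch lengths for `n_genomes =
#'   5`, a ladder tree otherwise.
#' @param loss_prob Per-gene per-branch loss probability.
#' @param dup_prob Per-gene per-branch single-gene duplication probability.
#' @param tandem_fraction Probability that a single-gene copy is placed
#'   immediately downstream of its template (else at a random position).
#' @param block_dup_prob Per-gene per-branch probability that a duplicated
#'   block starts at the gene.
#' @param block_len_mean Mean block length (geometric, truncated at 2).
#' @param lgt_influx_rate Expected novel families gained per branch
#'   (Poisson).
#' @param subst_prob Per-site per-branch substitution probability.
#' @param len_range Ancestral protein length range (uniform integer).
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genomes = 5L, n_ancestral_families = 200L,
                       tree = NULL, loss_prob = 0.05, dup_prob = 0.02,
                       tandem_fraction = 0.5, block_dup_prob = 0.002,
                       block_len_mean = 3, lgt_influx_rate = 2,
                       subst_prob = 0.03, len_range = c(80L, 150L),
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  probs <- c(loss_prob, dup_prob, tandem_fraction, block_dup_prob,
             subst_prob)
  stopifnot(all(probs >= 0), all(probs <= 1), block_len_mean >= 2,
            lgt_influx_rate >= 0, n_genomes >= 2,
            n_ancestral_families >= 1)
  if (is.null(tree)) {
    tree <- default_sim_tree(n_genomes)
  }
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) == n_genomes)
  structure(list(n_genomes = as.integer(n_genomes),
                 n_ancestral_families = as.integer(n_ancestral_families),
                 tree = tree, loss_prob = loss_prob, dup_prob = dup_prob,
                 tandem_fraction = tandem_fraction,
                 block_dup_prob = block_dup_prob,
                 block_len_mean = block_len_mean,
                 lgt_influx_rate = lgt_influx_rate,
                 subst_prob = subst_prob,
                 len_range = as.integer(len_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

default_sim_tree <- function(n) {
  if (n == 5) {
    ape::read.tree(
      text = "((sim1:1,sim2:1):1,(sim3:1,(sim4:1,sim5:1):1):1);")
  } else {
    tr <- ape::stree(n, type = "left")
    tr$tip.label <- paste0("sim", seq_len(n))
    tr$edge.length <- rep(1, nrow(tr$edge))
    tr
  }
}

#' Simulate genome evolution with ground truth
#'
#' Runs the birth/death/duplication/transfer process of a [sim_config()]
#' down its tree and emits leaf proteomes, gene-order tables and a full
#' ground-truth record.  Identical configurations (including seed) produce
#' byte-identical output.
#'
#' @param config A `sim_config`.
#' @return List with:
#'   \describe{
#'     \item{proteins}{named character vector of all leaf protein
#'       sequences (`<genome>_<uid>` ids).}
#'     \item{genes}{gene table in [read_gene_table()] layout (one replicon
#'       per genome).}
#'     \item{truth}{list: `gene_family` (named true family label per leaf
#'       gene), `events` (event log `data.frame`; branches are labelled
#'       `"parent->child"` with the tree's node numbers), `tandem`
#'       (lineage-specific true tandem arrays: adjacency runs under the
#'       true labels that contain at least one gene copy created on the
#'       genome's terminal branch), `tandem_all` (all adjacency runs,
#'       including arrays that predate the last speciation), `blocks`
#'       (list of true duplicated-block gene-id sets per surviving event,
#'       with genome, template and copy members), and `partition` (the true
#'       `pan_partition`).}
#'   }
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lens <- sample(seq(config$len_range[1], config$len_range[2]),
                 config$n_ancestral_families, replace = TRUE)
  fams <- sprintf("fam%04d", seq_len(config$n_ancestral_families))
  root <- list(
    uid = sprintf("g%06d", seq_len(config$n_ancestral_families)),
    family = fams,
    strand = rep("+", config$n_ancestral_families),
    seq = vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), "")
  )
  env <- new.env()
  env$uid_counter <- config$n_ancestral_families
  env$lgt_counter <- 0L
  env$events <- list()
  env$blocks <- list()
  leaves <- list()

  tree <- stats::reorder(config$tree, "cladewise")
  tips <- tree$tip.label
  recurse <- function(node, state, path_blocks, branch_minted) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) {
      leaves[[tips[node]]] <<- list(state = state, blocks = path_blocks,
                                    terminal_minted = branch_minted)
      return(invisible())
    }
    for (kid in kids) {
      branch <- paste0(node, "->", kid)
      res <- evolve_branch(state, config, env, branch)
      recurse(kid, res$state, c(path_blocks, res$blocks), res$minted)
    }
  }
  root_node <- length(tips) + 1L
  recurse(root_node, root, list(), character(0))

  serialize_simulation(leaves, tips, config, env)
}

# one branch: losses, single duplications, block duplications, LGT influx,
# then substitutions
evolve_branch <- function(state, config, env, branch) {
  n <- length(state$uid)
  start_uids <- state$uid
  log_event <- function(type, family, n_genes, detail = "") {
    env$events[[length(env$events) + 1L]] <- data.frame(
      branch = branch, event = type, family = family,
      n_genes = n_genes, detail = detail, stringsAsFactors = FALSE)
  }
  branch_blocks <- list()

  # losses
  if (n > 0 && config$loss_prob > 0) {
    lost <- stats::runif(n) < config$loss_prob
    if (any(lost)) {
      for (f in unique(state$family[lost])) {
        log_event("loss", f, sum(lost & state$family == f))
      }
      state <- state_subset(state, !lost)
    }
  }

  # single-gene duplications
  n <- length(state$uid)
  if (n > 0 && config$dup_prob > 0) {
    dup_idx <- which(stats::runif(n) < config$dup_prob)
    for (i in rev(dup_idx)) { # right-to-left keeps earlier indices valid
      env$uid_counter <- env$uid_counter + 1L
      new <- list(uid = sprintf("g%06d", env$uid_counter),
                  family = state$family[i], strand = state$strand[i],
                  seq = state$seq[i])
      tandem <- stats::runif(1) < config$tandem_fraction
      pos <- if (tandem) i else
        sample.int(length(state$uid) + 1L, 1L) - 1L
      state <- state_insert(state, new, after = pos)
      log_event(if (tandem) "tandem_dup" else "dispersed_dup",
                new$family, 1L)
    }
  }

  # block duplications
  n <- length(state$uid)
  if (n > 1 && config$block_dup_prob > 0) {
    starts <- which(stats::runif(n) < config$block_dup_prob)
    for (s in rev(starts)) {
      n_cur <- length(state$uid)
      if (s > n_cur - 1L) next
      L <- max(2L, stats::rgeom(1L, 1 / config$block_len_mean) + 1L)
      L <- min(L, n_cur - s + 1L)
      if (L < 2L) next
      src <- s:(s + L - 1L)
      src_uids <- state$uid[src]
      inverted <- stats::runif(1) < 0.5
      env$uid_counter <- env$uid_counter + L
      new_uids <- sprintf("g%06d", (env$uid_counter - L + 1L):
                                   env$uid_counter)
      ord <- if (inverted) rev(src) else src
      new <- list(uid = new_uids, family = state$family[ord],
                  strand = if (inverted)
                    chartr("+-", "-+", state$strand[ord]) else
                    state$strand[ord],
                  seq = state$seq[ord])
      # insertion point outside the source span
      slots <- setdiff(0:n_cur, s:(s + L - 2L))
      pos <- slots[sample.int(length(slots), 1L)]
      state <- state_insert(state, new, after = pos)
      blk <- list(branch = branch, template_uids = src_uids,
                  copy_uids = new_uids,
                  orientation = if (inverted) "inverted" else "forward")
      branch_blocks[[length(branch_blocks) + 1L]] <- blk
      log_event("block_dup", paste(new$family, collapse = ","), L,
                detail = blk$orientation)
    }
  }

  # lateral influx of novel single-gene families
  n_new <- stats::rpois(1L, config$lgt_influx_rate)
  if (n_new > 0) {
    for (k in seq_len(n_new)) {
      env$lgt_counter <- env$lgt_counter + 1L
      env$uid_counter <- env$uid_counter + 1L
      L <- sample(seq(config$len_range[1], config$len_range[2]), 1L)
      new <- list(uid = sprintf("g%06d", env$uid_counter),
                  family = sprintf("lgt%04d", env$lgt_counter),
                  strand = "+",
                  seq = paste(sample(AA_ALPHABET, L, replace = TRUE),
                              collapse = ""))
      pos <- sample.int(length(state$uid) + 1L, 1L) - 1L
      state <- state_insert(state, new, after = pos)
      log_event("lgt_gain", new$family, 1L)
    }
  }

  # substitutions, uniform over the 19 alternatives
  if (config$subst_prob > 0 && length(state$uid)) {
    state$seq <- vapply(state$seq, mutate_seq, "",
                        p = config$subst_prob, USE.NAMES = FALSE)
  }
  list(state = state, blocks = branch_blocks,
       minted = setdiff(state$uid, start_uids))
}

mutate_seq <- function(s, p) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA_ALPHABET, a), 1L), "", USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

state_subset <- function(state, keep) {
  lapply(state, function(x) x[keep])
}

# insert `new` genes after position `after` (0 = front)
state_insert <- function(state, new, after) {
  n <- length(state$uid)
  pre <- seq_len(after)
  post <- if (after < n) (after + 1L):n else integer(0)
  Map(function(old, add) c(old[pre], add, old[post]), state, new)
}

serialize_simulation <- function(leaves, tips, config, env) {
  genes_list <- list()
  proteins <- character(0)
  gene_family <- character(0)
  truth_blocks <- list()
  for (tip in tips) {
    st <- leaves[[tip]]$state
    n <- length(st$uid)
    if (n == 0) {
      warning("simulate_genomes: genome ", tip, " went extinct")
      next
    }
    ids <- paste(tip, st$uid, sep = "_")
    start <- (seq_len(n) - 1L) * 1200L + 1L
    genes_list[[tip]] <- data.frame(
      gene_id = ids, genome_id = tip,
      replicon_id = paste0(tip, "_chr"),
      locus_index = seq_len(n) - 1L,
      start_bp = start, end_bp = start + 3L * nchar(st$seq) - 1L,
      strand = st$strand, stringsAsFactors = FALSE)
    proteins <- c(proteins, setNames(st$seq, ids))
    gene_family <- c(gene_family, setNames(st$family, ids))
    for (blk in leaves[[tip]]$blocks) {
      tmpl <- paste(tip, intersect(blk$template_uids, st$uid), sep = "_")
      copy <- paste(tip, intersect(blk$copy_uids, st$uid), sep = "_")
      if (length(tmpl) >= 2 && length(copy) >= 2) {
        truth_blocks[[length(truth_blocks) + 1L]] <- list(
          genome_id = tip, template = tmpl, copy = copy,
          orientation = blk$orientation, branch = blk$branch)
      }
    }
  }
  genes <- do.call(rbind, genes_list)
  rownames(genes) <- NULL
  events <- if (length(env$events)) do.call(rbind, env$events) else
    data.frame(branch = character(0), event = character(0),
               family = character(0), n_genes = integer(0),
               detail = character(0), stringsAsFactors = FALSE)

  true_fams <- split(names(gene_family), gene_family)
  fam_long <- data.frame(
    family_id = rep(names(true_fams), lengths(true_fams)),
    gene_id = unlist(true_fams, use.names = FALSE),
    stringsAsFactors = FALSE)
  fam_long$genome_id <- genes$genome_id[match(fam_long$gene_id,
                                              genes$gene_id)]
  cm <- copy_matrix(fam_long, genome_ids = sort(unique(genes$genome_id)))
  tandem_all <- find_tandem_runs(genes, gene_family)
  # lineage-specific arrays: runs holding at least one copy minted on the
  # genome's terminal branch.  Arrays formed before the last speciation are
  # shared between genomes, hence not lineage-specific expansions, and the
  # orthogroup rules deliberately split such ancient paralogs.
  minted_ids <- unlist(lapply(tips, function(tip)
    paste(tip, leaves[[tip]]$terminal_minted, sep = "_")),
    use.names = FALSE)
  keep <- vapply(seq_len(nrow(tandem_all)), function(k)
    any(strsplit(tandem_all$gene_ids[k], ",")[[1]] %in% minted_ids), TRUE)
  tandem_ls <- tandem_all[keep, , drop = FALSE]
  rownames(tandem_ls) <- NULL
  truth <- list(
    gene_family = gene_family,
    events = events,
    tandem = tandem_ls,
    tandem_all = tandem_all,
    blocks = truth_blocks,
    partition = pan_partition(cm))
  list(proteins = proteins, genes = genes, truth = truth)
}

#' Write simulated data in pipeline input formats
#'
#' @param sim Result of [simulate_genomes()].
#' @param out_dir Output directory.
#' @return Paths written (FASTA per genome, one gene table TSV, truth
#'   JSON), invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in sort(unique(sim$genes$genome_id))) {
    ids <- sim$genes$gene_id[sim$genes$genome_id == g]
    p <- file.path(out_dir, paste0(g, ".faa"))
    write_fasta(sim$proteins[ids], p)
    paths <- c(paths, p)
  }
  gt <- file.path(out_dir, "genes.tsv")
  write_gene_table(sim$genes, gt)
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(gene_family = as.list(sim$truth$gene_family),
         events = sim$truth$events,
         blocks = sim$truth$blocks,
         partition_totals = sim$truth$partition$totals),
    tj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, gt, tj))
}
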