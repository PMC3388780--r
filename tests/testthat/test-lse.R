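test_that("LSE calls distinguish lineage-unique from typical expansions", {
  cm <- matrix(c(2, 0, 0,    # f1 only in A, 2 copies -> lineage-unique
                 3, 1, 0,    # f2 expanded in A, present in B -> typical
                 1, 1, 1),   # f3 no expansion
               nrow = 3, byrow = FALSE,
               dimnames = list(c("A", "B", "C"), c("f1", "f2", "f3")))
  # byrow=FALSE fills columns; rebuild explicitly to avoid confusion
  cm <- matrix(c(2, 0, 0,
                 3, 1, 0,
                 1, 1, 1), nrow = 3, byrow = FALSE,
               dimnames = list(c("A", "B", "C"), c("f1", "f2", "f3")))
  p <- pan_partition(cm)
  lse <- classify_lse(cm, p, genome_sizes = c(A = 20, B = 10, C = 10))
  calls <- lse$calls
  expect_equal(nrow(calls), 2)
  expect_equal(calls$lse_type[calls$family_id == "f1"], "lineage-unique")
  expect_equal(calls$lse_type[calls$family_id == "f2"], "typical")
  expect_true(all(calls$genome_id == "A"))
  summ <- lse$summary
  a <- summ[summ$genome_id == "A", ]
  expect_equal(a$lineage_unique_families, 1)
  expect_equal(a$lineage_unique_genes, 2)
  expect_equal(a$lse_genes, 5)
  expect_equal(a$pct_lse, 25)
  # no calls elsewhere
  expect_equal(summ$lse_genes[summ$genome_id != "A"], c(0, 0))
})

test_that("per-genome LSE accounting is conserved against the partition", {
  set.seed(61)
  for (rep in 1:10) {
    cm <- matrix(rpois(5 * 40, 0.9), nrow = 5,
                 dimnames = list(paste0("G", 1:5), sprintf("f%02d", 1:40)))
    cm[1, colSums(cm) == 0] <- 1
    p <- pan_partition(cm)
    lse <- classify_lse(cm, p)
    expect_true(all(lse$calls$copies >= 2))
    expect_true(all(lse$summary$lineage_unique_genes <=
                    lse$summary$lse_genes))
    # lineage-unique family calls = partition lineage-unique-LSE total
    expect_equal(sum(lse$summary$lineage_unique_families),
                 p$totals$lineage_unique_lse)
  }
})

test_that("size distribution bins copy numbers with an open top bin", {
  calls <- data.frame(family_id = paste0("f", 1:4), genome_id = "A",
                      lse_type = "typical", copies = c(2, 2, 3, 75))
  d <- lse_size_distribution(calls)
  h <- d$histogram
  expect_equal(h$n_families[h$bin == "2"], 2L)
  expect_equal(h$n_families[h$bin == "3"], 1L)
  expect_equal(h$n_families[h$bin == ">=11"], 1L)
  expect_equal(sum(h$n_families), 4L)
  expect_equal(unname(d$two_copy_fraction["A"]), 0.5)
})

test_that("tandem runs are maximal adjacent same-family stretches", {
  lay <- layout_genes(list(chr = c("F1", "F1", "X", "F2", "Y", "F2",
                                   "F3", "F3", "F3", "F3")))
  runs <- find_tandem_runs(lay$genes, lay$family_of)
  expect_equal(nrow(runs), 2)
  r1 <- runs[runs$family_id == "F1", ]
  expect_equal(c(r1$start_locus, r1$end_locus, r1$length), c(0, 1, 2))
  # four consecutive copies: one run of 4, not three of 2
  r3 <- runs[runs$family_id == "F3", ]
  expect_equal(c(r3$start_locus, r3$end_locus, r3$length), c(6, 9, 4))
  # F2 copies separated by an unrelated gene: no run
  expect_false("F2" %in% runs$family_id)
})

test_that("tandem runs equal a linear-scan oracle on random layouts", {
  set.seed(62)
  for (rep in 1:20) {
    fams <- sample(c(paste0("F", 1:4), NA), 30, replace = TRUE)
    lay <- layout_genes(list(chr = fams))
    runs <- find_tandem_runs(lay$genes, lay$family_of)
    # simple scan oracle
    exp_runs <- 0L
    i <- 1
    while (i <= 29) {
      if (!is.na(fams[i]) && !is.na(fams[i + 1]) &&
          fams[i] == fams[i + 1]) {
        j <- i
        while (j < 30 && !is.na(fams[j + 1]) && fams[j + 1] == fams[i]) {
          j <- j + 1
        }
        exp_runs <- exp_runs + 1L
        i <- j + 1
      } else i <- i + 1
    }
    expect_equal(nrow(runs), exp_runs, info = paste("replicate", rep))
    # every run really is homogeneous and maximal
    for (k in seq_len(nrow(runs))) {
      lo <- runs$start_locus[k]; hi <- runs$end_locus[k]
      expect_true(all(fams[(lo:hi) + 1] == runs$family_id[k]))
      if (lo > 0) expect_false(isTRUE(fams[lo] == runs$family_id[k]))
      if (hi < 29) expect_false(isTRUE(fams[hi + 2] == runs$family_id[k]))
    }
  }
})

test_that("a repeated three-gene cassette is one forward block", {
  lay <- layout_genes(list(chr = c("X", "Y", "Z", ".", ".", ".",
                                   "X", "Y", "Z")))
  blocks <- find_dup_blocks(lay$genes, lay$family_of)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$orientation, "forward")
  expect_equal(blocks$n_anchors, 3)
  expect_equal(c(blocks$a_start, blocks$a_end), c(0, 2))
  expect_equal(c(blocks$b_start, blocks$b_end), c(6, 8))
})

test_that("an inverted gapped copy is one inverted block", {
  # X,Y,.,W,V ... V,W,.,Y,X
  lay <- layout_genes(list(chr = c("X", "Y", ".", "W", "V", ".", ".",
                                   "V", "W", ".", "Y", "X")))
  blocks <- find_dup_blocks(lay$genes, lay$family_of)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$orientation, "inverted")
  expect_equal(blocks$n_anchors, 4)
  expect_equal(c(blocks$a_start, blocks$a_end), c(0, 4))
  expect_equal(c(blocks$b_start, blocks$b_end), c(7, 11))
  expect_gt(blocks$gaps, 0)
})

test_that("unrelated intervals yield no blocks and tandem echoes are suppressed", {
  lay <- layout_genes(list(chr = c("A", "B", "C", "D", "E", "F")))
  expect_equal(nrow(find_dup_blocks(lay$genes, lay$family_of)), 0)
  # a pure tandem array must not come back as a block
  lay2 <- layout_genes(list(chr = c("T", "T", "T", "T", ".", ".")))
  expect_equal(nrow(find_dup_blocks(lay2$genes, lay2$family_of)), 0)
  expect_equal(nrow(find_tandem_runs(lay2$genes, lay2$family_of)), 1)
})

test_that("block extraction equals the exhaustive chaining oracle", {
  set.seed(63)
  for (rep in 1:25) {
    n <- sample(8:15, 1)
    fams <- sample(c(paste0("F", 1:4), ".", "."), n, replace = TRUE)
    lay <- layout_genes(list(chr = fams))
    got <- find_dup_blocks(lay$genes, lay$family_of, max_gap = 1,
                           min_anchors = 2)
    ref <- oracle_dup_blocks(lay$genes, lay$family_of, max_gap = 1,
                             min_anchors = 2)
    cols <- c("genome_id", "replicon_a", "a_start", "a_end", "replicon_b",
              "b_start", "b_end", "orientation", "n_anchors")
    if (nrow(ref) == 0) {
      expect_equal(nrow(got), 0, info = paste("replicate", rep))
    } else {
      expect_equal(got[cols], ref[cols], info = paste("replicate", rep))
    }
  }
  # and with the default gap allowance
  for (rep in 1:10) {
    n <- sample(10:15, 1)
    fams <- sample(c(paste0("F", 1:3), ".", "."), n, replace = TRUE)
    lay <- layout_genes(list(chr = fams))
    got <- find_dup_blocks(lay$genes, lay$family_of)
    ref <- oracle_dup_blocks(lay$genes, lay$family_of)
    cols <- c("a_start", "a_end", "b_start", "b_end", "orientation",
              "n_anchors")
    if (nrow(ref) == 0) {
      expect_equal(nrow(got), 0, info = paste("gap3 replicate", rep))
    } else {
      expect_equal(got[cols], ref[cols],
                   info = paste("gap3 replicate", rep))
    }
  }
})

test_that("block calls are stable under coordinate reversal", {
  lay <- layout_genes(list(chr = c("X", "Y", "Z", ".", ".", ".",
                                   "X", "Y", "Z", ".")))
  fwd <- find_dup_blocks(lay$genes, lay$family_of)
  rev_lay <- layout_genes(list(chr = rev(c("X", "Y", "Z", ".", ".", ".",
                                           "X", "Y", "Z", "."))))
  bwd <- find_dup_blocks(rev_lay$genes, rev_lay$family_of)
  expect_equal(nrow(bwd), nrow(fwd))
  expect_equal(bwd$n_anchors, fwd$n_anchors)
  # forward stays forward under whole-replicon reversal
  expect_equal(bwd$orientation, fwd$orientation)
  n <- 10
  expect_equal(c(bwd$a_start, bwd$a_end),
               c(n - 1 - fwd$b_end, n - 1 - fwd$b_start))
})

test_that("terminal flagging requires full containment in a window", {
  blocks <- data.frame(
    genome_id = "G", replicon_a = "chr",
    a_start = c(0L, 45L, 5L), a_end = c(4L, 50L, 12L),
    replicon_b = "chr",
    b_start = c(50L, 60L, 95L), b_end = c(54L, 66L, 99L),
    orientation = "forward", n_anchors = 2L, gaps = 0L,
    anchors = "x|y", terminal_flag = NA)
  out <- flag_terminal(blocks, c(chr = 100), terminal_fraction = 0.1)
  expect_true(out$terminal_flag[1])    # a interval in [0, 9]
  expect_false(out$terminal_flag[2])   # both mid-chromosome
  expect_true(out$terminal_flag[3])    # b interval in [90, 99]
  # straddling the boundary does not count
  straddle <- blocks[1, ]
  straddle$a_start <- 7L; straddle$a_end <- 12L
  straddle$b_start <- 40L; straddle$b_end <- 45L
  expect_false(flag_terminal(straddle, c(chr = 100), 0.1)$terminal_flag)
})
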