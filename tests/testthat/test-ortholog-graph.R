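test_that("reciprocal best hits become ortholog pairs", {
  # 2 genomes, 1 gene each, mutual hits
  h <- mutual_hits("a1", "b1", 1e-30)
  expect_equal(find_orthologs(h, genomes2, 1e-5),
               data.frame(gene_a = "a1", gene_b = "b1",
                          stringsAsFactors = FALSE))

  # a's best in B is b1, but b1's best in A is a2: no (a1, b1) pair
  h <- rbind(hit_rows(list("a1", "b1", 1e-40)),
             hit_rows(list("b1", "a1", 1e-10), list("b1", "a2", 1e-42)),
             hit_rows(list("a2", "b1", 1e-42)))
  ort <- find_orthologs(h, genomes2, 1e-5)
  expect_false(any(ort$gene_a == "a1" & ort$gene_b == "b1"))
  expect_true(any(ort$gene_a == "a2" & ort$gene_b == "b1"))
})

test_that("ortholog pairs equal exhaustive reciprocal-best enumeration", {
  set.seed(31)
  genes <- names(genomes2)
  for (rep in 1:5) {
    # random directed hit table
    pairs <- expand.grid(q = genes, s = genes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$q != pairs$s, ]
    pairs <- pairs[runif(nrow(pairs)) < 0.6, ]
    pairs$ev <- 10^-sample.int(50, nrow(pairs), replace = TRUE)
    h <- do.call(hit_rows, lapply(seq_len(nrow(pairs)), function(i)
      list(pairs$q[i], pairs$s[i], pairs$ev[i])))
    got <- find_orthologs(h, genomes2, 1e-5)
    # brute force
    exp <- list()
    for (x in genes) {
      for (y in genes) {
        if (x >= y || genomes2[x] == genomes2[y]) next
        hx <- h[h$query_id == x & genomes2[h$subject_id] == genomes2[y] &
                h$evalue <= 1e-5, ]
        hy <- h[h$query_id == y & genomes2[h$subject_id] == genomes2[x] &
                h$evalue <= 1e-5, ]
        if (!nrow(hx) || !nrow(hy)) next
        x_best <- hx$subject_id[hx$evalue == min(hx$evalue)]
        y_best <- hy$subject_id[hy$evalue == min(hy$evalue)]
        if (y %in% x_best && x %in% y_best) {
          exp[[length(exp) + 1]] <- c(x, y)
        }
      }
    }
    exp_df <- if (length(exp)) {
      m <- do.call(rbind, exp)
      df <- data.frame(gene_a = pmin(m[, 1], m[, 2]),
                       gene_b = pmax(m[, 1], m[, 2]),
                       stringsAsFactors = FALSE)
      df[order(df$gene_a, df$gene_b), ]
    } else data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
    rownames(exp_df) <- NULL
    expect_equal(got, exp_df, info = paste("replicate", rep))
  }
})

test_that("in-paralogy requires dominance over inter-genome hits", {
  # mutual 1e-60, worst inter-genome hit of a1 is 1e-20: in-paralogs
  h <- rbind(mutual_hits("a1", "a2", 1e-60),
             mutual_hits("a1", "b1", 1e-20))
  inp <- find_inparalogs(h, genomes2, 1e-5)
  expect_equal(inp$gene_a, "a1")
  expect_equal(inp$gene_b, "a2")

  # mutual 1e-10 but a1 has an inter-genome hit at 1e-30: not in-paralogs
  h <- rbind(mutual_hits("a1", "a2", 1e-10),
             mutual_hits("a1", "b1", 1e-30))
  expect_equal(nrow(find_inparalogs(h, genomes2, 1e-5)), 0)

  # no inter-genome hits at all: any mutual within-genome hit qualifies
  h <- mutual_hits("a1", "a2", 1e-6)
  expect_equal(nrow(find_inparalogs(h, genomes2, 1e-5)), 1)
})

test_that("in-paralog pairs equal brute-force rule application", {
  set.seed(32)
  genes <- names(genomes2)
  for (rep in 1:5) {
    pairs <- expand.grid(q = genes, s = genes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$q != pairs$s, ]
    pairs <- pairs[runif(nrow(pairs)) < 0.5, ]
    pairs$ev <- 10^-sample.int(40, nrow(pairs), replace = TRUE)
    h <- do.call(hit_rows, lapply(seq_len(nrow(pairs)), function(i)
      list(pairs$q[i], pairs$s[i], pairs$ev[i])))
    cutoff <- 1e-5
    got <- find_inparalogs(h, genomes2, cutoff)
    hc <- h[h$evalue <= cutoff, ]
    worst_inter <- function(g) {
      v <- hc$evalue[hc$query_id == g &
                     genomes2[hc$subject_id] != genomes2[g]]
      if (!length(v)) Inf else max(v)
    }
    exp <- list()
    for (x in genes) {
      for (y in genes) {
        if (x >= y || genomes2[x] != genomes2[y]) next
        exy <- hc$evalue[hc$query_id == x & hc$subject_id == y]
        eyx <- hc$evalue[hc$query_id == y & hc$subject_id == x]
        if (!length(exy) || !length(eyx)) next
        thr <- min(worst_inter(x), worst_inter(y))
        if (exy < thr && eyx < thr) exp[[length(exp) + 1]] <- c(x, y)
      }
    }
    exp_df <- if (length(exp)) {
      m <- do.call(rbind, exp)
      df <- data.frame(gene_a = m[, 1], gene_b = m[, 2],
                       stringsAsFactors = FALSE)
      df[order(df$gene_a, df$gene_b), ]
    } else data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
    rownames(exp_df) <- NULL
    expect_equal(got, exp_df, info = paste("replicate", rep))
  }
})

test_that("co-orthologs are reached through in-paralogy", {
  # orthologs (a1,b1); in-paralogs (a1,a2); hits a2<->b1 present
  h <- rbind(mutual_hits("a1", "b1", 1e-40),
             mutual_hits("a1", "a2", 1e-60),
             mutual_hits("a2", "b1", 1e-35))
  ort <- find_orthologs(h, genomes2, 1e-5)
  inp <- find_inparalogs(h, genomes2, 1e-5)
  coo <- find_coorthologs(h, genomes2, ort, inp, 1e-5)
  expect_equal(coo, data.frame(gene_a = "a2", gene_b = "b1",
                               stringsAsFactors = FALSE))

  # without in-paralog pairs the co-ortholog set is empty
  coo2 <- find_coorthologs(h, genomes2, ort, empty_rows <-
                             data.frame(gene_a = character(0),
                                        gene_b = character(0)), 1e-5)
  expect_equal(nrow(coo2), 0)

  # missing reverse hit a2->b1 blocks the pair
  h2 <- rbind(mutual_hits("a1", "b1", 1e-40),
              mutual_hits("a1", "a2", 1e-60),
              hit_rows(list("b1", "a2", 1e-35)))
  coo3 <- find_coorthologs(h2, genomes2, ort, inp, 1e-5)
  expect_equal(nrow(coo3), 0)
})

test_that("graph weights average -log10 evalues and normalize per class", {
  # single ortholog edge: raw (20+30)/2 = 25, norm 1 (class of itself)
  h <- mutual_hits("a1", "b1", 1e-20, 1e-30)
  ort <- data.frame(gene_a = "a1", gene_b = "b1")
  g <- build_graph(h, genomes2, ort,
                   data.frame(gene_a = character(0),
                              gene_b = character(0)))
  expect_equal(g$edges$raw_weight, 25)
  expect_equal(g$edges$norm_weight, 1)

  # evalue 0 capped at 316
  h <- mutual_hits("a1", "b1", 0, 1e-300)
  g <- build_graph(h, genomes2, ort,
                   data.frame(gene_a = character(0),
                              gene_b = character(0)))
  expect_equal(g$edges$raw_weight, (316 + 300) / 2)

  # two-class fixture: weights equal hand-computed normalization
  h <- rbind(mutual_hits("a1", "b1", 1e-10),   # raw 10
             mutual_hits("a2", "b2", 1e-30),   # raw 30
             mutual_hits("a1", "a2", 1e-40),   # raw 40 (inparalog, A)
             mutual_hits("c1", "c2", 1e-20))   # raw 20 (inparalog, C)
  ort <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"))
  inp <- data.frame(gene_a = c("a1", "c1"), gene_b = c("a2", "c2"))
  g <- build_graph(h, genomes2, ort, inp)
  e <- g$edges
  expect_equal(e$norm_weight[e$gene_a == "a1" & e$gene_b == "b1"], 10 / 20)
  expect_equal(e$norm_weight[e$gene_a == "a2" & e$gene_b == "b2"], 30 / 20)
  expect_equal(e$norm_weight[e$gene_a == "a1" & e$gene_b == "a2"], 1)
  expect_equal(e$norm_weight[e$gene_a == "c1" & e$gene_b == "c2"], 1)

  # class means of norm weights are 1
  cls <- paste(genomes2[e$gene_a], genomes2[e$gene_b], e$type)
  expect_true(all(abs(tapply(e$norm_weight, cls, mean) - 1) < 1e-12))
})

test_that("edge sets shrink monotonically as the cutoff tightens", {
  set.seed(33)
  genes <- names(genomes2)
  pairs <- expand.grid(q = genes, s = genes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$q < pairs$s, ]
  h <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    mutual_hits(pairs$q[i], pairs$s[i],
                10^-sample.int(30, 1))))
  key <- function(g) paste(g$edges$gene_a, g$edges$gene_b)
  gl <- hits_to_graph(h, genomes2, cutoff = 10)
  gs <- hits_to_graph(h, genomes2, cutoff = 1e-10)
  expect_true(all(key(gs) %in% key(gl)))
})

test_that("unknown genomes are a mapping error", {
  h <- mutual_hits("a1", "zz", 1e-30)
  expect_error(find_orthologs(h, genomes2, 1e-5), "unknown genome")
})
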