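# panstrep

Pan-genome partitioning and lineage-specific expansion (LSE) analysis for
small sets of closely related bacterial genomes, in the mould of
multi-strain *Streptomyces* comparative studies.

Given per-genome protein sets, gene-order tables and all-versus-all protein
similarity hits, the package

1. builds an **OrthoMCL-style typed homology graph** — reciprocal-best
   ortholog pairs, in-paralog pairs (within-genome pairs whose mutual
   E-value dominates their inter-genome hits), and co-ortholog pairs
   reached through in-paralogy — with edge weights `w = mean(-log10 E)`
   normalized per (genome pair, edge type) class;
2. clusters gene families with a **from-scratch sparse Markov clustering
   (MCL)** implementation: iterate expansion (`M <- M %*% M`) and inflation
   (entry-wise power `r` with column renormalization) on the
   column-stochastic graph matrix until convergence, reading clusters off
   the attractor structure — including the standard **E-value × inflation
   parameter sweep** (12 cutoffs from 10 down to 1e-10 × inflations 1.0,
   1.5, 2.0; defaults E = 1e-5, r = 1.5);
3. partitions families into the **pan-genome** compartments: *core*
   (present in every genome), *dispensable* (≥ 2 but not all), *unique*
   (one genome only, split into multi-copy lineage-unique LSE families and
   singletons), with per-genome core percentages;
4. classifies **lineage-specific expansions** (family × genome cells with
   ≥ 2 copies; *lineage-unique* vs *typical*) and detects their chromosomal
   patterns: maximal **tandem arrays** of consecutive same-family genes,
   and **duplicated blocks** — pairs of intervals whose gene orders match
   through same-family anchors, chained by dynamic programming in forward
   or inverted orientation with bounded gaps, and flagged when they fall in
   the terminal regions of the chromosome;
5. screens core families for **genus signature proteins** against an
   outgroup hit table (a family is signature iff no member has an outgroup
   hit with E < 1e-5, identity > 30 % and query coverage > 50 %, all
   strict) and tabulates **GO functional categories** per family.

A genome-evolution **simulator** (gene loss, tandem and dispersed
single-gene duplication, forward/inverted block duplication, lateral influx
of novel families, per-site substitutions down a 5-taxon tree) emits the
exact input formats the pipeline reads plus a ground-truth event log, so
clustering and expansion detection are verifiable end to end — by adjusted
Rand index and by precision/recall of recovered arrays and blocks — without
any external data. For real data, compute hits with any BLAST-compatible
aligner and ingest the 12-column tabular output; the built-in
Smith–Waterman stage (Biostrings) is intended for toy and synthetic scale.

## Worked example

```r
library(panstrep)

cfg <- sim_config(seed = 42)          # 5 genomes, 200 ancestral families
sim <- simulate_genomes(cfg)
res <- run_pipeline(sim$proteins, sim$genes)
print(res)
#> pan-genome pipeline: 940 genes in 5 genomes
#> pan-genome: 214 families = 126 core + 76 dispensable + 12 unique ( 0 lineage-unique LSE + 12 singletons )
#> tandem runs: 12 ; duplicated blocks: 2 ( 2 terminal )

evaluate_clustering(sim$truth$gene_family, res$clusters)$ari
#> [1] 0.9983466
evaluate_expansions(sim$truth, res$tandem_runs, res$dup_blocks,
                    sim$genes)$tandem$recall
#> [1] 1
```

The pipeline recovered the simulated families almost perfectly (ARI 0.998;
the residual is a handful of ancient paralog pairs that the orthogroup
rules deliberately keep apart) and found every lineage-specific tandem
array. `res$lse$summary` gives the per-genome Table-style accounting
(lineage-unique and typical LSE family counts, LSE gene counts and their
percentage of the genome), `res$partition` the pan-genome totals, and
`res$dup_blocks` the duplicated blocks with orientation and terminal flag.

A thin command-line wrapper with `simulate`, `run` and `evaluate`
subcommands is installed at `inst/scripts/panstrep-pipeline.R`.

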