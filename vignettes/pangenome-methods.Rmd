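---
title: "Methods: homology graphs, Markov clustering and expansion detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology graphs, Markov clustering and expansion detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panstrep)
```

panstrep reconstructs the classical comparative-genomics inference chain
for a handful of closely related bacterial genomes: all-versus-all protein
similarity, an OrthoMCL-style typed homology graph, Markov clustering into
gene families, pan-genome partitioning, and the classification and
chromosomal mapping of lineage-specific expansions (LSEs). This vignette
explains each model, its assumptions, the tunable parameters, and the
design choices made where the method family leaves them open.

## Similarity stage

At real scale the similarity search belongs to an external BLAST-compatible
aligner whose 12-column tabular output `read_blast_tab()` ingests (when a
pair has several HSPs, only the lowest-E-value row is kept — no HSP tiling,
matching common OrthoMCL practice). For synthetic and toy data the package
aligns internally: `local_align()` computes an optimal Smith–Waterman local
alignment with affine gaps via Biostrings (`BLOSUM62`, gap open 11, extend
1 — the standard protein defaults), and `estimate_evalue()` converts scores
with the raw Karlin–Altschul form

$$E = K \, m \, n \, e^{-\lambda S}, \qquad K = 0.041,\ \lambda = 0.267,$$

using actual (not effective) sequence lengths. These are ungapped-style
constants applied to gapped scores, so the E-values are a comparable
ranking statistic rather than BLAST-calibrated significances; only rank
order and thresholding matter downstream. `all_vs_all()` prunes the
quadratic pair set with an exact k-mer prescreen (default: share at least
one 4-mer) before aligning; detectable homologs virtually always share
short exact words, and `prescreen = FALSE` restores the fully exhaustive
contract. A guard refuses more than 20,000 sequences, pointing at external
alignment instead.

## The typed homology graph

Edges are typed by the OrthoMCL-family rules, fixed here as a deterministic
contract:

* **ortholog** — inter-genome pair `(a, b)` where each is among the other's
  best hits in the partner genome (minimal E-value per target genome;
  co-best ties at 15 significant digits are all kept);
* **in-paralog** — within-genome pair whose two directed E-values are below
  the cutoff and strictly smaller than each member's worst inter-genome
  E-value (a gene with no inter-genome hits contributes +Inf, so purely
  genome-private pairs qualify);
* **co-ortholog** — inter-genome pair connected through an in-paralog of an
  ortholog, with both directed hits present at the cutoff.

Edge weight is the average of the two directed `-log10 E` values, with
E = 0 capped at 316 and each term floored at `1e-3` — the floor matters
only at sweep cutoffs above E = 1, where `-log10` would otherwise go
negative. Weights are then normalized by the mean of their (genome pair,
edge type) class, so every non-empty class has mean 1; this keeps closely
related genome pairs from dominating the clustering.

The in-paralog dominance threshold takes the *worst* (largest) inter-genome
E-value per gene and combines the two genes with `min`. The consequence,
intended, is that within-genome pairs whose divergence predates the
speciations — pairs roughly as distant from each other as from their
cross-genome counterparts — are left untyped, and ancient paralogs resolve
into separate orthologous groups.

## Markov clustering

`mcl_cluster()` is a from-scratch sparse implementation. The adjacency
matrix (normalized weights, self-loop per node equal to its maximum
incident weight, 1 for isolated nodes) is column-normalized and iterated:
expansion (matrix squaring) followed by inflation (entry-wise power `r`,
pruning of entries below `1e-5`, column renormalization) until the largest
entry change drops below `1e-8` or 100 iterations pass (non-convergence is
flagged, not fatal). Clusters are read from the attractor structure:
attractors are nodes with positive converged diagonal, attractor systems
are connected components of the attractor–attractor support, and every
remaining node joins the system holding its highest attraction weight
(ties resolved toward the system with the lexicographically smallest
attractor id, so results are reproducible under any input order). The test
suite checks this implementation against an independent dense reference on
all small fixtures and verifies that every column stays stochastic to
1e-9 after each inflation step.

Inflation controls granularity — larger `r` gives tighter clusters — and
the conventional grid is swept by `mcl_sweep()`: cutoffs
10, 1, 0.1, …, 1e-10 by inflations 1.0, 1.5, 2.0, with E = 1e-5 and
r = 1.5 as the working default. Group counts report clusters with at
least two members; singletons are accounted separately throughout, and
genes absent from the graph (no retained hits) re-enter as singleton
families before labelling.

## Families and the pan-genome

Families are labelled `strep1001`, `strep1002`, … in descending size (ties
by smallest member id), four digits wide until 9999 and widened after.
With copy matrix `C` (genomes × families), a family is *core* if present
in every genome, *unique* if present in exactly one (subdivided into
multi-copy lineage-unique-LSE families and single-gene singletons) and
*dispensable* otherwise. Presence means copy count ≥ 1, and plasmid genes
count toward their genome. Per-genome core percentage is
`100 × core genes / total genes`, reported to 2 decimals.

## Lineage-specific expansions and their chromosomal patterns

Every (family, genome) cell with ≥ 2 copies is an LSE call —
*lineage-unique* when the family is private to that genome, *typical*
otherwise. The per-genome summary mirrors the usual published table:
lineage-unique family and gene counts, typical family count, total LSE
genes and their percentage of the genome; `lse_size_distribution()` bins
family sizes at 2…10 and ≥ 11.

**Tandem arrays** are maximal runs of ≥ 2 consecutive loci sharing a
family, per replicon, strand ignored.

**Duplicated blocks** are found per genome by anchor chaining: anchors are
within-genome same-family gene pairs; chains require consecutive anchors
to advance on both intervals (forward) or advance/retreat (inverted) with
at most `max_gap` interleaved genes per side (default 3 — the published
examples of gapped inverted copies need gap tolerance; the method family
states no explicit value). Chains are scored by anchor count and
extracted greedily in descending score, ties resolved toward the leftmost
first interval, and each gene participates in one extracted chain.
Interval disjointness is enforced exactly: inverted chains are
intrinsically disjoint, while forward chains constrain the admissible
anchor set per starting anchor, handled by a per-start longest-path pass
whenever the unconstrained optimum would overlap. Chains that merely
restate a tandem array (single family, span inside one run) are
suppressed, since those belong to the tandem report. The implementation is
tested for exact equality against an exhaustive chain-enumeration oracle
on small layouts, including the forward-cassette and inverted-gapped
geometries.

`flag_terminal()` marks blocks with either interval entirely inside the
first or last `terminal_fraction` of its replicon's gene count (default
0.1). This is a coordinate proxy for the terminal inverted repeats of
linear chromosomes; true TIR boundaries would need repeat annotations that
are out of scope, so the fraction is exposed as a parameter. The same
windows define the "central region" used by `central_fraction()` for
signature genes.

## Signature screening and GO tabulation

`screen_signature()` reads the screening criteria literally: an outgroup
hit is acceptable iff `E < 1e-5` **and** identity `> 30` **and** query
coverage `> 0.5`, all strict, and a family is signature iff no member has
an acceptable hit. "Similarity" is mapped to percent identity and
"coverage" to query coverage (the subject-coverage reading is equally
consistent with the wording; query coverage was chosen and documented).
Producing the outgroup hit table — including excluding the genus of
interest — is the caller's responsibility. GO annotation stays at direct
GAF assignments (`NOT` rows skipped); family term sets are unions over
members with no ancestor propagation, since published per-category family
counts behave like direct-annotation tallies, and `go_tabulate()` counts
subset families per requested term, reporting zeros rather than omitting.

## The synthetic generator and what passing tests mean

`simulate_genomes()` evolves a set of ancestral single-copy families (200
by default, protein lengths uniform on 80–150, residues uniform) down a
balanced 5-taxon tree. Per branch, each gene is lost with probability
0.05 and duplicated with probability 0.02 (half of the copies placed
immediately downstream — tandem — and half at random positions); block
duplications start at each gene with probability 0.002, copy a geometric
length of mean 3 (minimum 2, inverted with probability 0.5) to a position
outside the source span; novel single-gene families arrive as a Poisson
influx of mean 2 per branch; and each site substitutes with probability
0.03 to a uniformly chosen alternative residue. These defaults were chosen
once as a realistic regime for a five-genome bacterial comparison —
roughly a fifth of each genome in multi-copy families, most LSE families
at two copies, divergence low enough that homologs stay alignable — and
give genomes of roughly 200 genes each, i.e. full runs of about 1,000
genes, which the whole pipeline processes in well under a minute per
replicate.

The ground truth records the event log (replayable per leaf to the exact
per-family copy counts, which a test verifies), the true family label per
gene, true duplicated blocks (template and copy gene sets per surviving
event) and true tandem arrays. The tandem truth distinguishes
*lineage-specific* arrays — those containing at least one copy minted on
the genome's terminal branch — from the full adjacency list
(`tandem_all`): arrays formed before the last speciation are shared
between genomes, are not lineage-specific expansions, and the orthograph
rules above split their members into separate orthogroups by design.
Recovery recall is therefore measured on the lineage-specific set, while
precision is judged against every true array.

What the simulator does *not* emulate: insertions/deletions within
proteins, empirical substitution matrices, codon-level or GC-content
effects, rearrangements other than duplication-insertion, pseudogenes, and
multi-replicon genomes by default (one chromosome per genome; the gene
table and all detectors handle additional replicons). Passing the
recovery tests therefore shows the inference chain is correct and
well-calibrated under divergence-only noise; it does not certify
performance on real proteomes, where alignment statistics, domain
shuffling and annotation artifacts add failure modes the generator cannot
produce.

## Numerical and degenerate-input choices

* E-value ties for "best hit" are compared at 15 significant digits;
  co-best subjects are all kept.
* E = 0 maps to `-log10 E = 316` (just beyond the double-precision
  floor); terms are floored at `1e-3` so loose-cutoff edges keep positive
  weight.
* Empty similarity graphs, edgeless nodes and extinct simulated genomes
  are all legal: isolated genes become singleton clusters, and an extinct
  genome is emitted empty with a warning.
* MCL non-convergence at `max_iter` flags the result instead of failing;
  all fixtures converge in far fewer than 100 iterations.
* Chain extraction tie-breaks (leftmost first interval, then second
  interval, forward before inverted) make block detection invariant to
  input order; a dedicated test checks invariance of block calls under
  whole-replicon coordinate reversal.

## Known limitations

* The built-in aligner's E-values are not BLAST-calibrated; absolute
  cutoff semantics differ from a real BLASTP run, though ordering and the
  sweep's monotone structure carry over.
* Orthograph construction follows one fixed reconstruction of the
  OrthoMCL rules (v1-style weights, per-class normalization); other
  normalizations would shift cluster boundaries for borderline pairs.
* Block detection chains anchors within genomes only; inter-genome synteny
  is out of scope.
* The terminal-region flag is a positional proxy, not a repeat-based TIR
  annotation.
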