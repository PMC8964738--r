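---
title: "Ranking CRISPR resistance hits by multi-objective optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking CRISPR resistance hits by multi-objective optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprank)
```

## The problem

A genome-wide pooled CRISPR resistance screen in EGFR-mutant lung cancer
cells, treated with an EGFR inhibitor such as gefitinib or osimertinib,
typically returns hundreds to thousands of statistically enriched genes.
Only a handful can be followed up at the bench. The triage that selects
them has traditionally been manual: experts weigh screen statistics against
literature support, clinical evidence, druggability and network context.
crisprank formalises that triage as a multi-objective optimisation problem.

Each line of evidence about a gene becomes one objective $f_i(x)$; the gene
$x$ lives in the decision space spanned by a gene-by-feature table. A gene
$x_1$ *dominates* $x_2$ when it is at least as good on every objective
(respecting each objective's direction) and strictly better on at least
one. Genes dominated by nobody form Pareto level 1 — the recommended set of
best trade-offs. Peeling level 1 away and repeating yields levels
$2, \dots, n$. There is no scalarisation and no weighting: a gene earns its
recommendation by being unimprovable, not by scoring well on a weighted
average.

## Screen desirability and hit calling

The screen contributes two comparisons per condition: Control vs Treated
(CvT), which carries the resistance signal, and Control vs Plasmid (CvP),
which carries essentiality information. (Treated vs Plasmid is ingested for
completeness but does not enter the default aggregation.) Four partial
desirability curves summarise a gene's CvT/CvP statistics, each mapping
into $[0,1]$:

* **FDR gate** — `d_fdr()`: 1 when the CvT FDR is at most 0.1, else 0. A
  hard gate: because the aggregate is a geometric mean, failing it zeroes
  the gene.
* **p-value curve** — `d_pvalue()`: 0.01 above p = 0.1, 1 at or below
  p = 1e-4, and in between a power curve on the $-\log_{10}$ axis,
  $d = 0.01 + 0.99\,t^{\text{shape}}$ with $t$ the normalised log-distance
  from the 0.1 end. The exponent (default 2) controls how fast the curve
  rises; it is exposed because the qualitative requirement — "rises quickly
  towards 1" — admits a family of curves. The 0.01 floor keeps weak
  p-values from annihilating the aggregate outright, unlike the FDR gate.
* **effect size** — `d_lfc()`: a step at the distribution-derived boundary
  `mean(LFC) + 3 sd(LFC)` (sample SD; the sensitivity analysis flips to
  $-3$ SD). At-boundary values take the favourable branch; a smoothed
  logistic variant is available behind `smooth = TRUE` for users who prefer
  a soft margin.
* **essentiality filter** — `d_essentiality()`: zero for genes called
  essential in both CvP and CvT, or with negative CvT LFC. This removes the
  classic false positive where knocking out a slow essential gene merely
  makes treated cells die slower than controls.

`overall_desirability()` aggregates the components as an equally weighted
geometric mean (weights are exposed but default equal, since nothing in the
method's definition privileges one component). A gene is a **hit** in a
condition when its overall desirability exceeds 0.7 and its CvT
positive-selection FDR is below 0.1 — both strict, as stated.

Hits across conditions are folded into exactly seven consistency features:
per technology (knock-out and activation) the number of hit conditions,
distinct hit cell lines and distinct hit treatments, plus `full_screen`,
the number of distinct cell lines hit in either technology. The 3 + 3 + 1
split is this package's concretisation of "three features per screen arm
plus one summary"; the counts themselves are what the published feature
set fixes.

### Boundary conventions

Equalities favour the gene everywhere: FDR exactly 0.1 passes the gate, an
LFC exactly on the boundary scores 1, a dependency fraction of exactly 90%
is essential. The original rules use open phrasing ("higher than",
"lower"), leaving ties unspecified; resolving them towards the favourable
branch makes the favourable sets closed, which is the convention easiest
to state and test.

## Graph features

The knowledge graph is a typed edge list (Hetionet-style). Features follow
a deliberate scope split: descriptive structure (degree, unique
neighbours) and embeddings are computed on the **full** heterogeneous
graph, while PageRank and betweenness are computed on the **PPI subgraph**
(the `interacts` relation, treated undirected), where centrality has a
mechanistic interpretation. Both scopes are available through
`centrality_scope` in `kg_feature_table()`.

PageRank uses power iteration with damping 0.85, L1 tolerance 1e-9, at
most 200 iterations (standard defaults; non-convergence is an error, not a
silent partial result). Betweenness is exact Brandes betweenness,
unnormalised, endpoints excluded; the test-suite cross-checks it against
an exhaustive all-shortest-paths enumeration on small graphs.

Embeddings come from RESCAL: the per-relation adjacency tensor is
factorised as $X_k \approx A R_k A^\top$ by alternating least squares with
ridge penalty $\lambda$ (default 0.01) and seeded uniform$(-1,1)$
initialisation. The $R_k$ update is an exact ridge solve, so it can never
increase the penalised loss; the $A$ update is guarded by backtracking —
a candidate that would increase the loss is shrunk towards the current
factor until the loss decreases. The recorded loss sequence is therefore
monotone non-increasing by construction, which is also what the tests
assert. Rank defaults to 8 at desk scale; at this scale ALS recovers a
noiseless low-rank tensor to numerical precision.

Relevance to the disease context is expressed as L2 distance in embedding
space from each gene to the anchor entities `EGFR` and `NSCLC`, computed
exactly (no approximate search is needed at desk scale). By default the
embedding vectors are L2-normalised first: raw RESCAL vector norms grow
with node degree, so unnormalised distances conflate *how connected* a
node is with *how it is connected*. On the unit sphere the distance
compares connectivity patterns, which is the quantity of interest;
`normalize = FALSE` restores raw Euclidean distances for users who want
them.

## Literature, clinical, tractability, essentiality

* **Literature** — the corpus arrives pre-abstracted as documents with
  entity-mention sets. For each gene and key term (`EGFR`, `NSCLC`) the
  package counts co-mentioning documents and a normalised frequency:
  co-mentions divided by the gene's total mention count. The per-gene
  denominator is chosen because publication volume varies by orders of
  magnitude between genes; the normalised metric asks "of the papers about
  this gene, what fraction touch the context?". A gene co-occurrence
  matrix (`cooccurrence_matrix()`) supports cluster exploration. Year
  filtering (2000–2019 in the emulated corpus) is a configurable filter,
  not hard-coded.
* **Clinical** — a responder is a patient with RECIST CR or PR *and*
  PFS > 6 months (strict). Per trial — never pooled, since panels differ —
  the enrichment score of a gene is
  $\log_2\frac{\text{prev}_{\text{non-resp}} + \varepsilon}
  {\text{prev}_{\text{resp}} + \varepsilon}$ with pseudocount
  $\varepsilon = 0.01$. The exact functional form of a prevalence contrast
  is a design choice; a log ratio with a documented pseudocount keeps the
  score finite, sign-interpretable (positive = enriched in non-responders
  = resistance-associated) and antisymmetric under group swap at
  $\varepsilon = 0$. The raw 2×2 counts are always emitted alongside so any
  alternative statistic can be recomputed.
* **Tractability** — ordinal buckets (bucket 1 = most druggable) are
  reversed to scores via $(\text{max}+1) - b$, so the most druggable
  bucket scores 10 and the reversal is an involution.
* **Essentiality** — a gene is flagged essential when at least 90% of the
  dependency panel's cell lines depend on it. In the feature table the
  flag is encoded as `nonessential` $\in \{0, 1\}$ so that, like every
  other column, larger is more attractive.

## Preferences, missing values and ranking

A preference is an ordered set of (objective, direction) pairs, read from
YAML/JSON. The shipped default carries ten objectives — `full_screen`,
`RNASeq_LFC`, `clinical_ES1..3`, `lit_EGFR`, `lit_NSCLC`, `pagerank`,
`betweenness`, `RNASeq_pval` — all set to maximize. The all-maximize
default reflects the resistance framing in which every listed feature is
evidence *for* a gene; it is deliberately crude for `RNASeq_pval` (a small
p-value is stronger evidence), and users are expected to override
directions per analysis. Nothing in the ranking machinery privileges the
default.

Dominance is undefined on missing coordinates, so genes missing any
selected objective are excluded from ranking with a warning listing them —
the conservative default. `missing = "impute_worst"` substitutes the worst
observed value per objective instead, which keeps the gene rankable while
guaranteeing imputation can only hurt it.

Output order is deterministic: Pareto level, then optional user-chosen
sort-within features (direction-corrected descending), then gene id. Two
genes with identical objective vectors are mutually non-dominating and
share a level. The engine is the repeated-peeling non-dominated sort; at
desk scale (thousands of genes, ~10 objectives) its $O(n^2 k)$ worst case
is comfortable, and the test-suite proves it equivalent to a brute-force
pairwise-dominance oracle on hundreds of random instances.

## The synthetic study

`synthetic_spec()` fixes the simulated study conditions: 500 genes of
which 5 are planted resistance drivers, screened across the
PC-9/HCC827 × gefitinib/osimertinib × KO/activation grid (8 conditions),
with a 300-document corpus, three 100-patient trials and a ~500-node
knowledge graph (Erdős–Rényi background at p = 0.01 over three relation
types, plus a dense planted cluster containing the anchors and the planted
genes at p = 0.9). Null screen statistics are LFC ~ N(0,1), p ~ U(0,1)
with Benjamini–Hochberg FDRs — BH stands in for the screen tools' native
FDRs because only the *consumption* of an FDR column is under test.
Planted genes sit 4 null SDs above the null LFC mean (safely beyond the
3-SD boundary; the multiple is configurable to probe boundary behaviour),
carry p ≤ 1e-5, are never essential, are upregulated in the transcriptomic
contrast, are altered with a +0.3 prevalence gap in non-responders, and are
mentioned alongside the anchors at 0.3 per document against a 0.02 null
rate.

One spec-level seed feeds independent per-generator substreams, so any
single input can be regenerated in isolation without disturbing the
others. Every generator emits a ground-truth sidecar (planted genes,
cluster membership, realised co-mention counts, intended responder
labels), and downstream checks read truth from the sidecars.

What the generator does *not* emulate: guide-level count distributions,
realistic scale-free KG degree structure, panel differences between
trials, or correlated evidence between modalities. Passing the planted
recovery suite therefore demonstrates that the machinery ranks concordant
multi-modal signal to the front — not that any particular real screen's
biology would be recovered.

Problem sizes for the validation suites were chosen to make each property
statistically decisive at desk scale: 500 random instances up to 200
points × 5 objectives for the Pareto oracle equivalence, 20 seeds of the
default 500-gene study for end-to-end planted recovery, 20-node tensors
for exact RESCAL recovery.

## Worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 42)
gu <- synthetic_genes(spec)
ann <- generate_annotations(spec)
ft <- assemble_feature_table(
  screens = generate_screen(spec), kg = generate_kg(spec),
  corpus = generate_corpus(spec), cohort = generate_cohort(spec),
  rnaseq = generate_rnaseq(spec), tractability = ann$tractability,
  essentiality = ann$essentiality)
ranked <- rank_genes(ft, default_preference())
all(gu$planted %in% ranked$gene[ranked$pareto_level == 1])
```

The same pipeline is scriptable from the shell through
`inst/cli/crisprank.R` (`simulate`, `features`, `rank` subcommands), which
adds provenance manifests with input checksums and the documented exit-code
contract (0 success, 2 usage error, 1 runtime failure).

## Known limitations

* The published 57-gene list of the study this framework emulates depends
  on an externally hosted feature table; `external_benchmark()` reruns the
  ranking given a downloaded copy but the package makes no claim of
  bit-compatibility with the original interface's defaults, whose exact
  objective directions are not public.
* Pareto fronts widen quickly with objective count; with ten objectives a
  level-1 set of hundreds of genes is normal, and the intended workflow is
  to sharpen the preference (fewer objectives, explicit directions,
  `sort_within`) rather than to read the front as a ranking.
* Enrichment scores from small trials are noisy and the pseudocount biases
  them towards zero; the emitted 2×2 counts should be consulted before
  acting on any single score.
* RESCAL embeddings are reproducible only given the seed; different seeds
  give equally good but non-identical geometries, so distances should be
  consumed ordinally, not as absolute values.
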