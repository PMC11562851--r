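---
title: "Linking shared disease genetics to drugs by network propagation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking shared disease genetics to drugs by network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the propagation model, the permutation null, the multiple-testing
structure, the synthetic-data generator, and the numerical and design
choices made where conventions are genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The pipeline in one paragraph

For each pair (target disease, predisposing disease) the input is a set
of genomic loci where SNP effects are locally correlated between the two
GWAS, plus gene-level association statistics (MAGMA-style) and signed
gene-regulation statistics (S-MultiXcan-style) for both diseases.
Shared genes are the protein-coding genes positionally inside positively
correlated loci that survive a gene-association filter and a
direction-concordance filter. Each shared gene then seeds a personalized
PageRank (PPR) walk on a confidence-filtered protein–protein interaction
network; pathways whose members receive high average scores relative to
a degree-matched permutation null are the shared canonical pathways.
Drug targets are propagated through the identical machinery against
those pathways, drugs with a significantly linked target become
repurposing candidates, and the candidate list is evaluated against an
external list of investigated/approved drugs with a one-sided Fisher
exact test.

## Propagation model

The score vector from seed gene $g$ solves

$$ s = \alpha\, e_g + (1-\alpha)\, W^\top s, \qquad W = D^{-1} A , $$

where $A$ is the 0/1 adjacency of the undirected network, $D$ the degree
matrix, and $\alpha$ the probability of returning to the seed at each
step.

* **Restart $\alpha = 0.8$ (default).** The restart probability is
  deliberately taken literally, not converted to the more common
  PageRank damping convention ($0.85$ *continue* probability, i.e.
  restart $0.15$). A large restart concentrates mass near the seed, so
  the statistic measures *local* connectivity to the pathway rather than
  global centrality. The parameter is exposed in `ppr_params()`;
  sensitivity across $\alpha \in \{0.15, 0.2, 0.8, 0.85\}$ is easy to
  explore and the two-node closed form $s(\text{seed}) = 1/(2-\alpha)$
  in the test suite pins the convention.
* **Unweighted edges.** Confidence scores are used only as a filter
  (combined score $\ge 700$ on STRING's 0–1000 scale); the walk itself
  treats surviving edges as binary. Weighting the walk by residual
  confidence is a different estimator and deliberately out of scope.
* **Numerics.** Power iteration with an $L_1$ tolerance of $10^{-10}$;
  the error contracts by a factor $(1-\alpha)$ per sweep, so at
  $\alpha = 0.8$ convergence takes $\sim 15$ iterations regardless of
  network size. Equivalence with a direct linear solve is enforced to
  $10^{-8}$ on random graphs in the tests. Isolated nodes cannot arise
  from an edge-built network; should one appear, its walk mass teleports
  back to the seed.

The pathway statistic is the arithmetic mean of $s$ over the pathway's
(network-restricted) members. When the seed is itself a member, its own
score is included: that is the natural reading of "average score of the
genes in the pathway", and the self-score is informative (it encodes how
much mass the seed retains vs. spreads). A flag in `ppr_params()`
switches this off.

## Permutation null and significance

Genes are grouped into four degree-quartile bins. Binning is by degree
*value* (quantile breakpoints, ties always share a bin), not by sorted
rank: with rank-splitting, two genes of identical degree could land in
different bins, which contradicts the point of degree matching. When
fewer than four distinct quartile boundaries exist the bins degenerate
gracefully (down to one bin for a regular graph) with a warning.

For a (seed, pathway) pair, `n_perm` (default 1,000) permuted seeds are
drawn *with replacement* from the seed's bin, excluding the seed itself;
a bin containing only the seed falls back to the nearest bin with a
warning. Two empirical p-values are reported from the count $c$ of
permuted means at or above the observed mean:

* `p_raw` $= c/N$ — the plain frequency ("how often the observed score
  is at or below the permuted scores"); it can reach zero;
* `p_perm` $= (1+c)/(1+N)$ — the add-one estimator, a conservative,
  never-zero upper bound.

**The significance decision uses the frequency estimator.** The
Bonferroni family of the gene stage is (#seeds × #pathways), which is
hundreds at desk scale and $\sim 7\times 10^5$ at biobank scale. Under
the add-one estimator the smallest attainable adjusted p-value is
$m/(N+1)$, which exceeds 1 whenever the family outgrows the permutation
count — no pair could ever be significant and the method would be
vacuously empty. The frequency estimator reaches zero exactly when the
observed connectivity beats every permutation, which is the event the
test is designed to detect; the add-one value is reported alongside as
the honest finite-sample bound. Calibration of `p_perm` under the null
(fraction $\le 0.05$ within the binomial band around $0.05$) is part of
the acceptance tests.

Reproducibility: every (seed gene, pathway) pair derives its own RNG
substream from a stable hash of `(rng_seed, seed, pathway)`, so linkage
tables are identical regardless of evaluation order, subsetting, or
parallel scheduling, and a target shared by several drugs is computed
once with one answer.

### Multiple-testing structure

* Gene stage: $p_{\text{adj}} = \min(1,\ p \times |\text{seeds}| \times
  |\text{pathways}|)$ per disease pair; a pathway is *shared* when at
  least one seed reaches $p_{\text{adj}} < 0.05$ (strict).
* Drug stage: the family is the number of distinct in-network targets
  tested for the predisposing disease. The shared-pathway set is fixed
  by stage one and is not counted again — the stage-two hypotheses are
  "is this target connected to the already-established shared biology",
  not a fresh scan over all pathways. The family size is overridable
  (`family_size`) for callers who prefer the stricter product.

## Shared-gene filters

* Coordinates are 1-based with intervals inclusive at both ends
  throughout; overlap means at least one shared base.
* The ±10 kb positional window is inclusive: a gap of exactly 10,000 bp
  still maps, 10,001 bp does not. The boundary is pinned by generated
  boundary genes in the synthetic bundle and by unit tests.
* Mapping uses locus intervals directly rather than per-SNP lists. A
  SNP-based mapping through all SNPs inside a locus is equivalent up to
  SNP density; the interval form is deterministic without a reference
  panel.
* The BH family for the gene-association filter is every gene in the
  disease's gene-based output (genome-wide), not only locus genes, and
  the threshold is strict (`p_adjusted < 0.05`).
* Direction concordance requires equal, non-zero signs of the two
  regulation statistics; $z = 0$ carries no direction and is treated as
  discordant. Genes missing either statistic are dropped with a recorded
  reason. (The canonical cautionary example: a gene upregulated in the
  predisposing disease but downregulated in the target disease is not a
  useful inhibition target, however strong its association signal.)
* The imputation-quality filter (INFO ≥ 0.3) applies only when the
  column exists, since most GWAS do not ship one.
* Only positively correlated loci enter by default: genes under
  negatively correlated loci act in opposite directions in the two
  diseases and do not support same-direction therapeutic reasoning.

## Enrichment evaluation

The candidate list is compared with the external drug list over the full
universe of drugs indicated for the predisposing diseases — including
drugs with no network-mapped targets, which can never become candidates
but belong in the denominator. The one-sided p-value is the exact upper
hypergeometric tail $P(X \ge a)$ given the table margins. Two odds
ratios are reported: the conditional MLE $\hat\psi$ solving
$E_\psi[X] = a$ under Fisher's noncentral hypergeometric distribution
(the estimate standard Fisher-test implementations print, computed here
by a monotone root-solve and cross-checked in tests against both
`fisher.test` and a grid-search likelihood oracle), and the sample
cross-product $ad/bc$ (infinite when $bc = 0$). The CMLE shrinks toward
1 relative to the cross-product; both are emitted so readers can compare
against either convention.

## The synthetic-data generator

`simulate_inputs()` writes every input format the pipeline consumes —
STRING-style links and alias files (including sub-threshold edges,
duplicates, self-loops and unmapped proteins, so loader filters are
exercised, not just trusted), a GMT file, per-pair locus /
gene-association / regulation tables, and drug tables — with a planted
causal structure:

* Two disease pairs, three planted pathway modules per pair. Each module
  is a dense subgraph (within-module edge probability 0.4, topped up so
  every member keeps ≥ 5 within-module edges) whose members form a GMT
  pathway; the dense wiring places all module cores in the top degree
  bin.
* One low-degree **anchor** gene per module, wired into the core by
  three edges. Anchors are the planted shared genes *and* the
  true-positive drug targets (several drugs sharing one target is
  pharmacologically ordinary — think of the statins all targeting
  HMGCR). The degree separation between anchors (middle bin) and cores
  (top bin) is what makes the planted signal recoverable at desk scale:
  with 2,000 genes and 1,000 draws the permutation effectively
  exhausts a bin, so a planted seed must be the strongest gene of its
  bin for its pathway, and that is only structurally guaranteed when
  its equally-connected module partners live in a different bin. This
  mirrors the real-data situation of a peripheral disease gene feeding
  into a dense functional module rather than sitting at its center.
* Per pair, shared-gene planting follows `frac_planted`: anchors plus
  ordinary locus genes that pass the statistical filters but carry no
  network signal. Decoys pin each filter: a sign-discordant gene inside
  a positive locus, a passing gene inside a *negative* locus, boundary
  genes at gaps of exactly 10,000 and 10,001 bp, and null fillers in
  every locus.
* Drugs: 12 true positives targeting anchors, decoys targeting random
  unrelated genes, three decoys with only off-network targets; the
  external "investigated/approved" list contains 10 true positives and
  2 decoys, so the enrichment evaluation has planted signal and planted
  noise.

Defaults (2,000 genes, 100 pathways of 10–50 genes, 60 drugs, 8 positive
loci per pair, 1,000 permutations) keep a full pipeline run around a few
seconds while loosely mirroring the shape of the real inputs. Identical
configurations produce byte-identical files.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: linkage disequilibrium and the
local-correlation scan itself (locus tables are drawn, not scanned);
realistic pharmacology or polypharmacy; the real network's size (16k
nodes, 240k edges) and its correlated annotation biases; literature
curation of predisposing diseases. Recovering planted signal shows the
machinery is correct and calibrated, not that any particular real drug
recommendation is right.

## Problem sizes used for validation

The acceptance tests run the solver-oracle comparison on 100 random
graphs of up to 50 nodes, null calibration with 500 replicates at 200
permutations on the default 2,000-gene network, and planted-signal
recovery over 20 generator seeds at full defaults; the published-counts
Fisher check uses the printed 112/74/16/15 margins directly. These sizes
were chosen to give stable Monte-Carlo bands at interactive runtimes.

## Known limitations

* Pathway collections are redundant; overlapping gene sets are tested
  as-is and Bonferroni pays for the redundancy. Semantic deduplication
  is out of scope.
* The statistic uses membership only, not pathway topology.
* Region-based positional mapping can differ from per-SNP mapping at
  loci with very uneven SNP density.
* The drug-stage Bonferroni family reading ("number of targets tested")
  is the literal one; multiplying additionally by the number of shared
  pathways would be stricter, and is available via `family_size`.
* Propagation on the unweighted graph ignores residual confidence
  differences among retained edges.
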