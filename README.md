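# pleiodrug

Drug repurposing from the shared genetics of a target disease and the
diseases that predispose to it.

## The problem

Several common conditions — depression, high HDL/LDL cholesterol,
prostate cancer, schizophrenia, type 2 diabetes — raise the risk of
breast cancer, and part of that link is genetic. If a predisposing
disease contributes to breast-cancer pathology through pleiotropic
genes, then among all drugs already approved for the predisposing
disease, the ones acting on that shared biology are promising
repurposing candidates — with known safety profiles and, crucially, a
mechanistic story (gene → pathway → drug target) attached to each
recommendation.

`pleiodrug` implements that reasoning as a tested pipeline for anyone
with GWAS summary-level derivatives and a drug–target table:

1. **Shared genes.** Starting from locally correlated genomic loci for a
   disease pair (e.g. a LOGODetect-style scan), keep protein-coding genes
   positionally located within *positively* correlated loci (±10 kb,
   inclusive), that are significantly associated with the predisposing
   disease (gene-based p-values, Benjamini–Hochberg adjusted < 0.05) and
   predicted to be dysregulated in the *same direction* in both diseases
   (sign concordance of S-MultiXcan-style z-scores).
2. **Shared pathways.** On a STRING-style protein–protein interaction
   network (combined score ≥ 700, deduplicated, Entrez-mapped), compute
   personalized PageRank from each shared gene *g*: the fixed point of

   *s* = α·e(g) + (1 − α)·Wᵀ·s,  with restart α = 0.8 and W the
   row-stochastic transition matrix of the undirected graph.

   For each canonical pathway *P* (MSigDB-style GMT, restricted to the
   network) the statistic is the mean score over members,
   s̄(g, P) = (1/|P|) Σ_{v∈P} s(v). Its null distribution comes from 1,000
   permuted seeds drawn from the same degree quartile as *g*; the
   permutation p-value is Bonferroni-corrected for (#shared genes ×
   #pathways). Pathways significant for ≥ 1 shared gene are the *shared
   canonical pathways*.
3. **Candidate drugs.** The same machinery links each drug target to the
   shared pathways (Bonferroni family: #targets tested for the disease).
   A drug indicated for the predisposing disease with ≥ 1 target
   significantly linked to ≥ 1 shared pathway is a candidate, and every
   significant (drug, target, pathway) triple becomes an evidence chain
   back to the supporting shared genes.
4. **Evaluation.** Candidates are tested for overlap with drugs already
   investigated or approved for the target disease using a one-sided
   Fisher exact test: the upper hypergeometric tail p-value and the
   conditional maximum-likelihood odds ratio (the estimate `fisher.test`
   reports), alongside the sample cross-product ratio.

A first-class synthetic-data module (`synthetic_config()`,
`simulate_inputs()`) emulates every input format — STRING links/aliases,
GMT gene sets, locus tables, MAGMA-style and S-MultiXcan-style
statistics, drug tables — with planted gene → pathway → drug signal, so
the entire pipeline is testable offline.

## Worked example

```r
library(pleiodrug)

## a complete synthetic input bundle with planted signal
config <- simulate_inputs(synthetic_config(seed = 1), "syn_demo")
run <- run_pipeline(config, write_output = FALSE)
run
#> <pleiodrug_run>
#>   pairs: PD1, PD2
#>   PD1: 6 shared gene(s), 3 shared pathway(s)
#>   PD2: 6 shared gene(s), 4 shared pathway(s)
#>   candidates: 13 of 60 drugs
#>   enrichment: p = 2.24e-07, OR(cmle) = 63.1

run$enrichment
#> <enrichment_result>
#>          bc_drug
#> candidate yes no
#>       yes  10  3
#>       no    2 45
#> one-sided exact p = 2.24e-07; OR (conditional MLE) = 63.1; OR (sample) = 75

head(run$chains[, .(drug_id, target, pathway, shared_genes, p_raw_adj)], 4)
#>      drug_id target         pathway shared_genes p_raw_adj
#> 1: SYNDB0001 100615 SYN_PW_PD2_MOD2       100615         0
#> 2: SYNDB0005 101102 SYN_PW_PD1_MOD2       101102         0
#> 3: SYNDB0005 101518 SYN_PW_PD1_MOD3       101518         0
#> 4: SYNDB0012 101348 SYN_PW_PD1_MOD1       101348         0
```

Reading the output: per disease pair the pipeline found 6 shared genes
and linked them to the planted pathway modules; 13 of 60 drugs were
prioritized, 10 of the 12 that appear on the synthetic "investigated or
approved" list, giving a 2×2 table whose one-sided exact p-value is
2.2e-07. Each chain row is one recommendation's mechanism: the drug's
target, the shared canonical pathway it is linked to, and the shared
gene(s) supporting that pathway.

Real data drop into the same entry point: a YAML configuration pointing
at STRING links/alias files, a GMT file, per disease-pair region /
gene-association / regulation tables, and drug tables (see
`?run_pipeline` for the schema).

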