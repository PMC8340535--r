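# medinet

Network-diffusion detection of multi-omics **mediators** — genes and proteins
that relay, via molecular interactions, the effects of per-tumor upstream
aberrations (somatic mutations, dysregulated miRNAs) to the downstream
molecular changes observed at the mRNA, protein and phosphosite level.

## The problem

Tumors of the same aetiology often carry *different* mutations that converge
functionally on the *same* downstream pathways. A gene can be a pivotal relay
of an oncogenic program — and a potential drug target — while being neither
mutated nor differentially expressed itself. Finding such mediators requires
integrating the genome, miRNome, transcriptome, proteome and phosphoproteome
of every tumor over a directed functional-interaction network, rather than
inspecting any single omics layer.

`medinet` is aimed at computational biologists who have, per tumor sample:

* a somatic mutation table (depth/VAF-filtered exome calls),
* per-layer differential tables (mRNA, miRNA, protein, phosphosite) versus
  matched controls, and
* a merged directed interaction network (e.g. Kegg + Signor + miRTarBase),

and want a cohort-level ranked list of mediator candidates with
permutation-based false-discovery control — plus a fully synthetic cohort
generator so the whole pipeline is testable without any external data.

## The method

Scoring works on the largest strongly connected component (SCC) of the
network, where a random walk has a unique stationary behaviour. With
`W` the row-stochastic transition matrix (uniform over out-edges) and
restart probability `β ∈ (0, 1]`, the insulated-diffusion operator is

```
F = β (I − (1 − β) W)⁻¹
```

Row `i` of `F` spreads node `i`'s signal over its reachable neighbourhood
with geometric decay. For each sample:

* `f` = mean of the **forward** operator's rows at the *upstream events*
  (mutated genes ∪ significantly DE miRNAs),
* `b` = mean of the **reverse-network** operator's rows at the *downstream
  events* (genes DE at RNA/protein/phospho after the layer-combination rule:
  protein-or-phospho significance wins; detected-but-unchanged protein
  evidence vetoes the RNA call; undetected proteins defer to RNA),
* combined score `c = f ⊙ b` — high only for genes that both receive the
  upstream signal and feed the downstream evidence.

Per-sample scores are ranked (1 = best, ties averaged) and integrated across
the cohort by median rank. Significance: event labels are permuted uniformly
within sample and category (genes onto genes, miRNAs onto miRNAs, sizes
preserved), the aggregated statistic is recomputed (10,000× by default), and
per-gene empirical p-values `p = (1 + #{null ≤ observed}) / (1 + n_perm)` are
Benjamini–Hochberg adjusted. The reported mediator set is the top 5% of the
cohort ranking with `q ≤ 0.05`.

## Worked example

Simulate a 12-tumor cohort on a 2,000-gene / 150-miRNA network with 10
planted mediators, score it, and run the permutation test:

```r
library(medinet)

cfg <- simulation_config(n_samples = 12, n_genes = 2000, n_mirnas = 150,
                         n_planted_mediators = 10, seed = 42)
net <- generate_network(cfg)
cohort <- simulate_cohort(net, cfg)
run <- score_cohort(cohort$network, cohort$mutations, cohort$layers, beta = 0.4)
result <- detect_mediators(run, n_perm = 500, seed = 43)
result
#> medinet_result: 93 mediators (top 5.0%, q <= 0.05, 500 permutations)
head(result$mediators[, c("gene", "agg_rank", "q")])
#>           gene agg_rank          q
#> 1     Gene0835      1.0 0.02959598
#> 2     Gene0036      7.5 0.02959598
#> 3 mmu-miR-0042      9.5 0.02959598
#> 4 mmu-miR-0034     12.0 0.02959598
#> 5 mmu-miR-0063     12.5 0.02959598
#> 6 mmu-miR-0057     14.5 0.02959598
recovery_metrics(run$ranking, cohort$truth, selected = result$mediators)
#> recall 1.0, precision 0.108, median cohort rank of planted mediators 27.5,
#> AUROC 0.983
```

Reading the output: 93 genes sit in the top 5% of the aggregated ranking with
permutation FDR `q ≤ 0.05`; all 10 planted mediators are among them (recall
1.0) and the planted set is almost perfectly separated from the rest of the
network (AUROC 0.98). `agg_rank` is the median across samples of the gene's
per-sample diffusion rank — the planted mediators occupy the very top.

A command-line interface covers the same flow
(`exec/medinet simulate | rank | permute | report | fixtures`); `fixtures`
recomputes the tallies of the packaged reference tables (157 somatic calls
across 12 tumor nodules with no recurrent passenger mutation; mean
dysregulated features per sample 4,348 mRNAs / 108 miRNAs / 2,389 proteins /
906 phosphosites; 12 of 74 mediators detectable from the transcriptome alone
and none from proteome or phosphoproteome alone).

## Package layout

* `R/network.R` — edge-table loading, SCC reduction, transition matrix,
  diffusion operators.
* `R/events.R` — mutation parsing/filtering, phosphosite collapse,
  layer-combination rule, per-sample event sets.
* `R/ranking.R` — per-sample bidirectional scores, rank aggregation,
  top-fraction selection.
* `R/permutation.R` — event-label permutation null, empirical p, BH FDR.
* `R/simulate.R` — synthetic network and cohort generator with planted
  ground truth.
* `R/report.R`, `R/cli.R`, `R/pipeline.R` — reference-table tallies, CLI,
  end-to-end drivers.
* `vignettes/medinet-methods.Rmd` — model assumptions, parameter choices,
  what the simulator does and does not emulate.
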