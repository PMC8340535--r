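---
title: "medinet: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medinet: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`medinet` ranks network genes by how well they *relay* per-tumor upstream
aberrations to downstream molecular evidence. The substrate is a directed
functional-interaction network over genes and miRNAs; "binding"/"complex"
interactions enter as edge pairs in both orientations, self-interactions are
discarded, and scoring is restricted to the largest strongly connected
component (SCC) so that the random walk below has a unique, well-behaved
solution on every row.

The walk is an insulated diffusion (random walk with restart). With the
row-stochastic transition matrix $W$ (uniform over out-edges) and restart
probability $\beta$,

$$F \;=\; \beta\,\bigl(I - (1-\beta)\,W\bigr)^{-1}
      \;=\; \beta \sum_{k\ge 0} (1-\beta)^k W^k ,$$

so row $i$ of $F$ is a probability distribution that decays geometrically
with path length from node $i$. Two operators are built: one on the network
as given (upstream signal flows *with* the edges) and one on the
edge-reversed network (downstream evidence flows *against* them). Reversal
happens **before** row-normalisation; this is deliberately not the transpose
of the forward operator, because out-degree normalisation after reversal is
what preserves the "evidence traces back to its regulators" reading.

Per sample, with upstream events $U$ (filtered somatically mutated genes and
significantly differentially expressed miRNAs) and downstream events $D$
(genes differential at RNA/protein/phosphosite level after the
layer-combination rule):

$$f = \tfrac1{|U|}\sum_{u\in U} F^{\text{fwd}}_{u\cdot},\qquad
  b = \tfrac1{|D|}\sum_{d\in D} F^{\text{rev}}_{d\cdot},\qquad
  c = f \odot b .$$

The element-wise product demands *both* signals: a gene scores highly only if
upstream causes flow into it and downstream consequences flow back onto it.
A sum would reward either signal alone; both alternatives remain available
(`combine = "sum"`, `"forward_only"`) for sensitivity analyses.

Genes are ranked per sample (rank 1 = best, ties averaged) and integrated
across samples by the **median rank** — robust to a single aberrant tumor in
a cohort of about a dozen; mean and sum aggregation are provided. The cohort
order breaks ties by mean combined score (descending), then node id, making
every run totally ordered and byte-reproducible.

## The layer-combination rule for downstream events

Protein-level evidence overrides transcript-level evidence wherever the
protein was measured:

| RNA | protein or phospho | downstream event? |
|-----|--------------------|-------------------|
| any | significant        | yes (via protein/phospho) |
| any | detected, not significant | no |
| significant | not detected | yes (via RNA) |
| otherwise | not detected | no |

The proteome and phosphoproteome are merged with OR before the rule is
applied, and a gene counts as phospho-significant if *any* of its sites is
(`collapse_phosphosites()`). A gene with ten non-significant sites is not an
event.

## Somatic variant filters

Records must have: tumor depth ≥ 10 reads, germline depth ≥ 5 reads,
supporting reads ≥ 3, tumor VAF at least 5× the germline VAF, and presence in
fewer than 2 panel-of-normals samples. Supporting reads are not a column of
the input dialect and are derived as `round(depth_tumor * vaf_tumor)` — the
only derivation possible from the printed fields. A record with germline VAF
0 passes the ratio filter (zero germline evidence is the strongest somatic
signal). Missing optional fields pass their specific filter. The filter is
monotone: relaxing any threshold never removes a survivor (property-tested).

## Permutation test and FDR

The null relabels events uniformly **within sample and within category**:
mutated-gene labels move onto gene nodes, DE-miRNA labels onto miRNA nodes,
downstream labels onto gene nodes, with per-category sizes preserved exactly
(asserted on every repetition). The diffusion operators are computed once and
reused; only the index sets change, so each repetition costs two matrix
products. For each gene, $p = (1 + \#\{\text{null agg} \le \text{observed
agg}\})/(1 + n_{\text{perm}})$ — the add-one estimator can never return 0,
which plain counting can, and 0 breaks Benjamini–Hochberg. "Better" is
defined on the aggregated cohort statistic (smaller median rank), because
p-values are reported per gene across the cohort. BH is implemented directly
(and cross-checked against `stats::p.adjust` in the tests). The mediator set
is the top `fraction` of the cohort order with $q \le$ `q_alpha`.

This per-gene null absorbs degree bias: hub genes rank highly under random
relabelling too, so their observed ranks must beat a much stronger null —
visible in practice as hubs with top cohort ranks but unremarkable p-values.

# Parameters that matter

| parameter | default | units / range | rationale |
|-----------|---------|---------------|-----------|
| `beta` | 0.4 | restart probability, (0, 1] | Walk length ~$1/\beta$ ≈ 2.5 steps matches the 1–2-hop regulatory reach of the event placement; the source method's family default. Configurable since the closed form is a design choice. |
| `alpha` | 0.05 | FDR threshold per layer | The ingestion contract for all differential tables (mRNA, miRNA, protein 5% FDR). |
| `fraction` | 0.05 | top share of the ranking | "Top 5%" reporting convention; 125 candidates on a 2,484-node SCC. |
| `q_alpha` | 0.05 | permutation FDR cut | Reported mediator sets exclude $q > 0.05$. |
| `n_perm` | 10,000 | repetitions | Floor $p = 1/(n+1)$; at 10,000 the BH step-up has ample resolution. Scaled runs use ≥ 500 (see limitations). |
| aggregation | median | — | Robust for ~12 samples; mean/sum available. |
| normalisation | row (out-degree) | — | Column-stochastic available behind `transition_matrix(orientation=)`; row is the default because it respects edge direction as "regulates". |

# The synthetic cohort generator

The generator states a 12-tumor world modelled on an engineered
two-tumor-suppressor liver cancer cohort: every tumor carries the same two
driver lesions, plus ~13 private passenger mutations (never shared between
tumors), ~27 differentially expressed miRNAs and ~1,000 downstream
differential genes per sample — one quarter of the full study's per-sample
differential scale, so the default test world runs in seconds. The network
is a directed Poisson($\bar d = 13$) random graph over 2,000 genes with 150
miRNA nodes wired into the SCC; mean out-degree 13 matches the density of
the curated network's strongly connected core (32,954 edges / 2,484 nodes).

Planted structure, from causes to consequences:

* **Drivers** are two high-out-degree genes, mutated in every sample.
* **Mediators** (10) are direct targets of the drivers with at least median
  out-degree — each mediator must be able to *receive* the driver signal in
  one hop and *emit* evidence of its own.
* **Downstream events** are drawn per mediator from its forward
  neighbourhood (70% direct targets, 30% two-hop), allocated evenly across
  mediators; the mediators themselves are also downstream events, reflecting
  that relays of an always-on driver program are typically dysregulated at
  some layer themselves.
* **DE miRNAs** are regulators of the mediators (direct preferred, two-hop
  fallback), allocated evenly.
* **Shared program + noise**: the signal portion of the miRNA and downstream
  sets is drawn once per cohort and shared by all samples — tumors of one
  aetiology show commonly dysregulated features — while a `noise_fraction`
  (default 0.3) of each set is redrawn uniformly per sample, and passengers
  are always private noise.

Differential tables emit adjusted p-values directly (below/above
$\alpha = 0.05$), with evidence routes chosen per event to exercise the
combination rule: protein-significant, phospho-significant (1–5 sites per
gene, ≥ 1 significant), or RNA-significant-with-undetected-protein. Decoy
genes with significant RNA but detected-unchanged protein are sprinkled in;
the rule must veto them.

**What a green test establishes — and what it does not.** The generator
emulates network-mediated convergence, cohort consistency, private
passengers and the ingestion dialects. It does **not** emulate read-count
noise (DE calling is out of scope; significance calls are emitted directly),
copy-number segments, batch effects, correlated measurement error between
layers, or realistic scale-free degree structure. Recovery of planted
mediators therefore validates the *pipeline's mechanics and statistics*, not
performance on any real cohort.

A no-signal configuration (`n_planted_mediators = 0`, `n_shared_drivers = 0`,
`noise_fraction = 1`) yields fully exchangeable events; the empirical
p-values are then uniform (KS-tested in the acceptance suite) — the
calibration check for the permutation machinery.

# Numerical choices and degenerate inputs

* **Dense vs iterative solve.** The operator is solved densely up to 3,000
  nodes (exact, fast at the scale of curated SCCs); above that a truncated
  power series with tolerance 1e-12 is used. Both agree to 1e-10 on test
  graphs; rows are verified to sum to 1 within 1e-9 at construction.
* **Ties.** Within-sample score ties get average ranks; cohort-order ties
  break by mean combined score then node id. All orderings use C-locale
  radix sorting, so results do not depend on the session locale.
* **Unscoreable samples** (no on-network upstream or downstream events) are
  dropped from aggregation with a warning; a cohort with zero scoreable
  samples is an error.
* **Off-network events** are counted and reported per sample rather than
  silently discarded.
* **Identifier matching** is case-insensitive after trimming; no ortholog
  mapping is attempted (single-species symbol space). miRNA nodes are
  recognised by the `miR`/`let-`/`mir` prefix convention.
* **Seeds.** Every stochastic step (network generation, cohort simulation,
  permutation test) takes a mandatory seed; identical (config, seed) pairs
  are bit-identical end to end, including output bytes.

# Open design decisions, resolved

* *Row- vs column-stochastic normalisation*: not derivable from the source
  material; row-stochastic is the default (edge direction = regulatory
  direction), column-stochastic sits behind a switch.
* *Score combination*: the product is the default for the reasons above;
  this is a declared divergence risk, not a claim of bit-compatibility with
  the original implementation, whose exact operators are not printed.
* *Permutation granularity*: upstream and downstream categories permute
  independently per sample; whether the original analysis permuted jointly
  is not stated. Degree-preserving permutation is a known, unimplemented
  alternative — the implemented null is degree-blind by construction.
* *Event intersection timing*: events are intersected with the SCC before
  permutation labelling, so null categories draw from exactly the nodes that
  can score.

# Known limitations

* With few permutations the add-one estimator's floor $p = 1/(n_{\rm perm}+1)$
  interacts with BH granularity: at $n_{\rm perm} = 500$ and ~2,000 genes,
  $q \le 0.05$ requires ≥ ~86 genes at the floor. Cohorts with narrow signal
  can yield empty mediator sets at scaled-down permutation counts even when
  the ranking itself is excellent; production runs should use 10,000.
* The uniform null ignores degree structure; empirical p-values correct hub
  bias on average, but a degree-matched null would be stricter.
* The Poisson degree model understates the heavy-tailed hubbiness of curated
  networks; recovery numbers on synthetic cohorts should be read with that
  in mind.
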