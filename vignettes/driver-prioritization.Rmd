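---
title: "Personalized driver prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized driver prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcstdriver)
```

`pcstdriver` ranks the mutated genes of an individual cancer patient by
how much of the patient's pathway dysregulation each mutation can
explain on that patient's own rewired interaction network. This
vignette documents the underlying models, every tunable parameter, the
synthetic data the tests rely on, and the places where the design was
genuinely open and a choice had to be made.

## The paired single-sample network

The co-expression state of a gene pair is estimated from the cohort's
normal samples (the *reference*, n samples). Appending one extra sample
changes the pair's Pearson correlation by
$\Delta PCC_{ij} = PCC^{n+1}_{ij} - PCC^{n}_{ij}$, and the statistic

$$Z_{ij} = \frac{\Delta PCC_{ij}}{(1 - (PCC^{n}_{ij})^2)/(n-1)}$$

is treated as standard normal under the null that the extra sample is an
ordinary draw from the reference state. The model assumes expression is
roughly jointly Gaussian per gene pair, that n is large enough for the
perturbation expansion behind the denominator (we require n >= 3 and
recommend dozens), and that the appended sample is exchangeable with the
reference under the null.

Both of the patient's paired samples are scored this way. An interactome
edge enters the personalized network iff exactly one of the two
p-values falls below `alpha_sig` — the interaction responds abnormally
to the tumor state but not to the same individual's normal state, or
vice versa. The XOR keeps the patient's normal sample as an internal
control: an edge that looks extreme in both states reflects the
individual, not the tumor.

Numerical edge cases:

* Pairs with $PCC^n = \pm 1$ make the Z denominator vanish; they are
  excluded outright and counted (`n_degenerate`), never raised as
  errors. Zero-variance genes (undefined correlation) are handled the
  same way.
* The p-value is the two-sided normal tail. The statistic is a signed
  perturbation and gains can be as meaningful as losses; a one-sided
  test would silently drop half the alternatives.
* The paired weight $w_{ij} = |\log_2|\Delta PCC_T / \Delta PCC_N||$ is
  singular when either perturbation is 0. Both magnitudes are floored at
  `clamp_eps` (default 1e-6) before the ratio, which keeps every weight
  finite without discarding informative edges; the floor only matters
  when a perturbation is smaller than any biologically meaningful
  correlation change.
* An optional `neg_pcc_filter` drops edges whose reference correlation
  is below a threshold (e.g. -0.4) before the flip test. It is off by
  default; the headline pipeline does not use it.

The reference set is all normal samples of the cohort, including the
patient's own normal sample. Only the `tumor_only` ablation removes it,
because that mode scores the tumor sample alone and would otherwise
compare the tumor against a reference containing its own pair.

## DEGs and dysregulated pathways

DEGs are genes with $|\log_2((t + c)/(n + c))| > \beta$, strictly, with
pseudocount c (default 1) guarding zero expression; c = 0 is allowed for
strictly positive data. `beta = 1` (a two-fold change) is the package
default.

Pathway enrichment uses the upper-tail hypergeometric probability with
Benjamini–Hochberg adjustment across all tested pathways and an FDR
threshold of 0.05. The enrichment background is the set of genes present
in both the expression matrix and the interactome — the same universe
the network stages operate on — and is configurable. Pathways are
intersected with the background before testing; empty intersections get
p = 1 rather than an error.

## Screening key mutant genes

All of the patient's mutated genes (any nonzero SNV or CNV entry) seed a
random walk with restart on the personalized network:
$p \leftarrow (1-r)\,W p + r\,e$, with $W$ the column-normalized
adjacency and $e$ uniform over seeds. Defaults and rationale:

* `restart = 0.7`, a common choice in RWR-based gene prioritization;
  exposed as a parameter.
* The walk is *unweighted* by default so that observed scores are
  comparable with the degree-preserving topological nulls (which carry
  no weights); a weighted walk is available via `weighted = TRUE`.
* Mass reaching a degree-zero node is re-injected at the seeds, keeping
  the vector a probability distribution; convergence is declared at an
  L1 change below `tol` (1e-10).

Each mutated gene's observed score is compared with its score on
`n_random = 50` degree-preserving random networks (double-edge swaps,
10 x |E| attempts each). The empirical p-value uses the add-one
estimator $(1 + \#\{null \ge obs\})/(1 + 50)$, so the smallest
attainable p is 1/51 and p is never zero; genes with p < 0.05 form K.
Hubs H are nodes whose degree strictly exceeds the network mean — on the
personalized network, not the reference interactome, since hubness there
reflects this patient's rewiring. The key mutant set is M = K ∩ H;
ablations expose K alone, H ∩ mutated, or all mutated genes.

## The prize-collecting Steiner tree

For root g and pathway p = (V_p, E_p), the mutation–dysregulation graph
takes nodes $V_p \cup \{g\} \cup N_h$, where $N_h$ are the first-order
network neighbors of the *union* of pathway members and root (the union
reading of "neighbors of V_p and g"; neighbors of the root alone would
make small pathways unreachable). Edges are the pathway topology plus
every network edge inside the node set. Prizes are |log2 fold change| on
DEG pathway members, 0 elsewhere; costs are `1 - norm(w)` under min–max
normalization over all network weights, and pathway-topology edges
missing from the network get the minimum possible cost, 0, which
deliberately favors walking along curated pathway structure. When every
weight is identical (the `same` ablation), `norm` is taken as 1 and all
costs collapse to 0: a single-valued weight distribution carries no
differential signal, so connectivity should not be penalized.

The rooted maximization $f(T) = \sum_{v \in T} P(v) - \sum_{e \in T} c(e)$
is solved on the root's connected component:

* **Exact** for components up to `exact_limit` (default 15) nodes:
  enumeration of connected root-containing node subsets, with the
  cheapest tree on a subset being its minimum spanning tree. The limit
  keeps the worst case at 2^14 subset evaluations.
* **Heuristic** above that: for components up to 20 nodes, a beam search
  over connected subsets (beam width 1024, ranked by objective) followed
  by hill-climb polish; for larger components, greedy growth plus
  add-one/add-two/remove-one local search multi-started from the root,
  the greedy solution and the full component. Neither route guarantees
  optimality, but the heuristic's objective can never fall below the
  root-only tree, and the test suite checks it against exhaustive
  enumeration on random instances with up to 12 nodes.

An isolated root with no prize admits no tree but the trivial one with
f = 0 and no explanatory content; the solution is flagged infeasible and
the influence defined as 0 rather than an error, because downstream
aggregation needs a number for every (pathway, root) pair. Influence
scores $f(T)/\sum_{v \in DEG \cap V_p} P(v)$ are clipped into [0, 1]
against floating-point overshoot; an empty DEG ∩ V_p also scores 0.
Gene totals are ranked descending with lexicographic tie-breaks, so
rankings are deterministic.

## Cohort aggregation and evaluation

The Condorcet variant is Copeland's method: gene a beats gene b when
strictly more patients rank a above b than b above a; genes are ordered
by wins minus losses, with mean rank (absent genes counting one past the
list length) and then gene name breaking ties. Copeland was chosen
because it is anonymous, cycle-tolerant and deterministic; the exact
variant used by prior cohort-voting pipelines is not documented, and the
implementation is isolated behind `condorcet_rank()` so it can be
swapped. Genes a patient did not rank are treated as tied below that
patient's ranked genes — a patient is silent about genes it could not
score, not negative. Full per-patient lists enter the vote; truncation
to the top k happens only at evaluation, where precision, recall and F1
are computed for k = 1..50 with recall denominated by
|mutated ∩ gold standard|. F1 is defined as 0 whenever precision or
recall is 0, and recall is reported as 0 with a warning when no mutated
gene is in the gold standard.

## What the synthetic cohorts emulate

`generate_cohort()` builds cohorts with exactly the statistical
structure the method assumes:

* **Block-correlated modules.** One latent activity factor per pathway;
  module genes load on their pathway's factor (loading 2 against noise
  sd 1 around a baseline of 10), giving within-module reference
  correlations of roughly 0.8.
* **Paired samples.** A patient's tumor sample shares the individual's
  factor vector with their normal sample (which is a reference column),
  so with no planted effects tumor and normal differ only by gene-level
  noise and fold changes are forced to the planted values as noise goes
  to 0.
* **Driver rewiring.** Each patient's driver is its module's interactome
  hub (a star in the interactome; the pathway's own topology is a random
  tree, kept distinct so pathway-only edges exercise the zero-cost
  branch). In the tumor sample the driver module's coherent signal is
  replaced, in proportion `rewiring_strength`, by an incoherent
  high-amplitude component, so appending the tumor sample perturbs the
  module's correlations while the normal sample does not — the
  significance flip.
* **DEGs downstream of the driver.** Module genes are multiplied by
  `2^deg_effect` in the tumor sample.
* **Mutations.** Drivers always carry SNV = 1; `n_comutated` (default 4)
  additional mutated genes are planted inside the driver's module, and
  passengers hit every gene at `passenger_rate` (default 0.01), half as
  SNVs and half as CNVs. The module co-mutations matter: the screening
  step scores *co-mutation* proximity, which is undefined for a patient
  with a single isolated mutation. Real tumors carry orders of magnitude
  more mutations than a 300-gene synthetic genome, so a handful of
  co-mutated pathway partners is the desk-scale analogue of the
  clustering the method exploits.

All randomness flows from one `rng_seed`; regeneration is bit-identical.
What the generator does **not** emulate: library-size and batch effects,
count-distribution marginals (values are Gaussian around a positive
baseline, clipped at 0), overlapping pathways, directed regulation, or
mutation hotspots. Passing tests therefore demonstrate that the
implementation recovers the signal class it models — significance-flip
rewiring around mutated hubs with pathway-aligned expression shifts —
not that it will attain any particular precision on real cohorts.

Default study conditions are 10 patients x 300 genes x 10 pathways of
10–20 genes with 50 reference samples, rewiring strength 0.8 and DEG
effect 2 for the strong-signal condition, and both rewiring and DEG
effect 0 for the null condition; the test suite and the acceptance
script run 5 cohorts of each. Smaller 120-gene cohorts back the
unit-level tests. These sizes were chosen so the full suite exercises
every stage, including 50-null randomization screening for every
patient, at interactive runtimes.

## Known limitations

* The network is undirected; directed regulatory information is ignored.
* The Z statistic's normality is asymptotic in n; with very few
  reference samples the edge p-values are only approximate (the package
  enforces n >= 3 but makes no small-sample correction).
* The PCST heuristic above 20-node components is local search without an
  approximation guarantee.
* The randomization test for co-mutation significance fixes the null at
  50 networks; finer p-value resolution than 1/51 requires raising
  `n_random` at linear cost.
* Copeland aggregation, like all Condorcet completions, can reorder
  near-tied genes relative to other tie-breaking conventions.
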