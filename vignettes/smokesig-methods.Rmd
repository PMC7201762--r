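---
title: "Tobacco-exposure methylation signatures: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tobacco-exposure methylation signatures: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesig)
```

`smokesig` identifies DNA methylation probes whose β-values separate current
from never smokers in lung adenocarcinoma cohorts, and traces the genes and
proteins those probes plausibly regulate. This vignette explains each model
in the chain, the tunable parameters and the reasoning behind their
defaults, what the synthetic generator does and does not emulate, and the
design choices made where the methodology was genuinely open.

## The statistical chain

**Why rank tests.** A β-value is a bounded ratio in [0, 1]; across a 450K
array most probes sit near one of the two methylation extremes, so their
sampling distributions are skewed and often bimodal. The package audits this
directly with the Jarque–Bera statistic, $JB = \frac{n}{6}\left(S^2 +
\frac{(K-3)^2}{4}\right)$, computed from biased ($1/n$) central moments and
referred to $\chi^2_2$. We use the classical moment form because it is the
canonical definition; the audit deliberately applies an *uncorrected*
per-probe $\alpha = 0.05$, since its purpose is a descriptive share of
"normal-looking" probes, not inference. On generated cohorts of 300 samples
roughly 10 % of probes pass, which is why the group contrast uses the
Wilcoxon rank-sum test (exact when $n_1 + n_2 \le 20$ without ties,
normal approximation with midrank tie- and continuity corrections
otherwise) with Benjamini–Hochberg FDR control at $q = 0.05$ ($q$ is
exposed; the level is a convention, not derived).

**Deep selecting.** With thousands of prescreened probes and ~100 samples, a
single model cannot isolate a compact signature. The deep-selecting loop
alternates PLS-DA fitting with elimination of the least important probes:

1. fit NIPALS PLS1 on the active probes (columns centered and scaled to
   unit variance; the ±1 label centered);
2. rank probes by VIP (squares average to one over probes — an internal
   identity the tests verify to 1e-8);
3. drop the lowest 10 % (at least one probe), refit, and record stratified
   5-fold cross-validated SN/SP/ACC;
4. stop when CV accuracy has not beaten its running best for 5 consecutive
   rounds (`patience`) or fewer than `min_probes = 10` remain, and return
   the probe set of the best iteration (first occurrence on ties).

Open choices, decided here: the contribution measure is VIP, the canonical
PLS importance (absolute regression coefficients are selectable via
`importance = "coef"`); the elimination schedule is a fixed 10 % per round,
a geometric decay that covers 10^5 → 10^2 probes in roughly forty rounds;
"accuracy could not be improved any more" is operationalized as
patience-based early stopping on CV accuracy, which is monotone-safe and
returns the best-so-far set; class prediction thresholds the continuous
PLS prediction at zero on the ±1 scale, with exact zeros assigned to the
positive (smoker) class; CV folds are stratified and seeded. Probes are
scaled to unit variance before PLS because β-value dynamic range varies
systematically with CpG context (`scale = FALSE` is available).
Cross-validation here selects components and stops elimination; because the
same folds steer the search, the best trace accuracy on pure noise runs
above 0.5 (the tests bound it away from genuine separation rather than at
the binomial band). An unbiased error estimate would need a nested outer
loop, which is out of scope; held-out cohorts serve that purpose instead.

**Differential correlation (DCS).** For every signature probe and every
gene, within-group correlations $r_{\text{current}}$ and $r_{\text{never}}$
are computed; a pair is selected when $|r| \ge TS_2$ in one group and
$|r| \le TS_1$ in the other (thresholds inclusive; defaults
$TS_1 = 0.3$, $TS_2 = 0.6$, the strategy's standard operating point). The
two-threshold form — high in one condition, low in the other — is the
natural reading of a differential-correlation rule with two named
thresholds, and the rule is a small pluggable predicate if another variant
is wanted. Correlations come in two flavors: the biweight midcorrelation
(bicor), with the unscaled MAD and the classical `9·MAD` tuning constant
(no 1.4826 consistency factor — the tuning constant absorbs scale), and
Spearman's ρ as Pearson on midranks. Zero-MAD vectors fall back to Pearson
with a warning by default (`zero_mad = "error"` to refuse). Gene sets found
by the two methods are intersected.

**Gene weight network.** On the related genes, adjacency
$a_{ij} = |cor|^{\beta}$ with Pearson correlation by default (the network
describes co-expression; bicor is selectable) and soft power $\beta = 6$,
the conventional unsigned choice — the power is exposed rather than fit by
a scale-free criterion, because at the 30–100-gene scale of related-gene
modules a scale-free fit is not meaningful. Connectivity is the adjacency
row sum excluding the diagonal; hubs are genes with $k > 10.75$ (strict,
matching the reported usage of that cutoff). Module detection and
topological-overlap measures are deliberately out of scope.

**PPI tracing.** STRING-style combined scores $s \in (0,1000]$ become edge
distances $d = 1001 - s$: strictly positive, strictly decreasing, and
integer-valued so cost ties are exact. The transform is a choice — any
decreasing map preserves paths only when hop counts tie — so
$-\ln(s/1000)$ (floored at 1e-9 to stay positive) is available via
`transform = "log"`. Edges below 400 (STRING's medium confidence) are
dropped at load time: including all pairs adds noise and cost without
changing high-confidence paths. One shortest path is traced per seed pair
(Dijkstra distances via igraph; the path itself is reconstructed as the
lexicographically smallest node sequence among ties, making betweenness
counts deterministic). A node's betweenness is the number of seed-pair
paths across it — endpoints excluded — which is not Brandes betweenness
centrality (that would count *all* tied shortest paths over *all* node
pairs); counting all tied paths per pair is available behind
`all-shortest-paths` semantics in igraph but is not the default because
the single-path count is what the betweenness floors refer to. The
permutation background reruns the trace on 100 random seed sets of the
same size and removes proteins hitting the betweenness floor in ≥ 50 % of
rounds — "appears more frequently in randomized results" needs an
operational cutoff, and universal hubs (TP53-like) sit far above any
reasonable one, so the result is insensitive to its exact value.

## The synthetic generator

`generate_study()` plants known structure so that every stage has a
ground-truth test:

- **β-values** are Beta$(\mu\kappa, (1-\mu)\kappa)$ draws with probe-level
  means from a bimodal mixture (45 % Beta(1.5, 12), 45 % Beta(12, 1.5),
  10 % Beta(2, 2)) — the hypo-/hyper-methylated modes plus an intermediate
  shelf, chosen so the marginals are bounded, bimodal across probes and
  mostly non-normal within probes, as on real arrays. The β-value marginal
  model is not dictated by any published description, so this mixture is the
  package's own choice. Precision $\kappa = 30$ gives within-probe spreads
  of ~0.05–0.09, typical of 450K replicates.
- **Signature probes** (default 50) have their current-smoker mean shifted
  by ±`delta_beta` (default 0.25, a strong smoking-associated effect of the
  magnitude seen at loci like *AHRR* cg05575921); shift directions flip
  when they would leave (0, 1), and an error is raised if neither direction
  fits. Cohort sizes default to 102 current / 43 never — the discovery
  cohort composition of the motivating study design.
- **Coupled pairs**: for each planted probe–gene pair, expression in ONE
  group is $r z(\beta) + \sqrt{1-r^2}\,\varepsilon$ with $r$ = `r_high`
  (0.9), and independent noise (or `r_low` coupling) in the other group —
  a transparent regression construction rather than a copula; the achieved
  correlation is verified empirically in tests rather than imposed exactly.
- **PPI graph**: a preferential-attachment background (scores 400–800) plus
  a small clique of bridge proteins receiving one 990-score edge from every
  seed. Bridges therefore dominate seed-pair shortest paths. Note that
  this also makes them attractive to *random* traffic — like real universal
  hubs they can be flagged by the permutation background — so bridge
  recovery is asserted through betweenness ranks and forced topologies, not
  through the background filter.
- **Structure vs noise seeds**: planted structure depends only on
  `rng_seed`; sampling noise on `noise_seed`. Holding the config fixed and
  changing `noise_seed` draws an independent validation cohort with the
  same biology, emulating a train/validate two-cohort design.

What the generator does **not** emulate: genomic coordinates, probe-type
(Infinium I/II) chemistry, batch effects, cell-type composition, age or
stage confounding, and correlated probe blocks (probes are independent
given their means). Passing recovery tests therefore demonstrate that the
algorithms do what they claim under their own assumptions — not that the
pipeline is robust to the full messiness of real cohort data.

## Numerical choices and degenerate inputs

- Percentages in annotation summaries round half away from zero to one
  decimal. On the packaged 105-probe table the shore share is
  20/105 = 19.048 % → 19.0, whereas the published figure prints 19.1 % —
  a rounding discrepancy we document rather than force.
- Manifest dash cells ("—" or "-") parse to an empty gene list and the
  OpenSea feature; the first listed gene is taken as a probe's gene for all
  probe–gene analyses (multi-gene rows keep their full ordered list).
- Exact Wilcoxon p-values use the two-sided doubling convention
  (min(1, 2·min(tail probabilities))); identical multisets give p = 1.
- Zero-variance probes are dropped (with a warning) before scaling in PLS;
  an all-constant input is an error. Constant within-group genes yield NA
  correlations and are excluded from DCS selection.
- BH adjustment, Wilcoxon tests, Dijkstra distances and graph containers
  are delegated to `stats` and `igraph`; the Jarque–Bera statistic, bicor,
  NIPALS PLS1/VIP, the DCS rule, the weight network and the deterministic
  path reconstruction are implemented in the package and tested against
  independent definitional or enumeration oracles.

## Problem sizes used in the tests

The test suite and acceptance script exercise the pipeline at desk scale:
2000-probe cohorts with 50 planted probes (Δβ = 0.25, 70 + 30 samples, ten
replicate seeds) for prescreen power and deep-select recovery; 100 samples
per group, 600 probes × 400 genes with 25 planted couplings for DCS recall
and its null false-pair rate; 300-sample cohorts for the normality audit;
and ≤ 12-node graphs for exhaustive path enumeration. These sizes keep
ground-truth recovery statistically stable while each stage completes in
seconds; the algorithms themselves have no size-specific constants, and all
thresholds discussed above are identical at epigenome scale.

## Known limitations

- CV-guided elimination without an outer validation loop biases the trace's
  apparent accuracy upward; use held-out cohorts for honest error rates.
- The DCS rule tests marginal within-group correlations; it does not model
  confounding between smoking status and expression.
- Single-path betweenness depends (deterministically) on the tie-break when
  many equal-cost paths exist, as in unweighted or score-saturated graphs.
- The permutation background assumes the real seed count; seed sets of very
  different sizes need their own background runs.
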