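---
title: "Methods: per-group co-expression networks and gene-metabolite integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-group co-expression networks and gene-metabolite integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Paired transcriptome and metabolome profiles from two phenotype groups — the
motivating design is artificial-insemination pregnant (AI-P) versus
nonpregnant (NP) beef heifers, six animals per group — carry two kinds of
signal that single-feature differential tests miss: coordinated expression
*within* a molecular layer that differs between the groups (network
rewiring), and gene-metabolite relationships whose *slope* depends on
phenotype. `gminet` implements the full analysis chain for that design:
quality control, per-group PCIT co-expression networks, hub and
differential-connectivity statistics, cross-layer integration by combined
PCIT correlation and by a phenotype-interaction linear model, and pathway
over-representation against user-supplied GMT collections. A synthetic-data
generator with planted structure makes every stage scoreable against ground
truth.

## Quality control and normalization

Gene counts pass three sequential filters, each removal attributed to the
first rule failed: (i) features with zero counts everywhere; (ii) features
with mean CPM below 1; (iii) features with CPM >= 1 in fewer than 50% of
samples. "Present" in rule (iii) is undefined in common usage; we take
CPM >= 1 in a sample, the same unit as rule (ii), and expose the threshold.
The retained set equals the intersection of the three rules, so the order
affects only the report. Library sizes are the column sums of the
*unfiltered* matrix, the standard CPM convention, and `log2(CPM + 1)` is
the working scale for all downstream gene analyses.

Metabolite peak heights are screened per group by relative standard
deviation (sd/mean of the raw values): a metabolite is retained for a
group's analyses when RSD <= 0.15 there, so the two groups may retain
different sets (the container keeps one matrix and per-group masks).
Retained values are natural-log transformed; inputs must be positive, with
an optional +1 pseudocount for tables containing zeros. The RSD rule
screens *technical* stability; synthetic data whose metabolite variation is
biological (log-scale sd 0.5 by default) would lose essentially every
feature to it, so the synthetic protocol runs with `rsd_max = Inf` — a
documented configuration choice, not a change of default.

## Differential features

The network filters need differential gene/metabolite anchors. The built-in
caller is a Welch two-sample t-test per feature on the log scale, chosen
for transparency; any external caller's list can be substituted via
`load_external_calls()`. Significance uses raw `p <= 0.05` and
`|log2FC| >= 0.5`, both boundaries inclusive; a BH-FDR column is emitted
for users but not used by the default rule. The sign convention follows the
reference-group reading: positive log2FC means higher expression in the
reference (NP) group; `fc_direction = "other"` flips it.

## PCIT networks

For each phenotype group separately, Pearson correlations are computed
across the group's samples and every trio of features (x, y, z) is tested:
the three first-order partial correlations

    r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))

yield a local tolerance `eps`, the mean of the partial-to-direct ratios
over the trio's edges, and the edge (x, y) is eliminated when
`|r_xy| < |eps r_xz|` and `|r_xy| < |eps r_yz|` for some z — its
correlation is explainable through a third feature. Surviving edges are
"PCIT-significant". Numerical choices: comparisons are strict, so ties
retain the edge; ratio terms whose direct correlation is below 1e-12 in
magnitude are dropped from the tolerance average; trios containing a
correlation of +/-1 are skipped entirely (their partials are undefined),
which also means exactly collinear features keep their unit-correlation
edge; with fewer than three features the trio test is undefined and all
non-zero pairs are returned flagged, with a warning. The trio loop is cubic
and implemented in compiled code; instances up to a few thousand features
are practical, and the package's own checks run at up to ~330.

Two properties of the rule are worth understanding. First, it is
threshold-free: "significance" is survival of the elimination, and the
analysis adds an absolute-correlation floor afterwards (`|r| >= 0.99` for
gene pairs, `>= 0.9` for metabolite pairs, `>= 0.75` cross-layer) plus the
differential anchoring rule (at least one endpoint differential). Second,
elimination only removes an explained edge when it is weak relative to the
tolerance-scaled alternatives: a two-hop edge in a moderate chain
(r = 0.5, 0.5, 0.25) is pruned, but in a strong chain (0.9, 0.9, 0.81) the
indirect edge survives because 0.81 exceeds eps * 0.9 ~ 0.45. The test
suite pins both regimes against a naive triple-loop oracle.

A note on the gene-layer floor: at six samples per group, sample
correlations are so variable that `|r| >= 0.99` still passes many pairs; at
fifty samples per group it passes almost none. The floor is therefore tied
to the cohort scale, and simulation studies at larger n use lower floors
(the synthetic protocol uses 0.5 for rewiring detection) — configuration,
not hard-coding.

## Topology, hubs, and differential connectivity

Node degree and exact (Brandes) betweenness are computed on the simple
undirected graph, betweenness unnormalized by default with a
`(N-1)(N-2)/2` normalization flag for comparability with Cytoscape output.
The lenient hub boundary (`degree >= 1`, `betweenness >= 0`) admits every
non-isolated node, which cannot explain the small hub sets this style of
analysis reports; the package's default is therefore the practical rule
`betweenness > 0` (nodes actually on shortest paths between others), with
the lenient boundary (`betweenness_strict = FALSE`) and a `top_k` option
both available.

Rewiring between groups is summarized two ways. The union ("central
reference") network annotates every node and edge as A-only, B-only or
shared, for export to SIF plus attribute tables. The differential
connectivity index per node is `DK = K_ref - K_other` over a stated node
universe (nodes absent from a network count degree zero; by default the
union of the two node tables, configurable to the full analyzed feature
set), standardized to `z = (DK - mean) / sd`, significant at
`|z| >= 1.96`, the two-sided 5% normal critical value. "Gain" means
significantly more connected in the reference network. Swapping the inputs
negates every DK and z exactly. If all DK are equal the z-scores are
undefined and no calls are made, with a warning.

## Integration

Targets for cross-layer anchoring are, per group, the union of hubs and
significantly differentially connected features; *unique* targets are those
exclusive to one group. The combined gene + metabolite matrix (normalized
genes stacked on log metabolites over shared samples) is run through PCIT
per group and only cross-layer edges kept; pairs need `|r| >= 0.75` and an
endpoint among the group's unique targets (`targets = NULL` disables
anchoring for designs that do not want it).

The model route fits, per candidate (gene, metabolite) pair over all
samples jointly,

    m = b1 + b2 g + b3 p + b4 (g : p) + e

with `m` the log metabolite abundance, `g` the normalized gene expression,
and `p` coded 0 for the reference level, 1 otherwise. The two-sided p-value
on the interaction coefficient `b4` (t distribution, n - 4 df) flags
phenotype-dependent relationships at raw `p <= 0.05`; a BH column is
emitted. Singular designs (e.g. a gene constant within a level) are skipped
with a reason rather than fitted. Genes in the lowest 5% of variance are
excluded beforehand, ties at the cut retained. Within-group Spearman
correlations and their difference (non-reference minus reference) accompany
every fit; the final selection rule is configurable because the choice
between the interaction p-value and the Spearman-difference magnitude is
genuinely open — both are always reported, and the default significance cut
is the interaction p-value. The candidate universe defaults to
differential features plus targets (the study design), with an
all-pairs option. Pairs identified by both routes (`overlap_pairs()`)
carry `evidence = "both"` and a per-group correlation sign call.

The phenotype coding, the reference level, and the log2(CPM + 1) gene scale
are the package's resolutions of genuinely open conventions; each has a
flag. No covariate adjustment is applied because none is defined for the
two-group design.

## Over-representation

Enrichment is the exact hypergeometric upper tail `P[X >= k]` of query hits
against each annotation set, over a stated background universe (default:
features surviving QC in the relevant layer). Multiple testing uses the
Bonferroni step-down (Holm) procedure, implemented from its definition and
cross-checked against the stock reference implementation in the tests.
Joint gene + metabolite pathway evidence combines the two layers' raw
p-values per pathway with Fisher's method (chi-squared, 4 df); a layer
missing a pathway contributes p = 1, so the combination can only add
evidence. Fisher was chosen over weighted schemes for its transparency;
term clustering and topology-weighted variants of web tools are out of
scope, as are annotation database clients — collections are user-supplied
GMT files.

## The synthetic generator

`simulation_spec()` describes a two-group paired study: NB gene counts
(size 10 by default, log-normal baseline means around 200) with a
Gaussian-copula latent layer, Gaussian log-scale metabolites, and three
kinds of planted structure — latent-factor modules (optionally active in
only one group, which creates genuine per-group correlation differences),
log2 fold changes applied to the non-reference group, and gene-metabolite
pairs generated from the interaction model itself. Module members share a
per-sample factor scaled by the loading; mapping through the NB quantile
function keeps marginal count distributions exactly NB. Each generation
stage draws from its own seed stream derived from the global seed, so
extending a spec never shifts earlier draws and output is bit-reproducible.

The default cohort scale is six per group; the canonical benchmark
(`planted_study_spec()`) uses 300 genes, 30 metabolites, modules of 15 at
loading 0.9 (one both-group, one reference-only), ten DE genes at
|log2FC| = 1.5, three DE metabolites, and three planted pairs with
`b2 = 0.5`, `b4 = 1.5`, noise sd 0.5 — effect sizes a well-powered
integration study would target, checked at n = 50 per group and smoked at
n = 6. The generator does not attempt GC-TOF-MS peak artifacts, batch or
library-composition effects, or real bovine expression distributions;
passing tests demonstrate that the machinery recovers planted structure
under clean NB/Gaussian sampling, not that any particular real dataset
would yield the same lists.

## Verification scale

The package's checks run at sizes chosen to finish comfortably on one CPU:
PCIT oracle equivalence on 200 random instances of 3-30 features;
betweenness against exhaustive path enumeration on 200 graphs of up to 10
nodes; interaction-model calibration on 2,000 null pairs at n = 12 and
power on 500 replicates at n = 50 per group; end-to-end planted-pair
recovery over 20 seeds of the canonical benchmark; enrichment against
exhaustive draw enumeration for universes up to 15. The reproducibility
script (`scripts/acceptance.R`) recomputes the same quantities from
scratch for any seed.

## Known limitations

- The trio test retains strong indirect edges (the 0.9-chain case above);
  it is a pruning heuristic, not a consistent graphical-model estimator,
  and no higher-order partial correlations are attempted.
- The Welch-t differential caller is a transparent stand-in, not a
  replacement for count-model callers; use external lists where those are
  preferred.
- Betweenness-based hub calling depends on a rule the source analyses
  leave underdetermined; both modes are provided and reported hub counts
  should state the rule used.
- The interaction model assumes Gaussian residuals on the log scales and
  fits pairs independently; it shares no information across pairs.
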