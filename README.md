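# gminet

Co-expression networks and gene–metabolite integration for two-group
paired omics studies.

## What problem this solves

Small paired transcriptome + metabolome cohorts — the motivating design is
six artificial-insemination pregnant (AI-P) versus six nonpregnant (NP)
beef heifers profiled by RNA-seq and untargeted metabolomics — hide two
signals that per-feature differential tests miss: **rewiring** of
co-expression structure between phenotype groups, and **gene–metabolite
relationships whose slope depends on phenotype**. `gminet` implements the
complete analysis chain for that design, for analysts who want every stage
scriptable, testable and reproducible rather than spread across web tools:

1. **QC** — count filters (zero counts; mean CPM < 1; present in < 50% of
   samples) and per-group metabolite RSD ≤ 0.15 screening with log
   normalization.
2. **Differential features** — a transparent Welch-t stand-in caller
   (p ≤ 0.05, |log2FC| ≥ 0.5), or externally computed lists.
3. **Per-group PCIT networks** — for every trio (x, y, z), the first-order
   partial correlations

       r_xy.z = (r_xy − r_xz·r_yz) / √((1 − r_xz²)(1 − r_yz²))

   define a local tolerance ε (mean partial-to-direct ratio); edge (x, y)
   is eliminated when |r_xy| < |ε·r_xz| and |r_xy| < |ε·r_yz| for some z.
   Survivors are filtered at |r| ≥ 0.99 (genes) / 0.90 (metabolites) and
   anchored on differential features.
4. **Topology** — degree, exact betweenness, hub calls, union
   ("central reference") networks, and per-node differential connectivity
   DK = K_NP − K_AI-P standardized to z = (DK − μ)/σ, significant at
   |z| ≥ 1.96.
5. **Integration** — per-group combined-layer PCIT pairs (|r| ≥ 0.75,
   anchored on group-exclusive targets) intersected with the
   phenotype-interaction linear model

       m = b1 + b2·g + b3·p + b4·(g:p) + e

   fitted per pair (p coded 0 = NP, 1 = AI-P; lowest-5%-variance genes
   excluded; within-group Spearman difference reported alongside).
6. **Over-representation** — exact hypergeometric tails against
   user-supplied GMT collections, Holm (Bonferroni step-down) correction,
   and Fisher-combined joint gene + metabolite pathway p-values.

A synthetic-data generator (`simulation_spec()` / `simulate_omics()`)
plants co-expression modules (optionally group-gated), fold changes and
interaction pairs with full ground truth, so every stage is scoreable.

## Worked example

A seeded synthetic study at the benchmark scale (300 genes, 30
metabolites, 50 samples per group), run through the full pipeline with
thresholds suited to that sample size:

```r
library(gminet)

sim <- simulate_omics(planted_study_spec(n_per_group = 50, seed = 42))
cfg <- pipeline_config(r_gene = 0.6, r_metab = 0.6, rsd_max = Inf,
                       candidate_rule = "all")
run <- run_pipeline(sim$genes, sim$metabolites, cfg)
print(run)
#> gm_pipeline run
#>   genes: 300 -> 300 after count QC; 15 differential
#>   metabolites: 30 input; retained per group: NP=30, AIP=30; 6 differential
#>   gene network edges: NP=60, AIP=0 | metabolite: NP=9, AIP=8
#>   hubs: NP=7, AIP=2 | differentially connected: gain=0 loss=0
#>   targets: 7 / 2 (shared 1; exclusive 6 / 1)
#>   gene-metabolite pairs: PCIT NP=0, AIP=3; model-tested 8550, significant 472; overlap 3
```

The 60 NP-only gene edges are the reference-gated module anchored by its
differential members; the three AI-P pairs that survive both evidence
routes include a planted interaction pair:

```r
run$overlap
#>   gene_id metabolite_id         r group sign_call       b4 p_interaction spearman_diff evidence
#> 1   g0041          m004 0.8985224   AIP  positive 1.304775  2.128990e-07     0.3726291     both
#> 2   g0043          m004 0.8046514   AIP  positive 1.791765  2.823168e-11     0.6676591     both
#> 3   g0044          m004 0.8018422   AIP  positive 1.825873  8.329139e-10     0.9284034     both
```

`g0041–m004` was generated with interaction slope b4 = 1.5; its estimate
here is 1.30 with p ≈ 2×10⁻⁷, and it is positively correlated in the AI-P
group (r = 0.90) where the planted slope is active. Scoring against the
planted truth:

```r
score_pipeline(run, sim$truth)$de
#> $tp [1] 18   $fp [1] 3   $fn [1] 0   $precision [1] 0.857   $recall [1] 1
```

Without target anchoring (the pure evidence-overlap route), the three
planted pairs are recovered essentially every time; that is the
recovery-rate computation the reproducibility script repeats over 20
seeds. Artifacts for any run are written with
`write_pipeline(run, "outdir/")` as deterministic TSV/SIF files.

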