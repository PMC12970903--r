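# iscn — individualized structural covariance networks

`iscn` is an R package for asking whether long-term skill training is
associated with reorganized brain network topology when all you have per
subject is a table of regional gray-matter volumes (GMV). It is aimed at
researchers analyzing expert-vs-novice (or patient-vs-control) cohorts
with atlas-level morphometry: it builds a **per-subject** structural
covariance network (SCN) from a normative control group, quantifies each
network's topology across a range of sparsity thresholds, compares groups
nonparametrically, and tests whether network topology mediates a
training→performance association.

## The method

Classical SCNs are group-level: one correlation matrix per cohort. `iscn`
individualizes them via inter-regional effect-size-difference (ESD)
weighting:

1. Per-region OLS residualization of volumes on age, sex, and total
   intracranial volume — coefficients fit on **controls only**, applied to
   everyone.
2. Group reference network: `SCN_control[j,k] = cor(res_j, res_k)` across
   control subjects (Pearson).
3. Control reference `M_control`, `SD_control` per region.
4. Subject weight matrix from standardized deviations
   `z_r = (res_r − M_r)/SD_r`:
   `W[j,k] = exp(−|z_j − z_k|) ∈ (0, 1]`.
5. Individual network: `W ⊙ SCN_control` (element-wise).

Each weighted network is binarized at sparsity levels `K = 0.14–0.50`
(step 0.01, strongest `|edges|` retained), and at every level the package
computes clustering coefficient (Cp), characteristic path length (Lp),
global and local efficiency (Eg, Eloc), nodal degree, and betweenness
centrality, each summarized by the trapezoidal area under its sparsity
curve (AUC). Groups are compared by label-permutation tests on AUC with
Benjamini–Hochberg FDR within metric families and Cohen's *d*; small-world
validity is screened via degree-preserving rewired surrogates
(σ = (Cp/Cp_rand)/(Lp/Lp_rand)). Mediation of training duration →
topology → performance uses standardized OLS paths (a, b, c, c′; the
identity c = c′ + a·b holds exactly) with bias-corrected bootstrap CIs
for the indirect effect a·b.

A synthetic cohort generator (`generate_cohort()`) emulates the target
study design — three groups of 20, 116 AAL regions, modular covariance,
covariate confounds, planted regional effects, and a mechanistic mediation
chain in which training tightens within-module covariance and performance
regresses on that tightness — with full ground truth, so every stage of
the pipeline is testable against known signals.

## Worked example

A synthetic cohort with tighter within-module covariance planted in
experts, analyzed end to end:

```r
library(iscn)

cfg <- pipeline_config(
  input = cohort_config(n_regions = 16, n_modules = 4, seed = 2024,
                        group_tightness = c(expert = 1.5, novice = 0,
                                            control = 0)),
  metrics = c("Cp", "Lp", "Eg", "Eloc"),
  n_perm = 2000, n_boot = 2000, seed = 2024)
res <- run_pipeline(cfg)
print(res$comparison, digits = 3)
#>   metric node mean_a mean_b   sd_a    sd_b observed_diff p_perm p_fdr cohen_d
#> 1     Cp <NA>  0.200  0.177 0.0234 0.02051       0.02330 0.0020 0.004   1.059
#> 2     Eg <NA>  0.195  0.201 0.0108 0.00906      -0.00578 0.0645 0.086  -0.579
#> 3   Eloc <NA>  0.239  0.217 0.0203 0.02081       0.02167 0.0020 0.004   1.053
#> 4     Lp <NA>  0.705  0.717 0.0412 0.03729      -0.01186 0.3178 0.318  -0.302
```

Experts (`mean_a`) show higher clustering and local efficiency AUC than
novices (`mean_b`) — large effects (*d* ≈ 1.05) surviving FDR — while
global efficiency trends lower: the planted shift toward modular, locally
specialized topology is recovered with the expected signs. The mediation
stage then tests whether a topology metric carries the
duration→performance association:

```r
print(res$mediation)
#> Mediation (standardized, n = 40):
#>   a = 0.4765, b = -0.0403, c = -0.2928, c' = -0.2736
#>   indirect a*b = -0.0192, 95% BC bootstrap CI [-0.1855, 0.1468] (not significant)
```

At n = 40 the indirect effect is honestly underpowered; the package's
simulation tests show the same machinery recovers a planted indirect
effect of −0.25 with 90–99% CI coverage at n = 200.

Individual pieces are usable on their own, e.g.:

```r
parts <- build_individual_scns(res$cohort)        # steps 1-5 above
net   <- binarize(parts$scns[[1]], k = 0.2)       # one binary network
clustering_coefficient(net)$global
small_world_index(net, n_random = 20, seed = 1)$sigma
```

A command-line wrapper lives at `inst/scripts/scn-pipeline.R`
(`simulate` and `run` verbs).

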