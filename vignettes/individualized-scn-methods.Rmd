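---
title: "Individualized structural covariance networks: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized structural covariance networks: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscn)
```

## The problem

Structural covariance networks (SCNs) describe how regional brain
morphometry — here, gray-matter volume (GMV) per atlas region — covaries
across subjects. A classical SCN is a single group-level graph: one Pearson
correlation matrix per cohort, which forfeits subject-level inference.
`iscn` implements an individualized construction: a normative control
cohort defines a reference covariance network, and each subject receives
their own weighted network by modulating that reference according to how
far the subject's regional volumes deviate from the control norm. The
resulting per-subject networks support standard group statistics (here:
expert versus novice athletes) and brain-behavior models such as mediation.

## The construction

For each subject and each of the $p$ regions (the AAL-116 atlas by
default):

1. **Residualization.** Regional volumes are adjusted for age, sex, and
   total intracranial volume by per-region OLS with intercept. The
   coefficients are estimated **on the control group only** and applied to
   every subject. Fitting on controls keeps the adjustment normative: a
   per-group or pooled fit would absorb part of any genuine group effect
   into the covariate model. Control residuals are exactly orthogonal to
   the covariates by construction; other groups' residuals are deviations
   from the control-predicted norm.
2. **Group SCN.** $SCN_{control}$ is the $p \times p$ Pearson correlation
   matrix of control residuals, unit diagonal.
3. **Control reference.** Per-region mean $M_{control}$ and standard
   deviation $SD_{control}$ (denominator $n-1$) of the control residuals.
4. **ESD weight matrix.** A subject's residual vector is standardized,
   $z_r = (res_r - M_r)/SD_r$, and the inter-regional effect-size
   difference is $ESD_{jk} = |z_j - z_k|$. The weight is
   $W_{jk} = \exp(-ESD_{jk})$.
5. **Individualization.** The subject's network is the element-wise
   product $W \odot SCN_{control}$.

The exponential ESD-to-weight transform is a design choice of this
package: it is bounded in $(0, 1]$, equals 1 exactly when the subject
deviates identically at both regions (so a subject lying at the control
mean reproduces the group SCN bit-for-bit), and decays smoothly as a
region pair decouples. Because $W \in (0,1]$, individualized edges keep
the sign of the group edge and can only shrink, never grow — the group SCN
is an upper envelope. The transform is pluggable
(`transform = "inverse"` gives $1/(1+|\Delta z|)$, or pass any function)
so the sensitivity of downstream results to this convention can be
checked directly.

## Graph topology over a sparsity grid

Weighted individual networks are binarized at each sparsity $K$ in a grid
(default $K = 0.14$ to $0.50$, step $0.01$; 37 levels): the
$\mathrm{round}(K\,p(p-1)/2)$ edges of largest **absolute** weight are
retained. Absolute ranking is the dominant convention for
correlation-derived networks, whose informative edges can be negative; a
`positive`-only mode is exposed. Rounding is half-away-from-zero and ties
at the cutoff break by lexicographic region order, so edge sets are
deterministic and nested across increasing $K$.

Per binary network the package computes: clustering coefficient ($C_p$,
nodal and global), characteristic path length ($L_p$), global efficiency
($E_g$), local efficiency ($E_{loc}$), nodal degree, and betweenness
centrality (unnormalized, each unordered pair counted once). Conventions
for degenerate structure: pairs in different components are *excluded*
from $L_p$ averages rather than given a surrogate distance (grid
validation separately enforces that networks stay essentially connected),
an isolated node has nodal $L_p = 0$, and nodes of degree $< 2$ have
clustering and local efficiency 0. $L_p$ is the arithmetic mean of finite
shortest-path lengths — the conventional characteristic path length —
while $E_g$ (mean inverse distance with $1/\infty = 0$) carries the
harmonic-mean information and is robust to disconnection; reporting both
keeps the two summaries cleanly separated. Distances come from a
vectorized breadth-first expansion; betweenness and degree-preserving
rewiring are delegated to igraph; everything is cross-checked in the test
suite against brute-force oracles (Floyd–Warshall, exhaustive triangle
and path enumeration) on hundreds of small random graphs.

Each metric's curve over the grid is summarized by the composite
trapezoidal area under the curve (AUC), making group comparisons
independent of any single threshold. A constant curve $c$ integrates to
$c \times (K_{max} - K_{min}) = 0.36c$ at the default grid.

Grid validity is reported per level: the fraction of networks whose
largest connected component covers more than 90% of nodes, and the
fraction with small-world index $\sigma > 1$, where
$\sigma = (C_p/C_p^{rand})/(L_p/L_p^{rand})$ against degree-preserving
rewired surrogates (default 10 surrogates with $10 \times |E|$ swap
attempts each; surrogate count is a screen, not an estimator, so a small
default keeps the report cheap).

## Group inference

AUC values are compared between groups with a label-permutation test on
the mean difference. Small samples are handled exactly: when the number
of distinct splits is at most `n_perm` the test enumerates all of them;
otherwise it draws `n_perm` random splits and uses the add-one-corrected
two-sided p-value $(b+1)/(n_{perm}+1)$, which is never zero and is
calibrated (type-I error $0.05 \pm 0.02$ in the package's null
simulations). Benjamini–Hochberg FDR correction is applied within metric
families — the four global metrics form one family, each nodal metric a
family across its regions — matching how global and nodal results are
conventionally tabulated; a pooled mode is exposed. Cohen's $d$ with
pooled $n-1$ SD accompanies every comparison. Brain–behavior associations
use a Shapiro–Wilk gate at $p > 0.05$: Pearson when both variables pass,
Spearman otherwise.

## Mediation

The three-variable mediation model uses z-scored variables throughout, so
paths are standardized $\beta$: $a$ (predictor $\to$ mediator), $b$
(mediator $\to$ outcome given predictor), $c$ (total), $c'$ (direct). On
standardized OLS the decomposition $c = c' + ab$ is an algebraic identity
(the package asserts it to $10^{-10}$). The indirect effect $ab$ gets a
nonparametric bootstrap (subjects resampled with replacement;
default 5000 replicates) with a **bias-corrected** percentile interval:
$z_0 = \Phi^{-1}(\Pr(ab^* < \widehat{ab}))$ and bounds at the
$\Phi(2z_0 \pm z_{0.975})$ percentiles. BC rather than BCa: no
acceleration term is estimated, keeping the interval assumption-light;
simulation in the test suite shows 90–99% coverage at nominal 95% under
the planted chain. Candidate mediators are metrics with a significant
group difference *and* significant correlations with both the predictor
and the outcome. Mediation runs on experts and novices pooled (controls
have no performance score); the subject set is configurable.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the analysis is meant for:
three groups of 20 (experts with ~12.4 ± 1.2 years of training and
72.05 ± 4.3 strokes per 18 holes, novices 1.8 ± 1.1 years and
86.15 ± 5.63 strokes, untrained controls), 116 regions, and full ground
truth for every planted signal. Conventions chosen once as field-realistic
defaults:

* **Volumes** are multivariate normal on the log scale and exponentiated
  — GMV is positive and approximately log-normal — with baseline regional
  log-volumes uniform on $[\log 2000, \log 15000]$ mm³ and an 8%
  coefficient of variation for subject deviations.
* **Covariance structure** is modular: 4 blocks, within-block correlation
  0.5, between-block 0.10 (typical magnitudes for structural covariance),
  validated positive-definite before sampling.
* **Covariates**: age $\approx$ 27 ± 3 years per the emulated design, sex
  balanced 0/1 within group (no breakdown is specified by the design, so
  balance is the neutral convention), TIV $\sim N(1.45 \times 10^6,
  1.2 \times 10^5)$ mm³, with small log-scale effects
  (−0.003/yr, +0.02 for sex, +0.06 per TIV SD).
* **Group effects** on named regions are planted as SD-unit shifts of the
  deviation term.
* **The mediation chain** is planted mechanistically, not by drawing the
  mediator directly: training duration (standardized) drives a latent
  *tightness* variable with slope $a$; each subject's deviation pattern
  is drawn with within-module correlation
  $\rho_w (1 + \mathrm{gain} \cdot tightness)$ (gain 0.5, clamped to
  $[\rho_b, 0.95]$); and strokes regress on tightness ($b$) and duration
  ($c'$), centered on the pooled expert/novice stroke location. Tighter
  within-module covariance makes a subject's within-module deviations
  more similar, shrinking their inter-regional ESD, pushing within-module
  weights toward 1 — and therefore raising clustering and local
  efficiency of the binarized network. The chain thus propagates through
  the *entire* pipeline rather than short-circuiting it. Consequence:
  when the chain is active, group stroke means emerge from the chain
  (defaults imply a smaller expert-novice stroke gap than the marginal
  group parameters would give); when it is off, strokes are drawn
  independently per group. The two specifications cannot hold
  simultaneously, and the chain takes precedence. Novice/control
  durations are truncated at zero, a negligible distortion at the default
  parameters.

What the generator does **not** emulate: spatial autocorrelation and
atlas geometry, scanner/site effects, non-Gaussian volume artifacts,
age × group interactions, and any claim about real neuroanatomy. Passing
tests therefore demonstrate the statistical machinery — recovery of
planted effects under the assumed generative family — not validity on
real MRI-derived tables.

## Numerical and reproducibility choices

* All randomness flows from one root seed, split into fixed per-stage
  substreams, so a stage can be re-run in isolation; identical config +
  seed reproduces every output file byte-for-byte (checksums are recorded
  in the run manifest).
* Problem sizes in the test suite are scaled to keep the default run
  fast: most cohorts use 16 regions and the full 37-level grid; the
  package-level acceptance script runs the full 116-region design.
* Degenerate inputs fail loudly with the offending column/region named:
  zero-variance regions, rank-deficient covariate designs,
  non-positive-definite covariance specifications, constant variables in
  correlation/mediation, sparsity levels yielding zero edges.
* Bootstrap resamples with a constant variable are redrawn (at most 10
  attempts) rather than silently dropped.

## Known limitations

* The ESD weighting assumes the control reference is estimated well;
  with very small control groups ($n \lesssim 15$) the reference SD is
  noisy and individual weights inherit that noise.
* Betweenness at high sparsity on dense networks is near-degenerate
  (most geodesics are direct edges), so its AUC carries little signal.
* The permutation test uses the raw mean difference as its statistic; a
  studentized statistic would be more robust under strong
  variance heterogeneity between groups.
* BC (not BCa) intervals can under-cover when the bootstrap distribution
  of $ab$ is strongly skewed at small $n$.
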