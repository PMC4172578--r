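---
title: "Methods: mixed-model association scans with complementary trait-specific kinship"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model association scans with complementary trait-specific kinship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supergwas)
```

## The model

All scans in this package are F-tests of a single marker effect inside
the mixed linear model

$$ y = X\beta + w v + u + e, \qquad
   u \sim N(0,\ \sigma_a^2 K), \qquad e \sim N(0,\ \sigma_e^2 I), $$

where $X$ holds the intercept and any user covariates, $w$ is the tested
marker's dosage vector, and $K$ is a marker-derived kinship. The GLM scan
is the special case $\sigma_a^2 = 0$. The null hypothesis $v = 0$ is
tested with 1 numerator degree of freedom and $n - \mathrm{rank}(X) - 1$
denominator degrees of freedom; covariates count toward
$\mathrm{rank}(X)$.

The assumptions are the standard ones for quantitative-trait association:
an additive polygenic background whose covariance is proportional to $K$,
Gaussian residuals, and biallelic markers coded as allele dosages in
$[0, 2]$ (fractional after mean imputation). Multi-allelic VCF records are
rejected rather than split, because the whole testing framework assumes
one dosage per marker.

## Variance components: spectral REML

`estimate_variance_components()` maximizes the restricted likelihood over
the single ratio $\delta = \sigma_e^2 / \sigma_a^2$ (the EMMA reduction).
The kinship is projected onto the residual space of $X$ through an
orthonormal complement $Q_2$ ($X^\top Q_2 = 0$), and
$Q_2^\top K Q_2$ is eigendecomposed once, giving eigenvalues $\theta_i$
and rotated data $\eta_i$. The profiled restricted log-likelihood

$$ \ell_R(\delta) = \tfrac12\Big[(n-q)\log\tfrac{n-q}{2\pi} - (n-q)
   - (n-q)\log\sum_i \tfrac{\eta_i^2}{\theta_i+\delta}
   - \sum_i \log(\theta_i+\delta)\Big] $$

is evaluated on a 100-point grid uniform in $\ln\delta$ over $[-10, 10]$,
and every interior local maximum (plus the boundaries) is refined by
bounded scalar optimization to $10^{-8}$ in $\ln\delta$. The
global-then-local search guards against the multimodality that pure
derivative methods can fall into. REML — not ML — is the criterion
everywhere a likelihood is maximized, including pseudo-QTN selection.
The test suite certifies the spectral path against an independent
dense-matrix oracle (explicit $V$ inversion and log-determinants on a
10,001-point grid) to $10^{-6}$ log-likelihood units.

Degenerate inputs are rejected rather than patched: a trait numerically
perfectly explained by the fixed effects is an error, and a kinship with
an eigenvalue below $-10^{-8}$ is an input error. Eigenvalues in
$[-10^{-8}, 0)$ are floored to zero — round-off tolerance without masking
genuinely bad kinships.

## P3D testing

`make_p3d_context()` factorizes $V = \sigma_a^2 K + \sigma_e^2 I$
spectrally and whitens $y$, $X$ and each marker once, so every test is an
ordinary least-squares fit on transformed data at $O(n^2)$ per marker,
with the variance components estimated once (without any marker) and then
fixed — the P3D/EMMAX strategy. Eigenvalues of $V$ that underflow are
floored at $10^{-12}$ of the largest so the whitening stays finite even
for rank-deficient kinships built from very few markers. `mlm_scan(...,
p3d = FALSE)` instead re-estimates the components for every marker with
the marker in the fixed effects; the two orderings agree to rank
correlation above 0.99 on the synthetic panels (1,000 markers, 150
individuals) used in the acceptance tests, which is why P3D is the
default.

A marker collinear with the fixed effects (e.g. monomorphic) yields a
*no-test sentinel* — `p_value = NA` with a recorded reason — rather than
`p = 1` or an exception, so power bookkeeping can distinguish
"untestable" from "not significant". Sentinels never enter null
distributions.

## Kinship and its downdates

`compute_kinship()` implements the VanRaden genomic relationship
$K = MM^\top / c$ with $M$ the column-centred dosages
($M_{\cdot j} = w_j - 2p_j$, $p_j$ the observed allele frequency) and
$c = 2\sum_j p_j(1-p_j)$ over the included polymorphic markers. Constant
(monomorphic) columns contribute zero to both the numerator and $c$, so
appending one changes nothing. Allele frequencies are the *observed*
ones, recomputed from the current sample set; after exclusion, $c$ is
renormalized over the retained markers. This convention keeps
`exclude_markers()` — which subtracts each excluded column's outer
product from a retained $MM^\top$ and its $2p(1-p)$ term from $c$ —
*numerically identical* to a from-scratch recomputation ($\le 10^{-10}$
elementwise, verified on randomized subsets). The cross-product retention
doubles memory and is optional (`keep_crossproduct`), but it is what
makes per-marker complementary kinships affordable: a downdate is
$O(n^2)$ against $O(n^2 m)$ for recomputation.

## The SUPER procedure

1. **First stage.** Any scan that ranks markers works; the default is
   GLM because it is by far the cheapest and the downstream selection is
   robust to the first stage's inflation (an MLM first stage is one flag
   away).
2. **Bin optimization.** Markers at 1-based position $p$ map to bin
   $\lfloor (p-1)/b \rfloor$ per chromosome. Each non-empty bin is
   represented by its smallest-p marker (ties: smaller position, then
   lexicographic id). For each $(s, b)$ on a grid, the top $s$
   representatives define a kinship, and the restricted likelihood of the
   no-marker MLM under it is recorded; the maximizing cell wins (ties:
   smaller $s$, then smaller $b$). Defaults
   $b \in \{5\times10^5, 5\times10^6, 5\times10^7\}$ bp and
   $s \in \{10, 20, 40, 80\}$ span sparse-to-dense marker maps; both are
   configurable, and the full grid is retained in the result's
   `grid_log`. $s$ is capped at $n - \mathrm{rank}(X) - 2$ so the
   variance-component fit stays identifiable, and at the number of
   non-empty bins; capped cells are flagged, not dropped.
3. **Complementary scan.** For each tested marker $m$, the pseudo-QTNs
   $q$ with $r^2(m, q) \ge t$ are excluded from the kinship — genome-wide,
   because structure-driven LD is not local. $r^2$ is the squared Pearson
   correlation of dosage vectors, 0 by convention when either is
   constant. A marker in LD with *every* pseudo-QTN (always including
   itself, since $r^2 = 1$) is tested by GLM: an empty kinship carries no
   information, and the fixed-effects test is the natural limit. The
   default threshold $t = 0.10$ is the value that proved robust across
   the species panels in the method's original evaluation; `t > 1` turns
   exclusion off entirely (recovering the plain MLM under the pseudo-QTN
   kinship) and `t = 0` excludes everything (recovering GLM) — both
   limits hold exactly in the tests, to $10^{-10}$ in p-values.

Variance components are estimated once from the *full* pseudo-QTN
kinship and reused for every exclusion subset. Re-estimating per
exclusion set would cost an eigendecomposition per distinct set for a
second-order correction; we chose not to, and the limit equivalences and
power results support the choice. Test contexts are cached keyed by the
exclusion set, so the typical marker (which excludes nothing, or shares
its exclusions with its neighbours) reuses a factorization.

## The simulator

`simulate_genotypes()` draws structured panels under a Balding–Nichols
model: ancestral frequencies uniform on $[0.1, 0.9]$, subpopulation
frequencies $\mathrm{Beta}\!\big(p\frac{1-F_{st}}{F_{st}},
(1-p)\frac{1-F_{st}}{F_{st}}\big)$, and first-order local LD by copying
the previous marker's allelic state along each gamete with probability
`ld_rho`. Positions are evenly spaced on a stated chromosome plan.
Realized differentiation matches the $F_{st}$ parameter within $\pm0.05$
under a Hudson-type estimator in the tests. The default study panel —
two subpopulations at $F_{st} = 0.2$, `ld_rho = 0.5` (adjacent-marker
$r^2 \approx 0.25$), 3,000 markers on ten 100-Mb chromosomes, 200
individuals — is chosen to resemble a moderately structured diversity
panel with enough local LD for binning to matter, and it is *fixed*: all
power comparisons in the tests and the acceptance script run under these
conditions.

`simulate_phenotype()` builds traits exactly as the evaluation protocol
prescribes: QTNs sampled uniformly (optionally off a held-out
chromosome), effects $N(0, 1)$ applied to raw dosages, additive values
summed per individual, and residual variance
$V_e = V_a(1-h^2)/h^2$ where $V_a$ is the **realized** variance of the
additive values — so $h^2 = 0.75$ gives $V_e = V_a/3$ exactly, by
construction rather than in expectation. Two corner conventions:
$h^2 = 1$ returns the additive values with no residual, and $h^2 = 0$
(where the formula divides by zero) is defined as pure noise of variance
$V_a$, with the sampled QTNs recorded but unused and a loud message.
Genotypes, QTN sampling, effects, and residuals use separately derived
random streams so replicates differ only where intended.

What the simulator does **not** emulate: coalescent-exact LD decay,
allele-frequency spectra from real demography, dominance and epistasis,
genotyping error, and linked selection. Passing power comparisons on
these panels therefore demonstrate the *ordering* of methods under
controlled confounding — not absolute power on any real panel, where LD
structure and causal architecture differ.

## Evaluation protocol

`run_power_study()` reproduces the empirical-null design: per replicate,
simulate a trait on a fixed panel (regeneration per replicate is
optional), scan with each method, build the null from the non-QTN
markers — or, in the held-out-chromosome scenario, from the last
chromosome, which is barred from carrying QTNs — and take the
$\lceil \alpha k\rceil$-th smallest null p-value as the threshold (the
lower empirical quantile; the protocol's "threshold at 5% type I error"
does not specify a convention, and the lower quantile makes the realized
type-I error at most $\alpha + 1/k$). Power is the fraction of QTNs at
or below the threshold, credited **only to the QTN marker itself**, not
to linked neighbours — the strictest reading of "proportion of QTNs
detected". Failed replicates are warned about and excluded, never
silently dropped.

The method roster mirrors the five kinship strategies the method was
originally compared under: all SNPs (with and without the QTNs), QTNs
only, SUPER with known QTNs, and SUPER with masked QTNs. At the study
conditions above (20 QTNs, $h^2 = 0.75$, $\alpha = 0.05$, 30
replicates), the package reproduces the characteristic ordering —
SUPER-known > SUPER > all-SNP MLM > QTN-only — with the QTN-only kinship
collapsing because every tested QTN is confounded with the random
effect it helped define.

Problem sizes throughout the tests and `scripts/acceptance.R` (200
individuals, 1,000–10,000 markers, 30 replicates, 50 heritability
draws) are the package's choices for a thorough desk-scale
characterization; the drivers accept larger values unchanged.

## Numerical conventions, in one place

- Dosage bounds $[0, 2]$ enforced at construction; MAF
  $= \min(p, 1-p)$ with $p$ = mean dosage / 2.
- Marker filter keeps `maf >= min_maf` (boundary kept) and missingness
  `<= max_missing`; mean imputation preserves each marker's mean.
- Chromosome order: numeric-looking labels numerically, others after,
  lexicographically; positions non-decreasing within chromosome.
- $\delta$ search bounds $e^{\pm10}$; boundary optima are legitimate
  results (a trait with no polygenic signal lands at the upper bound).
- p-values are clamped away from exact zero at the smallest
  representable double, so $\lambda_{GC}$ and q-value math never see 0.
- Heterozygote coding in inbred panels is not special-cased: any dosage
  in $[0, 2]$ is accepted, and the kinship and F-tests are invariant to
  flipping a marker's coding $d \to 2 - d$.

## Known limitations

- No compressed MLM (grouped random effects), no factored single-
  decomposition speedup for the per-exclusion factorizations, and no
  exact per-marker variance re-estimation by default (available via
  `p3d = FALSE` at its full cost).
- Covariates are user-supplied; the package computes no structure PCs.
- The CLI's `power` subcommand generates panels via the simulator only;
  plugging a real panel into the study driver is an R-level call
  (`run_power_study(panel = ...)` on a read and imputed
  `genotype_matrix`) rather than a shell flag.
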