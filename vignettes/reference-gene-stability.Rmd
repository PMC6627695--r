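---
title: "Selecting stable qRT-PCR reference genes with miRGstab"
author: "miRGstab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable qRT-PCR reference genes with miRGstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRGstab)
```

## The problem

Relative quantification by qRT-PCR divides a target's signal by that of a
reference gene (RG) assumed invariant across conditions. When the RG is
itself regulated — a chronic risk for miRNA panels, where no universal
normalizer exists — every downstream fold change, significance call and
clustering inherits the distortion. miRGstab implements the standard
multi-algorithm workflow for choosing an RG from a panel of candidates
measured as quantification cycles (Ct or Crt; one cycle is roughly a
two-fold abundance difference at perfect efficiency) across grouped
samples, such as precursor (PC), differentiated (DC) and hypertrophic
(HYP) chondrocyte populations profiled during cartilage development.

Data live in a `CtExperiment`, a `SummarizedExperiment` with a single
`ct` assay, a `group` factor (and optionally `donor`) in `colData`, and
`NA` for undetected calls. Candidates must be completely detected:
`filterCompleteDetection()` drops any assay missing in at least one
sample before anything else runs, because every estimator below relies
on complete pairwise or per-group information.

## The four stability estimators

All "lower = more stable" values; each estimator ranks the full candidate
panel with ties broken by input order.

**BestKeeper** works on Ct values directly. Its dispersion is the mean
absolute deviation of a gene's Ct around its arithmetic mean (the
applet's "SD (± Ct)"), with `cv_pct = 100 · dispersion / mean` as an
auxiliary diagnostic. We deliberately use the mean absolute deviation,
not the n−1 standard deviation: the two are distinct statistics (MAD <
SD for any non-degenerate sample), and the descriptive SD of
`describeCt()` is kept separate for exactly that reason. Because it
never forms ratios, BestKeeper responds to shared per-sample technical
offsets — which is also what makes it a useful complement to the three
ratio-based methods.

**geNorm** transforms cycles to relative quantities
$q_{gs} = (1+E_g)^{\,Ct_{\min,g}-Ct_{gs}}$ with amplification efficiency
$E_g \in (0,1]$ (default 1, the ideal doubling, giving the familiar
$2^{-\Delta Ct}$). For genes $j,k$ the pairwise variation $V_{jk}$ is the
n−1 standard deviation over samples of $\log_2(q_j/q_k)$, and a gene's
$M_j$ is the mean of its $V_{jk}$ over all other remaining candidates.
The gene with the largest M is excluded and M is recomputed until two
genes remain; that final pair shares the final M. Internally $V_{jk}$ is
evaluated through the covariance identity
$V_{jk} = \sqrt{C_{jj}+C_{kk}-2C_{jk}}$ on the gene-by-gene covariance
matrix of $\log_2 q$, which is exact and makes each exclusion round a
subset operation; the test suite checks the whole exclusion sequence
against a naive implementation that recomputes every pairwise SD from
scratch each round. Because the published procedure reports the best two
genes jointly, integer ranks need a convention: the final pair takes
ranks 1 and 2 ordered by their M in the last three-gene iteration, the
remaining genes follow reverse exclusion order, and ties at an exclusion
step remove the gene occurring later in input order. The pairwise-
variation criterion for choosing *how many* RGs to use is not part of
this workflow and is not implemented.

**Comparative delta-Ct** scores gene $g$ by the mean, over partners $h$,
of the n−1 SD across samples of the pairwise difference
$\log_2 q_g - \log_2 q_h$ (at $E=1$, literally the SD of
$Ct_g - Ct_h$). This equals the mean of geNorm's pairwise $V_{gk}$ on
the full panel — an identity the acceptance tests assert to 1e−9 —
but involves no exclusion, so the two methods can rank differently.

**NormFinder** fits a two-way model on $y = \log_2 q$. Per-sample
technical effects are removed by subtracting each sample's mean over
genes. Within each group of $n_g$ samples and a panel of $k$ genes, the
raw residual variance $s^2_{ig}$ is corrected for the finite panel
($E[s^2_{ig}] = (1-2/k)\sigma^2_{ig} + \bar\sigma^2_g/k$ under the
model), giving
$\hat\sigma^2_{ig} = \max\!\big(0,\ \tfrac{k}{k-2}\,(s^2_{ig}-\bar
s^2_g/(k-1))\big)$ — negative estimates are clipped at zero before any
square root. In multi-group mode the gene's intergroup deviation
$d_{ig}$ (its sample-effect-corrected group mean minus its across-group
mean) is doubly centered — deviations sum to zero over genes within each
group and over groups within each gene, leaving $(k-1)(G-1)$ effective
degrees of freedom — and shrunk toward zero in proportion to its
estimation variance:
$\tilde d_{ig} = d_{ig}\,\gamma^2/(\gamma^2 + \hat\sigma^2_{ig}/n_g)$,
with $\gamma^2 = \max\!\big(0, \sum d^2/((k-1)(G-1)) - \overline{
\hat\sigma^2/n}\big)$ the estimated true intergroup variance. The
stability value averages over groups the magnitude of the shrunk
deviation plus the intragroup standard error,
$\rho_i = \tfrac1G\sum_g\big(|\tilde d_{ig}| +
\sqrt{\hat\sigma^2_{ig}/n_g}\big)$; in single-group mode (one tissue at
a time, where no sub-grouping exists) it is simply
$\sqrt{\hat\sigma^2_i}$. The exact bias-correction and shrinkage
weighting of the original publication leave some freedom of formulation;
the variant above was chosen for its clean unbiasedness derivation and
is validated behaviourally — identical gene profiles yield $\rho = 0$
exactly, a planted 2-cycle group shift makes its gene the least stable
in ≥95% of 200 simulated panels, and per-sample offsets cancel to
machine precision.

## Consensus and overlap

`combineRankings()` takes the integer ranks (never the raw values, whose
scales are incommensurable) and computes each gene's geometric mean
rank; the consensus ordering is ascending in that geomean. Ties are
broken by the better comparative delta-Ct rank — it aggregates all
pairwise information without exclusion — then input order.
`topKOverlap()` reports Venn region counts of each method's top-k set
(k = 15 by convention for a ~47-gene panel).

## Impact of the normalizer

`normalizeToReference()` produces per-sample
$\Delta Ct = Ct_{target} - Ct_{ref}$; `compareGroups()` applies the
unpaired two-tailed Student's t-test with pooled variance (the classical
test, not Welch — group variances are assumed comparable on the
$\Delta Ct$ scale), with tiers \*\*\*\* ≤ 1e−4, \*\*\* ≤ 1e−3, \*\* ≤
0.01, \* ≤ 0.05, and `#` marking the trend band 0.05 < p ≤ 0.1.
Outliers are screened by the two-sided single-outlier Grubbs test
(critical value $\frac{N-1}{\sqrt N}\sqrt{t^2/(N-2+t^2)}$ with $t$ the
upper $\alpha/2N$ quantile on $N-2$ df). Whether flagged points are
*removed* before testing is a genuinely open choice; removal is
off by default, limited to a single pass and one point per group when
enabled, and flags are disclosed either way.

`clusterHeatmap()` reproduces heatmap-style clustering of a
reference-normalized panel: normalize every gene by the reference, drop
the reference row, center rows to mean zero, and cluster rows and
columns by average linkage on correlation distance (1 − Pearson r). A
row that is constant after normalization has undefined correlation
distance; such rows are excluded from the dendrogram with a warning
(never silently imputed) and reported alongside the centered matrix.
Constancy is judged at a variance below 1e−20, i.e. numerical zero on
the cycles scale.

## The synthetic generator

`synthConfig()`/`simulateCtExperiment()` draw
$Ct_{gs} = B_g + \delta_{g,\mathrm{group}(s)} + u_s + \varepsilon_{gs}$:
uniform baselines $B_g$ on 13–26 cycles (the observed span of mean
expression in the motivating chondrocyte panels), shared per-sample
offsets $u_s \sim N(0, \tau^2)$ with $\tau = 0.5$ cycles (a typical
loading/RT technical spread), Gaussian per-gene noise with background
$\sigma_g \sim U(0.5, 1.2)$, and planted roles: 3 stable genes
($\sigma = 0.2$), 3 high-variance genes ($\sigma = 2$), 3 group-shifted
genes ($\delta = 2$ cycles in one group, round-robin over groups) in a
47-gene × 26-sample (PC 8, DC 9, HYP 9) default layout. Gaussian noise
on the cycle (log-fluorescence) scale is the standard qPCR error model.
Missing calls, when requested, hit background genes uniformly at random
— dropout is *not* abundance-dependent here, so the generator exercises
the detection filter but does not emulate the censoring-by-low-expression
mechanism of real panels. Likewise absent: plate/position effects,
probe cross-hybridization, and efficiency variation. Passing tests on
this generator therefore demonstrate algorithmic correctness and
sensitivity under an idealized error model, not robustness to every
artifact of array-based qPCR.

The offset SD multiplies a pre-drawn standard-normal stream, so two
simulations with the same seed and different $\tau$ share identical gene
noise — the construction behind the sensitivity result that raising
$\tau$ inflates BestKeeper dispersions while leaving the three
ratio-based estimators bit-for-bit unchanged.

`recoveryExperiment()` wraps the full pipeline over replicates and
reports three rates: how often a planted stable gene is consensus
rank 1, how often planted group-shifted genes land in NormFinder's
bottom decile, and how often the offset contrast above affects
BestKeeper alone. With strong separation (stable $\sigma = 0.1$ against
background $\sigma = 1.5$ and 2-cycle shifts) consensus recovery is
essentially certain; the problem sizes used throughout (47 × 26 panels,
100–200 replicates) keep each experiment in the tens of seconds.

## Numerical and design notes

- All sample SDs use the n−1 denominator except BestKeeper's dispersion,
  which is a mean absolute deviation by definition.
- Efficiencies are per-gene, default 1; the transformation to relative
  quantities anchors each gene at its minimum Ct within the analyzed
  subset, a choice the stability values are invariant to (it rescales
  every $q$ of a gene by a constant).
- Ct and Crt are one currency; the reader records which label the source
  used purely as metadata (`ctDialect`).
- The between-tissue correlation of `datasetCorrelation()` pairs genes
  by group-mean Ct (donor-level pairing is not generally available when
  group sizes differ); bands: R² > 0.8 very strong, < 0.6 fair.
- No multiple-testing correction is applied across group comparisons —
  the workflow mirrors the single-target testing practice it models;
  users scanning many targets should correct downstream.
- Degenerate inputs: a pooled t-test with zero pooled variance returns
  t = 0, p = 1 when means agree (and p = 0 otherwise); Grubbs on a
  constant vector reports no outlier with an undefined G.

## A worked run

```{r example, eval = FALSE}
sim <- simulateCtExperiment(synthConfig(), seed = 1)
ce  <- sim$experiment
tabs <- runAllStability(ce, dataset = "pooled")
cons <- combineRankings(tabs)
head(cons, 3)
sim$truth$role[cons$gene[1:3]]  # the top consensus genes are planted stable
```

File-based runs (`rankWorkflow()`, `impactWorkflow()`,
`simulateWorkflow()`) write plain CSV/JSON run directories with a
manifest; `inst/cli/mirgstab.R` is a thin Rscript front end over the
same functions.
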