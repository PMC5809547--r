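---
title: "Accuracy and stability of regularized partial correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accuracy and stability of regularized partial correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Psychological and epidemiological networks are *estimated* objects: each
edge is a statistical parameter fitted to a finite sample, and every
quantity derived from the network — most prominently the centrality
indices used to single out "important" variables — inherits that sampling
error. A network estimated from a few hundred cases can look richly
structured while none of its apparent asymmetries survive replication.
This package implements a post-estimation workflow that makes the
uncertainty visible: bootstrapped confidence intervals for edge weights,
a subset-bootstrap stability analysis for centrality orderings, and
bootstrapped difference tests between edges and between centralities.

## The model

For approximately multivariate-normal (or latent-normal ordinal) data the
pairwise conditional-independence model is the Gaussian graphical model
(GGM). Writing $K$ for the precision matrix (inverse covariance), the
edge weight between nodes $i$ and $j$ is the partial correlation

$$ w_{ij} \;=\; -\,\frac{\kappa_{ij}}{\sqrt{\kappa_{ii}\,\kappa_{jj}}}, $$

the correlation between $i$ and $j$ after conditioning on all other
variables; $w_{ij} = 0$ means conditional independence. A $p$-node GGM
has $p + p(p-1)/2$ free parameters (`paramCount()`), which quickly
outgrows typical sample sizes, so estimation uses the graphical lasso:
$\ell_1$-penalized precision estimation that sets many $w_{ij}$ to exactly
zero. The penalty $\lambda$ is chosen by minimizing the extended Bayesian
information criterion

$$ \mathrm{EBIC}_\gamma \;=\; -2\,\ell(\hat K)\; +\; E \log n\; +\;
   4\,E\,\gamma \log p, $$

with $E$ the number of nonzero edges and
$\ell(\hat K) = \tfrac n2\big(\log\det\hat K -
\operatorname{tr}(S\hat K)\big)$ up to a constant. Constant terms are
dropped (only EBIC differences matter) and the likelihood uses the
denominator-$n$ convention; selection is invariant to that choice but it
is fixed here for reproducibility.

### Ordinal data

Questionnaire items with a handful of score categories are treated as
discretized latent normal variables. `estimateCorrelations()` computes
two-step polychoric correlations: thresholds are fixed at the inverse
normal CDF of the cumulative category proportions, then the latent
correlation of each pair maximizes the bivariate-normal likelihood of the
contingency table over $[-0.999, 0.999]$. Mixed pairs use the analogous
two-step polyserial; continuous pairs use product-moment correlations. A
column is auto-detected as ordinal when it is integer-valued with at most
10 distinct values; the rule can be overridden per column. Tables with an
empty cell receive a continuity constant of 0.5 in every cell before
likelihood evaluation (switchable off), which prevents boundary estimates
at $\pm 1$. Because a pairwise-assembled polychoric matrix need not be
positive definite, the result is repaired by `nearestPD()`: eigenvalues
clipped at `pdFloor = 1e-6`, rescaled to unit diagonal, iterating the
clip because the rescaling itself can nudge the smallest eigenvalue back
under the floor. Missing values use pairwise-complete observations by
default (listwise available); neither choice is canonical and both are
stated rather than inferred.

## Centrality

`centralityTable()` computes the three standard weighted-network indices:
node *strength* $\sum_j |w_{ij}|$, *closeness* (inverse summed
shortest-path distance), and *betweenness* (number of shortest paths
through a node, fractional credit for ties, endpoints excluded). Edge
lengths are $1/|w_{ij}|$: stronger associations are shorter. The
absolute value matters — it makes all three indices invariant to edge
signs, so a ring network with constant $|w|$ (the simulator's null
model) has exactly equal centralities whatever the sign pattern. A node
that cannot reach some other node gets closeness 0, a convention that is
defined, conservative, and stable under bootstrap resampling where edges
vanish. Z-standardized columns use the population SD across nodes, with
z = 0 when the SD is zero.

## The accuracy workflow

### Edge-weight confidence intervals

`nonparametricBoot()` resamples rows with replacement, re-runs the
estimator and stores every replicate's edge weights and centralities.
`edgeCITable()` forms the $1-\alpha$ interval between bootstrap
quantiles $\alpha/2$ and $1-\alpha/2$. Quantiles use the Hyndman–Fan
type-6 rule, $h = (n+1)p$, clamped to the extreme order statistics
outside $[1, n]$: the default type-7 rule produces intervals that are
too narrow for this purpose. With $N_B$ replicates no CI below
$\alpha = 2/N_B$ exists (`minAlpha()`); at exactly that level the CI is
defined as the range of the replicates. Two deliberate omissions: the
CIs are never turned into edge-vs-zero significance flags (the lasso
already performed model selection, so a retained edge is already
evidence of presence), and no $p$-values are ever derived from the
bootstrap distributions — regularized estimates have decidedly
non-normal sampling distributions and only CI-based decisions are
supported.

A parametric variant (`parametricBoot()`) samples multivariate-normal
data from the correlation implied by the estimated network
(`pcorToCor()`). Its replicates are continuous even when the original
data were ordinal, and lasso shrinkage biases the generating model
toward zero, so the nonparametric bootstrap is preferred for ordinal
data; the result carries a `continuousData` flag as a reminder.

### Centrality stability and the CS coefficient

Bootstrapped sampling distributions of centrality indices are biased, so
no centrality CIs are produced anywhere in the package. Instead
`caseDropBoot()` probes *stability*: drop a fixed proportion of rows at
random (the m-out-of-n bootstrap), re-estimate, and correlate subset
centralities with the full-sample ones, over a grid of drop proportions
(default: ten levels from 0.10 to 0.75, so at least a quarter of the
cases always remain). The correlation is product-moment by default
(Spearman by flag). A subset whose centralities have zero variance has
no defined correlation; it is recorded as 0, so degenerate estimates
count against stability instead of hiding inside an average.

`csCoefficient()` condenses the curves: CS(cor = 0.7) is the largest
tested drop proportion at which at least 95% of replicates still
correlate $\ge 0.7$ with the original centralities. When Monte-Carlo
noise makes the qualifying proportion non-monotone over levels, the
largest qualifying level is still reported (that is the definition) with
a warning naming the failing smaller levels. Simulation evidence puts
the interpretability bar at CS $\ge$ 0.25, preferably $\ge$ 0.5; both
cutoffs are attached to printed output as indicative bands, never
enforced as errors. Node-dropping is available through the same code
path (`dropNodes = TRUE`) but is harder to interpret — dropping half the
nodes yields a structurally different network — and is documented as a
minor option.

### Difference tests

`differenceTest()` subtracts the bootstrap values of one edge (or one
node's centrality) from another *within each replicate* and builds a
type-6 CI around the paired differences; the null of equality is
rejected when 0 falls outside. A zero-width interval at exactly 0 —
common under the lasso, which ties many estimates at zero — counts as
containing zero, a conservative convention. `differenceMatrix()` runs
all pairs and reports the analytic test count; no multiple-testing
correction is applied or offered, because the smallest attainable level
$2/N_B$ is orders of magnitude above a Bonferroni level such as
$0.05/17{,}955 \approx 0.000003$ for all edge pairs of a 20-node network
(`edgeDiffCount()`, `bonferroniAlpha()` provide the arithmetic only).

## The simulator

`chainNetwork()` builds the canonical null model: a closed ring
(each node tied to its two neighbours) with constant weight magnitude
(0.25 by default, 0.3 in the edge-difference design) and a random half
of the edges negated — all centralities exactly equal by symmetry.
`rewireNetwork()` applies Watts–Strogatz rewiring: each edge
independently, with the given probability, keeps one endpoint and moves
the other to a uniformly chosen node that creates no self-loop or
duplicate; the current partner is excluded, so a selected edge always
moves. Edge count and the weight multiset are conserved, and the result
is redrawn (bounded retries) if the implied precision loses positive
definiteness. `simulateDataset()` draws multivariate-normal data from
the implied correlation and ordinalizes each variable at `levels - 1`
i.i.d. standard-normal thresholds, redrawing a variable's thresholds
until every category is observed (polychoric estimation needs all
categories present; the redraw rule is this package's declared choice).
Ordinalization is strictly monotone per variable.

`runStudy()` chains the pieces into three validation studies — the CS
distribution, edge-difference calibration, and centrality-difference
calibration — enumerating rewiring probability × sample size conditions
with a fresh network, dataset, and bootstrap per replicate. Monte-Carlo
standard errors are computed across datasets, the independent
replication unit (pairs within a dataset share one bootstrap and are
dependent).

```{r}
library(netstab)
design <- simulationDesign(rewiring = 0, n = c(100, 500, 2500),
                           replicates = 100, nBoots = 200, seed = 301)
study <- runStudy(design, "centrality_diff")
summary(study)
```

### Problem sizes

`simulationDesign(scale = "desk")` (the default) uses 100 datasets per
condition and 200 bootstrap samples per dataset, sizes chosen so a full
calibration study completes on one desktop core in minutes; the shipped
test suite and `scripts/acceptance.R` run at this scale.
`scale = "full"` switches to 1000 datasets and 1000 bootstrap samples —
24,000 datasets for the four-rewiring, six-sample-size CS and centrality
designs, 6,000 for the edge design — for cluster-scale replication.
Desk-scale rates carry Monte-Carlo error of a few percentage points;
every summary therefore reports its MC-SE alongside.

## What the synthetic data do and do not show

The generator emulates the study conditions the methodology was
validated under: latent-normal variables, symmetric-ring or rewired
sparse truths with homogeneous edge magnitudes, four-category
ordinalization at random thresholds. Real questionnaire data differ in
ways the simulator deliberately does not model: heterogeneous edge
weights, skewed category distributions, local dependence violating the
latent-normal assumption, and missingness. Passing calibration tests on
the simulator therefore shows the bootstrap machinery is correct and
calibrated *under the model*, not that any particular empirical network
is accurate. The bundled `ptsdFixture()` is likewise synthetic — a
17-item, four-category positive-manifold network with three deliberately
dominant edges — built so the tutorial workflow can run end-to-end
without gated clinical data; `externalReference()` records the published
results for the real 17-item PTSD analysis (N = 359) purely as
reference numbers for users who obtain that dataset.

## Numerical choices and degenerate inputs

* Polychoric likelihood: bivariate-normal CDF via Gauss–Legendre
  quadrature of the asin-substituted integral for $|\rho| \le 0.925$ and
  panelled quadrature of the conditional-CDF integral above; cell
  probabilities floored at $10^{-12}$; Brent search with tolerance
  $10^{-7}$, non-convergence reported per pair.
* Graphical lasso: blockwise coordinate descent, diagonal unpenalized,
  100 log-spaced $\lambda$ values from $\lambda_{\max}$ (the largest
  absolute input correlation, giving an empty graph) down to
  $0.01\,\lambda_{\max}$, warm starts along the path, convergence
  tolerance $10^{-4}$ relative to the mean absolute off-diagonal input
  (tightened automatically for fixed-$\lambda$ fits). An edge counts as
  present when $|w| > 10^{-10}$. $\gamma$ defaults to 0.5; these grid
  defaults follow the established tooling for EBIC-selected glasso since
  the methodology itself does not prescribe them.
* EBIC ties along the path resolve to the larger $\lambda$ (sparser
  model).
* Shortest-path ties are detected with a $10^{-12}$ relative tolerance;
  Brandes accumulation then assigns fractional betweenness credit.
* Estimator failures inside any bootstrap loop are redrawn with fresh
  resamples — keeping the replicate count, and with it the $2/N_B$
  bound, as specified — with an abort once failures exceed 10%.
* Constant columns, single-category ordinal variables, and
  non-Gaussian-representable networks raise immediate errors naming the
  offending variable or pair.

## Known limitations

* EBIC-selected glasso networks at large $n$ typically retain a few
  spurious edges of very small magnitude alongside the fully recovered
  true structure; the test suite pins down exactly this behaviour (full
  recall, weak extras). Edge *presence* near the selection boundary
  should not be over-interpreted.
* No confidence intervals for centrality indices are produced — the
  bootstrapped sampling distributions are biased and an unbiased
  interval construction is an open problem.
* Bonferroni-corrected bootstrap difference tests are out of scope (the
  required $\alpha$ levels are unattainable with feasible $N_B$), as are
  network-vs-network comparison tests, Ising/mixed graphical models, and
  the nonparanormal transformation; the estimator argument of the
  bootstrap functions accepts any `function(data) -> networkModel`, so
  other estimators can be plugged into the same accuracy machinery.
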