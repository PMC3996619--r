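---
title: "Dating waves of habitat colonization: models, nulls, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating waves of habitat colonization: models, nulls, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefwaves)
```

## The question and the inference chain

Given a time-calibrated, family-level phylogeny and a binary habitat state
per family (here: reef-dwelling vs not), when did lineages move into the
habitat, and did those moves cluster into discrete waves? `reefwaves`
answers this with a chain of five linked analyses:

1. **Habitat resampling.** Each family's fraction of reef-associated
   species is treated as a Bernoulli probability, and replicate binary
   habitat datasets are drawn, so habitat-coding uncertainty propagates
   into everything downstream instead of being collapsed by a threshold.
2. **Stochastic character mapping.** A two-state continuous-time Markov
   (Mk) model is fitted per (dataset, tree) pair, and full character
   histories — event ages on branches, not just ancestral states — are
   sampled from the posterior.
3. **Transition timing.** Event ages are pooled into 1-Myr bins (in Ma
   before present) and compared with a tip-shuffle null: the same
   machinery run on datasets whose states were permuted across families.
   Contiguous runs of positive excess are the candidate colonization
   waves.
4. **Phylogenetic clustering.** Two views of the same question: fewer
   empirical transitions than the null implies phylogenetic inertia in
   the habitat state, and the net relatedness index (NRI) measures
   whether reef families sit closer on the tree than a random set of the
   same size.
5. **Disparity through time (DTT).** On phylogenetic principal
   components of 12 morphometric traits, mean relative subclade
   disparity is tracked from root to present and placed, per 1-Myr bin,
   as a percentile within a Brownian-motion (BM) null; values near 100
   indicate within-clade disparity as high as the whole fauna —
   morphological convergence across clades.

Ages are always Ma before present (tips at 0); rates are per Myr.

## The Mk model and its grid posterior

The binary chain is parameterized by an overall rate $r > 0$ and a bias
$b \in (0,1)$:

$$q_{01} = 2rb, \qquad q_{10} = 2r(1-b),$$

so $b = 0.5$ recovers the symmetric model with $q_{01}=q_{10}=r$ and $r$
keeps the interpretation of expected events per lineage-Myr in the
symmetric case. Transition probabilities use the closed form
$P_{00}(t) = (q_{10} + q_{01}e^{-st})/s$ with $s = q_{01}+q_{10}$, and the
tip-data likelihood is the standard pruning recursion, computed in log
space with per-node rescaling.

Rather than MCMC, the posterior over $(b, r)$ is computed by direct
normalization over a discrete grid:

* **Bias prior:** a symmetric Beta($\alpha,\alpha$) discretized into
  $\kappa$ category midpoints, with $\alpha = 1$, $\kappa = 101$ as the
  flat default — the discretization conventionally used for this prior in
  stochastic-mapping software.
* **Rate prior:** a Gamma(shape $1.25$) discretized into 60
  equal-probability quantile midpoints. The scale is set, by default, so
  the prior mean equals (Fitch parsimony changes)/(total tree length).
  Software implementing stochastic mapping describes a branch-length
  based rate prior without reducing it to hyperparameters; this auto-scaled
  Gamma is this package's declared, fully reproducible stand-in, and both
  hyperparameters are configurable in `mk_prior()`.

With two states the grid (101 × 60 points) is exact to evaluate, removes
convergence diagnostics from scope, and makes parameter draws trivially
reproducible. The root prior defaults to the stationary distribution of
$Q$ ($\pi_1 = q_{01}/s$), configurable to flat or to an explicit simplex.

## Sampling histories

Internal node states are drawn jointly by the standard two-pass scheme:
conditional likelihoods up the tree, then root-to-tip sampling. Branch
paths conditional on endpoint states use rejection sampling: the
unconditioned chain is simulated from the parent state and accepted when
the endpoint matches; when the endpoints differ, the first event is drawn
from a truncated exponential, which is an exact conditioning on the event
"at least one jump" and therefore leaves the target law unchanged. After
10 000 failed attempts the sampler falls back to uniformization — jump
count drawn from the Poisson mixture conditioned on the endpoints, jump
times uniform, states filled by a discrete bridge, virtual jumps dropped —
which terminates for any rates and branch length. The two samplers are
checked against each other, and against the closed-form parity-restricted
Poisson law of the symmetric chain, in the test suite.

Event ages are stored in Ma before present, because all downstream
binning is in absolute time. Bins are half-open $(a-1, a]$ with integer
right edges, so an event at exactly 70.0 Ma falls in $(69, 70]$. Reported
series are per-map means ("average number of transitions per Myr"); the
per-map count matrices are retained so dispersion and null quantiles can
be recovered under any other aggregation.

Wave detection follows the sign of the per-bin excess (empirical mean
minus null mean), with no formal test — the comparison is qualitative by
design — but per-bin 2.5%/97.5% null quantiles are reported alongside.

## The tip-shuffle null

Every null dataset is a uniform permutation of a real dataset's states
across families, conserving state counts exactly while destroying
phylogenetic association. Null datasets are mapped and binned by the
identical code path. The default design multiplies each of the habitat
datasets into $k = 5$ shuffled copies, mirroring the study design of 100
empirical datasets × 50 trees × 10 maps against 500 null datasets × 10
trees × 10 maps.

## Disparity through time

Traits enter as natural logs of linear measures, $\ln(\mathrm{mass}^{1/3})$
for mass, and the suction index passed through unchanged. The suction
index is computed as
$\mathrm{SI} = \mathrm{CSA}_{ep} \cdot (L_{in}/L_{out}) / A_{buccal}$ with
an elliptical epaxial cross-section $\mathrm{CSA}_{ep} = (\pi/4)hw$ and a
rectangular buccal projection $A_{buccal} = \text{gape} \times
\text{buccal length}$. The exact cross-section geometry lives in the
functional-morphology literature rather than in the analysis this package
reimplements; the formula above is the package's declared convention, and
it is dimensionless and linear in epaxial area, the two properties the
tests pin down.

Phylogenetic PCA removes the generalized-least-squares mean and
eigendecomposes the BM evolutionary covariance
$(X-\hat a)^\top C^{-1} (X-\hat a)/(n-1)$; all 12 axes are retained and
enter the DTT equally weighted, which is how "the same variances as the
12 PC axes" is read here.

Subclade disparity is the mean squared Euclidean distance over unordered
tip pairs, computed through the exact identity
$\sum_{i<j} d^2_{ij} = m \sum_i \lVert x_i - \bar x \rVert^2$ (checked
against the brute-force double loop to $10^{-12}$). The DTT curve
evaluates, at every internal node age from root to present, the mean of
the relative disparities (subclade over whole tree) of all subclades
whose ancestral lineages are present at that age; it starts at exactly 1
(the single root lineage is the whole tree) and ends at exactly 0
(singleton subclades).

The BM null simulates 1000 datasets (200 in the desk-scale demo) of
independent axes with per-axis rates estimated from the data by the
independent-contrasts variance estimator, computes each DTT curve, and
places the empirical curve per 1-Myr bin as a midrank percentile —
midranks so that exact ties (e.g. the root value of 1 shared by every
curve) resolve to 50 instead of saturating at 0 or 100. Conversion from
relative to absolute time uses each tree's own root age; bins older than
a given tree's root contribute nothing for that tree. Percentile profiles
pool across trees into per-bin histograms (the density-strip data), with
the central 95% interval of the uniform null (2.5, 97.5) as reference
lines.

Two calibration facts the test suite enforces: profiled against a null
simulated at the generating rates, BM data give percentiles uniform on
(0,100) (exact exchangeability); profiled against re-estimated rates —
the operational procedure — the tail calibration still holds (≈2.5% of
bins above the 97.5th percentile). The uniformity check excludes bins in
the root segment of the curve, where relative disparity is identically 1
for data and null alike and the percentile is degenerately 50.

## NRI

Mean pairwise patristic distance (MPD) among reef tips, against MPDs of
uniformly resampled tip sets of the same size.
$\mathrm{SES} = (\mathrm{obs} - \bar{\mathrm{null}})/\mathrm{sd}(\mathrm{null})$
and $\mathrm{NRI} = -\mathrm{SES}$ are both reported to sidestep the
literature's sign ambiguity; clustering means negative SES, positive NRI.
The rank p-value uses the +1 correction,
$p = (1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(n_{null}+1)$, for the
clustering tail. A degenerate null (zero SD, e.g. two tips) is flagged
rather than divided by.

## The synthetic-data generator

Every stage is validated against data with known truth:

* **Trees.** Crown birth–death simulation conditioned on both crown
  lineages surviving, so the root age is exact; extinct lineages pruned.
  To emulate *family-level* trees — whose divergences are concentrated
  deep, because within-family speciation is pruned away by exemplar
  sampling — the generator can subsample a fixed number of tips uniformly
  from a large simulated species pool (`sample_tips`). Deep lineages
  survive subsampling almost surely, so the retained tree has the bulk of
  its nodes before ~40 Ma, matching the geometry of the empirical system.
  Posterior-like tree sets are produced by jittering node ages with
  order-preserving lognormal perturbations of the age ratios
  (`perturb_tree_ages`), holding taxa and topology fixed — an emulation
  of dating uncertainty, not of topological uncertainty.
* **Histories.** Exact piecewise forward simulation of the 2-state chain,
  with optional time windows multiplying the gain/loss rates (segment
  boundaries at window edges; no discretization). The default demo
  scenario has ~200 families at root age 120 Ma with the gain rate
  elevated tenfold inside (90, 72] and (65, 56] Ma — a two-wave geometry —
  base rate 0.011/Myr with bias 0.11 (gains rare, losses common enough to
  prune colonist clades toward single families), and a non-reef root.
  Under these conditions a realization carries roughly 30–65 true gains
  and a reef minority of about 25–90 of 200 families, the scale of the
  empirical system (~50 inferred gains; 35–53 reef families of 228).
* **Traits.** BM per axis; optionally, lineage segments in state 1 evolve
  under an exact Ornstein–Uhlenbeck pull toward a shared optimum, the
  generating analogue of habitat-linked convergence. The demo uses a
  moderate pull (optimum ~1 BM-SD away, characteristic time ~14 Myr) so
  reef and non-reef morphologies overlap; the validation scenario for the
  convergence signature uses a strong pull with gains confined to an old
  window, so every reef lineage has had time to converge.
* **Percentages.** A mixture of point masses at 0 and 1 plus a Beta
  component, matching the empirical pattern that most families are
  mostly-reef or mostly-not.

What passing tests on these data do **not** show: the generator has no
topological uncertainty across trees, no trait-dependent diversification,
no rate variation among lineages, and habitat percentages tied tightly to
the generating states; real data violate all four, so green validation
here demonstrates correctness of the machinery, not robustness of the
scientific inference to model misspecification.

## Validation experiments and their scales

The acceptance suite (one test per claim, `tests/testthat/test-acceptance.R`,
mirrored by `scripts/acceptance.R`) runs at these problem sizes, chosen to
give each binomial or distributional check useful resolution at desk
scale:

* Pruning likelihood vs brute-force enumeration: 200 random trees of 3–6
  tips, agreement to $10^{-10}$.
* Node-state marginals vs enumeration on a 4-tip tree at 100 000 draws
  (3 SE); conditional path law vs the closed-form symmetric pmf at
  50 000 draws ($\chi^2$, $p > 0.01$).
* Transition recovery: 50 scenarios of ~200 tips; the true total must
  fall inside the central 95% of 100 mapped counts in ≥ 90% of
  replicates. Wave recovery: 15 two-wave replicates, 100 empirical vs
  100 null maps each; a positive-excess interval must overlap each
  generating window in ≥ 90% of replicates.
* Clustering direction: 30 low-rate replicates conditioned on an
  informative split (≥ 5 families per state, since minimal datasets give
  exact ties); NRI calibration over 400 random label draws.
* DTT calibration: 150 trees of 40 tips, 500-simulation nulls, one
  independent bin per tree for the KS check.
* Convergence signature: 40 replicates with ≥ 15 reef tips (DTT medians
  on smaller subtrees are rank-noisy).

Wave recovery for the younger window is the chain's known hard case: the
tip-shuffle null carries more total events than clustered empirical data,
and mapped event ages smear over the branches crossing a window, which are
long once branching thins after ~56 Ma. The older window is recovered
reliably; the younger one in roughly 60–95% of replicates depending on the
seed. The per-bin null quantiles reported by `compare_series()` make this
resolution limit visible in any concrete run.

## Numerical choices and degenerate inputs

* Ultrametricity tolerance $10^{-6} \times$ root age; violating trees are
  rejected with the offending tip named, never repaired.
* Zero-length branches carry no events by construction; a zero-length
  branch with differing endpoint states is an error.
* Exact zeros of the uniformization bridge probabilities can round to
  tiny negatives; they are clamped at 0.
* Posterior grids that underflow to zero mass everywhere raise an error
  rather than returning NaNs.
* All-identical habitat states are legal: the auto-scaled rate prior
  floors the parsimony count at one change.
* Families missing a percentage are dropped with a warning, not imputed.
* Seeds: every orchestration stage derives its seed from the master seed
  and a stage label (`derive_seed`), all below $2^{31}$.

## Known limitations

* The Mk model is homogeneous in time and across lineages; the waves are
  recovered through the data's demands, not through a time-varying rate
  model, and inferred event ages inherit branch-scale uncertainty.
* Wave detection is sign-based by design and carries no multiplicity
  control; intervals should be read alongside the null quantiles.
* The grid posterior's resolution is bounded by its 101 × 60 default; for
  very large trees with extreme rate scales the auto-scaled Gamma grid
  should be revisited.
* `phylo_pca` assumes a non-singular phylogenetic covariance; duplicate
  zero-length tips will error.
* The DTT percentile against re-estimated rates is mildly conservative
  (mid-concentrated), a property shared with the procedure it
  reimplements.
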