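---
title: "Ensemble neural-network scoring functions: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble neural-network scoring functions: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affinet)
```

# The model

A scoring function maps a protein–ligand complex, described by a numeric
feature vector, to a binding affinity on the $-\log K_d$ / $-\log K_i$
scale. The base learner throughout `affinet` is a one-hidden-layer
feed-forward perceptron with logistic-sigmoid hidden units and a linear
output neuron, with both bias parameters absorbed into the weight sets via
constant units:

$$\hat y = O\!\left(\sum_{h=0}^{H} w_{h,o}\,
  S\!\left(\sum_{i=0}^{|p|} w_{i,h}\, x_i\right)\right),
  \qquad S(u) = \frac{e^u}{1+e^u},\quad O(u) = u,$$

where $x_0 = 1$ feeds the hidden biases and the $h = 0$ term passes the
output bias through $S(\cdot) \equiv 1$. A model with `hidden = 20`
therefore has 19 sigmoid units plus the constant unit. Weights minimise
the weight-decay (ridge-penalised) least-squares criterion over **all**
weights of both layers, biases included:

$$E = \sum_{n=1}^{N} (y_n - \hat y_n)^2 + \lambda \sum_{i,j} w_{i,j}^2 .$$

Inputs are min/range scaled to $[0,1]$ on the training rows (the scaler is
stored in the model); the target is left unscaled, since the linear output
neuron covers its range.

Two ensembles are built from this learner:

* **Bagging (BgN-Score).** Each of $L$ members trains on a bootstrap
  resample of the $N$ rows (drawn with replacement, size exactly $N$) and
  on a random subset $p_l$ of `subset_size` features drawn without
  replacement — the random-subspace convention. The prediction is the
  member average $\hat y = \tfrac1L \sum_l f_l(x^{p_l})$. Rows absent from
  a member's bootstrap are its out-of-bag (OOB) validation set; on average
  $(1 - 1/N)^N \approx 34\%$ of rows are out-of-bag for any member.

* **Boosting (BsN-Score).** Stage 1 trains on *all* rows against the
  measured affinities; the working residuals start at
  $R^1 = Y - \nu\,\hat Y_1$. Each later stage bootstraps the rows, draws a
  fresh feature subset, trains on the *sampled rows' current residuals*
  (duplicated rows carry duplicated residuals), predicts on the full
  training set and updates $R^l = R^{l-1} - \nu\,\hat Y_l$. The prediction
  is the shrunk sum $\hat y = \sum_l \nu f_l(x^{p_l})$.

A deliberate property of the boosted model: *every* stage, the first
included, is shrunk by $\nu$, so the total model weight is $L\nu$. With the
benchmark shrinkage $\nu = 0.001$ the matching stage count is $L = 3000$;
a short model with small $\nu$ is correlation-accurate but systematically
under-dispersed (visible as inflated RMSE next to a normal SD). The
package documents this consequence of the aggregation rule rather than
adding the intercept or per-stage line search of other gradient-boosting
traditions, and adds no base score: the printed algorithm has none.

# Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `L` | ensemble members / boosting stages | 3000 | desk-scale runs use 50–200 |
| `subset_size` ($|p|$) | features per member | 10 | 3 when only the 6 X-block features are used |
| `hidden` ($H{+}1$) | hidden neurons incl. bias unit | 20 | 19 sigmoid units |
| `epochs` | optimizer iteration cap | 3000 | see numerics below |
| `lambda` ($\lambda$) | weight decay | 0.005 | on scaled inputs |
| `abstol` | early stop on $E$ | $10^{-4}$ | absolute, on the penalised criterion |
| `init_range` | uniform init half-width | 0.7 | weights $\sim U(-0.7, 0.7)$ |
| `nu` ($\nu$) | boosting shrinkage | 0.001 | pair small $\nu$ with large $L$ |

Validation follows the benchmark protocol: OOB error for bagged models
(`oob_rmse()`), 10-fold cross-validation for boosted and single-network
models (`tune_by_cv()`, `cv_predictions` inside the CLI). Fold assignment
shuffles indices under the given seed and deals them round-robin, so fold
sizes differ by at most one; candidate ties break toward the simpler
configuration (fewer stages, then a smaller feature subset). Model/feature
selection only ever reads validation quantities — the test partition is
touched once, for the final report.

# Evaluation statistics

`score_report()` assembles the four scoring-power statistics: Pearson
$R_p$; Spearman $R_s$ computed on average ranks (equal to the classical
$1 - 6\sum d_i^2 / (n(n^2-1))$ form whenever there are no ties); the
standard deviation of errors about the least-squares line of measured on
predicted affinity,

$$SD = \sqrt{\frac{\sum_i \left(y_i - (\beta_0 + \beta_1 \hat y_i)\right)^2}{n-2}},$$

regressing $y$ on $\hat y$ exactly as printed in benchmark practice; and
plain RMSE. SD is invariant under affine rescalings of the predictions,
so — unlike RMSE — it does not punish the boosted model's $L\nu$
under-dispersion; reporting both is informative. Degenerate inputs
(constant vectors, $n < 3$) raise classed errors instead of returning
`NaN`, so pipelines fail loudly.

# The synthetic generator

Real benchmark tables (refined sets of crystal complexes with measured
affinities) cannot ship with a package; `generate_complexes()` produces
tables with the same shape and known ground truth so that every learner
and metric is testable offline.

* **Shape.** $n$ complexes in `families` protein-family clusters; four
  feature blocks of 6 (X), 30 (A), 36 (R) and 14 (G) columns.
* **Correlation structure.** One latent factor per block and complex;
  each feature is $\sqrt{\rho}\,z + \sqrt{1-\rho}\,\varepsilon$ with
  `redundancy_rho` $\rho = 0.7$ by default, giving within-block pairwise
  correlation $\rho$. Block latents share a global factor with variance
  share `block_coupling` $= 0.6$, emulating the dominant shared direction
  (roughly "interface size") that real descriptor families all load on.
  Latents carry a family-level component (`family_cohesion` $= 0.3$), so
  same-family complexes cluster in feature space.
* **Signal.** The ground truth $g$ mixes linear terms, a centred
  quadratic, a pairwise product and an odd saturating sigmoid over the
  standardised grand feature mean, block means and one raw column
  (`default_signal()`); block/grand means are standardised by their
  analytic population variances so $g$ is a fixed function, not a
  sample-dependent one. Placing most weight on the shared direction makes
  the surface recoverable from random 10-of-86 feature subsets — the
  premise the ensembles rely on — while the nonlinear terms keep linear
  baselines beatable. The intercept of 6.3 puts affinities on a realistic
  $-\log K$ scale.
* **Noise.** Gaussian on the $-\log K$ scale. The default
  `noise_sd = NULL` resolves to $0.8 \times \mathrm{sd}(g)$ over the
  generated rows, which places the attainable test correlation near the
  0.8 regime familiar from real benchmarks.
* **Benchmark split.** `generate_refined_core()` carves out a
  family-stratified core set with equal per-family counts where divisible;
  at $n = 1300$, 65 families and `core_fraction = 0.15` this reproduces
  the familiar 1105/195 split with 3 core complexes per family.

What the generator does *not* emulate: integer-valued, heavily skewed
contact-count marginals; heteroscedastic experimental error across assay
types; inter-block correlation structure beyond a single global factor;
docking-pose geometry. Tests passing on this generator therefore
demonstrate the correctness and the relative behaviour of the learners,
not their absolute accuracy on real crystallographic data.

# Numerical choices

* **Optimizer.** The fitting criterion and its analytic gradient are
  implemented in C++ (RcppArmadillo) and driven by full-batch BFGS
  (`stats::optim`); "epochs" is the iteration cap, and training stops
  early when $E$ drops below `abstol`. Gradients are exact; a unit test
  checks them against central finite differences and a pure-R reference.
  Accepted quasi-Newton steps never increase $E$.
* **Determinism.** A root seed expands to a $2 \times L$ matrix of member
  seeds (one stream for resampling, one for initialisation), so ensembles
  are reproducible bit-for-bit from `config$seed` and members could be
  trained in any order.
* **Degenerate features.** A constant training column scales to 0 (range
  treated as 1) instead of dividing by zero. Test-time inputs outside the
  training range extrapolate; clipping would silently distort the ranking
  of extreme complexes.
* **Failed members.** Members whose optimisation returns non-finite
  weights are refit with a bumped seed (at most 3 retries); members that
  merely hit the iteration cap are kept — imperfectly tuned members
  increase ensemble diversity.
* **Boosting bookkeeping.** Stage-1 residuals are computed in-sample on
  the stage's own training rows, per the literal stage-wise recipe; each
  stage refits its input scaler on its own bootstrap sample so members
  stay self-contained. The stored residual trace satisfies
  $R^L = Y - \nu \sum_l \hat Y_l$ to $10^{-10}$, and the suite asserts it.
* **Contact descriptors.** The element-pair counting rule is stated
  explicitly because published contact-count feature sets leave it
  implicit: protein alphabet $\{C,N,O,S\}$, ligand alphabet
  $\{C,N,O,F,P,S,Cl,Br,I\}$ (36 pairs), cutoff 12 Å, boundary
  *inclusive*; all are configurable and stamped into the output
  attributes. Squared distances are computed from coordinate differences —
  the same arithmetic as an all-pairs loop — so the inclusive boundary is
  exact, and a test compares against a brute-force double loop on random
  atom clouds. Elements outside the alphabets never match (hydrogens are
  kept but uncounted); strict mode turns alien elements into errors.
* **File formats.** CSV tables are written with shortest-round-trip
  numeric rendering, so write-then-read reproduces every double exactly.
  Models serialise to a single self-contained JSON document per model
  (members embedded), with a `format_version` field.

# Desk-scale experiment sizes

The test suite and `scripts/acceptance.R` exercise the full pipeline at
sizes a laptop CPU handles in minutes: tables of 600 training / 200 test
complexes with the default 86 features, ensembles of $L = 100$ members
with $|p| = 10$, 9 sigmoid units (`hidden = 10`), `epochs = 200` and
$\lambda = 0.02$ per member, boosting shrinkage $\nu = 0.01$. The smaller
networks and stronger decay are deliberate variance control for the
smaller training sets: at $n = 600$ a 19-unit member fits enough of the
shared noise realisation to cap ensemble accuracy, and since all members
see the same noisy targets that error component does not average out.
The single-network baseline keeps the benchmark-style settings
(`hidden = 20`, $\lambda = 0.005$) on all features. Under these
conditions the bagged and boosted ensembles recover the synthetic surface
to within a few percent of the noise ceiling and beat the single network
on essentially every seed, the desk-scale analogue of the ensembles'
advantage on real benchmarks.

# Known limitations

* The boosted model's shrink-every-stage rule needs $L\nu \approx 1$ for
  calibrated predictions; the package warns in documentation rather than
  silently rescaling.
* OOB validation averages per complex (each row's prediction is the mean
  over members that excluded it), one of the two defensible conventions.
* The PDB reader delegates to `bio3d` and applies the package's filters
  (HOH excluded, altLoc `A`/blank kept, element from columns 77–78 with
  an atom-name fallback); exotic records (insertion-code collisions,
  multi-model files) inherit `bio3d`'s behaviour.
* Only squared-error boosting is implemented — no general loss functions,
  no line search; multiple hidden layers and classification outputs are
  out of scope for the base learner.
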