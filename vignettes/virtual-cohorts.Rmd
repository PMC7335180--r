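---
title: "Generating virtual patient cohorts with modular Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating virtual patient cohorts with modular Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vcforge)
```

## The problem

Longitudinal observational studies of progressive diseases (Alzheimer's,
Parkinson's and similar) collect clinical scores, imaging measurements,
biomarkers and genotype over repeated visits. Legal and ethical constraints
usually prevent sharing the patient-level records, producing data silos. A
*virtual cohort* is a simulated set of patient trajectories drawn from a
generative model of the real cohort: statistically close enough to support
hypothesis generation and study planning, but containing no real patient.

vcforge builds such a generative model as a **modular discrete Bayesian
network (BN)**: variables are grouped into clinically meaningful modules
(cognition tests, brain volumes, CSF markers, ...), each module is aggregated
per visit into a low-dimensional score by a sparse autoencoder, the scores are
discretized, and a BN over the module scores is learned under structural
constraints. The fitted BN is the cohort model: virtual patients are joint
samples from it.

## The model

Let $G = (V, E)$ be a DAG and $X = (X_v)_{v \in V}$ the module-score, static
and auxiliary variables. The joint distribution factorizes as

$$p(X_1 = x_1, \ldots, X_n = x_n) = \prod_{v \in V} p(X_v = x_v \mid
X_{pa(v)} = x_{pa(v)}),$$

with one conditional probability table (CPT) $\theta_v$ per node. Time is
handled by *explicit unfolding*: every time-varying module appears once per
visit (e.g. `cognition@bl`, `cognition@m06`, ...), with its own parameters,
because disease progression makes the transition distributions non-stationary
— a first-order stationary dynamic BN would force
$p(\tilde X(t) \mid \tilde X(t-1))$ to be the same at every $t$.

### Structural constraints

Unrestricted structure learning over clinical data is both computationally
hard and causally unidentifiable, so the search space is cut down by
class-level rules expanded to a node-level edge blacklist/whitelist
(`expand_constraints()`):

* demographic baseline features may influence anything but are never
  influenced;
* imaging features may relate to each other but do not drive other groups;
* diagnosis depends on cognition scores, never the reverse;
* no edge points backwards in time (this includes edges from visit-indexed
  nodes into static nodes, which we treat as temporally prior);
* auxiliary missingness nodes have fixed topology (below).

Rules are user-extensible (`group_rules()`, the `vocabulary` argument); the
defaults ship in `inst/extdata/rules_default.yaml`. The most specific matching
rule wins; unmatched edges are allowed.

### Missing data

Block-wise missingness in longitudinal studies is usually systematic — a
patient drops out, or an entire test battery is skipped — and therefore MNAR:
the probability of being missing depends on the (unobserved) disease state.
Deleting incomplete records or imputing as if data were MAR biases the model.
vcforge follows the indicator strategy: `add_auxiliary_nodes()` creates one
binary auxiliary variable per (group, visit) block containing missing values,
equal to 0 exactly when the patient's whole block is absent. Each auxiliary
node is a *fixed* parent of its group's score node at the same visit and of
the same group's auxiliary node at the next visit (whitelisted, so structure
search can neither remove nor redirect them); all other edges touching
auxiliary nodes are blacklisted. Parameter estimates downstream are thereby
conditioned on the missingness pattern.

A design point the data cannot decide: when a block is only *partially*
missing at a visit, the indicator stays 1 and the cells are left to
imputation. We consider partial missingness item-level noise rather than
drop-out; only whole-block absence is treated as the MNAR event.

Remaining cells are completed by iterative random-forest imputation
(`rf_impute()`): initialize with column means/modes, then repeatedly re-fit a
forest per incomplete column (all other columns as one-hot predictors,
auxiliary indicators included as predictors but never imputed) until the
convergence statistic — normalized squared change of continuous imputations
plus the fraction of changed categories — first increases; the previous
iteration's values are kept. Defaults: 100 trees, at most 10 iterations.
Imputation runs jointly over the full wide table (all visits as columns), so
later-visit information can inform earlier gaps and vice versa.

### Module aggregation by sparse autoencoders

Each (group, visit) block $x \in \mathbb{R}^d$ is encoded to
$\tilde x = s(Wx + b) \in \mathbb{R}^q$ and decoded by
$z = s'(W'\tilde x + b')$; training minimizes reconstruction MSE plus an
$\ell_2$ weight penalty, with dropout on the *input* layer as the sparsity
device. The default latent dimension is $q = 1$, so each group at each visit
becomes a single BN node; single-feature groups bypass the autoencoder
(identity pass-through). Hyper-parameters are chosen by grid search on a
random 80/20 split (`default_ae_grid()`: one or two encoder layers, sigmoid or
relu, dropout 0.2/0.5, $\ell_2$ 1e-4/1e-3), and the winner is refit on all
rows. Continuous inputs are z-scored with training-time statistics;
categorical inputs are one-hot encoded (already min-max scaled by
construction). The decoder's output layer is linear so that standardized
values are reconstructible. Optimization is Adam over minibatches; a plain
gradient-descent option exists mainly to make the training loss exactly
monotone in the noiseless linear case, a property the test suite checks.

Per-input importance uses the Gedeon weight-path measure: within one layer
$P_{ij} = |w_{ij}| / \sum_p |w_{pj}|$, and across layers
$P_{ik} = \sum_r P_{ir} P_{rk}$ — the sum over all input-to-output paths of
the products of normalized edge weights, biases ignored. Influences are
non-negative and sum to one per latent output.

### Discretization

BN structure learning with marginal-likelihood scores needs multinomial
nodes, so encoded scores are discretized. Two modes mirror two study designs:

* **supervised** (`tree_discretize()`): when a meaningful label exists (e.g.
  baseline diagnosis), cut points are the thresholds of a univariate CART
  tree predicting the label, capped at `max_levels` (default 4) with a
  minimum leaf of 5% of n;
* **unsupervised** (`gmm_discretize()`): univariate Gaussian mixtures with
  the component count selected by BIC, values assigned to the
  maximum-responsibility component, levels ordered by component mean.

Out-of-range values clamp to the nearest boundary level; missing cells stay
missing. GMM assignment by responsibility (not fixed cut points) handles
overlapping components; for cut-point maps discretization is monotone.

### Structure and parameter learning

The BDeu score (imaginary sample size 1 by default) is maximized by greedy
hill climbing with random restarts (default 50) or tabu search — the two
score-based searches that win model selection on data of this kind;
constraint-based and hybrid algorithms are deliberately out of scope. Score
ties break on lexicographic edge order, making results reproducible under a
seed. Hill climbing never accepts a score-decreasing move (asserted at every
step); tabu search does accept worsening moves by design and returns the best
structure seen, which is monotone in iterations. Algorithms are compared by
k-fold cross-validation (default k = 10) on the negated held-out mean
log-likelihood (`cv_select()`).

CPTs are posterior means under a uniform Dirichlet prior with pseudo-count
$\alpha$ (default 1):
$\hat\theta_{v}(x \mid pa) = (N + \alpha) / (N_{pa} + \alpha L_v)$, so parent
configurations never observed yield uniform rows rather than zeros. Edge
stability is quantified by a nonparametric bootstrap over patients
(`bootstrap_edges()`, default B = 1000): the relative frequency of each
directed edge across replicate structure learns.

### Simulating virtual patients, conservatively

`ancestral_sample()` draws joint configurations in topological order. Because
a fitted BN can misfit (finite data, unobserved confounding), raw draws may
contain unrealistic patients. The conservative filter
(`conservative_filter()`) trains a cost-sensitive random forest to separate
real from virtual patients with a 100:1 weight on correctly classifying real
ones. The weight enters the splitting criterion (class weights) and the
confidence score, which is the weighted posterior odds of the out-of-bag leaf
frequencies: $c = w p / (w p + 1 - p)$ with $p$ the out-of-bag
$\hat P(\text{real} \mid x)$. A virtual patient indistinguishable from real
ones scores near $w/(w+1) \approx 0.99$; one in a region without real support
scores near 0. Patients below the 0.5 threshold are rejected, and
`generate_vc()` iterates sample-filter rounds until the target count is
reached. Deliberate asymmetry: misclassifying a virtual patient as real is
almost costless, misclassifying a real patient as virtual is heavily
penalized — the filter only removes clear outliers. The forest sees the BN's
node columns (discretized module scores, statics, auxiliary indicators), i.e.
realism is judged in the modelled representation; auxiliary columns are
included so missingness patterns count towards realism. Decoding virtual
patients back to raw feature space via the autoencoder decoders
(`decode_scores()`) is available but optional.

### Interventions

Counterfactual interventions follow Pearl's do-operator: `mutilate()` deletes
all incoming edges of the target and fixes its CPT; `simulate_intervention()`
forward-samples the mutilated network (logic sampling — for pure
do-interventions the target is a root, so no draws are rejected). Per-patient
intervention values are supported, which is how an encoded, shifted baseline
cognition score can be imposed on each subject individually. Intervening is
not conditioning: on a collider $A \to C \leftarrow B$, $do(C = c)$ leaves
the marginal of $A$ untouched while conditioning on $C = c$ changes it; the
test suite checks both against an exact enumeration oracle.

### Evaluating realism

Two complementary views:

* **multivariate** (`pauc_cv()`): within 10 repeats of a stratified 10-fold
  cross-validation, an unweighted random forest learns to separate real from
  virtual patients; performance is the standardized partial AUC over the
  sensitivity region [0.9, 1] for the positive class "real" — the operating
  region that matters, since missing a real patient is the costly error. The
  raw partial area $A$ is standardized as
  $\tfrac12 (1 + (A - A_{\min})/(A_{\max} - A_{\min}))$ with
  $A_{\max} = 1 - s_0$ and $A_{\min}$ the chance-diagonal area over the same
  region, so 0.5 is chance and 1 perfect discrimination. Note the
  standardized statistic has a floor slightly below 0.5 (about 0.474 at
  $s_0 = 0.9$), not 0: an anti-separating classifier maps to the floor, not
  to zero.
* **univariate** (`homogeneity_tests()`): per variable, a Pearson
  chi-squared homogeneity test of real vs virtual level distributions
  (no continuity correction), Benjamini-Hochberg adjusted across variables
  (the correction method is configurable). Columns with a single observed
  level carry no information and are flagged as skipped.

Per-patient confidence scores are kept on the virtual cohort tibble
(`.confidence`, `.accepted`) and can be exported as CSV; low-dimensional
embedding plots of them are left to downstream tools.

## The synthetic ground-truth generator

Real AD/PD study databases are access-restricted, so all validation runs on
`make_ground_truth()` / `sample_cohort()` cohorts that reproduce exactly the
structure the method assumes: discrete latent group scores evolving over
visits under a known forward-in-time DAG (each group's temporal chain always
present, random within-visit and cross-group edges), continuous raw features
emitted as loading x level plus Gaussian noise, and monotone MNAR drop-out
whose per-visit hazard is `dropout_strength * plogis(2 z)` with `z` the
latent level scaled to [-1, 1] — sicker (higher-score) patients drop out
more, and a dropped group stays missing at all later visits, which is what
justifies the auxiliary chain edges. Latent scores are generated directly as
discrete levels so the fitted BN's estimand is well defined; the continuous
emissions exist to exercise imputation, autoencoding and discretization. CPT
rows are Dirichlet draws rescaled into [0.05, 0.95], so no configuration is
deterministic; the `concentration` parameter controls dependence strength.

What the generator does *not* emulate: realistic clinical marginals or
variable lists, measurement floors/ceilings, visit-specific assessment
batteries, informative baseline missingness, or label noise in diagnoses.
Passing tests on these cohorts show the machinery is correct under the
model's assumptions; they do not certify performance on any particular real
study.

## Numerical choices and problem sizes

* Dirichlet pseudo-count $\alpha = 1$; BDeu imaginary sample size 1.
* Forest sizes: 500 trees for the conservative filter and the evaluation
  classifier, 100 per column/iteration for imputation.
* Hill climbing: 50 random restarts by default (tests and bootstrap runs use
  fewer — the search space there is small and caching makes restarts cheap);
  tabu list length 10; maximum parent count 8.
* The test suite validates at desk scale: chance-level pAUC on a 4-group,
  3-visit cohort of n = 600 under the full 10x10 CV; the paired
  filtered-vs-unfiltered comparison over 10 seeds with 10x2 CV (the paired
  design — one ancestral batch per seed, the conservative arm being its
  accepted subset — removes between-batch sampling noise from the
  comparison); bootstrap stability with B = 200 replicates; intervention
  correctness at n = 20,000 against exact enumeration (total variation
  0.02).
* Ties in structure-search scores break lexicographically; degenerate inputs
  (constant columns, single-feature groups, single-class labels) short-circuit
  to the sensible special case rather than erroring.

## Limitations

* Variable groups and constraint classes must be declared by someone who
  understands the data; they are not inferred.
* Discretization loses within-level information, and $q = 1$ aggregation
  loses within-group structure; both are the price of tractable, assumption-
  free BN learning on realistic sample sizes.
* The conservative filter scores plausibility relative to the fitted
  representation; it cannot detect unrealism in directions the encoders do
  not represent.
* No formal privacy guarantee is provided: unlikely re-identification is an
  empirical property here, not a theorem. Differentially private autoencoder
  training would be the natural extension.
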