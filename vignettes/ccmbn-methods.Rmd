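---
title: "Causal network inference for ecological time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal network inference for ecological time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmbn)
```

## The problem

Plankton blooms — and many other ecological events — emerge from networks of
nonlinear, lagged interactions among species and their environment. Pearson
correlation cannot orient such interactions and is blind to nonlinear
coupling; regression-style structure learning assumes the data-generating
process factorizes the way the fitted model does. `ccmbn` implements a
target-focused alternative built on empirical dynamic modeling: convergent
cross mapping (CCM) detects and orients interactions from reconstructed
state-space geometry, extended CCM (ECCM) estimates interaction delays and
strips out synchrony artifacts, and the surviving network — converted to a
directed acyclic graph — parameterizes a discrete Bayesian network whose
inference answers "which conditions make the target event likely".

## State-space reconstruction and cross mapping

A scalar series $x_t$ observed from a deterministic dynamical system can be
unfolded into a shadow manifold by delay embedding: the state at time $t$ is
$(x_t, x_{t-l}, \dots, x_{t-(E-1)l})$ with embedding dimension $E$ and lag
$l$. If $X$ causally forces $Y$, the history of $Y$ carries an imprint of
$X$, so states on $Y$'s manifold can be used to *cross map* (estimate)
contemporaneous values of $X$. Cross-map skill $\rho$ — here the Pearson
correlation between cross-mapped and observed values, the convention of the
CCM literature — *increases with library size* (the number of manifold
states available as neighbours) when the causal imprint is real, because a
denser manifold has closer neighbours. That convergence, not the skill level
itself, is the causal signature.

The forecast step is simplex projection: a query state's value is the
weighted mean over its $E+1$ nearest library neighbours, with weights
$w_i = \exp(-d_i/d_1)$ ($d_1$ the nearest distance; co-located neighbours
share the weight equally). Embedding parameters are selected per variable —
$l$ from the first minimum of the lagged mutual information, $E$ by
leave-one-out simplex skill — and the cross map of a pair uses the
parameters of the *effect* variable, whose manifold does the predicting.
Selections above 20 fall back to $E=5$, $l=2$, keeping reconstructions in
the range of short- to mid-term ecological memory.

The S-map test (`smap_nonlinearity()`) guards the premise: locally weighted
linear forecasts with weighting parameter $\theta$ reduce to a single global
linear map at $\theta = 0$; if skill improves for $\theta > 0$ the dynamics
are state-dependent, i.e. nonlinear, and CCM is the right tool.

### Sliding windows

Ecological coupling strengths drift: a driver may matter in some years and
not in others. Testing one long series dilutes episodes of strong coupling
with episodes of none. The pipeline therefore slides a 100-sample window in
steps of 10 over each pair, makes each window stationary (first differences
when an augmented Dickey–Fuller test cannot reject a unit root at the 0.05
level), runs the cross map per window, and scores the pair by the *mean
final skill over converged windows only*. An interaction is retained when at
least 10 windows converge with mean skill at least 0.01. A window of 100
samples at the default 5-day grid spans roughly 1.4 annual cycles — long
enough to contain a full seasonal cycle, short enough to localize episodes.

Convergence itself is operationalized as: skill at the largest library
exceeds skill at the smallest by at least 0.05 *and* a one-sided Kendall
trend test over (library size, skill) is positive at the 0.05 level. The
library schedule is 15 log-spaced sizes from $E+2$ to the library pool
maximum; the pool is the chronological first 75% of states and skill is
measured on the final 25%, respecting temporal order.

### Surrogate significance

Cross-map skill inherits sampling noise, and strongly autocorrelated series
can cross map each other by chance. Each candidate interaction is therefore
re-tested against phase-randomized (Ebisuzaki) surrogates of the putative
cause: the Fourier amplitudes — hence mean, variance and autocorrelation —
are preserved exactly (the Nyquist component keeps its amplitude with a
random sign) while the phases are randomized. An edge is significant when
its observed skill strictly exceeds the empirical 0.9 quantile of 1000
surrogate skills computed on a fixed 400-sample frame; the observed value is
not pooled into the null. Under independent AR(1) nulls the test fires at
close to its nominal 10% rate (the acceptance suite measures this).

## Extended CCM and interaction classification

A cause can only influence the present or future of its effect, so the
effect's manifold can only recover *present or past* values of the cause:
scanning the cross map over time shifts $s \in [-20, 20]$, a genuine
interaction peaks at a non-positive shift whose position estimates the
cause-to-effect delay. The joint pattern of the two directions' optima
classifies the pair: both at 0 with similar skill means a strong common
force drives both instantaneously; one negative and one positive optimum
means the stronger variable has enslaved the other through synchrony; both
negative means bidirectional coupling; exactly one valid direction means
unidirectional causation; a strictly positive optimum (or no peak reaching
the 0.01 skill floor) marks a false interaction. Edges classified as
synchrony or false are removed; surviving edges carry their optimal lag,
reported in days as $|s| \times$ grid step.

Two numerical choices matter here. First, the skill-floor rule is applied
before the lag-pattern rules: below the floor no lag pattern is
interpretable. Second, optima are located with a similar-skill tie tolerance
of 0.05, resolved toward shift 0. The tolerance is not cosmetic: when an
effect is (close to) a lagged copy of its cause, every shift at which the
copy appears as an embedding coordinate (spacing $l$) attains near-identical
skill, and machine-precision argmax would let sampling jitter pick among
them; the tolerance makes the estimator prefer the shortest delay consistent
with the data, which is also the parsimonious reading of a peak-with-
shoulder profile.

## From network to Bayesian network

Bayesian networks require acyclic structure, while ecological interaction
networks are full of feedback loops (nutrient → alga → nutrient). Cycles are
broken deterministically: a cycle through the target loses the target's
out-edge within the cycle (the target's in-edges — the edges the model
exists to use — are never touched); any other cycle loses its weakest-skill
edge entering a confounder (a node with at least two out-edges), ties
resolved lexicographically; a cycle without a confounder loses its
weakest edge. Non-target sink nodes are then pruned repeatedly. The
procedure is idempotent, and an independent topological sort verifies
acyclicity in the test suite. Mechanistically established interactions
missing from the data-driven network can be appended as expert edges when
they do not create cycles.

Before fitting, each variable is advanced by its cumulative lag toward the
target (a parent uses its edge lag; an indirect cause follows its
maximum-skill out-edge and accumulates lags), aligning cause values with the
effect rows they act on. Variables are discretized on the resampled raw
data — predictors into tertiles, the target into low/high at its 0.75
quantile with the boundary value counted as high; quantile codes are
scale-invariant, so categorization deliberately reads un-normalized values
and stores its cutoffs in measurement units for reuse on test data.
Conditional probability tables are maximum-likelihood with add-one
smoothing, fit on the chronological first 75% of rows; a state-support check
(every state of every variable observed more than 20 times) warns against
over-fitting. Inference is exact variable elimination, test-verified against
brute-force joint enumeration; evaluation reports accuracy at the 0.5
probability cutoff (inclusive), a rank-based AUC with half credit for ties,
and the confusion matrix, on the held-out 25%.

A hill-climbing structure-learning baseline (greedy add/remove/reverse moves
under the BIC score from an empty graph, deterministic lexicographic tie
breaks) is included because it is the conventional alternative; on the
synthetic validation system it fails to recover the causal chain, which is
the point of the comparison.

## Sensitivity analysis

Up to 20 000 random category assignments over the non-target nodes (the full
space is enumerated when smaller) are pushed through exact inference.
Residuals are the inferred target probabilities centred on their mean. A
variable's contribution is $|m^+| + |m^-|$, where $m^+$ is the mean residual
over all scenarios in which the variable takes its modal category among
bloom-favouring scenarios ($P > 0.5$), and $m^-$ mirrors this for
$P < 0.5$. For a variable disconnected from the target the residuals within
any of its categories cancel, so its contribution is near zero; a
deterministic parent's bloom-favouring state collects the positive residuals
and scores highest. Mean blooming and non-blooming profiles are per-variable
mean categories over the two scenario sides, with ties at exactly 0.5
belonging to neither.

## The synthetic validation systems

### Four coupled logistic species

The validation harness iterates four species with chained couplings
(Y1 → Y2 → Y3 → Y4) and logistic self-dynamics, e.g.
$Y2_{t+1} = Y2_t(3.6 - 0.4\,Y1_t - 3.6\,Y2_t)$. The chain creates indirect
dependencies (Y1 on Y3 and Y4, Y2 on Y4) that a causal method should not
confuse with direct ones. The homogeneous regime is deterministic and
chaotic; the default initial condition is $(0.4, 0.4, 0.4, 0.4)$ with
seed-controlled jitter of $\pm 0.05$ for replicate runs, and the first 100
steps are discarded so analyses see post-transient dynamics.

The heterogeneous regime emulates a system whose interaction strengths
drift: over the final two thirds of the run, Y2 and Y3 are multiplied inside
the iteration by i.i.d. Uniform(0.5, 1.5) draws and clipped to $[0, 1]$, so
the weakening propagates dynamically through the couplings. One subtlety is
deliberate: a noise excursion can push a logistic update negative, and a
clip to exactly 0 would extinguish the species for the remainder of the run
because 0 is an absorbing fixed point of every update rule. Negative updates
are therefore floored at a tiny biomass ($10^{-4}$) from which the logistic
term regrows within a few steps; exact-zero states remain fixed. Without
this floor the weakened regime collapses into constant series and the
fixture cannot serve its validation purpose.

### Lake-like seasonal fixture

`simulate_lake_like()` generates phase-shifted seasonal sinusoids plus
Gaussian noise, with declared lagged linear dependencies among variables and
the declaring edge table returned as ground truth. It emulates the gross
statistical shape of lake monitoring data — seasonality, lagged drivers,
noise, a 5-day grid — and is used to exercise preprocessing, alignment and
Bayesian-network fitting against a known structure. It is deliberately
*linear*: its couplings live entirely in the power spectrum, which is
exactly what phase-randomized surrogates preserve, so the CCM stage
correctly refuses to call them nonlinear-causal. Passing tests on this
fixture therefore demonstrate the plumbing and the discrete model, not CCM
discovery; discovery is validated on the four-species system, and neither
fixture reproduces features of real monitoring data such as irregular
sampling, observation error structure, or regime shifts.

## Numerical choices and degenerate inputs

* Distances are Euclidean in embedding space; the query point and its exact
  time match are excluded from their own neighbour set (leave-one-out).
* S-map local regressions are ridge-stabilized with $10^{-8}$ on the normal
  equations' diagonal.
* Mutual information uses a 2-D histogram with $\lceil\sqrt{n/5}\rceil$
  bins per axis. The lag-MI curve is smoothed with a centred 3-point moving
  average before the first-minimum search, and a lag whose MI is already
  within 10% of the curve's range above its interior minimum counts as the
  first minimum — a chaotic or white series whose MI collapses at once then
  selects a small lag instead of a jitter artifact. A curve whose minimum
  sits at the boundary (no interior minimum) falls back to the default
  lag 2.
* The augmented Dickey–Fuller regression selects its augmentation order by
  AIC up to Schwert's short rule $\lfloor 4 (n/100)^{1/4}\rfloor$ and uses
  MacKinnon (2010) response-surface critical values (constant-only case).
  This test is implemented in the package because no installed dependency
  provides it.
* Outlier z-scores use the population standard deviation in a single pass.
  With $n$ observations the largest attainable sample-sd z-score is
  $(n-1)/\sqrt{n}$, so a sample-sd convention could never flag a single
  spike in ten observations at the conventional threshold of 3 — the
  population convention can, and does.
* Constant columns: normalization maps them to 0, outlier removal passes
  them through, stationarity handling treats them as stationary.
* Library subsampling at size $L$ takes the first $L$ pool states,
  deterministically; all remaining randomness (surrogates, scenario draws,
  replicate initial conditions) is seed-controlled, and the pipeline fans a
  single seed out to fixed per-stage seeds, so a configuration reproduces
  byte-identical artifacts.

## Problem sizes

The shipped test and acceptance runs use series of 1000 post-burn-in steps
for the four-species system (91 sliding windows per pair), 400-sample
frames with 200 surrogates for significance and calibration (200 null
replicates), 20 replicate systems per recovery experiment, and Bayesian
networks of up to 12 nodes for the exact-inference cross-checks. These sizes
give stable statistics for every quantity the package reports while keeping
a full run on a single CPU comfortable.

## Known limitations

* CCM presumes deterministic nonlinear dynamics observed with modest noise;
  purely stochastic linear systems are outside its remit (by design — the
  surrogate test will reject them).
* The convergence criterion, window geometry and skill floors are the
  framework's operating point, not estimated quantities; shifting them
  shifts edge counts, which is why the pipeline logs every filter decision.
* Discretization to tertiles loses information relative to ecological
  thresholds chosen per variable; the categorization API accepts custom
  cutoffs for exactly that reason.
* The Bayesian network is static after lag alignment: it conditions on
  shifted states rather than modelling temporal evolution (no dynamic
  Bayesian network).
* On strongly coupled deterministic systems, generalized synchrony can make
  reverse-direction cross maps score well; the ECCM stage mitigates but
  cannot fully eliminate this, and recovered networks on such systems
  typically contain extra edges beyond the true chain.
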