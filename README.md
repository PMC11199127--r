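# ccmbn

Target-focused causal network inference for multivariate ecological time
series, coupling **convergent cross mapping (CCM)**, **extended CCM
(ECCM)** and a **discrete Bayesian network** into one pipeline. The package
was built for the question "which environmental conditions and competitor
dynamics drive a cyanobacterial bloom?", but applies to any regularly
sampled table of interacting variables with a designated target.

## The method in brief

For a pair of variables where $X$ forces $Y$, the delay-embedded manifold of
$Y$ carries an imprint of $X$: simplex-projection estimates of $X$ from
$Y$'s manifold improve as the library of manifold states grows. That
*convergence* of cross-map skill $\rho$ (Pearson correlation between
cross-mapped and observed values) is the causal signature, robust to the
nonlinearity that defeats correlation. The pipeline:

1. conditions the data (outlier interpolation at |z| ≥ 3, resampling to a
   uniform 5-day grid, min–max normalization);
2. screens every variable against the target and then all pairs among the
   survivors with sliding-window CCM (100-sample windows, step 10,
   per-window Dickey–Fuller differencing), keeping interactions with mean
   converged skill ≥ 0.01 over ≥ 10 converged windows;
3. scans each surviving pair over time shifts −20..20 (ECCM): a true cause
   peaks at a non-positive shift, whose position is the interaction delay;
   synchrony and false interactions are discarded;
4. validates each edge against 1000 phase-randomized (Ebisuzaki) surrogates
   at the 0.9 quantile;
5. converts the network to a DAG (deterministic loop truncation, sink
   pruning), optionally adds expert edges;
6. lag-aligns the categorized data, fits a Bayesian network (add-1
   smoothing, chronological 0.75/0.25 split), evaluates accuracy and AUC at
   the 0.5 cutoff, and runs a 20 000-scenario sensitivity analysis.

A four-species coupled-logistic simulator with known ground truth
(Y1 → Y2 → Y3 → Y4 plus indirect dependencies) ships as the validation
harness, in a deterministic homogeneous regime and a heterogeneous regime
whose couplings weaken over the final two thirds of the run.

## Worked example

```r
library(ccmbn)

sim <- simulate_four_species(1000, seed = 1)   # known truth: Y1->Y2->Y3->Y4
cfg <- pipeline_config(target = "Y4", surrogates = 200,
                       sensitivity_n = 2000, seed = 42, step_days = 1)
res <- run_pipeline(cfg, data = sim, verbose = TRUE)
#> input: 1000 rows, 4 variables
#> preprocess: 1000 resampled rows
#> ccm: 3 screening variables, 12 candidate pairs, 12 edges
#> eccm: 10 edges kept, 2 dropped
#> surrogates: 6 of 10 edges significant at q = 0.9
#> dag: 2 nodes, 1 edges
#> bn: accuracy 0.728, auc 0.722
#> sensitivity: 3 scenarios (0 maximizing, 3 minimizing)
```

Reading the log: all 3 non-target variables pass the CCM screen and all 12
ordered pairs converge — on a strongly coupled deterministic system,
generalized synchrony makes even reverse directions cross-map well. The
ECCM lag scan then removes 2 synchrony/false edges, the surrogate test
removes 4 more, and loop truncation plus sink pruning reduce the graph to
the single strongest causal in-edge of the target: `Y3 -> Y4`, the true
direct driver. The fitted two-node Bayesian network predicts the held-out
"Y4 high" state (upper quartile) with accuracy 0.728 and AUC 0.722 from the
lag-aligned state of Y3 alone.

Individual stages are ordinary functions on tibbles:

```r
net <- build_target_network(sim, "Y4")     # sliding-window CCM, both iterations
prof <- eccm_scan(sim$Y1, sim$Y2)          # lag scan for one pair
glance(prof)                               # optimal lags + classification
autoplot(cross_map(sim$Y1, sim$Y2, E = 2, l = 1))  # convergence curve
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/ccmbn.R` (subcommands `simulate`, `preprocess`, `ccm`, `eccm`,
`network`, `dagify`, `bn-fit`, `bn-eval`, `sensitivity`, `run`).

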