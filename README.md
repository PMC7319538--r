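# causalmix

Causal discovery for tabular datasets that mix continuous and
categorical variables — gene expression next to clinical covariates and
a diagnosis column, metabolite levels next to treatment arms. Standard
correlation networks overestimate causal structure and usually assume a
single variable type; `causalmix` instead learns, from observational
data alone:

1. an **undirected conditional-dependence graph** — a sparse pairwise
   mixed graphical model (MGM, Gaussian conditionals for continuous
   nodes, multinomial-logistic conditionals for categorical nodes) fit
   by penalized negative log pseudo-likelihood with proximal gradient
   descent; an edge between A and B means they are dependent given all
   other variables;
2. a **partially directed causal graph (CPDAG)** — the PC-Stable
   algorithm, seeded with the MGM graph for speed and accuracy, prunes
   edges with regression-based conditional-independence tests, orients
   colliders, and propagates Meek rules; arrows mark directions on
   which every Markov-equivalent DAG agrees.

Around that core: **StEPS** selects the three sparsity penalties
(λ_CC, λ_CD, λ_DD — one per edge type) automatically from subsampling
stability; **Pref-Div** pre-selects features associated with a target
while suppressing redundant ones; a **Lee–Hastie-style simulator**
generates mixed graphical models and DAGs with known ground truth for
benchmarking; graphs export to **SIF** and **Cytoscape.js JSON** for
any downstream network tool.

## The model in brief

For continuous variables $x_s$ (standardized internally) and
categorical variables $y_j$ with $L_j$ levels, the fit minimizes

$$
\frac1n\sum_i\Big[\sum_s \tfrac12\big(x_{is}-\eta_{is}\big)^2
+\sum_j\big(\log\sum_\ell e^{s_{ij\ell}}-s_{ijy_{ij}}\big)\Big]
\;+\;\lambda_{CC}\sum_{s<t}|\beta_{st}|
+\lambda_{CD}\sum_{s,j}\lVert\rho_{sj}\rVert_2
+\lambda_{DD}\sum_{r<j}\lVert\phi_{rj}\rVert_F
$$

where $\eta_{is}$ and $s_{ij\ell}$ are the node-wise linear predictors
built from the pairwise blocks $\beta$ (continuous–continuous, scalar),
$\rho$ (continuous–categorical, level vector) and $\phi$
(categorical–categorical, level matrix). Group soft-thresholding makes
whole blocks exactly zero, so the graph is the support of the estimate.
Conditional-independence tests are the field's regression tests: a
t-test (or partial F-test) on the tested coefficient in an OLS model
when either variable is continuous, a multinomial-logistic
likelihood-ratio test when both are categorical, α = 0.05 by default.

## Worked example

Simulate a known mixed graphical model, learn it back, and orient:

```r
library(causalmix)

cfg   <- simulation_config(p_continuous = 8, p_discrete = 2, levels = 2,
                           expected_degree = 2, n = 1000, seed = 42)
truth <- random_mixed_graph(cfg)
data  <- sample_mixed_data(truth, n = 1000, burn_in = 200, seed = 43)
data
#> mixed_dataset: 1000 samples x 10 variables (8 continuous, 2 categorical)

fit <- fit_mgm(data, lambda_triple(0.15))
fit
#> mgm_fit: 15 iterations, converged, objective 10.74109

undirected <- extract_graph(fit)
undirected
#> endpoint_graph: 10 nodes, 16 edges (16 undirected, 0 directed, 0 conflicted)

sk    <- pcs_skeleton(data, pc_config(alpha = 0.05, initial_graph = undirected))
cpdag <- apply_meek_rules(orient_colliders(sk$graph, sk$sepsets))
cpdag
#> endpoint_graph: 10 nodes, 9 edges (3 undirected, 4 directed, 2 conflicted)

write_sif(cpdag, "example.cpdag.sif")
```

The SIF output (one edge per line; `dir` = directed with the cause
first, `undir` = undirected, `conf` = conflicting orientation evidence;
bare lines are isolated nodes):

```
C1	dir	D1
C2	conf	C7
C2	conf	D1
C3
C4	dir	D1
C4	undir	C5
C4	undir	C6
C6	dir	D1
C6	undir	C8
D2	dir	C7
```

Read it as: `C1`, `C4` and `C6` are inferred causes of the binary
variable `D1`; `C4–C5` and `C4–C6` are conditional dependencies whose
direction the data cannot settle; the `conf` edges around `C2` carry
contradictory collider evidence (a pattern that latent confounding also
produces). The truth graph here has 11 undirected edges; at this fixed
penalty the MGM keeps 16 candidates (10 true, 6 spurious) and the
PC-Stable stage prunes the graph down to 9 edges.

The same pipeline runs in one call on a file — with automatic penalty
selection if wanted:

```r
run_pipeline(run_config("data.tsv",
                        lambdas = NULL, steps = steps_config(),
                        alpha = 0.05, out_prefix = "run1", seed = 7))
# writes run1.undirected.sif, run1.cpdag.sif, run1.cpdag.json, run1.log
```

A thin CLI wraps the same functions
(`inst/cli/causalmix.R`; subcommands `simulate`, `prefdiv`, `mgm`,
`steps`, `citest`, `pcstable`, `run`):

```sh
Rscript inst/cli/causalmix.R run --input data.tsv --steps --out-prefix run1 --seed 7
```

Input is delimited text with a header; column types are inferred
(non-numeric tokens, or at most 5 distinct integral values, mean
categorical), missing cells are rejected, and
`nonparanormal_transform()` is available for non-normal continuous
margins. See the vignette
(`vignettes/causal-discovery-mixed-data.Rmd`) for the model,
assumptions, tuning parameters and known limitations.

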