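---
title: "Causal discovery for mixed data: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal discovery for mixed data: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalmix)
```

# Overview

`causalmix` infers conditional-dependence and causal structure from
tabular observational data containing both continuous and categorical
variables — the typical shape of a biomedical dataset mixing expression
measurements with clinical covariates and outcomes. The pipeline has
four stages, each usable on its own:

1. **Pref-Div** — optional feature pre-selection around a target
   variable, suppressing redundant (highly inter-correlated) candidates.
2. **MGM** — a sparse pairwise mixed graphical model fit by penalized
   negative log pseudo-likelihood; its support is the undirected
   conditional-dependence graph.
3. **StEPS** — optional automatic selection of the three edge-type
   penalties from subsampling stability.
4. **PC-Stable** — order-independent constraint-based pruning and
   orientation, seeded with the MGM graph and driven by regression-based
   conditional-independence tests.

This vignette is the package's account of the underlying models, the
numerical choices, and what the accompanying simulations do and do not
establish.

# The mixed graphical model

The joint model is a pairwise Markov random field over continuous
variables $x_s$ and categorical variables $y_j$ (with $L_j$ levels).
Each node's conditional distribution is what a practitioner would fit
per node: a Gaussian linear regression for continuous nodes and a
multinomial logistic regression for categorical nodes. Writing
$\eta_{is} = \alpha_s + \sum_t \beta_{st} x_{it} + \sum_j \rho_{sj}(y_{ij})$
for the continuous linear predictor, the loss is the average negative
log *pseudo-likelihood*

$$
\ell = \frac1n \sum_i \Big[ \sum_s \tfrac12 (x_{is} - \eta_{is})^2 +
\tfrac12\log 2\pi + \sum_j \big( \log \textstyle\sum_\ell e^{s_{ij\ell}}
- s_{ij y_{ij}} \big) \Big],
$$

with categorical level scores
$s_{ij\ell} = \alpha_{j\ell} + \sum_s \rho_{sj}(\ell) x_{is} +
\sum_r \phi_{rj}(y_{ir}, \ell)$. Pseudo-likelihood replaces the
intractable joint normalizing constant with node-wise conditionals; it
is convex in the parameters and consistent for the edge support.

Assumptions worth stating plainly: continuous variables are modeled as
conditionally Gaussian with **unit conditional variance after
standardization** (the package standardizes continuous columns
internally before fitting). This keeps the objective convex and matches
the simulator's convention; it trades away efficiency when true
conditional variances differ, but does not change which blocks are
nonzero at the optimum in the well-specified case. Heavily non-normal
continuous margins should be passed through
`nonparanormal_transform()` first (opt-in, see below).

## Penalties and the proximal step

Sparsity is imposed blockwise with three weights: `lambda_cc` on each
scalar $\beta_{st}$ (lasso), `lambda_cd` on each level-effect vector
$\rho_{sj}$ (group lasso, $\ell_2$ norm) and `lambda_dd` on each
level-interaction matrix $\phi_{rj}$ (group lasso, Frobenius norm).
Group norms are the natural blockwise notion of "one edge, one
penalty": an edge is present exactly when its whole block survives the
group soft-threshold, and the proximal operator produces exact zeros,
so the estimated graph is read directly off the support
(`extract_graph()`, threshold `eps = 1e-8` only guards against
floating-point dust).

Identifiability: adding a constant to a $\rho_{sj}$ vector (or a row or
column of $\phi_{rj}$) can be absorbed by an intercept without changing
any conditional distribution. After every proximal step the package
re-centers each block to mean zero and shifts the intercepts
accordingly. Centering is the minimum-norm representative of the
equivalence class, so the smooth loss is unchanged and the penalty
never increases — the objective trace stays monotone.

## Optimization

`fit_mgm()` minimizes loss + penalty by proximal gradient descent with
FISTA momentum. The step size comes from backtracking line search on
the quadratic-majorization condition (halving until satisfied, with the
accepted step doubled at the next iteration). A *monotone restart*
guards the acceleration: if an extrapolated step would raise the
objective, momentum resets and a plain proximal step is taken, so the
recorded `objective_trace` is non-increasing by construction — a
property the test suite asserts on every fitted model. Convergence is
declared when the relative objective change drops below `tol`
(default `1e-5`, 1000 iterations cap). The analytic gradient is
verified against central finite differences to a relative error below
`1e-4` in the tests.

Default penalties are `lambda_triple(0.25)` on all three types — an
arbitrary but serviceable middle of the stability grid; StEPS selection
is recommended whenever runtime allows.

# StEPS: stability-based penalty selection

StEPS chooses the triple $(\lambda_{CC}, \lambda_{CD}, \lambda_{DD})$
without cross-validation. For `N = 20` subsamples of size
$\min(\lfloor 10\sqrt n\rfloor, \lfloor 0.75\,n\rfloor)$ drawn without
replacement, the MGM is fit and, per edge type, the instability
$\mathrm{mean}_{\text{pairs}}\, 2\bar\theta(1-\bar\theta)$ is computed,
where $\bar\theta$ is the fraction of subsamples containing the edge.
Starting from the smallest value of a 30-point log grid on
$[0.05, 0.9]$ applied to all three types, any type whose instability
exceeds $\gamma = 0.05$ advances to the next grid value; a type at or
below $\gamma$ freezes. Frozen types keep their value while the
subsample fits are re-run at the updated mixed triple, so all
instabilities are always measured under one consistent model. Reported
profiles also carry a monotonized instability (running maximum from the
sparse end), which guards threshold crossing against non-monotone
noise.

Two consequences of the iterative design are worth knowing. First,
freezing is permanent: a type that froze early is not revisited when
other types later move, so its instability *measured at the final
triple* can drift above $\gamma$ on strongly dependent data. On
mutually independent variables — the regime in which the
self-consistency of the procedure is tested — the recomputed
instability of the chosen triple stays within $\gamma + 0.02$ on fresh
subsamples. Second, the grid is the package's own policy (the method
only requires *some* ascending grid); both bounds and resolution are
configurable in `steps_config()`.

# Conditional-independence tests

`ci_test()` dispatches on types. If either variable is continuous, it
becomes the response of an ordinary least-squares regression on the
other variable plus the conditioning set (categorical predictors
dummy-encoded against their first level); the p-value is the two-sided
t-test on the tested coefficient, or the partial F-test of the dummy
group when the tested variable is categorical with more than two levels
(the F-test equals the squared t-test when the group has one column, so
this is the unique consistent generalization). When both variables are
categorical, two nested multinomial logistic models (with and without
the tested variable) are compared by a likelihood-ratio test on
$(L_y - 1)\,m$ degrees of freedom. Multinomial fits use `nnet`, with a
tiny ridge (`decay = 1e-8`) retry on non-convergence; complete
separation is handled by the same stabilization.

Edge cases are resolved in the direction that is safe for skeleton
pruning: a pair that *cannot* be tested (no residual degrees of
freedom) is reported dependent, i.e. the edge is kept, with a warning.
A tested variable that is constant or fully aliased given the
conditioning set yields p = 1. When both variables are continuous the
lexicographically later name is the response — an arbitrary but
deterministic choice; the test is symmetric in theory and the suite
checks agreement to `1e-8` in practice.

# PC-Stable and orientation

`pcs_skeleton()` starts from the MGM graph rather than the complete
graph. At each depth $d$ it snapshots every node's adjacency set
before any removal, then, for each surviving edge $X\!-\!Y$, enumerates
size-$d$ subsets of the snapshot neighborhoods of $X$ and of $Y$ in
lexicographic order; the first accepting test removes the edge and
records the separating set. Because both the candidate edges and the
neighborhoods come from the start-of-depth snapshot, the result is
independent of variable order — the suite verifies exact CPDAG
invariance under all 720 relabelings of a six-node fixture.

`orient_colliders()` orients every unshielded triple $X - Z - Y$ as
$X \to Z \gets Y$ exactly when $Z$ is absent from the recorded
separating set of $(X, Y)$. When two triples disagree about an edge the
package does not let one overwrite the other: the edge is marked
conflicted (arrow–arrow, exported as `conf`), which preserves order
independence at the cost of being stricter than PC variants that keep
the first orientation. A nonadjacent pair that was never tested (it can
arise when the pair was already nonadjacent in the MGM seed graph) is
treated as separated by the empty set, with a warning.
`apply_meek_rules()` then propagates rules R1–R3 to a fixed point,
never reorienting conflicted edges; rule R4 is omitted because the
package has no background-knowledge edges that could trigger it.

The output is a CPDAG-like endpoint graph: directed edges where all
Markov-equivalent DAGs agree, undirected where they do not, conflicted
where the data contradict themselves. Interpreting any of it causally
requires the usual assumptions — acyclicity, causal Markov,
faithfulness, and causal sufficiency (no unobserved confounders, no
selection bias). None of these are checkable in code, and violations
(a latent confounder, say) show up as extra or conflicted edges.

# Pref-Div feature selection

Association with the target is $|r|$ (Pearson) for a continuous target
and $1 - p$ from the logistic (multinomial if needed) likelihood-ratio
test for a categorical target. Candidates are swept in descending
association order; a candidate whose absolute correlation with an
already-selected variable reaches the threshold $\tau$ is *marked* —
clustered under its representative or dropped — and the working list
refills until the requested count is reached. Categorical candidates
bypass scoring and are always included (no mixed-pair similarity is
defined), as are user-kept variables, and neither counts against the
requested total. Ties in association are broken lexicographically; a
marked variable joins the earliest-selected qualifying representative.

When `tau = "auto"`, the threshold is chosen by the same stability
logic as StEPS: over 50 half-sample subsamples, each candidate pair's
"similar" indicator ($|r| \ge \tau$) is tracked across a grid
$\tau \in \{0.10, 0.15, \dots, 0.90\}$, and the smallest $\tau$ whose
monotonized instability is at most 0.05 wins. This construction is the
package's own (declared, not inherited), and it is validated by
recomputing the instability of the chosen threshold on fresh
subsamples.

# The simulator

`random_mixed_graph()` draws an Erdős–Rényi graph with edge probability
`expected_degree / (p - 1)` and equips edges with potentials drawn
uniformly from $\pm[0.5, 1] \cdot$ `effect_scale` (default 1):
scalars for continuous–continuous edges (off-diagonal entries of the
continuous precision block, whose diagonal is fixed at 1), zero-sum
level vectors for continuous–categorical edges, and doubly centered
matrices for categorical–categorical edges. The potential convention
means a single continuous–continuous edge with parameter $\beta$ implies
correlation $-\beta$; the MGM fit uses the regression-coefficient
convention, so estimated signs flip relative to the generator while the
support is identical.

Two safeguards/choices deserve explicit mention:

* **Positive definiteness.** Nothing in the $\pm[0.5,1]$ draw
  guarantees $I + B$ (the continuous precision block) is positive
  definite. When its smallest eigenvalue falls below 0.2 the block is
  rescaled so that it equals 0.2; the factor is recorded on the model.
  Without this the Gibbs conditionals diverge.
* **Sampling scheme.** Samples are drawn by Gibbs sweeps over the full
  conditionals (Gaussian for continuous nodes, multinomial-logistic for
  categorical ones). The default scheme runs `n` *independent chains in
  parallel*, vectorizing each sweep across chains and keeping one draw
  per chain after 200 burn-in sweeps — this yields exactly independent
  samples and is orders of magnitude faster in R than one long chain. A
  single-chain sampler with thinning (default 10) is available via
  `chains = "single"`. The parallel sampler is validated against exact
  answers where they exist: the empirical covariance of all-continuous
  models matches the inverse precision matrix to 0.05, and on small
  discretizable models the sampled joint matches the enumerated one to
  ~0.003.

`dag_model_for_pc()` provides directed ground truth for orientation
benchmarks: a random topological order, Erdős–Rényi edges respecting
it, linear-Gaussian and multinomial-logistic structural equations, and
ancestral sampling (no chains involved).

**What the simulations do not show.** The generator produces exactly
the model family the MGM assumes — Gaussian conditionals with unit
variance, multinomial-logistic conditionals, faithful sparse structure.
Passing recovery tests therefore demonstrates correctness of the
estimator under its own assumptions, not robustness to the
misspecification real data bring (non-normal margins, ordinal scales,
measurement error, latent confounding). The non-paranormal transform
addresses only the first of these.

A further caveat that the benchmarks surface honestly: centering the
drawn level-effect vectors and matrices (required for identifiability)
can nearly cancel a block whose entries were drawn with independent
random signs. A fraction of true edges in any simulated model —
typically a fifth at the default settings — end up with block norms far
below $0.5$ and are statistically invisible at moderate sample sizes.
Structure-recovery scores at `p = 20, n = 2000` average an F1 around
0.74 over seeds, with an oracle ceiling near 0.86 imposed purely by
those faint edges; the same benchmark with the faint edges excluded
from the truth would score far higher. We keep the generator convention
(and the resulting honest score) rather than redefining the truth set.

# Problem sizes used in the checks

The test suite and the acceptance script favor many small, sharp checks
over few large ones: calibration of the CI test uses 1000 null
replicates at n = 500; gradient checks use mixed instances with p = 6;
order independence enumerates all 720 relabelings of a 6-node fixture
at n = 600; recovery uses p = 20 at n = 2000 over 10 seeds; StEPS
self-consistency uses p = 10 at n = 300 with 15 subsamples; collider
orientation uses 20 replicates at n = 5000. These sizes were chosen as
the smallest at which the corresponding statistical statement is
cleanly separated from Monte-Carlo noise.

# Numerical details in one place

| Quantity | Default | Where |
|---|---|---|
| MGM convergence tolerance | 1e-5 (relative objective change) | `fit_mgm(tol=)` |
| MGM iteration cap | 1000 | `fit_mgm(max_iter=)` |
| Edge-support threshold | 1e-8 on block norms (prox zeros are exact) | `extract_graph(eps=)` |
| Default penalty triple | 0.25 / 0.25 / 0.25 | `lambda_triple()` |
| StEPS grid | 30 log-spaced points in [0.05, 0.9] | `steps_config()` |
| StEPS instability bound | gamma = 0.05 | `steps_config()` |
| Subsamples | N = 20, size min(10 sqrt(n), 0.75 n) | `subsample_indices()` |
| CI-test level | alpha = 0.05 | `ci_test()`, `pc_config()` |
| Pref-Div stability grid | tau in 0.10..0.90 step 0.05, B = 50 halves | `stability_threshold()` |
| Non-paranormal truncation | 1 / (4 n^{1/4} sqrt(pi log n)) | `nonparanormal_transform()` |
| Gibbs burn-in | 200 sweeps per chain | `sample_mixed_data()` |
| Categorical inference cutoff | max_levels = 5 integral values | `read_mixed_table()` |

Degenerate inputs: missing cells are a load error (imputation would
silently change every downstream stage); constant columns are kept but
excluded from models, with a warning; ties in the non-paranormal
transform use average ranks; collinear test designs drop aliased
columns and warn.
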