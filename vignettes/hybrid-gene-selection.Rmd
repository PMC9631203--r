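---
title: "Hybrid FCBF + MLP-PSO gene selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid FCBF + MLP-PSO gene selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesift)
```

## The problem

Expression studies of binary phenotypes — here, ruptured (label 1) versus
unruptured (label 0) intracranial aneurysms — typically start from a
differential-expression screen that still leaves hundreds of genes, many of
them mutually redundant (co-regulated genes share expression patterns) or
simply irrelevant. Classifiers trained on all of them overfit, and a
hundreds-of-genes signature is clinically unusable. genesift implements a
two-stage hybrid selection that combines the speed of an
information-theoretic filter with the model-awareness of a wrapper:

1. **Stage 1 — FCBF (fast correlation-based filter).** Genes are ranked by
   symmetrical uncertainty with the class,
   $$SU(X, Y) = \frac{2\,[H(X) - H(X\mid Y)]}{H(X) + H(Y)} \in [0, 1],$$
   genes with $SU \le \delta$ are dropped as irrelevant, and the
   predominant-feature rule removes redundancy: walking the ranking from the
   top, a gene $g_j$ is deleted when some kept, higher-ranked $g_i$
   satisfies $SU(g_j, g_i) \ge SU(g_j, C)$ — it tells the classifier
   nothing that $g_i$ does not already tell it.
2. **Stage 2 — MLP-PSO wrapper.** A particle swarm searches subsets of the
   surviving candidates. Each particle's continuous position
   $x \in [0,1]^D$ decodes to a subset (gene $j$ included iff
   $x_j \ge 0.5$), which is scored by a small multilayer perceptron under
   stratified cross-validation. Velocities and positions follow the
   canonical recursion
   $$v^{t+1} = \omega v^t + c_1 r_1 (pbest - x^t) + c_2 r_2 (gbest - x^t),
     \qquad x^{t+1} = x^t + v^{t+1}.$$
3. **Step 3 — benchmark.** Any subset can be evaluated with ten classifier
   families under stratified 10-fold cross-validation (accuracy, recall,
   precision, F1, per-fold ROC AUC mean ± SD, pooled confusion matrices),
   before and after selection.

## Discretization

Symmetrical uncertainty needs discrete variables; expression is continuous.
The default is the supervised Fayyad–Irani minimum-description-length
criterion: recursive binary splitting of each gene's values, a cut accepted
only when its information gain beats the MDL coding cost
$\big(\log_2(n-1) + \log_2(3^k - 2) - [k\,H(S) - k_1 H(S_1) - k_2 H(S_2)]\big)/n$.
MDL is parameter-free, is the de-facto companion of FCBF in standard
machine-learning toolkits, and has a useful side effect: a gene with no
accepted cut collapses to a single bin, gets $SU = 0$, and is discarded at
the default $\delta = 0$ — the relevance filter and the discretizer agree
on what "uninformative" means. Equal-frequency and equal-width binning
(default 10 bins) are available for unsupervised use. Entropies use
empirical plug-in frequencies without smoothing, in bits.

Conventions for degenerate inputs: a constant vector has entropy 0; SU
involving a constant variable is 0 (it carries no information about
anything); SU is clamped to $[0,1]$ against floating-point drift; ranking
ties are broken by ascending gene identifier so the sweep is reproducible.

## Wrapper fitness

A subset's fitness is
$$\mathrm{ACC} - \lambda_{\mathrm{mse}}\,\mathrm{MSE}
  - \lambda_{\mathrm{size}}\,\frac{|S|}{D},$$
with ACC and MSE (mean squared difference between out-of-fold predicted
probability and the 0/1 label) estimated by stratified 5-fold
cross-validation of the MLP on the subset's columns. Defaults
$\lambda_{\mathrm{mse}} = 0.1$ and $\lambda_{\mathrm{size}} = 0.05$ keep
accuracy dominant while still preferring calibrated, small subsets between
accuracy ties; both weights are exposed in `eval_config()`. The fitness RNG
is derived from the run seed and the subset mask, so a subset's score is
stable no matter when the swarm revisits it, and scores are cached by mask.

The MLP is deliberately minimal: one hidden layer (default $m = 10$) with
logistic activations feeding a logistic output
$f(d) = 1/(1 + e^{-g(d)})$, trained by full-batch gradient descent on MSE
(learning rate 0.1, up to 300 epochs, early stop when the loss improves by
less than $10^{-6}$), weights initialized uniform$(-0.5, 0.5)$ from the
seed, features standardized with training-fold statistics. Full-batch
training makes the fit a pure function of (data, config, seed), which the
wrapper requires; it is a scorer, not a competitive classifier.

An all-excluded decoded mask is repaired by including the gene with the
largest position component rather than assigning a penalty fitness — the
classifier then always has at least one feature and the search surface has
no artificial cliffs.

## Swarm settings

Defaults: 30 particles, 100 iterations, $\omega = 0.7$,
$c_1 = c_2 = 2$ (the conventional acceleration values), velocity clamp
$v_{\max} = 0.6$, decode threshold 0.5. Positions are clipped to
$[0,1]^D$, velocities to $[-v_{\max}, v_{\max}]$, after every update. The
stopping rule is the fixed iteration budget only; personal and global bests
update on strict improvement, so the reported global-best trace is
non-decreasing by construction.

One improvement over the plain recursion addresses a known pathology of
threshold-decoded swarms: once every particle sits on the same side of the
decode threshold in some coordinate, the attraction terms vanish there,
inertia decays, and that bit can never flip again. When the global best has
not improved for `stall_refine` iterations (default 10), the search
therefore evaluates every single-bit flip of the global-best mask and
adopts the best strict improvement — a memetic local-refinement step
costing at most D fitness evaluations (served partly from the cache) that
restores the ability to correct one stuck coordinate. It draws no random
numbers, so reproducibility is unaffected; `stall_refine = 0` disables it. Positions stay continuous and the
binarization is an explicit decode step; this keeps the update equations in
their canonical form and makes the discrete mapping a documented,
replaceable choice rather than an implicit one.

## Benchmark protocol

The ten families are XGBoost, LightGBM-style leaf-wise gradient boosting
(implemented with xgboost's histogram `lossguide` grower, 31 leaves),
random forest, extremely randomized trees, Gaussian naive Bayes,
k-nearest neighbours, L2-regularized logistic regression (ridge penalty
$1/n$), a decision tree, an RBF support-vector machine, and linear
discriminant analysis. Hyperparameters are the pinned library defaults in
`inst/config/benchmark_defaults.yaml`; no per-dataset tuning.

Accuracy, recall, precision, and F1 come from the pooled out-of-fold
predictions (one confusion matrix per model, rows true 0/1, columns
predicted 0/1); AUC is the per-fold mean ± SD — the mixed convention most
papers print. Positive class is 1 (ruptured); precision is defined as 0,
with a warning, when a model predicts no positives. All folds are
stratified with a seeded shuffle and shared across models, so model rows
are directly comparable.

Two protocols are exposed:

- `protocol = "paper"` (default): selection runs once on the full dataset,
  then the benchmark cross-validates on the same samples. This replicates
  the prevailing published procedure, but the test folds have already been
  seen by the selection stage, so its estimates are optimistically biased.
- `protocol = "nested"`: FCBF + PSO are re-run inside each outer training
  fold and metrics come from the outer test folds only. This is the
  leakage-free estimate; it is slower (selection runs $k$ times) and its
  per-fold gene lists (`fold_selections`) show how stable the signature is.

Keeping both makes the bias visible instead of silently choosing either.

## The synthetic generator

`synth_expression()` emulates the statistical shape of a
differential-expression-filtered matrix on a log2-like scale: class sizes
default to 48/40 (the positive/negative totals typical of the pooled
aneurysm cohorts this method targets); *informative* genes are Gaussian
within class with means separated by `effect_size` (default
$0.585 = \log_2 1.5$, the usual fold-change screen); *redundant* genes are
noisy copies of randomly chosen informative genes
(`redundancy_noise_sd = 0.1`, small enough that "redundant" is
unambiguous); *noise* genes are label-independent Gaussians. Ground-truth
roles are attached to the returned tibble, so filter and wrapper behavior
can be scored exactly. `deg_prefilter()` offers the t-test + fold-change
screen as an optional pre-step.

What the generator does **not** emulate: cross-platform batch effects and
their correction, count-based sequencing noise, correlated pathway blocks
(redundancy here is pairwise copying, not co-regulation networks), or
class-dependent variance. Passing tests on this fixture therefore
demonstrate algorithmic correctness — the filter removes planted
redundancy, the wrapper finds high-fitness subsets, selection improves
cross-validated accuracy — not performance on real, batch-corrected
multi-platform data.

## Reproducibility

Every run hangs off one master seed. Stage seeds (swarm, benchmark folds,
per-model fits, per-subset fitness) are derived from it by a stable string
hash (`derive_seed()`), so stages can be re-run in isolation and two runs
with the same seed write byte-identical artifacts
(`candidates_ranked.tsv`, `selected_genes.txt`, `fitness_history.tsv`,
`benchmark_report.tsv`, `confusion_<model>.tsv`, `run_manifest.json`).
All model fits are single-threaded; seeded RNG use is scoped so library
calls cannot perturb the caller's stream.

## Validation scale

The package's end-to-end validation runs use 60 + 60 samples with
5 informative, 10 redundant, and 600 noise genes at effect size 2.0, a
swarm of 20 particles for 25 iterations, and a 200-epoch MLP — sizes at
which the planted structure is comfortably detectable and a full
five-seed replication of the pipeline (plus before/after 10-fold
benchmarks of all ten families) completes in minutes on a single core.
The injected-fitness swarm validation uses $D = 10$, where exhaustive
enumeration of all 1,024 masks is feasible as an oracle.

## Known limitations

- **Group representatives, not originals.** When a gene has near-duplicate
  copies (copy noise sd 0.1 against within-class sd 1.0), the true SU
  difference between original and copy (~0.1%) is far below SU estimation
  noise at ~100 samples (~2–5%). Which member of a correlated group tops
  the ranking is therefore essentially arbitrary, and the predominant-
  feature rule keeps exactly one arbitrary representative per group. The
  filter reliably eliminates *duplication* — at most one member per planted
  group survives — but cannot be expected to prefer the designated
  "original" over its copies; only in the exact-duplicate limit, where SU
  values tie and the identifier tie-break applies, is the kept member
  deterministic. Downstream interpretation should treat a selected gene as
  a representative of its correlation neighbourhood.
- The paper-protocol benchmark is optimistically biased by design (see
  above); use `protocol = "nested"` for honest error estimates.
- Binary phenotypes only; multi-class SU ranking is out of scope.
- The MLP scorer uses plain gradient descent; it is not intended as a
  standalone classifier.
- `delta` (FCBF relevance threshold) defaults to 0; on very large gene
  universes with heavy-tailed SU noise a small positive `delta` or the
  `deg_prefilter()` step shrinks Stage 1's output and speeds the wrapper.

## A worked miniature

```{r example, eval = FALSE}
set.seed(1)
d <- synth_expression(n_pos = 60, n_neg = 60, n_informative = 5,
                      n_redundant = 10, n_noise = 600,
                      effect_size = 2, seed = 1)
run <- run_hybrid(d, run_config(
  swarm = swarm_config(n_particles = 20, n_iterations = 25),
  mlp = mlp_config(epochs = 200), seed = 101
))
print(run)
tidy(run$benchmark_after)     # per-model metrics on the selected subset
autoplot(run$selection)       # swarm convergence trace
```
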