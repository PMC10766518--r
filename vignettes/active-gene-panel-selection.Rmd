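---
title: "Active selection of minimal gene panels with linear SVMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active selection of minimal gene panels with linear SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Targeted transcriptomic assays, spatial panels and clinical screens cannot
measure the whole transcriptome: they need a small set of genes that still
separates the cell states of interest. Given a cells × genes expression
matrix and a per-cell class label (from upstream clustering, experimental
metadata or prior biology), `activesvm` searches for a minimal ordered gene
panel such that a linear classifier restricted to the panel reproduces the
labels well — while examining the full transcriptome of only a small,
actively chosen subset of cells.

## The model

The classifier is the soft-margin linear SVM. For cells $x_i \in
\mathbb{R}^{|J|}$ restricted to the current panel $J$ and labels $y_i \in
\{-1, +1\}$, training minimizes the L2-regularized hinge loss
$\tfrac12\lVert w\rVert^2 + C\sum_i \max\{0,\, 1 - y_i(w^\top x_i + b)\}$.
The dual form attaches a coefficient $\alpha_i \in [0, C]$ to every training
cell, and complementarity ties it to the functional margin
$f_i = y_i(w^\top x_i + b)$:

* $\alpha_i = 0 \Rightarrow f_i > 1$ — the cell sits outside the margin;
* $0 < \alpha_i < C \Rightarrow f_i = 1$ — an on-margin support vector;
* $\alpha_i = C \Rightarrow f_i < 1$ — a margin violator (misclassified or
  deep inside the margin).

The package's production solver (libsvm through `e1071`, linear kernel) does
not expose all duals, so margin status is derived from the functional
margins directly — equivalent under the complementarity conditions above.
The category boundary at $f = 1$ uses a tolerance of $10^{-4}$; the solver
convergence tolerance is $10^{-6}$. With $Z > 2$ classes, one machine is fit
per class one-vs-rest, and a cell is pool-eligible if it violates any
machine's margin.

## The iteration

1. **Fit** the SVM on *all* training cells restricted to the current panel
   $J$ and record train/test accuracy. Only an $N \times |J|$ block is
   needed.
2. **Pool** the margin violators (optionally violators plus on-margin
   cells).
3. **Acquire** a cell set $I$ from the pool:
   * *min-complexity*: a fresh sample of $c$ cells each iteration;
   * *min-cell*: previously acquired violators are reused with highest
     priority; with $a$ of them in the pool and $b$ new pool cells, only
     $\min(c - a,\, b)$ new cells are added when $a < c$, and the whole
     accumulated set is used. The unique-cell count is monotone and
     typically flattens, which is the point of the strategy.
   Sampling is uniform or *class-balanced*: visiting classes from the
   smallest candidate pool to the largest, a class whose pool fits its even
   share $(c' - \text{taken})/(\text{classes left})$ is taken whole,
   larger classes get the floor of the share, remainders flowing to later
   classes.
4. **Select the next gene** on $I$ only: for each candidate $j \notin J$ an
   SVM on $(I, J\cup\{j\})$ gives $w_j$, and the score is the *margin
   rotation*
   $\vartheta_j = \arccos\frac{\langle w_j, w_{\mathrm{pad}}\rangle}
   {\lVert w_j\rVert\,\lVert w_{\mathrm{pad}}\rVert}$, where
   $w_{\mathrm{pad}}$ is the current weight vector $w$ zero-padded into the
   new dimension. In the driver, $w$ is the step SVM of stage 1 — the
   machine trained on all training cells, i.e. the one that actually
   selected the cells — which is a far more stable rotation reference than
   a refit on the small cell set ($|I| \approx 20$ cells); called outside
   the driver without a reference, `select_next_gene` falls back to the
   cell-set refit. With $Z$ classes the per-machine angles are summed, so
   $\vartheta_j \in [0, Z\pi]$; machines for classes absent from $I$
   contribute nothing. The candidate with the largest rotation — the
   largest expected model change — is appended; ties break to the smallest
   gene index.

The loop stops at the requested panel size $k$ or as soon as the pool is
empty (perfect training classification). Because the rotation score needs an
existing $w$, the first gene is bootstrapped differently: on a seeded random
cell sample, every gene is scored by its 1-D SVM training accuracy and the
best one seeds the panel. The bootstrap sample defaults to
$\max(c, 100)$ cells (capped at the training set): an accuracy scan over
thousands of candidate genes on a 20-cell sample overfits often enough to
seed the panel with a noise gene, which then costs several early
iterations. The accumulated cell set of the min-cell strategy starts from
this bootstrap sample, since those cells have genuinely been examined.

**A degeneracy worth knowing about.** If the current panel carries no class
signal, $w$ is essentially zero and almost every candidate rotates the
margin to $\pi/2$; the argmax is then decided by numerical noise. The
accuracy bootstrap exists precisely to avoid starting in that regime, and
the oracle-equivalence tests seed the panel with an informative gene for the
same reason. Zero-norm weight vectors are defined to contribute angle 0.

## Memory and time

Only two dense blocks are ever live: the $N \times |J|$ block of all cells
on the panel, and the $|I| \times M$ block of the acquired cells on all
genes, keeping memory at $O(N k + |I| M)$ rather than $O(NM)$. The on-disk
store backing (a binary CSR+CSC layout with per-row/per-column seeks)
honors this block-access contract out of core, and every store counts the
dense entries it has handed out, so the contract is assertable. Per-candidate
refits involve only $|I|$ cells and $|J|+1$ genes, so each iteration costs
one $O(N|J|)$ fit plus $M - |J|$ small fits — linear in $M$.

## Preprocessing dialects

Two presets reflect common practice for UMI count matrices:

* `colnorm_log_l2`: each gene column divided by its total over cells, then
  `log1p`, then each cell row scaled to unit Euclidean norm (the default);
* `l2_only`: per-cell unit scaling alone, for very large or
  already-transformed matrices.

All-zero genes and cells are removed first (`drop_empty`), with index maps
back to the original coordinates. The log transform uses the natural log
with pseudocount 1; a different pseudocount `p` is applied as
`log1p(x / p)`, which keeps zeros exactly zero and thus preserves sparsity.
Zero rows encountered by the l2 step are left unchanged with a warning —
they have no direction to normalize.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | target panel size (genes) |
| `c_budget` | 20 | cells acquired per iteration |
| `C` | 1 | SVM cost: margin width vs violation trade-off |
| `pool_criterion` | violators | `violators` ($\alpha = C$) or `violators_or_margin` ($\alpha > 0$) |
| `strategy` | min_complexity | cell acquisition strategy |
| `sampling` | random | uniform or class-balanced pool sampling |
| `train_fraction` | 0.8 | uniform train/test split of cells |
| `seed` | 0 | root seed; all streams derive from it |

The split is uniform over cells by default (stratified splitting is
available but off, since plain uniform splitting is the common protocol);
every random draw (split, bootstrap, per-iteration sampling, baselines,
simulator) uses a named stream derived from the root seed, so identical
configurations reproduce results exactly and changing one stage never
perturbs another.

## The synthetic generator

`generate_planted()` draws negative-binomial counts
(`variance = mu + phi * mu^2`) with background mean $\mu_0$ everywhere and
mean $f\mu_0$ for each class's disjoint marker genes in that class's cells,
then applies independent Bernoulli dropout. Defaults — $\mu_0 = 2$,
dispersion $\phi = 0.5$, dropout $0.3$, fold-change $f = 6$, three equal
classes of 200 cells, five markers per class among 1,000 genes — are a
plausible droplet-scRNA-seq regime with strong but not caricatural markers;
$f = 1$ plants no signal and serves as the null for calibration checks. The
generator emulates class structure and sparsity only: it has no library-size
variation, batch effects, correlated gene modules beyond the planted
markers, or cell-type hierarchy. Passing tests on planted data therefore
demonstrate the mechanics of the method (recovery, calibration, strategy
contracts), not performance on any real tissue.

The simulation studies preprocess planted counts with the `l2_only`
dialect. The generator's counts are library-size-uniform by construction,
so per-gene column normalization contributes nothing there; worse, it
shrinks every feature to a scale at which, with $C = 1$, functional margins
rarely exceed 1, nearly every cell is a violator for some one-vs-rest
machine, and the pool never focuses. On real count matrices with variable
sequencing depth the `colnorm_log_l2` dialect remains the appropriate
default.

## Validation strategy and numerical choices

* The production solver is cross-checked against an independent dual
  quadratic program: `kernlab::ipop` on the box-constrained dual, with
  weight reconstruction $w = \sum_i \alpha_i y_i x_i$. Because the
  interior-point solver can fail to factor its system on poorly scaled
  rank-deficient kernels, the reference escalates a diagonal ridge and
  finally falls back to a deterministic pure-R SMO ascent on the same dual;
  either way it shares no code with the libsvm path.
* `select_next_gene` must agree with a naive sequential reimplementation
  built on that reference solver.
* Angle computation clamps the cosine to $[-1, 1]$ before `acos`; angles
  are invariant to positive rescaling of either weight vector.
* Degenerate situations are defined, not left to chance: single-class cell
  samples are augmented with extra seeded draws (with a warning); constant
  candidate genes score angle 0 in selection and 0 in every baseline
  statistic; constant genes get correlation coefficient 0 (with a warning)
  in the reported correlation matrix; an empty pool stops the run with
  status `"pool_empty"`.
* Ties everywhere break to the smallest gene index, making runs
  reproducible bit-for-bit under a fixed seed.

Test problem sizes are chosen to exercise the full pipeline at desk scale:
the end-to-end checks use the 600 × 1,000 planted configuration above
(5 replicate seeds), solver cross-checks use ≤ 60-cell toys, and the
out-of-core contract is asserted on a 300 × 400 disk-backed run.

## Baselines

The comparison selectors (`correlation`, `mutual_information`, `chi2`,
`tree_importance`, `random`) share an iterative protocol with no active
learning: each iteration draws `c` cells uniformly and appends the
highest-scoring unselected gene. Multiclass correlation and chi-squared use
one-vs-rest indicators; mutual information uses 10 equal-width bins;
the tree method reads the candidate's impurity importance from a seeded
depth-10 CART refit on selected + candidate genes. These are reasonable
defaults rather than canonical definitions, and all are configurable.

## Known limitations

* Linear machines only; no kernels, no probability calibration.
* One gene is added at a time; pair/triple addition is out of scope.
* Labels are taken as given — the package does not cluster.
* The balanced-allocation recurrence assumes class pools sorted by
  ascending size; `balanced_allocation` enforces this rather than sorting
  silently.
* HDF5 input is not supported; for out-of-core runs use
  `write_disk_store()`/`open_disk_store()`, whose layout is private to this
  package.
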