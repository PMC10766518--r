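# activesvm

Active feature selection of minimal gene panels for cell-state
classification, for people designing targeted transcriptomic assays
(spatial panels, qPCR/amplicon panels, clinical screens) or simply looking
for a compact, ordered set of marker genes that reproduces a given cell
labelling.

## What it does

Given a cells × genes expression matrix and an integer class label per cell,
the package grows a gene panel one gene at a time with a linear soft-margin
SVM in the loop:

1. train the SVM on **all** training cells restricted to the current panel
   *J* and record accuracy;
2. pool the cells that classify poorly — the margin violators, i.e. cells
   whose dual coefficient sits at the cost cap *C* under the KKT
   complementarity conditions;
3. acquire a small cell set *I* from the pool (*min-complexity*: a fresh
   sample of *c* cells; *min-cell*: reuse previously acquired violators
   first and accumulate), uniformly or class-balanced;
4. for every candidate gene *j*, refit on (*I*, *J* ∪ {*j*}) and score the
   **margin rotation** — the angle
   θ<sub>j</sub> = arccos ⟨w<sub>j</sub>, w<sub>pad</sub>⟩ ⁄
   (‖w<sub>j</sub>‖ ‖w<sub>pad</sub>‖) between the new weight vector and
   the zero-padded current one, summed over one-vs-rest machines for
   multiclass problems. The gene rotating the margin most is appended.

Only an *N* × |*J*| block and an |*I*| × *M* block are ever dense in
memory, so the procedure scales to matrices that never fit in RAM (an
on-disk store backing with block access is included, plus an
instrumentation counter that makes the memory contract assertable).

Also included: five baseline selectors (correlation, mutual information,
chi-squared, tree importance, random) under the same iterative protocol, a
planted-marker negative-binomial simulator with recovery scoring, MTX/CSV
/TSV readers and writers, and proportion confidence intervals for accuracy
curves.

## Worked example

```r
library(activesvm)

# synthetic counts: 600 cells, 1,000 genes, 3 classes, 5 planted markers
# per class at 6x fold-change, NB noise + 30% dropout
d  <- generate_planted(planted_spec(seed = 0))
de <- drop_empty(d$store)
pp <- preprocess(de$store, "l2_only")

cfg <- run_config("min_complexity", "random", k = 20, c_budget = 20,
                  C = 1, seed = 0, dialect = "l2_only")
res <- run_activesvm(cfg, pp, d$labels[de$kept_cell_indices])
tail(res$records[, c("iteration", "gene_name", "train_accuracy",
                     "test_accuracy", "unique_cells")], 3)
marker_recovery(res$gene_names, d$truth)
```

```
   iteration gene_name train_accuracy test_accuracy unique_cells
18        18     g0010      0.9666667     0.9666667          289
19        19     g0235      0.9666667     0.9666667          296
20        20     g0348      0.9666667     0.9666667          298
[1] 1
```

Reading: with 20 genes the held-out accuracy is 97% (it first passes 90% at
11 genes), the run examined the full transcriptome of only 298 of the 480
training cells, and all 15 planted markers were recovered within the 20
selections. `res$records` holds the full accuracy-vs-panel-size curve;
`write_run_outputs(res, pp, "out/")` writes `genes.csv`, `curves.csv`,
`correlation.csv` and `run.json`.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/activesvm-cli.R simulate --cells 600 --genes 1000 \
    --classes 3 --markers-per-class 5 --seed 0 --out sim/
Rscript inst/scripts/activesvm-cli.R run --matrix sim/matrix.mtx \
    --labels sim/labels.csv --strategy min_cell --k 20 \
    --cells-per-iter 20 --seed 0 --out out/
```

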