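# scprogram

Supervised gene-program learning for single-cell expression data.

## What problem this solves

Differential-expression scans of modern scRNA-seq cohorts return thousands of
"significant" genes whose effect sizes are negligible, leaving biologists to
filter ad hoc. `scprogram` inverts the workflow: it learns a small number of
**gene programs** — weighted gene groups — that simultaneously classify cells
by phenotype and stay coherent on a gene–gene functional-annotation graph
(e.g. a BioGRID protein–protein interaction network). Because the loadings
are pushed toward near-binary values, each program doubles as a gene set
ready for enrichment tools, and because donors, not cells, are the clinical
unit, cell-level scores are averaged per donor into individual-level
predictions.

It is aimed at analysts of case/control single-cell cohorts (one cell type
at a time) who want interpretable, annotation-grounded signatures along with
donor-level classification.

## The model

With $X \in \mathbb{R}^{p\times n}$ the gene-by-training-cell expression
(depth-normalized, log1p) and $\tilde A = D^{-1/2} A D^{-1/2}$ the normalized
self-looped annotation adjacency, two graph-convolution layers

$$H^{(\ell)} = \mathrm{ReLU}\!\left(\tilde A\, H^{(\ell-1)} W^{(\ell-1)} +
H^{(\ell-1)} W_{skip}^{(\ell-1)}\right), \quad H^{(0)} = X,$$

feed a row-wise softmax pooling $S = \mathrm{Softmax}(H W_H) \in
\mathbb{R}^{p\times d}$ that assigns every gene a weight distribution over
$d$ programs. Cells are projected as $X_r = X^\top S$ and classified by a
three-layer MLP. Everything trains jointly under

$$L_{clf} + w\,(L_c + L_o), \qquad
L_c = -\frac{\mathrm{Tr}(S^\top \tilde A S)}{\mathrm{Tr}(S^\top \tilde D S)},
\qquad
L_o = \left\lVert \tfrac{S^\top S}{\lVert S^\top S\rVert_F} -
\tfrac{I_d}{\sqrt d} \right\rVert_F,$$

the minCUT cut and orthogonality relaxations: connected genes share programs,
loadings become near-one-hot, program sizes stay comparable. `w = 0` is the
annotation-free baseline; `w = 2` is the default. See the methods vignette
(`vignettes/gene-programs.Rmd`) for every convention and numerical choice.

## Worked example

The built-in generator plants graph-aligned gene modules and a donor-level
phenotype, so the whole pipeline runs without downloads:

```r
library(scprogram)

ds <- simulate_dataset(sim_config(seed = 1))
#> <synthetic_dataset>
#> <sc_dataset> 400 cells x 300 genes (counts)
#>   donors: 20; labels: 0/1
#>   split: test=200 train=200
#> <gene_graph> 300 genes, 718 edges (excl. self-loops)
#>   planted modules: 5 x 20 genes; informative: 1,2

norm  <- normalize_counts(ds$expression)
marks <- select_marker_genes(norm)        # one-sided MW + BH + HVG cap
train <- subset_genes(norm, marks$genes)  # 186 candidate genes

cfg <- train_config(w = 2, d = 10, max_epochs = 2000, min_epochs = 2000,
                    patience_epochs = 2000, learning_rate = 1e-3, seed = 1)
fit <- fit_gene_programs(train, ds$graph, cfg)
#> <gene_program_fit> 186 genes -> 10 programs (w = 2, task = binary)
#>   trained 2000 epochs; best validation classification = 0.2954 at epoch 236

head(program_diagnostics(fit, ds$graph, n_null = 1000, seed = 1))
#>   program  size connectivity conn_quantile mean_hoyer
#> 1       1    17        4.24          1          0.976
#> 2       2    15        3.6           1          0.967
#> 3       3    15        1.07          0.996      0.972
#> 4       4    12        0.667        0.942       0.937
#> 5       5    14        0.286        0.554       0.996
#> 6       6    15        1.2          0.998       0.960
```

Programs are small (12–17 genes), their loading rows are near-one-hot
(`mean_hoyer` ≈ 0.94–1), and most sit far above chance connectivity on the
annotation graph (`conn_quantile` near 1) — the two planted informative
modules surface as the dense, perfectly coherent programs 1–2.

Held-out donors are classified by averaging their cells' scores:

```r
test   <- subset_cells(train, train$cell_meta$split == "test")
donors <- predict(fit, test, level = "donor")
head(donors, 4)
#>   donor_id label n_cells  score
#> 1 D002         0      20 0.123
#> 2 D003         0      20 0.0802
#> 3 D005         0      20 0.137
#> 4 D006         0      20 0.177
rank_auc(donors$score, donors$label)
#> [1] 1
```

Control-donor scores sit near 0 and the ten held-out donors are ranked
perfectly (AUC 1) under this strong planted effect.

Other entry points: `graph_from_biogrid()` / `graph_from_edgelist()` for
real annotation graphs, `sweep_w()` + `select_w()` for choosing the graph
weight, `perturb_graph()` for annotation-sensitivity analyses,
`extract_gene_sets()` + `write_gmt()` for enrichment hand-off,
`tidy()` / `glance()` / `autoplot()` for tidy summaries and plots, and a
shell interface `inst/cli/scprogram.R` with subcommands
`simulate | fit | predict | evaluate | sweep-w | perturb-graph`.

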