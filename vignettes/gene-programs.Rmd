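---
title: "Supervised gene-program learning with an annotation graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised gene-program learning with an annotation graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scprogram)
```

## The problem

Gene-by-gene differential expression on large single-cell RNA-seq datasets
produces long lists of genes with tiny p-values and negligible effect sizes.
`scprogram` addresses interpretation directly: it learns a small number of
*gene programs* — weighted groups of genes that are simultaneously (i)
predictive of a phenotype at the cell level and (ii) coherent on a gene–gene
functional-annotation graph such as a protein–protein interaction network.
Cell-level prediction scores are averaged within each donor to give
individual-level predictions, the quantity of clinical interest when cells
are nested within patients.

## Model

Let $X \in \mathbb{R}^{p \times n}$ be the transposed expression matrix over
$p$ candidate genes and $n$ training cells (depth-normalized,
log-transformed), and let $A \in \mathbb{R}^{p \times p}$ be the symmetric
annotation adjacency including self-connections, with normalized form
$\tilde A = D^{-1/2} A D^{-1/2}$ where $D$ is the degree matrix of $A$.

Two graph-convolution layers embed each gene, using the gene's expression
across training cells as its node features:

$$H^{(1)} = \mathrm{ReLU}(\tilde A X W + X W_{skip}), \qquad
  H^{(2)} = \mathrm{ReLU}(\tilde A H^{(1)} W^{(1)} + H^{(1)} W^{(1)}_{skip}),$$

each with $h = 64$ hidden units. The skip term lets a gene retain influence
from its own profile where the graph is uninformative. A single pooling step
maps embeddings to the $p \times d$ loading matrix

$$S = \mathrm{Softmax}(H^{(2)} W_H),$$

row-wise, so each gene carries a weight distribution over the $d$ programs
(default $d = 40$). Cells are projected into program space as $X_r = X^\top
S$ and classified by an MLP with three 64-unit ReLU hidden layers (dropout
0.5 after hidden layers only).

Training minimizes

$$L_{clf} + w\,(L_c + L_o),$$

where $L_{clf}$ is the mean cross-entropy (binary by default; softmax
cross-entropy and mean-squared-error variants support multiclass and
continuous outcomes), and the two graph terms are the minCUT relaxation

$$L_c = -\frac{\mathrm{Tr}(S^\top \tilde A S)}{\mathrm{Tr}(S^\top \tilde D S)}
 \in [-1, 0], \qquad
 L_o = \left\lVert \frac{S^\top S}{\lVert S^\top S \rVert_F} -
 \frac{I_d}{\sqrt d} \right\rVert_F,$$

with $\tilde D$ the degree matrix of $\tilde A$. $L_c$ rewards placing
strongly connected genes in the same program; $L_o$ pushes loading vectors
toward near-binary, balanced assignments, which is what lets programs double
as gene sets. With $w = 0$ the model degenerates to an annotation-free
softmax-pooled MLP baseline; the graph-term values are still recorded in the
history for diagnostics but receive zero weight.

### The orthogonality target

For the target matrix in $L_o$ we use $I_d/\sqrt d$, the standard minCUT
orthogonality target: it is the unique scaled identity reachable by
$S^\top S / \lVert S^\top S\rVert_F$, and balanced one-hot loadings attain
$L_o = 0$ exactly — consistent with the term's purpose of promoting
one-program-per-gene assignments of comparable sizes. A plain $I_d$ variant
is selectable via `train_config(ortho_target = "identity")`; it cannot reach
zero (the normalized Gram matrix has unit Frobenius norm while
$\lVert I_d \rVert_F = \sqrt d$), which is why it is not the default.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `w` | 2 | weight on $L_c + L_o$; 0 disables annotation guidance |
| `d` | 40 | number of gene programs |
| `h` | 64 | hidden units per graph-convolution layer |
| `learning_rate` | 1e-4 | Adam step size |
| `weight_decay` | 1e-4 | L2 penalty added to gradients |
| `max_epochs` / `min_epochs` | 50,000 / 10,000 | full-batch epoch budget |
| `patience_epochs` | 3,000 | early-stopping patience on validation loss |
| `dropout_p` | 0.5 | dropout after MLP hidden layers |
| `validation_fraction` | 0.1 | training cells reserved for early stopping |
| membership threshold | 0.8 | a gene joins a program iff loading > 0.8 (strict) |
| `target_sum` | 10,000 | per-cell total after depth normalization |
| `fdr` / `max_per_class` | 0.05 / 1,000 | marker-gene preselection |
| `n_null` | 1,000 | null sets per connectivity quantile |

### Choosing `w`

`sweep_w()` refits over a grid (default $\{0, 0.25, 0.5, 1, 2, 5, 10\}$) and
tabulates, per `w`, the best validation loss, the number of non-empty
programs at the membership threshold, and the mean within-set connectivity
quantile. `select_w()` returns the smallest `w` whose validation metric is
within 0.02 (absolute) of the best — the least-regularized fit that is still
competitive once the graph diagnostics have stabilized. Ties favour the
smaller `w`.

## Preprocessing conventions

Marker preselection runs one-vs-rest one-sided Mann–Whitney tests per class
on the training cells only (validation and test cells never enter), controls
FDR at 0.05 by Benjamini–Hochberg, ranks survivors by *normalized variance*
— the variance of the depth-normalized, log-transformed expression across
all training cells, the simplest faithful reading of a variance computed
"from normalized expression data across all class labels" — and keeps at most
1,000 genes per class, de-duplicated across classes in stable order. Ties in
the variance ranking break lexicographically by gene symbol so selection is
deterministic. The preselection is intentionally inclusive: the programs
themselves decide which of the candidates matter.

## Graph construction

BioGRID TAB3 files are read through the two "Official Symbol" columns;
protein/isoform records collapse to gene-level nodes and duplicate or
reciprocal records to single undirected edges. Symbols match case-sensitively
after whitespace trimming; alias resolution is out of scope. Every node gets
a self-connection so degrees are positive: weight 1 on binary graphs, and the
maximum observed edge weight on weighted graphs so self-influence stays
comparable to the strongest neighbour (the convention is only visible on
weighted inputs, which the model accepts but the reference annotation — PPI —
does not produce). Genes of the universe absent from the file remain as
isolated self-looped nodes rather than being dropped, so the model can still
use their expression.

`perturb_graph()` supports sensitivity analyses: it removes a uniformly
chosen fraction of off-diagonal edges and replaces them with uniformly chosen
previously-absent pairs, preserving the edge count and self-loops and
reassigning the removed weights in random order. It is documented as a
utility dialect of "progressive graph perturbation", not as a bit-exact
replication of any particular published protocol.

## Inference and transfer

The loading matrix is cell-independent, so a trained model transfers to any
dataset sharing part of its gene list: `align_genes()` matches the
intersection (ordered by the training list) and projection uses the
corresponding submatrices of the data and of $S$. Missing genes therefore
contribute exactly nothing. Retained rows of the $S$ submatrix are *not*
renormalized by default — renormalization would change scores even when all
genes are present in a different order only conceptually, and the submatrix
convention is the direct consequence of subsetting; `renormalize = TRUE`
exists for users who prefer unit row sums after subsetting. Individual-level
scores are unweighted means of the donor's cell scores; no alternative
aggregations are offered.

## Diagnostics

*Hoyer sparsity* $(\sqrt d - \lVert v\rVert_1/\lVert v\rVert_2)/(\sqrt d -
1)$ summarizes how nearly one-hot a loading vector is (0 uniform, 1 one-hot,
scale-invariant). *Connectivity* of a gene set is $2 \times$ edges / genes
within the set, self-loops excluded (they are a normalization device, not
annotation evidence); on weighted graphs an edge counts when its weight is
positive, with a weighted-sum variant behind a flag. The *connectivity
quantile* compares a set's connectivity with `n_null` random same-size sets
drawn from the graph's full gene universe, using the mid-rank convention
`(#{null < C} + 0.5 #{null = C}) / n_null` so that fully tied references
(complete or empty graphs) give 0.5 rather than an arbitrary 0 or 1.

## The synthetic-data generator

`simulate_dataset()` builds the controlled conditions every downstream stage
is tested under: genes partitioned into planted modules, a planted-partition
graph (edge probability `p_in` within modules, `p_out` otherwise,
symmetrized, self-looped), per-cell module activities $a \sim N(\mu, 1)$
with $\mu$ shifted by `effect_size` in informative modules for
positive-class cells, gene-level means $\exp(a + N(0,
\texttt{noise\_sd}))$ scaled and Poisson-sampled into counts (right-skewed,
integer, linear in the planted structure after log transform). Background
genes get independent activities and join the graph only via `p_out` edges.
A `cell_label_noise` fraction of each donor's cells draws activities from
the opposite class, emulating cell labels inherited inaccurately from
donor-level phenotypes; `cell_meta$activity_label` records the generating
class so the mechanism is directly testable. Donors are split into train and
test stratified by class. One master seed drives graph, activities, label
flips and the split through independent substreams, so datasets are
byte-reproducible.

The default configuration — 300 genes, 5 modules of 20, `p_in` 0.3 / `p_out`
0.01, 10 donors per class with 20 cells each, `effect_size` 2 (a strong
donor effect), the first two modules informative — is the fixture used
throughout the test suite.

What the generator does *not* emulate: dropout/zero inflation beyond
Poisson sampling, batch effects, multiple cell types, varying library-size
distributions, or annotation graphs that disagree with expression modules
(planted modules are graph-aligned by construction). Passing tests on this
fixture therefore demonstrate correct mechanics and recoverability under
idealized conditions, not robustness to the full messiness of real
single-cell data. One visible consequence of the idealization: because
informative genes raise class-1 library sizes, depth normalization induces
compositional shifts that make some background genes significant as
class-0 markers — a realistic artifact that the inclusive preselection
absorbs.

## Numerical choices

* Softmax rows are computed with max-subtraction; results equal the
  mathematical softmax.
* The denominator of $L_c$ is guarded at $10^{-12}$; falling below it raises
  a degenerate-pooling error rather than silently producing huge gradients.
* $L_o$'s gradient at exactly zero loss uses the zero subgradient.
* Binary cross-entropy is computed in logit space
  ($\max(z,0) - zy + \log(1+e^{-|z|})$), never through saturated sigmoids.
* Optimization is full batch: the first-layer weights are $n \times h$, tied
  to the full training-cell feature vector, so minibatching would change the
  architecture. Adam uses classic L2 weight decay added to the gradient.
* Node features use training-split cells only; validation cells are scored
  through the current $S$ and head each epoch. This keeps validation out of
  representation learning. The early-stopping metric is the validation
  *classification* loss by default (the graph terms are cell-independent, so
  adding them would only shift the metric by a training-side quantity);
  `early_stopping_metric = "total"` switches to the full objective.
* Validation improvement means strictly lower than the running best;
  parameters are snapshotted at the best epoch and restored after training,
  and the restored bundle reproduces the recorded best validation loss
  exactly (a regression test asserts this).
* Dropout masks, initialization and the validation split all derive from the
  single config seed, so fits are bit-reproducible.
* Weight matrices initialize from
  $U(-1/\sqrt{\text{fan-in}}, 1/\sqrt{\text{fan-in}})$, the convention of
  the reference deep-learning stack's linear layers.

## Desk-scale training schedule

The shipped defaults (50,000 max epochs, learning rate $10^{-4}$) describe
the reference schedule for real cohorts. The package's own test suite and
examples run the planted-module fixture on a scaled-down schedule — 2,000
full-batch epochs at learning rate $10^{-3}$, with validation-based early
stopping — under which the fixture's informative modules are recovered and
held-out donors classified essentially perfectly. The larger step size
compensates for the 25-fold smaller epoch budget; rates much above
$2\times10^{-3}$ were observed to kill all ReLU units on some
initializations of this architecture (the first optimizer steps drive every
first-layer pre-activation negative, after which gradients vanish), so the
schedule is a genuine stability boundary, not a tuning knob. Problem sizes
used by the tests: $p$ ≈ 130–160 selected genes, $n$ = 180 training cells,
$d$ = 10, $h$ = 64.

## Known limitations

* Hierarchical (multi-layer) pooling and multi-branch multi-cell-type
  integration are out of scope; one model handles one cell type.
* No gene-alias or ortholog mapping when aligning gene lists; matching is
  exact on symbols.
* Prediction scores are not calibrated probabilities; they are ranking
  scores whose donor-level means feed AUC-style evaluation.
* The Mann–Whitney preselection treats cells as independent, which inflates
  significance under donor correlation; this is acceptable for an
  intentionally inclusive prefilter but would not be for inference.
* Functional-category enrichment of the learned sets requires external
  annotation databases and is left to dedicated tools (the GMT export exists
  for exactly that hand-off).
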