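#' Configuration for the synthetic multi-donor single-cell generator
#'
#' Defines a simulated study in which genes are partitioned into
#' graph-coherent modules, per-cell module activities drive expression, and a
#' donor-level binary phenotype propagates to cells with optional label
#' noise. Defaults describe a compact study with a strong donor effect:
#' 300 genes carrying 5 planted modules of 20 genes, module edge
#' probabilities 0.3 within / 0.01 between, 10 donors per class with 20 cells
#' each (half of the donors held out as a test set), and the first two
#' modules driving the phenotype.
#'
#' @param n_genes total genes (modules + background).
#' @param n_modules number of planted modules.
#' @param module_size genes per module; `n_modules * module_size <= n_genes`.
#' @param n_donors_per_class donors per phenotype class (classes 0 and 1).
#' @param cells_per_donor cells per donor.
#' @param p_in,p_out within-/between-module edge probabilities in \[0, 1\].
#' @param effect_size mean shift of informative-module activity in the
#'   positive class (expression units on the log scale); must be >= 0.
#' @param informative_modules indices of the modules that drive the label.
#' @param cell_label_noise fraction of each donor's cells drawing activities
#'   from the opposite class's distribution, emulating cell-level labels
#'   inherited inaccurately from donor-level phenotypes.
#' @param noise_sd per-gene Gaussian noise SD on the log scale.
#' @param depth_scale multiplicative scale applied to expression means before
#'   Poisson sampling (controls sequencing depth).
#' @param train_donor_fraction fraction of donors (per class) tagged `train`;
#'   the rest are `test`.
#' @param seed master RNG seed; graph, activities, noise, label flips and the
#'   donor split use independent substreams derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 300, n_modules = 5, module_size = 20,
                       n_donors_per_class = 10, cells_per_donor = 20,
                       p_in = 0.3, p_out = 0.01, effect_size = 2,
                       informative_modules = c(1L, 2L),
                       cell_label_noise = 0, noise_sd = 0.3,
                       depth_scale = 1, train_donor_fraction = 0.5,
                       seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_modules <- assert_count(n_modules, "n_modules")
  module_size <- assert_count(module_size, "module_size")
  n_donors_per_class <- assert_count(n_donors_per_class, "n_donors_per_class")
  cells_per_donor <- assert_count(cells_per_donor, "cells_per_donor")
  assert_fraction(p_in, "p_in"); assert_fraction(p_out, "p_out")
  assert_fraction(cell_label_noise, "cell_label_noise")
  assert_fraction(train_donor_fraction, "train_donor_fraction")
  if (effect_size < 0) {
    abort("`effect_size` must be >= 0.", class = "scprogram_argument")
  }
  if (n_modules * module_size > n_genes) {
    abort("Module assignment impossible: n_modules * module_size > n_genes.",
          class = "scprogram_argument")
  }
  informative_modules <- as.integer(informative_modules)
  if (length(informative_modules) &&
      (min(informative_modules) < 1L || max(informative_modules) > n_modules)) {
    abort("`informative_modules` out of range.", class = "scprogram_argument")
  }
  structure(
    list(n_genes = n_genes, n_modules = n_modules, module_size = module_size,
         n_donors_per_class = n_donors_per_class,
         cells_per_donor = cells_per_donor, p_in = p_in, p_out = p_out,
         effect_size = effect_size, informative_modules = informative_modules,
         cell_label_noise = cell_label_noise, noise_sd = noise_sd,
         depth_scale = depth_scale,
         train_donor_fraction = train_donor_fraction,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a synthetic multi-donor single-cell dataset
#'
#' Simulates (i) a planted-partition gene graph (edge probability `p_in`
#' within modules, `p_out` otherwise, symmetrized, self-loops added), (ii)
#' per-cell module activities `a ~ Normal(class mean, 1)` where informative
#' modules are shifted by `effect_size` in the positive class, and (iii)
#' counts `Poisson(depth_scale * exp(a + Normal(0, noise_sd)))` per gene.
#' Background genes receive independent per-cell activities and join the
#' graph only through `p_out` edges and their self-loop. A
#' `cell_label_noise` fraction of each donor's cells draws activities from
#' the opposite class's distribution. Donors are split into train/test
#' stratified by class.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_dataset` with `expression`
#'   ([sc_dataset()] of counts, split-tagged; `cell_meta$activity_label`
#'   records which class's activity distribution generated each cell),
#'   `graph` ([gene_graph()]), and `truth` (tibble `gene`, `module`;
#'   background genes have `NA` module).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- substream_seeds(config$seed, 4L)
  p <- config$n_genes
  genes <- sprintf("G%04d", seq_len(p))
  module_of <- rep(NA_integer_, p)
  planted <- config$n_modules * config$module_size
  module_of[seq_len(planted)] <- rep(seq_len(config$n_modules),
                                     each = config$module_size)

  graph <- planted_partition_graph(genes, module_of, config$p_in,
                                   config$p_out, seeds[1L])

  # donors and cell-level design
  n_donors <- 2L * config$n_donors_per_class
  donor_class <- rep(c(0L, 1L), each = config$n_donors_per_class)
  donor_id <- sprintf("D%03d", seq_len(n_donors))
  cells_per <- config$cells_per_donor
  n_cells <- n_donors * cells_per
  cell_donor <- rep(seq_len(n_donors), each = cells_per)
  cell_class <- donor_class[cell_donor]

  # label noise: a fixed-size subset of each donor's cells samples activities
  # from the opposite class
  set.seed(seeds[3L])
  effective_class <- cell_class
  n_flip <- floor(config$cell_label_noise * cells_per)
  if (n_flip > 0L) {
    for (dn in seq_len(n_donors)) {
      cells <- which(cell_donor == dn)
      flip <- sample(cells, n_flip)
      effective_class[flip] <- 1L - effective_class[flip]
    }
  }

  # module activities and expression
  set.seed(seeds[2L])
  act_mean <- matrix(0, n_cells, config$n_modules)
  if (length(config$informative_modules)) {
    act_mean[, config$informative_modules] <-
      config$effect_size * effective_class
  }
  activity <- act_mean + matrix(rnorm(n_cells * config$n_modules),
                                n_cells, config$n_modules)
  log_mean <- matrix(0, n_cells, p)
  if (planted > 0L) {
    log_mean[, seq_len(planted)] <- activity[, module_of[seq_len(planted)]]
  }
  if (planted < p) {
    n_bg <- p - planted
    log_mean[, (planted + 1L):p] <- matrix(rnorm(n_cells * n_bg),
                                           n_cells, n_bg)
  }
  lambda <- config$depth_scale *
    exp(log_mean + matrix(rnorm(n_cells * p, sd = config$noise_sd), n_cells, p))
  counts <- matrix(rpois(n_cells * p, lambda), n_cells, p)
  zero_cells <- which(rowSums(counts) == 0L)
  for (i in zero_cells) {
    # guarantee positive per-cell totals without re-drawing the whole cell
    counts[i, which.max(lambda[i, ])] <- 1L
  }

  # donor-level stratified train/test split
  set.seed(seeds[4L])
  split_of_donor <- rep("test", n_donors)
  for (cl in c(0L, 1L)) {
    donors_cl <- which(donor_class == cl)
    n_train <- round(config$train_donor_fraction * length(donors_cl))
    split_of_donor[sample(donors_cl, n_train)] <- "train"
  }

  meta <- tibble(
    cell_id = sprintf("C%05d", seq_len(n_cells)),
    donor_id = donor_id[cell_donor],
    label = cell_class,
    split = split_of_donor[cell_donor],
    # class whose activity distribution actually generated the cell; differs
    # from `label` exactly for the label-noise cells
    activity_label = effective_class
  )
  expression <- sc_dataset(counts, genes, meta, normalized = FALSE)
  structure(
    list(expression = expression, graph = graph,
         truth = tibble(gene = genes, module = module_of),
         config = config),
    class = "synthetic_dataset"
  )
}

# Planted-partition graph: independent Bernoulli edges, p_in within modules,
# p_out otherwise (background genes have no module, so only p_out applies).
planted_partition_graph <- function(genes, module_of, p_in, p_out, seed) {
  p <- length(genes)
  set.seed(seed)
  lo <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  hi <- sequence((p - 1L):1L, from = 2L:p)
  same <- !is.na(module_of[lo]) & !is.na(module_of[hi]) &
    module_of[lo] == module_of[hi]
  prob <- ifelse(same, p_in, p_out)
  present <- runif(length(lo)) < prob
  A <- Matrix::sparseMatrix(i = c(lo[present], hi[present], seq_len(p)),
                            j = c(hi[present], lo[present], seq_len(p)),
                            x = 1, dims = c(p, p))
  gene_graph(A, genes, add_self_loops = FALSE)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  print(x$expression)
  print(x$graph)
  cat(sprintf("  planted modules: %d x %d genes; informative: %s\n",
              x$config$n_modules, x$config$module_size,
              paste(x$config$informative_modules, collapse = ",")))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the expression matrix as MTX plus gene/cell TSVs (via
#' [write_dataset()]), the graph as an edge-list TSV, and the planted truth
#' table as TSV.
#'
#' @param x a `synthetic_dataset`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(x$expression, dir)
  write_edge_list(x$graph, file.path(dir, "graph_edges.tsv"))
  readr::write_tsv(x$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
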