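#' Gene-gene annotation graph
#'
#' Builds the graph object used as the GNN backbone: a symmetric, nonnegative
#' adjacency matrix over an ordered gene universe, with self-connections so
#' every node has positive degree, plus its symmetrically normalized form
#' \eqn{\tilde A = D^{-1/2} A D^{-1/2}} where \eqn{D} is the degree matrix
#' of \eqn{A}.
#'
#' Self-loops are added wherever the diagonal is zero: with weight 1 for
#' binary graphs, or the maximum edge weight for weighted graphs so that
#' self-influence stays comparable to the strongest neighbour.
#'
#' @param A symmetric, nonnegative p x p adjacency (dense or sparse).
#' @param genes character vector of p gene symbols, in matrix order.
#' @param add_self_loops logical; add self-connections where absent.
#'
#' @return An object of class `gene_graph`: list with `genes`, `A` (sparse
#'   symmetric adjacency incl. self-loops), `A_norm`, `deg` (degrees of `A`),
#'   and `deg_norm` (row sums of `A_norm`).
#' @export
gene_graph <- function(A, genes, add_self_loops = TRUE) {
  p <- length(genes)
  if (anyDuplicated(genes)) {
    abort("Duplicate gene symbols in graph universe.", class = "scprogram_argument")
  }
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(A) != p || ncol(A) != p) {
    abort("`A` must be square with one row per gene.", class = "scprogram_argument")
  }
  if (any(A@x < 0) || any(!is.finite(A@x))) {
    abort("Adjacency entries must be finite and nonnegative.",
          class = "scprogram_argument")
  }
  if (!Matrix::isSymmetric(A, tol = 1e-10)) {
    abort("Adjacency must be symmetric.", class = "scprogram_argument")
  }
  if (add_self_loops) {
    d <- Matrix::diag(A)
    if (any(d == 0)) {
      off <- A
      Matrix::diag(off) <- 0
      w <- if (length(off@x) && any(off@x != 1)) max(off@x) else 1
      Matrix::diag(A) <- ifelse(d == 0, w, d)
    }
  }
  if (any(Matrix::diag(A) <= 0)) {
    abort("Every node needs a positive self-connection.",
          class = "scprogram_argument")
  }
  norm <- normalize_adjacency(A)
  structure(
    list(genes = as.character(genes), A = A, A_norm = norm$A_norm,
         deg = norm$deg, deg_norm = norm$deg_norm),
    class = "gene_graph"
  )
}

#' @export
print.gene_graph <- function(x, ...) {
  off <- x$A
  Matrix::diag(off) <- 0
  cat(sprintf("<gene_graph> %d genes, %d edges (excl. self-loops)\n",
              length(x$genes), sum(off@x != 0) / 2))
  invisible(x)
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' Computes \eqn{\tilde A = D^{-1/2} A D^{-1/2}} with \eqn{D} the (weighted)
#' degree matrix of `A`, together with the degree vectors of `A` and of
#' \eqn{\tilde A}.
#'
#' @param A symmetric nonnegative adjacency with strictly positive degrees.
#' @return list with `A_norm`, `deg` (row sums of `A`), `deg_norm` (row sums
#'   of `A_norm`, the diagonal of \eqn{\tilde D}).
#' @export
normalize_adjacency <- function(A) {
  deg <- Matrix::rowSums(A)
  if (any(deg <= 0)) {
    abort("Zero-degree node encountered; add self-connections first.",
          class = "scprogram_degenerate")
  }
  inv_sqrt <- 1 / sqrt(deg)
  A_norm <- Matrix::Diagonal(x = inv_sqrt) %*% A %*% Matrix::Diagonal(x = inv_sqrt)
  A_norm <- methods::as(A_norm, "CsparseMatrix")
  list(A_norm = A_norm, deg = deg, deg_norm = Matrix::rowSums(A_norm))
}

#' Build a gene graph from a BioGRID TAB3 file
#'
#' Reads a BioGRID TAB3 interaction table (gzip-transparent) and places an
#' unweighted edge between two distinct genes of `gene_universe` whenever any
#' interaction between their proteins/isoforms is recorded; duplicate records
#' and reciprocal orientations collapse to a single gene-level edge. Gene
#' symbols are matched case-sensitively after trimming whitespace, against
#' the two "Official Symbol" columns. Universe genes absent from the file
#' become isolated nodes carrying only their self-connection.
#'
#' @param path TAB3 file (`.txt` or `.txt.gz`).
#' @param gene_universe non-empty character vector of gene symbols defining
#'   the node set and its order.
#' @return a [gene_graph()].
#' @export
graph_from_biogrid <- function(path, gene_universe) {
  if (!length(gene_universe)) {
    abort("`gene_universe` must be non-empty.", class = "scprogram_argument")
  }
  tab <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort(sprintf("Cannot parse '%s' as BioGRID TAB3: %s",
                                      path, conditionMessage(e)),
                              class = "scprogram_format")
  )
  col_a <- grep("^Official Symbol Interactor A$", names(tab), value = TRUE)
  col_b <- grep("^Official Symbol Interactor B$", names(tab), value = TRUE)
  if (length(col_a) != 1L || length(col_b) != 1L) {
    abort("File lacks the two 'Official Symbol Interactor' columns expected of TAB3.",
          class = "scprogram_format")
  }
  a <- trimws(tab[[col_a]])
  b <- trimws(tab[[col_b]])
  edges_to_graph(a, b, rep(1, length(a)), trimws(gene_universe))
}

#' Build a gene graph from a generic edge list
#'
#' Accepts a data frame (or TSV path) with two columns of gene symbols and an
#' optional third weight column. Weighted graphs are supported; parallel
#' records collapse by taking the maximum weight.
#'
#' @param x data frame or path to a 2/3-column TSV (`gene_a`, `gene_b`,
#'   optional `weight`); a header is detected by non-numeric third column or
#'   column names.
#' @param gene_universe optional node universe; defaults to all genes seen.
#' @return a [gene_graph()].
#' @export
graph_from_edgelist <- function(x, gene_universe = NULL) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- as.data.frame(x)
  if (ncol(x) < 2L) {
    abort("Edge list needs at least two columns.", class = "scprogram_format")
  }
  a <- trimws(as.character(x[[1L]]))
  b <- trimws(as.character(x[[2L]]))
  w <- if (ncol(x) >= 3L) as.numeric(x[[3L]]) else rep(1, length(a))
  if (is.null(gene_universe)) gene_universe <- sort(unique(c(a, b)))
  edges_to_graph(a, b, w, trimws(gene_universe))
}

# Shared edge-list -> gene_graph assembly: restrict to the universe, drop
# self-pairs, symmetrize, collapse duplicates by max weight, add self-loops.
edges_to_graph <- function(a, b, w, gene_universe) {
  p <- length(gene_universe)
  i <- match(a, gene_universe)
  j <- match(b, gene_universe)
  keep <- !is.na(i) & !is.na(j) & i != j & !is.na(w) & w > 0
  i <- i[keep]; j <- j[keep]; w <- w[keep]
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (length(lo)) {
    key <- (lo - 1) * p + hi
    agg <- tapply(w, key, max)
    key <- as.numeric(names(agg))
    lo <- floor((key - 1) / p) + 1
    hi <- key - (lo - 1) * p
    w <- as.numeric(agg)
  }
  A <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                            dims = c(p, p))
  gene_graph(A, gene_universe, add_self_loops = TRUE)
}

#' Randomly rewire a fraction of graph edges
#'
#' Removes a uniformly chosen fraction of the off-diagonal edges and replaces
#' them with an equal number of uniformly chosen previously-absent edges, so
#' the off-diagonal edge count is preserved; the removed edge weights are
#' reassigned to the new edges in random order. Self-loops are untouched and
#' the normalized adjacency is recomputed. Used for graph-sensitivity
#' analyses in which the annotation prior is progressively degraded.
#'
#' @param graph a [gene_graph()].
#' @param fraction fraction of off-diagonal edges to rewire, in \[0, 1\].
#' @param seed RNG seed.
#' @return a new `gene_graph`.
#' @export
perturb_graph <- function(graph, fraction, seed = 1L) {
  assert_fraction(fraction, "fraction")
  A <- graph$A
  p <- nrow(A)
  diag_w <- Matrix::diag(A)
  off <- A
  Matrix::diag(off) <- 0
  off <- Matrix::triu(off)
  sm <- Matrix::summary(off)
  ei <- sm$i; ej <- sm$j; ew <- sm$x
  keep_nz <- ew != 0
  ei <- ei[keep_nz]; ej <- ej[keep_nz]; ew <- ew[keep_nz]
  n_edges <- length(ei)
  n_move <- round(fraction * n_edges)
  if (n_move > 0L) {
    set.seed(as.integer(seed))
    drop_idx <- sample.int(n_edges, n_move)
    # sample replacement pairs from the complement of the retained edge set
    existing <- (pmin(ei, ej) - 1) * p + pmax(ei, ej)
    kept <- existing[-drop_idx]
    new_keys <- sample_absent_pairs(p, kept, n_move)
    moved_w <- ew[drop_idx][sample.int(n_move)]
    ei <- ei[-drop_idx]; ej <- ej[-drop_idx]; ew <- ew[-drop_idx]
    nlo <- floor((new_keys - 1) / p) + 1
    nhi <- new_keys - (nlo - 1) * p
    ei <- c(ei, nlo); ej <- c(ej, nhi); ew <- c(ew, moved_w)
  }
  A_new <- Matrix::sparseMatrix(i = c(ei, ej, seq_len(p)),
                                j = c(ej, ei, seq_len(p)),
                                x = c(ew, ew, diag_w), dims = c(p, p))
  gene_graph(A_new, graph$genes, add_self_loops = FALSE)
}

# Uniformly sample n distinct off-diagonal pairs (as lo-major keys) avoiding
# `taken`; exact enumeration for small universes, rejection sampling otherwise.
sample_absent_pairs <- function(p, taken, n) {
  total <- p * (p - 1) / 2
  if (n > total - length(taken)) {
    abort("Not enough absent pairs to rewire into.", class = "scprogram_argument")
  }
  if (total <= 2e6) {
    lo <- rep(seq_len(p - 1), times = (p - 1):1)
    hi <- sequence((p - 1):1, from = 2:p)
    keys <- (lo - 1) * p + hi
    pool <- setdiff(keys, taken)
    return(sample(pool, n))
  }
  found <- numeric(0)
  avoid <- c(taken, numeric(0))
  while (length(found) < n) {
    i <- sample.int(p, n * 2L, replace = TRUE)
    j <- sample.int(p, n * 2L, replace = TRUE)
    ok <- i != j
    key <- (pmin(i, j)[ok] - 1) * p + pmax(i, j)[ok]
    key <- setdiff(unique(key), avoid)
    found <- c(found, key)
    avoid <- c(avoid, key)
  }
  found[seq_len(n)]
}

#' Write a graph as a 3-column edge-list TSV
#'
#' Off-diagonal edges only (`gene_a`, `gene_b`, `weight`), each undirected
#' edge once. Reading the file back with [graph_from_edgelist()] over the same
#' universe reproduces the graph.
#'
#' @param graph a [gene_graph()].
#' @param path output file.
#' @export
write_edge_list <- function(graph, path) {
  off <- graph$A
  Matrix::diag(off) <- 0
  sm <- Matrix::summary(Matrix::triu(off))
  sm <- sm[sm$x != 0, , drop = FALSE]
  tbl <- tibble(gene_a = graph$genes[sm$i], gene_b = graph$genes[sm$j],
                weight = sm$x)
  readr::write_tsv(tbl, path)
  invisible(path)
}
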