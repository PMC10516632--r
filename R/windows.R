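#' Enumerate (or subsample) prediction targets from a methylation matrix
#'
#' Training and evaluation both traverse observed entries of the matrix;
#' each one becomes a masked target whose state the model must recover.
#' With `fraction < 1` a uniform random subsample without replacement is
#' drawn, which is how large methylomes are trained in practice (a small
#' fraction of sites per epoch already converges).
#'
#' @param matrix A [meth_matrix()].
#' @param fraction Fraction of observed entries to keep, in `(0, 1]`.
#' @param seed Optional integer; when given, sampling is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Data frame with columns `u`, `v`, `state` (one row per target).
#' @export
enumerate_targets <- function(matrix, fraction = 1, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  e <- observed_entries(matrix)
  if (fraction < 1 && nrow(e) > 0) {
    k <- max(1L, round(fraction * nrow(e)))
    idx <- local_seed(seed, sample.int(nrow(e), k))
    e <- e[sort(idx), , drop = FALSE]
    rownames(e) <- NULL
  }
  e
}

#' Extract the locus-aware neighboring subgraph around a target entry
#'
#' The subgraph is the bipartite graph induced by all `N` cells and the `W`
#' loci centered on the target locus, with the target's own edge removed
#' (masked) whether or not it is observed. Geometry is fixed: there are
#' always exactly `N + W` nodes and the target locus sits at window offset
#' `(W + 1) / 2`; window positions that fall off the chromosome end become
#' padding locus nodes with no edges.
#'
#' @param matrix A [meth_matrix()].
#' @param u,v Cell and locus index of the target (1-based).
#' @param W Odd window width (number of locus nodes).
#' @param with_labels Attach cell identifiers and `chrom:pos` locus labels
#'   (used by reporting; skipped on the training fast path).
#' @return A `neighbor_subgraph`: list with `n_cells`, `W`, `edges`
#'   (data frame `i` = cell index, `k` = window offset 1..W, `type` = 0/1),
#'   `target` (`u`, `k`), `locus_cols` (matrix column per offset, `NA` =
#'   padding), and optionally `cells` / `locus_labels`.
#' @export
extract_subgraph <- function(matrix, u, v, W, with_labels = FALSE) {
  if (W %% 2L == 0L) stop("window width W must be odd", call. = FALSE)
  N <- n_cells(matrix)
  P <- n_loci(matrix)
  stopifnot(u >= 1L, u <= N, v >= 1L, v <= P)
  h <- (W - 1L) %/% 2L
  lo <- v - h
  hi <- v + h
  cl <- max(1L, lo)
  ch <- min(P, hi)
  ent <- mm_window_entries(matrix, cl, ch)
  k <- ent$v - lo + 1L
  drop <- ent$u == u & ent$v == v
  edges <- data.frame(i = ent$u[!drop], k = k[!drop], type = ent$state[!drop])
  locus_cols <- lo:hi
  locus_cols[locus_cols < 1L | locus_cols > P] <- NA_integer_
  g <- structure(
    list(n_cells = N, W = as.integer(W), edges = edges,
         target = c(u = as.integer(u), k = h + 1L),
         locus_cols = as.integer(locus_cols)),
    class = "neighbor_subgraph"
  )
  if (with_labels) {
    g$cells <- matrix$cells
    g$locus_labels <- ifelse(
      is.na(locus_cols), NA_character_,
      paste0(matrix$chrom, ":", matrix$positions[pmax(locus_cols, 1L)]))
  }
  g
}

#' @export
print.neighbor_subgraph <- function(x, ...) {
  cat(sprintf(
    "<neighbor_subgraph> %d cells + %d loci, %d edges, target cell %d @ offset %d\n",
    x$n_cells, x$W, nrow(x$edges), x$target[["u"]], x$target[["k"]]))
  invisible(x)
}

#' One-hot node encodings for a neighboring subgraph
#'
#' Three schemes, from most to least informative:
#' * `locus_aware` — every cell shares one code (the abstract cell type of
#'   the dataset) and the W window loci get consecutive positional codes, so
#'   the network can tell relative distance to the target locus. `F = W + 1`.
#' * `role_only` — cells vs loci only (`F = 2`).
#' * `none` — all nodes identical (`F = 1`).
#'
#' Row order is the `N` cells then the `W` loci; each row is one-hot.
#'
#' @param subgraph A `neighbor_subgraph` (or any list with `n_cells`, `W`).
#' @param scheme Encoding name.
#' @return `(N + W) x F` numeric matrix.
#' @export
encode_nodes <- function(subgraph,
                         scheme = c("locus_aware", "role_only", "none")) {
  scheme <- match.arg(scheme)
  encoding_block(subgraph$n_cells, subgraph$W, scheme)
}

# Shared by encode_nodes and the batch forward pass (the block is identical
# for every subgraph of one matrix, so batches reuse a single copy).
encoding_block <- function(N, W, scheme) {
  S <- N + W
  switch(scheme,
    locus_aware = {
      X <- matrix(0, S, W + 1L)
      X[seq_len(N), 1L] <- 1
      X[cbind(N + seq_len(W), 1L + seq_len(W))] <- 1
      X
    },
    role_only = {
      X <- matrix(0, S, 2L)
      X[seq_len(N), 1L] <- 1
      X[N + seq_len(W), 2L] <- 1
      X
    },
    none = matrix(1, S, 1L)
  )
}

#' @rdname encode_nodes
#' @param scheme Encoding name.
#' @return `encoding_dim()`: the feature dimension F of a scheme.
#' @export
encoding_dim <- function(scheme = c("locus_aware", "role_only", "none"), W) {
  scheme <- match.arg(scheme)
  switch(scheme, locus_aware = W + 1L, role_only = 2L, none = 1L)
}

#' Random edge dropout for training regularization
#'
#' Independently removes each edge of the subgraph with probability `rate`,
#' leaving the node set (and hence geometry) unchanged. Applied per subgraph
#' per epoch during training, never at validation or inference. Draws from
#' the caller's RNG stream, so a seeded training loop is reproducible.
#'
#' @param subgraph A `neighbor_subgraph`.
#' @param rate Drop probability in `[0, 1)`.
#' @return The subgraph with a thinned edge list.
#' @export
edge_dropout <- function(subgraph, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || nrow(subgraph$edges) == 0L) return(subgraph)
  keep <- stats::runif(nrow(subgraph$edges)) >= rate
  subgraph$edges <- subgraph$edges[keep, , drop = FALSE]
  subgraph
}

#' Binary Shannon entropy of the states in a window
#'
#' With `p` the fraction of methylated edges among the observed edges of the
#' subgraph, returns `-p log2 p - (1-p) log2 (1-p)`; an edgeless window has
#' entropy 0 by convention. High entropy marks windows where methylated and
#' unmethylated states are mixed — the hard regime for imputation.
#'
#' @param subgraph A `neighbor_subgraph`.
#' @return Entropy in `[0, 1]` (base 2).
#' @export
window_entropy <- function(subgraph) {
  types <- subgraph$edges$type
  binary_entropy(if (length(types)) mean(types) else 0)
}

binary_entropy <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Fraction of unobserved entries inside a window
#'
#' `1 - edges / (N * W)`; padding loci count as unobserved, matching the
#' fixed subgraph geometry.
#'
#' @param subgraph A `neighbor_subgraph`.
#' @return A number in `[0, 1]`.
#' @export
window_sparsity <- function(subgraph) {
  1 - nrow(subgraph$edges) / (subgraph$n_cells * subgraph$W)
}
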