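#' Embedding-based report for one neighboring subgraph
#'
#' Runs the message-passing stack in evaluation mode, then compares rows of
#' the embedding plane by cosine similarity: the target cell against every
#' cell, and the (center) target locus against every window locus. Node
#' indices are mapped back to cell identifiers and `chrom:pos` strings, so
#' the subgraph is fully retrievable. Also reports the model's prediction
#' for the masked state.
#'
#' @param matrix A [meth_matrix()].
#' @param u,v Target cell and locus index (observed or missing).
#' @param checkpoint Trained `gcpg_checkpoint` or `gcpg_model`.
#' @return A `subgraph_report`: `target` (cell label, locus label),
#'   `prediction`, `cell_similarities` (data frame `cell`, `similarity`),
#'   `locus_similarities` (data frame `offset`, `locus`, `similarity`;
#'   `NA` labels mark padding), and `edges` with retrieved labels.
#' @export
subgraph_report <- function(matrix, u, v, checkpoint) {
  model <- as_model(checkpoint)
  g <- extract_subgraph(matrix, u, v, model$config$W, with_labels = TRUE)
  H <- node_representations(g, model)
  N <- g$n_cells
  W <- g$W
  kc <- g$target[["k"]]
  cell_sim <- row_cosine(H[seq_len(N), , drop = FALSE], H[u, ])
  locus_sim <- row_cosine(H[N + seq_len(W), , drop = FALSE], H[N + kc, ])
  structure(
    list(
      target = c(cell = g$cells[u], locus = g$locus_labels[kc]),
      prediction = predict_state(model, g),
      cell_similarities = data.frame(cell = g$cells,
                                     similarity = cell_sim,
                                     is_target = seq_len(N) == u),
      locus_similarities = data.frame(offset = seq_len(W),
                                      locus = g$locus_labels,
                                      similarity = locus_sim,
                                      is_target = seq_len(W) == kc),
      edges = data.frame(cell = g$cells[g$edges$i],
                         locus = g$locus_labels[g$edges$k],
                         type = ifelse(g$edges$type == 1,
                                       "methylated", "unmethylated")),
      subgraph = g),
    class = "subgraph_report")
}

row_cosine <- function(M, ref) {
  nr <- sqrt(rowSums(M^2)) * sqrt(sum(ref^2))
  s <- as.numeric(M %*% ref) / ifelse(nr == 0, NA_real_, nr)
  # exact self-similarity even under rounding
  pmin(pmax(s, -1), 1)
}

#' @export
print.subgraph_report <- function(x, ...) {
  cat(sprintf(
    "<subgraph_report> target %s @ %s: prediction %.4f, %d edges\n",
    x$target[["cell"]], x$target[["locus"]], x$prediction, nrow(x$edges)))
  invisible(x)
}

#' Export a subgraph report as a bipartite graph file
#'
#' Nodes carry their partition (`cell` / `locus`), retrieved label,
#' positional encoding index and cosine similarity to the target; edges
#' carry their methylation type. GraphML and DOT load in standard graph
#' viewers; JSON is a node-link document.
#'
#' @param report A [subgraph_report()].
#' @param path Output file.
#' @param format `"graphml"`, `"dot"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_bipartite <- function(report, path,
                             format = c("graphml", "dot", "json")) {
  format <- match.arg(format)
  g <- report$subgraph
  N <- g$n_cells
  W <- g$W
  node_name <- c(paste0("cell:", g$cells),
                 paste0("locus:", ifelse(is.na(g$locus_labels),
                                         paste0("pad", seq_len(W)),
                                         g$locus_labels)))
  partition <- c(rep("cell", N), rep("locus", W))
  label <- c(g$cells, g$locus_labels)
  encoding <- c(rep(0L, N), seq_len(W))
  similarity <- c(report$cell_similarities$similarity,
                  report$locus_similarities$similarity)
  edges_idx <- cbind(g$edges$i, N + g$edges$k)
  etype <- ifelse(g$edges$type == 1, "methylated", "unmethylated")

  if (format == "json") {
    doc <- list(
      target = as.list(report$target),
      prediction = report$prediction,
      nodes = data.frame(id = node_name, partition = partition,
                         label = label, encoding = encoding,
                         similarity = similarity),
      links = data.frame(source = node_name[edges_idx[, 1]],
                         target = node_name[edges_idx[, 2]],
                         type = etype))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    return(invisible(path))
  }

  ig <- igraph::make_empty_graph(n = N + W, directed = FALSE)
  igraph::V(ig)$name <- node_name
  igraph::V(ig)$partition <- partition
  igraph::V(ig)$label <- ifelse(is.na(label), "", label)
  igraph::V(ig)$encoding <- encoding
  igraph::V(ig)$similarity <- ifelse(is.na(similarity), NaN, similarity)
  if (nrow(edges_idx)) {
    ig <- igraph::add_edges(ig, t(edges_idx), type = etype)
  }
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}

#' Inter-cellular Spearman similarity matrix
#'
#' Entry (a, b) is the Spearman correlation of methylation states over the
#' loci observed in *both* cells. On binary data this behaves like a phi
#' coefficient; pairs with fewer than `min_overlap` shared loci, or with a
#' constant state vector, have no defined correlation and are reported as
#' `NA` rather than fabricated. The diagonal is 1.
#'
#' @param x A [meth_matrix()], a named list of them (loci are pooled), or a
#'   dense numeric cell-by-locus matrix (e.g. observed states merged with
#'   imputed probabilities), where every entry counts as observed.
#' @param min_overlap Minimum number of shared loci per pair.
#' @return Symmetric `N x N` matrix with unit diagonal, cells as dimnames.
#' @export
cell_similarity_matrix <- function(x, min_overlap = 3) {
  if (inherits(x, "meth_matrix")) x <- list(x)
  if (is.list(x)) {
    vals <- do.call(cbind, lapply(x, function(m) {
      v <- as.matrix(m$M)
      v[v == 0] <- NA
      v - 1
    }))
    cells <- x[[1]]$cells
  } else {
    vals <- as.matrix(x)
    cells <- rownames(vals) %||% paste0("cell", seq_len(nrow(vals)))
  }
  N <- nrow(vals)
  if (N < 2) stop("need at least two cells", call. = FALSE)
  sim <- matrix(NA_real_, N, N, dimnames = list(cells, cells))
  diag(sim) <- 1
  for (a in seq_len(N - 1)) {
    for (b in (a + 1):N) {
      ok <- !is.na(vals[a, ]) & !is.na(vals[b, ])
      if (sum(ok) < min_overlap) next
      xa <- vals[a, ok]
      xb <- vals[b, ok]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) next
      s <- stats::cor(xa, xb, method = "spearman")
      sim[a, b] <- s
      sim[b, a] <- s
    }
  }
  sim
}

#' Hierarchical clustering of a cell similarity matrix
#'
#' Average-linkage clustering on the distance `1 - similarity`. Undefined
#' similarities are filled with the mean off-diagonal similarity before
#' clustering (so sparse pairs neither attract nor repel). When cell-type
#' labels are supplied, the tree is cut at the known number of types and
#' the adjusted Rand index against the labels is reported.
#'
#' @param similarity Symmetric matrix from [cell_similarity_matrix()].
#' @param labels Optional vector of true cell types (length N).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `hclust`, `order` (dendrogram leaf order), `newick`
#'   (nested-parenthesis rendering of the dendrogram), and, when labels are
#'   given, `clusters` (the cut) and `ari`.
#' @export
hierarchical_cluster <- function(similarity, labels = NULL,
                                 linkage = "average") {
  if (!isSymmetric(unname(as.matrix(similarity)))) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  sim <- as.matrix(similarity)
  off <- sim[row(sim) != col(sim)]
  fill <- mean(off, na.rm = TRUE)
  if (is.nan(fill)) fill <- 0
  sim[is.na(sim)] <- fill
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc, order = hc$order, newick = hclust_newick(hc))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(sim))
    k <- length(unique(labels))
    out$clusters <- stats::cutree(hc, k = k)
    out$ari <- mclust::adjustedRandIndex(out$clusters, labels)
  }
  out
}

# Minimal Newick rendering of an hclust tree (labels + merge heights on
# internal nodes; the root carries no branch length).
hclust_newick <- function(hc) {
  lab <- hc$labels %||% as.character(seq_along(hc$order))
  render <- function(i, top = FALSE) {
    if (i < 0) return(lab[-i])
    s <- paste0("(", render(hc$merge[i, 1]), ",", render(hc$merge[i, 2]), ")")
    if (top) s else paste0(s, ":", format(hc$height[i], digits = 6))
  }
  paste0(render(nrow(hc$merge), top = TRUE), ";")
}

#' Merge observed states with imputed probabilities into a dense matrix
#'
#' Convenience for downstream clustering: observed entries keep their
#' binary state, imputed entries take the predicted probability, anything
#' else stays `NA`.
#'
#' @param matrix A [meth_matrix()].
#' @param predictions Data frame `u`, `v`, `prob` from [impute_matrix()].
#' @return Dense `N x P` numeric matrix with cells as rownames.
#' @export
merge_imputed <- function(matrix, predictions) {
  out <- as.matrix(matrix$M)
  out[out == 0] <- NA
  out <- out - 1
  if (nrow(predictions)) {
    out[cbind(predictions$u, predictions$v)] <- predictions$prob
  }
  rownames(out) <- matrix$cells
  out
}
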