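#' Network configuration
#'
#' Describes the architecture used to score a masked methylation state from
#' its neighboring subgraph: a stack of relational graph convolution
#' (R-GCN) layers with one learnable transform per edge type (methylated /
#' unmethylated) shared through a small basis, cross-layer concatenation of
#' node features, two convolution + max-pool stages over the resulting
#' node-by-feature plane, and a one-hidden-layer perceptron with a sigmoid
#' output.
#'
#' @param layer_dims Hidden dimension of each message-passing layer. The
#'   default six-layer stack `32, 64, 128, 128, 64, 32` gives a concatenated
#'   embedding of width `D = 448`.
#' @param basis_count Number of shared basis matrices expressing the two
#'   per-relation transforms (default 2, one basis per relation's worth of
#'   capacity).
#' @param activation Elementwise nonlinearity after each message-passing
#'   layer; `"tanh"` only.
#' @param conv_spec Two stages, each `list(filters, kernel = c(h, w),
#'   pool = c(h, w))`; ReLU follows each convolution.
#' @param mlp_hidden Width of the fully connected hidden layer.
#' @param W Odd window width (number of locus nodes per subgraph).
#' @param encoding Node encoding scheme; see [encode_nodes()].
#' @param use_bias Include bias terms in message passing, convolution and
#'   the perceptron.
#' @param directed_relations If `TRUE`, cell-to-locus and locus-to-cell
#'   messages use separate relations (4 instead of 2). The default treats
#'   each typed edge as undirected: it is inserted in both directions under
#'   the same relation weight.
#' @return A `model_config` list.
#' @export
model_config <- function(layer_dims = c(32, 64, 128, 128, 64, 32),
                         basis_count = 2,
                         activation = "tanh",
                         conv_spec = list(
                           list(filters = 16, kernel = c(3, 7), pool = c(2, 4)),
                           list(filters = 32, kernel = c(3, 5), pool = c(2, 4))),
                         mlp_hidden = 128,
                         W = 21,
                         encoding = c("locus_aware", "role_only", "none"),
                         use_bias = TRUE,
                         directed_relations = FALSE) {
  encoding <- match.arg(encoding)
  stopifnot(length(layer_dims) >= 1, all(layer_dims >= 1),
            W %% 2 == 1, basis_count >= 1, length(conv_spec) == 2,
            identical(activation, "tanh"))
  structure(
    list(layer_dims = as.integer(layer_dims),
         basis_count = as.integer(basis_count),
         activation = activation, conv_spec = conv_spec,
         mlp_hidden = as.integer(mlp_hidden), W = as.integer(W),
         encoding = encoding, use_bias = isTRUE(use_bias),
         directed_relations = isTRUE(directed_relations)),
    class = "model_config")
}

# Number of relations seen by the message-passing layers.
n_relations <- function(config) if (config$directed_relations) 4L else 2L

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases. The convolution / perceptron shapes
#' depend on the number of cells `N` (the node axis of the pooled embedding
#' plane is `N + W`), so a model is bound to a dataset's cell count.
#'
#' @param config A [model_config()].
#' @param n_cells Number of cells `N` of the matrices the model will see.
#' @param seed Integer seed for the parameter draw.
#' @return A `gcpg_model`: `config`, `n_cells`, `dims` (derived shapes) and
#'   `params` (nested list of numeric arrays).
#' @export
init_model <- function(config, n_cells, seed = 1) {
  stopifnot(inherits(config, "model_config"), n_cells >= 1)
  S <- n_cells + config$W
  Fin <- encoding_dim(config$encoding, config$W)
  D <- sum(config$layer_dims)
  cs <- config$conv_spec
  shape <- conv_shapes(S, D, cs)
  local_seed(seed, {
    nb <- config$basis_count
    nr <- n_relations(config)
    rgcn <- list()
    din <- Fin
    for (l in seq_along(config$layer_dims)) {
      dout <- config$layer_dims[l]
      V <- array(0, c(din, dout, nb))
      for (b in seq_len(nb)) V[, , b] <- glorot(din, dout)
      rgcn[[l]] <- list(
        V = V,
        a = glorot(nr, nb),
        W0 = glorot(din, dout),
        b = numeric(dout))
      din <- dout
    }
    conv <- lapply(1:2, function(s) {
      k <- cs[[s]]$kernel
      Cin <- if (s == 1) 1L else cs[[1]]$filters
      list(K = glorot(k[1] * k[2] * Cin, cs[[s]]$filters),
           b = numeric(cs[[s]]$filters))
    })
    mlp <- list(W1 = glorot(shape$flat, config$mlp_hidden),
                b1 = numeric(config$mlp_hidden),
                w2 = glorot(config$mlp_hidden, 1L),
                b2 = numeric(1L))
    structure(
      list(config = config, n_cells = as.integer(n_cells),
           dims = shape,
           params = list(rgcn = rgcn, conv = conv, mlp = mlp)),
      class = "gcpg_model")
  })
}

# Derived spatial shapes of the two conv/pool stages over an S x D plane.
conv_shapes <- function(S, D, cs) {
  h <- S; w <- D
  out <- list(S = S, D = D)
  for (s in 1:2) {
    k <- cs[[s]]$kernel; p <- cs[[s]]$pool
    oh <- h - k[1] + 1L; ow <- w - k[2] + 1L
    if (oh < 1 || ow < 1) {
      stop("embedding plane ", h, "x", w,
           " smaller than stage-", s, " kernel", call. = FALSE)
    }
    h <- oh %/% p[1]; w <- ow %/% p[2]
    if (h < 1 || w < 1) {
      stop("stage-", s, " pooling leaves no output", call. = FALSE)
    }
    out[[paste0("conv", s)]] <- c(oh = oh, ow = ow)
    out[[paste0("pool", s)]] <- c(oh = h, ow = w)
  }
  out$flat <- h * w * cs[[2]]$filters
  out
}

#' @export
print.gcpg_model <- function(x, ...) {
  np <- sum(unlist(rapply(x$params, length, how = "list")))
  cat(sprintf(
    "<gcpg_model> N = %d, W = %d, encoding = %s, layers [%s], %d parameters\n",
    x$n_cells, x$config$W, x$config$encoding,
    paste(x$config$layer_dims, collapse = ", "), np))
  invisible(x)
}

#' One relational message-passing layer
#'
#' Computes, for every node `i`,
#' `x_i' = sigma( sum_m sum_{j in N_m(i)} W_m x_j / |N_m(i)| + W_0 x_i + b )`
#' where `m` ranges over the edge types (0 = unmethylated, 1 = methylated),
#' `N_m(i)` are `i`'s neighbors under relation `m`, and each `W_m` is a
#' linear combination of shared basis matrices, `W_m = sum_b a[m, b] V_b`.
#' Edges are undirected: a typed edge contributes to the neighborhood of
#' both endpoints under the same relation. Nodes with no neighbors under a
#' relation simply receive no term for it.
#'
#' This is the reference entry point for a single graph; batched training
#' uses the same arithmetic over block-diagonal adjacency.
#'
#' @param features Numeric `n_nodes x d_in` matrix.
#' @param edges Data frame with columns `i`, `j` (node indices, 1-based) and
#'   `type` (0/1).
#' @param params List with `V` (`d_in x d_out x n_basis` array), `a`
#'   (`n_relations x n_basis`), `W0` (`d_in x d_out`), `b` (length `d_out`).
#' @param activation `"tanh"` (default) or `"identity"`.
#' @return `n_nodes x d_out` matrix of updated node features.
#' @export
rgcn_layer <- function(features, edges, params, activation = "tanh") {
  n <- nrow(features)
  if (ncol(features) != nrow(params$W0)) {
    stop("feature dimension ", ncol(features), " does not match layer input ",
         nrow(params$W0), call. = FALSE)
  }
  A <- relation_adjacency(edges$i, edges$j, edges$type, n)
  Wm <- basis_weights(params)
  Z <- features %*% params$W0
  for (m in seq_along(A)) {
    if (!is.null(A[[m]])) Z <- Z + A[[m]] %*% (features %*% Wm[[m]])
  }
  Z <- as.matrix(Z)
  Z <- Z + rep(params$b, each = n)
  if (identical(activation, "tanh")) tanh(Z) else Z
}

# Materialize the per-relation weights W_m from the basis decomposition.
basis_weights <- function(params) {
  dims <- dim(params$V)
  nb <- dims[3]
  lapply(seq_len(nrow(params$a)), function(m) {
    Wm <- params$a[m, 1] * params$V[, , 1]
    if (nb > 1) for (b in 2:nb) Wm <- Wm + params$a[m, b] * params$V[, , b]
    matrix(Wm, dims[1], dims[2])
  })
}

# Row-normalized sparse adjacency per relation (1/|N_m(i)| aggregation).
# Undirected: every typed edge is inserted in both directions.
relation_adjacency <- function(i, j, type, n_nodes) {
  lapply(0:1, function(m) {
    sel <- type == m
    if (!any(sel)) return(NULL)
    r <- c(i[sel], j[sel])
    cc <- c(j[sel], i[sel])
    deg <- tabulate(r, nbins = n_nodes)
    Matrix::sparseMatrix(i = r, j = cc, x = 1 / deg[r],
                         dims = c(n_nodes, n_nodes))
  })
}

#' Cross-layer node embeddings of one subgraph
#'
#' Runs the full message-passing stack from the one-hot node encodings and
#' concatenates each layer's output per node, giving the
#' `(N + W) x D` embedding plane `H` (`D` = sum of layer widths). Rows are
#' the `N` cells followed by the `W` window loci. Evaluation mode: no
#' dropout, deterministic.
#'
#' @param subgraph A `neighbor_subgraph`.
#' @param model A `gcpg_model` (or checkpoint).
#' @return Numeric `(N + W) x D` matrix.
#' @export
node_representations <- function(subgraph, model) {
  model <- as_model(model)
  fw <- forward_batch(model, list(subgraph), upto = "rgcn")
  fw$H
}

#' Convolutional pooling of an embedding plane
#'
#' Two stages of 2-D convolution + ReLU + max pooling over the node-by-
#' feature plane, then flattening to the graph-level vector `g`. Output
#' length depends only on the configured shapes, never on edge content.
#'
#' @param H `(N + W) x D` embedding matrix (from [node_representations()]).
#' @param model A `gcpg_model`.
#' @return Numeric vector `g`.
#' @export
cnn_pool <- function(H, model) {
  model <- as_model(model)
  d <- model$dims
  if (nrow(H) != d$S || ncol(H) != d$D) {
    stop("H must be ", d$S, " x ", d$D, call. = FALSE)
  }
  cube <- array(H, c(d$S, d$D, 1L))
  st <- conv_forward_stages(model, cube)
  as.numeric(st$Gmat)
}

#' Predict masked methylation states
#'
#' Full forward pass: encode, message-pass, pool, score. Probabilities are
#' strictly inside (0, 1). Batched prediction over a list of subgraphs is
#' numerically equivalent to per-subgraph calls.
#'
#' @param model A `gcpg_model` or checkpoint.
#' @param subgraphs One `neighbor_subgraph` or a list of them (all from
#'   matrices with the model's cell count).
#' @return Numeric vector of probabilities, one per subgraph.
#' @export
predict_state <- function(model, subgraphs) {
  model <- as_model(model)
  if (inherits(subgraphs, "neighbor_subgraph")) subgraphs <- list(subgraphs)
  fw <- forward_batch(model, subgraphs)
  fw$prob
}

# Accept either a model or a checkpoint wherever a model is needed.
as_model <- function(x) {
  if (inherits(x, "gcpg_model")) return(x)
  if (inherits(x, "gcpg_checkpoint")) return(x$model)
  stop("expected a gcpg_model or gcpg_checkpoint", call. = FALSE)
}
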