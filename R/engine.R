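# Batched forward / backward passes. Subgraphs in a batch share the cell
# count N and window width W, so their node blocks stack: message passing
# runs over a block-diagonal sparse adjacency per relation, and the pooled
# embedding planes stack into a cube for the C++ convolution stages.

# Block-diagonal row-normalized adjacency, one sparse matrix per relation.
# Undirected mode: 2 relations (edge types), each edge inserted both ways.
# Directed mode: 4 relations = edge type x direction.
batch_adjacency <- function(subgraphs, N, W, directed = FALSE) {
  S <- N + W
  B <- length(subgraphs)
  ne <- vapply(subgraphs, function(g) nrow(g$edges), integer(1))
  off <- rep((seq_len(B) - 1L) * S, ne)
  i_cell <- unlist(lapply(subgraphs, function(g) g$edges$i), use.names = FALSE)
  k_loc <- unlist(lapply(subgraphs, function(g) g$edges$k), use.names = FALSE)
  type <- unlist(lapply(subgraphs, function(g) g$edges$type), use.names = FALSE)
  cells <- off + i_cell
  loci <- off + N + k_loc
  n_nodes <- B * S
  mk <- function(r, cc) {
    if (!length(r)) return(NULL)
    deg <- tabulate(r, nbins = n_nodes)
    Matrix::sparseMatrix(i = r, j = cc, x = 1 / deg[r],
                         dims = c(n_nodes, n_nodes))
  }
  if (!directed) {
    lapply(0:1, function(m) {
      sel <- type == m
      mk(c(cells[sel], loci[sel]), c(loci[sel], cells[sel]))
    })
  } else {
    out <- list()
    for (m in 0:1) {
      sel <- type == m
      out[[2L * m + 1L]] <- mk(cells[sel], loci[sel])  # locus -> cell message
      out[[2L * m + 2L]] <- mk(loci[sel], cells[sel])  # cell -> locus message
    }
    out
  }
}

# Column ranges of each layer's block inside the concatenated embedding H.
layer_blocks <- function(layer_dims) {
  ends <- cumsum(layer_dims)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

# Full forward pass over a batch of subgraphs.
# upto = "rgcn" stops after concatenation (returns H); "prob" runs to the
# sigmoid head. need_grad keeps the caches required by backward_batch.
forward_batch <- function(model, subgraphs, upto = "prob",
                          need_grad = FALSE) {
  cfg <- model$config
  N <- model$n_cells
  W <- cfg$W
  S <- N + W
  B <- length(subgraphs)
  for (g in subgraphs) {
    if (g$n_cells != N || g$W != W) {
      stop("subgraph geometry (", g$n_cells, " cells, W = ", g$W,
           ") does not match model (", N, ", ", W, ")", call. = FALSE)
    }
  }
  X0blk <- encoding_block(N, W, cfg$encoding)
  X0 <- X0blk[rep.int(seq_len(S), B), , drop = FALSE]
  A <- batch_adjacency(subgraphs, N, W, cfg$directed_relations)

  L <- length(cfg$layer_dims)
  Xs <- vector("list", L + 1L)
  Xs[[1L]] <- X0
  Wms <- vector("list", L)
  nr <- nrow(X0)
  for (l in seq_len(L)) {
    P <- model$params$rgcn[[l]]
    Wm <- basis_weights(P)
    Wms[[l]] <- Wm
    X <- Xs[[l]]
    Z <- X %*% P$W0
    for (m in seq_along(A)) {
      if (!is.null(A[[m]])) Z <- Z + A[[m]] %*% (X %*% Wm[[m]])
    }
    Z <- as.matrix(Z)
    if (cfg$use_bias) Z <- Z + rep(P$b, each = nr)
    Xs[[l + 1L]] <- tanh(Z)
  }
  H <- do.call(cbind, Xs[-1L])
  if (identical(upto, "rgcn")) {
    return(list(H = H, Xs = Xs, A = A, Wms = Wms, B = B))
  }

  cube <- aperm(array(H, c(S, B, ncol(H))), c(1L, 3L, 2L))
  st <- conv_forward_stages(model, cube, need_grad)
  P <- model$params$mlp
  hid <- st$Gmat %*% P$W1
  if (cfg$use_bias) hid <- hid + rep(P$b1, each = B)
  hid_act <- pmax(hid, 0)
  logit <- hid_act %*% P$w2
  if (cfg$use_bias) logit <- logit + P$b2
  prob <- 1 / (1 + exp(-logit))
  out <- list(prob = pmin(pmax(as.numeric(prob), 1e-12), 1 - 1e-12),
              logit = as.numeric(logit))
  if (need_grad) {
    out$cache <- list(Xs = Xs, A = A, Wms = Wms,
                      conv_cache = st$cache, Gmat = st$Gmat,
                      hid_act = hid_act, B = B)
  }
  out
}

conv_spec_vec <- function(cs) {
  c(cs$kernel[1], cs$kernel[2], cs$pool[1], cs$pool[2])
}

conv_forward_stages <- function(model, cube, need_grad = FALSE) {
  cs <- model$config$conv_spec
  pc <- model$params$conv
  bias1 <- if (model$config$use_bias) pc[[1]]$b else numeric(cs[[1]]$filters)
  bias2 <- if (model$config$use_bias) pc[[2]]$b else numeric(cs[[2]]$filters)
  st <- conv_stages_forward(cube, pc[[1]]$K, bias1, conv_spec_vec(cs[[1]]),
                            pc[[2]]$K, bias2, conv_spec_vec(cs[[2]]),
                            need_grad)
  list(Gmat = t(st$Gt), cache = st$cache)
}

# Backward pass; dlogit is the gradient of the loss wrt the pre-sigmoid
# score, one value per batch element. Returns gradients shaped like params.
backward_batch <- function(model, cache, dlogit) {
  cfg <- model$config
  cs <- cfg$conv_spec
  pc <- model$params$conv
  P <- model$params$mlp
  B <- cache$B
  dlogit <- matrix(dlogit, B, 1L)

  g_mlp <- list(
    W1 = NULL, b1 = NULL,
    w2 = crossprod(cache$hid_act, dlogit),
    b2 = sum(dlogit))
  dhid <- dlogit %*% t(P$w2)
  dhid[cache$hid_act <= 0] <- 0
  g_mlp$W1 <- crossprod(cache$Gmat, dhid)
  g_mlp$b1 <- colSums(dhid)
  dGmat <- dhid %*% t(P$W1)

  cb <- conv_stages_backward(cache$conv_cache, t(dGmat),
                             pc[[1]]$K, conv_spec_vec(cs[[1]]),
                             pc[[2]]$K, conv_spec_vec(cs[[2]]))
  g_conv <- list(list(K = cb$dK1, b = cb$dbias1),
                 list(K = cb$dK2, b = cb$dbias2))

  S <- model$dims$S
  D <- model$dims$D
  dH <- matrix(aperm(cb$dH, c(1L, 3L, 2L)), S * B, D)

  Xs <- cache$Xs
  A <- cache$A
  Wms <- cache$Wms
  L <- length(cfg$layer_dims)
  blocks <- layer_blocks(cfg$layer_dims)
  g_rgcn <- vector("list", L)
  carry <- NULL
  for (l in rev(seq_len(L))) {
    Pl <- model$params$rgcn[[l]]
    dXout <- dH[, blocks[[l]], drop = FALSE]
    if (!is.null(carry)) dXout <- dXout + carry
    Xout <- Xs[[l + 1L]]
    dZ <- dXout * (1 - Xout * Xout)
    X <- Xs[[l]]
    gl <- list(V = array(0, dim(Pl$V)), a = Pl$a * 0,
               W0 = crossprod(X, dZ), b = colSums(dZ))
    carry <- dZ %*% t(Pl$W0)
    nb <- dim(Pl$V)[3]
    for (m in seq_along(A)) {
      if (is.null(A[[m]])) next
      U <- as.matrix(Matrix::crossprod(A[[m]], dZ))
      dWm <- crossprod(X, U)
      for (b in seq_len(nb)) {
        gl$V[, , b] <- gl$V[, , b] + Pl$a[m, b] * dWm
        gl$a[m, b] <- gl$a[m, b] + sum(Pl$V[, , b] * dWm)
      }
      carry <- carry + U %*% t(Wms[[l]][[m]])
    }
    g_rgcn[[l]] <- gl
  }
  grads <- list(rgcn = g_rgcn, conv = g_conv, mlp = g_mlp)
  if (!cfg$use_bias) grads <- zero_bias_grads(grads)
  grads
}

zero_bias_grads <- function(grads) {
  for (l in seq_along(grads$rgcn)) grads$rgcn[[l]]$b <- grads$rgcn[[l]]$b * 0
  for (s in 1:2) grads$conv[[s]]$b <- grads$conv[[s]]$b * 0
  grads$mlp$b1 <- grads$mlp$b1 * 0
  grads$mlp$b2 <- 0
  grads
}

#' Binary cross-entropy loss
#'
#' Mean over the masked observed targets of
#' `-[m log(mhat) + (1 - m) log(1 - mhat)]`.
#'
#' @param predictions Probabilities in (0, 1).
#' @param truths Binary states, same length.
#' @return Scalar loss.
#' @export
bce_loss <- function(predictions, truths) {
  if (!length(predictions) || length(predictions) != length(truths)) {
    stop("predictions and truths must be non-empty and of equal length",
         call. = FALSE)
  }
  p <- pmin(pmax(predictions, 1e-12), 1 - 1e-12)
  -mean(truths * log(p) + (1 - truths) * log(1 - p))
}

# ---- Adam ------------------------------------------------------------------

zeros_like <- function(x) if (is.list(x)) lapply(x, zeros_like) else x * 0

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  t <- state$t + 1L
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(rec, p, g, m, v, SIMPLIFY = FALSE)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
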