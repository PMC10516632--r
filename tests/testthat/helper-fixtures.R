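# Shared fixtures and independent oracles.

# Small deterministic matrix: N cells x P loci with a seeded random pattern.
random_matrix <- function(seed, N = 5, P = 50, density = 0.3,
                          chrom = "chr1") {
  withr::with_seed(seed, {
    n_obs <- max(1L, round(N * P * density))
    keys <- sample.int(N * P, n_obs)
    u <- ((keys - 1L) %% N) + 1L
    v <- ((keys - 1L) %/% N) + 1L
    meth_matrix(chrom, sprintf("c%02d", seq_len(N)),
                sort(sample.int(P * 100, P)),
                data.frame(u = u, v = v,
                           state = stats::rbinom(n_obs, 1, 0.5)))
  })
}

# Brute-force dense evaluation of one relational message-passing layer:
# materializes the full per-relation adjacency and normalization matrices
# and loops over nodes. Kept deliberately naive and independent of the
# package's sparse implementation.
dense_rgcn_oracle <- function(features, edges, params,
                              activation = "tanh") {
  n <- nrow(features)
  Wm <- lapply(seq_len(nrow(params$a)), function(m) {
    W <- 0
    for (b in seq_len(dim(params$V)[3])) {
      W <- W + params$a[m, b] * params$V[, , b]
    }
    W
  })
  A <- lapply(0:1, function(m) {
    M <- matrix(0, n, n)
    sel <- which(edges$type == m)
    for (r in sel) {
      M[edges$i[r], edges$j[r]] <- 1
      M[edges$j[r], edges$i[r]] <- 1
    }
    M
  })
  out <- matrix(0, n, ncol(params$W0))
  for (i in seq_len(n)) {
    acc <- as.numeric(features[i, ] %*% params$W0)
    for (m in 1:2) {
      nb <- which(A[[m]][i, ] > 0)
      if (!length(nb)) next
      msg <- 0
      for (j in nb) msg <- msg + as.numeric(features[j, ] %*% Wm[[m]])
      acc <- acc + msg / length(nb)
    }
    out[i, ] <- acc + params$b
  }
  if (identical(activation, "tanh")) tanh(out) else out
}

# Naive R implementation of conv + ReLU + maxpool over one (h x w) plane
# with C input channels (list of matrices), F filters.
r_reference_conv_stage <- function(planes, K, bias, kernel, pool) {
  C <- length(planes)
  h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
  kh <- kernel[1]; kw <- kernel[2]
  oh <- h - kh + 1; ow <- w - kw + 1
  F <- ncol(K)
  conv <- lapply(seq_len(F), function(f) {
    O <- matrix(bias[f], oh, ow)
    for (c in seq_len(C)) {
      for (dx in seq_len(kw)) {
        for (dy in seq_len(kh)) {
          q <- (c - 1) * kh * kw + (dx - 1) * kh + dy
          O <- O + planes[[c]][dy:(dy + oh - 1), dx:(dx + ow - 1)] * K[q, f]
        }
      }
    }
    pmax(O, 0)
  })
  ph <- pool[1]; pw <- pool[2]
  oh2 <- oh %/% ph; ow2 <- ow %/% pw
  lapply(conv, function(O) {
    P <- matrix(0, oh2, ow2)
    for (x2 in seq_len(ow2)) {
      for (y2 in seq_len(oh2)) {
        P[y2, x2] <- max(O[((y2 - 1) * ph + 1):(y2 * ph),
                           ((x2 - 1) * pw + 1):(x2 * pw)])
      }
    }
    P
  })
}

# Full reference pooling path: H plane -> flattened graph vector.
r_reference_cnn_pool <- function(H, model) {
  cs <- model$config$conv_spec
  pc <- model$params$conv
  p1 <- r_reference_conv_stage(list(H), pc[[1]]$K, pc[[1]]$b,
                               cs[[1]]$kernel, cs[[1]]$pool)
  p2 <- r_reference_conv_stage(p1, pc[[2]]$K, pc[[2]]$b,
                               cs[[2]]$kernel, cs[[2]]$pool)
  unlist(lapply(p2, as.numeric), use.names = FALSE)
}

# O(n^2) pairwise-concordance AUROC (0.5 credit for ties).
concordance_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Tiny architecture used wherever a test only needs *a* working network.
tiny_config <- function(W = 5) {
  model_config(layer_dims = c(4, 6),
               conv_spec = list(
                 list(filters = 3, kernel = c(2, 3), pool = c(2, 2)),
                 list(filters = 4, kernel = c(2, 2), pool = c(1, 2))),
               mlp_hidden = 8, W = W)
}

# Mid-size architecture for short end-to-end trainings (seconds, not
# minutes); W = 11 keeps the window inside one methylation region.
small_config <- function(encoding = "locus_aware", W = 11) {
  model_config(layer_dims = c(16, 32, 32),
               conv_spec = list(
                 list(filters = 8, kernel = c(3, 5), pool = c(2, 4)),
                 list(filters = 8, kernel = c(3, 3), pool = c(2, 2))),
               mlp_hidden = 32, W = W, encoding = encoding)
}

small_train_config <- function(seed = 1, max_epochs = 3,
                               train_fraction = 0.3) {
  train_config(batch_size = 32, lr_peak = 2e-3, warmup_steps = 100,
               decay = 0.9, max_epochs = max_epochs,
               train_fraction = train_fraction, seed = seed,
               val_max = 256)
}

# The default simulated fixture, built once per test run.
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_methylome(sim_config())
    cache
  }
})
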