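random_layer_params <- function(seed, d_in, d_out, n_basis = 2) {
  withr::with_seed(seed, {
    list(V = array(stats::rnorm(d_in * d_out * n_basis), c(d_in, d_out, n_basis)),
         a = matrix(stats::rnorm(2 * n_basis), 2, n_basis),
         W0 = matrix(stats::rnorm(d_in * d_out), d_in, d_out),
         b = stats::rnorm(d_out))
  })
}

# Random simple typed graph: unordered node pairs are unique (the bipartite
# methylation graph never carries parallel edges).
random_graph_edges <- function(n_nodes, n_edges) {
  if (n_edges == 0L) {
    return(data.frame(i = integer(), j = integer(), type = integer()))
  }
  ij <- t(replicate(n_edges, sort(sample.int(n_nodes, 2))))
  keep <- !duplicated(paste(ij[, 1], ij[, 2]))
  data.frame(i = ij[keep, 1], j = ij[keep, 2],
             type = stats::rbinom(sum(keep), 1, 0.5))
}

test_that("message passing matches the dense brute-force oracle", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(2:8, 1)
      d_in <- sample(1:4, 1)
      d_out <- sample(1:5, 1)
      edges <- random_graph_edges(n, sample(0:10, 1))
      X <- matrix(stats::rnorm(n * d_in), n, d_in)
    })
    params <- random_layer_params(seed + 100, d_in, d_out)
    got <- rgcn_layer(X, edges, params)
    want <- dense_rgcn_oracle(X, edges, params)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("a single methylated edge aggregates by hand-computed Eq. form", {
  # 1 cell (x = 0.5) -- methylated edge -- 1 locus (x = 0.25); identity
  # transforms: new cell feature = tanh(neighbor + self).
  params <- list(V = array(c(1, 0), c(1, 1, 2)),     # V1 = I, V2 = 0
                 a = matrix(c(0, 1, 0, 0), 2, 2),    # W_unmeth = 0, W_meth = V1
                 W0 = matrix(1, 1, 1), b = 0)
  X <- matrix(c(0.5, 0.25), 2, 1)
  edges <- data.frame(i = 1L, j = 2L, type = 1L)
  out <- rgcn_layer(X, edges, params)
  expect_equal(out[1, 1], tanh(0.25 + 0.5))
  expect_equal(out[2, 1], tanh(0.5 + 0.25))
})

test_that("edgeless graphs reduce to the self-connection", {
  params <- random_layer_params(5, 3, 4)
  X <- matrix(stats::rnorm(6 * 3), 6, 3)
  out <- rgcn_layer(X, data.frame(i = integer(), j = integer(),
                                  type = integer()), params)
  want <- tanh(X %*% params$W0 + rep(params$b, each = 6))
  expect_equal(out, want)
})

test_that("an explicit per-relation weight pair is representable by 2 bases", {
  W_un <- matrix(stats::rnorm(9), 3, 3)
  W_me <- matrix(stats::rnorm(9), 3, 3)
  params <- list(V = array(c(W_un, W_me), c(3, 3, 2)),
                 a = diag(2), W0 = diag(3), b = numeric(3))
  X <- matrix(stats::rnorm(15), 5, 3)
  edges <- random_graph_edges(5, 6)
  got <- rgcn_layer(X, edges, params)
  # direct computation with the explicit weights through the oracle
  want <- dense_rgcn_oracle(X, edges, params)
  expect_equal(got, want)
})

test_that("swapping edge types and relation weights leaves output unchanged", {
  params <- random_layer_params(9, 2, 3)
  swapped <- params
  swapped$a <- params$a[2:1, ]
  X <- matrix(stats::rnorm(12), 6, 2)
  edges <- random_graph_edges(6, 8)
  flipped <- edges
  flipped$type <- 1L - flipped$type
  expect_equal(rgcn_layer(X, edges, params),
               rgcn_layer(X, flipped, swapped))
})

test_that("embedding plane has the concatenated cross-layer shape", {
  m <- random_matrix(21, N = 10, P = 60, density = 0.3)
  mod <- init_model(model_config(), n_cells = 10, seed = 1)
  g <- extract_subgraph(m, 3, 30, 21)
  H <- node_representations(g, mod)
  expect_equal(dim(H), c(31L, 448L))
  expect_equal(448L, sum(c(32L, 64L, 128L, 128L, 64L, 32L)))
  # single-layer model: H is just that layer's output
  mod1 <- init_model(model_config(layer_dims = 8,
                                  conv_spec = tiny_config()$conv_spec,
                                  W = 21), 10, seed = 2)
  expect_equal(ncol(node_representations(g, mod1)), 8L)
})

test_that("cells with identical window patterns share embedding rows", {
  # cells 1 and 2 observe the same loci with the same states
  ent <- data.frame(u = c(1, 1, 2, 2, 3),
                    v = c(2, 4, 2, 4, 3),
                    state = c(1, 0, 1, 0, 1))
  m <- meth_matrix("chr1", c("a", "b", "c"), (1:5) * 10, ent)
  mod <- init_model(tiny_config(W = 5), n_cells = 3, seed = 4)
  g <- extract_subgraph(m, 3, 3, 5)
  H <- node_representations(g, mod)
  expect_equal(H[1, ], H[2, ])
  expect_false(isTRUE(all.equal(H[1, ], H[3, ])))
})

test_that("convolutional pooling matches the naive R reference", {
  cfg <- tiny_config()
  mod <- init_model(cfg, n_cells = 6, seed = 11)
  S <- mod$dims$S; D <- mod$dims$D
  withr::with_seed(31, H <- matrix(stats::rnorm(S * D), S, D))
  g <- cnn_pool(H, mod)
  expect_equal(g, r_reference_cnn_pool(H, mod), tolerance = 1e-12)
  # all-zero plane with zero biases -> all-zero graph vector
  expect_equal(cnn_pool(matrix(0, S, D), mod), rep(0, length(g)))
  # bitwise stability
  expect_identical(cnn_pool(H, mod), cnn_pool(H, mod))
})

test_that("predictions are probabilities and zero head weights give 0.5", {
  m <- random_matrix(33, N = 6, P = 40, density = 0.3)
  mod <- init_model(tiny_config(), n_cells = 6, seed = 5)
  g <- extract_subgraph(m, 2, 20, 5)
  p <- predict_state(mod, g)
  expect_gt(p, 0); expect_lt(p, 1)
  mod0 <- mod
  mod0$params$mlp$w2[] <- 0
  mod0$params$mlp$b2 <- 0
  expect_equal(predict_state(mod0, g), 0.5)
})

test_that("batched prediction equals independent single predictions", {
  m <- random_matrix(34, N = 6, P = 60, density = 0.35)
  mod <- init_model(tiny_config(), n_cells = 6, seed = 6)
  tg <- enumerate_targets(m, fraction = 0.2, seed = 1)
  sgs <- lapply(seq_len(nrow(tg)), function(r) {
    extract_subgraph(m, tg$u[r], tg$v[r], 5)
  })
  pb <- predict_state(mod, sgs)
  ps <- vapply(sgs, function(g) predict_state(mod, g), numeric(1))
  expect_lt(max(abs(pb - ps)), 1e-6)
})

test_that("analytic gradients match central finite differences", {
  m <- random_matrix(35, N = 5, P = 30, density = 0.4)
  mod <- init_model(tiny_config(), n_cells = 5, seed = 7)
  sgs <- lapply(c(5, 12, 20), function(v) extract_subgraph(m, 2, v, 5))
  truth <- c(1, 0, 1)
  lossfn <- function(model) {
    bce_loss(methylgraph:::forward_batch(model, sgs)$prob, truth)
  }
  fw <- methylgraph:::forward_batch(mod, sgs, need_grad = TRUE)
  gr <- methylgraph:::backward_batch(mod, fw$cache,
                                     (fw$prob - truth) / length(truth))
  eps <- 1e-6
  paths <- list(c("rgcn", "1", "V"), c("rgcn", "1", "a"),
                c("rgcn", "2", "W0"), c("rgcn", "2", "b"),
                c("conv", "1", "K"), c("conv", "2", "K"),
                c("mlp", "W1"), c("mlp", "w2"))
  for (path in paths) {
    p <- mod$params; g <- gr
    for (k in path) {
      k2 <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
      p <- p[[k2]]; g <- g[[k2]]
    }
    idx <- withr::with_seed(1, sample(length(p), min(5, length(p))))
    for (i in idx) {
      bump <- function(d) {
        mm <- mod
        ref <- mm$params
        # walk down, modify, walk back up
        modify <- function(node, depth) {
          if (depth > length(path)) {
            node[i] <- node[i] + d
            return(node)
          }
          k <- path[depth]
          k2 <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
          node[[k2]] <- modify(node[[k2]], depth + 1)
          node
        }
        mm$params <- modify(ref, 1)
        mm
      }
      num <- (lossfn(bump(eps)) - lossfn(bump(-eps))) / (2 * eps)
      expect_lt(abs(num - g[i]), 1e-6)
    }
  }
})

test_that("direction-resolved relations run and stay batch-consistent", {
  m <- random_matrix(44, N = 5, P = 40, density = 0.4)
  cfg <- tiny_config()
  cfg$directed_relations <- TRUE
  mod <- init_model(cfg, n_cells = 5, seed = 9)
  expect_equal(nrow(mod$params$rgcn[[1]]$a), 4L)
  sgs <- lapply(c(10, 20, 30), function(v) extract_subgraph(m, 2, v, 5))
  pb <- predict_state(mod, sgs)
  ps <- vapply(sgs, function(g) predict_state(mod, g), numeric(1))
  expect_lt(max(abs(pb - ps)), 1e-6)
  expect_true(all(pb > 0 & pb < 1))
})

test_that("model shape validation rejects oversized kernels", {
  expect_error(init_model(model_config(layer_dims = 4,
    conv_spec = list(list(filters = 2, kernel = c(50, 3), pool = c(1, 1)),
                     list(filters = 2, kernel = c(1, 1), pool = c(1, 1))),
    W = 5), n_cells = 3), "smaller than")
})
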