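#' Training configuration
#'
#' @param batch_size Subgraphs per optimizer step.
#' @param lr_peak Peak learning rate of the Adam schedule.
#' @param warmup_steps Steps over which the learning rate ramps linearly
#'   from 0 to `lr_peak`.
#' @param decay Multiplicative learning-rate factor applied per epoch.
#' @param max_epochs Maximum number of passes over the (sub)sampled
#'   training targets.
#' @param edge_dropout Probability of removing each subgraph edge during
#'   training (regularization; never applied at validation or inference).
#' @param train_fraction Fraction of observed training sites sampled per
#'   epoch, in `(0, 1]`. Large methylomes converge with small fractions, so
#'   this is the main runtime dial.
#' @param seed Integer seed; the whole run (parameter draw, target
#'   sampling, shuffling, dropout) is reproducible from it.
#' @param early_stop_patience Stop after this many epochs without a new
#'   best validation loss.
#' @param val_max Cap on the number of cached validation targets.
#' @param verbose Print an epoch summary line.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32, lr_peak = 1e-3, warmup_steps = 1000,
                         decay = 0.9, max_epochs = 10, edge_dropout = 0.2,
                         train_fraction = 1, seed = 1,
                         early_stop_patience = 5, val_max = 1024,
                         verbose = FALSE) {
  stopifnot(lr_peak > 0, train_fraction > 0, train_fraction <= 1,
            edge_dropout >= 0, edge_dropout < 1, batch_size >= 1,
            max_epochs >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Train an imputation model
#'
#' Minimizes binary cross-entropy over masked observed entries of the
#' training matrices with Adam. Each step samples a batch of targets,
#' extracts and encodes their neighboring subgraphs, applies edge dropout,
#' and updates all parameters. The learning rate warms up linearly and then
#' decays multiplicatively per epoch. After every epoch the loss is
#' measured on a fixed, dropout-free cache of validation subgraphs, and the
#' parameters with the lowest validation loss are returned.
#'
#' @param train_matrices,val_matrices Named lists of [meth_matrix()] objects
#'   (or a single matrix each); all must share the same cell panel.
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @return A `gcpg_checkpoint`: the best model, both configs, the epoch log
#'   (data frame with train/validation losses and learning rate) and the
#'   best epoch index.
#' @export
train_model <- function(train_matrices, val_matrices, config = model_config(),
                        tc = train_config()) {
  train_matrices <- as_matrix_list(train_matrices)
  val_matrices <- as_matrix_list(val_matrices)
  if (!length(train_matrices) || !sum(vapply(train_matrices, n_observed, numeric(1)))) {
    stop("no observed sites in the training matrices", call. = FALSE)
  }
  if (!length(val_matrices) || !sum(vapply(val_matrices, n_observed, numeric(1)))) {
    stop("no observed sites in the validation matrices", call. = FALSE)
  }
  N <- n_cells(train_matrices[[1]])
  for (m in c(train_matrices, val_matrices)) stopifnot(n_cells(m) == N)

  local_seed(tc$seed, {
    model <- init_model(config, N, seed = derive_seed(tc$seed, 1))

    # Fixed validation cache: subsample once, no dropout, fixed order.
    val <- list(subgraphs = list(), states = integer())
    for (vm in val_matrices) {
      tg <- enumerate_targets(vm)
      if (nrow(tg) > tc$val_max %/% length(val_matrices) + 1L) {
        keep <- sort(sample.int(nrow(tg),
                                tc$val_max %/% length(val_matrices) + 1L))
        tg <- tg[keep, , drop = FALSE]
      }
      val$subgraphs <- c(val$subgraphs, lapply(seq_len(nrow(tg)), function(r) {
        extract_subgraph(vm, tg$u[r], tg$v[r], config$W)
      }))
      val$states <- c(val$states, tg$state)
    }

    ast <- adam_init(model$params)
    step <- 0L
    best <- list(loss = Inf, params = model$params, epoch = 0L)
    log <- NULL
    for (epoch in seq_len(tc$max_epochs)) {
      losses <- c()
      n_seen <- 0L
      for (tm in train_matrices) {
        tg <- enumerate_targets(tm, fraction = tc$train_fraction)
        if (!nrow(tg)) next
        perm <- sample.int(nrow(tg))
        starts <- seq(1L, nrow(tg), by = tc$batch_size)
        for (s in starts) {
          rows <- perm[s:min(s + tc$batch_size - 1L, nrow(tg))]
          sgs <- lapply(rows, function(r) {
            edge_dropout(extract_subgraph(tm, tg$u[r], tg$v[r], config$W),
                         tc$edge_dropout)
          })
          m <- tg$state[rows]
          fw <- forward_batch(model, sgs, need_grad = TRUE)
          losses <- c(losses, bce_loss(fw$prob, m))
          n_seen <- n_seen + length(rows)
          grads <- backward_batch(model, fw$cache,
                                  (fw$prob - m) / length(m))
          step <- step + 1L
          lr <- tc$lr_peak * min(step / tc$warmup_steps, 1) *
            tc$decay^(epoch - 1)
          upd <- adam_step(model$params, grads, ast, lr)
          model$params <- upd$params
          ast <- upd$state
        }
      }
      val_loss <- batched_loss(model, val$subgraphs, val$states, tc$batch_size)
      log <- rbind(log, data.frame(
        epoch = epoch, train_loss = mean(losses), val_loss = val_loss,
        lr = lr, n_targets = n_seen))
      if (tc$verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f (lr %.2e, %d targets)",
                        epoch, mean(losses), val_loss, lr, n_seen))
      }
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= tc$early_stop_patience) {
        break
      }
    }
    model$params <- best$params
    structure(
      list(schema_version = 1L, model = model, train_config = tc,
           log = log, best_epoch = best$epoch, best_val_loss = best$loss),
      class = "gcpg_checkpoint")
  })
}

batched_loss <- function(model, subgraphs, states, batch_size) {
  probs <- predict_batched(model, subgraphs, batch_size)
  bce_loss(probs, states)
}

predict_batched <- function(model, subgraphs, batch_size = 64L) {
  if (!length(subgraphs)) return(numeric(0))
  starts <- seq(1L, length(subgraphs), by = batch_size)
  unlist(lapply(starts, function(s) {
    idx <- s:min(s + batch_size - 1L, length(subgraphs))
    forward_batch(model, subgraphs[idx])$prob
  }), use.names = FALSE)
}

as_matrix_list <- function(x) {
  if (inherits(x, "meth_matrix")) {
    out <- list(x)
    names(out) <- x$chrom
    return(out)
  }
  stopifnot(all(vapply(x, inherits, logical(1), "meth_matrix")))
  x
}

#' @export
print.gcpg_checkpoint <- function(x, ...) {
  cat(sprintf(
    "<gcpg_checkpoint> best epoch %d (val loss %.4f), %d epochs logged\n",
    x$best_epoch, x$best_val_loss, nrow(x$log)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries a schema version, both configurations, all
#' parameters and the training log, so imputation and evaluation reload the
#' exact trained model.
#'
#' @param checkpoint A `gcpg_checkpoint`.
#' @param path File path (RDS).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "gcpg_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "gcpg_checkpoint") ||
      !identical(ck$schema_version, 1L)) {
    stop("not a recognized checkpoint file (schema 1)", call. = FALSE)
  }
  ck
}

#' Impute unobserved methylation states
#'
#' Extracts the neighboring subgraph of every requested unobserved entry
#' and scores it with a trained model. Observed entries are never
#' overwritten; requesting one is an error.
#'
#' @param matrix A [meth_matrix()].
#' @param checkpoint A trained `gcpg_checkpoint` (or a `gcpg_model`).
#' @param sites Data frame with columns `u`, `v` of entries to impute;
#'   `NULL` imputes every unobserved entry.
#' @param batch_size Prediction batch size.
#' @return Data frame `u`, `v`, `prob` (probability the entry is
#'   methylated).
#' @export
impute_matrix <- function(matrix, checkpoint, sites = NULL,
                          batch_size = 64L) {
  model <- as_model(checkpoint)
  stopifnot(n_cells(matrix) == model$n_cells)
  if (is.null(sites)) {
    obs <- matrix$M != 0
    miss <- which(!as.matrix(obs), arr.ind = TRUE)
    sites <- data.frame(u = as.integer(miss[, 1]), v = as.integer(miss[, 2]))
  } else {
    if (any(matrix$M[cbind(sites$u, sites$v)] != 0)) {
      stop("requested site is observed; observed entries are never overwritten",
           call. = FALSE)
    }
  }
  if (!nrow(sites)) {
    return(data.frame(u = integer(), v = integer(), prob = numeric()))
  }
  W <- model$config$W
  sgs <- lapply(seq_len(nrow(sites)), function(r) {
    extract_subgraph(matrix, sites$u[r], sites$v[r], W)
  })
  data.frame(u = sites$u, v = sites$v,
             prob = predict_batched(model, sgs, batch_size))
}

#' Evaluate a trained model on held-out matrices
#'
#' Every observed entry of the test matrices is masked, predicted from its
#' neighboring subgraph, and scored against its true state: threshold-free
#' AUROC plus MCC, macro-F1 and balanced accuracy at threshold 0.5.
#' Breakdowns: per cell, per window-entropy bin (with each bin's mean
#' window sparsity), and optionally inside/outside a set of BED intervals.
#'
#' @param matrices A [meth_matrix()] or named list of them.
#' @param checkpoint Trained `gcpg_checkpoint` (or `gcpg_model`).
#' @param entropy_bins Number of equal-width entropy bins on `[0, 1]`.
#' @param region_bed Optional path to a BED file (0-based half-open) for
#'   region stratification.
#' @param fraction Subsample this fraction of test targets (seeded).
#' @param seed Seed for the target subsample.
#' @param batch_size Prediction batch size.
#' @param min_bin_n Bins with fewer targets are flagged low-confidence.
#' @return An `eval_report`: overall metrics, `n_targets`, `per_cell` and
#'   `per_entropy_bin` data frames, optional `per_region`, and the raw
#'   per-target `scores` data frame.
#' @export
evaluate_model <- function(matrices, checkpoint, entropy_bins = 10,
                           region_bed = NULL, fraction = 1, seed = NULL,
                           batch_size = 64L, min_bin_n = 50L) {
  matrices <- as_matrix_list(matrices)
  model <- as_model(checkpoint)
  W <- model$config$W
  res <- NULL
  for (nm in names(matrices)) {
    mat <- matrices[[nm]]
    stopifnot(n_cells(mat) == model$n_cells)
    tg <- enumerate_targets(mat, fraction = fraction,
                            seed = if (is.null(seed)) NULL
                                   else derive_seed(seed, match(nm, names(matrices))))
    if (!nrow(tg)) next
    sgs <- lapply(seq_len(nrow(tg)), function(r) {
      extract_subgraph(mat, tg$u[r], tg$v[r], W)
    })
    res <- rbind(res, data.frame(
      chrom = mat$chrom, cell = mat$cells[tg$u], u = tg$u,
      pos = mat$positions[tg$v], state = tg$state,
      prob = predict_batched(model, sgs, batch_size),
      entropy = vapply(sgs, window_entropy, numeric(1)),
      wsparsity = vapply(sgs, window_sparsity, numeric(1))))
  }
  if (is.null(res)) stop("no observed test targets", call. = FALSE)

  overall <- stratum_metrics(res$prob, res$state)
  per_cell <- do.call(rbind, lapply(split(res, res$cell), function(d) {
    cbind(data.frame(cell = d$cell[1]), stratum_metrics(d$prob, d$state))
  }))
  rownames(per_cell) <- NULL

  bin <- pmin(floor(res$entropy * entropy_bins) + 1L, entropy_bins)
  per_bin <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    d <- res[bin == b, , drop = FALSE]
    cbind(data.frame(bin = b,
                     entropy_lo = (b - 1) / entropy_bins,
                     entropy_hi = b / entropy_bins),
          stratum_metrics(d$prob, d$state),
          data.frame(mean_sparsity = mean(d$wsparsity)))
  }))
  per_bin$low_confidence <- per_bin$n < min_bin_n

  out <- list(auroc = overall$auroc, mcc = overall$mcc,
              macro_f1 = overall$macro_f1,
              balanced_accuracy = overall$balanced_accuracy,
              bce = overall$bce, n_targets = nrow(res),
              per_cell = per_cell, per_entropy_bin = per_bin,
              scores = res)
  if (!is.null(region_bed)) {
    inside <- in_bed_regions(res$chrom, res$pos, region_bed)
    out$per_region <- do.call(rbind, lapply(c(TRUE, FALSE), function(w) {
      d <- res[inside == w, , drop = FALSE]
      if (!nrow(d)) return(NULL)
      cbind(data.frame(stratum = if (w) "in_regions" else "outside"),
            stratum_metrics(d$prob, d$state))
    }))
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d targets: AUROC %.4f, MCC %.4f, macro-F1 %.4f, bal.acc %.4f\n",
    x$n_targets, x$auroc, x$mcc, x$macro_f1, x$balanced_accuracy))
  invisible(x)
}

# Membership of 1-based positions in BED intervals (0-based half-open).
in_bed_regions <- function(chrom, pos, bed_path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(bed_path, format = "BED")
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start0 = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr))
  } else {
    raw <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                             colClasses = c("character", "numeric", "numeric"))
    bed <- data.frame(chrom = raw[, 1], start0 = raw[, 2], end = raw[, 3])
  }
  inside <- logical(length(pos))
  for (ch in unique(chrom)) {
    b <- bed[bed$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!nrow(b)) next
    p <- pos[sel]
    hit <- rep(FALSE, length(p))
    for (r in seq_len(nrow(b))) {
      hit <- hit | (p > b$start0[r] & p <= b$end[r])
    }
    inside[sel] <- hit
  }
  inside
}

#' Cell-count subsampling experiment
#'
#' Restricts the dataset to seeded random cell subsets of increasing size,
#' trains and evaluates a model per subset, and reports how imputation
#' quality scales with the number of cells (more cells give the model more
#' inter-cellular evidence per window).
#'
#' @param matrices Named list of [meth_matrix()] objects covering train,
#'   validation and test chromosomes.
#' @param cell_counts Integer vector of subset sizes (each `<= N`).
#' @param seeds Integer vector; each count is run once per seed and
#'   metrics are averaged.
#' @param config A [model_config()].
#' @param tc A [train_config()] (its `seed` is overridden per run).
#' @param split A [chromosome_split()].
#' @param eval_fraction Fraction of test targets scored per run.
#' @return A list with `summary` (data frame: one row per count x seed with
#'   `n_cells`, `seed`, `auroc`, `mcc`, `n_targets`) and `reports` (the
#'   full `eval_report`s).
#' @export
cell_subsampling_experiment <- function(matrices, cell_counts, seeds = 1L,
                                        config = model_config(),
                                        tc = train_config(),
                                        split = chromosome_split(),
                                        eval_fraction = 1) {
  matrices <- as_matrix_list(matrices)
  N <- n_cells(matrices[[1]])
  if (any(cell_counts > N)) {
    stop("cell count exceeds the ", N, " available cells", call. = FALSE)
  }
  summary <- NULL
  reports <- list()
  for (count in cell_counts) {
    for (seed in seeds) {
      keep <- sort(local_seed(derive_seed(seed, count),
                              sample.int(N, count)))
      sub <- lapply(matrices, subset_cells, cells = keep)
      sp <- split_matrices(sub, split)
      tci <- tc
      tci$seed <- seed
      ck <- train_model(sp$train, sp$val, config, tci)
      rep <- evaluate_model(sp$test, ck, fraction = eval_fraction,
                            seed = derive_seed(seed, count + 1))
      key <- paste0("n", count, "_s", seed)
      reports[[key]] <- rep
      summary <- rbind(summary, data.frame(
        n_cells = count, seed = seed, auroc = rep$auroc, mcc = rep$mcc,
        n_targets = rep$n_targets))
    }
  }
  list(summary = summary, reports = reports)
}
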