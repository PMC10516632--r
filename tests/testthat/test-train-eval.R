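# Short end-to-end trainings on a small simulated methylome. The trainings
# here are deliberately tiny (seconds); deeper learning behavior is covered
# by the acceptance suite.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_methylome(sim_config(
        n_cells = 12, n_loci_per_chrom = 150,
        chroms = c("chr1", "chr2", "chr13"), seed = 3))
    }
    cache
  }
})

test_that("training reduces the loss and checkpoints the best epoch", {
  sp <- split_matrices(small_sim()$observed)
  ck <- train_model(sp$train, sp$val, tiny_config(W = 5),
                    small_train_config(seed = 2, max_epochs = 4,
                                       train_fraction = 1))
  expect_s3_class(ck, "gcpg_checkpoint")
  expect_lt(ck$log$train_loss[nrow(ck$log)], ck$log$train_loss[1])
  expect_equal(ck$best_val_loss, min(ck$log$val_loss))
  expect_equal(ck$log$n_targets[1], n_observed(sp$train$chr1))
})

test_that("training fails cleanly without observed sites", {
  empty <- meth_matrix("chr1", c("a", "b"), c(10, 20),
                       data.frame(u = integer(), v = integer(),
                                  state = integer()))
  sp <- split_matrices(small_sim()$observed)
  expect_error(train_model(list(chr1 = empty), sp$val, tiny_config(W = 5),
                           small_train_config()), "no observed sites")
})

test_that("identical seeds reproduce identical training logs", {
  sp <- split_matrices(small_sim()$observed)
  tc <- small_train_config(seed = 11, max_epochs = 2)
  ck1 <- train_model(sp$train, sp$val, tiny_config(W = 5), tc)
  ck2 <- train_model(sp$train, sp$val, tiny_config(W = 5), tc)
  expect_identical(ck1$log, ck2$log)
  expect_identical(ck1$model$params, ck2$model$params)
})

test_that("site subsampling scales the per-epoch target count", {
  sp <- split_matrices(small_sim()$observed)
  tc_full <- small_train_config(seed = 1, max_epochs = 1,
                                train_fraction = 1)
  tc_sub <- small_train_config(seed = 1, max_epochs = 1,
                               train_fraction = 0.05)
  ck_full <- train_model(sp$train, sp$val, tiny_config(W = 5), tc_full)
  ck_sub <- train_model(sp$train, sp$val, tiny_config(W = 5), tc_sub)
  expect_lt(abs(ck_sub$log$n_targets[1] / ck_full$log$n_targets[1] - 0.05),
            0.01)
})

test_that("imputation covers exactly the unobserved entries", {
  sp <- split_matrices(small_sim()$observed)
  ck <- train_model(sp$train, sp$val, tiny_config(W = 5),
                    small_train_config(seed = 5, max_epochs = 1))
  mat <- sp$test$chr2
  preds <- impute_matrix(mat, ck)
  expect_equal(nrow(preds), n_cells(mat) * n_loci(mat) - n_observed(mat))
  expect_true(all(preds$prob > 0 & preds$prob < 1))
  expect_true(all(mat$M[cbind(preds$u, preds$v)] == 0))
  # repeat imputation from one checkpoint is identical
  some <- preds[1:5, c("u", "v")]
  expect_identical(impute_matrix(mat, ck, sites = some),
                   impute_matrix(mat, ck, sites = some))
  # fully observed matrix -> nothing to impute
  N <- n_cells(mat)
  dense <- meth_matrix("chrZ", mat$cells, c(1, 5),
                       data.frame(u = rep(seq_len(N), 2),
                                  v = rep(1:2, each = N),
                                  state = rep(0:1, N)))
  expect_equal(nrow(impute_matrix(dense, ck)), 0L)
  # observed entries are protected
  obs1 <- observed_entries(mat)[1, ]
  expect_error(impute_matrix(mat, ck, sites = obs1), "observed")
})

test_that("checkpoints round-trip bitwise through save/load", {
  sp <- split_matrices(small_sim()$observed)
  ck <- train_model(sp$train, sp$val, tiny_config(W = 5),
                    small_train_config(seed = 8, max_epochs = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  expect_identical(ck2$model$params, ck$model$params)
  ev1 <- evaluate_model(sp$test, ck, entropy_bins = 5)
  ev2 <- evaluate_model(sp$test, ck2, entropy_bins = 5)
  expect_identical(ev1$auroc, ev2$auroc)
  expect_identical(ev1$scores$prob, ev2$scores$prob)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(), bad)
  expect_error(load_checkpoint(bad), "schema")
})

test_that("evaluation reports overall, per-cell and per-entropy strata", {
  sp <- split_matrices(small_sim()$observed)
  ck <- train_model(sp$train, sp$val, tiny_config(W = 5),
                    small_train_config(seed = 9, max_epochs = 2))
  ev <- evaluate_model(sp$test, ck, entropy_bins = 5)
  expect_s3_class(ev, "eval_report")
  expect_equal(ev$n_targets, n_observed(sp$test$chr2))
  expect_true(ev$auroc >= 0 && ev$auroc <= 1)
  expect_true(ev$mcc >= -1 && ev$mcc <= 1)
  # per-cell covers every cell with at least one target
  cells_with_targets <- unique(observed_entries(sp$test$chr2)$u)
  expect_setequal(ev$per_cell$cell, sp$test$chr2$cells[cells_with_targets])
  expect_true(all(ev$per_entropy_bin$n >= 1))
  expect_true(all(ev$per_entropy_bin$mean_sparsity >= 0 &
                    ev$per_entropy_bin$mean_sparsity <= 1))
  expect_equal(sum(ev$per_entropy_bin$n), ev$n_targets)
})

test_that("region stratification splits targets by BED intervals", {
  sp <- split_matrices(small_sim()$observed)
  ck <- train_model(sp$train, sp$val, tiny_config(W = 5),
                    small_train_config(seed = 10, max_epochs = 1))
  mat <- sp$test$chr2
  bed <- withr::local_tempfile(fileext = ".bed")
  # 0-based half-open interval covering the first half of the positions
  mid <- mat$positions[round(n_loci(mat) / 2)]
  writeLines(sprintf("chr2\t0\t%d", mid), bed)
  ev <- evaluate_model(mat, ck, region_bed = bed)
  expect_setequal(ev$per_region$stratum, c("in_regions", "outside"))
  expect_equal(sum(ev$per_region$n), ev$n_targets)
})

test_that("single-class strata report missing AUROC, not zero", {
  scores <- data.frame(prob = c(0.2, 0.9, 0.7), state = c(1, 1, 1))
  expect_true(is.na(metric_auroc(scores$prob, scores$state)))
})

test_that("cell subsampling restricts the panel and keeps bookkeeping", {
  tr <- small_sim()
  res <- cell_subsampling_experiment(
    tr$observed, cell_counts = c(4, 12), seeds = 1,
    config = tiny_config(W = 5),
    tc = small_train_config(max_epochs = 1))
  expect_equal(res$summary$n_cells, c(4, 12))
  expect_equal(nrow(res$summary), 2L)
  expect_true(all(res$summary$n_targets > 0))
  # count = N uses the full panel: matches a direct train+evaluate
  expect_error(cell_subsampling_experiment(tr$observed, cell_counts = 50,
                                           config = tiny_config(W = 5)),
               "exceeds")
})
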