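#' Synthetic methylome configuration
#'
#' Parameters of the generative model behind [simulate_methylome()]. The
#' simulator reproduces the statistical structure that neighborhood-based
#' imputation exploits in real single-cell bisulfite data:
#' * **bimodal region propensity** — loci are partitioned into contiguous
#'   regions whose methylation propensity is drawn from a two-component
#'   Beta mixture (mostly-methylated vs mostly-unmethylated), giving the
#'   bimodal state distribution and locus-local correlation;
#' * **cell-type block structure** — each cell type flips a random subset
#'   of region modes, so cells of one type share methylation patterns;
#' * **sparsity** — an i.i.d. observation mask hides the target fraction of
#'   entries (real datasets run ~85-99% unobserved), optionally modulated
#'   by per-cell coverage multipliers;
#' * **read sampling** — observed entries are emitted as read counts around
#'   `read_depth` and re-binarized, so the count-rounding path of the
#'   reader is exercised and a small fraction of observed states flip.
#'
#' @param n_cells Number of cells.
#' @param n_cell_types Number of cell types (cells are split into
#'   contiguous equal blocks).
#' @param n_loci_per_chrom Loci per chromosome.
#' @param chroms Chromosome names; the defaults place loci on training
#'   (`chr1`, `chr3`), test (`chr2`) and validation (`chr13`) chromosomes
#'   of the default [chromosome_split()].
#' @param region_length Loci per methylation region.
#' @param p_meth_high,p_meth_low Mean propensity of the methylated and
#'   unmethylated Beta modes (must straddle 0.5).
#' @param beta_conc Concentration of both Beta modes.
#' @param type_flip_prob Probability that a region's mode is inverted in a
#'   given non-reference cell type.
#' @param within_region_noise Per-cell, per-site state flip probability on
#'   top of the region propensity.
#' @param sparsity Target unobserved fraction in `[0, 1)`.
#' @param read_depth Mean total reads per observed site (minimum 1).
#' @param cell_coverage_sd Standard deviation (log scale) of optional
#'   per-cell coverage multipliers; 0 disables them.
#' @param read_error Probability a single read contradicts the true state.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 40, n_cell_types = 2,
                       n_loci_per_chrom = 500,
                       chroms = c("chr1", "chr3", "chr2", "chr13"),
                       region_length = 20,
                       p_meth_high = 0.95, p_meth_low = 0.05, beta_conc = 30,
                       type_flip_prob = 0.2, within_region_noise = 0.02,
                       sparsity = 0.85, read_depth = 4,
                       cell_coverage_sd = 0, read_error = 0.02,
                       seed = 7) {
  stopifnot(sparsity >= 0, sparsity < 1,
            p_meth_high > 0.5, p_meth_low < 0.5,
            region_length >= 1, n_cell_types >= 1)
  if (n_cell_types > n_cells) {
    stop("more cell types than cells", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a sparse single-cell methylome with ground truth
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `full_states` (named list of dense
#'   `N x P` 0/1 matrices, one per chromosome — the complete ground truth),
#'   `observed` (named list of [meth_matrix()] objects after masking and
#'   read sampling), `cell_type_labels` (integer per cell), `cell_ids`,
#'   and `config`.
#' @export
simulate_methylome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  c_ <- config
  local_seed(c_$seed, {
    N <- c_$n_cells
    cell_ids <- sprintf("cell%02d", seq_len(N))
    types <- rep(seq_len(c_$n_cell_types), length.out = N)
    types <- sort(types)
    cov_mult <- if (c_$cell_coverage_sd > 0) {
      exp(stats::rnorm(N, 0, c_$cell_coverage_sd))
    } else {
      rep(1, N)
    }

    full <- list()
    observed <- list()
    for (ch in c_$chroms) {
      P <- c_$n_loci_per_chrom
      positions <- cumsum(sample(30:300, P, replace = TRUE)) + 10000L
      region <- rep(seq_len(ceiling(P / c_$region_length)),
                    each = c_$region_length)[seq_len(P)]
      nR <- max(region)
      mode_high <- stats::runif(nR) < 0.5
      shape <- function(mean) c(mean * c_$beta_conc, (1 - mean) * c_$beta_conc)
      prop <- numeric(nR)
      sh <- shape(c_$p_meth_high)
      sl <- shape(c_$p_meth_low)
      prop[mode_high] <- stats::rbeta(sum(mode_high), sh[1], sh[2])
      prop[!mode_high] <- stats::rbeta(sum(!mode_high), sl[1], sl[2])
      # Region-by-type propensities: type 1 keeps the template; other types
      # mirror a region's propensity with probability type_flip_prob.
      prop_t <- matrix(prop, nR, c_$n_cell_types)
      if (c_$n_cell_types > 1) {
        for (t in 2:c_$n_cell_types) {
          fl <- stats::runif(nR) < c_$type_flip_prob
          prop_t[fl, t] <- 1 - prop_t[fl, t]
        }
      }
      p_mat <- prop_t[region, types, drop = FALSE]  # P x N
      states <- matrix(stats::rbinom(P * N, 1, p_mat), P, N)
      if (c_$within_region_noise > 0) {
        flip <- matrix(stats::runif(P * N) < c_$within_region_noise, P, N)
        states[flip] <- 1L - states[flip]
      }
      states <- t(states)  # N x P
      dimnames(states) <- list(cell_ids, positions)

      p_obs <- pmin((1 - c_$sparsity) * rep(cov_mult, P), 1)
      mask <- matrix(stats::runif(N * P) < p_obs, N, P)
      idx <- which(mask, arr.ind = TRUE)
      total <- 1L + stats::rpois(nrow(idx), max(c_$read_depth - 1, 0))
      p_read <- ifelse(states[idx] == 1L, 1 - c_$read_error, c_$read_error)
      meth <- stats::rbinom(nrow(idx), total, p_read)
      entries <- data.frame(u = as.integer(idx[, 1]), v = as.integer(idx[, 2]),
                            state = binarize(meth, total),
                            meth_count = meth, total_count = total)
      full[[ch]] <- states
      observed[[ch]] <- meth_matrix(ch, cell_ids, positions,
                                    entries[c("u", "v", "state")])
      attr(observed[[ch]], "read_counts") <- entries
    }
    structure(
      list(full_states = full, observed = observed,
           cell_type_labels = types, cell_ids = cell_ids, config = c_),
      class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  sp <- vapply(x$observed, sparsity, numeric(1))
  cat(sprintf(
    "<sim_truth> %d cells (%d types), %d chromosomes x %d loci, sparsity %.3f\n",
    length(x$cell_ids), x$config$n_cell_types, length(x$observed),
    x$config$n_loci_per_chrom, mean(sp)))
  invisible(x)
}

#' Write a simulated methylome as per-cell coverage files
#'
#' Emits one bismark-style coverage file per cell (readable by
#' [read_coverage_file()]) plus a JSON sidecar with the ground-truth states
#' and cell-type labels for scoring.
#'
#' @param truth A `sim_truth` from [simulate_methylome()].
#' @param dir Output directory (created if needed).
#' @return Character vector of coverage file paths, invisibly.
#' @export
write_fixture <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- length(truth$cell_ids)
  per_cell <- vector("list", N)
  for (ch in names(truth$observed)) {
    mat <- truth$observed[[ch]]
    rc <- attr(mat, "read_counts")
    for (u in unique(rc$u)) {
      rows <- rc[rc$u == u, , drop = FALSE]
      per_cell[[u]] <- rbind(per_cell[[u]], data.frame(
        chrom = ch, pos = mat$positions[rows$v],
        meth_count = rows$meth_count, total_count = rows$total_count))
    }
  }
  paths <- character(N)
  for (u in seq_len(N)) {
    path <- file.path(dir, paste0(truth$cell_ids[u], ".cov"))
    df <- per_cell[[u]]
    con <- file(path, open = "wt")
    writeLines("#chrom\tpos\tmeth_count\ttotal_count", con)
    if (!is.null(df)) {
      df <- df[order(df$chrom, df$pos), , drop = FALSE]
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    close(con)
    paths[u] <- path
  }
  sidecar <- list(
    cell_ids = truth$cell_ids,
    cell_type_labels = truth$cell_type_labels,
    full_states = lapply(truth$full_states, function(m) {
      list(positions = as.numeric(colnames(m)),
           states = apply(m, 1, paste0, collapse = ""))
    }))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
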