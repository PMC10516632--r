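#' Sparse binary methylation matrix for one chromosome
#'
#' The central data container: an `N x P` cell-by-locus matrix of binarized
#' CpG methylation states in which most entries are unobserved. Observed
#' entries are the links of an undirected bipartite graph between cell nodes
#' (rows) and locus nodes (columns); the stored state is 1 for methylated and
#' 0 for unmethylated. Internally the matrix is held as a
#' [Matrix::sparseMatrix()] with coded values `state + 1`, so that an explicit
#' unmethylated observation (state 0) is distinguishable from a missing entry.
#'
#' @param chrom Chromosome name (single string).
#' @param cells Character vector of unique cell identifiers (length `N`).
#' @param positions Strictly increasing integer vector of genomic coordinates
#'   (1-based, length `P`).
#' @param entries A data frame with integer columns `u` (cell index, 1-based),
#'   `v` (locus index, 1-based) and `state` (0 or 1), one row per observed
#'   entry. Duplicate `(u, v)` keys are an error.
#'
#' @return An object of class `meth_matrix` with fields `chrom`, `cells`,
#'   `positions` and the coded sparse matrix `M`.
#' @seealso [build_matrices()], [sparsity()], [observed_entries()]
#' @export
meth_matrix <- function(chrom, cells, positions, entries) {
  stopifnot(is.character(cells), length(cells) >= 1L, !anyDuplicated(cells))
  positions <- as.numeric(positions)
  if (length(positions) >= 2L && any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  n <- length(cells)
  p <- length(positions)
  if (nrow(entries)) {
    u <- as.integer(entries$u)
    v <- as.integer(entries$v)
    s <- as.integer(entries$state)
    if (any(u < 1L | u > n) || any(v < 1L | v > p)) {
      stop("entry indices out of range for ", n, " cells x ", p, " loci",
           call. = FALSE)
    }
    if (!all(s %in% c(0L, 1L))) {
      stop("methylation states must be 0 or 1", call. = FALSE)
    }
    if (anyDuplicated(u + n * (v - 1))) {
      stop("duplicate (cell, locus) entries", call. = FALSE)
    }
    M <- Matrix::sparseMatrix(i = u, j = v, x = s + 1, dims = c(n, p))
  } else {
    M <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, p))
  }
  structure(
    list(chrom = as.character(chrom), cells = cells, positions = positions,
         M = M),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf(
    "<meth_matrix> %s: %d cells x %d loci, %d observed (sparsity %.4f)\n",
    x$chrom, n_cells(x), n_loci(x), n_observed(x), sparsity(x)))
  invisible(x)
}

#' @rdname meth_matrix
#' @param x A `meth_matrix`.
#' @export
n_cells <- function(x) length(x$cells)

#' @rdname meth_matrix
#' @export
n_loci <- function(x) length(x$positions)

#' @rdname meth_matrix
#' @export
n_observed <- function(x) length(x$M@x)

#' Fraction of unobserved entries
#'
#' `1 - |observed| / (N * P)`: the proportion of cell/locus pairs with no
#' sequencing coverage. Real single-cell bisulfite datasets run roughly
#' 85-99% unobserved.
#'
#' @param x A `meth_matrix`.
#' @return A number in `[0, 1]`.
#' @export
sparsity <- function(x) {
  1 - n_observed(x) / (n_cells(x) * n_loci(x))
}

#' Observed entries as a triplet data frame
#'
#' @param x A `meth_matrix`.
#' @return Data frame with columns `u` (cell index), `v` (locus index) and
#'   `state` (0/1), 1-based indices, ordered column-major (by locus, then
#'   cell).
#' @export
observed_entries <- function(x) {
  Mt <- methods::as(x$M, "TsparseMatrix")
  ord <- order(Mt@j, Mt@i)
  data.frame(u = Mt@i[ord] + 1L, v = Mt@j[ord] + 1L,
             state = as.integer(Mt@x[ord]) - 1L)
}

#' Look up the state of one entry
#'
#' @param x A `meth_matrix`.
#' @param u,v Cell and locus index (1-based).
#' @return 0, 1 or `NA` (unobserved).
#' @export
entry_state <- function(x, u, v) {
  code <- x$M[u, v]
  if (code == 0) NA_integer_ else as.integer(code) - 1L
}

#' @rdname entry_state
#' @export
is_observed <- function(x, u, v) x$M[u, v] != 0

# Coded column slab [v_lo, v_hi]: triplets (u, v, state) within the window.
# Uses the dgCMatrix column pointers directly so window extraction stays O(edges).
mm_window_entries <- function(x, v_lo, v_hi) {
  M <- x$M
  pl <- M@p[v_lo] + 1L
  ph <- M@p[v_hi + 1L]
  if (ph < pl) {
    return(data.frame(u = integer(), v = integer(), state = integer()))
  }
  idx <- pl:ph
  v <- rep.int(v_lo:v_hi, diff(M@p[v_lo:(v_hi + 1L)]))
  data.frame(u = M@i[idx] + 1L, v = v, state = as.integer(M@x[idx]) - 1L)
}

#' Restrict a methylation matrix to a subset of cells
#'
#' Loci are kept as-is (columns may become empty); used by the
#' cell-subsampling experiment.
#'
#' @param x A `meth_matrix`.
#' @param cells Integer indices or cell names to keep.
#' @return A `meth_matrix` over the selected cells.
#' @export
subset_cells <- function(x, cells) {
  if (is.character(cells)) cells <- match(cells, x$cells)
  stopifnot(!anyNA(cells), all(cells >= 1L), all(cells <= n_cells(x)))
  out <- x
  out$cells <- x$cells[cells]
  out$M <- x$M[cells, , drop = FALSE]
  out
}

#' Serialize / deserialize a methylation matrix as sparse triplets
#'
#' Writes the observed entries as a tab-separated triplet file
#' (`cell_id`, `chrom`, `pos`, `state`) plus a JSON sidecar carrying the full
#' cell order and position array, so that empty rows/columns survive the
#' round trip exactly.
#'
#' @param x A `meth_matrix`.
#' @param path Path of the triplet TSV to write; the sidecar is written to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_matrix_triplets <- function(x, path) {
  e <- observed_entries(x)
  df <- data.frame(cell_id = x$cells[e$u], chrom = x$chrom,
                   pos = x$positions[e$v], state = e$state)
  df <- df[order(match(df$cell_id, x$cells), df$pos), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  sidecar <- list(chrom = x$chrom, cells = x$cells, positions = x$positions)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_matrix_triplets
#' @export
read_matrix_triplets <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "numeric", "integer"))
  u <- match(df$cell_id, sidecar$cells)
  v <- match(df$pos, sidecar$positions)
  if (anyNA(u) || anyNA(v)) {
    stop("triplet file refers to cells or positions absent from the sidecar",
         call. = FALSE)
  }
  meth_matrix(sidecar$chrom, sidecar$cells, sidecar$positions,
              data.frame(u = u, v = v, state = df$state))
}
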