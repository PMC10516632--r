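#' Read a per-cell coverage or triplet file
#'
#' Parses tab-separated methylation calls. The `coverage` dialect is
#' bismark-like: `chrom`, `pos` (1-based), `meth_count`, `total_count`, one
#' file per cell. The `triplet` dialect carries an explicit cell column:
#' `cell_id`, `chrom`, `pos`, `state` with `state` already binarized.
#' Lines starting with `#` are skipped; gzipped files are read transparently.
#'
#' @param path Path to the file (optionally `.gz`).
#' @param format `"coverage"` or `"triplet"`.
#' @return A data frame of records; for `coverage` the columns are
#'   `chrom`, `pos`, `meth_count`, `total_count`; for `triplet` they are
#'   `cell_id`, `chrom`, `pos`, `state`. Records need not be sorted.
#' @export
read_coverage_file <- function(path, format = c("coverage", "triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  ncol_expect <- 4L
  if (!length(lines)) {
    return(if (format == "coverage") {
      data.frame(chrom = character(), pos = numeric(),
                 meth_count = integer(), total_count = integer())
    } else {
      data.frame(cell_id = character(), chrom = character(),
                 pos = numeric(), state = integer())
    })
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != ncol_expect)
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: expected %d tab-separated fields, got %d",
                 line_no[bad[1]], path, ncol_expect, lengths(parts)[bad[1]]),
         call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = ncol_expect, byrow = TRUE)
  num <- function(col, name) {
    x <- suppressWarnings(as.numeric(col))
    if (anyNA(x)) {
      stop(sprintf("parse error at line %d of %s: non-numeric %s field",
                   line_no[which(is.na(x))[1]], path, name), call. = FALSE)
    }
    x
  }
  if (format == "coverage") {
    rec <- data.frame(chrom = m[, 1], pos = num(m[, 2], "pos"),
                      meth_count = as.integer(num(m[, 3], "meth_count")),
                      total_count = as.integer(num(m[, 4], "total_count")))
    bad <- which(rec$pos < 1 | rec$total_count < 1 |
                   rec$meth_count < 0 | rec$meth_count > rec$total_count)
    if (length(bad)) {
      stop(sprintf("validation error at line %d of %s: need 1 <= pos, 0 <= meth_count <= total_count, total_count >= 1",
                   line_no[bad[1]], path), call. = FALSE)
    }
  } else {
    rec <- data.frame(cell_id = m[, 1], chrom = m[, 2],
                      pos = num(m[, 3], "pos"),
                      state = as.integer(num(m[, 4], "state")))
    bad <- which(rec$pos < 1 | !(rec$state %in% c(0L, 1L)))
    if (length(bad)) {
      stop(sprintf("validation error at line %d of %s: pos must be >= 1 and state 0/1",
                   line_no[bad[1]], path), call. = FALSE)
    }
  }
  rec
}

#' Binarize a methylation call
#'
#' Rounds the ratio of methylated to total read counts to a hard state:
#' 1 if `meth_count / total_count >= 0.5`, else 0. The half-up tie rule
#' (ratio exactly 0.5 maps to methylated) is a fixed convention for
#' determinism.
#'
#' @param meth_count Non-negative integer vector of methylated read counts.
#' @param total_count Positive integer vector of total read counts.
#' @return Integer vector of 0/1 states.
#' @export
binarize <- function(meth_count, total_count) {
  if (any(total_count < 1)) stop("total_count must be >= 1", call. = FALSE)
  if (any(meth_count < 0) || any(meth_count > total_count)) {
    stop("need 0 <= meth_count <= total_count", call. = FALSE)
  }
  as.integer(meth_count / total_count >= 0.5)
}

#' Assemble per-chromosome methylation matrices from per-cell records
#'
#' Takes one record set per cell (as returned by [read_coverage_file()]) and
#' builds one [meth_matrix()] per chromosome. Locus sets are the sorted union
#' of covered positions across cells. Duplicate records for one
#' (cell, position) are merged by summing read counts before binarization;
#' pre-binarized records (`state` column) may not conflict.
#'
#' @param records_per_cell List of record data frames, one per cell. Each
#'   must have columns `chrom`, `pos` and either `meth_count`/`total_count`
#'   (counts, binarized here) or `state` (already binary).
#' @param cell_ids Character vector of unique cell identifiers, parallel to
#'   `records_per_cell`.
#' @return Named list mapping chromosome name to `meth_matrix`.
#' @export
build_matrices <- function(records_per_cell, cell_ids) {
  stopifnot(length(records_per_cell) == length(cell_ids),
            !anyDuplicated(cell_ids))
  cell_ids <- as.character(cell_ids)
  recs <- do.call(rbind, lapply(seq_along(cell_ids), function(k) {
    r <- records_per_cell[[k]]
    if (!nrow(r)) return(NULL)
    r$.cell <- k
    r
  }))
  if (is.null(recs) || !nrow(recs)) return(structure(list(), names = character()))
  counts_mode <- "meth_count" %in% names(recs)
  out <- list()
  for (ch in unique(recs$chrom)) {
    rc <- recs[recs$chrom == ch, , drop = FALSE]
    positions <- sort(unique(rc$pos))
    v <- match(rc$pos, positions)
    key <- paste0(rc$.cell, "_", v)
    if (counts_mode) {
      meth <- rowsum(rc$meth_count, key, reorder = FALSE)
      tot <- rowsum(rc$total_count, key, reorder = FALSE)
      first <- !duplicated(key)
      entries <- data.frame(u = rc$.cell[first], v = v[first],
                            state = binarize(meth[, 1], tot[, 1]))
    } else {
      dup <- duplicated(key)
      if (any(dup)) {
        agree <- tapply(rc$state, key, function(s) length(unique(s)) == 1L)
        if (!all(agree)) {
          stop("conflicting pre-binarized states for one (cell, position) on ",
               ch, call. = FALSE)
        }
      }
      first <- !duplicated(key)
      entries <- data.frame(u = rc$.cell[first], v = v[first],
                            state = as.integer(rc$state[first]))
    }
    out[[ch]] <- meth_matrix(ch, cell_ids, positions, entries)
  }
  out
}

#' Default chromosome-wise data split
#'
#' Validation loci come from chromosomes 13-19 and test loci from
#' chromosomes 2, 4, 6, 8, 10 and 12; every other chromosome (including
#' non-autosomes) trains. Chromosome names are matched with any `chr`
#' prefix stripped, so `"chr13"` and `"13"` are equivalent.
#'
#' @param train,val,test Character vectors of chromosome names. `train = NULL`
#'   (default) means "everything not in val or test".
#' @return A `chromosome_split` object.
#' @export
chromosome_split <- function(train = NULL,
                             val = as.character(13:19),
                             test = as.character(c(2, 4, 6, 8, 10, 12))) {
  norm <- function(x) if (is.null(x)) NULL else sub("^chr", "", as.character(x))
  s <- list(train = norm(train), val = norm(val), test = norm(test))
  named <- unlist(s[!vapply(s, is.null, logical(1))])
  if (anyDuplicated(named)) {
    stop("chromosome assigned to more than one split: ",
         paste(unique(named[duplicated(named)]), collapse = ", "),
         call. = FALSE)
  }
  structure(s, class = "chromosome_split")
}

#' Partition matrices by chromosome
#'
#' @param matrices Named list of `meth_matrix` objects (names = chromosomes).
#' @param split A [chromosome_split()].
#' @return List with elements `train`, `val`, `test`, each a named list of
#'   matrices. Matrices are passed through unmodified.
#' @export
split_matrices <- function(matrices, split = chromosome_split()) {
  stopifnot(inherits(split, "chromosome_split"))
  bare <- sub("^chr", "", names(matrices))
  grp <- rep("train", length(matrices))
  grp[bare %in% split$val] <- "val"
  grp[bare %in% split$test] <- "test"
  if (!is.null(split$train)) {
    explicit <- bare %in% split$train
    grp[!explicit & grp == "train"] <- "drop"
    grp[explicit] <- "train"
  }
  list(train = matrices[grp == "train"],
       val = matrices[grp == "val"],
       test = matrices[grp == "test"])
}

#' Write observed plus imputed states for one chromosome
#'
#' Emits one tab-separated file per cell under `dir`, columns
#' `chrom`, `pos`, `value`, `source`. Observed entries echo their binary
#' state with source `observed`; supplied predictions appear as
#' probabilities with source `imputed`. Output is sorted by position and is
#' deterministic given its inputs.
#'
#' @param matrix A `meth_matrix`.
#' @param predictions Data frame with columns `u`, `v`, `prob`; keys must be
#'   unobserved entries of `matrix` (an overlap with an observed entry is a
#'   leakage guard error).
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_imputed <- function(matrix, predictions, dir) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (is.null(predictions)) {
    predictions <- data.frame(u = integer(), v = integer(), prob = numeric())
  }
  if (nrow(predictions)) {
    obs <- matrix$M[cbind(predictions$u, predictions$v)] != 0
    if (any(obs)) {
      stop("prediction supplied for an observed entry (cell ",
           predictions$u[which(obs)[1]], ", locus ",
           predictions$v[which(obs)[1]], ")", call. = FALSE)
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- observed_entries(matrix)
  all <- rbind(
    data.frame(u = e$u, v = e$v, value = as.numeric(e$state),
               source = rep("observed", nrow(e))),
    data.frame(u = predictions$u, v = predictions$v,
               value = predictions$prob,
               source = rep("imputed", nrow(predictions)))
  )
  paths <- character(0)
  for (u in sort(unique(all$u))) {
    rows <- all[all$u == u, , drop = FALSE]
    rows <- rows[order(rows$v), , drop = FALSE]
    df <- data.frame(chrom = matrix$chrom, pos = matrix$positions[rows$v],
                     value = rows$value, source = rows$source)
    path <- file.path(dir, paste0(matrix$cells[u], ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
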