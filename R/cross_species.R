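#' Cell-by-peak accessibility container
#'
#' @param matrix Cells x peaks matrix (counts or binary indicators; dense
#'   or \pkg{Matrix} sparse) with cell and peak dimnames.
#' @param peak_class_map data.frame (`peak`, `class`) assigning marker
#'   peaks to a cell type / cluster; every mapped peak must exist among
#'   the matrix columns.
#' @param cell_types Optional named character vector of true per-cell type
#'   annotations (for downsampling and evaluation).
#' @return A list of class `cell_accessibility`.
#' @export
cell_accessibility <- function(matrix, peak_class_map, cell_types = NULL) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop2("accessibility matrix needs cell rownames and peak colnames")
  }
  missing <- setdiff(peak_class_map$peak, colnames(matrix))
  if (length(missing)) {
    stop2("peak(s) in peak_class_map absent from the matrix: ",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  structure(list(matrix = matrix, peak_class_map = peak_class_map,
                 cell_types = cell_types),
            class = "cell_accessibility")
}

#' Downsample cells per annotated type
#'
#' Types with more cells than `cap_per_type` are subsampled to the cap
#' (seeded, uniform); smaller types are untouched.
#'
#' @param access A `cell_accessibility` with `cell_types` set.
#' @param cap_per_type Maximum cells per type (default 1000, the study
#'   setting).
#' @param seed Integer seed.
#' @return The downsampled `cell_accessibility`.
#' @export
downsample_cells <- function(access, cap_per_type = 1000L, seed = 1L) {
  if (is.null(access$cell_types)) {
    stop2("downsample_cells requires per-cell type annotations")
  }
  ann <- access$cell_types[rownames(access$matrix)]
  with_rng_seed(seed, {
    keep <- unlist(lapply(unique(ann), function(tp) {
      cells <- rownames(access$matrix)[ann == tp]
      if (length(cells) > cap_per_type) {
        cells[sample.int(length(cells), cap_per_type)]
      } else {
        cells
      }
    }), use.names = FALSE)
    keep <- rownames(access$matrix)[rownames(access$matrix) %in% keep]
    cell_accessibility(access$matrix[keep, , drop = FALSE],
                       access$peak_class_map,
                       access$cell_types[keep])
  })
}

#' Aggregate per-peak Shapley values into per-cell profiles
#'
#' For every cell that has at least `min_peaks` accessible marker peaks
#' (accessible means entry > 0; for binary matrices, exactly 1), takes the
#' arithmetic mean of motif attributions over its accessible peaks, per
#' motif and model class. By default each marker peak contributes only
#' under its own class's attribution slice. Peaks used in model training
#' or validation can be excluded. Each surviving cell's values are then
#' normalized by the sum of their absolute values across all motifs and
#' classes.
#'
#' @param expl A `bom_explanation` from a multiclass model over the marker
#'   peaks (rows = peaks).
#' @param access A `cell_accessibility`.
#' @param min_peaks Minimum accessible marker peaks per cell (default 20).
#' @param exclude_peaks Peak names to drop before aggregation.
#' @param matched_slice_only When `TRUE` (default) a peak of class `k`
#'   contributes only to the class-`k` slice; otherwise to all slices.
#' @return A list of class `cell_shap_aggregate`: `values` (cells x motifs
#'   x classes array, normalized per cell), `n_peaks` (accessible marker
#'   peaks per surviving cell), `filtered` (per-filter casualty counts),
#'   `cell_types` (annotations of surviving cells, when available).
#' @export
aggregate_cell_shap <- function(expl, access, min_peaks = 20L,
                                exclude_peaks = character(0),
                                matched_slice_only = TRUE) {
  if (length(dim(expl$values)) != 3L) {
    stop2("aggregate_cell_shap expects a per-class (multiclass) explanation")
  }
  map <- access$peak_class_map
  map <- map[!(map$peak %in% exclude_peaks), , drop = FALSE]
  map <- map[map$peak %in% expl$row_ids, , drop = FALSE]
  if (!nrow(map)) stop2("no marker peaks remain after exclusion")
  classes <- expl$class_names
  motifs <- expl$motif_ids

  acc <- access$matrix[, map$peak, drop = FALSE] > 0
  acc <- as.matrix(acc)
  n_acc <- rowSums(acc)
  keep_cells <- n_acc >= min_peaks
  n_dropped <- sum(!keep_cells)
  if (!any(keep_cells)) {
    stop2("no cells survive the filters: ", n_dropped, " of ",
          length(keep_cells), " cells had fewer than ", min_peaks,
          " accessible marker peaks")
  }
  cells <- rownames(access$matrix)[keep_cells]
  acc <- acc[keep_cells, , drop = FALSE]

  vals <- array(0, dim = c(length(cells), length(motifs), length(classes)),
                dimnames = list(cells, motifs, classes))
  peak_rows <- match(map$peak, expl$row_ids)
  for (k in seq_along(classes)) {
    in_slice <- if (matched_slice_only) map$class == classes[k]
                else rep(TRUE, nrow(map))
    if (!any(in_slice)) next
    phi_k <- expl$values[peak_rows[in_slice], , k, drop = FALSE]
    phi_k <- base::matrix(phi_k, ncol = length(motifs))
    a_k <- acc[, in_slice, drop = FALSE]
    npk <- rowSums(a_k)
    agg <- (a_k %*% phi_k)
    nz <- npk > 0
    agg[nz, ] <- agg[nz, , drop = FALSE] / npk[nz]
    agg[!nz, ] <- 0
    vals[, , k] <- agg
  }
  # per-cell normalization by the sum of absolute values
  tot <- apply(abs(vals), 1L, sum)
  for (i in seq_along(cells)) {
    if (tot[i] > 0) vals[i, , ] <- vals[i, , ] / tot[i]
  }
  structure(list(values = vals,
                 n_peaks = stats::setNames(rowSums(acc), cells),
                 filtered = c(min_peaks = n_dropped),
                 cell_types = if (!is.null(access$cell_types))
                   access$cell_types[cells] else NULL),
            class = "cell_shap_aggregate")
}

#' Assign cells to model classes from aggregated attributions
#'
#' For each cell and class, computes the ratio of the sum of positive
#' attributions to the sum of absolute attributions, ratio =
#' sum(max(phi, 0)) / sum(abs(phi)) (0 when the slice is all zero),
#' z-score-transforms each class column across cells (sample SD; raw `r`
#' is kept for a class whose SD is zero), and assigns each cell to the
#' class with the highest score.
#'
#' @param aggregates A `cell_shap_aggregate`.
#' @param use_z Standardize across cells per class before the argmax
#'   (default `TRUE`); with a single cell the raw-ratio argmax is used
#'   with a warning.
#' @return data.frame with one row per cell: per-class `r_*` and `z_*`
#'   columns and `predicted` label.
#' @export
assign_cell_types <- function(aggregates, use_z = TRUE) {
  vals <- aggregates$values
  cells <- dimnames(vals)[[1]]
  classes <- dimnames(vals)[[3]]
  if (length(classes) < 2L) stop2("assignment needs >= 2 classes")
  r <- base::matrix(0, length(cells), length(classes),
                    dimnames = list(cells, classes))
  for (k in seq_along(classes)) {
    sl <- base::matrix(vals[, , k], nrow = length(cells))
    pos <- rowSums(pmax(sl, 0))
    tot <- rowSums(abs(sl))
    r[, k] <- ifelse(tot > 0, pos / tot, 0)
  }
  z <- r
  if (use_z && length(cells) < 2L) {
    warning("single cell: falling back to the raw-ratio argmax")
    use_z <- FALSE
  }
  if (use_z) {
    for (k in seq_along(classes)) {
      s <- stats::sd(r[, k])
      z[, k] <- if (s > 0) (r[, k] - mean(r[, k])) / s else r[, k]
    }
  }
  score <- if (use_z) z else r
  pred <- classes[max.col(score, ties.method = "first")]
  out <- data.frame(cell = cells, stringsAsFactors = FALSE)
  for (k in seq_along(classes)) out[[paste0("r_", classes[k])]] <- r[, k]
  for (k in seq_along(classes)) out[[paste0("z_", classes[k])]] <- z[, k]
  out$predicted <- pred
  out
}

#' Read / write a cell-by-peak accessibility matrix as MTX with sidecars
#'
#' @param prefix Path prefix: `<prefix>.mtx`, `<prefix>.cells`,
#'   `<prefix>.peaks`.
#' @param matrix Cells x peaks matrix.
#' @export
write_accessibility_mtx <- function(matrix, prefix) {
  sp <- Matrix::Matrix(as.matrix(matrix), sparse = TRUE)
  Matrix::writeMM(sp, paste0(prefix, ".mtx"))
  writeLines(rownames(matrix), paste0(prefix, ".cells"))
  writeLines(colnames(matrix), paste0(prefix, ".peaks"))
  invisible(prefix)
}

#' @rdname write_accessibility_mtx
#' @export
read_accessibility_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".cells"))
  colnames(m) <- readLines(paste0(prefix, ".peaks"))
  m
}
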