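#' Build a CRE x motif count matrix from motif hits
#'
#' Rows are candidate CREs, columns are TF binding motifs; entry `[i, j]`
#' is the number of retained hits of motif `j` in CRE `i`. CREs with no
#' hits are kept as all-zero rows, so the matrix total equals the number
#' of hits exactly.
#'
#' @param hits Hit data.frame (after any q-value / overlap filtering).
#' @param cre_ids Character vector of all CRE names (row universe).
#' @param motif_ids Character vector of all motif ids (column universe).
#' @return Integer matrix with `cre_ids` rownames and `motif_ids` colnames.
#' @export
build_count_matrix <- function(hits, cre_ids, motif_ids) {
  if (anyDuplicated(cre_ids) || anyDuplicated(motif_ids)) {
    stop2("cre_ids and motif_ids must be unique")
  }
  m <- matrix(0L, nrow = length(cre_ids), ncol = length(motif_ids),
              dimnames = list(cre_ids, motif_ids))
  if (nrow(hits) > 0L) {
    ri <- match(hits$seq_id, cre_ids)
    ci <- match(hits$motif_id, motif_ids)
    if (anyNA(ri)) {
      stop2("hit sequence id(s) not in cre_ids: ",
            paste(unique(hits$seq_id[is.na(ri)]), collapse = ", "))
    }
    if (anyNA(ci)) {
      stop2("hit motif id(s) not in motif_ids: ",
            paste(unique(hits$motif_id[is.na(ci)]), collapse = ", "))
    }
    tab <- table(factor(ri, levels = seq_along(cre_ids)),
                 factor(ci, levels = seq_along(motif_ids)))
    m <- matrix(as.integer(tab), nrow = length(cre_ids),
                dimnames = list(cre_ids, motif_ids))
  }
  m
}

#' Assemble a class-balanced binary dataset with a stratified background
#'
#' Positives are the rows labeled `positive_class`; the negative
#' (background) set draws equally from every other class. The per-class
#' contribution is `k = floor(n_pos / n_background_classes)`; any
#' remainder is filled round-robin from the largest background classes.
#' If some background class has fewer than `k` rows, `k` drops to the
#' smallest background class size and the positives are downsampled to
#' `k * n_background_classes` so the two sides stay equal (the study's
#' shortage rule). Classes below `min_peaks` positives are refused.
#'
#' @param counts Count matrix from [build_count_matrix()].
#' @param labels data.frame (`name`, `label`); multilabel rows allowed.
#' @param positive_class Target class label.
#' @param min_peaks Minimum unique positives per context (default 100).
#' @param seed Integer seed for all sampling.
#' @return A list of class `balanced_dataset`: `matrix` (rows: positives
#'   then negatives), `y` (1/0), `positive_class`,
#'   `negative_composition` (named vector of per-class row counts),
#'   `seed`.
#' @export
assemble_balanced <- function(counts, labels, positive_class,
                              min_peaks = 100L, seed = 1L) {
  labels <- labels[labels$name %in% rownames(counts), , drop = FALSE]
  pos_names <- unique(labels$name[labels$label == positive_class])
  if (length(pos_names) < min_peaks) {
    stop2("class '", positive_class, "' has ", length(pos_names),
          " unique peaks; a minimum of ", min_peaks, " is required")
  }
  bg_labels <- labels[labels$label != positive_class &
                        !(labels$name %in% pos_names), , drop = FALSE]
  bg_classes <- sort(unique(bg_labels$label))
  if (!length(bg_classes)) stop2("no background classes available")

  bg_pool <- lapply(bg_classes, function(cl) {
    unique(bg_labels$name[bg_labels$label == cl])
  })
  names(bg_pool) <- bg_classes
  sizes <- vapply(bg_pool, length, integer(1))

  n_pos <- length(pos_names)
  n_bg <- length(bg_classes)
  k <- n_pos %/% n_bg
  shortage <- any(sizes < k)
  if (shortage) k <- min(sizes)

  with_rng_seed(seed, {
    take <- stats::setNames(rep(k, n_bg), bg_classes)
    if (!shortage) {
      rem <- n_pos - k * n_bg
      if (rem > 0L) {
        avail <- sizes - take
        ord <- names(sort(sizes[avail > 0L], decreasing = TRUE))
        if (length(ord) >= rem) {
          take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
        } else {
          # not enough spare rows anywhere: fall back to the shortage rule
          shortage <- TRUE
        }
      }
    }
    neg_names <- unlist(lapply(bg_classes, function(cl) {
      pool <- bg_pool[[cl]]
      pool[sample.int(length(pool), take[[cl]])]
    }), use.names = FALSE)
    if (shortage || length(neg_names) < n_pos) {
      pos_keep <- pos_names[sample.int(n_pos, length(neg_names))]
    } else {
      pos_keep <- pos_names
    }
    comp <- take[take > 0L]
    mat <- counts[c(pos_keep, neg_names), , drop = FALSE]
    structure(list(matrix = mat,
                   y = c(rep(1L, length(pos_keep)),
                         rep(0L, length(neg_names))),
                   positive_class = positive_class,
                   negative_composition = comp,
                   seed = seed),
              class = "balanced_dataset")
  })
}

#' Split rows into train/validation/test sets
#'
#' Seeded shuffle with per-label proportional allocation when stratified;
#' fractions default to the study's 60/20/20.
#'
#' @param n Number of rows, or a vector of row ids.
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @param labels Optional per-row labels for stratification.
#' @return List with integer index vectors `train`, `validation`, `test`
#'   (a partition of `seq_len(n)`).
#' @export
split_dataset <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                          labels = NULL) {
  if (length(n) > 1L) n <- length(n)
  if (abs(sum(fractions) - 1) > 1e-9) stop2("fractions must sum to 1")
  if (is.null(labels)) labels <- rep("all", n)
  labels <- as.character(labels)
  parts <- list(train = integer(0), validation = integer(0),
                test = integer(0))
  with_rng_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      m <- length(idx)
      # largest-remainder rounding keeps sizes within one row of exact
      raw <- fractions * m
      sizes <- floor(raw)
      rem <- m - sum(sizes)
      if (rem > 0L) {
        ord <- order(raw - sizes, decreasing = TRUE)
        sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
      }
      cuts <- cumsum(sizes)
      parts$train <- c(parts$train, idx[seq_len(sizes[1])])
      if (sizes[2] > 0L) {
        parts$validation <- c(parts$validation,
                              idx[(cuts[1] + 1L):cuts[2]])
      }
      if (sizes[3] > 0L) {
        parts$test <- c(parts$test, idx[(cuts[2] + 1L):cuts[3]])
      }
    }
  })
  parts <- lapply(parts, sort)
  if (any(vapply(parts, length, integer(1)) == 0L)) {
    stop2("a split partition is empty; provide more rows or larger fractions")
  }
  parts
}

#' Remove a fraction of hit-units from a count matrix by subsampling
#'
#' Removes exactly `floor(remove_fraction * sum(counts))` individual
#' hit-units uniformly at random without replacement across all nonzero
#' cells (the count-perturbation used to probe sensitivity to lenient
#' motif thresholds).
#'
#' @param counts Integer count matrix.
#' @param remove_fraction Proportion of total counts to remove, in [0, 1).
#' @param seed Integer seed.
#' @return Perturbed integer count matrix of the same shape.
#' @export
subsample_counts <- function(counts, remove_fraction, seed = 1L) {
  if (remove_fraction < 0 || remove_fraction >= 1) {
    stop2("remove_fraction must be in [0, 1)")
  }
  total <- sum(counts)
  m <- as.integer(floor(remove_fraction * total))
  if (m == 0L) return(counts)
  with_rng_seed(seed, {
    nz <- which(counts > 0L)
    # each unit belongs to a nonzero cell; sample unit indices 1..total
    bounds <- cumsum(counts[nz])
    units <- sample.int(total, m)
    cell_of_unit <- findInterval(units - 1L, c(0L, bounds),
                                 rightmost.closed = FALSE)
    rem <- tabulate(cell_of_unit, nbins = length(nz))
    out <- counts
    out[nz] <- counts[nz] - as.integer(rem)
    out
  })
}

#' Min-max normalize a vector of motif counts for display
#'
#' `(c - min(c)) / (max(c) - min(c))`; a constant vector maps to zeros.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Vector in [0, 1].
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0L) stop2("empty vector")
  lo <- min(values, na.rm = TRUE)
  hi <- max(values, na.rm = TRUE)
  if (!is.finite(lo)) stop2("no finite values")
  if (hi == lo) return(rep(0, length(values)))
  (values - lo) / (hi - lo)
}

#' Write / read count matrices as TSV or sparse MTX
#'
#' @param counts Integer count matrix.
#' @param file Output path (TSV: rows CREs, columns motifs).
#' @export
write_count_matrix <- function(counts, file) {
  df <- data.frame(cre = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' @rdname write_count_matrix
#' @param prefix Path prefix; writes `<prefix>.mtx`, `<prefix>.rows`,
#'   `<prefix>.cols`.
#' @export
write_count_mtx <- function(counts, prefix) {
  sp <- Matrix::Matrix(counts, sparse = TRUE)
  Matrix::writeMM(sp, paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".rows"))
  writeLines(colnames(counts), paste0(prefix, ".cols"))
  invisible(prefix)
}

#' @rdname write_count_matrix
#' @export
read_count_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  storage.mode(m) <- "integer"
  rownames(m) <- readLines(paste0(prefix, ".rows"))
  colnames(m) <- readLines(paste0(prefix, ".cols"))
  m
}
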