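#' Per-CRE, per-motif Shapley attributions for a trained model
#'
#' Computes tree-exact Shapley values in model-margin (log-odds) units.
#' With `reference = NULL` (default) the booster's built-in TreeSHAP
#' (tree-path-dependent expectations) is used. Supplying a `reference`
#' matrix switches to an interventional explainer implemented in the
#' package: for each reference row the attribution distributes
#' `f(x) - f(z)` over features via the exact Shapley formula applied to
#' the tree ensemble (coalition value = prediction with out-of-coalition
#' features set to the reference), and attributions are averaged over
#' reference rows. Both satisfy the efficiency axiom: the attributions of
#' a row plus the base value sum to its margin prediction.
#'
#' @param model A `bom_model`.
#' @param matrix Count matrix of rows to explain.
#' @param reference Optional reference matrix (e.g. a single all-zero row,
#'   or a subsample of the training matrix) for interventional
#'   attributions.
#' @param strict Error on unknown feature columns.
#' @return An object of class `bom_explanation`: `values` (rows x motifs
#'   matrix, or rows x motifs x classes array for multiclass/multilabel),
#'   `base_values` (per class), `row_ids`, `motif_ids`, `class_names`,
#'   `counts` (the aligned explained matrix).
#' @export
explain <- function(model, matrix, reference = NULL, strict = TRUE) {
  x <- align_features(matrix, model$feature_names, strict)
  mode <- model$config$mode
  feats <- model$feature_names
  classes <- model$class_names

  if (is.null(reference)) {
    if (mode %in% c("binary", "regression")) {
      ctr <- predict(model$ensembles[[1]],
                     xgboost::xgb.DMatrix(x, nthread = model$config$nthread),
                     predcontrib = TRUE)
      vals <- ctr[, feats, drop = FALSE]
      base <- unname(ctr[1, ncol(ctr)])
    } else if (mode == "multiclass") {
      ctr <- predict(model$ensembles[[1]],
                     xgboost::xgb.DMatrix(x, nthread = model$config$nthread),
                     predcontrib = TRUE)
      # rows x classes x (features + 1)
      vals <- aperm(ctr[, , seq_along(feats), drop = FALSE], c(1, 3, 2))
      base <- ctr[1, , dim(ctr)[3]]
      names(base) <- classes
      dimnames(vals) <- list(rownames(x), feats, classes)
    } else {
      per <- lapply(model$ensembles, function(b) {
        predict(b, xgboost::xgb.DMatrix(x, nthread = model$config$nthread),
                predcontrib = TRUE)
      })
      vals <- array(0, dim = c(nrow(x), length(feats), length(classes)),
                    dimnames = list(rownames(x), feats, classes))
      base <- numeric(length(classes))
      for (k in seq_along(per)) {
        vals[, , k] <- per[[k]][, feats, drop = FALSE]
        base[k] <- per[[k]][1, ncol(per[[k]])]
      }
      names(base) <- classes
    }
  } else {
    ref <- align_features(reference, feats, strict)
    if (mode %in% c("binary", "regression")) {
      iv <- interventional_shap(model$ensembles[[1]], x, ref, feats,
                                nthread = model$config$nthread)
      vals <- iv$values
      base <- iv$base
    } else if (mode == "multiclass") {
      iv <- interventional_shap(model$ensembles[[1]], x, ref, feats,
                                num_class = length(classes),
                                nthread = model$config$nthread)
      vals <- iv$values
      dimnames(vals) <- list(rownames(x), feats, classes)
      base <- stats::setNames(iv$base, classes)
    } else {
      vals <- array(0, dim = c(nrow(x), length(feats), length(classes)),
                    dimnames = list(rownames(x), feats, classes))
      base <- numeric(length(classes))
      for (k in seq_along(model$ensembles)) {
        iv <- interventional_shap(model$ensembles[[k]], x, ref, feats,
                                  nthread = model$config$nthread)
        vals[, , k] <- iv$values
        base[k] <- iv$base
      }
      names(base) <- classes
    }
  }
  if (is.matrix(vals)) {
    dimnames(vals) <- list(rownames(x), feats)
  }
  structure(list(values = vals, base_values = base,
                 row_ids = rownames(x), motif_ids = feats,
                 class_names = classes, counts = x, mode = mode),
            class = "bom_explanation")
}

# Parse booster trees into per-leaf path constraints: for every leaf, the
# per-feature half-open interval [lower, upper) that the split path
# imposes. Counts are never missing, so the Missing branch is ignored.
parse_tree_leaves <- function(bst, feature_names) {
  dt <- xgboost::xgb.model.dt.tree(bst)
  dt <- as.data.frame(dt)
  leaf_col <- if ("Gain" %in% names(dt)) "Gain" else "Quality"
  out <- list()
  for (tr in unique(dt$Tree)) {
    nodes <- dt[dt$Tree == tr, , drop = FALSE]
    rownames(nodes) <- nodes$ID
    leaves <- list()
    walk <- function(id, lo, hi) {
      nd <- nodes[id, ]
      if (nd$Feature == "Leaf") {
        leaves[[length(leaves) + 1L]] <<-
          list(value = nd[[leaf_col]],
               feats = names(lo)[is.finite(hi) | lo > -Inf],
               lo = lo, hi = hi)
        return(invisible())
      }
      f <- nd$Feature
      s <- nd$Split
      lo_y <- lo; hi_y <- hi
      hi_y[f] <- min(hi_y[f], s)
      walk(nd$Yes, lo_y, hi_y)
      lo_n <- lo; hi_n <- hi
      lo_n[f] <- max(lo_n[f], s)
      walk(nd$No, lo_n, hi_n)
      invisible()
    }
    lo0 <- stats::setNames(rep(-Inf, length(feature_names)), feature_names)
    hi0 <- stats::setNames(rep(Inf, length(feature_names)), feature_names)
    root <- nodes$ID[nodes$Node == 0]
    walk(root, lo0, hi0)
    out[[length(out) + 1L]] <- leaves
  }
  out
}

# Trees actually used by predict: with early stopping only rounds up to
# best_iteration (0-based) contribute, num_class trees per round.
used_trees <- function(bst, trees, num_class = 1L) {
  b <- best_iteration(bst)
  if (is.na(b)) return(trees)
  trees[seq_len(min(length(trees), (b + 1L) * num_class))]
}

# Double-precision leaf sums: rows x classes matrix of summed leaf values
# for each row of X routed through the parsed trees.
leaf_sums <- function(trees, X, feature_names, num_class = 1L) {
  out <- base::matrix(0, nrow(X), num_class)
  for (ti in seq_along(trees)) {
    cls <- if (num_class > 1L) ((ti - 1L) %% num_class) + 1L else 1L
    for (leaf in trees[[ti]]) {
      pf <- leaf$feats
      if (!length(pf)) {
        out[, cls] <- out[, cls] + leaf$value
        next
      }
      lo <- leaf$lo[pf]
      hi <- leaf$hi[pf]
      for (i in seq_len(nrow(X))) {
        if (all(X[i, pf] >= lo & X[i, pf] < hi)) {
          out[i, cls] <- out[i, cls] + leaf$value
        }
      }
    }
  }
  out
}

# Margin predictions recomputed in double precision from the parsed trees
# (leaf sums plus an intercept calibrated against the booster's margin on
# the first row). Used by the attribution axioms, where float32
# accumulation in the booster's own predict would dominate the tolerance.
margin_double <- function(model, x, strict = TRUE) {
  X <- align_features(x, model$feature_names, strict)
  nc <- if (model$config$mode == "multiclass") length(model$class_names)
        else 1L
  res <- vector("list", length(model$ensembles))
  for (e in seq_along(model$ensembles)) {
    bst <- model$ensembles[[e]]
    trees <- used_trees(bst, parse_tree_leaves(bst, model$feature_names),
                        nc)
    ls <- leaf_sums(trees, X, model$feature_names, nc)
    m1 <- predict(bst, xgboost::xgb.DMatrix(X[1L, , drop = FALSE],
                                            nthread = model$config$nthread),
                  outputmargin = TRUE)
    intercept <- as.numeric(m1) - ls[1L, ]
    res[[e]] <- sweep(ls, 2L, -intercept)
  }
  if (model$config$mode %in% c("binary", "regression")) {
    stats::setNames(res[[1]][, 1L], rownames(X))
  } else if (model$config$mode == "multiclass") {
    out <- res[[1]]
    dimnames(out) <- list(rownames(X), model$class_names)
    out
  } else {
    out <- do.call(cbind, lapply(res, function(m) m[, 1L]))
    dimnames(out) <- list(rownames(X), model$class_names)
    out
  }
}

# Interventional (reference-based) Shapley attributions for one booster.
# For a leaf with value v, reachable feature-sets A (x satisfies, z does
# not) and B (z satisfies, x does not), the induced game contributes
#   phi_j = +v * (a-1)! b! / (a+b)!   for j in A
#   phi_j = -v * a! (b-1)! / (a+b)!   for j in B
# summed over leaves and trees, per reference row, then averaged.
interventional_shap <- function(bst, x, ref, feature_names,
                                num_class = NULL, nthread = 1L) {
  trees <- used_trees(bst, parse_tree_leaves(bst, feature_names),
                      num_class %||% 1L)
  n <- nrow(x)
  f <- length(feature_names)
  nc <- num_class %||% 1L
  vals <- array(0, dim = c(n, f, nc))
  lf <- lgamma(seq_len(2L * f + 1L))  # lf[k] = lgamma(k) = log((k-1)!)
  coef_pos <- function(a, b) exp(lf[a] + lf[b + 1L] - lf[a + b + 1L])
  coef_neg <- function(a, b) exp(lf[a + 1L] + lf[b] - lf[a + b + 1L])

  for (ti in seq_along(trees)) {
    cls <- if (nc > 1L) ((ti - 1L) %% nc) + 1L else 1L
    for (leaf in trees[[ti]]) {
      pf <- leaf$feats
      if (!length(pf)) next
      lo <- leaf$lo[pf]
      hi <- leaf$hi[pf]
      for (r in seq_len(nrow(ref))) {
        z_ok <- ref[r, pf] >= lo & ref[r, pf] < hi
        for (i in seq_len(n)) {
          x_ok <- x[i, pf] >= lo & x[i, pf] < hi
          if (any(!x_ok & !z_ok)) next
          A <- pf[x_ok & !z_ok]
          B <- pf[z_ok & !x_ok]
          a <- length(A); b <- length(B)
          if (a == 0L && b == 0L) next
          if (a > 0L) {
            vals[i, match(A, feature_names), cls] <-
              vals[i, match(A, feature_names), cls] +
              leaf$value * coef_pos(a, b) / nrow(ref)
          }
          if (b > 0L) {
            vals[i, match(B, feature_names), cls] <-
              vals[i, match(B, feature_names), cls] -
              leaf$value * coef_neg(a, b) / nrow(ref)
          }
        }
      }
    }
  }
  # base value in double precision (mean reference margin), with the
  # intercept calibrated once against the booster's own margin
  ls_ref <- leaf_sums(trees, ref, feature_names, nc)
  m1 <- predict(bst, xgboost::xgb.DMatrix(ref[1L, , drop = FALSE],
                                          nthread = nthread),
                outputmargin = TRUE)
  intercept <- as.numeric(m1) - ls_ref[1L, ]
  base <- colMeans(ls_ref) + intercept
  if (nc > 1L) {
    list(values = vals, base = base)
  } else {
    list(values = base::matrix(vals[, , 1L],
                               nrow = n, ncol = f,
                               dimnames = list(rownames(x), feature_names)),
         base = base)
  }
}

#' Exact Shapley values by subset enumeration
#'
#' Brute-force oracle: the coalition value `v(S)` evaluates `model_fn` on
#' the instance with features outside `S` replaced by the reference, and
#' each feature's attribution is the classical weighted average of its
#' marginal contributions over all `2^(n-1)` coalitions. Refuses more than
#' 12 features.
#'
#' @param model_fn Function taking a named numeric vector and returning a
#'   single numeric prediction (margin).
#' @param instance Named numeric feature vector.
#' @param reference Named numeric feature vector (same names).
#' @return Named numeric attribution vector; satisfies
#'   `sum(phi) = model_fn(instance) - model_fn(reference)`.
#' @export
exact_shapley <- function(model_fn, instance, reference) {
  n <- length(instance)
  if (n > 12L) stop2("exact_shapley enumerates 2^n subsets; n must be <= 12")
  nm <- names(instance) %||% paste0("f", seq_len(n))
  v <- function(mask) {
    z <- reference
    z[mask] <- instance[mask]
    model_fn(z)
  }
  phi <- stats::setNames(numeric(n), nm)
  masks <- lapply(0:(2^n - 1L), function(code) {
    as.logical(bitwAnd(code, 2L^(0:(n - 1L))))
  })
  vals <- vapply(masks, v, numeric(1))
  sizes <- vapply(masks, sum, integer(1))
  wt <- function(s) exp(lgamma(s + 1) + lgamma(n - s) - lgamma(n + 1))
  for (j in seq_len(n)) {
    bit <- 2L^(j - 1L)
    for (code in 0:(2^n - 1L)) {
      if (bitwAnd(code, bit) > 0L) next
      s <- sizes[code + 1L]
      phi[j] <- phi[j] +
        wt(s) * (vals[bitwOr(code, bit) + 1L] - vals[code + 1L])
    }
  }
  phi
}

#' Global motif importance ranking from an explanation
#'
#' Motifs are ranked by the sum of absolute Shapley values across rows
#' (the study's global ranking); the mean absolute and signed mean values
#' are reported alongside. Exact ties break lexicographically by motif id.
#'
#' @param expl A `bom_explanation`.
#' @param class For multiclass/multilabel explanations: the class slice to
#'   rank; `NULL` aggregates absolute values over all classes.
#' @return data.frame (`motif`, `sum_abs`, `mean_abs`, `mean_signed`,
#'   `rank`) sorted by rank.
#' @export
rank_motifs <- function(expl, class = NULL) {
  v <- expl$values
  if (length(dim(v)) == 3L) {
    if (!is.null(class)) {
      v <- v[, , class, drop = FALSE][, , 1L, drop = TRUE]
      v <- base::matrix(v, ncol = length(expl$motif_ids),
                        dimnames = list(expl$row_ids, expl$motif_ids))
    } else {
      v <- apply(abs(v), c(1, 2), sum)
    }
  }
  sum_abs <- colSums(abs(v))
  mean_abs <- colMeans(abs(v))
  mean_signed <- colMeans(v)
  ord <- order(-sum_abs, expl$motif_ids)
  out <- data.frame(motif = expl$motif_ids[ord],
                    sum_abs = unname(sum_abs[ord]),
                    mean_abs = unname(mean_abs[ord]),
                    mean_signed = unname(mean_signed[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Local explanation: top motifs for one CRE
#'
#' @param expl A `bom_explanation` (binary/regression, or give `class`).
#' @param row_id Row (CRE) name.
#' @param top_k Number of motifs to report, by absolute attribution
#'   (default 4, as in the study's local-explanation plots).
#' @param class Class slice for multiclass/multilabel explanations.
#' @return data.frame (`motif`, `phi`, `count`) in decreasing `|phi|`.
#' @export
local_explanation <- function(expl, row_id, top_k = 4L, class = NULL) {
  i <- match(row_id, expl$row_ids)
  if (is.na(i)) stop2("unknown row id: ", row_id)
  v <- expl$values
  row <- if (length(dim(v)) == 3L) {
    if (is.null(class)) stop2("class required for per-class explanations")
    v[i, , class]
  } else {
    v[i, ]
  }
  k <- min(top_k, length(row))
  ord <- order(-abs(row), expl$motif_ids)[seq_len(k)]
  data.frame(motif = expl$motif_ids[ord], phi = unname(row[ord]),
             count = unname(expl$counts[i, ord]),
             stringsAsFactors = FALSE)
}
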