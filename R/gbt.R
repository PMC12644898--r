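#' Training configuration for boosted-tree CRE models
#'
#' Defaults are the study's hyperparameters: up to 10,000 boosting rounds,
#' learning rate 0.01, maximum depth 6, row and column subsampling 0.5,
#' early stopping after 100 rounds without validation improvement.
#'
#' @param mode One of `"binary"`, `"multiclass"`, `"multilabel"`,
#'   `"regression"`.
#' @param rounds Maximum boosting rounds.
#' @param learning_rate Shrinkage (eta).
#' @param max_depth Maximum tree depth.
#' @param row_subsample Row subsample fraction per tree.
#' @param column_subsample Column subsample fraction per tree.
#' @param early_stopping_rounds Stop when the validation metric has not
#'   improved for this many rounds.
#' @param eval_metric Validation metric; `NULL` selects logloss (binary /
#'   multilabel), mlogloss (multiclass) or rmse (regression).
#' @param seed Integer seed passed to the booster.
#' @param nthread Threads (default 1 for bit-reproducible runs).
#' @return A list of class `bom_train_config`.
#' @export
bom_train_config <- function(mode = c("binary", "multiclass", "multilabel",
                                      "regression"),
                             rounds = 10000L, learning_rate = 0.01,
                             max_depth = 6L, row_subsample = 0.5,
                             column_subsample = 0.5,
                             early_stopping_rounds = 100L,
                             eval_metric = NULL, seed = 1L, nthread = 1L) {
  mode <- match.arg(mode)
  stopifnot(learning_rate > 0, learning_rate <= 1,
            row_subsample > 0, row_subsample <= 1,
            column_subsample > 0, column_subsample <= 1, rounds >= 1)
  if (is.null(eval_metric)) {
    eval_metric <- switch(mode, binary = "logloss", multilabel = "logloss",
                          multiclass = "mlogloss", regression = "rmse")
  }
  structure(list(mode = mode, rounds = as.integer(rounds),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 row_subsample = row_subsample,
                 column_subsample = column_subsample,
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 eval_metric = eval_metric, seed = as.integer(seed),
                 nthread = as.integer(nthread)),
            class = "bom_train_config")
}

xgb_params_for <- function(config, objective, num_class = NULL) {
  p <- list(objective = objective,
            eta = config$learning_rate,
            max_depth = config$max_depth,
            subsample = config$row_subsample,
            colsample_bytree = config$column_subsample,
            eval_metric = config$eval_metric,
            nthread = config$nthread,
            seed = config$seed)
  if (!is.null(num_class)) p$num_class <- num_class
  do.call(xgboost::xgb.params, p)
}

train_one_booster <- function(x_train, y_train, x_val, y_val, config,
                              objective, num_class = NULL) {
  dtr <- xgboost::xgb.DMatrix(x_train, label = y_train,
                              nthread = config$nthread)
  dva <- xgboost::xgb.DMatrix(x_val, label = y_val,
                              nthread = config$nthread)
  bst <- xgboost::xgb.train(
    params = xgb_params_for(config, objective, num_class),
    data = dtr, nrounds = config$rounds,
    evals = list(validation = dva),
    early_stopping_rounds = config$early_stopping_rounds,
    verbose = 0)
  bst
}

#' Train a bag-of-motifs boosted-tree model
#'
#' Trains gradient-boosted decision trees on a motif count matrix with the
#' study's objectives: `binary:logistic` (binary and per-class multilabel),
#' `multi:softprob` (multiclass) or `reg:squarederror` (regression), with
#' early stopping on the validation set.
#'
#' @param x_train,x_val Count matrices (same columns) for training and
#'   validation.
#' @param y_train,y_val Labels: 0/1 for binary; class factors/characters
#'   for multiclass; a binary matrix (rows x classes) for multilabel;
#'   numeric for regression.
#' @param config A [bom_train_config()].
#' @return An object of class `bom_model` holding the ensemble(s), the
#'   feature names in training order, class names, config and best
#'   iteration(s).
#' @export
train_bom <- function(x_train, y_train, x_val, y_val,
                      config = bom_train_config("binary")) {
  if (!identical(colnames(x_train), colnames(x_val))) {
    stop2("training and validation matrices must share identical columns")
  }
  feature_names <- colnames(x_train)
  mode <- config$mode
  if (mode == "binary") {
    y <- as.integer(y_train)
    if (length(unique(y)) < 2L) {
      stop2("binary training labels contain a single class")
    }
    bst <- train_one_booster(x_train, y, x_val, as.integer(y_val),
                             config, "binary:logistic")
    ens <- list(bst)
    classes <- NULL
    best <- best_iteration(bst)
  } else if (mode == "multiclass") {
    classes <- sort(unique(as.character(y_train)))
    if (length(classes) < 2L) stop2("multiclass mode needs >= 2 classes")
    ytr <- match(as.character(y_train), classes) - 1L
    yva <- match(as.character(y_val), classes) - 1L
    if (anyNA(yva)) stop2("validation labels outside the training classes")
    bst <- train_one_booster(x_train, ytr, x_val, yva, config,
                             "multi:softprob", num_class = length(classes))
    ens <- list(bst)
    best <- best_iteration(bst)
  } else if (mode == "multilabel") {
    if (is.null(dim(y_train))) {
      stop2("multilabel mode expects a binary label matrix (rows x classes)")
    }
    classes <- colnames(y_train)
    ens <- lapply(classes, function(cl) {
      train_one_booster(x_train, as.integer(y_train[, cl]),
                        x_val, as.integer(y_val[, cl]),
                        config, "binary:logistic")
    })
    best <- vapply(ens, best_iteration, numeric(1))
  } else {
    bst <- train_one_booster(x_train, as.numeric(y_train),
                             x_val, as.numeric(y_val),
                             config, "reg:squarederror")
    ens <- list(bst)
    classes <- NULL
    best <- best_iteration(bst)
  }
  structure(list(ensembles = ens, feature_names = feature_names,
                 class_names = classes, config = config,
                 best_iteration = best),
            class = "bom_model")
}

best_iteration <- function(bst) {
  b <- xgboost::xgb.attr(bst, "best_iteration")
  if (is.null(b) || is.na(suppressWarnings(as.numeric(b)))) NA_real_
  else as.numeric(b)
}

# Reorder `matrix` columns to the model's feature order. Missing motif
# columns are imputed as zero counts (a motif never scanned is
# indistinguishable from absent); unknown extra columns are an error in
# strict mode, silently dropped otherwise.
align_features <- function(matrix, feature_names, strict = TRUE) {
  extra <- setdiff(colnames(matrix), feature_names)
  if (length(extra) && strict) {
    stop2("unknown feature columns: ", paste(extra, collapse = ", "))
  }
  out <- base::matrix(0, nrow = nrow(matrix), ncol = length(feature_names),
                      dimnames = list(rownames(matrix), feature_names))
  common <- intersect(colnames(matrix), feature_names)
  out[, common] <- matrix[, common]
  out
}

#' Predict with a bag-of-motifs model
#'
#' Scores follow the study's decision rule: probabilities at or above the
#' threshold are positive. Matrices whose motif vocabulary differs from
#' training are aligned by name, with missing motifs imputed as zero
#' counts (the cross-dataset / cross-species transfer contract).
#'
#' @param object A `bom_model`.
#' @param newdata Count matrix.
#' @param threshold Positive-call threshold (default 0.5).
#' @param strict Error on unknown feature columns (default `TRUE`).
#' @param outputmargin Return raw margins instead of probabilities.
#' @param ... Unused.
#' @return Binary: data.frame (`score`, `label`). Multiclass: list with
#'   probability matrix `prob` and `label`. Multilabel: list of per-class
#'   score matrices and label matrix. Regression: numeric vector.
#' @export
predict.bom_model <- function(object, newdata, threshold = 0.5,
                              strict = TRUE, outputmargin = FALSE, ...) {
  x <- align_features(newdata, object$feature_names, strict)
  dm <- xgboost::xgb.DMatrix(x, nthread = object$config$nthread)
  mode <- object$config$mode
  if (mode == "binary") {
    p <- predict(object$ensembles[[1]], dm, outputmargin = outputmargin)
    if (outputmargin) return(stats::setNames(p, rownames(x)))
    data.frame(row.names = rownames(x), score = p,
               label = as.integer(p >= threshold))
  } else if (mode == "multiclass") {
    p <- predict(object$ensembles[[1]], dm, outputmargin = outputmargin)
    colnames(p) <- object$class_names
    rownames(p) <- rownames(x)
    if (outputmargin) return(p)
    list(prob = p,
         label = object$class_names[max.col(p, ties.method = "first")])
  } else if (mode == "multilabel") {
    ps <- vapply(object$ensembles, function(b) {
      predict(b, dm, outputmargin = outputmargin)
    }, numeric(nrow(x)))
    ps <- base::matrix(ps, nrow = nrow(x),
                       dimnames = list(rownames(x), object$class_names))
    if (outputmargin) return(ps)
    list(score = ps, label = (ps >= threshold) * 1L)
  } else {
    stats::setNames(predict(object$ensembles[[1]], dm), rownames(x))
  }
}

#' Save / load a bag-of-motifs model directory
#'
#' The ensemble(s) are written as the booster's native JSON text dumps
#' plus a `manifest.json` recording feature names, class names, config and
#' best iterations.
#'
#' @param model A `bom_model`.
#' @param dir Output directory (created if needed).
#' @export
save_bom_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(model$ensembles)) {
    xgboost::xgb.save(model$ensembles[[i]],
                      file.path(dir, sprintf("ensemble_%02d.json", i)))
  }
  manifest <- list(feature_names = model$feature_names,
                   class_names = model$class_names,
                   config = unclass(model$config),
                   best_iteration = model$best_iteration,
                   n_ensembles = length(model$ensembles))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_bom_model
#' @export
load_bom_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ens <- lapply(seq_len(manifest$n_ensembles), function(i) {
    xgboost::xgb.load(file.path(dir, sprintf("ensemble_%02d.json", i)))
  })
  cfg <- manifest$config
  config <- bom_train_config(cfg$mode, cfg$rounds, cfg$learning_rate,
                             cfg$max_depth, cfg$row_subsample,
                             cfg$column_subsample,
                             cfg$early_stopping_rounds, cfg$eval_metric,
                             cfg$seed, cfg$nthread)
  structure(list(ensembles = ens,
                 feature_names = manifest$feature_names,
                 class_names = manifest$class_names,
                 config = config,
                 best_iteration = manifest$best_iteration),
            class = "bom_model")
}
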