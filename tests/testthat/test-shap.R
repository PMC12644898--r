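shap_model <- function(seed = 51L, n = 200L, n_noise = 4L) {
  d <- make_separable_counts(n, n_noise = n_noise, seed = seed)
  sp <- split_dataset(n, seed = seed, labels = d$y)
  model <- train_bom(d$x[sp$train, ], d$y[sp$train],
                     d$x[sp$validation, ], d$y[sp$validation],
                     bom_train_config("binary", rounds = 60L,
                                      learning_rate = 0.3,
                                      early_stopping_rounds = 15L,
                                      seed = seed))
  list(model = model, x = d$x, y = d$y, sp = sp)
}

test_that("default TreeSHAP explanations satisfy efficiency", {
  fx <- shap_model()
  te <- fx$x[fx$sp$test, ]
  expl <- explain(fx$model, te)
  marg <- predict(fx$model, te, outputmargin = TRUE)
  expect_equal(unname(rowSums(expl$values) + expl$base_values),
               unname(marg), tolerance = 1e-6)
})

test_that("interventional explanations close exactly against double margins", {
  fx <- shap_model()
  te <- fx$x[fx$sp$test[1:20], ]
  zero_ref <- matrix(0, 1, ncol(te), dimnames = list("ref", colnames(te)))
  expl <- explain(fx$model, te, reference = zero_ref)
  marg <- motifbag:::margin_double(fx$model, te)
  expect_lt(max(abs(rowSums(expl$values) + expl$base_values - marg)),
            1e-6)
})

test_that("tree explanations with an all-zero reference match exact Shapley", {
  fx <- shap_model(n = 150L, n_noise = 3L)  # 4 features total
  te <- fx$x[fx$sp$test[1:8], ]
  zero_ref <- matrix(0, 1, ncol(te), dimnames = list("ref", colnames(te)))
  expl <- explain(fx$model, te, reference = zero_ref)
  model_fn <- function(v) {
    motifbag:::margin_double(fx$model,
                             matrix(v, 1, dimnames = list("q", names(v))))
  }
  ref_vec <- stats::setNames(rep(0, ncol(te)), colnames(te))
  for (i in seq_len(nrow(te))) {
    phi <- exact_shapley(model_fn, te[i, ], ref_vec)
    expect_lt(max(abs(expl$values[i, ] - phi)), 1e-6)
  }
})

test_that("exact Shapley recovers additive models and rejects blowups", {
  f <- function(v) 2 * v[["x1"]] + 3 * v[["x2"]]
  phi <- exact_shapley(f, c(x1 = 1, x2 = 1), c(x1 = 0, x2 = 0))
  expect_equal(unname(phi), c(2, 3))
  # constant model: all zero
  phi0 <- exact_shapley(function(v) 7, c(a = 1, b = 2), c(a = 0, b = 0))
  expect_equal(unname(phi0), c(0, 0))
  # symmetry: interchangeable features split the credit equally
  g <- function(v) as.numeric(v[["a"]] + v[["b"]] > 0) * 2
  phis <- exact_shapley(g, c(a = 1, b = 1), c(a = 0, b = 0))
  expect_equal(phis[["a"]], phis[["b"]])
  expect_equal(sum(phis), 2)
  big <- stats::setNames(rep(1, 13), paste0("f", 1:13))
  expect_error(exact_shapley(function(v) 0, big, big * 0), "12")
})

test_that("features never used by the trees get zero attribution", {
  d <- make_separable_counts(200, n_noise = 2, seed = 61)
  x <- cbind(d$x, DEAD = 0L)  # constant column can never split
  sp <- split_dataset(200, seed = 61, labels = d$y)
  model <- train_bom(x[sp$train, ], d$y[sp$train], x[sp$validation, ],
                     d$y[sp$validation],
                     bom_train_config("binary", rounds = 50L,
                                      learning_rate = 0.3,
                                      early_stopping_rounds = 10L,
                                      seed = 61))
  expl <- explain(model, x[sp$test, ])
  expect_true(all(expl$values[, "DEAD"] == 0))
  zero_ref <- matrix(0, 1, ncol(x), dimnames = list("r", colnames(x)))
  expl2 <- explain(model, x[sp$test[1:5], ], reference = zero_ref)
  expect_true(all(expl2$values[, "DEAD"] == 0))
})

test_that("multiclass explanations carry one slice per class with efficiency", {
  set.seed(62)
  n <- 210
  y <- rep(c("a", "b", "c"), each = n / 3)
  x <- matrix(rpois(n * 4, 1), n, 4,
              dimnames = list(sprintf("r%d", 1:n), paste0("M", 1:4)))
  x[y == "a", 1] <- x[y == "a", 1] + 3L
  x[y == "b", 2] <- x[y == "b", 2] + 3L
  x[y == "c", 3] <- x[y == "c", 3] + 3L
  sp <- split_dataset(n, seed = 62, labels = y)
  model <- train_bom(x[sp$train, ], y[sp$train], x[sp$validation, ],
                     y[sp$validation],
                     bom_train_config("multiclass", rounds = 60L,
                                      learning_rate = 0.3,
                                      early_stopping_rounds = 15L,
                                      seed = 62))
  te <- x[sp$test, ]
  expl <- explain(model, te)
  expect_identical(dim(expl$values),
                   c(nrow(te), 4L, 3L))
  marg <- predict(model, te, outputmargin = TRUE)
  for (k in 1:3) {
    expect_equal(unname(rowSums(expl$values[, , k]) + expl$base_values[k]),
                 unname(marg[, k]), tolerance = 1e-5)
  }
})

test_that("global ranking orders by summed absolute attribution", {
  expl <- structure(list(
    values = matrix(c(1, 1, -0.5, 0), 2, 2,
                    dimnames = list(c("r1", "r2"), c("M1", "M2"))),
    base_values = 0, row_ids = c("r1", "r2"), motif_ids = c("M1", "M2"),
    class_names = NULL,
    counts = matrix(0L, 2, 2, dimnames = list(c("r1", "r2"),
                                              c("M1", "M2"))),
    mode = "binary"), class = "bom_explanation")
  rk <- rank_motifs(expl)
  expect_identical(rk$motif, c("M1", "M2"))
  expect_equal(rk$sum_abs, c(2, 0.5))
  expect_equal(rk$mean_signed, c(1, -0.25))

  # all-zero attributions: lexicographic order, zero importance
  expl$values[] <- 0
  rk0 <- rank_motifs(expl)
  expect_identical(rk0$motif, c("M1", "M2"))
  expect_equal(rk0$sum_abs, c(0, 0))

  # invariance to row order
  expl$values <- matrix(c(1, 1, -0.5, 0), 2, 2,
                        dimnames = list(c("r1", "r2"), c("M1", "M2")))
  perm <- expl
  perm$values <- perm$values[c(2, 1), ]
  perm$row_ids <- rev(perm$row_ids)
  expect_identical(rank_motifs(perm)$motif, rk$motif)
  expect_equal(rank_motifs(perm)$sum_abs, rk$sum_abs)
})

test_that("local explanations return the top motifs with signs and counts", {
  expl <- structure(list(
    values = matrix(c(0.9, -0.4, 0.1), 1, 3,
                    dimnames = list("r1", c("M1", "M2", "M3"))),
    base_values = 0, row_ids = "r1", motif_ids = c("M1", "M2", "M3"),
    class_names = NULL,
    counts = matrix(c(3L, 1L, 7L), 1, 3,
                    dimnames = list("r1", c("M1", "M2", "M3"))),
    mode = "binary"), class = "bom_explanation")
  loc <- local_explanation(expl, "r1", top_k = 2)
  expect_identical(loc$motif, c("M1", "M2"))
  expect_equal(loc$phi, c(0.9, -0.4))
  expect_identical(loc$count, c(3L, 1L))
  # top_k beyond the vocabulary returns everything
  expect_identical(nrow(local_explanation(expl, "r1", top_k = 10)), 3L)
  expect_error(local_explanation(expl, "nope"), "unknown row")
})
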