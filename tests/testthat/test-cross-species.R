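# Build a hand-crafted per-peak, per-class explanation object.
fake_peak_explanation <- function(peaks, motifs, classes, values) {
  structure(list(values = values, base_values = rep(0, length(classes)),
                 row_ids = peaks, motif_ids = motifs,
                 class_names = classes,
                 counts = matrix(0L, length(peaks), length(motifs),
                                 dimnames = list(peaks, motifs)),
                 mode = "multiclass"),
            class = "bom_explanation")
}

test_that("aggregation means attributions over accessible peaks", {
  peaks <- sprintf("p%02d", 1:40)
  classes <- c("k1", "k2")
  motifs <- c("M1", "M2")
  vals <- array(0, dim = c(40, 2, 2),
                dimnames = list(peaks, motifs, classes))
  vals[1:20, "M1", "k1"] <- rep(c(0.2, 0.4), 10)
  expl <- fake_peak_explanation(peaks, motifs, classes, vals)

  acc <- matrix(0L, 2, 40, dimnames = list(c("cellA", "cellB"), peaks))
  acc[1, 1:20] <- 1L   # cellA: all k1 peaks
  acc[2, 1:19] <- 1L   # cellB: 19 peaks -> filtered at min_peaks = 20
  ca <- cell_accessibility(acc, data.frame(peak = peaks,
                                           class = rep(classes, each = 20)))
  agg <- aggregate_cell_shap(expl, ca, min_peaks = 20)
  expect_identical(dimnames(agg$values)[[1]], "cellA")
  expect_identical(unname(agg$filtered["min_peaks"]), 1L)
  # mean of alternating 0.2/0.4 is 0.3; normalization by total |values|
  # (only this one nonzero entry) rescales it to 1
  expect_equal(unname(agg$values["cellA", "M1", "k1"]), 1)
})

test_that("excluded (training) peaks do not contribute", {
  peaks <- sprintf("p%02d", 1:30)
  vals <- array(0.1, dim = c(30, 1, 2),
                dimnames = list(peaks, "M1", c("k1", "k2")))
  vals[30, "M1", "k1"] <- 100  # an outlier peak we will exclude
  expl <- fake_peak_explanation(peaks, "M1", c("k1", "k2"), vals)
  acc <- matrix(1L, 1, 30, dimnames = list("c1", peaks))
  ca <- cell_accessibility(acc, data.frame(peak = peaks, class = "k1"))
  agg_all <- aggregate_cell_shap(expl, ca, min_peaks = 10,
                                 matched_slice_only = FALSE)
  agg_excl <- aggregate_cell_shap(expl, ca, min_peaks = 10,
                                  exclude_peaks = "p30",
                                  matched_slice_only = FALSE)
  expect_gt(agg_all$values["c1", "M1", "k1"],
            agg_all$values["c1", "M1", "k2"])
  # with the outlier removed the k1 mean equals the k2 mean again
  expect_equal(unname(agg_excl$values["c1", "M1", "k1"]),
               unname(agg_excl$values["c1", "M1", "k2"]))
})

test_that("ratio scores are scale invariant and the z example reproduces", {
  # craft aggregates with known positive ratios
  r_target <- matrix(c(1.0, 0.4, 0.9, 0.2, 0.8, 0.3), 3, 2,
                     dimnames = list(c("c1", "c2", "c3"), c("k1", "k2")))
  cells <- rownames(r_target)
  vals <- array(0, dim = c(3, 2, 2),
                dimnames = list(cells, c("Mpos", "Mneg"), c("k1", "k2")))
  for (k in 1:2) {
    vals[, "Mpos", k] <- r_target[, k]
    vals[, "Mneg", k] <- -(1 - r_target[, k])
  }
  agg <- structure(list(values = vals, n_peaks = NULL, filtered = NULL,
                        cell_types = NULL), class = "cell_shap_aggregate")
  out <- assign_cell_types(agg)
  expect_equal(out$r_k1, r_target[, "k1"], ignore_attr = TRUE)
  expect_equal(out$z_k1, c(0.7259, -1.1406, 0.4148), tolerance = 1e-3)
  expect_equal(out$z_k2, c(-0.7259, 1.1406, -0.4148), tolerance = 1e-3)
  expect_identical(out$predicted, c("k1", "k2", "k1"))

  # positive rescaling of one cell's aggregates leaves r unchanged
  vals2 <- vals
  vals2[1, , ] <- vals2[1, , ] * 37
  agg2 <- structure(list(values = vals2), class = "cell_shap_aggregate")
  expect_equal(assign_cell_types(agg2)$r_k1, out$r_k1)
})

test_that("degenerate assignment branches fall back to raw ratios", {
  vals <- array(0.5, dim = c(3, 2, 2),
                dimnames = list(c("c1", "c2", "c3"), c("M1", "M2"),
                                c("k1", "k2")))
  vals[, 2, 2] <- -0.5  # class k2 ratio 0.5, class k1 ratio 1, all cells
  agg <- structure(list(values = vals), class = "cell_shap_aggregate")
  out <- assign_cell_types(agg)  # zero SD per column -> raw r used
  expect_identical(out$predicted, rep("k1", 3))

  one <- structure(list(values = vals[1, , , drop = FALSE]),
                   class = "cell_shap_aggregate")
  expect_warning(o1 <- assign_cell_types(one), "single cell")
  expect_identical(o1$predicted, "k1")
})

test_that("downsampling caps each annotated type reproducibly", {
  sim <- simulate_cell_accessibility(c("t1", "t2"), c(30L, 8L), 25L,
                                     seed = 71)
  capped <- downsample_cells(sim, cap_per_type = 10L, seed = 72)
  tab <- table(capped$cell_types)
  expect_identical(as.integer(tab[c("t1", "t2")]), c(10L, 8L))
  again <- downsample_cells(sim, cap_per_type = 10L, seed = 72)
  expect_identical(rownames(capped$matrix), rownames(again$matrix))
  no_ann <- cell_accessibility(sim$matrix, sim$peak_class_map)
  expect_error(downsample_cells(no_ann), "annotation")
})

test_that("simulated accessibility honors contamination and dropout", {
  sim0 <- simulate_cell_accessibility(c("a", "b"), 20L, 30L,
                                      contamination = 0, dropout = 0,
                                      seed = 73)
  # block-diagonal: own peaks all on, others all off
  own <- sim0$matrix[1:20, 1:30]
  other <- sim0$matrix[1:20, 31:60]
  expect_true(all(own == 1L))
  expect_true(all(other == 0L))

  sim1 <- simulate_cell_accessibility(c("a", "b"), 60L, 40L,
                                      contamination = 0.2, dropout = 0.1,
                                      seed = 74)
  per_cell <- rowSums(sim1$matrix)
  expected <- 40 * 0.9 + 40 * 0.2
  sd3 <- 3 * sqrt(40 * 0.9 * 0.1 + 40 * 0.2 * 0.8)
  expect_lt(abs(mean(per_cell) - expected), sd3)

  # total dropout: every cell fails a min_peaks filter downstream
  sim2 <- simulate_cell_accessibility(c("a", "b"), 5L, 30L,
                                      contamination = 0, dropout = 1,
                                      seed = 75)
  expect_true(all(rowSums(sim2$matrix) == 0))
})

test_that("accessibility matrices round-trip through MTX sidecars", {
  sim <- simulate_cell_accessibility(c("a", "b"), 6L, 10L, 0.1, 0.1,
                                     seed = 76)
  pre <- withr::local_tempfile()
  write_accessibility_mtx(sim$matrix, pre)
  back <- read_accessibility_mtx(pre)
  expect_identical(unname(back == 1), unname(sim$matrix == 1L))
  expect_identical(rownames(back), rownames(sim$matrix))
})
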