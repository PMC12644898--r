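test_that("near-delta palindromic motif is found on both strands", {
  m <- delta_motif("ACGTm", "ACGT")
  hits <- scan_motifs(c(s1 = "AAACGTAA"), list(m), p_threshold = 1e-2)
  expect_identical(nrow(hits), 2L)
  expect_true(all(hits$start == 2L))
  expect_setequal(hits$strand, c("+", "-"))
  # maximal score at the consensus
  lom <- motif_logodds(m)
  expect_equal(hits$score[1], sum(apply(lom, 1, max)), tolerance = 1e-9)
})

test_that("width-2 top score has exact p-value 1/16 under uniform background", {
  lom <- matrix(-1, 2, 4)
  lom[1, 1] <- 2  # A at position 1
  lom[2, 2] <- 2  # C at position 2
  d <- score_pvalue(lom, rep(0.25, 4))
  expect_equal(score_pvalue_lookup(d, 4), 1 / 16)
  expect_equal(score_pvalue_lookup(d, -2), 1)
  # monotone non-increasing over a grid of scores
  grid <- seq(-2, 4, length.out = 50)
  p <- score_pvalue_lookup(d, grid)
  expect_true(all(diff(p) <= 0))
})

test_that("DP tail matches exhaustive enumeration for random small motifs", {
  set.seed(101)
  for (rep_i in 1:3) {
    w <- sample(4:6, 1)
    bg <- as.numeric(stats::runif(4, 0.5, 1.5))
    bg <- bg / sum(bg)
    probs <- t(vapply(seq_len(w), function(j) {
      g <- stats::rgamma(4, 1)
      g / sum(g)
    }, numeric(4)))
    colnames(probs) <- c("A", "C", "G", "T")
    lom <- motif_logodds(list(probs = probs), bg)
    d <- score_pvalue(lom, bg)
    tail_oracle <- oracle_enumerate_tail(d$ints, bg)
    expect_equal(d$tail, tail_oracle, tolerance = 1e-9)
  }
})

test_that("non-finite score matrices are rejected", {
  lom <- matrix(0, 2, 4)
  lom[1, 1] <- Inf
  expect_error(score_pvalue(lom, rep(0.25, 4)), "finite")
})

test_that("scanner equals the brute-force oracle on random instances", {
  set.seed(202)
  ms <- make_motif_set(3, c(6L, 10L), concentration = 8, seed = 203)
  seqs <- stats::setNames(
    vapply(1:8, function(i) {
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
            collapse = "")
    }, character(1)), sprintf("seq%02d", 1:8))
  got <- scan_motifs(seqs, ms$motifs, p_threshold = 1e-3)
  want <- oracle_scan(seqs, ms$motifs, p_threshold = 1e-3)
  expect_identical(nrow(got), nrow(want))
  key <- function(h) paste(h$seq_id, h$motif_id, h$start, h$strand)
  expect_identical(key(got), key(want))
  expect_equal(got$score, want$score, tolerance = 1e-9)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
})

test_that("windows containing N are skipped and short sequences give no hits", {
  m <- delta_motif("m1", "ACGTAC")
  hits <- scan_motifs(c(s1 = "ACGNACGTACGG", s2 = "ACG"), list(m),
                      p_threshold = 0.5)
  expect_true(all(hits$start >= 4L))  # any window touching the N is skipped
  expect_false("s2" %in% hits$seq_id)
})

test_that("scanning mirrors under reverse complementation", {
  set.seed(33)
  ms <- make_motif_set(2, c(6L, 8L), concentration = 6, seed = 34)
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
             collapse = "")
  rc <- oracle_revcomp(s)
  h_fwd <- scan_motifs(c(x = s), ms$motifs, background = c(0.3, 0.2, 0.2, 0.3),
                       p_threshold = 1e-2)
  h_rc <- scan_motifs(c(x = rc), ms$motifs, background = c(0.3, 0.2, 0.2, 0.3),
                      p_threshold = 1e-2)
  # mirror h_rc back into forward coordinates of s
  w <- h_rc$end - h_rc$start
  mirrored <- data.frame(motif_id = h_rc$motif_id,
                         start = nchar(s) - h_rc$end,
                         strand = ifelse(h_rc$strand == "+", "-", "+"),
                         score = h_rc$score)
  mirrored <- mirrored[order(mirrored$motif_id, mirrored$start,
                             mirrored$strand), ]
  orig <- data.frame(motif_id = h_fwd$motif_id, start = h_fwd$start,
                     strand = h_fwd$strand, score = h_fwd$score)
  orig <- orig[order(orig$motif_id, orig$start, orig$strand), ]
  expect_equal(orig$start, mirrored$start)
  expect_identical(orig$strand, mirrored$strand)
  expect_equal(orig$score, mirrored$score, tolerance = 1e-9)
})

test_that("raising the p threshold never loses hits", {
  set.seed(44)
  ms <- make_motif_set(2, c(6L, 8L), concentration = 5, seed = 45)
  s <- c(a = paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                   collapse = ""))
  h1 <- scan_motifs(s, ms$motifs, p_threshold = 1e-4)
  h2 <- scan_motifs(s, ms$motifs, p_threshold = 1e-3)
  expect_gte(nrow(h2), nrow(h1))
  key <- function(h) paste(h$seq_id, h$motif_id, h$start, h$strand)
  expect_true(all(key(h1) %in% key(h2)))
})

test_that("BH q-values reproduce the hand-worked example and filter", {
  hits <- data.frame(seq_id = "s", motif_id = "m", start = 0:3, end = 4:7,
                     strand = "+", score = 4:1,
                     p_value = c(0.001, 0.01, 0.04, 0.2),
                     q_value = NA_real_, matched = "",
                     stringsAsFactors = FALSE)
  out <- qvalue_filter(hits, q_cutoff = 0.5)
  expect_equal(out$q_value, c(0.004, 0.02, 16 / 300, 0.2),
               tolerance = 1e-12)
  expect_identical(nrow(out), 4L)

  # equal p-values: q = p * m / m = p
  hits5 <- hits[rep(1, 5), ]
  hits5$p_value <- 0.3
  expect_equal(qvalue_filter(hits5, 0.5)$q_value, rep(0.3, 5))

  # a lone hit above the cutoff is removed
  one <- hits[1, ]
  one$p_value <- 0.6
  expect_identical(nrow(qvalue_filter(one, 0.5)), 0L)

  # empty input passes through
  expect_identical(nrow(qvalue_filter(hits[0, ], 0.5)), 0L)
})

test_that("q-values are adjusted per motif, not across motifs", {
  hits <- data.frame(seq_id = "s", motif_id = rep(c("m1", "m2"), c(2, 1)),
                     start = 0:2, end = 4:6, strand = "+", score = 1,
                     p_value = c(0.01, 0.02, 0.3), q_value = NA_real_,
                     matched = "", stringsAsFactors = FALSE)
  out <- qvalue_filter(hits, 1)
  expect_equal(out$q_value[out$motif_id == "m2"], 0.3)
  expect_equal(out$q_value[out$motif_id == "m1"], c(0.02, 0.02))
})

test_that("overlap removal keeps the dominant hit and is deterministic", {
  h <- data.frame(seq_id = "s1", motif_id = c("A", "B", "C"),
                  start = c(0L, 5L, 12L), end = c(10L, 15L, 20L),
                  strand = "+", score = c(5, 7, 6), p_value = 1e-5,
                  q_value = NA_real_, matched = "",
                  stringsAsFactors = FALSE)
  out <- remove_overlapping_hits(h, seed = 1)
  expect_identical(out$motif_id, "B")

  # non-overlapping input unchanged
  h2 <- h
  h2$start <- c(0L, 20L, 40L)
  h2$end <- c(10L, 30L, 50L)
  expect_identical(remove_overlapping_hits(h2, seed = 1), h2)

  # exact tie: exactly one survives, reproducibly per seed
  tie <- h[1:2, ]
  tie$score <- c(5, 5)
  s1 <- remove_overlapping_hits(tie, seed = 10)
  s2 <- remove_overlapping_hits(tie, seed = 10)
  expect_identical(nrow(s1), 1L)
  expect_identical(s1, s2)
})

test_that("overlap removal matches the naive oracle on random configs", {
  set.seed(77)
  for (i in 1:50) {
    cfg <- random_hit_config(sample(3:10, 1))
    got <- remove_overlapping_hits(cfg, seed = i)
    want <- oracle_overlap_removal(cfg, seed = i)
    expect_identical(got$start, want$start)
    expect_identical(got$motif_id, want$motif_id)
    # pairwise non-overlap
    if (nrow(got) > 1L) {
      for (a in seq_len(nrow(got) - 1L)) {
        for (b in (a + 1L):nrow(got)) {
          expect_true(got$start[a] >= got$end[b] ||
                        got$start[b] >= got$end[a])
        }
      }
    }
  }
})

test_that("hit tables round-trip through TSV", {
  m <- delta_motif("m1", "ACGTAC")
  hits <- scan_motifs(c(s1 = "TTACGTACTT"), list(m), p_threshold = 0.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, f)
  back <- read_hits(f)
  expect_equal(back$score, hits$score)
  expect_identical(back$start, hits$start)
})
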