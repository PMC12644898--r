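#' Log-odds score matrix for a motif
#'
#' Converts a position probability matrix into a log2 log-odds matrix
#' against a 0-order background, with a pseudocount distributed
#' proportionally to the background frequencies:
#' `log2((p + pseudocount * bg) / ((1 + pseudocount) * bg))`.
#'
#' @param motif Motif object (list with `probs`, a `w x 4` matrix).
#' @param background Length-4 background probabilities (A, C, G, T).
#' @param pseudocount Probability mass added per entry, proportional to the
#'   background (default 0.1, the FIMO convention).
#' @return A `w x 4` numeric matrix of log2 odds, columns A, C, G, T.
#' @export
motif_logodds <- function(motif, background = c(0.25, 0.25, 0.25, 0.25),
                          pseudocount = 0.1) {
  background <- as.numeric(background) / sum(background)
  if (any(background <= 0)) stop2("background frequencies must be > 0")
  p <- motif$probs
  lom <- log2(sweep(sweep(p, 2L, pseudocount * background, "+"),
                    2L, (1 + pseudocount) * background, "/"))
  colnames(lom) <- DNA_BASES
  lom
}

# Reverse-complement a log-odds matrix: scoring a window with the result
# equals scoring the reverse complement of the window with the original.
revcomp_logodds <- function(lom) {
  out <- lom[rev(seq_len(nrow(lom))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

#' Exact null distribution of PWM scores by dynamic programming
#'
#' Discretizes a log-odds matrix to integer scores and computes the exact
#' distribution of the discretized score of a random word drawn from the
#' 0-order background, by convolving per-position score distributions. The
#' tail gives the p-value `P(score >= s)` of any window score.
#'
#' @param log_odds `w x 4` numeric matrix of finite per-position, per-base
#'   scores (columns A, C, G, T).
#' @param background Length-4 background probabilities.
#' @param resolution Number of discretization bins spanning the achievable
#'   score range (default 1000).
#' @return An object of class `motif_score_dist` with elements `ints`
#'   (integer score matrix), `offset`, `scale`, `tail` (tail probabilities
#'   indexed by integer score + 1), `min_score`, `max_score`.
#' @examples
#' lom <- matrix(c(2, -1, -1, -1, -1, 2, -1, -1), nrow = 2, byrow = TRUE)
#' d <- score_pvalue(lom, rep(0.25, 4))
#' score_pvalue_lookup(d, 4)   # only AC scores 4: p = 1/16
#' @export
score_pvalue <- function(log_odds, background = c(0.25, 0.25, 0.25, 0.25),
                         resolution = 1000L) {
  if (!all(is.finite(log_odds))) stop2("log-odds entries must be finite")
  background <- as.numeric(background) / sum(background)
  w <- nrow(log_odds)
  col_min <- apply(log_odds, 1L, min)
  col_max <- apply(log_odds, 1L, max)
  range_total <- sum(col_max - col_min)
  scale <- if (range_total > 0) resolution / range_total else 1
  ints <- round(sweep(log_odds, 1L, col_min, "-") * scale)
  storage.mode(ints) <- "integer"
  max_int <- sum(apply(ints, 1L, max))

  prob <- numeric(max_int + 1L)
  prob[1L] <- 1
  top <- 0L
  for (j in seq_len(w)) {
    nxt <- numeric(max_int + 1L)
    for (b in 1:4) {
      sh <- ints[j, b]
      idx <- seq_len(top + 1L)
      nxt[idx + sh] <- nxt[idx + sh] + prob[idx] * background[b]
    }
    prob <- nxt
    top <- top + max(ints[j, ])
  }
  tail <- rev(cumsum(rev(prob)))

  structure(list(ints = ints, offset = sum(col_min), scale = scale,
                 prob = prob, tail = tail,
                 min_score = sum(col_min), max_score = sum(col_max)),
            class = "motif_score_dist")
}

#' Look up the p-value of a score under a `motif_score_dist`
#'
#' @param dist Object from [score_pvalue()].
#' @param score Numeric score(s) in the same log2 units.
#' @return Tail probability `P(discretized score >= discretized s)`,
#'   monotone non-increasing in `score`.
#' @export
score_pvalue_lookup <- function(dist, score) {
  idx <- as.integer(round((score - dist$offset) * dist$scale))
  idx <- pmax(0L, pmin(idx, length(dist$tail) - 1L))
  dist$tail[idx + 1L]
}

# Integer discretized score of every window of an encoded sequence
# (1..4, 0 for N) under an integer score matrix; N windows get NA.
window_int_scores <- function(enc, ints) {
  w <- nrow(ints)
  n_win <- length(enc) - w + 1L
  if (n_win < 1L) return(integer(0))
  # pad score matrix with an NA row for N (code 0 -> row 1)
  m5 <- rbind(NA_integer_, t(ints))  # 5 x w after transpose stack
  enc1 <- enc + 1L
  sc <- integer(n_win)
  for (j in seq_len(w)) {
    sc <- sc + m5[enc1[j:(j + n_win - 1L)], j]
  }
  sc
}

# Continuous log-odds score of every window; N windows get NA.
window_scores <- function(enc, lom) {
  w <- nrow(lom)
  n_win <- length(enc) - w + 1L
  if (n_win < 1L) return(numeric(0))
  m5 <- rbind(NA_real_, t(lom))
  enc1 <- enc + 1L
  sc <- numeric(n_win)
  for (j in seq_len(w)) {
    sc <- sc + m5[enc1[j:(j + n_win - 1L)], j]
  }
  sc
}

#' Scan sequences with PWMs on both strands
#'
#' FIMO-style scanning: each motif is scored at every window of every
#' sequence, on the forward strand and, via the reverse-complemented score
#' matrix, on the reverse strand. Window p-values are exact tail
#' probabilities from the dynamic program of [score_pvalue()]; windows with
#' p-value at or below `p_threshold` are reported as hits. Windows
#' containing N are skipped. Reverse-strand hits are reported in
#' forward-strand coordinates. q-values are left `NA`; apply
#' [qvalue_filter()] afterwards.
#'
#' Because both strands are scanned, the background is symmetrized across
#' complementary bases (A with T, C with G) before scoring, so that a
#' sequence and its reverse complement yield mirrored hit sets with
#' identical scores and p-values.
#'
#' @param sequences Named character vector of uppercase DNA sequences.
#' @param motifs List of motif objects (see [parse_meme()]).
#' @param background Length-4 background probabilities; `NULL` for uniform.
#' @param p_threshold Report windows with `p_value <= p_threshold`
#'   (default 1e-4, the study setting).
#' @param pseudocount Pseudocount mass for [motif_logodds()].
#' @param resolution Discretization bins for [score_pvalue()].
#' @return A data.frame with columns `seq_id`, `motif_id`, `start`, `end`
#'   (0-based half-open within the sequence), `strand`, `score` (log2
#'   odds), `p_value`, `q_value` (`NA`), `matched` (forward-strand
#'   subsequence).
#' @export
scan_motifs <- function(sequences, motifs,
                        background = NULL,
                        p_threshold = 1e-4, pseudocount = 0.1,
                        resolution = 1000L) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop2("sequences must be uniquely named")
  }
  if (is.null(background)) background <- rep(0.25, 4)
  background <- as.numeric(background) / sum(background)
  background <- (background + background[c(4, 3, 2, 1)]) / 2
  enc_list <- lapply(sequences, function(s) encode_dna(toupper(s)))

  res <- vector("list", length(motifs) * 2L * length(sequences))
  ri <- 0L
  for (m in motifs) {
    lom_f <- motif_logodds(m, background, pseudocount)
    lom_r <- revcomp_logodds(lom_f)
    dist_f <- score_pvalue(lom_f, background, resolution)
    dist_r <- score_pvalue(lom_r, background, resolution)
    w <- nrow(lom_f)
    for (strand in c("+", "-")) {
      lom <- if (strand == "+") lom_f else lom_r
      dist <- if (strand == "+") dist_f else dist_r
      for (sn in names(sequences)) {
        enc <- enc_list[[sn]]
        if (length(enc) < w) next
        is_ <- window_int_scores(enc, dist$ints)
        pv <- rep(NA_real_, length(is_))
        ok <- !is.na(is_)
        pv[ok] <- dist$tail[is_[ok] + 1L]
        keep <- which(ok & pv <= p_threshold)
        if (!length(keep)) next
        sc <- window_scores(enc, lom)
        ri <- ri + 1L
        res[[ri]] <- data.frame(
          seq_id = sn, motif_id = m$id,
          start = keep - 1L, end = keep - 1L + w,
          strand = strand, score = sc[keep], p_value = pv[keep],
          q_value = NA_real_,
          matched = substring(toupper(sequences[[sn]]), keep, keep + w - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (ri == 0L) {
    return(data.frame(seq_id = character(0), motif_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      matched = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res[seq_len(ri)])
  out <- out[order(out$seq_id, out$motif_id, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg q-value filter for motif hits
#'
#' Adjusts hit p-values per motif across all scanned sequences in the run
#' (`m` = number of candidate hits for that motif) with the step-up BH
#' procedure, and removes hits whose q-value exceeds `q_cutoff` (default
#' 0.5, the study's lenient retention threshold).
#'
#' @param hits Hit data.frame from [scan_motifs()].
#' @param q_cutoff Retain hits with `q_value <= q_cutoff`.
#' @return The filtered hit data.frame with `q_value` filled in.
#' @export
qvalue_filter <- function(hits, q_cutoff = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  q <- numeric(nrow(hits))
  for (mid in unique(hits$motif_id)) {
    sel <- hits$motif_id == mid
    q[sel] <- stats::p.adjust(hits$p_value[sel], method = "BH")
  }
  hits$q_value <- q
  out <- hits[q <= q_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove overlapping motif hits, keeping higher scores
#'
#' Within each sequence, while any two retained hits overlap on forward
#' coordinates (strand-agnostic), the lowest-scoring hit that overlaps
#' another retained hit is removed; exact score ties are broken by a seeded
#' uniform choice. The output is pairwise non-overlapping per sequence.
#' Note that the study's default pipeline does NOT remove overlaps
#' (removal degraded classification); this filter reproduces the
#' overlap-sensitivity analysis.
#'
#' @param hits Hit data.frame.
#' @param seed Integer seed for tie-breaking.
#' @return The reduced hit data.frame.
#' @export
remove_overlapping_hits <- function(hits, seed = 1L) {
  if (nrow(hits) == 0L) return(hits)
  with_rng_seed(seed, {
    keep_all <- logical(nrow(hits))
    for (sn in unique(hits$seq_id)) {
      idx <- which(hits$seq_id == sn)
      h <- hits[idx, , drop = FALSE]
      alive <- rep(TRUE, nrow(h))
      repeat {
        ai <- which(alive)
        if (length(ai) < 2L) break
        ir <- IRanges::IRanges(start = h$start[ai] + 1L, end = h$end[ai])
        ov <- IRanges::findOverlaps(ir, drop.self = TRUE,
                                    drop.redundant = TRUE)
        if (!length(ov)) break
        inv <- unique(c(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov)))
        cand <- ai[inv]
        lo <- cand[h$score[cand] == min(h$score[cand])]
        victim <- if (length(lo) > 1L) lo[sample.int(length(lo), 1L)] else lo
        alive[victim] <- FALSE
      }
      keep_all[idx[alive]] <- TRUE
    }
    out <- hits[keep_all, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write or read a motif hit table as TSV
#'
#' The column layout follows the FIMO TSV convention used downstream:
#' sequence, motif, start, end, strand, score, p-value, q-value, matched.
#'
#' @param hits Hit data.frame.
#' @param file Output path.
#' @export
write_hits <- function(hits, file) {
  utils::write.table(hits, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_hits
#' @export
read_hits <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
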