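# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized scanning path: windows are scored one at a time by
# direct summation, reverse-strand windows by literal reverse
# complementation of the window string.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Score one window string under a log-odds matrix; NA if it contains N.
oracle_window_score <- function(win, lom) {
  idx <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  sum(lom[cbind(seq_along(idx), idx)])
}

oracle_window_int <- function(win, ints) {
  idx <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_integer_)
  sum(ints[cbind(seq_along(idx), idx)])
}

# Brute-force both-strand scan of every window of every sequence. Uses the
# same p-value lookup tables as the scanner (those are validated against
# exhaustive enumeration separately) but enumerates, scores and
# strand-handles windows independently.
oracle_scan <- function(sequences, motifs, background = rep(0.25, 4),
                        p_threshold = 1e-4, pseudocount = 0.1) {
  background <- background / sum(background)
  background <- (background + background[c(4, 3, 2, 1)]) / 2
  rows <- list()
  for (m in motifs) {
    lom <- motif_logodds(m, background, pseudocount)
    w <- nrow(lom)
    dist_f <- score_pvalue(lom, background)
    lom_r <- lom[rev(seq_len(w)), c(4, 3, 2, 1)]
    colnames(lom_r) <- c("A", "C", "G", "T")
    dist_r <- score_pvalue(lom_r, background)
    for (sn in names(sequences)) {
      s <- toupper(sequences[[sn]])
      L <- nchar(s)
      if (L < w) next
      for (i in seq_len(L - w + 1L)) {
        win <- substring(s, i, i + w - 1L)
        # forward strand
        isc <- oracle_window_int(win, dist_f$ints)
        if (!is.na(isc) && dist_f$tail[isc + 1L] <= p_threshold) {
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = sn, motif_id = m$id, start = i - 1L,
            end = i - 1L + w, strand = "+",
            score = oracle_window_score(win, lom),
            p_value = dist_f$tail[isc + 1L], stringsAsFactors = FALSE)
        }
        # reverse strand: score the reverse complement against the
        # forward matrix (equivalent to the reverse-complemented matrix)
        rc <- oracle_revcomp(win)
        isc_r <- oracle_window_int(rc, dist_f$ints)
        if (!is.na(isc_r) && dist_r$tail[isc_r + 1L] <= p_threshold) {
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = sn, motif_id = m$id, start = i - 1L,
            end = i - 1L + w, strand = "-",
            score = oracle_window_score(rc, lom),
            p_value = dist_r$tail[isc_r + 1L], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), motif_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      p_value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$seq_id, out$motif_id, out$start, out$strand), ]
}

# Exhaustive tail distribution of discretized PWM scores over all 4^w
# words, weighted by the background.
oracle_enumerate_tail <- function(ints, background) {
  background <- background / sum(background)
  w <- nrow(ints)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- integer(nrow(words))
  probs <- numeric(nrow(words)) + 1
  for (j in seq_len(w)) {
    scores <- scores + ints[j, words[, j]]
    probs <- probs * background[words[, j]]
  }
  max_int <- sum(apply(ints, 1L, max))
  tail <- numeric(max_int + 1L)
  for (k in 0:max_int) tail[k + 1L] <- sum(probs[scores >= k])
  tail
}

# Naive overlap-removal: repeatedly drop the lowest-scoring hit (per
# sequence) that overlaps another remaining hit; seeded choice among ties.
oracle_overlap_removal <- function(hits, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  keep <- logical(nrow(hits))
  for (sn in unique(hits$seq_id)) {
    h <- hits[hits$seq_id == sn, , drop = FALSE]
    alive <- rep(TRUE, nrow(h))
    repeat {
      idx <- which(alive)
      overlapping <- logical(length(idx))
      for (a in seq_along(idx)) {
        for (b in seq_along(idx)) {
          if (a == b) next
          ia <- idx[a]; ib <- idx[b]
          if (h$start[ia] < h$end[ib] && h$start[ib] < h$end[ia]) {
            overlapping[a] <- TRUE
          }
        }
      }
      if (!any(overlapping)) break
      cand <- idx[overlapping]
      lo <- cand[h$score[cand] == min(h$score[cand])]
      victim <- if (length(lo) > 1L) lo[sample.int(length(lo), 1L)] else lo
      alive[victim] <- FALSE
    }
    keep[which(hits$seq_id == sn)[alive]] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A small near-delta motif from a consensus string.
delta_motif <- function(id, consensus, p = 0.997) {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  probs <- matrix((1 - p) / 3, length(idx), 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  probs[cbind(seq_along(idx), idx)] <- p
  list(id = id, name = id, width = length(idx), probs = probs, nsites = 20)
}

# Random hit configurations for overlap-removal fuzzing.
random_hit_config <- function(n_hits, seq_len = 60L, max_w = 12L) {
  starts <- sample.int(seq_len - max_w, n_hits, replace = TRUE) - 1L
  widths <- sample.int(max_w - 3L, n_hits, replace = TRUE) + 3L
  data.frame(seq_id = "s1", motif_id = sprintf("m%d", seq_len(n_hits)),
             start = starts, end = starts + widths, strand = "+",
             score = round(stats::runif(n_hits), 6), p_value = 1e-5,
             q_value = NA_real_, matched = "", stringsAsFactors = FALSE)
}

# Shared quick training fixture: counts where class 1 means motif M1
# present, plus noise motifs.
make_separable_counts <- function(n = 200L, n_noise = 4L, seed = 42L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  m1 <- ifelse(y == 1L, 1L + stats::rpois(n, 1), 0L)
  noise <- matrix(stats::rpois(n * n_noise, 1), n, n_noise)
  x <- cbind(m1, noise)
  colnames(x) <- c("M1", sprintf("N%d", seq_len(n_noise)))
  rownames(x) <- sprintf("cre%03d", seq_len(n))
  list(x = x, y = y)
}
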