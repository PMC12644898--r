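#' Generate a random motif set
#'
#' Draws seeded PWMs whose columns sit on the probability simplex: each
#' position picks a consensus base and draws probabilities from a
#' Dirichlet with concentration `concentration` on the consensus and 1 on
#' the other bases, so large `concentration` gives near-delta
#' (information-rich) columns.
#'
#' @param n_motifs Number of motifs.
#' @param width_range Length-2 integer range of motif widths (default
#'   8-12, wide enough that a consensus instance passes the 1e-4 scan
#'   threshold).
#' @param concentration Dirichlet concentration on the consensus base
#'   (default 50).
#' @param seed Integer seed.
#' @param prefix Motif id prefix.
#' @return List with `motifs` (motif objects) and `meme` (MEME minimal
#'   text).
#' @export
make_motif_set <- function(n_motifs, width_range = c(8L, 12L),
                           concentration = 50, seed = 1L,
                           prefix = "SYN") {
  stopifnot(n_motifs >= 1L)
  with_rng_seed(seed, {
    motifs <- lapply(seq_len(n_motifs), function(i) {
      w <- sample(seq.int(width_range[1], width_range[2]), 1L)
      probs <- t(vapply(seq_len(w), function(j) {
        cons <- sample.int(4L, 1L)
        alpha <- rep(1, 4)
        alpha[cons] <- concentration
        g <- stats::rgamma(4L, shape = alpha)
        g / sum(g)
      }, numeric(4)))
      colnames(probs) <- DNA_BASES
      list(id = sprintf("%s_%03d", prefix, i),
           name = sprintf("%s_%03d", prefix, i),
           width = w, probs = probs, nsites = 20)
    })
    list(motifs = motifs, meme = write_meme(motifs))
  })
}

#' Simulate a labeled CRE sequence dataset with controlled implant rates
#'
#' Each CRE is an i.i.d. background sequence of the given GC fraction;
#' for each motif, with probability `implant_rate[class, motif]`, one
#' PWM-sampled instance is implanted at a uniform position that does not
#' overlap previous implants. The truth table records every implant.
#'
#' @param classes Character vector of class names.
#' @param n_per_class CREs per class (recycled).
#' @param motifs List of motif objects.
#' @param implant_rate Matrix `classes x motifs` of implant
#'   probabilities (dimnames optional; recycled by position).
#' @param cre_width CRE length in bases (default 500).
#' @param gc Background GC fraction (default 0.41, a vertebrate-like
#'   genome average).
#' @param seed Integer seed.
#' @return List of class `cre_simulation`: `sequences` (named character),
#'   `labels` (data.frame name, label), `implants` (data.frame cre,
#'   motif, start, instance), `motifs`.
#' @export
simulate_cre_dataset <- function(classes, n_per_class, motifs,
                                 implant_rate, cre_width = 500L,
                                 gc = 0.41, seed = 1L) {
  n_per_class <- rep_len(n_per_class, length(classes))
  implant_rate <- base::matrix(implant_rate, nrow = length(classes),
                               ncol = length(motifs))
  stopifnot(all(implant_rate >= 0), all(implant_rate <= 1))
  widths <- vapply(motifs, function(m) nrow(m$probs), integer(1))
  if (any(widths > cre_width)) stop2("motif wider than the CRE width")
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_rng_seed(seed, {
    seqs <- character(sum(n_per_class))
    nm <- character(sum(n_per_class))
    lab <- character(sum(n_per_class))
    implants <- list()
    idx <- 0L
    for (ci in seq_along(classes)) {
      for (r in seq_len(n_per_class[ci])) {
        idx <- idx + 1L
        nm[idx] <- sprintf("%s_cre_%04d", classes[ci], r)
        lab[idx] <- classes[ci]
        chars <- sample(DNA_BASES, cre_width, replace = TRUE,
                        prob = base_probs)
        occ_start <- integer(0)
        occ_end <- integer(0)
        for (mi in seq_along(motifs)) {
          if (stats::runif(1) >= implant_rate[ci, mi]) next
          w <- widths[mi]
          placed <- FALSE
          for (try in seq_len(1000L)) {
            s <- sample.int(cre_width - w + 1L, 1L) - 1L
            if (!any(s < occ_end & s + w > occ_start)) {
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            stop2("could not place implant of motif ", motifs[[mi]]$id,
                  " in CRE ", nm[idx], " after 1000 retries")
          }
          inst <- vapply(seq_len(w), function(j) {
            sample(DNA_BASES, 1L, prob = motifs[[mi]]$probs[j, ])
          }, character(1))
          chars[(s + 1L):(s + w)] <- inst
          occ_start <- c(occ_start, s)
          occ_end <- c(occ_end, s + w)
          implants[[length(implants) + 1L]] <- data.frame(
            cre = nm[idx], motif = motifs[[mi]]$id, start = s,
            instance = paste(inst, collapse = ""),
            stringsAsFactors = FALSE)
        }
        seqs[idx] <- paste(chars, collapse = "")
      }
    }
    names(seqs) <- nm
    truth <- if (length(implants)) do.call(rbind, implants) else
      data.frame(cre = character(0), motif = character(0),
                 start = integer(0), instance = character(0))
    structure(list(sequences = seqs,
                   labels = data.frame(name = nm, label = lab,
                                       stringsAsFactors = FALSE),
                   implants = truth, motifs = motifs, seed = seed),
              class = "cre_simulation")
  })
}

#' Simulate a toy cell-by-peak accessibility matrix
#'
#' Each cell accesses the marker peaks of its own type with probability
#' `1 - dropout` and every other type's marker peaks with probability
#' `contamination`; entries are binary. Marker peaks are named per type
#' unless an explicit `marker_peaks` list (type -> peak names) is given.
#'
#' @param types Character vector of cell types.
#' @param cells_per_type Cells per type (recycled).
#' @param marker_peaks_per_type Marker peaks per type, or a named list of
#'   peak-name vectors per type.
#' @param contamination Cross-type access probability (default 0).
#' @param dropout Probability of missing an own-type peak (default 0).
#' @param seed Integer seed.
#' @return A `cell_accessibility` with truth annotations attached.
#' @export
simulate_cell_accessibility <- function(types, cells_per_type,
                                        marker_peaks_per_type,
                                        contamination = 0, dropout = 0,
                                        seed = 1L) {
  stopifnot(contamination >= 0, contamination <= 1,
            dropout >= 0, dropout <= 1)
  cells_per_type <- rep_len(cells_per_type, length(types))
  peaks_by_type <- if (is.list(marker_peaks_per_type)) {
    marker_peaks_per_type[types]
  } else {
    stats::setNames(lapply(types, function(tp) {
      sprintf("%s_peak_%03d", tp, seq_len(marker_peaks_per_type))
    }), types)
  }
  all_peaks <- unlist(peaks_by_type, use.names = FALSE)
  peak_class <- rep(types, vapply(peaks_by_type, length, integer(1)))
  with_rng_seed(seed, {
    cell_ids <- unlist(lapply(seq_along(types), function(ti) {
      sprintf("%s_cell_%04d", types[ti], seq_len(cells_per_type[ti]))
    }), use.names = FALSE)
    cell_type <- rep(types, cells_per_type)
    m <- base::matrix(0L, length(cell_ids), length(all_peaks),
                      dimnames = list(cell_ids, all_peaks))
    for (i in seq_along(cell_ids)) {
      own <- peak_class == cell_type[i]
      p <- ifelse(own, 1 - dropout, contamination)
      m[i, ] <- as.integer(stats::runif(length(all_peaks)) < p)
    }
    cell_accessibility(
      m,
      data.frame(peak = all_peaks, class = peak_class,
                 stringsAsFactors = FALSE),
      stats::setNames(cell_type, cell_ids))
  })
}
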