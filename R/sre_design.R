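#' Select the top-ranked motifs from a global importance ranking
#'
#' @param ranking data.frame from [rank_motifs()].
#' @param k Number of motifs (default 5, the study's choice).
#' @return Character vector of `k` motif ids in rank order.
#' @export
select_top_motifs <- function(ranking, k = 5L) {
  if (k > nrow(ranking)) {
    stop2("k = ", k, " exceeds the ", nrow(ranking), " ranked motifs")
  }
  ranking$motif[seq_len(k)]
}

#' Consensus sequence of a PWM
#'
#' Per-position argmax base; ties break in A < C < G < T order.
#'
#' @param motif Motif object with a `probs` matrix.
#' @return Nucleotide string of the motif's width.
#' @export
pwm_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$probs, 1L, which.max)], collapse = "")
}

#' Design synthetic regulatory elements by motif implantation
#'
#' Builds `n_designs` elements from a fixed-length template: the instance
#' multiset (`copies_per_motif` copies of each selected motif) is
#' permuted (seeded) and each instance is placed at a random
#' non-overlapping position, REPLACING template bases so the total length
#' never changes (the study used a 260-bp template with the top 5 motifs,
#' 2 copies each). Instances are motif consensus sequences by default, or
#' sampled from the PWM per implant.
#'
#' @param template Nucleotide template string (defines the target length).
#' @param motifs List of motif objects (e.g. the top-k by
#'   [select_top_motifs()]).
#' @param copies_per_motif Copies of each motif per design (default 2).
#' @param n_designs Number of designs (default 5).
#' @param seed Integer seed.
#' @param sample_instances Sample instances from the PWM instead of the
#'   consensus (default `FALSE`).
#' @param max_retries Placement retries per instance before aborting.
#' @return List of class `sre_design_set`: `designs` (named character
#'   vector of sequences) and `implants` (data.frame design, motif,
#'   start, strand, instance; `start` 0-based).
#' @export
design_sres <- function(template, motifs, copies_per_motif = 2L,
                        n_designs = 5L, seed = 1L,
                        sample_instances = FALSE, max_retries = 1000L) {
  template <- toupper(template)
  len <- nchar(template)
  widths <- vapply(motifs, function(m) nrow(m$probs), integer(1))
  need <- sum(widths) * copies_per_motif
  if (need > len) {
    stop2("implants need ", need, " bases but the template has only ", len)
  }
  with_rng_seed(seed, {
    designs <- character(n_designs)
    recs <- list()
    for (d in seq_len(n_designs)) {
      units <- rep(seq_along(motifs), each = copies_per_motif)
      units <- units[sample.int(length(units))]
      placed_start <- integer(0)
      placed_end <- integer(0)
      seq_chars <- strsplit(template, "")[[1]]
      for (u in units) {
        w <- widths[u]
        inst <- if (sample_instances) {
          paste(vapply(seq_len(w), function(j) {
            sample(DNA_BASES, 1L, prob = motifs[[u]]$probs[j, ])
          }, character(1)), collapse = "")
        } else {
          pwm_consensus(motifs[[u]])
        }
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          s <- sample.int(len - w + 1L, 1L) - 1L
          if (!any(s < placed_end & s + w > placed_start)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop2("could not place all implants after ", max_retries,
                " retries (", need, " implant bases in a ", len,
                "-base template)")
        }
        seq_chars[(s + 1L):(s + w)] <- strsplit(inst, "")[[1]]
        placed_start <- c(placed_start, s)
        placed_end <- c(placed_end, s + w)
        recs[[length(recs) + 1L]] <- data.frame(
          design = sprintf("sre_%02d", d),
          motif = motifs[[u]]$id, start = s, strand = "+",
          instance = inst, stringsAsFactors = FALSE)
      }
      designs[d] <- paste(seq_chars, collapse = "")
    }
    names(designs) <- sprintf("sre_%02d", seq_len(n_designs))
    implants <- do.call(rbind, recs)
    implants <- implants[order(implants$design, implants$start), ]
    rownames(implants) <- NULL
    structure(list(designs = designs, implants = implants, seed = seed),
              class = "sre_design_set")
  })
}
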