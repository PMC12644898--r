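#' Parse motifs from a MEME minimal format file
#'
#' Reads position probability matrices (PPMs) and the 0-order background
#' model from a MEME minimal motif file, the interchange format used by the
#' MEME Suite tools (FIMO and friends) and by most motif databases.
#'
#' Each `MOTIF` block becomes one motif: a list with elements `id`, `name`,
#' `width`, `probs` (a `width x 4` matrix, columns A, C, G, T) and `nsites`
#' (NA when the letter-probability header does not state it). Rows whose sum
#' deviates from 1 by at most 1e-3 are renormalized; larger deviations are an
#' error.
#'
#' @param source Path to a MEME minimal file, or a character vector of its
#'   lines.
#' @return A list with elements `motifs` (list of motif objects) and
#'   `background` (numeric length-4 probability vector named A, C, G, T;
#'   uniform when the file carries no background block).
#' @examples
#' meme <- write_meme(make_motif_set(2, seed = 1)$motifs)
#' parsed <- parse_meme(meme)
#' length(parsed$motifs)
#' @export
parse_meme <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
                 file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1L && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
  lines <- trimws(lines)

  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_idx <- grep("^Background letter frequencies", lines)
  if (length(bg_idx) >= 1L) {
    i <- bg_idx[1] + 1L
    toks <- character(0)
    while (i <= length(lines) && !grepl("^MOTIF", lines[i])) {
      toks <- c(toks, strsplit(lines[i], "\\s+")[[1]])
      if (length(toks) >= 8L) break
      i <- i + 1L
    }
    toks <- toks[toks != ""]
    if (length(toks) >= 8L) {
      vals <- suppressWarnings(as.numeric(toks[c(2, 4, 6, 8)]))
      names(vals) <- toupper(toks[c(1, 3, 5, 7)])
      if (!anyNA(vals) && all(c("A", "C", "G", "T") %in% names(vals))) {
        vals <- vals[DNA_BASES]
        background <- vals / sum(vals)
      }
    }
  }

  motif_idx <- grep("^MOTIF\\b", lines)
  motifs <- vector("list", length(motif_idx))
  bounds <- c(motif_idx, length(lines) + 1L)
  for (k in seq_along(motif_idx)) {
    block <- lines[motif_idx[k]:(bounds[k + 1L] - 1L)]
    head_toks <- strsplit(block[1], "\\s+")[[1]]
    id <- if (length(head_toks) >= 2L) head_toks[2] else
      stop2("MOTIF line without an identifier at line ", motif_idx[k])
    name <- if (length(head_toks) >= 3L) head_toks[3] else id

    lp <- grep("^letter-probability matrix", block)
    if (length(lp) != 1L) {
      stop2("motif '", id, "': missing letter-probability matrix header")
    }
    hdr <- block[lp]
    w <- sub(".*w\\s*=\\s*([0-9]+).*", "\\1", hdr)
    w <- if (grepl("^[0-9]+$", w)) as.integer(w) else NA_integer_
    nsites <- if (grepl("nsites\\s*=", hdr)) {
      as.numeric(sub(".*nsites\\s*=\\s*([0-9.eE+-]+).*", "\\1", hdr))
    } else {
      NA_real_
    }

    rows <- list()
    i <- lp + 1L
    while (i <= length(block)) {
      ln <- block[i]
      if (ln == "" || grepl("^(MOTIF|URL)", ln)) break
      toks <- strsplit(ln, "\\s+")[[1]]
      toks <- toks[toks != ""]
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals) || length(vals) != 4L) {
        stop2("motif '", id, "': malformed probability row '", ln,
              "' (expected 4 numeric columns)")
      }
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    probs <- do.call(rbind, rows)
    if (is.null(probs) || nrow(probs) == 0L) {
      stop2("motif '", id, "': empty probability matrix")
    }
    if (!is.na(w) && nrow(probs) != w) {
      stop2("motif '", id, "': header says w=", w, " but ", nrow(probs),
            " rows were found")
    }
    sums <- rowSums(probs)
    if (any(abs(sums - 1) > 1e-3 + 1e-9) || any(probs < 0)) {
      stop2("motif '", id, "': probability rows must be non-negative and ",
            "sum to 1 within 1e-3")
    }
    probs <- probs / sums
    colnames(probs) <- DNA_BASES
    motifs[[k]] <- list(id = id, name = name, width = nrow(probs),
                        probs = probs, nsites = nsites)
  }
  list(motifs = motifs, background = background)
}

#' Write motifs to MEME minimal format
#'
#' @param motifs List of motif objects as returned by [parse_meme()] or
#'   [make_motif_set()].
#' @param background Length-4 background probabilities (A, C, G, T).
#' @param file Optional output path; when `NULL` the text is returned
#'   invisibly as a single string.
#' @return The MEME text, invisibly when written to `file`.
#' @export
write_meme <- function(motifs, background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                       file = NULL) {
  background <- background / sum(background)
  out <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f",
            background[1], background[2], background[3], background[4]),
    ""
  )
  for (m in motifs) {
    out <- c(out,
             paste("MOTIF", m$id, m$name %||% m$id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %s E= 0",
                     nrow(m$probs),
                     if (is.null(m$nsites) || is.na(m$nsites)) "20"
                     else format(m$nsites)),
             apply(m$probs, 1L, function(r) {
               sprintf("%.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])
             }),
             "")
  }
  text <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(text))
  }
  text
}
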