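#' Genomic interval containers
#'
#' Intervals are plain data.frames with columns `chrom`, `start`, `end`
#' (0-based, half-open, the BED convention used throughout the package),
#' `name`, `summit` (absolute offset or `NA`) and `strand` (`+`, `-` or
#' `*`). Class labels live in a separate two-column data.frame
#' (`name`, `label`) so that one element may carry several labels
#' (pleiotropic CREs).
#'
#' @param chrom,start,end,name,summit,strand Vectors (recycled) defining
#'   the intervals.
#' @return A validated interval data.frame.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL,
                              summit = NA, strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  if (is.null(name)) name <- sprintf("iv_%d", seq_len(n))
  out <- data.frame(chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    name = as.character(name),
                    summit = as.integer(summit),
                    strand = as.character(strand),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0L) || any(out$start >= out$end)) {
    stop2("intervals must satisfy 0 <= start < end")
  }
  bad <- !is.na(out$summit) &
    (out$summit < out$start | out$summit >= out$end)
  if (any(bad)) {
    stop2("summit outside [start, end) for: ",
          paste(out$name[bad], collapse = ", "))
  }
  if (anyDuplicated(out$name)) stop2("interval names must be unique")
  out
}

as_iranges_by_chrom <- function(iv) {
  split(IRanges::IRanges(start = iv$start + 1L, end = iv$end,
                         names = iv$name),
        iv$chrom)
}

#' Read and write BED6 interval files
#'
#' BED columns chrom, start, end, name, score, strand are mapped onto the
#' package's interval data.frame; the score column carries the summit as an
#' absolute offset when non-zero, `NA` otherwise.
#'
#' @param file Path to a BED file.
#' @return Interval data.frame.
#' @export
read_bed <- function(file) {
  x <- utils::read.table(file, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  ncol_x <- ncol(x)
  genomic_intervals(
    chrom = x[[1]], start = x[[2]], end = x[[3]],
    name = if (ncol_x >= 4L) x[[4]] else NULL,
    summit = if (ncol_x >= 5L) ifelse(x[[5]] > 0, x[[5]], NA) else NA,
    strand = if (ncol_x >= 6L) ifelse(x[[6]] %in% c("+", "-"), x[[6]], "*")
             else "*")
}

#' @rdname read_bed
#' @param intervals Interval data.frame.
#' @export
write_bed <- function(intervals, file) {
  out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    intervals$name,
                    ifelse(is.na(intervals$summit), 0L, intervals$summit),
                    ifelse(intervals$strand %in% c("+", "-"),
                           intervals$strand, "."))
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a name-to-label table
#'
#' Two-column TSV (`name`, `label`); a name may appear on several rows
#' (multilabel elements).
#'
#' @param file Path to the TSV.
#' @return data.frame with columns `name`, `label`.
#' @export
read_labels <- function(file) {
  x <- utils::read.table(file, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  names(x)[1:2] <- c("name", "label")
  x
}

#' Extract gene annotation (TSS and exons) from GTF/GFF3
#'
#' Reads an annotation file with \pkg{rtracklayer} and collects per-gene /
#' per-transcript transcription start sites and the union of all annotated
#' exons, converted to the package's 0-based half-open convention.
#'
#' @param file Path to a GTF or GFF3 file.
#' @return A list with `tss` (data.frame `chrom`, `pos`; 0-based base
#'   offsets) and `exons` (interval-style data.frame `chrom`, `start`,
#'   `end`).
#' @export
read_gene_annotation <- function(file) {
  gr <- rtracklayer::import(file)
  type <- as.character(gr$type %||% rep("exon", length(gr)))
  tx <- gr[type %in% c("transcript", "mRNA", "gene")]
  if (!length(tx)) tx <- gr
  tss_pos <- ifelse(as.character(GenomicRanges::strand(tx)) == "-",
                    GenomicRanges::end(tx) - 1L,
                    GenomicRanges::start(tx) - 1L)
  tss <- unique(data.frame(chrom = as.character(GenomicRanges::seqnames(tx)),
                           pos = as.integer(tss_pos),
                           stringsAsFactors = FALSE))
  ex <- gr[type == "exon"]
  exons <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                      start = GenomicRanges::start(ex) - 1L,
                      end = GenomicRanges::end(ex),
                      stringsAsFactors = FALSE)
  list(tss = tss, exons = exons)
}

#' Extract interval sequences from a genome
#'
#' @param genome Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param intervals Interval data.frame (0-based half-open coordinates).
#' @return Named uppercase character vector, one sequence of length
#'   `end - start` per interval; characters restricted to A, C, G, T, N.
#' @export
load_sequences <- function(genome, intervals) {
  seqs <- if (inherits(genome, "DNAStringSet")) genome
          else Biostrings::readDNAStringSet(genome)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(intervals$chrom), names(seqs))
  if (length(missing)) {
    stop2("chromosome(s) not in genome: ", paste(missing, collapse = ", "))
  }
  lens <- Biostrings::width(seqs)[match(intervals$chrom, names(seqs))]
  bad <- intervals$start < 0L | intervals$end > lens
  if (any(bad)) {
    stop2("interval(s) out of chromosome bounds: ",
          paste(intervals$name[bad], collapse = ", "))
  }
  out <- as.character(Biostrings::subseq(
    seqs[intervals$chrom], start = intervals$start + 1L,
    end = intervals$end))
  out <- toupper(out)
  if (any(grepl("[^ACGTN]", out))) {
    out <- gsub("[^ACGTN]", "N", out)
  }
  names(out) <- intervals$name
  out
}

#' Define distal, non-exonic, fixed-width CRE windows
#'
#' Centers each peak to a fixed-width window (on the summit when present,
#' else the interval midpoint) and removes windows that lie within
#' `min_tss_distance` of any transcription start site (measured from the
#' window edges: every base must be more than `min_tss_distance` away),
#' overlap any annotated exon, or extend past a chromosome end.
#'
#' @param intervals Interval data.frame of candidate peaks.
#' @param annotation Gene annotation list from [read_gene_annotation()].
#' @param min_tss_distance Minimum distance in bases from any window base
#'   to every TSS (default 1000; the study's ">1 kb" rule).
#' @param width Fixed window width in bases (default 500).
#' @param chrom_sizes Optional named vector of chromosome lengths; windows
#'   running past an end are dropped.
#' @return Interval data.frame of fixed-width windows (names preserved).
#' @export
define_cres <- function(intervals, annotation, min_tss_distance = 1000L,
                        width = 500L, chrom_sizes = NULL) {
  anchor <- ifelse(!is.na(intervals$summit), intervals$summit,
                   (intervals$start + intervals$end) %/% 2L)
  half <- width %/% 2L
  win_start <- as.integer(anchor - half)
  win_end <- win_start + as.integer(width)

  keep <- win_start >= 0L
  if (!is.null(chrom_sizes)) {
    lens <- chrom_sizes[intervals$chrom]
    keep <- keep & !is.na(lens) & win_end <= lens
  }

  # distal filter: min over TSS of distance from the nearest window base
  tss <- annotation$tss
  for (i in which(keep)) {
    tp <- tss$pos[tss$chrom == intervals$chrom[i]]
    if (!length(tp)) next
    d <- pmax(0L, pmax(win_start[i] - tp, tp - (win_end[i] - 1L)))
    if (min(d) <= min_tss_distance) keep[i] <- FALSE
  }

  # non-exonic filter: zero overlap with any annotated exon
  ex <- annotation$exons
  if (nrow(ex) > 0L && any(keep)) {
    ki <- which(keep)
    win_gr <- GenomicRanges::GRanges(
      intervals$chrom[ki],
      IRanges::IRanges(start = win_start[ki] + 1L, end = win_end[ki]))
    ex_gr <- GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(start = ex$start + 1L, end = ex$end))
    hit <- GenomicRanges::countOverlaps(win_gr, ex_gr) > 0L
    keep[ki[hit]] <- FALSE
  }

  if (!any(keep)) {
    warning("no CRE windows survive the distal/non-exonic filters")
  }
  out <- intervals[keep, , drop = FALSE]
  out$start <- win_start[keep]
  out$end <- win_end[keep]
  rownames(out) <- NULL
  out
}

#' Tile flanking negative windows around CREs
#'
#' Slides fixed-width windows with a given stride across the regions
#' `[start - span, start)` and `[end, end + span)` of each CRE (anchored on
#' the original interval), then discards every window that overlaps ANY CRE
#' in the input set.
#'
#' @param cres Interval data.frame of CREs.
#' @param span Flank span in bases on each side (default 2000).
#' @param width Window width (default 500).
#' @param stride Window stride (default 50).
#' @return Interval data.frame of negative windows; names record the
#'   source CRE and side/offset.
#' @export
flanking_negatives <- function(cres, span = 2000L, width = 500L,
                               stride = 50L) {
  if (nrow(cres) == 0L) stop2("flanking_negatives requires at least one CRE")
  if (span < width) stop2("span must be >= width")
  rows <- vector("list", nrow(cres))
  for (i in seq_len(nrow(cres))) {
    up0 <- cres$start[i] - span
    up_starts <- seq.int(up0, cres$start[i] - width, by = stride)
    up_starts <- up_starts[up_starts >= up0 &
                             up_starts + width <= cres$start[i]]
    dn0 <- cres$end[i]
    dn_starts <- seq.int(dn0, dn0 + span - width, by = stride)
    starts <- c(up_starts, dn_starts)
    starts <- starts[starts >= 0L]
    if (!length(starts)) next
    side <- c(rep("up", sum(starts < cres$start[i])),
              rep("dn", sum(starts >= cres$start[i])))
    rows[[i]] <- data.frame(
      chrom = cres$chrom[i], start = as.integer(starts),
      end = as.integer(starts + width),
      name = sprintf("%s_flank_%s_%d", cres$name[i], side,
                     as.integer(starts)),
      summit = NA_integer_, strand = "*", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    warning("no flanking windows could be constructed")
    return(genomic_intervals(character(0), integer(0), integer(0) + 1L)[0, ])
  }
  # drop windows overlapping ANY input CRE
  win_gr <- GenomicRanges::GRanges(
    out$chrom, IRanges::IRanges(start = out$start + 1L, end = out$end))
  cre_gr <- GenomicRanges::GRanges(
    cres$chrom, IRanges::IRanges(start = cres$start + 1L, end = cres$end))
  ov <- GenomicRanges::countOverlaps(win_gr, cre_gr) > 0L
  out <- out[!ov, , drop = FALSE]
  out <- out[!duplicated(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param file Output path.
#' @export
write_fasta <- function(sequences, file) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), file)
}
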