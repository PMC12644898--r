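#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All seeded operations in the package route through this.
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Encode an uppercase DNA string as integers A=1, C=2, G=3, T=4, other
# (N and ambiguity codes) = 0.
encode_dna <- function(seq) {
  codes <- integer(256)
  codes[utf8ToInt("A")] <- 1L
  codes[utf8ToInt("C")] <- 2L
  codes[utf8ToInt("G")] <- 3L
  codes[utf8ToInt("T")] <- 4L
  codes[utf8ToInt(seq)]
}

decode_dna <- function(x) {
  stopifnot(all(x >= 1L & x <= 4L))
  paste(DNA_BASES[x], collapse = "")
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
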