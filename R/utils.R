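# Small internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                a = "t", c = "g", g = "c", t = "a", N = "N", n = "n")

#' Reverse complement of a nucleotide string
#'
#' Case is preserved; `N` maps to `N`.
#'
#' @param x a nucleotide string (character scalar or vector).
#' @return the reverse complement(s), same case pattern reversed.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    comp <- COMPLEMENT[ch]
    if (anyNA(comp)) {
      bad <- unique(ch[is.na(comp)])
      stop("invalid nucleotide character(s): ", paste(bad, collapse = ", "))
    }
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Split a string into single characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Validate an ACGT-only sequence; returns the uppercased string or errors
# naming the offending character.  `min_len` guards operations (e.g. the NN
# Tm model) that are undefined for very short oligos.
check_dna <- function(seq, min_len = 1L, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string")
  }
  up <- toupper(seq)
  ch <- chars(up)
  bad <- setdiff(unique(ch), DNA_BASES)
  if (length(bad) > 0L) {
    stop("invalid ", what, ": character(s) ", paste(bad, collapse = ", "),
         " not in {A,C,G,T}")
  }
  if (nchar(up) < min_len) {
    stop("invalid ", what, ": length ", nchar(up), " < minimum ", min_len)
  }
  up
}

# Round half away from zero at `digits` decimals (Tm values are reported to
# 0.1 degC, round-half-up, unlike base round()'s banker's rounding).
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Deterministic per-run RNG scope: evaluate `expr` under `seed` and restore
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
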