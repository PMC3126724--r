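# In-silico mispriming screen: a self-contained stand-in for database
# homology searches and empirical no-amplification tests.  A primer is
# considered able to prime where its 3'-terminal seed matches the template
# exactly and the rest of the primer carries at most a capped number of
# mismatches -- the PCR-relevant question, asked directly, rather than a
# local-alignment E-value.
#
# Coordinates are 0-based half-open internally; written TSV output is
# 1-based inclusive and BED output stays 0-based half-open.

as_seq_collection <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else if (is.character(sequences)) {
    out <- sequences
  } else {
    stop("sequences must be a named character vector or a DNAStringSet")
  }
  if (is.null(names(out)) || any(names(out) == "")) {
    stop("all sequences must be named (seq_id)")
  }
  out
}

#' Find potential priming sites for a primer on background sequences
#'
#' Exact-match index on the primer's 3'-terminal `seed_len`-mer (both
#' strands), extended over the full primer length with `N` never matching.
#' A site is reported when the perfect match anchored at the primer 3'
#' terminus is at least `seed_len` and total mismatches are at most
#' `max_mismatches`.
#'
#' @param primer nucleotide string (length >= `seed_len`).
#' @param sequences named character vector or `Biostrings::DNAStringSet` of
#'   background sequences.
#' @param seed_len exact 3'-seed length (default 8 nt: one more than the
#'   7-nt split segments that cannot prime).
#' @param max_mismatches mismatch cap outside the seed (default 2).
#' @return data.frame of class `priming_sites` with columns `seq_id`,
#'   `start`, `end` (0-based half-open, forward strand), `strand`,
#'   `three_prime_match`, `total_mismatches`, sorted by (seq_id, start).
#' @export
find_priming_sites <- function(primer, sequences, seed_len = 8L,
                               max_mismatches = 2L) {
  primer <- check_dna(primer, what = "primer")
  L <- nchar(primer)
  if (L < seed_len) {
    stop("primer length ", L, " is shorter than seed length ", seed_len)
  }
  seqs <- as_seq_collection(sequences)
  seed <- substr(primer, L - seed_len + 1L, L)
  pchars <- chars(primer)
  rc_primer <- revcomp(primer)
  rc_chars <- chars(rc_primer)
  rows <- list()
  for (sid in names(seqs)) {
    s <- toupper(seqs[[sid]])
    slen <- nchar(s)
    if (slen < L) next
    subject <- Biostrings::DNAString(s)
    schars <- NULL # lazily split
    # "+" sites: primer matches the forward strand text; 3' end at the right.
    hits <- Biostrings::start(Biostrings::matchPattern(seed, subject,
                                                       fixed = TRUE))
    for (h in hits) {
      start0 <- h - 1L + seed_len - L # 0-based window start
      if (start0 < 0L || start0 + L > slen) next
      if (is.null(schars)) schars <- chars(s)
      win <- schars[(start0 + 1L):(start0 + L)]
      mm <- sum(win != pchars | win == "N")
      if (mm <= max_mismatches) {
        neq <- which(win != pchars | win == "N")
        tpm <- if (length(neq)) L - max(neq) else L
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = sid, start = start0, end = start0 + L, strand = "+",
          three_prime_match = tpm, total_mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
    # "-" sites: reverse complement of the primer on the forward strand;
    # the primer's 3' end maps to the window start.
    rseed <- substr(rc_primer, 1L, seed_len)
    hits <- Biostrings::start(Biostrings::matchPattern(rseed, subject,
                                                       fixed = TRUE))
    for (h in hits) {
      start0 <- h - 1L
      if (start0 + L > slen) next
      if (is.null(schars)) schars <- chars(s)
      win <- schars[(start0 + 1L):(start0 + L)]
      mm <- sum(win != rc_chars | win == "N")
      if (mm <= max_mismatches) {
        neq <- which(win != rc_chars | win == "N")
        # on "-", primer position i aligns to window position L - i + 1
        tpm <- if (length(neq)) min(neq) - 1L else L
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = sid, start = start0, end = start0 + L, strand = "-",
          three_prime_match = tpm, total_mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), three_prime_match = integer(0),
               total_mismatches = integer(0), stringsAsFactors = FALSE)
  out <- out[out$three_prime_match >= seed_len, , drop = FALSE]
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "primer") <- primer
  attr(out, "params") <- list(seed_len = seed_len,
                              max_mismatches = max_mismatches)
  class(out) <- c("priming_sites", "data.frame")
  out
}

#' Predict amplicons from priming sites of a primer pool
#'
#' Finds sites for every primer and pairs each forward-strand site with each
#' reverse-strand site on the same sequence whose 3' ends converge, keeping
#' products up to `max_product` bp.
#'
#' @param forward_primers,reverse_primers named character vectors of primers
#'   (names become primer labels).  Both pools are site-scanned on both
#'   strands; any convergent +/- site pair (from either pool) is a candidate
#'   product, matching what a PCR tube would do.
#' @param sequences background collection as in [find_priming_sites()].
#' @param max_product maximum product length in bp (default 2000).
#' @param seed_len,max_mismatches site-scan parameters.
#' @return data.frame of class `amplicons` with columns `seq_id`,
#'   `fwd_primer`, `rev_primer`, `fwd_start`, `fwd_end`, `rev_start`,
#'   `rev_end` (0-based half-open) and `product_length`.
#' @export
predict_amplicons <- function(forward_primers, reverse_primers = NULL,
                              sequences, max_product = 2000L,
                              seed_len = 8L, max_mismatches = 2L) {
  pool <- c(forward_primers, reverse_primers)
  if (is.null(names(pool)) || any(names(pool) == "")) {
    stop("primers must be named")
  }
  pool <- pool[!duplicated(names(pool))]
  sites <- lapply(names(pool), function(nm) {
    s <- find_priming_sites(pool[[nm]], sequences, seed_len, max_mismatches)
    if (nrow(s)) s$primer <- nm
    s
  })
  sites <- sites[vapply(sites, nrow, integer(1)) > 0]
  sites <- if (length(sites)) do.call(rbind, sites) else NULL
  empty <- data.frame(seq_id = character(0), fwd_primer = character(0),
                      rev_primer = character(0), fwd_start = integer(0),
                      fwd_end = integer(0), rev_start = integer(0),
                      rev_end = integer(0), product_length = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(sites) || nrow(sites) == 0L) {
    class(empty) <- c("amplicons", "data.frame")
    return(empty)
  }
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(plus))) {
    f <- plus[i, ]
    cand <- minus[minus$seq_id == f$seq_id &
                    minus$end > f$start &        # forward.start < reverse.end
                    minus$start >= f$start &     # 3' ends converge
                    (minus$end - f$start) <= max_product, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      r <- cand[j, ]
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = f$seq_id, fwd_primer = f$primer, rev_primer = r$primer,
        fwd_start = f$start, fwd_end = f$end,
        rev_start = r$start, rev_end = r$end,
        product_length = r$end - f$start, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$seq_id, out$fwd_start, out$rev_end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("amplicons", "data.frame")
  out
}

#' Screen a tagged assay (or bare tag pool) for unintended amplification
#'
#' Wraps [find_priming_sites()] and [predict_amplicons()].  For a marker
#' assay the tagged forward and tailed reverse oligos are screened and
#' amplicons on the assay's annotated target sequence are counted as
#' intended; for a plain list/vector of oligos every predicted amplicon is
#' unintended.  The report passes iff zero unintended amplicons are found.
#'
#' @param x a `marker_assay` or a named character vector of oligos.
#' @param sequences background collection.
#' @param seed_len,max_mismatches,max_product scan parameters.
#' @return object of class `screen_report`: `pass`, `header` (notes the
#'   seed/mismatch stand-in for an empirical annealing gradient), `sites`
#'   (per-primer site counts), `amplicons`, `intended`, `unintended`.
#' @export
screen_assay <- function(x, sequences, seed_len = 8L, max_mismatches = 2L,
                         max_product = 2000L) {
  if (inherits(x, "marker_assay")) {
    primers <- c(toupper(x$tagged_forward), toupper(x$tailed_reverse))
    names(primers) <- paste0(x$name, c("_F", "_R"))
    target <- x$target_seq_id
  } else {
    primers <- unlist(x)
    if (is.null(names(primers))) names(primers) <- paste0("oligo", seq_along(primers))
    target <- NULL
  }
  amps <- predict_amplicons(primers, NULL, sequences, max_product,
                            seed_len, max_mismatches)
  intended <- if (!is.null(target)) amps[amps$seq_id == target, , drop = FALSE]
              else amps[0, , drop = FALSE]
  unintended <- if (!is.null(target)) amps[amps$seq_id != target, , drop = FALSE]
                else amps
  sites <- lapply(names(primers), function(nm)
    find_priming_sites(primers[[nm]], sequences, seed_len, max_mismatches))
  names(sites) <- names(primers)
  structure(list(
    pass = nrow(unintended) == 0L,
    header = sprintf(
      "in-silico screen: 3' seed %d nt exact + <= %d mismatches (stand-in for an empirical 52-56 degC annealing gradient)",
      seed_len, max_mismatches),
    sites = sites, amplicons = amps,
    intended = intended, unintended = unintended
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(x$header, "\n")
  cat(sprintf("Screen: %s (%d intended, %d unintended amplicon(s))\n",
              if (x$pass) "PASS" else "FAIL",
              nrow(x$intended), nrow(x$unintended)))
  if (nrow(x$unintended)) print(x$unintended)
  invisible(x)
}

#' Write priming sites as TSV (1-based inclusive) or BED (0-based half-open)
#'
#' @param sites a `priming_sites` data.frame.
#' @param path output file.
#' @param format `"tsv"` or `"bed"`; BED name is the primer label and score
#'   the mismatch count.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  primer <- attr(sites, "primer")
  label <- if (!is.null(sites$primer)) sites$primer else
    rep(if (is.null(primer)) "primer" else primer, nrow(sites))
  if (format == "tsv") {
    out <- data.frame(seq_id = sites$seq_id, start = sites$start + 1L,
                      end = sites$end, strand = sites$strand,
                      primer = label,
                      three_prime_match = sites$three_prime_match,
                      total_mismatches = sites$total_mismatches)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(chrom = sites$seq_id, chromStart = sites$start,
                      chromEnd = sites$end, name = label,
                      score = sites$total_mismatches, strand = sites$strand)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write predicted amplicons as TSV (1-based inclusive coordinates)
#'
#' @param amps an `amplicons` data.frame.
#' @param path output file.
#' @export
write_amplicons <- function(amps, path) {
  out <- data.frame(seq_id = amps$seq_id, fwd_primer = amps$fwd_primer,
                    rev_primer = amps$rev_primer,
                    start = amps$fwd_start + 1L, end = amps$rev_end,
                    product_length = amps$product_length)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
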