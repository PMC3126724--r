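# Shared helpers and independent oracles used across the suite.
# Oracles are deliberately naive (character loops, full scans) so they stay
# independent of the production code paths they check.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force base-by-base duplex comparator: compares probe against the
# reverse complement of the template site one character at a time
oracle_duplex <- function(probe, template_site) {
  pb <- strsplit(probe, "")[[1]]
  target <- strsplit(revcomp(template_site), "")[[1]]
  n <- length(pb)
  mm <- integer(0)
  for (i in seq_len(n)) if (pb[i] != target[i]) mm <- c(mm, i)
  longest <- 0L
  run <- 0L
  for (i in seq_len(n)) {
    if (i %in% mm) run <- 0L else run <- run + 1L
    if (run > longest) longest <- run
  }
  anchored <- 0L
  for (i in n:1) {
    if (i %in% mm) break
    anchored <- anchored + 1L
  }
  list(mismatch_positions = mm, total_mismatches = length(mm),
       three_prime_anchored_run = anchored, longest_contiguous_run = longest)
}

# brute-force priming-site scan: slide the primer over every position on
# both strands, count mismatches and the 3'-anchored perfect run directly
oracle_scan <- function(primer, seqs, seed_len = 8L, max_mismatches = 2L) {
  L <- nchar(primer)
  pch <- strsplit(primer, "")[[1]]
  rch <- strsplit(revcomp(primer), "")[[1]]
  rows <- list()
  for (sid in names(seqs)) {
    sch <- strsplit(toupper(seqs[[sid]]), "")[[1]]
    slen <- length(sch)
    if (slen < L) next
    npos <- slen - L + 1L
    for (strand in c("+", "-")) {
      ref <- if (strand == "+") pch else rch
      mmcount <- integer(npos)
      lastmm <- integer(npos) # primer-coordinate position of the 3'-most mismatch
      for (j in seq_len(L)) {
        bad <- sch[j:(j + npos - 1L)] != ref[j] | sch[j:(j + npos - 1L)] == "N"
        mmcount <- mmcount + bad
        # primer coordinate of window column j
        pj <- if (strand == "+") j else L - j + 1L
        if (strand == "+") {
          lastmm[bad] <- pmax(lastmm[bad], pj)
        } else {
          lastmm[bad] <- pmax(lastmm[bad], pj)
        }
      }
      tpm <- L - lastmm
      keep <- which(mmcount <= max_mismatches & tpm >= seed_len)
      for (p in keep) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = sid, start = p - 1L, end = p - 1L + L, strand = strand,
          three_prime_match = tpm[p], total_mismatches = mmcount[p],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), three_prime_match = integer(0),
               total_mismatches = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random sequence-specific core with Tm comfortably above the tag window
random_hot_core <- function(conditions, min_tm = 58, len = 22L) {
  repeat {
    core <- random_seq(len)
    if (melt_temp(core, conditions) >= min_tm) return(core)
  }
}

# calibration fitted once per test run (grid search is cheap but not free)
cached_calibration <- local({
  cal <- NULL
  function() {
    if (is.null(cal)) cal <<- calibrate_conditions(published_tag_table())
    cal
  }
})
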