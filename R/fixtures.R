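# Seeded fixture generator: synthetic background "genomes" with optionally
# planted primer-binding sites, SSR loci and biallelic SNPs, plus truth
# tables.  Everything is deterministic per seed, so screens and simulations
# are testable offline; the default of 12 backgrounds emulates a screen
# against a dozen unrelated plant genomes.

#' Specification for synthetic screening fixtures
#'
#' @param seed integer RNG seed; identical (seed, spec) pairs produce
#'   byte-identical output files.
#' @param n_backgrounds number of background sequences (default 12).
#' @param background_length length of each background in bp.
#' @param planted list of planted loci, each a list with a `type` of
#'   `"primer_site"` (fields `oligo`, `background`, `pos`, `strand`),
#'   `"ssr"` (fields `fwd_core`, `rev_core`, `motif`, `reps`, `background`,
#'   `pos`) or `"insert"` (fields `seq`, `background`, `pos`).  Positions
#'   are 1-based; planted material overwrites the background in place.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_backgrounds = 12L,
                         background_length = 20000L, planted = list()) {
  stopifnot(n_backgrounds >= 1L, background_length >= 100L)
  structure(list(seed = as.integer(seed),
                 n_backgrounds = as.integer(n_backgrounds),
                 background_length = as.integer(background_length),
                 planted = planted),
            class = "fixture_spec")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

plant_into <- function(seq, insert, pos) {
  if (pos < 1L || pos + nchar(insert) - 1L > nchar(seq)) {
    stop("planted locus (", nchar(insert), " bp at ", pos,
         ") does not fit in background of ", nchar(seq), " bp")
  }
  paste0(substr(seq, 1L, pos - 1L), insert,
         substr(seq, pos + nchar(insert), nchar(seq)))
}

#' Generate synthetic background sequences with planted loci
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory; when given, writes
#'   `backgrounds.fasta` and `truth.tsv` (1-based inclusive coordinates).
#' @return list with `sequences` (named character) and `truth` (data.frame:
#'   `background`, `type`, `start`, `end`, `strand`, `payload`).
#' @export
make_fixtures <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  seqs <- with_seed(spec$seed, {
    out <- vapply(seq_len(spec$n_backgrounds), function(i)
      random_dna(spec$background_length), character(1))
    names(out) <- sprintf("background_%02d", seq_len(spec$n_backgrounds))
    out
  })
  truth <- list()
  note <- function(bg, type, start, len, strand, payload) {
    truth[[length(truth) + 1L]] <<- data.frame(
      background = bg, type = type, start = start, end = start + len - 1L,
      strand = strand, payload = payload, stringsAsFactors = FALSE)
  }
  for (p in spec$planted) {
    bg <- names(seqs)[p$background]
    if (p$type == "primer_site") {
      ins <- if (identical(p$strand, "-")) revcomp(toupper(p$oligo))
             else toupper(p$oligo)
      seqs[[bg]] <- plant_into(seqs[[bg]], ins, p$pos)
      note(bg, "primer_site", p$pos, nchar(ins),
           if (identical(p$strand, "-")) "-" else "+", toupper(p$oligo))
    } else if (p$type == "ssr") {
      ins <- paste0(toupper(p$fwd_core),
                    strrep(toupper(p$motif), p$reps),
                    revcomp(toupper(p$rev_core)))
      seqs[[bg]] <- plant_into(seqs[[bg]], ins, p$pos)
      note(bg, "ssr", p$pos, nchar(ins), "+",
           sprintf("%sx%d:%s/%s", toupper(p$motif), p$reps,
                   toupper(p$fwd_core), toupper(p$rev_core)))
    } else if (p$type == "insert") {
      seqs[[bg]] <- plant_into(seqs[[bg]], toupper(p$seq), p$pos)
      note(bg, "insert", p$pos, nchar(p$seq), "+", toupper(p$seq))
    } else {
      stop("unknown planted locus type: ", p$type)
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(background = character(0), type = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               payload = character(0), stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(seqs, file.path(dir, "backgrounds.fasta"))
    utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(sequences = seqs, truth = truth_df)
}
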