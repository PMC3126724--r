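# Assembly of tagged SSR/indel assays and APLP-style ASO+LSO SNP assays.
#
# Rendering convention: sequence-specific cores are uppercase; the reverse
# pig-tail and introduced destabilizing mismatches are lowercase.  Re-writing
# a parsed assay reproduces the printed oligo byte-for-byte.

#' Attach a split tag to the 5' end of a forward core primer
#'
#' @param tag a [split_tag].
#' @param forward_core sequence-specific forward primer (>= 15 nt, ACGT).
#' @return the tagged oligo (tag + core).  A warning (not an error) is
#'   raised when the core contains the tag's own 3'-terminal 8-mer, a
#'   self-priming risk.
#' @export
attach_tag <- function(tag, forward_core) {
  stopifnot(inherits(tag, "split_tag"))
  core <- check_dna(forward_core, min_len = 15L, what = "forward core")
  tail8 <- substr(tag$full_seq, 9L, 16L)
  if (grepl(tail8, core, fixed = TRUE)) {
    warning("forward core contains the tag's 3'-terminal 8-mer (", tail8,
            "): self-priming risk")
  }
  paste0(tag$full_seq, core)
}

#' Prepend the pig-tail to a reverse core primer
#'
#' The tail is rendered lowercase and the core uppercase, preserving the
#' printed convention.
#'
#' @param reverse_core sequence-specific reverse primer (ACGT).
#' @param tail 5' extension promoting uniform non-templated adenylation
#'   (default `"gtttctt"`).
#' @return the tailed oligo.
#' @export
pigtail <- function(reverse_core, tail = "gtttctt") {
  core <- check_dna(reverse_core, what = "reverse core")
  if (nchar(tail)) check_dna(tail, what = "pig-tail")
  paste0(tolower(tail), core)
}

#' Assemble a tagged SSR/indel marker assay
#'
#' Builds the tagged forward and tailed reverse oligos and enforces the
#' Tm-gap invariant: the core forward primer must melt at least `min_gap`
#' degC above the tag, confining labeling to the low-temperature stage.
#' Cores whose amplification fails in practice do so because this margin is
#' too small, hence the gap violation is a hard error, not a warning.
#'
#' @param name marker name.
#' @param forward_core,reverse_core sequence-specific primer cores (ACGT).
#' @param tag a [split_tag].
#' @param dye dye label (e.g. "6-FAM", "VIC", "NED", "PET").
#' @param conditions [thermo_conditions] for Tm computation.
#' @param min_gap required core-minus-tag Tm margin in degC (default 6).
#' @param tail pig-tail for the reverse primer.
#' @param expected_size_range optional [min, max] bp of the untagged product.
#' @param motif optional repeat-motif annotation.
#' @param ddbj_id,target_seq_id optional metadata (accession; annotated
#'   target sequence for specificity screens).
#' @return object of class `marker_assay`.
#' @export
build_ssr_assay <- function(name, forward_core, reverse_core, tag, dye,
                            conditions = calibrated_conditions(),
                            min_gap = 6, tail = "gtttctt",
                            expected_size_range = NULL, motif = NULL,
                            ddbj_id = NULL, target_seq_id = NULL) {
  stopifnot(inherits(tag, "split_tag"))
  fc <- check_dna(forward_core, min_len = 15L, what = "forward core")
  rc <- check_dna(reverse_core, min_len = 15L, what = "reverse core")
  core_tm <- melt_temp(fc, conditions)
  tag_tm <- if (!is.na(tag$tm)) tag$tm else melt_temp(tag$full_seq, conditions)
  gap <- core_tm - tag_tm
  if (gap < min_gap) {
    stop(structure(class = c("bstag_tm_gap", "error", "condition"),
                   list(message = sprintf(
                     "Tm gap violation for %s: core Tm %.1f - tag Tm %.1f = %.1f degC < required %.1f (insufficient-amplification risk)",
                     name, core_tm, tag_tm, gap, min_gap),
                     call = sys.call(), core_tm = core_tm, tag_tm = tag_tm)))
  }
  structure(list(name = name, forward_core = fc, reverse_core = rc,
                 tag = tag, dye = dye, pigtail = tolower(tail),
                 tagged_forward = attach_tag(tag, fc),
                 tailed_reverse = pigtail(rc, tail),
                 core_tm = core_tm, tag_tm = tag_tm, tm_gap = gap,
                 expected_size_range = expected_size_range, motif = motif,
                 ddbj_id = ddbj_id, target_seq_id = target_seq_id),
            class = "marker_assay")
}

#' @export
print.marker_assay <- function(x, ...) {
  cat(sprintf("MarkerAssay %s [%s/%s]\n", x$name, x$tag$name, x$dye))
  cat(sprintf("  forward: %s\n  reverse: %s\n", x$tagged_forward,
              x$tailed_reverse))
  cat(sprintf("  core Tm %.1f, tag Tm %.1f, gap %.1f degC\n",
              round_half_up(x$core_tm), round_half_up(x$tag_tm),
              round_half_up(x$tm_gap)))
  if (!is.null(x$expected_size_range)) {
    cat(sprintf("  expected product: %d-%d bp (untagged)\n",
                x$expected_size_range[1], x$expected_size_range[2]))
  }
  invisible(x)
}

#' Check a sequence for long G/C runs
#'
#' Locally GC-rich stretches are too stable for allele-specific
#' discrimination; a maximal run of G and/or C longer than `max_run` fails.
#'
#' @param seq nucleotide string (case ignored).
#' @param max_run longest acceptable G/C run (default 5).
#' @return list `pass`, `max_run_found`, `at` (1-based start of the longest
#'   run).
#' @export
gc_run_check <- function(seq, max_run = 5L) {
  up <- check_dna(seq, what = "sequence")
  mask <- chars(up) %in% c("G", "C")
  r <- rle(mask)
  gc_runs <- r$lengths[r$values]
  longest <- if (length(gc_runs)) max(gc_runs) else 0L
  at <- NA_integer_
  if (longest > 0L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- which(r$values & r$lengths == longest)[1L]
    at <- starts[i]
  }
  list(pass = longest <= max_run, max_run_found = as.integer(longest),
       at = at)
}

# offsets (distance upstream of the 3'-terminal SNP base) of lowercase
# letters marking introduced mismatches in an ASO core
mismatch_offset_from_case <- function(core) {
  ch <- chars(core)
  lower <- which(ch %in% letters)
  as.integer(nchar(core) - lower)
}

#' Design an allele-specific (ASO) primer pair plus locus-specific (LSO) primer
#'
#' Implements the APLP-style design rules: each ASO ends 3' in its allele
#' base; a destabilizing mismatch is introduced at the closest template G/C
#' within 1-6 nt upstream of the SNP base, replacing it by its transversion
#' partner (G->T, C->A) rendered lowercase; candidates with G/C runs longer
#' than `max_gc_run` are rejected; the second allele's core is extended by
#' one template base at its 5' end so the two tagged oligos differ in length
#' by exactly 1 bp; the LSO is a pig-tailed reverse-orientation primer on the
#' flank downstream of the SNP.
#'
#' @param template genomic template string (ACGT), forward strand.
#' @param snp_pos 1-based position of the SNP base in `template`.
#' @param alleles two distinct allele bases at the SNP.
#' @param tags list of two distinct [split_tag] objects (allele order).
#' @param dyes two dye labels (allele order).
#' @param conditions [thermo_conditions] for core Tm targeting.
#' @param min_core_tm extend the ASO core 5'-ward until its Tm reaches this
#'   value (degC, default 57).
#' @param min_core_len,max_core_len ASO core length bounds (nt).
#' @param max_gc_run passed to [gc_run_check()].
#' @param lso_len LSO core length (nt, default 22).
#' @param tail pig-tail for the LSO.
#' @return object of class `snp_assay` with fields `name`, `lso`,
#'   `snp_alleles` and `aso` (two records: `allele`, `core` (mixed case),
#'   `tag`, `dye`, `tagged`, `introduced_mismatch_offset`).
#' @export
design_aso_pair <- function(template, snp_pos, alleles, tags, dyes,
                            conditions = calibrated_conditions(),
                            min_core_tm = 57, min_core_len = 16L,
                            max_core_len = 30L, max_gc_run = 5L,
                            lso_len = 22L, tail = "gtttctt",
                            name = "snp") {
  tpl <- check_dna(template, what = "template")
  n <- nchar(tpl)
  if (snp_pos < 1L || snp_pos > n) stop("snp_pos outside template")
  if (length(alleles) != 2L || alleles[1] == alleles[2]) {
    stop("exactly two distinct alleles required")
  }
  alleles <- toupper(alleles)
  if (tags[[1]]$full_seq == tags[[2]]$full_seq) {
    stop("the two ASO tags must be distinct")
  }
  if (snp_pos - 1L < 25L) {
    stop("upstream flank too short (< 25 bp) for ASO design")
  }
  if (n - snp_pos < lso_len) {
    stop("downstream flank too short for LSO design")
  }
  # destabilizer: nearest template G/C at offsets 1..6 upstream of the SNP
  up_window <- chars(substr(tpl, snp_pos - 6L, snp_pos - 1L))
  offs <- 6L:1L # window is printed 5'->3'; offset = distance upstream
  gc_at <- rev(up_window) %in% c("G", "C") # index = offset
  if (!any(gc_at)) {
    stop(structure(class = c("bstag_no_destabilizer", "error", "condition"),
                   list(message = paste0(
                     "no G/C within 6 nt upstream of the SNP at position ",
                     snp_pos, ": cannot introduce a destabilizing mismatch"),
                     call = sys.call())))
  }
  offset <- which(gc_at)[1L] # smallest offset
  tpl_base <- substr(tpl, snp_pos - offset, snp_pos - offset)
  sub_base <- tolower(if (tpl_base == "G") "T" else "A") # transversion partner
  # core length: extend 5'-ward until Tm (computed on the modified core)
  build_core <- function(len, allele) {
    start <- snp_pos - len + 1L
    if (start < 1L) return(NULL)
    core <- chars(substr(tpl, start, snp_pos))
    core[len] <- allele
    core[len - offset] <- sub_base
    paste(core, collapse = "")
  }
  len <- min_core_len
  core1 <- build_core(len, alleles[1])
  while (!is.null(core1) && len < max_core_len &&
         melt_temp(toupper(core1), conditions) < min_core_tm) {
    len <- len + 1L
    core1 <- build_core(len, alleles[1])
  }
  if (is.null(core1)) stop("upstream flank too short to reach the core Tm target")
  chk <- gc_run_check(core1, max_gc_run)
  if (!chk$pass) {
    stop(structure(class = c("bstag_gc_run", "error", "condition"),
                   list(message = sprintf(
                     "ASO candidate rejected: G/C run of %d (> %d) at position %d",
                     chk$max_run_found, max_gc_run, chk$at),
                     call = sys.call())))
  }
  # second allele: one extra 5' template base => tagged lengths differ by 1
  core2 <- build_core(len + 1L, alleles[2])
  if (is.null(core2)) stop("upstream flank too short for the staggered allele core")
  chk2 <- gc_run_check(core2, max_gc_run)
  if (!chk2$pass) {
    stop(structure(class = c("bstag_gc_run", "error", "condition"),
                   list(message = sprintf(
                     "staggered ASO candidate rejected: G/C run of %d (> %d)",
                     chk2$max_run_found, max_gc_run),
                     call = sys.call())))
  }
  # LSO: reverse-orientation primer on the downstream flank
  lso_core <- revcomp(substr(tpl, n - lso_len + 1L, n))
  aso <- list(
    list(allele = alleles[1], core = core1, tag = tags[[1]], dye = dyes[1],
         tagged = paste0(tags[[1]]$full_seq, core1),
         introduced_mismatch_offset = offset),
    list(allele = alleles[2], core = core2, tag = tags[[2]], dye = dyes[2],
         tagged = paste0(tags[[2]]$full_seq, core2),
         introduced_mismatch_offset = offset))
  structure(list(name = name, lso = pigtail(lso_core, tail),
                 snp_alleles = alleles, aso = aso),
            class = "snp_assay")
}

#' @export
print.snp_assay <- function(x, ...) {
  cat(sprintf("SnpAssay %s (%s/%s)\n", x$name, x$snp_alleles[1],
              x$snp_alleles[2]))
  cat(sprintf("  LSO: %s\n", x$lso))
  for (a in x$aso) {
    cat(sprintf("  ASO/%s [%s/%s]: %s (mismatch offset %s)\n", a$allele,
                a$tag$name, a$dye, a$tagged,
                paste(a$introduced_mismatch_offset, collapse = ",")))
  }
  invisible(x)
}

#' Validate a SNP assay record
#'
#' Checks every invariant decidable without the genomic template: each ASO
#' core's 3' base equals its allele; annotated introduced-mismatch offsets
#' (lowercase letters) fall in 1-6; the two tags are distinct; tagged oligo
#' lengths differ by exactly 1 bp; each tagged oligo starts with its tag's
#' sequence.  The identity of the replaced base is not checked (it is not
#' decidable from the printed record alone).
#'
#' @param assay a `snp_assay` (from [design_aso_pair()] or parsed from an
#'   assay sheet).
#' @return list of class `snp_verdict`: `pass`, `reasons`, `tagged_lengths`.
#' @export
validate_snp_assay <- function(assay) {
  stopifnot(inherits(assay, "snp_assay"))
  reasons <- character(0)
  if (length(assay$aso) != 2L) {
    reasons <- c(reasons, "exactly two ASO records required")
  } else {
    for (a in assay$aso) {
      last <- toupper(substr(a$core, nchar(a$core), nchar(a$core)))
      if (last != toupper(a$allele)) {
        reasons <- c(reasons, sprintf(
          "ASO/%s 3' base %s does not equal the allele", a$allele, last))
      }
      offs <- a$introduced_mismatch_offset
      if (length(offs) == 0L) {
        reasons <- c(reasons, sprintf("ASO/%s has no annotated introduced mismatch",
                                      a$allele))
      } else if (any(offs < 1L | offs > 6L)) {
        reasons <- c(reasons, sprintf(
          "ASO/%s introduced mismatch offset(s) %s outside 1-6", a$allele,
          paste(offs, collapse = ",")))
      }
      if (!startsWith(toupper(a$tagged), a$tag$full_seq)) {
        reasons <- c(reasons, sprintf("ASO/%s tagged oligo does not start with tag %s",
                                      a$allele, a$tag$name))
      }
    }
    if (assay$aso[[1]]$tag$full_seq == assay$aso[[2]]$tag$full_seq) {
      reasons <- c(reasons, "the two ASO tags are identical")
    }
    lens <- vapply(assay$aso, function(a) nchar(a$tagged), integer(1))
    if (abs(diff(lens)) != 1L) {
      reasons <- c(reasons, sprintf(
        "tagged lengths %d and %d must differ by exactly 1 bp", lens[1], lens[2]))
    }
  }
  lens <- if (length(assay$aso) == 2L)
    vapply(assay$aso, function(a) nchar(a$tagged), integer(1)) else integer(0)
  structure(list(pass = length(reasons) == 0L, reasons = reasons,
                 tagged_lengths = lens, name = assay$name),
            class = "snp_verdict")
}

#' @export
print.snp_verdict <- function(x, ...) {
  cat(sprintf("SNP assay %s: %s (tagged lengths %s)\n", x$name,
              if (x$pass) "PASS" else "FAIL",
              paste(x$tagged_lengths, collapse = "/")))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' The two-stage PCR labeling protocol as data
#'
#' Stage 1 amplifies the target with the tagged (unlabeled) primers; stage 2
#' drops the annealing temperature so the labeled tag primer can extend on
#' single-stranded tagged product.
#'
#' @param stage1_cycles amplification cycles (default 31).
#' @param stage1_annealing annealing range in degC (default c(54, 62)).
#' @param stage2_cycles labeling cycles (default 3).
#' @param stage2_annealing labeling annealing temperature (default 49 degC).
#' @return list of class `pcr_protocol`.
#' @export
default_protocol <- function(stage1_cycles = 31L,
                             stage1_annealing = c(54, 62),
                             stage2_cycles = 3L, stage2_annealing = 49) {
  if (stage2_annealing >= min(stage1_annealing)) {
    stop("stage-2 annealing must be below stage-1 annealing")
  }
  structure(list(
    stage1 = list(denature_c = 94, denature_s = 180, cycles = stage1_cycles,
                  cycle_denature_s = 20, annealing_c = stage1_annealing,
                  annealing_s = 30),
    stage2 = list(cycles = stage2_cycles, denature_s = 20,
                  annealing_c = stage2_annealing, annealing_s = 10,
                  extension_c = 72, extension_s = 5),
    final_extension = list(temp_c = 72, minutes = 10),
    primer_pmol = c(reverse = 2, tagged_forward = 0.5, labeled_tag = 0.5)
  ), class = "pcr_protocol")
}
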