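# Bar-coded split tag (BStag) data model, validators and generator.
#
# A tag is a 16-nt oligo: a conserved 13-nt basal region broken at position 8
# by a variable "split" base, followed by a 3-nt bar-code whose 3'-terminal
# base is G or C (GC clamp).  Any two tags differ in the bar-code, so a
# mismatched tag/labeled-primer combination leaves at most a 2-nt
# 3'-anchored match and two sub-8-nt basal segments -- too short to prime.

#' Tag scaffold (conserved basal region)
#'
#' @param part5 the 7-nt 5' basal segment (positions 1-7).
#' @param part3 the 5-nt basal segment between split base and bar-code
#'   (positions 9-13).
#' @return object of class `bstag_scaffold`.
#' @export
bstag_scaffold <- function(part5 = "CTAGTAT", part3 = "AGGAC") {
  part5 <- check_dna(part5, what = "scaffold part5")
  part3 <- check_dna(part3, what = "scaffold part3")
  if (nchar(part5) != 7L) stop("scaffold part5 must be 7 nt, got ", nchar(part5))
  if (nchar(part3) != 5L) stop("scaffold part3 must be 5 nt, got ", nchar(part3))
  structure(list(part5 = part5, part3 = part3), class = "bstag_scaffold")
}

#' Construct a split tag from its parts
#'
#' @param split_base single nucleotide at position 8.
#' @param barcode 3-nt bar-code; its 3'-terminal base should be G or C
#'   (checked by [validate_tag()], not here).
#' @param scaffold a [bstag_scaffold()].
#' @param name tag label; defaults to `"F9"` + bar-code.
#' @param conditions optional [thermo_conditions] used to cache Tm.
#' @return object of class `split_tag` with fields `name`, `full_seq`,
#'   `scaffold5`, `split_base`, `scaffold3`, `barcode`, `tm`.
#' @export
split_tag <- function(split_base, barcode, scaffold = bstag_scaffold(),
                      name = NULL, conditions = NULL) {
  split_base <- check_dna(split_base, what = "split_base")
  barcode <- check_dna(barcode, what = "barcode")
  if (nchar(split_base) != 1L) stop("split_base must be a single nucleotide")
  if (nchar(barcode) != 3L) stop("barcode must be 3 nt, got ", nchar(barcode))
  full <- paste0(scaffold$part5, split_base, scaffold$part3, barcode)
  if (is.null(name)) name <- paste0("F9", barcode)
  tm <- if (!is.null(conditions)) melt_temp(full, conditions) else NA_real_
  structure(list(name = name, full_seq = full,
                 scaffold5 = scaffold$part5, split_base = split_base,
                 scaffold3 = scaffold$part3, barcode = barcode, tm = tm),
            class = "split_tag")
}

#' Parse a 16-nt sequence into a split tag
#'
#' Decomposes by fixed positions (1-7 scaffold, 8 split base, 9-13 scaffold,
#' 14-16 bar-code) and verifies the scaffold.
#'
#' @param seq 16-nt A/C/G/T string.
#' @param scaffold expected [bstag_scaffold()].
#' @param conditions optional [thermo_conditions] to cache Tm.
#' @param name optional label (default `"F9"` + bar-code).
#' @return a [split_tag] object.
#' @export
parse_tag <- function(seq, scaffold = bstag_scaffold(), conditions = NULL,
                      name = NULL) {
  up <- check_dna(seq, what = "tag sequence")
  if (nchar(up) != 16L) {
    stop("invalid tag sequence: length ", nchar(up), " != 16")
  }
  expect <- paste0(scaffold$part5, ".", scaffold$part3)
  got <- substr(up, 1L, 13L)
  ok <- chars(expect) == chars(got) | chars(expect) == "."
  if (!all(ok)) {
    stop("scaffold violation at position(s) ",
         paste(which(!ok), collapse = ", "),
         " (expected ", scaffold$part5, "N", scaffold$part3, ")")
  }
  split_tag(substr(up, 8L, 8L), substr(up, 14L, 16L), scaffold,
            name = name, conditions = conditions)
}

#' @export
print.split_tag <- function(x, ...) {
  cat(sprintf("SplitTag %s: 5'-%s|%s|%s|%s-3'%s\n",
              x$name, x$scaffold5, x$split_base, x$scaffold3, x$barcode,
              if (is.na(x$tm)) "" else sprintf(" (Tm %.1f degC)",
                                               round_half_up(x$tm))))
  invisible(x)
}

#' Structural and thermodynamic verdict for one tag
#'
#' Checks the GC clamp at the bar-code 3' terminus and that Tm falls inside
#' the working window (default 46-53 degC, bracketing the published set).
#'
#' @param tag a [split_tag]; its `tm` field must be set unless `conditions`
#'   is supplied.
#' @param tm_window numeric length-2, inclusive Tm bounds in degC.
#' @param conditions optional [thermo_conditions] to (re)compute Tm.
#' @return list of class `tag_verdict`: `pass` flag, `reasons` (character),
#'   `tm`.
#' @export
validate_tag <- function(tag, tm_window = c(46, 53), conditions = NULL) {
  stopifnot(inherits(tag, "split_tag"))
  tm <- if (!is.null(conditions)) melt_temp(tag$full_seq, conditions) else tag$tm
  reasons <- character(0)
  clamp <- substr(tag$barcode, 3L, 3L)
  if (!clamp %in% c("G", "C")) {
    reasons <- c(reasons, "3' clamp: bar-code must end in G or C")
  }
  if (is.na(tm)) {
    reasons <- c(reasons, "Tm not available (no conditions supplied)")
  } else if (tm < tm_window[1] || tm > tm_window[2]) {
    reasons <- c(reasons, sprintf("Tm %.1f degC outside window [%g, %g]",
                                  round_half_up(tm), tm_window[1], tm_window[2]))
  }
  structure(list(pass = length(reasons) == 0L, reasons = reasons, tm = tm,
                 name = tag$name),
            class = "tag_verdict")
}

#' Positions conserved across a tag set
#'
#' @param tags list of [split_tag] objects (>= 2), equal lengths.
#' @return sorted integer vector of 1-based positions identical in all tags.
#' @export
conserved_positions <- function(tags) {
  if (length(tags) < 2L) stop("need at least 2 tags")
  seqs <- vapply(tags, function(t) t$full_seq, character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("tags have unequal lengths")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  which(apply(mat, 2L, function(col) length(unique(col)) == 1L))
}

#' Pairwise discrimination policy
#'
#' @param min_weighted_score minimum 3'-weighted mismatch score between two
#'   tags (both orientations); default 3, the score of a single bar-code
#'   difference, chosen so every published pair passes.
#' @param require_barcode_diff must the bar-codes differ?  (A bar-code
#'   difference caps the 3'-anchored match at 2 nt.)
#' @return list of class `pair_policy`.
#' @export
pair_policy <- function(min_weighted_score = 3, require_barcode_diff = TRUE) {
  structure(list(min_weighted_score = min_weighted_score,
                 require_barcode_diff = require_barcode_diff),
            class = "pair_policy")
}

#' Can two tags be distinguished at the labeling stage?
#'
#' Scores tag A's probe against the template site a B-tagged product
#' presents (and vice versa).  Default pass rule: bar-codes differ and the
#' weighted mismatch score reaches the policy threshold in both orientations.
#'
#' @param tag_a,tag_b [split_tag] objects sharing a scaffold.
#' @param policy a [pair_policy()].
#' @return list of class `pair_report`: `pass`, `reasons`, `report_ab`,
#'   `report_ba` (both-orientation [duplex_score()] reports).
#' @export
pair_discrimination <- function(tag_a, tag_b, policy = pair_policy()) {
  stopifnot(inherits(tag_a, "split_tag"), inherits(tag_b, "split_tag"))
  if (tag_a$scaffold5 != tag_b$scaffold5 || tag_a$scaffold3 != tag_b$scaffold3) {
    stop("tags use different scaffolds: ", tag_a$name, " vs ", tag_b$name)
  }
  # a B-tagged product's complementary strand carries revcomp(B); probe A
  # anneals (or not) to that strand
  rep_ab <- duplex_score(tag_a$full_seq, revcomp(tag_b$full_seq))
  rep_ba <- duplex_score(tag_b$full_seq, revcomp(tag_a$full_seq))
  reasons <- character(0)
  if (policy$require_barcode_diff && tag_a$barcode == tag_b$barcode) {
    reasons <- c(reasons, "bar-codes identical")
  }
  sc <- min(rep_ab$weighted_score, rep_ba$weighted_score)
  if (sc < policy$min_weighted_score) {
    reasons <- c(reasons, sprintf("weighted score %g < threshold %g",
                                  sc, policy$min_weighted_score))
  }
  structure(list(pass = length(reasons) == 0L, reasons = reasons,
                 pair = c(tag_a$name, tag_b$name),
                 report_ab = rep_ab, report_ba = rep_ba),
            class = "pair_report")
}

#' Validate a whole tag set
#'
#' Aggregates [validate_tag()] over tags and [pair_discrimination()] over all
#' unordered pairs; the set passes iff every check passes.
#'
#' @param tags list of [split_tag] (>= 2).
#' @param policy a [pair_policy()].
#' @param tm_window passed to [validate_tag()].
#' @param conditions optional [thermo_conditions].
#' @return object of class `set_report`: `pass`, `tag_verdicts`,
#'   `pair_reports`, `min_pair_score`, `max_pair_run`.
#' @export
validate_set <- function(tags, policy = pair_policy(), tm_window = c(46, 53),
                         conditions = NULL) {
  if (length(tags) < 2L) stop("need at least 2 tags")
  tv <- lapply(tags, validate_tag, tm_window = tm_window,
               conditions = conditions)
  pairs <- utils::combn(length(tags), 2L, simplify = FALSE)
  pr <- lapply(pairs, function(ij) {
    pair_discrimination(tags[[ij[1]]], tags[[ij[2]]], policy)
  })
  scores <- vapply(pr, function(p)
    min(p$report_ab$weighted_score, p$report_ba$weighted_score), numeric(1))
  runs <- vapply(pr, function(p)
    max(p$report_ab$longest_contiguous_run,
        p$report_ba$longest_contiguous_run), numeric(1))
  structure(list(
    pass = all(vapply(tv, `[[`, logical(1), "pass")) &&
           all(vapply(pr, `[[`, logical(1), "pass")),
    tag_verdicts = tv, pair_reports = pr,
    min_pair_score = if (length(scores)) min(scores) else NA_real_,
    max_pair_run = if (length(runs)) max(runs) else NA_real_
  ), class = "set_report")
}

#' @export
print.set_report <- function(x, ...) {
  np <- sum(vapply(x$tag_verdicts, `[[`, logical(1), "pass"))
  pp <- sum(vapply(x$pair_reports, `[[`, logical(1), "pass"))
  cat(sprintf("Tag set report: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  tags passing:  %d/%d\n", np, length(x$tag_verdicts)))
  cat(sprintf("  pairs passing: %d/%d\n", pp, length(x$pair_reports)))
  cat(sprintf("  min pairwise weighted score: %g\n", x$min_pair_score))
  cat(sprintf("  max pairwise contiguous run: %g\n", x$max_pair_run))
  for (v in x$tag_verdicts) {
    if (!v$pass) cat("  FAIL", v$name, ":", paste(v$reasons, collapse = "; "), "\n")
  }
  for (p in x$pair_reports) {
    if (!p$pass) cat("  FAIL pair", paste(p$pair, collapse = "/"), ":",
                     paste(p$reasons, collapse = "; "), "\n")
  }
  invisible(x)
}

# all 4 * 4 * 4 * 2 = 128 candidate (split_base, barcode) combinations in
# lexicographic order (bar-code 3' base restricted to the GC clamp)
candidate_tag_space <- function(scaffold = bstag_scaffold(),
                                conditions = NULL) {
  combos <- expand.grid(clamp = c("C", "G"), b2 = DNA_BASES, b1 = DNA_BASES,
                        split = DNA_BASES, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$split, combos$b1, combos$b2, combos$clamp), ]
  lapply(seq_len(nrow(combos)), function(i) {
    split_tag(combos$split[i],
              paste0(combos$b1[i], combos$b2[i], combos$clamp[i]),
              scaffold, conditions = conditions)
  })
}

pairwise_score_matrix <- function(tags) {
  n <- length(tags)
  m <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- duplex_score(tags[[i]]$full_seq, revcomp(tags[[j]]$full_seq))
      m[i, j] <- m[j, i] <- p$weighted_score
    }
  }
  m
}

#' Generate a discriminable split-tag set
#'
#' Enumerates the 128-candidate space (4 split bases x 32 GC-clamped
#' bar-codes) over the given scaffold, filters by [validate_tag()], and
#' selects a size-`k` subset maximizing the minimum pairwise weighted
#' mismatch score.  Selection is exhaustive when the number of subsets is
#' small (<= `exhaustive_limit`), otherwise greedy max-min; all tie-breaking
#' is lexicographic on the full sequence, so output is deterministic.
#'
#' @param scaffold a [bstag_scaffold()].
#' @param k requested set size (>= 2).
#' @param tm_window Tm constraint passed to [validate_tag()].
#' @param policy a [pair_policy()].
#' @param conditions [thermo_conditions] for Tm (required for the Tm filter).
#' @param exhaustive_limit maximum number of subsets to enumerate exhaustively.
#' @return object of class `tagset_generation`: `tags` (list of [split_tag]),
#'   `min_pair_score`, and `log` (candidate counts at each filter stage).
#'   If fewer than `k` candidates survive or no subset meets the policy, an
#'   error of class `bstag_infeasible` reports the largest achievable size.
#' @export
generate_tagset <- function(scaffold = bstag_scaffold(), k = 6L,
                            tm_window = c(46, 53), policy = pair_policy(),
                            conditions = calibrated_conditions(),
                            exhaustive_limit = 20000) {
  if (k < 2L) stop("k must be >= 2 (pairwise policy undefined for k = 1)")
  cands <- candidate_tag_space(scaffold, conditions)
  verdicts <- vapply(cands, function(t) validate_tag(t, tm_window)$pass,
                     logical(1))
  pool <- cands[verdicts]
  log <- list(candidates = length(cands), passing_tag_filter = length(pool))
  if (length(pool) < k) {
    stop(structure(class = c("bstag_infeasible", "error", "condition"),
                   list(message = sprintf(
                     "only %d candidates pass tag constraints; largest achievable set size is %d",
                     length(pool), length(pool)),
                     call = sys.call(), achievable = length(pool), log = log)))
  }
  # keep pool in lexicographic full_seq order for deterministic tie-breaks
  pool <- pool[order(vapply(pool, `[[`, character(1), "full_seq"))]
  score <- pairwise_score_matrix(pool)
  bc <- vapply(pool, `[[`, character(1), "barcode")
  pair_ok <- function(i, j) {
    (!policy$require_barcode_diff || bc[i] != bc[j]) &&
      score[i, j] >= policy$min_weighted_score
  }
  n <- length(pool)
  n_subsets <- choose(n, k)
  sel <- NULL
  if (n_subsets <= exhaustive_limit) {
    log$strategy <- "exhaustive"
    best_min <- -Inf
    subs <- utils::combn(n, k, simplify = FALSE)
    for (s in subs) {
      prs <- utils::combn(s, 2L, simplify = FALSE)
      if (!all(vapply(prs, function(ij) pair_ok(ij[1], ij[2]), logical(1)))) next
      mn <- min(vapply(prs, function(ij) score[ij[1], ij[2]], numeric(1)))
      if (mn > best_min) { # first (lexicographically earliest) strict max wins
        best_min <- mn
        sel <- s
      }
    }
  } else {
    log$strategy <- "greedy max-min"
    # seed: lexicographically earliest pair with maximal score among valid pairs
    best_min <- -Inf
    seed <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (pair_ok(i, j) && score[i, j] > best_min) {
          best_min <- score[i, j]
          seed <- c(i, j)
        }
      }
    }
    if (!is.null(seed)) {
      sel <- seed
      while (length(sel) < k) {
        rest <- setdiff(seq_len(n), sel)
        gains <- vapply(rest, function(c) {
          if (!all(vapply(sel, function(s) pair_ok(s, c), logical(1))))
            return(-Inf)
          min(score[c, sel])
        }, numeric(1))
        if (all(is.infinite(gains) & gains < 0)) break
        sel <- sort(c(sel, rest[which.max(gains)])) # which.max: first tie wins
      }
      if (length(sel) < k) {
        ach <- length(sel)
        stop(structure(class = c("bstag_infeasible", "error", "condition"),
                       list(message = sprintf(
                         "no size-%d subset satisfies the pair policy; largest achievable is %d",
                         k, ach), call = sys.call(), achievable = ach, log = log)))
      }
      best_min <- min(score[sel, sel][upper.tri(diag(length(sel)))])
    }
  }
  if (is.null(sel)) {
    stop(structure(class = c("bstag_infeasible", "error", "condition"),
                   list(message = sprintf(
                     "no size-%d subset satisfies the pair policy", k),
                     call = sys.call(), achievable = NA_integer_, log = log)))
  }
  log$selected <- k
  log$min_pair_score <- best_min
  structure(list(tags = pool[sel], min_pair_score = best_min, log = log),
            class = "tagset_generation")
}

#' @export
print.tagset_generation <- function(x, ...) {
  cat(sprintf("Generated tag set: %d tags (%s selection), min pair score %g\n",
              length(x$tags), x$log$strategy, x$min_pair_score))
  cat(sprintf("  candidate funnel: %d enumerated -> %d passing constraints -> %d selected\n",
              x$log$candidates, x$log$passing_tag_filter, x$log$selected))
  for (t in x$tags) print(t)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Tag set I/O: TSV (name, sequence, tm) mirroring the published table layout,
# and JSON with the full decomposition.

#' Write a tag set as TSV
#'
#' Columns `name`, `sequence`, `tm` (Tm rounded to 0.1 degC, round-half-up).
#'
#' @param tags list of [split_tag].
#' @param path output file.
#' @export
write_tagset <- function(tags, path) {
  df <- data.frame(name = vapply(tags, `[[`, character(1), "name"),
                   sequence = vapply(tags, `[[`, character(1), "full_seq"),
                   tm = vapply(tags, function(t)
                     if (is.na(t$tm)) NA_real_ else round_half_up(t$tm),
                     numeric(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tag set from TSV
#'
#' @param path TSV with columns `name`, `sequence` and optionally `tm`.
#' @param scaffold expected scaffold (default inferred from the first row's
#'   positions 1-7 and 9-13).
#' @param conditions optional [thermo_conditions]; when given, Tm is
#'   recomputed and cached, otherwise any `tm` column is used as-is.
#' @return list of [split_tag].
#' @export
read_tagset <- function(path, scaffold = NULL, conditions = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "sequence") %in% names(df)))
  if (is.null(scaffold)) {
    s1 <- toupper(df$sequence[1])
    scaffold <- bstag_scaffold(substr(s1, 1, 7), substr(s1, 9, 13))
  }
  tags <- lapply(seq_len(nrow(df)), function(i) {
    t <- parse_tag(df$sequence[i], scaffold, conditions = conditions,
                   name = df$name[i])
    if (is.null(conditions) && "tm" %in% names(df)) t$tm <- df$tm[i]
    t
  })
  tags
}

#' Serialize tags to JSON with the full decomposition
#'
#' @param tags list of [split_tag].
#' @param path output file.
#' @export
write_tagset_json <- function(tags, path) {
  x <- lapply(tags, function(t) {
    list(name = t$name, full_seq = t$full_seq, scaffold5 = t$scaffold5,
         split_base = t$split_base, scaffold3 = t$scaffold3,
         barcode = t$barcode,
         tm = if (is.na(t$tm)) NULL else round_half_up(t$tm))
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
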