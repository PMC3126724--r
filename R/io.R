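# File formats: FASTA (case-preserving, line-number diagnostics), marker
# assay sheets (TSV mirroring the published table layout, byte-stable on
# round trip), config files (YAML key-value).

#' Read a multi-record FASTA file
#'
#' Case is preserved (lowercase segments are meaningful in assay sheets and
#' may appear in templates); wrapped and unwrapped records are accepted.
#' Malformed headers and duplicate ids are reported with diagnostics.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) {
    stop("malformed FASTA: line 1 does not start with '>' in ", path)
  }
  blank_at <- which(!hdr & !nzchar(trimws(lines)))
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (any(ids == ">") || any(!nzchar(ids))) {
    bad <- which(hdr)[!nzchar(sub("^>\\s*", "", lines[hdr]))][1]
    stop("malformed FASTA: empty header at line ", bad, " in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], " in ", path)
  }
  grp <- cumsum(hdr)
  body <- lines
  body[hdr] <- ""
  body <- gsub("\\s", "", body)
  seqs <- vapply(split(body, grp), paste, character(1), collapse = "")
  names(seqs) <- ids
  if (length(blank_at)) seqs <- seqs # blanks already stripped
  seqs
}

#' Write sequences as FASTA, wrapped to 60 columns
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a marker assay sheet
#'
#' TSV with columns `marker`, `ddbj_id`, `info`, `role`, `allele`, `tag`,
#' `dye`, `sequence` (optionally `size_min`, `size_max`).  Roles: `forward`
#' and `reverse` rows define a tagged SSR/indel assay; `lso` and `aso` rows
#' define a SNP assay.  Lowercase segments (pig-tail, introduced mismatches)
#' are preserved verbatim.  Row-level problems (unknown tag name, non-ACGT
#' sequence ignoring case) are collected and reported together.
#'
#' @param path TSV file.
#' @param tags named list of [split_tag] resolving tag names (default the
#'   published set).
#' @param conditions optional [thermo_conditions] for the Tm-gap check when
#'   assembling SSR assays.
#' @param min_gap Tm-gap threshold for SSR assembly (degC).
#' @return named list of `marker_assay` / `snp_assay` objects.
#' @export
read_marker_table <- function(path, tags = published_tags(),
                              conditions = calibrated_conditions(),
                              min_gap = 6) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("marker", "role", "tag", "dye", "sequence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("marker table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  errs <- character(0)
  for (i in seq_len(nrow(df))) {
    sq <- gsub("[acgtACGT]", "", df$sequence[i])
    if (nzchar(sq)) {
      errs <- c(errs, sprintf("row %d (%s): non-ACGT character(s) '%s'",
                              i, df$marker[i], sq))
    }
    if (df$role[i] %in% c("forward", "aso") && !df$tag[i] %in% names(tags)) {
      errs <- c(errs, sprintf("row %d (%s): unknown tag '%s'",
                              i, df$marker[i], df$tag[i]))
    }
  }
  if (length(errs)) {
    stop("marker table errors:\n  ", paste(errs, collapse = "\n  "))
  }
  out <- list()
  for (m in unique(df$marker)) {
    rows <- df[df$marker == m, , drop = FALSE]
    if ("lso" %in% rows$role) {
      asos <- rows[rows$role == "aso", , drop = FALSE]
      aso_list <- lapply(seq_len(nrow(asos)), function(i) {
        tg <- tags[[asos$tag[i]]]
        core <- substr(asos$sequence[i], 17L, nchar(asos$sequence[i]))
        list(allele = asos$allele[i], core = core, tag = tg,
             dye = asos$dye[i], tagged = asos$sequence[i],
             introduced_mismatch_offset = mismatch_offset_from_case(core))
      })
      out[[m]] <- structure(
        list(name = m, ddbj_id = rows$ddbj_id[1], info = rows$info[1],
             lso = rows[rows$role == "lso", "sequence"],
             snp_alleles = asos$allele, aso = aso_list),
        class = "snp_assay")
    } else {
      fwd <- rows[rows$role == "forward", , drop = FALSE]
      rev <- rows[rows$role == "reverse", , drop = FALSE]
      if (nrow(fwd) != 1L || nrow(rev) != 1L) {
        stop("marker ", m, " must have one forward and one reverse row")
      }
      tg <- tags[[fwd$tag]]
      core <- substr(toupper(fwd$sequence), 17L, nchar(fwd$sequence))
      tail <- sub("[ACGT].*$", "", rev$sequence)
      rev_core <- substr(rev$sequence, nchar(tail) + 1L, nchar(rev$sequence))
      rng <- NULL
      if (all(c("size_min", "size_max") %in% names(rows)) &&
          nzchar(fwd$size_min) && fwd$size_min != "-") {
        rng <- c(as.numeric(fwd$size_min), as.numeric(fwd$size_max))
      }
      out[[m]] <- build_ssr_assay(m, core, rev_core, tg, fwd$dye, conditions,
                                  min_gap = min_gap, tail = tail,
                                  expected_size_range = rng,
                                  ddbj_id = rows$ddbj_id[1], motif = fwd$info)
    }
  }
  out
}

#' Write assays as a marker assay sheet (TSV)
#'
#' Re-renders the printed oligo strings (case included); reading a sheet and
#' writing it back is byte-identical.
#'
#' @param assays list of `marker_assay` / `snp_assay` objects.
#' @param path output TSV.
#' @export
write_assay_sheet <- function(assays, path) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  with_sizes <- any(vapply(assays, function(a)
    inherits(a, "marker_assay") && !is.null(a$expected_size_range), logical(1)))
  size_cols <- function(a) {
    if (!with_sizes) return(NULL)
    r <- if (inherits(a, "marker_assay")) a$expected_size_range else NULL
    if (is.null(r)) list(size_min = "-", size_max = "-")
    else list(size_min = r[1], size_max = r[2])
  }
  for (a in assays) {
    if (inherits(a, "marker_assay")) {
      do.call(add, c(list(marker = a$name,
          ddbj_id = if (is.null(a$ddbj_id)) "-" else a$ddbj_id,
          info = if (is.null(a$motif)) "-" else a$motif,
          role = "forward", allele = "-", tag = a$tag$name, dye = a$dye,
          sequence = a$tagged_forward), size_cols(a)))
      do.call(add, c(list(marker = a$name,
          ddbj_id = if (is.null(a$ddbj_id)) "-" else a$ddbj_id,
          info = if (is.null(a$motif)) "-" else a$motif,
          role = "reverse", allele = "-", tag = "-", dye = "-",
          sequence = a$tailed_reverse), size_cols(a)))
    } else if (inherits(a, "snp_assay")) {
      info <- if (!is.null(a$info)) a$info else
        paste0("(", paste(a$snp_alleles, collapse = "/"), ")")
      do.call(add, c(list(marker = a$name,
          ddbj_id = if (is.null(a$ddbj_id)) "-" else a$ddbj_id,
          info = info, role = "lso", allele = "-", tag = "-", dye = "-",
          sequence = a$lso), size_cols(a)))
      for (s in a$aso) {
        do.call(add, c(list(marker = a$name,
            ddbj_id = if (is.null(a$ddbj_id)) "-" else a$ddbj_id,
            info = info, role = "aso", allele = s$allele, tag = s$tag$name,
            dye = s$dye, sequence = s$tagged), size_cols(a)))
      }
    } else stop("unsupported assay object of class ", class(a)[1])
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a key-value configuration file (YAML)
#'
#' Documented keys: `monovalent_salt`, `divalent_salt`, `oligo_conc`,
#' `dntp_conc` (mol/L, for [thermo_conditions()]), `seed_len`,
#' `mismatch_cap`, `margin` (for [anneal_policy()]), `weights`,
#' `min_weighted_score`, `tm_window`, `size_tolerance`, `max_assays`.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

conditions_from_config <- function(cfg, default = calibrated_conditions()) {
  if (is.null(cfg)) return(default)
  thermo_conditions(
    monovalent_salt = cfg$monovalent_salt %||% default$monovalent_salt,
    divalent_salt = cfg$divalent_salt %||% default$divalent_salt,
    oligo_conc = cfg$oligo_conc %||% default$oligo_conc,
    dntp_conc = cfg$dntp_conc %||% default$dntp_conc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
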