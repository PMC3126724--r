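# Multiplex panel construction and rule-based two-stage PCR labeling
# simulation.  The simulator is deliberately not kinetic: it applies the
# annealing gates (core primers prime at stage-1 temperature, tag primers
# only at the lower stage-2 temperature, and only on a perfectly matching
# tag site) plus pool arithmetic, which is exactly the level at which
# exclusive labeling and the mismatch no-peak behavior are defined.

#' Default dye palette
#'
#' Four capillary dyes with detection channels and per-dye electrophoretic
#' mobility offsets (bp).  The offsets are placeholders spanning [-3, +1] so
#' that tag length (16) + offset reproduces the 13-17 bp apparent-size shift
#' of post-labeled products; instruments should be calibrated per dye.
#'
#' @return data.frame with columns `name`, `channel`, `mobility_offset`,
#'   `color`.
#' @export
dye_palette <- function() {
  data.frame(name = c("6-FAM", "VIC", "NED", "PET"),
             channel = 1:4,
             mobility_offset = c(-3, -2, -1, 1),
             color = c("blue", "green", "black", "red"),
             stringsAsFactors = FALSE)
}

dye_offset <- function(dye, dyes = dye_palette()) {
  i <- match(dye, dyes$name)
  if (is.na(i)) stop("unknown dye: ", dye)
  dyes$mobility_offset[i]
}

#' Apparent (electrophoretic) size of a labeled product
#'
#' @param product_len untagged, unlabeled product length (bp, > 0).
#' @param tag the [split_tag] attached to the forward primer.
#' @param dye dye name or a one-row slice of [dye_palette()].
#' @param dyes dye palette for name lookup.
#' @return apparent size in bp: `product_len + tag length + mobility offset`.
#' @export
apparent_size <- function(product_len, tag, dye, dyes = dye_palette()) {
  stopifnot(all(product_len > 0))
  off <- if (is.character(dye)) dye_offset(dye, dyes) else dye$mobility_offset
  product_len + nchar(tag$full_seq) + off
}

panel_windows <- function(panel) {
  t(vapply(panel$assays, function(a) {
    r <- a$expected_size_range
    if (is.null(r)) stop("assay ", a$name, " has no expected_size_range")
    off <- dye_offset(a$dye, panel$dyes)
    c(r[1] + nchar(a$tag$full_seq) + off, r[2] + nchar(a$tag$full_seq) + off)
  }, numeric(2)))
}

#' Validate panel invariants
#'
#' Tags distinct; same-dye apparent-size windows separated by at least the
#' guard band; assay count within capacity.
#'
#' @param panel a `bstag_panel`.
#' @return list `pass`, `reasons`.
#' @export
validate_panel <- function(panel) {
  reasons <- character(0)
  n <- length(panel$assays)
  if (n > panel$max_assays) {
    reasons <- c(reasons, sprintf("%d assays exceed capacity %d", n,
                                  panel$max_assays))
  }
  tags <- vapply(panel$assays, function(a) a$tag$full_seq, character(1))
  if (anyDuplicated(tags)) {
    reasons <- c(reasons, "duplicate tags within the panel")
  }
  dyes <- vapply(panel$assays, `[[`, character(1), "dye")
  if (n >= 2L) {
    win <- panel_windows(panel)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (dyes[i] != dyes[j]) next
        sep <- max(win[i, 1], win[j, 1]) - min(win[i, 2], win[j, 2])
        if (sep < panel$size_tolerance) {
          reasons <- c(reasons, sprintf(
            "same-dye (%s) windows of %s and %s separated by %g < %g bp",
            dyes[i], panel$assays[[i]]$name, panel$assays[[j]]$name,
            sep, panel$size_tolerance))
        }
      }
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Construct a panel from assays with (tag, dye) already assigned
#'
#' @param assays list of `marker_assay` objects carrying `tag`, `dye` and
#'   `expected_size_range`.
#' @param dyes dye palette.
#' @param size_tolerance guard band (bp) between same-dye windows.
#' @param max_assays tube capacity (default 6, the published tag-set size).
#' @param check validate invariants on construction (default TRUE).
#' @return object of class `bstag_panel`.
#' @export
new_panel <- function(assays, dyes = dye_palette(), size_tolerance = 10,
                      max_assays = 6L, check = TRUE) {
  p <- structure(list(assays = assays, dyes = dyes,
                      size_tolerance = size_tolerance,
                      max_assays = as.integer(max_assays)),
                 class = "bstag_panel")
  if (check) {
    v <- validate_panel(p)
    if (!v$pass) stop("invalid panel: ", paste(v$reasons, collapse = "; "))
  }
  p
}

#' @export
print.bstag_panel <- function(x, ...) {
  cat(sprintf("Panel: %d assay(s), guard band %g bp, capacity %d\n",
              length(x$assays), x$size_tolerance, x$max_assays))
  for (a in x$assays) {
    r <- a$expected_size_range
    cat(sprintf("  %s -> %s/%s [%s bp]\n", a$name, a$tag$name, a$dye,
                if (is.null(r)) "?" else paste(r, collapse = "-")))
  }
  invisible(x)
}

# can assay `a` (with tentative tag/dye) coexist with already-assigned assays?
.fits <- function(a, assigned, dyes, size_tolerance) {
  for (b in assigned) {
    if (a$tag$full_seq == b$tag$full_seq) return(FALSE)
    if (a$dye == b$dye) {
      wa <- a$expected_size_range + nchar(a$tag$full_seq) + dye_offset(a$dye, dyes)
      wb <- b$expected_size_range + nchar(b$tag$full_seq) + dye_offset(b$dye, dyes)
      sep <- max(wa[1], wb[1]) - min(wa[2], wb[2])
      if (sep < size_tolerance) return(FALSE)
    }
  }
  TRUE
}

.assign_search <- function(assays, tag_pool, dye_names, dyes, size_tolerance) {
  n <- length(assays)
  assigned <- vector("list", n)
  # candidate (tag, dye) orders: tags lexicographic by name; dyes in palette
  # order, but dyes not yet used anywhere are preferred (distinct dyes first)
  recurse <- function(i, used_dyes) {
    if (i > n) return(TRUE)
    a <- assays[[i]]
    dye_order <- c(setdiff(dye_names, used_dyes),
                   intersect(dye_names, used_dyes))
    for (d in dye_order) {
      for (t in tag_pool) {
        cand <- a
        cand$tag <- t
        cand$dye <- d
        if (.fits(cand, assigned[seq_len(i - 1L)], dyes, size_tolerance)) {
          assigned[[i]] <<- cand
          if (recurse(i + 1L, union(used_dyes, d))) return(TRUE)
          assigned[i] <<- list(NULL)
        }
      }
    }
    FALSE
  }
  if (recurse(1L, character(0))) assigned else NULL
}

#' Assign tags and dyes to co-tubed assays
#'
#' Deterministic backtracking assignment satisfying the panel invariants
#' (distinct tags; same-dye apparent-size windows separated by the guard
#' band; capacity).  Distinct dyes are preferred before size separation is
#' relied upon.  On infeasibility, a minimal conflicting assay set is
#' diagnosed: removing any one named member restores feasibility.
#'
#' @param assays list of `marker_assay` objects with `expected_size_range`
#'   set (their current tag/dye assignments, if any, are ignored).
#' @param tag_pool list of [split_tag] objects available for assignment.
#' @param dyes dye palette (data.frame as [dye_palette()]).
#' @param size_tolerance guard band (bp).
#' @param max_assays tube capacity.
#' @return a `bstag_panel` on success, otherwise an object of class
#'   `panel_infeasibility` with fields `constraint` and `conflict` (assay
#'   names).
#' @export
build_panel <- function(assays, tag_pool, dyes = dye_palette(),
                        size_tolerance = 10, max_assays = 6L) {
  nm <- vapply(assays, `[[`, character(1), "name")
  tag_pool <- tag_pool[order(vapply(tag_pool, `[[`, character(1), "name"))]
  feasible_for <- function(sub) {
    if (length(sub) > max_assays || length(sub) > length(tag_pool)) return(NULL)
    .assign_search(assays[sub], tag_pool, dyes$name, dyes, size_tolerance)
  }
  all_idx <- seq_along(assays)
  sol <- feasible_for(all_idx)
  if (!is.null(sol)) {
    return(new_panel(sol, dyes, size_tolerance, max_assays))
  }
  # minimal infeasible core: drop assays that are not needed for infeasibility
  core <- all_idx
  for (i in all_idx) {
    trial <- setdiff(core, i)
    if (length(trial) >= 2L && is.null(feasible_for(trial))) core <- trial
  }
  constraint <- if (length(core) > max_assays) "max_assays"
    else if (length(core) > length(tag_pool)) "tag_pool"
    else "dye_size_separation"
  structure(list(constraint = constraint, conflict = nm[core]),
            class = "panel_infeasibility")
}

#' @export
print.panel_infeasibility <- function(x, ...) {
  cat(sprintf("Panel infeasible: constraint '%s'; conflicting assays: %s\n",
              x$constraint, paste(x$conflict, collapse = ", ")))
  invisible(x)
}

#' Swap the dye of one assay in a panel
#'
#' The tag assignment is unchanged; invariants are re-checked and the swap
#' fails atomically (the original panel is untouched) on violation.
#'
#' @param panel a `bstag_panel`.
#' @param assay_name assay to recolor.
#' @param new_dye dye name (must be in the panel's palette).
#' @return the updated panel.
#' @export
dye_swap <- function(panel, assay_name, new_dye) {
  i <- match(assay_name, vapply(panel$assays, `[[`, character(1), "name"))
  if (is.na(i)) stop("no assay named ", assay_name, " in panel")
  if (!new_dye %in% panel$dyes$name) stop("dye ", new_dye, " not in palette")
  cand <- panel
  cand$assays[[i]]$dye <- new_dye
  v <- validate_panel(cand)
  if (!v$pass) {
    stop(structure(class = c("bstag_swap_rejected", "error", "condition"),
                   list(message = paste0("dye swap rejected: ",
                                         paste(v$reasons, collapse = "; ")),
                        call = sys.call(), reasons = v$reasons)))
  }
  cand
}

#' Simulate two-stage post-PCR labeling of a panel
#'
#' Stage 1: each assay's tagged product pool forms iff its core forward
#' primer anneals at the stage-1 annealing temperature; labeled tag primers
#' are suppressed during stage 1 when their Tm is below the stage-1
#' annealing temperature (any tag hot enough to prime during amplification
#' is flagged in the `stage1_leak` attribute).  Stage 2: for every (labeled
#' tag primer, product pool) pair, a labeled peak is emitted iff the tag
#' probe anneals to the product's tag site at the stage-2 temperature.
#'
#' @param panel a `bstag_panel`.
#' @param templates named list: for each assay name, the numeric vector of
#'   allele product lengths (bp, untagged).
#' @param labeled_primers data.frame with columns `tag` (tag name) and `dye`;
#'   defaults to each assay's own (tag, dye) pair (matched labeling).
#' @param protocol a [default_protocol()].
#' @param conditions [thermo_conditions].
#' @param policy an [anneal_policy()].
#' @return data.frame of peaks: `assay`, `allele_length`, `dye`,
#'   `apparent_size`, `labeled`.  Attribute `stage1_leak` names tags whose
#'   Tm reaches the stage-1 annealing temperature.
#' @export
simulate_labeling <- function(panel, templates, labeled_primers = NULL,
                              protocol = default_protocol(),
                              conditions = calibrated_conditions(),
                              policy = anneal_policy()) {
  v <- validate_panel(panel)
  if (!v$pass) stop("invalid panel: ", paste(v$reasons, collapse = "; "))
  if (is.null(labeled_primers)) {
    labeled_primers <- data.frame(
      tag = vapply(panel$assays, function(a) a$tag$name, character(1)),
      dye = vapply(panel$assays, `[[`, character(1), "dye"),
      stringsAsFactors = FALSE)
  }
  stage1_t <- min(protocol$stage1$annealing_c)
  stage2_t <- protocol$stage2$annealing_c
  tag_by_name <- c(lapply(panel$assays, `[[`, "tag"))
  names(tag_by_name) <- vapply(panel$assays, function(a) a$tag$name, character(1))
  # tag sequences of labeled primers may reference tags outside the panel
  all_tags <- published_tags()
  lookup_tag <- function(nm) {
    if (nm %in% names(tag_by_name)) tag_by_name[[nm]]
    else if (nm %in% names(all_tags)) all_tags[[nm]]
    else stop("unknown tag name in labeled_primers: ", nm)
  }
  leak <- character(0)
  peaks <- list()
  for (a in panel$assays) {
    # stage 1 gate: does the core primer prime its own perfect site?
    core_ok <- anneals(a$forward_core, revcomp(a$forward_core), stage1_t,
                       conditions, policy)
    if (!core_ok) next
    tag_tm <- if (!is.na(a$tag$tm)) a$tag$tm else
      melt_temp(a$tag$full_seq, conditions)
    if (tag_tm >= stage1_t) leak <- c(leak, a$tag$name)
    lens <- templates[[a$name]]
    if (is.null(lens)) next
    # the product's complementary strand presents revcomp(tag) as the site
    site <- revcomp(a$tag$full_seq)
    for (k in seq_len(nrow(labeled_primers))) {
      lp_tag <- lookup_tag(labeled_primers$tag[k])
      lp_dye <- labeled_primers$dye[k]
      if (anneals(lp_tag$full_seq, site, stage2_t, conditions, policy)) {
        for (len in lens) {
          peaks[[length(peaks) + 1L]] <- data.frame(
            assay = a$name, allele_length = len, dye = lp_dye,
            apparent_size = apparent_size(len, a$tag, lp_dye, panel$dyes),
            labeled = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(assay = character(0), allele_length = numeric(0),
               dye = character(0), apparent_size = numeric(0),
               labeled = logical(0), stringsAsFactors = FALSE)
  out <- out[order(out$dye, out$apparent_size), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage1_leak") <- unique(leak)
  out
}

#' Post-PCR labeling yield curve
#'
#' Pool-arithmetic recurrence: each labeling cycle converts
#' `min(conversion x remaining single-stranded template, remaining labeled
#' primer)` into labeled product, consuming both pools.  The cumulative
#' curve is non-decreasing and concave; with the default pools it rises
#' near-linearly for three cycles and plateaus at the fourth.
#'
#' @param cycles number of labeling cycles (>= 0).
#' @param template_amount single-stranded tagged template pool (arbitrary
#'   units, default 5).
#' @param primer_amount labeled tag-primer pool (default 0.5, limiting).
#' @param conversion per-cycle conversion fraction in (0, 1] (default 0.035).
#' @return data.frame with columns `cycle` (0..cycles), `increment` and
#'   `labeled` (cumulative).
#' @export
labeling_yield <- function(cycles, template_amount = 5, primer_amount = 0.5,
                           conversion = 0.035) {
  stopifnot(cycles >= 0, template_amount > 0, primer_amount > 0,
            conversion > 0, conversion <= 1)
  inc <- numeric(cycles)
  tmpl <- template_amount
  prim <- primer_amount
  for (i in seq_len(cycles)) {
    x <- min(conversion * tmpl, prim)
    inc[i] <- x
    tmpl <- tmpl - x
    prim <- prim - x
  }
  data.frame(cycle = 0:cycles, increment = c(0, inc),
             labeled = cumsum(c(0, inc)))
}
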