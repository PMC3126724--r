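# Panel assembly, dye swapping, two-stage labeling simulation, yield model.

make_published_panel <- function(cal = cached_calibration()) {
  tags <- published_tags(cal$conditions)
  tab <- published_ssr_table()
  ranges <- list(SSR08A04 = c(150, 170), SSR08A09 = c(200, 220),
                 SSR08B15 = c(250, 270), SSR08B25 = c(300, 320))
  assays <- lapply(names(ranges), function(m) {
    fwd <- tab[tab$marker == m & tab$role == "forward", ]
    rev <- tab[tab$marker == m & tab$role == "reverse", ]
    build_ssr_assay(m, substr(toupper(fwd$sequence), 17, nchar(fwd$sequence)),
                    sub("^gtttctt", "", rev$sequence), tags[[fwd$tag]],
                    fwd$dye, cal$conditions,
                    expected_size_range = ranges[[m]])
  })
  names(assays) <- names(ranges)
  new_panel(assays)
}

test_that("apparent size adds the tag length and the dye mobility offset", {
  tag <- published_tags()$F9GAC
  flat <- data.frame(name = "FLAT", channel = 1L, mobility_offset = 0,
                     color = "gray")
  expect_identical(apparent_size(200, tag, "FLAT", flat), 216)
  # default dyes keep the apparent-size shift inside the observed 13-17 bp
  for (d in dye_palette()$name) {
    shift <- apparent_size(200, tag, d) - 200
    expect_gte(shift, 13)
    expect_lte(shift, 17)
  }
  mind <- data.frame(name = "LOW", channel = 1L, mobility_offset = -3,
                     color = "gray")
  expect_identical(apparent_size(200, tag, "LOW", mind) - 200, 13)
  expect_error(apparent_size(0, tag, "FLAT", flat))
})

test_that("the published four-marker single-tube combination is a valid panel", {
  panel <- make_published_panel()
  v <- validate_panel(panel)
  expect_true(v$pass)
  expect_identical(
    vapply(panel$assays, function(a) paste(a$tag$name, a$dye), character(1)),
    c(SSR08A04 = "F9GCC VIC", SSR08A09 = "F9GTC PET",
      SSR08B15 = "F9GAC NED", SSR08B25 = "F9TAC 6-FAM"))
})

test_that("build_panel assigns four assays and rejects a seventh", {
  cal <- cached_calibration()
  tags <- published_tags(cal$conditions)
  base <- make_published_panel(cal)$assays
  res <- build_panel(base, tags)
  expect_s3_class(res, "bstag_panel")
  expect_true(validate_panel(res)$pass)
  # seven assays cannot fit a six-tag pool / six-assay tube
  seven <- base[c(1, 2, 3, 4, 1, 2, 3)]
  for (i in seq_along(seven)) seven[[i]]$name <- paste0("assay", i)
  res7 <- build_panel(seven, tags)
  expect_s3_class(res7, "panel_infeasibility")
  expect_identical(res7$constraint, "max_assays")
  expect_length(res7$conflict, 7)
  # removing any named conflict member restores feasibility (minimality)
  drop1 <- seven[-1]
  expect_s3_class(build_panel(drop1, tags), "bstag_panel")
})

test_that("identical size windows with a single dye are diagnosed minimally", {
  cal <- cached_calibration()
  tags <- published_tags(cal$conditions)
  a <- make_published_panel(cal)$assays[[1]]
  b <- a
  b$name <- "twin"
  one_dye <- dye_palette()[1, , drop = FALSE]
  res <- build_panel(list(a, b), tags, dyes = one_dye)
  expect_s3_class(res, "panel_infeasibility")
  expect_identical(res$constraint, "dye_size_separation")
  expect_setequal(res$conflict, c("SSR08A04", "twin"))
  # either assay alone is feasible
  expect_s3_class(build_panel(list(a), tags, dyes = one_dye), "bstag_panel")
})

test_that("dye swaps are atomic and re-checked", {
  panel <- make_published_panel()
  # swapping to the same dye is the identity
  same <- dye_swap(panel, "SSR08A04", "VIC")
  expect_identical(vapply(same$assays, `[[`, character(1), "dye"),
                   vapply(panel$assays, `[[`, character(1), "dye"))
  # swap to a dye not used by any size-overlapping assay is accepted
  moved <- dye_swap(panel, "SSR08A04", "6-FAM")
  expect_identical(moved$assays$SSR08A04$dye, "6-FAM")
  expect_identical(moved$assays$SSR08A04$tag$name,
                   panel$assays$SSR08A04$tag$name)
  # force an overlap: two assays same window, swap onto the occupied dye
  overlap <- panel
  overlap$assays$SSR08A09$expected_size_range <- c(150, 170)
  err <- tryCatch(dye_swap(overlap, "SSR08A04", "PET"),
                  bstag_swap_rejected = identity)
  expect_s3_class(err, "bstag_swap_rejected")
  # the original panel is untouched
  expect_identical(overlap$assays$SSR08A04$dye, "VIC")
})

test_that("matched labeling yields dye-exclusive peaks and mismatches yield none", {
  cal <- cached_calibration()
  panel <- make_published_panel(cal)
  templates <- list(SSR08A04 = 160, SSR08A09 = 210,
                    SSR08B15 = 260, SSR08B25 = c(305, 311))
  peaks <- simulate_labeling(panel, templates, conditions = cal$conditions)
  # every assay labeled, each with exactly its own dye
  expect_setequal(unique(peaks$assay), names(templates))
  for (a in panel$assays) {
    expect_identical(unique(peaks$dye[peaks$assay == a$name]), a$dye)
  }
  expect_identical(attr(peaks, "stage1_leak"), character(0))
  # heterozygote: two peaks, same dye, separated by the allele difference
  het <- peaks[peaks$assay == "SSR08B25", ]
  expect_identical(nrow(het), 2L)
  expect_identical(diff(het$apparent_size), 6)
  # a mismatched labeled primer alone produces no peaks
  wrong <- data.frame(tag = "F9GTC", dye = "PET")
  none <- simulate_labeling(panel, templates["SSR08B15"],
                            labeled_primers = wrong,
                            conditions = cal$conditions)
  expect_identical(nrow(none[none$assay == "SSR08B15", ]), 0L)
})

test_that("exclusivity holds over fuzzed random panels", {
  cal <- cached_calibration()
  tags <- published_tags(cal$conditions)
  dyes <- dye_palette()
  set.seed(33)
  for (rep in 1:200) {
    k <- sample(2:4, 1)
    pick <- sample(names(tags), k)
    dye_pick <- sample(dyes$name, k)
    assays <- lapply(seq_len(k), function(i) {
      lo <- 100 + 60 * i
      build_ssr_assay(paste0("m", i), random_hot_core(cal$conditions),
                      random_hot_core(cal$conditions), tags[[pick[i]]],
                      dye_pick[i], cal$conditions,
                      expected_size_range = c(lo, lo + 20))
    })
    names(assays) <- vapply(assays, `[[`, character(1), "name")
    panel <- new_panel(assays)
    templates <- lapply(assays, function(a)
      sample(a$expected_size_range[1]:a$expected_size_range[2], 1))
    peaks <- simulate_labeling(panel, templates, conditions = cal$conditions)
    # exclusivity: every labeled peak carries its source assay's dye
    for (i in seq_len(nrow(peaks))) {
      expect_identical(peaks$dye[i], assays[[peaks$assay[i]]]$dye)
    }
    expect_setequal(unique(peaks$assay), names(assays))
  }
})

test_that("removing one matched labeled primer removes exactly that assay's peaks", {
  cal <- cached_calibration()
  panel <- make_published_panel(cal)
  templates <- list(SSR08A04 = 160, SSR08A09 = 210,
                    SSR08B15 = 260, SSR08B25 = 305)
  full <- simulate_labeling(panel, templates, conditions = cal$conditions)
  primers <- data.frame(
    tag = vapply(panel$assays, function(a) a$tag$name, character(1)),
    dye = vapply(panel$assays, `[[`, character(1), "dye"))
  drop <- primers[primers$tag != "F9GCC", ] # SSR08A04's matched primer out
  reduced <- simulate_labeling(panel, templates, labeled_primers = drop,
                               conditions = cal$conditions)
  expect_identical(nrow(reduced), nrow(full) - 1L)
  expect_false("SSR08A04" %in% reduced$assay)
  kept <- full[full$assay != "SSR08A04", c("assay", "dye", "apparent_size")]
  rownames(kept) <- NULL
  got <- reduced[, c("assay", "dye", "apparent_size")]
  rownames(got) <- NULL
  expect_identical(got, kept)
})

test_that("the labeling yield curve is concave and plateaus by cycle four", {
  expect_identical(labeling_yield(0)$labeled, 0)
  # unlimited primer with full conversion exhausts the template at cycle 1
  y1 <- labeling_yield(4, template_amount = 1, primer_amount = 100,
                       conversion = 1)
  expect_equal(y1$labeled[-1], rep(1, 4))
  # defaults: non-decreasing, concave, flat by cycle 4
  y <- labeling_yield(4)
  expect_true(all(diff(y$labeled) >= 0))
  expect_true(all(diff(y$increment[-1]) <= 1e-12))
  expect_lt(y$increment[5], 0.2 * y$increment[2])
  expect_error(labeling_yield(3, conversion = 0))
})
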