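# Tag data model, parser, validators, conserved positions, set generator.

test_that("parse_tag decomposes published sequences by fixed positions", {
  t1 <- parse_tag("CTAGTATCAGGACGAC")
  expect_identical(t1$split_base, "C")
  expect_identical(t1$barcode, "GAC")
  expect_identical(t1$name, "F9GAC")
  t2 <- parse_tag("CTAGTATTAGGACCCG")
  expect_identical(t2$split_base, "T")
  expect_identical(t2$barcode, "CCG")
  # scaffold violations outside position 8 are named
  expect_error(parse_tag("CTAGTAACAGGACGAC"), "position\\(s\\) 7")
  expect_error(parse_tag("CTAGTATCAGGACGA"), "length 15")
  expect_error(parse_tag("CTAGTATCAGGACGAX"), "X")
})

test_that("parse_tag inverts field concatenation on every candidate tag", {
  sc <- bstag_scaffold()
  for (split in c("A", "C", "G", "T")) {
    for (bc in c("GAC", "CCG", "ATC", "TTG")) {
      t <- split_tag(split, bc, sc)
      back <- parse_tag(paste0(t$scaffold5, t$split_base, t$scaffold3,
                               t$barcode), sc)
      expect_identical(back$full_seq, t$full_seq)
      expect_identical(back$split_base, split)
      expect_identical(back$barcode, bc)
    }
  }
})

test_that("validate_tag enforces the GC clamp and the Tm window", {
  cal <- cached_calibration()
  tags <- published_tags(cal$conditions)
  expect_true(validate_tag(tags$F9GAC)$pass)
  bad <- split_tag("C", "GAT", conditions = cal$conditions)
  v <- validate_tag(bad)
  expect_false(v$pass)
  expect_match(v$reasons, "clamp", all = FALSE)
  # window verdict agrees with a direct Tm computation
  t <- parse_tag("CTAGTATGAGGACGGG", conditions = cal$conditions)
  tm <- melt_temp("CTAGTATGAGGACGGG", cal$conditions)
  v <- validate_tag(t, tm_window = c(46, 53))
  expect_identical(v$pass, tm >= 46 && tm <= 53)
})

test_that("conserved positions across the published set are the 12 basal ones", {
  tags <- published_tags()
  cp <- conserved_positions(tags)
  expect_identical(cp, c(1:7, 9:13))
  expect_identical(setdiff(1:16, cp), c(8L, 14:16))
  # a duplicated tag conserves everything
  expect_length(conserved_positions(list(tags$F9GAC, tags$F9GAC)), 16)
  short <- tags$F9GAC
  short$full_seq <- substr(short$full_seq, 1, 15)
  expect_error(conserved_positions(list(tags$F9GAC, short)), "unequal")
})

test_that("pair discrimination passes all 15 published pairs and fails self-pairs", {
  tags <- published_tags()
  pr <- pair_discrimination(tags$F9GAC, tags$F9GTC)
  expect_true(pr$pass)
  expect_identical(pr$report_ab$mismatch_positions, c(8L, 15L))
  self <- pair_discrimination(tags$F9GAC, tags$F9GAC)
  expect_false(self$pass)
  expect_identical(self$report_ab$total_mismatches, 0L)
  combos <- combn(length(tags), 2)
  for (k in seq_len(ncol(combos))) {
    expect_true(pair_discrimination(tags[[combos[1, k]]],
                                    tags[[combos[2, k]]])$pass)
  }
  other <- split_tag("C", "GAC", bstag_scaffold("AAAAAAA", "CCCCC"))
  expect_error(pair_discrimination(tags$F9GAC, other), "different scaffolds")
})

test_that("validate_set passes the published set and catches forced collisions", {
  cal <- cached_calibration()
  tags <- published_tags(cal$conditions)
  rep <- validate_set(tags)
  expect_true(rep$pass)
  expect_length(rep$tag_verdicts, 6)
  expect_length(rep$pair_reports, 15)
  expect_true(all(vapply(rep$tag_verdicts, `[[`, logical(1), "pass")))
  expect_true(all(vapply(rep$pair_reports, `[[`, logical(1), "pass")))
  # duplicate tag: self-similar pair fails the set
  expect_false(validate_set(c(tags, tags["F9GAC"]))$pass)
  # bar-code collision: F9GAC mutated to the GTC bar-code
  mut <- split_tag("C", "GTC", name = "F9GAC*", conditions = cal$conditions)
  expect_false(validate_set(c(tags[-1], list(mut)))$pass)
})

test_that("generated tag sets validate under the same policy (closed loop)", {
  cal <- cached_calibration()
  for (k in c(3L, 6L)) {
    for (win in list(c(46, 53), c(47, 52))) {
      gen <- generate_tagset(k = k, tm_window = win,
                             conditions = cal$conditions)
      expect_length(gen$tags, k)
      rep <- validate_set(gen$tags, tm_window = win)
      expect_true(rep$pass)
      expect_gte(gen$min_pair_score, pair_policy()$min_weighted_score)
    }
  }
})

test_that("tag generation is deterministic and rejects degenerate requests", {
  cal <- cached_calibration()
  g1 <- generate_tagset(k = 5L, conditions = cal$conditions)
  g2 <- generate_tagset(k = 5L, conditions = cal$conditions)
  expect_identical(vapply(g1$tags, `[[`, character(1), "full_seq"),
                   vapply(g2$tags, `[[`, character(1), "full_seq"))
  expect_error(generate_tagset(k = 1L), "k must be >= 2")
  err <- tryCatch(generate_tagset(k = 200L, conditions = cal$conditions),
                  bstag_infeasible = identity)
  expect_s3_class(err, "bstag_infeasible")
  expect_true(err$achievable < 200L)
})

test_that("the selector matches exhaustive subset search on a reduced pool", {
  cal <- cached_calibration()
  # narrow Tm window shrinks the candidate pool below 20 tags
  win <- c(51.5, 52.4)
  cands <- Filter(function(t) validate_tag(t, win)$pass,
                  bstag:::candidate_tag_space(conditions = cal$conditions))
  expect_lte(length(cands), 20)
  expect_gte(length(cands), 5)
  for (k in 2:4) {
    gen <- generate_tagset(k = k, tm_window = win, conditions = cal$conditions)
    # independent exhaustive oracle over the same candidate pool
    best <- -Inf
    idx <- combn(length(cands), k)
    for (col in seq_len(ncol(idx))) {
      sub <- cands[idx[, col]]
      ok <- TRUE
      mn <- Inf
      prs <- combn(k, 2)
      for (pc in seq_len(ncol(prs))) {
        a <- sub[[prs[1, pc]]]
        b <- sub[[prs[2, pc]]]
        if (a$barcode == b$barcode) { ok <- FALSE; break }
        sc <- oracle_duplex(a$full_seq, revcomp(b$full_seq))
        w <- sum(default_weights(16)[sc$mismatch_positions])
        if (w < pair_policy()$min_weighted_score) { ok <- FALSE; break }
        mn <- min(mn, w)
      }
      if (ok && mn > best) best <- mn
    }
    expect_equal(gen$min_pair_score, best)
  }
})

test_that("tag sets round-trip through TSV and JSON", {
  cal <- cached_calibration()
  tags <- published_tags(cal$conditions)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tagset(tags, tsv)
  back <- read_tagset(tsv)
  expect_identical(vapply(back, `[[`, character(1), "full_seq"),
                   unname(vapply(tags, `[[`, character(1), "full_seq")))
  expect_identical(vapply(back, `[[`, character(1), "name"),
                   unname(vapply(tags, `[[`, character(1), "name")))
  js <- withr::local_tempfile(fileext = ".json")
  write_tagset_json(tags, js)
  parsed <- jsonlite::read_json(js)
  expect_length(parsed, 6)
  expect_identical(parsed[[1]]$barcode, "GAC")
})
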