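# In-silico mispriming screen: planted-site recovery, brute-force
# equivalence, strand symmetry, amplicon prediction, assay screening.

test_that("planted sites are recovered with correct anatomy", {
  tags <- published_tags()
  gac <- tags$F9GAC$full_seq
  set.seed(42)
  bg <- random_seq(10000)
  # the tag's reverse complement planted at position 1000 (1-based)
  seqs <- c(bg1 = paste0(substr(bg, 1, 999), revcomp(gac),
                         substr(bg, 1016, 10000)))
  sites <- find_priming_sites(gac, seqs)
  planted <- sites[sites$start == 999, ]
  expect_gte(nrow(planted), 1)
  expect_identical(planted$strand, "-")
  expect_identical(planted$three_prime_match, 16L)
  expect_identical(planted$total_mismatches, 0L)
  # planted forward site with one internal mismatch at primer position 5
  primer <- "GATTACCAGTTGACCAGTAG"
  site <- strsplit(primer, "")[[1]]
  site[5] <- setdiff(c("A", "C", "G", "T"), site[5])[1]
  seqs2 <- c(bg2 = paste0(substr(bg, 1, 499), paste(site, collapse = ""),
                          substr(bg, 520, 10000)))
  hits <- find_priming_sites(primer, seqs2)
  hit <- hits[hits$start == 499, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$strand, "+")
  expect_identical(hit$total_mismatches, 1L)
  expect_identical(hit$three_prime_match, 15L)
  expect_error(find_priming_sites("ACGTA", seqs), "shorter than seed")
})

test_that("the indexed scan is equivalent to a brute-force full scan", {
  set.seed(101)
  spec <- fixture_spec(seed = 101, n_backgrounds = 2L,
                       background_length = 15000L)
  seqs <- make_fixtures(spec)$sequences
  # plant a handful of decoys for one primer so both hit and no-hit paths run
  primers <- c(vapply(1:20, function(i) random_seq(sample(16:24, 1)),
                      character(1)),
               vapply(published_tags(), `[[`, character(1), "full_seq"))
  names(primers) <- paste0("p", seq_along(primers))
  seqs[["background_01"]] <- paste0(substr(seqs[["background_01"]], 1, 3000),
                                    primers[[1]], revcomp(primers[[2]]),
                                    substr(seqs[["background_01"]], 3051, 15000))
  for (p in primers) {
    got <- find_priming_sites(p, seqs)
    ref <- oracle_scan(p, seqs)
    expect_identical(got$seq_id, ref$seq_id)
    expect_identical(got$start, ref$start)
    expect_identical(got$strand, ref$strand)
    expect_identical(got$three_prime_match, ref$three_prime_match)
    expect_identical(got$total_mismatches, ref$total_mismatches)
  }
})

test_that("screening a reverse-complemented collection mirrors coordinates", {
  set.seed(7)
  primer <- "CAAACACTTATTCGGGATCAG"
  bg <- random_seq(8000)
  bg <- paste0(substr(bg, 1, 2000), primer, substr(bg, 2022, 8000))
  fwd <- c(s = bg)
  rcc <- c(s = revcomp(bg))
  L <- nchar(bg)
  a <- find_priming_sites(primer, fwd)
  b <- find_priming_sites(primer, rcc)
  expect_identical(nrow(a), nrow(b))
  mirrored <- data.frame(start = L - b$end, end = L - b$start,
                         strand = ifelse(b$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start), ]
  expect_identical(a$start, mirrored$start)
  expect_identical(a$end, mirrored$end)
  expect_identical(a$strand, mirrored$strand)
})

test_that("loosening the mismatch cap never reduces the site count", {
  set.seed(8)
  seqs <- c(bg = random_seq(20000))
  primer <- "ATCGGATTACCAGTGAC"
  counts <- vapply(0:3, function(m)
    nrow(find_priming_sites(primer, seqs, max_mismatches = m)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("amplicons require convergent sites within the product cap", {
  set.seed(9)
  fwd <- "CAAACACTTATTCGGGATCAG"
  rev <- "AATGCCATTATCAAACCGCC"
  bg <- random_seq(12000)
  # convergent pair 300 bp apart: fwd at 1001, revcomp(rev) ending at 1300
  ins <- paste0(fwd, random_seq(300 - nchar(fwd) - nchar(rev)), revcomp(rev))
  planted <- paste0(substr(bg, 1, 1000), ins, substr(bg, 1301, 12000))
  amps <- predict_amplicons(c(F = fwd), c(R = rev), c(bg = planted))
  expect_identical(nrow(amps), 1L)
  expect_identical(amps$product_length, 300L)
  expect_identical(amps$fwd_primer, "F")
  expect_identical(amps$rev_primer, "R")
  # same pair 3000 bp apart is rejected by the 2000 bp cap
  ins2 <- paste0(fwd, random_seq(3000 - nchar(fwd) - nchar(rev)), revcomp(rev))
  planted2 <- paste0(substr(bg, 1, 1000), ins2, substr(bg, 4001, 12000))
  expect_identical(nrow(predict_amplicons(c(F = fwd), c(R = rev),
                                          c(bg = planted2))), 0L)
})

test_that("the published tags alone amplify nothing on synthetic backgrounds", {
  spec <- fixture_spec(seed = 42, n_backgrounds = 12L,
                       background_length = 20000L)
  seqs <- make_fixtures(spec)$sequences
  tags <- vapply(published_tags(), `[[`, character(1), "full_seq")
  amps <- predict_amplicons(tags, NULL, seqs)
  expect_identical(nrow(amps), 0L)
  # and all 36 ordered pseudo primer pairs stay silent
  for (a in names(tags)) {
    for (b in names(tags)) {
      pair <- c(tags[a], tags[b])
      names(pair) <- c("fwd", "rev")
      expect_identical(nrow(predict_amplicons(pair["fwd"], pair["rev"],
                                              seqs["background_01"])), 0L)
    }
  }
})

test_that("screen_assay separates intended loci from decoys", {
  cal <- cached_calibration()
  tags <- published_tags(cal$conditions)
  assay <- build_ssr_assay("SSR08A04", "CAAACACTTATTCGGGATCAG",
                           "AATGCCATTATCAAACCGCC", tags$F9GCC, "VIC",
                           cal$conditions, target_seq_id = "target")
  set.seed(10)
  locus <- paste0(toupper(assay$tagged_forward), random_seq(150),
                  revcomp(toupper(assay$tailed_reverse)))
  genome <- c(target = paste0(random_seq(500), locus, random_seq(500)),
              other = random_seq(2000))
  rep <- screen_assay(assay, genome)
  expect_true(rep$pass)
  expect_gte(nrow(rep$intended), 1)
  expect_identical(nrow(rep$unintended), 0L)
  # a decoy forward-primer site on another sequence creates a 500 bp product
  decoy <- paste0(toupper(assay$tagged_forward), random_seq(430),
                  revcomp(toupper(assay$tailed_reverse)))
  genome2 <- c(genome["target"],
               other = paste0(random_seq(300), decoy, random_seq(300)))
  rep2 <- screen_assay(assay, genome2)
  expect_false(rep2$pass)
  expect_gte(nrow(rep2$unintended), 1)
  expect_match(rep2$header, "seed")
})

test_that("site and amplicon writers use the documented coordinate systems", {
  primer <- "CAAACACTTATTCGGGATCAG"
  seqs <- c(bg = paste0(strrep("T", 100), primer, strrep("T", 100)))
  sites <- find_priming_sites(primer, seqs)
  expect_identical(sites$start, 100L) # 0-based half-open internally
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites(sites, tsv, "tsv")
  write_sites(sites, bed, "bed")
  t <- read.delim(tsv)
  expect_identical(t$start, 101L) # 1-based inclusive in TSV
  expect_identical(t$end, 121L)
  b <- read.delim(bed, header = FALSE)
  expect_identical(b$V2, 100L)    # BED stays 0-based half-open
  expect_identical(b$V3, 121L)
  expect_identical(b$V5, 0L)      # score = mismatches
})
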