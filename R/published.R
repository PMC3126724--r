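# The published reference set: six tags, four tagged SSR markers and two
# ASO/LSO SNP markers, carried in code as golden fixtures.  DDBJ accessions
# are opaque metadata; nothing is fetched.

#' The six published split tags
#'
#' Names, sequences and published melting temperatures of the reference tag
#' set.
#'
#' @return data.frame with columns `name`, `sequence`, `tm`.
#' @export
published_tag_table <- function() {
  data.frame(
    name = c("F9GAC", "F9GTC", "F9TAC", "F9GCC", "F9CCG", "F9AGG"),
    sequence = c("CTAGTATCAGGACGAC", "CTAGTATGAGGACGTC", "CTAGTATCAGGACTAC",
                 "CTAGTATTAGGACGCC", "CTAGTATTAGGACCCG", "CTAGTATTAGGACAGG"),
    tm = c(51.3, 51.3, 47.2, 51.7, 50.8, 47.5),
    stringsAsFactors = FALSE)
}

#' The published tags as parsed split_tag objects
#'
#' @param conditions optional [thermo_conditions]; when supplied, Tm is
#'   computed under them, otherwise the published values are cached.
#' @return named list of [split_tag] objects.
#' @export
published_tags <- function(conditions = NULL) {
  tab <- published_tag_table()
  tags <- lapply(seq_len(nrow(tab)), function(i) {
    t <- parse_tag(tab$sequence[i], conditions = conditions, name = tab$name[i])
    if (is.null(conditions)) t$tm <- tab$tm[i]
    t
  })
  names(tags) <- tab$name
  tags
}

#' The four published tagged SSR markers
#'
#' Forward oligos carry a 16-nt tag prefix; reverse oligos carry the
#' lowercase `gtttctt` pig-tail.  (One forward label was printed as
#' "G9GAC" in the source table; the sequence is that of F9GAC and the name
#' is normalized here.)
#'
#' @return data.frame with one row per oligo: `marker`, `ddbj_id`, `info`
#'   (repeat motif), `role`, `allele`, `tag`, `dye`, `sequence`.
#' @export
published_ssr_table <- function() {
  data.frame(
    marker = rep(c("SSR08A04", "SSR08A09", "SSR08B15", "SSR08B25"), each = 2),
    ddbj_id = rep(c("DY293653", "CX663959", "DY292389", "DY289996"), each = 2),
    info = rep(c("(aaac)n", "(cagg)n", "(acc)n", "(tta)n"), each = 2),
    role = rep(c("forward", "reverse"), 4),
    allele = "-",
    tag = c("F9GCC", "-", "F9GTC", "-", "F9GAC", "-", "F9TAC", "-"),
    dye = c("VIC", "-", "PET", "-", "NED", "-", "6-FAM", "-"),
    sequence = c(
      "CTAGTATTAGGACGCCCAAACACTTATTCGGGATCAG",
      "gtttcttAATGCCATTATCAAACCGCC",
      "CTAGTATGAGGACGTCCATCATTGCATCAGCATCAC",
      "gtttcttAGTTCTACATCATAACCTGCC",
      "CTAGTATCAGGACGACCCCATACTTGAAACCAAACC",
      "gtttcttAGCAGCATGACTTAATCCA",
      "CTAGTATCAGGACTACCGTTGACTCTCAAGAGATCTG",
      "gtttcttCTTCACAGTCCGCAGCATTA"),
    stringsAsFactors = FALSE)
}

#' The two published ASO/LSO SNP markers
#'
#' Lowercase letters inside ASO cores mark the introduced destabilizing
#' mismatch; the 3'-terminal base is the SNP allele.
#'
#' @return data.frame with one row per oligo: `marker`, `ddbj_id`, `info`
#'   (SNP alleles), `role`, `allele`, `tag`, `dye`, `sequence`.
#' @export
published_snp_table <- function() {
  data.frame(
    marker = c(rep("LLL0729", 3), rep("MAPGR75R", 3)),
    ddbj_id = c(rep("DC891931", 3), rep("DC893380", 3)),
    info = c(rep("(C/G)", 3), rep("(A/T)", 3)),
    role = c("lso", "aso", "aso", "lso", "aso", "aso"),
    allele = c("-", "C", "G", "-", "T", "A"),
    tag = c("-", "F9GAC", "F9GTC", "-", "F9GTC", "F9TAC"),
    dye = c("-", "NED", "PET", "-", "PET", "6-FAM"),
    sequence = c(
      "gtttcttGAAGTAGAAGGATGATAATCAC",
      "CTAGTATCAGGACGACATGGACACAACTCAAGTtC",
      "CTAGTATGAGGACGTCAATGGACACAACTCAAGTtG",
      "gtttcttGGTTGGTATATCTACGAGAC",
      "CTAGTATGAGGACGTCTATCCGATTGAGCCTTTcT",
      "CTAGTATCAGGACTACATCCGATTGAGCCTTTcA"),
    stringsAsFactors = FALSE)
}

#' Published SSR markers as assembled assay objects
#'
#' @param conditions [thermo_conditions] used for the Tm-gap invariant.
#' @param min_gap required core-minus-tag Tm margin (degC).
#' @return named list of `marker_assay` objects.
#' @export
published_ssr_assays <- function(conditions = calibrated_conditions(),
                                 min_gap = 6) {
  tab <- published_ssr_table()
  tags <- published_tags(conditions)
  markers <- unique(tab$marker)
  assays <- lapply(markers, function(m) {
    rows <- tab[tab$marker == m, ]
    fwd <- rows[rows$role == "forward", ]
    rev <- rows[rows$role == "reverse", ]
    tag <- tags[[fwd$tag]]
    core <- sub(paste0("^", tag$full_seq), "", toupper(fwd$sequence))
    rev_core <- sub("^[acgt]+", "", rev$sequence)
    tail <- sub("[ACGT].*$", "", rev$sequence)
    build_ssr_assay(m, core, rev_core, tag, fwd$dye, conditions,
                    min_gap = min_gap, tail = tail,
                    ddbj_id = fwd$ddbj_id, motif = fwd$info)
  })
  names(assays) <- markers
  assays
}

#' Published SNP markers as snp_assay objects
#'
#' @return named list of `snp_assay` objects (see [validate_snp_assay()]).
#' @export
published_snp_assays <- function() {
  tab <- published_snp_table()
  tags <- published_tags()
  markers <- unique(tab$marker)
  assays <- lapply(markers, function(m) {
    rows <- tab[tab$marker == m, ]
    lso <- rows[rows$role == "lso", "sequence"]
    asos <- rows[rows$role == "aso", ]
    alleles <- asos$allele
    aso_list <- lapply(seq_len(nrow(asos)), function(i) {
      tg <- tags[[asos$tag[i]]]
      core <- sub(paste0("^", tg$full_seq), "", asos$sequence[i],
                  ignore.case = FALSE)
      list(allele = asos$allele[i], core = core, tag = tg, dye = asos$dye[i],
           tagged = asos$sequence[i],
           introduced_mismatch_offset = mismatch_offset_from_case(core))
    })
    structure(list(name = m, ddbj_id = rows$ddbj_id[1], info = rows$info[1],
                   lso = lso, snp_alleles = alleles, aso = aso_list),
              class = "snp_assay")
  })
  names(assays) <- markers
  assays
}
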