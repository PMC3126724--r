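# bstag

Design and in-silico validation of **bar-coded split tags (BStags)** —
16-nt universal 5' primer extensions that enable selective post-PCR
fluorescent labeling of SSR, indel and SNP genotyping assays, so that up to
six markers with different dyes can be amplified and labeled in a single
tube without pre-labeled locus primers.

## Who this is for

Labs running fragment-analysis genotyping on capillary sequencers who want
to replace per-marker fluorescent primers (the dominant assay cost) with a
small reusable set of labeled tag primers, and who need to design, audit or
extend tag sets and multiplex panels before ordering oligos.

## The design in brief

A split tag is `scaffold5 (7 nt) | split base (1 nt) | scaffold3 (5 nt) |
bar-code (3 nt)`:

```
5'-CTAGTAT C AGGAC GAC-3'    (tag F9GAC)
   |basal region (13)|bar-code|
```

* The 13-nt **basal region** is conserved across a set; the variable
  **split base** at position 8 breaks it into two 7-nt halves.
* The 3-nt **bar-code** distinguishes tags and ends in G/C (GC clamp).
* For any mismatched tag/labeled-primer pair, the 3'-anchored perfect match
  is at most 2 nt and no basal match exceeds 7 nt — below priming length —
  while the matched pair anneals over the full 16-mer.
* Tags melt around 47–52 °C, at least 6 °C below the sequence-specific
  primers (the **Tm gap**), so labeling is confined to a short
  low-temperature second PCR stage (3 cycles at 49 °C).

Melting temperatures use the unified nearest-neighbor model,

Tm = ΔH° / (ΔS°_salt + R ln(C_T/4)) − 273.15,

with SantaLucia entropic salt correction and von Ahsen Mg²⁺ conversion.
The buffer conditions behind the published reference Tm values are unstated,
so `calibrate_conditions()` grid-searches standard values and pins the
conditions reproducing the published table (max residual 0.024 °C).

## Worked example

```r
library(bstag)

## 1. calibrate the Tm model against the published six-tag table
cal <- calibrate_conditions(published_tag_table())
cal
#> Nearest-neighbor Tm calibration
#>   grid points searched: 336
#>   max |residual|: 0.024 degC (tolerance 0.50, achieved)
#> Thermodynamic conditions
#>   monovalent salt: 100 mM
#>   divalent salt:   3 mM
#>   oligo conc:      200 nM
#>   dNTP conc:       0 mM

## 2. validate the published tag set: every tag and every pair
tags <- published_tags(cal$conditions)
validate_set(tags)
#> Tag set report: PASS
#>   tags passing:  6/6
#>   pairs passing: 15/15
#>   min pairwise weighted score: 3
#>   max pairwise contiguous run: 13

## 3. assemble a tagged SSR assay (tag + core, pig-tailed reverse)
assay <- build_ssr_assay("SSR08B25", "CGTTGACTCTCAAGAGATCTG",
                         "CTTCACAGTCCGCAGCATTA", tags$F9TAC, "6-FAM",
                         cal$conditions, expected_size_range = c(300, 320))
assay
#> MarkerAssay SSR08B25 [F9TAC/6-FAM]
#>   forward: CTAGTATCAGGACTACCGTTGACTCTCAAGAGATCTG
#>   reverse: gtttcttCTTCACAGTCCGCAGCATTA
#>   core Tm 60.8, tag Tm 47.2, gap 13.6 degC
#>   expected product: 300-320 bp (untagged)
```

The set report says all six tags pass the structural checks (GC clamp, Tm
window) and all 15 pairs are discriminable (distinct bar-codes, weighted
3'-mismatch score ≥ 3 in both orientations). The assay printout shows the
two oligos to order — the 16-nt tag prefix on the forward primer, the
lowercase `gtttctt` pig-tail on the reverse — and the 13.6 °C Tm gap that
confines labeling to the second stage; a gap under 6 °C is a hard error.

Other entry points: `generate_tagset()` (new tag sets over any scaffold),
`find_priming_sites()` / `predict_amplicons()` / `screen_assay()`
(mispriming screen against any FASTA collection), `design_aso_pair()` /
`validate_snp_assay()` (allele-specific SNP assays), `build_panel()` /
`dye_swap()` / `simulate_labeling()` (single-tube multiplex panels),
`make_fixtures()` (seeded synthetic backgrounds). A command-line wrapper
over the same functions is installed at `inst/cli/bstag`
(`design-tags`, `validate-tags`, `screen`, `design-ssr`, `design-snp`,
`validate-snp`, `build-panel`, `simulate`, `fixtures`; exit status 0 =
pass/feasible, 1 = validated fail/infeasible, 2 = usage error).

See `vignettes/bstag-design.Rmd` for the model details, parameter defaults
and design rationale.

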