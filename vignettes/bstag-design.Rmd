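---
title: "Designing bar-coded split tags for single-tube multiplexed post-PCR labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing bar-coded split tags for single-tube multiplexed post-PCR labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bstag)
```

## The problem this package addresses

Fragment-analysis genotyping (SSR/microsatellite, indel and SNP markers on a
capillary sequencer) traditionally requires a fluorescently pre-labeled
primer per marker, which is the dominant cost of an assay. Post-PCR labeling
replaces the labeled locus primer with (i) an unlabeled forward primer
carrying a short universal 5' tag and (ii) a cheap fluorescently labeled
primer matching the tag. The labeled primer extends on tagged single-stranded
product during a few extra low-temperature cycles, attaching the dye after
amplification. The difficulty is multiplexing: when several markers with
different intended dyes share one tube, tags that are too similar
cross-label, and tags that anneal during the amplification stage produce
spurious peaks.

A bar-coded split tag (BStag) solves both problems structurally. It is a
16-nt oligo with three parts:

* a conserved 13-nt **basal region** common to every tag in a set,
* a variable **split base** at position 8 that breaks the basal region into
  two 7-nt halves, and
* a 3-nt **bar-code** at the 3' end whose terminal base is G or C (a GC
  clamp for polymerase "landing").

For a mismatched tag/labeled-primer combination the bar-code difference caps
the 3'-anchored perfect match at 2 nt, and the split base caps any basal
match at 7 nt — both below the length a primer needs to prime. For the
matched combination the full 16-mer anneals. Because the whole tag melts
several degrees below the sequence-specific primers, labeling can be confined
to a short second stage at lower annealing temperature, after amplification
has consumed the tagged forward primer.

This package implements the design method as a toolkit: a calibrated
nearest-neighbor melting-temperature engine, structural and pairwise
validators plus a deterministic generator for tag sets, an in-silico
mispriming screen, assembly of tagged SSR assays and allele-specific (ASO/LSO)
SNP assays, and single-tube panel construction checked by a rule-based
two-stage-PCR simulation.

## The melting-temperature model and its calibration

`melt_temp()` implements the unified nearest-neighbor model (SantaLucia 1998
parameter set): duplex enthalpy and entropy are sums of dinucleotide-step
terms plus terminal initiation terms, the entropy is salt-corrected by
`0.368 (N-1) ln[Na+]`, free Mg²⁺ is folded into an effective monovalent
concentration by the von Ahsen square-root conversion, and

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ_{salt} + R\,\ln(C_T/4)} - 273.15$$

for a non-self-complementary primer at total strand concentration $C_T$.
The model is strand-symmetric and monotone in GC content; both properties
are enforced by tests.

The buffer conditions behind the reference tag set's published Tm values are
not part of the tag design, so they are treated as data to be estimated.
`calibrate_conditions()` grid-searches a documented finite set of standard
values (monovalent salt 50–1000 mM, Mg²⁺ 0–3 mM, oligo 50 nM–1 µM, dNTP 0 or
0.2 mM; 336 combinations in a fixed order) and returns the conditions
minimizing the maximum absolute residual over the supplied (sequence, Tm)
table. The result is a classed model object with `print`, `summary`, `coef`,
`predict` and `residuals` methods:

```{r calibration}
cal <- calibrate_conditions(published_tag_table())
summary(cal)
```

On the published six-tag table the best grid point (100 mM monovalent, 3 mM
Mg²⁺, 200 nM oligo) reproduces every value to within 0.03 °C — the published
numbers are evidently nearest-neighbor computations, and the pinned
conditions are exported as `calibrated_conditions()` and used as defaults
throughout. If no grid point reaches the requested tolerance the fit is
returned anyway with `achieved = FALSE` and the residuals pinned in the
report, rather than raising an error; a leave-one-out check in the test
suite confirms the fit is not overdetermined by any single tag.

## Positional mismatch scoring instead of mismatch thermodynamics

Discrimination between tags is decided by *where* mismatches sit, not by
their free energies: the design argument is positional (sub-8-nt match
segments cannot prime). `duplex_score()` therefore compares a probe
base-by-base against the reverse complement of its template site and reports
mismatch positions, the longest contiguous match, the 3'-anchored match run,
and a weighted score with weights 3 / 2 / 1 for positions 1–3 / 4–8 / >8
counted from the 3' terminus (configurable). Mismatch-specific
nearest-neighbor parameters are deliberately out of scope.

`anneals()` is the rule-based gate built on this: a probe anneals at
temperature $T$ iff its longest perfectly matched sub-duplex melts at or
above $T - margin$, its 3'-anchored run reaches the seed length (default
8 nt — one more than the 7-nt split halves), and total mismatches do not
exceed a cap. The default margin is 3 °C: primers prime slightly below their
duplex Tm, and the published protocol itself labels a tag melting at 47.2 °C
during 49 °C cycles, so a zero margin would contradict the reference
conditions the package must reproduce.

## Tag-set validation and generation

`validate_tag()` checks the GC clamp and a Tm window (default 46–53 °C,
bracketing the published set). `pair_discrimination()` requires distinct
bar-codes plus a minimum weighted mismatch score in both orientations. The
default threshold is 3 — the weight of a single bar-code mismatch. A
stricter literal rule ("must differ at the split base *and* the bar-code")
would reject two of the published pairs, which differ only in the bar-code;
consistency with the published set was given precedence over the stricter
reading, and the threshold is configurable for users who want it.

`generate_tagset()` enumerates the full candidate space over a scaffold —
4 split bases × 32 GC-clamped bar-codes = 128 candidates — filters by
`validate_tag()`, and selects a size-*k* subset maximizing the minimum
pairwise weighted score. Selection is exhaustive when the number of subsets
is at most 20 000 and greedy max-min otherwise: with ~100 candidates
passing default constraints, exhaustive search at *k* = 6 would require
~10⁹ subsets, so the exhaustive path is reserved for the small pools where
it is tractable (the test suite cross-checks greedy vs exhaustive results on
reduced pools). All orderings and tie-breaks are lexicographic on the full
sequence; identical inputs give byte-identical output.

## The in-silico specificity screen

`find_priming_sites()` replaces database homology searches with the question
PCR actually asks: where does the primer's 3'-terminal seed (default 8 nt)
match the template exactly, with at most *m* (default 2) mismatches over the
rest of the primer? Seeds are located with an exact-match index
(`Biostrings::matchPattern`) on both strands and extended in R; `N` bases
never match. `predict_amplicons()` pairs convergent sites within a product
cap (default 2000 bp), and `screen_assay()` wraps both, excluding the
assay's annotated target locus from "unintended". The original empirical
screen used an annealing gradient; mapping a temperature gradient onto
(seed, mismatch-cap) parameters is a modeling choice, and every report
header says so. Equivalence with a brute-force all-positions scanner is a
test-suite property.

Coordinates are 0-based half-open internally; TSV reports are 1-based
inclusive and BED output stays 0-based half-open.

## SSR and SNP assay assembly

`build_ssr_assay()` concatenates tag + forward core and pig-tails the
reverse core (`gtttctt`, rendered lowercase as in the reference tables; the
tail promotes uniform non-templated adenylation and is carried as a
configurable constant). The Tm-gap invariant — core Tm at least 6 °C above
tag Tm — is a hard error, not a warning: assays violating it amplify poorly
because the tagged forward primer is consumed inefficiently, which is
exactly the failure mode reported for the handful of markers that did not
convert to post-PCR labeling.

`design_aso_pair()` follows the APLP-style rules for allele-specific SNP
typing: each allele-specific oligo (ASO) ends 3' in its allele base; a
destabilizing mismatch is introduced at the nearest template G or C within
1–6 nt upstream of the SNP (the offset convention counts upstream of the
3'-terminal SNP base, which is excluded), replacing it with its transversion
partner (G→T, C→A, configurable — the reference only requires "A or T");
candidates containing a G/C run longer than 5 are rejected; the two ASOs get
distinct tags and dyes; and the second allele's core is extended by one
template base at its 5' end so the tagged oligos differ in length by exactly
1 bp (the stagger is never made by trimming the 3' end). The locus-specific
oligo (LSO) is a pig-tailed reverse-orientation primer on the downstream
flank. `validate_snp_assay()` checks every invariant decidable from the
printed record alone — it does not check the identity of the replaced base,
which is unknowable without the genomic template (one published ASO marks a
lowercase `c` as its introduced mismatch, so annotation position rather than
substitution identity is the reliable signal).

## Panels and the two-stage labeling simulation

A panel is feasible when all tags are distinct, assays sharing a dye have
apparent-size windows separated by a guard band, and the assay count is
within capacity (six, the tag-set size). Apparent size is
`product length + 16 + dye mobility offset`; the default per-dye offsets
(−3…+1 bp) are placeholders spanning the observed 13–17 bp shift of
post-labeled versus pre-labeled products, pending per-instrument
calibration. The 10 bp guard band between same-dye windows is the package's
own choice — no published value exists — set to exceed typical SSR allele
steps (2–6 bp). `build_panel()` assigns tags and dyes by deterministic
backtracking, preferring distinct dyes before relying on size separation;
infeasibility is diagnosed with a minimal conflicting assay set (removing
any named member restores feasibility). `dye_swap()` recolors one assay and
re-validates atomically.

`simulate_labeling()` is deliberately rule-based, not kinetic. Stage 1: an
assay's tagged product pool forms iff its core primer anneals at the stage-1
annealing temperature, while tag primers are suppressed when their Tm is
below it (a tag hot enough to prime during amplification is flagged).
Stage 2: a labeled peak is emitted for a (labeled primer, product) pair iff
the tag probe anneals to the product's tag site at the stage-2 temperature
(49 °C). The claims this must reproduce — exclusive dye labeling, no peak
for mismatched combinations, heterozygote peak spacing — are qualitative,
and a kinetic model would add parameters without adding decidability.
`labeling_yield()` models the labeling plateau with pool arithmetic: each
cycle converts `min(conversion × template, primer)` and consumes both pools.
Defaults (template 5, labeled primer 0.5 — the limiting reagent, mirroring
the 0.5 pmol used per reaction — conversion 0.035/cycle) give near-linear
yield through three cycles and a plateau at the fourth, matching the
observed behavior that fixed the protocol at three labeling cycles.

```{r yield}
labeling_yield(4)
```

## The fixture generator

`make_fixtures()` produces seeded uniform-composition background sequences
(default 12, emulating a screen against a dozen unrelated plant genomes)
with optionally planted primer sites, SSR loci and inserts, plus a truth
table with 1-based coordinates. Identical (seed, spec) pairs give
byte-identical files. Synthetic backgrounds have uniform base composition
and no repeat structure, homopolymer tracts or paralogy, so a clean screen
against them demonstrates the scan machinery and the tags' self-consistency
— not specificity against any real genome. Users screening against real
assemblies can pass any FASTA collection to the same functions.

## Problem sizes used by the test suite

The suite exercises: strand symmetry on 1000 random oligos; brute-force
equivalence of the specificity scan on two 10–15 kb backgrounds for ~30
primers; the generator/validator closed loop over multiple constraint
settings with exhaustive-vs-greedy cross-checks on reduced pools; labeling
exclusivity over 200 random valid panels; and the ASO designer/validator
closed loop over 500 random templates. These sizes were chosen to exercise
every code path and boundary generously while keeping the suite quick to
run during development.

## Known limitations

* Mismatch discrimination is positional; no mismatch nearest-neighbor free
  energies, hairpin or primer-dimer thermodynamics are computed.
* The labeling simulation is a rule-based gate plus pool arithmetic; it
  predicts peak presence and apparent size, never fluorescence intensity.
* Dye mobility offsets are placeholders until calibrated per instrument.
* The screen's (seed length, mismatch cap) parameters approximate an
  empirical annealing-temperature gradient; there is no formal mapping
  between the two.
* Scaffold discovery is out of scope: scaffolds are inputs, and new ones
  should be validated against the user's own background collections.
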