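---
title: "Diagnosing mid-frequency hearing loss: methods and design notes"
author: "audiogene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing mid-frequency hearing loss: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audiogene)
```

# The problem

Mid-frequency ("cookie-bite", mediocochlear, U-shaped) sensorineural hearing
loss is a rare audiometric configuration — well under 1% of sensorineural
cases — in which the worst pure-tone thresholds sit in the 1–4 kHz band with
better hearing at both the low and high flanks. Most of it is believed to be
monogenic, but the candidate gene space is large (virtual deafness panels
run past 200 genes), so cohorts are worked up by exome sequencing followed
by a filtering-and-classification cascade. `audiogene` implements that
cascade as a reusable, fully testable pipeline: variant normalization,
sidecar annotation, popmax-frequency and virtual-panel prioritization,
strength-modified ACMG/AMP classification, audiometric phenotyping, and
pedigree-aware family resolution, with a seeded synthetic-cohort generator
standing in for patient data.

# Variant normalization

Matching a called variant against a panel, a sidecar annotation, or another
call set requires one canonical representation per allele. `audiogene`
follows the standard decompose-then-left-align discipline:

* `decompose_variants()` splits multiallelic records into one biallelic
  record per ALT. Genotype allele indices that point at *other* ALTs are
  recoded to missing rather than to reference — the decomposed record simply
  does not know what the other haplotype carries, and inventing a `0` there
  would fabricate a reference call. A conservation property (the multiset of
  non-missing alt calls is preserved across the split) is enforced by test.
* `left_normalize()` trims shared trailing bases, re-anchors empty alleles
  by extending left into a *reference window*, and trims shared leading
  bases while both alleles remain non-empty — the vt algorithm. The package
  carries windows (contig, 1-based start, sequence) instead of a whole
  genome; a window must cover every variant it normalizes plus whatever left
  flank the shift needs, and an undersized window is a hard error rather
  than a silently unshifted variant.

Correctness is checked against an independent enumeration oracle: every
representation of a variant inside its window that reproduces the identical
haplotype is enumerated, the parsimonious ones are kept, and the smallest
position must equal the implementation's output. Idempotence
(`normalize(normalize(x)) == normalize(x)`) is tested on randomized indels.

`N` bases are permitted in windows but match nothing — not even another `N`
— so normalization refuses to trim or anchor across them.

Coordinates are 1-based inclusive wherever VCF is touched; the gene panel is
stored 0-based half-open (BED convention) and converted exactly once, at the
`GenomicRanges` boundary inside the panel filter.

# Annotation and popmax

Annotations (gene, transcript, exon, HGVS strings, Sequence Ontology
consequence, per-population allele frequencies, CADD, REVEL, rsID, and a
curated ACMG evidence string) come from a TSV sidecar keyed by the
normalized `(chrom, pos, ref, alt)`. A sidecar rather than a live annotation
service keeps the artifact self-contained and deterministic. Two rules are
deliberately strict:

* attachment is total — every record lands in `annotated` or `unannotated`,
  nothing is silently dropped; and
* a sidecar key that is itself not left-normalized is an error, which forces
  normalization upstream instead of hiding representation mismatches.

Popmax is the maximum over the global frequency and *all* per-population
frequencies, with the arg-max label. No bottleneck-population exclusion is
applied: the clinical source data this package is calibrated against reports
Ashkenazi Jewish as a popmax population, so excluding founder populations
would change results. Absent frequencies (`NA`) are distinct from observed
zeros and are never imputed; missing CADD/REVEL stays missing.

# Prioritization

`prioritize_two_pass()` runs the cascade per family:

1. **Frequency filter**: remove iff popmax `>= 0.01`. The boundary is
   removed (a variant at exactly 1% is common); variants with no frequency
   data are kept — absence of evidence of commonness is not evidence of
   commonness. The filter is applied to popmax, the strictest reading of
   "maximal MAF over all population databases".
2. **Virtual panel filter**: keep iff the variant's reference span
   intersects any panel interval (one base suffices). Gene-symbol
   disagreements between annotation and panel are logged, not dropped.
3. **Whole-exome fallback**: if the panel leaves a family empty-handed, the
   frequency-filtered variants genome-wide are returned, flagged.

The bundled demo panel covers the nine implicated genes plus seven further
well-known deafness genes. A real deployment would substitute a full
200-plus-gene panel: the panel is two TSVs (`panel_intervals.tsv`,
`gene_modes.tsv`) and nothing in the code depends on its size. Inheritance
modes in the demo follow established usage: TECTA/DIAPH1/MYO7A/TMC1 and the
other dominant deafness genes AD, MYO15A/OTOGL/TMPRSS3/TSPEAR AR, COL4A5 XL.

Fallback candidates can land in genes absent from the mode table;
`resolve_family()` treats that as an error unless the caller supplies
`default_modes`, and `run_pipeline()` passes `c("AD", "AR")` for
fallback-flagged candidates so the pipeline degrades gracefully rather than
aborting a whole cohort.

# ACMG/AMP evidence calculus

Evidence strings such as `"PM3_S, PP1_S, PP3, BS1_P"` are parsed into coded
items whose strength may be modified per variant (`_P` supporting, `_M`
moderate, `_S` strong, `_VS` very strong), as hearing-loss guideline
practice prescribes. Two combining engines are provided:

* **Categorical rules (authoritative).** Items are tallied *at applied
  strength* — an upgraded `PM3_S` is a Strong, which is the entire point of
  strength modification — and the generalized Richards combinations fire on
  the tallies. Pathogenic: two VeryStrong; one VeryStrong plus (one Strong,
  two Moderate, Moderate+Supporting, or two Supporting); two Strong; or one
  Strong with three Moderate / two Moderate + two Supporting / one Moderate
  + four Supporting. Likely pathogenic: VeryStrong + Moderate; one Strong
  with one or two Moderate; one Strong with two Supporting; three Moderate;
  two Moderate + two Supporting; one Moderate + four Supporting; or
  VeryStrong + Supporting (the PVS1 + PM2_Supporting convention). Benign:
  BA1 or two benign-Strong; Likely benign: one benign-Strong + one
  Supporting, or two Supporting.
* **Bayesian points (advisory).** +1/+2/+4/+8 per pathogenic
  Supporting/Moderate/Strong/VeryStrong, negated for benign; `>= 10`
  Pathogenic, 6–9 Likely pathogenic, 0–5 VUS, −1 to −6 Likely benign,
  `<= −7` Benign.

The two engines agree on 15 of the 16 distinct evidence sets in the bundled
clinical fixture. The sole disagreement — `PM3_S, PP1_S, PP3, BS1_P`, two
upgraded Strongs worth 9 points — is asserted in the tests as a documented
expectation, not a bug: it is exactly the kind of case where categorical
combining at modified strengths is more generous than the point sum. The
categorical engine is authoritative because it reproduces every printed
class in the fixture.

Design points worth recording:

* **Conflict policy.** Default `pathogenic_priority`: benign-direction
  evidence sets `conflict_flag` but does not veto a Pathogenic/Likely
  pathogenic combination (required to reproduce the fixture's MYO15A row,
  Pathogenic despite `BS1_P`). `strict` is available and yields VUS on any
  two-direction conflict.
* **Two VeryStrong items.** The generalized combinations, read literally,
  give `{VS, VS}` no rule and hence VUS — so upgrading the Strong partner
  of a PVS1 would *demote* a Pathogenic call. That violates monotonicity
  (adding or upgrading pathogenic evidence must never lower the tier), which
  this package enforces by property test; a `nVS >= 2 -> Pathogenic` rule is
  therefore included, matching ClinGen practice.
* **Benign Moderate.** The combining formulas define only benign Strong and
  Supporting slots; a downgraded-to-Moderate benign item counts with
  Supporting (conservative: it can never strengthen a benign call).
* **PVS1 decision tree.** `pvs1_strength()` maps loss-of-function
  consequences plus minimal context flags: NMD-predicted truncation →
  VeryStrong; frame-preserving exon skip outside a critical region → Strong;
  last-exon truncation replacing a short terminal segment → Moderate.
  Missing context is an explicit "insufficient context" error — the caller
  must then curate the evidence by hand. Leaf outcomes are configurable.
* **Suggestions are advisory.** `suggest_score_evidence()` proposes PP3 at
  REVEL `>= 0.7` (a threshold that exactly separates PP3-bearing from
  PP3-free missense rows in the fixture), PM2 at popmax 0, PM2_Supporting
  up to a configurable rare bound (default 1e-4), and BS1_Supporting above a
  mode-dependent bound (default AD/XL 2e-4, AR 1e-3). The fixture itself is
  internally inconsistent about the PM2 full/supporting boundary (full
  Moderate at popmax 6.5e-5 in one row, Supporting at 2.4e-5 in another), so
  curated evidence strings always win and the suggestion thresholds remain
  configuration, not ground truth.

# Audiometry

`pta()` is the unrounded arithmetic mean over 0.5/1/2/4 kHz (configurable);
the quarter-dB values the clinic reports fall out naturally. `grade_degree()`
bands: normal `<= 20`, mild 21–40, moderate 41–55, moderately severe 56–70,
severe 71–90, profound `> 90` dB HL. The severe/profound boundary at 90 dB
is convention; the clinical source only constrains it to lie between 81 and
109.

`classify_shape()` encodes the inclusion rule for mid-frequency loss: with
W the worst mid-band (1–4 kHz) threshold, a typical cookie-bite requires W
to be the global worst and to exceed the *best* flanking threshold on each
side (250/500 Hz low band, 8 kHz high band) by at least 20 dB. "Best
threshold per flank" is the strictest reading that still admits U-shapes
whose flanks partially recover; whether the high flank should be a wider
band than 8 kHz alone is genuinely open, so the band is a parameter. Shallow
curves relax the margin to 10–19 dB on at least one side. Flat means total
range `<= 15` dB; high-/low-frequency shapes are monotone curves with total
change `>= 20` dB. Evaluation order (flat, typical, shallow, high, low,
other) makes the labels exhaustive and mutually exclusive, and the mid/flat
predicates are shift-invariant by construction (they depend only on
differences).

`confirm_reproducible()` implements the borderline-inclusion rule: a shallow
curve counts only when a mid-frequency shape reproduces at a second visit; a
single typical curve stands on its own.

# Pedigrees and family resolution

`causal_configuration()` reduces a member's genotypes over one gene's
qualifying variants to `full` / `half` / `none` under AD, AR, or XL dosing.
Compound heterozygotes phase through the parents when possible
(`phase_compound_het()`: trans when each parent carries exactly one variant,
cis when one parent carries both and the other neither, unknown otherwise —
never cis/trans without both parental genotypes). Unknown phase is treated
as potentially trans for resolution — families are routinely resolved
without parental DNA — but the resolution record carries `phase = "unknown"`
so reports can caveat it. X-linked heterozygous females count as
affected-compatible by default (manifesting carriers are expected in
X-linked disease); this is a switch.

`resolve_family()` assigns one of four statuses: `solved` (every dose slot
filled by Pathogenic/Likely pathogenic), `compound_P_plus_VUS` (AR only:
exactly one P/LP heterozygote plus one warm-VUS heterozygote, phase not
proven cis), `candidate_VUS` (dose filled by warm VUS alone), `unsolved`. A
**warm VUS** is a VUS whose evidence set contains no benign-direction item.
This is the package's explicit mechanization of a curation judgement: the
clinical workflow selects "candidate VUS" by expert reading, and the warm
rule is the approximation that lets planted candidates count while
benign-leaning background variation does not. `compound_P_plus_VUS` is kept
distinct from both `solved` and `candidate_VUS` because cohort reports count
it separately. Competing genes are ranked by best achievable status, then
more P/LP variants, then lower popmax, then gene symbol — fully
deterministic under input reordering.

Segregation support: `count_informative_meioses()` counts parent-to-child
transmissions where parent and child are genotyped and the child's affection
is known, scoring consistency as the mode predicts and resetting to zero on
any contradiction (also flagged). It matches a brute-force enumeration of
parent-child edges on pedigrees of up to 10 members by test.
`pp1_strength()` maps counts to PP1 strength at thresholds 2/4/6
(Supporting/Moderate/Strong) — a documented convention, not derivable from
the clinical source, and configurable. `detect_inconsistencies()` reports
affected relatives under-dosed relative to a full-configuration proband (the
affected-sibling-heterozygous-carrier pattern, which flags a possible second
cause) and unaffected members with a full configuration (non-penetrance
candidates in late-onset dominant genes).

# The synthetic cohort

`generate_cohort()` emits a complete fake cohort — per-family VCFs, a merged
sidecar, PED files, audiograms, the panel pair, reference windows, a family
manifest, and `truth.json` — from a single seed. Its defaults *are* the
study conditions: 30 families, the 15 carrier families planted with the
fixture variants at their published zygosities, 15 decoy-only families, and
upstream context of 851 screened probands of whom 245 were solved by
first-line GJB2 testing.

Choices a scientist should know about:

* **Decoy discipline.** Every family receives six decoys by default: two
  common (popmax `>= 0.01`; the first is planted exactly at the 0.01
  boundary to pin the filter's edge), two rare off-panel, two rare on-panel
  with benign-direction evidence (`BP4`). Decoy evidence is constrained so
  no decoy ever classifies Pathogenic/Likely pathogenic or counts as a warm
  VUS — this, not curator judgement, is what makes the 8-of-30 candidate
  figure a mechanical outcome. Decoy-only families therefore always have
  pass-1 candidates and the whole-exome fallback is never triggered in the
  default cohort (it is unit-tested separately).
* **Pedigree templates.** Carrier families follow their published
  family-history flags (familial dominant families get an affected
  transmitting parent; sporadic recessive families get ungenotyped parents,
  so compound-het phase stays honestly unknown; the X-linked family has an
  affected brother and carrier mother; one family has an affected sister
  who is only a heterozygous carrier; one has an unaffected carrier
  daughter). Full published pedigree structures are not machine-readable
  here, so these are labelled approximations in `truth.json` metadata; the
  X-linked affected sister's zygosity is assumed heterozygous.
* **Audiograms** are parameterized template curves (U-shaped, shallow-U,
  flat, descending), not resampled patient data. Proband curves anchor to
  the published PTA per ear (including the asymmetric cases) with ±2 dB
  integer jitter and two visits; unaffected relatives get flat 10 dB
  curves. `make_audiogram()` resamples (bounded retries) until the curve
  classifies as its template and lands within the jitter of the target PTA.
* **Indel contexts.** The 53-bp deletion and the TA insertion are embedded
  in synthetic, frozen flanking sequence (the source prints coordinates, not
  flanks); the generator writes them into the VCFs in a deliberately
  non-parsimonious representation so the normalization stage does real work
  on every run.
* **Determinism.** One `set.seed()` call at generation start governs every
  draw; no timestamps are written; regeneration under one seed is
  byte-identical (tested). The headline yields are seed-invariant because
  no random draw can change a family's status.

What passing on this cohort does **not** show: performance on real exomes
(thousands of variants per family rather than a handful; the decoy counts
are deliberately small so the suite runs in seconds), annotation-service
quirks, panel completeness beyond the demo genes, CNVs and structural
variants (out of scope throughout), or the robustness of the warm-VUS rule
against real curation practice.

# Numerical conventions and degenerate inputs

* Percentages are rounded half-up (base R rounds half to even); the cohort's
  share of the upstream screening population is reported at two decimals.
* An empty evidence set classifies VUS with empty rationale, not an error.
* An empty panel removes everything, with a warning.
* An empty VCF body with a valid header is an empty record set.
* Problem sizes in the test suite: 30-family cohorts with 6 decoys per
  family, 40–80-case property loops, pedigrees up to 10 members — chosen so
  the whole suite runs in well under a minute while still exercising every
  stage end to end.

# Known limitations

* The evidence calculus classifies curated evidence; it does not derive
  PS1/PM1/PM5/PP4/PS2/PS4 from raw data (those need literature, hotspot and
  de-novo knowledge).
* HGVS strings are carried opaquely, never validated or projected.
* The audiogram model covers air conduction only — no bone conduction,
  air-bone gaps, ABR/ASSR, or pediatric behavioral testing.
* Family resolution assumes one causal gene per family; digenic and
  mosaic mechanisms are out of scope.
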