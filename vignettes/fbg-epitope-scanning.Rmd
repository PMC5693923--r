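---
title: "Scanning fibrinogen-like globe domains for the TLR4-activating epitope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning fibrinogen-like globe domains for the TLR4-activating epitope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbgscan)
```

## The biological problem

Twenty-four human proteins — the fibrinogen chains, tenascins,
angiopoietins, angiopoietin-like proteins, ficolins, fibroleukin, FGL1,
FIBCD-1 and MFAP4 — share a C-terminal fibrinogen-like globe (FBG) domain
of roughly 230 residues. A subset of these domains behaves as
damage-associated molecular patterns: released or exposed on tissue
injury, they bind and activate toll-like receptor 4 (TLR4) and drive
sterile inflammation. The prototype is the FBG domain of tenascin-C.

Three sequence-localisable sites on the domain surface account for this
activity:

* a **cationic ridge** of non-contiguous K/R residues contributed by
  loops 5, 6 and 7 (in tenascin-C the loop-5 motif `KTRYKLK` carries four
  of them);
* a **loop-7 triad** of polar/hydrophobic residues (D157/I160/N162 in
  domain-local numbering) that assists receptor binding;
* a **cationic C-tail** in loop 10 (`RRKRA`, residues 224–228) that
  cooperates with loop 5.

The classification rule is deliberately simple and binary: *a domain is a
predicted TLR4 activator if and only if its cationic ridge carries at
least three positive charges.* Applied to the catalogued per-protein ridge
counts this calls all tenascins except tenascin-X, and 10 of the 20
non-tenascin FRePs.

`fbgscan` turns this into an executable pipeline: a packaged reference
annotation, alignment-mediated annotation transfer, feature extraction,
the threshold rule, the published mutant/chimera panels as edit
specifications, and a synthetic-domain generator for ground-truth
benchmarking.

## The procedure

For a query domain $t$ and the reference annotation $(r, \mathcal{A})$:

1. **Align** $t$ to $r$ with Needleman–Wunsch under BLOSUM62 and affine
   gap penalties (a gap of length $L$ costs
   $g_\mathrm{open} + L\,g_\mathrm{ext}$; defaults 10 and 0.5). End gaps
   are penalised — the inputs are whole domains, not fragments.
2. **Reject non-members**: if percent identity (identities over the
   shorter input) falls below the floor (default 15%), the sequence is not
   treated as an FBG domain.
3. **Transfer** each annotated interval to the smallest target interval
   covering its non-gap columns; triad positions map one-to-one (a
   gapped position means the triad is absent); the loop-10 region maps to
   every target residue at or after the anchor column, *including*
   overhang past the reference C-terminus, so extended and truncated
   tails are distinguished.
4. **Extract**: ridge count = K/R inside the mapped loops 5∪6∪7
   (histidine excluded — every documented charged motif of this epitope,
   `KTRYKLK`, `RRKRA`, `KAKYR`, uses only K/R); triad present (default
   `exact` mode) iff the three mapped residues equal D/I/N; C-tail
   present iff the mapped loop-10 region holds ≥ 3 K/R (the reference
   tail has 4).
5. **Classify**: predicted activator iff ridge count ≥ 3.

Surface exposure is approximated by sequence intervals: the real epitope
is a three-dimensional patch read off structures and homology models, and
this package transfers fixed reference intervals by alignment instead.
The interval extents are package data, shipped pre-calibrated so that
scanning the packaged domain set reproduces the catalogued ridge column
exactly; they are not uniquely determined by the published anchors
(only the motifs and a handful of residue numbers are printed), which is
a standing limitation.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| substitution matrix | BLOSUM62 | standard for ~30–60% identity proteins |
| gap open / extend | 10 / 0.5 | conventional affine costs at this divergence |
| identity convention | identities ÷ shorter sequence | common reporting convention; reproduces the calibrated 43% FIBCD-1 figure |
| identity floor | 15% | below this, annotation transfer is meaningless |
| ridge threshold | 3 charges | the published rule's boundary (2 → No, 3 → Yes) |
| triad mode | `exact` | the catalogue marks triads sparsely (6/24); conservative scoring over-calls |
| C-tail minimum | 3 K/R | `RRKRA` has 4; only the three active tenascins are marked |
| tiling window/stride | 30 / 25 | nine ~30-mers on a 228-residue domain, matching the peptide-mapping design |

All are exposed through `align_params()` and `scan_params()`.

## Numerical and determinism choices

Traceback ties are broken *diagonal > up > left* (and the same ordering
across the three affine states), making alignments bitwise reproducible.
One consequence worth knowing: where several optimal gap placements tie —
e.g. aligning `KTRYKLK` to `KTRYK`, where the two-residue gap can sit
before or between the C-terminal lysines at equal score — the diagonal
preference during traceback from the C-terminus selects the placement
whose last column is a match. Scores are integer multiples of 0.5 and
therefore exact in floating point; tie comparisons use equality, not a
tolerance. Degenerate inputs fail loudly: empty sequences, out-of-bounds
intervals, residues outside the 20 standard letters (the ambiguity code
`X` is tolerated on input, scored by BLOSUM62, never counted as cationic,
and rejected by mass computation, where it would silently bias the
answer).

The aligner is implemented in the package rather than delegated, so that
the gap convention and the tie-break are exactly as stated and the score
is testable against exhaustive enumeration of all gapped alignments on
short sequences — the test suite does this on random pairs up to length 8.

## The mutant and chimera panel

Eleven published designs ship as data in a small edit grammar
(`sub:124K>A`, `replace:105-134:…`, `trunc:223`, `append:RRKRA`), applied
left to right with from-residue guards so a spec applied to the wrong
parent — or twice — fails instead of silently drifting. Re-scanning the
variants reproduces the designed feature losses: truncation at 223 loses
the C-tail flag, the triad swap to the tenascin-X residues (D157P, I160L,
N162S) loses the triad flag, and the chimeras restore loop 5, tail and
triad on the tenascin-X background.

The panel also exposes, deliberately, where the binary rule stops
working. Removing the four loop-5 charges leaves $7-4 = 3$ ridge charges,
so the rule still calls the variant an activator although the
corresponding protein was inactive in vitro; the same arithmetic affects
both combination mutants, and the `KAKYR` chimera gains three loop-5
charges yet remained inactive. These four rows are reported as
*discordant and flagged*, not suppressed: loop-5 charges are necessary
for activity, while the rule counts charges anywhere in the ridge. A rule
that additionally required ≥ 3 charges *within loop 5* would fit the
panel better, but it is not the published rule, so the package applies
the published one and surfaces the disagreement. Graded ("reduced")
activity is treated as concordant with either binary call and flagged,
since a threshold classifier cannot express it.

## Synthetic domains and what they demonstrate

`generate_domain()` starts from the reference scaffold and implants an
exact number of ridge charges at the seven canonical slots (4 in loop 5,
2 in loop 6, 1 in loop 7; switched-off slots become non-cationic polar
fillers drawn from T/S/N/Q/A so no charge can appear by accident), sets
the triad to D/I/N or P/L/S, keeps, neutralises or truncates the tail,
and then applies background substitutions *outside* the annotated
regions — conservative-only mode restricts them to BLOSUM62-positive
partners. Ground truth is exact by construction; `hard_mode` lifts the
region restriction and recomputes truth from the final sequence. Seeds
are derived as `master + i` for record *i*.

Benchmark conditions used by the tests and `analysis/05`: *n* = 100 clean
domains (ridge uniform on 0–7, triad probability 0.25 and tail
probability 0.125 — the catalogue frequencies 6/24 and 3/24), and
*n* = 200 at a 5% conservative background rate, seed 0. Recovery is exact
in both. What this shows: annotation transfer, counting and
classification are correct and stable under mild, conservation-shaped
noise. What it does not show: performance on real, indel-rich divergence,
on domains whose loop boundaries genuinely shift, or on the structural
component of the epitope that sequence intervals cannot see.

## The packaged sequences are synthetic stand-ins

This package is built and tested fully offline, so the UniProt sequences
behind the catalogue are not shipped. Instead,
`inst/extdata/frep_parents_synthetic.fasta` (and the reference scaffold
itself) contain **synthetic stand-ins**, every header marked
`SYNTHETIC`. They are designed to the documented properties of the real
molecules, fixed before any testing and regenerable deterministically by
`synthesize_frep_fixture()`:

* the reference domain is 228 residues (the documented tenascin-C FBG
  span 1974–2201), has average mass 26.1 kDa, carries `KTRYKLK` once
  inside loop 5, D/I/N at 157/160/162, `NFRNLEG` before the tail and
  `RRKRA` at 224–228;
* each catalogue stand-in carries exactly the catalogued ridge count,
  triad and tail flags; tenascin-R/-W/-X have the documented domain
  lengths (232/241/231), and tenascin-X additionally realises the
  documented chimera geometry — `S-A-T-Y-S` at the KTRYK positions (three
  substitutions create `KAKYR`) and its triad at X-local 161/165/167;
* family divergence follows a star phylogeny: a latent ancestor drawn
  from the scaffold (45% of eligible background positions), members
  diverging from it at 45% (R, W) or 28% (X), which lands all six
  tenascin pairwise identities in the documented 50–60% band; the FIBCD-1
  stand-in is built with exactly 130 differences so its identity to the
  reference is 98/228 = 43%, the documented figure for that pair;
* loop flanks (3 residues each side), the loop-5 aromatic anchors and the
  pre-tail strand are held fixed in all stand-ins — the structurally
  constrained scaffold of the domain — which keeps transferred intervals
  in register at high divergence.

Consequently, catalogue-scan concordance, the identity matrix and the
mass check in the test suite validate the *pipeline against its design
inputs*; they are not an independent confirmation on database sequences.
Re-running the scan on real UniProt sequences only requires replacing the
FASTA and, if necessary, re-running the documented interval calibration.

A note on domain length: the catalogue's printed tenascin spans imply
228–241 residues, slightly wider than the "229–240" range quoted for the
family; the packaged data follow the printed spans.

## Repository shape

The package's computations are all in `R/`; the numbered scripts under
`analysis/` are thin narrative drivers that write the result tables under
`results/` (tiling, catalogue reproduction, panel concordance, identity
matrix, benchmark). They, together with the exported functions, are the
intended command-line surface; there is no separate CLI binary.

## Worked example

```{r example}
ref <- load_reference()
scan_domain(ref$sequence, ref)[, c("ridge_count", "triad_present",
                                   "ctail_present", "predicted_activator")]

mut6 <- apply_mutations(fbg_domain("FBG-C", ref$sequence),
                        parse_mutation_spec("triad swap",
                                            "sub:157D>P;sub:160I>L;sub:162N>S"))
scan_domain(mut6, ref)[, c("ridge_count", "triad_present",
                           "predicted_activator")]
```

## Known limitations

* The epitope is structural; interval transfer is a sequence
  approximation, and the loop boundaries are calibrated, not measured.
* The classifier is binary by design; it predicts neither graded potency
  nor in-vivo inflammation, and the panel shows its blind spot for
  charge *placement* within the ridge.
* No multiple sequence alignment, profile/HMM search, indel simulation
  (outside `hard_mode`) or nucleotide input.
* Histidine is never counted as cationic; at acidic pH this may
  undercount ridges.
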