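# fbgscan

Sequence-based prediction of which human fibrinogen-like globe (FBG)
domains are TLR4 agonists.

Twenty-four human fibrinogen-related proteins (FRePs) — fibrinogen
chains, tenascins, angiopoietins, angiopoietin-like proteins, ficolins,
fibroleukin, FGL1, FIBCD-1, MFAP4 — end in a ~230-residue FBG domain.
Some of these domains act as damage-associated molecular patterns: on
tissue injury they engage toll-like receptor 4 and trigger sterile
inflammation; others are immunologically silent. The discriminating
epitope is sequence-localisable, and this package implements it as a
reproducible pipeline for anyone who wants to scan, mutate or benchmark
FBG-like domains:

* a packaged **reference annotation** of the tenascin-C FBG domain —
  cationic ridge loops 5/6/7 (loop-5 motif `KTRYKLK`), the loop-7
  polar/hydrophobic triad D157/I160/N162, the cationic loop-10 tail
  `RRKRA` (224–228);
* **annotation transfer** onto query domains by global Needleman–Wunsch
  alignment (BLOSUM62, affine gaps 10/0.5, deterministic traceback);
* **feature extraction and classification** by the published rule

  `predicted activator  ⇔  #{K,R in mapped loops 5∪6∪7} ≥ 3`

  plus triad detection (exact D/I/N match by default) and C-tail
  detection (≥ 3 K/R in the mapped loop-10 region);
* the published **mutant/chimera panels** (FBG-C mutants 1–7, FBG-X
  chimeras 1–4) as executable edit specifications with
  predicted-vs-observed concordance reporting;
* **peptide tiling** (nine overlapping 30-mers per domain) and a
  **synthetic-domain generator** with exact ground truth for end-to-end
  benchmarking.

All packaged sequences are **synthetic stand-ins** built to the
documented properties of the real domains (lengths, mass, motifs,
identity structure); headers say so, and the vignette
(`vignettes/fbg-epitope-scanning.Rmd`) explains precisely what they do
and do not emulate. Swap in real UniProt FASTA to scan real proteins.

## Worked example

```r
library(fbgscan)

ref <- load_reference()
scan_domain(ref$sequence, ref)
#>   domain_id identity loop5_count loop6_count loop7_count ridge_count
#> 1    domain      100           4           2           1           7
#>   triad_present ctail_present ctail_positive_count predicted_activator
#> 1          TRUE          TRUE                    4                TRUE
```

The reference scans to a 7-charge ridge (4 from the `KTRYKLK` loop, 2
from loop 6, 1 from loop 7), triad and cationic tail present — a
predicted activator. Catalogue-wide:

```r
cat24   <- load_catalog()
parents <- read_fasta(system.file("extdata", "frep_parents_synthetic.fasta",
                                  package = "fbgscan"))
res <- scan_catalog(cat24, parents)
attr(res, "summary")
#> tenascin_activators    other_activators
#>                   3                  10
```

Three of the four tenascins and 10 of the 20 other FRePs carry a ridge of
three or more charges. Applying a published mutant design and re-scanning:

```r
mut4 <- apply_mutations(fbg_domain("FBG-C", ref$sequence), "trunc:223")
scan_domain(mut4, ref)[, c("ridge_count", "ctail_present", "predicted_activator")]
#>   ridge_count ctail_present predicted_activator
#> 1           7         FALSE                TRUE
```

Truncation at residue 223 removes `RRKRA`: the C-tail flag is lost while
the ridge — the dominant epitope — is intact.

The numbered scripts under `analysis/` run the full study: reference
self-scan and peptide tiling (`01`), the 24-protein catalogue scan
(`02`), the 11-variant mutant panel (`03`), the identity matrix (`04`)
and the synthetic benchmark (`05`), each writing its table under
`results/`.

## Layout

```
R/                 reference annotation, catalogue, FASTA IO, aligner,
                   scanner, mutation engine, synthetic generator, fixtures
inst/extdata/      catalogue TSV, mutant panel TSV, synthetic parent FASTA
analysis/          numbered drivers writing results/
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance suites
vignettes/         methods vignette
```
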