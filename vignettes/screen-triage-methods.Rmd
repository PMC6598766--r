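---
title: "Methods: triaging an ordinal-scored whole-organism drug screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triaging an ordinal-scored whole-organism drug screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfscreen)
```

## The screening model

`zfscreen` implements the decision logic of a zebrafish whole-organism
phenotypic screen in which compound efficacy is read out by in situ
hybridisation (ISH) and summarised as ordinal scores. The screen targets the
adhesion GPCR Adgrg6 (Gpr126) pathway: homozygous mutants over-express the
marker *vcanb* in the developing inner ear and lose *mbp* expression around
the posterior lateral line ganglion. A compound that restores wild-type
expression of both markers in the hypomorphic allele is a pathway modulator;
re-screening on a strong (protein-truncating) allele then separates
compounds acting downstream of the receptor (which still rescue) from
candidate receptor-level agonists (which cannot, because the receptor
protein is absent).

Each assay well holds three embryos. Each live embryo is scored 0–3: for
*vcanb*, 0 means expression suppressed back to wild-type levels (a strong
rescue) and 3 means no effect; for *mbp* the polarity is reversed (3 =
expression restored). The well sum therefore lies in 0–9.

The pipeline stages, each an exported function, are:

1. **Well scoring** (`score_well`): sum the live embryos' scores, or raise
   a `toxic` flag (dead/abnormal embryos present) or an `empty` flag (no
   embryos found).
2. **Primary categorisation** (`categorize_primary`): map the sum to
   categories A–E (A = strongest rescue, sum ≤ 2; E = no effect, sum 9),
   with F for toxic wells and G for empty wells.
3. **Hit confirmation** (`select_hits`): a compound whose primary well lands
   in A–C is retested twice; it is a confirmed hit iff the average of the
   three sums (nine embryos) maps to A–C *and* no individual sum exceeds 7.
4. **Counter screen** (`classify_mbp`): the average of two *mbp* wells (six
   embryos) is binned into `rescue` (> 3.5), `no_rescue` ((1.5, 3.5]) and
   `downregulated` (≤ 1.5); the last group behaves like global transcription
   inhibition and is treated as a false positive of the down-regulation
   assay.
5. **Mechanism classification** (`classify_fr24`): for counter-screen
   rescuers, the strong-allele well sum maps to `downstream` (≤ 7),
   `receptor_candidate` (= 9) or `inconclusive` (= 8, or the missing-data
   codes `ND`/`DE`).

`triage_screen()` composes the stages over a well-results table and returns
one record per compound; `mechanism_report()` tallies the mechanism classes
overall and per library.

## Chemical structuring

Libraries are compared and displayed through standard cheminformatics
primitives, all computed with OpenBabel (via ChemmineR/ChemmineOB):

* **Standardisation** (`standardize_structure`): largest organic fragment,
  charge neutralisation where valence permits, canonical SMILES. The
  procedure is deterministic and idempotent. It intentionally performs no
  tautomer canonicalisation; two tautomeric drawings of a molecule are
  treated as distinct.
* **Fingerprints** (`compute_fingerprint`): binary ECFP4 (Morgan radius 2).
  OpenBabel enumerates circular environments into a fixed 4096-bit space;
  we fold to 2048 bits (index modulo width), the common ECFP4 convention.
  Folding can alias rare bits; at these fingerprint densities (tens of set
  bits) the effect on Tanimoto values is negligible.
* **Similarity** (`tanimoto`, `similarity_matrix`): set Tanimoto. The
  degenerate both-empty case is defined as 0 (with a warning) so matrices
  stay total.
* **Scaffolds** (`bemis_murcko_scaffold`): ring systems plus linkers, side
  chains pruned, exocyclic multiply-bonded atoms retained. Acyclic
  molecules return the empty scaffold and are tallied separately in
  `scaffold_summary()`, excluded from the scaffold count.
* **Duplicates** (`find_duplicates`): full 27-character InChIKey equality
  across libraries, so stereoisomers are distinct compounds.
* **Clustering and layout** (`ward_cluster`, `polar_layout`): Ward
  (`ward.D2`) agglomeration on the distance `d = 1 - Tanimoto`; the polar
  plot encodes dendrogram position as angle and screen category as
  concentric rings (A innermost through G outermost, equally spaced).
* **Networks** (`build_network`, `extract_clusters`): an edge joins two
  compounds iff similarity is *strictly* greater than the threshold
  (default 0.5); connected components with ≥ 5 members are reported as
  candidate structure–activity families.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| category bins | A 0–2, B 3–4, C 5–6, D 7–8, E 9 | well sum | only the A edge is externally fixed; the remainder follow the convention that E is the all-embryos-score-3 "no effect" bin and D is partial suppression. Configurable; validated to partition 0–9. |
| toxicity rule | `any` | — | one dead/abnormal embryo flags the well; a `majority` rule is available. |
| mbp bin edges | 1.5, 3.5 | 6-embryo average | inclusive upper edges. |
| fr24 rule | ≤ 7 / 8 / 9 | 3-embryo sum | downstream / inconclusive / receptor candidate. |
| fingerprint | radius 2, 2048 bits | — | ECFP4 convention. |
| network threshold | 0.5 | Tanimoto | strict inequality. |
| ring radii | 1–7 | — | categories A–G. |
| jitter | ± 0.45 × spacing | radians | seeded, bounded so angular order is preserved; the seed is recorded in the layout. |

For hit confirmation the three-test *average* is categorised on the
continuous scale by treating the integer bin upper edges as inclusive cuts
(A ≤ 2 < B ≤ 4 < C ≤ 6 < D ≤ 8 < E).

## Statistics

* **SSMD** (`ssmd`): β = (μ₁ − μ₂) / √(σ₁² + σ₂²), with unbiased (n − 1)
  standard deviations by default (pass `zf_group_stats` objects to use
  population values). If both spreads are zero, β is 0 for equal means and
  a signed infinity (with a warning) otherwise.
* **LD50** (`fit_ld50`): two-parameter maximum-likelihood sigmoid (logistic
  by default, probit optional) of mortality against log10 concentration.
  The confidence interval profiles the deviance over log10(LD50),
  maximising over the slope at each candidate (the slope search runs over
  log-slope in [10⁻³, 10³], which keeps the one-dimensional optimisation
  well conditioned), and cuts at the χ²₁ quantile. Saturated data (all dead
  or all alive everywhere) are rejected as non-identifiable; grossly
  non-monotone mortality is warned about but fitted.
* **Dose–response tables** (`dose_response_table`): per-concentration counts
  of embryos at each staining-intensity and projection score; dead embryos
  are excluded from score tables and counted in survival only. A Spearman
  correlation of mean score against concentration summarises monotonicity.
* **Ear-width normalisation** (`normalize_ear_width`): plain ratio of
  ear-to-ear width to head width. The upstream study normalised against a
  head-size measurement whose exact definition is not recoverable from the
  available text; the ratio is the simplest scale-invariant choice and is
  documented as such.

The estimator is validated by simulation (`simulate_ld50_series`) at the
assay design the screen describes: 16 embryos per concentration on a
1.5-fold dilution series spanning 0.3–222.2 µM. Over 200 seeded replicates
the test suite requires ≥ 90% coverage of the 95% profile interval and a
median absolute relative LD50 error below 15%. The printed LD50 values of
the original study are *not* reproduced — the underlying survival tables
are not available — only the estimator's statistical behaviour is.

## The synthetic screen

Because no raw screen data are deposited, `generate_library()` and
`simulate_screen()` provide a fully synthetic stand-in with known ground
truth, sized like the real screen (two libraries of 1000 and 2000
compounds).

**What it emulates.** Scaffold-family structure (substituents grafted onto
family cores — dihydropyridine-, xanthine-, flavone-, quinolone-,
benzodiazepinone- and triterpenoid-like — so within-family Tanimoto exceeds
family-to-filler similarity); a diverse singleton remainder; cross-library
duplicates (5% of the first library reappears in the second,
`round(duplicate_fraction * n[1])` pairs); six planted activity classes
(`downstream_agonist`, `receptor_agonist`, `ear_specific`,
`transcription_inhibitor`, `inactive`, `toxic`) with proportions
0.01/0.01/0.01/0.01/0.91/0.05, chosen so primary-screen A–C rates land near
the ~8–10% of the real screen and the toxic fraction near its 5%;
structure–activity coherence (a family member shares its family's class
with probability 0.8); ordinal scoring noise (a score deviates from its
class target by ±1 with total probability 0.15, split evenly and clamped to
0–3); and embryo death (Bernoulli per embryo: 0.9 for the toxic class, a
0.005 background elsewhere — whole-organism assays at this stage have low
but non-zero handling mortality). One master seed drives every stage, and
runs are bitwise reproducible.

**What it does not emulate.** Real vendor catalogues (so the published
scaffold counts 693/682, the 155 duplicate pairs and the 92/205 category
A–C counts are not reproducible here — they depend on the actual
structures); concentration–response of the ordinal scores (everything is
simulated at the screen's single 25 µM design; dose–response enters only
through the separate LD50 simulator); plate-position or batch effects;
compound availability and the manual cherry-picking of category-C
compounds. Passing tests on synthetic data therefore demonstrate that the
*decision logic* is faithful and recoverable, not that any particular real
library would yield particular counts.

At zero noise the pipeline must recover every planted class exactly for
non-toxic compounds; the test suite asserts this exhaustively at the full
3000-compound scale. At the default noise the suite locks the recall
observed at a fixed seed as a regression value; recall of agonist-class
compounds stays above 0.9, with the only losses being compounds that lose
an embryo to background mortality in a retest well (the default `any`-death
rule then voids that retest and the record is flagged incomplete rather
than promoted).

## Numerical and degenerate-input choices

* Averages are kept as doubles and rounded only for display (two decimals,
  as in the published hit table).
* Duplicate-difference bins treat printed integer labels as inclusive upper
  edges on |Δ|: 0, (0, 2], (2, 6], (6, 9].
* Heatmap ordering breaks ties lexicographically by compound id; records
  with a missing counter-screen average sort last and are flagged.
* `ward_cluster` of a single compound returns an empty linkage; an empty
  matrix is an error. Ward heights are monotone by construction
  (Lance–Williams with a reducible criterion); the tests assert it.
* The polar layout clamps the first leaf's angle at 0 rather than wrapping,
  preserving both the [0, 2π) range and strict angular order.
* Libraries cluster jointly by default when laid out together; per-library
  clustering is obtained by simply subsetting the compound table before
  `similarity_matrix()` — both modes are exercised in the tests.

## Problem sizes

The test suite runs the brute-force oracle comparisons (similarity matrix,
network thresholding, scaffolds, duplicate binning) at n ≤ 100 compounds,
the zero-noise end-to-end recovery at 3000 compounds, the noisy regression
run at 3000 compounds, and the LD50 simulation at 200 replicates of a
17-concentration × 16-embryo design. These sizes were chosen to exercise
the pipeline at the scale of the real screen while keeping a full check run
in the low minutes on a single core.

## Known limitations

* OpenBabel's ECFP enumeration is equivalent in spirit but not bit-for-bit
  identical to other toolkits' Morgan implementations; absolute Tanimoto
  values may differ slightly across toolkits even though orderings are very
  similar.
* Charge neutralisation is valence-based; zwitterions that cannot be
  neutralised remain charged, and no tautomer canonicalisation is applied.
* InChIKey-based duplicate detection is sensitive to the drawn protonation
  state in rare edge cases, as in any InChI workflow.
* The LD50 profile interval assumes the two-parameter sigmoid is adequate;
  strong over-dispersion across embryos (clutch effects) would make the
  interval anti-conservative.
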