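---
title: "Quantifying amino-acid misincorporation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amino-acid misincorporation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mistraq)
```

This vignette is the package's own account of the model it implements,
the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic-data generators do and do not
emulate.

## The measurement model

A variant serine tRNA whose anticodon pairs threonine (or valine)
codons misincorporates serine at those codons. In a shotgun proteomics
experiment the proteome is digested with Lys-C (cleaving C-terminal to
every lysine, including before proline), and spectra are searched with
the substitution as a variable modification: a peptide may be matched
in its wild-type form or with serine replacing threonine (−14.0156 Da)
or valine (−12.0364 Da) at up to two positions. Search results arrive
as a PSM table: one row per spectrum with the matched base (wild-type)
sequence, the substituted positions if any, a score, and a decoy flag.

The analysis then proceeds in four stages.

**1. FDR control.** A target–decoy q-value estimator replaces the
semi-supervised rescoring used by production pipelines: for every
score threshold *s*,

$$\widehat{FDR}(s) = \frac{\#\{\text{decoys} \ge s\}}{\max(1, \#\{\text{targets} \ge s\})},$$

capped at 1, and a target's q-value is the minimum of
$\widehat{FDR}$ over thresholds at or below its score, so q is
nonincreasing in score. Score ties count decoys before targets (the
conservative convention). PSMs are gated at q ≤ 0.01 (PSM level) and
decoys removed. We do not attempt to reproduce a rescoring engine's
exact scores: the downstream counting only needs a calibrated 1% gate,
and a transparent estimator makes the gate auditable.

**2. Unique peptides.** Retained PSMs collapse to unique peptide
identity tuples (base sequence, substituted positions, substitution).
The wild-type and substituted forms of one base sequence are distinct
tuples. Counting unique peptides, not spectra, is the primary mode;
spectral-count weighting (`count = "psm"`) is provided because "counts
of peptides" is ambiguous in informal usage, but it is off by default
and the run log records the mode in effect.

**3. Residue-level frequency.** For substitution X→Y,

$$f = 100 \times \frac{\#\{\text{unique substituted peptides with an
observed wild-type sibling}\}}{\#\{\text{unique peptides whose base
sequence contains X}\}}.$$

Two design points deserve justification:

* *The sibling rule cancels detection bias.* Suppose a peptide's
  wild-type form is observed with probability $d$ (abundance,
  ionization, scheduling) and each origin site is substituted with
  probability $r$. The numerator then accrues events at rate
  $r \cdot d$ (substitution and sibling detection are independent) and
  the origin-containing denominator at rate $d$; the ratio estimates
  $r$ with $d$ cancelled. Without the sibling requirement the
  numerator would be gated differently from the denominator and the
  estimate would depend on $d$.
* *Substituted forms stay in the denominator*, counted through their
  base sequence (which contains the origin residue pre-substitution).
  Excluding them would let high mistranslation shrink its own
  denominator. At realistic rates the difference is negligible; the
  flag `denominator_includes_substituted` makes the choice explicit
  and reversible.

A zero denominator yields `NA` with a warning, never 0: "no evidence"
and "no mistranslation" are different results.

**4. Codon level.** Only events that can be attributed to exactly one
codon are counted: the peptide must carry exactly one substituted
position and its base sequence must occur at exactly one location
across the protein database (substring matching, not digest-anchored,
so ambiguity from internal repeats is caught). Events map through the
paired CDS to a codon; each origin-residue occurrence in a uniquely
locating wild-type peptide contributes one wild-type event at its
codon. Per-codon frequency is $100 \cdot n_{sub}/(n_{sub} + n_{wt})$,
and the event-weighted mean over codons reproduces the event-level
overall frequency by construction.

Note the per-codon truth under this counting: a site substituted with
per-molecule probability $r$ contributes (when its sibling is
observed) one substituted event *in addition to* its wild-type
occurrence, so the expected per-codon proportion is $r/(1+r)$ — for
$r \le 1\%$ indistinguishable from $r$ at realistic sample sizes, but
the tests use the exact form.

## Decoding classification

Anticodon bases 34–36 (5′→3′) pair antiparallel with codon positions
3–1. Positions 35/36 must Watson–Crick pair codon positions 2/1; a
mispair there is classed `other`. At the wobble position (34 vs the
codon's 3′ base):

| anticodon 34 | codon 3 | class |
|---|---|---|
| WC partner | — | `watson_crick` |
| A | C or A | `wobble_I34` (A34 deaminated to inosine pairs U, C, A) |
| G | U | `wobble_GU` |
| U | G | `wobble_GU` |
| anything else | — | `mismatch_3prime` |

A34:U is classed `watson_crick`, not wobble: the fully complementary
codon is the reference decoding even though A34 is typically modified
to inosine in vivo. For the AGU anticodon this gives ACU →
`watson_crick`, ACC/ACA → `wobble_I34`, ACG → `mismatch_3prime`.

## Phenotype statistics

The comparison battery mirrors the statistical toolkit of fly
mistranslation studies. Standard fits are delegated to `stats` and
`survival`; only the 2×2 exact test is computed directly, because its
two-sided rule needed to be pinned down precisely.

* **Fisher exact (2×2):** two-sided p is the sum of hypergeometric
  point probabilities ≤ the observed one, with a 1e-12 *relative*
  slack for floating-point ties (distinct hypergeometric probabilities
  at these table sizes differ by far more, so the slack only captures
  genuine rational ties). Degenerate margins return p = 1 with a
  warning. `stats::fisher.test` (which uses a looser 1e-7 slack
  convention) serves as an independent cross-check in the tests.
* **Holm–Bonferroni** via `stats::p.adjust`. Families follow the
  study design: climbing and longevity p-values are corrected
  together when both assays are run on the same animals.
* **Wilcoxon rank-sum:** exact enumeration when the pooled n ≤ 12
  with no ties, otherwise the normal approximation with tie and
  continuity corrections (`stats::wilcox.test` underneath, with the
  mode rule made explicit and reported).
* **Welch t** (unequal variances, Satterthwaite df), the default
  two-sample t of the statistical environment such studies use. The
  both-groups-constant degenerate case returns t = 0, p = 1 with a
  warning instead of an error.
* **Kaplan–Meier** product-limit estimates with Greenwood variance
  and log-log 95% bands (`survival::survfit`); censored subjects
  (e.g. escaped flies) reduce the risk set without a step. **Log-rank**
  via `survival::survdiff` (1 df).
* **Wilson score intervals** for proportions (good small-n coverage;
  the studies' error bars name no method, so the choice is logged
  here and in the run log).
* **Top-quantile subsetting** retains, per group, the ⌈q·n⌉ subjects
  with the largest *death* times (censored subjects are not eligible
  to be "longest-lived"), ties broken by subject id for determinism.

## The synthetic-data generators

`simulation_spec()` defaults define the study-emulating conditions:

| parameter | default | rationale |
|---|---|---|
| substitution / anticodon | T→S, AGU | the threonine-decoding serine variant |
| per-codon rates | ACT 1%, ACC 0.5%, ACA 0, ACG 0 | the recovery-test truth: activity at the Watson–Crick and one wobble codon, none at the 3′ mismatch |
| n_genes, length | 1500, Gamma(12, 29) (~350 aa) | ≥ 5,000 origin-residue events per ACN codon after digestion and length filtering |
| codon weights | uniform over 61 sense codons | neutral usage; configurable for biased genomes |
| detection_prob | 0.95 | wild-type forms of detectable peptides are nearly always seen; < 1 exercises the sibling rule |
| decoy_fraction | 0.2 | typical decoy share after search |
| scores | targets N(6,1), decoys N(0,1) | well-separated, so the 1% gate keeps essentially all targets while decoys calibrate it |
| peptide length | 5–60 aa | detectable Lys-C peptide range |
| ppm jitter | ±5 ppm uniform | well inside the 20 ppm tolerance |

The generator digests every protein, substitutes each origin site
independently at its codon's rate (one substituted PSM per event),
emits the wild-type form with probability `detection_prob` (plus
Poisson-distributed spectral replicates), and appends
reversed-sequence decoys. A ledger records every simulated event per
codon, and a conservation test re-derives the ledger from the emitted
table via independent localization.

What the generators deliberately do **not** emulate: spectrum-level
detail (fragment ions, chromatography, charge states beyond a nominal
2+), abundance-dependent detection (detection is homogeneous across
peptides), search-engine score idiosyncrasies, shared peptides from
homologous gene families (random sequences make cross-gene repeats
vanishingly rare, so the unique-localization filter is exercised by
dedicated fixtures instead), and biased codon usage (available via
weights but not default). Passing recovery tests therefore
demonstrates that the *counting rules and plumbing* are unbiased under
the stated sampling model — not that real spectra are identified
correctly, which is the search engine's job upstream of this package.

Survival fixtures discretize exponential deaths to 3-day inspection
intervals, matching the food-transfer schedule of fly longevity
assays, with escape-type censoring at a uniformly drawn inspection day
at or before death.

## Numerical and interface conventions

* Coordinates are 0-based half-open in memory; file dialects (PSM
  `sub_positions`, location reports) are 1-based. The conversion
  happens exactly once, at I/O.
* CDS records may retain one trailing stop codon (trimmed and
  flagged); internal stops, non-ACGT characters (including N), length
  mismatches and translation mismatches are load-time errors naming
  the gene and first discordant position — per-codon counting cannot
  tolerate ambiguous codon identity.
* I and L are distinct residues with identical mass; collision scans
  report I/L-involving pairs as unresolvable by precursor mass.
* Residue masses are hard-coded standard monoisotopic values; a test
  re-derives all 20 from elemental isotope masses (agreement within
  1e-5 Da). The acetyl delta is the elemental value 42.0106 Da
  (C2H2O); search configurations sometimes print 42.0102, which
  appears to be a transcription variant and is not used anywhere.
* Deltas are carried at full double precision; 4-decimal rounding is
  presentation-only.
* Ties: decoys before targets at equal score (FDR, conservative);
  `gene_id` then position for localization order; `subject_id` for
  survival cutoffs; lexicographic gene id for ranking ties.

## Problem sizes used by the test suite

Simulation-based checks are sized to be decisive yet quick: the
end-to-end per-codon recovery runs one full default-size replicate
(~20,000 PSMs, ≥ 5,000 events per codon, estimates required within 3
binomial SE of the generator truth); the residue-level
estimator-consistency check uses 20 PSM-table replicates over a fixed
600-gene proteome against a closed-form expected frequency; the
log-rank size check uses 1,000 null replicates at n = 100/group; the
Fisher sweep enumerates all 135,750 tables with N ≤ 40. These sizes
are the package's chosen trade-off between statistical resolution and
suite runtime.

## Known limitations

* The q-value estimator is deliberately simpler than semi-supervised
  rescoring; absolute identification rates will differ from
  production pipelines even though the FDR gate is calibrated.
* Frequencies are based on steady-state detected peptides; events
  that destabilize the protein enough to escape detection are
  invisible, so estimates are lower bounds on synthesis-level error.
* Isoform handling is by independent FASTA records: peptides shared
  across isoforms are discarded by the unique-localization filter
  rather than apportioned.
* No MS1-intensity quantitation, probabilistic site localization, or
  Cox/frailty survival modelling; the statistics battery covers the
  comparisons the experimental design calls for and no more.
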