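---
title: "Methods: N-acyl-specific SRM design and internal-standard quantification of NAPE species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: N-acyl-specific SRM design and internal-standard quantification of NAPE species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napequant)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, and the choices made where
the design was genuinely open.

## The species model and its mass arithmetic

A NAPE is represented by its PE-body totals (O-acyl carbons `C` and
double bonds `D`), its N-acyl chain (`n:dn`), and — at molecular-species
level — the explicit *sn*-1/*sn*-2 assignment. The neutral elemental
composition is the closed form

> C(C+n+5) H(2C−2D+2n−2dn+8) N O9 P,

derived once from the structure: a glycerol backbone, two O-acyl esters,
a phosphodiester to ethanolamine, and the amide-linked N-acyl chain.
Because condensation bookkeeping is a classic source of off-by-one-water
errors, the test suite carries an independent oracle that assembles the
molecule from building blocks (glycerol + 2 fatty acids + phosphoric
acid + ethanolamine + N-acyl fatty acid − 5 H2O) and checks exact
agreement on hundreds of randomized species; the oracle is test code,
not part of the library. Masses are monoisotopic throughout (quadrupole
windows are 2 m/z wide, so average masses would also work, but
monoisotopic matches MS practice), and adduct shifts include the
electron mass so positive- and negative-mode conventions agree to
sub-mDa: M+H is +1.007276, M+NH4 +18.033826, M−H −1.007276.

The composition depends only on `(C, D, n, dn)`. That invariance is the
chemistry behind isobaric structural isomers: PE 38:2-N-16:0,
PE 36:2-N-18:0 and PE 36:1-N-18:1 share one formula and precursor m/z.

Parsing accepts the Unicode hyphen variants produced by copying names
from typeset text, and tolerates double-bond position/geometry
annotations (`18:1(9Z)`), which are discarded with a warning because the
mass arithmetic is position-blind.

## Fragmentation model and transition design

Positive-mode collision-induced dissociation of the protonated molecule
(or ammonium adduct) cleaves the C–O bonds on either side of the
phosphate, producing two ions that retain only the N-acyl chain:

* **F1** — protonated N-acyl-phosphoethanolamine, neutral
  C(n+2) H(2n−2dn+6) N O5 P;
* **F2** — F1 minus a neutral loss. Both H-transfer bookkeepings are
  chemically consistent: loss of H3PO4 (giving the dehydrated protonated
  N-acylethanolamine) or of HPO3 (the protonated N-acylethanolamine),
  differing by exactly one water. The package defaults to the H3PO4
  loss and exposes the alternative (`f2_neutral_loss = "HPO3"`); the
  choice affects only the qualifier m/z, not the selectivity argument.

`build_srm_method()` emits exactly two transitions per species. Role
assignment is a design choice the source assay leaves open: F1 — the
phosphate-containing, more NAPE-specific fragment — is the quantifier,
F2 the qualifier; both share the precursor (M+H by default, M+NH4
selectable), a single collision energy (20 eV default; a per-species
table can be supplied via the run configuration), and an acquisition
window of `rt_window` (default 3 min) centred on the predicted
retention time.

`find_isobars()` groups candidates whose precursors fall within a
tolerance (default 0.01 m/z; at tolerance zero, grouping coincides with
compositional identity) and reports, per pair, whether their product-ion
sets differ by more than the Q3 match tolerance (default 1 m/z, half the
2-m/z instrument window). Pairs with disjoint product sets are
*resolvable* by two-transition SRM even when fully co-eluting; pairs
with overlapping products are flagged ambiguous.

Scheduling statistics follow directly from interval arithmetic: the
concurrency at time *t* is the number of windows containing *t*, and the
dwell (dynamic scan) time of a transition is the cycle time divided by
the concurrency at its window centre. The cycle time is an instrument
setting that the assay description does not state; the default of 0.6 s
is typical for the instrument class and is carried only into dwell
statistics, never into any assertion.

## Retention model

Reversed-phase retention of lipids increases with total acyl carbons and
decreases with double bonds. The package fits the bivariate linear form

> rt = b0 + bC·(C+n) + bD·(D+dn)

by unweighted OLS. This strictly generalises the single-parameter ECN
predictor (ECN = C − k·DB corresponds to bD = −k·bC); since no published
k is available for NAPEs the two coefficients are always fitted, never
hard-coded. The fit refuses rank-deficient designs (no variation in
either regressor) and warns — without failing — when a coefficient has a
physically unexpected sign. Predictions are clipped to the run length
(default 18 min, matching a 15-min gradient plus hold) with a warning.
`flag_rt_outliers()` reports observations deviating by more than
`k`·residual SD (default 3), with a machine-epsilon floor on the
threshold so exact fits never flag rounding error: it supports the
homologous-series plausibility check in the chromatographic dimension.

One consequence, documented rather than asserted as chemistry: isobaric
isomers with equal chain totals receive *equal* predicted retention
times. Their partial chromatographic separation in reality is beyond a
totals-based model; the selectivity argument therefore rests on the
product ions, not on retention.

## What the simulator emulates — and what it does not

`simulate_sample()` produces, per transition, a Gaussian peak centred at
the scheduled retention time (plus optional per-species jitter shared by
the transition pair), with area = amount × response factor (times the
species ion ratio for the qualifier), Gaussian baseline noise, clipping
at zero counts, and scheduled acquisition (exactly zero signal outside
the window). Defaults: peak σ = 4 s, sampling interval 0.5 s, run length
18 min, IS = PE 18:1/18:1-N-19:0 at 50 pmol, tissue mass 0.1 g, ion
ratio 0.35. Everything is reproducible from a single integer seed;
calibration samples derive their seeds deterministically from
(base seed, level index, replicate index).

`simulate_calibration()` emulates the validation design: spiked levels
spanning 10–2300 pmol/g (the interior levels are not published; the
default ladder 10, 20, 50, 100, 200, 500, 1000, 1600, 2300 is an
approximately geometric choice spanning that range), processed in
triplicate, with two multiplicative lognormal error components:

* a **per-sample yield factor** (`prep_cv`, default 0.27) shared by all
  species including the IS — the preparation-loss structure that makes
  an internal standard necessary and that cancels exactly under IS
  normalisation; its default reproduces an IS-area RSD around 27 %;
* a **per-species residual factor** (`cv`, default 0.05) applied to
  analytes only and shared by each analyte's two transitions — the
  variability that *survives* normalisation and limits linearity. The
  IS deliberately carries no independent residual, so `cv` is exactly
  the CV of the normalised response.

The simulator does not model peak tailing by default (an EMG option is a
deliberate non-goal at this stage), ion suppression, chemical noise
structure, carryover, or matrix effects. Passing tests therefore
demonstrate correctness of the *computational* pipeline under its own
generative assumptions — they do not validate the wet-lab method on real
tissue, whose headline figures (41 quantified species, ~3 nmol/g total)
derive from measurements no simulation can reproduce.

## Peak detection, integration and S/N: numerical choices

* **Baseline and noise.** The baseline is the median intensity of the
  acquisition window. The noise SD is robust:
  max(1.4826·MAD, (Q60 − median)/qnorm(0.6)). The quantile term exists
  because clipped counts make a near-zero baseline heavily zero-inflated
  — about half the points are exactly zero, which collapses the MAD to
  zero — while the 60th-percentile spread equals the SD for Gaussian
  noise, is insensitive to clipping from below, and stays clear of a
  peak occupying the top of the intensity distribution.
* **Candidates.** Local maxima above baseline + 3·SD whose two
  neighbours exceed baseline + 2·SD. The neighbour rule suppresses
  single-sample spikes and keeps the per-window false-positive rate on
  pure noise well under 1 %.
* **Bounds.** From the apex, the signal is followed outward until it
  returns to baseline + 1·SD, or until a genuine valley: the running
  minimum has dropped below half the apex height and the signal rises
  again by more than 2·SD on two consecutive points. The half-height
  condition prevents noise wiggles near a flat apex from bisecting a
  peak; the two-point confirmation prevents single spikes from
  truncating a flank. A candidate that is not the maximum of its own
  extent is discarded (the true apex claims the region).
* **Apex.** Parabolic interpolation of the top three samples,
  constrained to ±half a sampling interval.
* **Integration.** Trapezoidal, after subtracting the straight line
  between the bound endpoints; negative results are clipped to zero and
  flagged. Integration truncates the far tails at the noise floor, so
  even exact ratio identities (equal analyte and IS areas → exactly
  500 pmol/g) are reproduced to ~1e-6 relative rather than to machine
  precision.
* **S/N** = (apex − baseline)/noise SD, reported as the capped sentinel
  1e6 when the baseline is perfectly flat.

## Confirmation and quantification

A species is detected only if both transitions yield peaks, the apexes
co-elute within `rt_delta` (default 0.05 min) and the observed ion ratio
is within ±`ratio_rel_tol` (default 30 %) of expectation; both
tolerances are package defaults, config-exposed, since the assay
description states the two-transition principle without numbers. Every
failed criterion is named in the result's flags, so an isobaric
interference that contaminates a single product ion surfaces as
`ion_ratio_fail` (or `rt_mismatch`) instead of a silently wrong number.

Concentration uses the quantifier only:
`conc = (area / IS area) × IS amount / tissue mass` (pmol/g). The
qualifier never enters the number — single-transition quantification
with dual-transition confirmation. A sample whose IS fails detection is
invalid and raises a hard error. No multiplicity correction is applied:
this is a targeted assay with a fixed analyte list.

Validation statistics mirror the assay's own battery: unweighted OLS of
response ratio on nominal concentration (slope, intercept, R²),
back-calculated accuracy at low/medium/high QC levels (absolute percent
deviation reported, signed bias alongside; back-calculation through an
unweighted line is intrinsically intercept-noise-limited at the low
end), replicate RSD, and the LLOQ as the lowest level at which every
replicate is detected with quantifier S/N ≥ 10. Whether the original
S/N figure used SD-based or peak-to-peak noise is unstated; the robust
SD definition above is this package's documented choice.

## Problem sizes and degenerate inputs

The bundled test-and-acceptance runs use deliberately modest sizes — a
60-species candidate panel (9 PE bodies × 6 N-acyl chains, plus five
N-17:0 validation analytes and the IS), calibration series of 9–11
levels in triplicate, traces of ~2200 points — chosen so the entire
suite exercises every stage end to end in well under a minute while
leaving the statistics informative. Degenerate inputs are contracts,
not accidents: empty pools error; a zero-width integration is zero; a
constant calibration response has slope 0 and R² 0 by definition; a
flat baseline caps S/N at the sentinel; `k = Inf` flags no outliers.

## Known limitations

* Retention prediction cannot separate equal-total isobars (above).
* Unweighted calibration makes low-level back-calculated accuracy
  sensitive to intercept noise; weighted fits are deliberately out of
  scope to match the assay's validation style.
* The Gaussian peak model understates integration error for tailing
  peaks; the ion-ratio tolerance (±30 %) absorbs moderate shape
  mismatch.
* Negative-mode fragmentation (product ions from the *sn*-1/*sn*-2
  chains, not the N-acyl) is documented here for completeness but is
  intentionally not implemented for quantification.
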