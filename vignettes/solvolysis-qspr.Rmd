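---
title: "Solvolysis kinetics and QSPR of fluocinolone acetonide ester prodrugs"
author: "esterkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solvolysis kinetics and QSPR of fluocinolone acetonide ester prodrugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esterkin)
```

## The scientific problem

Topical corticosteroid esters are prodrugs: pharmacological activity
appears only after the C-21 ester bond is cleaved and the parent alcohol —
here fluocinolone acetonide (FA) — is released. How fast a candidate ester
is cleaved is therefore a design property, and an inexpensive *in vitro*
surrogate for enzymatic activation is solvolysis in ethanol–water (90:10
v/v) with excess NaHCO~3~, followed by HPLC over 24 h. `esterkin`
implements that analysis for six FA C-21 esters (the acetate FA-21-Ac and
five α-alkoxy/aryloxy-alkanoyl esters), links the rate constants to
quantum-chemical descriptors of the ester moiety, and links rate constant
plus lipophilicity to anti-inflammatory activity.

## The kinetic model

With the base in large excess the cleavage is pseudo-first-order in the
ester:

$$c_\mathrm{ester}(t) = c_0 e^{-K t}, \qquad
  \ln c_\mathrm{ester}(t) = \ln c_0 - K t .$$

What the detector sees is the *liberated FA*, quantified through a
calibration line fitted by ordinary least squares (free intercept — the
origin is not forced). The ester concentration follows by molar mass
balance,

$$c_\mathrm{ester}(t) = c_0 - c_\mathrm{FA}(t),$$

which is exact only in molar units; weighed masses (mg) are converted to
µmol/L via monoisotopic molar masses derived from the esters' reported
ESI-MS [M+H]^+^ values. `fit_rate_constant()` then regresses
$\ln c_\mathrm{ester}$ on time (natural logarithm, unweighted OLS,
$t = 0$ included as a fit point) and reports $K = -\mathrm{slope}$ in
h^−1^ — the sampling grid is in hours, so rate constants are per hour
throughout.

Numerical edge cases are handled conservatively rather than silently:

* FA concentrations that come out negative under noise are floored at 0
  with a warning;
* FA above $c_0$ is clipped to $c_0$;
* ester concentrations below a floor of $10^{-9} c_0$ are excluded from
  the log fit (the logarithm is meaningless there) and counted in
  `n_excluded`; at least three usable points are required.

## Descriptors

The electronic descriptors are built from tabulated Mulliken charges on
the ester moiety's carbonyl carbon (C), carbonyl oxygen (O1) and ester
oxygen (O2) at seven theory/solvation levels (AM1; HF and B3LYP with
STO-3G and 6-31G bases, in gas phase and in ethanol via COSMO or CPCM).
Two derived quantities are formed per level:

* charge differences, e.g. $\Delta q_{C\text{-}O2} = q_C - q_{O2}$
  (carbon minus oxygen, so typical values are positive), and
* bond polarities, $P = \Delta q \times d$, with $d$ the bond length in Å
  from the AM1-optimised structure.

AM1 bond lengths are paired with *every* level's charges — the only
convention under which the published derived cells reproduce, and the one
stated for the solvated model. Level labels form a closed vocabulary
(`table1_levels()`) so a misspelled level can never silently misalign a
column. Steric hindrance and cLogP are passthrough inputs; their
generating tools are out of scope.

## The packaged table and its annotations

The package ships the published per-ester table verbatim as checksummed
CSVs (`load_table1()`, `table1_descriptors()`). Transcription fidelity is
taken literally: apparent defects are preserved as printed and declared in
a machine-readable annotation file instead of being corrected, in three
categories:

* `typo` — cells inconsistent with the rest of the table: one level block
  printed twice (stored once, flagged), one O1 charge that echoes the C
  row, three O1 charges repeating another level's row, and the derived
  cells computed from them. Computations touching these cells warn.
* `rounding` — derived cells whose printed value sits one unit in the
  fourth decimal away from recomputation on the printed charges. The
  published derivations evidently used unrounded charges, so agreement
  from the rounded table is attainable only to one ulp at the table's
  4-decimal resolution; 94 of the 168 derived cells close exactly and the
  annotated remainder close to one ulp (the closure test asserts both).
* `r_unrounded` — rows whose printed correlation with K differs by more
  than 0.002 from recomputation on the printed row values, again because
  the published statistics used unrounded internals; recomputation stays
  within 0.006 for all of them.

Comparisons at the table's precision use round-half-even to 4 decimals.

## Correlation screen and regressions

`screen_descriptors()` computes the Pearson product-moment correlation of
every descriptor row with the rate constants and ranks by $|r|$ (ties
broken lexicographically by label, for determinism). No multiple-testing
correction is applied — the screen is a ranking device, not an inference —
and with $n = 6$ esters none would be meaningful.

`fit_slr()` is the single-descriptor QSPR line written out from the
classical normal equations, reporting slope and intercept with their
standard errors, the correlation $R$, the standard error of the estimate
$\sqrt{SSE/(n-2)}$ and $F = MSR/MSE$ on $(1, n-2)$ degrees of freedom.
Unweighted OLS is used throughout; in particular the 24 h leverage point
of the kinetic fits receives no special weight. On the study table the
top-ranked descriptor is the C–O2 bond polarity from B3LYP/STO-3G charges
with COSMO ethanol solvation, and regressing K on it reproduces the
published line $K \approx 2.58\,P_{C\text{-}O2} - 1.47$ (the tests
recompute the full statistics).

`fit_mlr()` links activity (percent edema reduction) to K and cLogP by
OLS with an intercept. The published description of that regression does
not write out the design matrix; an intercept and no interaction is the
conventional reading and is what the generator and fit use. With $n = 6$
and three coefficients, only three residual degrees of freedom remain —
the fit warns whenever one or fewer remain.

## What the synthetic generator emulates — and what it does not

`simulate_calibration()` follows the published dilution design: 8 mg FA
in 5 mL ethanol, aliquots of 0.1, 0.4, 0.7, 1.0 and 1.3 mL made up to
10 mL, i.e. standards at the 0.1 : 0.4 : 0.7 : 1 : 1.3 ratios
(≈ 35–460 µmol/L). `simulate_time_course()` uses the published weighed
masses (16–20 mg per 100 mL) and sampling schedule (0, 2, 4, 6, 8, 24 h).
Detector behaviour is not described in the publication, so two generator
settings are declared rather than inferred and fixed once: a detector
response of 25 area units per µmol/L with zero offset (arbitrary detector
units), and multiplicative Gaussian noise with standard deviation equal
to 1 % of the signal — typical UV-HPLC peak-area repeatability. The
activity generator is linear in K and cLogP with coefficients (30, 350,
5) and 5 % noise, chosen to place the six esters' activities in a
plausible 45–75 % edema-reduction band; the real assay values are
published elsewhere and are deliberately not reproduced here.

The generator emulates integrated peak areas only. It does **not**
simulate chromatogram shapes, retention-time drift, integration error,
carry-over, baseline artefacts, or any deviation from first-order
kinetics at late times. Passing recovery tests therefore show that the
estimators invert this idealised measurement model — unbiased rate
recovery at 1 % noise, median recovery within a few percent over
simulated repeats — not that real chromatographic data would behave as
well.

## Reproducibility and problem sizes

Every stochastic function takes an integer `seed` and restores the
caller's RNG state; `run_pipeline()` derives per-stage seeds from one
master seed so stages can be re-run independently, and writes a manifest
with md5 checksums of every output — identical configurations give
identical checksums. The recovery studies in the test suite use 200
simulated repeats per ester for kinetic recovery, 500 repeats for the
activity regression and 1000 random datasets for the OLS identity checks;
these sizes make the Monte-Carlo medians stable to well under the
tolerances they are compared at while keeping the suite quick.

## Known limitations

* Six esters is a very small sample: the screen's correlations carry wide
  sampling error, and the QSPR line's impressive $R = 0.99$ rests on four
  residual degrees of freedom.
* The published raw chromatographic data are not available, so the
  measured rate constants are fixture constants; only simulated recovery
  is testable.
* Closure of the printed derived cells is limited to one ulp by the
  table's own rounding (see the annotation categories above).
* The activity regression is exercised on synthetic data only; the
  published multiple correlation against the real assay is not
  desk-reproducible from the material packaged here.
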