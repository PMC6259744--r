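# esterkin

Solvolysis kinetics and QSPR modelling of corticosteroid ester prodrugs.

Corticosteroid C-21 esters are prodrugs: they act only after the ester
bond is cleaved and the parent alcohol — here fluocinolone acetonide
(FA) — is released. Solvolysis in ethanol–water (90:10 v/v) with excess
NaHCO₃, followed by HPLC quantitation of liberated FA over 24 h, is a
cheap *in vitro* surrogate for that activation. `esterkin` implements the
full analysis for six FA C-21 esters, for medicinal chemists who want to
rank candidate esters by cleavage rate and relate that rate to computable
molecular descriptors:

* **Kinetics.** FA is quantified through an OLS calibration line; the
  ester concentration follows by molar mass balance
  `c_ester(t) = c0 − c_FA(t)`; the pseudo-first-order rate constant is
  the negative slope of `ln c_ester` versus time (h⁻¹).
* **Descriptors.** Per theory/solvation level, charge differences
  `Δq = q_C − q_O` across the C–O2 (ester) and C=O1 (carbonyl) bonds and
  bond polarities `P = Δq × d` with AM1 bond lengths `d`.
* **QSPR.** A Pearson correlation screen of every descriptor against the
  rate constants, then the single-descriptor line
  `K = a · P_C-O2 + b` with full OLS statistics (standard errors of both
  coefficients, R, SE of estimate, F), and a multiple regression of
  anti-inflammatory activity on K and cLogP.
* **Data.** The published descriptor table ships as a checksummed
  plain-text fixture, with a machine-readable annotation list of its
  typos and rounding artefacts; a seeded synthetic generator emulates the
  calibration standards, solvolysis time courses and activity data, so
  every stage is testable without instrument data.

## Worked example

Screen the packaged descriptor table against the measured rate constants
and fit the QSPR line on the top-ranked descriptor:

```r
library(esterkin)

t1  <- load_table1()
d   <- table1_descriptors()
scr <- screen_descriptors(d, t1$K)
scr
#> <descriptor_screen> 53 descriptors vs K (n = 6); top 10 by |r|:
#>  rank                        descriptor      r flagged
#>     1 B3LYP/STO-3G COSMO ethanol P_C-O2 0.9924   FALSE
#>     2   B3LYP/STO-3G COSMO ethanol C-O2 0.9853   FALSE
#>     3                            d_C_O2 0.9627   FALSE
#>     4      HF/6-31G CPCM ethanol P_C-O2 0.9578   FALSE
#>     ...

p  <- as.numeric(as.data.frame(d)[d$level == "B3LYP/STO-3G COSMO ethanol" &
                                  d$quantity == "P_C-O2", attr(d, "esters")])
fit_slr(p, unname(t1$K), xname = "P_C-O2", yname = "K")
#> K = (2.5831±0.1597) × P_C-O2 − (1.4672±0.0920)
#> R = 0.9924, SE = 0.0034, F = 261.689  (df = 1, 4; n = 6)
```

The best predictor of the solvolysis rate is the polarity of the C–O2
ester bond computed with ethanol solvation (COSMO), and the fitted line
says each 0.01 e·Å of extra bond polarity buys about 0.026 h⁻¹ of
cleavage rate across these esters.

Simulate one ester's solvolysis experiment end to end and recover its
rate constant:

```r
cal <- fit_calibration(simulate_calibration(seed = 1))
tc  <- simulate_time_course(fa_esters()[["FA-21-Ac"]], calibration = cal,
                            seed = 2)
s   <- ester_concentration(quantify_fa(tc$fa_peak_area, cal),
                           c0 = attr(tc, "c0"), times = tc$time_h)
fit_rate_constant(s)
#> <rate_fit> K = 0.06167 1/h  (r = -1.0000, n = 6)
round(solvolysis_percentage(s), 1)
#> [1]  0.0 11.6 22.1 30.5 38.8 77.2
```

At 1 % detector noise the fitted K (0.0617 h⁻¹) sits within a percent of
the generator's truth (0.0615 h⁻¹), and three quarters of the acetate is
cleaved by 24 h. `run_pipeline(pipeline_config(seed = 1))` chains all
stages — simulation, kinetics, descriptors, screen, QSPR, activity
regression — and writes every table plus a checksum manifest.

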