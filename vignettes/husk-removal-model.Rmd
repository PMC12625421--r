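---
title: "Modelling selective THC removal from hemp seeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling selective THC removal from hemp seeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huskmodel)
```

## The problem

Hemp seeds are regulated on their delta-9-tetrahydrocannabinol (THC)
content — in Korea, 5 mg/kg for seeds and 10 mg/kg for hemp seed oil. The
THC is very unevenly distributed: the dense outer husk (hull) carries on the
order of 300 mg/kg while the pressed nut kernel carries about 2 mg/kg, a
husk-to-kernel ratio above 100. Traditional practice removes a third or more
of the seed mass by mechanical dehulling to be safe; the model in this
package quantifies how little actually needs to go.

## The spherical shell model

The seed is modelled as a sphere of radius $R$ whose outer shell of
thickness $t_H$ is husk and whose inner ball of radius $r_{c,max} = R - t_H$
is kernel. The husk volume fraction is

$$f_H = 1 - \left(1 - \frac{t_H}{R}\right)^3 .$$

Processing pares the seed from the outside in: removing a fraction $x$ of
the whole-seed volume leaves a core of radius $r_c = R (1-x)^{1/3}$.
Removing a shell down to $r_c$ removes volume
$\tfrac{4\pi}{3}(R^3 - r_c^3)$, the integral of $4\pi r^2$; the package
checks this closed form against numerical quadrature. If removal goes past
the husk, the over-extraction thickness $t_{OE} = R - r_c - t_H$ measures
kernel lost.

While some husk remains ($x \le f_H$), the remainder is a husk/kernel
mixture. For any conserved quantity carried at level $\rho_H$ by husk and
$\rho_c$ by kernel (density, or a component concentration),

$$\rho_{remain}(x) = \rho_H - (\rho_H - \rho_c)\,\frac{1 - f_H}{1 - x},$$

decreasing from the whole-seed mixture value at $x = 0$ to the kernel value
at $x = f_H$; beyond that only kernel remains. Density and THC concentration
are deliberately implemented through one shared kernel function
(`remainder_density()`, `remainder_concentration()`), because the
concentration model *is* the density model under the substitution
$\rho \to C$. For the reference seed (10% husk at 1.5 times kernel density)
the density runs from $1.05\,\rho_c$ down to $\rho_c$.

Setting $\rho_{remain}(x^*) = L$ for a regulatory ceiling $L$ gives the
closed-form minimal removal

$$x^* = 1 - \frac{(C_H - C_C)(1 - f_H)}{C_H - L},$$

which `min_removal_for_limit()` evaluates and cross-checks by bisection.

```{r threshold}
thr <- min_removal_for_limit(0.10, 300, 2, korea_limits("seed"))
thr
```

Removing just over 9.1% of the seed volume — essentially the husk alone —
meets the Korean seed ceiling; the traditional one-third removal is far more
than necessary.

### Conventions and open choices

* **$x$ is a fraction of whole-seed volume.** The source analysis phrases
  the threshold as a percentage "of $V_H$", but its own algebra divides by
  $V_R - x V_R$, i.e. $x$ scales the *total* volume. Treating $x$ as a
  fraction of $V_R$ reproduces the printed 9.1% exactly (9.1% of $V_R$ is
  about 91% of a 10% husk), so that reading is canonical here.
* **Volume weighting.** The concentration formula volume-weights husk and
  kernel even when their densities differ. That is kept as the canonical
  model; `whole_seed_concentration()` exposes a clearly labelled
  mass-weighted variant for comparison.
* **Husk thickness vs fraction.** The exact spherical formula maps husk
  fractions of 10–75% to relative thicknesses of 3.45–37.0%. Published
  simulation summaries quote 2–33% for the same range; that plotted
  convention cannot be recovered from the text, so the exact formula is used
  and the discrepancy simply noted.
* **Inclusive boundary.** Compliance uses $\le$: a value exactly at the
  ceiling passes, matching the "at or below" phrasing of the regulation.
* **Units.** The canonical concentration unit is mg per kg of matrix
  (regulatory limits are mass-per-mass); `mg_per_L_to_mg_per_kg()` converts
  solution measurements when a density is known. Lengths are mm, volumes
  mm³.

## Fitting peeling series, and what is identifiable

`fit_peeling_series()` recovers parameters from measurements $(x_i, C_i)$ on
the partial-husk branch. In the transformed predictor $u = 1/(1-x)$ the
model is the straight line $C = a - b\,u$ with $a = C_H$ and
$b = (C_H - C_C)(1 - f_H)$: the branch carries exactly **two** identifiable
parameters. $f_H$ and $C_C$ cannot both be separated from $b$ by such data —
the likelihood is flat along the ridge
$C_C(f_H) = a - b/(1 - f_H)$. The fitter therefore requires the
husk-fraction search bound (in practice known from seed geometry or
dehulling practice), estimates $(a, b)$ by exact ordinary least squares,
pins $f_H$ at the bound, and reports this explicitly (`f_H_at_bound`).
Standard errors for $C_H$ and $C_C$ come from the OLS covariance by the
delta method, with residual-bootstrap intervals as a check. On noiseless
series the recovery is exact; with 1 mg/kg noise on 50 points the estimates
fall within three standard errors of the truth in well over 95% of
replicates (verified over 200 seeded replicates in the test suite).

## The extraction simulator

The roast-and-wash protocol (5 g seed; 10–40% edible oil by seed mass;
50 °C for 30 min; washing with water at four times the seed mass) is
simulated as a mass balance over four THC pools: free (recovered) oil, wash
water, the absorbed-oil/surface film on the residue, and the seed interior.

* **Kinetics.** No kinetic law is published beyond first-order dependence on
  concentration, so roasting moves the husk-accessible pool toward its
  equilibrium split as $1 - e^{-kt}$, with $k = 0.2\,\mathrm{min^{-1}}$ by
  default. The equilibrium split $K m_{oil} / (K m_{oil} + m_{seed})$ uses
  the oil/water partition coefficient $K = 10^{\log P}$
  (`partition_coefficient()`); cannabinoid $\log P$ values near 6–7 make
  this split essentially complete.
* **Accessible pool.** Only husk THC is extractable during roasting; the
  kernel pool is shielded. This mirrors the selective-removal premise and is
  configurable.
* **Oil absorption.** Seeds retain oil up to a fixed capacity, default
  0.025 g oil per g seed, so that 5–25% of the input oil stays absorbed
  across the 10–40% oil grid. Raising the capacity reproduces the observed
  failure of oil separation at low oil fractions (a `no_free_oil` flag).
* **Routing.** Separated oils showed no cannabinoid peaks, so by default
  only 10% of extracted THC leaves with the free oil; the rest sits in the
  surface film, where washing reaches it.
* **Washing.** Each cycle contacts 80% of the surface pool and transfers at
  most what the water can dissolve (2.8 mg/L for THC — the aqueous
  solubility cap is enforced as an invariant). The default uses fresh water
  per cycle; reusing water accumulates solute toward the cap and provably
  removes no more than fresh water. The reported practice of reusing water
  with small top-ups sits between these extremes but is not identifiable
  from published data.

Per-stage THC masses were never published — only the endpoint (residue
totals of 1.5–3.3 mg/kg, compliant at 5 mg/kg) — so $k$, the routing split
and the wash efficiency are tuned to that endpoint only.
`scripts/tune_extraction.R` prints the tuning grid; with shipped defaults
the simulated residue is about 2.8 mg/kg, inside the published band, and
mass balance holds to 10⁻⁹ relative across random protocols (property-tested
on 1,000 draws). Temperature is recorded metadata only: the protocol fixes
50 °C and no degradation kinetics are modelled.

## Chromatographic quantification

The PK16-style pipeline quantifies a 10-min isocratic run at 220 nm:

1. **Detection** (`detect_peaks()`): local maxima of a lightly smoothed
   trace above a height threshold, filtered by topographic prominence and
   merged within a 0.1-min resolution window.
2. **Integration**: trapezoidal rule over a region bounded at the midpoint
   to the neighbouring peak or at ±0.45 min, minus a linear baseline whose
   endpoint levels are averaged over flanking windows of clean baseline
   (up to 0.35 min outward); this averaging is what keeps low-concentration
   areas accurate under noise and absorbs slow drift.
3. **Assignment** (`assign_peaks()`): by retention window. Anchored windows:
   impurity/solvent front < 2 min (pushed there by the PK0 diluent, and
   excluded from potency), CBD 2.7–3.3 min, delta8-THC 4.0–5.0 min,
   delta9-THC 5.0–6.0 min; under the slower AOA condition delta9-THC elutes
   near 7 min. The other thirteen analyte windows are explicit repository
   conventions placed non-overlapping within 2–10 min, used consistently by
   the generator and the assigner — they are not claims about the real
   instrument table, which is unpublished.
4. **Calibration** (`fit_calibration()`): per-analyte ordinary least
   squares, intercept reported (not forced through origin), from the
   8-level twofold serial dilution of a 50 mg/L stock standard mixture
   ("ppm" read as mg/L). Quantification refuses to extrapolate beyond 1.5×
   the top level.
5. **Verdict** (`total_thc_verdict()`): total THC is the sum of the neutral
   delta8 and delta9 isomers; acid forms are quantified but reported
   separately because no decarboxylation weighting is defined.

Dilution ratios "a:b" are read as a parts diluent to b parts sample (factor
$(a+b)/b$, so the 4:1, 1:1, 1:1 pretreatment chain composes to 20) — the
notation is not defined in the source, so the convention is fixed here and
documented.

Closed-loop accuracy: synthetic chromatograms spanning 0.5–50 mg/L,
quantified against a calibration built from integrated synthetic standards,
recover the generating concentration within 2% in all of 100 fixed-seed
cases (the observed worst case is under 1%).

## What the synthetic generators emulate — and what they do not

`gen_seed_lot()`, `gen_peeling_series()`, `gen_chromatogram()` and
`gen_calibration_set()` produce every input the pipeline needs, with ground
truth attached. Central values are the reported ones (10% husk, density
ratio 1.5, 300/2 mg/kg); all spreads and noise levels are repository
conventions (husk fraction SD 0.01, density-ratio SD 0.05, concentration SDs
20 and 0.2 mg/kg, chromatogram baseline noise SD 0.3 signal units with a
0.5-unit slow drift — signal-to-noise above 50 even at 0.5 mg/L). Peaks are
symmetric Gaussians of SD 0.08 min at window centres with area strictly
proportional to concentration. Real chromatograms have tailing, retention
drift, co-elution and matrix effects; real seeds are ellipsoidal and
heterogeneous. Passing tests therefore demonstrate the correctness of the
computations and the internal consistency of the pipeline, not instrument
performance on real extracts.

Every generator takes an explicit seed, uses a private RNG stream (the
global RNG state is saved and restored), and is bit-reproducible.

## Numerical choices

* Thresholds solve in closed form; the bisection cross-check uses
  `stats::uniroot()` at machine tolerance, and the two agree to 10⁻¹⁰ over
  10⁴ random parameter draws in the test suite.
* The shared mixing kernel clamps its output to the $[\rho_c, \rho_H]$
  interval to absorb floating-point undershoot at the exact-husk boundary;
  the over-extracted branch returns the kernel value rather than
  extrapolating the formula to non-physical negatives, and $x = 1$ is a
  domain error for concentration (nothing remains to have a concentration).
* Degenerate inputs: a huskless seed ($t_H = 0$) is accepted and gives
  $f_H = 0$; a peeling series with fewer than four distinct removal levels
  is rejected as under-determined, and identical levels as singular.
* Test problem sizes were chosen to keep the default suite fast while still
  exercising the asymptotics: 10⁶ random geometries for volume
  conservation, 10⁴ draws for solver agreement, 1,000 random protocols for
  mass balance, 100 chromatogram round-trips, 200 replicate fits.

## Limitations

The model is volumetrically ideal (perfect spheres, uniform shells); it does
not address seed-to-seed variability beyond the lot generator's simple
truncated-normal spreads. The extraction simulator's stage parameters are
endpoint-calibrated, not mechanistic. Cannabinoids other than total THC are
carried only through the chromatography module; decarboxylation (THCA to
THC) and thermal isomerisation are out of scope, as are real vendor data
formats and MS/MS identification.
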