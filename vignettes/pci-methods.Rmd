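---
title: "Postcolumn infusion QC: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Postcolumn infusion QC: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pciqc)
```

## The measurement model

Postcolumn infusion (PCI) adds a constant flow of standards to the LC
eluent between column and source. Because the infused amount reaching the
sprayer per unit time is constant, any time structure in a standard's
extracted-ion trace reflects changes in ionization efficiency — i.e. the
matrix arriving from the column at that retention time. The package's core
quantity is the matrix-effect profile

$$R_s(t) = \frac{I_s^{\mathrm{sample}}(t)}{I_s^{\mathrm{reference}}(t)}$$

for standard $s$, with a solvent (or extracted-blank) injection as the
reference. The model assumptions are:

1. **Constant infusion.** The PCI pump is stable over a run; slow drift is
   a batch-level observable (see drift detection), not corrected for.
2. **Multiplicative suppression.** Coeluting matrix competes for charge,
   scaling — not offsetting — the standard's response. The ratio $R_s(t)$
   therefore recovers the suppression depth directly: a matrix that
   removes 80% of the ionization gives $R \approx 0.2$.
3. **Shared time axis.** Sample and reference runs use the same gradient;
   traces are resampled onto the reference scan grid by linear
   interpolation but never warped. Retention-time shifts between runs blur
   region boundaries rather than being corrected (a stated non-goal).

The reference is a designated solvent run. Using a batch-median reference
instead is possible by passing precomputed median traces to
`injection_metrics()`, but the solvent default keeps the interpretation of
$R$ absolute rather than relative to the batch.

## Standards panel

The default panel (`default_panel()`) holds eight isotope-labelled drugs
spanning a wide polarity range — metformin-d6, atenolol-d7,
acetaminophen-d4, caffeine-d3, nifedipine-d6, diclofenac-13C6,
lacidipine-13C8 and simvastatin-d6 — at infusion concentrations between
0.025 and 0.25 mg/L, chosen so each trace sits well above background noise
without suppressing the analytes themselves. Isotope labels are first-class
element symbols (`D`, `[13C]`) with their own monoisotopic masses, since
label-aware formulas are what make the panel distinguishable from the
analytes it monitors. Simvastatin-d6 is additionally monitored as its
Na$^+$ and K$^+$ adducts, reflecting its weak protonation.

Adduct m/z values are computed in the electron-corrected convention by
default. The lock-mass constant is deliberately *not* recomputed: the
shipped value 556.2771 is the leucine-enkephalin [M+H]$^+$ in the
hydrogen-atom convention (neutral mass + 1.007825, no electron
subtraction), which is what TOF instrument software reports. Recomputing it
with electron correction gives 556.2766 — a ~1 ppm systematic offset
against the instrument's own axis — so the verbatim constant is the
default and both conventions are exposed through
`adduct_spec(electron_correction=)`. Neither is asserted "correct"; they
are different bookkeeping conventions for the same ion.

## Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| XIC tolerance | 10 | ppm | matches high-resolution TOF mass accuracy after lock-mass correction |
| fragment screen window | ±0.025 | Da | absolute, not ppm: the conventional 184.075 phosphocholine value and the exact formula value 184.0733 differ by ~2 mDa, and low-mass fragments need an absolute window to span both |
| ratio floor | 25 | counts | 5× the simulator's additive baseline; masks dead-volume points where the reference is too weak for a meaningful ratio |
| suppression threshold `low` | 0.7 | ratio | regions are "significant" suppression; qualitative in routine practice, so tunable with a documented default |
| enhancement threshold `high` | 1.4 | ratio | symmetric on the log scale with 0.7 |
| `min_width` | 0.05 | min | 30 scans at 0.1 s — shorter excursions are noise, not chromatographic events |
| `merge_gap` | 0.03 | min | a single region briefly interrupted by noise is one event |
| smoothing window | 5 | scans | moving median on the *ratio* (not raw traces): kills single-scan outliers without biasing event depth or shifting box edges by more than 2 scans |
| lock-mass interval / averaging | 10 s / 3 scans | | standard single-point correction settings for this acquisition mode |
| buildup `drop` / `k` | 0.25 / 2 | | an injection is flagged below 75% of the rolling baseline; ≥2 consecutive flags make an event |
| screen verdict | enrichment ≥ 3, overlap ≥ 0.5 | | the qualitative "fragment fits the suppression area" criterion made explicit; both statistics are scale-invariant |
| polymer series | repeat 40–50 Da, tol 0.02 Da, ≥5 members | | brackets the ethylene-oxide repeat 44.0262 Da; 5 members at 0.02 Da makes chance progressions in a 50-peak spectrum rare (≤1/20 seeded spectra) |

## Region detection

`detect_regions()` median-smooths the ratio, thresholds it, merges
same-kind intervals separated by gaps ≤ `merge_gap` (masked points always
break intervals — a masked gap is missing evidence, not continuity), then
drops intervals narrower than `min_width`. Merging precedes the width
filter so a noise-split event is judged at its full width. The extreme
ratio reported per region is the minimum (suppression) or maximum
(enhancement) of the smoothed ratio inside it.

## Diagnostics

**Phospholipid screen.** Glycerophosphocholine lipids share the 184.07
phosphocholine head-group fragment, produced nonselectively in the
high-collision-energy channel. The screen extracts that fragment XIC and
computes (i) enrichment — mean fragment intensity inside vs outside the
region — and (ii) overlap — the fraction of the fragment's above-threshold
span (>10% of its own maximum, hence scale-invariant) inside the region.
Requiring both prevents a large but elsewhere-eluting lipid signal from
"explaining" an unrelated region.

**Polymer series.** Polyethylene glycol from collection-tube plastics
appears as an oligomer ladder spaced by the ethylene-oxide repeat,
44.0262 Da (the nominal "44 Da"). Detection chains peaks greedily: every
pair with spacing in `repeat_range` seeds a progression extended while a
peak lies within `tol` of the next expected member; the longest chain wins
(ties: higher summed intensity, then lower starting m/z), its members are
removed, and the accepted series is refit by least squares of m/z on
member index — exact on noise-free ladders, and agnostic to charge state:
the detector reports spacing without assigning z.

## Batch monitoring

The per-injection "response" of a standard is the **median of its trace
over the whole gradient** — robust to localized regions, sensitive to
global sensitivity changes. This is a deliberate proxy choice: in routine
use one monitors the infused standard, not each analyte, and the two are
equivalent only to the extent that suppression is analyte-independent.
A consequence is that only *broad* suppression (a large fraction of the
gradient, as when accumulated phospholipids bleed across the late
gradient) moves the metric; a 0.5-min dip in a 5-min run does not shift
the median, by design — such localized events are caught per injection by
`suppressed_fraction` instead. The simulator's `batch_buildup` preset
therefore uses a wide (3 min) modulated event.

`detect_buildup()` keeps a rolling baseline (median of up to 5 preceding
non-flagged injections, initialized from the first injection — "the
initial values"), flags injections below $(1-\mathrm{drop})$ of it, and
reports ≥ `k` consecutive flags followed by recovery as a buildup event;
a flagged tail with no recovery is drift. Intragroup RSD
($100\,\mathrm{sd}/\mathrm{mean}$, $n-1$ denominator) is computed per
(group, standard); the intergroup figure is reported as the min–max range
across groups. QC verdicts evaluate fail → warn → pass: fail on excessive
suppressed fraction or membership in a buildup event, warn on intragroup
RSD above threshold.

## The simulator: what it emulates, and what it does not

`simulate_run()` generates two interleaved MS1 channels (per-channel scan
interval 0.1 s, run length 5 min, scan range consistent with a 50–850 m/z
method) containing:

- flat infused-standard ions at their adduct m/z, intensity
  `conc × 4e4` counts (so the 0.025–0.25 mg/L panel spans
  1 000–10 000 counts — realistic TOF trace heights), scaled by
  $\prod_e (1 - d_e(t))$ over suppression events;
- a leucine-enkephalin reference ion in the low-energy channel,
  unaffected by matrix events (it enters via an independent sprayer);
- an optional phospholipid band: gaussian precursor ions in the low-energy
  channel plus the phosphocholine fragment in the high-energy channel over
  the same window;
- an optional PEG ladder inside its retention window;
- mean-corrected log-normal multiplicative noise (default CV 5%, typical
  of TOF trace variability) plus a 5-count additive baseline on persistent
  ions; with CV 0 and no events, every standard trace is exactly flat;
- optional constant or linearly drifting m/z error (ppm) applied to every
  peak, which `lockmass_correct()` must remove.

Scenario presets (`scenario_library()`) encode the canonical situations:
`ppt_plasma` (deep 2.75–3.25 min suppression box + phospholipid band),
`ostro_plasma` (band attenuated 20-fold after cleanup, residual
suppression below the detection threshold), `heparin` (PEG ladder near
1.5 min with co-located suppression), `citrate` (clean), `solvent` (null)
and `batch_buildup`. Event depths in presets are chosen values — the
magnitudes of real suppression areas vary with sample and instrument and
are not calibrated quantities here.

Not emulated: chromatographic peak shapes of the analytes themselves
(PCI monitors infused standards, not eluting peaks), retention-time
drift between runs, detector saturation, isotope fine structure, carryover
and electrospray physics. Passing tests therefore demonstrate the
*algorithms* recover known ground truth under realistic noise; they do not
validate instrument-specific behaviour such as RT warping robustness.

## Numerical choices and degenerate inputs

- Ratios with reference below the floor are masked (`NA`), never 0 or
  `Inf`; masked points break regions and are excluded from statistics.
- Median smoothing uses shrinking windows at trace ends and smooths each
  unmasked segment independently.
- Profile-mode spectra are centroided on load by local maxima with
  3-point log-parabolic apex interpolation (apex shift clamped to half the
  local spacing).
- Lock-mass intervals with no reference observation carry the previous
  interval's correction (logged); a run with no reference at all is
  returned unchanged with a warning rather than failing the pipeline.
- `ppm_window()` clamps the lower bound at 0 for degenerate tolerances.
- Per-run batch seeds are derived as `(seed + 7919·i) mod (2³¹−1)`,
  keeping runs independent but the batch reproducible from one master
  seed.
- Channel assignment on read prefers filter-string rules over the
  collision-energy fallback because collision energy is not reliably
  round-tripped for MS1 scans across mzML writers; the rule table is
  explicit config so vendor conversions can be accommodated.

## Problem sizes used by the shipped tests

Single-run checks (boundary recovery, lock-mass residuals, identity
profiles) use the full default conditions: 5-min runs at 0.1 s per
channel (~6 000 spectra), 20 seeds where sensitivity is claimed.
Batch-level checks simulate 8-injection batches at a 0.5 s scan interval —
the per-injection median over ~600 scans has a standard error far below
the 25% buildup threshold, so the coarser grid tests the same decision
problem at lower cost; 20 dip batches and 20 null batches bound
sensitivity (≥18/20) and false positives (≤2/20). Round-trip and
XIC-oracle checks use small randomized runs (up to 12 scans, 100 cases)
because correctness there is per-peak, not per-run-length.

## Known limitations

- No retention-time alignment: profiles from runs with shifted RT compare
  suppression at nominal, not corresponded, times.
- The per-injection response proxies analyte response with the PCI
  standard's trace; the substitution is documented, not asserted as
  equivalent (analyte-specific suppression will be underestimated).
- Polymer-series detection reports spacing without charge-state
  deconvolution; a doubly charged 88 Da repeat is indistinguishable from a
  singly charged 44 Da repeat.
- Negative-mode adducts are supported only as explicit-m/z panel entries.
- Coeluting-feature listing stops at (m/z, apex RT, intensity); database
  annotation is left to the analyst.
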