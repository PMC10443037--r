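# pciqc — postcolumn infusion quality control for LC-MS

Matrix effect — the alteration of an analyte's ionization by coeluting
compounds — is one of the main weaknesses of quantitative LC-MS. Postcolumn
infusion (PCI) attacks it directly: a solution of standards is infused at
constant flow into the LC eluent *after* the column, so each standard's
extracted-ion trace is a time-resolved readout of ionization efficiency at
every retention time of the chromatogram. Dividing a sample injection's
trace by a solvent (or blank) reference yields the **matrix effect
profile**

> R(t) = I_sample(t) / I_reference(t)

where R(t) ≈ 1 means no matrix effect, R(t) < 1 ion suppression and
R(t) > 1 ion enhancement at retention time t. Run routinely — not just
during method validation — these profiles catch failures that calibration
and internal standards miss: incomplete phospholipid removal during sample
preparation, column buildup of matrix compounds that elutes injections
later, and polymer contamination leached from collection tubes.

`pciqc` is an R toolkit for that workflow, aimed at bioanalytical and
metabolomics labs running high-resolution LC-MS (MSe-style alternating
low/high collision-energy acquisition). It provides:

- **Masses** — monoisotopic mass and adduct m/z arithmetic for
  isotope-labelled standards panels (`monoisotopic_mass()`, `adduct_mz()`),
  with an embedded versioned atomic-mass table.
- **mzML I/O** — two-channel mzML read/write via Bioconductor `mzR`
  (`read_run()`, `write_run()`) and single-point lock-mass recalibration
  against leucine enkephalin, 556.2771 m/z (`lockmass_correct()`).
- **Profiles** — XIC extraction at ppm tolerance (`extract_xic()`),
  sample/reference ratio profiles (`profile_ratio()`) and
  suppression/enhancement region detection with merging and minimum-width
  rules (`detect_regions()`); spike-based `matrix_effect_percent()`.
- **Diagnostics** — phospholipid screening via the phosphocholine fragment
  (184.075 m/z) in the high-energy channel (`phospholipid_screen()`),
  polyethylene-glycol detection via arithmetic m/z ladders with ~44 Da
  repeat (`detect_polymer_series()`), and coeluting-feature listing.
- **Batch monitoring** — per-injection PCI metrics, intragroup/intergroup
  RSD, buildup (dip-recovery) and drift detection, and pass/warn/fail QC
  verdicts (`batch_report()`, `detect_buildup()`, `qc_evaluate()`).
- **Simulator** — a seeded synthetic LC-MS run/batch generator
  (`simulate_run()`, `scenario_library()`) reproducing flat infusion
  baselines, suppression events, phospholipid bands, PEG ladders,
  injection-order modulation and multiplicative noise, so the whole
  pipeline is testable without instrument data.

## Worked example

Simulate a solvent reference and a protein-precipitated plasma injection
(whose phospholipids elute late and suppress ionization around 3 min),
then profile atenolol-d7 and screen the detected region:

```r
library(pciqc)

solv <- simulate_run(scenario_library("solvent"),    seed = 101, group = "solvent")
ppt  <- simulate_run(scenario_library("ppt_plasma"), seed = 102, group = "ppt")

tg   <- panel_targets(default_panel())
mz   <- tg$mz[tg$name == "atenolol-d7"]          # 274.2143, [M+H]+
tr   <- extract_xic(ppt,  mz, standard_id = "atenolol-d7")
rf   <- extract_xic(solv, mz, standard_id = "atenolol-d7")
prof <- profile_ratio(tr, rf)
regs <- detect_regions(prof)
regs
#>      standard        kind start_min end_min extreme_ratio mean_ratio
#> 1 atenolol-d7 suppression      2.75    3.25     0.1827822  0.2048456

phospholipid_screen(ppt, regs[1, ])
#> <phospholipid screen> [2.75, 3.25] min: enrichment 88.09, overlap 0.80 -> phospholipid-consistent
```

The region table says atenolol-d7's ionization dropped to ~18% of the
reference (extreme_ratio 0.18, i.e. ~82% suppression) between 2.75 and
3.25 min. The screen then extracts the 184.075 phosphocholine fragment
from the high-collision-energy channel: its signal is 88-fold enriched
inside the region and 80% of its above-threshold span falls there, so the
suppression is attributed to coeluting phospholipids — the signature of a
protein-precipitation-only sample preparation.

A command-line interface wraps the same functions
(`system.file("cli", "pciqc", package = "pciqc")`):

```sh
pciqc simulate --scenario ppt_plasma --seed 7 --out run.mzML
pciqc profile  --run run.mzML --reference solvent.mzML --out regions.tsv
pciqc diagnose --run run.mzML --regions regions.tsv --out diagnostics.json
pciqc batch    --metadata batch.tsv --out report.json
```

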