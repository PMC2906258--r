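# xtalfit

Crystallographic model-to-data fit, statistics and likelihood-weighted maps
in R.

Given a macromolecular model (PDB) and reduced experimental structure-factor
amplitudes or intensities (SHELX HKL, CNS text, or plain columns), xtalfit
answers the question every depositor, referee and database curator asks:
*does this model reproduce these data, and if not, why not?* It is aimed at
structural biologists and methods developers who want the full chain —
structure factors, bulk solvent, scaling, twinning, TLS, map coefficients,
audits — as inspectable R functions rather than a monolithic binary.

## What it computes

The model-to-data fit is summarized by

    R = sum_h ||F_obs(h)| - |F_model(h)|| / sum_h |F_obs(h)|

over working and free reflections, with

    F_model(h) = k * exp(-B_ov s^2/4) * exp(-2 pi^2 s' U_cryst s)
                 * | F_calc(h) + k_sol exp(-B_sol s^2/4) F_mask(h) |

— the flat bulk-solvent model (mask radii r_solv = 1.11 A,
r_shrink = 0.9 A) with anisotropic scaling. Around that core:

* structure factors by direct summation and by FFT density sampling
  (agreement below 0.01% in R), for X-ray and neutron scattering;
* merohedral twin-law enumeration from the lattice metric and
  twin-fraction refinement, `|F_twin|^2 = (1-a) F^2(h) + a F^2(Th)`;
* TLS header parsing in the two common dialects, defect taxonomy
  (selection / origin / matrix problems), U reconstruction
  `U = T + A L A' + A S + S' A'`, and automatic resolution of the
  total-vs-residual ADP convention by "lowest R wins";
* Wilson B, amplitude/intensity auto-detection, Wilson outlier rejection,
  completeness shells, free-flag convention detection;
* sigma-A estimation (Rice/Woolfson likelihood), 2mFo-DFc / mFo-DFc /
  3Fo-2Fc / anomalous map coefficients, FFT map synthesis, per-atom and
  per-residue real-space correlation;
* model audits for the pathologies found in deposited files
  (non-positive-definite ADPs, zero H ADPs, negative occupancies, unknown
  scattering types, altloc and multi-model occupancy sums, H/D exchange);
* a synthetic-crystal generator with known ground truth for every one of
  those pathologies, used throughout the tests.

## A worked example

```r
library(xtalfit)
ens   <- makeToyCrystal(60, "P21", seed = 11, hFraction = 0.3)  # 60 heavy + 18 H
truth <- groundTruth(kSol = 0.35, bSol = 46, noise = 0.03, seed = 5)
set   <- simulateFobs(ens, truth, dMin = 1.8)
writeFixture(ens, set, "fix", "toy")                 # PDB + SHELX + manifest
report <- runModelVsData("fix/toy.pdb", "fix/toy.hkl")
print(report)
```

prints

```
MODEL VS DATA
=============
Model:
  models            : 1
  atoms per model   : 78 (H/D: 18)
  mean B            : 20.89
  anisotropic atoms : 0
  TLS groups        : 0 (defects: 0)
  audit: non-PD ADP 0 | zero ADP 0 | occ<0 0 | unknown type 0
Data:
  kind              : amplitude (moment 1.346, confidence high)
  unique reflections: 694 (redundant input rows: 0)
  resolution        : 15.372 - 1.800
  free set          : 31
  completeness      : 1.00 1.00 1.00 1.00 1.00 1.00 1.00 1.00 1.00 1.00
  Wilson B          : 17.7
  outliers removed  : 0
Fit:
  ADP convention    : total
  [all data] r_work      : 0.0251
  [all data] r_free      : 0.0272
  [all data] n_work/free : 663 / 31
  [all data] k_sol/b_sol : 0.358 / 48.0
Header comparison:
  reported r_work   : n.a.
  recomputed r_work : 0.0251
  difference        : n.a.
```

Reading it: the amplitude/intensity call comes from the acentric moment
(1.346, near the amplitude expectation 4/pi); the fitted bulk-solvent
parameters (0.358 / 48.0) recover the generating truth (0.35 / 46); and
R_work = 0.0251 sits at the floor set by the 3% amplitude noise
(0.03 * sqrt(2/pi) = 0.024). `renderJson(report)` emits the same numbers
machine-readably.

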