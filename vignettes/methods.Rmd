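---
title: "Population-of-models proarrhythmia assessment on a reduced ventricular myocyte engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-of-models proarrhythmia assessment on a reduced ventricular myocyte engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardiotrial)
```

## What this package computes

`cardiotrial` implements the cell-scale analysis stack used for in silico
assessment of drug-induced Torsades de Pointes risk and related disease
protocols:

1. a **population of models** — an ensemble of myocyte model instances whose
   ionic conductance and calcium-handling multipliers are sampled to
   represent inter-subject variability, filtered by biomarker calibration
   ranges;
2. **channel-level pharmacology** — Hill pore block
   $b(C) = 1/(1 + (C/\mathrm{IC}_{50})^h)$ and dose-dependent enhancement
   schedules, mapped multiplicatively onto the multiplier set;
3. **abnormality detectors** for early afterdepolarizations (EADs),
   repolarization failure and calcium-transient alternans, and the two
   threshold-search protocols built on them (largest $I_{\mathrm{Kr}}$
   multiplier supporting EADs at 0.25 Hz; longest cycle length with CaT
   alternans);
4. a **concentration-weighted torsadogenic risk score**
   $S = \sum_j f_j w_j / \sum_j w_j$ with $w_j = 1/c_j$, classified into
   safe/unsafe against CredibleMeds-style labels;
5. **disease variants** (LQTS2; six type-2-diabetes remodeling
   parameterizations) with knockout and population-level analyses; and
6. an optional **Nav1.8 current** with right-shifted gating.

Everything runs on a reduced human ventricular myocyte engine so that the
full pipeline is exercisable in minutes on one CPU without any external
model download.

## The reduced myocyte engine

The engine is a 21-state ventricular cardiomyocyte model with the membrane
currents $I_{\mathrm{Na}}$, $I_{\mathrm{NaL}}$, $I_{\mathrm{to}}$,
$I_{\mathrm{CaL}}$, $I_{\mathrm{Kr}}$, $I_{\mathrm{Ks}}$, $I_{\mathrm{K1}}$,
$I_{\mathrm{NaCa}}$, $I_{\mathrm{NaK}}$ (plus small background and pump
terms), sarcoplasmic-reticulum fluxes $J_{\mathrm{up}}$, $J_{\mathrm{rel}}$,
$J_{\mathrm{leak}}$, a calcium-driven active-tension read-out, and an
optional Nav1.8 current. Gating uses Hodgkin–Huxley formulations with
kinetics adapted from established human ventricular models; the L-type
driving force is GHK-style. Every current and flux carries a dimensionless
multiplier (`ionicParams()`), the single hook through which populations,
drugs and disease variants act. CaMKII is a static composite hook: per unit
activity above 1 it scales SERCA uptake by 0.85 and $I_{\mathrm{CaL}}$ by
1.2 (configurable); dynamic CaMKII signalling is out of scope.

The engine is **not** a transcription of any published model: it is a
purpose-built reduced model tuned to a behaviour contract (monotone
APD--$g_{Kr}$ and APD--$g_{NaL}$ relations, ICaL-window EADs at slow pacing
under $I_{\mathrm{Kr}}$ reduction, repolarization failure when both delayed
rectifiers are removed, SERCA-dependent relaxation, alternans below a
critical cycle length, tension increasing in $g_{CaL}$), which is what the
downstream analyses actually rely on. The contract is enforced by the test
suite.

Numerics: fixed-step integration with Rush–Larsen gate updates, a 0.02 ms
step inside a 10 ms window after each stimulus (upstroke) and 0.05 ms
elsewhere; voltage-dependent gate steady states, Rush–Larsen factors and
current prefactors are precomputed on a 0.05 mV lookup table per run.
Output is resampled on a uniform 0.1 ms grid. The integrator is fully
deterministic: identical inputs give bit-identical traces, and a run
restarted from its final state continues exactly. We chose this integrator
class (standard for cardiac AP models) over generic adaptive stiff solvers
because a population trial needs thousands of runs and reproducibility to
the bit. The stimulus is rectangular, $-52\ \mu A/\mu F$ for 1 ms by
default.

### Selected engine behaviours and their mechanisms

* **EADs** arise from L-type window current: with $I_{\mathrm{Kr}}$
  reduced, late repolarization stalls near $-10$ to $-30$ mV where the
  f-gate recovers and the d-gate window re-activates $I_{\mathrm{CaL}}$.
  Takeoff potentials are $-10$ to $-18$ mV.
* **Nav1.8-driven EADs**: the Nav1.8 gating is slow and right-shifted
  (activation midpoint $-24$ mV, slope 8; inactivation $-30$ mV, slope 4);
  its window sits below the ICaL window, so Nav1.8-initiated EADs take off
  near $-22$ to $-25$ mV, clearly more negative than ICaL-driven events.
  Published gating parameters for cardiac Nav1.8 vary widely across
  preparations; the defaults here are the package's own behavioural
  choices, configurable in `engineConfig()`.
* **Calcium-transient alternans** emerges near the 1:1 capture limit
  through ICaL restitution (slow f-gate recovery at diastolic potentials).
  Reducing SERCA ($j_{up}$) does not lower the threshold (it is equal on
  the default grid), and APD-prolonging remodeling (LQTS2-like, T2D D1)
  raises it strongly. True SR-release-refractoriness alternans is not
  reproducible in a single-compartment bulk-calcium engine, because SERCA
  re-sequesters most released calcium within the same cycle (high
  recirculation), which erases the beat-to-beat load memory that the
  instability requires; we verified this against several alternative
  release formulations before settling on the restitution route. A
  consequence is that the per-model association between tension-relaxation
  tau (SERCA-driven) and the alternans threshold (APD-driven) is weak in
  this engine, unlike in full-scale models.
* **NCX**: at slow pacing the exchanger is predominantly in reverse mode
  during the late plateau (cytosolic calcium has already declined), so
  *increasing* NCX is mildly anti-arrhythmic here. The T2D variant library
  therefore realises its vulnerability ordering mainly through the
  $I_{\mathrm{Kr}}$ component.

## Biomarkers and detectors

APD$_x$ is measured from the maximum upstroke velocity to
$x\%$ repolarization, where the repolarization level is
$V_{peak} - x/100\,(V_{peak} - V_{dias})$ with $V_{dias}$ the pre-stimulus
diastolic potential. A beat whose pre-stimulus potential exceeds $-60$ mV
has no valid diastole; its APD90 is undefined and the beat counts as
repolarization failure (this also catches fully failed steady states where
consecutive beats never repolarize). Relaxation tau is a least-squares
single-exponential-plus-offset fit of the tension decay between 90% and
10% of the beat peak, computed by profiling: for fixed $\tau$ the model is
linear in amplitude and offset, and the residual sum of squares is
minimized over $\log \tau$; boundary solutions are reported as undefined.

The EAD detector scans, per beat, the window from the action-potential
peak to the earlier of the 90% repolarization crossing and the next
stimulus, after a 1 ms moving-average smoothing; every local minimum above
$-60$ mV followed by a rise of at least 2 mV is an event, with the takeoff
potential read at the minimum. There is no standard choice for these detector
constants; the values here are robust on 0.1 ms grids and are exposed in
`detectorConfig()`. Diastolic events (DADs) are excluded by the $-60$ mV
floor and are not scored. Alternans magnitude is
$\mathrm{mean}|A_n - A_{n-1}| / \mathrm{mean}(A)$ over the assessed beats
(default last 10, at least 6) and requires strict sign alternation plus a
0.05 magnitude threshold.

The EAD threshold search verifies monotonicity of EAD presence on a coarse
multiplier grid and then bisects over the resolution grid (default 0.01);
if the coarse check fails it falls back to an exhaustive descending scan,
so the result always equals the grid oracle. The alternans threshold uses
pure grid semantics (default 600 to 250 ms in 10 ms steps, no
interpolation) because alternans windows can be non-contiguous in cycle
length.

## Populations and calibration

Sampling is Latin-hypercube on a log scale over the twelve
conductance/flux multipliers, default range $[0.5, 2]$ (the conventional
population-of-models range for inter-subject variability), fully
reproducible from the seed. Calibration runs every model to quasi-steady
state at 1 Hz and accepts models whose APD90, CaT amplitude/diastolic
level, normalized peak tension and relaxation tau fall inside documented
human-plausible default ranges (`calibrationRanges()`, every value
overridable); models with integration failures or undefined APD90 are
rejected with a recorded reason. Calibration additionally screens each
model drug-free at the trial pacing rate and rejects models that already
trigger the abnormality detectors — an in silico trial population must be
arrhythmia-free at baseline — and caches the screened state, which makes
the subsequent per-drug runs cheap. With the default ranges the acceptance
fraction on the reference engine is informative (strictly between 0
and 1), mirroring the structure of published calibrated populations
without claiming their numbers.

## Trials, scoring and description checking

A drug trial applies each compound at multiples of its effective free
therapeutic plasma concentration (default 1, 10, 30, 100), re-runs every
accepted model from its cached state at the trial pacing rate (default CL
2000 ms, a package default chosen because slow pacing favours EADs), and counts models with any repolarization abnormality. Models
whose integration fails under drug are excluded from the denominator
rather than counted abnormal, to avoid inflating risk from numerics. The
risk score weights the per-concentration abnormal fractions by
$1/c_j$ (the alternative $1/\log_{10}(10c_j)$ is available); the
classification threshold is 0 — any abnormality at any tested
concentration marks a compound unsafe — both configurable.

The phenotype-discrepancy check runs a drug on the baseline model and
compares signed relative biomarker changes against expectations such as
"APD90 decreases" or "peak tension increases markedly". Because the
engine's quartic force–calcium relation amplifies relative tension
changes, the bundled cilostazol expectation uses a +100% bar for "marked"
inotropy. The bundled fixtures mark every constant as paper-printed or
placeholder; placeholder values (e.g. the lidocaine and mexiletine IC50s)
are plausible inventions used for direction-level analyses only.

## Disease variants

LQTS2 is $g_{Kr} \times 0.30$ with $g_{NaL} \times 1.82$. The six T2D
variants share $g_{Kr} \times 0.55$, $g_{NaCa} \times 1.6$,
$j_{up} \times 0.5$; D1/D2 increase $g_{CaL}$ by 1.2, D3–D6 reduce it to
0.8 (a printed value), with and without CaMKII hyperactivity (which
carries a coupled $g_{NaL} \times 1.3$) and direct late-Na remodeling.
The exact magnitudes are package defaults, parameterized so the library
reproduces the intended qualitative ordering — every variant more EAD-vulnerable than control,
isolated $I_{CaL}$ reduction less vulnerable — and every value is
overridable through `diseaseVariant()`.

## Synthetic data

`makeSyntheticTrace()` builds voltage/calcium/tension series from smooth
analytic segments. EAD implants are exact by construction: the template
pauses at the requested takeoff potential, a raised-cosine bump of exactly
the requested amplitude is inserted, and the repolarization resumes
time-shifted, so the annotated ground truth (takeoff, amplitude, count) is
not an approximation. Repolarization-failure beats suppress the final
fall; alternans patterns scale even-beat amplitudes by a known ratio. A
seeded low-frequency jitter (0.15 mV) exercises the smoothing without ever
creating spurious detector events.

`makeSyntheticCompendium()` draws risky (strong hERG block near the
therapeutic range, optionally with an L-type enhancement schedule) and
benign profiles, then **certifies** every label by running the full trial
on the reference population: the label is the brute-force outcome, not the
design intent. This makes perfect specificity on the synthetic compendium
a well-posed end-to-end check of the pipeline, while saying nothing about
performance on real pharmacology — the generator does not emulate real
IC50 distributions, multi-channel correlation structure, or measurement
error, and the engine is not a full-scale ventricular model.

## Problem sizes and limitations

The test suite and the acceptance script use reduced problem sizes chosen
as the package's own defaults for a desk-scale analysis: populations of
50–100 sampled models, 60–150 pre-beats to quasi-steady state, 8–15 beats
per threshold-search candidate, 20-compound compendia, and a 0.01–0.02
multiplier resolution. These keep every stage to minutes on one CPU; the
protocols accept larger sizes unchanged.

Known limitations, stated plainly: the engine is a reduced model and its
quantitative biomarkers are not those of any full-scale published model;
NCX's arrhythmogenic role and the SERCA–alternans association do not
transfer from full models (see above); tension is a read-out with no
mechano-electric feedback; the sex-difference and β-adrenergic layers of
full-scale frameworks, and all tissue- and organ-level phenomena, are out
of scope.
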