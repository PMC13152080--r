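# cardiotrial

Population-of-models in silico cardiac drug trials on a reduced human
ventricular myocyte engine.

## The problem

Drug-induced Torsades de Pointes (TdP) is the most common form of
drug-induced proarrhythmia and a major cause of compound attrition. A
well-established computational screen exposes a *population of models* —
an ensemble of ventricular myocyte model instances with sampled ionic
conductance multipliers, filtered by experimental biomarker ranges — to a
compound's channel-block profile across concentrations, counts models
developing repolarization abnormalities (early afterdepolarizations, EADs,
or repolarization failure), and aggregates them into a torsadogenic risk
score. The same machinery supports mechanistic questions: detecting
incomplete pharmacological descriptions from phenotype disagreement,
dissecting multichannel drugs by single-factor knockout, quantifying
arrhythmia vulnerability in disease remodeling (long QT syndrome type 2,
type 2 diabetes), and probing noncanonical currents such as Nav1.8.

`cardiotrial` implements this full cell-scale stack for electrophysiology
researchers and safety-pharmacology modellers, on a purpose-built reduced
myocyte engine (21 states, compiled) so every analysis runs in minutes on
one CPU with no external model download.

## The core quantities

* Channel block: `b(C) = 1 / (1 + (C/IC50)^h)` per channel, composed
  multiplicatively with dose-dependent enhancement schedules and disease
  variants on a per-current multiplier set.
* Risk score over concentration multiples `c_j` (of the effective free
  therapeutic plasma concentration) with abnormal fractions `f_j`:
  `S = sum(f_j / c_j) / sum(1 / c_j)`; a compound is classified unsafe
  when `S > 0`, and predictions are scored against CredibleMeds-style
  labels as accuracy / sensitivity / specificity.
* EAD threshold: the largest `I_Kr` multiplier at which EADs still occur
  at 0.25 Hz pacing (higher = more vulnerable). Alternans threshold: the
  longest pacing cycle length with calcium-transient alternans.

## A worked example

```r
library(cardiotrial)

## calibrate a small population (50 sampled models, 80 pre-beats at 1 Hz)
pop <- samplePopulation(samplingSpec(seed = 42), 50)
cal <- calibratePopulation(pop, protocol = pacingProtocol(1000, 80L, 3L))
cal
#> PopulationTable: 50 models, 9 accepted (18%)

## the two cilostazol descriptions: hERG/L-type block only, and with the
## PDE3-mediated L-type enhancement (+10% @10x, +22% @30x, +40% @100x)
fx <- makeReferenceFixtures()
tB <- runDrugTrial(cal, fx$drugs$cilostazol_block,
                   protocol = pacingProtocol(2000, 12L, 4L))
tE <- runDrugTrial(cal, fx$drugs$cilostazol_enh,
                   protocol = pacingProtocol(2000, 12L, 4L))
tE
#> TrialResult 'cilostazol_enh':
#>  multiple nAbnormal nUndetermined nModels  fraction
#>         1         0             0       9 0.0000000
#>        10         0             0       9 0.0000000
#>        30         2             0       9 0.2222222
#>       100         4             0       9 0.4444444
trialRiskScore(tB)@score   # 0.0019 : block-only, marginal risk
trialRiskScore(tE)@score   # 0.0104 : the enhancement reveals the risk
```

The description including the L-type enhancement is markedly more
inotropic and about five times more torsadogenic than the block-only
description (4/9 vs 2/9 abnormal models at the 100x dose) — the phenotype
disagreement that flags the block-only description as incomplete. `knockoutAnalysis()` dissects multichannel drugs the same
way; on the LQTS2 variant (`g_Kr x 0.30`, `g_NaL x 1.82`) a
mexiletine-like blocker lowers the EAD threshold from 0.92 to 0.60
(protective), and removing its `I_CaL` block component removes most of
that protection.

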