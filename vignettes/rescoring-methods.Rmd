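---
title: "Rescoring features, collision-energy calibration and best-model search: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring features, collision-energy calibration and best-model search: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinboost)
```

## The problem

A database search assigns each MS/MS spectrum a best-matching peptide
(a PSM) with a generic score such as an expectation value. Semi-supervised
rescoring (Percolator and kin) re-ranks PSMs using additional features.
The most informative modern features compare the observed data against
*predictions* from machine-learned peptide-property models: how well the
observed fragment intensities match a predicted spectrum, and how far the
observed retention time (RT) falls from a calibrated predicted RT.
`pinboost` implements those two features, the calibration steps they
need, and the machinery for choosing among several candidate prediction
models. All algorithmic steps operate on plain domain objects
(peptidoforms, spectra, pin tables) so each can be tested in isolation.

## The MS2 feature: unweighted spectral entropy similarity

For a PSM we take the model's predicted fragment list (b/y ions, single
charge) and align it with the experimental peak list: every predicted
fragment is matched to the nearest experimental peak within a mass
tolerance (default **20 ppm**, configurable, with a Dalton mode), each
experimental peak usable at most once, conflicts resolved greedily in
order of ascending relative m/z distance. Unmatched predicted fragments
receive experimental intensity 0.

With the matched intensity vectors $p$ (predicted) and $q$
(experimental), each normalized to sum 1, $m = (p+q)/2$ and
$H(x) = -\sum_i x_i \ln x_i$:

$$S(p,q) = 1 - \frac{2H(m) - H(p) - H(q)}{\ln 4} \in [0, 1].$$

$S$ is 1 iff the normalized vectors coincide, 0 for disjoint support,
symmetric, and invariant to rescaling either vector. Two conventions are
deliberate and isolated behind `match_peaks()` /`entropy_similarity()`:

- The similarity is computed **over the predicted fragment set only**;
  experimental peaks matching no predicted fragment are ignored. Since
  predictions contain only b/y ions, a full-spectrum union would penalize
  every PSM for peaks the models cannot predict (precursor ions,
  immonium ions, neutral losses). The union variant would be a drop-in
  replacement of `match_peaks()` if ever wanted.
- Experimental intensities are used **as stored**; any square-root or
  other transform is upstream search configuration, not applied here.

Degenerate inputs: an all-zero experimental vector scores 0 by
convention (nothing matched); an all-zero predicted vector is an invalid
prediction and errors. Results are clamped to $[0,1]$ against
floating-point rounding a few ulps outside the interval.

## The RT feature: delta-RT loess

Models output RT on their own native scale (minutes, indexed units,
arbitrary). A locally weighted regression of experimental RT (minutes)
on predicted RT is fitted on a confident PSM subset and the feature is
the absolute residual in minutes — small is good, matching its use as a
rescoring feature. Calibration choices (all configurable):

- loess **degree 1**, tricube weights, **one robustifying iteration**
  (via `stats::loess`, `family = "symmetric"`), **span 0.3**. Degree 1
  with a moderate span tracks the mildly nonlinear gradient/scale
  relationships seen in practice without chasing outliers; the
  robustifying pass prevents mis-assigned PSMs in the calibration subset
  from bending the curve.
- duplicate predicted values are averaged before fitting; evaluation
  outside the fitted range clamps to the boundary fit (extrapolating a
  local fit is meaningless);
- fewer than **20 points** is refused with an instruction to fall back
  to a linear fit; the pipeline does exactly that
  (`fit_rt_calibration_linear`).

Because loess weights depend only on relative distances, the feature is
invariant to affine changes of the model's native RT scale once the
calibration is refit — models need not be normalized to a common scale.

## Handling peptides a model cannot predict

Model constraints are explicit configuration (`model_spec`): length
window, allowed charges, supported UNIMOD accessions. Checks run in a
fixed order (length → charge → modifications) so verdicts are
reproducible. Peptides outside the length/charge window are not
predictable at all; their features are imputed with the subset median
(flag-controlled) so the pin table stays rectangular. Peptides with
*unsupported modifications* are stripped to the supported part,
predicted, and every fragment covering a removed site is shifted by
$\Delta m / z_{frag}$ (b$_k$ covers the N-terminus and residues
$1..k$; y$_k$ covers residues $len{-}k{+}1..len$ and the C-terminus).
This reproduces the standard "query the unmodified peptide and adjust
fragment m/z" behaviour and is exact for position-localized mass
shifts — intensities, however, remain those of the stripped peptide,
which is the method's inherent approximation.

## NCE calibration

Fragment intensities depend on the instrument's normalized collision
energy, and a model's notion of NCE rarely matches a given instrument's.
Calibration: take the top **1000** PSMs by e-value pooled across pin
files, predict them at **every integer NCE in 20–40%** (defaults), and
pick the NCE with the highest **median** entropy similarity, ties to the
lowest value. PSMs failing the model's support check are excluded and
counted, not backfilled — backfilling would make the calibration subset
depend on the model under test. Decoys are *not* excluded by default
(they are rare in the top subset at realistic rankings); a flag restricts
to targets. The per-NCE score distributions (median, quartiles, n) are
written as a TSV report for QC plotting.

## Heuristic best-model search

To choose among candidate models without rescoring the whole dataset
with each, a subset of `floor(1000/P)` lowest-e-value PSMs per pin file
(P files) is scored under every candidate; models are compared on the
identical PSM intersection (a PSM unsupported by any one candidate is
dropped for all). Selection statistics:

- **median** — highest median similarity (MS2) / lowest median deviation
  (RT);
- **top consensus (n)** — each model's n best-feature values (largest
  similarities; largest deviations for RT) sorted; at each rank position
  the model with the better value (greater similarity / smaller
  deviation) gets one vote; most votes wins. Vote fractions are bounded
  by 0 and 1. Presets n = 10, 50, 100;
- **bottom consensus (n)** — the same vote over each model's n smallest
  values;
- **RMSE** (RT only) — lowest root mean squared deviation.

Positions are aligned **by rank**, not by shared PSM identity: the
methods compare the shape of each model's sorted score list, which is
what the ranked-list framing of the selection problem implies. A flagged
PSM-aligned variant would be easy to add but is not the implemented
interpretation. Tie handling is deterministic everywhere: statistic ties
break lexicographically by model name; vote ties fall back to the median
statistic among the tied leaders; a rank-position tie awards its single
vote to the lexicographically first model, keeping vote totals equal
to n.

The production rule (`select_models()`) is **median for MS2** and
**top consensus with 10 PSMs for RT**. The rationale is visible in the
synthetic world: an RT model with a tight core but a heavy outlier tail
wins the median comparison while being the worse rescoring feature —
rescoring is hurt most by confident PSMs with wildly wrong predictions.
The top-consensus vote over the ten largest deviations catches exactly
that tail.

Two evaluation utilities complete the machinery. The **heuristic summary
score** of a selection method over several datasets is the mean of the
squared ratios between the picked model's empirical peptide yield and
the best model's yield; squaring penalizes bad picks more heavily, and
the score is 1 iff every pick is empirically best. **Position
classification** labels each rank position of the sorted score lists
gray (the empirically best model also has the best score there), red
(the winning model's mean yield + 1 sd is below the best model's mean −
1 sd), or white (overlapping intervals). Empirical yields are *inputs*
(they come from repeated Percolator runs, outside this package's scope);
the synthetic harness supplies deterministic stand-in yields derived
from each model's effective error so the machinery is exercisable end to
end.

## The synthetic ground-truth world

All recovery tests run against a simulated world
(`synthetic_world()`) in which the truth is known:

- **Fragmentation**: every residue pair has a base cleavage propensity
  (uniform in 0.05–1, fixed by the world seed; y ions get a 1.3×
  factor), modulated by a Gaussian collision-energy response
  $\exp(-(\mathrm{NCE} - \mathrm{NCE}^*)^2 / 2\sigma^2)$ with
  $\mathrm{NCE}^* = 27$ and width $\sigma = 2.5$ NCE units, plus an
  additive baseline of 0.1, max-normalized per peptide. The width and
  baseline are set so that single-percent NCE steps change the
  normalized fragment pattern by roughly 10% — integer-grid calibration
  is only a meaningful procedure in a world where the energy response is
  informative at that granularity, and real HCD spectra do change
  visibly per NCE percent. The response is strictly unimodal in NCE by
  construction.
- **Retention**: additive per-residue coefficients (0.5–4 min) plus an
  intercept.
- **Experimental data** (`simulate_dataset()`): tryptic-like random
  peptides (7–15 residues, K/R C-terminus, charge 2–3); spectra are the
  ground-truth profile at the true NCE under multiplicative log-normal
  intensity noise (sdlog 0.3 by default — a realistic ±35% spread) plus
  5 uniform noise peaks; e-values are anticorrelated with each
  spectrum's realized noise so "top PSMs by e-value" are genuinely
  cleaner; decoys carry shuffled sequences (terminal residue kept) while
  their spectra remain those of the original peptide.
- **Models**: a noise-free reference (`ms2_true`), four MS2 models with
  intensity noise sdlog 0.02/0.05/0.10/0.20, and two RT models realizing
  the tail dichotomy: `rt_shift` (constant +3 min offset — absorbed by
  the loess refit, standing in for a model trained on a different
  gradient — plus light 0.5 min noise) and `rt_heavy` (tight 0.15 min
  core, 5% outliers with 8 min spread). Model noise is keyed
  deterministically to (world seed, model, peptide, charge), so
  predictions are reproducible and independent of request batching.

What the world does *not* emulate — and hence what passing tests do not
show about real data: fragment-charge states above 1+, neutral losses
and non-b/y series, isotope envelopes, chimeric spectra, peptide-level
intensity-NCE interactions (every bond shares one Gaussian response),
retention drift within a run, and search-engine score distributions. The
harness validates the *algorithms* (recovery of injected truth,
invariances, tie rules), not model quality on real spectra.

## Defaults at a glance

| Parameter | Default | Where |
|---|---|---|
| Match tolerance | 20 ppm (Da mode available) | `match_peaks`, pipeline |
| Loess span / degree / robustifying iterations | 0.3 / 1 / 1 | `fit_rt_calibration` |
| Minimum loess points | 20 (else linear fallback) | `fit_rt_calibration` |
| NCE grid | integers 20–40% | `nce_grid` |
| Calibration subset | top 1000 PSMs by e-value, pooled | `select_top_psms` |
| Search subset | floor(1000/P) per file | `select_search_psms` |
| RT consensus tail | n = 10 | `select_models` |
| E-value column | `log10_evalue` (configurable) | `read_pin` |
| RT unit | minutes everywhere; MGF seconds converted at the boundary | `read_mgf` |

## Numerical and interface choices

- Pin tables preserve raw cell text, so an unmodified read→write round
  trip is byte identical; added columns are formatted to at most 6
  significant digits without scientific notation. A `DefaultDirection`
  row is carried through verbatim. New feature columns
  (`unweighted_spectral_entropy`, `delta_RT_loess`) are inserted
  immediately before `Peptide` because downstream consumers key on the
  trailing `Peptide`/`Proteins` columns.
- The predicted-library MGF writes `TITLE=<ProForma>/<charge>` and a
  third peak-line token `b3^1`/`y5^2`; this TITLE grammar is this
  package's own documented convention.
- The ProForma subset covers named UNIMOD modifications (bundled table:
  oxidation, carbamidomethyl, acetyl, phospho, pyro-Glu from Gln/Glu,
  TMT11), numeric mass deltas, terminal modifications and a charge
  suffix; ranges, ambiguity groups and crosslinks are rejected with a
  character-indexed error. Pyro-Glu is stored as a delta on residue 1
  with an N-terminal rendering flag, so its mass is attributed to the
  first residue's fragments while round-tripping the conventional
  `[U:Gln->pyro-Glu]-` notation.
- Modification positions use 0 = N-terminus, 1..len = residues,
  len+1 = C-terminus; at most one modification per position.
- The remote prediction client is a contract: named-tensor payloads,
  request batching, per-batch retry with exponential backoff, all around
  an injectable transport function. No live network is ever touched by
  the tests.

## Problem sizes in the test suite

The suite validates formulas on 10,000 random vector pairs, round trips
on 1,000 generated peptidoforms, fragment oracles on 500 random
fragments, consensus voting on 200 random 5×50 tables, NCE recovery on
20 simulated datasets of 1,000 PSMs each (noiseless and noisy),
MS2-model recovery on 100 datasets of 1,000 PSMs, and end-to-end
determinism on a 500-PSM pipeline run — sizes chosen to exercise the
asymptotic behaviour of each statistic while keeping a full run at
desk scale.

## Known limitations

- Only b/y single-charge fragments are predicted and matched; models
  emitting other series would need `ion_series` extended.
- The stripped-modification adjustment corrects m/z, not intensity.
- mzML/mzXML reading, running Percolator, and DIA-specific processing
  are out of scope; spectra enter via MGF, and empirical outcomes enter
  as tables.
- The entropy feature's behaviour under heavy experimental noise has a
  known mild bias toward flatter (lower-energy) predictions — visible in
  the synthetic world as a tendency of calibration picks toward the low
  side of the optimum — because multiplicative noise inflates the
  observed spectrum's entropy. The median-over-PSMs statistic and an
  informative energy response keep the bias within one grid unit under
  the default conditions.
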