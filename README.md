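# pinboost

Rescoring features for peptide-spectrum matches (PSMs) from
peptide-property predictions.

Database search engines report PSMs with generic scores; re-ranking them
with features that measure agreement between the *observed* data and
*predicted* peptide properties (fragment intensities, retention time)
substantially increases the number of confidently identified peptides,
especially for immunopeptidomics and other large-search-space
experiments. `pinboost` implements the computational core of that
workflow for Percolator-style rescoring, for proteomics researchers and
tool developers who want the individual steps available as composable,
testable R functions:

- **ProForma 2.0 peptidoform interface** — parsing/rendering of a
  practical subset (named UNIMOD mods, numeric mass deltas, terminal
  mods, charge), model-compatibility checks, and monoisotopic b/y
  fragment m/z computation.
- **File plumbing** — Percolator `.pin` PSM tables (byte-preserving
  round trips, feature columns inserted before the `Peptide` column) and
  MGF peak lists, including annotated predicted-library MGF export.
- **The two rescoring features**
  - *Unweighted spectral entropy similarity* between matched predicted
    and experimental intensity vectors `p`, `q` (each normalized to sum
    1, `m = (p+q)/2`, `H` the Shannon entropy):

    `S(p, q) = 1 − (2·H(m) − H(p) − H(q)) / ln 4  ∈ [0, 1]`

  - *Delta-RT-loess*: `|RT_obs − f(RT_pred)|` in minutes, where `f` is a
    loess calibration (degree 1, tricube, one robustifying iteration)
    fitted on a confident PSM subset.
- **Collision-energy (NCE) calibration** — the top 1000 PSMs by e-value
  are predicted at every integer NCE in 20–40%; the NCE with the highest
  median entropy similarity wins.
- **Heuristic best-model search** — score a 1000/P-per-file PSM subset
  under every candidate model and select by *median* (MS2) and
  *top consensus with 10 PSMs* (RT), with bottom-consensus and RMSE
  variants, the squared-ratio heuristic summary score, and gray/red/white
  ranked-position classification for QC plots.
- **Prediction backends** — a Koina-style remote client contract
  (named-tensor payloads, batching, retry with backoff; transport
  injectable) and a deterministic synthetic ground-truth backend that
  makes every algorithm testable offline with known answers.

## Worked example

Simulate a dataset with known ground truth, calibrate the collision
energy, and run the full rescoring pipeline with automatic model
selection:

```r
library(pinboost)

world <- synthetic_world(seed = 7)      # true NCE is 27%
sim <- simulate_dataset(world, 300, decoy_fraction = 0.1, seed = 7,
                        dir = "demo")

backend <- synthetic_backend(world, "ms2_a")
top <- select_top_psms(list(sim$pin), 300)
calibrate_nce(top, sim$spectra, backend)
#> <nce_calibration> chosen NCE 27% (median similarity 0.9838) over 300 PSM(s), 0 excluded

cfg <- run_config(
  pins = "demo/psms.pin", spectra = "demo/spectra.mgf",
  backends = list(ms2_a = synthetic_backend(world, "ms2_a"),
                  ms2_c = synthetic_backend(world, "ms2_c"),
                  rt_shift = synthetic_backend(world, "rt_shift"),
                  rt_heavy = synthetic_backend(world, "rt_heavy")),
  ms2_model = "auto", rt_model = "auto",
  calibration_n = 300, search_budget = 300, out_dir = "demo/out")
res <- augment_pins(cfg)
#> [pinboost] read: 300 PSM(s) from 1 pin file(s), 300 spectrum(s)
#> [pinboost] calibrate-nce: model ms2_a -> 27% (300 PSMs, 0 excluded)
#> [pinboost] calibrate-nce: model ms2_c -> 27% (300 PSMs, 0 excluded)
#> [pinboost] select-models: MS2 ms2_a (median), RT rt_shift (top_consensus_10)
#> [pinboost] calibrate-rt: model rt_shift fitted on 300 PSM(s)
#> [pinboost] write-pin: demo/out/psms.pin (300 row(s))
#> [pinboost] write-library: 300 entries -> demo/out/predicted_library.mgf

read_pin("demo/out/psms.pin")
#> <pin_table> 300 PSM(s), 10 column(s)
```

The calibration recovered the world's true collision energy (27%). Auto
selection picked the lowest-noise MS2 model (`ms2_a`) by median
similarity, and — the instructive case — picked `rt_shift` over
`rt_heavy` for RT: `rt_heavy` has the *lower median* delta RT but a
heavy outlier tail, and the top-consensus vote over the ten largest
deviations catches exactly that:

```r
res$selection$reports$RT$top_consensus
#> <selection_report> top_consensus_10 -> rt_shift
#>   rt_shift     1  (10 vote(s))
#>   rt_heavy     0  (0 vote(s))
```

The edited pin gained two feature columns,
`unweighted_spectral_entropy` and `delta_RT_loess`, inserted immediately
before `Peptide`, and a predicted spectral library was written as
annotated MGF.

A command-line wrapper with the same functionality ships as
`inst/cli/pinboost` (subcommands `simulate`, `calibrate-nce`,
`select-models`, `rescore`, `library`).

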