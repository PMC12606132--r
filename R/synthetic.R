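# Synthetic ground-truth prediction world.
#
# The world fixes a "true" fragmentation chemistry (per-bond cleavage
# propensities with a Gaussian collision-energy response) and a "true"
# retention chemistry (additive per-residue coefficients). Experimental
# data and model predictions are both derived from the same ground truth,
# so every upstream algorithm (NCE calibration, best-model search, feature
# scoring) can be tested against known answers. Identical seeds give
# identical worlds, datasets and predictions.

#' Create a synthetic prediction world
#'
#' @param seed Integer seed fixing the world's chemistry and all derived
#'   noise.
#' @param true_nce The collision energy (percent) at which experimental
#'   spectra are generated; the calibration algorithms should recover it.
#' @param nce_width Width (percent units) of the Gaussian collision-energy
#'   response of every bond.
#' @param baseline Additive baseline intensity; keeps the fragment pattern
#'   NCE-dependent after normalization.
#' @param y_factor Multiplier on y-ion propensities relative to b ions.
#' @param exp_noise_sd Log-normal (sdlog) multiplicative intensity noise on
#'   experimental spectra.
#' @param exp_rt_sd Gaussian noise (minutes) on experimental retention
#'   times.
#' @param noise_peaks Number of uniform noise peaks added per experimental
#'   spectrum.
#' @param models List of synthetic model definitions (see
#'   [synthetic_models_default()]).
#' @return A `synthetic_world`.
#' @export
synthetic_world <- function(seed = 1L, true_nce = 27, nce_width = 2.5,
                            baseline = 0.1, y_factor = 1.3,
                            exp_noise_sd = 0.3, exp_rt_sd = 0.2,
                            noise_peaks = 5L,
                            models = synthetic_models_default()) {
  stopifnot(nce_width > 0, baseline >= 0)
  chem <- with_seed(as.integer(seed) * 7L + 13L, {
    aff <- matrix(stats::runif(400, 0.05, 1), 20, 20,
                  dimnames = list(CANONICAL_RESIDUES, CANONICAL_RESIDUES))
    rtc <- stats::runif(20, 0.5, 4)
    names(rtc) <- CANONICAL_RESIDUES
    list(aff = aff, rtc = rtc, rt_intercept = stats::runif(1, 2, 8))
  })
  names(models) <- vapply(models, `[[`, character(1), "name")
  structure(
    list(seed = as.integer(seed), true_nce = true_nce, nce_width = nce_width,
         baseline = baseline, y_factor = y_factor,
         exp_noise_sd = exp_noise_sd, exp_rt_sd = exp_rt_sd,
         noise_peaks = as.integer(noise_peaks),
         bond_affinities = chem$aff, rt_coefficients = chem$rtc,
         rt_intercept = chem$rt_intercept, models = models),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> seed %d, true NCE %g%%, %d model(s)\n",
              x$seed, x$true_nce, length(x$models)))
  invisible(x)
}

#' Default synthetic model panel
#'
#' A noise-free reference MS2 model (`ms2_true`), four MS2 models with
#' strictly ordered intensity noise, and two RT
#' models realizing the tail-behaviour dichotomy: `rt_shift` predicts with
#' a constant offset (absorbed by the loess calibration) plus light
#' Gaussian noise, while `rt_heavy` has a tighter core but draws 5% of its
#' predictions from a wide-tailed outlier distribution. The heavy-tail
#' model wins on median delta RT yet is the empirically worse rescorer.
#'
#' @param supported_mods UNIMOD accessions every synthetic model supports.
#' @return A list of model definition lists.
#' @export
synthetic_models_default <- function(
    supported_mods = modification_table()$accession) {
  ms2 <- function(name, sd) {
    list(name = name, task = "MS2", intensity_sd = sd, rt_sd = NA,
         rt_bias = "none", shift = 0, out_frac = 0, out_sd = 0,
         supported_mods = supported_mods)
  }
  rt <- function(name, sd, bias, shift = 0, out_frac = 0, out_sd = 0) {
    list(name = name, task = "RT", intensity_sd = NA, rt_sd = sd,
         rt_bias = bias, shift = shift, out_frac = out_frac, out_sd = out_sd,
         supported_mods = supported_mods)
  }
  list(
    ms2("ms2_true", 0), ms2("ms2_a", 0.02), ms2("ms2_b", 0.05),
    ms2("ms2_c", 0.10), ms2("ms2_d", 0.20),
    rt("rt_shift", 0.5, "median_shift", shift = 3),
    rt("rt_heavy", 0.15, "heavy_tail", out_frac = 0.05, out_sd = 8)
  )
}

#' Model spec of a synthetic model
#'
#' @param world A [synthetic_world()].
#' @param name Model name present in `world$models`.
#' @param min_length,max_length,allowed_charges Constraint overrides.
#' @return A [model_spec()].
#' @export
synthetic_model_spec <- function(world, name, min_length = 6L,
                                 max_length = 30L, allowed_charges = 1:4) {
  def <- world$models[[name]]
  if (is.null(def)) stop("unknown synthetic model: ", name, call. = FALSE)
  model_spec(name, task = def$task, supported_mods = def$supported_mods,
             min_length = min_length, max_length = max_length,
             allowed_charges = allowed_charges,
             takes_nce = def$task == "MS2")
}

# Ground-truth b/y fragment profile of a peptidoform at a given NCE:
# intensity_i = affinity(bond_i) * exp(-(nce - true)^2 / (2 width^2)) +
# baseline, max-normalized per peptide. The profile is strictly unimodal
# in NCE (most structured at the true energy, flattening away from it).
ground_truth_profile <- function(world, p, nce) {
  res <- p$residues
  n <- length(res)
  ords <- seq_len(n - 1L)
  pair_b <- cbind(match(res[ords], CANONICAL_RESIDUES),
                  match(res[ords + 1L], CANONICAL_RESIDUES))
  aff_b <- world$bond_affinities[pair_b]
  # y_k cleaves the bond between residues n-k and n-k+1
  pair_y <- cbind(match(res[n - ords], CANONICAL_RESIDUES),
                  match(res[n - ords + 1L], CANONICAL_RESIDUES))
  aff_y <- world$bond_affinities[pair_y] * world$y_factor
  g <- exp(-(nce - world$true_nce)^2 / (2 * world$nce_width^2))
  raw <- c(aff_b, aff_y) * g + world$baseline
  raw / max(raw)
}

#' Ground-truth relative intensity of one fragment
#'
#' @param world A [synthetic_world()].
#' @param peptide A [peptidoform()].
#' @param series `"b"` or `"y"`.
#' @param ordinal Fragment ordinal.
#' @param nce Collision energy (percent).
#' @return Relative intensity in `(0, 1]` within the peptide's
#'   max-normalized b/y fragment set.
#' @export
ground_truth_intensity <- function(world, peptide, series = c("b", "y"),
                                   ordinal, nce) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(peptide, "peptidoform"))
  series <- match.arg(series)
  n <- length(peptide$residues)
  ordinal <- as.integer(ordinal)
  stopifnot(ordinal >= 1L, ordinal <= n - 1L)
  prof <- ground_truth_profile(world, peptide, nce)
  idx <- if (series == "b") ordinal else (n - 1L) + ordinal
  prof[idx]
}

# True retention time (minutes) of a peptidoform in this world.
ground_truth_rt <- function(world, p) {
  world$rt_intercept + sum(world$rt_coefficients[p$residues])
}

#' Create a synthetic prediction backend
#'
#' Serves one of the world's models. Predictions are the world's ground
#' truth perturbed by the model's own noise; the noise is keyed to
#' (world seed, model, peptide, charge), so repeated or re-batched
#' requests give identical answers.
#'
#' @param world A [synthetic_world()].
#' @param name Model name in `world$models`.
#' @param ... Constraint overrides passed to [synthetic_model_spec()].
#' @return A `synthetic_backend`.
#' @export
synthetic_backend <- function(world, name, ...) {
  spec <- synthetic_model_spec(world, name, ...)
  structure(
    list(world = world, def = world$models[[name]], model = spec,
         cache = new.env(parent = emptyenv())),
    class = c("synthetic_backend", "prediction_backend"))
}

#' @export
print.synthetic_backend <- function(x, ...) {
  cat(sprintf("<synthetic_backend> %s [%s] on world seed %d\n",
              x$model$name, x$model$task, x$world$seed))
  invisible(x)
}

# Per-item static state (support verdict, fragment table, bond
# propensities, the item's deterministic noise draws) is computed once and
# memoized in the backend's cache environment; only the NCE response
# factor changes between calls. Memoization never changes results -- the
# noise is keyed to (world seed, model, peptide, charge) either way.
synthetic_item_state <- function(backend, raw, p, charge) {
  key <- paste0(raw, "/", charge)
  st <- backend$cache[[key]]
  if (!is.null(st)) return(st)
  world <- backend$world
  def <- backend$def
  spec <- backend$model
  pq <- p
  pq$charge <- charge
  status <- check_model_support(pq, spec)
  if (status$verdict != "supported") {
    st <- list(error = list(reason = status$verdict,
                            offending_mods = status$offending_mods))
  } else if (spec$task == "MS2") {
    canon <- render_proforma(p)
    ft <- fragment_table(p, 1L)
    res <- p$residues
    nres <- length(res)
    ords <- seq_len(nres - 1L)
    aff_b <- world$bond_affinities[cbind(match(res[ords], CANONICAL_RESIDUES),
                                         match(res[ords + 1L],
                                               CANONICAL_RESIDUES))]
    aff_y <- world$bond_affinities[cbind(match(res[nres - ords],
                                               CANONICAL_RESIDUES),
                                         match(res[nres - ords + 1L],
                                               CANONICAL_RESIDUES))] *
      world$y_factor
    aff <- c(aff_b, aff_y)
    mult <- if (def$intensity_sd > 0) {
      exp(with_seed(item_seed(world$seed, def$name, canon, charge),
                    stats::rnorm(length(aff), 0, def$intensity_sd)))
    } else {
      rep(1, length(aff))
    }
    st <- list(p = p, ft = ft, aff = aff, mult = mult)
  } else {
    canon <- render_proforma(p)
    rt <- ground_truth_rt(world, p) + def$shift
    draws <- with_seed(item_seed(world$seed, def$name, canon),
                       list(u = stats::runif(1), z = stats::rnorm(2)))
    rt <- rt + draws$z[1] * def$rt_sd
    if (def$rt_bias == "heavy_tail" && draws$u < def$out_frac) {
      rt <- rt + draws$z[2] * def$out_sd
    }
    st <- list(rt = rt)
  }
  backend$cache[[key]] <- st
  st
}

#' @export
predict_peptides.synthetic_backend <- function(backend, req, ...) {
  world <- backend$world
  spec <- backend$model
  n <- length(req$peptides)
  if (spec$task == "MS2" && spec$takes_nce && is.null(req$nce)) {
    stop("this model takes NCE; supply it in the request", call. = FALSE)
  }
  entries <- vector("list", n)
  errors <- vector("list", n)
  for (i in seq_len(n)) {
    st <- synthetic_item_state(backend, req$peptides[i], req$parsed[[i]],
                               req$charges[i])
    if (!is.null(st$error)) {
      errors[[i]] <- st$error
      next
    }
    if (spec$task == "MS2") {
      g <- exp(-(req$nce[i] - world$true_nce)^2 / (2 * world$nce_width^2))
      raw <- st$aff * g + world$baseline
      prof <- (raw / max(raw)) * st$mult
      ft <- st$ft
      ft$intensity <- prof / max(prof)
      entries[[i]] <- structure(
        list(peptidoform = st$p, precursor_charge = req$charges[i],
             fragments = ft, predicted_rt = NA_real_, adjustment = NULL),
        class = "predicted_entry")
    } else {
      entries[[i]] <- st$rt
    }
  }
  prediction_response(entries, errors, spec$name, "synthetic")
}
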