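# Synthetic dataset generator: tryptic-like peptides, experimental
# spectra, a pin table and a full truth record, all reproducible from
# (world, seed).

#' Simulate a rescoring dataset with known ground truth
#'
#' Generates random tryptic-like peptides, experimental MS/MS spectra
#' (ground-truth fragment intensities at the world's true NCE under
#' multiplicative log-normal noise plus uniform noise peaks), experimental
#' retention times from the world's additive RT chemistry, and a pin table
#' whose expectation values are anticorrelated with the injected noise, so
#' the "top PSMs by e-value" really are the cleanest spectra. Decoys carry
#' shuffled sequences (terminal residue preserved) while their spectra
#' still come from the original target peptide, so their predictions match
#' poorly, as in a real decoy search.
#'
#' @param world A [synthetic_world()].
#' @param n_psms Number of PSMs to simulate.
#' @param decoy_fraction Fraction of PSMs labelled decoy, in `[0, 1)`.
#' @param seed Integer seed for the dataset draw.
#' @param intensity_noise_sd Experimental intensity noise (sdlog);
#'   defaults to the world's setting.
#' @param noise_peaks Noise peaks per spectrum; defaults to the world's
#'   setting.
#' @param dir Optional output directory; when given, writes
#'   `spectra.mgf`, `psms.pin`, `truth_psms.tsv` and
#'   `truth_outcomes.tsv`.
#' @return A list with `spectra` (list of spectra), `pin` (a
#'   `pin_table`), and `truth` (peptides, noise magnitudes, true NCE,
#'   true RTs, synthetic empirical outcomes, seed).
#' @export
simulate_dataset <- function(world, n_psms, decoy_fraction = 0, seed = 1L,
                             intensity_noise_sd = world$exp_noise_sd,
                             noise_peaks = world$noise_peaks, dir = NULL) {
  stopifnot(inherits(world, "synthetic_world"), n_psms >= 1,
            decoy_fraction >= 0, decoy_fraction < 1)
  sim <- with_seed(as.integer(seed), {
    lens <- sample(7:15, n_psms, replace = TRUE)
    charges <- sample(2:3, n_psms, replace = TRUE)
    is_decoy <- stats::runif(n_psms) < decoy_fraction
    interior <- setdiff(CANONICAL_RESIDUES, c("K", "R"))
    peptides <- character(n_psms)
    decoy_peptides <- character(n_psms)
    for (i in seq_len(n_psms)) {
      res <- c(sample(interior, lens[i] - 1L, replace = TRUE),
               sample(c("K", "R"), 1L))
      peptides[i] <- paste(res, collapse = "")
      if (is_decoy[i]) {
        core <- res[-length(res)]
        decoy_peptides[i] <- paste(
          c(core[sample.int(length(core))], res[length(res)]),
          collapse = "")
      }
    }
    spectra <- vector("list", n_psms)
    noise_mag <- numeric(n_psms)
    true_rt <- numeric(n_psms)
    for (i in seq_len(n_psms)) {
      p <- peptidoform(peptides[i])
      ft <- fragment_table(p, 1L)
      prof <- ground_truth_profile(world, p, world$true_nce)
      eps <- if (intensity_noise_sd > 0)
        stats::rnorm(nrow(ft), 0, intensity_noise_sd) else numeric(nrow(ft))
      inten <- prof * exp(eps)
      mz <- ft$mz
      if (noise_peaks > 0) {
        nmz <- stats::runif(noise_peaks, 150, max(mz) + 50)
        nint <- stats::runif(noise_peaks, 0, 0.1) * max(inten)
        mz <- c(mz, nmz); inten <- c(inten, nint)
      }
      ord <- order(mz)
      true_rt[i] <- ground_truth_rt(world, p)
      rt <- true_rt[i] +
        if (world$exp_rt_sd > 0) stats::rnorm(1, 0, world$exp_rt_sd) else 0
      noise_mag[i] <- mean(abs(eps))
      spectra[[i]] <- structure(
        list(scan_number = i,
             precursor_mz = precursor_mz(p, charges[i]),
             precursor_charge = charges[i], retention_time = rt,
             mz = mz[ord], intensity = inten[ord],
             annotation = rep(NA_character_, length(mz)),
             nce = world$true_nce, instrument = NA_character_,
             title = sprintf("sim.%d.%d.%d", i, i, charges[i])),
        class = "spectrum")
    }
    log10_e <- ifelse(is_decoy,
                      stats::rnorm(n_psms, 0.5, 0.5) + 10 * noise_mag,
                      -6 + 10 * noise_mag + stats::rnorm(n_psms, 0, 0.3))
    hyperscore <- 25 - 4 * log10_e + stats::rnorm(n_psms, 0, 1)
    abs_ppm <- stats::runif(n_psms, 0, 5)
    list(lens = lens, charges = charges, is_decoy = is_decoy,
         peptides = peptides, decoy_peptides = decoy_peptides,
         spectra = spectra, noise_mag = noise_mag, true_rt = true_rt,
         log10_e = log10_e, hyperscore = hyperscore, abs_ppm = abs_ppm)
  })

  reported <- ifelse(sim$is_decoy, sim$decoy_peptides, sim$peptides)
  proteins <- ifelse(sim$is_decoy,
                     sprintf("rev_sp|SIMP%04d|SIM", seq_len(n_psms)),
                     sprintf("sp|SIMP%04d|SIM", seq_len(n_psms)))
  lines <- c(
    paste(c("SpecId", "Label", "ScanNr", "hyperscore", "log10_evalue",
            "abs_ppm", "Peptide", "Proteins"), collapse = "\t"),
    sprintf("sim.%d.%d.%d\t%d\t%d\t%.3f\t%.4f\t%.3f\t-.%s.-\t%s",
            seq_len(n_psms), seq_len(n_psms), sim$charges,
            ifelse(sim$is_decoy, -1L, 1L), seq_len(n_psms),
            sim$hyperscore, sim$log10_e, sim$abs_ppm, reported, proteins)
  )
  con <- textConnection(lines)
  pin <- read_pin(con)
  close(con)
  pin <- attach_spectra(pin, sim$spectra)

  truth <- list(
    seed = as.integer(seed), true_nce = world$true_nce,
    peptides = sim$peptides, reported_peptides = reported,
    charges = sim$charges, is_decoy = sim$is_decoy,
    true_rt = sim$true_rt, noise_magnitude = sim$noise_mag,
    outcomes = synthetic_outcomes(world))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_spectra_mgf(sim$spectra, file.path(dir, "spectra.mgf"))
    write_pin(pin, file.path(dir, "psms.pin"))
    truth_df <- data.frame(
      scan = seq_len(n_psms), peptide = sim$peptides,
      reported_peptide = reported, charge = sim$charges,
      label = ifelse(sim$is_decoy, -1L, 1L),
      true_rt = sprintf("%.4f", sim$true_rt),
      noise_magnitude = sprintf("%.5f", sim$noise_mag))
    utils::write.table(truth_df, file.path(dir, "truth_psms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$outcomes, file.path(dir, "truth_outcomes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(spectra = sim$spectra, pin = pin, truth = truth)
}

#' Synthetic empirical rescoring outcomes
#'
#' Real empirical outcomes (peptides identified over repeated Percolator
#' runs) are inputs to the selection machinery, not something this package
#' computes. The synthetic harness stands in with a deterministic yield
#' derived from each model's effective post-calibration error: MS2 models
#' are penalized by their intensity noise, RT models by their root mean
#' square prediction error including the outlier component (a constant
#' offset is absorbed by calibration and does not count). Lower effective
#' error means more peptides.
#'
#' @param world A [synthetic_world()].
#' @param dataset Dataset label.
#' @param n_base Baseline peptide yield.
#' @return A data.frame with columns `dataset`, `model`, `mean_peptides`,
#'   `sd`, `n_runs` (the `EmpiricalOutcome` layout).
#' @export
synthetic_outcomes <- function(world, dataset = "sim", n_base = 1000) {
  rows <- lapply(world$models, function(def) {
    eff <- if (def$task == "MS2") {
      def$intensity_sd
    } else {
      sqrt((1 - def$out_frac) * def$rt_sd^2 + def$out_frac * def$out_sd^2)
    }
    data.frame(dataset = dataset, model = def$name,
               mean_peptides = round(n_base * (0.55 + 0.45 / (1 + eff))),
               sd = round(n_base * 0.008), n_runs = 10L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
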