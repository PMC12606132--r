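# End-to-end workflow: read pins and spectra, calibrate NCE, optionally
# run the heuristic best-model search, compute the two rescoring features
# for every PSM, and write edited pins, the predicted library MGF and the
# TSV reports.

MS2_FEATURE_NAME <- "unweighted_spectral_entropy"
RT_FEATURE_NAME <- "delta_RT_loess"

#' Assemble a pipeline run configuration
#'
#' Defaults follow the production workflow: NCE grid 20-40%, calibration
#' and search subsets of 1000 PSMs, top consensus with 10 PSMs for RT
#' model selection.
#'
#' @param pins Character vector of pin paths.
#' @param spectra Character vector of MGF paths.
#' @param backends Named list of prediction backends (candidate models).
#' @param ms2_model,rt_model Model name, `"auto"` (heuristic search;
#'   requires >= 2 candidates for the task), or `NA` to skip the feature.
#' @param nce_lo,nce_hi Integer NCE grid bounds.
#' @param tol Fragment match tolerance.
#' @param unit `"ppm"` or `"da"`.
#' @param span Loess span for RT calibration.
#' @param consensus_n Tail size for RT model selection.
#' @param calibration_n PSM subset size for NCE calibration.
#' @param search_budget Total PSM budget for the best-model search.
#' @param impute_unsupported Impute the subset median feature for PSMs the
#'   chosen model cannot predict at all (too long/short, bad charge)?
#' @param evalue_column Pin column holding log10 e-values.
#' @param seed Integer seed (reserved for stochastic backends).
#' @param out_dir Output directory.
#' @return A `run_config`.
#' @export
run_config <- function(pins, spectra, backends, ms2_model = "auto",
                       rt_model = "auto", nce_lo = 20L, nce_hi = 40L,
                       tol = 20, unit = "ppm", span = 0.3,
                       consensus_n = 10L, calibration_n = 1000L,
                       search_budget = 1000L, impute_unsupported = TRUE,
                       evalue_column = "log10_evalue", seed = 1L,
                       out_dir = ".") {
  stopifnot(length(pins) >= 1, length(spectra) >= 1,
            !is.null(names(backends)))
  tasks <- vapply(backends, function(b) b$model$task, character(1))
  if (identical(ms2_model, "auto") && sum(tasks == "MS2") < 2) {
    stop("ms2_model = 'auto' requires at least 2 MS2 candidates",
         call. = FALSE)
  }
  if (identical(rt_model, "auto") && sum(tasks == "RT") < 2) {
    stop("rt_model = 'auto' requires at least 2 RT candidates",
         call. = FALSE)
  }
  structure(
    list(pins = pins, spectra = spectra, backends = backends,
         ms2_model = ms2_model, rt_model = rt_model,
         nce_lo = as.integer(nce_lo), nce_hi = as.integer(nce_hi),
         tol = tol, unit = unit, span = span,
         consensus_n = as.integer(consensus_n),
         calibration_n = as.integer(calibration_n),
         search_budget = as.integer(search_budget),
         impute_unsupported = isTRUE(impute_unsupported),
         evalue_column = evalue_column, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[pinboost] %s: %s", stage, sprintf(...)))
}

# Predict MS2 entries for arbitrary peptidoforms under one model,
# stripping unsupported modifications and adjusting fragment m/z where
# needed. Returns list(entries, status) where status is per-PSM one of
# supported / adjusted / dropped.
predict_with_adjustment <- function(peptidoforms, charges, backend, nce) {
  spec <- backend$model
  n <- length(peptidoforms)
  status <- character(n)
  query <- vector("list", n)
  removed <- vector("list", n)
  for (i in seq_len(n)) {
    p <- peptidoforms[[i]]
    pq <- p; pq$charge <- charges[i]
    v <- check_model_support(pq, spec)$verdict
    if (v == "supported") {
      status[i] <- "supported"; query[[i]] <- p
    } else if (v == "unsupported_mods") {
      s <- strip_unsupported_mods(p, spec)
      status[i] <- "adjusted"
      query[[i]] <- s$peptidoform
      removed[[i]] <- s$removed
    } else {
      status[i] <- "dropped"
    }
  }
  keep <- which(status != "dropped")
  entries <- vector("list", n)
  if (length(keep) > 0) {
    req <- prediction_request(
      vapply(query[keep], render_proforma, character(1)),
      charges[keep],
      nce = if (is.null(nce) || is.na(nce)) NULL
            else rep(nce, length(keep)))
    resp <- predict_peptides(backend, req)
    for (j in seq_along(keep)) {
      i <- keep[j]
      if (!is.null(resp$errors[[j]])) {
        status[i] <- "dropped"
        next
      }
      e <- resp$entries[[j]]
      if (inherits(e, "predicted_entry") && status[i] == "adjusted") {
        e <- adjust_fragment_mzs(e, removed[[i]])
        # restore the original peptidoform on the entry for the library
        e$peptidoform <- peptidoforms[[i]]
      }
      entries[[i]] <- e
    }
  }
  list(entries = entries, status = status)
}

#' Run the rescoring pipeline and write edited pin files
#'
#' Stages, in order: read inputs; filter peptides outside model limits;
#' strip unsupported modifications (marking fragments for m/z
#' adjustment); calibrate NCE on the top-1000 e-value PSMs for every MS2
#' model that takes it; heuristic best-model search on the 1000/P subset
#' when a model is `"auto"`; predict all candidates at the chosen NCE;
#' compute the requested features; write edited pins (feature columns
#' inserted before Peptide), the predicted library MGF and the TSV
#' reports. Any stage error aborts the run and removes partial outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the chosen models, calibrations,
#'   selection reports, per-stage counts and output paths.
#' @export
augment_pins <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  written <- character()
  result <- tryCatch(
    augment_pins_impl(cfg, function(p) written <<- c(written, p)),
    error = function(e) {
      for (p in written) if (file.exists(p)) unlink(p)
      stop("pipeline aborted: ", conditionMessage(e), call. = FALSE)
    })
  invisible(result)
}

augment_pins_impl <- function(cfg, register) {
  counts <- list()
  pins <- lapply(cfg$pins, read_pin, evalue_column = cfg$evalue_column)
  spectra <- do.call(c, lapply(cfg$spectra, read_mgf))
  pins <- lapply(pins, attach_spectra, spectra = spectra)
  n_psms <- sum(vapply(pins, function(p) length(p$records), integer(1)))
  pipeline_log("read", "%d PSM(s) from %d pin file(s), %d spectrum(s)",
               n_psms, length(pins), length(spectra))
  counts$input_psms <- n_psms

  backends <- cfg$backends
  tasks <- vapply(backends, function(b) b$model$task, character(1))
  ms2_candidates <- backends[tasks == "MS2"]
  rt_candidates <- backends[tasks == "RT"]
  grid <- nce_grid(cfg$nce_lo, cfg$nce_hi)

  # --- NCE calibration on the pooled top subset
  top <- select_top_psms(pins, cfg$calibration_n)
  calibrations <- list()
  chosen_nce <- stats::setNames(rep(NA_real_, length(ms2_candidates)),
                                names(ms2_candidates))
  for (m in names(ms2_candidates)) {
    b <- ms2_candidates[[m]]
    if (!b$model$takes_nce) next
    cal <- calibrate_nce(top, spectra, b, grid = grid, tol = cfg$tol,
                         unit = cfg$unit)
    calibrations[[m]] <- cal
    chosen_nce[m] <- cal$chosen_nce
    path <- file.path(cfg$out_dir, sprintf("nce_calibration_%s.tsv", m))
    write_nce_report(cal, path)
    register(path)
    pipeline_log("calibrate-nce", "model %s -> %d%% (%d PSMs, %d excluded)",
                 m, cal$chosen_nce, cal$n_psms, cal$n_excluded)
  }

  # --- heuristic best-model search
  selection <- NULL
  ms2_model <- cfg$ms2_model
  rt_model <- cfg$rt_model
  if (identical(ms2_model, "auto") || identical(rt_model, "auto")) {
    sel_psms <- select_search_psms(pins, cfg$search_budget)
    ms2_table <- build_score_table(sel_psms, spectra, ms2_candidates,
                                   task = "MS2", nce = chosen_nce,
                                   tol = cfg$tol, unit = cfg$unit)
    rt_table <- build_score_table(sel_psms, spectra, rt_candidates,
                                  task = "RT", span = cfg$span)
    selection <- select_models(ms2_table, rt_table,
                               consensus_n = cfg$consensus_n)
    if (identical(ms2_model, "auto")) ms2_model <- selection$ms2
    if (identical(rt_model, "auto")) rt_model <- selection$rt
    path <- file.path(cfg$out_dir, "model_selection.tsv")
    write_selection_report(selection$reports, path)
    register(path)
    pipeline_log("select-models", "MS2 %s (%s), RT %s (%s)",
                 selection$ms2, selection$ms2_criterion,
                 selection$rt, selection$rt_criterion)
  }

  do_ms2 <- !is.na(ms2_model) && !is.null(ms2_model)
  do_rt <- !is.na(rt_model) && !is.null(rt_model)
  ms2_backend <- if (do_ms2) backends[[ms2_model]] else NULL
  rt_backend <- if (do_rt) backends[[rt_model]] else NULL
  if (do_ms2 && is.null(ms2_backend)) stop("unknown MS2 model: ", ms2_model,
                                           call. = FALSE)
  if (do_rt && is.null(rt_backend)) stop("unknown RT model: ", rt_model,
                                         call. = FALSE)

  # --- RT calibration on the top subset under the chosen model
  rt_cal <- NULL
  if (do_rt) {
    top_p <- lapply(top, psm_peptidoform)
    top_z <- vapply(top, function(r) {
      z <- r$precursor_charge; if (is.na(z)) 2L else as.integer(z)
    }, integer(1))
    pr <- predict_with_adjustment(top_p, top_z, rt_backend, NA)
    ok <- which(pr$status != "dropped")
    pred_rt <- vapply(pr$entries[ok], as.numeric, numeric(1))
    exp_rt <- vapply(top[ok], function(r) r$retention_time, numeric(1))
    rt_cal <- if (length(ok) >= 20) {
      fit_rt_calibration(pred_rt, exp_rt, span = cfg$span)
    } else {
      fit_rt_calibration_linear(pred_rt, exp_rt)
    }
    pipeline_log("calibrate-rt", "model %s fitted on %d PSM(s)",
                 rt_model, length(ok))
  }

  # --- per-pin feature computation and output
  library_entries <- list()
  seen_keys <- character()
  out_pins <- character()
  total_adjusted <- 0L
  total_dropped <- 0L
  for (f in seq_along(pins)) {
    pin <- pins[[f]]
    recs <- pin$records
    peps <- lapply(recs, psm_peptidoform)
    zs <- vapply(recs, function(r) {
      z <- r$precursor_charge; if (is.na(z)) 2L else as.integer(z)
    }, integer(1))
    if (do_ms2) {
      nce_use <- if (ms2_model %in% names(chosen_nce))
        chosen_nce[[ms2_model]] else NA_real_
      pr <- predict_with_adjustment(peps, zs, ms2_backend, nce_use)
      scores <- rep(NA_real_, length(recs))
      sindex <- spectrum_index(spectra)
      for (i in seq_along(recs)) {
        e <- pr$entries[[i]]
        if (is.null(e)) next
        s <- lookup_spectrum(sindex, recs[[i]]$scan_number)
        if (is.null(s)) next
        scores[i] <- entropy_similarity(
          match_peaks(s, e, tol = cfg$tol, unit = cfg$unit))
        key <- paste0(render_proforma(e$peptidoform), "/", zs[i])
        if (!(key %in% seen_keys)) {
          seen_keys <- c(seen_keys, key)
          library_entries[[length(library_entries) + 1L]] <- e
        }
      }
      total_adjusted <- total_adjusted + sum(pr$status == "adjusted")
      total_dropped <- total_dropped + sum(is.na(scores))
      if (any(is.na(scores))) {
        if (!cfg$impute_unsupported) {
          stop(sum(is.na(scores)), " PSM(s) without MS2 feature",
               call. = FALSE)
        }
        scores[is.na(scores)] <- stats::median(scores, na.rm = TRUE)
      }
      pin <- add_pin_feature(pin, MS2_FEATURE_NAME, scores)
    }
    if (do_rt) {
      pr <- predict_with_adjustment(peps, zs, rt_backend, NA)
      deltas <- rep(NA_real_, length(recs))
      for (i in seq_along(recs)) {
        e <- pr$entries[[i]]
        if (is.null(e)) next
        deltas[i] <- delta_rt_loess(recs[[i]]$retention_time,
                                    as.numeric(e), rt_cal)
      }
      if (any(is.na(deltas))) {
        if (!cfg$impute_unsupported) {
          stop(sum(is.na(deltas)), " PSM(s) without RT feature",
               call. = FALSE)
        }
        deltas[is.na(deltas)] <- stats::median(deltas, na.rm = TRUE)
      }
      pin <- add_pin_feature(pin, RT_FEATURE_NAME, deltas)
    }
    out_path <- file.path(cfg$out_dir, basename(
      if (is.na(pin$source_path)) sprintf("psms_%d.pin", f)
      else pin$source_path))
    write_pin(pin, out_path)
    register(out_path)
    out_pins <- c(out_pins, out_path)
    pipeline_log("write-pin", "%s (%d row(s))", out_path, length(recs))
  }
  counts$adjusted <- total_adjusted
  counts$imputed <- total_dropped

  library_path <- NULL
  if (do_ms2 && length(library_entries) > 0) {
    library_path <- file.path(cfg$out_dir, "predicted_library.mgf")
    write_library_mgf(library_entries, library_path)
    register(library_path)
    pipeline_log("write-library", "%d entries -> %s",
                 length(library_entries), library_path)
  }

  stage_df <- data.frame(stage = names(counts),
                         count = unlist(counts, use.names = FALSE))
  stage_path <- file.path(cfg$out_dir, "stage_counts.tsv")
  utils::write.table(stage_df, stage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  register(stage_path)

  list(ms2_model = if (do_ms2) ms2_model else NA_character_,
       rt_model = if (do_rt) rt_model else NA_character_,
       chosen_nce = chosen_nce, calibrations = calibrations,
       selection = selection, rt_calibration = rt_cal,
       counts = counts, pins = out_pins, library = library_path)
}
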