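# Collision-energy calibration: find the NCE at which a model's predicted
# spectra best match the experimental ones.

#' Integer NCE grid
#'
#' @param lo,hi Inclusive integer bounds (percent); default 20-40.
#' @return An `nce_grid` with `lo`, `hi` and `values`.
#' @export
nce_grid <- function(lo = 20L, hi = 40L) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(lo <= hi)
  structure(list(lo = lo, hi = hi, values = lo:hi), class = "nce_grid")
}

#' Top PSMs by expectation value across pin files
#'
#' Pools all PSMs, sorts ascending by e-value and returns the first
#' `total`. Ties are broken by file order, then row order, so the subset
#' is deterministic.
#'
#' @param pins List of `pin_table` objects.
#' @param total Number of PSMs to keep (default 1000).
#' @return A list of PSM records.
#' @export
select_top_psms <- function(pins, total = 1000L) {
  stopifnot(length(pins) > 0, total >= 1)
  records <- list(); file_idx <- integer(); row_idx <- integer()
  for (f in seq_along(pins)) {
    rs <- pins[[f]]$records
    records <- c(records, rs)
    file_idx <- c(file_idx, rep.int(f, length(rs)))
    row_idx <- c(row_idx, seq_along(rs))
  }
  if (length(records) == 0) stop("no PSMs in any pin file", call. = FALSE)
  ev <- vapply(records, function(r) r$evalue, numeric(1))
  ord <- order(ev, file_idx, row_idx)
  records[ord[seq_len(min(total, length(records)))]]
}

# Index spectra by scan number.
spectrum_index <- function(spectra) {
  scans <- vapply(spectra, function(s) s$scan_number, integer(1))
  idx <- seq_along(spectra)
  names(idx) <- as.character(scans)
  list(spectra = spectra, idx = idx)
}

lookup_spectrum <- function(sindex, scan) {
  j <- sindex$idx[[as.character(scan)]]
  if (is.null(j)) NULL else sindex$spectra[[j]]
}

# Entropy-similarity scores of a PSM set against one MS2 backend at one
# NCE. Matching is computed once (fragment m/z do not depend on NCE) and
# can be reused across NCE values through the returned closure.
ms2_scoring_context <- function(psms, spectra, backend, tol = 20,
                                unit = "ppm") {
  sindex <- spectrum_index(spectra)
  peptides <- vapply(psms, function(r) pin_peptide_core(r$peptide),
                     character(1))
  charges <- vapply(psms, function(r) {
    z <- r$precursor_charge
    if (is.na(z)) 2L else as.integer(z)
  }, integer(1))
  specs <- lapply(psms, function(r) {
    s <- lookup_spectrum(sindex, r$scan_number)
    if (is.null(s)) stop("no spectrum for scan ", r$scan_number,
                         call. = FALSE)
    s
  })
  base_req <- prediction_request(peptides, charges)
  exp_flat <- NULL; group <- NULL; n_frag <- NULL
  score_at <- function(nce) {
    req <- base_req
    req$nce <- if (is.null(nce) || is.na(nce)) NULL
               else rep(nce, length(peptides))
    resp <- predict_peptides(backend, req)
    bad <- !vapply(resp$errors, is.null, logical(1))
    if (any(bad)) {
      stop("backend rejected ", sum(bad), " peptide(s): first reason ",
           resp$errors[[which(bad)[1]]]$reason, call. = FALSE)
    }
    pred_int <- unlist(lapply(resp$entries,
                              function(e) e$fragments$intensity))
    if (is.null(exp_flat)) {
      n_frag <<- vapply(resp$entries, function(e) nrow(e$fragments),
                        integer(1))
      group <<- rep.int(seq_along(psms), n_frag)
      exp_flat <<- unlist(lapply(seq_along(psms), function(i) {
        match_intensities(resp$entries[[i]]$fragments$mz,
                          specs[[i]]$mz, specs[[i]]$intensity, tol, unit)
      }))
    }
    entropy_similarity_grouped(pred_int, exp_flat, group, length(psms))
  }
  list(score_at = score_at, n = length(psms))
}

#' Calibrate a model's collision energy against experimental spectra
#'
#' The calibration PSMs (normally the top 1000 by e-value, see
#' [select_top_psms()]) are predicted at every integer NCE in the grid;
#' for each value the median unweighted spectral entropy similarity
#' between predicted and experimental spectra is recorded, and the NCE
#' with the highest median wins (ties go to the lowest NCE). PSMs whose
#' peptide fails the model's support check are excluded beforehand and
#' counted, not backfilled.
#'
#' @param psms List of PSM records (with spectra metadata attached).
#' @param spectra List of spectra covering every PSM's scan.
#' @param backend A prediction backend for an MS2 model with
#'   `takes_nce = TRUE`.
#' @param model The [model_spec()]; defaults to the backend's.
#' @param grid An [nce_grid()].
#' @param tol Match tolerance (default 20 ppm).
#' @param unit `"ppm"` or `"da"`.
#' @return An `nce_calibration`: `per_nce_median` (named by NCE),
#'   `per_nce_quartiles`, `chosen_nce`, `n_psms`, `n_excluded`.
#' @export
calibrate_nce <- function(psms, spectra, backend, model = backend$model,
                          grid = nce_grid(), tol = 20,
                          unit = c("ppm", "da")) {
  unit <- match.arg(unit)
  stopifnot(inherits(model, "model_spec"))
  if (!model$takes_nce) stop("model does not take NCE", call. = FALSE)
  supported <- vapply(psms, function(r) {
    check_model_support(psm_peptidoform(r), model)$verdict == "supported"
  }, logical(1))
  n_excluded <- sum(!supported)
  psms <- psms[supported]
  if (length(psms) == 0) {
    stop("all calibration PSMs excluded by model support", call. = FALSE)
  }
  ctx <- ms2_scoring_context(psms, spectra, backend, tol, unit)
  values <- grid$values
  med <- numeric(length(values))
  q1 <- numeric(length(values)); q3 <- numeric(length(values))
  for (k in seq_along(values)) {
    scores <- tryCatch(ctx$score_at(values[k]), error = function(e) {
      stop(sprintf("prediction failed at NCE %d: %s", values[k],
                   conditionMessage(e)), call. = FALSE)
    })
    med[k] <- stats::median(scores)
    qq <- stats::quantile(scores, c(0.25, 0.75), names = FALSE)
    q1[k] <- qq[1]; q3[k] <- qq[2]
  }
  names(med) <- values
  structure(
    list(per_nce_median = med,
         per_nce_quartiles = data.frame(nce = values, n = length(psms),
                                        median = med, q1 = q1, q3 = q3),
         chosen_nce = values[which.max(med)],
         n_psms = length(psms), n_excluded = n_excluded),
    class = "nce_calibration")
}

#' @export
print.nce_calibration <- function(x, ...) {
  cat(sprintf("<nce_calibration> chosen NCE %d%% (median similarity %.4f) over %d PSM(s), %d excluded\n",
              x$chosen_nce, max(x$per_nce_median), x$n_psms, x$n_excluded))
  invisible(x)
}

#' Write an NCE calibration report as TSV
#'
#' Columns: nce, n, median, q1, q3 -- the per-NCE similarity distribution
#' summaries behind the chosen value.
#'
#' @param cal An `nce_calibration`.
#' @param path Output path.
#' @export
write_nce_report <- function(cal, path) {
  stopifnot(inherits(cal, "nce_calibration"))
  df <- cal$per_nce_quartiles
  df$median <- sprintf("%.6f", df$median)
  df$q1 <- sprintf("%.6f", df$q1)
  df$q3 <- sprintf("%.6f", df$q3)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cal)
}
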