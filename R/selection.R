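# Heuristic best-model search: per-model feature scores on a confident
# PSM subset, several selection statistics (median, top/bottom consensus,
# RMSE), the squared-ratio summary score, and the gray/red/white region
# classification of ranked score lists.

#' Per-file PSM subset for the best-model search
#'
#' Takes the `floor(budget / P)` lowest-e-value PSMs from each of the P
#' pin files independently (ties broken by row order). Empty files
#' contribute nothing and trigger a warning; there is no redistribution.
#'
#' @param pins List of `pin_table` objects.
#' @param budget Total PSM budget (default 1000).
#' @return List of PSM records.
#' @export
select_search_psms <- function(pins, budget = 1000L) {
  P <- length(pins)
  stopifnot(P >= 1, budget >= 1)
  k <- budget %/% P
  out <- list()
  for (f in seq_along(pins)) {
    rs <- pins[[f]]$records
    if (length(rs) == 0) {
      warning("pin file ", f, " contributes no PSMs")
      next
    }
    ev <- vapply(rs, function(r) r$evalue, numeric(1))
    ord <- order(ev, seq_along(rs))
    out <- c(out, rs[ord[seq_len(min(k, length(rs)))]])
  }
  out
}

#' Construct a score table
#'
#' @param psm_ids Character vector of PSM identifiers.
#' @param scores Numeric matrix, rows = PSMs, columns = models.
#' @param task `"MS2"` (higher similarity is better) or `"RT"` (lower
#'   deviation is better).
#' @return A `score_table`.
#' @export
score_table <- function(psm_ids, scores, task = c("MS2", "RT")) {
  task <- match.arg(task)
  scores <- as.matrix(scores)
  stopifnot(length(psm_ids) == nrow(scores), !is.null(colnames(scores)),
            !anyNA(scores))
  structure(
    list(psm_ids = psm_ids, models = colnames(scores), task = task,
         scores = scores,
         direction = if (task == "MS2") "higher" else "lower"),
    class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> [%s] %d PSM(s) x %d model(s); %s is better\n",
              x$task, nrow(x$scores), length(x$models), x$direction))
  invisible(x)
}

#' Score a PSM subset under every candidate model
#'
#' For MS2 the entry is the unweighted spectral entropy similarity at each
#' model's calibrated NCE; for RT it is the delta-RT-loess deviation in
#' minutes against each model's own calibration. PSMs unsupported by any
#' model are dropped entirely so all models are compared on an identical
#' PSM set.
#'
#' @param psms List of PSM records (spectra metadata attached).
#' @param spectra List of spectra.
#' @param backends Named list of prediction backends, one per model.
#' @param task `"MS2"` or `"RT"`.
#' @param nce Named numeric vector of calibrated NCEs (required for MS2
#'   models with `takes_nce`).
#' @param rt_calibrations Optional named list of `rt_calibration` objects;
#'   fitted on the subset itself when missing (linear fallback below 20
#'   points).
#' @param tol Match tolerance for MS2 (default 20 ppm).
#' @param unit `"ppm"` or `"da"`.
#' @param span Loess span used when fitting RT calibrations internally.
#' @return A `score_table`.
#' @export
build_score_table <- function(psms, spectra, backends,
                              task = c("MS2", "RT"), nce = NULL,
                              rt_calibrations = NULL, tol = 20,
                              unit = c("ppm", "da"), span = 0.3) {
  task <- match.arg(task)
  unit <- match.arg(unit)
  stopifnot(length(backends) >= 2, !is.null(names(backends)))
  models <- names(backends)
  peps <- lapply(psms, psm_peptidoform)
  support <- vapply(models, function(m) {
    spec <- backends[[m]]$model
    vapply(peps, function(p) {
      check_model_support(p, spec)$verdict == "supported"
    }, logical(1))
  }, logical(length(psms)))
  support <- matrix(support, nrow = length(psms),
                    dimnames = list(NULL, models))
  per_model_n <- colSums(support)
  if (any(per_model_n == 0)) {
    stop("model(s) with zero supported PSMs: ",
         paste(models[per_model_n == 0], collapse = ", "), call. = FALSE)
  }
  keep <- rowSums(support) == length(models)
  psms <- psms[keep]
  if (length(psms) == 0) stop("no PSM supported by all models",
                              call. = FALSE)
  scores <- matrix(NA_real_, nrow = length(psms), ncol = length(models),
                   dimnames = list(NULL, models))
  if (task == "MS2") {
    for (m in models) {
      b <- backends[[m]]
      nce_m <- if (b$model$takes_nce) {
        if (is.null(nce) || is.null(nce[[m]]) || is.na(nce[[m]])) {
          stop("no calibrated NCE supplied for model ", m, call. = FALSE)
        }
        nce[[m]]
      } else NA_real_
      ctx <- ms2_scoring_context(psms, spectra, b, tol, unit)
      scores[, m] <- ctx$score_at(nce_m)
    }
  } else {
    peptides <- vapply(psms, function(r) pin_peptide_core(r$peptide),
                       character(1))
    charges <- vapply(psms, function(r) {
      z <- r$precursor_charge; if (is.na(z)) 2L else as.integer(z)
    }, integer(1))
    exp_rt <- vapply(psms, function(r) r$retention_time, numeric(1))
    if (anyNA(exp_rt)) stop("PSMs missing retention times; attach spectra",
                            call. = FALSE)
    for (m in models) {
      req <- prediction_request(peptides, charges)
      resp <- predict_peptides(backends[[m]], req)
      bad <- !vapply(resp$errors, is.null, logical(1))
      if (any(bad)) stop("model ", m, " rejected ", sum(bad), " peptide(s)",
                         call. = FALSE)
      pred_rt <- vapply(resp$entries, as.numeric, numeric(1))
      cal <- rt_calibrations[[m]]
      if (is.null(cal)) {
        cal <- if (length(pred_rt) >= 20) {
          fit_rt_calibration(pred_rt, exp_rt, span = span)
        } else {
          fit_rt_calibration_linear(pred_rt, exp_rt)
        }
      }
      scores[, m] <- delta_rt_loess(exp_rt, pred_rt, cal)
    }
  }
  ids <- vapply(psms, function(r) r$spec_id, character(1))
  score_table(ids, scores, task)
}

better <- function(direction) {
  if (direction == "higher") function(a, b) a > b else function(a, b) a < b
}

# Lexicographically first among the models attaining the optimum of
# `stat` in the given direction.
argbest <- function(stat, direction) {
  opt <- if (direction == "higher") max(stat) else min(stat)
  sort(names(stat)[stat == opt])[1]
}

selection_report <- function(method, statistic, chosen, votes = NULL) {
  structure(
    list(method = method, per_model_statistic = statistic, votes = votes,
         chosen = chosen),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %s -> %s\n", x$method, x$chosen))
  stat <- format(signif(x$per_model_statistic, 5))
  for (m in names(x$per_model_statistic)) {
    cat(sprintf("  %-12s %s%s\n", m, stat[m],
                if (!is.null(x$votes)) sprintf("  (%d vote(s))", x$votes[m])
                else ""))
  }
  invisible(x)
}

#' Median model selection
#'
#' The MS2 model with the highest median similarity, or the RT model with
#' the lowest median deviation; statistic ties break lexicographically by
#' model name.
#'
#' @param t A `score_table`.
#' @return A `selection_report`.
#' @export
pick_median <- function(t) {
  stopifnot(inherits(t, "score_table"))
  stat <- apply(t$scores, 2, stats::median)
  selection_report("median", stat, argbest(stat, t$direction))
}

# Shared voting engine for both consensus methods. `tail` is "top"
# (each model's n largest scores sorted descending) or "bottom" (its n
# smallest, sorted ascending); at each rank position the model with the
# best value per the table's direction receives exactly one vote
# (position ties to the lexicographically first model).
consensus_votes <- function(t, n, tail) {
  stopifnot(inherits(t, "score_table"))
  n <- as.integer(n)
  if (n > nrow(t$scores)) {
    stop(sprintf("n = %d exceeds PSM count %d", n, nrow(t$scores)),
         call. = FALSE)
  }
  ranked <- vapply(t$models, function(m) {
    col <- sort(t$scores[, m], decreasing = (tail == "top"))
    col[seq_len(n)]
  }, numeric(n))
  ranked <- matrix(ranked, nrow = n, dimnames = list(NULL, t$models))
  votes <- stats::setNames(integer(length(t$models)), t$models)
  model_order <- sort(t$models)
  for (pos in seq_len(n)) {
    v <- ranked[pos, ]
    opt <- if (t$direction == "higher") max(v) else min(v)
    winner <- model_order[model_order %in% names(v)[v == opt]][1]
    votes[winner] <- votes[winner] + 1L
  }
  votes
}

# Chosen = most votes; vote ties resolved by the median statistic among
# the tied leaders (then lexicographically).
consensus_report <- function(t, votes, method) {
  leaders <- names(votes)[votes == max(votes)]
  chosen <- if (length(leaders) == 1) {
    leaders
  } else {
    med <- apply(t$scores[, leaders, drop = FALSE], 2, stats::median)
    argbest(med, t$direction)
  }
  stat <- votes / sum(votes)  # vote fraction in [0, 1]
  selection_report(method, stat, chosen, votes = votes)
}

#' Top-consensus model selection
#'
#' Each model's `n` largest scores (highest similarities for MS2, largest
#' RT deviations for RT) are sorted; at every rank position from 1 to `n`
#' the model with the best value (greatest similarity or smallest
#' deviation) gets a vote, and the model with the most votes wins. The
#' reported statistic is the vote fraction, bounded by 0 (no votes) and 1
#' (all votes).
#'
#' @param t A `score_table`.
#' @param n Tail size; 10, 50 and 100 are the standard presets.
#' @return A `selection_report` with `votes`.
#' @export
pick_top_consensus <- function(t, n = 10L) {
  consensus_report(t, consensus_votes(t, n, "top"),
                   sprintf("top_consensus_%d", as.integer(n)))
}

#' Bottom-consensus model selection
#'
#' As [pick_top_consensus()], but over each model's `n` smallest scores
#' (lowest similarities / smallest deviations).
#'
#' @inheritParams pick_top_consensus
#' @return A `selection_report` with `votes`.
#' @export
pick_bottom_consensus <- function(t, n = 10L) {
  consensus_report(t, consensus_votes(t, n, "bottom"),
                   sprintf("bottom_consensus_%d", as.integer(n)))
}

#' RMSE model selection (RT only)
#'
#' Root mean squared error of the RT deviations; lowest wins, ties break
#' lexicographically.
#'
#' @param t An RT `score_table`.
#' @return A `selection_report`.
#' @export
pick_rmse <- function(t) {
  stopifnot(inherits(t, "score_table"))
  if (t$task != "RT") stop("RMSE selection applies to RT tables only",
                           call. = FALSE)
  stat <- sqrt(colMeans(t$scores^2))
  selection_report("rmse", stat, argbest(stat, "lower"))
}

#' Select the best MS2 and RT models
#'
#' Applies the production criteria -- median for MS2, top consensus with
#' 10 PSMs for RT -- and also returns the full reports of every method on
#' both tables for transparency.
#'
#' @param ms2_table An MS2 `score_table`.
#' @param rt_table An RT `score_table`.
#' @param consensus_n Tail size for the RT consensus (default 10).
#' @return A list with `ms2`, `rt` (chosen model names) and `reports`.
#' @export
select_models <- function(ms2_table, rt_table, consensus_n = 10L) {
  stopifnot(ms2_table$task == "MS2", rt_table$task == "RT")
  cap <- function(t, n) min(n, nrow(t$scores))
  ms2_reports <- list(
    median = pick_median(ms2_table),
    top_consensus = pick_top_consensus(ms2_table, cap(ms2_table, consensus_n)),
    bottom_consensus = pick_bottom_consensus(ms2_table,
                                             cap(ms2_table, consensus_n)))
  rt_reports <- list(
    median = pick_median(rt_table),
    top_consensus = pick_top_consensus(rt_table, cap(rt_table, consensus_n)),
    bottom_consensus = pick_bottom_consensus(rt_table,
                                             cap(rt_table, consensus_n)),
    rmse = pick_rmse(rt_table))
  list(ms2 = ms2_reports$median$chosen,
       rt = rt_reports$top_consensus$chosen,
       ms2_criterion = "median",
       rt_criterion = sprintf("top_consensus_%d",
                              cap(rt_table, consensus_n)),
       reports = list(MS2 = ms2_reports, RT = rt_reports))
}

#' Heuristic summary score of a selection method
#'
#' For each dataset, the picked model's empirical mean peptide yield is
#' divided by the best model's mean yield; the squares of these ratios are
#' averaged across datasets. Squaring penalizes small ratios more heavily.
#' The score lies in (0, 1] and equals 1 iff every pick is empirically
#' best.
#'
#' @param picks Named character vector, dataset -> picked model.
#' @param outcomes Data frame with columns `dataset`, `model`,
#'   `mean_peptides` (and optionally `sd`, `n_runs`).
#' @return Scalar in (0, 1].
#' @export
heuristic_summary_score <- function(picks, outcomes) {
  stopifnot(!is.null(names(picks)), length(picks) >= 1)
  ratios <- vapply(names(picks), function(d) {
    sub <- outcomes[outcomes$dataset == d, , drop = FALSE]
    i <- match(picks[[d]], sub$model)
    if (nrow(sub) == 0 || is.na(i)) {
      stop("no empirical outcome for pick '", picks[[d]], "' in dataset '",
           d, "'", call. = FALSE)
    }
    sub$mean_peptides[i] / max(sub$mean_peptides)
  }, numeric(1))
  mean(ratios^2)
}

#' Classify ranked score positions as gray, red or white
#'
#' Each model's score column is sorted ascending; at every rank position
#' the model with the best score (per the table's direction) is found.
#' The position is gray when that model is the empirically best rescoring
#' model; otherwise red when that model's mean peptide yield plus one
#' standard deviation is below the best model's mean minus one standard
#' deviation (clearly worse), and white when the intervals overlap
#' (comparable).
#'
#' @param t A `score_table`.
#' @param outcomes Data frame with columns `model`, `mean_peptides`, `sd`
#'   covering every model in the table (a single dataset).
#' @param best_model Name of the empirically best rescoring model.
#' @return Character vector of labels, one per rank position.
#' @export
classify_positions <- function(t, outcomes, best_model) {
  stopifnot(inherits(t, "score_table"))
  if ("dataset" %in% names(outcomes) &&
      length(unique(outcomes$dataset)) > 1) {
    stop("outcomes must cover a single dataset", call. = FALSE)
  }
  miss <- setdiff(t$models, outcomes$model)
  if (length(miss) > 0) stop("outcomes missing model(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  mean_p <- stats::setNames(outcomes$mean_peptides, outcomes$model)
  sd_p <- stats::setNames(outcomes$sd, outcomes$model)
  sorted <- apply(t$scores, 2, sort)
  sorted <- matrix(sorted, nrow = nrow(t$scores),
                   dimnames = list(NULL, t$models))
  model_order <- sort(t$models)
  vapply(seq_len(nrow(sorted)), function(pos) {
    v <- sorted[pos, ]
    opt <- if (t$direction == "higher") max(v) else min(v)
    m <- model_order[model_order %in% names(v)[v == opt]][1]
    if (m == best_model) return("gray")
    if (mean_p[m] + sd_p[m] < mean_p[best_model] - sd_p[best_model]) {
      "red"
    } else {
      "white"
    }
  }, character(1))
}

#' Write selection reports as TSV
#'
#' One row per (task, method, model): the method's statistic, vote count
#' where applicable, and a flag on the chosen model.
#'
#' @param reports The `reports` element of [select_models()].
#' @param path Output path.
#' @export
write_selection_report <- function(reports, path) {
  rows <- list()
  for (task in names(reports)) {
    for (method in names(reports[[task]])) {
      r <- reports[[task]][[method]]
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, method = r$method,
        model = names(r$per_model_statistic),
        statistic = sprintf("%.6f", r$per_model_statistic),
        votes = if (is.null(r$votes)) NA_integer_
                else r$votes[names(r$per_model_statistic)],
        chosen = as.integer(names(r$per_model_statistic) == r$chosen),
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(reports)
}

#' Write a region-classification track as TSV
#'
#' @param labels Output of [classify_positions()].
#' @param path Output path.
#' @export
write_region_report <- function(labels, path) {
  utils::write.table(
    data.frame(position = seq_along(labels), region = labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(labels)
}
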