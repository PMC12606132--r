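# Rescoring features: unweighted spectral entropy similarity (MS2) and
# delta-RT-loess (RT), plus the peak matching and fragment m/z adjustment
# they depend on.

# Greedy nearest-match of predicted fragment m/z against an experimental
# peak list. Each experimental peak is used at most once; candidate pairs
# within tolerance are assigned in order of ascending relative distance.
# Returns the matched experimental intensity per predicted fragment
# (0 where unmatched). `tol` is ppm unless `unit == "da"`.
match_intensities <- function(pred_mz, peak_mz, peak_intensity, tol,
                              unit = c("ppm", "da")) {
  unit <- match.arg(unit)
  out <- numeric(length(pred_mz))
  if (length(peak_mz) == 0 || length(pred_mz) == 0) return(out)
  d <- if (unit == "ppm") pred_mz * tol * 1e-6 else rep(tol, length(pred_mz))
  lo <- findInterval(pred_mz - d, peak_mz) + 1L
  hi <- findInterval(pred_mz + d, peak_mz)
  counts <- pmax(hi - lo + 1L, 0L)
  if (sum(counts) == 0) return(out)
  frag_idx <- rep.int(seq_along(pred_mz), counts)
  peak_idx <- sequence(counts[counts > 0L], from = lo[counts > 0L])
  dist <- abs(peak_mz[peak_idx] - pred_mz[frag_idx]) / pred_mz[frag_idx]
  ord <- order(dist)
  frag_used <- logical(length(pred_mz))
  peak_used <- logical(length(peak_mz))
  for (k in ord) {
    fi <- frag_idx[k]; pi <- peak_idx[k]
    if (!frag_used[fi] && !peak_used[pi]) {
      frag_used[fi] <- TRUE
      peak_used[pi] <- TRUE
      out[fi] <- peak_intensity[pi]
    }
  }
  out
}

#' Match predicted fragments to experimental peaks
#'
#' Each predicted fragment is matched to the nearest experimental peak
#' within the mass tolerance; each experimental peak is used at most once,
#' with conflicts resolved greedily in order of ascending m/z distance.
#' Unmatched predicted fragments receive experimental intensity 0.
#' Experimental peaks matching no predicted fragment are ignored: the
#' similarity is computed over the predicted (b/y) fragment set only.
#'
#' @param spec A `spectrum` from [read_mgf()].
#' @param pred A [predicted_entry()] with at least one fragment.
#' @param tol Mass tolerance (default 20 ppm).
#' @param unit `"ppm"` or `"da"`.
#' @return An `aligned_intensities` object: `predicted` and `experimental`
#'   intensity vectors of equal length, plus the tolerance used.
#' @export
match_peaks <- function(spec, pred, tol = 20, unit = c("ppm", "da")) {
  stopifnot(inherits(pred, "predicted_entry"), tol > 0)
  unit <- match.arg(unit)
  if (nrow(pred$fragments) == 0) stop("prediction has no fragments",
                                      call. = FALSE)
  exp_int <- match_intensities(pred$fragments$mz, spec$mz, spec$intensity,
                               tol, unit)
  structure(
    list(predicted = pred$fragments$intensity, experimental = exp_int,
         tolerance = tol, unit = unit),
    class = "aligned_intensities")
}

#' Unweighted spectral entropy similarity
#'
#' Both intensity vectors are normalized to sum 1; with `m = (p + q) / 2`
#' and Shannon entropy `H(x) = -sum(x * log(x))`, the score is
#' `1 - (2 * H(m) - H(p) - H(q)) / log(4)`. It lies in `[0, 1]`, equals 1
#' iff the normalized vectors are identical, equals 0 for disjoint
#' support, and is invariant to rescaling either vector. An all-zero
#' experimental vector scores 0 by convention; an all-zero predicted
#' vector is an invalid prediction and raises an error.
#'
#' @param a An `aligned_intensities` object from [match_peaks()], or any
#'   list with numeric `predicted` and `experimental` of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
entropy_similarity <- function(a) {
  p <- a$predicted
  q <- a$experimental
  stopifnot(length(p) == length(q))
  if (sum(p) <= 0) stop("all-zero predicted intensity vector", call. = FALSE)
  if (sum(q) <= 0) return(0)
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  s <- 1 - (2 * shannon_entropy(m) - shannon_entropy(p) -
              shannon_entropy(q)) / log(4)
  min(1, max(0, s))  # guard against rounding just outside [0, 1]
}

shannon_entropy <- function(x) {
  x <- x[x > 0]
  -sum(x * log(x))
}

# Vectorized entropy similarity over many PSMs at once: `pred` and `expv`
# are flat intensity vectors, `group` maps each element to its PSM
# (integers 1..ngroup). Groups with all-zero experimental intensity score
# 0. Returns one score per group.
entropy_similarity_grouped <- function(pred, expv, group, ngroup) {
  gsum_p <- rowsum_by(pred, group, ngroup)
  gsum_q <- rowsum_by(expv, group, ngroup)
  if (any(gsum_p <= 0)) stop("all-zero predicted intensity vector",
                             call. = FALSE)
  p <- pred / gsum_p[group]
  safe_q <- ifelse(gsum_q > 0, gsum_q, 1)
  q <- expv / safe_q[group]
  m <- (p + q) / 2
  hterm <- function(x) ifelse(x > 0, -x * log(x), 0)
  hm <- rowsum_by(hterm(m), group, ngroup)
  hp <- rowsum_by(hterm(p), group, ngroup)
  hq <- rowsum_by(hterm(q), group, ngroup)
  score <- 1 - (2 * hm - hp - hq) / log(4)
  score[gsum_q <= 0] <- 0
  pmin(1, pmax(0, score))
}

rowsum_by <- function(x, group, ngroup) {
  out <- numeric(ngroup)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# ---------------------------------------------------------------------------
# Retention-time calibration

#' Fit a loess retention-time calibration
#'
#' Locally weighted regression (degree 1, tricube weights, one
#' robustifying iteration) of experimental retention time (minutes) on
#' the model-native predicted retention value, fitted on a confident PSM
#' subset. Duplicate predicted values are averaged before fitting.
#' Evaluation outside the fitted range clamps to the boundary fit.
#'
#' @param predicted Numeric vector of model-native predicted RT values.
#' @param experimental Numeric vector of experimental RTs in minutes.
#' @param span Loess smoothing fraction in (0, 1]; default 0.3.
#' @return An `rt_calibration` with `knots` (sorted unique predicted
#'   values), `fitted` (calibrated minutes at the knots), `span` and
#'   `n_points`.
#' @export
fit_rt_calibration <- function(predicted, experimental, span = 0.3) {
  stopifnot(length(predicted) == length(experimental),
            span > 0, span <= 1)
  ok <- is.finite(predicted) & is.finite(experimental)
  predicted <- predicted[ok]
  experimental <- experimental[ok]
  if (length(predicted) < 20) {
    stop("fewer than 20 calibration points; fall back to a linear fit",
         call. = FALSE)
  }
  agg <- tapply(experimental, predicted, mean)
  x <- as.numeric(names(agg))
  y <- as.numeric(agg)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  fit <- stats::loess(y ~ x, span = span, degree = 1, family = "symmetric",
                      control = stats::loess.control(surface = "direct",
                                                     iterations = 2))
  fitted <- stats::predict(fit, data.frame(x = x))
  structure(
    list(knots = x, fitted = as.numeric(fitted), span = span,
         n_points = length(predicted)),
    class = "rt_calibration")
}

# Linear fallback for subsets too small for loess.
fit_rt_calibration_linear <- function(predicted, experimental) {
  stopifnot(length(predicted) == length(experimental), length(predicted) >= 2)
  fit <- stats::lm(experimental ~ predicted)
  x <- sort(unique(predicted))
  structure(
    list(knots = x, fitted = as.numeric(stats::predict(
           fit, data.frame(predicted = x))),
         span = NA_real_, n_points = length(predicted)),
    class = "rt_calibration")
}

#' @export
print.rt_calibration <- function(x, ...) {
  cat(sprintf("<rt_calibration> %d point(s), %d knot(s), span %s\n",
              x$n_points, length(x$knots),
              if (is.na(x$span)) "linear" else format(x$span)))
  invisible(x)
}

#' Evaluate an RT calibration
#'
#' @param object An `rt_calibration`.
#' @param newdata Predicted RT values (model-native scale).
#' @param ... Unused.
#' @return Calibrated retention times in minutes; values outside the knot
#'   range are clamped to the boundary fit.
#' @export
predict.rt_calibration <- function(object, newdata, ...) {
  if (length(object$knots) == 1) {
    return(rep(object$fitted, length(newdata)))
  }
  stats::approx(object$knots, object$fitted, xout = newdata, rule = 2)$y
}

#' Delta-RT-loess feature
#'
#' Absolute deviation, in minutes, between a PSM's observed retention time
#' and the calibrated prediction. Small values indicate agreement.
#'
#' @param psm_rt Observed retention time(s), minutes.
#' @param predicted_rt Model-native predicted retention value(s).
#' @param cal An `rt_calibration` from [fit_rt_calibration()].
#' @return Non-negative deviation(s) in minutes.
#' @export
delta_rt_loess <- function(psm_rt, predicted_rt, cal) {
  stopifnot(inherits(cal, "rt_calibration"))
  abs(psm_rt - predict(cal, predicted_rt))
}

# ---------------------------------------------------------------------------
# Fragment m/z adjustment for stripped modifications

#' Shift predicted fragment m/z for stripped modifications
#'
#' When a model cannot predict a modified peptidoform, the stripped
#' version is predicted instead and each fragment covering a removed
#' modification site is shifted by `delta / fragment charge`. A b_k
#' fragment covers the N-terminus and residues 1..k; a y_k fragment covers
#' residues len-k+1..len and the C-terminus. Intensities are unchanged and
#' an adjustment record is attached to the returned entry.
#'
#' @param pred A [predicted_entry()] for the stripped peptidoform.
#' @param removed Data frame of `position`, `delta` from
#'   [strip_unsupported_mods()].
#' @return The adjusted [predicted_entry()].
#' @export
adjust_fragment_mzs <- function(pred, removed) {
  stopifnot(inherits(pred, "predicted_entry"))
  removed <- as.data.frame(removed)
  if (nrow(removed) == 0) return(pred)
  n <- length(pred$peptidoform$residues)
  if (any(removed$position < 0 | removed$position > n + 1)) {
    stop("removed modification position out of range", call. = FALSE)
  }
  f <- pred$fragments
  shift <- numeric(nrow(f))
  for (k in seq_len(nrow(removed))) {
    pos <- removed$position[k]
    delta <- removed$delta[k]
    covered <- ifelse(f$series == "b",
                      pos <= f$ordinal,            # 0..ordinal
                      pos >= n - f$ordinal + 1L)   # len-k+1..len+1
    shift <- shift + ifelse(covered, delta / f$charge, 0)
  }
  f$mz <- f$mz + shift
  pred$fragments <- f
  pred$adjustment <- removed
  pred
}
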