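#' Declare a prediction model's constraints
#'
#' Peptide-property predictors accept only a subset of peptidoforms: a
#' length window, a set of precursor charges, and a set of supported
#' modifications. `model_spec` records those constraints plus the model's
#' task and whether it consumes collision energy / instrument metadata.
#'
#' @param name Model name.
#' @param task One of `"MS2"`, `"RT"`, `"IM"`.
#' @param supported_mods Character vector of UNIMOD accessions the model
#'   understands (e.g. `"UNIMOD:35"`).
#' @param min_length,max_length Residue-count limits.
#' @param allowed_charges Integer vector of precursor charges.
#' @param takes_nce Does the model condition on normalized collision energy?
#' @param takes_instrument Does the model condition on instrument type?
#' @param ion_series Fragment series the model predicts; b/y only by default.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, task = c("MS2", "RT", "IM"),
                       supported_mods = character(),
                       min_length = 6L, max_length = 30L,
                       allowed_charges = 1:4,
                       takes_nce = identical(task[1], "MS2"),
                       takes_instrument = FALSE,
                       ion_series = c("b", "y")) {
  task <- match.arg(task)
  min_length <- as.integer(min_length)
  max_length <- as.integer(max_length)
  stopifnot(min_length <= max_length, length(allowed_charges) > 0)
  structure(
    list(name = name, task = task,
         supported_mods = toupper(supported_mods),
         min_length = min_length, max_length = max_length,
         allowed_charges = as.integer(allowed_charges),
         takes_nce = isTRUE(takes_nce),
         takes_instrument = isTRUE(takes_instrument),
         ion_series = ion_series),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s [%s] length %d-%d, charges %s, %d supported mod(s)%s\n",
              x$name, x$task, x$min_length, x$max_length,
              paste(x$allowed_charges, collapse = "/"),
              length(x$supported_mods),
              if (x$takes_nce) ", takes NCE" else ""))
  invisible(x)
}

#' Check whether a model can predict a peptidoform
#'
#' Constraints are checked in a fixed order -- length, charge, then
#' modifications -- and the verdict reflects the first violation, so the
#' result is reproducible. Mass-delta-only modifications (no accession)
#' are never considered supported.
#'
#' @param p A [peptidoform()].
#' @param m A [model_spec()].
#' @return A list with `verdict` (one of `supported`, `too_long`,
#'   `too_short`, `unsupported_mods`, `unsupported_charge`) and
#'   `offending_mods`, a data.frame of the unsupported modifications
#'   (non-empty iff the verdict is `unsupported_mods`).
#' @export
check_model_support <- function(p, m) {
  stopifnot(inherits(p, "peptidoform"), inherits(m, "model_spec"))
  none <- empty_mods()[, c("position", "accession", "delta")]
  n <- length(p$residues)
  if (n > m$max_length) {
    return(support_status("too_long", none))
  }
  if (n < m$min_length) {
    return(support_status("too_short", none))
  }
  if (!is.null(p$charge) && !(p$charge %in% m$allowed_charges)) {
    return(support_status("unsupported_charge", none))
  }
  if (nrow(p$mods) > 0) {
    ok <- !is.na(p$mods$accession) &
      toupper(p$mods$accession) %in% m$supported_mods
    if (any(!ok)) {
      off <- p$mods[!ok, c("position", "accession", "delta"), drop = FALSE]
      rownames(off) <- NULL
      return(support_status("unsupported_mods", off))
    }
  }
  support_status("supported", none)
}

support_status <- function(verdict, offending_mods) {
  structure(list(verdict = verdict, offending_mods = offending_mods),
            class = "support_status")
}

#' @export
print.support_status <- function(x, ...) {
  cat("<support_status>", x$verdict, "\n")
  if (nrow(x$offending_mods) > 0) print(x$offending_mods)
  invisible(x)
}

#' Remove modifications a model does not support
#'
#' When a peptidoform carries modifications outside a model's repertoire,
#' the unmodified (or partially modified) version can be queried instead
#' and the predicted fragment m/z values shifted afterwards (see
#' [adjust_fragment_mzs()]). Supported modifications are kept.
#'
#' @inheritParams check_model_support
#' @return A list with `peptidoform` (the stripped peptidoform) and
#'   `removed`, a data.frame of `position`, `delta` for every removed
#'   modification.
#' @export
strip_unsupported_mods <- function(p, m) {
  stopifnot(inherits(p, "peptidoform"), inherits(m, "model_spec"))
  if (nrow(p$mods) == 0) {
    return(list(peptidoform = p,
                removed = data.frame(position = integer(), delta = numeric())))
  }
  ok <- !is.na(p$mods$accession) &
    toupper(p$mods$accession) %in% m$supported_mods
  removed <- p$mods[!ok, c("position", "delta"), drop = FALSE]
  rownames(removed) <- NULL
  kept <- p$mods[ok, , drop = FALSE]
  list(
    peptidoform = peptidoform(paste(p$residues, collapse = ""), kept, p$charge),
    removed = removed
  )
}
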