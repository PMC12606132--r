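# Prediction backend contract: a request/response pair plus a predict()
# generic. Two backends exist: a remote Koina-style client (contract level
# only; transport injectable, no live network in tests) and the synthetic
# ground-truth backend defined in synthetic.R.

#' Build a prediction request
#'
#' Lists are parallel by index; all present lists must have equal length
#' and every peptide string must parse as ProForma.
#'
#' @param peptides Character vector of ProForma strings.
#' @param charges Integer vector of precursor charges.
#' @param nce Optional numeric vector of normalized collision energies
#'   (percent).
#' @param instrument Optional character vector of instrument labels.
#' @return A `prediction_request`.
#' @export
prediction_request <- function(peptides, charges, nce = NULL,
                               instrument = NULL) {
  n <- length(peptides)
  stopifnot(length(charges) == n)
  if (!is.null(nce)) {
    if (length(nce) == 1) nce <- rep(nce, n)
    stopifnot(length(nce) == n)
  }
  if (!is.null(instrument)) {
    if (length(instrument) == 1) instrument <- rep(instrument, n)
    stopifnot(length(instrument) == n)
  }
  parsed <- lapply(peptides, parse_proforma)
  structure(
    list(peptides = peptides, parsed = parsed,
         charges = as.integer(charges), nce = nce, instrument = instrument),
    class = "prediction_request")
}

#' @export
print.prediction_request <- function(x, ...) {
  cat(sprintf("<prediction_request> %d peptide(s)%s\n", length(x$peptides),
              if (!is.null(x$nce)) sprintf(", NCE %s",
                paste(unique(x$nce), collapse = "/")) else ""))
  invisible(x)
}

# Slice a request to a subset of indices (used for batching).
slice_request <- function(req, idx) {
  structure(
    list(peptides = req$peptides[idx], parsed = req$parsed[idx],
         charges = req$charges[idx],
         nce = if (is.null(req$nce)) NULL else req$nce[idx],
         instrument = if (is.null(req$instrument)) NULL
                      else req$instrument[idx]),
    class = "prediction_request")
}

#' Obtain predictions from a backend
#'
#' Responses are parallel to the request: `entries[[i]]` is a
#' [predicted_entry()] (MS2), a numeric retention value (RT), or `NULL`
#' when `errors[[i]]` records a per-item failure (e.g. a peptide exceeding
#' the model's length limit). Items never go silently missing. Splitting a
#' request into batches and concatenating the responses yields the same
#' result as a single call.
#'
#' @param backend A backend object (`synthetic_backend` or
#'   `koina_backend`).
#' @param req A [prediction_request()].
#' @param ... Backend-specific arguments.
#' @return A `prediction_response`: `entries`, `errors`, `model_name`,
#'   `model_version`.
#' @export
predict_peptides <- function(backend, req, ...) {
  UseMethod("predict_peptides")
}

prediction_response <- function(entries, errors, model_name, model_version) {
  structure(
    list(entries = entries, errors = errors,
         model_name = model_name, model_version = model_version),
    class = "prediction_response")
}

#' @export
print.prediction_response <- function(x, ...) {
  n_err <- sum(!vapply(x$errors, is.null, logical(1)))
  cat(sprintf("<prediction_response> %s (%s): %d item(s), %d error(s)\n",
              x$model_name, x$model_version, length(x$entries), n_err))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Remote (Koina-style) client: contract only. The transport function
# receives a payload list (named tensors) and must return the parsed
# response or signal a condition of class "pinboost_transport_error"
# (retryable). Batching and retry with exponential backoff live here and
# are exercised with mock transports in the tests.

#' Declare a remote prediction service client
#'
#' Contract-level client for Koina-style inference servers: it prepares
#' named-tensor request payloads, batches large requests, and retries
#' transient transport failures with exponential backoff. The actual wire
#' transfer is delegated to the injectable `transport` function, so no
#' network access is required to exercise the client logic.
#'
#' @param url Server URL.
#' @param model A [model_spec()] describing the served model.
#' @param version Model version string.
#' @param batch_size Maximum peptides per transport call.
#' @param retries Transport retries per batch.
#' @param backoff_base Seconds for the first backoff (doubles per retry).
#' @param tensor_names Named list mapping the logical inputs
#'   (`peptides`, `charges`, `nce`, `instrument`) to the server's tensor
#'   names.
#' @param transport Function `(payload) -> list of entries`; `NULL` means
#'   unconfigured and any prediction attempt errors.
#' @return A `koina_backend`.
#' @export
koina_backend <- function(url, model, version = "1", batch_size = 1000L,
                          retries = 3L, backoff_base = 0.5,
                          tensor_names = list(peptides = "peptide_sequences",
                                              charges = "precursor_charges",
                                              nce = "collision_energies",
                                              instrument = "instrument_types"),
                          transport = NULL) {
  stopifnot(inherits(model, "model_spec"))
  structure(
    list(url = url, model = model, version = version,
         batch_size = as.integer(batch_size), retries = as.integer(retries),
         backoff_base = backoff_base, tensor_names = tensor_names,
         transport = transport),
    class = c("koina_backend", "prediction_backend"))
}

# Named-tensor payload for one batch, shaped [n, 1] per Koina convention.
build_koina_payload <- function(backend, req) {
  tn <- backend$tensor_names
  inputs <- list()
  add <- function(name, values, datatype) {
    inputs[[length(inputs) + 1L]] <<- list(
      name = name, shape = c(length(values), 1L),
      datatype = datatype, data = values)
  }
  add(tn$peptides, req$peptides, "BYTES")
  add(tn$charges, req$charges, "INT32")
  if (!is.null(req$nce)) add(tn$nce, req$nce, "FP32")
  if (!is.null(req$instrument)) add(tn$instrument, req$instrument, "BYTES")
  list(model_name = backend$model$name, model_version = backend$version,
       inputs = inputs)
}

transport_error <- function(message) {
  structure(
    class = c("pinboost_transport_error", "error", "condition"),
    list(message = message, call = NULL))
}

#' @export
predict_peptides.koina_backend <- function(backend, req, ...) {
  if (is.null(backend$transport)) {
    stop("koina_backend has no transport configured; ",
         "supply one or use the synthetic backend", call. = FALSE)
  }
  n <- length(req$peptides)
  entries <- vector("list", n)
  errors <- vector("list", n)
  starts <- seq(1L, n, by = backend$batch_size)
  for (s in starts) {
    idx <- s:min(s + backend$batch_size - 1L, n)
    sub <- slice_request(req, idx)
    payload <- build_koina_payload(backend, sub)
    result <- NULL
    for (attempt in seq_len(backend$retries + 1L)) {
      result <- tryCatch(backend$transport(payload),
                         pinboost_transport_error = function(e) e)
      if (!inherits(result, "pinboost_transport_error")) break
      if (attempt <= backend$retries) {
        Sys.sleep(backend$backoff_base * 2^(attempt - 1L))
      }
    }
    if (inherits(result, "pinboost_transport_error")) {
      stop(result)
    }
    stopifnot(length(result) == length(idx))
    entries[idx] <- result
  }
  prediction_response(entries, errors, backend$model$name, backend$version)
}
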