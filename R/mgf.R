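# Mascot Generic Format reading and writing.
#
# Experimental spectra and predicted libraries both travel as MGF. Library
# blocks carry a third peak-line token with the fragment annotation
# (e.g. "y3^1"). TITLE lines written by this package use the convention
# "<ProForma>/<charge>" for library entries.

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with the standard headers
#' (TITLE, PEPMASS, CHARGE, RTINSECONDS, SCANS plus optional NCE and
#' INSTRUMENT). Retention times are converted from seconds to minutes;
#' peaks are sorted by ascending m/z. Missing optional headers are left
#' absent (`NA`), never defaulted.
#'
#' @param path Path or connection.
#' @return A list of `spectrum` objects: each has `scan_number`,
#'   `precursor_mz`, `precursor_charge`, `retention_time` (minutes), `mz`,
#'   `intensity`, `annotation`, `nce`, `instrument`, `title`.
#' @export
read_mgf <- function(path) {
  if (is.character(path) && !file.exists(path)) {
    stop("MGF file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line != "BEGIN IONS") {
      if (nzchar(line)) {
        stop(sprintf("MGF line %d: expected BEGIN IONS, got '%s'", i, line),
             call. = FALSE)
      }
      i <- i + 1L
      next
    }
    begin_line <- i
    i <- i + 1L
    hdr <- list(title = NA_character_, pepmass = NA_real_,
                charge = NA_integer_, rt = NA_real_, scans = NA_integer_,
                nce = NA_real_, instrument = NA_character_)
    mz <- numeric(); inten <- numeric(); ann <- character()
    ended <- FALSE
    while (i <= n) {
      line <- trimws(lines[i])
      if (line == "END IONS") { ended <- TRUE; i <- i + 1L; break }
      if (grepl("=", line, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", line))
        val <- sub("^[^=]*=", "", line)
        switch(key,
          TITLE = hdr$title <- val,
          PEPMASS = hdr$pepmass <- as.numeric(strsplit(val, "[ \t]+")[[1]][1]),
          CHARGE = hdr$charge <- parse_mgf_charge(val, i),
          RTINSECONDS = hdr$rt <- as.numeric(val) / 60,
          SCANS = hdr$scans <- as.integer(val),
          NCE = hdr$nce <- as.numeric(val),
          INSTRUMENT = hdr$instrument <- val,
          NULL)  # unknown headers ignored
      } else if (nzchar(line)) {
        tok <- strsplit(line, "[ \t]+")[[1]]
        m <- suppressWarnings(as.numeric(tok[1]))
        h <- suppressWarnings(as.numeric(tok[2]))
        if (length(tok) < 2 || is.na(m) || is.na(h)) {
          stop(sprintf("MGF line %d: malformed peak line '%s'", i, line),
               call. = FALSE)
        }
        mz <- c(mz, m); inten <- c(inten, h)
        ann <- c(ann, if (length(tok) >= 3) tok[3] else NA_character_)
      }
      i <- i + 1L
    }
    if (!ended) {
      stop(sprintf("MGF: unterminated block starting at line %d", begin_line),
           call. = FALSE)
    }
    ord <- order(mz)
    spectra[[length(spectra) + 1L]] <- structure(
      list(scan_number = hdr$scans, precursor_mz = hdr$pepmass,
           precursor_charge = hdr$charge, retention_time = hdr$rt,
           mz = mz[ord], intensity = inten[ord], annotation = ann[ord],
           nce = hdr$nce, instrument = hdr$instrument, title = hdr$title),
      class = "spectrum")
  }
  spectra
}

parse_mgf_charge <- function(val, line_no) {
  v <- sub("\\+$", "", sub("^\\+", "", trimws(val)))
  z <- suppressWarnings(as.integer(v))
  if (is.na(z)) {
    stop(sprintf("MGF line %d: unparseable CHARGE '%s'", line_no, val),
         call. = FALSE)
  }
  z
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> scan %s, %d peak(s), precursor %.4f m/z (%s+), RT %.3f min\n",
              x$scan_number, length(x$mz), x$precursor_mz,
              x$precursor_charge, x$retention_time))
  invisible(x)
}

#' Construct a predicted library entry
#'
#' @param peptidoform A [peptidoform()].
#' @param precursor_charge Integer charge.
#' @param fragments Data frame with columns `series`, `ordinal`, `charge`,
#'   `mz`, `intensity`. Intensities must lie in `[0, 1]` with maximum 1
#'   when non-empty.
#' @param predicted_rt Optional predicted retention value (model-native
#'   scale; treated as minutes when written to MGF).
#' @param adjustment Optional record of fragment m/z adjustments applied
#'   for stripped modifications (see [adjust_fragment_mzs()]).
#' @return A `predicted_entry`.
#' @export
predicted_entry <- function(peptidoform, precursor_charge, fragments,
                            predicted_rt = NA_real_, adjustment = NULL) {
  stopifnot(inherits(peptidoform, "peptidoform"))
  fragments <- as.data.frame(fragments, stringsAsFactors = FALSE)
  if (nrow(fragments) > 0) {
    if (any(fragments$intensity < 0 | fragments$intensity > 1)) {
      stop("fragment intensities must lie in [0, 1]", call. = FALSE)
    }
    if (abs(max(fragments$intensity) - 1) > 1e-9) {
      stop("fragment intensities must be max-normalized to 1", call. = FALSE)
    }
  }
  structure(
    list(peptidoform = peptidoform,
         precursor_charge = as.integer(precursor_charge),
         fragments = fragments, predicted_rt = predicted_rt,
         adjustment = adjustment),
    class = "predicted_entry")
}

#' @export
print.predicted_entry <- function(x, ...) {
  cat(sprintf("<predicted_entry> %s/%d, %d fragment(s)%s\n",
              render_proforma(x$peptidoform), x$precursor_charge,
              nrow(x$fragments),
              if (!is.na(x$predicted_rt))
                sprintf(", RT %.3f", x$predicted_rt) else ""))
  invisible(x)
}

#' Write a predicted spectral library as MGF
#'
#' One block per entry. The TITLE line is `<ProForma>/<charge>`; peak
#' lines carry the fragment annotation as a third token (`b3^1`, `y5^2`).
#'
#' @param entries List of [predicted_entry()] objects.
#' @param path Output path or connection.
#' @export
write_library_mgf <- function(entries, path) {
  out <- character()
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    stopifnot(inherits(e, "predicted_entry"))
    pform <- render_proforma(e$peptidoform)
    block <- c(
      "BEGIN IONS",
      paste0("TITLE=", pform, "/", e$precursor_charge),
      sprintf("PEPMASS=%.5f", precursor_mz(e$peptidoform, e$precursor_charge)),
      sprintf("CHARGE=%d+", e$precursor_charge),
      sprintf("SCANS=%d", k)
    )
    if (!is.na(e$predicted_rt)) {
      block <- c(block, sprintf("RTINSECONDS=%.3f", e$predicted_rt * 60))
    }
    if (nrow(e$fragments) > 0) {
      f <- e$fragments
      block <- c(block, sprintf("%.5f %.6f %s%d^%d",
                                f$mz, f$intensity, f$series, f$ordinal,
                                f$charge))
    }
    block <- c(block, "END IONS", "")
    out <- c(out, block)
  }
  writeLines(out, path)
  invisible(entries)
}

# Write experimental spectra as plain MGF (used by the simulator).
write_spectra_mgf <- function(spectra, path) {
  out <- character()
  for (s in spectra) {
    block <- c(
      "BEGIN IONS",
      paste0("TITLE=", s$title),
      sprintf("PEPMASS=%.5f", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      sprintf("RTINSECONDS=%.3f", s$retention_time * 60),
      sprintf("SCANS=%d", s$scan_number),
      sprintf("%.5f %.6f", s$mz, s$intensity),
      "END IONS", ""
    )
    out <- c(out, block)
  }
  writeLines(out, path)
  invisible(spectra)
}
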