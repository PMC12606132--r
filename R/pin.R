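# Percolator input (.pin) reading and writing.
#
# A pin file is tab-separated with a header starting SpecId, Label, ScanNr,
# followed by feature columns, then Peptide and Proteins. The Proteins
# field may itself contain tabs, so every field from the Proteins column
# onward belongs to Proteins. Cell text is preserved verbatim so that an
# unmodified read -> write round trip is byte identical.

PIN_MANDATORY <- c("SpecId", "Label", "ScanNr", "Peptide", "Proteins")

#' Read a Percolator input file
#'
#' @param path Path to a `.pin` file (or a connection).
#' @param evalue_column Name of the feature column holding the log10
#'   expectation value used for PSM ranking. Configurable because search
#'   engines name it differently.
#' @return A `pin_table`: list with `header` (column names), `cells`
#'   (character matrix of raw fields, Proteins collapsed), `records`
#'   (list of parsed PSM records), `default_direction` (the optional
#'   `DefaultDirection` row, preserved verbatim) and `evalue_column`.
#' @export
read_pin <- function(path, evalue_column = "log10_evalue") {
  if (is.character(path) && !file.exists(path)) {
    stop("pin file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty pin file", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(PIN_MANDATORY, header)
  if (length(missing) > 0) {
    stop("pin header missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!(evalue_column %in% header)) {
    stop(sprintf("pin header missing e-value column '%s'", evalue_column),
         call. = FALSE)
  }
  pep_idx <- match("Peptide", header)
  prot_idx <- match("Proteins", header)
  if (prot_idx != length(header) || prot_idx != pep_idx + 1L) {
    stop("Peptide and Proteins must be the final two pin columns",
         call. = FALSE)
  }
  feature_cols <- setdiff(header, PIN_MANDATORY)

  body <- lines[-1]
  default_direction <- NULL
  if (length(body) > 0 &&
      startsWith(body[1], "DefaultDirection")) {
    default_direction <- body[1]
    body <- body[-1]
  }

  ncol <- length(header)
  cells <- matrix(character(), nrow = length(body), ncol = ncol,
                  dimnames = list(NULL, header))
  records <- vector("list", length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < ncol) {
      stop(sprintf("pin line %d: %d fields, expected at least %d",
                   i + 1L + !is.null(default_direction), length(fields), ncol),
           call. = FALSE)
    }
    row <- fields[seq_len(ncol)]
    if (length(fields) > ncol) {
      row[ncol] <- paste(fields[prot_idx:length(fields)], collapse = "\t")
    }
    cells[i, ] <- row
    feats <- suppressWarnings(as.numeric(row[match(feature_cols, header)]))
    if (anyNA(feats)) {
      bad <- feature_cols[is.na(feats)][1]
      stop(sprintf("pin line %d: non-numeric value in feature column '%s'",
                   i + 1L + !is.null(default_direction), bad), call. = FALSE)
    }
    names(feats) <- feature_cols
    records[[i]] <- list(
      spec_id = row[1], label = as.integer(row[match("Label", header)]),
      scan_number = as.integer(row[match("ScanNr", header)]),
      evalue = 10^feats[[evalue_column]],
      features = feats,
      peptide = row[pep_idx],
      proteins = strsplit(row[ncol], "\t", fixed = TRUE)[[1]],
      retention_time = NA_real_, precursor_charge = NA_integer_
    )
  }
  structure(
    list(header = header, cells = cells, records = records,
         default_direction = default_direction,
         evalue_column = evalue_column,
         source_path = if (is.character(path)) path else NA_character_),
    class = "pin_table"
  )
}

#' @export
print.pin_table <- function(x, ...) {
  cat(sprintf("<pin_table> %d PSM(s), %d column(s)\n",
              length(x$records), length(x$header)))
  invisible(x)
}

#' Write a Percolator input file
#'
#' Unmodified tables round-trip byte-identically; columns added with
#' [add_pin_feature()] are written with fixed numeric formatting (up to 6
#' significant digits, never scientific notation).
#'
#' @param x A `pin_table`.
#' @param path Output path or connection.
#' @export
write_pin <- function(x, path) {
  stopifnot(inherits(x, "pin_table"))
  out <- paste(x$header, collapse = "\t")
  if (!is.null(x$default_direction)) out <- c(out, x$default_direction)
  if (nrow(x$cells) > 0) {
    out <- c(out, apply(x$cells, 1L, paste, collapse = "\t"))
  }
  writeLines(out, path)
  invisible(x)
}

format_pin_number <- function(v) {
  s <- vapply(v, function(x) {
    if (is.na(x)) return("NA")
    format(signif(x, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
  s
}

#' Insert a feature column into a pin table
#'
#' New rescoring features go immediately before the Peptide column, so
#' downstream tools that key on the trailing Peptide/Proteins columns keep
#' working.
#'
#' @param x A `pin_table`.
#' @param name Column name.
#' @param values Numeric vector, one value per PSM row.
#' @return The updated `pin_table`.
#' @export
add_pin_feature <- function(x, name, values) {
  stopifnot(inherits(x, "pin_table"), length(values) == length(x$records))
  if (name %in% x$header) stop("column already present: ", name, call. = FALSE)
  pep_idx <- match("Peptide", x$header)
  new_header <- append(x$header, name, after = pep_idx - 1L)
  txt <- format_pin_number(values)
  cells <- cbind(x$cells[, seq_len(pep_idx - 1L), drop = FALSE],
                 txt,
                 x$cells[, pep_idx:length(x$header), drop = FALSE])
  colnames(cells) <- new_header
  if (!is.null(x$default_direction)) {
    dd <- strsplit(x$default_direction, "\t", fixed = TRUE)[[1]]
    dd <- append(dd, "0", after = pep_idx - 1L)
    x$default_direction <- paste(dd, collapse = "\t")
  }
  for (i in seq_along(x$records)) {
    x$records[[i]]$features[[name]] <- values[i]
  }
  x$header <- new_header
  x$cells <- cells
  x
}

# Strip flanking residues ("K.PEPTIDE.R" -> "PEPTIDE") from a pin Peptide
# field; the inner part is a ProForma string in this toolchain.
pin_peptide_core <- function(peptide) {
  sub("^.?\\.(.*)\\..?$", "\\1", peptide)
}

#' Parse the peptidoform of a pin PSM record
#'
#' @param record A PSM record from a `pin_table`.
#' @return A [peptidoform()]; the precursor charge is attached when known.
#' @export
psm_peptidoform <- function(record) {
  p <- parse_proforma(pin_peptide_core(record$peptide))
  if (!is.na(record$precursor_charge) && is.null(p$charge)) {
    p$charge <- as.integer(record$precursor_charge)
  }
  p
}

#' Attach spectrum metadata to pin PSM records
#'
#' Copies retention time and precursor charge from the spectra (matched by
#' scan number) into the PSM records.
#'
#' @param x A `pin_table`.
#' @param spectra A list of spectra as returned by [read_mgf()].
#' @return The updated `pin_table`.
#' @export
attach_spectra <- function(x, spectra) {
  stopifnot(inherits(x, "pin_table"))
  scans <- vapply(spectra, function(s) s$scan_number, integer(1))
  for (i in seq_along(x$records)) {
    j <- match(x$records[[i]]$scan_number, scans)
    if (!is.na(j)) {
      x$records[[i]]$retention_time <- spectra[[j]]$retention_time
      x$records[[i]]$precursor_charge <- spectra[[j]]$precursor_charge
    }
  }
  x
}
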