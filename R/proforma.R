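#' Construct a peptidoform
#'
#' A peptidoform is a peptide sequence plus localized modifications and an
#' optional precursor charge. Modification positions follow the convention
#' 0 = N-terminus, 1..len = residues, len + 1 = C-terminus; at most one
#' modification may sit at any position.
#'
#' @param sequence Character scalar of canonical amino-acid letters.
#' @param mods Data frame with columns `position` (integer), `name`
#'   (character or NA), `accession` (character or NA), `delta` (Da) and
#'   `nterm_style` (logical; render as an N-terminal mod even though the
#'   delta is carried by residue 1, as for pyro-Glu).
#' @param charge Optional positive integer precursor charge.
#' @return An object of class `peptidoform`.
#' @export
peptidoform <- function(sequence, mods = empty_mods(), charge = NULL) {
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(residues, CANONICAL_RESIDUES)
  if (length(bad) > 0) {
    stop("non-canonical residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  if (length(residues) == 0) stop("empty peptide sequence", call. = FALSE)
  if (!is.data.frame(mods)) mods <- as.data.frame(mods,
                                                  stringsAsFactors = FALSE)
  if (nrow(mods) > 0) {
    n <- length(residues)
    if (any(mods$position < 0 | mods$position > n + 1)) {
      stop("modification position out of range 0..len+1", call. = FALSE)
    }
    if (anyDuplicated(mods$position)) {
      stop("at most one modification per position", call. = FALSE)
    }
    mods <- mods[order(mods$position), , drop = FALSE]
    rownames(mods) <- NULL
  }
  if (!is.null(charge)) {
    charge <- as.integer(charge)
    if (is.na(charge) || charge < 1) stop("charge must be a positive integer",
                                          call. = FALSE)
  }
  structure(
    list(residues = residues, mods = mods, charge = charge),
    class = "peptidoform"
  )
}

EMPTY_MODS <- data.frame(position = integer(), name = character(),
                         accession = character(), delta = numeric(),
                         nterm_style = logical(), stringsAsFactors = FALSE)

empty_mods <- function() EMPTY_MODS

#' @export
print.peptidoform <- function(x, ...) {
  cat("<peptidoform> ", render_proforma(x), "\n", sep = "")
  if (nrow(x$mods) > 0) {
    cat("  ", nrow(x$mods), " modification(s), total delta ",
        sprintf("%+.4f", sum(x$mods$delta)), " Da\n", sep = "")
  }
  invisible(x)
}

#' @export
length.peptidoform <- function(x) length(x$residues)

# ---------------------------------------------------------------------------
# Parsing

# Resolve a bracket payload ("U:Name", "UNIMOD:ID", or a signed mass) to a
# (name, accession, delta) triple. `at` is the character offset used in
# error messages.
resolve_mod_payload <- function(payload, at) {
  if (grepl("^U:", payload)) {
    hit <- mod_mass_by_name(substring(payload, 3))
    if (is.null(hit)) {
      stop(sprintf("unknown modification name '%s' at character %d",
                   payload, at), call. = FALSE)
    }
    list(name = hit$name, accession = hit$accession, delta = hit$mono_mass)
  } else if (grepl("^UNIMOD:[0-9]+$", payload, ignore.case = TRUE)) {
    hit <- mod_mass_by_accession(payload)
    if (is.null(hit)) {
      stop(sprintf("unknown modification accession '%s' at character %d",
                   payload, at), call. = FALSE)
    }
    list(name = hit$name, accession = hit$accession, delta = hit$mono_mass)
  } else if (grepl("^[+-][0-9]*\\.?[0-9]+$", payload)) {
    list(name = NA_character_, accession = NA_character_,
         delta = as.numeric(payload))
  } else {
    stop(sprintf("unparseable modification payload '%s' at character %d",
                 payload, at), call. = FALSE)
  }
}

is_pyro_glu <- function(name) {
  !is.na(name) && name %in% c("Gln->pyro-Glu", "Glu->pyro-Glu")
}

#' Parse a ProForma 2.0 peptidoform string
#'
#' Supports the practical subset used with peptide-property prediction
#' services: a bare sequence, an N-terminal modification written
#' `[...]-SEQ`, a C-terminal modification written `SEQ-[...]`, per-residue
#' modifications written `X[...]`, and an optional `/charge` suffix.
#' Bracket payloads may be `U:Name`, `UNIMOD:ID`, or a signed monoisotopic
#' mass delta such as `+79.9663`. Ranges, ambiguity groups, crosslinks and
#' the rest of the full grammar are rejected with an error.
#'
#' Pyro-Glu modifications parsed from the N-terminal position are stored as
#' a delta on residue 1 with an N-terminal rendering flag, so fragment
#' masses attribute the delta to the first residue.
#'
#' @param text ProForma string.
#' @return A [peptidoform()].
#' @examples
#' parse_proforma("EM[U:Oxidation]EVEES[+79.9663]PEK/2")
#' @export
parse_proforma <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    stop("text must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  charge <- NULL
  # optional /charge suffix
  slash <- regexpr("/", text, fixed = TRUE)
  if (slash > 0) {
    suffix <- substring(text, slash + 1)
    if (!grepl("^[0-9]+$", suffix)) {
      stop(sprintf("unparseable charge suffix at character %d",
                   as.integer(slash)), call. = FALSE)
    }
    charge <- as.integer(suffix)
    n <- slash - 1L
  }

  read_bracket <- function(i) {
    # chars[i] == "[" ; returns list(payload, next_index)
    j <- i + 1L
    depth <- 1L
    while (j <= n) {
      if (chars[j] == "[") depth <- depth + 1L
      if (chars[j] == "]") {
        depth <- depth - 1L
        if (depth == 0L) break
      }
      j <- j + 1L
    }
    if (j > n) stop(sprintf("unterminated '[' at character %d", i),
                    call. = FALSE)
    list(payload = substr(text, i + 1L, j - 1L), nxt = j + 1L)
  }

  seq_chars <- character()
  mods <- list()
  add_mod <- function(position, m, nterm_style = FALSE) {
    mods[[length(mods) + 1L]] <<- data.frame(
      position = as.integer(position), name = m$name,
      accession = m$accession, delta = m$delta,
      nterm_style = nterm_style, stringsAsFactors = FALSE)
  }

  nterm_pending <- NULL   # payload parsed before the sequence
  if (i <= n && chars[i] == "[") {
    br <- read_bracket(i)
    if (br$nxt > n || chars[br$nxt] != "-") {
      stop(sprintf("expected '-' after N-terminal modification at character %d",
                   br$nxt), call. = FALSE)
    }
    nterm_pending <- resolve_mod_payload(br$payload, i)
    i <- br$nxt + 1L
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "-") {
      # C-terminal mod: -[...]
      if (i + 1L > n || chars[i + 1L] != "[") {
        stop(sprintf("unexpected '-' at character %d", i), call. = FALSE)
      }
      br <- read_bracket(i + 1L)
      if (br$nxt <= n) {
        stop(sprintf("trailing characters after C-terminal modification at character %d",
                     br$nxt), call. = FALSE)
      }
      m <- resolve_mod_payload(br$payload, i + 1L)
      add_mod(length(seq_chars) + 1L + 1L, m)  # len+1 once sequence complete
      i <- br$nxt
    } else if (ch == "[") {
      if (length(seq_chars) == 0) {
        stop(sprintf("modification before any residue at character %d", i),
             call. = FALSE)
      }
      br <- read_bracket(i)
      m <- resolve_mod_payload(br$payload, i)
      add_mod(length(seq_chars), m)
      i <- br$nxt
    } else if (ch %in% CANONICAL_RESIDUES) {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    } else {
      stop(sprintf("unparseable character '%s' at character %d", ch, i),
           call. = FALSE)
    }
  }
  if (length(seq_chars) == 0) stop("no residues in peptide", call. = FALSE)

  if (!is.null(nterm_pending)) {
    if (is_pyro_glu(nterm_pending$name)) {
      # carried by residue 1, rendered N-terminally
      mods <- c(list(data.frame(
        position = 1L, name = nterm_pending$name,
        accession = nterm_pending$accession, delta = nterm_pending$delta,
        nterm_style = TRUE, stringsAsFactors = FALSE)), mods)
    } else {
      mods <- c(list(data.frame(
        position = 0L, name = nterm_pending$name,
        accession = nterm_pending$accession, delta = nterm_pending$delta,
        nterm_style = FALSE, stringsAsFactors = FALSE)), mods)
    }
  }
  mods_df <- if (length(mods) > 0) do.call(rbind, mods) else empty_mods()
  # fix up C-terminal position recorded before sequence length was known
  cterm <- mods_df$position > length(seq_chars)
  mods_df$position[cterm] <- length(seq_chars) + 1L

  peptidoform(paste(seq_chars, collapse = ""), mods_df, charge)
}

render_mod_payload <- function(name, delta) {
  if (!is.na(name)) {
    paste0("[U:", name, "]")
  } else {
    # trim trailing zeros but keep at least one decimal place
    s <- sprintf("%+.6f", delta)
    s <- sub("0+$", "", s)
    s <- sub("\\.$", ".0", s)
    paste0("[", s, "]")
  }
}

#' Render a peptidoform as a canonical ProForma 2.0 string
#'
#' Inverse of [parse_proforma()]: `parse_proforma(render_proforma(p))`
#' reproduces `p` for every supported peptidoform.
#'
#' @param p A [peptidoform()].
#' @return Character scalar.
#' @export
render_proforma <- function(p) {
  stopifnot(inherits(p, "peptidoform"))
  n <- length(p$residues)
  pieces <- p$residues
  prefix <- ""
  suffix <- ""
  if (nrow(p$mods) > 0) {
    for (k in seq_len(nrow(p$mods))) {
      m <- p$mods[k, ]
      payload <- render_mod_payload(m$name, m$delta)
      if (m$position == 0 || isTRUE(m$nterm_style)) {
        prefix <- paste0(payload, "-")
      } else if (m$position == n + 1) {
        suffix <- paste0("-", payload)
      } else {
        pieces[m$position] <- paste0(pieces[m$position], payload)
      }
    }
  }
  out <- paste0(prefix, paste(pieces, collapse = ""), suffix)
  if (!is.null(p$charge)) out <- paste0(out, "/", p$charge)
  out
}
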