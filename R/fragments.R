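# Theoretical fragment and precursor masses for b/y ion series.
#
# Position bookkeeping matches the peptidoform convention: a b_k fragment
# covers the N-terminus (position 0) and residues 1..k; a y_k fragment
# covers residues (len-k+1)..len and the C-terminus (position len+1).

#' Monoisotopic fragment m/z of a b or y ion
#'
#' @param p A [peptidoform()].
#' @param series `"b"` or `"y"`.
#' @param ordinal Fragment ordinal, 1..len-1.
#' @param frag_charge Fragment charge, >= 1.
#' @return m/z in Thomson.
#' @examples
#' fragment_mz(parse_proforma("PEPTIDEK"), "y", 1, 1)  # 147.1128
#' @export
fragment_mz <- function(p, series = c("b", "y"), ordinal, frag_charge = 1L) {
  stopifnot(inherits(p, "peptidoform"))
  series <- match.arg(series)
  n <- length(p$residues)
  ordinal <- as.integer(ordinal)
  if (ordinal < 1L || ordinal > n - 1L) {
    stop(sprintf("ordinal %d out of range 1..%d", ordinal, n - 1L),
         call. = FALSE)
  }
  frag_charge <- as.integer(frag_charge)
  stopifnot(frag_charge >= 1L)
  if (series == "b") {
    span <- seq_len(ordinal)
    mod_positions <- 0:ordinal
    base <- 0
  } else {
    span <- (n - ordinal + 1L):n
    mod_positions <- (n - ordinal + 1L):(n + 1L)
    base <- WATER_MASS
  }
  neutral <- sum(RESIDUE_MASSES[p$residues[span]]) + base
  if (nrow(p$mods) > 0) {
    neutral <- neutral + sum(p$mods$delta[p$mods$position %in% mod_positions])
  }
  (neutral + frag_charge * PROTON_MASS) / frag_charge
}

#' Precursor m/z of a peptidoform
#'
#' @param p A [peptidoform()].
#' @param charge Precursor charge; defaults to the peptidoform's own.
#' @return m/z in Thomson.
#' @export
precursor_mz <- function(p, charge = p$charge) {
  stopifnot(inherits(p, "peptidoform"))
  if (is.null(charge)) stop("no charge available", call. = FALSE)
  neutral <- sum(RESIDUE_MASSES[p$residues]) + WATER_MASS + sum(p$mods$delta)
  (neutral + charge * PROTON_MASS) / charge
}

# Full singly-charged b/y fragment table for a peptidoform; used by the
# synthetic backend and the library writer. Returns a data.frame
# (series, ordinal, charge, mz) ordered b1..b(n-1), y1..y(n-1).
fragment_table <- function(p, frag_charge = 1L) {
  n <- length(p$residues)
  ords <- seq_len(n - 1L)
  # vectorized cumulative sums, modifications folded in by position
  res_mass <- unname(RESIDUE_MASSES[p$residues])
  mod_on_res <- numeric(n)
  nterm_delta <- 0
  cterm_delta <- 0
  if (nrow(p$mods) > 0) {
    for (k in seq_len(nrow(p$mods))) {
      pos <- p$mods$position[k]
      if (pos == 0) nterm_delta <- nterm_delta + p$mods$delta[k]
      else if (pos == n + 1L) cterm_delta <- cterm_delta + p$mods$delta[k]
      else mod_on_res[pos] <- mod_on_res[pos] + p$mods$delta[k]
    }
  }
  fwd <- cumsum(res_mass + mod_on_res)
  b_neutral <- fwd[ords] + nterm_delta
  rev_mass <- rev(res_mass + mod_on_res)
  bwd <- cumsum(rev_mass)
  y_neutral <- bwd[ords] + WATER_MASS + cterm_delta
  z <- as.integer(frag_charge)
  nf <- 2L * length(ords)
  # bare-bones data.frame construction; this sits on the hot path of the
  # synthetic backend
  structure(
    list(series = rep(c("b", "y"), each = length(ords)),
         ordinal = rep(ords, 2L),
         charge = rep(z, nf),
         mz = (c(b_neutral, y_neutral) + z * PROTON_MASS) / z),
    class = "data.frame", row.names = c(NA_integer_, -nf))
}
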