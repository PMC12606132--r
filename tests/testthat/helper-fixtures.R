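# Shared fixtures: random peptidoform generator, independent mass oracle,
# small pin fixtures built in code.

# Independent monoisotopic residue masses (typed in separately from the
# package's table; same physical constants, used as the oracle).
ORACLE_RESIDUES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
ORACLE_PROTON <- 1.007276
ORACLE_WATER <- 18.010565

# Brute-force fragment m/z: explicit residue-by-residue summation,
# independent of the package's cumulative-sum implementation.
oracle_fragment_mz <- function(seq_str, mods, series, ordinal, z) {
  res <- strsplit(seq_str, "")[[1]]
  n <- length(res)
  if (series == "b") {
    positions <- 0:ordinal
    span <- seq_len(ordinal)
    mass <- 0
  } else {
    positions <- (n - ordinal + 1):(n + 1)
    span <- (n - ordinal + 1):n
    mass <- ORACLE_WATER
  }
  for (r in res[span]) mass <- mass + ORACLE_RESIDUES[[r]]
  if (nrow(mods) > 0) {
    for (k in seq_len(nrow(mods))) {
      if (mods$position[k] %in% positions) mass <- mass + mods$delta[k]
    }
  }
  (mass + z * ORACLE_PROTON) / z
}

# Random peptidoform: random length/sequence, 0-2 modifications drawn from
# the bundled table (named) or a random numeric delta, optional charge.
random_peptidoform <- function(min_len = 6, max_len = 20,
                               p_charge = 0.5) {
  tab <- modification_table()
  len <- sample(min_len:max_len, 1)
  seq_str <- paste(sample(names(ORACLE_RESIDUES), len, replace = TRUE),
                   collapse = "")
  n_mods <- sample(0:2, 1)
  positions <- sample(0:(len + 1), n_mods)
  rows <- lapply(positions, function(pos) {
    if (runif(1) < 0.7) {
      k <- sample(nrow(tab), 1)
      # pyro-Glu is only representable N-terminally; keep it off random
      # interior positions
      while (grepl("pyro", tab$name[k])) k <- sample(nrow(tab), 1)
      data.frame(position = pos, name = tab$name[k],
                 accession = tab$accession[k], delta = tab$mono_mass[k],
                 nterm_style = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(position = pos, name = NA_character_,
                 accession = NA_character_,
                 delta = round(runif(1, -50, 250), 4),
                 nterm_style = FALSE, stringsAsFactors = FALSE)
    }
  })
  mods <- if (n_mods > 0) do.call(rbind, rows) else NULL
  charge <- if (runif(1) < p_charge) sample(1:4, 1) else NULL
  if (is.null(mods)) peptidoform(seq_str, charge = charge)
  else peptidoform(seq_str, mods, charge = charge)
}

peptidoforms_equal <- function(a, b) {
  identical(a$residues, b$residues) &&
    identical(is.null(a$charge), is.null(b$charge)) &&
    (is.null(a$charge) || a$charge == b$charge) &&
    nrow(a$mods) == nrow(b$mods) &&
    (nrow(a$mods) == 0 ||
       (all(a$mods$position == b$mods$position) &&
          all(abs(a$mods$delta - b$mods$delta) < 1e-6)))
}

# Small pin fixture written to a temp file; returns the path.
write_pin_fixture <- function(n = 3, seed = 11) {
  lines <- withr::with_seed(seed, {
    header <- paste(c("SpecId", "Label", "ScanNr", "score", "log10_evalue",
                      "Peptide", "Proteins"), collapse = "\t")
    rows <- sprintf("run.%d.%d.2\t%d\t%d\t%.4f\t%.4f\t-.%s.-\tsp|P%05d|HUMAN",
                    1:n, 1:n, rep(c(1L, -1L), length.out = n), 1:n,
                    runif(n, 10, 40), runif(n, -6, 1),
                    replicate(n, paste(sample(names(ORACLE_RESIDUES), 8,
                                              replace = TRUE),
                                       collapse = "")),
                    1:n)
    c(header, rows)
  })
  path <- withr::local_tempfile(fileext = ".pin",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Direct evaluation of the entropy similarity formula, written as a
# straight transcription (the oracle for the optimized implementation).
oracle_entropy_similarity <- function(p, q) {
  if (sum(q) == 0) return(0)
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  H <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
  1 - (2 * H(m) - H(p) - H(q)) / log(4)
}

# Tiny synthetic world used by most integration tests (cheap but with all
# default structure).
tiny_world <- function(seed = 101, ...) synthetic_world(seed = seed, ...)
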