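# Monoisotopic mass constants. Residue masses are the standard amino-acid
# monoisotopic residue (i.e. dehydrated) masses; PROTON is the mass of H+.

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

CANONICAL_RESIDUES <- names(RESIDUE_MASSES)

# Modification table bundled with the package: name, UNIMOD accession,
# monoisotopic mass delta. Loaded once per session.
.mod_table_env <- new.env(parent = emptyenv())

#' Bundled modification mass table
#'
#' Returns the table of post-translational modifications the ProForma parser
#' resolves by name or UNIMOD accession: oxidation, carbamidomethylation,
#' acetylation, phosphorylation, pyro-Glu formation from Gln/Glu, and the
#' TMT 11-plex label.
#'
#' @return A data.frame with columns `name`, `accession` and `mono_mass` (Da).
#' @export
modification_table <- function() {
  if (is.null(.mod_table_env$table)) {
    path <- system.file("extdata", "modifications.tsv", package = "pinboost")
    if (!nzchar(path)) {
      path <- file.path("inst", "extdata", "modifications.tsv")
    }
    .mod_table_env$table <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .mod_table_env$table
}

mod_mass_by_name <- function(name) {
  tab <- modification_table()
  i <- match(tolower(name), tolower(tab$name))
  if (is.na(i)) NULL else tab[i, , drop = FALSE]
}

mod_mass_by_accession <- function(accession) {
  tab <- modification_table()
  i <- match(toupper(accession), toupper(tab$accession))
  if (is.na(i)) NULL else tab[i, , drop = FALSE]
}
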