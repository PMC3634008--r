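#' contactcascade: cascaded neural-network contact map prediction
#'
#' Tools for predicting protein residue-residue contact maps with a
#' two-level cascade of feed-forward neural networks: contact-map
#' extraction from PDB chains, a staged 1747-element residue-pair
#' encoding built from multiple sequence alignments, six length-routed
#' sub-networks combined by a cascade network, balanced training,
#' coverage-knee threshold optimization, and the accuracy/coverage
#' evaluation protocol.
#'
#' @keywords internal
"_PACKAGE"

## The 20 standard amino acids, one-letter codes in alphabetical order.
## All residue -> integer conversions in the package use this ordering.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Run code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`
#' and restores the previous state on exit, so seeded package functions
#' never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## integer codes 1..20 for a character vector of one-letter residues;
## NA for gaps and non-standard letters (B, Z, X, U, O, ...).
aa_code <- function(x) {
  m <- match(toupper(x), AA_LETTERS)
  m
}

stop2 <- function(...) stop(..., call. = FALSE)
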