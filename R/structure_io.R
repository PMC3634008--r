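## Structure input: PDB chains -> curated chain records -> contact maps.

#' Parse a single protein chain from PDB-format text
#'
#' Reads the ATOM records of one chain and reduces every residue to a
#' single representative coordinate: the C-beta atom, or C-alpha for
#' glycine (which has no side chain beyond a hydrogen). HETATM records
#' are ignored. For alternate locations the first occurring altloc is
#' kept; residues are ordered by file appearance (insertion codes
#' included).
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format
#'   lines (anything containing a newline or more than one element is
#'   treated as text).
#' @param chain_id one-letter chain identifier.
#' @param strict logical; if `TRUE`, a non-glycine residue lacking a
#'   C-beta atom is an error. The default falls back to C-alpha with a
#'   warning so structurally imperfect chains can still be predicted.
#' @return an object of class `chain_record`: a list with elements
#'   `chain_id`, `sequence` (one-letter string; non-standard residues
#'   appear as `X`), `coords` (N x 3 matrix of representative-atom
#'   coordinates in Angstrom), `representative_atom` (per-residue `"CB"`
#'   or `"CA"`), `experiment_method`, `resolution`,
#'   `backbone_complete` (every residue has N, CA and C atoms) and
#'   `has_nonstandard_residues`.
#' @export
#' @examples
#' chain <- synth_chain(60, seed = 1)
#' rec <- parse_structure(chain$pdb_text, "A")
#' nchar(rec$sequence)
parse_structure <- function(pdb, chain_id, strict = FALSE) {
  txt <- as_pdb_lines(pdb)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  p <- suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE))
  at <- p$atom
  at <- at[at$type == "ATOM" & !is.na(at$chain) & at$chain == chain_id, ,
           drop = FALSE]
  if (nrow(at) == 0L) stop2("chain not found: '", chain_id, "'")

  ## residue key preserves file order; insertion codes distinguish residues
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  keys <- unique(key)
  n <- length(keys)

  seq_letters <- character(n)
  rep_atom <- character(n)
  coords <- matrix(NA_real_, n, 3)
  backbone_ok <- TRUE
  nonstd <- FALSE

  for (r in seq_len(n)) {
    sub <- at[key == keys[r], , drop = FALSE]
    sub <- sub[!duplicated(sub$elety), , drop = FALSE]  # first altloc wins
    res3 <- sub$resid[1L]
    one <- AA_THREE[res3]
    if (is.na(one)) { one <- "X"; nonstd <- TRUE }
    seq_letters[r] <- one
    if (!all(c("N", "CA", "C") %in% sub$elety)) backbone_ok <- FALSE

    cb <- match("CB", sub$elety)
    ca <- match("CA", sub$elety)
    if (res3 == "GLY") {
      if (is.na(ca))
        stop2("unusable residue at index ", r, ": glycine without CA")
      use <- ca; rep_atom[r] <- "CA"
    } else if (!is.na(cb)) {
      use <- cb; rep_atom[r] <- "CB"
    } else {
      if (strict)
        stop2("unusable residue at index ", r, ": non-glycine without CB")
      if (is.na(ca))
        stop2("unusable residue at index ", r, ": no CB or CA atom")
      warning("residue ", r, " (", res3, ") lacks CB; using CA",
              call. = FALSE)
      use <- ca; rep_atom[r] <- "CA"
    }
    coords[r, ] <- c(sub$x[use], sub$y[use], sub$z[use])
  }

  structure(list(
    chain_id = chain_id,
    sequence = paste(seq_letters, collapse = ""),
    coords = coords,
    representative_atom = rep_atom,
    experiment_method = pdb_method(txt),
    resolution = pdb_resolution(txt),
    backbone_complete = backbone_ok,
    has_nonstandard_residues = nonstd
  ), class = "chain_record")
}

as_pdb_lines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb, fixed = TRUE) &&
      file.exists(pdb)) {
    readLines(pdb)
  } else {
    unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
}

pdb_method <- function(lines) {
  m <- grep("^EXPDTA", lines, value = TRUE)
  if (length(m) == 0L) return(NA_character_)
  trimws(substring(m[1L], 11L))
}

pdb_resolution <- function(lines) {
  m <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(m) == 0L) return(NA_real_)
  s <- substring(m[1L], 23L)
  v <- regmatches(s, regexpr("[0-9]+\\.?[0-9]*", s))
  if (length(v) == 0L) return(NA_real_)
  as.numeric(v)
}

#' @export
print.chain_record <- function(x, ...) {
  cat("chain_record: chain", x$chain_id, "-", nchar(x$sequence), "residues\n")
  cat("  method:", x$experiment_method, " resolution:", x$resolution, "A\n")
  invisible(x)
}

#' @export
length.chain_record <- function(x) nchar(x$sequence)

#' Chain curation settings
#'
#' Filters applied to candidate chains before training/testing: X-ray
#' structures only, resolution at most 1.5 Angstrom, complete backbone,
#' standard residues only, and length between 51 and 450 residues.
#'
#' @param max_resolution maximum crystallographic resolution in
#'   Angstrom (`Inf` disables; chains without a recorded resolution
#'   fail this filter when enabled).
#' @param allowed_method substring the experiment method must contain,
#'   case-insensitively (`NULL` disables).
#' @param min_length,max_length inclusive residue-count bounds.
#' @param require_backbone drop chains with missing N/CA/C atoms.
#' @param require_standard_residues drop chains containing residues
#'   outside the 20 standard amino acids.
#' @return a `curation_config` list.
#' @export
curation_config <- function(max_resolution = 1.5,
                            allowed_method = "X-RAY",
                            min_length = 51L,
                            max_length = 450L,
                            require_backbone = TRUE,
                            require_standard_residues = TRUE) {
  stopifnot(max_resolution > 0, min_length <= max_length)
  structure(list(max_resolution = max_resolution,
                 allowed_method = allowed_method,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 require_backbone = isTRUE(require_backbone),
                 require_standard_residues = isTRUE(require_standard_residues)),
            class = "curation_config")
}

#' Apply curation filters to a list of chains
#'
#' Retains exactly the chains passing every enabled filter, preserving
#' order. An empty result is legal. The operation is idempotent.
#'
#' @param chains list of [parse_structure()] `chain_record`s.
#' @param config a [curation_config()].
#' @return the filtered list.
#' @export
filter_chains <- function(chains, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  keep <- vapply(chains, function(ch) {
    n <- nchar(ch$sequence)
    if (n < config$min_length || n > config$max_length) return(FALSE)
    if (!is.null(config$allowed_method)) {
      if (is.na(ch$experiment_method) ||
          !grepl(toupper(config$allowed_method), toupper(ch$experiment_method),
                 fixed = TRUE)) return(FALSE)
    }
    if (is.finite(config$max_resolution)) {
      if (is.na(ch$resolution) || ch$resolution > config$max_resolution)
        return(FALSE)
    }
    if (config$require_backbone && !isTRUE(ch$backbone_complete)) return(FALSE)
    if (config$require_standard_residues &&
        isTRUE(ch$has_nonstandard_residues)) return(FALSE)
    TRUE
  }, logical(1L))
  chains[keep]
}

#' Compute the binary contact map of a chain
#'
#' Two residues are in contact when the Euclidean distance between
#' their representative atoms (C-beta; C-alpha for glycine) is strictly
#' less than `cutoff`. The 8 Angstrom default is the standard
#' threshold in the contact-prediction literature. The map is an
#' N x N binary symmetric matrix; the diagonal is 1 since the
#' self-distance 0 is below any positive cutoff.
#'
#' @param chain a `chain_record`.
#' @param cutoff distance cutoff in Angstrom (default 8.0).
#' @return an object of class `contact_map`: list with `length`,
#'   `cells` (N x N 0/1 integer matrix) and `cutoff`.
#' @export
#' @examples
#' ch <- synth_chain(60, seed = 1)$chain
#' cm <- contact_map(ch)
#' sum(cm$cells) # total contacts (incl. diagonal, both triangles)
contact_map <- function(chain, cutoff = 8.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop2("invalid cutoff")
  xyz <- chain$coords
  stopifnot(!anyNA(xyz))
  d <- as.matrix(stats::dist(xyz))
  cells <- matrix(as.integer(d < cutoff), nrow(xyz), nrow(xyz))
  structure(list(length = nrow(xyz), cells = cells, cutoff = cutoff),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  up <- x$cells[upper.tri(x$cells)]
  cat("contact_map:", x$length, "residues, cutoff", x$cutoff, "A,",
      sum(up), "contacts (i<j)\n")
  invisible(x)
}

#' Residue pairs at or above a minimum sequence separation
#'
#' Returns all residue index pairs (i, j), i < j, with j - i >= s.
#' Both training labels and evaluation are restricted to these pairs:
#' short-range pairs contact trivially and are excluded.
#'
#' @param x a `contact_map` or a single integer chain length N.
#' @param s minimum sequence separation (>= 0).
#' @return an integer matrix with columns `i` and `j` (1-based).
#' @export
#' @examples
#' separation_mask(10L, 6L)
separation_mask <- function(x, s) {
  n <- if (inherits(x, "contact_map")) x$length else as.integer(x)
  if (!is.numeric(s) || length(s) != 1L || s < 0) stop2("invalid separation")
  s <- as.integer(s)
  ss <- max(s, 1L)  # pairs require i < j even at s = 0
  if (n < 2L || ss >= n) {
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  }
  counts <- (n - ss):1L                      # pairs per i, i = 1..n-ss
  i <- rep.int(seq_len(n - ss), counts)
  j <- i + ss - 1L + sequence(counts)
  cbind(i = i, j = j)
}

#' Write a contact map to disk
#'
#' `format = "pairs"` writes one `i<TAB>j` line (1-based, i < j) per
#' contact; `format = "matrix"` writes the full square 0/1 matrix as
#' tab-separated rows.
#'
#' @param map a `contact_map`.
#' @param file output path.
#' @param format `"pairs"` or `"matrix"`.
#' @param min_separation only pairs with j - i at least this value are
#'   written in pairs format (default 1: all off-diagonal contacts).
#' @return the file path, invisibly.
#' @export
write_contact_map <- function(map, file, format = c("pairs", "matrix"),
                              min_separation = 1L) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(map$cells, file, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(map$cells) & map$cells == 1L, arr.ind = TRUE)
    idx <- idx[idx[, 2L] - idx[, 1L] >= min_separation, , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    utils::write.table(idx, file, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(file)
}

#' Read a tab-separated contact pair list
#'
#' @param file path to a file of `i<TAB>j` lines (1-based).
#' @return integer matrix with columns `i`, `j`.
#' @export
read_contact_pairs <- function(file) {
  if (file.size(file) == 0L)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  m <- as.matrix(utils::read.table(file, sep = "\t",
                                   col.names = c("i", "j")))
  storage.mode(m) <- "integer"
  m
}
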