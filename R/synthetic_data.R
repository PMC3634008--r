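## Synthetic fixtures: compact self-avoiding chains with realistic
## consecutive-residue spacing, mutated-copy alignments, and labelled
## pair datasets whose contact density falls off as ~1/N, emulating
## the thin-density problem of real contact maps.

## hydrophobic residues (the set driven toward the core)
HYDROPHOBIC_AA <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' Generate a compact synthetic protein chain
#'
#' Grows a self-avoiding 3D walk with consecutive representative-atom
#' spacing 3.8 +/- 0.1 Angstrom and minimum non-consecutive spacing
#' 3.0 Angstrom, confined to a sphere of radius ~3.2 N^(1/3) so that
#' 8 Angstrom contacts occur in realistic, length-proportional
#' numbers. The sequence is assigned after the walk with a
#' hydrophobic-core bias: a residue's probability of being
#' hydrophobic (A, C, F, I, L, M, V, W, Y) falls linearly from 0.9
#' for the most buried position to 0.1 for the most exposed, so
#' contacting (mostly buried) residue pairs are enriched in
#' hydrophobic pairs — the basic sequence-structure correlation of
#' globular proteins, and the signal that makes the alignment-derived
#' pair features informative on synthetic data. The chain is emitted
#' both as a `chain_record` and as PDB text (chain A, full N/CA/C
#' backbone plus CB for non-glycines) that round-trips through
#' [parse_structure()].
#'
#' @param n chain length (>= 2).
#' @param seed integer seed; the same seed reproduces the chain
#'   exactly.
#' @return list with elements `chain` (a `chain_record`) and
#'   `pdb_text` (character vector of PDB lines).
#' @export
synth_chain <- function(n, seed = 1L) {
  stopifnot(n >= 2L)
  radius <- 3.2 * n^(1 / 3)
  coords <- with_seed(seed, {
    for (attempt in 1:25) {
      xyz <- matrix(NA_real_, n, 3L)
      xyz[1L, ] <- 0
      ok <- TRUE
      for (t in 2:n) {
        placed <- FALSE
        for (try in 1:60) {
          dir <- stats::rnorm(3L)
          prev <- xyz[t - 1L, ]
          if (sqrt(sum(prev^2)) > radius)
            dir <- dir - 1.5 * prev / sqrt(sum(prev^2))
          dir <- dir / sqrt(sum(dir^2))
          step <- 3.8 + stats::runif(1L, -0.1, 0.1)
          cand <- prev + step * dir
          if (t > 2L) {
            d2 <- rowSums(sweep(xyz[seq_len(t - 2L), , drop = FALSE],
                                2L, cand)^2)
            if (min(d2) < 9.0) next  # clashes a non-consecutive residue
          }
          xyz[t, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop2("packing failed: could not place chain of length ", n)
    xyz
  })
  sequence <- with_seed(seed + 500000L, {
    ## burial rank in [0,1]: 0 = most buried, 1 = most exposed
    d <- sqrt(rowSums(sweep(coords, 2L, colMeans(coords))^2))
    expo <- (rank(d, ties.method = "first") - 1) / max(n - 1L, 1L)
    p_hydro <- 0.9 - 0.8 * expo
    polar <- setdiff(AA_LETTERS, HYDROPHOBIC_AA)
    letters1 <- vapply(seq_len(n), function(r) {
      if (stats::runif(1L) < p_hydro[r]) sample(HYDROPHOBIC_AA, 1L)
      else sample(polar, 1L)
    }, character(1L))
    paste(letters1, collapse = "")
  })
  pdb_text <- chain_to_pdb(sequence, coords)
  letters1 <- strsplit(sequence, "")[[1L]]
  chain <- structure(list(
    chain_id = "A",
    sequence = sequence,
    coords = round(coords, 3L),  # matches PDB format precision
    representative_atom = ifelse(letters1 == "G", "CA", "CB"),
    experiment_method = "X-RAY DIFFRACTION",
    resolution = 1.2,
    backbone_complete = TRUE,
    has_nonstandard_residues = FALSE
  ), class = "chain_record")
  list(chain = chain, pdb_text = pdb_text)
}

AA_ONE_TO_THREE <- local({
  x <- names(AA_THREE)
  names(x) <- unname(AA_THREE)
  x
})

## representative coordinate -> minimal ATOM records (N, CA, C, CB)
chain_to_pdb <- function(sequence, coords) {
  letters1 <- strsplit(sequence, "")[[1L]]
  lines <- c("HEADER    SYNTHETIC CHAIN",
             "EXPDTA    X-RAY DIFFRACTION",
             "REMARK   2 RESOLUTION.    1.20 ANGSTROMS.")
  serial <- 0L
  atom_line <- function(name, res3, resno, p, elem) {
    serial <<- serial + 1L
    ## strict PDB columns: name 13-16, altLoc 17, resName 18-20,
    ## chain 22, resSeq 23-26, x/y/z 31-54, occ/B 55-66, element 77-78
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, sprintf(" %-3s", name), res3, "A", resno,
            p[1L], p[2L], p[3L], 1.0, 0.0, elem)
  }
  for (r in seq_along(letters1)) {
    res3 <- AA_ONE_TO_THREE[letters1[r]]
    p <- coords[r, ]
    if (letters1[r] == "G") {
      ca <- p                      # glycine: CA is the representative
    } else {
      ca <- p + c(0, 1.5, 0)
    }
    lines <- c(lines,
               atom_line("N", res3, r, ca + c(-1.2, 0, 0), "N"),
               atom_line("CA", res3, r, ca, "C"),
               atom_line("C", res3, r, ca + c(1.2, 0, 0), "C"))
    if (letters1[r] != "G")
      lines <- c(lines, atom_line("CB", res3, r, p, "C"))
  }
  c(lines, "END")
}

#' Generate a synthetic multiple sequence alignment
#'
#' The target sequence plus `n_rows - 1` mutated copies: each position
#' is substituted independently with probability `mutation_rate`,
#' uniformly over the 19 other standard residues, so the expected
#' identity of a row to the target is `1 - mutation_rate`. A uniform
#' substitution model is enough to exercise frequency counting; it
#' makes no claim of biological realism.
#'
#' @param sequence target sequence (one-letter string).
#' @param n_rows total rows including the target (>= 1).
#' @param mutation_rate per-position substitution probability.
#' @param seed integer seed.
#' @return an [msa_alignment()] (conservation computed on demand,
#'   secondary structure unknown).
#' @export
synth_msa <- function(sequence, n_rows, mutation_rate = 0.25, seed = 1L) {
  stopifnot(n_rows >= 1L, mutation_rate >= 0, mutation_rate <= 1)
  codes <- aa_code(strsplit(toupper(sequence), "")[[1L]])
  stopifnot(!anyNA(codes))
  n <- length(codes)
  rows <- with_seed(seed, {
    out <- character(n_rows)
    out[1L] <- toupper(sequence)
    for (r in seq_len(n_rows - 1L) + 1L) {
      mut <- stats::runif(n) < mutation_rate
      cc <- codes
      if (any(mut)) {
        shift <- sample.int(19L, sum(mut), replace = TRUE)
        cc[mut] <- ((cc[mut] - 1L + shift) %% 20L) + 1L
      }
      out[r] <- paste(AA_LETTERS[cc], collapse = "")
    }
    out
  })
  msa_alignment(rows)
}

#' Specification of a synthetic benchmark set
#'
#' @param lengths integer vector of chain lengths, each in 51..450.
#' @param msa_rows alignment rows per protein (<= 100).
#' @param mutation_rate per-position substitution probability of the
#'   mutated alignment rows.
#' @param seed master seed; per-protein seeds are derived from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(lengths, msa_rows = 20L, mutation_rate = 0.25,
                           seed = 1L) {
  lengths <- as.integer(lengths)
  stopifnot(all(lengths >= 51L & lengths <= 450L), msa_rows >= 1L,
            msa_rows <= 100L, mutation_rate >= 0, mutation_rate <= 1)
  structure(list(lengths = lengths, msa_rows = as.integer(msa_rows),
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a full synthetic protein set
#'
#' One (chain, alignment, contact map) triple per requested length.
#' Contact maps come from the chain geometry, so across the set the
#' contact count at separation >= 6 grows roughly linearly with N
#' while possible pairs grow with N^2: the empirical contact density
#' decreases with length, mirroring real proteins.
#'
#' @param spec a [synthetic_spec()].
#' @return list of proteins, each a list with `chain`, `pdb_text`,
#'   `aln`, `features` (precomputed [alignment_features()]) and `map`.
#' @export
synth_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lapply(seq_along(spec$lengths), function(idx) {
    n <- spec$lengths[idx]
    sd_i <- spec$seed + 1000L * idx
    sc <- synth_chain(n, seed = sd_i)
    aln <- synth_msa(sc$chain$sequence, spec$msa_rows,
                     spec$mutation_rate, seed = sd_i + 1L)
    list(chain = sc$chain, pdb_text = sc$pdb_text, aln = aln,
         features = alignment_features(aln),
         map = contact_map(sc$chain))
  })
}

#' Write a synthetic set as a fixture directory
#'
#' Emits `prot_###.pdb`, `prot_###.fa` (FASTA MSA) and
#' `prot_###.contacts.tsv` (1-based `i<TAB>j` truth pairs) per
#' protein, plus `manifest.json` recording the generating spec.
#'
#' @param dataset a [synth_dataset()] result.
#' @param dir output directory (created).
#' @param spec the generating [synthetic_spec()], stored in the
#'   manifest.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(dataset, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (idx in seq_along(dataset)) {
    p <- dataset[[idx]]
    stem <- sprintf("prot_%03d", idx)
    writeLines(p$pdb_text, file.path(dir, paste0(stem, ".pdb")))
    fa <- character(0)
    for (r in seq_along(p$aln$rows))
      fa <- c(fa, paste0(">", stem, if (r == 1L) "" else paste0("_h", r)),
              p$aln$rows[r])
    writeLines(fa, file.path(dir, paste0(stem, ".fa")))
    write_contact_map(p$map, file.path(dir, paste0(stem, ".contacts.tsv")))
  }
  manifest <- list(format = "fixture-dir-1",
                   n_proteins = length(dataset),
                   spec = if (is.null(spec)) NULL else unclass(spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory back into a dataset
#'
#' @param dir a directory written by [write_fixture_dir()].
#' @return list of proteins as in [synth_dataset()] (without
#'   `pdb_text`).
#' @export
read_fixture_dir <- function(dir) {
  pdbs <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (length(pdbs) == 0L) stop2("no proteins in ", dir)
  lapply(pdbs, function(pf) {
    stem <- sub("\\.pdb$", "", basename(pf))
    chain <- parse_structure(pf, "A")
    aln <- read_alignment(file.path(dir, paste0(stem, ".fa")))
    list(chain = chain, aln = aln,
         features = alignment_features(aln),
         map = contact_map(chain))
  })
}

#' Linearly separable encoded dataset
#'
#' A sanity fixture for network training: 1747-wide vectors whose
#' label is determined by whether coordinate 1 exceeds coordinate 2
#' (with a small noise margin); the remaining coordinates are
#' low-amplitude uniform noise. Labels are exactly balanced by
#' construction. A 1747-5-1 network reaches >= 95% training accuracy
#' on it.
#'
#' @param n_samples sample count (>= 4).
#' @param seed integer seed.
#' @return list with `x` (n x 1747 matrix) and `y` (0/1 labels).
#' @export
separable_dataset <- function(n_samples, seed = 1L) {
  stopifnot(n_samples >= 4L)
  with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n_samples)
    x <- matrix(stats::runif(n_samples * 1747L, 0, 0.1),
                n_samples, 1747L)
    hi <- stats::runif(n_samples, 0.55, 1.0)
    lo <- stats::runif(n_samples, 0.0, 0.45)
    x[, 1L] <- ifelse(y == 1L, hi, lo)
    x[, 2L] <- ifelse(y == 1L, lo, hi)
    list(x = x, y = y)
  })
}
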