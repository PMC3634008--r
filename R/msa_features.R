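## Alignment input and the per-position / per-pair statistics the
## residue-pair encoder consumes.

#' Construct a multiple-alignment object
#'
#' @param rows character vector of aligned sequences (equal widths,
#'   gaps as `-`); the first row is the target/master sequence.
#' @param conservation optional numeric vector (one value per column,
#'   in \[0, 1\]) of annotated conservation weights.
#' @param ss optional character vector of per-column secondary
#'   structure states in `H`, `E`, `C` (`NA` = unknown).
#' @return an object of class `msa_alignment`.
#' @export
msa_alignment <- function(rows, conservation = NULL, ss = NULL) {
  rows <- toupper(as.character(rows))
  if (length(rows) == 0L) stop2("no sequences")
  w <- nchar(rows)
  if (length(unique(w)) != 1L) stop2("ragged alignment")
  n <- w[1L]
  if (!is.null(conservation)) {
    stopifnot(length(conservation) == n)
    if (any(conservation < 0 | conservation > 1, na.rm = TRUE))
      stop2("conservation weights must lie in [0, 1]")
  }
  if (!is.null(ss)) {
    stopifnot(length(ss) == n)
    ss <- toupper(ss)
    ss[!ss %in% c("H", "E", "C")] <- NA_character_
  }
  structure(list(rows = rows, conservation = conservation, ss = ss),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("msa_alignment:", length(x$rows), "rows x", nchar(x$rows[1L]),
      "columns;",
      if (is.null(x$conservation)) "conservation: computed" else
        "conservation: annotated",
      "/", if (is.null(x$ss)) "ss: unknown" else "ss: annotated", "\n")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Supports plain FASTA multiple alignments and an HSSP-like annotated
#' fixture dialect. The first/master sequence is the prediction target.
#'
#' The HSSP-like dialect is a plain-text file:
#' \preformatted{
#' HSSPLIKE 1
#' ## ANNOTATION pos aa ss weight
#'     1 A H 0.63
#'     ...          (one line per target position; ss is a DSSP state
#'                   or '-', weight a number in [0,1] or '-')
#' ## ALIGNMENT
#' ACDE-F...        (one aligned row per line, target first)
#' }
#' Eight-state DSSP annotations are reduced to three states
#' (H,G,I -> H; E,B -> E; otherwise C).
#'
#' @param file path to the alignment file, or its text.
#' @param format `"auto"` (default; sniffs the first line), `"fasta"`
#'   or `"hssp"`.
#' @return an [msa_alignment()] object; conservation and secondary
#'   structure are populated from annotation when present, else left
#'   `NULL` (computed on demand / unknown).
#' @export
read_alignment <- function(file, format = c("auto", "fasta", "hssp")) {
  format <- match.arg(format)
  lines <- as_pdb_lines(file)  # same path-or-text convention
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop2("no sequences")
  if (format == "auto") {
    format <- if (grepl("^HSSPLIKE", lines[1L])) "hssp" else
      if (startsWith(lines[1L], ">")) "fasta" else
        stop2("cannot determine alignment format")
  }
  if (format == "fasta") read_alignment_fasta(lines) else
    read_alignment_hssp(lines)
}

read_alignment_fasta <- function(lines) {
  tmp <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  fa <- bio3d::read.fasta(tmp)
  rows <- apply(fa$ali, 1L, paste, collapse = "")
  rows <- gsub(".", "-", rows, fixed = TRUE)
  msa_alignment(rows)
}

read_alignment_hssp <- function(lines) {
  ia <- grep("^## ANNOTATION", lines)
  im <- grep("^## ALIGNMENT", lines)
  if (length(ia) != 1L || length(im) != 1L || im <= ia)
    stop2("malformed HSSP-like file: ANNOTATION/ALIGNMENT sections required")
  ann <- lines[(ia + 1L):(im - 1L)]
  rows <- trimws(lines[(im + 1L):length(lines)])
  if (length(rows) == 0L) stop2("no sequences")
  fields <- strsplit(trimws(ann), "[[:space:]]+")
  if (any(lengths(fields) != 4L)) stop2("malformed annotation line")
  ann <- do.call(rbind, fields)
  n <- nrow(ann)
  if (nchar(rows[1L]) != n)
    stop2("annotation rows do not match alignment width")
  ss <- reduce_dssp(ann[, 3L])
  w <- suppressWarnings(as.numeric(ann[, 4L]))  # '-' -> NA
  if (all(is.na(w))) w <- NULL
  msa_alignment(rows, conservation = w, ss = ss)
}

## 8-state DSSP -> 3-state reduction (standard convention)
reduce_dssp <- function(x) {
  x <- toupper(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("H", "G", "I")] <- "H"
  out[x %in% c("E", "B")] <- "E"
  out[x %in% c("T", "S", "C", "L", " ", ".")] <- "C"
  out
}

#' Filter alignment rows by identity and count
#'
#' Removes non-target rows whose identity to the target is at or above
#' `max_identity`, then truncates to at most `max_rows` rows (target
#' included), keeping file order. Identity is the fraction of matching
#' characters over columns where both rows are non-gap; a row sharing
#' no aligned columns with the target has identity 0.
#'
#' @param aln an [msa_alignment()].
#' @param max_identity identity threshold; rows at or above it are
#'   dropped (default 0.80, i.e. only rows with identity < 80% kept).
#' @param max_rows maximum retained rows including the target
#'   (default 100).
#' @return the filtered `msa_alignment` (annotation untouched).
#' @export
filter_alignment <- function(aln, max_identity = 0.80, max_rows = 100L) {
  stopifnot(inherits(aln, "msa_alignment"))
  rows <- aln$rows
  if (length(rows) > 1L) {
    tgt <- strsplit(rows[1L], "")[[1L]]
    keep <- vapply(rows[-1L], function(r) {
      rr <- strsplit(r, "")[[1L]]
      both <- tgt != "-" & rr != "-"
      if (!any(both)) return(TRUE)  # identity 0
      mean(tgt[both] == rr[both]) < max_identity
    }, logical(1L), USE.NAMES = FALSE)
    rows <- c(rows[1L], rows[-1L][keep])
  }
  rows <- rows[seq_len(min(length(rows), max_rows))]
  msa_alignment(rows, conservation = aln$conservation, ss = aln$ss)
}

#' Precompute encoder-ready alignment statistics
#'
#' Converts an alignment into the numeric form the pair encoder works
#' from: an integer residue-code matrix (gaps and non-standard letters
#' as `NA`), per-position conservation weights (annotated values
#' passed through, otherwise the frequency of the modal non-gap
#' residue), and the 3-state secondary-structure one-hot matrix
#' (all-zero where unknown).
#'
#' @param aln an [msa_alignment()].
#' @return an object of class `alignment_features` with elements
#'   `target` (string), `n` (columns), `nrows`, `codes`
#'   (rows x n integer matrix), `conservation` (length n),
#'   `ss_onehot` (n x 3 matrix, columns H/E/C).
#' @export
alignment_features <- function(aln) {
  stopifnot(inherits(aln, "msa_alignment"))
  chars <- do.call(rbind, strsplit(aln$rows, ""))
  codes <- matrix(aa_code(chars), nrow(chars), ncol(chars))
  n <- ncol(codes)
  if (!is.null(aln$conservation)) {
    cons <- aln$conservation
    ## annotated files may leave single positions unweighted
    fb <- which(is.na(cons))
    if (length(fb)) cons[fb] <- vapply(fb, function(p)
      modal_freq(codes[, p], nrow(codes)), numeric(1L))
  } else {
    cons <- vapply(seq_len(n), function(p)
      modal_freq(codes[, p], nrow(codes)), numeric(1L))
  }
  ssh <- matrix(0, n, 3L, dimnames = list(NULL, c("H", "E", "C")))
  if (!is.null(aln$ss)) {
    m <- match(aln$ss, c("H", "E", "C"))
    ok <- which(!is.na(m))
    ssh[cbind(ok, m[ok])] <- 1
  }
  structure(list(target = aln$rows[1L], n = n, nrows = nrow(codes),
                 codes = codes, conservation = cons, ss_onehot = ssh),
            class = "alignment_features")
}

modal_freq <- function(col, nrows) {
  col <- col[!is.na(col)]
  if (length(col) == 0L) return(0)
  max(tabulate(col, 20L)) / nrows
}

as_features <- function(x) {
  if (inherits(x, "alignment_features")) x else alignment_features(x)
}

#' Amino-acid pair frequencies for one position pair
#'
#' For every alignment row with standard residues at both positions,
#' the unordered amino-acid pair category is counted; counts are
#' divided by the total number of retained rows. Rows with a gap (or a
#' non-standard letter) at either position contribute nothing, so the
#' vector sum equals (rows standard at both positions) / (rows).
#'
#' @param aln an [msa_alignment()] or [alignment_features()].
#' @param i,j 1-based column positions.
#' @return numeric vector of length 210, one entry per unordered
#'   amino-acid pair, named `"AA"`, `"AC"`, ...; symmetric in `i`, `j`.
#' @export
pair_frequency <- function(aln, i, j) {
  f <- as_features(aln)
  if (any(c(i, j) < 1L) || any(c(i, j) > f$n)) stop2("bad position")
  cat <- pair_cat_codes(f$codes[, i], f$codes[, j])
  cat[is.na(cat)] <- 0L  # ignored by tabulate
  v <- tabulate(cat, 210L) / f$nrows
  names(v) <- PAIR_CATEGORY_NAMES
  v
}

#' Conservation weight of an alignment column
#'
#' Returns the annotated weight when the alignment carries one,
#' otherwise the frequency of the most common standard residue in the
#' column (count over total rows).
#'
#' @inheritParams pair_frequency
#' @param i 1-based column position.
#' @return a value in \[0, 1\].
#' @export
conservation_weight <- function(aln, i) {
  f <- as_features(aln)
  if (i < 1L || i > f$n) stop2("bad position")
  f$conservation[i]
}

#' Secondary-structure one-hot coding of a column
#'
#' @inheritParams conservation_weight
#' @return numeric 3-vector over (H, E, C); all zeros when unknown.
#' @export
ss_coding <- function(aln, i) {
  f <- as_features(aln)
  if (i < 1L || i > f$n) stop2("bad position")
  f$ss_onehot[i, ]
}
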