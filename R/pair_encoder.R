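## Staged residue-pair input coding: 210 pair frequencies -> 218 base
## block (+ conservation and secondary structure of both positions) ->
## 1090 (five content-window blocks) -> 1744 (three segment-window
## blocks) -> 1747 (three global descriptors).

## names of the 210 unordered amino-acid pair categories, and a
## 20 x 20 lookup giving the 1-based category for any ordered code pair
PAIR_CATEGORY_NAMES <- local({
  out <- character(210L)
  k <- 0L
  for (x in 1:20) for (y in x:20) {
    k <- k + 1L
    out[k] <- paste0(AA_LETTERS[x], AA_LETTERS[y])
  }
  out
})

PAIR_CAT_LOOKUP <- local({
  m <- matrix(0L, 20L, 20L)
  for (x in 1:20) for (y in 1:20) {
    a <- min(x, y); b <- max(x, y)
    m[x, y] <- 21L * (a - 1L) - (a * (a - 1L)) %/% 2L + (b - a) + 1L
  }
  m
})

## vectorized: integer codes (NA-safe) -> 1-based category in 1..210
pair_cat_codes <- function(cx, cy) {
  out <- rep(NA_integer_, length(cx))
  ok <- !is.na(cx) & !is.na(cy)
  out[ok] <- PAIR_CAT_LOOKUP[cbind(cx[ok], cy[ok])]
  out
}

## maximum modelled chain length; also the global-feature normalizer
MAX_CHAIN_LENGTH <- 450L

#' Category index of an unordered amino-acid pair
#'
#' Maps the 400 ordered one-letter pairs onto the 210 unordered pair
#' categories (20 same-type pairs plus 190 mixed pairs). The index is
#' the zero-based offset of the category inside the 210-element
#' pair-frequency block, under lexicographic ordering of the sorted
#' pair: (A,A) is 0, (A,C) is 1, ..., (Y,Y) is 209. Invariant under
#' swapping the two arguments.
#'
#' @param aa1,aa2 one-letter residue codes (vectorized).
#' @return integer offset(s) in `[0, 210)`.
#' @export
#' @examples
#' pair_category_index("A", "C") == pair_category_index("C", "A")
pair_category_index <- function(aa1, aa2) {
  c1 <- aa_code(aa1); c2 <- aa_code(aa2)
  if (anyNA(c1) || anyNA(c2)) stop2("bad residue")
  PAIR_CAT_LOOKUP[cbind(c1, c2)] - 1L
}

#' Global descriptors for a residue pair
#'
#' The three whole-protein features: sequence separation `j - i`,
#' sequence length `N`, and segment separation length `j - i - 1`
#' (residues strictly between the pair). Each is divided by 450, the
#' maximum modelled chain length, so all inputs share the \[0, 1\]
#' scale of the frequency features.
#'
#' @param n chain length N.
#' @param i,j residue positions with `i < j`.
#' @return numeric 3-vector (normalized separation, length, segment
#'   separation).
#' @export
global_features <- function(n, i, j) {
  stopifnot(i >= 1L, j > i, j <= n)
  c(j - i, n, j - i - 1) / MAX_CHAIN_LENGTH
}

#' The 218-element base block for one position pair
#'
#' Concatenation of the 210 pair frequencies for (i, j), then the
#' conservation weight and 3-state secondary-structure one-hot of
#' position i, then the same two features of position j
#' (210 + 2 x (1 + 3) = 218).
#'
#' @param features an [alignment_features()] (or `msa_alignment`).
#' @param i,j 1-based positions.
#' @return numeric vector of length 218.
#' @export
encode_base_block <- function(features, i, j) {
  f <- as_features(features)
  if (any(c(i, j) < 1L) || any(c(i, j) > f$n)) stop2("bad position")
  c(unname(pair_frequency(f, i, j)),
    f$conservation[i], f$ss_onehot[i, ],
    f$conservation[j], f$ss_onehot[j, ])
}

#' Layout of the 1747-element pair encoding
#'
#' Named index ranges (1-based, inclusive) of every slice of the
#' encoding: the base block for (i, j); the four additional
#' content-window blocks for the shifted pairs (i+d, j+d),
#' d in -2, -1, +1, +2; the three segment-window blocks for the pairs
#' (k, k), (k-1, k+1), (k-2, k+2) around the midpoint
#' k = floor((i+j)/2); and the three global descriptors. The staged
#' totals 210 / 218 / 1090 / 1744 / 1747 are recoverable by slicing.
#'
#' @return a data frame with columns `name`, `start`, `end`.
#' @export
encoding_layout <- function() {
  blocks <- c("base", "content_m2", "content_m1", "content_p1",
              "content_p2", "segment_0", "segment_1", "segment_2")
  out <- data.frame(
    name = c("pair_freq", blocks, "global"),
    start = c(1L, (0:7) * 218L + 1L, 1745L),
    end = c(210L, (1:8) * 218L, 1747L),
    stringsAsFactors = FALSE)
  out
}

## per-slot shifted pairs for a pair matrix; returns list(a, b) n x 8
derived_pairs <- function(i, j, scheme = "paired") {
  k <- (i + j) %/% 2L
  a <- cbind(i, i - 2L, i - 1L, i + 1L, i + 2L,
             if (scheme == "paired") cbind(k, k - 1L, k - 2L)
             else cbind(k - 1L, k, k + 1L))
  b <- cbind(j, j - 2L, j - 1L, j + 1L, j + 2L,
             if (scheme == "paired") cbind(k, k + 1L, k + 2L)
             else cbind(k - 1L, k, k + 1L))
  list(a = a, b = b)
}

#' Encode a batch of residue pairs
#'
#' Vectorized construction of the full 1747-element encoding for many
#' pairs of one protein at once (the form consumed by training and
#' prediction). Blocks whose window positions fall outside `[1, N]`
#' are all-zero.
#'
#' @param features an [alignment_features()] (or `msa_alignment`).
#' @param pairs integer matrix with columns i, j (1-based, i < j).
#' @param segment_scheme `"paired"` (default): segment blocks are the
#'   midpoint-symmetric pairs (k, k), (k-1, k+1), (k-2, k+2);
#'   `"self"`: the self-paired positions (k-1, k-1), (k, k),
#'   (k+1, k+1).
#' @return numeric matrix, `nrow(pairs)` x 1747.
#' @export
encode_pairs <- function(features, pairs,
                         segment_scheme = c("paired", "self")) {
  segment_scheme <- match.arg(segment_scheme)
  f <- as_features(features)
  n <- f$n
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) == 0L) return(matrix(0, 0L, 1747L))
  i <- pairs[, 1L]; j <- pairs[, 2L]
  if (any(i >= j)) stop2("unordered pair required (i < j)")
  if (any(i < 1L) || any(j > n)) stop2("bad pair")

  dp <- derived_pairs(i, j, segment_scheme)
  a <- dp$a; b <- dp$b
  valid <- a >= 1L & b >= 1L & a <= n & b <= n & a <= b

  ## unique derived pairs -> one pair-frequency computation each
  key <- ifelse(valid, a + (n + 1L) * b, NA_integer_)
  ukey <- unique(key[!is.na(key)])
  ua <- ukey %% (n + 1L)
  ub <- ukey %/% (n + 1L)
  u <- length(ukey)
  R <- f$nrows
  catm <- matrix(pair_cat_codes(f$codes[, ua], f$codes[, ub]), R, u)
  vals <- catm + rep.int((seq_len(u) - 1L) * 210L, rep.int(R, u))
  vals[is.na(vals)] <- 0L
  pf <- matrix(tabulate(vals, 210L * u), 210L, u) / R

  out <- matrix(0, nrow(pairs), 1747L)
  cons <- f$conservation; ssh <- f$ss_onehot
  for (s in 1:8) {
    ok <- valid[, s]
    if (!any(ok)) next
    col0 <- (s - 1L) * 218L
    idx <- match(key[cbind(which(ok), s)], ukey)
    out[ok, col0 + (1:210)] <- t(pf[, idx, drop = FALSE])
    va <- a[ok, s]; vb <- b[ok, s]
    out[ok, col0 + 211L] <- cons[va]
    out[ok, col0 + (212:214)] <- ssh[va, , drop = FALSE]
    out[ok, col0 + 215L] <- cons[vb]
    out[ok, col0 + (216:218)] <- ssh[vb, , drop = FALSE]
  }
  out[, 1745L] <- (j - i) / MAX_CHAIN_LENGTH
  out[, 1746L] <- n / MAX_CHAIN_LENGTH
  out[, 1747L] <- (j - i - 1) / MAX_CHAIN_LENGTH
  out
}

#' Encode one residue pair
#'
#' Builds the full 1747-element input vector for a single pair.
#' Arguments given as (j, i) with j > i are canonicalized to (i, j),
#' so a map cell and its transpose share one encoding.
#'
#' @inheritParams encode_pairs
#' @param i,j residue positions (i != j).
#' @return numeric vector of length 1747.
#' @export
#' @examples
#' aln <- synth_msa(strrep("ACDEFGHIKL", 6), n_rows = 5, 0.2, seed = 1)
#' length(encode_pair(alignment_features(aln), 3, 40))
encode_pair <- function(features, i, j,
                        segment_scheme = c("paired", "self")) {
  if (i == j) stop2("unordered pair required (i != j)")
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  drop(encode_pairs(features, cbind(i, j), segment_scheme))
}

#' Write / read an encoding matrix with its layout descriptor
#'
#' Encodings are stored as a dense tab-separated numeric matrix next
#' to a JSON descriptor mapping slice names to 1-based index ranges,
#' so training sets can be reused without re-encoding.
#'
#' @param x encoding matrix from [encode_pairs()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.layout.json`.
#' @return the prefix, invisibly.
#' @export
write_encodings <- function(x, prefix) {
  utils::write.table(x, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(encoding_layout(), paste0(prefix, ".layout.json"),
                       dataframe = "rows")
  invisible(prefix)
}

#' @rdname write_encodings
#' @export
read_encodings <- function(prefix) {
  x <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(x) <- NULL
  x
}
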