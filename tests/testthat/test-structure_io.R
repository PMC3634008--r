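test_that("parse_structure picks CB, falling back to CA for glycine", {
  rec <- parse_structure(tiny_pdb(), "A")
  expect_s3_class(rec, "chain_record")
  expect_equal(rec$sequence, "AGA")
  expect_equal(rec$representative_atom, c("CB", "CA", "CB"))
  expect_equal(rec$coords[1, ], c(0, 1.5, 0))
  expect_equal(rec$coords[2, ], c(4, 0, 0))   # glycine CA
  expect_equal(rec$experiment_method, "X-RAY DIFFRACTION")
  expect_equal(rec$resolution, 1.2)
  expect_true(rec$backbone_complete)
  expect_false(rec$has_nonstandard_residues)
})

test_that("parse_structure selects the requested chain only", {
  recB <- parse_structure(two_chain_pdb(), "B")
  expect_equal(recB$sequence, "S")
  recA <- parse_structure(two_chain_pdb(), "A")
  expect_equal(recA$sequence, "AG")
  expect_error(parse_structure(two_chain_pdb(), "C"), "chain not found")
})

test_that("non-glycine without CB falls back to CA unless strict", {
  expect_warning(rec <- parse_structure(missing_cb_pdb(), "A"),
                 "lacks CB")
  expect_equal(rec$representative_atom, c("CB", "CA"))
  expect_equal(rec$coords[2, ], c(5, 0, 0))
  expect_error(suppressWarnings(
    parse_structure(missing_cb_pdb(), "A", strict = TRUE)),
    "unusable residue")
})

test_that("curation filters drop chains by the stated rules", {
  chains <- list(ok = meta_chain(),
                 lowres = meta_chain(resolution = 2.0),
                 nmr = meta_chain(method = "SOLUTION NMR"),
                 long = meta_chain(n = 460),
                 max_ok = meta_chain(n = 450),
                 short = meta_chain(n = 50),
                 broken = meta_chain(backbone = FALSE),
                 nonstd = meta_chain(nonstd = TRUE))
  kept <- filter_chains(chains)
  expect_equal(names(kept), c("ok", "max_ok"))
  # idempotence
  expect_identical(filter_chains(kept), kept)
  # empty result is legal
  expect_equal(length(filter_chains(list(meta_chain(resolution = 3)))), 0L)
})

test_that("contact cutoff is a strict less-than", {
  ch <- collinear_chain(5, gap = 4.0)
  cm <- contact_map(ch, cutoff = 8.0)
  expect_equal(cm$cells[1, 2], 1L)   # 4.0 < 8
  expect_equal(cm$cells[1, 3], 0L)   # 8.0 is not < 8
  expect_equal(diag(cm$cells), rep(1L, 5))
  expect_error(contact_map(ch, cutoff = -1), "invalid cutoff")
})

test_that("contact maps are symmetric, binary and match a brute-force oracle", {
  brute <- function(coords, cutoff) {
    n <- nrow(coords)
    m <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff)
        m[i, j] <- 1L
    }
    m
  }
  for (seed in 1:10) {
    n <- 20L + (seed %% 4L) * 10L
    ch <- synth_chain(n, seed = seed)$chain
    cm <- contact_map(ch)
    expect_identical(cm$cells, t(cm$cells))
    expect_true(all(cm$cells %in% c(0L, 1L)))
    expect_identical(cm$cells, brute(ch$coords, 8.0))
  }
})

test_that("separation mask enumerates exactly the pairs j - i >= s", {
  m <- separation_mask(10L, 6L)
  expect_equal(unname(m),
               cbind(c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4),
                     c(7, 8, 9, 10, 8, 9, 10, 9, 10, 10)))
  expect_equal(nrow(separation_mask(10L, 0L)), 45L)  # N(N-1)/2
  expect_equal(nrow(separation_mask(10L, 10L)), 0L)
  expect_error(separation_mask(10L, -1L), "invalid separation")
  # matches a naive enumeration for assorted N, s
  for (n in c(5L, 12L, 30L)) for (s in c(0L, 3L, 7L)) {
    all_pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- all_pairs[all_pairs[, 2] - all_pairs[, 1] >= s, , drop = FALSE]
    keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
    expect_equal(unname(separation_mask(n, s)), unname(cbind(keep)),
                 ignore_attr = TRUE)
  }
})

test_that("contact maps round-trip through the pair-list format", {
  ch <- synth_chain(40, seed = 3)$chain
  cm <- contact_map(ch)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(cm, f)
  pairs <- read_contact_pairs(f)
  idx <- which(upper.tri(cm$cells) & cm$cells == 1L, arr.ind = TRUE)
  expect_equal(nrow(pairs), nrow(idx))
  expect_true(all(cm$cells[pairs] == 1L))
})
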