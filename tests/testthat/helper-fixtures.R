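# Shared hand-written fixtures and tiny builders.

pdb_atom <- function(serial, name, res3, chain, resno, x, y, z) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          serial, sprintf(" %-3s", name), res3, chain, resno, x, y, z,
          1.0, 0.0, substr(name, 1, 1))
}

# three residues ALA / GLY / ALA along x, CB displaced in y
tiny_pdb <- function() {
  c("EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.20 ANGSTROMS.",
    pdb_atom(1, "N",  "ALA", "A", 1, -1.0, 0, 0),
    pdb_atom(2, "CA", "ALA", "A", 1,  0.0, 0, 0),
    pdb_atom(3, "C",  "ALA", "A", 1,  1.0, 0, 0),
    pdb_atom(4, "CB", "ALA", "A", 1,  0.0, 1.5, 0),
    pdb_atom(5, "N",  "GLY", "A", 2,  3.0, 0, 0),
    pdb_atom(6, "CA", "GLY", "A", 2,  4.0, 0, 0),
    pdb_atom(7, "C",  "GLY", "A", 2,  5.0, 0, 0),
    pdb_atom(8, "N",  "ALA", "A", 3,  7.0, 0, 0),
    pdb_atom(9, "CA", "ALA", "A", 3,  8.0, 0, 0),
    pdb_atom(10, "C", "ALA", "A", 3,  9.0, 0, 0),
    pdb_atom(11, "CB", "ALA", "A", 3, 8.0, 1.5, 0),
    "END")
}

# two chains A (2 res) and B (1 res)
two_chain_pdb <- function() {
  c(pdb_atom(1, "N",  "ALA", "A", 1, 0, 0, 0),
    pdb_atom(2, "CA", "ALA", "A", 1, 1, 0, 0),
    pdb_atom(3, "C",  "ALA", "A", 1, 2, 0, 0),
    pdb_atom(4, "CB", "ALA", "A", 1, 1, 1.5, 0),
    pdb_atom(5, "N",  "GLY", "A", 2, 4, 0, 0),
    pdb_atom(6, "CA", "GLY", "A", 2, 5, 0, 0),
    pdb_atom(7, "C",  "GLY", "A", 2, 6, 0, 0),
    pdb_atom(8, "N",  "SER", "B", 1, 10, 0, 0),
    pdb_atom(9, "CA", "SER", "B", 1, 11, 0, 0),
    pdb_atom(10, "C", "SER", "B", 1, 12, 0, 0),
    pdb_atom(11, "CB", "SER", "B", 1, 11, 1.5, 0),
    "END")
}

# residue 2 is LEU (non-glycine) with CA but no CB
missing_cb_pdb <- function() {
  c(pdb_atom(1, "N",  "ALA", "A", 1, 0, 0, 0),
    pdb_atom(2, "CA", "ALA", "A", 1, 1, 0, 0),
    pdb_atom(3, "C",  "ALA", "A", 1, 2, 0, 0),
    pdb_atom(4, "CB", "ALA", "A", 1, 1, 1.5, 0),
    pdb_atom(5, "N",  "LEU", "A", 2, 4, 0, 0),
    pdb_atom(6, "CA", "LEU", "A", 2, 5, 0, 0),
    pdb_atom(7, "C",  "LEU", "A", 2, 6, 0, 0),
    "END")
}

# a collinear chain of n residues spaced `gap` Angstrom apart (all ALA)
collinear_chain <- function(n, gap = 4.0) {
  structure(list(
    chain_id = "A",
    sequence = strrep("A", n),
    coords = cbind(gap * (seq_len(n) - 1), 0, 0),
    representative_atom = rep("CB", n),
    experiment_method = "X-RAY DIFFRACTION",
    resolution = 1.2,
    backbone_complete = TRUE,
    has_nonstandard_residues = FALSE
  ), class = "chain_record")
}

# chain_record with arbitrary metadata (for curation-filter tests)
meta_chain <- function(n = 60, resolution = 1.2,
                       method = "X-RAY DIFFRACTION",
                       backbone = TRUE, nonstd = FALSE) {
  ch <- collinear_chain(n)
  ch$resolution <- resolution
  ch$experiment_method <- method
  ch$backbone_complete <- backbone
  ch$has_nonstandard_residues <- nonstd
  ch
}

# HSSP-like fixture: 4 positions, 3 aligned rows, annotated ss + weights
hssp_fixture <- function() {
  c("HSSPLIKE 1",
    "## ANNOTATION pos aa ss weight",
    "  1 A H 0.63",
    "  2 C E 1.00",
    "  3 D G 0.40",
    "  4 E - -",
    "## ALIGNMENT",
    "ACDE",
    "ACDF",
    "GCDE")
}

# a six-range toy dataset (one or two proteins per range), small MSAs
toy_dataset <- function(n_per_range = 1L, seed = 7L,
                        lengths1 = c(55L, 75L, 95L, 135L, 195L, 295L)) {
  lengths <- rep(lengths1, each = n_per_range) +
    rep(seq_len(n_per_range) - 1L, times = 6L)
  synth_dataset(synthetic_spec(lengths, msa_rows = 8L,
                               mutation_rate = 0.25, seed = seed))
}

# bundle whose nets all output 0.5 (zero weights) for plumbing tests
stub_bundle <- function() {
  zero_net <- function(sizes) {
    net <- init_network(sizes, seed = 1L)
    net$W1[] <- 0; net$b1[] <- 0; net$W2[] <- 0; net$b2[] <- 0
    net
  }
  cascade_bundle(replicate(6, zero_net(c(1747L, 5L, 1L)),
                           simplify = FALSE),
                 zero_net(c(9L, 6L, 1L)), trained = TRUE, seed = 1L)
}
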