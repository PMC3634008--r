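Package: contactcascade
Title: Cascaded Neural Network Prediction of Protein Residue Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts protein residue-residue contact maps (8 Angstrom
    C-beta cutoff) with a two-level cascade of feed-forward neural
    networks. Proteins are routed by sequence length to one of six
    1747-5-1 sub-networks whose inputs are a staged encoding of multiple
    sequence alignment pair frequencies, conservation weights and
    secondary structure; a 9-6-1 cascade network combines the outputs of
    the routed sub-network and its two neighbours with distance-based
    balance weights. Includes contact-map extraction from PDB chains with
    curation filters, balanced training for the heavy contact/non-contact
    class imbalance, coverage-knee threshold optimization, the
    specificity/sensitivity evaluation protocol with top-n selection, and
    a synthetic-data generator (compact self-avoiding chains, mutated
    alignments) so the full pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
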