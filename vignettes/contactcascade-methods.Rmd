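---
title: "Cascaded length-routed networks for contact map prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded length-routed networks for contact map prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(contactcascade)
```

## The problem and the model

A residue–residue contact map is the N×N binary symmetric matrix C with
C[i,j] = 1 when the representative side-chain atoms of residues i and j
(Cβ, or Cα for glycine, which has no side chain beyond a hydrogen) lie
strictly within 8 Å of each other — the standard cutoff in the contact
prediction literature. Contact maps are the classic intermediate
between sequence and full 3D structure: they turn fold recognition into
a binary classification over residue pairs.

Two features make this classification hard. First, extreme class
imbalance: the number of contacts grows roughly linearly with chain
length N while the number of candidate pairs grows with N², so the
contact density falls as ~1/N — the *thin density problem* — and long
chains are disproportionately difficult. Second, trivial short-range
contacts must be excluded: only pairs at sequence separation
j − i ≥ s are labelled and evaluated, with s growing with chain length.

`contactcascade` addresses length dependence structurally. Chains are
partitioned into six length ranges:

| sub-network | length range | separation s | default threshold |
|---|---|---|---|
| 1 | 51–70   | 6  | 0.1 |
| 2 | 71–90   | 7  | 0.6 |
| 3 | 91–130  | 10 | 0.7 |
| 4 | 131–190 | 13 | 0.7 |
| 5 | 191–290 | 17 | 0.8 |
| 6 | 291–450 | 21 | 0.9 |

Each range owns a 1747–5–1 feed-forward sub-network. A protein of
length N is routed to the range containing N; the routed sub-network
and its left and right neighbours each score every masked pair. A
second-stage 9–6–1 *cascade* network then combines the three opinions:
its first six inputs hold the consulted sub-networks' probabilities at
their id-slots (zeros elsewhere), and the last three hold (left, own,
right) *balance weights* — here inverse distance from N to each
consulted range's midpoint, renormalized to sum to one. The cascade
output is the final contact probability; a per-range decision
threshold converts it to calls.

## The 1747-element pair encoding

Each residue pair (i, j) is encoded in stages:

1. **210** — frequencies of the unordered amino-acid pair categories
   observed at columns (i, j) across the alignment rows, divided by
   the total retained row count (rows gapped at either column
   contribute nothing, so the block sums to the fraction of rows
   standard at both columns). 210 = 20 same-type + 190 mixed
   categories; the encoding of (i, j) and (j, i) is identical.
2. **218** — plus the conservation weight (one value) and the 3-state
   secondary-structure one-hot (H/E/C) of each of the two positions:
   210 + 2×(1+3).
3. **1090** — content windows: base blocks for the shifted pairs
   (i+d, j+d), d ∈ {−2, −1, 0, +1, +2} (5 × 218). The two size-2
   windows around i and j are coupled offset-wise; this is the only
   pairing consistent with the stage length being exactly 5 × 218.
4. **1744** — segment window: base blocks for the pairs (k, k),
   (k−1, k+1), (k−2, k+2) around the midpoint k = ⌊(i+j)/2⌋ (3 × 218
   more). An alternative reading — three self-paired positions k−1,
   k, k+1 — is available via `segment_scheme = "self"`.
5. **1747** — three global descriptors: sequence separation j − i,
   chain length N, and segment separation j − i − 1, each divided by
   450 (the maximum modelled length) so that every input shares the
   [0, 1] scale.

Any window position outside [1, N] zeroes its whole 218-block. MSA
rows are filtered before encoding: rows with identity to the target
≥ 80% are dropped (identity = matches over mutually non-gap columns),
then rows are truncated to 100 including the target, in file order.
Non-standard letters (B, Z, X, U, O) count as gaps. Annotated
conservation weights (from HSSP-like files) pass through unchanged;
without annotation the fallback is the modal-residue frequency of the
column — a declared, non-canonical substitute. Eight-state DSSP codes
reduce to three states by the standard H,G,I→H; E,B→E; else→C rule.

## Training

**Balanced sampling.** Contacts are rare, so each training protein
contributes an equal number of positive and negative pairs
(`min(#pos, #neg)` each, drawn without replacement, capped at
`max_pairs_per_protein`, default 1200). The balancing probability
factor (default 1.0) optionally thins the selection further while
keeping the class counts exactly equal (a negatives-only switch
exists).

**Back-propagation.** All networks are plain 3-layer sigmoid nets
trained by full-batch gradient descent with momentum on mean binary
cross-entropy (loss and activations are package choices; the method
itself only fixes the architectures). Defaults: learning rate 1.0,
momentum 0.9, up to 800–1000 epochs with early stopping. The learning
rate looks large; it is not. The gradient of a *mean* cross-entropy
over thousands of rows of sparse [0, 1] features is tiny, and rates
two orders of magnitude smaller leave the network indistinguishable
from its initialization (we verified this directly: discrimination
stays at chance).

**Protein-level validation.** During bundle training, early stopping
watches pairs from *whole held-out proteins* (about 20% of each
range's training proteins), not a random row split. Pairs from one
protein share windows and residues; a row split therefore leaks
protein identity and rewards memorization, which is exactly the
failure mode a contact predictor must avoid. This choice matters: the
1747-dimensional encoding lets a 5-hidden-unit net interpolate its
training set, and only a cross-protein signal generalizes.

**Stage 2 and thresholds.** The cascade trains on the consulted
sub-networks' outputs (plus balance weights) over the same training
proteins, balanced the same way. Per-range decision thresholds are
then optimized by the *coverage-knee* rule: sweep a threshold grid,
compute coverage (fraction of true contacts still called) at each
point, and take the threshold at which the single largest coverage
drop begins, breaking ties toward the smaller threshold. The table
thresholds above ship as the fallback whenever no tuning data is
available. Bundle training uses a 0.02-step grid; the exported
`optimize_threshold()` defaults to the coarser 0.05 grid matching the
printed precision of the shipped table.

## The synthetic generator

Real training corpora (curated X-ray chains with HSSP alignments) are
external data; the package instead ships a generator that reproduces
the *structural* properties the method depends on:

- **Geometry.** Chains are self-avoiding 3D walks with consecutive
  spacing 3.8 ± 0.1 Å, non-consecutive clearance ≥ 3.0 Å, confined to
  a sphere of radius 3.2·N^(1/3). Constant packing density makes the
  8 Å contact count grow ~linearly with N, so density falls as ~1/N —
  the thin-density trend, verified by a rank-correlation test.
- **Sequence–structure coupling.** Sequences are assigned after the
  walk with a hydrophobic-core bias: the probability of a hydrophobic
  residue (A, C, F, I, L, M, V, W, Y) falls linearly from 0.9 at the
  most buried position to 0.1 at the most exposed. Contacting pairs
  are therefore enriched in hydrophobic–hydrophobic categories — the
  elementary sequence signal of globular proteins. Without this
  coupling the alignment features carry *no* information about
  contacts and any architecture comparison on synthetic data reduces
  to noise.
- **Alignments.** MSA rows are mutated copies of the target (uniform
  substitution over the 19 other residues at the given per-position
  rate), so expected row identity is 1 − rate. This exercises
  frequency counting, identity filtering and conservation fallbacks;
  it does **not** emulate phylogeny, gaps, or correlated mutations.

What passing tests therefore show: the plumbing, the encoding
arithmetic, the training loop, the routing/combination machinery and
the evaluation protocol behave as specified, and the cascade's
combination step adds accuracy over its sub-networks when a genuine
(if weak) signal is present. What they cannot show: performance
levels on real proteins, where evolutionary information is far richer.

## The benchmark and its problem sizes

`run_benchmark()` fixes the study conditions used by the acceptance
suite: 12 proteins per range (72 total, lengths uniform within each
range), 20 alignment rows at mutation rate 0.25, six training and six
test proteins per range, package-default training configuration, one
master seed. Per test protein both levels are scored at their
optimized thresholds against the geometric truth restricted to the
routed range's separation mask: the routed sub-network alone, and the
full cascade. Set-level sub-network accuracy is the mean of the six
per-range macro accuracies (the "average sub-network" figure);
cascade accuracy is the macro mean over all test proteins. These sizes
keep a full benchmark run in the low minutes on one core.

## Known limitations

- The accuracy-vs-length *flattening* seen with real data does not
  reproduce under the synthetic conditions, and for a structural
  reason: with density ~c/N and a discrimination lift that is
  approximately length-independent (the uniform hydrophobic signal),
  per-protein accuracy scales like lift·c/N — so a predictor with a
  *larger* lift necessarily shows a *steeper* absolute slope.
  Flattening requires the lift itself to grow with N, which real
  evolutionary couplings provide and uniform-substitution synthetic
  alignments cannot. The test suite asserts the property as stated
  and it is expected to fail on synthetic data; the set-level
  accuracy gain of the cascade is asserted by the same test and does
  hold.
- The conservation-weight fallback is not the HSSP definition (which
  is unpublished in closed form); annotated weights always win.
- Balanced training miscalibrates absolute probabilities (by design);
  decision thresholds absorb this, but the RR-file probabilities
  should be read as scores, not calibrated frequencies.
- Strict inequality at the 8 Å cutoff follows the definition "less
  than 8 Å"; borderline pairs at exactly 8.000 Å differ between
  conventions.
- A non-glycine residue lacking Cβ falls back to Cα with a warning
  (curation would normally have removed such chains); `strict = TRUE`
  raises instead.

## Numerical and degenerate-input choices

- Residue indexing is 1-based everywhere user-facing (RR convention);
  the single exception is `pair_category_index()`, which returns the
  zero-based offset of the category inside the 210-block.
- Alternate-location atoms: first occurring altloc wins; residues are
  ordered by file appearance, insertion codes included.
- "Backbone complete" means every residue has N, CA and C atoms.
- `separation_mask(N, 0)` returns all i < j pairs; `s ≥ N` returns
  the empty pair list.
- Empty prediction sets make accuracy *undefined*; such proteins are
  excluded from macro means and counted, never scored zero.
- T/2 and 2T/3 in the top-n protocol use floor.
- Ties in top-n selection break by smaller i, then smaller j.
- All randomness flows through explicit seeds (generation, weight
  initialization, sampling, validation splits); repeated runs are
  bit-identical, and seeded helpers restore the caller's RNG state.
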