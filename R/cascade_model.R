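## Length-routed sub-networks + cascade combiner.
##
## A protein of length N is routed to the sub-network whose length
## range contains N; that sub-network, its left and right neighbours
## score every residue pair passing the routed range's separation
## mask, and a 9-input cascade network combines the three opinions
## together with three distance-based balance weights into the final
## contact probability.

#' The six-range length partition
#'
#' Ships the routing table: length ranges 51-70, 71-90, 91-130,
#' 131-190, 191-290 and 291-450; the per-range minimum sequence
#' separations (6, 7, 10, 13, 17, 21); and the per-range default
#' decision thresholds (0.1, 0.6, 0.7, 0.7, 0.8, 0.9) used when no
#' tuning data is supplied.
#'
#' @return an object of class `length_partition` (a data frame with
#'   columns `id`, `lower`, `upper`, `separation`, `threshold`).
#' @export
length_partition <- function() {
  structure(data.frame(
    id = 1:6,
    lower = c(51L, 71L, 91L, 131L, 191L, 291L),
    upper = c(70L, 90L, 130L, 190L, 290L, 450L),
    separation = c(6L, 7L, 10L, 13L, 17L, 21L),
    threshold = c(0.1, 0.6, 0.7, 0.7, 0.8, 0.9)
  ), class = c("length_partition", "data.frame"))
}

#' Route a chain length to its sub-network
#'
#' @param length residue count (must lie in 51..450).
#' @param partition a [length_partition()].
#' @return sub-network id in 1..6.
#' @export
#' @examples
#' route_length(100)  # 3
route_length <- function(length, partition = length_partition()) {
  id <- which(length >= partition$lower & length <= partition$upper)
  if (length(id) != 1L)
    stop2("unsupported length: ", length, " (supported range ",
          min(partition$lower), "-", max(partition$upper), ")")
  partition$id[id]
}

#' Sub-networks consulted for a routed protein
#'
#' The routed sub-network plus its left and right neighbours;
#' out-of-range neighbours are dropped at the ends.
#'
#' @param id routed sub-network id in 1..6.
#' @return ordered integer vector of consulted ids.
#' @export
corresponding_subnets <- function(id) {
  stopifnot(id >= 1L, id <= 6L)
  intersect(id + (-1L:1L), 1:6)
}

#' Balance weights for the three consulted sub-networks
#'
#' Non-negative (left, own, right) weights summing to 1, inverse to
#' the distance from the protein length to each consulted range's
#' midpoint (1 / (1 + |length - midpoint|)); a missing neighbour gets
#' weight 0 before renormalization.
#'
#' @param length residue count.
#' @param partition a [length_partition()].
#' @return named numeric 3-vector `(left, own, right)`.
#' @export
balance_weights <- function(length, partition = length_partition()) {
  id <- route_length(length, partition)
  mids <- (partition$lower + partition$upper) / 2
  w <- vapply(id + (-1L:1L), function(k) {
    if (k < 1L || k > 6L) 0 else 1 / (1 + abs(length - mids[k]))
  }, numeric(1L))
  w <- w / sum(w)
  names(w) <- c("left", "own", "right")
  w
}

#' Assemble the 9-element cascade input for one pair
#'
#' Slots 1..6 hold the consulted sub-networks' output probabilities at
#' their own id positions (zeros for unconsulted nets); slots 7..9
#' hold the (left, own, right) balance weights. With
#' `slotting = "packed"` the consulted outputs occupy slots 1..3 in
#' (left, own, right) order instead.
#'
#' @param subnet_probs named numeric vector of probabilities, names
#'   being consulted sub-network ids (`"2"`, `"3"`, ...).
#' @param weights (left, own, right) balance weights.
#' @param slotting `"slotted"` (default) or `"packed"`.
#' @param routed_id the routed sub-network id (needed for `"packed"`
#'   at the edge ranges; by default inferred from a zero left/right
#'   balance weight, else the middle consulted id).
#' @return numeric vector of length 9.
#' @export
#' @examples
#' cascade_input(c(`2` = 0.4, `3` = 0.9, `4` = 0.5), c(0.2, 0.6, 0.2))
cascade_input <- function(subnet_probs, weights,
                          slotting = c("slotted", "packed"),
                          routed_id = NULL) {
  slotting <- match.arg(slotting)
  ids <- as.integer(names(subnet_probs))
  if (length(ids) == 0L || anyNA(ids)) stop2("empty cascade input")
  out <- numeric(9L)
  if (slotting == "slotted") {
    out[ids] <- as.numeric(subnet_probs)
  } else {
    if (is.null(routed_id)) {
      routed_id <- if (length(ids) == 3L) ids[2L]
      else if (weights[1L] == 0) min(ids) else max(ids)
    }
    out[2L + (ids - routed_id)] <- as.numeric(subnet_probs)
  }
  out[7:9] <- as.numeric(weights)
  out
}

#' Bundle the six sub-networks and the cascade network
#'
#' @param subnets list of six trained 1747-5-1 `ffnet`s (index = id).
#' @param cascade a trained 9-6-1 `ffnet`.
#' @param partition a [length_partition()].
#' @param subnet_thresholds,cascade_thresholds per-range decision
#'   thresholds (default: the partition's shipped values).
#' @param slotting cascade input layout, see [cascade_input()].
#' @param segment_scheme see [encode_pairs()].
#' @param trained logical; prediction refuses untrained bundles.
#' @param seed integer seed recorded in the manifest.
#' @return an object of class `cascade_bundle`.
#' @export
cascade_bundle <- function(subnets, cascade,
                           partition = length_partition(),
                           subnet_thresholds = partition$threshold,
                           cascade_thresholds = partition$threshold,
                           slotting = "slotted",
                           segment_scheme = "paired",
                           trained = TRUE, seed = NA_integer_) {
  if (length(subnets) != 6L) stop2("exactly six sub-networks required")
  if (cascade$layer_sizes[1L] != 9L) stop2("cascade input width must be 9")
  structure(list(subnets = subnets, cascade = cascade,
                 partition = partition,
                 subnet_thresholds = subnet_thresholds,
                 cascade_thresholds = cascade_thresholds,
                 slotting = slotting, segment_scheme = segment_scheme,
                 trained = isTRUE(trained), seed = seed),
            class = "cascade_bundle")
}

#' @export
print.cascade_bundle <- function(x, ...) {
  cat("cascade_bundle: 6 sub-networks (",
      paste(x$subnets[[1L]]$layer_sizes, collapse = "-"),
      ") + cascade (", paste(x$cascade$layer_sizes, collapse = "-"),
      "),", if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

#' Predict the contact map of one protein
#'
#' Routes the protein by length, scores every pair passing the routed
#' range's separation mask with the consulted sub-networks, and feeds
#' the slotted probabilities plus balance weights through the cascade
#' network. Both the cascade probabilities and the routed
#' sub-network's own probabilities are returned so the two levels can
#' be compared.
#'
#' @param bundle a trained [cascade_bundle()].
#' @param features [alignment_features()] (or `msa_alignment`) of the
#'   target protein; the chain length is its column count.
#' @param threshold optional cascade decision-threshold override.
#' @param chunk pairs encoded per block (memory control).
#' @return an object of class `prediction_map`: list with `length`,
#'   `subnet_id`, `separation`, `pairs` (m x 2), `prob`, `threshold`,
#'   `calls`, and the sub-network-level `subnet_prob`,
#'   `subnet_threshold`, `subnet_calls`.
#' @export
predict_map <- function(bundle, features, threshold = NULL,
                        chunk = 8192L) {
  if (!isTRUE(bundle$trained)) stop2("model not trained")
  f <- as_features(features)
  n <- f$n
  part <- bundle$partition
  id <- route_length(n, part)
  s <- part$separation[id]
  pairs <- separation_mask(n, s)
  consulted <- corresponding_subnets(id)
  w3 <- balance_weights(n, part)

  m <- nrow(pairs)
  prob <- numeric(m)
  own_prob <- numeric(m)
  starts <- seq(1L, m, by = chunk)
  for (st in starts) {
    en <- min(st + chunk - 1L, m)
    X <- encode_pairs(f, pairs[st:en, , drop = FALSE],
                      segment_scheme = bundle$segment_scheme)
    C <- matrix(0, nrow(X), 9L)
    for (cid in consulted) {
      p <- nn_forward(bundle$subnets[[cid]], X)
      if (bundle$slotting == "slotted") C[, cid] <- p
      else C[, 2L + (cid - id)] <- p     # packed: (left,own,right) in 1..3
      if (cid == id) own_prob[st:en] <- p
    }
    C[, 7L] <- w3[1L]; C[, 8L] <- w3[2L]; C[, 9L] <- w3[3L]
    prob[st:en] <- nn_forward(bundle$cascade, C)
  }
  thr <- if (is.null(threshold)) bundle$cascade_thresholds[id] else threshold
  sthr <- bundle$subnet_thresholds[id]
  structure(list(length = n, subnet_id = id, separation = s,
                 pairs = pairs, prob = prob,
                 threshold = thr, calls = prob >= thr,
                 subnet_prob = own_prob, subnet_threshold = sthr,
                 subnet_calls = own_prob >= sthr),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat("prediction_map:", x$length, "residues (sub-network", x$subnet_id,
      ", separation >=", x$separation, ");", nrow(x$pairs),
      "pairs scored,", sum(x$calls), "called at threshold",
      x$threshold, "\n")
  invisible(x)
}

#' Coverage-knee threshold optimization
#'
#' Sweeps a threshold grid, computes the coverage (fraction of true
#' contacts still called) at each value, and returns the grid point at
#' which the single largest coverage drop begins: coverage typically
#' falls sharply once the threshold passes a network-specific value,
#' and that value is the optimized per-sub-network threshold. Ties are
#' broken toward the smaller threshold.
#'
#' @param probabilities predicted probabilities.
#' @param truths binary labels (both classes must be present).
#' @param grid ascending threshold grid.
#' @return the selected threshold.
#' @export
optimize_threshold <- function(probabilities, truths,
                               grid = seq(0.05, 0.95, by = 0.05)) {
  y <- as.integer(truths)
  if (length(unique(y)) < 2L) stop2("cannot optimize: degenerate truths")
  stopifnot(length(probabilities) == length(y), !is.unsorted(grid))
  npos <- sum(y == 1L)
  cov <- vapply(grid, function(t)
    sum(y == 1L & probabilities >= t) / npos, numeric(1L))
  if (length(grid) == 1L) return(grid[1L])
  drops <- cov[-length(cov)] - cov[-1L]
  grid[which.max(drops)]   # first maximum -> smaller threshold on ties
}

#' Configuration for bundle training
#'
#' @param n_train proteins drawn per length range for sub-network
#'   training (default 50; capped at availability).
#' @param max_pairs_per_protein cap on balanced training pairs taken
#'   from one protein.
#' @param epochs_subnet,epochs_cascade epoch budgets for the two
#'   training stages.
#' @param learning_rate,momentum,patience,val_fraction,balance_factor
#'   passed to [train_config()]. During bundle training, early
#'   stopping watches pairs from whole held-out proteins
#'   (`val_fraction` of each range's training proteins, at least one
#'   when three or more are available), because cross-protein
#'   generalization is what a contact predictor must achieve; a
#'   random row split leaks protein identity.
#' @param optimize_thresholds tune per-range thresholds by the
#'   coverage-knee rule on the training proteins; otherwise the
#'   shipped defaults are used.
#' @param threshold_grid grid for [optimize_threshold()].
#' @param slotting,segment_scheme layout switches, see
#'   [cascade_input()] and [encode_pairs()].
#' @param seed master seed; all per-range and per-protein seeds are
#'   derived from it.
#' @return a `bundle_config` list.
#' @export
bundle_config <- function(n_train = 50L, max_pairs_per_protein = 1200L,
                          epochs_subnet = 1000L, epochs_cascade = 1000L,
                          learning_rate = 1.0, momentum = 0.9,
                          patience = 250L, val_fraction = 0.2,
                          balance_factor = 1.0,
                          optimize_thresholds = TRUE,
                          threshold_grid = seq(0.02, 0.98, by = 0.02),
                          slotting = "slotted",
                          segment_scheme = "paired",
                          seed = 1L) {
  structure(as.list(environment()), class = "bundle_config")
}

## balanced pair selection for one protein, capped
sample_training_pairs <- function(labels, factor, cap, seed) {
  sel <- balanced_sample(labels, factor = factor, seed = seed)
  if (length(sel) > cap) {
    pos <- sel[labels[sel] == 1L]; neg <- sel[labels[sel] == 0L]
    k <- max(1L, cap %/% 2L)
    sel <- sort(c(pos[seq_len(min(k, length(pos)))],
                  neg[seq_len(min(k, length(neg)))]))
  }
  sel
}

#' Train the full cascade bundle
#'
#' Orchestrates the two-stage training: each sub-network is trained by
#' balanced back-propagation on pairs from proteins of its own length
#' range (`n_train` proteins per range); the cascade network is then
#' trained on the consulted sub-networks' outputs plus balance weights
#' over the same proteins; finally per-range decision thresholds are
#' optimized by the coverage-knee rule (on the training proteins)
#' unless disabled.
#'
#' @param dataset list of proteins, each a list with elements `chain`
#'   (a `chain_record`), `aln` (an `msa_alignment`) and/or `features`
#'   (an [alignment_features()]), and `map` (a [contact_map()]).
#' @param config a [bundle_config()].
#' @return a trained [cascade_bundle()].
#' @export
train_bundle <- function(dataset, config = bundle_config()) {
  part <- length_partition()
  feats <- lapply(dataset, function(p)
    if (!is.null(p$features)) p$features else alignment_features(p$aln))
  lens <- vapply(feats, function(f) f$n, integer(1L))
  ids <- vapply(lens, route_length, integer(1L), partition = part)

  for (k in 1:6) if (!any(ids == k))
    stop2("empty range ", k, " (", part$lower[k], "-", part$upper[k],
          " residues): no training protein available")

  subnets <- vector("list", 6L)
  train_idx <- vector("list", 6L)
  val_idx <- vector("list", 6L)
  for (k in 1:6) {
    cand <- which(ids == k)
    take <- if (length(cand) > config$n_train)
      with_seed(config$seed + 1000L + k, sample(cand, config$n_train))
    else cand
    ## hold out whole proteins for early stopping when possible
    n_val <- if (length(take) >= 3L)
      max(1L, floor(config$val_fraction * length(take))) else 0L
    vp <- if (n_val > 0L)
      with_seed(config$seed + 2000L + k, sample(take, n_val))
    else integer(0)
    train_idx[[k]] <- setdiff(take, vp)
    val_idx[[k]] <- vp

    enc <- function(pi) {
      s <- part$separation[k]
      pairs <- separation_mask(lens[pi], s)
      labels <- dataset[[pi]]$map$cells[pairs]
      sel <- sample_training_pairs(labels, config$balance_factor,
                                   config$max_pairs_per_protein,
                                   seed = config$seed + 17L * pi)
      list(x = encode_pairs(feats[[pi]], pairs[sel, , drop = FALSE],
                            segment_scheme = config$segment_scheme),
           y = labels[sel])
    }
    tr <- lapply(train_idx[[k]], enc)
    va <- lapply(val_idx[[k]], enc)
    X <- do.call(rbind, lapply(tr, `[[`, "x"))
    y <- unlist(lapply(tr, `[[`, "y"))
    net <- init_network(c(1747L, 5L, 1L), seed = config$seed + k)
    tc <- train_config(learning_rate = config$learning_rate,
                       momentum = config$momentum,
                       max_epochs = config$epochs_subnet,
                       patience = config$patience,
                       val_fraction = config$val_fraction,
                       seed = config$seed + 100L + k)
    subnets[[k]] <- if (length(va) > 0L)
      nn_train(net, X, y, tc,
               X_val = do.call(rbind, lapply(va, `[[`, "x")),
               y_val = unlist(lapply(va, `[[`, "y")))
    else nn_train(net, X, y, tc)
  }

  ## second stage: consulted sub-network outputs on balanced pairs of
  ## every training protein -> cascade inputs; fit on the fit
  ## proteins, early-stop on the held-out proteins; the same
  ## probabilities feed the per-range threshold optimization
  stage2 <- function(pi) {
    k <- ids[pi]
    s <- part$separation[k]
    pairs <- separation_mask(lens[pi], s)
    labels <- dataset[[pi]]$map$cells[pairs]
    sel <- sample_training_pairs(labels, 1.0,
                                 config$max_pairs_per_protein,
                                 seed = config$seed + 31L * pi)
    X <- encode_pairs(feats[[pi]], pairs[sel, , drop = FALSE],
                      segment_scheme = config$segment_scheme)
    consulted <- corresponding_subnets(k)
    w3 <- balance_weights(lens[pi], part)
    C <- matrix(0, nrow(X), 9L)
    own <- NULL
    for (cid in consulted) {
      p <- nn_forward(subnets[[cid]], X)
      if (config$slotting == "slotted") C[, cid] <- p
      else C[, 2L + (cid - k)] <- p
      if (cid == k) own <- p
    }
    C[, 7L] <- w3[1L]; C[, 8L] <- w3[2L]; C[, 9L] <- w3[3L]
    list(C = C, y = labels[sel], own = own, k = k)
  }
  fit2 <- lapply(sort(unlist(train_idx)), stage2)
  val2 <- lapply(sort(unlist(val_idx)), stage2)

  Cmat <- do.call(rbind, lapply(fit2, `[[`, "C"))
  cy <- unlist(lapply(fit2, `[[`, "y"))
  casc <- init_network(c(9L, 6L, 1L), seed = config$seed + 7L)
  tc <- train_config(learning_rate = config$learning_rate,
                     momentum = config$momentum,
                     max_epochs = config$epochs_cascade,
                     patience = config$patience,
                     val_fraction = config$val_fraction,
                     seed = config$seed + 107L)
  casc <- if (length(val2) > 0L)
    nn_train(casc, Cmat, cy, tc,
             X_val = do.call(rbind, lapply(val2, `[[`, "C")),
             y_val = unlist(lapply(val2, `[[`, "y")))
  else nn_train(casc, Cmat, cy, tc)

  sub_thr <- part$threshold
  cas_thr <- part$threshold
  if (isTRUE(config$optimize_thresholds)) {
    ## thresholds tuned on all training proteins (fit + held-out)
    all2 <- c(fit2, val2)
    kvec <- vapply(all2, `[[`, integer(1L), "k")
    for (k in 1:6) {
      blocks <- all2[kvec == k]
      if (length(blocks) == 0L) next
      yk <- unlist(lapply(blocks, `[[`, "y"))
      if (length(unique(yk)) < 2L) next
      own <- unlist(lapply(blocks, `[[`, "own"))
      sub_thr[k] <- optimize_threshold(own, yk, config$threshold_grid)
      cas_k <- nn_forward(casc, do.call(rbind, lapply(blocks, `[[`, "C")))
      cas_thr[k] <- optimize_threshold(cas_k, yk, config$threshold_grid)
    }
  }

  cascade_bundle(subnets, casc, part,
                 subnet_thresholds = sub_thr,
                 cascade_thresholds = cas_thr,
                 slotting = config$slotting,
                 segment_scheme = config$segment_scheme,
                 trained = TRUE, seed = config$seed)
}

#' Save / load a bundle directory
#'
#' Writes six sub-network model files, the cascade model file and a
#' JSON manifest (partition, separations, thresholds, balance rule,
#' seeds, layout switches).
#'
#' @param bundle a [cascade_bundle()].
#' @param dir bundle directory.
#' @return `save_bundle` returns `dir` invisibly; `load_bundle` the
#'   bundle.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in 1:6)
    save_network(bundle$subnets[[k]],
                 file.path(dir, sprintf("subnet_%d.json", k)))
  save_network(bundle$cascade, file.path(dir, "cascade.json"))
  manifest <- list(
    format = "cascade-bundle-1",
    partition = bundle$partition,
    subnet_thresholds = bundle$subnet_thresholds,
    cascade_thresholds = bundle$cascade_thresholds,
    balance_rule = "inverse_midpoint_distance",
    slotting = bundle$slotting,
    segment_scheme = bundle$segment_scheme,
    trained = bundle$trained,
    seed = bundle$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "cascade-bundle-1"))
    stop2("unknown bundle format")
  subnets <- lapply(1:6, function(k)
    load_network(file.path(dir, sprintf("subnet_%d.json", k))))
  casc <- load_network(file.path(dir, "cascade.json"))
  part <- structure(as.data.frame(man$partition),
                    class = c("length_partition", "data.frame"))
  cascade_bundle(subnets, casc, part,
                 subnet_thresholds = as.numeric(man$subnet_thresholds),
                 cascade_thresholds = as.numeric(man$cascade_thresholds),
                 slotting = man$slotting,
                 segment_scheme = man$segment_scheme,
                 trained = isTRUE(man$trained),
                 seed = if (is.null(man$seed)) NA_integer_ else man$seed)
}

#' Write a prediction in CASP RR dialect
#'
#' Header `PFRMAT RR` and `TARGET`, then one line `i j 0 8 p` per
#' scored pair (1-based indices, distance bounds 0 and 8 Angstrom,
#' probability `p`), sorted by decreasing probability, then `END`.
#'
#' @param pmap a [predict_map()] result.
#' @param file output path.
#' @param target target identifier for the header.
#' @return `file`, invisibly.
#' @export
write_rr <- function(pmap, file, target = "T0000") {
  o <- order(-pmap$prob, pmap$pairs[, 1L], pmap$pairs[, 2L])
  lines <- c("PFRMAT RR",
             paste("TARGET", target),
             sprintf("%d %d 0 8 %.6f",
                     pmap$pairs[o, 1L], pmap$pairs[o, 2L], pmap$prob[o]),
             "END")
  writeLines(lines, file)
  invisible(file)
}

#' Read a CASP RR-dialect prediction file
#'
#' @param file path written by [write_rr()] (or any RR file with
#'   `i j d1 d2 p` body lines).
#' @return list with `target`, `pairs` (m x 2 integer matrix) and
#'   `prob`.
#' @export
read_rr <- function(file) {
  lines <- readLines(file)
  tgt <- sub("^TARGET\\s+", "", grep("^TARGET", lines, value = TRUE)[1L])
  body <- grep("^[0-9]+\\s+[0-9]+\\s", lines, value = TRUE)
  if (length(body) == 0L)
    return(list(target = tgt,
                pairs = matrix(integer(0), 0L, 2L,
                               dimnames = list(NULL, c("i", "j"))),
                prob = numeric(0)))
  f <- do.call(rbind, strsplit(trimws(body), "[[:space:]]+"))
  pairs <- cbind(i = as.integer(f[, 1L]), j = as.integer(f[, 2L]))
  list(target = tgt, pairs = pairs, prob = as.numeric(f[, 5L]))
}
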