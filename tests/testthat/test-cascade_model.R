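test_that("the shipped partition matches the routing table", {
  p <- length_partition()
  expect_equal(p$lower, c(51, 71, 91, 131, 191, 291))
  expect_equal(p$upper, c(70, 90, 130, 190, 290, 450))
  expect_equal(p$separation, c(6, 7, 10, 13, 17, 21))
  expect_equal(p$threshold, c(0.1, 0.6, 0.7, 0.7, 0.8, 0.9))
  # every supported integer length maps to exactly one range
  ids <- vapply(51:450, route_length, integer(1))
  expect_true(all(ids %in% 1:6))
  expect_equal(sum(ids == 3), 130 - 91 + 1)
  expect_true(all(diff(p$separation) >= 0))
})

test_that("length routing matches the published ranges", {
  expect_equal(route_length(100), 3L)
  expect_equal(route_length(51), 1L)
  expect_equal(route_length(450), 6L)
  expect_error(route_length(50), "unsupported length")
  expect_error(route_length(451), "unsupported length")
})

test_that("consulted sub-networks are the routed one and its neighbours", {
  expect_equal(corresponding_subnets(3), c(2, 3, 4))
  expect_equal(corresponding_subnets(1), c(1, 2))
  expect_equal(corresponding_subnets(6), c(5, 6))
})

test_that("balance weights are a normalized inverse-distance rule", {
  p <- length_partition()
  for (len in c(55, 110, 240, 445)) {
    w <- balance_weights(len, p)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  # at a range midpoint the own weight dominates
  w <- balance_weights(110, p)  # midpoint of 91-130 is 110.5, close enough
  expect_gt(w["own"], w["left"])
  expect_gt(w["own"], w["right"])
  # nearer the right edge, the right neighbour gains weight
  expect_gt(balance_weights(70, p)["right"], balance_weights(51, p)["right"])
  # a missing neighbour has zero weight
  expect_equal(unname(balance_weights(51, p)["left"]), 0)
})

test_that("the cascade input slots probabilities by sub-network id", {
  v <- cascade_input(c(`2` = 0.4, `3` = 0.9, `4` = 0.5), c(0.2, 0.6, 0.2))
  expect_equal(v, c(0, 0.4, 0.9, 0.5, 0, 0, 0.2, 0.6, 0.2))
  edge <- cascade_input(c(`1` = 0.7, `2` = 0.3), c(0, 0.8, 0.2))
  expect_length(edge, 9L)
  expect_equal(edge[3:6], rep(0, 4))
  expect_equal(edge[7], 0)
  packed <- cascade_input(c(`2` = 0.4, `3` = 0.9, `4` = 0.5),
                          c(0.2, 0.6, 0.2), slotting = "packed")
  expect_equal(packed[1:3], c(0.4, 0.9, 0.5))
  expect_error(cascade_input(numeric(0), c(1, 0, 0)), "empty cascade input")
})

test_that("threshold optimization finds where coverage collapses", {
  # construct labels/probabilities whose coverage profile over the grid
  # 0.1/0.3/0.5/0.7/0.9 is approximately (0.90, 0.88, 0.85, 0.30, 0.05):
  # the biggest drop (0.85 -> 0.30) begins at threshold 0.5
  npos <- 100
  pos_p <- c(rep(0.95, 5), rep(0.8, 25), rep(0.6, 55), rep(0.4, 3),
             rep(0.2, 2), rep(0.05, 10))
  stopifnot(length(pos_p) == npos)
  neg_p <- rep(0.01, 50)
  probs <- c(pos_p, neg_p)
  truths <- c(rep(1, npos), rep(0, 50))
  grid <- seq(0.1, 0.9, by = 0.2)
  cov_at <- vapply(grid, function(t) mean(pos_p >= t), numeric(1))
  expect_equal(cov_at, c(0.90, 0.88, 0.85, 0.30, 0.05))
  expect_equal(optimize_threshold(probs, truths, grid), 0.5)
  # strictly linear decline -> tie broken toward the smaller threshold
  lin_pos <- seq(0.05, 0.95, length.out = 20)
  expect_equal(optimize_threshold(c(lin_pos, 0.01), c(rep(1, 20), 0),
                                  seq(0.1, 0.9, by = 0.2)), 0.1)
  expect_error(optimize_threshold(c(0.5, 0.6), c(1, 1)), "cannot optimize")
})

test_that("constant sub-networks propagate through the cascade as 0.5", {
  b <- stub_bundle()
  aln <- synth_msa(strrep("ACDEFGHIKL", 6), 5, 0.2, seed = 1)
  pm <- predict_map(b, alignment_features(aln))
  expect_s3_class(pm, "prediction_map")
  expect_true(all(pm$prob == 0.5))
  expect_true(all(pm$subnet_prob == 0.5))
  # a 60-residue protein is routed to sub-network 1: separation >= 6
  expect_equal(pm$subnet_id, 1L)
  expect_true(all(pm$pairs[, 2] - pm$pairs[, 1] >= 6))
  # untrained bundles refuse to predict
  b$trained <- FALSE
  expect_error(predict_map(b, alignment_features(aln)), "model not trained")
})

test_that("raising the threshold never increases the number of calls", {
  b <- stub_bundle()
  # give the cascade net some spread so thresholds bite
  b$cascade <- init_network(c(9, 6, 1), seed = 3)
  aln <- synth_msa(strrep("ACDEFGHIKL", 6), 5, 0.2, seed = 2)
  f <- alignment_features(aln)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(t)
    sum(predict_map(b, f, threshold = t)$calls), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("prediction is deterministic and survives a bundle round-trip", {
  ds <- toy_dataset()
  cfg <- bundle_config(epochs_subnet = 15, epochs_cascade = 20,
                       max_pairs_per_protein = 150, seed = 5)
  b <- train_bundle(ds, cfg)
  pm1 <- predict_map(b, ds[[2]]$features)
  pm2 <- predict_map(b, ds[[2]]$features)
  expect_identical(pm1, pm2)
  dir <- withr::local_tempdir()
  save_bundle(b, dir)
  b2 <- load_bundle(dir)
  expect_identical(predict_map(b2, ds[[2]]$features)$prob, pm1$prob)
  expect_equal(b2$subnet_thresholds, b$subnet_thresholds)
  rr <- file.path(dir, "out.rr")
  write_rr(pm1, rr, target = "prot_002")
  back <- read_rr(rr)
  expect_equal(back$target, "prot_002")
  expect_equal(nrow(back$pairs), nrow(pm1$pairs))
  expect_equal(sort(back$prob, decreasing = TRUE), back$prob)
})

test_that("training requires every length range to be populated", {
  ds <- toy_dataset()[-6]  # drop the only 291-450 protein
  expect_error(train_bundle(ds, bundle_config(epochs_subnet = 5)),
               "empty range 6")
})
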