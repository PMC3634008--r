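test_that("accuracy and coverage reproduce hand-computed values", {
  truth <- rbind(c(1, 9), c(2, 10), c(3, 11), c(4, 12), c(5, 13), c(6, 14))
  pred4 <- rbind(c(1, 9), c(2, 10), c(3, 11), c(7, 15))  # 3 of 4 correct
  expect_equal(accuracy(pred4, truth), 75)
  expect_equal(coverage(pred4, truth), 50)               # 3 of 6 observed
  expect_equal(accuracy(truth, truth), 100)
  expect_equal(coverage(truth, truth), 100)
  expect_equal(accuracy(rbind(c(20, 30)), truth), 0)     # disjoint
  # pair order within a row is irrelevant
  expect_equal(accuracy(rbind(c(9, 1)), truth), 100)
})

test_that("undefined scores are reported as missing, not zero", {
  truth <- rbind(c(1, 9))
  empty <- matrix(integer(0), 0, 2)
  expect_warning(a <- accuracy(empty, truth), "undefined accuracy")
  expect_true(is.na(a))
  expect_warning(cv <- coverage(truth, empty), "undefined coverage")
  expect_true(is.na(cv))
})

test_that("counting identities hold for random prediction/truth sets", {
  for (seed in 1:6) {
    sets <- contactcascade:::with_seed(seed, {
      all_pairs <- separation_mask(30L, 6L)
      list(pred = all_pairs[sample(nrow(all_pairs), 40), ],
           obs = all_pairs[sample(nrow(all_pairs), 25), ])
    })
    s <- contact_scores(sets$pred, sets$obs)
    expect_lte(s$n_correct, s$n_predicted)
    expect_lte(s$n_correct, s$n_observed)
    expect_equal(s$accuracy * s$n_predicted, 100 * s$n_correct)
    # shared numerator: equal set sizes would give equal scores
    if (s$n_predicted == s$n_observed)
      expect_equal(s$accuracy, s$coverage)
  }
})

test_that("aggregation reports macro mean, SD and SE and skips NAs", {
  df <- data.frame(accuracy = c(40, 60), coverage = c(30, 50),
                   n_correct = 1, n_predicted = 2, n_observed = 3)
  rep <- aggregate_scores(df)
  acc <- rep$summary[rep$summary$metric == "accuracy", ]
  expect_equal(acc$mean, 50)
  expect_equal(acc$sd, sqrt((10^2 + 10^2) / 1), tolerance = 1e-6) # 14.142
  expect_equal(acc$se, 10)
  # single protein: mean is the score, dispersion zero by convention
  one <- aggregate_scores(df[1, ])
  expect_equal(one$summary$mean[1], 40)
  expect_equal(one$summary$sd[1], 0)
  # permutation invariance
  expect_equal(aggregate_scores(df[2:1, ])$summary$mean,
               rep$summary$mean)
  # NA rows are excluded and counted
  df2 <- rbind(df, data.frame(accuracy = NA, coverage = 20, n_correct = 0,
                              n_predicted = 0, n_observed = 4))
  r2 <- aggregate_scores(df2)
  expect_equal(r2$summary$mean[r2$summary$metric == "accuracy"], 50)
  expect_equal(r2$summary$n_excluded[r2$summary$metric == "accuracy"], 1)
  expect_error(aggregate_scores(df[0, ]), "nothing to aggregate")
})

test_that("top-n selection sorts by probability with deterministic ties", {
  m <- list(pairs = rbind(c(1, 9), c(2, 10), c(1, 10)),
            prob = c(0.9, 0.7, 0.4))
  expect_equal(unname(top_n_select(m, 2)), rbind(c(1, 9), c(2, 10)))
  tie <- list(pairs = rbind(c(2, 9), c(1, 10)), prob = c(0.5, 0.5))
  expect_equal(unname(top_n_select(tie, 1)), rbind(c(1, 10)))
  expect_equal(nrow(top_n_select(m, 10)), 3L)  # saturates
})

test_that("the top-n protocol evaluates at n = T/2, 2T/3 and T", {
  truth <- separation_mask(20L, 6L)[1:12, ]   # T = 12
  perfect <- list(pairs = truth, prob = seq(1, 0.5, length.out = 12))
  rep <- compare_protocol(list(perfect), list(truth))
  expect_equal(rep$settings$n, c(6, 8, 12))
  expect_equal(rep$settings$accuracy, rep(100, 3))
  expect_equal(rep$settings$coverage, c(50, 200 / 3, 100))
  # at n = T a perfect predictor has accuracy == coverage
  expect_equal(rep$settings$accuracy[3], rep$settings$coverage[3])
  # floor arithmetic on the fractions
  truth13 <- separation_mask(20L, 6L)[1:13, ]
  p13 <- list(pairs = truth13, prob = seq(1, 0.5, length.out = 13))
  expect_equal(compare_protocol(list(p13), list(truth13))$settings$n,
               c(6, 8, 13))
  expect_error(compare_protocol(list(perfect),
                                list(matrix(integer(0), 0, 2))),
               "no observed contacts")
})

test_that("pooling over proteins is order-invariant", {
  t1 <- separation_mask(15L, 6L)[1:4, ]
  t2 <- separation_mask(18L, 6L)[5:10, ]
  m1 <- list(pairs = separation_mask(15L, 6L),
             prob = seq(0.99, 0.01, length.out = nrow(separation_mask(15L, 6L))))
  m2 <- list(pairs = separation_mask(18L, 6L),
             prob = seq(0.98, 0.02, length.out = nrow(separation_mask(18L, 6L))))
  a <- compare_protocol(list(m1, m2), list(t1, t2))
  b <- compare_protocol(list(m2, m1), list(t2, t1))
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$coverage, b$coverage)
})
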