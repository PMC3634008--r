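test_that("initialization is seeded and has the right parameter counts", {
  a <- init_network(c(1747, 5, 1), seed = 42)
  b <- init_network(c(1747, 5, 1), seed = 42)
  expect_identical(a, b)
  expect_equal(n_parameters(init_network(c(9, 6, 1))), 67L)
  expect_equal(n_parameters(a), 8746L)
  expect_error(init_network(c(3, 0, 1)), "bad architecture")
})

test_that("the forward pass matches manual arithmetic", {
  net <- init_network(c(2, 2, 1), seed = 1)
  net$W1 <- matrix(c(0.5, -0.25, 1.0, 0.75), 2, 2)
  net$b1 <- c(0.1, -0.2)
  net$W2 <- matrix(c(0.3, -0.6), 2, 1)
  net$b2 <- 0.05
  x <- c(1.0, 2.0)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- sig(c(1 * 0.5 + 2 * -0.25 + 0.1, 1 * 1.0 + 2 * 0.75 - 0.2))
  want <- sig(h[1] * 0.3 + h[2] * -0.6 + 0.05)
  expect_equal(nn_forward(net, x), want)
  # zero weights -> sigmoid(0) = 0.5 regardless of input
  net$W1[] <- 0; net$b1[] <- 0; net$W2[] <- 0; net$b2[] <- 0
  expect_equal(nn_forward(net, c(13, -4)), 0.5)
  expect_error(nn_forward(net, c(1, 2, 3)), "bad input width")
})

test_that("outputs always lie strictly inside (0, 1)", {
  for (seed in 1:5) {
    net <- init_network(c(6, 3, 1), seed = seed)
    x <- matrix(contactcascade:::with_seed(seed, stats::rnorm(60, sd = 5)),
                10, 6)
    p <- nn_forward(net, x)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("backprop gradients match central finite differences", {
  numeric_grad <- function(net, X, y, field, eps = 1e-6) {
    v <- net[[field]]
    g <- v
    for (k in seq_along(v)) {
      up <- net; up[[field]][k] <- v[k] + eps
      dn <- net; dn[[field]][k] <- v[k] - eps
      g[k] <- (contactcascade:::bce_loss(nn_forward(up, X), y) -
               contactcascade:::bce_loss(nn_forward(dn, X), y)) / (2 * eps)
    }
    g
  }
  for (seed in 1:4) {
    net <- init_network(c(3, 2, 1), seed = seed)
    X <- matrix(contactcascade:::with_seed(seed, stats::rnorm(18)), 6, 3)
    y <- rep(c(0, 1), 3)
    g <- nn_gradient(net, X, y)
    for (field in c("W1", "b1", "W2", "b2")) {
      expect_lt(max(abs(g[[field]] - numeric_grad(net, X, y, field))),
                1e-6)
    }
  }
})

test_that("balanced sampling equalizes the classes", {
  y <- c(rep(1, 10), rep(0, 100))
  s <- balanced_sample(y, factor = 1.0, seed = 1)
  expect_equal(sum(y[s] == 1), 10)
  expect_equal(sum(y[s] == 0), 10)
  # already balanced input, factor 1 -> identity up to order
  yb <- rep(c(0, 1), 8)
  expect_setequal(balanced_sample(yb, 1.0, seed = 2), seq_along(yb))
  # the balancing probability factor shrinks both classes equally
  s5 <- balanced_sample(y, factor = 0.5, seed = 3)
  expect_equal(sum(y[s5] == 1), sum(y[s5] == 0))
  expect_identical(s5, balanced_sample(y, factor = 0.5, seed = 3))
  expect_error(balanced_sample(rep(1, 5)), "cannot balance")
})

test_that("training reaches a separable dataset and is reproducible", {
  ds <- separable_dataset(200, seed = 0)
  net <- init_network(c(1747, 5, 1), seed = 0)
  cfg <- train_config(max_epochs = 300, seed = 0)
  tr1 <- nn_train(net, ds$x, ds$y, cfg)
  expect_gte(mean((nn_forward(tr1, ds$x) >= 0.5) == ds$y), 0.95)
  tr2 <- nn_train(net, ds$x, ds$y, cfg)
  expect_identical(tr1$W1, tr2$W1)  # bit-reproducible
  expect_error(nn_train(net, ds$x[0, , drop = FALSE], integer(0)),
               "no samples")
})

test_that("a single repeated positive sample is driven towards 1", {
  net <- init_network(c(4, 3, 1), seed = 2)
  X <- matrix(rep(c(0.2, 0.8, 0.1, 0.5), 8), 8, 4, byrow = TRUE)
  y <- rep(1, 8)
  tr <- nn_train(net, X, y,
                 train_config(learning_rate = 0.5, momentum = 0,
                              max_epochs = 200, val_fraction = 0))
  h <- attr(tr, "history")
  expect_true(all(diff(h$train_loss) <= 1e-12))
  expect_gt(nn_forward(tr, X[1, ]), 0.95)
})

test_that("full-batch loss is non-increasing at a small learning rate", {
  ds <- separable_dataset(60, seed = 4)
  net <- init_network(c(1747, 5, 1), seed = 4)
  tr <- nn_train(net, ds$x, ds$y,
                 train_config(learning_rate = 1e-3, momentum = 0,
                              max_epochs = 50, val_fraction = 0))
  h <- attr(tr, "history")
  expect_true(all(diff(h$train_loss) <= 1e-12))
})

test_that("model files round-trip exactly", {
  net <- init_network(c(9, 6, 1), seed = 9)
  net$threshold <- 0.7
  f <- withr::local_tempfile(fileext = ".json")
  save_network(net, f)
  back <- load_network(f)
  expect_equal(back$layer_sizes, net$layer_sizes)
  expect_identical(back$W1, net$W1)
  expect_identical(back$W2, net$W2)
  expect_equal(back$threshold, 0.7)
  x <- seq(0.1, 0.9, length.out = 9)
  expect_identical(nn_forward(net, x), nn_forward(back, x))
})
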