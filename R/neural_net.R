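## Plain 3-layer feed-forward networks (logistic sigmoid throughout)
## trained by standard back-propagation on binary cross-entropy, with
## momentum, optional early stopping and balanced sampling. These nets
## are deliberately small (two weight matrices); no autodiff.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize a 3-layer feed-forward network
#'
#' Weights are drawn uniformly from (-1/sqrt(fan_in), +1/sqrt(fan_in));
#' biases start at zero. Reproducible given `seed`.
#'
#' @param layer_sizes integer 3-vector (inputs, hidden, outputs),
#'   e.g. `c(1747, 5, 1)` for a sub-network or `c(9, 6, 1)` for the
#'   cascade network.
#' @param seed integer seed.
#' @return an object of class `ffnet`.
#' @export
init_network <- function(layer_sizes, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) != 3L || any(layer_sizes <= 0L))
    stop2("bad architecture: three positive layer sizes required")
  ni <- layer_sizes[1L]; nh <- layer_sizes[2L]; no <- layer_sizes[3L]
  with_seed(seed, {
    r1 <- 1 / sqrt(ni); r2 <- 1 / sqrt(nh)
    structure(list(
      layer_sizes = layer_sizes,
      W1 = matrix(stats::runif(ni * nh, -r1, r1), ni, nh),
      b1 = numeric(nh),
      W2 = matrix(stats::runif(nh * no, -r2, r2), nh, no),
      b2 = numeric(no),
      activation = "sigmoid",
      seed = as.integer(seed),
      threshold = NA_real_
    ), class = "ffnet")
  })
}

#' @export
print.ffnet <- function(x, ...) {
  cat("ffnet:", paste(x$layer_sizes, collapse = "-"),
      "(", n_parameters(x), "parameters ) threshold:", x$threshold, "\n")
  invisible(x)
}

#' Number of free parameters of a network
#' @param model an `ffnet`.
#' @return integer parameter count (weights + biases).
#' @export
n_parameters <- function(model) {
  length(model$W1) + length(model$b1) + length(model$W2) + length(model$b2)
}

## forward pass keeping the hidden activations (for backprop)
forward_full <- function(model, X) {
  H <- sigmoid(sweep(X %*% model$W1, 2L, model$b1, "+"))
  P <- sigmoid(sweep(H %*% model$W2, 2L, model$b2, "+"))
  list(H = H, P = P)
}

#' Forward pass through a network
#'
#' @param model an `ffnet`.
#' @param x numeric input vector of length `layer_sizes[1]`, or a
#'   matrix with that many columns (one row per sample).
#' @return output probability (strictly in (0, 1)), one per row.
#' @export
nn_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$layer_sizes[1L]) stop2("bad input width")
  drop(forward_full(model, x)$P)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Back-propagation gradient of the mean cross-entropy
#'
#' Exact analytic gradient of mean binary cross-entropy with respect
#' to all weights and biases (the quantity checked against central
#' finite differences in the test suite).
#'
#' @param model an `ffnet`.
#' @param X input matrix (n x inputs).
#' @param y binary labels (length n).
#' @return list with elements `W1`, `b1`, `W2`, `b2`.
#' @export
nn_gradient <- function(model, X, y) {
  n <- nrow(X)
  fw <- forward_full(model, X)
  dZ2 <- (fw$P - y) / n                         # sigmoid + BCE shortcut
  dH <- tcrossprod(dZ2, model$W2) * fw$H * (1 - fw$H)
  list(W1 = crossprod(X, dH), b1 = colSums(dH),
       W2 = crossprod(fw$H, dZ2), b2 = colSums(dZ2))
}

#' Training configuration
#'
#' Back-propagation hyperparameters. The defaults are package choices
#' (full-batch gradient descent, learning rate 1.0, momentum 0.9, at
#' most 500 epochs, early stopping with patience 50 on a 20%
#' validation split); all are exposed because none is dictated by the
#' method itself. The learning rate looks large, but the gradient of
#' the mean cross-entropy over a full batch of sparse \[0, 1\]
#' features is small; much lower rates leave the network at its
#' initialization.
#'
#' @param learning_rate positive step size.
#' @param momentum momentum coefficient in \[0, 1).
#' @param max_epochs maximum full-batch epochs.
#' @param patience epochs without validation improvement before
#'   stopping (ignored when `val_fraction = 0`).
#' @param val_fraction fraction of samples held out for early
#'   stopping (0 disables; patience then watches the training loss).
#' @param balance_factor balancing probability factor in (0, 1]: after
#'   class balancing, a further random keep-probability applied by
#'   [balanced_sample()] to shrink the training set.
#' @param seed integer seed governing the validation split (and any
#'   caller-side sampling).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1.0, momentum = 0.9,
                         max_epochs = 500L, patience = 50L,
                         val_fraction = 0.2, balance_factor = 1.0,
                         seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            max_epochs >= 1, patience >= 1,
            val_fraction >= 0, val_fraction < 1,
            balance_factor > 0, balance_factor <= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 balance_factor = balance_factor,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a network by standard back-propagation
#'
#' Full-batch gradient descent with momentum on mean binary
#' cross-entropy. With a validation split, training stops once the
#' validation loss has not improved for `patience` epochs and the
#' best-validation weights are restored. Fully deterministic given
#' `config$seed`.
#'
#' @param model an initialized `ffnet`.
#' @param X input matrix (n x inputs).
#' @param y binary labels (length n).
#' @param config a [train_config()].
#' @param X_val,y_val optional explicit validation set for early
#'   stopping (e.g. pairs from held-out proteins, which measures
#'   cross-protein generalization much better than a random row
#'   split); when supplied, `config$val_fraction` is ignored.
#' @return the trained `ffnet`, with attribute `"history"` (a data
#'   frame of per-epoch train/validation losses).
#' @export
nn_train <- function(model, X, y, config = train_config(),
                     X_val = NULL, y_val = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = length(y))
  n <- nrow(X)
  if (n == 0L) stop2("no samples")
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  if (ncol(X) != model$layer_sizes[1L]) stop2("bad input width")

  if (!is.null(X_val)) {
    use_val <- TRUE
    Xtr <- X; ytr <- y
    Xv <- X_val; yv <- y_val
  } else {
    n_val <- floor(config$val_fraction * n)
    use_val <- n_val >= 2L
    idx_val <- if (use_val)
      with_seed(config$seed, sample.int(n, n_val)) else integer(0)
    idx_tr <- setdiff(seq_len(n), idx_val)
    Xtr <- X[idx_tr, , drop = FALSE]; ytr <- y[idx_tr]
    Xv <- X[idx_val, , drop = FALSE]; yv <- y[idx_val]
  }

  v <- list(W1 = model$W1 * 0, b1 = model$b1 * 0,
            W2 = model$W2 * 0, b2 = model$b2 * 0)
  best <- model; best_loss <- Inf; wait <- 0L
  hist_tr <- hist_val <- numeric(config$max_epochs)
  ep_done <- 0L

  for (ep in seq_len(config$max_epochs)) {
    g <- nn_gradient(model, Xtr, ytr)
    for (nm in names(v)) {
      v[[nm]] <- config$momentum * v[[nm]] - config$learning_rate * g[[nm]]
      model[[nm]] <- model[[nm]] + v[[nm]]
    }
    tl <- bce_loss(nn_forward(model, Xtr), ytr)
    vl <- if (use_val) bce_loss(nn_forward(model, Xv), yv) else tl
    ep_done <- ep
    hist_tr[ep] <- tl; hist_val[ep] <- vl
    if (vl < best_loss - 1e-9) {
      best_loss <- vl; best <- model; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  out <- best
  attr(out, "history") <- data.frame(epoch = seq_len(ep_done),
                                     train_loss = hist_tr[seq_len(ep_done)],
                                     val_loss = hist_val[seq_len(ep_done)])
  out
}

#' Balanced sampling of a two-class label vector
#'
#' Classical balanced training for contact prediction: contacts are
#' vastly outnumbered by non-contacts, so an equal number of each
#' class is drawn without replacement (`min(#pos, #neg)` per class at
#' `factor = 1`). The balancing probability `factor` further shrinks
#' the selection at random while keeping the two class counts exactly
#' equal; with `negatives_only = TRUE` the factor thins only the
#' negative class.
#'
#' @param labels binary vector (0/1 or logical).
#' @param factor keep-probability in (0, 1].
#' @param seed integer seed (sampling is reproducible).
#' @param negatives_only apply `factor` to negatives only.
#' @return sorted integer vector of selected indices into `labels`.
#' @export
balanced_sample <- function(labels, factor = 1.0, seed = 1L,
                            negatives_only = FALSE) {
  y <- as.integer(labels)
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (length(pos) == 0L || length(neg) == 0L)
    stop2("cannot balance: a class is absent")
  stopifnot(factor > 0, factor <= 1)
  k <- min(length(pos), length(neg))
  with_seed(seed, {
    sp <- sample(pos, k); sn <- sample(neg, k)
    if (factor < 1) {
      m <- max(1L, stats::rbinom(1L, k, factor))
      if (negatives_only) sn <- sn[seq_len(m)]
      else { sp <- sp[seq_len(m)]; sn <- sn[seq_len(m)] }
    }
    sort(c(sp, sn))
  })
}

#' Save / load a network model file
#'
#' Single-file JSON container (`"ffnet-1"` format tag): architecture,
#' activation, seed, decision threshold and the dense weight matrices
#' at full double precision.
#'
#' @param model an `ffnet`.
#' @param file path to the model file.
#' @return `save_network` returns `file` invisibly; `load_network`
#'   returns the `ffnet`.
#' @export
save_network <- function(model, file) {
  obj <- list(format = "ffnet-1",
              layer_sizes = model$layer_sizes,
              activation = model$activation,
              seed = model$seed,
              threshold = model$threshold,
              W1 = model$W1, b1 = model$b1,
              W2 = model$W2, b2 = model$b2)
  jsonlite::write_json(obj, file, digits = I(17), auto_unbox = TRUE,
                       na = "null", matrix = "rowmajor")
  invisible(file)
}

#' @rdname save_network
#' @export
load_network <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(obj$format, "ffnet-1")) stop2("unknown model format")
  ls <- as.integer(obj$layer_sizes)
  as_mat <- function(w, nr) if (is.matrix(w)) w else matrix(w, nrow = nr)
  structure(list(
    layer_sizes = ls,
    W1 = as_mat(obj$W1, ls[1L]),
    b1 = as.numeric(obj$b1),
    W2 = as_mat(obj$W2, ls[2L]),
    b2 = as.numeric(obj$b2),
    activation = obj$activation,
    seed = as.integer(obj$seed),
    threshold = if (is.null(obj$threshold) || length(obj$threshold) == 0L)
      NA_real_ else as.numeric(obj$threshold)
  ), class = "ffnet")
}
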