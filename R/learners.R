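# Local learners with a uniform federation contract:
#   init_learner()     -> deterministic initial state
#   local_fit()        -> E epochs of local optimization, optional proximal
#                         penalty toward a global anchor (FedProx)
#   get_parameters() / set_parameters()  -> aggregable parameter transport
#   predict_scores()   -> case-probabilities in [0, 1]
#
# Three parametric kinds optimize mean regularized log-loss:
#   logistic_regression — full-batch gradient descent (one step per epoch)
#   sgd_linear          — per-sample stochastic gradient descent
#   mlp                 — one-hidden-layer tanh network, mini-batch GD
# The fourth kind, "forest", is a boosted tree ensemble (see forest.R).
#
# The proximal term (mu/2)||w - anchor||^2 is applied IMPLICITLY: after the
# loss-gradient step each tensor is pulled toward the anchor by the exact
# proximal map  w <- (w + eta*mu*anchor) / (1 + eta*mu).  This is stable for
# every mu >= 0 (mu -> Inf collapses onto the anchor instead of diverging)
# and reduces bitwise to the plain update at mu = 0.

LEARNER_KINDS <- c("logistic_regression", "sgd_linear", "mlp", "forest")

default_hyperparams <- function(kind) {
  base <- list(learning_rate = 0.1, l2 = 1e-4, batch_size = 32L,
               hidden = 32L, trees_per_round = 5L, max_depth = 3L,
               tree_eta = 0.3, tree_lambda = 1, min_node = 5L)
  # per-sample updates need a smaller base rate than batch updates
  if (kind == "sgd_linear") base$learning_rate <- 0.01
  base
}

#' Proximal penalty specification for FedProx local fitting
#'
#' @param mu Nonnegative proximal strength; 0 degenerates to plain FedAvg
#'   local fitting.
#' @param anchor The current global `ModelParams` (architecture must match
#'   the learner being fitted).
#' @return A `prox_spec` list.
#' @export
prox_spec <- function(mu, anchor) {
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    stop("prox mu must be a nonnegative scalar", call. = FALSE)
  structure(list(mu = mu, anchor = anchor), class = "prox_spec")
}

#' Initialize a local learner
#'
#' @param kind One of `"logistic_regression"`, `"sgd_linear"`, `"mlp"`,
#'   `"forest"`.
#' @param n_features Feature dimension d the learner will see.
#' @param hyperparams Named list overriding the defaults (`learning_rate`
#'   0.1, `l2` 1e-4, `batch_size` 32, `hidden` 32 units for the MLP;
#'   `trees_per_round` 5, `max_depth` 3, `tree_eta` 0.3, `tree_lambda` 1 for
#'   the forest).
#' @param seed Integer seed; initialization (and the learner's epoch shuffle
#'   schedule) is deterministic in it.
#' @return A `fed_learner` state.
#' @export
init_learner <- function(kind, n_features, hyperparams = list(), seed = 1L) {
  kind <- match.arg(kind, LEARNER_KINDS)
  stopifnot(is.numeric(n_features), n_features >= 1)
  d <- as.integer(n_features)
  hp <- default_hyperparams(kind)
  if (length(hyperparams)) {
    unknown <- setdiff(names(hyperparams), names(hp))
    if (length(unknown))
      stop("unknown hyperparameters: ", paste(unknown, collapse = ", "), call. = FALSE)
    hp[names(hyperparams)] <- hyperparams
  }
  params <- switch(kind,
    logistic_regression = ,
    sgd_linear = list(w = numeric(d), b = 0),
    mlp = {
      H <- as.integer(hp$hidden)
      with_seed(derive_seed(seed, "init", kind), {
        s1 <- 1 / sqrt(d)
        s2 <- 1 / sqrt(H)
        list(W1 = matrix(stats::runif(d * H, -s1, s1), d, H),
             b1 = numeric(H),
             W2 = matrix(stats::runif(H, -s2, s2), H, 1L),
             b2 = 0)
      })
    },
    forest = list(trees = list())
  )
  structure(list(kind = kind, n_features = d, hyper = hp, params = params,
                 seed = as.integer(seed), epochs_done = 0L),
            class = "fed_learner")
}

#' @export
print.fed_learner <- function(x, ...) {
  cat(sprintf("<fed_learner %s: d=%d, %d epochs fitted>\n",
              x$kind, x$n_features, x$epochs_done))
  invisible(x)
}

#' Extract / load aggregable model parameters
#'
#' `get_parameters()` returns the learner's parameters in aggregable form (a
#' named list of numeric tensors, or the tree list for the forest kind);
#' `set_parameters()` loads parameters of the identical architecture back
#' (the broadcast step of a federation round). `set(get(state))` leaves
#' predictions unchanged.
#'
#' @param state A `fed_learner`.
#' @param params A parameter list as returned by `get_parameters()`.
#' @return `get_parameters()`: the parameter list; `set_parameters()`: the
#'   updated state.
#' @export
get_parameters <- function(state) {
  stopifnot(inherits(state, "fed_learner"))
  state$params
}

#' @rdname get_parameters
#' @export
set_parameters <- function(state, params) {
  stopifnot(inherits(state, "fed_learner"))
  if (state$kind == "forest") {
    if (!is.list(params) || is.null(params$trees))
      stop("forest parameters must carry a `trees` list", call. = FALSE)
    state$params <- params
    return(state)
  }
  check_architecture(state$params, params)
  state$params <- params
  state
}

check_architecture <- function(ref, params) {
  if (!identical(names(ref), names(params)))
    stop("parameter tensor names differ: expected {",
         paste(names(ref), collapse = ", "), "}, got {",
         paste(names(params), collapse = ", "), "}", call. = FALSE)
  bad <- names(ref)[!vapply(names(ref), function(nm) {
    identical(dim_or_len(ref[[nm]]), dim_or_len(params[[nm]]))
  }, logical(1))]
  if (length(bad))
    stop("parameter tensor shape mismatch for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# Exact proximal map applied after a loss-gradient step.
prox_shrink <- function(value, anchor, eta, mu) {
  if (mu == 0) return(value)
  (value + eta * mu * anchor) / (1 + eta * mu)
}

#' Fit a learner locally for a number of epochs
#'
#' Runs `epochs` epochs of the kind's local optimizer on the given shard,
#' starting from the state's current parameters. With a [prox_spec()], each
#' update additionally applies the exact proximal map toward the anchor
#' (FedProx local objective: mean log-loss + (mu/2)||w - anchor||^2). The
#' forest kind instead grows `trees_per_round * epochs` boosted trees from
#' the incoming ensemble; the proximal penalty is unsupported for it.
#'
#' Epoch shuffles are seeded from the state's seed and its cumulative epoch
#' counter, so fitting E epochs equals E chained 1-epoch fits, and a
#' federation of one client replays central training exactly.
#'
#' @param state A `fed_learner`.
#' @param x Numeric feature matrix (rows = shard samples).
#' @param y Binary 0/1 label vector.
#' @param epochs Number of local epochs E (>= 1).
#' @param prox Optional [prox_spec()].
#' @return The updated `fed_learner`.
#' @export
local_fit <- function(state, x, y, epochs = 1L, prox = NULL) {
  stopifnot(inherits(state, "fed_learner"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (ncol(x) != state$n_features)
    stop(sprintf("feature dimension mismatch: learner expects %d, data has %d",
                 state$n_features, ncol(x)), call. = FALSE)
  if (length(y) != nrow(x)) stop("label length must match rows of x", call. = FALSE)
  if (!any(y == 1) || !any(y == 0))
    stop(sprintf("single-class shard (%d cases, %d controls): local fitting requires both classes",
                 sum(y == 1), sum(y == 0)), call. = FALSE)
  if (!is.null(prox)) {
    if (!inherits(prox, "prox_spec")) stop("prox must be a prox_spec", call. = FALSE)
    if (state$kind == "forest")
      stop("proximal penalty is unsupported for the forest learner", call. = FALSE)
    check_architecture(state$params, prox$anchor)
  }
  epochs <- as.integer(epochs)
  stopifnot(epochs >= 1L)
  switch(state$kind,
         logistic_regression = fit_logreg(state, x, y, epochs, prox),
         sgd_linear = fit_sgd(state, x, y, epochs, prox),
         mlp = fit_mlp(state, x, y, epochs, prox),
         forest = fit_forest(state, x, y, epochs))
}

fit_logreg <- function(state, x, y, epochs, prox) {
  hp <- state$hyper
  eta <- hp$learning_rate
  w <- state$params$w
  b <- state$params$b
  n <- nrow(x)
  mu <- if (is.null(prox)) 0 else prox$mu
  for (e in seq_len(epochs)) {
    p <- stats::plogis(drop(x %*% w) + b)
    gw <- drop(crossprod(x, p - y)) / n + hp$l2 * w
    gb <- mean(p - y)
    w <- w - eta * gw
    b <- b - eta * gb
    if (mu > 0) {
      w <- prox_shrink(w, prox$anchor$w, eta, mu)
      b <- prox_shrink(b, prox$anchor$b, eta, mu)
    }
  }
  state$params <- list(w = w, b = b)
  state$epochs_done <- state$epochs_done + epochs
  state
}

# Per-sample averaged SGD (textbook ASGD): updates run on the raw iterate
# with a Robbins-Monro decaying step size eta_t = eta0 / sqrt(t) (t counts
# updates cumulatively across epochs and rounds), while each epoch
# accumulates a running mean of the iterates and ends by collapsing onto it
# (the `average = TRUE` convention of standard SGD classifiers). The
# exported parameters therefore approximate the local empirical optimum
# rather than a noisy last iterate. Both the update counter and the
# averaging are per-epoch-chained, so E epochs equal E chained 1-epoch fits
# and a federation of one replays central training exactly.
fit_sgd <- function(state, x, y, epochs, prox) {
  hp <- state$hyper
  eta0 <- hp$learning_rate
  w <- state$params$w
  b <- state$params$b
  n <- nrow(x)
  mu <- if (is.null(prox)) 0 else prox$mu
  t_upd <- state$updates_done
  if (is.null(t_upd)) t_upd <- 0
  for (e in seq_len(epochs)) {
    ord <- with_seed(derive_seed(state$seed, "order", state$epochs_done + 1L),
                     sample.int(n))
    wsum <- numeric(length(w))
    bsum <- 0
    for (i in ord) {
      t_upd <- t_upd + 1
      eta <- eta0 / sqrt(t_upd)
      xi <- x[i, ]
      p <- stats::plogis(sum(xi * w) + b)
      r <- p - y[i]
      w <- w - eta * (r * xi + hp$l2 * w)
      b <- b - eta * r
      if (mu > 0) {
        w <- prox_shrink(w, prox$anchor$w, eta, mu)
        b <- prox_shrink(b, prox$anchor$b, eta, mu)
      }
      wsum <- wsum + w
      bsum <- bsum + b
    }
    w <- wsum / n
    b <- bsum / n
    state$epochs_done <- state$epochs_done + 1L
  }
  state$updates_done <- t_upd
  state$params <- list(w = w, b = b)
  state
}

fit_mlp <- function(state, x, y, epochs, prox) {
  hp <- state$hyper
  eta <- hp$learning_rate
  P <- state$params
  n <- nrow(x)
  bs <- min(as.integer(hp$batch_size), n)
  mu <- if (is.null(prox)) 0 else prox$mu
  for (e in seq_len(epochs)) {
    ord <- with_seed(derive_seed(state$seed, "order", state$epochs_done + 1L),
                     sample.int(n))
    starts <- seq(1L, n, by = bs)
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      nb <- length(idx)
      A1 <- tanh(sweep(xb %*% P$W1, 2L, P$b1, "+"))
      z <- drop(A1 %*% P$W2) + P$b2
      p <- stats::plogis(z)
      dz <- (p - yb) / nb
      gW2 <- crossprod(A1, dz) + hp$l2 * P$W2
      gb2 <- sum(dz)
      dA1 <- tcrossprod(dz, drop(P$W2)) * (1 - A1^2)
      gW1 <- crossprod(xb, dA1) + hp$l2 * P$W1
      gb1 <- colSums(dA1)
      P$W1 <- P$W1 - eta * gW1
      P$b1 <- P$b1 - eta * gb1
      P$W2 <- P$W2 - eta * gW2
      P$b2 <- P$b2 - eta * gb2
      if (mu > 0) {
        P$W1 <- prox_shrink(P$W1, prox$anchor$W1, eta, mu)
        P$b1 <- prox_shrink(P$b1, prox$anchor$b1, eta, mu)
        P$W2 <- prox_shrink(P$W2, prox$anchor$W2, eta, mu)
        P$b2 <- prox_shrink(P$b2, prox$anchor$b2, eta, mu)
      }
    }
    state$epochs_done <- state$epochs_done + 1L
  }
  state$params <- P
  state
}

#' Predict case-probabilities
#'
#' @param state A fitted (or initialized) `fed_learner`.
#' @param x Feature matrix with the learner's feature dimension.
#' @return Numeric vector of probabilities in \[0, 1\], one per row of `x`.
#' @export
predict_scores <- function(state, x) {
  stopifnot(inherits(state, "fed_learner"))
  x <- as.matrix(x)
  if (ncol(x) != state$n_features)
    stop(sprintf("feature dimension mismatch: learner expects %d, data has %d",
                 state$n_features, ncol(x)), call. = FALSE)
  switch(state$kind,
         logistic_regression = ,
         sgd_linear = stats::plogis(drop(x %*% state$params$w) + state$params$b),
         mlp = {
           A1 <- tanh(sweep(x %*% state$params$W1, 2L, state$params$b1, "+"))
           stats::plogis(drop(A1 %*% state$params$W2) + state$params$b2)
         },
         forest = stats::plogis(forest_margin(state$params, x)))
}

#' Train a learner centrally (no federation)
#'
#' Convenience wrapper: initialize and fit on the full training data for a
#' total number of epochs — the central baseline every federated variant is
#' compared against.
#'
#' @inheritParams init_learner
#' @param x,y Training features and 0/1 labels.
#' @param epochs Total training epochs.
#' @return A fitted `fed_learner`.
#' @export
train_central <- function(kind, x, y, epochs, hyperparams = list(), seed = 1L) {
  state <- init_learner(kind, ncol(as.matrix(x)), hyperparams, seed)
  local_fit(state, x, y, epochs = epochs)
}

#' Serialize model parameters to JSON
#' @param params A parameter list from [get_parameters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_params <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}
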