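test_that("initialization is deterministic and architecture-correct", {
  a <- init_learner("mlp", 10, seed = 3)
  b <- init_learner("mlp", 10, seed = 3)
  expect_identical(a$params, b$params)
  expect_equal(dim(a$params$W1), c(10L, 32L))
  expect_length(a$params$b1, 32L)
  expect_equal(dim(a$params$W2), c(32L, 1L))
  expect_length(a$params$b2, 1L)
  lr <- init_learner("logistic_regression", 7, seed = 1)
  expect_length(lr$params$w, 7L)
  expect_identical(lr$params$b, 0)
  fo <- init_learner("forest", 5, seed = 1)
  expect_length(fo$params$trees, 0L)
  expect_error(init_learner("svm", 5), "arg")
  expect_error(init_learner("mlp", 5, hyperparams = list(nope = 1)), "nope")
})

test_that("one full-batch logistic step matches the hand-computed gradient", {
  # two symmetric samples; mean log-loss gradient at w = 0 is
  # ((0.5-1)*1 + (0.5-0)*(-1)) / 2 = -0.5, bias gradients cancel
  x <- matrix(c(1, -1), 2, 1)
  y <- c(1, 0)
  eta <- 0.3
  st <- init_learner("logistic_regression", 1,
                     hyperparams = list(learning_rate = eta, l2 = 0), seed = 1)
  st <- local_fit(st, x, y, epochs = 1)
  expect_equal(st$params$w, eta * 0.5, tolerance = 1e-12)
  expect_equal(st$params$b, 0)
  # and against the generic oracle on an asymmetric shard
  sh <- make_shard(20, 4, seed = 2)
  st2 <- init_learner("logistic_regression", 4,
                      hyperparams = list(learning_rate = 0.2, l2 = 0.01))
  st2 <- local_fit(st2, sh$x, sh$y, epochs = 1)
  want <- oracle_logreg_step(sh$x, sh$y, numeric(4), 0, 0.2, 0.01)
  expect_equal(st2$params$w, want$w, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(st2$params$b, want$b, tolerance = 1e-10)
})

test_that("E epochs equal E chained single-epoch fits for every parametric kind", {
  sh <- make_shard(30, 5, seed = 4)
  for (kind in c("logistic_regression", "sgd_linear", "mlp")) {
    whole <- local_fit(init_learner(kind, 5, seed = 9), sh$x, sh$y, epochs = 3)
    chained <- init_learner(kind, 5, seed = 9)
    for (e in 1:3) chained <- local_fit(chained, sh$x, sh$y, epochs = 1)
    expect_identical(whole$params, chained$params)
  }
})

test_that("parameter get/set round-trips and rejects shape mismatches", {
  sh <- make_shard(30, 5, seed = 5)
  st <- local_fit(init_learner("mlp", 5, seed = 2), sh$x, sh$y, epochs = 2)
  xnew <- matrix(rnorm(50), 10, 5)
  st2 <- set_parameters(init_learner("mlp", 5, seed = 99), get_parameters(st))
  expect_identical(predict_scores(st2, xnew), predict_scores(st, xnew))
  wrong <- get_parameters(init_learner("mlp", 5, hyperparams = list(hidden = 8L)))
  expect_error(set_parameters(st, wrong), "W1")
  skinny <- get_parameters(init_learner("logistic_regression", 4))
  expect_error(set_parameters(init_learner("logistic_regression", 5), skinny), "w")
})

test_that("predicted scores follow the logistic link", {
  st <- init_learner("logistic_regression", 1)
  expect_equal(predict_scores(st, matrix(c(-5, 0, 5), 3, 1)), rep(0.5, 3))
  st <- set_parameters(st, list(w = 1, b = 0))
  expect_equal(predict_scores(st, matrix(0, 1, 1)), 0.5)
  expect_gt(predict_scores(st, matrix(50, 1, 1)), 1 - 1e-9)
  expect_error(predict_scores(st, matrix(0, 1, 2)), "dimension")
})

test_that("single-class shards and forest proximal fits are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  st <- init_learner("logistic_regression", 2)
  expect_error(local_fit(st, x, rep(1, 5)), "single-class")
  fo <- init_learner("forest", 2)
  anchor <- get_parameters(fo)
  expect_error(local_fit(fo, x, c(1, 0, 1, 0, 1),
                         prox = prox_spec(0.5, anchor)), "unsupported")
  expect_error(prox_spec(-1, anchor), "nonnegative")
})

test_that("a dominant proximal term pins parameters to the anchor", {
  sh <- make_shard(40, 6, seed = 6)
  for (kind in c("logistic_regression", "sgd_linear", "mlp")) {
    st0 <- init_learner(kind, 6, seed = 4)
    anchor <- get_parameters(st0)
    fit <- local_fit(st0, sh$x, sh$y, epochs = 3,
                     prox = prox_spec(1e9, anchor))
    expect_lt(param_dist(fit$params, anchor), 1e-3)
  }
})

test_that("mu = 0 proximal fitting is bitwise plain fitting", {
  sh <- make_shard(40, 6, seed = 7)
  for (kind in c("logistic_regression", "sgd_linear", "mlp")) {
    st0 <- init_learner(kind, 6, seed = 4)
    anchor <- get_parameters(st0)
    plain <- local_fit(st0, sh$x, sh$y, epochs = 2)
    prox0 <- local_fit(st0, sh$x, sh$y, epochs = 2,
                       prox = prox_spec(0, anchor))
    expect_identical(plain$params, prox0$params)
  }
})

test_that("distance to the anchor contracts monotonically in mu", {
  sh <- make_shard(50, 6, seed = 8)
  mus <- c(0, 0.5, 2, 10, 1e9)
  for (kind in c("logistic_regression", "sgd_linear", "mlp")) {
    st0 <- init_learner(kind, 6, seed = 11)
    anchor <- get_parameters(st0)
    d <- vapply(mus, function(mu) {
      fit <- local_fit(st0, sh$x, sh$y, epochs = 3,
                       prox = if (mu > 0) prox_spec(mu, anchor) else NULL)
      param_dist(fit$params, anchor)
    }, numeric(1))
    expect_true(all(diff(d) <= 1e-12))
    expect_lt(d[length(d)], 1e-3)
  }
})

test_that("a hand-built two-leaf tree scores by the logistic of its leaf value", {
  v <- 0.7
  tree <- list(node = list(leaf = FALSE, feature = 1L, threshold = 0,
                           left = list(leaf = TRUE, value = -v),
                           right = list(leaf = TRUE, value = v)),
               round = 1L, client = 1L)
  st <- set_parameters(init_learner("forest", 2), list(trees = list(tree)))
  x <- matrix(c(-1, 1, 0, 0), 2, 2)  # first row goes left, second right
  expect_equal(predict_scores(st, x), plogis(c(-v, v)))
})

test_that("boosted forest fitting reduces training log-loss and chains epochs", {
  sh <- make_shard(60, 4, seed = 9)
  st <- init_learner("forest", 4, hyperparams = list(trees_per_round = 3L))
  fit1 <- local_fit(st, sh$x, sh$y, epochs = 1)
  expect_length(fit1$params$trees, 3L)
  p0 <- rep(0.5, 60)
  p1 <- predict_scores(fit1, sh$x)
  ll <- function(p) -mean(sh$y * log(p) + (1 - sh$y) * log(1 - p))
  expect_lt(ll(p1), ll(p0))
  fit2 <- local_fit(fit1, sh$x, sh$y, epochs = 1)
  expect_length(fit2$params$trees, 6L)
  expect_identical(fit2$params$trees[1:3], fit1$params$trees)
  expect_lt(ll(predict_scores(fit2, sh$x)), ll(p1))
})

test_that("model parameters serialize to JSON", {
  st <- local_fit(init_learner("logistic_regression", 3),
                  make_shard(20, 3)$x, make_shard(20, 3)$y, epochs = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_params(get_parameters(st), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$w, unname(get_parameters(st)$w), tolerance = 1e-12)
})
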