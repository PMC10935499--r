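test_that("aggregate_mean is the unweighted elementwise mean", {
  a <- list(w = c(0, 2), b = 1)
  b <- list(w = c(2, 4), b = 3)
  m <- aggregate_mean(list(a, b))
  expect_equal(m$w, c(1, 3))
  expect_equal(m$b, 2)
  expect_identical(aggregate_mean(list(a)), a)  # federation of one
  expect_error(aggregate_mean(list()), "empty")
  expect_error(aggregate_mean(list(a, list(w = c(1, 2, 3), b = 0))), "w")
  expect_error(aggregate_mean(list(list(trees = list()))), "aggregate_forest")
})

test_that("aggregate_mean matches a brute-force loop and is exactly idempotent", {
  set.seed(21)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    clients <- lapply(seq_len(k), function(i)
      list(w = rnorm(10), b = rnorm(1)))
    got <- aggregate_mean(clients)
    want_w <- numeric(10)
    want_b <- 0
    for (cl in clients) {
      want_w <- want_w + cl$w
      want_b <- want_b + cl$b
    }
    expect_lt(max(abs(got$w - want_w / k)), 1e-12)
    expect_lt(abs(got$b - want_b / k), 1e-12)
    copies <- rep(list(clients[[1]]), k)
    expect_identical(aggregate_mean(copies), clients[[1]])
  }
})

test_that("weighted aggregation honours shard sizes when enabled", {
  a <- list(w = 0, b = 0)
  b <- list(w = 4, b = 4)
  m <- aggregate_mean(list(a, b), weights = c(3, 1))
  expect_equal(m$w, 1)
})

test_that("forest aggregation concatenates scaled increments over the prefix", {
  sh1 <- make_shard(40, 3, seed = 1)
  sh2 <- make_shard(40, 3, seed = 2)
  hp <- list(trees_per_round = 1L)
  global <- get_parameters(init_learner("forest", 3, hp))
  c1 <- local_fit(set_parameters(init_learner("forest", 3, hp), global),
                  sh1$x, sh1$y)
  c2 <- local_fit(set_parameters(init_learner("forest", 3, hp), global),
                  sh2$x, sh2$y)
  agg <- aggregate_forest(list(get_parameters(c1), get_parameters(c2)),
                          global, round_index = 1L)
  expect_length(agg$trees, 2L)
  expect_equal(vapply(agg$trees, `[[`, 1L, "client"), c(1L, 2L))
  # aggregated margin is the mean of the two unscaled single-tree margins
  xnew <- matrix(rnorm(30), 10, 3)
  m1 <- fedomics:::forest_margin(get_parameters(c1), xnew)
  m2 <- fedomics:::forest_margin(get_parameters(c2), xnew)
  expect_equal(fedomics:::forest_margin(agg, xnew), (m1 + m2) / 2,
               tolerance = 1e-12)
  # federation of one appends unscaled; empty increments are no-ops
  agg1 <- aggregate_forest(list(get_parameters(c1)), global)
  expect_equal(fedomics:::forest_margin(agg1, xnew), m1, tolerance = 1e-12)
  expect_identical(aggregate_forest(list(global), global)$trees, global$trees)
  # clients trained from a different global state are rejected
  expect_error(aggregate_forest(list(get_parameters(c2)), get_parameters(c1)),
               "prefix")
})

test_that("a single-client fedavg round returns the client's fitted parameters", {
  sh <- make_shard(40, 5, seed = 3)
  cfg <- federation_config("fedavg", n_clients = 1, local_epochs = 2, seed = 7)
  st0 <- init_learner("logistic_regression", 5, seed = 7)
  out <- run_round(get_parameters(st0), list(sh), cfg)
  direct <- local_fit(st0, sh$x, sh$y, epochs = 2)
  expect_identical(out$global, direct$params)
})

test_that("a two-client logistic round equals the mean of hand-computed steps", {
  x1 <- matrix(c(0.5, -1, 2, 0.3), 2, 2)
  y1 <- c(1, 0)
  x2 <- matrix(c(-0.2, 1.5, 0.8, -0.7), 2, 2)
  y2 <- c(0, 1)
  hp <- list(learning_rate = 0.2, l2 = 0.001)
  cfg <- federation_config("fedavg", n_clients = 2, local_epochs = 1,
                           learner = "logistic_regression", hyperparams = hp,
                           seed = 1)
  g0 <- get_parameters(init_learner("logistic_regression", 2, hp, seed = 1))
  out <- run_round(g0, list(list(x = x1, y = y1), list(x = x2, y = y2)), cfg)
  s1 <- oracle_logreg_step(x1, y1, g0$w, g0$b, 0.2, 0.001)
  s2 <- oracle_logreg_step(x2, y2, g0$w, g0$b, 0.2, 0.001)
  expect_equal(out$global$w, (s1$w + s2$w) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(out$global$b, (s1$b + s2$b) / 2, tolerance = 1e-12)
})

test_that("federation round errors are annotated with the client index", {
  sh <- make_shard(20, 3, seed = 4)
  bad <- list(x = sh$x[sh$y == 1, ], y = sh$y[sh$y == 1])
  cfg <- federation_config("fedavg", n_clients = 2, seed = 1)
  g0 <- get_parameters(init_learner("logistic_regression", 3, seed = 1))
  expect_error(run_round(g0, list(sh, bad), cfg), "client 2")
})

test_that("fedprox with mu = 0 reproduces fedavg bitwise over a full run", {
  co <- generate_cohort(small_spec(seed = 31L))
  ss <- split_uniform_stratified(co, 2, seed = 3)
  shards <- shard_data(ss, co)
  val <- list(x = co$features[1:20, ], y = co$labels[1:20])
  for (kind in c("logistic_regression", "mlp")) {
    avg <- train_federated(shards, val,
      federation_config("fedavg", rounds = 3, learner = kind, seed = 5))
    prox <- train_federated(shards, val,
      federation_config("fedprox", mu = 0, rounds = 3, learner = kind, seed = 5))
    expect_identical(avg$best_params, prox$best_params)
    expect_identical(avg$validation_auc_pr, prox$validation_auc_pr)
  }
})

test_that("train_federated records history, broadcast consistency and best round", {
  co <- generate_cohort(small_spec(n_cases = 40L, n_controls = 40L, seed = 32L))
  ss <- split_uniform_stratified(co, 2, seed = 4)
  val <- list(x = co$features[1:24, ], y = co$labels[1:24])
  cfg <- federation_config("fedavg", rounds = 4, local_epochs = 2,
                           learner = "logistic_regression", n_clients = 2,
                           seed = 9)
  res <- train_federated(shard_data(ss, co), val, cfg)
  expect_length(res$history, 4L)
  expect_true(all(res$validation_auc_pr >= 0 & res$validation_auc_pr <= 1))
  expect_equal(res$chosen_round, which.max(res$validation_auc_pr))
  expect_identical(res$best_params, res$history[[res$chosen_round]]$global)
  expect_gt(res$seconds, 0)
  # replaying round 2 from the recorded round-1 global reproduces history
  replay <- run_round(res$history[[1]]$global, shard_data(ss, co), cfg,
                      client_states = NULL, round_index = 2L)
  # (fresh client states differ only in their epoch counters, which logistic
  #  regression does not consume)
  expect_identical(replay$global, res$history[[2]]$global)
  expect_error(train_federated(shard_data(ss, co),
                               list(x = co$features[0, , drop = FALSE], y = integer(0)),
                               cfg), "validation")
})

test_that("identical client shards make federation equal central training", {
  sh <- make_shard(30, 4, seed = 5)
  cfg <- federation_config("fedavg", rounds = 3, local_epochs = 1,
                           learner = "logistic_regression", n_clients = 2,
                           seed = 2)
  res <- train_federated(list(sh, sh), list(x = sh$x, y = sh$y), cfg)
  central <- train_central("logistic_regression", sh$x, sh$y, epochs = 3, seed = 2)
  expect_equal(res$history[[3]]$global$w, central$params$w, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("mean aggregation is invariant to client order", {
  co <- generate_cohort(small_spec(n_cases = 40L, n_controls = 40L, seed = 33L))
  ss <- split_uniform_stratified(co, 3, seed = 6)
  shards <- shard_data(ss, co)
  val <- list(x = co$features[1:20, ], y = co$labels[1:20])
  cfg <- federation_config("fedavg", rounds = 2, learner = "logistic_regression",
                           n_clients = 3, seed = 3)
  a <- train_federated(shards, val, cfg)
  b <- train_federated(shards[c(3, 1, 2)], val, cfg)
  expect_equal(a$best_params$w, b$best_params$w, tolerance = 1e-12)
})

test_that("federation config invariants are enforced", {
  expect_error(federation_config("fedprox"), "mu")
  expect_error(federation_config("fedavg", mu = 1), "fedprox")
  expect_error(federation_config("fedavg", rounds = 0), "rounds")
})
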