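# The cross-silo simulation engine: synchronous communication rounds of
# broadcast -> local fit -> aggregate, with best-round selection on a
# validation set. Rounds are failure-free and synchronous; aggregation is
# the UNWEIGHTED elementwise mean of client parameters (client sizes are
# ignored even under size-heterogeneous sharding; a size-weighted mean is
# available behind `weighted = TRUE` but off by default).

#' Configure a federated training run
#'
#' @param strategy `"fedavg"` (plain parameter averaging) or `"fedprox"`
#'   (proximal local objective + parameter averaging).
#' @param mu Proximal strength; required (nonnegative) for fedprox,
#'   forbidden for fedavg.
#' @param rounds Number of communication rounds R (default 5).
#' @param local_epochs Local epochs E per round (default 1).
#' @param learner Local learner kind (see [init_learner()]).
#' @param hyperparams Learner hyperparameter overrides.
#' @param n_clients Number of federation clients N.
#' @param seed Master seed for learner initialization and epoch shuffles.
#' @param weighted Use a shard-size-weighted mean instead of the unweighted
#'   mean (off by default, matching the reference protocol).
#' @return A `federation_config` list.
#' @export
federation_config <- function(strategy = c("fedavg", "fedprox"), mu = NULL,
                              rounds = 5L, local_epochs = 1L,
                              learner = "logistic_regression",
                              hyperparams = list(), n_clients = 2L,
                              seed = 1L, weighted = FALSE) {
  strategy <- match.arg(strategy)
  if (strategy == "fedprox") {
    if (is.null(mu) || !is.numeric(mu) || mu < 0)
      stop("fedprox requires a nonnegative mu", call. = FALSE)
  } else if (!is.null(mu)) {
    stop("mu is only meaningful for strategy = 'fedprox'", call. = FALSE)
  }
  stopifnot(rounds >= 1L, n_clients >= 1L, local_epochs >= 1L)
  learner <- match.arg(learner, LEARNER_KINDS)
  structure(list(strategy = strategy, mu = mu, rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs), learner = learner,
                 hyperparams = hyperparams, n_clients = as.integer(n_clients),
                 seed = as.integer(seed), weighted = isTRUE(weighted)),
            class = "federation_config")
}

#' Unweighted elementwise mean of client parameters
#'
#' Every tensor of the output is the arithmetic mean of the corresponding
#' client tensors; client dataset sizes are ignored unless `weights` is
#' given. Forest parameters are rejected (use [aggregate_forest()]).
#'
#' @param params_list Non-empty list of parameter lists with identical
#'   architecture.
#' @param weights Optional nonnegative weights (normalized internally).
#' @return The aggregated parameter list.
#' @export
aggregate_mean <- function(params_list, weights = NULL) {
  if (!length(params_list)) stop("empty client list", call. = FALSE)
  if (!is.null(params_list[[1L]]$trees))
    stop("forest parameters must be aggregated with aggregate_forest()", call. = FALSE)
  ref <- params_list[[1L]]
  for (p in params_list[-1L]) check_architecture(ref, p)
  N <- length(params_list)
  if (is.null(weights)) weights <- rep(1 / N, N) else {
    stopifnot(length(weights) == N, all(weights >= 0), sum(weights) > 0)
    weights <- weights / sum(weights)
  }
  # centered formulation: ref + sum_i w_i (p_i - ref). Numerically tighter
  # than a weighted sum, and exactly idempotent when all clients agree
  # (every deviation is exactly zero).
  out <- ref
  for (nm in names(ref)) {
    acc <- (params_list[[1L]][[nm]] - ref[[nm]]) * weights[1L]
    if (N > 1L) for (i in 2:N)
      acc <- acc + (params_list[[i]][[nm]] - ref[[nm]]) * weights[i]
    out[[nm]] <- ref[[nm]] + acc
  }
  out
}

init_client_states <- function(config, d) {
  lapply(seq_len(config$n_clients), function(i)
    init_learner(config$learner, d, config$hyperparams, seed = config$seed))
}

#' Run one synchronous federation round
#'
#' Broadcast the global parameters to every client, fit each client locally
#' for E epochs (with the proximal anchor set to the incoming global model
#' under fedprox), and aggregate the resulting client parameters into the
#' new global model.
#'
#' @param global The incoming global parameter list.
#' @param shards List of client datasets, each `list(x = matrix, y = 0/1)`.
#' @param config A [federation_config()].
#' @param client_states Persistent client `fed_learner` states (created via
#'   the internal initializer when absent); carrying them across rounds
#'   keeps each client's epoch-shuffle schedule consecutive.
#' @param round_index 1-based round number (recorded on forest trees).
#' @return A list: `global` (new parameters), `client_params`,
#'   `client_states`.
#' @export
run_round <- function(global, shards, config, client_states = NULL,
                      round_index = 1L) {
  stopifnot(inherits(config, "federation_config"),
            length(shards) == config$n_clients)
  d <- ncol(shards[[1L]]$x)
  if (is.null(client_states)) client_states <- init_client_states(config, d)
  client_params <- vector("list", config$n_clients)
  for (i in seq_len(config$n_clients)) {
    st <- set_parameters(client_states[[i]], global)
    prox <- if (config$strategy == "fedprox") prox_spec(config$mu, global) else NULL
    st <- tryCatch(
      local_fit(st, shards[[i]]$x, shards[[i]]$y,
                epochs = config$local_epochs, prox = prox),
      error = function(e) stop(sprintf("client %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
    client_states[[i]] <- st
    client_params[[i]] <- get_parameters(st)
  }
  new_global <- if (config$learner == "forest") {
    aggregate_forest(client_params, global, round_index = round_index)
  } else {
    w <- if (config$weighted)
      vapply(shards, function(s) nrow(s$x), numeric(1)) else NULL
    aggregate_mean(client_params, weights = w)
  }
  list(global = new_global, client_params = client_params,
       client_states = client_states)
}

#' Train a global model over R federation rounds
#'
#' Runs `config$rounds` synchronous rounds on the given client shards,
#' scores the global model on the validation set after every round
#' (AUC-PR), and returns the best-round global model (earliest round on
#' ties) — the best-global-model selection of the evaluation protocol.
#'
#' @param shards List of client datasets `list(x, y)`; must be disjoint from
#'   the validation set.
#' @param validation `list(x, y)` used only for best-round selection.
#' @param config A [federation_config()].
#' @return A `federated_result`: `best_params`, `chosen_round`, `history`
#'   (per-round validation AUC-PR and parameters), `seconds`, `config`.
#' @export
train_federated <- function(shards, validation, config) {
  stopifnot(inherits(config, "federation_config"))
  if (is.null(validation$x) || nrow(as.matrix(validation$x)) == 0L)
    stop("empty validation set", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  d <- ncol(shards[[1L]]$x)
  scorer <- init_learner(config$learner, d, config$hyperparams, seed = config$seed)
  global <- get_parameters(scorer)
  client_states <- init_client_states(config, d)
  history <- vector("list", config$rounds)
  val_scores <- numeric(config$rounds)
  for (t in seq_len(config$rounds)) {
    step <- tryCatch(
      run_round(global, shards, config, client_states, round_index = t),
      error = function(e) stop(sprintf("round %d: %s", t, conditionMessage(e)),
                               call. = FALSE))
    global <- step$global
    client_states <- step$client_states
    sc <- predict_scores(set_parameters(scorer, global), validation$x)
    val_scores[t] <- auc_pr(validation$y, sc)
    history[[t]] <- list(round = t, global = global,
                         client_params = step$client_params,
                         validation_auc_pr = val_scores[t])
  }
  chosen <- which.max(val_scores)  # earliest on ties
  structure(list(best_params = history[[chosen]]$global,
                 chosen_round = chosen,
                 validation_auc_pr = val_scores,
                 history = history,
                 seconds = proc.time()[["elapsed"]] - t0,
                 config = config),
            class = "federated_result")
}

#' @export
print.federated_result <- function(x, ...) {
  cat(sprintf("<federated_result: %s %s, %d clients, %d rounds, best round %d (val AUC-PR %.3f), %.2fs>\n",
              x$config$strategy, x$config$learner, x$config$n_clients,
              x$config$rounds, x$chosen_round,
              x$validation_auc_pr[x$chosen_round], x$seconds))
  invisible(x)
}

#' Turn a shard set into per-client datasets
#' @param shardset A `shard_set` over `cohort`.
#' @param cohort The source `labeled_cohort`.
#' @return List of `list(x, y)` client datasets.
#' @export
shard_data <- function(shardset, cohort) {
  lapply(shardset$shards, function(idx)
    list(x = cohort$features[idx, , drop = FALSE], y = cohort$labels[idx]))
}
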