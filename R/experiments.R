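# The three experiment arms, reproducible end-to-end from a single plan:
#   central_vs_federated — central roster vs federated roster at n = 2
#                          stratified, paired AUC-PR deltas;
#   dispersion_sweep     — federated AUC-PR as the client count grows over
#                          stratified shards of the same fit split (total
#                          data constant);
#   heterogeneity        — three split strategies crossed with n in {2, 4},
#                          deltas against the stratified baseline plus the
#                          shard heterogeneity indices that produced them.
# Every arm emits a manifest (plan + seed) from which its outputs replay
# bit-for-bit.

#' Build an experiment plan
#'
#' @param arm One of `"central_vs_federated"`, `"dispersion_sweep"`,
#'   `"heterogeneity"`.
#' @param cohort A [cohort_spec()] for the internal (training) cohort.
#' @param external_shift A [shift_spec()] for the external cohort, or `NULL`
#'   to skip external testing.
#' @param learners Local learner kinds in the roster.
#' @param fedprox_mu FedProx mu values crossed with the fedprox roster
#'   learners (arm 1 only).
#' @param fedprox_learners Learner kinds that get FedProx variants.
#' @param client_counts Client-count grid. Defaults: `c(2L)` for arm 1,
#'   `seq(2, 18, by = 2)` for the dispersion sweep, `c(2L, 4L)` for the
#'   heterogeneity arm.
#' @param strategies Split strategies (heterogeneity arm).
#' @param K Cross-validation folds.
#' @param rounds,local_epochs Federation schedule (R rounds, E local epochs
#'   per round); central baselines train for `rounds * local_epochs` epochs
#'   so comparisons are epoch-matched.
#' @param seed Master seed.
#' @return An `experiment_plan`.
#' @export
experiment_plan <- function(arm = c("central_vs_federated", "dispersion_sweep",
                                    "heterogeneity"),
                            cohort = cohort_spec(171L, 427L),
                            external_shift = shift_spec(
                              mean_shift = 0.2, effect_attenuation = 0.6,
                              label_ratio_override = c(404L, 712L)),
                            learners = c("logistic_regression", "sgd_linear",
                                         "mlp", "forest"),
                            fedprox_mu = c(0.5, 2),
                            fedprox_learners = c("logistic_regression", "mlp"),
                            client_counts = NULL,
                            strategies = SPLIT_STRATEGIES,
                            K = 6L, rounds = 5L, local_epochs = 8L,
                            seed = 1L) {
  arm <- match.arg(arm)
  if (is.null(client_counts))
    client_counts <- switch(arm,
                            central_vs_federated = 2L,
                            dispersion_sweep = seq(2L, 18L, by = 2L),
                            heterogeneity = c(2L, 4L))
  structure(list(arm = arm, cohort = unclass(cohort),
                 external_shift = if (is.null(external_shift)) NULL
                                  else unclass(external_shift),
                 learners = as.character(learners),
                 fedprox_mu = as.numeric(fedprox_mu),
                 fedprox_learners = as.character(fedprox_learners),
                 client_counts = as.integer(client_counts),
                 strategies = as.character(strategies), K = as.integer(K),
                 rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

plan_cohorts <- function(plan) {
  spec <- do.call(cohort_spec, plan$cohort[names(plan$cohort) != "tag"])
  train <- generate_cohort(spec)
  external <- if (is.null(plan$external_shift)) NULL else
    generate_external_cohort(spec, do.call(shift_spec, plan$external_shift))
  list(train = train, external = external)
}

learner_label <- function(kind) {
  c(logistic_regression = "LR", sgd_linear = "SGD", mlp = "MLP",
    forest = "XGBRF")[[kind]]
}

finish_arm <- function(plan, results, extra = NULL) {
  manifest <- list(arm = plan$arm, plan = unclass(plan),
                   package = "fedomics",
                   version = as.character(utils::packageVersion("fedomics")))
  out <- c(list(results = results, manifest = manifest), extra)
  class(out) <- "experiment_result"
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %s, %d result rows>\n",
              x$manifest$arm, nrow(x$results)))
  invisible(x)
}

#' Arm 1: central versus federated training
#'
#' Trains the central roster and the matched federated roster (FedAvg per
#' learner; FedProx at each mu for the fedprox learners) under the K-fold
#' protocol at the plan's client count (default n = 2, stratified shards),
#' and emits the per-metric summary plus paired federated-minus-central
#' AUC-PR deltas per local learner.
#'
#' @param plan An [experiment_plan()] with `arm = "central_vs_federated"`.
#' @return An `experiment_result`: `results` (tidy summary), `deltas`
#'   (paired AUC-PR deltas), `cv` (the full `cv_summary`), `manifest`.
#' @export
run_central_vs_federated <- function(plan) {
  stopifnot(plan$arm == "central_vs_federated")
  co <- plan_cohorts(plan)
  n2 <- plan$client_counts[1L]
  epochs <- plan$rounds * plan$local_epochs
  models <- list()
  for (lk in plan$learners) {
    models[[length(models) + 1L]] <-
      central_model(paste0("central ", learner_label(lk)), lk, epochs = epochs)
    models[[length(models) + 1L]] <-
      federated_model(paste0("FedAvg ", learner_label(lk)), lk,
                      n_clients = n2, rounds = plan$rounds,
                      local_epochs = plan$local_epochs)
  }
  for (lk in intersect(plan$fedprox_learners, setdiff(plan$learners, "forest")))
    for (mu in plan$fedprox_mu)
      models[[length(models) + 1L]] <-
        federated_model(sprintf("FedProx mu=%g %s", mu, learner_label(lk)), lk,
                        strategy = "fedprox", mu = mu, n_clients = n2,
                        rounds = plan$rounds, local_epochs = plan$local_epochs)
  cv <- kfold_protocol(co$train, co$external, models, K = plan$K,
                       seed = plan$seed)
  aucpr <- cv$summary[cv$summary$metric == "auc_pr", , drop = FALSE]
  deltas <- list()
  for (lk in plan$learners) {
    for (ts in unique(aucpr$test_set)) {
      cen <- aucpr$mean[aucpr$model == paste0("central ", learner_label(lk)) &
                          aucpr$test_set == ts]
      fed <- aucpr$mean[aucpr$model == paste0("FedAvg ", learner_label(lk)) &
                          aucpr$test_set == ts]
      deltas[[length(deltas) + 1L]] <- tibble::tibble(
        learner = learner_label(lk), test_set = ts,
        central_auc_pr = cen, federated_auc_pr = fed,
        delta = fed - cen)
    }
  }
  finish_arm(plan, cv$summary,
             extra = list(deltas = dplyr::bind_rows(deltas), cv = cv))
}

#' Arm 2: client dispersion sweep
#'
#' For every client count n in the plan's grid, trains the federated roster
#' on uniform-stratified shards of the same fit split (the globally
#' available sample set is constant; only its dispersion across silos
#' varies) under the K-fold protocol, and emits AUC-PR against n per
#' algorithm. Infeasible n (too few cases or controls per client) are
#' skipped with a logged reason.
#'
#' @param plan An [experiment_plan()] with `arm = "dispersion_sweep"`.
#' @return An `experiment_result`: `results` (model, n_clients, test_set,
#'   metric summary), `skipped` (n values skipped and why), `manifest`.
#' @export
run_dispersion_sweep <- function(plan) {
  stopifnot(plan$arm == "dispersion_sweep")
  co <- plan_cohorts(plan)
  fit_cases <- min(table(co$train$labels))   # conservative feasibility bound
  models <- list()
  skipped <- list()
  for (n in plan$client_counts) {
    # a fold's fit split holds ~ratio*(K-1)/K of each class
    approx_cases <- floor(sum(co$train$labels == 1L) * 0.8 * (plan$K - 1) / plan$K)
    approx_ctrls <- floor(sum(co$train$labels == 0L) * 0.8 * (plan$K - 1) / plan$K)
    if (approx_cases < n || approx_ctrls < n) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        n_clients = n, reason = "fewer cases or controls than clients")
      next
    }
    for (lk in plan$learners)
      models[[length(models) + 1L]] <-
        federated_model(sprintf("FedAvg %s n=%d", learner_label(lk), n), lk,
                        n_clients = n, rounds = plan$rounds,
                        local_epochs = plan$local_epochs)
  }
  cv <- kfold_protocol(co$train, co$external, models, K = plan$K,
                       seed = plan$seed)
  res <- cv$summary
  res$n_clients <- as.integer(sub(".* n=(\\d+)$", "\\1", res$model))
  res$algorithm <- sub(" n=\\d+$", "", res$model)
  finish_arm(plan, res,
             extra = list(cv = cv,
                          skipped = if (length(skipped))
                            dplyr::bind_rows(skipped) else NULL))
}

#' Arm 3: split-strategy heterogeneity
#'
#' Crosses the three split strategies with the plan's client counts
#' (default n in {2, 4}) for the federated roster under the K-fold
#' protocol. Emits per-strategy AUC-PR, the delta of each strategy against
#' the uniform-stratified baseline, and the shard heterogeneity indices
#' (label skew, size skew) of the shard sets that produced each cell.
#'
#' @param plan An [experiment_plan()] with `arm = "heterogeneity"`.
#' @return An `experiment_result`: `results` (summary with strategy and
#'   n_clients), `deltas` (strategy minus stratified per algorithm/n),
#'   `heterogeneity` (indices per model and fold), `manifest`.
#' @export
run_heterogeneity <- function(plan) {
  stopifnot(plan$arm == "heterogeneity")
  co <- plan_cohorts(plan)
  models <- list()
  for (strat in plan$strategies)
    for (n in plan$client_counts)
      for (lk in plan$learners)
        models[[length(models) + 1L]] <-
          federated_model(sprintf("FedAvg %s %s n=%d", learner_label(lk), strat, n),
                          lk, split = strat, n_clients = n,
                          rounds = plan$rounds, local_epochs = plan$local_epochs)
  cv <- kfold_protocol(co$train, co$external, models, K = plan$K,
                       seed = plan$seed)
  res <- cv$summary
  res$strategy <- sub("^FedAvg \\S+ (\\S+) n=\\d+$", "\\1", res$model)
  res$n_clients <- as.integer(sub(".* n=(\\d+)$", "\\1", res$model))
  res$algorithm <- sub("^FedAvg (\\S+) .*$", "\\1", res$model)
  aucpr <- res[res$metric == "auc_pr", , drop = FALSE]
  deltas <- list()
  for (alg in unique(aucpr$algorithm))
    for (n in unique(aucpr$n_clients))
      for (ts in unique(aucpr$test_set)) {
        sel <- aucpr$algorithm == alg & aucpr$n_clients == n & aucpr$test_set == ts
        base <- aucpr$mean[sel & aucpr$strategy == "uniform_stratified"]
        for (strat in unique(aucpr$strategy[sel])) {
          val <- aucpr$mean[sel & aucpr$strategy == strat]
          deltas[[length(deltas) + 1L]] <- tibble::tibble(
            algorithm = alg, n_clients = n, test_set = ts, strategy = strat,
            auc_pr = val, delta_vs_stratified = val - base)
        }
      }
  finish_arm(plan, res,
             extra = list(cv = cv, deltas = dplyr::bind_rows(deltas),
                          heterogeneity = cv$heterogeneity))
}

#' Run an experiment plan
#' @param plan An [experiment_plan()].
#' @return The arm's `experiment_result`.
#' @export
run_experiment <- function(plan) {
  switch(plan$arm,
         central_vs_federated = run_central_vs_federated(plan),
         dispersion_sweep = run_dispersion_sweep(plan),
         heterogeneity = run_heterogeneity(plan))
}

#' Write an experiment's manifest and results to disk
#' @param result An `experiment_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_csv(result$results, file.path(dir, "results.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Replay an experiment from its manifest
#'
#' Reconstructs the plan from a manifest (list or path to `manifest.json`)
#' and re-runs the arm; because every random stream derives from the plan's
#' master seed, the outputs reproduce the original run bit-for-bit.
#'
#' @param manifest A manifest list or path to a `manifest.json`.
#' @return The re-run `experiment_result`.
#' @export
replay_experiment <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  p <- manifest$plan
  plan <- experiment_plan(
    arm = p$arm,
    cohort = do.call(cohort_spec, p$cohort),
    external_shift = if (is.null(p$external_shift)) NULL else
      do.call(shift_spec, p$external_shift),
    learners = p$learners, fedprox_mu = p$fedprox_mu,
    fedprox_learners = p$fedprox_learners,
    client_counts = p$client_counts, strategies = p$strategies,
    K = p$K, rounds = p$rounds, local_epochs = p$local_epochs,
    seed = p$seed)
  run_experiment(plan)
}

# --- Multi-seed desk-scale comparisons -------------------------------------
# Lighter than the full K-fold protocol: a single stratified
# holdout/fit/validation split per seed, used for seed-averaged trend
# summaries (FL-vs-central gap, dispersion trend).

single_split <- function(cohort, seed, holdout_frac = 1 / 6, ratio = 0.8) {
  idx <- seq_len(n_samples(cohort))
  hold <- integer(0)
  for (cl in c(1L, 0L)) {
    cl_idx <- which(cohort$labels == cl)
    perm <- with_seed(derive_seed(seed, "holdout", cl), sample(cl_idx))
    hold <- c(hold, perm[seq_len(max(1L, round(holdout_frac * length(cl_idx))))])
  }
  hold <- sort(hold)
  rest <- setdiff(idx, hold)
  sp <- split_fit_val(cohort$labels, rest, ratio, derive_seed(seed, "fv"))
  std_src <- subset_cohort(cohort, sp$fit, tag = "fit")
  std <- fit_standardizer(std_src)
  list(fit = apply_standardizer(std, std_src),
       val = apply_standardizer(std, subset_cohort(cohort, sp$val, tag = "val")),
       holdout = apply_standardizer(std, subset_cohort(cohort, hold, tag = "holdout")),
       std = std)
}

#' Seed-averaged federated-versus-central AUC-PR gap
#'
#' For each of `n_seeds` master seeds: generate a cohort from the spec,
#' split it (stratified holdout, then 80:20 fit/validation), train a
#' central learner for `rounds * local_epochs` epochs and a FedAvg
#' federation (`n_clients` stratified shards, same epoch budget), and score
#' both on the internal holdout.
#'
#' @param spec A [cohort_spec()] (its seed field is overridden per run).
#' @param learner Learner kind.
#' @param n_seeds Number of independent seeds.
#' @param n_clients Federation size.
#' @param rounds,local_epochs Federation schedule.
#' @param hyperparams Learner hyperparameter overrides.
#' @param seed Base seed from which the per-run seeds derive.
#' @return Tibble with one row per seed: central and federated internal
#'   AUC-PR and their difference.
#' @export
fl_central_gap <- function(spec, learner = "logistic_regression",
                           n_seeds = 10L, n_clients = 2L, rounds = 5L,
                           local_epochs = 8L, hyperparams = list(),
                           seed = 1L) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- derive_seed(seed, "gap", i)
    spec_i <- do.call(cohort_spec, utils::modifyList(unclass(spec), list(seed = s)))
    cohort <- generate_cohort(spec_i)
    sp <- single_split(cohort, s)
    central <- train_central(learner, sp$fit$features, sp$fit$labels,
                             epochs = rounds * local_epochs,
                             hyperparams = hyperparams, seed = s)
    shardset <- split_uniform_stratified(sp$fit, n_clients,
                                         seed = derive_seed(s, "shards"))
    config <- federation_config("fedavg", rounds = rounds,
                                local_epochs = local_epochs, learner = learner,
                                hyperparams = hyperparams,
                                n_clients = n_clients, seed = s)
    fed <- train_federated(shard_data(shardset, sp$fit),
                           list(x = sp$val$features, y = sp$val$labels), config)
    scorer <- set_parameters(init_learner(learner, n_features(cohort),
                                          hyperparams, seed = s),
                             fed$best_params)
    tibble::tibble(
      seed = s,
      central_auc_pr = auc_pr(sp$holdout$labels,
                              predict_scores(central, sp$holdout$features)),
      federated_auc_pr = auc_pr(sp$holdout$labels,
                                predict_scores(scorer, sp$holdout$features)))
  })
  out <- dplyr::bind_rows(rows)
  out$delta <- out$federated_auc_pr - out$central_auc_pr
  out
}

#' Seed-averaged dispersion trend
#'
#' Federated internal-test AUC-PR per client count, averaged over seeds,
#' holding the fit split constant within a seed (only its dispersion across
#' silos changes with n).
#'
#' @inheritParams fl_central_gap
#' @param client_counts Client-count grid.
#' @return Tibble with one row per (seed, n_clients): internal AUC-PR.
#' @export
dispersion_curve <- function(spec, learner = "logistic_regression",
                             client_counts = c(2L, 18L), n_seeds = 10L,
                             rounds = 5L, local_epochs = 8L,
                             hyperparams = list(), seed = 1L) {
  rows <- list()
  for (i in seq_len(n_seeds)) {
    s <- derive_seed(seed, "disp", i)
    spec_i <- do.call(cohort_spec, utils::modifyList(unclass(spec), list(seed = s)))
    cohort <- generate_cohort(spec_i)
    sp <- single_split(cohort, s)
    for (n in client_counts) {
      shardset <- split_uniform_stratified(sp$fit, n,
                                           seed = derive_seed(s, "shards", n))
      config <- federation_config("fedavg", rounds = rounds,
                                  local_epochs = local_epochs,
                                  learner = learner, hyperparams = hyperparams,
                                  n_clients = n, seed = s)
      fed <- train_federated(shard_data(shardset, sp$fit),
                             list(x = sp$val$features, y = sp$val$labels),
                             config)
      scorer <- set_parameters(init_learner(learner, n_features(cohort),
                                            hyperparams, seed = s),
                               fed$best_params)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = s, n_clients = n,
        auc_pr = auc_pr(sp$holdout$labels,
                        predict_scores(scorer, sp$holdout$features)))
    }
  }
  dplyr::bind_rows(rows)
}
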