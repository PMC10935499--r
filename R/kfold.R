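# The evaluation protocol: stratified K-fold cross-validation (K = 6 by
# default, so a ~600-sample cohort yields ~100-sample folds). Per fold the
# remaining samples are split 80:20 (stratified) into fit and validation
# subsets; preprocessing and all training see ONLY the fit subset, the
# validation subset drives best-round selection, and models are scored on
# the holdout fold (internal test) and on the full external cohort, which
# is never touched during fitting or selection.

#' Declare a centrally trained model for the protocol
#'
#' @param name Unique display name.
#' @param learner Learner kind (see [init_learner()]).
#' @param epochs Total training epochs.
#' @param hyperparams Hyperparameter overrides.
#' @return A `model_spec`.
#' @export
central_model <- function(name, learner, epochs = 40L, hyperparams = list()) {
  structure(list(name = name, type = "central", learner = learner,
                 epochs = as.integer(epochs), hyperparams = hyperparams),
            class = "model_spec")
}

#' Declare a federated model for the protocol
#'
#' @inheritParams central_model
#' @param strategy `"fedavg"` or `"fedprox"`.
#' @param mu Proximal strength (fedprox only).
#' @param n_clients Number of federation clients.
#' @param split Shard strategy (see [split_cohort()]).
#' @param rounds Communication rounds R.
#' @param local_epochs Local epochs E per round.
#' @return A `model_spec`.
#' @export
federated_model <- function(name, learner, strategy = "fedavg", mu = NULL,
                            n_clients = 2L, split = "uniform_stratified",
                            rounds = 5L, local_epochs = 8L,
                            hyperparams = list()) {
  split <- match.arg(split, SPLIT_STRATEGIES)
  structure(list(name = name, type = "federated", learner = learner,
                 strategy = strategy, mu = mu, n_clients = as.integer(n_clients),
                 split = split, rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 hyperparams = hyperparams),
            class = "model_spec")
}

# Stratified fold assignment: per-class seed-shuffled round sizes
# floor(n_class/K) with class surpluses spread from opposite ends of the
# fold range, so total fold sizes differ by at most 1 whenever possible
# (598 samples, K = 6 -> sizes 99/100).
make_folds <- function(labels, K, seed) {
  n <- length(labels)
  fold <- integer(n)
  assign_class <- function(idx, from_front, sub) {
    perm <- with_seed(derive_seed(seed, "folds", sub), sample(idx))
    m <- length(idx)
    base <- m %/% K
    s <- m %% K
    extra_folds <- if (from_front) seq_len(s) else rev(seq_len(K))[seq_len(s)]
    sizes <- rep(base, K)
    sizes[extra_folds] <- sizes[extra_folds] + 1L
    fold[perm] <<- rep(seq_len(K), times = sizes)
    invisible(NULL)
  }
  assign_class(which(labels == 1L), TRUE, "case")
  assign_class(which(labels == 0L), FALSE, "control")
  fold
}

# Stratified fit/validation split of a set of indices at the given ratio.
split_fit_val <- function(labels, idx, ratio, seed) {
  fit <- integer(0)
  for (cl in c(1L, 0L)) {
    cl_idx <- idx[labels[idx] == cl]
    perm <- with_seed(derive_seed(seed, "fitval", cl), sample(cl_idx))
    n_fit <- max(1L, min(length(cl_idx) - 1L, round(ratio * length(cl_idx))))
    fit <- c(fit, perm[seq_len(n_fit)])
  }
  fit <- sort(fit)
  list(fit = fit, val = sort(setdiff(idx, fit)))
}

# Train one model spec on a prepared fold; returns a scorer state.
fit_model_spec <- function(model, fit_cohort, val, seed) {
  if (model$type == "central") {
    train_central(model$learner, fit_cohort$features, fit_cohort$labels,
                  epochs = model$epochs, hyperparams = model$hyperparams,
                  seed = seed)
  } else {
    shardset <- split_cohort(fit_cohort, model$split, model$n_clients,
                             seed = derive_seed(seed, "shards"))
    rep_ <- validate_shards(shardset, fit_cohort)
    if (!rep_$pass)
      stop("infeasible shard set for model ", model$name, ": ",
           paste(rep_$failures, collapse = "; "), call. = FALSE)
    config <- federation_config(strategy = model$strategy, mu = model$mu,
                                rounds = model$rounds,
                                local_epochs = model$local_epochs,
                                learner = model$learner,
                                hyperparams = model$hyperparams,
                                n_clients = model$n_clients, seed = seed)
    res <- train_federated(shard_data(shardset, fit_cohort), val, config)
    scorer <- init_learner(model$learner, n_features(fit_cohort),
                           model$hyperparams, seed = seed)
    st <- set_parameters(scorer, res$best_params)
    attr(st, "federated_result") <- res
    attr(st, "heterogeneity") <- shard_heterogeneity(shardset, fit_cohort)
    st
  }
}

#' Run the K-fold evaluation protocol
#'
#' @param train_cohort The training `labeled_cohort` (internal cohort).
#' @param external_cohort Optional external `labeled_cohort`; used
#'   exclusively for testing, never for fitting or selection.
#' @param models List of [central_model()] / [federated_model()] specs.
#' @param K Number of folds (default 6).
#' @param seed Master seed; fold assignment, fit/validation splits, shard
#'   draws and learner seeds all derive from it.
#' @param ratio Fit:validation ratio within each fold's remainder
#'   (default 0.8, i.e. 80:20).
#' @param threshold Decision threshold for thresholded metrics.
#' @return A `cv_summary`: `per_fold` tidy tibble (model, fold, test_set,
#'   metric, value), `summary` (mean and sd per metric over the K folds),
#'   `folds` (fold assignment vector), `audit` (per-fold fit/validation/
#'   holdout index sets, for leakage inspection), `heterogeneity` (per
#'   federated model and fold), `K`, `seed`.
#' @export
kfold_protocol <- function(train_cohort, external_cohort = NULL, models,
                           K = 6L, seed = 1L, ratio = 0.8, threshold = 0.5) {
  stopifnot(inherits(train_cohort, "labeled_cohort"))
  if (inherits(models, "model_spec")) models <- list(models)
  nms <- vapply(models, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("model names must be unique", call. = FALSE)
  K <- as.integer(K)
  n <- n_samples(train_cohort)
  folds <- make_folds(train_cohort$labels, K, seed)

  rows <- list()
  audit <- vector("list", K)
  het <- list()
  for (k in seq_len(K)) {
    holdout <- which(folds == k)
    rest <- which(folds != k)
    sp <- split_fit_val(train_cohort$labels, rest, ratio,
                        derive_seed(seed, "fold", k))
    # leakage guard: the three index sets must be pairwise disjoint and the
    # holdout must never reach a fitting function
    stopifnot(length(intersect(sp$fit, sp$val)) == 0L,
              length(intersect(sp$fit, holdout)) == 0L,
              length(intersect(sp$val, holdout)) == 0L)
    audit[[k]] <- list(fit = sp$fit, val = sp$val, holdout = holdout)

    fit_cohort <- subset_cohort(train_cohort, sp$fit, tag = "fit")
    std <- fit_standardizer(fit_cohort)
    fit_cohort <- apply_standardizer(std, fit_cohort)
    val_cohort <- apply_standardizer(std, subset_cohort(train_cohort, sp$val, tag = "val"))
    hold_cohort <- apply_standardizer(std, subset_cohort(train_cohort, holdout, tag = "holdout"))
    ext_cohort <- if (!is.null(external_cohort))
      apply_standardizer(std, external_cohort)
    val <- list(x = val_cohort$features, y = val_cohort$labels)

    for (m in models) {
      mseed <- derive_seed(seed, "model", m$name, k)
      st <- fit_model_spec(m, fit_cohort, val, mseed)
      tests <- list(internal = hold_cohort)
      if (!is.null(ext_cohort)) tests$external <- ext_cohort
      for (ts in names(tests)) {
        rep_ <- compute_metrics(tests[[ts]]$labels,
                                predict_scores(st, tests[[ts]]$features),
                                threshold = threshold)
        rows[[length(rows) + 1L]] <- tibble::add_column(
          metrics_rows(rep_), model = m$name, fold = k, test_set = ts,
          .before = 1L)
      }
      hh <- attr(st, "heterogeneity")
      if (!is.null(hh))
        het[[length(het) + 1L]] <- tibble::tibble(
          model = m$name, fold = k,
          label_skew = hh$label_skew, size_skew = hh$size_skew)
    }
  }
  per_fold <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(per_fold, model, test_set, metric),
    mean = mean(value), sd = stats::sd(value), .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary, folds = folds,
                 audit = audit,
                 heterogeneity = if (length(het)) dplyr::bind_rows(het) else NULL,
                 K = K, seed = as.integer(seed), models = nms),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary: %d models, K = %d folds>\n", length(x$models), x$K))
  aucpr <- dplyr::filter(x$summary, metric == "auc_pr")
  print(as.data.frame(aucpr), digits = 3)
  invisible(x)
}

#' Format a mean +/- sd table over metrics
#'
#' @param cv A `cv_summary`.
#' @param test_set `"internal"` or `"external"`.
#' @return A tibble, one row per model, one `mean ± sd` column per metric.
#' @export
metrics_table <- function(cv, test_set = "internal") {
  which_set <- test_set
  df <- cv$summary[cv$summary$test_set == which_set, , drop = FALSE]
  df$cell <- sprintf("%.3f ± %.3f", df$mean, df$sd)
  tidyr_like <- stats::reshape(
    as.data.frame(df[, c("model", "metric", "cell")]),
    idvar = "model", timevar = "metric", direction = "wide")
  names(tidyr_like) <- sub("^cell\\.", "", names(tidyr_like))
  tibble::as_tibble(tidyr_like[, c("model", METRIC_NAMES)])
}

#' Measure training wall-clock time for a model spec
#'
#' Seconds from model initialization to the end of training (for federated
#' specs, to the end of the whole FL simulation). Hardware-dependent — a
#' reporting utility, not an evaluation metric.
#'
#' @param model A `model_spec`.
#' @param fit_cohort Training `labeled_cohort`.
#' @param val `list(x, y)` validation set (federated best-round selection).
#' @param seed Integer seed.
#' @return Elapsed seconds (positive finite).
#' @export
measure_runtime <- function(model, fit_cohort, val, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  fit_model_spec(model, fit_cohort, val, seed)
  proc.time()[["elapsed"]] - t0
}
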