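# Feature preparation fitted on training data only: Z-transform of
# continuous features, covariate residualization, and extra-trees importance
# feature selection with correlation pruning. Fitting functions accept only
# the training cohort, so test rows can never leak into fitted parameters.

#' Fit a Z-transform on a training cohort
#'
#' Computes per-feature mean and standard deviation (population convention,
#' divide by n) on the training cohort. Binary features are passed through
#' unchanged (mean 0, sd 1 recorded). Constant continuous columns get their
#' sd floored at 1e-12 so the standardized column is ~0 instead of dividing
#' by zero.
#'
#' @param train A `labeled_cohort` (the training split only).
#' @return A `standardizer_params` list: `mean`, `sd` (named vectors) and
#'   `fitted_on` (the training cohort's tag).
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "labeled_cohort"), nrow(train$features) >= 1L)
  X <- train$features
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)           # population sd
  sdv <- pmax(sdv, 1e-12)
  is_bin <- train$feature_meta$kind == "binary"
  mu[is_bin] <- 0
  sdv[is_bin] <- 1
  structure(list(mean = mu, sd = sdv, fitted_on = train$cohort_tag),
            class = "standardizer_params")
}

#' Apply fitted standardization parameters to a cohort
#'
#' @param params A `standardizer_params` from [fit_standardizer()]; reused
#'   verbatim for validation/test cohorts (never refit on test data).
#' @param cohort A `labeled_cohort` with the identical feature set.
#' @return The cohort with continuous features standardized.
#' @export
apply_standardizer <- function(params, cohort) {
  stopifnot(inherits(params, "standardizer_params"),
            inherits(cohort, "labeled_cohort"))
  have <- colnames(cohort$features)
  want <- names(params$mean)
  if (!identical(have, want)) {
    diffs <- c(setdiff(want, have), setdiff(have, want))
    stop("feature-name mismatch between standardizer and cohort: ",
         paste(diffs, collapse = ", "), call. = FALSE)
  }
  X <- sweep(sweep(cohort$features, 2L, params$mean, "-"), 2L, params$sd, "/")
  out <- cohort
  out$features <- X
  out
}

#' Residualize features on caller-supplied covariates
#'
#' Replaces every feature column by the residuals of an ordinary
#' least-squares fit on the covariates plus an intercept (the covariate
#' adjustment used to strip population-structure components from omics
#' features). Residuals are orthogonal to every covariate column.
#'
#' @param cohort A `labeled_cohort`.
#' @param covariates Numeric matrix, one row per cohort sample; must have
#'   full column rank (including the implicit intercept) and fewer columns
#'   than samples.
#' @return The cohort with residualized features.
#' @export
residualize <- function(cohort, covariates) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  covariates <- as.matrix(covariates)
  n <- nrow(cohort$features)
  if (nrow(covariates) != n)
    stop("covariate rows must align with cohort rows", call. = FALSE)
  if (ncol(covariates) + 1L >= n)
    stop("covariate count (plus intercept) must be < sample count", call. = FALSE)
  M <- cbind(`(Intercept)` = 1, covariates)
  qrM <- qr(M)
  if (qrM$rank < ncol(M))
    stop(sprintf("rank-deficient covariate matrix (rank %d < %d columns incl. intercept)",
                 qrM$rank, ncol(M)), call. = FALSE)
  out <- cohort
  out$features <- qr.resid(qrM, cohort$features)
  dimnames(out$features) <- dimnames(cohort$features)
  out
}

#' Select features by extra-trees importance with correlation pruning
#'
#' Fits an extremely-randomized-trees classifier (via \pkg{ranger},
#' `splitrule = "extratrees"`) on the training cohort, drops features whose
#' impurity importance falls below the given importance quantile, then
#' greedily drops, from any remaining pair whose squared correlation exceeds
#' `correlation_cap`, the lower-importance member. Deterministic for a fixed
#' seed.
#'
#' @param train Training `labeled_cohort` (both classes present).
#' @param importance_quantile Quantile of the importance distribution below
#'   which features are dropped (0 keeps all).
#' @param correlation_cap Maximum allowed squared correlation r^2 in (0, 1]
#'   between two kept features (1 disables pruning).
#' @param seed Integer seed for the tree ensemble.
#' @param num_trees Number of trees in the importance forest.
#' @return A `feature_mask`: sorted unique `kept` indices, per-feature
#'   `importance`, and a `pruning_log` tibble (feature, reason, partner).
#' @export
select_features <- function(train, importance_quantile = 0.5,
                            correlation_cap = 0.36, seed = 1L,
                            num_trees = 200L) {
  stopifnot(inherits(train, "labeled_cohort"))
  if (length(unique(train$labels)) < 2L)
    stop("training cohort must contain both classes", call. = FALSE)
  stopifnot(importance_quantile >= 0, importance_quantile <= 1,
            correlation_cap > 0, correlation_cap <= 1)
  X <- train$features
  p <- ncol(X)
  fit <- ranger::ranger(
    x = as.data.frame(X), y = factor(train$labels, levels = c(0, 1)),
    num.trees = num_trees, splitrule = "extratrees", num.random.splits = 1L,
    importance = "impurity", seed = seed, num.threads = 1L,
    classification = TRUE)
  imp <- as.numeric(fit$variable.importance)
  names(imp) <- colnames(X)

  thresh <- stats::quantile(imp, importance_quantile, names = FALSE, type = 7)
  kept <- which(imp >= thresh)
  dropped_low <- setdiff(seq_len(p), kept)
  log_feat <- dropped_low
  log_reason <- rep("low_importance", length(dropped_low))
  log_partner <- rep(NA_integer_, length(dropped_low))

  # Greedy correlation pruning: walk survivors in decreasing importance,
  # drop any feature too correlated with an already-accepted one.
  ord <- kept[order(-imp[kept], kept)]
  accepted <- integer(0)
  for (j in ord) {
    if (length(accepted)) {
      r2 <- suppressWarnings(stats::cor(X[, j], X[, accepted, drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      if (any(r2 > correlation_cap)) {
        partner <- accepted[which.max(r2)]
        log_feat <- c(log_feat, j)
        log_reason <- c(log_reason, "correlated")
        log_partner <- c(log_partner, partner)
        next
      }
    }
    accepted <- c(accepted, j)
  }
  kept <- sort(accepted)
  if (!length(kept))
    stop("feature mask is empty; relax importance_quantile or correlation_cap",
         call. = FALSE)
  structure(list(kept = kept, importance = imp,
                 pruning_log = tibble::tibble(feature = log_feat,
                                              reason = log_reason,
                                              partner = log_partner),
                 importance_quantile = importance_quantile,
                 correlation_cap = correlation_cap, seed = seed),
            class = "feature_mask")
}

#' Apply a feature mask to a cohort
#' @param mask A `feature_mask` from [select_features()].
#' @param cohort A `labeled_cohort` over the same feature space.
#' @return The cohort restricted to the kept features.
#' @export
apply_feature_mask <- function(mask, cohort) {
  stopifnot(inherits(mask, "feature_mask"), inherits(cohort, "labeled_cohort"))
  out <- cohort
  out$features <- cohort$features[, mask$kept, drop = FALSE]
  out$feature_meta <- cohort$feature_meta[mask$kept, , drop = FALSE]
  out
}

#' Serialize a feature mask to JSON
#' @param mask A `feature_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_mask <- function(mask, path) {
  jsonlite::write_json(unclass(mask), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
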