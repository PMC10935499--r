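# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately naive: explicit loops over pairs,
# thresholds and confusion cells.

oracle_roc_auc <- function(y, s) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  tot / (length(pos) * length(neg))
}

oracle_auc_pr <- function(y, s) {
  th <- sort(unique(s), decreasing = TRUE)
  P <- sum(y == 1)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    pred <- s >= t
    tp <- sum(pred & y == 1)
    fp <- sum(pred & y == 0)
    prec <- tp / (tp + fp)
    rec <- tp / P
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

oracle_thresholded <- function(y, s, thr = 0.5) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(y)) {
    pred <- s[i] >= thr
    if (pred && y[i] == 1) tp <- tp + 1
    if (pred && y[i] == 0) fp <- fp + 1
    if (!pred && y[i] == 0) tn <- tn + 1
    if (!pred && y[i] == 1) fn <- fn + 1
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  tnr <- if (tn + fp == 0) 0 else tn / (tn + fp)
  fb <- function(beta) {
    den <- beta^2 * prec + rec
    if (den == 0) 0 else (1 + beta^2) * prec * rec / den
  }
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  ll <- 0
  for (i in seq_along(y)) {
    p <- min(max(s[i], 1e-15), 1 - 1e-15)
    ll <- ll - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
  }
  list(balanced_accuracy = (rec + tnr) / 2, precision = prec, recall = rec,
       f_half = fb(0.5), f1 = fb(1), f2 = fb(2), log_loss = ll / length(y),
       mcc = mcc)
}

# random metric instance with ties and both classes guaranteed
random_metric_instance <- function(n) {
  repeat {
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (any(y == 1) && any(y == 0)) break
  }
  s <- round(runif(n), 2)
  list(y = y, s = s)
}

# closed-form OLS residuals via the normal equations
oracle_ols_resid <- function(X, covs) {
  M <- cbind(1, covs)
  beta <- solve(t(M) %*% M, t(M) %*% X)
  X - M %*% beta
}

# one full-batch gradient step of mean regularized log-loss from (w, b)
oracle_logreg_step <- function(x, y, w, b, eta, l2) {
  n <- nrow(x)
  p <- 1 / (1 + exp(-(x %*% w + b)))
  gw <- t(x) %*% (p - y) / n + l2 * w
  gb <- mean(p - y)
  list(w = drop(w - eta * gw), b = b - eta * gb)
}

# small dense shard with both classes, deterministic
make_shard <- function(n = 40, d = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  y <- rep(c(0L, 1L), length.out = n)
  x[y == 1, 1] <- x[y == 1, 1] + 1
  list(x = x, y = y)
}

small_spec <- function(n_cases = 30L, n_controls = 60L, seed = 1L, ...) {
  cohort_spec(n_cases, n_controls, n_genetic = 8L, n_transcriptomic = 12L,
              seed = seed, ...)
}

param_dist <- function(a, b) {
  sqrt(sum(vapply(names(a), function(nm) sum((a[[nm]] - b[[nm]])^2), numeric(1))))
}

max_param_diff <- function(a, b) {
  max(vapply(names(a), function(nm) max(abs(a[[nm]] - b[[nm]])), numeric(1)))
}
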