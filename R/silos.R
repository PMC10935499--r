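# Client sharding: partition a training cohort's sample indices into n
# disjoint silo datasets under three strategies of increasing heterogeneity:
#   uniform_stratified — label and size homogeneity,
#   uniform_random     — label heterogeneity, size homogeneity,
#   linear_random      — label and size heterogeneity (sizes grow linearly).
# Surplus samples always go to the LAST client (deterministic rule).

SPLIT_STRATEGIES <- c("uniform_stratified", "uniform_random", "linear_random")

new_shard_set <- function(shards, strategy, seed, source_size) {
  structure(list(shards = shards, strategy = strategy,
                 n_clients = length(shards), seed = as.integer(seed),
                 source_size = as.integer(source_size)),
            class = "shard_set")
}

#' @export
print.shard_set <- function(x, ...) {
  cat(sprintf("<shard_set: %s, %d clients over %d samples, seed %d>\n",
              x$strategy, x$n_clients, x$source_size, x$seed))
  cat("  sizes:", paste(lengths(x$shards), collapse = ", "), "\n")
  invisible(x)
}

check_split_pre <- function(cohort, n_clients) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  n_clients <- as.integer(n_clients)
  if (n_clients < 1L) stop("n_clients must be >= 1", call. = FALSE)
  n_clients
}

#' Partition a cohort by phenotype into balanced client shards
#'
#' Splits the cohort by phenotype, shuffles each phenotype partition, and
#' assigns `floor(n_class / n_clients)` samples of each class to every
#' client; class surpluses go to the last client. Every shard therefore has
#' a case:control ratio within integer rounding of the global ratio.
#'
#' @param cohort A `labeled_cohort`.
#' @param n_clients Number of federation clients (N >= 1).
#' @param seed Integer seed for the shuffles.
#' @return A `shard_set`: list of disjoint sample-index vectors covering the
#'   cohort, plus strategy/seed/source-size provenance.
#' @export
split_uniform_stratified <- function(cohort, n_clients, seed = 1L) {
  n_clients <- check_split_pre(cohort, n_clients)
  cases <- which(cohort$labels == 1L)
  controls <- which(cohort$labels == 0L)
  if (length(cases) < n_clients || length(controls) < n_clients)
    stop(sprintf("infeasible stratified split: %d cases / %d controls for %d clients (need >= 1 of each class per client)",
                 length(cases), length(controls), n_clients), call. = FALSE)
  assign_class <- function(idx, sub) {
    perm <- with_seed(derive_seed(seed, "stratified", sub), sample(idx))
    base <- length(idx) %/% n_clients
    out <- split(perm[seq_len(base * n_clients)], rep(seq_len(n_clients), each = base))
    out <- unname(out)
    surplus <- perm[-seq_len(base * n_clients)]
    if (length(surplus)) out[[n_clients]] <- c(out[[n_clients]], surplus)
    out
  }
  by_case <- assign_class(cases, "case")
  by_ctrl <- assign_class(controls, "control")
  shards <- lapply(seq_len(n_clients), function(i) sort(c(by_case[[i]], by_ctrl[[i]])))
  new_shard_set(shards, "uniform_stratified", seed, n_samples(cohort))
}

#' Partition a cohort uniformly at random into equal-size shards
#'
#' Assigns `floor(C / n_clients)` samples per client by uniform random
#' sampling without replacement (surplus to the last client). Class
#' composition is random, so shards exhibit label heterogeneity. Draws whose
#' shards miss a class are resampled with a fresh derived seed, up to
#' `max_retries` attempts.
#'
#' @inheritParams split_uniform_stratified
#' @param max_retries Resampling attempts before giving up on feasibility.
#' @return A `shard_set`.
#' @export
split_uniform_random <- function(cohort, n_clients, seed = 1L, max_retries = 100L) {
  n_clients <- check_split_pre(cohort, n_clients)
  C <- n_samples(cohort)
  if (C < 2L * n_clients)
    stop("infeasible uniform split: need at least 2 samples per client", call. = FALSE)
  base <- C %/% n_clients
  for (attempt in seq_len(max_retries)) {
    perm <- with_seed(derive_seed(seed, "uniform", attempt), sample.int(C))
    shards <- unname(split(perm[seq_len(base * n_clients)],
                           rep(seq_len(n_clients), each = base)))
    surplus <- perm[-seq_len(base * n_clients)]
    if (length(surplus)) shards[[n_clients]] <- c(shards[[n_clients]], surplus)
    shards <- lapply(shards, sort)
    ok <- all(vapply(shards, function(s) {
      y <- cohort$labels[s]; any(y == 1L) && any(y == 0L)
    }, logical(1)))
    if (ok) return(new_shard_set(shards, "uniform_random", seed, C))
  }
  stop(sprintf("could not draw a feasible uniform_random split in %d attempts (every shard needs both classes)",
               max_retries), call. = FALSE)
}

#' Partition a cohort into linearly growing shards
#'
#' Client i (1-based) receives `i * c` samples where
#' `c = floor(2C / (N (N + 1)))`, chosen by uniform random sampling without
#' replacement; the surplus `C - c N (N + 1) / 2` goes to the last client.
#' Shard sizes strictly increase with the client index, giving both size and
#' label heterogeneity.
#'
#' @inheritParams split_uniform_stratified
#' @return A `shard_set`.
#' @export
split_linear_random <- function(cohort, n_clients, seed = 1L) {
  n_clients <- check_split_pre(cohort, n_clients)
  C <- n_samples(cohort)
  cbase <- (2L * C) %/% (n_clients * (n_clients + 1L))
  if (cbase < 1L)
    stop(sprintf("infeasible linear split: base allotment floor(2*%d/(%d*%d)) = 0 (too many clients)",
                 C, n_clients, n_clients + 1L), call. = FALSE)
  sizes <- cbase * seq_len(n_clients)
  sizes[n_clients] <- sizes[n_clients] + (C - sum(sizes))
  perm <- with_seed(derive_seed(seed, "linear"), sample.int(C))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  shards <- lapply(seq_len(n_clients),
                   function(i) sort(perm[starts[i]:ends[i]]))
  new_shard_set(shards, "linear_random", seed, C)
}

#' Split a cohort under a named strategy
#' @param cohort A `labeled_cohort`.
#' @param strategy One of `"uniform_stratified"`, `"uniform_random"`,
#'   `"linear_random"`.
#' @param n_clients,seed Passed to the strategy function.
#' @return A `shard_set`.
#' @export
split_cohort <- function(cohort, strategy, n_clients, seed = 1L) {
  strategy <- match.arg(strategy, SPLIT_STRATEGIES)
  switch(strategy,
         uniform_stratified = split_uniform_stratified(cohort, n_clients, seed),
         uniform_random = split_uniform_random(cohort, n_clients, seed),
         linear_random = split_linear_random(cohort, n_clients, seed))
}

#' Validate a shard set against its source cohort
#'
#' Checks the partition invariants (pairwise-disjoint shards whose union is
#' exactly the cohort's index set) and federation feasibility (every shard
#' holds at least one case and one control).
#'
#' @param shardset A `shard_set`.
#' @param cohort The source `labeled_cohort`.
#' @return A list: `pass` (logical), `per_shard` tibble (shard, size,
#'   n_cases, n_controls, feasible), `partition_ok`, and `failures`
#'   (character vector naming offending shards, empty when passing).
#' @export
validate_shards <- function(shardset, cohort) {
  stopifnot(inherits(shardset, "shard_set"), inherits(cohort, "labeled_cohort"))
  C <- n_samples(cohort)
  all_idx <- sort(unlist(shardset$shards, use.names = FALSE))
  if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > C))
    stop("shard indices out of cohort bounds", call. = FALSE)
  partition_ok <- identical(all_idx, seq_len(C)) # disjoint + exhaustive
  per <- tibble::tibble(
    shard = seq_along(shardset$shards),
    size = lengths(shardset$shards),
    n_cases = vapply(shardset$shards, function(s) sum(cohort$labels[s] == 1L), 1L),
    n_controls = vapply(shardset$shards, function(s) sum(cohort$labels[s] == 0L), 1L))
  per$feasible <- per$n_cases >= 1L & per$n_controls >= 1L
  failures <- character(0)
  if (!partition_ok) failures <- "partition (shards not disjoint-exhaustive)"
  bad <- per$shard[!per$feasible]
  if (length(bad))
    failures <- c(failures, sprintf("shard %d missing a class", bad))
  list(pass = partition_ok && all(per$feasible), per_shard = per,
       partition_ok = partition_ok, failures = failures)
}

#' Heterogeneity summary indices of a shard set
#'
#' `label_skew` is the maximum pairwise difference in shard case fractions;
#' `size_skew` is the max/min shard size ratio. Stratified splits minimize
#' both; uniform random raises label skew; linear random raises both.
#'
#' @param shardset A `shard_set`.
#' @param cohort The source `labeled_cohort`.
#' @return A list with `label_skew` and `size_skew`.
#' @export
shard_heterogeneity <- function(shardset, cohort) {
  frac <- vapply(shardset$shards,
                 function(s) mean(cohort$labels[s] == 1L), numeric(1))
  sizes <- lengths(shardset$shards)
  list(label_skew = max(frac) - min(frac),
       size_skew = max(sizes) / min(sizes))
}

#' Serialize / load a shard set as JSON
#' @param shardset A `shard_set`.
#' @param path File path.
#' @return `path` invisibly for write; a `shard_set` for read.
#' @export
write_shards <- function(shardset, path) {
  jsonlite::write_json(unclass(shardset), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shards
#' @export
read_shards <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  shards <- lapply(x$shards, as.integer)
  new_shard_set(shards, x$strategy, x$seed, x$source_size)
}
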