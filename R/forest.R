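# Boosted-forest learner: an ensemble of shallow regression trees fitted to
# the gradient/Hessian of the log-loss (Newton boosting), grown from
# whatever global ensemble a client receives. Trees are plain nested lists
# (split feature, threshold, children, leaf value) so they can be
# serialized, concatenated across clients, and have their leaf values
# rescaled by the server — the aggregable ModelParams form for the
# non-parametric learner family.
#
# Leaf-to-probability transform: a sample's score is the logistic of the
# sum of leaf values over all trees (boosted-forest convention; the empty
# ensemble scores 0.5 everywhere).

# Exact greedy split search on the working gradients. Deterministic:
# features scanned in order, thresholds at midpoints of consecutive
# distinct values, first best gain wins.
build_tree <- function(x, g, h, max_depth, lambda, min_node) {
  grow <- function(idx, depth) {
    G <- sum(g[idx]); H <- sum(h[idx])
    leaf <- function() list(leaf = TRUE, value = -G / (H + lambda))
    if (depth >= max_depth || length(idx) < 2L * min_node) return(leaf())
    best <- list(gain = 1e-12, feature = NA_integer_, threshold = NA_real_)
    parent_score <- G^2 / (H + lambda)
    for (j in seq_len(ncol(x))) {
      xv <- x[idx, j]
      ord <- order(xv, method = "radix")
      xs <- xv[ord]
      gs <- cumsum(g[idx][ord])
      hs <- cumsum(h[idx][ord])
      n <- length(idx)
      valid <- which(xs[-n] < xs[-1L])        # split between distinct values
      valid <- valid[valid >= min_node & valid <= n - min_node]
      if (!length(valid)) next
      GL <- gs[valid]; HL <- hs[valid]
      gain <- GL^2 / (HL + lambda) + (G - GL)^2 / (H - HL + lambda) - parent_score
      k <- which.max(gain)
      if (gain[k] > best$gain) {
        best <- list(gain = gain[k], feature = j,
                     threshold = (xs[valid[k]] + xs[valid[k] + 1L]) / 2)
      }
    }
    if (is.na(best$feature)) return(leaf())
    go_left <- x[idx, best$feature] <= best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }
  grow(seq_len(nrow(x)), 0L)
}

predict_tree <- function(node, x) {
  out <- numeric(nrow(x))
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (isTRUE(node$leaf)) {
      out[idx] <<- node$value
      return()
    }
    go_left <- x[idx, node$feature] <= node$threshold
    recurse(node$left, idx[go_left])
    recurse(node$right, idx[!go_left])
  }
  recurse(node, seq_len(nrow(x)))
  out
}

forest_margin <- function(params, x) {
  m <- numeric(nrow(x))
  for (tr in params$trees) m <- m + predict_tree(tr$node, x)
  m
}

scale_tree_leaves <- function(node, factor) {
  if (isTRUE(node$leaf)) {
    node$value <- node$value * factor
    return(node)
  }
  node$left <- scale_tree_leaves(node$left, factor)
  node$right <- scale_tree_leaves(node$right, factor)
  node
}

# Grow trees_per_round * epochs new trees from the current ensemble.
fit_forest <- function(state, x, y, epochs) {
  hp <- state$hyper
  params <- state$params
  F <- forest_margin(params, x)
  n_new <- as.integer(hp$trees_per_round) * epochs
  for (t in seq_len(n_new)) {
    p <- stats::plogis(F)
    g <- p - y
    h <- pmax(p * (1 - p), 1e-16)
    node <- build_tree(x, g, h, hp$max_depth, hp$tree_lambda, hp$min_node)
    node <- scale_tree_leaves(node, hp$tree_eta)
    params$trees[[length(params$trees) + 1L]] <-
      list(node = node, round = NA_integer_, client = NA_integer_)
    F <- F + predict_tree(node, x)
  }
  state$params <- params
  state$epochs_done <- state$epochs_done + epochs
  state
}

# Strip provenance so tree prefixes can be compared structurally.
tree_structures <- function(params) lapply(params$trees, `[[`, "node")

#' Aggregate client forest ensembles into a new global ensemble
#'
#' Every client must have grown its trees from the same incoming global
#' ensemble (a shared prefix). The new global ensemble is that prefix plus
#' the concatenation of each client's newly grown trees, with every new
#' tree's leaf values scaled by 1/N — a bagging-style average of the round's
#' increment, so the aggregated margin is the mean of the clients' new
#' margins. With N = 1 the client's trees are appended unscaled, making a
#' federation of one reduce to central boosting. Per-tree provenance
#' (round, client) is recorded.
#'
#' @param params_list List of client forest parameter lists.
#' @param global The incoming global forest parameters (the shared prefix).
#' @param round_index Round number recorded on the new trees.
#' @return The new global forest parameters.
#' @export
aggregate_forest <- function(params_list, global, round_index = NA_integer_) {
  if (!length(params_list)) stop("empty client list", call. = FALSE)
  n_prefix <- length(global$trees)
  prefix <- tree_structures(global)
  N <- length(params_list)
  out <- global
  for (i in seq_along(params_list)) {
    cl <- params_list[[i]]
    if (length(cl$trees) < n_prefix ||
        !identical(tree_structures(cl)[seq_len(n_prefix)], prefix))
      stop(sprintf("client %d ensemble does not extend the incoming global ensemble (prefix mismatch)",
                   i), call. = FALSE)
    new_trees <- cl$trees[seq_len(length(cl$trees) - n_prefix) + n_prefix]
    for (tr in new_trees) {
      tr$node <- scale_tree_leaves(tr$node, 1 / N)
      tr$round <- round_index
      tr$client <- i
      out$trees[[length(out$trees) + 1L]] <- tr
    }
  }
  out
}
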