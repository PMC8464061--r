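#' Simulate expression data with an induced hierarchical structure
#'
#' Generates a random balanced binary tree over `n_terminal_clusters`
#' terminal clusters (each split divides the clusters as evenly as possible,
#' with random membership) and partitions the signal features (a
#' `signal_fraction` of all features) over the tree's internal branches:
#' each branch receives at least one feature and the remainder is allocated
#' proportionally to the number of terminal clusters under the branch, so
#' that shallower divisions involve more features, as major lineage splits
#' do in transcriptomic data. A feature assigned to a branch separates that
#' branch's two sides by exactly `effect_size`: one side is shifted by
#' `+effect_size/2` and the other by `-effect_size/2` (which side is
#' positive is drawn per feature). Observations are allocated near-evenly
#' to the terminal clusters (remainder round-robin) and i.i.d. Gaussian
#' noise with standard deviation `noise_sd` is added to every entry. The
#' defaults mirror an observation-level simulation regime of 300
#' observations by 10,000 features with unit noise.
#'
#' @param n_observations,n_features Matrix dimensions.
#' @param n_terminal_clusters Number of leaves of the generating tree.
#' @param signal_fraction Fraction of features carrying branch signal, in
#'   (0, 1].
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param effect_size Magnitude of each branch-wise mean shift (log scale).
#' @param seed Integer seed; output is fully determined by it.
#' @return A list of class `k2_simulation`: `matrix` (features x
#'   observations), `truth` (the generating tree as a `k2_tree`), `labels`
#'   (named character vector observation -> terminal cluster, usable as
#'   group labels), and `spec` (the arguments).
#' @export
simulate_hierarchy <- function(n_observations = 300L, n_features = 10000L,
                               n_terminal_clusters = 4L,
                               signal_fraction = 0.1, noise_sd = 1,
                               effect_size = 1, seed = 1L) {
  stopifnot(
    n_terminal_clusters >= 2L, n_terminal_clusters <= n_observations,
    signal_fraction > 0, signal_fraction <= 1, noise_sd > 0, effect_size > 0
  )
  L <- as.integer(n_terminal_clusters)
  n_signal <- round(signal_fraction * n_features)
  if (n_signal < L - 1L) stop("insufficient signal features", call. = FALSE)

  with_seed(seed, {
    clusters <- sprintf("C%d", seq_len(L))
    # random full binary tree over the cluster labels, recorded pre-order
    records <- list()
    recurse <- function(members, path, parent, depth) {
      rec <- list(
        node_id = path, parent = parent, depth = depth,
        items = list(sort(members)), n_items = length(members),
        is_leaf = length(members) == 1L, children = list(NULL)
      )
      if (length(members) > 1L) {
        k <- length(members)
        left <- sample(members, k %/% 2L)
        right <- setdiff(members, left)
        rec$children <- list(c(paste0(path, "0"), paste0(path, "1")))
        records[[length(records) + 1L]] <<- rec
        recurse(left, paste0(path, "0"), path, depth + 1L)
        recurse(right, paste0(path, "1"), path, depth + 1L)
      } else {
        records[[length(records) + 1L]] <<- rec
      }
    }
    recurse(clusters, "r", NA_character_, 0L)
    truth <- tree_from_records(records)

    internal_ids <- truth$nodes$node_id[!truth$nodes$is_leaf]
    n_branches <- length(internal_ids)
    feat_ids <- sprintf("g%05d", seq_len(n_features))
    signal <- sample.int(n_features, n_signal)
    # every branch gets >= 1 signal feature; the remainder is multinomial
    # with weights proportional to the branch's terminal-cluster count
    wts <- vapply(
      internal_ids,
      function(id) truth$nodes$n_items[match(id, truth$nodes$node_id)],
      numeric(1)
    )
    alloc <- rep(1L, n_branches)
    if (n_signal > n_branches) {
      alloc <- alloc +
        as.vector(stats::rmultinom(1L, n_signal - n_branches, wts / sum(wts)))
    }
    branch_of <- rep(seq_len(n_branches), alloc)[order(runif(n_signal))]

    means <- matrix(0, n_features, L, dimnames = list(feat_ids, clusters))
    for (j in seq_len(n_branches)) {
      node <- truth$nodes[match(internal_ids[j], truth$nodes$node_id), ]
      kids <- node$children[[1L]]
      side_a <- truth$nodes$items[[match(kids[1L], truth$nodes$node_id)]]
      side_b <- truth$nodes$items[[match(kids[2L], truth$nodes$node_id)]]
      feats <- signal[branch_of == j]
      sgn <- sample(c(-1, 1), length(feats), replace = TRUE)
      means[feats, side_a] <- means[feats, side_a] + sgn * effect_size / 2
      means[feats, side_b] <- means[feats, side_b] - sgn * effect_size / 2
    }

    base_sizes <- rep(n_observations %/% L, L)
    extra <- n_observations %% L
    if (extra > 0L) base_sizes[seq_len(extra)] <- base_sizes[seq_len(extra)] + 1L
    labels <- rep(clusters, base_sizes)
    obs_ids <- sprintf("obs%04d", seq_len(n_observations))
    names(labels) <- obs_ids

    mat <- means[, labels, drop = FALSE] +
      matrix(rnorm(n_features * n_observations, 0, noise_sd), n_features)
    dimnames(mat) <- list(feat_ids, obs_ids)

    structure(
      list(
        matrix = mat, truth = truth, labels = labels,
        spec = list(
          n_observations = n_observations, n_features = n_features,
          n_terminal_clusters = L, signal_fraction = signal_fraction,
          noise_sd = noise_sd, effect_size = effect_size, seed = seed
        )
      ),
      class = "k2_simulation"
    )
  })
}

# Assemble a k2_tree from pre-order node records; heights are set so the
# deepest internal node sits at 1 and leaves at half their parent.
tree_from_records <- function(records) {
  nodes <- dplyr::bind_rows(lapply(records, function(r) {
    tibble(
      node_id = r$node_id, parent = r$parent, depth = r$depth,
      m = if (r$is_leaf) NA_integer_ else r$depth + 1L,
      items = r$items, n_items = r$n_items, is_leaf = r$is_leaf,
      ps = NA_real_, height = NA_real_, stop_reason = NA_character_,
      children = r$children, seed = NA_integer_
    )
  }))
  max_d <- max(nodes$depth[!nodes$is_leaf])
  nodes$height <- ifelse(nodes$is_leaf, NA_real_, max_d - nodes$depth + 1)
  for (i in seq_len(nrow(nodes))) {
    if (nodes$is_leaf[i]) {
      nodes$height[i] <- nodes$height[match(nodes$parent[i], nodes$node_id)] * 0.5
    }
  }
  structure(
    list(nodes = nodes, items = sort(unlist(nodes$items[nodes$is_leaf]))),
    class = "k2_tree"
  )
}

#' Build a binary tree from a nested list specification
#'
#' Convenience constructor for tests and examples: a leaf is a character
#' vector of item ids, an internal node is a list of exactly two nested
#' specifications.
#'
#' @param nested Nested list / character structure.
#' @return A `k2_tree`.
#' @export
#' @examples
#' k2_tree(list(list("a", "b"), list("c", "d")))
k2_tree <- function(nested) {
  records <- list()
  recurse <- function(node, path, parent, depth) {
    if (is.character(node)) {
      records[[length(records) + 1L]] <<- list(
        node_id = path, parent = parent, depth = depth,
        items = list(sort(node)), n_items = length(node),
        is_leaf = TRUE, children = list(NULL)
      )
      return(node)
    }
    if (!is.list(node) || length(node) != 2L) {
      stop("internal nodes must be lists of exactly two children", call. = FALSE)
    }
    idx <- length(records) + 1L
    records[[idx]] <<- list() # placeholder to keep pre-order
    left <- recurse(node[[1L]], paste0(path, "0"), path, depth + 1L)
    right <- recurse(node[[2L]], paste0(path, "1"), path, depth + 1L)
    records[[idx]] <<- list(
      node_id = path, parent = parent, depth = depth,
      items = list(sort(c(left, right))), n_items = length(left) + length(right),
      is_leaf = FALSE, children = list(c(paste0(path, "0"), paste0(path, "1")))
    )
    c(left, right)
  }
  recurse(nested, "r", NA_character_, 0L)
  tree_from_records(records)
}

# Convert an hclust fit (over item labels) to a k2_tree.
hclust_to_tree <- function(hc) {
  labels <- hc$labels
  members <- function(i) {
    if (i < 0) {
      labels[-i]
    } else {
      c(members(hc$merge[i, 1L]), members(hc$merge[i, 2L]))
    }
  }
  records <- list()
  recurse <- function(i, path, parent, depth) {
    if (i < 0) {
      records[[length(records) + 1L]] <<- list(
        node_id = path, parent = parent, depth = depth,
        items = list(labels[-i]), n_items = 1L,
        is_leaf = TRUE, children = list(NULL)
      )
      return(invisible(NULL))
    }
    records[[length(records) + 1L]] <<- list(
      node_id = path, parent = parent, depth = depth,
      items = list(sort(members(i))), n_items = length(members(i)),
      is_leaf = FALSE, children = list(c(paste0(path, "0"), paste0(path, "1")))
    )
    recurse(hc$merge[i, 1L], paste0(path, "0"), path, depth + 1L)
    recurse(hc$merge[i, 2L], paste0(path, "1"), path, depth + 1L)
  }
  recurse(nrow(hc$merge), "r", NA_character_, 0L)
  tree_from_records(records)
}

#' @export
print.k2_simulation <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<k2_simulation> %d features x %d observations, %d terminal clusters\n",
    s$n_features, s$n_observations, s$n_terminal_clusters
  ))
  cat(sprintf(
    "  signal fraction %.2f, noise sd %.2f, effect size %.2f, seed %d\n",
    s$signal_fraction, s$noise_sd, s$effect_size, s$seed
  ))
  invisible(x)
}
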