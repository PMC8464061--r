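#' Configuration for the recursive taxonomy
#'
#' @param mode `"observation"` (each column is an item) or `"group"` (items
#'   are pre-labeled groups of observations, split by constrained k-means).
#' @param p Number of perturbations per candidate partition. More
#'   perturbations shrink the Monte-Carlo error of the stability score at
#'   roughly `1/sqrt(p)`.
#' @param feature_select `"MAD"`, `"SD"`, or `"F"` (see [select_features()]).
#' @param n_features `"sqrt"` (default, `round(sqrt(F))`) or an integer.
#' @param perturbation_linkage,aggregate_linkage Agglomeration methods for
#'   the per-perturbation observation clustering and for the cosine-matrix
#'   aggregation: `"ward"`, `"average"`, `"complete"`, `"single"`.
#' @param stability_min Nodes whose partition stability falls below this
#'   value become leaves. Default 0 disables stability stopping.
#' @param min_items Nodes with fewer items are not split. Defaults to 3 in
#'   observation mode and 2 in group mode.
#' @param seed Master seed; together with the other settings it fully
#'   determines the output.
#' @param custom_partitioner Optional function `(x_selected, groups, seed)`
#'   returning a named `{-1, +1}` vector over items, plugged in as the
#'   perturbation-specific partitioner.
#' @return A list of class `k2_config`.
#' @export
taxonomy_config <- function(mode = c("observation", "group"), p = 100L,
                            feature_select = c("MAD", "SD", "F"),
                            n_features = "sqrt",
                            perturbation_linkage = "ward",
                            aggregate_linkage = "ward",
                            stability_min = 0, min_items = NULL,
                            seed = 42L, custom_partitioner = NULL) {
  mode <- match.arg(mode)
  feature_select <- match.arg(feature_select)
  p <- as.integer(p)
  if (p < 1L) stop("`p` must be >= 1", call. = FALSE)
  if (!identical(n_features, "sqrt")) {
    n_features <- as.integer(n_features)
    if (is.na(n_features) || n_features < 1L) {
      stop("`n_features` must be \"sqrt\" or a positive integer", call. = FALSE)
    }
  }
  linkage_method(perturbation_linkage)
  linkage_method(aggregate_linkage)
  if (stability_min < 0 || stability_min > 1) {
    stop("`stability_min` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(min_items)) min_items <- if (mode == "group") 2L else 3L
  min_items <- as.integer(min_items)
  if (min_items < 2L) stop("`min_items` must be >= 2", call. = FALSE)
  if (!is.null(custom_partitioner) && !is.function(custom_partitioner)) {
    stop("`custom_partitioner` must be a function", call. = FALSE)
  }
  structure(
    list(
      mode = mode, p = p, feature_select = feature_select,
      n_features = n_features,
      perturbation_linkage = perturbation_linkage,
      aggregate_linkage = aggregate_linkage,
      stability_min = stability_min, min_items = min_items,
      seed = as.integer(seed), custom_partitioner = custom_partitioner
    ),
    class = "k2_config"
  )
}

#' Recursive ensemble K=2 partitioning
#'
#' Builds a binary taxonomy over items (observations, or pre-labeled groups)
#' by depth-first recursion: at each node with at least `min_items` items, an
#' ensemble of `p` feature-bootstrap perturbations is partitioned, aggregated
#' into a cosine similarity matrix, scored for stability, and split at K = 2;
#' the recursion descends into both sides. A node becomes a leaf when it has
#' fewer than `min_items` items, when its stability falls below
#' `stability_min`, or when more than half of its perturbations are
#' degenerate. Branch heights are assigned by [compute_heights()].
#'
#' @param x Numeric matrix, features x observations, with dimnames.
#' @param config A [taxonomy_config()].
#' @param groups Named character vector observation id -> group label;
#'   required in group mode.
#' @return Object of class `k2_taxonomy`: a list with a `nodes` tibble
#'   (`node_id`, `parent`, `depth`, `m`, `items`, `n_items`, `is_leaf`,
#'   `ps`, `height`, `stop_reason`, `children`), plus `mode`, `config`,
#'   `groups`, `items`.
#' @export
#' @examples
#' sim <- simulate_hierarchy(
#'   n_observations = 40, n_features = 200,
#'   n_terminal_clusters = 2, signal_fraction = 0.2, noise_sd = 0.3, seed = 7
#' )
#' tax <- run_taxonomy(sim$matrix, taxonomy_config(p = 20, seed = 1))
#' tidy(tax)
run_taxonomy <- function(x, config = taxonomy_config(), groups = NULL) {
  validate_matrix(x)
  stopifnot(inherits(config, "k2_config"))
  if (config$mode == "group") {
    if (is.null(groups)) stop("group mode requires `groups`", call. = FALSE)
    groups <- validate_groups(x, groups)
    items <- levels(factor(groups))
  } else {
    items <- colnames(x)
  }
  if (length(items) < 2L) stop("need >= 2 items", call. = FALSE)

  records <- list()
  recurse <- function(node_items, path, parent, depth, m_parent) {
    node_obs <- if (config$mode == "group") {
      names(groups)[groups %in% node_items]
    } else {
      node_items
    }
    sub <- x[, node_obs, drop = FALSE]
    sub_groups <- if (!is.null(groups)) groups[node_obs]
    rec <- list(
      node_id = path, parent = parent, depth = depth, m = NA_integer_,
      items = list(sort(node_items)), n_items = length(node_items),
      is_leaf = TRUE, ps = NA_real_, height = NA_real_,
      stop_reason = NA_character_, children = list(NULL),
      seed = derive_seed(config$seed, path)
    )
    if (length(node_items) < config$min_items) {
      rec$stop_reason <- "min_items"
      records[[length(records) + 1L]] <<- rec
      return(invisible(NULL))
    }
    ens <- tryCatch(
      build_ensemble(sub, config, groups = sub_groups, node_path = path),
      k2_degenerate = function(e) e
    )
    if (inherits(ens, "k2_degenerate")) {
      rec$stop_reason <- "degenerate"
      records[[length(records) + 1L]] <<- rec
      message(sprintf("node %s: %s", path, conditionMessage(ens)))
      return(invisible(NULL))
    }
    Q <- cosine_similarity(ens)
    ps <- partition_stability(Q)
    rec$ps <- ps
    if (ps < config$stability_min) {
      rec$stop_reason <- "stability"
      records[[length(records) + 1L]] <<- rec
      return(invisible(NULL))
    }
    split <- aggregate_partition(Q, config$aggregate_linkage)
    side_a <- names(split)[split > 0]
    side_b <- names(split)[split < 0]
    rec$is_leaf <- FALSE
    rec$m <- m_parent + 1L
    rec$children <- list(c(paste0(path, "0"), paste0(path, "1")))
    records[[length(records) + 1L]] <<- rec
    message(sprintf(
      "node %s: N=%d PS=%.4f split %d|%d",
      path, length(node_items), ps, length(side_a), length(side_b)
    ))
    recurse(side_a, paste0(path, "0"), path, depth + 1L, m_parent + 1L)
    recurse(side_b, paste0(path, "1"), path, depth + 1L, m_parent + 1L)
  }
  recurse(items, "r", NA_character_, 0L, 0L)

  nodes <- dplyr::bind_rows(lapply(records, function(r) {
    tibble(
      node_id = r$node_id, parent = r$parent, depth = r$depth, m = r$m,
      items = r$items, n_items = r$n_items, is_leaf = r$is_leaf,
      ps = r$ps, height = r$height, stop_reason = r$stop_reason,
      children = r$children, seed = r$seed
    )
  }))
  out <- structure(
    list(
      nodes = nodes, mode = config$mode, config = config,
      groups = groups, items = items
    ),
    class = c("k2_taxonomy", "k2_tree")
  )
  compute_heights(out)
}

#' Assign branch heights from partition stabilities
#'
#' For an internal node reached through partitions `1..m` (its own included)
#' with stabilities \eqn{PS_1..PS_m} and item count \eqn{N_m}, the raw height
#' is \eqn{r_m = \log(N_m) + \sum_{l=1}^m \log(PS_l)} (natural logarithm);
#' one constant `c` per tree shifts all raw heights so that the minimum
#' partition-node height is exactly 1. Leaves, which carry no partition, are
#' displayed at half their parent's height; heights strictly decrease along
#' every root-to-leaf path.
#'
#' @param tax A `k2_taxonomy`.
#' @return The taxonomy with the `height` column filled in.
#' @export
compute_heights <- function(tax) {
  nodes <- tax$nodes
  internal <- !nodes$is_leaf
  if (!any(internal)) { # unsplit root
    nodes$height <- 1
    tax$nodes <- nodes
    return(tax)
  }
  if (any(internal & (!is.finite(nodes$ps) | nodes$ps <= 0))) {
    stop("internal node with non-positive stability", call. = FALSE)
  }
  cum <- setNames(rep(NA_real_, nrow(nodes)), nodes$node_id)
  raw <- rep(NA_real_, nrow(nodes))
  for (i in seq_len(nrow(nodes))) { # pre-order: parents precede children
    if (!internal[i]) next
    up <- nodes$parent[i]
    base <- if (is.na(up) || is.na(cum[up])) 0 else cum[up]
    cum[nodes$node_id[i]] <- base + log(nodes$ps[i])
    raw[i] <- log(nodes$n_items[i]) + cum[nodes$node_id[i]]
  }
  const <- 1 - min(raw[internal])
  h <- raw + const
  for (i in seq_len(nrow(nodes))) {
    if (!internal[i]) h[i] <- h[match(nodes$parent[i], nodes$node_id)] * 0.5
  }
  # root leaf under a stability/min_items stop at depth 0 is handled above
  for (i in seq_len(nrow(nodes))) {
    up <- nodes$parent[i]
    if (!is.na(up) && h[i] >= h[match(up, nodes$node_id)]) {
      stop("height monotonicity violated", call. = FALSE)
    }
  }
  nodes$height <- h
  tax$nodes <- nodes
  tax
}

#' Cut a taxonomy into K mutually exclusive clusters
#'
#' Opens internal nodes in order of decreasing height (ties broken by node
#' identifier) until K clusters exist; each cluster is the item set of one
#' frontier node.
#'
#' @param tax A `k2_taxonomy` (or truth tree from [simulate_hierarchy()]).
#' @param K Number of clusters, between 2 and the number of leaves.
#' @return Tibble with columns `item` and `cluster` (the frontier node id).
#' @export
cut_tree <- function(tax, K) {
  nodes <- tax$nodes
  n_leaves <- sum(nodes$is_leaf)
  K <- as.integer(K)
  if (K < 2L || K > n_leaves) {
    stop(sprintf("K must lie in [2, %d]", n_leaves), call. = FALSE)
  }
  frontier <- nodes$node_id[is.na(nodes$parent)]
  while (length(frontier) < K) {
    cand <- nodes[nodes$node_id %in% frontier & !nodes$is_leaf, ]
    cand <- cand[order(-cand$height, cand$node_id), ]
    open <- cand$node_id[1L]
    kids <- nodes$children[[match(open, nodes$node_id)]]
    frontier <- c(setdiff(frontier, open), kids)
  }
  out <- lapply(sort(frontier), function(id) {
    tibble(item = nodes$items[[match(id, nodes$node_id)]], cluster = id)
  })
  dplyr::bind_rows(out)
}

#' @export
print.k2_taxonomy <- function(x, ...) {
  n <- x$nodes
  cat(sprintf(
    "<k2_taxonomy> %s mode: %d items, %d nodes (%d leaves)\n",
    x$mode, length(x$items), nrow(n), sum(n$is_leaf)
  ))
  if (any(!n$is_leaf)) {
    cat(sprintf(
      "  root PS %.3f; internal PS range [%.3f, %.3f]; heights [1, %.3f]\n",
      n$ps[1L], min(n$ps[!n$is_leaf]), max(n$ps[!n$is_leaf]),
      max(n$height)
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Node-level summary of a taxonomy
#'
#' @param x A `k2_taxonomy`.
#' @param ... Unused.
#' @return Tibble with one row per node: identifiers, membership, item count,
#'   partition stability, height and stop reason.
#' @method tidy k2_taxonomy
#' @export
tidy.k2_taxonomy <- function(x, ...) {
  dplyr::select(
    x$nodes, "node_id", "parent", "depth", "m", "n_items", "is_leaf",
    "ps", "height", "stop_reason", "items"
  )
}

#' One-row summary of a taxonomy fit
#'
#' @param x A `k2_taxonomy`.
#' @param ... Unused.
#' @method glance k2_taxonomy
#' @export
glance.k2_taxonomy <- function(x, ...) {
  n <- x$nodes
  tibble(
    mode = x$mode, n_items = length(x$items), n_nodes = nrow(n),
    n_leaves = sum(n$is_leaf), max_depth = max(n$depth),
    root_ps = n$ps[1L], mean_ps = mean(n$ps[!n$is_leaf]),
    p = x$config$p, seed = x$config$seed
  )
}
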