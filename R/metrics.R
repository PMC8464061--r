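# Pairwise LCA partition depths: for every unordered item pair, the number
# of partitions separating the root from the pair's lowest common ancestor
# (root = 0). Pairs inside a multi-item leaf take the leaf's depth.
pair_lca_depths <- function(tree) {
  nodes <- tree$nodes
  labels <- sort(unlist(nodes$items[nodes$is_leaf]))
  n <- length(labels)
  M <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(nrow(nodes))) {
    d <- nodes$depth[i]
    if (!nodes$is_leaf[i]) {
      kids <- nodes$children[[i]]
      a <- nodes$items[[match(kids[1L], nodes$node_id)]]
      b <- nodes$items[[match(kids[2L], nodes$node_id)]]
      M[a, b] <- d
      M[b, a] <- d
    } else if (nodes$n_items[i] > 1L) {
      it <- nodes$items[[i]]
      M[it, it] <- d
    }
  }
  M[upper.tri(M)]
}

#' Baker's gamma similarity between two trees
#'
#' For every pair of leaves, the number of partitions separating the root
#' from the pair's lowest common ancestor is recorded in each tree; Baker's
#' gamma is the Spearman rank correlation between the two pairwise-depth
#' vectors. It equals 1 for identical tree structure and is invariant to
#' leaf-order permutations and child swaps.
#'
#' @param tree_a,tree_b `k2_taxonomy` or `k2_tree` objects over the same
#'   item set.
#' @return A number in `[-1, 1]`.
#' @export
bakers_gamma <- function(tree_a, tree_b) {
  la <- sort(unlist(tree_a$nodes$items[tree_a$nodes$is_leaf]))
  lb <- sort(unlist(tree_b$nodes$items[tree_b$nodes$is_leaf]))
  if (!identical(la, lb)) stop("trees have different leaf sets", call. = FALSE)
  da <- pair_lca_depths(tree_a)
  db <- pair_lca_depths(tree_b)
  if (identical(rank(da), rank(db))) {
    return(1)
  }
  suppressWarnings(cor(da, db, method = "spearman"))
}

#' Weighted conditional entropy of labels within clusters
#'
#' \deqn{H(L \mid C) = \sum_c \frac{n_c}{N} \sum_l -p_{l|c} \log_2 p_{l|c}}
#' in bits; 0 if and only if every cluster is label-pure. Lower values mean
#' purer subgroups.
#'
#' @param labels Character/factor vector of phenotype labels, named by item
#'   (or aligned with `clusters`).
#' @param clusters Cluster assignment vector (same length; if both are
#'   named, they are aligned by name), e.g. the `cluster` column of
#'   [cut_tree()] named by `item`.
#' @return Non-negative entropy in bits.
#' @export
cluster_entropy <- function(labels, clusters) {
  if (!is.null(names(labels)) && !is.null(names(clusters))) {
    if (!setequal(names(labels), names(clusters))) {
      stop("labels and clusters cover different items", call. = FALSE)
    }
    clusters <- clusters[names(labels)]
  }
  stopifnot(length(labels) == length(clusters))
  N <- length(labels)
  h <- 0
  for (cl in unique(clusters)) {
    sel <- clusters == cl
    nc <- sum(sel)
    if (nc == 0L) next
    p <- table(labels[sel]) / nc
    p <- p[p > 0]
    h <- h + (nc / N) * sum(-p * log2(p))
  }
  as.numeric(h)
}

#' Simulation benchmark: ensemble taxonomy vs Ward on group means
#'
#' Runs the group-level taxonomy and a Ward agglomerative baseline (Ward's
#' linkage on the Euclidean distances between per-group mean profiles, all
#' features) over a grid of simulation settings, scoring each recovered tree
#' against the generating tree with Baker's gamma. Per grid cell, the two
#' methods are compared with a paired two-sided Wilcoxon signed-rank test
#' across replicates, with BH FDR over cells.
#'
#' @param grid Data frame with columns `noise_sd` and `n_terminal_clusters`,
#'   one row per cell.
#' @param n_observations,n_features,signal_fraction,effect_size Simulation
#'   settings shared across cells.
#' @param replicates Replicates per cell (>= 3).
#' @param p Perturbations per partition for the taxonomy runs.
#' @param seed Master seed.
#' @return Object of class `k2_benchmark`: list with `results` (tibble:
#'   cell, replicate, method, gamma) and `summary` (per cell x method mean
#'   gamma, Wilcoxon p and q).
#' @export
benchmark_taxonomy <- function(grid, n_observations = 200L,
                               n_features = 2000L, replicates = 5L,
                               signal_fraction = 0.1, effect_size = 1,
                               p = 100L, seed = 1L) {
  stopifnot(
    is.data.frame(grid),
    all(c("noise_sd", "n_terminal_clusters") %in% names(grid)),
    replicates >= 3L
  )
  res <- list()
  for (i in seq_len(nrow(grid))) {
    sd_i <- grid$noise_sd[i]
    L_i <- grid$n_terminal_clusters[i]
    cell <- sprintf("sd%.1f_L%d", sd_i, L_i)
    for (r in seq_len(replicates)) {
      sim <- simulate_hierarchy(
        n_observations = n_observations, n_features = n_features,
        n_terminal_clusters = L_i, signal_fraction = signal_fraction,
        noise_sd = sd_i, effect_size = effect_size,
        seed = derive_seed(seed, paste0("sim_", cell), r)
      )
      g_k2 <- tryCatch(
        {
          tax <- run_taxonomy(
            sim$matrix,
            taxonomy_config(
              mode = "group", p = p,
              seed = derive_seed(seed, paste0("fit_", cell), r)
            ),
            groups = sim$labels
          )
          bakers_gamma(tax, sim$truth)
        },
        error = function(e) {
          warning(sprintf("taxonomy failed in %s rep %d: %s", cell, r, conditionMessage(e)),
            call. = FALSE
          )
          NA_real_
        }
      )
      cent <- group_centroids(sim$matrix, factor(sim$labels))
      hc <- hclust(dist(cent), method = "ward.D2")
      g_ward <- bakers_gamma(hclust_to_tree(hc), sim$truth)
      res[[length(res) + 1L]] <- tibble(
        noise_sd = sd_i, n_terminal_clusters = L_i, replicate = r,
        method = c("k2tax", "ward"), gamma = c(g_k2, g_ward)
      )
    }
  }
  results <- dplyr::bind_rows(res)
  summary <- results |>
    tidyr::pivot_wider(names_from = "method", values_from = "gamma") |>
    dplyr::group_by(.data$noise_sd, .data$n_terminal_clusters) |>
    dplyr::summarise(
      n_pairs = sum(stats::complete.cases(.data$k2tax, .data$ward)),
      mean_k2tax = mean(.data$k2tax, na.rm = TRUE),
      mean_ward = mean(.data$ward, na.rm = TRUE),
      p_value = if (sum(stats::complete.cases(.data$k2tax, .data$ward)) >= 3) {
        d <- .data$k2tax - .data$ward
        if (all(d == 0)) 1 else suppressWarnings(wilcox.test(d)$p.value)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, method = "BH"))
  structure(list(results = results, summary = summary), class = "k2_benchmark")
}

#' @export
print.k2_benchmark <- function(x, ...) {
  cat("<k2_benchmark>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy k2_benchmark
#' @export
tidy.k2_benchmark <- function(x, ...) x$summary

#' @method glance k2_benchmark
#' @export
glance.k2_benchmark <- function(x, ...) {
  tibble(
    n_cells = nrow(x$summary),
    n_replicates = max(x$results$replicate),
    cells_k2_ge_ward = sum(x$summary$mean_k2tax >= x$summary$mean_ward),
    cells_significant = sum(x$summary$q_value < 0.05, na.rm = TRUE)
  )
}
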