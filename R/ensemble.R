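#' Bootstrap the feature dimension of an expression matrix
#'
#' Draws `nrow(x)` features with replacement from the rows of `x`, keeping the
#' observation columns unchanged. Duplicated features are kept (their
#' identifiers are suffixed to remain unique), which is the perturbation step
#' of the ensemble partitioning algorithm: each perturbation sees a
#' feature-bootstrapped view of the data.
#'
#' @param x Numeric matrix, features x observations, with unique dimnames.
#' @param seed Integer seed; the resample is fully determined by it.
#' @return A matrix with the same dimensions as `x` whose rows are the
#'   bootstrap sample.
#' @export
#' @examples
#' m <- matrix(rnorm(20), 5, 4,
#'   dimnames = list(paste0("f", 1:5), paste0("s", 1:4))
#' )
#' b <- bootstrap_features(m, seed = 1)
#' dim(b)
bootstrap_features <- function(x, seed) {
  validate_matrix(x)
  idx <- with_seed(seed, sample.int(nrow(x), nrow(x), replace = TRUE))
  out <- x[idx, , drop = FALSE]
  rownames(out) <- make.unique(rownames(x)[idx])
  out
}

# Per-feature selection statistic over the observations (and, for the
# F statistic, groups) at the current node. Returns one value per row of x.
feature_stat <- function(x, method = c("MAD", "SD", "F"), groups = NULL) {
  method <- match.arg(method)
  n <- ncol(x)
  if (method == "MAD") {
    med <- apply(x, 1L, median)
    apply(abs(x - med), 1L, median) * 1.4826
  } else if (method == "SD") {
    mu <- rowMeans(x)
    sqrt(rowSums((x - mu)^2) / (n - 1L))
  } else {
    if (is.null(groups)) {
      stop("F-statistic selection requires group labels", call. = FALSE)
    }
    g <- factor(validate_groups(x, groups))
    k <- nlevels(g)
    if (k < 2L) stop("F-statistic selection requires >= 2 groups", call. = FALSE)
    if (n <= k) stop("F-statistic selection requires observations beyond groups", call. = FALSE)
    sizes <- as.numeric(table(g))
    gm <- t(apply(x, 1L, function(row) tapply(row, g, mean)))
    mu <- rowMeans(x)
    ssb <- rowSums(sweep((gm - mu)^2, 2L, sizes, "*"))
    sst <- rowSums((x - mu)^2)
    ssw <- sst - ssb
    msb <- ssb / (k - 1L)
    msw <- ssw / (n - k)
    f <- msb / msw
    f[msw == 0 & msb == 0] <- 0
    f[msw == 0 & msb > 0] <- Inf
    f
  }
}

#' Variability-based feature selection
#'
#' Ranks features by a dispersion statistic computed only over the
#' observations at hand and returns the top `n`. The default `n = "sqrt"`
#' selects `round(sqrt(F))` of the `F` features, so the selected fraction
#' shrinks with the feature count (3.2% of 1,000 features, 1.0% of 10,000).
#'
#' @param x Numeric matrix, features x observations.
#' @param method `"MAD"` (median absolute deviation, default), `"SD"`, or
#'   `"F"` (one-way between/within group variance ratio; requires `groups`).
#' @param n `"sqrt"` or an explicit integer number of features to keep.
#' @param groups Optional named character vector (observation id -> group),
#'   required for `method = "F"`.
#' @return Character vector of the selected feature identifiers, best first.
#'   Ties are broken by feature order.
#' @export
select_features <- function(x, method = c("MAD", "SD", "F"), n = "sqrt",
                            groups = NULL) {
  validate_matrix(x)
  method <- match.arg(method)
  nf <- nrow(x)
  if (identical(n, "sqrt")) {
    n <- max(1L, as.integer(round(sqrt(nf))))
  } else {
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("`n` must be a positive integer or \"sqrt\"", call. = FALSE)
  }
  if (n > nf) stop(sprintf("cannot select %d of %d features", n, nf), call. = FALSE)
  stat <- feature_stat(x, method, groups)
  if (all(!is.finite(stat) | stat == 0)) stop("degenerate node", call. = FALSE)
  ord <- order(stat, decreasing = TRUE) # stable: ties keep feature order
  rownames(x)[ord[seq_len(n)]]
}

# Condition signalled when a perturbation cannot produce a K = 2 split
# (all items coincide in the selected-feature space).
unsplittable <- function(msg = "unsplittable perturbation") {
  structure(
    class = c("k2_unsplittable", "condition"),
    list(message = msg, call = NULL)
  )
}

#' Perturbation-specific K=2 partition of observations
#'
#' Hierarchical clustering of the Euclidean distance matrix over the selected
#' features, cut at K = 2. The sign of the labels is arbitrary (cluster of
#' the first observation gets +1); downstream cosine aggregation is invariant
#' to per-perturbation sign flips.
#'
#' @param x Numeric matrix of selected features x observations (already
#'   bootstrapped and filtered).
#' @param linkage Agglomeration method: `"ward"` (default, run as `ward.D2`
#'   on Euclidean distances), `"average"`, `"complete"`, or `"single"`.
#' @return Named vector in `{-1, +1}` over observations.
#' @export
perturb_partition_observation <- function(x, linkage = "ward") {
  if (ncol(x) < 2L) stop("need >= 2 observations", call. = FALSE)
  d <- dist(t(x))
  if (all(d < 1e-12)) stop(unsplittable())
  cl <- cutree(hclust(d, method = linkage_method(linkage)), k = 2L)
  setNames(c(1, -1)[cl], colnames(x))
}

# Weighted K=2 k-means over the rows of `pts` with observation weights `w`.
# Used for group-level partitions: with complete must-link blocks, k-means
# over group centroids weighted by group size is exactly equivalent to
# constrained k-means over the observations. For the small group counts
# typical of this mode (G <= 12) the weighted within-cluster sum of squares
# is minimized exactly by enumerating all bipartitions — Lloyd iterations
# with weighted points can sink into a local optimum from every random
# start; for larger G, k-means++ seeding with Lloyd restarts is used.
weighted_kmeans2 <- function(pts, w, seed, nstart = 10L, max_iter = 300L,
                             tol = 1e-6) {
  g <- nrow(pts)
  if (g <= 12L) {
    best <- NULL
    for (code in 0:(2^(g - 1L) - 2L)) {
      side <- c(TRUE, bitwAnd(code, 2^(seq_len(g - 1L) - 1L)) > 0)
      wss <- 0
      centers <- matrix(0, 2L, ncol(pts))
      for (k in 1:2) {
        s <- if (k == 1L) side else !side
        mu <- colSums(pts[s, , drop = FALSE] * w[s]) / sum(w[s])
        centers[k, ] <- mu
        wss <- wss +
          sum(w[s] * rowSums((pts[s, , drop = FALSE] - rep(mu, each = sum(s)))^2))
      }
      if (is.null(best) || wss < best$wss - 1e-12) {
        best <- list(assign = ifelse(side, 1L, 2L), wss = wss, centers = centers)
      }
    }
    return(best)
  }
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(nstart)) {
      # k-means++ seeding, weight-aware
      c1 <- sample.int(g, 1L, prob = w)
      d2 <- rowSums((pts - rep(pts[c1, ], each = g))^2)
      probs <- w * d2
      c2 <- if (all(probs == 0)) {
        sample.int(g, 1L)
      } else {
        sample.int(g, 1L, prob = probs)
      }
      centers <- pts[c(c1, c2), , drop = FALSE]
      assign_old <- rep(0L, g)
      converged <- FALSE
      wss <- Inf
      for (it in seq_len(max_iter)) {
        d1 <- rowSums((pts - rep(centers[1L, ], each = g))^2)
        d2 <- rowSums((pts - rep(centers[2L, ], each = g))^2)
        assign_new <- ifelse(d1 <= d2, 1L, 2L)
        # guard empty cluster: move the farthest point over
        for (k in 1:2) {
          if (!any(assign_new == k)) {
            far <- which.max(ifelse(assign_new == k, -Inf, pmin(d1, d2)))
            assign_new[far] <- k
          }
        }
        for (k in 1:2) {
          sel <- assign_new == k
          centers[k, ] <- colSums(pts[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
        }
        wss_new <- sum(w * ifelse(assign_new == 1L,
          rowSums((pts - rep(centers[1L, ], each = g))^2),
          rowSums((pts - rep(centers[2L, ], each = g))^2)
        ))
        if (identical(assign_new, assign_old) || abs(wss - wss_new) < tol) {
          converged <- TRUE
          wss <- wss_new
          assign_old <- assign_new
          break
        }
        wss <- wss_new
        assign_old <- assign_new
      }
      if (!converged) {
        warning("weighted k-means did not converge; returning best iterate",
          call. = FALSE
        )
      }
      if (is.null(best) || wss < best$wss - 1e-12) {
        best <- list(assign = assign_old, wss = wss, centers = centers)
      }
    }
  })
  best
}

#' Perturbation-specific K=2 partition of pre-labeled groups
#'
#' Constrained K = 2 k-means in the selected-feature space where all
#' observations sharing a group label are must-linked: every member of a
#' group receives the same cluster. Implemented as k-means over group
#' centroids weighted by group size, which is exactly equivalent for complete
#' must-link blocks (a block's cost against a center decomposes as
#' size x dist(block centroid, center)^2 plus a constant).
#'
#' @param x Numeric matrix of selected features x observations.
#' @param groups Named character vector, observation id -> group label; every
#'   column of `x` must be labeled and every group present must be nonempty.
#' @param seed Integer seed (k-means++ init, 10 restarts).
#' @param nstart,max_iter,tol k-means controls.
#' @return Named vector in `{-1, +1}` over the group labels.
#' @export
perturb_partition_group <- function(x, groups, seed, nstart = 10L,
                                    max_iter = 300L, tol = 1e-6) {
  groups <- validate_groups(x, groups)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  sizes <- as.numeric(table(g))
  if (any(sizes == 0)) stop("group with zero observations", call. = FALSE)
  cent <- group_centroids(x, g) # G x features
  if (all(dist(cent) < 1e-12)) stop(unsplittable())
  fit <- weighted_kmeans2(cent, sizes, seed, nstart, max_iter, tol)
  lab <- c(1, -1)[fit$assign]
  setNames(lab, levels(g))
}

# Group centroid matrix: one row per group level, columns = features.
group_centroids <- function(x, g) {
  G <- nlevels(g)
  out <- matrix(0, G, nrow(x), dimnames = list(levels(g), rownames(x)))
  for (k in seq_len(G)) {
    out[k, ] <- rowMeans(x[, g == levels(g)[k], drop = FALSE])
  }
  out
}

#' Build the perturbation ensemble for one candidate partition
#'
#' Runs `p` perturbations: feature bootstrap, variability-based feature
#' selection on the bootstrapped matrix, then the mode-appropriate K = 2
#' partition (hierarchical for observations, constrained k-means for groups).
#' Perturbations in which every item coincides are resampled up to 10 times
#' and then dropped; if more than half of the perturbations drop, the node is
#' declared degenerate (error of class `k2_degenerate`).
#'
#' @param x Numeric matrix, features x observations at the current node.
#' @param config A [taxonomy_config()] list.
#' @param groups Named character vector of group labels (group mode, or for
#'   F-statistic selection).
#' @param node_path Internal node identifier folded into per-perturbation
#'   seeds (the default corresponds to a standalone root-level call).
#' @return Object of class `k2_ensemble`: a list with `assignments`
#'   (items x p matrix in `{-1, +1}`), `p`, `seeds`, `dropped`, `mode`.
#' @export
build_ensemble <- function(x, config = taxonomy_config(), groups = NULL,
                           node_path = "r") {
  validate_matrix(x)
  mode <- config$mode
  if (mode == "group") {
    groups <- validate_groups(x, groups)
    items <- levels(factor(groups))
  } else {
    items <- colnames(x)
  }
  if (length(items) < 2L) stop("need >= 2 items", call. = FALSE)

  # Row statistics are invariant under row duplication, so the statistic for
  # a bootstrapped matrix is the node-level vector indexed by the resample.
  stat <- feature_stat(x, config$feature_select, groups)
  nf <- nrow(x)
  n_sel <- if (identical(config$n_features, "sqrt")) {
    max(1L, as.integer(round(sqrt(nf))))
  } else {
    as.integer(config$n_features)
  }
  if (n_sel > nf) stop(sprintf("cannot select %d of %d features", n_sel, nf), call. = FALSE)
  cent <- if (mode == "group") group_centroids(x, factor(groups)) # G x F

  cols <- vector("list", config$p)
  seeds <- integer(config$p)
  dropped <- 0L
  for (b in seq_len(config$p)) {
    seeds[b] <- derive_seed(config$seed, node_path, b)
    col <- NULL
    for (attempt in 0:9) {
      sb <- derive_seed(config$seed, node_path, b, attempt)
      idx <- with_seed(sb, sample.int(nf, nf, replace = TRUE))
      ord <- order(stat[idx], decreasing = TRUE)
      sel <- idx[ord[seq_len(n_sel)]]
      res <- tryCatch(
        {
          if (!is.null(config$custom_partitioner)) {
            config$custom_partitioner(
              x[sel, , drop = FALSE], groups,
              derive_seed(config$seed, node_path, b, attempt + 100L)
            )
          } else if (mode == "group") {
            cs <- cent[, sel, drop = FALSE]
            if (all(dist(cs) < 1e-12)) stop(unsplittable())
            fit <- weighted_kmeans2(
              cs,
              as.numeric(table(factor(groups))),
              seed = derive_seed(config$seed, node_path, b, attempt + 100L)
            )
            setNames(c(1, -1)[fit$assign], rownames(cent))
          } else {
            perturb_partition_observation(
              x[sel, , drop = FALSE],
              linkage = config$perturbation_linkage
            )
          }
        },
        k2_unsplittable = function(e) NULL
      )
      if (!is.null(res)) {
        col <- res
        break
      }
    }
    if (is.null(col)) dropped <- dropped + 1L else cols[[b]] <- col
  }
  kept <- !vapply(cols, is.null, logical(1))
  if (dropped > config$p / 2) {
    stop(structure(
      class = c("k2_degenerate", "error", "condition"),
      list(
        message = sprintf(
          "degenerate node: %d of %d perturbations unsplittable", dropped, config$p
        ),
        call = NULL
      )
    ))
  }
  A <- do.call(cbind, lapply(cols[kept], function(col) col[items]))
  rownames(A) <- items
  structure(
    list(
      assignments = A, p = ncol(A), seeds = seeds[kept],
      dropped = dropped, mode = mode
    ),
    class = "k2_ensemble"
  )
}

#' @export
print.k2_ensemble <- function(x, ...) {
  cat(sprintf(
    "<k2_ensemble> %d items x %d perturbations (%s mode, %d dropped)\n",
    nrow(x$assignments), x$p, x$mode, x$dropped
  ))
  invisible(x)
}
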