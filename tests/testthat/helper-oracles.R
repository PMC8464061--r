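# Independent oracles and small fixture builders used across the suite.

make_matrix <- function(nf, no, seed = 1, sd = 1, mean = 0) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(nf * no, mean, sd), nf, no)
    dimnames(m) <- list(sprintf("f%03d", seq_len(nf)), sprintf("s%03d", seq_len(no)))
    m
  })
}

# All bipartitions of n items as logical membership vectors (first item fixed
# to side TRUE to avoid duplicates); 2^(n-1) - 1 proper bipartitions.
all_bipartitions <- function(n) {
  out <- list()
  for (code in 0:(2^(n - 1) - 2)) {
    side <- c(TRUE, as.logical(bitwAnd(code, 2^(seq_len(n - 1) - 1)) > 0))
    out[[length(out) + 1L]] <- side
  }
  out
}

# Brute-force best 2-split of observations (columns) by total within-cluster
# sum of squares.
oracle_split_wss <- function(x) {
  n <- ncol(x)
  best <- NULL
  best_wss <- Inf
  for (side in all_bipartitions(n)) {
    if (all(side) || !any(side)) next
    wss <- 0
    for (s in list(side, !side)) {
      mu <- rowMeans(x[, s, drop = FALSE])
      wss <- wss + sum((x[, s, drop = FALSE] - mu)^2)
    }
    if (wss < best_wss) {
      best_wss <- wss
      best <- side
    }
  }
  list(side = best, wss = best_wss)
}

# Brute-force weighted K=2 split of points (rows) with weights w, minimizing
# the weighted within-cluster sum of squares.
oracle_weighted_split <- function(pts, w) {
  n <- nrow(pts)
  best <- NULL
  best_wss <- Inf
  for (side in all_bipartitions(n)) {
    wss <- 0
    for (s in list(side, !side)) {
      mu <- colSums(pts[s, , drop = FALSE] * w[s]) / sum(w[s])
      wss <- wss + sum(w[s] * rowSums((pts[s, , drop = FALSE] -
        rep(mu, each = sum(s)))^2))
    }
    if (wss < best_wss - 1e-12) {
      best_wss <- wss
      best <- side
    }
  }
  list(side = best, wss = best_wss)
}

# Brute-force bipartition of a similarity matrix maximizing mean within-side
# similarity minus mean cross-side similarity.
oracle_split_similarity <- function(Q) {
  n <- nrow(Q)
  best <- NULL
  best_score <- -Inf
  for (side in all_bipartitions(n)) {
    if (all(side) || !any(side)) next
    within <- c()
    cross <- c()
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (side[i] == side[j]) within <- c(within, Q[i, j]) else cross <- c(cross, Q[i, j])
      }
    }
    score <- mean(within) - mean(cross)
    if (score > best_score) {
      best_score <- score
      best <- side
    }
  }
  best
}

# Exhaustive two-sided Fisher p for a 2x2 table: sum the probabilities of
# all tables with the same margins that are no more probable than observed.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  prob <- function(a) dhyper(a, r1, r2, c1)
  p_obs <- prob(tab[1, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(a_range, prob, numeric(1))[vapply(a_range, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all sign patterns.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(code) {
    pos <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    sum(r[pos])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Hand-coded BH step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Random nested-list tree over the given labels (for tree-metric tests).
random_nested <- function(labels) {
  if (length(labels) == 1L) {
    return(labels)
  }
  k <- length(labels)
  nl <- if (k == 2L) 1L else sample.int(k - 1L, 1L)
  left <- sample(labels, nl)
  list(random_nested(left), random_nested(setdiff(labels, left)))
}
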