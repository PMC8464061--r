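test_that("feature bootstrap is deterministic and preserves dimensions", {
  m <- make_matrix(50, 6, seed = 2)
  b1 <- bootstrap_features(m, seed = 11)
  b2 <- bootstrap_features(m, seed = 11)
  expect_identical(b1, b2)
  expect_equal(dim(b1), dim(m))
  expect_false(identical(b1, bootstrap_features(m, seed = 12)))
  expect_false(anyDuplicated(rownames(b1)) > 0)

  one <- m[1, , drop = FALSE]
  expect_identical(bootstrap_features(one, seed = 3), one)

  expect_error(
    bootstrap_features(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("a", "b", "c"))), 1),
    "no features"
  )
})

test_that("fraction of features absent from a bootstrap matches (1 - 1/F)^F", {
  f <- 1000L
  m <- make_matrix(f, 2, seed = 4)
  ids <- rownames(m)
  absent <- vapply(seq_len(10000L), function(b) {
    res <- bootstrap_features(m, seed = b)
    orig <- sub("\\.\\d+$", "", rownames(res))
    1 - length(unique(orig)) / f
  }, numeric(1))
  expect_lt(abs(mean(absent) - (1 - 1 / f)^f), 0.01)
})

test_that("sqrt feature selection yields the documented fractions", {
  m1 <- make_matrix(1000, 5, seed = 5)
  expect_length(select_features(m1, "MAD", "sqrt"), 32L) # 3.2%
  m2 <- make_matrix(10000, 3, seed = 6)
  expect_length(select_features(m2, "SD", "sqrt"), 100L) # 1.0%
})

test_that("selection ranks by the statistic and breaks ties by feature order", {
  m <- make_matrix(20, 8, seed = 7, sd = 0)
  m[c(3, 9, 15), ] <- make_matrix(3, 8, seed = 8, sd = 2)
  sel <- select_features(m, "MAD", 3)
  expect_setequal(sel, rownames(m)[c(3, 9, 15)])

  # tied statistics: identical rows rank in feature order
  tied <- rbind(m[c(3, 3, 3, 9), ], m[15, , drop = FALSE])
  rownames(tied) <- paste0("t", 1:5)
  stat <- apply(tied, 1, function(r) mad(r))
  top <- select_features(tied, "MAD", 2)
  expect_identical(top, rownames(tied)[order(stat, decreasing = TRUE)][1:2])

  expect_error(select_features(m, "MAD", 100), "cannot select")
  flat <- matrix(1, 5, 4, dimnames = list(paste0("f", 1:5), paste0("s", 1:4)))
  expect_error(select_features(flat, "MAD", 2), "degenerate")
})

test_that("F-statistic selection needs groups and favors between-group signal", {
  m <- make_matrix(100, 12, seed = 9)
  g <- setNames(rep(c("a", "b", "c"), each = 4), colnames(m))
  m[7, g == "a"] <- m[7, g == "a"] + 10
  expect_error(select_features(m, "F", 5), "group")
  expect_true("f007" %in% select_features(m, "F", 5, groups = g))
})

test_that("observation partition matches the within-SS oracle for separated blobs", {
  withr::with_seed(21, {
    centers <- cbind(matrix(-10, 4, 3), matrix(10, 4, 3))
    x <- centers + matrix(rnorm(24, 0, 0.1), 4)
    dimnames(x) <- list(paste0("f", 1:4), paste0("s", 1:6))
  })
  split <- perturb_partition_observation(x)
  expect_setequal(unname(split), c(-1, -1, -1, 1, 1, 1))
  oracle <- oracle_split_wss(x)
  got <- unname(split > 0)
  expect_true(identical(got, oracle$side) || identical(got, !oracle$side))

  # permutation equivariance up to sign: same set bipartition
  perm <- c(4, 2, 6, 1, 3, 5)
  split_p <- perturb_partition_observation(x[, perm])
  sides <- function(s) {
    g <- split(names(s), s)
    unname(lapply(g[order(vapply(g, min, character(1)))], sort))
  }
  expect_identical(sides(split), sides(split_p))

  two <- x[, 1:2]
  s2 <- perturb_partition_observation(two)
  expect_setequal(unname(s2), c(-1, 1))
})

test_that("group partition equals the brute-force weighted k-means oracle", {
  # 4 groups forming two separated pairs
  withr::with_seed(31, {
    gcent <- rbind(c(-5, -5), c(-5.5, -4.5), c(5, 5), c(4.5, 5.5))
    obs <- do.call(cbind, lapply(1:4, function(g) {
      t(gcent[rep(g, 5), ] + matrix(rnorm(10, 0, 0.05), 5))
    }))
    dimnames(obs) <- list(c("fA", "fB"), sprintf("o%02d", 1:20))
  })
  groups <- setNames(rep(paste0("G", 1:4), each = 5), colnames(obs))
  split <- perturb_partition_group(obs, groups, seed = 7)
  expect_setequal(names(split), paste0("G", 1:4))
  expect_identical(split[["G1"]], split[["G2"]])
  expect_identical(split[["G3"]], split[["G4"]])
  expect_false(split[["G1"]] == split[["G3"]])

  # random configurations: solution WSS matches exhaustive enumeration
  for (case in 1:20) {
    withr::with_seed(100 + case, {
      g <- sample(3:6, 1)
      pts <- matrix(rnorm(g * 2, 0, 2), g)
      w <- sample(1:6, g, replace = TRUE)
    })
    fit <- k2tax:::weighted_kmeans2(pts, w, seed = case)
    oracle <- oracle_weighted_split(pts, w)
    expect_equal(fit$wss, oracle$wss, tolerance = 1e-8)
  }
})

test_that("group weights steer symmetric configurations as the oracle predicts", {
  # three collinear group centroids; the heavy end captures the middle group
  pts <- matrix(c(-1, 0, 1), 3, 1)
  for (heavy in c(1, 3)) {
    w <- c(1, 1, 1)
    w[heavy] <- 8
    fit <- k2tax:::weighted_kmeans2(pts, w, seed = 5)
    oracle <- oracle_weighted_split(pts, w)
    expect_equal(fit$wss, oracle$wss, tolerance = 1e-10)
    # middle point joins the lighter side (centroid of heavy side stays put)
    expect_identical(fit$assign[2], fit$assign[c(1, 3)[c(1, 3) != heavy]])
  }
})

test_that("must-link blocks are preserved exhaustively in group ensembles", {
  sim <- simulate_hierarchy(40, 300, 4, 0.2, 0.5, seed = 5)
  cfg <- taxonomy_config(mode = "group", p = 15, seed = 2)
  ens <- build_ensemble(sim$matrix, cfg, groups = sim$labels)
  expect_identical(sort(rownames(ens$assignments)), sort(unique(unname(sim$labels))))
  # expanding each group's label to its observations is constant by design;
  # every perturbation must assign both labels
  for (b in seq_len(ens$p)) {
    expect_setequal(unique(ens$assignments[, b]), c(-1, 1))
  }
})

test_that("ensembles are deterministic and respect forced two-item splits", {
  m <- make_matrix(64, 2, seed = 12)
  cfg <- taxonomy_config(mode = "observation", p = 9, min_items = 2, seed = 3)
  e1 <- build_ensemble(m, cfg)
  e2 <- build_ensemble(m, cfg)
  expect_identical(e1$assignments, e2$assignments)
  expect_true(all(e1$assignments %in% c(-1, 1)))
  expect_true(all(colSums(e1$assignments) == 0)) # both labels per column
  Q <- cosine_similarity(e1)
  expect_equal(Q[1, 2], -1)

  p1 <- taxonomy_config(mode = "observation", p = 1, min_items = 2, seed = 3)
  es <- build_ensemble(m, p1)
  expect_identical(es$assignments[, 1], e1$assignments[, 1])
})

test_that("a constant node aborts as degenerate", {
  flat <- matrix(3, 30, 6, dimnames = list(paste0("f", 1:30), paste0("s", 1:6)))
  cfg <- taxonomy_config(mode = "observation", p = 8, min_items = 2, seed = 1)
  expect_error(build_ensemble(flat, cfg), class = "k2_degenerate")
})

test_that("a custom perturbation partitioner can be plugged in", {
  m <- make_matrix(40, 6, seed = 13)
  fixed <- setNames(c(1, 1, 1, -1, -1, -1), colnames(m))
  cfg <- taxonomy_config(
    mode = "observation", p = 5, min_items = 2, seed = 1,
    custom_partitioner = function(x, groups, seed) fixed[colnames(x)]
  )
  ens <- build_ensemble(m, cfg)
  expect_true(all(apply(ens$assignments, 2, function(col) {
    identical(unname(col), unname(fixed)) || identical(unname(col), -unname(fixed))
  })))
})
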