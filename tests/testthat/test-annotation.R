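two_group_fixture <- function(n_feat = 300, n1 = 10, n2 = 10, seed = 1,
                              shift_rows = integer(), shift = 0) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_feat * (n1 + n2)), n_feat)
    dimnames(x) <- list(sprintf("g%03d", 1:n_feat), sprintf("s%03d", 1:(n1 + n2)))
    x[shift_rows, seq_len(n1)] <- x[shift_rows, seq_len(n1)] + shift
    part <- setNames(rep(c("A", "B"), c(n1, n2)), colnames(x))
    list(x = x, part = part)
  })
}

test_that("the moderated t agrees with the limma empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  fx <- two_group_fixture(n_feat = 250, n1 = 8, n2 = 12, shift_rows = 1:5, shift = 3)
  de <- differential_expression(fx$x, fx$part)
  design <- cbind(A = rep(c(1, 0), c(8, 12)), B = rep(c(0, 1), c(8, 12)))
  fit <- limma::lmFit(fx$x, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(A - B, levels = design))
  fit <- limma::eBayes(fit)
  expect_equal(attr(de, "df_prior"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(de, "var_prior"), fit$s2.prior, tolerance = 1e-8)
  expect_equal(de$t, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(de$p_value, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("a strongly shifted feature ranks first; constants give p = 1", {
  fx <- two_group_fixture(n_feat = 120, shift_rows = 42, shift = 5)
  fx$x[7, ] <- 1.5 # identical values on both sides
  de <- differential_expression(fx$x, fx$part)
  expect_identical(de$feature[which.min(de$p_value)], "g042")
  const <- de[de$feature == "g007", ]
  expect_equal(const$effect, 0)
  expect_equal(const$t, 0)
  expect_equal(const$p_value, 1)
})

test_that("type-I error is calibrated under the per-feature null", {
  fx <- two_group_fixture(n_feat = 2000, seed = 9)
  de <- differential_expression(fx$x, fx$part)
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 0.02)
})

test_that("swapping partition sides negates effects and keeps p-values", {
  fx <- two_group_fixture(n_feat = 150, shift_rows = 1:10, shift = 2)
  de1 <- differential_expression(fx$x, fx$part)
  flipped <- setNames(ifelse(fx$part == "A", "B2", "A2"), names(fx$part))
  de2 <- differential_expression(fx$x, flipped)
  expect_equal(de2$effect, -de1$effect)
  expect_equal(de2$t, -de1$t)
  expect_equal(de2$p_value, de1$p_value)
  expect_equal(de2$q_value, de1$q_value)
})

test_that("a one-observation side falls back to the ordinary t with a warning", {
  fx <- two_group_fixture(n_feat = 50, n1 = 1, n2 = 10)
  expect_warning(de <- differential_expression(fx$x, fx$part), "ordinary")
  expect_identical(attr(de, "method"), "ordinary")
  expect_true(all(is.finite(de$p_value)))
})

test_that("signatures apply the FDR/expression/size rule deterministically", {
  withr::with_seed(4, {
    x <- matrix(rnorm(200 * 20, 0, 0.2), 200)
    dimnames(x) <- list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:20))
    x[1:60, 1:10] <- x[1:60, 1:10] + 5 # strong up-regulation, mean >> 0.5
  })
  part <- setNames(
    factor(rep(c("up", "down"), each = 10), levels = c("up", "down")),
    colnames(x)
  )
  de <- differential_expression(x, part)
  sig <- derive_signature(de, fdr_max = 1e-10, min_mean = 0.5, max_genes = 50)
  expect_length(sig, 50L)
  expect_true(all(sig %in% sprintf("g%03d", 1:60)))
  expect_identical(sig, derive_signature(de, 1e-10, 0.5, 50)) # stable rerun
  expect_length(derive_signature(de, 1e-10, 0.5, 80), 60L)
  none <- derive_signature(de, fdr_max = 1e-300, min_mean = 1e6, max_genes = 50)
  expect_length(none, 0L)
})

test_that("hypergeometric enrichment matches closed-form combinatorics", {
  universe <- paste0("u", 1:10)
  sets <- list(hit = universe[1:5], empty = c("zz1", "zz2"))
  sig <- universe[1:4]
  expect_warning(res <- hypergeometric_enrichment(sig, sets, universe), "no overlap")
  expect_equal(nrow(res), 1L)
  expect_equal(res$p_value, choose(5, 4) * choose(5, 0) / choose(10, 4)) # 5/210

  # signature = universe: overlap fixed at set size, p = 1
  res2 <- hypergeometric_enrichment(universe, list(s = universe[1:5]), universe)
  expect_equal(res2$p_value, 1)

  # overlap at the null expectation: upper tail >= 0.5 (brute-force tail sum)
  big <- paste0("g", 1:100)
  set <- big[1:20]
  sig3 <- big[c(1:4, 21:36)] # overlap 4 = 20 * 20/100
  res3 <- hypergeometric_enrichment(sig3, list(s = set), big)
  tail_sum <- sum(dhyper(4:20, 20, 80, 20))
  expect_equal(res3$p_value, tail_sum)
  expect_gte(res3$p_value, 0.5)

  expect_error(hypergeometric_enrichment(c("nope"), list(s = set), big), "universe")
})

test_that("projection scores hit the bounds and ignore monotone transforms", {
  withr::with_seed(12, x <- matrix(rnorm(200 * 6), 200))
  dimnames(x) <- list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6))
  # set occupying exactly the top |S| ranks of observation 1
  top <- rownames(x)[order(x[, 1], decreasing = TRUE)][1:30]
  sc <- project_gene_sets(x, list(top = top))
  expect_equal(sc["top", 1], 1)
  expect_true(all(abs(sc) <= 1 + 1e-12))

  # uniformly interleaved set: near-zero score
  ord <- rownames(x)[order(x[, 2])]
  inter <- ord[seq(2, 200, by = 2)]
  sci <- project_gene_sets(x, list(i = inter))
  expect_lt(abs(sci["i", 2]), 0.05)

  # random sets are centred at zero
  withr::with_seed(30, {
    null_scores <- vapply(1:200, function(i) {
      project_gene_sets(x, list(s = sample(rownames(x), 60)))["s", 3]
    }, numeric(1))
  })
  expect_lt(abs(mean(null_scores)), 2 * sd(null_scores) / sqrt(200))

  # monotone invariance: exp() on one observation leaves its scores unchanged
  xe <- x
  xe[, 4] <- exp(xe[, 4])
  expect_equal(
    project_gene_sets(xe, list(top = top))[, 4],
    sc[, 4]
  )

  small <- project_gene_sets(x, list(tiny = rownames(x)[1]))
  expect_true(all(is.na(small["tiny", ])))
  expect_identical(attr(small, "missing_sets"), "tiny")
})

test_that("phenotype tests match exact enumeration oracles", {
  part <- setNames(rep(c("L", "R"), each = 10), sprintf("s%02d", 1:20))

  # Fisher on [[8,2],[1,9]] against exhaustive enumeration
  ph <- data.frame(
    flag = rep(c("y", "n", "y", "n"), c(8, 2, 1, 9)),
    row.names = names(part)
  )
  res <- phenotype_tests(ph, part, tests = c(flag = "fisher"))
  tab <- matrix(c(8, 1, 2, 9), 2)
  expect_equal(res$p_value, oracle_fisher_2x2(tab), tolerance = 1e-12)

  # Wilcoxon on fully separated samples: exact two-sided tail 2 / C(20,10)
  ph2 <- data.frame(v = c(1:10, 101:110), row.names = names(part))
  res2 <- phenotype_tests(ph2, part, tests = c(v = "wilcoxon"))
  expect_equal(res2$p_value, 2 / choose(20, 10))

  # identical continuous samples on both sides: zero effect, p = 1
  ph3 <- data.frame(v = rep(1:10, 2), row.names = names(part))
  res3 <- phenotype_tests(ph3, part, tests = c(v = "t"))
  expect_equal(res3$p_value, 1)

  # constant variable flagged with p = 1
  ph4 <- data.frame(v = rep(3.3, 20), row.names = names(part))
  res4 <- phenotype_tests(ph4, part)
  expect_equal(res4$p_value, 1)
  expect_identical(res4$note, "constant")

  # multi-level categorical runs through Fisher (possibly simulated)
  ph5 <- data.frame(
    lv = rep(c("a", "b", "c", "a", "c", "b"), c(4, 3, 3, 1, 5, 4)),
    row.names = names(part)
  )
  res5 <- phenotype_tests(ph5, part, tests = c(lv = "fisher"))
  expect_true(res5$p_value > 0 && res5$p_value <= 1)
})

test_that("BH adjustment matches the hand-coded step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(23, {
    for (case in 1:200) {
      p <- runif(sample(1:40, 1))
      expect_equal(fdr_adjust(p), oracle_bh(p))
    }
  })
  expect_message(q <- fdr_adjust(c(0.5, NaN, 0.1)), "dropped 1")
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(c(0.5, 0.1)))
})

test_that("the full pipeline stays calibrated under a global null", {
  false_rates <- vapply(1:20, function(r) {
    fx <- two_group_fixture(n_feat = 400, n1 = 8, n2 = 8, seed = 100 + r)
    de <- differential_expression(fx$x, fx$part)
    hits <- sum(de$q_value <= 0.1)
    hits / max(hits, 1) * (hits > 0)
  }, numeric(1))
  expect_lte(mean(false_rates), 0.15)
})

test_that("taxonomy-wide annotation produces per-node tables", {
  sim <- simulate_hierarchy(60, 300, 4, 0.3, 0.3, effect_size = 3, seed = 21)
  tax <- suppressMessages(
    run_taxonomy(sim$matrix, taxonomy_config(mode = "group", p = 10, seed = 2), groups = sim$labels)
  )
  sets <- list(
    sA = rownames(sim$matrix)[1:40],
    sB = rownames(sim$matrix)[41:120]
  )
  phen <- data.frame(
    depth2 = as.numeric(sub("C", "", sim$labels)),
    cl = unname(sim$labels),
    row.names = names(sim$labels)
  )
  ann <- suppressMessages(annotate_taxonomy(
    tax, sim$matrix,
    gene_sets = sets,
    phenotypes = phen, tests = c(depth2 = "t", cl = "fisher")
  ))
  internal <- tax$nodes$node_id[!tax$nodes$is_leaf]
  expect_setequal(unique(ann$differential$node_id), internal)
  expect_setequal(unique(ann$phenotypes$node_id), internal)
  expect_true(all(ann$differential$q_value >= ann$differential$p_value - 1e-12 |
    ann$differential$q_value <= 1))
  expect_true(all(ann$signatures$feature %in% rownames(sim$matrix)))
})
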