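# Newton inversion of the trigamma function, used when fitting the prior
# degrees of freedom of the variance shrinkage by moments.
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) {
    return(Inf)
  }
  if (x > 1e7) {
    return(1 / sqrt(x))
  }
  if (x < 1e-6) {
    return(1 / x)
  }
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Empirical-Bayes shrinkage of per-feature sample variances (all with the
# same residual df): the marginal distribution of log s^2 under a scaled-F
# model gives moment equations for the prior df and prior variance; the
# posterior variance is the df-weighted blend of prior and observed.
squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    return(list(
      var_post = s2, df_prior = 0,
      var_prior = if (any(ok)) mean(s2[ok]) else 0
    ))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  var_post <- if (is.finite(df_prior)) {
    (df_prior * var_prior + df * s2) / (df_prior + df)
  } else {
    rep(var_prior, length(s2))
  }
  list(var_post = var_post, df_prior = df_prior, var_prior = var_prior)
}

#' Two-group differential expression with moderated t statistics
#'
#' Per-feature comparison of the two sides of a partition. Per-feature
#' pooled residual variances are shrunk toward a prior fitted by moments on
#' the log variances (empirical Bayes); the moderated t uses the blended
#' variance and augmented degrees of freedom. P-values are two-sided and
#' BH-adjusted across features.
#'
#' @param x Numeric matrix, features x observations.
#' @param partition Two-level factor/character/`{-1,+1}` vector named by (or
#'   aligned with) the columns of `x`. The first factor level (or `+1`) is
#'   "side 1"; `effect = mean(side1) - mean(side2)`.
#' @param method `"moderated"` (default) or `"ordinary"` (plain pooled-t).
#'   If either side has fewer than 2 observations the function falls back to
#'   the ordinary t with a warning.
#' @return Tibble with columns `feature`, `effect`, `mean_side1`,
#'   `mean_side2`, `t`, `df_total`, `p_value`, `q_value`; attributes `sides`
#'   (the side labels), `df_prior`, `var_prior`.
#' @export
differential_expression <- function(x, partition,
                                    method = c("moderated", "ordinary")) {
  validate_matrix(x)
  method <- match.arg(method)
  if (!is.null(names(partition))) {
    missing <- setdiff(colnames(x), names(partition))
    if (length(missing)) stop("partition misses observations: ", paste(head(missing, 5), collapse = ", "), call. = FALSE)
    partition <- partition[colnames(x)]
  } else if (length(partition) != ncol(x)) {
    stop("partition length must match the observation count", call. = FALSE)
  }
  if (is.numeric(partition)) {
    part <- factor(partition, levels = c(1, -1))
  } else {
    part <- factor(partition)
  }
  if (nlevels(part) != 2L || anyNA(part)) {
    stop("partition must have exactly two sides", call. = FALSE)
  }
  s1 <- part == levels(part)[1L]
  n1 <- sum(s1)
  n2 <- sum(!s1)
  if (min(n1, n2) < 1L) stop("both sides must be nonempty", call. = FALSE)
  if (min(n1, n2) < 2L && method == "moderated") {
    warning("a side has < 2 observations; falling back to ordinary t",
      call. = FALSE
    )
    method <- "ordinary"
  }
  if (n1 + n2 < 3L) stop("need >= 3 observations in total", call. = FALSE)

  x1 <- x[, s1, drop = FALSE]
  x2 <- x[, !s1, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  effect <- m1 - m2
  df <- n1 + n2 - 2L
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / df

  if (method == "moderated") {
    sq <- squeeze_var(s2, df)
    var_use <- sq$var_post
    df_total <- min(df + sq$df_prior, df * nrow(x))
  } else {
    sq <- list(df_prior = 0, var_prior = NA_real_)
    var_use <- s2
    df_total <- df
  }
  se <- sqrt(var_use * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, Inf * sign(effect)))
  p <- 2 * pt(-abs(t_stat), df = df_total)
  out <- tibble(
    feature = rownames(x), effect = unname(effect),
    mean_side1 = unname(m1), mean_side2 = unname(m2),
    t = unname(t_stat), df_total = df_total,
    p_value = unname(p), q_value = unname(fdr_adjust(p))
  )
  attr(out, "sides") <- levels(part)
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  attr(out, "method") <- method
  out
}

#' Derive an up-regulated subgroup signature
#'
#' Selects features up-regulated on side 1 of a differential result: FDR
#' below `fdr_max`, side-1 mean above `min_mean` (log2 scale), positive
#' effect; the result is capped at `max_genes` features ranked by q-value
#' and then by absolute t.
#'
#' @param result Output of [differential_expression()].
#' @param fdr_max,min_mean,max_genes Signature rule; the defaults (1e-10,
#'   0.5, 50) correspond to a stringent expression signature.
#' @return Character vector of feature ids (possibly empty).
#' @export
derive_signature <- function(result, fdr_max = 1e-10, min_mean = 0.5,
                             max_genes = 50L) {
  stopifnot(max_genes >= 1L)
  pass <- result$q_value < fdr_max &
    result$mean_side1 > min_mean &
    result$effect > 0
  pass[is.na(pass)] <- FALSE
  hits <- result[pass, ]
  hits <- hits[order(hits$q_value, -abs(hits$t)), ]
  head(hits$feature, max_genes)
}

#' Hypergeometric over-representation of gene sets in a signature
#'
#' One-sided upper-tail hypergeometric test per gene set: the probability of
#' observing at least the attained overlap between the signature and the set
#' when drawing `|signature|` features from the universe. BH FDR across
#' sets.
#'
#' @param signature Character vector of feature ids (must be contained in
#'   `universe`).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param universe Character vector of all testable feature ids.
#' @return Tibble with `set`, `n_set` (set size within the universe),
#'   `n_overlap`, `expected`, `p_value`, `q_value`. Sets with no member in
#'   the universe are skipped with a warning.
#' @export
hypergeometric_enrichment <- function(signature, gene_sets, universe) {
  if (!all(signature %in% universe)) {
    stop("signature contains features outside the universe", call. = FALSE)
  }
  N <- length(unique(universe))
  n <- length(unique(signature))
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    if (length(s) == 0L) {
      warning(sprintf("gene set '%s' has no overlap with the universe; skipped", nm),
        call. = FALSE
      )
      return(NULL)
    }
    K <- length(s)
    k <- length(intersect(signature, s))
    tibble(
      set = nm, n_set = K, n_overlap = k, expected = n * K / N,
      p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$q_value <- fdr_adjust(out$p_value)
  out
}

#' Single-sample gene-set projection scores
#'
#' For each observation, features are ranked by expression (average ties);
#' a set's score is the difference between the mean rank of in-set and
#' out-of-set features, scaled by its maximum `F/2` so that scores lie in
#' `[-1, 1]` (1 when the set occupies exactly the top ranks). Scores depend
#' only on within-observation ranks and are therefore invariant under any
#' monotone transform of an observation's expression values.
#'
#' @param x Numeric matrix, features x observations.
#' @param gene_sets Named list of character vectors.
#' @return Matrix of scores, sets x observations. Sets with fewer than 2
#'   features present in `x` (or with no out-of-set feature) get `NA` rows
#'   and are listed in the `missing_sets` attribute.
#' @export
project_gene_sets <- function(x, gene_sets) {
  validate_matrix(x)
  nf <- nrow(x)
  R <- apply(x, 2L, rank)
  tot <- colSums(R)
  out <- matrix(NA_real_, length(gene_sets), ncol(x),
    dimnames = list(names(gene_sets), colnames(x))
  )
  missing <- character()
  for (nm in names(gene_sets)) {
    present <- intersect(gene_sets[[nm]], rownames(x))
    S <- length(present)
    if (S < 2L || S > nf - 1L) {
      missing <- c(missing, nm)
      next
    }
    in_sum <- colSums(R[present, , drop = FALSE])
    out[nm, ] <- (in_sum / S - (tot - in_sum) / (nf - S)) / (nf / 2)
  }
  attr(out, "missing_sets") <- missing
  out
}

#' Phenotype association tests for one partition
#'
#' Compares user-provided phenotype variables between the two sides of a
#' partition: Student's t (equal variances) or the Wilcoxon rank-sum test
#' for continuous variables, Fisher's exact test for categorical variables
#' (falling back to a seeded simulated p-value when the exact network
#' algorithm exceeds its workspace). Two-sided throughout; BH FDR across
#' variables.
#'
#' @param phenotypes Data frame of variables with observation ids as row
#'   names (or an `observation` column).
#' @param partition Two-level vector named by observation (as in
#'   [differential_expression()]).
#' @param tests Optional named character vector per variable, values in
#'   `c("t", "wilcoxon", "fisher")`. Unspecified variables default to `"t"`
#'   if numeric, `"fisher"` otherwise.
#' @param seed Seed for simulated Fisher p-values.
#' @return Tibble with `variable`, `test`, `statistic`, `p_value`,
#'   `q_value`, `note` (`"constant"` flags variables with a single value).
#' @export
phenotype_tests <- function(phenotypes, partition, tests = NULL, seed = 1L) {
  phenotypes <- as.data.frame(phenotypes)
  if ("observation" %in% names(phenotypes)) {
    rownames(phenotypes) <- phenotypes$observation
    phenotypes$observation <- NULL
  }
  obs <- names(partition)
  if (is.null(obs)) stop("partition must be named by observation id", call. = FALSE)
  missing <- setdiff(obs, rownames(phenotypes))
  if (length(missing)) {
    stop("phenotypes missing for: ", paste(head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  phenotypes <- phenotypes[obs, , drop = FALSE]
  side <- factor(if (is.numeric(partition)) {
    ifelse(partition > 0, "side1", "side2")
  } else {
    partition
  })
  if (nlevels(side) != 2L) stop("partition must have exactly two sides", call. = FALSE)

  rows <- lapply(names(phenotypes), function(v) {
    val <- phenotypes[[v]]
    test <- if (!is.null(tests) && v %in% names(tests)) {
      match.arg(tests[[v]], c("t", "wilcoxon", "fisher"))
    } else if (is.numeric(val)) "t" else "fisher"
    keep <- !is.na(val)
    if (length(unique(val[keep])) < 2L) {
      return(tibble(
        variable = v, test = test, statistic = NA_real_,
        p_value = 1, note = "constant"
      ))
    }
    ft <- switch(test,
      t = {
        tt <- tryCatch(
          t.test(val[keep] ~ side[keep], var.equal = TRUE),
          error = function(e) NULL
        )
        if (is.null(tt)) {
          # degenerate: zero variance within both sides; p reflects whether
          # the side means coincide
          mm <- tapply(val[keep], side[keep], mean)
          c(stat = NA_real_, p = if (isTRUE(all.equal(mm[[1]], mm[[2]]))) 1 else 0)
        } else {
          c(stat = unname(tt$statistic), p = tt$p.value)
        }
      },
      wilcoxon = {
        wt <- suppressWarnings(wilcox.test(val[keep] ~ side[keep]))
        c(stat = unname(wt$statistic), p = wt$p.value)
      },
      fisher = {
        tab <- table(factor(val[keep]), side[keep])
        res <- tryCatch(
          fisher.test(tab),
          error = function(e) {
            with_seed(
              seed,
              fisher.test(tab, simulate.p.value = TRUE, B = 1e5)
            )
          }
        )
        c(
          stat = if (!is.null(res$estimate)) unname(res$estimate) else NA_real_,
          p = res$p.value
        )
      }
    )
    tibble(
      variable = v, test = test, statistic = ft[["stat"]],
      p_value = ft[["p"]], note = NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- fdr_adjust(out$p_value)
  dplyr::select(
    out, "variable", "test", "statistic", "p_value", "q_value", "note"
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values; non-finite p-values are dropped (reported via a
#' message) and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length as `p`.
#' @export
fdr_adjust <- function(p) {
  bad <- !is.finite(p)
  if (any(p[!bad] < 0 | p[!bad] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(bad)) {
    message(sprintf("fdr_adjust: dropped %d non-finite p-value(s)", sum(bad)))
  }
  q <- rep(NA_real_, length(p))
  q[!bad] <- p.adjust(p[!bad], method = "BH")
  q
}

#' Annotate every partition of a taxonomy
#'
#' Runs the subgroup characterization suite at each internal node of a
#' fitted taxonomy, comparing the two child subgroups: differential
#' expression (with per-side up-regulated signatures and, when gene sets are
#' supplied, hypergeometric over-representation and differential analysis of
#' single-sample projection scores) and phenotype association tests.
#'
#' @param tax A `k2_taxonomy`.
#' @param x The expression matrix the taxonomy was fitted on.
#' @param gene_sets Optional named list of gene sets.
#' @param phenotypes Optional phenotype data frame (see [phenotype_tests()]).
#' @param tests Optional per-variable test choice for `phenotypes`.
#' @param fdr_max,min_mean,max_genes Signature rule (see
#'   [derive_signature()]).
#' @return List of class `k2_annotation` with tibbles `differential`,
#'   `signatures`, `enrichment`, `projection_differential`, `phenotypes`,
#'   each carrying a `node_id` column.
#' @export
annotate_taxonomy <- function(tax, x, gene_sets = NULL, phenotypes = NULL,
                              tests = NULL, fdr_max = 1e-10, min_mean = 0.5,
                              max_genes = 50L) {
  stopifnot(inherits(tax, "k2_taxonomy"))
  validate_matrix(x)
  nodes <- tax$nodes
  internal <- nodes[!nodes$is_leaf, ]
  scores <- if (!is.null(gene_sets)) project_gene_sets(x, gene_sets)

  item_obs <- function(items) {
    if (tax$mode == "group") names(tax$groups)[tax$groups %in% items] else items
  }
  de_all <- list()
  sig_all <- list()
  enr_all <- list()
  proj_all <- list()
  phen_all <- list()
  for (i in seq_len(nrow(internal))) {
    nid <- internal$node_id[i]
    kids <- internal$children[[i]]
    obs1 <- item_obs(nodes$items[[match(kids[1L], nodes$node_id)]])
    obs2 <- item_obs(nodes$items[[match(kids[2L], nodes$node_id)]])
    part <- setNames(
      factor(rep(kids, c(length(obs1), length(obs2))), levels = kids),
      c(obs1, obs2)
    )
    sub <- x[, names(part), drop = FALSE]
    de <- differential_expression(sub, part)
    de_all[[nid]] <- dplyr::mutate(de, node_id = nid, .before = 1L)
    for (sideflip in c(FALSE, TRUE)) {
      de_side <- if (sideflip) {
        dplyr::mutate(de,
          effect = -.data$effect,
          mean_side1 = de$mean_side2, mean_side2 = de$mean_side1
        )
      } else {
        de
      }
      sig <- derive_signature(de_side, fdr_max, min_mean, max_genes)
      side_id <- kids[if (sideflip) 2L else 1L]
      if (length(sig)) {
        sig_all[[paste(nid, side_id)]] <- tibble(
          node_id = nid, side = side_id, feature = sig
        )
        if (!is.null(gene_sets)) {
          enr <- hypergeometric_enrichment(sig, gene_sets, rownames(x))
          if (nrow(enr)) {
            enr_all[[paste(nid, side_id)]] <- dplyr::mutate(enr,
              node_id = nid, side = side_id, .before = 1L
            )
          }
        }
      }
    }
    if (!is.null(gene_sets)) {
      sc <- scores[!rownames(scores) %in% attr(scores, "missing_sets"), ,
        drop = FALSE
      ]
      if (nrow(sc) > 0L) {
        pd <- differential_expression(sc[, names(part), drop = FALSE], part)
        proj_all[[nid]] <- dplyr::mutate(
          dplyr::rename(pd, set = "feature"),
          node_id = nid, .before = 1L
        )
      }
    }
    if (!is.null(phenotypes)) {
      ph <- phenotype_tests(phenotypes, part, tests)
      phen_all[[nid]] <- dplyr::mutate(ph, node_id = nid, .before = 1L)
    }
  }
  structure(
    list(
      differential = dplyr::bind_rows(de_all),
      signatures = dplyr::bind_rows(sig_all),
      enrichment = dplyr::bind_rows(enr_all),
      projection_differential = dplyr::bind_rows(proj_all),
      phenotypes = dplyr::bind_rows(phen_all)
    ),
    class = "k2_annotation"
  )
}

#' @export
print.k2_annotation <- function(x, ...) {
  cat(sprintf(
    "<k2_annotation> %d partitions, %d signature(s), %d enrichment row(s)\n",
    length(unique(x$differential$node_id)),
    nrow(x$signatures), nrow(x$enrichment)
  ))
  invisible(x)
}
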