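#' Cosine (Hamann) similarity matrix of an assignment ensemble
#'
#' For items with dichotomous assignment vectors \eqn{X_i \in \{-1,+1\}^p},
#' the pairwise cosine similarity is \eqn{CS(X_i, X_j) = X_i \cdot X_j /
#' (\|X_i\| \|X_j\|) = (p - 2Z)/p}, where Z counts the mismatching
#' perturbations — the Hamann similarity of the two dichotomies, equal to the
#' Pearson correlation of the standardized rows. The diagonal is exactly 1.
#'
#' @param ensemble A `k2_ensemble` from [build_ensemble()], or a plain
#'   items x p matrix with entries in `{-1, +1}`.
#' @return Symmetric items x items similarity matrix `Q` with unit diagonal.
#' @export
#' @examples
#' A <- rbind(a = c(1, 1, 1, 1), b = c(1, 1, 1, -1))
#' cosine_similarity(A) # off-diagonal (3 - 1)/4 = 0.5
cosine_similarity <- function(ensemble) {
  A <- if (inherits(ensemble, "k2_ensemble")) ensemble$assignments else ensemble
  if (!is.matrix(A) || !all(A %in% c(-1, 1))) {
    stop("assignments must be a matrix with entries in {-1, +1}", call. = FALSE)
  }
  Q <- tcrossprod(A) / ncol(A)
  diag(Q) <- 1
  Q
}

#' Partition stability from the cosine matrix
#'
#' The eigendecomposition of the cosine matrix `Q` measures how consistently
#' item pairs co-assigned across perturbations. With eigenvalues
#' \eqn{\lambda_1 \ge \dots \ge \lambda_N} and cumulative variance fractions
#' \eqn{v_k = \sum_{l \le k} \lambda_l / N}, the partition stability is
#' \deqn{PS = \max_k (v_k - k/N),}
#' the maximal excess of explained variance over the linear-independence null
#' \eqn{v_k = k/N}. PS ranges from 0 (random perturbation assignments,
#' `Q` near identity) to \eqn{1 - 1/N} (all perturbations induce the same
#' bipartition, \eqn{\lambda_1 = N}); the maximum is 0.5 when N = 2.
#'
#' @param Q Symmetric cosine matrix (asymmetry beyond 1e-8 is an error).
#' @param details If `TRUE`, return a list with `ps`, `eigenvalues`, and
#'   `cum_var` instead of the bare statistic.
#' @return The stability (a number in `[0, 1 - 1/N]` for ensemble-derived
#'   `Q`), or a detail list.
#' @export
partition_stability <- function(Q, details = FALSE) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || nrow(Q) < 2L) {
    stop("`Q` must be a square matrix with N >= 2", call. = FALSE)
  }
  if (max(abs(Q - t(Q))) > 1e-8) stop("`Q` is not symmetric", call. = FALSE)
  n <- nrow(Q)
  lambda <- eigen((Q + t(Q)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambda[abs(lambda) < 1e-10] <- 0 # clip numerical noise around zero
  v <- cumsum(lambda) / n
  ps <- max(v - seq_len(n) / n)
  if (details) list(ps = ps, eigenvalues = lambda, cum_var = v) else ps
}

#' Aggregate an ensemble into a single K=2 partition
#'
#' Transforms the cosine similarity matrix into a distance `D = 1 - Q`
#' (range `[0, 2]`), clusters it agglomeratively with the configured linkage,
#' and cuts the tree at K = 2.
#'
#' @param Q Cosine similarity matrix from [cosine_similarity()].
#' @param linkage `"ward"`, `"average"`, `"complete"`, or `"single"`.
#' @return Named vector in `{-1, +1}` over items (+1 for the side containing
#'   the first item); both sides are nonempty.
#' @export
aggregate_partition <- function(Q, linkage = "ward") {
  if (nrow(Q) < 2L) stop("need >= 2 items", call. = FALSE)
  D <- 1 - Q
  diag(D) <- 0
  cl <- cutree(hclust(as.dist(D), method = linkage_method(linkage)), k = 2L)
  side <- ifelse(cl == cl[1L], 1, -1)
  setNames(side, rownames(Q))
}
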