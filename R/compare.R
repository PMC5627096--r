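# Between-network comparisons: Mantel correlation of association matrices
# and the consistency of individual weighted-degree ranks across networks,
# summarized by a sum-of-variances statistic (SV_O) compared with its
# swap-permutation null (SV_R). Small SV_O means individuals keep the same
# relative network position in both datasets.

#' Mantel matrix correlation test
#'
#' Pearson correlation of the vectorized strict upper triangles; the null
#' distribution comes from jointly permuting rows and columns of `m2` by a
#' random relabelling of individuals. One-tailed (greater) by default.
#'
#' @param m1,m2 `association_matrix` objects on an identical individual
#'   index (use [align_individuals()] first); at least 3 individuals.
#' @param n_permutations Monte-Carlo permutations (default 999).
#' @param direction `"greater"` (default) or `"less"`.
#' @param seed optional RNG seed.
#' @param exact if TRUE, enumerate all n! relabellings (n <= 8) and report
#'   the exact permutation p (proportion of relabellings, identity
#'   included, at least as extreme as observed).
#' @return list of class `mantel_result` with `r`, `p`, `n_permutations`,
#'   `n_individuals`.
#' @export
mantel_test <- function(m1, m2, n_permutations = 999,
                        direction = c("greater", "less"), seed = NULL,
                        exact = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(m1, "association_matrix"), inherits(m2, "association_matrix"))
  if (!identical(rownames(m1), rownames(m2))) {
    stop_fmt("matrices must share an identical individual index; align first")
  }
  n <- nrow(m1)
  if (n < 3L) stop_fmt("Mantel test requires at least 3 individuals")
  v1 <- upper_vec(unclass(m1))
  a2 <- unclass(m2)
  v2 <- upper_vec(a2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop_fmt("undefined correlation: zero variance in an upper triangle")
  }
  r_obs <- stats::cor(v1, v2)
  cmp <- function(r_null) {
    if (direction == "greater") r_null >= r_obs - 1e-12 else r_null <= r_obs + 1e-12
  }
  if (exact) {
    if (n > 8L) stop_fmt("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    r_all <- vapply(perms, function(p) stats::cor(v1, upper_vec(a2[p, p])),
                    numeric(1L))
    p_val <- mean(cmp(r_all))
    n_perm <- length(perms)
  } else {
    if (!is_count(n_permutations) || n_permutations < 1) {
      stop_fmt("n_permutations must be a positive count")
    }
    r_null <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
      p <- sample.int(n)
      stats::cor(v1, upper_vec(a2[p, p]))
    }, numeric(1L)))
    p_val <- (1 + sum(cmp(r_null))) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(r = r_obs, p = p_val, n_permutations = n_perm,
                 n_individuals = n, direction = direction, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %s (%d individuals, %d permutations, %s)\n",
              x$r, format_p(x$p), x$n_individuals, x$n_permutations, x$direction))
  invisible(x)
}

# all permutations of 1..n, recursively (n <= 8 guard upstream)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

#' Scaled ranks of weighted degree
#'
#' Individuals are ranked by weighted degree (average ranks for ties) and
#' scaled to [0,1] as `(rank - 1) / (n - 1)`, making network positions
#' relative to all others in the network.
#' @param matrix an `association_matrix` with >= 2 individuals.
#' @return named numeric vector in [0,1].
#' @export
scaled_degree_ranks <- function(matrix) {
  deg <- weighted_degree(matrix)
  n <- length(deg)
  if (n < 2L) stop_fmt("scaled ranks require at least 2 individuals")
  (rank(deg, ties.method = "average") - 1) / (n - 1)
}

#' Sum of variances of scaled ranks across networks
#'
#' `SV = sum_i var(rank_i across networks)` with the sample (n-1) variance;
#' for two networks the per-individual term is `(a - b)^2 / 2`. Identical
#' rank vectors give SV = 0.
#' @param rank_vectors list (or matrix, networks in rows) of >= 2 aligned
#'   named rank vectors.
#' @return SV >= 0.
#' @export
sum_of_variances <- function(rank_vectors) {
  if (is.matrix(rank_vectors)) {
    X <- rank_vectors
  } else {
    stopifnot(is.list(rank_vectors), length(rank_vectors) >= 2L)
    nm <- names(rank_vectors[[1L]])
    for (v in rank_vectors[-1L]) {
      if (length(v) != length(rank_vectors[[1L]]) ||
          (!is.null(nm) && !identical(names(v), nm))) {
        stop_fmt("rank vectors are not aligned on the same individuals")
      }
    }
    X <- do.call(rbind, rank_vectors)
  }
  if (nrow(X) < 2L) stop_fmt("need >= 2 networks")
  sum(apply(X, 2L, stats::var))
}

#' Consistency of individual network position between two datasets
#'
#' Builds the observed association matrix of each group dataset, aligns
#' them on common individuals, and computes the observed sum of variances
#' (SV_O) of scaled weighted-degree ranks. The null SV_R distribution comes
#' from running an independent serial swap chain on each dataset and
#' recomputing SV after every `swaps_between_samples` swaps. Low p (add-one
#' rule on `SV_R <= SV_O`) indicates significantly consistent individual
#' positions. Both datasets are randomized; SV_R's interval is the 2.5/97.5
#' empirical percentile range (recorded in `meta`).
#'
#' @param periods_1,periods_2 `period_table` objects sharing >= 2
#'   individuals.
#' @param n_permutations recorded SV_R values (default 10000).
#' @param swaps_between_samples swaps per recorded value (default 1).
#' @param constraint a [swap_constraint()].
#' @param seed optional RNG seed.
#' @return list of class `consistency_result`: `sv_observed`, `sv_null`,
#'   `null_mean`, `null_lo`, `null_hi`, `p`, `n_individuals`, `meta`.
#' @export
consistency_test <- function(periods_1, periods_2, n_permutations = 10000,
                             swaps_between_samples = 1,
                             constraint = swap_constraint(), seed = NULL) {
  if (!is_count(n_permutations) || n_permutations < 1) {
    stop_fmt("n_permutations must be a positive count")
  }
  ids1 <- sort(unique(unlist(periods_1$members)))
  ids2 <- sort(unique(unlist(periods_2$members)))
  common <- intersect(ids1, ids2)
  if (length(common) < 2L) stop_fmt("datasets share fewer than 2 individuals")
  s1 <- swap_state(periods_1, constraint)
  s2 <- swap_state(periods_2, constraint)
  sv_of <- function() {
    r1 <- scaled_ranks_from_sri(state_sri(s1), common)
    r2 <- scaled_ranks_from_sri(state_sri(s2), common)
    sum_of_variances(list(r1, r2))
  }
  sv_obs <- sv_of()
  sv_null <- numeric(n_permutations)
  n_identity <- 0L
  with_seed(seed, {
    for (i in seq_len(n_permutations)) {
      for (s in seq_len(swaps_between_samples)) {
        ok1 <- state_swap_once(s1)
        ok2 <- state_swap_once(s2)
        if (!ok1 && !ok2) n_identity <- n_identity + 1L
      }
      sv_null[i] <- sv_of()
    }
  })
  if (n_identity == n_permutations * swaps_between_samples) {
    warn_fmt("no swaps possible in either dataset: SV_R null collapses to a point")
  }
  structure(list(sv_observed = sv_obs,
                 sv_null = sv_null,
                 null_mean = mean(sv_null),
                 null_lo = stats::quantile(sv_null, 0.025, names = FALSE),
                 null_hi = stats::quantile(sv_null, 0.975, names = FALSE),
                 p = add_one_p(sv_obs, sv_null, "less"),
                 n_individuals = length(common),
                 n_permutations = n_permutations,
                 meta = list(randomized = "both datasets, independent chains",
                             interval = "2.5/97.5 empirical percentiles")),
            class = "consistency_result")
}

scaled_ranks_from_sri <- function(sri, common) {
  sub <- sri[common, common, drop = FALSE]
  deg <- rowSums(sub)
  (rank(deg, ties.method = "average") - 1) / (length(deg) - 1)
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("rank consistency: SV_O = %.3f, SV_R = %.3f (%.3f; %.3f), p = %s (%d individuals)\n",
              x$sv_observed, x$null_mean, x$null_lo, x$null_hi,
              format_p(x$p), x$n_individuals))
  invisible(x)
}
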