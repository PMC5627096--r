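# Data-stream (swap) permutations of group data and non-randomness tests.
#
# The null model serially exchanges two individuals between two groups drawn
# from the same sampling period (by default), preserving every group's size
# and every individual's total number of group memberships — so the null
# keeps the sampling structure and destroys only the identity of who is
# with whom. After each swap the association matrix is rebuilt and the
# requested statistics (mean and CV of the indices) recorded, giving a
# null distribution against which the observed statistic is compared.

#' Swap constraint set
#'
#' @param within_period restrict swaps to groups of the same sampling period
#'   (default TRUE: controls for temporal presence).
#' @param within_receiver additionally require the same receiver
#'   (default FALSE).
#' @return list of class `swap_constraint`.
#' @export
swap_constraint <- function(within_period = TRUE, within_receiver = FALSE) {
  structure(list(within_period = isTRUE(within_period),
                 within_receiver = isTRUE(within_receiver)),
            class = "swap_constraint")
}

# Mutable permutation state. Keeps, besides the group lists, per-period
# incidence/co-occurrence and their aggregates so a swap costs O(n^2) for
# the affected period(s) rather than a full rebuild.
swap_state <- function(periods, constraint = swap_constraint(), ids = NULL) {
  stopifnot(inherits(periods, "period_table"), inherits(constraint, "swap_constraint"))
  ids <- as.character(ids %||% sort(unique(unlist(periods$members))))
  inc <- period_incidence(periods, ids)
  n <- length(ids)
  P <- inc$n_periods
  # per-period co-occurrence matrices, for delta updates
  Cp <- vector("list", P)
  Op <- vector("list", P)
  for (p in seq_len(P)) {
    gs <- inc$groups_int[inc$group_period == p]
    M <- matrix(FALSE, n, max(1L, length(gs)))
    for (k in seq_along(gs)) M[gs[[k]], k] <- TRUE
    C <- tcrossprod(M) > 0; diag(C) <- FALSE
    Cp[[p]] <- C
    Op[[p]] <- rowSums(M) > 0
  }
  cell <- if (constraint$within_period && constraint$within_receiver) {
    paste(inc$group_period, periods$receiver_id)
  } else if (constraint$within_period) {
    as.character(inc$group_period)
  } else {
    rep("*", length(inc$group_period))
  }
  cell_groups <- split(seq_along(inc$groups_int), cell)
  cell_groups <- cell_groups[lengths(cell_groups) >= 2L]
  npairs <- vapply(cell_groups, function(g) length(g) * (length(g) - 1) / 2, numeric(1L))
  env <- new.env(parent = emptyenv())
  env$ids <- ids; env$n <- n; env$P <- P
  env$groups <- inc$groups_int
  env$group_period <- inc$group_period
  env$period_groups <- split(seq_along(inc$groups_int), inc$group_period)
  env$Cp <- Cp; env$Op <- Op
  env$X <- Reduce(`+`, lapply(Cp, `*`, 1), matrix(0, n, n))
  env$B <- Reduce(`+`, lapply(Op, function(o) tcrossprod(o * 1)), matrix(0, n, n))
  env$d <- rowSums(matrix(unlist(Op), nrow = n))
  env$cell_groups <- cell_groups
  env$npairs <- npairs
  # cells never change under swaps: precompute the cumulative pair weights
  # once so each draw is O(log cells)
  env$cum_pairs <- cumsum(npairs)
  env$constraint <- constraint
  env
}

refresh_period <- function(state, p) {
  gs <- state$groups[state$period_groups[[as.character(p)]]]
  n <- state$n
  M <- matrix(FALSE, n, max(1L, length(gs)))
  for (k in seq_along(gs)) M[gs[[k]], k] <- TRUE
  C <- tcrossprod(M) > 0; diag(C) <- FALSE
  o <- rowSums(M) > 0
  state$X <- state$X + C - state$Cp[[p]]
  state$B <- state$B + tcrossprod(o * 1) - tcrossprod(state$Op[[p]] * 1)
  state$d <- state$d + o - state$Op[[p]]
  state$Cp[[p]] <- C
  state$Op[[p]] <- o
  invisible(state)
}

# One Bejder-style swap on the state. Returns TRUE if a non-identity swap
# happened, FALSE if the bounded retries found no exchangeable pair.
state_swap_once <- function(state, max_retries = 100L) {
  if (!length(state$cell_groups)) return(FALSE)
  tot <- state$cum_pairs[length(state$cum_pairs)]
  for (try in seq_len(max_retries)) {
    c_i <- if (length(state$cell_groups) == 1L) 1L else
      findInterval(stats::runif(1L) * tot, state$cum_pairs) + 1L
    gs <- state$cell_groups[[c_i]]
    pick <- gs[sample.int(length(gs), 2L)]
    g1 <- state$groups[[pick[1L]]]; g2 <- state$groups[[pick[2L]]]
    a_pool <- g1[!g1 %in% g2]; b_pool <- g2[!g2 %in% g1]
    if (!length(a_pool) || !length(b_pool)) next
    a <- if (length(a_pool) == 1L) a_pool else sample(a_pool, 1L)
    b <- if (length(b_pool) == 1L) b_pool else sample(b_pool, 1L)
    state$groups[[pick[1L]]] <- c(g1[g1 != a], b)
    state$groups[[pick[2L]]] <- c(g2[g2 != b], a)
    for (p in unique(state$group_period[pick])) refresh_period(state, p)
    return(TRUE)
  }
  FALSE
}

state_sri <- function(state) {
  denom <- outer(state$d, state$d, "+") - state$B
  sri <- matrix(0, state$n, state$n, dimnames = list(state$ids, state$ids))
  pos <- denom > 0
  sri[pos] <- state$X[pos] / denom[pos]
  diag(sri) <- 0
  sri
}

state_to_period_table <- function(state, periods) {
  out <- as.data.frame(periods)
  out$members <- lapply(state$groups, function(g) sort(state$ids[g]))
  as_group_table(out, bin_width = attr(periods, "bin_width"),
                 period_width = attr(periods, "period_width"))
}

#' Perform a single data-stream swap
#'
#' Two groups satisfying the constraint are drawn uniformly among eligible
#' pairs; one individual exclusive to each is exchanged. Group sizes and all
#' individual membership counts are preserved. If no exchangeable pair is
#' found within the retry budget the input is returned unchanged with
#' attribute `swapped = FALSE`.
#'
#' @param periods a `period_table`.
#' @param constraint a [swap_constraint()].
#' @param seed optional RNG seed.
#' @param max_retries bounded redraws when a drawn pair has no exchangeable
#'   individuals.
#' @return a `period_table` with attribute `swapped` (logical).
#' @export
swap_once <- function(periods, constraint = swap_constraint(), seed = NULL,
                      max_retries = 100L) {
  state <- swap_state(periods, constraint)
  ok <- with_seed(seed, state_swap_once(state, max_retries))
  out <- state_to_period_table(state, periods)
  attr(out, "swapped") <- ok
  out
}

matrix_stat_fns <- list(
  mean = function(sri) mean(upper_vec(sri)),
  cv = function(sri) {
    v <- upper_vec(sri)
    m <- mean(v)
    if (m == 0) NA_real_ else stats::sd(v) / m
  }
)

#' Serial swap-permutation null distributions
#'
#' A single evolving copy of the group data is serially mutated; after every
#' `swaps_between_samples` swaps the simple-ratio matrix is rebuilt and each
#' requested statistic recorded, for `n_permutations` recorded values
#' (one swap between samples and 10 000 permutations by default).
#'
#' @param periods a `period_table`.
#' @param n_permutations recorded null values (default 10000).
#' @param swaps_between_samples swaps per recorded value (default 1).
#' @param constraint a [swap_constraint()].
#' @param statistics subset of `c("mean", "cv")`.
#' @param seed optional RNG seed (chain is fully reproducible).
#' @param individuals optional individual index for the matrices.
#' @return named list of `null_distribution` objects, one per statistic:
#'   each has `statistic`, `values`, `observed` and a one-sided (greater)
#'   `p` computed by the add-one rule.
#' @export
permuted_null_stream <- function(periods, n_permutations = 10000,
                                 swaps_between_samples = 1,
                                 constraint = swap_constraint(),
                                 statistics = c("mean", "cv"),
                                 seed = NULL, individuals = NULL) {
  if (!is_count(n_permutations) || n_permutations < 1) {
    stop_fmt("n_permutations must be a positive count")
  }
  statistics <- match.arg(statistics, names(matrix_stat_fns), several.ok = TRUE)
  if (nrow(periods) == 0L) stop_fmt("empty period table")
  state <- swap_state(periods, constraint, ids = individuals)
  observed <- vapply(statistics, function(s) matrix_stat_fns[[s]](state_sri(state)),
                     numeric(1L))
  vals <- matrix(NA_real_, n_permutations, length(statistics),
                 dimnames = list(NULL, statistics))
  n_identity <- 0L
  with_seed(seed, {
    for (i in seq_len(n_permutations)) {
      for (s in seq_len(swaps_between_samples)) {
        if (!state_swap_once(state)) n_identity <- n_identity + 1L
      }
      sri <- state_sri(state)
      for (s in statistics) vals[i, s] <- matrix_stat_fns[[s]](sri)
    }
  })
  if (n_identity > 0L) {
    warn_fmt("%d of %d swap draws were identity swaps (degenerate group data)",
             n_identity, n_permutations * swaps_between_samples)
  }
  out <- lapply(statistics, function(s) {
    null_distribution(s, vals[, s], observed[[s]])
  })
  names(out) <- statistics
  out
}

#' Null distribution container
#' @param statistic statistic name.
#' @param values numeric vector of null statistics.
#' @param observed observed statistic.
#' @return object of class `null_distribution` with the add-one one-sided
#'   (greater) p-value.
#' @export
null_distribution <- function(statistic, values, observed) {
  p <- add_one_p(observed, values, "greater")
  structure(list(statistic = statistic, values = values,
                 observed = observed, p = p, n = length(values)),
            class = "null_distribution")
}

add_one_p <- function(observed, null_values, direction) {
  null_values <- null_values[!is.na(null_values)]
  if (!length(null_values) || is.na(observed)) return(NA_real_)
  k <- if (direction == "greater") {
    sum(null_values >= observed - 1e-12)
  } else {
    sum(null_values <= observed + 1e-12)
  }
  (1 + k) / (1 + length(null_values))
}

#' Test for non-random associations
#'
#' Compares an observed matrix statistic (typically the mean or the CV of
#' the association indices) against its swap-permutation null. A
#' significantly higher CV than random indicates preferred/avoided
#' relationships; a higher mean indicates overall non-random grouping.
#' p-values use the add-one rule `(1 + #\{null >= obs\}) / (1 + n)` so they
#' are never exactly zero.
#'
#' @param observed an `association_matrix`, or the observed statistic value.
#' @param null a `null_distribution`.
#' @param direction `"greater"` (default) or `"less"`.
#' @return list of class `nonrandomness_test`: observed value, null mean,
#'   null 2.5/97.5 percentiles, p-value.
#' @export
nonrandomness_test <- function(observed, null, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(inherits(null, "null_distribution"))
  if (!length(null$values)) stop_fmt("empty null distribution")
  obs <- if (inherits(observed, "association_matrix")) {
    matrix_stat_fns[[null$statistic]](unclass(observed))
  } else {
    stopifnot(is.numeric(observed), length(observed) == 1L)
    observed
  }
  vals <- null$values[!is.na(null$values)]
  structure(list(statistic = null$statistic,
                 observed = obs,
                 null_mean = mean(vals),
                 null_lo = stats::quantile(vals, 0.025, names = FALSE),
                 null_hi = stats::quantile(vals, 0.975, names = FALSE),
                 p = add_one_p(obs, vals, direction),
                 direction = direction,
                 n_permutations = length(vals)),
            class = "nonrandomness_test")
}

#' @export
print.nonrandomness_test <- function(x, ...) {
  cat(sprintf("non-randomness test (%s, %s): observed %.4f, null %.4f (%.4f; %.4f), p = %s\n",
              x$statistic, x$direction, x$observed, x$null_mean, x$null_lo,
              x$null_hi, format_p(x$p)))
  invisible(x)
}

# Display convention: small/large add-one p-values print as 0.000 / 1.000
# while the exact value stays in the object.
format_p <- function(p) {
  if (is.na(p)) return("NA")
  sprintf("%.3f", p)
}

#' Export a null distribution as single-column CSV for audit
#' @param null a `null_distribution`.
#' @param path CSV path.
#' @export
write_null_distribution <- function(null, path) {
  stopifnot(inherits(null, "null_distribution"))
  utils::write.csv(data.frame(value = null$values), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
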