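# Dyadic counts and simple-ratio-index association matrices.
#
# Counting is period-level: within one sampling period an individual is
# "observed" if it appears in any group, and a dyad "co-occurs" if some
# single group of the period contains both. For a dyad (A,B) over P periods
#   x    : periods where A and B co-occurred,
#   y_AB : periods where both were observed but never together,
#   y_A  : periods where only A (of the two) was observed,
#   y_B  : periods where only B was observed,
# and the simple ratio index is E_AB = x / (x + y_AB + y_A + y_B), a
# co-occurrence proportion in [0,1]: 0 = never in the same group,
# 1 = always in the same group when either was seen.

#' Period-level incidence and co-occurrence
#'
#' Internal workhorse shared by dyad_counts and the permutation engine.
#' Returns, for n individuals and P periods, the observed-incidence matrix
#' O (n x P logical) and the co-occurrence period count matrix X (n x n).
#' @noRd
period_incidence <- function(periods, ids) {
  pid <- as.numeric(periods$period_start)
  pf <- factor(pid, levels = sort(unique(pid)))
  P <- nlevels(pf)
  n <- length(ids)
  O <- matrix(FALSE, n, P)
  X <- matrix(0, n, n)
  groups_int <- lapply(periods$members, function(m) {
    i <- match(m, ids)
    if (anyNA(i)) stop_fmt("group member(s) missing from the individual index: %s",
                           paste(m[is.na(i)], collapse = ", "))
    i
  })
  gp <- as.integer(pf)
  for (p in seq_len(P)) {
    gs <- groups_int[gp == p]
    if (!length(gs)) next
    M <- matrix(FALSE, n, length(gs))
    for (k in seq_along(gs)) M[gs[[k]], k] <- TRUE
    O[, p] <- rowSums(M) > 0
    C <- tcrossprod(M) > 0   # dyad shares >=1 group this period
    diag(C) <- FALSE
    X <- X + C
  }
  list(ids = ids, O = O, X = X, n_periods = P,
       period_levels = as.numeric(levels(pf)), group_period = gp,
       groups_int = groups_int)
}

#' Dyadic counts over sampling periods
#'
#' @param periods a `period_table` (see [collapse_to_periods()]).
#' @param individuals optional individual index (character); defaults to the
#'   sorted set of individuals appearing in the groups. Must contain every
#'   group member.
#' @return object of class `dyad_counts`: matrices `x`, `y_ab`, `y_a`, `y_b`
#'   (symmetric up to the y_a/y_b transpose relation), vector
#'   `times_observed`, and `n_periods`.
#' @export
dyad_counts <- function(periods, individuals = NULL) {
  stopifnot(inherits(periods, "period_table"))
  ids <- individuals %||% sort(unique(unlist(periods$members)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_fmt("individual index contains duplicates")
  inc <- period_incidence(periods, ids)
  d <- rowSums(inc$O)                   # periods each individual observed
  B <- tcrossprod(inc$O * 1)            # periods both observed
  x <- inc$X
  y_ab <- B - x
  y_a <- outer(d, rep(0, length(d)), "+") - B   # [A,B] = d_A - B_AB
  y_b <- t(y_a)
  diag(x) <- diag(y_ab) <- diag(y_a) <- diag(y_b) <- 0
  dimnames(x) <- dimnames(y_ab) <- dimnames(y_a) <- dimnames(y_b) <-
    dimnames(B) <- list(ids, ids)
  names(d) <- ids
  structure(list(ids = ids, n_periods = inc$n_periods,
                 x = x, y_ab = y_ab, y_a = y_a, y_b = y_b,
                 both_observed = B, times_observed = d),
            class = "dyad_counts")
}

#' Simple ratio index matrix from dyadic counts
#'
#' Dyads whose denominator is zero (neither individual ever observed) get
#' weight 0 and are flagged in the `unsampled` attribute so the matrix stays
#' dense for Mantel tests.
#' @param counts a `dyad_counts` object.
#' @param provenance optional named list recorded on the matrix.
#' @return an `association_matrix`.
#' @export
simple_ratio_index <- function(counts, provenance = NULL) {
  stopifnot(inherits(counts, "dyad_counts"))
  denom <- counts$x + counts$y_ab + counts$y_a + counts$y_b
  sri <- ifelse(denom > 0, counts$x / pmax(denom, 1), 0)
  diag(sri) <- 0
  unsampled <- denom == 0
  diag(unsampled) <- FALSE
  association_matrix(sri, counts = counts, unsampled = unsampled,
                     provenance = provenance)
}

#' Association matrix container
#'
#' A symmetric individual-by-individual matrix of association indices in
#' [0,1] with zero diagonal, optionally carrying the underlying dyadic
#' counts, an `unsampled` dyad flag and provenance metadata.
#' @param m numeric matrix with identical row/column individual ids.
#' @param counts optional `dyad_counts`.
#' @param unsampled optional logical matrix flagging zero-denominator dyads.
#' @param provenance optional named list (receiver set, window, parameters).
#' @return object of class `association_matrix`.
#' @export
association_matrix <- function(m, counts = NULL, unsampled = NULL,
                               provenance = NULL) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) {
    dimnames(m) <- list(as.character(seq_len(nrow(m))),
                        as.character(seq_len(nrow(m))))
  }
  if (!identical(rownames(m), colnames(m))) stop_fmt("row/column ids differ")
  if (nrow(m)) {
    if (any(m < 0 | m > 1)) stop_fmt("association indices must lie in [0, 1]")
    if (max(abs(m - t(m))) > 1e-12) stop_fmt("association matrix must be symmetric")
    if (any(diag(m) != 0)) stop_fmt("association matrix diagonal must be zero")
  }
  structure(m, counts = counts, unsampled = unsampled, provenance = provenance,
            class = c("association_matrix", "matrix"))
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association matrix: %d individuals\n", nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov$network)) cat("network:", prov$network, "\n")
  print(round(unclass(x)[, , drop = FALSE], 3))
  invisible(x)
}

#' Weighted degree (strength)
#'
#' Sum of an individual's association indices — the centrality compared
#' across networks.
#' @param matrix an `association_matrix`.
#' @return named numeric vector.
#' @export
weighted_degree <- function(matrix) {
  stopifnot(inherits(matrix, "association_matrix"))
  rowSums(unclass(matrix))
}

#' Align association matrices on their common individuals
#'
#' Restricts every matrix to the sorted intersection of the individual sets,
#' subsetting attached counts consistently (dyadic counts are dyad-local, so
#' subsetting is exact).
#' @param matrices list of `association_matrix` objects (length >= 2).
#' @return list of matrices on the common index.
#' @export
align_individuals <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2L,
            all(vapply(matrices, inherits, logical(1L), "association_matrix")))
  common <- sort(Reduce(intersect, lapply(matrices, rownames)))
  if (!length(common)) stop_fmt("matrices share no individuals")
  lapply(matrices, function(m) {
    sub <- unclass(m)[common, common, drop = FALSE]
    cnt <- attr(m, "counts")
    if (!is.null(cnt)) {
      for (f in c("x", "y_ab", "y_a", "y_b", "both_observed")) {
        cnt[[f]] <- cnt[[f]][common, common, drop = FALSE]
      }
      cnt$times_observed <- cnt$times_observed[common]
      cnt$ids <- common
    }
    uns <- attr(m, "unsampled")
    if (!is.null(uns)) uns <- uns[common, common, drop = FALSE]
    association_matrix(sub, counts = cnt, unsampled = uns,
                       provenance = attr(m, "provenance"))
  })
}
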