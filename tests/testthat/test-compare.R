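rand_am <- function(ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(ids)
  x <- matrix(0, n, n)
  x[upper.tri(x)] <- round(runif(n * (n - 1) / 2), 3)
  x <- x + t(x)
  dimnames(x) <- list(ids, ids)
  association_matrix(x)
}

test_that("mantel_test basics: identity, zero variance, symmetry", {
  m <- rand_am(LETTERS[1:5], seed = 1)
  expect_equal(mantel_test(m, m, n_permutations = 9, seed = 1)$r, 1)
  const <- association_matrix(matrix(0.5, 5, 5) - diag(0.5, 5),
                              counts = NULL)
  dimnames_const <- list(LETTERS[1:5], LETTERS[1:5])
  const <- association_matrix(`dimnames<-`(unclass(const), dimnames_const))
  expect_error(mantel_test(m, const, seed = 1), "zero variance")
  m2 <- rand_am(LETTERS[1:5], seed = 2)
  expect_equal(mantel_test(m, m2, n_permutations = 9, seed = 3)$r,
               mantel_test(m2, m, n_permutations = 9, seed = 3)$r)
  expect_error(mantel_test(m, rand_am(LETTERS[2:6], seed = 3)), "identical")
  expect_error(mantel_test(rand_am(c("A", "B"), 1), rand_am(c("A", "B"), 2)),
               "3 individuals")
})

test_that("mantel r is invariant to simultaneous relabelling of both matrices", {
  m1 <- rand_am(LETTERS[1:6], seed = 4)
  m2 <- rand_am(LETTERS[1:6], seed = 5)
  r0 <- mantel_test(m1, m2, n_permutations = 9, seed = 1)$r
  set.seed(9); p <- sample(6)
  relab <- function(m) {
    x <- unclass(m)[p, p]
    dimnames(x) <- list(LETTERS[1:6], LETTERS[1:6])
    association_matrix(x)
  }
  expect_equal(mantel_test(relab(m1), relab(m2), n_permutations = 9, seed = 1)$r, r0)
})

test_that("exact 4x4 Mantel p equals the brute-force enumeration oracle", {
  m1 <- rand_am(LETTERS[1:4], seed = 6)
  m2 <- rand_am(LETTERS[1:4], seed = 7)
  res <- mantel_test(m1, m2, exact = TRUE)
  expect_equal(res$n_permutations, 24)
  # oracle: enumerate the 24 relabellings independently
  ut <- function(m) m[upper.tri(m)]
  v1 <- ut(unclass(m1))
  r_all <- vapply(oracle_all_perms(4), function(p) {
    cor(v1, ut(unclass(m2)[p, p]))
  }, numeric(1))
  expect_equal(res$r, cor(v1, ut(unclass(m2))))
  expect_equal(res$p, mean(r_all >= res$r - 1e-12))
})

test_that("mantel r agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  m1 <- rand_am(LETTERS[1:7], seed = 8)
  m2 <- rand_am(LETTERS[1:7], seed = 9)
  ref <- vegan::mantel(as.dist(unclass(m1)), as.dist(unclass(m2)),
                       permutations = 99)
  expect_equal(mantel_test(m1, m2, n_permutations = 9, seed = 1)$r,
               unname(ref$statistic), tolerance = 1e-12)
})

test_that("scaled_degree_ranks follows the average-rank, (r-1)/(n-1) convention", {
  mk <- function(deg) {
    # build a star-free matrix whose degrees are proportional to deg
    n <- length(deg)
    x <- outer(deg, deg) / (sum(deg) * 2)
    diag(x) <- 0
    x <- pmin(x, 1)
    dimnames(x) <- list(letters[1:n], letters[1:n])
    association_matrix((x + t(x)) / 2)
  }
  m <- mk(c(1, 2, 3))
  expect_equal(unname(scaled_degree_ranks(m)), c(0, 0.5, 1))
  tie <- association_matrix(matrix(c(0, .4, .4, 0), 2,
                                   dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(unname(scaled_degree_ranks(tie)), c(0.5, 0.5))
  set.seed(10)
  r <- scaled_degree_ranks(rand_am(letters[1:9]))
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(min(r) + max(r), 1, tolerance = 1e-12)
})

test_that("sum_of_variances uses the sample variance and is order-invariant", {
  v <- c(a = 0.2, b = 0.8, c = 0.5)
  expect_equal(sum_of_variances(list(v, v)), 0)
  # two networks, ranks [0,1] vs [1,0]: per-individual (a-b)^2/2 = 0.5 each
  r1 <- c(a = 0, b = 1); r2 <- c(a = 1, b = 0)
  expect_equal(sum_of_variances(list(r1, r2)), 1.0)
  w <- c(a = 0.1, b = 0.9, c = 0.4)
  expect_equal(sum_of_variances(list(v, w)), sum_of_variances(list(w, v)))
  expect_error(sum_of_variances(list(v, w[c(2, 1, 3)])), "aligned")
})

test_that("consistency_test: a dataset against its copy gives SV_O = 0, minimal p", {
  # dense data (most individuals seen every period, several groups) so that
  # swaps essentially always perturb the degree ranks
  set.seed(12)
  pl <- lapply(1:40, function(p) {
    present <- LETTERS[1:10][runif(10) < 0.8]
    if (length(present) < 4) present <- LETTERS[1:4]
    unname(split(present, sample(rep(1:3, length.out = length(present)))))
  })
  periods <- make_periods(pl)
  res <- consistency_test(periods, periods, n_permutations = 400, seed = 3)
  expect_equal(res$sv_observed, 0)
  # early samples of the serial chains can still tie at SV = 0, so p sits at
  # or just above the add-one floor 1/(n+1)
  expect_gte(res$p, 1 / 401)
  expect_lt(res$p, 0.05)
  expect_lte(res$null_lo, res$null_hi)
})

test_that("consistency_test p is stable under swapping dataset order", {
  set.seed(13)
  base <- random_period_list(7, 25)
  # second dataset: same individuals, independently shuffled groups
  other <- random_period_list(7, 25)
  ids <- union(unlist(base), unlist(other))
  p1 <- consistency_test(make_periods(base), make_periods(other),
                         n_permutations = 400, seed = 21)$p
  p2 <- consistency_test(make_periods(other), make_periods(base),
                         n_permutations = 400, seed = 21)$p
  expect_lt(abs(p1 - p2), 0.2)   # equal up to Monte-Carlo noise
})

test_that("degenerate group data collapses the SV_R null with a warning", {
  # one group per period: no eligible swap pair exists in either dataset
  lone <- make_periods(list(list(c("A", "B")), list(c("A", "B"))))
  expect_warning(res <- consistency_test(lone, lone,
                                         n_permutations = 20, seed = 1),
                 "collapses")
  expect_equal(res$sv_observed, 0)
  expect_true(all(res$sv_null == 0))
})
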