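# Fixtures and independent oracles. Oracles are deliberately literal
# (nested loops over periods/dyads, recursive permutation enumeration)
# and share no code with the implementation paths they check.

EPOCH <- as.POSIXct("2012-08-25 00:00:00", tz = "UTC")

# Build a period_table from a list of periods, each a list of character
# groups. Period p starts at EPOCH + (p-1) hours; groups are spread over
# the six 10-min bins of the hour (several groups may share a bin).
make_periods <- function(period_list, receiver = "R1") {
  rid <- character(0); bins <- numeric(0); members <- list()
  for (p in seq_along(period_list)) {
    for (g in seq_along(period_list[[p]])) {
      rid <- c(rid, receiver)
      bins <- c(bins, as.numeric(EPOCH) + (p - 1) * 3600 + ((g - 1) %% 6) * 600)
      members <- c(members, list(period_list[[p]][[g]]))
    }
  }
  gt <- group_table(rid, as.POSIXct(bins, origin = "1970-01-01", tz = "UTC"),
                    members, bin_width = 600)
  collapse_to_periods(gt, 3600)
}

# Literal brute-force SRI: loops over periods and dyads exactly as defined.
oracle_sri <- function(period_list, ids = NULL) {
  ids <- sort(ids %||% unique(unlist(period_list)))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    A <- ids[i]; B <- ids[j]
    x <- yab <- ya <- yb <- 0
    for (period in period_list) {
      seen_a <- any(vapply(period, function(g) A %in% g, logical(1)))
      seen_b <- any(vapply(period, function(g) B %in% g, logical(1)))
      together <- any(vapply(period, function(g) A %in% g && B %in% g, logical(1)))
      if (together) x <- x + 1
      else if (seen_a && seen_b) yab <- yab + 1
      else if (seen_a) ya <- ya + 1
      else if (seen_b) yb <- yb + 1
    }
    denom <- x + yab + ya + yb
    m[i, j] <- m[j, i] <- if (denom > 0) x / denom else 0
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random gambit-of-the-group instance: up to n_ind individuals, n_per periods.
random_period_list <- function(n_ind = 10, n_per = 30) {
  ids <- LETTERS[seq_len(sample(2:n_ind, 1))]
  lapply(seq_len(sample(1:n_per, 1)), function(p) {
    present <- ids[runif(length(ids)) < 0.6]
    if (!length(present)) present <- sample(ids, 1)
    grps <- list()
    while (length(present)) {
      k <- sample(seq_len(min(4, length(present))), 1)
      grps <- c(grps, list(sort(sample(present, k))))
      present <- setdiff(present, grps[[length(grps)]])
    }
    grps
  })
}

# Independent permutation enumerator (iterative, Heap-free lexicographic
# construction through expand-and-filter; distinct from the package's
# recursive generator).
oracle_all_perms <- function(n) {
  out <- list(integer(0))
  for (k in seq_len(n)) {
    out <- do.call(c, lapply(out, function(p) {
      lapply(seq_len(n)[!seq_len(n) %in% p], function(v) c(p, v))
    }))
  }
  out
}

# membership multiset fingerprints used by swap-conservation checks
membership_counts <- function(periods) sort(table(unlist(periods$members)))
group_sizes <- function(periods) sort(lengths(periods$members))

# tiny preference-free calibration scenario: independent hourly samples
# (short rest bouts), well-separated sites each covered by a 10 m receiver
calib_scenario <- function(seed, p_social = 0, pref = NULL, n = 8,
                           duration = 2 * 86400, rest = 900) {
  sites <- rbind(c(0, 0), c(60, 0), c(0, 60), c(60, 60), c(30, 120))
  cfg <- sim_config(n_individuals = n, site_positions = sites,
                    duration = duration, preference_matrix = pref,
                    p_social = p_social, rest_duration_mean = rest,
                    step = 60, seed = seed)
  rec <- receiver_table(receiver_id = sprintf("S%d", 1:5), kind = "fixed",
                        detection_radius = 10,
                        x = sites[, 1], y = sites[, 2])
  traj <- simulate_trajectories(cfg)
  pings <- generate_pings(traj, cfg)
  det <- simulate_detections(pings, traj, rec, cfg)
  list(cfg = cfg, receivers = rec, traj = traj, det = det)
}

# detections -> hourly period table (10-min bins)
det_to_periods <- function(det) {
  collapse_to_periods(bin_detections(det, 600), 3600)
}

# plain matrix view of an association_matrix (drop class and attributes,
# keep dims/dimnames even for 1x1)
strip_am <- function(m) {
  a <- unclass(m)
  attributes(a) <- list(dim = dim(m), dimnames = dimnames(m))
  a
}
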