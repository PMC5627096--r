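two_site <- rbind(c(0, 0), c(200, 0))

test_that("sim_config validates its invariants", {
  expect_error(sim_config(2, matrix(numeric(0), 0, 2), 100), "at least one site")
  expect_error(sim_config(2, two_site, -1), "duration")
  bad_pref <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(sim_config(2, two_site, 100, preference_matrix = bad_pref),
               "symmetric")
  expect_error(sim_config(2, two_site, 100, rest_duration_mean = 0),
               "rest_duration_mean")
})

test_that("trajectories are seed-deterministic and respect the speed bound", {
  cfg <- sim_config(4, two_site, duration = 6 * 3600, rest_duration_mean = 1800,
                    step = 60, seed = 5)
  t1 <- simulate_trajectories(cfg)
  t2 <- simulate_trajectories(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  expect_identical(t1$site, t2$site)
  # per-step displacement bounded by travel_speed * step (+ tiny slack)
  disp <- sqrt(diff(t1$x)^2 + diff(t1$y)^2)
  expect_lte(max(disp), cfg$travel_speed * cfg$step + 1e-9)
  expect_true(all(is.finite(t1$x)))
  # duration 0 -> empty trajectories
  t0 <- simulate_trajectories(sim_config(4, two_site, duration = 0, seed = 1))
  expect_equal(nrow(t0$x), 0)
})

test_that("social site choice pulls preferred partners together", {
  pref <- matrix(c(0, 1, 1, 0), 2, 2)
  base <- list(n_individuals = 2, site_positions = rbind(c(0, 0), c(300, 0), c(0, 300)),
               duration = 2 * 86400, rest_duration_mean = 1800, step = 60)
  frac_close <- function(p_social, seed) {
    cfg <- do.call(sim_config, c(base, list(
      preference_matrix = pref, p_social = p_social, seed = seed)))
    tr <- simulate_trajectories(cfg)
    # independent pairwise-distance computation straight from positions
    d <- sqrt((tr$x[, 1] - tr$x[, 2])^2 + (tr$y[, 1] - tr$y[, 2])^2)
    mean(d <= cfg$contact_radius)
  }
  soc <- mean(vapply(1:4, function(s) frac_close(1, s), numeric(1)))
  lone <- mean(vapply(1:4, function(s) frac_close(0, s + 100), numeric(1)))
  expect_gt(soc, lone)
})

test_that("ping generation matches the delay arithmetic", {
  cfg <- sim_config(20, two_site, duration = 600, nominal_delay = 90,
                    delay_jitter = 0, seed = 11)
  pings <- generate_pings(simulate_trajectories(cfg), cfg)
  counts <- table(pings$individual_id)
  expect_true(all(counts %in% c(6, 7)))   # never fewer than six per 10-min bin
  # delay equal to duration -> at most one ping
  cfg1 <- sim_config(5, two_site, duration = 90, nominal_delay = 90, seed = 2)
  p1 <- generate_pings(simulate_trajectories(cfg1), cfg1)
  expect_true(all(table(p1$individual_id) <= 1))
  # jittered intervals: mean ~ nominal over many intervals
  cfgj <- sim_config(2, two_site, duration = 500000, nominal_delay = 90,
                     delay_jitter = 0.33, seed = 3)
  pj <- generate_pings(simulate_trajectories(cfgj), cfgj)
  ivl <- diff(pj$time[pj$individual_id == pj$individual_id[1]])
  ivl <- ivl[ivl > 1]  # guard against interleaving artifacts
  expect_gt(length(ivl), 5000)
  expect_lt(abs(mean(ivl) - 90), 2)
})

test_that("detections respect range, hosts and the step model", {
  # one individual resting tightly at (0,0); site 2 is 500 m away
  sites <- rbind(c(0, 0), c(500, 0))
  cfg <- sim_config(2, sites, duration = 4 * 3600, rest_duration_mean = 1e9,
                    site_scatter_sd = 0, step = 60, seed = 8)
  tr <- simulate_trajectories(cfg)
  # force known start sites: regenerate until ID01 rests at site 1
  stopifnot(any(tr$site[1, ] == 1))
  i1 <- which(tr$site[1, ] == 1)[1]
  id1 <- cfg$individual_ids[i1]
  pings <- generate_pings(tr, cfg)
  rec <- receiver_table(c("NEAR10", "FAR400"), "fixed", c(10, 400),
                        x = c(1, 5000), y = c(0, 0))
  det <- simulate_detections(pings, tr, rec, cfg)
  # 1 m from a 10 m receiver: every ping of the resident detected
  expect_equal(sum(det$receiver_id == "NEAR10" & det$individual_id == id1),
               sum(pings$individual_id == id1))
  # receiver 5 km away never detects anything
  expect_equal(sum(det$receiver_id == "FAR400"), 0)
  # mobile receiver: never records its own host
  mob <- receiver_table("PROX", "mobile", 4, host_individual = id1)
  detm <- simulate_detections(pings, tr, mob, cfg)
  expect_false(any(detm$individual_id == id1))
  ghost <- receiver_table("PROX2", "mobile", 4, host_individual = "NOPE")
  expect_error(simulate_detections(pings, tr, ghost, cfg), "without a trajectory")
})

test_that("logistic detection probability at the midpoint is p_det_inside / 2", {
  sites <- rbind(c(0, 0))
  cfg <- sim_config(1, sites, duration = 10000 * 90, rest_duration_mean = 1e12,
                    site_scatter_sd = 0, detection_model = "logistic",
                    logistic_midpoint_fraction = 0.8, logistic_steepness = 12,
                    p_det_inside = 1, seed = 17)
  tr <- simulate_trajectories(cfg)
  pings <- generate_pings(tr, cfg)
  expect_gte(nrow(pings), 9999)
  # receiver placed so the sender sits exactly at midpoint_fraction * radius
  rec <- receiver_table("L", "fixed", 100, x = 80, y = 0)
  det <- simulate_detections(pings, tr, rec, cfg)
  expect_lt(abs(nrow(det) / nrow(pings) - 0.5), 0.02)
})

test_that("ground-truth association matrix reproduces the contact definitions", {
  # two individuals pinned together, third far away
  cfg <- sim_config(2, rbind(c(0, 0)), duration = 6 * 3600,
                    rest_duration_mean = 1e12, site_scatter_sd = 0, seed = 4)
  tr <- simulate_trajectories(cfg)
  led <- true_contact_ledger(tr)
  m <- true_association_matrix(led)
  expect_equal(m["ID01", "ID02"], 1)     # always within contact radius
  cfg2 <- sim_config(2, rbind(c(0, 0), c(1000, 0)), duration = 6 * 3600,
                     rest_duration_mean = 1e12, site_scatter_sd = 0, seed = 23)
  tr2 <- simulate_trajectories(cfg2)
  if (tr2$site[1, 1] != tr2$site[1, 2]) {
    m2 <- true_association_matrix(true_contact_ledger(tr2))
    expect_equal(m2["ID01", "ID02"], 0)  # never within 10x the radius
  }
})

test_that("chain rule merges contact components transitively", {
  led <- structure(data.frame(time = c(0, 0), a = c("A", "B"), b = c("B", "C"),
                              stringsAsFactors = FALSE),
                   ids = c("A", "B", "C"), duration = 600,
                   origin = EPOCH, class = c("contact_ledger", "data.frame"))
  m <- true_association_matrix(led, bin_width = 600, period_width = 600)
  expect_equal(m["A", "C"], 1)   # one group {A,B,C} under transitive closure
  mp <- true_association_matrix(led, bin_width = 600, period_width = 600,
                                chain = FALSE)
  expect_equal(mp["A", "C"], 0)  # pairwise-only alternative
  expect_equal(mp["A", "B"], 1)
})
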