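# Agent-based generator of the study system: individuals alternate
# exponential-duration rest bouts at discrete sites (reef gutters) with
# straight-line travel between sites; site choice is social with
# probability p_social (move to the current site of a partner sampled
# proportionally to preference weights) and uniform otherwise. Tags emit
# pings on a nominal delay; fixed and animal-borne receivers record pings
# within a detection radius (sharp or logistic edge). The true contact
# network (dyads within contact_radius) is logged per step so inferred
# networks can be validated against ground truth.

#' Simulation configuration
#'
#' Defaults describe a benthic reef aggregation: ~6 h rest bouts, ~3 m
#' scatter of resting spots around a site, 0.5 m/s travel, 90 s nominal tag
#' delay and a 4 m contact scale (two to three body lengths of a ~1.2 m
#' shark).
#'
#' @param n_individuals number of tagged individuals.
#' @param site_positions numeric matrix (n_sites x 2) of site centres, metres.
#' @param duration simulated time span, seconds.
#' @param preference_matrix symmetric non-negative dyadic weights with zero
#'   diagonal (true sociality); default all-zero (no preferences).
#' @param p_social probability that a bout ends with a move to a partner's
#'   site; individuals with all-zero preference rows always choose uniformly.
#' @param rest_duration_mean mean of the exponential rest-bout length, s.
#' @param site_scatter_sd isotropic Gaussian sd of the resting spot around
#'   the site centre, metres.
#' @param travel_speed metres per second.
#' @param step trajectory time step, seconds.
#' @param nominal_delay nominal inter-ping interval, seconds (tag delay).
#' @param delay_jitter fraction in \[0,1): ping intervals uniform on
#'   `nominal_delay * (1 +/- delay_jitter)`; 0 = fixed delay.
#' @param contact_radius true-contact distance, metres.
#' @param detection_model `"step"` (detect iff distance <= radius) or
#'   `"logistic"`.
#' @param logistic_midpoint_fraction,logistic_steepness logistic edge shape:
#'   detection probability
#'   `p_det_inside / (1 + exp(steepness * (d/radius - midpoint)))`.
#' @param p_det_inside detection probability inside range (step model) or
#'   plateau (logistic).
#' @param individual_ids optional character ids (default ID01, ID02, ...).
#' @param origin POSIXct study start (detection timestamps are
#'   `origin + t`); defaults to 2012-08-25 00:00:00 UTC.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals, site_positions, duration,
                       preference_matrix = NULL, p_social = 0,
                       rest_duration_mean = 21600, site_scatter_sd = 3,
                       travel_speed = 0.5, step = 60,
                       nominal_delay = 90, delay_jitter = 0,
                       contact_radius = 4,
                       detection_model = c("step", "logistic"),
                       logistic_midpoint_fraction = 1,
                       logistic_steepness = 10,
                       p_det_inside = 1,
                       individual_ids = NULL,
                       origin = as.POSIXct("2012-08-25 00:00:00", tz = "UTC"),
                       seed = NULL) {
  detection_model <- match.arg(detection_model)
  if (!is_count(n_individuals) || n_individuals < 1) stop_fmt("n_individuals must be >= 1")
  site_positions <- as.matrix(site_positions)
  if (nrow(site_positions) == 0L) stop_fmt("at least one site is required")
  if (ncol(site_positions) != 2L || !all(is.finite(site_positions))) {
    stop_fmt("site_positions must be a finite n_sites x 2 matrix")
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0) {
    stop_fmt("duration must be >= 0")
  }
  if (is.null(preference_matrix)) {
    preference_matrix <- matrix(0, n_individuals, n_individuals)
  }
  preference_matrix <- as.matrix(preference_matrix)
  if (!all(dim(preference_matrix) == n_individuals) ||
      any(preference_matrix < 0) ||
      max(abs(preference_matrix - t(preference_matrix))) > 1e-12 ||
      any(diag(preference_matrix) != 0)) {
    stop_fmt("preference_matrix must be symmetric, non-negative, zero-diagonal, n x n")
  }
  stopifnot(p_social >= 0, p_social <= 1,
            delay_jitter >= 0, delay_jitter < 1,
            p_det_inside >= 0, p_det_inside <= 1)
  for (nm in c("rest_duration_mean", "site_scatter_sd", "travel_speed", "step",
               "nominal_delay", "contact_radius")) {
    v <- get(nm)
    if (!is_pos_num(v) && !(nm == "site_scatter_sd" && v == 0)) {
      stop_fmt("%s must be > 0", nm)
    }
  }
  ids <- individual_ids %||% sprintf("ID%02d", seq_len(n_individuals))
  if (length(ids) != n_individuals || anyDuplicated(ids)) {
    stop_fmt("individual_ids must be %d unique ids", n_individuals)
  }
  structure(list(n_individuals = n_individuals, site_positions = site_positions,
                 n_sites = nrow(site_positions), duration = duration,
                 preference_matrix = preference_matrix, p_social = p_social,
                 rest_duration_mean = rest_duration_mean,
                 site_scatter_sd = site_scatter_sd, travel_speed = travel_speed,
                 step = step, nominal_delay = nominal_delay,
                 delay_jitter = delay_jitter, contact_radius = contact_radius,
                 detection_model = detection_model,
                 logistic_midpoint_fraction = logistic_midpoint_fraction,
                 logistic_steepness = logistic_steepness,
                 p_det_inside = p_det_inside,
                 individual_ids = as.character(ids), origin = origin,
                 seed = seed),
            class = "sim_config")
}

#' Simulate rest/travel trajectories
#'
#' Each individual alternates exponential rest bouts at a site (position =
#' site centre + isotropic Gaussian scatter, fixed for the bout) with
#' straight-line travel at `travel_speed` to the next site. Fully
#' reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return object of class `trajectories`: matrices `x`, `y` (steps x
#'   individuals), integer matrix `site` (0 while travelling), the step
#'   times and ids.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  n_steps <- floor(config$duration / config$step)
  ids <- config$individual_ids
  X <- matrix(NA_real_, n_steps, n, dimnames = list(NULL, ids))
  Y <- X
  S <- matrix(0L, n_steps, n, dimnames = list(NULL, ids))
  if (n_steps == 0L) {
    return(structure(list(x = X, y = Y, site = S, times = numeric(0),
                          ids = ids, config = config), class = "trajectories"))
  }
  with_seed(stage_seed(config$seed, "trajectories"), {
    sites <- config$site_positions
    pref <- config$preference_matrix
    social <- rowSums(pref) > 0
    site <- sample.int(config$n_sites, n, replace = TRUE)
    tx <- sites[site, 1L] + stats::rnorm(n, 0, config$site_scatter_sd)
    ty <- sites[site, 2L] + stats::rnorm(n, 0, config$site_scatter_sd)
    px <- tx; py <- ty
    resting <- rep(TRUE, n)
    rest_end <- stats::rexp(n, 1 / config$rest_duration_mean)
    dmax <- config$travel_speed * config$step
    pick_site <- function(i) {
      if (social[i] && stats::runif(1) < config$p_social) {
        j <- sample.int(n, 1L, prob = pref[i, ])
        site[j]          # partner's current site (destination while travelling)
      } else {
        sample.int(config$n_sites, 1L)
      }
    }
    for (k in seq_len(n_steps)) {
      t_now <- (k - 1) * config$step
      # bout ends
      enders <- which(resting & t_now >= rest_end)
      for (i in enders) {
        nxt <- pick_site(i)
        site[i] <- nxt
        tx[i] <- sites[nxt, 1L] + stats::rnorm(1, 0, config$site_scatter_sd)
        ty[i] <- sites[nxt, 2L] + stats::rnorm(1, 0, config$site_scatter_sd)
        if (sqrt((tx[i] - px[i])^2 + (ty[i] - py[i])^2) <= dmax) {
          px[i] <- tx[i]; py[i] <- ty[i]
          rest_end[i] <- t_now + stats::rexp(1, 1 / config$rest_duration_mean)
        } else {
          resting[i] <- FALSE
        }
      }
      # advance travellers
      mov <- which(!resting)
      if (length(mov)) {
        dx <- tx[mov] - px[mov]; dy <- ty[mov] - py[mov]
        dd <- sqrt(dx^2 + dy^2)
        arrive <- dd <= dmax
        ia <- mov[arrive]
        px[ia] <- tx[ia]; py[ia] <- ty[ia]
        resting[ia] <- TRUE
        if (length(ia)) {
          rest_end[ia] <- t_now + stats::rexp(length(ia), 1 / config$rest_duration_mean)
        }
        im <- mov[!arrive]
        if (length(im)) {
          f <- dmax / dd[!arrive]
          px[im] <- px[im] + dx[!arrive] * f
          py[im] <- py[im] + dy[!arrive] * f
        }
      }
      X[k, ] <- px; Y[k, ] <- py
      S[k, ] <- ifelse(resting, site, 0L)
    }
  })
  structure(list(x = X, y = Y, site = S,
                 times = (seq_len(n_steps) - 1) * config$step,
                 ids = ids, config = config),
            class = "trajectories")
}

#' Generate tag ping events
#'
#' Per individual: the first ping at `U(0, first interval)` after the start,
#' then i.i.d. intervals — fixed at `nominal_delay` when `delay_jitter` is
#' 0, else uniform on `nominal_delay * (1 +/- delay_jitter)`.
#'
#' @param trajectories a `trajectories` object.
#' @param config the [sim_config()] (defaults to the trajectories' config).
#' @return data.frame of class `ping_events` with `individual_id` and `time`
#'   (seconds from study start), sorted by time; attribute `origin`.
#' @export
generate_pings <- function(trajectories, config = trajectories$config) {
  stopifnot(inherits(trajectories, "trajectories"), inherits(config, "sim_config"))
  if (!length(trajectories$times)) stop_fmt("trajectories are empty")
  dur <- config$duration
  out <- with_seed(stage_seed(config$seed, "pings"), {
    lapply(config$individual_ids, function(id) {
      lo <- config$nominal_delay * (1 - config$delay_jitter)
      hi <- config$nominal_delay * (1 + config$delay_jitter)
      m <- ceiling(dur / lo) + 2L
      ivl <- if (config$delay_jitter == 0) rep(config$nominal_delay, m) else
        stats::runif(m, lo, hi)
      t0 <- stats::runif(1, 0, ivl[1L])
      times <- t0 + c(0, cumsum(ivl[-1L]))
      data.frame(individual_id = id, time = times[times < dur],
                 stringsAsFactors = FALSE)
    })
  })
  df <- do.call(rbind, out)
  df <- df[order(df$time, df$individual_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, origin = config$origin, class = c("ping_events", "data.frame"))
}

#' Simulate range-dependent detections
#'
#' A ping is recorded by a receiver with probability `p_det_inside` if the
#' sender is within `detection_radius` (step model), or with the logistic
#' edge probability otherwise configured. Animal-borne receivers sit at
#' their host's position and never record the host's own pings.
#'
#' @param pings a `ping_events` data.frame.
#' @param trajectories the matching `trajectories`.
#' @param receivers validated receiver metadata (see [read_receivers()] /
#'   [receiver_table()]).
#' @param config the [sim_config()].
#' @return a `detections` data.frame (time POSIXct UTC, receiver_id,
#'   individual_id), time-sorted.
#' @export
simulate_detections <- function(pings, trajectories, receivers,
                                config = trajectories$config) {
  stopifnot(inherits(trajectories, "trajectories"))
  receivers <- validate_receivers(as.data.frame(receivers))
  ids <- trajectories$ids
  miss <- setdiff(unique(pings$individual_id), ids)
  if (length(miss)) stop_fmt("ping sender(s) without a trajectory: %s",
                             paste(miss, collapse = ", "))
  hosts <- receivers$host_individual[receivers$kind == "mobile"]
  miss <- setdiff(hosts, ids)
  if (length(miss)) stop_fmt("mobile receiver host(s) without a trajectory: %s",
                             paste(miss, collapse = ", "))
  n_steps <- length(trajectories$times)
  idx <- pmin(pmax(floor(pings$time / config$step) + 1L, 1L), n_steps)
  si <- match(pings$individual_id, ids)
  sx <- trajectories$x[cbind(idx, si)]
  sy <- trajectories$y[cbind(idx, si)]
  res <- with_seed(stage_seed(config$seed, "detections"), {
    lapply(seq_len(nrow(receivers)), function(r) {
      if (receivers$kind[r] == "fixed") {
        rx <- receivers$x[r]; ry <- receivers$y[r]
        keepable <- rep(TRUE, nrow(pings))
      } else {
        hi <- match(receivers$host_individual[r], ids)
        rx <- trajectories$x[cbind(idx, rep(hi, length(idx)))]
        ry <- trajectories$y[cbind(idx, rep(hi, length(idx)))]
        keepable <- si != hi
      }
      d <- sqrt((sx - rx)^2 + (sy - ry)^2)
      p <- if (config$detection_model == "step") {
        config$p_det_inside * (d <= receivers$detection_radius[r])
      } else {
        config$p_det_inside /
          (1 + exp(config$logistic_steepness *
                     (d / receivers$detection_radius[r] -
                        config$logistic_midpoint_fraction)))
      }
      keep <- keepable & stats::runif(length(d)) < p
      data.frame(time = pings$time[keep],
                 receiver_id = rep(receivers$receiver_id[r], sum(keep)),
                 individual_id = pings$individual_id[keep],
                 stringsAsFactors = FALSE)
    })
  })
  det <- do.call(rbind, res)
  det$time <- config$origin + det$time
  as_detections(det)
}

#' Build a receiver metadata table in code
#'
#' @param receiver_id,kind,x,y,detection_radius,host_individual parallel
#'   vectors; see [read_receivers()] for semantics.
#' @return validated receiver data.frame.
#' @export
receiver_table <- function(receiver_id, kind, detection_radius,
                           x = NA_real_, y = NA_real_,
                           host_individual = NA_character_) {
  df <- data.frame(receiver_id = as.character(receiver_id),
                   kind = as.character(kind),
                   x = as.numeric(x), y = as.numeric(y),
                   detection_radius = as.numeric(detection_radius),
                   host_individual = as.character(host_individual),
                   stringsAsFactors = FALSE)
  df$host_individual[is.na(df$host_individual)] <- ""
  validate_receivers(df)
}

#' Ground-truth contact ledger
#'
#' All unordered dyads at Euclidean distance <= `contact_radius`, per
#' trajectory step.
#' @param trajectories a `trajectories` object.
#' @param contact_radius metres (default from the config).
#' @return data.frame of class `contact_ledger` with `time` (seconds),
#'   `a`, `b` (ids, a < b); attributes `ids`, `duration`, `period_origin`.
#' @export
true_contact_ledger <- function(trajectories,
                                contact_radius = trajectories$config$contact_radius) {
  stopifnot(inherits(trajectories, "trajectories"))
  ids <- trajectories$ids
  n <- length(ids)
  r2 <- contact_radius^2
  rows <- list()
  k <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d2 <- (trajectories$x[, i] - trajectories$x[, j])^2 +
          (trajectories$y[, i] - trajectories$y[, j])^2
        hit <- which(d2 <= r2)
        if (length(hit)) {
          k <- k + 1L
          rows[[k]] <- data.frame(time = trajectories$times[hit],
                                  a = ids[i], b = ids[j],
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  led <- if (k) do.call(rbind, rows) else
    data.frame(time = numeric(0), a = character(0), b = character(0))
  led <- led[order(led$time, led$a, led$b), , drop = FALSE]
  rownames(led) <- NULL
  structure(led, ids = ids, duration = trajectories$config$duration,
            origin = trajectories$config$origin,
            class = c("contact_ledger", "data.frame"))
}

# minimal union-find for per-step contact components
uf_components <- function(ids, a, b) {
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_along(ids), find, integer(1L))
}

#' Ground-truth association matrix
#'
#' Converts the contact ledger to groups (transitive closure of the contact
#' relation per time step by default, so a chain A-B, B-C forms one group
#' \{A,B,C\}), then bins, aggregates and scores them through the same
#' grouping/association pipeline as observed data. Every individual counts
#' as observed in every period (perfect knowledge), so the index reduces to
#' the fraction of periods with at least one true contact.
#'
#' @param ledger a `contact_ledger`.
#' @param bin_width,period_width seconds (defaults 600 / 3600).
#' @param chain if FALSE, use pairwise dyad groups instead of transitive
#'   closure.
#' @return an `association_matrix` over all simulated individuals.
#' @export
true_association_matrix <- function(ledger, bin_width = 600,
                                    period_width = 3600, chain = TRUE) {
  stopifnot(inherits(ledger, "contact_ledger"))
  ids <- attr(ledger, "ids")
  origin_s <- as.numeric(attr(ledger, "origin"))
  duration <- attr(ledger, "duration")
  n_periods <- max(1L, ceiling(duration / period_width))
  period_starts <- origin_s + (seq_len(n_periods) - 1L) * period_width
  grp_members <- list(); grp_bin <- numeric(0)
  if (nrow(ledger)) {
    by_step <- split(seq_len(nrow(ledger)), ledger$time)
    for (rows in by_step) {
      t_abs <- origin_s + ledger$time[rows[1L]]
      bin <- floor(t_abs / bin_width) * bin_width
      if (chain) {
        comp <- uf_components(ids, match(ledger$a[rows], ids),
                              match(ledger$b[rows], ids))
        touched <- unique(c(match(ledger$a[rows], ids), match(ledger$b[rows], ids)))
        for (cc in unique(comp[touched])) {
          mem <- ids[touched[comp[touched] == cc]]
          grp_members <- c(grp_members, list(sort(mem)))
          grp_bin <- c(grp_bin, bin)
        }
      } else {
        for (r in rows) {
          grp_members <- c(grp_members, list(c(ledger$a[r], ledger$b[r])))
          grp_bin <- c(grp_bin, bin)
        }
      }
    }
  }
  # perfect observation: one singleton per individual per period
  single_members <- rep(as.list(ids), each = 1L, times = n_periods)
  single_bin <- rep(period_starts, each = length(ids))
  df <- data.frame(receiver_id = "truth",
                   bin_start = as.POSIXct(c(grp_bin, single_bin),
                                          origin = "1970-01-01", tz = "UTC"),
                   stringsAsFactors = FALSE)
  df$members <- c(grp_members, single_members)
  groups <- as_group_table(df, bin_width = bin_width)
  periods <- collapse_to_periods(groups, period_width)
  simple_ratio_index(dyad_counts(periods, individuals = ids),
                     provenance = list(network = "truth",
                                       contact_radius = "ledger",
                                       chain = chain))
}
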