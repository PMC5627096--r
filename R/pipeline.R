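# Configuration-driven end-to-end runs: simulate (or load) detections,
# build one association network per receiver subset, test each for
# non-random associations, and run all configured pairwise comparisons
# (Mantel + rank consistency), emitting a report in the layout
# year_label, comparison, mantel_r, mantel_p, sv_o, sv_r_mean, sv_r_lo,
# sv_r_hi, sv_p.

#' Scenario preset: one season at a mating aggregation
#'
#' Fifteen individuals over a 47-day window; two social blocks of five
#' (preference weight 1 within block, p_social 0.8) and five solitary
#' individuals; six reef "gutter" sites within ~150 m of the main receiver
#' plus two distant reefs outside its range. Receivers mirror the deployed
#' array: one fixed 400 m receiver at the main reef, two fixed 10 m
#' receivers at gutters inside its range, and one 4 m animal-borne
#' proximity logger on the first individual (its host is excluded from the
#' proximity network).
#'
#' @param duration_days simulated span (default 47).
#' @param seed master seed.
#' @param ... overrides forwarded to [sim_config()].
#' @return list of class `scenario`: `config`, `receivers`, `individuals`,
#'   `networks`, `comparisons`, `window`, `host`.
#' @export
preset_jervis2012 <- function(duration_days = 47, seed = NULL, ...) {
  ids <- sprintf("PJ%02d", 1:15)
  pref <- matrix(0, 15, 15, dimnames = list(ids, ids))
  pref[1:5, 1:5] <- 1
  pref[6:10, 6:10] <- 1
  diag(pref) <- 0
  sites <- rbind(c(0, 0), c(40, 25), c(-50, 60), c(80, -40), c(-30, -70),
                 c(120, 60),              # gutters at the main reef
                 c(900, 0), c(-800, -300)) # distant reefs, outside 400 m
  origin <- as.POSIXct("2012-08-25 00:00:00", tz = "UTC")
  cfg_args <- utils::modifyList(
    list(n_individuals = 15, site_positions = sites,
         duration = duration_days * 86400,
         preference_matrix = pref, p_social = 0.8,
         individual_ids = ids, origin = origin, seed = seed),
    list(...))
  config <- do.call(sim_config, cfg_args)
  receivers <- receiver_table(
    receiver_id = c("VR2W-1", "SUR-1", "SUR-2", "PROX-1"),
    kind = c("fixed", "fixed", "fixed", "mobile"),
    detection_radius = c(400, 10, 10, 4),
    x = c(0, 0, 40, NA), y = c(0, 0, 25, NA),
    host_individual = c(NA, NA, NA, "PJ01"))
  individuals <- data.frame(individual_id = ids,
                            sex = rep(c("F", "M"), length.out = 15),
                            total_length_cm = round(seq(90, 125, length.out = 15)),
                            stringsAsFactors = FALSE)
  networks <- list(
    network_def("VR2W",  "VR2W-1"),
    network_def("SUR-10m", c("SUR-1", "SUR-2")),
    network_def("Proxi", "PROX-1"),
    network_def("Proxi-restricted", "PROX-1", reference = "VR2W-1"))
  comparisons <- list(c("Proxi", "SUR-10m"),
                      c("Proxi", "VR2W"),
                      c("SUR-10m", "VR2W"),
                      c("Proxi", "Proxi-restricted"),
                      c("SUR-10m", "Proxi-restricted"))
  structure(list(config = config, receivers = receivers,
                 individuals = individuals, networks = networks,
                 comparisons = comparisons,
                 window = study_window(origin, origin + duration_days * 86400),
                 host = "PJ01"),
            class = "scenario")
}

#' Define a network by its receiver subset
#'
#' @param name network label.
#' @param receivers receiver ids contributing per-receiver groups.
#' @param reference optional fixed receiver id: keep only groups with a
#'   member detected by this receiver within tolerance (proximity-logger
#'   restriction).
#' @param member_rule,tolerance forwarded to
#'   [restrict_proximity_groups()].
#' @return list of class `network_def`.
#' @export
network_def <- function(name, receivers, reference = NULL,
                        member_rule = "any", tolerance = 600) {
  stopifnot(is.character(name), length(receivers) >= 1L)
  structure(list(name = name, receivers = as.character(receivers),
                 reference = reference, member_rule = member_rule,
                 tolerance = tolerance),
            class = "network_def")
}

#' Build one association network from detections
#'
#' Composition of the inference pipeline for a receiver subset: window
#' filter, per-receiver 10-min binning, host exclusion for animal-borne
#' receivers, optional restriction to a reference receiver's coverage,
#' hourly aggregation, dyad counts, simple ratio index. Deterministic given
#' its inputs; provenance is recorded on the matrix, and the sampling-period
#' group data is attached (attribute `periods`) for downstream permutation
#' tests.
#'
#' @param detections detections data.frame.
#' @param receivers validated receiver metadata.
#' @param network a [network_def()].
#' @param window optional [study_window()].
#' @param bin_width,period_width seconds (defaults 600 / 3600).
#' @param individuals optional individual index for the matrix.
#' @return an `association_matrix`.
#' @export
build_network <- function(detections, receivers, network, window = NULL,
                          bin_width = 600, period_width = 3600,
                          individuals = NULL) {
  stopifnot(inherits(network, "network_def"))
  if (!is.null(window)) detections <- filter_window(detections, window)
  miss <- setdiff(network$receivers, receivers$receiver_id)
  if (length(miss)) stop_fmt("network %s references unknown receiver(s): %s",
                             network$name, paste(miss, collapse = ", "))
  sub <- detections[detections$receiver_id %in% network$receivers, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop_fmt("network %s: no detections after filtering (window and receiver subset)",
             network$name)
  }
  groups <- bin_detections(sub, bin_width = bin_width)
  hosts <- receivers$host_individual[receivers$kind == "mobile" &
                                       receivers$receiver_id %in% network$receivers]
  for (h in hosts[!is.na(hosts)]) groups <- exclude_individual(groups, h)
  if (!is.null(network$reference)) {
    ref <- detections[detections$receiver_id == network$reference, , drop = FALSE]
    groups <- restrict_proximity_groups(groups, ref,
                                        tolerance = network$tolerance,
                                        member_rule = network$member_rule)
  }
  if (nrow(groups) == 0L) {
    stop_fmt("network %s: no groups after restriction", network$name)
  }
  periods <- collapse_to_periods(groups, period_width)
  counts <- dyad_counts(periods, individuals = individuals)
  m <- simple_ratio_index(counts,
                          provenance = list(network = network$name,
                                            receivers = network$receivers,
                                            reference = network$reference,
                                            bin_width = bin_width,
                                            period_width = period_width))
  attr(m, "periods") <- periods
  m
}

#' Run a full comparison study
#'
#' Simulates (or accepts) detections, builds every configured network on
#' the common window, runs mean/CV non-randomness tests per network and
#' Mantel + rank-consistency tests per comparison (networks aligned to
#' common individuals pairwise). Comparisons with fewer than 3 common
#' individuals are reported as unavailable and the run continues.
#'
#' @param scenario a `scenario` (e.g. [preset_jervis2012()]).
#' @param detections optional detections (skips simulation).
#' @param n_perm_null permutations for the per-network mean/CV tests.
#' @param n_perm_mantel Mantel permutations (default 999).
#' @param n_perm_consistency SV_R randomizations (default 10000).
#' @param seed master seed; stage seeds are derived from it (falls back to
#'   the scenario config's seed).
#' @param out_dir optional directory: writes `report.tsv`, `networks.tsv`
#'   and a readable `report.txt`.
#' @param year_label label for the report rows (default "sim").
#' @return list of class `study_report`: data.frames `networks` and
#'   `comparisons`, plus `matrices` and provenance.
#' @export
run_comparison_study <- function(scenario, detections = NULL,
                                 n_perm_null = 1000, n_perm_mantel = 999,
                                 n_perm_consistency = 10000,
                                 seed = scenario$config$seed,
                                 out_dir = NULL, year_label = "sim") {
  stopifnot(inherits(scenario, "scenario"))
  cfg <- scenario$config
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(detections)) {
    traj <- simulate_trajectories(cfg)
    pings <- generate_pings(traj, cfg)
    detections <- simulate_detections(pings, traj, scenario$receivers, cfg)
  }
  detections <- filter_window(detections, scenario$window)
  mats <- list()
  net_rows <- list()
  for (nd in scenario$networks) {
    m <- build_network(detections, scenario$receivers, nd,
                       window = scenario$window)
    mats[[nd$name]] <- m
    periods <- attr(m, "periods")
    nulls <- permuted_null_stream(periods, n_permutations = n_perm_null,
                                  seed = stage_seed(seed, paste0("null:", nd$name)))
    net_rows[[nd$name]] <- data.frame(
      network = nd$name,
      n_individuals = nrow(m),
      n_groups = nrow(periods),
      n_periods = length(unique(periods$period_start)),
      mean_obs = nulls$mean$observed, mean_p = nulls$mean$p,
      cv_obs = nulls$cv$observed, cv_p = nulls$cv$p,
      stringsAsFactors = FALSE)
  }
  cmp_rows <- list()
  for (cmp in scenario$comparisons) {
    label <- paste(cmp, collapse = " vs ")
    row <- data.frame(year_label = year_label, comparison = label,
                      mantel_r = NA_real_, mantel_p = NA_real_,
                      sv_o = NA_real_, sv_r_mean = NA_real_,
                      sv_r_lo = NA_real_, sv_r_hi = NA_real_,
                      sv_p = NA_real_, n_common = NA_integer_,
                      status = "ok", stringsAsFactors = FALSE)
    m1 <- mats[[cmp[1L]]]; m2 <- mats[[cmp[2L]]]
    if (is.null(m1) || is.null(m2)) stop_fmt("comparison references undefined network: %s", label)
    common <- intersect(rownames(m1), rownames(m2))
    row$n_common <- length(common)
    if (length(common) < 3L) {
      row$status <- "unavailable: <3 common individuals"
      cmp_rows[[label]] <- row
      next
    }
    al <- align_individuals(list(m1, m2))
    mt <- tryCatch(
      mantel_test(al[[1L]], al[[2L]], n_permutations = n_perm_mantel,
                  seed = stage_seed(seed, paste0("mantel:", label))),
      error = function(e) e)
    if (inherits(mt, "error")) {
      row$status <- paste("mantel unavailable:", conditionMessage(mt))
    } else {
      row$mantel_r <- mt$r; row$mantel_p <- mt$p
    }
    ct <- consistency_test(attr(m1, "periods"), attr(m2, "periods"),
                           n_permutations = n_perm_consistency,
                           seed = stage_seed(seed, paste0("sv:", label)))
    row$sv_o <- ct$sv_observed; row$sv_r_mean <- ct$null_mean
    row$sv_r_lo <- ct$null_lo; row$sv_r_hi <- ct$null_hi; row$sv_p <- ct$p
    cmp_rows[[label]] <- row
  }
  report <- structure(list(networks = do.call(rbind, c(net_rows, list(make.row.names = FALSE))),
                           comparisons = do.call(rbind, c(cmp_rows, list(make.row.names = FALSE))),
                           matrices = mats, seed = seed,
                           scenario = scenario),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("networks:\n")
  print(x$networks, digits = 3, row.names = FALSE)
  cat("\ncomparisons:\n")
  print(x$comparisons[, c("comparison", "mantel_r", "mantel_p", "sv_o",
                          "sv_r_mean", "sv_p", "status")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' `report.tsv` carries the machine-readable comparison rows (add-one
#' p-values), `networks.tsv` the per-network summaries, and `report.txt` a
#' readable rendering with the display convention p < 1/(n+1) shown as
#' "0.000".
#' @param report a `study_report`.
#' @param out_dir output directory (created if needed).
#' @return out_dir, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$comparisons, file.path(out_dir, "report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$networks, file.path(out_dir, "networks.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Export upper-triangle heat maps of aligned association matrices
#'
#' One PNG per matrix, identical individual order and a shared colour scale
#' across files; the lower triangle and diagonal are blanked.
#' @param matrices named list of `association_matrix` objects.
#' @param path output directory.
#' @param width,height device size in pixels.
#' @return character vector of written file paths, invisibly.
#' @export
export_heatmaps <- function(matrices, path, width = 600, height = 600) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  if (length(matrices) >= 2L &&
      !all(vapply(matrices[-1L], function(m)
        identical(rownames(m), rownames(matrices[[1L]])), logical(1L)))) {
    message("aligning matrices to their common individuals before export")
    matrices <- stats::setNames(align_individuals(matrices), names(matrices))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  zmax <- max(1e-9, vapply(matrices, function(m) max(upper_vec(unclass(m))), numeric(1L)))
  nm <- names(matrices) %||% sprintf("matrix%02d", seq_along(matrices))
  files <- character(length(matrices))
  cols <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  for (i in seq_along(matrices)) {
    m <- unclass(matrices[[i]])
    m[lower.tri(m, diag = TRUE)] <- NA
    files[i] <- file.path(path, paste0(gsub("[^A-Za-z0-9_-]+", "_", nm[i]), ".png"))
    grDevices::png(files[i], width = width, height = height)
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m, zlim = c(0, zmax),
                    col = cols, axes = FALSE, xlab = "", ylab = "",
                    main = nm[i])
    graphics::axis(1, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
    graphics::box()
    grDevices::dev.off()
  }
  invisible(files)
}

#' Read a flat key/value run configuration
#'
#' Lines of the form `key: value`; `#` starts a comment. Values are coerced
#' to numeric where possible; comma-separated values become vectors. Known
#' keys mirror the [sim_config()] and [run_comparison_study()] arguments
#' (e.g. `preset: jervis2012`, `duration_days`, `seed`, `p_social`,
#' `n_perm_consistency`).
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) stop_fmt("malformed config line: %s", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Build a scenario from a parsed run configuration
#'
#' Currently supports `preset: jervis2012` with scalar overrides
#' (`duration_days`, `seed`, `p_social`, `rest_duration_mean`,
#' `site_scatter_sd`, `travel_speed`, `step`, `nominal_delay`,
#' `delay_jitter`, `contact_radius`, `p_det_inside`).
#' @param cfg list from [read_run_config()].
#' @return a `scenario`.
#' @export
scenario_from_config <- function(cfg) {
  preset <- cfg$preset %||% "jervis2012"
  if (!identical(preset, "jervis2012")) stop_fmt("unknown preset: %s", preset)
  over <- cfg[intersect(names(cfg),
                        c("p_social", "rest_duration_mean", "site_scatter_sd",
                          "travel_speed", "step", "nominal_delay",
                          "delay_jitter", "contact_radius", "p_det_inside"))]
  do.call(preset_jervis2012,
          c(list(duration_days = cfg$duration_days %||% 47,
                 seed = cfg$seed %||% NULL),
            over))
}
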