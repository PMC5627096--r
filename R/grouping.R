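# Gambit-of-the-group construction: detections -> clock-aligned bins per
# receiver -> group observations -> hourly sampling periods, plus the
# window / host-exclusion / proximity-restriction filters applied to
# group data before association indices are computed.

#' Restrict detections to a study window
#'
#' Keeps records with `start <= time < end` (half-open); order preserved.
#' @param detections detections data.frame.
#' @param window a [study_window()].
#' @return filtered detections.
#' @export
filter_window <- function(detections, window) {
  stopifnot(inherits(window, "study_window"))
  keep <- detections$time >= window$start & detections$time < window$end
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Guaranteed transmissions per bin
#'
#' Number of complete nominal transmission intervals fitting in one bin:
#' `floor(bin_width / nominal_delay)`. With 10-min bins and a 90 s tag delay
#' every receiver has at least six detection opportunities per bin.
#' @param bin_width,nominal_delay seconds, both > 0.
#' @return integer count.
#' @export
bin_capacity <- function(bin_width, nominal_delay) {
  if (!is_pos_num(bin_width) || !is_pos_num(nominal_delay)) {
    stop_fmt("bin_capacity requires positive bin_width and nominal_delay")
  }
  as.integer(floor(bin_width / nominal_delay))
}

#' Bin detections into group observations
#'
#' Bins are clock-aligned half-open intervals `[k*width, (k+1)*width)`
#' counted from the epoch (so 10-min bins fall on :00, :10, ... as in
#' 0.00-0.09, 0.10-0.19). One group per (receiver, bin) holding the distinct
#' individuals detected there; singleton groups are retained — they carry
#' the "seen alone" information used by the simple ratio index denominator.
#'
#' @param detections detections data.frame (any row order).
#' @param bin_width bin width in seconds (default 600).
#' @param per_receiver if FALSE, individuals detected anywhere in a bin form
#'   one group (used for perfect-knowledge data; the default TRUE matches
#'   co-occurrence within a single receiver's detection range).
#' @return a `group_table`: data.frame with `receiver_id`, `bin_start`
#'   (POSIXct) and list-column `members`.
#' @export
bin_detections <- function(detections, bin_width = 600, per_receiver = TRUE) {
  if (!is_pos_num(bin_width)) stop_fmt("bin_width must be > 0")
  secs <- as.numeric(detections$time)
  bin <- floor(secs / bin_width) * bin_width
  rid <- if (per_receiver) detections$receiver_id else rep("*", length(secs))
  dt <- data.table::data.table(receiver_id = rid, bin = bin,
                               individual_id = detections$individual_id)
  g <- dt[, .(members = list(sort(unique(individual_id)))),
          by = .(receiver_id, bin)]
  data.table::setorder(g, receiver_id, bin)
  out <- data.frame(receiver_id = g$receiver_id,
                    bin_start = as.POSIXct(g$bin, origin = "1970-01-01", tz = "UTC"),
                    stringsAsFactors = FALSE)
  out$members <- g$members
  as_group_table(out, bin_width = bin_width)
}

as_group_table <- function(df, bin_width = NULL, period_width = NULL) {
  rownames(df) <- NULL
  structure(df,
            bin_width = bin_width,
            period_width = period_width,
            class = c(if (!is.null(period_width)) "period_table", "group_table",
                      "data.frame"))
}

#' Construct a group table directly
#'
#' Mostly for tests and for ground-truth group data that does not come from
#' binned detections.
#' @param receiver_id,bin_start,members parallel vectors/list.
#' @param bin_width optional bin width attribute (seconds).
#' @return a `group_table`.
#' @export
group_table <- function(receiver_id, bin_start, members, bin_width = NULL) {
  stopifnot(is.list(members))
  receiver_id <- rep_len(receiver_id, length(members))
  bin_start <- rep(bin_start, length.out = length(members))
  if (any(lengths(members) == 0L)) stop_fmt("groups must have at least one member")
  df <- data.frame(receiver_id = as.character(receiver_id),
                   bin_start = as.POSIXct(bin_start, tz = "UTC"),
                   stringsAsFactors = FALSE)
  df$members <- lapply(members, as.character)
  as_group_table(df, bin_width = bin_width)
}

#' Aggregate group observations into sampling periods
#'
#' Assigns each group to the clock-aligned sampling period containing its
#' bin. Dyad counting later operates per period: a dyad co-occurs in a
#' period if any group of that period contains both individuals.
#'
#' @param groups a `group_table`.
#' @param period_width seconds (default 3600, hourly periods); must be an
#'   integer multiple of the bin width when that is known.
#' @return a `period_table` (group_table with a `period_start` column).
#' @export
collapse_to_periods <- function(groups, period_width = 3600) {
  if (!is_pos_num(period_width)) stop_fmt("period_width must be > 0")
  bw <- attr(groups, "bin_width")
  if (!is.null(bw) && period_width %% bw != 0) {
    stop_fmt("period_width (%g) must be an integer multiple of bin_width (%g)",
             period_width, bw)
  }
  secs <- as.numeric(groups$bin_start)
  df <- as.data.frame(groups)
  df$period_start <- as.POSIXct(floor(secs / period_width) * period_width,
                                origin = "1970-01-01", tz = "UTC")
  as_group_table(df, bin_width = bw, period_width = period_width)
}

#' Remove one individual from all groups
#'
#' Used for the host of an animal-borne proximity logger, which would by
#' construction appear in every association event it records and is
#' therefore excluded from the network. Groups emptied by the removal are
#' dropped.
#' @param groups a `group_table`.
#' @param individual_id id to remove.
#' @return filtered `group_table`.
#' @export
exclude_individual <- function(groups, individual_id) {
  members <- lapply(groups$members, setdiff, y = individual_id)
  keep <- lengths(members) > 0L
  out <- as.data.frame(groups)[keep, , drop = FALSE]
  out$members <- members[keep]
  as_group_table(out, bin_width = attr(groups, "bin_width"),
                 period_width = attr(groups, "period_width"))
}

#' Restrict proximity-logger groups to a reference receiver's coverage
#'
#' An animal-borne logger records associations anywhere the host swims. To
#' compare with a fixed reference receiver, a logger group is kept only if
#' member(s) of the group were detected by the reference receiver within the
#' group's bin extended by ±`tolerance` seconds.
#'
#' @param proximity_groups a `group_table` from the proximity logger
#'   (host already excluded upstream).
#' @param reference_detections detections from one fixed reference receiver.
#' @param tolerance seconds added on both sides of the group's bin
#'   (default 600, i.e. ±1 bin).
#' @param member_rule `"any"` (default) keeps a group if at least one member
#'   was reference-detected; `"all"` requires every member.
#' @return filtered `group_table`.
#' @export
restrict_proximity_groups <- function(proximity_groups, reference_detections,
                                      tolerance = 600,
                                      member_rule = c("any", "all")) {
  member_rule <- match.arg(member_rule)
  stopifnot(tolerance >= 0)
  bw <- attr(proximity_groups, "bin_width") %||% 600
  if (nrow(reference_detections) == 0L) {
    warn_fmt("empty reference detection stream: all %d proximity groups dropped",
             nrow(proximity_groups))
    return(proximity_groups[integer(0L), , drop = FALSE])
  }
  if (length(unique(reference_detections$receiver_id)) > 1L) {
    stop_fmt("reference detections must come from a single receiver")
  }
  ref_t <- as.numeric(reference_detections$time)
  ref_id <- reference_detections$individual_id
  lo <- as.numeric(proximity_groups$bin_start) - tolerance
  hi <- as.numeric(proximity_groups$bin_start) + bw + tolerance
  keep <- vapply(seq_len(nrow(proximity_groups)), function(i) {
    mem <- proximity_groups$members[[i]]
    hit <- vapply(mem, function(id) {
      any(ref_id == id & ref_t >= lo[i] & ref_t < hi[i])
    }, logical(1L))
    if (member_rule == "any") any(hit) else all(hit)
  }, logical(1L))
  out <- as.data.frame(proximity_groups)[keep, , drop = FALSE]
  out$members <- proximity_groups$members[keep]
  as_group_table(out, bin_width = bw,
                 period_width = attr(proximity_groups, "period_width"))
}

#' Export / import group observations as CSV
#'
#' Columns `receiver_id`, `bin_start`, `members` (semicolon-joined ids).
#' @param groups a `group_table`.
#' @param path CSV path.
#' @param bin_width bin width attribute to attach on read (seconds).
#' @return the path (write) or a `group_table` (read).
#' @export
write_groups <- function(groups, path) {
  df <- data.frame(receiver_id = groups$receiver_id,
                   bin_start = format(groups$bin_start, "%Y-%m-%d %H:%M:%S",
                                      tz = "UTC"),
                   members = vapply(groups$members, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_groups
#' @export
read_groups <- function(path, bin_width = NULL) {
  if (!file.exists(path)) stop_fmt("group file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  group_table(raw$receiver_id, parse_utc(raw$bin_start, path),
              strsplit(raw$members, ";", fixed = TRUE), bin_width = bin_width)
}
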