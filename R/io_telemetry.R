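# Readers and writers for the tabular artifacts of a telemetry study:
# detection logs, receiver/individual metadata and association matrices.
#
# Canonical dialect: comma-separated, UTF-8, ISO-8601 timestamps in UTC
# ("YYYY-MM-DD HH:MM:SS", "T" separator and trailing "Z" accepted),
# "." decimal mark. Timestamps carrying any other UTC offset are rejected
# rather than silently converted.

.TIME_RE <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}[T ][0-9]{2}:[0-9]{2}:[0-9]{2}(\\.[0-9]+)?Z?$"

#' Parse ISO-8601 UTC timestamps
#'
#' @param x character vector.
#' @param what label used in error messages (e.g. a file name).
#' @return POSIXct vector in UTC.
#' @noRd
parse_utc <- function(x, what = "timestamp") {
  x <- trimws(x)
  bad <- !grepl(.TIME_RE, x)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_fmt("%s: unparseable or non-UTC timestamp %s at row %d",
             what, dQuote(x[i]), i)
  }
  x <- sub("Z$", "", sub("T", " ", x, fixed = TRUE))
  out <- as.POSIXct(x, tz = "UTC",
                    format = if (any(grepl("\\.", x))) "%Y-%m-%d %H:%M:%OS" else "%Y-%m-%d %H:%M:%S")
  if (anyNA(out)) {
    i <- which(is.na(out))[1L]
    stop_fmt("%s: invalid calendar timestamp %s at row %d", what, dQuote(x[i]), i)
  }
  out
}

#' Read a detection log
#'
#' Reads `detections.csv` (columns `time`, `receiver_id`, `individual_id`),
#' parses timestamps as UTC, drops exact duplicate rows, and returns records
#' sorted by time (ties broken by receiver then individual id).
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of class `detections` with columns `time`
#'   (POSIXct, UTC), `receiver_id`, `individual_id` (character).
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop_fmt("detection file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("time", "receiver_id", "individual_id")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_fmt("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(as_detections(data.frame(time = as.POSIXct(character(), tz = "UTC"),
                                    receiver_id = character(),
                                    individual_id = character())))
  }
  if (any(!nzchar(trimws(raw$receiver_id))) || any(!nzchar(trimws(raw$individual_id)))) {
    i <- which(!nzchar(trimws(raw$receiver_id)) | !nzchar(trimws(raw$individual_id)))[1L]
    stop_fmt("%s: empty id at row %d", path, i)
  }
  det <- data.frame(time = parse_utc(raw$time, path),
                    receiver_id = trimws(raw$receiver_id),
                    individual_id = trimws(raw$individual_id),
                    stringsAsFactors = FALSE)
  det <- unique(det)
  as_detections(det)
}

as_detections <- function(df) {
  o <- order(df$time, df$receiver_id, df$individual_id)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("detections", "data.frame")
  df
}

#' Read receiver and individual metadata
#'
#' `receivers.csv` has columns `receiver_id,kind,x,y,detection_radius,
#' host_individual`; `individuals.csv` has `individual_id,sex,total_length_cm`.
#' Receiver kinds are `fixed` (positioned, no host) or `mobile`
#' (animal-borne: a host individual and no fixed position).
#'
#' @param receiver_path,individual_path CSV paths.
#' @return list with elements `receivers` and `individuals` (data.frames).
#' @export
read_array_metadata <- function(receiver_path, individual_path) {
  list(receivers = read_receivers(receiver_path),
       individuals = read_individuals(individual_path))
}

#' @rdname read_array_metadata
#' @export
read_receivers <- function(receiver_path) {
  if (!file.exists(receiver_path)) stop_fmt("receiver file not found: %s", receiver_path)
  raw <- utils::read.csv(receiver_path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("receiver_id", "kind", "x", "y", "detection_radius", "host_individual")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_fmt("%s: missing required column(s): %s", receiver_path,
             paste(miss, collapse = ", "))
  }
  rec <- data.frame(receiver_id = trimws(raw$receiver_id),
                    kind = trimws(raw$kind),
                    x = suppressWarnings(as.numeric(raw$x)),
                    y = suppressWarnings(as.numeric(raw$y)),
                    detection_radius = suppressWarnings(as.numeric(raw$detection_radius)),
                    host_individual = trimws(raw$host_individual),
                    stringsAsFactors = FALSE)
  validate_receivers(rec)
}

#' Validate a receiver table against its invariants
#' @noRd
validate_receivers <- function(rec) {
  if (anyDuplicated(rec$receiver_id)) {
    stop_fmt("duplicate receiver_id: %s",
             paste(unique(rec$receiver_id[duplicated(rec$receiver_id)]), collapse = ", "))
  }
  if (any(!rec$kind %in% c("fixed", "mobile"))) {
    stop_fmt("receiver kind must be 'fixed' or 'mobile' (got %s)",
             paste(setdiff(rec$kind, c("fixed", "mobile")), collapse = ", "))
  }
  if (any(is.na(rec$detection_radius)) || any(rec$detection_radius <= 0)) {
    stop_fmt("detection_radius must be > 0 for every receiver")
  }
  fixed <- rec$kind == "fixed"
  if (any(fixed & (is.na(rec$x) | is.na(rec$y)))) {
    stop_fmt("fixed receivers require finite x and y positions")
  }
  if (any(!fixed & !nzchar(rec$host_individual))) {
    stop_fmt("mobile receivers require a host_individual")
  }
  rec$host_individual[fixed] <- NA_character_
  rec$x[!fixed] <- NA_real_
  rec$y[!fixed] <- NA_real_
  rownames(rec) <- NULL
  rec
}

#' @rdname read_array_metadata
#' @export
read_individuals <- function(individual_path) {
  if (!file.exists(individual_path)) stop_fmt("individual file not found: %s", individual_path)
  raw <- utils::read.csv(individual_path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("individual_id", "sex", "total_length_cm")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_fmt("%s: missing required column(s): %s", individual_path,
             paste(miss, collapse = ", "))
  }
  ind <- data.frame(individual_id = trimws(raw$individual_id),
                    sex = trimws(raw$sex),
                    total_length_cm = suppressWarnings(as.numeric(raw$total_length_cm)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ind$individual_id)) {
    stop_fmt("duplicate individual_id: %s",
             paste(unique(ind$individual_id[duplicated(ind$individual_id)]), collapse = ", "))
  }
  ind$sex[!nzchar(ind$sex)] <- "unknown"
  if (any(!ind$sex %in% c("F", "M", "unknown"))) {
    stop_fmt("sex must be one of F, M, unknown")
  }
  rownames(ind) <- NULL
  ind
}

#' Warn about detections of individuals missing from metadata
#'
#' Field data routinely contain foreign tags; such records are retained.
#' @param detections detections data.frame.
#' @param individuals individual metadata data.frame.
#' @return detections, invisibly.
#' @export
check_known_individuals <- function(detections, individuals) {
  unknown <- setdiff(unique(detections$individual_id), individuals$individual_id)
  if (length(unknown)) {
    warn_fmt("detections contain %d individual id(s) absent from metadata (retained): %s",
             length(unknown), paste(unknown, collapse = ", "))
  }
  invisible(detections)
}

#' Write / read an association matrix as CSV
#'
#' Layout: individual ids as first row and first column; values written with
#' full precision so a write-then-read round trip is exact.
#'
#' @param matrix an [association_matrix()].
#' @param path CSV path.
#' @return `read_association_matrix` returns an `association_matrix`.
#' @export
write_association_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "association_matrix"))
  ids <- rownames(matrix)
  m <- unclass(matrix)
  attributes(m) <- list(dim = dim(matrix), dimnames = dimnames(matrix))
  if (length(ids) == 0L) {
    writeLines("id", path)
    return(invisible(path))
  }
  txt <- apply(m, c(1, 2), function(v) sprintf("%.17g", v))
  df <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), as.data.frame(txt))
  names(df) <- c("id", ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_association_matrix
#' @export
read_association_matrix <- function(path) {
  if (!file.exists(path)) stop_fmt("matrix file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  ids <- as.character(raw[[1L]])
  if (!identical(names(raw)[-1L], ids)) {
    stop_fmt("%s: row and column individual ids disagree", path)
  }
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(ids)) {
    vals <- suppressWarnings(vapply(as.list(raw[-1L]), as.numeric, numeric(length(ids))))
    m[] <- matrix(vals, length(ids), length(ids))
  }
  if (anyNA(m)) stop_fmt("%s: non-numeric matrix entry", path)
  if (any(m < 0 | m > 1)) stop_fmt("%s: association index outside [0, 1]", path)
  if (length(ids) && max(abs(m - t(m))) > 1e-12) stop_fmt("%s: matrix not symmetric", path)
  if (length(ids) && any(diag(m) != 0)) stop_fmt("%s: nonzero diagonal", path)
  association_matrix(m)
}

#' Write a detection log in the canonical dialect
#' @param detections detections data.frame.
#' @param path CSV path.
#' @export
write_detections <- function(detections, path) {
  df <- data.frame(time = format(detections$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                   receiver_id = detections$receiver_id,
                   individual_id = detections$individual_id,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Study window
#'
#' Half-open monitoring interval `[start, end)`.
#' @param start,end POSIXct or ISO-8601 strings (UTC).
#' @return list of class `study_window`.
#' @export
study_window <- function(start, end) {
  if (is.character(start)) start <- parse_utc(start, "window start")
  if (is.character(end)) end <- parse_utc(end, "window end")
  stopifnot(inherits(start, "POSIXct"), inherits(end, "POSIXct"))
  if (!(start < end)) stop_fmt("study window requires start < end")
  structure(list(start = start, end = end), class = "study_window")
}
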