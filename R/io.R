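#' Construct a scan record
#'
#' A scan record is a tibble with one row per frame (TR) and one numeric
#' column per region or network, carrying acquisition metadata as
#' attributes. It is the entry point of the analysis pipeline.
#'
#' @param data Numeric matrix or data frame, frames in rows, regions in
#'   columns. Column names are the region labels and must be unique.
#' @param subject_id,session_id,condition Metadata strings.
#' @param tr_seconds Repetition time in seconds (positive).
#' @return A `scan_record` tibble (frames x regions).
#' @examples
#' scan_record(matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b"))))
#' @export
scan_record <- function(data, subject_id = "s1", session_id = "ses1",
                        condition = "rest", tr_seconds = 0.72) {
  df <- as.data.frame(data, check.names = FALSE)
  labels <- colnames(df)
  if (is.null(labels) || anyDuplicated(labels)) {
    abort("region labels (column names) must be present and unique.")
  }
  if (nrow(df) < 2 || ncol(df) < 2) {
    abort("a scan needs at least 2 frames and 2 regions.")
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("non-numeric column(s): %s", paste(labels[bad], collapse = ", ")))
  }
  if (anyNA(df)) abort("scan contains missing values.")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0) {
    abort("tr_seconds must be a single positive number.")
  }
  out <- as_tibble(df)
  attr(out, "subject_id") <- subject_id
  attr(out, "session_id") <- session_id
  attr(out, "condition") <- condition
  attr(out, "tr_seconds") <- tr_seconds
  class(out) <- c("scan_record", class(out))
  out
}

scan_meta <- function(scan) {
  list(subject_id = attr(scan, "subject_id"),
       session_id = attr(scan, "session_id"),
       condition = attr(scan, "condition"),
       tr_seconds = attr(scan, "tr_seconds") %||% 0.72)
}

scan_matrix <- function(scan) {
  m <- as.matrix(as.data.frame(scan, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Read a BOLD time-series table from disk
#'
#' Reads a delimited table (comma for `.csv`, tab for `.tsv`/anything else)
#' whose header row holds region labels and whose body is one numeric row
#' per frame.
#'
#' @param path File path.
#' @inheritParams scan_record
#' @return A `scan_record`.
#' @export
read_scan <- function(path, subject_id = "s1", session_id = "ses1",
                      condition = "rest", tr_seconds = 0.72) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  hdr <- strsplit(readr::read_lines(path, n_max = 1), delim, fixed = TRUE)[[1]]
  if (anyDuplicated(hdr)) {
    abort(sprintf("duplicate region label(s) in header of %s: %s", path,
                  paste(unique(hdr[duplicated(hdr)]), collapse = ", ")))
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) < 2) abort(sprintf("%s: table body must have at least 2 frames.", path))
  # as.numeric (strtod) is correctly rounded, so written tables round-trip
  # bit-exactly; it also lets us report the offending cell on parse failure
  df <- lapply(raw, function(x) suppressWarnings(as.numeric(x)))
  for (j in seq_along(df)) {
    bad <- which(is.na(df[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric cell at data row %d, column '%s' of %s",
                    bad[1], names(raw)[j], path))
    }
  }
  scan_record(as.data.frame(df, check.names = FALSE, optional = TRUE),
              subject_id = subject_id, session_id = session_id,
              condition = condition, tr_seconds = tr_seconds)
}

#' Write a scan record to disk
#'
#' @param scan A `scan_record`.
#' @param path Output path; `.csv` writes comma-delimited, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(as_tibble(as.data.frame(scan, check.names = FALSE)),
                     path, delim = delim)
  invisible(path)
}

#' Read a region-to-network mapping table
#'
#' @param path Two-column delimited file (`region_label`, `network_label`),
#'   with or without a header named exactly that way.
#' @return A `network_map` tibble with columns `region_label` and
#'   `network_label`; network order of first appearance is recorded in the
#'   `network_order` attribute.
#' @export
read_network_map <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = "cc",
                          show_col_types = FALSE, progress = FALSE)
  if (!identical(names(df), c("region_label", "network_label"))) {
    names(df) <- c("region_label", "network_label")
  }
  network_map(df)
}

#' Construct a region-to-network map
#'
#' @param entries Data frame with columns `region_label` and
#'   `network_label`, one row per region.
#' @param network_order Optional character vector fixing the network
#'   (column) order of aggregated scans; defaults to order of first
#'   appearance.
#' @return A `network_map` tibble.
#' @export
network_map <- function(entries, network_order = NULL) {
  entries <- as_tibble(entries)
  if (!all(c("region_label", "network_label") %in% names(entries))) {
    abort("entries needs columns region_label and network_label.")
  }
  if (anyDuplicated(entries$region_label)) {
    abort("every region must map to exactly one network.")
  }
  if (is.null(network_order)) network_order <- unique(entries$network_label)
  if (!setequal(network_order, unique(entries$network_label))) {
    abort("network_order must name exactly the networks present in entries.")
  }
  if (length(network_order) < 2) abort("a network map needs at least 2 networks.")
  attr(entries, "network_order") <- network_order
  class(entries) <- c("network_map", class(entries))
  entries
}

#' Aggregate region time series into network time series
#'
#' Each network column is the unweighted mean of its member-region columns;
#' columns are ordered by the map's `network_order`. Aggregation is
#' invariant to permutations of the scan's region columns.
#'
#' @param scan A `scan_record` at region level.
#' @param map A `network_map` covering every region of `scan`.
#' @return A `scan_record` at network level (same metadata).
#' @export
aggregate_networks <- function(scan, map) {
  stopifnot(inherits(map, "network_map"))
  labels <- colnames(scan)
  missing <- setdiff(labels, map$region_label)
  if (length(missing) > 0) {
    abort(sprintf("region(s) absent from network map: %s",
                  paste(missing, collapse = ", ")))
  }
  m <- scan_matrix(scan)
  order_nets <- attr(map, "network_order")
  net_of <- setNames(map$network_label, map$region_label)[labels]
  agg <- vapply(order_nets, function(nw) {
    cols <- which(net_of == nw)
    if (length(cols) == 0) abort(sprintf("network %s has no member region in this scan.", nw))
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  dimnames(agg) <- list(NULL, order_nets)
  meta <- scan_meta(scan)
  scan_record(agg, subject_id = meta$subject_id, session_id = meta$session_id,
              condition = meta$condition, tr_seconds = meta$tr_seconds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
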