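## Calibrations: exact node times (leaf sampling dates and/or internal-node
## ages) that define the linear constraint system. Times are decimal reals
## in forward-time units (larger = more recent); calendar dates are a
## convenience layer converted to decimal years.

#' Create a calibration set
#'
#' @param node integer vector of node ids
#' @param time numeric vector of times (forward time: larger = younger)
#' @param name optional display names
#' @return an object of class `calibration_set` (a data frame with columns
#'   node, time, name)
#' @export
calibration_set <- function(node, time, name = NULL) {
  node <- as.integer(node); time <- as.numeric(time)
  stopifnot(length(node) == length(time))
  if (is.null(name)) name <- as.character(node)
  if (length(node) < 2L)
    stop("at least two calibration points are required")
  if (anyDuplicated(node))
    stop("duplicate calibration for node ",
         node[anyDuplicated(node)])
  if (length(unique(time)) < 2L)
    stop("insufficient temporal signal: all calibration times are equal")
  structure(data.frame(node = node, time = time, name = name,
                       stringsAsFactors = FALSE),
            class = c("calibration_set", "data.frame"))
}

#' Number of calibration points
#' @param cal a `calibration_set`
#' @return integer count
#' @export
n_calibrations <- function(cal) nrow(cal)

.days_in_year <- function(y) {
  ifelse((y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0, 366, 365)
}

#' Convert a calendar date to a decimal year
#'
#' Uses year + (day_of_year - 1) / days_in_year, so January 1 maps exactly
#' to the integer year.
#'
#' @param x character vector of "YYYY-MM-DD" dates
#' @return numeric decimal years
#' @export
decimal_year <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  if (any(is.na(d))) stop("invalid calendar date: ", x[is.na(d)][1])
  y <- as.integer(format(d, "%Y"))
  doy <- as.integer(format(d, "%j"))
  y + (doy - 1) / .days_in_year(y)
}

.parse_time_token <- function(tok) {
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", tok)) return(decimal_year(tok))
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) stop("cannot parse time value ", sQuote(tok))
  v
}

.resolve_node_name <- function(name, tree) {
  m <- regmatches(name, regexec("^mrca\\((.+)\\)$", name))[[1]]
  if (length(m) == 2L) {
    labs <- trimws(strsplit(m[2], ",", fixed = TRUE)[[1]])
    ids <- match(labs, tree$label) - 1L
    if (any(is.na(ids)))
      stop("unknown label in mrca(): ", sQuote(labs[is.na(ids)][1]))
    return(mrca_node(tree, ids))
  }
  id <- match(name, tree$label) - 1L
  if (is.na(id)) stop("unknown node label: ", sQuote(name))
  id
}

#' Parse an LSD-style date file
#'
#' Format: first line is the number of entries; each following line is
#' `<name> <time>` where `<name>` is a leaf or internal-node label, or
#' `mrca(l1,l2,...)` selecting the MRCA of the named leaves. `<time>` is a
#' decimal number or a calendar date `YYYY-MM-DD` (converted to a decimal
#' year).
#'
#' @param text the date file content as a single string, or a file path
#' @param tree the `rooted_tree` the names refer to
#' @return a `calibration_set`
#' @export
parse_date_file <- function(text, tree) {
  .check_tree(tree)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty date file")
  k <- suppressWarnings(as.integer(lines[1]))
  if (is.na(k)) stop("first line must be the number of entries")
  entries <- lines[-1]
  if (length(entries) != k)
    stop("date file announces ", k, " entries but contains ",
         length(entries))
  node <- integer(k); time <- numeric(k); nm <- character(k)
  for (i in seq_len(k)) {
    ## name may contain spaces inside mrca(...); split on last whitespace
    m <- regmatches(entries[i],
                    regexec("^(.*\\S)\\s+(\\S+)$", entries[i]))[[1]]
    if (length(m) != 3L) stop("malformed date line: ", sQuote(entries[i]))
    nm[i] <- m[2]
    node[i] <- .resolve_node_name(m[2], tree)
    time[i] <- .parse_time_token(m[3])
  }
  calibration_set(node, time, nm)
}

#' Diagnostics for a calibration set
#'
#' Pure report: returns the number of points, the time span, whether every
#' leaf is dated (phylodynamics mode), and whether the set is degenerate.
#'
#' @param cal a `calibration_set`
#' @param tree the `rooted_tree` it refers to
#' @return a list with elements k, span, all_leaves_dated, degenerate
#' @export
validate_calibrations <- function(cal, tree) {
  .check_tree(tree)
  lv <- leaf_ids(tree)
  out <- list(k = nrow(cal),
              span = max(cal$time) - min(cal$time),
              all_leaves_dated = all(lv %in% cal$node),
              degenerate = length(unique(cal$time)) < 2L)
  class(out) <- "calibration_report"
  out
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibrations: k =", x$k, "| span =", format(x$span), "\n")
  if (x$all_leaves_dated) cat("phylodynamics mode (all leaves dated)\n")
  if (x$degenerate) cat("DEGENERATE: fewer than two distinct times\n")
  invisible(x)
}

#' Write an LSD-style date file
#' @param cal a `calibration_set`
#' @param tree the tree (used for display names when absent)
#' @param path output file path
#' @return invisibly, the path
#' @export
write_date_file <- function(cal, tree, path) {
  nm <- cal$name
  fallback <- tree$label[.id(cal$node)]
  nm[!nzchar(nm)] <- fallback[!nzchar(nm)]
  writeLines(c(as.character(nrow(cal)),
               paste(nm, format(cal$time, digits = 12))), path)
  invisible(path)
}
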