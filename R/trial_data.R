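# Core data container: per-center daily recruitment counts.
#
# Calendar-day convention: a center initiated on calendar day s recruits on
# center-local days t = 1, 2, ..., where local day t covers the half-open
# calendar interval (s + t - 1, s + t].  At a census on calendar day T the
# center has been observed for tau = T - s local days.

#' Construct a trial recruitment data set
#'
#' Bundles per-center daily recruitment count series with the center
#' initiation days and the census (interim analysis) day.
#'
#' @param counts named list of non-negative integer vectors, one per center;
#'   element \code{counts[[c]][t]} is the number recruited by center \code{c}
#'   on its local day \code{t}.  Centers not yet initiated at the census have
#'   zero-length count vectors.
#' @param initiation_day named integer vector of calendar initiation days
#'   (\code{>= 0}), names matching \code{counts}.
#' @param census_day integer calendar day at which observation ends; every
#'   initiated center must satisfy \code{length(counts[[c]]) ==
#'   census_day - initiation_day[c]}.
#' @param first_recruitment_deterministic logical; if \code{TRUE} the first
#'   local day of each center is treated as containing one deterministic
#'   recruitment (the initiation recruit), which is removed before likelihood
#'   evaluation and added back deterministically in forecasts.  Use this when
#'   initiation days were taken to be the first recruitment days.
#' @return an object of class \code{"trial_data"}.
#' @examples
#' td <- trial_data(list(A = c(1L, 0L, 2L)), c(A = 0L), census_day = 3)
#' totals(td)
#' @export
trial_data <- function(counts, initiation_day, census_day,
                       first_recruitment_deterministic = FALSE) {
  if (!is.list(counts)) stop("`counts` must be a list of integer vectors")
  ids <- names(counts)
  if (length(counts) > 0 && (is.null(ids) || anyDuplicated(ids) || any(ids == "")))
    stop("`counts` must have unique non-empty names (center ids)")
  if (length(initiation_day) != length(counts) ||
      (length(counts) > 0 && !setequal(names(initiation_day), ids)))
    stop("`initiation_day` must be named to match `counts`")
  initiation_day <- initiation_day[ids]
  census_day <- as.integer(census_day)
  if (length(census_day) != 1L || is.na(census_day) || census_day < 0)
    stop("`census_day` must be a single non-negative integer")
  init <- as.integer(round(initiation_day))
  if (any(is.na(init)) || any(init < 0))
    stop("initiation days must be non-negative integers")
  counts <- lapply(counts, function(y) {
    if (any(is.na(y)) || any(y < 0) || any(y != round(y)))
      stop("counts must be non-negative integers")
    as.integer(y)
  })
  tau <- pmax(census_day - init, 0L)
  obs_len <- lengths(counts)
  if (any(obs_len != tau))
    stop("length of each count series must equal census_day - initiation_day ",
         "(zero for centers initiated at or after the census)")
  structure(
    list(center_ids = ids %||% character(0),
         initiation_day = stats::setNames(init, ids),
         counts = counts,
         census_day = census_day,
         first_recruitment_deterministic =
           isTRUE(first_recruitment_deterministic)),
    class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  tt <- totals(x)
  cat("Multi-center trial recruitment data\n")
  cat(sprintf("  centers: %d (%d initiated), census day: %d\n",
              length(x$center_ids), sum(lengths(x$counts) > 0), x$census_day))
  cat(sprintf("  total recruits: %d\n", tt$n_total))
  if (x$first_recruitment_deterministic)
    cat("  first recruitment at each center treated as deterministic\n")
  invisible(x)
}

#' Total and per-center recruitment counts
#'
#' @param data a \code{\link{trial_data}} object.
#' @return list with \code{n_total} (grand total) and \code{per_center}
#'   (named integer vector of per-center totals).
#' @export
totals <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  per <- vapply(data$counts, function(y) sum(as.numeric(y)), numeric(1))
  list(n_total = as.integer(sum(per)),
       per_center = stats::setNames(as.integer(per), data$center_ids))
}

#' Observation lengths per center
#'
#' Number of local observation days \code{tau_c = census_day -
#' initiation_day} for each center (zero for centers not yet initiated).
#'
#' @param data a \code{\link{trial_data}} object.
#' @return named integer vector.
#' @export
observation_days <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  stats::setNames(lengths(data$counts), data$center_ids)
}

# Counts as used by the model likelihood: when the first recruitment is
# deterministic, one recruit is removed from each initiated center's first
# local day before likelihood evaluation.
model_counts <- function(data) {
  if (!data$first_recruitment_deterministic) return(data$counts)
  lapply(data$counts, function(y) {
    if (length(y) == 0L) return(y)
    if (y[1L] < 1L)
      warning("first-day count is zero but the deterministic-first-recruitment ",
              "flag is set; leaving it at zero")
    y[1L] <- max(y[1L] - 1L, 0L)
    y
  })
}

#' Truncate trial data at an earlier census day
#'
#' Restricts the observation window to \code{census_day}; counts after the
#' new census are dropped and centers initiated at or after it become
#' not-yet-initiated (empty series).
#'
#' @param data a \code{\link{trial_data}} object.
#' @param census_day new census day, at most \code{data$census_day}.
#' @return a \code{\link{trial_data}} object.
#' @export
truncate_trial <- function(data, census_day) {
  stopifnot(inherits(data, "trial_data"))
  census_day <- as.integer(census_day)
  if (census_day > data$census_day)
    stop("new census day is after the end of the observed data")
  tau_new <- pmax(census_day - data$initiation_day, 0L)
  counts <- Map(function(y, k) y[seq_len(k)], data$counts,
                as.list(tau_new[data$center_ids]))
  trial_data(counts, data$initiation_day, census_day,
             data$first_recruitment_deterministic)
}

#' Read trial recruitment data from CSV
#'
#' Reads a long-format CSV of daily recruitment events with columns
#' \code{center_id}, \code{day} (calendar day), and \code{count}.  Days with
#' no row are taken as zero recruitment.  Initiation days come either from a
#' separate CSV/data frame with columns \code{center_id},
#' \code{initiation_day}, or from an \code{initiation_day} column of the
#' main file.
#'
#' @param path path to the counts CSV.
#' @param census_day integer calendar census day.
#' @param initiation optional path or data frame giving initiation days; if
#'   \code{NULL} the main file must carry an \code{initiation_day} column.
#' @param first_recruitment_deterministic see \code{\link{trial_data}}.
#' @return a \code{\link{trial_data}} object.
#' @export
read_trial_csv <- function(path, census_day, initiation = NULL,
                           first_recruitment_deterministic = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0 && !all(c("center_id", "day", "count") %in% names(df)))
    stop("counts CSV must have columns center_id, day, count")
  if (is.null(initiation)) {
    if (!"initiation_day" %in% names(df))
      stop("no initiation information: supply `initiation` or an ",
           "initiation_day column")
    ini <- unique(df[, c("center_id", "initiation_day")])
  } else {
    ini <- if (is.character(initiation))
      utils::read.csv(initiation, stringsAsFactors = FALSE) else initiation
    if (!all(c("center_id", "initiation_day") %in% names(ini)))
      stop("initiation table must have columns center_id, initiation_day")
  }
  ini$center_id <- as.character(ini$center_id)
  if (anyDuplicated(ini$center_id))
    stop("conflicting initiation days for a center")
  init <- stats::setNames(as.integer(ini$initiation_day), ini$center_id)
  tau <- pmax(as.integer(census_day) - init, 0L)
  counts <- lapply(stats::setNames(nm = names(init)), function(id)
    integer(tau[[id]]))
  if (nrow(df) > 0) {
    df$center_id <- as.character(df$center_id)
    unknown <- setdiff(df$center_id, names(init))
    if (length(unknown))
      stop("counts present for centers with no initiation day: ",
           paste(unknown, collapse = ", "))
    if (any(df$count != round(df$count)) || any(df$count < 0))
      stop("counts must be non-negative integers")
    for (i in seq_len(nrow(df))) {
      id <- df$center_id[i]
      t_local <- df$day[i] - init[[id]]
      if (df$day[i] > census_day)
        stop("count recorded after the census day for center ", id)
      if (t_local < 1)
        stop("count recorded before initiation for center ", id)
      counts[[id]][t_local] <- counts[[id]][t_local] + as.integer(df$count[i])
    }
  }
  trial_data(counts, init, census_day, first_recruitment_deterministic)
}

#' Write trial recruitment data to CSV
#'
#' Inverse of \code{\link{read_trial_csv}}: writes the non-zero daily counts
#' in long format (columns \code{center_id}, \code{day}, \code{count}) plus
#' an initiation table.
#'
#' @param data a \code{\link{trial_data}} object.
#' @param path path for the counts CSV.
#' @param initiation_path path for the initiation CSV (columns
#'   \code{center_id}, \code{initiation_day}).
#' @return invisibly, the two paths.
#' @export
write_trial_csv <- function(data, path, initiation_path) {
  stopifnot(inherits(data, "trial_data"))
  rows <- do.call(rbind, lapply(data$center_ids, function(id) {
    y <- data$counts[[id]]
    keep <- which(y > 0L)
    if (!length(keep)) return(NULL)
    data.frame(center_id = id, day = data$initiation_day[[id]] + keep,
               count = y[keep])
  }))
  if (is.null(rows))
    rows <- data.frame(center_id = character(0), day = integer(0),
                       count = integer(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(center_id = data$center_ids,
               initiation_day = unname(data$initiation_day)),
    initiation_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, initiation_path))
}

#' Future center-initiation schedule
#'
#' Validates a planned schedule of center initiations after the census day,
#' used when forecasting accrual.
#'
#' @param center_id character vector of new center identifiers.
#' @param day integer calendar initiation days, all strictly greater than
#'   \code{census_day}.
#' @param data the \code{\link{trial_data}} the schedule extends (ids must
#'   be disjoint from its centers).
#' @return a data frame of class \code{"initiation_schedule"}.
#' @export
initiation_schedule <- function(center_id, day, data) {
  stopifnot(inherits(data, "trial_data"))
  center_id <- as.character(center_id)
  day <- as.integer(day)
  if (length(center_id) != length(day))
    stop("`center_id` and `day` must have equal length")
  if (anyDuplicated(center_id) || any(center_id %in% data$center_ids))
    stop("schedule ids must be unique and disjoint from existing centers")
  if (any(day <= data$census_day))
    stop("scheduled initiation days must be after the census day")
  structure(data.frame(center_id = center_id, day = day,
                       stringsAsFactors = FALSE),
            class = c("initiation_schedule", "data.frame"))
}
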