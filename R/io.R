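timecourse_columns <- c("elevation", "temperature_C", "replicate",
                        "n_seeds", "day", "cumulative_germinated")

validate_timecourses <- function(tc, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  if (!is.data.frame(tc)) stop("time-course input must be a data frame")
  missing_cols <- setdiff(timecourse_columns, names(tc))
  if (length(missing_cols))
    stop("malformed time-course table", where, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tc) == 0L) stop("empty time-course input", where)
  if (any(!is.finite(tc$day) | tc$day <= 0))
    stop("day indices must be positive", where)
  if (anyNA(tc$elevation))
    stop("elevation must not be missing", where)
  bad <- which(tc$cumulative_germinated < 0 |
                 tc$cumulative_germinated > tc$n_seeds)
  if (length(bad))
    stop("count outside [0, n_seeds] at row ", bad[1L], where)
  key <- interaction(tc$elevation, tc$temperature_C, tc$replicate,
                     drop = TRUE)
  for (d in split(seq_len(nrow(tc)), key)) {
    idx <- d[order(tc$day[d])]
    if (any(diff(tc$day[idx]) <= 0))
      stop("duplicated day index at row ",
           idx[which(diff(tc$day[idx]) <= 0)[1L] + 1L], where)
    dec <- which(diff(tc$cumulative_germinated[idx]) < 0)
    if (length(dec))
      stop("decreasing cumulative count at row ", idx[dec[1L] + 1L], where)
  }
  tc
}

#' Read germination time courses from CSV
#'
#' Reads the long census dialect written by [write_timecourses()]
#' (comma-separated, UTF-8, `.` decimal, header `elevation,
#' temperature_C, replicate, n_seeds, day, cumulative_germinated`) and
#' validates it: counts must be nondecreasing within each (elevation,
#' temperature, replicate) and bounded by `n_seeds`; violations raise an
#' error naming the offending row.
#'
#' @param path Path to the CSV file.
#' @return Validated time-course data frame.
#' @export
read_timecourses <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tc <- tryCatch(read.csv(path, fileEncoding = "UTF-8"),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  validate_timecourses(tc, file = path)
}

#' Write germination time courses to CSV
#'
#' @param timecourses Validated time-course data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(timecourses, path) {
  tc <- validate_timecourses(timecourses)
  write.csv(tc[timecourse_columns], path, row.names = FALSE,
            fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read a soil-temperature logger trace from CSV
#'
#' Expects columns `timestamp_minutes` and `temperature_C`, strictly
#' increasing equally spaced timestamps; the sampling interval is
#' inferred from the timestamps.
#'
#' @param path Path to the CSV file.
#' @return A `soil_trace` data frame.
#' @export
read_soil_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- read.csv(path, fileEncoding = "UTF-8")
  tr <- validate_soil_trace(tr)
  class(tr) <- c("soil_trace", "data.frame")
  tr
}

#' Write a soil-temperature trace to CSV
#'
#' @param trace A `soil_trace` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_soil_trace <- function(trace, path) {
  trace <- validate_soil_trace(trace)
  write.csv(trace[c("timestamp_minutes", "temperature_C")], path,
            row.names = FALSE, fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}
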