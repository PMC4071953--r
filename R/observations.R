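#' Construct an observation set
#'
#' One literature-style dataset: a single observed variable, its sampling
#' times and values, and a fitting weight.  Several sets are combined in a
#' plain data frame (long format) for calibration.
#'
#' @param dataset_id character label.
#' @param variable one of `"H"`, `"C"`, `"M"` (cells/mm^3) or `"N"`, `"D"`,
#'   `"R"` (percent).
#' @param time sampling times in weeks.
#' @param value observed values, same length as `time`, `>= 0`.
#' @param weight non-negative scalar weight (default 1).
#' @return Data frame with columns `dataset_id`, `variable`, `time`,
#'   `value`, `weight`.
#' @export
observation_set <- function(dataset_id, variable, time, value, weight = 1) {
  variable <- match.arg(variable, STATE_VARS)
  stopifnot(length(time) == length(value), length(time) >= 1,
            all(is.finite(time)), all(time >= 0),
            all(is.finite(value)), all(value >= 0),
            is.numeric(weight), length(weight) == 1, weight >= 0)
  data.frame(dataset_id = as.character(dataset_id), variable = variable,
             time = as.numeric(time), value = as.numeric(value),
             weight = as.numeric(weight))
}

validate_observations <- function(obs) {
  need <- c("dataset_id", "variable", "time", "value", "weight")
  missing <- setdiff(need, names(obs))
  if (length(missing))
    stop("observation table is missing columns: ",
         paste(missing, collapse = ", "))
  stopifnot(all(obs$variable %in% STATE_VARS),
            all(obs$value >= 0), all(obs$time >= 0), all(obs$weight >= 0))
  invisible(obs)
}

#' Read / write observation tables
#'
#' The on-disk format is delimited text with columns
#' `dataset_id,variable,time_days,value,weight`; ages are stored in days
#' (the unit of the source literature) and converted to weeks on ingest.
#'
#' @param obs observation data frame (times in weeks).
#' @param path CSV file path.
#' @return `read_observations()` returns the observation data frame with
#'   `time` in weeks; `write_observations()` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dataset_id", "variable", "time_days", "value")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("observation file is missing columns: ",
         paste(missing, collapse = ", "))
  if (is.null(raw$weight)) raw$weight <- 1
  obs <- data.frame(dataset_id = as.character(raw$dataset_id),
                    variable = raw$variable,
                    time = raw$time_days / 7,
                    value = raw$value,
                    weight = raw$weight)
  validate_observations(obs)
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  validate_observations(obs)
  out <- data.frame(dataset_id = obs$dataset_id, variable = obs$variable,
                    time_days = obs$time * 7, value = obs$value,
                    weight = obs$weight)
  utils::write.csv(format(out, digits = 17, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
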