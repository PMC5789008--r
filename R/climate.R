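#' Climatic demand from four monthly temperature extremes
#'
#' Thermal stress on a population is scored as the sum of absolute
#' deviations from a 22 degrees C reference (about 72 F, a temperature
#' regarded as optimal for human functioning) of four values: the lowest and
#' highest temperatures of the coldest month and the lowest and highest
#' temperatures of the hottest month. The index is nonnegative and zero only
#' when all four temperatures equal the reference. No latitude adjustment is
#' applied; unadjusted deviations give the more conservative estimate of
#' climate effects.
#'
#' @param climate Data frame with numeric columns `t_cold_low`,
#'   `t_cold_high`, `t_hot_low`, `t_hot_high` (degrees C) and optionally a
#'   `population_id` column used to name the result.
#' @param reference Reference temperature in degrees C (default 22).
#' @return Numeric vector of demands, one per row.
#' @export
#' @examples
#' climatic_demand(data.frame(t_cold_low = 0, t_cold_high = 10,
#'                            t_hot_low = 25, t_hot_high = 35))  # 50
climatic_demand <- function(climate, reference = 22) {
  need <- c("t_cold_low", "t_cold_high", "t_hot_low", "t_hot_high")
  miss <- setdiff(need, names(climate))
  if (length(miss)) {
    stop("climate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tm <- as.matrix(climate[need])
  if (any(!is.finite(tm))) stop("non-finite temperatures", call. = FALSE)
  bad <- climate$t_cold_low > climate$t_cold_high |
    climate$t_hot_low > climate$t_hot_high
  if (any(bad)) {
    who <- if ("population_id" %in% names(climate)) {
      paste(climate$population_id[bad], collapse = ", ")
    } else {
      paste(which(bad), collapse = ", ")
    }
    stop("monthly low exceeds monthly high for: ", who, call. = FALSE)
  }
  out <- rowSums(abs(tm - reference))
  if ("population_id" %in% names(climate)) {
    names(out) <- as.character(climate$population_id)
  }
  out
}

#' Read a climate table from CSV
#'
#' Expects header `population_id,t_cold_low,t_cold_high,t_hot_low,t_hot_high`.
#'
#' @param path Path to the CSV file.
#' @return Data frame.
#' @export
read_climate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("population_id", "t_cold_low", "t_cold_high", "t_hot_low",
            "t_hot_high")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("climate table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d
}
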