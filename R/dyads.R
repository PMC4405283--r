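#' @useDynLib remtriad, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm rnorm sd setNames
#' @importFrom utils read.csv write.csv head modifyList packageVersion
NULL

# Dyad coding follows the field convention for a coded triad: animals 1 and 2
# are the familiar pair, animal 3 the newly introduced (unfamiliar) animal.
# Contact types: 1 = tie (1,2), 2 = tie (1,3), 3 = tie (2,3).
DYAD_MEMBERS <- list(`1` = c(1L, 2L), `2` = c(1L, 3L), `3` = c(2L, 3L))

ONSET_TYPES <- c("pair", "group", "triangle")
OFFSET_TYPES <- c("pair_dissolution", "group_dissolution", "triangle_dissolution")
EFFECTS <- c("unfam", "pair_hour", "pair_day", "group_hour", "group_day")

#' Animals forming a coded dyad
#'
#' @param dyad Integer dyad code in 1:3 (1 = animals 1-2, 2 = animals 1-3,
#'   3 = animals 2-3).
#' @return Integer vector of the two animal codes.
#' @export
dyad_members <- function(dyad) {
  stopifnot(length(dyad) == 1L, dyad %in% 1:3)
  DYAD_MEMBERS[[as.character(dyad)]]
}

#' Dyad code for a pair of animals
#'
#' @param a,b Animal codes in 1:3, distinct.
#' @return Integer dyad code in 1:3.
#' @export
dyad_code <- function(a, b) {
  stopifnot(a %in% 1:3, b %in% 1:3, a != b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  # (1,2)->1, (1,3)->2, (2,3)->3
  ifelse(lo == 1L & hi == 2L, 1L, ifelse(lo == 1L & hi == 3L, 2L, 3L))
}

#' Does a dyad involve the unfamiliar animal?
#'
#' Animal 3 is the unfamiliar animal by coding convention, so dyads 2 (1-3)
#' and 3 (2-3) are the unfamiliar pairings.
#'
#' @param dyad Integer dyad code(s).
#' @return 0/1 numeric vector.
#' @export
dyad_unfamiliar <- function(dyad) as.numeric(dyad %in% c(2L, 3L))

# third animal not in the given dyad
other_animal <- function(dyad) setdiff(1:3, dyad_members(dyad))

#' Day start times for daily stratification
#'
#' The model is stratified by day, with day 1 being the (usually partial)
#' calendar day on which the unfamiliar animal was introduced. In
#' `"calendar"` mode day boundaries fall at local midnights of the logger
#' clock; in `"fixed"` mode days are 24-hour blocks from the introduction.
#'
#' @param introduction POSIXct introduction time (clock of the loggers), or
#'   for `"fixed"` mode may be `NULL`.
#' @param n_days Number of observation days.
#' @param mode `"calendar"` or `"fixed"`.
#' @return Numeric vector of length `n_days`: the start of each day in
#'   seconds since introduction (`day_starts[1]` is always 0).
#' @export
day_start_times <- function(introduction, n_days, mode = c("calendar", "fixed")) {
  mode <- match.arg(mode)
  stopifnot(n_days >= 1)
  if (mode == "fixed") return(86400 * (seq_len(n_days) - 1))
  stopifnot(inherits(introduction, "POSIXct"))
  lt <- as.POSIXlt(introduction)
  into_day <- lt$hour * 3600 + lt$min * 60 + lt$sec
  first_midnight <- 86400 - into_day
  c(0, first_midnight + 86400 * (seq_len(n_days - 1) - 1))
}

# day index for event times given the day-start vector
day_of <- function(t, day_starts) findInterval(t, day_starts)
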