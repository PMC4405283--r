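# Classification of tie onsets and offsets by triadic configuration.
#
# With three animals there are three possible ties. An onset from the empty
# configuration is a pair event; an onset when exactly one tie is active is
# a group event (the third animal joins one member of the active pair); an
# onset when two ties are active necessarily closes the triad and is a
# triangle event. Offsets are labelled by the configuration they dissolve.

#' Classify an onset against the current triad configuration
#'
#' @param state Integer vector of currently active dyad codes (subset of 1:3).
#' @param dyad Dyad code of the onset; must not be active.
#' @return `"pair"`, `"group"` or `"triangle"`.
#' @export
classify_onset <- function(state, dyad) {
  if (dyad %in% state)
    stop("onset of dyad ", dyad, " but the tie is already active")
  switch(as.character(length(state)),
         "0" = "pair",
         "1" = "group",
         "2" = "triangle",
         stop("no onset is possible from a saturated triad"))
}

#' Classify an offset against the current triad configuration
#'
#' @param state Integer vector of currently active dyad codes.
#' @param dyad Dyad code of the offset; must be active.
#' @return `"pair_dissolution"`, `"group_dissolution"` or
#'   `"triangle_dissolution"`.
#' @export
classify_offset <- function(state, dyad) {
  if (!(dyad %in% state))
    stop("offset of dyad ", dyad, " but the tie is not active")
  switch(as.character(length(state)),
         "1" = "pair_dissolution",
         "2" = "group_dissolution",
         "3" = "triangle_dissolution")
}

#' Build the classified event stream of a triad
#'
#' Merges all per-dyad contact intervals into one time-ordered stream of
#' onset and offset events, classifies each event against the running
#' configuration, and assigns the day index. At equal seconds offsets are
#' processed before onsets, so a tie dissolving in the same second as a new
#' onset does not inflate the configuration the onset sees; equal-second
#' events of the same kind are ordered by dyad code.
#'
#' @param intervals `rem_intervals` for a single triad (onsets already
#'   distinct via [break_onset_ties()]).
#' @param day_starts Numeric vector of day start times in seconds since
#'   introduction (from [day_start_times()]); `day_starts[1]` must be 0.
#' @return Data frame of class `rem_stream` with columns `triad_id`, `t`,
#'   `dyad`, `kind` ("onset"/"offset"), `etype`, `base_dyad` (for group
#'   onsets, the pre-existing tie of the configuration they create; NA
#'   otherwise), `day` and `day_start`.
#' @export
build_event_stream <- function(intervals, day_starts = 0) {
  stopifnot(day_starts[1] == 0)
  triad <- if (nrow(intervals)) intervals$triad_id[1] else NA_character_
  ev <- rbind(
    data.frame(t = intervals$onset_t, dyad = intervals$dyad, kind = "onset"),
    data.frame(t = intervals$offset_t, dyad = intervals$dyad, kind = "offset"))
  # offsets first at equal seconds, then dyad order
  ev <- ev[order(ev$t, ev$kind != "offset", ev$dyad), , drop = FALSE]

  n <- nrow(ev)
  etype <- character(n); base <- rep(NA_integer_, n)
  state <- integer(0)
  for (i in seq_len(n)) {
    d <- ev$dyad[i]
    if (ev$kind[i] == "onset") {
      if (d %in% state)
        stop("onset without a preceding offset for dyad ", d, " at t=", ev$t[i])
      etype[i] <- classify_onset(state, d)
      if (etype[i] == "group") base[i] <- state[1]
      state <- sort(c(state, d))
    } else {
      if (!(d %in% state))
        stop("offset without a preceding onset for dyad ", d, " at t=", ev$t[i])
      etype[i] <- classify_offset(state, d)
      state <- setdiff(state, d)
    }
  }
  day <- day_of(ev$t, day_starts)
  # offsets can land beyond the last tabulated day start; day index still counts on
  out <- data.frame(triad_id = triad, t = as.integer(round(ev$t)), dyad = ev$dyad,
                    kind = ev$kind, etype = etype, base_dyad = base,
                    day = day, day_start = day_starts[pmin(day, length(day_starts))],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rem_stream", "data.frame")
  out
}

#' Tabulate events per day and type
#'
#' One row per day with the three onset types and the three dissolution
#' types, the layout used for event-count summaries of a study.
#'
#' @param stream A `rem_stream` (possibly several triads row-bound).
#' @return Data frame with columns `day`, `pair`, `group`, `triangle`,
#'   `pair_dissolution`, `group_dissolution`, `triangle_dissolution`,
#'   `total_onsets`, `total_offsets`.
#' @export
summarize_event_counts <- function(stream) {
  days <- if (nrow(stream)) seq_len(max(stream$day)) else integer(0)
  cols <- c(ONSET_TYPES, OFFSET_TYPES)
  out <- data.frame(day = days)
  for (cl in cols)
    out[[cl]] <- vapply(days, function(d)
      sum(stream$day == d & stream$etype == cl), integer(1))
  out$total_onsets <- if (nrow(out)) rowSums(out[ONSET_TYPES]) else integer(0)
  out$total_offsets <- if (nrow(out)) rowSums(out[OFFSET_TYPES]) else integer(0)
  out
}

#' Write / read a classified event stream
#'
#' @param stream `rem_stream` data frame.
#' @param path CSV path.
#' @return `path` invisibly; for the reader, the stream.
#' @export
write_stream <- function(stream, path) {
  write.csv(stream, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  out <- read.csv(path, colClasses = c(triad_id = "character"))
  class(out) <- c("rem_stream", "data.frame")
  out
}
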