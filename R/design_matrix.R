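# Risk sets and history statistics for the ordinal relational event model.
#
# Each modelled onset forms one stratum: the realized event plus the
# potential onsets that could have occurred at that moment instead. Every
# row carries five statistics: an unfamiliarity indicator, and counts of the
# candidate dyad's prior pair and group onsets over the past hour and over
# the current day. Days are modelled separately and history never crosses a
# day boundary.

#' Potential onsets at the moment of a realized onset
#'
#' For a pair event (empty configuration) all three dyads could have formed;
#' for a group event (one active tie) only the two dyads joining the
#' unconnected third animal to a member of the active pair are possible.
#'
#' @param state Integer vector of active dyad codes before the onset.
#' @param realized_dyad Dyad code of the onset that occurred.
#' @param model_type `"pair"` or `"group"`.
#' @return Integer vector of candidate dyad codes (realized one included).
#' @export
enumerate_risk_set <- function(state, realized_dyad, model_type = c("pair", "group")) {
  model_type <- match.arg(model_type)
  if (model_type == "pair") {
    if (length(state) != 0L)
      stop("pair model requires an empty configuration")
    cand <- 1:3
  } else {
    if (length(state) != 1L)
      stop("group model requires exactly one active tie")
    cand <- setdiff(1:3, state)
  }
  if (!(realized_dyad %in% cand))
    stop("realized dyad ", realized_dyad, " is not a possible onset here")
  cand
}

#' History statistics for one candidate dyad at one moment
#'
#' Counts are over half-open windows ending just before `t`: the hourly
#' window is `(t - hour_window_s, t)` (an onset exactly one hour old has
#' left the window) and the daily window `[day_start, t)`; both are
#' truncated at `day_start`, so hourly counts are nested within daily counts
#' and nothing recorded before the current day is considered. A prior group
#' onset is credited to a dyad if that dyad was one of the two ties of the
#' configuration the onset created (the newly formed tie or the pre-existing
#' one).
#'
#' @param stream `rem_stream` of one triad (the history).
#' @param dyad Candidate dyad code.
#' @param t Time of the modelled onset (seconds since introduction).
#' @param day_start Start second of the day containing `t`.
#' @param hour_window_s Width of the short window (default 3600 s).
#' @return Named numeric vector `(unfam, pair_hour, pair_day, group_hour,
#'   group_day)`.
#' @export
compute_statistics <- function(stream, dyad, t, day_start, hour_window_s = 3600) {
  on <- stream[stream$kind == "onset", , drop = FALSE]
  in_day <- on$t >= day_start & on$t < t
  in_hour <- in_day & on$t > t - hour_window_s
  is_pair <- on$etype == "pair" & on$dyad == dyad
  is_group <- on$etype == "group" &
    (on$dyad == dyad | (!is.na(on$base_dyad) & on$base_dyad == dyad))
  c(unfam = dyad_unfamiliar(dyad),
    pair_hour = sum(is_pair & in_hour),
    pair_day = sum(is_pair & in_day),
    group_hour = sum(is_group & in_hour),
    group_day = sum(is_group & in_day))
}

#' Build the strata of a (model type, day) dataset
#'
#' One stratum per onset of the requested type on the requested day, pooled
#' across the triads present in `stream`; statistics for each row are
#' computed against that triad's own history only. Triangle onsets are
#' forced (probability 1 given two ties) and contribute no strata.
#'
#' @param stream `rem_stream`, possibly several triads row-bound.
#' @param model_type `"pair"` or `"group"`.
#' @param day Day index to model; `NULL` pools all days (each onset still
#'   uses only its own day's history).
#' @param hour_window_s Short-window width in seconds.
#' @return Data frame of class `rem_design`: `stratum_id`, `model_type`,
#'   `day`, `triad_id`, `t`, `dyad`, `outcome` and the five statistic
#'   columns. Zero rows if no such onsets.
#' @export
build_strata <- function(stream, model_type = c("pair", "group"), day = NULL,
                         hour_window_s = 3600) {
  model_type <- match.arg(model_type)
  pieces <- lapply(split(seq_len(nrow(stream)), stream$triad_id), function(idx) {
    tri <- stream[idx, , drop = FALSE]
    build_strata_one(tri, model_type, day, hour_window_s)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(stratum_id = character(), model_type = character(),
                      day = integer(), triad_id = character(), t = numeric(),
                      dyad = integer(), outcome = integer(),
                      unfam = numeric(), pair_hour = numeric(),
                      pair_day = numeric(), group_hour = numeric(),
                      group_day = numeric())
  rownames(out) <- NULL
  class(out) <- c("rem_design", "data.frame")
  out
}

build_strata_one <- function(tri, model_type, day, hour_window_s) {
  on <- tri[tri$kind == "onset", , drop = FALSE]
  keep <- on$etype == model_type
  if (!is.null(day)) keep <- keep & on$day %in% day
  ev <- on[keep, , drop = FALSE]
  n <- nrow(ev)
  if (!n) return(NULL)

  # per-dyad sorted times of creditable prior events
  pair_t <- lapply(1:3, function(d) sort(on$t[on$etype == "pair" & on$dyad == d]))
  grp_t <- lapply(1:3, function(d)
    sort(on$t[on$etype == "group" &
                (on$dyad == d | (!is.na(on$base_dyad) & on$base_dyad == d))]))

  # windowed counts for all events x all dyads at once; cut points sit
  # between the integer event times, the hourly window open at the left
  tt <- ev$t; ds <- ev$day_start
  hi <- tt - 0.5
  lo_h <- pmax(tt - hour_window_s + 0.5, ds - 0.5)
  lo_d <- ds - 0.5
  cnt <- function(times, lo) matrix(vapply(1:3, function(d)
    findInterval(hi, times[[d]]) - findInterval(lo, times[[d]]),
    numeric(n)), nrow = n)
  ph <- cnt(pair_t, lo_h); pd <- cnt(pair_t, lo_d)
  gh <- cnt(grp_t, lo_h); gd <- cnt(grp_t, lo_d)

  if (model_type == "pair") {
    cand <- matrix(1:3, nrow = n, ncol = 3, byrow = TRUE)
  } else {
    cand <- matrix(0L, nrow = n, ncol = 2)
    for (i in seq_len(n)) cand[i, ] <- setdiff(1:3, ev$base_dyad[i])
  }
  k <- ncol(cand)
  idx <- rep(seq_len(n), each = k)
  cd <- as.integer(t(cand))
  pick <- cbind(idx, cd)
  data.frame(
    stratum_id = paste0(ev$triad_id[idx], ":", model_type, ":", tt[idx]),
    model_type = model_type, day = ev$day[idx], triad_id = ev$triad_id[idx],
    t = tt[idx], dyad = cd, outcome = as.integer(cd == ev$dyad[idx]),
    unfam = dyad_unfamiliar(cd),
    pair_hour = ph[pick], pair_day = pd[pick],
    group_hour = gh[pick], group_day = gd[pick])
}

#' Normalise the count statistics of a fitted dataset
#'
#' Each count column (`pair_hour`, `pair_day`, `group_hour`, `group_day`) is
#' centred and scaled to unit sample standard deviation across all rows of
#' the dataset, so effects are comparable in scale over the period. Constant
#' columns map to all zeros. The binary `unfam` contrast is left unscaled so
#' its estimate keeps its familiar-versus-unfamiliar interpretation.
#'
#' @param design A `rem_design` for one fitted dataset.
#' @return The design with scaled statistic columns; attribute `"scales"`
#'   holds the centre and sd used per column (sd `NA` for constants).
#' @export
normalize_statistics <- function(design) {
  cols <- c("pair_hour", "pair_day", "group_hour", "group_day")
  centers <- setNames(numeric(length(cols)), cols)
  sds <- setNames(rep(NA_real_, length(cols)), cols)
  for (cl in cols) {
    x <- design[[cl]]
    m <- mean(x); s <- sd(x)
    centers[cl] <- m
    if (length(x) >= 2 && is.finite(s) && s > 0) {
      sds[cl] <- s
      design[[cl]] <- (x - m) / s
    } else {
      design[[cl]] <- rep(0, length(x))
    }
  }
  attr(design, "scales") <- list(center = centers, sd = sds)
  design
}

#' Write / read a long-format design file
#'
#' @param design `rem_design` data frame.
#' @param path CSV path.
#' @return `path` invisibly; for the reader, the design.
#' @export
write_design <- function(design, path) {
  write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  out <- read.csv(path, colClasses = c(triad_id = "character",
                                       stratum_id = "character"))
  class(out) <- c("rem_design", "data.frame")
  out
}
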