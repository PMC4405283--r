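# Generative counterpart of the fitted model: synthetic triad studies in the
# logger dialect, with known parameters, so the full pipeline can be
# validated end-to-end (round trips, distributional checks, parameter
# recovery) without external data.

#' Configuration of the triad contact simulator
#'
#' Onset rates are `exp(beta0 + theta . s_d(t))` with the same five history
#' statistics the model fits (on the unnormalized count scale); active ties
#' dissolve at a covariate-free exponential hazard; from a two-tie
#' configuration the closing triangle onset occurs at rate
#' `exp(beta0_group)`. Defaults emulate a cattle-triad introduction study:
#' 36 triads observed for 5 days, the first day a partial day starting at
#' midday, roughly 60-90 pair onsets and a handful of group onsets per triad
#' per full day, and contacts lasting about a minute on average.
#'
#' @param beta0_pair,beta0_group Baseline log-rates (events per second) for
#'   pair and group onsets.
#' @param theta_pair,theta_group Length-5 effect vectors `(unfam, pair_hour,
#'   pair_day, group_hour, group_day)` on the unnormalized count scale.
#' @param offset_hazard Dissolution rate of an active tie (1/s).
#' @param horizon_days Number of observation days (day 1 is partial).
#' @param introduction_offset_s Seconds into day 1 at which the unfamiliar
#'   animal is introduced (calendar day-boundary mode).
#' @param n_triads Number of independent triads in a study.
#' @param seed Master seed; per-triad seeds are derived from it.
#' @param hour_window_s Short statistic window (must match the fit).
#' @param day_mode `"calendar"` or `"fixed"` day boundaries.
#' @param reciprocal_noise If `TRUE`, each contact is additionally reported
#'   by the partner's logger with up to +/-2 s boundary jitter, to exercise
#'   reciprocal compression (the exact round-trip guarantee is then waived).
#' @param intro_date Calendar date of introduction, day-first.
#' @param max_events Safety cap on events per triad.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(beta0_pair = -8, beta0_group = -7,
                       theta_pair = c(unfam = -0.5, pair_hour = 0.05,
                                      pair_day = 0.01, group_hour = 0.05,
                                      group_day = 0.01),
                       theta_group = c(unfam = 0.5, pair_hour = 0.05,
                                       pair_day = 0.01, group_hour = 0.05,
                                       group_day = 0.01),
                       offset_hazard = 1 / 60, horizon_days = 5L,
                       introduction_offset_s = 43200, n_triads = 36L,
                       seed = 1L, hour_window_s = 3600,
                       day_mode = c("calendar", "fixed"),
                       reciprocal_noise = FALSE,
                       intro_date = "09/03/2009", max_events = 500000L) {
  day_mode <- match.arg(day_mode)
  stopifnot(offset_hazard > 0, horizon_days >= 1,
            length(theta_pair) == 5, length(theta_group) == 5,
            n_triads >= 0, introduction_offset_s >= 0,
            introduction_offset_s < 86400)
  cfg <- list(beta0_pair = beta0_pair, beta0_group = beta0_group,
              theta_pair = setNames(as.numeric(theta_pair), EFFECTS),
              theta_group = setNames(as.numeric(theta_group), EFFECTS),
              offset_hazard = offset_hazard,
              horizon_days = as.integer(horizon_days),
              introduction_offset_s = introduction_offset_s,
              n_triads = as.integer(n_triads), seed = as.integer(seed),
              hour_window_s = hour_window_s, day_mode = day_mode,
              reciprocal_noise = reciprocal_noise,
              intro_date = intro_date, max_events = as.integer(max_events))
  class(cfg) <- "sim_config"
  cfg
}

sim_introduction_time <- function(config) {
  d <- as.POSIXct(config$intro_date, format = "%d/%m/%Y", tz = "UTC")
  d + config$introduction_offset_s
}

sim_horizon <- function(config, day_starts) {
  day_starts[length(day_starts)] +
    if (config$day_mode == "calendar" && length(day_starts) > 1)
      86400 else 86400 - config$introduction_offset_s * (config$day_mode == "calendar")
}

#' Simulate one triad
#'
#' @param config A [sim_config()].
#' @param triad_seed Seed for this triad's random stream.
#' @param triad_id Label for the triad.
#' @param animal_ids Raw logger IDs for coded animals 1:3.
#' @return A list of class `rem_sim`: `manifest`, `records` (logger-dialect
#'   data frame), `intervals`, `stream` (the true classified event stream),
#'   `day_starts`, `horizon`, `config`, `triad_seed`.
#' @export
simulate_triad <- function(config, triad_seed, triad_id = "T01",
                           animal_ids = c("101", "102", "103")) {
  introduction <- sim_introduction_time(config)
  manifest <- triad_manifest(triad_id, animal_ids, introduction)
  day_starts <- day_start_times(introduction, config$horizon_days,
                                config$day_mode)
  horizon <- sim_horizon(config, day_starts)

  set.seed(triad_seed)
  m <- sim_triad_core(config$beta0_pair, config$beta0_group,
                      config$theta_pair, config$theta_group,
                      config$offset_hazard, day_starts, horizon,
                      config$hour_window_s, config$max_events)

  etypes <- c(ONSET_TYPES, OFFSET_TYPES)
  # ties still open at the horizon close exactly on the final boundary, which
  # the calendar convention assigns to the next day; keep that boundary in
  # the day vector so truth and re-ingestion agree
  ds_all <- c(day_starts, horizon)
  day <- day_of(m[, "t"], ds_all)
  stream <- data.frame(
    triad_id = triad_id, t = m[, "t"], dyad = m[, "dyad"],
    kind = ifelse(m[, "kind"] == 0L, "onset", "offset"),
    etype = etypes[m[, "etype"]], base_dyad = m[, "base_dyad"],
    day = day, day_start = ds_all[pmin(day, length(ds_all))],
    stringsAsFactors = FALSE)
  class(stream) <- c("rem_stream", "data.frame")

  intervals <- stream_to_intervals(stream)
  records <- intervals_to_records(intervals, manifest)
  if (config$reciprocal_noise)
    records <- add_reciprocal_noise(records, intervals, manifest, horizon)

  structure(list(manifest = manifest, records = records,
                 intervals = intervals, stream = stream,
                 day_starts = ds_all, horizon = horizon,
                 config = config, triad_seed = triad_seed),
            class = "rem_sim")
}

# pair up each dyad's alternating onsets/offsets into intervals
stream_to_intervals <- function(stream) {
  pieces <- lapply(1:3, function(d) {
    on <- stream$t[stream$dyad == d & stream$kind == "onset"]
    off <- stream$t[stream$dyad == d & stream$kind == "offset"]
    if (length(on) != length(off))
      stop("unbalanced onsets/offsets for dyad ", d)
    if (!length(on)) return(NULL)
    data.frame(triad_id = stream$triad_id[1], dyad = d,
               onset_t = on, offset_t = off)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(triad_id = character(), dyad = integer(),
                      onset_t = integer(), offset_t = integer())
  out <- out[order(out$onset_t, out$dyad), ]
  rownames(out) <- NULL
  class(out) <- c("rem_intervals", "data.frame")
  out
}

# one logger row per interval, focal = lower-coded animal
intervals_to_records <- function(intervals, manifest) {
  ids <- names(manifest$id_map)
  mem <- do.call(rbind, DYAD_MEMBERS)[intervals$dyad, , drop = FALSE]
  start <- manifest$introduction + intervals$onset_t
  end <- manifest$introduction + intervals$offset_t
  data.frame(
    cow_id = ids[mem[, 1]],
    encountered_cow_id = ids[mem[, 2]],
    start_date = format(start, "%d/%m/%Y"),
    start_time = format(start, "%H:%M:%S"),
    end_date = format(end, "%d/%m/%Y"),
    end_time = format(end, "%H:%M:%S"),
    duration_s = intervals$offset_t - intervals$onset_t,
    stringsAsFactors = FALSE)
}

# duplicate each contact from the partner's logger with boundary jitter
add_reciprocal_noise <- function(records, intervals, manifest, horizon) {
  n <- nrow(intervals)
  if (!n) return(records)
  j1 <- sample(-2:2, n, replace = TRUE)
  j2 <- sample(-2:2, n, replace = TRUE)
  dup <- intervals
  dup$onset_t <- pmax(intervals$onset_t + j1, 0)
  dup$offset_t <- pmin(pmax(intervals$offset_t + j2, dup$onset_t + 2), horizon)
  twin <- intervals_to_records(dup, manifest)
  # partner reports it: swap the ID columns
  twin[, 1:2] <- twin[, 2:1]
  out <- rbind(records, twin)
  out[order(out$start_date, out$start_time), ]
}

#' Simulate a study of independent triads
#'
#' Per-triad seeds are `seed + 1, ..., seed + n_triads`.
#'
#' @param config A [sim_config()].
#' @return A list of class `rem_study` with elements `triads` (list of
#'   `rem_sim`) and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(config$seed + config$n_triads < 2^31)
  triads <- lapply(seq_len(config$n_triads), function(i) {
    simulate_triad(config, triad_seed = config$seed + i,
                   triad_id = sprintf("T%03d", i),
                   animal_ids = sprintf("%d0%d", i, 1:3))
  })
  structure(list(triads = triads, config = config), class = "rem_study")
}

#' Write a simulated study to disk
#'
#' Writes one logger-dialect contact file and one YAML manifest per triad,
#' plus a JSON truth file with the generative parameters and per-triad
#' seeds, all consumable by the ingestion pipeline and the CLI.
#'
#' @param study A `rem_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a data frame listing the files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- lapply(study$triads, function(tr) {
    id <- tr$manifest$triad_id
    cpath <- file.path(dir, paste0("contacts_", id, ".csv"))
    mpath <- file.path(dir, paste0("manifest_", id, ".yml"))
    write.csv(tr$records, cpath, row.names = FALSE, quote = FALSE)
    write_triad_manifest(tr$manifest, mpath)
    data.frame(triad_id = id, contacts = cpath, manifest = mpath)
  })
  cfg <- study$config
  truth <- list(
    beta0_pair = cfg$beta0_pair, beta0_group = cfg$beta0_group,
    theta_pair = as.list(cfg$theta_pair),
    theta_group = as.list(cfg$theta_group),
    offset_hazard = cfg$offset_hazard, horizon_days = cfg$horizon_days,
    seed = cfg$seed,
    triad_seeds = vapply(study$triads, function(tr) tr$triad_seed, 0))
  jsonlite::write_json(truth, file.path(dir, "truth_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(do.call(rbind, files))
}

#' Pool the true event streams of a study
#'
#' @param study A `rem_study`.
#' @return A pooled `rem_stream` across all triads.
#' @export
study_stream <- function(study) {
  out <- do.call(rbind, lapply(study$triads, function(tr) tr$stream))
  class(out) <- c("rem_stream", "data.frame")
  out
}
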