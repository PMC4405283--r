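# Ingestion of raw proximity-logger contact records.
#
# Loggers report one row per close-proximity contact: the focal animal, the
# encountered animal, start and end timestamps at 1 s resolution, and the
# contact duration in whole seconds. Both collars of a dyad may log the same
# encounter with slightly different boundaries, so per-dyad records are
# compressed to their union before any event-level analysis.

#' Construct a triad manifest
#'
#' A manifest maps raw logger animal IDs onto the coded triad (1, 2 =
#' familiar pair; 3 = the unfamiliar, newly introduced animal) and records
#' the introduction time, which becomes time zero of the analysis clock.
#'
#' @param triad_id Label for the triad.
#' @param animals Character vector of length 3: raw IDs for coded animals
#'   1, 2 and 3 in that order (the third is the unfamiliar animal).
#' @param introduction Introduction time: POSIXct, or a string in day-first
#'   `"dd/mm/YYYY HH:MM:SS"` form.
#' @return An object of class `triad_manifest`.
#' @export
triad_manifest <- function(triad_id, animals, introduction) {
  animals <- as.character(animals)
  if (length(animals) != 3L || anyDuplicated(animals))
    stop("a triad manifest needs exactly three distinct animals")
  if (is.character(introduction))
    introduction <- parse_logger_time(introduction)
  stopifnot(inherits(introduction, "POSIXct"), length(introduction) == 1L,
            !is.na(introduction))
  structure(
    list(triad_id = as.character(triad_id),
         id_map = setNames(1:3, animals),
         introduction = introduction),
    class = "triad_manifest")
}

#' @export
print.triad_manifest <- function(x, ...) {
  cat("Triad manifest", x$triad_id, "\n")
  cat("  familiar:  ", names(x$id_map)[1:2], "\n")
  cat("  unfamiliar:", names(x$id_map)[3], "\n")
  cat("  introduced:", format(x$introduction, "%d/%m/%Y %H:%M:%S"), "\n")
  invisible(x)
}

#' Read a triad manifest from a YAML file
#'
#' Expected keys: `triad_id`, `animals` (a map raw ID -> code 1:3, or a list
#' of the three raw IDs in code order) and `introduction` (day-first
#' timestamp string).
#'
#' @param path Path to the YAML manifest.
#' @return A [triad_manifest] object.
#' @export
read_triad_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("triad_id", "animals", "introduction"))
    if (is.null(y[[k]])) stop("manifest ", path, " is missing key '", k, "'")
  a <- y$animals
  if (!is.null(names(a)) && all(nzchar(names(a)))) {
    codes <- as.integer(unlist(a))
    if (!setequal(codes, 1:3)) stop("manifest animal codes must be exactly 1, 2, 3")
    ids <- names(a)[order(codes)]
  } else {
    ids <- as.character(unlist(a))
  }
  triad_manifest(y$triad_id, ids, as.character(y$introduction))
}

#' Write a triad manifest to YAML
#'
#' @param manifest A [triad_manifest].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triad_manifest <- function(manifest, path) {
  yaml::write_yaml(
    list(triad_id = manifest$triad_id,
         animals = as.list(setNames(1:3, names(manifest$id_map))),
         introduction = format(manifest$introduction, "%d/%m/%Y %H:%M:%S")),
    path)
  invisible(path)
}

# day-first by default; `dayfirst = FALSE` flips to month-first dialects
parse_logger_time <- function(x, dayfirst = TRUE) {
  fmt <- if (dayfirst) "%d/%m/%Y %H:%M:%S" else "%m/%d/%Y %H:%M:%S"
  as.POSIXct(x, format = fmt, tz = "UTC")
}

#' Parse a proximity-logger contact file
#'
#' Reads delimited text (comma or tab, auto-detected) with a header and the
#' seven logger columns in order: focal animal ID, encountered animal ID,
#' start date, start time, end date, end time, duration in seconds. The
#' duration column is recomputed from the timestamps and must agree; rows
#' naming animals absent from the manifest are rejected and reported via the
#' `"rejected"` attribute.
#'
#' @param path Path to the contact file (or a literal character vector of
#'   lines via `text =` semantics when `path` has length > 1).
#' @param manifest A [triad_manifest] used to validate animal IDs.
#' @param dayfirst Logical; are dates day-first (`9/03/2009` = 9 March)?
#' @return A data frame of class `rem_contacts` with columns `focal_id`,
#'   `partner_id`, `start`, `end` (POSIXct) and `duration_s`, attribute
#'   `"rejected"` holding any rows with unknown animals.
#' @export
parse_logger_file <- function(path, manifest, dayfirst = TRUE) {
  literal <- length(path) > 1L || grepl("\n", path[1]) ||
    (!file.exists(path[1]) && grepl("[,\t]", path[1]))
  if (!literal && !file.exists(path[1]))
    stop("cannot open logger file: ", path[1])
  lines <- if (literal) unlist(strsplit(path, "\n")) else readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) {   # header only, or nothing at all
    out <- data.frame(focal_id = character(), partner_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_s = integer())
    class(out) <- c("rem_contacts", "data.frame")
    attr(out, "rejected") <- out[0, ]
    return(out)
  }
  sep <- if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) > 0) "\t" else ","
  df <- read.csv(text = lines, sep = sep, header = TRUE,
                 colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 7L)
    stop("logger file must have 7 columns (focal, partner, start date/time, ",
         "end date/time, duration); got ", ncol(df))
  df <- df[, 1:7]
  names(df) <- c("focal_id", "partner_id", "start_date", "start_time",
                 "end_date", "end_time", "duration_s")

  start <- parse_logger_time(paste(df$start_date, df$start_time), dayfirst)
  end <- parse_logger_time(paste(df$end_date, df$end_time), dayfirst)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed timestamp in row ", bad[1], ": '",
         paste(df$start_date[bad[1]], df$start_time[bad[1]]), "' / '",
         paste(df$end_date[bad[1]], df$end_time[bad[1]]), "'")
  neg <- which(end < start)
  if (length(neg))
    stop("end before start in row ", neg[1])
  same <- which(df$focal_id == df$partner_id)
  if (length(same))
    stop("focal and encountered animal identical in row ", same[1])

  dur <- as.integer(round(as.numeric(difftime(end, start, units = "secs"))))
  printed <- suppressWarnings(as.integer(df$duration_s))
  mism <- which(!is.na(printed) & printed != dur)
  if (length(mism))
    stop("duration column disagrees with timestamps in row ", mism[1],
         " (printed ", printed[mism[1]], " s, timestamps give ",
         dur[mism[1]], " s)")

  out <- data.frame(focal_id = df$focal_id, partner_id = df$partner_id,
                    start = start, end = end, duration_s = dur,
                    stringsAsFactors = FALSE)
  known <- names(manifest$id_map)
  keep <- out$focal_id %in% known & out$partner_id %in% known
  rejected <- out[!keep, , drop = FALSE]
  if (nrow(rejected))
    message(nrow(rejected), " row(s) rejected: animals not in manifest ",
            manifest$triad_id)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rem_contacts", "data.frame")
  attr(out, "rejected") <- rejected
  out
}

#' Drop contacts shorter than a minimum duration
#'
#' Very short detections arise spuriously when two collars sit at the edge
#' of their detection zones, so contacts below a minimum length (default
#' 2 s, i.e. 1 s contacts removed) are discarded before analysis.
#'
#' @param records Contact records from [parse_logger_file()].
#' @param min_duration_s Minimum retained duration in seconds.
#' @return The records with `duration_s >= min_duration_s`, order preserved.
#' @export
filter_short_contacts <- function(records, min_duration_s = 2L) {
  out <- records[records$duration_s >= min_duration_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compress reciprocal records into per-dyad contact intervals
#'
#' The two collars of a dyad may both report one encounter, with boundaries
#' that need not agree. For each dyad the reported intervals are unioned:
#' overlapping or abutting intervals merge into maximal disjoint half-open
#' intervals `[onset, offset)` on the analysis clock (seconds since
#' introduction). Intervals ending at or before introduction are dropped;
#' intervals straddling it are clipped to start at 0.
#'
#' @param records Filtered contact records.
#' @param manifest A [triad_manifest]; supplies the ID coding and time zero.
#' @return Data frame of class `rem_intervals` with columns `triad_id`,
#'   `dyad` (code 1:3), `onset_t`, `offset_t` (integer seconds).
#' @export
compress_reciprocal <- function(records, manifest) {
  empty <- data.frame(triad_id = character(), dyad = integer(),
                      onset_t = integer(), offset_t = integer())
  class(empty) <- c("rem_intervals", "data.frame")
  if (nrow(records) == 0L) return(empty)

  code <- manifest$id_map
  a <- code[records$focal_id]; b <- code[records$partner_id]
  dyad <- dyad_code(a, b)
  t0 <- manifest$introduction
  on <- as.numeric(difftime(records$start, t0, units = "secs"))
  off <- as.numeric(difftime(records$end, t0, units = "secs"))
  keep <- off > 0
  dyad <- dyad[keep]; on <- pmax(on[keep], 0); off <- off[keep]
  if (!length(dyad)) return(empty)

  pieces <- lapply(sort(unique(dyad)), function(d) {
    i <- dyad == d
    m <- merge_intervals(on[i], off[i])
    data.frame(triad_id = manifest$triad_id, dyad = d,
               onset_t = m$onset, offset_t = m$offset)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$onset_t, out$dyad), ]
  rownames(out) <- NULL
  class(out) <- c("rem_intervals", "data.frame")
  out
}

# union of half-open intervals; abutting ([a,b) + [b,c)) also merge
merge_intervals <- function(onset, offset) {
  o <- order(onset, offset)
  onset <- onset[o]; offset <- offset[o]
  res_on <- onset[1]; res_off <- offset[1]
  k <- 1L
  for (i in seq_along(onset)[-1]) {
    if (onset[i] <= res_off[k]) {
      res_off[k] <- max(res_off[k], offset[i])
    } else {
      k <- k + 1L
      res_on[k] <- onset[i]; res_off[k] <- offset[i]
    }
  }
  list(onset = res_on, offset = res_off)
}

#' Separate simultaneous onsets by one-second shifts
#'
#' The ordinal event model needs a strict ordering of onsets. When k onsets
#' fall in the same second, the 2nd..kth (in ascending dyad-code order) are
#' shifted by +1..+(k-1) seconds. Offsets move only if the shift would leave
#' a non-positive interval. Shifting is iterated to a fixed point so onsets
#' end up globally distinct.
#'
#' @param intervals `rem_intervals` for one triad.
#' @return The intervals with globally distinct onset seconds.
#' @export
break_onset_ties <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals)
  for (pass in 1:1000) {
    o <- order(intervals$onset_t, intervals$dyad)
    intervals <- intervals[o, ]
    dup <- duplicated(intervals$onset_t)
    if (!any(dup)) break
    # within each tied second, shift the 2nd..kth by +1..+(k-1)
    shift <- stats::ave(seq_len(nrow(intervals)), intervals$onset_t,
                        FUN = seq_along) - 1L
    newon <- intervals$onset_t + shift
    grow <- newon >= intervals$offset_t
    intervals$offset_t[grow] <- intervals$offset_t[grow] + shift[grow]
    intervals$onset_t <- newon
  }
  if (anyDuplicated(intervals$onset_t))
    stop("could not separate simultaneous onsets")  # unreachable in practice
  rownames(intervals) <- NULL
  intervals
}

#' Write / read canonical contact intervals
#'
#' @param intervals `rem_intervals` data frame.
#' @param path Output CSV path.
#' @return `path` invisibly; for the reader, the intervals.
#' @export
write_intervals <- function(intervals, path) {
  write.csv(intervals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  out <- read.csv(path, colClasses = c(triad_id = "character"))
  class(out) <- c("rem_intervals", "data.frame")
  out
}

#' Write contact intervals back out in the logger dialect
#'
#' Each interval becomes one logger row (focal = the lower-coded animal),
#' timestamped on the original clock. Re-parsing the file through
#' [parse_logger_file()] and [compress_reciprocal()] reproduces the
#' intervals exactly.
#'
#' @param intervals `rem_intervals` for one triad.
#' @param manifest The triad's [triad_manifest].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logger_file <- function(intervals, manifest, path) {
  ids <- names(manifest$id_map)
  mem <- do.call(rbind, DYAD_MEMBERS)[intervals$dyad, , drop = FALSE]
  start <- manifest$introduction + intervals$onset_t
  end <- manifest$introduction + intervals$offset_t
  df <- data.frame(
    cow_id = ids[mem[, 1]],
    encountered_cow_id = ids[mem[, 2]],
    start_date = format(start, "%d/%m/%Y"),
    start_time = format(start, "%H:%M:%S"),
    end_date = format(end, "%d/%m/%Y"),
    end_time = format(end, "%H:%M:%S"),
    duration_s = intervals$offset_t - intervals$onset_t)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
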