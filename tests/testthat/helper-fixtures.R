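# shared fixtures, built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

demo_contacts_path <- function()
  system.file("extdata", "demo_contacts.csv", package = "remtriad")

demo_manifest <- function()
  read_triad_manifest(system.file("extdata", "demo_manifest.yml",
                                  package = "remtriad"))

# quick interval constructor for one triad on the analysis clock
iv <- function(dyad, onset, offset, triad_id = "X") {
  out <- data.frame(triad_id = triad_id, dyad = as.integer(dyad),
                    onset_t = as.numeric(onset), offset_t = as.numeric(offset))
  out <- out[order(out$onset_t, out$dyad), ]
  rownames(out) <- NULL
  class(out) <- c("rem_intervals", "data.frame")
  out
}

# a random valid micro event-stream: n_onsets nested/sequential contacts
random_micro_stream <- function(n_onsets = 4, t_max = 5000) {
  repeat {
    state <- integer(0)
    t <- 0
    rows <- list()
    open <- list()
    for (i in seq_len(n_onsets)) {
      t <- t + sample(30:400, 1)
      # close some open ties first, sometimes
      while (length(state) && runif(1) < 0.4) {
        d <- state[sample.int(length(state), 1)]
        rows[[length(rows) + 1]] <- data.frame(dyad = d, kind = "offset", t = t)
        state <- setdiff(state, d)
        t <- t + sample(10:200, 1)
      }
      if (length(state) == 3) break
      cand <- setdiff(1:3, state)
      d <- cand[sample.int(length(cand), 1)]
      rows[[length(rows) + 1]] <- data.frame(dyad = d, kind = "onset", t = t)
      state <- sort(c(state, d))
    }
    for (d in rev(state)) {   # close remaining, reverse order
      t <- t + sample(10:200, 1)
      rows[[length(rows) + 1]] <- data.frame(dyad = d, kind = "offset", t = t)
    }
    ev <- do.call(rbind, rows)
    ons <- ev[ev$kind == "onset", ]
    offs <- ev[ev$kind == "offset", ]
    ivs <- iv(ons$dyad, ons$t,
              vapply(seq_len(nrow(ons)), function(i) {
                cand <- offs$t[offs$dyad == ons$dyad[i] & offs$t > ons$t[i]]
                min(cand)
              }, 0))
    if (sum(ev$kind == "onset") >= 2) return(build_event_stream(ivs, 0))
  }
}

# brute-force statistic recount by exhaustive scan (independent oracle)
brute_stats <- function(stream, dyad, t, day_start, hour_window_s = 3600) {
  on <- stream[stream$kind == "onset", ]
  cred_pair <- 0; cred_group <- 0; cred_pair_h <- 0; cred_group_h <- 0
  for (i in seq_len(nrow(on))) {
    te <- on$t[i]
    if (te < day_start || te >= t) next
    in_hour <- te > t - hour_window_s   # open at the hour boundary
    if (on$etype[i] == "pair" && on$dyad[i] == dyad) {
      cred_pair <- cred_pair + 1
      if (in_hour) cred_pair_h <- cred_pair_h + 1
    }
    if (on$etype[i] == "group" &&
        (on$dyad[i] == dyad ||
         (!is.na(on$base_dyad[i]) && on$base_dyad[i] == dyad))) {
      cred_group <- cred_group + 1
      if (in_hour) cred_group_h <- cred_group_h + 1
    }
  }
  c(unfam = as.numeric(dyad %in% c(2, 3)), pair_hour = cred_pair_h,
    pair_day = cred_pair, group_hour = cred_group_h, group_day = cred_group)
}

# brute-force conditional-logit log-likelihood: product of per-stratum
# multinomial probabilities computed directly (no log-sum-exp machinery)
brute_loglik <- function(theta, design) {
  ll <- 0
  for (sid in unique(design$stratum_id)) {
    s <- design[design$stratum_id == sid, ]
    w <- exp(as.matrix(s[names(theta)]) %*% theta)
    ll <- ll + log(w[s$outcome == 1] / sum(w))
  }
  ll
}

# disjoint-union helper for building valid per-dyad interval fixtures
merge_sorted <- function(on, off) {
  m <- remtriad:::merge_intervals(on, off)
  list(on = m$onset, off = m$offset)
}

# tiny ingest convenience for tests
ingest_sim_triad <- function(tr, min_duration_s = 2) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  p <- file.path(d, "c.csv"); m <- file.path(d, "m.yml")
  write.csv(tr$records, p, row.names = FALSE, quote = FALSE)
  write_triad_manifest(tr$manifest, m)
  man <- read_triad_manifest(m)
  rec <- parse_logger_file(p, man)
  ivs <- break_onset_ties(
    compress_reciprocal(filter_short_contacts(rec, min_duration_s), man))
  build_event_stream(ivs, tr$day_starts)
}
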