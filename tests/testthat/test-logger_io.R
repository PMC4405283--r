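test_that("parsing the demo logger fragment recomputes durations from timestamps", {
  man <- demo_manifest()
  rec <- parse_logger_file(demo_contacts_path(), man)
  expect_s3_class(rec, "rem_contacts")
  expect_equal(nrow(rec), 6)
  expect_equal(rec$duration_s, c(1L, 183L, 16L, 110L, 16L, 3L))
  expect_equal(as.numeric(difftime(rec$end, rec$start, units = "secs")),
               c(1, 183, 16, 110, 16, 3))
})

test_that("parser rejects malformed and inconsistent rows, naming the row", {
  man <- demo_manifest()
  hdr <- "cow_id,encountered_cow_id,start_date,start_time,end_date,end_time,duration_s"
  expect_error(
    parse_logger_file(c(hdr, "1,2,9/03/2009,25:99:00,9/03/2009,18:00:00,10"), man),
    "malformed timestamp in row 1")
  expect_error(
    parse_logger_file(c(hdr, "1,2,9/03/2009,18:00:10,9/03/2009,18:00:00,10"), man),
    "end before start in row 1")
  expect_error(
    parse_logger_file(c(hdr, "1,2,9/03/2009,18:00:00,9/03/2009,18:00:30,29"), man),
    "duration column disagrees .* row 1")
  expect_error(
    parse_logger_file(c(hdr, "1,1,9/03/2009,18:00:00,9/03/2009,18:00:30,30"), man),
    "identical in row 1")
})

test_that("rows naming animals outside the manifest are rejected with a report", {
  man <- demo_manifest()
  hdr <- "cow_id,encountered_cow_id,start_date,start_time,end_date,end_time,duration_s"
  rows <- c(hdr,
            "1,2,9/03/2009,18:00:00,9/03/2009,18:00:30,30",
            "1,9,9/03/2009,18:01:00,9/03/2009,18:01:30,30")
  expect_message(rec <- parse_logger_file(rows, man), "rejected")
  expect_equal(nrow(rec), 1)
  expect_equal(nrow(attr(rec, "rejected")), 1)
  expect_equal(attr(rec, "rejected")$partner_id, "9")
})

test_that("empty source parses to an empty record collection", {
  man <- demo_manifest()
  hdr <- "cow_id,encountered_cow_id,start_date,start_time,end_date,end_time,duration_s"
  rec <- parse_logger_file(hdr, man)
  expect_equal(nrow(rec), 0)
  expect_equal(nrow(filter_short_contacts(rec)), 0)
})

test_that("the >=2 s minimum-duration filter keeps exactly the long-enough contacts", {
  man <- demo_manifest()
  rec <- parse_logger_file(demo_contacts_path(), man)
  kept <- filter_short_contacts(rec, 2)
  expect_equal(nrow(kept), 5)            # the 1 s record is removed
  expect_true(all(kept$duration_s >= 2))
  expect_true(2L %in% filter_short_contacts(rec, 2)$duration_s ||
                !any(rec$duration_s == 2L))  # boundary duration retained
  # a record of exactly the threshold is retained
  kept3 <- filter_short_contacts(rec, 3)
  expect_true(3L %in% kept3$duration_s)
  # everything below a huge threshold goes
  expect_equal(nrow(filter_short_contacts(rec, 1e6)), 0)
  # order preserved
  expect_equal(kept$start, rec$start[rec$duration_s >= 2])
})

test_that("reciprocal compression is the union of reported seconds", {
  man <- demo_manifest()
  rec <- parse_logger_file(demo_contacts_path(), man)
  ivs <- compress_reciprocal(filter_short_contacts(rec), man)
  # the duplicated 16 s record collapses to one interval
  expect_equal(nrow(ivs), 4)
  expect_equal(ivs$offset_t - ivs$onset_t, c(183, 16, 110, 3))

  # overlap merge oracle: covered seconds equal the union, second by second
  hdr <- "cow_id,encountered_cow_id,start_date,start_time,end_date,end_time,duration_s"
  rows <- c(hdr,
            "1,2,9/03/2009,18:51:14,9/03/2009,18:52:54,100",   # [100,200)
            "2,1,9/03/2009,18:52:04,9/03/2009,18:54:34,150",   # [150,300)
            "1,2,9/03/2009,18:54:34,9/03/2009,18:54:44,10",    # [300,310) abuts
            "1,2,9/03/2009,18:56:14,9/03/2009,18:57:54,100")   # [400,500)
  got <- compress_reciprocal(parse_logger_file(rows, man), man)
  expect_equal(got$onset_t, c(100, 400))
  expect_equal(got$offset_t, c(310, 500))
  covered <- function(x) {
    s <- rep(FALSE, 600)
    for (i in seq_len(nrow(x))) s[(x$onset_t[i] + 1):x$offset_t[i]] <- TRUE
    s
  }
  want <- rep(FALSE, 600)
  for (r in list(c(100, 200), c(150, 300), c(300, 310), c(400, 500)))
    want[(r[1] + 1):r[2]] <- TRUE
  expect_equal(covered(got), want)

  # idempotence: re-compressing the canonical intervals changes nothing
  rt <- tempfile(fileext = ".csv")
  write_logger_file(got, man, rt)
  again <- compress_reciprocal(parse_logger_file(rt, man), man)
  expect_equal(as.data.frame(again), as.data.frame(got))
})

test_that("records before introduction are dropped and straddlers clipped at zero", {
  man <- triad_manifest("X", c("1", "2", "3"), "09/03/2009 12:00:00")
  hdr <- "cow_id,encountered_cow_id,start_date,start_time,end_date,end_time,duration_s"
  rows <- c(hdr,
            "1,2,9/03/2009,11:00:00,9/03/2009,11:10:00,600",  # fully before
            "1,3,9/03/2009,11:59:30,9/03/2009,12:01:00,90",   # straddles
            "2,3,9/03/2009,12:05:00,9/03/2009,12:06:00,60")   # fully after
  ivs <- compress_reciprocal(parse_logger_file(rows, man), man)
  expect_equal(nrow(ivs), 2)
  expect_equal(ivs$onset_t, c(0, 300))
  expect_equal(ivs$offset_t, c(60, 360))
  expect_true(all(ivs$onset_t >= 0))
})

test_that("simultaneous onsets separate by +1 s in dyad order", {
  x <- iv(c(1, 2), c(500, 500), c(600, 700))
  y <- break_onset_ties(x)
  expect_equal(y$onset_t[y$dyad == 1], 500)
  expect_equal(y$onset_t[y$dyad == 2], 501)
  expect_equal(y$offset_t, c(600, 700))  # offsets untouched

  # three-way tie shifts +0, +1, +2 by dyad order
  z <- break_onset_ties(iv(c(3, 1, 2), c(80, 80, 80), c(200, 300, 400)))
  expect_equal(z$onset_t[order(z$dyad)], c(80, 81, 82))

  # no ties: unchanged
  w <- iv(c(1, 2), c(10, 20), c(15, 30))
  expect_equal(as.data.frame(break_onset_ties(w)), as.data.frame(w))

  # a shift that would null the interval drags the offset along
  v <- break_onset_ties(iv(c(1, 2), c(10, 10), c(50, 11)))
  expect_equal(v$onset_t[v$dyad == 2], 11)
  expect_equal(v$offset_t[v$dyad == 2], 12)
  expect_true(all(v$offset_t > v$onset_t))
})

test_that("tie-broken onsets are globally distinct and increasing per dyad", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    x <- iv(sample(1:3, n, replace = TRUE),
            on <- sample(0:40, n, replace = TRUE), on + sample(2:50, n))
    # make per-dyad intervals disjoint first (as compression guarantees)
    x <- do.call(rbind, lapply(split(x, x$dyad), function(d) {
      m <- merge_sorted(d$onset_t, d$offset_t)
      data.frame(triad_id = "X", dyad = d$dyad[1], onset_t = m$on, offset_t = m$off)
    }))
    class(x) <- c("rem_intervals", "data.frame")
    y <- break_onset_ties(x)
    expect_false(anyDuplicated(y$onset_t) > 0)
    for (d in 1:3) {
      o <- y$onset_t[y$dyad == d]
      expect_true(all(diff(o) > 0))
      expect_true(all(y$offset_t[y$dyad == d] > o))
    }
  }
})

test_that("intervals round-trip through the logger dialect exactly", {
  man <- demo_manifest()
  x <- iv(c(1, 2, 3, 1), c(0, 50, 120, 4000), c(30, 100, 200, 90000), "DEMO")
  p <- tempfile(fileext = ".csv")
  write_logger_file(x, man, p)
  back <- compress_reciprocal(
    filter_short_contacts(parse_logger_file(p, man)), man)
  expect_equal(as.data.frame(back), as.data.frame(x))
})
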