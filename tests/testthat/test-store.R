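test_that("journal append is durable, deduplicated, and offline-safe", {
  j <- ema_journal()
  rec <- make_record(1)
  append_record(j, rec)
  back <- store_records(j)
  expect_equal(nrow(back), 1)
  expect_equal(back$record_id, rec$record_id)
  expect_identical(back$payload[[1]], rec$payload)
  expect_false(back$synced)  # appended while offline: local, unsynced

  expect_error(append_record(j, rec), "duplicate record_id")
  expect_error(append_record(j, make_record(2)[-1]), "missing field")
  bad <- make_record(3); bad$categorization <- "X"
  expect_error(append_record(j, bad), "H, V0, V1")
})

test_that("sync is idempotent and resumes exactly after injected failures", {
  j <- filled_journal(5)
  remote <- ema_remote()
  r1 <- sync_journal(j, remote)
  expect_equal(r1$pushed, 5L)
  r2 <- sync_journal(j, remote)
  expect_equal(r2$pushed, 0L)

  # failure after 2 of 5: high-water mark holds, next sync pushes the 3
  j2 <- filled_journal(5)
  remote2 <- ema_remote()
  f1 <- sync_journal(j2, remote2, fail_after = 2)
  expect_equal(f1$pushed, 2L)
  expect_true(f1$failed)
  f2 <- sync_journal(j2, remote2)
  expect_equal(f2$pushed, 3L)
  expect_identical(store_records(remote2)$record_id,
                   store_records(j2)$record_id)

  expect_equal(sync_journal(ema_journal(), ema_remote())$pushed, 0L)
})

test_that("replaying a journal reproduces the remote under any failure prefix", {
  j <- filled_journal(8)
  # remote assembled across an arbitrary sequence of partial syncs
  battered <- ema_remote()
  for (fa in c(1, 0, 3, 2, Inf)) sync_journal(j, battered, fail_after = fa)
  # remote assembled in one clean pass from a journal file round-trip
  path <- withr::local_tempfile(fileext = ".ndjson")
  write_journal(j, path)
  replayed <- read_journal(path)
  clean <- ema_remote()
  sync_journal(replayed, clean)
  b <- store_records(battered); c2 <- store_records(clean)
  expect_identical(b$record_id, c2$record_id)
  expect_identical(b[, setdiff(names(b), "payload")],
                   c2[, setdiff(names(c2), "payload")])
})

test_that("filtering is conjunctive, order-insensitive, and canonical", {
  j <- ema_journal()
  grid <- expand.grid(patient = c("P001", "P002"),
                      type = c("scales", "fit_test"),
                      session = c("on_waking", "evening"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    r <- make_record(i, patient = grid$patient[i], type = grid$type[i],
                     session = grid$session[i], day = (i %% 3) + 1L)
    if (r$record_type == "fit_test") {
      r$hand <- c("left", "right")[(i %% 2) + 1]
      r$payload <- list(scores = score_trial(valid_fit_record()$trials[[1]]))
    }
    append_record(j, r)
  }

  got <- filter_records(j, patient = "P001", record_type = "fit_test",
                        hand = "left")
  # brute-force list comprehension over the raw records
  want <- Filter(function(r) {
    r$patient_id == "P001" && r$record_type == "fit_test" &&
      identical(r$hand, "left")
  }, j$records)
  expect_setequal(got$record_id, vapply(want, `[[`, "", "record_id"))

  # conjunction is order-insensitive: filtering stepwise matches one call
  stepwise <- filter_records(
    filter_records(filter_records(j, hand = "left"), record_type = "fit_test"),
    patient = "P001")
  expect_identical(got$record_id, stepwise$record_id)

  # empty filter returns everything in canonical order
  all_recs <- filter_records(j)
  expect_equal(nrow(all_recs), nrow(grid))
  key <- order(all_recs$patient_id, all_recs$date,
               match(all_recs$session_kind,
                     c("on_waking", "after_medications", "afternoon",
                       "evening", "nap")),
               all_recs$created_at)
  expect_equal(key, seq_len(nrow(all_recs)))

  expect_equal(nrow(filter_records(j, categorization = "V0")), 0)
  expect_equal(nrow(filter_records(j, from = "2018-03-08", to = "2018-03-08")),
               sum(store_records(j)$date == as.Date("2018-03-08")))
})

test_that("CSV export round-trips byte-identically, quoting embedded commas", {
  j <- ema_journal()
  for (i in 1:3) {
    r <- make_record(i, patient = if (i == 2) "Smith, John" else "P001")
    append_record(j, r)
  }
  path1 <- withr::local_tempfile(fileext = ".csv")
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_records_csv(store_records(j), path1)

  txt <- readLines(path1)
  expect_equal(length(txt), 1 + 3 * 2)  # header + 3 records x 2 answers
  expect_true(any(grepl("\"Smith, John\"", txt)))

  re <- read_records_csv(path1)
  expect_equal(unique(re$patient_id), c("P001", "Smith, John"))
  export_records_csv(re, path2)
  expect_identical(readLines(path2), txt)

  mixed <- dplyr::bind_rows(store_records(j),
                            store_records(filled_journal(1)) |>
                              dplyr::mutate(record_type = "anchor"))
  expect_error(export_records_csv(mixed, path2), "homogeneous")
})

test_that("fit-test exports carry the portal's per-hand score columns", {
  j <- ema_journal()
  tr <- valid_fit_record()$trials
  for (i in 1:2) {
    r <- make_record(i, type = "fit_test")
    r$hand <- tr[[i]]$hand
    r$payload <- list(scores = score_trial(tr[[i]]))
    append_record(j, r)
  }
  path <- withr::local_tempfile(fileext = ".csv")
  export_records_csv(store_records(j), path)
  re <- read_records_csv(path)
  expect_equal(names(re)[1:8],
               c("patient_id", "date", "session_kind", "hand",
                 "kinesia_score", "akinesia_time", "incoordination_score",
                 "dysmetria_score"))
  expect_setequal(re$hand, c("left", "right"))
  expect_equal(as.numeric(re$kinesia_score), c(20, 20))
})
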