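test_that("anchors schedule sessions at the protocol offsets", {
  st <- morning_state(wake = ts("2018-03-06 07:00:00"))
  ow <- st$instances[st$instances$kind == "on_waking", ]
  expect_equal(ow$due_at, ts("2018-03-06 07:30:00"))

  st <- ingest_anchor(st, "first_med_intake", ts("2018-03-06 08:00:00"), 1L)
  am <- st$instances[st$instances$kind == "after_medications", ]
  expect_equal(am$due_at, ts("2018-03-06 09:00:00"))
  # the med anchor truncates the on-waking window
  ow <- st$instances[st$instances$kind == "on_waking", ]
  expect_equal(ow$expires_at, ts("2018-03-06 08:00:00"))

  st <- ingest_anchor(st, "nap_end", ts("2018-03-06 15:10:00"), 1L)
  nap <- st$instances[st$instances$kind == "nap", ]
  expect_equal(nap$due_at, ts("2018-03-06 15:10:00"))

  # anchors must move forward within a day
  expect_error(
    ingest_anchor(st, "nap_end", ts("2018-03-06 15:00:00"), 1L),
    "not after")
  expect_error(ingest_anchor(st, "wake_time", Sys.time(), 1L), "timezone")
})

test_that("next_due picks the earliest due session, nap last on ties", {
  st <- morning_state()
  expect_null(next_due(st, ts("2018-03-06 07:10:00")))  # nothing due yet
  expect_equal(next_due(st, ts("2018-03-06 07:45:00"))$kind, "on_waking")

  # afternoon and nap due at the same instant: fixed kind order wins
  st2 <- new_scheduler(default_protocol("v2.0"), "PT2", tz = TZ)
  st2 <- ingest_anchor(st2, "afternoon_dose_due", ts("2018-03-06 15:00:00"), 1L)
  st2 <- ingest_anchor(st2, "nap_end", ts("2018-03-06 15:00:00"), 1L)
  expect_equal(next_due(st2, ts("2018-03-06 15:00:00"))$kind, "afternoon")

  # alpha has no automatic flow; list_selectable serves instead
  al <- new_scheduler(default_protocol("alpha"), "PT3", tz = TZ)
  al <- ingest_anchor(al, "wake_time", ts("2018-03-06 07:00:00"), 1L)
  expect_error(next_due(al, ts("2018-03-06 07:45:00")), "list_selectable")
  expect_gte(nrow(list_selectable(al, ts("2018-03-06 07:45:00"))), 1)
})

test_that("expiry uses a half-open window and is idempotent", {
  st <- morning_state()
  exp_at <- st$instances$expires_at[st$instances$kind == "on_waking"]
  r1 <- expire_sessions(st, exp_at)   # now == expires_at -> expired
  expect_true("on_waking" %in% r1$expired$kind)
  r2 <- expire_sessions(r1$state, exp_at)
  expect_equal(nrow(r2$expired), 0)
  expect_equal(
    r2$state$instances$state[r2$state$instances$kind == "on_waking"],
    "expired")
})

test_that("only fully completed task records are stored", {
  p <- default_protocol("v2.0")
  st <- morning_state(p)
  now <- ts("2018-03-06 07:40:00")
  id <- st$instances$id[st$instances$kind == "on_waking"]

  full <- full_answers(p, "subjective_scales")
  st2 <- complete_task(st, id, "subjective_scales",
                       list(answers = full), now)
  recs <- scheduler_records(st2)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$completed_at, now)

  # 10 of 11 answers: rejected, nothing stored
  expect_error(
    complete_task(st, id, "subjective_scales",
                  list(answers = full[-1, ]), now),
    "10 of 11")
  # an out-of-domain answer in an otherwise complete set is also partial
  bad <- full
  bad$value[[1]] <- 99L
  expect_error(
    complete_task(st, id, "subjective_scales", list(answers = bad), now),
    "outside range")

  # completion after expiry is rejected with reason "expired"
  late <- ts("2018-03-06 11:00:00")
  expect_error(
    complete_task(st, id, "subjective_scales", list(answers = full), late),
    "expired")

  # a fit test needs a valid trial for each hand
  one_hand <- valid_fit_record()
  one_hand$trials <- one_hand$trials[1]
  expect_error(
    complete_task(st, id, "fit_test", one_hand, now),
    "per hand")
  st3 <- complete_task(st, id, "fit_test", valid_fit_record(), now)
  expect_equal(scheduler_records(st3)$task_kind, "fit_test")
})

test_that("the diary is once daily with carryover prompting", {
  p <- default_protocol("v2.0")
  st <- morning_state(p)
  now <- ts("2018-03-06 07:40:00")
  id <- st$instances$id[st$instances$kind == "on_waking"]

  expect_true(diary_pending(st, 1L))
  st <- complete_task(st, id, "sleep_diary",
                      list(answers = full_answers(p, "sleep_diary")), now)
  expect_false(diary_pending(st, 1L))
  expect_true(diary_pending(st, 2L))  # a new day resets the prompt

  # a second diary the same day is rejected, even in another session
  st <- ingest_anchor(st, "first_med_intake", ts("2018-03-06 08:00:00"), 1L)
  id2 <- st$instances$id[st$instances$kind == "after_medications"]
  expect_error(
    complete_task(st, id2, "sleep_diary",
                  list(answers = full_answers(p, "sleep_diary")),
                  ts("2018-03-06 09:10:00")),
    "already completed today")
})

test_that("replay is deterministic and events never regress state", {
  sim <- small_sim()
  pid <- sim$cohort$patient_id[1]
  ev <- sim$events[sim$events$patient_id == pid, ]
  r1 <- replay_events(sim$protocol, ev, pid, tz = TZ)
  r2 <- replay_events(sim$protocol, ev, pid, tz = TZ)
  expect_identical(r1$state, r2$state)
  expect_identical(serialize(r1$state, NULL), serialize(r2$state, NULL))
  expect_equal(nrow(r1$log), 0)

  # partition: every instance is in exactly one state
  states <- r1$state$instances$state
  expect_true(all(states %in% c("pending", "open", "completed", "expired")))

  # monotone clock: sweeping far forward expires the rest, un-completes none
  n_completed <- sum(states == "completed")
  sweep <- expire_sessions(r1$state, ts("2030-01-01 00:00:00"))$state
  expect_equal(sum(sweep$instances$state == "completed"), n_completed)
  expect_true(all(sweep$instances$state %in% c("completed", "expired")))
})

test_that("a simulated run's instances account for the full task ledger", {
  nights <- 5
  sim <- small_sim(n_patients = 2, nights = nights, seed = 11)
  ledger <- expected_tasks(sim$protocol)
  for (pid in sim$cohort$patient_id) {
    ev <- sim$events[sim$events$patient_id == pid, ]
    st <- replay_events(sim$protocol, ev, pid, tz = TZ)$state
    st <- expire_sessions(st, max(ev$at) + 86400)$state
    non_nap <- st$instances[st$instances$kind != "nap", ]
    # every scheduled slot ends completed or expired, matching the ledger
    expect_equal(nrow(non_nap), ledger$subjective_scales)
    expect_true(all(non_nap$state %in% c("completed", "expired")))
    recs <- scheduler_records(st)
    expect_lte(sum(recs$task_kind == "sleep_diary"), nights)
  }
})

test_that("a fully non-adherent day contributes zero completions", {
  sim <- small_sim(n_patients = 1, nights = 2, seed = 3,
                   adherence = c(on_waking = 0, after_medications = 0,
                                 afternoon = 0, evening = 0))
  ev <- sim$events[sim$events$patient_id == "P001", ]
  st <- replay_events(sim$protocol, ev, "P001", tz = TZ)$state
  st <- expire_sessions(st, max(ev$at) + 86400)$state
  expect_equal(nrow(scheduler_records(st)), 0)
  expect_true(all(st$instances$state == "expired"))
})
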