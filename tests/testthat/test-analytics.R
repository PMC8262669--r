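test_that("compliance reproduces printed-style percentages exactly", {
  expect_identical(compliance(5707, 6420), 88.89)
  expect_identical(compliance(2070, 2356), 87.86)
  expect_identical(compliance(2899, 3224), 89.92)
  expect_identical(compliance(0, 100), 0)
  expect_identical(compliance(100, 100), 100)
  expect_error(compliance(5, 0))
  expect_error(compliance(7, 5))
})

test_that("percent rounding is half-up, not banker's", {
  expect_equal(round_half_up(0.125, 2), 0.13)   # base round() gives 0.12
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(88.885, 2), 88.89)
  # integer satisfaction percents
  expect_equal(round_half_up(100 * 25 / 26), 96)
  expect_equal(round_half_up(100 * 8 / 26), 31)
})

test_that("compare_proportions matches the textbook pooled z formula", {
  # independent closed-form recomputation, kept separate from the package
  pooled_z <- function(x1, n1, x2, n2) {
    p <- (x1 + x2) / (n1 + n2)
    ((x2 / n2) - (x1 / n1)) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  }
  cases <- list(c(50, 100, 50, 100), c(0, 10, 10, 10),
                c(2070, 2356, 2899, 3224), c(12, 40, 30, 45))
  for (cs in cases) {
    got <- compare_proportions(cs[1], cs[2], cs[3], cs[4])
    z <- pooled_z(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got$z, z, tolerance = 1e-10)
    expect_equal(got$p_one_tailed, pnorm(z, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_equal(compare_proportions(50, 100, 50, 100)$p_one_tailed, 0.5)
  expect_lt(compare_proportions(0, 10, 10, 10)$p_one_tailed, 0.001)

  # agreement with the reference implementation: z^2 equals the
  # uncorrected chi-squared statistic and p-values match one-sided
  pt <- prop.test(c(2899, 2070), c(3224, 2356),
                  alternative = "greater", correct = FALSE)
  got <- compare_proportions(2070, 2356, 2899, 3224)
  expect_equal(got$z^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(got$p_one_tailed, pt$p.value, tolerance = 1e-10)

  # one-tailed direction is antisymmetric
  ab <- compare_proportions(30, 50, 40, 50)
  ba <- compare_proportions(40, 50, 30, 50)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_one_tailed + ba$p_one_tailed, 1)

  # the continuity-corrected variant shrinks |z|
  cc <- compare_proportions(30, 50, 40, 50, correct = TRUE)
  expect_lt(cc$z, ab$z)
})

test_that("satisfaction summaries use integer half-up percents and pooling", {
  # willingness to reuse: 17 same period, 8 longer, 1 would not
  reuse <- tibble::tibble(
    respondent = sprintf("R%02d", 1:26), question_id = "reuse",
    group = "general", level = c(rep(3, 17), rep(4, 8), 1)
  )
  s <- satisfaction_summary(reuse)
  tq <- s$per_question
  expect_equal(tq$percent[tq$level == 3], 65)
  expect_equal(tq$percent[tq$level == 4], 31)
  expect_equal(sum(tq$count[tq$level >= 3]), 25)
  expect_equal(round_half_up(100 * sum(tq$count[tq$level >= 3]) / 26), 96)

  # usability: 3 questions pooled over 26 respondents -> denominator 78
  lv <- c(rep(4, 55), rep(3, 19), rep(2, 3), 1)
  usab <- tibble::tibble(
    respondent = rep(sprintf("R%02d", 1:26), 3),
    question_id = rep(c("u1", "u2", "u3"), each = 26),
    group = "usability", level = lv
  )
  g <- satisfaction_summary(usab)$per_group
  expect_equal(g$pooled_n[1], 78L)
  expect_equal(g$percent[g$level == 4], 71)  # 55/78 no difficulty
  expect_equal(g$percent[g$level == 3], 24)
  expect_equal(g$percent[g$level == 2], 4)
  expect_equal(g$percent[g$level == 1], 1)

  # degenerate: everyone at one level
  uni <- tibble::tibble(respondent = sprintf("R%d", 1:5),
                        question_id = "q", level = 4)
  expect_equal(satisfaction_summary(uni)$per_question$percent, 100)

  expect_error(satisfaction_summary(
    tibble::tibble(respondent = c("a", "a"), question_id = "q",
                   level = c(1, 2))), "one response")
  expect_error(satisfaction_summary(
    tibble::tibble(respondent = "a", question_id = "q", level = 5)))
})

test_that("workload averages day sums within then across patients", {
  d <- tibble::tibble(
    patient_id = c("A", "A", "A", "B"),
    study_day = c(1L, 1L, 2L, 1L),
    duration_min = c(3, 4, 4, 10)
  )
  w <- workload_summary(d)
  # A: day sums 7 and 4 -> 5.5; B: 10 -> cohort mean 7.75
  expect_equal(w$per_patient$mean_daily_min, c(5.5, 10))
  expect_equal(w$cohort_mean_min, 7.75)

  one_day <- workload_summary(tibble::tibble(
    patient_id = "A", study_day = 1L, duration_min = c(3, 4, 4)))
  expect_equal(one_day$cohort_mean_min, 11)

  empty <- workload_summary(tibble::tibble(patient_id = character(),
                                           study_day = integer(),
                                           duration_min = numeric()))
  expect_true(is.na(empty$cohort_mean_min))

  # start/end timestamps are an equivalent input
  spans <- tibble::tibble(
    patient_id = "A", study_day = 1L,
    started_at = ts("2018-03-06 08:00:00"),
    ended_at = ts("2018-03-06 08:11:00"))
  expect_equal(workload_summary(spans)$cohort_mean_min, 11)
})

test_that("compliance_report counts match brute force on a simulated store", {
  sim <- small_sim(n_patients = 3, nights = 4, seed = 13)
  run <- run_study(sim)
  tasks <- run_tasks(run)
  rep <- compliance_report(tasks, sim$cohort, sim$protocol)

  ledger <- expected_tasks(sim$protocol)
  n_pat <- nrow(sim$cohort)
  expect_equal(rep$overall$expected, ledger$total_tasks * n_pat)

  # brute-force recount of completions from the raw task table
  sched <- expected_schedule(sim$protocol)
  in_window <- mapply(function(d, s) any(sched$study_day == d & sched$kind == s),
                      tasks$study_day, tasks$session_kind)
  for (tk in c("subjective_scales", "fit_test", "sleep_diary")) {
    expect_equal(
      sum(rep$cells$completed[rep$cells$task_kind == tk]),
      sum(tasks$task_kind == tk & in_window & tasks$session_kind != "nap"))
  }
  expect_equal(rep$overall$completed, sum(in_window))
  expect_equal(rep$overall$percent,
               round_half_up(100 * sum(in_window) / rep$overall$expected, 2))

  # full adherence scores 100.00 everywhere
  perfect <- small_sim(n_patients = 2, nights = 3, seed = 5,
                       adherence = c(on_waking = 1, after_medications = 1,
                                     afternoon = 1, evening = 1),
                       decline = 1, diary_p = 1)
  prep <- compliance_report(run_tasks(run_study(perfect)), perfect$cohort, perfect$protocol)
  expect_equal(prep$overall$percent, 100)
  expect_true(all(prep$cells$percent == 100))
})

test_that("tidiers and autoplot expose report internals consistently", {
  sim <- small_sim(n_patients = 2, nights = 3, seed = 21)
  rep <- compliance_report(run_tasks(run_study(sim)), sim$cohort, sim$protocol)
  expect_identical(tidy(rep), rep$cells)
  expect_equal(glance(rep)$percent, rep$overall$percent)
  expect_s3_class(autoplot(rep), "ggplot")

  tr <- average_target_ratio(sim$touches, sim$protocol)
  expect_identical(tidy(tr), tr$per_patient)
  expect_equal(glance(tr)$cohort_mean, tr$cohort_mean)
  expect_s3_class(autoplot(tr), "ggplot")
})
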