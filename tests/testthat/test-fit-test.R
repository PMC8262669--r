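mk_trial <- function(down, up, key = NULL, hand = "right") {
  key <- key %||% rep(c("s", ";"), length.out = length(down))
  fit_trial(tibble::tibble(key = key, down_ms = down, up_ms = up),
            hand = hand)
}

test_that("trial validation rejects malformed streams", {
  expect_true(validate_trial(random_trial(40)))
  expect_match(attr(validate_trial(mk_trial(numeric(0), numeric(0), key = character(0))),
                    "reason"), "no keystrokes")
  expect_match(attr(validate_trial(mk_trial(c(0, 31000), c(100, 31100))),
                    "reason"), "outside window")
  expect_match(attr(validate_trial(mk_trial(c(0, 50), c(100, 150))),
                    "reason"), "overlapping")
  expect_match(attr(validate_trial(mk_trial(c(500, 0), c(600, 100))),
                    "reason"), "not ordered")
  expect_match(attr(validate_trial(mk_trial(0, -1)), "reason"),
               "key-up before")
  expect_error(score_trial(mk_trial(c(0, 31000), c(100, 31100))), "rejected")
})

test_that("the four scores match their defining formulas on hand cases", {
  # dwell times {100, 200} -> mean 150; travel {100, 300} -> var 20000
  tr <- mk_trial(down = c(0, 200, 700), up = c(100, 400, 800))
  expect_equal(kinesia_score(tr), 3L)
  expect_equal(akinesia_time(tr), mean(c(100, 200, 100)))
  expect_equal(incoordination_score(tr), stats::var(c(100, 300)))
  expect_equal(incoordination_score(tr), 20000)

  expect_equal(kinesia_score(mk_trial(0, 85)), 1L)
  expect_equal(akinesia_time(mk_trial(0, 85)), 85)
  # fewer than 3 keystrokes: incoordination undefined
  expect_true(is.na(incoordination_score(mk_trial(c(0, 500), c(100, 600)))))
  # constant travel -> zero variance
  reg <- mk_trial(down = seq(0, 2000, by = 500),
                  up = seq(0, 2000, by = 500) + 100)
  expect_equal(incoordination_score(reg), 0)

  # 42 alternating key-downs counts 42
  n <- 42
  expect_equal(kinesia_score(mk_trial(seq(0, by = 600, length.out = n),
                                      seq(0, by = 600, length.out = n) + 90)),
               42L)
})

test_that("dysmetria weights target 0, adjacent 1, distant 2", {
  on_target <- mk_trial(seq(0, by = 600, length.out = 10),
                        seq(0, by = 600, length.out = 10) + 80)
  expect_equal(dysmetria_score(on_target), 0)

  keys <- rep(c("s", ";"), 5)
  keys[4] <- "a"  # adjacent to "s"
  one_adj <- mk_trial(seq(0, by = 600, length.out = 10),
                      seq(0, by = 600, length.out = 10) + 80, key = keys)
  expect_equal(dysmetria_score(one_adj), 0.1)

  distant <- mk_trial(seq(0, by = 600, length.out = 10),
                      seq(0, by = 600, length.out = 10) + 80,
                      key = rep("m", 10))
  expect_equal(dysmetria_score(distant), 2)
})

test_that("scores are invariant to time shift and unrelated kinematics", {
  withr::local_seed(421)
  for (i in 1:20) {
    tr <- random_trial()
    shifted <- tr
    shift <- 29999 - max(tr$events$up_ms)  # keep inside the window
    shifted$events$down_ms <- tr$events$down_ms + shift
    shifted$events$up_ms <- tr$events$up_ms + shift
    s0 <- score_trial(tr); s1 <- score_trial(shifted)
    expect_equal(s1$kinesia_score, s0$kinesia_score)
    expect_equal(s1$akinesia_time, s0$akinesia_time)
    expect_equal(s1$incoordination_score, s0$incoordination_score)
    expect_equal(s1$dysmetria_score, s0$dysmetria_score)
  }

  # kinesia ignores dwell; incoordination ignores a constant travel offset
  base <- mk_trial(down = c(0, 500, 1100, 1500), up = c(90, 560, 1190, 1580))
  squashed <- mk_trial(down = base$events$down_ms,
                       up = base$events$down_ms + 10)
  expect_equal(kinesia_score(squashed), kinesia_score(base))

  tt <- c(150, 260, 90)
  build_from_travel <- function(travel, dwell = 100) {
    down <- cumsum(c(0, travel + dwell))
    mk_trial(down, down + dwell)
  }
  expect_equal(
    incoordination_score(build_from_travel(tt + 500)),
    incoordination_score(build_from_travel(tt))
  )
})

test_that("score_trial equals the naive single-pass oracle on random trials", {
  withr::local_seed(99)
  for (i in 1:120) {
    tr <- random_trial()
    want <- oracle_score(tr)
    got <- score_trial(tr)
    expect_equal(got$kinesia_score, want$ks)
    expect_equal(got$akinesia_time, want$at)
    expect_equal(got$incoordination_score, want$is)
    expect_equal(got$dysmetria_score, want$ds)
  }
})

test_that("the scorer recovers generator kinematics within 3 standard errors", {
  withr::local_seed(2024)
  n_trials <- 200

  # dwell ~ N(120, 10^2): mean akinesia time recovers 120
  at <- vapply(seq_len(n_trials), function(i) {
    akinesia_time(tapping_stream(rate_hz = 1.7, dwell_mean_ms = 120,
                                 dwell_sd_ms = 10, travel_sd_ms = 30))
  }, 0)
  expect_lt(abs(mean(at) - 120), 3 * sd(at) / sqrt(n_trials))

  # travel sd 30 ms: mean incoordination recovers 900 ms^2
  is <- vapply(seq_len(n_trials), function(i) {
    incoordination_score(tapping_stream(rate_hz = 1.7, dwell_mean_ms = 120,
                                        dwell_sd_ms = 10, travel_sd_ms = 30))
  }, 0)
  expect_lt(abs(mean(is) - 900), 3 * sd(is) / sqrt(n_trials))

  # mean inter-tap interval 600 ms -> about 50 strikes per 30 s
  ks <- vapply(seq_len(n_trials), function(i) {
    kinesia_score(tapping_stream(rate_hz = 1000 / 600, dwell_mean_ms = 120,
                                 dwell_sd_ms = 10, travel_sd_ms = 30))
  }, 0L)
  expect_lt(abs(mean(ks) - 50), 3 * sqrt(50 / n_trials))

  # no injected errors -> dysmetria identically zero
  expect_true(all(vapply(1:20, function(i) {
    dysmetria_score(tapping_stream(error_rate = 0))
  }, 0) == 0))
})
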