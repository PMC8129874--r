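test_that("build_default_roster honors category counts and MET anchors", {
  roster <- build_default_roster(32, 4)
  cats <- vapply(roster, function(a) a$category, character(1))
  expect_length(roster, 32)
  expect_identical(sum(cats == "sedentary"), 4L)
  expect_identical(sum(cats == "locomotion"), 6L)
  expect_identical(sum(cats == "lifestyle"), 22L) # 32 - 4 - 6
  mets <- vapply(roster, function(a) a$true_met_mean, numeric(1))
  expect_true(all(mets[cats == "sedentary"] < 1.6))
  expect_true(all(mets[cats == "locomotion"] >= 2.5))
  expect_true(all(mets >= 0.9))
  # exactly one category flag per activity
  for (a in roster)
    expect_identical(sum(a$is_sedentary, a$is_locomotion, a$is_lifestyle), 1L)
  # minimal roster
  tiny <- build_default_roster(2, 1)
  expect_identical(sum(vapply(tiny, function(a) a$is_sedentary, logical(1))), 1L)
  expect_error(build_default_roster(4, 0), class = "placewear_argument_error")
  expect_error(build_default_roster(4, 4), class = "placewear_argument_error")
})

test_that("roster templates satisfy the signal invariants", {
  roster <- build_default_roster(32, 4)
  for (a in roster) {
    expect_true(a$duration_range[1] >= 360 && a$duration_range[2] <= 480)
    for (pl in names(PLACEMENTS)) {
      tpl <- a$templates[[pl]]
      expect_equal(sum(tpl$gravity_axis^2), 1, tolerance = 1e-9)
      for (comp in tpl$periodic) expect_gte(comp$amp, 0)
    }
    if (a$is_locomotion) {
      for (pl in c("ankle", "hip", "thigh")) {
        freqs <- vapply(a$templates[[pl]]$periodic, `[[`, numeric(1), "freq")
        expect_true(any(freqs >= 0.6 & freqs <= 2.5))
      }
    }
  }
})

test_that("simulate_session produces the stated sample count and is seeded", {
  roster <- fixture_roster()
  p <- participant_spec("P01", amplitude_factor = 1.1)
  loco <- roster[[which(vapply(roster, function(a) a$is_locomotion,
                               logical(1)))[1]]]
  s <- simulate_session(p, loco, "ankle", 360, seed = 11)
  expect_identical(nrow(s$samples), 36000L) # 360 s x 100 Hz
  expect_identical(s$stop_time - s$start_time, 360)
  s2 <- simulate_session(p, loco, "ankle", 360, seed = 11)
  expect_identical(s$samples, s2$samples)
  s3 <- simulate_session(p, loco, "ankle", 360, seed = 12)
  expect_false(identical(s$samples, s3$samples))
  expect_error(simulate_session(p, loco, "chest", 360, seed = 1),
               class = "placewear_argument_error")
  expect_error(simulate_session(p, loco, "ankle", 100, seed = 1),
               class = "placewear_argument_error")
})

test_that("a noiseless static template reproduces the gravity axis exactly", {
  tpl <- signal_template(c(0, 0, 1), periodic = list(), noise_sd = 0,
                         drift_sd = 0)
  act <- structure(list(name = "static", category = "sedentary",
                        is_sedentary = TRUE, is_locomotion = FALSE,
                        is_lifestyle = FALSE, duration_range = c(360, 480),
                        true_met_mean = 1, true_met_sd_between_participants = 0,
                        templates = list(hip = tpl)), class = "activity_spec")
  s <- simulate_session(participant_spec("P01"), act, "hip", 360, seed = 1)
  expect_true(all(s$samples[, 1] == 0))
  expect_true(all(s$samples[, 2] == 0))
  expect_true(all(s$samples[, 3] == 1))
})

test_that("simulate_vo2_trace plateaus at 3.5 x MET with exponential onset", {
  roster <- fixture_roster()
  sed <- roster[[1]] # true MET 1.0
  p0 <- participant_spec("P01", met_offset = 0)
  tr <- simulate_vo2_trace(p0, sed, 360, seed = 1, noise_sd = 0)
  expect_true(all(diff(tr$breath_times) > 0))
  expect_true(all(tr$vo2_values > 0))
  # MET 1 activity: flat at the 3.5 resting standard
  expect_equal(mean(tr$vo2_values), 3.5, tolerance = 1e-6)

  # closed-form plateau check for MET 2: mean over [120, end] within the
  # onset deficit tau*(e^{-120/tau} - e^{-T/tau})/(T - 120) of 7.0
  act2 <- sed; act2$true_met_mean <- 2.0
  tr2 <- simulate_vo2_trace(p0, act2, 360, seed = 2, noise_sd = 0)
  keep <- tr2$breath_times >= 120
  deficit <- 3.5 * 40 * (exp(-120 / 40) - exp(-360 / 40)) / (360 - 120)
  expect_equal(mean(tr2$vo2_values[keep]), 7.0 - deficit, tolerance = 0.01)
  expect_equal(mean(tr2$vo2_values[keep]), 7.0, tolerance = 0.1)

  tr3 <- simulate_vo2_trace(p0, sed, 360, seed = 3)
  tr4 <- simulate_vo2_trace(p0, sed, 360, seed = 4)
  expect_false(identical(tr3$breath_times, tr4$breath_times))
  expect_error(simulate_vo2_trace(p0, sed, 150, seed = 1),
               class = "placewear_argument_error")
})

test_that("simulate_cohort emits the full session grid and honors drops", {
  ch <- simulate_cohort(6, build_default_roster(2, 1), seed = 1)
  expect_identical(nrow(ch$sessions), 60L) # 6 x 2 x 5
  expect_identical(nrow(ch$activity_log), 12L)
  expect_length(ch$vo2, 12)
  # determinism: same seed => identical manifest and signals
  ch2 <- simulate_cohort(6, build_default_roster(2, 1), seed = 1)
  expect_identical(ch$sessions, ch2$sessions)
  expect_identical(realize_session(ch, 5)$samples,
                   realize_session(ch2, 5)$samples)
  # drop_prob 1 removes every activity from every log
  ch3 <- simulate_cohort(6, build_default_roster(2, 1), seed = 1,
                         drop_prob = 1)
  expect_null(ch3$sessions)
  expect_error(simulate_cohort(5, build_default_roster(2, 1), seed = 1),
               class = "placewear_argument_error")
})

test_that("sedentary windows are a minority but present (epoch imbalance)", {
  # (32, 4) roster at default durations: sedentary share should bracket a
  # small-minority fraction (the 4/32 activity share puts it near 12.5%)
  ch <- simulate_cohort(6, build_default_roster(32, 4), seed = 55,
                        placements = "hip")
  counts <- table(ch$activity_log$category)
  n_win <- vapply(split(ch$activity_log, seq_len(nrow(ch$activity_log))),
                  function(r) floor((r$stop - r$start) / 16), numeric(1))
  share <- sum(n_win[ch$activity_log$category == "sedentary"]) / sum(n_win)
  expect_gt(share, 0.04)
  expect_lt(share, 0.20)
})

test_that("locomotion windows carry more 0.6-2.5 Hz power than sedentary at
           every placement", {
  feats <- fixture_features6()
  for (pl in names(PLACEMENTS)) {
    col <- paste0(pl, "_power_frac_band")
    m_loco <- mean(feats[[col]][feats$is_locomotion])
    m_sed <- mean(feats[[col]][feats$is_sedentary])
    expect_gt(m_loco, m_sed)
  }
})

test_that("session MET labels recover the true MET on noiseless traces", {
  ch <- fixture_cohort12() # vo2_noise_sd = 0
  labs <- met_labels(ch)
  truth <- vapply(ch$vo2, function(tr) tr$true_met, numeric(1))
  key <- paste(labs$participant_id, labs$activity, sep = "|")
  err <- abs(labs$met - truth[key])
  expect_lt(max(err), 0.15)
})
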