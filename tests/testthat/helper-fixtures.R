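# Shared fixtures, built once per test run and memoized. Sizes are scaled to
# keep the whole suite inside a desk-scale budget; the acceptance tests state
# where they scale the stated world down (forest size only, never the
# generator's signal/MET parameters).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 8-activity roster used by the cohort fixtures: 2 sedentary, 2 locomotion,
# 4 lifestyle.
fixture_roster <- function() memo("roster8", function()
  build_default_roster(8, 2, 2))

# 6-participant cohort + features: used for separability/imbalance
# properties and the CV-hygiene run.
fixture_cohort6 <- function() memo("cohort6", function()
  simulate_cohort(6, fixture_roster(), seed = 101))

fixture_features6 <- function() memo("features6", function() {
  ch <- fixture_cohort6()
  extract_feature_table(ch, met_labels = met_labels(ch))
})

# 12-participant cohort with noiseless calorimetry: the acceptance
# parameter-recovery fixture.
fixture_cohort12 <- function() memo("cohort12", function()
  simulate_cohort(12, fixture_roster(), seed = 202, vo2_noise_sd = 0))

fixture_features12 <- function() memo("features12", function() {
  ch <- fixture_cohort12()
  extract_feature_table(ch, met_labels = met_labels(ch))
})

# Small deterministic window for feature unit tests.
toy_window <- function(n = 64, rate = 100, freq = NULL, amp = 0.2,
                       base = c(0, 0, 1), noise = 0) {
  t <- (seq_len(n) - 1) / rate
  m <- matrix(rep(base, each = n), ncol = 3)
  if (!is.null(freq)) m[, 3] <- m[, 3] + amp * cos(2 * pi * freq * t)
  if (noise > 0) m <- m + matrix(rnorm(3 * n, sd = noise), ncol = 3)
  colnames(m) <- c("x", "y", "z")
  m
}

# Independent brute-force DFT oracle for the frequency features: plain
# O(n^2) summation, no FFT.
oracle_frequency_features <- function(m, rate, band = c(0.6, 2.5)) {
  vm <- sqrt(rowSums(m^2))
  z <- vm - mean(vm)
  n <- length(z)
  ks <- seq_len(n %/% 2)
  mod <- vapply(ks, function(k) {
    re <- sum(z * cos(-2 * pi * k * (seq_len(n) - 1) / n))
    im <- sum(z * sin(-2 * pi * k * (seq_len(n) - 1) / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
  freqs <- ks * rate / n
  total <- sum(mod)
  dom <- which.max(mod)
  c(power_frac_band = sum(mod[freqs >= band[1] & freqs <= band[2]]) / total,
    dom_freq = freqs[dom],
    frac_at_dom = mod[dom] / total)
}

# Assert that a cv plan and prediction records never mix participants
# across a train/test boundary.
expect_participant_exclusive <- function(records, plan) {
  for (f in unique(records$fold)) {
    fold <- plan$outer[[f]]
    expect_length(intersect(fold$development, fold$test), 0)
    expect_true(all(records$participant_id[records$fold == f] %in% fold$test))
    for (inner in fold$inner) {
      expect_length(intersect(inner$train, inner$validation), 0)
      expect_setequal(c(inner$train, inner$validation), fold$development)
    }
  }
}
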