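# Activity roster: parameterized stand-in for the 32 scripted activities of
# daily life (4 sedentary, 6 locomotion, 22 lifestyle by default). Each
# activity carries a ground-truth MET level and one deterministic signal
# template per placement; templates encode the qualitative structure the
# analysis assumes (strong 0.6-2.5 Hz periodicity at ankle/hip/thigh during
# locomotion, high wrist variability during lifestyle tasks, near-static
# gravity-dominated signals during sedentary tasks).

ACTIVITY_CATEGORIES <- c("sedentary", "locomotion", "lifestyle")

DEFAULT_NAMES <- list(
  sedentary = c("computer_work", "tv_watching", "reading", "handwriting"),
  locomotion = c("leisure_walk", "brisk_walk", "treadmill_slow",
                 "treadmill_brisk", "stair_ascent", "stair_descent"),
  lifestyle = c("washing_dishes", "washing_windows", "vacuuming", "sweeping",
                "mopping", "yard_work", "gardening", "raking",
                "folding_laundry", "ironing", "bed_making", "cooking",
                "grocery_shelving", "light_home_repair", "dusting",
                "trash_removal", "car_washing", "strength_exercise",
                "stretching", "yoga", "dancing", "playing_catch"))

#' Construct a signal template for one placement
#'
#' @param gravity_axis numeric length-3 device orientation (normalized to
#'   unit length, the direction gravity projects onto the axes at rest).
#' @param periodic list of components, each `list(freq, amp, mix)` with
#'   frequency in Hz, amplitude in g and a length-3 axis-mixing vector.
#' @param noise_sd,drift_sd white-noise and slow random-walk amplitudes (g).
#' @return object of class `signal_template`.
#' @export
signal_template <- function(gravity_axis, periodic = list(),
                            noise_sd = 0.02, drift_sd = 0) {
  gravity_axis <- normalize3(gravity_axis)
  for (comp in periodic) {
    if (comp$amp < 0) stop_arg("periodic amplitudes must be >= 0")
    if (comp$freq <= 0) stop_arg("periodic frequencies must be > 0")
  }
  if (noise_sd < 0 || drift_sd < 0) stop_arg("noise/drift sd must be >= 0")
  structure(list(gravity_axis = gravity_axis, periodic = periodic,
                 noise_sd = noise_sd, drift_sd = drift_sd),
            class = "signal_template")
}

#' @noRd
activity_spec <- function(name, category, true_met_mean, true_met_sd,
                          templates, duration_range = c(360, 480)) {
  if (!category %in% ACTIVITY_CATEGORIES) stop_arg("bad category ", category)
  if (true_met_mean < 0.9) stop_arg("true_met_mean must be >= 0.9")
  if (duration_range[1] > duration_range[2]) stop_arg("bad duration_range")
  structure(list(
    name = name, category = category,
    is_sedentary = category == "sedentary",
    is_locomotion = category == "locomotion",
    is_lifestyle = category == "lifestyle",
    duration_range = duration_range,
    true_met_mean = true_met_mean,
    true_met_sd_between_participants = true_met_sd,
    templates = templates), class = "activity_spec")
}

# Device orientation at each placement for the two postures used by the
# generator; a small deterministic per-activity tilt is added on top so that
# activities differ in their angle features as real re-wearing/posture does.
POSTURE_AXES <- list(
  upright = list(ankle = c(1, 0, 0), upper_arm = c(0.9, 0.3, 0.3),
                 hip = c(1, 0.1, 0), thigh = c(0.95, 0.1, 0.3),
                 wrist = c(0.6, 0.6, 0.5)),
  seated = list(ankle = c(0.9, 0.3, 0.3), upper_arm = c(0.8, 0.4, 0.4),
                hip = c(0.85, 0.4, 0.3), thigh = c(0.15, 0.9, 0.4),
                wrist = c(0.3, 0.8, 0.5)))

#' @noRd
activity_axis <- function(placement, posture, index) {
  base <- POSTURE_AXES[[posture]][[placement]]
  tilt <- 0.12 * c(sin(1.7 * index), cos(2.3 * index), sin(0.9 * index + 1))
  normalize3(normalize3(base) + tilt)
}

#' @noRd
mix_vector <- function(gravity_axis, index) {
  # substantial gravity-axis component so the periodicity survives into the
  # vector magnitude (a purely orthogonal tone only enters VM at second order)
  orth <- c(gravity_axis[2], -gravity_axis[1], 0)
  if (sum(orth^2) < 1e-6) orth <- c(0, 1, 0)
  normalize3(0.8 * gravity_axis + 0.6 * sin(index + 1) * normalize3(orth))
}

#' @noRd
sedentary_templates <- function(index, met) {
  tpl <- list()
  for (pl in names(PLACEMENTS)) {
    ax <- activity_axis(pl, "seated", index)
    periodic <- if (pl %in% c("wrist", "upper_arm")) {
      list(list(freq = 3.0 + 0.5 * index, amp = 0.008, mix = mix_vector(ax, index)))
    } else list()
    tpl[[pl]] <- signal_template(ax, periodic,
                                 noise_sd = if (pl == "wrist") 0.022 else 0.012,
                                 drift_sd = 0.002)
  }
  tpl
}

#' @noRd
locomotion_templates <- function(index, met) {
  cadence <- 0.8 + 0.25 * (index - 1) # step frequency, Hz, inside 0.6-2.5
  s <- max(met - 1, 0.05)             # movement intensity scales with MET
  amp <- list(ankle = 0.30, thigh = 0.22, hip = 0.18,
              wrist = 0.10, upper_arm = 0.08)
  noise <- list(ankle = 0.040, thigh = 0.035, hip = 0.030,
                wrist = 0.050, upper_arm = 0.040)
  tpl <- list()
  for (pl in names(PLACEMENTS)) {
    ax <- activity_axis(pl, "upright", index)
    periodic <- list(
      list(freq = cadence, amp = amp[[pl]] * s, mix = mix_vector(ax, index)),
      list(freq = 2 * cadence, amp = 0.35 * amp[[pl]] * s,
           mix = mix_vector(ax, index + 3)))
    tpl[[pl]] <- signal_template(ax, periodic, noise_sd = noise[[pl]],
                                 drift_sd = 0.003)
  }
  tpl
}

#' @noRd
lifestyle_templates <- function(index, met) {
  f1 <- 0.3 + 0.17 * ((index - 1) %% 8)  # slow task rhythm
  f2 <- 2.7 + 0.30 * ((index - 1) %% 5)  # faster arm component, outside band
  s <- max(met - 1, 0.05)
  amp1 <- list(wrist = 0.16, upper_arm = 0.12, hip = 0.05,
               thigh = 0.04, ankle = 0.03)
  amp2 <- list(wrist = 0.06, upper_arm = 0.05, hip = 0.015,
               thigh = 0.01, ankle = 0.01)
  noise <- list(wrist = 0.12, upper_arm = 0.10, hip = 0.05,
                thigh = 0.04, ankle = 0.04)
  posture <- if (index %% 4 == 0) "seated" else "upright"
  tpl <- list()
  for (pl in names(PLACEMENTS)) {
    ax <- activity_axis(pl, posture, index)
    periodic <- list(
      list(freq = f1, amp = amp1[[pl]] * s, mix = mix_vector(ax, index)),
      list(freq = f2, amp = amp2[[pl]] * s, mix = mix_vector(ax, index + 5)))
    tpl[[pl]] <- signal_template(ax, periodic, noise_sd = noise[[pl]],
                                 drift_sd = 0.004)
  }
  tpl
}

#' Build the default synthetic activity roster
#'
#' Produces `n_activities` activity specifications with exactly
#' `n_sedentary` sedentary, `n_locomotion` locomotion and the remainder
#' lifestyle activities (the default 32/4/6 split mirrors a roster of
#' activities of daily life in which sedentary tasks are a small minority).
#' Sedentary MET means are below 1.6; locomotion MET means are at least 2.5.
#' The roster is fully deterministic: no RNG is consumed.
#'
#' @param n_activities total number of activities.
#' @param n_sedentary number of sedentary activities (`0 < n_sedentary <
#'   n_activities`).
#' @param n_locomotion number of locomotion activities; remainder after
#'   sedentary and locomotion becomes lifestyle.
#' @param met_sd between-participant SD of the true MET level (MET units),
#'   applied to every activity.
#' @return object of class `activity_roster` (a list of `activity_spec`).
#' @export
#' @examples
#' roster <- build_default_roster(32, 4)
#' table(vapply(roster, function(a) a$category, ""))
build_default_roster <- function(n_activities = 32L, n_sedentary = 4L,
                                 n_locomotion = min(6L, n_activities - n_sedentary),
                                 met_sd = 0.25) {
  if (n_sedentary <= 0 || n_sedentary >= n_activities)
    stop_arg("need 0 < n_sedentary < n_activities")
  if (n_locomotion < 0 || n_sedentary + n_locomotion > n_activities)
    stop_arg("n_locomotion incompatible with n_activities and n_sedentary")
  n_lifestyle <- n_activities - n_sedentary - n_locomotion

  pick_names <- function(category, k) {
    pool <- DEFAULT_NAMES[[category]]
    if (k <= length(pool)) pool[seq_len(k)]
    else c(pool, sprintf("%s_%02d", category, seq_len(k - length(pool))))
  }

  specs <- list()
  for (i in seq_len(n_sedentary)) {
    met <- 1.0 + 0.45 * (i - 1) / max(n_sedentary - 1, 1) # 1.0 .. 1.45 < 1.6
    specs[[length(specs) + 1L]] <- activity_spec(
      pick_names("sedentary", n_sedentary)[i], "sedentary", met, met_sd,
      sedentary_templates(i, met))
  }
  for (i in seq_len(n_locomotion)) {
    met <- 2.8 + 0.35 * (i - 1) # 2.8 upward, >= 2.5
    specs[[length(specs) + 1L]] <- activity_spec(
      pick_names("locomotion", n_locomotion)[i], "locomotion", met, met_sd,
      locomotion_templates(i, met))
  }
  for (i in seq_len(n_lifestyle)) {
    met <- 1.8 + 2.4 * (i - 1) / max(n_lifestyle - 1, 1) # 1.8 .. 4.2
    specs[[length(specs) + 1L]] <- activity_spec(
      pick_names("lifestyle", n_lifestyle)[i], "lifestyle", met, met_sd,
      lifestyle_templates(i, met))
  }
  names(specs) <- vapply(specs, function(a) a$name, character(1))
  structure(specs, class = "activity_roster")
}

#' @export
print.activity_roster <- function(x, ...) {
  cats <- vapply(x, function(a) a$category, character(1))
  cat("<activity_roster> ", length(x), " activities (",
      sum(cats == "sedentary"), " sedentary, ",
      sum(cats == "locomotion"), " locomotion, ",
      sum(cats == "lifestyle"), " lifestyle)\n", sep = "")
  invisible(x)
}

#' Roster summary as a data frame
#' @param roster an `activity_roster`.
#' @return data.frame with name, category and true MET parameters.
#' @export
roster_table <- function(roster) {
  data.frame(
    activity = vapply(roster, function(a) a$name, character(1)),
    category = vapply(roster, function(a) a$category, character(1)),
    true_met_mean = vapply(roster, function(a) a$true_met_mean, numeric(1)),
    true_met_sd = vapply(roster, function(a)
      a$true_met_sd_between_participants, numeric(1)),
    row.names = NULL)
}
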