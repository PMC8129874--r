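# Cohort simulator: accelerometer sessions (gravity + sinusoids + Gaussian
# noise + random-walk drift) and breath-by-breath VO2 traces with an
# exponential onset toward an activity-specific MET plateau. All randomness
# flows from one cohort seed through derive_seed(), so any single session can
# be regenerated independently of the rest of the cohort.

MET_REF_SD <- 0.25 # reference SD used to express participant MET offsets

#' Construct a participant specification
#'
#' @param participant_id string id.
#' @param amplitude_factor positive multiplier on movement amplitudes
#'   (vigour of movement; 1 = cohort average).
#' @param met_offset participant-level MET offset (MET units) at the
#'   reference between-participant SD of 0.25 MET; for an activity with a
#'   different SD the applied offset is scaled proportionally.
#' @param rng_seed integer seed for this participant's random stream.
#' @return object of class `participant_spec`.
#' @export
participant_spec <- function(participant_id, amplitude_factor = 1,
                             met_offset = 0, rng_seed = 1L) {
  if (amplitude_factor <= 0) stop_arg("amplitude_factor must be > 0")
  structure(list(participant_id = participant_id,
                 amplitude_factor = amplitude_factor,
                 met_offset = met_offset,
                 rng_seed = as.integer(rng_seed)),
            class = "participant_spec")
}

#' Simulate one accelerometer recording session
#'
#' Generates a triaxial signal at `sample_rate` Hz as the placement's gravity
#' axis plus the template's sinusoidal components (amplitudes scaled by the
#' participant's `amplitude_factor`, random phases), Gaussian sensor noise and
#' a slow random-walk drift. Deterministic given `seed`.
#'
#' @param participant a `participant_spec`.
#' @param activity an `activity_spec`.
#' @param placement one of `names(PLACEMENTS)`.
#' @param duration seconds; must lie within the activity's `duration_range`.
#' @param seed integer seed.
#' @param sample_rate sampling frequency in Hz (default 100).
#' @param start_time session start in seconds from the cohort epoch.
#' @return object of class `recording_session` with an `n x 3` sample matrix
#'   in g and columns `x`, `y`, `z`.
#' @export
#' @examples
#' roster <- build_default_roster(8, 2, 2)
#' p <- participant_spec("P01")
#' s <- simulate_session(p, roster$leisure_walk, "ankle", 360, seed = 1)
#' nrow(s$samples) # 36000
simulate_session <- function(participant, activity, placement, duration,
                             seed, sample_rate = 100, start_time = 0) {
  check_placement(placement)
  if (duration < activity$duration_range[1] ||
      duration > activity$duration_range[2])
    stop_arg("duration ", duration, " outside activity duration_range [",
             activity$duration_range[1], ", ", activity$duration_range[2], "]")
  tpl <- activity$templates[[placement]]
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  samples <- with_seed(seed, {
    m <- matrix(rep(tpl$gravity_axis, each = n), ncol = 3)
    for (comp in tpl$periodic) {
      phase <- runif(1, 0, 2 * pi)
      wave <- participant$amplitude_factor * comp$amp *
        sin(2 * pi * comp$freq * t + phase)
      m <- m + outer(wave, comp$mix)
    }
    if (tpl$noise_sd > 0)
      m <- m + matrix(rnorm(3 * n, sd = tpl$noise_sd), ncol = 3)
    if (tpl$drift_sd > 0) {
      step_sd <- tpl$drift_sd / sqrt(n) # total drift SD ~ drift_sd over session
      m <- m + apply(matrix(rnorm(3 * n, sd = step_sd), ncol = 3), 2, cumsum)
    }
    m
  })
  colnames(samples) <- c("x", "y", "z")
  structure(list(participant_id = participant$participant_id,
                 activity_name = activity$name,
                 placement = placement,
                 sample_rate = sample_rate,
                 samples = samples,
                 start_time = start_time,
                 stop_time = start_time + duration),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat("<recording_session> ", x$participant_id, " / ", x$activity_name,
      " @ ", x$placement, ": ", nrow(x$samples), " samples at ",
      x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Simulate a breath-by-breath VO2 trace
#'
#' VO2 starts near rest (3.5 mL·min⁻¹·kg⁻¹) and rises with an exponential
#' onset (time constant `tau_s`) toward a plateau at `3.5 * (true MET +
#' participant offset)`, sampled at irregular breath times (shifted
#' exponential inter-breath intervals, mean `breath_mean_s`) with Gaussian
#' breath-level noise.
#'
#' @inheritParams simulate_session
#' @param duration seconds, at least 180 (otherwise no steady state is
#'   reachable and an argument error is raised).
#' @param tau_s onset time constant in seconds (default 40).
#' @param breath_mean_s mean inter-breath interval in seconds (default 3).
#' @param noise_sd breath-level VO2 noise SD in mL·min⁻¹·kg⁻¹ (default 1).
#' @return object of class `vo2_trace` with strictly increasing
#'   `breath_times` (s from activity start) and positive `vo2_values`.
#' @export
simulate_vo2_trace <- function(participant, activity, duration, seed,
                               tau_s = 40, breath_mean_s = 3, noise_sd = 1) {
  if (duration < 180)
    stop_arg("duration must be >= 180 s for a steady state to be reachable")
  sd_scale <- activity$true_met_sd_between_participants / MET_REF_SD
  true_met <- activity$true_met_mean + participant$met_offset * sd_scale
  plateau <- 3.5 * true_met
  rest <- 3.5
  with_seed(seed, {
    gaps <- 0.8 + rexp(ceiling(duration / 0.8) + 8,
                       rate = 1 / max(breath_mean_s - 0.8, 1e-6))
    times <- cumsum(gaps)
    times <- times[times <= duration]
    vals <- rest + (plateau - rest) * (1 - exp(-times / tau_s))
    if (noise_sd > 0) vals <- vals + rnorm(length(times), sd = noise_sd)
    vals <- pmax(vals, 0.1)
    structure(list(participant_id = participant$participant_id,
                   activity_name = activity$name,
                   breath_times = times,
                   vo2_values = vals,
                   true_met = true_met),
              class = "vo2_trace")
  })
}

#' @export
print.vo2_trace <- function(x, ...) {
  cat("<vo2_trace> ", x$participant_id, " / ", x$activity_name, ": ",
      length(x$breath_times), " breaths over ",
      round(max(x$breath_times)), " s\n", sep = "")
  invisible(x)
}

#' Simulate a full cohort
#'
#' Draws participants (log-normal amplitude factors, Gaussian MET offsets),
#' assigns each a subset of the roster (each activity independently dropped
#' with probability `drop_prob`, emulating incomplete task completion), picks
#' per-session durations uniformly within each activity's duration range, and
#' derives per-session seeds. Raw signals are *not* materialized here; the
#' returned bundle holds a session manifest and `realize_session()` generates
#' any single session on demand, which keeps memory flat and partial
#' regeneration stable.
#'
#' @param n_participants at least 6 (so default outer folds are non-empty).
#' @param roster an `activity_roster`.
#' @param seed master cohort seed.
#' @param drop_prob probability that a given participant skips a given
#'   activity (default 0 = everyone performs everything).
#' @param placements placements worn (default all five).
#' @param sample_rate Hz (default 100).
#' @param vo2_noise_sd breath-level VO2 noise SD (default 1; set 0 for
#'   noiseless calorimetry).
#' @param rest_gap_s rest between consecutive activities in the schedule.
#' @return object of class `cohort`: participants table, roster, session
#'   manifest (`$sessions`, one row per participant x activity x placement),
#'   activity log (`$activity_log`), and VO2 traces (`$vo2`).
#' @export
#' @examples
#' roster <- build_default_roster(2, 1)
#' ch <- simulate_cohort(6, roster, seed = 1)
#' nrow(ch$sessions) # 6 * 2 * 5 = 60
simulate_cohort <- function(n_participants, roster, seed, drop_prob = 0,
                            placements = names(PLACEMENTS), sample_rate = 100,
                            vo2_noise_sd = 1, rest_gap_s = 420) {
  if (n_participants < 6)
    stop_arg("n_participants must be >= 6 so outer folds are non-empty")
  vapply(placements, check_placement, character(1))
  ids <- sprintf("P%02d", seq_len(n_participants))
  participants <- with_seed(derive_seed(seed, "participants"), {
    data.frame(participant_id = ids,
               amplitude_factor = exp(rnorm(n_participants, sd = 0.10)),
               met_offset = rnorm(n_participants, sd = MET_REF_SD),
               rng_seed = vapply(ids, function(id) derive_seed(seed, id),
                                 integer(1)),
               row.names = NULL)
  })

  manifest <- list(); log_rows <- list(); vo2 <- list()
  for (i in seq_len(n_participants)) {
    pid <- ids[i]
    pspec <- participant_spec(pid, participants$amplitude_factor[i],
                              participants$met_offset[i],
                              participants$rng_seed[i])
    clock <- 0
    for (act in roster) {
      sseed <- derive_seed(seed, pid, act$name)
      keep_dur <- with_seed(sseed, c(runif(1) >= drop_prob,
                                     round(runif(1, act$duration_range[1],
                                                 act$duration_range[2]))))
      if (!keep_dur[1]) next
      duration <- keep_dur[2]
      start <- clock
      stop <- clock + duration
      clock <- stop + rest_gap_s
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        participant_id = pid, activity = act$name, category = act$category,
        start = start, stop = stop)
      for (pl in placements) {
        manifest[[length(manifest) + 1L]] <- data.frame(
          participant_id = pid, activity = act$name, placement = pl,
          duration = duration, start = start, stop = stop,
          seed = derive_seed(seed, pid, act$name, pl))
      }
      vo2[[paste(pid, act$name, sep = "|")]] <-
        simulate_vo2_trace(pspec, act, duration,
                           seed = derive_seed(seed, pid, act$name, "vo2"),
                           noise_sd = vo2_noise_sd)
    }
  }
  structure(list(participants = participants, roster = roster,
                 placements = placements, seed = seed,
                 sample_rate = sample_rate,
                 sessions = do.call(rbind, manifest),
                 activity_log = do.call(rbind, log_rows),
                 vo2 = vo2),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$participants), " participants, ",
      length(x$roster), " activities, ",
      length(x$placements), " placements: ",
      nrow(x$sessions), " sessions, ", length(x$vo2), " VO2 traces\n",
      sep = "")
  invisible(x)
}

#' Materialize one session of a cohort
#'
#' @param cohort a `cohort`.
#' @param row row index into `cohort$sessions`, or omit and give the key.
#' @param participant_id,activity,placement alternative key lookup.
#' @return a `recording_session`.
#' @export
realize_session <- function(cohort, row = NULL, participant_id = NULL,
                            activity = NULL, placement = NULL) {
  m <- cohort$sessions
  if (is.null(row)) {
    row <- which(m$participant_id == participant_id & m$activity == activity &
                   m$placement == placement)
    if (length(row) != 1L) stop_arg("session not found in manifest")
  }
  rec <- m[row, ]
  p <- cohort$participants[cohort$participants$participant_id ==
                             rec$participant_id, ]
  pspec <- participant_spec(p$participant_id, p$amplitude_factor,
                            p$met_offset, p$rng_seed)
  simulate_session(pspec, cohort$roster[[rec$activity]], rec$placement,
                   rec$duration, seed = rec$seed,
                   sample_rate = cohort$sample_rate, start_time = rec$start)
}
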