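# MET labeling from breath-by-breath VO2: 30-second running-average
# smoothing (time-based, since breaths are irregular), steady-state plateau
# extraction from a fixed onset (default 120 s, the typical time to plateau),
# and conversion to METs via the 3.5 mL·min⁻¹·kg⁻¹ resting convention.

#' Smooth a VO2 trace with a time-based running average
#'
#' For each breath at time `t`, the smoothed value is the mean of the raw
#' values at breaths within `[t - half_width_s, t + half_width_s]`; breath
#' times are unchanged. The default half width of 15 s gives the conventional
#' 30-second running-average window.
#'
#' @param trace a `vo2_trace`.
#' @param half_width_s half of the smoothing window in seconds.
#' @return a `vo2_trace` with smoothed `vo2_values`.
#' @export
smooth_vo2 <- function(trace, half_width_s = 15) {
  if (length(trace$breath_times) == 0) stop_arg("empty VO2 trace")
  if (half_width_s <= 0) stop_arg("half_width_s must be > 0")
  t <- trace$breath_times
  v <- trace$vo2_values
  cs <- cumsum(v)
  lo <- findInterval(t - half_width_s, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half_width_s, t)
  sm <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
  out <- trace
  out$vo2_values <- sm
  out
}

#' Steady-state MET label for one session
#'
#' Smooths the trace, discards everything before `onset_s` (default 120 s,
#' when the VO2 plateau is typically established), and divides the mean
#' plateau VO2 by 3.5 mL·min⁻¹·kg⁻¹. A trace that ends before `onset_s`, or
#' that retains fewer than `min_breaths` breaths, raises an exclusion error
#' (condition class `placewear_exclusion`) so batch labeling can count it. An
#' optional slope test rejects plateaus whose smoothed VO2 still trends more
#' than `max_slope` mL·min⁻¹·kg⁻¹ per second in absolute value.
#'
#' @param trace a `vo2_trace`.
#' @param onset_s steady-state onset in seconds (default 120).
#' @param half_width_s smoothing half width passed to [smooth_vo2()].
#' @param min_breaths minimum breaths in the plateau window (default 10).
#' @param max_slope optional absolute slope threshold; `NULL` disables.
#' @return object of class `met_label`: `met_value`,
#'   `steady_state_window`, `n_breaths_used`, ids.
#' @export
#' @examples
#' roster <- build_default_roster(2, 1)
#' tr <- simulate_vo2_trace(participant_spec("P01"), roster[[2]], 360,
#'                          seed = 1, noise_sd = 0)
#' steady_state_met(tr)$met_value # ~ roster[[2]]$true_met_mean
steady_state_met <- function(trace, onset_s = 120, half_width_s = 15,
                             min_breaths = 10, max_slope = NULL) {
  t_end <- max(trace$breath_times)
  if (t_end <= onset_s)
    exclusion_error("trace ends at ", round(t_end, 1), " s, before the ",
                    onset_s, " s steady-state onset; session excluded")
  sm <- smooth_vo2(trace, half_width_s)
  keep <- sm$breath_times >= onset_s
  if (sum(keep) < min_breaths)
    exclusion_error("only ", sum(keep), " breaths past onset (need ",
                    min_breaths, "); session excluded")
  tt <- sm$breath_times[keep]
  vv <- sm$vo2_values[keep]
  if (!is.null(max_slope)) {
    slope <- stats::coef(stats::lm.fit(cbind(1, tt), vv))[2]
    if (abs(slope) > max_slope)
      exclusion_error("no plateau: |slope| ", signif(abs(slope), 3),
                      " exceeds ", max_slope, "; session excluded")
  }
  structure(list(participant_id = trace$participant_id,
                 activity_name = trace$activity_name,
                 met_value = mean(vv) / 3.5,
                 steady_state_window = c(onset_s, t_end),
                 n_breaths_used = sum(keep)),
            class = "met_label")
}

#' @export
print.met_label <- function(x, ...) {
  cat("<met_label> ", x$participant_id, " / ", x$activity_name, ": ",
      round(x$met_value, 2), " MET over [",
      round(x$steady_state_window[1]), ", ",
      round(x$steady_state_window[2]), "] s (",
      x$n_breaths_used, " breaths)\n", sep = "")
  invisible(x)
}

#' MET labels for all traces of a cohort
#'
#' Applies [steady_state_met()] to every trace; sessions that fail the
#' steady-state contract are excluded and counted (the `exclusions`
#' attribute lists them with reasons), mirroring real calorimetry pipelines
#' in which sessions not reaching a steady-state metabolic rate are dropped.
#'
#' @param x a `cohort` or a list of `vo2_trace` objects.
#' @param ... passed to [steady_state_met()].
#' @return data.frame with `participant_id`, `activity`, `met`, `t_start`,
#'   `t_end`, `n_breaths`; excluded sessions in `attr(, "exclusions")`.
#' @export
met_labels <- function(x, ...) {
  traces <- if (inherits(x, "cohort")) x$vo2 else x
  rows <- list(); excl <- list()
  for (tr in traces) {
    lab <- tryCatch(steady_state_met(tr, ...),
                    placewear_exclusion = function(e) e)
    if (inherits(lab, "placewear_exclusion")) {
      excl[[length(excl) + 1L]] <- data.frame(
        participant_id = tr$participant_id, activity = tr$activity_name,
        reason = conditionMessage(lab))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = lab$participant_id, activity = lab$activity_name,
        met = lab$met_value, t_start = lab$steady_state_window[1],
        t_end = lab$steady_state_window[2], n_breaths = lab$n_breaths_used)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(), activity = character(),
               met = numeric(), t_start = numeric(), t_end = numeric(),
               n_breaths = integer())
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(participant_id = character(), activity = character(),
               reason = character())
  out
}
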