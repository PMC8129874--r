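# Windowed feature extraction: contiguous 16-second windows, 12 time-domain
# and 3 frequency-domain features of the vector magnitude (VM) and raw axes.
# Feature names, in fixed order:
#   mean_vm sd_vm mean_angle sd_angle autocov_vm skew_vm kurt_vm entropy_vm
#   cv_vm corr_xy corr_yz corr_xz power_frac_band dom_freq frac_at_dom

FEATURE_NAMES <- c("mean_vm", "sd_vm", "mean_angle", "sd_angle", "autocov_vm",
                   "skew_vm", "kurt_vm", "entropy_vm", "cv_vm",
                   "corr_xy", "corr_yz", "corr_xz",
                   "power_frac_band", "dom_freq", "frac_at_dom")

#' Segment a recording session into contiguous windows
#'
#' Windows are non-overlapping (an `overlap` fraction can be configured),
#' start at the session start, and a trailing partial window is discarded.
#'
#' @param session a `recording_session`.
#' @param window_s window length in seconds (default 16).
#' @param overlap fractional overlap between consecutive windows in `[0, 1)`
#'   (default 0 = contiguous).
#' @return list of `triaxial_window` objects (possibly empty for a session
#'   shorter than one window).
#' @export
#' @examples
#' roster <- build_default_roster(2, 1)
#' s <- simulate_session(participant_spec("P01"), roster[[2]], "hip", 360, 1)
#' length(segment_windows(s)) # floor(360 / 16) = 22
segment_windows <- function(session, window_s = 16, overlap = 0) {
  if (window_s <= 0) stop_arg("window_s must be > 0")
  if (overlap < 0 || overlap >= 1) stop_arg("overlap must be in [0, 1)")
  n <- nrow(session$samples)
  if (n == 0) stop_arg("session is empty")
  win_n <- round(window_s * session$sample_rate)
  if (n < win_n) {
    message("session shorter than one window; 0 windows emitted")
    return(list())
  }
  step <- max(1L, round(win_n * (1 - overlap)))
  starts <- seq(1L, n - win_n + 1L, by = step)
  lapply(seq_along(starts), function(k) {
    i0 <- starts[k]
    structure(list(
      samples = session$samples[i0:(i0 + win_n - 1L), , drop = FALSE],
      sample_rate = session$sample_rate,
      window_start = session$start_time + (i0 - 1L) / session$sample_rate,
      window_index = k,
      participant_id = session$participant_id,
      activity_name = session$activity_name,
      placement = session$placement), class = "triaxial_window")
  })
}

#' Vector magnitude of a window
#'
#' @param window a `triaxial_window`, or an `n x 3` numeric matrix.
#' @return numeric vector of per-sample Euclidean norms
#'   `sqrt(x^2 + y^2 + z^2)`.
#' @export
#' @examples
#' vector_magnitude(matrix(c(3, 4, 0), 1)) # 5
vector_magnitude <- function(window) {
  m <- if (inherits(window, "triaxial_window")) window$samples else window
  sqrt(rowSums(m^2))
}

#' @noRd
shannon_entropy_bits <- function(x, bins = 20) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0) # degenerate: all mass in one bin
  counts <- tabulate(pmin(floor((x - rng[1]) / diff(rng) * bins) + 1L, bins),
                     nbins = bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

#' Time-domain features of a window
#'
#' Computes the 12 time-domain features: mean and SD of VM; mean and SD of
#' the per-sample angle `acos(axis / VM)` between the configured axis and the
#' VM; lag-1 autocovariance of VM (configurable to plain variance); sample
#' skewness and excess kurtosis of VM; Shannon entropy (bits) of a 20-bin
#' equal-width VM histogram; coefficient of variation `100 * sd / mean`; and
#' the three pairwise axis Pearson correlations.
#'
#' Samples with `VM == 0` are skipped for the angle features; a zero-variance
#' axis yields correlation 0 with a warning; an all-zero window flags the
#' angle and CV features as `NA`.
#'
#' @param window a `triaxial_window` or `n x 3` matrix (needs `n >= 4`).
#' @param entropy_bins histogram bins for the entropy feature.
#' @param autocov one of `"lag1"` (default) or `"variance"`.
#' @param angle_axis axis for the angle features (default `"x"`).
#' @return named numeric vector of 12 features.
#' @export
time_features <- function(window, entropy_bins = 20,
                          autocov = c("lag1", "variance"),
                          angle_axis = c("x", "y", "z")) {
  autocov <- match.arg(autocov)
  angle_axis <- match.arg(angle_axis)
  m <- if (inherits(window, "triaxial_window")) window$samples else window
  n <- nrow(m)
  if (n < 4) stop_arg("need at least 4 samples for higher moments")
  vm <- sqrt(rowSums(m^2))
  mu <- mean(vm)
  s <- sd(vm)

  ok <- vm > 0
  ax <- m[, match(angle_axis, c("x", "y", "z"))]
  if (!any(ok)) {
    mean_angle <- NA_real_; sd_angle <- NA_real_; cv <- NA_real_
  } else {
    if (!all(ok)) message(sum(!ok), " zero-VM samples skipped for angle features")
    ang <- acos(pmin(pmax(ax[ok] / vm[ok], -1), 1))
    mean_angle <- mean(ang)
    sd_angle <- if (sum(ok) > 1) sd(ang) else 0
    cv <- if (mu > 0) 100 * s / mu else NA_real_
  }

  d <- vm - mu
  ac <- if (autocov == "lag1") {
    if (n > 1) sum(d[-n] * d[-1]) / (n - 1) else 0
  } else sum(d^2) / (n - 1)
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 - 3 else 0

  degenerate_axes <- apply(m, 2, sd) == 0
  if (any(degenerate_axes))
    warning("zero-variance axis (",
            paste(c("x", "y", "z")[degenerate_axes], collapse = ", "),
            "); affected correlations reported as 0", call. = FALSE)
  safe_cor <- function(i, j) {
    if (degenerate_axes[i] || degenerate_axes[j]) return(0)
    cor(m[, i], m[, j])
  }
  c(mean_vm = mu, sd_vm = s, mean_angle = mean_angle, sd_angle = sd_angle,
    autocov_vm = ac, skew_vm = skew, kurt_vm = kurt,
    entropy_vm = shannon_entropy_bits(vm, entropy_bins), cv_vm = cv,
    corr_xy = safe_cor(1, 2), corr_yz = safe_cor(2, 3),
    corr_xz = safe_cor(1, 3))
}

#' Frequency-domain features of a window
#'
#' The mean-removed VM is Fourier transformed; moduli are taken at the
#' positive frequencies `f_k = k * rate / n`, `k = 1..floor(n/2)` (DC is
#' excluded exactly by the mean removal). Features: fraction of the total
#' modulus in the 0.6-2.5 Hz band, the dominant frequency (largest modulus,
#' ties toward the lowest frequency), and the modulus fraction at the
#' dominant frequency. A constant window yields `power_frac_band = 0`,
#' `frac_at_dom = 0`, `dom_freq = 0` with a `degenerate` attribute.
#'
#' @param window a `triaxial_window`, or an `n x 3` matrix plus
#'   `sample_rate`.
#' @param sample_rate required when `window` is a bare matrix.
#' @param band numeric length-2 frequency band in Hz (default `c(0.6, 2.5)`).
#' @return named numeric vector: `power_frac_band`, `dom_freq`,
#'   `frac_at_dom`.
#' @export
frequency_features <- function(window, sample_rate = NULL,
                               band = c(0.6, 2.5)) {
  if (inherits(window, "triaxial_window")) {
    m <- window$samples
    sample_rate <- window$sample_rate
  } else {
    m <- window
    if (is.null(sample_rate)) stop_arg("sample_rate required for bare matrix")
  }
  n <- nrow(m)
  if (n < 16) stop_arg("need at least 16 samples for frequency features")
  vm <- sqrt(rowSums(m^2))
  z <- vm - mean(vm)
  if (all(abs(z) < 1e-12)) {
    out <- c(power_frac_band = 0, dom_freq = 0, frac_at_dom = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ks <- seq_len(n %/% 2)
  mod <- Mod(fft(z))[ks + 1L]
  freqs <- ks * sample_rate / n
  total <- sum(mod)
  in_band <- freqs >= band[1] & freqs <= band[2]
  dom <- which.max(mod) # which.max takes the first (lowest-frequency) tie
  c(power_frac_band = sum(mod[in_band]) / total,
    dom_freq = freqs[dom],
    frac_at_dom = mod[dom] / total)
}

#' All 15 features of one window
#'
#' @inheritParams time_features
#' @inheritParams frequency_features
#' @return named numeric vector of the 15 features in `FEATURE_NAMES` order.
#' @export
window_features <- function(window, sample_rate = NULL, band = c(0.6, 2.5),
                            entropy_bins = 20, autocov = "lag1",
                            angle_axis = "x") {
  tf <- time_features(window, entropy_bins = entropy_bins, autocov = autocov,
                      angle_axis = angle_axis)
  ff <- frequency_features(window, sample_rate = sample_rate, band = band)
  c(tf, ff)[FEATURE_NAMES]
}

#' Extract the per-window feature table for a cohort or session list
#'
#' Produces one row per (participant, activity, window index) with the 15
#' features of every available placement in fixed placement order, columns
#' named `<placement>_<feature>`, plus identifier and label columns
#' (`participant_id`, `activity`, `category`, the three category flags,
#' `window_index`, `window_start`) and, when `met_labels` is supplied, the
#' session-level `met`. Windows must lie entirely inside the logged
#' `[start, stop]` interval; windows crossing a boundary are dropped and
#' counted in the `n_dropped` attribute. Sessions missing a placement yield
#' `NA` features for that placement (flagged via the `incomplete` attribute).
#'
#' @param sessions a `cohort` (sessions realized lazily) or a list of
#'   `recording_session` objects.
#' @param activity_log data.frame with `participant_id`, `activity`,
#'   `category`, `start`, `stop` (defaults to the cohort's own log).
#' @param window_s window length in seconds.
#' @param met_labels optional MET label data.frame from [met_labels()].
#' @param ... passed to [window_features()].
#' @return data.frame of class `feature_table`.
#' @export
extract_feature_table <- function(sessions, activity_log = NULL,
                                  window_s = 16, met_labels = NULL, ...) {
  is_cohort <- inherits(sessions, "cohort")
  if (is_cohort && is.null(activity_log)) activity_log <- sessions$activity_log
  if (is.null(activity_log)) stop_arg("activity_log required")
  if (nrow(activity_log) == 0) {
    out <- empty_feature_table()
    return(out)
  }
  placements <- if (is_cohort) sessions$placements else
    unique(vapply(sessions, function(s) s$placement, character(1)))
  placements <- names(PLACEMENTS)[names(PLACEMENTS) %in% placements]

  get_session <- function(pid, act, pl) {
    if (is_cohort) {
      hit <- which(sessions$sessions$participant_id == pid &
                     sessions$sessions$activity == act &
                     sessions$sessions$placement == pl)
      if (length(hit) != 1L) return(NULL)
      realize_session(sessions, hit)
    } else {
      for (s in sessions)
        if (s$participant_id == pid && s$activity_name == act &&
            s$placement == pl) return(s)
      NULL
    }
  }

  rows <- list()
  n_dropped <- 0L
  incomplete <- 0L
  for (r in seq_len(nrow(activity_log))) {
    log <- activity_log[r, ]
    per_placement <- list()
    keep <- NULL
    starts <- NULL
    for (pl in placements) {
      s <- get_session(log$participant_id, log$activity, pl)
      if (is.null(s)) {
        per_placement[[pl]] <- NULL
        incomplete <- incomplete + 1L
        next
      }
      wins <- segment_windows(s, window_s = window_s)
      if (length(wins) == 0) next
      ws <- vapply(wins, function(w) w$window_start, numeric(1))
      inside <- ws >= log$start & (ws + window_s) <= log$stop + 1e-9
      n_dropped <- n_dropped + sum(!inside)
      feats <- t(vapply(wins[inside], function(w)
        window_features(w, ...), numeric(length(FEATURE_NAMES))))
      colnames(feats) <- paste(pl, FEATURE_NAMES, sep = "_")
      per_placement[[pl]] <- feats
      if (is.null(keep) || sum(inside) < keep) keep <- sum(inside)
      if (is.null(starts)) starts <- ws[inside]
    }
    if (is.null(keep) || keep == 0) next
    block <- data.frame(participant_id = log$participant_id,
                        activity = log$activity,
                        category = log$category,
                        is_sedentary = log$category == "sedentary",
                        is_locomotion = log$category == "locomotion",
                        is_lifestyle = log$category == "lifestyle",
                        window_index = seq_len(keep),
                        window_start = starts[seq_len(keep)])
    for (pl in placements) {
      f <- per_placement[[pl]]
      if (is.null(f)) {
        f <- matrix(NA_real_, keep, length(FEATURE_NAMES),
                    dimnames = list(NULL, paste(pl, FEATURE_NAMES, sep = "_")))
      } else f <- f[seq_len(keep), , drop = FALSE]
      block <- cbind(block, as.data.frame(f))
    }
    rows[[length(rows) + 1L]] <- block
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_feature_table()
  rownames(out) <- NULL
  if (!is.null(met_labels) && nrow(out) > 0) {
    key <- paste(out$participant_id, out$activity, sep = "|")
    mkey <- paste(met_labels$participant_id, met_labels$activity, sep = "|")
    out$met <- met_labels$met[match(key, mkey)]
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "incomplete") <- incomplete
  class(out) <- c("feature_table", class(out))
  out
}

#' @noRd
empty_feature_table <- function() {
  out <- data.frame(participant_id = character(), activity = character(),
                    category = character(), is_sedentary = logical(),
                    is_locomotion = logical(), is_lifestyle = logical(),
                    window_index = integer(), window_start = numeric())
  class(out) <- c("feature_table", class(out))
  out
}

#' Feature columns of a feature table for a placement set
#' @param features a `feature_table`.
#' @param set a `placement_set`.
#' @return character vector of column names in fixed order.
#' @export
feature_columns <- function(features, set) {
  cols <- unlist(lapply(set$members, function(pl)
    paste(pl, FEATURE_NAMES, sep = "_")))
  missing <- setdiff(cols, names(features))
  if (length(missing))
    stop_arg("feature table lacks columns: ", paste(missing, collapse = ", "))
  cols
}
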