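#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a temporary RNG seed, restoring global RNG state after.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and string tags
#'
#' All randomness in a cohort flows from one master seed; per-session and
#' per-cell seeds are derived by hashing the identifying strings, so
#' regenerating a single session or experiment cell is stable regardless of
#' generation order.
#'
#' @param seed integer master seed.
#' @param ... character or numeric tags identifying the sub-stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "P01", "leisure_walk", "hip")
derive_seed <- function(seed, ...) {
  mod <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% mod
  for (tag in list(...)) {
    for (code in utf8ToInt(paste0("|", as.character(tag)))) {
      h <- (h * 31 + code) %% mod
    }
  }
  as.integer(h %% (mod - 1) + 1)
}

#' @noRd
stop_arg <- function(...) {
  stop(errorCondition(paste0(...), class = c("placewear_argument_error",
                                             "error", "condition")))
}

#' @noRd
exclusion_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("placewear_exclusion",
                                             "error", "condition")))
}

#' @noRd
normalize3 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop_arg("cannot normalize a zero vector")
  v / nv
}

#' @noRd
iso8601 <- function(seconds, epoch = "2020-01-06 08:00:00") {
  t0 <- as.POSIXct(epoch, tz = "UTC")
  format(t0 + seconds, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

#' @noRd
from_iso8601 <- function(x, epoch = "2020-01-06 08:00:00") {
  t0 <- as.POSIXct(epoch, tz = "UTC")
  t <- if (inherits(x, "POSIXt")) as.POSIXct(x) else
    as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  as.numeric(difftime(t, t0, units = "secs"))
}
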