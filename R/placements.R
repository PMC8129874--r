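#' Body placements and their single-letter codes
#'
#' The five wear locations and the fixed letter codes used in all reports:
#' A = ankle, B = upper arm, C = hip, D = thigh, E = wrist. Combination codes
#' are the sorted concatenation of member letters (e.g. `"CE"` = hip + wrist).
#'
#' @format a named character vector mapping placement name to letter code.
#' @export
PLACEMENTS <- c(ankle = "A", upper_arm = "B", hip = "C",
                thigh = "D", wrist = "E")

#' Default usability ordering of placements, most to least usable
#' @export
USABILITY_ORDER <- c("wrist", "hip", "ankle", "upper_arm", "thigh")

#' @noRd
check_placement <- function(placement) {
  if (length(placement) != 1L || !placement %in% names(PLACEMENTS))
    stop_arg("unknown placement '", paste(placement, collapse = ","),
             "'; must be one of: ", paste(names(PLACEMENTS), collapse = ", "))
  placement
}

#' Construct a placement set
#'
#' @param members character vector of placement names (subset of
#'   `names(PLACEMENTS)`, non-empty, no duplicates).
#' @return an object of class `placement_set` with fields `members` (in fixed
#'   A-E order) and `code` (sorted letter string).
#' @export
#' @examples
#' placement_set(c("wrist", "hip"))$code # "CE"
placement_set <- function(members) {
  if (length(members) == 0L) stop_arg("placement set must be non-empty")
  if (anyDuplicated(members)) stop_arg("duplicate placements in set")
  vapply(members, check_placement, character(1))
  ord <- order(match(members, names(PLACEMENTS)))
  members <- members[ord]
  structure(list(members = members,
                 code = paste(PLACEMENTS[members], collapse = "")),
            class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat("<placement_set> ", x$code, ": ",
      paste(x$members, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' @noRd
code_to_members <- function(code) {
  letters5 <- strsplit(code, "")[[1]]
  names(PLACEMENTS)[match(letters5, PLACEMENTS)]
}
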