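# Metrics and reporting: balanced accuracy (mean of sensitivity and
# specificity), accuracy, RMSE, multiclass confusion matrices,
# difference-versus-all-five rankings, and the "most efficient combination"
# guideline rule (fewest sensors within a margin of the best combination,
# ties resolved by a wearability preference ordering).

#' Balanced accuracy of binary predictions
#'
#' Defined as the mean of sensitivity (true-positive rate on the positive
#' class) and specificity (true-negative rate). Robust to class imbalance.
#'
#' @param truth,pred factors/vectors of binary labels.
#' @param positive the positive class (default: the last factor level).
#' @return numeric in `[0, 1]`; `NA` with a warning when `truth` contains
#'   only one class (the quantity is undefined).
#' @export
#' @examples
#' balanced_accuracy(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = 1) # 0.75
balanced_accuracy <- function(truth, pred, positive = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop_arg("length mismatch")
  classes <- sort(unique(truth))
  if (length(classes) != 2) {
    warning("balanced accuracy undefined: truth does not contain exactly ",
            "two classes", call. = FALSE)
    return(NA_real_)
  }
  if (is.null(positive)) positive <- classes[2]
  positive <- as.character(positive)
  sens <- mean(pred[truth == positive] == positive)
  spec <- mean(pred[truth != positive] != positive)
  (sens + spec) / 2
}

#' Classification accuracy
#' @param truth,pred label vectors.
#' @return fraction of exact matches.
#' @export
accuracy <- function(truth, pred) {
  if (length(truth) == 0) stop_arg("empty records")
  if (length(truth) != length(pred)) stop_arg("length mismatch")
  mean(as.character(truth) == as.character(pred))
}

#' Root mean square error
#' @param truth,pred numeric vectors (measured and predicted values).
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(truth, pred) {
  if (length(truth) == 0) stop_arg("empty records")
  if (length(truth) != length(pred)) stop_arg("length mismatch")
  sqrt(mean((as.numeric(pred) - as.numeric(truth))^2))
}

#' Confusion matrix of actual versus predicted labels
#'
#' @param truth,pred label vectors.
#' @param class_list full class vocabulary (rows = actual, columns =
#'   predicted); labels outside it raise an error naming the offender.
#' @return integer matrix with `sum(cells) == length(truth)`.
#' @export
confusion_matrix <- function(truth, pred,
                             class_list = sort(unique(c(as.character(truth),
                                                        as.character(pred))))) {
  truth <- as.character(truth); pred <- as.character(pred)
  bad <- setdiff(unique(c(truth, pred)), class_list)
  if (length(bad))
    stop_arg("label(s) outside class_list: ", paste(bad, collapse = ", "))
  f <- function(x) factor(x, levels = class_list)
  unclass(table(actual = f(truth), predicted = f(pred)))
}

#' Random-chance accuracy level
#'
#' @param n_classes number of equally likely classes (at least 2).
#' @return percent, rounded to one decimal for display (32 classes: 3.1).
#' @export
chance_level <- function(n_classes) {
  if (length(n_classes) != 1 || is.na(n_classes) || n_classes < 2)
    stop_arg("n_classes must be >= 2")
  round(100 / n_classes, 1)
}

#' @noRd
check_cells <- function(cells, task) {
  cells <- cells[cells$task == task, , drop = FALSE]
  if (nrow(cells) == 0) stop_arg("no cells for task ", task)
  if (anyDuplicated(cells$code)) stop_arg("duplicate codes for task ", task)
  cells
}

#' Rank combinations against the five-placement combination
#'
#' @param cells data.frame with columns `task`, `code`, `metric`, `value`
#'   (one row per combination, e.g. `experiment_result$metrics`).
#' @param task task kind to rank.
#' @param full_code code of the reference combination (default `"ABCDE"`).
#' @return data.frame ordered by descending group size then by performance
#'   within group (decreasing for accuracy metrics, increasing for RMSE),
#'   with `difference = value - value(full)`.
#' @export
difference_vs_full <- function(cells, task, full_code = "ABCDE") {
  cells <- check_cells(cells, task)
  full <- cells$value[cells$code == full_code]
  if (length(full) != 1)
    stop_arg("missing reference combination ", full_code, " for task ", task)
  out <- data.frame(task = task, code = cells$code,
                    n_members = nchar(cells$code),
                    metric = cells$metric, value = cells$value,
                    difference = cells$value - full)
  inc <- !metric_higher_better(out$metric[1])
  out <- out[order(-out$n_members,
                   if (inc) out$value else -out$value, out$code), ]
  rownames(out) <- NULL
  out
}

#' @noRd
usability_rank <- function(code, usability_order) {
  members <- code_to_members(code)
  min(match(members, usability_order))
}

#' Select the most efficient placement combination for a task
#'
#' Implements the guideline rule: candidates are the combinations whose
#' performance is within `margin` of the most accurate combination
#' (`relative` mode: within `margin * best`; `absolute` mode: within
#' `margin` on the metric scale; for RMSE the margin is applied upward).
#' Among candidates the fewest-sensor combinations win; ties are broken by
#' the usability order applied to each combination's most usable member,
#' then by lexicographic code. Comparisons use unrounded values.
#'
#' @inheritParams difference_vs_full
#' @param margin similarity margin (default 0.10).
#' @param margin_mode `"relative"` (default) or `"absolute"`.
#' @param usability_order placements most-to-least usable (default
#'   wrist > hip > ankle > upper arm > thigh).
#' @return object of class `guideline_row`: the most accurate combination,
#'   the most accurate single placement(s), and the most efficient
#'   combination, each with its value.
#' @export
#' @examples
#' cells <- data.frame(task = "sedentary_vs_non",
#'                     code = c("ABCDE", "C", "A"),
#'                     metric = "balanced_accuracy",
#'                     value = c(0.78, 0.73, 0.65))
#' select_most_efficient(cells, "sedentary_vs_non")$most_efficient_code # "C"
select_most_efficient <- function(cells, task, margin = 0.10,
                                  margin_mode = c("relative", "absolute"),
                                  usability_order = USABILITY_ORDER) {
  margin_mode <- match.arg(margin_mode)
  cells <- check_cells(cells, task)
  metric <- cells$metric[1]
  higher <- metric_higher_better(metric)
  best_i <- if (higher) which.max(cells$value) else which.min(cells$value)
  best <- cells$value[best_i]
  threshold <- if (higher) {
    if (margin_mode == "relative") best * (1 - margin) else best - margin
  } else {
    if (margin_mode == "relative") best * (1 + margin) else best + margin
  }
  ok <- if (higher) cells$value >= threshold else cells$value <= threshold
  cand <- cells[ok, , drop = FALSE]
  if (nrow(cand) == 0) stop("internal error: best is not its own candidate")
  nm <- nchar(cand$code)
  cand <- cand[nm == min(nm), , drop = FALSE]
  ur <- vapply(cand$code, usability_rank, numeric(1),
               usability_order = usability_order)
  cand <- cand[order(ur, cand$code), , drop = FALSE]
  eff <- cand[1, ]

  singles <- cells[nchar(cells$code) == 1, , drop = FALSE]
  if (nrow(singles) > 0) {
    sbest <- if (higher) max(singles$value) else min(singles$value)
    scodes <- singles$code[abs(singles$value - sbest) < 1e-12]
  } else {
    sbest <- NA_real_; scodes <- character()
  }
  structure(list(task = task, metric = metric,
                 most_accurate_code = cells$code[best_i],
                 most_accurate_value = best,
                 most_accurate_single_codes = sort(scodes),
                 most_accurate_single_value = sbest,
                 most_efficient_code = eff$code,
                 most_efficient_value = eff$value,
                 margin = margin, margin_mode = margin_mode),
            class = "guideline_row")
}

#' @export
print.guideline_row <- function(x, ...) {
  lab <- function(code) paste(code_to_members(code), collapse = "+")
  cat("<guideline_row> ", x$task, " (", x$metric, ")\n",
      "  most accurate combination: ", lab(x$most_accurate_code), " (",
      round(x$most_accurate_value, 2), ")\n",
      "  most accurate single:      ",
      paste(vapply(x$most_accurate_single_codes, lab, ""), collapse = "; "),
      " (", round(x$most_accurate_single_value, 2), ")\n",
      "  most efficient:            ", lab(x$most_efficient_code), " (",
      round(x$most_efficient_value, 2), ")\n", sep = "")
  invisible(x)
}

#' Guideline table across tasks
#'
#' @inheritParams select_most_efficient
#' @param tasks task kinds to include (default: all present in `cells`).
#' @return data.frame with one row per task, mirroring a
#'   number-and-placement guideline table.
#' @export
guideline_table <- function(cells, tasks = unique(cells$task), margin = 0.10,
                            margin_mode = "relative",
                            usability_order = USABILITY_ORDER) {
  rows <- lapply(tasks, function(tk) {
    g <- select_most_efficient(cells, tk, margin = margin,
                               margin_mode = margin_mode,
                               usability_order = usability_order)
    data.frame(task = g$task, metric = g$metric,
               most_accurate_code = g$most_accurate_code,
               most_accurate_value = g$most_accurate_value,
               most_accurate_single_codes =
                 paste(g$most_accurate_single_codes, collapse = ";"),
               most_accurate_single_value = g$most_accurate_single_value,
               most_efficient_code = g$most_efficient_code,
               most_efficient_value = g$most_efficient_value)
  })
  do.call(rbind, rows)
}
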