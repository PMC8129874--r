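# R interface to the compiled random forest (see src/forest.cpp). Bundled
# because no forest learner ships with the target environment; the algorithm
# is the standard one: bootstrap-resampled CART trees with per-node feature
# subsampling, majority vote (classification) or mean (regression).

#' Fit a random forest
#'
#' @param x numeric feature matrix (rows = observations).
#' @param y factor/character (classification) or numeric (regression).
#' @param n_trees number of trees (default 300).
#' @param mtry features tried per split; default `floor(sqrt(p))` for
#'   classification, `max(1, floor(p / 3))` for regression.
#' @param min_node minimum observations in a leaf (default 1 classification,
#'   5 regression).
#' @param seed integer seed (forest growth is deterministic given it).
#' @return object of class `placewear_rf`.
#' @export
#' @examples
#' x <- matrix(rnorm(200), 100, 2)
#' y <- factor(ifelse(x[, 1] + x[, 2] > 0, "a", "b"))
#' fit <- rf_fit(x, y, n_trees = 50, seed = 1)
#' mean(predict(fit, x) == y) # close to 1
rf_fit <- function(x, y, n_trees = 300, mtry = NULL, min_node = NULL,
                   seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop_arg("feature matrix contains NA")
  if (nrow(x) != length(y)) stop_arg("x and y lengths differ")
  if (nrow(x) < 2) stop_arg("need at least 2 observations")
  classification <- is.factor(y) || is.character(y) || is.logical(y)
  if (classification) {
    y <- factor(y)
    levels_y <- levels(y)
    y_num <- as.numeric(y) - 1
    n_classes <- length(levels_y)
    if (n_classes < 2) stop_arg("need at least 2 classes")
  } else {
    levels_y <- NULL
    y_num <- as.numeric(y)
    if (anyNA(y_num)) stop_arg("regression target contains NA")
    n_classes <- 0L
  }
  p <- ncol(x)
  if (!is.null(mtry) && is.na(mtry)) mtry <- NULL
  if (!is.null(min_node) && is.na(min_node)) min_node <- NULL
  if (is.null(mtry))
    mtry <- if (classification) max(1L, floor(sqrt(p))) else
      max(1L, floor(p / 3))
  if (is.null(min_node)) min_node <- if (classification) 1L else 5L
  trees <- with_seed(seed, cpp_rf_fit(x, y_num, as.integer(n_classes),
                                      as.integer(n_trees), as.integer(mtry),
                                      as.integer(min_node)))
  structure(list(trees = trees, levels = levels_y, p = p,
                 n_trees = n_trees, mtry = mtry, min_node = min_node),
            class = "placewear_rf")
}

#' @export
print.placewear_rf <- function(x, ...) {
  kind <- if (is.null(x$levels)) "regression" else
    paste0(length(x$levels), "-class classification")
  cat("<placewear_rf> ", kind, ", ", x$n_trees, " trees, mtry ", x$mtry,
      ", min_node ", x$min_node, "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted random forest
#'
#' @param object a `placewear_rf`.
#' @param newdata numeric matrix with the training column count.
#' @param ... unused.
#' @return factor (classification, majority vote; ties break toward the
#'   first level) or numeric (regression, tree mean).
#' @export
predict.placewear_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$p)
    stop_arg("newdata has ", ncol(newdata), " columns; model expects ",
             object$p)
  n_classes <- if (is.null(object$levels)) 0L else length(object$levels)
  out <- cpp_rf_predict(object$trees, newdata, as.integer(n_classes))
  if (n_classes > 0)
    factor(object$levels[out + 1], levels = object$levels)
  else out
}
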