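# Experiment engine: enumerate placement combinations, build
# participant-exclusive nested cross-validation plans, and run tuned random
# forests for the five prediction tasks. Outer folds hold out one-sixth of
# participants for testing; inner folds split each development set 4/5-1/5
# for hyperparameter tuning. Predictions are emitted for outer test
# participants only, so tuning can never see test data by construction.

TASK_KINDS <- c("sedentary_vs_non", "locomotion_vs_non", "lifestyle_vs_non",
                "individual_32class", "met_regression")

#' Enumerate all non-empty placement combinations
#'
#' @param placements character vector of placement names (1 to 5, no
#'   duplicates); default all five, giving the full 31 combinations.
#' @return list of `placement_set`, ordered by size then lexicographic code.
#' @export
#' @examples
#' length(enumerate_placement_sets()) # 31
enumerate_placement_sets <- function(placements = names(PLACEMENTS)) {
  if (length(placements) == 0) stop_arg("need at least one placement")
  if (anyDuplicated(placements)) stop_arg("duplicate placements")
  vapply(placements, check_placement, character(1))
  sets <- list()
  for (k in seq_along(placements)) {
    combos <- utils::combn(placements, k, simplify = FALSE)
    ps <- lapply(combos, placement_set)
    ps <- ps[order(vapply(ps, function(s) s$code, character(1)))]
    sets <- c(sets, ps)
  }
  sets
}

#' Build a participant-exclusive nested cross-validation plan
#'
#' Participants are randomly partitioned into `n_outer` near-equal outer
#' test groups; for each outer fold the remaining participants form the
#' development set, itself partitioned into `n_inner` near-equal inner
#' validation groups. No participant ever appears on both sides of any
#' boundary, because the split is by participant id, never by window.
#'
#' @param participant_ids character vector of ids.
#' @param n_outer outer folds (default 6: one-sixth held out for testing).
#' @param n_inner inner folds (default 5: one-fifth of development held out
#'   for validation).
#' @param seed integer seed; the plan is deterministic given it.
#' @return object of class `cv_plan`.
#' @export
#' @examples
#' plan <- make_cv_plan(sprintf("P%02d", 1:12), seed = 1)
#' lengths(lapply(plan$outer, `[[`, "test")) # six test sets of 2
make_cv_plan <- function(participant_ids, n_outer = 6, n_inner = 5, seed = 1L) {
  ids <- unique(as.character(participant_ids))
  if (length(ids) < n_outer)
    stop_arg("fewer participants (", length(ids), ") than outer folds (",
             n_outer, ")")
  split_groups <- function(x, k) {
    sizes <- rep(length(x) %/% k, k)
    extra <- length(x) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    split(x, rep(seq_len(k), times = sizes))
  }
  outer <- with_seed(seed, {
    groups <- split_groups(sample(ids), n_outer)
    lapply(seq_len(n_outer), function(f) {
      test <- groups[[f]]
      dev <- setdiff(ids, test)
      k_in <- min(n_inner, length(dev))
      inner_groups <- with_seed(derive_seed(seed, "inner", f),
                                split_groups(sample(dev), k_in))
      inner <- lapply(seq_len(k_in), function(g)
        list(train = setdiff(dev, inner_groups[[g]]),
             validation = inner_groups[[g]]))
      list(development = dev, test = test, inner = inner)
    })
  })
  structure(list(outer = outer, participant_ids = ids,
                 n_outer = n_outer, n_inner = n_inner, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("<cv_plan> ", length(x$participant_ids), " participants, ",
      x$n_outer, " outer x ", x$n_inner, " inner folds\n", sep = "")
  invisible(x)
}

#' Define a prediction task
#'
#' @param kind one of `"sedentary_vs_non"`, `"locomotion_vs_non"`,
#'   `"lifestyle_vs_non"` (binary, balanced accuracy),
#'   `"individual_32class"` (multiclass over activity names, accuracy) or
#'   `"met_regression"` (continuous MET, RMSE).
#' @return object of class `task_spec` with the target-extraction function
#'   and the matching metric name.
#' @export
task_spec <- function(kind = TASK_KINDS) {
  kind <- match.arg(kind)
  flag_col <- c(sedentary_vs_non = "is_sedentary",
                locomotion_vs_non = "is_locomotion",
                lifestyle_vs_non = "is_lifestyle")
  spec <- switch(kind,
    individual_32class = list(
      metric = "accuracy", type = "classification",
      target = function(features) factor(features$activity)),
    met_regression = list(
      metric = "rmse", type = "regression",
      target = function(features) features$met),
    list(metric = "balanced_accuracy", type = "classification",
         target = local({
           col <- flag_col[[kind]]
           function(features) factor(ifelse(features[[col]], "yes", "no"),
                                     levels = c("no", "yes"))
         })))
  structure(c(list(kind = kind), spec), class = "task_spec")
}

#' The five default tasks
#' @return named list of `task_spec`.
#' @export
default_tasks <- function() {
  tasks <- lapply(TASK_KINDS, task_spec)
  names(tasks) <- TASK_KINDS
  tasks
}

#' Default hyperparameter grid
#'
#' @param p number of features available to the model.
#' @param n_trees trees per forest (default 300).
#' @return data.frame with columns `n_trees`, `mtry`, `min_node`.
#' @export
default_hyper_grid <- function(p, n_trees = 300) {
  unique(expand.grid(n_trees = n_trees,
                     mtry = unique(c(max(1L, floor(sqrt(p))),
                                     max(1L, floor(p / 3)))),
                     min_node = c(1L, 5L)))
}

#' @noRd
tuning_metric <- function(task, truth, pred) {
  switch(task$metric,
         balanced_accuracy = balanced_accuracy(truth, pred),
         accuracy = accuracy(truth, pred),
         rmse = rmse(truth, pred))
}

#' @noRd
metric_higher_better <- function(metric) metric != "rmse"

#' Train, tune and predict for one task and one placement set
#'
#' For each outer fold, hyperparameters are chosen by the mean inner-fold
#' validation metric over `hyper_grid` (skipped when the grid has a single
#' row), a final model is fit on the full development set with the chosen
#' hyperparameters, and predictions are emitted for the outer test
#' participants only. Inner folds in which a class is absent from the
#' training side are flagged and skipped with a warning; an outer fold whose
#' development set lacks a class is skipped entirely.
#'
#' @param features a `feature_table` (with `met` merged for regression).
#' @param task a `task_spec`.
#' @param set a `placement_set`.
#' @param cv_plan a `cv_plan`.
#' @param hyper_grid data.frame as from [default_hyper_grid()]; `NULL` uses
#'   the default for this set's feature count.
#' @param seed integer seed for model fitting.
#' @return list with `records` (one row per test-set window: ids, fold,
#'   truth, prediction), `chosen` (per-fold hyperparameters) and `flagged`
#'   (count of skipped inner folds).
#' @export
train_and_predict <- function(features, task, set, cv_plan,
                              hyper_grid = NULL, seed = 1L) {
  cols <- feature_columns(features, set)
  keep <- stats::complete.cases(features[, cols, drop = FALSE])
  y_all <- task$target(features)
  keep <- keep & !is.na(y_all)
  dat <- features[keep, , drop = FALSE]
  x <- as.matrix(dat[, cols, drop = FALSE])
  y <- if (task$type == "classification") droplevels(factor(y_all[keep]))
       else as.numeric(y_all[keep])
  pid <- dat$participant_id
  if (is.null(hyper_grid)) hyper_grid <- default_hyper_grid(ncol(x))
  if (nrow(hyper_grid) == 0) stop_arg("empty hyperparameter grid")

  fit_one <- function(rows, grid_row, fit_seed) {
    rf_fit(x[rows, , drop = FALSE], y[rows],
           n_trees = grid_row$n_trees, mtry = grid_row$mtry,
           min_node = grid_row$min_node, seed = fit_seed)
  }
  has_all_classes <- function(rows) {
    task$type == "regression" || all(levels(y) %in% unique(as.character(y[rows])))
  }

  records <- list(); chosen <- list(); flagged <- 0L
  for (f in seq_along(cv_plan$outer)) {
    fold <- cv_plan$outer[[f]]
    dev_rows <- which(pid %in% fold$development)
    test_rows <- which(pid %in% fold$test)
    if (length(dev_rows) == 0 || length(test_rows) == 0) next
    if (!has_all_classes(dev_rows)) {
      warning("outer fold ", f, ": class absent from development set; skipped",
              call. = FALSE)
      flagged <- flagged + 1L
      next
    }
    best <- hyper_grid[1, , drop = FALSE]
    if (nrow(hyper_grid) > 1) {
      scores <- vapply(seq_len(nrow(hyper_grid)), function(g) {
        vals <- c()
        for (j in seq_along(fold$inner)) {
          tr <- which(pid %in% fold$inner[[j]]$train)
          va <- which(pid %in% fold$inner[[j]]$validation)
          if (length(tr) == 0 || length(va) == 0 || !has_all_classes(tr)) {
            flagged <<- flagged + 1L
            warning("inner fold ", f, ".", j,
                    ": class absent from training set; skipped", call. = FALSE)
            next
          }
          fit <- fit_one(tr, hyper_grid[g, , drop = FALSE],
                         derive_seed(seed, "inner", f, j, g))
          vals <- c(vals, tuning_metric(task, y[va],
                                        predict(fit, x[va, , drop = FALSE])))
        }
        if (length(vals) == 0) NA_real_ else mean(vals, na.rm = TRUE)
      }, numeric(1))
      if (all(is.na(scores))) {
        warning("outer fold ", f, ": no valid inner folds; skipped",
                call. = FALSE)
        next
      }
      pick <- if (metric_higher_better(task$metric)) which.max(scores)
              else which.min(scores)
      best <- hyper_grid[pick, , drop = FALSE]
    }
    fit <- fit_one(dev_rows, best, derive_seed(seed, "outer", f))
    pred <- predict(fit, x[test_rows, , drop = FALSE])
    records[[f]] <- data.frame(
      participant_id = pid[test_rows],
      activity = dat$activity[test_rows],
      window_index = dat$window_index[test_rows],
      task = task$kind, code = set$code, fold = f,
      truth = as.character(y[test_rows]),
      pred = as.character(pred),
      truth_num = if (task$type == "regression") y[test_rows] else NA_real_,
      pred_num = if (task$type == "regression") as.numeric(pred) else NA_real_,
      stringsAsFactors = FALSE)
    chosen[[f]] <- cbind(data.frame(fold = f), best)
  }
  list(records = if (length(records)) do.call(rbind, records) else NULL,
       chosen = if (length(chosen)) do.call(rbind, chosen) else NULL,
       flagged = flagged)
}

#' @noRd
cell_metric <- function(task, records) {
  if (task$type == "regression")
    rmse(records$truth_num, records$pred_num)
  else tuning_metric(task, factor(records$truth), factor(records$pred))
}

#' Run the full placement-combination experiment
#'
#' Loops tasks x placement sets, runs [train_and_predict()] for each cell
#' with a per-cell derived seed, and collects pooled and per-fold metrics.
#' When `store_dir` is given, each cell's predictions and metrics are
#' written as CSV on completion and existing cells are skipped on rerun, so
#' an interrupted experiment is resumable by cell.
#'
#' @param features a `feature_table` (with `met` merged if the MET task is
#'   included).
#' @param tasks list of `task_spec` (default all five).
#' @param sets list of `placement_set` (default all 31).
#' @param cv_plan a `cv_plan`; built from the feature table's participants
#'   when `NULL`.
#' @param seed master seed for fold assignment and model fitting.
#' @param n_trees,hyper_grid forest size / tuning grid; `hyper_grid = NULL`
#'   uses [default_hyper_grid()] per cell, a 1-row grid disables tuning.
#' @param n_outer,n_inner folds when `cv_plan` is `NULL`.
#' @param store_dir optional directory for per-cell CSV persistence.
#' @return object of class `experiment_result`: `$metrics` (one row per
#'   task x set: pooled metric plus per-fold mean/sd), `$fold_metrics`,
#'   `$predictions`, `$cv_plan`.
#' @export
run_full_experiment <- function(features, tasks = default_tasks(),
                                sets = enumerate_placement_sets(),
                                cv_plan = NULL, seed = 1L, n_trees = 300,
                                hyper_grid = NULL, n_outer = 6, n_inner = 5,
                                store_dir = NULL) {
  if (is.null(cv_plan))
    cv_plan <- make_cv_plan(unique(features$participant_id),
                            n_outer = n_outer, n_inner = n_inner,
                            seed = derive_seed(seed, "cv"))
  if (!is.null(store_dir) && !dir.exists(store_dir))
    dir.create(store_dir, recursive = TRUE)
  metrics <- list(); fold_metrics <- list(); preds <- list()
  for (task in tasks) {
    for (set in sets) {
      tag <- paste0(task$kind, "_", set$code)
      cell_file <- if (!is.null(store_dir))
        file.path(store_dir, paste0("cell_", tag, ".csv")) else NULL
      if (!is.null(cell_file) && file.exists(cell_file)) {
        rec <- utils::read.csv(cell_file, stringsAsFactors = FALSE)
      } else {
        grid <- hyper_grid %||%
          default_hyper_grid(15L * length(set$members), n_trees = n_trees)
        grid$n_trees <- n_trees
        res <- tryCatch(
          train_and_predict(features, task, set, cv_plan,
                            hyper_grid = grid,
                            seed = derive_seed(seed, task$kind, set$code)),
          placewear_argument_error = function(e) {
            message("cell ", tag, " skipped: ", conditionMessage(e))
            NULL
          })
        if (is.null(res) || is.null(res$records)) next
        rec <- res$records
        if (!is.null(cell_file)) utils::write.csv(rec, cell_file,
                                                  row.names = FALSE)
      }
      preds[[tag]] <- rec
      pooled <- cell_metric(task, rec)
      per_fold <- vapply(split(rec, rec$fold), function(r)
        cell_metric(task, r), numeric(1))
      metrics[[tag]] <- data.frame(
        task = task$kind, code = set$code, metric = task$metric,
        value = pooled, fold_mean = mean(per_fold), fold_sd = sd(per_fold),
        n_windows = nrow(rec),
        n_participants = length(unique(rec$participant_id)))
      fold_metrics[[tag]] <- data.frame(
        task = task$kind, code = set$code, metric = task$metric,
        fold = as.integer(names(per_fold)), value = unname(per_fold))
    }
  }
  structure(list(metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
                 fold_metrics = do.call(rbind, c(fold_metrics,
                                                 list(make.row.names = FALSE))),
                 predictions = do.call(rbind, c(preds,
                                                list(make.row.names = FALSE))),
                 cv_plan = cv_plan, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", length(unique(x$metrics$task)), " tasks x ",
      length(unique(x$metrics$code)), " placement sets = ",
      nrow(x$metrics), " cells\n", sep = "")
  invisible(x)
}
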