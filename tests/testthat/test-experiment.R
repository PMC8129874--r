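test_that("enumerate_placement_sets yields all non-empty subsets in order", {
  sets <- enumerate_placement_sets()
  expect_length(sets, 31) # 2^5 - 1
  codes <- vapply(sets, function(s) s$code, character(1))
  expect_false(anyDuplicated(codes) > 0)
  sizes <- nchar(codes)
  expect_true(all(diff(sizes) >= 0)) # grouped by size
  expect_identical(codes[1:5], c("A", "B", "C", "D", "E"))
  expect_identical(codes[31], "ABCDE")
  expect_length(enumerate_placement_sets("hip"), 1)
  expect_length(enumerate_placement_sets(c("ankle", "hip", "wrist")), 7)
  expect_error(enumerate_placement_sets(character()),
               class = "placewear_argument_error")
  # letter codes follow the fixed A-E mapping
  expect_identical(placement_set(c("wrist", "hip"))$code, "CE")
})

test_that("make_cv_plan partitions participants exclusively and evenly", {
  ids <- sprintf("P%02d", 1:12)
  plan <- make_cv_plan(ids, n_outer = 6, n_inner = 5, seed = 4)
  test_sets <- lapply(plan$outer, `[[`, "test")
  expect_true(all(lengths(test_sets) == 2))
  expect_setequal(unlist(test_sets), ids)
  expect_identical(anyDuplicated(unlist(test_sets)), 0L)
  for (fold in plan$outer) {
    expect_length(intersect(fold$development, fold$test), 0)
    expect_setequal(c(fold$development, fold$test), ids)
    for (inner in fold$inner) {
      expect_length(intersect(inner$train, inner$validation), 0)
      expect_setequal(c(inner$train, inner$validation), fold$development)
    }
    vals <- unlist(lapply(fold$inner, `[[`, "validation"))
    expect_setequal(vals, fold$development) # inner folds partition dev
    expect_identical(anyDuplicated(vals), 0L)
  }
  # 93 participants over 6 folds: test sets of 15 or 16
  plan93 <- make_cv_plan(sprintf("S%03d", 1:93), seed = 1)
  sizes <- lengths(lapply(plan93$outer, `[[`, "test"))
  expect_true(all(sizes %in% c(15L, 16L)))
  expect_identical(sum(sizes), 93L)
  # determinism
  expect_identical(make_cv_plan(ids, seed = 4), plan)
  expect_error(make_cv_plan(ids[1:3], n_outer = 6),
               class = "placewear_argument_error")
})

test_that("train_and_predict separates a separable binary task and honors
           participant exclusivity", {
  feats <- fixture_features6()
  plan <- make_cv_plan(unique(feats$participant_id), seed = 8)
  res <- train_and_predict(feats, task_spec("locomotion_vs_non"),
                           placement_set("hip"), plan,
                           hyper_grid = data.frame(n_trees = 50, mtry = 4,
                                                   min_node = 1),
                           seed = 9)
  ba <- balanced_accuracy(res$records$truth, res$records$pred,
                          positive = "yes")
  expect_gte(ba, 0.95)
  expect_participant_exclusive(res$records, plan)
  # predictions exist only for test participants of their fold, for all rows
  expect_identical(nrow(res$records), nrow(feats))
})

test_that("a constant regression target gives zero test RMSE", {
  feats <- fixture_features6()
  feats$met <- 2.5
  plan <- make_cv_plan(unique(feats$participant_id), seed = 8)
  res <- train_and_predict(feats, task_spec("met_regression"),
                           placement_set("wrist"), plan,
                           hyper_grid = data.frame(n_trees = 10, mtry = 4,
                                                   min_node = 5),
                           seed = 2)
  expect_equal(rmse(res$records$truth_num, res$records$pred_num), 0)
})

test_that("hyperparameter tuning picks from the grid using inner folds only", {
  feats <- fixture_features6()
  plan <- make_cv_plan(unique(feats$participant_id), n_outer = 3,
                       n_inner = 3, seed = 2)
  grid <- data.frame(n_trees = 25, mtry = c(2, 6), min_node = c(1, 5))
  res <- train_and_predict(feats, task_spec("sedentary_vs_non"),
                           placement_set("hip"), plan, hyper_grid = grid,
                           seed = 1)
  expect_identical(nrow(res$chosen), 3L) # one choice per outer fold
  expect_true(all(res$chosen$mtry %in% grid$mtry))
  expect_error(train_and_predict(feats, task_spec("sedentary_vs_non"),
                                 placement_set("hip"), plan,
                                 hyper_grid = grid[0, ]),
               class = "placewear_argument_error")
})

test_that("folds missing a class are flagged and skipped", {
  feats <- fixture_features6()
  # make one participant the only carrier of the positive class
  feats <- feats[!(feats$is_sedentary & feats$participant_id != "P01"), ]
  plan <- make_cv_plan(unique(feats$participant_id), n_outer = 6,
                       n_inner = 2, seed = 3)
  ws <- capture_warnings(
    res <- train_and_predict(feats, task_spec("sedentary_vs_non"),
                             placement_set("hip"), plan,
                             hyper_grid = data.frame(n_trees = 10,
                                                     mtry = c(2, 4),
                                                     min_node = 1),
                             seed = 1))
  expect_true(any(grepl("absent", ws)))
  expect_gt(res$flagged + 0L, 0L)
})

test_that("run_full_experiment covers tasks x sets, is deterministic and
           resumable", {
  feats <- fixture_features6()
  labs <- met_labels(fixture_cohort6())
  key <- paste(feats$participant_id, feats$activity, sep = "|")
  feats$met <- labs$met[match(key, paste(labs$participant_id, labs$activity,
                                         sep = "|"))]
  tasks <- default_tasks()[c("locomotion_vs_non", "met_regression")]
  sets <- enumerate_placement_sets(c("hip", "wrist"))
  grid <- data.frame(n_trees = 15, mtry = NA, min_node = 1)
  res <- run_full_experiment(feats, tasks = tasks, sets = sets, seed = 10,
                             hyper_grid = grid, n_trees = 15)
  expect_identical(nrow(res$metrics), 6L) # 2 tasks x 3 sets
  expect_setequal(unique(res$metrics$code), c("C", "E", "CE"))
  res2 <- run_full_experiment(feats, tasks = tasks, sets = sets, seed = 10,
                              hyper_grid = grid, n_trees = 15)
  expect_identical(res$metrics, res2$metrics)
  # store_dir persistence: rerun reuses cells byte-identically
  store <- withr::local_tempdir()
  res3 <- run_full_experiment(feats, tasks = tasks, sets = sets, seed = 10,
                              hyper_grid = grid, n_trees = 15,
                              store_dir = store)
  expect_length(list.files(store, pattern = "^cell_"), 6)
  res4 <- run_full_experiment(feats, tasks = tasks, sets = sets, seed = 10,
                              hyper_grid = grid, n_trees = 15,
                              store_dir = store)
  expect_equal(res3$metrics$value, res4$metrics$value)
  expect_equal(res3$metrics$value, res$metrics$value)
})

test_that("adding a sensor does not systematically hurt (scaled-down
           superset property)", {
  # scaled down from the spec-level property (default cohort, >= 5 seeds,
  # all 31 sets) to fit the test budget: 3 seeds, hip/wrist vs hip+wrist,
  # the three binary category tasks, 25-tree forests
  feats <- fixture_features6()
  tasks <- default_tasks()[c("sedentary_vs_non", "locomotion_vs_non",
                             "lifestyle_vs_non")]
  sets <- enumerate_placement_sets(c("hip", "wrist"))
  grid <- data.frame(n_trees = 25, mtry = NA, min_node = 1)
  gaps <- c()
  for (seed in 1:3) {
    res <- run_full_experiment(feats, tasks = tasks, sets = sets,
                               seed = seed, hyper_grid = grid)
    for (tk in names(tasks)) {
      m <- res$metrics[res$metrics$task == tk, ]
      best1 <- max(m$value[nchar(m$code) == 1])
      best2 <- max(m$value[nchar(m$code) == 2])
      gaps <- c(gaps, best2 - best1)
    }
  }
  expect_true(all(gaps >= -0.02))
})
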