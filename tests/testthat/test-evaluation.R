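test_that("balanced accuracy is the mean of sensitivity and specificity", {
  # sensitivity 0.9, specificity 0.5 -> 0.7
  truth <- c(rep("yes", 10), rep("no", 10))
  pred <- c(rep("yes", 9), "no", rep("no", 5), rep("yes", 5))
  expect_equal(balanced_accuracy(truth, pred, positive = "yes"), 0.7)
  expect_equal(balanced_accuracy(truth, truth, positive = "yes"), 1.0)
  # all-positive predictor on imbalanced truth: sens 1, spec 0 -> 0.5
  truth2 <- c(rep("yes", 2), rep("no", 18))
  expect_equal(balanced_accuracy(truth2, rep("yes", 20), positive = "yes"),
               0.5)
  expect_warning(out <- balanced_accuracy(rep("yes", 5), rep("yes", 5)),
                 "undefined")
  expect_true(is.na(out))
})

test_that("accuracy and rmse follow their definitions", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(2, 1)), 1.0)
  expect_error(accuracy(character(), character()),
               class = "placewear_argument_error")
  expect_error(rmse(numeric(), numeric()),
               class = "placewear_argument_error")
  # chance predictions over k balanced classes give accuracy ~ 1/k
  set.seed(1)
  k <- 32; n <- 20000
  truth <- sample(letters_k <- sprintf("c%02d", 1:k), n, replace = TRUE)
  pred <- sample(letters_k, n, replace = TRUE)
  expect_lt(abs(accuracy(truth, pred) - 1 / k), 3 * sqrt((1 / k) / n))
})

test_that("confusion_matrix conserves marginals and flags foreign labels", {
  cls <- sprintf("c%02d", 1:32)
  set.seed(2)
  truth <- sample(cls, 500, replace = TRUE)
  pred <- sample(cls, 500, replace = TRUE)
  cm <- confusion_matrix(truth, pred, cls)
  expect_identical(dim(cm), c(32L, 32L))
  expect_identical(sum(cm), 500L)
  expect_identical(as.integer(unname(rowSums(cm))), unname(as.integer(table(
    factor(truth, levels = cls)))))
  # perfect predictions -> diagonal
  cmd <- confusion_matrix(truth, truth, cls)
  expect_identical(sum(diag(cmd)), 500L)
  # single record -> one nonzero cell at (a, b)
  cm1 <- confusion_matrix("c01", "c02", cls)
  expect_identical(sum(cm1), 1L)
  expect_identical(cm1["c01", "c02"], 1L)
  expect_error(confusion_matrix("zz", "c01", cls),
               class = "placewear_argument_error")
  # marginals conserved under any relabeling permutation
  perm <- sample(cls)
  cmp <- confusion_matrix(perm[match(truth, cls)], perm[match(pred, cls)], cls)
  expect_identical(sum(cmp), sum(cm))
  expect_setequal(as.integer(rowSums(cmp)),
                  as.integer(rowSums(cm)[match(perm, cls)]))
})

test_that("chance_level reports 100/k at one-decimal rounding", {
  expect_equal(chance_level(32), 3.1)
  expect_equal(chance_level(2), 50.0)
  expect_equal(chance_level(4), 25.0)
  expect_error(chance_level(1), class = "placewear_argument_error")
})

test_that("difference_vs_full ranks against the five-placement reference", {
  cells <- data.frame(
    task = "sedentary_vs_non", metric = "balanced_accuracy",
    code = c("ABCDE", "C", "A", "CE", "AC"),
    value = c(0.78, 0.73, 0.65, 0.76, 0.70))
  d <- difference_vs_full(cells, "sedentary_vs_non")
  expect_equal(d$difference[d$code == "ABCDE"], 0)
  expect_equal(d$difference[d$code == "C"], -0.05)
  # grouped by member count, sorted decreasing within group
  expect_identical(d$code, c("ABCDE", "CE", "AC", "C", "A"))
  # RMSE groups sort increasing: first row of each group is its minimum
  rcells <- data.frame(task = "met_regression", metric = "rmse",
                       code = c("ABCDE", "C", "D", "CE"),
                       value = c(0.88, 0.91, 0.93, 0.89))
  dr <- difference_vs_full(rcells, "met_regression")
  singles <- dr[dr$n_members == 1, ]
  expect_identical(singles$code[1], "C")
  expect_error(difference_vs_full(cells[cells$code != "ABCDE", ],
                                  "sedentary_vs_non"),
               class = "placewear_argument_error")
})

test_that("select_most_efficient applies margin, fewest-sensors and
           usability tie-breaks", {
  cells <- data.frame(task = "sedentary_vs_non", metric = "balanced_accuracy",
                      code = c("ABCDE", "C", "A"),
                      value = c(0.78, 0.73, 0.65))
  g <- select_most_efficient(cells, "sedentary_vs_non")
  expect_identical(g$most_efficient_code, "C") # hip within 10% of 0.78
  expect_identical(g$most_accurate_code, "ABCDE")
  # usability tie-break: wrist beats upper arm and hip at equal value
  cells2 <- data.frame(task = "lifestyle_vs_non", metric = "balanced_accuracy",
                       code = c("ABCE", "B", "E", "C"),
                       value = c(0.92, 0.87, 0.87, 0.87))
  g2 <- select_most_efficient(cells2, "lifestyle_vs_non")
  expect_identical(g2$most_efficient_code, "E")
  # single-combination input returns itself
  one <- data.frame(task = "t", metric = "accuracy", code = "C", value = 0.5)
  expect_identical(select_most_efficient(one, "t")$most_efficient_code, "C")
  # RMSE margin is applied upward
  rcells <- data.frame(task = "met_regression", metric = "rmse",
                       code = c("ABCD", "CE", "A"),
                       value = c(0.87, 0.89, 1.2))
  gr <- select_most_efficient(rcells, "met_regression")
  expect_identical(gr$most_efficient_code, "CE") # A is 38% worse, excluded
  # absolute margin mode
  ga <- select_most_efficient(rcells, "met_regression", margin = 0.01,
                              margin_mode = "absolute")
  expect_identical(ga$most_efficient_code, "ABCD")
})

test_that("difference of the full combination is exactly zero per task", {
  for (metric in c("balanced_accuracy", "rmse")) {
    cells <- data.frame(task = "t", metric = metric,
                        code = c("ABCDE", "C"), value = c(0.8, 0.7))
    expect_identical(
      difference_vs_full(cells, "t")$difference[
        difference_vs_full(cells, "t")$code == "ABCDE"], 0)
  }
})

test_that("label-permuted balanced accuracy concentrates at 0.5", {
  set.seed(3)
  n <- 4000
  truth <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.1, 0.9))
  vals <- replicate(20, balanced_accuracy(truth, sample(truth),
                                          positive = "yes"))
  # binomial bound: sd of (sens + spec)/2 under permutation
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})
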