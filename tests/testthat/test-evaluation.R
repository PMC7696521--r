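test_that("folds partition items into near-equal shuffled subsets", {
  f <- make_folds(75, k = 5, seed = 3)
  expect_equal(as.vector(table(f)), rep(15L, 5L))
  f2 <- make_folds(77, k = 5, seed = 3)
  expect_lte(diff(range(table(f2))), 1L)
  expect_equal(sort(unique(f2)), 1:5)
  # reproducible from the seed, different across seeds
  expect_identical(f, make_folds(75, k = 5, seed = 3))
  expect_false(identical(f, make_folds(75, k = 5, seed = 4)))
  expect_error(make_folds(4, k = 5), "fewer items")
})

test_that("subject-level folds never split a subject", {
  subj <- rep(sprintf("s%02d", 1:10), each = 7)
  f <- make_folds(length(subj), k = 5, mode = "subject", seed = 2,
                  subject_id = subj)
  tab <- table(subj, f)
  expect_true(all(rowSums(tab > 0) == 1L))
  expect_error(make_folds(10, k = 5, mode = "subject",
                          subject_id = rep("a", 10)), "fewer subjects")
})

test_that("stratified folds balance classes", {
  labels <- rep(c(1, 0), times = c(60, 40))
  f <- make_folds(100, k = 5, seed = 1, labels = labels, stratified = TRUE)
  tab <- table(f, labels)
  expect_true(all(tab[, "1"] == 12L))
  expect_true(all(tab[, "0"] == 8L))
})

test_that("confusion metrics match the defining arithmetic", {
  m <- confusion_metrics(list(TP = 50, TN = 45, FP = 5, FN = 0))
  expect_equal(unname(m), c(95, 100, 90))
  perfect <- confusion_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(100, 100, 100))
  half <- confusion_metrics(list(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_equal(unname(half), c(50, 50, 50))
  # empty class yields NaN markers, never silent zeros
  noneg <- confusion_metrics(list(TP = 3, TN = 0, FP = 0, FN = 1))
  expect_true(is.nan(noneg[["specificity"]]))
})

test_that("accuracy equals the class-weighted mean of sens and spec", {
  set.seed(21)
  for (i in 1:1000) {
    cts <- as.list(stats::setNames(sample(0:50, 4, replace = TRUE),
                                   c("TP", "TN", "FP", "FN")))
    if (cts$TP + cts$FN == 0 || cts$TN + cts$FP == 0) next
    m <- confusion_metrics(cts)
    P <- cts$TP + cts$FN
    N <- cts$TN + cts$FP
    expect_equal(m[["accuracy"]],
                 (P * m[["sensitivity"]] + N * m[["specificity"]]) / (P + N),
                 tolerance = 1e-10)
  }
})

test_that("ROC/AUC: perfect, chance and tie-handling cases", {
  labels <- c(1, 1, 0, 0, 1)
  perfect <- roc_and_auc(labels, labels)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$roc_points$fpr[1], 0)
  expect_equal(utils::tail(perfect$roc_points$tpr, 1), 1)
  const <- roc_and_auc(rep(0.4, 5), labels)
  expect_equal(const$auc, 0.5)
  expect_warning(one <- roc_and_auc(c(0.1, 0.9), c(1, 1)), "single class")
  expect_true(is.na(one$auc))
})

test_that("trapezoid AUC equals the pair-counting statistic", {
  # independent oracle: exhaustive positive-negative pair enumeration
  pair_auc <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
    s / (length(pos) * length(neg))
  }
  set.seed(8)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)  # rounding forces ties
    got <- roc_and_auc(p, y)$auc
    expect_equal(got, pair_auc(p, y), tolerance = 1e-12)
  }
})

test_that("our ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rbinom(150, 1, 0.5)
  p <- runif(150)
  ours <- roc_and_auc(p, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("cross-validation reports coherent fold metrics on easy data", {
  imgs <- make_separable_images(n = 80)
  cfg <- cnn_config(seed = 4, epochs = 3)
  rep <- cross_validate(imgs, cfg, k = 5, mode = "epoch")
  expect_equal(nrow(rep$per_fold), 5L)
  expect_equal(sum(rep$per_fold$n_test), 80L)
  expect_true(all(rep$per_fold$accuracy >= 0 & rep$per_fold$accuracy <= 100))
  expect_equal(unname(rep$means["accuracy"]),
               mean(rep$per_fold$accuracy))
  expect_gte(rep$means[["accuracy"]], 90)
  # mean ROC is a proper monotone curve on the FPR grid
  expect_equal(nrow(rep$mean_roc), 101L)
  expect_true(all(diff(rep$mean_roc$tpr) >= -1e-12))
  expect_false(is.null(rep$leakage_note))
  # identical seed reruns give the identical report
  rep2 <- cross_validate(imgs, cfg, k = 5, mode = "epoch")
  expect_identical(rep$per_fold, rep2$per_fold)
  expect_identical(rep$means, rep2$means)
})

test_that("cross-validation is at chance on label-independent images", {
  imgs <- make_null_images(n = 100)
  accs <- aucs <- numeric(3)
  for (i in 1:3) {
    rep <- cross_validate(imgs, cnn_config(seed = 40 + i, epochs = 2),
                          k = 5, mode = "epoch")
    accs[i] <- rep$means[["accuracy"]]
    aucs[i] <- rep$means[["auc"]]
  }
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("cv reports serialize to JSON, CSV and PNG", {
  imgs <- make_separable_images(n = 40)
  rep <- cross_validate(imgs, cnn_config(seed = 2, epochs = 1), k = 4)
  path <- tempfile(fileext = ".json")
  write_cv_report(rep, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$k, 4)
  expect_equal(got$means$accuracy, rep$means[["accuracy"]])
  csv <- tempfile(fileext = ".csv")
  write_roc_csv(rep, csv)
  roc <- utils::read.csv(csv)
  expect_setequal(unique(roc$fold), c("1", "2", "3", "4", "mean"))
  expect_equal(sum(roc$fold == "mean"), 101L)
  png_path <- tempfile(fileext = ".png")
  plot_roc_png(rep, png_path)
  expect_gt(file.size(png_path), 0)
  unlink(c(path, csv, png_path))
})
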