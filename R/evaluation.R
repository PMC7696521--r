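# k-fold cross-validated evaluation: confusion metrics, ROC/AUC.

#' Partition items into k cross-validation folds
#'
#' Items are shuffled and split into `k` near-equal folds (sizes differing
#' by at most one).  `mode = "epoch"` splits individual items irrespective
#' of subject; `mode = "subject"` keeps all epochs of a subject in one fold
#' (leakage-safe), assigning whole subjects to folds round-robin after a
#' shuffle.  `stratified = TRUE` shuffles and splits within each class so
#' every fold has a near-equal class mix.
#'
#' @param n Number of items, or a data frame/manifest with `subject_id`.
#' @param k Number of folds (>= 2).
#' @param mode `"epoch"` or `"subject"`.
#' @param seed Integer seed; folds are reproducible from it.
#' @param subject_id Subject identifiers (required for subject mode when
#'   `n` is a count).
#' @param labels Class labels, required when `stratified = TRUE`.
#' @param stratified Stratify folds by class (default `FALSE`).
#' @return Integer vector of fold assignments in `1..k`, one per item.
#' @export
make_folds <- function(n, k = 5L, mode = c("epoch", "subject"), seed = 1L,
                       subject_id = NULL, labels = NULL,
                       stratified = FALSE) {
  mode <- match.arg(mode)
  if (is.data.frame(n)) {
    if (is.null(subject_id)) subject_id <- n$subject_id
    n <- nrow(n)
  }
  n <- as.integer(n)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("fewer items than folds", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  # fold labels for m items: near-equal sizes, order as given
  balanced_labels <- function(m) {
    sizes <- rep(m %/% k, k)
    extra <- m %% k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    rep(seq_len(k), times = sizes)
  }
  if (mode == "subject") {
    if (is.null(subject_id)) {
      stop("subject-level folds require subject_id", call. = FALSE)
    }
    subjects <- unique(subject_id)
    if (length(subjects) < k) {
      stop("fewer subjects than folds", call. = FALSE)
    }
    perm <- sample(subjects)
    fold_of_subject <- stats::setNames(rep_len(seq_len(k), length(perm)),
                                       perm)
    return(unname(fold_of_subject[as.character(subject_id)]))
  }
  if (stratified) {
    if (is.null(labels)) stop("stratified folds require labels",
                              call. = FALSE)
    folds <- integer(n)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      folds[idx[sample.int(length(idx))]] <- balanced_labels(length(idx))
    }
    return(folds)
  }
  folds <- integer(n)
  folds[sample.int(n)] <- balanced_labels(n)
  folds
}

#' Confusion counts from probabilities and labels
#'
#' @param probabilities Numeric scores in `[0, 1]`.
#' @param labels Binary truth (1 = MDD-like positive class).
#' @param threshold Decision threshold (default 0.5; calls are positive
#'   when `p >= threshold`).
#' @return List of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels))
  pred <- probabilities >= threshold
  truth <- labels >= 0.5
  structure(list(TP = sum(pred & truth), TN = sum(!pred & !truth),
                 FP = sum(pred & !truth), FN = sum(!pred & truth)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = 100 (TP + TN) / (TP + TN + FP + FN);
#' sensitivity = 100 TP / (TP + FN) (true-positive rate over MDD cases);
#' specificity = 100 TN / (TN + FP) (true-negative rate over controls).
#' An absent class yields `NaN` for the affected rate, never a silent zero.
#'
#' @param counts A `confusion_counts` (or list with TP/TN/FP/FN).
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   in percent.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table", call. = FALSE)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NaN
  c(accuracy = 100 * (tp + tn) / total, sensitivity = sens,
    specificity = spec)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over all distinct scores (plus the
#' all-positive and all-negative extremes), collecting (FPR, TPR) points,
#' and integrates the curve by the trapezoid rule.  Ties receive half
#' credit, so the AUC equals the Mann-Whitney pair-ordering statistic.
#'
#' @param probabilities Numeric scores.
#' @param labels Binary truth (1 = positive).
#' @return List with `roc_points` (data frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc` in `[0, 1]`; `NA` AUC with a warning when only one
#'   class is present.
#' @export
roc_and_auc <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  truth <- labels >= 0.5
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    warning("ROC undefined with a single class", call. = FALSE)
    return(list(roc_points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auc = NA_real_))
  }
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t)
    sum(probabilities >= t & truth) / n_pos, numeric(1L)))
  fpr <- c(0, vapply(thr, function(t)
    sum(probabilities >= t & !truth) / n_neg, numeric(1L)))
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# Vertical averaging of fold ROC curves on a fixed FPR grid.
average_roc <- function(roc_list, grid = seq(0, 1, length.out = 101L)) {
  tprs <- vapply(roc_list, function(r) {
    stats::approx(r$fpr, r$tpr, xout = grid, method = "linear",
                  ties = "ordered", rule = 2L)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}

#' Cross-validated training and evaluation of the CNN
#'
#' Splits the labeled image set into `k` folds ([make_folds()]), trains a
#' fresh CNN on each training split and evaluates on the held-out fold,
#' reporting per-fold and mean accuracy/sensitivity/specificity (percent),
#' per-fold ROC/AUC, and a vertically averaged mean ROC on a 101-point
#' FPR grid.
#'
#' With `mode = "epoch"` (the default) epochs of one subject can appear in
#' both training and test folds; the report carries a leakage note in that
#' case.  `mode = "subject"` holds out whole subjects.
#'
#' @param images An `image_set` (see [make_benchmark()] or
#'   [image_set()]).
#' @param config A [cnn_config()]; its seed governs fold assignment and
#'   per-fold training (each fold trains under `seed + fold - 1`).
#' @param k Number of folds (default 5).
#' @param mode `"epoch"` or `"subject"`.
#' @param stratified Stratify folds by class (default `FALSE`).
#' @param labels Optional label override (e.g. a permutation for a null
#'   experiment).
#' @return An object of class `cv_report`.
#' @export
cross_validate <- function(images, config = cnn_config(), k = 5L,
                           mode = c("epoch", "subject"),
                           stratified = FALSE, labels = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(images, "image_set"))
  if (is.null(labels)) labels <- images$manifest$label
  labels <- as.integer(labels >= 0.5)
  folds <- make_folds(nrow(images$x), k = k, mode = mode,
                      seed = config$seed,
                      subject_id = images$manifest$subject_id,
                      labels = labels, stratified = stratified)
  fold_rows <- vector("list", k)
  metrics <- vector("list", k)
  rocs <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    fold_cfg <- config
    fold_cfg$seed <- config$seed + f - 1L
    model <- build_cnn(fold_cfg)
    model <- train_cnn(model,
                       images = images$x[train_idx, , drop = FALSE],
                       labels = labels[train_idx])
    p <- predict_cnn(model, images$x[test_idx, , drop = FALSE])
    cm <- confusion_metrics(
      confusion_counts(p, labels[test_idx], config$threshold))
    roc <- roc_and_auc(p, labels[test_idx])
    metrics[[f]] <- data.frame(fold = f, n_test = length(test_idx),
                               accuracy = cm[["accuracy"]],
                               sensitivity = cm[["sensitivity"]],
                               specificity = cm[["specificity"]],
                               auc = roc$auc)
    rocs[[f]] <- roc$roc_points
    fold_rows[[f]] <- test_idx
  }
  per_fold <- do.call(rbind, metrics)
  rownames(per_fold) <- NULL
  means <- colMeans(per_fold[, c("accuracy", "sensitivity",
                                 "specificity", "auc")])
  structure(
    list(per_fold = per_fold, means = means,
         mean_roc = average_roc(rocs), fold_rocs = rocs,
         split_mode = mode, stratified = stratified, k = k,
         seed = config$seed,
         leakage_note = if (mode == "epoch")
           paste("epoch-level folds: epochs of one subject may appear in",
                 "both training and test sets") else NULL),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold, %s-level split, seed %d\n",
              x$k, x$split_mode, x$seed))
  print(x$per_fold, row.names = FALSE)
  cat(sprintf(
    "means: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.4f\n",
    x$means[["accuracy"]], x$means[["sensitivity"]],
    x$means[["specificity"]], x$means[["auc"]]))
  if (!is.null(x$leakage_note)) cat("note:", x$leakage_note, "\n")
  invisible(x)
}

#' Write ROC points of a cross-validation report as CSV
#'
#' One row per ROC point with columns `fold` (`"mean"` for the vertically
#' averaged curve), `fpr`, `tpr`.
#'
#' @param report A `cv_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  rows <- do.call(rbind, lapply(seq_along(report$fold_rocs), function(f)
    cbind(fold = as.character(f), report$fold_rocs[[f]])))
  rows <- rbind(rows, cbind(fold = "mean", report$mean_roc))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Diagnostic ROC plot of a cross-validation report
#'
#' Draws the per-fold ROC curves and the vertically averaged mean curve
#' against the chance diagonal, as a PNG.
#'
#' @param report A `cv_report`.
#' @param path Output PNG path.
#' @param width,height Plot size in pixels.
#' @return `path`, invisibly.
#' @export
plot_roc_png <- function(report, path, width = 600, height = 600) {
  stopifnot(inherits(report, "cv_report"))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False-positive rate", ylab = "True-positive rate",
                 main = sprintf("%d-fold ROC (mean AUC %.3f)",
                                report$k, report$means[["auc"]]))
  graphics::abline(0, 1, lty = 3, col = "grey50")
  for (r in report$fold_rocs) {
    graphics::lines(r$fpr, r$tpr, col = "grey70")
  }
  graphics::lines(report$mean_roc$fpr, report$mean_roc$tpr,
                  col = "firebrick", lwd = 2)
  invisible(path)
}

#' Serialize a cross-validation report as JSON
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  jsonlite::write_json(
    list(k = report$k, split_mode = report$split_mode,
         stratified = report$stratified, seed = report$seed,
         leakage_note = report$leakage_note,
         per_fold = report$per_fold, means = as.list(report$means),
         mean_roc = report$mean_roc),
    path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}
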