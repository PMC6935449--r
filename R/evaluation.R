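#' Confusion matrix with the percentage-table conventions
#'
#' Rows are true classes, columns predictions. Derived fields: row-normalized
#' percentages, per-class accuracies (diagonal percentages), their mean
#' (\code{average}, the confusion-table "Average" convention) and the overall
#' micro accuracy (\code{accuracy}, correct / total).
#'
#' @param true character vector of true labels.
#' @param pred character vector of predicted labels (same length).
#' @param labels ordered class list; defaults to sorted union.
#' @return object of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(true, pred, labels = NULL) {
  if (length(true) != length(pred))
    stop("confusion_matrix: true and pred must have equal length")
  if (is.null(labels)) labels <- sort(unique(c(true, pred)))
  counts <- table(factor(true, levels = labels),
                  factor(pred, levels = labels))
  counts <- matrix(as.integer(counts), length(labels), length(labels),
                   dimnames = list(true = labels, predicted = labels))
  rs <- rowSums(counts)
  perc <- 100 * counts / ifelse(rs == 0, 1, rs)
  per_class <- diag(perc)
  structure(list(labels = labels, counts = counts, percentages = perc,
                 per_class = setNames(per_class, labels),
                 average = mean(per_class[rs > 0]),
                 accuracy = if (sum(counts) > 0)
                   100 * sum(diag(counts)) / sum(counts) else NaN),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("Confusion matrix (row-normalized, unit: %)\n")
  print(round(x$percentages, digits))
  cat(sprintf("Average (mean of diagonal): %.2f%%; overall accuracy: %.2f%%\n",
              x$average, x$accuracy))
  invisible(x)
}

#' k-fold partitions, grouped or stratified
#'
#' Grouped mode assigns whole groups (pseudo-subjects) to folds — each fold's
#' test set is the sequences of a disjoint group subset, the
#' leave-subjects-out protocol. Stratified mode deals each class's sequences
#' round-robin into class-balanced folds. Partitions cover the dataset
#' exactly once; deterministic per seed.
#'
#' @param dataset list of \code{feature_sequence} objects.
#' @param k number of folds.
#' @param mode \code{"grouped"} or \code{"stratified"}.
#' @param seed integer seed for the shuffles.
#' @return list of k folds, each a list with integer index vectors
#'   \code{train} and \code{test}.
#' @export
kfold_split <- function(dataset, k, mode = c("grouped", "stratified"),
                        seed = 1L) {
  mode <- match.arg(mode)
  n <- length(dataset)
  set.seed(as.integer(seed))
  if (mode == "grouped") {
    groups <- vapply(dataset, function(s)
      if (is.null(s$group_id)) NA_character_ else s$group_id, character(1))
    if (anyNA(groups))
      stop("kfold_split: grouped mode requires group_id on every sequence")
    ug <- sort(unique(groups))
    if (length(ug) < k)
      stop("kfold_split: ", length(ug), " groups but k = ", k)
    ug <- sample(ug)
    fold_of_group <- setNames(rep(seq_len(k), length.out = length(ug)), ug)
    fold_of <- unname(fold_of_group[groups])
  } else {
    labs <- vapply(dataset, function(s)
      if (is.null(s$label)) "" else s$label, character(1))
    fold_of <- integer(n)
    for (lv in unique(labs)) {
      idx <- sample(which(labs == lv))
      fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Cross-validated evaluation of an HCRF variant
#'
#' Trains from scratch on each fold's training split (fresh seeded
#' initialization computed on the training split only) and predicts the test
#' split. Folds whose training split misses a class are skipped with a
#' warning and recorded.
#'
#' @param dataset labeled list of \code{feature_sequence} objects.
#' @param config a \code{train_config} (its \code{cov} field selects the full
#'   or diagonal model).
#' @param k number of folds.
#' @param mode split mode, see \code{\link{kfold_split}}.
#' @param seed seed for the fold split (training seeds derive from
#'   \code{config$seed}).
#' @return object of class \code{cv_report}: per-fold confusion matrices and
#'   accuracies, pooled confusion matrix, mean and sd of fold accuracies,
#'   fold metadata, indices of skipped folds.
#' @export
cross_validate <- function(dataset, config = train_config(), k = 5L,
                           mode = c("grouped", "stratified"), seed = 1L) {
  mode <- match.arg(mode)
  labs <- dataset_labels(dataset)
  labels <- sort(unique(labs))
  folds <- kfold_split(dataset, k, mode, seed)
  fold_cm <- vector("list", k)
  fold_acc <- rep(NA_real_, k)
  skipped <- integer(0)
  all_true <- character(0); all_pred <- character(0)
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    if (!setequal(unique(labs[tr]), labels)) {
      warning("cross_validate: fold ", f,
              " training split misses a class; fold skipped")
      skipped <- c(skipped, f)
      next
    }
    cfg <- config
    cfg$seed <- config$seed + 131L * f
    fit <- fit_gmhcrf(dataset[tr], cfg)
    pred <- predict(fit$model, dataset[te])
    fold_cm[[f]] <- confusion_matrix(labs[te], pred, labels)
    fold_acc[f] <- fold_cm[[f]]$accuracy
    all_true <- c(all_true, labs[te]); all_pred <- c(all_pred, pred)
  }
  used <- which(!is.na(fold_acc))
  structure(list(fold_confusions = fold_cm, fold_accuracies = fold_acc,
                 pooled = confusion_matrix(all_true, all_pred, labels),
                 mean_accuracy = mean(fold_acc[used]),
                 sd_accuracy = stats::sd(fold_acc[used]),
                 skipped = skipped,
                 meta = list(k = k, mode = mode, seed = seed,
                             cov = config$cov, labels = labels)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold (%s) cross-validation, %s-covariance model\n",
              x$meta$k, x$meta$mode, x$meta$cov))
  cat(sprintf("  fold accuracies: %s\n",
              paste(sprintf("%.1f", x$fold_accuracies), collapse = " ")))
  cat(sprintf("  mean +/- sd: %.2f +/- %.2f %%; pooled: %.2f %%\n",
              x$mean_accuracy, x$sd_accuracy, x$pooled$accuracy))
  if (length(x$skipped)) cat("  skipped folds:",
                             paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

# exact two-sided sign-flip signed-rank p-value (average ranks, zeros dropped)
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= 16L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- drop(signs %*% r)
    p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
    return(min(1, p))
  }
  # normal approximation for large n
  mu <- n * (n + 1) / 4
  sg <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  min(1, 2 * stats::pnorm(-abs(w_obs - mu) / sg))
}

#' Paired fold-level comparison of two cross-validation reports
#'
#' Paired two-sided Wilcoxon signed-rank test (exact sign-flip enumeration
#' for up to 16 informative folds) on the fold accuracies of two reports
#' built over the same folds, plus the mean difference A - B.
#'
#' @param reportA,reportB \code{cv_report} objects with identical fold
#'   structure (same k, mode and split seed).
#' @return list with \code{mean_difference}, \code{differences} (per fold),
#'   and \code{p_value}.
#' @export
compare_models <- function(reportA, reportB) {
  ma <- reportA$meta; mb <- reportB$meta
  if (!identical(ma[c("k", "mode", "seed")], mb[c("k", "mode", "seed")]))
    stop("compare_models: reports were built over different folds")
  d <- reportA$fold_accuracies - reportB$fold_accuracies
  d <- d[!is.na(d)]
  list(mean_difference = mean(d), differences = d,
       p_value = signed_rank_exact_p(d))
}
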