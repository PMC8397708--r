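# Per-sample chromothripsis prediction from signature exposures:
# stratified k-fold cross-validated L2 logistic regression, per-fold ROC/AUC
# averaging, bootstrap AUC-difference comparison, and CN_pred binarization
# at probability >= 0.6.

#' Trapezoidal ROC AUC with midrank tie handling
#'
#' Computed as the normalized Mann-Whitney statistic, which equals the
#' trapezoidal area under the ROC curve with ties handled by midranks.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (1 = chromothripsis).
#' @return AUC in `[0, 1]`; constant scores give 0.5.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

exposures_xy <- function(exposures, labels) {
  x <- as_count_matrix(exposures)
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample", "chromothripsis") %in% names(labels)))
    lab <- setNames(labels$chromothripsis, labels$sample)
    y <- as.integer(lab[rownames(x)])
    if (anyNA(y)) abort("labels missing for some samples")
  } else {
    y <- as.integer(labels)
    stopifnot(length(y) == nrow(x))
  }
  if (!all(y %in% 0:1)) abort("labels must be 0/1")
  list(x = x, y = y)
}

# Stratified fold assignment: within each class, samples are shuffled
# (seeded) and dealt round-robin over folds.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# Ridge logistic fit + prediction; penalty strength C on the sklearn-like
# scale (lambda = 1 / (n * C)).
ridge_logistic_prob <- function(x_train, y_train, x_test, C = 1) {
  pad <- ncol(x_train) < 2
  if (pad) { # glmnet needs >= 2 columns; a zero column is inert
    x_train <- cbind(x_train, .pad = 0)
    x_test <- cbind(x_test, .pad = 0)
  }
  fit <- withCallingHandlers(
    glmnet::glmnet(
      x_train, y_train,
      family = "binomial", alpha = 0,
      lambda = 1 / (nrow(x_train) * C), standardize = FALSE
    ),
    # expected on small CV folds; the ridge penalty handles the imbalance
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  as.numeric(predict(fit, newx = x_test, type = "response"))
}

#' Cross-validated chromothripsis prediction from exposures
#'
#' Stratified k-fold cross-validation: within each training fold an
#' L2-regularized logistic model is fitted on the exposure fractions (all
#' signatures as input); out-of-fold probabilities are recorded. The
#' headline AUC is the average of per-fold AUCs (the pooled out-of-fold AUC
#' is also reported).
#'
#' @param exposures Samples-by-signatures matrix or wide tibble.
#' @param labels 0/1 vector aligned with the exposure rows, or a tibble
#'   `sample, chromothripsis`.
#' @param k Number of folds (10 by default; use 5 for small cohorts).
#' @param seed Fold-assignment seed.
#' @param C Inverse regularization strength of the ridge logistic model.
#' @param threshold CN_pred binarization threshold (probability scale).
#' @return An object of class `chromothripsis_prediction` with the
#'   out-of-fold probability table, per-fold AUCs, `mean_auc`, `pooled_auc`
#'   and the binarized `cn_pred` call.
#' @export
crossval_predict <- function(exposures, labels, k = 10, seed = 1, C = 1,
                             threshold = 0.6) {
  d <- exposures_xy(exposures, labels)
  x <- d$x; y <- d$y
  if (length(unique(y)) < 2) abort("labels contain a single class")
  if (k > length(y)) abort("k exceeds the number of samples")
  if (k > min(table(y))) abort("k exceeds the minority-class count")
  fold <- stratified_folds(y, k, seed)
  prob <- numeric(length(y))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    test <- fold == f
    prob[test] <- ridge_logistic_prob(
      x[!test, , drop = FALSE], y[!test], x[test, , drop = FALSE], C = C
    )
    fold_auc[f] <- roc_auc(prob[test], y[test])
  }
  res <- tibble(
    sample = rownames(x), prob = prob, fold = fold, label = y,
    cn_pred = if_else(prob >= threshold, "high", "low")
  )
  structure(
    list(
      predictions = res,
      fold_auc = fold_auc,
      mean_auc = mean(fold_auc, na.rm = TRUE),
      pooled_auc = roc_auc(prob, y),
      k = k, seed = seed, threshold = threshold
    ),
    class = "chromothripsis_prediction"
  )
}

#' @exportS3Method base::print
print.chromothripsis_prediction <- function(x, ...) {
  cat(
    "<chromothripsis_prediction> ", nrow(x$predictions), " samples, ",
    x$k, "-fold CV, mean AUC ", sprintf("%.3f", x$mean_auc),
    " (pooled ", sprintf("%.3f", x$pooled_auc), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.chromothripsis_prediction <- function(x, ...) x$predictions

#' @export
glance.chromothripsis_prediction <- function(x, ...) {
  tibble(
    n = nrow(x$predictions), k = x$k,
    mean_auc = x$mean_auc, pooled_auc = x$pooled_auc,
    threshold = x$threshold
  )
}

# ROC points (sens/spec sweep) for one score vector.
roc_points <- function(scores, labels) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble(
    threshold = ths,
    sensitivity = vapply(ths, function(t) mean(scores[labels == 1] >= t), 0),
    specificity = vapply(ths, function(t) mean(scores[labels == 0] < t), 0)
  )
}

#' @export
autoplot.chromothripsis_prediction <- function(object, ...) {
  d <- object$predictions
  per_fold <- d |>
    group_by(.data$fold) |>
    reframe(roc_points(.data$prob, .data$label)) |>
    ungroup()
  pooled <- roc_points(d$prob, d$label)
  ggplot2::ggplot(per_fold, ggplot2::aes(
    x = 1 - .data$specificity, y = .data$sensitivity, group = .data$fold
  )) +
    ggplot2::geom_step(color = "steelblue", alpha = 0.5) +
    ggplot2::geom_step(
      data = pooled, ggplot2::aes(group = NULL), color = "red", linewidth = 1
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("mean AUC = %.3f", object$mean_auc)
    )
}

#' Binarize the chromothripsis prediction score
#'
#' Calls each sample high/low CN_pred at `threshold` (probability >= 0.6 by
#' default is "high"), summarizes the confusion matrix against the labels,
#' and returns a threshold sweep table (sensitivity/specificity per
#' threshold) supporting threshold selection at a specificity target.
#'
#' @param result A `chromothripsis_prediction`.
#' @param threshold Probability cutoff (default 0.6).
#' @return A list: `calls` tibble (`sample, prob, cn_pred`), `sensitivity`,
#'   `specificity`, `confusion` tibble, and the `sweep` table.
#' @export
call_cn_pred <- function(result, threshold = 0.6) {
  d <- result$predictions
  call <- if_else(d$prob >= threshold, "high", "low")
  tp <- sum(call == "high" & d$label == 1)
  fp <- sum(call == "high" & d$label == 0)
  fn <- sum(call == "low" & d$label == 1)
  tn <- sum(call == "low" & d$label == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  sweep_tab <- roc_points(d$prob, d$label)
  list(
    calls = tibble(sample = d$sample, prob = d$prob, cn_pred = call),
    sensitivity = sens, specificity = spec,
    confusion = tibble(tp = tp, fp = fp, fn = fn, tn = tn),
    sweep = sweep_tab,
    threshold = threshold
  )
}

#' Bootstrap comparison of two feature sets' CV AUCs
#'
#' Point estimate: difference in mean cross-validated AUC between feature
#' sets A and B on the full data. Uncertainty: samples are resampled with
#' replacement; on each bootstrap replicate the k-fold CV is re-run for both
#' feature sets and the AUC difference recorded. The standard deviation over
#' replicates yields a two-sided p-value by normal approximation.
#' Replicates drawing a single class are redrawn (and logged).
#'
#' @param exposures_a,exposures_b Two feature matrices over the same
#'   samples.
#' @param labels 0/1 labels (vector or `sample, chromothripsis` tibble).
#' @param k CV folds per replicate.
#' @param n_boot Bootstrap replicates (>= 2; the reference analysis used
#'   1000).
#' @param seed RNG seed.
#' @param C Ridge strength passed through to the classifier.
#' @return An object of class `auc_comparison` with `auc_a`, `auc_b`,
#'   `difference`, `sd`, `p_value`, `n_boot`.
#' @export
compare_auc_bootstrap <- function(exposures_a, exposures_b, labels, k = 10,
                                  n_boot = 1000, seed = 1, C = 1) {
  if (n_boot < 2) abort("n_boot must be at least 2 to estimate an SD")
  da <- exposures_xy(exposures_a, labels)
  db <- exposures_xy(exposures_b, labels)
  if (!identical(da$y, db$y) || nrow(da$x) != nrow(db$x)) {
    abort("feature sets must cover the same samples and labels")
  }
  y <- da$y
  auc_a <- crossval_predict(da$x, y, k = k, seed = derive_seed(seed, 0), C = C)$mean_auc
  auc_b <- crossval_predict(db$x, y, k = k, seed = derive_seed(seed, 0), C = C)$mean_auc
  diff_point <- auc_a - auc_b
  diffs <- numeric(n_boot)
  redraws <- 0
  set.seed(derive_seed(seed, 1))
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample(length(y), replace = TRUE)
      if (length(unique(y[idx])) == 2 && min(table(y[idx])) >= k) break
      redraws <- redraws + 1
      if (redraws > 100 * n_boot) abort("could not draw two-class bootstrap replicates")
    }
    fs <- derive_seed(seed, b + 1)
    a <- crossval_predict(da$x[idx, , drop = FALSE], y[idx], k = k, seed = fs, C = C)$mean_auc
    bb <- crossval_predict(db$x[idx, , drop = FALSE], y[idx], k = k, seed = fs, C = C)$mean_auc
    diffs[b] <- a - bb
  }
  sd_boot <- sd(diffs)
  p <- if (sd_boot == 0) {
    if (diff_point == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(diff_point) / sd_boot)
  }
  structure(
    list(
      auc_a = auc_a, auc_b = auc_b, difference = diff_point,
      sd = sd_boot, p_value = p, n_boot = n_boot, redraws = redraws,
      boot_differences = diffs
    ),
    class = "auc_comparison"
  )
}

#' @exportS3Method base::print
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "<auc_comparison> AUC A %.3f vs B %.3f; diff %.3f (SD %.3f, p = %.3g, %d bootstraps)\n",
    x$auc_a, x$auc_b, x$difference, x$sd, x$p_value, x$n_boot
  ))
  invisible(x)
}

#' @export
tidy.auc_comparison <- function(x, ...) {
  tibble(
    auc_a = x$auc_a, auc_b = x$auc_b, difference = x$difference,
    sd = x$sd, p_value = x$p_value, n_boot = x$n_boot
  )
}

#' Audit discrepant predictions
#'
#' Lists false-positive and false-negative samples at the CN_pred threshold
#' together with their complex-event content, to examine whether
#' near-threshold complexity (e.g. complex-NOS just under the chromothripsis
#' pair minimum) explains the discrepancy.
#'
#' @param result A `chromothripsis_prediction`.
#' @param calls Event calls from [classify_complex_events()].
#' @param threshold Probability cutoff (default the result's).
#' @return A tibble of discrepant samples with `kind` (`false_positive` /
#'   `false_negative`) and their event-class counts.
#' @export
audit_discrepant <- function(result, calls, threshold = NULL) {
  threshold <- threshold %||% result$threshold
  d <- result$predictions |>
    mutate(pred = as.integer(.data$prob >= threshold)) |>
    filter(.data$pred != .data$label) |>
    mutate(kind = if_else(.data$pred == 1, "false_positive", "false_negative"))
  ev <- calls |>
    filter(.data$class != "single") |>
    count(.data$sample, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0)
  d |>
    select("sample", "prob", "label", "kind") |>
    left_join(ev, by = "sample") |>
    mutate(across(-c("sample", "prob", "label", "kind"),
                  ~ dplyr::coalesce(.x, 0L)))
  }
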