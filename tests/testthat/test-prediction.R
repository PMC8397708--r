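# Synthetic exposure matrices with a chromothripsis-informative signature:
# positives put ~`shift` of their weight on SIG1, negatives at most 0.4, so
# at noise = 0 the classes are strictly separable.
informative_exposures <- function(n, frac_pos = 0.3, shift = 0.9, noise = 0.1,
                                  seed = 1) {
  set.seed(seed)
  y <- rep(0L, n)
  y[sample(n, round(n * frac_pos))] <- 1L
  w <- ifelse(y == 1, shift + runif(n, 0, 0.05), runif(n, 0, 0.4)) +
    rnorm(n, 0, noise)
  w <- pmin(pmax(w, 0), 0.98)
  rest <- matrix(rgamma(n * 3, 1), n, 3)
  rest <- rest / rowSums(rest) * (1 - w)
  base <- cbind(w, rest)
  rownames(base) <- sprintf("S%03d", seq_len(n))
  colnames(base) <- paste0("SIG", 1:4)
  list(x = base, y = y)
}

test_that("roc_auc matches pair enumeration and handles ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  # invariant under strictly monotone transforms
  s <- runif(50); y <- rbinom(50, 1, 0.4)
  expect_equal(roc_auc(s, y), roc_auc(qlogis(s), y))
  expect_equal(roc_auc(s, y), roc_auc(s^3, y))
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  s <- c(runif(40), runif(30) + 0.3)
  y <- rep(c(0, 1), c(40, 30))
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(s, y), ref)
})

test_that("perfectly separable exposures give mean CV AUC of 1", {
  d <- informative_exposures(100, shift = 0.9, noise = 0)
  res <- crossval_predict(d$x, d$y, k = 10, seed = 2)
  expect_equal(res$mean_auc, 1)
  expect_true(all(res$predictions$prob >= 0 & res$predictions$prob <= 1))
  # each sample appears in exactly one test fold
  expect_equal(sort(unique(res$predictions$fold)), 1:10)
  expect_equal(nrow(res$predictions), 100)
})

test_that("label permutation drives the CV AUC to chance", {
  d <- informative_exposures(120, shift = 0.8, seed = 3)
  set.seed(4)
  aucs <- replicate(25, {
    crossval_predict(d$x, sample(d$y), k = 5, seed = sample(1e4, 1))$mean_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("single-class labels and oversized k are rejected", {
  d <- informative_exposures(30)
  expect_error(crossval_predict(d$x, rep(1, 30)), "single class")
  expect_error(crossval_predict(d$x, d$y, k = 29), "minority")
})

test_that("duplicating a separable cohort leaves the AUC unchanged", {
  d <- informative_exposures(60, shift = 0.9, noise = 0, seed = 5)
  a <- crossval_predict(d$x, d$y, k = 5, seed = 6)$mean_auc
  x2 <- rbind(d$x, d$x)
  rownames(x2) <- sprintf("D%03d", seq_len(nrow(x2)))
  b <- crossval_predict(x2, c(d$y, d$y), k = 5, seed = 6)$mean_auc
  expect_equal(a, b)
})

test_that("CN_pred binarizes at the 0.6 boundary inclusively", {
  res <- structure(
    list(
      predictions = tibble(
        sample = c("A", "B", "C"), prob = c(0.6, 0.59999, 0.0),
        fold = 1L, label = c(1L, 0L, 0L),
        cn_pred = NA_character_
      ),
      threshold = 0.6
    ),
    class = "chromothripsis_prediction"
  )
  cp <- call_cn_pred(res, threshold = 0.6)
  expect_equal(cp$calls$cn_pred, c("high", "low", "low"))
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)
})

test_that("all-zero probabilities yield all-low calls with specificity 1", {
  res <- structure(
    list(
      predictions = tibble(
        sample = paste0("S", 1:6), prob = 0, fold = 1L,
        label = c(1L, 0L, 0L, 0L, 1L, 0L), cn_pred = NA_character_
      ),
      threshold = 0.6
    ),
    class = "chromothripsis_prediction"
  )
  cp <- call_cn_pred(res)
  expect_true(all(cp$calls$cn_pred == "low"))
  expect_equal(cp$specificity, 1)
  expect_equal(cp$sensitivity, 0)
})

test_that("the threshold sweep is monotone along the ROC", {
  d <- informative_exposures(80, seed = 8)
  res <- crossval_predict(d$x, d$y, k = 5, seed = 9)
  sw <- call_cn_pred(res)$sweep
  expect_true(all(diff(sw$sensitivity) >= 0)) # descending thresholds
  expect_true(all(diff(sw$specificity) <= 0))
})

test_that("identical feature sets give zero AUC difference with p = 1", {
  d <- informative_exposures(80, seed = 10)
  cmp <- compare_auc_bootstrap(d$x, d$x, d$y, k = 5, n_boot = 10, seed = 11)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(
    compare_auc_bootstrap(d$x, d$x, d$y, n_boot = 1),
    "n_boot"
  )
})

test_that("informative features beat pure noise in the bootstrap comparison", {
  d <- informative_exposures(120, shift = 0.7, seed = 12)
  set.seed(13)
  noise <- matrix(rgamma(120 * 4, 1), 120, 4)
  noise <- noise / rowSums(noise)
  rownames(noise) <- rownames(d$x)
  cmp <- compare_auc_bootstrap(d$x, noise, d$y, k = 5, n_boot = 40, seed = 14)
  expect_gt(cmp$difference, 0)
  expect_lt(cmp$p_value, 0.05)
})

test_that("discrepant-case audit lists complex-event content", {
  d <- informative_exposures(60, shift = 0.4, noise = 0.3, seed = 15)
  res <- crossval_predict(d$x, d$y, k = 5, seed = 16)
  calls <- tibble(
    sample = rownames(d$x)[1:5],
    event_id = paste0("e", 1:5),
    class = c("complex_nos", "chromothripsis", "single", "chromoplexy", "complex_nos"),
    n_pairs = 3L, chroms = "1", member_ids = "x",
    oscillating_cn = FALSE, cn_loss_associated = FALSE,
    focal_gain_associated = FALSE
  )
  aud <- audit_discrepant(res, calls)
  expect_true(all(aud$kind %in% c("false_positive", "false_negative")))
  expect_true("complex_nos" %in% names(aud) || nrow(aud) == 0)
})
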