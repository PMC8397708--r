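# Helper: minimal long feature table from named lists of values.
feature_table <- function(values_by_feature, sample = "S1") {
  bind_rows(lapply(names(values_by_feature), function(f) {
    tibble(sample = sample, feature = f, value = values_by_feature[[f]])
  }))
}

base_features <- function(sample = "S1") {
  # one plausible value set per feature so schemes can always be fitted
  feature_table(list(
    bkpt_10mb = c(0, 0, 1, 0, 2, 0), seg_cn = c(0, 1, 2, 3, 4, 7),
    cn_jump = c(1, 1, 2, 1), bkpt_arm = c(0, 1, 0, 2),
    osc_len = c(0, 0, 3, 0), seg_size = c(1e5, 5e5, 1e6, 5e6, 1e7, 5e7)
  ), sample = sample)
}

test_that("absolute CN uses the five fixed states with >=4 pooled", {
  f <- base_features()
  scheme <- suppressWarnings(fit_category_scheme(f, seed = 1))
  expect_equal(nrow(scheme$features$seg_cn), 5)
  row <- assign_counts(f, scheme)
  cn_cols <- grep("^seg_cn", names(row), value = TRUE)
  expect_equal(cn_cols, c("seg_cn_0", "seg_cn_1", "seg_cn_2", "seg_cn_3", "seg_cn_4p"))
  # values 0,1,2,3,4,7: one each in states 1-4, two in state 5 (4 and 7)
  expect_equal(as.numeric(row[1, cn_cols]), c(1, 1, 1, 1, 2))
  bad <- dplyr::mutate(f, value = ifelse(feature == "seg_cn", -1, value))
  expect_error(assign_counts(bad, scheme), "negative")
})

test_that("BIC selects two components for two well-separated size modes", {
  set.seed(5)
  sizes <- c(10^rnorm(500, 4.5, 0.12), 10^rnorm(500, 7.5, 0.12))
  f <- bind_rows(
    base_features()[base_features()$feature != "seg_size", ],
    tibble(sample = "S1", feature = "seg_size", value = sizes)
  )
  scheme <- suppressWarnings(fit_category_scheme(f, seed = 2))
  expect_equal(nrow(scheme$features$seg_size), 2)
  means <- scheme$features$seg_size$mean
  expect_equal(means, sort(means)) # components ordered by increasing mean
  expect_lt(abs(means[1] - 4.5), 0.3)
  expect_lt(abs(means[2] - 7.5), 0.3)
  # the selected count equals the argmax of an exhaustive BIC scan
  vals <- sort(log10(f$value[f$feature == "seg_size"]))
  scan <- mclust::mclustBIC(vals, G = 1:10, modelNames = "V", verbose = FALSE)
  expect_equal(which.max(scan[, "V"]), 2L, ignore_attr = TRUE)
})

test_that("Poisson mixtures recover well-separated rates and the BIC count", {
  set.seed(9)
  x <- c(rpois(500, 0.2), rpois(300, 9))
  fit <- chromosig:::fit_poisson_mixture(x, max_k = 6, seed = 3)
  expect_equal(nrow(fit), 2)
  expect_lt(abs(fit$rate[1] - 0.2), 0.15)
  expect_lt(abs(fit$rate[2] - 9), 1)
  expect_equal(fit$rate, sort(fit$rate))
})

test_that("a degenerate single-sample cohort yields one component per fit", {
  f <- feature_table(list(
    bkpt_10mb = rep(0, 5), seg_cn = rep(2, 5), cn_jump = rep(1, 3),
    bkpt_arm = rep(0, 4), osc_len = rep(0, 3), seg_size = rep(1e6, 5)
  ))
  scheme <- suppressWarnings(fit_category_scheme(f, seed = 1))
  # 1 component for each of the 5 fitted features + 5 fixed CN states
  expect_equal(scheme$n_categories, 10)
})

test_that("hard assignment matches a brute-force posterior on a toy", {
  f <- base_features()
  scheme <- suppressWarnings(fit_category_scheme(f, seed = 4))
  tab <- scheme$features$bkpt_10mb
  vals <- c(0, 1, 2, 5, 9)
  got <- chromosig:::assign_component(vals, tab)
  want <- vapply(vals, function(v) {
    post <- tab$weight * dpois(v, tab$rate)
    which.max(signif(post, 10))
  }, integer(1))
  expect_equal(got, want)
})

test_that("values midway between equal Gaussian components go to the lower index", {
  tab <- tibble(
    component = 1:2, family = "gaussian",
    mean = c(0, 2), sd = c(1, 1), weight = c(0.5, 0.5)
  )
  expect_equal(chromosig:::assign_component(1, tab), 1L)
})

test_that("per-feature counts are conserved for every sample", {
  assets <- toy_assets()
  set.seed(31)
  seg <- bind_rows(lapply(1:6, function(i) {
    random_profile(sprintf("S%d", i), assets)
  }))
  seg <- apply_filters(seg, NULL, assets)$segments
  feats <- cn_features(seg, assets)
  scheme <- suppressWarnings(fit_category_scheme(feats, seed = 6))
  mat <- build_cn_matrix(feats, scheme)
  sizes <- dplyr::count(feats, sample, feature)
  for (i in seq_len(nrow(sizes))) {
    cols <- scheme$features[[sizes$feature[i]]]$label
    got <- sum(mat[mat$sample == sizes$sample[i], cols])
    expect_equal(got, sizes$n[i])
  }
})

test_that("the scheme is invariant to sample order and cohort duplication", {
  # two clearly separated clusters per fitted feature, spread over samples
  set.seed(32)
  feats <- bind_rows(
    feature_table(list(
      bkpt_10mb = c(rpois(150, 0.2), rpois(60, 12)),
      seg_cn = sample(0:5, 120, replace = TRUE),
      cn_jump = c(rnorm(100, 1, 0.08), rnorm(60, 4, 0.2)),
      bkpt_arm = c(rpois(120, 0.1), rpois(50, 8)),
      osc_len = c(rpois(130, 0.1), rpois(40, 7)),
      seg_size = 10^c(rnorm(150, 4.5, 0.12), rnorm(120, 7.5, 0.12))
    ), sample = "S1"),
    feature_table(list(
      bkpt_10mb = c(rpois(150, 0.2), rpois(60, 12)),
      seg_cn = sample(0:5, 120, replace = TRUE),
      cn_jump = c(rnorm(100, 1, 0.08), rnorm(60, 4, 0.2)),
      bkpt_arm = c(rpois(120, 0.1), rpois(50, 8)),
      osc_len = c(rpois(130, 0.1), rpois(40, 7)),
      seg_size = 10^c(rnorm(150, 4.5, 0.12), rnorm(120, 7.5, 0.12))
    ), sample = "S2")
  )
  s1 <- suppressWarnings(fit_category_scheme(feats, seed = 8))
  s2 <- suppressWarnings(
    fit_category_scheme(dplyr::arrange(feats, dplyr::desc(sample), value), seed = 8)
  )
  expect_equal(tidy(s1), tidy(s2))
  expect_equal(vapply(s1$features, nrow, integer(1))[c("cn_jump", "seg_size")],
    c(cn_jump = 2L, seg_size = 2L)
  )
  dup <- bind_rows(feats, dplyr::mutate(feats, sample = paste0(sample, "_dup")))
  s3 <- suppressWarnings(fit_category_scheme(dup, seed = 8))
  expect_equal(
    vapply(s1$features, nrow, integer(1)),
    vapply(s3$features, nrow, integer(1))
  )
})

test_that("identical samples produce identical matrix rows, order permutes rows only", {
  f <- bind_rows(base_features("A"), base_features("B"))
  scheme <- suppressWarnings(fit_category_scheme(f, seed = 10))
  mat <- build_cn_matrix(f, scheme)
  expect_equal(unlist(mat[1, -1]), unlist(mat[2, -1]))
  perm <- build_cn_matrix(
    dplyr::arrange(f, dplyr::desc(sample)), scheme
  )
  expect_equal(perm$sample, rev(mat$sample))
  expect_equal(
    dplyr::arrange(perm, sample),
    dplyr::arrange(mat, sample)
  )
})

test_that("schemes round-trip through YAML", {
  f <- base_features()
  scheme <- suppressWarnings(fit_category_scheme(f, seed = 12))
  path <- tempfile(fileext = ".yaml")
  write_category_scheme(scheme, path)
  back <- read_category_scheme(path)
  expect_equal(back$columns, scheme$columns)
  expect_equal(back$n_categories, scheme$n_categories)
  expect_equal(
    assign_counts(f, back),
    assign_counts(f, scheme)
  )
})
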