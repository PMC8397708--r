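# Cohort-wide category definition for the six CN features and tabulation of
# the samples x categories CN count matrix.
#
# Count-valued features (bkpt_10mb, bkpt_arm, osc_len) get Poisson mixtures;
# cn_jump gets a Gaussian mixture; seg_size a Gaussian mixture on log10(bp).
# The absolute-CN feature bypasses fitting: five fixed states are installed
# (0 = bi-allelic deletion, 1 = monoallelic deletion, 2 = diploid,
# 3 = single gain, >= 4 = two or more gains).  The number of components per
# fitted feature is chosen by BIC; the total category count is therefore a
# data-dependent output, not a constant.

DEFAULT_FAMILIES <- c(
  bkpt_10mb = "poisson", seg_cn = "fixed_state", cn_jump = "gaussian",
  bkpt_arm = "poisson", osc_len = "poisson", seg_size = "gaussian_log10"
)

FIXED_CN_STATES <- tibble(
  component = 1:5,
  family = "fixed_state",
  state = c("0", "1", "2", "3", "4+"),
  label = c("seg_cn_0", "seg_cn_1", "seg_cn_2", "seg_cn_3", "seg_cn_4p")
)

# Weighted Poisson mixture via EM on aggregated unique values; k selected by
# BIC over 1..max_k.  Deterministic given seed (restart jitter only).
fit_poisson_mixture <- function(x, max_k = 10, seed = 1, n_restarts = 20,
                                max_iter = 500, tol = 1e-8) {
  agg <- as.data.frame(table(x), stringsAsFactors = FALSE)
  v <- as.numeric(agg$x); w <- as.numeric(agg$Freq)
  n <- sum(w)
  n_distinct <- length(v)
  max_k <- min(max_k, n_distinct)
  best <- NULL
  set.seed(seed)
  for (k in seq_len(max_k)) {
    best_k <- NULL
    for (r in seq_len(if (k == 1) 1 else n_restarts)) {
      # spread initial rates over the value quantiles, jittered
      qs <- quantile(rep(v, w), probs = (seq_len(k) - 0.5) / k, names = FALSE)
      lam <- pmax(qs + runif(k, -0.25, 0.25) * (sd(rep(v, w)) + 0.5), 1e-6)
      pi_k <- rep(1 / k, k)
      ll_old <- -Inf; ll <- -Inf
      for (it in seq_len(max_iter)) {
        logd <- vapply(seq_len(k), function(j) {
          log(pmax(pi_k[j], 1e-12)) + dpois(v, lam[j], log = TRUE)
        }, numeric(length(v)))
        logd <- matrix(logd, nrow = length(v))
        m <- apply(logd, 1, max)
        lse <- m + log(rowSums(exp(logd - m)))
        ll <- sum(w * lse)
        if (!is.finite(ll)) { ll <- -Inf; break }
        resp <- exp(logd - lse)
        wr <- resp * w
        nk <- colSums(wr)
        pi_k <- pmax(nk / n, 1e-12)
        pi_k <- pi_k / sum(pi_k)
        lam <- pmax(colSums(wr * v) / pmax(nk, 1e-12), 1e-6)
        if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
        ll_old <- ll
      }
      if (is.null(best_k) || isTRUE(ll > best_k$ll)) {
        best_k <- list(ll = ll, lambda = lam, weight = pi_k)
      }
    }
    bic <- 2 * best_k$ll - (2 * k - 1) * log(n)
    if (is.null(best) || isTRUE(bic > best$bic)) {
      best <- c(best_k, list(bic = bic, k = k))
    }
  }
  ord <- order(best$lambda)
  tibble(
    component = seq_len(best$k), family = "poisson",
    rate = best$lambda[ord], weight = best$weight[ord]
  )
}

# 1-D Gaussian mixture with BIC selection via mclust (unequal variances,
# equal-variance fallback for heavily tied data).
fit_gaussian_mixture <- function(x, max_k = 10) {
  x <- sort(x) # order-invariant fits regardless of cohort ordering
  if (length(x) > 20000) { # deterministic quantile thinning for huge pools
    x <- x[round(seq(1, length(x), length.out = 20000))]
  }
  n_distinct <- length(unique(x))
  if (n_distinct == 1 || sd(x) == 0) {
    return(tibble(
      component = 1L, family = "gaussian",
      mean = x[1], sd = 1e-6, weight = 1
    ))
  }
  max_k <- min(max_k, n_distinct)
  try_mclust <- function(model, G) {
    tryCatch(
      suppressWarnings(mclust::Mclust(x, G = G, modelNames = model, verbose = FALSE)),
      error = function(e) NULL
    )
  }
  fit <- try_mclust("V", seq_len(max_k))
  if (is.null(fit)) fit <- try_mclust("E", seq_len(max_k))
  if (is.null(fit)) fit <- try_mclust("E", seq_len(min(2, max_k)))
  if (is.null(fit)) { # moment-matched single component as a last resort
    return(tibble(
      component = 1L, family = "gaussian",
      mean = mean(x), sd = max(sd(x), 1e-6), weight = 1
    ))
  }
  p <- fit$parameters
  sds <- sqrt(if (length(p$variance$sigmasq) == 1) {
    rep(p$variance$sigmasq, fit$G)
  } else p$variance$sigmasq)
  ord <- order(p$mean)
  tibble(
    component = seq_len(fit$G), family = "gaussian",
    mean = unname(p$mean[ord]), sd = pmax(unname(sds[ord]), 1e-9),
    weight = unname(p$pro[ord])
  )
}

#' Fit the per-feature category scheme from cohort feature values
#'
#' Pools each feature's values across the cohort and defines its categories:
#' Poisson mixtures for the count features (`bkpt_10mb`, `bkpt_arm`,
#' `osc_len`), a Gaussian mixture for `cn_jump`, a Gaussian mixture on
#' log10(bp) for `seg_size`, and the five fixed absolute-CN states for
#' `seg_cn`. The number of mixture components is selected by BIC over
#' `1..max_components`. All-constant features collapse to a single component
#' with a warning. Deterministic given `seed`, invariant to sample order.
#'
#' @param features Long feature tibble from [cn_features()].
#' @param max_components Maximum mixture components per feature.
#' @param seed Controls mixture-initialization restarts.
#' @param families Named character vector overriding the per-feature family
#'   (one of `poisson`, `gaussian`, `gaussian_log10`, `fixed_state`).
#' @return An object of class `cn_category_scheme` with per-feature
#'   component tables, the global category column order, and
#'   `n_categories`.
#' @export
fit_category_scheme <- function(features, max_components = 10, seed = 1,
                                families = DEFAULT_FAMILIES) {
  stopifnot(all(CN_FEATURES %in% names(families)))
  if (length(unique(features$sample)) < 1) abort("no samples in feature table")
  comps <- list()
  for (f in CN_FEATURES) {
    vals <- features$value[features$feature == f]
    if (length(vals) == 0) abort(sprintf("feature %s has no values", f))
    fam <- families[[f]]
    if (fam == "fixed_state") {
      comps[[f]] <- FIXED_CN_STATES
      next
    }
    if (length(unique(vals)) == 1 && fam != "fixed_state") {
      warn(sprintf("feature %s is constant; using a single component", f))
    }
    tab <- switch(fam,
      poisson = fit_poisson_mixture(vals,
        max_k = max_components,
        seed = derive_seed(seed, match(f, CN_FEATURES))
      ),
      gaussian = fit_gaussian_mixture(vals, max_k = max_components),
      gaussian_log10 = {
        t <- fit_gaussian_mixture(log10(vals), max_k = max_components)
        t$family <- "gaussian_log10"
        t
      },
      abort(sprintf("unknown family: %s", fam))
    )
    tab$label <- paste0(f, "_", tab$component)
    comps[[f]] <- tab
  }
  columns <- unlist(lapply(CN_FEATURES, function(f) comps[[f]]$label),
    use.names = FALSE
  )
  structure(
    list(
      features = comps, families = families, columns = columns,
      n_categories = length(columns)
    ),
    class = "cn_category_scheme"
  )
}

#' @exportS3Method base::print
print.cn_category_scheme <- function(x, ...) {
  cat("<cn_category_scheme> ", x$n_categories, " categories\n", sep = "")
  for (f in names(x$features)) {
    cat(" ", f, ": ", nrow(x$features[[f]]), " (", x$families[[f]], ")\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.cn_category_scheme <- function(x, ...) {
  purrr::imap(x$features, function(tab, f) mutate(tab, feature = f)) |>
    bind_rows() |>
    select("feature", "label", "component", "family",
           dplyr::any_of(c("rate", "mean", "sd", "weight", "state")))
}

# Hard assignment of one feature's values to that feature's components:
# maximal posterior responsibility, ties to the lower-indexed component.
assign_component <- function(values, tab) {
  fam <- tab$family[1]
  if (fam == "fixed_state") {
    if (any(values < 0)) abort("negative copy number outside fixed-state domain")
    return(pmin(values, 4) + 1)
  }
  x <- if (fam == "gaussian_log10") log10(values) else values
  k <- nrow(tab)
  if (k == 1) return(rep(1L, length(values)))
  dens <- vapply(seq_len(k), function(j) {
    if (fam == "poisson") {
      log(tab$weight[j]) + dpois(x, tab$rate[j], log = TRUE)
    } else {
      log(tab$weight[j]) + dnorm(x, tab$mean[j], tab$sd[j], log = TRUE)
    }
  }, numeric(length(x)))
  dens <- matrix(signif(dens, 10), nrow = length(x)) # blunt FP noise so exact
  apply(dens, 1, which.max)                          # ties go to lower index
}

#' Tabulate one sample's CN category counts
#'
#' Each feature value is hard-assigned to the component with maximal
#' posterior responsibility (ties to the lower-indexed component) and counts
#' are tallied per category. Per feature, the counts sum exactly to the
#' feature's number of values.
#'
#' @param features Long feature tibble for one or more samples.
#' @param scheme A fitted [fit_category_scheme()] object.
#' @return A wide tibble: `sample` plus one integer column per category, in
#'   scheme column order.
#' @export
assign_counts <- function(features, scheme) {
  stopifnot(inherits(scheme, "cn_category_scheme"))
  missing_f <- setdiff(unique(features$feature), names(scheme$features))
  if (length(missing_f) > 0) {
    abort(sprintf("scheme does not cover feature(s): %s",
                  paste(missing_f, collapse = ", ")))
  }
  samples <- unique(features$sample)
  out <- matrix(0L, nrow = length(samples), ncol = scheme$n_categories,
    dimnames = list(samples, scheme$columns)
  )
  for (f in CN_FEATURES) {
    sub <- features[features$feature == f, ]
    if (nrow(sub) == 0) next
    comp <- assign_component(sub$value, scheme$features[[f]])
    lab <- scheme$features[[f]]$label[comp]
    tab <- table(factor(sub$sample, levels = samples),
                 factor(lab, levels = scheme$features[[f]]$label))
    out[, colnames(tab)] <- out[, colnames(tab), drop = FALSE] + unclass(tab)
  }
  matrix_to_tibble(out)
}

#' Build the cohort CN count matrix
#'
#' Rows follow cohort (first-appearance) sample order; columns follow the
#' stable category order of the scheme.
#'
#' @inheritParams assign_counts
#' @return A wide tibble, samples by categories.
#' @export
build_cn_matrix <- function(features, scheme) {
  assign_counts(features, scheme)
}

#' Serialize / load a category scheme
#'
#' The scheme (families, component parameters, column order) round-trips
#' through YAML so runs are auditable and reusable.
#'
#' @param scheme A `cn_category_scheme`.
#' @param path Output path.
#' @return `write_category_scheme()` returns `path` invisibly;
#'   `read_category_scheme()` returns the scheme.
#' @export
write_category_scheme <- function(scheme, path) {
  obj <- list(
    families = as.list(scheme$families),
    columns = scheme$columns,
    n_categories = scheme$n_categories,
    features = purrr::map(scheme$features, function(tab) {
      lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ]))
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_category_scheme
#' @export
read_category_scheme <- function(path) {
  obj <- yaml::read_yaml(path)
  feats <- purrr::map(obj$features, function(rows) {
    bind_rows(lapply(rows, as_tibble))
  })
  structure(
    list(
      features = feats,
      families = unlist(obj$families),
      columns = obj$columns,
      n_categories = obj$n_categories
    ),
    class = "cn_category_scheme"
  )
}
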