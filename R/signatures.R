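# De novo signature extraction from CN or SV count matrices and exposure
# fitting.  Two backends: a hierarchical Dirichlet process Gibbs sampler
# (the default, matching the extraction style used for mutational-signature
# work) and a seeded KL-divergence NMF.

new_signature_fit <- function(signatures, exposures, backend, diagnostics = list(),
                              prefix = "SIG") {
  stopifnot(is.matrix(signatures), is.matrix(exposures))
  # order signatures by descending mean exposure and name SIG1..k
  ord <- order(colMeans(exposures), decreasing = TRUE)
  signatures <- signatures[ord, , drop = FALSE]
  exposures <- exposures[, ord, drop = FALSE]
  nm <- paste0(prefix, seq_len(nrow(signatures)))
  rownames(signatures) <- nm
  colnames(exposures) <- nm
  structure(
    list(
      signatures = signatures, exposures = exposures,
      backend = backend, diagnostics = diagnostics
    ),
    class = "signature_fit"
  )
}

#' @exportS3Method base::print
print.signature_fit <- function(x, ...) {
  cat(
    "<signature_fit> ", nrow(x$signatures), " signatures x ",
    ncol(x$signatures), " categories, ", nrow(x$exposures),
    " samples (backend: ", x$backend, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.signature_fit <- function(x, matrix = c("signatures", "exposures"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "signatures") {
    as_tibble(x$signatures, rownames = "signature") |>
      tidyr::pivot_longer(-"signature", names_to = "category", values_to = "weight")
  } else {
    as_tibble(x$exposures, rownames = "sample") |>
      tidyr::pivot_longer(-"sample", names_to = "signature", values_to = "exposure")
  }
}

#' @export
glance.signature_fit <- function(x, ...) {
  tibble(
    n_signatures = nrow(x$signatures),
    n_categories = ncol(x$signatures),
    n_samples = nrow(x$exposures),
    backend = x$backend,
    converged = isTRUE(x$diagnostics$converged %||% TRUE)
  )
}

#' @export
autoplot.signature_fit <- function(object, ...) {
  d <- tidy(object, "signatures")
  d$category <- factor(d$category, levels = colnames(object$signatures))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~signature, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6)) +
    ggplot2::labs(x = NULL, y = "category weight")
}

validate_count_matrix <- function(m) {
  if (anyNA(m) || any(m < 0)) abort("count matrix must be non-negative")
  if (any(m != round(m))) abort("count matrix must hold integer counts")
  if (nrow(m) < 2) abort("need at least 2 samples")
  invisible(m)
}

# Greedy cosine consolidation of posterior components into consensus
# signatures.  Components are pooled across posterior draws and chains,
# heaviest first; each joins the first consensus cluster whose centroid has
# cosine >= threshold, else founds a new one.  Kept clusters must appear in
# a strict majority of posterior draws (pooled over chains, so a component
# private to a single stuck chain is discarded) and carry a minimum share
# of the posterior mass.
consolidate_components <- function(comp_list, threshold = 0.9,
                                   min_presence = 0.5, min_weight = 0.02) {
  pooled <- bind_rows(comp_list)
  pooled <- pooled[order(-pooled$weight), ]
  n_draws <- length(unique(pooled$draw))
  centroids <- list(); cweight <- numeric(0); draws <- list()
  vecs <- pooled$vec
  for (i in seq_len(nrow(pooled))) {
    v <- vecs[[i]]
    placed <- FALSE
    for (k in seq_along(centroids)) {
      if (cosine_similarity(v, centroids[[k]] / cweight[k]) >= threshold) {
        centroids[[k]] <- centroids[[k]] + pooled$weight[i] * v
        cweight[k] <- cweight[k] + pooled$weight[i]
        draws[[k]] <- union(draws[[k]], pooled$draw[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1]] <- pooled$weight[i] * v
      cweight <- c(cweight, pooled$weight[i])
      draws[[length(centroids)]] <- pooled$draw[i]
    }
  }
  presence <- vapply(draws, length, integer(1)) / n_draws
  share <- cweight / n_draws # each draw's dish weights sum to ~1
  keep <- which(presence > min_presence & share >= min_weight)
  if (length(keep) == 0) keep <- which.max(presence)
  sig <- do.call(rbind, lapply(keep, function(k) {
    v <- centroids[[k]] / cweight[k]
    v / sum(v)
  }))
  list(signatures = sig, keep = keep, centroids = centroids,
       cweight = cweight, presence = presence)
}

#' Extract signatures with the hierarchical Dirichlet process sampler
#'
#' Runs `chains` independent Gibbs chains of a two-level Dirichlet process
#' mixture over the count matrix (cohort-level base measure, per-sample
#' DPs). Raw posterior components are consolidated across draws and chains
#' by greedy cosine clustering (threshold `cos_threshold`); consensus
#' signatures are the weighted cluster centroids and exposures are the
#' per-sample component weights mapped onto the consensus clusters and
#' renormalized. Deterministic given `seed` and chain count.
#'
#' @param x Count matrix or wide tibble (first column `sample`) of
#'   non-negative integers.
#' @param chains Number of independent chains (default 4).
#' @param burnin Burn-in sweeps per chain (default 5000).
#' @param posterior_samples Posterior draws collected per chain (default 25).
#' @param thin Sweeps between collected draws (default 50).
#' @param alpha Per-sample DP concentration.
#' @param gamma0 Top-level DP concentration.
#' @param eta Symmetric Dirichlet base over categories.
#' @param cos_threshold Consolidation cosine threshold (default 0.9).
#' @param seed RNG seed.
#' @param prefix Signature name prefix (e.g. `"CN-SIG"`).
#' @return A `signature_fit` object; rows of `$signatures` and `$exposures`
#'   lie on the simplex.
#' @export
extract_hdp <- function(x, chains = 4, burnin = 5000, posterior_samples = 25,
                        thin = 50, alpha = 1, gamma0 = 1, eta = 0.5,
                        cos_threshold = 0.9, seed = 1, prefix = "SIG") {
  m <- as_count_matrix(x)
  validate_count_matrix(m)
  storage.mode(m) <- "integer"
  comp_list <- list()
  n_dishes <- numeric(0)
  draw_id <- 0
  set.seed(seed)
  for (ch in seq_len(chains)) {
    res <- hdp_gibbs_chain(m, burnin, posterior_samples, thin,
                           alpha, gamma0, eta)
    for (d in seq_along(res$phi)) {
      draw_id <- draw_id + 1
      phi <- res$phi[[d]]; w <- res$weights[[d]]
      n_dishes <- c(n_dishes, nrow(phi))
      comp_list[[draw_id]] <- tibble(
        draw = draw_id,
        weight = as.numeric(w),
        vec = lapply(seq_len(nrow(phi)), function(k) phi[k, ]),
        theta = lapply(seq_len(nrow(phi)), function(k) NULL)
      )
      comp_list[[draw_id]]$theta <- lapply(
        seq_len(nrow(phi)), function(k) res$theta[[d]][, k]
      )
    }
  }
  cons <- consolidate_components(comp_list, threshold = cos_threshold)
  sig <- cons$signatures
  colnames(sig) <- colnames(m)
  # exposures: map each draw's dishes onto the kept consensus clusters,
  # average normalized per-sample weights across draws
  S <- nrow(m); kk <- nrow(sig)
  expo_sum <- matrix(0, S, kk)
  expo_n <- 0
  for (d in seq_along(comp_list)) {
    tabd <- comp_list[[d]]
    ed <- matrix(0, S, kk)
    for (i in seq_len(nrow(tabd))) {
      sims <- vapply(seq_len(kk), function(k) {
        cosine_similarity(tabd$vec[[i]], sig[k, ])
      }, numeric(1))
      k <- which.max(sims)
      if (sims[k] >= cos_threshold * 0.9) { # tolerate consolidation drift
        ed[, k] <- ed[, k] + tabd$theta[[i]]
      }
    }
    expo_sum <- expo_sum + simplex_rows(ed)
    expo_n <- expo_n + 1
  }
  expo <- simplex_rows(expo_sum / expo_n)
  rownames(expo) <- rownames(m)
  # crude split-chain stability diagnostic on the number of occupied dishes
  half <- split(n_dishes, rep(1:2, length.out = length(n_dishes)))
  rhat <- tryCatch({
    mns <- vapply(half, mean, numeric(1))
    vrs <- vapply(half, var, numeric(1))
    wv <- mean(vrs)
    if (is.na(wv) || wv == 0) 1 else sqrt((wv + var(mns)) / wv)
  }, error = function(e) NA_real_)
  converged <- is.na(rhat) || rhat < 1.2
  if (!converged) {
    warn(sprintf("HDP dish-count stability diagnostic %.2f > 1.2; consider longer chains", rhat))
  }
  new_signature_fit(sig, expo,
    backend = "hdp",
    diagnostics = list(
      rhat = rhat, converged = converged,
      mean_dishes = mean(n_dishes), presence = cons$presence[cons$keep],
      chains = chains, burnin = burnin, thin = thin, seed = seed
    ),
    prefix = prefix
  )
}

# One KL-NMF run with multiplicative updates; returns W (S x k), H (k x K)
# and the final KL divergence.
nmf_kl_once <- function(V, k, max_iter = 2000, tol = 1e-6) {
  S <- nrow(V); K <- ncol(V)
  eps <- 1e-12
  W <- matrix(runif(S * k, 0.1, 1), S, k)
  H <- matrix(runif(k * K, 0.1, 1), k, K)
  kl_old <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / matrix(rowSums(H), S, k, byrow = TRUE)
    if (it %% 10 == 0) {
      WH <- W %*% H + eps
      kl <- sum(V * log((V + eps) / WH) - V + WH)
      if (abs(kl_old - kl) < tol * (1 + abs(kl))) break
      kl_old <- kl
    }
  }
  WH <- W %*% H + eps
  kl <- sum(V * log((V + eps) / WH) - V + WH)
  # normalize H rows to the simplex, move scale into W
  hs <- rowSums(H)
  H <- H / hs
  W <- W * matrix(hs, S, k, byrow = TRUE)
  list(W = W, H = H, kl = kl)
}

# Mean silhouette (cosine distance) of restart signatures clustered to the
# best restart's signatures: measures how stable a rank-k solution is.
nmf_stability <- function(runs, k) {
  if (k == 1 || length(runs) < 2) return(1)
  best <- runs[[which.min(vapply(runs, function(r) r$kl, numeric(1)))]]
  ref <- best$H
  vecs <- do.call(rbind, lapply(runs, function(r) r$H))
  assign <- apply(vecs, 1, function(v) {
    which.max(apply(ref, 1, function(u) cosine_similarity(u, v)))
  })
  if (length(unique(assign)) < 2) return(0)
  dmat <- 1 - outer(seq_len(nrow(vecs)), seq_len(nrow(vecs)),
    Vectorize(function(i, j) cosine_similarity(vecs[i, ], vecs[j, ]))
  )
  sil <- vapply(seq_len(nrow(vecs)), function(i) {
    own <- assign == assign[i]
    a <- mean(dmat[i, own & seq_len(nrow(vecs)) != i])
    if (is.nan(a)) a <- 0
    b <- min(vapply(setdiff(unique(assign), assign[i]), function(g) {
      mean(dmat[i, assign == g])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

#' Extract signatures by KL-divergence NMF
#'
#' Seeded fallback backend: non-negative matrix factorization under the
#' Kullback-Leibler objective with multiplicative updates and random
#' restarts. When `k_range` has several values, the rank is chosen by
#' restart stability (mean cosine silhouette of restart signatures) with the
#' reconstruction-error elbow as tie-break.
#'
#' @inheritParams extract_hdp
#' @param k_range Candidate signature counts (a single value skips
#'   selection).
#' @param n_restarts Random restarts per rank.
#' @param max_iter,tol Multiplicative-update controls.
#' @return A `signature_fit` object.
#' @export
extract_nmf <- function(x, k_range = 2:8, n_restarts = 10, seed = 1,
                        max_iter = 2000, tol = 1e-6, prefix = "SIG") {
  V <- as_count_matrix(x)
  if (all(V == 0)) abort("all-zero matrix")
  if (anyNA(V) || any(V < 0)) abort("count matrix must be non-negative")
  rk <- qr(V)$rank
  if (max(k_range) > rk) {
    warn(sprintf("k_range capped at matrix rank %d", rk))
    k_range <- k_range[k_range <= rk]
    if (length(k_range) == 0) k_range <- rk
  }
  set.seed(seed)
  per_k <- list()
  for (k in sort(unique(k_range))) {
    runs <- lapply(seq_len(n_restarts), function(r) {
      nmf_kl_once(V, k, max_iter = max_iter, tol = tol)
    })
    kls <- vapply(runs, function(r) r$kl, numeric(1))
    per_k[[as.character(k)]] <- list(
      k = k, best = runs[[which.min(kls)]],
      stability = nmf_stability(runs, k), kl = min(kls)
    )
  }
  if (length(per_k) == 1) {
    chosen <- per_k[[1]]
  } else {
    stab <- vapply(per_k, function(p) p$stability, numeric(1))
    cand <- which(stab >= max(stab) - 0.01)
    if (length(cand) > 1) {
      # tie-break: largest relative reconstruction improvement over the
      # previous rank (rank-1 baseline ahead of the first candidate)
      kl0 <- nmf_kl_once(V, 1, max_iter = max_iter, tol = tol)$kl
      kls <- vapply(per_k, function(p) p$kl, numeric(1))
      gain <- -diff(c(kl0, kls)) / utils::head(c(kl0, kls), -1)
      chosen <- per_k[[cand[which.max(gain[cand])]]]
    } else {
      chosen <- per_k[[cand]]
    }
  }
  H <- chosen$best$H
  colnames(H) <- colnames(V)
  expo <- simplex_rows(chosen$best$W)
  rownames(expo) <- rownames(V)
  new_signature_fit(H, expo,
    backend = "nmf",
    diagnostics = list(
      k = chosen$k, kl = chosen$kl, stability = chosen$stability,
      k_scan = lapply(per_k, function(p) p[c("k", "kl", "stability")]),
      seed = seed
    ),
    prefix = prefix
  )
}

#' Project samples onto fixed signatures
#'
#' Fits per-sample exposures to a fixed signature set by multinomial EM
#' (equivalently, maximum-likelihood mixture weights on the simplex).
#' Samples with no events get an all-zero row.
#'
#' @param x Count matrix or wide tibble.
#' @param signatures A `signature_fit` or a signatures-by-categories matrix
#'   with rows on the simplex.
#' @param max_iter,tol EM controls.
#' @return An exposure matrix (samples x signatures), rows on the simplex.
#' @export
fit_exposures <- function(x, signatures, max_iter = 500, tol = 1e-10) {
  sig <- if (inherits(signatures, "signature_fit")) signatures$signatures else signatures
  V <- as_count_matrix(x)
  if (!identical(colnames(V), colnames(sig))) {
    if (!is.null(colnames(V)) && !is.null(colnames(sig)) &&
        setequal(colnames(V), colnames(sig))) {
      sig <- sig[, colnames(V), drop = FALSE]
    }
  }
  k <- nrow(sig)
  expo <- matrix(0, nrow(V), k, dimnames = list(rownames(V), rownames(sig)))
  for (j in seq_len(nrow(V))) {
    xj <- V[j, ]
    n <- sum(xj)
    if (n == 0) next
    p <- rep(1 / k, k)
    for (it in seq_len(max_iter)) {
      mix <- as.numeric(p %*% sig) # expected category distribution
      # responsibility of signature r for category c: p_r s_rc / mix_c
      w <- sweep(sig, 2, pmax(mix, 1e-300), "/") * p
      p_new <- as.numeric(w %*% xj)
      p_new <- p_new / sum(p_new)
      if (sum(abs(p_new - p)) < tol) { p <- p_new; break }
      p <- p_new
    }
    expo[j, ] <- p
  }
  expo
}
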