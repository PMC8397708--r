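# End-to-end orchestration: filters -> CN features -> category fit -> CN
# matrix -> SV annotation -> SV matrix -> complex-event classification ->
# signature extraction -> prediction -> reports.  Every stage's outputs,
# parameters and seeds are serialized; reruns with the same config
# reproduce the matrices exactly.

default_run_params <- function() {
  list(
    min_seg_bp = 5e4,
    max_components = 10,
    sv_gamma = 25, sv_fraction = 0.1,
    event_config = default_event_config(),
    extraction_backend = "nmf", # "nmf" or "hdp"
    cn_k_range = 2:6, sv_k_range = 2:8, nmf_restarts = 8,
    hdp = list(chains = 4, burnin = 5000, posterior_samples = 25, thin = 50),
    cv_folds = 10, ridge_C = 1, threshold = 0.6
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a cohort (either read from files or passed as
#' in-memory tibbles): artefact filtering, CN feature extraction, category
#' fitting, CN/SV matrix construction, clustered-SV annotation,
#' complex-event classification, signature extraction for both matrices,
#' and—when labels are available—cross-validated chromothripsis prediction.
#' All stage outputs are written under `out_dir` together with a
#' `run_metadata.json` carrying the config hash and seeds; missing labels
#' skip the prediction stage with a logged notice.
#'
#' @param segments Cohort segment tibble (or a path readable by
#'   [read_segments()]).
#' @param svs Cohort SV tibble (or a pooled BEDPE path).
#' @param labels Optional `sample, chromothripsis` tibble (or TSV path).
#'   When absent, prediction is skipped.
#' @param out_dir Output directory (created; refuses to overwrite a
#'   non-empty directory unless `force`).
#' @param assets Genome assets.
#' @param seed Master seed for all stochastic stages.
#' @param params Stage parameters; see `default_run_params()`.
#' @param force Overwrite a non-empty `out_dir`.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   `out_dir` path.
#' @export
run_end_to_end <- function(segments, svs, labels = NULL, out_dir,
                           assets = genome_assets(), seed = 1,
                           params = list(), force = FALSE) {
  params <- modifyList(default_run_params(), params)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort(sprintf("output directory %s is not empty (use force = TRUE)", out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    inform(sprintf("[chromosig] stage: %s", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }
  if (is.character(segments)) segments <- read_segments(segments)
  if (is.character(svs)) svs <- read_sv_bedpe(svs, assets = assets)
  if (is.character(labels)) {
    labels <- readr::read_tsv(labels, col_types = readr::cols(
      sample = readr::col_character(), chromothripsis = readr::col_integer()
    ))
  }

  filt <- stage("filters", apply_filters(segments, svs, assets,
    min_seg_bp = params$min_seg_bp
  ))
  write_segments(filt$segments, file.path(out_dir, "segments_filtered.tsv"))
  write_sv_bedpe(filt$svs, file.path(out_dir, "svs_filtered.bedpe"))

  feats <- stage("cn_features", cn_features(filt$segments, assets))
  readr::write_tsv(feats, file.path(out_dir, "cn_features.tsv"))

  scheme <- stage("cn_categories", fit_category_scheme(feats,
    max_components = params$max_components, seed = derive_seed(seed, 11)
  ))
  write_category_scheme(scheme, file.path(out_dir, "category_scheme.yaml"))

  cn_mat <- stage("cn_matrix", build_cn_matrix(feats, scheme))
  write_matrix(cn_mat, file.path(out_dir, "cn_matrix.tsv"))

  sv_ann <- stage("sv_annotate", detect_clustered(filt$svs,
    gamma = params$sv_gamma, fraction = params$sv_fraction
  ))
  readr::write_tsv(annotate_sv_pairs(sv_ann), file.path(out_dir, "sv_annotation.tsv"))

  sv_mat <- stage("sv_matrix", build_sv_matrix(sv_ann))
  write_matrix(sv_mat, file.path(out_dir, "sv_matrix.tsv"))

  calls <- stage("classify", classify_complex_events(sv_ann, filt$segments,
    config = params$event_config
  ))
  readr::write_tsv(calls, file.path(out_dir, "complex_calls.tsv"))
  readr::write_tsv(
    sample_chromothripsis_labels(calls, samples = unique(filt$segments$sample)),
    file.path(out_dir, "called_labels.tsv")
  )

  extract_one <- function(mat, prefix, k_range, seed_off) {
    if (params$extraction_backend == "hdp") {
      extract_hdp(mat,
        chains = params$hdp$chains, burnin = params$hdp$burnin,
        posterior_samples = params$hdp$posterior_samples,
        thin = params$hdp$thin, seed = derive_seed(seed, seed_off),
        prefix = prefix
      )
    } else {
      extract_nmf(mat,
        k_range = k_range, n_restarts = params$nmf_restarts,
        seed = derive_seed(seed, seed_off), prefix = prefix
      )
    }
  }
  cn_fit <- stage("extract_cn", extract_one(cn_mat, "CN-SIG", params$cn_k_range, 21))
  sv_ok <- nrow(sv_mat) >= 2 && sum(as_count_matrix(sv_mat)) > 0
  sv_fit <- if (sv_ok) {
    stage("extract_sv", extract_one(sv_mat, "SV-SIG", params$sv_k_range, 22))
  } else {
    inform("[chromosig] too few SVs for SV-signature extraction; skipped")
    NULL
  }
  write_matrix(matrix_to_tibble(cn_fit$exposures), file.path(out_dir, "cn_exposures.tsv"))
  readr::write_tsv(tidy(cn_fit, "signatures"), file.path(out_dir, "cn_signatures.tsv"))
  if (!is.null(sv_fit)) {
    write_matrix(matrix_to_tibble(sv_fit$exposures), file.path(out_dir, "sv_exposures.tsv"))
    readr::write_tsv(tidy(sv_fit, "signatures"), file.path(out_dir, "sv_signatures.tsv"))
  }

  pred <- NULL
  if (is.null(labels)) {
    inform("[chromosig] no labels supplied; prediction stage skipped")
  } else {
    pred <- stage("predict", {
      expo <- cn_fit$exposures
      lab <- labels[match(rownames(expo), labels$sample), ]
      k_use <- min(params$cv_folds, min(table(lab$chromothripsis)))
      if (k_use < params$cv_folds) {
        inform(sprintf(
          "[chromosig] reducing CV folds to %d (minority class size)", k_use
        ))
      }
      crossval_predict(expo, lab$chromothripsis,
        k = k_use,
        seed = derive_seed(seed, 31), C = params$ridge_C,
        threshold = params$threshold
      )
    })
    readr::write_tsv(pred$predictions, file.path(out_dir, "predictions.tsv"))
  }

  meta <- list(
    package = "chromosig",
    version = as.character(utils::packageVersion("chromosig")),
    seed = seed,
    params = rapply(params, as.character, how = "replace"),
    config_hash = rlang::hash(list(seed = seed, params = params)),
    n_samples = length(unique(filt$segments$sample)),
    n_categories = scheme$n_categories,
    cn_signatures = nrow(cn_fit$signatures),
    sv_signatures = if (!is.null(sv_fit)) nrow(sv_fit$signatures) else NA,
    mean_auc = if (!is.null(pred)) pred$mean_auc else NA,
    hdp_converged = cn_fit$diagnostics$converged %||% NA
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  invisible(list(
    out_dir = out_dir, filtered = filt, features = feats, scheme = scheme,
    cn_matrix = cn_mat, sv_matrix = sv_mat, sv_annotated = sv_ann,
    calls = calls, cn_fit = cn_fit, sv_fit = sv_fit, prediction = pred,
    metadata = meta
  ))
}
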