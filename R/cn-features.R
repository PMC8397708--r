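# The six per-sample copy-number features measured from a filtered segment
# profile:
#   bkpt_10mb  breakpoints per 10 Mb window (counts, zero-inflated)
#   seg_cn     absolute total CN of each segment
#   cn_jump    |CN difference| between adjacent segments
#   bkpt_arm   breakpoints per chromosome arm
#   osc_len    lengths of oscillating CN segment chains
#   seg_size   segment sizes in bp
#
# Windows, arms and chromosomes with no events contribute explicit zeros so
# downstream mixture fits see the zero mass.

# CN junctions: one row per boundary between adjacent segments within a
# sample/chromosome.  Position is the end of the left segment.
cn_junctions <- function(segments) {
  if (nrow(segments) < 2) {
    return(tibble(sample = character(), chrom = character(), pos = double()))
  }
  seg <- arrange(segments, .data$sample, .data$chrom, .data$start)
  grp <- paste(seg$sample, seg$chrom)
  i <- which(grp[-nrow(seg)] == grp[-1])
  tibble(sample = seg$sample[i], chrom = seg$chrom[i], pos = seg$end[i])
}

# Grid of all (sample x included chromosome) combinations for zero filling.
sample_chrom_grid <- function(samples, assets) {
  chroms <- included_chroms(assets)
  tidyr::expand_grid(sample = samples, chrom = chroms)
}

#' Breakpoints per 10 Mb
#'
#' Each included chromosome is tiled into consecutive non-overlapping 10 Mb
#' windows anchored at position 1 (the last partial window is kept); the
#' value is the number of CN junctions whose position falls in the window.
#' A junction exactly on a window boundary belongs to the left window.
#' Windows with no junctions contribute explicit zeros.
#'
#' @param segments Filtered segment tibble.
#' @param assets A [genome_assets()] object.
#' @param window_bp Window size in bp (default 10 Mb).
#' @return Tibble `sample, value` with one row per window.
#' @export
breakpoints_per_10mb <- function(segments, assets, window_bp = 1e7) {
  samples <- unique(segments$sample)
  if (length(samples) == 0) return(tibble(sample = character(), value = double()))
  lens <- setNames(assets$chrom_lengths$length, assets$chrom_lengths$chrom)
  grid <- sample_chrom_grid(samples, assets) |>
    mutate(n_windows = ceiling(lens[.data$chrom] / window_bp))
  jn <- cn_junctions(segments) |>
    filter(.data$chrom %in% included_chroms(assets)) |>
    mutate(window = ceiling(.data$pos / window_bp)) |>
    count(.data$sample, .data$chrom, .data$window)
  out <- grid |>
    group_by(.data$sample, .data$chrom) |>
    reframe_windows(jn)
  tibble(sample = out$sample, value = out$value)
}

# Expand the per-chromosome window grid and join junction counts.
reframe_windows <- function(grid, jn) {
  grid <- ungroup(grid)
  expanded <- grid |>
    mutate(window = purrr::map(.data$n_windows, seq_len)) |>
    tidyr::unnest("window")
  expanded |>
    left_join(jn, by = c("sample", "chrom", "window")) |>
    mutate(value = dplyr::coalesce(as.double(.data$n), 0))
}

#' Absolute copy number of segments
#'
#' One value (`total_cn`) per segment.
#'
#' @inheritParams breakpoints_per_10mb
#' @return Tibble `sample, value`.
#' @export
segment_cn_values <- function(segments) {
  tibble(sample = segments$sample, value = as.double(segments$total_cn))
}

#' Copy-number jumps between adjacent segments
#'
#' Absolute CN difference for each pair of adjacent segments within a
#' chromosome; single-segment chromosomes contribute nothing.
#'
#' @inheritParams breakpoints_per_10mb
#' @return Tibble `sample, value`.
#' @export
cn_jumps <- function(segments) {
  if (nrow(segments) < 2) return(tibble(sample = character(), value = double()))
  seg <- arrange(segments, .data$sample, .data$chrom, .data$start)
  grp <- paste(seg$sample, seg$chrom)
  i <- which(grp[-nrow(seg)] == grp[-1])
  tibble(
    sample = seg$sample[i],
    value = abs(seg$total_cn[i + 1] - seg$total_cn[i])
  )
}

#' Breakpoints per chromosome arm
#'
#' Junctions are assigned to the p arm (before the centromere interval) or q
#' arm (after it); junctions inside the centromere interval are assigned to
#' neither arm. Arms with no junctions contribute explicit zeros.
#'
#' @inheritParams breakpoints_per_10mb
#' @return Tibble `sample, value` with one row per arm.
#' @export
breakpoints_per_arm <- function(segments, assets) {
  samples <- unique(segments$sample)
  if (length(samples) == 0) return(tibble(sample = character(), value = double()))
  cen <- assets$arm_boundaries
  jn <- cn_junctions(segments) |>
    filter(.data$chrom %in% included_chroms(assets)) |>
    left_join(cen, by = "chrom") |>
    mutate(arm = dplyr::case_when(
      .data$pos < .data$cen_start ~ "p",
      .data$pos > .data$cen_end ~ "q",
      TRUE ~ NA_character_ # centromeric junction: neither arm
    )) |>
    filter(!is.na(.data$arm)) |>
    count(.data$sample, .data$chrom, .data$arm)
  grid <- tidyr::expand_grid(
    sample = samples, chrom = included_chroms(assets), arm = c("p", "q")
  )
  out <- grid |>
    left_join(jn, by = c("sample", "chrom", "arm")) |>
    mutate(value = dplyr::coalesce(as.double(.data$n), 0))
  tibble(sample = out$sample, value = out$value)
}

# Left-to-right scan for maximal non-overlapping runs of >= min_len adjacent
# segments whose CN alternates between exactly two distinct values.
oscillation_runs <- function(cn, min_len = 3) {
  n <- length(cn)
  runs <- integer(0)
  i <- 1
  while (i <= n - 1) {
    if (cn[i] == cn[i + 1]) { i <- i + 1; next }
    a <- cn[i]; b <- cn[i + 1]
    j <- i + 1
    while (j < n && cn[j + 1] == (if ((j - i) %% 2 == 0) b else a)) {
      # next element must continue the a,b,a,b pattern
      j <- j + 1
    }
    len <- j - i + 1
    if (len >= min_len) {
      runs <- c(runs, len)
      i <- j + 1 # non-overlapping: resume after the run
    } else {
      i <- i + 1
    }
  }
  runs
}

#' Lengths of oscillating CN segment chains
#'
#' Per chromosome, maximal non-overlapping runs of at least `min_len`
#' consecutive segments whose total CN alternates between exactly two
#' distinct values (a, b, a, b, ...); the value is the number of segments in
#' the run. Chromosomes with no run contribute an explicit 0.
#'
#' @inheritParams breakpoints_per_10mb
#' @param min_len Minimum run length (default 3).
#' @return Tibble `sample, value`.
#' @export
oscillation_chain_lengths <- function(segments, min_len = 3) {
  if (nrow(segments) == 0) return(tibble(sample = character(), value = double()))
  seg <- arrange(segments, .data$sample, .data$chrom, .data$start)
  seg |>
    group_by(.data$sample, .data$chrom) |>
    summarise(value = list({
      r <- oscillation_runs(.data$total_cn, min_len)
      if (length(r) == 0) 0 else as.double(r)
    }), .groups = "drop") |>
    tidyr::unnest("value") |>
    select("sample", "value")
}

#' Segment sizes
#'
#' `end - start + 1` per segment, in bp.
#'
#' @inheritParams breakpoints_per_10mb
#' @return Tibble `sample, value`.
#' @export
segment_sizes <- function(segments) {
  tibble(
    sample = segments$sample,
    value = as.double(segments$end - segments$start + 1)
  )
}

#' Compute all six CN feature value distributions
#'
#' Runs the six extractors on a filtered cohort segment table and binds the
#' results into a long tibble. This is the substrate for category fitting
#' ([fit_category_scheme()]) and matrix construction ([build_cn_matrix()]).
#'
#' @param segments Filtered cohort segment tibble.
#' @param assets A [genome_assets()] object.
#' @return A tibble `sample, feature, value` with `feature` one of
#'   `bkpt_10mb, seg_cn, cn_jump, bkpt_arm, osc_len, seg_size`.
#' @examples
#' cohort <- simulate_cohort(scenario_presets("quiet", n_samples = 2, seed = 1))
#' feats <- cn_features(cohort$segments, genome_assets())
#' dplyr::count(feats, feature)
#' @export
cn_features <- function(segments, assets = genome_assets()) {
  bind_rows(
    mutate(breakpoints_per_10mb(segments, assets), feature = "bkpt_10mb"),
    mutate(segment_cn_values(segments), feature = "seg_cn"),
    mutate(cn_jumps(segments), feature = "cn_jump"),
    mutate(breakpoints_per_arm(segments, assets), feature = "bkpt_arm"),
    mutate(oscillation_chain_lengths(segments), feature = "osc_len"),
    mutate(segment_sizes(segments), feature = "seg_size")
  ) |>
    select("sample", "feature", "value")
}
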