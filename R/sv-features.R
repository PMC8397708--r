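# Clustered/non-clustered annotation of SV breakpoint pairs and the fixed
# 32-category SV count matrix:
# {clustered, non-clustered} x ({deletion, tandem-duplication, inversion} x
# 5 size bins, plus translocation).

sv_matrix_columns <- function() {
  intra <- setdiff(SV_TYPES, "translocation")
  short <- c(deletion = "del", `tandem-duplication` = "dup", inversion = "inv")
  unlist(lapply(c("clustered", "non-clustered"), function(status) {
    c(
      unlist(lapply(intra, function(ty) {
        paste(status, short[[ty]], SV_SIZE_BINS, sep = "_")
      })),
      paste(status, "tra", sep = "_")
    )
  }), use.names = FALSE)
}

#' Size bin of an intra-chromosomal SV
#'
#' Bins the span `pos2 - pos1` into the standard rearrangement size classes
#' 1-10 kb, 10-100 kb, 100 kb-1 Mb, 1-10 Mb, >10 Mb (half-open boundaries,
#' `[low, high)`). Translocations have no span and return `NA`. Spans below
#' 1 kb are assigned to the smallest bin with a warning.
#'
#' @param svs SV tibble.
#' @return A character vector of size-bin labels aligned with the rows of
#'   `svs` (`NA` for translocations).
#' @export
sv_size_bin <- function(svs) {
  span <- svs$pos2 - svs$pos1
  is_tra <- svs$sv_type == "translocation"
  if (any(!is_tra & span < 1e3)) {
    warn("SV span(s) below 1 kb assigned to the 1-10 kb bin")
  }
  bin <- dplyr::case_when(
    is_tra ~ NA_character_,
    span < 1e4 ~ SV_SIZE_BINS[1],
    span < 1e5 ~ SV_SIZE_BINS[2],
    span < 1e6 ~ SV_SIZE_BINS[3],
    span < 1e7 ~ SV_SIZE_BINS[4],
    TRUE ~ SV_SIZE_BINS[5]
  )
  bin
}

# Exact piecewise-constant fit: minimize sum of within-segment squared error
# plus `penalty` per segment, by dynamic programming (O(n^2)).
# Returns the segment id of each point.
pcf_segment <- function(x, penalty) {
  n <- length(x)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  sse <- function(i, j) { # within-segment SSE for x[i..j]
    s <- cs[j + 1] - cs[i]; s2 <- cs2[j + 1] - cs2[i]
    s2 - s^2 / (j - i + 1)
  }
  cost <- c(0, rep(Inf, n))
  back <- integer(n)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      c_ij <- cost[i] + sse(i, j) + penalty
      if (c_ij < cost[j + 1]) {
        cost[j + 1] <- c_ij
        back[j] <- i
      }
    }
  }
  seg <- integer(n)
  j <- n; id <- 0L
  bounds <- list()
  while (j >= 1) {
    i <- back[j]
    bounds[[length(bounds) + 1]] <- c(i, j)
    j <- i - 1
  }
  bounds <- rev(bounds)
  for (k in seq_along(bounds)) {
    seg[bounds[[k]][1]:bounds[[k]][2]] <- k
  }
  seg
}

#' Flag clustered SV breakpoint pairs
#'
#' Rearrangement clustering in the style used for SV-signature analysis:
#' per sample, breakends are pooled per chromosome and sorted; the
#' inter-breakend distances are segmented by an exact piecewise-constant fit
#' (on log10 distance, penalty `gamma` times a robust noise variance); a
#' breakend is clustered when its segment's mean inter-breakend distance is
#' at most `fraction` of the sample's genome-averaged inter-breakend
#' distance (total included genome length divided by the breakend count —
#' the expected spacing were the sample's breakends spread uniformly, which
#' stays meaningful even when one dense event carries most breakends). A
#' pair is clustered if either breakend is. A qualifying segment must carry
#' at least `min_breakends` breakends — an isolated pair of nearby breakends
#' (e.g. the two ends of a single deletion) is not a cluster. Chromosomes
#' with fewer than two breakends contribute no clustered calls.
#' Deterministic, invariant to id relabeling and to whole-genome coordinate
#' translation.
#'
#' @param svs SV tibble (one or more samples).
#' @param gamma Segmentation penalty multiplier (default 25).
#' @param fraction Clustered threshold as a fraction of the genome-averaged
#'   inter-breakend distance (default 0.1).
#' @param min_breakends Minimum breakends in a clustered segment (default 6,
#'   i.e. at least three rearrangements' worth of local density).
#' @param assets Genome assets supplying the included genome length.
#' @return `svs` with a logical `clustered` column.
#' @export
detect_clustered <- function(svs, gamma = 25, fraction = 0.1,
                             min_breakends = 6, assets = genome_assets()) {
  if (nrow(svs) == 0) return(mutate(svs, clustered = logical(0)))
  genome_bp <- sum(assets$chrom_lengths$length[
    assets$chrom_lengths$chrom %in% included_chroms(assets)
  ])
  out <- svs
  out$clustered <- FALSE
  for (s in unique(svs$sample)) {
    rows <- which(svs$sample == s)
    be <- bind_rows(
      tibble(row = rows, chrom = svs$chrom1[rows], pos = svs$pos1[rows]),
      tibble(row = rows, chrom = svs$chrom2[rows], pos = svs$pos2[rows])
    )
    be <- arrange(be, .data$chrom, .data$pos)
    genome_mean <- genome_bp / nrow(be)
    clustered_rows <- integer(0)
    for (ch in unique(be$chrom)) {
      idx <- which(be$chrom == ch)
      if (length(idx) < 2) next
      g <- diff(be$pos[idx])
      lg <- log10(g + 1)
      sig2 <- if (length(lg) > 2) {
        max((stats::mad(diff(lg)) / sqrt(2))^2, stats::var(lg) * 0.05, 1e-4)
      } else {
        max(stats::var(lg), 1e-4)
      }
      seg <- pcf_segment(lg, penalty = gamma * sig2)
      seg_mean <- tapply(g, seg, mean)
      seg_size <- tapply(g, seg, length) + 1 # breakends per segment
      gap_clustered <- seg_mean[as.character(seg)] <= fraction * genome_mean &
        seg_size[as.character(seg)] >= min_breakends
      # breakend i is adjacent to gaps i-1 and i
      be_clustered <- logical(length(idx))
      be_clustered[-length(idx)] <- be_clustered[-length(idx)] | gap_clustered
      be_clustered[-1] <- be_clustered[-1] | gap_clustered
      clustered_rows <- c(clustered_rows, be$row[idx][be_clustered])
    }
    out$clustered[unique(clustered_rows)] <- TRUE
  }
  out
}

#' Build the 32-category SV count matrix
#'
#' Tallies each sample's pairs into the fixed 32 columns:
#' clustered/non-clustered crossed with deletion, tandem-duplication and
#' inversion in five size bins plus translocation. Per sample the row sum
#' equals the catalog size. If the catalog lacks a `clustered` column it is
#' computed with [detect_clustered()] defaults.
#'
#' @param svs SV tibble for a cohort.
#' @return A wide tibble, samples by the 32 SV categories.
#' @export
build_sv_matrix <- function(svs) {
  cols <- sv_matrix_columns()
  if (!"clustered" %in% names(svs)) svs <- detect_clustered(svs)
  samples <- unique(svs$sample)
  m <- matrix(0L, nrow = length(samples), ncol = length(cols),
    dimnames = list(samples, cols)
  )
  if (nrow(svs) > 0) {
    short <- c(deletion = "del", `tandem-duplication` = "dup",
               inversion = "inv", translocation = "tra")
    bin <- sv_size_bin(svs)
    status <- if_else(svs$clustered, "clustered", "non-clustered")
    lab <- if_else(
      svs$sv_type == "translocation",
      paste(status, "tra", sep = "_"),
      paste(status, short[svs$sv_type], bin, sep = "_")
    )
    tab <- table(factor(svs$sample, levels = samples), factor(lab, levels = cols))
    m <- m + unclass(tab)
  }
  matrix_to_tibble(m)
}

#' Per-pair SV annotation table
#'
#' Convenience export of the per-pair annotation (type, size bin, clustered
#' flag) used by the SV matrix.
#'
#' @param svs SV tibble; `clustered` computed if absent.
#' @return A tibble `sample, id, sv_type, size_bin, clustered`.
#' @export
annotate_sv_pairs <- function(svs) {
  if (!"clustered" %in% names(svs)) svs <- detect_clustered(svs)
  tibble(
    sample = svs$sample, id = svs$id, sv_type = svs$sv_type,
    size_bin = sv_size_bin(svs), clustered = svs$clustered
  )
}
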