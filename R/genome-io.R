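# Reading, writing and filtering of segment tables, BEDPE SV catalogs and
# genome annotation assets.  Internal coordinates are 1-based inclusive;
# BEDPE is read and written as 0-based half-open.

#' Genome annotation assets
#'
#' Bundles chromosome lengths, centromere (arm-boundary) intervals, the
#' immunoglobulin-locus mask (IGH/IGK/IGL) and the set of excluded
#' chromosomes. Defaults ship as editable GRCh37 text assets under
#' `inst/extdata`; coordinates are an asset, not hard-coded.
#'
#' The X chromosome is excluded because the source copy-number profiles do
#' not resolve sex-chromosome ploidy; Y is excluded by default for the same
#' reason.
#'
#' @param chrom_sizes Path to a UCSC-style chrom sizes TSV
#'   (`chrom`, `length`), or a data frame with those columns.
#' @param centromeres Path to a TSV (`chrom`, `cen_start`, `cen_end`), or a
#'   data frame.
#' @param ig_mask Path to a BED file of masked intervals (0-based half-open),
#'   or a data frame with 1-based `chrom`, `start`, `end`.
#' @param excluded_chroms Chromosomes dropped from all analyses.
#' @return An object of class `genome_assets`: a list with tibbles
#'   `chrom_lengths`, `arm_boundaries`, `ig_mask` and the character vector
#'   `excluded_chroms`.
#' @examples
#' assets <- genome_assets()
#' assets$chrom_lengths
#' @export
genome_assets <- function(chrom_sizes = NULL, centromeres = NULL,
                          ig_mask = NULL, excluded_chroms = c("X", "Y")) {
  read_or_df <- function(x, default_file, reader) {
    if (is.null(x)) {
      x <- system.file("extdata", default_file, package = "chromosig", mustWork = TRUE)
    }
    if (is.character(x)) reader(x) else as_tibble(x)
  }
  sizes <- read_or_df(chrom_sizes, "grch37_chrom_sizes.tsv", function(p) {
    readr::read_tsv(p, col_types = readr::cols(
      chrom = readr::col_character(), length = readr::col_double()
    ))
  })
  cen <- read_or_df(centromeres, "grch37_centromeres.tsv", function(p) {
    readr::read_tsv(p, col_types = readr::cols(
      chrom = readr::col_character(),
      cen_start = readr::col_double(), cen_end = readr::col_double()
    ))
  })
  mask <- read_or_df(ig_mask, "grch37_ig_loci.bed", function(p) {
    bed <- readr::read_tsv(p,
      col_names = c("chrom", "start0", "end", "name"),
      col_types = "cddc"
    )
    tibble(
      chrom = bed$chrom, start = bed$start0 + 1, end = bed$end,
      name = bed$name
    )
  })
  sizes$chrom <- normalize_chrom(sizes$chrom)
  cen$chrom <- normalize_chrom(cen$chrom)
  mask$chrom <- normalize_chrom(mask$chrom)
  lens <- setNames(sizes$length, sizes$chrom)
  bad <- mask$end > lens[mask$chrom] | mask$start < 1
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    abort("masked interval outside its chromosome length")
  }
  structure(
    list(
      chrom_lengths = sizes,
      arm_boundaries = cen,
      ig_mask = mask,
      excluded_chroms = normalize_chrom(excluded_chroms)
    ),
    class = "genome_assets"
  )
}

#' @exportS3Method base::print
print.genome_assets <- function(x, ...) {
  cat(
    "<genome_assets> ", nrow(x$chrom_lengths), " chromosomes, ",
    nrow(x$ig_mask), " masked intervals, excluded: ",
    paste(x$excluded_chroms, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

# Chromosomes retained for analysis, in asset order.
included_chroms <- function(assets) {
  setdiff(assets$chrom_lengths$chrom, assets$excluded_chroms)
}

validate_segments <- function(seg, context = "segments") {
  req <- c("sample", "chrom", "start", "end", "total_cn")
  missing_cols <- setdiff(req, names(seg))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s: missing required column(s): %s", context,
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- which(!(seg$start < seg$end) | seg$total_cn < 0 |
    !is.finite(seg$start) | !is.finite(seg$end) | !is.finite(seg$total_cn))
  if ("minor_cn" %in% names(seg)) {
    bad <- union(bad, which(!is.na(seg$minor_cn) & seg$minor_cn > seg$total_cn))
  }
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: invalid row(s) (need start < end, total_cn >= 0, minor_cn <= total_cn) at line(s): %s",
      context, paste(sort(bad) + 1, collapse = ", ")
    ))
  }
  invisible(seg)
}

# Sort within sample/chromosome and merge adjacent equal-CN neighbors.
merge_equal_neighbors <- function(seg) {
  if (nrow(seg) == 0) return(seg)
  seg <- arrange(seg, .data$sample, .data$chrom, .data$start)
  grp <- paste(seg$sample, seg$chrom)
  new_run <- c(TRUE, grp[-1] != grp[-nrow(seg)] |
    seg$total_cn[-1] != seg$total_cn[-nrow(seg)])
  run_id <- cumsum(new_run)
  out <- seg |>
    mutate(.run = run_id) |>
    group_by(.data$.run) |>
    summarise(
      sample = first(.data$sample), chrom = first(.data$chrom),
      start = min(.data$start), end = max(.data$end),
      total_cn = first(.data$total_cn),
      dplyr::across(dplyr::any_of("minor_cn"), first),
      .groups = "drop"
    ) |>
    select(-".run")
  arrange(out, .data$sample, .data$chrom, .data$start)
}

#' Read per-sample copy-number segment profiles
#'
#' Reads a SEG-like TSV with header
#' `sample, chrom, start, end, total_cn[, minor_cn]` (1-based inclusive
#' coordinates). Rows are validated (start < end, non-negative integer CN),
#' sorted per sample and chromosome, and adjacent segments with equal
#' `total_cn` are merged so that every junction is a real CN change.
#'
#' @param path Path to the TSV file.
#' @param dialect `"seg_tsv"` (total CN only) or `"allele_specific_tsv"`
#'   (requires a `minor_cn` column).
#' @return A tibble of segments, one cohort-wide table keyed by `sample`.
#' @export
read_segments <- function(path, dialect = c("seg_tsv", "allele_specific_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  seg <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), chrom = readr::col_character(),
    .default = readr::col_double()
  ))
  if (dialect == "allele_specific_tsv" && !"minor_cn" %in% names(seg)) {
    abort("allele_specific_tsv requires a `minor_cn` column")
  }
  validate_segments(seg, context = path)
  seg$chrom <- normalize_chrom(seg$chrom)
  merge_equal_neighbors(seg)
}

#' Write segment profiles to TSV
#'
#' @param segments Segment tibble as returned by [read_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  readr::write_tsv(segments, path)
  invisible(path)
}

normalize_sv_type <- function(type) {
  key <- toupper(as.character(type))
  map <- c(
    DEL = "deletion", DELETION = "deletion",
    DUP = "tandem-duplication", `TANDEM-DUPLICATION` = "tandem-duplication",
    TANDEM_DUPLICATION = "tandem-duplication",
    INV = "inversion", INVERSION = "inversion",
    TRA = "translocation", TRANSLOCATION = "translocation", BND = "translocation",
    CTX = "translocation"
  )
  out <- unname(map[key])
  if (anyNA(out)) {
    abort(sprintf(
      "unknown sv_type token(s): %s",
      paste(unique(type[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

# Enforce the breakpoint-pair invariants: intra-chromosomal pairs have
# pos1 < pos2 (swapping breakends if needed) and inter-chromosomal pairs are
# translocations.
normalize_sv_pairs <- function(sv) {
  intra <- sv$chrom1 == sv$chrom2
  flip <- intra & sv$pos1 > sv$pos2
  if (any(flip)) {
    tmp_p <- sv$pos1[flip]; sv$pos1[flip] <- sv$pos2[flip]; sv$pos2[flip] <- tmp_p
    tmp_s <- sv$strand1[flip]; sv$strand1[flip] <- sv$strand2[flip]; sv$strand2[flip] <- tmp_s
  }
  sv$sv_type[!intra] <- "translocation"
  if (any(intra & sv$sv_type == "translocation")) {
    abort("intra-chromosomal pair labeled translocation")
  }
  dup <- sv |>
    group_by(.data$sample) |>
    filter(duplicated(.data$id)) |>
    ungroup()
  if (nrow(dup) > 0) {
    abort(sprintf("duplicated SV id(s) within sample: %s",
                  paste(unique(dup$id), collapse = ", ")))
  }
  sv
}

#' Read a structural-variant catalog from BEDPE
#'
#' Reads 10-column BEDPE (`chrom1, start1, end1, chrom2, start2, end2, name,
#' score, strand1, strand2`) plus a `type` column; an optional `sample`
#' column allows pooled files, otherwise `sample` is taken from the file
#' name. BEDPE 0-based half-open starts are converted to internal 1-based
#' breakend positions. When `type` is absent, intra-chromosomal types are
#' derived from the strand orientation (`+-` deletion, `-+`
#' tandem-duplication, `++`/`--` inversion).
#'
#' @param path Path to a BEDPE file (tab-separated, with header).
#' @param assets Optional [genome_assets()]; when given, chromosomes not
#'   present in the assets raise a validation error.
#' @param sample Sample id used when the file has no `sample` column.
#' @return A tibble with columns `sample, chrom1, pos1, strand1, chrom2,
#'   pos2, strand2, sv_type, id`; empty files yield an empty tibble.
#' @export
read_sv_bedpe <- function(path, assets = NULL, sample = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  empty <- tibble(
    sample = character(), chrom1 = character(), pos1 = double(),
    strand1 = character(), chrom2 = character(), pos2 = double(),
    strand2 = character(), sv_type = character(), id = character()
  )
  first_line <- readLines(path, n = 1)
  if (length(first_line) == 0) return(empty)
  bed <- readr::read_tsv(path, col_types = readr::cols(
    chrom1 = readr::col_character(), chrom2 = readr::col_character(),
    name = readr::col_character(),
    .default = readr::col_guess()
  ))
  if (nrow(bed) == 0) return(empty)
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
           "name", "score", "strand1", "strand2")
  missing_cols <- setdiff(req, names(bed))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing BEDPE column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  sv <- tibble(
    sample = if ("sample" %in% names(bed)) as.character(bed$sample) else {
      sample %||% sub("\\.bedpe$", "", basename(path))
    },
    chrom1 = normalize_chrom(bed$chrom1), pos1 = bed$start1 + 1,
    strand1 = as.character(bed$strand1),
    chrom2 = normalize_chrom(bed$chrom2), pos2 = bed$start2 + 1,
    strand2 = as.character(bed$strand2),
    id = as.character(bed$name)
  )
  if ("type" %in% names(bed)) {
    sv$sv_type <- normalize_sv_type(bed$type)
  } else {
    intra <- sv$chrom1 == sv$chrom2
    orient <- paste0(sv$strand1, sv$strand2)
    sv$sv_type <- if_else(!intra, "translocation", dplyr::case_when(
      orient == "+-" ~ "deletion",
      orient == "-+" ~ "tandem-duplication",
      TRUE ~ "inversion"
    ))
  }
  if (!is.null(assets)) {
    known <- assets$chrom_lengths$chrom
    bad <- setdiff(unique(c(sv$chrom1, sv$chrom2)), known)
    if (length(bad) > 0) {
      abort(sprintf("%s: chromosome(s) not in assets: %s", path,
                    paste(bad, collapse = ", ")))
    }
  }
  normalize_sv_pairs(sv)
}

#' Write an SV catalog as BEDPE
#'
#' Internal 1-based breakend positions are written as 0-based half-open
#' single-base intervals, so a read/write round-trip is exact.
#'
#' @param svs SV tibble as returned by [read_sv_bedpe()].
#' @param path Output path.
#' @param keep_sample Write the `sample` column (for pooled files).
#' @return `path`, invisibly.
#' @export
write_sv_bedpe <- function(svs, path, keep_sample = TRUE) {
  out <- tibble(
    chrom1 = svs$chrom1, start1 = svs$pos1 - 1, end1 = svs$pos1,
    chrom2 = svs$chrom2, start2 = svs$pos2 - 1, end2 = svs$pos2,
    name = svs$id, score = ".", strand1 = svs$strand1, strand2 = svs$strand2,
    type = svs$sv_type
  )
  if (keep_sample) out$sample <- svs$sample
  readr::write_tsv(out, path)
  invisible(path)
}

in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[i] &
      pos >= intervals$start[i] & pos <= intervals$end[i])
  }
  hit
}

# Dissolve CN junctions falling inside masked intervals: the two flanking
# segments are merged, keeping the CN of the longer flank.
dissolve_masked_junctions <- function(seg, mask) {
  repeat {
    if (nrow(seg) < 2) return(seg)
    grp <- paste(seg$sample, seg$chrom)
    left <- seq_len(nrow(seg) - 1)
    junction <- which(grp[left] == grp[left + 1])
    if (length(junction) == 0) return(seg)
    jpos <- seg$end[junction] # junction sits between end[i] and start[i+1]
    masked <- in_intervals(seg$chrom[junction], jpos, mask) |
      in_intervals(seg$chrom[junction], seg$start[junction + 1], mask)
    idx <- junction[masked]
    if (length(idx) == 0) return(seg)
    i <- idx[1]
    len_l <- seg$end[i] - seg$start[i] + 1
    len_r <- seg$end[i + 1] - seg$start[i + 1] + 1
    keep_cn <- if (len_r > len_l) seg$total_cn[i + 1] else seg$total_cn[i]
    seg$end[i] <- seg$end[i + 1]
    seg$total_cn[i] <- keep_cn
    seg <- seg[-(i + 1), ]
    seg <- merge_equal_neighbors(seg)
  }
}

# Remove CN changes shorter than min_seg_bp by absorbing the short segment
# into the flanking neighbor with the closer total_cn (tie: preceding).
absorb_short_segments <- function(seg, min_seg_bp) {
  repeat {
    if (nrow(seg) < 2) return(seg)
    grp <- paste(seg$sample, seg$chrom)
    len <- seg$end - seg$start + 1
    has_prev <- c(FALSE, grp[-1] == grp[-nrow(seg)])
    has_next <- c(grp[-nrow(seg)] == grp[-1], FALSE)
    short <- which(len < min_seg_bp & (has_prev | has_next))
    if (length(short) == 0) return(seg)
    i <- short[order(len[short], short)][1] # shortest first, then leftmost
    cand <- c(
      if (has_prev[i]) abs(seg$total_cn[i] - seg$total_cn[i - 1]) else Inf,
      if (has_next[i]) abs(seg$total_cn[i] - seg$total_cn[i + 1]) else Inf
    )
    take_prev <- cand[1] <= cand[2] # tie goes to the preceding neighbor
    seg$total_cn[i] <- if (take_prev) seg$total_cn[i - 1] else seg$total_cn[i + 1]
    seg <- merge_equal_neighbors(seg)
  }
}

#' Apply the artefact filters to segments and SV catalogs
#'
#' Implements the quality filters used before feature extraction: segments on
#' excluded chromosomes are dropped; CN breakpoints falling inside the
#' immunoglobulin mask are dissolved (flanks merged, keeping the CN of the
#' longer flank); CN changes shorter than `min_seg_bp` (default 50 kb) are
#' removed by merging each short segment into the flanking neighbor with the
#' closer total CN (ties to the preceding neighbor); SV pairs with either
#' breakend inside the mask or on an excluded chromosome are dropped.
#' Equal-CN neighbors are re-merged afterwards. Masking precedes the size
#' filter.
#'
#' The operation is idempotent: applying it twice equals applying it once.
#'
#' @param segments Segment tibble (may be `NULL`).
#' @param svs SV tibble (may be `NULL`).
#' @param assets A [genome_assets()] object.
#' @param min_seg_bp Minimum CN-change size in bp; smaller changes are
#'   treated as artefacts.
#' @return A list with filtered `segments` and `svs` tibbles.
#' @export
apply_filters <- function(segments, svs = NULL, assets = genome_assets(),
                          min_seg_bp = 50000) {
  out_seg <- NULL
  if (!is.null(segments)) {
    validate_segments(segments)
    seg <- segments
    seg$chrom <- normalize_chrom(seg$chrom)
    seg <- filter(seg, !.data$chrom %in% assets$excluded_chroms)
    seg <- merge_equal_neighbors(seg)
    seg <- dissolve_masked_junctions(seg, assets$ig_mask)
    seg <- absorb_short_segments(seg, min_seg_bp)
    out_seg <- seg
  }
  out_sv <- NULL
  if (!is.null(svs)) {
    sv <- svs
    sv$chrom1 <- normalize_chrom(sv$chrom1)
    sv$chrom2 <- normalize_chrom(sv$chrom2)
    drop <- sv$chrom1 %in% assets$excluded_chroms |
      sv$chrom2 %in% assets$excluded_chroms |
      in_intervals(sv$chrom1, sv$pos1, assets$ig_mask) |
      in_intervals(sv$chrom2, sv$pos2, assets$ig_mask)
    out_sv <- sv[!drop, , drop = FALSE]
  }
  list(segments = out_seg, svs = out_sv)
}

#' Write / read a samples-by-categories count matrix
#'
#' Lossless TSV round-trip of a matrix-shaped tibble whose first column is
#' `sample`. Counts must be finite; duplicated sample or category labels are
#' an error.
#'
#' @param x Wide tibble (first column `sample`) or a named matrix.
#' @param path Output path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` returns
#'   a wide tibble.
#' @export
write_matrix <- function(x, path) {
  m <- as_count_matrix(x)
  if (anyNA(m) || any(!is.finite(m))) abort("matrix values must be finite")
  if (anyDuplicated(rownames(m))) abort("duplicated sample labels")
  if (anyDuplicated(colnames(m))) abort("duplicated category labels")
  readr::write_tsv(matrix_to_tibble(m), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), .default = readr::col_double()
  ))
  if (anyDuplicated(x$sample)) abort("duplicated sample labels")
  if (anyDuplicated(names(x))) abort("duplicated category labels")
  x
}
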