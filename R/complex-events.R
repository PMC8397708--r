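# Breakpoint-interconnection graph and classification of complex structural
# events.  Rules, applied in priority order per component:
#   chromothripsis: more than 10 interconnected breakpoint pairs with
#     oscillating CN across one or more chromosomes;
#   chromoplexy: interconnection across >2 chromosomes with associated CN
#     loss;
#   templated insertion: translocation(s) with focal CN gain spanning a
#     breakend (simple on <=2 chromosomes, complex on >2);
#   complex_nos: >=3 interconnected pairs fitting none of the above;
#   single: everything else.

default_event_config <- function() {
  list(
    link_bp = 1e6,       # interconnection radius between breakends
    min_osc = 6,         # minimum oscillating-run length for chromothripsis
    max_osc_states = 3,  # oscillation over 2 or 3 CN states
    focal_gain_max_bp = 5e6
  )
}

#' Build the breakpoint-interconnection graph
#'
#' Nodes are SV breakpoint pairs; an edge joins two pairs when any breakend
#' of one lies within `link_bp` of any breakend of the other (same
#' chromosome). Connected components are numbered deterministically by the
#' position-sorted order of their first member pair.
#'
#' @param svs SV tibble (one or more samples).
#' @param link_bp Interconnection radius in bp (default 1 Mb).
#' @return `svs` with an integer `component` column (numbered per sample).
#' @export
build_event_graph <- function(svs, link_bp = 1e6) {
  if (nrow(svs) == 0) return(mutate(svs, component = integer(0)))
  out <- svs
  out$component <- NA_integer_
  for (s in unique(svs$sample)) {
    rows <- which(svs$sample == s)
    sub <- svs[rows, ]
    ord <- order(sub$chrom1, sub$pos1, sub$chrom2, sub$pos2, sub$id)
    sub <- sub[ord, ]
    n <- nrow(sub)
    be <- bind_rows(
      tibble(pair = seq_len(n), chrom = sub$chrom1, pos = sub$pos1),
      tibble(pair = seq_len(n), chrom = sub$chrom2, pos = sub$pos2)
    )
    edges <- integer(0)
    for (ch in unique(be$chrom)) {
      bc <- be[be$chrom == ch, ]
      bc <- arrange(bc, .data$pos)
      m <- nrow(bc)
      if (m < 2) next
      # link runs of breakends whose consecutive gaps are within link_bp
      for (i in seq_len(m - 1)) {
        j <- i + 1
        while (j <= m && bc$pos[j] - bc$pos[i] <= link_bp) {
          if (bc$pair[i] != bc$pair[j]) {
            edges <- c(edges, bc$pair[i], bc$pair[j])
          }
          j <- j + 1
        }
      }
    }
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (length(edges) > 0) g <- igraph::add_edges(g, edges)
    memb <- igraph::components(g)$membership
    # renumber components by first (position-sorted) member
    first_idx <- tapply(seq_len(n), memb, min)
    relabel <- rank(first_idx)
    comp <- as.integer(relabel[as.character(memb)])
    out$component[rows[ord]] <- comp
  }
  out
}

# Length-weighted modal total CN per chromosome of one sample's profile.
modal_cn_by_chrom <- function(seg) {
  seg |>
    group_by(.data$chrom, .data$total_cn) |>
    summarise(len = sum(.data$end - .data$start + 1), .groups = "drop_last") |>
    arrange(dplyr::desc(.data$len), .data$total_cn) |>
    slice(1) |>
    ungroup() |>
    select("chrom", modal_cn = "total_cn")
}

# Longest run of adjacent differing CN values using at most `max_states`
# distinct states (O(n^2) scan; profiles are short).
longest_multistate_oscillation <- function(cn, max_states = 3) {
  n <- length(cn)
  if (n < 2) return(if (n == 0) 0L else 1L)
  best <- 1L
  for (i in seq_len(n - 1)) {
    states <- cn[i]
    j <- i
    while (j < n && cn[j + 1] != cn[j]) {
      cand <- union(states, cn[j + 1])
      if (length(cand) > max_states) break
      states <- cand
      j <- j + 1
    }
    best <- max(best, j - i + 1L)
  }
  best
}

#' Oscillating CN within a component footprint
#'
#' The footprint is, per involved chromosome, the breakend span padded by
#' `link_bp`. The component is oscillating when any chromosome's overlapping
#' segments contain a run of at least `min_osc` adjacent segments with
#' alternating CN over at most `max_osc_states` distinct states.
#'
#' @param segments One sample's filtered segment tibble.
#' @param component_svs The component's SV rows (same sample).
#' @param config See `link_bp`, `min_osc`, `max_osc_states` in the event
#'   classifier configuration.
#' @return A list: `oscillating` (logical), `max_run` (longest qualifying
#'   run), `chrom` (chromosome carrying it, or `NA`).
#' @export
oscillating_cn_in_footprint <- function(segments, component_svs,
                                        config = default_event_config()) {
  be <- bind_rows(
    tibble(chrom = component_svs$chrom1, pos = component_svs$pos1),
    tibble(chrom = component_svs$chrom2, pos = component_svs$pos2)
  )
  best <- 0L; best_chrom <- NA_character_
  for (ch in unique(be$chrom)) {
    span <- range(be$pos[be$chrom == ch])
    lo <- span[1] - config$link_bp; hi <- span[2] + config$link_bp
    seg <- segments |>
      filter(.data$chrom == ch, .data$end >= lo, .data$start <= hi) |>
      arrange(.data$start)
    if (nrow(seg) < 2) next
    run <- longest_multistate_oscillation(seg$total_cn, config$max_osc_states)
    if (run > best) { best <- run; best_chrom <- ch }
  }
  list(
    oscillating = best >= config$min_osc,
    max_run = best, chrom = best_chrom
  )
}

# Segments containing or immediately flanking a breakend position.
segments_at_breakend <- function(seg, pos) {
  idx <- which(seg$start <= pos & seg$end >= pos)
  if (length(idx) == 0) {
    after <- which(seg$start > pos)
    before <- which(seg$end < pos)
    idx <- c(if (length(before)) max(before), if (length(after)) min(after))
  } else {
    idx <- unique(c(idx, idx - 1, idx + 1))
    idx <- idx[idx >= 1 & idx <= nrow(seg)]
  }
  idx
}

#' Classify interconnected SV components into complex event classes
#'
#' Builds the interconnection graph (unless `svs` already carries a
#' `component` column) and applies the classification rules in priority
#' order. "CN loss" means a member breakend abuts a segment below the
#' chromosome's length-weighted modal CN; "focal gain" means a gained
#' segment of at most `focal_gain_max_bp` spans a translocation breakend.
#'
#' @param svs SV tibble (filtered).
#' @param segments Matching filtered segment tibble.
#' @param config List of tuning knobs, see `default_event_config()`:
#'   `link_bp` (1 Mb), `min_osc` (6), `max_osc_states` (3),
#'   `focal_gain_max_bp` (5 Mb).
#' @return A tibble of event calls: `sample, event_id, class, n_pairs,
#'   chroms, member_ids, oscillating_cn, cn_loss_associated,
#'   focal_gain_associated`.
#' @export
classify_complex_events <- function(svs, segments,
                                    config = default_event_config()) {
  config <- modifyList(default_event_config(), config)
  if (!"component" %in% names(svs)) {
    svs <- build_event_graph(svs, link_bp = config$link_bp)
  }
  calls <- list()
  for (s in unique(svs$sample)) {
    sv_s <- filter(svs, .data$sample == s)
    seg_s <- filter(segments, .data$sample == s) |>
      arrange(.data$chrom, .data$start)
    modal <- modal_cn_by_chrom(seg_s)
    modal_vec <- setNames(modal$modal_cn, modal$chrom)
    for (comp in sort(unique(sv_s$component))) {
      part <- filter(sv_s, .data$component == comp)
      chroms <- sort(unique(c(part$chrom1, part$chrom2)))
      n_pairs <- nrow(part)
      osc <- oscillating_cn_in_footprint(seg_s, part, config)
      be <- bind_rows(
        tibble(chrom = part$chrom1, pos = part$pos1,
               is_tra = part$sv_type == "translocation"),
        tibble(chrom = part$chrom2, pos = part$pos2,
               is_tra = part$sv_type == "translocation")
      )
      cn_loss <- FALSE; focal_gain <- FALSE
      for (i in seq_len(nrow(be))) {
        ch <- be$chrom[i]
        seg_ch <- filter(seg_s, .data$chrom == ch)
        if (nrow(seg_ch) == 0) next
        mcn <- modal_vec[[ch]] %||% 2
        idx <- segments_at_breakend(seg_ch, be$pos[i])
        if (any(seg_ch$total_cn[idx] < mcn)) cn_loss <- TRUE
        if (be$is_tra[i]) {
          span_idx <- which(seg_ch$start <= be$pos[i] & seg_ch$end >= be$pos[i])
          if (length(span_idx) > 0) {
            hit <- seg_ch[span_idx, ]
            if (any(hit$total_cn > mcn &
                (hit$end - hit$start + 1) <= config$focal_gain_max_bp)) {
              focal_gain <- TRUE
            }
          }
        }
      }
      has_tra <- any(part$sv_type == "translocation")
      class <- if (n_pairs > 10 && osc$oscillating) {
        "chromothripsis"
      } else if (length(chroms) > 2 && cn_loss) {
        "chromoplexy"
      } else if (has_tra && focal_gain) {
        if (length(chroms) > 2) "templated_insertion_complex" else "templated_insertion_simple"
      } else if (n_pairs >= 3) {
        "complex_nos"
      } else {
        "single"
      }
      calls[[length(calls) + 1]] <- tibble(
        sample = s,
        event_id = sprintf("%s_cx%d", s, comp),
        class = class,
        n_pairs = n_pairs,
        chroms = paste(chroms, collapse = ","),
        member_ids = paste(sort(part$id), collapse = ","),
        oscillating_cn = osc$oscillating,
        cn_loss_associated = cn_loss,
        focal_gain_associated = focal_gain
      )
    }
  }
  if (length(calls) == 0) {
    return(tibble(
      sample = character(), event_id = character(), class = character(),
      n_pairs = integer(), chroms = character(), member_ids = character(),
      oscillating_cn = logical(), cn_loss_associated = logical(),
      focal_gain_associated = logical()
    ))
  }
  bind_rows(calls)
}

#' Per-sample chromothripsis labels from event calls
#'
#' A sample is chromothripsis-positive when any of its components is
#' classified as chromothripsis.
#'
#' @param calls Event-call tibble from [classify_complex_events()].
#' @param samples Optional full sample vector (samples without any SV
#'   component are labeled 0).
#' @return A tibble `sample, chromothripsis` (0/1).
#' @export
sample_chromothripsis_labels <- function(calls, samples = NULL) {
  lab <- calls |>
    group_by(.data$sample) |>
    summarise(
      chromothripsis = as.integer(any(.data$class == "chromothripsis")),
      .groups = "drop"
    )
  if (!is.null(samples)) {
    lab <- tibble(sample = samples) |>
      left_join(lab, by = "sample") |>
      mutate(chromothripsis = dplyr::coalesce(.data$chromothripsis, 0L))
  }
  lab
}
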