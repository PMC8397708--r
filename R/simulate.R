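# Myeloma-like synthetic cohort generator: hyperdiploid/quiet baseline
# karyotypes, arm-level CNAs, planted chromothripsis (interconnected
# breakpoint pairs with oscillating CN), chromoplexy, templated insertions,
# complex-NOS, and scattered passenger SVs.  Fully seed-reproducible; the
# truth table records every planted event so downstream recovery is
# testable without controlled-access data.

#' Simulation configuration
#'
#' Defaults emulate newly diagnosed multiple myeloma cohorts: 24%
#' chromothripsis prevalence, chromothripsis breakpoint-pair counts drawn
#' log-normally around a median of 24 (IQR roughly 12-35, truncated above
#' 10 pairs), total CN capped at 9 with modal diploid background, a
#' hyperdiploid subgroup with whole-chromosome trisomies, and a 50 kb
#' segment-size floor. Per-class event rates beyond chromothripsis are not
#' published and are package defaults.
#'
#' @param n_samples Cohort size.
#' @param seed RNG seed (all outputs are byte-identical given the seed).
#' @param chromothripsis_prevalence Fraction of samples with a planted
#'   chromothripsis event; positives are allocated as
#'   `round(n * prevalence)` so cohort composition is exact.
#' @param chromoplexy_rate,templated_insertion_rate,complex_nos_rate
#'   Per-sample probabilities of the other planted event classes.
#' @param hyperdiploid_fraction Fraction with a trisomy baseline karyotype.
#' @param arm_cna_rate Mean number of arm-level CN changes per sample.
#' @param focal_cna_rate Mean number of focal (sub-chromosomal) CN changes
#'   per sample.
#' @param amplification_rate Mean number of high-level focal amplifications
#'   per sample (0 in the myeloma-like preset; solid-tumor-like genomes use
#'   a positive rate).
#' @param passenger_sv_rate Mean number of scattered passenger SVs.
#' @param ct_npairs_meanlog,ct_npairs_sdlog Log-normal parameters of the
#'   chromothripsis pair count.
#' @param ct_min_pairs Truncation floor of the pair count; must exceed 10
#'   when prevalence is positive (the chromothripsis rule requires more than
#'   10 interconnected pairs).
#' @param max_total_cn Total-CN ceiling (9 in the myeloma-like preset).
#' @param min_seg_bp Segment-size floor in bp.
#' @param osc_delta Oscillation amplitude in CN states (1 = two adjacent
#'   integer states).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 100, seed = 1,
                              chromothripsis_prevalence = 0.24,
                              chromoplexy_rate = 0.10,
                              templated_insertion_rate = 0.15,
                              complex_nos_rate = 0.15,
                              hyperdiploid_fraction = 0.55,
                              arm_cna_rate = 1.5,
                              focal_cna_rate = 3,
                              amplification_rate = 0,
                              passenger_sv_rate = 6,
                              ct_npairs_meanlog = log(24),
                              ct_npairs_sdlog = 0.55,
                              ct_min_pairs = 11,
                              max_total_cn = 9,
                              min_seg_bp = 5e4,
                              osc_delta = 1) {
  cfg <- as.list(environment())
  if (cfg$chromothripsis_prevalence < 0 || cfg$chromothripsis_prevalence > 1) {
    abort("prevalence must be in [0, 1]")
  }
  if (cfg$chromothripsis_prevalence > 0 && cfg$ct_min_pairs <= 10) {
    abort("chromothripsis requires a pair-count support above 10 pairs")
  }
  structure(cfg, class = "simulation_config")
}

#' Scenario presets
#'
#' `mm_like` is the default myeloma-like cohort (total CN capped at 9,
#' modal diploid, 24% chromothripsis prevalence). `quiet` plants no complex
#' events. `solid_like` allows higher copy numbers, more arm-level change
#' and longer oscillation chains, for contrast tests.
#'
#' @param name One of `"mm_like"`, `"quiet"`, `"solid_like"`.
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
scenario_presets <- function(name = c("mm_like", "quiet", "solid_like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    mm_like = list(),
    quiet = list(
      chromothripsis_prevalence = 0, chromoplexy_rate = 0,
      templated_insertion_rate = 0, complex_nos_rate = 0,
      passenger_sv_rate = 2
    ),
    solid_like = list(
      chromothripsis_prevalence = 0.24,
      ct_npairs_meanlog = log(60), ct_npairs_sdlog = 0.5,
      max_total_cn = 30, arm_cna_rate = 4, passenger_sv_rate = 15,
      amplification_rate = 1.5, osc_delta = 2
    )
  )
  do.call(simulation_config, modifyList(base, list(...)))
}

# --- per-chromosome CN editing helpers --------------------------------------

# df: tibble(start, end, cn) sorted, non-overlapping, covering the
# chromosome.  Set CN on [s, e].
cn_set <- function(df, s, e, value) {
  keep <- df[df$end < s | df$start > e, ]
  left <- df[df$start < s & df$end >= s, ]
  if (nrow(left)) left$end <- s - 1
  right <- df[df$start <= e & df$end > e, ]
  if (nrow(right)) right$start <- e + 1
  out <- bind_rows(keep, left, right, tibble(start = s, end = e, cn = value))
  out <- out[out$start <= out$end, ]
  arrange(out, .data$start)
}

# Shift CN by delta on [s, e], clamped to [lo, hi].
cn_shift <- function(df, s, e, delta, lo = 0, hi = Inf) {
  parts <- list()
  for (i in seq_len(nrow(df))) {
    st <- df$start[i]; en <- df$end[i]; v <- df$cn[i]
    if (en < s || st > e) {
      parts[[length(parts) + 1]] <- tibble(start = st, end = en, cn = v)
      next
    }
    if (st < s) parts[[length(parts) + 1]] <- tibble(start = st, end = s - 1, cn = v)
    parts[[length(parts) + 1]] <- tibble(
      start = max(st, s), end = min(en, e),
      cn = min(max(v + delta, lo), hi)
    )
    if (en > e) parts[[length(parts) + 1]] <- tibble(start = e + 1, end = en, cn = v)
  }
  arrange(bind_rows(parts), .data$start)
}

random_strand_pair <- function(type) {
  switch(type,
    deletion = c("+", "-"),
    `tandem-duplication` = c("-", "+"),
    inversion = if (runif(1) < 0.5) c("+", "+") else c("-", "-"),
    translocation = sample(c("+", "-"), 2, replace = TRUE)
  )
}

# Breakend positions with consecutive gaps below the interconnection radius,
# so the planted component is guaranteed to be a single connected cluster.
clustered_positions <- function(n, start, min_gap = 2e4, max_gap = 9e5) {
  start + cumsum(c(0, round(runif(n - 1, min_gap, max_gap))))
}

#' Simulate a myeloma-like cohort
#'
#' Generates per-sample genome-wide CN segment profiles and SV catalogs on
#' GRCh37 autosomes, with planted complex events recorded in a truth table.
#' Chromothripsis is planted as `n > 10` interconnected breakpoint pairs
#' whose footprint CN oscillates between two adjacent integer states;
#' chromoplexy as a balanced translocation ring across 3+ chromosomes with
#' deletion bridges; templated insertions as translocations with focal
#' gains; complex-NOS as 3-9 interconnected pairs without oscillation.
#' Passenger SVs are scattered away from planted footprints.
#'
#' @param config A [simulation_config()] (or [scenario_presets()]).
#' @param assets Genome assets (GRCh37 by default); only included autosomes
#'   are simulated.
#' @return An object of class `simulated_cohort`: tibbles `segments`,
#'   `svs`, `truth` (`sample, chromothripsis`), `events` (planted events
#'   with class and member ids), plus the `config`.
#' @examples
#' cohort <- simulate_cohort(scenario_presets("quiet", n_samples = 2, seed = 7))
#' cohort$truth
#' @export
simulate_cohort <- function(config = simulation_config(),
                            assets = genome_assets()) {
  stopifnot(inherits(config, "simulation_config"))
  chroms <- included_chroms(assets)
  lens <- setNames(assets$chrom_lengths$length, assets$chrom_lengths$chrom)[chroms]
  hyperdiploid_set <- intersect(c("3", "5", "7", "9", "11", "15", "19", "21"), chroms)
  cen <- assets$arm_boundaries

  set.seed(config$seed)
  n <- config$n_samples
  n_pos <- round(n * config$chromothripsis_prevalence)
  pos_idx <- sample(n, n_pos)

  seg_out <- list(); sv_out <- list(); ev_out <- list(); truth <- list()

  for (si in seq_len(n)) {
    sid <- sprintf("S%03d", si)
    # baseline karyotype
    profile <- lapply(chroms, function(ch) {
      tibble(start = 1, end = unname(lens[[ch]]), cn = 2)
    })
    names(profile) <- chroms
    if (runif(1) < config$hyperdiploid_fraction) {
      tri <- sample(hyperdiploid_set, sample(4:7, 1))
      for (ch in tri) profile[[ch]]$cn <- 3
    }
    # arm-level CNAs
    n_arm <- rpois(1, config$arm_cna_rate)
    for (a in seq_len(n_arm)) {
      ch <- sample(chroms, 1)
      arm <- sample(c("p", "q"), 1)
      ci <- cen[cen$chrom == ch, ]
      rng <- if (arm == "p") c(1, ci$cen_start - 1) else c(ci$cen_end + 1, lens[[ch]])
      if (rng[2] - rng[1] < 2 * config$min_seg_bp) next
      delta <- sample(c(-2L, -1L, 1L, 2L), 1, prob = c(0.1, 0.4, 0.4, 0.1))
      profile[[ch]] <- cn_shift(profile[[ch]], rng[1], rng[2], delta,
        lo = 0, hi = config$max_total_cn
      )
    }
    # focal CNAs (sub-chromosomal gains/losses, incl. occasional deep ones)
    n_focal <- rpois(1, config$focal_cna_rate)
    for (a in seq_len(n_focal)) {
      ch <- sample(chroms, 1)
      w <- round(min(max(rlnorm(1, log(8e5), 1), 2 * config$min_seg_bp), 2e7))
      s0 <- round(runif(1, 1e6, lens[[ch]] - w - 1e6))
      delta <- sample(c(-2L, -1L, 1L, 2L), 1, prob = c(0.1, 0.4, 0.4, 0.1))
      profile[[ch]] <- cn_shift(profile[[ch]], s0, s0 + w - 1, delta,
        lo = 0, hi = config$max_total_cn
      )
    }
    # high-level focal amplifications (absent in myeloma-like genomes)
    n_amp <- rpois(1, config$amplification_rate)
    for (a in seq_len(n_amp)) {
      ch <- sample(chroms, 1)
      w <- round(runif(1, 4 * config$min_seg_bp, 2e6))
      s0 <- round(runif(1, 1e6, lens[[ch]] - w - 1e6))
      amp_cn <- sample(10:max(10, min(25, config$max_total_cn)), 1)
      profile[[ch]] <- cn_set(profile[[ch]], s0, s0 + w - 1,
        min(amp_cn, config$max_total_cn)
      )
    }

    svs <- list(); events <- list()
    sv_n <- 0
    used <- character(0) # chromosomes already hosting a planted event
    next_sv_id <- function() {
      sv_n <<- sv_n + 1
      sprintf("%s_sv%03d", sid, sv_n)
    }
    add_sv <- function(c1, p1, c2, p2, type) {
      st <- random_strand_pair(type)
      id <- next_sv_id()
      if (c1 == c2 && p1 > p2) { tmp <- p1; p1 <- p2; p2 <- tmp }
      svs[[length(svs) + 1]] <<- tibble(
        sample = sid, chrom1 = c1, pos1 = p1, strand1 = st[1],
        chrom2 = c2, pos2 = p2, strand2 = st[2], sv_type = type, id = id
      )
      id
    }
    pick_chroms <- function(k, min_len = 6e7) {
      avail <- setdiff(chroms, used)
      avail <- avail[lens[avail] >= min_len]
      ch <- sample(avail, k)
      used <<- c(used, ch)
      ch
    }

    # --- chromothripsis ----------------------------------------------------
    if (si %in% pos_idx) {
      n_pairs <- min(70, max(
        config$ct_min_pairs,
        round(rlnorm(1, config$ct_npairs_meanlog, config$ct_npairs_sdlog))
      ))
      ch <- pick_chroms(1, min_len = 9e7)
      n_tra <- rbinom(1, n_pairs, 0.1)
      partner <- if (n_tra > 0) pick_chroms(1) else NULL
      n_be <- 2 * (n_pairs - n_tra) + n_tra
      # tight breakpoint spacing (mean ~190 kb): shattered regions are dense
      # relative to the genome-wide inter-breakend distance
      max_gap <- min(3.5e5, (lens[[ch]] - 3e7) / n_be)
      be_rel <- clustered_positions(n_be, 0, max_gap = max_gap)
      fp_start <- round(runif(1, 5e6, lens[[ch]] - max(be_rel) - 6e6))
      be_pos <- fp_start + be_rel
      fp_end <- max(be_pos)
      # oscillating CN: alternate base <-> base+osc_delta across the footprint
      base <- profile[[ch]]$cn[
        profile[[ch]]$start <= fp_start & profile[[ch]]$end >= fp_start
      ][1]
      alt <- if (base + config$osc_delta <= config$max_total_cn) {
        base + config$osc_delta
      } else {
        max(base - config$osc_delta, 0)
      }
      pos0 <- fp_start
      seg_i <- 0
      while (pos0 < fp_end - 2 * config$min_seg_bp) {
        w <- round(runif(1, 1.2 * config$min_seg_bp, 6 * config$min_seg_bp))
        if (seg_i %% 2 == 1) {
          profile[[ch]] <- cn_set(profile[[ch]], pos0, min(pos0 + w - 1, fp_end), alt)
        }
        pos0 <- pos0 + w
        seg_i <- seg_i + 1
      }
      be_pool <- sample(be_pos)
      ids <- character(0)
      for (t in seq_len(n_tra)) {
        pp <- round(runif(1, 5e6, lens[[partner]] - 5e6))
        ids <- c(ids, add_sv(ch, be_pool[1], partner, pp, "translocation"))
        be_pool <- be_pool[-1]
      }
      while (length(be_pool) >= 2) {
        ty <- sample(c("deletion", "tandem-duplication", "inversion"), 1)
        ids <- c(ids, add_sv(ch, be_pool[1], ch, be_pool[2], ty))
        be_pool <- be_pool[-(1:2)]
      }
      events[[length(events) + 1]] <- tibble(
        sample = sid, event_id = paste0(sid, "_chromothripsis"),
        class = "chromothripsis",
        chroms = paste(sort(unique(c(ch, partner))), collapse = ","),
        n_pairs = n_pairs, member_ids = paste(sort(ids), collapse = ",")
      )
    }

    # --- chromoplexy -------------------------------------------------------
    if (runif(1) < config$chromoplexy_rate) {
      k <- sample(3:4, 1)
      chs <- pick_chroms(k)
      pos <- vapply(chs, function(c0) round(runif(1, 5e6, lens[[c0]] - 5e6)), 0)
      bridge <- round(runif(k, 1e5, 8e5))
      ids <- character(0)
      for (i in seq_len(k)) {
        j <- if (i == k) 1 else i + 1
        ids <- c(ids, add_sv(chs[i], pos[i] + bridge[i], chs[j], pos[j], "translocation"))
        profile[[chs[i]]] <- cn_shift(
          profile[[chs[i]]], pos[i], pos[i] + bridge[i] - 1, -1L,
          lo = 0, hi = config$max_total_cn
        )
      }
      events[[length(events) + 1]] <- tibble(
        sample = sid, event_id = paste0(sid, "_chromoplexy"),
        class = "chromoplexy", chroms = paste(sort(chs), collapse = ","),
        n_pairs = k, member_ids = paste(sort(ids), collapse = ",")
      )
    }

    # --- templated insertion ----------------------------------------------
    if (runif(1) < config$templated_insertion_rate) {
      complex_ti <- runif(1) < 0.3
      k <- if (complex_ti) 3 else 2
      chs <- pick_chroms(k)
      pos <- vapply(chs, function(c0) round(runif(1, 8e6, lens[[c0]] - 8e6)), 0)
      ids <- character(0)
      for (i in seq_len(k - 1)) {
        ids <- c(ids, add_sv(chs[i], pos[i], chs[i + 1], pos[i + 1], "translocation"))
      }
      for (i in seq_len(k)) {
        g <- round(runif(1, 2e5, 3e6))
        profile[[chs[i]]] <- cn_shift(
          profile[[chs[i]]], pos[i] - round(g / 2), pos[i] + round(g / 2), 1L,
          lo = 0, hi = config$max_total_cn
        )
      }
      events[[length(events) + 1]] <- tibble(
        sample = sid,
        event_id = paste0(sid, "_templated_insertion"),
        class = if (complex_ti) "templated_insertion_complex" else "templated_insertion_simple",
        chroms = paste(sort(chs), collapse = ","),
        n_pairs = k - 1, member_ids = paste(sort(ids), collapse = ",")
      )
    }

    # --- complex, not otherwise specified ---------------------------------
    if (runif(1) < config$complex_nos_rate) {
      n_pairs <- sample(3:9, 1)
      ch <- pick_chroms(1)
      fp_start <- round(runif(1, 5e6, lens[[ch]] - 2 * n_pairs * 1e6 - 5e6))
      be_pos <- clustered_positions(2 * n_pairs, fp_start)
      be_pool <- sample(be_pos)
      ids <- character(0)
      while (length(be_pool) >= 2) {
        ty <- sample(c("deletion", "tandem-duplication", "inversion"), 1)
        ids <- c(ids, add_sv(ch, be_pool[1], ch, be_pool[2], ty))
        be_pool <- be_pool[-(1:2)]
      }
      events[[length(events) + 1]] <- tibble(
        sample = sid, event_id = paste0(sid, "_complex_nos"),
        class = "complex_nos", chroms = ch,
        n_pairs = n_pairs, member_ids = paste(sort(ids), collapse = ",")
      )
    }

    # --- passengers --------------------------------------------------------
    planted_be <- if (length(svs) > 0) {
      b <- bind_rows(svs)
      bind_rows(
        tibble(chrom = b$chrom1, pos = b$pos1),
        tibble(chrom = b$chrom2, pos = b$pos2)
      )
    } else {
      tibble(chrom = character(), pos = double())
    }
    far_from_events <- function(ch, p, min_dist = 2e6) {
      hit <- planted_be$chrom == ch & abs(planted_be$pos - p) < min_dist
      !any(hit)
    }
    n_pass <- rpois(1, config$passenger_sv_rate)
    for (pv in seq_len(n_pass)) {
      for (attempt in 1:20) {
        ty <- sample(SV_TYPES, 1, prob = c(0.35, 0.25, 0.2, 0.2))
        if (ty == "translocation") {
          c1 <- sample(chroms, 1); c2 <- sample(setdiff(chroms, c1), 1)
          p1 <- round(runif(1, 2e6, lens[[c1]] - 2e6))
          p2 <- round(runif(1, 2e6, lens[[c2]] - 2e6))
          if (far_from_events(c1, p1) && far_from_events(c2, p2)) {
            add_sv(c1, p1, c2, p2, ty)
            planted_be <- bind_rows(planted_be,
              tibble(chrom = c(c1, c2), pos = c(p1, p2)))
            break
          }
        } else {
          c1 <- sample(chroms, 1)
          span <- round(min(max(rlnorm(1, log(1e6), 1), 2e3), 3e7))
          p1 <- round(runif(1, 2e6, lens[[c1]] - span - 2e6))
          p2 <- p1 + span
          if (far_from_events(c1, p1) && far_from_events(c1, p2)) {
            add_sv(c1, p1, c1, p2, ty)
            planted_be <- bind_rows(planted_be,
              tibble(chrom = c(c1, c1), pos = c(p1, p2)))
            break
          }
        }
      }
    }

    seg_sample <- purrr::imap(profile, function(df, ch) {
      tibble(
        sample = sid, chrom = ch, start = df$start, end = df$end,
        total_cn = df$cn, minor_cn = df$cn %/% 2
      )
    }) |> bind_rows()
    seg_out[[si]] <- merge_equal_neighbors(seg_sample)
    sv_out[[si]] <- if (length(svs) > 0) bind_rows(svs) else NULL
    ev_out[[si]] <- if (length(events) > 0) bind_rows(events) else NULL
    truth[[si]] <- tibble(sample = sid, chromothripsis = as.integer(si %in% pos_idx))
  }

  empty_sv <- tibble(
    sample = character(), chrom1 = character(), pos1 = double(),
    strand1 = character(), chrom2 = character(), pos2 = double(),
    strand2 = character(), sv_type = character(), id = character()
  )
  structure(
    list(
      segments = bind_rows(seg_out),
      svs = bind_rows(c(list(empty_sv), sv_out)),
      truth = bind_rows(truth),
      events = bind_rows(ev_out) %||% tibble(),
      config = config
    ),
    class = "simulated_cohort"
  )
}

#' @exportS3Method base::print
print.simulated_cohort <- function(x, ...) {
  cat(
    "<simulated_cohort> ", nrow(x$truth), " samples, ",
    nrow(x$svs), " SVs, ", sum(x$truth$chromothripsis),
    " chromothripsis-positive\n",
    sep = ""
  )
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `segments.tsv` (pooled, with a `sample` column), one BEDPE per
#' sample (`sv_<sample>.bedpe`), `truth.tsv` and `events.tsv`. Files
#' round-trip exactly through [read_segments()] / [read_sv_bedpe()].
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(sprintf("directory %s is not empty (use force = TRUE)", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments(cohort$segments, file.path(dir, "segments.tsv"))
  for (s in unique(cohort$truth$sample)) {
    sv_s <- filter(cohort$svs, .data$sample == s)
    write_sv_bedpe(sv_s, file.path(dir, sprintf("sv_%s.bedpe", s)))
  }
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  if (nrow(cohort$events) > 0) {
    readr::write_tsv(cohort$events, file.path(dir, "events.tsv"))
  }
  invisible(dir)
}
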