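test_that("the interconnection graph links breakends within the radius", {
  two_close <- make_sv(1, c(10e6, 10.1e6), 1, c(12e6, 12.2e6), "deletion")
  g <- build_event_graph(two_close)
  expect_equal(length(unique(g$component)), 1)

  two_far <- make_sv(c(1, 4), c(10e6, 10e6), c(2, 5), c(10e6, 10e6),
    "translocation"
  )
  g2 <- build_event_graph(two_far)
  expect_equal(length(unique(g2$component)), 2)

  ring <- make_sv(
    chrom1 = c(1, 2, 3), pos1 = c(10e6, 20e6, 30e6),
    chrom2 = c(2, 3, 1), pos2 = c(20.5e6, 30.5e6, 10.5e6),
    type = "translocation"
  )
  g3 <- build_event_graph(ring)
  expect_equal(length(unique(g3$component)), 1)
  expect_equal(nrow(g3), 3)
})

test_that("every pair belongs to exactly one component", {
  set.seed(51)
  sv <- bind_rows(
    cluster_pairs(5, start = 30e6),
    cluster_pairs(4, chrom = "7", start = 60e6, prefix = "q"),
    make_sv(9, 10e6, 10, 50e6, "translocation", id = "lone")
  )
  g <- build_event_graph(sv)
  expect_false(anyNA(g$component))
  expect_equal(nrow(g), nrow(sv))
})

test_that("footprint oscillation detection follows the run definition", {
  assets <- genome_assets()
  len1 <- assets$chrom_lengths$length[assets$chrom_lengths$chrom == "1"]
  osc <- make_profile(
    c(2, 1, 2, 1, 2, 1, 2),
    round(seq(49e6, 58e6, length.out = 8)),
    chrom = "1"
  )
  prof <- bind_rows(
    make_profile(2, c(1, 49e6 - 1), chrom = "1"),
    osc,
    make_profile(2, c(58e6 + 1, len1), chrom = "1")
  ) |> chromosig:::merge_equal_neighbors()
  comp <- cluster_pairs(11, start = 50e6, gap = 3e5)
  expect_true(oscillating_cn_in_footprint(prof, comp)$oscillating)

  stair <- bind_rows(
    make_profile(c(2, 3, 4, 5), round(seq(45e6, 60e6, length.out = 5)), chrom = "1"),
    make_profile(2, c(1, 45e6 - 1), chrom = "1"),
    make_profile(2, c(60e6 + 1, len1), chrom = "1")
  ) |> chromosig:::merge_equal_neighbors()
  expect_false(oscillating_cn_in_footprint(stair, comp)$oscillating)

  flat <- flat_genome(chroms = "1")
  expect_false(oscillating_cn_in_footprint(flat, comp)$oscillating)
})

test_that("chromothripsis requires strictly more than 10 oscillating pairs", {
  assets <- genome_assets()
  len1 <- assets$chrom_lengths$length[assets$chrom_lengths$chrom == "1"]
  # oscillating CN across the region the pairs occupy
  k_alt <- 12
  bounds <- round(seq(49e6, 64e6, length.out = 2 * k_alt + 1))
  osc <- make_profile(rep(c(2, 3), k_alt)[seq_len(2 * k_alt)], bounds, chrom = "1")
  prof <- bind_rows(
    make_profile(2, c(1, bounds[1] - 1), chrom = "1"),
    osc,
    make_profile(2, c(max(bounds) + 1, len1), chrom = "1")
  ) |> chromosig:::merge_equal_neighbors()
  prof <- bind_rows(prof, flat_genome(chroms = as.character(2:22)))

  sv11 <- cluster_pairs(11, start = 50e6, gap = 5e5)
  calls11 <- classify_complex_events(sv11, prof)
  expect_equal(calls11$class, "chromothripsis")
  expect_equal(calls11$n_pairs, 11)

  sv10 <- cluster_pairs(10, start = 50e6, gap = 5e5)
  calls10 <- classify_complex_events(sv10, prof)
  expect_equal(calls10$class, "complex_nos") # exactly 10 is not enough
  expect_true(calls10$oscillating_cn)
})

test_that("chromoplexy needs >2 chromosomes and deletion bridges", {
  prof <- flat_genome()
  for (i in 1:3) { # deletion bridge at each ring junction
    ch <- as.character(i)
    prof <- bind_rows(
      prof[prof$chrom != ch | prof$sample != "S1", ],
      {
        sub <- prof[prof$chrom == ch, ]
        len <- sub$end[1]
        make_profile(c(2, 1, 2), c(1, 10e6, 10.4e6 + 1, len), chrom = ch)
      }
    )
  }
  ring <- make_sv(
    chrom1 = c("1", "2", "3"), pos1 = c(10.4e6, 10.4e6, 10.4e6),
    chrom2 = c("2", "3", "1"), pos2 = c(10e6, 10e6, 10e6),
    type = "translocation"
  )
  calls <- classify_complex_events(ring, prof)
  expect_equal(calls$class, "chromoplexy")
  expect_true(calls$cn_loss_associated)
  # same ring without any CN loss falls through to complex-NOS
  calls_flat <- classify_complex_events(ring, flat_genome())
  expect_equal(calls_flat$class, "complex_nos")
})

test_that("translocations with focal gains are templated insertions", {
  prof <- flat_genome()
  gain <- function(prof, ch, center, width = 1e6) {
    sub <- prof[prof$chrom == ch, ]
    len <- sub$end[nrow(sub)]
    bind_rows(
      prof[prof$chrom != ch, ],
      make_profile(c(2, 3, 2),
        c(1, center - width / 2, center + width / 2 + 1, len),
        chrom = ch
      )
    )
  }
  prof2 <- gain(gain(flat_genome(), "1", 30e6), "2", 40e6)
  single_tra <- make_sv("1", 30e6, "2", 40e6, "translocation")
  calls <- classify_complex_events(single_tra, prof2)
  expect_equal(calls$class, "templated_insertion_simple")
  expect_true(calls$focal_gain_associated)

  prof3 <- gain(prof2, "3", 50e6)
  chain <- make_sv(
    chrom1 = c("1", "2"), pos1 = c(30e6, 40.2e6),
    chrom2 = c("2", "3"), pos2 = c(40e6, 50e6),
    type = "translocation"
  )
  calls3 <- classify_complex_events(chain, prof3)
  expect_equal(calls3$class, "templated_insertion_complex")

  # a lone translocation without any gain is a single event
  lone <- classify_complex_events(single_tra, flat_genome())
  expect_equal(lone$class, "single")
})

test_that("classification is deterministic and invariant to pair order", {
  set.seed(61)
  sv <- bind_rows(
    cluster_pairs(4, start = 40e6),
    make_sv("5", 30e6, "6", 40e6, "translocation", id = "t1")
  )
  prof <- flat_genome()
  a <- classify_complex_events(sv, prof)
  b <- classify_complex_events(sv[sample(nrow(sv)), ], prof)
  expect_equal(a, b)
})

test_that("planted events are recovered class-for-class at zero noise", {
  cfg <- scenario_presets("mm_like",
    n_samples = 60, seed = 17,
    arm_cna_rate = 0, focal_cna_rate = 0, passenger_sv_rate = 0,
    chromoplexy_rate = 0.3, templated_insertion_rate = 0.3,
    complex_nos_rate = 0.3
  )
  co <- simulate_cohort(cfg)
  filt <- apply_filters(co$segments, co$svs, genome_assets())
  calls <- classify_complex_events(filt$svs, filt$segments)
  expect_gt(nrow(co$events), 40) # enough planted events to be meaningful
  # match each planted event to the call containing its first member pair
  first_member <- vapply(
    strsplit(co$events$member_ids, ","), `[[`, character(1), 1
  )
  for (i in seq_len(nrow(co$events))) {
    hit <- calls[calls$sample == co$events$sample[i] &
      grepl(first_member[i], calls$member_ids, fixed = TRUE), ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$class, co$events$class[i],
      label = sprintf("event %s", co$events$event_id[i])
    )
  }
  # per-sample labels match the truth table exactly
  lab <- sample_chromothripsis_labels(calls, samples = co$truth$sample)
  expect_equal(lab$chromothripsis, co$truth$chromothripsis)
})
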