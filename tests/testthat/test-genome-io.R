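test_that("segment reading merges equal-CN neighbors and sorts per sample", {
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(
    sample = c("A", "A", "A", "B", "B"),
    chrom = c("1", "1", "1", "1", "1"),
    start = c(1, 1e6 + 1, 2e6 + 1, 5e6 + 1, 1),
    end = c(1e6, 2e6, 3e6, 6e6, 5e6),
    total_cn = c(2, 2, 2, 3, 2)
  ), tsv)
  seg <- read_segments(tsv)
  a <- seg[seg$sample == "A", ]
  expect_equal(nrow(a), 1) # three contiguous diploid rows merge to one
  expect_equal(c(a$start, a$end, a$total_cn), c(1, 3e6, 2))
  b <- seg[seg$sample == "B", ]
  expect_equal(b$start, c(1, 5e6 + 1)) # interleaved rows come back sorted
})

test_that("malformed segment rows are rejected with line numbers", {
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(
    sample = "A", chrom = "1", start = 2e6, end = 1e6, total_cn = 2
  ), tsv)
  expect_error(read_segments(tsv), "line")
  tsv2 <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(sample = "A", chrom = "1", start = 1, end = 10), tsv2)
  expect_error(read_segments(tsv2), "total_cn")
})

test_that("BEDPE reading converts coordinates and enforces pair invariants", {
  bedpe <- tempfile(fileext = ".bedpe")
  readr::write_tsv(tibble(
    chrom1 = c("chr1", "chr2"), start1 = c(1000, 5000), end1 = c(1001, 5001),
    chrom2 = c("chr1", "chr5"), start2 = c(5000, 100), end2 = c(5001, 101),
    name = c("sv1", "sv2"), score = ".", strand1 = c("+", "+"),
    strand2 = c("-", "-"), type = c("DEL", "TRA")
  ), bedpe)
  sv <- read_sv_bedpe(bedpe, sample = "S1")
  expect_equal(sv$pos1[1], 1001) # 0-based half-open -> 1-based
  expect_equal(sv$sv_type, c("deletion", "translocation"))
  expect_true(all(sv$pos1[sv$chrom1 == sv$chrom2] <
    sv$pos2[sv$chrom1 == sv$chrom2]))
  # inter-chromosomal rows are translocations regardless of the type token
  expect_equal(sv$sv_type[sv$chrom1 != sv$chrom2], "translocation")
})

test_that("empty BEDPE yields an empty catalog without error", {
  f <- tempfile(fileext = ".bedpe")
  file.create(f)
  expect_equal(nrow(read_sv_bedpe(f)), 0)
})

test_that("unknown sv type and unknown chromosome are format errors", {
  bedpe <- tempfile(fileext = ".bedpe")
  readr::write_tsv(tibble(
    chrom1 = "1", start1 = 1000, end1 = 1001, chrom2 = "1",
    start2 = 5000, end2 = 5001, name = "sv1", score = ".",
    strand1 = "+", strand2 = "-", type = "WEIRD"
  ), bedpe)
  expect_error(read_sv_bedpe(bedpe), "unknown sv_type")
  bedpe2 <- tempfile(fileext = ".bedpe")
  readr::write_tsv(tibble(
    chrom1 = "99", start1 = 1000, end1 = 1001, chrom2 = "99",
    start2 = 5000, end2 = 5001, name = "sv1", score = ".",
    strand1 = "+", strand2 = "-", type = "DEL"
  ), bedpe2)
  expect_error(read_sv_bedpe(bedpe2, assets = toy_assets()), "not in assets")
})

test_that("BEDPE round-trip is coordinate-exact", {
  assets <- toy_assets()
  sv <- tibble(
    sample = "S1", chrom1 = c("1", "2"), pos1 = c(1234567, 99), strand1 = c("+", "-"),
    chrom2 = c("1", "1"), pos2 = c(2234567, 1e6), strand2 = c("-", "+"),
    sv_type = c("deletion", "translocation"), id = c("a", "b")
  )
  f <- tempfile(fileext = ".bedpe")
  write_sv_bedpe(sv, f)
  back <- read_sv_bedpe(f)
  expect_equal(back[names(sv)], sv)
})

test_that("sub-50kb CN changes are absorbed into the closer-CN flank", {
  assets <- toy_assets()
  seg <- make_profile(c(2, 3, 2), c(1, 10e6 + 1, 10e6 + 40001, 30e6))
  out <- apply_filters(seg, NULL, assets)$segments
  expect_equal(nrow(out), 1)
  expect_equal(out$total_cn, 2)
  expect_equal(c(out$start, out$end), c(1, 30e6))
})

test_that("short-segment merge prefers the closer CN, ties to the left", {
  assets <- toy_assets()
  # CN 4 short segment between 3 (left) and 2 (right): closer to 3
  seg <- make_profile(c(3, 4, 2), c(1, 10e6 + 1, 10e6 + 40001, 30e6))
  out <- apply_filters(seg, NULL, assets)$segments
  expect_equal(out$total_cn, c(3, 2))
  expect_equal(out$end[1], 10e6 + 40000)
  # equidistant (3 between 2 and 4): merged left
  seg2 <- make_profile(c(2, 3, 4), c(1, 10e6 + 1, 10e6 + 40001, 30e6))
  out2 <- apply_filters(seg2, NULL, assets)$segments
  expect_equal(out2$total_cn, c(2, 4))
  expect_equal(out2$end[1], 10e6 + 40000)
})

test_that("Ig-mask junctions are dissolved keeping the longer flank's CN", {
  assets <- toy_assets() # mask on chrom 1: (20e6, 21e6]
  seg <- make_profile(c(2, 3), c(1, 20.5e6 + 1, 30e6)) # junction at 20.5e6
  out <- apply_filters(seg, NULL, assets)$segments
  expect_equal(nrow(out), 1)
  expect_equal(out$total_cn, 2) # left flank is longer
})

test_that("SV breakends in the mask or on excluded chromosomes are dropped", {
  assets <- toy_assets()
  sv <- tibble(
    sample = "S1",
    chrom1 = c("1", "1", "X"), pos1 = c(20.2e6, 5e6, 1e6), strand1 = "+",
    chrom2 = c("1", "1", "X"), pos2 = c(22e6, 6e6, 2e6), strand2 = "-",
    sv_type = "deletion", id = c("in_mask", "keep", "on_x")
  )
  out <- apply_filters(NULL, sv, assets)$svs
  expect_equal(out$id, "keep")
})

test_that("profiles restricted to excluded chromosomes come back empty", {
  assets <- toy_assets()
  seg <- make_profile(c(2, 3), c(1, 5e6 + 1, 10e6), chrom = "X")
  out <- apply_filters(seg, NULL, assets)$segments
  expect_equal(nrow(out), 0)
})

test_that("filtering is idempotent and never grows genome coverage", {
  assets <- toy_assets()
  set.seed(421)
  for (r in 1:20) {
    seg <- random_profile(sprintf("S%d", r), assets)
    once <- apply_filters(seg, NULL, assets)$segments
    twice <- apply_filters(once, NULL, assets)$segments
    expect_equal(twice, once)
    cover <- function(x) sum(x$end - x$start + 1)
    expect_lte(cover(once), cover(seg))
    # no overlaps within a chromosome
    by_chrom <- split(once, paste(once$sample, once$chrom))
    for (b in by_chrom) {
      if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    }
  }
})

test_that("count matrices round-trip losslessly and reject bad input", {
  m <- tibble(
    sample = c("A", "B", "C"),
    x1 = c(1, 0, 5), x2 = c(2.5, 1, 0), x3 = 1, x4 = 0, x5 = c(9, 9, 9)
  )
  f <- tempfile(fileext = ".tsv")
  write_matrix(m, f)
  expect_equal(read_matrix(f), m)
  expect_error(write_matrix(dplyr::mutate(m, x1 = NaN), f), "finite")
  expect_error(
    write_matrix(dplyr::mutate(m, sample = c("A", "A", "B")), f),
    "duplicated"
  )
  # empty matrix: header-only file, read back as empty
  e <- m[0, ]
  write_matrix(e, f)
  expect_equal(nrow(read_matrix(f)), 0)
})
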