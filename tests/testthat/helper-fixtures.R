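# Shared fixtures: a small toy genome, compact profile builders, and
# independent brute-force oracles for the six CN features.

library(dplyr)
library(tibble)

toy_assets <- function() {
  genome_assets(
    chrom_sizes = data.frame(
      chrom = c("1", "2", "X"), length = c(30e6, 25e6, 10e6)
    ),
    centromeres = data.frame(
      chrom = c("1", "2", "X"),
      cen_start = c(12e6, 10e6, 4e6), cen_end = c(13e6, 11e6, 5e6)
    ),
    ig_mask = data.frame(chrom = "1", start = 20e6 + 1, end = 21e6, name = "IG"),
    excluded_chroms = "X"
  )
}

# Build a single-chromosome profile from segment boundaries and CN values:
# breaks has length(cns) + 1; segments are [breaks[i], breaks[i+1] - 1]
# except the last, which ends at breaks[k + 1].
make_profile <- function(cns, breaks, sample = "S1", chrom = "1") {
  k <- length(cns)
  stopifnot(length(breaks) == k + 1)
  tibble(
    sample = sample, chrom = chrom,
    start = breaks[-(k + 1)],
    end = c(breaks[-c(1, k + 1)] - 1, breaks[k + 1]),
    total_cn = cns
  )
}

# Evenly sized segments covering [1, len] with the given CN sequence.
even_profile <- function(cns, len = 30e6, sample = "S1", chrom = "1") {
  k <- length(cns)
  b <- round(seq(1, len + 1, length.out = k + 1))
  make_profile(cns, c(b[-(k + 1)], len), sample = sample, chrom = chrom)
}

# Random valid profile on the toy genome: <= max_segs segments total,
# integer CN 0..6, no equal-CN neighbors, 100 kb grid coordinates.
random_profile <- function(sample, assets, max_segs = 20) {
  chroms <- included_chroms(assets)
  n_chrom <- sample(seq_along(chroms), 1)
  use <- sample(chroms, n_chrom)
  lens <- setNames(assets$chrom_lengths$length, assets$chrom_lengths$chrom)
  out <- list()
  remaining <- max_segs
  for (ch in use) {
    k <- sample(seq_len(min(6, remaining)), 1)
    remaining <- remaining - k
    len <- lens[[ch]]
    cuts <- if (k > 1) {
      sort(sample(seq(1e5, len - 1e5, by = 1e5), k - 1))
    } else {
      numeric(0)
    }
    breaks <- c(1, cuts + 1, len)
    cns <- integer(k)
    cns[1] <- sample(0:6, 1)
    for (i in seq_len(k - 1)) {
      cns[i + 1] <- sample(setdiff(0:6, cns[i]), 1)
    }
    out[[ch]] <- make_profile(cns, breaks, sample = sample, chrom = ch)
    if (remaining <= 0) break
  }
  bind_rows(out)
}

make_sv <- function(chrom1, pos1, chrom2, pos2, type, sample = "S1",
                    id = NULL) {
  n <- length(pos1)
  tibble(
    sample = sample, chrom1 = as.character(chrom1), pos1 = pos1, strand1 = "+",
    chrom2 = as.character(chrom2), pos2 = pos2, strand2 = "-",
    sv_type = type, id = id %||% sprintf("sv%03d", seq_len(n))
  )
}

`%||%` <- rlang::`%||%`

flat_genome <- function(sample = "S1", chroms = as.character(1:22), cn = 2) {
  assets <- genome_assets()
  lens <- setNames(assets$chrom_lengths$length, assets$chrom_lengths$chrom)
  bind_rows(lapply(chroms, function(ch) {
    tibble(sample = sample, chrom = ch, start = 1, end = lens[[ch]], total_cn = cn)
  }))
}

# n interconnected intra-chromosomal pairs in a compact region.
cluster_pairs <- function(n, chrom = "1", start = 50e6, gap = 4e5,
                          type = "deletion", sample = "S1", prefix = "p") {
  pos <- start + gap * seq_len(2 * n)
  make_sv(chrom, pos[seq_len(n) * 2 - 1], chrom, pos[seq_len(n) * 2],
    type,
    sample = sample, id = sprintf("%s%02d", prefix, seq_len(n))
  )
}

# ---- independent brute-force oracles ---------------------------------------
# Straight loops over the definitions; no shared code with the extractors.

oracle_junctions <- function(seg) {
  seg <- seg[order(seg$sample, seg$chrom, seg$start), ]
  out <- list()
  for (s in unique(seg$sample)) {
    for (ch in unique(seg$chrom[seg$sample == s])) {
      sub <- seg[seg$sample == s & seg$chrom == ch, ]
      if (nrow(sub) >= 2) {
        for (i in 2:nrow(sub)) {
          out[[length(out) + 1]] <- data.frame(
            sample = s, chrom = ch, pos = sub$end[i - 1]
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    data.frame(sample = character(), chrom = character(), pos = double())
  } else {
    do.call(rbind, out)
  }
}

oracle_bkpt_10mb <- function(seg, assets, window_bp = 1e7) {
  jn <- oracle_junctions(seg)
  lens <- setNames(assets$chrom_lengths$length, assets$chrom_lengths$chrom)
  vals <- c()
  for (s in unique(seg$sample)) {
    for (ch in included_chroms(assets)) {
      nw <- ceiling(lens[[ch]] / window_bp)
      for (w in seq_len(nw)) {
        lo <- (w - 1) * window_bp # junction at the boundary goes left
        hi <- w * window_bp
        vals <- c(vals, sum(
          jn$sample == s & jn$chrom == ch & jn$pos > lo & jn$pos <= hi
        ))
      }
    }
  }
  vals
}

oracle_bkpt_arm <- function(seg, assets) {
  jn <- oracle_junctions(seg)
  cen <- assets$arm_boundaries
  vals <- c()
  for (s in unique(seg$sample)) {
    for (ch in included_chroms(assets)) {
      ci <- cen[cen$chrom == ch, ]
      sel <- jn$sample == s & jn$chrom == ch
      vals <- c(
        vals,
        sum(sel & jn$pos < ci$cen_start),
        sum(sel & jn$pos > ci$cen_end)
      )
    }
  }
  vals
}

oracle_cn_jumps <- function(seg) {
  seg <- seg[order(seg$sample, seg$chrom, seg$start), ]
  vals <- c()
  for (s in unique(seg$sample)) {
    for (ch in unique(seg$chrom[seg$sample == s])) {
      cn <- seg$total_cn[seg$sample == s & seg$chrom == ch]
      if (length(cn) >= 2) {
        for (i in 2:length(cn)) vals <- c(vals, abs(cn[i] - cn[i - 1]))
      }
    }
  }
  vals
}

# Check that a CN vector alternates between exactly two distinct values.
is_two_state_alternation <- function(cn) {
  if (length(cn) < 2) return(FALSE)
  if (cn[1] == cn[2]) return(FALSE)
  all(cn == rep(cn[1:2], length.out = length(cn)))
}

oracle_osc_len <- function(seg, min_len = 3) {
  seg <- seg[order(seg$sample, seg$chrom, seg$start), ]
  vals <- c()
  for (s in unique(seg$sample)) {
    for (ch in unique(seg$chrom[seg$sample == s])) {
      cn <- seg$total_cn[seg$sample == s & seg$chrom == ch]
      found <- c()
      i <- 1
      while (i <= length(cn) - 1) {
        # longest alternating stretch starting at i
        j <- i + 1
        while (j + 1 <= length(cn) &&
          is_two_state_alternation(cn[i:(j + 1)])) {
          j <- j + 1
        }
        if (is_two_state_alternation(cn[i:j]) && j - i + 1 >= min_len) {
          found <- c(found, j - i + 1)
          i <- j + 1
        } else {
          i <- i + 1
        }
      }
      vals <- c(vals, if (length(found) == 0) 0 else found)
    }
  }
  vals
}

# Multiset equality helper.
expect_same_multiset <- function(a, b) {
  expect_equal(sort(as.numeric(a)), sort(as.numeric(b)))
}

# Best-permutation cosine matching of recovered signatures to truth.
match_cosines <- function(fit_sig, true_sig) {
  k <- nrow(true_sig)
  perms <- combinat_perms(seq_len(nrow(fit_sig)), k)
  best <- rep(-Inf, k)
  for (p in perms) {
    cs <- vapply(seq_len(k), function(i) {
      cosine_similarity(fit_sig[p[i], ], true_sig[i, ])
    }, numeric(1))
    if (mean(cs) > mean(best)) best <- cs
  }
  best
}

# All k-permutations of v (tiny k only).
combinat_perms <- function(v, k) {
  if (k == 1) return(lapply(v, function(x) x))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i], k - 1)) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# Three well-separated simplex signatures over K categories.
planted_signatures <- function(K = 28, seed = 99) {
  set.seed(seed)
  sig <- matrix(0, 3, K)
  thirds <- split(seq_len(K), cut(seq_len(K), 3, labels = FALSE))
  for (i in 1:3) sig[i, thirds[[i]]] <- rgamma(length(thirds[[i]]), 2)
  sig <- sig / rowSums(sig)
  colnames(sig) <- sprintf("cat%02d", seq_len(K))
  sig
}
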