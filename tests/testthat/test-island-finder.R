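track1 <- function(v, bin = 10L) signal_track(list(c1 = v), bin)

test_that("island calling follows the worked gap/score example", {
  # bins: 0 1 1 0 0 1 1 1 0; threshold 1, gap 1, min length 2, min score 2
  tr <- track1(c(0, 1, 1, 0, 0, 1, 1, 1, 0))
  p <- island_params(10L, 1, 1L, 2, 2L)
  isl <- call_islands(tr, p)
  # the run of two ineligible bins is not bridged: two islands
  expect_equal(nrow(isl), 2L)
  expect_equal(isl$start, c(10L, 50L))
  expect_equal(isl$end, c(30L, 80L))
  expect_equal(isl$score, c(2, 3))

  # with gap 2 the runs merge into one island spanning both
  isl2 <- call_islands(tr, island_params(10L, 1, 2L, 2, 2L))
  expect_equal(nrow(isl2), 1L)
  expect_equal(c(isl2$start, isl2$end), c(10L, 80L))
  expect_equal(isl2$score, 5)

  expect_equal(nrow(call_islands(track1(rep(0, 30)), p)), 0L)

  # 20 bins exactly at threshold: score 20, forced by the definitions
  isl3 <- call_islands(track1(rep(1, 20)), island_params(10L, 1, 0L, 16, 15L))
  expect_equal(isl3$score, 20)
  expect_equal(isl3$n_eligible, 20L)
})

test_that("bin-size mismatch and bad parameters are rejected", {
  expect_error(call_islands(track1(1:5, bin = 10L),
                            island_params(25L, 1, 1L, 1, 1L)),
               "does not match")
  expect_error(island_params(0, 1, 1, 1, 1))
  expect_error(island_params(10, -1, 1, 1, 1))
  expect_error(island_params(10, 1, -1, 1, 1))
})

test_that("islands match the brute-force span enumerator on random tracks", {
  set.seed(77)
  for (rep in 1:300) {
    n <- sample(10:60, 1)
    v <- round(runif(n, 0, 2), 2)
    v[runif(n) < 0.15] <- NA
    wv <- runif(1, 0.3, 1.5)
    gap <- sample(0:4, 1)
    score <- runif(1, 0, 5)
    len <- sample(1:8, 1)
    got <- call_islands(track1(v), island_params(10L, wv, gap, score, len))
    want <- oracle_islands(v, wv, gap, score, len)
    expect_equal(nrow(got), length(want),
                 info = sprintf("rep %d", rep))
    if (length(want)) {
      wm <- do.call(rbind, want)
      expect_equal(got$start, unname((wm[, "start_bin"] - 1L) * 10L))
      expect_equal(got$end, unname(wm[, "end_bin"] * 10L))
      expect_equal(got$score, unname(wm[, "score"]))
    }
  }
})

test_that("raising the threshold never increases the eligible-bin count", {
  set.seed(78)
  v <- runif(150, 0, 2)
  tr <- track1(v)
  counts <- vapply(c(0.2, 0.5, 0.8, 1.1, 1.4), function(wv) {
    isl <- call_islands(tr, island_params(10L, wv, 2L, 0, 1L))
    sum(isl$n_eligible)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("called islands are sorted and non-overlapping", {
  set.seed(79)
  v <- runif(400, 0, 1.5)
  isl <- call_islands(track1(v), island_params(10L, 0.9, 1L, 2, 2L))
  if (nrow(isl) > 1L) {
    expect_true(all(diff(isl$start) > 0))
    expect_true(all(isl$start[-1L] >= isl$end[-nrow(isl)]))
  }
})

test_that("planted skewed cores are recovered with matching signs", {
  spec <- simulation_spec(chrom_lengths = c(s1 = 150000L), n_origins = 30L,
                          n_g4 = 0L, n_ig4 = 0L, n_skew_cores = 6L,
                          n_ards = 0L, seed = 21L)
  sim <- build_diploid_genome(spec)
  cores <- sim$truth$skew_cores
  gc_cores <- cores[cores$pair == "GC", ]
  isl <- call_skewed_regions(sim$hap1, "GC")
  expect_gte(interval_jaccard(isl, gc_cores), 0.8)
  # every core is hit by exactly one island of the matching sign
  hit <- oriallele:::count_interval_overlaps(gc_cores, isl)
  expect_true(all(hit == 1L))
  for (i in seq_len(nrow(gc_cores))) {
    ov <- isl[isl$chrom == gc_cores$chrom[i] &
                isl$end > gc_cores$start[i] &
                isl$start < gc_cores$end[i], ]
    expect_equal(ov$sign, gc_cores$strand[i])
  }
})

test_that("complementing the genome mirrors skew island signs", {
  spec <- simulation_spec(chrom_lengths = c(s1 = 100000L), n_origins = 20L,
                          n_g4 = 0L, n_ig4 = 0L, n_skew_cores = 4L,
                          n_ards = 0L, seed = 22L)
  sim <- build_diploid_genome(spec)
  isl <- call_skewed_regions(sim$hap1, "GC")
  comp <- vapply(sim$hap1, complement_seq, character(1))
  isl_c <- call_skewed_regions(comp, "GC")
  expect_equal(isl$start, isl_c$start)
  expect_equal(isl$end, isl_c$end)
  expect_equal(isl$sign, chartr("+-", "-+", isl_c$sign))
})

test_that("chi-squared 2x2 statistic matches the expected-count formula", {
  tab <- matrix(c(100, 150, 100, 50), nrow = 2)
  got <- chisq_2x2(tab)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  want <- sum((tab - exp_counts)^2 / exp_counts)
  expect_equal(got$statistic, want)
  expect_equal(got$p_value, pchisq(want, df = 1, lower.tail = FALSE))
})

test_that("ARD calling recovers planted domains and rejects identical tracks", {
  spec <- simulation_spec(chrom_lengths = c(s1 = 500000L, s2 = 500000L),
                          n_origins = 10L, n_g4 = 0L, n_ig4 = 0L,
                          n_skew_cores = 0L, n_ards = 2L,
                          ard_length = 200000L, ard_amplitude = 0.12,
                          seed = 23L)
  sim <- build_diploid_genome(spec)
  tx <- simulate_timex_tracks(sim$truth)
  ard <- call_ards(tx$maternal, tx$paternal, "ard", tx$counts)
  core <- call_ards(tx$maternal, tx$paternal, "core", tx$counts)
  expect_gte(interval_jaccard(ard, sim$truth$ards), 0.8)
  expect_gte(interval_jaccard(core, sim$truth$ards), 0.8)
  expect_equal(sort(ard$sign), sort(sim$truth$ards$sign))

  # identical tracks: no domains
  none <- call_ards(tx$maternal, tx$maternal, "ard",
                    list(s_maternal = tx$counts$s_maternal,
                         g1_maternal = tx$counts$g1_maternal,
                         s_paternal = tx$counts$s_maternal,
                         g1_paternal = tx$counts$g1_maternal))
  expect_equal(nrow(none), 0L)
})

test_that("overlapping planted ARDs are rejected by the track simulator", {
  spec <- simulation_spec(n_ards = 0L, seed = 5L)
  sim <- build_diploid_genome(spec)
  sim$truth$ards <- data.frame(
    chrom = "sim1", start = c(0L, 100000L), end = c(200000L, 300000L),
    amplitude = 0.1, sign = "+", stringsAsFactors = FALSE)
  expect_error(simulate_timex_tracks(sim$truth), "overlap")
})
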