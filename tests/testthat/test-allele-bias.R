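make_peaks <- function(starts, ends, chrom = "c1") {
  data.frame(peak_id = sprintf("p%d", seq_along(starts)), chrom = chrom,
             start = starts, end = ends, stringsAsFactors = FALSE)
}

make_vars <- function(pos, ad1, ad2, chrom = "c1", indel = FALSE) {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
             hap1_allele = "A", hap2_allele = "T", ad1 = ad1, ad2 = ad2,
             is_indel = rep_len(indel, length(pos)), stringsAsFactors = FALSE)
}

test_that("allelic read counting sums SNP depths with half-open bounds", {
  peaks <- make_peaks(100, 200)
  vars <- make_vars(c(120, 150), c(10L, 7L), c(5L, 3L))
  rec <- count_allelic_reads(peaks, vars)
  expect_equal(rec$n1, 17L)
  expect_equal(rec$n2, 8L)
  expect_equal(rec$n_snps, 2L)

  # SNP exactly at `end` is outside the half-open interval
  rec <- count_allelic_reads(peaks, make_vars(200, 9L, 9L))
  expect_equal(rec$n1, 0L)
  expect_equal(rec$n_snps, 0L)
  # SNP at `start` is inside
  rec <- count_allelic_reads(peaks, make_vars(100, 9L, 2L))
  expect_equal(rec$n1, 9L)

  # indels are excluded from counting
  rec <- count_allelic_reads(peaks, make_vars(150, 30L, 2L, indel = TRUE))
  expect_equal(rec$n1 + rec$n2, 0L)

  # peaks without SNPs are kept with zero counts
  rec <- count_allelic_reads(make_peaks(c(0, 500), c(50, 600)),
                             make_vars(520, 4L, 6L))
  expect_equal(rec$n1, c(0L, 4L))
})

test_that("two-sided binomial p-values match closed forms and the pmf oracle", {
  expect_equal(binom_allele_p(25, 25), 1)
  expect_equal(binom_allele_p(50, 0), 2 * 0.5^50)
  expect_equal(binom_allele_p(35, 15), oracle_binom_p(35, 15))
  # spot grid against the summation oracle
  for (n1 in c(0, 1, 10, 26, 51)) for (n2 in c(0, 3, 25, 49)) {
    if (n1 + n2 == 0) next
    expect_equal(binom_allele_p(n1, n2), oracle_binom_p(n1, n2),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("bias classification applies the read filter, BH and thresholds", {
  rec <- data.frame(peak_id = sprintf("p%d", 1:6),
                    n1 = c(10L, 40L, 60L, 25L, 90L, 500L),
                    n2 = c(10L, 9L, 40L, 25L, 10L, 480L))
  out <- test_allele_bias(rec, min_reads = 50L, fdr = 0.05)
  expect_equal(out$class[1], "non_analysable")   # 20 reads
  expect_equal(out$class[2], "non_analysable")   # 49 reads
  expect_true(is.na(out$p_value[1]))
  # BH over the analysable records only, matching the step-up oracle
  an <- !is.na(out$p_value)
  expect_equal(out$q_value[an], oracle_bh(out$p_value[an]))
  expect_equal(out$class[5], "allele_biased")    # 90:10
  expect_equal(out$class[4], "analysable_unbiased")
  # log2 ratio sign and sentinel
  expect_equal(out$log2_ratio[4], 0)
  out0 <- test_allele_bias(data.frame(peak_id = "x", n1 = 60L, n2 = 0L))
  expect_true(is.infinite(out0$log2_ratio))

  expect_error(test_allele_bias(rec, min_reads = 0L), "min_reads")
  expect_error(test_allele_bias(rec, fdr = 1.2), "fdr")
})

test_that("p-values are symmetric in the haplotypes and monotone in imbalance", {
  set.seed(5)
  n1 <- rpois(50, 60)
  n2 <- rpois(50, 60)
  expect_equal(binom_allele_p(n1, n2), binom_allele_p(n2, n1))
  # at fixed total, p is non-increasing as |n1 - n2| grows
  total <- 120L
  k <- 0:60
  p <- binom_allele_p(60L + k, 60L - k)
  expect_true(all(diff(p) <= 1e-12))
  # swapping haplotypes negates the log ratio and keeps the class
  rec <- data.frame(peak_id = c("a", "b"), n1 = c(80L, 30L), n2 = c(20L, 70L))
  fwd <- test_allele_bias(rec)
  swp <- test_allele_bias(transform(rec, n1 = rec$n2, n2 = rec$n1))
  expect_equal(fwd$p_value, swp$p_value)
  expect_equal(fwd$class, swp$class)
  expect_equal(fwd$log2_ratio, -swp$log2_ratio)
})

test_that("BH q-values match hand computation on fixed p-lists", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(p.adjust(p, "BH"), oracle_bh(p))
})

test_that("null simulation keeps the false-discovery proportion controlled", {
  fdp <- vapply(1:8, function(r) {
    cnt <- simulate_allele_counts(2000, e1 = 0.5, mean_depth = 100,
                                  seed = 400 + r)
    out <- test_allele_bias(cnt, min_reads = 50L, fdr = 0.05)
    calls <- sum(out$class == "allele_biased")
    if (calls > 0) 1 else 0   # every call is false under the null
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / length(fdp))
  expect_lte(mean(fdp), 0.05 + 3 * se)
})

test_that("polymorphic motif tallies respect the restriction modes", {
  rec <- data.frame(peak_id = c("a", "b", "c", "d"),
                    n1 = c(80L, 20L, 90L, 55L),
                    n2 = c(20L, 80L, 10L, 45L))
  c1 <- c(a = 1, b = 0, c = 2, d = 1)
  c2 <- c(a = 0, b = 1, c = 0, d = 1)
  cmp <- compare_polymorphic_motifs(rec, c1, c2, "any")
  # d excluded (equal counts); a: richer=1 eff=1; b: richer=2 eff=2; c: 1/1
  expect_equal(cmp$n_pairs, 3L)
  expect_equal(cmp$most_efficient, 3L)
  expect_equal(cmp$least_efficient, 0L)

  single <- compare_polymorphic_motifs(rec, c1, c2, "single_motif")
  expect_equal(single$n_pairs, 2L)  # c dropped: two copies on hap1

  other1 <- c(a = 1, b = 0, c = 0, d = 0)
  other2 <- c(a = 0, b = 0, c = 0, d = 0)
  none <- compare_polymorphic_motifs(rec, c1, c2, "single_motif_no_other",
                                     other1 = other1, other2 = other2)
  expect_equal(none$n_pairs, 1L)    # a dropped: carries the other motif
  expect_equal(none$table$peak_id, "b")

  expect_error(compare_polymorphic_motifs(rec, c1[-1], c2, "any"), "missing")
})

test_that("motif placement independent of bias splits the tally evenly", {
  set.seed(9)
  n <- 500
  rec <- data.frame(peak_id = sprintf("p%d", 1:n),
                    n1 = 50L + rbinom(n, 60, 0.5),
                    n2 = 50L + rbinom(n, 60, 0.5))
  on1 <- runif(n) < 0.5
  c1 <- setNames(as.numeric(on1), rec$peak_id)
  c2 <- setNames(as.numeric(!on1), rec$peak_id)
  cmp <- compare_polymorphic_motifs(rec, c1, c2, "any")
  # binomial 95% interval around an even split
  half <- cmp$n_pairs / 2
  margin <- 1.96 * sqrt(cmp$n_pairs) / 2
  expect_lt(abs(cmp$most_efficient - half), 3 * margin)
})
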