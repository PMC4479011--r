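test_that("window densities follow the definition and a recount oracle", {
  expect_equal(window_density("GGGGG", "G", window = 5), 1)
  expect_equal(window_density("GCGCGC", "G", window = 2), rep(0.5, 5))
  expect_error(window_density("ACG", "G", window = 5), "window larger")
  # N counts as absence
  expect_equal(window_density("GNGG", "G", window = 4), 0.75)

  set.seed(2)
  s <- random_seq(600)
  got <- window_density(s, c("G", "C"), window = 50)
  x <- strsplit(s, "")[[1]]
  want <- vapply(1:(600 - 49), function(i)
    sum(x[i:(i + 49)] %in% c("G", "C")) / 50, numeric(1))
  expect_equal(got, want)
})

test_that("skew obeys the formula, the 0/0 rule and complement antisymmetry", {
  s <- paste0(paste(rep("G", 3), collapse = ""),
              paste(rep("C", 2), collapse = ""),
              paste(rep("A", 45), collapse = ""))
  expect_equal(skew_track(s, "GC", window = 50), 0.2)
  expect_true(is.na(skew_track(paste(rep("A", 50), collapse = ""), "GC",
                               window = 50)))
  set.seed(3)
  for (rep in 1:5) {
    s <- random_seq(300)
    fwd <- skew_track(s, "GC", window = 50)
    rc <- skew_track(revcomp(s), "GC", window = 50)
    expect_equal(rc, -rev(fwd))
    fwd_at <- skew_track(s, "AT", window = 50)
    rc_at <- skew_track(revcomp(s), "AT", window = 50)
    expect_equal(rc_at, -rev(fwd_at))
  }
})

# a little genome with G-rich, C-rich and balanced summit neighbourhoods
toy_genome <- function() {
  piece <- function(p) random_seq(2000, p)
  set.seed(12)
  g_rich <- piece(c(A = .15, C = .15, G = .55, T = .15))
  c_rich <- piece(c(A = .15, C = .55, G = .15, T = .15))
  neutral <- piece(c(A = .25, C = .25, G = .25, T = .25))
  c(chrA = paste0(neutral, g_rich, c_rich, neutral))
}

test_that("orientation flips C-rich centres, keeps G-rich centres and ties", {
  g <- toy_genome()
  peaks <- data.frame(peak_id = c("gr", "cr"), chrom = "chrA",
                      start = c(2500, 4500), end = c(3500, 5500),
                      summit = 500L)
  or <- orient_profiles(peaks, g)
  expect_equal(or$flip, c(FALSE, TRUE))

  # exact tie keeps the reference orientation
  tie <- c(t1 = paste(rep("GCAT", 300), collapse = ""))
  pk <- data.frame(peak_id = "t", chrom = "t1", start = 100, end = 1100,
                   summit = 500L)
  expect_false(orient_profiles(pk, tie)$flip)

  # peak too close to the edge is dropped with a warning
  edge <- data.frame(peak_id = "e", chrom = "chrA", start = 0, end = 600,
                     summit = 300L)
  expect_warning(out <- orient_profiles(rbind(peaks, edge), g), "edge")
  expect_equal(nrow(out), 2L)
})

test_that("orientation is idempotent on an adjusted peak set", {
  g <- toy_genome()
  peaks <- data.frame(peak_id = c("gr", "cr"), chrom = "chrA",
                      start = c(2500, 4500), end = c(3500, 5500),
                      summit = 500L)
  or <- orient_profiles(peaks, g)
  # build the adjusted genome: flip the flipped peak's central region
  adj <- g
  fl <- or[or$flip, ]
  s <- fl$start + fl$summit
  ctr <- substring(g["chrA"], s - 500 + 1, s + 500)
  substr(adj["chrA"], s - 500 + 1, s + 500) <- revcomp(ctr)
  or2 <- orient_profiles(or[, names(peaks)], adj)
  expect_false(any(or2$flip))
})

test_that("adjusted central skew is non-negative for oriented peaks", {
  g <- toy_genome()
  peaks <- data.frame(peak_id = c("gr", "cr"), chrom = "chrA",
                      start = c(2500, 4500), end = c(3500, 5500),
                      summit = 500L, enrichment = c(2, 1))
  prof <- summit_profiles(peaks, g, width = 1000, type = "skew",
                          pair = "GC", oriented = TRUE)
  central <- prof[, 400:551]
  expect_true(all(rowMeans(central, na.rm = TRUE) >= 0))
})

test_that("stratified skew profiles average per stratum as defined", {
  g <- toy_genome()
  peaks <- data.frame(peak_id = c("a", "b"), chrom = "chrA",
                      start = c(2500, 2500), end = c(3500, 3500),
                      summit = 500L, enrichment = c(9, 5))
  one <- stratified_skew_profile(peaks, g, strata = 1L, width = 1000)
  single <- summit_profiles(peaks[1, ], g, width = 1000, type = "skew")
  expect_equal(unname(one[1, ]), unname(single[1, ]))

  # two identical peaks: the stratum mean equals either profile
  two <- stratified_skew_profile(peaks, g, strata = 2L, width = 1000)
  expect_equal(unname(two[1, ]), unname(single[1, ]))

  expect_error(stratified_skew_profile(peaks, g, strata = 5L), "stratum")
})

test_that("planted skewed cores raise central skew above the flanks", {
  set.seed(33)
  spec <- simulation_spec(chrom_lengths = c(s1 = 200000L), n_origins = 40L,
                         n_g4 = 0L, n_ig4 = 0L, n_skew_cores = 8L,
                         n_ards = 0L, seed = 17L)
  sim <- build_diploid_genome(spec)
  cores <- sim$truth$skew_cores
  host <- sim$truth$origins[match(cores$origin_id[cores$pair == "GC"],
                                  sim$truth$origins$origin_id), ]
  prof <- suppressWarnings(
    summit_profiles(host, sim$hap1, width = 3000, type = "skew",
                    pair = "GC", oriented = TRUE))
  m <- colMeans(prof, na.rm = TRUE)
  central <- mean(m[1300:1700])
  flank <- mean(c(m[1:400], m[(length(m) - 399):length(m)]), na.rm = TRUE)
  expect_gt(central, flank + 0.2)
})

test_that("summit G histogram measures the reference strand G fraction", {
  g <- c(gg = paste(rep("G", 300), collapse = ""))
  pk <- data.frame(peak_id = "p", chrom = "gg", start = 100, end = 200,
                   summit = 50L)
  h <- summit_g_histogram(pk, g, width = 100)
  expect_equal(h$values, 1)
  expect_equal(sum(h$counts), 1)

  # uniform random genome: unimodal near 0.25
  set.seed(44)
  g2 <- c(r = random_seq(60000))
  pk2 <- data.frame(peak_id = sprintf("p%d", 1:100), chrom = "r",
                    start = seq(100, 59000, length.out = 100),
                    end = seq(100, 59000, length.out = 100) + 200,
                    summit = 100L)
  h2 <- summit_g_histogram(pk2, g2, width = 100)
  expect_lt(abs(mean(h2$values) - 0.25), 3 * sqrt(0.25 * 0.75 / 100) / 10 * 10)
  expect_lt(sd(h2$values), 3 * sqrt(0.25 * 0.75 / 100))
})

test_that("summit G histogram is bimodal when G-rich cores sit on random strands", {
  set.seed(55)
  spec <- simulation_spec(chrom_lengths = c(s1 = 300000L), n_origins = 60L,
                         n_g4 = 0L, n_ig4 = 0L, n_skew_cores = 20L,
                         n_ards = 0L, seed = 18L)
  sim <- build_diploid_genome(spec)
  cores <- sim$truth$skew_cores[sim$truth$skew_cores$pair == "GC", ]
  host <- sim$truth$origins[match(cores$origin_id,
                                  sim$truth$origins$origin_id), ]
  h <- summit_g_histogram(host, sim$hap1, width = 100)
  # G-rich strand is + or - at random: one mode high, one low
  expect_gt(sum(h$values > 0.4), 0)
  expect_gt(sum(h$values < 0.3), 0)
  expect_equal(sum(h$values > 0.4) + sum(h$values < 0.3), length(h$values))
})

test_that("k-means recovers planted profile archetypes and is reproducible", {
  set.seed(66)
  width <- 200
  archetype <- function(core) {
    prof <- rep(0.25, width)
    mid <- (width - core) / 2
    prof[(mid + 1):(mid + core)] <- 0.55
    prof
  }
  cores <- c(20, 60, 120, 180)
  truth <- rep(1:4, each = 50)
  profs <- do.call(rbind, lapply(cores, function(cw) {
    t(replicate(50, archetype(cw) + rnorm(width, 0, 0.03)))
  }))
  cl <- cluster_g_profiles(profs, k = 4, seed = 99)
  expect_gte(adjusted_rand_index(cl$labels, truth), 0.9)
  cl2 <- cluster_g_profiles(profs, k = 4, seed = 99)
  expect_identical(cl$labels, cl2$labels)

  # k = 1: centroid is the position-wise mean
  one <- cluster_g_profiles(profs, k = 1, seed = 1)
  expect_equal(unname(one$centers[1, ]), unname(colMeans(profs)))

  # duplicated rows land in the same cluster
  dup <- rbind(profs[1, ], profs[1, ], profs[151, ], profs[151, ])
  cld <- cluster_g_profiles(dup, k = 2, seed = 3)
  expect_equal(cld$labels[1], cld$labels[2])
  expect_equal(cld$labels[3], cld$labels[4])

  expect_error(cluster_g_profiles(profs[1:3, ], k = 4), "k larger")
})
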