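test_that("canonical G4 patterns are found with correct strand and bounds", {
  h <- find_g4("GGGTTAGGGTTAGGGTTAGGG")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 21L))
  expect_equal(h$strand, "+")

  h <- find_g4("CCCTAACCCTAACCCTAACCC")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 21L))
  expect_equal(h$strand, "-")

  # first loop of 8 exceeds the 7-nt bound
  expect_equal(nrow(find_g4("GGGTTTTTTTTGGGTTGGGTTGGG")), 0L)
  # N never counts toward a tract or loop
  expect_equal(nrow(find_g4("GGGTNAGGGTTAGGGTTAGGG")), 0L)
  expect_equal(nrow(find_g4("")), 0L)
})

test_that("overlapping G4 matches merge into maximal regions", {
  # five chained tracts: one merged hit spanning all of them
  s <- "GGGAGGGAGGGAGGGAGGG"
  h <- find_g4(s)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, nchar(s)))
})

test_that("G4 scan matches the anchored-regex oracle on random sequences", {
  set.seed(42)
  for (rep in 1:15) {
    s <- random_seq(140, c(A = .15, C = .2, G = .45, T = .2))
    got <- find_g4(s)
    want <- oracle_g4_regions(s)
    plus <- got[got$strand == "+", ]
    minus <- got[got$strand == "-", ]
    expect_equal(cbind(start = plus$start, end = plus$end), want$plus)
    expect_equal(cbind(start = minus$start, end = minus$end), want$minus)
  }
})

test_that("G4 scan is symmetric under reverse complement", {
  set.seed(7)
  for (rep in 1:10) {
    s <- random_seq(500, c(A = .15, C = .35, G = .35, T = .15))
    n <- nchar(s)
    fwd <- find_g4(s)
    rev <- find_g4(revcomp(s))
    expect_equal(nrow(rev), nrow(fwd))
    if (nrow(fwd) == 0L) next
    mirrored <- data.frame(start = n - rev$end, end = n - rev$start,
                           strand = chartr("+-", "-+", rev$strand))
    mirrored <- mirrored[order(mirrored$start), ]
    expect_equal(mirrored$start, fwd$start)
    expect_equal(mirrored$end, fwd$end)
    expect_equal(mirrored$strand, fwd$strand)
  }
})

test_that("iG4 pattern matching and G4 subtraction follow the definitions", {
  # mixed C/G tracts form an iG4 that is not a G4
  h <- find_ig4("CCCACCCACCCAGGG")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 15L))
  expect_equal(h$strand, ".")

  # a pure-G match is removed because it overlaps a G4 hit
  expect_equal(nrow(find_ig4("GGGAGGGAGGGAGGG")), 0L)
  # a pure-C match is removed: it is a minus-strand G4
  expect_equal(nrow(find_ig4("CCCACCCACCCACCC")), 0L)
  # the spacer class admits any letter, including N
  expect_equal(nrow(find_ig4("CCCNNACCCACCCAGGG")), 1L)
})

test_that("iG4 regions match the exhaustive chain-enumeration oracle", {
  set.seed(11)
  for (rep in 1:20) {
    s <- random_seq(120, c(A = .15, C = .35, G = .35, T = .15))
    got <- find_ig4(s, g4_hits = data.frame(start = integer(),
                                            end = integer()))
    want <- oracle_ig4_regions(s)
    expect_equal(cbind(start = got$start, end = got$end), want)
  }
})

test_that("iG4 hits never overlap G4 hits", {
  set.seed(19)
  for (rep in 1:10) {
    s <- random_seq(2000, c(A = .1, C = .4, G = .4, T = .1))
    g4 <- find_g4(s)
    ig4 <- find_ig4(s, g4)
    if (nrow(ig4) == 0L || nrow(g4) == 0L) next
    ov <- oriallele:::count_interval_overlaps(
      data.frame(chrom = "s", start = ig4$start, end = ig4$end),
      data.frame(chrom = "s", start = g4$start, end = g4$end))
    expect_true(all(ov == 0L))
  }
})

test_that("triplex candidates behave like purine/pyrimidine mirror repeats", {
  h <- find_triplex_candidates("GAGAGAGAGAGAGAGAGAGA")
  expect_gte(nrow(h), 1L)
  expect_true(all(h$triplex_type >= 4L))  # purine arms: antiparallel class

  pyr <- find_triplex_candidates("TCTCTCTCTCTCTCTCTCTC")
  expect_gte(nrow(pyr), 1L)
  expect_true(all(pyr$triplex_type <= 3L)) # pyrimidine arms: parallel class

  expect_equal(nrow(find_triplex_candidates("ACGTACGTACGTACGTACGT")), 0L)
})

test_that("triplex detector agrees with the naive mirror-repeat oracle", {
  set.seed(23)
  # plant purine mirror repeats (arm 10, loop 2) in random background
  bg <- strsplit(random_seq(1500), "")[[1]]
  for (at in c(200, 700, 1200)) {
    arm <- sample(c("A", "G"), 10, replace = TRUE)
    mr <- c(arm, sample(c("C", "T"), 2, replace = TRUE), rev(arm))
    bg[at:(at + length(mr) - 1L)] <- mr
  }
  s <- paste(bg, collapse = "")
  got <- find_triplex_candidates(s)
  expect_gte(nrow(got), 3L)
  got_iv <- oriallele:::reduce_intervals(
    data.frame(chrom = rep("s", nrow(got)), start = got$start,
               end = got$end))
  want <- oracle_mirror_repeats(s)
  expect_equal(cbind(start = got_iv$start, end = got_iv$end), want)

  # and on background with no planted repeats both report nothing
  set.seed(24)
  s0 <- random_seq(3000, c(A = .35, C = .15, G = .35, T = .15))
  expect_equal(nrow(find_triplex_candidates(s0)),
               nrow(oracle_mirror_repeats(s0)))
})

test_that("k-mer enumeration flags match per-kmer brute force", {
  set.seed(31)
  s <- paste0(random_seq(80, c(A = .1, C = .4, G = .4, T = .1)),
              "GGGAGGGAGGGAGGG", "CCCACCCACCCAGGG",
              random_seq(40, c(A = .1, C = .4, G = .4, T = .1)))
  g <- c(chrX = s)
  km <- enumerate_kmers(g, k = 30L, gc_min = 0)
  n <- nchar(s)
  expect_equal(nrow(km), n - 30L + 1L)
  for (i in seq_len(nrow(km))) {
    sub <- substring(s, km$start[i] + 1L, km$end[i])
    gc_want <- sum(strsplit(sub, "")[[1]] %in% c("G", "C")) / 30
    expect_equal(km$gc[i], gc_want)
    g4_want <- grepl("G{3,}([ACGT]{1,7}G{3,}){3}", sub, perl = TRUE) ||
      grepl("C{3,}([ACGT]{1,7}C{3,}){3}", sub, perl = TRUE)
    ig4_want <- grepl("(CCC|GGG)([A-Z]{1,7}(CCC|GGG)){3}", sub, perl = TRUE)
    expect_identical(km$has_g4[i], g4_want)
    expect_identical(km$has_ig4[i], ig4_want)
  }
})

test_that("k-mer GC threshold implies the expected integer GC count", {
  g <- c(c1 = paste(rep("GGGGGAAACC", 20), collapse = ""))
  km <- enumerate_kmers(g, k = 30L, gc_min = 0.71)
  if (nrow(km) > 0L) expect_true(all(km$gc * 30 >= 22))
  g2 <- c(c1 = paste(rep("G", 30), collapse = ""))
  km2 <- enumerate_kmers(g2, k = 30L, gc_min = 0.71)
  expect_equal(nrow(km2), 1L)
  expect_equal(km2$gc, 1)
  expect_true(km2$has_g4)
})
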