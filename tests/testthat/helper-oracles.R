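# Independent brute-force oracles used to freeze expected values.
# These deliberately re-derive results from first principles (anchored
# regex scans, exhaustive chain enumeration, O(n^2) span filtering, direct
# pmf summation) rather than reusing any package internals.

# --- G4: full-match test of every (start, end) substring, merged.
# This enumerates the *entire* raw-match set (every parse), not just one
# greedy match per start, so it is definitionally exact.
oracle_g4_regions <- function(seq, tract = 3L, loop_min = 1L, loop_max = 7L,
                              tracts = 4L) {
  pat_for <- function(letter) {
    sprintf("^%s{%d,}([ACGT]{%d,%d}%s{%d,}){%d}$", letter, tract,
            loop_min, loop_max, letter, tract, tracts - 1L)
  }
  min_len <- tracts * tract + (tracts - 1L) * loop_min
  scan <- function(letter) {
    n <- nchar(seq)
    out <- list()
    for (i in seq_len(n)) {
      if (i + min_len - 1L > n) break
      for (e in (i + min_len - 1L):n) {
        if (grepl(pat_for(letter), substring(seq, i, e), perl = TRUE)) {
          out[[length(out) + 1L]] <- c(i - 1L, e)
        }
      }
    }
    out
  }
  merge0 <- function(iv) {
    if (length(iv) == 0L) return(cbind(start = integer(), end = integer()))
    m <- do.call(rbind, iv)
    m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    res <- list(m[1L, ])
    for (k in seq_len(nrow(m))[-1L]) {
      last <- res[[length(res)]]
      if (m[k, 1L] <= last[2L]) {
        res[[length(res)]][2L] <- max(last[2L], m[k, 2L])
      } else res[[length(res) + 1L]] <- m[k, ]
    }
    out <- do.call(rbind, res)
    colnames(out) <- c("start", "end")
    out
  }
  list(plus = merge0(scan("G")), minus = merge0(scan("C")))
}

# --- iG4: exhaustive enumeration of all 4-anchor chains (anchors are CCC
# or GGG triplets; consecutive anchors separated by 1-7 arbitrary letters)
oracle_ig4_regions <- function(seq) {
  n <- nchar(seq)
  is_anchor <- function(p) {
    s <- substring(seq, p + 1L, p + 3L)
    s == "CCC" || s == "GGG"
  }
  anchors <- Filter(is_anchor, 0:(n - 3L))
  iv <- list()
  for (a1 in anchors) for (a2 in anchors) for (a3 in anchors)
    for (a4 in anchors) {
      if (a2 - (a1 + 3L) >= 1L && a2 - (a1 + 3L) <= 7L &&
          a3 - (a2 + 3L) >= 1L && a3 - (a2 + 3L) <= 7L &&
          a4 - (a3 + 3L) >= 1L && a4 - (a3 + 3L) <= 7L) {
        iv[[length(iv) + 1L]] <- c(a1, a4 + 3L)
      }
    }
  if (length(iv) == 0L) return(cbind(start = integer(), end = integer()))
  m <- unique(do.call(rbind, iv))
  df <- data.frame(chrom = "s", start = m[, 1L], end = m[, 2L])
  red <- oriallele:::reduce_intervals(df)
  cbind(start = red$start, end = red$end)
}

# --- two-sided binomial p by direct pmf summation
oracle_binom_p <- function(n1, n2) {
  n <- n1 + n2
  pmf <- dbinom(0:n, n, 0.5)
  lower <- sum(pmf[seq_len(n1 + 1L)])
  upper <- sum(pmf[(n1 + 1L):(n + 1L)])
  min(1, 2 * min(lower, upper))
}

# --- Benjamini-Hochberg by the step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# --- island finder: all candidate spans over eligible bins, filtered by
# the definitions (eligible endpoints, internal gaps bridged, maximality,
# score and length thresholds)
oracle_islands <- function(values, window_value, gap, island_score,
                           island_length) {
  elig <- which(!is.na(values) & values >= window_value)
  m <- length(elig)
  out <- list()
  if (m == 0L) return(out)
  for (a in seq_len(m)) for (b in a:m) {
    i <- elig[a]; j <- elig[b]
    inner <- elig[elig >= i & elig <= j]
    if (length(inner) > 1L && any(diff(inner) - 1L > gap)) next
    if (a > 1L && i - elig[a - 1L] - 1L <= gap) next   # extendable left
    if (b < m && elig[b + 1L] - j - 1L <= gap) next    # extendable right
    span <- j - i + 1L
    score <- sum(values[inner] / window_value)
    if (span < island_length || score < island_score) next
    out[[length(out) + 1L]] <- c(start_bin = i, end_bin = j, score = score)
  }
  out
}

# --- naive mirror-repeat scan for the triplex detector
oracle_mirror_repeats <- function(seq, arm_min = 8L, loop_max = 8L,
                                  purity = 0.9) {
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(x)
  acgt <- x %in% c("A", "C", "G", "T")
  pur <- x %in% c("A", "G")
  iv <- list()
  for (l in seq_len(n)) for (g in 0:loop_max) {
    k <- 0L
    while (l - k >= 1L && l + g + 1L + k <= n &&
           x[l - k] == x[l + g + 1L + k] && acgt[l - k]) k <- k + 1L
    if (k < arm_min) next
    arm_idx <- c((l - k + 1L):l, (l + g + 1L):(l + g + k))
    pfrac <- mean(pur[arm_idx])
    if (pfrac >= purity || (1 - pfrac) >= purity) {
      iv[[length(iv) + 1L]] <- c(l - k, l + g + k)
    }
  }
  if (length(iv) == 0L) return(cbind(start = integer(), end = integer()))
  m <- unique(do.call(rbind, iv))
  df <- data.frame(chrom = "s", start = m[, 1L], end = m[, 2L])
  red <- oriallele:::reduce_intervals(df)
  cbind(start = red$start, end = red$end)
}

# --- adjusted Rand index for cluster recovery checks
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# --- random sequence helpers
random_seq <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

complement_seq <- function(s) chartr("ACGT", "TGCA", s)
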