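# Permutation-based overlap enrichment, interval shuffling, GC/length
# matched control sampling and peak-height matched resampling.

#' Overlap summary between a query and a feature set
#'
#' A query interval counts as a hit when it overlaps at least one feature
#' by at least 1 bp; the percentage is `100 * hits / n_query`.
#'
#' @param query,feature Interval data frames on the same genome.
#' @return List of class `overlap_summary`: `n_query`, `n_query_hit`,
#'   `percent`.
#' @export
overlap_summary <- function(query, feature) {
  if (nrow(query) == 0L) stop("empty query set")
  hits <- sum(count_interval_overlaps(query, feature) > 0L)
  structure(list(n_query = nrow(query), n_query_hit = hits,
                 percent = 100 * hits / nrow(query)),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("%d / %d query intervals hit (%.1f%%)\n",
              x$n_query_hit, x$n_query, x$percent))
  invisible(x)
}

#' Randomly relocate intervals on the genome
#'
#' Interval lengths are preserved exactly and new start positions are
#' uniform over the valid placements; shuffled intervals may overlap each
#' other.  By default each interval stays on its own chromosome.
#'
#' @param intervals Interval data frame.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param seed Optional RNG seed.
#' @param within_chrom Keep each interval on its chromosome (default);
#'   otherwise chromosomes are drawn with probability proportional to the
#'   number of valid start positions.
#' @return Interval data frame with relocated `start`/`end`.
#' @export
shuffle_intervals <- function(intervals, chrom_lengths, seed = NULL,
                              within_chrom = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(intervals)
  len <- df$end - df$start
  if (within_chrom) {
    L <- chrom_lengths[df$chrom]
    if (any(is.na(L))) stop("interval chromosome absent from chrom_lengths")
    if (any(len > L)) stop("interval longer than its chromosome")
    df$start <- as.integer(floor(runif(nrow(df)) * (L - len + 1)))
  } else {
    maxlen <- max(chrom_lengths)
    if (any(len > maxlen)) stop("interval longer than any chromosome")
    for (i in seq_len(nrow(df))) {
      w <- pmax(chrom_lengths - len[i] + 1, 0)
      ch <- sample(names(chrom_lengths), 1L, prob = w)
      df$chrom[i] <- ch
      df$start[i] <- as.integer(floor(runif(1L) *
                                        (chrom_lengths[ch] - len[i] + 1)))
    }
  }
  df$end <- df$start + len
  df
}

#' Permutation test of interval overlap
#'
#' The feature set is shuffled on each iteration while the query set stays
#' fixed.  The empirical enrichment p-value is the fraction of iterations
#' whose statistic is strictly above the observed one; the complementary
#' fraction strictly below is reported for depletion.
#'
#' @param query,feature Interval data frames.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param statistic `"n_query_hit"` (queries hit by a feature),
#'   `"n_feature_hit"` (features hitting a query) or `"percent"` (query
#'   hit percentage).
#' @param n_iter Number of shuffles (error if 0; warning below 100).
#' @param seed Optional RNG seed.
#' @param within_chrom Passed to [shuffle_intervals()].
#' @param plus_one Apply the (obs+1)/(n+1) small-sample correction
#'   (off by default; the plain strictly-above fraction is reported).
#' @return List of class `enrichment_result`: `statistic`, `observed`,
#'   `expected_mean`, `expected_sd`, `n_iter`, `p_value` (enrichment),
#'   `p_depletion`, `perm_stats`.
#' @export
permutation_test <- function(query, feature, chrom_lengths,
                             statistic = c("n_query_hit", "n_feature_hit",
                                           "percent"),
                             n_iter = 1000L, seed = NULL,
                             within_chrom = TRUE, plus_one = FALSE) {
  statistic <- match.arg(statistic)
  if (n_iter < 1L) stop("n_iter must be positive")
  if (n_iter < 100L) warning("n_iter below 100 gives a coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- function(feat) {
    switch(statistic,
           n_query_hit = sum(count_interval_overlaps(query, feat) > 0L),
           n_feature_hit = sum(count_interval_overlaps(feat, query) > 0L),
           percent = 100 * sum(count_interval_overlaps(query, feat) > 0L) /
             nrow(query))
  }
  observed <- stat_fun(feature)
  perm <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    perm[i] <- stat_fun(shuffle_intervals(feature, chrom_lengths,
                                          within_chrom = within_chrom))
  }
  above <- sum(perm > observed)
  below <- sum(perm < observed)
  p_enr <- if (plus_one) (above + 1) / (n_iter + 1) else above / n_iter
  p_dep <- if (plus_one) (below + 1) / (n_iter + 1) else below / n_iter
  structure(list(statistic = statistic, observed = observed,
                 expected_mean = mean(perm), expected_sd = sd(perm),
                 n_iter = n_iter, p_value = p_enr, p_depletion = p_dep,
                 perm_stats = perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "%s: observed %.3g, expected %.3g +/- %.3g (n_iter %d)\n  P(enrich) = %.4g, P(deplete) = %.4g\n",
    x$statistic, x$observed, x$expected_mean, x$expected_sd, x$n_iter,
    x$p_value, x$p_depletion))
  invisible(x)
}

# GC fraction of each interval of a genome
interval_gc <- function(genome, df) {
  seqs <- substring(genome[df$chrom], df$start + 1L, df$end)
  freq <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs), "CG")
  as.numeric(freq[, 1L]) / (df$end - df$start)
}

#' Sample GC- and length-matched control regions
#'
#' Draws control intervals with the template's length distribution
#' (resampled), placed uniformly and rejected when they overlap the
#' exclusion set, then resamples candidates per GC bin so every control
#' set matches the template's GC histogram at the bin resolution.
#'
#' @param genome Named character vector of sequences.
#' @param template Interval data frame whose length and GC distributions
#'   are matched (e.g. G4 hits).
#' @param exclusions Interval data frame the controls must not overlap
#'   (e.g. G4 plus iG4 hits); NULL for none.
#' @param n_sets Number of control sets.
#' @param set_size Intervals per set.
#' @param gc_bin GC histogram bin width.
#' @param seed Optional RNG seed.
#' @param max_attempts Candidate-pool growth rounds before giving up on an
#'   unfillable GC bin.
#' @return List of `n_sets` interval data frames.
#' @export
sample_gc_matched_controls <- function(genome, template, exclusions = NULL,
                                       n_sets = 100L, set_size = 10000L,
                                       gc_bin = 0.01, seed = NULL,
                                       max_attempts = 50L) {
  if (nrow(template) == 0L) stop("empty template set")
  if (!is.null(seed)) set.seed(seed)
  lens <- genome_lengths(genome)
  breaks <- seq(0, 1 + gc_bin, by = gc_bin)
  gc_t <- interval_gc(genome, template)
  bin_t <- findInterval(gc_t, breaks, rightmost.closed = TRUE)
  target_prop <- tabulate(bin_t, nbins = length(breaks) - 1L) / length(gc_t)
  target_counts <- round(target_prop * set_size)
  need <- which(target_counts > 0L)
  tmpl_len <- template$end - template$start

  pool <- data.frame(chrom = character(), start = integer(),
                     end = integer(), gc = numeric(), bin = integer())
  batch <- max(2000L, 4L * set_size)
  attempt <- 0L
  pool_short <- function() {
    cnt <- tabulate(pool$bin, nbins = length(breaks) - 1L)
    any(cnt[need] == 0L)
  }
  while (attempt < max_attempts &&
         (nrow(pool) < n_sets * set_size / 2 || pool_short())) {
    attempt <- attempt + 1L
    len <- sample(tmpl_len, batch, replace = TRUE)
    cand <- data.frame(chrom = sample(names(lens), batch, replace = TRUE,
                                      prob = lens))
    cand$start <- as.integer(floor(runif(batch) *
                                     (lens[cand$chrom] - len + 1)))
    cand$end <- cand$start + len
    cand <- cand[cand$end <= lens[cand$chrom] & cand$start >= 0L, ,
                 drop = FALSE]
    if (!is.null(exclusions) && nrow(exclusions) > 0L) {
      cand <- cand[count_interval_overlaps(cand, exclusions) == 0L, ,
                   drop = FALSE]
    }
    if (nrow(cand) == 0L) next
    cand$gc <- interval_gc(genome, cand)
    cand$bin <- findInterval(cand$gc, breaks, rightmost.closed = TRUE)
    cand <- cand[cand$bin %in% need, , drop = FALSE]
    pool <- rbind(pool, cand)
  }
  cnt <- tabulate(pool$bin, nbins = length(breaks) - 1L)
  if (any(cnt[need] == 0L)) {
    bad <- need[cnt[need] == 0L][1L]
    stop(sprintf("no candidate regions in GC bin [%.2f, %.2f)",
                 breaks[bad], breaks[bad + 1L]))
  }
  by_bin <- split(seq_len(nrow(pool)), pool$bin)
  replace_warned <- FALSE
  sets <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    picks <- integer()
    for (b in need) {
      avail <- by_bin[[as.character(b)]]
      k <- target_counts[b]
      if (length(avail) < k && !replace_warned) {
        warning("candidate pool short in some GC bins; sampling with replacement")
        replace_warned <- TRUE
      }
      picks <- c(picks, sample(avail, k, replace = length(avail) < k))
    }
    sets[[s]] <- pool[picks, c("chrom", "start", "end", "gc"), drop = FALSE]
    rownames(sets[[s]]) <- NULL
  }
  sets
}

#' Resample a peak pool to match a reference peak-height distribution
#'
#' Reference heights are split into quantile bins; the pool is sampled per
#' bin (without replacement where possible) so the resampled subset's bin
#' proportions match the reference's.  The subset size is the largest
#' achievable without replacement and is reported as an attribute.
#'
#' @param reference,pool Peak data frames with an `enrichment` column.
#' @param n_bins Number of quantile bins (default 20).
#' @param seed Optional RNG seed.
#' @return Subset of `pool` with attribute `size`.
#' @export
resample_matched_height <- function(reference, pool, n_bins = 20L,
                                    seed = NULL) {
  stopifnot("enrichment" %in% names(reference),
            "enrichment" %in% names(pool))
  if (!is.null(seed)) set.seed(seed)
  probs <- seq(0, 1, length.out = n_bins + 1L)
  breaks <- unique(quantile(reference$enrichment, probs))
  breaks[1L] <- -Inf; breaks[length(breaks)] <- Inf
  ref_bin <- cut(reference$enrichment, breaks, labels = FALSE)
  pool_bin <- cut(pool$enrichment, breaks, labels = FALSE)
  nb <- length(breaks) - 1L
  ref_prop <- tabulate(ref_bin, nbins = nb) / length(ref_bin)
  pool_cnt <- tabulate(pool_bin, nbins = nb)
  used <- which(ref_prop > 0)
  size <- floor(min(pool_cnt[used] / ref_prop[used]))
  replace_warned <- FALSE
  picks <- integer()
  for (b in used) {
    k <- round(ref_prop[b] * size)
    avail <- which(pool_bin == b)
    if (length(avail) < k) {
      if (!replace_warned) {
        warning("pool bin short of the reference; sampling with replacement")
        replace_warned <- TRUE
      }
      picks <- c(picks, sample(avail, k, replace = TRUE))
    } else {
      picks <- c(picks, sample(avail, k))
    }
  }
  out <- pool[picks, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "size") <- length(picks)
  out
}
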