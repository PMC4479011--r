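# SICER-style island detection over binned signal, reused for skewed
# regions and asynchronously replicated domains (ARDs), plus the ARD
# chi-squared significance stage.
#
# Definitions: a bin is eligible when its (non-missing) value reaches
# window_value; eligible bins separated by at most `gap` consecutive
# ineligible bins merge into one island; the island score is the sum of
# value / window_value over its eligible bins; islands shorter than
# island_length bins (span from first to last eligible bin) or scoring
# below island_score are dropped; islands are trimmed to eligible bins.

#' Island-finder parameterisation
#'
#' @param bin_size Bin size of the track, bp.
#' @param window_value Eligibility threshold on the bin value.
#' @param gap Maximum run of consecutive ineligible bins bridged.
#' @param island_score Minimum island score (sum of value/window_value
#'   over eligible bins); 0 disables the score filter.
#' @param island_length Minimum island span in bins.
#' @return List of class `island_params`.
#' @export
island_params <- function(bin_size, window_value, gap, island_score,
                          island_length) {
  stopifnot(bin_size > 0, window_value > 0, gap >= 0, island_score >= 0,
            island_length > 0)
  structure(list(bin_size = as.integer(bin_size),
                 window_value = as.numeric(window_value),
                 gap = as.integer(gap),
                 island_score = as.numeric(island_score),
                 island_length = as.integer(island_length)),
            class = "island_params")
}

#' Skewed-region island parameters
#'
#' The default parameter set for calling skewed regions on 25-bp binned
#' skew tracks (threshold 0.375, gap 4 bins, score 16, length 15 bins);
#' 16 threshold-level 25-bp bins correspond to the ~400 bp minimum size of
#' a called skewed region.
#' @return An [island_params()] object.
#' @export
skew_island_params <- function() island_params(25L, 0.375, 4L, 16, 15L)

#' ARD island parameters
#'
#' For 5-kb timing-difference tracks: ARDs use a 0.02 threshold, a 250-kb
#' gap (50 bins) and a 50-kb minimum size (10 bins); core ARDs use 0.1 /
#' 50 kb / 50 kb.  No score filter is applied (the domain definition is by
#' threshold, gap and size only).
#' @param mode `"ard"` or `"core"`.
#' @return An [island_params()] object.
#' @export
ard_island_params <- function(mode = c("ard", "core")) {
  mode <- match.arg(mode)
  if (mode == "ard") island_params(5000L, 0.02, 50L, 0, 10L)
  else island_params(5000L, 0.1, 10L, 0, 10L)
}

#' Call islands on a binned signal track
#'
#' @param track A [signal_track()]; missing values are ineligible.
#' @param params An [island_params()]; its `bin_size` must equal the
#'   track's window.
#' @return Data frame of islands: `chrom`, `start`, `end` (bp, trimmed to
#'   eligible bins), `score`, `n_eligible`, `mean_value`.
#' @export
call_islands <- function(track, params) {
  stopifnot(inherits(track, "signal_track"), inherits(params, "island_params"))
  if (track$window != params$bin_size) {
    stop("track window (", track$window, ") does not match params bin_size (",
         params$bin_size, ")")
  }
  out <- list()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    elig <- which(!is.na(v) & v >= params$window_value)
    if (length(elig) == 0L) next
    grp <- cumsum(c(0L, diff(elig) - 1L > params$gap))
    for (g in unique(grp)) {
      idx <- elig[grp == g]
      span <- idx[length(idx)] - idx[1L] + 1L
      score <- sum(v[idx] / params$window_value)
      if (span < params$island_length || score < params$island_score) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = (idx[1L] - 1L) * params$bin_size,
        end = idx[length(idx)] * params$bin_size,
        score = score,
        n_eligible = length(idx),
        mean_value = mean(v[idx]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric(),
                      n_eligible = integer(), mean_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Bin a 1-bp resolution skew track of a genome
#'
#' Sliding-window skew (window value assigned to the window start) binned
#' by mean; bins with no defined skew value are missing.
#'
#' @param genome Named character vector of sequences.
#' @param pair `"GC"` or `"AT"`.
#' @param window Skew window, bp.
#' @param bin Bin size, bp.
#' @return A [signal_track()] at `bin` resolution.
#' @export
binned_skew_track <- function(genome, pair = "GC", window = 50L, bin = 25L) {
  vals <- list()
  for (ch in names(genome)) {
    s <- skew_track(genome[[ch]], pair, window = window, step = 1L)
    n_bins <- ceiling(length(s) / bin)
    grp <- rep(seq_len(n_bins), each = bin, length.out = length(s))
    sums <- tapply(s, grp, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) mean(x) else NA_real_
    })
    vals[[ch]] <- as.numeric(sums)
  }
  signal_track(vals, bin)
}

#' Call G/C- or A/T-skewed regions genome-wide
#'
#' The 1-bp skew track is binned at 25 bp; positive skew is islanded with
#' the standard parameters, the track is negated and re-islanded for the
#' negative sign, and both are returned with the sign recorded.
#'
#' @param genome Named character vector of sequences.
#' @param pair `"GC"` or `"AT"`.
#' @param params An [island_params()] (default [skew_island_params()]).
#' @param window Skew window in bp (default 50).
#' @return Island data frame with an added `sign` column (`"+"`/`"-"`).
#' @export
call_skewed_regions <- function(genome, pair = c("GC", "AT"),
                                params = skew_island_params(),
                                window = 50L) {
  pair <- match.arg(pair)
  track <- binned_skew_track(genome, pair, window = window,
                             bin = params$bin_size)
  pos <- call_islands(track, params)
  neg_track <- signal_track(lapply(track$values, function(v) -v),
                            track$window)
  neg <- call_islands(neg_track, params)
  if (nrow(pos)) pos$sign <- "+"
  if (nrow(neg)) neg$sign <- "-"
  res <- rbind(pos, neg)
  if (nrow(res) == 0L) {
    res$sign <- character()
    return(res)
  }
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pearson chi-squared statistic on a 2x2 table
#'
#' Classical goodness-of-fit formula, no continuity correction
#' (delegates to [stats::chisq.test()]).
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return List with `statistic` and `p_value` (1 df).
#' @export
chisq_2x2 <- function(tab) {
  fit <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Call asynchronously replicated domains from haplotype timing tracks
#'
#' Islands are called on the absolute maternal-paternal timing-ratio
#' difference with the `mode` parameter set ([ard_island_params()]).  Each
#' island is then tested on a 2x2 contingency table of total S- and
#' G1-phase read counts for the maternal and paternal chromosomes (Pearson
#' chi-squared, 1 df, no continuity correction); Benjamini-Hochberg
#' adjustment is applied over islands and those with `q < fdr` are
#' retained.  The sign of an island records which homologue has the higher
#' mean timing ratio (`"+"` = maternal).
#'
#' @param maternal,paternal [signal_track()]s of S/G1 timing ratios on a
#'   shared binning.
#' @param mode `"ard"` or `"core"`.
#' @param counts List of four [signal_track()]s of read counts:
#'   `s_maternal`, `g1_maternal`, `s_paternal`, `g1_paternal`.
#' @param fdr FDR threshold (default 0.05).
#' @return Island data frame with `sign`, `chisq`, `p_value`, `q_value`,
#'   restricted to significant islands.
#' @export
call_ards <- function(maternal, paternal, mode = c("ard", "core"),
                      counts, fdr = 0.05) {
  mode <- match.arg(mode)
  params <- ard_island_params(mode)
  stopifnot(maternal$window == paternal$window,
            identical(names(maternal$values), names(paternal$values)))
  if (maternal$window != params$bin_size) {
    stop("timing tracks must be binned at ", params$bin_size, " bp")
  }
  need <- c("s_maternal", "g1_maternal", "s_paternal", "g1_paternal")
  if (!all(need %in% names(counts))) {
    stop("counts must contain tracks: ", paste(need, collapse = ", "))
  }
  diff_vals <- mapply(function(m, p) m - p, maternal$values,
                      paternal$values, SIMPLIFY = FALSE)
  abs_track <- signal_track(lapply(diff_vals, abs), maternal$window)
  islands <- call_islands(abs_track, params)
  if (nrow(islands) == 0L) {
    islands$sign <- character(); islands$chisq <- numeric()
    islands$p_value <- numeric(); islands$q_value <- numeric()
    return(islands)
  }
  sum_over <- function(track, ch, start, end) {
    i0 <- start %/% track$window + 1L
    i1 <- end %/% track$window
    sum(track$values[[ch]][i0:i1], na.rm = TRUE)
  }
  n <- nrow(islands)
  islands$sign <- vapply(seq_len(n), function(i) {
    ch <- islands$chrom[i]
    i0 <- islands$start[i] %/% maternal$window + 1L
    i1 <- islands$end[i] %/% maternal$window
    d <- mean(diff_vals[[ch]][i0:i1], na.rm = TRUE)
    if (d >= 0) "+" else "-"
  }, character(1L))
  stat <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ch <- islands$chrom[i]; s0 <- islands$start[i]; e0 <- islands$end[i]
    tab <- matrix(c(sum_over(counts$s_maternal, ch, s0, e0),
                    sum_over(counts$g1_maternal, ch, s0, e0),
                    sum_over(counts$s_paternal, ch, s0, e0),
                    sum_over(counts$g1_paternal, ch, s0, e0)),
                  nrow = 2L)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    fit <- chisq_2x2(tab)
    stat[i] <- fit$statistic
    p[i] <- fit$p_value
  }
  dropped <- is.na(p)
  if (any(dropped)) {
    warning(sum(dropped), " island(s) without usable count data dropped")
  }
  islands <- islands[!dropped, , drop = FALSE]
  islands$chisq <- stat[!dropped]
  islands$p_value <- p[!dropped]
  islands$q_value <- p.adjust(islands$p_value, method = "BH")
  islands <- islands[islands$q_value < fdr, , drop = FALSE]
  rownames(islands) <- NULL
  islands
}
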