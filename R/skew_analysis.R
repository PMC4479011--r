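# Nucleotide-composition machinery: sliding-window densities, G/C and A/T
# skew, orientation-adjusted summit profiles, k-means profile clustering
# and summit composition histograms.
#
# Window values are assigned to the window *start* position throughout.

#' Sliding-window letter density
#'
#' `value[i] = count(letters in seq[i, i + window)) / window`, step
#' positions only.  N counts as absence of every letter.
#'
#' @param seq Uppercase nucleotide string.
#' @param letters Subset of `c("A","C","G","T")` to count.
#' @param window Window size in bp (<= sequence length).
#' @param step Step between window starts in bp.
#' @return Numeric vector of densities in \[0, 1\].
#' @export
window_density <- function(seq, letters, window = 50L, step = 1L) {
  n <- nchar(seq)
  if (window > n) stop("window larger than sequence")
  counts <- as.vector(Biostrings::letterFrequencyInSlidingView(
    Biostrings::DNAString(seq), window, paste(letters, collapse = "")))
  v <- counts / window
  v[seq.int(1L, length(v), by = step)]
}

#' Sliding-window composition skew
#'
#' G/C skew is `(G - C) / (G + C)` per window; A/T skew is
#' `(A - T) / (A + T)`.  Windows where the pair is absent give `NA`.
#'
#' @param seq Uppercase nucleotide string.
#' @param pair `"GC"` or `"AT"`.
#' @param window Window size in bp.
#' @param step Step between window starts.
#' @return Numeric vector of skew values in \[-1, 1\] (or NA).
#' @export
skew_track <- function(seq, pair = c("GC", "AT"), window = 50L, step = 1L) {
  pair <- match.arg(pair)
  n <- nchar(seq)
  if (window > n) stop("window larger than sequence")
  l1 <- substr(pair, 1L, 1L)
  l2 <- substr(pair, 2L, 2L)
  dna <- Biostrings::DNAString(seq)
  x <- as.vector(Biostrings::letterFrequencyInSlidingView(dna, window, l1))
  y <- as.vector(Biostrings::letterFrequencyInSlidingView(dna, window, l2))
  s <- (x - y) / (x + y)
  s[x + y == 0] <- NA_real_
  s[seq.int(1L, length(s), by = step)]
}

# Absolute summit coordinate of each peak (0-based)
peak_summits <- function(peaks) {
  if (!"summit" %in% names(peaks) || anyNA(peaks$summit)) {
    return(peaks$start + (peaks$end - peaks$start) %/% 2L)
  }
  peaks$start + peaks$summit
}

#' Decide peak orientation from central G versus C content
#'
#' A peak is tagged `flip = TRUE` when its central window (summit +/-
#' `center_width/2`) contains fewer Gs than Cs; ties keep the reference
#' orientation.  Peaks whose central window leaves the chromosome are
#' dropped with a warning.
#'
#' @param peaks Peak data frame (uses `summit` when present, else the
#'   interval midpoint).
#' @param genome Named character vector of sequences.
#' @param center_width Width of the central window in bp (default 1000).
#' @return `peaks` restricted to usable rows, with a logical `flip`
#'   column added.
#' @export
orient_profiles <- function(peaks, genome, center_width = 1000L) {
  peaks <- as.data.frame(peaks)
  lens <- genome_lengths(genome)
  s <- peak_summits(peaks)
  half <- center_width %/% 2L
  lo <- s - half
  hi <- lo + center_width           # half-open [lo, hi)
  ok <- lo >= 0L & hi <= lens[peaks$chrom]
  if (any(!ok)) {
    warning(sum(!ok), " peak(s) too close to a chromosome edge excluded")
  }
  peaks <- peaks[ok, , drop = FALSE]
  lo <- lo[ok]; hi <- hi[ok]
  win <- substring(genome[peaks$chrom], lo + 1L, hi)
  freq <- Biostrings::letterFrequency(Biostrings::DNAStringSet(win),
                                      c("G", "C"))
  peaks$flip <- freq[, "G"] < freq[, "C"]
  rownames(peaks) <- NULL
  peaks
}

# Sequence of width `width` centred on each peak summit, reverse
# complemented where flip is TRUE; NULL rows for out-of-bounds peaks.
summit_sequences <- function(peaks, genome, width, flip = NULL) {
  lens <- genome_lengths(peaks_genome <- genome)
  s <- peak_summits(peaks)
  half <- width %/% 2L
  lo <- s - half
  hi <- lo + width
  ok <- lo >= 0L & hi <= lens[peaks$chrom]
  seqs <- rep(NA_character_, nrow(peaks))
  seqs[ok] <- substring(genome[peaks$chrom[ok]], lo[ok] + 1L, hi[ok])
  if (!is.null(flip)) {
    fl <- which(ok & flip)
    for (i in fl) seqs[i] <- revcomp(seqs[i])
  }
  seqs
}

#' Matrix of per-peak composition profiles around summits
#'
#' @param peaks Peak data frame; when `oriented = TRUE` the peaks are first
#'   passed through [orient_profiles()] and flipped peaks are reverse
#'   complemented.
#' @param genome Named character vector of sequences.
#' @param width Extracted width centred on the summit, in bp.
#' @param type `"density"` (of `letters`) or `"skew"` (of `pair`).
#' @param letters,pair Composition target, as in [window_density()] /
#'   [skew_track()].
#' @param window,step Sliding-window parameters.
#' @param oriented Apply the central-window G-vs-C orientation rule.
#' @param center_width Central window for orientation.
#' @return Numeric matrix, one row per usable peak (rownames = peak ids
#'   when available).
#' @export
summit_profiles <- function(peaks, genome, width = 1000L,
                            type = c("density", "skew"), letters = "G",
                            pair = "GC", window = 50L, step = 1L,
                            oriented = TRUE, center_width = 1000L) {
  type <- match.arg(type)
  peaks <- as.data.frame(peaks)
  if (oriented) {
    peaks <- orient_profiles(peaks, genome, center_width)
    flip <- peaks$flip
  } else {
    flip <- rep(FALSE, nrow(peaks))
  }
  seqs <- summit_sequences(peaks, genome, width, flip)
  ok <- !is.na(seqs)
  if (any(!ok)) {
    warning(sum(!ok), " peak(s) too close to a chromosome edge excluded")
  }
  peaks <- peaks[ok, , drop = FALSE]
  seqs <- seqs[ok]
  prof <- t(vapply(seqs, function(s) {
    if (type == "density") window_density(s, letters, window, step)
    else skew_track(s, pair, window, step)
  }, numeric(length(seq.int(1L, width - window + 1L, by = step)))))
  rownames(prof) <- if ("peak_id" %in% names(peaks)) peaks$peak_id else NULL
  prof
}

#' Mean adjusted-skew profile for efficiency strata
#'
#' Peaks are ranked by `enrichment`; for each stratum (top N), peaks are
#' orientation-adjusted and their skew profiles averaged position-wise
#' (missing windows excluded from the mean).
#'
#' @param peaks Peak data frame with an `enrichment` column.
#' @param genome Named character vector of sequences.
#' @param strata Integer vector of top-N stratum sizes.
#' @param width Profile width centred on the summit.
#' @param pair `"GC"` or `"AT"`.
#' @param window,step,center_width See [summit_profiles()].
#' @return Numeric matrix, one row per stratum (rownames `"top_N"`).
#' @export
stratified_skew_profile <- function(peaks, genome, strata, width = 5000L,
                                    pair = "GC", window = 50L, step = 1L,
                                    center_width = 1000L) {
  peaks <- as.data.frame(peaks)
  if (!"enrichment" %in% names(peaks)) stop("peaks need an enrichment column")
  if (any(strata > nrow(peaks))) stop("stratum larger than the peak list")
  ord <- peaks[order(-peaks$enrichment), , drop = FALSE]
  out <- matrix(NA_real_, nrow = length(strata),
                ncol = length(seq.int(1L, width - window + 1L, by = step)),
                dimnames = list(paste0("top_", strata), NULL))
  for (i in seq_along(strata)) {
    sub <- ord[seq_len(strata[i]), , drop = FALSE]
    prof <- suppressWarnings(
      summit_profiles(sub, genome, width, type = "skew", pair = pair,
                      window = window, step = step, oriented = TRUE,
                      center_width = center_width))
    out[i, ] <- colMeans(prof, na.rm = TRUE)
  }
  out
}

#' Histogram of per-peak summit G frequency
#'
#' One G fraction per peak, measured on the reference strand over a window
#' centred on the summit; binned at 0.01.
#'
#' @param peaks Peak data frame.
#' @param genome Named character vector of sequences.
#' @param width Window width (default 100 bp).
#' @param top_n Restrict to the top N peaks by `enrichment` (default all).
#' @return List with `values` (per-peak G fraction), `breaks` and
#'   `counts` (0.01 bins).
#' @export
summit_g_histogram <- function(peaks, genome, width = 100L, top_n = NULL) {
  peaks <- as.data.frame(peaks)
  if (!is.null(top_n)) {
    if (!"enrichment" %in% names(peaks)) stop("top_n needs an enrichment column")
    if (top_n > nrow(peaks)) stop("top_n larger than the peak list")
    peaks <- peaks[order(-peaks$enrichment), , drop = FALSE][seq_len(top_n), ]
  }
  seqs <- summit_sequences(peaks, genome, width)
  seqs <- seqs[!is.na(seqs)]
  g <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs), "G")[, 1L]
  vals <- as.numeric(g) / width
  breaks <- seq(0, 1, by = 0.01)
  counts <- tabulate(pmin(findInterval(vals, breaks, rightmost.closed = TRUE),
                          length(breaks) - 1L), nbins = length(breaks) - 1L)
  list(values = vals, breaks = breaks, counts = counts)
}

# k-means++ seeding
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j + 1L, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j + 1L, ])^2))
  }
  centers
}

#' Cluster composition profiles with k-means
#'
#' Euclidean k-means with k-means++ initialisation, best of `restarts`
#' runs by total within-cluster sum of squares.  Missing values are
#' imputed by the profile (row) mean.  Clusters are relabelled in order of
#' decreasing mean central value (central fifth of the positions) so that
#' labels are comparable across runs.
#'
#' @param profiles Numeric matrix, one profile per row.
#' @param k Number of clusters (default 4).
#' @param seed Optional RNG seed for reproducibility.
#' @param restarts Number of k-means++ restarts.
#' @return List with `labels`, `centers`, `tot_withinss`.
#' @export
cluster_g_profiles <- function(profiles, k = 4L, seed = NULL, restarts = 10L) {
  x <- as.matrix(profiles)
  if (k > nrow(x)) stop("k larger than the number of profiles")
  if (anyNA(x)) {
    rm_ <- rowMeans(x, na.rm = TRUE)
    for (i in seq_len(nrow(x))) x[i, is.na(x[i, ])] <- rm_[i]
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- tryCatch(
      kmeans(x, centers = kmeanspp_centers(x, k), iter.max = 100L),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  nc <- ncol(x)
  central <- seq.int(max(1L, floor(nc * 0.4)), ceiling(nc * 0.6))
  strength <- rowMeans(best$centers[, central, drop = FALSE])
  ord <- order(-strength)
  relabel <- match(seq_len(k), ord)
  list(labels = relabel[best$cluster],
       centers = best$centers[ord, , drop = FALSE],
       tot_withinss = best$tot.withinss)
}
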