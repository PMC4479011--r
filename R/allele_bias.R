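# Per-origin allele-specific read counting and bias classification.
#
# The allele-informative signal for an origin peak is the sum of the
# per-haplotype allele depths (AD) over the phased heterozygous SNPs it
# contains.  Origins with fewer than `min_reads` haplotype-assignable
# reads are non-analysable; the remainder are tested for unequal usage of
# the two homologues with a two-sided exact binomial test against 0.5 and
# classified at a Benjamini-Hochberg FDR.

#' Sum allele depths of phased SNPs within each peak
#'
#' Indels are excluded; only single-nucleotide variants contribute to the
#' counts.  A SNP at position `p` belongs to a peak `[start, end)` iff
#' `start <= p < end`.  Reads spanning two SNPs are counted once per SNP
#' (the counts are sums of per-SNP depths, not de-duplicated reads).
#'
#' @param peaks Interval data frame of origin peaks; a `peak_id` column is
#'   added from `name` (or the row index) when absent.
#' @param variants Phased-variant data frame (see
#'   [load_phased_variants()]).
#' @return Data frame with one row per peak: `peak_id`, `chrom`, `start`,
#'   `end`, `n1`, `n2`, `n_snps`.
#' @export
count_allelic_reads <- function(peaks, variants) {
  peaks <- as.data.frame(peaks)
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- if ("name" %in% names(peaks) &&
                         !anyDuplicated(peaks$name) && !all(peaks$name == "."))
      peaks$name else sprintf("peak_%d", seq_len(nrow(peaks)))
  }
  snv <- variants[!variants$is_indel, , drop = FALSE]
  n1 <- integer(nrow(peaks)); n2 <- integer(nrow(peaks))
  n_snps <- integer(nrow(peaks))
  if (nrow(snv) > 0L && nrow(peaks) > 0L) {
    pg <- intervals_to_granges(peaks)
    vg <- GenomicRanges::GRanges(snv$chrom,
                                 IRanges::IRanges(snv$pos + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(pg, vg)
    pi <- S4Vectors::queryHits(ov); vi <- S4Vectors::subjectHits(ov)
    if (length(pi) > 0L) {
      agg1 <- tapply(snv$ad1[vi], pi, sum)
      agg2 <- tapply(snv$ad2[vi], pi, sum)
      cnt <- tapply(vi, pi, length)
      idx <- as.integer(names(agg1))
      n1[idx] <- as.integer(agg1)
      n2[idx] <- as.integer(agg2)
      n_snps[idx] <- as.integer(cnt)
    }
  }
  data.frame(peak_id = peaks$peak_id, chrom = peaks$chrom,
             start = peaks$start, end = peaks$end,
             n1 = n1, n2 = n2, n_snps = n_snps,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided exact binomial p-value for allelic counts
#'
#' `p = min(1, 2 * min(P(X <= n1), P(X >= n1)))` with
#' `X ~ Binomial(n1 + n2, 0.5)`.
#'
#' @param n1,n2 Non-negative integer vectors of per-haplotype read counts.
#' @return Numeric vector of p-values (NA where `n1 + n2 == 0`).
#' @export
binom_allele_p <- function(n1, n2) {
  n <- n1 + n2
  lower <- pbinom(n1, n, 0.5)
  upper <- pbinom(n1 - 1L, n, 0.5, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[n == 0L] <- NA_real_
  p
}

#' Classify origins by allelic bias
#'
#' Origins with `n1 + n2 < min_reads` are `non_analysable` and excluded
#' from testing.  The rest receive a two-sided exact binomial p-value
#' ([binom_allele_p()]); Benjamini-Hochberg adjustment is applied over the
#' analysable origins only, and `q < fdr` defines `allele_biased`.
#'
#' @param records Output of [count_allelic_reads()] (needs `n1`, `n2`).
#' @param min_reads Minimum haplotype-assignable reads (default 50).
#' @param fdr False-discovery-rate threshold (default 0.05).
#' @return `records` with added columns `p_value`, `q_value`,
#'   `log2_ratio` (`log2(n1/n2)`; infinite when one side is 0) and
#'   `class`.
#' @export
test_allele_bias <- function(records, min_reads = 50L, fdr = 0.05) {
  if (min_reads < 1L) stop("min_reads must be >= 1")
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  records <- as.data.frame(records)
  n <- records$n1 + records$n2
  analysable <- n >= min_reads
  p <- rep(NA_real_, nrow(records))
  q <- rep(NA_real_, nrow(records))
  p[analysable] <- binom_allele_p(records$n1[analysable],
                                  records$n2[analysable])
  q[analysable] <- p.adjust(p[analysable], method = "BH")
  cls <- rep("non_analysable", nrow(records))
  cls[analysable] <- ifelse(q[analysable] < fdr, "allele_biased",
                            "analysable_unbiased")
  records$p_value <- p
  records$q_value <- q
  records$log2_ratio <- log2(records$n1 / records$n2)
  records$class <- cls
  records
}

#' Compare polymorphic motif content with origin efficiency
#'
#' For allele-biased origins whose two haplotypes carry unequal counts of
#' a motif (because variants create or destroy copies), tallies how often
#' the motif-richer allele is also the more efficient allele.  The
#' `restrict` modes reproduce the usual presentation: all polymorphic
#' pairs; pairs whose total motif count is a single copy; and single-copy
#' pairs additionally free of a second motif kind.
#'
#' @param records Allele-bias records (rows are the origins to compare;
#'   typically the `allele_biased` subset) with `peak_id`, `n1`, `n2`.
#' @param counts1,counts2 Named numeric vectors: motif count per origin on
#'   haplotype 1 / haplotype 2 sequence; names are `peak_id`s and must
#'   cover all records.
#' @param restrict `"any"`, `"single_motif"`, or
#'   `"single_motif_no_other"`.
#' @param other1,other2 Counts of the other motif kind (required for
#'   `"single_motif_no_other"`).
#' @return List with the tallies (`n_pairs`, `most_efficient`,
#'   `least_efficient`) and the per-origin table.
#' @export
compare_polymorphic_motifs <- function(records, counts1, counts2,
                                       restrict = c("any", "single_motif",
                                                    "single_motif_no_other"),
                                       other1 = NULL, other2 = NULL) {
  restrict <- match.arg(restrict)
  ids <- as.character(records$peak_id)
  missing1 <- setdiff(ids, names(counts1))
  missing2 <- setdiff(ids, names(counts2))
  if (length(missing1) || length(missing2)) {
    stop("motif counts missing for origin(s): ",
         paste(head(unique(c(missing1, missing2)), 5L), collapse = ", "))
  }
  c1 <- counts1[ids]; c2 <- counts2[ids]
  keep <- c1 != c2
  if (restrict != "any") keep <- keep & pmax(c1, c2) == 1
  if (restrict == "single_motif_no_other") {
    if (is.null(other1) || is.null(other2)) {
      stop("other1/other2 counts required for restrict = 'single_motif_no_other'")
    }
    keep <- keep & (other1[ids] + other2[ids]) == 0
  }
  keep <- keep & records$n1 != records$n2   # need a defined efficiency order
  sub <- records[keep, , drop = FALSE]
  richer <- ifelse(c1[keep] > c2[keep], 1L, 2L)
  efficient <- ifelse(sub$n1 > sub$n2, 1L, 2L)
  tab <- data.frame(peak_id = sub$peak_id,
                    count_hap1 = as.numeric(c1[keep]),
                    count_hap2 = as.numeric(c2[keep]),
                    richer_hap = richer, efficient_hap = efficient,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(restrict = restrict,
       n_pairs = nrow(tab),
       most_efficient = sum(richer == efficient),
       least_efficient = sum(richer != efficient),
       table = tab)
}

#' Per-origin motif counts on one haplotype
#'
#' Counts motif hits whose interval overlaps each origin, scanning the
#' supplied haplotype genome.
#'
#' @param peaks Peak data frame with `peak_id` (or `name`) column.
#' @param genome Haplotype genome (named character vector).
#' @param kind Motif kind passed to [scan_motifs()].
#' @param ... Extra scanner parameters.
#' @return Named integer vector of counts keyed by `peak_id`.
#' @export
origin_motif_counts <- function(peaks, genome, kind = "G4", ...) {
  peaks <- as.data.frame(peaks)
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak_%d", seq_len(nrow(peaks)))
  }
  hits <- scan_motifs(genome, kind, ...)
  n <- count_interval_overlaps(peaks, hits)
  setNames(as.integer(n), peaks$peak_id)
}
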