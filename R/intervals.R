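#' Construct a genomic-interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `name`, `score` and `strand`, with 0-based half-open coordinates.  This
#' constructor fills defaults and validates the coordinate invariants.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open (`start < end`).
#' @param name Optional labels (default `"."`).
#' @param score Optional numeric scores (default 0).
#' @param strand Strand characters among `+`, `-`, `.` (default `.`).
#' @param genome Optional genome (named character vector of sequences); when
#'   supplied, chromosome membership and bounds are checked.
#' @return A `data.frame` with the six BED columns.
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = 0,
                              strand = ".", genome = NULL) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df, genome)
  df
}

validate_intervals <- function(df, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start < 0)) stop("negative interval start")
  if (any(df$start >= df$end)) stop("interval start must be < end")
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    bad <- !(df$chrom %in% names(lens))
    if (any(bad)) {
      stop("interval on chromosome absent from genome: ",
           paste(unique(df$chrom[bad]), collapse = ", "))
    }
    if (any(df$end > lens[df$chrom])) stop("interval extends past chromosome end")
  }
  invisible(df)
}

#' Convert an interval table to a GRanges object
#'
#' Internal shim between the package's 0-based half-open tables and the
#' 1-based closed convention of GenomicRanges, used for overlap machinery.
#'
#' @param df Interval data frame.
#' @return A [GenomicRanges::GRanges] object.
#' @keywords internal
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Number of overlapping features per query interval
#'
#' @param query,feature Interval data frames.
#' @return Integer vector: for each query row, the number of feature rows it
#'   overlaps by at least 1 bp.
#' @keywords internal
count_interval_overlaps <- function(query, feature) {
  out <- integer(nrow(query))
  if (nrow(feature) == 0L) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fi <- which(feature$chrom == ch)
    if (length(fi) == 0L) next
    out[qi] <- IRanges::countOverlaps(
      IRanges::IRanges(query$start[qi] + 1L, query$end[qi]),
      IRanges::IRanges(feature$start[fi] + 1L, feature$end[fi]))
  }
  out
}

#' Merge overlapping intervals
#'
#' @param df Interval data frame.
#' @return Interval data frame of the merged (reduced) regions, sorted.
#' @keywords internal
reduce_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(intervals_to_granges(df))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Total number of bases covered by a set of intervals
#' @param df Interval data frame.
#' @return Number of distinct covered bases.
#' @keywords internal
covered_bases <- function(df) {
  r <- reduce_intervals(df)
  sum(r$end - r$start)
}

#' Jaccard index between two interval sets
#'
#' Base-pair intersection over union, after merging each set.
#'
#' @param a,b Interval data frames.
#' @return Scalar in \[0, 1\].
#' @export
interval_jaccard <- function(a, b) {
  ra <- reduce_intervals(a)
  rb <- reduce_intervals(b)
  if (nrow(ra) == 0L && nrow(rb) == 0L) return(1)
  ga <- intervals_to_granges(ra)
  gb <- intervals_to_granges(rb)
  inter <- sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(IRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}
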