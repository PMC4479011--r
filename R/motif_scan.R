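# Non-B-DNA sequence annotation: G-quadruplex (G4) motifs, the mixed C/G
# four-tract "intermolecular G4" (iG4) pattern, and a simplified
# mirror-repeat triplex candidate detector.
#
# G4 scanning uses an anchor dynamic programme that is exactly equivalent
# to taking every match of G{t,}(loop G{t,}){c-1} at every feasible start
# position and merging overlapping matches into maximal regions.  Note the
# loop class [ACGT] admits G itself, so one long G-run can host several
# tracts; the DP accounts for that.

#' G-quadruplex scan parameters
#'
#' Defaults are the classical quadparser settings: four tracts of at least
#' three Gs separated by loops of one to seven bases.
#'
#' @param tract_len Minimum G-tract length (>= 2).
#' @param loop_min,loop_max Loop length bounds (loop_min >= 1).
#' @param tract_count Number of tracts required (>= 4 by default).
#' @return List of class `g4_params`.
#' @export
g4_params <- function(tract_len = 3L, loop_min = 1L, loop_max = 7L,
                      tract_count = 4L) {
  stopifnot(tract_len >= 2L, loop_min >= 1L, loop_max >= loop_min,
            tract_count >= 2L)
  structure(list(tract_len = as.integer(tract_len),
                 loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 tract_count = as.integer(tract_count)),
            class = "g4_params")
}

# Maximal runs of `letter` of length >= len: matrix of 0-based [start, end)
letter_runs <- function(seq, letter, len) {
  m <- gregexpr(sprintf("%s{%d,}", letter, len), seq)[[1L]]
  if (m[1L] == -1L) return(cbind(start = integer(), end = integer()))
  s <- as.integer(m) - 1L
  cbind(start = s, end = s + attr(m, "match.length"))
}

# Dynamic programme over tract-start anchors.  An anchor is any position
# where a tract (>= tract_len consecutive `letter`s) can start; a match is
# a chain of `tract_count` anchors where consecutive tract start positions
# differ by tract_len + loop_min .. run_remaining + loop_max and the
# intervening loop bases contain no N.  Because the loop class admits the
# tract letter itself, long runs can host several tracts; the anchor DP
# handles that case exactly.  Returns, per anchor, the op-best (max or
# min) end over all chains of `tract_count` tracts starting there (NA when
# none exists).
g4_anchor_ends <- function(seq, letter, params, op = max) {
  t <- params$tract_len
  runs <- letter_runs(seq, letter, t)
  if (nrow(runs) == 0L) return(NULL)
  pos <- unlist(lapply(seq_len(nrow(runs)), function(i)
    seq.int(runs[i, 1L], runs[i, 2L] - t)))
  r <- unlist(lapply(seq_len(nrow(runs)), function(i)
    runs[i, 2L] - seq.int(runs[i, 1L], runs[i, 2L] - t)))
  mN <- gregexpr("N", seq, fixed = TRUE)[[1L]]
  posN <- if (mN[1L] == -1L) integer() else as.integer(mN) - 1L
  n_limit <- if (length(posN)) {
    idx <- findInterval(pos + t - 0.5, posN) + 1L
    ifelse(idx <= length(posN), posN[idx], Inf)
  } else rep(Inf, length(pos))
  lo_j <- pos + t + params$loop_min
  hi_j <- pmin(pos + r + params$loop_max, n_limit)
  lo_i <- findInterval(lo_j - 0.5, pos) + 1L
  hi_i <- findInterval(hi_j, pos)
  cur <- if (identical(op, max)) as.numeric(pos + r) else as.numeric(pos + t)
  for (s in seq_len(params$tract_count - 1L)) {
    nxt <- rep(NA_real_, length(pos))
    for (i in seq_along(pos)) {
      if (lo_i[i] <= hi_i[i]) {
        v <- cur[seq.int(lo_i[i], hi_i[i])]
        v <- v[!is.na(v)]
        if (length(v)) nxt[i] <- op(v)
      }
    }
    cur <- nxt
  }
  keep <- !is.na(cur)
  if (!any(keep)) return(NULL)
  cbind(start = pos[keep], end = as.integer(cur[keep]))
}

# Merged maximal G4 regions on one strand (union of all raw matches)
g4_regions <- function(seq, letter, params) {
  spans <- g4_anchor_ends(seq, letter, params, op = max)
  if (is.null(spans)) return(cbind(start = integer(), end = integer()))
  red <- reduce_intervals(data.frame(chrom = "s", start = spans[, 1L],
                                     end = spans[, 2L]))
  cbind(start = red$start, end = red$end)
}

#' Find G-quadruplex-forming sequences
#'
#' Scans one uppercase sequence for the canonical G4 pattern (four or more
#' G-tracts of length >= 3 separated by 1-7 nt loops) on the plus strand
#' and the complementary C-pattern on the minus strand.  Overlapping raw
#' matches on a strand are merged into maximal regions.  Ambiguous bases
#' (N) never count toward tracts or loops.
#'
#' @param seq Uppercase nucleotide string over `{A,C,G,T,N}`.
#' @param params A [g4_params()] object.
#' @return Data frame with columns `start`, `end` (0-based half-open),
#'   `strand`, `kind` (`"G4"`), `detail` (matched subsequence), sorted by
#'   start.
#' @export
find_g4 <- function(seq, params = g4_params()) {
  out <- list()
  for (st in c("+", "-")) {
    letter <- if (st == "+") "G" else "C"
    h <- g4_regions(seq, letter, params)
    if (nrow(h) > 0L) {
      out[[st]] <- data.frame(start = h[, 1L], end = h[, 2L], strand = st,
                              stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), strand = character())
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits$kind <- rep("G4", nrow(hits))
  hits$detail <- if (nrow(hits)) substring(seq, hits$start + 1L, hits$end)
                 else character()
  hits
}

# 0-based start positions of every CCC or GGG triplet occurrence
ig4_anchors <- function(seq) {
  m <- gregexpr("(?=CCC|GGG)", seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer())
  as.integer(m) - 1L
}

# Dynamic programme over anchors: best end (max or min) of a chain of
# exactly `steps` further anchors, consecutive anchors separated by a
# 1-7 letter gap (any letter, per the pattern's [A-Z] loop class).
ig4_chain_ends <- function(anchors, steps = 3L, op = max) {
  n <- length(anchors)
  e <- anchors + 3L  # end of the anchor's own triplet
  cur <- as.numeric(e)
  lo <- findInterval(anchors + 3.5, anchors) + 1L
  hi <- findInterval(anchors + 10.5, anchors)
  for (s in seq_len(steps)) {
    nxt <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (lo[i] <= hi[i]) {
        v <- cur[seq.int(lo[i], hi[i])]
        v <- v[!is.na(v)]
        if (length(v)) nxt[i] <- op(v)
      }
    }
    cur <- nxt
  }
  cur
}

#' Find intermolecular-G4-forming sequences
#'
#' Matches the four-tract mixed C/G pattern
#' `(CCC|GGG)([A-Z]{1,7}(CCC|GGG)){3}` (any letter, including N, is
#' admitted in the spacers, following the pattern's literal letter class),
#' merges overlapping matches into maximal regions, and removes every
#' region that overlaps a G4 hit on either strand by at least 1 bp.
#'
#' @param seq Uppercase nucleotide string.
#' @param g4_hits G4 hits for the same sequence, from [find_g4()]; computed
#'   on the fly when omitted.
#' @return Data frame like [find_g4()], with `kind = "iG4"` and strand ".".
#' @export
find_ig4 <- function(seq, g4_hits = NULL) {
  if (is.null(g4_hits)) g4_hits <- find_g4(seq)
  anchors <- ig4_anchors(seq)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), kind = character(),
                      detail = character(), stringsAsFactors = FALSE)
  if (length(anchors) < 4L) return(empty)
  ends <- ig4_chain_ends(anchors, steps = 3L, op = max)
  keep <- !is.na(ends)
  if (!any(keep)) return(empty)
  raw <- data.frame(chrom = "seq", start = anchors[keep],
                    end = as.integer(ends[keep]))
  merged <- reduce_intervals(raw)
  if (nrow(g4_hits) > 0L) {
    g4 <- data.frame(chrom = "seq", start = g4_hits$start, end = g4_hits$end)
    hit <- count_interval_overlaps(merged, g4) > 0L
    merged <- merged[!hit, , drop = FALSE]
  }
  if (nrow(merged) == 0L) return(empty)
  data.frame(start = merged$start, end = merged$end, strand = ".",
             kind = "iG4",
             detail = substring(seq, merged$start + 1L, merged$end),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find triplex-forming candidate sequences (simplified detector)
#'
#' A deliberately simple approximation of dynamic-programming triplex
#' scanners: candidates are mirror repeats (arm length >=
#' `ceiling(min_core/2)`, loop <= `loop_max`) whose arms are at least
#' `purity` purine or pyrimidine.  A type code 0-7 is assigned from three
#' binary attributes: parallel (pyrimidine third strand, types 0-3) versus
#' antiparallel (purine third strand, types 4-7); which arm donates the
#' third strand (the more purine-rich arm; 5' on ties); and the strand
#' carrying the purine-rich tract.  Overlapping candidates of the same
#' type are merged.
#'
#' @param seq Uppercase nucleotide string.
#' @param min_core Minimum core size in bp; the minimum arm is half of it.
#' @param loop_max Maximum loop (spacer) length in bp.
#' @param purity Minimum purine (or pyrimidine) fraction of the arms.
#' @param arm_max Cap on the arm extension.
#' @return Data frame with `start`, `end`, `strand`, `kind = "triplex"`,
#'   `triplex_type` (0-7) and `detail`.
#' @export
find_triplex_candidates <- function(seq, min_core = 15L, loop_max = 8L,
                                    purity = 0.9, arm_max = 200L) {
  n <- nchar(seq)
  arm_min <- as.integer(ceiling(min_core / 2))
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), kind = character(),
                      triplex_type = integer(), detail = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L * arm_min) return(empty)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  acgt <- x %in% c("A", "C", "G", "T")
  pur <- x %in% c("A", "G")
  cum_pur <- cumsum(pur)
  cand <- list()
  for (g in 0:loop_max) {
    # l = 1-based index of the inner end of the left arm
    l_all <- seq_len(n - g - 1L)
    alive <- l_all
    armlen <- integer(length(l_all))
    names(armlen) <- l_all
    d <- 0L
    while (length(alive) > 0L && d < arm_max) {
      li <- alive - d
      ri <- alive + g + 1L + d
      okpos <- li >= 1L & ri <= n
      li <- li[okpos]; ri <- ri[okpos]; alive <- alive[okpos]
      m <- x[li] == x[ri] & acgt[li] & acgt[ri]
      alive <- alive[m]
      armlen[as.character(alive)] <- d + 1L
      d <- d + 1L
    }
    ls <- as.integer(names(armlen)[armlen >= arm_min])
    for (l in ls) {
      k <- unname(armlen[as.character(l)])
      a1s <- l - k + 1L; a1e <- l                 # left arm, 1-based closed
      a2s <- l + g + 1L; a2e <- l + g + k
      p1 <- (cum_pur[a1e] - if (a1s > 1L) cum_pur[a1s - 1L] else 0L) / k
      p2 <- (cum_pur[a2e] - if (a2s > 1L) cum_pur[a2s - 1L] else 0L) / k
      pfrac <- (p1 + p2) / 2
      is_pur <- pfrac >= purity
      is_pyr <- (1 - pfrac) >= purity
      if (!is_pur && !is_pyr) next
      antiparallel <- is_pur               # purine third strand
      donor3 <- p2 > p1                    # more purine-rich arm donates
      minus <- is_pyr                      # purine-rich tract on minus strand
      type <- 4L * antiparallel + 2L * donor3 + 1L * minus
      cand[[length(cand) + 1L]] <-
        c(start = a1s - 1L, end = a2e, type = type)
    }
  }
  if (length(cand) == 0L) return(empty)
  cm <- do.call(rbind, cand)
  out <- list()
  for (tp in sort(unique(cm[, "type"]))) {
    sub <- cm[cm[, "type"] == tp, , drop = FALSE]
    merged <- reduce_intervals(data.frame(chrom = "seq",
                                          start = sub[, "start"],
                                          end = sub[, "end"]))
    out[[length(out) + 1L]] <-
      data.frame(start = merged$start, end = merged$end,
                 strand = if (tp %% 2L == 0L) "+" else "-",
                 kind = "triplex", triplex_type = as.integer(tp),
                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$triplex_type), , drop = FALSE]
  rownames(res) <- NULL
  res$detail <- substring(seq, res$start + 1L, res$end)
  res
}

#' Scan a whole genome for a motif kind
#'
#' @param genome Named character vector of sequences.
#' @param kind One of `"G4"`, `"iG4"`, `"triplex"`.
#' @param ... Passed to the per-sequence scanner.
#' @return Interval data frame with a `chrom` column prepended.
#' @export
scan_motifs <- function(genome, kind = c("G4", "iG4", "triplex"), ...) {
  kind <- match.arg(kind)
  res <- lapply(names(genome), function(ch) {
    h <- switch(kind,
                G4 = find_g4(genome[[ch]], ...),
                iG4 = find_ig4(genome[[ch]], ...),
                triplex = find_triplex_candidates(genome[[ch]], ...))
    if (nrow(h) > 0L) cbind(chrom = ch, h, stringsAsFactors = FALSE) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  if (length(res) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      kind = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Enumerate GC-rich k-mers and their quadruplex content
#'
#' Every k-mer position with GC fraction at least `gc_min` is reported,
#' flagged by whether it fully contains a G4 pattern match (either strand)
#' or an iG4 pattern match.  Flags refer to the raw patterns; no G4
#' subtraction is applied to the iG4 flag.
#'
#' @param genome Named character vector of sequences.
#' @param k K-mer size (default 30).
#' @param gc_min Minimum GC fraction for a k-mer to be emitted.
#' @param g4 A [g4_params()] object for the G4 flag.
#' @return Data frame with `chrom`, `start`, `end`, `gc`, `has_g4`,
#'   `has_ig4`.
#' @export
enumerate_kmers <- function(genome, k = 30L, gc_min = 0, g4 = g4_params()) {
  out <- list()
  for (ch in names(genome)) {
    seq <- genome[[ch]]
    n <- nchar(seq)
    if (k > n) stop("k larger than chromosome ", ch)
    gc <- as.vector(Biostrings::letterFrequencyInSlidingView(
      Biostrings::DNAString(seq), k, "CG")) / k
    n_kmer <- n - k + 1L
    mark_spans <- function(spans) {
      flag <- logical(n_kmer)
      if (is.null(spans) || nrow(spans) == 0L) return(flag)
      for (i in seq_len(nrow(spans))) {
        s <- spans[i, 1L]; e <- spans[i, 2L]
        if (e - s > k) next
        p0 <- max(0L, e - k); p1 <- min(s, n_kmer - 1L)
        if (p0 <= p1) flag[(p0 + 1L):(p1 + 1L)] <- TRUE
      }
      flag
    }
    g4_spans <- rbind(g4_anchor_ends(seq, "G", g4, op = min),
                      g4_anchor_ends(seq, "C", g4, op = min))
    anchors <- ig4_anchors(seq)
    ig4_spans <- NULL
    if (length(anchors) >= 4L) {
      ends_min <- ig4_chain_ends(anchors, steps = 3L, op = min)
      keep <- !is.na(ends_min)
      if (any(keep)) {
        ig4_spans <- cbind(anchors[keep], as.integer(ends_min[keep]))
      }
    }
    has_g4 <- mark_spans(g4_spans)
    has_ig4 <- mark_spans(ig4_spans)
    sel <- which(gc >= gc_min)
    if (length(sel) == 0L) next
    out[[ch]] <- data.frame(
      chrom = ch, start = sel - 1L, end = sel - 1L + k, gc = gc[sel],
      has_g4 = has_g4[sel], has_ig4 = has_ig4[sel],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gc = numeric(), has_g4 = logical(),
                      has_ig4 = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
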