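# Readers and writers for the standard formats the pipeline touches.
# Genomes are named character vectors of uppercase sequences; intervals are
# 0-based half-open data frames (see genomic_intervals()); signal tracks are
# fixed-window binned values (see signal_track()).

#' Load a genome from a FASTA file
#'
#' Sequences are uppercased and IUPAC ambiguity codes other than N are
#' collapsed to N, so downstream code only ever sees the alphabet
#' `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per chromosome.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
  names(seqs) <- nm
  seqs
}

#' Write a genome to a FASTA file
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Chromosome length table of a genome
#' @param genome Named character vector of sequences.
#' @return Named integer vector of lengths.
#' @export
genome_lengths <- function(genome) {
  setNames(nchar(genome), names(genome))
}

#' Load intervals from a BED or narrowPeak file
#'
#' BED3 to BED6 and the MACS narrowPeak dialect (10 columns; column 10 is
#' the summit offset, column 7 the fold enrichment) are accepted.  Input
#' order and the 0-based half-open coordinates are preserved.
#'
#' @param path Path to the file.
#' @param genome Optional genome used to check chromosome membership/bounds.
#' @return Interval data frame; narrowPeak input adds `summit` and
#'   `enrichment` columns.
#' @export
load_intervals <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("interval file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   comment.char = "#", stringsAsFactors = FALSE)
  nc <- ncol(df)
  if (nc < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(
    chrom = as.character(df[[1L]]),
    start = as.integer(df[[2L]]),
    end = as.integer(df[[3L]]),
    name = if (nc >= 4L) as.character(df[[4L]]) else ".",
    score = if (nc >= 5L) as.numeric(df[[5L]]) else 0,
    strand = if (nc >= 6L) as.character(df[[6L]]) else ".",
    stringsAsFactors = FALSE
  )
  if (nc >= 10L) { # narrowPeak
    out$enrichment <- as.numeric(df[[7L]])
    out$summit <- as.integer(df[[10L]])
    if (any(out$summit < 0 | out$summit >= out$end - out$start)) {
      stop("narrowPeak summit offset outside its interval")
    }
  }
  validate_intervals(out, genome)
  out
}

#' Write intervals as BED6 (or narrowPeak when summits are present)
#'
#' Tab-separated, newline-terminated, no header.  Canonical BED6 records
#' round-trip byte-identically through [load_intervals()].
#'
#' @param df Interval data frame.
#' @param path Output path.
#' @param narrowpeak Write the 10-column narrowPeak dialect (requires
#'   `summit` and `enrichment` columns).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(df, path, narrowpeak = FALSE) {
  fmt_num <- function(x) {
    vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE),
           character(1L))
  }
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  cols <- list(df$chrom, fmt_num(df$start), fmt_num(df$end), name,
               fmt_num(score), strand)
  if (narrowpeak) {
    stopifnot(all(c("summit", "enrichment") %in% names(df)))
    cols <- c(cols, list(fmt_num(df$enrichment), "-1", "-1", fmt_num(df$summit)))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Load phased heterozygous variants from a VCF file
#'
#' Only phased (`|`-separated genotype) heterozygous records are retained;
#' unphased heterozygous sites are skipped with a warning, homozygous sites
#' are dropped silently.  `hap1` is the allele left of the phase separator.
#' Per-haplotype read depths are taken verbatim from the AD FORMAT field.
#'
#' @param path Path to a VCF file (plain text or gzip).
#' @param sample Sample column to use (default: the first).
#' @return Data frame with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `hap1_allele`, `hap2_allele`, `ad1`, `ad2`, `is_indel`.
#' @export
load_phased_variants <- function(path, sample = 1L) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) == 0L) stop("no genotype records in VCF: ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample]
  ad <- vcfR::extract.gt(vcf, element = "AD")[, sample]
  if (all(is.na(ad))) stop("VCF has no AD (allele depth) FORMAT field: ", path)
  fix <- vcfR::getFIX(vcf)
  chrom <- fix[, "CHROM"]
  pos0 <- as.integer(fix[, "POS"]) - 1L
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  phased <- !is.na(gt) & grepl("|", gt, fixed = TRUE)
  idx <- strsplit(ifelse(phased, gt, "0|0"), "|", fixed = TRUE)
  a1 <- suppressWarnings(as.integer(vapply(idx, `[`, "", 1L)))
  a2 <- suppressWarnings(as.integer(vapply(idx, `[`, "", 2L)))
  het <- phased & !is.na(a1) & !is.na(a2) & a1 != a2

  unphased_het <- !phased & !is.na(gt) &
    vapply(strsplit(gt, "/", fixed = TRUE),
           function(g) length(unique(g)) > 1L, logical(1L))
  if (any(unphased_het)) {
    warning(sum(unphased_het), " unphased heterozygous record(s) skipped")
  }
  if (!any(het)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), hap1_allele = character(),
                      hap2_allele = character(), ad1 = integer(),
                      ad2 = integer(), is_indel = logical()))
  }

  allele_string <- function(i, k) {
    # allele index k (0 = REF, j = j-th ALT) at record i
    if (k == 0L) ref[i] else strsplit(alt[i], ",", fixed = TRUE)[[1L]][k]
  }
  keep <- which(het)
  depths <- strsplit(ad[keep], ",", fixed = TRUE)
  if (anyNA(ad[keep])) stop("missing AD value at phased heterozygous site")
  hap1 <- mapply(allele_string, keep, a1[keep])
  hap2 <- mapply(allele_string, keep, a2[keep])
  ad1 <- as.integer(mapply(function(d, k) d[k + 1L], depths, a1[keep]))
  ad2 <- as.integer(mapply(function(d, k) d[k + 1L], depths, a2[keep]))
  data.frame(
    chrom = chrom[keep], pos = pos0[keep], ref = ref[keep], alt = alt[keep],
    hap1_allele = hap1, hap2_allele = hap2, ad1 = ad1, ad2 = ad2,
    is_indel = nchar(hap1) != 1L | nchar(hap2) != 1L,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write phased variants as a VCF file
#'
#' Emits a minimal VCF 4.2 with GT (phased) and AD fields for one sample.
#' Assumes `ref`/`alt` name the two alleles and `hap1_allele`/`hap2_allele`
#' pick between them.
#'
#' @param variants Variant data frame as produced by
#'   [load_phased_variants()] or the simulator.
#' @param path Output path.
#' @param sample Sample name written in the header.
#' @return `path`, invisibly.
#' @export
write_phased_variants <- function(variants, path, sample = "sample1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  h1 <- ifelse(variants$hap1_allele == variants$ref, 0L, 1L)
  h2 <- ifelse(variants$hap2_allele == variants$ref, 0L, 1L)
  # AD is ordered (REF, ALT): map haplotype depths back to allele order
  ad_ref <- ifelse(h1 == 0L, variants$ad1, variants$ad2)
  ad_alt <- ifelse(h1 == 0L, variants$ad2, variants$ad1)
  rows <- paste(variants$chrom, variants$pos + 1L, ".", variants$ref,
                variants$alt, ".", "PASS", ".", "GT:AD",
                paste0(h1, "|", h2, ":", ad_ref, ",", ad_alt),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Construct a fixed-window signal track
#'
#' @param values Named list of numeric vectors, one value per window and per
#'   chromosome; `NA` marks windows without data.
#' @param window Window size in bp (> 0).
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, window) {
  stopifnot(is.list(values), !is.null(names(values)), window > 0)
  structure(list(values = lapply(values, as.numeric),
                 window = as.integer(window)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$values), "chromosome(s), window",
      x$window, "bp\n")
  for (ch in names(x$values)) {
    v <- x$values[[ch]]
    cat(" ", ch, ":", length(v), "windows,",
        sum(is.na(v)), "missing\n")
  }
  invisible(x)
}

#' Load a bedGraph file onto a fixed window grid
#'
#' Records are resampled onto windows of the requested size by
#' coverage-weighted mean; windows with no coverage are `NA`.  Overlapping
#' records are an error.
#'
#' @param path Path to a bedGraph file.
#' @param window Target window size in bp.
#' @return A [signal_track()].
#' @export
load_signal_track <- function(path, window) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("bedGraph needs 4 columns: ", path)
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  vals <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$start[-1L] < d$end[-nrow(d)])) {
      stop("overlapping bedGraph records on ", ch)
    }
    n_win <- ceiling(max(d$end) / window)
    num <- numeric(n_win)
    den <- numeric(n_win)
    rec <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    grid <- IRanges::IRanges(start = seq_len(n_win) * window - window + 1L,
                             width = window)
    ov <- IRanges::findOverlaps(rec, grid)
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(rec[qi], grid[si]))
    for (k in seq_along(qi)) {
      num[si[k]] <- num[si[k]] + w[k] * d$value[qi[k]]
      den[si[k]] <- den[si[k]] + w[k]
    }
    v <- ifelse(den > 0, num / den, NA_real_)
    vals[[ch]] <- v
  }
  signal_track(vals, window)
}

#' Write a signal track as bedGraph
#'
#' One record per non-missing window; tab-separated, no header.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @param digits Number of significant digits for values.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path, digits = 6L) {
  lines <- character()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    i <- which(!is.na(v))
    if (length(i) == 0L) next
    lines <- c(lines, paste(ch, (i - 1L) * track$window, i * track$window,
                            signif(v[i], digits), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Reverse complement of a sequence string
#' @param seq Uppercase nucleotide string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
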