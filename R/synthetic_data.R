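# Synthetic diploid genomes with a known truth table.
#
# The generator emulates the study conditions of an allele-specific
# nascent-strand experiment at desk scale: a pair of haplotype genomes
# differing by SNPs (some of which destroy planted G4/iG4 motifs on one
# haplotype), origin peaks with per-allele firing efficiencies (a minority
# allele-biased with allelic ratios spanning 1.5-100), binomially sampled
# allele read depths over heterozygous SNPs, G/C- and A/T-skewed origin
# cores planted via per-position nucleotide probabilities, and
# maternal/paternal S/G1 timing tracks carrying asynchronous domains.

#' Simulation parameterisation
#'
#' Defaults define the package's reference simulation: two 500-kb
#' chromosomes carrying 200 origins (median-realistic 750-bp peaks), 10%
#' of them allele-biased with allelic ratios log-uniform on 1.5-100, a
#' heterozygous SNP density of 1/kb, and a mean of 100 allele-informative
#' reads per origin.  Planted non-B-DNA features: G4 and iG4 motifs (half
#' carrying a haplotype-specific motif-destroying SNP), 500-bp skewed
#' origin cores (major-strand G probability 0.55 versus 0.15 for C, and
#' the A/T analogue), and 200-kb asynchronous timing domains of amplitude
#' 0.12 on 5-kb S/G1 tracks.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_origins Number of origin peaks.
#' @param origin_width Peak width (bp).
#' @param frac_biased Fraction of origins that are allele-biased.
#' @param ratio_range Allelic-ratio range for biased origins (log-uniform;
#'   both entries > 1).
#' @param read_depth Mean allele-informative read depth per origin.
#' @param background_depth Mean read depth of SNPs outside origins.
#' @param snp_density Heterozygous SNPs per bp.
#' @param n_g4,n_ig4 Planted G4 / iG4 motif copies (half inside origins).
#' @param frac_g4_disrupted,frac_ig4_disrupted Fraction of planted copies
#'   destroyed on one haplotype by a SNP.
#' @param n_skew_cores Planted skewed origin cores (split evenly between
#'   G/C and A/T skew, random strand).
#' @param skew_core_length Core length (bp).
#' @param skew_major,skew_minor Per-position probability of the major /
#'   minor letter of the skewed pair inside a core.
#' @param n_ards Planted asynchronously replicated domains.
#' @param ard_length ARD length (bp; multiple of `timex_window`).
#' @param ard_amplitude Maternal-paternal timing-ratio difference inside
#'   an ARD.
#' @param timex_window Timing-track window (bp).
#' @param timex_noise_sd Gaussian noise s.d. added to each timing-ratio
#'   window.
#' @param timex_reads Mean G1-phase read count per timing window.
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(chrom_lengths = c(sim1 = 500000L, sim2 = 500000L),
                            n_origins = 200L, origin_width = 750L,
                            frac_biased = 0.1, ratio_range = c(1.5, 100),
                            read_depth = 100, background_depth = 10,
                            snp_density = 0.001,
                            n_g4 = 40L, n_ig4 = 30L,
                            frac_g4_disrupted = 0.5,
                            frac_ig4_disrupted = 0.5,
                            n_skew_cores = 12L, skew_core_length = 500L,
                            skew_major = 0.55, skew_minor = 0.15,
                            n_ards = 2L, ard_length = 200000L,
                            ard_amplitude = 0.12,
                            timex_window = 5000L, timex_noise_sd = 0.005,
                            timex_reads = 500,
                            seed = 1L) {
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)),
            n_origins >= 0, origin_width > 0,
            frac_biased >= 0, frac_biased <= 1,
            all(ratio_range > 1), ratio_range[1] <= ratio_range[2],
            read_depth > 0, snp_density >= 0,
            n_g4 >= 0, n_ig4 >= 0, n_skew_cores >= 0,
            skew_core_length > 0, skew_major + 3 * skew_minor <= 1 + 1e-9,
            n_ards >= 0, ard_length > 0, ard_amplitude >= 0,
            timex_window > 0, seed == as.integer(seed))
  spec <- as.list(environment())
  spec$chrom_lengths <- setNames(as.integer(chrom_lengths),
                                 names(chrom_lengths))
  structure(spec, class = "simulation_spec")
}

# Planted motif sequences.  Pads of A/T on both sides isolate the motif
# from the random background so a planted copy is intact iff undisrupted.
.motif_pad <- "TTATTATT"
.g4_core <- "GGGTTAGGGTTAGGGTTAGGG"     # four G-tracts, 2-nt loops
.g4_core_broken <- "GGGTTAGGGTTAGAGTTAGGG" # G>A destroys the third tract
.ig4_core <- "CCCTACCCTAGGGTACCC"       # mixed C/G tracts: iG4, not G4
.ig4_core_broken <- "CCCTACTCTAGGGTACCC" # C>T destroys the second tract

# Intact/disrupted insert pair on a random strand, plus the SNP offset
motif_insert <- function(kind, disrupted, strand) {
  core <- if (kind == "G4") .g4_core else .ig4_core
  broken <- if (kind == "G4") .g4_core_broken else .ig4_core_broken
  intact <- paste0(.motif_pad, core, .motif_pad)
  other <- if (disrupted) paste0(.motif_pad, broken, .motif_pad) else intact
  if (strand == "-") {
    intact <- revcomp(intact)
    other <- revcomp(other)
  }
  list(intact = intact, broken = other,
       snp_offset = if (disrupted)
         which(strsplit(intact, "")[[1L]] != strsplit(other, "")[[1L]]) - 1L
       else NA_integer_)
}

# Skewed-core sequence from per-position letter probabilities
skew_core_seq <- function(len, pair, strand, major, minor) {
  rest <- (1 - major - minor) / 2
  probs <- if (pair == "GC") {
    if (strand == "+") c(A = rest, C = minor, G = major, T = rest)
    else c(A = rest, C = major, G = minor, T = rest)
  } else {
    if (strand == "+") c(A = major, C = rest, G = rest, T = minor)
    else c(A = minor, C = rest, G = rest, T = major)
  }
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

#' Build a synthetic diploid genome pair with truth table
#'
#' Background sequence is i.i.d. uniform over ACGT.  Origins, planted
#' motifs (with haplotype-specific disrupting SNPs), skewed origin cores
#' and background heterozygous SNPs are inserted at recorded positions.
#' All RNG is seeded from `spec$seed`: rerunning with the same spec gives
#' identical output.
#'
#' @param spec A [simulation_spec()].
#' @return List with `hap1`, `hap2` (named character genomes sharing
#'   coordinates; the variants are all substitutions), `variants` (phased
#'   variant data frame, depths unset), and `truth` (list of `origins`,
#'   `motifs`, `skew_cores`, `ards` data frames plus the spec).
#' @export
build_diploid_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  lens <- spec$chrom_lengths
  chroms <- names(lens)

  # --- feature layout on a slot grid (keeps everything non-overlapping)
  slot <- max(2L * spec$origin_width, 2500L)
  slots <- do.call(rbind, lapply(chroms, function(ch) {
    n_slot <- lens[[ch]] %/% slot
    if (n_slot < 1L) return(NULL)
    data.frame(chrom = ch, start = (seq_len(n_slot) - 1L) * slot)
  }))
  n_bg_motifs <- ceiling(spec$n_g4 / 2) + ceiling(spec$n_ig4 / 2)
  if (spec$n_origins + n_bg_motifs > nrow(slots)) {
    stop("requested features denser than the genome can hold")
  }
  pick <- sample.int(nrow(slots), spec$n_origins + n_bg_motifs)
  origin_slots <- slots[pick[seq_len(spec$n_origins)], , drop = FALSE]
  bg_slots <- slots[pick[-seq_len(spec$n_origins)], , drop = FALSE]

  # --- origins with true allelic efficiencies
  n_biased <- round(spec$frac_biased * spec$n_origins)
  biased <- seq_len(spec$n_origins) %in% sample.int(spec$n_origins, n_biased)
  ratio <- rep(1, spec$n_origins)
  if (n_biased > 0L) {
    lr <- runif(n_biased, log(spec$ratio_range[1]), log(spec$ratio_range[2]))
    ratio[biased] <- exp(lr)
  }
  e1 <- ratio / (1 + ratio)
  flip_side <- runif(spec$n_origins) < 0.5
  e1[flip_side] <- 1 - e1[flip_side]
  e1[!biased] <- 0.5
  origins <- data.frame(
    origin_id = sprintf("origin_%04d", seq_len(spec$n_origins)),
    chrom = origin_slots$chrom,
    start = origin_slots$start + ((slot - spec$origin_width) %/% 2L),
    stringsAsFactors = FALSE)
  origins$end <- origins$start + spec$origin_width
  origins$summit <- rep(spec$origin_width %/% 2L, nrow(origins))
  origins$enrichment <- round(5 * exp(abs(rnorm(spec$n_origins, 0, 1))), 2)
  origins$e1 <- e1
  origins$ratio <- ratio
  origins$biased <- biased

  # --- assign origins to carry skewed cores or planted motifs (disjoint)
  if (spec$n_skew_cores + ceiling(spec$n_g4 / 2) + ceiling(spec$n_ig4 / 2) >
      spec$n_origins) {
    stop("not enough origins to host the requested cores and motifs")
  }
  host <- sample.int(spec$n_origins)
  core_hosts <- host[seq_len(spec$n_skew_cores)]
  g4_in <- ceiling(spec$n_g4 / 2)
  ig4_in <- ceiling(spec$n_ig4 / 2)
  g4_hosts <- host[spec$n_skew_cores + seq_len(g4_in)]
  ig4_hosts <- host[spec$n_skew_cores + g4_in + seq_len(ig4_in)]

  # --- background genome, shared by both haplotypes before SNPs
  base <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), lens[[ch]], replace = TRUE),
          collapse = "")
  }, character(1L))
  hap1 <- base
  hap2 <- base

  motifs <- list()
  variants <- list()
  footprints <- list()
  add_footprint <- function(ch, s, e) {
    footprints[[length(footprints) + 1L]] <<-
      data.frame(chrom = ch, start = s, end = e)
  }

  plant_motif <- function(kind, ch, pos, disrupted, origin_id) {
    strand <- sample(c("+", "-"), 1L)
    ins <- motif_insert(kind, disrupted, strand)
    w <- nchar(ins$intact)
    intact_hap <- sample(1:2, 1L)
    s1 <- if (intact_hap == 1L) ins$intact else ins$broken
    s2 <- if (intact_hap == 1L) ins$broken else ins$intact
    substr(hap1[[ch]], pos + 1L, pos + w) <<- s1
    substr(hap2[[ch]], pos + 1L, pos + w) <<- s2
    pad <- nchar(.motif_pad)
    motifs[[length(motifs) + 1L]] <<- data.frame(
      chrom = ch, start = pos + pad, end = pos + w - pad, kind = kind,
      strand = strand, disrupted = disrupted,
      intact_hap = if (disrupted) intact_hap else NA_integer_,
      origin_id = origin_id, stringsAsFactors = FALSE)
    if (disrupted) {
      p <- pos + ins$snp_offset
      a1 <- substr(s1, ins$snp_offset + 1L, ins$snp_offset + 1L)
      a2 <- substr(s2, ins$snp_offset + 1L, ins$snp_offset + 1L)
      variants[[length(variants) + 1L]] <<- data.frame(
        chrom = ch, pos = p, ref = a1, alt = a2,
        hap1_allele = a1, hap2_allele = a2, ad1 = NA_integer_,
        ad2 = NA_integer_, is_indel = FALSE, stringsAsFactors = FALSE)
    }
    add_footprint(ch, pos, pos + w)
  }

  place_in_origin <- function(oid, width) {
    # near the peak start, clear of the central core region
    o <- origins[oid, ]
    c(o$chrom, o$start + 20L)
  }

  n_disr_g4 <- round(spec$frac_g4_disrupted * spec$n_g4)
  disr_g4 <- seq_len(spec$n_g4) %in% sample.int(max(spec$n_g4, 1L), n_disr_g4)
  n_disr_ig4 <- round(spec$frac_ig4_disrupted * spec$n_ig4)
  disr_ig4 <- seq_len(spec$n_ig4) %in%
    sample.int(max(spec$n_ig4, 1L), n_disr_ig4)

  gi <- 0L
  for (k in seq_len(spec$n_g4)) {
    if (k <= g4_in) {
      oid <- g4_hosts[k]
      loc <- place_in_origin(oid, 37L)
      plant_motif("G4", loc[1L], as.integer(loc[2L]), disr_g4[k],
                  origins$origin_id[oid])
    } else {
      gi <- gi + 1L
      plant_motif("G4", bg_slots$chrom[gi],
                  bg_slots$start[gi] + slot %/% 2L, disr_g4[k], NA_character_)
    }
  }
  for (k in seq_len(spec$n_ig4)) {
    if (k <= ig4_in) {
      oid <- ig4_hosts[k]
      loc <- place_in_origin(oid, 34L)
      plant_motif("iG4", loc[1L], as.integer(loc[2L]), disr_ig4[k],
                  origins$origin_id[oid])
    } else {
      gi <- gi + 1L
      plant_motif("iG4", bg_slots$chrom[gi],
                  bg_slots$start[gi] + slot %/% 2L, disr_ig4[k],
                  NA_character_)
    }
  }

  # --- skewed origin cores, centred on their host origin summit
  skew_cores <- list()
  for (k in seq_along(core_hosts)) {
    o <- origins[core_hosts[k], ]
    pair <- if (k %% 2L == 1L) "GC" else "AT"
    strand <- sample(c("+", "-"), 1L)
    s <- o$start + o$summit - spec$skew_core_length %/% 2L
    core <- skew_core_seq(spec$skew_core_length, pair, strand,
                          spec$skew_major, spec$skew_minor)
    substr(hap1[[o$chrom]], s + 1L, s + spec$skew_core_length) <- core
    substr(hap2[[o$chrom]], s + 1L, s + spec$skew_core_length) <- core
    skew_cores[[k]] <- data.frame(
      chrom = o$chrom, start = s, end = s + spec$skew_core_length,
      pair = pair, strand = strand, origin_id = o$origin_id,
      stringsAsFactors = FALSE)
    add_footprint(o$chrom, s, s + spec$skew_core_length)
  }

  # --- background heterozygous SNPs outside planted footprints
  fp <- if (length(footprints)) do.call(rbind, footprints) else NULL
  n_planted <- length(variants)
  n_snps <- max(0L, round(spec$snp_density * sum(lens)) - n_planted)
  if (n_snps > 0L) {
    cand <- data.frame(
      chrom = sample(chroms, 2L * n_snps, replace = TRUE,
                     prob = lens))
    cand$pos <- as.integer(floor(runif(nrow(cand)) * lens[cand$chrom]))
    cand <- cand[!duplicated(cand[c("chrom", "pos")]), , drop = FALSE]
    if (!is.null(fp)) {
      cand_iv <- data.frame(chrom = cand$chrom, start = cand$pos,
                            end = cand$pos + 1L)
      cand <- cand[count_interval_overlaps(cand_iv, fp) == 0L, ,
                   drop = FALSE]
    }
    cand <- cand[seq_len(min(n_snps, nrow(cand))), , drop = FALSE]
    cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      ch <- cand$chrom[i]; p <- cand$pos[i]
      ref <- substr(hap1[[ch]], p + 1L, p + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      substr(hap2[[ch]], p + 1L, p + 1L) <- alt
      variants[[length(variants) + 1L]] <- data.frame(
        chrom = ch, pos = p, ref = ref, alt = alt, hap1_allele = ref,
        hap2_allele = alt, ad1 = NA_integer_, ad2 = NA_integer_,
        is_indel = FALSE, stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), hap1_allele = character(),
               hap2_allele = character(), ad1 = integer(), ad2 = integer(),
               is_indel = logical())
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL

  # --- planted asynchronous domains, aligned to the timing grid
  ards <- NULL
  if (spec$n_ards > 0L) {
    win <- spec$timex_window
    ard_wins <- spec$ard_length %/% win
    rows <- list()
    occupied <- stats::setNames(vector("list", length(chroms)), chroms)
    for (k in seq_len(spec$n_ards)) {
      ch <- chroms[(k - 1L) %% length(chroms) + 1L]
      n_win <- lens[[ch]] %/% win
      if (n_win < ard_wins) stop("ARD longer than chromosome ", ch)
      placed <- FALSE
      for (try in 1:50) {
        s_win <- sample.int(n_win - ard_wins + 1L, 1L) - 1L
        iv <- c(s_win, s_win + ard_wins)
        clash <- any(vapply(occupied[[ch]], function(o)
          iv[1L] < o[2L] && o[1L] < iv[2L], logical(1L)))
        if (!clash) {
          occupied[[ch]] <- c(occupied[[ch]], list(iv))
          rows[[k]] <- data.frame(
            chrom = ch, start = s_win * win, end = (s_win + ard_wins) * win,
            amplitude = spec$ard_amplitude,
            sign = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place non-overlapping ARDs")
    }
    ards <- do.call(rbind, rows)
  } else {
    ards <- data.frame(chrom = character(), start = integer(),
                       end = integer(), amplitude = numeric(),
                       sign = character())
  }

  motifs <- if (length(motifs)) do.call(rbind, motifs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               kind = character(), strand = character(),
               disrupted = logical(), intact_hap = integer(),
               origin_id = character())
  rownames(motifs) <- NULL
  skew_cores <- if (length(skew_cores)) do.call(rbind, skew_cores) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               pair = character(), strand = character(),
               origin_id = character())
  rownames(skew_cores) <- NULL

  list(hap1 = hap1, hap2 = hap2, variants = variants,
       truth = list(origins = origins, motifs = motifs,
                    skew_cores = skew_cores, ards = ards, spec = spec))
}

#' Simulate nascent-strand peaks and allele read depths
#'
#' Each origin becomes one peak.  For every heterozygous SNP inside an
#' origin, a total depth is drawn from a Poisson whose mean is the
#' origin's mean allele-informative depth split over its SNPs, and the
#' haplotype-1 depth is binomial with the origin's true efficiency `e1`.
#' SNPs outside origins receive balanced depths at the background rate.
#'
#' @param truth Truth list from [build_diploid_genome()].
#' @param variants Variant data frame from the same build.
#' @param seed RNG seed (default `spec$seed + 1`).
#' @return List with `peaks` (peak data frame with `peak_id`, interval,
#'   `summit`, `enrichment`) and `variants` (depths filled in).
#' @export
simulate_ns_peaks <- function(truth, variants, seed = NULL) {
  spec <- truth$spec
  if (is.null(seed)) seed <- spec$seed + 1L
  set.seed(seed)
  org <- truth$origins
  peaks <- data.frame(peak_id = org$origin_id, chrom = org$chrom,
                      start = org$start, end = org$end, name = org$origin_id,
                      score = rep(0, nrow(org)), strand = rep(".", nrow(org)),
                      summit = org$summit, enrichment = org$enrichment,
                      stringsAsFactors = FALSE)
  v <- variants
  n_v <- nrow(v)
  v$ad1 <- integer(n_v)
  v$ad2 <- integer(n_v)
  if (n_v > 0L) {
    vg <- GenomicRanges::GRanges(v$chrom,
                                 IRanges::IRanges(v$pos + 1L, width = 1L))
    og <- intervals_to_granges(org)
    ov <- GenomicRanges::findOverlaps(vg, og)
    vi <- S4Vectors::queryHits(ov)
    oi <- S4Vectors::subjectHits(ov)
    snps_per_origin <- tabulate(oi, nbins = nrow(org))
    in_origin <- rep(FALSE, n_v)
    in_origin[vi] <- TRUE
    # origin SNPs
    if (length(vi) > 0L) {
      mean_d <- spec$read_depth / snps_per_origin[oi]
      d <- rpois(length(vi), mean_d)
      a1 <- rbinom(length(vi), d, org$e1[oi])
      v$ad1[vi] <- a1
      v$ad2[vi] <- d - a1
    }
    # background SNPs
    bg <- which(!in_origin)
    if (length(bg) > 0L) {
      d <- rpois(length(bg), spec$background_depth)
      a1 <- rbinom(length(bg), d, 0.5)
      v$ad1[bg] <- a1
      v$ad2[bg] <- d - a1
    }
  }
  list(peaks = peaks, variants = v)
}

#' Count-level null/alternative simulation of allelic depths
#'
#' Draws per-origin allele-informative totals directly (Poisson) and
#' splits them binomially by the true efficiency, without constructing a
#' genome.  Used for calibration and power studies of the allele-bias
#' caller at scale.
#'
#' @param n_origins Number of origins.
#' @param e1 True haplotype-1 efficiency; scalar or per-origin vector.
#' @param mean_depth Mean total allele-informative depth per origin.
#' @param seed Optional RNG seed.
#' @return Data frame with `peak_id`, `n1`, `n2`, `n_snps` and the truth
#'   column `e1`, ready for [test_allele_bias()].
#' @export
simulate_allele_counts <- function(n_origins, e1 = 0.5, mean_depth = 100,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e1 <- rep_len(e1, n_origins)
  d <- rpois(n_origins, mean_depth)
  n1 <- rbinom(n_origins, d, e1)
  data.frame(peak_id = sprintf("origin_%05d", seq_len(n_origins)),
             n1 = n1, n2 = d - n1, n_snps = 1L, e1 = e1,
             stringsAsFactors = FALSE)
}

#' Simulate maternal/paternal S/G1 timing tracks
#'
#' Both homologues share a smooth S/G1 base profile within \[1, 2\];
#' inside each planted asynchronous domain the maternal-paternal ratio
#' difference equals the planted amplitude (signed).  Gaussian noise is
#' added to the ratio tracks, and S- and G1-phase read-count tracks
#' consistent with the ratios are drawn (Poisson) for the chi-squared
#' stage of [call_ards()].
#'
#' @param truth Truth list from [build_diploid_genome()] (uses `ards` and
#'   the spec).
#' @param seed RNG seed (default `spec$seed + 2`).
#' @return List with `maternal`, `paternal` ([signal_track()] ratios) and
#'   `counts` (list of `s_maternal`, `g1_maternal`, `s_paternal`,
#'   `g1_paternal` tracks).
#' @export
simulate_timex_tracks <- function(truth, seed = NULL) {
  spec <- truth$spec
  if (is.null(seed)) seed <- spec$seed + 2L
  set.seed(seed)
  ards <- truth$ards
  if (nrow(ards) > 1L) {
    iv <- intervals_to_granges(ards)
    if (any(GenomicRanges::countOverlaps(iv, iv) > 1L)) {
      stop("planted ARDs overlap")
    }
  }
  win <- spec$timex_window
  lens <- spec$chrom_lengths
  ratio_m <- ratio_p <- noisy_m <- noisy_p <- list()
  cnt <- list(s_maternal = list(), g1_maternal = list(),
              s_paternal = list(), g1_paternal = list())
  for (ch in names(lens)) {
    n <- lens[[ch]] %/% win
    mid <- (seq_len(n) - 0.5) * win
    base <- 1.5 + 0.3 * sin(2 * pi * 3 * mid / lens[[ch]])
    delta <- numeric(n)
    a <- ards[ards$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      w0 <- a$start[i] %/% win + 1L
      w1 <- a$end[i] %/% win
      s <- if (a$sign[i] == "+") 1 else -1
      delta[w0:w1] <- s * a$amplitude[i]
    }
    rm_ <- base + delta / 2
    rp_ <- base - delta / 2
    noisy_m[[ch]] <- rm_ + rnorm(n, 0, spec$timex_noise_sd)
    noisy_p[[ch]] <- rp_ + rnorm(n, 0, spec$timex_noise_sd)
    g1m <- rpois(n, spec$timex_reads)
    g1p <- rpois(n, spec$timex_reads)
    cnt$g1_maternal[[ch]] <- as.numeric(g1m)
    cnt$g1_paternal[[ch]] <- as.numeric(g1p)
    cnt$s_maternal[[ch]] <- as.numeric(rpois(n, spec$timex_reads * rm_))
    cnt$s_paternal[[ch]] <- as.numeric(rpois(n, spec$timex_reads * rp_))
  }
  list(maternal = signal_track(noisy_m, win),
       paternal = signal_track(noisy_p, win),
       counts = lapply(cnt, signal_track, window = win))
}

#' Run the full simulation and optionally write its files
#'
#' Convenience wrapper: builds the diploid genome, draws peak read depths
#' and timing tracks, and (when `dir` is given) writes haplotype FASTAs,
#' a phased VCF with AD, peaks as narrowPeak, timing bedGraphs, the truth
#' tables as TSV and the spec as YAML.
#'
#' @param spec A [simulation_spec()].
#' @param dir Optional output directory.
#' @return List with `hap1`, `hap2`, `variants`, `truth`, `peaks`,
#'   `timex`, and (if written) `files`.
#' @export
simulate_dataset <- function(spec, dir = NULL) {
  g <- build_diploid_genome(spec)
  ns <- simulate_ns_peaks(g$truth, g$variants)
  tx <- simulate_timex_tracks(g$truth)
  out <- list(hap1 = g$hap1, hap2 = g$hap2, variants = ns$variants,
              truth = g$truth, peaks = ns$peaks, timex = tx)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(dir, x)
    write_genome(out$hap1, fp("hap1.fa"))
    write_genome(out$hap2, fp("hap2.fa"))
    write_phased_variants(out$variants, fp("variants.vcf"))
    write_intervals(out$peaks, fp("peaks.narrowPeak"), narrowpeak = TRUE)
    write_signal_track(tx$maternal, fp("timex_maternal.bedGraph"))
    write_signal_track(tx$paternal, fp("timex_paternal.bedGraph"))
    for (nm in names(out$truth)[names(out$truth) != "spec"]) {
      write.table(out$truth[[nm]], fp(paste0("truth_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    spec_plain <- unclass(spec)
    spec_plain$chrom_lengths <- as.list(spec$chrom_lengths)
    yaml::write_yaml(spec_plain, fp("spec.yaml"))
    out$files <- list.files(dir, full.names = TRUE)
  }
  out
}
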