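# One-command orchestration of the full analysis on synthetic or
# file-based inputs, with a manifest of outputs.

#' Pipeline configuration
#'
#' Exactly one of `sim_spec` (simulate the inputs) or `paths` (load them
#' from files) must be supplied.  `paths` is a named list with entries
#' `hap1`, `hap2` (FASTA), `peaks` (BED/narrowPeak), `vcf` (phased VCF
#' with AD) and optionally `timex_maternal`, `timex_paternal`,
#' `s_maternal`, `g1_maternal`, `s_paternal`, `g1_paternal` (bedGraph) for
#' the timing-domain stage.
#'
#' @param sim_spec A [simulation_spec()], or NULL.
#' @param paths Named list of input paths, or NULL.
#' @param out_dir Output directory.
#' @param min_reads,fdr Allele-bias calling parameters.
#' @param n_iter Permutation iterations for enrichment tests.
#' @param strata Top-N stratum sizes for skew profiles.
#' @param top_peaks Number of top peaks for summit histograms/clustering.
#' @param cluster_k Number of k-means clusters.
#' @param control_sets,control_size GC-matched control sampling size.
#' @param control_gc_bin GC histogram bin width for control matching.
#' @param kmer_k,kmer_gc_min K-mer enumeration parameters.
#' @param timex_window Timing-track window (bp) used when loading tracks
#'   from paths.
#' @param seed Master seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim_spec = NULL, paths = NULL,
                            out_dir = tempfile("oriallele_"),
                            min_reads = 50L, fdr = 0.05, n_iter = 200L,
                            strata = c(20L, 50L, 100L), top_peaks = 100L,
                            cluster_k = 4L, control_sets = 5L,
                            control_size = 200L, control_gc_bin = 0.05,
                            kmer_k = 30L,
                            kmer_gc_min = 0.4, timex_window = 5000L,
                            seed = NULL) {
  if (is.null(sim_spec) == is.null(paths)) {
    stop("supply exactly one of sim_spec or paths")
  }
  if (is.null(seed)) {
    seed <- if (!is.null(sim_spec)) sim_spec$seed else 1L
  }
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  flat <- config
  flat$sim_spec <- if (!is.null(config$sim_spec)) {
    s <- unclass(config$sim_spec)
    s$chrom_lengths <- as.list(s$chrom_lengths)
    s
  }
  flat$out_dir <- NULL   # the hash identifies the analysis, not its location
  yaml::write_yaml(flat, tf)
  unname(tools::md5sum(tf))
}

#' Run the full allele-specific origin analysis
#'
#' Stages, in order: motif scanning (G4, iG4, triplex), allele-specific
#' read counting and bias classification, polymorphic-motif versus
#' efficiency tallies, asynchronous-domain calling, skewed-region calling,
#' permutation enrichment panels, GC-matched control overlap, GC-rich
#' 30-mer analysis, and summit composition profiles with k-means
#' clustering.  Every output file is recorded in a manifest with its MD5
#' checksum and the configuration hash; rerunning the same configuration
#' reproduces the outputs byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest data frame.  A failure in any stage
#'   aborts with the stage name after writing the partial manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  fp <- function(x) file.path(out_dir, x)
  save_tsv <- function(df, name) {
    write.table(df, fp(name), sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, name)
  }
  save_bed <- function(df, name, ...) {
    write_intervals(df, fp(name), ...)
    files <<- c(files, name)
  }
  finish_manifest <- function(status) {
    manifest <- data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))),
      stringsAsFactors = FALSE)
    attr(manifest, "config_hash") <- config_hash(config)
    header <- sprintf("# config_hash: %s", attr(manifest, "config_hash"))
    con <- file(fp("manifest.tsv"), "w")
    writeLines(header, con)
    write.table(manifest, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    manifest
  }
  stage_name <- "setup"
  stage <- function(name, expr) {
    stage_name <<- name
    message("[oriallele] stage: ", name)
    tryCatch(force(expr), error = function(e) {
      finish_manifest("failed")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- inputs
  inputs <- stage("inputs", {
    if (!is.null(config$sim_spec)) {
      sim <- simulate_dataset(config$sim_spec, dir = fp("inputs"))
      files <- c(files, file.path("inputs", basename(sim$files)))
      list(hap1 = sim$hap1, hap2 = sim$hap2, peaks = sim$peaks,
           variants = sim$variants, timex = sim$timex, truth = sim$truth)
    } else {
      p <- config$paths
      hap1 <- load_genome(p$hap1)
      hap2 <- if (!is.null(p$hap2)) load_genome(p$hap2) else NULL
      timex <- NULL
      if (!is.null(p$timex_maternal)) {
        timex <- list(
          maternal = load_signal_track(p$timex_maternal, config$timex_window),
          paternal = load_signal_track(p$timex_paternal, config$timex_window),
          counts = if (!is.null(p$s_maternal)) list(
            s_maternal = load_signal_track(p$s_maternal, config$timex_window),
            g1_maternal = load_signal_track(p$g1_maternal, config$timex_window),
            s_paternal = load_signal_track(p$s_paternal, config$timex_window),
            g1_paternal = load_signal_track(p$g1_paternal, config$timex_window)))
      }
      list(hap1 = hap1, hap2 = hap2,
           peaks = load_intervals(p$peaks, genome = hap1),
           variants = load_phased_variants(p$vcf), timex = timex,
           truth = NULL)
    }
  })
  hap1 <- inputs$hap1
  lens <- genome_lengths(hap1)
  peaks <- inputs$peaks
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak_%d", seq_len(nrow(peaks)))
  }

  # ---- motif scans on the reference haplotype
  motifs <- stage("motif_scan", {
    g4 <- scan_motifs(hap1, "G4")
    ig4 <- scan_motifs(hap1, "iG4")
    tpx <- scan_motifs(hap1, "triplex")
    save_bed(data.frame(chrom = g4$chrom, start = g4$start, end = g4$end,
                        name = g4$kind, score = rep(0, nrow(g4)),
                        strand = g4$strand), "g4_hits.bed")
    save_bed(data.frame(chrom = ig4$chrom, start = ig4$start, end = ig4$end,
                        name = ig4$kind, score = rep(0, nrow(ig4)),
                        strand = ig4$strand), "ig4_hits.bed")
    save_bed(data.frame(chrom = tpx$chrom, start = tpx$start, end = tpx$end,
                        name = if (nrow(tpx)) paste0("triplex_type", tpx$triplex_type) else character(),
                        score = rep(0, nrow(tpx)), strand = tpx$strand),
             "triplex_hits.bed")
    list(g4 = g4, ig4 = ig4, tpx = tpx)
  })

  # ---- allele-specific counting and bias classification
  bias <- stage("allele_bias", {
    rec <- count_allelic_reads(peaks, inputs$variants)
    rec <- test_allele_bias(rec, min_reads = config$min_reads,
                            fdr = config$fdr)
    save_tsv(rec, "allele_bias.tsv")
    biased <- rec[rec$class == "allele_biased", , drop = FALSE]
    if (nrow(biased) > 0L) {
      save_bed(data.frame(chrom = biased$chrom, start = biased$start,
                          end = biased$end, name = biased$peak_id,
                          score = round(biased$log2_ratio, 3),
                          strand = rep(".", nrow(biased))),
               "allele_biased_origins.bed")
    }
    rec
  })
  biased <- bias[bias$class == "allele_biased", , drop = FALSE]

  # ---- polymorphic motifs versus efficiency
  stage("polymorphic_motifs", {
    if (is.null(inputs$hap2) || nrow(biased) == 0L) {
      message("  (skipped: needs both haplotypes and biased origins)")
    } else {
      g4_1 <- origin_motif_counts(biased, hap1, "G4")
      g4_2 <- origin_motif_counts(biased, inputs$hap2, "G4")
      ig4_1 <- origin_motif_counts(biased, hap1, "iG4")
      ig4_2 <- origin_motif_counts(biased, inputs$hap2, "iG4")
      rows <- list()
      add_row <- function(kind, cmp) {
        rows[[length(rows) + 1L]] <<- data.frame(
          motif = kind, restrict = cmp$restrict, n_pairs = cmp$n_pairs,
          richer_is_most_efficient = cmp$most_efficient,
          richer_is_least_efficient = cmp$least_efficient)
      }
      add_row("G4", compare_polymorphic_motifs(biased, g4_1, g4_2, "any"))
      add_row("G4", compare_polymorphic_motifs(biased, g4_1, g4_2,
                                               "single_motif"))
      add_row("G4", compare_polymorphic_motifs(biased, g4_1, g4_2,
                                               "single_motif_no_other",
                                               other1 = ig4_1, other2 = ig4_2))
      add_row("iG4", compare_polymorphic_motifs(biased, ig4_1, ig4_2, "any"))
      add_row("iG4", compare_polymorphic_motifs(biased, ig4_1, ig4_2,
                                                "single_motif_no_other",
                                                other1 = g4_1, other2 = g4_2))
      save_tsv(do.call(rbind, rows), "polymorphic_motifs.tsv")
    }
  })

  # ---- asynchronous replication domains
  ards <- stage("ards", {
    tx <- inputs$timex
    if (is.null(tx) || is.null(tx$counts)) {
      message("  (skipped: no timing tracks with counts)")
      NULL
    } else {
      a <- call_ards(tx$maternal, tx$paternal, "ard", tx$counts,
                     fdr = config$fdr)
      k <- call_ards(tx$maternal, tx$paternal, "core", tx$counts,
                     fdr = config$fdr)
      a$mode <- rep("ard", nrow(a))
      k$mode <- rep("core", nrow(k))
      save_tsv(rbind(a, k), "ards.tsv")
      list(ard = a, core = k)
    }
  })

  # ---- skewed regions
  skew <- stage("skew_islands", {
    gc <- call_skewed_regions(hap1, "GC")
    at <- call_skewed_regions(hap1, "AT")
    gc$pair <- rep("GC", nrow(gc))
    at$pair <- rep("AT", nrow(at))
    both <- rbind(gc, at)
    save_tsv(both, "skew_islands.tsv")
    list(gc = gc, at = at, both = both)
  })

  # ---- enrichment panels
  stage("enrichment", {
    rows <- list()
    add <- function(panel, res) {
      rows[[length(rows) + 1L]] <<- data.frame(
        panel = panel, statistic = res$statistic, observed = res$observed,
        expected_mean = res$expected_mean, expected_sd = res$expected_sd,
        p_enrichment = res$p_value, p_depletion = res$p_depletion,
        n_iter = res$n_iter)
    }
    set.seed(config$seed + 100L)
    add("origins_vs_g4",
        permutation_test(peaks, motifs$g4, lens, "n_query_hit",
                         n_iter = config$n_iter))
    add("origins_vs_ig4",
        permutation_test(peaks, motifs$ig4, lens, "n_query_hit",
                         n_iter = config$n_iter))
    if (!is.null(ards) && nrow(ards$ard) > 0L && nrow(biased) > 0L) {
      add("ards_containing_biased_origins",
          permutation_test(ards$ard, biased, lens, "percent",
                           n_iter = config$n_iter))
    }
    if (nrow(skew$both) > 0L) {
      topn <- min(config$top_peaks, nrow(peaks))
      top <- peaks[order(-peaks$enrichment), ][seq_len(topn), ]
      add("top_origins_vs_skewed_regions",
          permutation_test(top, skew$both, lens, "percent",
                           n_iter = config$n_iter))
    }
    if (nrow(motifs$tpx) > 0L) {
      anti <- motifs$tpx[motifs$tpx$triplex_type >= 4L, , drop = FALSE]
      if (nrow(anti) > 0L) {
        add("origins_vs_antiparallel_triplex",
            permutation_test(peaks, anti, lens, "n_query_hit",
                             n_iter = config$n_iter))
      }
    }
    save_tsv(do.call(rbind, rows), "enrichment.tsv")
  })

  # ---- origin/feature overlap table with height-matched resampling
  stage("feature_table", {
    subsets <- list(all = bias,
                    non_analysable = bias[bias$class == "non_analysable", ],
                    analysable = bias[bias$class != "non_analysable", ],
                    allele_biased = biased,
                    non_allele_biased =
                      bias[bias$class == "analysable_unbiased", ])
    ph <- peaks[match(bias$peak_id, peaks$peak_id), "enrichment"]
    bias$enrichment <- ph
    resampled <- NULL
    if (nrow(subsets$analysable) > 0L && nrow(subsets$non_analysable) > 0L) {
      ref <- bias[bias$class != "non_analysable", ]
      pool <- bias[bias$class == "non_analysable", ]
      resampled <- suppressWarnings(
        resample_matched_height(ref, pool, seed = config$seed + 200L))
      subsets$non_analysable_resampled <- resampled
    }
    feats <- list(G4 = motifs$g4, iG4 = motifs$ig4, skew = skew$both)
    rows <- list()
    for (sn in names(subsets)) {
      q <- subsets[[sn]]
      if (nrow(q) == 0L) next
      for (fn in names(feats)) {
        if (nrow(feats[[fn]]) == 0L) next
        s <- overlap_summary(q, feats[[fn]])
        rows[[length(rows) + 1L]] <- data.frame(
          subset = sn, feature = fn, n = s$n_query, n_hit = s$n_query_hit,
          percent = round(s$percent, 1))
      }
    }
    save_tsv(do.call(rbind, rows), "feature_table.tsv")
  })

  # ---- GC/length-matched control overlap
  stage("gc_controls", {
    if (nrow(motifs$g4) == 0L) {
      message("  (skipped: no G4 hits)")
    } else {
      excl <- rbind(motifs$g4[c("chrom", "start", "end")],
                    motifs$ig4[c("chrom", "start", "end")])
      sets <- suppressWarnings(sample_gc_matched_controls(
        hap1, motifs$g4, excl, n_sets = config$control_sets,
        set_size = config$control_size, gc_bin = config$control_gc_bin,
        seed = config$seed + 300L))
      pct <- vapply(sets, function(s)
        overlap_summary(peaks, s)$percent, numeric(1L))
      obs <- overlap_summary(peaks, motifs$g4)$percent
      save_tsv(data.frame(
        statistic = c("origins_hit_by_g4_pct",
                      "origins_hit_by_matched_controls_pct_mean",
                      "origins_hit_by_matched_controls_pct_sd"),
        value = c(obs, mean(pct), sd(pct))), "gc_control_overlap.tsv")
    }
  })

  # ---- GC-rich 30-mer analysis
  stage("kmers", {
    km <- enumerate_kmers(hap1, k = config$kmer_k,
                          gc_min = config$kmer_gc_min)
    quad <- km$has_g4 | km$has_ig4
    gc_thresh <- if (any(quad)) mean(km$gc[quad]) else NA_real_
    ov_pct <- function(sub) {
      if (nrow(sub) == 0L) return(NA_real_)
      overlap_summary(sub, peaks)$percent
    }
    save_tsv(data.frame(
      subset = c("all_gc_rich", "no_quad_high_gc", "with_g4", "with_ig4"),
      n = c(nrow(km), sum(!quad & km$gc > gc_thresh), sum(km$has_g4),
            sum(km$has_ig4)),
      gc_threshold = gc_thresh,
      percent_overlapping_origin = c(
        ov_pct(km), ov_pct(km[!quad & km$gc > gc_thresh, ]),
        ov_pct(km[km$has_g4, ]), ov_pct(km[km$has_ig4, ]))),
      "kmer_analysis.tsv")
  })

  # ---- summit composition profiles and clustering
  stage("summit_profiles", {
    topn <- min(config$top_peaks, nrow(peaks))
    hist_ <- summit_g_histogram(peaks, hap1, width = 100L, top_n = topn)
    save_tsv(data.frame(bin_start = hist_$breaks[-length(hist_$breaks)],
                        count = hist_$counts), "summit_g_histogram.tsv")
    top <- peaks[order(-peaks$enrichment), ][seq_len(topn), ]
    prof <- suppressWarnings(
      summit_profiles(top, hap1, width = 1000L, type = "density",
                      letters = "G", oriented = TRUE))
    cl <- cluster_g_profiles(prof, k = config$cluster_k,
                             seed = config$seed + 400L)
    save_tsv(data.frame(peak_id = rownames(prof), cluster = cl$labels),
             "g_profile_clusters.tsv")
    save_tsv(as.data.frame(cl$centers), "g_profile_centroids.tsv")
    strata <- config$strata[config$strata <= nrow(peaks)]
    if (length(strata) > 0L) {
      sk <- suppressWarnings(
        stratified_skew_profile(peaks, hap1, strata, width = 5000L))
      save_tsv(data.frame(stratum = rownames(sk), as.data.frame(sk)),
               "stratified_skew_profiles.tsv")
    }
  })

  manifest <- finish_manifest("ok")
  invisible(manifest)
}
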