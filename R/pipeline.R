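#' Run the full synthetic MeRIP-seq analysis pipeline
#'
#' Generates a seeded synthetic dataset and runs every analysis stage:
#' model collapsing and filtering, metagene binning and IP/input
#' enrichment (basal and HS, control genotype), the metagene profile and
#' paired 5'UTR comparison, peak calling with region assignment,
#' differential methylation (control vs knockdown, basal), the m6A gene
#' set, DE classification with skew and overlap tests, and decay fitting
#' with the 4-h remaining comparison. When `outdir` is given, every
#' result is written as deterministic TSV/BED/text so that two runs with
#' the same seed are byte-identical.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed driving every random draw.
#' @param outdir Optional output directory (created if missing).
#' @return A named list with the dataset and all intermediate and final
#'   results, invisibly when `outdir` is given.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1, outdir = NULL) {
  sim <- sim_annotation(config, seed)
  models <- collapse_models(sim$annotation)
  report <- filter_models(models)
  kept <- kept_models(models, report)
  grid <- make_grid(kept)
  windows <- make_windows(kept)

  libs <- sim_reads(sim, seed + 1)
  man <- attr(libs, "manifest")
  pick <- function(type, condition, genotype) {
    ids <- man$library[man$sample_type == type & man$condition == condition &
      man$genotype == genotype]
    libs[ids]
  }
  bin_counts_of <- function(lst) map(lst, count_bin_reads, models = kept, grid = grid)
  win_counts_of <- function(lst) map(lst, count_window_reads, models = kept, windows = windows)

  # enrichment matrices and profiles (control genotype)
  enr_basal <- enrichment(
    bin_counts_of(pick("ip", "basal", "control")),
    bin_counts_of(pick("input", "basal", "control")), grid
  )
  enr_hs <- enrichment(
    bin_counts_of(pick("ip", "hs", "control")),
    bin_counts_of(pick("input", "hs", "control")), grid
  )
  profile_basal <- metagene_profile(enr_basal)
  profile_hs <- metagene_profile(enr_hs)
  u5_basal <- region_mean(enr_basal, "utr5")
  u5_hs <- region_mean(enr_hs, "utr5")
  paired_u5 <- paired_region_test(u5_hs$mean, u5_basal$mean)

  # peaks from pooled basal control reads
  pool_reads <- function(lst) list_rbind(map(lst, as_tibble))
  ip_pool <- pool_reads(pick("ip", "basal", "control"))
  attr(ip_pool, "library_size") <- sum(man$n_reads[man$sample_type == "ip" &
    man$condition == "basal" & man$genotype == "control"])
  in_pool <- pool_reads(pick("input", "basal", "control"))
  attr(in_pool, "library_size") <- sum(man$n_reads[man$sample_type == "input" &
    man$condition == "basal" & man$genotype == "control"])
  peaks <- call_peaks(
    count_window_reads(ip_pool, kept, windows),
    count_window_reads(in_pool, kept, windows), kept,
    ip_library_size = attr(ip_pool, "library_size"),
    input_library_size = attr(in_pool, "library_size")
  )
  peaks <- assign_peak_region(peaks, kept)
  distribution <- if (nrow(peaks) > 0) region_distribution(peaks) else NULL
  peak_eval <- evaluate_peaks(peaks, sim$truth)

  # differential methylation: control vs knockdown at basal
  dm <- differential_methylation(
    win_counts_of(pick("ip", "basal", "control")),
    win_counts_of(pick("input", "basal", "control")),
    win_counts_of(pick("ip", "basal", "knockdown")),
    win_counts_of(pick("input", "basal", "knockdown"))
  )
  m6a_genes <- m6a_gene_set(dm)
  m6a_eval <- evaluate_m6a_genes(m6a_genes, sim$truth)

  # DE skew and overlap
  de <- sim_de_table(sim, seed + 2, contrast = "hs")
  labels <- classify_de(de$table)
  membership <- tibble(
    gene_id = labels$gene_id,
    in_class = labels$gene_id %in% m6a_genes
  )
  skew <- skew_test(labels, membership)
  up_set <- labels$gene_id[labels$label == "up"]
  overlap <- overlap_test(m6a_genes, up_set, labels$gene_id)

  # decay
  decay <- sim_decay(sim, seed + 3)
  fits <- decay |>
    group_by(.data$gene_id, .data$genotype) |>
    group_modify(~ glance(fit_decay(.x$time, .x$level))) |>
    ungroup()
  rem <- decay |>
    filter(.data$time %in% c(0, 4)) |>
    group_by(.data$gene_id, .data$genotype, .data$replicate) |>
    summarise(
      frac = mean(.data$level[.data$time == 4]) /
        mean(.data$level[.data$time == 0]),
      .groups = "drop"
    )
  rem_cmp <- rem |>
    group_by(.data$gene_id) |>
    group_modify(~ compare_remaining(
      .x$frac[.x$genotype == "knockdown"], .x$frac[.x$genotype == "control"]
    )) |>
    ungroup()

  res <- list(
    sim = sim, models = models, filter_report = report, kept = kept,
    grid = grid, windows = windows, manifest = man,
    enrichment_basal = enr_basal, enrichment_hs = enr_hs,
    profile_basal = profile_basal, profile_hs = profile_hs,
    paired_utr5 = paired_u5,
    peaks = peaks, region_distribution = distribution,
    peak_eval = peak_eval,
    diff_methyl = dm, m6a_genes = m6a_genes, m6a_eval = m6a_eval,
    de_labels = labels, skew = skew, overlap = overlap,
    decay = decay, decay_fits = fits, remaining = rem,
    remaining_test = rem_cmp
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) readr::write_tsv(as_tibble(x), file.path(outdir, f))
    write_models_tsv(models, file.path(outdir, "models.tsv"))
    wt(report, "filter_report.tsv")
    write_bin_matrix(enr_basal, file.path(outdir, "enrichment_basal.tsv"))
    wt(profile_basal, "profile_basal.tsv")
    wt(profile_hs, "profile_hs.tsv")
    wt(paired_u5, "paired_utr5.tsv")
    write_peaks_bed(peaks, file.path(outdir, "peaks.bed"))
    if (!is.null(distribution)) wt(distribution, "region_distribution.tsv")
    wt(dm, "diff_methyl.tsv")
    write_gene_set(m6a_genes, file.path(outdir, "m6a_genes.txt"))
    wt(labels, "de_labels.tsv")
    wt(skew, "skew_test.tsv")
    wt(overlap, "overlap_test.tsv")
    wt(fits, "decay_fits.tsv")
    wt(rem_cmp, "remaining_test.tsv")
    return(invisible(res))
  }
  res
}
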