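test_that("annotation generation is byte-deterministic and filter-clean by default", {
  s1 <- sim_annotation(sim_config(n_genes = 10), seed = 1)
  s2 <- sim_annotation(sim_config(n_genes = 10), seed = 1)
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(s1$annotation, f1)
  write_gtf(s2$annotation, f2)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
    readBin(f2, "raw", file.info(f2)$size))
  expect_identical(s1$genome, s2$genome)
  # zero violation fractions: every gene passes the filters
  rep <- filter_models(collapse_models(s1$annotation))
  expect_true(all(rep$kept))
})

test_that("planted filter violations are recovered exactly by the filter report", {
  cfg <- sim_config(n_genes = 100, violation_frac = c(
    utr5_short = 0.2, utr3_short = 0.1, cds_short = 0.1, missing_utr = 0.1
  ))
  sim <- sim_annotation(cfg, seed = 9)
  rep <- filter_models(collapse_models(sim$annotation))
  got <- table(rep$reason)
  expect_equal(got[["utr5_short"]], 20)
  expect_equal(got[["utr3_short"]], 10)
  expect_equal(got[["cds_short"]], 10)
  expect_equal(got[["missing_utr"]], 10)
  expect_equal(sum(rep$kept), 50)
  # the report agrees with the planted truth gene by gene
  cmp <- inner_join(rep, sim$truth, by = "gene_id")
  expect_equal(cmp$reason, cmp$violation)
})

test_that("read simulation is deterministic and splice-aware", {
  sim <- sim_annotation(sim_config(n_genes = 6), seed = 2)
  l1 <- sim_reads(sim, seed = 3, conditions = "basal", genotypes = "control",
    n_replicates = 1)
  l2 <- sim_reads(sim, seed = 3, conditions = "basal", genotypes = "control",
    n_replicates = 1)
  expect_identical(
    as.data.frame(l1$input_basal_control_rep1),
    as.data.frame(l2$input_basal_control_rep1)
  )
  reads <- l1$input_basal_control_rep1
  expect_equal(attr(reads, "library_size"), n_distinct(reads$read_id))
  # every read block lies inside an exon of its gene's model
  mods <- kept_models(collapse_models(sim$annotation))
  seg <- as_tibble(mods)
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    any(seg$chrom == reads$chrom[i] & seg$start <= reads$start[i] &
      seg$end >= reads$end[i])
  }, logical(1))
  expect_true(all(ok))
  # spliced reads exist when genes have introns (blocks per read >= 1)
  expect_gte(max(table(reads$read_id)), 1)
})

test_that("planted IP enrichment appears at the planted fold inside peaks", {
  cfg <- sim_config(n_genes = 1, fraction_modified = 1,
    region_weights = c(utr5 = 1, cds = 0, utr3 = 0),
    len_utr5 = c(400, 400), len_cds = c(600, 600), len_utr3 = c(400, 400))
  ratios <- vapply(1:10, function(s) {
    sim <- sim_annotation(cfg, seed = s)
    tr <- sim$truth
    libs <- sim_reads(sim, seed = 100 + s, conditions = "basal",
      genotypes = "control", n_replicates = 1)
    ip <- libs$ip_basal_control_rep1
    # per-base IP coverage inside the peak vs the CDS interior (far from
    # the peak and from edge ramps)
    mods <- kept_models(collapse_models(sim$annotation))
    map_in <- function(s1, s2) {
      # mean coverage over spliced interval [s1, s2)
      blocks <- meripr:::spliced_to_genomic(
        meripr:::model_exon_map(mods),
        tibble(gene_id = tr$gene_id[1], s1 = s1, s2 = s2)
      )
      covs <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
        per_base_coverage(ip, blocks$chrom[i], blocks$gstart[i], blocks$gend[i])
      }))
      mean(covs)
    }
    pk <- map_in(tr$peak_sstart[1] + 10L, tr$peak_send[1] - 10L)
    flank <- map_in(500L, 900L)
    pk / flank
  }, numeric(1))
  # mean ratio across seeds close to the planted gamma = 8
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 8), 3 * se + 1)
})

test_that("gamma = 1 everywhere yields a null IP library with ~no peaks", {
  cfg <- sim_config(n_genes = 40, gamma = 1)
  sim <- sim_annotation(cfg, seed = 14)
  libs <- sim_reads(sim, seed = 15, conditions = "basal",
    genotypes = "control", n_replicates = 1)
  mods <- kept_models(collapse_models(sim$annotation))
  pk <- call_peaks(libs$ip_basal_control_rep1, libs$input_basal_control_rep1,
    mods)
  expect_lte(nrow(pk), 1)
})

test_that("DE tables carry the planted composition and determinism", {
  sim <- sim_annotation(sim_config(n_genes = 200), seed = 4)
  d1 <- sim_de_table(sim, seed = 5)
  d2 <- sim_de_table(sim, seed = 5)
  expect_identical(as.data.frame(d1$table), as.data.frame(d2$table))
  labels <- classify_de(d1$table)
  expect_equal(labels$label, d1$truth$direction)
  # modified genes skew upward relative to others
  j <- inner_join(labels, sim$truth[, c("gene_id", "modified")], by = "gene_id") |>
    filter(label != "ns")
  p_up_mod <- mean(j$label[j$modified] == "up")
  p_up_other <- mean(j$label[!j$modified] == "up")
  expect_gt(p_up_mod, p_up_other)
})

test_that("decay series are deterministic and recover planted half-lives", {
  sim <- sim_annotation(sim_config(n_genes = 40), seed = 6)
  d1 <- sim_decay(sim, seed = 7)
  d2 <- sim_decay(sim, seed = 7)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # noise-free series recover k exactly
  d0 <- sim_decay(sim, seed = 8, noise_sdlog = 0)
  g <- d0$gene_id[1]
  ser <- d0 |> filter(gene_id == g, genotype == "control", replicate == 1)
  fit <- fit_decay(ser$time, ser$level)
  expect_equal(fit$k, log(2) / sim$truth$half_life_control[
    sim$truth$gene_id == g], tolerance = 1e-10)
  # knockdown series decay slower for modified genes
  kd <- d0 |> filter(gene_id == g, genotype == "knockdown", replicate == 1)
  expect_equal(fit_decay(kd$time, kd$level)$k,
    log(2) / sim$truth$half_life_knockdown[sim$truth$gene_id == g],
    tolerance = 1e-10)
})

test_that("planted 1 h vs 4 h half-lives separate in the remaining-at-4h test", {
  sim <- sim_annotation(sim_config(n_genes = 30), seed = 16)
  hits <- vapply(1:10, function(s) {
    d <- sim_decay(sim, seed = 20 + s)
    g <- sim$truth$gene_id[sim$truth$modified][1]
    rem <- d |> filter(gene_id == g, time %in% c(0, 4)) |>
      group_by(genotype, replicate) |>
      summarise(frac = mean(level[time == 4]) / mean(level[time == 0]),
        .groups = "drop")
    compare_remaining(rem$frac[rem$genotype == "knockdown"],
      rem$frac[rem$genotype == "control"])$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
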