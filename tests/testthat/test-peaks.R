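one_gene_windows <- function(u5 = 100L, cd = 300L, u3 = 100L) {
  m <- collapse_models(as_annotation(tibble(
    gene_id = "g1", transcript_id = "t1",
    feature = c("exon", "cds"), chrom = "chr1", strand = "+",
    start = c(0L, u5), end = c(u5 + cd + u3, u5 + cd)
  )))
  list(m = m, w = make_windows(m))
}

mk_win_counts <- function(w, counts, lib) {
  x <- mutate(as_tibble(w), count = as.integer(counts))
  attr(x, "library_size") <- lib
  x
}

test_that("a strongly enriched window is significant with the exact binomial tail", {
  f <- one_gene_windows()
  n_win <- nrow(f$w)
  ip <- mk_win_counts(f$w, c(100L, rep(10L, n_win - 1)), 1e5)
  input <- mk_win_counts(f$w, rep(10L, n_win), 1e5)
  pk <- call_peaks(ip, input, f$m)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$enrichment, 10)
  # window [0,50) of a plus-strand intronless gene
  expect_equal(pk$start, 0L)
  expect_equal(pk$end, 50L)
  # p_adj bounded by the exact one-sided binomial tail times the BH factor
  p_raw <- pbinom(99, 110, 0.5, lower.tail = FALSE)
  expect_lt(p_raw, 1e-6)
  expect_lte(pk$p_adj, p_raw * n_win)
})

test_that("ip = input everywhere yields zero peaks", {
  f <- one_gene_windows()
  cnt <- mk_win_counts(f$w, rep(20L, nrow(f$w)), 1e5)
  pk <- call_peaks(cnt, cnt, f$m)
  expect_equal(nrow(pk), 0)
})

test_that("zero input library size is rejected", {
  f <- one_gene_windows()
  cnt <- mk_win_counts(f$w, rep(5L, nrow(f$w)), 1e5)
  expect_error(
    call_peaks(cnt, cnt, f$m, input_library_size = 0),
    "input library"
  )
})

test_that("adjacent significant windows merge into one peak", {
  f <- one_gene_windows()
  n_win <- nrow(f$w)
  counts <- rep(10L, n_win)
  counts[3:5] <- 200L
  ip <- mk_win_counts(f$w, counts, 1e5)
  input <- mk_win_counts(f$w, rep(10L, n_win), 1e5)
  pk <- call_peaks(ip, input, f$m)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$n_windows, 3L)
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 250L)
})

test_that("peak region assignment follows the majority rule with priority ties", {
  f <- one_gene_windows(u5 = 100L, cd = 300L, u3 = 100L)
  mk_peak <- function(s, e) {
    p <- tibble(
      chrom = "chr1", start = s, end = e, gene_id = "g1", strand = "+",
      n_windows = 1L, enrichment = 5, p_adj = 1e-4, score = 4,
      region = NA_character_
    )
    class(p) <- c("peak_set", class(tibble()))
    p
  }
  # fully inside 5'UTR
  expect_equal(assign_peak_region(mk_peak(10L, 60L), f$m)$region, "utr5")
  # 40 bp in CDS, 60 bp in 3'UTR -> utr3
  expect_equal(assign_peak_region(mk_peak(360L, 460L), f$m)$region, "utr3")
  # exact 50/50 utr5/cds tie -> utr5 by priority
  expect_equal(assign_peak_region(mk_peak(50L, 150L), f$m)$region, "utr5")
  # no exonic overlap -> unassigned with warning
  mi <- collapse_models(as_annotation(tibble(
    gene_id = "g1", transcript_id = "t1",
    feature = c("exon", "exon", "cds"), chrom = "chr1", strand = "+",
    start = c(0L, 500L, 30L), end = c(100L, 1000L, 560L)
  )))
  expect_warning(out <- assign_peak_region(mk_peak(200L, 300L), mi), "unassigned")
  expect_true(is.na(out$region))
})

test_that("majority rule agrees with per-base brute-force labeling", {
  withr::local_seed(13)
  n_checked <- 0
  for (i in 1:40) {
    ann <- random_gene_annotation()
    m <- collapse_models(ann)
    lab <- oracle_label_map(
      as_tibble(ann) |> filter(feature == "exon"),
      as_tibble(ann) |> filter(feature == "cds"), ann$strand[1]
    )
    lo <- min(m$start); hi <- max(m$end)
    for (j in 1:25) {
      s <- sample(lo:(hi - 10), 1)
      e <- s + sample(10:120, 1)
      p <- tibble(
        chrom = "chr1", start = s, end = as.integer(e), gene_id = "g1",
        strand = ann$strand[1], n_windows = 1L, enrichment = 1,
        p_adj = 0.01, score = 2, region = NA_character_
      )
      class(p) <- c("peak_set", class(tibble()))
      bp <- table(lab$region[lab$pos >= s & lab$pos < e])
      got <- suppressWarnings(assign_peak_region(p, m)$region)
      if (length(bp) == 0) {
        expect_true(is.na(got))
      } else {
        mx <- max(bp)
        winners <- names(bp)[bp == mx]
        want <- c("utr5", "cds", "utr3")[min(match(winners, c("utr5", "cds", "utr3")))]
        expect_equal(got, want)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 500)
})

test_that("region distribution reports percentages that sum to 100", {
  mk <- function(n, region) {
    tibble(
      chrom = "chr1", start = 0L, end = 10L, gene_id = paste0("g", seq_len(n)),
      strand = "+", n_windows = 1L, enrichment = 5, p_adj = 1e-3, score = 3,
      region = region
    )
  }
  pk <- bind_rows(mk(94, "utr5"), mk(4, "cds"), mk(2, "utr3"))
  class(pk) <- c("peak_set", class(tibble()))
  d <- region_distribution(pk)
  expect_equal(d$pct[match(c("utr5", "cds", "utr3"), d$region)], c(94, 4, 2))
  expect_equal(sum(d$pct), 100)
  one <- mk(1, "cds")
  class(one) <- c("peak_set", class(tibble()))
  d1 <- region_distribution(one)
  expect_equal(d1$pct[d1$region == "cds"], 100)
  expect_error(region_distribution(mk(0, character(0))), "no assigned peaks")
})

test_that("identical inputs produce byte-identical peak BED output", {
  sim <- sim_annotation(sim_config(n_genes = 30), seed = 21)
  mods <- kept_models(collapse_models(sim$annotation))
  call_once <- function() {
    libs <- sim_reads(sim, seed = 22, conditions = "basal",
      genotypes = "control", n_replicates = 1)
    pk <- call_peaks(libs$ip_basal_control_rep1, libs$input_basal_control_rep1,
      mods)
    pk <- suppressWarnings(assign_peak_region(pk, mods))
    f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
    write_peaks_bed(pk, f)
    readBin(f, "raw", file.info(f)$size)
  }
  expect_identical(call_once(), call_once())
})
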