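enr_fixture <- function() {
  m <- collapse_models(as_annotation(tibble(
    gene_id = "g1", transcript_id = "t1",
    feature = c("exon", "cds"), chrom = "chr1", strand = "+",
    start = c(0L, 30L), end = c(160L, 130L)
  )))
  list(m = m, g = make_grid(m))
}

mk_counts <- function(g, counts, lib) {
  x <- tibble(gene_id = g$gene_id, bin = g$bin, count = as.integer(counts))
  attr(x, "library_size") <- lib
  x
}

test_that("enrichment is the ratio of renormalised summed replicates", {
  f <- enr_fixture()
  ipc <- mk_counts(f$g, rep(2L, 160), 1e6)
  inc <- mk_counts(f$g, rep(1L, 160), 1e6)
  e <- enrichment(ipc, inc, f$g, pseudocount = 0)
  expect_equal(unique(e$enrichment), 2)
  # replicate-sum invariance: k identical replicates equal one
  e2 <- enrichment(list(ipc, ipc), list(inc, inc), f$g, pseudocount = 0)
  expect_equal(e2$enrichment, e$enrichment)
  # brute force on random replicates
  withr::local_seed(3)
  ips <- lapply(1:3, function(i) mk_counts(f$g, rpois(160, 5), 5e5 + i * 1000))
  ins <- lapply(1:2, function(i) mk_counts(f$g, rpois(160, 3), 4e5 + i * 1000))
  got <- enrichment(ips, ins, f$g, pseudocount = 0.25)
  xs <- Reduce(`+`, lapply(ips, `[[`, "count"))
  ys <- Reduce(`+`, lapply(ins, `[[`, "count"))
  li <- sum(5e5 + (1:3) * 1000)
  ln <- sum(4e5 + (1:2) * 1000)
  want <- (xs / f$g$width / li * 1e6 + 0.25) / (ys / f$g$width / ln * 1e6 + 0.25)
  expect_equal(got$enrichment, want)
})

test_that("mismatched gene sets between ip and input are rejected by name", {
  f <- enr_fixture()
  ipc <- mk_counts(f$g, rep(1L, 160), 1e6)
  inc <- mk_counts(mutate(f$g, gene_id = "gX"), rep(1L, 160), 1e6)
  expect_error(enrichment(ipc, inc, f$g), "gX|g1")
})

test_that("metagene profile averages genes and flags flat signals", {
  f <- enr_fixture()
  e <- enrichment(mk_counts(f$g, rep(2L, 160), 1e6),
    mk_counts(f$g, rep(1L, 160), 1e6), f$g, pseudocount = 0)
  p <- metagene_profile(e)
  expect_equal(nrow(p), 160)
  expect_equal(p$mean, e$enrichment)   # one gene: profile equals its row
  expect_equal(unique(p$n_genes), 1L)
  expect_error(metagene_profile(e[0, ]), "empty")
})

test_that("row z-scores have mean 0, sd 1; constant rows flagged as zeros", {
  x <- tibble(
    gene_id = rep(c("a", "b"), each = 3), bin = rep(1:3, 2),
    value = c(1, 2, 3, 5, 5, 5)
  )
  z <- zscore_rows(x, value = "value")
  expect_equal(z$z[z$gene_id == "a"], c(-1, 0, 1))
  expect_true(all(z$constant[z$gene_id == "b"]))
  expect_equal(z$z[z$gene_id == "b"], c(0, 0, 0))
  withr::local_seed(1)
  big <- tibble(
    gene_id = rep(paste0("g", 1:20), each = 10),
    bin = rep(1:10, 20), value = rnorm(200)
  )
  zz <- zscore_rows(big, value = "value") |> group_by(gene_id) |>
    summarise(m = mean(z), s = sd(z))
  expect_true(all(abs(zz$m) < 1e-12))
  expect_true(all(abs(zz$s - 1) < 1e-12))
})

test_that("log2 ratio track matches the per-base formula", {
  # equal CPM coverage everywhere -> all zeros
  t0 <- log_ratio_track(rep(4, 50), rep(2, 50), ip_library_size = 4 * 50,
    input_library_size = 2 * 50, pseudocount = 0)
  expect_equal(t0$value, 0)
  # ip_cpm = 4 x input_cpm on an interval -> 2 there
  ip <- c(rep(1, 10), rep(4, 10))
  input <- rep(1, 20)
  t1 <- log_ratio_track(ip, input, ip_library_size = 1e6, input_library_size = 1e6,
    pseudocount = 0)
  expect_equal(t1$value, c(0, 2))
  expect_equal(t1$start, c(0L, 10L))
  expect_error(log_ratio_track(1:5, 1:6), "differ in length")
  # random coverages vs direct computation
  withr::local_seed(9)
  a <- rpois(100, 5); b <- rpois(100, 5) + 1
  tr <- log_ratio_track(a, b, ip_library_size = 1000, input_library_size = 2000)
  per_base <- log2((a / 1000 * 1e6 + 0.25) / (b / 2000 * 1e6 + 0.25))
  expanded <- unlist(Map(function(s, e, v) rep(v, e - s), tr$start, tr$end, tr$value))
  expect_equal(expanded, per_base)
})

test_that("per-base coverage accumulates overlapping reads", {
  reads <- tibble(
    read_id = c("a", "b"), chrom = "chr1",
    start = c(0L, 5L), end = c(10L, 15L)
  )
  cov <- per_base_coverage(reads, "chr1", 0L, 15L)
  expect_equal(cov, c(rep(1, 5), rep(2, 5), rep(1, 5)))
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  expect_equal(paired_region_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(paired_region_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  d <- c(1.1, 0.9, 1.0)
  r <- paired_region_test(d, rep(0, 3))
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(r$t, t_hand)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-abs(t_hand), 2))
  # agrees with stats::t.test paired
  withr::local_seed(2)
  a <- rnorm(20); b <- rnorm(20)
  tt <- t.test(a, b, paired = TRUE)
  r2 <- paired_region_test(a, b)
  expect_equal(r2$t, unname(tt$statistic))
  expect_equal(r2$p, tt$p.value)
  expect_error(paired_region_test(1:2, 2:3), "n >= 3")
})

test_that("paired test holds its size under a null shift", {
  withr::local_seed(31)
  ps <- replicate(400, {
    a <- rnorm(8); b <- rnorm(8)
    paired_region_test(a, b)$p
  })
  rate <- mean(ps < 0.05)
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})
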