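simple_gene <- function(strand = "+") {
  as_annotation(tibble(
    gene_id = "g1", transcript_id = "g1.t1",
    feature = c("exon", "cds"), chrom = "chr1", strand = strand,
    start = c(0L, 100L), end = c(300L, 200L)
  ))
}

test_that("single-transcript collapse labels UTRs strand-aware", {
  m <- collapse_models(simple_gene("+"))
  expect_equal(m$region, c("utr5", "cds", "utr3"))
  expect_equal(m$start, c(0L, 100L, 200L))
  expect_equal(m$end, c(100L, 200L, 300L))

  m2 <- collapse_models(simple_gene("-"))
  expect_equal(m2$region[m2$start == 200], "utr5")
  expect_equal(m2$region[m2$start == 0], "utr3")
  # minus strand: 5'UTR lies at higher genomic coordinates than the CDS
  u5 <- m2[m2$region == "utr5", ]
  cds <- m2[m2$region == "cds", ]
  expect_true(all(u5$start >= cds$end))
})

test_that("two transcripts with offset CDS collapse to the outer CDS span", {
  ann <- as_annotation(tibble(
    gene_id = "g1",
    transcript_id = c("t1", "t1", "t2", "t2"),
    feature = c("exon", "cds", "exon", "cds"),
    chrom = "chr1", strand = "+",
    start = c(0L, 100L, 0L, 150L), end = c(300L, 200L, 300L, 250L)
  ))
  m <- collapse_models(ann)
  expect_equal(m$region, c("utr5", "cds", "utr3"))
  expect_equal(m$start, c(0L, 100L, 250L))
  expect_equal(m$end, c(100L, 250L, 300L))
})

test_that("mixed strands within a gene are rejected", {
  ann <- as_annotation(tibble(
    gene_id = "g1", transcript_id = c("t1", "t2"), feature = "exon",
    chrom = "chr1", strand = c("+", "-"), start = c(0L, 50L), end = c(40L, 90L)
  ))
  expect_error(collapse_models(ann), "mixed strands")
})

test_that("collapse agrees with per-base brute-force labeling on random genes", {
  withr::local_seed(42)
  for (i in 1:25) {
    ann <- random_gene_annotation()
    m <- collapse_models(ann)
    ex <- as_tibble(ann) |> filter(feature == "exon")
    cds <- as_tibble(ann) |> filter(feature == "cds")
    lab <- oracle_label_map(ex, cds, ann$strand[1])
    # union conservation
    expect_equal(sum(m$end - m$start), nrow(lab))
    # per-base region labels agree
    got <- locate_position(m, rep("g1", nrow(lab)), lab$pos)
    expect_equal(got$region, lab$region)
    expect_equal(got$offset, lab$soffset)
  }
})

test_that("region lengths partition total exonic bp and mirror under strand flip", {
  withr::local_seed(7)
  for (i in 1:10) {
    u5 <- sample(40:200, 1); cd <- sample(120:600, 1); u3 <- sample(40:200, 1)
    nint <- sample(0:2, 1)
    br <- if (nint > 0) sort(sample(seq_len(u5 + cd + u3 - 1), nint)) else integer(0)
    plus <- {
      withr::with_seed(99 + i, random_gene_annotation(
        strand = "+", u5 = u5, cd = cd, u3 = u3, n_introns = nint
      ))
    }
    minus <- {
      withr::with_seed(99 + i, random_gene_annotation(
        strand = "-", u5 = u5, cd = cd, u3 = u3, n_introns = nint
      ))
    }
    rlp <- region_lengths(collapse_models(plus))
    rlm <- region_lengths(collapse_models(minus))
    expect_equal(rlp$utr5 + rlp$cds + rlp$utr3, rlp$total)
    # same seed, mirrored construction: region lengths identical
    expect_equal(rlp[c("utr5", "cds", "utr3")], rlm[c("utr5", "cds", "utr3")])
  }
})

test_that("filters keep/exclude by the documented rules and reason order", {
  mk <- function(id, u5, cd, u3, coding = TRUE) {
    segs <- list()
    at <- 0L
    if (coding) {
      if (u5 > 0) segs <- c(segs, list(tibble(region = "utr5", start = at, end = at + u5))) -> segs
      at <- at + u5
      segs <- c(segs, list(tibble(region = "cds", start = at, end = at + cd)))
      at <- at + cd
      if (u3 > 0) segs <- c(segs, list(tibble(region = "utr3", start = at, end = at + u3)))
    } else {
      segs <- list(tibble(region = NA_character_, start = 0L, end = cd))
    }
    bind_rows(segs) |>
      mutate(gene_id = id, chrom = "chr1", strand = "+", coding = coding)
  }
  models <- bind_rows(
    mk("ok", 100, 500, 100),
    mk("short5", 29, 500, 100),
    mk("short3", 100, 500, 29),
    mk("shortcds", 100, 99, 100),
    mk("nc", 0, 400, 0, coding = FALSE)
  )
  class(models) <- c("gene_models", class(tibble()))
  rep <- filter_models(models)
  expect_equal(sum(rep$kept), 1)
  expect_equal(rep$reason[match(
    c("ok", "short5", "short3", "shortcds", "nc"), rep$gene_id
  )], c(NA, "utr5_short", "utr3_short", "cds_short", "missing_utr"))
  # boundary: exactly 30/30/100 passes
  expect_true(filter_models(mk("b", 30, 100, 30) |>
    (\(x) { class(x) <- c("gene_models", class(tibble())); x })())$kept)
  # idempotence: filtering the kept set excludes nothing
  kept <- kept_models(models, rep)
  rep2 <- filter_models(kept)
  expect_true(all(rep2$kept))
})

test_that("locate_position flags off-model and intronic positions", {
  ann <- as_annotation(tibble(
    gene_id = "g1", transcript_id = "t1",
    feature = c("exon", "exon", "cds"),
    chrom = "chr1", strand = "+",
    start = c(0L, 200L, 50L), end = c(100L, 300L, 250L)
  ))
  m <- collapse_models(ann)
  expect_error(locate_position(m, "g1", 10, chrom = "chr2"), "chr2")
  got <- locate_position(m, rep("g1", 3), c(150L, 0L, 299L))
  expect_equal(got$region, c("intronic", "utr5", "utr3"))
  # minus-strand mirror: utr5=[200,300), pos 299 -> (utr5, 0)
  m2 <- collapse_models(simple_gene("-"))
  got2 <- locate_position(m2, "g1", 299)
  expect_equal(got2$region, "utr5")
  expect_equal(got2$offset, 0L)
})
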