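#' Configuration for the synthetic MeRIP-seq generator
#'
#' Collects every knob of the simulated study design with defaults chosen
#' to mirror a brain MeRIP-seq experiment contrasting heat shock (HS)
#' against basal conditions and a methyltransferase knockdown against
#' control: three replicates per library, ~30x input coverage, planted
#' peaks heavily weighted to the 5'UTR, an 8-fold IP enrichment inside
#' peaks that collapses to 1 in the knockdown, an HS-responsive 5'UTR
#' boost, an upward DE skew for modified genes, and faster decay of
#' modified transcripts in the control genotype.
#'
#' @param n_genes Number of genes (default 200).
#' @param len_utr5,len_cds,len_utr3 Uniform length ranges in bp.
#' @param violation_frac Named fractions of genes planted to violate each
#'   model filter (`utr5_short`, `utr3_short`, `cds_short`,
#'   `missing_utr`); counts are rounded and the sets are disjoint.
#' @param max_introns Maximum introns per gene (default 2).
#' @param intron_len Uniform intron length range.
#' @param max_transcripts Transcripts per gene drawn from
#'   `1:max_transcripts`; extra transcripts trim UTR ends but share the
#'   CDS core, so the exon union equals the primary transcript.
#' @param fraction_modified Fraction of filter-passing genes carrying a
#'   planted peak (default 0.15).
#' @param region_weights Placement probabilities of planted peaks over
#'   (5'UTR, CDS, 3'UTR); default `c(0.9, 0.07, 0.03)`.
#' @param peak_len Planted peak length in spliced bp (default 100,
#'   truncated to the host region).
#' @param gamma IP enrichment fold inside planted peaks (default 8).
#' @param hs_utr5_factor Multiplier applied to gamma of 5'UTR peaks under
#'   HS (default 1.5).
#' @param frac_dependent Fraction of planted peaks that are
#'   methyltransferase-dependent, i.e. collapse to gamma = 1 in the
#'   knockdown (default 1).
#' @param depth Mean per-base input coverage (default 30).
#' @param read_length Read length in bp (default 50).
#' @param n_replicates Replicates per library type (default 3).
#' @param expr_sdlog Log-sd of per-gene expression weights (default 0.5).
#' @param p_up_modified,p_up_other Probability that a significantly DE
#'   gene is upregulated, for modified vs other genes (defaults 0.8/0.4).
#' @param frac_sig Fraction of genes significantly DE (default 0.5).
#' @param lfc_meanlog,lfc_sdlog Lognormal magnitude of significant log2
#'   fold changes.
#' @param de_alpha DE significance level used when drawing adjusted p
#'   values (default 0.05).
#' @param half_life_control,half_life_knockdown Decay half-lives (h) of
#'   modified transcripts in the two genotypes (defaults 1 and 4);
#'   unmodified transcripts keep the control half-life in both.
#' @param decay_times Sampling timepoints in hours.
#' @param decay_noise_sdlog Lognormal noise sd on decay levels.
#' @param n_decay_replicates Replicates per decay series (default 6).
#' @param chrom_genes Genes per simulated chromosome (default 25).
#' @param gene_gap Intergenic gap in bp (default 1000).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       len_utr5 = c(60, 600), len_cds = c(300, 3000),
                       len_utr3 = c(60, 600),
                       violation_frac = c(utr5_short = 0, utr3_short = 0,
                         cds_short = 0, missing_utr = 0),
                       max_introns = 2, intron_len = c(60, 400),
                       max_transcripts = 3,
                       fraction_modified = 0.15,
                       region_weights = c(utr5 = 0.9, cds = 0.07, utr3 = 0.03),
                       peak_len = 100, gamma = 8, hs_utr5_factor = 1.5,
                       frac_dependent = 1,
                       depth = 30, read_length = 50, n_replicates = 3,
                       expr_sdlog = 0.5,
                       p_up_modified = 0.8, p_up_other = 0.4, frac_sig = 0.5,
                       lfc_meanlog = log(1.5), lfc_sdlog = 0.4,
                       de_alpha = 0.05,
                       half_life_control = 1, half_life_knockdown = 4,
                       decay_times = c(0, 0.5, 1, 2, 4),
                       decay_noise_sdlog = 0.1, n_decay_replicates = 6,
                       chrom_genes = 25, gene_gap = 1000) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_genes > 0, cfg$depth > 0, cfg$read_length > 0,
    all(cfg$region_weights >= 0), abs(sum(cfg$region_weights) - 1) < 1e-8,
    all(cfg$violation_frac >= 0), sum(cfg$violation_frac) <= 1,
    cfg$fraction_modified >= 0, cfg$fraction_modified <= 1
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an annotation, genome and ground-truth skeleton
#'
#' Generates `n_genes` genes laid out on one chromosome per `chrom_genes`
#' genes. Each gene has 5'UTR/CDS/3'UTR lengths drawn from the configured
#' ranges, 0-2 introns, and 1-3 transcripts sharing the CDS core (extra
#' transcripts trim the UTR ends, so the collapsed exon union equals the
#' primary transcript). A configurable fraction of genes violates each
#' model filter. Modified genes get one planted peak whose region is drawn
#' from `region_weights` and which lies wholly within that region.
#' Output is byte-reproducible under `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `merip_sim`: `annotation`
#'   (`meripr_annotation`), `genome` (named character vector of
#'   chromosome sequences), `truth` (per-gene tibble: validity, planted
#'   violation, expression weight, modification flag, peak coordinates,
#'   gamma, dependence, half-lives), and `config`.
#' @export
sim_annotation <- function(config = sim_config(), seed = 1) {
  cfg <- config
  withr::with_seed(seed, {
    n <- cfg$n_genes
    runif_len <- function(rng, n) {
      as.integer(round(runif(n, rng[1], rng[2])))
    }
    # disjoint violation sets, deterministic counts
    v_counts <- vapply(cfg$violation_frac, function(f) as.integer(round(f * n)), 1L)
    pool <- sample.int(n)
    violation <- rep(NA_character_, n)
    at <- 1L
    for (rule in names(v_counts)) {
      k <- v_counts[[rule]]
      if (k > 0) {
        violation[pool[at:(at + k - 1L)]] <- rule
        at <- at + k
      }
    }
    u5 <- runif_len(cfg$len_utr5, n)
    cd <- runif_len(cfg$len_cds, n)
    u3 <- runif_len(cfg$len_utr3, n)
    u5[which(violation == "utr5_short")] <- sample(1:29,
      sum(violation == "utr5_short", na.rm = TRUE), replace = TRUE)
    u3[which(violation == "utr3_short")] <- sample(1:29,
      sum(violation == "utr3_short", na.rm = TRUE), replace = TRUE)
    cd[which(violation == "cds_short")] <- sample(30:99,
      sum(violation == "cds_short", na.rm = TRUE), replace = TRUE)
    noncoding <- !is.na(violation) & violation == "missing_utr"
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_id <- sprintf("g%03d", seq_len(n))
    chrom <- paste0("chr", (seq_len(n) - 1L) %/% cfg$chrom_genes + 1L)

    ann_rows <- vector("list", n)
    truth_rows <- vector("list", n)
    cursor <- integer(0)
    for (i in seq_len(n)) {
      Ttot <- if (noncoding[i]) cd[i] else u5[i] + cd[i] + u3[i]
      n_int <- sample(0:cfg$max_introns, 1)
      n_int <- min(n_int, Ttot - 1L)
      breaks <- if (n_int > 0) sort(sample(seq_len(Ttot - 1L), n_int)) else integer(0)
      ilens <- runif_len(cfg$intron_len, n_int)
      # forward layout: spliced ascending == genomic ascending
      ex_s <- c(0L, breaks)
      ex_e <- c(breaks, Ttot)
      goff <- cumsum(c(0L, ilens))
      g0 <- if (is.null(cursor[chrom[i]]) || is.na(cursor[chrom[i]])) 0L else cursor[chrom[i]]
      fstart <- g0 + ex_s + goff
      fend <- g0 + ex_e + goff
      glen <- Ttot + sum(ilens)
      cursor[chrom[i]] <- g0 + glen + as.integer(cfg$gene_gap)
      mirror <- function(s, e) {
        if (strand[i] == "+") list(s = s, e = e)
        else list(s = g0 + glen - (e - g0), e = g0 + glen - (s - g0))
      }
      # spliced->genomic for an interval [a,b) in forward layout
      sp2g <- function(a, b) {
        hit <- which(a < ex_e & b > ex_s)
        ss <- pmax(a, ex_s[hit])
        ee <- pmin(b, ex_e[hit])
        m <- mirror(g0 + ss + goff[hit], g0 + ee + goff[hit])
        tibble(start = as.integer(m$s), end = as.integer(m$e))
      }
      exm <- mirror(fstart, fend)
      exons <- tibble(start = as.integer(exm$s), end = as.integer(exm$e)) |>
        arrange(.data$start)
      n_tx <- sample(seq_len(cfg$max_transcripts), 1)
      tx_rows <- list()
      for (tx in seq_len(n_tx)) {
        if (tx == 1 || noncoding[i]) {
          tex <- exons
        } else {
          trim5 <- if (u5[i] > 1) sample(0:(u5[i] - 1L), 1) else 0L
          trim3 <- if (u3[i] > 1) sample(0:(u3[i] - 1L), 1) else 0L
          tex <- sp2g(trim5, Ttot - trim3) |> arrange(.data$start)
        }
        tid <- paste0(gene_id[i], ".t", tx)
        rows <- tex |> mutate(
          gene_id = gene_id[i], transcript_id = tid, feature = "exon",
          chrom = chrom[i], strand = strand[i]
        )
        if (!noncoding[i]) {
          cds_rows <- sp2g(u5[i], u5[i] + cd[i]) |>
            arrange(.data$start) |>
            mutate(
              gene_id = gene_id[i], transcript_id = tid, feature = "cds",
              chrom = chrom[i], strand = strand[i]
            )
          rows <- bind_rows(rows, cds_rows)
        }
        tx_rows[[tx]] <- rows
        if (noncoding[i]) break
      }
      ann_rows[[i]] <- list_rbind(tx_rows)
      truth_rows[[i]] <- tibble(
        gene_id = gene_id[i], chrom = chrom[i], strand = strand[i],
        violation = violation[i], valid = is.na(violation[i]),
        utr5_len = if (noncoding[i]) 0L else u5[i],
        cds_len = cd[i], utr3_len = if (noncoding[i]) 0L else u3[i],
        total_len = Ttot
      )
    }
    annotation <- new_annotation(
      list_rbind(ann_rows) |>
        select("gene_id", "transcript_id", "feature", "chrom", "strand",
          "start", "end") |>
        arrange(.data$gene_id, .data$transcript_id, .data$start)
    )
    truth <- list_rbind(truth_rows)
    truth$expr_w <- rlnorm(n, 0, cfg$expr_sdlog)

    # plant peaks in valid genes
    valid_idx <- which(truth$valid)
    n_mod <- as.integer(round(cfg$fraction_modified * length(valid_idx)))
    mod_idx <- sort(sample(valid_idx, n_mod))
    truth$modified <- FALSE
    truth$modified[mod_idx] <- TRUE
    truth$peak_region <- NA_character_
    truth$peak_sstart <- NA_integer_
    truth$peak_send <- NA_integer_
    truth$gamma <- NA_real_
    truth$dependent <- FALSE
    for (i in mod_idx) {
      reg <- sample(REGIONS, 1, prob = cfg$region_weights)
      rlen <- c(truth$utr5_len[i], truth$cds_len[i], truth$utr3_len[i])[match(reg, REGIONS)]
      plen <- min(cfg$peak_len, rlen)
      r0 <- switch(reg,
        utr5 = 0L,
        cds = truth$utr5_len[i],
        utr3 = truth$utr5_len[i] + truth$cds_len[i]
      )
      s <- r0 + sample(0:(rlen - plen), 1)
      truth$peak_region[i] <- reg
      truth$peak_sstart[i] <- s
      truth$peak_send[i] <- s + plen
      truth$gamma[i] <- cfg$gamma
      truth$dependent[i] <- runif(1) < cfg$frac_dependent
    }
    truth$half_life_control <- cfg$half_life_control
    truth$half_life_knockdown <- ifelse(
      truth$modified & truth$dependent,
      cfg$half_life_knockdown, cfg$half_life_control
    )

    # genomic span of planted peaks via the collapsed models
    models <- collapse_models(annotation)
    map <- model_exon_map(models)
    planted <- truth |>
      filter(.data$modified) |>
      select("gene_id", s1 = "peak_sstart", s2 = "peak_send")
    if (nrow(planted) > 0) {
      span <- spliced_to_genomic(map, planted) |>
        group_by(.data$gene_id) |>
        summarise(peak_start = min(.data$gstart), peak_end = max(.data$gend),
          .groups = "drop")
      truth <- left_join(truth, span, by = "gene_id")
    } else {
      truth$peak_start <- NA_integer_
      truth$peak_end <- NA_integer_
    }

    genome_len <- tapply(
      c(annotation$end, 0L), c(annotation$chrom, annotation$chrom[1]), max
    ) + 200L
    genome <- vapply(
      sort(names(genome_len)),
      function(ch) paste(sample(c("A", "C", "G", "T"), genome_len[[ch]],
        replace = TRUE), collapse = ""),
      character(1)
    )
    out <- list(annotation = annotation, genome = genome, truth = truth,
      config = cfg)
    class(out) <- "merip_sim"
    out
  })
}

# effective enrichment fold of each planted peak for a library
effective_gamma <- function(truth, condition, genotype, cfg) {
  g <- truth$gamma
  if (condition == "hs") {
    g <- ifelse(truth$peak_region == "utr5", g * cfg$hs_utr5_factor, g)
  }
  if (genotype == "knockdown") {
    g <- ifelse(truth$dependent, 1, g)
  }
  g
}

#' Simulate IP and input read libraries
#'
#' For each library, per-gene read counts are Poisson with mean
#' `depth * spliced_length / read_length * expression_weight`; read start
#' positions are uniform over the spliced transcript for input libraries.
#' IP libraries multiply the read-start rate by the peak's effective
#' enrichment fold for reads whose centre falls in a planted peak: the
#' knockdown collapses dependent peaks to fold 1, and HS multiplies the
#' fold of 5'UTR peaks by `hs_utr5_factor`. Spliced reads are emitted as
#' genomic blocks (one row per exon-side block).
#'
#' @param sim A `merip_sim` from [sim_annotation()].
#' @param seed Integer seed.
#' @param conditions Subset of `c("basal", "hs")`.
#' @param genotypes Subset of `c("control", "knockdown")`.
#' @param n_replicates Replicates per library (default from config).
#' @return A list of class `read_library_set`: one read-block tibble per
#'   library (named `<type>_<condition>_<genotype>_rep<r>`, each with a
#'   `library_size` attribute) plus a `manifest` attribute tibble.
#' @export
sim_reads <- function(sim, seed = 1, conditions = c("basal", "hs"),
                      genotypes = c("control", "knockdown"),
                      n_replicates = NULL) {
  cfg <- sim$config
  if (is.null(n_replicates)) n_replicates <- cfg$n_replicates
  truth <- sim$truth |> filter(.data$valid)
  models <- kept_models(collapse_models(sim$annotation))
  map <- model_exon_map(models)
  truth <- truth |> semi_join(distinct(map, .data$gene_id), by = "gene_id")
  rl <- cfg$read_length
  libs <- list()
  manifest <- list()
  withr::with_seed(seed, {
    for (condition in conditions) {
      for (genotype in genotypes) {
        gam <- effective_gamma(truth, condition, genotype, cfg)
        for (type in c("input", "ip")) {
          for (r in seq_len(n_replicates)) {
            lib_id <- paste0(type, "_", condition, "_", genotype, "_rep", r)
            starts_list <- vector("list", nrow(truth))
            genes_list <- vector("list", nrow(truth))
            for (gi in seq_len(nrow(truth))) {
              Ttot <- truth$total_len[gi]
              n_start <- max(1L, Ttot - rl + 1L)
              lam0 <- cfg$depth * Ttot / rl * truth$expr_w[gi]
              has_peak <- type == "ip" && truth$modified[gi] && !is.na(gam[gi]) && gam[gi] != 1
              if (has_peak) {
                # peak zone in read-start space: centres inside the peak
                z1 <- max(0L, truth$peak_sstart[gi] - rl %/% 2L)
                z2 <- min(n_start, truth$peak_send[gi] - rl %/% 2L)
                n_pk <- max(0L, z2 - z1)
                wsum <- (n_start - n_pk) + gam[gi] * n_pk
                lam <- lam0 * wsum / n_start
                nr <- rpois(1, lam)
                in_pk <- rbinom(1, nr, gam[gi] * n_pk / wsum)
                s <- c(
                  if (in_pk > 0) z1 + sample.int(n_pk, in_pk, replace = TRUE) - 1L else integer(0),
                  if (nr - in_pk > 0) {
                    out_pool <- c(seq_len(z1), seq.int(z2 + 1L, length.out = n_start - z2))
                    out_pool[sample.int(length(out_pool), nr - in_pk, replace = TRUE)] - 1L
                  } else integer(0)
                )
              } else {
                nr <- rpois(1, lam0)
                s <- sample.int(n_start, nr, replace = TRUE) - 1L
              }
              starts_list[[gi]] <- s
              genes_list[[gi]] <- rep(truth$gene_id[gi], length(s))
            }
            starts <- unlist(starts_list)
            genes <- unlist(genes_list)
            if (length(starts) == 0) {
              reads <- tibble(read_id = character(), chrom = character(),
                start = integer(), end = integer())
            } else {
              iv <- tibble(
                gene_id = genes,
                s1 = starts, s2 = pmin(starts + rl, rep(truth$total_len,
                  lengths(starts_list))),
                read_id = paste0(lib_id, ":", seq_along(starts))
              )
              reads <- spliced_to_genomic(map, iv) |>
                transmute(
                  read_id = .data$read_id, chrom = .data$chrom,
                  start = as.integer(.data$gstart), end = as.integer(.data$gend)
                ) |>
                arrange(.data$read_id, .data$start)
            }
            attr(reads, "library_size") <- length(starts)
            libs[[lib_id]] <- reads
            manifest[[lib_id]] <- tibble(
              library = lib_id, sample_type = type, condition = condition,
              genotype = genotype, replicate = r, n_reads = length(starts)
            )
          }
        }
      }
    }
  })
  attr(libs, "manifest") <- list_rbind(manifest)
  class(libs) <- "read_library_set"
  libs
}

#' Simulate a differential-expression table with a planted class skew
#'
#' Each gene is significantly DE with probability `frac_sig`; a
#' significant gene is upregulated with probability `p_up_modified` when
#' it carries a planted peak and `p_up_other` otherwise (for the `"hs"`
#' contrast; the knockdown contrast applies the same skew, emulating
#' de-repression of modified transcripts). Significant genes draw
#' adjusted p uniformly below `de_alpha` and lognormal fold-change
#' magnitudes; non-significant genes draw adjusted p uniformly above
#' `de_alpha`, so the planted composition recorded in the truth is exact.
#'
#' @param sim A `merip_sim`.
#' @param seed Integer seed.
#' @param contrast `"hs"` (HS vs basal) or `"knockdown"` (knockdown vs
#'   control); both use the modified-gene skew.
#' @return A list: `table` (tibble `gene_id`, `log2fc`, `p_adj`,
#'   `expressed`) and `truth` (tibble `gene_id`, `direction` in
#'   up/down/ns).
#' @export
sim_de_table <- function(sim, seed = 1, contrast = c("hs", "knockdown")) {
  contrast <- match.arg(contrast)
  cfg <- sim$config
  genes <- sim$truth |> filter(.data$valid)
  withr::with_seed(seed + match(contrast, c("hs", "knockdown")), {
    n <- nrow(genes)
    sig <- runif(n) < cfg$frac_sig
    p_up <- ifelse(genes$modified, cfg$p_up_modified, cfg$p_up_other)
    up <- runif(n) < p_up
    mag <- rlnorm(n, cfg$lfc_meanlog, cfg$lfc_sdlog)
    log2fc <- ifelse(sig, ifelse(up, mag, -mag), rnorm(n, 0, 0.2))
    p_adj <- ifelse(sig, runif(n) * cfg$de_alpha,
      cfg$de_alpha + runif(n) * (1 - cfg$de_alpha))
    list(
      table = tibble(gene_id = genes$gene_id, log2fc = log2fc, p_adj = p_adj,
        expressed = TRUE),
      truth = tibble(gene_id = genes$gene_id,
        direction = ifelse(sig, ifelse(up, "up", "down"), "ns"))
    )
  })
}

#' Simulate actinomycin-D decay time series
#'
#' Levels follow `exp(-k t)` with multiplicative lognormal noise, where
#' `k = ln(2) / half-life` comes from each gene's per-genotype truth:
#' modified, dependent genes decay with `half_life_control` in the
#' control genotype and `half_life_knockdown` in the knockdown;
#' unmodified genes keep the control half-life in both.
#'
#' @param sim A `merip_sim`.
#' @param seed Integer seed.
#' @param genes Gene ids to simulate (default: all modified genes, or the
#'   first 10 valid genes when none are modified).
#' @param noise_sdlog Lognormal noise sd; default from config.
#' @return A tibble `gene_id`, `genotype`, `replicate`, `time`, `level`.
#' @export
sim_decay <- function(sim, seed = 1, genes = NULL, noise_sdlog = NULL) {
  cfg <- sim$config
  if (is.null(noise_sdlog)) noise_sdlog <- cfg$decay_noise_sdlog
  truth <- sim$truth |> filter(.data$valid)
  if (is.null(genes)) {
    genes <- truth$gene_id[truth$modified]
    if (length(genes) == 0) genes <- head(truth$gene_id, 10)
  }
  tt <- truth |> filter(.data$gene_id %in% genes)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      gene_id = tt$gene_id,
      genotype = c("control", "knockdown"),
      replicate = seq_len(cfg$n_decay_replicates),
      time = cfg$decay_times
    ) |>
      left_join(
        tt |> select("gene_id", "half_life_control", "half_life_knockdown"),
        by = "gene_id"
      ) |>
      mutate(
        half_life = ifelse(.data$genotype == "control",
          .data$half_life_control, .data$half_life_knockdown),
        k = log(2) / .data$half_life,
        level = exp(-.data$k * .data$time) *
          (if (noise_sdlog > 0) rlnorm(n(), 0, noise_sdlog) else 1)
      ) |>
      select("gene_id", "genotype", "replicate", "time", "level")
    grid
  })
}

#' Compare called peaks with planted truth
#'
#' A planted peak counts as recovered when a called peak on the same
#' chromosome overlaps its genomic span by at least 1 bp; a called peak
#' overlapping no planted peak is spurious.
#'
#' @param peaks A `peak_set` of called peaks.
#' @param truth The `truth` tibble of a `merip_sim` (or any tibble with
#'   `modified`, `chrom`, `peak_start`, `peak_end`).
#' @return A one-row tibble: `n_true`, `n_called`, `n_recovered`,
#'   `sensitivity`, `n_false`, `false_rate`.
#' @export
evaluate_peaks <- function(peaks, truth) {
  tp <- as_tibble(truth) |>
    filter(.data$modified, !is.na(.data$peak_start))
  pk <- as_tibble(peaks)
  if (nrow(tp) == 0) {
    return(tibble(n_true = 0L, n_called = nrow(pk), n_recovered = 0L,
      sensitivity = NA_real_, n_false = nrow(pk),
      false_rate = if (nrow(pk) > 0) 1 else 0))
  }
  ov <- function(a_chrom, a1, a2, b_chrom, b1, b2) {
    vapply(seq_along(a1), function(i) {
      any(b_chrom == a_chrom[i] & b1 < a2[i] & b2 > a1[i])
    }, logical(1))
  }
  recovered <- if (nrow(pk) > 0) {
    ov(tp$chrom, tp$peak_start, tp$peak_end, pk$chrom, pk$start, pk$end)
  } else {
    rep(FALSE, nrow(tp))
  }
  spurious <- if (nrow(pk) > 0) {
    !ov(pk$chrom, pk$start, pk$end, tp$chrom, tp$peak_start, tp$peak_end)
  } else {
    logical(0)
  }
  tibble(
    n_true = nrow(tp), n_called = nrow(pk),
    n_recovered = sum(recovered), sensitivity = mean(recovered),
    n_false = sum(spurious),
    false_rate = if (nrow(pk) > 0) mean(spurious) else 0
  )
}

#' Compare a called m6A gene set with planted truth
#'
#' @param called Character vector of called gene ids.
#' @param truth The `truth` tibble of a `merip_sim`.
#' @return A one-row tibble: `n_true`, `n_called`, `n_hit`, `sensitivity`,
#'   `fdr`, `jaccard`.
#' @export
evaluate_m6a_genes <- function(called, truth) {
  true_set <- truth$gene_id[truth$modified & truth$dependent]
  hit <- intersect(called, true_set)
  tibble(
    n_true = length(true_set), n_called = length(called),
    n_hit = length(hit),
    sensitivity = if (length(true_set) > 0) length(hit) / length(true_set) else NA_real_,
    fdr = if (length(called) > 0) 1 - length(hit) / length(called) else 0,
    jaccard = length(hit) / length(union(called, true_set))
  )
}
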