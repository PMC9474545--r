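#' IP/input enrichment matrix from replicate bin counts
#'
#' Replicate raw counts are summed per bin within each sample type, the
#' sums are renormalised with the summed library sizes (reads per million
#' per bp), and the per-bin ratio `(ip + pseudocount) / (input +
#' pseudocount)` is computed. Summing counts before division (rather than
#' averaging per-replicate ratios) follows the convention of adding
#' replicates of the same condition and sample type together.
#'
#' @param ip,input A `bin_counts` tibble or a list of them (replicates).
#' @param grid The matching `bin_grid`.
#' @param pseudocount Added to both normalised coverages (default 0.25).
#' @param ip_library_sizes,input_library_sizes Optional numeric vectors
#'   overriding the `library_size` attributes of the count tables.
#' @return A tibble of class `enrichment_matrix`: `gene_id`, `bin`,
#'   `region`, `width`, `ip_value`, `input_value`, `enrichment`;
#'   attributes `pseudocount`, `ip_library_size`, `input_library_size`.
#' @export
enrichment <- function(ip, input, grid, pseudocount = 0.25,
                       ip_library_sizes = NULL, input_library_sizes = NULL) {
  ip <- if (inherits(ip, "data.frame")) list(ip) else ip
  input <- if (inherits(input, "data.frame")) list(input) else input
  pooled <- function(reps, sizes, label) {
    if (is.null(sizes)) {
      sizes <- map_dbl(reps, function(r) {
        s <- attr(r, "library_size")
        if (is.null(s)) abort(paste0(label, " replicate lacks a library_size"))
        s
      })
    }
    genes <- map(reps, function(r) sort(unique(r$gene_id)))
    if (length(unique(map_chr(genes, paste, collapse = "\r"))) > 1) {
      abort(paste0("mismatched gene sets across ", label, " replicates"))
    }
    counts <- reps |>
      map(~ select(as_tibble(.x), "gene_id", "bin", "count")) |>
      list_rbind() |>
      group_by(.data$gene_id, .data$bin) |>
      summarise(count = sum(.data$count), .groups = "drop")
    list(counts = counts, size = sum(sizes))
  }
  pi <- pooled(ip, ip_library_sizes, "ip")
  pn <- pooled(input, input_library_sizes, "input")
  gi <- sort(unique(pi$counts$gene_id))
  gn <- sort(unique(pn$counts$gene_id))
  if (!identical(gi, gn)) {
    missing <- union(setdiff(gi, gn), setdiff(gn, gi))
    abort(paste0(
      "ip and input cover different gene sets; offending genes: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  geom <- as_tibble(grid) |> select("gene_id", "bin", "region", "width")
  out <- geom |>
    inner_join(rename(pi$counts, ip_count = "count"), by = c("gene_id", "bin")) |>
    inner_join(rename(pn$counts, input_count = "count"), by = c("gene_id", "bin")) |>
    mutate(
      ip_value = .data$ip_count / .data$width / pi$size * 1e6,
      input_value = .data$input_count / .data$width / pn$size * 1e6,
      enrichment = (.data$ip_value + pseudocount) / (.data$input_value + pseudocount)
    ) |>
    select("gene_id", "bin", "region", "width", "ip_value", "input_value", "enrichment")
  attr(out, "pseudocount") <- pseudocount
  attr(out, "ip_library_size") <- pi$size
  attr(out, "input_library_size") <- pn$size
  class(out) <- c("enrichment_matrix", class(tibble()))
  out
}

#' Metagene profile: per-bin mean across genes
#'
#' @param x An `enrichment_matrix` (averages the `enrichment` column) or a
#'   `bin_coverage` (averages `value`).
#' @return A tibble of class `metagene_profile`: `bin`, `region`, `mean`,
#'   `n_genes` (genes contributing to each bin).
#' @export
metagene_profile <- function(x) {
  x <- as_tibble(x)
  value <- if ("enrichment" %in% names(x)) "enrichment" else "value"
  if (nrow(x) == 0) abort("empty matrix: no genes to profile")
  out <- x |>
    group_by(.data$bin, .data$region) |>
    summarise(
      mean = mean(.data[[value]][is.finite(.data[[value]])]),
      n_genes = sum(is.finite(.data[[value]])),
      .groups = "drop"
    ) |>
    arrange(.data$bin)
  class(out) <- c("metagene_profile", class(tibble()))
  out
}

#' Row z-scores for heatmap display
#'
#' Scales each gene's values to mean 0 and sample standard deviation 1
#' (n-1 denominator). Rows with fewer than two distinct values cannot be
#' scaled; they are emitted as zeros and flagged `constant`.
#'
#' @param x An `enrichment_matrix` or `bin_coverage` tibble.
#' @param value Column to scale; defaults to `enrichment` when present,
#'   else `value`.
#' @return The input with columns `z` and `constant` added.
#' @export
zscore_rows <- function(x, value = NULL) {
  x <- as_tibble(x)
  if (is.null(value)) value <- if ("enrichment" %in% names(x)) "enrichment" else "value"
  x |>
    group_by(.data$gene_id) |>
    mutate(
      constant = n_distinct(.data[[value]]) < 2,
      z = ifelse(.data$constant, 0,
        (.data[[value]] - mean(.data[[value]])) / sd(.data[[value]])
      )
    ) |>
    ungroup()
}

#' Per-base read coverage over a genomic span
#'
#' @param reads Read block tibble.
#' @param chrom Chromosome name.
#' @param start,end Span (0-based half-open).
#' @return Integer vector of length `end - start`: reads covering each base.
#' @export
per_base_coverage <- function(reads, chrom, start, end) {
  r <- as_tibble(reads) |>
    filter(.data$chrom == .env$chrom, .data$end > .env$start, .data$start < .env$end)
  cov <- integer(end - start)
  if (nrow(r) > 0) {
    s <- pmax(r$start, start) - start
    e <- pmin(r$end, end) - start
    delta <- integer(end - start + 1L)
    for (i in seq_along(s)) {
      delta[s[i] + 1L] <- delta[s[i] + 1L] + 1L
      delta[e[i] + 1L] <- delta[e[i] + 1L] - 1L
    }
    cov <- cumsum(delta[-length(delta)])
  }
  cov
}

#' Per-base log2(IP/input) track
#'
#' CPM-normalises each per-base coverage vector by its library size and
#' returns `log2((ip_cpm + pseudocount) / (input_cpm + pseudocount))` per
#' base, as a run-compressed bedGraph-style tibble.
#'
#' @param ip,input Numeric per-base coverage vectors over the same span.
#' @param chrom Chromosome name for the output intervals.
#' @param start Span start (0-based; default 0).
#' @param ip_library_size,input_library_size Totals used for CPM
#'   normalisation; default to `sum(ip)` / `sum(input)`.
#' @param pseudocount Added to both CPM values (default 0.25).
#' @return A tibble `chrom`, `start`, `end`, `value` (adjacent equal
#'   values merged), suitable for [write_bedgraph()].
#' @export
log_ratio_track <- function(ip, input, chrom = "chr1", start = 0,
                            ip_library_size = NULL, input_library_size = NULL,
                            pseudocount = 0.25) {
  if (length(ip) != length(input)) {
    abort("ip and input coverage spans differ in length")
  }
  if (is.null(ip_library_size)) ip_library_size <- sum(ip)
  if (is.null(input_library_size)) input_library_size <- sum(input)
  ip_cpm <- ip / ip_library_size * 1e6
  in_cpm <- input / input_library_size * 1e6
  val <- log2((ip_cpm + pseudocount) / (in_cpm + pseudocount))
  r <- rle(val)
  ends <- cumsum(r$lengths)
  run_start <- as.integer(start + c(0L, ends[-length(ends)]))
  run_end <- as.integer(start + ends)
  tibble(chrom = chrom, start = run_start, end = run_end, value = r$values)
}

#' Write a track tibble as bedGraph
#'
#' @param track Tibble `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @param name Track name for the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = "meripr") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  writeLines(
    sprintf("%s\t%d\t%d\t%g", track$chrom, track$start, track$end, track$value),
    con
  )
  invisible(path)
}

#' Per-gene mean enrichment within a region
#'
#' Convenience for condition comparisons of, e.g., 5'UTR enrichment.
#'
#' @param x An `enrichment_matrix` or `bin_coverage` tibble.
#' @param region One of `"utr5"`, `"cds"`, `"utr3"`.
#' @return A tibble `gene_id`, `mean` ordered by `gene_id`.
#' @export
region_mean <- function(x, region = "utr5") {
  x <- as_tibble(x)
  value <- if ("enrichment" %in% names(x)) "enrichment" else "value"
  x |>
    filter(.data$region == .env$region) |>
    group_by(.data$gene_id) |>
    summarise(mean = mean(.data[[value]]), .groups = "drop") |>
    arrange(.data$gene_id)
}

#' Paired two-tailed t-test between matched per-gene values
#'
#' Standard paired t-test on per-gene differences (e.g. mean 5'UTR
#' enrichment in two conditions over the same genes). When all differences
#' are zero the statistic is defined as t = 0 with p = 1; when the
#' differences are constant but non-zero the statistic is infinite with
#' p = 0 (degenerate, flagged by a warning).
#'
#' @param a,b Numeric vectors in the same gene order, length >= 3.
#' @return A one-row tibble: `estimate` (mean difference), `t`, `df`, `p`,
#'   `n`.
#' @export
paired_region_test <- function(a, b) {
  if (length(a) != length(b)) abort("paired vectors differ in length")
  n <- length(a)
  if (n < 3) abort("paired test requires n >= 3")
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      return(tibble(estimate = 0, t = 0, df = n - 1, p = 1, n = n))
    }
    warn("zero variance with non-zero mean difference; p set to 0")
    return(tibble(estimate = m, t = sign(m) * Inf, df = n - 1, p = 0, n = n))
  }
  t <- m / (s / sqrt(n))
  tibble(estimate = m, t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1), n = n)
}
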