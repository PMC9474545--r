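#' Call enriched peaks from IP vs input window counts
#'
#' Surrogate peak caller: for every spliced window over a gene's exonic
#' bases, the IP count is tested against the proportion expected from the
#' input count and the two library sizes with a one-sided binomial test
#' (`x ~ Binomial(x + y, L_ip / (L_ip + L_in))`, upper tail). P-values are
#' Benjamini-Hochberg corrected over all non-empty windows, and maximal
#' runs of adjacent significant windows within a gene are merged into
#' peaks. Merged peaks whose pooled IP/input enrichment falls below
#' `min_enrichment` are discarded — the customary fold-enrichment
#' requirement of MeRIP peak callers, which removes isolated windows that
#' reach BH significance by counting noise alone. The procedure is
#' deterministic given its inputs.
#'
#' @param ip,input Either `window_counts` tibbles (from
#'   [count_window_reads()], sharing the same window grid) or read block
#'   tibbles, in which case windows of width `window` are built and
#'   counted internally.
#' @param models A `gene_models` tibble (filtered).
#' @param window Window width in spliced bp, used when `ip`/`input` are
#'   reads (default 50).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param min_enrichment Minimum pooled IP/input fold enrichment a merged
#'   peak must reach to be reported (default 2).
#' @param pseudocount Used in place of a zero input count when computing
#'   peak enrichment (default 0.25).
#' @param ip_library_size,input_library_size Optional overrides for the
#'   `library_size` attributes.
#' @return A tibble of class `peak_set`: `chrom`, `start`, `end` (genomic
#'   span, 0-based half-open), `gene_id`, `strand`, `n_windows`,
#'   `enrichment` (pooled IP/input ratio over the peak), `p_adj` (minimum
#'   over merged windows), `score` (-log10 `p_adj`), `region` (`NA` until
#'   [assign_peak_region()]).
#' @export
call_peaks <- function(ip, input, models, window = 50, alpha = 0.05,
                       min_enrichment = 2, pseudocount = 0.25,
                       ip_library_size = NULL, input_library_size = NULL) {
  as_windows <- function(x) {
    if ("read_id" %in% names(x)) {
      count_window_reads(x, models, make_windows(models, window))
    } else {
      x
    }
  }
  ip <- as_windows(ip)
  input <- as_windows(input)
  if (is.null(ip_library_size)) ip_library_size <- attr(ip, "library_size")
  if (is.null(input_library_size)) input_library_size <- attr(input, "library_size")
  if (is.null(input_library_size) || input_library_size <= 0) {
    abort("input library size must be positive")
  }
  if (is.null(ip_library_size) || ip_library_size <= 0) {
    abort("ip library size must be positive")
  }
  p0 <- ip_library_size / (ip_library_size + input_library_size)
  w <- as_tibble(ip) |>
    rename(x = "count") |>
    inner_join(
      as_tibble(input) |> select("gene_id", "win", y = "count"),
      by = c("gene_id", "win")
    ) |>
    mutate(
      tested = .data$x + .data$y > 0,
      p = ifelse(.data$tested,
        pbinom(.data$x - 1, .data$x + .data$y, p0, lower.tail = FALSE), 1
      )
    )
  w$p_adj <- NA_real_
  w$p_adj[w$tested] <- p.adjust(w$p[w$tested], method = "BH")
  w <- w |> mutate(sig = .data$tested & .data$p_adj < alpha)

  empty_peaks <- function() {
    out <- tibble(
      chrom = character(), start = integer(), end = integer(),
      gene_id = character(), strand = character(), n_windows = integer(),
      enrichment = double(), p_adj = double(), score = double(),
      region = character()
    )
    class(out) <- c("peak_set", class(tibble()))
    out
  }
  if (!any(w$sig, na.rm = TRUE)) {
    return(empty_peaks())
  }
  sig <- w |>
    filter(.data$sig) |>
    group_by(.data$gene_id) |>
    arrange(.data$win, .by_group = TRUE) |>
    mutate(run = cumsum(c(1L, diff(.data$win) != 1L))) |>
    group_by(.data$gene_id, .data$run) |>
    summarise(
      s1 = min(.data$sstart), s2 = max(.data$send),
      n_windows = n(),
      x = sum(.data$x), y = sum(.data$y),
      p_adj = min(.data$p_adj),
      .groups = "drop"
    )
  sig <- sig |>
    mutate(
      enrichment = (.data$x / ip_library_size) /
        (pmax(.data$y, pseudocount) / input_library_size),
      score = -log10(pmax(.data$p_adj, 1e-300))
    ) |>
    filter(.data$enrichment >= min_enrichment)
  if (nrow(sig) == 0) {
    return(empty_peaks())
  }
  blocks <- spliced_to_genomic(
    model_exon_map(models),
    sig |> mutate(peak_id = row_number()) |> select("gene_id", s1 = "s1", s2 = "s2", "peak_id")
  )
  span <- blocks |>
    group_by(.data$peak_id) |>
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      start = min(.data$gstart), end = max(.data$gend), .groups = "drop"
    )
  out <- sig |>
    mutate(peak_id = row_number()) |>
    left_join(span, by = "peak_id") |>
    transmute(
      chrom = .data$chrom, start = as.integer(.data$start),
      end = as.integer(.data$end), gene_id = .data$gene_id,
      strand = .data$strand, n_windows = .data$n_windows,
      enrichment = .data$enrichment, p_adj = .data$p_adj,
      score = .data$score, region = NA_character_
    ) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
  class(out) <- c("peak_set", class(tibble()))
  out
}

#' Assign peaks to transcript regions by the majority rule
#'
#' Each peak is assigned to the region (5'UTR, CDS, 3'UTR) holding the
#' largest exonic share of the peak; a peak straddling a boundary goes to
#' the region where more of it resides. Exact ties are broken by the fixed
#' priority 5'UTR > CDS > 3'UTR (configurable). Peaks with no exonic
#' overlap stay unassigned with a warning.
#'
#' @param peaks A `peak_set` tibble.
#' @param models A `gene_models` tibble.
#' @param priority Region priority order for ties.
#' @return `peaks` with `region` filled in.
#' @export
assign_peak_region <- function(peaks, models, priority = c("utr5", "cds", "utr3")) {
  pk <- as_tibble(peaks) |> mutate(.pid = row_number())
  segs <- as_tibble(models) |>
    filter(!is.na(.data$region)) |>
    select("gene_id", seg_start = "start", seg_end = "end", seg_region = "region")
  ov <- pk |>
    inner_join(segs, by = "gene_id", relationship = "many-to-many") |>
    mutate(bp = pmax(0L, pmin(.data$end, .data$seg_end) - pmax(.data$start, .data$seg_start))) |>
    filter(.data$bp > 0) |>
    group_by(.data$.pid, .data$seg_region) |>
    summarise(bp = sum(.data$bp), .groups = "drop") |>
    mutate(pri = match(.data$seg_region, priority)) |>
    group_by(.data$.pid) |>
    arrange(desc(.data$bp), .data$pri, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(".pid", assigned = "seg_region")
  out <- pk |>
    left_join(ov, by = ".pid") |>
    mutate(region = .data$assigned) |>
    select(-".pid", -"assigned")
  if (anyNA(out$region)) {
    warn(paste0(sum(is.na(out$region)), " peak(s) without exonic overlap left unassigned"))
  }
  class(out) <- c("peak_set", class(tibble()))
  out
}

#' Regional distribution of assigned peaks
#'
#' @param peaks A `peak_set` with `region` assigned.
#' @return A tibble `region`, `n`, `pct` (percentages over assigned peaks,
#'   summing to 100).
#' @export
region_distribution <- function(peaks) {
  pk <- as_tibble(peaks) |> filter(!is.na(.data$region))
  if (nrow(pk) == 0) abort("no assigned peaks to summarise")
  pk |>
    count(region = factor(.data$region, levels = REGIONS), name = "n", .drop = FALSE) |>
    mutate(region = as.character(.data$region), pct = 100 * .data$n / sum(.data$n))
}

#' Write peaks as BED6 plus annotation columns
#'
#' Columns: chrom, start, end, name (`gene:index`), score (-log10
#' adjusted p, capped at 1000), strand, then enrichment, adjusted p and
#' assigned region. Output ordering and number formatting are
#' deterministic so identical peak sets produce byte-identical files.
#'
#' @param peaks A `peak_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  pk <- as_tibble(peaks) |>
    arrange(.data$chrom, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$gene_id) |>
    mutate(name = paste0(.data$gene_id, ":", row_number())) |>
    ungroup()
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%.6g\t%.6g\t%s",
    pk$chrom, pk$start, pk$end, pk$name,
    pmin(as.integer(round(pk$score)), 1000L), pk$strand,
    pk$enrichment, pk$p_adj,
    ifelse(is.na(pk$region), ".", pk$region)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read peaks written by [write_peaks_bed()]
#'
#' @param path Input path.
#' @return A `peak_set`-shaped tibble.
#' @export
read_peaks_bed <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c(
      "chrom", "start", "end", "name", "score", "strand",
      "enrichment", "p_adj", "region"
    ),
    col_types = "ciicdcddc", progress = FALSE
  )
  out <- x |>
    mutate(
      gene_id = sub(":[0-9]+$", "", .data$name),
      region = ifelse(.data$region == ".", NA_character_, .data$region),
      score = -log10(pmax(.data$p_adj, 1e-300))
    ) |>
    select(
      "chrom", "start", "end", "gene_id", "strand",
      "enrichment", "p_adj", "score", "region"
    )
  class(out) <- c("peak_set", class(tibble()))
  out
}
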