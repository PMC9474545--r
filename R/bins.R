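#' Build the metagene bin grid for filtered gene models
#'
#' Tiles each gene's 5'UTR, CDS and 3'UTR into fixed numbers of evenly
#' spaced bins (defaults 30/100/30) on the spliced transcript axis. When a
#' region length is not divisible by its bin count, the remainder is
#' spread deterministically: the first `length %% n` bins (in transcript
#' orientation) are one bp wider, so widths differ by at most 1 bp.
#'
#' @param models A `gene_models` tibble; every gene must be coding and
#'   each region at least as long as its bin count.
#' @param n_utr5,n_cds,n_utr3 Bins per region.
#' @return A tibble of class `bin_grid`: `gene_id`, `bin` (1..total),
#'   `region`, `region_bin`, `width`, `sstart`, `send` (spliced
#'   coordinates on the per-gene axis, 0 = 5' end of the 5'UTR).
#' @export
make_grid <- function(models, n_utr5 = 30, n_cds = 100, n_utr3 = 30) {
  rl <- region_lengths(models)
  nbin <- c(utr5 = n_utr5, cds = n_cds, utr3 = n_utr3)
  long <- rl |>
    tidyr::pivot_longer(c("utr5", "cds", "utr3"),
      names_to = "region", values_to = "len"
    ) |>
    mutate(n = unname(nbin[.data$region]))
  short <- long |> filter(.data$len < .data$n)
  if (nrow(short) > 0) {
    abort(paste0(
      "region shorter than its bin count (cannot tile): gene ",
      short$gene_id[1], " ", short$region[1], " (", short$len[1], " bp < ",
      short$n[1], " bins)"
    ))
  }
  expanded <- long |>
    mutate(region = factor(.data$region, levels = REGIONS)) |>
    arrange(.data$gene_id, .data$region)
  grid <- expanded[rep(seq_len(nrow(expanded)), expanded$n), ] |>
    group_by(.data$gene_id, .data$region) |>
    mutate(
      region_bin = row_number(),
      width = .data$len %/% .data$n + as.integer(.data$region_bin <= .data$len %% .data$n)
    ) |>
    group_by(.data$gene_id) |>
    mutate(
      bin = row_number(),
      send = cumsum(.data$width),
      sstart = .data$send - .data$width,
      region = as.character(.data$region)
    ) |>
    ungroup() |>
    select("gene_id", "bin", "region", "region_bin", "width", "sstart", "send")
  attr(grid, "n_bins") <- c(n_utr5, n_cds, n_utr3)
  class(grid) <- c("bin_grid", class(tibble()))
  grid
}

#' Tile gene models into fixed-width spliced windows
#'
#' Windows tile the spliced transcript axis of each gene from its 5' end;
#' the last window of a gene may be shorter. Each window is labelled with
#' the region holding the majority of its bases (ties resolved in
#' transcript order 5'UTR > CDS > 3'UTR).
#'
#' @param models A `gene_models` tibble.
#' @param window Window width in spliced bp (default 50).
#' @return A tibble of class `window_grid`: `gene_id`, `win`, `region`,
#'   `width`, `sstart`, `send`.
#' @export
make_windows <- function(models, window = 50) {
  rl <- region_lengths(models)
  n_win <- pmax(1L, as.integer(ceiling(rl$total / window)))
  base <- rl[rep(seq_len(nrow(rl)), n_win), c("gene_id", "utr5", "cds", "utr3", "total")]
  wins <- base |>
    group_by(.data$gene_id) |>
    mutate(
      win = row_number(),
      sstart = (.data$win - 1L) * as.integer(window),
      send = pmin(.data$sstart + as.integer(window), .data$total),
      width = .data$send - .data$sstart
    ) |>
    ungroup() |>
    mutate(
      ov5 = pmax(0, pmin(.data$send, .data$utr5) - .data$sstart),
      ovc = pmax(0, pmin(.data$send, .data$utr5 + .data$cds) - pmax(.data$sstart, .data$utr5)),
      ov3 = pmax(0, .data$send - pmax(.data$sstart, .data$utr5 + .data$cds)),
      region = REGIONS[max.col(cbind(.data$ov5, .data$ovc, .data$ov3), ties.method = "first")]
    ) |>
    select("gene_id", "win", "region", "width", "sstart", "send")
  class(wins) <- c("window_grid", class(tibble()))
  wins
}

# Shared counting engine: number of distinct reads overlapping (>= 1 bp of
# genomic footprint) each per-gene spliced interval. `intervals` must have
# gene_id, sstart, send and a unique row id column named `iid`.
count_spliced_intervals <- function(reads, models, intervals) {
  map <- model_exon_map(models)
  # genomic overlap of read blocks with model segments
  r_gr <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end))
  m_gr <- GenomicRanges::GRanges(map$chrom, IRanges::IRanges(map$start + 1L, map$end))
  hits <- GenomicRanges::findOverlaps(r_gr, m_gr, minoverlap = 1L)
  ri <- S4Vectors::queryHits(hits)
  mi <- S4Vectors::subjectHits(hits)
  if (length(ri) == 0) {
    return(mutate(intervals, count = 0L))
  }
  i_start <- pmax(reads$start[ri], map$start[mi])
  i_end <- pmin(reads$end[ri], map$end[mi])
  plus <- map$strand[mi] == "+"
  s1 <- ifelse(plus,
    map$sstart[mi] + (i_start - map$start[mi]),
    map$sstart[mi] + (map$end[mi] - i_end)
  )
  s2 <- s1 + (i_end - i_start)
  pieces <- tibble(
    read_id = reads$read_id[ri], gene_id = map$gene_id[mi], s1 = s1, s2 = s2
  )
  # overlap pieces with intervals on a concatenated per-gene axis
  gene_len <- map |>
    group_by(.data$gene_id) |>
    summarise(len = max(.data$send), .groups = "drop")
  gene_len$offset <- cumsum(as.numeric(gene_len$len) + 1) - (gene_len$len + 1)
  off <- setNames(gene_len$offset, gene_len$gene_id)
  p_ir <- IRanges::IRanges(
    off[pieces$gene_id] + pieces$s1 + 1, off[pieces$gene_id] + pieces$s2
  )
  iv_ir <- IRanges::IRanges(
    off[intervals$gene_id] + intervals$sstart + 1,
    off[intervals$gene_id] + intervals$send
  )
  h2 <- IRanges::findOverlaps(p_ir, iv_ir, minoverlap = 1L)
  pair <- tibble(
    read_id = pieces$read_id[S4Vectors::queryHits(h2)],
    iid = intervals$iid[S4Vectors::subjectHits(h2)]
  ) |> distinct()
  counts <- pair |> count(.data$iid, name = "count")
  intervals |>
    left_join(counts, by = "iid") |>
    mutate(count = as.integer(tidyr::replace_na(.data$count, 0L)))
}

#' Count reads overlapping metagene bins
#'
#' A read increments every bin whose genomic footprint it overlaps by at
#' least 1 bp (so a read spanning several bins counts in each of them);
#' reads with no exonic overlap count nowhere.
#'
#' @param reads Read block tibble (see [read_alignments()]).
#' @param models A `gene_models` tibble (the grid's genes).
#' @param grid A `bin_grid` from [make_grid()].
#' @return A tibble of class `bin_counts`: `gene_id`, `bin`, `count`, with
#'   attribute `library_size` (distinct reads in `reads`, overridable at
#'   normalisation).
#' @export
count_bin_reads <- function(reads, models, grid) {
  iv <- as_tibble(grid) |> mutate(iid = row_number())
  res <- count_spliced_intervals(as_tibble(reads), models, iv) |>
    select("gene_id", "bin", "count")
  attr(res, "library_size") <- n_distinct(reads$read_id)
  class(res) <- c("bin_counts", class(tibble()))
  res
}

#' Count reads overlapping spliced windows
#'
#' Window analogue of [count_bin_reads()], used by the peak caller and the
#' differential methylation test.
#'
#' @inheritParams count_bin_reads
#' @param windows A `window_grid` from [make_windows()].
#' @return A tibble of class `window_counts`: `gene_id`, `win`, `region`,
#'   `width`, `sstart`, `send`, `count`; attribute `library_size`.
#' @export
count_window_reads <- function(reads, models, windows) {
  iv <- as_tibble(windows) |> mutate(iid = row_number())
  res <- count_spliced_intervals(as_tibble(reads), models, iv) |>
    select("gene_id", "win", "region", "width", "sstart", "send", "count")
  attr(res, "library_size") <- n_distinct(reads$read_id)
  class(res) <- c("window_counts", class(tibble()))
  res
}

#' Pool replicate count tables
#'
#' Sums raw counts cell-wise across replicate `bin_counts` or
#' `window_counts` tables and adds their library sizes, e.g. to feed
#' replicate-summed counts to [call_peaks()].
#'
#' @param counts A list of count tibbles sharing the same grid.
#' @return A single count tibble with summed counts and a summed
#'   `library_size` attribute.
#' @export
pool_counts <- function(counts) {
  sizes <- map_dbl(counts, function(x) {
    s <- attr(x, "library_size")
    if (is.null(s)) abort("count table lacks a library_size attribute")
    s
  })
  key <- setdiff(names(counts[[1]]), "count")
  out <- counts |>
    map(as_tibble) |>
    list_rbind() |>
    group_by(across(all_of(key))) |>
    summarise(count = sum(.data$count), .groups = "drop")
  attr(out, "library_size") <- sum(sizes)
  class(out) <- class(counts[[1]])
  out
}

#' Normalise bin counts to reads per million per bp
#'
#' Each count is divided by the bin width and the library size and scaled
#' by one million: `value = count / width / library_size * 1e6`.
#'
#' @param counts A `bin_counts` tibble.
#' @param grid The matching `bin_grid` (provides widths and regions).
#' @param library_size Total mapped reads; defaults to the `library_size`
#'   attribute carried by `counts`. Must be positive.
#' @return A tibble of class `bin_coverage`: `gene_id`, `bin`, `region`,
#'   `width`, `count`, `value`; attribute `library_size`.
#' @export
normalize_bins <- function(counts, grid, library_size = NULL) {
  if (is.null(library_size)) library_size <- attr(counts, "library_size")
  if (is.null(library_size) || library_size <= 0) {
    abort("library_size must be a positive count")
  }
  out <- as_tibble(counts) |>
    inner_join(
      as_tibble(grid) |> select("gene_id", "bin", "region", "width"),
      by = c("gene_id", "bin")
    ) |>
    mutate(value = .data$count / .data$width / library_size * 1e6) |>
    select("gene_id", "bin", "region", "width", "count", "value")
  attr(out, "library_size") <- library_size
  class(out) <- c("bin_coverage", class(tibble()))
  out
}

#' Write a gene-by-bin matrix as TSV
#'
#' Wide export of bin values with columns labelled `U1..U30`, `C1..C100`,
#' `D1..D30` (for the default grid geometry).
#'
#' @param x A `bin_coverage` or `enrichment_matrix` tibble.
#' @param path Output path.
#' @param value Column to spread (default `"value"`, or `"enrichment"`
#'   when present).
#' @return `path`, invisibly.
#' @export
write_bin_matrix <- function(x, path, value = NULL) {
  x <- as_tibble(x)
  if (is.null(value)) value <- if ("enrichment" %in% names(x)) "enrichment" else "value"
  lab <- x |>
    distinct(.data$bin, .data$region) |>
    arrange(.data$bin) |>
    group_by(.data$region) |>
    mutate(lab = paste0(c(utr5 = "U", cds = "C", utr3 = "D")[.data$region], row_number())) |>
    ungroup()
  wide <- x |>
    left_join(lab |> select("bin", "lab"), by = "bin") |>
    select("gene_id", "lab", value = all_of(value)) |>
    tidyr::pivot_wider(names_from = "lab", values_from = "value") |>
    arrange(.data$gene_id)
  readr::write_tsv(wide, path)
  invisible(path)
}
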