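#' Collapse transcripts into one model per gene
#'
#' For each gene, the exons of all transcripts are collapsed into their
#' interval union, and the union is split into 5'UTR, CDS and 3'UTR
#' segments relative to the outermost CDS boundaries over all transcripts
#' (strand-aware): exonic bases 5' of the outermost CDS start are 5'UTR,
#' bases between the outermost CDS boundaries are CDS, and bases 3' of the
#' outermost CDS end are 3'UTR. Genes with no CDS in any transcript are
#' flagged non-coding and keep unlabelled exon segments.
#'
#' @param annotation A `meripr_annotation` tibble (see [parse_annotation()]).
#' @return A tibble of class `gene_models` with one row per region segment:
#'   `gene_id`, `chrom`, `strand`, `coding`, `region` (`"utr5"`, `"cds"`,
#'   `"utr3"`, or `NA` for non-coding genes), `start`, `end` (0-based
#'   half-open), sorted genomically within gene.
#' @export
collapse_models <- function(annotation) {
  ann <- as_tibble(annotation)
  bad <- ann |>
    group_by(.data$gene_id) |>
    summarise(
      n_strand = n_distinct(.data$strand),
      n_chrom = n_distinct(.data$chrom), .groups = "drop"
    ) |>
    filter(.data$n_strand > 1 | .data$n_chrom > 1)
  if (nrow(bad) > 0) {
    abort(paste0("gene on mixed strands or chromosomes: ", bad$gene_id[1]))
  }

  per_gene <- ann |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    group_split()
  rows <- map(per_gene, function(g) {
    gene_id <- g$gene_id[1]
    chrom <- g$chrom[1]
    strand <- g$strand[1]
    ex <- g |> filter(.data$feature == "exon")
    if (nrow(ex) == 0) abort(paste0("gene without exons: ", gene_id))
    exu <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    cds <- g |> filter(.data$feature == "cds")
    if (nrow(cds) == 0) {
      return(tibble(
        gene_id = gene_id, chrom = chrom, strand = strand, coding = FALSE,
        region = NA_character_,
        start = IRanges::start(exu) - 1L, end = IRanges::end(exu)
      ))
    }
    cds_lo <- min(cds$start)
    cds_hi <- max(cds$end)
    # split the exon union at the outermost CDS boundaries
    cut_one <- function(lo, hi) {
      hit <- IRanges::restrict(exu, start = lo + 1L, end = hi)
      hit <- hit[IRanges::width(hit) > 0]
      tibble(start = IRanges::start(hit) - 1L, end = IRanges::end(hit))
    }
    span_lo <- min(IRanges::start(exu)) - 1L
    span_hi <- max(IRanges::end(exu))
    left <- cut_one(span_lo, cds_lo)
    mid <- cut_one(cds_lo, cds_hi)
    right <- cut_one(cds_hi, span_hi)
    if (strand == "+") {
      left$region <- "utr5"; right$region <- "utr3"
    } else {
      left$region <- "utr3"; right$region <- "utr5"
    }
    mid$region <- "cds"
    bind_rows(left, mid, right) |>
      mutate(gene_id = gene_id, chrom = chrom, strand = strand, coding = TRUE) |>
      select("gene_id", "chrom", "strand", "coding", "region", "start", "end") |>
      arrange(.data$start)
  })
  out <- list_rbind(rows)
  class(out) <- c("gene_models", class(tibble()))
  out
}

#' Region lengths of collapsed gene models
#'
#' @param models A `gene_models` tibble.
#' @return A tibble with one row per gene: `gene_id`, `coding`, `utr5`,
#'   `cds`, `utr3` (summed bp per region) and `total` exonic bp.
#' @export
region_lengths <- function(models) {
  as_tibble(models) |>
    mutate(width = .data$end - .data$start) |>
    group_by(.data$gene_id, .data$coding) |>
    summarise(
      utr5 = sum(.data$width[.data$region %in% "utr5"]),
      cds = sum(.data$width[.data$region %in% "cds"]),
      utr3 = sum(.data$width[.data$region %in% "utr3"]),
      total = sum(.data$width),
      .groups = "drop"
    )
}

#' Apply the gene-model inclusion filters
#'
#' A gene is kept iff both UTRs are present, each UTR is at least
#' `min_utr` bp, and the CDS is at least `min_cds` bp; genes lacking a CDS
#' (non-coding) or either UTR are excluded. Each excluded gene carries the
#' first failing reason in the fixed check order `missing_utr`,
#' `utr5_short`, `utr3_short`, `cds_short`.
#'
#' @param models A `gene_models` tibble.
#' @param min_utr Minimum UTR length in bp (default 30).
#' @param min_cds Minimum CDS length in bp (default 100).
#' @return A tibble of class `filter_report` with one row per gene:
#'   `gene_id`, `kept` (logical), `reason` (`NA` when kept).
#' @export
filter_models <- function(models, min_utr = 30, min_cds = 100) {
  rl <- region_lengths(models)
  rep <- rl |>
    mutate(
      reason = case_when(
        !.data$coding | .data$utr5 == 0 | .data$utr3 == 0 ~ "missing_utr",
        .data$utr5 < min_utr ~ "utr5_short",
        .data$utr3 < min_utr ~ "utr3_short",
        .data$cds < min_cds ~ "cds_short",
        TRUE ~ NA_character_
      ),
      kept = is.na(.data$reason)
    ) |>
    select("gene_id", "kept", "reason")
  class(rep) <- c("filter_report", class(tibble()))
  rep
}

#' Keep only the gene models passing the inclusion filters
#'
#' @param models A `gene_models` tibble.
#' @param report Optional `filter_report`; computed from `models` with
#'   default thresholds when missing.
#' @inheritParams filter_models
#' @return The filtered `gene_models` tibble.
#' @export
kept_models <- function(models, report = NULL, min_utr = 30, min_cds = 100) {
  if (is.null(report)) report <- filter_models(models, min_utr, min_cds)
  out <- semi_join(
    as_tibble(models), filter(report, .data$kept), by = "gene_id"
  )
  class(out) <- c("gene_models", class(tibble()))
  out
}

# Per-gene spliced coordinate map: one row per region segment, ordered 5'->3'
# in transcript orientation, with spliced offsets [sstart, send) on a
# per-gene axis whose 0 is the 5' end of the 5'UTR (or of the first exon for
# non-coding genes).
model_exon_map <- function(models) {
  as_tibble(models) |>
    mutate(
      region_rank = match(.data$region, REGIONS),
      ord = ifelse(.data$strand == "+", .data$start, -.data$start)
    ) |>
    group_by(.data$gene_id) |>
    arrange(.data$region_rank, .data$ord, .by_group = TRUE) |>
    mutate(
      width = .data$end - .data$start,
      send = cumsum(.data$width),
      sstart = .data$send - .data$width
    ) |>
    ungroup() |>
    select(
      "gene_id", "chrom", "strand", "region", "start", "end",
      "sstart", "send"
    )
}

# Map per-gene spliced intervals to genomic blocks.
# intervals: tibble(gene_id, s1, s2) (+ any extra columns, carried through).
# Returns one row per genomic block with columns chrom, strand, gstart, gend.
spliced_to_genomic <- function(map, intervals) {
  hits <- intervals |>
    inner_join(map, by = "gene_id", relationship = "many-to-many") |>
    filter(.data$s1 < .data$send, .data$s2 > .data$sstart) |>
    mutate(
      o1 = pmax(.data$s1, .data$sstart) - .data$sstart,
      o2 = pmin(.data$s2, .data$send) - .data$sstart,
      gstart = ifelse(.data$strand == "+",
        .data$start + .data$o1,
        .data$end - .data$o2
      ),
      gend = ifelse(.data$strand == "+",
        .data$start + .data$o2,
        .data$end - .data$o1
      )
    )
  hits |> select(-"start", -"end", -"sstart", -"send", -"o1", -"o2")
}

#' Locate genomic positions on a collapsed gene model
#'
#' Maps genomic positions onto a gene's transcript regions: returns the
#' region containing each position and the spliced offset (exonic bases
#' from the region's 5' end, in transcript orientation). Positions inside
#' the gene span but not exonic are flagged `"intronic"`; positions outside
#' the span are `"intergenic"`.
#'
#' @param models A `gene_models` tibble.
#' @param gene_id Gene identifier(s), recycled against `pos`.
#' @param pos Genomic position(s), 0-based.
#' @param chrom Optional chromosome name(s); an error is raised if it does
#'   not match the model's chromosome.
#' @return A tibble `gene_id`, `pos`, `region`, `offset` (`NA` off-exon).
#' @export
locate_position <- function(models, gene_id, pos, chrom = NULL) {
  q <- tibble(gene_id = gene_id, pos = as.integer(pos))
  if (!is.null(chrom)) q$qchrom <- chrom
  map <- model_exon_map(models)
  gene_info <- map |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[1],
      span_lo = min(.data$start), span_hi = max(.data$end), .groups = "drop"
    )
  q <- left_join(q, gene_info, by = "gene_id")
  if (anyNA(q$chrom)) {
    abort(paste0("unknown gene: ", q$gene_id[is.na(q$chrom)][1]))
  }
  if (!is.null(chrom) && any(q$qchrom != q$chrom)) {
    i <- which(q$qchrom != q$chrom)[1]
    abort(paste0(
      "position on ", q$qchrom[i], " but gene ", q$gene_id[i],
      " lies on ", q$chrom[i]
    ))
  }
  q$row <- seq_len(nrow(q))
  hit <- q |>
    inner_join(
      map |> select("gene_id", "region", "start", "end", "sstart", strand = "strand"),
      by = "gene_id", relationship = "many-to-many"
    ) |>
    filter(.data$pos >= .data$start, .data$pos < .data$end) |>
    mutate(
      s = ifelse(.data$strand == "+",
        .data$sstart + (.data$pos - .data$start),
        .data$sstart + (.data$end - 1L - .data$pos)
      )
    )
  region_off <- map |>
    group_by(.data$gene_id, .data$region) |>
    summarise(region_s0 = min(.data$sstart), .groups = "drop")
  hit <- hit |>
    left_join(region_off, by = c("gene_id", "region")) |>
    mutate(offset = .data$s - .data$region_s0) |>
    select("row", "region", "offset")
  out <- q |>
    left_join(hit, by = "row") |>
    mutate(
      region = case_when(
        !is.na(.data$region) ~ .data$region,
        .data$pos >= .data$span_lo & .data$pos < .data$span_hi ~ "intronic",
        TRUE ~ "intergenic"
      )
    ) |>
    select("gene_id", "pos", "region", "offset")
  out
}

#' Write gene models as a BED-like TSV
#'
#' One row per region segment with 0-based half-open coordinates.
#'
#' @param models A `gene_models` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_tsv <- function(models, path) {
  readr::write_tsv(as_tibble(models), path)
  invisible(path)
}
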