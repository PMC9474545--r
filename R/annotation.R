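#' Parse a GTF or GFF3 gene annotation
#'
#' Reads an annotation file and returns a tidy exon/CDS feature table with
#' gene and transcript linkage. Coordinates are converted from the 1-based
#' inclusive convention of GTF/GFF3 to the package-internal 0-based
#' half-open convention on read.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"` or `"gff3"`. Defaults to guessing from the file
#'   extension (`.gff`/`.gff3` is GFF3, anything else GTF).
#' @return A tibble of class `meripr_annotation` with one row per exon or
#'   CDS feature: `gene_id`, `transcript_id`, `feature` (`"exon"` or
#'   `"cds"`), `chrom`, `strand`, `start`, `end` (0-based half-open).
#' @details In GFF3, exons and CDS must carry a `Parent` naming a
#'   transcript feature (`mRNA`/`transcript`), which in turn has a `Parent`
#'   (or `gene_id`) naming the gene. A feature whose parent cannot be
#'   resolved raises a linkage error naming the feature. An exon lying
#'   outside its transcript's declared span (when transcript features are
#'   present) raises a validation error.
#' @export
parse_annotation <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  dialect <- match.arg(dialect, c("gtf", "gff3"))
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  md <- as.data.frame(S4Vectors::mcols(gr))
  tbl <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = tolower(as.character(md$type))
  )

  if (dialect == "gtf") {
    if (!all(c("gene_id", "transcript_id") %in% names(md))) {
      abort("GTF lacks gene_id/transcript_id attributes")
    }
    tbl$gene_id <- as.character(md$gene_id)
    tbl$transcript_id <- as.character(md$transcript_id)
    feats <- tbl |> filter(.data$type %in% c("exon", "cds"))
    bad <- feats |> filter(is.na(.data$gene_id) | is.na(.data$transcript_id))
    if (nrow(bad) > 0) {
      abort(paste0(
        "feature without gene/transcript linkage at ", bad$chrom[1], ":",
        bad$start[1] + 1L, "-", bad$end[1]
      ))
    }
    tx_spans <- tbl |>
      filter(.data$type == "transcript") |>
      select(transcript_id = "transcript_id", tx_start = "start", tx_end = "end")
  } else {
    id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, nrow(tbl))
    parent <- if ("Parent" %in% names(md)) {
      vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, character(1))
    } else {
      rep(NA_character_, nrow(tbl))
    }
    tbl$id <- id
    tbl$parent <- parent
    tx_types <- c("mrna", "transcript", "ncrna", "lnc_rna")
    tx <- tbl |> filter(.data$type %in% tx_types)
    genes <- tbl |> filter(.data$type == "gene")
    tx_gene <- setNames(tx$parent, tx$id)
    known_tx <- tx$id
    feats <- tbl |> filter(.data$type %in% c("exon", "cds"))
    unknown <- feats$parent[!feats$parent %in% known_tx]
    if (length(unknown) > 0 || anyNA(feats$parent)) {
      offender <- c(unknown, feats$id[is.na(feats$parent)])[1]
      abort(paste0("exon/CDS with unresolvable Parent: ", offender))
    }
    if (nrow(genes) > 0 && any(!tx$parent %in% genes$id)) {
      offender <- tx$id[!tx$parent %in% genes$id][1]
      abort(paste0("transcript with unresolvable Parent gene: ", offender))
    }
    feats$transcript_id <- feats$parent
    feats$gene_id <- unname(tx_gene[feats$parent])
    tx_spans <- tx |> select(transcript_id = "id", tx_start = "start", tx_end = "end")
  }

  out <- feats |>
    mutate(feature = ifelse(.data$type == "cds", "cds", "exon")) |>
    select("gene_id", "transcript_id", "feature", "chrom", "strand", "start", "end") |>
    arrange(.data$gene_id, .data$transcript_id, .data$start)

  if (nrow(tx_spans) > 0) {
    chk <- out |>
      inner_join(tx_spans, by = "transcript_id") |>
      filter(.data$start < .data$tx_start | .data$end > .data$tx_end)
    if (nrow(chk) > 0) {
      abort(paste0(
        "exon outside declared transcript span: transcript ",
        chk$transcript_id[1], " at ", chk$chrom[1], ":", chk$start[1] + 1L, "-", chk$end[1]
      ))
    }
  }
  new_annotation(out)
}

new_annotation <- function(tbl) {
  stopifnot(all(c("gene_id", "transcript_id", "feature", "chrom", "strand", "start", "end") %in% names(tbl)))
  class(tbl) <- c("meripr_annotation", class(tibble::as_tibble(tbl)))
  tbl
}

#' Construct an annotation table directly
#'
#' Builds a [parse_annotation()]-compatible annotation from a data frame of
#' exon/CDS features (0-based half-open coordinates), validating linkage.
#'
#' @param features Data frame with columns `gene_id`, `transcript_id`,
#'   `feature` (`"exon"`/`"cds"`), `chrom`, `strand`, `start`, `end`.
#' @return A `meripr_annotation` tibble.
#' @export
as_annotation <- function(features) {
  features <- as_tibble(features)
  stopifnot(all(features$feature %in% c("exon", "cds")), all(features$start < features$end))
  new_annotation(arrange(features, .data$gene_id, .data$transcript_id, .data$start))
}

#' Write an annotation as GTF
#'
#' Emits exon and CDS lines (plus transcript lines) in GTF format,
#' converting internal 0-based half-open coordinates back to 1-based
#' inclusive. Output is deterministic: rows are ordered by gene,
#' transcript, and coordinate.
#'
#' @param annotation A `meripr_annotation` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  ann <- as_tibble(annotation) |>
    arrange(.data$gene_id, .data$transcript_id, .data$start, .data$feature)
  tx <- ann |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    mutate(feature = "transcript")
  all_rows <- bind_rows(tx, ann) |>
    arrange(.data$gene_id, .data$transcript_id, .data$feature != "transcript", .data$start)
  lines <- sprintf(
    "%s\tmeripr\t%s\t%d\t%d\t.\t%s\t%s\tgene_id \"%s\"; transcript_id \"%s\";",
    all_rows$chrom,
    ifelse(all_rows$feature == "cds", "CDS", all_rows$feature),
    all_rows$start + 1L, all_rows$end,
    all_rows$strand,
    ifelse(all_rows$feature == "cds", "0", "."),
    all_rows$gene_id, all_rows$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}
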