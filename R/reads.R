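#' Read alignments as a tidy block table
#'
#' Loads read alignments into the package's block representation: one row
#' per aligned block, so a spliced read spanning an intron contributes one
#' row per exon-side block sharing a `read_id`.
#'
#' Supported formats:
#' * `"bed"` — a BED6 read dialect: `chrom start end name score strand`,
#'   0-based half-open; rows sharing a `name` are blocks of one read.
#' * `"sam"` — plain-text SAM; blocks are derived from the CIGAR
#'   (`M/=/X/D` consume reference within a block, `N` splits blocks,
#'   `I/S/H/P` are skipped). Unmapped records are dropped.
#' * `"bam"` — as `"sam"`, read via Rsamtools (must be installed).
#'
#' @param path Input file.
#' @param format `"bed"`, `"sam"` or `"bam"`; guessed from the extension
#'   by default.
#' @return A tibble `read_id`, `chrom`, `start`, `end` (0-based half-open)
#'   with attribute `library_size` = number of distinct reads.
#' @export
read_alignments <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bed", "sam", "bam")) ext else "bed"
  }
  format <- match.arg(format, c("bed", "sam", "bam"))
  out <- switch(format,
    bed = {
      x <- readr::read_tsv(path,
        col_names = c("chrom", "start", "end", "read_id", "score", "strand"),
        col_types = "ciicdc", progress = FALSE
      )
      x |> select("read_id", "chrom", "start", "end")
    },
    sam = parse_sam_lines(readLines(path)),
    bam = {
      if (!requireNamespace("Rsamtools", quietly = TRUE)) {
        abort("BAM input requires the Rsamtools package")
      }
      b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
        what = c("qname", "rname", "pos", "cigar", "flag")
      ))[[1]]
      keep <- !is.na(b$pos) & !bitwAnd(b$flag, 4L)
      cigar_blocks(b$qname[keep], as.character(b$rname[keep]),
        b$pos[keep], b$cigar[keep])
    }
  )
  attr(out, "library_size") <- n_distinct(out$read_id)
  out
}

parse_sam_lines <- function(lines) {
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  f <- stringr::str_split_fixed(lines, "\t", 7)
  flag <- as.integer(f[, 2])
  keep <- f[, 3] != "*" & !bitwAnd(flag, 4L)
  cigar_blocks(f[keep, 1], f[keep, 3], as.integer(f[keep, 4]), f[keep, 6])
}

# Expand 1-based alignment positions + CIGAR strings into 0-based blocks.
cigar_blocks <- function(qname, chrom, pos1, cigar) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  rows <- map(seq_along(ops), function(i) {
    m <- ops[[i]]
    len <- as.integer(m[, 2])
    op <- m[, 3]
    ref_consumes <- op %in% c("M", "D", "N", "=", "X")
    at <- pos1[i] - 1L + c(0L, cumsum(len * ref_consumes))
    in_block <- op %in% c("M", "D", "=", "X")
    if (!any(in_block)) return(NULL)
    b <- tibble(start = at[which(in_block)], end = at[which(in_block) + 1L])
    # merge blocks contiguous across D ops
    grp <- cumsum(c(TRUE, b$start[-1] != b$end[-nrow(b)]))
    b |>
      group_by(grp) |>
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
      mutate(read_id = qname[i], chrom = chrom[i]) |>
      select("read_id", "chrom", "start", "end")
  })
  list_rbind(rows)
}

#' Write read blocks in the BED6 read dialect
#'
#' @param reads Tibble `read_id`, `chrom`, `start`, `end`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  r <- as_tibble(reads) |> arrange(.data$chrom, .data$start, .data$read_id)
  readr::write_tsv(
    tibble(r$chrom, r$start, r$end, r$read_id, 0L, "+"),
    path, col_names = FALSE
  )
  invisible(path)
}
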