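#' Length-matched background intervals for motif analysis
#'
#' For each peak, draws one background interval of identical length,
#' uniformly over the peak-free exonic space of expressed genes: peak
#' intervals (plus an optional flanking `buffer`) are subtracted from the
#' exonic segments of `expressed_models`, and a start position is drawn
#' uniformly over all remaining placements that fit the peak's length
#' within a single exonic segment. Sampling is deterministic under `seed`.
#'
#' @param peaks A `peak_set` tibble (or any tibble with `chrom`, `start`,
#'   `end`).
#' @param expressed_models A `gene_models` tibble of expressed genes.
#' @param genome A named character vector, `Biostrings::DNAStringSet`, or
#'   FASTA path.
#' @param seed Integer seed making the draw reproducible.
#' @param buffer Flank excluded around each peak, bp (default 0).
#' @return A list with `intervals` (tibble `peak_id`, `chrom`, `start`,
#'   `end`, `strand`, `gene_id`), `peak_seqs` and `background_seqs`
#'   (named character vectors; minus-strand sequences are
#'   reverse-complemented).
#' @export
background_sequences <- function(peaks, expressed_models, genome, seed,
                                 buffer = 0) {
  genome <- load_genome(genome)
  pk <- as_tibble(peaks) |> mutate(peak_id = row_number(), len = .data$end - .data$start)
  segs <- as_tibble(expressed_models) |>
    select("gene_id", "chrom", "strand", "start", "end")
  # subtract peaks (+/- buffer) from exonic segments
  seg_gr <- GenomicRanges::GRanges(segs$chrom, IRanges::IRanges(segs$start + 1L, segs$end))
  pk_gr <- GenomicRanges::GRanges(
    pk$chrom,
    IRanges::IRanges(pmax(0L, pk$start - buffer) + 1L, pk$end + buffer)
  )
  free <- GenomicRanges::setdiff(
    GenomicRanges::reduce(seg_gr), GenomicRanges::reduce(pk_gr)
  )
  free_tbl <- tibble(
    chrom = as.character(GenomicRanges::seqnames(free)),
    start = GenomicRanges::start(free) - 1L,
    end = GenomicRanges::end(free)
  ) |> mutate(width = .data$end - .data$start)
  draw <- withr::with_seed(seed, {
    map(pk$len, function(L) {
      cand <- free_tbl |> filter(.data$width >= L)
      if (nrow(cand) == 0) {
        abort(paste0(
          "no peak-free exonic segment can hold a background of length ", L
        ))
      }
      npos <- cand$width - L + 1L
      i <- sample.int(nrow(cand), 1, prob = npos)
      s <- cand$start[i] + sample.int(npos[i], 1) - 1L
      tibble(chrom = cand$chrom[i], start = s, end = s + L)
    }) |> list_rbind()
  })
  # attach gene and strand of the segment each background falls in
  owner <- draw |>
    mutate(.bid = row_number()) |>
    inner_join(segs, by = "chrom", suffix = c("", ".seg"),
      relationship = "many-to-many") |>
    filter(.data$start >= .data$start.seg, .data$end <= .data$end.seg) |>
    group_by(.data$.bid) |>
    slice(1) |>
    ungroup()
  intervals <- owner |>
    transmute(
      peak_id = pk$peak_id[.data$.bid],
      chrom = .data$chrom, start = .data$start, end = .data$end,
      strand = .data$strand, gene_id = .data$gene_id
    )
  pk_strand <- if ("strand" %in% names(pk)) pk$strand else rep("+", nrow(pk))
  list(
    intervals = intervals,
    peak_seqs = extract_seqs(genome, pk$chrom, pk$start, pk$end, pk_strand,
      paste0("peak_", pk$peak_id)),
    background_seqs = extract_seqs(genome, intervals$chrom, intervals$start,
      intervals$end, intervals$strand, paste0("bg_", intervals$peak_id))
  )
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome))) {
    abort("genome must be a FASTA path, DNAStringSet, or named character vector")
  }
  genome
}

extract_seqs <- function(genome, chrom, start, end, strand, ids) {
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing) > 0) {
    abort(paste0("genome lacks chromosome(s): ", paste(missing, collapse = ", ")))
  }
  seqs <- substring(genome[chrom], start + 1L, end)
  minus <- strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus]))
    )
  }
  setNames(as.character(seqs), ids)
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70
  )
  invisible(path)
}

#' K-mer enrichment of peak sequences over a background
#'
#' Surrogate for de novo motif discovery: every k-mer of each length in
#' `k` is scored by the 2x2 presence/absence table (sequences containing
#' the k-mer at least once, peak vs background) with a one-sided
#' hypergeometric/Fisher test for over-representation in the peaks, then
#' Benjamini-Hochberg corrected across all k-mers and ranked by adjusted
#' p (ties by raw p, then descending peak incidence, then alphabetically).
#' Presence/absence (not occurrence counts) keeps the 2x2 exact.
#'
#' @param peak_seqs,background_seqs Character vectors (or named vectors)
#'   of DNA sequences over A/C/G/T/N.
#' @param k Integer vector of k-mer lengths (default `5:7`).
#' @param alpha Threshold reported in the `significant` column.
#' @param rna Display k-mers in the RNA alphabet (T shown as U).
#' @return A tibble: `kmer`, `k`, `n_peak`, `n_background`, `p`, `p_adj`,
#'   `significant`, ranked by adjusted p.
#' @export
kmer_enrichment <- function(peak_seqs, background_seqs, k = 5:7,
                            alpha = 0.05, rna = TRUE) {
  if (length(peak_seqs) == 0 || length(background_seqs) == 0) {
    abort("both sequence sets must be non-empty")
  }
  check_alpha <- function(s, label) {
    if (any(grepl("[^ACGTN]", toupper(s)))) {
      abort(paste0(label, " sequences contain non-ACGTN characters"))
    }
  }
  check_alpha(peak_seqs, "peak")
  check_alpha(background_seqs, "background")
  pset <- Biostrings::DNAStringSet(toupper(peak_seqs))
  bset <- Biostrings::DNAStringSet(toupper(background_seqs))
  res <- map(k, function(kk) {
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), kk)
    pd <- Biostrings::PDict(kmers)
    n_peak <- rowSums(Biostrings::vcountPDict(pd, pset) > 0)
    n_bg <- rowSums(Biostrings::vcountPDict(pd, bset) > 0)
    tibble(kmer = kmers, k = kk, n_peak = n_peak, n_background = n_bg)
  }) |> list_rbind()
  np <- length(pset)
  nb <- length(bset)
  # one-sided Fisher == hypergeometric upper tail; vectorised for the
  # ~21.5k k-mers of lengths 5-7
  res <- res |>
    mutate(
      p = fisher_p_greater(.data$n_peak, np - .data$n_peak,
        .data$n_background, nb - .data$n_background),
      p_adj = p.adjust(.data$p, method = "BH"),
      significant = .data$p_adj < alpha
    ) |>
    arrange(.data$p_adj, .data$p, desc(.data$n_peak), .data$kmer)
  if (rna) res$kmer <- gsub("T", "U", res$kmer)
  res
}
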