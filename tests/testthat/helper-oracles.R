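# Brute-force oracles, written independently of the package internals:
# per-base maps built with plain loops, exact tail sums from factorials.

# Per-base label map of a collapsed gene, by brute force: every exonic base
# of every transcript is marked in a bitmap over the gene span, then each
# base is labelled by comparing against the outermost CDS boundaries.
# Returns a tibble (pos, region, soffset) where soffset is the spliced
# offset within the region in transcript orientation.
oracle_label_map <- function(exons, cds, strand) {
  # exons/cds: data.frames with start, end (0-based half-open, any overlap)
  lo <- min(exons$start)
  hi <- max(exons$end)
  exonic <- rep(FALSE, hi - lo)
  for (i in seq_len(nrow(exons))) {
    exonic[(exons$start[i] - lo + 1):(exons$end[i] - lo)] <- TRUE
  }
  pos <- (lo:(hi - 1))[exonic]
  if (nrow(cds) == 0) {
    return(data.frame(pos = pos, region = NA_character_))
  }
  cds_lo <- min(cds$start)
  cds_hi <- max(cds$end)
  region <- ifelse(pos < cds_lo, ifelse(strand == "+", "utr5", "utr3"),
    ifelse(pos >= cds_hi, ifelse(strand == "+", "utr3", "utr5"), "cds")
  )
  # transcript orientation: + ascending, - descending
  ord <- if (strand == "+") order(pos) else order(-pos)
  df <- data.frame(pos = pos[ord], region = region[ord])
  df$soffset <- stats::ave(seq_len(nrow(df)), df$region, FUN = seq_along) - 1L
  df
}

# Genomic footprint (set of bases) of each spliced bin of one gene, by
# walking the exonic bases in transcript orientation.
oracle_bin_bases <- function(model_segments, breaks) {
  # model_segments: region-labelled segments of one gene (gene_models rows)
  # breaks: spliced boundaries (0, b1, ..., total)
  strand <- model_segments$strand[1]
  ord <- match(model_segments$region, c("utr5", "cds", "utr3"))
  segs <- model_segments[order(ord, if (strand == "+") model_segments$start else -model_segments$start), ]
  bases <- integer(0)
  for (i in seq_len(nrow(segs))) {
    b <- segs$start[i]:(segs$end[i] - 1)
    if (strand == "-") b <- rev(b)
    bases <- c(bases, b)
  }
  lapply(seq_len(length(breaks) - 1), function(j) {
    bases[(breaks[j] + 1):breaks[j + 1]]
  })
}

# Count reads per bin by direct set intersection of read-block bases with
# bin bases.
oracle_count_bins <- function(reads, bin_bases) {
  counts <- integer(length(bin_bases))
  for (rid in unique(reads$read_id)) {
    blocks <- reads[reads$read_id == rid, ]
    rbases <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
      blocks$start[i]:(blocks$end[i] - 1)
    }))
    for (j in seq_along(bin_bases)) {
      if (any(rbases %in% bin_bases[[j]])) counts[j] <- counts[j] + 1L
    }
  }
  counts
}

# Exact hypergeometric tail P(X >= x) by factorial enumeration.
oracle_hyper_tail <- function(x, N, K, n) {
  kmax <- min(K, n)
  if (x > kmax) return(0)
  ks <- max(x, max(0, n - (N - K))):kmax
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# One-sided (greater) Fisher p for table [[a, b], [c, d]] by enumeration.
oracle_fisher_greater <- function(a, b, c, d) {
  oracle_hyper_tail(a, a + b + c + d, a + b, a + c)
}

# Random collapsed-gene fixture: returns an annotation tibble for one gene
# with 1-3 transcripts and optional introns. Pure base R + sampling.
random_gene_annotation <- function(gene_id = "g1", chrom = "chr1",
                                   strand = sample(c("+", "-"), 1),
                                   u5 = sample(40:200, 1),
                                   cd = sample(120:600, 1),
                                   u3 = sample(40:200, 1),
                                   n_introns = sample(0:2, 1),
                                   offset = 0L) {
  total <- u5 + cd + u3
  n_introns <- min(n_introns, total - 1L)
  breaks <- if (n_introns > 0) sort(sample(seq_len(total - 1), n_introns)) else integer(0)
  ilen <- sample(30:120, n_introns, replace = TRUE)
  ex_s <- c(0L, breaks)
  ex_e <- c(breaks, total)
  goff <- cumsum(c(0L, ilen))
  fs <- offset + ex_s + goff
  fe <- offset + ex_e + goff
  glen <- total + sum(ilen)
  mirror <- function(s, e) {
    if (strand == "+") list(s = s, e = e)
    else list(s = offset + glen - (e - offset), e = offset + glen - (s - offset))
  }
  sp2g <- function(a, b) {
    hit <- which(a < ex_e & b > ex_s)
    ss <- pmax(a, ex_s[hit])
    ee <- pmin(b, ex_e[hit])
    m <- mirror(offset + ss + goff[hit], offset + ee + goff[hit])
    data.frame(start = as.integer(m$s), end = as.integer(m$e))
  }
  exm <- mirror(fs, fe)
  exons <- data.frame(start = as.integer(exm$s), end = as.integer(exm$e))
  cds <- sp2g(u5, u5 + cd)
  tibble::tibble(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
    feature = c(rep("exon", nrow(exons)), rep("cds", nrow(cds))),
    chrom = chrom, strand = strand,
    start = c(exons$start, cds$start), end = c(exons$end, cds$end)
  )
}

# Uniform random reads (contiguous genomic intervals) over a span.
random_reads <- function(n, chrom, lo, hi, len = 30, prefix = "r") {
  s <- sample(lo:(hi - len), n, replace = TRUE)
  tibble::tibble(
    read_id = paste0(prefix, seq_len(n)), chrom = chrom,
    start = as.integer(s), end = as.integer(s + len)
  )
}

# Pool replicate window-count tables (sum counts and library sizes).
pool_window_counts <- function(lst) {
  x <- dplyr::bind_rows(lapply(lst, tibble::as_tibble)) |>
    dplyr::group_by(gene_id, win, region, width, sstart, send) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
  attr(x, "library_size") <- sum(vapply(lst, attr, 0, "library_size"))
  x
}
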