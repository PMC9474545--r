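#' Classify differential expression calls
#'
#' Labels each gene `up` (adjusted p below `alpha` and positive log2 fold
#' change), `down` (adjusted p below `alpha`, negative fold change) or
#' `ns`. A significant gene with a fold change of exactly zero has no
#' direction and is labelled `ns`.
#'
#' @param table Data frame with columns `gene_id`, `log2fc`, `p_adj`
#'   (unique gene ids, p in \[0,1\]).
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @return The table with a `label` column added.
#' @export
classify_de <- function(table, alpha = 0.05) {
  table <- as_tibble(table)
  need <- c("gene_id", "log2fc", "p_adj")
  if (!all(need %in% names(table))) {
    abort(paste0(
      "DE table lacks column(s): ",
      paste(setdiff(need, names(table)), collapse = ", ")
    ))
  }
  if (anyDuplicated(table$gene_id)) abort("duplicate gene ids in DE table")
  table |>
    mutate(label = case_when(
      .data$p_adj < alpha & .data$log2fc > 0 ~ "up",
      .data$p_adj < alpha & .data$log2fc < 0 ~ "down",
      TRUE ~ "ns"
    ))
}

#' One-sided Fisher test for expression skew of a gene class
#'
#' Builds the 2x2 table of class membership against direction among
#' significant genes (`up` vs `down`; `ns` genes drop out) and tests for
#' over-representation of `up` calls inside the class with a one-sided
#' Fisher exact test. With `margin = "universe"`, the alternative table
#' (class-up vs everything else in the universe) is used instead.
#'
#' @param labels Data frame `gene_id`, `label` (from [classify_de()]).
#' @param membership Data frame `gene_id`, `in_class` (logical), covering
#'   the same universe.
#' @param margin `"significant"` (default; class x up/down among
#'   significant genes) or `"universe"`.
#' @return A one-row tibble of class `set_test`: `test`, the four table
#'   cells (`class_up`, `class_down`, `out_up`, `out_down`), `odds_ratio`,
#'   `p`.
#' @export
skew_test <- function(labels, membership, margin = c("significant", "universe")) {
  margin <- match.arg(margin)
  d <- inner_join(as_tibble(labels), as_tibble(membership), by = "gene_id")
  if (margin == "significant") {
    d <- d |> filter(.data$label %in% c("up", "down"))
    a <- sum(d$in_class & d$label == "up")
    b <- sum(d$in_class & d$label == "down")
    c_ <- sum(!d$in_class & d$label == "up")
    dd <- sum(!d$in_class & d$label == "down")
  } else {
    a <- sum(d$in_class & d$label == "up")
    b <- sum(d$in_class & d$label != "up")
    c_ <- sum(!d$in_class & d$label == "up")
    dd <- sum(!d$in_class & d$label != "up")
  }
  if (a + b == 0 || c_ + dd == 0 || a + c_ == 0 || b + dd == 0) {
    empty <- c("class", "non-class", "up", "down")[
      c(a + b == 0, c_ + dd == 0, a + c_ == 0, b + dd == 0)
    ]
    abort(paste0("empty margin in skew table: ", paste(empty, collapse = ", ")))
  }
  out <- tibble(
    test = "fisher_one_sided",
    class_up = a, class_down = b, out_up = c_, out_down = dd,
    odds_ratio = (a * dd) / (b * c_),
    p = fisher_p_greater(a, b, c_, dd)
  )
  class(out) <- c("set_test", class(tibble()))
  out
}

#' One-sided Fisher exact p for over-representation
#'
#' P-value of Fisher's exact test with alternative "greater" for the 2x2
#' table `[[a, b], [c, d]]`, computed as the hypergeometric upper tail
#' (the two are identical). Vectorised over the four cell counts.
#'
#' @param a,b,c,d Non-negative cell counts (a = class & outcome cell whose
#'   over-representation is tested).
#' @return Numeric vector of p-values.
#' @export
fisher_p_greater <- function(a, b, c, d) {
  phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' One-sided hypergeometric overlap test between two gene sets
#'
#' Tests whether the overlap of `set_a` and `set_b` within `universe` is
#' larger than expected by chance: `p = P(X >= overlap)` with
#' `X ~ Hypergeometric(|universe|, |A|, |B|)`.
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all eligible gene ids (e.g. every
#'   gene with detectable expression).
#' @return A one-row tibble of class `set_test`: `test`, `n_universe`,
#'   `n_a`, `n_b`, `overlap`, `expected`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  stray <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(stray) > 0) {
    abort(paste0(
      "sets not contained in universe; offenders: ",
      paste(head(stray, 5), collapse = ", ")
    ))
  }
  N <- length(universe)
  m <- length(set_a)
  k <- length(set_b)
  ov <- length(intersect(set_a, set_b))
  out <- tibble(
    test = "hypergeometric_one_sided",
    n_universe = N, n_a = m, n_b = k, overlap = ov,
    expected = m * k / N,
    p = phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
  )
  class(out) <- c("set_test", class(tibble()))
  out
}

#' Read / write one-id-per-line gene sets
#'
#' @param path File path.
#' @return `read_gene_set()` returns a character vector.
#' @export
read_gene_set <- function(path) readLines(path)

#' @rdname read_gene_set
#' @param ids Character vector of gene ids.
#' @export
write_gene_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read a differential-expression TSV
#'
#' Expects a named header with at least `gene_id`, `log2fc`, `p_adj`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_de_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
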