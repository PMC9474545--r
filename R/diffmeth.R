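#' Differential methylation between control and treatment
#'
#' Surrogate for replicate-aware differential MeRIP analysis: for every
#' spliced window, each replicate's methylation level is summarised as
#' `m = log2((ip_cpm + pc) / (input_cpm + pc))` (replicate r's IP paired
#' with replicate r's input), and treatment is compared to control with a
#' two-sample t-test on the replicate levels. By default the pooled
#' (equal-variance) statistic with `nT + nC - 2` degrees of freedom is
#' used: with the typical three replicates per condition, the
#' Welch-Satterthwaite degrees of freedom can collapse towards 2, placing
#' a floor on attainable p-values that no effect size can cross once
#' thousands of windows are BH-corrected; the pooled statistic keeps the
#' full 4 degrees of freedom while replicate variability still enters the
#' test. Set `var_equal = FALSE` for Welch. `beta` is the mean difference
#' in `m`
#' (treatment minus control, i.e. a log2 fold change of enrichment).
#' Windows whose summed raw IP count falls below `min_count` in either
#' condition are excluded before testing; Benjamini-Hochberg correction is
#' applied across the tested windows only.
#'
#' A window is called `dependent` (methylation lost in the knockdown) iff
#' it passes the count filter, `p_adj < alpha`, `|beta| >= beta_cutoff`,
#' and the log2 fold change is below `-lfc_cutoff` (for the default
#' `direction = "loss"`; `"gain"` and `"both"` invert or drop the sign
#' requirement).
#'
#' With two replicates per condition the test has 2 (pooled) or as little
#' as 1 (Welch) degrees of freedom and is severely underpowered; this is
#' permitted but a minimum of three replicates is recommended. Windows
#' where both conditions have zero variance get p = 1 when `beta == 0`
#' and p = 0 otherwise.
#'
#' @param ip_control,input_control,ip_treatment,input_treatment Lists of
#'   `window_counts` tibbles (one per replicate, all on the same window
#'   grid), each carrying a `library_size` attribute.
#' @param min_count Minimum summed raw IP count per condition (default 15).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param beta_cutoff Minimum |beta| (default 0.5).
#' @param lfc_cutoff Log2 fold-change magnitude required in the stated
#'   direction (default 1).
#' @param direction `"loss"` (default), `"gain"`, or `"both"`.
#' @param var_equal Use the pooled-variance statistic (default `TRUE`);
#'   `FALSE` gives Welch with Satterthwaite degrees of freedom.
#' @param pseudocount Added to both CPM values (default 0.25).
#' @return A tibble of class `diff_methyl`: `gene_id`, `win`, `region`,
#'   `sstart`, `send`, `ip_count_control`, `ip_count_treatment`, `beta`,
#'   `p`, `p_adj`, `passes_count_filter`, `dependent`.
#' @export
differential_methylation <- function(ip_control, input_control,
                                     ip_treatment, input_treatment,
                                     min_count = 15, alpha = 0.05,
                                     beta_cutoff = 0.5, lfc_cutoff = 1,
                                     direction = c("loss", "gain", "both"),
                                     var_equal = TRUE, pseudocount = 0.25) {
  direction <- match.arg(direction)
  if (length(ip_control) < 2 || length(ip_treatment) < 2) {
    abort("each condition needs at least 2 replicates")
  }
  if (length(ip_control) != length(input_control) ||
      length(ip_treatment) != length(input_treatment)) {
    abort("each IP replicate needs a matching input replicate")
  }
  rep_m <- function(ip, input, group) {
    map(seq_along(ip), function(r) {
      li <- attr(ip[[r]], "library_size")
      ln <- attr(input[[r]], "library_size")
      if (is.null(li) || is.null(ln) || li <= 0 || ln <= 0) {
        abort("window counts must carry positive library_size attributes")
      }
      as_tibble(ip[[r]]) |>
        select("gene_id", "win", "region", "width", "sstart", "send", ipc = "count") |>
        inner_join(
          as_tibble(input[[r]]) |> select("gene_id", "win", inc = "count"),
          by = c("gene_id", "win")
        ) |>
        mutate(
          m = log2((.data$ipc / li * 1e6 + pseudocount) /
            (.data$inc / ln * 1e6 + pseudocount)),
          group = group, rep = r
        )
    }) |> list_rbind()
  }
  long <- bind_rows(
    rep_m(ip_control, input_control, "control"),
    rep_m(ip_treatment, input_treatment, "treatment")
  )
  nC <- length(ip_control)
  nT <- length(ip_treatment)
  stats <- long |>
    group_by(.data$gene_id, .data$win, .data$region, .data$sstart, .data$send) |>
    summarise(
      ip_count_control = sum(.data$ipc[.data$group == "control"]),
      ip_count_treatment = sum(.data$ipc[.data$group == "treatment"]),
      mC = mean(.data$m[.data$group == "control"]),
      mT = mean(.data$m[.data$group == "treatment"]),
      vC = var(.data$m[.data$group == "control"]),
      vT = var(.data$m[.data$group == "treatment"]),
      .groups = "drop"
    ) |>
    mutate(
      passes_count_filter = .data$ip_count_control >= min_count &
        .data$ip_count_treatment >= min_count,
      beta = .data$mT - .data$mC,
      se2 = if (var_equal) {
        ((nT - 1) * .data$vT + (nC - 1) * .data$vC) / (nT + nC - 2) *
          (1 / nT + 1 / nC)
      } else {
        .data$vT / nT + .data$vC / nC
      },
      df = if (var_equal) {
        ifelse(.data$se2 > 0, nT + nC - 2, NA_real_)
      } else {
        ifelse(.data$se2 > 0,
          .data$se2^2 / ((.data$vT / nT)^2 / (nT - 1) + (.data$vC / nC)^2 / (nC - 1)),
          NA_real_
        )
      },
      p = case_when(
        .data$se2 > 0 ~ 2 * pt(-abs(.data$beta / sqrt(.data$se2)), .data$df),
        .data$beta == 0 ~ 1,
        TRUE ~ 0
      )
    )
  if (!any(stats$passes_count_filter)) {
    warn("all windows removed by the count filter")
  }
  stats$p_adj <- NA_real_
  keep <- stats$passes_count_filter
  stats$p_adj[keep] <- p.adjust(stats$p[keep], method = "BH")
  dir_ok <- switch(direction,
    loss = stats$beta < -lfc_cutoff,
    gain = stats$beta > lfc_cutoff,
    both = abs(stats$beta) > lfc_cutoff
  )
  out <- stats |>
    mutate(dependent = .data$passes_count_filter &
      !is.na(.data$p_adj) & .data$p_adj < alpha &
      abs(.data$beta) >= beta_cutoff & dir_ok) |>
    select(
      "gene_id", "win", "region", "sstart", "send",
      "ip_count_control", "ip_count_treatment",
      "beta", "p", "p_adj", "passes_count_filter", "dependent"
    ) |>
    arrange(.data$gene_id, .data$win)
  class(out) <- c("diff_methyl", class(tibble()))
  out
}

#' Genes with at least one dependent window ("m6A genes")
#'
#' @param results A `diff_methyl` tibble.
#' @return A sorted character vector of de-duplicated gene ids.
#' @export
m6a_gene_set <- function(results) {
  sort(unique(results$gene_id[results$dependent]))
}
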