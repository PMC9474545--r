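#' Delta-delta-Ct fold change between two groups
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; then
#' `ddCt = mean(dCt_treated) - mean(dCt_control)` and the fold change is
#' `2^(-ddCt)`. Computed per target gene; the reference gene must match
#' across groups.
#'
#' @param treated,control Data frames with columns `gene_id`,
#'   `reference_gene_id`, `ct_target`, `ct_reference` (one row per
#'   replicate; Ct values finite and positive).
#' @return A tibble per gene: `gene_id`, `reference_gene_id`, `n_treated`,
#'   `n_control`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(treated, control) {
  chk <- function(x, label) {
    x <- as_tibble(x)
    need <- c("gene_id", "reference_gene_id", "ct_target", "ct_reference")
    if (!all(need %in% names(x))) {
      abort(paste0(label, " lacks column(s): ",
        paste(setdiff(need, names(x)), collapse = ", ")))
    }
    if (any(!is.finite(x$ct_target)) || any(!is.finite(x$ct_reference)) ||
        any(x$ct_target <= 0) || any(x$ct_reference <= 0)) {
      abort(paste0(label, " contains non-finite or non-positive Ct values"))
    }
    x
  }
  treated <- chk(treated, "treated")
  control <- chk(control, "control")
  sumr <- function(x, suffix) {
    x |>
      mutate(dct = .data$ct_target - .data$ct_reference) |>
      group_by(.data$gene_id, .data$reference_gene_id) |>
      summarise(
        "n_{suffix}" := n(), "dct_{suffix}" := mean(.data$dct),
        .groups = "drop"
      )
  }
  j <- inner_join(sumr(treated, "treated"), sumr(control, "control"),
    by = c("gene_id", "reference_gene_id"))
  refs_t <- distinct(treated, .data$gene_id, .data$reference_gene_id)
  refs_c <- distinct(control, .data$gene_id, .data$reference_gene_id)
  if (nrow(j) < nrow(refs_t) || nrow(j) < nrow(refs_c)) {
    abort("treated and control use mismatched target/reference gene pairs")
  }
  j |>
    mutate(
      ddct = .data$dct_treated - .data$dct_control,
      fold_change = 2^(-.data$ddct)
    ) |>
    select("gene_id", "reference_gene_id", "n_treated", "n_control",
      "ddct", "fold_change")
}

#' Fit an exponential decay to relative RNA levels
#'
#' Least-squares fit of `N(t) = N0 * exp(-k * t)` by linear regression on
#' log levels. With `fix_n0 = TRUE` the intercept is fixed at `N0 = 1`
#' (regression through the origin on the log scale), matching data already
#' normalised to the no-drug control at t = 0. A fitted `k < 0`
#' (apparent increase over time) is returned with `no_decay = TRUE` and an
#' undefined half-life.
#'
#' @param time Timepoints in hours (must include 0, at least 3 distinct).
#' @param level Relative RNA levels, strictly positive. Replicates may be
#'   supplied as repeated timepoints.
#' @param fix_n0 Fix the intercept to 1 (default `FALSE`).
#' @return An object of class `decay_fit`: a list with `k` (1/h),
#'   `half_life` (h, `ln(2)/k`), `n0`, `rss` (residual sum of squares on
#'   the log scale), `no_decay`, `n`, and the input series. Supports
#'   [tidy()], [glance()], [autoplot()] and `predict()`.
#' @export
fit_decay <- function(time, level, fix_n0 = FALSE) {
  if (length(time) != length(level)) abort("time and level differ in length")
  if (any(level <= 0)) abort("levels must be positive (log-scale fit)")
  if (n_distinct(time) < 3) abort("need at least 3 distinct timepoints")
  if (!any(time == 0)) abort("series must include t = 0")
  y <- log(level)
  if (fix_n0) {
    slope <- sum(time * y) / sum(time^2)
    n0 <- 1
    fitted <- slope * time
  } else {
    fit <- lm(y ~ time)
    slope <- unname(coef(fit)[2])
    n0 <- exp(unname(coef(fit)[1]))
    fitted <- unname(fit$fitted.values)
  }
  k <- -slope
  no_decay <- k <= 0
  if (no_decay && k < 0) {
    warn("fitted decay rate is negative (levels increase with time)")
  }
  out <- structure(
    list(
      k = k, half_life = if (k > 0) log(2) / k else NA_real_,
      n0 = n0, rss = sum((y - fitted)^2), no_decay = no_decay,
      fix_n0 = fix_n0, n = length(time),
      series = tibble(time = time, level = level)
    ),
    class = "decay_fit"
  )
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential decay fit (n =", x$n, "points)\n")
  cat(sprintf("  k = %.4g /h, half-life = %.4g h, N0 = %.4g, RSS(log) = %.4g\n",
    x$k, x$half_life, x$n0, x$rss))
  if (x$no_decay) cat("  flagged: no decay (k <= 0)\n")
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, time, ...) {
  object$n0 * exp(-object$k * time)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(
    term = c("k", "half_life", "n0"),
    estimate = c(x$k, x$half_life, x$n0)
  )
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(
    k = x$k, half_life = x$half_life, n0 = x$n0, rss = x$rss,
    no_decay = x$no_decay, n = x$n
  )
}

#' Fraction of the t = 0 level remaining at a timepoint
#'
#' In fit mode (`x` is a [fit_decay()] object) returns the N0-normalised
#' model value `exp(-k t)`. In raw mode (`x` is a series tibble with
#' `time` and `level`) returns the measured mean level at `t` divided by
#' the mean level at 0.
#'
#' @param x A `decay_fit` or a data frame with `time` and `level`.
#' @param t Timepoint in hours (default 4).
#' @return A single fraction.
#' @export
remaining_at <- function(x, t = 4) {
  if (inherits(x, "decay_fit")) {
    return(exp(-x$k * t))
  }
  x <- as_tibble(x)
  if (!all(c("time", "level") %in% names(x))) {
    abort("raw mode needs a series with `time` and `level` columns")
  }
  if (!any(x$time == t)) {
    abort(paste0("no observation at t = ", t, " in raw mode"))
  }
  mean(x$level[x$time == t]) / mean(x$level[x$time == 0])
}

#' Two-tailed Student t-test between groups of remaining fractions
#'
#' Pooled-variance Student t-test (two-tailed) comparing, e.g., the
#' fractions remaining at 4 h between genotypes. Identical degenerate
#' groups (zero pooled variance, equal means) return t = 0, p = 1; zero
#' variance with unequal means returns p = 0 with a warning.
#'
#' @param a,b Numeric vectors, each of length >= 3.
#' @return A one-row tibble: `estimate` (mean difference a - b), `t`,
#'   `df`, `p`, `n_a`, `n_b`.
#' @export
compare_remaining <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) abort("each group needs n >= 3")
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  est <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (est == 0) {
      return(tibble(estimate = 0, t = 0, df = na + nb - 2, p = 1, n_a = na, n_b = nb))
    }
    warn("zero pooled variance with unequal means; p set to 0")
    return(tibble(estimate = est, t = sign(est) * Inf, df = na + nb - 2, p = 0,
      n_a = na, n_b = nb))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble(
    estimate = est, t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, n_a = na, n_b = nb
  )
}
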