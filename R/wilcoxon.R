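#' Exact Wilcoxon signed-rank test for paired data
#'
#' Tests whether paired differences are symmetric about zero. Zero
#' differences are discarded (classical signed-rank convention) and tied
#' absolute differences receive midranks. For `n <= exact_limit` pairs the
#' two-sided p-value is exact, computed from the full distribution of the
#' positive rank sum over all 2^n sign assignments (evaluated by convolution
#' over the rank multiset); above that, a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param value_a,value_b Paired measurements (e.g. normal and decongested
#'   states), equal length.
#' @param alpha Significance threshold (default 0.05, the conventional 95%
#'   confidence level).
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return A `wilcoxon_test` list: `n` (non-zero pairs), `W` (min of the
#'   signed rank sums), `W_plus`, `p_value`, `significant`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(4, 4, 4, 4, 4))
#' @export
wilcoxon_signed_rank <- function(value_a, value_b, alpha = 0.05,
                                 exact_limit = 25) {
  if (length(value_a) != length(value_b)) abort("paired samples differ in length")
  d <- value_a - value_b
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) abort("degenerate paired sample: fewer than 2 non-zero differences")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  if (n <= exact_limit) {
    p <- exact_signed_rank_p(r, w_plus)
    method <- "exact"
  } else {
    s <- n * (n + 1) / 4
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w_plus - s)
    z <- (abs(z) - 0.5) / sigma
    p <- min(1, 2 * pnorm(-z))
    method <- "normal approximation"
  }
  structure(
    list(n = n, W = min(w_plus, w_minus), W_plus = w_plus, p_value = p,
         significant = p < alpha, alpha = alpha, method = method),
    class = "wilcoxon_test"
  )
}

## Exact two-sided p of the positive rank sum via convolution over the rank
## multiset (midranks doubled so all values are integers).
exact_signed_rank_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- rep(0, total + 1)     # counts[k + 1] = #assignments with sum k
  counts[1] <- 1
  for (rv in r2) {
    shifted <- c(rep(0, rv), counts[seq_len(total + 1 - rv)])
    counts <- counts + shifted
  }
  counts <- counts / sum(counts)
  w2 <- round(2 * w_plus)
  p_le <- sum(counts[seq_len(w2 + 1)])
  p_ge <- sum(counts[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.wilcoxon_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank (%s): n = %d, W = %g, p = %.4g%s\n",
    x$method, x$n, x$W, x$p_value, if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Boxplot summary
#'
#' Five-number boxplot summary with the plotting conventions used for paired
#' cohort panels: box edges at the first and third quartiles
#' (linear-interpolation quantiles), median line, whiskers at the most
#' extreme values within 1.5 IQR of the box, and outliers flagged beyond.
#'
#' @param values Numeric sample (length >= 1, NAs dropped).
#' @return A list with `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @examples
#' boxplot_summary(1:9)
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("empty sample")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  list(
    n = length(values),
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(values[inside]),
    whisker_high = max(values[inside]),
    outliers = sort(values[!inside])
  )
}

#' Paired cohort comparison
#'
#' Runs the Wilcoxon signed-rank test and boxplot summaries for every metric
#' of a paired cohort table, reporting the per-metric significance at the
#' chosen level and the median decongested/normal ratio.
#'
#' @param cohort A cohort table: tibble with columns `subject`, `metric`,
#'   `value_normal`, `value_decongested` (one row per subject per metric),
#'   optionally `units`.
#' @param alpha Significance threshold.
#' @param adjust P-value adjustment across metrics: `"none"` (default,
#'   per-panel convention) or any method of [stats::p.adjust()] such as
#'   `"holm"`.
#' @return A `cohort_comparison` object; see [tidy.cohort_comparison()] and
#'   [glance.cohort_comparison()].
#' @export
compare_cohort <- function(cohort, alpha = 0.05, adjust = "none") {
  need <- c("subject", "metric", "value_normal", "value_decongested")
  if (!all(need %in% names(cohort))) {
    abort(sprintf("cohort table must have columns %s", paste(need, collapse = ", ")))
  }
  dup <- cohort |>
    dplyr::count(.data$metric, .data$subject) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicated subject/metric pairs (e.g. %s / %s)",
                  dup$subject[1], dup$metric[1]))
  }
  incomplete <- cohort |>
    dplyr::filter(is.na(.data$value_normal) | is.na(.data$value_decongested))
  if (nrow(incomplete) > 0) {
    abort(sprintf("unpaired subject(s): %s",
                  paste(unique(incomplete$subject), collapse = ", ")))
  }
  metrics <- split(cohort, cohort$metric)
  rows <- purrr::map(metrics, function(tb) {
    wt <- wilcoxon_signed_rank(tb$value_normal, tb$value_decongested,
                               alpha = alpha)
    tibble(
      metric = tb$metric[1],
      units = if ("units" %in% names(tb)) tb$units[1] else NA_character_,
      n = wt$n,
      W = wt$W,
      p_value = wt$p_value,
      median_normal = median(tb$value_normal),
      median_decongested = median(tb$value_decongested),
      median_ratio = median(tb$value_decongested / tb$value_normal)
    )
  }) |> dplyr::bind_rows()
  rows$p_adjusted <- stats::p.adjust(rows$p_value, method = adjust)
  rows$significant <- rows$p_adjusted < alpha
  summaries <- purrr::map(metrics, function(tb) {
    list(normal = boxplot_summary(tb$value_normal),
         decongested = boxplot_summary(tb$value_decongested))
  })
  structure(
    list(tests = rows, summaries = summaries, alpha = alpha, adjust = adjust,
         cohort = cohort),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %d metric(s), alpha = %g (%s adjustment)\n",
              nrow(x$tests), x$alpha, x$adjust))
  df <- as.data.frame(x$tests[, c("metric", "n", "W", "p_value", "significant")])
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tidy a cohort comparison
#'
#' @param x A [compare_cohort()] result.
#' @param ... Unused.
#' @return A tibble with one row per metric: test statistics, p-values and
#'   median summaries.
#' @export
tidy.cohort_comparison <- function(x, ...) {
  x$tests
}

#' Glance at a cohort comparison
#'
#' @param x A [compare_cohort()] result.
#' @param ... Unused.
#' @return A one-row tibble: number of metrics, number significant, alpha,
#'   adjustment method.
#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble(
    n_metrics = nrow(x$tests),
    n_significant = sum(x$tests$significant),
    alpha = x$alpha,
    adjust = x$adjust
  )
}
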