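# Statistical comparison protocol: pairwise two-sided Mann-Whitney tests on
# per-study metrics between training strategies, with Benjamini-Hochberg
# adjustment and significance declared at q < 0.05.

#' Compare training strategies on per-study metrics
#'
#' For every unordered strategy pair and every requested metric, a two-sided
#' two-sample Wilcoxon rank-sum (Mann-Whitney) test on the per-study values.
#' P-values are Benjamini-Hochberg adjusted across the whole family of
#' comparisons within each grouping (overall, or separately per centre), and
#' `significant` flags `q_value < 0.05`. Ties are handled by midranks (the
#' test then uses the normal approximation, as `stats::wilcox.test` does).
#'
#' @param reports data frame of per-study metric rows (as produced by
#'   [voxel_metrics()], row-bound), with at least `strategy` and the metric
#'   columns; a `center_id` column is required for `grouping = "per_center"`.
#' @param metrics character vector of metric column names to compare.
#' @param grouping `"overall"` or `"per_center"`.
#' @param alpha significance level on the adjusted q-values (default 0.05).
#' @return data frame with `grouping`, `metric`, `strategy_a`, `strategy_b`,
#'   `n_a`, `n_b`, `p_value`, `q_value`, `significant`.
#' @export
compare_strategies <- function(reports,
                               metrics = c("ME", "MAE", "RE_pct", "ARE_pct",
                                           "PSNR_dB", "SSIM"),
                               grouping = c("overall", "per_center"),
                               alpha = 0.05) {
  grouping <- match.arg(grouping)
  metrics <- intersect(metrics, names(reports))
  stopifnot(length(metrics) >= 1, "strategy" %in% names(reports))
  groups <- if (grouping == "overall") list(overall = reports)
  else split(reports, reports$center_id)
  out <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    strats <- sort(unique(g$strategy))
    if (length(strats) < 2) next
    rows <- list()
    for (m in metrics) {
      for (i in seq_len(length(strats) - 1)) {
        for (j in (i + 1):length(strats)) {
          a <- g[g$strategy == strats[i], m]
          b <- g[g$strategy == strats[j], m]
          a <- a[is.finite(a)]; b <- b[is.finite(b)]
          if (length(a) < 3 || length(b) < 3)
            stop("need at least 3 studies per group for ", strats[i], " vs ",
                 strats[j])
          p <- suppressWarnings(
            stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
          rows[[length(rows) + 1]] <- data.frame(
            grouping = gname, metric = m,
            strategy_a = strats[i], strategy_b = strats[j],
            n_a = length(a), n_b = length(b), p_value = p,
            stringsAsFactors = FALSE)
        }
      }
    }
    res <- do.call(rbind, rows)
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$q_value < alpha
    out[[gname]] <- res
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summary table of per-study metrics by strategy
#'
#' Mean, SD, and normal-theory 95% confidence interval of the mean for each
#' metric within each strategy (and optionally each centre) - the layout used
#' for the study's comparison tables.
#'
#' @inheritParams compare_strategies
#' @param by extra grouping columns (e.g. `"center_id"`).
#' @return data frame with `strategy`, the grouping columns, `metric`, `mean`,
#'   `sd`, `ci_lo`, `ci_hi`, `n`.
#' @export
summarize_metrics <- function(reports,
                              metrics = c("ME", "MAE", "RE_pct", "ARE_pct",
                                          "PSNR_dB", "SSIM"),
                              by = character()) {
  metrics <- intersect(metrics, names(reports))
  keys <- c("strategy", by)
  sp <- split(reports, reports[keys], drop = TRUE)
  rows <- lapply(sp, function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- g[[m]][is.finite(g[[m]])]
      n <- length(v)
      se <- if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
      hw <- if (n > 1) stats::qt(0.975, n - 1) * se else NA_real_
      cbind(g[1, keys, drop = FALSE],
            data.frame(metric = m, mean = mean(v), sd = stats::sd(v),
                       ci_lo = mean(v) - hw, ci_hi = mean(v) + hw, n = n,
                       stringsAsFactors = FALSE))
    }))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
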