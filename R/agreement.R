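# Study-level agreement statistics between camera-based estimates and
# clinical reference annotations.

#' Bland-Altman agreement report
#'
#' Differences are estimate minus reference; limits are empirical 5th and
#' 95th percentiles of the differences (not Gaussian +/-1.96 SD limits).
#'
#' @param estimates,references equal-length paired numeric series.
#' @return An object of class `agreement_report`: list with
#'   `mean_difference`, `percentile_5`, `percentile_95`, `mae`, `n`, and the
#'   per-pair `differences` and `means` (the Bland-Altman x-axis).
#' @export
bland_altman <- function(estimates, references) {
  if (length(estimates) != length(references))
    stop("length mismatch between estimates and references")
  if (length(estimates) < 2) stop("need at least 2 pairs")
  d <- estimates - references
  structure(list(mean_difference = mean(d),
                 percentile_5 = unname(stats::quantile(d, 0.05, type = 7)),
                 percentile_95 = unname(stats::quantile(d, 0.95, type = 7)),
                 mae = mean(abs(d)),
                 n = length(d),
                 differences = d,
                 means = (estimates + references) / 2),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement: n=%d, mean diff %+0.2f, P5 %+0.2f, P95 %+0.2f, MAE %.2f>\n",
    x$n, x$mean_difference, x$percentile_5, x$percentile_95, x$mae))
  invisible(x)
}

#' Mean absolute error per group and unweighted mean across groups
#'
#' The summary "Mean" column convention of per-patient MAE tables is the
#' unweighted mean of per-patient MAEs, not the pooled per-pair MAE; both
#' are returned.
#'
#' @param estimates,references paired numeric series.
#' @param group_ids group label per pair (e.g. patient id).
#' @return List with `per_group` (data.frame `group`, `mae`, `n`),
#'   `mean_mae` (unweighted across groups) and `pooled_mae`.
#' @export
mae_by_group <- function(estimates, references, group_ids) {
  stopifnot(length(estimates) == length(references),
            length(estimates) == length(group_ids))
  d <- abs(estimates - references)
  groups <- unique(group_ids)
  per <- do.call(rbind, lapply(groups, function(g) {
    idx <- group_ids == g
    if (!any(idx)) stop("empty group: ", g)
    data.frame(group = g, mae = mean(d[idx]), n = sum(idx),
               stringsAsFactors = FALSE)
  }))
  list(per_group = per,
       mean_mae = mean(per$mae),
       pooled_mae = mean(d))
}
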