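## Stride-level aggregation and Pearson correlation analysis.

#' Aggregate step- and stride-level results for one trial
#'
#' Values measured per step are averaged first across the right and left
#' steps of each stride and then across strides; stride-level values are
#' averaged across strides directly.
#'
#' @param breakdown a `bw_breakdown` (per-stride work partition).
#' @param fits per-step spring-fit table from [spring_fits_by_step()].
#' @param meta optional `bw_meta` carrying subject/condition labels.
#' @return one-row data.frame (class `bw_summary`): subject/condition
#'   columns, stride-averaged work terms (J/kg), stride-averaged spring
#'   parameters, and `n_strides`.
#' @export
aggregate_trial <- function(breakdown, fits, meta = NULL) {
  if (nrow(breakdown) < 1) stop("no complete stride to aggregate", call. = FALSE)
  wk <- grep("_kg$", names(breakdown), value = TRUE)
  work_means <- colMeans(breakdown[, wk, drop = FALSE])

  spring_cols <- c("cst", "k", "c", "rmse", "r_squared", "delta_area")
  if (nrow(fits) > 0) {
    per_stride <- lapply(split(fits, fits$stride_id), function(d)
      colMeans(d[, spring_cols, drop = FALSE], na.rm = TRUE))
    spring_means <- colMeans(do.call(rbind, per_stride), na.rm = TRUE)
  } else {
    spring_means <- stats::setNames(rep(NA_real_, length(spring_cols)), spring_cols)
  }
  out <- data.frame(
    subject_id = if (is.null(meta)) NA_character_ else meta$subject_id,
    speed_kmh = if (is.null(meta)) NA_real_ else meta$belt_speed * 3.6,
    step_frequency = if (is.null(meta)) NA_real_ else meta$target_step_frequency,
    t(work_means), t(spring_means),
    n_strides = nrow(breakdown))
  ## total soft-tissue work magnitude used on the correlation axis
  out$W_ST_total_kg <- abs(out$W_ST_plus_kg) + abs(out$W_ST_minus_kg)
  class(out) <- c("bw_summary", "data.frame")
  out
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with the 95% confidence interval from the
#' Fisher transform `z = atanh(r)` (half-width `qnorm(.975)/sqrt(n-3)`,
#' back-transformed) and a two-sided p-value from the t distribution with
#' `n - 2` degrees of freedom.  `pearson_ci(r = , n = )` reproduces the
#' interval arithmetic for a published coefficient without raw data.
#'
#' @param x,y numeric vectors (n >= 4, nonzero variance), or omit and give
#'   `r` and `n` directly.
#' @param r,n optional: a correlation coefficient and its sample size.
#' @param conf confidence level (default 0.95).
#' @return list of class `bw_cor`: `r`, `df` (n-2), `ci95` = c(low, high),
#'   `p`, `n`.
#' @export
pearson_ci <- function(x = NULL, y = NULL, r = NULL, n = NULL, conf = 0.95) {
  if (is.null(r)) {
    stopifnot(length(x) == length(y))
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 4) stop("need at least 4 paired observations", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance: correlation undefined", call. = FALSE)
    r <- stats::cor(x, y)
  } else {
    if (is.null(n) || n < 4) stop("need n >= 4 with a supplied r", call. = FALSE)
  }
  if (abs(r) >= 1) {
    warning("|r| = 1: confidence interval degenerates to a point", call. = FALSE)
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    hw <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(r = r, df = n - 2, ci95 = ci, p = p, n = n), class = "bw_cor")
}

#' @export
print.bw_cor <- function(x, ...) {
  cat(sprintf("r(%d) = %.2f (95%% CI [%.2f, %.2f]); p = %.3g\n",
              x$df, x$r, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}

#' Correlation table across condition summaries
#'
#' Correlates the hysteresis area with the total soft-tissue work
#' (|W_ST+| + |W_ST-|), the damping coefficient c and the stiffness k over
#' all subject-condition rows.
#'
#' @param summaries data.frame of stacked [aggregate_trial()] rows (>= 4).
#' @return data.frame: `pair`, `r`, `df`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
correlation_table <- function(summaries) {
  pairs <- list(
    c("delta_area", "W_ST_total_kg"),
    c("delta_area", "c"),
    c("delta_area", "k"))
  rows <- lapply(pairs, function(pr) {
    res <- pearson_ci(summaries[[pr[1]]], summaries[[pr[2]]])
    data.frame(pair = paste(pr, collapse = " vs "), r = res$r, df = res$df,
               ci_low = res$ci95[1], ci_high = res$ci95[2], p = res$p,
               n = res$n)
  })
  do.call(rbind, rows)
}
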