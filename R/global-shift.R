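# Global methylation-shift analysis: the cumulative ratio-over-sum (RS)
# curve and the Gaussian-null shift significance test.

#' Ratio-over-sum (RS) curve
#'
#' A cumulative variant of the MA-plot visualizing a global methylation
#' shift between two groups. Probes are sorted by `|delta_beta|` in
#' decreasing order (ties broken by probe id, lexicographically); the N-th
#' point is the cumulative ratio
#' `y_N = sum(delta[1..N]) / sum(sums[1..N])` over the first N probes, with
#' `x_N = N / M`. `sums` is the per-probe sum of the two group means
#' (`beta_a + beta_b`). The final point `y_M` is the global shift ratio
#' (total delta over total beta sum), independent of the sort order.
#'
#' The cumulative reconstruction is this package's documented reading of
#' the ratio-over-sum construction; it is isolated here so an alternative
#' formula can be swapped without touching callers.
#'
#' @param delta per-probe delta-beta, named by probe id (or a
#'   `diff_result`, in which case `sums` is derived from its group means).
#' @param sums per-probe `beta_a + beta_b`; ignored when `delta` is a
#'   `diff_result`.
#' @return a `data.frame` of class `rs_curve` with columns `rank`, `x`,
#'   `y`, `probe_id`, `delta_beta`, `sum_beta`. Points whose cumulative
#'   denominator is zero carry `y = NA` and are counted in
#'   `attr(, "n_undefined")`.
#' @export
rs_curve <- function(delta, sums = NULL) {
  if (inherits(delta, "diff_result")) {
    sums <- setNames(delta$mean_a + delta$mean_b, delta$probe_id)
    delta <- setNames(delta$delta_beta, delta$probe_id)
  }
  if (is.null(sums)) input_error("`sums` is required")
  if (length(delta) == 0L) input_error("empty input")
  if (length(delta) != length(sums))
    input_error("`delta` and `sums` must be aligned")
  ids <- names(delta)
  if (is.null(ids)) ids <- sprintf("p%06d", seq_along(delta))
  ord <- order(-abs(delta), ids, method = "radix")
  d <- delta[ord]; s <- sums[ord]
  cd <- cumsum(d); cs <- cumsum(s)
  y <- ifelse(cs != 0, cd / cs, NA_real_)
  n_undef <- sum(is.na(y))
  if (n_undef) warning(sprintf("%d RS point(s) undefined (zero cumulative sum)",
                               n_undef))
  out <- data.frame(rank = seq_along(d),
                    x = seq_along(d) / length(d),
                    y = y, probe_id = ids[ord],
                    delta_beta = unname(d), sum_beta = unname(s),
                    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- n_undef
  class(out) <- c("rs_curve", "data.frame")
  out
}

#' Gaussian-null global methylation-shift test
#'
#' Tests whether the distribution of significant delta-beta values is
#' shifted away from zero: probes passing `p_bh < p_threshold` and
#' `sd < sd_threshold` (pooled within-group standard deviation of beta)
#' enter, and their delta-beta values are compared by Welch's two-sample
#' t-test against `n_null` draws from a reference Gaussian
#' `Normal(null_mean, null_sd)` of randomly generated methylation
#' differences. A one-sample variant (`null_sample = FALSE`) tests the
#' filtered delta-beta values directly against `mu = null_mean`.
#'
#' @param delta per-probe delta-beta (or a `diff_result`, from which
#'   `p_bh` and `sd` are taken).
#' @param p_bh per-probe BH-adjusted P-values.
#' @param sd per-probe pooled within-group standard deviation of beta.
#' @param p_threshold significance filter, default 0.01.
#' @param sd_threshold variability filter, default 0.1.
#' @param null_mean,null_sd reference Gaussian parameters (defaults 0.0
#'   and 0.1).
#' @param n_null number of null draws, default 10000.
#' @param null_sample draw a synthetic null sample (TRUE, default) or use
#'   the one-sample variant.
#' @param seed integer seed for the null draws.
#' @return list of class `shift_test` with `n_markers`, `mean_delta`,
#'   `sd_delta`, `t`, `p_value`, `method` and the null parameters.
#' @export
shift_test <- function(delta, p_bh = NULL, sd = NULL, p_threshold = 0.01,
                       sd_threshold = 0.1, null_mean = 0, null_sd = 0.1,
                       n_null = 10000L, null_sample = TRUE, seed = 1L) {
  if (inherits(delta, "diff_result")) {
    p_bh <- delta$p_bh
    sd <- delta$sd_pooled
    delta <- setNames(delta$delta_beta, delta$probe_id)
  }
  if (is.null(p_bh) || is.null(sd))
    input_error("`p_bh` and `sd` are required (or pass a diff_result)")
  if (!(length(delta) == length(p_bh) && length(delta) == length(sd)))
    input_error("`delta`, `p_bh` and `sd` must be aligned")
  pass_p <- !is.na(p_bh) & p_bh < p_threshold
  pass_sd <- !is.na(sd) & sd < sd_threshold
  keep <- pass_p & pass_sd & !is.na(delta)
  if (sum(keep) < 3L) {
    failed <- if (sum(pass_p) < 3L)
      sprintf("P(BH) < %g filter (left %d probes)", p_threshold,
              sum(pass_p))
    else sprintf("sd < %g filter (left %d probes)", sd_threshold,
                 sum(keep))
    stat_error(sprintf(
      "fewer than 3 probes survive the shift-test filters; %s", failed))
  }
  d <- delta[keep]
  if (null_sample) {
    # standardized so the null sample has exactly the nominal moments:
    # removes Monte Carlo error in the reference distribution and makes
    # the test antisymmetric under delta -> -delta
    raw <- with_seed(derive_seed(seed, "shift_null"), rnorm(n_null))
    null_draws <- null_mean + null_sd * (raw - mean(raw)) / stats::sd(raw)
    tt <- t.test(d, null_draws)
    method <- "Welch two-sample t vs Gaussian null"
  } else {
    tt <- t.test(d, mu = null_mean)
    method <- "one-sample t against null mean"
  }
  structure(list(n_markers = sum(keep), mean_delta = mean(d),
                 sd_delta = stats::sd(d), t = unname(tt$statistic),
                 p_value = tt$p.value, method = method,
                 null_mean = null_mean, null_sd = null_sd,
                 n_null = if (null_sample) n_null else 0L,
                 p_threshold = p_threshold, sd_threshold = sd_threshold),
            class = "shift_test")
}

#' @export
print.shift_test <- function(x, ...) {
  cat(sprintf(
    "shift_test: %d markers, mean delta %.4f (sd %.4f), t = %.2f, p = %.3g\n",
    x$n_markers, x$mean_delta, x$sd_delta, x$t, x$p_value))
  cat(sprintf("  %s (null mean %g, sd %g)\n", x$method, x$null_mean,
              x$null_sd))
  invisible(x)
}
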