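# Differential methylation: delta-beta, per-probe rank-sum tests,
# Benjamini-Hochberg adjustment, marker classification and the stratified
# summaries (CpG-island association, X-chromosome localization, marker-set
# overlap, profile correlation).

resolve_groups <- function(beta, group_a, group_b) {
  bmat <- if (inherits(beta, "beta_matrix")) beta$beta else beta
  if (!is.matrix(bmat)) input_error("`beta` must be a matrix or beta_matrix")
  if (length(group_a) == 0L || length(group_b) == 0L)
    input_error("both groups must be non-empty")
  overlap <- intersect(group_a, group_b)
  if (length(overlap))
    input_error(sprintf("groups overlap: %s",
                        paste(overlap, collapse = ", ")))
  missing_s <- setdiff(c(group_a, group_b), colnames(bmat))
  if (length(missing_s))
    input_error(sprintf("samples not in beta matrix: %s",
                        paste(missing_s, collapse = ", ")))
  list(beta = bmat, a = match(group_a, colnames(bmat)),
       b = match(group_b, colnames(bmat)))
}

#' Per-probe delta-beta between two groups
#'
#' `delta_beta = mean(group A) - mean(group B)` per probe, with missing
#' values excluded from the means.
#'
#' @param beta `beta_matrix` or probes x samples matrix.
#' @param group_a,group_b disjoint character vectors of sample ids.
#' @return named numeric vector of per-probe delta-beta.
#' @export
delta_beta <- function(beta, group_a, group_b) {
  g <- resolve_groups(beta, group_a, group_b)
  rowMeans(g$beta[, g$a, drop = FALSE], na.rm = TRUE) -
    rowMeans(g$beta[, g$b, drop = FALSE], na.rm = TRUE)
}

#' Per-probe two-sample Wilcoxon (rank-sum) P-values
#'
#' Two-sided Mann-Whitney test of group A versus group B per probe, on the
#' per-sample beta values. Exact null distribution for group sizes up to
#' `exact_max` per side (enumeration when ties occur); tie-corrected normal
#' approximation beyond. Probes that are constant across both groups get
#' P = 1; probes with fewer than 2 non-missing values in either group are
#' returned as `NA`.
#'
#' @inheritParams delta_beta
#' @param exact_max largest per-group size for which the exact null is used.
#' @return named numeric vector of raw P-values.
#' @export
wilcoxon_per_probe <- function(beta, group_a, group_b, exact_max = 10L) {
  g <- resolve_groups(beta, group_a, group_b)
  p <- ranksum_rows(g$beta, g$a, g$b, exact_max = exact_max)
  names(p) <- rownames(g$beta)
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment, returned in the input order.
#' A light wrapper around [stats::p.adjust()] with input validation; `NA`
#' values are carried through untouched.
#'
#' @param p_values numeric vector of P-values in \[0, 1\] (NAs allowed).
#' @return adjusted P-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    input_error("P-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Classify markers as hyper-, hypo-, or unmethylated
#'
#' Calls each probe `hyper` when `delta >= delta_threshold`, `hypo` when
#' `delta <= -delta_threshold`, otherwise `unchanged`; when `require_p` is
#' TRUE the adjusted P-value must additionally be below `p_threshold`.
#' `require_p = FALSE` reproduces delta-only marker counts, `require_p =
#' TRUE` the "substantial" (P(BH)-filtered) counts.
#'
#' @param delta per-probe delta-beta (named vector).
#' @param p_bh per-probe BH-adjusted P-values (ignored when
#'   `require_p = FALSE`; may be NULL in that case).
#' @param delta_threshold absolute delta-beta call threshold, default 0.2.
#' @param p_threshold adjusted-P threshold, default 0.01.
#' @param require_p demand `p_bh < p_threshold` in addition to the
#'   delta-beta cutoff.
#' @return list with `call` (named factor hyper/hypo/unchanged, NA for
#'   probes with missing inputs), `counts` and `fractions`.
#' @export
classify_markers <- function(delta, p_bh = NULL, delta_threshold = 0.2,
                             p_threshold = 0.01, require_p = TRUE) {
  if (delta_threshold < 0 || delta_threshold > 1)
    input_error("`delta_threshold` must be in [0, 1]")
  if (require_p) {
    if (is.null(p_bh)) input_error("`p_bh` required when require_p = TRUE")
    check_fraction(p_threshold, "p_threshold")
    if (length(p_bh) != length(delta))
      input_error("`delta` and `p_bh` must have equal length")
  }
  sig <- if (require_p) !is.na(p_bh) & p_bh < p_threshold else
    rep(TRUE, length(delta))
  call <- rep("unchanged", length(delta))
  call[!is.na(delta) & delta >= delta_threshold & sig] <- "hyper"
  call[!is.na(delta) & delta <= -delta_threshold & sig] <- "hypo"
  call[is.na(delta)] <- NA
  call <- factor(call, levels = c("hyper", "hypo", "unchanged"))
  names(call) <- names(delta)
  counts <- table(call, useNA = "no")
  n_eval <- sum(!is.na(call))
  list(call = call,
       counts = c(as.list(counts), n_excluded = sum(is.na(call)),
                  n_total = length(call)),
       fractions = as.list(counts / max(n_eval, 1L)))
}

#' Differential methylation between two sample groups
#'
#' The complete per-comparison analysis: delta-beta, per-probe two-sided
#' rank-sum P-values, Benjamini-Hochberg adjustment across all retained
#' probes, marker classification, and per-group descriptive statistics
#' (means and standard deviations, plus the pooled within-group standard
#' deviation used by the global shift test).
#'
#' @inheritParams delta_beta
#' @param annotation optional probe annotation joined onto the result
#'   (`cpg_island`, `chromosome`).
#' @param delta_threshold,p_threshold,require_p see [classify_markers()].
#' @return a `data.frame` of class `diff_result` with columns `probe_id`,
#'   `delta_beta`, `p_raw`, `p_bh`, `call`, `mean_a`, `mean_b`, `sd_a`,
#'   `sd_b`, `sd_pooled`, and (when annotated) `cpg_island`, `chromosome`.
#'   Probes with fewer than 2 values per group are dropped and listed in
#'   `attr(, "excluded")`.
#' @export
diff_methylation <- function(beta, group_a, group_b, annotation = NULL,
                             delta_threshold = 0.2, p_threshold = 0.01,
                             require_p = TRUE) {
  g <- resolve_groups(beta, group_a, group_b)
  a <- g$beta[, g$a, drop = FALSE]
  b <- g$beta[, g$b, drop = FALSE]
  n_a <- rowSums(!is.na(a)); n_b <- rowSums(!is.na(b))
  keep <- n_a >= 2L & n_b >= 2L
  excluded <- rownames(g$beta)[!keep]
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]

  delta <- rowMeans(a, na.rm = TRUE) - rowMeans(b, na.rm = TRUE)
  p_raw <- ranksum_rows(cbind(a, b), seq_len(ncol(a)),
                        ncol(a) + seq_len(ncol(b)))
  p_bh <- bh_adjust(p_raw)
  row_sd <- function(m) apply(m, 1L, sd, na.rm = TRUE)
  sd_a <- row_sd(a); sd_b <- row_sd(b)
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  sd_pooled <- sqrt(((na - 1) * sd_a^2 + (nb - 1) * sd_b^2) /
                      pmax(na + nb - 2, 1))
  cls <- classify_markers(delta, p_bh, delta_threshold, p_threshold,
                          require_p)
  out <- data.frame(probe_id = rownames(a), delta_beta = unname(delta),
                    p_raw = unname(p_raw), p_bh = unname(p_bh),
                    call = unname(cls$call),
                    mean_a = unname(rowMeans(a, na.rm = TRUE)),
                    mean_b = unname(rowMeans(b, na.rm = TRUE)),
                    sd_a = unname(sd_a), sd_b = unname(sd_b),
                    sd_pooled = unname(sd_pooled),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    idx <- match(out$probe_id, annotation$probe_id)
    out$cpg_island <- annotation$cpg_island[idx]
    out$chromosome <- annotation$chromosome[idx]
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "groups") <- list(a = group_a, b = group_b)
  attr(out, "thresholds") <- list(delta = delta_threshold, p = p_threshold,
                                  require_p = require_p)
  class(out) <- c("diff_result", "data.frame")
  out
}

#' CpG-island stratification of called markers
#'
#' @param results a `diff_result` (with `cpg_island` joined) or a
#'   data.frame with `call` and `cpg_island` columns.
#' @param call which call to stratify (`"hyper"` or `"hypo"`).
#' @return list with `n_island` and `n_total` called markers.
#' @export
stratify_by_island <- function(results, call = c("hyper", "hypo")) {
  call <- match.arg(call)
  if (!"cpg_island" %in% names(results))
    input_error("results lack a `cpg_island` column; join an annotation")
  sel <- !is.na(results$call) & results$call == call
  list(n_island = sum(results$cpg_island[sel], na.rm = TRUE),
       n_total = sum(sel))
}

#' Overlap of two marker sets
#'
#' @param set_a,set_b character vectors of probe ids.
#' @return list with `intersection`, `n_a`, `n_b`, `n_overlap`.
#' @export
overlap_markers <- function(set_a, set_b) {
  inter <- intersect(set_a, set_b)
  list(intersection = inter, n_a = length(unique(set_a)),
       n_b = length(unique(set_b)), n_overlap = length(inter))
}

#' Squared Pearson correlation between two methylation profiles
#'
#' @param beta_sample_1,beta_sample_2 per-probe beta vectors of equal
#'   length; pairs with missing values are dropped.
#' @return r-squared, or `NA` (with a warning) when either profile has zero
#'   variance.
#' @export
profile_correlation <- function(beta_sample_1, beta_sample_2) {
  if (length(beta_sample_1) != length(beta_sample_2))
    input_error("profiles must have equal length")
  ok <- !is.na(beta_sample_1) & !is.na(beta_sample_2)
  x <- beta_sample_1[ok]; y <- beta_sample_2[ok]
  if (length(x) < 3L)
    input_error("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in a profile; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)^2
}

#' X-chromosome localization of variable markers
#'
#' @param variable_markers character vector of probe ids (markers with
#'   `|delta_beta|` at or above the variability threshold, defined
#'   upstream).
#' @param annotation probe annotation with `probe_id` and `chromosome`.
#' @return list with `n_on_X` and `n_total`.
#' @export
x_localization <- function(variable_markers, annotation) {
  chr <- annotation$chromosome[match(variable_markers,
                                     annotation$probe_id)]
  list(n_on_X = sum(chr == "X", na.rm = TRUE),
       n_total = length(variable_markers))
}
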