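# Bead-level preprocessing: channel-wise quantile normalization, bead
# aggregation, detection P-values against negative-control beads, beta
# computation and detection filtering.

# Core quantile normalization on a list of numeric vectors (one per sample).
# Equal-length samples: every sample's sorted values are replaced by the
# rank-wise cross-sample mean; tied values receive the interpolated
# reference quantile at their mid-rank. Ragged samples are mapped through
# linear interpolation of the mean quantile function.
qn_core <- function(values) {
  ns <- length(values)
  lens <- lengths(values)
  if (any(lens < 1L)) input_error("every sample needs at least one value")
  if (ns == 1L) {
    warning("single sample: quantile normalization is the identity")
    return(values)
  }
  grid_n <- max(lens)
  grid <- if (grid_n == 1L) 0.5 else (seq_len(grid_n) - 1) / (grid_n - 1)
  sample_q <- vapply(values, function(x) {
    sx <- sort(x)
    if (length(sx) == grid_n) sx
    else stats::approx((seq_along(sx) - 1) / (length(sx) - 1), sx,
                       xout = grid, rule = 2)$y
  }, numeric(grid_n))
  ref <- rowMeans(sample_q)
  lapply(values, function(x) {
    r <- rank(x, ties.method = "average")
    if (length(x) == 1L) return(mean(ref))
    stats::approx(grid, ref, xout = (r - 1) / (length(x) - 1),
                  rule = 2)$y
  })
}

#' Quantile normalize one channel across samples
#'
#' Forces every sample's intensity distribution in one channel onto their
#' common (rank-wise mean) distribution, preserving within-sample rank
#' order. Green and red channels are normalized independently. Ties map to
#' the reference quantile at their mid-rank; samples with unequal value
#' counts are normalized through linear interpolation of the reference
#' quantile function.
#'
#' @param intensities a numeric matrix with one column per sample, or a list
#'   of numeric vectors (one per sample, lengths may differ).
#' @return normalized intensities in the same shape as the input.
#' @examples
#' quantile_normalize_channel(cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6)))
#' @export
quantile_normalize_channel <- function(intensities) {
  if (is.matrix(intensities)) {
    out <- qn_core(lapply(seq_len(ncol(intensities)),
                          function(j) intensities[, j]))
    res <- do.call(cbind, out)
    dimnames(res) <- dimnames(intensities)
    return(res)
  }
  if (!is.list(intensities))
    input_error("intensities must be a matrix or a list of numeric vectors")
  out <- qn_core(intensities)
  names(out) <- names(intensities)
  out
}

#' Aggregate beads to per-(sample, probe, allele) summaries
#'
#' Arithmetic mean, sample standard deviation (0 for a single bead) and bead
#' count for every (sample, probe, channel, allele) combination.
#' Negative-control beads (`probe_id == "NEGATIVE"`) are excluded.
#'
#' @param beads a bead table as produced by [simulate_beads()] or
#'   [read_beads()].
#' @return a `data.table` with columns `sample_id`, `probe_id`, `channel`,
#'   `allele`, `mean_intensity`, `sd_intensity`, `n_beads`.
#' @export
aggregate_beads <- function(beads) {
  beads <- as.data.table(beads)
  need <- c("sample_id", "probe_id", "channel", "allele", "intensity")
  missing <- setdiff(need, names(beads))
  if (length(missing))
    input_error(sprintf("bead table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  probe <- beads[probe_id != "NEGATIVE"]
  if (nrow(probe) == 0L) input_error("bead table contains no probe beads")
  out <- probe[, .(
    mean_intensity = mean(intensity),
    sd_intensity = if (.N > 1L) sd(intensity) else 0,
    n_beads = .N
  ), by = .(sample_id, probe_id, channel, allele)]
  setkey(out, sample_id, probe_id, channel)
  out[]
}

#' Detection P-values against negative-control beads
#'
#' For each probe and channel, a one-sided Mann-Whitney test of the probe's
#' beads exceeding the channel's negative-control beads gives a raw
#' P-value. Within each channel the raw P-values are Benjamini-Hochberg
#' adjusted across all probes, and the per-probe detection P-value is the
#' minimum of the two adjusted channel P-values.
#'
#' @param probe_beads list with elements `green` and `red`, each a named
#'   list of per-probe bead intensity vectors (same probes, same order).
#' @param negative_beads list with elements `green` and `red`, each a
#'   numeric vector of negative-control bead intensities.
#' @return list with `p_raw` and `p_adjusted` (probes x 2 matrices, columns
#'   `green`/`red`) and `detection_p` (named per-probe vector).
#' @export
detection_pvalue <- function(probe_beads, negative_beads) {
  for (ch in c("green", "red")) {
    if (is.null(negative_beads[[ch]]) || length(negative_beads[[ch]]) == 0L)
      config_error(sprintf("empty negative-bead pool for channel %s", ch))
    if (length(negative_beads[[ch]]) < 10L)
      input_error("need at least 10 negative beads per channel")
    if (any(lengths(probe_beads[[ch]]) < 3L))
      input_error("need at least 3 probe beads per channel")
  }
  if (length(probe_beads$green) != length(probe_beads$red))
    input_error("green and red probe lists must cover the same probes")
  np <- length(probe_beads$green)
  p_raw <- matrix(NA_real_, np, 2, dimnames = list(
    names(probe_beads$green), c("green", "red")))
  for (ch in c("green", "red")) {
    p_raw[, ch] <- vapply(probe_beads[[ch]], mw_pvalue, numeric(1),
                          y = negative_beads[[ch]],
                          alternative = "greater")
  }
  p_adj <- apply(p_raw, 2L, p.adjust, method = "BH")
  if (np == 1L) p_adj <- matrix(p_adj, 1L, 2L,
                                dimnames = dimnames(p_raw))
  list(p_raw = p_raw, p_adjusted = p_adj,
       detection_p = setNames(pmin(p_adj[, "green"], p_adj[, "red"]),
                              rownames(p_raw)))
}

#' Beta value from methylated and unmethylated intensities
#'
#' `beta = M / (M + U + offset)`, with negative intensities floored at zero
#' and a fully degenerate total (`M + U + offset == 0`) returning 0.
#' The default offset of 100 is the platform convention for this array
#' generation and shrinks noisy low-intensity probes towards 0.
#'
#' @param m_intensity,u_intensity methylated / unmethylated mean
#'   intensities (vectors allowed).
#' @param offset non-negative regularization constant, default 100.
#' @return beta values in \[0, 1\].
#' @examples
#' compute_beta(300, 100, offset = 100)  # 0.6
#' @export
compute_beta <- function(m_intensity, u_intensity, offset = 100) {
  if (offset < 0) input_error("`offset` must be non-negative")
  m <- pmax(m_intensity, 0)
  u <- pmax(u_intensity, 0)
  denom <- m + u + offset
  ifelse(denom > 0, m / denom, 0)
}

#' Filter probes by detection P-value
#'
#' Removes every probe whose detection P-value exceeds `threshold` in any of
#' the given samples and reports the exclusions.
#'
#' @param beta a `beta_matrix` from [preprocess_beads()].
#' @param threshold detection P-value cutoff in (0, 1), default 0.05.
#' @param samples sample ids to scan (default: all samples).
#' @return the filtered `beta_matrix`, with an `excluded` report
#'   (`probe_id`s removed, `fraction` of the probe universe).
#' @export
filter_detected <- function(beta, threshold = 0.05, samples = NULL) {
  if (!inherits(beta, "beta_matrix"))
    input_error("`beta` must be a beta_matrix object")
  if (threshold <= 0 || threshold >= 1)
    input_error("`threshold` must be in (0, 1)")
  samples <- if (is.null(samples)) colnames(beta$beta) else samples
  dp <- beta$detection_p[, samples, drop = FALSE]
  bad <- rowSums(dp > threshold, na.rm = TRUE) > 0L
  if (all(bad)) ms_error("all probes failed detection filtering",
                         "methylskin_stat_error")
  out <- beta
  out$beta <- beta$beta[!bad, , drop = FALSE]
  out$detection_p <- beta$detection_p[!bad, , drop = FALSE]
  out$excluded <- list(probe_id = rownames(beta$beta)[bad],
                       n_excluded = sum(bad),
                       fraction = mean(bad),
                       threshold = threshold)
  out
}

#' Preprocess a bead table into a beta matrix
#'
#' Runs the full bead-level preprocessing chain: channel-wise quantile
#' normalization of raw intensities across samples (probe and
#' negative-control beads together), aggregation to per-(sample, probe,
#' allele) means, per-sample detection P-values against the negative beads
#' (one-sided Mann-Whitney per channel, Benjamini-Hochberg adjusted across
#' probes within each channel, minimum over channels), and beta computation
#' from the methylated (green) and unmethylated (red) allele means.
#'
#' @param beads bead table ([simulate_beads()] / [read_beads()]).
#' @param design study manifest covering the bead table's samples.
#' @param offset beta regularization offset (see [compute_beta()]).
#' @param normalize quantile normalize intensities first (default TRUE).
#' @return an object of class `beta_matrix`: list with `beta` and
#'   `detection_p` (probes x samples matrices), `design`, `offset`,
#'   `n_beads` summary, `excluded` (NULL until [filter_detected()]).
#' @export
preprocess_beads <- function(beads, design, offset = 100,
                             normalize = TRUE) {
  design <- validate_design(design)
  samples <- design$sample_id
  # flat-vector fast path: bead tables reach tens of millions of rows, so
  # everything below works on integer group codes (factor columns are
  # recoded without materializing character vectors, and repeated
  # data.table subsetting would copy the table several times)
  col_codes <- function(v, table) {
    if (is.factor(v)) match(levels(v), table)[as.integer(v)]
    else match(as.character(v), table)
  }
  col_eq <- function(v, value) {
    if (is.factor(v)) as.integer(v) == match(value, levels(v))
    else as.character(v) == value
  }
  si <- col_codes(beads[["sample_id"]], samples)
  if (any(tabulate(si, ns <- length(samples)) == 0L)) {
    present <- samples[tabulate(si, ns) > 0L]
    input_error(sprintf("no beads for sample(s): %s",
                        paste(setdiff(samples, present), collapse = ", ")))
  }
  keep <- which(!is.na(si))
  if (!length(keep)) input_error("no beads after sample selection")
  all_rows <- length(keep) == length(si)
  pick <- function(v) if (all_rows) v else v[keep]
  si <- pick(si)
  negmask <- pick(col_eq(beads[["probe_id"]], "NEGATIVE"))
  if (!any(negmask))
    config_error("bead table has no negative-control beads")
  probe_col <- beads[["probe_id"]]
  probes <- if (is.factor(probe_col))
    sort(setdiff(levels(probe_col)[unique(as.integer(probe_col))],
                 "NEGATIVE"))
  else sort(setdiff(unique(as.character(probe_col)), "NEGATIVE"))
  np <- length(probes)
  pid <- pick(col_codes(probe_col, probes))
  rm(probe_col)
  is_green <- pick(col_eq(beads[["channel"]], "green"))
  meth <- pick(col_eq(beads[["allele"]], "methylated"))
  intensity <- pick(as.numeric(beads[["intensity"]]))

  if (normalize && ns > 1L) {
    for (chval in c(TRUE, FALSE)) {
      chidx <- which(is_green == chval)
      sidx <- split(chidx, si[chidx])
      norm <- qn_core(lapply(sidx, function(i) intensity[i]))
      for (j in seq_along(sidx)) intensity[sidx[[j]]] <- norm[[j]]
      rm(chidx, sidx, norm)
    }
  }

  # aggregate probe beads: mean M and U intensity per (probe, sample)
  pr <- which(!negmask & !is.na(pid) & !is.na(meth))
  g <- (si[pr] - 1L) * (2L * np) + as.integer(meth[pr]) * np + pid[pr]
  sums <- rowsum(intensity[pr], g, reorder = TRUE)
  cnts <- rowsum(rep(1L, length(pr)), g, reorder = TRUE)
  ug <- as.integer(rownames(sums))
  rm(g, pr)
  s_idx <- (ug - 1L) %/% (2L * np) + 1L
  rem <- (ug - 1L) %% (2L * np)
  grp_meth <- rem >= np
  p_idx <- rem %% np + 1L
  m_mat <- matrix(NA_real_, np, ns, dimnames = list(probes, samples))
  u_mat <- matrix(NA_real_, np, ns, dimnames = list(probes, samples))
  mean_int <- sums[, 1] / cnts[, 1]
  m_mat[cbind(p_idx[grp_meth], s_idx[grp_meth])] <- mean_int[grp_meth]
  u_mat[cbind(p_idx[!grp_meth], s_idx[!grp_meth])] <- mean_int[!grp_meth]
  median_beads <- stats::median(cnts[, 1])
  rm(sums, cnts, ug, s_idx, rem, grp_meth, p_idx, mean_int)

  beta <- compute_beta(m_mat, u_mat, offset = offset)
  dimnames(beta) <- list(probes, samples)

  # detection: batch Mann-Whitney of each probe's beads vs the channel's
  # negative pool, per sample; BH across probes within channel
  detection_p <- matrix(NA_real_, np, ns, dimnames = list(probes, samples))
  samp_idx <- split(seq_along(si), si)
  for (s in seq_len(ns)) {
    I <- samp_idx[[as.character(s)]]
    p_ch <- matrix(NA_real_, np, 2L)
    for (col in 1:2) {
      chval <- col == 1L
      negsel <- I[negmask[I] & is_green[I] == chval]
      if (length(negsel) < 10L)
        input_error(sprintf(
          "sample %s has fewer than 10 negative beads in channel %s",
          samples[s], if (chval) "green" else "red"))
      psel <- I[!negmask[I] & is_green[I] == chval]
      res <- mw_batch_grouped(intensity[psel], pid[psel], np,
                              intensity[negsel])
      p_ch[, col] <- p.adjust(res$p, method = "BH")
    }
    detection_p[, s] <- pmin(p_ch[, 1L], p_ch[, 2L], na.rm = TRUE)
  }

  structure(list(beta = beta, detection_p = detection_p, design = design,
                 offset = offset,
                 n_beads = data.table(median_beads = median_beads),
                 excluded = NULL),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (offset %g)\n",
              nrow(x$beta), ncol(x$beta), x$offset))
  if (!is.null(x$excluded))
    cat(sprintf("  %d probes excluded by detection filter (%.3f%%)\n",
                x$excluded$n_excluded, 100 * x$excluded$fraction))
  invisible(x)
}
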