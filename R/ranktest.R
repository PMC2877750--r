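# Mann-Whitney / Wilcoxon rank-sum machinery.
#
# Everything is built on the U statistic computed from mid-ranks.  Three
# evaluation strategies, chosen per input:
#   * tie-free exact: the null CDF of U from `pwilcox` (cached per (m, n));
#   * tied exact: full enumeration of all C(m+n, m) group assignments
#     (small groups only, the regime of 5-10 samples per arm);
#   * normal approximation with mid-rank tie correction and continuity
#     correction otherwise.
# Two-sided P-values use the symmetric-deviation convention
# P(|U - mn/2| >= |u_obs - mn/2|), which coincides with the doubled smaller
# tail for the symmetric tie-free null.

.u_cdf_cache <- new.env(parent = emptyenv())

# P(U <= q) under the tie-free null, vectorized over q, cached per (m, n).
exact_u_cdf <- function(m, n) {
  key <- paste(m, n, sep = "x")
  cdf <- .u_cdf_cache[[key]]
  if (is.null(cdf)) {
    cdf <- pwilcox(0:(m * n), m = m, n = n)
    .u_cdf_cache[[key]] <- cdf
  }
  cdf
}

# U statistic of x versus y (number of (x, y) pairs with x > y, ties count
# one half), computed from mid-ranks.
mw_u_statistic <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(m)]) - m * (m + 1) / 2
}

mw_enum_p <- function(x, y, alternative) {
  m <- length(x)
  N <- m + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  subsets <- utils::combn(N, m)
  u_null <- colSums(matrix(r[subsets], nrow = m)) - m * (m + 1) / 2
  mid <- m * length(y) / 2
  eps <- 1e-9
  switch(alternative,
    greater   = mean(u_null >= u_obs - eps),
    less      = mean(u_null <= u_obs + eps),
    two.sided = mean(abs(u_null - mid) >= abs(u_obs - mid) - eps))
}

mw_approx_p <- function(u, m, n, n_pooled_ties, alternative) {
  N <- m + n
  mu <- m * n / 2
  tie_term <- n_pooled_ties  # sum of (t^3 - t) over tied groups
  sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  sigma <- sqrt(sigma2)
  cc <- 0.5
  switch(alternative,
    greater   = pnorm((u - mu - cc) / sigma, lower.tail = FALSE),
    less      = pnorm((u - mu + cc) / sigma),
    two.sided = {
      z <- (abs(u - mu) - cc) / sigma
      min(1, 2 * pnorm(max(z, 0), lower.tail = FALSE))
    })
}

tie_correction_term <- function(values) {
  t <- tabulate(match(values, unique(values)))
  sum(t^3 - t)
}

#' Mann-Whitney U test P-value
#'
#' Rank-sum test of `x` against `y` using an exact null distribution whenever
#' feasible: the closed-form tie-free distribution for moderate sample sizes,
#' full enumeration of group assignments when ties are present and both
#' groups are small, and a tie- and continuity-corrected normal approximation
#' otherwise. Two-sided P-values follow the symmetric-deviation convention.
#'
#' @param x,y numeric vectors of observations for the two groups.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or `"less"`.
#' @param exact force (`TRUE`) or forbid (`FALSE`) an exact computation;
#'   `NULL` (default) chooses automatically.
#' @return a single P-value in \[0, 1\].
#' @examples
#' mw_pvalue(c(5, 6, 7), c(1, 2, 3), alternative = "greater")
#' @export
mw_pvalue <- function(x, y,
                      alternative = c("two.sided", "greater", "less"),
                      exact = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    input_error("both groups must be non-empty")
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0L
  u <- mw_u_statistic(x, y)

  enum_feasible <- choose(m + n, m) <= 2e5
  cdf_feasible <- m * n <= 1e4 && max(m, n) <= 500
  want_exact <- if (is.null(exact)) {
    if (has_ties) enum_feasible else cdf_feasible
  } else isTRUE(exact)

  if (want_exact && has_ties && enum_feasible)
    return(mw_enum_p(x, y, alternative))
  if (want_exact && !has_ties && cdf_feasible) {
    cdf <- exact_u_cdf(m, n)
    p_le <- function(q) if (q < 0) 0 else cdf[min(q, m * n) + 1L]
    p_ge <- function(q) if (q <= 0) 1 else 1 - p_le(q - 1L)
    return(switch(alternative,
      greater   = p_ge(u),
      less      = p_le(u),
      two.sided = {
        lo <- min(u, m * n - u); hi <- max(u, m * n - u)
        min(1, p_le(lo) + p_ge(hi))
      }))
  }
  mw_approx_p(u, m, n, tie_correction_term(pooled), alternative)
}

# Batch one-sided (greater) Mann-Whitney of many small bead sets against one
# shared reference pool. `x` is a list of numeric vectors (or a matrix with
# one row per set). The fast path assumes effectively continuous
# intensities: tie-free exact CDF when cheap, continuity-corrected normal
# approximation otherwise. Sets that do tie with the pool (or internally)
# are routed through the general scalar test.
mw_batch_greater <- function(x, reference) {
  if (is.matrix(x)) {
    x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
  }
  lens <- lengths(x)
  xv <- unlist(x, use.names = FALSE)
  n <- length(reference)
  if (n < 1L) config_error("reference (negative-bead) pool is empty")
  sy <- sort(reference)
  cnt_le <- findInterval(xv, sy)
  cnt_lt <- findInterval(xv, sy, left.open = TRUE)
  contrib <- cnt_lt + (cnt_le - cnt_lt) / 2
  idx <- rep.int(seq_along(lens), lens)
  u <- as.vector(rowsum(contrib, idx, reorder = TRUE))
  ref_tied <- as.vector(rowsum(as.numeric(cnt_le != cnt_lt), idx,
                               reorder = TRUE)) > 0
  self_tied <- vapply(x, anyDuplicated, integer(1)) > 0L
  tied <- ref_tied | self_tied

  p <- numeric(length(lens))
  for (m in unique(lens)) {
    sel <- which(lens == m & !tied)
    if (length(sel)) {
      if (m * n <= 1e4 && n <= 500) {
        cdf <- exact_u_cdf(m, n)
        q <- pmin(round(u[sel]) - 1, m * n)
        val <- 1 - cdf[pmax(q, 0) + 1L]
        val[q < 0] <- 1
        p[sel] <- val
      } else {
        mu <- m * n / 2
        sigma <- sqrt(m * n * (m + n + 1) / 12)
        p[sel] <- pnorm((u[sel] - mu - 0.5) / sigma, lower.tail = FALSE)
      }
    }
  }
  for (i in which(tied)) {
    p[i] <- mw_pvalue(x[[i]], reference, alternative = "greater")
  }
  list(u = u, p = p)
}

# Grouped variant of mw_batch_greater for flat vectors: `groups` are codes
# in 1..n_groups; groups absent from the data get NA. Same evaluation
# strategy, but avoids materializing one list element per probe, which
# matters at array scale.
mw_batch_grouped <- function(xv, groups, n_groups, reference) {
  n <- length(reference)
  if (n < 1L) config_error("reference (negative-bead) pool is empty")
  sy <- sort(reference)
  cnt_le <- findInterval(xv, sy)
  cnt_lt <- findInterval(xv, sy, left.open = TRUE)
  contrib <- cnt_lt + (cnt_le - cnt_lt) / 2

  u_s <- rowsum(contrib, groups, reorder = TRUE)
  ug <- as.integer(rownames(u_s))
  len_s <- rowsum(rep(1L, length(xv)), groups, reorder = TRUE)
  ref_tied_s <- rowsum(as.numeric(cnt_le != cnt_lt), groups,
                       reorder = TRUE) > 0
  u <- rep(NA_real_, n_groups); u[ug] <- u_s[, 1]
  lens <- integer(n_groups); lens[ug] <- len_s[, 1]
  tied <- logical(n_groups); tied[ug] <- ref_tied_s[, 1]
  # within-group duplicates (e.g. floored zero intensities)
  o <- order(groups, xv, method = "radix")
  if (length(o) > 1L) {
    same <- groups[o][-1L] == groups[o][-length(o)] &
      xv[o][-1L] == xv[o][-length(o)]
    tied[unique(groups[o][-1L][same])] <- TRUE
  }

  p <- rep(NA_real_, n_groups)
  for (m in unique(lens[lens > 0L])) {
    sel <- which(lens == m & !tied)
    if (!length(sel)) next
    if (m * n <= 1e4 && n <= 500) {
      cdf <- exact_u_cdf(m, n)
      q <- pmin(round(u[sel]) - 1, m * n)
      val <- 1 - cdf[pmax(q, 0) + 1L]
      val[q < 0] <- 1
      p[sel] <- val
    } else {
      mu <- m * n / 2
      sigma <- sqrt(m * n * (m + n + 1) / 12)
      p[sel] <- pnorm((u[sel] - mu - 0.5) / sigma, lower.tail = FALSE)
    }
  }
  tied_groups <- which(tied & lens > 0L)
  if (length(tied_groups)) {
    sel <- groups %in% tied_groups
    vals <- split(xv[sel], groups[sel])
    for (nm in names(vals)) {
      p[as.integer(nm)] <- mw_pvalue(vals[[nm]], reference,
                                     alternative = "greater")
    }
  }
  list(u = u, p = p, n_beads = lens)
}

# Per-row two-sided rank-sum P-values for a probes x samples matrix split
# into two sample groups. Exact (tie-free closed form, or enumeration when
# tied) for small groups; tie-corrected normal approximation otherwise.
ranksum_rows <- function(mat, idx_a, idx_b, exact_max = 10L) {
  m <- length(idx_a); n <- length(idx_b)
  if (m < 2L || n < 2L)
    input_error("need at least 2 samples per group for the rank-sum test")
  sub <- mat[, c(idx_a, idx_b), drop = FALSE]
  np <- nrow(sub)
  p <- rep(NA_real_, np)
  complete <- rowSums(is.na(sub)) == 0L
  use_exact <- max(m, n) <= exact_max

  r <- t(apply(sub, 1L, rank))  # mid-ranks, NA rows handled below
  u <- rowSums(r[, seq_len(m), drop = FALSE]) - m * (m + 1) / 2
  tied <- apply(sub, 1L, anyDuplicated) > 0L
  const <- apply(sub, 1L, function(v) length(unique(v[!is.na(v)])) == 1L)

  cdf <- if (use_exact) exact_u_cdf(m, n)
  for (i in which(complete)) {
    if (const[i]) { p[i] <- 1; next }
    if (use_exact && !tied[i]) {
      lo <- min(u[i], m * n - u[i]); hi <- max(u[i], m * n - u[i])
      p_lo <- if (lo < 0) 0 else cdf[lo + 1L]
      p_hi <- if (hi <= 0) 1 else 1 - (if (hi - 1 < 0) 0 else cdf[hi])
      p[i] <- min(1, p_lo + p_hi)
    } else if (use_exact && tied[i] && choose(m + n, m) <= 2e5) {
      vals <- sub[i, ]
      p[i] <- mw_enum_p(vals[seq_len(m)], vals[m + seq_len(n)], "two.sided")
    } else {
      p[i] <- mw_approx_p(u[i], m, n, tie_correction_term(sub[i, ]),
                          "two.sided")
    }
  }
  # rows with missing values: recompute pairwise-complete per row
  for (i in which(!complete)) {
    a <- sub[i, seq_len(m)]; b <- sub[i, m + seq_len(n)]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) next  # stays NA, excluded upstream
    p[i] <- if (length(unique(c(a, b))) == 1L) 1 else
      mw_pvalue(a, b, alternative = "two.sided")
  }
  p
}
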