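# Preprocessing: quantile normalization, bead aggregation, detection
# P-values, beta computation, detection filtering.

test_that("quantile normalization reproduces the rank-wise mean and equalizes distributions", {
  out <- quantile_normalize_channel(cbind(s1 = c(1, 2, 3),
                                          s2 = c(2, 4, 6)))
  expect_equal(unname(out[, "s1"]), c(1.5, 3.0, 4.5))
  expect_equal(unname(out[, "s2"]), c(1.5, 3.0, 4.5))

  set.seed(1)
  m <- cbind(rlnorm(200, 5, 1), rlnorm(200, 6, 0.5), rlnorm(200, 4, 2))
  norm <- quantile_normalize_channel(m)
  sorted <- apply(norm, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  # within-sample rank order preserved
  for (j in 1:3) expect_equal(order(norm[, j]), order(m[, j]))
})

test_that("quantile normalization matches limma on tie-free equal-count input", {
  skip_if_not_installed("limma")
  set.seed(2)
  m <- matrix(rnorm(600), 150, 4)
  expect_equal(unname(quantile_normalize_channel(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("ragged sample sizes are normalized by quantile interpolation", {
  set.seed(3)
  vals <- list(a = rnorm(100), b = rnorm(80) + 2, c = rnorm(120) * 3)
  norm <- quantile_normalize_channel(vals)
  expect_equal(lengths(norm), lengths(vals))
  # distributions are aligned: deciles agree closely across samples
  q <- sapply(norm, quantile, probs = seq(0.1, 0.9, 0.1))
  expect_lt(max(abs(q - rowMeans(q))), 0.15)
  for (s in names(vals)) expect_equal(order(norm[[s]]), order(vals[[s]]))
  expect_warning(quantile_normalize_channel(list(a = 1:5)), "identity")
})

test_that("bead aggregation computes mean, sample sd, and count per stratum", {
  beads <- data.table::data.table(
    sample_id = "s1", probe_id = c("p1", "p1", "p1", "p2"),
    channel = "green", allele = "methylated",
    intensity = c(100, 200, 300, 150))
  agg <- aggregate_beads(beads)
  p1 <- agg[probe_id == "p1"]
  expect_equal(p1$mean_intensity, 200)
  expect_equal(p1$sd_intensity, 100)
  expect_equal(p1$n_beads, 3L)
  expect_equal(agg[probe_id == "p2"]$sd_intensity, 0)  # single bead
  # permutation invariance
  agg2 <- aggregate_beads(beads[c(4, 2, 3, 1)])
  data.table::setkey(agg2, sample_id, probe_id, channel)
  expect_equal(agg, agg2)
})

test_that("beta values follow M / (M + U + offset) with flooring", {
  expect_equal(compute_beta(1000, 1000, 0), 0.5)
  expect_equal(compute_beta(0, 2000, 100), 0)
  expect_equal(compute_beta(300, 100, 100), 0.6)
  expect_equal(compute_beta(0, 0, 0), 0)       # degenerate total
  expect_equal(compute_beta(-50, 100, 0), 0)   # negative floored
  # monotone in M, antitone in U
  b <- compute_beta(seq(0, 1000, 100), 500, 100)
  expect_true(all(diff(b) > 0))
  b2 <- compute_beta(500, seq(0, 1000, 100), 100)
  expect_true(all(diff(b2) < 0))
  expect_true(all(b >= 0 & b <= 1))
})

test_that("detection P-values are BH-adjusted per channel before the minimum", {
  set.seed(10)
  neg <- list(green = rlnorm(50, 3, 0.5), red = rlnorm(50, 3, 0.5))
  probes <- list(
    green = list(p1 = rlnorm(5, 7, 0.3), p2 = rlnorm(5, 3, 0.5),
                 p3 = rlnorm(5, 7, 0.3)),
    red = list(p1 = rlnorm(5, 3, 0.5), p2 = rlnorm(5, 7, 0.3),
               p3 = rlnorm(5, 7, 0.3)))
  res <- detection_pvalue(probes, neg)
  # raw values match direct one-sided tests
  for (ch in c("green", "red")) {
    direct <- vapply(probes[[ch]], mw_pvalue, numeric(1), y = neg[[ch]],
                     alternative = "greater")
    expect_equal(res$p_raw[, ch], direct)
    expect_equal(res$p_adjusted[, ch],
                 p.adjust(direct, method = "BH"))
  }
  expect_equal(res$detection_p,
               pmin(res$p_adjusted[, "green"], res$p_adjusted[, "red"]))
  expect_true(all(res$detection_p[c("p1", "p2", "p3")] < 0.05))
  expect_error(detection_pvalue(probes, list(green = numeric(0),
                                             red = neg$red)),
               class = "methylskin_config_error")
})

test_that("probe beads identical to negatives give detection P near one half", {
  neg <- list(green = as.numeric(1:20), red = as.numeric(1:20))
  probes <- list(green = list(p1 = as.numeric(1:20)),
                 red = list(p1 = as.numeric(1:20)))
  res <- detection_pvalue(probes, neg)
  expect_lt(abs(res$p_raw["p1", "green"] - 0.5), 0.02)
})

test_that("detection filtering removes exactly the failing probes", {
  bm <- structure(list(
    beta = matrix(0.5, 4, 2, dimnames = list(paste0("p", 1:4),
                                             c("s1", "s2"))),
    detection_p = matrix(c(0.001, 0.001, 0.2, 0.001, 0.001, 0.001,
                           0.001, 0.03), 4, 2,
                         dimnames = list(paste0("p", 1:4),
                                         c("s1", "s2"))),
    design = NULL, offset = 100, excluded = NULL),
    class = "beta_matrix")
  out <- filter_detected(bm, threshold = 0.05)
  expect_equal(out$excluded$probe_id, "p3")
  expect_equal(out$excluded$fraction, 0.25)
  expect_equal(nrow(out$beta), 3)
  none <- bm; none$detection_p[] <- 0.001
  expect_equal(filter_detected(none)$excluded$n_excluded, 0L)
  all_bad <- bm; all_bad$detection_p[] <- 0.5
  expect_error(filter_detected(all_bad), class = "methylskin_stat_error")
})

test_that("the batched preprocessing path equals the per-operation composition", {
  fx <- small_study(n_probes = 40, seed = 19)
  design <- fx$design[fx$design$sampling == "suction_blister", ][1:4, ]
  beads <- fx$beads[fx$beads$sample_id %in% design$sample_id]
  bm <- preprocess_beads(beads, design, normalize = FALSE)
  agg <- aggregate_beads(beads)
  for (s in design$sample_id) {
    sub <- agg[agg$sample_id == s, ]
    m <- setNames(sub$mean_intensity[sub$allele == "methylated"],
                  sub$probe_id[sub$allele == "methylated"])
    u <- setNames(sub$mean_intensity[sub$allele == "unmethylated"],
                  sub$probe_id[sub$allele == "unmethylated"])
    probes <- rownames(bm$beta)
    expect_equal(bm$beta[, s],
                 compute_beta(m[probes], u[probes], offset = 100),
                 tolerance = 1e-12)
    # detection equals the reference implementation built on mw_pvalue
    pb <- beads[beads$probe_id != "NEGATIVE" & beads$sample_id == s]
    nb <- beads[beads$probe_id == "NEGATIVE" & beads$sample_id == s]
    probe_lists <- list(
      green = split(pb$intensity[pb$channel == "green"],
                    as.character(pb$probe_id[pb$channel == "green"])),
      red = split(pb$intensity[pb$channel == "red"],
                  as.character(pb$probe_id[pb$channel == "red"])))
    negatives <- list(green = nb$intensity[nb$channel == "green"],
                      red = nb$intensity[nb$channel == "red"])
    ref <- detection_pvalue(probe_lists, negatives)
    expect_equal(bm$detection_p[, s], ref$detection_p[probes],
                 tolerance = 1e-9)
  }
})

test_that("preprocessing a simulated study yields calibrated betas and full detection", {
  fx <- small_study(n_probes = 300, seed = 21)
  bm <- preprocess_beads(fx$beads, fx$design)
  expect_equal(dim(bm$beta), c(300L, 50L))
  expect_true(all(bm$beta >= 0 & bm$beta <= 1))
  # every simulated probe is real signal: detection exclusion below 0.1%
  filt <- filter_detected(bm)
  expect_lt(filt$excluded$fraction, 0.001)
  # estimated betas track truth (offset shrinks slightly towards 0)
  est <- rowMeans(bm$beta)
  tru <- rowMeans(fx$truth$beta[rownames(bm$beta), ])
  expect_gt(cor(est, tru), 0.99)
  expect_lt(mean(abs(est - tru * 2000 / 2100)), 0.02)
})
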