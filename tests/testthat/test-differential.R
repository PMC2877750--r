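# Differential methylation calling and its summaries.

test_that("delta-beta is the difference of group means and antisymmetric", {
  beta <- matrix(c(0.8, 0.1, 0.8, 0.3, 0.5, 0.2, 0.5, 0.4), 2, 4,
                 dimnames = list(c("p1", "p2"),
                                 c("a1", "a2", "b1", "b2")))
  d <- delta_beta(beta, c("a1", "a2"), c("b1", "b2"))
  expect_equal(unname(d["p1"]), mean(c(0.8, 0.8)) - mean(c(0.5, 0.5)))
  expect_equal(d, -delta_beta(beta, c("b1", "b2"), c("a1", "a2")))
  expect_equal(unname(delta_beta(beta, c("a1", "b1"),
                                 c("a2", "b2"))["p1"]),
               mean(c(0.8, 0.5)) - mean(c(0.8, 0.5)))
  expect_error(delta_beta(beta, c("a1", "a2"), c("a2", "b1")),
               class = "methylskin_input_error")
})

test_that("BH adjustment reproduces the step-up example and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(31)
  p <- runif(200)^2
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj <= 1))
  # permutation equivariance
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), class = "methylskin_input_error")
})

test_that("marker classification honors both thresholds and partitions probes", {
  delta <- c(a = 0.25, b = 0.25, c = -0.31, d = 0.1, e = NA)
  p_bh <- c(0.005, 0.5, 0.002, 0.001, 0.01)
  with_p <- classify_markers(delta, p_bh, require_p = TRUE)
  expect_equal(as.character(with_p$call[c("a", "b", "c", "d")]),
               c("hyper", "unchanged", "hypo", "unchanged"))
  expect_true(is.na(with_p$call["e"]))
  no_p <- classify_markers(delta, require_p = FALSE)
  expect_equal(as.character(no_p$call[c("a", "b", "c")]),
               c("hyper", "hyper", "hypo"))
  cnt <- with_p$counts
  expect_equal(cnt$hyper + cnt$hypo + cnt$unchanged + cnt$n_excluded,
               cnt$n_total)
})

test_that("island stratification, overlap, and X localization count correctly", {
  res <- data.frame(call = factor(c("hyper", "hyper", "hyper", "hypo"),
                                  levels = c("hyper", "hypo", "unchanged")),
                    cpg_island = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(stratify_by_island(res, "hyper"),
               list(n_island = 2, n_total = 3))
  empty <- res[0, ]
  expect_equal(stratify_by_island(empty, "hyper"),
               list(n_island = 0, n_total = 0))

  ov <- overlap_markers(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(sort(ov$intersection), c("b", "c"))
  expect_equal(c(ov$n_a, ov$n_b, ov$n_overlap), c(3, 3, 2))
  expect_equal(overlap_markers(c("a"), c("b"))$n_overlap, 0)
  expect_equal(overlap_markers(c("a", "b"), c("a", "b", "c"))$n_overlap, 2)

  ann <- data.frame(probe_id = paste0("p", 1:5),
                    chromosome = c("X", "X", "X", "X", "7"))
  expect_equal(x_localization(paste0("p", 1:5), ann),
               list(n_on_X = 4, n_total = 5))
  expect_equal(x_localization(character(0), ann),
               list(n_on_X = 0, n_total = 0))
})

test_that("profile correlation squares Pearson r and flags degenerate input", {
  x <- c(0.1, 0.5, 0.9, 0.2)
  expect_equal(profile_correlation(x, x), 1)
  expect_equal(profile_correlation(x, -x), 1)
  expect_equal(profile_correlation(c(0, 1, 2), c(0, 1, 3)), 27 / 28)
  expect_warning(r2 <- profile_correlation(c(1, 1, 1), c(0, 1, 2)),
                 "variance")
  expect_true(is.na(r2))
  expect_error(profile_correlation(1:3, 1:4),
               class = "methylskin_input_error")
})

test_that("noise-free planted effects are recovered perfectly by the delta-only rule", {
  ann <- make_annotation(3000, seed = 51)
  design <- default_study_design()
  spec <- effect_spec(frac_age_hyper = 0.02, frac_sun_hypo = 0,
                      frac_tissue_diff = 0, x_female_beta_shift = 0)
  truth <- make_true_betas(ann, design, spec, seed = 51)
  g <- design_groups(design)
  res <- diff_methylation(truth$beta, g$blister_old, g$blister_young,
                          annotation = ann, require_p = FALSE)
  hyper <- res$probe_id[res$call == "hyper"]
  expect_setequal(hyper, truth$labels$age_hyper)  # sensitivity 1, FPs 0
  expect_equal(sum(res$call == "hypo"), 0)
})

test_that("rank-sum p-values are calibrated under the per-probe null", {
  set.seed(61)
  n <- 10000
  beta <- matrix(runif(n * 10), n, 10,
                 dimnames = list(sprintf("p%05d", 1:n),
                                 c(paste0("a", 1:5), paste0("b", 1:5))))
  p <- wilcoxon_per_probe(beta, paste0("a", 1:5), paste0("b", 1:5))
  # 5v5 exact test is discrete: the rejection rate at 0.05 equals the
  # attainable null mass 2 * P(U <= 2) = 8/252, not 0.05 itself
  expect_lt(abs(mean(p < 0.05) - 8 / 252), binom99(8 / 252, n))
  expect_true(all(p >= 0 & p <= 1))
  # 6v6: rejection rate matches the exact attainable mass 2 * P(U <= 5),
  # which sits inside the 0.05 +/- 0.01 band
  beta12 <- matrix(runif(n * 12), n, 12,
                   dimnames = list(rownames(beta),
                                   c(paste0("a", 1:6), paste0("b", 1:6))))
  p12 <- wilcoxon_per_probe(beta12, paste0("a", 1:6), paste0("b", 1:6))
  mass12 <- 2 * pwilcox(5, 6, 6)
  expect_lt(abs(mass12 - 0.05), 0.01)
  expect_lt(abs(mean(p12 < 0.05) - mass12), binom99(mass12, n))
})

test_that("diff_methylation output is coherent and annotated", {
  fx <- small_study(n_probes = 200, seed = 71)
  bm <- preprocess_beads(fx$beads, fx$design)
  g <- design_groups(fx$design)
  res <- diff_methylation(bm, g$punch_epi_old, g$punch_epi_young,
                          annotation = fx$ann)
  expect_s3_class(res, "diff_result")
  expect_equal(nrow(res), 200)
  expect_equal(res$delta_beta, res$mean_a - res$mean_b)
  expect_true(all(res$p_bh >= res$p_raw - 1e-12))
  expect_true(all(c("cpg_island", "chromosome") %in% names(res)))
  # planted age effects dominate bead noise at 10v10
  planted <- res[res$probe_id %in% fx$truth$labels$age_hyper, ]
  expect_true(all(planted$call == "hyper"))
  expect_true(all(planted$p_bh < 0.01))
  expect_gte(mean(abs(planted$p_raw - 2 / choose(20, 10)) < 1e-12), 0.5)
})
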