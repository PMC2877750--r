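# Synthetic study generator: annotation, ground-truth betas, bead tables,
# bisulfite reads.

test_that("annotation has exact island/X counts, unique ids, and is seed-deterministic", {
  ann <- make_annotation(1000, island_fraction = 0.7, x_fraction = 0.04,
                         seed = 1)
  expect_equal(sum(ann$cpg_island), 700)
  expect_equal(sum(ann$chromosome == "X"), 40)
  expect_equal(anyDuplicated(ann$probe_id), 0L)
  expect_true(all(ann$chromosome %in% c(as.character(1:22), "X", "Y")))
  expect_identical(ann, make_annotation(1000, 0.7, 0.04, seed = 1))
  expect_false(identical(ann, make_annotation(1000, 0.7, 0.04, seed = 2)))
  expect_error(make_annotation(0), class = "methylskin_input_error")
  expect_error(make_annotation(100, island_fraction = 1.2),
               class = "methylskin_input_error")
})

test_that("planted effect subsets have the requested sizes and are disjoint", {
  ann <- make_annotation(27578, seed = 7)
  design <- default_study_design()
  truth <- make_true_betas(ann, design, effect_spec(), seed = 7)
  expect_length(truth$labels$age_hyper, round(27578 * 0.004))   # 110
  expect_length(truth$labels$sun_hypo, round(27578 * 0.0005))   # 14
  all_ids <- unlist(truth$labels)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_true(all(truth$beta >= 0 & truth$beta <= 1))
  # age-effect probes are island-biased 90%
  isl <- ann$cpg_island[match(truth$labels$age_hyper, ann$probe_id)]
  expect_equal(sum(isl), round(0.9 * 110))
})

test_that("baseline island beta fractions reproduce the target architecture", {
  ann <- make_annotation(27400, island_fraction = 0.73, seed = 11)
  design <- default_study_design()[1:4, ]
  spec <- effect_spec(frac_age_hyper = 0, frac_sun_hypo = 0,
                      frac_tissue_diff = 0, x_female_beta_shift = 0)
  truth <- make_true_betas(ann, design, spec, seed = 11)
  base <- truth$baseline[ann$cpg_island]
  n <- length(base)
  expect_gt(n, 10000)
  frac_low <- mean(base <= 0.2)
  frac_high <- mean(base >= 0.8)
  expect_lt(abs(frac_low - 0.86), max(binom99(0.86, n), 0.02))
  expect_lt(abs(frac_high - 0.05), max(binom99(0.05, n), 0.01))
  non <- truth$baseline[!ann$cpg_island]
  expect_lt(abs(mean(non >= 0.8) - 0.29), binom99(0.29, length(non)))
})

test_that("with all effects off, every sample shares the baseline profile", {
  ann <- make_annotation(300, seed = 5)
  design <- default_study_design()
  spec <- effect_spec(frac_age_hyper = 0, frac_sun_hypo = 0,
                      frac_tissue_diff = 0, x_female_beta_shift = 0)
  truth <- make_true_betas(ann, design, spec, seed = 5)
  expect_true(all(truth$beta == truth$baseline))
  # determinism
  truth2 <- make_true_betas(ann, design, spec, seed = 5)
  expect_identical(truth, truth2)
})

test_that("planted effects appear in the right samples with the right sign", {
  ann <- make_annotation(2000, seed = 9)
  design <- default_study_design()
  spec <- effect_spec(frac_age_hyper = 0.01, frac_sun_hypo = 0.01,
                      frac_tissue_diff = 0.02)
  truth <- make_true_betas(ann, design, spec, seed = 9)
  old <- design$sample_id[design$age_group == "old"]
  young <- design$sample_id[design$age_group == "young"]
  for (p in truth$labels$age_hyper) {
    expect_equal(unname(truth$beta[p, old[1]] - truth$beta[p, young[1]]),
                 spec$age_delta)
  }
  pe <- design$sampling == "punch_biopsy" & design$tissue == "epidermis"
  exposed <- design$sample_id[pe & design$sun == "exposed"]
  protected <- design$sample_id[pe & design$sun == "protected"]
  for (p in truth$labels$sun_hypo) {
    expect_equal(unname(truth$beta[p, exposed[1]] -
                          truth$beta[p, protected[1]]), -spec$sun_delta)
  }
})

test_that("bead intensities follow the beta split, floor at zero, and respect the CLT", {
  beta <- matrix(c(0.5, 1, 0.6), 3, 2,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  design <- data.frame(sample_id = c("s1", "s2"))
  noiseless <- simulate_beads(beta, design, total_intensity_mean = 2000,
                              bead_count = 3, noise_cv = 0, seed = 1)
  m <- noiseless[probe_id == "p1" & allele == "methylated", intensity]
  u <- noiseless[probe_id == "p1" & allele == "unmethylated", intensity]
  expect_equal(mean(m), mean(u))  # beta = 0.5 symmetry
  expect_true(all(noiseless[probe_id == "p2" & allele == "unmethylated",
                            intensity] == 0))  # beta = 1 floors U at 0
  expect_true(all(noiseless$intensity >= 0))

  noisy <- simulate_beads(beta, design, total_intensity_mean = 2000,
                          bead_count = 15, noise_cv = 0.1, seed = 2)
  mm <- noisy[probe_id == "p3" & allele == "methylated" &
                sample_id == "s1", intensity]
  expect_length(mm, 15)
  expect_lt(abs(mean(mm) - 1200), 3 * (0.1 * 1200) / sqrt(15))
  expect_error(simulate_beads(beta, design, bead_count = 2),
               class = "methylskin_input_error")
  expect_identical(noisy, simulate_beads(beta, design,
                                         total_intensity_mean = 2000,
                                         bead_count = 15, noise_cv = 0.1,
                                         seed = 2))
})

test_that("negative-control beads are present at the configured scale", {
  beta <- matrix(0.5, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  beads <- simulate_beads(beta, data.frame(sample_id = c("s1", "s2")),
                          total_intensity_mean = 2000, bead_count = 3,
                          negative_scale = 0.02, n_negative = 400,
                          seed = 4)
  neg <- beads[probe_id == "NEGATIVE"]
  expect_equal(nrow(neg), 2 * 2 * 400)  # samples x channels x beads
  expect_lt(abs(mean(neg$intensity) - 40), 5)
})

test_that("bisulfite read simulation respects site probabilities and conversion", {
  amp_seq <- "ACGGACGTTCACGTACCA"  # CpGs at 1, 5, 11 (0-based); non-CpG Cs too
  reads0 <- simulate_bisulfite_reads(amp_seq, c(0, 0, 0), n_reads = 20,
                                     conversion_rate = 1, seed = 1)
  expect_true(all(nchar(reads0) == nchar(amp_seq)))
  expect_false(any(grepl("C", reads0)))  # full conversion, no methylation
  reads1 <- simulate_bisulfite_reads(amp_seq, c(1, 1, 1), n_reads = 20,
                                     conversion_rate = 1, seed = 1)
  cpg_pos <- find_cpg_sites(amp_seq) + 1
  for (r in reads1) {
    chars <- strsplit(r, "")[[1]]
    expect_true(all(chars[cpg_pos] == "C"))
    expect_false(any(chars[-cpg_pos] == "C"))
  }
  # binomial bound at a partially methylated site
  reads <- simulate_bisulfite_reads(amp_seq, c(0.61, 0.5, 0.5),
                                    n_reads = 500, conversion_rate = 1,
                                    seed = 3)
  frac <- mean(substr(reads, cpg_pos[1], cpg_pos[1]) == "C")
  expect_lt(abs(frac - 0.61), 3 * sqrt(0.61 * 0.39 / 500))
  expect_error(simulate_bisulfite_reads(amp_seq, c(0.5, 0.5), 10),
               class = "methylskin_input_error")
})
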