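# Independent brute-force oracles and small fixture builders used across
# the suite.

# Full-enumeration rank-sum oracle: walks every assignment of the pooled
# observations to group A and counts assignments at least as extreme as
# the observed rank sum. Deliberately naive; independent of the package's
# U-statistic implementation.
oracle_ranksum_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  m <- length(x)
  N <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  center <- m * (N + 1) / 2
  sets <- utils::combn(N, m)
  stat <- apply(sets, 2L, function(i) sum(r[i]))
  eps <- 1e-9
  switch(alternative,
    greater   = mean(stat >= obs - eps),
    less      = mean(stat <= obs + eps),
    two.sided = mean(abs(stat - center) >= abs(obs - center) - eps))
}

# 99% binomial bound on an observed proportion around p at size n.
binom99 <- function(p, n) 2.576 * sqrt(p * (1 - p) / n)

# A small complete study fixture (annotation, design, truth, beads) used
# by several files; kept small so each test file can rebuild it cheaply.
small_study <- function(n_probes = 400, bead_count = 5, n_negative = 120,
                        seed = 42,
                        spec = effect_spec(frac_age_hyper = 0.025,
                                           frac_sun_hypo = 0.0125,
                                           frac_tissue_diff = 0.05)) {
  ann <- make_annotation(n_probes, seed = seed)
  design <- default_study_design()
  truth <- make_true_betas(ann, design, spec, seed = seed)
  beads <- simulate_beads(truth, design, bead_count = bead_count,
                          n_negative = n_negative, seed = seed)
  list(ann = ann, design = design, truth = truth, beads = beads,
       spec = spec)
}

# Sample groups of the default design, by role.
design_groups <- function(design) {
  sb <- design$sampling == "suction_blister"
  pe <- design$sampling == "punch_biopsy" & design$tissue == "epidermis"
  list(
    blister_old = design$sample_id[sb & design$age_group == "old"],
    blister_young = design$sample_id[sb & design$age_group == "young"],
    punch_epi_old = design$sample_id[pe & design$age_group == "old"],
    punch_epi_young = design$sample_id[pe & design$age_group == "young"],
    punch_epi_exposed = design$sample_id[pe & design$sun == "exposed"],
    punch_epi_protected = design$sample_id[pe & design$sun == "protected"],
    epidermis = design$sample_id[design$tissue == "epidermis" &
                                   design$sampling == "punch_biopsy"],
    dermis = design$sample_id[design$tissue == "dermis"])
}
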