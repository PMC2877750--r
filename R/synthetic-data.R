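# Synthetic study generator: probe annotation, study design, ground-truth
# beta values with planted effects, and bead-level intensities.

#' Generate a synthetic probe annotation
#'
#' Builds a probe universe in the style of a 27k CpG promoter array: unique
#' probe identifiers, chromosome assignment, and a CpG-island flag. Exactly
#' `round(n_probes * island_fraction)` probes are island-associated and
#' `round(n_probes * x_fraction)` are placed on chromosome X; the remainder
#' are spread over the autosomes.
#'
#' @param n_probes number of probes (the full array has 27,578).
#' @param island_fraction fraction of probes associated with CpG islands
#'   (default 0.73, reflecting the heavy island bias of promoter arrays).
#' @param x_fraction fraction of probes on chromosome X (default 0.04).
#' @param seed integer seed; the same seed reproduces the annotation exactly.
#' @return a `data.frame` with columns `probe_id`, `chromosome`,
#'   `cpg_island`, `gene_symbol`.
#' @export
make_annotation <- function(n_probes, island_fraction = 0.73,
                            x_fraction = 0.04, seed = 1L) {
  if (!is.numeric(n_probes) || length(n_probes) != 1L || is.na(n_probes) ||
      n_probes < 1)
    input_error("`n_probes` must be a positive integer")
  n_probes <- as.integer(n_probes)
  check_fraction(island_fraction, "island_fraction")
  check_fraction(x_fraction, "x_fraction")

  with_seed(derive_seed(seed, "annotation"), {
    probe_id <- sprintf("cg%08d", seq_len(n_probes))
    n_x <- round(n_probes * x_fraction)
    n_island <- round(n_probes * island_fraction)
    chromosome <- sample(as.character(1:22), n_probes, replace = TRUE)
    chromosome[sample.int(n_probes, n_x)] <- "X"
    cpg_island <- logical(n_probes)
    cpg_island[sample.int(n_probes, n_island)] <- TRUE
    # roughly two probes per annotated promoter
    gene_symbol <- sprintf("GENE%05d", sample.int(ceiling(n_probes / 2),
                                                  n_probes, replace = TRUE))
    data.frame(probe_id = probe_id, chromosome = chromosome,
               cpg_island = cpg_island, gene_symbol = gene_symbol,
               stringsAsFactors = FALSE)
  })
}

#' Default 50-sample skin study design
#'
#' The layout of the skin methylation study this package emulates: 10 male
#' suction-blister epidermis samples (5 young, 5 old; volar forearm,
#' sun-protected) and 20 female punch-biopsy donors' worth of paired samples
#' (5 young and 5 old donors, each contributing epidermis and dermis from a
#' sun-exposed and a sun-protected site), 50 samples in total with 5 samples
#' per design cell.
#'
#' @return a `data.frame` manifest with columns `sample_id`, `tissue`,
#'   `age_group`, `sun`, `sex`, `sampling`.
#' @export
default_study_design <- function() {
  blister <- data.frame(
    sample_id = sprintf("SB_%s_%02d", rep(c("young", "old"), each = 5), 1:5),
    tissue = "epidermis",
    age_group = rep(c("young", "old"), each = 5),
    sun = "protected",
    sex = "male",
    sampling = "suction_blister",
    stringsAsFactors = FALSE)
  donors <- data.frame(donor = sprintf("D%02d", 1:10),
                       age_group = rep(c("young", "old"), each = 5))
  grid <- expand.grid(tissue = c("epidermis", "dermis"),
                      sun = c("exposed", "protected"),
                      donor = donors$donor,
                      stringsAsFactors = FALSE)
  grid$age_group <- donors$age_group[match(grid$donor, donors$donor)]
  punch <- data.frame(
    sample_id = sprintf("PB_%s_%s_%s", grid$donor, substr(grid$tissue, 1, 3),
                        substr(grid$sun, 1, 4)),
    tissue = grid$tissue,
    age_group = grid$age_group,
    sun = grid$sun,
    sex = "female",
    sampling = "punch_biopsy",
    stringsAsFactors = FALSE)
  design <- rbind(blister, punch)
  rownames(design) <- NULL
  validate_design(design)
}

validate_design <- function(design) {
  required <- c("sample_id", "tissue", "age_group", "sun", "sex", "sampling")
  missing <- setdiff(required, names(design))
  if (length(missing))
    input_error(sprintf("study design is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  if (anyDuplicated(design$sample_id))
    input_error("sample_id values must be unique")
  levels_ok <- list(tissue = c("epidermis", "dermis"),
                    age_group = c("young", "old"),
                    sun = c("exposed", "protected"),
                    sex = c("male", "female"),
                    sampling = c("suction_blister", "punch_biopsy"))
  for (col in names(levels_ok)) {
    bad <- setdiff(unique(design[[col]]), levels_ok[[col]])
    if (length(bad))
      input_error(sprintf("invalid %s value(s): %s", col,
                          paste(bad, collapse = ", ")))
  }
  design
}

#' Effect specification for the synthetic study
#'
#' Collects the effect sizes and prevalences the generator plants, with
#' defaults chosen to match the study conditions this package emulates:
#' age-related hypermethylation at 0.4% of probes (110 of 27,578), sun
#' hypomethylation at 0.05% (14 probes), tissue-differential methylation at
#' 6.4% of probes, and female X-chromosome hypermethylation. The baseline
#' architecture parameters give 86% of island probes beta <= 0.2, 5% beta >=
#' 0.8, and 29% methylated probes outside islands.
#'
#' @param frac_age_hyper fraction of probes hypermethylated with age.
#' @param age_delta beta increase in old samples at age-effect probes.
#' @param frac_sun_hypo fraction of probes hypomethylated by sun exposure.
#' @param sun_delta beta decrease in sun-exposed samples at sun-effect probes.
#' @param frac_tissue_diff fraction of probes differential between epidermis
#'   and dermis.
#' @param tissue_delta beta difference magnitude for tissue-effect probes.
#' @param tissue_dermis_up_frac share of tissue-effect probes methylated
#'   higher in dermis (default 0.58, i.e. roughly 1034 dermis-high vs 742
#'   epidermis-high markers at the default prevalence).
#' @param x_female_beta_shift beta increase on chromosome X in females.
#' @param island_unmeth_frac fraction of island probes with baseline
#'   beta <= 0.2.
#' @param island_meth_frac fraction of island probes with baseline
#'   beta >= 0.8.
#' @param non_island_meth_frac fraction of non-island probes with baseline
#'   beta >= 0.8.
#' @param age_island_bias fraction of age-effect probes drawn from
#'   CpG-island probes (default 0.9; age hypermethylation concentrates at
#'   unmethylated islands).
#' @return a list of class `effect_spec`.
#' @export
effect_spec <- function(frac_age_hyper = 0.004, age_delta = 0.3,
                        frac_sun_hypo = 0.0005, sun_delta = 0.3,
                        frac_tissue_diff = 0.064, tissue_delta = 0.3,
                        tissue_dermis_up_frac = 0.58,
                        x_female_beta_shift = 0.3,
                        island_unmeth_frac = 0.86,
                        island_meth_frac = 0.05,
                        non_island_meth_frac = 0.29,
                        age_island_bias = 0.9) {
  spec <- list(frac_age_hyper = frac_age_hyper, age_delta = age_delta,
               frac_sun_hypo = frac_sun_hypo, sun_delta = sun_delta,
               frac_tissue_diff = frac_tissue_diff,
               tissue_delta = tissue_delta,
               tissue_dermis_up_frac = tissue_dermis_up_frac,
               x_female_beta_shift = x_female_beta_shift,
               island_unmeth_frac = island_unmeth_frac,
               island_meth_frac = island_meth_frac,
               non_island_meth_frac = non_island_meth_frac,
               age_island_bias = age_island_bias)
  fracs <- c("frac_age_hyper", "frac_sun_hypo", "frac_tissue_diff",
             "tissue_dermis_up_frac", "island_unmeth_frac",
             "island_meth_frac", "non_island_meth_frac", "age_island_bias")
  for (f in fracs) check_fraction(spec[[f]], f)
  for (d in c("age_delta", "sun_delta", "tissue_delta",
              "x_female_beta_shift")) {
    if (spec[[d]] < 0 || spec[[d]] > 1)
      input_error(sprintf("`%s` must be in [0, 1]", d))
  }
  if (spec$island_unmeth_frac + spec$island_meth_frac > 1)
    input_error("island baseline fractions sum to more than 1")
  structure(spec, class = "effect_spec")
}

# Draw baseline beta values from a three-component mixture (low Beta(1,20),
# high Beta(20,1), mid Uniform(0.2, 0.8)). Component weights are calibrated
# so that the realized tail masses equal the requested fractions: Beta(1,20)
# carries only P(X <= 0.2) = 1 - 0.8^20 = 0.988 of its mass below 0.2, so
# the low/high weights are inflated by 1/0.988 and the remainder goes to the
# mid component.
draw_baseline <- function(n, unmeth_frac, meth_frac) {
  tail_mass <- 1 - 0.8^20
  w_low <- unmeth_frac / tail_mass
  w_high <- meth_frac / tail_mass
  if (w_low + w_high > 1)
    input_error("baseline fractions too large for the mixture components")
  comp <- sample.int(3L, n, replace = TRUE,
                     prob = c(w_low, w_high, 1 - w_low - w_high))
  out <- numeric(n)
  out[comp == 1L] <- rbeta(sum(comp == 1L), 1, 20)
  out[comp == 2L] <- rbeta(sum(comp == 2L), 20, 1)
  out[comp == 3L] <- runif(sum(comp == 3L), 0.2, 0.8)
  out
}

#' Ground-truth beta values with planted effects
#'
#' Draws a bimodal baseline methylation level per probe (CpG-island probes
#' mostly unmethylated, non-island probes more often methylated) and plants
#' four classes of effects on disjoint probe subsets: age hypermethylation
#' (+`age_delta` in old samples), sun-exposure hypomethylation (-`sun_delta`
#' in exposed samples), tissue-differential methylation (the baseline is
#' the epidermis state; dermis samples gain `tissue_delta` at dermis-high
#' probes and lose it at epidermis-high probes), and female X-chromosome
#' hypermethylation. Age, sun and tissue
#' effects are planted on autosomal probes only (X probes already carry
#' the sex effect, which would otherwise stack and clamp away the planted
#' signal). Hypermethylation
#' effects are planted on probes with baseline headroom (baseline
#' <= 1 - delta) and hypomethylation effects on probes with baseline
#' >= delta, so each planted effect is fully expressed after clamping to
#' \[0, 1\]; age-effect probes are preferentially drawn from CpG islands
#' (see `age_island_bias`).
#'
#' @param annotation probe annotation from [make_annotation()].
#' @param design study manifest, e.g. [default_study_design()].
#' @param spec an [effect_spec()].
#' @param seed integer seed.
#' @return list with `beta` (probes x samples matrix of true beta),
#'   `labels` (list of planted probe-id sets: `age_hyper`, `sun_hypo`,
#'   `tissue_epi_up`, `tissue_dermis_up`), and `baseline` (per-probe
#'   baseline beta).
#' @export
make_true_betas <- function(annotation, design = default_study_design(),
                            spec = effect_spec(), seed = 1L) {
  design <- validate_design(design)
  if (anyDuplicated(annotation$probe_id))
    input_error("annotation probe_id values must be unique")
  n <- nrow(annotation)
  with_seed(derive_seed(seed, "true_betas"), {
    baseline <- numeric(n)
    isl <- annotation$cpg_island
    baseline[isl] <- draw_baseline(sum(isl), spec$island_unmeth_frac,
                                   spec$island_meth_frac)
    # unmethylated fraction outside islands is not pinned by the emulated
    # study; 0.55 keeps the profile bimodal with a visible methylated mode
    baseline[!isl] <- draw_baseline(sum(!isl), 0.55,
                                    spec$non_island_meth_frac)

    n_age <- round(n * spec$frac_age_hyper)
    n_sun <- round(n * spec$frac_sun_hypo)
    n_tis <- round(n * spec$frac_tissue_diff)

    take <- function(pool, k, what) {
      if (length(pool) < k)
        input_error(sprintf(
          "cannot plant %d %s probes: only %d eligible probes remain",
          k, what, length(pool)))
      if (k == 0L) integer(0) else sample(pool, k)
    }
    used <- integer(0)
    # effects are planted on autosomes only: every X probe already carries
    # the female methylation shift, and stacking a second effect there
    # would be clamped away and confound sex with the planted factor
    autosomal <- annotation$chromosome != "X"
    # age: hyper, headroom above, island-biased
    elig_hyper <- which(baseline <= 1 - spec$age_delta & autosomal)
    n_age_isl <- round(n_age * spec$age_island_bias)
    age_isl <- take(setdiff(intersect(elig_hyper, which(isl)), used),
                    n_age_isl, "age (island)")
    used <- c(used, age_isl)
    age_non <- take(setdiff(setdiff(elig_hyper, which(isl)), used),
                    n_age - n_age_isl, "age (non-island)")
    age_idx <- sort(c(age_isl, age_non))
    used <- c(used, age_non)
    # sun: hypo, headroom below
    sun_idx <- take(setdiff(which(baseline >= spec$sun_delta & autosomal),
                            used), n_sun, "sun")
    used <- c(used, sun_idx)
    # tissue: the baseline is the epidermis state (the architecture
    # fractions describe epidermal profiles), so tissue effects modify
    # dermis columns only: dermis-high probes gain tissue_delta in dermis,
    # epidermis-high probes lose it there
    n_der <- round(n_tis * spec$tissue_dermis_up_frac)
    der_idx <- take(setdiff(which(baseline <= 1 - spec$tissue_delta &
                                    autosomal), used),
                    n_der, "tissue (dermis-high)")
    used <- c(used, der_idx)
    epi_idx <- take(setdiff(which(baseline >= spec$tissue_delta &
                                    autosomal), used),
                    n_tis - n_der, "tissue (epidermis-high)")

    beta <- matrix(rep(baseline, nrow(design)), nrow = n,
                   dimnames = list(annotation$probe_id, design$sample_id))
    old <- design$age_group == "old"
    exposed <- design$sun == "exposed"
    dermis <- design$tissue == "dermis"
    female <- design$sex == "female"
    beta[age_idx, old] <- beta[age_idx, old] + spec$age_delta
    beta[sun_idx, exposed] <- beta[sun_idx, exposed] - spec$sun_delta
    beta[der_idx, dermis] <- beta[der_idx, dermis] + spec$tissue_delta
    beta[epi_idx, dermis] <- beta[epi_idx, dermis] - spec$tissue_delta
    x_idx <- which(annotation$chromosome == "X")
    beta[x_idx, female] <- beta[x_idx, female] + spec$x_female_beta_shift
    beta <- pmin(pmax(beta, 0), 1)

    list(beta = beta,
         labels = list(
           age_hyper = annotation$probe_id[age_idx],
           sun_hypo = annotation$probe_id[sun_idx],
           tissue_epi_up = annotation$probe_id[epi_idx],
           tissue_dermis_up = annotation$probe_id[der_idx]),
         baseline = stats::setNames(baseline, annotation$probe_id))
  })
}

#' Simulate bead-level two-channel intensities
#'
#' Expands true beta values into a bead table in the platform's single-probe
#' two-allele layout: for every (sample, probe) the methylated allele is read
#' in the green channel with mean intensity `total_intensity_mean * beta` and
#' the unmethylated allele in the red channel with mean
#' `total_intensity_mean * (1 - beta)`. Bead intensities carry multiplicative
#' lognormal noise at coefficient of variation `noise_cv`; each sample also
#' gets `n_negative` negative-control beads per channel drawn from a
#' low-intensity lognormal with mean `total_intensity_mean * negative_scale`.
#'
#' @param true_betas output of [make_true_betas()] (or a bare probes x
#'   samples beta matrix).
#' @param design study manifest matching the beta columns.
#' @param total_intensity_mean expected total (methylated + unmethylated)
#'   fluorescence per probe, arbitrary units.
#' @param bead_count beads per (sample, probe, allele); at least 3.
#' @param noise_cv coefficient of variation of bead-level noise in \[0, 1).
#' @param negative_scale negative-bead mean as a fraction of
#'   `total_intensity_mean`.
#' @param n_negative negative-control beads per sample and channel.
#' @param negative_cv coefficient of variation of the negative-bead
#'   distribution.
#' @param seed integer seed.
#' @return a `data.table` with columns `sample_id`, `probe_id`, `channel`,
#'   `allele` (factor-encoded to keep large tables compact) and
#'   `intensity`; negative beads carry `probe_id == "NEGATIVE"` and an
#'   `NA` allele.
#' @export
simulate_beads <- function(true_betas, design = NULL,
                           total_intensity_mean = 2000, bead_count = 15L,
                           noise_cv = 0.15, negative_scale = 0.02,
                           n_negative = 500L, negative_cv = 0.5,
                           seed = 1L) {
  beta <- if (is.list(true_betas) && !is.null(true_betas$beta))
    true_betas$beta else true_betas
  if (!is.matrix(beta)) input_error("true_betas must contain a beta matrix")
  if (is.null(design)) {
    design <- data.frame(sample_id = colnames(beta))
  }
  if (!identical(colnames(beta), design$sample_id))
    input_error("beta columns and design sample_id must match")
  if (total_intensity_mean <= 0)
    input_error("`total_intensity_mean` must be positive")
  if (bead_count < 3L) input_error("`bead_count` must be at least 3")
  if (noise_cv < 0 || noise_cv >= 1)
    input_error("`noise_cv` must be in [0, 1)")
  if (n_negative < 100L)
    input_error("need at least 100 negative beads per channel")

  probes <- rownames(beta)
  samples <- colnames(beta)
  np <- length(probes); ns <- length(samples); k <- as.integer(bead_count)

  rlnorm_mean <- function(n, mean, cv) {
    # lognormal with E[X] = mean and CV = cv; mean 0 collapses to 0 (floor)
    if (cv == 0) return(mean)
    sdlog <- sqrt(log1p(cv^2))
    mulog <- ifelse(mean > 0, log(mean) - sdlog^2 / 2, -Inf)
    out <- numeric(n)
    pos <- mean > 0
    out[pos] <- rlnorm(sum(pos), mulog[pos], sdlog)
    out
  }

  with_seed(derive_seed(seed, "beads"), {
    # columns are built as factors over single integer allocations: bead
    # tables run into tens of millions of rows, and character columns
    # (plus intermediate copies) would dominate memory
    bv <- as.vector(beta)  # probe fastest, sample slowest
    nb <- np * k * ns      # rows per allele block
    nn <- as.integer(n_negative)
    nneg <- 2L * nn * ns
    m_int <- rlnorm_mean(nb, rep(total_intensity_mean * bv, each = k),
                         noise_cv)
    u_int <- rlnorm_mean(nb, rep(total_intensity_mean * (1 - bv),
                                 each = k), noise_cv)
    neg_mean <- total_intensity_mean * negative_scale
    neg_int <- rlnorm_mean(nneg, rep(neg_mean, nneg), negative_cv)
    fct <- function(codes, levels)
      structure(as.integer(codes), levels = levels, class = "factor")
    sample_block <- rep(seq_len(ns), each = np * k)
    probe_block <- rep(rep(seq_len(np), each = k), times = ns)
    beads <- data.table(
      sample_id = fct(c(sample_block, sample_block,
                        rep(seq_len(ns), each = 2L * nn)), samples),
      probe_id = fct(c(probe_block, probe_block,
                       rep(np + 1L, nneg)), c(probes, "NEGATIVE")),
      channel = fct(c(rep(1L, nb), rep(2L, nb),
                      rep(rep(1:2, each = nn), times = ns)),
                    c("green", "red")),
      allele = fct(c(rep(1L, nb), rep(2L, nb), rep(NA_integer_, nneg)),
                   c("methylated", "unmethylated")),
      intensity = c(m_int, u_int, neg_int))
    beads[]
  })
}
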