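# End-to-end pipeline: normalize -> aggregate -> detect -> beta -> filter
# -> differential comparisons -> global shift, from a single config.

#' Build a pipeline run configuration
#'
#' @param comparisons named list of comparisons; each element is a list
#'   with `group_by` (manifest column), `a` and `b` (its two levels), and
#'   an optional `subset` (named list of manifest column = allowed values
#'   applied before grouping).
#' @param delta_threshold,p_threshold,detect_threshold,null_sd analysis
#'   thresholds (defaults 0.2, 0.01, 0.05, 0.1).
#' @param offset beta regularization offset, default 100.
#' @param require_p demand the adjusted-P filter for marker calls.
#' @param seed integer seed used for every stochastic stage.
#' @param out_dir output directory (NULL disables file output).
#' @return list of class `run_config`.
#' @export
run_config <- function(comparisons, delta_threshold = 0.2,
                       p_threshold = 0.01, detect_threshold = 0.05,
                       null_sd = 0.1, offset = 100, require_p = TRUE,
                       seed = 1L, out_dir = NULL) {
  if (length(comparisons) == 0L)
    input_error("at least one comparison is required")
  if (is.null(names(comparisons)) || any(names(comparisons) == ""))
    input_error("comparisons must be a named list")
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    if (!all(c("group_by", "a", "b") %in% names(cmp)))
      input_error(sprintf(
        "comparison '%s' needs `group_by`, `a` and `b`", nm))
  }
  check_fraction(p_threshold, "p_threshold")
  if (detect_threshold <= 0 || detect_threshold >= 1)
    input_error("`detect_threshold` must be in (0, 1)")
  if (delta_threshold < 0 || delta_threshold > 1)
    input_error("`delta_threshold` must be in [0, 1]")
  structure(list(comparisons = comparisons,
                 delta_threshold = delta_threshold,
                 p_threshold = p_threshold,
                 detect_threshold = detect_threshold,
                 null_sd = null_sd, offset = offset,
                 require_p = require_p, seed = check_seed(seed),
                 out_dir = out_dir),
            class = "run_config")
}

comparison_samples <- function(design, cmp) {
  df <- design
  for (col in names(cmp$subset)) {
    if (!col %in% names(df))
      input_error(sprintf("subset column '%s' not in manifest", col))
    df <- df[df[[col]] %in% cmp$subset[[col]], , drop = FALSE]
  }
  if (!cmp$group_by %in% names(df))
    input_error(sprintf("group_by column '%s' not in manifest",
                        cmp$group_by))
  a <- df$sample_id[df[[cmp$group_by]] == cmp$a]
  b <- df$sample_id[df[[cmp$group_by]] == cmp$b]
  if (length(a) < 2L || length(b) < 2L)
    input_error(sprintf(
      "comparison groups too small (%d vs %d) for %s = %s vs %s",
      length(a), length(b), cmp$group_by, cmp$a, cmp$b))
  list(a = a, b = b)
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (quantile normalization, aggregation, detection,
#' beta computation, detection filtering) and every configured comparison
#' (delta-beta, rank-sum tests, BH adjustment, marker classification,
#' island stratification, RS curve, global shift test), writing per-stage
#' TSV outputs and a JSON summary when `config$out_dir` is set.
#'
#' @param beads bead table.
#' @param design study manifest.
#' @param annotation probe annotation.
#' @param config a [run_config()].
#' @return list of class `pipeline_result`: `beta` (filtered
#'   `beta_matrix`), `comparisons` (per-comparison list with `diff`,
#'   `rs`, `shift`, `counts`, `island`), and `summary` (the JSON-ready
#'   summary list).
#' @export
run_pipeline <- function(beads, design, annotation, config) {
  if (!inherits(config, "run_config"))
    input_error("`config` must be a run_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  bm <- stage("preprocess",
              preprocess_beads(beads, design, offset = config$offset))
  bm <- stage("detection_filter",
              filter_detected(bm, threshold = config$detect_threshold))

  results <- list()
  summary <- list(
    package_version = as.character(packageVersion("methylskin")),
    seed = config$seed,
    n_probes_retained = nrow(bm$beta),
    n_probes_excluded = bm$excluded$n_excluded,
    excluded_fraction = bm$excluded$fraction,
    thresholds = list(delta = config$delta_threshold,
                      p_bh = config$p_threshold,
                      detection = config$detect_threshold,
                      null_sd = config$null_sd),
    comparisons = list())

  for (nm in names(config$comparisons)) {
    cmp <- config$comparisons[[nm]]
    grp <- stage(nm, comparison_samples(design, cmp))
    dres <- stage(nm, diff_methylation(
      bm, grp$a, grp$b, annotation = annotation,
      delta_threshold = config$delta_threshold,
      p_threshold = config$p_threshold,
      require_p = config$require_p))
    cls_counts <- table(dres$call, useNA = "no")
    rs <- stage(nm, rs_curve(dres))
    sh <- tryCatch(
      shift_test(dres, p_threshold = config$p_threshold,
                 sd_threshold = config$null_sd,
                 null_sd = config$null_sd,
                 seed = derive_seed(config$seed, nm)),
      methylskin_stat_error = function(e) e)
    isl_hyper <- if ("cpg_island" %in% names(dres))
      stratify_by_island(dres, "hyper") else NULL
    isl_hypo <- if ("cpg_island" %in% names(dres))
      stratify_by_island(dres, "hypo") else NULL

    results[[nm]] <- list(diff = dres, rs = rs, shift = sh,
                          groups = grp,
                          counts = as.list(cls_counts),
                          island = list(hyper = isl_hyper,
                                        hypo = isl_hypo))
    summary$comparisons[[nm]] <- list(
      group_by = cmp$group_by, a = cmp$a, b = cmp$b,
      n_a = length(grp$a), n_b = length(grp$b),
      n_hyper = unname(cls_counts["hyper"]),
      n_hypo = unname(cls_counts["hypo"]),
      n_unchanged = unname(cls_counts["unchanged"]),
      island_hyper = isl_hyper, island_hypo = isl_hypo,
      global_shift_ratio = rs$y[nrow(rs)],
      shift = if (inherits(sh, "shift_test"))
        list(n_markers = sh$n_markers, mean_delta = sh$mean_delta,
             t = sh$t, p_value = sh$p_value)
      else list(error = conditionMessage(sh)))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_beta_matrix(bm, file.path(config$out_dir, "preprocessed"))
    for (nm in names(results)) {
      write_diff_result(results[[nm]]$diff,
                        file.path(config$out_dir,
                                  sprintf("diff_%s.tsv", nm)))
      write_tsv_atomic(as.data.frame(results[[nm]]$rs),
                       file.path(config$out_dir,
                                 sprintf("rs_%s.tsv", nm)))
    }
    write_summary_json(summary, file.path(config$out_dir,
                                          "summary.json"))
  }
  structure(list(beta = bm, comparisons = results, summary = summary),
            class = "pipeline_result")
}
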