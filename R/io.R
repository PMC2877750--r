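# File-format readers and writers. All tabular interchange is
# tab-separated UTF-8 with '#'-prefixed header comments carrying the
# package version and a parameter hash; writes are atomic (temp file in
# the target directory, then rename).

header_comment <- function(params = NULL) {
  h <- sprintf("# methylskin %s", as.character(packageVersion("methylskin")))
  if (!is.null(params)) {
    hash <- substr(digest_params(params), 1, 12)
    h <- c(h, sprintf("# config_hash %s", hash))
  }
  h
}

# Stable content hash of a parameter list (md5 of its deparsed form).
digest_params <- function(params) {
  txt <- paste(deparse(params[order(names(params))]), collapse = "")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

# Atomic TSV write with comment header.
write_tsv_atomic <- function(df, path, params = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "w", encoding = "UTF-8")
  writeLines(header_comment(params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  close(con)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Read a TSV written by write_tsv_atomic (or a plain headered TSV).
read_tsv_commented <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  first <- readLines(path, n = 50L)
  skip <- sum(cumprod(startsWith(first, "#")))
  dt <- data.table::fread(path, sep = "\t", skip = skip, header = TRUE,
                          na.strings = "NA", data.table = TRUE)
  dt
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    input_error(sprintf("%s is missing column(s): %s", what,
                        paste(missing, collapse = ", ")))
  invisible(df)
}

#' Read a study manifest
#'
#' Tab-separated manifest with columns `sample_id`, `tissue`, `age_group`,
#' `sun`, `sex`, `sampling`; values are validated against the allowed
#' levels and sample ids must be unique.
#'
#' @param path TSV file path.
#' @return a validated study design `data.frame`.
#' @export
read_manifest <- function(path) {
  df <- as.data.frame(read_tsv_commented(path))
  check_columns(df, c("sample_id", "tissue", "age_group", "sun", "sex",
                      "sampling"), "manifest")
  validate_design(df)
}

#' Write a study manifest
#' @param design study design data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(design, path) {
  write_tsv_atomic(validate_design(design), path)
}

#' Read a bead table
#'
#' TSV with columns `sample_id`, `probe_id`, `channel`, `allele`,
#' `intensity`; negative-control beads carry `probe_id == "NEGATIVE"`.
#' Intensities must be non-negative.
#'
#' @param path TSV file path.
#' @return a `data.table` bead table.
#' @export
read_beads <- function(path) {
  dt <- read_tsv_commented(path)
  if (nrow(dt) == 0L) input_error(sprintf("no beads in file: %s", path))
  check_columns(dt, c("sample_id", "probe_id", "channel", "allele",
                      "intensity"), "bead table")
  bad <- which(!is.finite(dt$intensity) | dt$intensity < 0)
  if (length(bad))
    input_error(sprintf(
      "bead table has negative or non-finite intensity at row %d", bad[1]))
  bad_ch <- which(!dt$channel %in% c("green", "red"))
  if (length(bad_ch))
    input_error(sprintf("invalid channel at row %d", bad_ch[1]))
  dt
}

#' Write a bead table
#' @param beads bead table.
#' @param path output TSV path.
#' @param params optional parameter list recorded in the header hash.
#' @return the path, invisibly.
#' @export
write_beads <- function(beads, path, params = NULL) {
  write_tsv_atomic(beads, path, params)
}

#' Read a probe annotation
#'
#' TSV with columns `probe_id`, `chromosome`, `cpg_island`
#' (TRUE/FALSE), `gene_symbol`; probe ids must be unique and chromosomes
#' in 1..22, X, Y.
#'
#' @param path TSV file path.
#' @return annotation `data.frame`.
#' @export
read_annotation <- function(path) {
  df <- as.data.frame(read_tsv_commented(path))
  check_columns(df, c("probe_id", "chromosome", "cpg_island"),
                "annotation")
  df$chromosome <- as.character(df$chromosome)
  if (anyDuplicated(df$probe_id)) {
    row <- which(duplicated(df$probe_id))[1]
    input_error(sprintf("duplicate probe_id at row %d", row))
  }
  bad <- which(!df$chromosome %in% c(as.character(1:22), "X", "Y"))
  if (length(bad))
    input_error(sprintf("invalid chromosome at row %d", bad[1]))
  df$cpg_island <- as.logical(df$cpg_island)
  df
}

#' Write a probe annotation
#' @param annotation annotation data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv_atomic(annotation, path)
}

#' Write a beta matrix (and its detection P-values)
#'
#' Writes `<stem>.beta.tsv` and `<stem>.detection_p.tsv`, each with a
#' `probe_id` column followed by one column per sample.
#'
#' @param beta a `beta_matrix`.
#' @param stem output path stem (directory + file prefix).
#' @return character vector of the two paths, invisibly.
#' @export
write_beta_matrix <- function(beta, stem) {
  if (!inherits(beta, "beta_matrix"))
    input_error("`beta` must be a beta_matrix")
  params <- list(offset = beta$offset)
  p1 <- write_tsv_atomic(
    data.frame(probe_id = rownames(beta$beta), beta$beta,
               check.names = FALSE), paste0(stem, ".beta.tsv"), params)
  p2 <- write_tsv_atomic(
    data.frame(probe_id = rownames(beta$detection_p), beta$detection_p,
               check.names = FALSE), paste0(stem, ".detection_p.tsv"),
    params)
  invisible(c(p1, p2))
}

#' Read a beta matrix written by [write_beta_matrix()]
#'
#' @param stem the path stem used when writing.
#' @param design optional manifest to attach.
#' @return a `beta_matrix` object (without exclusion report).
#' @export
read_beta_matrix <- function(stem, design = NULL) {
  read_mat <- function(path) {
    dt <- read_tsv_commented(path)
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt$probe_id
    m
  }
  beta <- read_mat(paste0(stem, ".beta.tsv"))
  dp_path <- paste0(stem, ".detection_p.tsv")
  dp <- if (file.exists(dp_path)) read_mat(dp_path) else
    matrix(NA_real_, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  structure(list(beta = beta, detection_p = dp, design = design,
                 offset = NA_real_, excluded = NULL),
            class = "beta_matrix")
}

#' Write a differential methylation result
#' @param results a `diff_result`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_diff_result <- function(results, path) {
  write_tsv_atomic(as.data.frame(results), path,
                   params = attr(results, "thresholds"))
}

#' Write reads or an amplicon reference as FASTA
#' @param sequences named character vector of DNA sequences.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  x <- Biostrings::DNAStringSet(sequences)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  Biostrings::writeXStringSet(x, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read FASTA sequences
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a JSON summary
#' @param x a list of results.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_summary_json <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
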