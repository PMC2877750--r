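# Bisulfite amplicon simulation and per-CpG methylation calling.
#
# Only the bisulfite top strand is modeled: amplicons are defined on one
# strand (matching single-strand primer design), and reads are compared
# against the reference with bisulfite-aware base matching (a read T matches
# a reference C outside the CpG context).

#' Find CpG sites in a DNA sequence
#'
#' @param sequence DNA string (uppercase A/C/G/T).
#' @return 0-based positions of the C of every CpG dinucleotide.
#' @export
find_cpg_sites <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Construct an amplicon object
#'
#' @param name amplicon name.
#' @param sequence reference DNA sequence (top strand, uppercase).
#' @param probe_links optional named character vector mapping CpG index
#'   (1-based site number as name) to an array probe_id.
#' @return list of class `amplicon` with fields `name`, `sequence`,
#'   `cpg_pos` (0-based C positions), `non_cpg_c` (0-based positions of
#'   cytosines outside CpG context) and `probe_links`.
#' @export
amplicon <- function(name, sequence, probe_links = NULL) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence))
    input_error("amplicon sequence must contain only A/C/G/T")
  cpg <- find_cpg_sites(sequence)
  if (length(cpg) == 0L)
    input_error("amplicon contains no CpG dinucleotide")
  all_c <- which(strsplit(sequence, "")[[1]] == "C") - 1L
  structure(list(name = name, sequence = sequence, cpg_pos = cpg,
                 non_cpg_c = setdiff(all_c, cpg),
                 probe_links = probe_links, strand = "top"),
            class = "amplicon")
}

#' Simulate bisulfite reads from an amplicon
#'
#' Full-length, error-free reads: at each CpG cytosine the C is retained
#' (methylated) with the site's probability and otherwise converted to T; at
#' each non-CpG cytosine the C is converted to T with probability
#' `conversion_rate` (deamination efficiency).
#'
#' @param amplicon_sequence reference DNA string, or an [amplicon()].
#' @param cpg_meth_probs per-CpG methylation probabilities, aligned to the
#'   amplicon's CpG sites.
#' @param n_reads number of reads.
#' @param conversion_rate bisulfite conversion rate in (0, 1\].
#' @param seed integer seed.
#' @return character vector of reads (length `n_reads`), each the amplicon
#'   length, named `read_0001`, ...
#' @export
simulate_bisulfite_reads <- function(amplicon_sequence, cpg_meth_probs,
                                     n_reads, conversion_rate = 0.995,
                                     seed = 1L) {
  amp <- if (inherits(amplicon_sequence, "amplicon")) amplicon_sequence
  else amplicon("amplicon", amplicon_sequence)
  if (length(cpg_meth_probs) != length(amp$cpg_pos))
    input_error(sprintf(
      "cpg_meth_probs has length %d but the amplicon has %d CpG sites",
      length(cpg_meth_probs), length(amp$cpg_pos)))
  if (any(cpg_meth_probs < 0 | cpg_meth_probs > 1))
    input_error("cpg_meth_probs must be in [0, 1]")
  if (conversion_rate <= 0 || conversion_rate > 1)
    input_error("conversion_rate must be in (0, 1]")
  if (n_reads < 1) input_error("n_reads must be positive")

  ref <- strsplit(amp$sequence, "")[[1]]
  with_seed(derive_seed(seed, "bisulfite_reads"), {
    reads <- vapply(seq_len(n_reads), function(i) {
      r <- ref
      meth <- rbinom(length(amp$cpg_pos), 1L, cpg_meth_probs) == 1L
      r[(amp$cpg_pos + 1L)[!meth]] <- "T"
      conv <- rbinom(length(amp$non_cpg_c), 1L, conversion_rate) == 1L
      r[(amp$non_cpg_c + 1L)[conv]] <- "T"
      paste(r, collapse = "")
    }, character(1))
    names(reads) <- sprintf("read_%04d", seq_len(n_reads))
    reads
  })
}

# Best ungapped offset of `read` against the amplicon under bisulfite-aware
# scoring (read base matches reference base, or read T matches reference C).
# Returns list(offset, identity); offset is 0-based.
align_read <- function(read, amp) {
  ref <- strsplit(amp$sequence, "")[[1]]
  rd <- strsplit(toupper(read), "")[[1]]
  L <- length(ref); l <- length(rd)
  if (l > L) return(list(offset = NA_integer_, identity = 0))
  best <- list(offset = 0L, identity = -1)
  for (off in 0:(L - l)) {
    seg <- ref[(off + 1L):(off + l)]
    ok <- rd == seg | (rd == "T" & seg == "C")
    id <- mean(ok)
    if (id > best$identity) best <- list(offset = off, identity = id)
    if (best$identity == 1) break
  }
  best
}

#' Call per-CpG methylation from one bisulfite read
#'
#' At each CpG cytosine covered by the read: read base C is called
#' methylated, T unmethylated, anything else (or an uncovered site) a gap.
#' Non-CpG cytosines are tallied as converted (read T) or unconverted
#' (read C) for deamination QC.
#'
#' @param read DNA string.
#' @param amplicon an [amplicon()].
#' @param min_identity reject reads whose best bisulfite-aware ungapped
#'   identity is below this (default 0.9).
#' @return list with `calls` (factor vector methylated/unmethylated/gap, one
#'   per amplicon CpG site), `converted`, `unconverted` (non-CpG C tallies),
#'   `offset`, `identity`; or a rejection with class
#'   `methylskin_input_error` if unmappable.
#' @export
call_read <- function(read, amplicon, min_identity = 0.9) {
  amp <- amplicon
  aln <- align_read(read, amp)
  if (is.na(aln$offset) || aln$identity < min_identity)
    input_error(sprintf(
      "read rejected: best bisulfite-aware identity %.2f below %.2f",
      max(aln$identity, 0), min_identity))
  rd <- strsplit(toupper(read), "")[[1]]
  covered <- function(pos0) pos0 >= aln$offset &
    pos0 < aln$offset + length(rd)
  base_at <- function(pos0) rd[pos0 - aln$offset + 1L]

  calls <- rep("gap", length(amp$cpg_pos))
  cov <- covered(amp$cpg_pos)
  b <- vapply(amp$cpg_pos[cov], base_at, character(1))
  idx <- which(cov)
  calls[idx[b == "C"]] <- "methylated"
  calls[idx[b == "T"]] <- "unmethylated"

  ncc <- amp$non_cpg_c[covered(amp$non_cpg_c)]
  nb <- vapply(ncc, base_at, character(1))
  list(calls = factor(calls, levels = c("methylated", "unmethylated",
                                        "gap")),
       converted = sum(nb == "T"), unconverted = sum(nb == "C"),
       offset = aln$offset, identity = aln$identity)
}

#' Call methylation for a set of reads
#'
#' Applies [call_read()] to every read, keeping rejected reads out of the
#' call table but reporting them.
#'
#' @param reads named character vector of reads (names become read ids) or a
#'   `DNAStringSet`.
#' @param amplicon an [amplicon()].
#' @param min_identity see [call_read()].
#' @return list of class `amplicon_calls`: `calls` (reads x CpG matrix of
#'   "M"/"U"/"."), `conversion` (per-read converted / total non-CpG C
#'   data.frame), `rejected` (read ids), `amplicon`.
#' @export
call_reads <- function(reads, amplicon, min_identity = 0.9) {
  if (inherits(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%04d", seq_along(reads))
  amp <- amplicon
  n_sites <- length(amp$cpg_pos)
  kept <- list(); rejected <- character(0)
  conv <- list()
  for (id in names(reads)) {
    res <- tryCatch(call_read(reads[[id]], amp, min_identity),
                    methylskin_input_error = function(e) NULL)
    if (is.null(res)) { rejected <- c(rejected, id); next }
    kept[[id]] <- res
    conv[[id]] <- c(res$converted, res$unconverted)
  }
  if (length(kept) == 0L)
    input_error("no read could be mapped to the amplicon")
  code <- c(methylated = "M", unmethylated = "U", gap = ".")
  mat <- do.call(rbind, lapply(kept, function(r)
    unname(code[as.character(r$calls)])))
  colnames(mat) <- sprintf("CpG_%02d", seq_len(n_sites))
  convdf <- data.frame(read_id = names(kept),
                       converted = vapply(conv, `[`, numeric(1), 1L),
                       unconverted = vapply(conv, `[`, numeric(1), 2L),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(calls = mat, conversion = convdf, rejected = rejected,
                 amplicon = amp),
            class = "amplicon_calls")
}

#' Per-CpG methylation percentages and coverage
#'
#' @param calls an `amplicon_calls` object from [call_reads()].
#' @return data.frame with one row per CpG site: `site` (1-based site
#'   number), `position` (0-based C position in the amplicon), `n_meth`,
#'   `n_unmeth`, `coverage` (non-gap calls) and `percent_meth` (`NA` for
#'   zero-coverage sites, reported missing rather than 0).
#' @export
site_fractions <- function(calls) {
  mat <- calls$calls
  n_meth <- colSums(mat == "M")
  n_unmeth <- colSums(mat == "U")
  coverage <- n_meth + n_unmeth
  percent <- ifelse(coverage > 0, 100 * n_meth / coverage, NA_real_)
  data.frame(site = seq_len(ncol(mat)),
             position = calls$amplicon$cpg_pos,
             n_meth = unname(n_meth), n_unmeth = unname(n_unmeth),
             coverage = unname(coverage),
             percent_meth = unname(percent),
             row.names = NULL)
}

#' Bisulfite conversion (deamination) efficiency
#'
#' Fraction of non-CpG cytosines read as T, pooled over all retained reads,
#' plus per-read efficiencies and a QC flag.
#'
#' @param calls an `amplicon_calls` object.
#' @param qc_threshold minimum acceptable pooled efficiency (default 0.99).
#' @return list with `efficiency` (pooled), `per_read` (named vector),
#'   `n_sites` (non-CpG C observations) and `qc_pass`.
#' @export
deamination_efficiency <- function(calls, qc_threshold = 0.99) {
  conv <- calls$conversion
  total <- sum(conv$converted) + sum(conv$unconverted)
  if (total == 0L) {
    warning("amplicon has no non-CpG cytosines; efficiency undefined")
    return(list(efficiency = NA_real_, per_read = NULL, n_sites = 0L,
                qc_pass = NA))
  }
  eff <- sum(conv$converted) / total
  per_read <- ifelse(conv$converted + conv$unconverted > 0,
                     conv$converted / (conv$converted + conv$unconverted),
                     NA_real_)
  names(per_read) <- conv$read_id
  list(efficiency = eff, per_read = per_read, n_sites = total,
       qc_pass = eff >= qc_threshold)
}

#' Compare amplicon sequencing fractions to array beta values
#'
#' Pairs each array-linked CpG site's sequencing methylation percentage with
#' 100 x the group-mean array beta of the linked probe and flags
#' concordance at a configurable absolute difference (default 20 percentage
#' points, mirroring the 0.2 delta-beta convention).
#'
#' @param fractions output of [site_fractions()].
#' @param amplicon an [amplicon()] with `probe_links`.
#' @param beta a `beta_matrix` (see [preprocess_beads()]) or a bare probes x
#'   samples beta matrix.
#' @param samples sample ids defining the group whose mean beta is compared.
#' @param threshold concordance threshold in percentage points.
#' @return data.frame with `site`, `probe_id`, `seq_percent`,
#'   `array_percent`, `difference`, `concordant`.
#' @export
compare_to_array <- function(fractions, amplicon, beta, samples,
                             threshold = 20) {
  links <- amplicon$probe_links
  if (is.null(links) || length(links) == 0L)
    input_error("amplicon has no array probe links")
  bmat <- if (inherits(beta, "beta_matrix")) beta$beta else beta
  missing_s <- setdiff(samples, colnames(bmat))
  if (length(missing_s))
    input_error(sprintf("samples not in beta matrix: %s",
                        paste(missing_s, collapse = ", ")))
  sites <- as.integer(names(links))
  rows <- lapply(seq_along(links), function(i) {
    site <- sites[i]; probe <- links[[i]]
    fr <- fractions[fractions$site == site, ]
    if (nrow(fr) == 0L || !probe %in% rownames(bmat)) {
      message(sprintf("site %d / probe %s skipped: not available",
                      site, probe))
      return(NULL)
    }
    arr <- 100 * mean(bmat[probe, samples], na.rm = TRUE)
    d <- fr$percent_meth - arr
    data.frame(site = site, probe_id = probe,
               seq_percent = fr$percent_meth, array_percent = arr,
               difference = d, concordant = abs(d) <= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    input_error("no linked CpG site could be compared")
  rownames(out) <- NULL
  out
}
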