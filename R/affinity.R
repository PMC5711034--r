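# Peptide-HLA binding affinities. Real data arrive as NetMHCpan-style
# tables (peptide, allele, IC50 in nM); for self-contained runs a
# deterministic synthetic model hashes (peptide, allele, seed) onto a
# log-uniform IC50 range. Binding affinity af = 1/IC50 (nM^-1) throughout.

#' Parse a predictor output table into peptide-HLA records
#'
#' Accepts NetMHCpan-style whitespace/TSV output (or any `data.frame`) with
#' peptide, allele and IC50 columns. Rows with non-positive or non-numeric
#' IC50 are rejected; duplicate (peptide, allele) rows are collapsed to the
#' minimum IC50. Both events are counted in the log.
#'
#' @param rows `data.frame` or path to a whitespace/tab-delimited file.
#' @param column_map named character vector mapping the roles `peptide`,
#'   `allele`, `ic50` to column names in `rows`.
#' @return a `data.frame` with `sequence`, `hla_allele`, `ic50_nm`,
#'   `affinity` (= 1/ic50_nm), one row per unique (peptide, allele).
#' @export
parse_affinity_table <- function(rows,
                                 column_map = c(peptide = "peptide",
                                                allele = "allele",
                                                ic50 = "ic50")) {
  if (is.character(rows) && length(rows) == 1L) {
    rows <- read.table(rows, header = TRUE, stringsAsFactors = FALSE)
  }
  need <- column_map[c("peptide", "allele", "ic50")]
  if (!all(need %in% names(rows))) {
    stopf("affinity table lacks columns: %s",
          paste(setdiff(need, names(rows)), collapse = ", "))
  }
  ic50 <- suppressWarnings(as.numeric(rows[[need[["ic50"]]]]))
  bad <- is.na(ic50) | ic50 <= 0
  df <- data.frame(
    sequence = as.character(rows[[need[["peptide"]]]])[!bad],
    hla_allele = as.character(rows[[need[["allele"]]]])[!bad],
    ic50_nm = ic50[!bad],
    stringsAsFactors = FALSE
  )
  # collapse duplicates to the minimum IC50
  key <- paste(df$sequence, df$hla_allele, sep = "\r")
  o <- order(key, df$ic50_nm)
  df <- df[o, , drop = FALSE]
  dup <- duplicated(key[o])
  res <- df[!dup, , drop = FALSE]
  res$affinity <- 1 / res$ic50_nm
  rownames(res) <- NULL
  set_log(res, c(rows_rejected = sum(bad), duplicates_collapsed = sum(dup)))
}

# 32-bit FNV-1a hash of a string, in double arithmetic (exact: every
# intermediate stays below 2^53). Used to make the synthetic affinity model
# deterministic per (peptide, allele, seed) without any RNG state.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), as.integer(b %% 256))
    # multiply by the 32-bit FNV prime mod 2^32, split to keep products exact
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619
    h <- h %% 4294967296
  }
  h
}

#' Deterministic synthetic peptide-HLA affinity
#'
#' Stand-in for an external MHC binding predictor: maps a hash of
#' (sequence, allele, seed) onto a log-uniform IC50 distribution. The same
#' inputs always produce the same IC50; across many peptides log10(IC50) is
#' uniform on the configured range.
#'
#' @param sequence character vector of peptides.
#' @param hla_allele character vector of HLA allele names (recycled).
#' @param ic50_range two positive numbers, the IC50 range in nM
#'   (default 1 to 50000, log-uniform).
#' @param seed integer; changes the whole mapping.
#' @return numeric vector of IC50 values (nM).
#' @export
synthetic_affinity <- function(sequence, hla_allele,
                               ic50_range = c(1, 50000), seed = 0) {
  if (length(ic50_range) != 2L || any(ic50_range <= 0)) {
    stopf("ic50_range must be two positive numbers")
  }
  lo <- min(ic50_range); hi <- max(ic50_range)
  n <- max(length(sequence), length(hla_allele))
  sequence <- rep_len(sequence, n)
  hla_allele <- rep_len(hla_allele, n)
  u <- vapply(paste(sequence, hla_allele, seed, sep = "|"),
              fnv1a32, 0, USE.NAMES = FALSE) / 4294967296
  exp(log(lo) + u * (log(hi) - log(lo)))
}

#' Score candidate peptides against a set of HLA alleles
#'
#' Forms every (peptide, allele) pair and attaches an IC50, either from a
#' parsed predictor table or from the synthetic model. Pairs absent from a
#' supplied table are dropped and counted.
#'
#' @param peptides candidate-peptide `data.frame`
#'   (from [build_peptide_library()] / [y_chromosome_peptides()]).
#' @param hla_alleles character vector of the pair's (up to six) HLA class I
#'   alleles.
#' @param method `"synthetic"` or `"table"`.
#' @param affinity_table parsed table from [parse_affinity_table()] (for
#'   `method = "table"`).
#' @param ic50_range,seed passed to [synthetic_affinity()].
#' @return peptide-HLA `data.frame` ("pmHA" records): candidate columns plus
#'   `hla_allele`, `ic50_nm`, `affinity`; (sequence, hla_allele) is unique.
#' @export
score_affinity <- function(peptides, hla_alleles,
                           method = c("synthetic", "table"),
                           affinity_table = NULL,
                           ic50_range = c(1, 50000), seed = 0) {
  method <- match.arg(method)
  if (anyDuplicated(peptides$sequence)) {
    stopf("candidate peptide sequences must be unique (run donor_self_filter)")
  }
  idx <- rep(seq_len(nrow(peptides)), times = length(hla_alleles))
  out <- peptides[idx, , drop = FALSE]
  out$hla_allele <- rep(hla_alleles, each = nrow(peptides))
  dropped <- 0L
  if (method == "synthetic") {
    out$ic50_nm <- synthetic_affinity(out$sequence, out$hla_allele,
                                      ic50_range = ic50_range, seed = seed)
  } else {
    if (is.null(affinity_table)) stopf("affinity_table required for method='table'")
    m <- match(paste(out$sequence, out$hla_allele, sep = "\r"),
               paste(affinity_table$sequence, affinity_table$hla_allele,
                     sep = "\r"))
    dropped <- sum(is.na(m))
    out <- out[!is.na(m), , drop = FALSE]
    out$ic50_nm <- affinity_table$ic50_nm[m[!is.na(m)]]
  }
  out$affinity <- 1 / out$ic50_nm
  rownames(out) <- NULL
  set_log(out, c(pairs_missing_from_table = dropped))
}

#' Filter peptide-HLA records on IC50
#'
#' The working library keeps binders with IC50 at or below the cutoff
#' (default 500 nM, boundary inclusive); order is preserved.
#'
#' @param pmhas peptide-HLA `data.frame` with an `ic50_nm` column.
#' @param cutoff_nm positive cutoff in nM.
#' @return the retained rows.
#' @export
filter_binders <- function(pmhas, cutoff_nm = 500) {
  if (cutoff_nm <= 0) stopf("cutoff_nm must be positive")
  res <- pmhas[pmhas$ic50_nm <= cutoff_nm, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count strong binders (IC50 strictly below a threshold)
#'
#' The strong-binder tally uses a strict inequality (IC50 < 50 nM by
#' default), distinct from the inclusive working-library cutoff of
#' [filter_binders()].
#'
#' @inheritParams filter_binders
#' @param threshold_nm strict upper bound, default 50 nM.
#' @return integer count.
#' @export
count_strong_binders <- function(pmhas, threshold_nm = 50) {
  sum(pmhas$ic50_nm < threshold_nm)
}
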