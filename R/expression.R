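# Tissue expression (RPKM) joining: each peptide-HLA record is weighted by
# the expression of its source gene in the target tissue (Pexp), and the
# RPKM >= 1 inclusion rule produces one organ-specific operator per tissue.

#' GVHD target tissues modelled by the simulator
#'
#' @return character vector of the nine target tissues.
#' @export
gvhd_target_tissues <- function() {
  c("skin", "salivary gland", "esophagus", "stomach", "small intestine",
    "colon", "liver", "lung", "blood")
}

default_tissue_map <- function() {
  tissues <- gvhd_target_tissues()
  setNames(tissues, gsub(" ", "_", tissues))
}

#' Read a gene-by-tissue expression table
#'
#' Reads a GTEx-style wide TSV (`gene_id` column plus one column per tissue)
#' into long format. Column headers are translated through `tissue_map`
#' (defaults map underscored headers such as `salivary_gland` to the tissue
#' names of [gvhd_target_tissues()]; `whole_blood` is accepted for blood).
#' Multiple rows per gene (e.g. per-transcript tables) are collapsed to the
#' maximum RPKM per (gene, tissue), counted in the log.
#'
#' @param file path to the TSV (or a wide `data.frame`).
#' @param tissue_map named character vector: names are column headers,
#'   values the canonical tissue names.
#' @return long `data.frame` with columns `gene_id`, `tissue`, `rpkm`.
#' @export
read_expression_table <- function(file, tissue_map = NULL) {
  wide <- if (is.data.frame(file)) file else {
    read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!"gene_id" %in% names(wide)) stopf("expression table needs a gene_id column")
  map <- default_tissue_map()
  map["whole_blood"] <- "blood"
  if (!is.null(tissue_map)) map[names(tissue_map)] <- tissue_map
  cols <- setdiff(names(wide), "gene_id")
  tissue_of <- ifelse(cols %in% names(map), map[cols], cols)
  long <- do.call(rbind, lapply(seq_along(cols), function(i) {
    data.frame(gene_id = wide$gene_id, tissue = tissue_of[i],
               rpkm = as.numeric(wide[[cols[i]]]), stringsAsFactors = FALSE)
  }))
  if (any(long$rpkm < 0, na.rm = TRUE)) stopf("negative RPKM values in table")
  key <- paste(long$gene_id, long$tissue, sep = "\r")
  collapsed <- 0L
  if (anyDuplicated(key)) {
    o <- order(key, -long$rpkm)
    long <- long[o, , drop = FALSE]
    dup <- duplicated(key[o])
    collapsed <- sum(dup)
    long <- long[!dup, , drop = FALSE]
  }
  rownames(long) <- NULL
  set_log(long, c(transcript_rows_collapsed = collapsed))
}

#' Build the organ-specific alloreactivity operator for one tissue
#'
#' Joins tissue expression onto binder-filtered peptide-HLA records and keeps
#' those whose source gene has RPKM at or above the cutoff (default 1) in
#' that tissue. Y-chromosome peptides have no expression entry and receive a
#' neutral multiplier `pexp = 1` so they participate in every organ; other
#' genes missing from the table are excluded and counted. Entries are sorted
#' by ascending IC50, ties broken by (sequence, hla_allele).
#'
#' @param pmhas binder-filtered peptide-HLA `data.frame`
#'   (see [filter_binders()]).
#' @param expression_records long expression table
#'   ([read_expression_table()]).
#' @param tissue one tissue name present in `expression_records`.
#' @param rpkm_cutoff inclusion cutoff (default 1, boundary inclusive).
#' @param y_pexp neutral expression multiplier for Y-derived peptides.
#' @return an `OrganOperator`: a `data.frame` of entries with a `pexp`
#'   column, attributes `tissue` and `rpkm_cutoff`.
#' @export
build_organ_operator <- function(pmhas, expression_records, tissue,
                                 rpkm_cutoff = 1, y_pexp = 1) {
  tissues <- unique(expression_records$tissue)
  if (!tissue %in% tissues) {
    stopf("unknown tissue '%s'; valid tissues: %s", tissue,
          paste(sort(tissues), collapse = ", "))
  }
  er <- expression_records[expression_records$tissue == tissue, , drop = FALSE]
  m <- match(pmhas$gene_id, er$gene_id)
  pexp <- er$rpkm[m]
  is_y <- !is.null(pmhas$origin) & pmhas$origin == "y_chromosome"
  pexp[is_y & is.na(pexp)] <- y_pexp
  missing_gene <- is.na(pexp)
  out <- pmhas[!missing_gene, , drop = FALSE]
  out$pexp <- pexp[!missing_gene]
  below <- out$pexp < rpkm_cutoff
  out <- out[!below, , drop = FALSE]
  out <- out[order(out$ic50_nm, out$sequence, out$hla_allele), , drop = FALSE]
  rownames(out) <- NULL
  out <- set_log(out, c(genes_missing_from_expression = sum(missing_gene),
                        below_rpkm_cutoff = sum(below)))
  structure(out, tissue = tissue, rpkm_cutoff = rpkm_cutoff,
            class = c("OrganOperator", class(out)))
}

#' @export
print.OrganOperator <- function(x, ...) {
  cat(sprintf("OrganOperator for tissue '%s': %d peptide-HLA entries (RPKM >= %g)\n",
              attr(x, "tissue"), nrow(x), attr(x, "rpkm_cutoff")))
  if (nrow(x)) {
    print(utils::head(as.data.frame(x)[, intersect(
      c("sequence", "hla_allele", "ic50_nm", "gene_id", "pexp"), names(x))], 5))
    if (nrow(x) > 5) cat(sprintf("... and %d more entries\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' Build operators for several tissues at once
#'
#' @inheritParams build_organ_operator
#' @param tissues tissue names (default all of [gvhd_target_tissues()]
#'   present in the table).
#' @return named list of `OrganOperator` objects.
#' @export
build_organ_operators <- function(pmhas, expression_records,
                                  tissues = NULL, rpkm_cutoff = 1,
                                  y_pexp = 1) {
  if (is.null(tissues)) {
    tissues <- intersect(gvhd_target_tissues(),
                         unique(expression_records$tissue))
  }
  setNames(lapply(tissues, function(ts) {
    build_organ_operator(pmhas, expression_records, ts,
                         rpkm_cutoff = rpkm_cutoff, y_pexp = y_pexp)
  }), tissues)
}
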