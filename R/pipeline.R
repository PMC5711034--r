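# End-to-end orchestration for one donor-recipient pair: variants ->
# peptides -> affinities -> organ operators -> repertoire simulation.

#' Load a synthetic (or similarly laid out) pair directory
#'
#' Expects the file set written by [generate_pair()]: donor.vcf,
#' recipient.vcf, proteome.fasta, annotation.tsv, rpkm.tsv, hla.txt and
#' optionally y_proteins.fasta.
#'
#' @param dir pair directory.
#' @return in-memory pair list (see [generate_pair()]).
#' @export
load_pair <- function(dir) {
  path <- function(f) file.path(dir, f)
  need <- c("donor.vcf", "recipient.vcf", "proteome.fasta", "annotation.tsv",
            "rpkm.tsv", "hla.txt")
  missing <- need[!file.exists(path(need))]
  if (length(missing)) {
    stopf("pair directory '%s' lacks: %s", dir, paste(missing, collapse = ", "))
  }
  yfile <- path("y_proteins.fasta")
  list(
    donor_calls = read_genotype_calls(path("donor.vcf"), "donor"),
    recipient_calls = read_genotype_calls(path("recipient.vcf"), "recipient"),
    annotation = read.delim(path("annotation.tsv"), stringsAsFactors = FALSE),
    proteome = as_protein_vector(Biostrings::readAAStringSet(path("proteome.fasta"))),
    expression = read_expression_table(path("rpkm.tsv")),
    hla = readLines(path("hla.txt")),
    y_proteins = if (file.exists(yfile)) {
      as_protein_vector(Biostrings::readAAStringSet(yfile))
    } else NULL,
    meta = list(pair_id = basename(dir))
  )
}

#' Run the full alloreactivity pipeline on one pair
#'
#' Chains [gvh_variants()], [annotate_gvh_variants()],
#' [build_peptide_library()] (plus [y_chromosome_peptides()] for
#' sex-mismatched pairs), [donor_self_filter()], [score_affinity()],
#' [filter_binders()], [build_organ_operators()] and [run_drp()].
#'
#' @param pair a pair directory path or an in-memory pair list
#'   ([generate_pair()] / [load_pair()]).
#' @param cfg a [sim_config()].
#' @param ic50_cutoff working-library binder cutoff (nM, inclusive).
#' @param rpkm_cutoff tissue-expression inclusion cutoff (inclusive).
#' @param affinity_method,affinity_table,ic50_range,affinity_seed see
#'   [score_affinity()].
#' @param tissues tissues to simulate (default: all present in the
#'   expression table among [gvhd_target_tissues()]).
#' @return list with the stage outputs (`gvh`, `annotated`, `peptides`,
#'   `pmha`, `binders`, `operators`, `simulation`) and a `summary` list
#'   (per-organ counts, total, clone/peptide tallies, strong-binder count).
#' @export
run_pair_pipeline <- function(pair, cfg = sim_config(),
                              ic50_cutoff = 500, rpkm_cutoff = 1,
                              affinity_method = c("synthetic", "table"),
                              affinity_table = NULL,
                              ic50_range = c(1, 50000), affinity_seed = 0,
                              tissues = NULL) {
  affinity_method <- match.arg(affinity_method)
  if (is.character(pair) && length(pair) == 1L) pair <- load_pair(pair)

  gvh <- gvh_variants(pair$donor_calls, pair$recipient_calls)
  ann <- annotate_gvh_variants(gvh, pair$annotation)
  pep <- build_peptide_library(ann, pair$proteome)
  if (!is.null(pair$y_proteins)) {
    pep <- rbind(pep, y_chromosome_peptides(pair$y_proteins))
  }
  cand <- donor_self_filter(pep, donor_reference_9mers(ann, pair$proteome))
  pmha <- score_affinity(cand, pair$hla, method = affinity_method,
                         affinity_table = affinity_table,
                         ic50_range = ic50_range, seed = affinity_seed)
  binders <- filter_binders(pmha, cutoff_nm = ic50_cutoff)
  operators <- build_organ_operators(binders, pair$expression,
                                     tissues = tissues,
                                     rpkm_cutoff = rpkm_cutoff)
  sim <- run_drp(operators, cfg)

  list(
    gvh = gvh, annotated = ann, peptides = pep, pmha = pmha,
    binders = binders, operators = operators, simulation = sim,
    summary = list(
      pair_id = pair$meta$pair_id,
      n_gvh_variants = nrow(gvh),
      n_nonsynonymous = sum(ann$consequence == "nonsynonymous"),
      n_candidate_peptides = nrow(cand),
      n_pmha = nrow(pmha),
      n_binders = nrow(binders),
      n_strong_binders = count_strong_binders(binders),
      organ_counts = sim$organ_counts,
      total = sim$total
    )
  )
}

#' Write pipeline outputs as deterministic text files
#'
#' One TSV per organ (clone-level window means) plus a `summary.json`.
#' Output bytes are a pure function of the pipeline result, which makes
#' whole-pipeline determinism directly checkable.
#'
#' @param result a [run_pair_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ts in names(result$simulation$organs)) {
    sim <- result$simulation$organs[[ts]]
    f <- file.path(out_dir, paste0("organ_", gsub(" ", "_", ts), ".tsv"))
    df <- sim$clone_summary
    df$mean_n <- sprintf("%.10g", df$mean_n)
    df$k_eff <- sprintf("%.10g", df$k_eff)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  s <- result$summary
  s$organ_counts <- as.list(s$organ_counts)
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(s, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, f))
}
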