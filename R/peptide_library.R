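# Candidate-peptide library: 17-mer contexts centred on each nonsynonymous
# GVH variant residue, expanded into the 9-mers that contain the variant,
# plus whole-protein 9-mer tiling of Y-chromosome proteins for
# female-donor -> male-recipient pairs.

#' Extract the (up to) 17-mer context around a variant residue
#'
#' Returns the protein subsequence from 8 residues before to 8 residues after
#' the variant position, with the variant residue substituted by the
#' alternate amino acid. The window is truncated (never padded) at protein
#' termini, so variants closer than 8 residues to a terminus yield a shorter
#' context.
#'
#' @param protein_seq protein sequence (string, single-letter amino acids).
#' @param aa_pos 1-based position of the variant residue.
#' @param alt_aa alternate amino acid (single letter).
#' @return the context string, with attribute `variant_index` giving the
#'   1-based position of the variant residue within the context.
#' @export
seventeen_mer <- function(protein_seq, aa_pos, alt_aa) {
  n <- nchar(protein_seq)
  if (aa_pos < 1L || aa_pos > n) {
    stopf("aa_pos %d outside protein (1..%d)", aa_pos, n)
  }
  from <- max(1L, aa_pos - 8L)
  to <- min(n, aa_pos + 8L)
  ctx <- substr(protein_seq, from, to)
  vi <- aa_pos - from + 1L
  substr(ctx, vi, vi) <- alt_aa
  structure(ctx, variant_index = vi)
}

#' Slide a 9-mer window across a variant context
#'
#' Enumerates every length-9 substring of `context` that contains the variant
#' residue. For a full 17-mer with the variant central this yields exactly 9
#' peptides, with the variant occupying positions 9, 8, ..., 1 of successive
#' windows.
#'
#' @param context context string (typically from [seventeen_mer()]).
#' @param variant_index 1-based position of the variant residue within
#'   `context`; defaults to the `variant_index` attribute.
#' @return a `data.frame` with columns `sequence` and `variant_offset`
#'   (position of the variant inside each 9-mer). A context shorter than 9
#'   residues yields zero rows with a warning.
#' @export
nine_mer_windows <- function(context, variant_index = attr(context, "variant_index")) {
  n <- nchar(context)
  if (is.null(variant_index)) stopf("variant_index is required")
  if (variant_index < 1L || variant_index > n) {
    stopf("variant_index %d outside context (1..%d)", variant_index, n)
  }
  if (n < 9L) {
    warnf("context shorter than 9 residues (%d); no windows generated", n)
    return(data.frame(sequence = character(0), variant_offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  starts <- seq.int(max(1L, variant_index - 8L), min(n - 8L, variant_index))
  data.frame(
    sequence = substring(context, starts, starts + 8L),
    variant_offset = as.integer(variant_index - starts + 1L),
    stringsAsFactors = FALSE
  )
}

#' Build the SNV-derived candidate 9-mer library for a pair
#'
#' Applies [seventeen_mer()] and [nine_mer_windows()] to every nonsynonymous,
#' non-stop GVH variant. Variants whose protein is missing from the proteome,
#' stop-gain/loss variants (no defined peptide context), and windows
#' containing non-standard residues are dropped and counted in the log.
#'
#' @param gvh_annotated annotated GVH variants ([annotate_gvh_variants()]).
#' @param proteome named character vector or `Biostrings::AAStringSet` of
#'   protein sequences keyed by `protein_id`.
#' @return a `data.frame` of candidate peptides: `sequence`, `gene_id`,
#'   `protein_id`, `aa_pos`, `variant_offset`, `origin = "snv"`.
#' @export
build_peptide_library <- function(gvh_annotated, proteome) {
  proteome <- as_protein_vector(proteome)
  v <- gvh_annotated[gvh_annotated$consequence == "nonsynonymous", , drop = FALSE]
  n_stop <- sum(v$stop_involved)
  v <- v[!v$stop_involved, , drop = FALSE]
  n_missing_protein <- sum(!v$protein_id %in% names(proteome))
  v <- v[v$protein_id %in% names(proteome), , drop = FALSE]

  n_truncated <- 0L
  out <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    pseq <- proteome[[v$protein_id[i]]]
    ref_at <- substr(pseq, v$aa_pos[i], v$aa_pos[i])
    if (ref_at != v$ref_aa[i]) {
      stopf("protein %s position %d has '%s' but annotation says ref_aa '%s'",
            v$protein_id[i], v$aa_pos[i], ref_at, v$ref_aa[i])
    }
    ctx <- seventeen_mer(pseq, v$aa_pos[i], v$alt_aa[i])
    if (nchar(ctx) < 17L) n_truncated <- n_truncated + 1L
    w <- suppressWarnings(nine_mer_windows(ctx))
    if (!nrow(w)) next
    out[[i]] <- data.frame(
      sequence = w$sequence,
      gene_id = v$gene_id[i],
      protein_id = v$protein_id[i],
      aa_pos = v$aa_pos[i],
      variant_offset = w$variant_offset,
      origin = "snv",
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) res <- empty_peptide_frame()
  n_nonstd <- sum(!is_standard_peptide(res$sequence))
  res <- res[is_standard_peptide(res$sequence), , drop = FALSE]
  rownames(res) <- NULL
  set_log(res, c(stop_variants_excluded = n_stop,
                 proteins_missing = n_missing_protein,
                 truncated_contexts = n_truncated,
                 nonstandard_windows_dropped = n_nonstd))
}

empty_peptide_frame <- function() {
  data.frame(sequence = character(0), gene_id = character(0),
             protein_id = character(0), aa_pos = integer(0),
             variant_offset = integer(0), origin = character(0),
             stringsAsFactors = FALSE)
}

as_protein_vector <- function(proteome) {
  if (methods::is(proteome, "XStringSet")) {
    proteome <- setNames(as.character(proteome), names(proteome))
  }
  if (is.null(names(proteome)) || anyNA(names(proteome))) {
    stopf("proteome sequences must be named by protein_id")
  }
  # FASTA headers may carry descriptions after the identifier
  names(proteome) <- sub("\\s.*$", "", names(proteome))
  proteome
}

#' Tile Y-chromosome proteins into 9-mers
#'
#' For female-donor to male-recipient pairs every Y-encoded protein is
#' entirely foreign to the donor immune system; all overlapping 9-mers
#' (stride 1) are added to the candidate library. Windows containing
#' non-standard residues are dropped and counted.
#'
#' @param y_proteins named character vector, `AAStringSet`, or FASTA path of
#'   Y-chromosome protein sequences.
#' @return candidate-peptide `data.frame` with `origin = "y_chromosome"` and
#'   `variant_offset = 0` (no polymorphic residue).
#' @export
y_chromosome_peptides <- function(y_proteins) {
  if (is.character(y_proteins) && length(y_proteins) == 1L &&
      file.exists(y_proteins)) {
    y_proteins <- Biostrings::readAAStringSet(y_proteins)
  }
  y_proteins <- as_protein_vector(y_proteins)
  out <- vector("list", length(y_proteins))
  for (i in seq_along(y_proteins)) {
    s <- y_proteins[[i]]
    n <- nchar(s)
    if (n < 9L) next
    starts <- seq_len(n - 8L)
    out[[i]] <- data.frame(
      sequence = substring(s, starts, starts + 8L),
      gene_id = names(y_proteins)[i],
      protein_id = names(y_proteins)[i],
      aa_pos = NA_integer_,
      variant_offset = 0L,
      origin = "y_chromosome",
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) res <- empty_peptide_frame()
  n_nonstd <- sum(!is_standard_peptide(res$sequence))
  res <- res[is_standard_peptide(res$sequence), , drop = FALSE]
  rownames(res) <- NULL
  set_log(res, c(nonstandard_windows_dropped = n_nonstd))
}

#' Remove candidate peptides identical to donor self peptides
#'
#' Drops every candidate whose 9-mer sequence occurs in the donor self
#' peptidome and deduplicates identical surviving sequences, keeping the
#' first record in (`gene_id`, `aa_pos`) order.
#'
#' @param candidates candidate-peptide `data.frame`.
#' @param donor_9mers character vector (or set) of donor self 9-mers.
#' @return the filtered, deduplicated candidate `data.frame`; log counters
#'   `self_peptides_removed`, `duplicate_sequences_collapsed`.
#' @export
donor_self_filter <- function(candidates, donor_9mers) {
  in_self <- candidates$sequence %in% donor_9mers
  out <- candidates[!in_self, , drop = FALSE]
  ord <- order(out$gene_id, out$aa_pos)
  out <- out[ord, , drop = FALSE]
  dup <- duplicated(out$sequence)
  res <- out[!dup, , drop = FALSE]
  rownames(res) <- NULL
  set_log(res, c(self_peptides_removed = sum(in_self),
                 duplicate_sequences_collapsed = sum(dup)))
}

#' Reference 9-mers at the GVH variant loci (donor self-peptidome proxy)
#'
#' When a donor-specific protein FASTA is unavailable the donor self
#' peptidome is approximated by the reference-protein 9-mers spanning each
#' variant locus (the unsubstituted counterparts of the candidate windows).
#' This guards against candidates that happen to equal the reference
#' sequence; it does not model the donor's own private variants.
#'
#' @inheritParams build_peptide_library
#' @return character vector of reference 9-mer sequences.
#' @export
donor_reference_9mers <- function(gvh_annotated, proteome) {
  proteome <- as_protein_vector(proteome)
  v <- gvh_annotated[gvh_annotated$consequence == "nonsynonymous" &
                       !gvh_annotated$stop_involved &
                       gvh_annotated$protein_id %in% names(proteome), ,
                     drop = FALSE]
  seqs <- character(0)
  for (i in seq_len(nrow(v))) {
    pseq <- proteome[[v$protein_id[i]]]
    ctx <- seventeen_mer(pseq, v$aa_pos[i], v$ref_aa[i])  # reference residue
    w <- suppressWarnings(nine_mer_windows(ctx))
    seqs <- c(seqs, w$sequence)
  }
  unique(seqs)
}
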