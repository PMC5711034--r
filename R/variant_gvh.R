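# Graft-versus-host-direction variant extraction: compare donor and recipient
# genotypes and keep the alleles the recipient carries but the donor does not
# (R+/D-), i.e. the alleles whose peptides are foreign to donor T cells.

#' Read per-site genotype calls from a VCF
#'
#' Parses a (single-sample) VCF into the flat genotype-call table used by
#' [gvh_variants()]. Genotypes are resolved from allele indices to allele
#' base strings; phasing is ignored (genotypes are unordered allele pairs).
#'
#' @param vcf_file path to a VCF v4.x file (plain text or bgzipped).
#' @param sample_role `"donor"` or `"recipient"`.
#' @param sample sample name to extract when the file holds several samples;
#'   defaults to the first sample.
#' @return a `data.frame` with columns `site_id`, `chrom`, `pos`, `ref`,
#'   `allele1`, `allele2`, `sample_role`. Rows with missing genotypes
#'   (`./.`) are dropped and counted in the log (see [allosim_log()]).
#' @export
read_genotype_calls <- function(vcf_file, sample_role = c("donor", "recipient"),
                                sample = NULL) {
  sample_role <- match.arg(sample_role)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(vcf_file))
  gt_mat <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt_mat)) stopf("VCF '%s' has no GT field", vcf_file)
  if (is.null(sample)) sample <- colnames(gt_mat)[1]
  if (!sample %in% colnames(gt_mat)) {
    stopf("sample '%s' not found in VCF '%s'", sample, vcf_file)
  }
  gt <- gt_mat[, sample]
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  alt_list <- lapply(seq_along(alts), function(i) as.character(alts[[i]]))
  site_id <- names(rr)
  if (is.null(site_id) || anyNA(site_id) || any(site_id == ".")) {
    site_id <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                      GenomicRanges::start(rr), "_", ref)
  }

  missing_gt <- grepl("\\.", gt)
  calls <- data.frame(
    site_id = site_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref,
    gt = gt,
    stringsAsFactors = FALSE
  )
  calls <- calls[!missing_gt, , drop = FALSE]
  alt_list <- alt_list[!missing_gt]

  al <- resolve_genotypes(calls$gt, calls$ref, alt_list, calls$site_id)
  out <- data.frame(
    site_id = calls$site_id,
    chrom = calls$chrom,
    pos = calls$pos,
    ref = calls$ref,
    allele1 = al$allele1,
    allele2 = al$allele2,
    sample_role = sample_role,
    stringsAsFactors = FALSE
  )
  set_log(out, c(missing_genotype_sites = sum(missing_gt)))
}

# Map GT strings ("0/1", "1|2") to allele base strings. Hard error on
# malformed genotypes or allele indices outside the ALT list.
resolve_genotypes <- function(gt, ref, alt_list, site_id) {
  ok <- grepl("^[0-9]+[/|][0-9]+$", gt)
  if (any(!ok)) {
    stopf("malformed genotype '%s' at site %s", gt[!ok][1], site_id[!ok][1])
  }
  parts <- strsplit(gt, "[/|]")
  i1 <- as.integer(vapply(parts, `[`, "", 1L))
  i2 <- as.integer(vapply(parts, `[`, "", 2L))
  pick <- function(idx, i) {
    alleles <- c(ref[i], alt_list[[i]])
    if (idx + 1L > length(alleles)) {
      stopf("genotype index %d exceeds allele count at site %s", idx, site_id[i])
    }
    alleles[idx + 1L]
  }
  list(
    allele1 = vapply(seq_along(i1), function(i) pick(i1[i], i), ""),
    allele2 = vapply(seq_along(i2), function(i) pick(i2[i], i), "")
  )
}

#' Extract variants in the graft-versus-host direction
#'
#' For every site genotyped in the recipient, returns the alleles present in
#' the recipient genotype and absent from the donor genotype (R+/D-). Sites
#' present in the recipient calls but absent from the donor calls are treated
#' as donor homozygous reference (the single-sample VCF convention for
#' unreported sites); such sites are counted in the log. Only SNP alleles are
#' processed; sites involving indel/MNP alleles are skipped and counted.
#' Multi-allelic sites yield one row per recipient-only alt allele.
#'
#' @param donor_calls,recipient_calls genotype-call tables as returned by
#'   [read_genotype_calls()].
#' @return a `data.frame` with columns `site_id`, `chrom`, `pos`,
#'   `ref_allele`, `gvh_allele`, ordered by (`chrom`, `pos`, `gvh_allele`).
#'   Log counters: `donor_missing_sites`, `skipped_non_snp_sites`.
#' @export
gvh_variants <- function(donor_calls, recipient_calls) {
  need <- c("site_id", "chrom", "pos", "ref", "allele1", "allele2")
  for (df in list(donor_calls, recipient_calls)) {
    if (!all(need %in% names(df))) {
      stopf("calls must have columns: %s", paste(need, collapse = ", "))
    }
  }
  if (anyDuplicated(recipient_calls$site_id)) {
    stopf("duplicate site_id in recipient calls: %s",
          recipient_calls$site_id[duplicated(recipient_calls$site_id)][1])
  }

  dmap <- match(recipient_calls$site_id, donor_calls$site_id)
  shared <- !is.na(dmap)
  bad_ref <- shared &
    donor_calls$ref[dmap] != recipient_calls$ref
  if (any(bad_ref)) {
    stopf("inconsistent REF alleles at site %s ('%s' vs '%s')",
          recipient_calls$site_id[bad_ref][1],
          donor_calls$ref[dmap[bad_ref]][1],
          recipient_calls$ref[bad_ref][1])
  }

  n <- nrow(recipient_calls)
  skipped_non_snp <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- c(recipient_calls$allele1[i], recipient_calls$allele2[i])
    don <- if (shared[i]) {
      c(donor_calls$allele1[dmap[i]], donor_calls$allele2[dmap[i]])
    } else {
      rep(recipient_calls$ref[i], 2L)  # donor hom-ref by convention
    }
    gvh <- setdiff(rec, don)
    if (!length(gvh)) next
    snp_ok <- nchar(recipient_calls$ref[i]) == 1L &&
      recipient_calls$ref[i] %in% DNA_BASES &&
      all(nchar(gvh) == 1L & gvh %in% DNA_BASES)
    if (!snp_ok) {
      skipped_non_snp <- skipped_non_snp + 1L
      next
    }
    rows[[i]] <- data.frame(
      site_id = recipient_calls$site_id[i],
      chrom = recipient_calls$chrom[i],
      pos = recipient_calls$pos[i],
      ref_allele = recipient_calls$ref[i],
      gvh_allele = gvh,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(site_id = character(0), chrom = character(0),
                      pos = integer(0), ref_allele = character(0),
                      gvh_allele = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$pos, out$gvh_allele), , drop = FALSE]
  rownames(out) <- NULL
  set_log(out, c(donor_missing_sites = sum(!shared),
                 skipped_non_snp_sites = skipped_non_snp))
}

#' Classify a coding variant as synonymous or nonsynonymous
#'
#' Minimal codon-table annotator used for synthetic fixtures (real data is
#' expected to arrive with a precomputed annotation table). Translates the
#' codon containing the variant with the reference and the alternate base and
#' compares the encoded amino acids under the standard genetic code.
#'
#' @param cds coding sequence (string, length divisible by 3, 5'->3',
#'   in-frame).
#' @param cds_pos 1-based position of the variant within the CDS.
#' @param ref_base,alt_base single reference/alternate bases (A/C/G/T).
#' @return a list with `aa_pos` (1-based protein coordinate), `ref_aa`,
#'   `alt_aa` (single-letter, `*` for stop), `consequence`
#'   (`"synonymous"`/`"nonsynonymous"`), and `stop_involved` (TRUE when a
#'   stop codon is gained or lost; such variants are nonsynonymous but are
#'   excluded from peptide generation downstream).
#' @export
annotate_consequence <- function(cds, cds_pos, ref_base, alt_base) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stopf("CDS length (%d) not divisible by 3", n)
  if (cds_pos < 1L || cds_pos > n) stopf("position %d outside CDS (1..%d)",
                                         cds_pos, n)
  if (!ref_base %in% DNA_BASES || !alt_base %in% DNA_BASES) {
    stopf("ambiguous or non-ACGT base in variant ('%s'>'%s')",
          ref_base, alt_base)
  }
  if (substr(cds, cds_pos, cds_pos) != ref_base) {
    stopf("reference base mismatch at CDS position %d: CDS has '%s', variant says '%s'",
          cds_pos, substr(cds, cds_pos, cds_pos), ref_base)
  }
  aa_pos <- (cds_pos - 1L) %/% 3L + 1L
  codon_start <- (aa_pos - 1L) * 3L + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cds_pos - codon_start + 1L,
         cds_pos - codon_start + 1L) <- alt_base
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[[ref_codon]])
  alt_aa <- unname(code[[alt_codon]])
  list(
    aa_pos = aa_pos,
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    consequence = if (identical(ref_aa, alt_aa)) "synonymous" else "nonsynonymous",
    stop_involved = (ref_aa == "*") != (alt_aa == "*")
  )
}

#' Join protein-level annotation onto GVH variants
#'
#' @param gvh output of [gvh_variants()].
#' @param annotation a `data.frame` (or TSV path) with columns `site_id`,
#'   `gene_id`, `protein_id`, `aa_pos`, `ref_aa`, `alt_aa` (one row per
#'   site/alt allele; an optional `alt` column disambiguates multi-allelic
#'   sites).
#' @return `gvh` with annotation columns plus `consequence` appended;
#'   unannotated variants are dropped and counted in the log.
#' @export
annotate_gvh_variants <- function(gvh, annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- read.delim(annotation, stringsAsFactors = FALSE)
  }
  need <- c("site_id", "gene_id", "protein_id", "aa_pos", "ref_aa", "alt_aa")
  if (!all(need %in% names(annotation))) {
    stopf("annotation must have columns: %s", paste(need, collapse = ", "))
  }
  key_gvh <- gvh$site_id
  key_ann <- annotation$site_id
  if ("alt" %in% names(annotation)) {
    key_gvh <- paste(gvh$site_id, gvh$gvh_allele)
    key_ann <- paste(annotation$site_id, annotation$alt)
  }
  m <- match(key_gvh, key_ann)
  dropped <- sum(is.na(m))
  keep <- !is.na(m)
  out <- cbind(
    gvh[keep, , drop = FALSE],
    annotation[m[keep], c("gene_id", "protein_id", "aa_pos", "ref_aa", "alt_aa"),
               drop = FALSE]
  )
  out$consequence <- ifelse(out$ref_aa == out$alt_aa,
                            "synonymous", "nonsynonymous")
  out$stop_involved <- (out$ref_aa == "*") != (out$alt_aa == "*")
  rownames(out) <- NULL
  set_log(out, c(unannotated_variants = dropped))
}
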