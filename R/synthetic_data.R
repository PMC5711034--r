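# Synthetic donor-recipient pairs: a toy proteome with a consistent CDS, a
# planted set of GVH-direction variants, VCFs for both samples, an
# annotation table, a gene-by-tissue RPKM table and an HLA list -- enough to
# run every pipeline stage without any external data. Deterministic per
# (spec, pair_index, seed).

#' Default toy HLA class I allele set
#' @return six class I allele names (A, B, C pairs).
#' @export
default_hla_alleles <- function() {
  c("HLA-A01:01", "HLA-A02:01", "HLA-B07:02",
    "HLA-B08:01", "HLA-C04:01", "HLA-C07:02")
}

#' Cohort specification for the synthetic-data generator
#'
#' Defaults emulate the scale of HLA-matched transplant cohorts: matched
#' related (MRD-like) pairs carry on average 2463 +/- 603 GVH-direction
#' nonsynonymous SNPs and matched unrelated (MUD-like) pairs 4287 +/- 1154;
#' 17/77 of pairs are female-donor to male-recipient; synthetic IC50s are
#' log-uniform on 1-50000 nM and per-tissue RPKM log-normal (median 5,
#' sigma = 0.8 log10 units). `scale` shrinks the variant counts (and the toy
#' proteome) proportionally for desk-scale runs while preserving the
#' MRD/MUD ratio.
#'
#' @param n_pairs number of donor-recipient pairs.
#' @param mud_fraction fraction of MUD-like pairs.
#' @param mean_nssnp,sd_nssnp named vectors (`mrd`, `mud`) of the per-type
#'   nonsynonymous GVH SNP count distribution.
#' @param shared_fraction,donor_only_fraction,syn_ratio realism knobs:
#'   variants shared by both samples and donor-only variants (fractions of
#'   the nsSNP count, both excluded by the GVH comparison) and synonymous
#'   recipient-only variants (ratio to nsSNPs, excluded by the consequence
#'   filter).
#' @param ic50_log_range synthetic IC50 range (nM, log-uniform).
#' @param rpkm_meanlog,rpkm_sdlog log-normal RPKM parameters (natural log).
#' @param female_to_male_fraction fraction of F->M (sex-mismatched) pairs.
#' @param n_genes,protein_length toy proteome size and protein length range.
#' @param hla_alleles HLA class I alleles shared by all pairs.
#' @param n_y_proteins toy Y-chromosome proteins for F->M pairs.
#' @param scale multiplier (0 < scale <= 1) applied to `mean_nssnp`,
#'   `sd_nssnp` and `n_genes`.
#' @param seed master seed; each pair derives its own sub-seed.
#' @return a `CohortSpec` (list).
#' @export
cohort_spec <- function(n_pairs = 10, mud_fraction = 0.5,
                        mean_nssnp = c(mrd = 2463, mud = 4287),
                        sd_nssnp = c(mrd = 603, mud = 1154),
                        shared_fraction = 0.3, donor_only_fraction = 0.3,
                        syn_ratio = 1.1,
                        ic50_log_range = c(1, 50000),
                        rpkm_meanlog = log(5), rpkm_sdlog = 0.8 * log(10),
                        female_to_male_fraction = 17 / 77,
                        n_genes = 200, protein_length = c(100, 500),
                        hla_alleles = default_hla_alleles(),
                        n_y_proteins = 3, scale = 1, seed = 1) {
  if (n_pairs < 0) stopf("n_pairs must be >= 0")
  if (mud_fraction < 0 || mud_fraction > 1) stopf("mud_fraction must be in [0,1]")
  if (scale <= 0 || scale > 1) stopf("scale must be in (0, 1]")
  if (any(mean_nssnp <= 0) || any(sd_nssnp < 0)) {
    stopf("nsSNP count parameters must be positive")
  }
  structure(list(
    n_pairs = as.integer(n_pairs), mud_fraction = mud_fraction,
    mean_nssnp = mean_nssnp * scale, sd_nssnp = sd_nssnp * scale,
    shared_fraction = shared_fraction,
    donor_only_fraction = donor_only_fraction, syn_ratio = syn_ratio,
    ic50_log_range = ic50_log_range,
    rpkm_meanlog = rpkm_meanlog, rpkm_sdlog = rpkm_sdlog,
    female_to_male_fraction = female_to_male_fraction,
    n_genes = max(10L, as.integer(round(n_genes * scale))),
    protein_length = as.integer(protein_length),
    hla_alleles = hla_alleles, n_y_proteins = as.integer(n_y_proteins),
    seed = as.integer(seed)
  ), class = "CohortSpec")
}

pair_seed <- function(spec, pair_index) {
  as.integer((as.numeric(spec$seed) * 1000003 + pair_index * 7919) %% 2147483629)
}

# Inverse genetic code: codons per amino acid (standard table, no stops).
codons_for_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# Random toy proteome: proteins of random standard residues plus a CDS that
# translates to them (codon chosen uniformly among synonyms).
random_proteome <- function(n_genes, length_range) {
  lens <- sample(seq.int(length_range[1], length_range[2]), n_genes,
                 replace = TRUE)
  by_aa <- codons_for_aa()
  by_aa <- by_aa[names(by_aa) != "*"]
  proteins <- character(n_genes)
  cds_codons <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    aa <- sample(AA_STANDARD, lens[g], replace = TRUE)
    proteins[g] <- paste(aa, collapse = "")
    cds_codons[[g]] <- vapply(aa, function(a) {
      syn <- by_aa[[a]]
      syn[sample.int(length(syn), 1L)]
    }, "", USE.NAMES = FALSE)
  }
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  protein_ids <- sprintf("PROT%04d", seq_len(n_genes))
  list(gene_id = gene_ids, protein_id = protein_ids,
       protein = setNames(proteins, protein_ids),
       cds_codons = setNames(cds_codons, gene_ids),
       length = lens,
       # genomic layout: all genes on chromosome 1, 100 bp intergenic gaps
       gene_start = cumsum(c(1L, 3L * lens[-n_genes] + 100L)))
}

# Pick a single-base substitution of `codon` with the requested consequence
# (never creating/destroying a stop). Returns NULL when impossible.
pick_substitution <- function(codon, consequence) {
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[[codon]])
  cands <- list()
  for (bp in 1:3) {
    ref_base <- substr(codon, bp, bp)
    for (alt_base in setdiff(DNA_BASES, ref_base)) {
      alt_codon <- codon
      substr(alt_codon, bp, bp) <- alt_base
      alt_aa <- unname(gc[[alt_codon]])
      if (alt_aa == "*") next
      type <- if (alt_aa == ref_aa) "synonymous" else "nonsynonymous"
      if (type == consequence) {
        cands[[length(cands) + 1L]] <- list(base_pos = bp, ref_base = ref_base,
                                            alt_base = alt_base,
                                            ref_aa = ref_aa, alt_aa = alt_aa)
      }
    }
  }
  if (!length(cands)) return(NULL)
  cands[[sample.int(length(cands), 1L)]]
}

write_minimal_vcf <- function(path, sample_name, chrom, pos, id, ref, alt, gt) {
  o <- order(pos)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=allosim-synthetic",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"),
    paste(chrom[o], pos[o], id[o], ref[o], alt[o], ".", "PASS", ".", "GT",
          gt[o], sep = "\t")
  )
  writeLines(lines, path)
}

write_fasta <- function(path, seqs) {
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
}

#' Generate one synthetic donor-recipient pair
#'
#' Builds a toy proteome and plants four variant classes: GVH-direction
#' nonsynonymous SNPs (recipient 0/1, absent from the donor VCF -- the
#' signal), synonymous recipient-only SNPs, variants shared by both samples,
#' and donor-only variants (all noise the pipeline must reject). Every
#' variant maps consistently into the proteome/CDS; output is deterministic
#' per (`spec`, `pair_index`).
#'
#' @param spec a [cohort_spec()].
#' @param pair_index 1-based pair index (isolates the per-pair RNG stream).
#' @param dir output directory; when non-NULL the standard file set
#'   (donor.vcf, recipient.vcf, proteome.fasta, cds.fasta, annotation.tsv,
#'   rpkm.tsv, hla.txt, y_proteins.fasta for F->M pairs) is written there.
#' @param donor_type `"mrd"`, `"mud"`, or NULL to draw from
#'   `spec$mud_fraction`.
#' @return (invisibly when `dir` is set) a list with the in-memory pair:
#'   `donor_calls`/`recipient_calls` (genotype-call tables), `annotation`,
#'   `proteome`, `cds`, `expression` (long), `hla`, `y_proteins` (or NULL),
#'   and `meta` (pair_id, donor_type, sex_mismatch, n_nssnp, seed, files).
#' @export
generate_pair <- function(spec, pair_index, dir = NULL, donor_type = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  seed <- pair_seed(spec, pair_index)
  set.seed(seed)

  if (is.null(donor_type)) {
    donor_type <- if (runif(1) < spec$mud_fraction) "mud" else "mrd"
  }
  donor_type <- match.arg(donor_type, c("mrd", "mud"))
  sex_mismatch <- runif(1) < spec$female_to_male_fraction
  n_nssnp <- max(0L, as.integer(round(rnorm(1, spec$mean_nssnp[[donor_type]],
                                            spec$sd_nssnp[[donor_type]]))))
  n_syn <- as.integer(round(n_nssnp * spec$syn_ratio))
  n_shared <- as.integer(round(n_nssnp * spec$shared_fraction))
  n_donor_only <- as.integer(round(n_nssnp * spec$donor_only_fraction))

  prot <- random_proteome(spec$n_genes, spec$protein_length)
  slots_gene <- rep(seq_len(spec$n_genes), prot$length)
  slots_pos <- unlist(lapply(prot$length, seq_len), use.names = FALSE)
  n_slots <- length(slots_gene)
  want <- n_nssnp + n_syn + n_shared + n_donor_only
  if (want > n_slots) {
    stopf("requested %d variant sites but the toy proteome has only %d codons; increase n_genes",
          want, n_slots)
  }
  pool <- sample.int(n_slots)  # shuffled candidate codon slots

  categories <- c(rep("nssnp", n_nssnp), rep("syn", n_syn),
                  rep("shared", n_shared), rep("donor_only", n_donor_only))
  rows <- vector("list", length(categories))
  filled <- 0L
  pi <- 1L
  while (filled < length(categories) && pi <= n_slots) {
    slot <- pool[pi]; pi <- pi + 1L
    g <- slots_gene[slot]; p <- slots_pos[slot]
    cat_i <- categories[filled + 1L]
    consequence <- if (cat_i == "syn") "synonymous" else "nonsynonymous"
    sub <- pick_substitution(prot$cds_codons[[g]][p], consequence)
    if (is.null(sub)) next
    pos <- prot$gene_start[g] + (p - 1L) * 3L + (sub$base_pos - 1L)
    rows[[filled + 1L]] <- data.frame(
      category = cat_i, gene = g, aa_pos = p, chrom = "1", pos = pos,
      site_id = sprintf("var%09d", pos),
      ref = sub$ref_base, alt = sub$alt_base,
      ref_aa = sub$ref_aa, alt_aa = sub$alt_aa,
      stringsAsFactors = FALSE
    )
    filled <- filled + 1L
  }
  if (filled < length(categories)) {
    stopf("could not place all %d variants in the toy proteome", length(categories))
  }
  vars <- do.call(rbind, rows)

  rec <- vars[vars$category %in% c("nssnp", "syn", "shared"), , drop = FALSE]
  don <- vars[vars$category %in% c("shared", "donor_only"), , drop = FALSE]

  annotation <- data.frame(
    site_id = vars$site_id,
    gene_id = prot$gene_id[vars$gene],
    protein_id = prot$protein_id[vars$gene],
    aa_pos = vars$aa_pos,
    ref_aa = vars$ref_aa,
    alt_aa = vars$alt_aa,
    alt = vars$alt,
    stringsAsFactors = FALSE
  )

  tissues <- gvhd_target_tissues()
  rpkm_wide <- data.frame(gene_id = prot$gene_id, stringsAsFactors = FALSE)
  for (ts in tissues) {
    rpkm_wide[[gsub(" ", "_", ts)]] <- round(
      rlnorm(spec$n_genes, spec$rpkm_meanlog, spec$rpkm_sdlog), 4)
  }

  y_proteins <- NULL
  if (sex_mismatch && spec$n_y_proteins > 0) {
    y_len <- sample(100:300, spec$n_y_proteins, replace = TRUE)
    y_proteins <- setNames(
      vapply(y_len, function(L) paste(sample(AA_STANDARD, L, replace = TRUE),
                                      collapse = ""), ""),
      sprintf("YPROT%02d", seq_len(spec$n_y_proteins)))
  }

  mk_calls <- function(v, role) {
    data.frame(site_id = v$site_id, chrom = v$chrom, pos = v$pos,
               ref = v$ref, allele1 = v$ref, allele2 = v$alt,
               sample_role = role, stringsAsFactors = FALSE)[order(v$pos), ]
  }
  donor_calls <- mk_calls(don, "donor")
  recipient_calls <- mk_calls(rec, "recipient")
  rownames(donor_calls) <- rownames(recipient_calls) <- NULL

  pair_id <- sprintf("pair%04d", pair_index)
  files <- NULL
  if (!is.null(dir)) {
    pd <- file.path(dir, pair_id)
    dir.create(pd, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      donor_vcf = file.path(pd, "donor.vcf"),
      recipient_vcf = file.path(pd, "recipient.vcf"),
      proteome = file.path(pd, "proteome.fasta"),
      cds = file.path(pd, "cds.fasta"),
      annotation = file.path(pd, "annotation.tsv"),
      rpkm = file.path(pd, "rpkm.tsv"),
      hla = file.path(pd, "hla.txt")
    )
    write_minimal_vcf(files$donor_vcf, "DONOR", don$chrom, don$pos,
                      don$site_id, don$ref, don$alt, rep("0/1", nrow(don)))
    write_minimal_vcf(files$recipient_vcf, "RECIPIENT", rec$chrom, rec$pos,
                      rec$site_id, rec$ref, rec$alt, rep("0/1", nrow(rec)))
    write_fasta(files$proteome, prot$protein)
    cds <- setNames(vapply(prot$cds_codons, paste, "", collapse = ""),
                    prot$gene_id)
    write_fasta(files$cds, cds)
    write.table(annotation, files$annotation, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(rpkm_wide, files$rpkm, sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(spec$hla_alleles, files$hla)
    if (!is.null(y_proteins)) {
      files$y_proteins <- file.path(pd, "y_proteins.fasta")
      write_fasta(files$y_proteins, y_proteins)
    }
  }

  res <- list(
    donor_calls = donor_calls,
    recipient_calls = recipient_calls,
    annotation = annotation,
    proteome = prot$protein,
    cds = setNames(vapply(prot$cds_codons, paste, "", collapse = ""),
                   prot$gene_id),
    gene_map = data.frame(gene_id = prot$gene_id,
                          protein_id = prot$protein_id,
                          stringsAsFactors = FALSE),
    expression = read_expression_table(rpkm_wide),
    hla = spec$hla_alleles,
    y_proteins = y_proteins,
    meta = list(pair_id = pair_id, donor_type = donor_type,
                sex_mismatch = sex_mismatch, n_nssnp = n_nssnp,
                seed = seed, files = files)
  )
  if (is.null(dir)) res else invisible(res)
}

#' Generate a synthetic cohort
#'
#' Donor types are assigned deterministically (the first
#' `round(n_pairs * mud_fraction)` pairs are MUD-like) so cohort-level
#' contrasts have exact group sizes.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory; when non-NULL each pair's file set is
#'   written under `dir/pairNNNN/` and a `manifest.tsv` at `dir`.
#' @return list with `pairs` (list of pair objects) and `manifest`
#'   (`data.frame`: pair_id, donor_type, sex_mismatch, n_nssnp, seed).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  n_mud <- as.integer(round(spec$n_pairs * spec$mud_fraction))
  types <- c(rep("mud", n_mud), rep("mrd", spec$n_pairs - n_mud))
  pairs <- vector("list", spec$n_pairs)
  for (i in seq_len(spec$n_pairs)) {
    pairs[[i]] <- generate_pair(spec, i, dir = dir, donor_type = types[i])
  }
  manifest <- if (spec$n_pairs == 0L) {
    data.frame(pair_id = character(0), donor_type = character(0),
               sex_mismatch = logical(0), n_nssnp = integer(0),
               seed = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(pairs, function(p) {
      data.frame(pair_id = p$meta$pair_id, donor_type = p$meta$donor_type,
                 sex_mismatch = p$meta$sex_mismatch,
                 n_nssnp = p$meta$n_nssnp, seed = p$meta$seed,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(pairs = pairs, manifest = manifest)
}
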