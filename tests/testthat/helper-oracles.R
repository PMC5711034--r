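# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: scalar loops, explicit matrices, exhaustive
# enumeration.

# Per-site GVH set difference: alleles in the recipient genotype that the
# donor genotype lacks.
oracle_gvh_alleles <- function(donor_alleles, recipient_alleles) {
  setdiff(unique(recipient_alleles), unique(donor_alleles))
}

# Scalar spreadsheet-style evaluation of the competition-modified logistic
# recurrence for a handful of clones. Returns a clones x iterations matrix.
oracle_clone_matrix <- function(ic50, pexp, k, n0, r, iters,
                                competition = TRUE) {
  m <- length(ic50)
  N <- matrix(NA_real_, m, iters + 1L)
  N[, 1] <- n0
  for (t in seq_len(iters)) {
    for (x in seq_len(m)) {
      keff <- (pexp[x] * k)^(1 / ic50[x])
      af <- 1 / ic50[x]
      s <- 0
      if (competition) {
        for (i in seq_len(m)) {
          s <- s + N[i, t] * (ic50[x] / ic50[i])
        }
      } else {
        s <- N[x, t]
      }
      val <- keff * n0 / ((keff - s) * exp(-r * t * af) + 1)
      N[x, t + 1L] <- max(0, val)
    }
  }
  N[, -1, drop = FALSE]
}

# Exhaustive multiset enumeration: all non-decreasing k-tuples over 1..n,
# with items 1..n_allo flagged alloreactive. Returns the fraction of
# multisets containing no alloreactive item.
oracle_presentation_probability <- function(n_total, n_allo, k_slots) {
  tuples <- as.matrix(do.call(expand.grid, rep(list(seq_len(n_total)), k_slots)))
  keep <- apply(tuples, 1, function(x) all(diff(x) >= 0))  # canonical multisets
  tuples <- tuples[keep, , drop = FALSE]
  favorable <- apply(tuples, 1, function(x) all(x > n_allo))
  list(total = nrow(tuples), favorable = sum(favorable),
       p = sum(favorable) / nrow(tuples))
}

# All length-9 substrings of a context that cover a given position.
oracle_covering_9mers <- function(context, pos) {
  n <- nchar(context)
  out <- character(0)
  if (n >= 9) {
    for (s in seq_len(n - 8L)) {
      if (s <= pos && pos <= s + 8L) out <- c(out, substr(context, s, s + 8L))
    }
  }
  out
}

# A small genotype-call table builder for variant tests.
make_calls <- function(site_id, ref, a1, a2, role = "donor",
                       chrom = "1", pos = seq_along(site_id) * 100L) {
  data.frame(site_id = site_id, chrom = chrom, pos = pos, ref = ref,
             allele1 = a1, allele2 = a2, sample_role = role,
             stringsAsFactors = FALSE)
}

# Tiny operator builder for simulator tests.
make_operator <- function(ic50, pexp = rep(1, length(ic50)), tissue = "colon") {
  op <- data.frame(
    sequence = sprintf("PEPTIDE%02d", seq_along(ic50)),
    hla_allele = rep("HLA-A01:01", length(ic50)),
    gene_id = sprintf("G%02d", seq_along(ic50)),
    ic50_nm = ic50, affinity = 1 / ic50, pexp = pexp,
    stringsAsFactors = FALSE
  )
  structure(op, tissue = tissue, rpkm_cutoff = 1,
            class = c("OrganOperator", class(op)))
}

# Shared tiny cohort spec for fast synthetic-data tests.
tiny_spec <- function(...) {
  cohort_spec(n_pairs = 2, mean_nssnp = c(mrd = 10, mud = 18),
              sd_nssnp = c(mrd = 0, mud = 0), n_genes = 12,
              protein_length = c(60, 120), seed = 99, ...)
}
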