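# GVH-direction genotype comparison.

test_that("recipient-only alt alleles are extracted, identical genotypes are not", {
  donor <- make_calls("s1", "A", "A", "A")
  recipient <- make_calls("s1", "A", "A", "G", role = "recipient")
  out <- gvh_variants(donor, recipient)
  expect_equal(nrow(out), 1L)
  expect_equal(out$gvh_allele, "G")
  expect_equal(out$ref_allele, "A")

  # identical het genotypes at every site -> nothing in GVH direction
  donor2 <- make_calls(c("s1", "s2"), c("A", "C"), c("A", "C"), c("G", "T"))
  recipient2 <- make_calls(c("s1", "s2"), c("A", "C"), c("A", "C"),
                           c("G", "T"), role = "recipient")
  expect_equal(nrow(gvh_variants(donor2, recipient2)), 0L)
})

test_that("all 9 diploid genotype combinations match the set-difference oracle", {
  gts <- list(c("A", "A"), c("A", "G"), c("G", "G"))
  for (d in gts) {
    for (r in gts) {
      donor <- make_calls("s1", "A", d[1], d[2])
      recipient <- make_calls("s1", "A", r[1], r[2], role = "recipient")
      out <- gvh_variants(donor, recipient)
      expect_setequal(out$gvh_allele, oracle_gvh_alleles(d, r))
    }
  }
})

test_that("randomized paired genotypes match the per-site oracle (property)", {
  set.seed(421)
  for (rep in 1:5) {
    n <- 60
    ids <- sprintf("s%03d", 1:n)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    draw <- function() {
      a1 <- ifelse(runif(n) < 0.5, ref, sample(c("A", "C", "G", "T"), n, TRUE))
      a2 <- ifelse(runif(n) < 0.5, ref, sample(c("A", "C", "G", "T"), n, TRUE))
      list(a1 = a1, a2 = a2)
    }
    d <- draw(); r <- draw()
    donor <- make_calls(ids, ref, d$a1, d$a2, pos = 1:n * 10L)
    recipient <- make_calls(ids, ref, r$a1, r$a2, role = "recipient",
                            pos = 1:n * 10L)
    out <- gvh_variants(donor, recipient)
    for (i in 1:n) {
      expect_setequal(out$gvh_allele[out$site_id == ids[i]],
                      oracle_gvh_alleles(c(d$a1[i], d$a2[i]),
                                         c(r$a1[i], r$a2[i])))
    }
    # self-comparison is always empty
    expect_equal(nrow(gvh_variants(donor, donor)), 0L)
    # allele-level anti-symmetry: no allele is GVH in both directions at a site
    rev <- gvh_variants(recipient, donor)
    both <- merge(out, rev, by = c("site_id", "gvh_allele"))
    expect_equal(nrow(both), 0L)
  }
})

test_that("sites missing from the donor are treated as hom-ref and counted", {
  donor <- make_calls("s1", "A", "A", "G")
  recipient <- make_calls(c("s1", "s2"), c("A", "C"), c("A", "C"),
                          c("G", "T"), role = "recipient",
                          pos = c(100L, 200L))
  out <- gvh_variants(donor, recipient)
  # s1: recipient {A,G} vs donor {A,G} -> none; s2: donor assumed C/C -> T
  expect_equal(out$site_id, "s2")
  expect_equal(out$gvh_allele, "T")
  expect_equal(unname(allosim_log(out)["donor_missing_sites"]), 1)
})

test_that("non-SNP alleles are skipped with a count; errors are hard", {
  donor <- make_calls(c("s1", "s2"), c("A", "AT"), c("A", "AT"), c("A", "AT"))
  recipient <- make_calls(c("s1", "s2"), c("A", "AT"), c("G", "A"),
                          c("G", "A"), role = "recipient")
  out <- gvh_variants(donor, recipient)
  expect_equal(out$site_id, "s1")
  expect_equal(unname(allosim_log(out)["skipped_non_snp_sites"]), 1)

  # inconsistent REF at a shared site names the site
  donor_bad <- make_calls("s1", "C", "C", "C")
  expect_error(gvh_variants(donor_bad, make_calls("s1", "A", "A", "G",
                                                  role = "recipient")),
               "s1")
})

test_that("output is ordered by chromosome and position", {
  recipient <- make_calls(c("x", "y", "z"), c("A", "A", "A"),
                          c("G", "G", "G"), c("G", "G", "G"),
                          role = "recipient",
                          chrom = c("2", "1", "1"), pos = c(50L, 900L, 10L))
  donor <- make_calls("none", "A", "A", "A")
  out <- gvh_variants(donor, recipient)
  expect_equal(out$site_id, c("z", "y", "x"))
})

test_that("annotate_consequence translates ref and alt codons correctly", {
  # GCT -> GGT at CDS position 4: Ala -> Gly, protein position 2
  r <- annotate_consequence("ATGGCT", 4L, "G", "G")  # ref base check first
  expect_error(annotate_consequence("ATGGCT", 4L, "A", "G"),
               "reference base mismatch")
  r <- annotate_consequence("ATGGCT", 5L, "C", "G")
  expect_equal(r[c("aa_pos", "ref_aa", "alt_aa", "consequence")],
               list(aa_pos = 2L, ref_aa = "A", alt_aa = "G",
                    consequence = "nonsynonymous"))

  # CTA -> CTG at CDS position 6: Leu -> Leu, synonymous
  r <- annotate_consequence("ATGCTA", 6L, "A", "G")
  expect_equal(r$consequence, "synonymous")
  expect_equal(r$ref_aa, "L")

  # alt equal to ref codon -> synonymous identity
  r <- annotate_consequence("ATGCTA", 6L, "A", "A")
  expect_equal(r$consequence, "synonymous")
  expect_equal(r$ref_aa, r$alt_aa)

  # stop gain is nonsynonymous and flagged
  r <- annotate_consequence("ATGTGC", 6L, "C", "A")  # TGC -> TGA
  expect_true(r$stop_involved)
  expect_equal(r$consequence, "nonsynonymous")

  expect_error(annotate_consequence("ATGGCT", 7L, "A", "G"), "outside CDS")
  expect_error(annotate_consequence("ATGGC", 2L, "T", "G"), "divisible by 3")
  expect_error(annotate_consequence("ATGGCT", 4L, "N", "G"), "base")
})

test_that("annotation join fills protein context and drops unannotated sites", {
  donor <- make_calls("none", "A", "A", "A")
  recipient <- make_calls(c("s1", "s2"), c("A", "C"), c("G", "T"),
                          c("G", "T"), role = "recipient")
  gvh <- gvh_variants(donor, recipient)
  ann <- data.frame(site_id = "s1", gene_id = "G1", protein_id = "P1",
                    aa_pos = 5L, ref_aa = "K", alt_aa = "E",
                    stringsAsFactors = FALSE)
  out <- annotate_gvh_variants(gvh, ann)
  expect_equal(nrow(out), 1L)
  expect_equal(out$consequence, "nonsynonymous")
  expect_equal(unname(allosim_log(out)["unannotated_variants"]), 1)
})
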