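# 17-mer contexts, 9-mer windowing, Y tiling, donor-self filtering.

test_that("seventeen_mer slices and substitutes correctly", {
  prot <- "ACDEFGHIKLMNPQRSTVWY"  # 20 aa
  ctx <- seventeen_mer(prot, 9L, "X")
  expect_equal(as.character(ctx), "ACDEFGHIXLMNPQRST")
  expect_equal(attr(ctx, "variant_index"), 9L)

  ctx <- seventeen_mer(prot, 3L, "X")
  expect_equal(as.character(ctx), "ACXEFGHIKLM")  # left flank truncated
  expect_equal(attr(ctx, "variant_index"), 3L)

  ctx <- seventeen_mer(prot, 1L, "X")
  expect_equal(as.character(ctx), "XCDEFGHIK")  # 9 residues from the variant
  expect_equal(attr(ctx, "variant_index"), 1L)

  expect_error(seventeen_mer(prot, 0L, "X"), "outside protein")
  expect_error(seventeen_mer(prot, 21L, "X"), "outside protein")
})

test_that("a full 17-mer context yields exactly 9 windows, offsets 9..1", {
  ctx <- "ABCDEFGHXKLMNPQRS"
  w <- nine_mer_windows(ctx, 9L)
  expect_equal(nrow(w), 9L)
  expect_equal(w$sequence[1], "ABCDEFGHX")
  expect_equal(w$sequence[9], "XKLMNPQRS")
  expect_equal(w$variant_offset, 9:1)
  expect_true(all(substr(w$sequence, w$variant_offset, w$variant_offset) == "X"))
})

test_that("windowing matches brute-force covering enumeration on truncated contexts", {
  # exactly one window for a length-9 context
  w <- nine_mer_windows("ABCDXFGHI", 5L)
  expect_equal(nrow(w), 1L)
  expect_equal(w$variant_offset, 5L)

  # every (length, position) combination agrees with the enumeration oracle
  set.seed(7)
  for (n in 9:17) {
    ctx <- paste(sample(LETTERS[1:20], n, replace = TRUE), collapse = "")
    for (vi in seq_len(n)) {
      w <- nine_mer_windows(ctx, vi)
      expect_equal(w$sequence, oracle_covering_9mers(ctx, vi),
                   info = sprintf("n=%d vi=%d", n, vi))
      # each window is a contiguous substring containing the variant residue
      expect_true(all(w$variant_offset >= 1 & w$variant_offset <= 9))
    }
  }

  expect_warning(w <- nine_mer_windows("SHORT", 2L), "shorter than 9")
  expect_equal(nrow(w), 0L)
})

test_that("Y-chromosome proteins tile into L-8 peptides each", {
  y <- c(YP1 = "ACDEFGHIKLM")  # 11 aa -> 3 windows
  expect_equal(nrow(y_chromosome_peptides(y)), 3L)
  y <- c(YP1 = "ACDEFGHIK")  # 9 aa -> 1 window
  p <- y_chromosome_peptides(y)
  expect_equal(nrow(p), 1L)
  expect_equal(p$origin, "y_chromosome")
  expect_equal(p$variant_offset, 0L)

  set.seed(11)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  y2 <- c(YA = paste(sample(aa, 20, TRUE), collapse = ""),
          YB = paste(sample(aa, 15, TRUE), collapse = ""))
  p2 <- y_chromosome_peptides(y2)
  expect_equal(nrow(p2), 12L + 7L)
  # brute-force tiling agreement
  expect_equal(p2$sequence[p2$gene_id == "YA"],
               substring(y2[["YA"]], 1:12, 9:20))
})

test_that("donor self filter removes self peptides and deduplicates", {
  cand <- data.frame(
    sequence = c("AAAAAAAAA", "CCCCCCCCC", "AAAAAAAAA", "DDDDDDDDD"),
    gene_id = c("G2", "G1", "G1", "G3"),
    aa_pos = c(5L, 1L, 2L, 9L),
    stringsAsFactors = FALSE
  )
  out <- donor_self_filter(cand, donor_9mers = "DDDDDDDDD")
  expect_setequal(out$sequence, c("AAAAAAAAA", "CCCCCCCCC"))
  # duplicate AAAAAAAAA: kept record is the first in (gene_id, aa_pos) order
  expect_equal(out$gene_id[out$sequence == "AAAAAAAAA"], "G1")
  lg <- allosim_log(out)
  expect_equal(unname(lg["self_peptides_removed"]), 1)
  expect_equal(unname(lg["duplicate_sequences_collapsed"]), 1)
})

test_that("randomized candidate/donor sets match the set-difference oracle", {
  set.seed(33)
  for (rep in 1:5) {
    pool <- unique(replicate(80, paste(sample(LETTERS[1:4], 9, TRUE),
                                       collapse = "")))
    cand_seq <- sample(pool, 40, replace = FALSE)
    donor <- sample(pool, 30, replace = FALSE)
    cand <- data.frame(sequence = cand_seq,
                       gene_id = sample(sprintf("G%d", 1:5), 40, TRUE),
                       aa_pos = sample(100L, 40), stringsAsFactors = FALSE)
    out <- donor_self_filter(cand, donor)
    expect_setequal(out$sequence, setdiff(cand_seq, donor))
  }
})

test_that("peptide library construction respects variant placement", {
  prot <- c(P1 = "ACDEFGHIKLMNPQRSTVWY")
  ann <- data.frame(site_id = "s1", chrom = "1", pos = 1L, ref_allele = "A",
                    gvh_allele = "G", gene_id = "G1", protein_id = "P1",
                    aa_pos = 10L, ref_aa = "L", alt_aa = "W",
                    consequence = "nonsynonymous", stop_involved = FALSE,
                    stringsAsFactors = FALSE)
  lib <- build_peptide_library(ann, prot)
  expect_equal(nrow(lib), 9L)
  # every snv peptide carries the alt residue at its variant offset
  expect_true(all(substr(lib$sequence, lib$variant_offset,
                         lib$variant_offset) == "W"))
  # the union of the windows reconstructs the 17-mer context
  ctx <- as.character(seventeen_mer(prot[["P1"]], 10L, "W"))
  expect_true(all(vapply(lib$sequence, grepl, TRUE, x = ctx, fixed = TRUE)))

  # a mismatching annotation is a hard error
  ann_bad <- ann; ann_bad$ref_aa <- "Q"
  expect_error(build_peptide_library(ann_bad, prot), "annotation says")

  # stop variants are excluded and counted
  ann_stop <- ann; ann_stop$alt_aa <- "*"; ann_stop$stop_involved <- TRUE
  lib2 <- build_peptide_library(ann_stop, prot)
  expect_equal(nrow(lib2), 0L)
  expect_equal(unname(allosim_log(lib2)["stop_variants_excluded"]), 1)
})
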