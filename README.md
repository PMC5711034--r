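# allosim

Simulation of donor T cell alloreactivity potential in HLA-matched stem
cell transplantation, from exome-derived minor histocompatibility antigens.

## The problem

After allogeneic stem cell transplantation, donor CD8+ T cells encounter
recipient peptides that differ from the donor's own proteome. Every coding
variant present in the recipient but absent from the donor (the
graft-versus-host direction, R+/D−) can yield 9-mer peptides that bind the
pair's shared HLA class I molecules — *putative minor histocompatibility
antigens* (pmHA). The number, binding strength and tissue expression of
these antigens differ enormously between donor–recipient pairs, which is one
reason graft-versus-host disease (GVHD) appears so unpredictable.

`allosim` implements the full in-silico chain for quantifying this
*alloreactivity potential*:

1. **Variant comparison** — extract R+/D− SNPs from paired VCFs
   (`gvh_variants()`), with a minimal codon-table annotator for fixtures
   (`annotate_consequence()`).
2. **Peptide library** — a 17-mer context centred on each nonsynonymous
   variant residue, expanded into the nine 9-mers containing the variant
   (`seventeen_mer()`, `nine_mer_windows()`); whole-protein 9-mer tiling of
   Y-chromosome proteins for female→male pairs (`y_chromosome_peptides()`);
   donor-self filtering (`donor_self_filter()`).
3. **HLA binding** — IC50 (nM) per peptide×allele from a NetMHCpan-style
   table (`parse_affinity_table()`) or a deterministic synthetic model
   (`synthetic_affinity()`); working library keeps IC50 ≤ 500 nM
   (`filter_binders()`), strong binders counted at IC50 < 50 nM.
4. **Tissue expression** — GTEx-style RPKM joined per gene; peptides kept
   where RPKM ≥ 1, producing one *organ operator* per target tissue
   (`build_organ_operator()`).
5. **Repertoire simulation** — each clone `x` targeting complex `x` with
   affinity `af_x = 1/IC50_x` iterates

   ```
   N_t = K_eff · N0 / ((K_eff − Σ_i N_{t−1,i}·α(x,i)) · e^{−r·t·af_x} + 1)
   K_eff = (Pexp · K)^{af_x},   α(x,i) = IC50_x / IC50_i
   ```

   with N0 = 1, K = 10^6 cells, r = 1.5, 500 iterations; the organ count is
   the clone sum of the iteration-401–500 means, and the pair total sums the
   nine organs (skin, salivary gland, esophagus, stomach, small intestine,
   colon, liver, lung, blood). See `sim_config()`, `run_organ()`,
   `run_drp()`, `power_law_diagnostic()`.

Model extensions: APC effect vector `ν_APC = (1 − (N_APC/K_APC)^t) + 1`
coupling (`apc_effect()`, `couple_apc()`), Treg-mediated growth-rate
switching (`treg_switch()`), TCR-affinity exponent
(`tcr_adjusted_capacity()`), and the multiset combinatorial probability that
an HLA presentation contains no alloreactive peptide
(`presentation_probability()`).

A synthetic cohort generator (`cohort_spec()`, `generate_pair()`,
`generate_cohort()`) emits complete toy pairs — VCFs, proteome/CDS FASTA,
annotation, RPKM table, HLA list — so every stage runs with no external
data.

## Worked example

```r
library(allosim)

spec <- cohort_spec(n_pairs = 1, scale = 1/30, seed = 42)  # desk-scale pair
pair <- generate_pair(spec, 1, donor_type = "mud")
res  <- run_pair_pipeline(pair)
str(res$summary)
```

```
$ n_gvh_variants      : int 319
$ n_nonsynonymous     : int 152
$ n_candidate_peptides: int 1312
$ n_pmha              : int 7872
$ n_binders           : int 4539
$ n_strong_binders    : int 2893
$ organ_counts        : Named num [1:9] 8.30e+08 3.15e+08 5.80e+08 ...
$ total               : num 6.8e+09
```

Reading: this MUD-like pair carries 152 GVH-direction nonsynonymous SNPs;
after windowing, donor-self filtering and crossing with 6 HLA alleles, 4539
peptide–HLA complexes bind at ≤ 500 nM. Simulating the clonal response
gives, e.g., a colon-specific count of ~2.4×10^9 cells (3812 expressed
pmHA), and a pair total of 6.8×10^9 — counts whose *relative* magnitude
across pairs and organs is the alloreactivity-potential readout. The colon
repertoire's rank–frequency line fits log10 size vs log10 rank with
R² ≈ 0.95:

```r
power_law_diagnostic(res$simulation$organs[["colon"]]$clone_summary$mean_n)
#> $slope       -4.35
#> $r_squared    0.95
```

The presentation-competition worked example — 10 peptides, 3 alloreactive,
4 HLA slots:

```r
presentation_combinations(10, 4)        # 715 possible multisets
presentation_combinations(7, 4)         # 210 without any mHA
presentation_probability(10, 3, 4)      # 0.2937 chance of no mHA presented
```

## Command line

```sh
Rscript -e 'allosim::allosim_cli()' synth --out data --pairs 2 --seed 7 --scale 0.05
Rscript -e 'allosim::allosim_cli()' gvh --donor data/pair0001/donor.vcf \
    --recipient data/pair0001/recipient.vcf --out gvh.tsv
Rscript -e 'allosim::allosim_cli()' simulate --pair data/pair0001 --out results
Rscript -e 'allosim::allosim_cli()' presentation --n-total 10 --n-allo 3 --k-slots 4
```

(`inst/cli/allosim` is an equivalent launcher script.)

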