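---
title: "The alloreactivity-potential model: assumptions, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The alloreactivity-potential model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosim)
```

## Overview

`allosim` estimates, for one stem cell transplant donor–recipient pair, how
large an alloreactive donor CD8+ T cell response the recipient's
exome-encoded antigens could support in each GVHD target organ. The readout
is not a predicted cell count in any physiological sense: it is a
*potential*, a deterministic function of the pair's variant set, HLA binding
affinities and tissue expression, whose spread across pairs and organs is
the quantity of interest.

The pipeline has a sequence front end and a dynamical-system back end.

## Front end: from VCFs to organ operators

**GVH-direction variants.** A variant allele is alloreactive material only
if the recipient carries it and the donor does not (R+/D−): the donor's
T cell repertoire is tolerant of everything the donor expresses. The
comparison is a per-site set difference of unordered genotype allele pairs.
Two conventions needed fixing where standard practice is silent:

* *Sites absent from the donor VCF* are treated as donor homozygous
  reference — the usual single-sample VCF convention (callers omit hom-ref
  sites). The count of such sites is logged (`allosim_log()`), because for
  genuinely missing genotypes the assumption is optimistic.
* *Only SNPs* are processed. Indel/MNP alleles are skipped with a count;
  frameshift peptides have no defined single-residue context in this model.

**Peptide windows.** Each nonsynonymous variant contributes the protein
subsequence from 8 residues before to 8 after the variant (17-mer with the
variant central), substituted with the alternate residue; every 9-mer window
containing the variant is a candidate peptide — exactly 9 for a full-length
context. At protein termini the context is *truncated, never padded*:
padding would manufacture non-biological sequence. A variant within 8
residues of a terminus therefore yields fewer than 9 windows (counted, kept).
Stop-gain/-loss variants are nonsynonymous but have no defined context and
are excluded (counted).

**Donor-self filter.** Candidates whose 9-mer occurs in the donor self
peptidome are removed. Without a donor-specific FASTA, the self peptidome is
approximated by the reference 9-mers spanning the same loci (the
unsubstituted counterparts); this catches reversion-type candidates but not
the donor's private variants — an acknowledged approximation.

**Affinity.** Binding is expressed as IC50 in nM; affinity is exactly
`1/IC50` (nM⁻¹) with no rescaling, and the exponent it feeds is treated as
dimensionless. The working library keeps IC50 ≤ 500 nM (inclusive); the
"strong binder" tally uses strict IC50 < 50 nM. Both cutoffs are arguments.
When no predictor output is available, `synthetic_affinity()` maps an
FNV-1a hash of (peptide, allele, seed) to a log-uniform IC50 on
[1, 50000] nM — deterministic per input, uniform in log across inputs
(KS-checked in the tests). It is a stand-in with the right *distributional*
shape, not a binding model: real predictors concentrate far more mass at
weak binding, so synthetic binder fractions run higher than patient data.

**Expression.** Peptides are weighted by the RPKM of their source gene in
the target tissue (`Pexp`) and kept where RPKM ≥ 1 (inclusive). Y-chromosome
peptides, which enter only for female→male pairs and have no tissue entry in
a gene table keyed on autosomal/reference genes, receive a neutral
`Pexp = 1` so they participate in every organ without inflating any.
Per-transcript tables collapse to the per-gene maximum. The result is one
*organ operator* per tissue: the peptide–HLA entries sorted by ascending
IC50 (ties by sequence then allele — this ordering makes the competition
matrix's above/below-diagonal structure literal).

## Back end: the iterated clonal dynamical system

One T cell clone is assumed per peptide–HLA complex (an identity pairing:
`TCR_x` recognises complex `x` and no other), founded at `N0 = 1` cell at
`t = 1`. Clone `x` iterates

$$N_t^{x} = \frac{K_{\mathrm{eff}}^{x} \, N_0}
  {\left(K_{\mathrm{eff}}^{x} - \sum_i N_{t-1}^{i}\,\alpha(x,i)\right)
   e^{-r\,t\,af_x} + 1}, \qquad
  K_{\mathrm{eff}}^{x} = (P_{\mathrm{exp}}\,K)^{af_x}, \quad af_x = 1/IC50_x$$

* **Capacity.** `K = 10^6` cells stands in for organ mass and
  lympho-vascular supply, identical for every organ; tissue expression
  multiplies it *inside* the affinity exponent, so expression and affinity
  trade off multiplicatively on the log scale. Strong binders
  (IC50 → 1 nM) retain nearly the whole capacity; weak binders collapse
  toward 1 cell.
* **Growth.** `r = 1.5` for all simulations, attenuated per clone by its
  affinity in the exponent `e^{-r·t·af}`. Different texts describe the same
  growth regime with opposite signs for `r`; here positive `r` produces
  sigmoid growth toward capacity (this satisfies every stated limit), and a
  `flip_sign` flag in `sim_config()` flips the convention for sensitivity
  analysis. `t` is the global iteration index, shared by all clones.
* **Competition.** Lotka–Volterra: the load on clone `x` is
  `Σ_i N_{t-1,i} · IC50_x/IC50_i`. Strong binders weigh heavily on weak ones
  and barely feel them in return. The sum *includes* the test clone itself
  (its weight is exactly 1), the standard self-limitation reading;
  `exclude_self = TRUE` implements the alternative. When the weighted load
  exceeds `K_eff` early on, the denominator goes negative and the clone is
  clamped to 0 for that iteration — it may regrow, because `N0` re-enters
  the numerator. This clamping is what produces the late-window fluctuation
  that motivates averaging.
* **Summaries.** 500 iterations; each clone is summarised by its mean size
  over iterations 401–500 (competition keeps late trajectories noisy), the
  organ count is the clone sum, and the pair total sums the nine organs.
  The core contains no random number generator: identical inputs give
  bit-identical trajectories.
* **Numerics.** All state is double precision; every exponential argument is
  clamped to ±700 before `exp()`, and any non-finite or negative step result
  is set to 0, so trajectories can never contain NaN/Inf.

**Repertoire shape.** `power_law_diagnostic()` regresses log10(clone size)
on log10(rank). Simulated organ repertoires under a log-uniform IC50
operator typically fit with R² above 0.9; the R² ≥ 0.8 bar used in the
acceptance suite is our diagnostic convention for "power-law-like", not a
sharp theoretical claim.

## Extensions

* **APC effect.** Antigen presentation waxes and wanes: with the APC
  population following the same logistic engine (defaults `K_APC = 10^4`,
  `r_APC = 1`; the model source is silent on these, and only the shape —
  logistic rise to capacity — matters), the effect term
  `ν = (1 − (N_APC/K_APC)^t) + 1` starts at 2 (maximal amplification) and
  decays to 1 (homeostatic persistence). Multiplying a clone trajectory by
  this vector (the two vectors are aligned, cos θ = 1) yields the familiar
  crescendo–decrescendo antigen-challenge curve.
* **Treg switching.** Regulatory suppression is modelled entirely through
  `r`: `treg_switch(cfg, t0, new_r)` installs a piecewise `r` schedule. A
  smaller-magnitude `r` slows growth; a sign-reversed one collapses the
  population below its pre-switch peak.
* **TCR affinity.** When TCR–complex affinity is known it multiplies the
  capacity exponent: `(Pexp·K)^{af_mHA · af_TCR}`; the default assumption
  `IC50_TCR = 1` nM makes this the identity.
* **Presentation combinatorics.** With `n` peptides filling `k` HLA slots
  with repetition and without order, there are `C(n+k−1, k)` multisets; the
  chance that none of the `a` alloreactive peptides appears is
  `C(n−a+k−1, k)/C(n+k−1, k)`. This is computed as the cancelled product
  `Π_{i<k} (n−a+i)/(n+i)`: algebraically exact, no large factorials, no
  big-integer dependency (none is available in the target environment), and
  verified against exhaustive multiset enumeration for all n ≤ 5, k ≤ 3.

## The synthetic world

The generator states one fixed world per seed:

| Parameter | Default | Why |
|---|---|---|
| nsSNP count, MRD-like | Normal(2463, 603) | matched-related exome-difference scale |
| nsSNP count, MUD-like | Normal(4287, 1154) | matched-unrelated scale |
| shared / donor-only variants | 0.3 / 0.3 × nsSNP | material the GVH comparison must reject |
| synonymous recipient-only | 1.1 × nsSNP | material the consequence filter must reject |
| IC50 | log-uniform 1–50000 nM | spans predictor output range |
| RPKM | log-normal, median 5, σ = 0.8 log10 | heavy right tail; ~81% of genes ≥ 1 RPKM per tissue (comfortably above the ≥60% floor that keeps toy operators non-empty, so no clamping is applied) |
| F→M pairs | 17/77 | sex-mismatch frequency of a realistic cohort |
| toy proteome | 200 genes, 100–500 aa | enough codon slots for full-scale variant counts |

`scale` shrinks variant counts and the proteome proportionally (preserving
the MRD/MUD ratio) so cohort-level tests finish within their time budgets —
the acceptance cohort uses `scale = 1/30`. The claims tested at that scale
(MUD-like > MRD-like mean totals; power-law-like repertoires; determinism)
do not depend on absolute counts.

What a green cohort test does **not** establish: the generator has no
linkage, no allele-frequency structure, no HLA haplotypes, random protein
sequence (so no realistic anchor-residue binding motifs), and
tissue-independent RPKM draws. It validates the pipeline's plumbing and the
simulator's comparative statics, not biological calibration.

## Degenerate inputs and conventions

* Genotypes are unordered allele multisets; phasing is ignored. Inconsistent
  REF alleles at a shared site are a hard error naming the site.
* Multi-allelic sites yield one GVH record per recipient-only alt allele.
* Contexts shorter than 9 residues produce zero windows with a warning.
* Peptides containing non-standard residues (U/X/*/B/…) are dropped with a
  count.
* Duplicate (peptide, allele) rows in predictor tables collapse to the
  minimum IC50; duplicate candidate sequences keep the first record in
  (gene, position) order.
* An empty organ operator simulates to a count of 0 with a warning.
* `clone_capacity()` can legitimately return values ≤ 1 when
  `Pexp·K < 1`; trajectories then sit near the founding cell.

## Known limitations

Proteasomal cleavage and post-translational modification are not modelled
(candidate libraries are therefore larger than what is biologically
presentable); expression is normal-tissue expression, not the post-conditioning
inflamed state; only 9-mers on class I are considered; the TCR repertoire is
assumed complete (every pmHA finds a clone) and private TCR affinities are
fixed at 1 nM. The clinical-association layer (survival/regression analysis
on patient outcomes) is deliberately out of scope.
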