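# Model extensions: antigen-presenting-cell (APC) effect vector and its
# dot-product coupling to T cell trajectories, regulatory-T-cell-mediated
# growth-rate switching, TCR-affinity exponent, and the multiset
# combinatorial probability of an all-non-alloreactive presentation.

#' APC effect term
#'
#' `v_APC = (1 - (N_APC/K_APC)^t) + 1`. At the start of the reaction
#' (APC fraction near 0) the term is at its maximum, 2, amplifying T cell
#' growth; as the APC population approaches its carrying capacity it decays
#' to 1, the homeostatic level at which a T cell clone merely persists.
#'
#' @param n_apc APC population (0 <= n_apc <= k_apc; vectorised).
#' @param k_apc APC carrying capacity (> 0).
#' @param t iteration index (>= 1; vectorised).
#' @return the effect value in `[1, 2]`.
#' @export
apc_effect <- function(n_apc, k_apc, t) {
  if (any(k_apc <= 0)) stopf("k_apc must be positive")
  if (any(t < 1)) stopf("t must be >= 1")
  if (any(n_apc < 0 | n_apc > k_apc)) stopf("n_apc must lie in [0, k_apc]")
  (1 - (n_apc / k_apc)^t) + 1
}

#' Logistic APC trajectory with its effect vector
#'
#' Runs the same iterated logistic engine as the T cell clones for the APC
#' population (its own capacity and growth rate) and evaluates the APC
#' effect term at every iteration.
#'
#' @param iterations number of iterations.
#' @param k_apc APC carrying capacity (default 1e4).
#' @param r_apc APC growth-rate parameter (default 1).
#' @param n0 initial APC population (default 1).
#' @return `data.frame` with columns `t`, `n_apc`, `v_apc`.
#' @export
apc_trajectory <- function(iterations, k_apc = 1e4, r_apc = 1, n0 = 1) {
  n <- numeric(iterations)
  prev <- n0
  for (t in seq_len(iterations)) {
    prev <- logistic_step(prev, n0, k_apc, r_apc, t)
    n[t] <- prev
  }
  data.frame(t = seq_len(iterations), n_apc = n,
             v_apc = apc_effect(pmin(n, k_apc), k_apc, seq_len(iterations)))
}

#' Couple a T cell trajectory with an APC effect vector
#'
#' Elementwise product of the clone trajectory with the APC effect vector
#' (the dot-product coupling of the two aligned vectors; the angle between
#' them is 0, so cos(theta) = 1). With a logistic APC population this
#' produces the crescendo-decrescendo antigen-challenge response: an early
#' amplified peak that relaxes to the uncoupled steady state as the effect
#' decays to 1.
#'
#' @param trajectory numeric vector of clone sizes per iteration.
#' @param v_apc numeric vector of APC effect values, same length.
#' @param cos_theta angle term between the two vectors (default 1: the TCR
#'   recognises the complex the APC presents).
#' @return the modified trajectory.
#' @export
couple_apc <- function(trajectory, v_apc, cos_theta = 1) {
  if (length(trajectory) != length(v_apc)) {
    stopf("trajectory (%d) and v_apc (%d) lengths differ",
          length(trajectory), length(v_apc))
  }
  trajectory * v_apc * cos_theta
}

#' Switch the growth-rate parameter mid-simulation (Treg effect)
#'
#' Regulatory T cells are modelled purely through the growth parameter `r`
#' (the proliferative effect of the cytokine milieu): iterations before
#' `switch_iteration` use the configured `r`, iterations from the switch
#' onward use `new_r`. A reduced-magnitude `new_r` slows growth; a
#' sign-reversed one makes the population decline from its pre-switch level.
#'
#' @param cfg a [sim_config()].
#' @param switch_iteration iteration at which the new value takes effect
#'   (1 <= switch_iteration <= iterations).
#' @param new_r the post-switch growth-rate parameter.
#' @return the config with an `r_schedule` installed.
#' @export
treg_switch <- function(cfg, switch_iteration, new_r) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (switch_iteration < 1 || switch_iteration > cfg$iterations) {
    stopf("switch_iteration must lie in [1, %d]", cfg$iterations)
  }
  base <- if (is.null(cfg$r_schedule)) rep(cfg$r, cfg$iterations) else cfg$r_schedule
  base[seq.int(switch_iteration, cfg$iterations)] <- new_r
  cfg$r_schedule <- base
  cfg
}

#' Carrying capacity with an explicit TCR-affinity exponent
#'
#' `K_eff = (Pexp*K)^{(1/IC50_mHA) * (1/IC50_TCR)}`: when the affinity of
#' the TCR for the peptide-HLA complex is known it multiplies the
#' peptide-HLA affinity in the capacity exponent. With `ic50_tcr = 1` nM
#' (the default assumption) this reduces to [clone_capacity()].
#'
#' @param pexp tissue expression multiplier.
#' @param k base carrying capacity.
#' @param ic50_mha peptide-HLA IC50 (nM).
#' @param ic50_tcr TCR IC50 (nM).
#' @return effective capacity.
#' @export
tcr_adjusted_capacity <- function(pexp, k, ic50_mha, ic50_tcr) {
  if (any(ic50_mha <= 0) || any(ic50_tcr <= 0)) {
    stopf("IC50 values must be positive")
  }
  (pexp * k)^((1 / ic50_mha) * (1 / ic50_tcr))
}

#' Number of multisets of k presentation slots over n peptides
#'
#' Combinations with repetition: `C(n + k - 1, k)` distinct ways to fill `k`
#' HLA presentation slots from `n` distinct peptides, allowing duplicates
#' and ignoring order.
#'
#' @param n_total number of distinct peptides.
#' @param k_slots number of HLA presentation slots.
#' @return the count (exact in double precision for desk-scale inputs).
#' @export
presentation_combinations <- function(n_total, k_slots) {
  if (k_slots < 1) stopf("k_slots must be >= 1")
  if (n_total < 1) stopf("n_total must be >= 1")
  choose(n_total + k_slots - 1, k_slots)
}

#' Probability that a presentation contains no alloreactive peptide
#'
#' Among the `C(n+k-1, k)` equally likely multisets of `k` presentation
#' slots over `n` peptides, the favorable ones draw only from the
#' `n - n_allo` non-alloreactive peptides. The probability is
#' `C(n - n_allo + k - 1, k) / C(n + k - 1, k)`, computed as the exactly
#' cancelled product `prod_{i=0}^{k-1} (n - n_allo + i) / (n + i)` so no
#' large factorials are ever formed.
#'
#' @param n_total number of distinct peptides available for presentation.
#' @param n_allo how many of them are alloreactive (0 <= n_allo <= n_total).
#' @param k_slots number of HLA presentation slots (>= 1).
#' @return the probability; 0 when every peptide is alloreactive, 1 when
#'   none is. The complement is the chance that at least one alloreactive
#'   peptide is presented.
#' @export
presentation_probability <- function(n_total, n_allo, k_slots) {
  if (n_allo < 0 || n_allo > n_total) {
    stopf("n_allo must lie in [0, n_total]")
  }
  if (k_slots < 1) stopf("k_slots must be >= 1")
  m <- n_total - n_allo
  if (m == 0) return(0)
  i <- seq.int(0, k_slots - 1)
  prod((m + i) / (n_total + i))
}
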