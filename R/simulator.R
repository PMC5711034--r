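# Core dynamical system. Each T cell clone x targeting peptide-HLA complex x
# with binding affinity af_x = 1/IC50_x grows by the iterated logistic map
#
#   N_t = K_eff * N0 / ((K_eff - S_{t-1}) * exp(-r * t * af_x) + 1)
#
# with K_eff = (Pexp * K)^af_x (tissue expression scales the carrying
# capacity before the affinity exponent) and S_{t-1} the Lotka-Volterra
# competition load: S = sum_i N_{t-1,i} * alpha(x, i), alpha(x, i) =
# IC50_x / IC50_i. With competition off, S reduces to the clone's own
# N_{t-1}. The core is fully deterministic (no RNG).

#' Simulation configuration
#'
#' Bundles every model constant. Defaults are the reference conditions used
#' throughout: one founding cell per clone, base carrying capacity 10^6
#' cells, growth-rate parameter 1.5, 500 iterations, organ counts averaged
#' over iterations 401-500, competition on.
#'
#' @param n0 initial clone size (cells).
#' @param k base carrying capacity (cells).
#' @param r growth-rate parameter; the growth exponent is `exp(-r*t*af)`, so
#'   positive `r` drives sigmoid growth toward the carrying capacity.
#' @param iterations number of iterations.
#' @param window inclusive iteration range `c(from, to)` averaged for organ
#'   counts (the late window smooths competition-driven fluctuation).
#' @param competition logical; Lotka-Volterra inter-clonal competition.
#' @param exclude_self logical; drop the test clone's own (alpha = 1) term
#'   from the competition sum. Default FALSE (standard self-limitation).
#' @param flip_sign logical; flip the sign convention of `r` in the growth
#'   exponent (sensitivity analysis).
#' @param r_schedule optional numeric vector of length `iterations` giving a
#'   per-iteration `r` (see [treg_switch()]); overrides `r` when set.
#' @param keep_trajectories logical; retain the full clone-by-iteration
#'   matrix (memory-heavy for large operators).
#' @return a `SimulationConfig` object (list).
#' @export
sim_config <- function(n0 = 1, k = 1e6, r = 1.5, iterations = 500,
                       window = c(401, 500), competition = TRUE,
                       exclude_self = FALSE, flip_sign = FALSE,
                       r_schedule = NULL, keep_trajectories = FALSE) {
  if (n0 < 1) stopf("n0 must be >= 1")
  if (k <= n0) stopf("k must exceed n0")
  if (length(window) != 2L || window[1] > window[2]) {
    stopf("window must be c(from, to) with from <= to")
  }
  if (window[1] < 1 || window[2] > iterations) {
    stopf("averaging window [%d, %d] must lie within [1, %d]",
          window[1], window[2], iterations)
  }
  if (!is.null(r_schedule) && length(r_schedule) != iterations) {
    stopf("r_schedule must have length iterations (%d)", iterations)
  }
  structure(list(n0 = n0, k = k, r = r, iterations = as.integer(iterations),
                 window = as.integer(window), competition = competition,
                 exclude_self = exclude_self, flip_sign = flip_sign,
                 r_schedule = r_schedule,
                 keep_trajectories = keep_trajectories),
            class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(
    "SimulationConfig: n0=%g, K=%g, r=%g, %d iterations (window %d-%d), competition %s\n",
    x$n0, x$k, x$r, x$iterations, x$window[1], x$window[2],
    if (x$competition) "on" else "off"))
  invisible(x)
}

#' One step of the iterated logistic map
#'
#' `N_t = K * N0 / ((K - N_{t-1}) * exp(-r*t) + 1)`. At `N_{t-1} = K` the
#' denominator collapses to 1 and the step returns `K * N0`; as `t` grows
#' the exponential vanishes and the population approaches `K * N0`.
#' The result is clamped to be non-negative and finite.
#'
#' @param n_prev population at the previous iteration (vectorised).
#' @param n0 initial population.
#' @param k carrying capacity.
#' @param r growth-rate parameter.
#' @param t iteration index (>= 1).
#' @return population at iteration `t`.
#' @export
logistic_step <- function(n_prev, n0, k, r, t) {
  if (k <= 0) stopf("k must be positive")
  if (any(t < 1)) stopf("t must be >= 1")
  denom <- (k - n_prev) * safe_exp(-r * t) + 1
  n_t <- k * n0 / denom
  n_t[!is.finite(n_t) | n_t < 0] <- 0
  n_t
}

#' Effective carrying capacity of a clone
#'
#' `K_eff = (Pexp * K)^(1/IC50)`: tissue expression multiplies the base
#' capacity, and the peptide-HLA binding affinity (1/IC50, nM^-1) enters as
#' the exponent, so strong binders (small IC50) retain most of the capacity
#' while weak binders collapse toward 1.
#'
#' @param pexp tissue expression (RPKM) of the source gene.
#' @param k base carrying capacity.
#' @param ic50_nm peptide-HLA IC50 in nM.
#' @return effective capacity (vectorised). Values below 1 (when
#'   `pexp * k < 1`) are allowed.
#' @export
clone_capacity <- function(pexp, k, ic50_nm) {
  if (any(pexp < 0)) stopf("pexp must be non-negative")
  if (k <= 0) stopf("k must be positive")
  if (any(ic50_nm <= 0)) stopf("ic50_nm must be positive")
  (pexp * k)^(1 / ic50_nm)
}

#' Competition weight matrix
#'
#' `alpha(x, i) = IC50_x / IC50_i`: the impact of competitor clone `i` on
#' test clone `x`. The diagonal is 1; with clones ordered by ascending IC50
#' entries above the diagonal are < 1 and below it > 1 (strong binders
#' suppress weak binders disproportionately).
#'
#' @param ic50_nm vector of clone IC50 values (in clone order).
#' @return the `n x n` alpha matrix (rows = test clone x, columns =
#'   competitor i).
#' @export
competition_weights <- function(ic50_nm) {
  outer(ic50_nm, ic50_nm, `/`)
}

#' Advance every clone of an organ operator by one iteration
#'
#' Implements the competition-modified logistic step for all clones at once.
#' The competition load on clone x is `S_x = IC50_x * sum_i N_i / IC50_i`
#' (which contains the clone's own `N_x` with weight alpha = 1); with
#' `competition = FALSE` it reduces to the clone's own `N_{t-1}`. A negative
#' denominator (early transients where the weighted load exceeds `K_eff`)
#' clamps the clone to 0; it may regrow later because `n0` re-enters the
#' numerator.
#'
#' @param n_prev numeric vector of clone sizes at `t - 1`.
#' @param k_eff per-clone effective capacities ([clone_capacity()]).
#' @param ic50_nm per-clone IC50 values.
#' @param n0,r scalars (see [sim_config()]).
#' @param t iteration index (global, starting at 1 for all clones).
#' @param competition,exclude_self,flip_sign see [sim_config()].
#' @return numeric vector of clone sizes at `t` (non-negative, finite).
#' @export
clone_step <- function(n_prev, k_eff, ic50_nm, n0, r, t,
                       competition = TRUE, exclude_self = FALSE,
                       flip_sign = FALSE) {
  af <- 1 / ic50_nm
  s <- if (competition) {
    load <- sum(n_prev / ic50_nm)
    if (exclude_self) ic50_nm * load - n_prev else ic50_nm * load
  } else {
    n_prev
  }
  sign <- if (flip_sign) 1 else -1
  denom <- (k_eff - s) * safe_exp(sign * r * t * af) + 1
  n_t <- k_eff * n0 / denom
  n_t[!is.finite(n_t) | n_t < 0] <- 0
  n_t
}

#' Simulate the T cell response to one organ operator
#'
#' Iterates every clone of the operator from `N_0 = n0` for
#' `cfg$iterations` steps and reports, per clone, the mean size over the
#' averaging window; the organ count is the sum of those means. Fully
#' deterministic.
#'
#' @param operator an `OrganOperator` ([build_organ_operator()]), or any
#'   `data.frame` with `ic50_nm` and `pexp` columns.
#' @param cfg a [sim_config()].
#' @return an `OrganSimulation`: list with `tissue`, `clone_summary`
#'   (`data.frame` of clone metadata, `k_eff` and window-mean `mean_n`),
#'   `organ_count`, `n_clones_active` (window mean > 0), `config`, and
#'   `trajectories` (clones x iterations matrix) when
#'   `cfg$keep_trajectories`.
#' @export
run_organ <- function(operator, cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  tissue <- attr(operator, "tissue")
  if (is.null(tissue)) tissue <- NA_character_
  m <- nrow(operator)
  if (m == 0L) {
    warnf("empty operator%s: organ count is 0",
          if (is.na(tissue)) "" else paste0(" for ", tissue))
    return(organ_simulation(tissue, operator, numeric(0), numeric(0), cfg, NULL))
  }
  ic50 <- operator$ic50_nm
  pexp <- if ("pexp" %in% names(operator)) operator$pexp else rep(1, m)
  k_eff <- clone_capacity(pexp, cfg$k, ic50)

  n <- rep(cfg$n0, m)
  win <- seq.int(cfg$window[1], cfg$window[2])
  win_sum <- numeric(m)
  traj <- if (cfg$keep_trajectories) {
    matrix(NA_real_, nrow = m, ncol = cfg$iterations)
  } else NULL
  for (t in seq_len(cfg$iterations)) {
    r_t <- if (is.null(cfg$r_schedule)) cfg$r else cfg$r_schedule[t]
    n <- clone_step(n, k_eff, ic50, cfg$n0, r_t, t,
                    competition = cfg$competition,
                    exclude_self = cfg$exclude_self,
                    flip_sign = cfg$flip_sign)
    if (t >= cfg$window[1] && t <= cfg$window[2]) win_sum <- win_sum + n
    if (!is.null(traj)) traj[, t] <- n
  }
  mean_n <- win_sum / length(win)
  organ_simulation(tissue, operator, k_eff, mean_n, cfg, traj)
}

organ_simulation <- function(tissue, operator, k_eff, mean_n, cfg, traj) {
  summary_cols <- intersect(c("sequence", "hla_allele", "gene_id",
                              "ic50_nm", "pexp"), names(operator))
  clone_summary <- cbind(
    data.frame(clone_id = seq_along(mean_n)),
    as.data.frame(operator)[seq_along(mean_n), summary_cols, drop = FALSE],
    data.frame(k_eff = k_eff, mean_n = mean_n)
  )
  rownames(clone_summary) <- NULL
  structure(list(
    tissue = tissue,
    clone_summary = clone_summary,
    organ_count = sum(mean_n),
    n_clones_active = sum(mean_n > 0),
    config = cfg,
    trajectories = traj
  ), class = "OrganSimulation")
}

#' @export
print.OrganSimulation <- function(x, ...) {
  cat(sprintf(
    "OrganSimulation '%s': %d clones (%d active), organ count %.4g (window mean %d-%d)\n",
    x$tissue, nrow(x$clone_summary), x$n_clones_active, x$organ_count,
    x$config$window[1], x$config$window[2]))
  invisible(x)
}

#' Simulate a donor-recipient pair across all organ operators
#'
#' Runs [run_organ()] per tissue and sums the organ counts into the total
#' alloreactive T cell count ("sum of all clones") for the pair.
#'
#' @param operators named list of organ operators
#'   ([build_organ_operators()]).
#' @param cfg a [sim_config()].
#' @return list with `organs` (named list of `OrganSimulation`),
#'   `organ_counts` (named numeric), and `total`.
#' @export
run_drp <- function(operators, cfg = sim_config()) {
  sims <- lapply(operators, run_organ, cfg = cfg)
  counts <- vapply(sims, function(s) s$organ_count, 0)
  list(organs = sims, organ_counts = counts, total = sum(counts))
}

#' Rank-frequency power-law diagnostic of a clonal repertoire
#'
#' Ordinary least squares of log10(clone size) against log10(rank) on the
#' positive clone sizes sorted in decreasing order. Simulated organ
#' repertoires are expected to be approximately linear on this scale
#' (power-law-like), so the fit quality serves as a repertoire-shape
#' diagnostic.
#'
#' @param clone_sizes numeric vector of clone sizes (window means); at least
#'   10 must be positive.
#' @return list with `slope` and `r_squared`.
#' @export
power_law_diagnostic <- function(clone_sizes) {
  sizes <- sort(clone_sizes[clone_sizes > 0], decreasing = TRUE)
  if (length(sizes) < 10L) {
    stopf("need at least 10 positive clone sizes (got %d)", length(sizes))
  }
  lr <- log10(seq_along(sizes))
  ls <- log10(sizes)
  if (max(ls) - min(ls) < .Machine$double.eps^0.5) {
    # constant sizes: the flat fit has slope 0 and undefined R^2
    return(list(slope = 0, r_squared = NA_real_))
  }
  fit <- lm(ls ~ lr)
  # R^2 computed directly (summary.lm warns on numerically perfect fits)
  r2 <- 1 - sum(fit$residuals^2) / sum((ls - mean(ls))^2)
  list(slope = unname(coef(fit)[2]), r_squared = r2)
}
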