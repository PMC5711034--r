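# The iterated logistic vector-operator system.

test_that("logistic_step matches the closed formula and its limits", {
  k <- 1e6; n0 <- 1; r <- 1.5
  # independent arithmetic evaluation of K*N0 / ((K - N_{t-1}) e^{-rt} + 1)
  expect_equal(logistic_step(1, n0, k, r, 1),
               k * n0 / ((k - 1) * exp(-1.5) + 1), tolerance = 1e-12)
  expect_equal(logistic_step(1, n0, k, r, 1), 4.4817, tolerance = 1e-4)
  # N_{t-1} = K collapses the denominator to 1
  expect_equal(logistic_step(k, n0, k, r, 3), k * n0)
  expect_equal(logistic_step(k, 2, k, r, 3), 2 * k)
  # the exponential term vanishes at large t
  expect_equal(logistic_step(42, n0, k, r, 1e4), k * n0, tolerance = 1e-9)
  expect_error(logistic_step(1, 1, -1, r, 1), "positive")
  expect_error(logistic_step(1, 1, k, r, 0), ">= 1")
})

test_that("clone_capacity applies the affinity exponent to Pexp*K", {
  expect_equal(clone_capacity(1, 1e6, 1), 1e6)
  expect_equal(clone_capacity(10, 1e6, 50), (1e7)^0.02, tolerance = 1e-12)
  expect_equal(clone_capacity(10, 1e6, 50), 1.3804, tolerance = 1e-4)
  expect_equal(clone_capacity(1, 1e6, 1e12), 1, tolerance = 1e-9)
  # pexp*k < 1 gives a value in (0, 1], allowed
  expect_lte(clone_capacity(1e-9, 1e6, 2), 1)
  expect_error(clone_capacity(-1, 1e6, 1), "non-negative")
})

test_that("competition weights are reciprocal ratios around a unit diagonal", {
  ic50 <- c(1, 20, 500)  # ascending
  a <- competition_weights(ic50)
  expect_equal(diag(a), rep(1, 3))
  expect_equal(a * t(a), matrix(1, 3, 3))
  expect_true(all(a[upper.tri(a)] < 1))
  expect_true(all(a[lower.tri(a)] > 1))
})

test_that("a single clone with af = 1 reduces to the plain logistic map", {
  k <- 1e6
  n_log <- 1; n_cl <- 1
  for (t in 1:50) {
    n_log <- logistic_step(n_log, 1, k, 1.5, t)
    n_cl <- clone_step(n_cl, k_eff = k, ic50_nm = 1, n0 = 1, r = 1.5, t = t,
                       competition = TRUE)
    expect_equal(n_cl, n_log, tolerance = 1e-12)
  }
})

test_that("clone_step matches the scalar spreadsheet oracle to 1e-9 relative", {
  cases <- list(
    list(ic50 = c(1, 500), pexp = c(1, 1)),
    list(ic50 = c(2, 35, 450), pexp = c(8, 1, 120)),
    list(ic50 = c(10, 10, 10), pexp = c(1, 2, 3))
  )
  for (cs in cases) {
    oracle <- oracle_clone_matrix(cs$ic50, cs$pexp, k = 1e6, n0 = 1, r = 1.5,
                                  iters = 10)
    n <- rep(1, length(cs$ic50))
    k_eff <- clone_capacity(cs$pexp, 1e6, cs$ic50)
    for (t in 1:10) {
      n <- clone_step(n, k_eff, cs$ic50, n0 = 1, r = 1.5, t = t)
      expect_equal(n, oracle[, t], tolerance = 1e-9)
    }
  }
})

test_that("the higher-affinity of two competing clones dominates throughout", {
  op <- make_operator(ic50 = c(1, 500))
  cfg <- sim_config(iterations = 200, window = c(101, 200),
                    keep_trajectories = TRUE)
  sim <- run_organ(op, cfg)
  traj <- sim$trajectories
  expect_true(all(traj[1, ] >= traj[2, ]))
})

test_that("run_organ converges, is additive without competition, sums per organ", {
  cfg <- sim_config()
  sim <- run_organ(make_operator(1), cfg)
  expect_equal(sim$organ_count, 1e6, tolerance = 0.01)
  expect_equal(sim$n_clones_active, 1L)

  expect_warning(sim0 <- run_organ(make_operator(numeric(0))), "empty")
  expect_equal(sim0$organ_count, 0)

  # duplicating every entry doubles the count when clones do not interact
  cfg_nc <- sim_config(iterations = 120, window = c(81, 120),
                       competition = FALSE)
  op1 <- make_operator(c(3, 40), pexp = c(2, 7))
  op2 <- make_operator(c(3, 3, 40, 40), pexp = c(2, 2, 7, 7))
  s1 <- run_organ(op1, cfg_nc)
  s2 <- run_organ(op2, cfg_nc)
  expect_equal(s2$organ_count, 2 * s1$organ_count, tolerance = 1e-12)

  # per-pair totals add across organs and are order-invariant
  ops <- list(colon = make_operator(c(2, 80)), skin = make_operator(c(5, 10)))
  drp <- run_drp(ops, cfg_nc)
  expect_equal(drp$total, sum(drp$organ_counts))
  drp_rev <- run_drp(rev(ops), cfg_nc)
  expect_equal(drp_rev$total, drp$total)
  expect_equal(drp_rev$organ_counts[names(drp$organ_counts)],
               drp$organ_counts)
})

test_that("trajectories stay finite, non-negative, and deterministic", {
  set.seed(88)
  for (rep in 1:3) {
    m <- 40
    op <- make_operator(ic50 = exp(runif(m, 0, log(500))),
                        pexp = rlnorm(m, log(5), 1.5))
    cfg <- sim_config(iterations = 150, window = c(101, 150),
                      keep_trajectories = TRUE)
    s <- run_organ(op, cfg)
    expect_true(all(is.finite(s$trajectories)))
    expect_true(all(s$trajectories >= 0))
    s2 <- run_organ(op, cfg)
    expect_identical(s$trajectories, s2$trajectories)  # bit-identical, no RNG
  }
})

test_that("without competition every trajectory is non-decreasing", {
  set.seed(12)
  op <- make_operator(ic50 = exp(runif(20, 0, log(500))),
                      pexp = rlnorm(20, log(5), 1))
  cfg <- sim_config(iterations = 100, window = c(51, 100),
                    competition = FALSE, keep_trajectories = TRUE)
  s <- run_organ(op, cfg)
  diffs <- t(apply(s$trajectories, 1, diff))
  expect_true(all(diffs >= -1e-9))
})

test_that("window-mean size is monotone in expression and in affinity", {
  cfg <- sim_config(iterations = 200, window = c(151, 200))
  base <- run_organ(make_operator(c(5, 100), pexp = c(3, 3)), cfg)
  # raising pexp of clone 2 never lowers its mean
  up_pexp <- run_organ(make_operator(c(5, 100), pexp = c(3, 30)), cfg)
  expect_gte(up_pexp$clone_summary$mean_n[2], base$clone_summary$mean_n[2])
  # lowering IC50 (raising affinity) of clone 2 never lowers its mean
  up_af <- run_organ(make_operator(c(5, 20), pexp = c(3, 3)), cfg)
  expect_gte(up_af$clone_summary$mean_n[2], base$clone_summary$mean_n[2])
})

test_that("power-law diagnostic recovers exact power laws and rejects tiny input", {
  sizes <- 1000 * (1:50)^(-1)
  pl <- power_law_diagnostic(sizes)
  expect_equal(pl$slope, -1, tolerance = 1e-9)
  expect_equal(pl$r_squared, 1, tolerance = 1e-9)

  pl2 <- power_law_diagnostic(rep(7, 25))
  expect_equal(pl2$slope, 0)

  expect_error(power_law_diagnostic(c(1, 2, 3)), "at least 10")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n0 = 0), "n0")
  expect_error(sim_config(k = 0.5), "exceed")
  expect_error(sim_config(window = c(400, 600), iterations = 500), "window")
  expect_error(sim_config(window = c(5, 2)), "from <= to")
})
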