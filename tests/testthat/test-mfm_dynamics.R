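# Constants a = 270 Hz/nA, b = 108 Hz, d = 0.154 s throughout.

test_that("firing rate hits the removable-singularity limit and asymptotes", {
  # L'Hopital limit at a*x = b: H = 1/d
  expect_equal(firing_rate(108 / 270), 1 / 0.154, tolerance = 1e-9)
  # series and direct formula agree just off the singularity
  eps <- 1e-8 / 270
  expect_equal(firing_rate(108 / 270 + eps), 1 / 0.154, tolerance = 1e-6)
  expect_equal(firing_rate(108 / 270 - eps), 1 / 0.154, tolerance = 1e-6)
  # large-current asymptote H ~ a*x - b (frozen high-precision evaluations)
  expect_equal(firing_rate(1.0), 162.0000000024, tolerance = 1e-8)
  expect_equal(firing_rate(1.0), 270 * 1.0 - 108, tolerance = 1e-6)
  # sub-threshold rate at zero current is tiny but positive
  h0 <- 108 / (exp(0.154 * 108) - 1)
  expect_equal(firing_rate(0), h0, tolerance = 1e-12)
  expect_lt(firing_rate(0), 1e-5)
  expect_error(firing_rate(NaN), "finite")
})

test_that("firing rate is monotone and non-negative on a dense grid", {
  x <- seq(-1, 3, length.out = 1e4)
  h <- firing_rate(x)
  expect_true(all(h >= 0))
  expect_true(all(diff(h) >= 0))
})

test_that("input current follows x = wJS + GJ*C%*%S + I", {
  p2 <- toy_parcellation(2)
  C0 <- structural_connectome(matrix(0, 2, 2), p2)
  g <- mfm_global_params(G = 2, sigma = 0.01)

  # decoupled, zero gating: current is the external input alone
  x <- input_current(c(0, 0), mfm_regional_params(c(0, 0), c(0.3, 0.3)),
                     g, C0)
  expect_equal(x, c(0.3, 0.3))

  # recurrent term only: w*J*S with J = 0.2609 nA
  x <- input_current(c(0.5, 0.5), mfm_regional_params(c(1, 1), c(0, 0)),
                     g, C0)
  expect_equal(x, c(0.13045, 0.13045))

  # pure coupling: x = G*J*C%*%S, hand-evaluated
  C1 <- structural_connectome(matrix(c(0, 1, 1, 0), 2, 2), p2)
  x <- input_current(c(0.5, 0.25), mfm_regional_params(c(0, 0), c(0, 0)),
                     g, C1)
  expect_equal(x, c(2 * 0.2609 * 0.25, 2 * 0.2609 * 0.5))

  expect_error(input_current(c(0.5, 0.5, 0.5),
                             mfm_regional_params(c(0, 0), c(0, 0)), g, C1),
               "mismatch")
})

test_that("noise-free sub-threshold dynamics stay near zero", {
  p2 <- toy_parcellation(2)
  C0 <- structural_connectome(matrix(0, 2, 2), p2)
  g <- mfm_global_params(G = 0, sigma = 1e-9)
  g$sigma <- 0
  tr <- simulate_neural(C0, g, mfm_regional_params(c(0, 0), c(0, 0)),
                        duration_s = 10, seed = 1, init_S = 0)
  expect_lt(max(tr$S), 1e-4)
})

test_that("identical symmetrically coupled regions stay identical", {
  p2 <- toy_parcellation(2)
  C1 <- structural_connectome(matrix(c(0, 1, 1, 0), 2, 2), p2)
  g <- mfm_global_params(G = 0.5, sigma = 0.01)
  g$sigma <- 0
  tr <- simulate_neural(C1, g, mfm_regional_params(c(0.9, 0.9), c(0.3, 0.3)),
                        duration_s = 5, seed = 1, init_S = 0.1)
  expect_equal(tr$S[, 1], tr$S[, 2], tolerance = 1e-14)
})

test_that("terminal state matches an independent bracketing root oracle", {
  # single decoupled region, w = 0.9, I = 0.3: the equilibrium solves
  # S/tau_s = r*(1-S)*H(w*J*S + I); uniroot is the independent oracle
  g <- mfm_global_params(G = 0, sigma = 0.01)
  g$sigma <- 0
  rhs <- function(S) {
    -S / g$tau_s + g$r_kin * (1 - S) * firing_rate(0.9 * g$J * S + 0.3)
  }
  root <- uniroot(rhs, c(1e-6, 0.5), tol = 1e-12)$root
  p2 <- toy_parcellation(2)
  C0 <- structural_connectome(matrix(0, 2, 2), p2)
  tr <- simulate_neural(C0, g, mfm_regional_params(c(0.9, 0.9), c(0.3, 0.3)),
                        duration_s = 20, seed = 1)
  expect_equal(unname(tr$S[nrow(tr$S), 1]), root, tolerance = 1e-4)

  # the damped fixed-point solver finds the same root
  fp <- find_fixed_point(C0, g, mfm_regional_params(c(0.9, 0.9), c(0.3, 0.3)))
  expect_true(fp$converged)
  expect_lt(fp$residual, 1e-10)
  expect_equal(fp$S[1], root, tolerance = 1e-6)
})

test_that("fixed point of the uncoupled zero-input system is ~0", {
  p2 <- toy_parcellation(2)
  C0 <- structural_connectome(matrix(0, 2, 2), p2)
  g <- mfm_global_params(G = 0, sigma = 0.01)
  fp <- find_fixed_point(C0, g, mfm_regional_params(c(0, 0), c(0, 0)))
  expect_true(fp$converged)
  expect_lt(max(fp$S), 1e-6)
  expect_error(find_fixed_point(C0, g, mfm_regional_params(c(0, 0), c(0, 0)),
                                init = 1.5),
               "\\[0,1\\]")
})

test_that("trajectories are deterministic, bounded, and dt-consistent", {
  syn <- make_synthetic_sc(n_regions = 12, n_networks = 2, seed = 4)
  reg <- mfm_regional_params(rep(0.9, 12), rep(0.3, 12))
  g <- mfm_global_params(G = 0.1, sigma = 0.02)
  t1 <- simulate_neural(syn$sc, g, reg, duration_s = 3, seed = 9)
  t2 <- simulate_neural(syn$sc, g, reg, duration_s = 3, seed = 9)
  expect_identical(t1$S, t2$S)
  expect_true(all(t1$S >= 0 & t1$S <= 1))

  # noise-free integration: halving dt moves the terminal state < 1e-3
  gd <- g; gd$sigma <- 0
  gh <- gd; gh$dt <- gd$dt / 2
  a <- simulate_neural(syn$sc, gd, reg, duration_s = 10, seed = 1)
  b <- simulate_neural(syn$sc, gh, reg, duration_s = 10, seed = 1)
  ta <- a$S[nrow(a$S), ]; tb <- b$S[nrow(b$S), ]
  expect_lt(max(abs(ta - tb) / pmax(abs(tb), 1e-8)), 1e-3)

  # and agrees with the damped fixed-point oracle
  fp <- find_fixed_point(syn$sc, gd, reg)
  expect_true(fp$converged)
  expect_lt(max(abs(ta - fp$S) / pmax(abs(fp$S), 1e-8)), 1e-3)
})

test_that("stationary gating variance scales with sigma^2", {
  p2 <- toy_parcellation(2)
  C0 <- structural_connectome(matrix(0, 2, 2), p2)
  reg <- mfm_regional_params(c(0.9, 0.9), c(0.3, 0.3))
  vs <- sapply(c(0.01, 0.02), function(s) {
    g <- mfm_global_params(G = 0, sigma = s)
    tr <- simulate_neural(C0, g, reg, duration_s = 60, seed = 21)
    var(tr$S[-(1:5000), 1])
  })
  expect_gt(vs[2] / vs[1], 3)
  expect_lt(vs[2] / vs[1], 5)
})

test_that("dt above the stability margin is rejected", {
  expect_error(mfm_global_params(dt = 0.02), "tau_s/10")
})
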