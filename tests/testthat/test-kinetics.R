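p <- csd_params()

test_that("reaction term has the resting and ceiling fixed points", {
  expect_equal(reaction_rate(p$K_rest, p$R_rest, p), 0)
  expect_equal(reaction_rate(p$K_max, p$R_rest, p), 0)
  # hand-evaluated signs of the bistable cubic at R = R_rest
  expect_gt(reaction_rate(0.5, 0.5, p), 0)
  expect_lt(reaction_rate(0.1, 0.5, p), 0)
  expect_error(reaction_rate(NaN, 0.5, p), "non-finite")
  expect_error(reaction_rate(0.5, Inf, p), "non-finite")
})

test_that("recovery rate vanishes at rest, grows with K, relaxes with R", {
  expect_equal(recovery_rate(p$K_rest, p$R_rest, p), 0)
  # frozen expected values of the shipped form dR/dt = E (K-Kr) - C (R-Rr)
  expect_equal(recovery_rate(1, 0.5, p), 0.03 * 0.97)
  expect_equal(recovery_rate(0.03, 0.8, p), -0.018 * 0.3)
  # monotone: increasing in K at fixed R, decreasing in R at fixed K
  Ks <- seq(0.03, 1, length.out = 41)
  expect_true(all(diff(recovery_rate(Ks, 0.7, p)) > 0))
  Rs <- seq(0.3, 1.3, length.out = 41)
  expect_true(all(diff(recovery_rate(0.5, Rs, p)) < 0))
})

test_that("every registered form satisfies the structural contracts", {
  for (nm in kinetics_forms()) {
    f <- kinetics_form(nm)
    expect_equal(f$reaction(p$K_rest, p$R_rest, p), 0, info = nm)
    expect_equal(f$recovery(p$K_rest, p$R_rest, p), 0, info = nm)
    # bistability with R frozen at rest: negative below threshold,
    # positive between threshold and ceiling
    lo <- seq(p$K_rest + 1e-3, p$K_theta - 1e-3, length.out = 25)
    hi <- seq(p$K_theta + 1e-3, p$K_max - 1e-3, length.out = 25)
    expect_true(all(f$reaction(lo, p$R_rest, p) < 0), info = nm)
    expect_true(all(f$reaction(hi, p$R_rest, p) > 0), info = nm)
    expect_true(all(diff(f$recovery(seq(0.03, 1, length.out = 20), 0.6, p)) > 0),
                info = nm)
    expect_true(all(diff(f$recovery(0.4, seq(0.4, 1.2, length.out = 20), p)) < 0),
                info = nm)
  }
})

test_that("modulation only slows recovery and never reverses it", {
  grid <- expand.grid(K = seq(0.03, 1, length.out = 9),
                      R = seq(0.35, 1.3, length.out = 9),
                      F = c(0.01, 0.1, 0.5, 1))
  for (i in seq_len(nrow(grid))) {
    pf <- csd_params(F = grid$F[i])
    base <- recovery_rate(grid$K[i], grid$R[i], pf)
    mod <- modulated_recovery_rate(grid$K[i], grid$R[i], pf,
                                   in_modulated_area = TRUE)
    out <- modulated_recovery_rate(grid$K[i], grid$R[i], pf,
                                   in_modulated_area = FALSE)
    expect_identical(out, base)          # control area: bitwise identical
    expect_equal(sign(mod), sign(base))  # never reverses
    expect_lte(abs(mod), abs(base))      # only slows
    if (base >= 0 || grid$F[i] == 1) expect_identical(mod, base)
    if (base < 0) expect_equal(mod, grid$F[i] * base)
  }
})

test_that("modulated rate examples follow the dR/dt < 0 rule", {
  pf <- csd_params(F = 0.1)
  # relaxing (negative) rate is scaled by F inside the area
  expect_equal(modulated_recovery_rate(0.03, 0.8, pf, TRUE), 0.1 * (-0.0054))
  # growth (positive) rate is never modulated
  expect_equal(modulated_recovery_rate(1, 0.5, pf, TRUE),
               recovery_rate(1, 0.5, pf))
  # F = 1 recovers control dynamics
  p1 <- csd_params(F = 1)
  expect_identical(modulated_recovery_rate(0.03, 0.8, p1, TRUE),
                   recovery_rate(0.03, 0.8, p1))
})

test_that("0-D excitability: threshold separates decay from full excitation", {
  # dK/dt = f(K, R_rest) with R frozen, integrated with deSolve as the
  # independent fine-step ODE oracle
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, parms) list(reaction_rate(y, p$R_rest, p))
  tt <- seq(0, 4000, by = 2)
  up <- deSolve::ode(y = c(K = p$K_theta + 0.01), times = tt, func = rhs,
                     parms = NULL)
  dn <- deSolve::ode(y = c(K = p$K_theta - 0.01), times = tt, func = rhs,
                     parms = NULL)
  expect_equal(unname(up[nrow(up), "K"]), p$K_max, tolerance = 1e-4)
  expect_equal(unname(dn[nrow(dn), "K"]), p$K_rest, tolerance = 1e-4)
})

test_that("kinetics forms are pluggable by name", {
  expect_setequal(intersect(c("default_cubic", "additive_cubic"),
                            kinetics_forms()),
                  c("default_cubic", "additive_cubic"))
  expect_error(kinetics_form("nope"), "unknown kinetics form")
  register_kinetics_form("test_linear",
                         reaction = function(K, R, params) -(K - params$K_rest),
                         recovery = function(K, R, params) 0 * K)
  expect_true("test_linear" %in% kinetics_forms())
  expect_equal(reaction_rate(0.5, 0.5, p, form = "test_linear"), -0.47)
})
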