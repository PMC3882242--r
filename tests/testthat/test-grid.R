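test_that("zero-flux Laplacian matches hand-computed stencils", {
  # constant field: identically zero
  expect_equal(laplacian_zero_flux(matrix(3.2, 4, 6)),
               matrix(0, 4, 6))
  # 3x3 point source: -4 at the centre, +1 at edge-adjacent cells
  m <- matrix(0, 3, 3); m[2, 2] <- 1
  want <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  expect_equal(laplacian_zero_flux(m), want)
  # 2x2 corner cell: two mirror ghosts contribute the cell's own value
  m2 <- matrix(c(1, 0, 0, 0), 2, 2)
  L2 <- laplacian_zero_flux(m2)
  expect_equal(L2[1, 1], -2)
  # dx scaling
  expect_equal(laplacian_zero_flux(m, dx = 0.5), want / 0.25)
})

test_that("zero-flux Laplacian conserves mass for arbitrary fields", {
  set.seed(42)
  for (dims in list(c(5, 5), c(3, 9), c(17, 12))) {
    f <- matrix(rexp(prod(dims)), dims[1], dims[2])
    expect_lt(abs(sum(laplacian_zero_flux(f))), 1e-10 * sum(abs(f)))
  }
})

test_that("diffusion-only stepping conserves the spatial sum of K", {
  # reaction switched off (A = B = 0 makes f identically zero; C = E = 0
  # freezes recovery)
  p <- csd_params(A = 0, B = 0, C = 0, E = 0)
  set.seed(7)
  K <- matrix(runif(20 * 20, 0.03, 1), 20, 20)
  st <- csd_state(K, matrix(p$R_rest, 20, 20))
  total0 <- sum(st$K)
  for (i in 1:200) st <- csd_step(st, p)
  expect_equal(sum(st$K), total0, tolerance = 1e-13)
  expect_equal(st$R, matrix(p$R_rest, 20, 20))
})

test_that("a single Euler step reproduces the scalar hand computation", {
  p <- csd_params()
  n <- 9
  K <- matrix(p$K_rest, n, n); K[5, 5] <- 0.5
  st <- csd_step(csd_state(K, matrix(p$R_rest, n, n)), p)
  hand <- 0.5 + p$dt * (p$D * (-4 * (0.5 - p$K_rest)) / p$dx^2 +
                          reaction_rate(0.5, p$R_rest, p))
  expect_equal(st$K[5, 5], hand)
  expect_equal(st$t, p$dt)
  expect_equal(st$step_index, 1L)
})

test_that("the resting state is a fixed point of the stepper", {
  p <- csd_params()
  st <- csd_state(matrix(p$K_rest, 8, 8), matrix(p$R_rest, 8, 8))
  st2 <- csd_step(csd_step(st, p), p)
  expect_identical(st2$K, st$K)
  expect_identical(st2$R, st$R)
})

test_that("numerical blow-up is reported with the step index", {
  p <- csd_params()
  p$dt <- 40; p$dx <- 1  # stable for diffusion but wildly stiff reaction
  st <- csd_state(matrix(0.5, 6, 6), matrix(p$R_rest, 6, 6))
  expect_error({
    for (i in 1:50) st <- csd_step(st, p)
  }, "blow-up at step")
})

test_that("Euler stepping is first-order accurate in dt", {
  p1 <- csd_params()        # dt = 0.05
  p2 <- csd_params(dt = 0.025)
  p4 <- csd_params(dt = 0.0125)
  K0 <- matrix(csd_params()$K_rest, 8, 8); K0[4, 4:5] <- 0.6
  R0 <- matrix(0.5, 8, 8)
  advance <- function(p, t_total) {
    st <- csd_state(K0, R0)
    for (i in seq_len(round(t_total / p$dt))) st <- csd_step(st, p)
    st$K
  }
  ref <- advance(csd_params(dt = 0.003125), 2)
  e1 <- max(abs(advance(p1, 2) - ref))
  e2 <- max(abs(advance(p2, 2) - ref))
  e4 <- max(abs(advance(p4, 2) - ref))
  expect_lt(e2, e1)          # error shrinks with dt
  expect_lt(e4, e2)
  expect_gt(e1 / e2, 1.6)    # ~first order: halving dt roughly halves error
  expect_lt(e1 / e2, 2.6)
})

test_that("compiled and reference engines agree bit-for-bit", {
  sc <- csd_scenario(
    params = csd_params(F = 0.1), nrow = 12, ncol = 12,
    modulated_region = region_rect(2, 5, 7, 11),
    stimuli = list(stimulus_event(0, 2, region_disk(6.5, 6.5, 2))),
    blocks = list(block_event(1, 3, region_rect(9, 10, 2, 6)),
                  block_event(2, 4, region_rect(2, 3, 2, 3),
                              mode = "insulate")),
    probes = tibble::tibble(name = c("a", "b"), row = c(3, 10), col = c(9, 3)),
    t_end = 6, probe_stride = 1L, snapshot_stride = 10L, snapshot_R = TRUE)
  rc <- csd_simulate(sc, engine = "compiled")
  rr <- csd_simulate(sc, engine = "reference")
  expect_identical(rc$K, rr$K)
  expect_identical(rc$R, rr$R)
  expect_identical(rc$probes, rr$probes)
  expect_identical(rc$snapshots$K, rr$snapshots$K)
  expect_identical(rc$snapshots$R, rr$snapshots$R)
})

test_that("insulated blocks seal their faces (no flux through walls)", {
  p <- csd_params(A = 0, B = 0, C = 0, E = 0)  # pure diffusion
  n <- 12
  walls <- matrix(FALSE, n, n); walls[5:8, 5:8] <- TRUE
  set.seed(11)
  K <- matrix(runif(n * n, 0, 1), n, n)
  inside0 <- K[walls]
  outside0 <- sum(K[!walls])
  st <- csd_state(K, matrix(p$R_rest, n, n))
  for (i in 1:100) st <- csd_step(st, p, insulated = walls)
  expect_identical(st$K[walls], inside0)                    # frozen
  expect_equal(sum(st$K[!walls]), outside0, tolerance = 1e-13)  # sealed
})

test_that("a centrally stimulated run keeps exact 4-fold symmetry", {
  sc <- make_scenario("homogeneous", t_end = 150)
  run <- csd_simulate(sc)
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  expect_lt(max(abs(run$K - rot90(run$K))), 1e-10)
  expect_lt(max(abs(run$K - rot90(rot90(run$K)))), 1e-10)
  expect_lt(max(abs(run$R - rot90(run$R))), 1e-10)
})
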