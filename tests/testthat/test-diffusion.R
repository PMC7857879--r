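test_that("block averaging redistributes mass within blocks and conserves it", {
  # uniform field is a fixed point
  u <- matrix(0.8, 9, 9)
  expect_equal(block_average(u, 0), u)
  # a single 9 in one block spreads to 1.0 over its nine sites
  m <- matrix(0, 6, 6)
  m[1, 1] <- 9
  b <- block_average(m, 0)
  expect_equal(b[1:3, 1:3], matrix(1, 3, 3))
  expect_equal(b[4:6, ], matrix(0, 3, 6))
  # conservation on random fields for every partition shift, wrapped sizes too
  set.seed(42)
  for (n in c(6, 7, 101)) {
    f <- matrix(stats::rexp(n * n), n, n)
    for (t in 0:3)
      expect_equal(sum(block_average(f, t)), sum(f), tolerance = 1e-9)
  }
  expect_error(block_average(matrix(0, 3, 6), 0), "square")
})

test_that("block averaging matches the explicit partition oracle", {
  set.seed(7)
  for (n in c(6, 7, 8)) {
    f <- matrix(stats::runif(n * n), n, n)
    for (t in 0:2)
      expect_equal(block_average(f, t), brute_block_average(f, t))
  }
})

test_that("the shifting schedule transports mass beyond the original block", {
  p <- small_params(ncell = 9,
                    alpha = c(o2 = 1 - 1e-9, gl = 0.5, h = 0.5,
                              gf = 0.5, if_ = 0.5))
  g <- tumor_grid(9)                      # empty: no sinks anywhere
  g$empty[] <- TRUE
  f <- metabolic_fields(p)
  f$o2[] <- 0
  f$o2[2, 2] <- 9                         # point mass inside block (1,1)
  for (t in 0:2) f <- diffusion_step(f, g, p, t)
  expect_gt(sum(f$o2[4:9, ]) + sum(f$o2[1:3, 4:9]), 0)
  expect_equal(sum(f$o2), 9, tolerance = 1e-9)
})

test_that("one diffusion step matches the site-by-site oracle on a 6x6 lattice", {
  set.seed(11)
  p <- small_params(ncell = 6)
  g <- tumor_grid(6)
  g$states[] <- sample(0:3, 36, replace = TRUE)
  g$mutant[g$states == 1L] <- TRUE
  f <- metabolic_fields(p)
  f$o2[] <- stats::runif(36, 0, 1)
  f$gl[] <- stats::runif(36, 0, 6)
  f$h[] <- stats::runif(36, 1e-8, 1e-6)
  for (t in 0:2) {
    got <- diffusion_step(f, g, p, t)
    want <- brute_diffusion_step(f, g, p, t)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("diffusion limits behave: strong mixing reproduces the block mean, weak mixing freezes", {
  g <- tumor_grid(9)
  g$empty[] <- TRUE                       # no cells, no sinks
  p_hi <- small_params(ncell = 9, alpha = c(o2 = 1 - 1e-12, gl = 0.5,
                                            h = 0.5, gf = 0.5, if_ = 0.5))
  p_lo <- small_params(ncell = 9, alpha = c(o2 = 1e-12, gl = 0.5, h = 0.5,
                                            gf = 0.5, if_ = 0.5))
  f <- metabolic_fields(p_hi)
  f$o2[] <- stats::runif(81)
  hi <- diffusion_step(f, g, p_hi, 0)
  expect_equal(hi$o2, block_average(f$o2, 0), tolerance = 1e-9)
  lo <- diffusion_step(f, g, p_lo, 0)
  expect_equal(lo$o2, f$o2, tolerance = 1e-9)
})

test_that("cell metabolism encodes the per-type consumption and production rules", {
  p <- small_params(ncell = 5)
  g <- tumor_grid(5)
  f <- metabolic_fields(p)
  # sites: necrotic, empty, aerobic PC, anaerobic PC, quiescent, normal
  g$states[1, 1] <- 3L
  g$empty[2, 2] <- TRUE
  g$states[3, 3] <- 1L                  # aerobic (background O2)
  g$states[4, 4] <- 1L
  f$o2[4, 4] <- 0.01                    # below O2_thre: anaerobic
  g$states[5, 5] <- 2L
  inc <- cell_metabolism(g, f, p)
  # necrotic: no uptake, still acidifying
  expect_equal(inc$o2[1, 1], 0)
  expect_equal(inc$gl[1, 1], 0)
  expect_lt(inc$h[1, 1], 0)
  # empty: inert
  expect_equal(inc$o2[2, 2], 0)
  expect_equal(inc$h[2, 2], 0)
  q_o2 <- p$rate_scale * p$Cr_o2
  q_gl <- p$rate_scale * p$Cr_gl
  expect_equal(inc$o2[3, 3], q_o2)
  expect_equal(inc$gl[3, 3], q_gl)
  # anaerobic switch: more glucose and acid, less oxygen
  expect_equal(inc$gl[4, 4], p$k_gl_anaerobic * q_gl)
  expect_equal(inc$o2[4, 4], p$k_o2_anaerobic * q_o2)
  expect_equal(inc$h[4, 4], p$k_H_anaerobic * inc$h[3, 3])
  # quiescent cells are damped versions of proliferating ones
  expect_equal(inc$o2[5, 5], p$quiescent_factor * q_o2)
  # normal tissue consumes oxygen/glucose but produces no acid
  expect_equal(inc$o2[1, 2], p$modulation_normal * q_o2)
  expect_equal(inc$h[1, 2], 0)
})

test_that("uptake is truncated so fields never go negative", {
  p <- small_params(ncell = 6)
  g <- grid_with_square(6, 2)             # dense tumor
  f <- metabolic_fields(p)
  f$o2[] <- 1e-12                         # almost exhausted
  inc <- cell_metabolism(g, f, p)
  expect_true(all(inc$o2 <= f$o2 + 1e-15))
  for (t in 0:5) f <- diffusion_step(f, g, p, t)
  for (nm in names(f)) expect_true(all(f[[nm]] >= 0))
})

test_that("medium replenishment restores background at normal sites only", {
  p <- small_params(ncell = 9)
  g <- tumor_grid(9)
  g$states[4:6, 4:6] <- 1L
  f <- metabolic_fields(p)
  f$o2[] <- 0.01
  f$gl[] <- 0.01
  f$h[] <- 1e-6
  f2 <- replenish_medium(f, g, p)
  normal <- g$states == 0L
  expect_true(all(f2$o2[normal] >= 0.95 * p$c0))
  expect_true(all(f2$gl[normal] >= 0.95 * p$g0))
  expect_true(all(f2$h[normal] <= h_from_ph(p$pH0) / 0.95))
  # tumor sites untouched
  expect_equal(f2$o2[!normal], f$o2[!normal])
  expect_equal(f2$h[!normal], f$h[!normal])
  # a lattice at exact background is a fixed point
  f3 <- metabolic_fields(p)
  expect_equal(replenish_medium(f3, g, p), f3)
})

test_that("boundary replenishment mode only feeds the outer ring", {
  p <- small_params(ncell = 9, replenish_mode = "boundary")
  g <- tumor_grid(9)
  f <- metabolic_fields(p)
  f$o2[] <- 0.01
  f2 <- replenish_medium(f, g, p)
  expect_true(all(f2$o2[c(1, 9), ] >= 0.95 * p$c0))
  expect_equal(f2$o2[2:8, 2:8], f$o2[2:8, 2:8])
})
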