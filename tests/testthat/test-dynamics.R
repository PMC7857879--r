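test_that("microenvironmental classification follows the threshold hierarchy", {
  p <- tumor_params()
  r <- classify_microenvironment(
    o2 = c(0.5, 0.015, 0.005, 0.5, 0.5),
    gl = c(5.0, 5.0, 5.0, 5.0, 0.02),
    ph = c(7.3, 7.3, 7.3, 5.9, 7.3), p)
  expect_equal(r$verdict,
               c("proliferation_permitted",  # everything above threshold
                 "quiescence_trigger",       # 0.015 < O2_thre = 0.02
                 "necrosis_trigger",         # 0.005 < O2_thre2 = 0.01
                 "necrosis_trigger",         # pH 5.9 < 6
                 "necrosis_trigger"))        # gl 0.02 < gl_thre2 = 0.03
  expect_equal(r$anaerobic, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # quiescence band for glucose
  q <- classify_microenvironment(0.5, 0.05, 7.3, p)
  expect_equal(q$verdict, "quiescence_trigger")
})

test_that("division probability has the stated values, bounds and monotonicity", {
  p <- tumor_params()
  expect_equal(division_probability(TRUE, 0, 0, p), 0.7)
  expect_equal(division_probability(FALSE, 0, 8, p), 0.6)
  expect_equal(division_probability(FALSE, 0, 0, p), 0)
  expect_equal(division_probability(TRUE, p$Rmax, 8, p), 0)
  expect_equal(division_probability(FALSE, p$Rmax + 5, 8, p), 0)
  # halved at half the maximum radius, scaled by the neighbor fraction
  expect_equal(division_probability(TRUE, p$Rmax / 2, 0, p), 0.35)
  expect_equal(division_probability(FALSE, p$Rmax / 2, 4, p),
               0.6 * 0.5 * 0.5)
  r <- seq(0, 40, by = 0.5)
  for (mut in c(TRUE, FALSE)) {
    pr <- division_probability(mut, r, 5, p)
    expect_true(all(diff(pr) <= 0))
    expect_true(all(pr >= 0 & pr <= 1))
  }
  pn <- division_probability(FALSE, 10, 0:8, p)
  expect_true(all(diff(pn) >= 0))
  expect_error(division_probability(TRUE, -1, 4, p), "non-negative")
  expect_error(division_probability(TRUE, 1, 9, p), "0..8")
})

test_that("empirical division frequency matches the analytic probability", {
  # Monte-Carlo check at 1e5 draws: a mutant PC at distance r with free
  # neighbors divides with frequency p0 * (1 - r/Rmax) within 3 SE.
  p <- tumor_params(ncell = 7, stall_limit = 1000L)
  g <- tumor_grid(7)
  site <- c(4L, 5L)                       # r = 1 from the center
  g$states[site[1], site[2]] <- 1L
  g$mutant[site[1], site[2]] <- TRUE
  prob <- division_probability(TRUE, 1, 8, p)
  n <- 1e5
  set.seed(123)
  hits <- 0L
  for (k in seq_len(n)) {
    out <- attempt_mitosis(site, g, p)
    hits <- hits + (sum(out$states == 1L) == 2L)
  }
  se <- sqrt(prob * (1 - prob) / n)
  expect_lt(abs(hits / n - prob), 3 * se)
})

test_that("mitosis places daughters on free neighbors and inherits phenotype via Nmm", {
  base <- tumor_params(ncell = 7, p0 = 1)   # certain division at r = 0
  g <- tumor_grid(7)
  g$states[4, 4] <- 1L
  g$mutant[4, 4] <- TRUE
  set.seed(1)
  # Nmm = 0: every daughter of a mutant is mutant
  p0nmm <- tumor_params_set(base, Nmm = 0)
  for (k in 1:50) {
    out <- attempt_mitosis(c(4L, 4L), g, p0nmm)
    d <- which(out$states == 1L & g$states != 1L)
    expect_length(d, 1L)
    expect_true(out$mutant[d])
  }
  # Nmm = 1: every daughter is nonmutant
  p1nmm <- tumor_params_set(base, Nmm = 1)
  for (k in 1:50) {
    out <- attempt_mitosis(c(4L, 4L), g, p1nmm)
    d <- which(out$states == 1L & g$states != 1L)
    expect_false(out$mutant[d])
  }
  # daughters land on state-0 sites only, parent stays
  out <- attempt_mitosis(c(4L, 4L), g, base)
  expect_equal(out$states[4, 4], 1L)
  expect_equal(sum(out$states == 1L), 2L)
  expect_error(attempt_mitosis(c(1L, 1L), g, base), "does not hold a PC")
})

test_that("a fully surrounded PC stalls and eventually falls quiescent", {
  p <- tumor_params(ncell = 7, stall_limit = 3L)
  g <- grid_with_square(7, 1)               # 3x3 tumor block: center enclosed
  for (k in 1:2) {
    g <- attempt_mitosis(c(4L, 4L), g, p)
    expect_equal(g$states[4, 4], 1L)
    expect_equal(g$stall[4, 4], k)
  }
  g <- attempt_mitosis(c(4L, 4L), g, p)
  expect_equal(g$states[4, 4], 2L)          # stalled out -> quiescent
  expect_equal(g$stall[4, 4], 0L)           # counter cleared on transition
})

test_that("quiescent cells recover with nutrients or at the rim, die deep in the core", {
  p <- tumor_params()
  g <- grid_with_square(101, 8)             # 17x17 tumor square
  f <- metabolic_fields(p)
  gm <- compute_geometry(8, p)              # Rt = 8: Wp = 0.44, Rn = 7.14
  starved <- f
  starved$o2[] <- 0.015                     # below O2_thre everywhere
  # deep QC without nutrients turns necrotic
  g$states[53, 51] <- 2L                    # r = 2 < Rn
  expect_equal(update_quiescent(c(53L, 51L), g, starved, gm, p), 3L)
  # same site with abundant nutrients recovers instead
  expect_equal(update_quiescent(c(53L, 51L), g, f, gm, p), 1L)
  # rim QC recovers even when starved (within Wp of the radius)
  g$states[59, 51] <- 2L                    # r = 8 >= Rt - Wp
  expect_equal(update_quiescent(c(59L, 51L), g, starved, gm, p), 1L)
  # mid-layer starved QC above Rn stays quiescent:
  # radius between Rn (11.00) and Rt - Wp (11.42) at Rt = 12
  gm2 <- compute_geometry(12, p)
  g$states[51 + 11, 51 + 2] <- 2L           # r = sqrt(121 + 4) = 11.18
  expect_equal(update_quiescent(c(62L, 53L), g, starved, gm2, p), 2L)
  expect_error(update_quiescent(c(1L, 1L), g, f, gm, p), "does not hold a QC")
})

test_that("necrosis is applied from the thresholds and is absorbing", {
  p <- tumor_params(ncell = 9)
  g <- tumor_grid(9)
  f <- metabolic_fields(p)
  g$states[2, 2] <- 3L                      # necrotic stays necrotic
  g$states[3, 3] <- 1L                      # PC in lethal acid
  f$h[3, 3] <- h_from_ph(5.5)
  g$states[4, 4] <- 2L                      # QC in anoxia
  f$o2[4, 4] <- 0.001
  f$o2[5, 5] <- 0.001                       # normal cell under anoxia
  g$states[6, 6] <- 1L                      # healthy PC survives
  g2 <- apply_necrosis(g, f, p)
  expect_equal(g2$states[2, 2], 3L)
  expect_equal(g2$states[3, 3], 3L)
  expect_equal(g2$states[4, 4], 3L)
  expect_equal(g2$states[5, 5], 0L)         # apoptosis: empty space
  expect_true(g2$empty[5, 5])
  expect_equal(g2$states[6, 6], 1L)
  # "necrotic" mode routes dead normal cells into the necrotic count
  p2 <- tumor_params(ncell = 9, normal_death = "necrotic")
  g3 <- apply_necrosis(g, f, p2)
  expect_equal(g3$states[5, 5], 3L)
})

test_that("full runs only use legal state transitions and keep necrosis absorbing", {
  p <- small_params(n_iter = 60, seed = 5, Rmax = 12)
  set.seed(5)
  st <- initialize_simulation(p)
  prev <- st$grid$states
  nec_prev <- 0L
  legal <- rbind(c(0L, 1L), c(1L, 2L), c(1L, 3L), c(2L, 1L), c(2L, 3L))
  for (t in 1:60) {
    st <- simulation_step(st$grid, st$fields, p, t)
    cur <- st$grid$states
    changed <- which(cur != prev)
    if (length(changed)) {
      tr <- unique(cbind(prev[changed], cur[changed]))
      for (k in seq_len(nrow(tr)))
        expect_true(any(tr[k, 1] == legal[, 1] & tr[k, 2] == legal[, 2]),
                    label = sprintf("transition %d->%d", tr[k, 1], tr[k, 2]))
    }
    # necrosis never reverses and never shrinks
    expect_true(all(cur[prev == 3L] == 3L))
    nec_now <- sum(cur == 3L)
    expect_gte(nec_now, nec_prev)
    nec_prev <- nec_now
    prev <- cur
  }
})

test_that("with Nmm = 0 and a mutant seed the nonmutant population never appears", {
  p <- small_params(Nmm = 0, n_iter = 40, Rmax = 12)
  sim <- run_simulation(p, seed = 3)
  expect_true(all(sim$record$n_pc_nonmutant == 0))
})
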