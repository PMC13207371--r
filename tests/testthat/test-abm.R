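test_that("named neighborhoods have the standard offset sets", {
  vn <- neighborhood_spec("von_neumann")
  expect_equal(vn$omega, 4)
  off <- neighborhood_offsets(vn)
  expect_setequal(paste(off[, 1], off[, 2]), c("-1 0", "1 0", "0 -1", "0 1"))
  expect_equal(neighborhood_spec("moore")$omega, 8)
  vn2 <- neighborhood_spec("von_neumann2")
  expect_equal(vn2$omega, 12)
  off2 <- neighborhood_offsets(vn2)
  expect_true(all(abs(off2[, 1]) + abs(off2[, 2]) <= 2))
  m2 <- neighborhood_spec("moore2")
  expect_equal(m2$omega, 24)
  expect_true(all(pmax(abs(m2$offsets[, 1]), abs(m2$offsets[, 2])) <= 2))
  expect_error(neighborhood_spec("custom", offsets = rbind(c(0, 0), c(1, 0))),
               "exclude")
  expect_error(neighborhood_spec("custom", offsets = rbind(c(1, 0), c(1, 0))),
               "duplicate")
})

test_that("identical seeds give bit-identical trajectories", {
  p <- abm_params(lam = 0.2, delta = 0.01, m = 0.5, seed = 99)
  r1 <- run_abm(24, 24, p, init = "center", steps = 80)
  r2 <- run_abm(24, 24, p, init = "center", steps = 80)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final_state$occupancy, r2$final_state$occupancy)
  p2 <- abm_params(lam = 0.2, delta = 0.01, m = 0.5, seed = 100)
  r3 <- run_abm(24, 24, p2, init = "center", steps = 80)
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("exclusion and conservation hold along ABM runs", {
  p <- abm_params(lam = 0.3, delta = 0.05, m = 1, seed = 5)
  r <- run_abm(16, 16, p, init = 30, steps = 150)
  expect_true(all(r$trajectory$n <= 16 * 16))
  expect_true(all(r$final_state$occupancy %in% c(0, 1)))
  expect_equal(sum(r$final_state$occupancy), tail(r$trajectory$n, 1))
  # no birth, no death: constant population
  p0 <- abm_params(lam = 0, delta = 0, m = 1, seed = 5)
  r0 <- run_abm(16, 16, p0, init = 30, steps = 50)
  expect_true(all(r0$trajectory$n == 30))
  # no death: nondecreasing population
  pg <- abm_params(lam = 0.2, delta = 0, m = 0, seed = 5)
  rg <- run_abm(16, 16, pg, init = "center", steps = 100)
  expect_true(all(diff(rg$trajectory$n) >= 0))
})

test_that("a full lattice without death stays full and fully blocked", {
  occ <- matrix(1L, 8, 8)
  p <- abm_params(lam = 0.5, delta = 0, m = 1, seed = 2)
  r <- run_abm(8, 8, p, init = occ, steps = 20)
  expect_true(all(r$trajectory$n == 64))
  expect_true(all(r$trajectory$blocked == 64))
  expect_true(all(r$trajectory$surface == 0))
})

test_that("early ABM growth matches the branching-process mean", {
  # while n << l and no crowding, E[n(t)] = n0 * (1 + lam*dt)^t
  lam <- 0.1; steps <- 25
  finals <- vapply(1:40, function(s) {
    p <- abm_params(lam = lam, delta = 0, m = 1,
                    migration_nbhd = neighborhood_spec("full_domain"), seed = 500 + s)
    r <- run_abm(51, 51, p, init = "center", steps = steps)
    tail(r$trajectory$n, 1)
  }, 0)
  expected <- (1 + lam)^steps
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3.5 * se + 0.05 * expected)
})

test_that("blocked fraction and surface count agree with direct constructions", {
  # single isolated cell
  occ <- matrix(0L, 10, 10); occ[5, 5] <- 1L
  st <- lattice_state(occ)
  vn <- neighborhood_spec("von_neumann")
  expect_equal(blocked_fraction(st, vn), 0)
  expect_equal(surface_cell_count(st, vn), 1)
  # full periodic lattice
  stf <- lattice_state(matrix(1L, 6, 6))
  expect_equal(blocked_fraction(stf, vn), 1)
  expect_equal(blocked_fraction(stf, vn, "per_lattice"), 1)
  expect_equal(surface_cell_count(stf, vn), 0)
  # solid 10x10 block on a 30x30 lattice: perimeter cells are the surface
  occ <- matrix(0L, 30, 30); occ[11:20, 11:20] <- 1L
  stb <- lattice_state(occ)
  expect_equal(surface_cell_count(stb, vn), 36)
  expect_equal(blocked_fraction(stb, vn), 64 / 100)
  expect_error(blocked_fraction(lattice_state(matrix(0L, 4, 4)), vn), "empty")
})

test_that("per-cell blocked fraction of random well-mixed states matches the hypergeometric value", {
  l <- 64 * 64; n <- l / 2
  vn <- neighborhood_spec("von_neumann")
  set.seed(31)
  fr <- vapply(1:20, function(i) {
    occ <- matrix(0L, 64, 64)
    occ[sample.int(l, n)] <- 1L
    blocked_fraction(lattice_state(occ), vn)
  }, 0)
  exact <- blocked_prob_wellmixed(n, l, 4)
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - exact), 3 * se)
})

test_that("C++ per-step blocked counts agree with the R matrix estimator", {
  p <- abm_params(lam = 0.2, delta = 0, m = 0.3, seed = 77)
  r <- run_abm(20, 20, p, init = "center", steps = 60)
  st <- r$final_state
  expect_equal(tail(r$trajectory$blocked, 1),
               round(blocked_fraction(st, p$birth_nbhd) * st$n))
  expect_equal(tail(r$trajectory$surface, 1),
               surface_cell_count(st, p$birth_nbhd))
})

test_that("fractal dimension estimates recover constructed geometries", {
  expect_equal(fractal_dimension_estimate(100, 100, 2), 2)  # all surface
  expect_equal(fractal_dimension_estimate(100, 36, 2), 2 * log(36) / log(100))
  # compact discs approach D = d - 1 from above as they grow
  dhat <- vapply(c(5, 15, 50), function(rad) {
    sz <- 2 * rad + 5
    occ <- matrix(0L, sz, sz)
    ctr <- (sz + 1) / 2
    for (i in 1:sz) for (j in 1:sz)
      if ((i - ctr)^2 + (j - ctr)^2 <= rad^2) occ[i, j] <- 1L
    st <- lattice_state(occ, boundary = "closed")
    fractal_dimension_estimate(st$n, surface_cell_count(st, neighborhood_spec("von_neumann")), 2)
  }, 0)
  expect_true(all(diff(dhat) < 0))
  expect_gt(dhat[3], 1)
  expect_error(fractal_dimension_estimate(1, 1, 2), "exceed 1")
})

test_that("ensemble summary computes pointwise means and SDs", {
  t1 <- data.frame(time = 0:5, n = 0:5)
  t2 <- data.frame(time = 0:5, n = 0:5 + 2)
  s <- ensemble_summary(list(t1, t2))
  expect_equal(s$mean, 0:5 + 1)
  expect_equal(s$sd, rep(sqrt(2), 6))
  s0 <- ensemble_summary(list(t1, t1, t1))
  expect_true(all(s0$sd == 0))
  expect_error(ensemble_summary(list(t1, data.frame(time = 0:4, n = 0:4))),
               "common time grid")
})

test_that("larger birth neighborhoods grow faster without migration", {
  mean_final <- function(kind) {
    mean(vapply(1:6, function(s) {
      p <- abm_params(lam = 0.1, delta = 0, m = 0,
                      birth_nbhd = neighborhood_spec(kind), seed = 600 + s)
      tail(run_abm(41, 41, p, init = "center", steps = 150)$trajectory$n, 1)
    }, 0))
  }
  n_vn <- mean_final("von_neumann")
  n_m2 <- mean_final("moore2")
  expect_gt(n_m2, n_vn)
})

test_that("with full-domain migration the birth neighborhood no longer matters", {
  curve <- function(kind, seeds) {
    sapply(seeds, function(s) {
      p <- abm_params(lam = 0.1, delta = 0, m = 1,
                      birth_nbhd = neighborhood_spec(kind),
                      migration_nbhd = neighborhood_spec("full_domain"),
                      seed = s)
      run_abm(32, 32, p, init = 10, steps = 100)$trajectory$n
    })
  }
  c4 <- curve("von_neumann", 701:710)
  c24 <- curve("moore2", 711:720)
  sd_band <- apply(cbind(c4, c24), 1, stats::sd)
  gap <- abs(rowMeans(c4) - rowMeans(c24))
  expect_true(all(gap <= pmax(2 * sd_band, 3)))
})

test_that("Gillespie chain respects absorbing and saturated states", {
  # saturated: birth rate vanishes at n = l, delta = 0: no events
  tr <- wellmixed_gillespie(100, 4, 0.5, 0, 100, 50, seed = 1)
  expect_equal(nrow(tr), 1)
  # pure death process mean: n0 * exp(-delta t)
  finals <- vapply(1:200, function(s) {
    tr <- wellmixed_gillespie(1000, 4, 0, 0.1, 200, 10, seed = 900 + s)
    f <- stats::stepfun(tr$time[-1], tr$n)
    f(10)
  }, 0)
  expected <- 200 * exp(-1)
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3.5 * se)
})

test_that("empirical drift matches the generator of the chain", {
  l <- 2000
  runs <- lapply(1:10, function(s)
    wellmixed_gillespie(l, 4, 0.1, 0.01, 20, 120, seed = 40 + s))
  a_fun <- function(u) 0.1 * u * (1 - u^4) - 0.01 * u
  dd <- empirical_drift_diffusion(runs, l, u_bins = seq(0.2, 0.8, 0.15),
                                  dt_window = 0.25, drift_fun = a_fun)
  ok <- !is.na(dd$a_hat)
  expect_true(any(ok))
  expect_true(all(abs(dd$a_hat[ok] - dd$a_ref[ok]) <= 3.5 * dd$a_se[ok]))
  # drift cancels when birth and death rates balance (omega -> 0 limit: constant rates)
  runs0 <- lapply(1:10, function(s)
    wellmixed_gillespie(l, 0, 0.1, 0.1, 1000, 60, seed = 80 + s))
  # omega = 0 blocks all births (u^0 = 1), so use matched constant rates instead:
  # pure-death vs pure-birth symmetry is covered above; here check near-zero drift
  dd0 <- empirical_drift_diffusion(runs0, l, u_bins = c(0.3, 0.7), dt_window = 0.5)
  if (!is.na(dd0$a_hat[1])) {
    expect_lt(abs(dd0$a_hat[1] - (-0.1 * dd0$u_mean[1])), 3.5 * dd0$a_se[1])
  }
})
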