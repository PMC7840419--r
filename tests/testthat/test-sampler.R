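test_that("free chain reproduces the ideal-chain mean squared end-to-end distance", {
  z <- load_chain_spec("zeta")
  run <- run_sampler(z, membrane = "none", seed = 42,
                     config = sampler_config(n_record = 15000))
  r2 <- rowSums(sweep(run$end_xyz[, 1:3, drop = FALSE], 2, z$anchor)^2)
  n_eff <- 2000  # conservative effective sample size for the SE
  se <- sd(r2) / sqrt(n_eff)
  expect_lt(abs(mean(r2) - 113 * 0.3^2), 3 * se)
})

test_that("hard-wall constraint holds for every recorded sample", {
  ch <- load_chain_spec("epsilon")
  run <- run_sampler(ch, membrane = "hard", seed = 7,
                     config = sampler_config(n_record = 5000))
  expect_true(all(run$site_z >= 0))
  expect_true(all(run$beads[, 3] >= -1e-9))
})

test_that("adaptive step drives the long-run acceptance rate to 0.44", {
  z <- load_chain_spec("zeta")
  run <- run_sampler(z, membrane = "hard", seed = 43,
                     config = sampler_config(n_record = 15000))
  expect_lt(abs(run$acc_rate - 0.44), 0.02)
})

test_that("seeded runs are bit-reproducible", {
  ch <- load_chain_spec("delta")
  cfg <- sampler_config(n_record = 2000)
  r1 <- run_sampler(ch, membrane = "hard", seed = 5, config = cfg)
  r2 <- run_sampler(ch, membrane = "hard", seed = 5, config = cfg)
  expect_identical(r1$site_z, r2$site_z)
  expect_identical(r1$occ, r2$occ)
  r3 <- run_sampler(ch, membrane = "hard", seed = 6, config = cfg)
  expect_false(identical(r1$site_z, r3$site_z))
})

test_that("pivot proposals preserve bond lengths and rigid segments exactly", {
  ch <- load_chain_spec("epsilon")
  conf <- initial_conformation(ch)
  anchors <- matrix(ch$anchor, 1)
  rigid <- matrix(c(1, 10, 20), 1)
  set.seed(1)
  cur <- conf
  for (i in 1:50) cur <- propose_move(cur, anchors, step_size = 0.8, rigid = rigid)
  coords <- rbind(ch$anchor, cur[[1]])
  bonds <- sqrt(rowSums(diff(coords)^2))
  expect_equal(max(abs(bonds - 0.3)), 0, tolerance = 1e-9)
  # rigid segment stays collinear
  seg <- cur[[1]][10:20, ]
  v <- diff(seg)
  v <- v / sqrt(rowSums(v^2))
  expect_lt(max(abs(sweep(v, 2, v[1, ]))), 1e-9)
  # zero-perturbation limit: candidate equals current conformation
  same <- propose_move(cur, anchors, step_size = 0)
  expect_equal(same[[1]], cur[[1]], tolerance = 1e-12)
})

test_that("stiffened windows are sampled as straight rods", {
  z <- load_chain_spec("zeta")
  run <- run_sampler(z, membrane = "hard", phospho = z$sites[1:2],
                     stiffen_w = 5, seed = 9,
                     config = sampler_config(n_record = 2000))
  beads <- run$beads
  for (s in z$sites[1:2]) {
    seg <- beads[(s - 5):(s + 5), ]
    v <- diff(seg)
    v <- v / sqrt(rowSums(v^2))
    expect_lt(max(abs(sweep(v, 2, v[1, ]))), 1e-6)
  }
})

test_that("quarter-wise KS convergence check distinguishes stationary from drifting", {
  set.seed(10)
  stationary <- rnorm(4000)
  expect_true(check_convergence(stationary)$converged)
  drifting <- rnorm(4000) + seq(0, 3, length.out = 4000)
  expect_false(check_convergence(drifting)$converged)
  expect_error(check_convergence(rnorm(50)), "too short")
})

test_that("KS statistic matches the hand-computed empirical-CDF gap", {
  # two explicit small samples; max ECDF gap computed by enumeration
  a <- c(0.1, 0.2, 0.6, 0.8)
  b <- c(0.3, 0.4, 0.5, 0.9)
  grid <- sort(c(a, b))
  gap <- max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x), 0)))
  expect_equal(unname(stats::ks.test(a, b)$statistic), gap)
  expect_equal(gap, 0.5)
})

test_that("step adaptation is monotone and freezes at the target", {
  s <- list(step_size = 1, acceptance = 1.0)
  expect_gt(adapt_step(s)$step_size, 1)
  s$acceptance <- 0
  expect_lt(adapt_step(s)$step_size, 1)
  s$acceptance <- 0.44
  expect_equal(adapt_step(s)$step_size, 1)
})

test_that("one-bead tether obeys the Boltzmann weight (quadrature oracle)", {
  # single bead on a sphere of radius 0.3 about the anchor, soft membrane,
  # phosphotyrosine repulsion: height density prop. to exp(-E_P0 e^{-z})
  ch <- chain_spec("t1", 1, sites = 1)
  pot <- membrane_params(E_P0 = 3)
  run <- run_sampler(ch, membrane = "soft", potentials = pot,
                     phospho = 1, seed = 21,
                     probe_sites = cbind(1, 1), probe_radius = 0.1,
                     config = sampler_config(n_record = 40000))
  z <- run$site_z[, 1]
  # free joint: z uniform on [-0.3, 0.3]; weight by the Boltzmann factor
  zz <- seq(-0.3, 0.3, length.out = 4001)
  w <- exp(-(3 * exp(-zz / 1) + ifelse(zz < 0, 0.05 * zz^2, 0)))
  mean_th <- sum(zz * w) / sum(w)
  n_eff <- 3000
  expect_lt(abs(mean(z) - mean_th), 3 * sd(z) / sqrt(n_eff))
})

test_that("anchored free-end height matches direct rejection sampling", {
  n_res <- 4
  ch <- chain_spec("t4", n_res, sites = n_res)
  run <- run_sampler(ch, membrane = "hard", seed = 31,
                     probe_sites = cbind(1, n_res), probe_radius = 0.1,
                     config = sampler_config(n_record = 30000))
  set.seed(32)
  oracle <- fjc_rejection_sample(n_res, 4000)
  z_mc <- run$site_z[seq(1, nrow(run$site_z), by = 15), 1]
  ks <- stats::ks.test(z_mc, oracle[, n_res, 3])
  expect_gt(ks$p.value, 0.001)
})
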