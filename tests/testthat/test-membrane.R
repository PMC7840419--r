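test_that("residue potentials take their defining values", {
  p <- membrane_params(E_B0 = 0.8, E_P0 = 2, z_debye = 1)
  expect_equal(residue_potential(0, "basic", p), -0.8)
  expect_equal(residue_potential(1, "phosphotyrosine", p), 2 / exp(1))
  expect_equal(residue_potential(0.5, "other", p), 0)
  expect_equal(residue_potential(-0.5, "other", p), 0.05 * 0.25)
  expect_error(residue_potential(0, "weird", p), "unknown residue class")
})

test_that("the basic potential is continuous at its crossover height", {
  for (E in c(0.3, 0.5, 1)) {
    p <- membrane_params(E_B0 = E)
    zc <- sqrt(E / p$k_PC)
    expect_equal(zc, 1)  # default pins the crossover to 1 nm
    eps <- 1e-9
    below <- residue_potential(zc - eps, "basic", p)
    above <- residue_potential(zc + eps, "basic", p)
    expect_lt(abs(below - above), 1e-6)
    expect_equal(above, 0)
  }
  # crossover scales as sqrt(E_B0 / k_PC) when the stiffness is explicit
  p2 <- membrane_params(E_B0 = 2, k_PC = 8)
  expect_equal(residue_potential(0.5 - 1e-9, "basic", p2), 8 * 0.25 - 2,
               tolerance = 1e-6)
  expect_equal(residue_potential(0.5 + 1e-9, "basic", p2), 0)
})

test_that("height density is normalised and tightens as E_B0 grows", {
  e <- load_chain_spec("epsilon")
  vars <- numeric(3)
  for (i in seq_along(c(0, 0.5, 1))) {
    E <- c(0, 0.5, 1)[i]
    run <- run_sampler(e, "soft", potentials = membrane_params(E_B0 = E),
                       probe_sites = cbind(1, e$sites[1]), probe_radius = 2.1,
                       seed = 22, config = sampler_config(n_record = 12000))
    d <- tyrosine_height_density(run, 1)
    dz <- diff(d$mids)[1]
    expect_equal(sum(d$density) * dz, 1, tolerance = 1e-9)
    vars[i] <- d$variance
  }
  expect_true(all(diff(vars) < 0))
})

test_that("zero-potential anchored chain matches the rejection-sampling oracle", {
  n_res <- 5
  ch <- chain_spec("t5", n_res, sites = n_res)
  run <- run_sampler(ch, "hard", probe_sites = cbind(1, n_res),
                     probe_radius = 0.3, seed = 23,
                     config = sampler_config(n_record = 24000))
  set.seed(24)
  oracle <- fjc_rejection_sample(n_res, 4000)
  z_mc <- run$site_z[seq(1, nrow(run$site_z), by = 12), 1]
  expect_gt(stats::ks.test(z_mc, oracle[, n_res, 3])$p.value, 0.001)
})

test_that("analytic repulsion bound is linear and uses fixture counts", {
  e <- load_chain_spec("epsilon")
  expect_equal(phospho_repulsion_bound(length(e$basics), length(e$sites), 0.5),
               3.5)
  expect_equal(phospho_repulsion_bound(0, 2, 0.5), 0)
  expect_equal(phospho_repulsion_bound(14, 2, 1.0),
               2 * phospho_repulsion_bound(14, 2, 0.5))
  expect_error(phospho_repulsion_bound(5, 0, 1), "positive")
})

test_that("confinement calibration finds the threshold crossing on a stiff toy", {
  # two-bead tether: variance of the end height falls with E_B0 (the end
  # bead is basic); quadrature oracle locates the 50% threshold crossing
  ch <- chain_spec("t2b", 2, sites = 2, basics = c(1, 2))
  grid <- seq(0, 30, by = 3)
  cal <- calibrate_EB0(ch, grid = grid, threshold_frac = 0.5, seed = 25,
                       config = sampler_config(n_record = 12000))
  expect_true(cal$E_B0_min %in% grid)
  # oracle: direct 2-bead sampling under the Boltzmann weight
  set.seed(26)
  n <- 4e5
  u1 <- matrix(rnorm(3 * n), ncol = 3); u1 <- 0.3 * u1 / sqrt(rowSums(u1^2))
  u2 <- matrix(rnorm(3 * n), ncol = 3); u2 <- 0.3 * u2 / sqrt(rowSums(u2^2))
  z1 <- u1[, 3]; z2 <- z1 + u2[, 3]
  Ez <- function(z, E) if (E == 0) 0 * z else ifelse(z < 1, E * z^2 - E, 0)
  oracle_var <- vapply(grid, function(E) {
    w <- exp(-(Ez(z1, E) + Ez(z2, E)))  # both beads are basic residues
    sum(w * z2^2) / sum(w) - (sum(w * z2) / sum(w))^2
  }, 0)
  hit <- which(oracle_var < 0.5 * oracle_var[1])
  # agreement within one grid step
  expect_lte(abs(cal$E_B0_min - grid[min(hit)]), 3)
})

test_that("phosphotyrosine repulsion restores the free height distribution
          below the analytic bound for epsilon", {
  e <- load_chain_spec("epsilon")
  cal <- calibrate_EP0(e, E_B0 = 0.5, grid = c(0, 1, 2, 3.5), seed = 28,
                       config = sampler_config(n_record = 15000))
  # no repulsion cannot undo the basic-residue attraction
  expect_gt(cal$ks_stat[1], cal$ks_stat[3])
  # the best-matching repulsion sits at or below the energy-balance bound
  bound <- phospho_repulsion_bound(length(e$basics), length(e$sites), 0.5)
  expect_lte(cal$best, bound)
  if (!is.na(cal$E_P0_min)) expect_lte(cal$E_P0_min, bound)
})
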