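test_that("single-configuration probe test matches closed-form sphere geometry", {
  # one-bead chain at the origin-adjacent position, one obstacle bead
  conf <- list(rbind(c(0, 0, 1), c(0, 0, 1.3)))
  # probe at site 1 pointing +x: centre (0.4, 0, 1); obstacle bead 2 at
  # distance sqrt(0.4^2 + 0.3^2) = 0.5 > 0.4 -> clear of beads and membrane
  expect_false(probe_occluded(conf, c(1, 1), 0.4, direction = c(1, 0, 0)))
  # larger probe: centre (0.6,0,1); bead 2 at sqrt(.36+.09)=.67>.6; but the
  # membrane blocks once the centre height (1) drops below the radius
  expect_false(probe_occluded(conf, c(1, 1), 0.6, direction = c(1, 0, 0)))
  expect_true(probe_occluded(conf, c(1, 1), 1.05, direction = c(1, 0, 0)))
  # pointing at the obstacle
  expect_true(probe_occluded(conf, c(1, 1), 0.2, direction = c(0, 0, 1)))
  # excluding the neighbour window clears it
  expect_false(probe_occluded(conf, c(1, 1), 0.2, direction = c(0, 0, 1),
                              exclude = 1))
  # membrane geometry: site low above wall blocks a downward probe
  expect_true(probe_occluded(conf, c(1, 1), 0.8, direction = c(0, 0, -1)))
  # bound ligand sphere blocks
  expect_true(probe_occluded(conf, c(1, 1), 0.3, direction = c(1, 0, 0),
                             ligand_centers = rbind(c(1, 0, 1)),
                             ligand_radii = 0.5))
})

test_that("occlusion probability is non-decreasing in probe radius", {
  ch <- load_chain_spec("gamma")
  p <- vapply(c(0.5, 1.0, 2.1, 3.4), function(r) {
    run <- run_sampler(ch, "hard", probe_sites = cbind(1, ch$sites[1]),
                       probe_radius = r, probe_exclude = 1, seed = 17,
                       config = sampler_config(n_record = 5000))
    mean(run$occ)
  }, 0)
  expect_true(all(diff(p) >= -0.02))  # allow tiny MC jitter
})

test_that("pipeline occlusion matches the brute-force rejection-sampling oracle", {
  # 3-bead chain above a hard wall, probe at the free end, no exclusion
  n_res <- 3
  ch <- chain_spec("t3", n_res, sites = n_res)
  run <- run_sampler(ch, "hard", probe_sites = cbind(1, n_res),
                     probe_radius = 0.45, probe_exclude = 0,
                     probe_placement = "tangent", seed = 18,
                     config = sampler_config(n_record = 30000))
  est <- estimate_occlusion(run, 1)
  set.seed(19)
  beads <- fjc_rejection_sample(n_res, 30000)
  p_oracle <- occlusion_oracle(beads, n_res, 0.45)
  sem_o <- sqrt(p_oracle * (1 - p_oracle) / 30000)
  expect_lt(abs(est$p_occ - p_oracle), 4 * sqrt(est$sem^2 + sem_o^2) + 0.005)
})

test_that("rates follow k_on = (1 - P_occ) k_on0", {
  expect_equal(rate_from_occlusion(0), 1)
  expect_equal(rate_from_occlusion(1), 0)
  expect_equal(rate_from_occlusion(0.25, k_on0 = 4), 3)
  # dissociation-constant ratio between two states
  kd_ratio <- rate_from_occlusion(0.5) / rate_from_occlusion(0.75)
  expect_equal(1 / kd_ratio, 0.5)
  expect_error(rate_from_occlusion(1.2), "0, 1")
})

test_that("estimate_occlusion refuses non-converged ensembles unless forced", {
  run <- list(converged = FALSE, occ = matrix(0L, 10, 1), probe_radius = 1)
  expect_error(estimate_occlusion(run, 1), "not converged")
  expect_equal(estimate_occlusion(run, 1, force = TRUE)$p_occ, 0)
})

test_that("evenly spaced cytosolic sites have mirror-symmetric rates", {
  ch <- chain_spec("sym", 40, sites = c(10, 20, 30))
  tab <- build_rate_table(ch, probe_radius = 1.2, membrane = "none",
                          seed = 20, states = 0L,
                          config = sampler_config(n_record = 15000))
  r <- tab$rates[1, ]
  sem <- tab$sem[1, ]
  # site 1 at 10 from anchor end, site 3 at 10 from the free end
  expect_lt(abs(r[1] - r[3]), 4 * sqrt(sem[1]^2 + sem[3]^2) + 0.01)
})

test_that("rate tables enumerate the full phosphostate space with metadata", {
  ch <- chain_spec("toy2", 12, sites = c(4, 8))
  tab <- build_rate_table(ch, probe_radius = 0.8, membrane = "hard",
                          seed = 21, config = sampler_config(n_record = 2000))
  expect_equal(dim(tab$rates), c(4L, 2L))
  expect_false(tab$partial)
  expect_true(all(tab$rates >= 0 & tab$rates <= 1, na.rm = TRUE))
  # direction masking: phosphorylation only toward unmodified sites
  kin <- tcrtails:::rate_matrix(tab, "phosphorylate")
  expect_equal(kin[4, ], c(0, 0))          # state 11: nothing to phosphorylate
  pho <- tcrtails:::rate_matrix(tab, "dephosphorylate")
  expect_equal(pho[1, ], c(0, 0))          # state 00: nothing to remove
  expect_equal(pho[2, 2], 0)               # state 01: site 2 not modified
})
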