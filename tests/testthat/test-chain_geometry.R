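test_that("packaged TCR tail fixtures satisfy their structural landmarks", {
  z <- load_chain_spec("zeta")
  expect_equal(z$n_residues, 113)
  expect_length(z$sites, 6)
  expect_equal(z$sites[1], 21)                      # proximal: 21 from anchor
  expect_equal(z$sites[6], z$n_residues - 12)       # distal: 12 from C-terminus
  expect_equal(z$sites[5], 83)                      # second-to-last tyrosine
  e <- load_chain_spec("epsilon")
  expect_equal(e$n_residues, 55)
  expect_length(e$sites, 2)
  expect_length(e$basics, 14)
  expect_equal(load_chain_spec("delta")$n_residues, 47)
  expect_equal(load_chain_spec("gamma")$n_residues, 45)
  for (nm in c("zeta", "epsilon", "delta", "gamma")) {
    ch <- load_chain_spec(nm)
    expect_true(all(diff(ch$sites) > 0))
    expect_true(all(ch$sites >= 1 & ch$sites <= ch$n_residues))
    expect_true(all(ch$basics >= 1 & ch$basics <= ch$n_residues))
  }
})

test_that("chain_spec validation names the offending field", {
  expect_error(chain_spec("x", 0, sites = integer()), "n_residues")
  expect_error(chain_spec("x", 10, sites = c(3, 12)), "sites")
  expect_error(chain_spec("x", 10, sites = c(5, 3)), "strictly increasing")
  expect_error(chain_spec("x", 10, sites = 5, basics = 11), "basics")
  expect_error(chain_spec("x", 10, sites = 5, anchor = c(0, 0, 1)), "membrane")
  expect_error(load_chain_spec("not-a-chain"), "unknown chain")
})

test_that("a synthetic evenly spaced chain has uniform inter-site gaps", {
  ch <- generate_fixture("toy-chain", list(n_residues = 6L, n_sites = 2L))
  expect_s3_class(ch, "chain_spec")
  expect_true(length(unique(diff(c(0, ch$sites)))) == 1)
})

test_that("sphere radius from molecular mass inverts the sphere volume", {
  # mass chosen so the volume equals that of a 2.1 nm sphere
  vol <- 4 / 3 * pi * 2.1^3
  mass <- vol * 1.41e-21 * 6.02214076e23 / 1000
  expect_equal(radius_from_mass(mass), 2.1, tolerance = 1e-12)
  # volume 1 nm^3
  mass1 <- 1 * 1.41e-21 * 6.02214076e23 / 1000
  expect_equal(radius_from_mass(mass1), (3 / (4 * pi))^(1 / 3),
               tolerance = 1e-12)
  # scaling law and monotonicity
  expect_equal(radius_from_mass(2 * 50) / radius_from_mass(50), 2^(1 / 3))
  m <- seq(1, 200, length.out = 50)
  expect_true(all(diff(radius_from_mass(m)) > 0))
  # composing with the volume recovers the mass
  r <- radius_from_mass(77)
  mass_back <- 4 / 3 * pi * r^3 * 1.41e-21 * 6.02214076e23 / 1000
  expect_equal(mass_back, 77, tolerance = 1e-9)
  expect_error(radius_from_mass(-1), "positive")
})

test_that("packaged ligands have the expected radii and roles", {
  expect_equal(load_ligand_spec("LCK")$radius, 2.1)
  expect_equal(load_ligand_spec("ZAP70")$radius, 2.7)
  expect_equal(load_ligand_spec("CD45")$radius, 3.4)
  expect_equal(load_ligand_spec("LCK")$role, "kinase")
})

test_that("the six-chain TCR assembly has 10 ITAM sites and 20 tyrosines", {
  tcr <- assemble_receptor("tcr-narrow")
  expect_length(tcr$chains, 6)
  sites <- assembly_sites <- tcrtails:::assembly_sites(tcr, use_itam = TRUE)
  expect_equal(nrow(sites), 10)
  n_tyr <- sum(vapply(tcr$chains, function(ch) length(ch$sites), 0L))
  expect_equal(n_tyr, 20)
  # narrow layout: nearest-neighbour anchor spacing ~1.5 nm
  d <- as.matrix(dist(tcr$anchors))
  diag(d) <- Inf
  expect_equal(min(d), 1.5, tolerance = 1e-9)
  expect_true(all(abs(tcr$anchors[, 3]) < 1e-12))
})

test_that("circle layouts space anchors evenly; errors on mismatch", {
  chains <- replicate(10, generate_fixture("toy-chain", list(n_residues = 20L, n_sites = 1L)),
                      simplify = FALSE)
  a <- assemble_receptor(list(type = "circle", radius = 5), chains)
  expect_equal(nrow(a$anchors), 10)
  r <- sqrt(rowSums(a$anchors[, 1:2]^2))
  expect_equal(r, rep(5, 10))
  gaps <- sqrt(rowSums((a$anchors[c(2:10, 1), ] - a$anchors)^2))
  expect_equal(max(gaps) - min(gaps), 0, tolerance = 1e-9)
  one <- assemble_receptor(list(type = "circle", radius = 3), chains[1])
  expect_equal(sqrt(sum(one$anchors[1, 1:2]^2)), 3)
  expect_error(assemble_receptor(matrix(0, 2, 3), chains[1]), "does not match")
})

test_that("chain fixtures round-trip through the YAML definition format", {
  chains <- lapply(c("zeta", "epsilon", "delta", "gamma"), load_chain_spec)
  f <- tempfile(fileext = ".yaml")
  write_chain_yaml(chains, f)
  back <- read_chain_yaml(f)
  for (i in seq_along(chains)) {
    for (fld in c("name", "n_residues", "kuhn_length", "sites", "site_kind",
                  "basics", "itam_centers")) {
      expect_identical(back[[i]][[fld]], chains[[i]][[fld]],
                       info = paste(chains[[i]]$name, fld))
    }
  }
  # and the rewritten file is byte-identical to a second write
  f2 <- tempfile(fileext = ".yaml")
  write_chain_yaml(back, f2)
  write_chain_yaml(chains, f)
  expect_identical(readLines(f), readLines(f2))
})
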