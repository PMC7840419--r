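test_that("equal rates make all modification orders equiprobable (1/720 null)", {
  tab <- generate_fixture("rate-table", list(n_sites = 6L, rate = 0.5))
  st <- simulate_sequences(tab, "phosphorylate", n_runs = 1e5, seed = 2)
  expect_equal(sum(st$probabilities), 1)
  expect_equal(length(st$probabilities), 720)
  obs <- st$probabilities * st$n_runs
  chi <- sum((obs - st$n_runs / 720)^2 / (st$n_runs / 720))
  expect_gt(pchisq(chi, df = 719, lower.tail = FALSE), 0.001)
})

test_that("competing exponentials: rates (9, 1) give P(site 1 first) = 0.9", {
  K <- matrix(0, 4, 2)
  K[1, ] <- c(9, 1); K[2, 2] <- 1; K[3, 1] <- 9
  tab <- toy_table(K, 2)
  st <- simulate_sequences(tab, "phosphorylate", n_runs = 2e5, seed = 3)
  p1 <- sum(st$probabilities[startsWith(names(st$probabilities), "1")])
  expect_lt(abs(p1 - 0.9), 3 * sqrt(0.9 * 0.1 / 2e5))
})

test_that("3-site state-dependent table matches the exhaustive path enumeration", {
  set.seed(4)
  K <- matrix(runif(8 * 3, 0.2, 2), 8, 3)
  for (s in 0:7) {  # zero out already-modified sites
    occ <- bitwAnd(s, 2^(0:2)) > 0
    K[s + 1, occ] <- 0
  }
  oracle <- enumerate_paths(K, 3)
  tab <- toy_table(K, 3)
  st <- simulate_sequences(tab, "phosphorylate", n_runs = 2e5, seed = 5)
  for (ord in names(oracle$probs)) {
    p <- oracle$probs[[ord]]
    se <- sqrt(p * (1 - p) / 2e5)
    expect_lt(abs(sequence_probability(st, ord) - p), 4 * se + 1e-4)
  }
  # path-weighted step rates match 1 / (path-weighted mean waiting time)
  for (k in 1:3) {
    expect_equal(path_weighted_rate(st, k), 1 / mean(st$waits[, k]),
                 tolerance = 1e-12)
    expect_lt(abs(mean(st$waits[, k]) - oracle$step_wait[k]),
              4 * sd(st$waits[, k]) / sqrt(2e5))
  }
})

test_that("path-weighted and unweighted step rates agree for state-independent rates", {
  tab <- generate_fixture("rate-table", list(n_sites = 3L, rate = 0.7))
  st <- simulate_sequences(tab, "phosphorylate", n_runs = 5e4, seed = 6)
  for (k in 1:3) {
    pw <- path_weighted_rate(st, k, "path-weighted")
    uw <- path_weighted_rate(st, k, "unweighted")
    # both equal the total exit rate (3, 2, 1 sites) x 0.7
    expect_equal(uw, (3 - k + 1) * 0.7, tolerance = 1e-9)
    expect_lt(abs(pw - uw) / uw, 0.02)
  }
  # and they differ for a biased, state-dependent table
  set.seed(7)
  K <- matrix(runif(8 * 3, 0.1, 3), 8, 3)
  for (s in 0:7) K[s + 1, bitwAnd(s, 2^(0:2)) > 0] <- 0
  stb <- simulate_sequences(toy_table(K, 3), "phosphorylate",
                            n_runs = 5e4, seed = 8)
  expect_gt(abs(path_weighted_rate(stb, 2, "path-weighted") -
                path_weighted_rate(stb, 2, "unweighted")), 1e-3)
})

test_that("waiting times are exponential with the correct total rate", {
  tab <- generate_fixture("rate-table", list(n_sites = 3L, rate = 0.5))
  st <- simulate_sequences(tab, "phosphorylate", n_runs = 2e4, seed = 9)
  w1 <- st$waits[, 1]  # first step leaves the empty state: total rate 1.5
  ks <- stats::ks.test(w1, "pexp", rate = 1.5)
  expect_gt(ks$p.value, 0.001)
})

test_that("label reversal of a symmetric table leaves the sequence law invariant", {
  tab <- generate_fixture("rate-table", list(n_sites = 3L, rate = 1))
  st <- simulate_sequences(tab, "phosphorylate", n_runs = 1e5, seed = 10)
  p123 <- sequence_probability(st, "123")
  p321 <- sequence_probability(st, "321")
  expect_lt(abs(p123 - p321), 4 * sqrt((1 / 6) * (5 / 6) / 1e5))
})

test_that("absorbing states are reported as errors", {
  K <- matrix(0, 4, 2)
  K[1, ] <- c(1, 0)  # site 2 can never be modified from state {1}
  tab <- toy_table(K, 2)
  expect_error(simulate_sequences(tab, "phosphorylate", n_runs = 10, seed = 11),
               "absorbing")
})

test_that("reversible cycle: symmetric single-site system balances at one half", {
  tab <- generate_fixture("rate-table", list(n_sites = 1L, rate = 1))
  dr <- reversible_steady_state(tab, "constant", ratio_grid = c(0.25, 1, 4),
                                n_events = 2e5, seed = 12)
  expect_lt(abs(dr$response[2] - 0.5), 0.01)
  # and detailed balance: response at ratio r mirrors 1 - response at 1/r
  expect_lt(abs(dr$response[1] - (1 - dr$response[3])), 0.02)
})

test_that("2-site reversible cycle matches the analytic stationary distribution", {
  set.seed(13)
  K <- matrix(runif(4 * 2, 0.3, 2), 4, 2)
  for (s in 0:3) K[s + 1, bitwAnd(s, 2^(0:1)) > 0] <- 0
  tab <- toy_table(K, 2)
  pho <- matrix(0, 4, 2)
  for (s in 0:3) pho[s + 1, bitwAnd(s, 2^(0:1)) > 0] <- 1
  for (r in c(0.5, 1.7)) {
    kin <- tcrtails:::rate_matrix(tab, "phosphorylate")
    exact <- stationary_mean_frac(kin, pho, r, 2)
    dr <- reversible_steady_state(tab, "constant", ratio_grid = r,
                                  n_events = 4e5, seed = 14)
    expect_lt(abs(dr$response - exact), 0.01)
  }
})

test_that("Hill extraction recovers known curve shapes", {
  r <- 10^seq(-3, 3, length.out = 25)
  mm <- list(ratio = r, response = r / (1 + r))
  h1 <- hill_coefficient(mm, "max-log-slope")
  expect_equal(h1$hill, 1, tolerance = 0.02)
  expect_equal(h1$ec50, 1, tolerance = 0.02)
  expect_equal(hill_coefficient(mm, "log-ec")$hill, 1, tolerance = 0.02)
  hill2 <- list(ratio = r, response = r^2 / (1 + r^2))
  expect_equal(hill_coefficient(hill2, "max-log-slope")$hill, 2, tolerance = 0.03)
  expect_equal(hill_coefficient(hill2, "log-ec")$hill, 2, tolerance = 0.03)
})

test_that("piecewise-linear toy curve gives the hand-computed maximal slope", {
  # log-odds rises with slope 0.5 then 3 then 0.5 on the log-ratio grid
  x <- c(-2, -1, 0, 1, 2)
  logodds <- c(-2, -1.5, 1.5, 2, 2.5)
  f <- 10^logodds / (1 + 10^logodds)
  toy <- list(ratio = 10^x, response = f)
  slopes <- diff(logodds) / diff(x)   # 0.5 3 0.5 0.5
  h <- hill_coefficient(toy, "max-log-slope")
  # central finite differences cap at (0.5+3)/2 = 1.75
  expect_equal(h$hill, 1.75, tolerance = 0.3)
  expect_error(hill_coefficient(list(ratio = c(1, 2), response = c(0, 0))),
               "transition")
})
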