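# Residue-membrane interaction potentials and their calibration.
#
# Three residue classes interact with the inner leaflet:
#   basic residues      E(z) = k_PC z^2 - E_B0  below the crossover height
#                       sqrt(E_B0 / k_PC), 0 above it (piecewise parabolic
#                       attractive well);
#   phosphotyrosines    E(z) = E_P0 exp(-z / z_debye) (screened repulsion);
#   everything else     E(z) = k_S z^2 for z < 0, 0 otherwise (soft wall).
# Energies are in kBT, heights in nm.

#' Membrane interaction parameters
#'
#' By default the crossover height of the basic-residue well is pinned to
#' 1 nm (one Debye length): `k_PC = E_B0` per nm^2, so that
#' `sqrt(E_B0 / k_PC) = 1`.
#'
#' @param E_B0 basic-residue well depth (kBT).
#' @param k_PC parabolic stiffness (kBT / nm^2); `NULL` pins the crossover
#'   height to 1 nm.
#' @param E_P0 phosphotyrosine repulsion strength (kBT).
#' @param z_debye Debye screening length (nm).
#' @param k_S soft-wall stiffness (kBT / nm^2).
#' @return list of parameters (class `membrane_params`).
#' @export
membrane_params <- function(E_B0 = 0, k_PC = NULL, E_P0 = 0, z_debye = 1,
                            k_S = 0.05) {
  if (is.null(k_PC)) k_PC <- if (E_B0 > 0) E_B0 else 1
  stopifnot(E_B0 >= 0, k_PC > 0, E_P0 >= 0, z_debye > 0, k_S >= 0)
  structure(list(E_B0 = E_B0, k_PC = k_PC, E_P0 = E_P0, z_debye = z_debye,
                 k_S = k_S), class = "membrane_params")
}

#' Per-residue membrane potential
#'
#' @param z height(s) above the membrane (nm; may be negative).
#' @param residue_class `"basic"`, `"phosphotyrosine"` or `"other"`.
#' @param params a [membrane_params()].
#' @return energy in kBT (vectorised over `z`).
#' @export
residue_potential <- function(z, residue_class, params = membrane_params()) {
  switch(residue_class,
    basic = {
      zc <- sqrt(params$E_B0 / params$k_PC)
      ifelse(z < zc, params$k_PC * z^2 - params$E_B0, 0)
    },
    phosphotyrosine = params$E_P0 * exp(-z / params$z_debye),
    other = ifelse(z < 0, params$k_S * z^2, 0),
    stop("unknown residue class: ", residue_class, call. = FALSE))
}

#' Height density of a probed site
#'
#' Normalised histogram of a site bead's height above the membrane, with the
#' series variance (the confinement summary used by the calibration
#' routines).
#'
#' @param run a [run_sampler()] result.
#' @param site probe-site index (column of the run).
#' @param breaks passed to [graphics::hist()] logic via [base::cut()]; number
#'   of equal-width bins.
#' @param force use a non-converged run anyway.
#' @return list with `mids`, `density`, `variance`, `mean`.
#' @export
tyrosine_height_density <- function(run, site = 1, breaks = 60, force = FALSE) {
  if (!run$converged && !force)
    stop("ensemble not converged; pass force = TRUE to override", call. = FALSE)
  z <- run$site_z[, site]
  h <- hist(z, breaks = breaks, plot = FALSE)
  list(mids = h$mids, density = h$density, variance = stats::var(z),
       mean = mean(z), z = z)
}

#' Minimal basic-residue attraction that confines the first tyrosine
#'
#' Sweeps `E_B0` over a grid (soft-wall membrane, unphosphorylated chain) and
#' returns the smallest value whose first-tyrosine height variance falls
#' below `threshold_frac` of the free (`E_B0 = 0`) variance.
#'
#' @param chain a [chain_spec()].
#' @param grid increasing `E_B0` values; must start at 0.
#' @param threshold_frac confinement criterion as a fraction of the free
#'   variance.
#' @param seed integer seed.
#' @param config a [sampler_config()].
#' @return list with `E_B0_min`, `grid`, `variance` per grid point, and the
#'   free-variance `reference`.
#' @export
calibrate_EB0 <- function(chain, grid = seq(0, 1, by = 0.1),
                          threshold_frac = 0.5, seed = 1L,
                          config = sampler_config()) {
  stopifnot(grid[1] == 0, !is.unsorted(grid))
  vars <- numeric(length(grid))
  for (i in seq_along(grid)) {
    run <- run_sampler(chain, membrane = "soft",
                       potentials = membrane_params(E_B0 = grid[i]),
                       probe_sites = cbind(1, chain$sites[1]),
                       probe_radius = 2.1, seed = seed + i,
                       config = config)
    vars[i] <- stats::var(run$site_z[, 1])
  }
  ref <- vars[1]
  hit <- which(vars < threshold_frac * ref)
  if (!length(hit))
    stop("confinement transition not bracketed by the grid", call. = FALSE)
  list(E_B0_min = grid[min(hit)], grid = grid, variance = vars,
       reference = ref, threshold = threshold_frac * ref)
}

#' Minimal phosphotyrosine repulsion that undoes membrane association
#'
#' With the chain fully phosphorylated and `E_B0` fixed, sweeps `E_P0` and
#' returns the smallest value for which the first-tyrosine height
#' distribution is statistically indistinguishable (two-sample KS test at
#' `alpha`) from the free reference (`E_B0 = 0`, unphosphorylated).
#'
#' @param chain a [chain_spec()].
#' @param E_B0 fixed basic-residue well depth.
#' @param grid increasing `E_P0` values.
#' @param alpha KS significance level.
#' @param seed integer seed.
#' @param config a [sampler_config()].
#' @param max_points KS subsample size per series.
#' @return list with `E_P0_min` (or `NA` if no grid value passes),
#'   `best` (closest KS statistic), `grid`, `ks_stat` per grid point.
#' @export
calibrate_EP0 <- function(chain, E_B0 = 0.5, grid = seq(0, 10, by = 0.5),
                          alpha = 0.05, seed = 1L,
                          config = sampler_config(), max_points = 400) {
  stopifnot(!is.unsorted(grid))
  ref_run <- run_sampler(chain, membrane = "soft",
                         potentials = membrane_params(E_B0 = 0),
                         probe_sites = cbind(1, chain$sites[1]),
                         probe_radius = 2.1, seed = seed, config = config)
  sub <- function(z) z[unique(as.integer(round(seq(1, length(z),
                                                   length.out = min(max_points, length(z))))))]
  zref <- sub(ref_run$site_z[, 1])
  ks <- numeric(length(grid))
  for (i in seq_along(grid)) {
    run <- run_sampler(chain, membrane = "soft",
                       potentials = membrane_params(E_B0 = E_B0, E_P0 = grid[i]),
                       phospho = chain$sites,
                       probe_sites = cbind(1, chain$sites[1]),
                       probe_radius = 2.1, seed = seed + 1000 + i,
                       config = config)
    ks[i] <- suppressWarnings(
      unname(stats::ks.test(sub(run$site_z[, 1]), zref)$statistic))
  }
  n <- length(zref)
  thr <- sqrt(-log(alpha / 2) / 2) * sqrt(2 / n)
  hit <- which(ks < thr)
  list(E_P0_min = if (length(hit)) grid[min(hit)] else NA_real_,
       best = grid[which.min(ks)], grid = grid, ks_stat = ks,
       threshold = thr)
}

#' Analytic lower bound on the phosphotyrosine repulsion
#'
#' Energy-balance bound: full phosphorylation can offset the basic-residue
#' membrane attraction only if `E_P0 >= (n_basic / n_tyrosine) * E_B0`.
#'
#' @param n_basic number of basic residues.
#' @param n_tyrosine number of tyrosines (> 0).
#' @param E_B0 basic-residue well depth (kBT).
#' @return minimal `E_P0` in kBT.
#' @export
phospho_repulsion_bound <- function(n_basic, n_tyrosine, E_B0) {
  if (n_tyrosine <= 0) stop("n_tyrosine must be positive", call. = FALSE)
  n_basic / n_tyrosine * E_B0
}
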