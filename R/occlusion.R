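# Occlusion probabilities and entropic binding rates.
#
# The dissociation constant of a tethered binding reaction changes between
# chain states purely through the probability that the region of space the
# ligand needs is sterically free: K_D1 / K_D2 = (1 - P_occ2) / (1 - P_occ1).
# Assuming the change falls entirely on the association rate, the relative
# on-rate in a state is k_on = (1 - P_occ) * k_on0, with k_on0 the free-space
# rate. All rates are reported in units of k_on0.

#' Geometric occlusion test for a single configuration
#'
#' The probe sphere is placed with its surface touching the site bead, its
#' centre at distance `probe_radius` along `direction`. The site is occluded
#' if the probe overlaps the membrane half-space, any other chain bead, or
#' any bound ligand sphere.
#'
#' @param conformation list of per-chain bead matrices.
#' @param site `c(chain, residue)` of the probed site.
#' @param probe_radius probe sphere radius (nm).
#' @param direction unit placement direction (default: straight up).
#' @param membrane logical: is a membrane present at z = 0?
#' @param ligand_centers,ligand_radii optional bound-ligand spheres.
#' @param exclude contour half-width around the site whose residues are not
#'   treated as obstacles (the peptide engulfed by the ligand's groove).
#' @return logical: is the probe blocked?
#' @export
probe_occluded <- function(conformation, site, probe_radius,
                           direction = c(0, 0, 1), membrane = TRUE,
                           ligand_centers = NULL, ligand_radii = NULL,
                           exclude = 0) {
  stopifnot(probe_radius > 0)
  bead <- conformation[[site[1]]][site[2], ]
  ctr <- bead + probe_radius * direction / sqrt(sum(direction^2))
  if (membrane && ctr[3] < probe_radius) return(TRUE)
  for (c in seq_along(conformation)) {
    d2 <- rowSums(sweep(conformation[[c]], 2, ctr)^2)
    if (c == site[1]) {
      win <- max(1, site[2] - exclude):min(nrow(conformation[[c]]), site[2] + exclude)
      d2[win] <- Inf
    }
    if (any(d2 < probe_radius^2)) return(TRUE)
  }
  if (!is.null(ligand_centers) && length(ligand_radii)) {
    for (l in seq_len(nrow(ligand_centers))) {
      if (sum((ligand_centers[l, ] - ctr)^2) < (probe_radius + ligand_radii[l])^2)
        return(TRUE)
    }
  }
  FALSE
}

#' Occlusion probability of a probed site
#'
#' Fraction of recorded samples in which the probe sphere at the site was
#' blocked, with the binomial standard error.
#'
#' @param run a [run_sampler()] result whose probes included the site.
#' @param site probe-site column index.
#' @param force use a non-converged ensemble anyway.
#' @return list with `p_occ`, `sem`, `n_samples`, `probe_radius`.
#' @export
estimate_occlusion <- function(run, site = 1, force = FALSE) {
  if (!run$converged && !force)
    stop("ensemble not converged; pass force = TRUE to override", call. = FALSE)
  x <- run$occ[, site]
  n <- length(x)
  p <- mean(x)
  list(p_occ = p, sem = sqrt(p * (1 - p) / n), n_samples = n,
       probe_radius = run$probe_radius)
}

#' Relative binding rate from an occlusion probability
#'
#' @param p_occ occlusion probability in `[0, 1]`.
#' @param k_on0 free-space binding rate (default 1: rates in units of k_on0).
#' @return on-rate `(1 - p_occ) * k_on0`.
#' @export
rate_from_occlusion <- function(p_occ, k_on0 = 1) {
  if (any(p_occ < 0 | p_occ > 1)) stop("p_occ must lie in [0, 1]", call. = FALSE)
  (1 - p_occ) * k_on0
}

#' Build the occlusion-derived rate table over all phosphostates
#'
#' Runs one converged sampler per phosphostate of a single chain (2^n_sites
#' states) and records, for every state and every site, the occlusion
#' probability of a ligand-sized probe and the relative binding rate
#' `(1 - P_occ)` in units of k_on0. Each phosphorylation may rigidify a
#' window of `2 * stiffen_w + 1` residues around its site (overlapping
#' windows merge), and phosphorylated tyrosines switch to the repulsive
#' membrane potential when potentials are active.
#'
#' @param chain a [chain_spec()].
#' @param probe_radius ligand probe radius (nm).
#' @param probe_exclude contour half-width excluded around probed sites
#'   (see [run_sampler()]).
#' @param membrane,potentials,stiffen_w forwarded to [run_sampler()].
#' @param seed integer seed; state `s` uses `seed + s`.
#' @param config a [sampler_config()].
#' @param states optional subset of state bitmasks (0-based) to compute.
#' @return object of class `rate_table`: matrices `p_occ`, `sem`, `rates`
#'   (2^n x n, rows indexed by state bitmask + 1), `converged` flags, and
#'   metadata. Tables with any non-converged member run are marked partial.
#' @export
build_rate_table <- function(chain, probe_radius = 2.1, membrane = "hard",
                             potentials = membrane_params(), stiffen_w = 0,
                             probe_exclude = NULL,
                             probe_placement = c("tangent", "centered", "normal"),
                             seed = 1L,
                             config = sampler_config(), states = NULL) {
  probe_placement <- match.arg(probe_placement)
  n <- length(chain$sites)
  n_states <- 2L^n
  if (is.null(states)) states <- 0:(n_states - 1L)
  p_occ <- matrix(NA_real_, n_states, n)
  sem <- matrix(NA_real_, n_states, n)
  conv <- rep(NA, n_states)
  for (s in states) {
    ph_idx <- which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) > 0L)
    run <- suppressWarnings(run_sampler(
      chain, membrane = membrane, potentials = potentials,
      phospho = chain$sites[ph_idx], stiffen_w = stiffen_w,
      probe_sites = cbind(1, chain$sites), probe_radius = probe_radius,
      probe_exclude = probe_exclude, probe_placement = probe_placement,
      seed = seed + s, config = config))
    p_occ[s + 1L, ] <- colMeans(run$occ)
    sem[s + 1L, ] <- sqrt(p_occ[s + 1L, ] * (1 - p_occ[s + 1L, ]) / nrow(run$occ))
    conv[s + 1L] <- run$converged
  }
  structure(list(chain = chain$name, n_sites = n, sites = chain$sites,
                 p_occ = p_occ, sem = sem, rates = 1 - p_occ,
                 converged = conv,
                 partial = any(!conv, na.rm = TRUE) || anyNA(conv),
                 meta = list(probe_radius = probe_radius, membrane = membrane,
                             stiffen_w = stiffen_w, seed = seed,
                             n_record = config$n_record)),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> %s: %d states x %d sites (probe %.2f nm%s)%s\n",
              x$chain, nrow(x$rates), x$n_sites, x$meta$probe_radius,
              if (x$meta$stiffen_w > 0)
                sprintf(", stiffening w = %d", x$meta$stiffen_w) else "",
              if (x$partial) " [PARTIAL]" else ""))
  invisible(x)
}

# Direction-specific rate matrix: entries toward applicable sites only
# (phosphorylation acts on unmodified sites, dephosphorylation on modified
# ones); inapplicable entries are zero.
rate_matrix <- function(table, direction = c("phosphorylate", "dephosphorylate")) {
  direction <- match.arg(direction)
  n <- table$n_sites
  out <- table$rates
  for (s in 0:(nrow(out) - 1L)) {
    occ <- bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) > 0L
    keep <- if (direction == "phosphorylate") !occ else occ
    out[s + 1L, !keep] <- 0
  }
  out
}
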