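# Multi-ligand simultaneous binding on multi-chain receptors: packing
# feasibility, per-event binding-rate decline, and site-distribution designs.

#' Number of distinct k-th binding transitions
#'
#' With `n_bound` ligands already bound to `n_sites` sites, the next binding
#' event can happen in `choose(n_sites, n_bound) * (n_sites - n_bound)` ways
#' (choice of predecessor bound-set times choice of target site).
#'
#' @param n_sites total binding sites.
#' @param n_bound ligands already bound (`0 <= n_bound < n_sites`).
#' @return transition count.
#' @export
count_transition_configs <- function(n_sites, n_bound) {
  if (any(n_bound < 0) || any(n_bound >= n_sites))
    stop("n_bound must satisfy 0 <= n_bound < n_sites", call. = FALSE)
  choose(n_sites, n_bound) * (n_sites - n_bound)
}

# Tilted straight-chain + side-sphere starting configuration for the packing
# search. Chains lean outward along their anchor azimuth; tethered spheres sit
# perpendicular to the chain, alternating sides along a chain, blended upward
# far enough to clear the membrane.
.packing_init <- function(assembly, sites, radius, tilt = 0.96, jitter = 0,
                          rng = NULL) {
  chains <- assembly$chains
  geo <- .build_geometry(chains)
  M <- sum(geo$chain_len)
  beads <- matrix(0, M, 3)
  dirs <- vector("list", length(chains))
  for (c in seq_along(chains)) {
    a <- chains[[c]]$anchor
    phi <- atan2(a[2], a[1])
    if (jitter > 0) phi <- phi + stats::runif(1, -jitter, jitter)
    th <- tilt + if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
    d <- c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
    dirs[[c]] <- d
    k <- seq_len(chains[[c]]$n_residues)
    beads[geo$offsets[c] + k, ] <- cbind(a[1] + geo$kuhn * k * d[1],
                                         a[2] + geo$kuhn * k * d[2],
                                         a[3] + geo$kuhn * k * d[3])
  }
  lig_u <- matrix(0, nrow(sites), 3)
  ord <- stats::ave(seq_len(nrow(sites)), sites[, 1], FUN = seq_along)
  for (l in seq_len(nrow(sites))) {
    c <- sites[l, 1]
    d <- dirs[[c]]
    side <- c(-d[2], d[1], 0)
    ns <- sqrt(sum(side^2))
    side <- if (ns > 1e-9) side / ns else c(1, 0, 0)
    side <- side * (-1)^ord[l]
    z_site <- beads[geo$offsets[c] + sites[l, 2], 3]
    multi <- sum(sites[, 1] == c) > 1
    uz <- max(0.4, (radius - z_site) / radius + 0.15)
    if (uz > 0.95) uz <- 0.95
    out <- c(cos(atan2(d[2], d[1])), sin(atan2(d[2], d[1])), 0)
    horiz <- if (multi) side else out
    w <- sqrt(1 - uz^2)
    u <- c(horiz[1] * w, horiz[2] * w, uz)
    if (jitter > 0 && !is.null(rng)) {
      u <- u + stats::rnorm(3, sd = 0.15)
      u <- u / sqrt(sum(u^2))
    }
    lig_u[l, ] <- u
  }
  list(beads = beads, lig_u = lig_u, geo = geo)
}

#' Independent validator for a packed configuration
#'
#' Plain-R check of every hard constraint: exact bond lengths, beads above
#' the membrane, no bead inside any ligand sphere (tether beads sit exactly
#' on their own sphere's surface), no sphere-sphere overlap, spheres clear of
#' the membrane.
#'
#' @param assembly a `receptor_assembly`.
#' @param beads total-bead x 3 coordinate matrix (chain-major).
#' @param sites matrix (chain, residue) of tether sites, one per ligand.
#' @param lig_u ligand orientation unit vectors (ligands x 3).
#' @param radius common ligand radius.
#' @param tol geometric tolerance (nm).
#' @return list with `ok` and per-constraint diagnostics.
#' @export
validate_packing <- function(assembly, beads, sites, lig_u, radius,
                             tol = 1e-6) {
  chains <- assembly$chains
  len <- vapply(chains, `[[`, 0L, "n_residues")
  off <- cumsum(c(0L, len[-length(len)]))
  kuhn <- chains[[1]]$kuhn_length
  bond_err <- 0
  for (c in seq_along(chains)) {
    coords <- rbind(chains[[c]]$anchor, beads[off[c] + seq_len(len[c]), ])
    d <- sqrt(rowSums(diff(coords)^2))
    bond_err <- max(bond_err, max(abs(d - kuhn)))
  }
  centers <- t(vapply(seq_len(nrow(sites)), function(l) {
    beads[off[sites[l, 1]] + sites[l, 2], ] + radius * lig_u[l, ]
  }, numeric(3)))
  min_bead_z <- min(beads[, 3])
  min_sph_z <- min(centers[, 3]) - radius
  worst_bead_sphere <- Inf
  for (l in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(beads, 2, centers[l, ])^2)
    d2[off[sites[l, 1]] + sites[l, 2]] <- Inf  # tether bead on the surface
    worst_bead_sphere <- min(worst_bead_sphere, sqrt(min(d2)) - radius)
  }
  worst_sphere_sphere <- Inf
  if (nrow(centers) > 1) {
    dd <- as.matrix(stats::dist(centers))
    worst_sphere_sphere <- min(dd[upper.tri(dd)]) - 2 * radius
  }
  ok <- bond_err < tol && min_bead_z > -tol && min_sph_z > -tol &&
    worst_bead_sphere > -tol && worst_sphere_sphere > -tol
  list(ok = ok, bond_err = bond_err, min_bead_z = min_bead_z,
       min_sphere_z = min_sph_z, bead_sphere_clearance = worst_bead_sphere,
       sphere_sphere_clearance = worst_sphere_sphere)
}

#' Search for a configuration with all ligands simultaneously bound
#'
#' Simulated annealing over chain conformations and ligand orientations,
#' starting from a tilted straight-chain layout, with the squared-overlap
#' penalty as the objective. Feasibility is a one-sided claim: a returned
#' witness is re-validated by the independent constraint checker
#' ([validate_packing()]); failure to find one within the budget is reported
#' as "not found", not as proven infeasibility.
#'
#' @param assembly a `receptor_assembly`.
#' @param n_ligands number of ligands to bind (tethered to the first
#'   `n_ligands` ITAM-centre sites).
#' @param radius ligand radius (nm).
#' @param n_restarts annealing restarts (first is deterministic, later ones
#'   jittered).
#' @param n_iter annealing moves per restart.
#' @param seed integer seed.
#' @return list with `feasible`, `witness` (beads, lig_u, sites) when found,
#'   and the validator report.
#' @export
feasible_packing <- function(assembly, n_ligands = 10, radius,
                             n_restarts = 8, n_iter = 150000, seed = 1L) {
  sites <- assembly_sites(assembly, use_itam = TRUE)
  if (n_ligands > nrow(sites))
    stop("n_ligands exceeds the number of sites", call. = FALSE)
  sites <- sites[seq_len(n_ligands), , drop = FALSE]
  set.seed(seed)
  geo <- .build_geometry(assembly$chains)
  lig <- cbind(sites[, 1], sites[, 2], radius)
  for (attempt in seq_len(n_restarts)) {
    ini <- .packing_init(assembly, sites, radius,
                         jitter = if (attempt == 1) 0 else 0.25,
                         rng = TRUE)
    out <- pack_anneal_cpp(geo$anchors, geo$chain_len, geo$kuhn, ini$beads,
                           lig, ini$lig_u, n_iter,
                           T0 = 2.0, T1 = 1e-5, step0 = 0.25,
                           seed = seed * 131 + attempt)
    rep <- validate_packing(assembly, out$beads, sites, out$lig_u, radius)
    if (rep$ok) {
      return(list(feasible = TRUE, witness = list(beads = out$beads,
                                                  lig_u = out$lig_u,
                                                  sites = sites),
                  report = rep, penalty = out$penalty, attempts = attempt))
    }
  }
  list(feasible = FALSE, witness = NULL, report = rep, penalty = out$penalty,
       attempts = n_restarts,
       note = "no valid configuration found within the search budget")
}

#' Per-event binding rates under multiple simultaneous binding
#'
#' Path-sampled estimate of the average (path-weighted) binding rate of the
#' k-th ligand: Gillespie paths over bound-site subsets are grown event by
#' event, with each visited bound-state's per-site rates computed from a
#' converged sampler run in which the already-bound ligands are tethered hard
#' spheres. The rate of event k is the reciprocal mean waiting time across
#' paths; predecessor states are thereby sampled proportionally to their path
#' probabilities. Sampler runs are cached per bound-state. Event waiting
#' times are Rao-Blackwellised: each visited state contributes its expected
#' waiting time (the reciprocal of its total accessible rate) rather than an
#' exponential draw, which leaves the path-weighted mean unchanged while
#' removing the exponential sampling noise.
#'
#' @param assembly a `receptor_assembly`.
#' @param radius ligand radius (nm).
#' @param events highest event index to measure.
#' @param n_paths Gillespie paths.
#' @param seed integer seed.
#' @param config per-state [sampler_config()] (base recording budget).
#' @param force accept non-converged member runs (flagged in the output).
#' @param min_hits crowded states leave few samples with an accessible site;
#'   each state's recording budget is doubled (pooling runs) until at least
#'   this many occlusion-free samples are seen or `max_record` is reached,
#'   keeping the rare late-event rates from being pure noise.
#' @param max_record per-state cap on pooled recorded samples.
#' @return list with `rate` (per event, units of k_on0), `n_waits`,
#'   `states_explored`, `non_converged`.
#' @export
multi_ligand_rate_curve <- function(assembly, radius = 2.7, events = 7,
                                    n_paths = 16, seed = 1L,
                                    config = sampler_config(n_record = 12000),
                                    force = TRUE, min_hits = 30,
                                    max_record = 1.6e5) {
  sites <- assembly_sites(assembly, use_itam = TRUE)
  n_sites <- nrow(sites)
  cache <- new.env(parent = emptyenv())
  non_conv <- 0L
  state_rates <- function(bound, state_id) {
    key <- paste0("s", paste(bound, collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    free <- setdiff(seq_len(n_sites), bound)
    bl <- if (length(bound)) {
      data.frame(chain = sites[bound, 1], residue = sites[bound, 2],
                 radius = radius)
    } else NULL
    hits <- numeric(length(free))
    n_tot <- 0
    chunk <- config$n_record
    rep_i <- 0L
    while (TRUE) {
      cfg <- config
      cfg$n_record <- as.integer(chunk)
      cfg$max_doublings <- 0  # pooling below already extends the budget
      run <- suppressWarnings(run_sampler(
        assembly, membrane = "hard", bound_ligands = bl,
        probe_sites = sites[free, , drop = FALSE], probe_radius = radius,
        seed = seed + 977L * state_id + 131L * rep_i, config = cfg))
      if (!run$converged) non_conv <<- non_conv + 1L
      hits <- hits + colSums(1L - run$occ)
      n_tot <- n_tot + nrow(run$occ)
      if (sum(hits) >= min_hits || n_tot + chunk > max_record) break
      rep_i <- rep_i + 1L
      chunk <- min(2 * chunk, max_record - n_tot)
    }
    r <- numeric(n_sites)
    r[free] <- hits / n_tot
    cache[[key]] <- r
    r
  }
  set.seed(seed)
  waits <- matrix(NA_real_, n_paths, events)
  state_id <- 0L
  for (p in seq_len(n_paths)) {
    bound <- integer()
    for (k in seq_len(events)) {
      state_id <- state_id + 1L
      r <- state_rates(sort(bound), state_id)
      tot <- sum(r)
      if (tot <= 0) break
      waits[p, k] <- 1 / tot  # expected waiting time given the state
      nxt <- sample.int(n_sites, 1, prob = r)
      bound <- c(bound, nxt)
    }
  }
  rate <- vapply(seq_len(events), function(k) {
    w <- waits[, k]
    w <- w[is.finite(w)]
    if (!length(w)) return(NA_real_)
    1 / mean(w)
  }, 0)
  list(rate = rate, n_waits = colSums(is.finite(waits)),
       states_explored = length(ls(cache)), non_converged = non_conv)
}

#' Sixth-event binding rate for alternative site distributions
#'
#' Builds synthetic receptors with `n_sites` evenly spaced binding sites
#' distributed across `n_chains` chains anchored evenly on a circle, and
#' measures the path-weighted rate of the `event`-th binding event.
#'
#' @param n_sites total binding sites.
#' @param n_chains number of chains carrying them.
#' @param circle_radius anchor circle radius (nm).
#' @param spacing residues between consecutive sites on a chain (8-20).
#' @param ligand_radius ligand radius (nm).
#' @param event event index to report.
#' @param n_paths,seed,config forwarded to [multi_ligand_rate_curve()].
#' @return list with `rate` (the event's rate), `curve` (full result),
#'   `assembly`.
#' @export
site_distribution_experiment <- function(n_sites = 10, n_chains = 5,
                                         circle_radius = 1.5, spacing = 12,
                                         ligand_radius = 2.7, event = 6,
                                         n_paths = 12, seed = 1L,
                                         config = sampler_config(n_record = 8000)) {
  per <- diff(round(seq(0, n_sites, length.out = n_chains + 1)))
  if (any(per < 1)) stop("more chains than sites", call. = FALSE)
  chains <- lapply(seq_len(n_chains), function(c) {
    k <- per[c]
    pos <- spacing * seq_len(k)
    n_res <- spacing * k + ceiling(spacing / 2)
    chain_spec(name = sprintf("syn%d", c), n_residues = n_res, sites = pos,
               itam_centers = pos)
  })
  assembly <- assemble_receptor(list(type = "circle", radius = circle_radius),
                                chains)
  curve <- multi_ligand_rate_curve(assembly, radius = ligand_radius,
                                   events = event, n_paths = n_paths,
                                   seed = seed, config = config)
  list(rate = curve$rate[event], curve = curve, assembly = assembly)
}
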