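# Metropolis-Hastings sampling of anchored freely jointed chains.
#
# The move set is a single-joint pivot: pick a residue, rotate the downstream
# sub-chain (and any ligands tethered to it) by a random rotation whose angle
# scales with the adaptive step size. Pivots preserve bond lengths exactly and
# rotate rigid (stiffened) segments as units. Bound ligands additionally
# reorient about their tether site. Hard constraints (membrane, ligand
# spheres) are enforced by rejection; soft membrane potentials enter through
# the usual Metropolis acceptance probability.

.membrane_mode_code <- function(mode) {
  switch(mode, none = 0L, hard = 1L, soft = 2L,
         stop("membrane mode must be 'none', 'hard' or 'soft'", call. = FALSE))
}

# Build the flat geometry arrays the compiled sampler consumes.
# phospho: list (per chain) of phosphorylated site residues.
.build_geometry <- function(chains, phospho = NULL, stiffen_w = 0) {
  n_chain <- length(chains)
  if (is.null(phospho)) phospho <- rep(list(integer()), n_chain)
  chain_len <- vapply(chains, `[[`, 0L, "n_residues")
  anchors <- do.call(rbind, lapply(chains, `[[`, "anchor"))
  off <- cumsum(c(0L, chain_len[-n_chain]))
  bead_class <- integer(sum(chain_len))
  rigid <- matrix(0L, 0, 3)
  for (c in seq_len(n_chain)) {
    ch <- chains[[c]]
    if (length(ch$basics)) bead_class[off[c] + ch$basics] <- 1L
    ph <- as.integer(phospho[[c]])
    if (length(ph)) {
      bead_class[off[c] + ph] <- 2L
      if (stiffen_w > 0) {
        win <- cbind(pmax(1L, ph - as.integer(stiffen_w)),
                     pmin(ch$n_residues, ph + as.integer(stiffen_w)))
        win <- win[order(win[, 1]), , drop = FALSE]
        merged <- win[1, , drop = FALSE]
        if (nrow(win) > 1) for (k in 2:nrow(win)) {
          last <- nrow(merged)
          if (win[k, 1] <= merged[last, 2]) {
            merged[last, 2] <- max(merged[last, 2], win[k, 2])
          } else merged <- rbind(merged, win[k, ])
        }
        rigid <- rbind(rigid, cbind(c, merged))
      }
    }
  }
  list(anchors = anchors, chain_len = as.integer(chain_len),
       bead_class = bead_class, rigid = rigid, offsets = off,
       kuhn = chains[[1]]$kuhn_length)
}

#' Sampler configuration defaults
#'
#' @param n_record recorded samples after burn-in.
#' @param thin proposals between recorded samples (`NULL`: half the total
#'   bead count, at least 20).
#' @param burnin burn-in proposals with step-size adaptation (`NULL`:
#'   `max(20000, 50 * n_beads)`).
#' @param adapt_window proposals per adaptation update.
#' @param step_init initial perturbation scale (radians).
#' @param target_acc target acceptance rate for the adaptive step.
#' @param ks_alpha significance level of the quarter-wise convergence test.
#' @param max_doublings times the recording budget is doubled on
#'   non-convergence before giving up.
#' @export
sampler_config <- function(n_record = 20000, thin = NULL, burnin = NULL,
                           adapt_window = 100, step_init = 0.5,
                           target_acc = 0.44, ks_alpha = 0.05,
                           max_doublings = 2) {
  list(n_record = n_record, thin = thin, burnin = burnin,
       adapt_window = adapt_window, step_init = step_init,
       target_acc = target_acc, ks_alpha = ks_alpha,
       max_doublings = max_doublings)
}

#' Sample chain configurations from the canonical ensemble
#'
#' Runs adaptive Metropolis-Hastings on a set of anchored freely jointed
#' chains and records, per sample, each probe site's height and whether a
#' ligand-sized probe sphere at the site is sterically occluded. Convergence
#' is declared when the third and fourth quarters of the recorded site-height
#' series agree by a two-sample Kolmogorov-Smirnov test; the budget is
#' doubled (fresh run) up to `max_doublings` times otherwise.
#'
#' @param chains a [chain_spec()], list of chain specs, or
#'   `receptor_assembly`.
#' @param membrane `"hard"` (impenetrable wall at z = 0), `"soft"` (potential
#'   wall, used with membrane-affinity potentials), or `"none"` (cytosolic).
#' @param potentials a [membrane_params()]; ignored for `membrane = "none"`.
#' @param phospho list per chain of phosphorylated site residues (or a
#'   vector for a single chain).
#' @param stiffen_w half-width of the rigid window around each phosphosite
#'   (0 = no stiffening; 5 stiffens 11 residues).
#' @param bound_ligands data frame with columns `chain`, `residue`, `radius`:
#'   hard spheres tethered to site beads (surface touching the site).
#' @param probe_sites matrix with columns `chain`, `residue` of sites to
#'   probe; defaults to every site of every chain.
#' @param probe_radius probe sphere radius in nm.
#' @param probe_exclude half-width (in residues) of the contour window
#'   around a probed site excluded from the occlusion test: the flanking
#'   peptide a bound ligand engulfs in its groove is not an obstacle.
#'   Default `floor(probe_radius / (2 * kuhn_length))`.
#' @param seed integer seed; runs are bit-reproducible.
#' @param config a [sampler_config()].
#' @return an object of class `sampler_run` with elements `occ` (0/1 matrix,
#'   samples x sites), `site_z`, `end_xyz`, `acc_rate`, `step`, `converged`,
#'   `ks`, `beads`, and the echoed configuration.
#' @export
run_sampler <- function(chains, membrane = "hard",
                        potentials = membrane_params(), phospho = NULL,
                        stiffen_w = 0, bound_ligands = NULL,
                        probe_sites = NULL, probe_radius = 2.1,
                        probe_exclude = NULL,
                        probe_placement = c("tangent", "centered", "normal"),
                        seed = 1L, config = sampler_config()) {
  probe_placement <- match.arg(probe_placement)
  if (inherits(chains, "receptor_assembly")) chains <- chains$chains
  if (inherits(chains, "chain_spec")) chains <- list(chains)
  if (!is.null(phospho) && !is.list(phospho)) phospho <- list(as.integer(phospho))
  geo <- .build_geometry(chains, phospho, stiffen_w)
  M <- sum(geo$chain_len)
  mode <- .membrane_mode_code(membrane)
  pot <- as.numeric(unlist(potentials[c("E_B0", "k_PC", "E_P0", "z_debye", "k_S")]))
  if (is.null(probe_sites)) {
    probe_sites <- do.call(rbind, lapply(seq_along(chains), function(c)
      if (length(chains[[c]]$sites)) cbind(c, chains[[c]]$sites) else NULL))
  }
  probe_sites <- matrix(as.integer(probe_sites), ncol = 2)
  lig <- if (is.null(bound_ligands) || nrow(bound_ligands) == 0) {
    matrix(0, 0, 3)
  } else {
    as.matrix(bound_ligands[, c("chain", "residue", "radius")])
  }
  if (is.null(probe_exclude)) {
    # tangent placement: only the site bead itself is exempt; the centred
    # variant must exempt the contour the ligand engulfs or it is degenerate
    probe_exclude <- if (probe_placement == "centered")
      as.integer(ceiling(probe_radius / geo$kuhn))
    else 0L
  }
  thin <- config$thin %||% max(20L, as.integer(round(M / 2)))
  burnin <- config$burnin %||% max(20000L, 50L * M)
  n_record <- config$n_record

  for (attempt in 0:config$max_doublings) {
    res <- mh_sample_cpp(geo$anchors, geo$chain_len, geo$kuhn,
                         geo$bead_class,
                         matrix(as.integer(geo$rigid), ncol = 3),
                         lig, matrix(0, 0, 3),
                         probe_sites, probe_radius, as.integer(probe_exclude),
                         switch(probe_placement, tangent = 0L, centered = 1L, normal = 2L),
                         mode, pot,
                         as.integer(n_record * 2^attempt), as.integer(thin),
                         as.integer(burnin), as.integer(config$adapt_window),
                         config$step_init, config$target_acc,
                         seed + attempt * 7919, 200L, matrix(0, 0, 3))
    if (!isTRUE(res$ok_init))
      stop("no valid initial configuration found within the retry budget",
           call. = FALSE)
    ks <- check_convergence(res$site_z, alpha = config$ks_alpha)
    if (ks$converged || config$max_doublings == 0) break
    if (attempt == config$max_doublings) break
  }
  if (!ks$converged)
    warning("sampler did not converge within the budget (KS statistic ",
            signif(ks$statistic, 3), " > ", signif(ks$threshold, 3), ")",
            call. = FALSE)
  structure(list(occ = res$occ, site_z = res$site_z, end_xyz = res$end_xyz,
                 acc_rate = res$acc_rate, step = res$step,
                 converged = ks$converged, ks = ks, beads = res$beads,
                 lig_u = res$lig_u, probe_sites = probe_sites,
                 probe_radius = probe_radius, probe_exclude = probe_exclude,
                 probe_placement = probe_placement,
                 config = list(seed = seed, thin = thin, burnin = burnin,
                               n_record = nrow(res$site_z),
                               membrane = membrane, stiffen_w = stiffen_w)),
            class = "sampler_run")
}

#' @export
print.sampler_run <- function(x, ...) {
  cat(sprintf(
    "<sampler_run> %d samples x %d site(s); acceptance %.3f; %s\n",
    nrow(x$site_z), ncol(x$site_z), x$acc_rate,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Quarter-wise Kolmogorov-Smirnov convergence check
#'
#' Declares a recorded observable series stationary when its third and fourth
#' quarters have the same distribution: the two-sample KS statistic must fall
#' below the critical value at level `alpha`. Quarters are subsampled to at
#' most `max_points` evenly spaced points so that residual autocorrelation
#' does not dominate the test. Matrices are checked column-wise and must pass
#' for every column.
#'
#' @param series numeric vector or matrix (samples x observables).
#' @param alpha significance level.
#' @param min_len minimum series length.
#' @param max_points per-quarter subsample cap.
#' @return list with `converged`, `statistic` (worst column), `threshold`.
#' @export
check_convergence <- function(series, alpha = 0.05, min_len = 400,
                              max_points = 400) {
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  n <- nrow(series)
  if (n < min_len) stop("series too short for convergence check", call. = FALSE)
  q <- floor(n / 4)
  idx3 <- seq.int(2 * q + 1, 3 * q)
  idx4 <- seq.int(3 * q + 1, 4 * q)
  sub <- function(ix) ix[unique(as.integer(round(seq(1, length(ix),
                                                     length.out = min(max_points, length(ix))))))]
  i3 <- sub(idx3); i4 <- sub(idx4)
  c_alpha <- sqrt(-log(alpha / 2) / 2)
  thr <- c_alpha * sqrt((length(i3) + length(i4)) / (length(i3) * length(i4)))
  stat <- 0
  for (j in seq_len(ncol(series))) {
    a <- series[i3, j]; b <- series[i4, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && a[1] == b[1]) next
    d <- suppressWarnings(stats::ks.test(a, b)$statistic)
    stat <- max(stat, unname(d))
  }
  list(converged = stat < thr, statistic = stat, threshold = thr)
}

#' Multiplicative step-size adaptation
#'
#' Increases the perturbation scale when the observed acceptance rate exceeds
#' the 0.44 target and decreases it otherwise; within `tol` of the target the
#' step is left unchanged (frozen), preserving detailed balance during the
#' measurement phase.
#'
#' @param state list with `step_size` and `acceptance` (fraction over the
#'   adaptation window).
#' @param target target acceptance rate.
#' @param factor multiplicative update.
#' @param tol freeze tolerance.
#' @return updated `state`.
#' @export
adapt_step <- function(state, target = 0.44, factor = 1.05, tol = 0.02) {
  stopifnot(state$step_size > 0, !is.null(state$acceptance))
  a <- state$acceptance
  if (abs(a - target) <= tol) return(state)
  state$step_size <- if (a > target) state$step_size * factor
                     else state$step_size / factor
  state
}

# ---- R-level reference conformation tools (used by tests and the packing
# initialiser; the compiled sampler implements the same move) ----

#' Build a straight initial conformation
#'
#' Each chain extends perpendicular to the membrane from its anchor; bound
#' ligands (if any) start perpendicular to the chain axis.
#'
#' @param chains list of [chain_spec()] or a `receptor_assembly`.
#' @return list of per-chain bead coordinate matrices (n x 3).
#' @export
initial_conformation <- function(chains) {
  if (inherits(chains, "receptor_assembly")) chains <- chains$chains
  if (inherits(chains, "chain_spec")) chains <- list(chains)
  lapply(chains, function(ch) {
    k <- seq_len(ch$n_residues)
    cbind(ch$anchor[1] + 0 * k, ch$anchor[2] + 0 * k,
          ch$anchor[3] + ch$kuhn_length * k)
  })
}

#' Propose a single pivot move (reference implementation)
#'
#' Rotates the sub-chain downstream of a uniformly chosen joint by a random
#' rotation with angle `step_size * N(0,1)`. Bond lengths and rigid-segment
#' collinearity are preserved exactly by construction. With `step_size = 0`
#' the candidate equals the current conformation.
#'
#' @param conformation list of per-chain bead matrices (see
#'   [initial_conformation()]).
#' @param anchors matrix of per-chain anchors.
#' @param step_size rotation scale in radians.
#' @param rigid optional matrix (chain, lo, hi) of rigid residue ranges.
#' @return the candidate conformation (same shape).
#' @export
propose_move <- function(conformation, anchors, step_size, rigid = NULL) {
  c_idx <- sample.int(length(conformation), 1)
  n <- nrow(conformation[[c_idx]])
  valid <- seq_len(n)
  if (!is.null(rigid) && nrow(rigid)) {
    for (r in seq_len(nrow(rigid))) {
      if (rigid[r, 1] != c_idx) next
      bad <- seq.int(rigid[r, 2] + 1, rigid[r, 3])
      valid <- setdiff(valid, bad)
    }
  }
  j <- valid[sample.int(length(valid), 1)]
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- step_size * stats::rnorm(1)
  pivot <- if (j == 1) as.numeric(anchors[c_idx, ])
           else conformation[[c_idx]][j - 1, ]
  beads <- conformation[[c_idx]]
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  sel <- seq.int(j, n)
  v <- sweep(beads[sel, , drop = FALSE], 2, pivot)
  beads[sel, ] <- sweep(v %*% t(Rm), 2, pivot, `+`)
  conformation[[c_idx]] <- beads
  conformation
}

#' Total configurational energy (reference implementation)
#'
#' Sums the per-residue membrane potentials over all beads and returns `Inf`
#' for hard-constraint violations (bead below a hard membrane, bead inside a
#' ligand sphere, overlapping ligand spheres).
#'
#' @param conformation list of per-chain bead matrices.
#' @param bead_class list of per-chain integer vectors (0 generic, 1 basic,
#'   2 phosphotyrosine).
#' @param potentials a [membrane_params()].
#' @param membrane `"none"`, `"hard"` or `"soft"`.
#' @param ligand_centers optional matrix of sphere centres, with radii in
#'   `ligand_radii`; `tether` gives the (chain, residue) pairs excluded from
#'   the bead-overlap test.
#' @param ligand_radii numeric vector of sphere radii.
#' @param tether optional 2-column matrix of tether sites.
#' @return energy in units of kBT.
#' @export
total_energy <- function(conformation, bead_class, potentials = membrane_params(),
                         membrane = "hard", ligand_centers = NULL,
                         ligand_radii = NULL, tether = NULL) {
  e <- 0
  for (c in seq_along(conformation)) {
    z <- conformation[[c]][, 3]
    cls <- bead_class[[c]]
    if (membrane == "hard" && any(z < -1e-9)) return(Inf)
    if (membrane != "none") {
      e <- e + sum(residue_potential(z[cls == 1], "basic", potentials)) +
        sum(residue_potential(z[cls == 2], "phosphotyrosine", potentials)) +
        sum(residue_potential(z[cls == 0], "other", potentials))
    }
  }
  if (!is.null(ligand_centers) && nrow(ligand_centers)) {
    for (l in seq_len(nrow(ligand_centers))) {
      for (c in seq_along(conformation)) {
        d2 <- rowSums(sweep(conformation[[c]], 2, ligand_centers[l, ])^2)
        skip <- if (!is.null(tether) && tether[l, 1] == c) tether[l, 2] else 0
        if (skip > 0) d2[skip] <- Inf
        if (any(d2 < (ligand_radii[l] - 1e-9)^2)) return(Inf)
      }
      if (l < nrow(ligand_centers)) for (m in seq.int(l + 1, nrow(ligand_centers))) {
        d <- sqrt(sum((ligand_centers[l, ] - ligand_centers[m, ])^2))
        if (d < ligand_radii[l] + ligand_radii[m] - 1e-9) return(Inf)
      }
    }
  }
  e
}
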