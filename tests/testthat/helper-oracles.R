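# Independent oracles used across tests.

# Direct rejection sampler for an anchored freely jointed chain above a hard
# wall: uniform random segment directions, configurations with any bead below
# z = 0 rejected. Returns bead coordinate array (n_kept x n_res x 3).
fjc_rejection_sample <- function(n_res, n_keep, kuhn = 0.3, wall = TRUE,
                                 anchor = c(0, 0, 0)) {
  kept <- array(NA_real_, c(n_keep, n_res, 3))
  got <- 0
  while (got < n_keep) {
    m <- max(1000, 2 * (n_keep - got))
    dirs <- array(stats::rnorm(m * n_res * 3), c(m, n_res, 3))
    nrm <- sqrt(dirs[, , 1]^2 + dirs[, , 2]^2 + dirs[, , 3]^2)
    for (d in 1:3) dirs[, , d] <- kuhn * dirs[, , d] / nrm
    beads <- dirs
    for (k in seq_len(n_res)) {
      if (k == 1) {
        for (d in 1:3) beads[, 1, d] <- anchor[d] + dirs[, 1, d]
      } else {
        for (d in 1:3) beads[, k, d] <- beads[, k - 1, d] + dirs[, k, d]
      }
    }
    ok <- if (wall) {
      apply(beads[, , 3, drop = FALSE] >= 0, 1, all)
    } else rep(TRUE, m)
    idx <- which(ok)
    take <- min(length(idx), n_keep - got)
    if (take > 0) {
      kept[got + seq_len(take), , ] <- beads[idx[seq_len(take)], , , drop = FALSE]
      got <- got + take
    }
  }
  kept
}

# Occlusion probability oracle on rejection-sampled configurations with the
# same randomized probe placement as the pipeline.
occlusion_oracle <- function(beads, site, probe_radius, wall = TRUE) {
  n <- dim(beads)[1]
  d <- matrix(stats::rnorm(3 * n), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  ctr <- beads[, site, ] + probe_radius * d
  blocked <- if (wall) ctr[, 3] < probe_radius else rep(FALSE, n)
  for (k in seq_len(dim(beads)[2])) {
    if (k == site) next
    dist2 <- rowSums((beads[, k, ] - ctr)^2)
    blocked <- blocked | dist2 < probe_radius^2
  }
  mean(blocked)
}

# Exhaustive path-probability enumeration for an irreversible modification
# cascade on a state-dependent rate matrix K (2^n x n, zero for inapplicable
# sites). Returns named probabilities over all n! orders and the expected
# waiting time per step.
enumerate_paths <- function(K, n) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  allp <- perms(seq_len(n))
  probs <- numeric(length(allp))
  wait <- matrix(0, length(allp), n)
  for (ip in seq_along(allp)) {
    ord <- allp[[ip]]
    s <- 0L
    pr <- 1
    for (k in seq_len(n)) {
      avail <- which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1))) == 0L)
      tot <- sum(K[s + 1L, avail])
      pr <- pr * K[s + 1L, ord[k]] / tot
      wait[ip, k] <- 1 / tot
      s <- bitwOr(s, bitwShiftL(1L, ord[k] - 1L))
    }
    probs[ip] <- pr
  }
  names(probs) <- vapply(allp, paste, "", collapse = "")
  step_wait <- colSums(wait * probs)  # path-weighted mean waiting time
  list(probs = probs, step_wait = step_wait)
}

# Stationary distribution of the reversible cycle by direct linear solve of
# the generator (the analytic birth-death/Markov-chain oracle).
stationary_mean_frac <- function(kin, pho, ratio, n) {
  ns <- 2^n
  Q <- matrix(0, ns, ns)
  for (s in 0:(ns - 1)) {
    for (i in seq_len(n)) {
      bit <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(s, bit) == 0L) {
        Q[s + 1, bitwOr(s, bit) + 1] <- Q[s + 1, bitwOr(s, bit) + 1] +
          ratio * kin[s + 1, i]
      } else {
        Q[s + 1, bitwAnd(s, bitwNot(bit)) + 1] <-
          Q[s + 1, bitwAnd(s, bitwNot(bit)) + 1] + pho[s + 1, i]
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, ns))
  b <- c(rep(0, ns), 1)
  pi_s <- qr.solve(A, b)
  np <- vapply(0:(ns - 1), function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(n - 1))) > 0), 0)
  sum(pi_s * np) / n
}

# Small deterministic toy systems
toy_table <- function(rates_matrix, n) {
  structure(list(chain = "toy", n_sites = n, sites = seq_len(n),
                 p_occ = 1 - rates_matrix, sem = rates_matrix * 0,
                 rates = rates_matrix, converged = rep(TRUE, nrow(rates_matrix)),
                 partial = FALSE,
                 meta = list(probe_radius = NA, membrane = "none",
                             stiffen_w = 0, seed = 0, n_record = NA)),
            class = "rate_table")
}
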