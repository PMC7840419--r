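# Gillespie dynamics on occlusion-derived rate tables: irreversible
# (de)phosphorylation sequences, path-weighted step rates, reversible
# kinase/phosphatase cycles, and Hill-coefficient extraction.

#' Simulate irreversible (de)phosphorylation sequences
#'
#' Each run starts from the all-unmodified (phosphorylation) or all-modified
#' (dephosphorylation) state and proceeds to completion; at every step the
#' next site is chosen with probability proportional to its state-dependent
#' rate and the waiting time is exponential with the total applicable rate.
#'
#' @param rate_table a [build_rate_table()] result.
#' @param direction `"phosphorylate"` or `"dephosphorylate"`.
#' @param n_runs number of Gillespie runs.
#' @param seed integer seed.
#' @return object of class `sequence_stats`: `perm` (runs x steps site
#'   matrix), `waits` (runs x steps waiting times), `origin` (runs x steps
#'   state bitmask before each step), `total_rate` (runs x steps),
#'   `probabilities` (named vector over realised permutations).
#' @export
simulate_sequences <- function(rate_table, direction = "phosphorylate",
                               n_runs = 1e5, seed = 1L) {
  K <- rate_matrix(rate_table, direction)
  n <- rate_table$n_sites
  set.seed(seed)
  state <- if (direction == "phosphorylate") rep(0L, n_runs)
           else rep(2L^n - 1L, n_runs)
  perm <- matrix(0L, n_runs, n)
  waits <- matrix(0, n_runs, n)
  origin <- matrix(0L, n_runs, n)
  totals <- matrix(0, n_runs, n)
  site_rate <- matrix(0, n_runs, n)
  bits <- bitwShiftL(1L, 0:(n - 1L))
  for (k in seq_len(n)) {
    R <- K[state + 1L, , drop = FALSE]
    tot <- rowSums(R)
    if (any(tot <= 0))
      stop("absorbing state reached: all applicable rates are zero for ",
           sum(tot <= 0), " run(s) at step ", k, call. = FALSE)
    origin[, k] <- state
    totals[, k] <- tot
    waits[, k] <- stats::rexp(n_runs) / tot
    cs <- R
    for (j in 2:n) cs[, j] <- cs[, j - 1] + R[, j]
    u <- stats::runif(n_runs) * tot
    site <- rowSums(u > cs) + 1L
    perm[, k] <- site
    site_rate[, k] <- R[cbind(seq_len(n_runs), site)]
    state <- if (direction == "phosphorylate") bitwOr(state, bits[site])
             else bitwAnd(state, bitwNot(bits[site]))
  }
  keys <- apply(perm, 1, paste, collapse = "")
  tab <- table(keys)
  probabilities <- as.numeric(tab) / n_runs
  names(probabilities) <- names(tab)
  structure(list(n_sites = n, direction = direction, n_runs = n_runs,
                 perm = perm, waits = waits, origin = origin,
                 total_rate = totals, site_rate = site_rate,
                 probabilities = probabilities),
            class = "sequence_stats")
}

#' Probability of a specific modification order
#'
#' @param stats a [simulate_sequences()] result.
#' @param order site order, e.g. `c(6, 5, 4, 3, 2, 1)` or `"654321"`.
#' @return estimated probability (0 if never realised).
#' @export
sequence_probability <- function(stats, order) {
  key <- if (is.character(order)) order else paste(order, collapse = "")
  p <- stats$probabilities[key]
  if (is.na(p)) 0 else unname(p)
}

#' Average binding rate of the k-th modification event
#'
#' Path-weighted: the reciprocal of the mean waiting time for the k-th event
#' pooled over runs, so transitions on likelier paths carry more weight.
#' Unweighted: the mean over the distinct chain states realised before the
#' k-th event of their total applicable rate, weighting every realised state
#' equally. The two agree when rates are state-independent.
#'
#' @param stats a [simulate_sequences()] result.
#' @param step event index (1 = first modification).
#' @param weighting `"path-weighted"` or `"unweighted"`.
#' @param per_site report the mean rate of the individual transition taken
#'   (the accessibility of the chosen site) instead of the total exit rate.
#'   The total-exit convention (default) answers "how long until the k-th
#'   event"; the per-site convention answers "how accessible is a remaining
#'   site at step k" and divides out the trivial decline from having fewer
#'   available sites.
#' @return rate in units of k_on0.
#' @export
path_weighted_rate <- function(stats, step,
                               weighting = c("path-weighted", "unweighted"),
                               per_site = FALSE) {
  weighting <- match.arg(weighting)
  if (step < 1 || step > stats$n_sites)
    stop("step never realised", call. = FALSE)
  if (weighting == "path-weighted") {
    if (per_site) mean(stats$site_rate[, step])
    else 1 / mean(stats$waits[, step])
  } else {
    ids <- !duplicated(stats$origin[, step])
    if (per_site) mean(stats$site_rate[ids, step])
    else mean(stats$total_rate[ids, step])
  }
}

#' Steady state of the reversible phosphorylation cycle
#'
#' Long-run Gillespie simulation of the kinase/phosphatase cycle on the
#' phosphostate lattice for each kinase:phosphatase free-space activity
#' ratio. The phosphatase either acts at a constant per-site rate
#' (`"constant"`: enzymatic domain too small for steric effects) or through
#' its own occlusion-derived table (`"steric"`). The response is the
#' time-averaged fraction of sites phosphorylated after discarding the first
#' half of the events.
#'
#' @param kinase_table a [build_rate_table()] result (kinase probe).
#' @param phosphatase_model `"constant"` or `"steric"`.
#' @param phosphatase_table table for the steric model (defaults to
#'   `kinase_table`, appropriate when both enzymes share a radius).
#' @param ratio_grid positive, strictly increasing kinase:phosphatase
#'   free-space ratios.
#' @param n_events Gillespie events per ratio.
#' @param burn_frac fraction of events discarded as transient.
#' @param seed integer seed.
#' @return object of class `dose_response` with `ratio` and `response`
#'   (fraction of sites phosphorylated).
#' @export
reversible_steady_state <- function(kinase_table,
                                    phosphatase_model = c("constant", "steric"),
                                    phosphatase_table = NULL,
                                    ratio_grid = 10^seq(-2, 2, length.out = 8),
                                    n_events = 1e6, burn_frac = 0.5,
                                    seed = 1L) {
  phosphatase_model <- match.arg(phosphatase_model)
  stopifnot(all(ratio_grid > 0), !is.unsorted(ratio_grid))
  kin <- rate_matrix(kinase_table, "phosphorylate")
  n <- kinase_table$n_sites
  pho <- if (phosphatase_model == "constant") {
    m <- matrix(0, nrow(kin), n)
    for (s in 0:(nrow(kin) - 1L))
      m[s + 1L, bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) > 0L] <- 1
    m
  } else {
    rate_matrix(phosphatase_table %||% kinase_table, "dephosphorylate")
  }
  response <- vapply(seq_along(ratio_grid), function(i) {
    out <- gillespie_cycle_cpp(kin, pho, ratio_grid[i], n_events, burn_frac,
                               seed + 7717 * i)
    if (out$absorbed_state >= 0)
      stop("absorbing state ", out$absorbed_state, " reached", call. = FALSE)
    out$mean_frac
  }, 0)
  structure(list(ratio = ratio_grid, response = response,
                 n_events = n_events, model = phosphatase_model),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %d ratio points in [%.3g, %.3g]; response in [%.3f, %.3f]\n",
              length(x$ratio), min(x$ratio), max(x$ratio),
              min(x$response), max(x$response)))
  invisible(x)
}

#' Hill coefficient of a dose-response curve
#'
#' Two conventions: `"max-log-slope"` takes the maximum of
#' d(log odds)/d(log ratio), smoothed by a cubic polynomial fitted to the
#' finite-difference slopes (its root-mean-square error is returned as the
#' uncertainty). `"log-ec"` is the log-effective-concentration definition
#' log(81) / log(EC90 / EC10), where EC10 and EC90 are the ratios at 10% and
#' 90% of the curve's own range; it is signed, so responses that decrease
#' with dose give negative values and shallow responses give values below 1.
#'
#' @param dose_response a `dose_response` object (or list with `ratio`,
#'   `response`).
#' @param method `"max-log-slope"` or `"log-ec"`.
#' @param response_max saturation used to form odds for the slope method
#'   (default 1 for fractional responses).
#' @return list with `hill`, `ec50`, `emax`, and `uncertainty` (slope
#'   method).
#' @export
hill_coefficient <- function(dose_response,
                             method = c("max-log-slope", "log-ec"),
                             response_max = 1) {
  method <- match.arg(method)
  r <- dose_response$ratio
  f <- dose_response$response
  if (all(f <= 0) || all(f >= response_max))
    stop("response does not traverse the transition on this grid", call. = FALSE)
  emax <- max(f)
  ec50 <- .crossing(r, f, min(f) + 0.5 * (max(f) - min(f)))
  if (method == "max-log-slope") {
    eps <- 1e-6
    keep <- f > eps & f < response_max - eps
    if (sum(keep) < 3) stop("too few points inside the transition", call. = FALSE)
    x <- log10(r[keep])
    y <- log10(f[keep] / (response_max - f[keep]))
    m <- length(x)
    xm <- x[2:(m - 1)]
    slope <- (y[3:m] - y[1:(m - 2)]) / (x[3:m] - x[1:(m - 2)])
    if (length(slope) >= 4) {
      fit <- stats::lm(slope ~ poly(xm, min(3, length(slope) - 1), raw = TRUE))
      fine <- seq(min(xm), max(xm), length.out = 400)
      pred <- stats::predict(fit, newdata = data.frame(xm = fine))
      hill <- max(pred)
      unc <- sqrt(mean(stats::residuals(fit)^2))
    } else {
      hill <- max(slope)
      unc <- NA_real_
    }
    list(hill = hill, ec50 = ec50, emax = emax, uncertainty = unc,
         method = method)
  } else {
    lo <- min(f); span <- max(f) - lo
    if (span <= 0) stop("flat response", call. = FALSE)
    r10 <- .crossing(r, f, lo + 0.10 * span)
    r90 <- .crossing(r, f, lo + 0.90 * span)
    if (is.na(r10) || is.na(r90))
      stop("curve does not bracket EC10/EC90 on this grid", call. = FALSE)
    list(hill = log(81) / log(r90 / r10), ec50 = ec50, emax = emax,
         uncertainty = NA_real_, method = method)
  }
}

# first crossing of level `lev` by (r, f), linear in log-ratio
.crossing <- function(r, f, lev) {
  x <- log(r)
  for (i in seq_len(length(f) - 1)) {
    if ((f[i] - lev) * (f[i + 1] - lev) <= 0 && f[i] != f[i + 1]) {
      t <- (lev - f[i]) / (f[i + 1] - f[i])
      return(exp(x[i] + t * (x[i + 1] - x[i])))
    }
  }
  NA_real_
}
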