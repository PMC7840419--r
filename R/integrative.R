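# Integrative continuous-state model of phosphorylation, dephosphorylation
# and ZAP70 loading on the 10-site receptor:
#
#   dnP/dt = kK (N - nP) - kF (nP - nZ)
#   dnZ/dt = kon (nP - nZ) - koff nZ
#
# with every enzymatic rate carrying the same state-dependent factor
# lambda_K^nP * lambda_Z^nZ: lambda_K > 1 is the per-phosphorylation rate
# enhancement (stiffening or membrane release), lambda_Z < 1 the
# per-bound-ZAP70 reduction (steric crowding). ZAP70-bound sites are
# protected from dephosphorylation.

#' Parameters of the integrative model
#'
#' @param n_sites number of ITAM sites N.
#' @param lambda_K per-phosphorylation rate-enhancement factor.
#' @param lambda_Z per-bound-ZAP70 rate-reduction factor.
#' @param k_K0,k_F0,k_on0 free-space phosphorylation, dephosphorylation and
#'   ZAP70 binding rates (per second; only ratios matter for the curves).
#'   The default `k_on0 = k_off / lambda_Z^6` at the estimated
#'   `lambda_Z = 0.6` places the binding crossover `k_on0 lambda_Z^n = k_off`
#'   at n = 6 bound ZAP70, reproducing the observed ~6-per-receptor
#'   stoichiometry.
#' @param k_off ZAP70 unbinding rate (per second).
#' @return list of parameters (class `integrative_params`).
#' @export
integrative_params <- function(n_sites = 10, lambda_K = 1.2, lambda_Z = 0.6,
                               k_K0 = 1, k_F0 = 1, k_on0 = 0.2 / 0.6^6,
                               k_off = 0.2) {
  stopifnot(n_sites > 0, lambda_K > 0, lambda_Z > 0, k_K0 >= 0, k_F0 >= 0,
            k_on0 >= 0, k_off >= 0)
  structure(list(n_sites = n_sites, lambda_K = lambda_K, lambda_Z = lambda_Z,
                 k_K0 = k_K0, k_F0 = k_F0, k_on0 = k_on0, k_off = k_off),
            class = "integrative_params")
}

#' State-modified rates
#'
#' Each base rate is multiplied by `lambda_K^n_p * lambda_Z^n_z`.
#'
#' @param n_p phosphorylated sites.
#' @param n_z ZAP70-bound sites (`0 <= n_z <= n_p <= N`).
#' @param params an [integrative_params()].
#' @return named vector `c(k_K, k_F, k_on)`.
#' @export
modified_rates <- function(n_p, n_z, params = integrative_params()) {
  if (n_z > n_p || n_p > params$n_sites || n_z < 0)
    stop("need 0 <= n_z <= n_p <= n_sites", call. = FALSE)
  fac <- params$lambda_K^n_p * params$lambda_Z^n_z
  c(k_K = params$k_K0 * fac, k_F = params$k_F0 * fac,
    k_on = params$k_on0 * fac)
}

.integrative_deriv <- function(t, y, p) {
  fac <- p$lambda_K^y[1] * p$lambda_Z^y[2]
  kK <- p$k_K0 * fac
  kF <- p$k_F0 * fac
  kon <- p$k_on0 * fac
  dnP <- kK * (p$n_sites - y[1]) - kF * (y[1] - y[2])
  dnZ <- kon * (y[1] - y[2]) - p$k_off * y[2]
  list(c(dnP, dnZ))
}

#' Steady state of the integrative model
#'
#' Integrates the two-variable system with a stiff solver until the
#' derivatives vanish, then polishes the fixed point by damped Newton
#' iteration with a numerical Jacobian.
#'
#' @param params an [integrative_params()].
#' @param tol relative residual tolerance.
#' @return list with `n_p`, `n_z`, `residual`, `converged`.
#' @export
integrative_steady_state <- function(params = integrative_params(),
                                     tol = 1e-8) {
  scale <- max(params$k_K0, params$k_F0, params$k_on0, params$k_off, 1e-12)
  y <- c(0, 0)
  t_end <- 50 / scale
  for (chunk in 1:12) {
    sol <- deSolve::lsoda(y, c(0, t_end), .integrative_deriv, params,
                          rtol = 1e-10, atol = 1e-12)
    y <- pmin(pmax(as.numeric(sol[nrow(sol), 2:3]), 0), params$n_sites)
    d <- unlist(.integrative_deriv(0, y, params))
    if (max(abs(d)) / scale < tol * 100) break
    t_end <- t_end * 4
  }
  for (i in 1:60) {  # Newton polish
    d <- unlist(.integrative_deriv(0, y, params))
    if (max(abs(d)) / scale < tol) break
    h <- 1e-6 * max(1, max(abs(y)))
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      yp <- y; yp[j] <- yp[j] + h
      J[, j] <- (unlist(.integrative_deriv(0, yp, params)) - d) / h
    }
    step <- tryCatch(solve(J, -d), error = function(e) -d / scale)
    lim <- max(1, max(abs(step)))
    y <- y + step / lim * min(1, lim)
    y[1] <- min(max(y[1], 0), params$n_sites)
    y[2] <- min(max(y[2], 0), y[1])
  }
  d <- unlist(.integrative_deriv(0, y, params))
  list(n_p = y[1], n_z = y[2], residual = max(abs(d)) / scale,
       converged = max(abs(d)) / scale < tol * 10)
}

#' Dose-response sweep of the integrative model
#'
#' Sweeps the kinase:phosphatase free-space ratio `k_K0 / k_F0` over a grid
#' (holding `k_F0` fixed) and returns steady-state curves for both the
#' number of phosphorylated sites and the number of bound ZAP70, with Hill
#' statistics by the log-effective-concentration convention.
#'
#' @param params an [integrative_params()].
#' @param ratio_grid positive increasing grid of `k_K0 / k_F0`.
#' @return list with `ratio`, `n_p`, `n_z`, and `hill_p`, `hill_z`
#'   ([hill_coefficient()] results on the fraction scale).
#' @export
dose_response_sweep <- function(params = integrative_params(),
                                ratio_grid = 10^seq(-3, 3, length.out = 41)) {
  stopifnot(all(ratio_grid > 0), !is.unsorted(ratio_grid))
  n_p <- n_z <- numeric(length(ratio_grid))
  for (i in seq_along(ratio_grid)) {
    p <- params
    p$k_K0 <- params$k_F0 * ratio_grid[i]
    ss <- integrative_steady_state(p)
    n_p[i] <- ss$n_p
    n_z[i] <- ss$n_z
  }
  dr_p <- structure(list(ratio = ratio_grid, response = n_p / params$n_sites),
                    class = "dose_response")
  dr_z <- structure(list(ratio = ratio_grid, response = n_z / params$n_sites),
                    class = "dose_response")
  list(ratio = ratio_grid, n_p = n_p, n_z = n_z,
       hill_p = hill_coefficient(dr_p, "log-ec"),
       hill_z = hill_coefficient(dr_z, "log-ec"))
}

#' Rate enhancement needed to counteract a binding-rate reduction
#'
#' Finds, by bisection, the `lambda_K` at which the ZAP70 dose-response
#' steepness (log-effective-concentration Hill coefficient) returns to its
#' neutral level (`lambda_K = lambda_Z = 1`), for a given `lambda_Z`.
#'
#' @param lambda_Z the rate-reduction factor to counteract.
#' @param params baseline [integrative_params()] (its `lambda` fields are
#'   overridden).
#' @param ratio_grid sweep grid.
#' @param interval search interval for `lambda_K`.
#' @param tol bisection tolerance.
#' @return list with `lambda_K`, `hill_neutral`, `hill_achieved`.
#' @export
neutralizing_lambda_K <- function(lambda_Z = 0.5,
                                  params = integrative_params(),
                                  ratio_grid = 10^seq(-3, 3, length.out = 41),
                                  interval = c(1, 6), tol = 1e-3) {
  hill_at <- function(lK, lZ) {
    p <- params
    p$lambda_K <- lK
    p$lambda_Z <- lZ
    dose_response_sweep(p, ratio_grid)$hill_z$hill
  }
  target <- hill_at(1, 1)
  g <- function(lK) hill_at(lK, lambda_Z) - target
  lo <- interval[1]; hi <- interval[2]
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0)
    stop("neutral steepness not bracketed on the interval", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm * glo <= 0) { hi <- mid; ghi <- gm } else { lo <- mid; glo <- gm }
  }
  lK <- (lo + hi) / 2
  list(lambda_K = lK, hill_neutral = target,
       hill_achieved = hill_at(lK, lambda_Z))
}
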