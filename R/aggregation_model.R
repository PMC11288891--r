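#' Aggregation rate parameters
#'
#' Parameter set for the nucleation-elongation-secondary-nucleation moment
#' model of amyloid fibril formation. The two moments are the fibril number
#' concentration P and the fibril mass concentration M, evolving as
#' \deqn{dP/dt = k_n m^{n_c} + k_2 m^{n_2} M, \qquad
#'       dM/dt = 2 k_+ m P, \qquad m = m_{tot} - M,}
#' with free monomer m obtained by mass conservation. The factor 2 accounts
#' for growth at both fibril ends and is configurable via `ends`.
#'
#' The default rate constants are order-of-magnitude values typical of Ab42
#' aggregation under quiescent conditions (they give a half-time of roughly
#' two hours at 2 uM monomer); they are placeholders for fitting, not
#' measured constants.
#'
#' @param kn primary nucleation rate constant (M^(1-nc) / s).
#' @param nc primary nucleation reaction order (>= 1, default 2).
#' @param kplus elongation rate constant (/M/s).
#' @param k2 secondary nucleation rate constant (M^(-n2) / s).
#' @param n2 secondary nucleation reaction order (>= 1, default 2).
#' @param m_total total monomer concentration (M).
#' @param M0,P0 initial fibril mass and number concentrations (M); zero for
#'   an unseeded reaction.
#' @param ends number of growing fibril ends (default 2).
#' @return An object of class `aggregation_params`.
#' @examples
#' p <- aggregation_params(m_total = 2e-6)
#' half_time(simulate_aggregation(p, seq(0, 4e4, by = 165)))
#' @export
aggregation_params <- function(kn = 1e-4, nc = 2, kplus = 3e6, k2 = 1e4,
                               n2 = 2, m_total = 2e-6, M0 = 0, P0 = 0,
                               ends = 2) {
  if (any(c(kn, kplus, k2) < 0)) stop("rate constants must be >= 0")
  if (nc < 1 || n2 < 1) stop("reaction orders must be >= 1")
  if (!is.finite(m_total) || m_total <= 0) stop("m_total must be > 0")
  if (M0 < 0 || P0 < 0 || M0 > m_total)
    stop("initial moments must satisfy 0 <= M0 <= m_total, P0 >= 0")
  structure(list(kn = kn, nc = nc, kplus = kplus, k2 = k2, n2 = n2,
                 m_total = m_total, M0 = M0, P0 = P0, ends = ends),
            class = "aggregation_params")
}

#' @export
print.aggregation_params <- function(x, ...) {
  cat("<aggregation_params>\n")
  cat(sprintf("  kn = %.3g M^(1-nc)/s (nc = %g), k+ = %.3g /M/s, k2 = %.3g M^(-n2)/s (n2 = %g)\n",
              x$kn, x$nc, x$kplus, x$k2, x$n2))
  cat(sprintf("  m_total = %.3g M, M0 = %.3g M, P0 = %.3g M, %g growing ends\n",
              x$m_total, x$M0, x$P0, x$ends))
  invisible(x)
}

#' Simulate an aggregation trajectory
#'
#' Integrates the moment equations numerically (stiff solver, relative
#' tolerance 1e-8) on the supplied time grid and returns the free monomer
#' m(t), fibril mass M(t) and fibril number P(t). Mass conservation
#' (m + M = m_total) holds to solver tolerance; M and P are nondecreasing.
#'
#' @param params an [aggregation_params()] object.
#' @param t_grid time grid (s), increasing from 0.
#' @return Data frame of class `aggregation_trajectory` with columns `t`,
#'   `m`, `M`, `P`; the parameters travel as attribute `params`.
#' @export
simulate_aggregation <- function(params, t_grid) {
  stopifnot(inherits(params, "aggregation_params"))
  check_time_grid(t_grid)
  if (t_grid[1L] != 0) stop("time grid must start at 0")
  mt <- params$m_total
  rhs <- function(t, y, p) {
    m <- max(mt - y[2L], 0)
    dP <- p$kn * m^p$nc + p$k2 * m^p$n2 * y[2L]
    dM <- p$ends * p$kplus * m * y[1L]
    list(c(dP, dM))
  }
  sol <- try(suppressWarnings(deSolve::lsoda(
    y = c(P = params$P0, M = params$M0),
    times = t_grid, func = rhs, parms = params,
    rtol = 1e-8, atol = c(mt * 1e-14, mt * 1e-10)
  )), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(t_grid)) {
    stop("aggregation ODE solver failed for parameters: ",
         paste(sprintf("%s=%.3g", names(unclass(params)),
                       unlist(params)), collapse = ", "))
  }
  M <- pmin(pmax(sol[, "M"], 0), mt)
  out <- data.frame(t = t_grid, m = mt - M, M = M,
                    P = pmax(sol[, "P"], 0))
  attr(out, "params") <- params
  class(out) <- c("aggregation_trajectory", "data.frame")
  out
}

#' @export
print.aggregation_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<aggregation_trajectory> %d points, t in [0, %.3g] s, m_total = %.3g M\n",
              nrow(x), max(x$t), p$m_total))
  cat(sprintf("  final fibril mass: %.3g M (%.1f%% converted)\n",
              x$M[nrow(x)], 100 * x$M[nrow(x)] / p$m_total))
  invisible(x)
}

#' @export
plot.aggregation_trajectory <- function(x, ...) {
  graphics::plot(x$t, x$M, type = "l", xlab = "time (s)",
                 ylab = "fibril mass (M)", ...)
  invisible(x)
}

#' Aggregation half-time
#'
#' Time at which the fibril mass first reaches half of its final plateau,
#' located by linear interpolation between grid points. The plateau is the
#' final value of the (monotone) mass curve; the curve must have flattened
#' -- if the mass still rises by more than 1% of the plateau over the last
#' tenth of the time window, the curve is judged incomplete and an error is
#' raised. An externally known plateau (e.g. borrowed from an uninhibited
#' control for curves that never level off) can be supplied instead.
#'
#' @param traj an [simulate_aggregation()] trajectory, or any list/data
#'   frame with numeric `t` and `M` components (e.g. a normalized
#'   fluorescence trace with `M` in fraction-aggregated units).
#' @param plateau optional plateau value overriding the final-value
#'   estimate.
#' @return Half-time in the units of `traj$t`.
#' @export
half_time <- function(traj, plateau = NULL) {
  t <- traj$t; M <- traj$M
  if (length(t) < 3L) stop("trajectory too short")
  if (is.null(plateau)) {
    Mend <- M[length(M)]
    if (Mend <= 0) stop("incomplete curve: no aggregation detected")
    M90 <- stats::approx(t, M, xout = 0.9 * t[length(t)])$y
    if ((Mend - M90) > 0.01 * Mend)
      stop("incomplete curve: fibril mass has not reached a plateau")
    plateau <- Mend
  }
  target <- 0.5 * plateau
  above <- which(M >= target)
  if (!length(above))
    stop("incomplete curve: trajectory never reaches half of the plateau")
  i <- above[1L]
  if (i == 1L) return(t[1L])
  # linear interpolation of the first crossing
  t[i - 1L] + (target - M[i - 1L]) * (t[i] - t[i - 1L]) / (M[i] - M[i - 1L])
}

#' Inhibitor coupling for aggregation simulations
#'
#' Describes how a monomer-binding inhibitor couples to the aggregation
#' reaction through the two mechanisms used in the analysis:
#' monomer sequestration (binder-bound monomer is removed from the reaction,
#' computed once at t = 0 from the exact 1:1 equilibrium -- dissociation of
#' the complex over the aggregation timescale is neglected) and suppression
#' of secondary nucleation (the rate constant k2 is multiplied by a
#' concentration-dependent factor in (0, 1]).
#'
#' The modulation is either a per-concentration factor table (interpolated
#' log-linearly in concentration when evaluated elsewhere) or the parametric
#' form `1 / (1 + conc / K_I)`.
#'
#' @param binder_Kd monomer-binder dissociation constant (M).
#' @param binder_conc binder concentration (M).
#' @param k2_factors named numeric vector or data frame
#'   (`conc`, `factor`) giving the multiplier per binder concentration;
#'   factors must lie in (0, 1].
#' @param K_I parametric modulation constant (M); used when `k2_factors` is
#'   `NULL`. `K_I = Inf` means no modulation.
#' @return An object of class `inhibitor_model`.
#' @export
inhibitor_model <- function(binder_Kd, binder_conc, k2_factors = NULL,
                            K_I = Inf) {
  if (!is.finite(binder_Kd) || binder_Kd <= 0) stop("binder_Kd must be > 0")
  check_conc(binder_conc, "binder_conc")
  if (!is.null(k2_factors)) {
    if (!is.data.frame(k2_factors))
      k2_factors <- data.frame(conc = as.numeric(names(k2_factors)),
                               factor = as.numeric(k2_factors))
    if (any(k2_factors$factor <= 0 | k2_factors$factor > 1))
      stop("k2 modulation factors must lie in (0, 1]")
    k2_factors <- k2_factors[order(k2_factors$conc), , drop = FALSE]
  } else if (!(K_I > 0)) {
    stop("K_I must be > 0")
  }
  structure(list(binder_Kd = binder_Kd, binder_conc = binder_conc,
                 k2_factors = k2_factors, K_I = K_I),
            class = "inhibitor_model")
}

#' Evaluate the secondary-nucleation modulation factor
#'
#' @param inhib an [inhibitor_model()].
#' @param conc binder concentration (M); defaults to the model's own.
#' @return Factor in (0, 1]; exactly 1 at zero concentration.
#' @export
modulation_factor <- function(inhib, conc = inhib$binder_conc) {
  stopifnot(inherits(inhib, "inhibitor_model"))
  out <- numeric(length(conc))
  for (i in seq_along(conc)) {
    cc <- conc[i]
    if (cc == 0) { out[i] <- 1; next }
    if (!is.null(inhib$k2_factors)) {
      tab <- inhib$k2_factors
      tab <- rbind(data.frame(conc = 0, factor = 1), tab)
      if (cc >= max(tab$conc)) {
        out[i] <- tab$factor[nrow(tab)]
      } else {
        # interpolate log(factor) linearly in conc
        out[i] <- exp(stats::approx(tab$conc, log(tab$factor), xout = cc)$y)
      }
    } else {
      out[i] <- 1 / (1 + cc / inhib$K_I)
    }
  }
  out
}

#' Simulate aggregation in the presence of a monomer-binding inhibitor
#'
#' Applies the two inhibition couplings of [inhibitor_model()] and runs
#' [simulate_aggregation()]: the effective initial monomer is the free
#' monomer from the exact 1:1 equilibrium with the binder (evaluated once
#' at t = 0), and the secondary nucleation rate constant is scaled by the
#' modulation factor. With sequestration alone (factor 1), the result is
#' identical to an uninhibited simulation at the reduced monomer
#' concentration.
#'
#' @param params an [aggregation_params()] object (total monomer before
#'   sequestration).
#' @param inhib an [inhibitor_model()].
#' @param t_grid time grid (s).
#' @return An `aggregation_trajectory`; attributes `effective_m_total` and
#'   `k2_factor` record the applied couplings.
#' @export
simulate_with_inhibitor <- function(params, inhib, t_grid) {
  stopifnot(inherits(params, "aggregation_params"),
            inherits(inhib, "inhibitor_model"))
  m_eff <- free_monomer(params$m_total, inhib$binder_conc, inhib$binder_Kd)
  fac <- modulation_factor(inhib)
  p2 <- params
  p2$m_total <- m_eff
  p2$k2 <- params$k2 * fac
  traj <- simulate_aggregation(p2, t_grid)
  attr(traj, "effective_m_total") <- m_eff
  attr(traj, "k2_factor") <- fac
  traj
}

# Simulate until the mass curve plateaus, doubling the window as needed.
# Returns a trajectory on n_points equally spaced times.
simulate_to_plateau <- function(params, n_points = 400L, t_end = NULL,
                                max_doublings = 24L) {
  if (is.null(t_end)) {
    # crude timescale guess from the dominant proliferation rate
    m <- params$m_total
    kap2 <- params$ends * params$kplus * params$k2 * m^(params$n2 + 1)
    lam2 <- params$ends * params$kplus * params$kn * m^params$nc
    rate <- sqrt(max(kap2, lam2, .Machine$double.xmin))
    t_end <- 10 / rate
  }
  for (i in seq_len(max_doublings)) {
    grid <- seq(0, t_end, length.out = n_points)
    traj <- simulate_aggregation(params, grid)
    Mend <- traj$M[n_points]
    flat <- Mend > 0 &&
      (Mend - traj$M[round(0.9 * n_points)]) <= 0.005 * Mend &&
      Mend >= 0.95 * params$m_total
    if (flat) return(traj)
    t_end <- t_end * 2
  }
  stop("trajectory did not plateau within the maximum simulated window")
}

#' Scaling of the half-time with monomer concentration
#'
#' Computes aggregation half-times over a grid of total monomer
#' concentrations and returns the log-log scaling exponent
#' gamma = d log t_half / d log m_total by least squares. For reactions
#' dominated by secondary nucleation with n2 = 2 the exponent is close to
#' -(n2 + 1)/2 = -1.5; primary-nucleation-dominated reactions give a
#' shallower exponent. The exponent is the standard mechanistic diagnostic
#' for which nucleation pathway controls proliferation.
#'
#' @param params an [aggregation_params()] object; `m_total` is overridden
#'   by each grid value.
#' @param m_grid monomer concentrations (M), >= 4 distinct values.
#' @return List with `slope`, `se`, and the data frame `points`
#'   (`m_total`, `t_half`).
#' @export
half_time_scaling <- function(params, m_grid) {
  m_grid <- sort(unique(m_grid))
  if (length(m_grid) < 4L)
    stop("need >= 4 distinct monomer concentrations")
  th <- vapply(m_grid, function(m) {
    p <- params; p$m_total <- m
    half_time(simulate_to_plateau(p))
  }, numeric(1))
  fit <- stats::lm(log(th) ~ log(m_grid))
  # a pure power law fits exactly; vcov then warns about a perfect fit
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2L]))
  list(slope = unname(stats::coef(fit)[2L]),
       se = se,
       points = data.frame(m_total = m_grid, t_half = th))
}
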