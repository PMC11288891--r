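#' Equilibrium complex concentration under ligand depletion
#'
#' Exact 1:1 equilibrium for total concentrations, without the
#' excess-ligand approximation: the complex concentration is the physical
#' root of the mass-balance quadratic,
#' \deqn{C = \frac{(L + B + K_d) - \sqrt{(L + B + K_d)^2 - 4 L B}}{2},}
#' evaluated in the numerically stable form `2LB / (S + sqrt(S^2 - 4LB))`
#' with `S = L + B + Kd`, which avoids catastrophic cancellation when
#' `Kd` is much larger than the totals. All quantities are molar.
#'
#' @param Ltot total labeled/tracked species (M). Vectorized.
#' @param Btot total binder (M). Vectorized.
#' @param Kd equilibrium dissociation constant (M), > 0.
#' @return Complex concentration (M), in `[0, min(Ltot, Btot)]`.
#' @examples
#' complex_conc_quadratic(2e-6, 1e-6, 83e-9)
#' @export
complex_conc_quadratic <- function(Ltot, Btot, Kd) {
  check_conc(Ltot, "Ltot")
  check_conc(Btot, "Btot")
  if (any(!is.finite(Kd)) || any(Kd <= 0))
    stop("Kd must be finite and > 0")
  S <- Ltot + Btot + Kd
  disc <- S^2 - 4 * Ltot * Btot
  disc[disc < 0] <- 0  # guard tiny negative round-off
  C <- 2 * Ltot * Btot / (S + sqrt(disc))
  pmin(pmax(C, 0), pmin(Ltot, Btot))
}

#' Free monomer after binder sequestration
#'
#' Monomer left unbound at 1:1 equilibrium with a binder, i.e.
#' `Ltot - complex_conc_quadratic(...)`. Under the sequestration assumption
#' (bound monomer is removed from the aggregation reaction for its full
#' duration), this is the effective initial monomer concentration of an
#' inhibited aggregation reaction.
#'
#' @inheritParams complex_conc_quadratic
#' @return Free monomer concentration (M), in `[0, Ltot]`.
#' @export
free_monomer <- function(Ltot, Btot, Kd) {
  Ltot - complex_conc_quadratic(Ltot, Btot, Kd)
}

check_conc <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " must be finite and >= 0")
  invisible(x)
}

#' 1:1 steady-state binding response
#'
#' Langmuir isotherm `R = Rmax * C / (C + Kd)` for the equilibrium response
#' of a biosensor at analyte concentration `C` (no depletion: the analyte
#' is in large excess over the immobilized species).
#'
#' @param C analyte concentration (M), >= 0. Vectorized.
#' @param Kd dissociation constant (M).
#' @param Rmax maximal response (sensor units).
#' @return Response in sensor units.
#' @export
steady_state_response <- function(C, Kd, Rmax) {
  check_conc(C, "C")
  Rmax * C / (C + Kd)
}

#' 1:1 biosensor association and dissociation traces
#'
#' Closed-form solutions of the 1:1 binding ODE
#' `dR/dt = kon * C * (Rmax - R) - koff * R`:
#' association from an empty sensor,
#' `R(t) = Req * (1 - exp(-(kon*C + koff) * t))` with
#' `Req = Rmax * C / (C + Kd)`, and first-order dissociation
#' `R(t) = R0 * exp(-koff * t)`.
#'
#' @param t time grid (s), nondecreasing from 0.
#' @param C analyte concentration during association (M).
#' @param kon association rate constant (per M per s).
#' @param koff dissociation rate constant (per s).
#' @param Rmax maximal response (sensor units).
#' @param R0 response at the start of dissociation.
#' @return Response series on `t`.
#' @export
association_trace <- function(t, C, kon, koff, Rmax) {
  check_time_grid(t)
  Kd <- koff / kon
  Req <- steady_state_response(C, Kd, Rmax)
  Req * (1 - exp(-(kon * C + koff) * t))
}

#' @rdname association_trace
#' @export
dissociation_trace <- function(t, R0, koff) {
  check_time_grid(t)
  R0 * exp(-koff * t)
}

check_time_grid <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("time grid must be finite and nonnegative")
  if (is.unsorted(t))
    stop("time grid must be nondecreasing")
  invisible(t)
}

# ---- fitting ---------------------------------------------------------------

#' Fit a 1:1 steady-state binding isotherm
#'
#' Nonlinear least squares of `R = Rmax * C / (C + Kd)` against equilibrium
#' responses over an analyte titration. Fitting is done in log10(Kd) with a
#' Levenberg-Marquardt optimizer and five log-spaced Kd starts spanning the
#' concentration range, keeping the best-converged solution.
#'
#' @param conc analyte concentrations (M), at least 4 distinct values.
#' @param response equilibrium responses (sensor units), same length.
#' @return A `binding_fit` object (subclass `steady_state_fit`): list with
#'   `estimates` (Kd, Rmax), `se` (standard errors from the Jacobian),
#'   `residuals`, `rss`, `converged` and a `diagnostics` list whose
#'   `identifiability` element is `"ok"` or a warning string when the
#'   titration does not bracket the fitted Kd.
#' @examples
#' C <- 2e-6 * 2^(-3:4)
#' fit <- fit_steady_state(C, steady_state_response(C, Kd = 2e-6, Rmax = 1))
#' coef(fit)[["Kd"]]
#' @export
fit_steady_state <- function(conc, response) {
  check_titration(conc, response)
  model <- function(p, C) steady_state_response(C, 10^p[1L], p[2L])
  starts <- lapply(kd_starts(conc), function(k)
    c(log10(k), max(response) * 1.1))
  best <- multistart_lm(
    starts,
    function(p) response - model(p, conc)
  )
  p <- best$par
  est <- c(Kd = unname(10^p[1L]), Rmax = unname(p[2L]))
  se <- lm_se(best)
  # delta method: se(Kd) = Kd * log(10) * se(log10 Kd)
  se <- c(Kd = unname(est[["Kd"]] * log(10) * se[1L]), Rmax = unname(se[2L]))
  new_binding_fit(
    subclass = "steady_state_fit",
    estimates = est, se = se,
    residuals = best$fvec, rss = sum(best$fvec^2),
    converged = best$converged,
    data = data.frame(conc = conc, response = response),
    diagnostics = list(
      identifiability = identifiability_flag(conc, est[["Kd"]]),
      message = best$message
    )
  )
}

#' Global 1:1 kinetic fit of biosensor titration traces
#'
#' Fits association and dissociation traces recorded at several analyte
#' concentrations with a single shared parameter set (kon, koff, Rmax) --
#' a global fit. Dissociation of each trace starts from the model-predicted
#' response at the end of its association phase, which ties the two phases
#' together. An optional per-trace linear baseline drift term can be
#' included. Reported `Kd = koff / kon`.
#'
#' @param data data frame with columns `time_s`, `conc_M`, `phase`
#'   (`"association"` or `"dissociation"`, time restarting at 0 within each
#'   phase), `response`, and optionally `replicate`.
#' @param t_assoc association duration (s); defaults to the maximum
#'   association time in the data.
#' @param drift if `TRUE`, adds one shared linear drift rate (units/s).
#' @return A `binding_fit` object (subclass `kinetic_fit`) with estimates
#'   `kon`, `koff`, `Kd`, `Rmax` (and `drift` if requested).
#' @export
fit_kinetic_global <- function(data, t_assoc = NULL, drift = FALSE) {
  need <- c("time_s", "conc_M", "phase", "response")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(data$phase %in% c("association", "dissociation")))
    stop("phase must be 'association' or 'dissociation'")
  concs <- sort(unique(data$conc_M))
  if (length(concs) < 2L)
    stop("global kinetic fit needs >= 2 analyte concentrations")
  if (is.null(t_assoc))
    t_assoc <- max(data$time_s[data$phase == "association"])
  Rmax0 <- max(data$response)

  # p = (log10 kon, log10 koff, Rmax[, drift]); closed forms evaluated
  # pointwise because rows interleave traces (times restart per phase)
  predict_rows <- function(p, d) {
    kon <- 10^p[1L]; koff <- 10^p[2L]; Rmax <- p[3L]
    req <- function(C) Rmax * C / (C + koff / kon)
    out <- numeric(nrow(d))
    ia <- d$phase == "association"
    out[ia] <- req(d$conc_M[ia]) *
      (1 - exp(-(kon * d$conc_M[ia] + koff) * d$time_s[ia]))
    if (any(!ia)) {
      R0 <- req(d$conc_M[!ia]) * (1 - exp(-(kon * d$conc_M[!ia] + koff) * t_assoc))
      out[!ia] <- R0 * exp(-koff * d$time_s[!ia])
    }
    if (length(p) > 3L) {
      tt <- d$time_s + ifelse(d$phase == "dissociation", t_assoc, 0)
      out <- out + p[4L] * tt
    }
    out
  }
  starts <- lapply(kd_starts(concs), function(k) {
    kon0 <- 1e4
    c(log10(kon0), log10(kon0 * k), Rmax0, if (drift) 0)
  })
  best <- multistart_lm(starts, function(p) data$response - predict_rows(p, data))
  p <- best$par
  est <- c(kon = unname(10^p[1L]), koff = unname(10^p[2L]),
           Kd = unname(10^(p[2L] - p[1L])), Rmax = unname(p[3L]))
  if (drift) est <- c(est, drift = unname(p[4L]))
  se_raw <- lm_se(best)
  se <- c(kon = unname(est[["kon"]] * log(10) * se_raw[1L]),
          koff = unname(est[["koff"]] * log(10) * se_raw[2L]),
          Kd = NA_real_, Rmax = unname(se_raw[3L]))
  if (drift) se <- c(se, drift = unname(se_raw[4L]))
  new_binding_fit(
    subclass = "kinetic_fit",
    estimates = est, se = se,
    residuals = best$fvec, rss = sum(best$fvec^2),
    converged = best$converged,
    data = data,
    diagnostics = list(
      identifiability = identifiability_flag(concs, est[["Kd"]]),
      t_assoc = t_assoc, message = best$message
    )
  )
}

#' Fit the exact ligand-depletion binding quadratic to a sizing titration
#'
#' Microfluidic diffusional sizing reports either the bound fraction of the
#' labeled species or its apparent hydrodynamic radius across a binder
#' titration. Because the labeled species is at a concentration comparable
#' to Kd, the simple isotherm misestimates the midpoint; the fit therefore
#' uses the exact mass-balance quadratic ([complex_conc_quadratic()]).
#' Fraction-bound data fit Kd alone; radius data fit Kd jointly with the
#' free and complex radii unless endpoints are fixed.
#'
#' @param conc binder concentrations (M), >= 4 distinct.
#' @param response bound fraction in about \[0, 1\] (default) or apparent
#'   radius (nm) when `readout = "radius"`.
#' @param Ltot total labeled species (M), known from the assay design.
#' @param readout `"fraction"` or `"radius"`.
#' @param Rh_fixed optional length-2 vector `c(Rh_free, Rh_complex)` to fix
#'   the radius endpoints.
#' @return A `binding_fit` object (subclass `mds_fit`).
#' @export
fit_mds_quadratic <- function(conc, response, Ltot,
                              readout = c("fraction", "radius"),
                              Rh_fixed = NULL) {
  readout <- match.arg(readout)
  check_titration(conc, response)
  check_conc(Ltot, "Ltot")
  fb <- function(Kd) complex_conc_quadratic(Ltot, conc, Kd) / Ltot

  if (readout == "fraction") {
    starts <- lapply(kd_starts(conc), function(k) c(log10(k)))
    best <- multistart_lm(starts, function(p) response - fb(10^p[1L]))
    Kd <- 10^best$par[1L]
    est <- c(Kd = unname(Kd))
    se <- c(Kd = unname(Kd * log(10) * lm_se(best)[1L]))
  } else if (!is.null(Rh_fixed)) {
    stopifnot(length(Rh_fixed) == 2L, Rh_fixed[2L] >= Rh_fixed[1L])
    starts <- lapply(kd_starts(conc), function(k) c(log10(k)))
    best <- multistart_lm(starts, function(p) {
      response - (Rh_fixed[1L] + fb(10^p[1L]) * diff(Rh_fixed))
    })
    Kd <- 10^best$par[1L]
    est <- c(Kd = unname(Kd), Rh_free = Rh_fixed[1L], Rh_complex = Rh_fixed[2L])
    se <- c(Kd = unname(Kd * log(10) * lm_se(best)[1L]),
            Rh_free = 0, Rh_complex = 0)
  } else {
    starts <- lapply(kd_starts(conc), function(k)
      c(log10(k), min(response), max(response)))
    best <- multistart_lm(starts, function(p) {
      response - (p[2L] + fb(10^p[1L]) * (p[3L] - p[2L]))
    })
    Kd <- 10^best$par[1L]
    se_raw <- lm_se(best)
    est <- c(Kd = unname(Kd), Rh_free = unname(best$par[2L]),
             Rh_complex = unname(best$par[3L]))
    se <- c(Kd = unname(Kd * log(10) * se_raw[1L]),
            Rh_free = unname(se_raw[2L]), Rh_complex = unname(se_raw[3L]))
  }
  new_binding_fit(
    subclass = "mds_fit",
    estimates = est, se = se,
    residuals = best$fvec, rss = sum(best$fvec^2),
    converged = best$converged,
    data = data.frame(conc = conc, response = response),
    diagnostics = list(
      identifiability = identifiability_flag(conc, est[["Kd"]]),
      Ltot = Ltot, readout = readout, message = best$message
    )
  )
}

# ---- fitting internals -----------------------------------------------------

check_titration <- function(conc, response) {
  if (length(conc) != length(response))
    stop("conc and response lengths differ")
  if (length(unique(conc)) < 4L)
    stop("need >= 4 distinct concentrations, got ", length(unique(conc)))
  if (any(!is.finite(response)))
    stop("responses must all be finite")
  check_conc(conc, "conc")
}

kd_starts <- function(conc) {
  pos <- conc[conc > 0]
  10^seq(log10(min(pos)) - 1, log10(max(pos)) + 1, length.out = 5L)
}

# Run nls.lm from several starts; keep the lowest converged RSS.
multistart_lm <- function(starts, resid_fn) {
  best <- NULL
  msgs <- character()
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      msgs <- c(msgs, conditionMessage(fit))
      next
    }
    ok <- fit$info %in% 1:4
    cand <- list(par = fit$par, fvec = fit$fvec, hessian = fit$hessian,
                 deviance = fit$deviance, converged = ok,
                 message = fit$message)
    if (is.null(best) || cand$deviance < best$deviance) best <- cand
  }
  if (is.null(best))
    stop("nonlinear least squares failed from every start: ",
         paste(unique(msgs), collapse = "; "))
  if (!best$converged)
    warning("least-squares fit did not formally converge: ", best$message)
  best
}

# Standard errors from the Gauss-Newton Hessian (J'J) at the optimum.
lm_se <- function(fit) {
  npar <- length(fit$par)
  dof <- max(length(fit$fvec) - npar, 1L)
  s2 <- fit$deviance / dof
  cov <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(cov)) return(rep(NA_real_, npar))
  sqrt(pmax(diag(cov), 0))
}

identifiability_flag <- function(conc, Kd) {
  pos <- conc[conc > 0]
  if (min(pos) > 10 * Kd)
    "all concentrations >> fitted Kd: lower bound only"
  else if (max(pos) < 0.1 * Kd)
    "all concentrations << fitted Kd: upper bound only"
  else "ok"
}

new_binding_fit <- function(subclass, estimates, se, residuals, rss,
                            converged, data, diagnostics) {
  structure(
    list(estimates = estimates, se = se, residuals = residuals, rss = rss,
         converged = converged, data = data, diagnostics = diagnostics),
    class = c(subclass, "binding_fit")
  )
}

#' @export
coef.binding_fit <- function(object, ...) object$estimates

#' @export
residuals.binding_fit <- function(object, ...) object$residuals

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<%s> 1:1 binding fit (%s)\n", class(x)[1L],
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(estimate = signif(x$estimates, 6),
                    se = signif(x$se, 3))
  print(tab)
  if (!identical(x$diagnostics$identifiability, "ok"))
    cat("warning:", x$diagnostics$identifiability, "\n")
  invisible(x)
}

#' @export
summary.binding_fit <- function(object, ...) {
  out <- list(
    class = class(object)[1L],
    estimates = object$estimates, se = object$se,
    rss = object$rss, n = length(object$residuals),
    converged = object$converged,
    diagnostics = object$diagnostics
  )
  class(out) <- "summary.binding_fit"
  out
}

#' @export
print.summary.binding_fit <- function(x, ...) {
  cat(sprintf("1:1 binding fit (%s), n = %d, RSS = %.4g\n",
              x$class, x$n, x$rss))
  print(data.frame(estimate = signif(x$estimates, 6), se = signif(x$se, 3)))
  cat("converged:", x$converged,
      "| identifiability:", x$diagnostics$identifiability, "\n")
  invisible(x)
}

#' @export
predict.steady_state_fit <- function(object, conc = NULL, ...) {
  if (is.null(conc)) conc <- object$data$conc
  steady_state_response(conc, object$estimates[["Kd"]],
                        object$estimates[["Rmax"]])
}

#' @export
predict.mds_fit <- function(object, conc = NULL, ...) {
  if (is.null(conc)) conc <- object$data$conc
  fbv <- complex_conc_quadratic(object$diagnostics$Ltot, conc,
                                object$estimates[["Kd"]]) /
    object$diagnostics$Ltot
  if (object$diagnostics$readout == "radius")
    object$estimates[["Rh_free"]] +
      fbv * (object$estimates[["Rh_complex"]] - object$estimates[["Rh_free"]])
  else fbv
}

#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  kon <- object$estimates[["kon"]]; koff <- object$estimates[["koff"]]
  Rmax <- object$estimates[["Rmax"]]; ta <- object$diagnostics$t_assoc
  req <- function(C) Rmax * C / (C + koff / kon)
  out <- numeric(nrow(newdata))
  ia <- newdata$phase == "association"
  out[ia] <- req(newdata$conc_M[ia]) *
    (1 - exp(-(kon * newdata$conc_M[ia] + koff) * newdata$time_s[ia]))
  if (any(!ia)) {
    R0 <- req(newdata$conc_M[!ia]) *
      (1 - exp(-(kon * newdata$conc_M[!ia] + koff) * ta))
    out[!ia] <- R0 * exp(-koff * newdata$time_s[!ia])
  }
  out
}

#' @export
plot.binding_fit <- function(x, ...) {
  d <- x$data
  if (inherits(x, "kinetic_fit")) {
    tt <- d$time_s + ifelse(d$phase == "dissociation",
                            x$diagnostics$t_assoc, 0)
    graphics::plot(tt, d$response, pch = 16, cex = 0.4,
                   xlab = "time (s)", ylab = "response", ...)
    ord <- order(d$conc_M, d$phase, d$time_s)
    for (cc in unique(d$conc_M)) {
      sel <- d$conc_M == cc
      graphics::lines(tt[sel][order(tt[sel])],
                      predict(x, d[sel, , drop = FALSE])[order(tt[sel])],
                      col = 2)
    }
  } else {
    graphics::plot(d$conc, d$response, log = "x", pch = 16,
                   xlab = "concentration (M)", ylab = "response", ...)
    grid_c <- 10^seq(log10(min(d$conc[d$conc > 0])),
                     log10(max(d$conc)), length.out = 100)
    graphics::lines(grid_c, predict(x, conc = grid_c), col = 2)
  }
  invisible(x)
}
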