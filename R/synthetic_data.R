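#' Generate a synthetic ThT aggregation dataset
#'
#' Simulates thioflavin-T plate-reader traces from the moment model with
#' the linear signal model F = a*M(t) + b plus additive Gaussian noise.
#' Defaults mirror a standard quiescent plate assay: 2 uM monomer sampled
#' every 165 s, three replicates, binder concentrations spanning 0-2 uM.
#' Inhibited conditions apply monomer sequestration (from `binder_Kd`) and
#' secondary-nucleation suppression (parametric in `K_I` or a per-
#' concentration `k2_factors` table). Per-trace signal constants a and b
#' are jittered a few percent around their nominal values, as between
#' wells of a real plate.
#'
#' The top-level `seed` derives one substream per trace (seed + 1000 *
#' trace index), so output is reproducible and individual traces are
#' independent of generation order.
#'
#' @param seed integer seed.
#' @param params uninhibited [aggregation_params()]; ground truth.
#' @param binder_Kd monomer-binder dissociation constant (M).
#' @param binder_concs binder concentrations (M), including 0.
#' @param K_I parametric secondary-nucleation modulation constant (M);
#'   ignored when `k2_factors` is given.
#' @param k2_factors optional data frame (`conc`, `factor`) of modulation
#'   factors for the nonzero binder concentrations.
#' @param replicates traces per condition.
#' @param dt sampling interval (s).
#' @param t_end assay duration (s); default six uninhibited half-times,
#'   rounded to the sampling grid.
#' @param sigma additive noise sd as a fraction of the uninhibited plateau
#'   signal.
#' @param a,b nominal signal slope (a.u. per M fibril mass) and baseline
#'   (a.u.).
#' @return A [tht_dataset()]; the generating truth (parameters, couplings,
#'   per-trace a and b) is attached as attribute `ground_truth`.
#' @export
gen_tht_dataset <- function(seed = 1L,
                            params = aggregation_params(m_total = 2e-6),
                            binder_Kd = 83e-9,
                            binder_concs = c(0, 0.25, 0.5, 1, 2) * 1e-6,
                            K_I = 5e-7, k2_factors = NULL,
                            replicates = 3L, dt = 165, t_end = NULL,
                            sigma = 0.02, a = 1e6, b = 0.25) {
  stopifnot(inherits(params, "aggregation_params"), sigma >= 0,
            length(binder_concs) >= 1L, replicates >= 1L)
  seed <- as.integer(seed)
  if (is.null(t_end))
    t_end <- dt * ceiling(6 * half_time(simulate_to_plateau(params)) / dt)
  t_grid <- seq(0, t_end, by = dt)

  fac_at <- function(bc) {
    if (bc == 0) return(1)
    if (!is.null(k2_factors)) {
      i <- match(bc, k2_factors$conc)
      if (is.na(i)) stop("no k2 factor supplied for conc ", bc)
      k2_factors$factor[i]
    } else 1 / (1 + bc / K_I)
  }

  plateau_signal <- a * params$m_total
  rows <- list()
  truth_ab <- list()
  trace_i <- 0L
  for (bc in binder_concs) {
    fac <- fac_at(bc)
    inh <- inhibitor_model(binder_Kd, bc,
                           k2_factors = if (bc > 0)
                             data.frame(conc = bc, factor = fac) else NULL,
                           K_I = Inf)
    traj <- simulate_with_inhibitor(params, inh, t_grid)
    for (r in seq_len(replicates)) {
      trace_i <- trace_i + 1L
      set.seed(seed + 1000L * trace_i)
      ai <- a * exp(stats::rnorm(1, 0, 0.03))
      bi <- b * exp(stats::rnorm(1, 0, 0.1))
      noise <- stats::rnorm(length(t_grid), 0, sigma * plateau_signal)
      rows[[trace_i]] <- data.frame(
        time_s = t_grid, F = ai * traj$M + bi + noise,
        binder_conc_M = bc, replicate = r
      )
      truth_ab[[trace_i]] <- data.frame(binder_conc_M = bc, replicate = r,
                                        a = ai, b = bi)
    }
  }
  out <- tht_dataset(do.call(rbind, rows),
                     monomer_conc = params$m_total,
                     binder = "synthetic", binder_Kd = binder_Kd)
  attr(out, "ground_truth") <- list(
    params = params, binder_Kd = binder_Kd,
    k2_factors = data.frame(
      conc = binder_concs,
      factor = vapply(binder_concs, fac_at, numeric(1))),
    K_I = if (is.null(k2_factors)) K_I else NA_real_,
    sigma = sigma, seed = seed, ab = do.call(rbind, truth_ab)
  )
  out
}

#' Generate a synthetic biosensor (BLI) titration dataset
#'
#' Association and dissociation traces from the closed-form 1:1 model at a
#' series of analyte concentrations, with additive Gaussian baseline noise
#' and optional linear drift. Dissociation starts from the true response at
#' the end of the association phase.
#'
#' @param seed integer seed.
#' @param kon,koff rate constants (/M/s, /s).
#' @param Rmax maximal response (sensor units).
#' @param concs analyte concentrations (M).
#' @param t_assoc,t_dissoc phase durations (s).
#' @param dt sampling interval (s).
#' @param sigma noise sd as a fraction of `Rmax`.
#' @param drift linear drift rate (fraction of `Rmax` per s).
#' @param replicates traces per concentration.
#' @return Data frame (`time_s`, `conc_M`, `phase`, `replicate`,
#'   `response`) with attribute `ground_truth`.
#' @export
gen_bli_dataset <- function(seed = 1L, kon = 1e4, koff = 1e-3, Rmax = 1,
                            concs = c(0.25, 0.5, 1, 2, 4) * koff / kon,
                            t_assoc = 600, t_dissoc = 600, dt = 2,
                            sigma = 0.01, drift = 0, replicates = 1L) {
  stopifnot(kon > 0, koff > 0, Rmax > 0, sigma >= 0)
  seed <- as.integer(seed)
  ta <- seq(0, t_assoc, by = dt)
  td <- seq(0, t_dissoc, by = dt)
  rows <- list()
  trace_i <- 0L
  for (cc in concs) {
    Ra <- association_trace(ta, cc, kon, koff, Rmax)
    R0 <- association_trace(t_assoc, cc, kon, koff, Rmax)
    Rd <- dissociation_trace(td, R0, koff)
    for (r in seq_len(replicates)) {
      trace_i <- trace_i + 1L
      set.seed(seed + 1000L * trace_i)
      na <- stats::rnorm(length(ta), 0, sigma * Rmax)
      nd <- stats::rnorm(length(td), 0, sigma * Rmax)
      rows[[trace_i]] <- rbind(
        data.frame(time_s = ta, conc_M = cc, phase = "association",
                   replicate = r,
                   response = Ra + na + drift * Rmax * ta),
        data.frame(time_s = td, conc_M = cc, phase = "dissociation",
                   replicate = r,
                   response = Rd + nd + drift * Rmax * (t_assoc + td))
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- list(kon = kon, koff = koff, Kd = koff / kon,
                                    Rmax = Rmax, sigma = sigma,
                                    drift = drift, seed = seed)
  out
}

#' Generate a synthetic sizing (MDS) titration dataset
#'
#' Fraction-bound readings across a binder titration from the exact
#' ligand-depletion quadratic, with Gaussian noise of sd `sigma` on the
#' fraction scale (so zero-binder rows read 0 +/- noise), in triplicate by
#' default. The apparent hydrodynamic radius, the fraction-weighted mean of
#' the free and complex radii, is reported alongside.
#'
#' @param seed integer seed.
#' @param Kd dissociation constant (M).
#' @param Ltot labeled species concentration (M).
#' @param concs binder concentrations (M).
#' @param replicates readings per concentration.
#' @param sigma noise sd on the fraction-bound scale.
#' @param Rh_free,Rh_complex hydrodynamic radii (nm) of free and bound
#'   labeled species.
#' @return Data frame (`conc_M`, `replicate`, `fraction_bound`, `Rh_nm`)
#'   with attribute `ground_truth`.
#' @export
gen_mds_dataset <- function(seed = 1L, Kd = 83e-9, Ltot = 10e-9,
                            concs = 10^seq(-9, -5, length.out = 12),
                            replicates = 3L, sigma = 0.03,
                            Rh_free = 1.8, Rh_complex = 3.2) {
  stopifnot(Kd > 0, Ltot > 0, sigma >= 0, Rh_complex >= Rh_free,
            Rh_free > 0)
  seed <- as.integer(seed)
  fb <- complex_conc_quadratic(Ltot, concs, Kd) / Ltot
  rows <- list()
  for (r in seq_len(replicates)) {
    set.seed(seed + 1000L * r)
    noisy <- fb + stats::rnorm(length(concs), 0, sigma)
    rows[[r]] <- data.frame(
      conc_M = concs, replicate = r, fraction_bound = noisy,
      Rh_nm = Rh_free + noisy * (Rh_complex - Rh_free)
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- list(Kd = Kd, Ltot = Ltot, sigma = sigma,
                                    Rh_free = Rh_free,
                                    Rh_complex = Rh_complex, seed = seed)
  out
}

#' Composition-preserving sequence shuffles
#'
#' Null model for scanner match counts: shuffles a target protein's
#' sequence `n` times, preserving length and residue composition.
#'
#' @param seed integer seed.
#' @param protein a [target_protein()] or sequence string.
#' @param n number of shuffles.
#' @return List of `target_protein` objects named `<name>_shuf<i>`.
#' @export
gen_scrambled_targets <- function(seed, protein, n = 100L) {
  if (!inherits(protein, "target_protein"))
    protein <- target_protein("query", protein)
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1L]]
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    target_protein(paste0(protein$name, "_shuf", i),
                   paste(sample(chars), collapse = ""))
  })
}
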