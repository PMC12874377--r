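#' Alchemical schedules for the pseudosupercritical path
#'
#' Builds the state schedule of one PSCP stage. Melting is a three-step
#' path: (i) `S->DWF`, weakening the solid's intermolecular interactions
#' under restraints into a dense weak fluid; (ii) `DWF->WF`, expanding
#' the dense weak fluid to the liquid volume; (iii) `WF->L`, restoring
#' full interactions in the liquid. Defaults: `S->DWF` uses 40 equally
#' spaced lambda values on `[0, 1]` plus extra points concentrated in
#' `[0.8, 0.9]` where the energy changes steeply (8 by default);
#' `WF->L` uses 20 equally spaced lambda values; `DWF->WF` uses 20
#' equally spaced volumes between the solid and liquid equilibrium
#' volumes.
#'
#' @param stage `"S->DWF"`, `"DWF->WF"` or `"WF->L"`.
#' @param config optional list overriding `n_lambda`, `n_extra`,
#'   `extra_range`, `n_wfl`, `n_vol`, `V_solid`, `V_liquid`.
#' @return An object of class `alchemical_schedule` with `stage` and
#'   either `lambda` or `volumes` (strictly monotone).
#' @export
build_schedule <- function(stage = c("S->DWF", "DWF->WF", "WF->L"),
                           config = list()) {
  stage <- match.arg(stage)
  cf <- utils::modifyList(list(n_lambda = 40, n_extra = 8,
                               extra_range = c(0.8, 0.9), n_wfl = 20,
                               n_vol = 20, V_solid = NULL,
                               V_liquid = NULL), config)
  if (stage == "S->DWF") {
    lam <- seq(0, 1, length.out = cf$n_lambda)
    if (cf$n_extra > 0) {
      extra <- seq(cf$extra_range[1], cf$extra_range[2],
                   length.out = cf$n_extra + 2)
      extra <- extra[-c(1, length(extra))]
      lam <- sort(unique(c(lam, extra)))
    }
    out <- list(stage = stage, lambda = lam)
  } else if (stage == "WF->L") {
    out <- list(stage = stage,
                lambda = seq(0, 1, length.out = cf$n_wfl))
  } else {
    if (is.null(cf$V_solid) || is.null(cf$V_liquid)) {
      stop("DWF->WF needs V_solid and V_liquid (run the endpoint NPT equilibrations first)")
    }
    out <- list(stage = stage,
                volumes = seq(cf$V_solid, cf$V_liquid,
                              length.out = cf$n_vol))
  }
  v <- if (is.null(out$lambda)) out$volumes else out$lambda
  if (any(diff(v) == 0) || !(all(diff(v) > 0) || all(diff(v) < 0))) {
    stop("schedule values must be strictly monotone")
  }
  if (!is.null(out$lambda) &&
      (out$lambda[1] != 0 || out$lambda[length(out$lambda)] != 1)) {
    stop("lambda schedules must span [0, 1]")
  }
  class(out) <- "alchemical_schedule"
  out
}

#' @export
print.alchemical_schedule <- function(x, ...) {
  v <- if (is.null(x$lambda)) x$volumes else x$lambda
  cat(sprintf("<alchemical_schedule %s> %d states: %s ... %s\n",
              x$stage, length(v), format(v[1]), format(v[length(v)])))
  invisible(x)
}

#' Lambda-scaled potential for a PSCP stage
#'
#' Returns a copy of the system with its interaction scaling set for
#' coupling value `lambda` of the given stage. Van der Waals
#' interactions use soft-core (power-4 shifted) scaling down to a
#' residual floor (`vdw_floor`, the "weak" in weak fluid);
#' electrostatics scale linearly; Gaussian restraints ramp
#' complementarily (fully on in the DWF, off at the physical
#' endpoints). For Einstein-style anchored toys, the harmonic anchors
#' morph linearly toward the system's `anchor_K2` spring set. At
#' `lambda` values corresponding to the physical endpoints the unscaled
#' potential is recovered exactly.
#'
#' @param sys a [toy_system()].
#' @param lambda coupling value in `[0, 1]`.
#' @param stage `"S->DWF"` (lambda 0 = physical solid) or `"WF->L"`
#'   (lambda 1 = physical liquid).
#' @param control list: `vdw_floor` (default 0.1), `softcore_a`
#'   (Angstrom, default 0.5).
#' @return the scaled `toy_system`.
#' @export
scaled_potential <- function(sys, lambda, stage = c("S->DWF", "WF->L"),
                             control = list()) {
  stage <- match.arg(stage)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  cf <- utils::modifyList(list(vdw_floor = 0.1, softcore_a = 0.5),
                          control)
  ## progress toward the weakened state
  w <- if (stage == "S->DWF") lambda else 1 - lambda
  sys$scale$vdw <- 1 - w * (1 - cf$vdw_floor)
  sys$scale$elec <- 1 - w
  sys$scale$restraint <- w
  sys$scale$softcore <- cf$softcore_a * w
  sys$scale$anchor_mix <- if (!is.null(sys$anchor_K2)) w else 0
  sys
}

#' Sample one PSCP stage and estimate its free-energy change
#'
#' Runs NVT Monte Carlo at every state of a schedule, cross-evaluates
#' all configurations under all states, and solves MBAR. For volume
#' stages (`DWF->WF`), configurations are mapped affinely between
#' volumes through fractional centroids (rigid molecular geometry
#' untouched) and the reduced potentials carry the `-M log V`
#' translational measure term.
#'
#' @param sys the stage's base [toy_system()]: the physical endpoint for
#'   `S->DWF` / `WF->L` (restraint and `anchor_K2` fields set as
#'   needed), the weakened DWF system for `DWF->WF`.
#' @param schedule an [build_schedule()] result.
#' @param T temperature (K).
#' @param n_sweeps,thin,seed sampling controls (seed is advanced per
#'   state).
#' @param control passed to [scaled_potential()].
#' @return An object of class `pscp_stage`: `dA` (kJ/mol per molecule,
#'   first state -> last state), `se`, `fit` (the [mbar_solve()]
#'   result), `samples`, `systems`, `states`, `stage`.
#' @export
pscp_stage <- function(sys, schedule, T, n_sweeps = 800, thin = 4,
                       seed = 1, control = list()) {
  stopifnot(inherits(sys, "toy_system"),
            inherits(schedule, "alchemical_schedule"))
  kBT <- .const$kB * T
  volume_stage <- is.null(schedule$lambda)
  if (volume_stage) {
    vols <- schedule$volumes
    V0 <- cell_volume(sys$structure$cell)
    systems <- lapply(vols, function(v) {
      s <- (v / V0)^(1 / 3)
      sys2 <- sys
      cl <- sys$structure$cell
      sys2$structure$cell <- unit_cell(cl$a * s, cl$b * s, cl$c * s,
                                       cl$alpha, cl$beta, cl$gamma)
      sys2
    })
    states <- lapply(vols, function(v) sim_state(T, ensemble = "NVT"))
  } else {
    systems <- lapply(schedule$lambda, function(l)
      scaled_potential(sys, l, schedule$stage, control))
    states <- lapply(schedule$lambda, function(l) {
      st <- sim_state(T, ensemble = "NVT", lambda = l)
      st
    })
  }
  K <- length(systems)
  ## anchored toys: start translation steps near the harmonic optimum
  ## of each state's effective spring so adaptation converges fast
  step_for <- function(sysk) {
    if (is.null(sysk$anchors)) return(0.3)
    Keff <- sysk$anchors$K
    if (!is.null(sysk$anchor_K2) && sysk$scale$anchor_mix > 0) {
      Keff <- (1 - sysk$scale$anchor_mix) * Keff +
        sysk$scale$anchor_mix * sysk$anchor_K2
    }
    0.7 * sqrt(kBT / max(mean(abs(Keff)), 1e-6))
  }
  trajs <- lapply(seq_len(K), function(k)
    run_nvt(systems[[k]], states[[k]], n_sweeps = n_sweeps,
            seed = (seed * 127 + 7919 * k) %% 2147483647,
            thin = thin, store_configs = TRUE,
            step = step_for(systems[[k]])))
  samp <- cross_evaluate_stage(trajs, systems, states,
                               map_cell = volume_stage)
  fit <- mbar_solve(samp)
  d <- delta_f(fit, 1, K)
  structure(list(stage = schedule$stage,
                 dA = kBT * d$df / sys$M, se = kBT * d$se / sys$M,
                 fit = fit, samples = samp, systems = systems,
                 states = states, trajs = trajs, T = T),
            class = "pscp_stage")
}

## cross-evaluation with optional affine volume mapping
cross_evaluate_stage <- function(trajs, systems, states,
                                 map_cell = FALSE,
                                 components = FALSE) {
  if (!map_cell) {
    return(cross_evaluate(trajs, systems, states,
                          components = components))
  }
  K <- length(systems)
  cfgs <- list(); origin <- integer()
  for (k in seq_len(K)) {
    cfgs <- c(cfgs, trajs[[k]]$configs)
    origin <- c(origin, rep(k, length(trajs[[k]]$configs)))
  }
  n <- length(cfgs)
  u_kn <- matrix(0, K, n)
  for (k in seq_len(K)) {
    cellk <- systems[[k]]$structure$cell
    Vk <- cell_volume(cellk)
    M <- systems[[k]]$M
    for (j in seq_len(n)) {
      cfg <- cfgs[[j]]
      cfg$cell <- cellk            # same fractional centroids
      e <- config_energy(systems[[k]], cfg)
      u_kn[k, j] <- reduced_potential(e$total, states[[k]]) -
        M * log(Vk)
    }
  }
  structure(list(u_kn = u_kn, N_k = tabulate(origin, K), comp = NULL,
                 origin = origin),
            class = "alchemical_samples")
}

#' @export
print.pscp_stage <- function(x, ...) {
  cat(sprintf("<pscp_stage %s> dA = %.4f +/- %.4f kJ/mol (T = %g K)\n",
              x$stage, x$dA, x$se, x$T))
  invisible(x)
}

#' Combine PSCP stage free energies
#'
#' Melting: `dA(S -> L) = dA(S -> DWF) + dA(DWF -> WF) + dA(WF -> L)`.
#' Solid-solid: each polymorph is independently converted into a DWF
#' and expanded to the common WF, so
#' `dA(S1 -> Sj) = [dA(S1 -> DWF1) + dA(DWF1 -> WF)] -
#' [dA(Sj -> DWFj) + dA(DWFj -> WF)]`. Stage uncertainties combine in
#' quadrature.
#'
#' @param stages named list of stage results (objects with `dA` and
#'   `se`, e.g. from [pscp_stage()]). Melting needs `s_dwf`, `dwf_wf`,
#'   `wf_l`; solid-solid needs `s1_dwf`, `dwf1_wf`, `sj_dwf`,
#'   `dwfj_wf`.
#' @param kind `"melt"` or `"solid_solid"`.
#' @param T_ref reference temperature (K), metadata.
#' @return An object of class `free_energy_result` with `dA`, `se`,
#'   `kind`, `T_ref`, `stages`.
#' @export
pscp_combine <- function(stages, kind = c("melt", "solid_solid"),
                         T_ref = NA_real_) {
  kind <- match.arg(kind)
  need <- if (kind == "melt") c("s_dwf", "dwf_wf", "wf_l") else
    c("s1_dwf", "dwf1_wf", "sj_dwf", "dwfj_wf")
  miss <- setdiff(need, names(stages))
  if (length(miss)) {
    stop("missing PSCP stage(s): ", paste(miss, collapse = ", "))
  }
  g <- function(nm) stages[[nm]]
  if (kind == "melt") {
    dA <- g("s_dwf")$dA + g("dwf_wf")$dA + g("wf_l")$dA
  } else {
    dA <- (g("s1_dwf")$dA + g("dwf1_wf")$dA) -
      (g("sj_dwf")$dA + g("dwfj_wf")$dA)
  }
  se <- sqrt(sum(vapply(need, function(nm) g(nm)$se^2, 0)))
  structure(list(dA = dA, se = se, kind = kind, T_ref = T_ref,
                 stages = stages[need]),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("<free_energy_result %s> dA = %.4f +/- %.4f kJ/mol at T_ref = %g K\n",
              x$kind, x$dA, x$se, x$T_ref))
  invisible(x)
}

#' Pressure-volume correction to a Helmholtz free-energy difference
#'
#' `dG = dA + P dV`. Near ambient pressure the correction is tiny
#' (1 atm x 10 cm^3/mol is ~0.001 kJ/mol), so `dG ~ dA`; the term is
#' carried anyway.
#'
#' @param dA Helmholtz free-energy difference (kJ/mol).
#' @param P pressure (atm).
#' @param dV molar volume change (cm^3/mol).
#' @return `dG` in kJ/mol.
#' @export
pv_correct <- function(dA, P, dV) {
  dA + P * dV * 101325 * 1e-6 / 1000
}

#' Gibbs free-energy difference versus temperature
#'
#' Temperature extrapolation of a reference PSCP result using reduced
#' free energies from NPT simulations:
#' `dG(T) = kB T [df(T) - df(T_ref)] + (T / T_ref) dG(T_ref)`.
#'
#' @param dG_ref reference Gibbs free-energy difference (kJ/mol per
#'   molecule) at `T_ref`.
#' @param df_table data.frame with columns `T`, `df` (dimensionless
#'   reduced free-energy difference) and optionally `se`.
#' @param T_ref reference temperature; must be a grid point (no
#'   interpolation is attempted).
#' @param dG_ref_se standard error of `dG_ref`.
#' @return data.frame of class `gibbs_curve`: `T`, `dG`, `se` (kJ/mol),
#'   `lo`/`hi` 95% band.
#' @export
gibbs_vs_temperature <- function(dG_ref, df_table, T_ref,
                                 dG_ref_se = 0) {
  if (!all(c("T", "df") %in% names(df_table))) {
    stop("df_table needs columns T and df")
  }
  iref <- which(abs(df_table$T - T_ref) < 1e-9)
  if (length(iref) != 1) {
    stop("T_ref must be a point of the df_table grid; refusing to interpolate")
  }
  kB <- .const$kB
  se_df <- if ("se" %in% names(df_table)) df_table$se else
    rep(0, nrow(df_table))
  dG <- kB * df_table$T * (df_table$df - df_table$df[iref]) +
    df_table$T / T_ref * dG_ref
  se <- vapply(seq_len(nrow(df_table)), function(i) {
    if (i == iref) return(dG_ref_se * 1)
    propagate_uncertainty(se_df[i], se_df[iref], dG_ref_se,
                          df_table$T[i], T_ref)
  }, 0)
  out <- data.frame(T = df_table$T, dG = dG, se = se,
                    lo = dG - 1.96 * se, hi = dG + 1.96 * se)
  class(out) <- c("gibbs_curve", "data.frame")
  out
}

#' Propagate uncertainty of the temperature-extrapolated Gibbs curve
#'
#' `(d dG / kB T)^2 = (d df_T)^2 + (d df_ref)^2 +
#' (d dG_ref / (kB T_ref))^2`.
#'
#' @param ddf_T,ddf_ref standard errors of the reduced free-energy
#'   differences at `T` and `T_ref` (dimensionless), `>= 0`.
#' @param ddG_ref standard error of the reference Gibbs difference
#'   (kJ/mol), `>= 0`.
#' @param T,T_ref temperatures (K).
#' @return standard error of `dG(T)` in kJ/mol.
#' @export
propagate_uncertainty <- function(ddf_T, ddf_ref, ddG_ref, T, T_ref) {
  if (any(c(ddf_T, ddf_ref, ddG_ref) < 0)) {
    stop("uncertainties must be >= 0")
  }
  kB <- .const$kB
  kB * T * sqrt(ddf_T^2 + ddf_ref^2 + (ddG_ref / (kB * T_ref))^2)
}

#' Locate a phase-transition temperature
#'
#' Finds where the Gibbs free-energy difference curve crosses zero by
#' piecewise-linear interpolation; the uncertainty is half the distance
#' between the crossings of the 95% confidence band edges with the zero
#' line. Optionally attaches enthalpy/heat-capacity differences (from
#' [phase_deltas()]) interpolated at the transition, with the
#' equilibrium identity `dS = dH / T*`.
#'
#' @param curve a [gibbs_vs_temperature()] result (columns `T`, `dG`,
#'   `lo`, `hi`).
#' @param deltas optional [phase_deltas()] table.
#' @return An object of class `transition_result` with `found`,
#'   `T_star`, `dT_star`, all roots if several (`roots`, with a
#'   multiplicity warning), and when available `dH`, `dS`, `dCp`.
#'   `found = FALSE` (no exception) when the curve does not change
#'   sign.
#' @export
find_transition <- function(curve, deltas = NULL) {
  lin_roots <- function(T, y) {
    r <- c()
    for (i in seq_len(length(y) - 1)) {
      if (y[i] == 0) r <- c(r, T[i])
      else if (y[i] * y[i + 1] < 0) {
        r <- c(r, T[i] - y[i] * (T[i + 1] - T[i]) / (y[i + 1] - y[i]))
      }
    }
    if (y[length(y)] == 0) r <- c(r, T[length(y)])
    unique(r)
  }
  roots <- lin_roots(curve$T, curve$dG)
  if (length(roots) == 0) {
    return(structure(list(found = FALSE), class = "transition_result"))
  }
  warn <- if (length(roots) > 1) {
    sprintf("multiple sign changes: %d roots", length(roots))
  } else NULL
  T_star <- roots[1]
  r_lo <- lin_roots(curve$T, curve$lo)
  r_hi <- lin_roots(curve$T, curve$hi)
  pick <- function(r) if (length(r)) r[which.min(abs(r - T_star))] else
    NA_real_
  dT <- abs(pick(r_lo) - pick(r_hi)) / 2
  out <- list(found = TRUE, T_star = T_star, dT_star = dT,
              roots = roots, warning = warn)
  if (!is.null(deltas)) {
    out$dH <- stats::approx(deltas$T, deltas$dH, T_star, rule = 2)$y
    out$dH_se <- stats::approx(deltas$T, deltas$dH_se, T_star,
                               rule = 2)$y
    ok <- !is.na(deltas$dCp)
    if (any(ok)) {
      out$dCp <- stats::approx(deltas$T[ok], deltas$dCp[ok], T_star,
                               rule = 2)$y
      out$dCp_se <- stats::approx(deltas$T[ok], deltas$dCp_se[ok],
                                  T_star, rule = 2)$y
    }
    out$dS <- out$dH / T_star
  }
  structure(out, class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  if (!x$found) {
    cat("<transition_result> no sign change on the grid\n")
    return(invisible(x))
  }
  cat(sprintf("<transition_result> T* = %.1f +/- %.1f K\n", x$T_star,
              x$dT_star))
  if (!is.null(x$dH)) {
    cat(sprintf("  dH = %.3f kJ/mol, dS = %.5f kJ/mol/K%s\n", x$dH,
                x$dS, if (!is.null(x$dCp))
                  sprintf(", dCp = %.1f J/mol/K", x$dCp) else ""))
  }
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Decomposition of a solid-solid PSCP free energy
#'
#' Re-expresses `dA(S1 -> Sj)` at the reference temperature in terms of
#' explicit intermolecular interactions: the van der Waals and
#' electrostatic terms come from component-resolved `S -> DWF`
#' sub-stages (electrostatics scaled off first, then van der Waals),
#' while the volumetric term is `dA(DWF1 -> WF) - dA(DWFj -> WF)`.
#'
#' @param s1,sj named lists with elements `elec`, `vdw`, `vol`, each an
#'   object with `dA` and `se` (the component-resolved stage results of
#'   polymorphs S1 and Sj).
#' @param tol tolerance for the closure check `total = vdw + elec +
#'   vol` (kJ/mol), default 0.02 (component rounding scale).
#' @param total optional independently computed total `dA(S1 -> Sj)`
#'   to check closure against; by default the component sum is used.
#' @return An object of class `decomposition_result` with `dA_total`,
#'   `dA_vdw`, `dA_elec`, `dA_vol` and standard errors.
#' @export
decompose_free_energy <- function(s1, sj, tol = 0.02, total = NULL) {
  need <- c("elec", "vdw", "vol")
  for (nm in need) {
    if (is.null(s1[[nm]]) || is.null(sj[[nm]])) {
      stop("component bookkeeping missing: need elec, vdw and vol stage results for both polymorphs")
    }
  }
  comp <- function(nm) {
    list(dA = s1[[nm]]$dA - sj[[nm]]$dA,
         se = sqrt(s1[[nm]]$se^2 + sj[[nm]]$se^2))
  }
  e <- comp("elec"); v <- comp("vdw"); vol <- comp("vol")
  dtot <- e$dA + v$dA + vol$dA
  setot <- sqrt(e$se^2 + v$se^2 + vol$se^2)
  if (!is.null(total) &&
      abs(total - dtot) > tol + 3 * setot) {
    stop(sprintf("decomposition does not close: components sum to %.4f but total is %.4f", dtot, total))
  }
  structure(list(dA_total = if (is.null(total)) dtot else total,
                 dA_vdw = v$dA, dA_elec = e$dA, dA_vol = vol$dA,
                 se_total = setot, se_vdw = v$se, se_elec = e$se,
                 se_vol = vol$se, tol = tol),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> dA = %.3f (vdW %.3f, elec %.3f, vol %.3f) kJ/mol\n",
              x$dA_total, x$dA_vdw, x$dA_elec, x$dA_vol))
  invisible(x)
}

#' Reduced free-energy differences over a temperature grid
#'
#' Builds the `df(T)` table consumed by [gibbs_vs_temperature()] from
#' per-phase NPT trajectories on a common temperature grid. Within each
#' phase, adjacent temperatures are bridged by two-state MBAR on the
#' cross-evaluated reduced potentials `beta (U + P V)` and the chain is
#' accumulated; the difference of the two phases' chains gives
#' `df_{p1 -> p2}(T)` up to a constant that cancels in the
#' extrapolation.
#'
#' @param trajs1,trajs2 lists of trajectories (with stored configs) for
#'   phases 1 and 2, one per temperature. NPT trajectories give reduced
#'   Gibbs free energies; NVT trajectories reduced Helmholtz free
#'   energies (appropriate when, as for the anchored toys, the two
#'   coincide).
#' @param systems1,systems2 the corresponding [toy_system()] objects
#'   (one per temperature; usually the same system repeated).
#' @param T_grid temperatures (K).
#' @return data.frame with `T`, `df`, `se`.
#' @export
temperature_mbar <- function(trajs1, systems1, trajs2, systems2,
                             T_grid) {
  chain <- function(trajs, systems) {
    n <- length(T_grid)
    f <- numeric(n); v <- numeric(n)
    for (i in seq_len(n - 1)) {
      samp <- cross_evaluate(list(trajs[[i]], trajs[[i + 1]]),
                             list(systems[[i]], systems[[i + 1]]),
                             list(trajs[[i]]$state,
                                  trajs[[i + 1]]$state))
      fit <- mbar_solve(samp)
      d <- delta_f(fit, 1, 2)
      M <- systems[[i]]$M
      f[i + 1] <- f[i] + d$df / M
      v[i + 1] <- v[i] + (d$se / M)^2
    }
    list(f = f, var = v)
  }
  c1 <- chain(trajs1, systems1)
  c2 <- chain(trajs2, systems2)
  data.frame(T = T_grid, df = c2$f - c1$f,
             se = sqrt(c1$var + c2$var))
}
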