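#' Thermodynamic state specification
#'
#' @param T temperature (K), `> 0`.
#' @param P pressure (atm); required for NPT.
#' @param ensemble `"NVT"` or `"NPT"`.
#' @param lambda coupling parameter in `[0, 1]` (alchemical states).
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(T, P = NULL, ensemble = c("NVT", "NPT"),
                      lambda = NULL) {
  ensemble <- match.arg(ensemble)
  if (!is.numeric(T) || T <= 0) stop("T must be > 0")
  if (ensemble == "NPT" && (is.null(P) || P < 0)) {
    stop("NPT requires a pressure")
  }
  if (!is.null(lambda) && (lambda < 0 || lambda > 1)) {
    stop("lambda must lie in [0, 1]")
  }
  structure(list(T = T, P = P, ensemble = ensemble, lambda = lambda),
            class = "sim_state")
}

#' Toy sampling system
#'
#' Bundles everything the rigid-body Monte Carlo sampler needs: a
#' crystal (or liquid box) structure, the pair force field, optional
#' harmonic anchors (Einstein-style toys; anchor sites are stored
#' fractionally so they scale affinely under volume moves), optional
#' Gaussian restraints, and the alchemical scaling factors applied by
#' [scaled_potential()].
#'
#' Pair interactions use the minimum-image convention within `cutoff`,
#' which therefore must not exceed half the shortest box length;
#' exceeding it raises an error instructing replication. Electrostatics
#' here are plain minimum-image Coulomb within the cutoff -- a
#' deliberately simple treatment for the neutral, mostly charge-free toy
#' systems the sampler is meant for (the static lattice-energy model
#' retains full Ewald sums).
#'
#' @param structure a [crystal_structure()].
#' @param ff a [force_field()].
#' @param cutoff pair cutoff (Angstrom); default
#'   `min(ff$cutoff_rd, 0.49 * shortest box length)`.
#' @param anchor_K,anchor_u0 optional harmonic anchors (see
#'   [with_anchors()]); sites are the structure's current atom positions.
#' @param restraint optional [restraint_spec()].
#' @return An object of class `toy_system`.
#' @export
toy_system <- function(structure, ff, cutoff = NULL,
                       anchor_K = NULL, anchor_u0 = 0,
                       restraint = NULL) {
  stopifnot(inherits(structure, "crystal_structure"))
  cellm <- cell_matrix(structure$cell)
  minlen <- min(structure$cell$a, structure$cell$b, structure$cell$c)
  if (is.null(cutoff)) cutoff <- min(ff$cutoff_rd, 0.49 * minlen)
  if (cutoff > 0.5 * minlen + 1e-9) {
    stop(sprintf("cutoff %.3g A exceeds the safe minimum-image radius %.3g A: replicate the cell first", cutoff, 0.5 * minlen))
  }
  at <- atom_table(structure)
  anchors <- NULL
  if (!is.null(anchor_K)) {
    tmp <- with_anchors(structure, anchor_K, anchor_u0)$anchors
    anchors <- list(K = tmp$K, sites_frac = tmp$sites %*% solve(cellm),
                    u0 = anchor_u0)
  }
  rest <- NULL
  if (!is.null(restraint)) {
    rest <- restraint
    rest$anchors_frac <- restraint$anchors %*% solve(cellm)
  }
  sys <- list(structure = structure, ff = ff, cutoff = cutoff,
              anchors = anchors, restraint = rest,
              pm = pair_param_matrices(ff, at$type),
              charge = at$charge, mol = at$mol, type = at$type,
              nat_mol = vapply(structure$molecules, n_atoms, 0L),
              M = structure$Z,
              scale = list(vdw = 1, elec = 1, restraint = 0,
                           softcore = 0, anchor_mix = 0),
              anchor_K2 = NULL, u_offset = 0)
  class(sys) <- "toy_system"
  sys
}

## initial configuration from the system's structure
init_config <- function(sys) {
  s <- sys$structure
  list(cents = s$centroids, rots = s$rotations, cell = s$cell)
}

## Cartesian atom coordinates for a configuration
config_coords <- function(sys, cfg) {
  cellm <- cell_matrix(cfg$cell)
  s <- sys$structure
  do.call(rbind, lapply(seq_len(s$Z), function(i) {
    xyz <- s$molecules[[i]]$ref_geom %*% t(cfg$rots[[i]])
    sweep(xyz, 2, as.numeric(cfg$cents[i, , drop = FALSE] %*% cellm), `+`)
  }))
}

## pair + field energy of molecule i against all others (or of the whole
## configuration when i is NULL); returns components
config_energy <- function(sys, cfg, i = NULL, coords = NULL) {
  cellm <- cell_matrix(cfg$cell)
  if (is.null(coords)) coords <- config_coords(sys, cfg)
  sc <- sys$scale
  rows_i <- if (is.null(i)) seq_len(nrow(coords)) else
    which(sys$mol == i)
  Xi <- coords[rows_i, , drop = FALSE]

  ## minimum-image displacements from atoms of interest to all atoms
  inv <- solve(cellm)
  fi <- Xi %*% inv
  fall <- coords %*% inv
  ni <- nrow(fi); nn <- nrow(fall)
  df1 <- rep(fall[, 1], each = ni) - fi[, 1]
  df2 <- rep(fall[, 2], each = ni) - fi[, 2]
  df3 <- rep(fall[, 3], each = ni) - fi[, 3]
  df1 <- df1 - round(df1); df2 <- df2 - round(df2); df3 <- df3 - round(df3)
  dd <- cbind(df1, df2, df3) %*% cellm
  r2 <- rowSums(dd^2)
  dim(r2) <- c(ni, nn)
  moli <- sys$mol[rows_i]
  cross <- outer(moli, sys$mol, `!=`)
  act <- cross & r2 < sys$cutoff^2 & r2 > 1e-12

  u_vdw <- 0; u_elec <- 0
  if (any(act)) {
    rr <- sqrt(r2[act])
    if (sc$softcore > 0) {
      rr <- (rr^4 + sc$softcore^4)^(1 / 4)
    }
    A <- sys$pm$A[rows_i, , drop = FALSE][act]
    B <- sys$pm$B[rows_i, , drop = FALSE][act]
    C <- sys$pm$C[rows_i, , drop = FALSE][act]
    u_vdw <- sc$vdw * sum(A * exp(-rr * B) - C / rr^6)
    if (sc$elec != 0 && any(sys$charge != 0)) {
      qi <- sys$charge[rows_i]
      qq <- (qi * matrix(sys$charge, ni, nn, byrow = TRUE))[act]
      u_elec <- sc$elec * .const$coulomb * sum(qq / rr)
    }
    if (is.null(i)) { u_vdw <- u_vdw / 2; u_elec <- u_elec / 2 }
  }

  u_anchor <- 0
  if (!is.null(sys$anchors)) {
    K <- sys$anchors$K
    if (!is.null(sys$anchor_K2) && sc$anchor_mix > 0) {
      K <- (1 - sc$anchor_mix) * K + sc$anchor_mix * sys$anchor_K2
    }
    sites <- sys$anchors$sites_frac %*% cellm
    d <- Xi - sites[rows_i, , drop = FALSE]
    u_anchor <- 0.5 * sum(K[rows_i, , drop = FALSE] * d * d)
    ## the static offset u0 ramps off together with the physical
    ## anchors so weakened endpoints of different phases coincide
    if (is.null(i)) {
      u_anchor <- u_anchor + (1 - sc$anchor_mix) * sys$anchors$u0
    }
  }

  u_rest <- 0
  if (!is.null(sys$restraint) && sc$restraint != 0) {
    anch <- sys$restraint$anchors_frac %*% cellm
    d2 <- rowSums((Xi - anch[rows_i, , drop = FALSE])^2)
    u_rest <- -sc$restraint * sys$restraint$epsilon *
      sum(exp(-d2 / (2 * sys$restraint$sigma^2)))
  }

  tot <- u_vdw + u_elec + u_anchor + u_rest
  if (is.null(i)) tot <- tot + sys$u_offset
  list(total = tot, vdw = u_vdw, elec = u_elec, anchor = u_anchor,
       restraint = u_rest)
}

## random rotation increment
rand_rot <- function(step) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, 0, step)
  W <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
              3, 3)
  diag(3) + sin(th) * W + (1 - cos(th)) * W %*% W
}

mc_run <- function(sys, state, n_sweeps, seed, thin, burnin,
                   step0, vstep0, store_configs, adapt_every = 25) {
  set.seed(seed)
  npt <- state$ensemble == "NPT"
  beta <- 1 / (.const$kB * state$T)
  cfg <- init_config(sys)
  M <- sys$M
  multi <- any(sys$nat_mol > 1)
  step <- step0; rstep <- step0; vstep <- vstep0
  nburn <- floor(burnin * n_sweeps)
  acc <- rej <- vacc <- vrej <- 0
  acc_w <- 0; try_w <- 0
  coords <- config_coords(sys, cfg)
  e_now <- config_energy(sys, cfg, coords = coords)

  rec_U <- c(); rec_V <- c(); rec_vdw <- c(); rec_elec <- c()
  rec_anchor <- c(); rec_rest <- c()
  configs <- list()

  isotropic <- is.null(sys$anchors) && all(sys$nat_mol >= 1) &&
    !is.null(attr(sys, "liquid"))

  for (sw in seq_len(n_sweeps)) {
    for (im in seq_len(M)) {
      i <- sample.int(M, 1)
      e_old <- config_energy(sys, cfg, i, coords)$total
      cfg2 <- cfg
      cellm <- cell_matrix(cfg$cell)
      dtf <- stats::rnorm(3, 0, step) %*% solve(cellm)
      cfg2$cents[i, ] <- cfg$cents[i, ] + as.numeric(dtf)
      if (multi && sys$nat_mol[i] > 1 && stats::runif(1) < 0.5) {
        cfg2$rots[[i]] <- rand_rot(rstep) %*% cfg$rots[[i]]
      }
      coords2 <- coords
      rows <- which(sys$mol == i)
      xyz <- sys$structure$molecules[[i]]$ref_geom %*% t(cfg2$rots[[i]])
      coords2[rows, ] <- sweep(xyz, 2,
        as.numeric(cfg2$cents[i, , drop = FALSE] %*% cellm), `+`)
      e_new <- config_energy(sys, cfg2, i, coords2)$total
      try_w <- try_w + 1
      if (is.finite(e_new) &&
          stats::runif(1) < exp(-beta * (e_new - e_old))) {
        cfg <- cfg2; coords <- coords2
        acc <- acc + 1; acc_w <- acc_w + 1
      } else rej <- rej + 1
    }
    if (npt) {
      e_now <- config_energy(sys, cfg, coords = coords)
      V <- cell_volume(cfg$cell)
      cfg2 <- cfg
      if (isotropic) {
        lnv <- log(V) + stats::rnorm(1, 0, vstep)
        s <- (exp(lnv) / V)^(1 / 3)
        cfg2$cell <- unit_cell(cfg$cell$a * s, cfg$cell$b * s,
                               cfg$cell$c * s, cfg$cell$alpha,
                               cfg$cell$beta, cfg$cell$gamma)
      } else {
        ax <- sample.int(3, 1)
        s <- exp(stats::rnorm(1, 0, vstep))
        len <- c(cfg$cell$a, cfg$cell$b, cfg$cell$c)
        len[ax] <- len[ax] * s
        cfg2$cell <- unit_cell(len[1], len[2], len[3], cfg$cell$alpha,
                               cfg$cell$beta, cfg$cell$gamma)
      }
      V2 <- cell_volume(cfg2$cell)
      if (sys$cutoff <= 0.5 * min(cfg2$cell$a, cfg2$cell$b,
                                  cfg2$cell$c)) {
        coords2 <- config_coords(sys, cfg2)
        e2 <- config_energy(sys, cfg2, coords = coords2)
        ## log-scale volume proposals: the coordinate-change Jacobian
        ## contributes (M + 1) ln(V'/V) for M scaled molecules
        darg <- -beta * (e2$total - e_now$total +
                           state$P * (V2 - V) * .const$atmA3_to_kJmol) +
          (M + 1) * log(V2 / V)
        if (is.finite(e2$total) && stats::runif(1) < exp(darg)) {
          cfg <- cfg2; coords <- coords2; e_now <- e2
          vacc <- vacc + 1
        } else vrej <- vrej + 1
      } else vrej <- vrej + 1
    }
    ## periodic full-energy refresh and step adaptation
    if (sw %% adapt_every == 0) {
      e_now <- config_energy(sys, cfg, coords = coords)
      if (sw <= nburn) {
        rate <- acc_w / max(1, try_w)
        f <- exp(1.2 * (rate - 0.4))
        step <- min(max(step * f, 1e-5), 5)
        rstep <- min(max(rstep * f, 1e-5), 1.5)
        if (npt && (vacc + vrej) > 0) {
          vr <- vacc / (vacc + vrej)
          vstep <- min(max(vstep * exp(0.5 * (vr - 0.3)), 1e-6), 0.3)
          vacc <- vrej <- 0
        }
        acc_w <- try_w <- 0
      }
    } else if (sw == nburn) {
      acc_w <- try_w <- 0
    }
    if (sw > nburn && (sw - nburn) %% thin == 0) {
      e_now <- config_energy(sys, cfg, coords = coords)
      V <- cell_volume(cfg$cell)
      rec_U <- c(rec_U, e_now$total)
      rec_V <- c(rec_V, V)
      rec_vdw <- c(rec_vdw, e_now$vdw)
      rec_elec <- c(rec_elec, e_now$elec)
      rec_anchor <- c(rec_anchor, e_now$anchor)
      rec_rest <- c(rec_rest, e_now$restraint)
      if (store_configs) {
        configs[[length(configs) + 1]] <-
          list(cents = cfg$cents, rots = cfg$rots, cell = cfg$cell)
      }
    }
  }
  if (length(rec_U) == 0) stop("no samples recorded; increase n_sweeps")
  if (acc == 0) stop("zero acceptance after adaptation: step-size failure")
  H <- rec_U + if (npt) state$P * rec_V * .const$atmA3_to_kJmol else 0
  samples <- data.frame(U = rec_U, V = rec_V, H = H, vdw = rec_vdw,
                        elec = rec_elec, anchor = rec_anchor,
                        restraint = rec_rest)
  structure(list(samples = samples, configs = configs, state = state,
                 seed = seed, n_sweeps = n_sweeps, thin = thin,
                 burnin = burnin, M = M,
                 acceptance = acc / (acc + rej),
                 v_acceptance = if (npt) vacc / max(1, vacc + vrej)
                 else NA_real_,
                 final = cfg),
            class = "trajectory")
}

#' Canonical (NVT) rigid-body Monte Carlo
#'
#' Metropolis Monte Carlo over molecular translations and rotations
#' targeting the canonical distribution of the system's (possibly
#' lambda-scaled, restrained) potential. Step sizes adapt toward ~40%
#' acceptance during burn-in and are then frozen so production sampling
#' obeys detailed balance. Runs are bit-exact reproducible for a fixed
#' seed.
#'
#' @param sys a [toy_system()].
#' @param state a [sim_state()] with ensemble `"NVT"`.
#' @param n_sweeps number of MC sweeps (one attempted move per molecule
#'   per sweep).
#' @param seed RNG seed.
#' @param thin record every `thin`-th sweep after burn-in.
#' @param burnin fraction of sweeps discarded (default 0.4).
#' @param step initial translation step (Angstrom).
#' @param store_configs keep thinned configurations for later
#'   cross-evaluation.
#' @return A `trajectory` object: `samples` data.frame (U, V, H and
#'   energy components per sample), optional `configs`, acceptance
#'   diagnostics.
#' @export
run_nvt <- function(sys, state, n_sweeps = 2000, seed = 1, thin = 5,
                    burnin = 0.4, step = 0.3, store_configs = FALSE) {
  stopifnot(inherits(sys, "toy_system"), inherits(state, "sim_state"))
  if (state$ensemble != "NVT") stop("state must be NVT")
  mc_run(sys, state, n_sweeps, seed, thin, burnin, step, 0,
         store_configs)
}

#' Isothermal-isobaric (NPT) rigid-body Monte Carlo
#'
#' Adds Monte Carlo volume moves to [run_nvt()]: anisotropic single-axis
#' cell-edge moves for crystals, isotropic log-volume moves for liquid
#' boxes (mark a system as liquid with `attr(sys, "liquid") <- TRUE`),
#' with the standard NPT acceptance including the molecular-scaling
#' Jacobian.
#'
#' @inheritParams run_nvt
#' @param vstep initial volume move scale (log units).
#' @return A `trajectory`; `samples$H` holds `U + P V`.
#' @export
run_npt <- function(sys, state, n_sweeps = 2000, seed = 1, thin = 5,
                    burnin = 0.4, step = 0.3, vstep = 0.02,
                    store_configs = FALSE) {
  stopifnot(inherits(sys, "toy_system"), inherits(state, "sim_state"))
  if (state$ensemble != "NPT") stop("state must be NPT")
  mc_run(sys, state, n_sweeps, seed, thin, burnin, step, vstep,
         store_configs)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples (%s, T = %g K), acc %.2f\n",
              nrow(x$samples), x$state$ensemble, x$state$T,
              x$acceptance))
  cat(sprintf("  <U> = %.4f  <V> = %.2f  <H> = %.4f\n",
              mean(x$samples$U), mean(x$samples$V), mean(x$samples$H)))
  invisible(x)
}

## block-averaged standard error
block_se <- function(x, nblocks = 10) {
  n <- length(x)
  if (n < nblocks * 2) nblocks <- max(2, floor(n / 2))
  bl <- split(x, cut(seq_len(n), nblocks, labels = FALSE))
  bm <- vapply(bl, mean, 0)
  stats::sd(bm) / sqrt(length(bm))
}

#' Ensemble averages with block standard errors
#'
#' @param traj a trajectory.
#' @param per_molecule divide by the molecule count.
#' @return data.frame with mean and block-averaged standard error of
#'   `U`, `V` and `H`.
#' @export
traj_means <- function(traj, per_molecule = FALSE) {
  f <- if (per_molecule) traj$M else 1
  data.frame(
    observable = c("U", "V", "H"),
    mean = c(mean(traj$samples$U), mean(traj$samples$V),
             mean(traj$samples$H)) / f,
    se = c(block_se(traj$samples$U), block_se(traj$samples$V),
           block_se(traj$samples$H)) / f)
}

#' Reduced potential of a configuration energy
#'
#' `u = beta * U` for NVT states, `u = beta * (U + P V)` for NPT states
#' (dimensionless).
#'
#' @param U potential energy (kJ/mol, can be a vector).
#' @param state a [sim_state()].
#' @param V volume (Angstrom^3, needed for NPT).
#' @return dimensionless reduced potential.
#' @export
reduced_potential <- function(U, state, V = NULL) {
  beta <- 1 / (.const$kB * state$T)
  if (state$ensemble == "NPT") {
    if (is.null(V)) stop("NPT reduced potential needs the volume")
    beta * (U + state$P * V * .const$atmA3_to_kJmol)
  } else beta * U
}

#' Cross-evaluated reduced potentials for MBAR
#'
#' Evaluates every stored configuration of a list of trajectories under
#' every supplied (system, state) pair, building the `u_kn` matrix and
#' sample counts MBAR consumes.
#'
#' @param trajs list of trajectories run with `store_configs = TRUE`
#'   (one per state, in state order).
#' @param systems list of [toy_system()] objects (the lambda-scaled
#'   potentials), same length/order as `states`.
#' @param states list of [sim_state()] objects.
#' @param components also return per-state vdW/electrostatic component
#'   energies of each sample (for free-energy decomposition).
#' @return An object of class `alchemical_samples`: `u_kn` (K x n
#'   matrix), `N_k`, optional `comp` list.
#' @export
cross_evaluate <- function(trajs, systems, states, components = FALSE) {
  K <- length(systems)
  stopifnot(length(states) == K, length(trajs) == K)
  cfgs <- list(); origin <- integer()
  for (k in seq_len(K)) {
    if (length(trajs[[k]]$configs) == 0) {
      stop("trajectory ", k, " has no stored configurations")
    }
    cfgs <- c(cfgs, trajs[[k]]$configs)
    origin <- c(origin, rep(k, length(trajs[[k]]$configs)))
  }
  n <- length(cfgs)
  u_kn <- matrix(0, K, n)
  comp <- if (components) {
    list(vdw = matrix(0, K, n), elec = matrix(0, K, n))
  } else NULL
  for (k in seq_len(K)) {
    for (j in seq_len(n)) {
      e <- config_energy(systems[[k]], cfgs[[j]])
      V <- cell_volume(cfgs[[j]]$cell)
      u_kn[k, j] <- reduced_potential(e$total, states[[k]], V)
      if (components) {
        comp$vdw[k, j] <- e$vdw; comp$elec[k, j] <- e$elec
      }
    }
  }
  structure(list(u_kn = u_kn, N_k = tabulate(origin, K), comp = comp,
                 origin = origin),
            class = "alchemical_samples")
}

#' Enthalpy and heat-capacity differences between two phases
#'
#' `dH(T) = <H>_B - <H>_A` per mole of molecules from matched NPT
#' trajectory grids, and `dCp(T)` from central finite differences of
#' `dH(T)` on the grid, with block-propagated standard errors.
#'
#' @param trajsA,trajsB lists of NPT trajectories for phases A and B,
#'   one per temperature, in `T_grid` order.
#' @param T_grid temperatures (K) the trajectories were run at.
#' @return data.frame with `T`, `dH`, `dH_se` (kJ/mol), `dCp`,
#'   `dCp_se` (J/mol/K; `NA` at the grid ends).
#' @export
phase_deltas <- function(trajsA, trajsB, T_grid) {
  n <- length(T_grid)
  if (length(trajsA) != n || length(trajsB) != n) {
    stop("trajectory lists must match the temperature grid")
  }
  for (i in seq_len(n)) {
    if (abs(trajsA[[i]]$state$T - T_grid[i]) > 1e-9 ||
        abs(trajsB[[i]]$state$T - T_grid[i]) > 1e-9) {
      stop("trajectory temperatures do not match T_grid")
    }
  }
  hA <- vapply(trajsA, function(t) mean(t$samples$H) / t$M, 0)
  hB <- vapply(trajsB, function(t) mean(t$samples$H) / t$M, 0)
  sA <- vapply(trajsA, function(t) block_se(t$samples$H) / t$M, 0)
  sB <- vapply(trajsB, function(t) block_se(t$samples$H) / t$M, 0)
  dH <- hB - hA
  dH_se <- sqrt(sA^2 + sB^2)
  dCp <- dCp_se <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    dT <- T_grid[i + 1] - T_grid[i - 1]
    dCp[i] <- (dH[i + 1] - dH[i - 1]) / dT * 1000      # J/mol/K
    dCp_se[i] <- sqrt(dH_se[i + 1]^2 + dH_se[i - 1]^2) / dT * 1000
  }
  data.frame(T = T_grid, dH = dH, dH_se = dH_se, dCp = dCp,
             dCp_se = dCp_se)
}

#' Write/read a trajectory store
#'
#' Samples go to a columnar whitespace-separated text table; the state
#' metadata (ensemble, T, P, seed, sweep counts, acceptance) to a JSON
#' sidecar `<path>.json`. Stored configurations are not serialised.
#'
#' @param traj a trajectory.
#' @param path base file path for the sample table.
#' @return `path` ([write_trajectory()]); a reconstructed trajectory
#'   without configurations ([read_trajectory()]).
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(traj$samples, path, row.names = FALSE,
                     quote = FALSE)
  meta <- list(ensemble = traj$state$ensemble, T = traj$state$T,
               P = traj$state$P, lambda = traj$state$lambda,
               seed = traj$seed, n_sweeps = traj$n_sweeps,
               thin = traj$thin, burnin = traj$burnin, M = traj$M,
               acceptance = traj$acceptance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  samples <- utils::read.table(path, header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  state <- sim_state(meta$T, P = meta$P,
                     ensemble = meta$ensemble,
                     lambda = meta$lambda)
  structure(list(samples = samples, configs = list(), state = state,
                 seed = meta$seed, n_sweeps = meta$n_sweeps,
                 thin = meta$thin, burnin = meta$burnin, M = meta$M,
                 acceptance = meta$acceptance, v_acceptance = NA_real_),
            class = "trajectory")
}
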