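#' Image-resolved force constants for lattice dynamics
#'
#' Builds the force-constant blocks `Phi(L)` between atoms of the
#' reference unit cell and atoms in every cell `L` of an
#' `n_sc x n_sc x n_sc` supercell, by computing the analytic Hessian of
#' the full supercell and slicing it. The supercell is sized by the
#' interaction-cutoff rule of [auto_supercell_size()] unless `n_sc` is
#' given.
#'
#' @param structure a [crystal_structure()] at a stationary point.
#' @param ff a [force_field()].
#' @param n_sc supercell replication per axis; default from
#'   [auto_supercell_size()] with the Buckingham cutoff.
#' @return An object of class `force_constants`: list with `blocks`
#'   (array `3*Na x 3*Na x ncells`), `Lfrac` (cell offsets, rows),
#'   `cellm`, `masses`, `n_sc`, `Z`, `Na`.
#' @export
force_constants <- function(structure, ff, n_sc = NULL) {
  if (is.null(n_sc)) {
    n_sc <- auto_supercell_size(structure$cell, ff$cutoff_rd)
  }
  n_sc <- as.integer(n_sc)
  at0 <- atom_table(structure)
  na <- at0$n
  sup <- build_supercell(structure, rep(n_sc, 3))
  if (!is.null(structure$anchors)) {
    sat <- atom_table(sup)
    sup$anchors <- list(K = structure$anchors$K[rep(seq_len(na),
                                                    n_sc^3), ],
                        sites = sat$xyz,
                        u0 = structure$anchors$u0 * n_sc^3)
  }
  gh <- gradient_and_hessian(sup, ff)
  H <- gh$hessian
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H)))) {
    stop("numerical consistency: supercell Hessian not symmetric")
  }
  ## atom ordering from build_supercell: cells (shift index) outer,
  ## molecules inner; cell 0 first
  ncell <- n_sc^3
  blocks <- array(0, c(3 * na, 3 * na, ncell))
  for (lc in seq_len(ncell)) {
    rows <- 1:(3 * na)
    cols <- (lc - 1) * 3 * na + 1:(3 * na)
    blocks[, , lc] <- H[rows, cols]
  }
  shifts <- as.matrix(expand.grid(sa = seq_len(n_sc) - 1L,
                                  sb = seq_len(n_sc) - 1L,
                                  sc = seq_len(n_sc) - 1L))
  structure(list(blocks = blocks, Lfrac = shifts, n_sc = n_sc,
                 cellm = cell_matrix(structure$cell),
                 masses = at0$mass, Na = na, Z = structure$Z,
                 max_grad = max(abs(gh$gradient))),
            class = "force_constants")
}

#' Dynamical matrix at a wave vector
#'
#' Mass-weighted Fourier transform of the force-constant blocks:
#' `D_{ia,jb}(k) = (m_i m_j)^(-1/2) sum_L Phi_{ia,jb}(L) exp(i k . r_L)`.
#' `k` is given in reciprocal fractional coordinates (units of the
#' reciprocal lattice vectors), so phases are `exp(2*pi*i k . L)`.
#'
#' @param fc a [force_constants()] object.
#' @param k length-3 wave vector in reciprocal fractional coordinates.
#' @param herm_tol tolerance on the Hermiticity defect.
#' @return complex Hermitian `3*Na x 3*Na` matrix (kJ/mol/A^2/amu).
#' @export
dynamical_matrix <- function(fc, k, herm_tol = 1e-8) {
  stopifnot(inherits(fc, "force_constants"))
  phase <- exp(2i * pi * as.numeric(fc$Lfrac %*% k))
  D <- matrix(0 + 0i, 3 * fc$Na, 3 * fc$Na)
  for (lc in seq_along(phase)) {
    D <- D + fc$blocks[, , lc] * phase[lc]
  }
  msr <- rep(1 / sqrt(fc$masses), each = 3)
  D <- D * tcrossprod(msr)
  defect <- max(abs(D - Conj(t(D))))
  if (defect > herm_tol * max(1, max(abs(D)))) {
    stop(sprintf("dynamical matrix not Hermitian (defect %.3g); the input force constants are inconsistent", defect))
  }
  (D + Conj(t(D))) / 2
}

#' Phonon frequencies on a k-mesh
#'
#' Diagonalises the dynamical matrix at every point of a uniform
#' Monkhorst-Pack-like mesh commensurate with the supercell (including
#' the Gamma point). The structure must be a tight stationary point of
#' the lattice energy; otherwise spurious imaginary frequencies appear,
#' so a loose gradient is refused with a "minimize first" error. At
#' Gamma, up to three acoustic eigenvalues with `|lambda|` below
#' `acoustic_tol` are zeroed; any eigenvalue below `-acoustic_tol`
#' anywhere flags the structure dynamically unstable.
#'
#' @inheritParams force_constants
#' @param k_mesh optional matrix of k-points (rows, reciprocal
#'   fractional); default the uniform `n_sc^3` mesh.
#' @param acoustic_tol zero/instability tolerance on mass-weighted
#'   eigenvalues (kJ/mol/A^2/amu).
#' @param grad_tol stationarity tolerance (kJ/mol/A).
#' @return An object of class `phonon_spectrum`: `k` (matrix),
#'   `lambda` (nk x 3Na, sorted ascending per k), `omega` (rad/s, signed),
#'   `stable`, `unstable_k`/`unstable_mode` when not, `Na`, `Z`, `n_k`.
#' @export
phonon_frequencies <- function(structure, ff, k_mesh = NULL, n_sc = NULL,
                               acoustic_tol = 1e-6, grad_tol = 1e-6) {
  fc <- force_constants(structure, ff, n_sc)
  if (fc$max_grad > grad_tol) {
    stop(sprintf("structure is not at a stationary point (max |gradient| = %.3g kJ/mol/A > %.1g): minimize first",
                 fc$max_grad, grad_tol))
  }
  if (is.null(k_mesh)) {
    n <- fc$n_sc
    k_mesh <- as.matrix(expand.grid(k1 = (0:(n - 1)) / n,
                                    k2 = (0:(n - 1)) / n,
                                    k3 = (0:(n - 1)) / n))
  }
  k_mesh <- matrix(as.numeric(k_mesh), ncol = 3)
  nk <- nrow(k_mesh)
  nm <- 3 * fc$Na
  lambda <- matrix(0, nk, nm)
  for (ik in seq_len(nk)) {
    D <- dynamical_matrix(fc, k_mesh[ik, ])
    ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
    if (all(k_mesh[ik, ] == 0)) {
      ## zero the (up to three) acoustic translations
      az <- which(abs(ev) < acoustic_tol)
      ev[utils::head(az, 3)] <- 0
    }
    lambda[ik, ] <- ev
  }
  unstable <- lambda < -acoustic_tol
  lambda[abs(lambda) < acoustic_tol & !unstable & lambda < 0] <- 0
  spec <- list(k = k_mesh, lambda = lambda,
               omega = matrix(omega_from_lambda(lambda), nk, nm),
               Na = fc$Na, Z = fc$Z, n_k = nk,
               acoustic_tol = acoustic_tol,
               stable = !any(unstable))
  if (!spec$stable) {
    w <- which(unstable, arr.ind = TRUE)
    spec$unstable_k <- k_mesh[w[, 1], , drop = FALSE]
    spec$unstable_mode <- w[, 2]
  }
  class(spec) <- "phonon_spectrum"
  spec
}

#' @export
print.phonon_spectrum <- function(x, ...) {
  cat(sprintf("<phonon_spectrum> %d k-points x %d modes (%s)\n",
              x$n_k, ncol(x$lambda),
              if (x$stable) "stable" else
                sprintf("UNSTABLE: %d imaginary modes",
                        length(x$unstable_mode))))
  invisible(x)
}

#' Vibrational Helmholtz free energy from a phonon spectrum
#'
#' Quantum harmonic-oscillator free energy summed over modes and
#' averaged over the k-mesh,
#' `A_vib = sum_k sum_n [ hbar*w/2 + kB*T*log(1 - exp(-hbar*w/(kB*T))) ]`
#' normalised per mole of molecules. Zero-frequency (acoustic) modes
#' contribute nothing; at `T = 0` only the zero-point term survives.
#'
#' @param spectrum a [phonon_frequencies()] result, all modes stable.
#' @param T temperature (K), `>= 0`.
#' @return list with `A_vib`, `U_ZPE` and `thermal_minus_TS`
#'   (kJ/mol per molecule).
#' @export
vibrational_free_energy <- function(spectrum, T) {
  stopifnot(inherits(spectrum, "phonon_spectrum"))
  if (!spectrum$stable) {
    w <- spectrum$unstable_k[1, ]
    stop(sprintf("imaginary modes present (first: mode %d at k = [%g %g %g]); cannot evaluate A_vib",
                 spectrum$unstable_mode[1], w[1], w[2], w[3]))
  }
  if (T < 0) stop("T must be >= 0")
  hw <- .const$hbar * spectrum$omega      # kJ/mol per mode
  hw <- hw[hw > 0]
  zpe <- sum(hw) / 2
  thermal <- if (T > 0) {
    sum(.const$kB * T * log1p(-exp(-hw / (.const$kB * T))))
  } else 0
  norm <- spectrum$n_k * spectrum$Z
  list(A_vib = (zpe + thermal) / norm, U_ZPE = zpe / norm,
       thermal_minus_TS = thermal / norm)
}

#' Helmholtz free-energy curves for a set of structures
#'
#' `A(T) = U_latt + A_vib(T)` per mole of molecules on a temperature
#' grid (default 0-400 K in 20 K steps). Geometry is held fixed across
#' temperatures (isochoric single-point evaluations). Structures whose
#' spectra contain imaginary modes get `stable = FALSE` curves with the
#' failure reason instead of free energies.
#'
#' @param structures list of [crystal_structure()] objects (minimized).
#' @param ff a [force_field()].
#' @param T_grid temperature grid (K).
#' @param ... passed to [phonon_frequencies()].
#' @return list of `free_energy_curve` objects: `id`, `T`, `A`, `A_vib`,
#'   `U_ZPE`, `U_static`, `stable`, `reason`.
#' @export
helmholtz_curves <- function(structures, ff, T_grid = seq(0, 400, 20),
                             ...) {
  lapply(seq_along(structures), function(i) {
    s <- structures[[i]]
    id <- if (!is.null(s$id)) s$id else paste0("S", i)
    out <- list(id = id, T = T_grid, stable = TRUE, reason = NULL)
    spec <- tryCatch(phonon_frequencies(s, ff, ...), error = identity)
    if (inherits(spec, "error")) {
      out$stable <- FALSE
      out$reason <- conditionMessage(spec)
    } else if (!spec$stable) {
      w <- spec$unstable_k[1, ]
      out$stable <- FALSE
      out$reason <- sprintf("imaginary frequency: mode %d at k = [%g %g %g]",
                            spec$unstable_mode[1], w[1], w[2], w[3])
    } else {
      u0 <- static_energy(s, ff)
      av <- vapply(T_grid, function(tt)
        vibrational_free_energy(spec, tt)$A_vib, 0)
      out$U_static <- u0
      out$U_ZPE <- vibrational_free_energy(spec, 0)$U_ZPE
      out$A_vib <- av
      out$A <- u0 + av
    }
    class(out) <- "free_energy_curve"
    out
  })
}

#' @export
print.free_energy_curve <- function(x, ...) {
  if (x$stable) {
    cat(sprintf("<free_energy_curve %s> U_static %.4f, U_ZPE %.4f, A(%g K) = %.4f kJ/mol\n",
                x$id, x$U_static, x$U_ZPE, x$T[length(x$T)],
                x$A[length(x$T)]))
  } else {
    cat(sprintf("<free_energy_curve %s> UNSTABLE: %s\n", x$id, x$reason))
  }
  invisible(x)
}

#' Stability screening and free-energy ranking
#'
#' Drops dynamically unstable structures (recording the reason),
#' ranks the survivors by Helmholtz free energy at the selection
#' temperature, and tabulates relative free energies
#' `dA_{S1 -> Sj}(T) = A_{Sj}(T) - A_{S1}(T)` against the rank-1
#' structure.
#'
#' @param curves list of curves from [helmholtz_curves()].
#' @param T_select selection temperature (K), default 300.
#' @param top_k how many structures advance, default 5.
#' @return An object of class `screening_report`: `ranking` data.frame
#'   (id, U_static, A_select, dA, rank, advance), `eliminated`
#'   data.frame (id, reason), `dA_curves` matrix (T x structure),
#'   `T_select`, `T_grid`.
#' @export
screen_and_rank <- function(curves, T_select = 300, top_k = 5) {
  stable <- Filter(function(cv) cv$stable, curves)
  elim <- Filter(function(cv) !cv$stable, curves)
  if (length(stable) == 0) {
    stop("all structures are dynamically unstable; empty ranking")
  }
  Tg <- stable[[1]]$T
  if (!(T_select %in% Tg)) stop("T_select must lie on the curve grid")
  it <- match(T_select, Tg)
  a_sel <- vapply(stable, function(cv) cv$A[it], 0)
  ord <- order(a_sel)
  stable <- stable[ord]; a_sel <- a_sel[ord]
  A <- vapply(stable, function(cv) cv$A, numeric(length(Tg)))
  if (is.null(dim(A))) A <- matrix(A, nrow = length(Tg))
  dA <- A - A[, 1]
  colnames(dA) <- vapply(stable, function(cv) cv$id, "")
  ranking <- data.frame(
    id = colnames(dA),
    U_static = vapply(stable, function(cv) cv$U_static, 0),
    A_select = a_sel,
    dA = a_sel - a_sel[1],
    rank = seq_along(stable),
    advance = seq_along(stable) <= top_k)
  out <- list(ranking = ranking,
              eliminated = data.frame(
                id = vapply(elim, function(cv) cv$id, ""),
                reason = vapply(elim, function(cv) cv$reason, "")),
              dA_curves = dA, T_grid = Tg, T_select = T_select,
              top_k = top_k)
  class(out) <- "screening_report"
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> at %g K (top %d advance)\n",
              x$T_select, x$top_k))
  print(x$ranking, row.names = FALSE)
  if (nrow(x$eliminated)) {
    cat("eliminated:\n")
    print(x$eliminated, row.names = FALSE)
  }
  invisible(x)
}

#' Rigid-body lattice relaxation
#'
#' Quasi-Newton (BFGS) minimisation of the lattice energy over molecular
#' centroids and orientations at fixed cell, with analytic forces and
#' torques projected from the atomic gradient; optionally an isotropic
#' cell scale. Lets fixture structures reach tight minima before lattice
#' dynamics.
#'
#' @param structure a [crystal_structure()].
#' @param ff a [force_field()].
#' @param relax_cell also optimise an isotropic cell scale factor.
#' @param maxit iteration budget.
#' @return list with `structure` (relaxed), `energy`, `converged`,
#'   `max_grad`.
#' @export
relax_structure <- function(structure, ff, relax_cell = FALSE,
                            maxit = 200) {
  z <- structure$Z
  pack <- function(s, lsc) {
    c(as.numeric(s$centroids), rep(0, 3 * z), if (relax_cell) lsc)
  }
  rotvec_to_R <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    a <- v / th
    W <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(th) * W + (1 - cos(th)) * W %*% W
  }
  base <- structure
  unpack <- function(p) {
    s <- base
    s$centroids <- matrix(p[1:(3 * z)], z, 3)
    rv <- matrix(p[3 * z + 1:(3 * z)], z, 3)
    for (i in seq_len(z)) {
      s$rotations[[i]] <- rotvec_to_R(rv[i, ]) %*% base$rotations[[i]]
    }
    if (relax_cell) {
      sc <- exp(p[length(p)])
      s$cell <- unit_cell(base$cell$a * sc, base$cell$b * sc,
                          base$cell$c * sc, base$cell$alpha,
                          base$cell$beta, base$cell$gamma)
    }
    s
  }
  fn <- function(p) {
    s <- unpack(p)
    pt <- periodic_terms(s, ff)
    pt$u_rd + pt$u_elec
  }
  gr <- function(p) {
    s <- unpack(p)
    pt <- periodic_terms(s, ff, do_grad = TRUE)
    at <- atom_table(s)
    g <- pt$grad
    cellm <- cell_matrix(s$cell)
    gc <- matrix(0, z, 3); gt <- matrix(0, z, 3)
    for (i in seq_len(z)) {
      rows <- at$mol == i
      F <- g[rows, , drop = FALSE]
      gc[i, ] <- colSums(F) %*% t(cellm)   # d/d frac = dU/dx . dx/dfrac
      cen <- colMeans(at$xyz[rows, , drop = FALSE])
      rrel <- sweep(at$xyz[rows, , drop = FALSE], 2, cen)
      ## torque about current orientation: dU/dtheta = sum r x F
      gt[i, ] <- colSums(cbind(rrel[, 2] * F[, 3] - rrel[, 3] * F[, 2],
                               rrel[, 3] * F[, 1] - rrel[, 1] * F[, 3],
                               rrel[, 1] * F[, 2] - rrel[, 2] * F[, 1]))
    }
    out <- c(as.numeric(gc), as.numeric(gt))
    if (relax_cell) {
      h <- 1e-5
      pp <- p; pp[length(p)] <- p[length(p)] + h
      pm <- p; pm[length(p)] <- p[length(p)] - h
      out <- c(out, (fn(pp) - fn(pm)) / (2 * h))
    }
    out
  }
  p0 <- pack(structure, 0)
  opt <- stats::optim(p0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  ## re-base and polish once (rotation vectors are incremental)
  base <- unpack(opt$par)
  base$rotations <- lapply(base$rotations, identity)
  p1 <- pack(base, if (relax_cell) 0 else NULL)
  opt2 <- stats::optim(p1, fn, gr, method = "BFGS",
                       control = list(maxit = maxit, reltol = 1e-16))
  s <- unpack(opt2$par)
  pt <- periodic_terms(s, ff, do_grad = TRUE)
  list(structure = s, energy = pt$u_rd + pt$u_elec,
       converged = opt2$convergence == 0,
       max_grad = max(abs(pt$grad)))
}
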