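#' Buckingham (exp-6) pair energy
#'
#' `U(r) = A * exp(-r * B) - C / r^6`. The exponent is written with `B`
#' in 1/Angstrom.
#'
#' @param r interatomic distance (Angstrom), `> 0`; vectorised.
#' @param params numeric vector `c(A, B, C)` (kJ/mol, 1/Angstrom,
#'   kJ mol^-1 Angstrom^6).
#' @return Energy in kJ/mol.
#' @examples
#' buckingham_pair_energy(2, c(1000, 3, 100))
#' @export
buckingham_pair_energy <- function(r, params) {
  if (any(r <= 0)) stop("r must be > 0")
  params <- as.numeric(params)
  params[1] * exp(-r * params[2]) - params[3] / r^6
}

erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
erf_ <- function(x) 1 - erfc_(x)

## auto-tuned Ewald parameters for a given cell and target accuracy
ewald_params <- function(cell, ff) {
  if (!identical(ff$ewald, "auto")) return(ff$ewald)
  s <- sqrt(-log(ff$ewald_accuracy))
  rcut <- max(min(cell$a, cell$b, cell$c), 8)
  alpha <- s / rcut
  list(alpha = alpha, rcut = rcut, gcut = 2 * alpha * s)
}

## integer lattice shifts (rows) covering |t . M| <= R plus a margin for
## intra-cell atom spread
image_shifts <- function(cell, R) {
  g <- reciprocal_matrix(cell)
  heights <- 2 * pi / sqrt(rowSums(g^2))
  nmax <- pmax(0L, as.integer(ceiling(R / heights)) + 1L)
  as.matrix(expand.grid(n1 = -nmax[1]:nmax[1],
                        n2 = -nmax[2]:nmax[2],
                        n3 = -nmax[3]:nmax[3]))
}

## reciprocal vectors with 0 < |G| <= gcut, half space only (callers
## double their contributions)
recip_vectors <- function(cell, gcut) {
  g <- reciprocal_matrix(cell)
  nb <- as.integer(ceiling(gcut / min(svd(g)$d))) + 1L
  grid <- as.matrix(expand.grid(m1 = -nb:nb, m2 = -nb:nb, m3 = -nb:nb))
  G <- grid %*% g
  g2 <- rowSums(G^2)
  hs <- (grid[, 1] > 0) |
    (grid[, 1] == 0 & grid[, 2] > 0) |
    (grid[, 1] == 0 & grid[, 2] == 0 & grid[, 3] > 0)
  G[g2 > 1e-12 & g2 <= gcut^2 & hs, , drop = FALSE]
}

## ---------------------------------------------------------------------
## Core periodic evaluator: energy, gradient and Hessian of
##   U_rd   : Buckingham over intermolecular pairs within cutoff_rd
##   U_elec : full Ewald (real + reciprocal + self) of the point charges
##            with intramolecular pairs excluded via erf corrections
## All periodic images are generated explicitly, so cutoffs may exceed
## the cell dimensions. Real-space terms are accumulated over ordered
## pairs and halved at the end.
## ---------------------------------------------------------------------
periodic_terms <- function(structure, ff, do_grad = FALSE,
                           do_hess = FALSE) {
  at <- atom_table(structure)
  N <- at$n
  X <- at$xyz
  q <- at$charge
  have_q <- any(q != 0)
  pm <- pair_param_matrices(ff, at$type)
  ew <- ewald_params(structure$cell, ff)
  alpha <- ew$alpha
  rc_rd <- ff$cutoff_rd
  rc_el <- if (have_q) ew$rcut else 0
  ke <- .const$coulomb

  shifts <- image_shifts(structure$cell, max(rc_rd, rc_el))
  cellm <- cell_matrix(structure$cell)
  tvec <- shifts %*% cellm

  u_rd <- 0; u_real <- 0; u_excl <- 0
  grad <- if (do_grad) matrix(0, N, 3) else NULL
  Hsub <- if (do_hess) {
    H0 <- replicate(9, matrix(0, N, N), simplify = FALSE)
    dim(H0) <- c(3, 3); H0
  } else NULL

  samemol <- outer(at$mol, at$mol, `==`)
  diagN <- diag(N) > 0
  qq <- if (have_q) ke * outer(q, q) else NULL

  for (s in seq_len(nrow(tvec))) {
    t0 <- all(shifts[s, ] == 0L)
    dx <- rep(X[, 1], each = N) - X[, 1] + tvec[s, 1]
    dy <- rep(X[, 2], each = N) - X[, 2] + tvec[s, 2]
    dz <- rep(X[, 3], each = N) - X[, 3] + tvec[s, 3]
    dim(dx) <- dim(dy) <- dim(dz) <- c(N, N)   # [i, j] = x_j - x_i + t
    r2 <- dx * dx + dy * dy + dz * dz
    r <- sqrt(pmax(r2, 1e-300))

    mask_rd <- r2 < rc_rd^2 & r2 > 1e-12
    if (t0) mask_rd <- mask_rd & !samemol
    mask_el <- if (have_q) {
      m <- r2 < rc_el^2 & r2 > 1e-12
      if (t0) m & !samemol else m
    } else FALSE
    mask_ex <- if (have_q && t0) (samemol & !diagN) else FALSE

    any_rd <- any(mask_rd); any_el <- any(mask_el); any_ex <- any(mask_ex)
    if (!any_rd && !any_el && !any_ex) next

    dphi <- matrix(0, N, N)
    ddphi <- if (do_hess) matrix(0, N, N) else NULL

    if (any_rd) {
      rr <- r[mask_rd]
      A <- pm$A[mask_rd]; B <- pm$B[mask_rd]; C <- pm$C[mask_rd]
      eb <- exp(-rr * B)
      u_rd <- u_rd + sum(A * eb - C / rr^6)
      if (do_grad || do_hess) {
        dphi[mask_rd] <- dphi[mask_rd] - A * B * eb + 6 * C / rr^7
      }
      if (do_hess) {
        ddphi[mask_rd] <- ddphi[mask_rd] + A * B^2 * eb - 42 * C / rr^8
      }
    }
    if (any_el) {
      rr <- r[mask_el]
      erfc_ar <- erfc_(alpha * rr)
      gauss <- (2 * alpha / sqrt(pi)) * exp(-alpha^2 * rr^2)
      p <- qq[mask_el]
      u_real <- u_real + sum(p * erfc_ar / rr)
      if (do_grad || do_hess) {
        dphi[mask_el] <- dphi[mask_el] -
          p * (erfc_ar / rr^2 + gauss / rr)
      }
      if (do_hess) {
        ddphi[mask_el] <- ddphi[mask_el] +
          p * (2 * erfc_ar / rr^3 + gauss * (2 / rr^2 + 2 * alpha^2))
      }
    }
    if (any_ex) {
      rr <- r[mask_ex]
      erf_ar <- erf_(alpha * rr)
      gauss <- (2 * alpha / sqrt(pi)) * exp(-alpha^2 * rr^2)
      p <- qq[mask_ex]
      u_excl <- u_excl - sum(p * erf_ar / rr)
      if (do_grad || do_hess) {
        dphi[mask_ex] <- dphi[mask_ex] -
          p * (gauss / rr - erf_ar / rr^2)
      }
      if (do_hess) {
        ddphi[mask_ex] <- ddphi[mask_ex] -
          p * (2 * erf_ar / rr^3 - gauss * (2 / rr^2 + 2 * alpha^2))
      }
    }

    if (do_grad || do_hess) {
      act <- (mask_rd | mask_el | mask_ex) & !diagN
      if (!any(act)) next
      w1 <- matrix(0, N, N)
      w1[act] <- dphi[act] / r[act]
      if (do_grad) {
        gx <- w1 * dx; gy <- w1 * dy; gz <- w1 * dz
        grad[, 1] <- grad[, 1] - rowSums(gx) + colSums(gx)
        grad[, 2] <- grad[, 2] - rowSums(gy) + colSums(gy)
        grad[, 3] <- grad[, 3] - rowSums(gz) + colSums(gz)
      }
      if (do_hess) {
        c1 <- matrix(0, N, N)
        c1[act] <- (ddphi[act] - dphi[act] / r[act]) / r2[act]
        D <- list(dx, dy, dz)
        for (a in 1:3) for (b in a:3) {
          K <- c1 * D[[a]] * D[[b]]
          if (a == b) K <- K + w1
          K[!act] <- 0
          Hab <- Hsub[[a, b]] - K
          diag(Hab) <- diag(Hab) + rowSums(K) + colSums(K)
          Hsub[[a, b]] <- Hab
        }
      }
    }
  }

  ## ordered-pair sums: energies and gradients count every interaction
  ## twice; Hessian sub-block diagonals too, but their off-diagonal
  ## entries only once (the mirrored ordering writes to the transposed
  ## entry)
  u_rd <- u_rd / 2; u_real <- u_real / 2; u_excl <- u_excl / 2
  if (do_grad) grad <- grad / 2
  if (do_hess) for (a in 1:3) for (b in a:3) {
    Hab <- Hsub[[a, b]]
    diag(Hab) <- diag(Hab) / 2
    Hsub[[a, b]] <- Hab
  }

  ## reciprocal and self terms
  u_recip <- 0; u_self <- 0
  if (have_q) {
    V <- cell_volume(structure$cell)
    G <- recip_vectors(structure$cell, ew$gcut)
    base <- 2 * pi * ke / V
    theta <- X %*% t(G)
    ct <- cos(theta); st <- sin(theta)
    Cg <- colSums(q * ct); Sg <- colSums(q * st)
    Ag <- exp(-rowSums(G^2) / (4 * alpha^2)) / rowSums(G^2)
    u_recip <- 2 * base * sum(Ag * (Cg^2 + Sg^2))
    u_self <- -ke * alpha / sqrt(pi) * sum(q^2)
    if (do_grad) {
      coef <- q * (sweep(ct, 2, Sg, `*`) - sweep(st, 2, Cg, `*`))
      for (a in 1:3) {
        grad[, a] <- grad[, a] +
          4 * base * rowSums(sweep(coef, 2, Ag * G[, a], `*`))
      }
    }
    if (do_hess) {
      for (gi in seq_len(nrow(G))) {
        w <- 4 * base * Ag[gi]
        cd <- outer(ct[, gi], ct[, gi]) + outer(st[, gi], st[, gi])
        M <- w * outer(q, q) * cd
        dM <- w * (q^2 - q * (Cg[gi] * ct[, gi] + Sg[gi] * st[, gi]))
        for (a in 1:3) for (b in a:3) {
          K <- G[gi, a] * G[gi, b] * M
          diag(K) <- G[gi, a] * G[gi, b] * dM
          Hsub[[a, b]] <- Hsub[[a, b]] + K
        }
      }
    }
  }

  H <- NULL
  if (do_hess) {
    H <- matrix(0, 3 * N, 3 * N)
    ia <- function(a) seq(a, 3 * N, by = 3)
    for (a in 1:3) for (b in a:3) {
      H[ia(a), ia(b)] <- Hsub[[a, b]]
      if (a != b) H[ia(b), ia(a)] <- t(Hsub[[a, b]])
    }
    H <- (H + t(H)) / 2
  }

  list(u_rd = u_rd, u_elec = u_real + u_recip + u_self + u_excl,
       u_real = u_real, u_recip = u_recip, u_self = u_self,
       u_excl = u_excl,
       grad = grad, H = H, N = N, ewald = ew)
}

#' Static lattice energy
#'
#' Decomposes the static lattice energy of a rigid-molecule crystal as
#' `U_latt = dU_intra + U_elec + U_rd`, where the intramolecular change
#' `dU_intra` is identically zero under the rigid-body model, `U_rd` is
#' the Buckingham repulsion-dispersion sum over intermolecular pairs and
#' `U_elec` the point-charge Ewald energy with intramolecular exclusions.
#' All values are reported per mole of molecules.
#'
#' @param structure a [crystal_structure()] (charge neutral).
#' @param ff a [force_field()] covering all atom types in the structure.
#' @return An object of class `energy_breakdown` with components
#'   `U_latt`, `U_inter`, `U_elec`, `U_rd`, `dU_intra` (kJ/mol per mole
#'   of molecules).
#' @export
lattice_energy <- function(structure, ff) {
  stopifnot(inherits(structure, "crystal_structure"),
            inherits(ff, "force_field"))
  pt <- periodic_terms(structure, ff)
  z <- structure$Z
  res <- list(U_rd = pt$u_rd / z, U_elec = pt$u_elec / z, dU_intra = 0)
  res$U_inter <- res$U_rd + res$U_elec
  res$U_latt <- res$U_inter + res$dU_intra
  res$ewald <- pt$ewald
  class(res) <- "energy_breakdown"
  res
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> (kJ/mol per molecule)\n  U_latt  %12.6f\n  U_elec  %12.6f\n  U_rd    %12.6f\n  dU_intra %11.6f\n",
              x$U_latt, x$U_elec, x$U_rd, x$dU_intra))
  invisible(x)
}

#' Analytic gradient and Hessian of the lattice energy
#'
#' First and second derivatives of `U_rd + U_elec` (plus any harmonic
#' anchor terms attached to the structure, see [anchor_spec()]) with
#' respect to the Cartesian positions of the atoms in the unit cell,
#' including all periodic-image contributions. The Hessian is the force
#' constant matrix used by lattice dynamics.
#'
#' @inheritParams lattice_energy
#' @return list with `gradient` (N x 3 matrix, kJ/mol/Angstrom), `hessian`
#'   (3N x 3N symmetric matrix, kJ/mol/Angstrom^2; coordinate order is
#'   atom-major x,y,z) and `energy` (total cell energy, kJ/mol).
#' @export
gradient_and_hessian <- function(structure, ff) {
  pt <- periodic_terms(structure, ff, do_grad = TRUE, do_hess = TRUE)
  g <- pt$grad
  H <- pt$H
  en <- pt$u_rd + pt$u_elec
  an <- structure$anchors
  if (!is.null(an)) {
    ae <- anchor_terms(structure, an)
    en <- en + ae$energy
    g <- g + ae$grad
    H <- H + ae$H
  }
  list(gradient = g, hessian = H, energy = en)
}

## -------------------- harmonic anchors (Einstein toys) ----------------

#' Harmonic anchor specification
#'
#' Attaches independent harmonic site anchors to every atom of a
#' structure: `U = u0 + 1/2 * sum_ia K_ia (x_ia - s_ia)^2`. Anchors turn
#' a crystal into an Einstein-style toy with an exactly known spectrum
#' and free energy; negative spring entries build saddle-point decoys.
#'
#' @param structure the [crystal_structure()] whose current atom
#'   positions become the anchor sites.
#' @param K spring constant(s), kJ/mol/Angstrom^2: a scalar, a per-atom
#'   vector, or an N x 3 per-atom-per-axis matrix.
#' @param u0 constant energy offset for the whole cell (kJ/mol).
#' @return The structure with an `anchors` field set.
#' @export
with_anchors <- function(structure, K, u0 = 0) {
  at <- atom_table(structure)
  if (is.matrix(K)) {
    Km <- K
  } else if (length(K) == 1) {
    Km <- matrix(K, at$n, 3)
  } else if (length(K) == 3) {
    Km <- matrix(K, at$n, 3, byrow = TRUE)
  } else if (length(K) == at$n) {
    Km <- matrix(rep(K, 3), at$n, 3)
  } else stop("bad K shape")
  if (!all(dim(Km) == c(at$n, 3))) stop("bad K shape")
  structure$anchors <- list(K = Km, sites = at$xyz, u0 = u0)
  structure
}

#' @rdname with_anchors
#' @param anchors an anchor list as stored by [with_anchors()].
#' @export
anchor_spec <- function(structure, K, u0 = 0) with_anchors(structure, K, u0)

anchor_terms <- function(structure, an) {
  at <- atom_table(structure)
  d <- at$xyz - an$sites
  en <- an$u0 + 0.5 * sum(an$K * d * d)
  g <- an$K * d
  N <- at$n
  H <- matrix(0, 3 * N, 3 * N)
  diag(H) <- as.numeric(t(an$K))    # atom-major x,y,z ordering
  list(energy = en, grad = g, H = H)
}

#' Static energy including anchors
#'
#' `U_latt` from [lattice_energy()] plus any anchor contribution, per
#' mole of molecules; the static part of the Helmholtz free energy
#' curves.
#'
#' @inheritParams lattice_energy
#' @return scalar, kJ/mol per molecule.
#' @export
static_energy <- function(structure, ff) {
  u <- lattice_energy(structure, ff)$U_latt
  an <- structure$anchors
  if (!is.null(an)) {
    u <- u + anchor_terms(structure, an)$energy / structure$Z
  }
  u
}

## -------------------- Gaussian restraints (PSCP) ----------------------

#' Gaussian restraint specification
#'
#' The pseudosupercritical path tethers every atom to an anchor point
#' with an attractive Gaussian well `-epsilon * exp(-|x - x0|^2 /
#' (2 sigma^2))`, keeping weakened intermediates ordered.
#'
#' @param epsilon well depth, kJ/mol, `> 0`. The protocol's convergence
#'   check runs both 20.92 and 41.84 kJ/mol.
#' @param sigma well width, Angstrom, `> 0`.
#' @param anchors N x 3 matrix of anchor Cartesian positions (Angstrom).
#' @return An object of class `restraint_spec`.
#' @export
restraint_spec <- function(epsilon, sigma, anchors) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  anchors <- matrix(as.numeric(anchors), ncol = 3)
  structure(list(epsilon = epsilon, sigma = sigma, anchors = anchors),
            class = "restraint_spec")
}

#' Gaussian restraint energy of one atom
#'
#' @param position Cartesian position (Angstrom, 3-vector).
#' @param spec a [restraint_spec()].
#' @param atom index of the restrained atom (selects its anchor row).
#' @return Energy in kJ/mol; `-epsilon` at the anchor, `0` far away.
#' @export
gaussian_restraint_energy <- function(position, spec, atom = 1L) {
  stopifnot(inherits(spec, "restraint_spec"))
  d2 <- sum((as.numeric(position) - spec$anchors[atom, ])^2)
  -spec$epsilon * exp(-d2 / (2 * spec$sigma^2))
}

## total restraint energy for an N x 3 coordinate matrix
restraint_energy_all <- function(X, spec) {
  d2 <- rowSums((X - spec$anchors)^2)
  -spec$epsilon * sum(exp(-d2 / (2 * spec$sigma^2)))
}

#' Calibrate the Gaussian restraint width
#'
#' Chooses `sigma` so that the Boltzmann positional variance of a single
#' atom in the well at temperature `T` matches a target variance
#' (normally the per-atom positional variance measured in an NVT run of
#' the crystal). The variance is computed by radial quadrature of the
#' Boltzmann density over the well region (out to where the well has
#' decayed to 1% of its depth; beyond that the crystal cage, not the
#' restraint, confines the atom) and the width solved by root finding.
#'
#' @param epsilon well depth (kJ/mol).
#' @param T temperature (K).
#' @param target_variance target one-dimensional positional variance
#'   (Angstrom^2).
#' @return calibrated `sigma` (Angstrom).
#' @export
calibrate_restraint_sigma <- function(epsilon, T, target_variance) {
  beta <- 1 / (.const$kB * T)
  var1d <- function(sigma) {
    rmax <- sigma * sqrt(-2 * log(0.01))
    w <- function(r) r^2 * exp(beta * epsilon * exp(-r^2 / (2 * sigma^2)))
    z <- stats::integrate(w, 0, rmax, rel.tol = 1e-10)$value
    m2 <- stats::integrate(function(r) r^2 * w(r), 0, rmax,
                           rel.tol = 1e-10)$value
    m2 / z / 3                           # isotropic: <x^2> = <r^2>/3
  }
  f <- function(s) var1d(s) - target_variance
  s0 <- sqrt(epsilon * target_variance * beta)  # harmonic guess
  stats::uniroot(f, c(s0 / 10, s0 * 10), tol = 1e-10)$root
}
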