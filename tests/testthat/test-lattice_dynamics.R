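## hand-built force constants for a 1D nearest-neighbour spring chain
## on a ring of n cells (one atom per cell)
chain_fc <- function(K, m, n, a = 4) {
  blocks <- array(0, c(3, 3, n))
  blocks[1, 1, 1] <- 2 * K
  blocks[1, 1, 2] <- -K
  blocks[1, 1, n] <- -K
  structure(list(blocks = blocks,
                 Lfrac = cbind(0:(n - 1), 0, 0), n_sc = n,
                 cellm = diag(3) * a, masses = m, Na = 1, Z = 1,
                 max_grad = 0),
            class = "force_constants")
}

test_that("dynamical matrices are Hermitian and real at Gamma", {
  st <- einstein_crystal(2.2)
  fc <- force_constants(st, einstein_ff(), n_sc = 2)
  for (k in list(c(0, 0, 0), c(0.5, 0, 0), c(0.5, 0.5, 0.5))) {
    D <- dynamical_matrix(fc, k)
    expect_lt(max(abs(D - Conj(t(D)))), 1e-10)
  }
  D0 <- dynamical_matrix(fc, c(0, 0, 0))
  expect_lt(max(abs(Im(D0))), 1e-12)
})

test_that("1D chain reproduces the textbook dispersion relation", {
  K <- 5; m <- 10; n <- 6
  fc <- chain_fc(K, m, n)
  ## brute-force 2-term Fourier sum oracle: lambda(k) = (2K - 2K cos(2 pi k))/m
  for (kk in (0:(n - 1)) / n) {
    D <- dynamical_matrix(fc, c(kk, 0, 0))
    lam <- max(Re(eigen(D, symmetric = TRUE, only.values = TRUE)$values))
    oracle <- (2 * K - K * exp(2i * pi * kk) - K * exp(-2i * pi * kk)) / m
    expect_equal(lam, Re(oracle), tolerance = 1e-12)
    expect_equal(lam, 4 * K / m * sin(pi * kk)^2, tolerance = 1e-12)
  }
})

test_that("Einstein toy has a flat spectrum at sqrt(K/m)", {
  K <- 2.2
  st <- einstein_crystal(K)
  spec <- phonon_frequencies(st, einstein_ff(), n_sc = 2)
  lam_expect <- K / 14.007
  expect_equal(as.numeric(spec$lambda), rep(lam_expect, length(spec$lambda)),
               tolerance = 1e-10)
  expect_equal(as.numeric(spec$omega),
               rep(sqrt(lam_expect * 1e26), length(spec$omega)),
               tolerance = 1e-4)
  expect_true(spec$stable)
})

test_that("fcc lattice has three acoustic modes and a stable spectrum", {
  ff <- exp6_ff()
  aopt <- stats::optimize(function(a)
    lattice_energy(fcc_argon(a), ff)$U_latt, c(4.5, 6.5),
    tol = 1e-10)$minimum
  spec <- phonon_frequencies(fcc_argon(aopt), ff, n_sc = 2,
                             grad_tol = 1e-5)
  expect_true(spec$stable)
  gam <- spec$lambda[rowSums(abs(spec$k)) == 0, ]
  expect_equal(sort(gam)[1:3], c(0, 0, 0))
  expect_gt(sort(gam)[4], 1e-4)
})

test_that("a saddle-point decoy is flagged unstable with its k-point", {
  st <- einstein_crystal(2.2)
  Kd <- st$anchors$K; Kd[, 3] <- -0.8
  st$anchors$K <- Kd
  spec <- phonon_frequencies(st, einstein_ff(), n_sc = 2)
  expect_false(spec$stable)
  expect_true(any(spec$lambda < -1e-6))
  expect_error(vibrational_free_energy(spec, 300), "imaginary")
})

test_that("non-stationary structures are refused with a minimize-first error", {
  ff <- exp6_ff()
  st <- fcc_argon(5.3)
  st$centroids[2, ] <- st$centroids[2, ] + c(0.06, 0, 0)  # broken symmetry
  expect_error(phonon_frequencies(st, ff, n_sc = 2), "minimize first")
})

test_that("vibrational free energy matches closed forms", {
  K <- 2.2; m <- 14.007
  st <- einstein_crystal(K)
  spec <- phonon_frequencies(st, einstein_ff(), n_sc = 2)
  lam2om <- 1000 / (6.02214076e23 * 1.66053906660e-27 * 1e-20)
  hw <- 6.62607015e-34 / (2 * pi) * sqrt(K / m * lam2om) *
    6.02214076e23 / 1000                     # kJ/mol, independent route
  ## T = 0: only the zero-point term
  v0 <- vibrational_free_energy(spec, 0)
  expect_equal(v0$A_vib, v0$U_ZPE)
  expect_equal(v0$A_vib, 3 * hw / 2, tolerance = 1e-9)
  ## finite T closed form against the package route (3 equal modes)
  T <- 300
  a_exact <- 3 * (hw / 2 + kB_ * T * log(1 - exp(-hw / (kB_ * T))))
  expect_equal(vibrational_free_energy(spec, T)$A_vib, a_exact,
               tolerance = 1e-9)
  ## single mode constructed with hbar*omega = kB * 300 K exactly:
  ## A_vib = kB*300*(1/2 + ln(1 - 1/e)), pure arithmetic oracle
  om <- kB_ * 300 / polystab:::.const$hbar
  spec1 <- structure(list(omega = matrix(om, 1, 1),
                          lambda = matrix(1, 1, 1), Na = 1, Z = 1,
                          n_k = 1, stable = TRUE),
                     class = "phonon_spectrum")
  expect_equal(vibrational_free_energy(spec1, 300)$A_vib,
               kB_ * 300 * (0.5 + log(1 - exp(-1))),
               tolerance = 1e-12)
  ## high-temperature classical limit at hw/kBT = 0.01
  Thi <- hw / (kB_ * 0.01)
  a_cl <- 3 * kB_ * Thi * log(hw / (kB_ * Thi))
  expect_equal(vibrational_free_energy(spec, Thi)$A_vib, a_cl,
               tolerance = 1e-3 * abs(a_cl))
})

test_that("supercell-Gamma equals the commensurate k-mesh", {
  ff <- exp6_ff(cutoff = 6)
  aopt <- stats::optimize(function(a)
    lattice_energy(fcc_argon(a), ff)$U_latt, c(4.5, 6.5),
    tol = 1e-10)$minimum
  st <- fcc_argon(aopt)
  ## mesh route: 2x2x2 mesh on the unit cell
  spec_mesh <- phonon_frequencies(st, ff, n_sc = 2, grad_tol = 1e-5)
  ## literal supercell route: Gamma of the 2x2x2 supercell
  sup <- build_supercell(st, c(2, 2, 2))
  spec_sup <- phonon_frequencies(sup, ff, n_sc = 1, grad_tol = 1e-5,
                                 acoustic_tol = 1e-5)
  expect_equal(sort(as.numeric(spec_mesh$lambda)),
               sort(as.numeric(spec_sup$lambda)), tolerance = 1e-6)
})

test_that("free energy per molecule is k-mesh invariant for Einstein toys", {
  st <- einstein_crystal(2.2)
  a1 <- vibrational_free_energy(
    phonon_frequencies(st, einstein_ff(), n_sc = 1), 300)$A_vib
  a2 <- vibrational_free_energy(
    phonon_frequencies(st, einstein_ff(), n_sc = 2), 300)$A_vib
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("Helmholtz curves combine statics and vibrations", {
  ff <- einstein_ff()
  Tg <- seq(0, 400, 50)
  stA <- einstein_crystal(2.2, id = "A")
  stB <- einstein_crystal(2.2, id = "B")
  cv <- helmholtz_curves(list(stA, stB), ff, T_grid = Tg, n_sc = 1)
  ## identical structures: dA = 0 at every T
  expect_equal(cv[[1]]$A, cv[[2]]$A, tolerance = 1e-12)
  ## closed-form difference of two Einstein solids, 3 modes each
  K1 <- 2.2; K2 <- 1.1; m <- 14.007
  stC <- einstein_crystal(K2, id = "C")
  cvc <- helmholtz_curves(list(stA, stC), ff, T_grid = Tg, n_sc = 1)
  hbar_ <- 6.62607015e-34 / (2 * pi) * 6.02214076e23 / 1000
  hw1 <- polystab::omega_from_lambda(K1 / m) * hbar_
  hw2 <- polystab::omega_from_lambda(K2 / m) * hbar_
  dA_exact <- vapply(Tg, function(T) {
    f <- function(hw) hw / 2 +
      if (T > 0) kB_ * T * log(1 - exp(-hw / (kB_ * T))) else 0
    3 * (f(hw2) - f(hw1))
  }, 0)
  expect_equal(cvc[[2]]$A - cvc[[1]]$A, dA_exact, tolerance = 1e-8)
  ## A(T) non-increasing beyond the zero-point value
  expect_true(all(diff(cv[[1]]$A) < 0))
})

test_that("parameter recovery: phonon A(T) equals -kBT ln Z mode-by-mode", {
  ## quantum: direct geometric-series partition sum per mode;
  ## classical limit: Gaussian integral over the same Hamiltonian
  K <- 0.9; m <- 14.007
  st <- einstein_crystal(K)
  spec <- phonon_frequencies(st, einstein_ff(), n_sc = 1)
  T <- 250
  lam2om <- 1000 / (6.02214076e23 * 1.66053906660e-27 * 1e-20)
  hw <- 6.62607015e-34 / (2 * pi) * 6.02214076e23 / 1000 *
    sqrt(K / m * lam2om)
  ## quantum oracle: Z = sum_n exp(-hw(n + 1/2)/kBT), summed to
  ## convergence well past machine precision
  zq <- sum(exp(-hw * ((0:5000) + 0.5) / (kB_ * T)))
  a_mode <- -kB_ * T * log(zq)
  expect_equal(vibrational_free_energy(spec, T)$A_vib, 3 * a_mode,
               tolerance = 1e-8)
  ## classical check at high T: A_cl = kBT ln(hw/kBT) from the Gaussian
  ## phase-space integral
  Thi <- 5000
  a_cl <- kB_ * Thi * log(hw / (kB_ * Thi))
  expect_equal(vibrational_free_energy(spec, Thi)$A_vib, 3 * a_cl,
               tolerance = 1e-4 * abs(a_cl))
})

test_that("screening ranks, swaps across crossings, and is antisymmetric", {
  ff <- einstein_ff()
  Tg <- seq(0, 400, 20)
  ## engineered crossing: stiff cheap vs soft penalised
  K1 <- 2.2; K2 <- K1 / exp(1)
  dU <- 1.5 * kB_ * 300
  stA <- einstein_crystal(K1, id = "stiff")
  stB <- einstein_crystal(K2, a = 6.2, u0_per_mol = dU, id = "soft")
  cv <- helmholtz_curves(list(stA, stB), ff, T_grid = Tg, n_sc = 1)
  low <- screen_and_rank(cv, T_select = 100, top_k = 2)
  high <- screen_and_rank(cv, T_select = 400, top_k = 2)
  expect_equal(low$ranking$id[1], "stiff")
  expect_equal(high$ranking$id[1], "soft")
  ## single stable structure
  single <- screen_and_rank(cv[1], T_select = 300, top_k = 5)
  expect_equal(single$ranking$rank, 1)
  expect_equal(single$ranking$dA, 0)
  ## antisymmetry of relative free energies
  dA_ab <- cv[[2]]$A - cv[[1]]$A
  dA_ba <- cv[[1]]$A - cv[[2]]$A
  expect_equal(dA_ab, -dA_ba, tolerance = 1e-12)
  ## all-unstable input errors
  Kd <- stA$anchors$K; Kd[, 1] <- -1
  stU <- stA; stU$anchors$K <- Kd
  cvu <- helmholtz_curves(list(stU), ff, T_grid = Tg, n_sc = 1)
  expect_error(screen_and_rank(cvu), "unstable")
})

test_that("rigid-body relaxation reaches tight minima", {
  ff <- exp6_ff(cutoff = 7)
  ## two-atom triclinic argon crystal, perturbed off its minimum
  m <- rigid_molecule("Ar", matrix(0, 1, 3))
  st <- crystal_structure(unit_cell(5.3, 5.3, 5.3, 90, 90, 90),
                          list(m, m),
                          rbind(c(0.02, 0.01, -0.015),
                                c(0.52, 0.49, 0.52)))
  rx <- relax_structure(st, ff)
  expect_lt(rx$max_grad, 1e-5)
  expect_lt(rx$energy,
            polystab:::periodic_terms(st, ff)$u_rd)
})
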