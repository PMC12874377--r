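mk_einstein_sys <- function(K = 2.2, u0 = 0, a = 6, n = 2) {
  st <- einstein_crystal(K, a = a, n = n, u0_per_mol = u0)
  toy_system(st, einstein_ff(), anchor_K = K, anchor_u0 = u0 * n^3)
}

test_that("NVT sampling reproduces harmonic statistics", {
  K <- 2.2; T <- 300
  sys <- mk_einstein_sys(K)
  st <- sim_state(T, ensemble = "NVT")
  tr <- run_nvt(sys, st, n_sweeps = 2500, seed = 42, thin = 2,
                store_configs = TRUE)
  ## equipartition: <U> = (3N/2) kBT
  M <- sys$M
  se <- polystab:::block_se(tr$samples$U)
  expect_lt(abs(mean(tr$samples$U) - 1.5 * 3 * M / 3 * kB_ * T), 3 * se)
  ## positional variance kBT/K per axis (pooled over molecules)
  cellm <- cell_matrix(sys$structure$cell)
  disp <- do.call(rbind, lapply(tr$configs, function(cfg) {
    (cfg$cents - sys$structure$centroids) %*% cellm
  }))
  v <- mean(apply(disp, 2, stats::var))
  expect_lt(abs(v - kB_ * T / K), 4 * kB_ * T / K / sqrt(nrow(disp) / 20))
})

test_that("T -> 0 keeps the system near its minimum", {
  sys <- mk_einstein_sys(2.2)
  tr <- run_nvt(sys, sim_state(0.5, ensemble = "NVT"), n_sweeps = 800,
                seed = 1, thin = 4, store_configs = TRUE)
  cellm <- cell_matrix(sys$structure$cell)
  dmax <- max(vapply(tr$configs, function(cfg)
    max(abs((cfg$cents - sys$structure$centroids) %*% cellm)), 0))
  expect_lt(dmax, 0.3)   # ~ sqrt(kBT/K) = 0.04 A scale, generous ball
})

test_that("runs are bit-exact under a fixed seed", {
  sys <- mk_einstein_sys()
  st <- sim_state(250, ensemble = "NVT")
  t1 <- run_nvt(sys, st, n_sweeps = 400, seed = 7, thin = 2)
  t2 <- run_nvt(sys, st, n_sweeps = 400, seed = 7, thin = 2)
  expect_identical(t1$samples, t2$samples)
  stp <- sim_state(250, P = 1, ensemble = "NPT")
  n1 <- run_npt(sys, stp, n_sweeps = 300, seed = 8, thin = 2)
  n2 <- run_npt(sys, stp, n_sweeps = 300, seed = 8, thin = 2)
  expect_identical(mean(n1$samples$H), mean(n2$samples$H))
})

test_that("NPT near-ideal fluid obeys the ideal gas law", {
  m <- rigid_molecule("N", matrix(0, 1, 3))
  nl <- 16
  set.seed(5)
  st <- crystal_structure(unit_cell(40, 40, 40), rep(list(m), nl),
                          matrix(runif(3 * nl), nl, 3), id = "L")
  sys <- toy_system(st, force_field(charges = c(N = 0), cutoff_rd = 3),
                    cutoff = 3)
  attr(sys, "liquid") <- TRUE
  state <- sim_state(300, P = 10, ensemble = "NPT")
  tr <- run_npt(sys, state, n_sweeps = 5000, seed = 3, thin = 3,
                vstep = 0.05)
  ## exact expectation for the sampled measure: <V> = (M+1) kBT / P
  conv <- 101325 * 1e-30 * 6.02214076e23 / 1000
  vexact <- (nl + 1) * kB_ * 300 / (10 * conv)
  se <- polystab:::block_se(tr$samples$V)
  expect_lt(abs(mean(tr$samples$V) - vexact), 4 * se)
  ## and the ideal gas law itself within 10%
  expect_lt(abs(mean(tr$samples$V) - nl * kB_ * 300 / (10 * conv)) /
              mean(tr$samples$V), 0.12)
})

test_that("NVT at the NPT mean volume reproduces <U> (toy crystal)", {
  ff <- exp6_ff(cutoff = 4.5)
  aopt <- stats::optimize(function(a)
    lattice_energy(fcc_argon(a), ff)$U_latt, c(4.5, 6.5),
    tol = 1e-8)$minimum
  sup <- build_supercell(fcc_argon(aopt), c(2, 2, 2))
  sys <- toy_system(sup, ff, cutoff = 4.5)
  T <- 40
  trn <- run_npt(sys, sim_state(T, P = 1, ensemble = "NPT"),
                 n_sweeps = 1500, seed = 11, thin = 3, vstep = 0.01)
  vbar <- mean(trn$samples$V)
  s <- (vbar / cell_volume(sup$cell))^(1 / 3)
  sup2 <- sup
  sup2$cell <- unit_cell(sup$cell$a * s, sup$cell$b * s, sup$cell$c * s)
  sys2 <- toy_system(sup2, ff, cutoff = 4.5)
  trv <- run_nvt(sys2, sim_state(T, ensemble = "NVT"),
                 n_sweeps = 1500, seed = 12, thin = 3)
  se <- sqrt(polystab:::block_se(trn$samples$U)^2 +
               polystab:::block_se(trv$samples$U)^2)
  expect_lt(abs(mean(trn$samples$U) - mean(trv$samples$U)), 4 * se)
})

test_that("acceptance follows the Boltzmann ratio (detailed balance)", {
  ## occupancy of the right half-well of a shifted harmonic well must
  ## match the analytic Boltzmann weight
  K <- 2.2; T <- 300
  sys <- mk_einstein_sys(K, n = 1)
  tr <- run_nvt(sys, sim_state(T, ensemble = "NVT"), n_sweeps = 6000,
                seed = 9, thin = 2, store_configs = TRUE)
  cellm <- cell_matrix(sys$structure$cell)
  x <- vapply(tr$configs, function(cfg)
    ((cfg$cents - sys$structure$centroids) %*% cellm)[1, 1], 0)
  s <- sqrt(kB_ * T / K)
  p_obs <- mean(x > s)
  p_exact <- stats::pnorm(1, lower.tail = FALSE)
  se <- stats::sd(x > s) / sqrt(length(x) / 10)   # correlation margin
  expect_lt(abs(p_obs - p_exact), 4 * se)
})

test_that("reduced potentials scale as beta and cross-evaluate exactly", {
  st1 <- sim_state(300, ensemble = "NVT")
  st2 <- sim_state(600, ensemble = "NVT")
  expect_equal(reduced_potential(0, st1), 0)
  expect_equal(reduced_potential(10, st2), reduced_potential(10, st1) / 2)
  stp <- sim_state(300, P = 2, ensemble = "NPT")
  conv <- 101325 * 1e-30 * 6.02214076e23 / 1000
  expect_equal(reduced_potential(5, stp, V = 100),
               (5 + 2 * 100 * conv) / (kB_ * 300))
  expect_error(reduced_potential(5, stp), "volume")

  ## cross-evaluation matrix equals direct per-state recomputation
  sysA <- mk_einstein_sys(2.2); sysB <- mk_einstein_sys(1.1)
  sysC <- mk_einstein_sys(0.7)
  sts <- list(sim_state(260, ensemble = "NVT"),
              sim_state(300, ensemble = "NVT"),
              sim_state(340, ensemble = "NVT"))
  trajs <- list(
    run_nvt(sysA, sts[[1]], n_sweeps = 200, seed = 1, thin = 5,
            store_configs = TRUE),
    run_nvt(sysB, sts[[2]], n_sweeps = 200, seed = 2, thin = 5,
            store_configs = TRUE),
    run_nvt(sysC, sts[[3]], n_sweeps = 200, seed = 3, thin = 5,
            store_configs = TRUE))
  samp <- cross_evaluate(trajs, list(sysA, sysB, sysC), sts)
  cfgs <- c(trajs[[1]]$configs, trajs[[2]]$configs, trajs[[3]]$configs)
  for (k in 1:3) {
    sys <- list(sysA, sysB, sysC)[[k]]
    u_direct <- vapply(cfgs, function(cfg)
      polystab:::config_energy(sys, cfg)$total / (kB_ * sts[[k]]$T), 0)
    expect_equal(samp$u_kn[k, ], u_direct, tolerance = 1e-12)
  }
})

test_that("phase deltas difference enthalpies and heat capacities", {
  sysA <- mk_einstein_sys(2.2)
  Tg <- c(260, 300, 340)
  trA <- lapply(Tg, function(T)
    run_nvt(sysA, sim_state(T, ensemble = "NVT"), n_sweeps = 600,
            seed = 20 + T, thin = 3))
  ## identical trajectories: all deltas zero
  pd0 <- phase_deltas(trA, trA, Tg)
  expect_equal(pd0$dH, rep(0, 3))
  expect_equal(pd0$dCp[2], 0)
  ## two harmonic crystals with equal mode counts: dCp ~ 0 (equipartition)
  sysB <- mk_einstein_sys(1.1)
  trB <- lapply(Tg, function(T)
    run_nvt(sysB, sim_state(T, ensemble = "NVT"), n_sweeps = 600,
            seed = 50 + T, thin = 3))
  pd <- phase_deltas(trA, trB, Tg)
  expect_lt(abs(pd$dCp[2]), 4 * pd$dCp_se[2] + 1)
  ## synthetic linear <H> difference: exact slope recovery
  mk_lin <- function(h) {
    structure(list(samples = data.frame(U = h, V = 0, H = h), M = 1,
                   state = sim_state(1, ensemble = "NVT")),
              class = "trajectory")
  }
  s <- 0.013
  trL1 <- lapply(Tg, function(T) { x <- mk_lin(rep(0, 20)); x$state$T <- T; x })
  trL2 <- lapply(Tg, function(T) { x <- mk_lin(rep(s * T, 20)); x$state$T <- T; x })
  pdl <- phase_deltas(trL1, trL2, Tg)
  expect_equal(pdl$dCp[2], s * 1000, tolerance = 1e-9)
  expect_error(phase_deltas(trA, trB, c(100, 200)), "match")
})

test_that("trajectory stores round-trip through text + JSON sidecar", {
  sys <- mk_einstein_sys()
  tr <- run_nvt(sys, sim_state(280, ensemble = "NVT"), n_sweeps = 300,
                seed = 4, thin = 3)
  f <- tempfile()
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$samples$U, tr$samples$U, tolerance = 1e-12)
  expect_equal(tr2$state$T, 280)
  expect_equal(tr2$seed, 4)
})

test_that("oversized cutoffs are refused with a replication hint", {
  st <- einstein_crystal(2.2, a = 3, n = 1)
  expect_error(toy_system(st, einstein_ff(), cutoff = 5,
                          anchor_K = 2.2), "replicate")
})
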