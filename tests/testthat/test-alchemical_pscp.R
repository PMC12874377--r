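mk_sys <- function(K, u0 = 0, Kw = 0.55, a = 6, n = 2) {
  st <- einstein_crystal(K, a = a, n = n, u0_per_mol = u0)
  sys <- toy_system(st, einstein_ff(), anchor_K = K,
                    anchor_u0 = u0 * n^3)
  sys$anchor_K2 <- matrix(Kw, nrow(sys$anchors$K), 3)
  sys
}

test_that("schedules carry the protocol state counts", {
  s1 <- build_schedule("S->DWF")
  expect_length(s1$lambda, 48)           # 40 uniform + 8 concentrated
  expect_equal(s1$lambda[1], 0)
  expect_equal(s1$lambda[length(s1$lambda)], 1)
  expect_true(all(diff(s1$lambda) > 0))
  expect_gte(sum(s1$lambda > 0.8 & s1$lambda < 0.9), 8)
  s2 <- build_schedule("WF->L")
  expect_length(s2$lambda, 20)
  expect_equal(range(s2$lambda), c(0, 1))
  s3 <- build_schedule("DWF->WF", list(V_solid = 100, V_liquid = 130))
  expect_length(s3$volumes, 20)
  expect_true(all(diff(s3$volumes) > 0))
  expect_error(build_schedule("DWF->WF"), "V_solid")
  expect_error(build_schedule("DWF->WF",
                              list(V_solid = 100, V_liquid = 100)),
               "monotone")
})

test_that("scaled potentials recover the physical endpoints exactly", {
  sys <- mk_sys(2.2)
  cfg <- polystab:::init_config(sys)
  cfg$cents <- cfg$cents + matrix(rnorm(nrow(cfg$cents) * 3, 0, 0.02),
                                  ncol = 3)
  e0 <- polystab:::config_energy(sys, cfg)$total
  eS <- polystab:::config_energy(scaled_potential(sys, 0, "S->DWF"),
                                 cfg)$total
  expect_equal(eS, e0, tolerance = 1e-12)
  eL <- polystab:::config_energy(scaled_potential(sys, 1, "WF->L"),
                                 cfg)$total
  expect_equal(eL, e0, tolerance = 1e-12)
  ## DWF endpoint: springs at the weak value, static offset off
  sysw <- scaled_potential(sys, 1, "S->DWF")
  expect_equal(sysw$scale$anchor_mix, 1)
  cfg0 <- polystab:::init_config(sys)
  expect_equal(polystab:::config_energy(sysw, cfg0)$total, 0,
               tolerance = 1e-12)   # at the sites, weak wells, no u0
  expect_error(scaled_potential(sys, 1.2, "S->DWF"), "lambda")
})

test_that("a PSCP stage recovers the analytic Einstein spring morph", {
  Tref <- 350; K <- 2.2; Kw <- 0.55
  sys <- mk_sys(K, Kw = Kw)
  sch <- build_schedule("S->DWF", list(n_lambda = 10, n_extra = 2))
  stg <- pscp_stage(sys, sch, Tref, n_sweeps = 1200, thin = 10,
                    seed = 3)
  exact <- 3 * (harm_f1d(Kw, Tref) - harm_f1d(K, Tref))
  expect_lt(abs(stg$dA - exact), 3 * stg$se + 0.02)
  ## round trip S -> DWF -> S on the same samples closes to zero
  fit <- stg$fit
  K_ <- length(fit$f)
  expect_lt(abs(delta_f(fit, 1, K_)$df + delta_f(fit, K_, 1)$df),
            1e-12)
})

test_that("the volume stage of an anchored toy is free-energy neutral", {
  Kw <- 0.55; Tref <- 350
  st <- einstein_crystal(Kw)
  sys <- toy_system(st, einstein_ff(), anchor_K = Kw)
  Vs <- cell_volume(st$cell)
  sch <- build_schedule("DWF->WF", list(n_vol = 6, V_solid = Vs,
                                        V_liquid = 1.4 * Vs))
  stg <- pscp_stage(sys, sch, Tref, n_sweeps = 800, thin = 8, seed = 5)
  expect_lt(abs(stg$dA), 3 * stg$se + 0.02)
})

test_that("stage combination follows the melt and solid-solid rules", {
  mk <- function(dA, se) list(dA = dA, se = se)
  melt <- pscp_combine(list(s_dwf = mk(1, 0.1), dwf_wf = mk(2, 0.2),
                            wf_l = mk(3, 0.2)), "melt", T_ref = 350)
  expect_equal(melt$dA, 6)
  expect_equal(melt$se, sqrt(0.01 + 0.04 + 0.04))
  ## same polymorph twice: exactly zero
  ss0 <- pscp_combine(list(s1_dwf = mk(1.3, 0.1), dwf1_wf = mk(0.4, 0.1),
                           sj_dwf = mk(1.3, 0.1), dwfj_wf = mk(0.4, 0.1)),
                      "solid_solid")
  expect_equal(ss0$dA, 0)
  expect_error(pscp_combine(list(s_dwf = mk(1, 0.1)), "melt"),
               "missing PSCP stage")
})

test_that("PV corrections are tiny at ambient pressure", {
  expect_equal(pv_correct(5, 0, 100), 5)
  expect_equal(pv_correct(0, 1, 10), 0.00101325, tolerance = 1e-6)
  expect_lt(abs(pv_correct(0, 1, 100)), 0.011)
  expect_lt(pv_correct(1, 1, -10), 1)
})

test_that("temperature extrapolation obeys its fixed point and closed form", {
  ## fixed point at T_ref and identical phases
  dft0 <- data.frame(T = c(300, 350, 400), df = c(0, 0, 0))
  g0 <- gibbs_vs_temperature(0, dft0, 350)
  expect_equal(g0$dG, c(0, 0, 0))
  dft <- data.frame(T = c(300, 350, 400), df = c(0.3, 0.1, -0.05),
                    se = c(0.01, 0.01, 0.01))
  g <- gibbs_vs_temperature(1.2, dft, 350, dG_ref_se = 0.05)
  expect_equal(g$dG[2], 1.2)
  expect_equal(g$dG[1],
               kB_ * 300 * (0.3 - 0.1) + 300 / 350 * 1.2,
               tolerance = 1e-12)
  expect_error(gibbs_vs_temperature(1.2, dft, 333), "grid")

  ## classical Einstein pair: exact df(T) gives the exact dA(T) curve
  K1 <- 2.2; K2 <- 1.1; Tg <- seq(250, 450, 50); Tref <- 350
  dA_T <- function(T) 3 * (harm_f1d(K2, T) - harm_f1d(K1, T))
  df_T <- vapply(Tg, function(T) dA_T(T) / (kB_ * T), 0)
  g2 <- gibbs_vs_temperature(dA_T(Tref),
                             data.frame(T = Tg, df = df_T), Tref)
  expect_equal(g2$dG, vapply(Tg, dA_T, 0), tolerance = 1e-10)
})

test_that("uncertainty propagation reproduces the quadrature identity", {
  expect_equal(propagate_uncertainty(0, 0, 0, 300, 350), 0)
  ## (3, 4, 0) -> 5 in reduced units
  expect_equal(propagate_uncertainty(3, 4, 0, 300, 350),
               kB_ * 300 * 5, tolerance = 1e-12)
  ## single term passes through
  expect_equal(propagate_uncertainty(2, 0, 0, 100, 350), kB_ * 100 * 2)
  expect_equal(propagate_uncertainty(0, 0, 1.5, 350, 350), 1.5,
               tolerance = 1e-12)
  expect_error(propagate_uncertainty(-1, 0, 0, 300, 350), ">= 0")
})

test_that("transition finding handles roots, bands and absences", {
  Tg <- seq(300, 500, 10)
  a <- -0.02
  curve <- data.frame(T = Tg, dG = a * (Tg - 400), se = 0.1,
                      lo = a * (Tg - 400) - 0.196,
                      hi = a * (Tg - 400) + 0.196)
  tr <- find_transition(curve)
  expect_true(tr$found)
  expect_equal(tr$T_star, 400, tolerance = 1e-9)
  ## constant band half-width delta, slope a: dT* = delta / |a|
  expect_equal(tr$dT_star, 0.196 / abs(a), tolerance = 1e-9)
  ## strictly positive curve: none found, no error
  up <- data.frame(T = Tg, dG = 1 + 0 * Tg, se = 0.1, lo = 0.8,
                   hi = 1.2)
  expect_false(find_transition(up)$found)
  ## multiple roots carry a warning
  wig <- data.frame(T = c(100, 200, 300, 400), dG = c(-1, 1, -1, 1),
                    se = 0.1, lo = c(-1.2, 0.8, -1.2, 0.8),
                    hi = c(-0.8, 1.2, -0.8, 1.2))
  trw <- find_transition(wig)
  expect_true(trw$found)
  expect_length(trw$roots, 3)
  expect_match(trw$warning, "multiple")
})

test_that("decomposition components sum to the total and null out", {
  mk <- function(dA, se = 0.01) list(dA = dA, se = se)
  ## identical polymorphs: all components zero
  s <- list(elec = mk(1.2), vdw = mk(-0.7), vol = mk(0.3))
  d0 <- decompose_free_energy(s, s)
  expect_equal(d0$dA_total, 0)
  expect_equal(d0$dA_vdw, 0)
  expect_equal(d0$dA_elec, 0)
  expect_equal(d0$dA_vol, 0)
  ## generic case closes by construction
  s1 <- list(elec = mk(2.0), vdw = mk(-3.0), vol = mk(0.5))
  sj <- list(elec = mk(1.0), vdw = mk(1.0), vol = mk(0.1))
  d <- decompose_free_energy(s1, sj)
  expect_equal(d$dA_total, d$dA_vdw + d$dA_elec + d$dA_vol,
               tolerance = 1e-12)
  expect_error(decompose_free_energy(list(elec = mk(1)), sj),
               "bookkeeping")
  ## closure check against an inconsistent externally supplied total
  expect_error(decompose_free_energy(s1, sj, total = 99), "close")
})

test_that("zero-charge toys have a null electrostatic component", {
  ## the Einstein fixture carries no charges: an electrostatics-only
  ## scaling stage must measure zero free-energy change
  Tref <- 350
  sys <- mk_sys(2.2)
  sys_e <- sys
  sys_e$scale$elec <- 0       # electrostatics fully off
  cfg <- polystab:::init_config(sys)
  expect_equal(polystab:::config_energy(sys_e, cfg)$elec, 0)
  expect_equal(polystab:::config_energy(sys, cfg)$elec, 0)
})

test_that("Eq-8-style extrapolation matches a direct PSCP at another T", {
  ## classical Einstein pair: run the spring morph at T_ref and at T2,
  ## and compare the direct T2 result with the extrapolated curve
  K1 <- 2.2; K2m <- 1.1; Kw <- 0.55
  Tref <- 350; T2 <- 250
  sch <- build_schedule("S->DWF", list(n_lambda = 8, n_extra = 2))
  sysA <- mk_sys(K1, Kw = Kw)
  sysB <- mk_sys(K2m, Kw = Kw)
  run_pair <- function(T, seed) {
    sA <- pscp_stage(sysA, sch, T, n_sweeps = 900, thin = 8,
                     seed = seed)
    sB <- pscp_stage(sysB, sch, T, n_sweeps = 900, thin = 8,
                     seed = seed + 500)
    list(dA = sA$dA - sB$dA, se = sqrt(sA$se^2 + sB$se^2))
  }
  ref <- run_pair(Tref, 11)
  direct <- run_pair(T2, 77)
  ## analytic reduced free-energy difference table
  Tg <- c(250, 300, 350)
  dfT <- vapply(Tg, function(T)
    3 * (harm_f1d(K2m, T) - harm_f1d(K1, T)) / (kB_ * T), 0)
  curve <- gibbs_vs_temperature(ref$dA, data.frame(T = Tg, df = dfT),
                                Tref, dG_ref_se = ref$se)
  expect_lt(abs(curve$dG[1] - direct$dA),
            3 * sqrt(curve$se[1]^2 + direct$se^2) + 0.03)
})
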