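#' Generate a toy polymorph set with engineered ground truth
#'
#' Builds a deterministic fixture emulating the statistical structure
#' the screening workflow assumes: at least two mechanically stable
#' packings of the same rigid molecule whose free-energy curves cross
#' at an engineered temperature, one dynamically unstable decoy, and a
#' liquid box. Three presets:
#'
#' * `"einstein"` -- single-atom molecules on cubic lattices held by
#'   independent harmonic anchors. Free energies, phonon spectra, the
#'   stability crossing and the melting point are all known in closed
#'   form. The stiff polymorph (`alpha`) wins at low temperature; the
#'   soft one (`beta`) carries a static-energy penalty chosen so the
#'   classical Helmholtz curves cross at `T_cross` (300 K by default).
#'   The decoy has a negative anchor curvature along z (a saddle).
#' * `"rigid-dimer"` -- the same construction with two-atom rigid
#'   dimers (both atoms anchored), exercising rotational sampling.
#' * `"buckingham-lattice"` -- argon-like exp-6 atoms: fcc and hcp
#'   packings (both mechanically stable, nearly degenerate) plus a
#'   simple-cubic decoy, which is genuinely shear-unstable for pair
#'   potentials; no engineered crossing is claimed for this preset.
#'
#' With a fixed seed the emitted file set is byte-identical across
#' runs.
#'
#' @param seed RNG seed (controls the liquid-box coordinates).
#' @param preset `"einstein"`, `"rigid-dimer"` or
#'   `"buckingham-lattice"`.
#' @param dir optional directory; when given, CIF files, the
#'   force-field file and a `ground_truth.json` sidecar are written
#'   there.
#' @param T_cross engineered classical crossing temperature (K) for the
#'   anchored presets.
#' @param n_liquid molecules in the liquid box (default 64).
#' @return An object of class `toy_polymorph_set`: named `structures`
#'   (with anchors attached where applicable), `liquid`, `ff`,
#'   `ground_truth`, `preset`, `seed`, `molecule_size`.
#' @export
generate_toy_polymorph_set <- function(seed = 1,
                                       preset = c("einstein",
                                                  "rigid-dimer",
                                                  "buckingham-lattice"),
                                       dir = NULL, T_cross = 300,
                                       n_liquid = 64) {
  preset <- match.arg(preset)
  set.seed(seed)
  kB <- .const$kB
  out <- switch(preset,
    "einstein" = , "rigid-dimer" = {
      dimer <- preset == "rigid-dimer"
      nat <- if (dimer) 2L else 1L
      geom <- if (dimer) rbind(c(-0.55, 0, 0), c(0.55, 0, 0)) else
        matrix(0, 1, 3)
      mol <- rigid_molecule(rep("N", nat), geom)
      nc <- 2L                            # 2x2x2 molecules per cell
      cents <- as.matrix(expand.grid(x = (0:(nc - 1)) / nc,
                                     y = (0:(nc - 1)) / nc,
                                     z = (0:(nc - 1)) / nc))
      z <- nrow(cents)
      K1 <- 2.2; K2 <- K1 / exp(1); Kw <- 0.55; Kl <- 0.4
      ## classical crossing: dU = (3*nat/2) kB T_cross ln(K1/K2) per mol
      dU <- (3 * nat / 2) * kB * T_cross * log(K1 / K2)
      mk <- function(a, K, u0, id) {
        st <- crystal_structure(unit_cell(a * nc, a * nc, a * nc),
                                rep(list(mol), z), cents, id = id)
        with_anchors(st, K, u0 = u0 * z)
      }
      alpha <- mk(6.0, K1, 0, "alpha")
      beta <- mk(6.2, K2, dU, "beta")
      decoy <- crystal_structure(unit_cell(6.0 * nc, 6.0 * nc, 6.0 * nc),
                                 rep(list(mol), z), cents, id = "decoy")
      Kd <- matrix(K1, z * nat, 3); Kd[, 3] <- -0.8
      decoy <- with_anchors(decoy, Kd, u0 = 0)
      ## liquid: random molecules, weak anchors, melting point of the
      ## stiff polymorph engineered at T_cross + 80 K
      Tm <- T_cross + 80
      u0L <- (3 * nat / 2) * kB * Tm * log(K1 / Kl)
      aL <- 6.0 * (n_liquid)^(1 / 3) * 1.12
      liq <- crystal_structure(unit_cell(aL, aL, aL),
                               rep(list(mol), n_liquid),
                               matrix(stats::runif(3 * n_liquid),
                                      n_liquid, 3),
                               id = "liquid")
      liq <- with_anchors(liq, Kl, u0 = u0L * n_liquid)
      ff <- force_field(charges = c(N = 0), cutoff_rd = 5)
      gt <- list(
        preset = preset, seed = seed, molecule_size = nat,
        K = list(alpha = K1, beta = K2, decoy_z = -0.8, weak = Kw,
                 liquid = Kl),
        u0_per_molecule = list(alpha = 0, beta = dU, liquid = u0L),
        T_cross_classical = T_cross,
        T_melt_alpha_classical = Tm,
        stability = list(alpha = TRUE, beta = TRUE, decoy = FALSE),
        order_low_T = c("alpha", "beta"),
        order_high_T = c("beta", "alpha"))
      list(structures = list(alpha = alpha, beta = beta, decoy = decoy),
           liquid = liq, ff = ff, ground_truth = gt,
           molecule_size = nat)
    },
    "buckingham-lattice" = {
      eps <- 1.0; rm <- 3.8; al <- 13
      A <- eps * 6 / (al - 6) * exp(al)
      B <- al / rm
      C <- eps * al / (al - 6) * rm^6
      ff <- force_field(pairs = data.frame(t1 = "Ar", t2 = "Ar",
                                           A = A, B = B, C = C),
                        charges = c(Ar = 0), cutoff_rd = 9)
      mAr <- rigid_molecule("Ar", matrix(0, 1, 3))
      opt_a <- function(build) {
        stats::optimize(function(a) lattice_energy(build(a), ff)$U_latt,
                        c(3.0, 7.0), tol = 1e-9)$minimum
      }
      mk_fcc <- function(a) crystal_structure(
        unit_cell(a, a, a), rep(list(mAr), 4),
        rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5)),
        id = "fcc")
      mk_hcp <- function(a) crystal_structure(
        unit_cell(a, a, a * sqrt(8 / 3), 90, 90, 120),
        rep(list(mAr), 2),
        rbind(c(0, 0, 0), c(1 / 3, 2 / 3, 1 / 2)), id = "hcp")
      mk_sc <- function(a) crystal_structure(
        unit_cell(a, a, a), list(mAr), rbind(c(0, 0, 0)), id = "sc")
      fcc <- mk_fcc(opt_a(mk_fcc))
      hcp <- mk_hcp(opt_a(mk_hcp))
      sc <- mk_sc(opt_a(mk_sc))
      vmol <- cell_volume(fcc$cell) / 4
      aL <- (n_liquid * vmol / 0.85)^(1 / 3)
      liq <- crystal_structure(unit_cell(aL, aL, aL),
                               rep(list(mAr), n_liquid),
                               matrix(stats::runif(3 * n_liquid),
                                      n_liquid, 3),
                               id = "liquid")
      gt <- list(preset = preset, seed = seed, molecule_size = 1L,
                 exp6 = list(epsilon = eps, r_m = rm, alpha = al),
                 stability = list(fcc = TRUE, hcp = TRUE, sc = FALSE),
                 T_cross_classical = NA)
      list(structures = list(fcc = fcc, hcp = hcp, sc = sc),
           liquid = liq, ff = ff, ground_truth = gt,
           molecule_size = 1L)
    })
  out$preset <- preset
  out$seed <- seed
  class(out) <- "toy_polymorph_set"
  if (!is.null(dir)) write_toy_polymorph_set(out, dir)
  out
}

#' @export
print.toy_polymorph_set <- function(x, ...) {
  cat(sprintf("<toy_polymorph_set %s> structures: %s; liquid box of %d molecules\n",
              x$preset, paste(names(x$structures), collapse = ", "),
              x$liquid$Z))
  invisible(x)
}

#' Write a toy polymorph set to disk
#'
#' One CIF per structure (plus the liquid box), the shared force-field
#' file, and `ground_truth.json` holding the engineered constants and
#' anchor definitions.
#'
#' @param set a [generate_toy_polymorph_set()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_polymorph_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  anch <- list()
  for (nm in names(set$structures)) {
    s <- set$structures[[nm]]
    write_cif(s, file.path(dir, paste0(nm, ".cif")))
    if (!is.null(s$anchors)) {
      anch[[nm]] <- list(K = s$anchors$K, u0 = s$anchors$u0)
    }
  }
  write_cif(set$liquid, file.path(dir, "liquid.cif"))
  if (!is.null(set$liquid$anchors)) {
    anch$liquid <- list(K = set$liquid$anchors$K,
                        u0 = set$liquid$anchors$u0)
  }
  write_forcefield(set$ff, file.path(dir, "forcefield.txt"))
  meta <- list(ground_truth = set$ground_truth, preset = set$preset,
               seed = set$seed, molecule_size = set$molecule_size,
               anchors = anch,
               structures = names(set$structures))
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a toy polymorph set from disk
#'
#' @param dir directory written by [write_toy_polymorph_set()].
#' @return a `toy_polymorph_set`.
#' @export
load_toy_polymorph_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
  ff <- read_forcefield(file.path(dir, "forcefield.txt"))
  ms <- meta$molecule_size
  structures <- list()
  for (nm in meta$structures) {
    s <- read_cif(file.path(dir, paste0(nm, ".cif")),
                  molecule_size = ms, id = nm)
    if (!is.null(meta$anchors[[nm]])) {
      s <- with_anchors(s, as.matrix(meta$anchors[[nm]]$K),
                        u0 = meta$anchors[[nm]]$u0)
    }
    structures[[nm]] <- s
  }
  liquid <- read_cif(file.path(dir, "liquid.cif"), molecule_size = ms,
                     id = "liquid")
  if (!is.null(meta$anchors$liquid)) {
    liquid <- with_anchors(liquid, as.matrix(meta$anchors$liquid$K),
                           u0 = meta$anchors$liquid$u0)
  }
  structure(list(structures = structures, liquid = liquid, ff = ff,
                 ground_truth = meta$ground_truth, preset = meta$preset,
                 seed = meta$seed, molecule_size = ms),
            class = "toy_polymorph_set")
}

## closed-form classical Helmholtz free energy per molecule of an
## anchored (Einstein) structure: u0 + sum over modes (kBT/2) ln(K / 2 pi kBT)
einstein_free_energy <- function(K_per_mode, T, u0 = 0) {
  kBT <- .const$kB * T
  u0 + sum(kBT / 2 * log(K_per_mode / (2 * pi * kBT)))
}
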