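## shared fixture builders and independent oracles

kB_ <- 0.008314462618
KE_ <- 1.602176634e-19^2 * 6.02214076e23 /
  (4 * pi * 8.8541878128e-12 * 1e-10) / 1000   # Coulomb kJ A / mol e^2

## small distorted two-dimer triclinic toy, optionally charged
toy_dimer_crystal <- function(q = 0.3) {
  m1 <- rigid_molecule(c("C", "N"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
                       charge = c(q, -q))
  m2 <- rigid_molecule(c("C", "N"), rbind(c(0, 0, 0), c(0, 1.2, 0)),
                       charge = c(q, -q))
  crystal_structure(unit_cell(6, 7, 8, 85, 95, 100), list(m1, m2),
                    rbind(c(0.1, 0.2, 0.3), c(0.6, 0.7, 0.4)))
}

toy_dimer_ff <- function(q = 0.3, cutoff = 12) {
  force_field(pairs = data.frame(t1 = c("C", "C", "N"),
                                 t2 = c("C", "N", "N"),
                                 A = c(30000, 25000, 20000),
                                 B = c(3.0, 3.2, 3.4),
                                 C = c(1200, 1000, 800)),
              charges = c(C = q, N = -q), cutoff_rd = cutoff)
}

## rock-salt toy (8 ions per cubic cell)
rocksalt <- function(a = 5.64) {
  na <- rigid_molecule("Na", matrix(0, 1, 3), charge = 1, mass = 22.99)
  cl <- rigid_molecule("Cl", matrix(0, 1, 3), charge = -1, mass = 35.45)
  cents <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5),
                 c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))
  crystal_structure(unit_cell(a, a, a),
                    c(rep(list(na), 4), rep(list(cl), 4)), cents)
}

## argon-like exp-6 force field and fcc builder
exp6_ff <- function(eps = 1.0, rm = 3.8, alpha = 13, cutoff = 9) {
  force_field(pairs = data.frame(
    t1 = "Ar", t2 = "Ar",
    A = eps * 6 / (alpha - 6) * exp(alpha),
    B = alpha / rm,
    C = eps * alpha / (alpha - 6) * rm^6),
    charges = c(Ar = 0), cutoff_rd = cutoff)
}

fcc_argon <- function(a) {
  mAr <- rigid_molecule("Ar", matrix(0, 1, 3))
  crystal_structure(unit_cell(a, a, a), rep(list(mAr), 4),
                    rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5),
                          c(0, .5, .5)), id = "fcc")
}

## anchored Einstein crystal of n^3 single atoms
einstein_crystal <- function(K, a = 6, n = 2, u0_per_mol = 0,
                             id = "E") {
  m <- rigid_molecule("N", matrix(0, 1, 3))
  cents <- as.matrix(expand.grid(x = (0:(n - 1)) / n,
                                 y = (0:(n - 1)) / n,
                                 z = (0:(n - 1)) / n))
  st <- crystal_structure(unit_cell(a * n, a * n, a * n),
                          rep(list(m), n^3), cents, id = id)
  with_anchors(st, K, u0 = u0_per_mol * n^3)
}

einstein_ff <- function() force_field(charges = c(N = 0), cutoff_rd = 5)

## classical configurational free energy per 1D harmonic mode
harm_f1d <- function(K, T) kB_ * T / 2 * log(K / (2 * pi * kB_ * T))

## independent BAR oracle: Bennett self-consistent Fermi equation
bar_oracle <- function(w_F, w_R) {
  M <- log(length(w_F) / length(w_R))
  g <- function(df) {
    sum(1 / (1 + exp(M + w_F - df))) -
      sum(1 / (1 + exp(-M + w_R + df)))
  }
  stats::uniroot(g, c(-500, 500), tol = 1e-14)$root
}

## direct-lattice-sum Coulomb oracle with Evjen (fractional boundary
## charge) neutralised expanding cubes; returns kJ/mol per cell
direct_coulomb_oracle <- function(structure, nmax = 8) {
  at <- polystab:::atom_table(structure)
  cm <- cell_matrix(structure$cell)
  e <- 0
  rng <- -nmax:nmax
  for (n1 in rng) for (n2 in rng) for (n3 in rng) {
    w <- prod(ifelse(abs(c(n1, n2, n3)) == nmax, 0.5, 1))
    tv <- c(n1, n2, n3) %*% cm
    for (i in seq_len(at$n)) for (j in seq_len(at$n)) {
      if (n1 == 0 && n2 == 0 && n3 == 0 && i == j) next
      if (n1 == 0 && n2 == 0 && n3 == 0 && at$mol[i] == at$mol[j]) next
      r <- sqrt(sum((at$xyz[j, ] + tv - at$xyz[i, ])^2))
      e <- e + w * at$charge[i] * at$charge[j] / r
    }
  }
  KE_ * e / 2
}

## brute-force periodic pair-sum oracle (Buckingham, all images within
## an explicit cutoff, no Ewald) -- independent of the package's
## masked/vectorised evaluator
brute_pair_sum <- function(structure, ff, cutoff) {
  at <- polystab:::atom_table(structure)
  cm <- cell_matrix(structure$cell)
  nmax <- ceiling(cutoff / min(structure$cell$a, structure$cell$b,
                               structure$cell$c)) + 1
  e <- 0
  rng <- -nmax:nmax
  for (n1 in rng) for (n2 in rng) for (n3 in rng) {
    t0 <- n1 == 0 && n2 == 0 && n3 == 0
    tv <- c(n1, n2, n3) %*% cm
    for (i in seq_len(at$n)) for (j in seq_len(at$n)) {
      if (t0 && at$mol[i] == at$mol[j]) next
      r <- sqrt(sum((at$xyz[j, ] + tv - at$xyz[i, ])^2))
      if (r > cutoff || r < 1e-9) next
      p <- polystab:::pair_params(ff, at$type[i], at$type[j])
      e <- e + p["A"] * exp(-r * p["B"]) - p["C"] / r^6
    }
  }
  unname(e / 2)
}

## random valid triclinic cell
random_cell <- function() {
  repeat {
    a <- runif(3, 3, 15)
    ang <- runif(3, 60, 120)
    ca <- cos(ang * pi / 180)
    disc <- 1 - sum(ca^2) + 2 * prod(ca)
    if (disc > 1e-3) {
      return(unit_cell(a[1], a[2], a[3], ang[1], ang[2], ang[3]))
    }
  }
}
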