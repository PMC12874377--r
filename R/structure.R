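#' Rigid molecules
#'
#' A rigid molecule stores its atoms (element, mass, partial charge and a
#' pair-type label used to index the force-field table) together with an
#' immutable reference internal geometry: Cartesian offsets of each atom
#' from the molecular centroid. The rigid-body model fixes the
#' intramolecular energy change at zero, so only the reference geometry is
#' ever used.
#'
#' @param element character vector of element symbols.
#' @param geometry n x 3 matrix of Cartesian positions (Angstrom); the
#'   centroid is subtracted to form the reference geometry.
#' @param charge numeric vector of partial charges (e); default 0.
#' @param type character vector of pair-type labels; defaults to the
#'   element symbols.
#' @param mass numeric vector of atomic masses (g/mol); defaults to
#'   standard atomic masses looked up from `element`.
#' @return An object of class `rigid_molecule`.
#' @export
rigid_molecule <- function(element, geometry, charge = 0, type = element,
                           mass = NULL) {
  geometry <- matrix(as.numeric(geometry), ncol = 3)
  n <- nrow(geometry)
  if (n < 1) stop("a rigid molecule needs at least one atom")
  if (length(element) != n) stop("element/geometry length mismatch")
  charge <- rep_len(charge, n)
  type <- rep_len(type, n)
  if (any(!nzchar(type))) stop("pair-type labels must be non-empty")
  if (is.null(mass)) mass <- element_mass(element)
  mass <- rep_len(mass, n)
  if (any(mass <= 0)) stop("atomic masses must be > 0")
  ref <- sweep(geometry, 2, colMeans(geometry))
  structure(list(element = element, mass = mass, charge = charge,
                 type = type, ref_geom = ref),
            class = "rigid_molecule")
}

n_atoms <- function(mol) nrow(mol$ref_geom)

molecule_formula <- function(mol) {
  tab <- table(mol$element)
  paste0(names(tab), as.integer(tab), collapse = "")
}

#' Crystal structures
#'
#' A crystal structure is a unit cell plus a list of placed rigid
#' molecules. Each placement gives the molecule's centroid in fractional
#' coordinates and a 3x3 rotation applied to the reference geometry.
#' Molecules are kept whole: the centroid is wrapped into `[0,1)^3` and
#' atoms follow it, so clustering and rigid-body energetics always see
#' intact molecules.
#'
#' @param cell a [unit_cell()].
#' @param molecules list of `rigid_molecule` objects (one per molecule in
#'   the cell; `Z` is their count).
#' @param centroids Z x 3 matrix of fractional centroid positions.
#' @param rotations list of Z rotation matrices (3x3); default identity.
#' @param id optional identifier label (e.g. `"ID-1"`).
#' @param zprime optional Z' bookkeeping value (metadata only, never used
#'   in computation).
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell, molecules, centroids, rotations = NULL,
                              id = NULL, zprime = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!is.list(molecules) || !all(vapply(molecules, inherits, TRUE,
                                         "rigid_molecule"))) {
    stop("molecules must be a list of rigid_molecule objects")
  }
  z <- length(molecules)
  if (z < 1) stop("need at least one molecule")
  centroids <- matrix(as.numeric(centroids), ncol = 3)
  if (nrow(centroids) != z) stop("Z mismatch: centroids vs molecules")
  if (!all(is.finite(centroids))) stop("non-finite fractional coordinates")
  if (is.null(rotations)) rotations <- rep(list(diag(3)), z)
  if (length(rotations) != z) stop("Z mismatch: rotations vs molecules")
  qtot <- sum(vapply(molecules, function(m) sum(m$charge), 0))
  if (abs(qtot) > 1e-8) {
    stop(sprintf("unit cell is not charge neutral (net %.3g e)", qtot))
  }
  centroids <- centroids - floor(centroids)   # keep molecules whole
  structure(list(cell = cell, molecules = molecules,
                 centroids = centroids, rotations = rotations,
                 Z = z, id = id, zprime = zprime),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure%s> Z=%d, %d atoms/cell\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$Z, sum(vapply(x$molecules, n_atoms, 0L))))
  print(x$cell)
  invisible(x)
}

## Cartesian atom coordinates of every atom in the cell, plus per-atom
## metadata; the workhorse layout for the energy model.
atom_table <- function(structure) {
  cellm <- cell_matrix(structure$cell)
  coords <- list(); elem <- list(); chg <- list(); typ <- list()
  mass <- list(); molid <- list()
  for (i in seq_len(structure$Z)) {
    mol <- structure$molecules[[i]]
    cen <- structure$centroids[i, , drop = FALSE] %*% cellm
    xyz <- mol$ref_geom %*% t(structure$rotations[[i]])
    xyz <- sweep(xyz, 2, as.numeric(cen), `+`)
    coords[[i]] <- xyz
    elem[[i]] <- mol$element; chg[[i]] <- mol$charge
    typ[[i]] <- mol$type; mass[[i]] <- mol$mass
    molid[[i]] <- rep(i, n_atoms(mol))
  }
  list(xyz = do.call(rbind, coords),
       element = unlist(elem), charge = unlist(chg),
       type = unlist(typ), mass = unlist(mass),
       mol = unlist(molid), n = length(unlist(molid)))
}

#' Crystal density
#'
#' `density = Z * M / (N_A * V)` with the cell volume from
#' [cell_volume()].
#'
#' @param structure a [crystal_structure()], or a [unit_cell()] combined
#'   with an explicit `Z`.
#' @param molar_mass molar mass of one molecule (g/mol).
#' @param Z molecules per cell; taken from `structure` when omitted.
#' @return Density in g/cm^3.
#' @examples
#' cb <- unit_cell(9.736, 9.736, 9.736)
#' compute_density(cb, molar_mass = 128.09, Z = 6)  # 1.383
#' @export
compute_density <- function(structure, molar_mass, Z = NULL) {
  if (inherits(structure, "crystal_structure")) {
    cell <- structure$cell
    if (is.null(Z)) Z <- structure$Z
  } else if (inherits(structure, "unit_cell")) {
    cell <- structure
    if (is.null(Z)) stop("Z must be given with a bare unit cell")
  } else stop("structure must be a crystal_structure or unit_cell")
  if (!is.numeric(molar_mass) || molar_mass <= 0) {
    stop("molar_mass must be > 0")
  }
  if (Z < 1 || Z != round(Z)) stop("Z must be a positive integer")
  v_cm3 <- cell_volume(cell) * 1e-24
  Z * molar_mass / (.const$N_A * v_cm3)
}

#' Build a supercell
#'
#' Replicates the unit cell `na x nb x nc` times. Lattice vectors are
#' scaled componentwise, molecule placements are translated into every
#' copy, and the density is unchanged to machine precision.
#'
#' @param structure a [crystal_structure()].
#' @param replication integer 3-vector `(na, nb, nc)`, each `>= 1`.
#' @return A new `crystal_structure` with `Z * na * nb * nc` molecules.
#' @export
build_supercell <- function(structure, replication) {
  stopifnot(inherits(structure, "crystal_structure"))
  r <- as.numeric(replication)
  if (length(r) != 3 || any(r < 1) || any(r != round(r))) {
    stop("replication must be three integers >= 1")
  }
  r <- as.integer(r)
  cell <- structure$cell
  newcell <- unit_cell(cell$a * r[1], cell$b * r[2], cell$c * r[3],
                       cell$alpha, cell$beta, cell$gamma)
  shifts <- as.matrix(expand.grid(sa = seq_len(r[1]) - 1L,
                                  sb = seq_len(r[2]) - 1L,
                                  sc = seq_len(r[3]) - 1L))
  mols <- list(); cents <- list(); rots <- list()
  k <- 0L
  for (s in seq_len(nrow(shifts))) {
    for (i in seq_len(structure$Z)) {
      k <- k + 1L
      mols[[k]] <- structure$molecules[[i]]
      cents[[k]] <- (structure$centroids[i, ] + shifts[s, ]) / r
      rots[[k]] <- structure$rotations[[i]]
    }
  }
  crystal_structure(newcell, mols, do.call(rbind, cents), rots,
                    id = structure$id, zprime = structure$zprime)
}

#' Automatic supercell sizing for lattice dynamics
#'
#' The supercell replication factor is the smallest integer strictly
#' exceeding the ratio of the interaction cutoff to the shortest unit-cell
#' length; low-frequency external modes need a periodic environment at
#' least as large as the interaction range. A zero cutoff gives the
#' Gamma-only limit `n_sc = 1`.
#'
#' @param cell a [unit_cell()].
#' @param cutoff interaction cutoff distance (Angstrom), `>= 0`.
#' @return Integer replication factor `n_sc >= 1`.
#' @examples
#' auto_supercell_size(unit_cell(13.905, 13.905, 8.515, 90, 90, 120), 30)  # 4
#' @export
auto_supercell_size <- function(cell, cutoff) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!is.numeric(cutoff) || cutoff < 0) stop("cutoff must be >= 0")
  ratio <- cutoff / min(cell$a, cell$b, cell$c)
  max(1L, as.integer(floor(ratio)) + 1L)
}
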