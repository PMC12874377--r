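#' Read a crystal structure from a minimal-dialect CIF
#'
#' Supports the subset of CIF used throughout this package:
#' `_cell_length_{a,b,c}`, `_cell_angle_{alpha,beta,gamma}` and an
#' `_atom_site` loop with `_atom_site_type_symbol` and
#' `_atom_site_fract_{x,y,z}`. Other loops and tags are skipped with a
#' warning. Charges and pair-type labels are not stored in CIF; they come
#' from the force-field file (see [apply_charges()]).
#'
#' Atoms are grouped into rigid molecules sequentially,
#' `molecule_size` atoms at a time; molecules split across the cell
#' boundary are rejoined to the image nearest their first atom.
#'
#' @param path CIF file path.
#' @param molecule_size atoms per molecule (sequential grouping);
#'   default 1.
#' @param id optional structure identifier.
#' @return A [crystal_structure()].
#' @export
read_cif <- function(path, molecule_size = 1L, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  num <- function(tag) {
    hit <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
    if (length(hit) == 0) stop("CIF missing tag ", tag)
    as.numeric(strsplit(hit[1], "[[:space:]]+")[[1]][2])
  }
  cell <- unit_cell(num("_cell_length_a"), num("_cell_length_b"),
                    num("_cell_length_c"), num("_cell_angle_alpha"),
                    num("_cell_angle_beta"), num("_cell_angle_gamma"))
  ## locate atom_site loop
  loops <- which(lines == "loop_")
  atoms <- NULL
  for (lp in loops) {
    j <- lp + 1
    hdr <- character()
    while (j <= length(lines) && startsWith(lines[j], "_")) {
      hdr <- c(hdr, lines[j]); j <- j + 1
    }
    if (!any(startsWith(hdr, "_atom_site_")) || !is.null(atoms)) {
      warning("ignoring CIF loop with tags: ",
              paste(utils::head(hdr, 3), collapse = ", "))
      next
    }
    rows <- list()
    while (j <= length(lines) && nzchar(lines[j]) &&
           !startsWith(lines[j], "_") && lines[j] != "loop_" &&
           !startsWith(lines[j], "data_")) {
      rows[[length(rows) + 1]] <- strsplit(lines[j], "[[:space:]]+")[[1]]
      j <- j + 1
    }
    need <- c("_atom_site_type_symbol", "_atom_site_fract_x",
              "_atom_site_fract_y", "_atom_site_fract_z")
    if (!all(need %in% hdr)) stop("CIF atom_site loop lacks required tags")
    ix <- match(need, hdr)
    atoms <- data.frame(
      element = vapply(rows, `[`, "", ix[1]),
      fx = as.numeric(vapply(rows, `[`, "", ix[2])),
      fy = as.numeric(vapply(rows, `[`, "", ix[3])),
      fz = as.numeric(vapply(rows, `[`, "", ix[4])))
  }
  if (is.null(atoms)) stop("CIF has no atom_site loop")
  structure_from_sites(cell, atoms$element,
                       cbind(atoms$fx, atoms$fy, atoms$fz),
                       molecule_size, id)
}

## assemble crystal_structure from per-atom fractional sites
structure_from_sites <- function(cell, element, frac, molecule_size = 1L,
                                 id = NULL) {
  n <- nrow(frac)
  if (n %% molecule_size != 0) {
    stop("atom count not a multiple of molecule_size")
  }
  z <- n %/% molecule_size
  cellm <- cell_matrix(cell)
  mols <- list(); cents <- matrix(0, z, 3)
  for (m in seq_len(z)) {
    rows <- ((m - 1) * molecule_size + 1):(m * molecule_size)
    f <- frac[rows, , drop = FALSE]
    ## rejoin molecules split across the boundary
    f <- sweep(f, 2, f[1, ], function(a, b) a - round(a - b))
    xyz <- f %*% cellm
    mols[[m]] <- rigid_molecule(element[rows], xyz)
    cents[m, ] <- colMeans(f)
  }
  crystal_structure(cell, mols, cents, id = id)
}

#' Write a crystal structure to a minimal-dialect CIF
#'
#' Atoms are written molecule-by-molecule so that [read_cif()] with the
#' matching `molecule_size` reconstructs the same rigid molecules.
#'
#' @param structure a [crystal_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  cell <- structure$cell
  at <- atom_table(structure)
  frac <- at$xyz %*% solve(cell_matrix(cell))
  out <- c(
    sprintf("data_%s", if (is.null(structure$id)) "structure" else
      gsub("[^A-Za-z0-9_-]", "_", structure$id)),
    sprintf("_cell_length_a %.8f", cell$a),
    sprintf("_cell_length_b %.8f", cell$b),
    sprintf("_cell_length_c %.8f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma),
    "loop_",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    sprintf("%s %.10f %.10f %.10f", at$element,
            frac[, 1], frac[, 2], frac[, 3]))
  writeLines(out, path)
  invisible(path)
}

#' Read/write the XYZ-with-cell dialect
#'
#' Extended-XYZ: the comment line carries the nine lattice-vector
#' components as `Lattice="ax ay az bx by bz cx cy cz"`; following lines
#' are `element x y z` in Cartesian Angstrom.
#'
#' @param path file path.
#' @param molecule_size atoms per molecule (sequential grouping).
#' @param id optional structure identifier.
#' @return [read_xyz()]: a [crystal_structure()];
#'   [write_xyz()]: `path` invisibly.
#' @export
read_xyz <- function(path, molecule_size = 1L, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  m <- regmatches(lines[2], regexpr('Lattice="[^"]*"', lines[2]))
  if (length(m) == 0) stop("XYZ comment line lacks Lattice=\"...\"")
  comp <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", m),
                              "[[:space:]]+")[[1]])
  if (length(comp) != 9) stop("Lattice needs 9 components")
  L <- matrix(comp, 3, 3, byrow = TRUE)
  ## rebuild cell parameters (rotation-invariant)
  len <- sqrt(rowSums(L^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  cell <- unit_cell(len[1], len[2], len[3],
                    ang(L[2, ], L[3, ]), ang(L[1, ], L[3, ]),
                    ang(L[1, ], L[2, ]))
  tok <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  element <- vapply(tok, `[`, "", 1)
  xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  ## express in the canonical (lower-triangular) frame via fractional
  frac <- xyz %*% solve(L)
  structure_from_sites(cell, element, frac, molecule_size, id)
}

#' @rdname read_xyz
#' @param structure a [crystal_structure()].
#' @export
write_xyz <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  at <- atom_table(structure)
  L <- cell_matrix(structure$cell)
  out <- c(
    sprintf("%d", at$n),
    sprintf('Lattice="%s" Properties=species:S:1:pos:R:3',
            paste(sprintf("%.10f", as.numeric(t(L))), collapse = " ")),
    sprintf("%s %.10f %.10f %.10f", at$element,
            at$xyz[, 1], at$xyz[, 2], at$xyz[, 3]))
  writeLines(out, path)
  invisible(path)
}
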