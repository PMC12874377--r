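#' Force fields: Buckingham pair table plus point charges
#'
#' The intermolecular energy model is a Buckingham (exp-6) pair potential
#' `A * exp(-r * B) - C / r^6` between atom types, plus point-charge
#' electrostatics evaluated by Ewald summation. The pair table is
#' symmetric under exchange of the two type labels. `B` carries units of
#' 1/Angstrom (the exponent is written as `-r * B`).
#'
#' @param pairs data.frame with columns `t1`, `t2`, `A` (kJ/mol),
#'   `B` (1/Angstrom, `> 0`), `C` (kJ mol^-1 Angstrom^6). Missing pairs
#'   are treated as non-interacting.
#' @param charges named numeric vector: partial charge (e) per type.
#' @param masses optional named numeric vector: mass (g/mol) per type.
#' @param cutoff_rd real-space cutoff for the Buckingham sum (Angstrom),
#'   default 30.
#' @param ewald either `"auto"` (parameters tuned from `ewald_accuracy`)
#'   or a list with `alpha` (1/Angstrom), `rcut` (Angstrom) and `gcut`
#'   (1/Angstrom).
#' @param ewald_accuracy target relative accuracy for auto-tuned Ewald
#'   parameters.
#' @return An object of class `force_field`.
#' @export
force_field <- function(pairs = NULL, charges = NULL, masses = NULL,
                        cutoff_rd = 30, ewald = "auto",
                        ewald_accuracy = 1e-8) {
  if (is.null(pairs)) {
    pairs <- data.frame(t1 = character(), t2 = character(),
                        A = numeric(), B = numeric(), C = numeric())
  }
  need <- c("t1", "t2", "A", "B", "C")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns t1, t2, A, B, C")
  }
  if (nrow(pairs) > 0 && any(pairs$B <= 0)) stop("all B must be > 0")
  if (cutoff_rd <= 0) stop("cutoff_rd must be > 0")
  if (is.null(charges)) charges <- numeric()
  structure(list(pairs = pairs, charges = charges, masses = masses,
                 cutoff_rd = cutoff_rd, ewald = ewald,
                 ewald_accuracy = ewald_accuracy),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("<force_field> %d pair entries, %d typed charges, rd cutoff %.2f A\n",
              nrow(x$pairs), length(x$charges), x$cutoff_rd))
  invisible(x)
}

## symmetric lookup of (A, B, C); unknown pair -> zeros (non-interacting)
pair_params <- function(ff, t1, t2) {
  p <- ff$pairs
  hit <- (p$t1 == t1 & p$t2 == t2) | (p$t1 == t2 & p$t2 == t1)
  if (!any(hit)) return(c(A = 0, B = 1, C = 0))
  row <- p[which(hit)[1], ]
  c(A = row$A, B = row$B, C = row$C)
}

## N x N parameter matrices for a vector of atom types
pair_param_matrices <- function(ff, types) {
  ut <- unique(types)
  kk <- length(ut)
  Am <- Bm <- Cm <- matrix(0, kk, kk, dimnames = list(ut, ut))
  Bm[] <- 1
  for (i in seq_len(kk)) for (j in i:kk) {
    p <- pair_params(ff, ut[i], ut[j])
    Am[i, j] <- Am[j, i] <- p["A"]
    Bm[i, j] <- Bm[j, i] <- p["B"]
    Cm[i, j] <- Cm[j, i] <- p["C"]
  }
  idx <- match(types, ut)
  list(A = Am[idx, idx, drop = FALSE], B = Bm[idx, idx, drop = FALSE],
       C = Cm[idx, idx, drop = FALSE])
}

#' Apply force-field charges to a structure
#'
#' Charges live in the force-field file, not the CIF; this stamps the
#' per-type charges onto every atom of every molecule.
#'
#' @param structure a [crystal_structure()].
#' @param ff a [force_field()] whose `charges` cover all atom types.
#' @return The structure with charges assigned.
#' @export
apply_charges <- function(structure, ff) {
  stopifnot(inherits(structure, "crystal_structure"),
            inherits(ff, "force_field"))
  for (i in seq_along(structure$molecules)) {
    mol <- structure$molecules[[i]]
    q <- ff$charges[mol$type]
    if (anyNA(q)) {
      stop("force field has no charge for type(s): ",
           paste(unique(mol$type[is.na(q)]), collapse = ", "))
    }
    structure$molecules[[i]]$charge <- unname(q)
  }
  qtot <- sum(vapply(structure$molecules, function(m) sum(m$charge), 0))
  if (abs(qtot) > 1e-8) stop("charges leave the cell non-neutral")
  structure
}

#' Read a force-field definition file
#'
#' Structured key-value text format, one directive per line:
#' \preformatted{
#' cutoff_rd 30.0
#' ewald auto              # or: ewald <alpha> <rcut> <gcut>
#' type C mass 12.011 charge -0.1
#' pair C C A 1000.0 B 3.0 C 100.0
#' }
#' Comments start with `#`. Schema violations raise errors carrying the
#' offending line number.
#'
#' @param path file path.
#' @return A [force_field()].
#' @export
read_forcefield <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pairs <- list(); charges <- c(); masses <- c()
  cutoff_rd <- 30; ewald <- "auto"
  bad <- function(i, msg) stop(sprintf("%s:%d: %s", path, i, msg))
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) == 0 || !nzchar(tok[1])) next
    key <- tok[1]
    if (key == "cutoff_rd") {
      v <- suppressWarnings(as.numeric(tok[2]))
      if (length(tok) != 2 || is.na(v) || v <= 0) bad(i, "cutoff_rd needs one positive number")
      cutoff_rd <- v
    } else if (key == "ewald") {
      if (length(tok) == 2 && tok[2] == "auto") {
        ewald <- "auto"
      } else if (length(tok) == 4) {
        v <- suppressWarnings(as.numeric(tok[2:4]))
        if (anyNA(v) || any(v <= 0)) bad(i, "ewald needs 'auto' or three positive numbers (alpha rcut gcut)")
        ewald <- list(alpha = v[1], rcut = v[2], gcut = v[3])
      } else bad(i, "ewald needs 'auto' or three numbers")
    } else if (key == "type") {
      if (length(tok) != 6 || tok[3] != "mass" || tok[5] != "charge") {
        bad(i, "type line must be: type <label> mass <m> charge <q>")
      }
      m <- suppressWarnings(as.numeric(tok[4]))
      q <- suppressWarnings(as.numeric(tok[6]))
      if (is.na(m) || m <= 0 || is.na(q)) bad(i, "bad mass/charge value")
      masses[tok[2]] <- m; charges[tok[2]] <- q
    } else if (key == "pair") {
      if (length(tok) != 9 || tok[4] != "A" || tok[6] != "B" || tok[8] != "C") {
        bad(i, "pair line must be: pair <t1> <t2> A <A> B <B> C <C>")
      }
      v <- suppressWarnings(as.numeric(tok[c(5, 7, 9)]))
      if (anyNA(v)) bad(i, "bad pair parameter value")
      if (v[2] <= 0) bad(i, "B must be > 0")
      pairs[[length(pairs) + 1]] <- data.frame(t1 = tok[2], t2 = tok[3],
                                               A = v[1], B = v[2], C = v[3])
    } else bad(i, paste0("unknown directive '", key, "'"))
  }
  force_field(pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
              charges = charges, masses = masses,
              cutoff_rd = cutoff_rd, ewald = ewald)
}

#' Write a force-field definition file
#'
#' Inverse of [read_forcefield()].
#'
#' @param ff a [force_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "force_field"))
  out <- c(sprintf("cutoff_rd %.10g", ff$cutoff_rd))
  out <- c(out, if (identical(ff$ewald, "auto")) "ewald auto" else
    sprintf("ewald %.10g %.10g %.10g", ff$ewald$alpha, ff$ewald$rcut,
            ff$ewald$gcut))
  for (t in names(ff$charges)) {
    m <- if (!is.null(ff$masses) && t %in% names(ff$masses)) ff$masses[[t]]
         else element_mass(t)
    out <- c(out, sprintf("type %s mass %.10g charge %.10g", t, m,
                          ff$charges[[t]]))
  }
  p <- ff$pairs
  for (i in seq_len(nrow(p))) {
    out <- c(out, sprintf("pair %s %s A %.10g B %.10g C %.10g",
                          p$t1[i], p$t2[i], p$A[i], p$B[i], p$C[i]))
  }
  writeLines(out, path)
  invisible(path)
}
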