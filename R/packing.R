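## Packing-similarity matching (COMPACK-like, simplified)

## the 24 proper rotations of the octahedral group (signed permutation
## matrices with det +1), used as ICP starting orientations
octahedral_rotations <- function() {
  out <- list()
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) for (s1 in c(-1, 1)) for (s2 in c(-1, 1))
    for (s3 in c(-1, 1)) {
      R <- matrix(0, 3, 3)
      R[1, p[1]] <- s1; R[2, p[2]] <- s2; R[3, p[3]] <- s3
      if (abs(det(R) - 1) < 1e-12) out[[length(out) + 1]] <- R
    }
  out
}

## Kabsch optimal superposition RMSD of two point sets with known
## correspondence
kabsch_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  S <- svd(crossprod(P, Q))
  d <- sign(det(S$v %*% t(S$u)))
  R <- S$v %*% diag(c(1, 1, d)) %*% t(S$u)
  D <- Q - P %*% t(R)
  sqrt(mean(rowSums(D^2)))
}

## N-molecule nearest-neighbour cluster around central molecule `centre`
## in a replicated environment; returns per-molecule atom coordinate
## matrices ordered by centroid distance. With `ties = TRUE` the list is
## extended past N to include every molecule tied (within tie_tol) with
## the N-th centroid distance, so boundary-shell degeneracies cannot
## exclude the matching partner.
shell_cluster <- function(structure, centre, N, ties = FALSE,
                          tie_tol = 1e-6) {
  nrep <- max(2L, ceiling((N / structure$Z)^(1 / 3)) + 1L)
  sup <- build_supercell(structure, rep(nrep, 3))
  at <- atom_table(sup)
  nm <- sup$Z
  cents <- t(vapply(seq_len(nm), function(m)
    colMeans(at$xyz[at$mol == m, , drop = FALSE]), numeric(3)))
  ## the centre molecule instance closest to the supercell middle
  mid <- colSums(cell_matrix(sup$cell)) / 2   # centre of the box
  cand <- seq(centre, nm, by = structure$Z)
  c0 <- cand[which.min(rowSums(sweep(cents[cand, , drop = FALSE], 2,
                                     mid)^2))]
  d <- sqrt(rowSums(sweep(cents, 2, cents[c0, ])^2))
  ord <- order(d)
  if (length(ord) < N) stop("replicated environment too small for N")
  keep <- N
  if (ties) {
    while (keep < length(ord) &&
           d[ord[keep + 1]] <= d[ord[N]] + tie_tol) keep <- keep + 1
  }
  sel <- ord[seq_len(keep)]
  lapply(sel, function(m) at$xyz[at$mol == m, , drop = FALSE])
}

## one-directional cluster match: reference cluster of exactly N
## molecules against a tie-extended candidate pool, ICP over the
## octahedral starting rotations with greedy nearest-centroid
## assignment and Kabsch refinement
cluster_match_rmsd <- function(reference, candidate, N) {
  rotset <- octahedral_rotations()
  best <- Inf
  for (cr in seq_len(reference$Z)) {
    clr <- shell_cluster(reference, cr, N)
    Pr <- do.call(rbind, clr)
    cenr <- t(vapply(clr, colMeans, numeric(3)))
    B <- sweep(cenr, 2, colMeans(cenr))
    for (cc in seq_len(candidate$Z)) {
      clc <- shell_cluster(candidate, cc, N, ties = TRUE)
      cenc <- t(vapply(clc, colMeans, numeric(3)))
      A <- sweep(cenc, 2, colMeans(cenc))
      for (R0 in rotset) {
        Arot <- A %*% t(R0)
        pair <- integer(N)
        for (it in 1:6) {
          used <- logical(nrow(Arot))
          newpair <- integer(N)
          for (k in seq_len(N)) {
            dd <- rowSums(sweep(Arot, 2, B[k, ])^2)
            dd[used] <- Inf
            newpair[k] <- which.min(dd)
            used[newpair[k]] <- TRUE
          }
          Am <- A[newpair, , drop = FALSE]
          S <- svd(crossprod(sweep(Am, 2, colMeans(Am)), B))
          d <- sign(det(S$v %*% t(S$u)))
          R <- S$v %*% diag(c(1, 1, d)) %*% t(S$u)
          Arot <- A %*% t(R)
          if (identical(newpair, pair)) break
          pair <- newpair
        }
        r <- kabsch_rmsd(do.call(rbind, clc[pair]), Pr)
        if (r < best) best <- r
      }
    }
  }
  best
}

#' Packing-shell RMSD between two crystal structures
#'
#' A COMPACK-like similarity score: around a central molecule, the
#' cluster of the `N` nearest molecules (by centroid distance) is built
#' in each structure within a sufficiently replicated environment; the
#' clusters are rigidly superposed and the root-mean-square deviation of
#' atomic positions minimised. Two structures match when the minimised
#' RMSD does not exceed the threshold (0.50 Angstrom by default).
#'
#' Simplifications relative to COMPACK: the central molecule iterates
#' over all molecules of both structures and the minimum RMSD is taken;
#' cluster molecules are paired by centroid-distance order with a few
#' rounds of nearest-centroid reassignment after superposition; atoms
#' within paired molecules are matched by identical ordering (the
#' fixture generators guarantee consistent atom order).
#'
#' @param reference,candidate [crystal_structure()] objects with
#'   identical molecular formulae.
#' @param N cluster size (default 15, the conventional RMSD15).
#' @param threshold match threshold in Angstrom (default 0.50).
#' @return list with `rmsd` (Angstrom), `match` (logical) and `N`.
#' @export
packing_shell_rmsd <- function(reference, candidate, N = 15,
                               threshold = 0.50) {
  stopifnot(inherits(reference, "crystal_structure"),
            inherits(candidate, "crystal_structure"))
  fref <- vapply(reference$molecules, molecule_formula, "")
  fcan <- vapply(candidate$molecules, molecule_formula, "")
  if (!setequal(unique(fref), unique(fcan)) ||
      length(unique(fref)) != 1 || length(unique(fcan)) != 1) {
    return(list(rmsd = Inf, match = FALSE, N = N,
                reason = "molecule formula mismatch"))
  }
  nat <- n_atoms(reference$molecules[[1]])
  if (n_atoms(candidate$molecules[[1]]) != nat) {
    return(list(rmsd = Inf, match = FALSE, N = N,
                reason = "molecule size mismatch"))
  }
  best <- min(cluster_match_rmsd(reference, candidate, N),
              cluster_match_rmsd(candidate, reference, N))
  list(rmsd = best, match = is.finite(best) && best <= threshold, N = N)
}
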