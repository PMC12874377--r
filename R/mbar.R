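#' Multistate Bennett acceptance ratio (MBAR) estimator
#'
#' Solves the self-consistent MBAR equations
#' `f_k = -log sum_n exp(-u_kn) / sum_l N_l exp(f_l - u_ln)`
#' for the dimensionless free energies of `K` thermodynamic states from
#' samples drawn in each of them, in the gauge `f_1 = 0`. The solver
#' minimises the convex MBAR objective by quasi-Newton (BFGS) and then
#' polishes with self-consistent iteration to `tol`. Uncertainties come
#' from the standard asymptotic covariance of the estimator; 95%
#' confidence intervals are `1.96 * sigma`.
#'
#' @param samples either an `alchemical_samples` object from
#'   [cross_evaluate()] or a `K x n` reduced-potential matrix `u_kn`.
#' @param N_k integer vector of per-state sample counts (columns of
#'   `u_kn` are ordered state-by-state); taken from `samples` when it is
#'   an `alchemical_samples`.
#' @param tol self-consistency tolerance on `max |delta f|`.
#' @param maxit iteration limit.
#' @param overlap_warn adjacent-state overlap threshold below which a
#'   warning is recorded in the result.
#' @return An object of class `mbar_fit`: `f` (reduced free energies,
#'   `f[1] = 0`), `Theta` (asymptotic covariance), `overlap`
#'   (adjacent-state overlap), `converged`, `iterations`, `warnings`.
#' @examples
#' ## two harmonic states sampled exactly
#' set.seed(1)
#' x1 <- rnorm(500, 0, 1); x2 <- rnorm(500, 0, sqrt(0.5))
#' u <- function(x, K) 0.5 * K * x^2
#' u_kn <- rbind(c(u(x1, 1), u(x2, 1)), c(u(x1, 2), u(x2, 2)))
#' fit <- mbar_solve(u_kn, N_k = c(500, 500))
#' delta_f(fit, 1, 2)   # ~ 0.5*log(2)
#' @export
mbar_solve <- function(samples, N_k = NULL, tol = 1e-10, maxit = 10000,
                       overlap_warn = 0.03) {
  if (inherits(samples, "alchemical_samples")) {
    u_kn <- samples$u_kn
    if (is.null(N_k)) N_k <- samples$N_k
  } else u_kn <- as.matrix(samples)
  K <- nrow(u_kn); n <- ncol(u_kn)
  if (K < 2) stop("need at least 2 states")
  if (is.null(N_k) || length(N_k) != K || any(N_k < 1)) {
    stop("every state needs at least one sample (N_k)")
  }
  if (sum(N_k) != n) stop("sum(N_k) must equal ncol(u_kn)")
  if (!all(is.finite(u_kn))) stop("non-finite reduced potentials")

  logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  lognk <- log(N_k)

  ## log denominator per sample: log sum_l N_l exp(f_l - u_ln)
  logden <- function(f) {
    A <- f + lognk - u_kn           # K x n (column recycling by rows)
    m <- apply(A, 2, max)
    m + log(colSums(exp(sweep(A, 2, m))))
  }
  ## convex objective (negative log likelihood up to constants)
  obj <- function(fr) {
    f <- c(0, fr)
    sum(logden(f)) - sum(N_k * f)
  }
  grad <- function(fr) {
    f <- c(0, fr)
    ld <- logden(f)
    Wsum <- rowSums(exp(sweep(f + lognk - u_kn, 2, ld)))
    (Wsum - N_k)[-1]
  }
  fr0 <- rep(0, K - 1)
  opt <- stats::optim(fr0, obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  f <- c(0, opt$par)
  ## self-consistent polish
  it <- 0; conv <- FALSE
  while (it < maxit) {
    it <- it + 1
    ld <- logden(f)
    fnew <- -vapply(seq_len(K), function(k)
      logsumexp(-u_kn[k, ] - ld), 0)
    fnew <- fnew - fnew[1]
    d <- max(abs(fnew - f))
    f <- fnew
    if (d < tol) { conv <- TRUE; break }
  }
  if (!conv) stop("MBAR did not converge within the iteration limit")

  ## weights and asymptotic covariance (SVD-reduced form)
  ld <- logden(f)
  W <- t(exp(sweep(f - u_kn, 2, ld)))       # n x K, colSums(W) = 1-ish
  eg <- eigen(crossprod(W), symmetric = TRUE)
  s <- sqrt(pmax(eg$values, 0))
  V <- eg$vectors
  S <- diag(s, K)
  Mi <- diag(K) - S %*% t(V) %*% (N_k * V) %*% S
  pinv <- function(A, rtol = 1e-10) {
    sv <- svd(A)
    keep <- sv$d > rtol * max(sv$d)
    sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  }
  Theta <- V %*% S %*% pinv(Mi) %*% S %*% t(V)

  ## overlap matrix O_kl = N_k sum_n W_nk W_nl
  O <- N_k * crossprod(W)
  ov <- vapply(seq_len(K - 1), function(k) O[k, k + 1], 0)
  warns <- character()
  if (any(ov < overlap_warn)) {
    warns <- sprintf("poor overlap between adjacent states %d-%d (%.3g)",
                     which(ov < overlap_warn),
                     which(ov < overlap_warn) + 1,
                     ov[ov < overlap_warn])
  }
  structure(list(f = f, Theta = Theta, overlap = ov, converged = conv,
                 iterations = it, N_k = N_k, warnings = warns),
            class = "mbar_fit")
}

#' @export
print.mbar_fit <- function(x, ...) {
  cat(sprintf("<mbar_fit> %d states, converged in %d iterations\n",
              length(x$f), x$iterations))
  cat("f:", paste(sprintf("%.4f", x$f), collapse = " "), "\n")
  if (length(x$warnings)) cat("warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' @export
summary.mbar_fit <- function(object, ...) {
  K <- length(object$f)
  se <- vapply(seq_len(K), function(k)
    sqrt(max(0, object$Theta[1, 1] + object$Theta[k, k] -
               2 * object$Theta[1, k])), 0)
  data.frame(state = seq_len(K), f = object$f, se_vs_state1 = se,
             N = object$N_k)
}

#' @export
coef.mbar_fit <- function(object, ...) object$f

#' Free-energy difference between two MBAR states
#'
#' @param fit an [mbar_solve()] result.
#' @param i,j state indices.
#' @return list with `df = f_j - f_i` (dimensionless), `se`, and the
#'   95% half-width `ci95 = 1.96 * se`.
#' @export
delta_f <- function(fit, i, j) {
  stopifnot(inherits(fit, "mbar_fit"))
  df <- fit$f[j] - fit$f[i]
  se <- sqrt(max(0, fit$Theta[i, i] + fit$Theta[j, j] -
                   2 * fit$Theta[i, j]))
  list(df = df, se = se, ci95 = 1.96 * se)
}
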