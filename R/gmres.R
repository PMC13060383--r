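#' Restarted GMRES (matrix-free)
#'
#' Standard restarted GMRES with modified Gram-Schmidt Arnoldi and Givens
#' rotations, taking the operator and the (left) preconditioner as
#' functions. Convergence is declared on the true unpreconditioned
#' residual, recomputed at each restart; the inner iteration monitors the
#' preconditioned residual estimate.
#'
#' @param Afun function(x) applying the system operator.
#' @param b right-hand side.
#' @param Mfun function(r) applying the preconditioner (default identity).
#' @param tol relative residual tolerance.
#' @param restart Krylov subspace dimension per cycle.
#' @param max_iter maximum total inner iterations.
#' @param x0 initial guess (default zero).
#' @return list: `x`, `iterations` (operator applications in the Krylov
#'   loop), `relres` (final true relative residual), `history` (true
#'   relative residual after each cycle), `converged`.
#' @export
gmres_solve <- function(Afun, b, Mfun = identity, tol = 1e-9, restart = 40,
                        max_iter = 300, x0 = NULL) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else x0
  nb <- sqrt(sum(b^2))
  if (nb == 0)
    return(list(x = numeric(n), iterations = 0L, relres = 0,
                history = numeric(0), converged = TRUE))
  iters <- 0L
  history <- numeric(0)
  repeat {
    r <- b - Afun(x)
    relres <- sqrt(sum(r^2)) / nb
    history <- c(history, relres)
    if (relres <= tol || iters >= max_iter) break
    z <- Mfun(r)
    beta <- sqrt(sum(z^2))
    V <- matrix(0, n, restart + 1)
    H <- matrix(0, restart + 1, restart)
    cs <- numeric(restart); sn <- numeric(restart)
    g <- numeric(restart + 1); g[1] <- beta
    V[, 1] <- z / beta
    j <- 0L
    while (j < restart && iters < max_iter) {
      j <- j + 1L
      iters <- iters + 1L
      w <- Mfun(Afun(V[, j]))
      for (i in seq_len(j)) {
        H[i, j] <- sum(w * V[, i])
        w <- w - H[i, j] * V[, i]
      }
      H[j + 1, j] <- sqrt(sum(w^2))
      if (H[j + 1, j] > 0) V[, j + 1] <- w / H[j + 1, j]
      # apply stored Givens rotations, then form the new one
      for (i in seq_len(j - 1)) {
        t <- cs[i] * H[i, j] + sn[i] * H[i + 1, j]
        H[i + 1, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1, j]
        H[i, j] <- t
      }
      d <- sqrt(H[j, j]^2 + H[j + 1, j]^2)
      if (d == 0) { j <- j; break }
      cs[j] <- H[j, j] / d
      sn[j] <- H[j + 1, j] / d
      H[j, j] <- d
      H[j + 1, j] <- 0
      g[j + 1] <- -sn[j] * g[j]
      g[j] <- cs[j] * g[j]
      if (abs(g[j + 1]) / beta <= 0.1 * tol) break
    }
    if (j > 0) {
      y <- backsolve(H[seq_len(j), seq_len(j), drop = FALSE], g[seq_len(j)])
      x <- x + V[, seq_len(j), drop = FALSE] %*% y
    } else break
  }
  list(x = as.vector(x), iterations = iters, relres = relres,
       history = history, converged = relres <= tol)
}
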