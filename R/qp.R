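# Exact primal active-set solver for small strictly convex quadratic
# programs: minimize 1/2 x'Hx + g'x subject to A x >= b. Dimensions here are
# tiny (<= 6 variables, ~15 constraints: box bounds on the free rates plus
# the per-state population-budget rows), so a dense KKT solve per iteration
# is exact and cheap. Used by fitDynamics; verified in the tests against an
# independent quasi-Newton solve.

solveQP <- function(H, g, A, b, x0, maxIter = 200L, tol = 1e-10) {
  n <- length(g)
  if (n == 0L) return(numeric(0))
  H <- (H + t(H)) / 2
  sc <- max(abs(H), 1)
  Hs <- H / sc; gs <- g / sc
  x <- x0
  if (nrow(A) && any(A %*% x < b - 1e-8))
    stop("solveQP: infeasible starting point")
  active <- if (nrow(A)) which(A %*% x - b < tol) else integer(0)

  for (iter in seq_len(maxIter)) {
    # drop linearly dependent active rows before the KKT solve
    if (length(active) > 1L) {
      qrA <- qr(t(A[active, , drop = FALSE]))
      active <- active[qrA$pivot[seq_len(qrA$rank)]]
    }
    m <- length(active)
    Aw <- A[active, , drop = FALSE]
    K <- rbind(cbind(Hs, t(Aw)), cbind(Aw, matrix(0, m, m)))
    rhs <- c(-(Hs %*% x + gs), rep(0, m))
    sol <- tryCatch(solve(K, rhs), error = function(e)
      solve(K + diag(1e-12, nrow(K)), rhs))
    p <- sol[seq_len(n)]
    # KKT block gives grad f = -A_W' * sol_lambda; the standard >=-constraint
    # multipliers are the negation
    lam <- if (m) -sol[n + seq_len(m)] else numeric(0)

    if (sqrt(sum(p^2)) < tol) {
      if (!m || all(lam >= -tol)) return(x)
      active <- active[-which.min(lam)]
      next
    }
    alpha <- 1
    blocker <- NA_integer_
    if (nrow(A)) {
      cand <- setdiff(seq_len(nrow(A)), active)
      Ap <- drop(A[cand, , drop = FALSE] %*% p)
      hit <- which(Ap < -tol)
      if (length(hit)) {
        ratios <- (b[cand[hit]] - drop(A[cand[hit], , drop = FALSE] %*% x)) /
          Ap[hit]
        j <- which.min(ratios)
        if (ratios[j] < alpha) {
          alpha <- max(ratios[j], 0)
          blocker <- cand[hit][j]
        }
      }
    }
    x <- x + alpha * p
    if (!is.na(blocker)) active <- c(active, blocker)
  }
  warning("solveQP: iteration limit reached")
  x
}
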