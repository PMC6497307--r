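# Dense two-phase simplex with Bland's anti-cycling rule.
#
# FBA problems are small here (toy networks) but routinely degenerate:
# many basic variables sit at zero and several bounds are active at the
# optimum. The general-purpose simplex routines available to the package
# (boot::simplex, pracma::linprog) both fail on such instances — returning
# spurious infeasibility or NA pivots — so the default backend is this
# textbook implementation: standard form with explicit upper-bound slacks,
# phase 1 with artificial variables, Bland's rule throughout (finite
# termination, no cycling), and a single numeric tolerance.

# Minimize cost'z subject to T z = rhs, z >= 0, starting from the given
# basis (one basic column per row, identity submatrix). Returns list
# (status, z, basis, T, rhs).
.simplex_phase <- function(T, rhs, cost, basis, tol) {
  m <- nrow(T); N <- ncol(T)
  it_max <- 500L * (N + m)
  for (it in seq_len(it_max)) {
    cb <- cost[basis]
    # reduced costs r = cost - cb' T  (T holds B^{-1}A throughout)
    r <- cost - as.numeric(crossprod(cb, T))
    r[basis] <- 0  # exact zeros for basic columns
    enter <- which(r < -tol)
    if (!length(enter)) {
      z <- numeric(N)
      z[basis] <- rhs
      return(list(status = "optimal", z = z, basis = basis, T = T,
                  rhs = rhs))
    }
    j <- min(enter)  # Bland: smallest eligible index
    col <- T[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- rhs[pos] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.min(basis[cand])]  # Bland on leaving variable
    # pivot on (i, j)
    piv <- T[i, j]
    T[i, ] <- T[i, ] / piv
    rhs[i] <- rhs[i] / piv
    others <- setdiff(seq_len(m), i)
    f <- T[others, j]
    T[others, ] <- T[others, , drop = FALSE] - outer(f, T[i, ])
    rhs[others] <- rhs[others] - f * rhs[i]
    rhs[rhs < 0 & rhs > -tol] <- 0
    basis[i] <- j
  }
  list(status = "maxiter")
}

# Maximize obj'x subject to Aeq x = beq, 0 <= x <= upper (finite).
# Returns list(status, x, value).
.lp_bounded <- function(Aeq, beq, obj, upper, tol = 1e-9) {
  n <- length(obj)
  m <- nrow(Aeq)
  flip <- beq < 0
  if (any(flip)) {
    Aeq[flip, ] <- -Aeq[flip, , drop = FALSE]
    beq[flip] <- -beq[flip]
  }
  # variables: x (n), bound slacks s (n), artificials a (m)
  # rows: m equality rows [Aeq 0 I], n bound rows [I I 0]
  Tm <- rbind(cbind(Aeq, matrix(0, m, n), diag(m)),
              cbind(diag(n), diag(n), matrix(0, n, m)))
  rhs <- c(beq, upper)
  basis <- c(2L * n + seq_len(m),  # artificials basic on eq rows
             n + seq_len(n))       # slacks basic on bound rows
  scale <- max(1, max(abs(rhs)))
  ptol <- tol * scale

  # phase 1: drive artificials to zero
  cost1 <- c(numeric(2L * n), rep(1, m))
  p1 <- .simplex_phase(Tm, rhs, cost1, basis, tol)
  if (p1$status != "optimal" || sum(p1$rhs[p1$basis > 2L * n]) > ptol * m) {
    return(list(status = "infeasible"))
  }
  Tm <- p1$T; rhs <- p1$rhs; basis <- p1$basis
  # pivot lingering zero-level artificials out of the basis when possible
  for (i in which(basis > 2L * n)) {
    j <- which(abs(Tm[i, seq_len(2L * n)]) > tol)[1]
    if (!is.na(j)) {
      piv <- Tm[i, j]
      Tm[i, ] <- Tm[i, ] / piv
      rhs[i] <- rhs[i] / piv
      others <- setdiff(seq_len(nrow(Tm)), i)
      f <- Tm[others, j]
      Tm[others, ] <- Tm[others, , drop = FALSE] - outer(f, Tm[i, ])
      rhs[others] <- rhs[others] - f * rhs[i]
      basis[i] <- j
    }
  }
  # phase 2 on the original objective (min -obj'x); artificials barred by
  # a prohibitive cost
  big <- 1e12
  cost2 <- c(-obj, numeric(n), rep(big, m))
  p2 <- .simplex_phase(Tm, rhs, cost2, basis, tol)
  if (p2$status != "optimal") return(list(status = p2$status))
  x <- p2$z[seq_len(n)]
  list(status = "optimal", x = x, value = sum(obj * x))
}
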