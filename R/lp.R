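## Internal dense linear programming.
##
## The feasibility and optimization problems in this package are tiny (at most
## ~15 variables and ~10 constraints), but they are equality-heavy and often
## degenerate, which is exactly the regime where general-purpose R simplex
## codes in this stack misbehave. This is a plain two-phase simplex on the
## standard form min c'x, A x = b, x >= 0, with Bland's rule (anti-cycling,
## guaranteed termination). It is oracle-checked against exhaustive vertex
## enumeration across the test suite.

## min cc'x st A x = b, x >= 0. Returns status optimal/infeasible/unbounded,
## with x, value, and an unbounded ray when applicable.
.simplex_core <- function(cc, A, b, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  ncols <- n + m

  pivot_run <- function(Tab, basis, obj, allowed) {
    for (it in seq_len(max_iter)) {
      cb <- obj[basis]
      red <- obj[seq_len(ncols)] -
        as.numeric(crossprod(cb, Tab[, seq_len(ncols), drop = FALSE]))
      red[!allowed] <- Inf
      enter <- which(red < -tol)
      if (!length(enter)) return(list(Tab = Tab, basis = basis, status = "optimal"))
      j <- min(enter) # Bland's rule: lowest index enters
      col <- Tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tab = Tab, basis = basis, status = "unbounded", enter = j))
      ratios <- Tab[pos, ncols + 1L] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      i <- cand[which.min(basis[cand])] # lowest-index leaving variable
      piv <- Tab[i, j]
      Tab[i, ] <- Tab[i, ] / piv
      for (k in seq_len(nrow(Tab))) {
        if (k != i && abs(Tab[k, j]) > 0) Tab[k, ] <- Tab[k, ] - Tab[k, j] * Tab[i, ]
      }
      basis[i] <- j
    }
    list(Tab = Tab, basis = basis, status = "maxiter")
  }

  ## phase 1: minimize the sum of artificial variables
  obj1 <- c(rep(0, n), rep(1, m))
  p1 <- pivot_run(Tab, basis, obj1, rep(TRUE, ncols))
  if (p1$status != "optimal") return(list(status = p1$status))
  if (sum(obj1[p1$basis] * p1$Tab[, ncols + 1L]) > 1e-7) {
    return(list(status = "infeasible"))
  }
  Tab <- p1$Tab
  basis <- p1$basis
  ## drive remaining artificials out of the basis (redundant rows stay put
  ## harmlessly: their rows are zero over the structural columns)
  for (i in which(basis > n)) {
    row <- Tab[i, seq_len(n)]
    j <- which(abs(row) > tol)[1]
    if (!is.na(j)) {
      Tab[i, ] <- Tab[i, ] / Tab[i, j]
      for (k in seq_len(nrow(Tab))) {
        if (k != i) Tab[k, ] <- Tab[k, ] - Tab[k, j] * Tab[i, ]
      }
      basis[i] <- j
    }
  }
  keep <- basis <= n
  Tab <- Tab[keep, , drop = FALSE]
  basis <- basis[keep]

  ## phase 2 over the structural columns only
  obj2 <- c(cc, rep(0, m))
  p2 <- pivot_run(Tab, basis, obj2, c(rep(TRUE, n), rep(FALSE, m)))
  if (p2$status == "maxiter") return(list(status = "maxiter"))
  x <- rep(0, n)
  x[p2$basis] <- p2$Tab[, ncols + 1L]
  if (p2$status == "unbounded") {
    ray <- rep(0, n)
    ray[p2$enter] <- 1
    ray[p2$basis] <- -p2$Tab[, p2$enter]
    return(list(status = "unbounded", x = x[seq_len(n)], ray = ray))
  }
  list(status = "optimal", x = x, value = sum(cc * x))
}

## General interface used throughout the package:
##   optimize v's subject to  Aeq s = beq,  Ale s <= ble,  lb <= s
## lb entries may be -Inf (free coordinates, handled by variable splitting);
## upper bounds are expressed through Ale rows. Returns list(status, s, value)
## or an unbounded certificate ray in the original coordinates.
.lp <- function(v, Aeq = NULL, beq = NULL, Ale = NULL, ble = NULL, lb,
                maximize = FALSE) {
  n <- length(lb)
  free <- !is.finite(lb)
  shift <- ifelse(free, 0, lb)
  Tmap <- cbind(diag(n), -diag(n)[, free, drop = FALSE]) # s = Tmap z + shift, z >= 0
  rows <- list()
  rhs <- c()
  n_slack <- if (is.null(Ale)) 0L else nrow(Ale)
  nz <- ncol(Tmap)
  if (!is.null(Aeq)) {
    rows[[length(rows) + 1L]] <- cbind(Aeq %*% Tmap, matrix(0, nrow(Aeq), n_slack))
    rhs <- c(rhs, as.numeric(beq - Aeq %*% shift))
  }
  if (n_slack > 0L) {
    rows[[length(rows) + 1L]] <- cbind(Ale %*% Tmap, diag(n_slack))
    rhs <- c(rhs, as.numeric(ble - Ale %*% shift))
  }
  A <- do.call(rbind, rows)
  cc <- c(as.numeric(v %*% Tmap), rep(0, n_slack))
  if (maximize) cc <- -cc
  r <- .simplex_core(cc, A, rhs)
  if (r$status == "optimal") {
    s <- as.numeric(Tmap %*% r$x[seq_len(nz)]) + shift
    return(list(status = "optimal", s = s, value = sum(v * s)))
  }
  if (r$status == "unbounded") {
    ray <- as.numeric(Tmap %*% r$ray[seq_len(nz)])
    return(list(status = "unbounded", ray = ray))
  }
  list(status = r$status)
}
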