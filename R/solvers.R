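# Pluggable LP backends.
#
# A backend is a function(lp) returning list(status, x) with status one of
# "optimal", "infeasible", "unbounded", "numerical_error" and x the primal
# point (length lp$n_var) when status == "optimal". Constraint rows of the
# assembled program are interpreted as A x (sense) rhs with sense in
# {"=", "<=", ">="}; variables are free (all bounds are explicit rows).

.solver_registry <- new.env(parent = emptyenv())

#' Register an LP feasibility backend
#'
#' @param name Backend token used in [solve_options()].
#' @param fun Function taking an assembled program (see [build_lp()]) and
#'   returning `list(status = <token>, x = <numeric or NULL>)` with status in
#'   `"optimal"`, `"infeasible"`, `"unbounded"`, `"numerical_error"`.
#' @return Invisibly, the previous backend of that name (or `NULL`).
#' @export
register_solver <- function(name, fun) {
  old <- .solver_registry[[name]]
  assign(name, fun, envir = .solver_registry)
  invisible(old)
}

#' List registered solver backends
#' @return Character vector of backend tokens.
#' @export
list_solvers <- function() sort(ls(.solver_registry))

get_solver <- function(name) {
  fun <- .solver_registry[[name]]
  if (is.null(fun))
    stop("unknown solver backend '", name, "'; available: ",
         paste(list_solvers(), collapse = ", "), call. = FALSE)
  fun
}

# Minimum-norm feasibility via the Goldfarb-Idnani dual QP method:
# min ||x||^2 s.t. the constraint rows. Equality rows are eliminated first
# by a QR null-space reduction (quadprog's active-set handling of many
# equalities is fragile: dependent active sets get misreported as
# inconsistent), so quadprog only ever sees inequalities. The returned
# point is the unique minimum-norm feasible point, which makes
# trajectories deterministic for this backend.
solve_quadprog <- function(lp, tol = 1e-9) {
  n <- lp$n_var
  A <- as.matrix(lp$A)
  eq <- lp$sense == "="
  ge <- lp$sense == ">="
  le <- lp$sense == "<="
  G <- rbind(A[ge, , drop = FALSE], -A[le, , drop = FALSE])
  h <- c(lp$rhs[ge], -lp$rhs[le])
  keep <- is.finite(h)            # rows with -Inf rhs are vacuous
  G <- G[keep, , drop = FALSE]
  h <- h[keep]

  Aeq <- A[eq, , drop = FALSE]
  beq <- lp$rhs[eq]
  if (nrow(Aeq)) {
    qe <- qr(t(Aeq))
    r <- qe$rank
    Q <- qr.Q(qe, complete = TRUE)
    Rr <- qr.R(qe)[seq_len(r), seq_len(r), drop = FALSE]
    # min-norm particular solution of Aeq x = beq: x0 = Q_1 R^-T P beq
    z <- backsolve(Rr, beq[qe$pivot][seq_len(r)], transpose = TRUE)
    x0 <- Q[, seq_len(r), drop = FALSE] %*% z
    if (max(abs(Aeq %*% x0 - beq)) > tol * max(1, max(abs(beq))))
      return(list(status = "infeasible", x = NULL))   # inconsistent equalities
    Z <- Q[, -seq_len(r), drop = FALSE]
  } else {
    x0 <- matrix(0, n, 1)
    Z <- diag(n)
  }
  if (ncol(Z) == 0L) {
    viol <- h - as.numeric(G %*% x0)
    if (length(viol) && max(viol) > tol * max(1, max(abs(h[is.finite(h)])), na.rm = TRUE))
      return(list(status = "infeasible", x = NULL))
    return(list(status = "optimal", x = as.numeric(x0)))
  }
  if (!nrow(G))
    return(list(status = "optimal", x = as.numeric(x0)))
  Gz <- G %*% Z
  hz <- h - as.numeric(G %*% x0)
  res <- tryCatch(
    quadprog::solve.QP(Dmat = diag(ncol(Z)), dvec = rep(0, ncol(Z)),
                       Amat = t(Gz), bvec = hz, meq = 0),
    error = function(e) e)
  if (inherits(res, "error")) {
    msg <- conditionMessage(res)
    if (grepl("constraints are inconsistent", msg, fixed = TRUE))
      return(list(status = "infeasible", x = NULL))
    return(list(status = "numerical_error", x = NULL, message = msg))
  }
  list(status = "optimal", x = as.numeric(x0 + Z %*% res$solution))
}

# Dense two-phase primal simplex with Bland's anti-cycling rule, on the
# standard form obtained by splitting every free variable (x = xp - xn) and
# adding slack/surplus columns. Phase 1 minimizes the sum of artificial
# variables; a positive phase-1 optimum means infeasible. The feasibility
# program has a zero objective, so phase 2 is vacuous and the phase-1 basic
# point is returned. Deterministic; independent of the quadprog backend.
solve_simplex <- function(lp, tol = 1e-9) {
  A <- as.matrix(lp$A)
  rhs <- lp$rhs
  sense <- lp$sense
  keep <- !((sense == ">=" & rhs == -Inf) | (sense == "<=" & rhs == Inf))
  A <- A[keep, , drop = FALSE]; rhs <- rhs[keep]; sense <- sense[keep]
  m <- nrow(A); nv <- lp$n_var
  ns <- sum(sense != "=")
  B <- cbind(A, -A, matrix(0, m, ns))
  sj <- 0L
  for (i in seq_len(m)) {
    if (sense[i] == "=") next
    sj <- sj + 1L
    B[i, 2L * nv + sj] <- if (sense[i] == "<=") 1 else -1
  }
  flip <- rhs < 0
  B[flip, ] <- -B[flip, , drop = FALSE]
  b <- abs(rhs)
  # row equilibration: unit inf-norm rows condition the pivoting
  rs <- pmax(apply(abs(B), 1, max), 1e-12)
  B <- B / rs
  b <- b / rs
  n <- ncol(B)
  m <- nrow(B)

  # phase-1: minimize the sum of artificial variables over [B | I_art] x' = b
  # starting from the all-artificial basis. Entering: most negative reduced
  # cost (Dantzig), falling back to lowest index (Bland) when the objective
  # stalls at a degenerate vertex; artificials (cols > n) may never
  # re-enter. Leaving: minimum ratio, ties broken by largest pivot; pivots
  # below piv_tol are never accepted (tiny pivots destroy the tableau).
  # The tableau is refactorized from the basis every refac_every pivots,
  # which clears accumulated roundoff.
  Borig <- cbind(B, diag(m))
  cost <- c(rep(0, n), rep(1, m))
  rc <- n + m + 1L
  basis <- n + seq_len(m)
  Tab <- cbind(Borig, b)
  objrow <- c(-colSums(B), rep(0, m), -sum(b))   # (reduced costs | -value)
  refactor <- function() {
    qb <- qr(Borig[, basis, drop = FALSE])
    if (qb$rank < m) return(FALSE)
    Tab <<- solve(qb, cbind(Borig, b))
    cB <- cost[basis]
    objrow <<- c(cost[seq_len(n + m)] - as.numeric(cB %*% Tab[, seq_len(n + m)]),
                 -sum(cB * Tab[, rc]))
    TRUE
  }
  piv_tol <- 1e-7
  refac_every <- 30L
  max_iter <- 100L * (n + 2L * m) + 1000L
  stall <- 0L
  last_val <- -objrow[rc]
  for (it in seq_len(max_iter)) {
    red <- objrow[seq_len(n)]
    if (all(red > -tol)) break
    entering <- if (stall > 3L * m) which(red < -tol)[1] else which.min(red)
    col <- Tab[, entering]
    pos <- which(col > 1e-11)   # every positive row joins the ratio test
    if (!length(pos))
      return(list(status = "numerical_error", x = NULL,
                  message = "phase-1 pivot column unbounded"))
    ratios <- pmax(Tab[pos, rc], 0) / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol * max(1, abs(rmin))]
    leave <- cand[which.max(col[cand])]
    piv <- Tab[leave, entering]
    Tab[leave, ] <- Tab[leave, ] / piv
    other <- setdiff(seq_len(m), leave)
    Tab[other, ] <- Tab[other, ] - outer(Tab[other, entering], Tab[leave, ])
    objrow <- objrow - objrow[entering] * Tab[leave, ]
    basis[leave] <- entering
    # refactorize periodically, and at once after an ill-conditioned pivot
    if (piv < piv_tol || it %% refac_every == 0L) refactor()
    val <- -objrow[rc]
    stall <- if (val < last_val - tol) 0L else stall + 1L
    last_val <- val
    if (it == max_iter)
      return(list(status = "numerical_error", x = NULL,
                  message = "simplex iteration limit reached"))
  }
  refactor()
  phase1 <- -objrow[rc]
  if (phase1 > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible", x = NULL))
  # drive remaining basic artificials out via degenerate pivots, so the
  # final basic point is expressed in original columns
  for (i in which(basis > n)) {
    cand <- setdiff(which(abs(Tab[i, seq_len(n)]) > piv_tol), basis)
    if (!length(cand)) next
    entering <- cand[which.max(abs(Tab[i, cand]))]
    piv <- Tab[i, entering]
    Tab[i, ] <- Tab[i, ] / piv
    other <- setdiff(seq_len(m), i)
    Tab[other, ] <- Tab[other, ] - outer(Tab[other, entering], Tab[i, ])
    basis[i] <- entering
  }
  refactor()
  # feasibility repair: right at the feasibility boundary the terminal basis
  # can carry a slightly negative basic value. Pivot it out (dual-simplex
  # style; the zero objective keeps any basis "optimal"). A negative basic
  # row with no negative nonbasic coefficient is a dual certificate that the
  # program is infeasible.
  for (rep in seq_len(3L * m + 10L)) {
    refactor()                       # decide on exact values, not pivot drift
    xB <- Tab[, rc]
    i <- which.min(xB)
    if (xB[i] > -1e-9) break
    row <- Tab[i, seq_len(n)]
    cand <- setdiff(which(row < -piv_tol), basis)
    if (!length(cand))
      return(list(status = "infeasible", x = NULL))
    entering <- cand[which.min(row[cand])]
    piv <- Tab[i, entering]
    Tab[i, ] <- Tab[i, ] / piv
    other <- setdiff(seq_len(m), i)
    Tab[other, ] <- Tab[other, ] - outer(Tab[other, entering], Tab[i, ])
    basis[i] <- entering
    if (rep == 3L * m + 10L)
      return(list(status = "numerical_error", x = NULL,
                  message = "feasibility repair did not converge"))
  }
  if (min(Tab[, rc]) < -1e-8 || -objrow[rc] > 1e-7 * max(1, max(abs(b))))
    return(list(status = "numerical_error", x = NULL,
                message = "terminal basis not feasible"))
  # extract with iterative refinement against the terminal basis
  Bb <- Borig[, basis, drop = FALSE]
  qb <- qr(Bb)
  xB <- if (qb$rank == m) {
    xx <- qr.coef(qb, b)
    for (k in 1:2) xx <- xx + qr.coef(qb, b - as.numeric(Bb %*% xx))
    xx
  } else Tab[, rc]
  xfull <- numeric(n + m)
  xfull[basis] <- pmax(xB, 0)
  x <- xfull[seq_len(nv)] - xfull[nv + seq_len(nv)]
  # self-certification: a mildly violating point can only happen within the
  # numerical sliver at the feasibility boundary -- report infeasible there
  # rather than hand out an uncertified point
  mv <- max(lp_residuals(lp, x))
  if (mv > 1e-5)
    return(list(status = "numerical_error", x = NULL,
                message = sprintf("uncertified point (residual %.3g)", mv)))
  if (mv > 1e-8)
    return(list(status = "infeasible", x = NULL))
  list(status = "optimal", x = x)
}

# Default backend: quadprog for speed and a deterministic minimum-norm
# point, with every infeasibility verdict confirmed by the independent
# simplex (the active-set method can misreport degenerate-but-feasible
# programs as inconsistent; the bisection must never accept a false
# infeasible). A simplex override is only taken when its point actually
# satisfies the program tightly.
solve_auto <- function(lp) {
  res <- solve_quadprog(lp)
  if (res$status != "infeasible") return(res)
  chk <- solve_simplex(lp)
  if (chk$status == "optimal" && max(lp_residuals(lp, chk$x)) <= 1e-8)
    return(chk)
  res
}

.onLoad <- function(libname, pkgname) {
  register_solver("auto", solve_auto)
  register_solver("quadprog", solve_quadprog)
  register_solver("simplex", solve_simplex)
}
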