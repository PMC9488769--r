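# Dense two-phase simplex with Bland's anti-cycling rule.
#
# Flux balance problems are heavily degenerate (the steady-state right-hand
# side is identically zero), which is exactly the regime where naive tableau
# implementations stall or crash; Bland's rule guarantees finite termination
# and the basis is refactorized (solve()) at every iteration, which is cheap
# at the problem sizes handled here (tens of reactions).

# min cost'x  s.t.  A x = b, x >= 0, with b >= 0 on entry.
# Returns list(status, x, objective).
simplex_phase <- function(A, b, cost, basis, tol = 1e-9, maxit = 10000L) {
  m <- nrow(A); n <- ncol(A)
  for (it in seq_len(maxit)) {
    B <- A[, basis, drop = FALSE]
    xB <- tryCatch(solve(B, b), error = function(e) NULL)
    if (is.null(xB)) return(list(status = "singular"))
    y <- solve(t(B), cost[basis])
    reduced <- cost - as.vector(crossprod(A, y))
    reduced[basis] <- 0
    entering <- which(reduced < -tol)
    if (!length(entering))
      return(list(status = "optimal", basis = basis, x = {
        x <- numeric(n); x[basis] <- xB; x
      }, objective = sum(cost[basis] * xB)))
    j <- min(entering)                      # Bland: lowest index enters
    d <- solve(B, A[, j])
    pos <- which(d > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- xB[pos] / d[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    leave <- cand[which.min(basis[cand])]   # Bland: lowest index leaves
    basis[leave] <- j
  }
  list(status = "maxit")
}

# min cost'x s.t. A x = b, x >= 0 (general b); two phases.
simplex_solve <- function(A, b, cost, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  # phase 1: artificial basis
  A1 <- cbind(A, diag(m))
  c1 <- c(numeric(n), rep(1, m))
  ph1 <- simplex_phase(A1, b, c1, basis = n + seq_len(m), tol = tol)
  if (!identical(ph1$status, "optimal")) return(list(status = "numerical"))
  if (ph1$objective > 1e-7) return(list(status = "infeasible"))
  basis <- ph1$basis
  # drive remaining artificials out of the degenerate basis
  drop_rows <- integer(0)
  art <- which(basis > n)
  if (length(art)) {
    B <- A1[, basis, drop = FALSE]
    for (k in art) {
      row <- solve(B, A)[k, ]               # row k of B^-1 A
      piv <- which(abs(row) > tol & !(seq_len(n) %in% basis))
      if (length(piv)) {
        basis[k] <- min(piv)
        B <- A1[, basis, drop = FALSE]
      } else drop_rows <- c(drop_rows, k)   # redundant constraint
    }
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(m), drop_rows)
    A <- A[keep, , drop = FALSE]; b <- b[keep]
    basis <- basis[keep]
    if (any(basis > n)) return(list(status = "numerical"))
    m <- length(keep)
  }
  if (any(basis > n)) return(list(status = "numerical"))
  ph2 <- simplex_phase(A, b, cost, basis = basis, tol = tol)
  if (!identical(ph2$status, "optimal"))
    return(list(status = ph2$status))
  list(status = "optimal", x = ph2$x[seq_len(n)], objective = ph2$objective)
}

#' Solve a bounded linear program
#'
#' Linear-programming interface used by flux balance analysis and the
#' gap-filling branch and bound:
#' \deqn{\min / \max\; a^T z \quad \mathrm{s.t.}\; A_{le} z \le b_{le},\;
#'   A_{ge} z \ge b_{ge},\; A_{eq} z = b_{eq},\; l \le z \le u.}
#' Variables are shifted to the nonnegative orthant, inequalities receive
#' slack/surplus variables and finite upper bounds become explicit rows; the
#' standard-form problem is then solved by a two-phase dense simplex with
#' Bland's rule (finite termination on the degenerate steady-state systems
#' that flux analysis produces).
#'
#' @param objective numeric objective coefficients, length n.
#' @param A_le,b_le less-than-or-equal constraint block, or NULL.
#' @param A_ge,b_ge greater-than-or-equal block, or NULL.
#' @param A_eq,b_eq equality block, or NULL.
#' @param lower,upper finite variable bounds, recycled to length n.
#' @param maximize logical; maximize instead of minimize.
#' @param tol pivot / feasibility tolerance.
#'
#' @return list with `status` ("optimal", "infeasible", or a numerical
#'   failure code), `objective` and `solution` (length n, original scale).
#' @keywords internal
solve_lp <- function(objective, A_le = NULL, b_le = NULL, A_ge = NULL,
                     b_ge = NULL, A_eq = NULL, b_eq = NULL,
                     lower = 0, upper = Inf, maximize = FALSE, tol = 1e-9) {
  n <- length(objective)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("solve_lp requires finite variable bounds")
  if (any(lower > upper + 1e-12))
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))

  as_block <- function(A, b) {
    if (is.null(A)) return(list(A = matrix(0, 0, n), b = numeric(0)))
    list(A = matrix(A, ncol = n), b = as.numeric(b))
  }
  le <- as_block(A_le, b_le); ge <- as_block(A_ge, b_ge); eq <- as_block(A_eq, b_eq)

  # shift z = x + lower, x >= 0
  shift <- lower
  adj <- function(blk) { blk$b <- blk$b - as.vector(blk$A %*% shift); blk }
  le <- adj(le); ge <- adj(ge); eq <- adj(eq)
  span <- upper - lower
  bounded <- which(span < Inf & span >= 0)
  Aub <- matrix(0, length(bounded), n)
  Aub[cbind(seq_along(bounded), bounded)] <- 1
  le$A <- rbind(le$A, Aub)
  le$b <- c(le$b, span[bounded])

  m_le <- nrow(le$A); m_ge <- nrow(ge$A); m_eq <- nrow(eq$A)
  # standard form: [x, slack_le, surplus_ge] with equality rows
  A <- rbind(cbind(le$A, diag(1, m_le), matrix(0, m_le, m_ge)),
             cbind(ge$A, matrix(0, m_ge, m_le), diag(-1, m_ge)),
             cbind(eq$A, matrix(0, m_eq, m_le + m_ge)))
  b <- c(le$b, ge$b, eq$b)
  cost <- c(if (maximize) -objective else objective,
            numeric(m_le + m_ge))
  res <- simplex_solve(A, b, cost, tol = tol)
  if (!identical(res$status, "optimal"))
    return(list(status = if (identical(res$status, "infeasible"))
      "infeasible" else res$status,
      objective = NA_real_, solution = NULL))
  z <- res$x[seq_len(n)] + shift
  list(status = "optimal", objective = sum(objective * z), solution = z)
}
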