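# Internal LP solver.
#
# All flux-balance problems in this package are box-constrained LPs
#   optimize  obj' v   subject to  A v = rhs,  lb <= v <= ub,
# with every structural variable carrying finite bounds (models encode
# "unbounded" as the +/-1000 sentinel), so the problems are never unbounded
# and the only non-optimal outcome is infeasibility.
#
# They are solved with a dense two-phase primal simplex for bounded
# variables: phase 1 drives artificial variables out of the basis, phase 2
# optimizes the real objective. Pivoting is Dantzig's rule with a
# smallest-index tie-break, falling back to Bland's rule (which cannot
# cycle) when the iteration count grows large; the basis inverse is updated
# by elementary row operations and refactorized periodically. Deterministic
# throughout: the same problem always yields the same vertex.

lp_simplex <- function(obj, A, rhs, lb, ub, maximize = TRUE,
                       tol = 1e-9, dual_tol = 1e-7, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_simplex requires finite variable bounds")
  if (any(lb > ub + tol)) return(list(status = "infeasible"))
  if (is.null(max_iter)) max_iter <- max(2000L, 200L * (n + m))

  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # start: structural variables nonbasic at lower bound; artificials absorb
  # the residual
  x_struct <- lb
  r <- as.numeric(rhs - A %*% x_struct)
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  N <- n + m
  ext_l <- c(lb, rep(0, m))
  ext_u <- c(ub, rep(Inf, m))
  c1 <- c(rep(0, n), rep(1, m))    # phase-1 cost
  c2 <- c(cc, rep(0, m))           # phase-2 cost

  status <- c(rep(1L, n), rep(0L, m))  # 0 basic, 1 at lower, 2 at upper
  basis <- n + seq_len(m)
  xB <- abs(r)
  Binv <- diag(m)
  diag(Binv) <- sgn  # inverse of B = diag(sgn)

  nb_value <- function(j) if (status[j] == 1L) ext_l[j] else ext_u[j]

  run_phase <- function(cost, phase, iter_used) {
    it <- iter_used
    bland_from <- round(0.75 * max_iter)
    repeat {
      it <- it + 1L
      if (it > max_iter)
        return(list(ok = FALSE, why = "iteration limit", iter = it))
      cB <- cost[basis]
      y <- drop(crossprod(Binv, cB))          # duals: y' = cB' Binv
      nonbasic <- which(status != 0L)
      dj <- cost[nonbasic] - drop(y %*% Aext[, nonbasic, drop = FALSE])
      eff <- ifelse(status[nonbasic] == 1L, dj, -dj)
      elig <- which(eff < -dual_tol)
      if (!length(elig)) return(list(ok = TRUE, iter = it))
      enter <- if (it >= bland_from) nonbasic[elig[1L]]
               else nonbasic[elig[which.min(eff[elig])]]
      sigma <- if (status[enter] == 1L) 1 else -1
      d <- drop(Binv %*% Aext[, enter])

      # ratio test: how far can the entering variable move?
      t_best <- ext_u[enter] - ext_l[enter]   # bound flip distance
      leave_pos <- 0L; leave_to <- 0L         # 0 = bound flip
      step <- sigma * d
      for (i in seq_len(m)) {
        if (step[i] > tol) {
          cap <- (xB[i] - ext_l[basis[i]]) / step[i]
          if (cap < t_best - tol ||
              (cap < t_best + tol && leave_pos != 0L && basis[i] < basis[leave_pos])) {
            t_best <- cap; leave_pos <- i; leave_to <- 1L
          }
        } else if (step[i] < -tol) {
          ubi <- ext_u[basis[i]]
          if (is.finite(ubi)) {
            cap <- (ubi - xB[i]) / (-step[i])
            if (cap < t_best - tol ||
                (cap < t_best + tol && leave_pos != 0L && basis[i] < basis[leave_pos])) {
              t_best <- cap; leave_pos <- i; leave_to <- 2L
            }
          }
        }
      }
      if (!is.finite(t_best))
        return(list(ok = FALSE, why = "unbounded", iter = it))
      t_best <- max(t_best, 0)

      if (leave_pos == 0L) {
        # entering variable runs to its other bound; basis unchanged
        xB <<- xB - step * t_best
        status[enter] <<- if (status[enter] == 1L) 2L else 1L
        next
      }
      # pivot: entering becomes basic, basis[leave_pos] leaves to a bound
      leave <- basis[leave_pos]
      xB <<- xB - step * t_best
      x_enter <- nb_value(enter) + sigma * t_best
      status[leave] <<- leave_to
      status[enter] <<- 0L
      basis[leave_pos] <<- enter
      xB[leave_pos] <<- x_enter
      alpha <- d[leave_pos]
      if (abs(alpha) < tol || it %% 100L == 0L) {
        B <- Aext[, basis, drop = FALSE]
        Binv <<- tryCatch(solve(B), error = function(e) NULL)
        if (is.null(Binv)) return(list(ok = FALSE, why = "singular basis",
                                       iter = it))
      } else {
        erow <- Binv[leave_pos, ] / alpha
        Binv <<- Binv - outer(d, erow)
        Binv[leave_pos, ] <<- erow
      }
    }
  }

  p1 <- run_phase(c1, 1L, 0L)
  if (!p1$ok) return(list(status = "infeasible"))
  art_basic <- basis > n
  infeas <- sum(xB[art_basic])
  if (infeas > 1e-6) return(list(status = "infeasible"))
  # keep any degenerate basic artificials pinned at zero in phase 2
  ext_u[(n + 1L):N] <- 0
  ext_l[(n + 1L):N] <- 0
  p2 <- run_phase(c2, 2L, p1$iter)
  if (!p2$ok)
    stop("simplex failed in phase 2 (", p2$why, ") after ", p2$iter,
         " iterations")

  x <- numeric(N)
  nb <- which(status != 0L)
  x[nb] <- ifelse(status[nb] == 1L, ext_l[nb], ext_u[nb])
  x[basis] <- xB
  v <- x[seq_len(n)]
  v <- pmin(pmax(v, lb), ub)  # clip roundoff at the bounds
  names(v) <- names(obj)
  value <- sum(obj * v)
  list(status = "optimal", x = v, value = value, iterations = p2$iter)
}

solve_lp <- function(obj, A, rhs, lb, ub, maximize = TRUE) {
  res <- lp_simplex(obj, A, rhs, lb, ub, maximize = maximize)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, value = NA_real_))
  res
}
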