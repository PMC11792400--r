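#' Bounded-variable linear programming by two-phase primal simplex
#'
#' Solves `maximize c'x  subject to  A x = b,  lb <= x <= ub` with all
#' bounds finite. This is the LP core behind [solve_fba()]: flux balance
#' problems are equality-constrained box LPs, which are typically highly
#' degenerate, so the implementation recomputes the basic solution from a
#' fresh factorization at every iteration and switches from Dantzig to
#' Bland's pivoting rule if progress stalls, guaranteeing termination.
#'
#' Not exported; the FBA interface is the supported entry point.
#'
#' @param obj Objective coefficients (length n).
#' @param A Constraint matrix (m x n).
#' @param b Right-hand side (length m).
#' @param lb,ub Finite variable bounds.
#' @param maximize Maximize (default) or minimize.
#' @param tol Numerical tolerance for reduced costs and pivots.
#' @return List with `status` (`"optimal"` or `"infeasible"`), `x`, and
#'   `obj`.
#' @keywords internal
#' @noRd
simplex_box <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("simplex_box requires finite bounds", call. = FALSE)
  }
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), obj = NA_real_))
  }
  sense <- if (maximize) 1 else -1
  cost <- sense * obj

  ## augment with m artificial variables, one per row
  at_lb <- abs(lb) <= abs(ub)             # start structurals nearest zero
  xval <- ifelse(at_lb, lb, ub)
  resid <- b - as.vector(A %*% xval)
  art_sign <- ifelse(resid >= 0, 1, -1)
  Aa <- cbind(A, diag(art_sign, nrow = m))
  ntot <- n + m
  lb_a <- c(lb, rep(0, m))
  ub_a <- c(ub, rep(Inf, m))
  xval <- c(xval, abs(resid))
  at_lb <- c(at_lb, rep(TRUE, m))         # unused for basics
  basis <- (n + 1L):ntot
  in_basis <- rep(FALSE, ntot)
  in_basis[basis] <- TRUE

  run_phase <- function(cost_a, basis, in_basis, xval, ub_a) {
    max_iter <- 200L * (ntot + m) + 200L
    bland_after <- 10L * (ntot + m) + 50L
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit", call. = FALSE)
      B <- Aa[, basis, drop = FALSE]
      ## basic values from current nonbasic assignment
      nb <- which(!in_basis)
      rhs <- b - as.vector(Aa[, nb, drop = FALSE] %*% xval[nb])
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB)) stop("singular simplex basis", call. = FALSE)
      xval[basis] <- xB
      y <- solve(t(B), cost_a[basis])
      d <- cost_a - as.vector(crossprod(Aa, y))
      ## eligible entering variables
      up <- !in_basis & at_lb & d > tol        # can increase
      dn <- !in_basis & !at_lb & d < -tol      # can decrease
      if (!any(up) && !any(dn)) {
        return(list(basis = basis, in_basis = in_basis, xval = xval,
                    obj = sum(cost_a * xval)))
      }
      cand <- which(up | dn)
      e <- if (iter > bland_after) cand[1L] else cand[which.max(abs(d[cand]))]
      dir <- if (at_lb[e]) 1 else -1           # movement direction of x_e
      w <- solve(B, Aa[, e]) * dir             # xB changes by -w * t
      ## ratio test
      t_bound <- ub_a[e] - lb_a[e]             # flip to opposite bound
      t_min <- t_bound
      leave <- 0L
      leave_to_lb <- TRUE
      for (i in seq_len(m)) {
        wi <- w[i]
        if (wi > tol) {
          ti <- (xval[basis[i]] - lb_a[basis[i]]) / wi
          if (ti < t_min - 1e-12) { t_min <- ti; leave <- i; leave_to_lb <- TRUE }
        } else if (wi < -tol) {
          ti <- (ub_a[basis[i]] - xval[basis[i]]) / (-wi)
          if (ti < t_min - 1e-12) { t_min <- ti; leave <- i; leave_to_lb <- FALSE }
        }
      }
      if (!is.finite(t_min)) stop("unbounded linear program", call. = FALSE)
      t_min <- max(t_min, 0)
      xval[e] <- xval[e] + dir * t_min
      xval[basis] <- xval[basis] - w * t_min
      if (leave == 0L) {                       # bound flip, basis unchanged
        at_lb[e] <<- !at_lb[e]
      } else {
        lv <- basis[leave]
        xval[lv] <- if (leave_to_lb) lb_a[lv] else ub_a[lv]
        at_lb[lv] <<- leave_to_lb
        in_basis[lv] <- FALSE
        in_basis[e] <- TRUE
        basis[leave] <- e
      }
    }
  }

  ## phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(cost1, basis, in_basis, xval, ub_a)
  if (ph1$obj < -1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), obj = NA_real_))
  }
  ## phase 2: original objective, artificials pinned at zero
  ub_a[(n + 1L):ntot] <- 0
  xv <- ph1$xval
  xv[(n + 1L):ntot][!ph1$in_basis[(n + 1L):ntot]] <- 0
  ph2 <- run_phase(c(cost, rep(0, m)), ph1$basis, ph1$in_basis, xv, ub_a)
  x <- ph2$xval[seq_len(n)]
  ## clamp solver noise back into the box
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", x = x, obj = sense * sum(cost * x))
}
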