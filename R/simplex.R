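# Bounded-variable primal simplex, dense, two-phase.
#
# Solves   max/min  c'v   s.t.  A v = b,  l <= v <= u
# which is the whole LP family this package needs (steady-state mass
# balance plus box bounds; extra constraints enter as bound changes).
#
# Phase 1 uses one artificial variable per row with a unit-infeasibility
# objective; phase 2 re-prices the true objective with artificials pinned
# at zero. Entering variable: Dantzig rule with a Bland fallback once the
# iteration count passes n+m (degeneracy guard). All arithmetic is dense
# double precision; intended for models up to a few hundred reactions --
# genome-scale work goes through the HiGHS backend.

simplex_solve <- function(A, b, c, lower, upper, sense = c("max", "min"),
                          tol = 1e-9, max_iter = NULL) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (length(b) != m || length(c) != n) stop("simplex: dimension mismatch")
  if (any(lower > upper + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  obj_sign <- if (sense == "max") 1 else -1
  cc <- obj_sign * c

  # augment with artificials: bounds [0, Inf), sign chosen so the initial
  # basic values are nonnegative
  nt <- n + m
  lo <- c(lower, rep(0, m))
  up <- c(upper, rep(Inf, m))
  Afull <- cbind(A, diag(1, m))

  # nonbasic start: every structural variable at the finite bound closer to
  # zero (free variables pinned at 0 conceptually need a finite bound; all
  # models here have finite bounds, but guard anyway)
  at_upper <- logical(nt)
  xN <- numeric(n)
  for (j in seq_len(n)) {
    lj <- lower[j]; uj <- upper[j]
    if (is.finite(lj) && is.finite(uj)) {
      if (abs(uj) < abs(lj)) { xN[j] <- uj; at_upper[j] <- TRUE } else xN[j] <- lj
    } else if (is.finite(lj)) xN[j] <- lj
    else if (is.finite(uj)) { xN[j] <- uj; at_upper[j] <- TRUE }
    else xN[j] <- 0
  }
  resid <- b - A %*% xN
  sg <- ifelse(resid >= 0, 1, -1)
  Afull[, n + seq_len(m)] <- diag(as.numeric(sg), m)

  basis <- n + seq_len(m)
  x <- c(xN, abs(as.numeric(resid)))

  run_phase <- function(cost, x, basis, at_upper, allow_enter, max_iter) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(status = "iteration_limit", x = x,
                                       basis = basis, at_upper = at_upper))
      B <- Afull[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular", x = x, basis = basis,
                                  at_upper = at_upper))
      d <- cost - as.numeric(crossprod(Afull, y))   # reduced costs
      nonbasic <- setdiff(seq_len(nt), basis)
      nonbasic <- nonbasic[allow_enter[nonbasic]]
      # improving: at lower bound and d>0, or at upper bound and d<0
      improve_lo <- nonbasic[!at_upper[nonbasic] & d[nonbasic] > tol]
      improve_up <- nonbasic[at_upper[nonbasic] & d[nonbasic] < -tol]
      cand <- c(improve_lo, improve_up)
      if (length(cand) == 0L) {
        return(list(status = "optimal", x = x, basis = basis,
                    at_upper = at_upper))
      }
      if (iter <= 3L * nt) {
        jin <- cand[which.max(abs(d[cand]))]       # Dantzig
      } else {
        jin <- min(cand)                           # Bland (anti-cycling)
      }
      dirsign <- if (at_upper[jin]) -1 else 1      # movement direction of x[jin]
      w <- as.numeric(solve(B, Afull[, jin]))      # basic response: xB -= w*t*dirsign
      # ratio test over basic variables plus the entering variable's own span
      tmax <- if (is.finite(up[jin]) && is.finite(lo[jin])) up[jin] - lo[jin] else Inf
      leave <- 0L; leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        wi <- w[i] * dirsign
        bi <- basis[i]
        t_i <- NA_real_; to_up <- FALSE
        if (wi > tol && is.finite(lo[bi])) {
          t_i <- (x[bi] - lo[bi]) / wi          # decreases toward lower bound
        } else if (wi < -tol && is.finite(up[bi])) {
          t_i <- (up[bi] - x[bi]) / (-wi)       # increases toward upper bound
          to_up <- TRUE
        }
        if (is.na(t_i)) next
        if (t_i < 0) t_i <- 0
        # strict improvement, or a tie when the current blocker is only the
        # entering variable's own span (prefer a genuine basis exchange)
        if (t_i < tmax - tol * max(1, abs(t_i)) ||
            (leave == 0L && t_i <= tmax + tol)) {
          tmax <- min(tmax, t_i); leave <- i; leave_to_upper <- to_up
        }
      }
      if (!is.finite(tmax)) {
        return(list(status = "unbounded", x = x, basis = basis,
                    at_upper = at_upper))
      }
      tmax <- max(tmax, 0)
      # update values
      x[jin] <- x[jin] + dirsign * tmax
      x[basis] <- x[basis] - w * dirsign * tmax
      if (leave == 0L) {
        at_upper[jin] <- !at_upper[jin]            # bound flip, basis unchanged
      } else {
        bi <- basis[leave]
        at_upper[bi] <- leave_to_upper
        x[bi] <- if (leave_to_upper) up[bi] else lo[bi]  # snap exactly
        basis[leave] <- jin
      }
    }
  }

  if (is.null(max_iter)) max_iter <- 50L * (nt + m) + 200L

  # phase 1: minimize sum of artificials (as a maximization of the negative)
  cost1 <- c(rep(0, n), rep(-1, m))
  allow <- rep(TRUE, nt)
  ph1 <- run_phase(cost1, x, basis, at_upper, allow, max_iter)
  if (ph1$status %in% c("singular", "iteration_limit")) {
    return(list(status = "error", objective = NA_real_, x = NULL,
                detail = ph1$status))
  }
  infeas <- sum(ph1$x[n + seq_len(m)])
  if (infeas > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  # pin artificials at zero and forbid re-entry
  up[n + seq_len(m)] <- 0
  ph1$x[n + seq_len(m)] <- pmax(0, pmin(ph1$x[n + seq_len(m)], 0))
  allow[n + seq_len(m)] <- FALSE

  cost2 <- c(cc, rep(0, m))
  ph2 <- run_phase(cost2, ph1$x, ph1$basis, ph1$at_upper, allow, max_iter)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  if (ph2$status %in% c("singular", "iteration_limit")) {
    return(list(status = "error", objective = NA_real_, x = NULL,
                detail = ph2$status))
  }
  v <- ph2$x[seq_len(n)]
  list(status = "optimal", objective = obj_sign * sum(cc * v), x = v)
}
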