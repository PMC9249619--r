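# Brute-force LP oracle: exhaustive basic-feasible-solution enumeration in
# exact rational arithmetic. Independent of both LP backends -- used to
# pin down expected optima on toy models.
#
# Rationals are (num, den) pairs of integer-valued doubles, reduced by gcd
# after every operation, with an overflow guard at 2^52. Vectors of
# rationals are stored as list(n = numeric, d = numeric).

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b != 0, a %% b, 0)
    a <- t
  }
  ifelse(a == 0, 1, a)
}

rat_norm <- function(n, d) {
  if (any(d == 0)) stop("rational with zero denominator")
  s <- ifelse(d < 0, -1, 1)
  n <- n * s; d <- d * s
  g <- rat_gcd(n, d)
  n <- n / g; d <- d / g
  if (any(abs(n) > 2^52) || any(abs(d) > 2^52)) {
    stop("rational overflow in oracle arithmetic")
  }
  list(n = n, d = d)
}

rat_add <- function(x, y) rat_norm(x$n * y$d + y$n * x$d, x$d * y$d)
rat_sub <- function(x, y) rat_norm(x$n * y$d - y$n * x$d, x$d * y$d)
rat_mul <- function(x, y) rat_norm(x$n * y$n, x$d * y$d)
rat_div <- function(x, y) {
  if (any(y$n == 0)) stop("rational division by zero")
  rat_norm(x$n * y$d, x$d * y$n)
}
rat_neg <- function(x) list(n = -x$n, d = x$d)
rat_cmp <- function(x, y) sign(x$n * y$d - y$n * x$d)  # -1, 0, 1
rat_num <- function(x) x$n / x$d
rat_slice <- function(x, i) list(n = x$n[i], d = x$d[i])

# decimal -> exact rational (denominators up to 10^6; model coefficients
# are constructed small rationals, so this is exact, not an approximation)
rat_from_num <- function(v) {
  n <- numeric(length(v)); d <- numeric(length(v))
  for (i in seq_along(v)) {
    found <- FALSE
    for (den in c(1, 2, 3, 4, 5, 6, 8, 10, 20, 100, 1000, 10^4, 10^5, 10^6)) {
      if (abs(v[i] * den - round(v[i] * den)) < 1e-9) {
        n[i] <- round(v[i] * den); d[i] <- den; found <- TRUE; break
      }
    }
    if (!found) stop("coefficient ", v[i], " is not a small rational; ",
                     "the exact oracle cannot represent it")
  }
  rat_norm(n, d)
}

# Gauss-Jordan elimination on an augmented rational matrix
# [M | rhs-block], returning the solved block or NULL when singular.
# Used both for single solves (rhs = one column) and inversion (rhs = I).
rat_solve_block <- function(M, rhs_cols) {
  r <- length(M)          # list of rows; each row a rational vector
  nc <- length(M[[1]]$n)
  nb <- length(rhs_cols[[1]]$n)
  aug <- lapply(seq_len(r), function(i) {
    list(n = c(M[[i]]$n, rhs_cols[[i]]$n), d = c(M[[i]]$d, rhs_cols[[i]]$d))
  })
  for (col in seq_len(nc)) {
    piv <- NULL
    for (row in col:r) if (aug[[row]]$n[col] != 0) { piv <- row; break }
    if (is.null(piv)) return(NULL)                 # singular
    tmp <- aug[[col]]; aug[[col]] <- aug[[piv]]; aug[[piv]] <- tmp
    prow <- aug[[col]]
    pval <- rat_slice(prow, col)
    for (row in seq_len(r)) {
      if (row == col) next
      f <- rat_slice(aug[[row]], col)
      if (f$n == 0) next
      factor <- rat_div(f, pval)
      scaled <- rat_mul(prow, list(n = rep(factor$n, nc + nb),
                                   d = rep(factor$d, nc + nb)))
      aug[[row]] <- rat_sub(aug[[row]], scaled)
    }
  }
  lapply(seq_len(r), function(i) {
    pv <- rat_slice(aug[[i]], i)
    rat_div(rat_slice(aug[[i]], nc + seq_len(nb)),
            list(n = rep(pv$n, nb), d = rep(pv$d, nb)))
  })
}

rat_solve <- function(M, rhs) {
  r <- length(M)
  res <- rat_solve_block(M, lapply(seq_len(r), function(i) {
    list(n = rhs$n[i], d = rhs$d[i])
  }))
  if (is.null(res)) return(NULL)
  list(n = vapply(res, function(x) x$n, numeric(1)),
       d = vapply(res, function(x) x$d, numeric(1)))
}

# rational row-reduction to find a maximal independent row subset of S
rat_independent_rows <- function(rows) {
  r <- length(rows)
  if (r == 0L) return(integer())
  nc <- length(rows[[1]]$n)
  work <- rows
  pivots <- integer()
  used_cols <- logical(nc)
  keep <- integer()
  for (i in seq_len(r)) {
    row <- work[[i]]
    # eliminate previously kept pivots
    for (k in seq_along(keep)) {
      pc <- pivots[k]
      if (row$n[pc] == 0) next
      f <- rat_div(rat_slice(row, pc), rat_slice(work[[keep[k]]], pc))
      scaled <- rat_mul(work[[keep[k]]],
                        list(n = rep(f$n, nc), d = rep(f$d, nc)))
      row <- rat_sub(row, scaled)
    }
    nz <- which(row$n != 0 & !used_cols)
    if (length(nz) > 0L) {
      keep <- c(keep, i)
      pivots <- c(pivots, nz[1])
      used_cols[nz[1]] <- TRUE
      work[[i]] <- row
    }
  }
  keep
}

#' Exact brute-force LP oracle for small models
#'
#' Computes the optimum of `max/min c'v` under `S v = 0` and bounds by
#' enumerating every basic feasible solution (vertex) in exact rational
#' arithmetic: choose `n - rank(S)` variables nonbasic at a finite bound,
#' solve the remaining square rational system, keep solutions inside the
#' bounds. Entirely independent of the floating-point LP backends; guarded
#' to models with at most `max_reactions` reactions.
#'
#' @param model a `cbm_model` with all bounds finite.
#' @param objective_id reaction flux to optimize.
#' @param direction `"max"` or `"min"`.
#' @param extra_constraints optional data.frame (`reaction_id`, `lower`,
#'   `upper`), intersected with model bounds.
#' @param max_reactions enumeration size guard (default 12).
#' @return list with `status` (`optimal` / `infeasible`), `objective`
#'   (exact value as numeric), and `vertex_count`.
#' @export
brute_force_oracle <- function(model, objective_id = model$objective_id,
                               direction = c("max", "min"),
                               extra_constraints = NULL, max_reactions = 12L) {
  direction <- match.arg(direction)
  n <- length(model$reactions)
  if (n > max_reactions) {
    stop("oracle guard: model has ", n, " reactions (> ", max_reactions, ")")
  }
  pr <- lp_problem(model)
  lb <- pr$lb; ub <- pr$ub
  ov <- constraints_to_overrides(pr, extra_constraints)
  lb[ov$lb_idx] <- ov$lb_val; ub[ov$ub_idx] <- ov$ub_val
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("oracle requires finite bounds on every reaction")
  }
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_, vertex_count = 0L))
  }
  S <- as.matrix(pr$S)
  rows <- lapply(seq_len(nrow(S)), function(i) rat_from_num(S[i, ]))
  keep <- rat_independent_rows(rows)
  rows <- rows[keep]
  r <- length(rows)
  lbr <- rat_from_num(lb); ubr <- rat_from_num(ub)
  cj <- match(objective_id, pr$rxn_ids)
  if (is.na(cj)) stop("unknown objective '", objective_id, "'")

  nfree <- n - r
  best <- NULL
  count <- 0L
  eval_vertex <- function(v) {
    val <- rat_slice(v, cj)
    if (is.null(best)) { best <<- val; return() }
    cmp <- rat_cmp(val, best)
    if ((direction == "max" && cmp > 0) || (direction == "min" && cmp < 0)) {
      best <<- val
    }
  }
  check_and_eval <- function(vfull) {
    for (i in seq_len(n)) {
      vi <- rat_slice(vfull, i)
      if (rat_cmp(vi, rat_slice(lbr, i)) < 0) return()
      if (rat_cmp(vi, rat_slice(ubr, i)) > 0) return()
    }
    count <<- count + 1L
    eval_vertex(vfull)
  }

  if (nfree == 0L) {
    # square system: at most one steady-state solution
    rhs <- list(n = rep(0, r), d = rep(1, r))
    M <- lapply(rows, function(rw) rw)
    x <- rat_solve(M, rhs)
    if (!is.null(x)) check_and_eval(x)
  } else {
    combs <- utils::combn(n, nfree, simplify = FALSE)
    sides <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nfree)))
    for (fix_idx in combs) {
      basic <- setdiff(seq_len(n), fix_idx)
      M <- lapply(rows, function(rw) rat_slice(rw, basic))
      # W = M^-1 (-S_F): basic response to each fixed variable, computed
      # once per column choice; every bound-side pattern is then a cheap
      # rational combination x_B = W x_F.
      negSF <- lapply(rows, function(rw) {
        s <- rat_slice(rw, fix_idx)
        list(n = -s$n, d = s$d)
      })
      W <- rat_solve_block(M, negSF)
      if (is.null(W)) next                         # singular basis
      # numeric shadow of W for a fast prefilter: side patterns whose
      # numeric vertex violates a bound by more than 1e-6 are skipped
      # before any exact arithmetic (the exact check below remains the
      # arbiter for everything near-feasible)
      W_num <- do.call(rbind, lapply(W, function(w) w$n / w$d))
      lb_num <- lbr$n / lbr$d; ub_num <- ubr$n / ubr$d
      for (si in seq_len(nrow(sides))) {
        at_up <- sides[si, ]
        xF_num <- ifelse(at_up, ub_num[fix_idx], lb_num[fix_idx])
        xB_num <- as.numeric(W_num %*% xF_num)
        if (any(xB_num < lb_num[basic] - 1e-6) ||
            any(xB_num > ub_num[basic] + 1e-6)) next
        # skip duplicate enumeration when lb == ub for a fixed variable
        if (any(at_up & lbr$n[fix_idx] * ubr$d[fix_idx] ==
                          ubr$n[fix_idx] * lbr$d[fix_idx])) next
        fixed <- list(n = ifelse(at_up, ubr$n[fix_idx], lbr$n[fix_idx]),
                      d = ifelse(at_up, ubr$d[fix_idx], lbr$d[fix_idx]))
        xB <- list(n = numeric(r), d = rep(1, r))
        for (i in seq_len(r)) {
          acc <- list(n = 0, d = 1)
          Wi <- W[[i]]
          for (k in seq_len(nfree)) {
            if (Wi$n[k] == 0) next
            acc <- rat_add(acc, rat_mul(rat_slice(Wi, k), rat_slice(fixed, k)))
          }
          xB$n[i] <- acc$n; xB$d[i] <- acc$d
        }
        vfull <- list(n = numeric(n), d = rep(1, n))
        vfull$n[fix_idx] <- fixed$n; vfull$d[fix_idx] <- fixed$d
        vfull$n[basic] <- xB$n; vfull$d[basic] <- xB$d
        check_and_eval(vfull)
      }
    }
  }
  if (is.null(best)) {
    return(list(status = "infeasible", objective = NA_real_,
                vertex_count = 0L))
  }
  list(status = "optimal", objective = rat_num(best), vertex_count = count)
}
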