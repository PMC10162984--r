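#' Mass-action steady state of an elementary mechanism
#'
#' Solves the linear steady-state balance of the enzyme-state distribution for
#' a given assignment of normalized elementary rate constants (the linear
#' solve equivalent of the King-Altman pattern method).  One balance row is
#' replaced by the total-enzyme conservation sum(e) = 1.
#'
#' @param mech an `enz_mechanism`.
#' @param rates data.frame with columns `index`, `k_f`, `k_b` (normalized,
#'   nonnegative).
#' @param point an `enz_point` supplying the dimensionless concentrations.
#' @return list with `e` (named state fractions), `v_net`, and `v_steps`
#'   (data.frame `index`, `v_f`, `v_b`, `v_net`, `gamma`).
#' @export
steady_state <- function(mech, rates, point) {
  st <- mech$steps
  rates <- rates[order(rates$index), , drop = FALSE]
  if (!all(rates$index == st$index)) stop("rates must cover every step index")
  if (any(rates$k_f < 0 | rates$k_b < 0)) stop("rate constants must be nonnegative")
  cc <- step_concentrations(mech, point)
  n <- mech$n_states
  A <- matrix(0, n, n, dimnames = list(mech$states, mech$states))
  for (i in seq_len(nrow(st))) {
    u <- st$from[i]; v <- st$to[i]
    kf <- rates$k_f[i] * cc$c_f[i]
    kb <- rates$k_b[i] * cc$c_b[i]
    A[v, u] <- A[v, u] + kf
    A[u, u] <- A[u, u] - kf
    A[u, v] <- A[u, v] + kb
    A[v, v] <- A[v, v] - kb
  }
  # absorbing-state guard: a state that can be entered but never left drains
  # the whole enzyme pool and leaves the distribution degenerate
  outflow <- vapply(mech$states, function(s) {
    any(st$from == s & rates$k_f > 0) || any(st$to == s & rates$k_b > 0)
  }, logical(1))
  if (any(!outflow)) {
    stop("singular steady-state system: absorbing state ",
         paste(mech$states[!outflow], collapse = ", "))
  }
  M <- rbind(A[-n, , drop = FALSE], rep(1, n))
  b <- c(rep(0, n - 1L), 1)
  qr_M <- qr(M)
  if (qr_M$rank < n) stop("singular steady-state system")
  e <- drop(solve(qr_M, b))
  names(e) <- mech$states
  v_f <- rates$k_f * cc$c_f * e[st$from]
  v_b <- rates$k_b * cc$c_b * e[st$to]
  v_steps <- data.frame(index = st$index, v_f = unname(v_f), v_b = unname(v_b),
                        v_net = unname(v_f - v_b),
                        gamma = unname(ifelse(v_f > 0, v_b / v_f, NA_real_)))
  v_net <- if (length(mech$unbranched_steps)) {
    v_steps$v_net[match(mech$unbranched_steps[1L], v_steps$index)]
  } else {
    sum(v_steps$v_net[match(mech$branch_combinations[[1L]], v_steps$index)])
  }
  list(e = e, v_net = v_net, v_steps = v_steps)
}

# Capped reciprocal helpers: a displacement of exactly 1 pins the step's net
# flux to zero, which the optimizers represent with an effectively infinite
# enzyme requirement.  Displacements are clamped to [0, 1] first: floating
# point can overshoot 1 by an ulp, which would flip the coefficient's sign
# and silently drop the requirement.
BIGC <- 1e300

req_coef_forward <- function(gamma, c_f) {
  g <- pmin(pmax(gamma, 0), 1)
  pmin(1 / (c_f * (1 - g)), BIGC)
}
req_coef_backward <- function(gamma, c_b) {
  g <- pmin(pmax(gamma, 0), 1)
  pmin(g / (c_b * (1 - g)), BIGC)
}

# Per-state enzyme requirements per unit step flux: for each state, the terms
# from steps leaving it forward (z_f <= e) and entering it backward
# (z_b <= e).  Returns a list by state: data.frame(step, coef-vector-matrix)
state_requirements <- function(mech, point, gamma_mat) {
  st <- mech$steps
  cc <- step_concentrations(mech, point)
  lapply(mech$states, function(s) {
    terms <- list()
    for (i in which(st$from == s)) {
      terms[[length(terms) + 1L]] <-
        list(step = st$index[i], coef = req_coef_forward(gamma_mat[, i], cc$c_f[i]))
    }
    for (i in which(st$to == s)) {
      terms[[length(terms) + 1L]] <-
        list(step = st$index[i], coef = req_coef_backward(gamma_mat[, i], cc$c_b[i]))
    }
    terms
  })
}

# Step membership for two-route mechanisms: "up" = branch containing the
# lowest-numbered branch step (species A association in the built-ins),
# "low" = the other branch, "trunk" = steps on every route.
two_route_classes <- function(mech) {
  if (length(mech$routes) != 2L) stop("mechanism does not have exactly two routes")
  trunk <- mech$unbranched_steps
  seg <- lapply(mech$routes, function(r) setdiff(r, trunk))
  up_first <- which.min(vapply(seg, min, numeric(1)))
  list(trunk = trunk, up = seg[[up_first]], low = seg[[-up_first + 3L]])
}

# Inner maximization for unbranched mechanisms, vectorized over rows of
# gamma_mat (combos x steps): v = 1 / sum_n a_n with a_n the largest
# requirement among the step half-reactions adjacent to state n.
inner_value_unbranched_vec <- function(mech, point, gamma_mat) {
  reqs <- state_requirements(mech, point, gamma_mat)
  a <- vapply(reqs, function(terms) {
    out <- rep(0, nrow(gamma_mat))
    for (tm in terms) out <- pmax(out, tm$coef)
    out
  }, numeric(nrow(gamma_mat)))
  a <- matrix(a, nrow = nrow(gamma_mat))
  1 / rowSums(a)
}

# Inner maximization for two-route mechanisms, vectorized over combos.
# With beta the fraction of net flux through the upper branch, the total
# enzyme requirement T(beta) = sum_n max(cu_n beta, cl_n (1 - beta), cm_n)
# is piecewise-linear convex; it is minimized exactly over its breakpoints.
# Returns value v = 1/min T plus the argmin interval of beta.
inner_value_two_route_vec <- function(mech, point, gamma_mat) {
  cls <- two_route_classes(mech)
  reqs <- state_requirements(mech, point, gamma_mat)
  nr <- nrow(gamma_mat)
  zero <- rep(0, nr)
  cu <- cl <- cm <- vector("list", length(mech$states))
  for (k in seq_along(reqs)) {
    u <- l <- m <- zero
    for (tm in reqs[[k]]) {
      if (tm$step %in% cls$up) u <- pmax(u, tm$coef)
      else if (tm$step %in% cls$low) l <- pmax(l, tm$coef)
      else m <- pmax(m, tm$coef)
    }
    cu[[k]] <- u; cl[[k]] <- l; cm[[k]] <- m
  }
  # candidate breakpoints: endpoints plus pairwise intersections per state
  cands <- list(zero, zero + 1)
  for (k in seq_along(reqs)) {
    u <- cu[[k]]; l <- cl[[k]]; m <- cm[[k]]
    cands[[length(cands) + 1L]] <- ifelse(u + l > 0, l / (u + l), NA_real_)
    cands[[length(cands) + 1L]] <- ifelse(u > 0, pmin(m / u, 1), NA_real_)
    cands[[length(cands) + 1L]] <- ifelse(l > 0, pmax(1 - m / l, 0), NA_real_)
  }
  Tof <- function(beta) {
    tot <- zero
    for (k in seq_along(reqs)) {
      tot <- tot + pmax(cu[[k]] * beta, cl[[k]] * (1 - beta), cm[[k]])
    }
    tot
  }
  Tvals <- vapply(cands, function(b) {
    b <- pmin(pmax(b, 0), 1)
    v <- Tof(ifelse(is.na(b), 0, b))
    ifelse(is.na(b), Inf, v)
  }, numeric(nr))
  Tvals <- matrix(Tvals, nrow = nr)
  Tmin <- do.call(pmin, as.data.frame(Tvals))
  # argmin interval: candidates whose T matches the minimum to relative 1e-9
  tol <- 1e-9 * pmax(Tmin, 1)
  blo <- rep(1, nr); bhi <- rep(0, nr)
  for (j in seq_along(cands)) {
    b <- pmin(pmax(ifelse(is.na(cands[[j]]), NA_real_, cands[[j]]), 0), 1)
    at_min <- !is.na(b) & (Tvals[, j] <= Tmin + tol)
    blo <- ifelse(at_min, pmin(blo, b), blo)
    bhi <- ifelse(at_min, pmax(bhi, b), bhi)
  }
  list(value = 1 / Tmin, beta_lo = blo, beta_hi = bhi,
       beta = (blo + bhi) / 2, Tmin = Tmin)
}

#' Maximum net flux at fixed elementary displacements
#'
#' The inner subproblem of the optimization: with every elementary
#' displacement pinned, the largest net steady-state flux compatible with the
#' rate-constant limits and total-enzyme conservation.  For unbranched
#' mechanisms this is the closed form 1 / sum of per-state enzyme
#' requirements; for two-route mechanisms the branch split is optimized
#' exactly over the breakpoints of the piecewise-linear enzyme requirement;
#' any other branched mechanism is solved as a small LP
#' (`method = "simplex"` forces the LP path for cross-checking).
#'
#' @param mech an `enz_mechanism`.
#' @param point an `enz_point`.
#' @param gamma numeric vector of per-step displacements (by step index).
#' @param method "auto" or "simplex".
#' @param details if TRUE also return the enzyme distribution, per-step
#'   fluxes and (branched) the optimal branch-split interval.
#' @return the maximal net flux, or a list when `details = TRUE`.
#' @export
inner_lp_value <- function(mech, point, gamma, method = c("auto", "simplex"),
                           details = FALSE) {
  method <- match.arg(method)
  if (any(gamma > 1 + 1e-12)) {
    stop("elementary displacements must not exceed 1 in the forward convention")
  }
  gm <- matrix(gamma, nrow = 1)
  if (method == "simplex") return(inner_lp_simplex(mech, point, gamma, details))
  if (length(mech$routes) <= 1L) {
    val <- inner_value_unbranched_vec(mech, point, gm)
    if (!details) return(val)
    reqs <- state_requirements(mech, point, gm)
    a <- vapply(reqs, function(terms) max(0, vapply(terms, function(tm) tm$coef, numeric(1))),
                numeric(1))
    e <- a * val
    names(e) <- mech$states
    v_i <- rep(val, mech$n_e)
    return(list(value = val, e = e, v_i = v_i, beta = NA_real_,
                beta_lo = NA_real_, beta_hi = NA_real_))
  }
  if (length(mech$routes) == 2L) {
    res <- inner_value_two_route_vec(mech, point, gm)
    if (!details) return(res$value)
    cls <- two_route_classes(mech)
    beta <- res$beta
    v <- res$value
    v_i <- numeric(mech$n_e)
    v_i[mech$steps$index %in% cls$up] <- beta * v
    v_i[mech$steps$index %in% cls$low] <- (1 - beta) * v
    v_i[mech$steps$index %in% cls$trunk] <- v
    e <- inner_e_from_fluxes(mech, point, gamma, v_i)
    # distribute any conservation slack onto the free state
    e[mech$free_state] <- e[mech$free_state] + max(0, 1 - sum(e))
    return(list(value = v, e = e, v_i = v_i, beta = beta,
                beta_lo = res$beta_lo, beta_hi = res$beta_hi))
  }
  inner_lp_simplex(mech, point, gamma, details)
}

# enzyme distribution implied by per-step fluxes at fixed displacements
inner_e_from_fluxes <- function(mech, point, gamma, v_i) {
  reqs <- state_requirements(mech, point, matrix(gamma, nrow = 1))
  e <- vapply(seq_along(mech$states), function(k) {
    val <- 0
    for (tm in reqs[[k]]) {
      val <- max(val, tm$coef * v_i[match(tm$step, mech$steps$index)])
    }
    val
  }, numeric(1))
  names(e) <- mech$states
  e
}

# Generic LP route (boot::simplex) in the variables (v_net, v_i, e_n); the
# change-of-variables z's are eliminated against their defining equalities.
inner_lp_simplex <- function(mech, point, gamma, details = FALSE) {
  st <- mech$steps
  nv <- 1L + mech$n_e + mech$n_states
  iv <- function(i) 1L + match(i, st$index)     # v_i columns
  ie <- function(s) 1L + mech$n_e + match(s, mech$states)
  reqs <- state_requirements(mech, point, matrix(gamma, nrow = 1))
  A1 <- NULL; b1 <- NULL  # <=
  for (k in seq_along(mech$states)) {
    for (tm in reqs[[k]]) {
      row <- numeric(nv)
      row[iv(tm$step)] <- tm$coef
      row[ie(mech$states[k])] <- -1
      A1 <- rbind(A1, row); b1 <- c(b1, 0)
    }
  }
  A3 <- NULL; b3 <- NULL  # ==
  for (j in mech$unbranched_steps) {
    row <- numeric(nv); row[1L] <- -1; row[iv(j)] <- 1
    A3 <- rbind(A3, row); b3 <- c(b3, 0)
  }
  for (bk in mech$branch_combinations) {
    row <- numeric(nv); row[1L] <- -1; row[iv(bk)] <- 1
    A3 <- rbind(A3, row); b3 <- c(b3, 0)
  }
  row <- numeric(nv); row[1L + mech$n_e + seq_len(mech$n_states)] <- 1
  A3 <- rbind(A3, row); b3 <- c(b3, 1)
  # the branch-combination rows are linearly dependent; the simplex tableau
  # needs a full-rank equality block
  qr_A3 <- qr(t(A3))
  keep <- sort(qr_A3$pivot[seq_len(qr_A3$rank)])
  A3 <- A3[keep, , drop = FALSE]; b3 <- b3[keep]
  obj <- numeric(nv); obj[1L] <- 1
  fit <- boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3, maxi = TRUE)
  if (fit$solved != 1) stop("inner LP did not solve (boot::simplex status ",
                            fit$solved, ")")
  if (!details) return(unname(fit$value))
  x <- fit$soln
  e <- x[1L + mech$n_e + seq_len(mech$n_states)]
  names(e) <- mech$states
  list(value = unname(fit$value), e = e,
       v_i = unname(x[1L + seq_len(mech$n_e)]),
       beta = NA_real_, beta_lo = NA_real_, beta_hi = NA_real_)
}

#' Brute-force optimum over a displacement grid
#'
#' Independent oracle for the MILP: maximizes the inner fixed-displacement
#' flux over a regular grid of the independent displacement variables (the
#' same independent set the MILP discretizes, so route and cycle products
#' hold by construction on the grid).
#'
#' @param mech an `enz_mechanism`.
#' @param point an `enz_point` with overall displacement in (0, 1).
#' @param n_grid number of grid intervals per independent variable.
#' @return list with `value`, `gamma_hat` (named optimal independent values),
#'   `gamma` (per-step), `width` (grid spacing), `n_combos`.
#' @export
brute_force_optimum <- function(mech, point, n_grid = 100) {
  G <- point$gamma
  if (G >= 1) {
    if (point$equilibrium) {
      return(list(value = 0, gamma_hat = NULL, gamma = rep(1, mech$n_e),
                  width = 0, n_combos = 0L))
    }
    stop("point runs in reverse (Gamma > 1); apply reverse_point/reverse_mechanism first")
  }
  plan <- discretization_plan(mech, G, resolution = (1 - G) / n_grid)
  ids <- plan$ids
  width <- (1 - G) / n_grid
  vals <- G + (0:n_grid) * width
  grid <- do.call(expand.grid, c(stats::setNames(rep(list(vals), length(ids)), ids),
                                 list(KEEP.OUT.ATTRS = FALSE)))
  keep <- rep(TRUE, nrow(grid))
  for (oc in plan$ordering) keep <- keep & (grid[[oc[1L]]] <= grid[[oc[2L]]] + 1e-15)
  for (pf in plan$product_floor) {
    prod_v <- Reduce(`*`, grid[pf], accumulate = FALSE)
    keep <- keep & (prod_v >= G - 1e-15)
  }
  grid <- grid[keep, , drop = FALSE]
  gamma_mat <- plan_gamma_matrix(plan, grid)
  ok <- rowSums(gamma_mat > 1 + 1e-12 | gamma_mat < G - 1e-12) == 0
  grid <- grid[ok, , drop = FALSE]
  gamma_mat <- gamma_mat[ok, , drop = FALSE]
  value <- if (length(mech$routes) <= 1L) {
    inner_value_unbranched_vec(mech, point, gamma_mat)
  } else if (length(mech$routes) == 2L) {
    inner_value_two_route_vec(mech, point, gamma_mat)$value
  } else {
    vapply(seq_len(nrow(gamma_mat)), function(r) {
      inner_lp_simplex(mech, point, gamma_mat[r, ])
    }, numeric(1))
  }
  best <- which.max(value)
  list(value = value[best],
       gamma_hat = unlist(grid[best, , drop = TRUE]),
       gamma = gamma_mat[best, ],
       width = width,
       n_combos = nrow(grid))
}

# per-step displacement matrix from independent-variable columns
plan_gamma_matrix <- function(plan, grid) {
  G <- plan$gamma
  out <- matrix(NA_real_, nrow(grid), length(plan$expressions))
  for (i in seq_along(plan$expressions)) {
    ex <- plan$expressions[[i]]
    v <- rep(G^ex$pow, nrow(grid))
    for (id in ex$num) v <- v * grid[[id]]
    for (id in ex$den) v <- v / grid[[id]]
    out[, i] <- v
  }
  colnames(out) <- names(plan$expressions)
  out
}
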