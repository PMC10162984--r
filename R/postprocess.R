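#' Back-calculate elementary rate constants from a solution
#'
#' The optimization carries the products z = k * e rather than the rate
#' constants themselves; dividing z_f and z_b by the occupancy of the
#' departure and arrival state recovers the normalized constants.  States
#' whose occupancy falls below `eps_e` give an undefined constant (NA):
#' below feasibility tolerance the ratio is numerically meaningless.
#'
#' @param sol an `enz_solution` (polished).
#' @param mech the mechanism the solution belongs to.
#' @param eps_e occupancy threshold for defined constants.
#' @param clip_tol values in [1, 1 + clip_tol] are clipped to the limit 1.
#' @return data.frame `index`, `k_f`, `k_b`.
#' @export
back_calculate_k <- function(sol, mech = sol$mech, eps_e = 1e-9,
                             clip_tol = 1e-6) {
  st <- mech$steps
  e_from <- sol$e[st$from]
  e_to <- sol$e[st$to]
  safe_div <- function(z, e) ifelse(e < eps_e, NA_real_, z / pmax(e, eps_e))
  clipk <- function(k) {
    bad <- !is.na(k) & k > 1 + clip_tol
    if (any(bad)) warning("rate constant exceeds its limit beyond tolerance")
    pmin(k, 1)
  }
  data.frame(index = st$index,
             k_f = clipk(unname(safe_div(sol$z_f, e_from))),
             k_b = clipk(unname(safe_div(sol$z_b, e_to))))
}

#' Enzyme saturation
#'
#' The fraction of enzyme not in the free state at the optimum,
#' sigma = 1 - e_free.
#'
#' @param sol an `enz_solution`.
#' @param mech the mechanism (for the free-state label).
#' @return saturation in [0, 1].
#' @export
saturation <- function(sol, mech = sol$mech) {
  if (is.null(sol$e)) return(NA_real_)
  unname(1 - sol$e[mech$free_state])
}

#' Splitting ratio of a branched mechanism
#'
#' alpha = v_net,up / v_net, the fraction of the net flux routed through the
#' upper branch (the branch whose first step binds substrate A in the
#' built-in random-ordered mechanism).  Unbranched mechanisms return NA with
#' attribute `not_applicable`; a zero net flux gives NaN.
#'
#' @param sol an `enz_solution`.
#' @param mech the mechanism.
#' @return the splitting ratio.
#' @export
splitting_ratio <- function(sol, mech = sol$mech) {
  if (length(mech$routes) <= 1L) {
    return(structure(NA_real_, not_applicable = TRUE))
  }
  cls <- two_route_classes(mech)
  v_up <- sol$v_i[as.character(min(cls$up))]
  unname(v_up / sol$v_net)
}

#' Free-energy allocation across elementary steps
#'
#' Each step's share of the overall thermodynamic driving force,
#' share_i = log(gamma_i) / log(Gamma).  Shares along any single route sum
#' to 1.
#'
#' @param sol an `enz_solution` (or any object with realized `gamma`).
#' @param gamma_overall overall displacement; defaults to the solution's.
#' @return named numeric vector of shares by step.
#' @export
dg_fractions <- function(sol, gamma_overall = sol$point$gamma) {
  if (gamma_overall >= 1) stop("free-energy shares require Gamma < 1")
  log(sol$gamma) / log(gamma_overall)
}

#' Variability analysis at a pinned objective
#'
#' Re-optimizes each requested variable to its minimum and maximum with the
#' net flux pinned at the optimum, detecting alternative optima.  Variables
#' are named as in the model registry (`v[1]`, `z_f[2]`, `e[EA]`, ...); the
#' pseudo-names `gamma_hat[<id>]` address the binary expansion of an
#' independent displacement.
#'
#' @param model an `enz_milp_model` (from [solve_optimal()] with
#'   `keep_model = TRUE`, or [build_milp()]).
#' @param sol the corresponding solved `enz_solution`.
#' @param variables character vector of variable names.
#' @param fix_tol relative slack used when pinning the optimum.
#' @return data.frame `variable`, `min`, `max`, `reliable`.
#' @export
variability <- function(model, sol, variables, fix_tol = 1e-9) {
  rows <- lapply(variables, function(v) {
    if (grepl("^gamma_hat\\[", v)) {
      id <- sub("^gamma_hat\\[(.*)\\]$", "\\1", v)
      h <- model$hats[[id]]
      if (is.null(h)) stop("unknown independent displacement: ", id)
      if (h$nbits == 0L) {
        mm <- c(min = h$offset, max = h$offset)
      } else {
        coefs <- stats::setNames(h$weights, model$names[h$dvars])
        mm <- milp_minmax(model, coefs, sol$objective, fix_tol)
        mm <- mm + h$offset  # expansion offset
      }
    } else {
      mm <- milp_minmax(model, stats::setNames(1, v), sol$objective, fix_tol)
    }
    data.frame(variable = v, min = mm["min"], max = mm["max"],
               reliable = !anyNA(mm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flexibility of the splitting ratio at the optimum
#'
#' Convenience wrapper: variability of the upper-branch net flux with the
#' overall net flux pinned, expressed as an interval on alpha (the ratio is
#' avoided in the objective by pinning the denominator).
#'
#' @param model,sol as in [variability()].
#' @param fix_tol relative slack on the pinned optimum.
#' @return list `alpha_min`, `alpha_max`, `midpoint`, `width`.
#' @export
alpha_variability <- function(model, sol, fix_tol = 1e-9) {
  mech <- model$mech
  if (length(mech$routes) <= 1L) stop("mechanism is unbranched")
  cls <- two_route_classes(mech)
  vname <- sprintf("v[%d]", min(cls$up))
  mm <- milp_minmax(model, stats::setNames(1, vname), sol$objective, fix_tol)
  a <- unname(mm / sol$objective)
  list(alpha_min = a[1L], alpha_max = a[2L],
       midpoint = mean(a), width = diff(a))
}

# ---- operating modes -------------------------------------------------------

# assemble one operating-mode row from displacements + fluxes + states
operating_mode <- function(mech, point, gamma, v_i, e, v_net) {
  cc <- step_concentrations(mech, point)
  z_f <- pmin(v_i * req_coef_forward(gamma, cc$c_f), BIGC)
  z_b <- pmin(v_i * req_coef_backward(gamma, cc$c_b), BIGC)
  sol <- list(e = e, z_f = z_f, z_b = z_b, v_i = stats::setNames(v_i, mech$steps$index),
              v_net = v_net, gamma = gamma, mech = mech, point = point)
  k <- back_calculate_k(sol, mech)
  alpha <- if (length(mech$routes) > 1L) {
    cls <- two_route_classes(mech)
    v_i[match(min(cls$up), mech$steps$index)] / v_net
  } else NA_real_
  c(stats::setNames(as.list(k$k_f), sprintf("k_f.%d", k$index)),
    stats::setNames(as.list(k$k_b), sprintf("k_b.%d", k$index)),
    stats::setNames(as.list(e), sprintf("e.%s", names(e))),
    stats::setNames(as.list(gamma), sprintf("gamma.%d", mech$steps$index)),
    list(v_net = v_net, sigma = unname(1 - e[mech$free_state]), alpha = alpha))
}

#' Sample alternative optimal operating modes
#'
#' At flexible optima the displacement variables are sampled uniformly
#' within their variability intervals; with the displacements fixed the
#' remaining feasible set is a linear polytope in the fluxes and enzyme
#' states, which is sampled with an artificially centered hit-and-run walk.
#' Draws whose fixed displacements cannot reach the pinned optimum are
#' discarded.
#'
#' @param model an `enz_milp_model`.
#' @param sol the solved `enz_solution`.
#' @param n number of retained rows.
#' @param seed RNG seed (sampler metadata).
#' @param opt_tol relative optimality tolerance a retained row must meet.
#' @param burn_in,thinning hit-and-run parameters.
#' @return object of class `enz_samples`: data.frame of operating modes with
#'   attributes `meta` (seed, burn_in, thinning, cut-off).
#' @export
sample_alternative_optima <- function(model, sol, n = 50, seed = 1L,
                                      opt_tol = 1e-6, burn_in = 100L,
                                      thinning = 10L) {
  sample_modes(model, sol, n = n, seed = seed, c_l = 1 - opt_tol,
               burn_in = burn_in, thinning = thinning, at_optimum = TRUE)
}

#' Sample suboptimal operating modes
#'
#' Explores the fitness landscape below the optimum: operating modes with
#' net flux at or beyond the cut-off c_l * v* are sampled by drawing
#' displacement assignments uniformly over their variability ranges at the
#' cut, then hit-and-run sampling of the continuous polytope.
#'
#' @param model an `enz_milp_model`.
#' @param sol the solved `enz_solution`.
#' @param c_l cut-off fraction in (0, 1].
#' @param n,seed,burn_in,thinning as in [sample_alternative_optima()].
#' @return an `enz_samples` data.frame.
#' @export
explore_suboptimal <- function(model, sol, c_l = 0.9, n = 50, seed = 1L,
                               burn_in = 100L, thinning = 10L) {
  if (c_l <= 0 || c_l > 1) stop("c_l must lie in (0, 1]")
  sample_modes(model, sol, n = n, seed = seed, c_l = c_l,
               burn_in = burn_in, thinning = thinning, at_optimum = FALSE)
}

sample_modes <- function(model, sol, n, seed, c_l, burn_in, thinning,
                         at_optimum) {
  mech <- model$mech
  point <- model$point
  plan <- model$plan
  set.seed(seed)
  v_cut <- c_l * sol$objective
  # displacement ranges at the cut (variability of each independent
  # expansion with the objective held at or beyond the cut)
  iv <- variability(model, structure(list(objective = v_cut),
                                     class = "enz_solution"),
                    sprintf("gamma_hat[%s]", plan$ids), fix_tol = 0)
  lo <- stats::setNames(iv$min, plan$ids)
  hi <- stats::setNames(iv$max, plan$ids)
  rows <- list()
  attempts <- 0L
  discarded <- 0L
  while (length(rows) < n && attempts < 50L * n) {
    attempts <- attempts + 1L
    hat <- stats::setNames(stats::runif(length(plan$ids), lo, hi), plan$ids)
    bad <- FALSE
    for (oc in plan$ordering) if (hat[oc[1L]] > hat[oc[2L]]) bad <- TRUE
    for (pf in plan$product_floor) if (prod(hat[pf]) < plan$gamma) bad <- TRUE
    if (bad) { discarded <- discarded + 1L; next }
    gamma <- plan_gamma_values(plan, hat)
    if (any(gamma > 1 + 1e-12 | gamma < plan$gamma - 1e-12)) {
      discarded <- discarded + 1L; next
    }
    names(gamma) <- names(plan$expressions)
    inner <- inner_lp_value(mech, point, gamma, details = TRUE)
    if (inner$value < v_cut * (1 - 1e-12)) { discarded <- discarded + 1L; next }
    draws <- if (at_optimum) {
      # the optimal set at fixed displacements is the flat segment of the
      # branch split (the enzyme states follow it exactly); sample it
      # uniformly rather than walking a measure-zero face
      optimal_face_mode(mech, point, gamma, inner)
    } else {
      polytope_modes(mech, point, gamma, inner, v_cut, n_draws = 1L,
                     burn_in = burn_in, thinning = thinning)
    }
    for (d in draws) {
      rows[[length(rows) + 1L]] <-
        operating_mode(mech, point, gamma, d$v_i, d$e, d$v_net)
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  attr(out, "meta") <- list(seed = seed, burn_in = burn_in,
                            thinning = thinning, c_l = c_l,
                            attempts = attempts, discarded = discarded)
  class(out) <- c("enz_samples", class(out))
  out
}

# one uniform draw on the optimal face at fixed displacements
optimal_face_mode <- function(mech, point, gamma, inner) {
  v <- inner$value
  if (length(mech$routes) <= 1L || !is.finite(inner$beta_lo) ||
      inner$beta_hi - inner$beta_lo < 1e-12) {
    return(list(list(v_i = inner$v_i, e = inner$e, v_net = v)))
  }
  beta <- stats::runif(1L, inner$beta_lo, inner$beta_hi)
  cls <- two_route_classes(mech)
  v_i <- numeric(mech$n_e)
  v_i[mech$steps$index %in% cls$up] <- beta * v
  v_i[mech$steps$index %in% cls$low] <- (1 - beta) * v
  v_i[mech$steps$index %in% cls$trunk] <- v
  e <- inner_e_from_fluxes(mech, point, gamma, v_i)
  e[mech$free_state] <- e[mech$free_state] + max(0, 1 - sum(e))
  list(list(v_i = v_i, e = e, v_net = v))
}

# One hit-and-run draw over the continuous polytope at fixed displacements:
# variables are the route fluxes and the enzyme states; z's follow exactly.
polytope_modes <- function(mech, point, gamma, inner, v_cut, n_draws,
                           burn_in, thinning) {
  reqs <- state_requirements(mech, point, matrix(gamma, nrow = 1))
  st <- mech$steps
  n_states <- mech$n_states
  routes <- mech$routes
  nr <- max(1L, length(routes))
  # x = (route fluxes rho_r, e_1..e_N); step flux v_i = sum of rho over
  # routes containing i; v_net = sum rho
  nx <- nr + n_states
  step_route <- vapply(st$index, function(i) {
    as.numeric(vapply(seq_len(nr), function(r) i %in% routes[[r]], logical(1)))
  }, numeric(nr))
  step_route <- matrix(step_route, nrow = nr)
  A <- NULL; b <- NULL  # A x <= b
  for (k in seq_len(n_states)) {
    for (tm in reqs[[k]]) {
      row <- numeric(nx)
      row[seq_len(nr)] <- tm$coef * step_route[, match(tm$step, st$index)]
      row[nr + k] <- -1
      A <- rbind(A, row); b <- c(b, 0)
    }
  }
  # rho >= 0, e >= 0
  A <- rbind(A, -diag(nx)); b <- c(b, numeric(nx))
  # v_net >= v_cut
  row <- numeric(nx); row[seq_len(nr)] <- -1
  A <- rbind(A, row); b <- c(b, -v_cut)
  # equality: sum e = 1  -> parameterize its null space
  ceq <- c(numeric(nr), rep(1, n_states))
  x0 <- c(route_fluxes_from(inner, mech), inner$e)
  NS <- nullspace_of(matrix(ceq, nrow = 1))
  y0 <- numeric(ncol(NS))
  Ay <- A %*% NS
  by <- b - A %*% x0
  samples <- achr_walk(Ay, by, y0, n_keep = n_draws, burn_in = burn_in,
                       thinning = thinning)
  lapply(samples, function(y) {
    x <- x0 + NS %*% y
    rho <- x[seq_len(nr)]
    e <- stats::setNames(x[nr + seq_len(n_states)], mech$states)
    v_i <- as.numeric(t(step_route) %*% rho)
    list(v_i = v_i, e = e, v_net = sum(rho))
  })
}

route_fluxes_from <- function(inner, mech) {
  nr <- length(mech$routes)
  if (nr <= 1L) return(inner$value)
  if (nr == 2L) {
    cls <- two_route_classes(mech)
    up_route <- which(vapply(mech$routes, function(r) all(cls$up %in% r),
                             logical(1)))[1L]
    rho <- numeric(2L)
    rho[up_route] <- inner$beta * inner$value
    rho[-up_route] <- (1 - inner$beta) * inner$value
    return(rho)
  }
  stop("route-flux recovery implemented for at most two routes")
}

nullspace_of <- function(A) {
  s <- svd(A, nv = ncol(A))
  rank <- sum(s$d > 1e-12 * max(s$d, 1))
  s$v[, seq(rank + 1L, ncol(A)), drop = FALSE]
}

# artificially centered hit and run on {y : A y <= b}, starting from y0
achr_walk <- function(A, b, y0, n_keep, burn_in, thinning) {
  d <- length(y0)
  if (d == 0L) return(replicate(n_keep, y0, simplify = FALSE))
  slack0 <- b - A %*% y0
  if (any(slack0 < -1e-8)) stop("hit-and-run start point infeasible")
  y <- y0
  center <- y0
  kept <- list()
  total <- burn_in + n_keep * thinning
  n_seen <- 1
  for (it in seq_len(total)) {
    dir <- if (length(kept) >= 2L && stats::runif(1) < 0.8) {
      pick <- kept[[sample.int(length(kept), 1L)]]
      dv <- pick - center
      if (sqrt(sum(dv^2)) < 1e-12) stats::rnorm(d) else dv
    } else stats::rnorm(d)
    dir <- dir / sqrt(sum(dir^2))
    Ad <- A %*% dir
    slack <- b - A %*% y
    slack <- pmax(slack, 0)
    tmax <- suppressWarnings(min((slack / Ad)[Ad > 1e-14]))
    tmin <- suppressWarnings(max((-slack / -Ad)[Ad < -1e-14]))
    if (!is.finite(tmax)) tmax <- 1e6
    if (!is.finite(tmin)) tmin <- -1e6
    if (tmax <= tmin) next
    y <- y + stats::runif(1, tmin, tmax) * dir
    n_seen <- n_seen + 1
    center <- center + (y - center) / n_seen
    if (it > burn_in && (it - burn_in) %% thinning == 0L) {
      kept[[length(kept) + 1L]] <- y
    } else if (it <= burn_in) {
      kept[[length(kept) + 1L]] <- y
      if (length(kept) > 25L) kept[[1L]] <- NULL
    }
  }
  utils::tail(kept, n_keep)
}

#' Write sampled operating modes to CSV
#'
#' One row per mode; sampler metadata goes into a sidecar JSON file next to
#' the CSV (same path with extension `.meta.json`).
#'
#' @param samples an `enz_samples` data.frame.
#' @param path output CSV path.
#' @return invisibly, the CSV path.
#' @export
write_samples_csv <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  meta <- attr(samples, "meta")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), ".meta.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}
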