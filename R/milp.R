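#' @title MILP formulation of optimal enzyme utilization
#' @description Internal machinery that assembles the mixed-integer linear
#'   program: change of variables z = k*e, binary expansion of the
#'   independent displacements, Petersen linearization of binary-continuous
#'   products and pairwise linearization of binary-binary products.
#' @name enz_milp
NULL

default_milp_options <- function() {
  list(mip_rel_gap = 1e-9, time_limit = 600, presolve = TRUE, seed = 1L,
       tighten = TRUE)
}

# A model is an environment so helper calls can grow it in place; clone
# before mutating a solved/shared model.
new_milp_model <- function(mech, point, plan, options) {
  m <- new.env(parent = emptyenv())
  m$mech <- mech
  m$point <- point
  m$plan <- plan
  m$options <- utils::modifyList(default_milp_options(), options)
  m$nvar <- 0L
  m$names <- character(0)
  m$obj <- numeric(0)
  m$lb <- numeric(0)
  m$ub <- numeric(0)
  m$vtype <- integer(0)      # 0 continuous, 1 binary
  m$ti <- integer(0); m$tj <- integer(0); m$tx <- numeric(0)
  m$nrow <- 0L
  m$rlb <- numeric(0)
  m$rub <- numeric(0)
  m$row_names <- character(0)
  m$t_cache <- new.env(parent = emptyenv())
  m$zeta_cache <- new.env(parent = emptyenv())
  m$hats <- list()
  m$maximize <- TRUE
  class(m) <- "enz_milp_model"
  m
}

milp_add_var <- function(m, name, lb = 0, ub = Inf, obj = 0, binary = FALSE) {
  m$nvar <- m$nvar + 1L
  m$names[m$nvar] <- name
  m$lb[m$nvar] <- lb
  m$ub[m$nvar] <- if (binary) 1 else ub
  m$obj[m$nvar] <- obj
  m$vtype[m$nvar] <- as.integer(binary)
  m$nvar
}

# coefs: named numeric (names = variable names) or integer-indexed
milp_add_row <- function(m, cols, coefs, lb = -Inf, ub = Inf, name = "") {
  if (is.character(cols)) {
    idx <- match(cols, m$names)
    if (anyNA(idx)) stop("unknown variable(s): ",
                         paste(cols[is.na(idx)], collapse = ", "))
  } else idx <- cols
  m$nrow <- m$nrow + 1L
  keep <- coefs != 0
  m$ti <- c(m$ti, rep(m$nrow, sum(keep)))
  m$tj <- c(m$tj, idx[keep])
  m$tx <- c(m$tx, coefs[keep])
  m$rlb[m$nrow] <- lb
  m$rub[m$nrow] <- ub
  m$row_names[m$nrow] <- name
  m$nrow
}

milp_clone <- function(m) {
  m2 <- new_milp_model(m$mech, m$point, m$plan, m$options)
  for (f in c("nvar", "names", "obj", "lb", "ub", "vtype", "ti", "tj", "tx",
              "nrow", "rlb", "rub", "row_names", "maximize", "big_m", "hats")) {
    assign(f, get(f, envir = m), envir = m2)
  }
  m2
}

var_idx <- function(m, name) {
  i <- match(name, m$names)
  if (is.na(i)) stop("unknown variable: ", name)
  i
}

delta_name <- function(id, s) sprintf("delta[%s][%d]", id, s)

# Petersen linearization: a fresh variable t = bin * cont under
#   cont + M bin - t <= M,  t - M bin <= 0,  t - cont <= 0,  t >= 0
# M is the upper bound of the continuous factor (the tightest valid choice).
petersen_t <- function(m, cont_idx, bin_idx) {
  key <- paste(cont_idx, bin_idx, sep = ":")
  if (!is.null(m$t_cache[[key]])) return(m$t_cache[[key]])
  M <- m$ub[cont_idx]
  if (!is.finite(M)) M <- m$big_m
  t <- milp_add_var(m, sprintf("t[%s|%s]", m$names[cont_idx], m$names[bin_idx]),
                    lb = 0, ub = M)
  milp_add_row(m, c(cont_idx, bin_idx, t), c(1, M, -1), ub = M)
  milp_add_row(m, c(t, bin_idx), c(1, -M), ub = 0)
  milp_add_row(m, c(t, cont_idx), c(1, -1), ub = 0)
  m$t_cache[[key]] <- t
  t
}

# binary product zeta = delta * lambda under
#   zeta <= delta, zeta <= lambda, zeta >= delta + lambda - 1
zeta_var <- function(m, bin1, bin2) {
  key <- paste(sort(c(bin1, bin2)), collapse = ":")
  if (!is.null(m$zeta_cache[[key]])) return(m$zeta_cache[[key]])
  z <- milp_add_var(m, sprintf("zeta[%s|%s]", m$names[bin1], m$names[bin2]),
                    binary = TRUE)
  milp_add_row(m, c(z, bin1), c(1, -1), ub = 0)
  milp_add_row(m, c(z, bin2), c(1, -1), ub = 0)
  milp_add_row(m, c(z, bin1, bin2), c(1, -1, -1), lb = -1)
  m$zeta_cache[[key]] <- z
  z
}

# expansion weights of the canonical (full-range) plan
plan_weights <- function(plan) plan$width * 2^(0:(plan$nbits - 1L))

# Register the binary expansion of one independent displacement over the
# bin window [p_lo, p_hi]: gamma_hat = offset + sum_s w_s delta_s with
# offset = Gamma + p_lo * width; narrow windows need few bits.
register_hat <- function(m, id, p_lo, p_hi) {
  plan <- m$plan
  pcap <- p_hi - p_lo
  nbits <- if (pcap <= 0L) 0L else as.integer(ceiling(log2(pcap + 1)))
  dvars <- integer(0)
  if (nbits > 0L) {
    dvars <- vapply(seq_len(nbits) - 1L, function(s) {
      milp_add_var(m, delta_name(id, s), binary = TRUE)
    }, integer(1))
    if (sum(2^(seq_len(nbits) - 1L)) > pcap) {
      milp_add_row(m, dvars, 2^(seq_len(nbits) - 1L), ub = pcap,
                   name = sprintf("bins[%s]", id))
    }
  }
  m$hats[[id]] <- list(offset = plan$gamma + p_lo * plan$width,
                       top = plan$gamma + p_hi * plan$width,
                       nbits = nbits, pcap = pcap, dvars = dvars,
                       weights = plan$width * 2^(seq_len(nbits) - 1L))
  invisible(m$hats[[id]])
}

# Linear expansion of scale * cont * prod(g_hat[ids]) as (cols, coefs),
# creating t and zeta variables as needed.  Supports 0, 1 or 2 identifiers.
expand_cont_hats <- function(m, cont_idx, ids, scale) {
  if (length(ids) == 0L) {
    return(list(cols = cont_idx, coefs = scale))
  }
  if (length(ids) == 1L) {
    h <- m$hats[[ids]]
    if (h$nbits == 0L) return(list(cols = cont_idx, coefs = scale * h$offset))
    fresh <- is.null(m$t_cache[[paste(cont_idx, h$dvars[1L], sep = ":")]])
    tvars <- vapply(h$dvars, function(b) petersen_t(m, cont_idx, b), integer(1))
    if (fresh) {
      # aggregate cut: sum_s w_s t_s = cont (gamma_hat - offset)
      #              <= (top - offset) cont
      milp_add_row(m, c(tvars, cont_idx),
                   c(h$weights, -(h$top - h$offset)), ub = 0,
                   name = sprintf("agg[%s|%s]", m$names[cont_idx], ids))
    }
    return(list(cols = c(cont_idx, tvars),
                coefs = scale * c(h$offset, h$weights)))
  }
  if (length(ids) == 2L) {
    ha <- m$hats[[ids[1L]]]
    hb <- m$hats[[ids[2L]]]
    if (ha$nbits == 0L) return(expand_cont_hats(m, cont_idx, ids[2L],
                                                scale * ha$offset))
    if (hb$nbits == 0L) return(expand_cont_hats(m, cont_idx, ids[1L],
                                                scale * hb$offset))
    ea <- expand_cont_hats(m, cont_idx, ids[1L], 1)
    eb <- expand_cont_hats(m, cont_idx, ids[2L], 1)
    ta <- setdiff(ea$cols, cont_idx)
    tb <- setdiff(eb$cols, cont_idx)
    zz <- integer(0); wz <- numeric(0)
    aggkey <- sprintf("%d:z:%s", cont_idx, paste(ids, collapse = ":"))
    fresh <- is.null(m$t_cache[[aggkey]])
    for (s in seq_len(ha$nbits)) {
      for (p in seq_len(hb$nbits)) {
        z <- zeta_var(m, ha$dvars[s], hb$dvars[p])
        zz <- c(zz, petersen_t(m, cont_idx, z))
        wz <- c(wz, ha$weights[s] * hb$weights[p])
      }
    }
    if (fresh) {
      m$t_cache[[aggkey]] <- TRUE
      milp_add_row(m, c(zz, cont_idx),
                   c(wz, -(ha$top - ha$offset) * (hb$top - hb$offset)), ub = 0,
                   name = sprintf("agg2[%s]", m$names[cont_idx]))
    }
    return(list(cols = c(cont_idx, ta, tb, zz),
                coefs = scale * c(ha$offset * hb$offset,
                                  hb$offset * ha$weights,
                                  ha$offset * hb$weights,
                                  wz)))
  }
  stop("products of more than two displacement expansions are not supported")
}

# linear coefficients of a registered expansion (for side constraints)
hat_terms <- function(m, id) {
  h <- m$hats[[id]]
  list(const = h$offset, cols = h$dvars, coefs = h$weights)
}

#' Build the optimal-enzyme-utilization MILP
#'
#' Assembles the full mixed-integer linear program for a mechanism at an
#' operating point under a discretization plan: per-step rate constraints in
#' multiplied-out (division-free) form, z bounds against the enzyme states,
#' flux coupling over the unbranched set and every branch combination, total
#' enzyme conservation, binary expansions with their bin-count caps, ordering
#' and product-floor constraints on the independent displacements, and the
#' Petersen / binary-product linearizations.  The objective maximizes the net
#' flux per total enzyme.
#'
#' By default ([displacement_windows()]) a certified interval presolve
#' restricts each binary expansion to the bins that can still reach the best
#' known lattice value, which shortens the branch-and-bound search without
#' excluding any optimal or alternative-optimal assignment.
#'
#' @param mech an `enz_mechanism`.
#' @param point an `enz_point` with Gamma < 1 (use [reverse_mechanism()] and
#'   [reverse_point()] first for Gamma > 1; equilibrium points short-circuit
#'   in [solve_optimal()]).
#' @param plan an `enz_plan` for this mechanism.
#' @param options list merged over the defaults `mip_rel_gap` (1e-9),
#'   `time_limit` (s), `presolve`, `seed`, `tighten` (certified domain
#'   reduction on/off), `suboptimal_cut` (c_l; retains all bin assignments
#'   reaching c_l times the optimum, for suboptimal exploration).
#' @return an `enz_milp_model` environment.
#' @export
build_milp <- function(mech, point, plan, options = list()) {
  if (point$gamma >= 1) stop("build_milp requires Gamma < 1")
  if (!setequal(names(plan$expressions), as.character(mech$steps$index))) {
    stop("discretization plan does not match the mechanism's steps")
  }
  m <- new_milp_model(mech, point, plan, options)
  st <- mech$steps
  cc <- step_concentrations(mech, point)
  # big-M fallback: every trunk step bounds v_net by its forward multiplier
  m$big_m <- if (length(mech$unbranched_steps)) {
    max(1, min(cc$c_f[match(mech$unbranched_steps, cc$index)]))
  } else max(1, max(cc$c_f, cc$c_b))
  M <- m$big_m
  G <- plan$gamma

  # valid flux bounds: for a trunk step j, v_net = v_j = z_jf c_jf (1-gamma_j)
  # with z <= 1 and gamma_j >= Gamma, so v_net <= c_jf (1-Gamma); likewise
  # every step flux is bounded by its own forward multiplier
  v_ub <- if (length(mech$unbranched_steps)) {
    min(M, (1 - G) * min(cc$c_f[match(mech$unbranched_steps, cc$index)]))
  } else M
  milp_add_var(m, "v_net", lb = 0, ub = v_ub, obj = 1)
  for (r in seq_len(nrow(st))) {
    milp_add_var(m, sprintf("v[%d]", st$index[r]),
                 lb = 0, ub = min(v_ub, (1 - G) * cc$c_f[r]))
  }
  for (i in st$index) {
    milp_add_var(m, sprintf("z_f[%d]", i), lb = 0, ub = 1)
    milp_add_var(m, sprintf("z_b[%d]", i), lb = 0, ub = 1)
  }
  for (s in mech$states) milp_add_var(m, sprintf("e[%s]", s), lb = 0, ub = 1)

  # certified domain reduction, then per-id binary expansions over windows
  cl <- m$options$suboptimal_cut
  if (is.null(cl)) cl <- 1
  dw <- if (!isFALSE(m$options$tighten) && length(mech$routes) <= 2L) {
    displacement_windows(mech, point, plan, keep_factor = cl)
  } else NULL
  m$windows <- dw
  for (id in plan$ids) {
    p_lo <- 0L; p_hi <- plan$N
    if (!is.null(dw)) {
      row <- dw$windows[dw$windows$id == id, ]
      p_lo <- row$p_lo; p_hi <- row$p_hi
    }
    register_hat(m, id, p_lo, p_hi)
  }
  if (!is.null(dw) && is.finite(dw$ub)) {
    # slack of 1e-9 keeps the pins outside the LP feasibility tolerance
    milp_add_row(m, "v_net", 1, ub = dw$ub * (1 + 1e-9), name = "obj_ub")
    if (cl == 1 && is.finite(dw$lb)) {
      milp_add_row(m, "v_net", 1, lb = dw$lb * (1 - 1e-9), name = "obj_lb")
    }
  }

  for (oc in plan$ordering) {
    a <- hat_terms(m, oc[1L]); b <- hat_terms(m, oc[2L])
    milp_add_row(m, c(a$cols, b$cols), c(a$coefs, -b$coefs),
                 ub = b$const - a$const,
                 name = sprintf("order[%s<=%s]", oc[1L], oc[2L]))
  }
  for (pf in plan$product_floor) {
    # prod(g_hat) >= Gamma, expanded over offsets, bits and zeta products
    ha <- m$hats[[pf[1L]]]; hb <- m$hats[[pf[2L]]]
    cols <- c(ha$dvars, hb$dvars)
    coefs <- c(hb$offset * ha$weights, ha$offset * hb$weights)
    for (s in seq_len(ha$nbits)) {
      for (p in seq_len(hb$nbits)) {
        cols <- c(cols, zeta_var(m, ha$dvars[s], hb$dvars[p]))
        coefs <- c(coefs, ha$weights[s] * hb$weights[p])
      }
    }
    milp_add_row(m, cols, coefs, lb = G - ha$offset * hb$offset,
                 name = sprintf("floor[%s]", paste(pf, collapse = "*")))
  }

  # per-step rate constraints, multiplied out by the denominator of the
  # displacement expression:
  #   v_i D - c_f z_f D + c_f z_f U = 0
  #   v_i U - c_b z_b D + c_b z_b U = 0
  # with U = Gamma^pow * prod(num), D = prod(den)
  for (r in seq_len(nrow(st))) {
    i <- st$index[r]
    ex <- plan$expressions[[as.character(i)]]
    vi <- var_idx(m, sprintf("v[%d]", i))
    zf <- var_idx(m, sprintf("z_f[%d]", i))
    zb <- var_idx(m, sprintf("z_b[%d]", i))
    upow <- G^ex$pow
    terms_f <- list(
      expand_cont_hats(m, vi, ex$den, 1),
      expand_cont_hats(m, zf, ex$den, -cc$c_f[r]),
      expand_cont_hats(m, zf, ex$num, cc$c_f[r] * upow)
    )
    milp_add_row(m,
                 unlist(lapply(terms_f, `[[`, "cols")),
                 unlist(lapply(terms_f, `[[`, "coefs")),
                 lb = 0, ub = 0, name = sprintf("rate_f[%d]", i))
    terms_b <- list(
      expand_cont_hats(m, vi, ex$num, upow),
      expand_cont_hats(m, zb, ex$den, -cc$c_b[r]),
      expand_cont_hats(m, zb, ex$num, cc$c_b[r] * upow)
    )
    milp_add_row(m,
                 unlist(lapply(terms_b, `[[`, "cols")),
                 unlist(lapply(terms_b, `[[`, "coefs")),
                 lb = 0, ub = 0, name = sprintf("rate_b[%d]", i))
    milp_add_row(m, c(zf, var_idx(m, sprintf("e[%s]", st$from[r]))), c(1, -1),
                 ub = 0, name = sprintf("zbound_f[%d]", i))
    milp_add_row(m, c(zb, var_idx(m, sprintf("e[%s]", st$to[r]))), c(1, -1),
                 ub = 0, name = sprintf("zbound_b[%d]", i))
    # displacement-implied cuts: v_i <= z_f c_f (1-Gamma), v_i Gamma <= z_b c_b (1-Gamma)
    milp_add_row(m, c(vi, zf), c(1, -cc$c_f[r] * (1 - G)), ub = 0,
                 name = sprintf("vcut_f[%d]", i))
    milp_add_row(m, c(vi, zb), c(G, -cc$c_b[r] * (1 - G)), ub = 0,
                 name = sprintf("vcut_b[%d]", i))
  }

  vn <- var_idx(m, "v_net")
  for (j in mech$unbranched_steps) {
    milp_add_row(m, c(var_idx(m, sprintf("v[%d]", j)), vn), c(1, -1),
                 lb = 0, ub = 0, name = sprintf("couple[%d]", j))
  }
  for (bk in mech$branch_combinations) {
    cols <- c(vapply(bk, function(j) var_idx(m, sprintf("v[%d]", j)), integer(1)), vn)
    milp_add_row(m, cols, c(rep(1, length(bk)), -1), lb = 0, ub = 0,
                 name = sprintf("branch[%s]", paste(bk, collapse = "+")))
  }
  milp_add_row(m, vapply(mech$states, function(s) var_idx(m, sprintf("e[%s]", s)),
                         integer(1)),
               rep(1, mech$n_states), lb = 1, ub = 1, name = "conservation")
  m
}

#' Pin or cut the objective of a built model
#'
#' Adds the constraint v_net >= value * (1 - slack).  With `slack = 0` the
#' optimum is pinned (for variability analysis); with `slack = 1 - c_l` it is
#' the suboptimality cut v_net >= c_l * v*.
#'
#' @param model an `enz_milp_model`.
#' @param value reference net flux (usually the solved optimum).
#' @param slack nonnegative fraction.
#' @return a new `enz_milp_model` with the extra row.
#' @export
fix_objective <- function(model, value, slack = 0) {
  if (value < 0) stop("objective value must be nonnegative")
  if (slack < 0) stop("slack must be nonnegative")
  m2 <- milp_clone(model)
  milp_add_row(m2, "v_net", 1, lb = value * (1 - slack), name = "objective_fix")
  m2
}

find_python <- function() {
  py <- getOption("enzopt.python", "")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) stop("no python interpreter found for the MILP backend")
  py
}

solver_script <- function() {
  path <- system.file("python", "solve_milp.py", package = "enzopt")
  if (!nzchar(path)) {
    # during development (load_all) fall back to the source tree
    path <- file.path("inst", "python", "solve_milp.py")
  }
  if (!file.exists(path)) stop("solver backend script not found")
  normalizePath(path)
}

milp_solve_raw <- function(m, objective = NULL, maximize = NULL) {
  obj <- if (is.null(objective)) m$obj else objective
  payload <- list(
    ncol = m$nvar, nrow = m$nrow,
    obj = obj,
    maximize = if (is.null(maximize)) m$maximize else maximize,
    lb = ifelse(is.finite(m$lb), m$lb, -1e30),
    ub = ifelse(is.finite(m$ub), m$ub, 1e30),
    integrality = m$vtype,
    A = list(i = m$ti, j = m$tj, x = m$tx),
    rlb = ifelse(is.finite(m$rlb), m$rlb, -1e30),
    rub = ifelse(is.finite(m$rub), m$rub, 1e30),
    options = list(mip_rel_gap = m$options$mip_rel_gap,
                   time_limit = m$options$time_limit,
                   presolve = m$options$presolve)
  )
  mf <- tempfile(fileext = ".json")
  rf <- tempfile(fileext = ".json")
  on.exit(unlink(c(mf, rf)), add = TRUE)
  jsonlite::write_json(payload, mf, auto_unbox = TRUE, digits = NA)
  status <- system2(find_python(), c(solver_script(), mf, rf),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(rf)) {
    stop("MILP backend failed: ", paste(status, collapse = "\n"))
  }
  res <- jsonlite::fromJSON(rf)
  res$x <- as.numeric(res$x)
  res
}

scipy_status <- function(code) {
  switch(as.character(code), "0" = "optimal", "1" = "limit_reached",
         "2" = "infeasible", "3" = "unbounded", "other")
}

#' Solve a built MILP
#'
#' Calls the MILP backend and, for the standard flux-maximization objective,
#' polishes the returned solution: the binary bin choices are decoded into
#' displacement values and the continuous part is recomputed exactly from the
#' inner fixed-displacement problem, so conservation and the rate identities
#' hold to machine precision rather than solver feasibility tolerance.
#'
#' @param model an `enz_milp_model` from [build_milp()].
#' @param polish recompute the continuous block exactly at the chosen bins.
#' @return object of class `enz_solution`: `status`, `objective` (polished),
#'   `objective_raw`, `gap`, `gamma_hat`, `gamma` (per step), `v_net`, `v_i`,
#'   `z_f`, `z_b`, `e`, `beta`/`beta_lo`/`beta_hi` (two-route mechanisms),
#'   `raw` (all solver variable values, named).
#' @export
solve_milp <- function(model, polish = TRUE) {
  res <- milp_solve_raw(model)
  status <- scipy_status(res$status)
  if (is.null(res$x) || length(res$x) == 0L ||
      (!isTRUE(res$success) && status != "limit_reached")) {
    return(structure(list(status = status, message = res$message,
                          objective = NA_real_, v_net = NA_real_,
                          gap = NA_real_),
                     class = "enz_solution"))
  }
  x <- stats::setNames(res$x, model$names)
  plan <- model$plan
  mech <- model$mech
  hat <- vapply(plan$ids, function(id) {
    h <- model$hats[[id]]
    if (h$nbits == 0L) return(h$offset)
    h$offset + sum(h$weights * round(x[h$dvars]))
  }, numeric(1))
  gamma <- plan_gamma_values(plan, hat)
  names(gamma) <- names(plan$expressions)
  sol <- list(status = status, message = res$message,
              objective_raw = res$objective, gap = res$mip_gap,
              gamma_hat = hat, gamma = gamma, raw = x,
              mech = mech, point = model$point, plan = plan)
  if (polish) {
    inner <- inner_lp_value(mech, model$point, gamma, details = TRUE)
    sol$objective <- inner$value
    sol$v_net <- inner$value
    sol$v_i <- stats::setNames(inner$v_i, names(gamma))
    sol$e <- inner$e
    sol$beta <- inner$beta
    sol$beta_lo <- inner$beta_lo
    sol$beta_hi <- inner$beta_hi
    cc <- step_concentrations(mech, model$point)
    sol$z_f <- stats::setNames(
      pmin(sol$v_i * req_coef_forward(gamma, cc$c_f), BIGC), names(gamma))
    sol$z_b <- stats::setNames(
      pmin(sol$v_i * req_coef_backward(gamma, cc$c_b), BIGC), names(gamma))
  } else {
    sol$objective <- res$objective
    sol$v_net <- unname(x["v_net"])
    idx <- as.character(mech$steps$index)
    sol$v_i <- stats::setNames(x[sprintf("v[%s]", idx)], idx)
    sol$z_f <- stats::setNames(x[sprintf("z_f[%s]", idx)], idx)
    sol$z_b <- stats::setNames(x[sprintf("z_b[%s]", idx)], idx)
    sol$e <- stats::setNames(x[sprintf("e[%s]", mech$states)], mech$states)
    sol$beta <- NA_real_
  }
  structure(sol, class = "enz_solution")
}

# minimize / maximize a named linear expression with v_net pinned near value
milp_minmax <- function(model, coef_named, fix_value, fix_tol = 1e-9) {
  m2 <- fix_objective(model, fix_value, slack = fix_tol)
  obj <- numeric(m2$nvar)
  obj[match(names(coef_named), m2$names)] <- coef_named
  lo <- milp_solve_raw(m2, objective = obj, maximize = FALSE)
  hi <- milp_solve_raw(m2, objective = obj, maximize = TRUE)
  c(min = if (isTRUE(lo$success)) lo$objective else NA_real_,
    max = if (isTRUE(hi$success)) hi$objective else NA_real_)
}

#' Solve a mechanism at an operating point
#'
#' High-level wrapper: handles the direction convention (points beyond
#' equilibrium are solved on the reversed mechanism and reported with a
#' negated net flux), answers exact-equilibrium points analytically with zero
#' flux, builds the default discretization plan, solves the MILP and polishes
#' the solution.
#'
#' @param mech an `enz_mechanism`.
#' @param point an `enz_point`.
#' @param resolution displacement bin width; `NULL` for the per-mechanism
#'   default (see [discretization_plan()]).
#' @param options solver options, see [build_milp()].
#' @param keep_model if TRUE, attach the built model (needed for variability
#'   and sampling).
#' @return an `enz_solution`; `v_net_signed` carries the sign of the
#'   original direction while all internal quantities refer to the
#'   forward-running (possibly reversed) problem; `mech` is the mechanism
#'   actually solved.
#' @export
solve_optimal <- function(mech, point, resolution = NULL, options = list(),
                          keep_model = FALSE) {
  reversed <- FALSE
  if (point$equilibrium) {
    sol <- structure(list(status = "equilibrium", objective = 0, v_net = 0,
                          v_net_signed = 0, gap = 0,
                          gamma = stats::setNames(rep(1, mech$n_e),
                                                  as.character(mech$steps$index)),
                          e = NULL, mech = mech, point = point,
                          reversed = FALSE),
                     class = "enz_solution")
    return(sol)
  }
  if (point$gamma > 1) {
    mech <- reverse_mechanism(mech)
    point <- reverse_point(point)
    reversed <- TRUE
  }
  plan <- discretization_plan(mech, point$gamma, resolution)
  model <- build_milp(mech, point, plan, options)
  sol <- solve_milp(model)
  sol$reversed <- reversed
  sol$v_net_signed <- if (is.null(sol$v_net) || !is.finite(sol$v_net)) {
    NA_real_
  } else if (reversed) -sol$v_net else sol$v_net
  if (keep_model) sol$model <- model
  sol
}

#' @export
print.enz_solution <- function(x, ...) {
  cat(sprintf("Optimal enzyme utilization (status: %s)\n", x$status))
  if (!is.null(x$objective) && is.finite(x$objective)) {
    cat(sprintf("  v_net* = %.6g%s\n", x$objective,
                if (isTRUE(x$reversed)) " (reverse direction)" else ""))
  }
  if (!is.null(x$e)) {
    cat("  enzyme states:",
        paste(sprintf("%s=%.4f", names(x$e), x$e), collapse = ", "), "\n")
    cat("  displacements:",
        paste(sprintf("g%s=%.4f", names(x$gamma), x$gamma), collapse = ", "), "\n")
  }
  invisible(x)
}
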