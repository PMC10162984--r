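# Rigorous domain reduction for the displacement binaries.
#
# The inner fixed-displacement flux is monotone in every elementary
# displacement: each enzyme-requirement coefficient (1/(c(1-gamma)) and
# gamma/(c(1-gamma))) increases with gamma.  Over a box of independent
# displacement values this yields certified bounds: evaluating the inner
# optimum at the per-step displacement lower bounds over-estimates the
# achievable flux anywhere in the box.  A breadth-first interval subdivision
# therefore (i) certifies a global upper bound, (ii) holds a feasible
# lattice incumbent as lower bound, and (iii) discards bins that provably
# contain no solution with value >= the incumbent.  The surviving hull per
# independent variable is handed to the MILP as bounds on the binary
# expansions -- optimality-preserving (no point with value >= the incumbent
# is ever discarded, so all optimal and alternative-optimal assignments
# survive).

# per-step displacement bounds over boxes (rows) given plan expressions
box_gamma_bounds <- function(plan, lo, hi) {
  G <- plan$gamma
  nb <- nrow(lo)
  ne <- length(plan$expressions)
  glo <- ghi <- matrix(NA_real_, nb, ne)
  for (i in seq_len(ne)) {
    ex <- plan$expressions[[i]]
    vlo <- vhi <- rep(G^ex$pow, nb)
    for (id in ex$num) {
      vlo <- vlo * lo[, id]
      vhi <- vhi * hi[, id]
    }
    for (id in ex$den) {
      vlo <- vlo / hi[, id]
      vhi <- vhi / lo[, id]
    }
    glo[, i] <- vlo
    ghi[, i] <- vhi
  }
  list(lo = glo, hi = ghi)
}

# feasibility of a box against ordering, floor and displacement-range rules
box_feasible <- function(plan, lo, hi, gb) {
  G <- plan$gamma
  ok <- rep(TRUE, nrow(lo))
  for (oc in plan$ordering) ok <- ok & (lo[, oc[1L]] <= hi[, oc[2L]] + 1e-15)
  for (pf in plan$product_floor) {
    ok <- ok & (Reduce(`*`, lapply(pf, function(id) hi[, id])) >= G - 1e-15)
  }
  ok & rowSums(gb$lo > 1 + 1e-12) == 0 & rowSums(gb$hi < G - 1e-12) == 0
}

box_upper_value <- function(mech, point, plan, lo, hi, gb) {
  glo <- pmin(pmax(gb$lo, 0), 1)
  if (length(mech$routes) <= 1L) {
    inner_value_unbranched_vec(mech, point, glo)
  } else {
    inner_value_two_route_vec(mech, point, glo)$value
  }
}

# exact inner value at integer lattice points (rows of p_mat, by plan id)
lattice_value <- function(mech, point, plan, p_mat) {
  G <- plan$gamma
  vals <- G + p_mat * plan$width
  colnames(vals) <- plan$ids
  grid <- as.data.frame(vals)
  keep <- rep(TRUE, nrow(grid))
  for (oc in plan$ordering) keep <- keep & (grid[[oc[1L]]] <= grid[[oc[2L]]] + 1e-15)
  for (pf in plan$product_floor) {
    keep <- keep & (Reduce(`*`, grid[pf]) >= G - 1e-15)
  }
  gm <- plan_gamma_matrix(plan, grid)
  keep <- keep & rowSums(gm > 1 + 1e-12 | gm < G - 1e-12) == 0
  out <- rep(-Inf, nrow(grid))
  if (any(keep)) {
    out[keep] <- if (length(mech$routes) <= 1L) {
      inner_value_unbranched_vec(mech, point, gm[keep, , drop = FALSE])
    } else {
      inner_value_two_route_vec(mech, point, gm[keep, , drop = FALSE])$value
    }
  }
  out
}

#' Certified bin windows for the displacement binaries
#'
#' Interval subdivision over the independent-displacement box: returns per
#' independent variable the range of bins that can contain a solution at
#' least as good as the best lattice point found, together with the
#' certified objective bounds.  Used by [build_milp()] to bound the binary
#' expansions before the solver runs; all optimal (and alternative-optimal)
#' bin assignments survive the reduction.
#'
#' @param mech an `enz_mechanism` with at most two routes.
#' @param point an `enz_point` with Gamma < 1.
#' @param plan the `enz_plan` to be solved.
#' @param n0 coarse lattice subdivisions per axis for the incumbent search.
#' @param max_depth number of subdivision rounds (each halves the widest
#'   box edge).
#' @param max_boxes subdivision stops when the frontier exceeds this size.
#' @param keep_factor retain every bin assignment whose certified value can
#'   reach `keep_factor` times the incumbent (set to the suboptimality
#'   cut-off c_l when the model will explore suboptimal modes).
#' @param max_enum largest window lattice that is enumerated exhaustively to
#'   pin the objective bounds onto the exact lattice optimum.
#' @return list with `windows` (data.frame `id`, `p_lo`, `p_hi`), `lb`
#'   (incumbent lattice value), `ub` (certified upper bound), `p_best`
#'   (incumbent bins).
#' @export
displacement_windows <- function(mech, point, plan, n0 = NULL,
                                 max_depth = 80L, max_boxes = 150000L,
                                 keep_factor = 1, max_enum = 8000000L) {
  G <- plan$gamma
  k <- length(plan$ids)
  if (length(mech$routes) > 2L) {
    return(list(windows = data.frame(id = plan$ids, p_lo = 0L, p_hi = plan$N),
                lb = NA_real_, ub = NA_real_, p_best = NULL))
  }
  if (is.null(n0)) n0 <- if (k <= 2L) 64L else 12L
  n0 <- min(n0, plan$N)
  # incumbent from a coarse exact sublattice
  pvals <- unique(round(seq(0, plan$N, length.out = n0 + 1L)))
  p_mat <- as.matrix(expand.grid(rep(list(pvals), k), KEEP.OUT.ATTRS = FALSE))
  colnames(p_mat) <- plan$ids
  vals <- lattice_value(mech, point, plan, p_mat)
  best <- which.max(vals)
  lb <- vals[best]
  p_best <- p_mat[best, ]
  # breadth-first refinement
  lo <- matrix(G, 1L, k, dimnames = list(NULL, plan$ids))
  hi <- matrix(1, 1L, k, dimnames = list(NULL, plan$ids))
  min_width <- plan$width
  for (depth in seq_len(max_depth)) {
    widths <- hi - lo
    widest <- max(widths)
    if (widest <= min_width || nrow(lo) > max_boxes) break
    split_dim <- apply(widths, 1L, which.max)
    mid <- (lo[cbind(seq_len(nrow(lo)), split_dim)] +
              hi[cbind(seq_len(nrow(lo)), split_dim)]) / 2
    lo1 <- lo; hi1 <- hi
    hi1[cbind(seq_len(nrow(lo)), split_dim)] <- mid
    lo2 <- lo; hi2 <- hi
    lo2[cbind(seq_len(nrow(lo)), split_dim)] <- mid
    lo <- rbind(lo1, lo2); hi <- rbind(hi1, hi2)
    gb <- box_gamma_bounds(plan, lo, hi)
    ok <- box_feasible(plan, lo, hi, gb)
    ub_box <- rep(-Inf, nrow(lo))
    ub_box[ok] <- box_upper_value(mech, point, plan, lo[ok, , drop = FALSE],
                                  hi[ok, , drop = FALSE],
                                  list(lo = gb$lo[ok, , drop = FALSE],
                                       hi = gb$hi[ok, , drop = FALSE]))
    # refresh the incumbent from box-center lattice points (every few
    # rounds; the bound sweep itself is the expensive part)
    if (any(ok) && (depth %% 3L == 0L || depth == max_depth)) {
      centers <- round(((lo[ok, , drop = FALSE] + hi[ok, , drop = FALSE]) / 2 - G) /
                         plan$width)
      centers <- pmin(pmax(centers, 0), plan$N)
      cv <- lattice_value(mech, point, plan, centers)
      cb <- which.max(cv)
      if (length(cb) && cv[cb] > lb) {
        lb <- cv[cb]
        p_best <- centers[cb, ]
      }
    }
    keep <- ub_box >= keep_factor * lb * (1 - 1e-12)
    lo <- lo[keep, , drop = FALSE]
    hi <- hi[keep, , drop = FALSE]
    if (nrow(lo) == 0L) break  # numerical corner: fall back to incumbent box
  }
  if (nrow(lo) == 0L) {
    win <- data.frame(id = plan$ids,
                      p_lo = pmax(0L, as.integer(p_best) - 2L),
                      p_hi = pmin(plan$N, as.integer(p_best) + 2L))
    return(list(windows = win, lb = lb, ub = lb, p_best = p_best))
  }
  # exact refinement: the optimum is certified to lie in a surviving box, so
  # enumerating the (few) lattice points they cover yields the exact lattice
  # optimum; with that incumbent the boxes are pruned once more before the
  # per-variable hull is formed
  gb <- box_gamma_bounds(plan, lo, hi)
  ub_box <- box_upper_value(mech, point, plan, lo, hi, gb)
  exact <- FALSE
  if (keep_factor == 1) {
    # vectorized enumeration of the lattice points covered by the boxes
    plo <- matrix(pmax(0, floor((lo - G) / plan$width - 1e-9)), nrow(lo), k)
    phi <- matrix(pmin(plan$N, ceiling((hi - G) / plan$width + 1e-9)), nrow(lo), k)
    len <- phi - plo + 1
    n_per_box <- .rowProds(len)
    n_combos <- sum(n_per_box)
    if (n_combos <= max_enum) {
      ib <- rep(seq_len(nrow(lo)), n_per_box)
      j <- sequence(n_per_box) - 1
      p_mat <- matrix(0, length(ib), k, dimnames = list(NULL, plan$ids))
      stride <- rep(1, nrow(lo))
      for (d in seq_len(k)) {
        p_mat[, d] <- plo[ib, d] + (j %/% stride[ib]) %% len[ib, d]
        stride <- stride * len[, d]
      }
      key <- p_mat[, 1L]
      for (d in seq_len(k)[-1L]) key <- key * (plan$N + 1) + p_mat[, d]
      p_mat <- p_mat[!duplicated(key), , drop = FALSE]
      # chunked evaluation bounds the working-set size
      vals <- numeric(nrow(p_mat))
      chunk <- 400000L
      for (start in seq(1L, nrow(p_mat), by = chunk)) {
        idx <- start:min(start + chunk - 1L, nrow(p_mat))
        vals[idx] <- lattice_value(mech, point, plan, p_mat[idx, , drop = FALSE])
      }
      best <- which.max(vals)
      if (is.finite(vals[best]) && vals[best] >= lb) {
        lb <- vals[best]
        p_best <- p_mat[best, ]
        exact <- TRUE
        # hull of the optimal tie set: every bin assignment whose value ties
        # the optimum within 1e-8 relative (an order wider than the slack
        # used when the objective is pinned for variability analysis)
        ties <- p_mat[vals >= lb * (1 - 1e-8), , drop = FALSE]
        win <- data.frame(
          id = plan$ids,
          p_lo = apply(ties, 2L, min),
          p_hi = apply(ties, 2L, max)
        )
        return(list(windows = win, lb = lb, ub = lb, p_best = p_best,
                    exact = TRUE))
      }
    }
  }
  win <- data.frame(
    id = plan$ids,
    p_lo = pmax(0L, floor((apply(lo, 2L, min) - G) / plan$width - 1e-9)),
    p_hi = pmin(plan$N, ceiling((apply(hi, 2L, max) - G) / plan$width + 1e-9))
  )
  list(windows = win, lb = lb, ub = max(ub_box), p_best = p_best,
       exact = exact)
}

.rowProds <- function(m) {
  out <- rep(1, nrow(m))
  for (d in seq_len(ncol(m))) out <- out * m[, d]
  out
}
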