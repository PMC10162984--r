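#' Discretization plan for the elementary displacements
#'
#' Chooses the independent displacement variables (or mechanistically
#' meaningful combinations of them), the number of bins N used for their
#' piecewise-constant approximation, and the expression of every elementary
#' displacement in terms of the independent set, such that the route and
#' cycle products equal the overall displacement identically.
#'
#' For an unbranched mechanism with steps (s1, ..., sk) the independent set
#' is the nested chain of cumulative products g_{s1}, g_{s1 s2}, ...,
#' g_{s1..s(k-1)} with gamma_{s1} = g_{s1}, gamma_{si} = g_{s1..si} /
#' g_{s1..s(i-1)} and gamma_{sk} = Gamma / g_{s1..s(k-1)}, plus the ordering
#' constraints g_{s1..si} <= g_{s1..s(i-1)}.  For a two-route mechanism the
#' set contains a chain per branch, the shared branch (cycle) product, and
#' one variable per trunk step except the last, whose displacement carries
#' the remaining overall displacement: for the random-ordered Bi-Uni this is
#' exactly (g_cycle, g_1, g_5, g_3) with gamma_2 = g_cycle/g_1, gamma_6 =
#' g_cycle/g_5, gamma_4 = Gamma/(g_cycle g_3), the orderings g_cycle <= g_1,
#' g_cycle <= g_5 and the floor g_cycle * g_3 >= Gamma.
#'
#' @param mech an `enz_mechanism`.
#' @param gamma_overall overall displacement Gamma, in (0, 1).
#' @param resolution target bin width (1 - Gamma)/N.  Default 1e-4 for
#'   unbranched mechanisms and 1e-3 for branched ones; tightened to 1e-4
#'   whenever Gamma >= 0.9 (close to equilibrium the displacement range is
#'   narrow and cheap to refine).
#' @return object of class `enz_plan`: list with `ids`, `N`, `nbits`,
#'   `width`, `gamma`, `expressions` (per step: `pow`, `num`, `den`),
#'   `ordering` (pairs c(smaller, larger)), `product_floor` (id sets whose
#'   product must stay >= Gamma), `resolution`.
#' @export
discretization_plan <- function(mech, gamma_overall, resolution = NULL) {
  G <- gamma_overall
  if (!is.finite(G) || G <= 0 || G >= 1) {
    stop("gamma_overall must lie strictly between 0 and 1")
  }
  branched <- length(mech$routes) > 1L
  if (is.null(resolution)) resolution <- if (branched) 1e-3 else 1e-4
  if (G >= 0.9) resolution <- min(resolution, 1e-4)
  degenerate <- FALSE
  if (resolution >= 1 - G) {
    warning("resolution >= 1 - Gamma: single-bin degenerate plan")
    degenerate <- TRUE
  }
  N <- max(1L, as.integer(ceiling((1 - G) / resolution - 1e-9)))
  nbits <- max(1L, as.integer(ceiling(log2(N + 1))))

  st <- mech$steps
  expressions <- stats::setNames(vector("list", mech$n_e), as.character(st$index))
  ordering <- list()
  product_floor <- list()
  ids <- character(0)

  chain_id <- function(steps) paste0("g", paste(steps, collapse = "_"))

  if (!branched) {
    route <- mech$routes[[1L]]
    k <- length(route)
    if (k < 2L) stop("mechanism route has fewer than two steps")
    prev <- NULL
    for (j in seq_len(k - 1L)) {
      id <- chain_id(route[seq_len(j)])
      ids <- c(ids, id)
      expressions[[as.character(route[j])]] <-
        list(pow = 0L, num = id, den = prev)
      if (!is.null(prev)) ordering[[length(ordering) + 1L]] <- c(id, prev)
      prev <- id
    }
    expressions[[as.character(route[k])]] <- list(pow = 1L, num = NULL, den = prev)
  } else {
    if (length(mech$routes) != 2L) {
      stop("no default discretization plan for mechanisms with more than two routes; ",
           "supply one explicitly")
    }
    cls <- two_route_classes(mech)
    cyc <- "gcycle"
    branch_chain <- function(steps) {
      # chain within a branch; the full branch product is the shared cycle id
      prev <- NULL
      m <- length(steps)
      for (j in seq_len(m)) {
        if (j < m) {
          id <- chain_id(steps[seq_len(j)])
          ids <<- c(ids, id)
        } else id <- cyc
        expressions[[as.character(steps[j])]] <<-
          list(pow = 0L, num = id, den = prev)
        if (!is.null(prev)) ordering[[length(ordering) + 1L]] <<- c(id, prev)
        prev <- id
      }
    }
    # order branch steps as they appear on their route
    up <- mech$routes[[which(vapply(mech$routes, function(r) all(cls$up %in% r), logical(1)))[1L]]]
    lo <- mech$routes[[which(vapply(mech$routes, function(r) all(cls$low %in% r), logical(1)))[1L]]]
    branch_chain(up[up %in% cls$up])
    branch_chain(lo[lo %in% cls$low])
    ids <- c(ids, cyc)
    trunk <- up[up %in% cls$trunk]
    k <- length(trunk)
    if (k == 0L) stop("two-route mechanism without trunk steps is not supported")
    if (k > 2L) {
      stop("default plan supports at most two trunk steps ",
           "(composite products of more than two expansions are not linearized)")
    }
    if (k == 2L) {
      id3 <- chain_id(trunk[1L])
      ids <- c(ids, id3)
      expressions[[as.character(trunk[1L])]] <- list(pow = 0L, num = id3, den = NULL)
      expressions[[as.character(trunk[2L])]] <- list(pow = 1L, num = NULL, den = c(cyc, id3))
      product_floor[[length(product_floor) + 1L]] <- c(cyc, id3)
    } else {
      expressions[[as.character(trunk[1L])]] <- list(pow = 1L, num = NULL, den = cyc)
    }
  }

  structure(
    list(ids = ids, N = N, nbits = nbits, width = (1 - G) / N, gamma = G,
         expressions = expressions, ordering = ordering,
         product_floor = product_floor, resolution = resolution,
         degenerate = degenerate),
    class = "enz_plan"
  )
}

#' Decode a binary bin choice into a displacement value
#'
#' g = Gamma + p (1 - Gamma) / N with p the binary expansion
#' sum(2^s delta_s); p may not exceed N, so g covers [Gamma, 1] inclusive.
#'
#' @param plan an `enz_plan`.
#' @param id independent-variable identifier (unused beyond validation; all
#'   identifiers share the same bin count).
#' @param delta_bits 0/1 vector, least significant bit first.
#' @return the displacement value.
#' @export
encode_displacement <- function(plan, id, delta_bits) {
  if (!id %in% plan$ids) stop("unknown independent displacement id: ", id)
  if (length(delta_bits) > plan$nbits) {
    stop("bit vector longer than the plan's ", plan$nbits, " bits")
  }
  p <- sum(2^(seq_along(delta_bits) - 1L) * delta_bits)
  if (p > plan$N) stop("binary expansion exceeds the bin count N")
  plan$gamma + p * (1 - plan$gamma) / plan$N
}

# evaluate per-step displacements for one named vector of independent values
plan_gamma_values <- function(plan, hat) {
  grid <- as.data.frame(as.list(hat))
  drop(plan_gamma_matrix(plan, grid))
}

#' @export
print.enz_plan <- function(x, ...) {
  cat(sprintf("Displacement discretization: %d independent variable(s), N = %d bins (%d bits), width %.3g\n",
              length(x$ids), x$N, x$nbits, x$width))
  cat("  independent:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}
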