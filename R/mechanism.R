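#' Elementary enzyme mechanisms as typed state graphs
#'
#' A mechanism is a set of enzyme states (one of which is the free enzyme)
#' connected by reversible elementary steps.  Each step may bind a species
#' when it runs forward (association) and/or release one that is re-bound when
#' it runs backward.  The constructor derives the route structure of the
#' graph: the set of simple catalytic routes from the free enzyme back to
#' itself, the unbranched step set `M` (steps common to all routes), the
#' branch combinations `B` (sets containing one step per parallel branch,
#' whose net fluxes sum to the overall net flux), and the fundamental branch
#' cycles along which microscopic reversibility couples the elementary
#' displacements.
#'
#' @param steps data.frame with columns `index` (integer 1..N_e), `from`,
#'   `to` (state labels, forward direction = direction of net product
#'   formation), `forward_binds`, `backward_binds` (species labels or `NA`).
#' @param free_state label of the unbound enzyme state.
#' @return An object of class `enz_mechanism`: list with `states`,
#'   `free_state`, `steps`, `n_e`, `n_states`, `n_b`, `routes`,
#'   `unbranched_steps`, `branch_combinations`, `fundamental_cycles`,
#'   `substrates`, `products`.
#' @examples
#' m <- mech_uni_uni()
#' m$unbranched_steps
#' @export
mechanism <- function(steps, free_state) {
  steps <- as.data.frame(steps, stringsAsFactors = FALSE)
  required <- c("index", "from", "to")
  if (!all(required %in% names(steps))) {
    stop("`steps` needs columns: ", paste(required, collapse = ", "))
  }
  if (is.null(steps$forward_binds)) steps$forward_binds <- NA_character_
  if (is.null(steps$backward_binds)) steps$backward_binds <- NA_character_
  steps$index <- as.integer(steps$index)
  steps <- steps[order(steps$index), , drop = FALSE]
  rownames(steps) <- NULL
  steps$forward_order <- ifelse(is.na(steps$forward_binds), 1L, 2L)
  steps$backward_order <- ifelse(is.na(steps$backward_binds), 1L, 2L)

  states <- unique(c(steps$from, steps$to))
  if (!free_state %in% states) {
    stop("free_state '", free_state, "' does not appear in any step")
  }

  routes <- enumerate_routes(steps, free_state)
  n_e <- nrow(steps)
  n_states <- length(states)

  mech <- structure(
    list(
      states = states,
      free_state = free_state,
      steps = steps,
      n_e = n_e,
      n_states = n_states,
      n_b = n_e - n_states,
      routes = routes,
      unbranched_steps = route_intersection(routes),
      branch_combinations = derive_branch_combinations(routes, steps),
      fundamental_cycles = NULL,
      substrates = unique(steps$forward_binds[!is.na(steps$forward_binds)]),
      products = unique(steps$backward_binds[!is.na(steps$backward_binds)])
    ),
    class = "enz_mechanism"
  )
  mech$fundamental_cycles <- find_fundamental_cycles(mech)
  mech
}

# Depth-first enumeration of simple catalytic routes: closed walks that leave
# the free state once and return to it, never revisiting an intermediate
# state.  Steps are traversed in their forward direction only (forward is the
# direction of net product formation by convention).
enumerate_routes <- function(steps, free_state) {
  routes <- list()
  walk <- function(state, used_steps, visited) {
    outgoing <- which(steps$from == state)
    for (j in outgoing) {
      nxt <- steps$to[j]
      if (nxt == free_state) {
        routes[[length(routes) + 1L]] <<- c(used_steps, steps$index[j])
      } else if (!nxt %in% visited) {
        walk(nxt, c(used_steps, steps$index[j]), c(visited, nxt))
      }
    }
  }
  walk(free_state, integer(0), free_state)
  routes
}

route_intersection <- function(routes) {
  if (length(routes) == 0L) return(integer(0))
  out <- routes[[1L]]
  for (r in routes[-1L]) out <- intersect(out, r)
  sort(out)
}

# Branch combinations B: every set of non-common steps that intersects each
# route exactly once.  Candidates are built as one step per route (cartesian
# product over the per-route branch segments) and then filtered.
derive_branch_combinations <- function(routes, steps) {
  if (length(routes) <= 1L) return(list())
  common <- route_intersection(routes)
  per_route <- lapply(routes, function(r) setdiff(r, common))
  combos <- expand.grid(per_route, KEEP.OUT.ATTRS = FALSE)
  sets <- unique(apply(combos, 1L, function(x) sort(unique(as.integer(x))),
                       simplify = FALSE))
  keep <- vapply(sets, function(s) {
    all(vapply(routes, function(r) length(intersect(s, r)) == 1L, logical(1)))
  }, logical(1))
  sets[keep]
}

#' Fundamental branch cycles of a mechanism
#'
#' Returns the independent closed cycles of the state graph that do not pass
#' through the overall catalytic turnover, i.e. the loops created by parallel
#' branches.  Each cycle is a signed step sequence (positive = traversed
#' forward); the product of elementary displacements with these signs equals 1
#' around each cycle, which together with the route product equal to the
#' overall displacement expresses microscopic reversibility.  Unbranched
#' mechanisms have none.
#'
#' @param mech an `enz_mechanism`.
#' @return list of data.frames with columns `index` and `sign`.
#' @export
find_fundamental_cycles <- function(mech) {
  g <- mechanism_graph(mech)
  if (!igraph::is_connected(g, mode = "weak")) {
    stop("invalid mechanism: state graph is disconnected")
  }
  routes <- mech$routes
  if (length(routes) <= 1L) return(list())
  ref <- routes[[1L]]
  lapply(routes[-1L], function(r) {
    fwd <- data.frame(index = r, sign = 1L)
    bwd <- data.frame(index = rev(ref), sign = -1L)
    cyc <- rbind(fwd, bwd)
    # cancel steps traversed once in each direction (shared trunk)
    drop <- integer(0)
    for (i in seq_len(nrow(cyc))) {
      if (i %in% drop || cyc$sign[i] != 1L) next
      j <- setdiff(which(cyc$index == cyc$index[i] & cyc$sign == -1L), drop)
      if (length(j)) drop <- c(drop, i, j[1L])
    }
    if (length(drop)) cyc <- cyc[-drop, , drop = FALSE]
    rownames(cyc) <- NULL
    cyc
  })
}

mechanism_graph <- function(mech) {
  igraph::graph_from_data_frame(
    mech$steps[, c("from", "to")],
    directed = TRUE,
    vertices = data.frame(name = mech$states)
  )
}

#' Validate a mechanism
#'
#' Checks the structural invariants of a mechanism and returns diagnostics
#' rather than raising on content errors.
#'
#' @param mech an `enz_mechanism`.
#' @return character vector of diagnostics; empty when the mechanism is valid.
#' @export
validate_mechanism <- function(mech) {
  out <- character(0)
  st <- mech$steps
  if (anyDuplicated(st$index)) out <- c(out, "duplicate step indices")
  if (anyDuplicated(mech$states)) out <- c(out, "duplicate state ids")
  if (sum(mech$states == mech$free_state) != 1L) {
    out <- c(out, "multiple free states")
  }
  same <- !is.na(st$forward_binds) & !is.na(st$backward_binds) &
    st$forward_binds == st$backward_binds
  if (any(same)) {
    out <- c(out, sprintf("step %d binds the same species in both directions",
                          st$index[same]))
  }
  bad_order <- (st$forward_order == 2L) != !is.na(st$forward_binds) |
    (st$backward_order == 2L) != !is.na(st$backward_binds)
  if (any(bad_order)) {
    out <- c(out, sprintf("step %d order/binding mismatch", st$index[bad_order]))
  }
  if (mech$n_states != mech$n_e - mech$n_b) out <- c(out, "state count mismatch")
  if (length(out)) return(out)  # graph checks need structurally sound input
  g <- mechanism_graph(mech)
  if (!igraph::is_connected(g, mode = "weak")) out <- c(out, "disconnected state graph")
  if (length(mech$routes) == 0L) out <- c(out, "no catalytic route through the free state")
  for (bk in mech$branch_combinations) {
    cuts <- vapply(mech$routes, function(r) length(intersect(bk, r)) == 1L, logical(1))
    if (!all(cuts)) {
      out <- c(out, sprintf("branch combination {%s} does not cut all routes",
                            paste(bk, collapse = ",")))
    }
  }
  for (cyc in mech$fundamental_cycles) {
    if (!cycle_conserves_state(mech, cyc)) {
      out <- c(out, "fundamental cycle does not return to its start state")
    }
  }
  out
}

cycle_conserves_state <- function(mech, cyc) {
  if (nrow(cyc) == 0L) return(TRUE)
  st <- mech$steps
  pos <- match(cyc$index, st$index)
  here <- if (cyc$sign[1L] == 1L) st$from[pos[1L]] else st$to[pos[1L]]
  start <- here
  for (i in seq_len(nrow(cyc))) {
    expected <- if (cyc$sign[i] == 1L) st$from[pos[i]] else st$to[pos[i]]
    if (!identical(here, expected)) return(FALSE)
    here <- if (cyc$sign[i] == 1L) st$to[pos[i]] else st$from[pos[i]]
  }
  identical(here, start)
}

#' Built-in mechanisms
#'
#' `mech_uni_uni()` is the three-step reversible Michaelis-Menten scheme
#' (E + S = ES = EP = E + P).  `mech_ordered_bi_uni()` is the compulsory-order
#' Bi-Uni scheme (A binds before B).  `mech_random_bi_uni()` is the
#' random-ordered Bi-Uni scheme in which either substrate may bind first,
#' giving one branching point and a single fundamental cycle coupling the two
#' binding orders.
#'
#' @return an `enz_mechanism`.
#' @export
mech_uni_uni <- function() {
  mechanism(
    data.frame(
      index = 1:3,
      from = c("E", "ES", "EP"),
      to = c("ES", "EP", "E"),
      forward_binds = c("S", NA, NA),
      backward_binds = c(NA, NA, "P")
    ),
    free_state = "E"
  )
}

#' @rdname mech_uni_uni
#' @export
mech_ordered_bi_uni <- function() {
  mechanism(
    data.frame(
      index = 1:4,
      from = c("E", "EA", "EAB", "EP"),
      to = c("EA", "EAB", "EP", "E"),
      forward_binds = c("A", "B", NA, NA),
      backward_binds = c(NA, NA, NA, "P")
    ),
    free_state = "E"
  )
}

#' @rdname mech_uni_uni
#' @export
mech_random_bi_uni <- function() {
  mechanism(
    data.frame(
      index = 1:6,
      from = c("E", "EA", "EAB", "EP", "E", "EB"),
      to = c("EA", "EAB", "EP", "E", "EB", "EAB"),
      forward_binds = c("A", "B", NA, NA, "B", "A"),
      backward_binds = c(NA, NA, NA, "P", NA, NA)
    ),
    free_state = "E"
  )
}

#' Reverse a mechanism
#'
#' Flips every elementary step so that the written scheme runs toward
#' substrate production: `from`/`to` states, binding annotations and
#' molecularities are swapped while step indices are preserved.  Used
#' together with [reverse_point()] to solve reactions whose overall
#' displacement exceeds 1 in the forward convention.
#'
#' @param mech an `enz_mechanism`.
#' @return the reversed `enz_mechanism`.
#' @export
reverse_mechanism <- function(mech) {
  st <- mech$steps
  mechanism(
    data.frame(
      index = st$index,
      from = st$to,
      to = st$from,
      forward_binds = st$backward_binds,
      backward_binds = st$forward_binds
    ),
    free_state = mech$free_state
  )
}

#' Mechanism JSON serialization
#'
#' Writes the declarative description (states and steps); all derived fields
#' (routes, unbranched set, branch combinations, cycles) are recomputed on
#' load, never trusted from file.
#'
#' @param mech an `enz_mechanism`.
#' @param path file path; for `mech_to_json` with `path = NULL` the JSON
#'   string is returned.
#' @return `mech_from_json` returns an `enz_mechanism`.
#' @export
mech_to_json <- function(mech, path = NULL) {
  obj <- list(
    states = data.frame(id = mech$states,
                        is_free = mech$states == mech$free_state),
    steps = mech$steps[, c("index", "from", "to",
                           "forward_binds", "backward_binds")]
  )
  json <- jsonlite::toJSON(obj, dataframe = "rows", na = "null",
                           auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname mech_to_json
#' @export
mech_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  free <- obj$states$id[obj$states$is_free]
  if (length(free) != 1L) stop("mechanism JSON must have exactly one free state")
  steps <- obj$steps
  for (col in c("forward_binds", "backward_binds")) {
    if (is.null(steps[[col]])) steps[[col]] <- NA_character_
    steps[[col]][steps[[col]] %in% c("", "null")] <- NA_character_
  }
  mechanism(steps, free_state = free)
}

#' @export
print.enz_mechanism <- function(x, ...) {
  cat(sprintf("Elementary mechanism: %d states, %d steps, %d branching point(s)\n",
              x$n_states, x$n_e, x$n_b))
  st <- x$steps
  for (i in seq_len(nrow(st))) {
    lhs <- st$from[i]
    if (!is.na(st$forward_binds[i])) lhs <- paste(lhs, "+", st$forward_binds[i])
    rhs <- st$to[i]
    if (!is.na(st$backward_binds[i])) rhs <- paste(rhs, "+", st$backward_binds[i])
    cat(sprintf("  %d: %s <-> %s\n", st$index[i], lhs, rhs))
  }
  invisible(x)
}
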