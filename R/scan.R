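#' Specification of a concentration-space scan
#'
#' @param mechanism a mechanism name ("uni_uni", "ordered_bi_uni",
#'   "random_bi_uni"), a path to a mechanism JSON file, or an
#'   `enz_mechanism`.
#' @param axes named list: species id -> vector of dimensionless
#'   concentrations to scan over (full factorial).
#' @param fixed named vector of fixed dimensionless concentrations.
#' @param keq dimensionless equilibrium constant.
#' @param resolution displacement bin width (NULL = per-mechanism default).
#' @param outputs quantities to report: subset of "sigma", "alpha", "k",
#'   "e", "gamma", "dg_fractions".
#' @param variability "none" or "alpha" (adds the splitting-ratio interval
#'   per point; branched mechanisms only).
#' @param paired traverse the axes in parallel (one point per index) instead
#'   of over their full factorial.
#' @param seed integer seed recorded in the provenance block and used for
#'   any stochastic post-processing.
#' @return object of class `enz_scan_spec`.
#' @export
scan_spec <- function(mechanism, axes, fixed = c(), keq,
                      resolution = NULL,
                      outputs = c("sigma", "alpha"),
                      variability = c("none", "alpha"),
                      paired = FALSE, seed = 1L) {
  if (length(axes) == 0L) stop("`axes` must name at least one species")
  if (paired && length(unique(lengths(axes))) != 1L) {
    stop("paired axes must all have the same length")
  }
  structure(
    list(mechanism = mechanism, axes = axes, fixed = fixed, keq = keq,
         resolution = resolution, outputs = outputs,
         variability = match.arg(variability), paired = paired,
         seed = as.integer(seed)),
    class = "enz_scan_spec"
  )
}

resolve_mechanism <- function(mechanism) {
  if (inherits(mechanism, "enz_mechanism")) return(mechanism)
  if (is.character(mechanism) && length(mechanism) == 1L) {
    builders <- list(uni_uni = mech_uni_uni,
                     ordered_bi_uni = mech_ordered_bi_uni,
                     random_bi_uni = mech_random_bi_uni)
    if (mechanism %in% names(builders)) return(builders[[mechanism]]())
    if (file.exists(mechanism)) return(mech_from_json(mechanism))
  }
  stop("unknown mechanism: supply a built-in name, a JSON file or an enz_mechanism")
}

#' Run a grid scan over concentration space
#'
#' Solves the optimization at every point of the factorial grid defined by
#' the scan specification and assembles the reported quantities.  Points at
#' (or numerically on) equilibrium are flagged and carry zero flux; points
#' beyond equilibrium are solved in the reverse direction.  Per-point solver
#' failures are recorded in the `status` column and the scan continues.
#'
#' @param spec an `enz_scan_spec`.
#' @return object of class `enz_scan`: list with `points` (one row per grid
#'   point: concentrations, gamma, direction, status, v_net, sigma, alpha
#'   and, when requested, alpha_min/alpha_max/alpha_flexible) and `values`
#'   (long format: point id, quantity, key, value) plus a provenance
#'   attribute.
#' @export
run_scan <- function(spec) {
  mech <- resolve_mechanism(spec$mechanism)
  grid <- if (isTRUE(spec$paired)) {
    as.data.frame(spec$axes)
  } else {
    expand.grid(spec$axes, KEEP.OUT.ATTRS = FALSE)
  }
  n <- nrow(grid)
  rows <- vector("list", n)
  longs <- vector("list", n)
  for (ix in seq_len(n)) {
    conc <- c(unlist(grid[ix, , drop = FALSE]), spec$fixed)
    base <- as.list(grid[ix, , drop = FALSE])
    names(base) <- names(spec$axes)
    row <- c(list(point = ix), base)
    long <- NULL
    res <- tryCatch({
      pt <- operating_point(mech, conc, keq = spec$keq)
      row$gamma_overall <- pt$gamma
      if (pt$equilibrium) {
        row <- c(row, list(direction = "equilibrium", status = "equilibrium",
                           v_net = 0, sigma = NA_real_, alpha = NA_real_))
      } else {
        need_model <- spec$variability == "alpha"
        sol <- solve_optimal(mech, pt, resolution = spec$resolution,
                             keep_model = need_model)
        smech <- sol$mech
        row$direction <- if (isTRUE(sol$reversed)) "reverse" else "forward"
        row$status <- sol$status
        row$v_net <- sol$v_net_signed
        row$sigma <- if ("sigma" %in% spec$outputs) saturation(sol, smech) else NA_real_
        row$alpha <- if ("alpha" %in% spec$outputs && length(smech$routes) > 1L) {
          splitting_ratio(sol, smech)
        } else NA_real_
        if (need_model && length(smech$routes) > 1L) {
          av <- alpha_variability(sol$model, sol)
          row$alpha_min <- av$alpha_min
          row$alpha_max <- av$alpha_max
          row$alpha_flexible <- isTRUE(av$width > 10 * 1e-6)
        }
        long <- scan_long_values(ix, sol, smech, spec$outputs, pt)
      }
      TRUE
    }, error = function(e) {
      row$status <<- paste0("error: ", conditionMessage(e))
      FALSE
    })
    rows[[ix]] <- as.data.frame(row, check.names = FALSE)
    longs[[ix]] <- long
  }
  points <- do.call(rbind_fill, rows)
  values <- do.call(rbind, longs)
  structure(
    list(points = points, values = values),
    provenance = list(package = "enzopt",
                      version = as.character(utils::packageVersion("enzopt")),
                      solver = "scipy-highs", seed = spec$seed,
                      resolution = spec$resolution,
                      timestamp = format(Sys.time(), tz = "UTC")),
    class = "enz_scan"
  )
}

# rbind for data.frames with unequal columns (missing -> NA)
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  filled <- lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, filled)
}

scan_long_values <- function(ix, sol, mech, outputs, pt) {
  out <- list()
  add <- function(quantity, keys, vals) {
    out[[length(out) + 1L]] <<- data.frame(point = ix, quantity = quantity,
                                           key = as.character(keys),
                                           value = as.numeric(vals))
  }
  if ("k" %in% outputs) {
    k <- back_calculate_k(sol, mech)
    add("k_f", k$index, k$k_f)
    add("k_b", k$index, k$k_b)
  }
  if ("e" %in% outputs) add("e", names(sol$e), sol$e)
  if ("gamma" %in% outputs) add("gamma", names(sol$gamma), sol$gamma)
  if ("dg_fractions" %in% outputs) {
    add("dg_fraction", names(sol$gamma), dg_fractions(sol, pt$gamma))
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Points along an iso-displacement line
#'
#' For a uni-uni reaction the overall displacement fixes the concentration
#' ratio: P/S = Gamma * Keq.  Returns `n` points log-spaced in S along the
#' line.
#'
#' @param gamma_target overall displacement in (0, 1].
#' @param keq equilibrium constant.
#' @param n number of points.
#' @param s_range range of substrate concentrations (dimensionless).
#' @return data.frame with columns `S`, `P` and attribute `equilibrium`
#'   flag when gamma_target = 1.
#' @export
isoline_points <- function(gamma_target, keq, n = 3, s_range = c(0.1, 10)) {
  if (gamma_target <= 0 || gamma_target > 1) {
    stop("gamma_target must lie in (0, 1]")
  }
  s <- 10^seq(log10(s_range[1L]), log10(s_range[2L]), length.out = n)
  out <- data.frame(S = s, P = gamma_target * keq * s)
  attr(out, "equilibrium") <- gamma_target == 1
  out
}

#' Deterministic fixture specifications for the test-suite
#'
#' Small canned scans plus a manifest of which invariant each one exercises.
#'
#' @param seed integer seed embedded in each spec.
#' @return named list of `enz_scan_spec` objects with a `manifest`
#'   attribute.
#' @export
fixture_suite <- function(seed = 1L) {
  fixtures <- list(
    uni_uni_oracle = scan_spec(
      "uni_uni",
      axes = list(S = c(0.1, 0.5, 1, 3, 10)),
      fixed = c(P = 1), keq = 2, resolution = 1e-4,
      outputs = c("sigma", "e", "gamma"), seed = seed
    ),
    bi_uni_antisymmetry = scan_spec(
      "random_bi_uni",
      axes = list(A = c(0.2, 5), B = c(0.2, 5)),
      fixed = c(P = 1), keq = 2, resolution = 1e-3,
      outputs = c("sigma", "alpha"), seed = seed
    ),
    equilibrium_line = scan_spec(
      "uni_uni",
      axes = list(S = c(0.5, 1, 2), P = 2 * c(0.5, 1, 2)),
      keq = 2, resolution = 1e-4,
      outputs = "sigma", paired = TRUE, seed = seed
    )
  )
  attr(fixtures, "manifest") <- data.frame(
    fixture = c("uni_uni_oracle", "bi_uni_antisymmetry", "equilibrium_line"),
    invariant = c("objective matches displacement-grid oracle",
                  "alpha(A,B) + alpha(B,A) = 1",
                  "net flux is exactly zero at equilibrium")
  )
  fixtures
}

#' Write scan results to long-format CSV
#'
#' One file with the per-point scalars and one long-format file with the
#' vector quantities; the provenance block goes into a JSON sidecar.
#'
#' @param scan an `enz_scan`.
#' @param path base path (without extension).
#' @return invisibly, the paths written.
#' @export
write_scan_csv <- function(scan, path) {
  p1 <- paste0(path, "_points.csv")
  utils::write.csv(scan$points, p1, row.names = FALSE)
  paths <- p1
  if (!is.null(scan$values)) {
    p2 <- paste0(path, "_values.csv")
    utils::write.csv(scan$values, p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  jsonlite::write_json(attr(scan, "provenance"), paste0(path, "_provenance.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}

#' @export
print.enz_scan <- function(x, ...) {
  cat(sprintf("Concentration scan: %d points\n", nrow(x$points)))
  print(utils::head(x$points, 10))
  if (nrow(x$points) > 10) cat("  ...\n")
  invisible(x)
}
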