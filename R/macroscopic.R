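#' Macroscopic kinetic parameters from in-silico initial-rate experiments
#'
#' Titrates one substrate over a log-spaced grid at vanishing product
#' concentration (and mirrored for the reverse direction), computes the
#' initial net rate from the mass-action steady state, and fits the
#' rectangular hyperbola v = kcat * S / (Km + S) by least squares.  The grid
#' is placed in two passes: a wide first pass, then 12 log-spaced points
#' spanning 0.01-100 times the first-pass Km estimate.  For multi-substrate
#' mechanisms the co-substrates are held at a saturating concentration.
#'
#' @param mech an `enz_mechanism`.
#' @param rates data.frame `index`, `k_f`, `k_b` (normalized constants).
#' @param titrate species to titrate; default the first substrate (forward)
#'   and the first product (reverse).
#' @param co_conc saturating dimensionless concentration for co-substrates.
#' @param residual_warn relative residual norm above which a warning about
#'   non-hyperbolic behaviour is issued.
#' @return object of class `enz_macroscopics`: list with `kcat_f`, `km_s`,
#'   `kcat_b`, `km_p`, `titrate_f`, `titrate_b`, `residual_f`, `residual_b`,
#'   `haldane_keq` (the ratio (kcat_f/Km_S)/(kcat_b/Km_P)).
#' @export
initial_rate_macroscopics <- function(mech, rates, titrate = NULL,
                                      co_conc = 1e3, residual_warn = 1e-3) {
  subs <- mech$substrates
  prods <- mech$products
  tit_f <- if (is.null(titrate)) subs[1L] else titrate
  tit_b <- prods[1L]

  fwd <- fit_initial_rates(mech, rates, tit_f,
                           zero_species = prods,
                           co_species = setdiff(subs, tit_f),
                           co_conc = co_conc, residual_warn = residual_warn)
  rev_mech <- reverse_mechanism(mech)
  bwd <- fit_initial_rates(rev_mech,
                           data.frame(index = rates$index,
                                      k_f = rates$k_b, k_b = rates$k_f),
                           tit_b,
                           zero_species = subs,
                           co_species = setdiff(prods, tit_b),
                           co_conc = co_conc, residual_warn = residual_warn)
  structure(
    list(kcat_f = fwd$kcat, km_s = fwd$km, kcat_b = bwd$kcat, km_p = bwd$km,
         titrate_f = tit_f, titrate_b = tit_b,
         residual_f = fwd$residual, residual_b = bwd$residual,
         haldane_keq = (fwd$kcat / fwd$km) / (bwd$kcat / bwd$km)),
    class = "enz_macroscopics"
  )
}

# one direction: titration + two-pass hyperbola fit
fit_initial_rates <- function(mech, rates, titrate, zero_species, co_species,
                              co_conc, residual_warn) {
  rate_at <- function(s_val) {
    conc <- stats::setNames(rep(co_conc, length(co_species)), co_species)
    conc[titrate] <- s_val
    # an exact zero product concentration is valid for the steady-state
    # solver (no displacement is formed); a tiny floor keeps Gamma finite
    # in the operating point but is not needed here
    conc[zero_species] <- 0
    pt <- structure(list(conc = pmax(conc, 0), keq = 1, gamma = 0,
                         direction = "forward", equilibrium = FALSE,
                         substrates = setdiff(names(conc), zero_species),
                         products = zero_species),
                    class = "enz_point")
    steady_state(mech, rates, pt)$v_net
  }
  fit_pass <- function(s_grid) {
    v <- vapply(s_grid, rate_at, numeric(1))
    keep <- v > 0
    s <- s_grid[keep]; v <- v[keep]
    if (length(s) < 3L) stop("initial-rate titration produced too few positive rates")
    # Hanes linearization S/v = S/kcat + Km/kcat gives exact starting values;
    # nls refinement can stall at machine precision on exactly hyperbolic
    # data, in which case the Hanes estimates already are the LS solution
    hf <- stats::lm(I(s / v) ~ s)
    kcat0 <- unname(1 / stats::coef(hf)[2L])
    km0 <- unname(stats::coef(hf)[1L] * kcat0)
    est <- c(kcat = kcat0, km = max(km0, 1e-12))
    fit <- tryCatch(
      suppressWarnings(stats::nls(v ~ kcat * s / (km + s),
                                  start = as.list(est),
                                  control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) est <- stats::coef(fit)
    resid <- v - est["kcat"] * s / (est["km"] + s)
    list(kcat = unname(est["kcat"]), km = unname(est["km"]),
         residual = sqrt(sum(resid^2)) / sqrt(sum(v^2)))
  }
  first <- fit_pass(10^seq(-2, 2, length.out = 12L))
  second <- fit_pass(first$km * 10^seq(-2, 2, length.out = 12L))
  if (second$residual > residual_warn) {
    warning(sprintf("initial-rate curve deviates from a hyperbola (relative residual %.2g)",
                    second$residual))
  }
  second
}

#' Closed-form macroscopic parameters for the three-step mechanism
#'
#' The textbook expressions for the reversible three-step uni-uni scheme in
#' normalized units: kcat_f = k2f k3f / (k2f + k2b + k3f),
#' Km_S = (k1b k2b + k1b k3f + k2f k3f) / (k1f (k2f + k2b + k3f)), and the
#' mirrored backward pair.  Serves as the independent cross-check for the
#' initial-rate fits.
#'
#' @param rates data.frame `index`, `k_f`, `k_b` for the 3-step mechanism.
#' @return list `kcat_f`, `km_s`, `kcat_b`, `km_p`, `keq`.
#' @export
uni_uni_closed_form <- function(rates) {
  k <- rates[order(rates$index), ]
  k1f <- k$k_f[1L]; k2f <- k$k_f[2L]; k3f <- k$k_f[3L]
  k1b <- k$k_b[1L]; k2b <- k$k_b[2L]; k3b <- k$k_b[3L]
  den_f <- k2f + k2b + k3f
  den_b <- k1b + k2f + k2b
  list(
    kcat_f = k2f * k3f / den_f,
    km_s = (k1b * k2b + k1b * k3f + k2f * k3f) / (k1f * den_f),
    kcat_b = k1b * k2b / den_b,
    km_p = (k3f * k2f + k3f * k1b + k2b * k1b) / (k3b * den_b),
    keq = (k1f * k2f * k3f) / (k1b * k2b * k3b)
  )
}

#' Random Haldane-consistent rate assignment
#'
#' Draws normalized rate constants uniformly in (lo, 1); the implied
#' equilibrium constant is the route product ratio prod(k_f)/prod(k_b), so
#' the assignment is thermodynamically consistent by construction.
#'
#' @param mech an `enz_mechanism`.
#' @param lo lower bound of the uniform draw (keeps constants well away
#'   from 0 so fits stay conditioned).
#' @return list `rates` (data.frame) and `keq`.
#' @export
random_rate_assignment <- function(mech, lo = 0.05) {
  st <- mech$steps
  rates <- data.frame(index = st$index,
                      k_f = stats::runif(nrow(st), lo, 1),
                      k_b = stats::runif(nrow(st), lo, 1))
  route <- mech$routes[[1L]]
  pos <- match(route, rates$index)
  keq <- prod(rates$k_f[pos]) / prod(rates$k_b[pos])
  list(rates = rates, keq = keq)
}

#' @export
print.enz_macroscopics <- function(x, ...) {
  cat(sprintf("Macroscopic parameters (normalized units)\n"))
  cat(sprintf("  forward: kcat = %.6g, Km(%s) = %.6g\n", x$kcat_f, x$titrate_f, x$km_s))
  cat(sprintf("  backward: kcat = %.6g, Km(%s) = %.6g\n", x$kcat_b, x$titrate_b, x$km_p))
  cat(sprintf("  Haldane Keq = %.6g\n", x$haldane_keq))
  invisible(x)
}
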