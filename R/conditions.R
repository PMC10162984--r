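#' Biophysical limits on elementary rate constants
#'
#' Bimolecular (association) rate constants are limited by diffusion,
#' typically 1e8-1e10 per molar per second; monomolecular (dissociation and
#' interconversion) rate constants by the frequency of molecular vibrations,
#' typically 1e4-1e6 per second.  Defaults are the geometric mid-range of the
#' two intervals.  Normalizing every rate constant by its limit confines them
#' to [0, 1].
#'
#' @param k_max_mono first-order limit (1/s).
#' @param k_max_bi second-order limit (1/(M s)).
#' @return list of class `enz_rate_limits`.
#' @export
rate_limits <- function(k_max_mono = 1e5, k_max_bi = 1e9) {
  if (k_max_mono <= 0 || k_max_bi <= 0) stop("rate-constant limits must be positive")
  structure(list(k_max_mono = k_max_mono, k_max_bi = k_max_bi),
            class = "enz_rate_limits")
}

#' Characteristic concentration
#'
#' The ratio of the monomolecular to the bimolecular rate-constant limit.  It
#' is the natural concentration unit of the normalized problem: one
#' dimensionless concentration unit is about 0.1 mM at the default limits.
#'
#' @param limits an `enz_rate_limits`.
#' @return concentration in molar.
#' @export
characteristic_concentration <- function(limits = rate_limits()) {
  limits$k_max_mono / limits$k_max_bi
}

GAS_CONSTANT_J <- 8.314 # J/(mol K)

#' Dimensionless operating point of a reaction
#'
#' Normalizes reactant concentrations and the equilibrium constant and
#' computes the overall thermodynamic displacement
#' Gamma = (1/Keq) * prod(products) / prod(substrates), the ratio of the
#' overall backward to forward rate.  Gamma < 1 means the reaction runs
#' toward products, Gamma = 1 is equilibrium.  Substrate and product roles
#' are read off the mechanism's binding annotations.
#'
#' @param mech an `enz_mechanism` defining which species are substrates
#'   (bound running forward) and products (bound running backward).
#' @param conc named numeric vector of species concentrations.  Dimensionless
#'   by default; molar when `dimensionless = FALSE`, in which case they are
#'   divided by the characteristic concentration.
#' @param keq equilibrium constant.  Dimensionless by default; when
#'   `dimensionless = FALSE` it is multiplied by the characteristic
#'   concentration raised to (number of substrates - number of products) so
#'   the displacement stays dimensionless for any stoichiometry.
#' @param dg0_kj_mol alternative to `keq`: standard Gibbs free energy of
#'   reaction in kJ/mol, converted with Keq = exp(-dG0/RT).
#' @param temperature temperature in K used for the `dg0_kj_mol` conversion.
#' @param dimensionless whether `conc` (and `keq`) are already normalized.
#' @param limits an `enz_rate_limits` used for normalization.
#' @param equilibrium_tol relative tolerance for flagging Gamma = 1.
#' @return object of class `enz_point`: list with `conc` (dimensionless),
#'   `keq`, `gamma`, `direction` ("forward"/"reverse"), `equilibrium` flag,
#'   `substrates`, `products`, `limits`.
#' @export
operating_point <- function(mech, conc, keq = NULL, dg0_kj_mol = NULL,
                            temperature = 298.15, dimensionless = TRUE,
                            limits = rate_limits(),
                            equilibrium_tol = 1e-12) {
  if (is.null(names(conc)) || any(!nzchar(names(conc)))) {
    stop("`conc` must be a named vector of species concentrations")
  }
  if (any(conc <= 0)) stop("all concentrations must be strictly positive")
  if (is.null(keq) == is.null(dg0_kj_mol)) {
    stop("supply exactly one of `keq` or `dg0_kj_mol`")
  }
  if (!is.null(dg0_kj_mol)) {
    if (temperature <= 0) stop("temperature must be positive")
    keq <- exp(-dg0_kj_mol * 1000 / (GAS_CONSTANT_J * temperature))
  }
  subs <- mech$substrates
  prods <- mech$products
  missing <- setdiff(c(subs, prods), names(conc))
  if (length(missing)) {
    stop("no concentration given for species: ", paste(missing, collapse = ", "))
  }
  if (!dimensionless) {
    cch <- characteristic_concentration(limits)
    conc <- conc / cch
    keq <- keq * cch^(length(subs) - length(prods))
  }
  gamma <- (1 / keq) * prod(conc[prods]) / prod(conc[subs])
  structure(
    list(
      conc = conc,
      keq = keq,
      gamma = gamma,
      direction = "forward",
      equilibrium = abs(gamma - 1) <= equilibrium_tol,
      substrates = subs,
      products = prods,
      limits = limits,
      temperature = temperature
    ),
    class = "enz_point"
  )
}

#' Reverse transform of an operating point
#'
#' Maps a point with overall displacement Gamma > 1 (reaction running toward
#' substrates) onto the forward convention: Gamma -> 1/Gamma, Keq -> 1/Keq,
#' substrate and product roles swap, and the direction is recorded so that
#' reported net fluxes are negated.  Applying it twice is the identity.
#' Points with Gamma <= 1 are returned unchanged with a warning.
#'
#' @param point an `enz_point`.
#' @return the transformed `enz_point`.
#' @export
reverse_point <- function(point) {
  if (point$equilibrium) return(point)
  if (point$gamma <= 1 && point$direction == "forward") {
    warning("operating point already runs forward (Gamma <= 1); returned unchanged")
    return(point)
  }
  point$gamma <- 1 / point$gamma
  point$keq <- 1 / point$keq
  tmp <- point$substrates
  point$substrates <- point$products
  point$products <- tmp
  point$direction <- if (point$direction == "forward") "reverse" else "forward"
  point
}

#' Overall displacement from the Gibbs free energy of reaction
#'
#' Gamma = exp(dG'/RT) with dG' = dG0' + RT log(prod(products)/prod(substrates)).
#' Agrees with the concentration-ratio definition used by [operating_point()].
#'
#' @param dg0_kj_mol standard Gibbs free energy of reaction (kJ/mol).
#' @param conc named dimensionless concentrations.
#' @param substrates,products species labels.
#' @param temperature temperature (K).
#' @return Gamma.
#' @export
gamma_from_dg <- function(dg0_kj_mol, conc, substrates, products,
                          temperature = 298.15) {
  rt <- GAS_CONSTANT_J * temperature / 1000 # kJ/mol
  dg <- dg0_kj_mol + rt * log(prod(conc[products]) / prod(conc[substrates]))
  exp(dg / rt)
}

#' Per-step concentration multipliers
#'
#' For each elementary step, the forward multiplier is the dimensionless
#' concentration of the species bound when the step runs forward (1 for
#' dissociation and interconversion half-reactions) and likewise backward.
#' These are the parameters c_i of the rate equations, resolved per
#' direction: in a product-release step the product concentration multiplies
#' only the backward (re-binding) term.
#'
#' @param mech an `enz_mechanism`.
#' @param point an `enz_point`.
#' @return data.frame with columns `index`, `c_f`, `c_b`.
#' @export
step_concentrations <- function(mech, point) {
  st <- mech$steps
  lookup <- function(sp) {
    ifelse(is.na(sp), 1, {
      unknown <- setdiff(sp[!is.na(sp)], names(point$conc))
      if (length(unknown)) stop("unknown species id: ",
                                paste(unknown, collapse = ", "))
      unname(point$conc[sp])
    })
  }
  data.frame(index = st$index,
             c_f = lookup(st$forward_binds),
             c_b = lookup(st$backward_binds))
}

#' @export
print.enz_point <- function(x, ...) {
  cat(sprintf("Operating point (%s direction%s)\n", x$direction,
              if (x$equilibrium) ", at equilibrium" else ""))
  cat("  conc:", paste(sprintf("%s=%g", names(x$conc), x$conc), collapse = ", "), "\n")
  cat(sprintf("  Keq = %g, Gamma = %g\n", x$keq, x$gamma))
  invisible(x)
}
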