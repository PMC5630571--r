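# C-mol yields, carbon and available-electron balances, and attribution of
# inorganic carbon capture.
#
# Apparent yields divide by sugar C-mol consumed only, never by consumed gas
# carbon: that is what makes apparent values above the heterotrophic maximum
# diagnostic of inorganic carbon capture. A separate "true" recovery over
# total carbon input is computed in the pipeline layer.

#' Apparent C-mol yield of a product
#'
#' Yp = (delta_product / molar_mass * carbons) / delta_substrate_cmol,
#' i.e. C-mol product formed per C-mol carbon source consumed.
#'
#' @param delta_product Concentration change of the product, g/L (must be >= 0:
#'   products only accumulate at steady state).
#' @param product A [compound_spec()] for the product.
#' @param delta_substrate_cmol Carbon source consumed, C-mol/L (> 0).
#' @return Apparent yield, C-mol/C-mol.
#' @examples
#' reg <- default_registry()
#' cmol_yield(1, reg$butanol, 0.333)  # ~0.162
#' @export
cmol_yield <- function(delta_product, product, delta_substrate_cmol) {
  stopifnot(inherits(product, "compound_spec"))
  if (delta_substrate_cmol <= 0) {
    stop("substrate consumption must be positive (got ",
         delta_substrate_cmol, " C-mol/L)")
  }
  if (delta_product < 0) {
    stop("negative concentration change for product '", product$name,
         "': products only accumulate at steady state")
  }
  (delta_product / product$molar_mass * product$atoms[["C"]]) /
    delta_substrate_cmol
}

#' Bundle apparent yields for balance computation
#'
#' @param products Named numeric vector of apparent product yields
#'   (C-mol/C-mol); may include `co2`.
#' @param biomass Biomass yield Yx, C-mol/C-mol.
#' @param h2 Hydrogen yield, mol H2 per C-mol substrate.
#' @return An object of class `yield_set`.
#' @export
yield_set <- function(products = numeric(0), biomass = 0, h2 = 0) {
  stopifnot(is.numeric(products), is.numeric(biomass), is.numeric(h2))
  if (length(products) > 0 && is.null(names(products))) {
    stop("product yields must be named")
  }
  if (any(products < 0) || biomass < 0 || h2 < 0) {
    stop("all yields must be nonnegative")
  }
  structure(list(products = products, biomass = biomass, h2 = h2),
            class = "yield_set")
}

#' @export
print.yield_set <- function(x, ...) {
  cat("<yield_set> Yx =", format(x$biomass, digits = 4),
      "C-mol/C-mol; Y(H2) =", format(x$h2, digits = 4), "mol/C-mol\n")
  if (length(x$products)) {
    print(round(x$products, 4))
  }
  invisible(x)
}

resolve_gamma_s <- function(substrate, registry) {
  if (is.numeric(substrate)) {
    gs <- substrate
  } else {
    gs <- mean(gamma_of(substrate, registry))
  }
  if (gs <= 0) stop("substrate degree of reduction must be positive")
  gs
}

#' Available-electron (degree-of-reduction) balance
#'
#' Electron recovery over substrate electrons:
#' sum(Yp * gamma_p / gamma_s) + Yx * gamma_x / gamma_s, with H2 contributing
#' 2 electrons per mol and CO2 contributing none. The printed balance formula
#' of the underlying method lists only product and biomass terms; H2 is
#' included here as a product carrying 2 electrons/mol because heterotrophic
#' closure to 1 is impossible for acidogenic stoichiometries without it.
#'
#' @param yields A [yield_set()].
#' @param substrate Substrate compound name(s) (averaged gamma) or a numeric
#'   gamma_s.
#' @param registry Compound registry carrying the gamma values.
#' @return Electron recovery, dimensionless (1 = closed).
#' @export
electron_balance <- function(yields, substrate = "sucrose",
                             registry = default_registry()) {
  stopifnot(inherits(yields, "yield_set"))
  gs <- resolve_gamma_s(substrate, registry)
  nonzero <- names(yields$products)[yields$products > 0]
  gp <- gamma_of(nonzero, registry)  # errors if a gamma is missing
  prod_term <- if (length(nonzero)) sum(yields$products[nonzero] * gp) else 0
  gx <- if (yields$biomass > 0) unname(gamma_of("biomass", registry)) else 0
  unname((prod_term + yields$biomass * gx + 2 * yields$h2) / gs)
}

#' C-mol carbon balance
#'
#' Carbon recovery = sum(Yp) + Yx + co2_yield: CO2 is counted for carbon but
#' carries no electrons in [electron_balance()].
#'
#' @param yields A [yield_set()] (any `co2` entry in its products is ignored
#'   in favour of `co2_yield`).
#' @param co2_yield CO2 evolved per C-mol substrate, C-mol/C-mol.
#' @return Carbon recovery, dimensionless (1 = closed).
#' @export
carbon_balance <- function(yields, co2_yield = 0) {
  stopifnot(inherits(yields, "yield_set"), co2_yield >= 0)
  prods <- yields$products[setdiff(names(yields$products), "co2")]
  sum(prods) + yields$biomass + co2_yield
}

#' Theoretical maximum heterotrophic apparent yield
#'
#' One of the three pyruvate carbons is lost as CO2 in the decarboxylation to
#' the C-2 acetyl group of acetyl-CoA, so at most 2/3 of sugar carbon can
#' reach acetyl-CoA-derived products. Conventionally reported truncated to two
#' decimals as 0.66.
#'
#' @param reported If `TRUE`, truncate to two decimals (0.66).
#' @return C-mol fraction.
#' @examples
#' theoretical_max_yield()                 # 2/3
#' theoretical_max_yield(reported = TRUE)  # 0.66
#' @export
theoretical_max_yield <- function(reported = FALSE) {
  if (reported) trunc(100 * 2 / 3) / 100 else 2 / 3
}

#' Excess recovery over a baseline
#'
#' 100 * (condition - baseline) / baseline, sign preserved. The default
#' baseline in the pipeline is the same-run heterotrophic (N2-sparged) control
#' recovery; the theoretical maximum 2/3 is available as an alternative.
#'
#' @param condition Recovery under the test condition (dimensionless).
#' @param baseline Baseline recovery (> 0).
#' @return Excess in percent of baseline.
#' @export
excess_recovery <- function(condition, baseline) {
  if (any(baseline <= 0)) stop("baseline recovery must be positive")
  100 * (condition - baseline) / baseline
}

#' Attribute product carbon to inorganic (C-1) capture
#'
#' Consumed CO and CO2 (positive net consumption, mol/h = C-mol/h for
#' one-carbon gases) are summed as the inorganic carbon assimilation rate and
#' expressed relative to the sugar carbon flux. Negative consumptions are
#' production, contribute zero to the attribution, and are echoed back.
#' An inconsistency flag is raised when product carbon exceeds sugar plus
#' inorganic carbon inputs.
#'
#' @param gas_consumption Named net consumption rates (mol/h), positive =
#'   consumed; entries `co` and `co2` are used.
#' @param product_carbon_flux Product + biomass carbon flux, C-mol/h.
#' @param sugar_carbon_flux Sugar carbon consumption flux, C-mol/h (> 0).
#' @return List with `c1_flux` (C-mol/h), `c1_fraction` (of sugar carbon),
#'   `produced` (gases with negative consumption), `inconsistent` flag.
#' @export
attribute_inorganic_carbon <- function(gas_consumption, product_carbon_flux,
                                       sugar_carbon_flux) {
  stopifnot(sugar_carbon_flux > 0)
  cg <- gas_consumption[intersect(c("co", "co2"), names(gas_consumption))]
  c1 <- sum(pmax(cg, 0))
  produced <- -pmin(cg, 0)
  list(
    c1_flux = c1,
    c1_fraction = c1 / sugar_carbon_flux,
    produced = produced[produced > 0],
    inconsistent = product_carbon_flux > sugar_carbon_flux + c1 + 1e-9
  )
}
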