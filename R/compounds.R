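# Compound registry and degree-of-reduction arithmetic.
#
# All carbon bookkeeping in the package is done on a C-mol basis: one mole of
# carbon atoms of a compound. The degree of reduction (gamma) of a compound is
# the number of electrons made available per C-mol upon complete oxidation to
# CO2, H2O and (on the ammonia basis used here) NH3.

ELEMENT_MASSES <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

#' Parse an elemental formula into atom counts
#'
#' Supports the elements C, H, O and N with integer or fractional subscripts,
#' so condensed biomass formulas such as `CH1.8O0.5N0.2` are accepted.
#'
#' @param formula Character scalar, e.g. `"C4H10O"`.
#' @return Named numeric vector with components `C`, `H`, `O`, `N`.
#' @examples
#' parse_formula("C12H22O11")
#' parse_formula("CH1.8O0.5N0.2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  tokens <- gregexpr("([A-Z][a-z]?)([0-9.]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9.]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  atoms <- c(C = 0, H = 0, O = 0, N = 0)
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    n <- sub("^[A-Z][a-z]?", "", p)
    n <- if (nzchar(n)) as.numeric(n) else 1
    if (!el %in% names(atoms)) {
      stop("unknown element '", el, "' in formula ", formula,
           " (supported: C, H, O, N)")
    }
    atoms[el] <- atoms[el] + n
  }
  atoms
}

#' Create a compound specification
#'
#' @param name Identifier used in yield sets and series columns.
#' @param formula Elemental formula over C/H/O/N (fractional subscripts allowed).
#' @param molar_mass Molar mass in g/mol; must agree with the formula within 1%.
#' @param role One of `"substrate"`, `"product"`, `"biomass"`, `"gas"`.
#' @return An object of class `compound_spec`.
#' @examples
#' butanol <- compound_spec("butanol", "C4H10O", 74.12, "product")
#' degree_of_reduction(butanol)
#' @export
compound_spec <- function(name, formula, molar_mass,
                          role = c("substrate", "product", "biomass", "gas")) {
  role <- match.arg(role)
  atoms <- parse_formula(formula)
  stopifnot(all(atoms >= 0), is.numeric(molar_mass), molar_mass > 0)
  mass_from_atoms <- sum(atoms * ELEMENT_MASSES[names(atoms)])
  if (abs(mass_from_atoms - molar_mass) > 0.01 * molar_mass) {
    stop("molar mass ", molar_mass, " for ", name,
         " inconsistent with formula (expected ~", round(mass_from_atoms, 2), ")")
  }
  if (atoms[["C"]] == 0 && role != "gas") {
    stop("carbon-free species '", name, "' only permitted with role = 'gas'")
  }
  structure(
    list(name = name, formula = formula, atoms = atoms,
         molar_mass = molar_mass, role = role),
    class = "compound_spec"
  )
}

#' @export
print.compound_spec <- function(x, ...) {
  cat(sprintf("<compound_spec> %s (%s, %.2f g/mol, %s)\n",
              x$name, x$formula, x$molar_mass, x$role))
  invisible(x)
}

#' Load a compound registry from a plain-text table
#'
#' The registry is a tab-separated table with columns `name`, `formula`,
#' `molar_mass` and `role`. The packaged default covers the sugars, ABE
#' fermentation products, a condensed biomass formula (CH1.8O0.5N0.2) and the
#' monitored gases.
#'
#' @param path Path to a TSV file; defaults to the packaged registry.
#' @return Named list of [compound_spec()] objects.
#' @export
load_registry <- function(path = system.file("extdata", "compounds.tsv",
                                             package = "mixocarb")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "formula", "molar_mass", "role")
  if (!all(needed %in% names(tab))) {
    stop("registry table must have columns: ", paste(needed, collapse = ", "))
  }
  reg <- lapply(seq_len(nrow(tab)), function(i) {
    compound_spec(tab$name[i], tab$formula[i], tab$molar_mass[i], tab$role[i])
  })
  names(reg) <- tab$name
  reg
}

registry_cache <- new.env(parent = emptyenv())

#' Default compound registry
#'
#' @return Named list of [compound_spec()] objects (cached).
#' @export
default_registry <- function() {
  if (is.null(registry_cache$reg)) registry_cache$reg <- load_registry()
  registry_cache$reg
}

#' Degree of reduction (available electrons)
#'
#' Electrons available per C-mol on the ammonia nitrogen basis:
#' gamma = 4 + h/c - 2 o/c - 3 n/c, where c, h, o, n are the atom counts.
#' Fully oxidized carbon (CO2) gives exactly 0. Two carbon-free gases are
#' admitted as special cases: H2 carries 2 electrons per mol and inert N2
#' carries 0; any other carbon-free species is rejected.
#'
#' @param compound A [compound_spec()].
#' @param n_basis Nitrogen reference; only `"ammonia"` is implemented.
#' @return Electrons per C-mol (per mol for H2/N2).
#' @examples
#' degree_of_reduction(default_registry()$butanol)  # 6
#' degree_of_reduction(default_registry()$co2)      # 0
#' @export
degree_of_reduction <- function(compound, n_basis = "ammonia") {
  stopifnot(inherits(compound, "compound_spec"))
  n_basis <- match.arg(n_basis, "ammonia")
  a <- compound$atoms
  if (a[["C"]] == 0) {
    if (a[["H"]] > 0 && a[["O"]] == 0 && a[["N"]] == 0) return(2 * a[["H"]] / 2) # H2
    if (a[["N"]] > 0 && a[["H"]] == 0 && a[["O"]] == 0) return(0)                # N2
    stop("degree of reduction undefined for carbon-free species '",
         compound$name, "' (only H2 and N2 are admitted)")
  }
  gamma <- 4 + a[["H"]] / a[["C"]] - 2 * a[["O"]] / a[["C"]] - 3 * a[["N"]] / a[["C"]]
  unname(gamma)
}

#' Degree-of-reduction lookup over the registry
#'
#' @param names Character vector of compound names.
#' @param registry Compound registry.
#' @return Named numeric vector of gamma values.
#' @export
gamma_of <- function(names, registry = default_registry()) {
  missing <- setdiff(names, names(registry))
  if (length(missing) > 0) {
    stop("compounds missing from registry: ", paste(missing, collapse = ", "))
  }
  vapply(registry[names], degree_of_reduction, numeric(1))
}
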