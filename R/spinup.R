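#' Cold-start spin-up for one forest class
#'
#' Runs the annual stock-flow step for `years` years on a single cell whose
#' stocks (including peat) start at zero, recording every pool at every age.
#' Because NPP is constant, the live wood pool follows the discrete
#' single-pool solution `B(t) = (I/m) (1 - (1 - m)^t)` with inflow
#' `I = f_wood * NPP` and mortality multiplier `m` exactly; the spin-up is
#' deterministic and bit-reproducible.
#'
#' @param species Forest class label.
#' @param params Species parameter set.
#' @param soil Soil parameters.
#' @param years Number of annual steps (default 300).
#' @param peat_mode Passed to [step_flows()].
#' @return An object of class `growth_curve`: list with `species`, `ages`
#'   (0:years), `pools` (a `(years+1) x 8` matrix of densities, t C/ha) and
#'   `live_tree` (live leaf + live wood, t C/ha).
#' @export
run_spinup <- function(species, params = load_species_params(),
                       soil = soil_params(), years = 300,
                       peat_mode = "steady_state") {
  if (!species %in% forest_classes()) stop("not a forest class: ", species)
  land <- new_landscape(species, "Wet", 0L, 1L, 1L, soil = soil)
  land$stocks[] <- 0  # cold start: every pool, including peat, at zero
  land$upper_peat_cm[] <- 0
  land$deep_peat_cm[] <- 0
  pools <- matrix(0, years + 1, length(pool_names()),
                  dimnames = list(NULL, pool_names()))
  for (t in seq_len(years)) {
    land <- step_flows(land, params, soil, peat_mode = peat_mode)$landscape
    pools[t + 1, ] <- land$stocks[1, ]
  }
  structure(list(species = species, ages = 0:years, pools = pools,
                 live_tree = pools[, "live_leaf"] + pools[, "live_wood"]),
            class = "growth_curve")
}

#' Spin-up growth curves for all forest classes
#'
#' @inheritParams run_spinup
#' @return Named list of `growth_curve` objects.
#' @export
run_all_spinups <- function(params = load_species_params(),
                            soil = soil_params(), years = 300,
                            peat_mode = "steady_state") {
  curves <- lapply(forest_classes(), run_spinup, params = params, soil = soil,
                   years = years, peat_mode = peat_mode)
  stats::setNames(curves, forest_classes())
}

#' Live-tree biomass of a growth curve
#'
#' @param curve A `growth_curve`.
#' @param include_roots Add the live root pool (default FALSE: live tree is
#'   leaf + wood).
#' @return Numeric vector over ages.
#' @export
live_tree_biomass <- function(curve, include_roots = FALSE) {
  b <- curve$live_tree
  if (include_roots) b <- b + curve$pools[, "live_root"]
  b
}

#' Growth-curve pool densities at given ages
#'
#' Ages beyond the curve are clamped to its final age.
#'
#' @param curve A `growth_curve`.
#' @param ages Integer ages.
#' @return Matrix of pool densities, one row per requested age.
#' @export
curve_stocks_at_age <- function(curve, ages) {
  i <- pmin(pmax(as.integer(ages), 0L), max(curve$ages)) + 1L
  curve$pools[i, , drop = FALSE]
}

#' Find the growth/age equilibrium of a curve
#'
#' Returns the smallest age at which the annual relative increase of
#' live-tree biomass falls below `tol`. If the curve never converges, the
#' final age is returned with a warning.
#'
#' @param curve A `growth_curve`.
#' @param tol Relative annual change threshold (default 1e-3 per year).
#' @return A list with `age` and `biomass` (t C/ha).
#' @export
find_equilibrium <- function(curve, tol = 1e-3) {
  b <- live_tree_biomass(curve)
  if (length(b) < 2) stop("curve must span at least two ages")
  prev <- b[-length(b)]
  rel <- ifelse(prev > 0, diff(b) / prev, ifelse(diff(b) > 0, Inf, 0))
  hit <- which(rel < tol)
  if (!length(hit)) {
    warning("no equilibrium within the curve; returning its final age")
    age <- max(curve$ages)
  } else {
    age <- curve$ages[hit[1] + 1L]
  }
  list(age = age, biomass = b[age + 1L])
}

#' Build the biomass-to-age lookup of a growth curve
#'
#' The inverse of the strictly increasing segment of the live-tree curve,
#' defined on [0, max biomass]; biomass above the maximum maps to the
#' equilibrium age.
#'
#' @param curve A `growth_curve`.
#' @param tol Equilibrium tolerance (see [find_equilibrium()]).
#' @return An object of class `age_lookup`.
#' @export
build_age_lookup <- function(curve, tol = 1e-3) {
  eq <- find_equilibrium(curve, tol)
  b <- live_tree_biomass(curve)[seq_len(eq$age + 1L)]
  if (any(diff(b) < 0))
    stop("live-tree curve is not monotone below the equilibrium age")
  structure(list(species = curve$species, biomass = b,
                 equilibrium_age = eq$age),
            class = "age_lookup")
}

#' Map biomass to stand age
#'
#' Returns the smallest age whose curve biomass is at least the input;
#' biomass above the curve maximum returns the equilibrium age. This is the
#' lookup used to build an age map from a live-tree biomass map.
#'
#' @param biomass Non-negative biomass value(s), t C/ha.
#' @param lookup An `age_lookup`, or a `growth_curve` (converted on the fly).
#' @return Integer age(s), years.
#' @export
biomass_to_age <- function(biomass, lookup) {
  if (inherits(lookup, "growth_curve")) lookup <- build_age_lookup(lookup)
  if (any(biomass < 0)) stop("biomass must be >= 0")
  # count of curve values strictly below the target = smallest age meeting it
  age <- findInterval(biomass - 1e-9, lookup$biomass, left.open = FALSE)
  pmin(age, lookup$equilibrium_age)
}
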