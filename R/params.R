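#' Soil (peat) parameters
#'
#' Peat bulk density, organic-matter fraction, carbon fraction and the
#' standardized column depths used to convert peat depth to carbon density.
#' Defaults are the site means measured on 26 soil cores: bulk density
#' 0.16 g/cm3, 95% organic matter, 59% carbon content, with a standardized
#' 100-cm peat column split into an upper (acrotelm, 0-40 cm) and a deep
#' (catotelm, 41-100 cm) layer.
#'
#' @param bulk_density Bulk density in g/cm3 (> 0).
#' @param organic_fraction Organic-matter fraction of soil mass, in (0, 1].
#' @param carbon_fraction Carbon fraction of organic matter, in (0, 1].
#' @param upper_depth Upper (acrotelm) layer thickness, cm.
#' @param total_depth Total standardized peat column depth, cm.
#' @return An object of class `soil_params`.
#' @export
soil_params <- function(bulk_density = 0.16, organic_fraction = 0.95,
                        carbon_fraction = 0.59, upper_depth = 40,
                        total_depth = 100) {
  if (bulk_density <= 0) stop("bulk_density must be > 0")
  if (organic_fraction <= 0 || organic_fraction > 1)
    stop("organic_fraction must be in (0, 1]")
  if (carbon_fraction <= 0 || carbon_fraction > 1)
    stop("carbon_fraction must be in (0, 1]")
  if (upper_depth < 0 || total_depth < upper_depth)
    stop("need 0 <= upper_depth <= total_depth")
  structure(list(bulk_density = bulk_density,
                 organic_fraction = organic_fraction,
                 carbon_fraction = carbon_fraction,
                 upper_depth = upper_depth,
                 total_depth = total_depth),
            class = "soil_params")
}

#' Peat carbon density per centimetre of depth
#'
#' Converts a peat depth to a carbon density using
#' `bulk_density * organic_fraction * carbon_fraction * 100` t C/ha per cm.
#' With the default soil parameters this is 8.968 t C/ha per cm, so the 40-cm
#' acrotelm holds ~358.4 t C/ha and the 60-cm catotelm ~537.6 t C/ha.
#'
#' @param soil A [soil_params()] object.
#' @return Carbon density in t C/ha per cm of peat.
#' @export
peat_carbon_per_cm <- function(soil = soil_params()) {
  stopifnot(inherits(soil, "soil_params"))
  soil$bulk_density * soil$organic_fraction * soil$carbon_fraction * 100
}

#' Fire-severity proportions
#'
#' Proportions of burned area falling in high, medium and low burn severity,
#' with the age-reset rule per severity. Defaults are the landscape's
#' historical burn-severity distribution (0.163/0.409/0.428); only high
#' severity (and repeat-catastrophic fire) resets stand age.
#'
#' @param p_high,p_med,p_low Severity proportions; must sum to 1.
#' @return An object of class `fire_severity_spec`.
#' @export
fire_severity_spec <- function(p_high = 0.163, p_med = 0.409, p_low = 0.428) {
  p <- c(high = p_high, med = p_med, low = p_low)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("severity proportions must be non-negative and sum to 1")
  structure(list(p = p, age_reset = c(high = TRUE, med = FALSE, low = FALSE)),
            class = "fire_severity_spec")
}

#' Load the per-species stock-flow parameter set
#'
#' Reads the packaged parameter tables (initial stock densities and NPP, flow
#' multipliers, species peat accumulation rates, age-class bounds) and returns
#' one parameter list per forest class. At load time the set is validated:
#' NPP partition fractions must sum to 1 for every species, pond pine stocks
#' must equal the mean of the other three species, and the multipliers must
#' reproduce the calibrated flow densities (see [check_flow_calibration()]).
#'
#' @param validate Run the load-time consistency checks (default TRUE).
#' @return A named list (one element per forest class) of class
#'   `species_params_set`. Each element carries `npp`, the partition fractions
#'   `f_leaf`/`f_wood`/`f_root`, the proportional flow multipliers, the
#'   absolute deep-peat accumulation rate `peat_accumulation` (t C/ha/yr), the
#'   mature-stand initial stock densities `init_stocks`, and age-class bounds.
#' @export
load_species_params <- function(validate = TRUE) {
  stocks <- utils::read.csv(extdata("initial_stocks.csv"), check.names = FALSE)
  mult <- utils::read.csv(extdata("flow_multipliers.csv"), check.names = FALSE)
  peat <- utils::read.csv(extdata("peat_accumulation.csv"))
  ages <- utils::read.csv(extdata("age_classes.csv"))

  species <- forest_classes()
  get_mult <- function(sp, from, to) {
    i <- mult$from_pool == from & mult$to_pool == to
    if (sum(i) != 1) stop("flow multiplier lookup failed: ", from, "->", to)
    mult[[sp]][i]
  }
  get_stock <- function(sp, q) stocks[[sp]][stocks$quantity == q]

  out <- lapply(species, function(sp) {
    init <- vapply(pool_names(), function(q) get_stock(sp, q), numeric(1))
    p <- list(
      name = sp,
      npp = get_stock(sp, "npp"),
      f_leaf = get_mult(sp, "atmosphere", "live_leaf"),
      f_wood = get_mult(sp, "atmosphere", "live_wood"),
      f_root = get_mult(sp, "atmosphere", "live_root"),
      m_litterfall_leaf = get_mult(sp, "live_leaf", "leaf_litter"),
      m_mortality_wood = get_mult(sp, "live_wood", "deadwood"),
      m_litterfall_root = get_mult(sp, "live_root", "dead_root"),
      m_humif_litter = get_mult(sp, "leaf_litter", "upper_peat"),
      m_humif_deadwood = get_mult(sp, "deadwood", "upper_peat"),
      m_humif_deadroot = get_mult(sp, "dead_root", "upper_peat"),
      m_emis_litter = get_mult(sp, "leaf_litter", "atmosphere"),
      m_emis_deadwood = get_mult(sp, "deadwood", "atmosphere"),
      m_emis_deadroot = get_mult(sp, "dead_root", "atmosphere"),
      m_emis_upper_peat = get_mult(sp, "upper_peat", "atmosphere"),
      m_accum_upper_peat = get_mult(sp, "upper_peat", "deep_peat"),
      peat_accumulation = peat$rate_t_c_ha_yr[peat$species == sp],
      init_stocks = init,
      age_classes = ages[ages$species == sp, -1, drop = FALSE]
    )
    p
  })
  names(out) <- species
  out <- structure(out, class = "species_params_set")
  if (validate) validate_species_params(out)
  out
}

#' Validate a species parameter set
#'
#' Asserts the structural invariants of the parameter tables: the NPP
#' partition fractions close to 1 for every species, and the pond pine stock
#' densities equal the mean of the Atlantic white cedar, cypress-gum and
#' maple-gum densities (the tables define pond pine that way).
#'
#' @param params A `species_params_set`.
#' @return Invisibly TRUE; stops on violation.
#' @export
validate_species_params <- function(params) {
  for (p in params) {
    s <- p$f_leaf + p$f_wood + p$f_root
    if (abs(s - 1) > 1e-9)
      stop("NPP partition fractions for ", p$name, " sum to ", s, ", not 1")
  }
  three <- c("AtlanticWhiteCedar", "CypressGum", "MapleGum")
  avg <- rowMeans(vapply(three, function(sp) params[[sp]]$init_stocks,
                         numeric(length(pool_names()))))
  pp <- params$PondPine$init_stocks
  # table values are printed to 2 decimals, so the mean agrees to ~0.01
  if (max(abs(avg - pp)) > 0.011)
    stop("pond pine stocks do not equal the three-species mean")
  invisible(TRUE)
}

#' Check flow multipliers against calibrated flow densities
#'
#' The operative annual flows are `multiplier x from-stock` (growth flows use
#' `fraction x NPP`). The packaged calibrated-flow table lists each flow as a
#' literature density plus a signed calibration delta; for every biomass flow
#' the identity `multiplier x mature stock = literature + delta` must hold.
#' The two upper-peat rows are excluded: the peat layer is governed by the
#' steady-state rule and the absolute species accumulation rates instead (the
#' multiplier-form peat rows are provided only for sensitivity runs).
#'
#' @param params A `species_params_set` from [load_species_params()].
#' @param tol Maximum absolute discrepancy in t C/ha/yr (default 0.01).
#' @return Invisibly, a data.frame of per-flow discrepancies.
#' @export
check_flow_calibration <- function(params = load_species_params(validate = FALSE),
                                   tol = 0.01) {
  cal <- utils::read.csv(extdata("calibrated_flows.csv"))
  abbr <- c(AtlanticWhiteCedar = "AWC", CypressGum = "CG",
            MapleGum = "MG", PondPine = "PP")
  rows <- cal$from_pool != "upper_peat"  # biomass rows only
  cal <- cal[rows, ]
  out <- list()
  for (sp in names(params)) {
    p <- params[[sp]]
    stock <- c(atmosphere = NA_real_, p$init_stocks)
    m <- vapply(seq_len(nrow(cal)), function(i) {
      from <- cal$from_pool[i]; to <- cal$to_pool[i]
      if (from == "atmosphere") {
        f <- switch(to, live_leaf = p$f_leaf, live_wood = p$f_wood,
                    live_root = p$f_root)
        f * p$npp
      } else {
        mult <- switch(paste(from, to, sep = ">"),
          "live_leaf>leaf_litter" = p$m_litterfall_leaf,
          "live_wood>deadwood" = p$m_mortality_wood,
          "live_root>dead_root" = p$m_litterfall_root,
          "leaf_litter>upper_peat" = p$m_humif_litter,
          "deadwood>upper_peat" = p$m_humif_deadwood,
          "dead_root>upper_peat" = p$m_humif_deadroot,
          "leaf_litter>atmosphere" = p$m_emis_litter,
          "deadwood>atmosphere" = p$m_emis_deadwood,
          "dead_root>atmosphere" = p$m_emis_deadroot)
        mult * stock[[from]]
      }
    }, numeric(1))
    expected <- cal[[paste0(abbr[[sp]], "_value")]] +
      cal[[paste0(abbr[[sp]], "_delta")]]
    out[[sp]] <- data.frame(species = sp, from = cal$from_pool,
                            to = cal$to_pool, operative = m,
                            calibrated = expected, diff = m - expected)
  }
  out <- do.call(rbind, out)
  if (max(abs(out$diff)) > tol)
    stop("flow multipliers disagree with calibrated flow densities; max |diff| = ",
         signif(max(abs(out$diff)), 3))
  invisible(out)
}

#' Default alternative-succession pathways
#'
#' Probabilistic conversion of recently disturbed (age <= 5) Atlantic white
#' cedar and pond pine stands to maple-gum, gated by 8-neighbour adjacency to
#' existing maple-gum. Annual probabilities are 0.80 (cedar) and 0.50 (pond
#' pine) in the Dry stratum and 0.04 / 0.01 in the Wet stratum.
#'
#' @return A data.frame with columns `from`, `to`, `stratum`, `probability`,
#'   `age_max`, `adjacency_class`, `age_reset`.
#' @export
default_pathways <- function() {
  data.frame(
    from = c("AtlanticWhiteCedar", "AtlanticWhiteCedar", "PondPine", "PondPine"),
    to = "MapleGum",
    stratum = c("Dry", "Wet", "Dry", "Wet"),
    probability = c(0.80, 0.04, 0.50, 0.01),
    age_max = 5L,
    adjacency_class = "MapleGum",
    age_reset = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Summary statistics of the mature-stand initial stocks
#'
#' Aggregates the packaged initial stock densities across the four forest
#' classes: mean total live biomass (leaf + wood + root), its per-class
#' maximum and minimum, and the mean above-ground live biomass (leaf + wood).
#'
#' @param params A `species_params_set`.
#' @return A list with `avg_live`, `max_live`, `min_live` (each named by
#'   class) and `avg_aboveground`, all in t C/ha.
#' @export
summarize_initial_stocks <- function(params = load_species_params()) {
  live <- vapply(params, function(p)
    sum(p$init_stocks[c("live_leaf", "live_wood", "live_root")]), numeric(1))
  ag <- vapply(params, function(p)
    sum(p$init_stocks[c("live_leaf", "live_wood")]), numeric(1))
  list(avg_live = mean(live),
       max_live = live[which.max(live)],
       min_live = live[which.min(live)],
       avg_aboveground = mean(ag))
}
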