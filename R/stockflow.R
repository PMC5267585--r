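flux_record <- function(category, from_pool, to_pool, amount) {
  data.frame(category = category, from_pool = from_pool, to_pool = to_pool,
             amount = amount, stringsAsFactors = FALSE)
}

species_param_vec <- function(landscape, params, field, cells) {
  sp <- landscape$state[cells]
  vals <- vapply(params, `[[`, numeric(1), field)
  unname(vals[sp])
}

#' Annual carbon flow step (gain-loss method)
#'
#' Executes one annual time-step of the stock-flow model on every forested
#' cell, computing all flows simultaneously from start-of-year stocks:
#'
#' * Growth: the species NPP partitioned into live leaf, wood and root by the
#'   partition fractions (inflow from the atmosphere).
#' * Litterfall / mortality: proportional multipliers of the live from-stocks
#'   into leaf litter, deadwood and dead root.
#' * Humification: proportional multipliers of the detritus from-stocks into
#'   the upper peat.
#' * Detritus emission: proportional multipliers of the detritus from-stocks
#'   to the atmosphere (heterotrophic respiration).
#' * Peat accumulation: the absolute species rate (t C/ha/yr) transferred
#'   from upper to deep peat (the long-term catotelm sink).
#' * Upper-peat emission: in the default steady-state mode,
#'   `max(0, humification inflow - peat accumulation)`, so the acrotelm
#'   neither gains nor loses once humification exceeds the accumulation rate;
#'   in `peat_mode = "multiplier"` the table multipliers are applied to the
#'   upper-peat stock instead (sensitivity mode).
#'
#' Outflows from a pool are proportionally rescaled if they would exceed the
#' start-of-year stock, so no pool ever goes negative.
#'
#' @param landscape A `peat_landscape`.
#' @param params Species parameter set.
#' @param soil Soil parameters.
#' @param peat_mode `"steady_state"` (default) or `"multiplier"`.
#' @return A list with `landscape` (updated) and `fluxes`, a data.frame of
#'   aggregated flux records (category, from_pool, to_pool, amount in t C
#'   summed over cells; cells are 1 ha so per-cell amounts are densities).
#' @export
step_flows <- function(landscape, params = load_species_params(),
                       soil = soil_params(),
                       peat_mode = c("steady_state", "multiplier")) {
  peat_mode <- match.arg(peat_mode)
  cells <- which(is_forested(landscape))
  if (!length(cells)) {
    return(list(landscape = landscape,
                fluxes = flux_record(character(0), character(0),
                                     character(0), numeric(0))))
  }
  S <- landscape$stocks[cells, , drop = FALSE]
  if (any(S < 0)) stop("negative stock on entry to step_flows")
  pv <- function(field) species_param_vec(landscape, params, field, cells)

  npp <- pv("npp")
  g_leaf <- pv("f_leaf") * npp
  g_wood <- pv("f_wood") * npp
  g_root <- pv("f_root") * npp
  lf_leaf <- pv("m_litterfall_leaf") * S[, "live_leaf"]
  mort <- pv("m_mortality_wood") * S[, "live_wood"]
  lf_root <- pv("m_litterfall_root") * S[, "live_root"]
  hum_lit <- pv("m_humif_litter") * S[, "leaf_litter"]
  hum_dw <- pv("m_humif_deadwood") * S[, "deadwood"]
  hum_dr <- pv("m_humif_deadroot") * S[, "dead_root"]
  em_lit <- pv("m_emis_litter") * S[, "leaf_litter"]
  em_dw <- pv("m_emis_deadwood") * S[, "deadwood"]
  em_dr <- pv("m_emis_deadroot") * S[, "dead_root"]
  hum_total <- hum_lit + hum_dw + hum_dr

  if (peat_mode == "steady_state") {
    accum <- pv("peat_accumulation")
    em_peat <- pmax(0, hum_total - accum)
  } else {
    accum <- pv("m_accum_upper_peat") * S[, "upper_peat"]
    em_peat <- pv("m_emis_upper_peat") * S[, "upper_peat"]
  }
  # outflows are limited by the start-of-year upper-peat stock
  out_peat <- accum + em_peat
  scale <- ifelse(out_peat > 0, pmin(1, S[, "upper_peat"] / out_peat), 1)
  accum <- accum * scale
  em_peat <- em_peat * scale

  S[, "live_leaf"] <- S[, "live_leaf"] + g_leaf - lf_leaf
  S[, "live_wood"] <- S[, "live_wood"] + g_wood - mort
  S[, "live_root"] <- S[, "live_root"] + g_root - lf_root
  S[, "leaf_litter"] <- S[, "leaf_litter"] + lf_leaf - hum_lit - em_lit
  S[, "deadwood"] <- S[, "deadwood"] + mort - hum_dw - em_dw
  S[, "dead_root"] <- S[, "dead_root"] + lf_root - hum_dr - em_dr
  S[, "upper_peat"] <- S[, "upper_peat"] + hum_total - accum - em_peat
  S[, "deep_peat"] <- S[, "deep_peat"] + accum
  landscape$stocks[cells, ] <- S

  fluxes <- rbind(
    flux_record("Growth", "atmosphere", "live_leaf", sum(g_leaf)),
    flux_record("Growth", "atmosphere", "live_wood", sum(g_wood)),
    flux_record("Growth", "atmosphere", "live_root", sum(g_root)),
    flux_record("Litterfall", "live_leaf", "leaf_litter", sum(lf_leaf)),
    flux_record("Mortality", "live_wood", "deadwood", sum(mort)),
    flux_record("Litterfall", "live_root", "dead_root", sum(lf_root)),
    flux_record("Humification", "leaf_litter", "upper_peat", sum(hum_lit)),
    flux_record("Humification", "deadwood", "upper_peat", sum(hum_dw)),
    flux_record("Humification", "dead_root", "upper_peat", sum(hum_dr)),
    flux_record("Emission", "leaf_litter", "atmosphere", sum(em_lit)),
    flux_record("Emission", "deadwood", "atmosphere", sum(em_dw)),
    flux_record("Emission", "dead_root", "atmosphere", sum(em_dr)),
    flux_record("Emission", "upper_peat", "atmosphere", sum(em_peat)),
    flux_record("PeatAccumulation", "upper_peat", "deep_peat", sum(accum))
  )
  list(landscape = landscape, fluxes = fluxes)
}

#' Fire consumption of biomass and peat
#'
#' Removes carbon from the cells of a burn. Above-ground consumption takes a
#' fraction of the live leaf, live wood, leaf litter and deadwood pools to the
#' atmosphere (`FireEmissionAGB`). Peat consumption removes the requested
#' depth of the peat column, upper layer first, at the soil carbon density per
#' cm, decrementing the depth fields (`FireEmissionBGB`); a request exceeding
#' the remaining column is clamped with a warning. With `include_roots` the
#' live and dead root pools are fully emitted as below-ground loss (deep peat
#' burns of repeat-catastrophic fires).
#'
#' @param landscape A `peat_landscape`.
#' @param cells Integer indices (or logical mask) of burned cells.
#' @param agb_fraction Fraction of each above-ground pool consumed, in [0,1].
#' @param peat_depth_cm Depth of peat consumed, cm.
#' @param include_roots Emit live + dead roots as below-ground loss.
#' @param fractions Optional named vector of per-pool fractions over
#'   `live_leaf`, `live_wood`, `leaf_litter`, `deadwood`, overriding
#'   `agb_fraction` (used for the severity-based default consumption).
#' @param soil Soil parameters.
#' @return A list with `landscape`, the aggregated `fluxes` records, and the
#'   scalars `agb`, `bgb_peat`, `bgb_root` (t C) plus `peat_cells`, the count
#'   of cells with nonzero peat consumption.
#' @export
apply_fire_consumption <- function(landscape, cells, agb_fraction = 0,
                                   peat_depth_cm = 0, include_roots = FALSE,
                                   fractions = NULL, soil = landscape$soil) {
  if (is.logical(cells)) cells <- which(cells)
  if (is.null(fractions)) {
    if (agb_fraction < 0 || agb_fraction > 1)
      stop("agb_fraction must be in [0, 1]")
    fractions <- stats::setNames(rep(agb_fraction, 4), agb_pools())
  }
  empty <- list(landscape = landscape,
                fluxes = flux_record(character(0), character(0),
                                     character(0), numeric(0)),
                agb = 0, bgb_peat = 0, bgb_root = 0, peat_cells = 0L)
  if (!length(cells)) return(empty)
  S <- landscape$stocks[cells, , drop = FALSE]
  agb_amt <- 0
  recs <- list()
  for (p in names(fractions)) {
    burned <- fractions[[p]] * S[, p]
    S[, p] <- S[, p] - burned
    agb_amt <- agb_amt + sum(burned)
    recs[[p]] <- flux_record("FireEmissionAGB", p, "atmosphere", sum(burned))
  }

  bgb_peat <- 0; peat_cells <- 0L
  if (peat_depth_cm > 0) {
    cpc <- peat_carbon_per_cm(soil)
    avail <- landscape$upper_peat_cm[cells] + landscape$deep_peat_cm[cells]
    if (any(peat_depth_cm > avail + 1e-9))
      warning("requested peat consumption exceeds remaining depth on ",
              sum(peat_depth_cm > avail + 1e-9), " cell(s); clamped")
    d <- pmin(peat_depth_cm, avail)
    d_up <- pmin(d, landscape$upper_peat_cm[cells])
    d_dp <- d - d_up
    burn_up <- pmin(S[, "upper_peat"], d_up * cpc)
    burn_dp <- pmin(S[, "deep_peat"], d_dp * cpc)
    S[, "upper_peat"] <- S[, "upper_peat"] - burn_up
    S[, "deep_peat"] <- S[, "deep_peat"] - burn_dp
    landscape$upper_peat_cm[cells] <- landscape$upper_peat_cm[cells] - d_up
    landscape$deep_peat_cm[cells] <- landscape$deep_peat_cm[cells] - d_dp
    bgb_peat <- sum(burn_up) + sum(burn_dp)
    peat_cells <- sum(d > 0)
    recs$peat_up <- flux_record("FireEmissionBGB", "upper_peat", "atmosphere",
                                sum(burn_up))
    recs$peat_dp <- flux_record("FireEmissionBGB", "deep_peat", "atmosphere",
                                sum(burn_dp))
  }

  bgb_root <- 0
  if (include_roots) {
    bgb_root <- sum(S[, "live_root"]) + sum(S[, "dead_root"])
    recs$root_l <- flux_record("FireEmissionBGB", "live_root", "atmosphere",
                               sum(S[, "live_root"]))
    recs$root_d <- flux_record("FireEmissionBGB", "dead_root", "atmosphere",
                               sum(S[, "dead_root"]))
    S[, "live_root"] <- 0
    S[, "dead_root"] <- 0
  }
  landscape$stocks[cells, ] <- S
  list(landscape = landscape, fluxes = do.call(rbind, unname(recs)),
       agb = agb_amt, bgb_peat = bgb_peat, bgb_root = bgb_root,
       peat_cells = peat_cells)
}

#' Hurricane blow-down transfer
#'
#' Moves all live biomass of the affected cells to the corresponding dead
#' pools (wood to deadwood, leaf to leaf litter, root to dead root). Total
#' cell carbon is unchanged; any age reset is handled by the transition layer.
#'
#' @param landscape A `peat_landscape`.
#' @param cells Cell indices or logical mask.
#' @return A list with `landscape` and `fluxes`.
#' @export
apply_hurricane_transfer <- function(landscape, cells) {
  if (is.logical(cells)) cells <- which(cells)
  S <- landscape$stocks[cells, , drop = FALSE]
  fluxes <- rbind(
    flux_record("HurricaneTransfer", "live_wood", "deadwood",
                sum(S[, "live_wood"])),
    flux_record("HurricaneTransfer", "live_leaf", "leaf_litter",
                sum(S[, "live_leaf"])),
    flux_record("HurricaneTransfer", "live_root", "dead_root",
                sum(S[, "live_root"])))
  S[, "deadwood"] <- S[, "deadwood"] + S[, "live_wood"]
  S[, "leaf_litter"] <- S[, "leaf_litter"] + S[, "live_leaf"]
  S[, "dead_root"] <- S[, "dead_root"] + S[, "live_root"]
  S[, c("live_wood", "live_leaf", "live_root")] <- 0
  landscape$stocks[cells, ] <- S
  list(landscape = landscape, fluxes = fluxes)
}

#' Deadwood salvage harvest
#'
#' Transfers the entire deadwood stock of the treated cells to the harvested
#' wood products pool, removing that carbon from the ecosystem ledger
#' (`ManagementRemoval`).
#'
#' @param landscape A `peat_landscape`.
#' @param cells Cell indices or logical mask.
#' @return A list with `landscape`, `fluxes` and `removed` (t C).
#' @export
apply_deadwood_harvest <- function(landscape, cells) {
  if (is.logical(cells)) cells <- which(cells)
  removed <- sum(landscape$stocks[cells, "deadwood"])
  landscape$stocks[cells, "deadwood"] <- 0
  list(landscape = landscape,
       fluxes = flux_record("ManagementRemoval", "deadwood",
                            "harvested_wood_products", removed),
       removed = removed)
}

#' Verify mass balance of a set of flux records
#'
#' Checks that the change in total ecosystem carbon between two landscape
#' states equals atmosphere inflows minus atmosphere outflows minus harvested
#' wood product outflows, i.e. that the gain-loss bookkeeping closes.
#'
#' @param before,after `peat_landscape` objects bracketing one or more
#'   operations.
#' @param records The concatenated flux records of those operations.
#' @param tol Absolute tolerance in t C per active cell (default 1e-9).
#' @return TRUE if the balance closes within tolerance, otherwise FALSE.
#' @export
mass_balance <- function(before, after, records, tol = 1e-9) {
  delta <- total_carbon(after) - total_carbon(before)
  inflow <- sum(records$amount[records$from_pool == "atmosphere"])
  out_atm <- sum(records$amount[records$to_pool == "atmosphere"])
  out_hwp <- sum(records$amount[records$to_pool == "harvested_wood_products"])
  n <- max(1, sum(!is.na(before$state)))
  abs(delta - (inflow - out_atm - out_hwp)) <= tol * n
}
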