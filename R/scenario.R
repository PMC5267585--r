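#' Define a disturbance or management event
#'
#' @param year Calendar year of the event.
#' @param kind `"Fire"`, `"Hurricane"` or `"DeadwoodRemoval"`.
#' @param mask Integer cell indices (or logical mask) of the event perimeter.
#' @param area_ha Target area (default: the full mask).
#' @param label Event name used in ledgers and summaries.
#' @param agb_fraction,peat_depth_cm,include_roots Fire consumption spec for
#'   ordinary burned cells; leave `agb_fraction` NULL to use the
#'   severity-based default consumption.
#' @param repeat_spec Optional list(agb_fraction, peat_depth_cm,
#'   include_roots) applied to repeat-catastrophic cells of this fire.
#' @param post_state_repeat State class assigned to repeat-catastrophic cells
#'   after the burn (default Marsh).
#' @param replant For deadwood removal: replant Atlantic white cedar at age 0
#'   on the treated cells.
#' @return A `disturbance_event` list.
#' @export
disturbance_event <- function(year, kind, mask, area_ha = NULL, label = kind,
                              agb_fraction = NULL, peat_depth_cm = 0,
                              include_roots = FALSE, repeat_spec = NULL,
                              post_state_repeat = "Marsh", replant = FALSE) {
  if (is.logical(mask)) mask <- which(mask)
  if (is.null(area_ha)) area_ha <- length(mask)
  spec <- if (!is.null(agb_fraction))
    list(agb_fraction = agb_fraction, peat_depth_cm = peat_depth_cm,
         include_roots = include_roots)
  structure(list(year = as.integer(year), kind = kind, mask = mask,
                 area_ha = area_ha, label = label, spec = spec,
                 repeat_spec = repeat_spec,
                 post_state_repeat = post_state_repeat, replant = replant),
            class = "disturbance_event")
}

#' Bundle disturbance events into a schedule
#'
#' @param ... `disturbance_event` objects (or a single list of them).
#' @return An `event_schedule` (list ordered by year).
#' @export
event_schedule <- function(...) {
  ev <- list(...)
  if (length(ev) == 1 && !inherits(ev[[1]], "disturbance_event")) ev <- ev[[1]]
  stopifnot(all(vapply(ev, inherits, logical(1), "disturbance_event")))
  structure(ev[order(vapply(ev, `[[`, integer(1), "year"))],
            class = "event_schedule")
}

#' Run the historic annual simulation
#'
#' Iterates the coupled state-and-transition / stock-flow model over the
#' simulation span. Each year executes, in order: (1) the year's area-targeted
#' transitions in random order (fires with severity assignment and
#' repeat-catastrophic detection, hurricane transfer, deadwood salvage),
#' (2) probabilistic alternative-succession transitions (adjacency multipliers
#' refreshed every 5 years), (3) the annual stock-flow step, (4) the age
#' increment for forested cells. All fluxes are aggregated into an annual
#' ledger in Tg C (cells are 1 ha, so cell densities in t C/ha sum directly
#' to t C).
#'
#' @param landscape An initialized `peat_landscape` (ages and stocks set).
#' @param schedule An [event_schedule()]; may be empty.
#' @param params,soil Parameter objects.
#' @param seed Integer seed for all stochastic components (severity draws,
#'   target cell selection, event order, succession). Identical seeds give
#'   identical ledgers and landscapes.
#' @param start_year First simulated year (default 1985).
#' @param years Number of annual steps (default 30).
#' @param pathways Probabilistic pathway table.
#' @param severity_spec Fire-severity proportions.
#' @param severity_consumption Severity-based default consumption.
#' @param peat_mode Passed to [step_flows()].
#' @param keep_log Keep the per-cell event log as an attribute.
#' @return An `annual_ledger` data.frame (one row per year; Tg C) with
#'   attributes `events` (per-event fire/management summaries), `initial_tg`
#'   (starting total carbon), `final_landscape`, and optionally `log`.
#' @export
run_historic <- function(landscape, schedule = event_schedule(),
                         params = load_species_params(),
                         soil = soil_params(), seed = NULL,
                         start_year = 1985L, years = 30L,
                         pathways = default_pathways(),
                         severity_spec = fire_severity_spec(),
                         severity_consumption = default_severity_consumption(),
                         peat_mode = "steady_state", keep_log = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  span <- start_year:(start_year + years - 1L)
  ev_years <- vapply(schedule, `[[`, integer(1), "year")
  if (length(ev_years) && !all(ev_years %in% span))
    stop("schedule year(s) outside the simulation span: ",
         paste(setdiff(ev_years, span), collapse = ", "))

  adjacency <- NULL
  rows <- vector("list", years)
  event_rows <- list(); logs <- list()
  initial_tg <- total_carbon(landscape, "Tg")
  adjacency_classes <- unique(stats::na.omit(pathways$adjacency_class))

  for (k in seq_along(span)) {
    y <- span[k]
    landscape$year <- y
    if ((k - 1L) %% 5L == 0L)
      adjacency <- stats::setNames(
        lapply(adjacency_classes, compute_adjacency_multiplier,
               landscape = landscape), adjacency_classes)

    tt <- apply_transition_targets(landscape, schedule[ev_years == y], y,
                                   severity_spec, severity_consumption, soil)
    landscape <- tt$landscape
    pt <- apply_probabilistic_transitions(landscape, pathways, adjacency)
    landscape <- pt$landscape
    sf <- step_flows(landscape, params, soil, peat_mode = peat_mode)
    landscape <- sf$landscape

    fl <- sf$fluxes
    growth <- sum(fl$amount[fl$category == "Growth"])
    rh <- sum(fl$amount[fl$category == "Emission"])
    es <- tt$fire_summaries
    fire_agb <- if (is.null(es)) 0 else sum(es$agb)
    fire_bgb <- if (is.null(es)) 0 else sum(es$bgb_peat + es$bgb_root)
    mgmt <- if (is.null(es)) 0 else sum(es$removed)
    if (!is.null(es)) event_rows[[length(event_rows) + 1L]] <- es
    if (keep_log) {
      if (!is.null(tt$log)) logs[[length(logs) + 1L]] <- tt$log
      if (nrow(pt$events))
        logs[[length(logs) + 1L]] <-
          cbind(year = y, pt$events[c("cell", "transition_type")],
                severity = NA_character_,
                pt$events[c("from_class", "to_class")])
    }

    forested <- is_forested(landscape)
    landscape$age[forested] <- landscape$age[forested] + 1L

    valid <- !is.na(landscape$state)
    agb_stock <- sum(landscape$stocks[valid, c("live_leaf", "live_wood",
                                               "live_root", "leaf_litter",
                                               "deadwood")])
    bgb_stock <- sum(landscape$stocks[valid, c("dead_root", "upper_peat",
                                               "deep_peat")])
    rows[[k]] <- data.frame(
      year = y,
      growth = growth * 1e-6, rh = rh * 1e-6,
      fire_agb = fire_agb * 1e-6, fire_bgb = fire_bgb * 1e-6,
      fire_total = (fire_agb + fire_bgb) * 1e-6,
      management = mgmt * 1e-6,
      nep = (growth - rh) * 1e-6,
      necb = (growth - rh - mgmt - fire_agb - fire_bgb) * 1e-6,
      total_c = total_carbon(landscape, "Tg"),
      agb_stock = agb_stock * 1e-6, bgb_stock = bgb_stock * 1e-6)
  }
  ledger <- do.call(rbind, rows)
  class(ledger) <- c("annual_ledger", "data.frame")
  attr(ledger, "events") <- if (length(event_rows)) do.call(rbind, event_rows)
  attr(ledger, "initial_tg") <- initial_tg
  attr(ledger, "final_landscape") <- landscape
  if (keep_log) attr(ledger, "log") <- do.call(rbind, logs)
  ledger
}

ledger_span <- function(ledger, span) {
  if (is.null(span)) rep(TRUE, nrow(ledger)) else ledger$year %in% span
}

#' Net ecosystem production over a span
#'
#' NEP = total Growth - total heterotrophic respiration, ignoring disturbance
#' and management. Positive values are a net sink.
#'
#' @param ledger An `annual_ledger`.
#' @param span Optional vector of years (default: the whole ledger).
#' @return NEP in Tg C.
#' @export
compute_nep <- function(ledger, span = NULL) {
  i <- ledger_span(ledger, span)
  sum(ledger$growth[i]) - sum(ledger$rh[i])
}

#' Net ecosystem carbon balance over a span
#'
#' NECB = NEP - management removals - fire emissions. Negative values denote
#' a net source.
#'
#' @inheritParams compute_nep
#' @return NECB in Tg C.
#' @export
compute_necb <- function(ledger, span = NULL) {
  i <- ledger_span(ledger, span)
  compute_nep(ledger, span) - sum(ledger$management[i]) -
    sum(ledger$fire_total[i])
}

#' Per-event fire emission summary
#'
#' Tabulates above-ground and below-ground carbon loss per fire event (Tg C)
#' and the soil-elevation-loss equivalent of the peat combustion: the peat
#' carbon emitted divided by (carbon density per cm x burned peat area),
#' reported in metres. A cumulative row sums the events.
#'
#' @param ledger An `annual_ledger` from [run_historic()].
#' @param soil Soil parameters.
#' @param events Restrict to these event labels (default: all fires).
#' @return A data.frame with one row per fire event plus a `Cumulative` row.
#' @export
summarize_fire_events <- function(ledger, soil = soil_params(),
                                  events = NULL) {
  es <- attr(ledger, "events")
  es <- es[es$kind == "Fire", , drop = FALSE]
  if (!is.null(events)) es <- es[es$event %in% events, , drop = FALSE]
  if (is.null(es) || !nrow(es)) stop("ledger contains no fire events")
  cpc <- peat_carbon_per_cm(soil)
  out <- data.frame(
    event = es$event, year = es$year, area_ha = es$area_ha,
    agb_loss = es$agb * 1e-6,
    bgb_loss = (es$bgb_peat + es$bgb_root) * 1e-6,
    total_loss = (es$agb + es$bgb_peat + es$bgb_root) * 1e-6,
    elevation_m = ifelse(es$peat_cells > 0,
                         es$bgb_peat / (cpc * es$peat_cells) / 100, 0))
  rbind(out, data.frame(event = "Cumulative", year = NA, area_ha = sum(out$area_ha),
                        agb_loss = sum(out$agb_loss),
                        bgb_loss = sum(out$bgb_loss),
                        total_loss = sum(out$total_loss),
                        elevation_m = sum(out$elevation_m)))
}

#' Years to re-accumulate a burned peat column
#'
#' Converts a peat depth to soil carbon (via the soil carbon density per cm)
#' and divides by a long-term peat accumulation rate, rounding to the nearest
#' decade. Used to express the permanence of deep peat combustion losses.
#'
#' @param peat_depth_cm Burned peat depth, cm.
#' @param rate Peat carbon accumulation rate, t C/ha/yr (> 0).
#' @param soil Soil parameters.
#' @return Years, rounded to the nearest 10.
#' @export
re_amass_time <- function(peat_depth_cm, rate, soil = soil_params()) {
  if (rate <= 0) stop("rate must be > 0")
  if (peat_depth_cm < 0) stop("peat_depth_cm must be >= 0")
  round(peat_depth_cm * peat_carbon_per_cm(soil) / rate / 10) * 10
}
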