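neighbor_shift_sum <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  pad <- function(m, dr, dc) {
    res <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    res[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    res
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + pad(mat, dr, dc)
  }
  out
}

#' Neighbourhood adjacency multiplier
#'
#' For every cell, the proportion of its 8 neighbours (moving window) in the
#' target state class. Edge cells are normalized by their in-grid neighbour
#' count, so the multiplier is always in [0, 1]. A cell with no matching
#' neighbour gets 0, which blocks adjacency-gated transitions into the target
#' class.
#'
#' @param landscape A `peat_landscape`.
#' @param target_class State-class label.
#' @return Numeric vector (row-major over cells) of multipliers in [0, 1].
#' @export
compute_adjacency_multiplier <- function(landscape, target_class) {
  m <- matrix(as.numeric(!is.na(landscape$state) &
                           landscape$state == target_class),
              landscape$n_rows, landscape$n_cols, byrow = TRUE)
  ones <- matrix(1, landscape$n_rows, landscape$n_cols)
  cnt <- neighbor_shift_sum(m)
  denom <- neighbor_shift_sum(ones)
  as.numeric(t(cnt / denom))
}

#' Draw fire-severity labels for burned cells
#'
#' Each burned cell is independently labelled high/med/low with the spec's
#' proportions. High severity resets stand age; medium and low do not.
#'
#' @param n_cells Number of burned cells.
#' @param spec A [fire_severity_spec()].
#' @return Character vector of labels.
#' @export
assign_fire_severity <- function(n_cells, spec = fire_severity_spec()) {
  stopifnot(inherits(spec, "fire_severity_spec"))
  sample(names(spec$p), n_cells, replace = TRUE, prob = spec$p)
}

#' Detect repeat-catastrophic fire cells
#'
#' A burning cell is a repeat-catastrophic fire if it lies in the Dry stratum
#' and burned previously within the last `window` years (strictly less than
#' `window` years before the current fire).
#'
#' @param landscape A `peat_landscape` (carries the per-cell last fire year).
#' @param cells Cells burning in `current_year`.
#' @param current_year Calendar year of the current fire.
#' @param window Repeat window in years (default 5).
#' @return Logical vector over `cells`.
#' @export
detect_repeat_catastrophic <- function(landscape, cells, current_year,
                                       window = 5) {
  if (is.logical(cells)) cells <- which(cells)
  lf <- landscape$last_fire_year[cells]
  gap <- current_year - lf
  landscape$stratum[cells] == "Dry" & !is.na(lf) & gap > 0 & gap < window
}

#' Apply probabilistic (alternative succession) transitions
#'
#' Each cell matching a pathway's from-class, stratum and age gate
#' (`age <= age_max`) transitions to the pathway's to-class with probability
#' `probability x adjacency multiplier`. Transitioned cells keep their age and
#' stocks unless the pathway resets age. Uses the current RNG state; seed the
#' caller for reproducibility.
#'
#' @param landscape A `peat_landscape`.
#' @param pathways Pathway table, see [default_pathways()].
#' @param adjacency Named list of per-cell adjacency multiplier vectors, keyed
#'   by target class (refreshed on the caller's cadence); computed fresh for
#'   any missing class.
#' @return A list with `landscape` and `events` (data.frame of transitions).
#' @export
apply_probabilistic_transitions <- function(landscape,
                                            pathways = default_pathways(),
                                            adjacency = NULL) {
  if (any(pathways$probability < 0 | pathways$probability > 1))
    stop("pathway probabilities must be in [0, 1]")
  events <- list()
  for (i in seq_len(nrow(pathways))) {
    pw <- pathways[i, ]
    adj <- adjacency[[pw$adjacency_class]]
    if (is.null(adj) && !is.na(pw$adjacency_class))
      adj <- compute_adjacency_multiplier(landscape, pw$adjacency_class)
    eligible <- which(!is.na(landscape$state) &
                        landscape$state == pw$from &
                        landscape$stratum == pw$stratum &
                        landscape$age <= pw$age_max)
    if (!length(eligible)) next
    p <- pw$probability * (if (is.null(adj)) 1 else adj[eligible])
    hit <- eligible[stats::runif(length(eligible)) < p]
    if (!length(hit)) next
    landscape$state[hit] <- pw$to
    if (isTRUE(pw$age_reset)) landscape$age[hit] <- 0L
    events[[i]] <- data.frame(cell = hit, from_class = pw$from,
                              to_class = pw$to,
                              transition_type = "AlternativeSuccession",
                              stringsAsFactors = FALSE)
  }
  list(landscape = landscape,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(cell = integer(0), from_class = character(0),
                                to_class = character(0),
                                transition_type = character(0)))
}

# per-severity default consumption fractions over the AGB pools
default_severity_consumption <- function() {
  list(
    low = c(leaf_litter = 0.5),
    med = c(leaf_litter = 1.0, deadwood = 0.5),
    high = c(live_leaf = 0.8, live_wood = 0.8, leaf_litter = 0.8,
             deadwood = 0.8)
  )
}

#' Apply the area-targeted transitions of one simulation year
#'
#' Executes the year's disturbance/management events (fire, hurricane,
#' deadwood removal with replanting) in random order. For each event exactly
#' `min(target area, eligible area)` cells inside the event mask transition
#' (uniform random selection without replacement when eligible area exceeds
#' the target; a shortfall is logged with a warning).
#'
#' Fires: each burned cell gets a severity label; cells flagged
#' repeat-catastrophic (second fire within 5 years, Dry stratum) receive the
#' event's catastrophic `repeat_spec` consumption, reset age and convert to
#' the post-fire state (Marsh by default); other burned cells receive the
#' event's own consumption spec, or severity-based default consumption when
#' the event does not define one. High-severity cells reset age.
#'
#' @param landscape A `peat_landscape`.
#' @param events List of [disturbance_event()]s scheduled for `year`.
#' @param year Calendar year.
#' @param severity_spec A [fire_severity_spec()].
#' @param severity_consumption Per-severity consumption fraction lists.
#' @param soil Soil parameters.
#' @return List with `landscape`, `fire_summaries` (per-event data.frame),
#'   `fluxes` (all flux records), and `log` (per-cell event log).
#' @export
apply_transition_targets <- function(landscape, events, year,
                                     severity_spec = fire_severity_spec(),
                                     severity_consumption =
                                       default_severity_consumption(),
                                     soil = landscape$soil) {
  fire_summaries <- list(); fluxes <- list(); log <- list()
  for (ev in events[sample.int(length(events))]) {
    mask <- ev$mask
    if (any(mask < 1 | mask > n_cells(landscape)))
      stop("event mask outside the grid")
    res <- switch(ev$kind,
      Fire = target_fire(landscape, ev, year, severity_spec,
                         severity_consumption, soil),
      Hurricane = target_hurricane(landscape, ev, year),
      DeadwoodRemoval = target_removal(landscape, ev, year),
      stop("unknown event kind: ", ev$kind))
    landscape <- res$landscape
    fire_summaries[[length(fire_summaries) + 1L]] <- res$summary
    fluxes[[length(fluxes) + 1L]] <- res$fluxes
    log[[length(log) + 1L]] <- res$log
  }
  list(landscape = landscape,
       fire_summaries = do.call(rbind, fire_summaries),
       fluxes = do.call(rbind, fluxes),
       log = do.call(rbind, log))
}

pick_target_cells <- function(eligible, area_ha, label) {
  if (length(eligible) > area_ha) {
    resample(eligible, area_ha)
  } else {
    if (length(eligible) < area_ha)
      warning(label, ": only ", length(eligible), " of ", area_ha,
              " eligible ha; target shortfall")
    eligible
  }
}

resample <- function(x, n) x[sample.int(length(x), n)]

target_fire <- function(landscape, ev, year, severity_spec,
                        severity_consumption, soil) {
  eligible <- ev$mask[!is.na(landscape$state[ev$mask]) &
                        landscape$state[ev$mask] %in% forest_classes()]
  burn <- pick_target_cells(eligible, ev$area_ha, ev$label)
  sev <- assign_fire_severity(length(burn), severity_spec)
  rep <- detect_repeat_catastrophic(landscape, burn, year)
  agb <- bgb_peat <- bgb_root <- 0; peat_cells <- 0L; fluxes <- list()

  consume <- function(cells, agb_fraction, peat_cm, roots, fractions = NULL) {
    r <- apply_fire_consumption(landscape, cells, agb_fraction = agb_fraction,
                                peat_depth_cm = peat_cm,
                                include_roots = roots, fractions = fractions,
                                soil = soil)
    landscape <<- r$landscape
    agb <<- agb + r$agb; bgb_peat <<- bgb_peat + r$bgb_peat
    bgb_root <<- bgb_root + r$bgb_root; peat_cells <<- peat_cells + r$peat_cells
    fluxes[[length(fluxes) + 1L]] <<- r$fluxes
  }

  if (any(rep)) {
    rs <- if (!is.null(ev$repeat_spec)) ev$repeat_spec else ev$spec
    if (is.null(rs)) rs <- list(agb_fraction = 0.8, peat_depth_cm = 0,
                                include_roots = FALSE)
    consume(burn[rep], rs$agb_fraction, rs$peat_depth_cm, rs$include_roots)
  }
  ordinary <- burn[!rep]
  if (length(ordinary)) {
    if (!is.null(ev$spec)) {
      consume(ordinary, ev$spec$agb_fraction, ev$spec$peat_depth_cm,
              ev$spec$include_roots)
    } else {
      for (s in names(severity_consumption)) {
        grp <- ordinary[sev[!rep] == s]
        if (length(grp))
          consume(grp, NULL, 0, FALSE, fractions = severity_consumption[[s]])
      }
    }
  }

  from_class <- landscape$state[burn]
  landscape$last_fire_year[burn] <- year
  landscape$last_fire_severity[burn] <- ifelse(rep, "repeat", sev)
  landscape$age[burn[sev == "high" | rep]] <- 0L
  if (any(rep)) {
    landscape$state[burn[rep]] <-
      if (!is.null(ev$post_state_repeat)) ev$post_state_repeat else "Marsh"
    landscape$age[burn[rep]] <- 0L
  }
  list(landscape = landscape,
       summary = data.frame(event = ev$label, year = year,
                            kind = "Fire", area_ha = length(burn),
                            agb = agb, bgb_peat = bgb_peat,
                            bgb_root = bgb_root, removed = 0,
                            peat_cells = peat_cells,
                            stringsAsFactors = FALSE),
       fluxes = do.call(rbind, fluxes),
       log = data.frame(year = year, cell = burn,
                        transition_type = ifelse(rep, "RepeatCatastrophicFire",
                                                 paste0("Fire", toupper(substr(sev, 1, 1)),
                                                        substr(sev, 2, 10))),
                        severity = ifelse(rep, "repeat", sev),
                        from_class = from_class,
                        to_class = landscape$state[burn],
                        stringsAsFactors = FALSE))
}

target_hurricane <- function(landscape, ev, year) {
  eligible <- ev$mask[!is.na(landscape$state[ev$mask]) &
                        landscape$state[ev$mask] %in% forest_classes()]
  hit <- pick_target_cells(eligible, ev$area_ha, ev$label)
  r <- apply_hurricane_transfer(landscape, hit)
  landscape <- r$landscape
  landscape$age[hit] <- 0L
  list(landscape = landscape,
       summary = data.frame(event = ev$label, year = year, kind = "Hurricane",
                            area_ha = length(hit), agb = 0, bgb_peat = 0,
                            bgb_root = 0, removed = 0, peat_cells = 0L,
                            stringsAsFactors = FALSE),
       fluxes = r$fluxes,
       log = data.frame(year = year, cell = hit,
                        transition_type = "Hurricane", severity = NA_character_,
                        from_class = landscape$state[hit],
                        to_class = landscape$state[hit],
                        stringsAsFactors = FALSE))
}

target_removal <- function(landscape, ev, year) {
  eligible <- ev$mask[!is.na(landscape$state[ev$mask]) &
                        landscape$stocks[ev$mask, "deadwood"] > 0]
  hit <- pick_target_cells(eligible, ev$area_ha, ev$label)
  r <- apply_deadwood_harvest(landscape, hit)
  landscape <- r$landscape
  if (isTRUE(ev$replant)) {
    landscape$state[hit] <- "AtlanticWhiteCedar"
    landscape$age[hit] <- 0L
  }
  list(landscape = landscape,
       summary = data.frame(event = ev$label, year = year,
                            kind = "DeadwoodRemoval", area_ha = length(hit),
                            agb = 0, bgb_peat = 0, bgb_root = 0,
                            removed = r$removed, peat_cells = 0L,
                            stringsAsFactors = FALSE),
       fluxes = r$fluxes,
       log = data.frame(year = year, cell = hit,
                        transition_type = "DeadwoodRemoval",
                        severity = NA_character_,
                        from_class = landscape$state[hit],
                        to_class = landscape$state[hit],
                        stringsAsFactors = FALSE))
}
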