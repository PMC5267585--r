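#' Configuration for the synthetic landscape generator
#'
#' The generator emulates the refuge's composition: ~54,000 ha with Atlantic
#' white cedar 3%, cypress-gum 12%, maple-gum 61%, pond pine 15% and the
#' remainder marsh/open water, a contiguous Dry moisture region around the
#' fire-scar area, and a forested age structure (uniform on
#' [`age_min`, `age_max`] by default).
#'
#' @param total_area_ha Total active area (default 54,000 ha).
#' @param class_proportions Named numeric vector of area fractions over state
#'   classes; must sum to 1.
#' @param dry_fraction Fraction of the landscape in the Dry stratum.
#' @param age_min,age_max Uniform age bounds for forested cells, years.
#' @param seed Integer seed; the generator is deterministic per seed.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(total_area_ha = 54000,
                             class_proportions = c(
                               AtlanticWhiteCedar = 0.03, CypressGum = 0.12,
                               MapleGum = 0.61, PondPine = 0.15,
                               Marsh = 0.06, OpenWater = 0.03),
                             dry_fraction = 0.10,
                             age_min = 20, age_max = 80, seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (any(class_proportions < 0) || any(class_proportions > 1))
    stop("class proportions must be in [0, 1]")
  bad <- setdiff(names(class_proportions), state_classes())
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  structure(list(total_area_ha = total_area_ha,
                 class_proportions = class_proportions,
                 dry_fraction = dry_fraction,
                 age_min = age_min, age_max = age_max, seed = seed),
            class = "landscape_config")
}

grid_shape <- function(area) {
  d <- which(area %% seq_len(area) == 0)
  d <- d[d >= sqrt(area) / 1.5 & d <= sqrt(area) * 1.5]
  if (length(d)) {
    nr <- d[which.min(abs(d - sqrt(area)))]
    c(nr, area %/% nr)
  } else {
    nr <- floor(sqrt(area))
    c(nr, ceiling(area / nr))  # trailing cells beyond `area` stay void
  }
}

neighbors8 <- function(cells, n_rows, n_cols) {
  r <- (cells - 1L) %/% n_cols
  cl <- (cells - 1L) %% n_cols
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- cl + dc
    ok <- rr >= 0 & rr < n_rows & cc >= 0 & cc < n_cols
    out <- c(out, rr[ok] * n_cols + cc[ok] + 1L)
  }
  unique(out)
}

#' Dilate a cell mask
#'
#' Morphological dilation by `radius` rings of 8-neighbours.
#'
#' @param cells Integer cell indices.
#' @param n_rows,n_cols Grid shape.
#' @param radius Number of dilation rings.
#' @return Integer cell indices of the dilated mask.
#' @export
dilate_mask <- function(cells, n_rows, n_cols, radius = 1) {
  for (i in seq_len(radius))
    cells <- union(cells, neighbors8(cells, n_rows, n_cols))
  sort(cells)
}

#' Generate a synthetic landscape
#'
#' Grows spatially clustered class patches from seeded nuclei until every
#' class hits its target cell count exactly (class areas are integers of ha
#' and match the configured proportions to the rounding of one cell). Strata
#' are assigned as a contiguous Dry region grown to `dry_fraction` of the
#' area (around `dry_core` when given, e.g. the fire-scar region); forested
#' ages are drawn uniformly on [`age_min`, `age_max`]; biomass stocks are
#' initialized from the spin-up growth curves at each cell's age. Output is
#' deterministic per `config$seed`.
#'
#' @param config A [landscape_config()].
#' @param params,soil Parameter objects.
#' @param curves Growth curves (computed if NULL).
#' @param dry_core Optional cell indices around which the Dry region grows.
#' @return A `peat_landscape`.
#' @export
generate_landscape <- function(config = landscape_config(),
                               params = load_species_params(),
                               soil = soil_params(), curves = NULL,
                               dry_core = NULL) {
  set.seed(config$seed)
  A <- config$total_area_ha
  shp <- grid_shape(A)
  n_rows <- shp[1]; n_cols <- shp[2]
  n <- n_rows * n_cols
  active <- seq_len(A)  # row-major block; any remainder cells are void

  props <- config$class_proportions[config$class_proportions > 0]
  counts <- round(props * A)
  counts[which.max(counts)] <- counts[which.max(counts)] + (A - sum(counts))
  cls <- rep(NA_character_, n)
  assigned <- rep(TRUE, n); assigned[active] <- FALSE

  frontiers <- lapply(names(counts), function(k) integer(0))
  names(frontiers) <- names(counts)
  need <- counts
  n_nuclei <- round(counts / 600)  # ~600-ha patches
  n_nuclei[n_nuclei < 1] <- 1
  for (k in names(counts)) {
    nuc <- resample(which(!assigned), min(n_nuclei[[k]], need[[k]]))
    frontiers[[k]] <- nuc
  }
  while (any(need > 0)) {
    for (k in names(counts)) {
      if (need[[k]] == 0) next
      f <- frontiers[[k]]
      f <- unique(f[!assigned[f]])
      if (!length(f)) f <- resample(which(!assigned), 1L)
      take <- resample(f, min(length(f), 64L, need[[k]]))
      cls[take] <- k
      assigned[take] <- TRUE
      need[[k]] <- need[[k]] - length(take)
      frontiers[[k]] <- c(f[!(f %in% take)],
                          neighbors8(take, n_rows, n_cols))
    }
  }

  # contiguous Dry region
  stratum <- rep("Wet", n)
  dry_target <- round(config$dry_fraction * A)
  if (dry_target > 0) {
    core <- if (!is.null(dry_core)) intersect(dry_core, active)
            else resample(active, 1L)
    dry <- core
    while (length(dry) < dry_target)
      dry <- intersect(dilate_mask(dry, n_rows, n_cols, 1), active)
    stratum[dry] <- "Dry"
  }

  age <- integer(n)
  forested <- !is.na(cls) & cls %in% forest_classes()
  age[forested] <- sample(config$age_min:config$age_max, sum(forested),
                          replace = TRUE)
  land <- new_landscape(cls, stratum, age, n_rows, n_cols, soil = soil)
  if (is.null(curves)) curves <- run_all_spinups(params, soil = soil)
  init_stocks(land, params, from = "curve", curves = curves)
}

#' Generate a contiguous fire perimeter
#'
#' Grows an 8-connected mask of exactly `round(area_ha)` cells by seeded
#' region growing. With `overlap_with`, exactly
#' `round(overlap_fraction * area_ha)` of the cells fall inside the prior
#' perimeter and the rest outside it (the perimeters of two sequential fires
#' on approximately the same patch).
#'
#' @param landscape A `peat_landscape` (supplies the grid and active cells).
#' @param area_ha Perimeter area in ha (= cells).
#' @param overlap_with Optional prior perimeter (integer cells).
#' @param overlap_fraction Fraction of this perimeter inside the prior one.
#' @param within Optional cell set the perimeter must stay inside.
#' @param start Optional starting cell (anchor).
#' @return Sorted integer cell indices.
#' @export
generate_fire_perimeter <- function(landscape, area_ha, overlap_with = NULL,
                                    overlap_fraction = 0, within = NULL,
                                    start = NULL) {
  n_rows <- landscape$n_rows; n_cols <- landscape$n_cols
  n <- n_rows * n_cols
  area <- round(area_ha)
  allowed <- !is.na(landscape$state)
  if (!is.null(within)) {
    w <- rep(FALSE, n); w[within] <- TRUE
    allowed <- allowed & w
  }
  if (sum(allowed) < area) stop("perimeter area exceeds the eligible area")
  inside <- rep(FALSE, n)
  if (!is.null(overlap_with)) inside[overlap_with] <- TRUE
  need_in <- if (is.null(overlap_with)) 0L else round(overlap_fraction * area)
  need_out <- area - need_in
  if (need_in > sum(inside & allowed))
    stop("requested overlap exceeds the prior perimeter")

  side_ok <- function(cells) {
    (inside[cells] & need_in > 0L) | (!inside[cells] & need_out > 0L)
  }
  chosen <- rep(FALSE, n)
  if (is.null(start)) {
    pool <- which(allowed & side_ok(seq_len(n)))
    if (!is.null(overlap_with) && need_in > 0L)
      pool <- intersect(pool, which(inside))
    start <- resample(pool, 1L)
  }
  frontier <- start
  while (need_in + need_out > 0L) {
    frontier <- frontier[!chosen[frontier] & allowed[frontier]]
    cand <- frontier[side_ok(frontier)]
    if (!length(cand)) {
      # re-nucleate on the needed side, adjacent to the mask to stay connected
      adj <- neighbors8(which(chosen), n_rows, n_cols)
      adj <- adj[!chosen[adj] & allowed[adj] & side_ok(adj)]
      if (!length(adj)) stop("infeasible perimeter/overlap request")
      cand <- adj
      frontier <- union(frontier, adj)
    }
    cell <- resample(cand, 1L)
    chosen[cell] <- TRUE
    if (inside[cell]) need_in <- need_in - 1L else need_out <- need_out - 1L
    frontier <- c(frontier, neighbors8(cell, n_rows, n_cols))
  }
  sort(which(chosen))
}

#' Default historic event schedule
#'
#' The reconstructed disturbance history: the 2003 hurricane blow-down
#' (625 ha of Atlantic white cedar), deadwood salvage and replanting of
#' 316 ha spread over 2004-2007, the 2008 South One fire (2400 ha, 80% of the
#' above-ground pools plus 20 cm of peat), the 2011 Lateral West fire
#' (2500 ha; repeat-catastrophic cells in the overlap lose their remaining
#' above-ground biomass, 50 cm of peat and their root pools, then convert to
#' Marsh), and four configurable background fires.
#'
#' @param masks A list with elements `south_one`, `lateral_west`, `hurricane`,
#'   `removal`, and optionally `other` (list of masks for background fires).
#' @param other_years Years of the background fires.
#' @param disturbances Set FALSE for an empty schedule.
#' @return An [event_schedule()].
#' @export
default_schedule <- function(masks, other_years = c(1989, 1995, 2001, 2014),
                             disturbances = TRUE) {
  if (!disturbances) return(event_schedule())
  ev <- list(
    disturbance_event(2003, "Hurricane", masks$hurricane, area_ha = 625,
                      label = "Hurricane Isabel"),
    disturbance_event(2008, "Fire", masks$south_one, label = "South One",
                      agb_fraction = 0.80, peat_depth_cm = 20,
                      include_roots = FALSE),
    disturbance_event(2011, "Fire", masks$lateral_west, label = "Lateral West",
                      repeat_spec = list(agb_fraction = 1.0,
                                         peat_depth_cm = 50,
                                         include_roots = TRUE),
                      post_state_repeat = "Marsh")
  )
  removal_years <- 2004:2007
  per_year <- rep(length(masks$removal) %/% length(removal_years),
                  length(removal_years))
  per_year[1] <- per_year[1] + length(masks$removal) - sum(per_year)
  for (i in seq_along(removal_years))
    ev[[length(ev) + 1L]] <- disturbance_event(
      removal_years[i], "DeadwoodRemoval", masks$removal,
      area_ha = per_year[i], label = "Deadwood salvage", replant = TRUE)
  for (i in seq_along(masks$other))
    ev[[length(ev) + 1L]] <- disturbance_event(
      other_years[i], "Fire", masks$other[[i]],
      label = paste0("Other fire ", other_years[i]))
  event_schedule(ev)
}

#' Build the reference synthetic study landscape and schedule
#'
#' Generates the full synthetic emulation of the study system in one call:
#' the class mosaic, the South One (2400 ha) and Lateral West (2500 ha, 85%
#' overlap) perimeters, a 625-ha hurricane footprint inside the overlap with
#' a 316-ha salvage block inside it, the Dry stratum grown around the scar,
#' the scar region forced to Atlantic white cedar at age 100 (the average
#' mature cedar age) with curve-derived stocks, and the default event
#' schedule. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param config A [landscape_config()] (its seed is overridden by `seed`).
#' @param params,soil Parameter objects.
#' @param curves Growth curves (computed if NULL).
#' @param scar_age Age assigned to the scar region in the start year.
#' @param disturbances Build the default schedule (FALSE for an undisturbed
#'   run).
#' @return A list with `landscape`, `schedule`, `masks` and `curves`.
#' @export
reference_scenario <- function(seed = 1L, config = landscape_config(),
                               params = load_species_params(),
                               soil = soil_params(), curves = NULL,
                               scar_age = 100L, disturbances = TRUE) {
  config$seed <- seed
  if (is.null(curves)) curves <- run_all_spinups(params, soil = soil)

  land <- generate_landscape(config, params, soil, curves)
  # set.seed in generate_landscape fixes the stream for everything below
  anchor <- (round(0.62 * land$n_rows) - 1L) * land$n_cols +
    round(0.35 * land$n_cols)
  s1 <- generate_fire_perimeter(land, 2400, start = anchor)
  lw <- generate_fire_perimeter(land, 2500, overlap_with = s1,
                                overlap_fraction = 0.85)
  hur <- generate_fire_perimeter(land, 625, within = intersect(s1, lw))
  removal <- generate_fire_perimeter(land, 316, within = hur)
  scar <- sort(union(s1, lw))

  # Dry stratum: contiguous region grown around the scar
  dry_target <- round(config$dry_fraction * config$total_area_ha)
  dry <- scar
  active <- which(!is.na(land$state))
  while (length(dry) < dry_target)
    dry <- intersect(dilate_mask(dry, land$n_rows, land$n_cols, 1), active)
  land$stratum[active] <- "Wet"
  land$stratum[dry] <- "Dry"

  land <- rollback_ages(land, 0, scar_mask = scar, scar_age = scar_age,
                        curves = curves, params = params, soil = soil)

  forested <- which(is_forested(land))
  other <- lapply(c(400, 250, 350, 300), function(a)
    generate_fire_perimeter(land, a,
                            within = setdiff(forested,
                                             dilate_mask(scar, land$n_rows,
                                                         land$n_cols, 2))))
  masks <- list(south_one = s1, lateral_west = lw, hurricane = hur,
                removal = removal, scar = scar, other = other)
  list(landscape = land,
       schedule = default_schedule(masks, disturbances = disturbances),
       masks = masks, curves = curves)
}
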