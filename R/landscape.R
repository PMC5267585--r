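#' Construct a simulation landscape
#'
#' A landscape is a row-major grid of 1-ha (100 m x 100 m) cells. Each cell
#' carries a state class, a moisture stratum (Wet/Dry), a stand age (forested
#' classes only), the eight carbon pools in t C/ha, the remaining upper and
#' deep peat depths in cm, and its fire history. Cells with `NA` state are
#' void (nodata) and excluded from all totals.
#'
#' @param state Character vector (length `n_rows * n_cols`, row-major) of
#'   state-class labels, NA for void cells.
#' @param stratum Character vector of "Wet"/"Dry" (recycled if length 1).
#' @param age Integer vector of stand ages (recycled if length 1); ignored
#'   (forced to 0) for non-forested cells.
#' @param n_rows,n_cols Grid shape.
#' @param year Current calendar year (optional).
#' @param soil A [soil_params()] object used to initialize the peat pools.
#' @return An object of class `peat_landscape`.
#' @export
new_landscape <- function(state, stratum = "Wet", age = 0L,
                          n_rows, n_cols, year = NA_integer_,
                          soil = soil_params()) {
  n <- n_rows * n_cols
  if (length(state) != n) stop("state must have length n_rows * n_cols")
  bad <- setdiff(unique(state[!is.na(state)]), state_classes())
  if (length(bad))
    stop("unknown state class code(s): ", paste(bad, collapse = ", "))
  stratum <- rep_len(as.character(stratum), n)
  if (!all(stratum[!is.na(state)] %in% strata()))
    stop("stratum must be 'Wet' or 'Dry'")
  age <- rep_len(as.integer(age), n)
  if (any(age[!is.na(state)] < 0)) stop("age must be >= 0")
  forested <- !is.na(state) & state %in% forest_classes()
  age[!forested] <- 0L

  stocks <- matrix(0, n, length(pool_names()),
                   dimnames = list(NULL, pool_names()))
  cpc <- peat_carbon_per_cm(soil)
  upper_cm <- ifelse(is.na(state), 0, soil$upper_depth)
  deep_cm <- ifelse(is.na(state), 0, soil$total_depth - soil$upper_depth)
  stocks[, "upper_peat"] <- upper_cm * cpc
  stocks[, "deep_peat"] <- deep_cm * cpc

  structure(list(
    n_rows = n_rows, n_cols = n_cols, cell_area = 1.0,
    state = as.character(state), stratum = stratum, age = age,
    stocks = stocks,
    upper_peat_cm = upper_cm, deep_peat_cm = deep_cm,
    last_fire_year = rep(NA_integer_, n),
    last_fire_severity = rep(NA_character_, n),
    year = year, soil = soil
  ), class = "peat_landscape")
}

n_cells <- function(landscape) landscape$n_rows * landscape$n_cols

#' @export
print.peat_landscape <- function(x, ...) {
  valid <- !is.na(x$state)
  cat("peat_landscape:", x$n_rows, "x", x$n_cols, "grid,",
      sum(valid), "ha active\n")
  if (any(valid)) {
    comp <- summarize_composition(x)
    cat(paste(sprintf("  %-18s %6d ha (%5.1f%%)", comp$state_class,
                      comp$area_ha, comp$percent), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Which cells are forested
#'
#' @param landscape A `peat_landscape`.
#' @return Logical vector over cells.
#' @export
is_forested <- function(landscape) {
  !is.na(landscape$state) & landscape$state %in% forest_classes()
}

#' Initialize biomass stocks of forested cells
#'
#' Sets the six biomass pools of every forested cell either to the
#' mature-stand densities of its class (`from = "mature"`) or to the spin-up
#' growth-curve densities at the cell's age (`from = "curve"`). Peat pools are
#' left untouched (they are set by the standardized column depths).
#'
#' @param landscape A `peat_landscape`.
#' @param params Species parameter set.
#' @param from `"mature"` or `"curve"`.
#' @param curves Named list of [run_spinup()] growth curves (required for
#'   `from = "curve"`).
#' @return The updated landscape.
#' @export
init_stocks <- function(landscape, params = load_species_params(),
                        from = c("mature", "curve"), curves = NULL) {
  from <- match.arg(from)
  biomass <- setdiff(pool_names(), c("upper_peat", "deep_peat"))
  for (sp in forest_classes()) {
    i <- which(!is.na(landscape$state) & landscape$state == sp)
    if (!length(i)) next
    if (from == "mature") {
      landscape$stocks[i, biomass] <-
        matrix(params[[sp]]$init_stocks[biomass], length(i), length(biomass),
               byrow = TRUE)
    } else {
      if (is.null(curves[[sp]]))
        stop("growth curve for ", sp, " required when from = 'curve'")
      landscape$stocks[i, biomass] <-
        curve_stocks_at_age(curves[[sp]], landscape$age[i])[, biomass]
    }
  }
  landscape
}

#' Load a landscape from raster grids or a cell table
#'
#' Reads the state-class, age and stratum layers either from three ESRI ASCII
#' grids (integer class codes per the packaged legend, 0 = Dry / 1 = Wet
#' stratum, -9999 nodata) or from a CSV cell table with columns
#' `row,col,state_class,stratum,age`. Stocks are initialized per
#' [init_stocks()].
#'
#' @param state_raster,age_raster,stratum_raster Paths to ASCII grids, or a
#'   single CSV path in `cell_table`.
#' @param cell_table Path to a CSV cell table (alternative to the rasters).
#' @param n_rows,n_cols Grid shape for the cell-table path (defaults to the
#'   maximum row/col present).
#' @param params,soil Parameter objects.
#' @param stocks_from,curves Passed to [init_stocks()].
#' @param year Calendar year tag.
#' @return A `peat_landscape`.
#' @export
load_landscape <- function(state_raster = NULL, age_raster = NULL,
                           stratum_raster = NULL, cell_table = NULL,
                           n_rows = NULL, n_cols = NULL,
                           params = load_species_params(),
                           soil = soil_params(),
                           stocks_from = "mature", curves = NULL,
                           year = NA_integer_) {
  if (!is.null(cell_table)) {
    df <- utils::read.csv(cell_table, stringsAsFactors = FALSE)
    need <- c("row", "col", "state_class", "stratum", "age")
    if (!all(need %in% names(df)))
      stop("cell table must have columns ", paste(need, collapse = ","))
    if (is.null(n_rows)) n_rows <- max(df$row) + 1L
    if (is.null(n_cols)) n_cols <- max(df$col) + 1L
    state <- rep(NA_character_, n_rows * n_cols)
    stratum <- rep("Wet", n_rows * n_cols)
    age <- integer(n_rows * n_cols)
    idx <- df$row * n_cols + df$col + 1L  # 0-based row/col, row-major
    state[idx] <- df$state_class
    stratum[idx] <- df$stratum
    age[idx] <- df$age
  } else {
    s <- read_ascii_grid(state_raster)
    a <- read_ascii_grid(age_raster)
    z <- read_ascii_grid(stratum_raster)
    if (!identical(dim(s$data), dim(a$data)) ||
        !identical(dim(s$data), dim(z$data)))
      stop("raster shape mismatch: state ", paste(dim(s$data), collapse = "x"),
           ", age ", paste(dim(a$data), collapse = "x"),
           ", stratum ", paste(dim(z$data), collapse = "x"))
    n_rows <- nrow(s$data); n_cols <- ncol(s$data)
    code <- as.integer(t(s$data))  # row-major
    codes <- class_codes()
    known <- is.na(code) | code %in% codes
    if (!all(known))
      stop("unknown state class code(s): ",
           paste(sort(unique(code[!known])), collapse = ", "))
    state <- names(codes)[match(code, codes)]
    age <- as.integer(t(a$data)); age[is.na(age)] <- 0L
    zc <- as.integer(t(z$data))
    stratum <- ifelse(!is.na(zc) & zc == 1L, "Wet", "Dry")
  }
  land <- new_landscape(state, stratum, age, n_rows, n_cols,
                        year = year, soil = soil)
  init_stocks(land, params, from = stocks_from, curves = curves)
}

#' Integer raster codes for the state classes
#'
#' @return Named integer vector mapping class label to raster code.
#' @export
class_codes <- function() {
  stats::setNames(seq_along(state_classes()), state_classes())
}

#' Write a landscape to disk
#'
#' `format = "csv"` writes a single cell table
#' (`row,col,state_class,stratum,age`, 0-based indices); `format = "ascii"`
#' writes three ESRI ASCII grids (`state.asc`, `age.asc`, `stratum.asc`) plus
#' a `legend.txt` sidecar mapping class codes to labels.
#'
#' @param landscape A `peat_landscape`.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` or `"ascii"`.
#' @return Invisibly, the paths written.
#' @export
write_landscape <- function(landscape, dir, format = c("csv", "ascii")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  valid <- which(!is.na(landscape$state))
  if (format == "csv") {
    path <- file.path(dir, "cells.csv")
    df <- data.frame(
      row = (valid - 1L) %/% landscape$n_cols,
      col = (valid - 1L) %% landscape$n_cols,
      state_class = landscape$state[valid],
      stratum = landscape$stratum[valid],
      age = landscape$age[valid])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  codes <- class_codes()
  as_grid <- function(v) matrix(v, landscape$n_rows, landscape$n_cols,
                                byrow = TRUE)
  paths <- c(state = file.path(dir, "state.asc"),
             age = file.path(dir, "age.asc"),
             stratum = file.path(dir, "stratum.asc"),
             legend = file.path(dir, "legend.txt"))
  write_ascii_grid(as_grid(unname(codes[landscape$state])), paths["state"])
  write_ascii_grid(as_grid(ifelse(is.na(landscape$state), NA,
                                  landscape$age)), paths["age"])
  write_ascii_grid(as_grid(ifelse(is.na(landscape$state), NA,
                                  as.integer(landscape$stratum == "Wet"))),
                   paths["stratum"])
  writeLines(paste(codes, names(codes)), paths["legend"])
  invisible(paths)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return A list with `data` (numeric matrix, NA for nodata) and `header`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("ASCII grid has ", length(vals), " values, expected ",
         hdr$nrows * hdr$ncols)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  list(data = matrix(vals, hdr$nrows, hdr$ncols, byrow = TRUE), header = hdr)
}

#' Write an ESRI ASCII grid
#'
#' @param mat Numeric matrix (NA written as the nodata value).
#' @param path Output path.
#' @param xllcorner,yllcorner,cellsize,nodata Header fields; the default cell
#'   size is 100 m (1-ha cells).
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(mat, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 100, nodata = -9999) {
  hdr <- c(paste("ncols", ncol(mat)), paste("nrows", nrow(mat)),
           paste("xllcorner", xllcorner), paste("yllcorner", yllcorner),
           paste("cellsize", cellsize), paste("NODATA_value", nodata))
  mat[is.na(mat)] <- nodata
  body <- apply(mat, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Summarize landscape composition
#'
#' Per-class area (ha) and percentage of the active landscape.
#'
#' @param landscape A `peat_landscape`.
#' @return A data.frame with columns `state_class`, `area_ha`, `percent`.
#' @export
summarize_composition <- function(landscape) {
  valid <- landscape$state[!is.na(landscape$state)]
  if (!length(valid)) stop("landscape has no active cells")
  tab <- table(factor(valid, levels = state_classes()))
  tab <- tab[tab > 0]
  data.frame(state_class = names(tab),
             area_ha = as.integer(tab) * landscape$cell_area,
             percent = 100 * as.integer(tab) / length(valid),
             row.names = NULL)
}

#' Roll back stand ages to a historic start year
#'
#' Forested cells outside the scar mask get `age = max(age - years, 0)`; cells
#' inside the scar mask are set to Atlantic white cedar at `scar_age` (the
#' average mature cedar age, default 100). All forested cells then have their
#' biomass pools re-derived from the spin-up growth curves at the new age,
#' since the mature-stand densities only describe stands at equilibrium.
#'
#' @param landscape A `peat_landscape`.
#' @param years Non-negative number of years to subtract.
#' @param scar_mask Optional integer cell indices (or logical vector) of the
#'   known disturbed area.
#' @param scar_age Age assigned inside the scar (default 100).
#' @param curves Named list of growth curves; computed from `params` if NULL.
#' @param params,soil Parameter objects.
#' @return The updated landscape.
#' @export
rollback_ages <- function(landscape, years, scar_mask = NULL, scar_age = 100L,
                          curves = NULL, params = load_species_params(),
                          soil = soil_params()) {
  if (years < 0) stop("years must be >= 0")
  if (is.logical(scar_mask)) scar_mask <- which(scar_mask)
  if (!is.null(scar_mask) &&
      (any(scar_mask < 1) || any(scar_mask > n_cells(landscape))))
    stop("scar_mask outside the grid")
  if (is.null(curves)) curves <- run_all_spinups(params, soil = soil)
  forested <- is_forested(landscape)
  landscape$age[forested] <- pmax(landscape$age[forested] - as.integer(years), 0L)
  if (length(scar_mask)) {
    keep <- scar_mask[!is.na(landscape$state[scar_mask])]
    landscape$state[keep] <- "AtlanticWhiteCedar"
    landscape$age[keep] <- as.integer(scar_age)
  }
  init_stocks(landscape, params, from = "curve", curves = curves)
}

#' Total ecosystem carbon of a landscape
#'
#' @param landscape A `peat_landscape`.
#' @param unit `"t"` (metric tons) or `"Tg"`.
#' @param by Optionally `"pool"` for a per-pool breakdown.
#' @return Total carbon, or a named vector per pool.
#' @export
total_carbon <- function(landscape, unit = c("t", "Tg"), by = NULL) {
  unit <- match.arg(unit)
  f <- if (unit == "Tg") 1e-6 else 1
  valid <- !is.na(landscape$state)
  if (identical(by, "pool")) colSums(landscape$stocks[valid, , drop = FALSE]) * f
  else sum(landscape$stocks[valid, ]) * f
}
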