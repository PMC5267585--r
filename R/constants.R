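#' State classes of the landscape model
#'
#' The six modelled land-cover/vegetation classes plus the inert upland pine
#' class. Only the four forest classes receive NPP and carbon flows; Marsh and
#' OpenWater carry passive peat pools; UplandPine is carried but frozen (no
#' transitions, no flows).
#'
#' @return Character vector of class labels.
#' @export
state_classes <- function() {
  c("AtlanticWhiteCedar", "CypressGum", "MapleGum", "PondPine",
    "Marsh", "OpenWater", "UplandPine")
}

#' Forested state classes
#'
#' Classes that carry an age, receive NPP, and participate in the annual
#' stock-flow step.
#'
#' @return Character vector.
#' @export
forest_classes <- function() {
  c("AtlanticWhiteCedar", "CypressGum", "MapleGum", "PondPine")
}

#' Per-cell carbon pools
#'
#' The eight ecosystem pools tracked per cell, in t C/ha. Atmosphere and
#' harvested wood products are external (unbounded) pools and appear only in
#' flux records.
#'
#' @return Character vector of pool names.
#' @export
pool_names <- function() {
  c("live_leaf", "live_wood", "live_root",
    "leaf_litter", "deadwood", "dead_root",
    "upper_peat", "deep_peat")
}

# AGB pools consumed by fire at the event's above-ground fraction
agb_pools <- function() c("live_leaf", "live_wood", "leaf_litter", "deadwood")

strata <- function() c("Wet", "Dry")

extdata <- function(file) {
  path <- system.file("extdata", file, package = "peatstsm")
  if (!nzchar(path)) stop("packaged parameter file not found: ", file)
  path
}
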