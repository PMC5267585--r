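test_that("adjacency multiplier matches a brute-force neighbour count", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(4:9, 1)
    state <- sample(c("MapleGum", "PondPine", "Marsh"), n * n, replace = TRUE)
    land <- new_landscape(state, "Wet", 10L, n, n)
    got <- compute_adjacency_multiplier(land, "MapleGum")
    oracle <- adjacency_oracle(matrix(state, n, n, byrow = TRUE), "MapleGum")
    expect_equal(got, as.numeric(t(oracle)), tolerance = 1e-12)
  }
})

test_that("adjacency saturates at 1, blocks at 0 and normalizes edges", {
  state <- rep("MapleGum", 9); state[5] <- "PondPine"
  land <- new_landscape(state, "Wet", 10L, 3, 3)
  adj <- compute_adjacency_multiplier(land, "MapleGum")
  expect_equal(adj[5], 1)            # interior cell, all 8 neighbours match
  expect_equal(adj[1], 2 / 3)        # corner: 2 of 3 in-grid neighbours
  land2 <- new_landscape(rep("PondPine", 9), "Wet", 10L, 3, 3)
  expect_true(all(compute_adjacency_multiplier(land2, "MapleGum") == 0))
})

test_that("succession respects the age gate and stratum-specific rates", {
  n <- 60
  mk <- function(age, stratum) {
    land <- uniform_landscape("AtlanticWhiteCedar", n = n, stratum = stratum,
                              age = age)
    apply_probabilistic_transitions(
      land, adjacency = list(MapleGum = rep(1, n * n)))$landscape
  }
  set.seed(5)
  dry <- mk(3L, "Dry")
  frac_dry <- mean(dry$state == "MapleGum")
  expect_lt(abs(frac_dry - 0.80), 3 * sqrt(0.8 * 0.2 / (n * n)))
  wet <- mk(3L, "Wet")
  frac_wet <- mean(wet$state == "MapleGum")
  expect_lt(abs(frac_wet - 0.04), 3 * sqrt(0.04 * 0.96 / (n * n)))
  old <- mk(6L, "Dry")                      # above the age gate
  expect_true(all(old$state == "AtlanticWhiteCedar"))
})

test_that("zero adjacency blocks succession entirely", {
  land <- uniform_landscape("AtlanticWhiteCedar", n = 10, stratum = "Dry",
                            age = 2L)
  set.seed(1)
  out <- apply_probabilistic_transitions(land)   # no maple-gum anywhere
  expect_true(all(out$landscape$state == "AtlanticWhiteCedar"))
})

test_that("severity draws follow the configured proportions", {
  set.seed(9)
  expect_true(all(assign_fire_severity(50, fire_severity_spec(1, 0, 0)) ==
                    "high"))
  sev <- assign_fire_severity(10000, fire_severity_spec())
  n_high <- sum(sev == "high")
  expect_lt(abs(n_high - 1630), 3 * sqrt(10000 * 0.163 * 0.837))
  big <- table(assign_fire_severity(1e5, fire_severity_spec()))
  chi <- suppressWarnings(stats::chisq.test(
    big[c("high", "med", "low")], p = c(0.163, 0.409, 0.428)))
  expect_gt(chi$p.value, 0.01)
})

test_that("repeat-catastrophic detection uses the dry-stratum 5-year window", {
  land <- uniform_landscape("AtlanticWhiteCedar", n = 2, stratum = "Dry",
                            age = 50L)
  land$stratum[2] <- "Wet"
  land$last_fire_year[1:2] <- 2008L
  land$last_fire_year[3] <- 2004L
  expect_true(detect_repeat_catastrophic(land, 1, 2011))    # 3-year gap, Dry
  expect_false(detect_repeat_catastrophic(land, 2, 2011))   # Wet stratum
  expect_false(detect_repeat_catastrophic(land, 3, 2011))   # 7-year gap
  expect_false(detect_repeat_catastrophic(land, 4, 2011))   # never burned
})

test_that("area targets are filled exactly and clamp on shortfall", {
  land <- mature_landscape("PondPine", n = 10, stratum = "Wet")
  ev <- disturbance_event(2000, "Fire", mask = 1:80, area_ha = 50,
                          label = "test fire", agb_fraction = 0.5)
  set.seed(2)
  out <- apply_transition_targets(land, list(ev), 2000)
  expect_equal(out$fire_summaries$area_ha, 50)
  expect_equal(sum(!is.na(out$landscape$last_fire_year)), 50)
  short <- disturbance_event(2000, "Fire", mask = 1:30, area_ha = 50,
                             label = "short fire", agb_fraction = 0.5)
  expect_warning(apply_transition_targets(land, list(short), 2000),
                 "shortfall")
})

test_that("hurricane targets transfer live mass and reset age", {
  land <- mature_landscape("AtlanticWhiteCedar", n = 5)
  ev <- disturbance_event(2003, "Hurricane", mask = 1:25, area_ha = 10,
                          label = "storm")
  set.seed(4)
  before <- total_carbon(land)
  out <- apply_transition_targets(land, list(ev), 2003)
  hit <- out$log$cell
  expect_equal(length(hit), 10)
  expect_true(all(out$landscape$age[hit] == 0))
  expect_true(all(out$landscape$stocks[hit, "live_wood"] == 0))
  expect_equal(total_carbon(out$landscape), before)  # transfer conserves C
})

test_that("deadwood salvage spread over years treats each cell once", {
  land <- mature_landscape("AtlanticWhiteCedar", n = 5)
  set.seed(6)
  treated <- integer(0)
  for (y in 2004:2007) {
    ev <- disturbance_event(y, "DeadwoodRemoval", mask = 1:20, area_ha = 5,
                            label = "salvage", replant = TRUE)
    out <- apply_transition_targets(land, list(ev), y)
    land <- out$landscape
    treated <- c(treated, out$log$cell)
  }
  expect_equal(length(unique(treated)), 20)  # deadwood-free cells not redrawn
  expect_true(all(land$stocks[1:20, "deadwood"] == 0))
  expect_true(all(land$age[treated] >= 0 & land$age[treated] <= 3))
})

test_that("identical seeds give identical targeted-transition outcomes", {
  land <- mature_landscape("MapleGum", n = 10, stratum = "Dry")
  evs <- list(
    disturbance_event(2000, "Fire", mask = 1:60, area_ha = 30, label = "f1",
                      agb_fraction = 0.8, peat_depth_cm = 10),
    disturbance_event(2000, "Fire", mask = 41:100, area_ha = 30, label = "f2"))
  run <- function() {
    set.seed(77)
    apply_transition_targets(land, evs, 2000)
  }
  a <- run(); b <- run()
  expect_identical(a$landscape, b$landscape)
  expect_identical(a$fire_summaries, b$fire_summaries)
})
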