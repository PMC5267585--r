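test_that("peat carbon density reproduces the standardized column stocks", {
  cpc <- peat_carbon_per_cm(SOIL)
  expect_equal(cpc, 0.16 * 0.95 * 0.59 * 100, tolerance = 1e-12)
  expect_lt(abs(cpc * 40 - 358.40) / 358.40, 0.002)
  expect_lt(abs(cpc * 60 - 537.60) / 537.60, 0.002)
})

test_that("annual flows equal multiplier times start-of-year from-stock", {
  land <- mature_landscape("AtlanticWhiteCedar", n = 1)
  out <- step_flows(land, PARAMS, SOIL)
  fl <- out$fluxes
  amt <- function(from, to) fl$amount[fl$from_pool == from & fl$to_pool == to]
  p <- PARAMS$AtlanticWhiteCedar
  expect_equal(amt("atmosphere", "live_leaf"), p$f_leaf * p$npp)   # 3.0418
  expect_equal(amt("live_leaf", "leaf_litter"),
               p$m_litterfall_leaf * 5.42)                         # 1.8428
  expect_equal(amt("live_wood", "deadwood"), p$m_mortality_wood * 103.87)
  expect_equal(amt("upper_peat", "deep_peat"), p$peat_accumulation)
  # steady-state acrotelm: upper peat neither gains nor loses
  expect_equal(out$landscape$stocks[1, "upper_peat"],
               land$stocks[1, "upper_peat"], tolerance = 1e-12)
})

test_that("a cold-start cell gains exactly its NPP in the first year", {
  for (sp in forest_classes()) {
    land <- uniform_landscape(sp, n = 1)
    land$stocks[] <- 0; land$upper_peat_cm[] <- 0; land$deep_peat_cm[] <- 0
    out <- step_flows(land, PARAMS, SOIL)
    expect_equal(total_carbon(out$landscape), PARAMS[[sp]]$npp,
                 tolerance = 1e-12)
    expect_true(mass_balance(land, out$landscape, out$fluxes))
  }
})

test_that("mass balance closes for every operation and detects perturbation", {
  land <- mature_landscape("CypressGum", n = 3)
  out <- step_flows(land, PARAMS, SOIL)
  expect_true(mass_balance(land, out$landscape, out$fluxes))
  fire <- apply_fire_consumption(out$landscape, 1:4, agb_fraction = 0.8,
                                 peat_depth_cm = 20, soil = SOIL)
  expect_true(mass_balance(out$landscape, fire$landscape, fire$fluxes))
  bad <- fire$fluxes
  bad$amount[1] <- bad$amount[1] + 1e-3
  expect_false(mass_balance(out$landscape, fire$landscape, bad))
})

test_that("fire consumption removes the specified fractions and peat depth", {
  land <- mature_landscape("MapleGum", n = 2)
  cpc <- peat_carbon_per_cm(SOIL)
  r <- apply_fire_consumption(land, 1:4, agb_fraction = 0.80,
                              peat_depth_cm = 20, soil = SOIL)
  expect_equal(r$bgb_peat / 4, 20 * cpc)       # ~179.4 t C/ha
  expect_equal(r$landscape$upper_peat_cm[1], 20)
  agb_expected <- 0.8 * sum(PARAMS$MapleGum$init_stocks[
    c("live_leaf", "live_wood", "leaf_litter", "deadwood")])
  expect_equal(r$agb / 4, agb_expected)
  # a zero spec is a no-op
  r0 <- apply_fire_consumption(land, 1:4, agb_fraction = 0, peat_depth_cm = 0)
  expect_equal(r0$agb + r0$bgb_peat + r0$bgb_root, 0)
  expect_identical(r0$landscape$stocks, land$stocks)
})

test_that("a deep repeat burn empties the acrotelm then draws the catotelm", {
  land <- mature_landscape("AtlanticWhiteCedar", n = 1)
  first <- apply_fire_consumption(land, 1, agb_fraction = 0.8,
                                  peat_depth_cm = 20, soil = SOIL)$landscape
  second <- apply_fire_consumption(first, 1, agb_fraction = 1.0,
                                   peat_depth_cm = 50, include_roots = TRUE,
                                   soil = SOIL)
  expect_equal(second$landscape$upper_peat_cm[1], 0)
  expect_equal(second$landscape$deep_peat_cm[1], 30)
  expect_equal(sum(second$landscape$stocks[1, c("live_leaf", "live_wood",
                                                "leaf_litter", "deadwood",
                                                "live_root", "dead_root")]), 0)
  # over-deep request clamps with a warning
  expect_warning(
    apply_fire_consumption(second$landscape, 1, peat_depth_cm = 60,
                           soil = SOIL),
    "clamped")
})

test_that("hurricane transfer moves live pools to dead pools conservatively", {
  land <- mature_landscape("AtlanticWhiteCedar", n = 1)
  r <- apply_hurricane_transfer(land, 1)
  s <- r$landscape$stocks[1, ]
  expect_equal(s[["deadwood"]], 25.07 + 103.87)
  expect_equal(s[["leaf_litter"]], 5.03 + 5.42)
  expect_equal(s[["dead_root"]], 2.54 + 5.46)
  expect_equal(sum(s), sum(land$stocks[1, ]), tolerance = 1e-12)
  expect_true(mass_balance(land, r$landscape, r$fluxes))
  # zero-biomass cell is a no-op
  land$stocks[1, ] <- 0
  expect_equal(sum(apply_hurricane_transfer(land, 1)$landscape$stocks), 0)
})

test_that("deadwood harvest moves the whole stock to wood products", {
  land <- mature_landscape("AtlanticWhiteCedar", n = 1)
  land$stocks[1, "deadwood"] <- 110
  r <- apply_deadwood_harvest(land, 1)
  expect_equal(r$removed, 110)
  expect_equal(unname(r$landscape$stocks[1, "deadwood"]), 0)
  expect_true(mass_balance(land, r$landscape, r$fluxes))
  expect_equal(apply_deadwood_harvest(r$landscape, 1)$removed, 0)
})

test_that("live wood converges to the analytic fixed point f_wood*NPP/m", {
  land <- uniform_landscape("AtlanticWhiteCedar", n = 1)
  land$stocks[] <- 0
  for (i in 1:2000) land <- step_flows(land, PARAMS, SOIL)$landscape
  p <- PARAMS$AtlanticWhiteCedar
  fp <- p$f_wood * p$npp / p$m_mortality_wood   # ~104.85, near the 103.87 stock
  expect_equal(land$stocks[1, "live_wood"], fp, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("no pool goes negative under random stock configurations", {
  set.seed(11)
  for (i in 1:25) {
    sp <- sample(forest_classes(), 1)
    land <- uniform_landscape(sp, n = 2)
    land$stocks[] <- matrix(stats::runif(4 * 8, 0, 5), 4, 8)
    land$upper_peat_cm[] <- stats::runif(4, 0, 40)
    land$deep_peat_cm[] <- stats::runif(4, 0, 60)
    out <- step_flows(land, PARAMS, SOIL)
    expect_true(all(out$landscape$stocks >= 0))
    expect_true(mass_balance(land, out$landscape, out$fluxes, tol = 1e-9))
  }
})

test_that("multiplier peat mode applies the table rates to the acrotelm", {
  land <- mature_landscape("AtlanticWhiteCedar", n = 1)
  out <- step_flows(land, PARAMS, SOIL, peat_mode = "multiplier")
  fl <- out$fluxes
  up_em <- fl$amount[fl$from_pool == "upper_peat" & fl$to_pool == "atmosphere"]
  expect_equal(up_em, 0.022 * 358.40 * (peat_carbon_per_cm(SOIL) * 40 / 358.40),
               tolerance = 1e-6)
})

test_that("negative stocks on entry are rejected", {
  land <- mature_landscape("MapleGum", n = 1)
  land$stocks[1, "live_leaf"] <- -1
  expect_error(step_flows(land, PARAMS, SOIL), "negative stock")
})
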