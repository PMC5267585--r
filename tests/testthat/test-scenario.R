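small_run <- function(seed = 1L, disturbances = TRUE) {
  cfg <- landscape_config(total_area_ha = 3000, seed = seed)
  land <- generate_landscape(cfg, PARAMS, SOIL, CURVES)
  set.seed(seed)
  s1 <- generate_fire_perimeter(land, 150)
  lw <- generate_fire_perimeter(land, 160, overlap_with = s1,
                                overlap_fraction = 0.85)
  hur <- generate_fire_perimeter(land, 60, within = intersect(s1, lw))
  rem <- generate_fire_perimeter(land, 32, within = hur)
  scar <- union(s1, lw)
  active <- which(!is.na(land$state))
  land$stratum[scar] <- "Dry"
  land <- rollback_ages(land, 0, scar_mask = scar, scar_age = 100L,
                        curves = CURVES, params = PARAMS, soil = SOIL)
  masks <- list(south_one = s1, lateral_west = lw, hurricane = hur,
                removal = rem, other = list())
  sched <- default_schedule(masks, disturbances = disturbances)
  if (disturbances) {
    # scale the hurricane target to the small landscape
    for (i in seq_along(sched))
      if (sched[[i]]$kind == "Hurricane") sched[[i]]$area_ha <- 60
  }
  list(landscape = land, schedule = sched, masks = masks)
}

test_that("NEP and NECB follow their defining arithmetic", {
  ledger <- data.frame(year = 1:2, growth = c(7.0, 7.73), rh = c(6.8, 6.96),
                       management = c(0, 0.01), fire_total = c(0.9, 0.96),
                       fire_agb = 0, fire_bgb = 0)
  expect_equal(compute_nep(ledger), 14.73 - 13.76)            # 0.97
  expect_equal(compute_necb(ledger), 14.73 - 13.76 - 0.01 - 1.86)  # -0.90
  # the fire term decomposes by event: 0.66 + 1.04 + 0.16 = 1.86
  expect_equal(0.66 + 1.04 + 0.16, sum(ledger$fire_total))
  # zero management and fire make the two measures coincide
  ledger$management[] <- 0; ledger$fire_total[] <- 0
  expect_equal(compute_necb(ledger), compute_nep(ledger))
})

test_that("the per-ha NEP rate follows from the landscape area and span", {
  rate <- 0.97e6 / (54000 * 30)
  expect_equal(rate, 0.599, tolerance = 0.002)
})

test_that("an all-marsh landscape has zero growth and zero NEP", {
  land <- new_landscape(rep("Marsh", 100), "Wet", 0L, 10, 10)
  led <- run_historic(land, event_schedule(), PARAMS, SOIL, seed = 1,
                      years = 5)
  expect_true(all(led$growth == 0))
  expect_true(all(led$rh == 0))
  expect_equal(compute_nep(led), 0)
  expect_equal(led$total_c[5], total_carbon(land, "Tg"))  # passive peat kept
})

test_that("the annual ledger closes and disturbance only lowers the balance", {
  run <- small_run(seed = 3L)
  led <- run_historic(run$landscape, run$schedule, PARAMS, SOIL, seed = 42)
  tot <- c(attr(led, "initial_tg"), led$total_c)
  expect_lt(max(abs(diff(tot) - led$necb)), 1e-6)
  expect_true(all(led$necb <= led$nep + 1e-12))
  expect_true(all(attr(led, "final_landscape")$stocks >= 0))
})

test_that("disabling all disturbance makes NECB equal NEP", {
  run <- small_run(seed = 3L, disturbances = FALSE)
  led <- run_historic(run$landscape, run$schedule, PARAMS, SOIL, seed = 42)
  expect_identical(compute_necb(led), compute_nep(led))
  expect_true(all(led$fire_total == 0))
})

test_that("identical seeds give identical ledgers", {
  run <- small_run(seed = 5L)
  a <- run_historic(run$landscape, run$schedule, PARAMS, SOIL, seed = 9)
  b <- run_historic(run$landscape, run$schedule, PARAMS, SOIL, seed = 9)
  expect_identical(a, b)
  c2 <- run_historic(run$landscape, run$schedule, PARAMS, SOIL, seed = 10)
  expect_false(identical(a$necb, c2$necb))
})

test_that("schedule years outside the span are rejected", {
  land <- new_landscape(rep("MapleGum", 25), "Wet", 10L, 5, 5)
  ev <- disturbance_event(1950, "Fire", 1:5, label = "too early",
                          agb_fraction = 0.5)
  expect_error(run_historic(land, event_schedule(ev), PARAMS, SOIL, seed = 1),
               "outside the simulation span")
})

test_that("fire summaries report elevation equivalents from peat carbon", {
  run <- small_run(seed = 7L)
  led <- run_historic(run$landscape, run$schedule, PARAMS, SOIL, seed = 11)
  fs <- summarize_fire_events(led)
  s1 <- fs[fs$event == "South One", ]
  lw <- fs[fs$event == "Lateral West", ]
  expect_equal(s1$elevation_m, 0.20, tolerance = 1e-9)
  expect_equal(lw$elevation_m, 0.50, tolerance = 1e-9)
  expect_equal(fs$total_loss[fs$event == "Cumulative"],
               sum(fs$total_loss[fs$event != "Cumulative"]))
  # an event with no peat consumption reports zero elevation loss
  hurless <- fs[!fs$event %in% c("South One", "Lateral West", "Cumulative"), ]
  if (nrow(hurless)) expect_true(all(hurless$elevation_m == 0))
})

test_that("re-accumulation horizons round the soil-carbon quotient", {
  expect_equal(re_amass_time(70, 0.36), 1740)
  expect_equal(re_amass_time(70, 0.71), 880)
  expect_equal(re_amass_time(0, 0.36), 0)
  expect_error(re_amass_time(70, 0), "> 0")
  expect_error(re_amass_time(-1, 0.5), ">= 0")
})
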