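# Stressor scenarios: run-name codes, the earthquake timeline, and
# counterfactual equivalence.

test_that("run names encode scenario and seed exactly as specified", {
  expect_identical(
    encode_run_name(scenario_settings(TRUE, 2.1, "status_quo"), 1),
    "EQ-21-12-01.csv")
  expect_identical(
    encode_run_name(scenario_settings(FALSE, 1.6, "heightened"), 7),
    "NE-16-09-07.csv")
  ## round trip over all eight combinations
  for (sc in all_scenarios()) {
    dec <- decode_run_name(encode_run_name(sc, 33))
    expect_equal(dec$settings, sc)
    expect_identical(dec$seed, 33L)
  }
  expect_error(decode_run_name("whatever.csv"), "not a run file name")
  expect_length(all_scenarios(), 8L)
})

test_that("the inactive earthquake operation is a strict no-op (counterfactual equality)", {
  st <- fresh_state(seed = 71)
  st$day <- villagesim:::quake_shock_day()
  rng_before <- with_stream(st$streams, "scenario", runif(1))
  st2 <- fresh_state(seed = 71)
  st2$day <- villagesim:::quake_shock_day()
  villagesim:::apply_earthquake_day(st2)       # scenario has earthquake=FALSE
  expect_identical(st2$labour_modifier, 1)
  expect_identical(st2$cashcrop_factor, 1)
  expect_true(all(st2$A$alive))
  ## no random numbers were consumed: the next draw matches
  rng_after <- with_stream(st2$streams, "scenario", runif(1))
  expect_identical(rng_before, rng_after)
})

test_that("the shock day kills ~5% of livestock and reroutes labour and yields", {
  cfgq <- function(seed) quick_config(
    seed = seed, days = 0L,
    scenario = scenario_settings(earthquake = TRUE))
  set.seed(72)
  n_animals <- 0L; n_dead <- 0L
  for (seed in 1:25) {
    st <- villagesim:::initialize_village(cfgq(seed))
    st$day <- villagesim:::quake_shock_day()
    n_animals <- n_animals + sum(st$A$alive)
    villagesim:::apply_earthquake_day(st)
    n_dead <- n_dead + sum(!st$A$alive)
    expect_identical(st$labour_modifier, 0)      # three-month stoppage
    expect_identical(st$cashcrop_factor, 0.85)   # permanent cash-crop hit
    ## boom window afterwards
    st$day <- villagesim:::quake_shock_day() + 100L
    villagesim:::apply_earthquake_day(st)
    expect_identical(st$labour_modifier, 1.5)
    st$day <- villagesim:::quake_shock_day() + 91L + 731L
    villagesim:::apply_earthquake_day(st)
    expect_identical(st$labour_modifier, 1)
  }
  p_hat <- n_dead / n_animals
  expect_lt(abs(p_hat - 0.05), 3 * sqrt(0.05 * 0.95 / n_animals) + 0.01)
})

test_that("reconstruction loans follow the household-size schedule", {
  expect_equal(villagesim:::reconstruction_loan_size(c(1, 2, 3, 4, 5, 6, 7, 9)),
               c(300000, 300000, 425000, 425000, 550000, 550000,
                 675000, 675000))
  st <- villagesim:::initialize_village(quick_config(
    seed = 73, days = 0L, scenario = scenario_settings(earthquake = TRUE)))
  st$day <- villagesim:::quake_loan_day()
  sizes <- villagesim:::hh_sizes(st)
  villagesim:::apply_earthquake_day(st)
  for (hid in villagesim:::live_households(st)) {
    expect_equal(st$H$recon_loan[hid],
                 villagesim:::reconstruction_loan_size(sizes[hid]))
    expect_equal(st$H$recon_principal[hid], st$H$recon_loan[hid])
  }
  led <- villagesim:::acc_collect(st$ledger)
  expect_equal(sum(led[led$category == "loan principal"]$amount),
               sum(st$H$recon_loan))
})

test_that("labourers never work during the post-quake stoppage", {
  st <- fresh_state(seed = 74)
  st$labour_modifier <- 0
  for (d in 1:50) {
    st$day <- d
    expect_length(villagesim:::draw_labour(st), 0L)
  }
})

test_that("the permanent 0.85 factor hits cash crops only", {
  cfg <- quick_config(seed = 75, days = 0L,
                      scenario = scenario_settings(earthquake = TRUE))
  st <- villagesim:::initialize_village(cfg)
  st$yields[,] <- 1
  st$cashcrop_factor <- 0.85
  hid <- villagesim:::live_households(st)[1]
  st$planted[hid, ] <- 0L
  st$day <- 600L                       # past the shock window
  villagesim:::plant_crop(st, "potato", hid, 1L, charge = FALSE)
  villagesim:::plant_crop(st, "maize", hid, 1L, charge = FALSE)
  n0 <- st$ledger$n
  villagesim:::harvest_crop(st, "potato", hid)
  villagesim:::harvest_crop(st, "maize", hid)
  led <- villagesim:::acc_collect(st$ledger)
  sale <- led[led$category == "crop sale" & led$day == 600]
  expect_equal(sale$amount[1], 22 * 793.1 * 0.85 * 0.5)  # potato reduced
  expect_equal(sale$amount[2], 25 * 84.8 * 0.5)          # maize untouched
})

test_that("crops in the ground during the shock window harvest 30% lower", {
  cfg <- quick_config(seed = 76, days = 0L,
                      scenario = scenario_settings(earthquake = TRUE))
  st <- villagesim:::initialize_village(cfg)
  st$yields[,] <- 1
  st$cashcrop_factor <- 1             # isolate the window effect
  hid <- villagesim:::live_households(st)[1]
  st$planted[hid, ] <- 0L
  ## maize: planted day 57, harvested day 256 - spans 25 Apr-12 Jun
  st$day <- 56L
  villagesim:::plant_crop(st, "maize", hid, 1L, charge = FALSE)
  st$day <- 255L
  villagesim:::harvest_crop(st, "maize", hid)
  led <- villagesim:::acc_collect(st$ledger)
  sale <- led[led$category == "crop sale" & led$day == 255]
  expect_equal(sale$amount, 25 * 84.8 * 0.5 * 0.7)
  ## a crop planted after the window is unaffected
  st$day <- 400L
  villagesim:::plant_crop(st, "maize", hid, 1L, charge = FALSE)
  st$day <- 500L
  villagesim:::harvest_crop(st, "maize", hid)
  led <- villagesim:::acc_collect(st$ledger)
  sale2 <- led[led$category == "crop sale" & led$day == 500]
  expect_equal(sale2$amount, 25 * 84.8 * 0.5)
})
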