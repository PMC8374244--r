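# Animal dynamics: feed costs, laying cycles, litters, milk, exits,
# ownership targets, rebalancing, valuation.

with_one_animal <- function(species, sex, age, hid_fields = 12L) {
  st <- tiny_state()
  st$H$fields[1] <- hid_fields
  villagesim:::add_animals(st, species, sex, as.integer(age), 1L)
  st
}

test_that("daily feed costs follow grain quantities times market prices", {
  p <- default_parameters()
  ## chicken: 32g maize, 32g millet, 10g wheat at 25/19/22 NPR per kg
  expect_equal(unname(feed_cost_per_day("chicken", p)),
               0.032 * 25 + 0.032 * 19 + 0.010 * 22)   # = 1.628
  expect_equal(unname(feed_cost_per_day("goat", p)), 0.025 * (25 + 19))
  expect_equal(unname(feed_cost_per_day("cattle", p)), 0.240 * (25 + 19))
  expect_equal(unname(feed_cost_per_day("buffalo", p)), 0.280 * (25 + 19))
  ## and the ledger charges exactly that
  st <- with_one_animal("chicken", "M", 50)
  villagesim:::step_animals(st)
  led <- villagesim:::acc_collect(st$ledger)
  expect_equal(led[led$category == "animal feed"]$amount, -1.628)
})

test_that("hens lay an egg a day for thirty days then three months of none", {
  st <- with_one_animal("chicken", "F", 182)
  eggs <- integer(0)
  for (d in 1:(121 * 2)) {
    st$day <- d
    n0 <- st$ledger$n
    villagesim:::step_animals(st)
    led <- villagesim:::acc_collect(st$ledger)
    eggs <- c(eggs, sum(led$category == "eggs" & led$day == d))
  }
  ## first 30 days from age 183: laying; then 91 egg-free; then again
  expect_identical(eggs[1:30], rep(1L, 30))
  expect_identical(eggs[31:121], rep(0L, 91))
  expect_identical(eggs[122:151], rep(1L, 30))
  led <- villagesim:::acc_collect(st$ledger)
  expect_true(all(led[led$category == "eggs"]$amount == 7))
})

test_that("goat litters recover the printed probabilities and kids are sold at once", {
  st <- tiny_state()
  set.seed(20)
  pmf <- st$species$goat$litter_pmf
  draws <- sample(as.integer(names(pmf)), 1e4, replace = TRUE, prob = pmf)
  p1 <- mean(draws == 1)
  expect_lt(abs(p1 - 0.622 / 0.999), 3 * sqrt(0.622 * 0.378 / 1e4))
  chi <- suppressWarnings(stats::chisq.test(table(draws), p = pmf))
  expect_gt(chi$p.value, 0.001)
  ## a birth credits litter * kid price
  st2 <- with_one_animal("goat", "F", 328)
  set.seed(1)
  villagesim:::step_animals(st2)
  led <- villagesim:::acc_collect(st2$ledger)
  tr <- led[led$category == "animal trade"]
  expect_true(tr$amount %in% (5000 * 1:3))
})

test_that("milk flows only to one- and two-member households outside blackout windows", {
  sp <- species_params()
  ## cow: lactating after first calf, dry 2 months before the next birth
  expect_false(villagesim:::milk_today(sp$cattle, 900))    # pre first birth
  expect_true(villagesim:::milk_today(sp$cattle, 1000))
  expect_false(villagesim:::milk_today(sp$cattle, 1430))   # 31 d before 1461
  expect_false(villagesim:::milk_today(sp$cattle, 4690))   # past cutoff
  ## buffalo blackout is three months
  expect_false(villagesim:::milk_today(sp$buffalo, 2140))  # 80 d before 2220
  expect_true(villagesim:::milk_today(sp$buffalo, 2100))
  ## household of two gets the two-member rate
  st <- with_one_animal("cattle", "F", 1000)
  villagesim:::step_animals(st)
  led <- villagesim:::acc_collect(st$ledger)
  expect_equal(led[led$category == "milk"]$amount, 90)
})

test_that("exits pay the slaughter price and buy the stated replacement", {
  ## male chicken at 183 days: sold, replaced by a 14-day chick for 400
  st <- with_one_animal("chicken", "M", 182)
  set.seed(2)
  villagesim:::step_animals(st)
  led <- villagesim:::acc_collect(st$ledger)
  tr <- led[led$category == "animal trade"]
  expect_setequal(tr$amount, c(1200, -400))
  expect_identical(st$A$age[1], 14L)
  ## cattle die at 18 without carcass income, replaced at 548 days for 3000
  st2 <- with_one_animal("cattle", "M", 6569)
  villagesim:::step_animals(st2)
  led2 <- villagesim:::acc_collect(st2$ledger)
  tr2 <- led2[led2$category == "animal trade"]
  expect_equal(tr2$amount, -3000)
  expect_identical(st2$A$age[1], 548L)
  ## female buffalo slaughtered at 10 years for 28000, replaced for 10000
  st3 <- with_one_animal("buffalo", "F", 3649)
  villagesim:::step_animals(st3)
  led3 <- villagesim:::acc_collect(st3$ledger)
  tr3 <- led3[led3$category == "animal trade"]
  expect_setequal(tr3$amount, c(28000, -10000))
})

test_that("no animal exceeds its exit age after the daily step", {
  st <- fresh_state(seed = 31)
  sp <- st$species
  for (d in 1:30) {
    st$day <- d
    villagesim:::step_animals(st)
    for (i in which(st$A$alive)) {
      s <- sp[[st$A$species[i]]]
      lim <- if (st$A$sex[i] == "M") s$exit_age_male else s$exit_age_female
      expect_lt(st$A$age[i], lim)
    }
  }
})

test_that("ownership targets follow the step tables and the landholding caps", {
  t1 <- target_animal_counts(2, 5)      # five ropani: no bovine possible
  expect_identical(t1$bovine, 0L)
  expect_identical(target_animal_counts(4, 12)$bovine, 2L)   # 11-16 cap 2
  expect_identical(target_animal_counts(8, 8)$bovine, 1L)    # 5.5-10.5 cap 1
  expect_identical(target_animal_counts(6, 20)$bovine, 3L)
  t0 <- target_animal_counts(0, 30)
  expect_identical(t0$chicken + t0$goat + t0$bovine, 0L)     # through origin
})

test_that("rebalancing buys into deficits and sells surpluses youngest-first", {
  st <- tiny_state()                     # 2 adults, 6 ropani
  villagesim:::rebalance_animals(st, 1L)
  tgt <- target_animal_counts(2, 6)
  cnt <- villagesim:::hh_animal_counts(st, 1L)
  expect_identical(unname(cnt["chicken"]), tgt$chicken)
  expect_identical(unname(cnt["goat"]), tgt$goat)
  expect_identical(unname(cnt["bovine"]), tgt$bovine)
  ## no trades when the targets are already met
  n_before <- st$ledger$n
  villagesim:::rebalance_animals(st, 1L)
  expect_identical(st$ledger$n, n_before)
  ## add two extra chickens; the two youngest must be the ones sold
  villagesim:::add_animals(st, c("chicken", "chicken"), c("M", "F"),
                           c(20L, 900L), 1L)
  young <- which(st$A$alive & st$A$species == "chicken" &
                   st$A$age %in% c(14L, 20L))
  villagesim:::rebalance_animals(st, 1L)
  expect_false(any(st$A$alive[young[order(st$A$age[young])][1:2]]))
})

test_that("bovine purchases prefer buffalo two-fifths of the time and females when the breed is new", {
  set.seed(30)
  n_buff <- 0L
  for (i in 1:500) {
    st <- tiny_state()
    villagesim:::buy_animals(st, 1L, "bovine", 1L)
    sp <- st$A$species[1]
    n_buff <- n_buff + (sp == "buffalo")
    expect_identical(st$A$sex[1], "F")   # household had no bovine
    expect_identical(st$A$age[1], 548L)
  }
  expect_lt(abs(n_buff / 500 - 0.4), 3 * sqrt(0.4 * 0.6 / 500))
})

test_that("animal worth interpolates linearly from purchase to slaughter", {
  p <- default_parameters()
  expect_equal(animal_value("goat", "F", 112), 5000)       # purchase endpoint
  expect_equal(animal_value("goat", "F", 730), 7600)       # slaughter endpoint
  expect_equal(animal_value("goat", "M", (112 + 730) / 2), 6300)  # midpoint
  expect_equal(animal_value("chicken", "F", 5000), 1200)   # clamped
  expect_equal(animal_value("cattle", "M", 3000), 3000)    # flat resale
})
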