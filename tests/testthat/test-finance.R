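# Finance-controller assignment, food costs, interest, forecasting, debt
# decisions, and household fission.

test_that("finance controllers follow the household/independent-son rules", {
  st <- fresh_state(seed = 51)
  hid <- villagesim:::add_household(st, fields = 12L)
  dad <- villagesim:::add_villagers(st, 1L, sex = "M", hh = hid,
                                    age = 50L * 365L,
                                    education = "left_none", career = "farm")
  son_done <- villagesim:::add_villagers(st, 1L, sex = "M", hh = hid,
                                         age = 24L * 365L, father = dad,
                                         education = "left_slc",
                                         career = "farm")
  son_school <- villagesim:::add_villagers(st, 1L, sex = "M", hh = hid,
                                           age = 12L * 365L, father = dad,
                                           education = "school",
                                           career = "student")
  wife <- villagesim:::add_villagers(st, 1L, sex = "F", hh = hid,
                                     age = 22L * 365L, partner = son_done,
                                     education = "left_none", career = "farm")
  st$V$partner[son_done] <- wife
  villagesim:::update_referents(st)
  expect_identical(st$H$referent[hid], dad)   # youngest sibling-free adult male
  villagesim:::update_controllers(st)
  expect_identical(st$V$controller[dad], 0L)           # the household itself
  expect_identical(st$V$controller[son_done], son_done) # education complete
  expect_identical(st$V$controller[wife], son_done)     # his wife follows him
  expect_identical(st$V$controller[son_school], 0L)     # still in education
})

test_that("food costs scale the adult-female basket by age-sex multipliers", {
  st <- tiny_state()
  ## Saturday (no work-away halving): day 2 of the run
  st$day <- 2L
  ids <- 1:2
  costs <- food_cost(st, ids)
  base <- 0.65 + 0.494 + 0.352 + 6.08 + 2.2 + 52   # 61.776
  expect_equal(costs[2], base)            # adult woman
  expect_equal(costs[1], base * 1.29)     # adult man
  ## abroad: no food expenses
  st$V$abroad[1] <- TRUE
  expect_equal(food_cost(st, ids)[1], 0)
  ## multiplier table spot checks
  expect_equal(food_multiplier(c(0.5, 2, 14, 11), c("F", "M", "F", "M")),
               c(0.37, 0.56, 0.93, 0.98))
})

test_that("unpaid debt grows exactly 20% over a 365-day year", {
  st <- tiny_state()
  st$H$debt[1] <- 100
  ## remove members so no income/expense mechanics interfere
  for (d in seq_len(365)) {
    st$day <- d
    debt0 <- st$H$debt[1]
    villagesim:::assess_finances(st, -1L)
    ## no repayment possible: forecast of a 2-member farm household is red
  }
  expect_gt(st$H$debt[1] / 100, 1.19)
  r_daily <- (1.2)^(1 / 365) - 1
  expect_equal((1 + r_daily)^365, 1.2, tolerance = 1e-12)
})

test_that("negative balances trigger member bailouts before loans", {
  st <- tiny_state()
  son <- villagesim:::add_villagers(st, 1L, sex = "M", hh = 1L, father = 1L,
                                    age = 25L * 365L, education = "left_slc",
                                    career = "farm", cash = 50000)
  st$V$controller[son] <- son
  st$H$cash[1] <- -20000
  villagesim:::assess_finances(st, -1L)
  expect_equal(st$H$cash[1], 0)
  expect_equal(st$V$cash[son], 30000)    # richest member covered it
  expect_equal(st$H$debt[1], 0)
  ## without a willing member the household borrows
  st2 <- tiny_state()
  st2$H$cash[1] <- -20000
  villagesim:::assess_finances(st2, -1L)
  expect_gte(st2$H$cash[1], 0)
  expect_gte(st2$H$debt[1], 20000)
  led <- villagesim:::acc_collect(st2$ledger)
  expect_equal(led[led$category == "loan principal"]$amount, 20000)
})

test_that("reconstruction instalments are one sixtieth and paid only when debt-free", {
  expect_equal(550000 / 60, 9166.667, tolerance = 1e-4)
  st <- tiny_state()
  st$H$recon_principal[1] <- 550000
  st$H$recon_loan[1] <- 550000
  st$H$cash[1] <- 5e6                    # comfortably affordable
  st$day <- 31L                          # 1 February: a month's first day
  villagesim:::assess_finances(st, -1L)
  expect_equal(st$H$recon_loan[1], 550000 - 550000 / 60)
  ## with outstanding ordinary debt the instalment is deferred
  st2 <- tiny_state()
  st2$H$recon_principal[1] <- 550000
  st2$H$recon_loan[1] <- 550000
  st2$H$debt[1] <- 1e7                   # cannot be cleared by the forecast
  st2$H$cash[1] <- 10000
  st2$day <- 31L
  villagesim:::assess_finances(st2, -1L)
  expect_equal(st2$H$recon_loan[1], 550000)
})

test_that("cash forecasts are structurally sound and meat choice is monotone in cash", {
  st <- tiny_state()
  base_path <- forecast_cashflow(st, -1L)
  expect_length(base_path, 365L)
  ## adding a dependent lowers the path pointwise
  villagesim:::add_villagers(st, 1L, sex = "M", hh = 1L, age = 8L * 365L,
                             education = "school", career = "student")
  with_dep <- forecast_cashflow(st, -1L)
  expect_true(all(with_dep <= base_path))
  ## more meat portions never raise the path
  expect_true(all(forecast_cashflow(st, -1L, meat_k = 3) <=
                    forecast_cashflow(st, -1L, meat_k = 1)))
  ## richer controller chooses at least as many portions
  chosen <- sapply(c(0, 5e5, 5e7), function(cash) {
    s <- tiny_state()
    s$H$cash[1] <- cash
    s$day <- 31L
    villagesim:::assess_finances(s, -1L)
    s$H$meat[1]
  })
  expect_true(all(diff(chosen) >= 0))
  expect_equal(chosen[3], 3)             # capped at three portions
})

test_that("fission entitlement arithmetic and thresholds are exact", {
  expect_identical(fission_entitlement(24L, 2L), 8L)    # 4 ropani: too small
  expect_lt(fission_entitlement(24L, 2L), 12L)
  expect_identical(fission_entitlement(48L, 1L), 24L)   # 12 ropani: viable
  expect_gte(fission_entitlement(48L, 1L), 12L)
  expect_equal(default_parameters()$house_cost +
                 default_parameters()$fission_buffer, 660000)
})

test_that("a rich married elder son splits off with his land entitlement", {
  st <- tiny_state()
  st$H$fields[1] <- 48L
  dad <- 1L
  sons <- c(villagesim:::add_villagers(st, 1L, sex = "M", hh = 1L,
                                       father = dad, age = 26L * 365L,
                                       education = "left_slc", career = "farm"),
            villagesim:::add_villagers(st, 1L, sex = "M", hh = 1L,
                                       father = dad, age = 20L * 365L,
                                       education = "left_slc", career = "farm"))
  wife <- villagesim:::add_villagers(st, 1L, sex = "F", hh = 1L,
                                     partner = sons[1], age = 24L * 365L,
                                     education = "left_none", career = "farm")
  st$V$partner[sons[1]] <- wife
  villagesim:::update_referents(st)
  villagesim:::update_controllers(st)
  st$V$cash[sons[1]] <- 700000
  villagesim:::household_fission_check(st, 1L)
  new_h <- 2L
  expect_true(st$H$alive[new_h])
  expect_identical(st$V$hh[sons[1]], new_h)
  expect_identical(st$V$hh[wife], new_h)
  E <- fission_entitlement(48L, 2L)      # 16 fields
  ## fields conserved between parent and child household
  expect_identical(st$H$fields[1] + st$H$fields[new_h] +
                     st$H$claim_n[new_h] - st$H$claim_n[new_h], 48L)
  expect_identical(st$H$fields[new_h] + st$H$claim_n[new_h], E)
  ## the house cost left the son's account
  led <- villagesim:::acc_collect(st$ledger)
  expect_equal(led[led$category == "house construction"]$amount, -625000)
  ## remaining personal cash became the new household's stock, net of the
  ## livestock the new household immediately buys
  animal_net <- sum(led[led$account == -new_h &
                          led$category == "animal trade"]$amount)
  expect_equal(st$H$cash[new_h], 700000 - 625000 + animal_net)
  expect_equal(st$V$cash[sons[1]], 0)
})

test_that("an entitlement below six ropani sends the son's family away instead", {
  st <- tiny_state()
  st$H$fields[1] <- 20L
  dad <- 1L
  sons <- c(villagesim:::add_villagers(st, 1L, sex = "M", hh = 1L,
                                       father = dad, age = 26L * 365L,
                                       education = "left_slc", career = "farm"),
            villagesim:::add_villagers(st, 1L, sex = "M", hh = 1L,
                                       father = dad, age = 20L * 365L,
                                       education = "left_slc", career = "farm"))
  wife <- villagesim:::add_villagers(st, 1L, sex = "F", hh = 1L,
                                     partner = sons[1], age = 24L * 365L,
                                     education = "left_none", career = "farm")
  st$V$partner[sons[1]] <- wife
  villagesim:::update_referents(st)
  villagesim:::update_controllers(st)
  villagesim:::household_fission_check(st, 1L)
  expect_false(st$V$present[sons[1]])    # E = 20/3 -> 7 fields < 12
  expect_false(st$V$present[wife])
  expect_true(st$V$present[sons[2]])     # the youngest stays and inherits
})

test_that("initial capitalisation makes every controller's first-year forecast non-negative", {
  for (seed in c(61, 62, 63)) {
    st <- fresh_state(seed = seed)
    accts <- c(-villagesim:::live_households(st),
               which(st$V$alive & st$V$controller == st$V$id))
    for (a in accts) {
      path <- forecast_cashflow(st, a, meat_k = 2)
      ## historical debts aside, the starting cash covers the planned year
      expect_gte(min(path), -1e-6)
    }
    ## exactly two households carry the remittance income
    expect_identical(sum(st$H$remittance), 2L)
  }
})
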