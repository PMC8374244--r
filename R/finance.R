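# Household and villager finances.
#
# Income (salaries, wages, pensions, remittances) and expenditure (food,
# daily living, education, festivals, meat) flow through finance-controller
# accounts.  Negative balances are covered first by cash-rich self-managing
# household members, then by informal loans at 20%/year (compounded daily as
# (1.2)^(1/365)-1 so unpaid debt grows exactly 20% in a year).  On the first
# day of each month controllers make a conservative twelve-month cash
# forecast which drives debt repayment, reconstruction-loan instalments, and
# the weekly meat-portion decision.  Household fission follows the land
# entitlement rule E = F/(S+1).

base_food_cost <- function(params) {
  sum(food_basket()$npr_per_day[1:5]) + params$other_food_expenses
}

is_saturday <- function(day_index) (day_index %% 7L) == 2L  # Nepali day off

## ---- daily income (P1) -------------------------------------------------------

# Short-term labour draws: who works today.  Returns the ids that worked.
draw_labour <- function(st) {
  yd <- day_of_year(st$day)
  if (yd %in% st$festivals || st$labour_modifier == 0) return(integer(0))
  idx <- resident(st)
  idx <- idx[st$V$career[idx] == "labourer"]
  if (!length(idx)) return(integer(0))
  pr <- min(1, st$params$labour_probability * st$labour_modifier)
  idx[stats::runif(length(idx)) < pr]
}

#' Simulate a labourer's worked days
#'
#' The daily Bernoulli availability draw for one short-term labourer over a
#' run of non-festival days (work opportunities never arise on festival
#' days and are never declined).
#'
#' @param n_days Number of non-festival days to simulate.
#' @param params Parameter list.
#' @param modifier Availability multiplier (0 during the post-earthquake
#'   stoppage, 1.5 during the reconstruction boom).
#' @return Logical vector: worked or not, per day.
#' @export
simulate_labour_days <- function(n_days, params = default_parameters(),
                                 modifier = 1) {
  stats::runif(n_days) < min(1, params$labour_probability * modifier)
}

daily_income <- function(st, worked) {
  p <- st$params
  yd <- day_of_year(st$day)
  V <- st$V
  idx <- living(st)
  if (is_month_last_day(yd)) {
    sal <- idx[V$career[idx] %in% CAREERS_SALARIED]
    if (length(sal)) {
      amt <- unlist(p[paste0("salary_level", V$salary_level[sal])])
      credit(st, account_of(st, sal), "salary", amt)
    }
    abroad <- idx[V$career[idx] == "salaried_abroad"]
    if (length(abroad))
      credit(st, account_of(st, abroad), "salary",
             rep(p$foreign_salary, length(abroad)))
  }
  if (is_month_first_day(yd)) {
    pen <- idx[V$career[idx] == "pensioner"]
    if (length(pen))
      credit(st, account_of(st, pen), "pension",
             rep(p$pension_income, length(pen)))
  }
  if (length(worked))
    credit(st, account_of(st, worked), "wage",
           rep(p$labour_wage, length(worked)))
  invisible(NULL)
}

## ---- daily expenses (P1, S2) -------------------------------------------------

#' Daily food cost of a villager
#'
#' The adult-female staple basket plus non-staple food, scaled by the
#' age-sex consumption multiplier; halved on days spent working or studying
#' away from home; zero while abroad.
#'
#' @param st Village state.
#' @param ids Villager ids.
#' @param worked Ids of labourers who worked today.
#' @return NPR cost vector.
#' @export
food_cost <- function(st, ids, worked = integer(0)) {
  V <- st$V; p <- st$params
  base <- st$base_food
  mult <- food_multiplier(V$age[ids] / YEAR_DAYS, V$sex[ids])
  cost <- base * mult
  workday <- !is_saturday(st$day) & !(day_of_year(st$day) %in% st$festivals)
  half <- (ids %in% worked) |
    (workday & (V$career[ids] %in% CAREERS_SALARIED |
                  (V$career[ids] == "student" &
                     V$education[ids] %in% c("school", "plus2"))))
  cost[half] <- cost[half] / 2
  cost[V$abroad[ids]] <- 0
  cost
}

daily_expenses <- function(st, worked) {
  p <- st$params
  yd <- day_of_year(st$day)
  V <- st$V
  idx <- resident(st)
  if (!length(idx)) return(invisible(NULL))
  acct <- account_of(st, idx)
  credit(st, acct, "food", -food_cost(st, idx, worked))
  credit(st, acct, "other living", rep(-p$other_living_expenses, length(idx)))
  if (is_month_first_day(yd)) {
    sch <- V$education[idx] == "school"
    col <- V$education[idx] == "plus2"
    if (any(sch)) credit(st, acct[sch], "education",
                         rep(-p$school_expenses, sum(sch)))
    if (any(col)) credit(st, acct[col], "education",
                         rep(-p$plus2_expenses, sum(col)))
  }
  if (yd %in% st$festivals)
    credit(st, acct, "festival", rep(-p$festival_expenses, length(idx)))
  ## weekly meat, paid each Sunday at the controller's chosen portion count
  if (is_sunday(st$day)) {
    meat_k <- ifelse(V$controller[idx] == 0L, st$H$meat[V$hh[idx]],
                     V$meat[pmax(V$controller[idx], 1L)])
    mult <- food_multiplier(V$age[idx] / YEAR_DAYS, V$sex[idx])
    cost <- meat_k * p$meat_portion_cost * mult
    cost[V$abroad[idx]] <- 0
    credit(st, acct, "meat", -cost)
  }
  invisible(NULL)
}

## ---- conservative 12-month cash forecast (S11) -------------------------------

#' Conservative twelve-month cash-flow forecast for a finance controller
#'
#' Deterministic daily projection of the controller's balance: scheduled
#' salaries, pensions and remittances, expected short-term labour earnings,
#' current milk/egg/tomato income rates, crop income at forecast multipliers
#' and crop input costs on their calendar days, and all known outgoings
#' (food, daily living, education, festivals, animal feed, optional weekly
#' meat and reconstruction instalments).  Windfalls such as animal sales and
#' wedding gifts are excluded - that is what makes the forecast
#' conservative.
#'
#' @param st Village state.
#' @param acct Account id (positive villager, negative household).
#' @param meat_k Meat portions per week to assume.
#' @param include_recon Include reconstruction-loan instalments.
#' @param horizon Days ahead (default 365).
#' @return Numeric vector of projected balances for each future day.
#' @export
forecast_cashflow <- function(st, acct, meat_k = 0, include_recon = FALSE,
                              horizon = 365L) {
  p <- st$params
  days <- st$day + seq_len(horizon)
  yd <- day_of_year(days)
  net <- numeric(horizon)
  first <- is_month_first_day(yd)
  last <- is_month_last_day(yd)
  fest <- yd %in% st$festivals

  V <- st$V
  mem <- living(st)
  mem <- mem[account_of(st, mem) == acct]
  for (v in mem) {
    car <- V$career[v]
    if (car %in% CAREERS_SALARIED)
      net[last] <- net[last] + p[[paste0("salary_level", V$salary_level[v])]]
    if (car == "salaried_abroad") net[last] <- net[last] + p$foreign_salary
    if (car == "pensioner") net[first] <- net[first] + p$pension_income
    if (car == "labourer")
      net[!fest] <- net[!fest] + p$labour_probability * p$labour_wage
    if (!V$abroad[v]) {
      mult <- food_multiplier(V$age[v] / YEAR_DAYS, V$sex[v])
      net <- net - st$base_food * mult - p$other_living_expenses
      net[fest] <- net[fest] - p$festival_expenses
      net <- net - meat_k * p$meat_portion_cost * mult / 7
      if (V$education[v] == "school") net[first] <- net[first] - p$school_expenses
      if (V$education[v] == "plus2") net[first] <- net[first] - p$plus2_expenses
    }
  }

  if (acct < 0) {
    hid <- -acct
    if (st$H$remittance[hid]) net[first] <- net[first] + p$remittance_income
    ## animals: feed out, expected egg/milk in (current herd, current rates)
    ai <- which(st$A$alive & st$A$hh == hid)
    if (length(ai)) {
      net <- net - sum(feed_cost_per_day(st$A$species[ai], p))
      hens <- sum(st$A$species[ai] == "chicken" & st$A$sex[ai] == "F" &
                    st$A$age[ai] >= st$species$chicken$laying_start_age)
      lay_frac <- with(st$species$chicken,
                       laying_on_days / (laying_on_days + laying_off_days))
      net <- net + hens * p$egg_price * lay_frac
      size <- length(members_of(st, hid))
      if (size %in% 1:2) {
        for (s in BOVINES) {
          sp <- st$species[[s]]
          fem <- ai[st$A$species[ai] == s & st$A$sex[ai] == "F"]
          lact <- sum(milk_today(sp, st$A$age[fem]))
          net <- net + lact * sp$milk_income[size]
        }
      }
    }
    ## crops at forecast multipliers, inputs at plantation
    sim_year <- st$day %/% 365L + 1L
    male_bov <- has_male_bovine(st, hid)
    for (crop in st$crops$crop) {
      cr <- st$crops[crop, ]
      n <- max(st$strategy[hid, crop], st$planted[hid, crop])
      if (n == 0L) next
      hist <- st$yields[as.character(
        seq(max(sim_year - 10L, -9L), sim_year - 1L)), crop]
      f <- forecast_yields(hist, p$smoothing_alpha)
      std <- cr$std_yield
      if (crop %in% CASH_CROPS) std <- std * st$cashcrop_factor
      hd <- yd == cr$harvest_day
      net[hd] <- net[hd] + cr$price * std * f * 0.5 * n
      pd <- yd == cr$plant_day
      net[pd] <- net[pd] - plant_cost_per_field(cr, p) * n
      if (!male_bov) {
        net[hd] <- net[hd] - p$oxen_hire_cost * n
        net[pd] <- net[pd] - p$oxen_hire_cost * n
      }
    }
    if (st$H$tunnels[hid] > 0L) {
      tun <- st$H$tunnels[hid]
      net[yd %in% tunnel_harvest_yeardays(p)] <-
        net[yd %in% tunnel_harvest_yeardays(p)] + p$tomato_income * tun
      net[yd == p$tunnel_maintenance_day] <-
        net[yd == p$tunnel_maintenance_day] - p$tunnel_maintenance_cost * tun
      net[yd == p$tunnel_plant_day] <-
        net[yd == p$tunnel_plant_day] -
        (p$tunnel_seed_cost + p$tunnel_fertiliser_cost) * tun
    }
    if (include_recon && st$H$recon_loan[hid] > 0)
      net[first] <- net[first] -
        min(st$H$recon_principal[hid] * p$recon_instalment_fraction,
            st$H$recon_loan[hid])
  }
  account_cash(st, acct) + cumsum(net)
}

## ---- daily balance check, interest, monthly decisions (S11) ------------------

account_debt <- function(st, acct) {
  if (acct > 0) st$V$debt[acct] else st$H$debt[-acct]
}

add_debt <- function(st, acct, amt) {
  if (acct > 0) st$V$debt[acct] <- st$V$debt[acct] + amt
  else st$H$debt[-acct] <- st$H$debt[-acct] + amt
}

assess_finances <- function(st, acct) {
  p <- st$params
  cash <- account_cash(st, acct)

  ## 1. cover a shortfall: intra-household bailout first, then a loan
  if (cash < 0) {
    if (acct < 0) {
      hid <- -acct
      m <- members_of(st, hid)
      donors <- m[st$V$controller[m] == m]
      donors <- donors[order(-st$V$cash[donors])]
      for (d in donors) {
        if (cash >= 0) break
        give <- min(st$V$cash[d], -cash)
        if (give <= 0) next
        credit(st, d, "bailout", -give)
        credit(st, acct, "bailout", give)
        cash <- cash + give
      }
    }
    if (cash < 0) {
      credit(st, acct, "loan principal", -cash)
      add_debt(st, acct, -cash)
      cash <- 0
    }
  }

  ## 2. daily interest so that unpaid debt grows exactly 20% per year
  debt <- account_debt(st, acct)
  if (debt > 0) {
    r_daily <- (1 + p$annual_interest_rate)^(1 / 365) - 1
    add_debt(st, acct, debt * r_daily)
  }

  ## 3. monthly forecast-driven decisions
  if (!is_month_first_day(day_of_year(st$day))) return(invisible(NULL))
  path <- forecast_cashflow(st, acct, meat_k = 0, include_recon = FALSE)
  floor_bal <- min(path)
  debt <- account_debt(st, acct)
  if (debt > 0 && floor_bal > 0) {
    repay <- min(debt, floor_bal)
    credit(st, acct, "repayment", -repay)
    add_debt(st, acct, -repay)
    floor_bal <- floor_bal - repay
  }
  if (acct < 0) {
    hid <- -acct
    if (st$H$recon_loan[hid] > 0 && account_debt(st, acct) <= 0) {
      inst <- min(st$H$recon_principal[hid] * p$recon_instalment_fraction,
                  st$H$recon_loan[hid])
      if (floor_bal >= inst * 12) {   # affordable for the year ahead
        credit(st, acct, "repayment", -inst)
        st$H$recon_loan[hid] <- st$H$recon_loan[hid] - inst
        floor_bal <- floor_bal - inst * 12
      }
    }
  }
  ## meat: the largest affordable weekly portion count
  deps <- living(st)
  deps <- deps[account_of(st, deps) == acct & !st$V$abroad[deps]]
  week_cost <- sum(p$meat_portion_cost *
                     food_multiplier(st$V$age[deps] / YEAR_DAYS,
                                     st$V$sex[deps]))
  k <- 0L
  if (week_cost > 0 && account_debt(st, acct) <= 0) {
    annual <- week_cost * 365 / 7
    k_max <- p$max_meat_portions
    k <- max(c(0L, which(floor_bal - (1:k_max) * annual >= 0)))
  }
  if (acct > 0) st$V$meat[acct] <- k else st$H$meat[-acct] <- k
  invisible(NULL)
}

## ---- household fission (S9) --------------------------------------------------

unused_fields <- function(st, hid) {
  max(0L, st$H$fields[hid] - st$H$paddy[hid] -
        sum(st$planted[hid, colnames(st$planted) != "rice"]))
}

# Transfer freed (non-paddy) fields to a child household holding a claim.
settle_field_claims <- function(st, hid, freed, paddy = FALSE) {
  if (paddy || freed <= 0L) return(invisible(NULL))
  kids <- which(st$H$alive & !is.na(st$H$claim_from) & st$H$claim_from == hid)
  for (k in kids) {
    if (freed <= 0L) break
    t <- min(freed, st$H$claim_n[k])
    if (t <= 0L) next
    st$H$fields[hid] <- st$H$fields[hid] - t
    st$H$fields[k] <- st$H$fields[k] + t
    st$H$claim_n[k] <- st$H$claim_n[k] - t
    if (st$H$claim_n[k] == 0L) st$H$claim_from[k] <- NA_integer_
    freed <- freed - t
    log_event(st, "fields_claimed", paste0(k, "<-", hid, ":", t))
  }
  invisible(NULL)
}

#' Land entitlement of a departing son
#'
#' \code{E = F / (S + 1)} fields, F the parent household's field count and S
#' its resident son count (including the departing son), rounded to the
#' nearest half ropani (i.e. to a whole field).
#'
#' @param fields Parent household field count.
#' @param n_sons Resident sons of the referent.
#' @return Entitlement in fields.
#' @export
fission_entitlement <- function(fields, n_sons) {
  as.integer(floor(fields / (n_sons + 1) + 0.5))
}

household_fission_check <- function(st, hid) {
  V <- st$V; p <- st$params
  r <- st$H$referent[hid]
  if (is.na(r) || !V$alive[r]) return(invisible(NULL))
  m <- members_of(st, hid)
  sons <- m[!is.na(V$father[m]) & V$father[m] == r & V$sex[m] == "M"]
  if (length(sons) < 2L) return(invisible(NULL))  # the only son inherits
  youngest <- sons[which.min(V$age[sons])]
  cands <- setdiff(sons, youngest)
  cands <- cands[V$controller[cands] == cands &
                   !is.na(V$partner[cands]) &
                   V$alive[V$partner[cands]] & V$present[V$partner[cands]]]
  for (s in cands) {
    E <- fission_entitlement(st$H$fields[hid], length(sons))
    if (E < 12L) {
      ## under six ropani the farm is not viable: the son emigrates
      fam <- c(s, V$partner[s], intersect(children_of(st, s), m))
      V$present[fam] <- FALSE
      for (d in fam) log_event(st, "departure", paste0("fission_emigration:", d))
      update_referents(st); update_controllers(st)
      next
    }
    if (V$cash[s] < p$house_cost + p$fission_buffer) next
    credit(st, s, "house construction", -p$house_cost)
    new_h <- add_household(st)
    fam <- c(s, V$partner[s], intersect(children_of(st, s), m))
    V$hh[fam] <- new_h
    take <- min(unused_fields(st, hid), E)
    st$H$fields[hid] <- st$H$fields[hid] - take
    st$H$fields[new_h] <- take
    if (take < E) {
      st$H$claim_from[new_h] <- hid
      st$H$claim_n[new_h] <- E - take
    }
    ## the couple's remaining cash becomes the household cash stock
    move <- V$cash[s]
    if (move != 0) {
      credit(st, s, "other", -move)
      credit(st, -new_h, "other", move)
    }
    log_event(st, "fission", paste0(s, "->hh", new_h))
    update_referents(st); update_controllers(st)
    rebalance_animals(st, new_h)
  }
  invisible(NULL)
}

## ---- initial finances (I11) --------------------------------------------------

# Rough annual net surplus of a career under default parameters, used only
# to size the historical savings of self-managing sons.
career_annual_net <- function(st, v) {
  p <- st$params
  V <- st$V
  basic <- 365 * (p$other_living_expenses +
                    st$base_food *
                      food_multiplier(V$age[v] / YEAR_DAYS, V$sex[v]))
  income <- switch(V$career[v],
    salaried_1 = 12 * p$salary_level1, salaried_2 = 12 * p$salary_level2,
    salaried_3 = 12 * p$salary_level3, salaried_4 = 12 * p$salary_level4,
    salaried_abroad = 12 * p$foreign_salary,
    labourer = 365 * p$labour_probability * p$labour_wage,
    0)
  income - basic
}

initialize_finances <- function(st, ref) {
  p <- st$params
  V <- st$V
  ## independent sons: savings reflecting net earnings since leaving school
  ctrls <- living(st)
  self <- ctrls[V$controller[ctrls] == ctrls]
  for (s in self) {
    years <- max(0, (V$age[s] - p$plus2_end_days) / YEAR_DAYS)
    V$cash[s] <- max(0, years * career_annual_net(st, s))
  }
  ## every controller starts with the cash its first-year forecast requires,
  ## assuming two weekly meat portions and expected yields
  accts <- unique(c(-live_households(st), self))
  for (a in accts) {
    path <- forecast_cashflow(st, a, meat_k = 2)
    req <- max(0, -min(path))
    if (a > 0) V$cash[a] <- V$cash[a] + req
    else st$H$cash[-a] <- st$H$cash[-a] + req
  }
  ## historical household savings/debts resampled without replacement
  hhs <- live_households(st)
  if (length(ref$household_net_finances) < length(hhs))
    stop("reference net-finance set smaller than household count")
  draw <- sample(ref$household_net_finances, length(hhs))
  for (i in seq_along(hhs)) {
    if (draw[i] >= 0) st$H$cash[hhs[i]] <- st$H$cash[hhs[i]] + draw[i]
    else st$H$debt[hhs[i]] <- st$H$debt[hhs[i]] - draw[i]
  }
  ## two households receive a monthly remittance
  rem <- sample(hhs, min(2L, length(hhs)))
  st$H$remittance[rem] <- TRUE
  st$H$meat[hhs] <- 2L
  V$meat[self] <- 2L
  invisible(NULL)
}
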