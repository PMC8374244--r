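# Crops and polytunnels.
#
# Each crop has a fixed plantation and harvest year-day, a modal "standard"
# yield, and an annual yield multiplier drawn from a calibrated beta
# distribution (one per crop class and variability scenario).  Households
# re-plan their crop mix on plantation days: grain first (to cover the
# forecast twelve-month grain consumption of members and animals), the
# remaining non-paddy fields split 20:9:3 between potato, cabbage and
# cauliflower; paddy fields always grow rice.

GRAINS <- c("maize", "millet", "wheat")
CASH_CROPS <- c("potato", "cabbage", "cauliflower")

#' Initialise the annual yield multiplier series
#'
#' Samples ten years of history plus one multiplier per simulation year for
#' every crop, mutually independent, from the class- and scenario-specific
#' calibrated distributions.
#'
#' @param crops Crop table.
#' @param scenario Scenario settings (for the half-yield intervals).
#' @param n_years Simulated years.
#' @param support_max Beta support upper bound.
#' @return Matrix (10 + n_years) x crops; rows named -9..n_years where row
#'   1 is the first simulated year.
#' @export
init_yield_series <- function(crops, scenario, n_years = 15,
                              support_max = 1.25) {
  Ts <- yield_T_years(scenario)
  dists <- list(
    subsistence = calibrate_yield_distribution(Ts["subsistence"], support_max),
    cash = calibrate_yield_distribution(Ts["cash"], support_max))
  n <- 10 + n_years
  m <- sapply(seq_len(nrow(crops)), function(i)
    sample_yield_multipliers(dists[[crops$class[i]]], n))
  colnames(m) <- crops$crop
  rownames(m) <- as.character(seq_len(n) - 10L)
  m
}

yield_T_years <- function(scenario) {
  if (identical(scenario$crop_variability, "heightened"))
    c(subsistence = 9, cash = 7)
  else c(subsistence = 12, cash = 10)
}

yield_multiplier <- function(st, crop, sim_year) {
  st$yields[as.character(sim_year), crop]
}

## ---- crop strategy (S6) ------------------------------------------------------

#' Split surplus fields between the cash crops
#'
#' Divides \code{n} fields 20:9:3 between potato, cabbage and cauliflower by
#' largest remainder, breaking ties in the priority order potato, cabbage,
#' cauliflower; the three counts always sum to \code{n}.
#'
#' @param n Number of surplus fields.
#' @return Named integer vector.
#' @export
split_cash_crops <- function(n) {
  ratio <- c(potato = 20, cabbage = 9, cauliflower = 3)
  quota <- n * ratio / sum(ratio)
  base <- floor(quota)
  left <- n - sum(base)
  rem <- quota - base
  ord <- order(-rem, seq_along(rem))   # ties resolve by priority order
  if (left > 0) base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  as.integer(base) |> stats::setNames(names(ratio))
}

# Twelve-month grain needs in kg (members plus animals) for one household.
grain_needs_kg <- function(st, hid) {
  m <- members_of(st, hid)
  m <- m[!st$V$abroad[m]]
  basket <- food_basket()
  qty <- stats::setNames(basket$kg_per_day[match(GRAINS, basket$food)], GRAINS)
  mult <- if (length(m))
    sum(food_multiplier(st$V$age[m] / YEAR_DAYS, st$V$sex[m])) else 0
  human <- qty * mult * 365
  ai <- which(st$A$alive & st$A$hh == hid)
  animal <- c(maize = 0, millet = 0, wheat = 0)
  for (s in unique(st$A$species[ai])) {
    n <- sum(st$A$species[ai] == s)
    animal <- animal + st$species[[s]]$feed[GRAINS] * n * 365
  }
  human + animal
}

#' Update one household's crop strategy
#'
#' @param st Village state.
#' @param hid Household id.
#' @return Named integer vector of intended field counts per crop (also
#'   stored in the state).
#' @export
update_crop_strategy <- function(st, hid) {
  crops <- st$crops
  sim_year <- st$day %/% 365L + 1L
  needs <- grain_needs_kg(st, hid)
  avail <- st$H$fields[hid] - st$H$paddy[hid]
  alpha <- st$params$smoothing_alpha
  grain_fields <- integer(length(GRAINS)); names(grain_fields) <- GRAINS
  for (g in GRAINS) {
    hist <- st$yields[as.character(seq(sim_year - 10L, sim_year - 1L)), g]
    f <- forecast_yields(hist, alpha)
    per_field <- f * crops[g, "std_yield"] * 0.5
    grain_fields[g] <- as.integer(ceiling(needs[g] / per_field))
  }
  if (sum(grain_fields) > avail) {
    ## grain shortfall: everything to grain, proportional largest remainder
    quota <- avail * grain_fields / sum(grain_fields)
    base <- floor(quota); left <- avail - sum(base)
    ord <- order(-(quota - base), seq_along(quota))
    if (left > 0) base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    grain_fields <- as.integer(base) |> stats::setNames(GRAINS)
    log_event(st, "grain_shortfall", hid)
  }
  surplus <- max(0L, avail - sum(grain_fields))
  cash <- split_cash_crops(surplus)
  strat <- integer(nrow(crops)); names(strat) <- crops$crop
  strat[GRAINS] <- grain_fields
  strat[names(cash)] <- cash
  strat["rice"] <- st$H$paddy[hid]
  st$strategy[hid, ] <- strat[colnames(st$strategy)]
  strat
}

## ---- planting and harvesting (S7, S8, P7) ------------------------------------

has_male_bovine <- function(st, hid) {
  any(st$A$alive & st$A$hh == hid & st$A$species %in% BOVINES &
        st$A$sex == "M")
}

plant_cost_per_field <- function(crop_row, params) {
  seed <- if (is.na(crop_row$seed_kg_per_ropani))
    crop_row$seed_flat_npr / 2
  else crop_row$seed_kg_per_ropani * crop_row$price / 2
  seed + crop_row$fertiliser_per_ropani / 2
}

plant_crop <- function(st, crop, hid, n_fields, charge = TRUE) {
  if (n_fields <= 0L) return(invisible(NULL))
  cr <- st$crops[crop, ]
  if (charge) {
    cost <- plant_cost_per_field(cr, st$params) * n_fields
    credit(st, -hid, "crop input", -cost)
    if (!has_male_bovine(st, hid))
      credit(st, -hid, "oxen hire", -st$params$oxen_hire_cost * n_fields)
  }
  st$planted[hid, crop] <- st$planted[hid, crop] + as.integer(n_fields)
  st$plant_day_abs[hid, crop] <- st$day
  invisible(NULL)
}

process_planting_day <- function(st, crop) {
  for (hid in live_households(st)) {
    update_crop_strategy(st, hid)
    if (crop == "rice") {
      n <- st$H$paddy[hid] - st$planted[hid, "rice"]
    } else {
      unused <- st$H$fields[hid] - st$H$paddy[hid] -
        sum(st$planted[hid, colnames(st$planted) != "rice"])
      n <- min(st$strategy[hid, crop], max(0L, unused))
      if (n < st$strategy[hid, crop]) log_event(st, "plant_shortfall",
                                                paste0(hid, ":", crop))
    }
    plant_crop(st, crop, hid, n)
  }
}

# A harvest takes the 30% earthquake hit when the crop's growing interval
# (plantation day through today's harvest) overlaps the fixed shock window,
# 25 April - 12 June 2015.
quake_window_hit <- function(st, crop, hid) {
  if (!isTRUE(st$scenario$earthquake)) return(FALSE)
  w0 <- day_index_of(2015L, 4L, 25L)
  w1 <- day_index_of(2015L, 6L, 12L)
  pd <- st$plant_day_abs[hid, crop]
  !is.na(pd) && pd <= w1 && st$day >= w0
}

harvest_crop <- function(st, crop, hid) {
  n <- st$planted[hid, crop]
  if (n <= 0L) return(invisible(NULL))
  cr <- st$crops[crop, ]
  sim_year <- st$day %/% 365L + 1L
  mult <- yield_multiplier(st, crop, sim_year)
  std <- cr$std_yield
  if (crop %in% CASH_CROPS) std <- std * st$cashcrop_factor
  if (quake_window_hit(st, crop, hid)) mult <- mult * 0.7
  income <- cr$price * std * mult * 0.5 * n
  credit(st, -hid, "crop sale", income)
  if (!has_male_bovine(st, hid))
    credit(st, -hid, "oxen hire", -st$params$oxen_hire_cost * n)
  st$planted[hid, crop] <- 0L
  st$plant_day_abs[hid, crop] <- NA_integer_
  ## fields freed: honour any outstanding fission claim on this household
  settle_field_claims(st, hid, freed = n, paddy = crop == "rice")
  invisible(NULL)
}

process_crop_days <- function(st) {
  yd <- day_of_year(st$day)
  crops <- st$crops
  for (crop in crops$crop[crops$harvest_day == yd])
    for (hid in live_households(st)) harvest_crop(st, crop, hid)
  for (crop in crops$crop[crops$plant_day == yd])
    process_planting_day(st, crop)
}

## ---- polytunnels (P8) --------------------------------------------------------

tunnel_harvest_yeardays <- function(params = default_parameters()) {
  start <- params$tunnel_harvest_start + params$tunnel_harvest_interval
  days <- seq(start, 365 + params$tunnel_harvest_end,
              by = params$tunnel_harvest_interval)
  ((days - 1L) %% 365L) + 1L
}

step_polytunnels <- function(st) {
  p <- st$params
  yd <- day_of_year(st$day)
  hh <- live_households(st)
  hh <- hh[st$H$tunnels[hh] > 0L]
  if (!length(hh)) return(invisible(NULL))
  tun <- st$H$tunnels[hh]
  if (yd == p$tunnel_maintenance_day)
    credit(st, -hh, "tomato", -p$tunnel_maintenance_cost * tun)
  if (yd == p$tunnel_plant_day)
    credit(st, -hh, "tomato", -(p$tunnel_seed_cost +
                                  p$tunnel_fertiliser_cost) * tun)
  if (yd %in% tunnel_harvest_yeardays(p))
    credit(st, -hh, "tomato", p$tomato_income * tun)
  invisible(NULL)
}
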