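# Simulation engine: configuration, initialisation, and the daily loop.
#
# One time-step is one day.  The default run is 5475 days (fifteen years,
# 1 January 2015 through 31 December 2029, no leap days).  Within a day the
# schedule is: villagers (age, career, income, expenses, self-managed
# finance checks, death, marriage, birth), then animals, then households
# (crops, referent and controller maintenance, remittances, fission, herd
# rebalancing, finance assessment), then polytunnels.  Agents are iterated
# in stable id order and all randomness flows through named substreams, so
# a (config, seed) pair reproduces a run exactly.

#' Simulation configuration
#'
#' @param seed Master integer seed.
#' @param simulation_length_days Days to simulate (default 5475 = 15 years).
#' @param scenario [scenario_settings()].
#' @param parameters Named overrides applied on top of [default_parameters()],
#'   or a complete parameter list.
#' @param n_households Households to synthesise (default 14).
#' @param reference Synthesis reference data (defaults to the seeded
#'   synthetic fixture).
#' @param log_data Keep daily agent-level logs (needed by [write_run_log()]).
#' @param festival_days Year-days of the 23 festivals.
#' @param schedules Demographic schedule distributions.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       simulation_length_days = 5475L,
                       scenario = scenario_settings(),
                       parameters = list(),
                       n_households = 14L,
                       reference = NULL,
                       log_data = TRUE,
                       festival_days = default_festival_days(),
                       schedules = default_schedules()) {
  if (simulation_length_days < 0) stop("config error: negative run length")
  if (length(festival_days) != 23L)
    stop("config error: the festival calendar must have 23 days")
  base <- default_parameters()
  if (length(parameters)) {
    unknown <- setdiff(names(parameters), names(base))
    if (length(unknown))
      stop("config error: unknown parameter(s): ",
           paste(unknown, collapse = ", "))
    base[names(parameters)] <- parameters
  }
  structure(list(seed = as.integer(seed),
                 simulation_length_days = as.integer(simulation_length_days),
                 scenario = scenario, parameters = base,
                 n_households = as.integer(n_households),
                 reference = reference, log_data = isTRUE(log_data),
                 festival_days = as.integer(festival_days),
                 schedules = schedules),
            class = "sim_config")
}

## ---- initialisation ----------------------------------------------------------

initialize_village <- function(cfg) {
  st <- empty_state(cfg)
  st$ref <- if (is.null(cfg$reference)) generate_reference_fixture()
            else cfg$reference

  with_stream(st$streams, "synthesis", {
    rosters <- synthesize_village(cfg$n_households, st$ref, st$params)
    for (r in rosters) {
      hid <- add_household(st, fields = r$n_fields, paddy = r$n_paddy,
                           tunnels = r$tunnels)
      mm <- r$members
      ids <- add_villagers(st, nrow(mm), sex = mm$sex,
                           age = as.integer(mm$age_days), hh = hid)
      remap <- function(ix) ifelse(is.na(ix), NA_integer_, ids[ix])
      st$V$father[ids] <- remap(mm$father)
      st$V$mother[ids] <- remap(mm$mother)
      st$V$partner[ids] <- remap(mm$partner)
      ## schedules: wives first (husbands' marriage dates follow theirs)
      ord <- order(mm$sex != "F")
      for (i in ord) {
        nb <- if (mm$role[i] == "partner") r$next_birth_in_days else NA
        initialize_villager_schedules(st, ids[i], next_birth_in = nb)
      }
    }
    update_referents(st)
    update_controllers(st)
    st$kin_dirty <- FALSE
    init_animals(st)
  })

  with_stream(st$streams, "yields", {
    n_years <- max(15L, ceiling(cfg$simulation_length_days / 365))
    st$yields <- init_yield_series(st$crops, cfg$scenario, n_years,
                                   st$params$yield_support_max)
  })

  with_stream(st$streams, "synthesis", {
    ## crops already in the ground on 1 January: wheat, cabbage, cauliflower
    for (hid in live_households(st)) {
      update_crop_strategy(st, hid)
      for (crop in c("wheat", "cabbage", "cauliflower")) {
        n <- st$strategy[hid, crop]
        plant_crop(st, crop, hid, n, charge = FALSE)
        if (n > 0)
          st$plant_day_abs[hid, crop] <- st$crops[crop, "plant_day"] - 365L
      }
    }
    initialize_finances(st, st$ref)
  })
  ## snapshot of post-initialisation balances: the ledger closes against
  ## these (cash at any time = snapshot + signed ledger sum)
  st$init_hh_cash <- st$H$cash
  st$init_v_cash <- st$V$cash
  st
}

## ---- the daily loop ----------------------------------------------------------

process_day <- function(st) {
  with_stream(st$streams, "scenario", apply_earthquake_day(st))

  ## villagers
  idx <- living(st)
  st$V$age[idx] <- st$V$age[idx] + 1L
  ## crossing the adult threshold can change the household referent
  if (any(st$V$age[idx] == st$params$adult_age_days + 1L))
    st$kin_dirty <- TRUE
  with_stream(st$streams, "demography", update_careers_daily(st))
  worked <- with_stream(st$streams, "labour", draw_labour(st))
  daily_income(st, worked)
  daily_expenses(st, worked)
  for (v in which(st$V$alive & st$V$present & st$V$controller == st$V$id))
    assess_finances(st, v)
  with_stream(st$streams, "demography", {
    for (v in which(st$V$alive & !is.na(st$V$death_day) &
                      st$V$death_day == st$day))
      process_death(st, v)
    for (v in which(st$V$alive & st$V$present &
                      !is.na(st$V$marriage_day) &
                      st$V$marriage_day == st$day & is.na(st$V$partner)))
      process_marriage(st, v, st$ref)
    for (v in which(st$V$alive & st$V$present &
                      !is.na(st$V$next_birth_day) &
                      st$V$next_birth_day == st$day))
      process_birth(st, v)
  })

  ## animals
  with_stream(st$streams, "livestock", step_animals(st))

  ## households
  with_stream(st$streams, "misc", process_crop_days(st))
  if (st$kin_dirty) {
    update_referents(st)
    update_controllers(st)
    st$kin_dirty <- FALSE
  }
  if (is_month_first_day(day_of_year(st$day))) {
    rem <- live_households(st)
    rem <- rem[st$H$remittance[rem]]
    if (length(rem))
      credit(st, -rem, "remittance",
             rep(st$params$remittance_income, length(rem)))
  }
  ## fission: only households holding a married self-managing son of the
  ## referent need the full check
  cand <- which(st$V$alive & st$V$present & st$V$sex == "M" &
                  st$V$controller == st$V$id & !is.na(st$V$father) &
                  !is.na(st$V$partner))
  is_son <- !is.na(st$H$referent[st$V$hh[cand]]) &
    st$V$father[cand] == st$H$referent[st$V$hh[cand]]
  cand_hh <- unique(st$V$hh[cand][is_son])
  cand_hh <- cand_hh[!is.na(cand_hh) & st$H$alive[cand_hh]]
  if (length(cand_hh))
    with_stream(st$streams, "misc", {
      for (hid in cand_hh) household_fission_check(st, hid)
    })
  with_stream(st$streams, "livestock", rebalance_all(st))
  for (hid in live_households(st)) assess_finances(st, -hid)

  ## polytunnels
  step_polytunnels(st)

  ## bookkeeping
  hh <- live_households(st)
  in_debt <- st$H$debt[hh] > 0
  st$H$debt_days[hh] <- st$H$debt_days[hh] + in_debt
  st$H$ever_debt[hh] <- st$H$ever_debt[hh] | in_debt
  if (st$cfg$log_data) log_day(st)
  invisible(NULL)
}

log_day <- function(st) {
  hh <- live_households(st)
  sizes <- hh_sizes(st)
  acc_add(st$hh_log, list(
    day = rep(st$day, length(hh)), hh = hh, size = sizes[hh],
    cash = st$H$cash[hh], debt = st$H$debt[hh],
    recon_loan = st$H$recon_loan[hh], meat = st$H$meat[hh],
    fields = st$H$fields[hh]))
  idx <- living(st)
  acc_add(st$vill_log, list(
    day = rep(st$day, length(idx)), id = st$V$id[idx], hh = st$V$hh[idx],
    age = st$V$age[idx], sex = st$V$sex[idx], career = st$V$career[idx],
    cash = st$V$cash[idx], debt = st$V$debt[idx]))
}

#' Run one simulation
#'
#' Initialises the virtual village from the configuration and advances it
#' day by day, returning the complete logs and end-of-run summary
#' statistics.  Identical configurations (including the seed) produce
#' identical results.
#'
#' @param config A [sim_config()].
#' @return A list of class \code{village_run}: \code{summary} (the eight
#'   end-of-run statistics), \code{ledger}, \code{events}, \code{hh_log},
#'   \code{vill_log} (data.tables), \code{yields}, \code{config}, and the
#'   final \code{state}.
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "sim_config")) stop("config error: not a sim_config")
  st <- initialize_village(config)
  if (config$simulation_length_days == 0L && config$log_data) log_day(st)
  for (d in seq_len(config$simulation_length_days) - 1L) {
    st$day <- d
    process_day(st)
  }
  structure(list(summary = run_summary(st),
                 ledger = acc_collect(st$ledger),
                 events = acc_collect(st$events),
                 hh_log = acc_collect(st$hh_log),
                 vill_log = acc_collect(st$vill_log),
                 yields = st$yields,
                 config = config,
                 state = st),
            class = "village_run")
}

#' @export
print.village_run <- function(x, ...) {
  cat("<village_run>", x$config$simulation_length_days, "days, seed",
      x$config$seed, "\n")
  s <- x$summary
  cat(sprintf("  households %d | villagers %d | mean size %.2f\n",
              s$final_households, s$final_villagers, s$mean_household_size))
  cat(sprintf("  cash %.0f | loans %.0f | debt-days %d | ever-in-debt %d | Gini %.3f\n",
              s$total_household_cash, s$total_household_loans,
              s$household_debt_days, s$households_ever_in_debt,
              s$gini_household_cash))
  invisible(x)
}

## ---- end-of-run summary statistics -------------------------------------------

run_summary <- function(st) {
  hh <- live_households(st)
  sizes <- hh_sizes(st)[hh]
  list(final_households = length(hh),
       mean_household_size = if (length(hh)) mean(sizes) else NA_real_,
       final_villagers = length(living(st)),
       household_debt_days = sum(st$H$debt_days),
       households_ever_in_debt = sum(st$H$ever_debt),
       total_household_cash = sum(st$H$cash[hh]),
       total_household_loans = sum(st$H$debt[hh] + st$H$recon_loan[hh]),
       gini_household_cash = if (length(hh)) gini(st$H$cash[hh]) else NA_real_)
}
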