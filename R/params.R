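# Default model parameters.
#
# Every monetary value is in Nepalese rupees (NPR), every age or duration in
# days unless a name says otherwise, and land is measured in fields of half a
# ropani each (1 ropani = 508.7 m^2).  The defaults encode the village
# economy as surveyed: produce prices, wages, salaries, livestock schedules,
# crop calendars, and household cost structure.

#' Default simulation parameters
#'
#' Returns the complete named list of model parameters with their standard
#' (baseline) values.  All of them can be overridden through the
#' \code{parameters} argument of [sim_config()].
#'
#' @param preset Either \code{"standard"} (the sensitivity-analysis baseline
#'   values) or \code{"narrative"} (an alternative preset that follows the
#'   prose sub-model descriptions where those differ from the baseline table:
#'   chicken carcass 1500, goat slaughter 8800, buffalo slaughter
#'   19875/26500 female/male, festival expense 200).
#' @return A named list of parameters.
#' @export
default_parameters <- function(preset = c("standard", "narrative")) {
  preset <- match.arg(preset)
  p <- list(
    ## -- animal purchase prices --------------------------------------------
    chicken_purchase_price = 400,
    goat_purchase_price = 5000,
    cattle_purchase_price = 3000,
    buffalo_purchase_price = 10000,
    ## -- animal slaughter prices -------------------------------------------
    chicken_slaughter_price = 1200,
    goat_slaughter_price = 7600,
    female_buff_slaughter_price = 28000,
    male_buff_slaughter_price = 42000,
    ## -- career advancement probabilities ----------------------------------
    prob_plus2 = 0.5,          # do +2 (college) after school
    prob_salaried = 0.25,      # salaried job after completing +2
    prob_level2 = 0.75,        # promotion I -> II
    prob_level3 = 0.5,         # promotion II -> III
    prob_level4 = 0.5,         # promotion III -> IV
    ## -- crop yields (kg/ropani, the mode) and prices (NPR/kg) -------------
    maize_yield = 84.8,  millet_yield = 104.9, wheat_yield = 55.3,
    rice_yield = 150.1,  potato_yield = 793.1, cabbage_yield = 1017.4,
    cauliflower_yield = 610.4,
    maize_price = 25, millet_price = 19, wheat_price = 22, rice_price = 20,
    potato_price = 22, cabbage_price = 18, cauliflower_price = 25,
    ## -- cottage industry ---------------------------------------------------
    egg_price = 7,
    cow_milk_income_1 = 135,   # NPR/day, one-member household
    cow_milk_income_2 = 90,    # NPR/day, two-member household
    buff_milk_income_1 = 225,
    buff_milk_income_2 = 150,
    tomato_income = 4140,      # NPR per fortnightly polytunnel harvest
    ## -- day-to-day expenses -----------------------------------------------
    other_living_expenses = 27,   # NPR/villager/day
    other_food_expenses = 52,     # NPR/villager/day, non-staple food
    ## -- education ----------------------------------------------------------
    school_expenses = 400,        # NPR/month
    plus2_expenses = 800,         # NPR/month
    ## -- festivals, weddings, funerals --------------------------------------
    festival_expenses = 320,      # NPR/villager per festival day
    wedding_gift = 100000,        # parents' gift to newlyweds
    dowry_cost = 100000,          # bride's parents' expense when she marries
    funeral_cost = 200000,
    ## -- incomes -------------------------------------------------------------
    foreign_salary = 10000,       # NPR/month, salaried job abroad
    salary_level1 = 12000, salary_level2 = 15000,
    salary_level3 = 20000, salary_level4 = 25000,
    labour_wage = 500,            # NPR per worked day
    labour_probability = 0.19,    # daily work chance on non-festival days
    pension_income = 10000,       # NPR/month
    remittance_income = 10000,    # NPR/month
    ## -- finances -------------------------------------------------------------
    annual_interest_rate = 0.20,
    house_cost = 625000,
    fission_buffer = 35000,
    recon_instalment_fraction = 1 / 60,
    meat_portion_cost = 102,      # NPR, scaled by the food multiplier
    max_meat_portions = 3,
    ## -- agriculture ----------------------------------------------------------
    oxen_hire_cost = 425,         # NPR/field when no male bovine owned
    brassica_seed_cost = 300,     # NPR/ropani flat, cabbage & cauliflower
    smoothing_alpha = 0.3,        # exponential smoothing for yield forecasts
    yield_support_max = 1.25,     # upper bound of the yield multiplier beta
    ## -- land -------------------------------------------------------------------
    land_intercept = 1.8854,      # ropani
    land_slope_per_adult = 2.0284,
    land_noise_sd1 = 1.6715,
    land_noise_sd2 = 0.4728,
    land_floor_ropani = 5,
    paddy_threshold_ropani = 16,
    ## -- polytunnels -------------------------------------------------------------
    tunnel_maintenance_day = 46,  tunnel_maintenance_cost = 700,
    tunnel_plant_day = 98,        tunnel_seed_cost = 100,
    tunnel_fertiliser_cost = 770,
    tunnel_harvest_start = 213,   tunnel_harvest_end = 44,  # wraps the year
    tunnel_harvest_interval = 14,
    ## -- demography ----------------------------------------------------------------
    adult_age_days = 6570,        # 18 years
    school_calendar_day = 100,    # year-day when education stages change
    preschool_end_days = 2090,    # I2 thresholds
    school_end_days = 5740,
    plus2_end_days = 6570,
    childless_marriage_cutoff_years = 9.78,
    last_birth_cutoff_years = 9.86,
    retirement_age_years = 60,
    years_per_promotion = 5,      # years in a salary level before the draw
    ## unverified career-flow defaults (the printed probabilities cover only
    ## the five advancement parameters above)
    prob_male_abroad = 0.30,      # male education leavers without salaried job
    prob_male_labourer = 0.40,
    prob_female_labourer = 0.20
  )
  if (preset == "narrative") {
    p$chicken_slaughter_price <- 1500
    p$goat_slaughter_price <- 8800
    p$female_buff_slaughter_price <- 19875
    p$male_buff_slaughter_price <- 26500
    p$festival_expenses <- 200
  }
  p
}

#' Crop parameter table
#'
#' Per-crop calendar and economics: plantation and harvest year-days (harvest
#' days that fall in the following calendar year are stored modulo 365),
#' seed requirement per ropani (kg, or a flat NPR price for cabbage and
#' cauliflower), fertiliser/pesticide cost per ropani, the standard (modal)
#' yield in kg/ropani, and the market price in NPR/kg.
#'
#' @param params A parameter list from [default_parameters()] (prices and
#'   yields are read from it so overrides propagate).
#' @return A data.frame with one row per crop.
#' @export
crop_table <- function(params = default_parameters()) {
  d <- data.frame(
    crop = c("potato", "maize", "millet", "wheat", "rice", "cabbage",
             "cauliflower"),
    class = c("cash", "subsistence", "subsistence", "subsistence",
              "subsistence", "cash", "cash"),
    plant_day = c(29L, 57L, 166L, 275L, 174L, 219L, 244L),
    harvest_day_raw = c(170L, 256L, 334L, 127L, 342L, 615L, 419L),
    seed_kg_per_ropani = c(110, 0.8, 1.2, 6.4, 28.8, NA, NA),
    fertiliser_per_ropani = c(627, 313, 313, 313, 313, 150, 76),
    stringsAsFactors = FALSE
  )
  d$harvest_day <- ((d$harvest_day_raw - 1L) %% 365L) + 1L
  d$std_yield <- unlist(params[paste0(d$crop, "_yield")])
  d$price <- unlist(params[paste0(d$crop, "_price")])
  d$seed_flat_npr <- ifelse(is.na(d$seed_kg_per_ropani),
                            params$brassica_seed_cost, NA)
  rownames(d) <- d$crop
  d
}

#' Staple food basket of an adult woman
#'
#' Daily staple quantities (kg) and their daily cost (NPR) for a reference
#' adult female; other villagers scale this basket by [food_multiplier()].
#'
#' @return A data.frame with one row per foodstuff plus the non-staple
#'   "other" row.
#' @export
food_basket <- function() {
  data.frame(
    food = c("maize", "millet", "wheat", "rice", "potato", "other"),
    kg_per_day = c(0.026, 0.026, 0.016, 0.304, 0.100, NA),
    npr_per_day = c(0.65, 0.494, 0.352, 6.08, 2.2, 52),
    stringsAsFactors = FALSE
  )
}

#' Age-sex food consumption multiplier
#'
#' Pre-meat food needs relative to an adult woman, from recommended calorific
#' consumption by age-sex group.
#'
#' @param age_years Numeric vector of ages in years.
#' @param sex Character vector, "M" or "F".
#' @return Numeric vector of multipliers.
#' @export
food_multiplier <- function(age_years, sex) {
  stopifnot(length(age_years) == length(sex))
  breaks <- c(-Inf, 1, 4, 7, 10, 13, 16, Inf)
  f_mult <- c(0.37, 0.56, 0.76, 0.88, 0.89, 0.93, 1.00)
  m_mult <- c(0.37, 0.56, 0.76, 0.88, 0.98, 1.10, 1.29)
  band <- findInterval(age_years, breaks[-1]) + 1L
  band[band > 7L] <- 7L
  ifelse(sex == "M", m_mult[band], f_mult[band])
}

#' Species parameter block for livestock and poultry
#'
#' Daily feed (kg of maize/millet/wheat), purchase and exit schedules, birth
#' schedules, and produce rules for the five animal types.
#'
#' @param params Parameter list.
#' @return A named list, one entry per species.
#' @export
species_params <- function(params = default_parameters()) {
  list(
    chicken = list(
      feed = c(maize = 0.032, millet = 0.032, wheat = 0.010),
      purchase_age = 14, purchase_price = params$chicken_purchase_price,
      exit_age_male = 183, exit_age_female = 1825,
      exit_price_male = params$chicken_slaughter_price,
      exit_price_female = params$chicken_slaughter_price,
      laying_start_age = 183, laying_on_days = 30, laying_off_days = 91,
      egg_price = params$egg_price
    ),
    goat = list(
      feed = c(maize = 0.025, millet = 0.025, wheat = 0),
      purchase_age = 112, purchase_price = params$goat_purchase_price,
      exit_age_male = 730, exit_age_female = 730,
      exit_price_male = params$goat_slaughter_price,
      exit_price_female = params$goat_slaughter_price,
      birth_ages = c(329, 612),
      litter_pmf = c(`1` = 0.622, `2` = 0.333, `3` = 0.044) / 0.999,
      kid_price = params$goat_purchase_price
    ),
    cattle = list(
      feed = c(maize = 0.240, millet = 0.240, wheat = 0),
      purchase_age = 548, purchase_price = params$cattle_purchase_price,
      exit_age_male = 6570, exit_age_female = 6570,   # die at 18, no carcass
      exit_price_male = 0, exit_price_female = 0,
      sale_value_male = params$cattle_purchase_price,   # flat resale value
      sale_value_female = params$cattle_purchase_price,
      birth_ages = c(913, 1461, 2009, 2557, 3105, 3653, 4201),
      calf_price = params$cattle_purchase_price,
      milk_stop_age = 4688, milk_blackout_days = 61,
      milk_income = c(params$cow_milk_income_1, params$cow_milk_income_2),
      replacement_age = 548, replacement_price = params$cattle_purchase_price
    ),
    buffalo = list(
      feed = c(maize = 0.280, millet = 0.280, wheat = 0),
      purchase_age = 548, purchase_price = params$buffalo_purchase_price,
      exit_age_male = 5110, exit_age_female = 3650,   # 14 / 10 years
      exit_price_male = params$male_buff_slaughter_price,
      exit_price_female = params$female_buff_slaughter_price,
      birth_ages = c(1642, 2220, 2798, 3376),
      calf_price = params$buffalo_purchase_price,
      milk_stop_age = 3650, milk_blackout_days = 91,
      milk_income = c(params$buff_milk_income_1, params$buff_milk_income_2),
      replacement_age = 548, replacement_price = params$buffalo_purchase_price
    )
  )
}

#' Stepped animal-ownership targets by adult count
#'
#' The deterministic relation between a household's adult membership and the
#' number of chickens, goats, and bovines it keeps.  The step tables are a
#' documented fixture (the survey regressions behind them are unpublished);
#' they pass through the origin and the bovine figure is afterwards capped by
#' landholding in [target_animal_counts()].
#'
#' @return A list of step functions given as integer vectors indexed by adult
#'   count 0..8 (counts above 8 use the last entry).
#' @export
ownership_steps <- function() {
  list(
    chicken = c(0L, 2L, 3L, 4L, 5L, 6L, 6L, 7L, 7L),
    goat    = c(0L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L),
    bovine  = c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L)
  )
}

#' Thematic parameter groups for sensitivity analysis
#'
#' The eleven parameter groups with each member's baseline (C), lower (Cminus)
#' and upper (Cplus) values used by [oat_sensitivity()].
#'
#' @return A named list of data.frames with columns
#'   \code{parameter}, \code{C}, \code{Cminus}, \code{Cplus}.
#' @export
parameter_groups <- function() {
  g <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(parameter = m[, 1],
               C = as.numeric(m[, 2]),
               Cminus = as.numeric(m[, 3]),
               Cplus = as.numeric(m[, 4]),
               stringsAsFactors = FALSE)
  }
  list(
    `Animal purchase price` = g(
      "chicken_purchase_price", 400, 320, 480,
      "goat_purchase_price", 5000, 4000, 6000,
      "cattle_purchase_price", 3000, 2550, 3900,
      "buffalo_purchase_price", 10000, 8500, 13000),
    `Animal slaughter price` = g(
      "chicken_slaughter_price", 1200, 960, 1440,
      "goat_slaughter_price", 7600, 6080, 9120,
      "female_buff_slaughter_price", 28000, 19600, 36400,
      "male_buff_slaughter_price", 42000, 29400, 54600),
    `Career advancement probability` = g(
      "prob_plus2", 0.5, 0.42, 0.57,
      "prob_salaried", 0.25, 0.17, 0.32,
      "prob_level2", 0.75, 0.64, 0.86,
      "prob_level3", 0.5, 0.43, 0.58,
      "prob_level4", 0.5, 0.43, 0.58),
    `Cash crop price` = g(
      "potato_price", 22, 18, 26,
      "cabbage_price", 18, 14, 22,
      "cauliflower_price", 25, 20, 30),
    `Cottage industry income` = g(
      "cow_milk_income_1", 135, 115, 155,
      "cow_milk_income_2", 90, 77, 104,
      "buff_milk_income_1", 225, 191, 259,
      "buff_milk_income_2", 150, 128, 173,
      "tomato_income", 4140, 3312, 4968),
    `Day-to-day expenses` = g(
      "other_living_expenses", 27, 22, 32,
      "other_food_expenses", 52, 42, 62),
    `Educational expenses` = g(
      "school_expenses", 400, 200, 800,
      "plus2_expenses", 800, 400, 1600),
    `Festival, funeral & wedding costs` = g(
      "festival_expenses", 200, 160, 240,
      "wedding_gift", 100000, 80000, 120000,
      "funeral_cost", 200000, 160000, 240000),
    `Salaried job abroad` = g(
      "foreign_salary", 10000, 9000, 12000),
    `Salaried job in Nepal` = g(
      "salary_level1", 12000, 10800, 13200,
      "salary_level2", 15000, 13500, 16500,
      "salary_level3", 20000, 18000, 22000,
      "salary_level4", 25000, 22500, 27500),
    `Short-term labouring` = g(
      "labour_wage", 500, 450, 600,
      "labour_probability", 0.19, 0.15, 0.23)
  )
}
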