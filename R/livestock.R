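# Livestock and poultry.
#
# Animals are fed daily at the grain market prices, lay or give birth on
# fixed age schedules, yield milk income for one- and two-member households,
# and are slaughtered/replaced at species- and sex-specific ages.  Household
# herd sizes track deterministic targets driven by adult membership and
# capped by landholding.

BOVINES <- c("cattle", "buffalo")

grain_price_per_kg <- function(params) {
  c(maize = params$maize_price, millet = params$millet_price,
    wheat = params$wheat_price)
}

feed_cost_per_day <- function(species, params = default_parameters()) {
  sp <- species_params(params)
  gp <- grain_price_per_kg(params)
  vapply(species, function(s) sum(sp[[s]]$feed * gp), numeric(1))
}

#' Linear resale value of an animal
#'
#' An animal's worth rises linearly with age from its purchase (age, price)
#' to its slaughter (age, price), clamped at the endpoints.  Cattle, which
#' die without a carcass sale, hold a flat resale value equal to their
#' purchase price.
#'
#' @param species,sex,age Vectors describing the animals (age in days).
#' @param params Parameter list.
#' @return NPR values.
#' @export
animal_value <- function(species, sex, age, params = default_parameters()) {
  sp <- species_params(params)
  vapply(seq_along(species), function(i) {
    s <- sp[[species[i]]]
    a0 <- s$purchase_age; p0 <- s$purchase_price
    if (species[i] == "cattle") {
      return(if (sex[i] == "M") s$sale_value_male else s$sale_value_female)
    }
    a1 <- if (sex[i] == "M") s$exit_age_male else s$exit_age_female
    p1 <- if (sex[i] == "M") s$exit_price_male else s$exit_price_female
    w <- (min(max(age[i], a0), a1) - a0) / (a1 - a0)
    p0 + w * (p1 - p0)
  }, numeric(1))
}

#' Household herd-size targets
#'
#' Chickens, goats and bovines follow stepped functions of the adult count;
#' the bovine figure is then capped by landholding: under 5.5 ropani no
#' bovine can be supported, 5.5-10.5 ropani one, 11-16 two, 16.5-21.5 three.
#'
#' @param n_adults Integer vector of adult member counts.
#' @param ropani Numeric vector of landholdings.
#' @param steps Step tables from [ownership_steps()].
#' @return A list of integer vectors \code{chicken}, \code{goat},
#'   \code{bovine}.
#' @export
target_animal_counts <- function(n_adults, ropani, steps = ownership_steps()) {
  look <- function(tbl) tbl[pmin(n_adults, length(tbl) - 1L) + 1L]
  cap <- ifelse(ropani < 5.5, 0L,
         ifelse(ropani <= 10.5, 1L,
         ifelse(ropani <= 16, 2L,
         ifelse(ropani <= 21.5, 3L, .Machine$integer.max))))
  list(chicken = look(steps$chicken),
       goat = look(steps$goat),
       bovine = pmin(look(steps$bovine), cap))
}

## ---- daily processing (vectorised over the whole herd) -----------------------

milk_today <- function(sp, age) {
  ## lactating: past the first birth, before the milk cutoff, and outside
  ## the pre-birth blackout window
  if (!length(age)) return(logical(0))
  first <- sp$birth_ages[1]
  nxt <- vapply(age, function(a) {
    up <- sp$birth_ages[sp$birth_ages > a]
    if (length(up)) up[1] else Inf
  }, numeric(1))
  age > first & age < sp$milk_stop_age & (nxt - age) > sp$milk_blackout_days
}

step_animals <- function(st) {
  A <- st$A; p <- st$params; spp <- st$species
  idx <- which(A$alive)
  if (!length(idx)) return(invisible(NULL))
  A$age[idx] <- A$age[idx] + 1L
  gp <- grain_price_per_kg(p)
  sizes <- hh_sizes(st)

  for (s in names(spp)) {
    sp <- spp[[s]]
    ai <- idx[A$species[idx] == s]
    if (!length(ai)) next
    ## feed
    cost <- sum(sp$feed * gp)
    credit(st, -A$hh[ai], "animal feed", rep(-cost, length(ai)))

    if (s == "chicken") {
      hens <- ai[A$sex[ai] == "F" & A$age[ai] >= sp$laying_start_age]
      cyc <- (A$age[hens] - sp$laying_start_age) %%
        (sp$laying_on_days + sp$laying_off_days)
      laying <- hens[cyc < sp$laying_on_days]
      if (length(laying))
        credit(st, -A$hh[laying], "eggs", rep(sp$egg_price, length(laying)))
    }

    if (s == "goat") {
      dams <- ai[A$sex[ai] == "F" & A$age[ai] %in% sp$birth_ages]
      for (d in dams) {
        litter <- sample(as.integer(names(sp$litter_pmf)), 1,
                         prob = sp$litter_pmf)
        credit(st, -A$hh[d], "animal trade", litter * sp$kid_price)
        log_event(st, "goat_birth", litter)
      }
    }
    if (s %in% BOVINES) {
      dams <- ai[A$sex[ai] == "F" & A$age[ai] %in% sp$birth_ages]
      if (length(dams))
        credit(st, -A$hh[dams], "animal trade",
               rep(sp$calf_price, length(dams)))
      ## milk for one- and two-member households
      fem <- ai[A$sex[ai] == "F"]
      if (length(fem)) {
        small <- sizes[A$hh[fem]] %in% c(1L, 2L)
        fem <- fem[small]
        lact <- fem[milk_today(sp, A$age[fem])]
        if (length(lact)) {
          inc <- sp$milk_income[sizes[A$hh[lact]]]
          credit(st, -A$hh[lact], "milk", inc)
        }
      }
    }

    ## exits and replacements
    exit_age <- ifelse(A$sex[ai] == "M", sp$exit_age_male, sp$exit_age_female)
    ex <- ai[A$age[ai] >= exit_age]
    for (e in ex) {
      price <- if (A$sex[e] == "M") sp$exit_price_male else sp$exit_price_female
      if (price != 0) credit(st, -A$hh[e], "animal trade", price)
      if (s %in% BOVINES) {
        credit(st, -A$hh[e], "animal trade", -sp$replacement_price)
        A$age[e] <- as.integer(sp$replacement_age)
      } else {
        credit(st, -A$hh[e], "animal trade", -sp$purchase_price)
        A$age[e] <- as.integer(sp$purchase_age)
        A$sex[e] <- sample(c("M", "F"), 1)
      }
      log_event(st, "animal_replaced", s)
    }
  }
  invisible(NULL)
}

## ---- rebalancing (S10) -------------------------------------------------------

hh_animal_counts <- function(st, hid) {
  ai <- which(st$A$alive & st$A$hh == hid)
  sp <- st$A$species[ai]
  c(chicken = sum(sp == "chicken"), goat = sum(sp == "goat"),
    bovine = sum(sp %in% BOVINES))
}

buy_animals <- function(st, hid, kind, n) {
  p <- st$params
  for (k in seq_len(n)) {
    if (kind == "chicken") {
      add_animals(st, "chicken", sample(c("M", "F"), 1), 14L, hid)
      credit(st, -hid, "animal trade", -p$chicken_purchase_price)
    } else if (kind == "goat") {
      add_animals(st, "goat", sample(c("M", "F"), 1), 112L, hid)
      credit(st, -hid, "animal trade", -p$goat_purchase_price)
    } else {
      species <- if (stats::runif(1) < 0.4) "buffalo" else "cattle"
      owned <- which(st$A$alive & st$A$hh == hid & st$A$species == species)
      sex <- if (length(owned) == 0L) "F" else "M"
      add_animals(st, species, sex, 548L, hid)
      price <- if (species == "buffalo") p$buffalo_purchase_price
               else p$cattle_purchase_price
      credit(st, -hid, "animal trade", -price)
    }
  }
}

sell_animals <- function(st, hid, kind, n) {
  species_set <- if (kind == "bovine") BOVINES else kind
  ai <- which(st$A$alive & st$A$hh == hid & st$A$species %in% species_set)
  ai <- ai[order(st$A$age[ai])][seq_len(min(n, length(ai)))]
  if (!length(ai)) return(invisible(NULL))
  val <- animal_value(st$A$species[ai], st$A$sex[ai], st$A$age[ai], st$params)
  credit(st, rep(-hid, length(ai)), "animal trade", val)
  st$A$alive[ai] <- FALSE
}

rebalance_animals <- function(st, hid, ads = NULL) {
  if (is.null(ads)) ads <- adult_counts(st)
  tgt <- target_animal_counts(ads[hid], st$H$fields[hid] / 2, st$steps)
  cur <- hh_animal_counts(st, hid)
  for (kind in c("chicken", "goat", "bovine")) {
    diff <- tgt[[kind]] - cur[[kind]]
    if (diff > 0) buy_animals(st, hid, kind, diff)
    else if (diff < 0) sell_animals(st, hid, kind, -diff)
  }
  invisible(NULL)
}

# Daily village-wide rebalancing pass, vectorised so the common no-trade
# case costs almost nothing.
rebalance_all <- function(st) {
  hh <- live_households(st)
  if (!length(hh)) return(invisible(NULL))
  ads <- adult_counts(st)
  tgt <- target_animal_counts(ads[hh], st$H$fields[hh] / 2, st$steps)
  nh <- length(st$H$id)
  ai <- which(st$A$alive)
  sp <- st$A$species[ai]; ahh <- st$A$hh[ai]
  cur_ch <- tabulate(ahh[sp == "chicken"], nbins = nh)
  cur_go <- tabulate(ahh[sp == "goat"], nbins = nh)
  cur_bo <- tabulate(ahh[sp %in% BOVINES], nbins = nh)
  for (k in seq_along(hh)) {
    hid <- hh[k]
    d <- tgt$chicken[k] - cur_ch[hid]
    if (d > 0) buy_animals(st, hid, "chicken", d)
    else if (d < 0) sell_animals(st, hid, "chicken", -d)
    d <- tgt$goat[k] - cur_go[hid]
    if (d > 0) buy_animals(st, hid, "goat", d)
    else if (d < 0) sell_animals(st, hid, "goat", -d)
    d <- tgt$bovine[k] - cur_bo[hid]
    if (d > 0) buy_animals(st, hid, "bovine", d)
    else if (d < 0) sell_animals(st, hid, "bovine", -d)
  }
  invisible(NULL)
}

## ---- initial herds (I10) -----------------------------------------------------

init_animals <- function(st) {
  ads <- adult_counts(st); p <- st$params; spp <- st$species
  for (hid in live_households(st)) {
    tgt <- target_animal_counts(ads[hid], st$H$fields[hid] / 2, st$steps)
    for (k in seq_len(tgt$chicken)) {
      sp <- spp$chicken
      sex <- sample(c("M", "F"), 1)
      hi <- if (sex == "M") sp$exit_age_male else sp$exit_age_female
      add_animals(st, "chicken", sex,
                  sample(seq(sp$purchase_age, hi - 1L), 1), hid)
    }
    for (k in seq_len(tgt$goat)) {
      sp <- spp$goat
      add_animals(st, "goat", sample(c("M", "F"), 1),
                  sample(seq(sp$purchase_age, sp$exit_age_male - 1L), 1), hid)
    }
    for (k in seq_len(tgt$bovine)) {
      species <- if (stats::runif(1) < 0.4) "buffalo" else "cattle"
      owned <- which(st$A$alive & st$A$hh == hid & st$A$species == species)
      sex <- if (length(owned) == 0L) "F" else "M"
      sp <- spp[[species]]
      hi <- if (sex == "M") sp$exit_age_male else sp$exit_age_female
      add_animals(st, species, sex,
                  sample(seq(sp$purchase_age, hi - 1L), 1), hid)
    }
  }
  invisible(NULL)
}
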