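# Household-structured population synthesis.
#
# The village is synthesised top-down: household archetypes are drawn first
# (stochastic universal sampling over the archetype frequencies), then each
# household is populated member by member (referent, partner, children,
# grandparents, siblings or brother and sister-in-law, depending on the
# archetype) by resampling observed reference sets of ages, age gaps and
# birth intervals.  The original survey reference sets are unpublished, so a
# seeded synthetic stand-in with the same structure is generated by
# [generate_reference_fixture()]; real data in the same schema can be
# substituted.

ARCHETYPES <- c("lone_individual", "lone_couple", "nuclear",
                "nuclear_grandmother", "nuclear_grandparents",
                "nuclear_dil", "complex")

#' Synthetic reference data fixture
#'
#' Generates a seeded stand-in for the (unpublished) survey reference
#' distributions that the population synthesiser resamples: archetype
#' frequencies, referent ages by archetype, spousal age gaps, conditional
#' children counts, eldest-child ages, birth intervals, intergenerational
#' age gaps, and household net finances.  Every sample set is labelled
#' synthetic; the structure is what the synthesiser requires, the values are
#' plausible for a Mid-Hills Tamang village.
#'
#' @param seed Integer seed for the fixture draws.
#' @return A list of class \code{synthesis_reference} (all ages in years).
#' @export
generate_reference_fixture <- function(seed = 20150101) {
  old <- get_random_seed(); on.exit(restore_random_seed(old))
  set.seed(seed %% .Machine$integer.max)

  cond_table <- function(ages, sampler) {
    tab <- lapply(ages, sampler)
    names(tab) <- ages
    tab
  }

  ref <- list(
    synthetic = TRUE,
    archetype_probs = c(lone_individual = 0.08, lone_couple = 0.10,
                        nuclear = 0.36, nuclear_grandmother = 0.10,
                        nuclear_grandparents = 0.10, nuclear_dil = 0.12,
                        complex = 0.14),
    referent_ages = list(
      lone_individual = round(stats::runif(12, 45, 80), 1),
      lone_couple = round(stats::runif(10, 40, 75), 1),
      nuclear = round(stats::runif(16, 28, 52), 1),
      nuclear_grandmother = round(stats::runif(10, 30, 48), 1),
      nuclear_grandparents = round(stats::runif(10, 28, 45), 1),
      nuclear_dil = round(stats::runif(10, 20, 30), 1),
      complex = round(stats::runif(8, 25, 40), 1)
    ),
    # husband minus wife, years; filtered on use so no partner is under 18
    spouse_age_gaps = round(stats::rnorm(25, 3.5, 2.5), 1),
    sister_in_law_gaps = round(stats::rnorm(15, 3.0, 2.5), 1),
    children_given_partner_age = cond_table(
      seq(20, 45, by = 5),
      function(a) pmax(1L, stats::rpois(12, lambda = 1 + a / 18))),
    eldest_child_age_given_partner_age = cond_table(
      seq(20, 45, by = 5),
      function(a) round(stats::runif(12, 0.3, max(1.5, a - 19)), 1)),
    birth_intervals = round(stats::runif(30, 1.6, 4.4), 2),
    referent_mother_age_gaps = round(stats::runif(15, 19, 32), 1),
    mother_father_age_gaps = round(stats::rnorm(15, 3, 2), 1),
    children_given_mother_age = cond_table(
      seq(40, 75, by = 5),
      function(a) pmax(1L, stats::rpois(12, lambda = 2.6))),
    household_net_finances = round(stats::rnorm(20, 40000, 120000)),
    sibling_gap_bound = 3
  )
  ref$archetype_probs <- ref$archetype_probs / sum(ref$archetype_probs)
  class(ref) <- "synthesis_reference"
  ref
}

#' Stochastic universal sampling of household archetypes
#'
#' Spins a single uniform pointer offset and places \code{n} equally spaced
#' pointers on the cumulative probability wheel, guaranteeing each archetype
#' a count within one of its expectation \code{n * P(t)}.
#'
#' @param n Number of households to draw.
#' @param probs Named probability vector over archetypes (sums to 1).
#' @return Character vector of \code{n} archetype labels (wheel order).
#' @export
sample_household_types <- function(n, probs) {
  stopifnot(n >= 1)
  if (abs(sum(probs) - 1) > 1e-9)
    stop("archetype probabilities must sum to 1")
  cum <- cumsum(probs)
  pointers <- stats::runif(1, 0, 1 / n) + (seq_len(n) - 1) / n
  idx <- findInterval(pointers, cum, left.open = TRUE) + 1L
  names(probs)[idx]
}

## ---- member-level synthesis --------------------------------------------------

draw_from <- function(set) set[sample.int(length(set), 1L)]

nearest_cond <- function(tab, age) {
  keys <- as.numeric(names(tab))
  tab[[which.min(abs(keys - age))]]
}

# ±0.5-year additive noise applied to drawn age gaps/ages
half_year_noise <- function(n = 1) stats::runif(n, -0.5, 0.5)

#' Synthesize one household's member roster
#'
#' Members are generated in a fixed order (referent, partner, children,
#' grandmother, grandfather, then siblings or brother plus sister-in-law,
#' as the archetype requires).  Referent ages get multiplicative noise of
#' up to 5 percent; every other drawn age gets up to half a year of
#' additive noise, so members of identically structured households do not
#' share birthdays.  Child sexes are equiprobable; the referent is male
#' except for lone individuals, whose sex is a fair draw.
#'
#' @param type Archetype label (one of [ARCHETYPES]).
#' @param ref Reference data ([generate_reference_fixture()] or real data in
#'   the same schema).
#' @return A list with \code{archetype}, a \code{members} data.frame (role,
#'   sex, age_days, father, mother, partner as row indices), the couple's
#'   \code{lifetime_children}, and \code{next_birth_in_days} (NA if none
#'   pending).
#' @export
synthesize_household <- function(type, ref) {
  if (!type %in% ARCHETYPES) stop("unknown archetype: ", type)
  YEAR <- 365
  role <- character(); sex <- character(); age <- numeric()
  father <- integer(); mother <- integer(); partner <- integer()
  add <- function(r, s, a, fa = NA_integer_, mo = NA_integer_,
                  pa = NA_integer_) {
    role <<- c(role, r); sex <<- c(sex, s); age <<- c(age, a)
    father <<- c(father, fa); mother <<- c(mother, mo)
    partner <<- c(partner, pa)
    length(role)
  }

  ## referent: observed age with up to +/-5% multiplicative noise
  ar <- draw_from(ref$referent_ages[[type]]) * stats::runif(1, 0.95, 1.05)
  r_sex <- if (type == "lone_individual") sample(c("M", "F"), 1) else "M"
  i_ref <- add("referent", r_sex, ar)
  lifetime_children <- 0L
  next_birth <- NA_real_

  if (type != "lone_individual") {
    ## partner: spousal age gap, filtered so she is at least 18
    gaps <- ref$spouse_age_gaps[ar - ref$spouse_age_gaps >= 18]
    ap <- if (length(gaps)) ar - (draw_from(gaps) + half_year_noise())
          else 18 + stats::runif(1, 0, 0.5)
    ap <- max(ap, 18)
    i_par <- add("partner", "F", ap, pa = i_ref)
    partner[i_ref] <- i_par
    lifetime_children <-
      as.integer(draw_from(nearest_cond(ref$children_given_partner_age, ap)))
  }

  has_children <- type %in% c("nuclear", "nuclear_grandmother",
                              "nuclear_grandparents", "complex")
  if (has_children) {
    ac1 <- draw_from(nearest_cond(ref$eldest_child_age_given_partner_age, ap))
    ac1 <- min(ac1, max(ap - 16, 0.2))   # mother at least ~16 at first birth
    a_k <- ac1; born <- 0L
    while (born < lifetime_children) {
      if (a_k >= 0) {
        add("child", sample(c("M", "F"), 1), a_k, fa = i_ref, mo = i_par)
        born <- born + 1L
        if (born == lifetime_children) break
        a_k <- a_k - draw_from(ref$birth_intervals)
      } else {
        next_birth <- -a_k * YEAR   # interval points into the future
        break
      }
    }
    if (is.na(next_birth) && born < lifetime_children)
      next_birth <- draw_from(ref$birth_intervals) * YEAR
  }

  if (type %in% c("nuclear_grandmother", "nuclear_grandparents",
                  "nuclear_dil", "complex")) {
    am <- ar + draw_from(ref$referent_mother_age_gaps) + half_year_noise()
    i_gm <- add("grandmother", "F", am)
    mother[i_ref] <- i_gm
    if (type != "nuclear_grandmother") {
      af <- am + draw_from(ref$mother_father_age_gaps) + half_year_noise()
      i_gf <- add("grandfather", "M", af, pa = i_gm)
      partner[i_gm] <- i_gf
      father[i_ref] <- i_gf
    }
  }

  if (type == "nuclear_dil") {
    ## the referent is the eldest of his parents' children; younger siblings
    ## live in the household, none yet married
    n_sibs <- max(0L, as.integer(
      draw_from(nearest_cond(ref$children_given_mother_age, am))) - 1L)
    a_k <- ar
    for (s in seq_len(n_sibs)) {
      a_k <- a_k - draw_from(ref$birth_intervals)
      if (a_k < 0) break
      add("sibling", sample(c("M", "F"), 1), a_k,
          fa = father[i_ref], mo = mother[i_ref])
    }
  }

  if (type == "complex") {
    ## married brother close in age (gap under the sibling bound)
    gaps_b <- ref$birth_intervals[ref$birth_intervals < ref$sibling_gap_bound]
    if (!length(gaps_b)) gaps_b <- min(ref$birth_intervals)
    ab <- ar + draw_from(gaps_b)
    i_bro <- add("brother", "M", ab, fa = father[i_ref], mo = mother[i_ref])
    gaps_s <- ref$sister_in_law_gaps[ab - ref$sister_in_law_gaps >= 18]
    asil <- if (length(gaps_s)) ab - (draw_from(gaps_s) + half_year_noise())
            else 18 + stats::runif(1, 0, 0.5)
    i_sil <- add("sister_in_law", "F", max(asil, 18), pa = i_bro)
    partner[i_bro] <- i_sil
  }

  list(archetype = type,
       members = data.frame(role = role, sex = sex,
                            age_days = round(age * YEAR),
                            father = father, mother = mother,
                            partner = partner, stringsAsFactors = FALSE),
       lifetime_children = lifetime_children,
       next_birth_in_days = if (is.na(next_birth)) NA_real_
                            else round(next_birth))
}

## ---- land, paddy, polytunnels ------------------------------------------------

round_half <- function(x) floor(x * 2 + 0.5) / 2

#' Allocate land to a household
#'
#' Landholding in ropani is a stochastic linear function of the adult count:
#' \code{r = 1.8854 + 2.0284 a + eta1 + eta2} with independent zero-mean
#' Gaussian noise terms (sd 1.6715 and 0.4728), rounded to the nearest half
#' ropani and floored at five ropani (the minimum viable farm).  Each
#' half-ropani is one field.
#'
#' @param n_adults Number of adult (over-18) members.
#' @param params Parameter list.
#' @param noise If FALSE the noise terms are suppressed (for testing).
#' @return Landholding in ropani (multiple of 0.5, >= 5).
#' @export
allocate_land <- function(n_adults, params = default_parameters(),
                          noise = TRUE) {
  r <- params$land_intercept + params$land_slope_per_adult * n_adults
  if (noise)
    r <- r + stats::rnorm(1, 0, params$land_noise_sd1) +
      stats::rnorm(1, 0, params$land_noise_sd2)
  max(params$land_floor_ropani, round_half(r))
}

#' Allocate paddy fields and polytunnels across the village
#'
#' Households with at least 16 ropani get two, three, or four paddy fields
#' (equiprobable).  Exactly three households with at least two adults under
#' 60 receive polytunnels (one to three each, equiprobable); if fewer than
#' three households are eligible, all eligible households receive tunnels.
#'
#' @param ropani Numeric vector of household landholdings.
#' @param adults_under_60 Integer vector of adult-under-60 counts.
#' @param params Parameter list.
#' @return A list with integer vectors \code{paddy} and \code{tunnels}.
#' @export
allocate_paddy_and_polytunnels <- function(ropani, adults_under_60,
                                           params = default_parameters()) {
  n <- length(ropani)
  paddy <- integer(n)
  big <- ropani >= params$paddy_threshold_ropani
  paddy[big] <- sample(2:4, sum(big), replace = TRUE)
  tunnels <- integer(n)
  eligible <- which(adults_under_60 >= 2)
  chosen <- if (length(eligible) > 3)
    sample(eligible, 3) else eligible
  tunnels[chosen] <- sample(1:3, length(chosen), replace = TRUE)
  list(paddy = paddy, tunnels = tunnels)
}

#' Synthesize a full village
#'
#' Draws archetypes for \code{n_households} households by stochastic
#' universal sampling, populates each household, allocates land (two fields
#' per ropani), paddy fields and polytunnels.
#'
#' @param n_households Number of households (the study village had 14).
#' @param ref Reference data.
#' @param params Parameter list.
#' @return A list of household rosters with land attached.
#' @export
synthesize_village <- function(n_households = 14,
                               ref = generate_reference_fixture(),
                               params = default_parameters()) {
  types <- sample_household_types(n_households, ref$archetype_probs)
  hhs <- lapply(types, synthesize_household, ref = ref)
  adult_days <- params$adult_age_days
  for (i in seq_along(hhs)) {
    m <- hhs[[i]]$members
    adults <- sum(m$age_days > adult_days)
    hhs[[i]]$ropani <- allocate_land(adults, params)
    hhs[[i]]$n_fields <- as.integer(hhs[[i]]$ropani * 2)
  }
  au60 <- vapply(hhs, function(h)
    sum(h$members$age_days > adult_days &
          h$members$age_days < 60 * 365), integer(1))
  pp <- allocate_paddy_and_polytunnels(
    vapply(hhs, `[[`, numeric(1), "ropani"), au60, params)
  for (i in seq_along(hhs)) {
    hhs[[i]]$n_paddy <- pp$paddy[i]
    hhs[[i]]$tunnels <- pp$tunnels[i]
  }
  hhs
}
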