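# Life-course demography: education and careers, marriage, birth, death,
# and villager-level schedule initialisation.
#
# Every villager carries a pre-drawn destiny: a scheduled marriage day and a
# scheduled death day drawn from the sex-specific schedule distributions,
# plus (for married women under fifty) a desired lifetime child count and
# the provisional day of the next birth.  Daily processing fires whichever
# of these fall due; education stages change only at the start of the school
# year (year-day 100) and other career change points on birthdays.

YEAR_DAYS <- 365

children_of <- function(st, vid) {
  which((!is.na(st$V$father) & st$V$father == vid) |
          (!is.na(st$V$mother) & st$V$mother == vid))
}

births_count <- function(st, mid) {
  sum(!is.na(st$V$mother) & st$V$mother == mid)
}

## ---- careers -----------------------------------------------------------------

# Career pathway for a villager leaving education (also used, with elapsed
# promotion periods replayed, when initialising mid-life villagers).  The
# printed probabilities cover salaried entry and promotions; the remaining
# branch shares are configurable defaults flagged as unverified.
draw_career_path <- function(st, sex, attainment, age_days) {
  p <- st$params
  age_y <- age_days / YEAR_DAYS
  career <- "farm"; level <- NA_integer_
  if (attainment == "left_plus2" && stats::runif(1) < p$prob_salaried) {
    career <- "salaried_1"; level <- 1L
    ## replay promotion draws for time already served
    n_periods <- max(0L, floor((age_y - 18) / p$years_per_promotion))
    probs <- c(p$prob_level2, p$prob_level3, p$prob_level4)
    for (k in seq_len(n_periods)) {
      if (level >= 4L) break
      if (stats::runif(1) < probs[level]) level <- level + 1L
    }
    career <- paste0("salaried_", level)
  } else if (sex == "M") {
    u <- stats::runif(1)
    career <- if (u < p$prob_male_abroad) "salaried_abroad"
              else if (u < p$prob_male_abroad + p$prob_male_labourer)
                "labourer" else "farm"
  } else {
    career <- if (stats::runif(1) < p$prob_female_labourer) "labourer"
              else "farm"
  }
  if (age_y >= p$retirement_age_years) {
    if (career %in% CAREERS_SALARIED) career <- "pensioner"
    if (career == "salaried_abroad") career <- "farm"
  }
  list(career = career, level = level)
}

#' Daily education and career update
#'
#' Education stages (begin/complete school, begin/complete +2) change only
#' on the year-day the school calendar starts; school completers enter +2
#' with the configured probability and +2 completers obtain a salaried job
#' with the configured probability.  Salary-level promotions are drawn on
#' birthdays after each full period in the level, and configured careers
#' retire to a pension at sixty.
#'
#' @param st Village state.
#' @keywords internal
update_careers_daily <- function(st) {
  p <- st$params
  yd <- day_of_year(st$day)
  V <- st$V
  idx <- living(st)
  if (!length(idx)) return(invisible(NULL))

  if (yd == p$school_calendar_day) {
    pre <- idx[V$education[idx] == "preschool" & V$age[idx] >= p$preschool_end_days]
    V$education[pre] <- "school"
    sch <- idx[V$education[idx] == "school" & V$age[idx] >= p$school_end_days]
    for (v in sch) {
      if (stats::runif(1) < p$prob_plus2) {
        V$education[v] <- "plus2"
      } else {
        V$education[v] <- "left_slc"
        cp <- draw_career_path(st, V$sex[v], "left_slc", V$age[v])
        set_career(st, v, cp)
      }
    }
    col <- idx[V$education[idx] == "plus2" & V$age[idx] >= p$plus2_end_days]
    for (v in col) {
      V$education[v] <- "left_plus2"
      cp <- draw_career_path(st, V$sex[v], "left_plus2", V$age[v])
      set_career(st, v, cp)
    }
  }

  ## birthday change points
  bidx <- idx[V$age[idx] %% YEAR_DAYS == 0L & V$age[idx] > 0L]
  for (v in bidx) {
    if (V$career[v] %in% CAREERS_SALARIED) {
      if (V$age[v] >= p$retirement_age_years * YEAR_DAYS) {
        V$career[v] <- "pensioner"; V$salary_level[v] <- NA_integer_
        next
      }
      lvl <- V$salary_level[v]
      if (!is.na(lvl) && lvl < 4L &&
          st$day - V$level_since[v] >= p$years_per_promotion * YEAR_DAYS) {
        pr <- c(p$prob_level2, p$prob_level3, p$prob_level4)[lvl]
        if (stats::runif(1) < pr) {
          V$salary_level[v] <- lvl + 1L
          V$career[v] <- paste0("salaried_", lvl + 1L)
          V$level_since[v] <- st$day
        }
      }
    } else if (V$career[v] == "salaried_abroad" &&
               V$age[v] >= p$retirement_age_years * YEAR_DAYS) {
      V$career[v] <- "farm"; V$abroad[v] <- FALSE
    }
  }
  invisible(NULL)
}

set_career <- function(st, v, cp) {
  st$kin_dirty <- TRUE
  st$V$career[v] <- cp$career
  st$V$salary_level[v] <- cp$level
  st$V$level_since[v] <- st$day
  st$V$abroad[v] <- cp$career == "salaried_abroad"
}

## ---- schedule initialisation (ages, education, marriage, fertility, death) ---

init_education <- function(st, v) {
  p <- st$params
  a <- st$V$age[v]
  if (a < p$preschool_end_days) {
    st$V$education[v] <- "preschool"; st$V$career[v] <- "student"
  } else if (a < p$school_end_days) {
    st$V$education[v] <- "school"; st$V$career[v] <- "student"
  } else if (a < p$plus2_end_days) {
    if (stats::runif(1) < 0.5) {
      st$V$education[v] <- "plus2"; st$V$career[v] <- "student"
    } else {
      st$V$education[v] <- "left_slc"
    }
  } else if (a < 28 * YEAR_DAYS) {
    u <- stats::runif(1)
    st$V$education[v] <- if (u < 0.25) "left_plus2"
                         else if (u < 0.5) "left_slc" else "left_none"
  } else if (a < 45 * YEAR_DAYS) {
    st$V$education[v] <- if (stats::runif(1) < 0.25) "left_slc" else "left_none"
  } else {
    st$V$education[v] <- "left_none"
  }
}

#' Schedule marriage age from the viable region
#'
#' Draws a marriage age (in years) from the sex-appropriate marriage-age
#' distribution restricted to \code{[lo, hi]} and renormalised; an empty
#' viable region falls back to the minimum viable age.
#'
#' @param st Village state (for the schedule distributions).
#' @param sex "M" or "F".
#' @param lo,hi Viable-age bounds in years.
#' @return Marriage age in years.
#' @export
schedule_marriage_age <- function(st, sex, lo = -Inf, hi = Inf) {
  sample_plcdf(st$schedules$marriage_age[[sex]], 1, lo = lo, hi = hi)
}

init_death_schedule <- function(st, v) {
  age_y <- st$V$age[v] / YEAR_DAYS
  d_age <- sample_plcdf(st$schedules$death_age[[st$V$sex[v]]], 1, lo = age_y)
  st$V$death_day[v] <- st$day + as.integer(round((d_age - age_y) * YEAR_DAYS))
  if (st$V$death_day[v] <= st$day) st$V$death_day[v] <- st$day + 1L
}

# I2-I6 for one synthesised villager.  Married members already have partner
# links; `eldest_child_age` (years, NA if none) constrains the woman's
# marriage age, and provisional next births are passed through from the
# synthesiser.
initialize_villager_schedules <- function(st, v, eldest_child_age = NA,
                                          next_birth_in = NA) {
  p <- st$params
  V <- st$V
  age_y <- V$age[v] / YEAR_DAYS
  init_education(st, v)
  if (V$education[v] %in% c("left_none", "left_slc", "left_plus2")) {
    cp <- draw_career_path(st, V$sex[v], V$education[v], V$age[v])
    set_career(st, v, cp)
  }
  married <- !is.na(V$partner[v])
  if (married && V$sex[v] == "F") {
    hi <- if (!is.na(eldest_child_age)) age_y - eldest_child_age else age_y
    m_age <- schedule_marriage_age(st, "F", hi = min(hi, age_y))
    V$marriage_day[v] <- st$day - as.integer(round((age_y - m_age) * YEAR_DAYS))
    ## husband married the same day
    h <- V$partner[v]
    V$marriage_day[h] <- V$marriage_day[v]
  } else if (!married) {
    m_age <- schedule_marriage_age(st, V$sex[v], lo = age_y)
    if (isTRUE(attr(m_age, "degenerate")) && age_y > 45) {
      V$marriage_day[v] <- NA_integer_       # beyond marriageable support
    } else {
      V$marriage_day[v] <- st$day +
        as.integer(round((max(m_age, age_y) - age_y) * YEAR_DAYS))
    }
  }
  init_death_schedule(st, v)

  ## fertility of married women under fifty
  if (married && V$sex[v] == "F" && age_y < 50) {
    n_kids <- births_count(st, v)
    years_married <- (st$day - V$marriage_day[v]) / YEAR_DAYS
    kids <- children_of(st, v)
    last_birth_y <- if (length(kids)) min(V$age[kids]) / YEAR_DAYS else NA
    if (n_kids == 0L && years_married > p$childless_marriage_cutoff_years) {
      V$desired_children[v] <- 0L
    } else if (!is.na(last_birth_y) &&
               last_birth_y > p$last_birth_cutoff_years) {
      V$desired_children[v] <- n_kids
    } else {
      V$desired_children[v] <-
        draw_desired_children(1, st$scenario$fertility_rate, floor = n_kids)
    }
    if (V$desired_children[v] > n_kids) {
      if (!is.na(next_birth_in)) {
        V$next_birth_day[v] <- st$day + as.integer(next_birth_in)
      } else if (n_kids == 0L) {
        delay <- sample_plcdf(st$schedules$first_birth_delay, 1,
                              lo = years_married)
        V$next_birth_day[v] <- V$marriage_day[v] +
          as.integer(round(delay * YEAR_DAYS))
      } else {
        gap <- sample_plcdf(st$schedules$birth_interval, 1, lo = last_birth_y)
        V$next_birth_day[v] <- st$day +
          as.integer(round((gap - last_birth_y) * YEAR_DAYS))
      }
      if (!is.na(V$next_birth_day[v]) && V$next_birth_day[v] <= st$day)
        V$next_birth_day[v] <- st$day + 1L
    }
  }
  invisible(NULL)
}

## ---- death (S3) --------------------------------------------------------------

process_death <- function(st, v) {
  V <- st$V; p <- st$params
  hid <- V$hh[v]
  partner <- V$partner[v]
  if (!is.na(partner) && V$alive[partner]) {
    V$widowed[partner] <- TRUE
    nb <- V$next_birth_day[partner]
    if (!is.na(nb) && nb - st$day > 274L)      # keep births due within 9 months
      V$next_birth_day[partner] <- NA_integer_
  }
  ## estate: cash and debts pass to the controller, or to the wife (else the
  ## household) when the deceased managed his own finances
  if (V$controller[v] == v) {
    heir <- if (!is.na(partner) && V$alive[partner] && V$present[partner] &&
                V$sex[partner] == "F") partner else -hid
    if (V$cash[v] != 0) {
      amt <- V$cash[v]
      credit(st, v, "inheritance", -amt)
      credit(st, heir, "inheritance", amt)
    }
    if (V$debt[v] > 0) {
      if (heir > 0) V$debt[heir] <- V$debt[heir] + V$debt[v]
      else st$H$debt[hid] <- st$H$debt[hid] + V$debt[v]
      V$debt[v] <- 0
    }
  } else if (V$controller[v] != 0L) {
    ## dependents have no personal account; nothing to transfer
  }
  credit(st, -hid, "funeral", -p$funeral_cost)
  log_event(st, if (V$present[v]) "death" else "death_absent", v)
  V$alive[v] <- FALSE
  st$kin_dirty <- TRUE

  ## widow and children of a self-managing man move to her natal village
  if (V$controller[v] == v && V$sex[v] == "M" &&
      !is.na(partner) && V$alive[partner] && V$present[partner]) {
    depart <- c(partner, intersect(children_of(st, v), living(st)))
    depart <- depart[V$age[depart] < p$adult_age_days | depart == partner]
    V$present[depart] <- FALSE
    for (d in depart) log_event(st, "departure", paste0("widow_family:", d))
  }

  ## orphans: adopted by in-village paternal grandparents, else leave
  kids <- intersect(children_of(st, v), living(st))
  kids <- kids[V$age[kids] < p$adult_age_days]
  for (k in kids) {
    fa <- V$father[k]; mo <- V$mother[k]
    fa_here <- !is.na(fa) && V$alive[fa] && V$present[fa]
    mo_here <- !is.na(mo) && V$alive[mo] && V$present[mo]
    if (fa_here || mo_here) next
    gps <- c(if (!is.na(fa)) V$father[fa], if (!is.na(fa)) V$mother[fa])
    gps <- gps[!is.na(gps)]
    gps <- gps[V$alive[gps] & V$present[gps]]
    if (length(gps)) {
      V$hh[k] <- V$hh[gps[1]]
      log_event(st, "adoption", k)
    } else {
      V$present[k] <- FALSE
      log_event(st, "departure", paste0("orphan:", k))
    }
  }

  ## a sole-member household dissolves with its assets
  if (st$H$alive[hid] && length(members_of(st, hid)) == 0L) {
    remove_household(st, hid, reason = "death_of_sole_member")
  }
  invisible(NULL)
}

remove_household <- function(st, hid, reason = "") {
  st$H$alive[hid] <- FALSE
  st$H$fields[hid] <- 0L; st$H$paddy[hid] <- 0L; st$H$tunnels[hid] <- 0L
  st$planted[hid, ] <- 0L
  dead_animals <- which(st$A$alive & st$A$hh == hid)
  st$A$alive[dead_animals] <- FALSE
  log_event(st, "household_removed", paste0(hid, ":", reason))
}

## ---- marriage (S4) -----------------------------------------------------------

process_marriage <- function(st, v, ref) {
  V <- st$V; p <- st$params
  parents <- c(V$father[v], V$mother[v])
  parents <- parents[!is.na(parents)]
  parents <- parents[V$alive[parents] & V$present[parents]]

  if (V$sex[v] == "F") {
    ## she marries out of the village; her parents provide the dowry
    if (length(parents))
      credit(st, account_of(st, parents[1]), "dowry", -p$dowry_cost)
    V$present[v] <- FALSE
    log_event(st, "departure", paste0("marriage_out:", v))
    return(invisible(NULL))
  }
  if (!V$present[v] || V$career[v] == "emigrated") {
    if (length(parents))
      credit(st, account_of(st, parents[1]), "wedding", -p$wedding_gift)
    log_event(st, "marriage_migrant", v)
    return(invisible(NULL))
  }

  ## a wife is created for a resident groom
  groom_age_y <- V$age[v] / YEAR_DAYS
  gaps <- ref$spouse_age_gaps[groom_age_y - ref$spouse_age_gaps >= 18]
  wife_age <- if (length(gaps))
    groom_age_y - (draw_from(gaps) + half_year_noise()) else 18
  wife_age <- max(wife_age, 18)
  w <- add_villagers(st, 1, sex = "F", hh = V$hh[v],
                     age = as.integer(round(wife_age * YEAR_DAYS)),
                     partner = v, marriage_day = st$day)
  V$partner[v] <- w
  init_education(st, w)
  if (V$education[w] %in% c("left_none", "left_slc", "left_plus2")) {
    cp <- draw_career_path(st, "F", V$education[w], V$age[w])
    set_career(st, w, cp)
  }
  init_death_schedule(st, w)
  V$desired_children[w] <-
    draw_desired_children(1, st$scenario$fertility_rate, floor = 0)
  if (V$desired_children[w] > 0L) {
    delay <- sample_plcdf(st$schedules$first_birth_delay, 1)
    V$next_birth_day[w] <- st$day + as.integer(round(delay * YEAR_DAYS))
  }
  ## wedding transfers: both sets of parents gift the couple; the bride's
  ## parents are outside the model so their gift enters from outside
  couple <- account_of(st, v)
  if (length(parents)) {
    credit(st, account_of(st, parents[1]), "wedding", -p$wedding_gift)
    credit(st, couple, "wedding", p$wedding_gift)
  }
  credit(st, couple, "wedding", p$wedding_gift)
  log_event(st, "marriage", paste0(v, "+", w))
  st$kin_dirty <- TRUE
  invisible(NULL)
}

## ---- birth (S5) --------------------------------------------------------------

process_birth <- function(st, mo) {
  V <- st$V
  fa <- V$partner[mo]
  sex <- sample(c("M", "F"), 1)
  b <- add_villagers(st, 1, sex = sex, hh = V$hh[mo],
                     mother = mo,
                     father = if (!is.na(fa)) fa else NA_integer_)
  ## destiny draws for the newborn
  m_age <- schedule_marriage_age(st, sex)
  V$marriage_day[b] <- st$day + as.integer(round(m_age * YEAR_DAYS))
  d_age <- sample_plcdf(st$schedules$death_age[[sex]], 1)
  V$death_day[b] <- st$day + max(1L, as.integer(round(d_age * YEAR_DAYS)))
  log_event(st, "birth", b)

  n_kids <- births_count(st, mo)
  if (!is.na(V$desired_children[mo]) && n_kids < V$desired_children[mo]) {
    gap <- sample_plcdf(st$schedules$birth_interval, 1)
    V$next_birth_day[mo] <- st$day + as.integer(round(gap * YEAR_DAYS))
  } else {
    V$next_birth_day[mo] <- NA_integer_
  }
  st$kin_dirty <- TRUE
  invisible(NULL)
}

## ---- referent and controller maintenance (E1.1-E1.2) -------------------------

has_sibling_in_hh <- function(st, v, members) {
  fa <- st$V$father[v]; mo <- st$V$mother[v]
  if (is.na(fa) && is.na(mo)) return(FALSE)
  sib <- members[members != v]
  any((!is.na(st$V$father[sib]) & !is.na(fa) & st$V$father[sib] == fa) |
        (!is.na(st$V$mother[sib]) & !is.na(mo) & st$V$mother[sib] == mo))
}

update_referents <- function(st) {
  p <- st$params
  for (hid in live_households(st)) {
    m <- members_of(st, hid)
    if (!length(m)) next
    adults <- m[st$V$age[m] > p$adult_age_days]
    males <- adults[st$V$sex[adults] == "M"]
    cand <- males[!vapply(males, has_sibling_in_hh, logical(1),
                          st = st, members = m)]
    if (!length(cand)) {
      wid <- adults[st$V$sex[adults] == "F" & st$V$widowed[adults]]
      cand <- wid
    }
    if (!length(cand)) cand <- adults
    if (!length(cand)) cand <- m
    st$H$referent[hid] <- cand[which.min(st$V$age[cand])]
  }
  invisible(NULL)
}

update_controllers <- function(st) {
  V <- st$V
  for (hid in live_households(st)) {
    m <- members_of(st, hid)
    if (!length(m)) next
    r <- st$H$referent[hid]
    V$controller[m] <- 0L
    if (is.na(r) || !(r %in% m)) next
    sons <- m[!is.na(V$father[m]) & V$father[m] == r & V$sex[m] == "M" &
                V$education[m] %in% c("left_none", "left_slc", "left_plus2")]
    for (s in sons) {
      V$controller[s] <- s
      w <- V$partner[s]
      if (!is.na(w) && w %in% m) V$controller[w] <- s
      kids <- intersect(children_of(st, s), m)
      V$controller[kids] <- s
    }
  }
  invisible(NULL)
}
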