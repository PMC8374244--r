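# Stressor scenarios.
#
# Three binary stressor pathways combine into eight scenarios: the 2015
# earthquake versus a no-earthquake counterfactual, fertility rates of 1.6
# versus 2.1 children per woman, and status-quo versus heightened crop-yield
# variability (half-yield recurrence intervals of 12/10 versus 9/7 years for
# subsistence/cash crops).

#' Scenario settings
#'
#' @param earthquake Simulate the 2015 earthquake (logical).
#' @param fertility_rate 1.6 or 2.1 children per woman.
#' @param crop_variability "status_quo" (12/10-year half-yield recurrence)
#'   or "heightened" (9/7-year).
#' @return A list of class \code{scenario_settings}.
#' @export
scenario_settings <- function(earthquake = FALSE, fertility_rate = 2.1,
                              crop_variability = c("status_quo",
                                                   "heightened")) {
  fertility_rate <- as.numeric(fertility_rate)
  if (!fertility_rate %in% c(1.6, 2.1))
    stop("fertility_rate must be 1.6 or 2.1")
  structure(list(earthquake = isTRUE(earthquake),
                 fertility_rate = fertility_rate,
                 crop_variability = match.arg(crop_variability)),
            class = "scenario_settings")
}

#' All eight scenario combinations
#' @return List of [scenario_settings()].
#' @export
all_scenarios <- function() {
  out <- list()
  for (eq in c(TRUE, FALSE))
    for (f in c(2.1, 1.6))
      for (cv in c("status_quo", "heightened"))
        out[[length(out) + 1L]] <- scenario_settings(eq, f, cv)
  out
}

#' Encode a run's output filename
#'
#' Pattern \code{{EQ|NE}-{16|21}-{12|09}-{seed}.csv}: earthquake or
#' no-earthquake, fertility rate, subsistence half-yield interval, and the
#' zero-padded seed.
#'
#' @param settings [scenario_settings()].
#' @param seed Integer seed.
#' @return File name string.
#' @export
encode_run_name <- function(settings, seed) {
  sprintf("%s-%s-%s-%02d.csv",
          if (settings$earthquake) "EQ" else "NE",
          if (settings$fertility_rate == 2.1) "21" else "16",
          if (settings$crop_variability == "status_quo") "12" else "09",
          as.integer(seed))
}

#' Decode a run filename back into scenario settings and seed
#' @param name File name from [encode_run_name()].
#' @return List with \code{settings} and \code{seed}.
#' @export
decode_run_name <- function(name) {
  m <- regmatches(name,
                  regexec("^(EQ|NE)-(16|21)-(12|09)-([0-9]+)\\.csv$", name))[[1]]
  if (!length(m)) stop("not a run file name: ", name)
  list(settings = scenario_settings(
         earthquake = m[2] == "EQ",
         fertility_rate = if (m[3] == "21") 2.1 else 1.6,
         crop_variability = if (m[4] == "12") "status_quo" else "heightened"),
       seed = as.integer(m[5]))
}

## ---- earthquake timeline (Sc1) -----------------------------------------------

quake_shock_day <- function() day_index_of(2015L, 4L, 25L)
quake_loan_day <- function() day_index_of(2016L, 10L, 25L)

reconstruction_loan_size <- function(n_members) {
  ifelse(n_members <= 2, 300000,
  ifelse(n_members <= 4, 425000,
  ifelse(n_members <= 6, 550000, 675000)))
}

# Called once per day when the earthquake scenario is active; a no-op
# otherwise (and it consumes no random numbers in that case, so
# counterfactual runs match runs where it is never invoked).
apply_earthquake_day <- function(st) {
  if (!isTRUE(st$scenario$earthquake)) return(invisible(NULL))
  shock <- quake_shock_day()
  ## off-farm labour: stops for three months, then a 24-month recovery boom
  st$labour_modifier <-
    if (st$day < shock) 1
    else if (st$day < shock + 91L) 0
    else if (st$day < shock + 91L + 730L) 1.5
    else 1

  if (st$day == shock) {
    st$cashcrop_factor <- 0.85
    ## five percent of livestock die, unsellable
    ai <- which(st$A$alive)
    dead <- ai[stats::runif(length(ai)) < 0.05]
    st$A$alive[dead] <- FALSE
    if (length(dead)) log_event(st, "quake_livestock_death", length(dead))
    ## emigration: lone individuals, and two-adult households with a
    ## salaried member, each leave with probability one half
    sizes <- hh_sizes(st)
    for (hid in live_households(st)) {
      m <- members_of(st, hid)
      lone <- sizes[hid] == 1L
      two_adult <- sizes[hid] == 2L &&
        sum(st$V$age[m] > st$params$adult_age_days) == 2L &&
        any(st$V$career[m] %in% c(CAREERS_SALARIED, "salaried_abroad"))
      if ((lone || two_adult) && stats::runif(1) < 0.5) {
        st$V$present[m] <- FALSE
        for (d in m) log_event(st, "departure", paste0("quake_emigration:", d))
        remove_household(st, hid, reason = "quake_emigration")
      }
    }
  }

  if (st$day == quake_loan_day()) {
    sizes <- hh_sizes(st)
    for (hid in live_households(st)) {
      loan <- reconstruction_loan_size(sizes[hid])
      st$H$recon_principal[hid] <- loan
      st$H$recon_loan[hid] <- loan
      credit(st, -hid, "loan principal", loan)
      log_event(st, "reconstruction_loan", paste0(hid, ":", loan))
    }
  }
  invisible(NULL)
}
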