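# Shared fixtures: a small fast configuration and a ready-initialised state.

quick_config <- function(seed = 1L, days = 60L, ...) {
  sim_config(seed = seed, simulation_length_days = days, ...)
}

# An initialised (day-0) state without any simulated dynamics.
fresh_state <- function(seed = 1L, ...) {
  villagesim:::initialize_village(quick_config(seed = seed, days = 0L, ...))
}

# A bare two-person household state for targeted unit checks.
tiny_state <- function(seed = 42L) {
  st <- villagesim:::empty_state(quick_config(seed = seed, days = 0L))
  st$ref <- generate_reference_fixture(seed)
  hid <- villagesim:::add_household(st, fields = 12L)
  ids <- villagesim:::add_villagers(
    st, 2L, sex = c("M", "F"), hh = hid,
    age = c(30L * 365L, 27L * 365L),
    education = "left_none", career = "farm")
  st$V$partner[ids] <- rev(ids)
  st$V$marriage_day[ids] <- -365L
  st$H$referent[hid] <- ids[1]
  st$yields <- init_yield_series(st$crops, st$scenario, 16)
  st$init_hh_cash <- st$H$cash
  st$init_v_cash <- st$V$cash
  st
}
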