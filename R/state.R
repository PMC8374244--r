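# Village state.
#
# The whole simulation state lives in one environment holding column vectors
# for villagers (V), households (H) and animals (A), plus planting matrices,
# the yield series, RNG substreams, the transaction ledger and the event
# log.  Accounts are encoded as integers: a positive id is a self-managing
# villager's personal account, a negative id is a household account.  Every
# cash movement goes through credit(), which both updates the account and
# appends a ledger row, so the ledger always closes against the cash deltas.

CAREERS_SALARIED <- c("salaried_1", "salaried_2", "salaried_3", "salaried_4")

# Chunked column accumulators: each chunk is a named list of equal-length
# column vectors; collection concatenates per column (far lighter than
# binding thousands of small data frames).
new_accumulator <- function() {
  acc <- new.env(parent = emptyenv())
  acc$store <- new.env(parent = emptyenv())   # O(1) appends
  acc$n <- 0L
  acc
}

acc_add <- function(acc, chunk) {
  acc$n <- acc$n + 1L
  assign(as.character(acc$n), chunk, envir = acc$store)
}

acc_collect <- function(acc) {
  if (acc$n == 0L) return(NULL)
  chunks <- mget(as.character(seq_len(acc$n)), envir = acc$store)
  cols <- names(chunks[[1]])
  out <- lapply(cols, function(cl) unlist(lapply(chunks, `[[`, cl),
                                          use.names = FALSE))
  names(out) <- cols
  data.table::setDT(out)[]
}

## ---- state construction ------------------------------------------------------

empty_state <- function(cfg) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$day <- 0L
  st$params <- cfg$parameters
  st$scenario <- cfg$scenario
  st$streams <- make_rng_streams(cfg$seed)
  st$festivals <- cfg$festival_days
  st$schedules <- cfg$schedules
  st$species <- species_params(cfg$parameters)
  st$crops <- crop_table(cfg$parameters)
  st$steps <- ownership_steps()
  st$base_food <- base_food_cost(cfg$parameters)  # cached daily constant

  st$V <- new.env(parent = emptyenv())
  for (col in c("id", "hh", "father", "mother", "partner", "controller",
                "marriage_day", "death_day", "desired_children",
                "next_birth_day", "salary_level", "level_since", "age",
                "meat"))
    assign(col, integer(0), envir = st$V)
  for (col in c("alive", "present", "widowed", "abroad"))
    assign(col, logical(0), envir = st$V)
  for (col in c("sex", "education", "career"))
    assign(col, character(0), envir = st$V)
  for (col in c("cash", "debt")) assign(col, numeric(0), envir = st$V)

  st$H <- new.env(parent = emptyenv())
  for (col in c("id", "referent", "fields", "paddy", "tunnels",
                "meat", "claim_from", "claim_n", "debt_days"))
    assign(col, integer(0), envir = st$H)
  for (col in c("alive", "remittance", "ever_debt"))
    assign(col, logical(0), envir = st$H)
  for (col in c("cash", "debt", "recon_principal", "recon_loan"))
    assign(col, numeric(0), envir = st$H)

  st$A <- new.env(parent = emptyenv())
  st$A$id <- integer(0); st$A$hh <- integer(0); st$A$age <- integer(0)
  st$A$alive <- logical(0)
  st$A$species <- character(0); st$A$sex <- character(0)

  ncrop <- nrow(st$crops)
  st$planted <- matrix(0L, nrow = 0, ncol = ncrop,
                       dimnames = list(NULL, st$crops$crop))
  st$strategy <- st$planted
  st$plant_day_abs <- matrix(NA_integer_, nrow = 0, ncol = ncrop,
                             dimnames = list(NULL, st$crops$crop))

  st$ledger <- new_accumulator()
  st$events <- new_accumulator()
  st$hh_log <- new_accumulator()
  st$vill_log <- new_accumulator()
  st$next_vid <- 1L
  st$next_hid <- 1L
  st$next_aid <- 1L
  st$kin_dirty <- TRUE            # referent/controller recompute needed
  st$labour_modifier <- 1         # earthquake window multiplier
  st$cashcrop_factor <- 1         # permanent post-quake cash-crop factor
  st
}

add_villagers <- function(st, n, ...) {
  vals <- list(...)
  V <- st$V
  ids <- st$next_vid - 1L + seq_len(n)
  st$next_vid <- st$next_vid + n
  defaults <- list(
    id = ids, hh = NA_integer_, father = NA_integer_, mother = NA_integer_,
    partner = NA_integer_, controller = 0L, marriage_day = NA_integer_,
    death_day = NA_integer_, desired_children = NA_integer_,
    next_birth_day = NA_integer_, salary_level = NA_integer_,
    level_since = NA_integer_, age = 0L, meat = 0L,
    alive = TRUE, present = TRUE, widowed = FALSE, abroad = FALSE,
    sex = NA_character_, education = "preschool", career = "student",
    cash = 0, debt = 0)
  for (col in names(defaults)) {
    v <- if (col %in% names(vals)) vals[[col]] else defaults[[col]]
    if (length(v) == 1L) v <- rep(v, n)
    assign(col, c(get(col, envir = V), v), envir = V)
  }
  ids
}

add_household <- function(st, ...) {
  vals <- list(...)
  H <- st$H
  id <- st$next_hid
  st$next_hid <- st$next_hid + 1L
  defaults <- list(
    id = id, referent = NA_integer_, fields = 0L, paddy = 0L, tunnels = 0L,
    meat = 0L, claim_from = NA_integer_, claim_n = 0L, debt_days = 0L,
    alive = TRUE, remittance = FALSE, ever_debt = FALSE,
    cash = 0, debt = 0, recon_principal = 0, recon_loan = 0)
  for (col in names(defaults)) {
    v <- if (col %in% names(vals)) vals[[col]] else defaults[[col]]
    assign(col, c(get(col, envir = H), v), envir = H)
  }
  st$planted <- rbind(st$planted, matrix(0L, 1, ncol(st$planted)))
  st$strategy <- rbind(st$strategy, matrix(0L, 1, ncol(st$strategy)))
  st$plant_day_abs <- rbind(st$plant_day_abs,
                            matrix(NA_integer_, 1, ncol(st$plant_day_abs)))
  id
}

add_animals <- function(st, species, sex, age, hh) {
  n <- length(species)
  if (n == 0L) return(invisible(integer(0)))
  A <- st$A
  ids <- st$next_aid - 1L + seq_len(n)
  st$next_aid <- st$next_aid + n
  A$id <- c(A$id, ids)
  A$hh <- c(A$hh, rep_len(as.integer(hh), n))
  A$age <- c(A$age, rep_len(as.integer(age), n))
  A$alive <- c(A$alive, rep(TRUE, n))
  A$species <- c(A$species, species)
  A$sex <- c(A$sex, rep_len(sex, n))
  invisible(ids)
}

## ---- accounts and the ledger -------------------------------------------------

# The finance-controller account a villager's flows are routed to:
# controller 0 means the household account, otherwise the controlling
# villager's personal account (their own id when self-managed).
account_of <- function(st, vid) {
  out <- st$V$controller[vid]
  hh_acc <- out == 0L
  out[hh_acc] <- -st$V$hh[vid[hh_acc]]
  out
}

account_cash <- function(st, acct) {
  ifelse(acct > 0, st$V$cash[acct], st$H$cash[-acct])
}

#' @keywords internal
credit <- function(st, acct, category, amount) {
  keep <- amount != 0 & !is.na(amount)
  acct <- acct[keep]; amount <- amount[keep]
  if (length(category) > 1L) category <- category[keep]
  if (!length(acct)) return(invisible(NULL))
  # aggregate per-account (an account can appear several times in one call)
  if (anyDuplicated(acct)) {
    agg <- rowsum(amount, acct)
    uacct <- as.integer(rownames(agg))
    amt <- as.numeric(agg)
  } else {
    uacct <- acct; amt <- amount
  }
  uv <- uacct > 0
  if (any(uv)) st$V$cash[uacct[uv]] <- st$V$cash[uacct[uv]] + amt[uv]
  if (any(!uv)) st$H$cash[-uacct[!uv]] <- st$H$cash[-uacct[!uv]] + amt[!uv]
  acc_add(st$ledger, list(
    day = rep(st$day, length(acct)), account = acct,
    category = rep(category, length.out = length(acct)), amount = amount))
  invisible(NULL)
}

log_event <- function(st, type, detail = "") {
  acc_add(st$events, list(day = st$day, type = type,
                          detail = as.character(detail)))
}

## ---- convenience views -------------------------------------------------------

living <- function(st) which(st$V$alive & st$V$present)
resident <- function(st) which(st$V$alive & st$V$present & !st$V$abroad)
live_households <- function(st) which(st$H$alive)

members_of <- function(st, hid) {
  which(st$V$alive & st$V$present & st$V$hh == hid)
}

hh_sizes <- function(st) {
  idx <- living(st)
  sz <- integer(length(st$H$id))
  if (length(idx)) {
    t <- table(st$V$hh[idx])
    sz[as.integer(names(t))] <- as.integer(t)
  }
  sz
}

adult_counts <- function(st) {
  idx <- living(st)
  ad <- integer(length(st$H$id))
  idx <- idx[st$V$age[idx] > st$params$adult_age_days]
  if (length(idx)) {
    t <- table(st$V$hh[idx])
    ad[as.integer(names(t))] <- as.integer(t)
  }
  ad
}
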