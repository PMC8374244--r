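# Life-course events: careers, death, marriage, birth, schedule
# initialisation.

test_that("career branch rates recover the printed probabilities", {
  st <- tiny_state()
  set.seed(10)
  ## +2 completers obtain salaried jobs a quarter of the time
  paths <- replicate(4000, villagesim:::draw_career_path(
    st, "M", "left_plus2", 19L * 365L)$career)
  p_sal <- mean(grepl("^salaried_[0-9]$", paths))
  expect_lt(abs(p_sal - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
})

test_that("education transitions fire only at the school-year boundary and ~50% enter +2", {
  set.seed(11)
  enter_plus2 <- 0L; n_completers <- 0L
  for (rep in 1:40) {
    st <- fresh_state(seed = rep)
    ## plant a cohort of school completers just below the threshold
    kids <- villagesim:::add_villagers(
      st, 10L, sex = "M", hh = 1L, age = st$params$school_end_days + 10L,
      education = "school", career = "student")
    ## a non-boundary day changes nothing
    st$day <- st$params$school_calendar_day - 2L   # year-day 99
    villagesim:::update_careers_daily(st)
    expect_true(all(st$V$education[kids] == "school"))
    ## the boundary day graduates the cohort
    st$day <- st$params$school_calendar_day - 1L   # year-day 100
    villagesim:::update_careers_daily(st)
    expect_true(all(st$V$education[kids] %in% c("plus2", "left_slc")))
    enter_plus2 <- enter_plus2 + sum(st$V$education[kids] == "plus2")
    n_completers <- n_completers + length(kids)
  }
  p <- enter_plus2 / n_completers
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n_completers))
})

test_that("death settles the estate, charges the funeral, and removes sole-member households", {
  st <- fresh_state(seed = 3)
  hid <- villagesim:::add_household(st, fields = 10L)
  v <- villagesim:::add_villagers(st, 1L, sex = "M", hh = hid,
                                  age = 70L * 365L,
                                  education = "left_none", career = "farm")
  st$H$referent[hid] <- v
  cash0 <- st$H$cash[hid]
  villagesim:::process_death(st, v)
  led <- villagesim:::acc_collect(st$ledger)
  fun <- led[led$account == -hid & led$category == "funeral"]
  expect_equal(fun$amount, -200000)
  expect_false(st$V$alive[v])
  expect_false(st$H$alive[hid])          # sole member: household dissolves
  expect_identical(st$H$fields[hid], 0L)
})

test_that("a widow's scheduled birth is kept only when due within nine months", {
  for (lead in c(150L, 400L)) {
    st <- tiny_state()
    husband <- 1L; wife <- 2L
    st$V$next_birth_day[wife] <- st$day + lead
    villagesim:::process_death(st, husband)
    expect_true(st$V$widowed[wife])
    if (lead <= 274L) expect_identical(st$V$next_birth_day[wife],
                                       st$day + lead)
    else expect_true(is.na(st$V$next_birth_day[wife]))
  }
})

test_that("marriage transfers follow the printed gift and dowry amounts", {
  ## resident groom with living parents: couple receives 100k + 100k
  st <- fresh_state(seed = 4)
  hid <- villagesim:::add_household(st, fields = 10L)
  dad <- villagesim:::add_villagers(st, 1L, sex = "M", hh = hid,
                                    age = 55L * 365L,
                                    education = "left_none", career = "farm")
  mum <- villagesim:::add_villagers(st, 1L, sex = "F", hh = hid,
                                    age = 52L * 365L,
                                    education = "left_none", career = "farm")
  st$V$partner[c(dad, mum)] <- c(mum, dad)
  groom <- villagesim:::add_villagers(st, 1L, sex = "M", hh = hid,
                                      age = 24L * 365L, father = dad,
                                      mother = mum,
                                      education = "left_slc", career = "farm")
  st$H$referent[hid] <- dad
  villagesim:::update_controllers(st)
  st$V$controller[groom] <- groom       # financially independent son
  n0 <- length(st$V$id)
  villagesim:::process_marriage(st, groom, st$ref)
  expect_identical(length(st$V$id), n0 + 1L)   # a wife was created
  wife <- st$V$partner[groom]
  expect_identical(st$V$hh[wife], hid)
  expect_gte(st$V$age[wife], 18L * 365L)
  led <- villagesim:::acc_collect(st$ledger)
  wed <- led[led$category == "wedding"]
  expect_equal(sum(wed$amount[wed$account == groom]), 200000)  # both gifts
  expect_equal(sum(wed$amount[wed$account == -hid]), -100000)  # groom's parents

  ## bride marrying out: her parents pay the dowry and she leaves
  st2 <- fresh_state(seed = 5)
  hid2 <- villagesim:::add_household(st2, fields = 10L)
  dad2 <- villagesim:::add_villagers(st2, 1L, sex = "M", hh = hid2,
                                     age = 50L * 365L,
                                     education = "left_none", career = "farm")
  bride <- villagesim:::add_villagers(st2, 1L, sex = "F", hh = hid2,
                                      age = 20L * 365L, father = dad2,
                                      education = "left_slc", career = "farm")
  st2$H$referent[hid2] <- dad2
  villagesim:::process_marriage(st2, bride, st2$ref)
  expect_false(st2$V$present[bride])
  led2 <- villagesim:::acc_collect(st2$ledger)
  expect_equal(led2[led2$category == "dowry"]$amount, -100000)

  ## groom with deceased parents: only the off-model bride-side gift arrives
  st3 <- tiny_state()
  groom3 <- villagesim:::add_villagers(st3, 1L, sex = "M", hh = 1L,
                                       age = 25L * 365L,
                                       education = "left_slc",
                                       career = "farm")
  villagesim:::process_marriage(st3, groom3, st3$ref)
  led3 <- villagesim:::acc_collect(st3$ledger)
  expect_equal(sum(led3[led3$category == "wedding"]$amount), 100000)
})

test_that("newborns draw a fair sex and schedule the next birth only below the desired count", {
  set.seed(12)
  st <- tiny_state()
  mother <- 2L
  st$V$desired_children[mother] <- 2L
  villagesim:::process_birth(st, mother)
  expect_false(is.na(st$V$next_birth_day[mother]))  # 1 of 2 born
  st$day <- st$V$next_birth_day[mother]
  villagesim:::process_birth(st, mother)
  expect_true(is.na(st$V$next_birth_day[mother]))   # desired count reached
  babies <- villagesim:::children_of(st, mother)
  expect_length(babies, 2L)
  ## every newborn's death day is strictly after its birth day
  birth_days <- st$V$death_day[babies] * 0 + c(0L, st$day)
  expect_true(all(st$V$death_day[babies] > birth_days))
  ## sex ratio over many births
  m <- 0L; n <- 3000L
  for (i in seq_len(n)) {
    stb <- st
    stb$V$desired_children[mother] <- 99L
    villagesim:::process_birth(stb, mother)
    m <- m + (stb$V$sex[length(stb$V$sex)] == "M")
  }
  expect_lt(abs(m / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("initial schedules respect ages, marriage constraints, and fertility cutoffs", {
  st <- fresh_state(seed = 21)
  V <- st$V
  idx <- villagesim:::living(st)
  ## education bands (I2)
  expect_true(all(V$education[idx][V$age[idx] < 2090] == "preschool"))
  expect_true(all(V$education[idx][V$age[idx] >= 2090 &
                                     V$age[idx] < 5740] == "school"))
  ## death always scheduled in the future
  expect_true(all(V$death_day[idx] > 0))
  ## married women were married before their eldest child was born
  wives <- idx[!is.na(V$partner[idx]) & V$sex[idx] == "F"]
  for (w in wives) {
    kids <- villagesim:::children_of(st, w)
    if (!length(kids)) next
    eldest_birth <- -max(V$age[kids])
    expect_lte(V$marriage_day[w], eldest_birth)
    ## and the husband's marriage day equals hers
    expect_identical(V$marriage_day[V$partner[w]], V$marriage_day[w])
  }
  ## long-childless married women desire no children
  childless <- 0L
  for (seed in 22:30) {
    st2 <- fresh_state(seed = seed)
    V2 <- st2$V
    idx2 <- villagesim:::living(st2)
    wives2 <- idx2[!is.na(V2$partner[idx2]) & V2$sex[idx2] == "F" &
                     V2$age[idx2] < 50 * 365]
    for (w in wives2) {
      years_married <- -V2$marriage_day[w] / 365
      n_kids <- length(villagesim:::children_of(st2, w))
      if (n_kids == 0L && years_married > 9.78) {
        childless <- childless + 1L
        expect_identical(V2$desired_children[w], 0L)
      }
    }
  }
})
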