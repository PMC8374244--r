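---
title: "The village model: structure, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The village model: structure, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(villagesim)
```

`villagesim` simulates a fourteen-household smallholder village in the
Nepalese Mid-Hills at a daily timestep over fifteen years (2015–2029).
This vignette explains the model's structure and assumptions, the
parameters that matter, what the synthetic-data machinery does and does
not emulate, and the choices made where the design was genuinely open.

## 1. Model structure

Eight kinds of entity exist: villagers, households, chickens, goats,
cattle, buffalo, fields and polytunnels. Villagers carry a pre-drawn
*destiny*: at creation (or at initialisation) each receives a scheduled
marriage day and a scheduled death day drawn from sex-specific schedule
distributions, and married women under fifty carry a desired lifetime
child count and the provisional day of their next birth. Daily processing
simply fires whatever falls due. Within a day the order is fixed:
villagers (ageing, career junctures, income, expenses, self-managed
finance checks, death, marriage, birth), then animals, then households
(crops, referent and controller maintenance, remittances, fission, herd
rebalancing, finance assessment), then polytunnels. Agents are iterated
in stable id order, and all randomness flows through named substreams
(`synthesis`, `demography`, `yields`, `labour`, `livestock`, `scenario`),
so one (configuration, seed) pair reproduces a run bit for bit and a
change in one sub-model's consumption of random numbers does not perturb
the others.

Two village-specific institutions organise the bookkeeping. The
*referent* is the youngest sibling-free adult male (failing that, the
youngest widowed adult female) and anchors kinship logic; it is a
modelling device, not a real village role. The *finance controller* is
the party that receives a villager's income and pays their expenses: the
household itself for most members, but sons of the referent who have
completed their education manage their own money and that of their wives
and children. Every rupee moved passes through `credit()`, which updates
the account and appends a ledger row, so cash balances provably equal the
signed ledger sums at all times — the test suite asserts this closure on
every run it makes.

## 2. Parameters

All defaults live in `default_parameters()` and are individually
overridable through `sim_config()`. The important groups:

* **Prices and wages (NPR)** — crop prices per kg, animal purchase and
  slaughter prices, salary scales (12,000–25,000/month in Nepal,
  10,000/month abroad), the 500/day labouring wage with 19% daily
  availability, and the 10,000/month pension and remittance.
* **Consumption** — the adult-female staple basket costs 61.776 NPR/day
  (9.776 staples + 52 other food), scaled by age-sex multipliers
  (0.37–1.29); 27 NPR/day other living costs; school/college fees of
  400/800 NPR/month; meat at 102 NPR per portion times the food
  multiplier, up to three portions a week, charged on Sundays.
* **Credit** — informal loans accrue 20%/year. The compounding convention
  is not stated in the sources, so the daily rate is defined as
  `(1.2)^(1/365) − 1`, which makes unpaid debt grow by exactly 20% over a
  365-day year. Earthquake reconstruction loans are interest-free and
  repaid in sixtieths, only while otherwise debt-free.
* **Festivals** — 23 festival days per year at 320 NPR per villager. The
  sources print both 320 (process description) and 200 (parameter table);
  320 is the default and 200 ships in the `"narrative"`-adjacent preset
  and as the sensitivity-analysis baseline, since the analysis groups
  explicitly carry their own C values. The identity of the 23 days is
  never given; a documented list spanning the major festivals of the
  Nepali year is the default, and only the count and cost affect
  dynamics.
* **Price conflicts** — chicken carcass 1,200 vs 1,500, goat 7,600 vs
  8,800, buffalo 28,000/42,000 vs 19,875/26,500 appear in the table and
  the prose respectively. The table values are the defaults (they are the
  sensitivity-analysis baseline); `default_parameters("narrative")`
  switches to the prose values. A bovine purchase price printed as 300 is
  treated as a typo for the tabled 3,000.

## 3. Demographic schedules

Marriage ages, death ages, first-birth delays and birth intervals are
piecewise-linear CDFs (`plcdf()`). Their published sources are curves
without printed knot values, so the default knots are qualitative,
configurable fixtures matching the cited shapes (survey marriage ages,
2015 WHO life-table survival, district birth-spacing data); every test
targets properties — monotonicity, constraint satisfaction, recovery of
the input CDF by sampling — rather than knot values. Constrained draws
(e.g. a death age that must exceed the current age, or a marriage age
that must precede the eldest child's birth) renormalise the CDF over the
viable region; a degenerate region falls back to the minimum viable value
and is flagged.

Desired-children distributions for the two fertility scenarios are built
by exponentially tilting a base preference shape concentrated on one and
two children (the stated preference of the next generation of parents)
until the mean equals the scenario rate, 1.6 or 2.1, within ±0.005. The
tilt is solved with `uniroot` to 1e−10.

Career flows beyond the five printed probabilities (50% enter +2, 25%
salaried after +2, 75/50/50% promotion chances) are configurable defaults
flagged as unverified: non-salaried male school-leavers go abroad with
probability 0.30 and into labouring with 0.40, females labour with 0.20,
otherwise farming; promotions are drawn after five years in a level;
salaried careers in Nepal retire to the pension at sixty. Education
stages change only on year-day 100, the start of the school year.

## 4. Population synthesis

Initialisation mirrors how the original village data could not be
published: all synthesis operations take a `SynthesisReferenceData`
object so real survey reference sets could be substituted, and the
package ships `generate_reference_fixture()`, a seeded synthetic stand-in
with the structure the synthesiser needs (archetype frequencies over the
seven observed household types, referent ages by type, spousal age gaps
filtered so no partner is under 18, conditional children counts,
eldest-child ages, non-integer birth intervals of roughly 1.6–4.4 years,
intergenerational gaps, and household net finances spanning debt and
savings). Archetype frequencies in the fixture are a configurable,
uniform-ish simplex — the published frequencies are graphical only.

Households are drawn by stochastic universal sampling (one uniform
pointer offset, fourteen equally spaced pointers), which guarantees each
archetype a count within one of its expectation. Members are generated
in a fixed order; referent ages get up to ±5% multiplicative noise (read
as uniform — the noise law is unstated) and all other drawn ages ±0.5
years additive uniform noise, so households never share birthdays.
Conditional tables are looked up at the nearest observed conditioning age.
Eldest-child draws that would imply birth before age ~16 of the mother
are clamped; birth intervals that point into the future become the
provisional next birth.

Land follows the printed regression with a five-ropani floor. The second
noise term is printed with a single argument (`N(0.4728)`); it is read as
zero-mean with that standard deviation, and this reading is flagged here
rather than silently assumed.

What the fixture does *not* emulate: the real correlation structure
between archetype frequency, age distributions and landholding in the
surveyed village. A green test therefore establishes that the synthesis
machinery satisfies its structural contracts (rosters match archetypes,
constraints hold, counts are exact), not that the synthetic village is
distributionally identical to the field site.

## 5. Agriculture and livestock

Yield multipliers use a scaled beta on [0, 1.25] — the sources fix only
the mode (1.0) and the tail mass, so the support is a configurable design
choice; the single free shape parameter is solved by `uniroot` to 1e−6 so
that `P(X ≤ 0.5) = 1/T`. Within a year, crops' multipliers are mutually
independent; ten years of history and one value per simulation year are
pre-drawn at initialisation.

Grain planning forecasts twelve-month needs of members and animals and
converts them to fields by per-grain independent ceiling division (the
footnote describing the original allocation is unavailable); if needs
exceed the non-paddy land, everything goes to grain by largest remainder
and the shortfall is logged. The smoothing constant for yield forecasts
is unspecified in the sources; the default is 0.3 and exposed. Harvest
days printed beyond 365 (cabbage 615, cauliflower 419) are normalised
modulo 365, and wheat, cabbage and cauliflower stand in the ground at
model start without re-charging their (pre-simulation) input costs. Oxen
hire (425 NPR/field for households without a male bovine) is charged at
both plantation and harvest, as both process descriptions state it.

Herd targets are stepped functions of the adult count. The published
step charts are graphical, so the tables in `ownership_steps()` are
documented fixtures constrained by the printed bovine caps (none under
5.5 ropani, then 1/2/3 by landholding band). Milk income is implemented
per lactating animal at the printed one- and two-member household rates;
larger households consume their milk (no income), which also makes the
blackout question moot for them. Cattle die at eighteen without a carcass
sale, so their resale value is held flat at the purchase price — the only
animal without printed slaughter endpoints. Polytunnel harvests are read
as "fortnightly from day 213", i.e. the first income arrives a fortnight
later, giving fourteen 4,140-NPR harvests through day 44 of the next
year.

## 6. Finances

The monthly assessment follows a strict priority: cover shortfalls
(cash-rich independent sons bail out the household first, richest first —
the ordering is unstated), accrue interest, then on the month's first day
repay debt up to the forecast minimum balance, pay the reconstruction
instalment if affordable, and finally choose the largest affordable
weekly meat portion count. The twelve-month forecast is deliberately
conservative: expected labour at the baseline rate, current milk/egg
rates, crop income at forecast multipliers, all scheduled outgoings, and
no windfalls (animal sales, gifts). Meat is smoothed to a daily
equivalent inside the forecast; in the simulation it is charged weekly,
so realised paths can dip a few hundred NPR below forecast paths — one
reason small first-year loans can still occur despite the initial
capitalisation, alongside labour-income randomness.

Initial cash makes each controller's first-year forecast non-negative
under two weekly meat portions (the test suite asserts this), after which
households additionally receive historical net finances resampled without
replacement and two households a monthly remittance. Independent sons
start with savings equal to years since leaving education times their
career's estimated annual net surplus (no formula is printed; this
definition is the package's).

`household_debt_days` and `households_ever_in_debt` count interest-bearing
debt only, not outstanding reconstruction loans — otherwise every
earthquake run would trivially spend its last thirteen years "in debt"
and the statistic would stop discriminating. Reconstruction balances are
reported separately inside `total_household_loans`.

## 7. Scenarios

The earthquake pathway fires once: on 25 April 2015 five percent of
livestock die unsold (independent Bernoulli per animal — the expectation
matches the stated share, the variance is a consequence), lone
individuals and two-adult households with a salaried member each leave
with probability one half (checked once, on the shock day), cash-crop
standard yields fall permanently to 85%, and crops whose
plantation-to-harvest interval overlaps 25 April–12 June harvest at a
further 70%. Off-farm labour stops for three months and then runs at
150% for twenty-four months. On 25 October 2016 households take
size-dependent interest-free reconstruction loans (300k/425k/550k/675k).
Emigrating households vanish entirely, so any salaried member's
remittance potential is not modelled. When the scenario is off the
operation consumes no state and no randomness, making counterfactual runs
exactly equal to runs in which it is never invoked.

## 8. Experiments

`cv_vs_runs()` reproduces the replicate-count analysis (coefficient of
variation of each summary statistic over the first *n* runs; 200 is the
recommended minimum). `oat_sensitivity()` varies the eleven thematic
parameter groups one at a time between their printed lower and upper
extremes, 200 replicates each by default (4,600 runs in all), and reports
percentage changes with two-sided Mann–Whitney p-values; the significance
threshold for reporting is α = 0.05, which the original shading does not
state. Replicate seeds follow a deterministic schedule
`f(scenario, i) = hash(code) XOR i` so sweeps reproduce byte-identically.
The test suite runs these procedures at reduced replicate counts and
shortened horizons to stay within its time budget; the directional check
on the day-to-day-expenses group uses paired seeds over a four-year
horizon, where the expense effect dominates the initial-capitalisation
artefact that short horizons exhibit.

## 9. Known limitations

Simulated kitchens never run out of food (harvests are sold and food
bought back at fixed prices); food prices are static; there is no
divorce, remarriage or polygamy; animal breeding chains are collapsed
into sell-newborns/buy-replacements; hired agricultural labour is absent;
and the unpublished survey reference sets are replaced by a synthetic
fixture, so distribution-level agreement with the original village
cannot be claimed — only structural and behavioural fidelity to the
documented processes, which is what the test suite checks.
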