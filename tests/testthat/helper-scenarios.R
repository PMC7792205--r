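# shared fixtures and independent oracles

one_outcome_scenario <- function(incidence = 0.03, risk_reduction = 0.40,
                                 unit_value = 89487, duration_years = 30,
                                 population = 1000,
                                 investment = 24433.80,
                                 discount_rate = 0.04,
                                 adjustments = impact_adjustments(
                                   0.05, 0.20, 0.25, 0.20
                                 ),
                                 ...) {
  sroi_scenario(
    population = population,
    outcomes = outcome_table("only", "infant", incidence, risk_reduction,
                             unit_value, duration_years),
    investment = investment,
    discount_rate = discount_rate,
    adjustments = adjustments,
    ...
  )
}

# brute-force year-by-year NPV of a drop-off-decayed stream; deliberately a
# plain loop, independent of the package's vectorized path
npv_brute <- function(annual, duration, drop_off, rate) {
  total <- 0
  value <- annual
  for (t in seq_len(duration)) {
    total <- total + value / (1 + rate)^t
    value <- value * (1 - drop_off)
  }
  total
}

# closed-form annuity present value for a constant stream
annuity_pv <- function(annual, duration, rate) {
  if (rate == 0) {
    return(annual * duration)
  }
  annual * (1 - (1 + rate)^(-duration)) / rate
}

expect_scenario_equal <- function(a, b) {
  expect_identical(a$population, b$population)
  expect_identical(a$investment, b$investment)
  expect_identical(a$discount_rate, b$discount_rate)
  expect_identical(a$breastfeeding_rate, b$breastfeeding_rate)
  expect_identical(a$apply_breastfeeding_rate, b$apply_breastfeeding_rate)
  expect_identical(a$total_benefit_override, b$total_benefit_override)
  expect_identical(unclass(a$adjustments), unclass(b$adjustments))
  expect_identical(as.data.frame(a$outcomes), as.data.frame(b$outcomes))
}
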