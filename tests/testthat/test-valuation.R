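test_that("annual benefit handles boundary inputs exactly", {
  adj0 <- impact_adjustments()
  # retention factor 1: 100 * 0.1 * 0.5 * 10 = 50
  oc <- outcome_table("x", "infant", 0.1, 0.5, 10, 1)
  expect_equal(annual_benefit(oc, 100, adj0)$annual_benefit, 50)

  # zero incidence yields zero value
  oc0 <- outcome_table("x", "infant", 0, 0.5, 10, 1)
  expect_equal(annual_benefit(oc0, 100, adj0)$annual_benefit, 0)

  # the optional cohort breastfeeding-rate multiplier scales linearly
  expect_equal(
    annual_benefit(oc, 100, adj0, breastfeeding_rate = 0.5)$annual_benefit, 25
  )
})

test_that("benefit streams decay geometrically from year 2", {
  st <- benefit_stream(100, 3, 0.2)
  expect_equal(st$value, c(100, 80, 64))
  expect_equal(st$year, 1:3)

  # zero drop-off gives a constant stream; year 1 is exact
  expect_equal(benefit_stream(7.25, 5, 0)$value, rep(7.25, 5))
  expect_identical(benefit_stream(612091.08, 30, 0.2)$value[1], 612091.08)

  # direct exponentiation oracle for the final year
  expect_equal(benefit_stream(612091.08, 30, 0.2)$value[30],
               612091.08 * 0.8^29)

  expect_error(benefit_stream(100, 0, 0.2), class = "sroikit_domain_error")
})

test_that("npv follows the end-of-year discounting convention", {
  expect_equal(npv(c(100, 80, 64), 0), 244)
  expect_equal(npv(c(104), 0.04), 100)
  expect_equal(npv(benefit_stream(100, 3, 0.2), 0),
               npv(c(100, 80, 64), 0))
  expect_error(npv(c(100), -0.01), class = "sroikit_domain_error")
})

test_that("npv of a constant stream matches the annuity closed form", {
  for (rate in c(0.01, 0.04, 0.1)) {
    for (dur in c(1, 2, 15, 30)) {
      st <- benefit_stream(1234.56, dur, 0)
      expect_equal(npv(st, rate), annuity_pv(1234.56, dur, rate),
                   tolerance = 1e-9)
    }
  }
})

test_that("sroi_ratio truncates the reported ratio toward zero", {
  r <- sroi_ratio(1375050, 24433.80)
  expect_equal(r$ratio_raw, (1375050 - 24433.80) / 24433.80)
  expect_identical(r$ratio_reported, 55L)

  expect_identical(sroi_ratio(100, 100)$ratio_reported, 0L)
  expect_equal(sroi_ratio(100, 100)$ratio_raw, 0)
  expect_identical(sroi_ratio(200, 100)$ratio_reported, 1L)
  expect_equal(sroi_ratio(200, 100)$ratio_raw, 1)
  expect_error(sroi_ratio(100, 0), class = "sroikit_domain_error")
})

test_that("payback period assumes uniform within-year accrual", {
  expect_equal(payback_months(100, 100), 12)
  expect_equal(payback_months(100, 200), 6)
  expect_equal(payback_months(24433.80, 1375050), 0.2132, tolerance = 1e-3)
  expect_error(payback_months(100, 0), class = "sroikit_domain_error")
})

test_that("simple and npv modes agree on a one-year undecayed scenario", {
  s <- one_outcome_scenario(duration_years = 1, discount_rate = 0,
                            adjustments = impact_adjustments())
  simple <- sroi_evaluate(s, "simple")
  disc <- sroi_evaluate(s, "npv")
  expect_equal(simple$benefit_basis, disc$benefit_basis)
  expect_equal(simple$ratio_raw, disc$ratio_raw)
})

test_that("npv-mode basis equals the sum of per-outcome NPVs", {
  fx <- calvary_fixture()
  res <- sroi_evaluate(fx, "npv")
  per <- outcome_npv(fx)
  expect_equal(res$benefit_basis, sum(per$npv), tolerance = 1e-12)

  # brute-force accumulation oracle per outcome
  ab <- annual_benefit(fx$outcomes, fx$population, fx$adjustments)
  oracle <- sum(mapply(
    npv_brute, ab$annual_benefit, fx$outcomes$duration_years,
    MoreArgs = list(drop_off = 0.20, rate = 0.04)
  ))
  expect_equal(res$benefit_basis, oracle, tolerance = 1e-9)
})

test_that("total annual benefit is a permutation-invariant sum of rows", {
  fx <- calvary_fixture()
  rows <- annual_benefit(fx$outcomes, fx$population, fx$adjustments)
  expect_equal(total_annual_benefit(fx), sum(rows$annual_benefit))

  shuffled <- fx
  shuffled$outcomes <- fx$outcomes[rev(seq_len(14)), ]
  expect_equal(total_annual_benefit(shuffled), total_annual_benefit(fx))

  # single outcome, no adjustments: the total is that outcome's value
  s1 <- one_outcome_scenario(adjustments = impact_adjustments())
  expect_equal(total_annual_benefit(s1),
               annual_benefit(s1$outcomes, s1$population,
                              s1$adjustments)$annual_benefit)
})

test_that("scaling unit values by k scales totals and net yield by k", {
  s <- generate_scenario(generator_spec(seed = 11))
  base <- sroi_evaluate(s)
  for (k in c(0.5, 2, 10)) {
    sk <- s
    sk$outcomes$unit_value <- s$outcomes$unit_value * k
    resk <- sroi_evaluate(sk)
    expect_equal(resk$total_annual_benefit, k * base$total_annual_benefit,
                 tolerance = 1e-12)
    expect_equal(resk$per_outcome$annual_benefit,
                 k * base$per_outcome$annual_benefit, tolerance = 1e-12)
    expect_equal(resk$npv_total, k * base$npv_total, tolerance = 1e-12)
  }
})

test_that("evaluate surfaces the override and the computed sum side by side", {
  fx <- calvary_fixture()
  res <- sroi_evaluate(fx)
  expect_equal(res$benefit_basis, 1375050)
  expect_equal(res$total_annual_benefit, sum(
    annual_benefit(fx$outcomes, fx$population, fx$adjustments)$annual_benefit
  ))
  expect_lt(abs(res$total_annual_benefit - 1321865.33), 0.5)
  expect_equal(benefit_basis(fx, "simple", use_override = FALSE),
               res$total_annual_benefit)

  g <- glance(res)
  expect_equal(g$ratio_reported, 55L)
  expect_equal(g$net_yield, 1375050 - 24433.80)
  td <- tidy(res)
  expect_equal(nrow(td), 14)
  expect_equal(td$annual_benefit_reported[td$name == "higher IQ"], 9)
})

test_that("evaluation refuses invalid scenarios", {
  s <- one_outcome_scenario(incidence = 2)
  expect_error(sroi_evaluate(s), class = "sroikit_validation_error")
})

test_that("autoplot renders the per-outcome benefit chart", {
  p <- ggplot2::ggplot_build(autoplot(sroi_evaluate(calvary_fixture())))
  expect_equal(nrow(p$data[[1]]), 14)
})
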