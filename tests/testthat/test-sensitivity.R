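test_that("perturbing an adjustment rescales the override by the retention factor ratio", {
  fx <- calvary_fixture()
  p <- perturb(fx, perturbation("adjustments.attribution", 0.50))
  expect_equal(p$adjustments$attribution, 0.50)
  expect_equal(p$total_benefit_override, 1375050 * (1 - 0.50) / (1 - 0.25))
  # base scenario untouched
  expect_equal(fx$adjustments$attribution, 0.25)
  expect_equal(fx$total_benefit_override, 1375050)
})

test_that("a global benefit multiplier rescales values and override together", {
  fx <- calvary_fixture()
  half <- perturb(fx, perturbation("benefit_multiplier", 0.5))
  expect_equal(half$total_benefit_override, 687525)
  expect_equal(half$outcomes$unit_value, fx$outcomes$unit_value / 2)
  expect_equal(half$outcomes$printed_value, fx$outcomes$printed_value / 2)
})

test_that("perturbing one outcome's risk reduction shifts the override by its row value", {
  fx <- calvary_fixture()
  p <- perturb(fx, perturbation("outcome:obesity:risk_reduction", 0.22))
  expect_equal(p$total_benefit_override,
               1375050 + 276832 * (0.22 / 0.26 - 1))
  expect_equal(p$outcomes$risk_reduction[p$outcomes$name == "obesity"], 0.22)
  # rows without a printed annotation fall back to the computed value
  s <- one_outcome_scenario(incidence = 0.1, risk_reduction = 0.5,
                            unit_value = 100, duration_years = 1,
                            adjustments = impact_adjustments(),
                            total_benefit_override = 5000)
  p2 <- perturb(s, perturbation("outcome:only:risk_reduction", 0.25))
  expect_equal(p2$total_benefit_override, 5000 + 5000 * (0.25 / 0.5 - 1))
})

test_that("unknown parameter paths and invalid new values are rejected", {
  fx <- calvary_fixture()
  expect_error(perturb(fx, perturbation("adjustments.nonsense", 0.1)),
               class = "sroikit_domain_error")
  expect_error(perturb(fx, perturbation("outcome:unicorn:incidence", 0.1)),
               class = "sroikit_domain_error")
  expect_error(perturb(fx, perturbation("adjustments.deadweight", 1.2)),
               class = "sroikit_validation_error")
})

test_that("the one-way table evaluates each row independently in input order", {
  fx <- calvary_fixture()
  ps <- list(
    perturbation("adjustments.displacement", 0),
    perturbation("benefit_multiplier", 0.5)
  )
  rows <- one_way_table(fx, ps)
  expect_equal(rows$target,
               c("adjustments.displacement", "benefit_multiplier"))
  expect_equal(rows$ratio_reported, c(69L, 27L))
  expect_equal(rows$base_value, c(0.20, 1))
  expect_equal(rows$delta_vs_base,
               rows$ratio_raw - sroi_evaluate(fx)$ratio_raw)
  # base preserved
  expect_equal(fx$adjustments$displacement, 0.20)

  expect_equal(nrow(one_way_table(fx, list())), 0)
})

test_that("drop-off and discount-rate rows are evaluated on discounted streams", {
  fx <- calvary_fixture()
  rows <- one_way_table(fx, list(
    perturbation("adjustments.drop_off", 0.5),
    perturbation("discount_rate", 0.06),
    perturbation("adjustments.deadweight", 0.5)
  ))
  expect_equal(rows$mode, c("npv", "npv", "simple"))
  # deeper drop-off and a higher discount rate both shrink the npv-mode ratio
  base_npv <- sroi_evaluate(fx, "npv")$ratio_raw
  expect_lt(rows$ratio_raw[1], base_npv)
  expect_lt(rows$ratio_raw[2], base_npv)
  expect_equal(rows$delta_vs_base[1], rows$ratio_raw[1] - base_npv)
})

test_that("tornado ranking sorts by absolute impact with stable ties", {
  rows <- tibble::tibble(
    target = c("a", "b", "c"), label = c("a", "b", "c"),
    base_value = 0, new_value = 1, mode = "simple",
    ratio_raw = 0, ratio_reported = 0L,
    delta_vs_base = c(2, -5, 1)
  )
  ranked <- tornado_rank(rows)
  expect_equal(ranked$delta_vs_base, c(-5, 2, 1))
  expect_equal(tornado_rank(rows[1, ])$target, "a")

  # on the case study, the global value rows dominate the retention
  # adjustment rows
  fx <- calvary_fixture()
  full <- tornado_rank(one_way_table(fx, calvary_perturbations()))
  mult_pos <- which(full$target == "benefit_multiplier")
  adj_pos <- which(full$target %in% c(
    "adjustments.attribution", "adjustments.deadweight",
    "adjustments.displacement"
  ))
  expect_true(max(mult_pos) < min(adj_pos))
})

test_that("the adjustment rescaling identity holds exactly in simple mode", {
  fx <- calvary_fixture()
  basis <- fx$total_benefit_override
  inv <- fx$investment
  cases <- list(
    list(target = "adjustments.attribution", old = 0.25, new = 0.50),
    list(target = "adjustments.deadweight", old = 0.05, new = 0.50),
    list(target = "adjustments.displacement", old = 0.20, new = 0.00)
  )
  rows <- one_way_table(
    fx, purrr::map(cases, ~ perturbation(.x$target, .x$new))
  )
  for (i in seq_along(cases)) {
    factor <- (1 - cases[[i]]$new) / (1 - cases[[i]]$old)
    expected_raw <- (basis * factor - inv) / inv
    expect_equal(rows$ratio_raw[i], expected_raw, tolerance = 1e-12)
    expect_identical(rows$ratio_reported[i], as.integer(trunc(expected_raw)))
  }
})

test_that("re-running evaluate after one adjustment change equals rescaling the basis", {
  for (seed in c(3, 4, 5)) {
    s <- generate_scenario(generator_spec(seed = seed, n_outcomes = 6))
    base <- sroi_evaluate(s)
    for (f in c("deadweight", "displacement", "attribution")) {
      old <- s$adjustments[[f]]
      new <- old / 2 + 0.1
      res <- sroi_evaluate(perturb(s, perturbation(
        paste0("adjustments.", f), new
      )))
      scaled_basis <- base$benefit_basis * (1 - new) / (1 - old)
      expect_equal(res$benefit_basis, scaled_basis,
                   tolerance = 1e-9)
    }
  }
})

test_that("monte carlo analysis is seed-reproducible", {
  fx <- calvary_fixture()
  specs <- list(
    list(target = "benefit_multiplier", dist = "uniform",
         min = 0.5, max = 2),
    list(target = "adjustments.attribution", dist = "uniform",
         min = 0.1, max = 0.5)
  )
  a <- monte_carlo_psa(fx, specs, n = 200, seed = 42)
  b <- monte_carlo_psa(fx, specs, n = 200, seed = 42)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)
  c <- monte_carlo_psa(fx, specs, n = 200, seed = 43)
  expect_false(identical(a$summary$mean, c$summary$mean))
})

test_that("degenerate point distributions collapse to the deterministic ratio", {
  fx <- calvary_fixture()
  det <- sroi_evaluate(fx, use_override = FALSE)$ratio_raw
  out <- monte_carlo_psa(fx, list(
    list(target = "benefit_multiplier", dist = "point", value = 1)
  ), n = 50, seed = 1)
  expect_equal(out$summary$mean, det)
  expect_equal(out$summary$sd, 0)
  expect_equal(out$summary$prob_ratio_above_1, 1)
})

test_that("uniform unit-value noise leaves the mean ratio near the deterministic value", {
  fx <- calvary_fixture()
  det <- sroi_evaluate(fx, use_override = FALSE)$ratio_raw
  specs <- purrr::map(fx$outcomes$name, function(nm) {
    uv <- fx$outcomes$unit_value[fx$outcomes$name == nm]
    list(target = paste0("outcome:", nm, ":unit_value"),
         dist = "uniform", min = 0.9 * uv, max = 1.1 * uv)
  })
  out <- monte_carlo_psa(fx, specs, n = 4000, seed = 7)
  expect_lt(abs(out$summary$mean - det) / det, 0.01)
  expect_gt(out$summary$sd, 0)
})

test_that("invalid distribution bounds are domain errors", {
  fx <- calvary_fixture()
  expect_error(monte_carlo_psa(fx, list(
    list(target = "adjustments.deadweight", dist = "uniform",
         min = -0.2, max = 0.5)
  ), n = 10, seed = 1), class = "sroikit_domain_error")
  expect_error(monte_carlo_psa(fx, list(
    list(target = "benefit_multiplier", dist = "lognormal", mu = 0)
  ), n = 10, seed = 1), class = "sroikit_domain_error")
  expect_error(monte_carlo_psa(fx, list(), n = 0, seed = 1),
               class = "sroikit_domain_error")
})
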