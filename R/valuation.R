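#' Annual benefit value of each outcome
#'
#' The valuation model prices each outcome line as
#' \deqn{population \times incidence \times risk\_reduction \times unit\_value
#'   \times (1-deadweight)(1-displacement)(1-attribution)}
#' i.e. the number of cases averted in one annual cohort, priced at the
#' financial proxy, with the SROI impact adjustments subtracted
#' multiplicatively. Values are returned at full precision; reporting rounds
#' to the nearest whole AUD.
#'
#' @param outcomes An outcome tibble (see [outcome_table()]); a single-row
#'   tibble values one outcome.
#' @param population Beneficiary units per year.
#' @param adjustments An [impact_adjustments()] object (`drop_off` plays no
#'   role in the annual value).
#' @param breastfeeding_rate Optional extra multiplier in `[0, 1]`; defaults
#'   to 1 (not applied).
#'
#' @return A tibble with columns `name`, `beneficiary`, `annual_benefit`.
#' @export
#' @examples
#' fx <- calvary_fixture()
#' annual_benefit(fx$outcomes, fx$population, fx$adjustments)
annual_benefit <- function(outcomes, population, adjustments,
                           breastfeeding_rate = 1) {
  ret <- retention_factor(adjustments)
  tibble::tibble(
    name = outcomes$name,
    beneficiary = outcomes$beneficiary,
    annual_benefit = population * breastfeeding_rate * outcomes$incidence *
      outcomes$risk_reduction * outcomes$unit_value * ret
  )
}

#' Drop-off-decayed benefit stream
#'
#' Year 1 pays the full annual benefit; each later year decays geometrically
#' by the drop-off fraction: `value_t = annual * (1 - drop_off)^(t - 1)`.
#'
#' @param annual Annual benefit value (AUD) in year 1.
#' @param duration_years Number of years the benefit persists (`>= 1`).
#' @param drop_off Annual decay fraction in `[0, 1)`.
#'
#' @return A tibble with columns `year` (1..duration) and `value`.
#' @export
#' @examples
#' benefit_stream(100, 3, 0.2)
benefit_stream <- function(annual, duration_years, drop_off = 0) {
  if (length(duration_years) != 1 || is.na(duration_years) ||
      duration_years < 1) {
    rlang::abort("duration_years must be a positive integer",
                 class = "sroikit_domain_error")
  }
  duration_years <- as.integer(duration_years)
  tibble::tibble(
    year = seq_len(duration_years),
    value = annual * (1 - drop_off)^(seq_len(duration_years) - 1)
  )
}

#' Net present value of a benefit stream
#'
#' Discounts each year's value at the end of the period:
#' `NPV = sum_t value_t / (1 + rate)^t`, t = 1..duration.
#'
#' @param stream A tibble from [benefit_stream()] (columns `year`, `value`)
#'   or a plain numeric vector of yearly values taken as years 1, 2, ...
#' @param discount_rate Annual discount rate, `>= 0`.
#'
#' @return A single numeric (AUD).
#' @export
#' @examples
#' npv(benefit_stream(100, 3, 0.2), 0.04)
npv <- function(stream, discount_rate) {
  if (is.data.frame(stream)) {
    years <- stream$year
    values <- stream$value
  } else {
    values <- as.numeric(stream)
    years <- seq_along(values)
  }
  if (is.na(discount_rate) || discount_rate < 0) {
    rlang::abort("discount_rate must be non-negative",
                 class = "sroikit_domain_error")
  }
  sum(values / (1 + discount_rate)^years)
}

#' Computed total annual benefit of a scenario
#'
#' The sum of [annual_benefit()] over all outcomes. When the scenario has a
#' `total_benefit_override`, this computed sum stays inspectable here while
#' [benefit_basis()] exposes the override used for ratio calculations.
#'
#' @param s A validated [sroi_scenario()].
#' @return A single numeric (AUD per year).
#' @export
total_annual_benefit <- function(s) {
  sum(annual_benefit(s$outcomes, s$population, s$adjustments,
                     breastfeeding_rate = effective_bf_rate(s))$annual_benefit)
}

#' Benefit basis used in ratio calculations
#'
#' In `simple` mode the basis is the annual benefit total — the scenario's
#' `total_benefit_override` when present, otherwise the computed sum. In
#' `npv` mode the basis is the sum over outcomes of the net present value of
#' each outcome's drop-off-decayed stream at the scenario discount rate; the
#' override is an annual-total concept and does not apply in `npv` mode.
#'
#' @param s A validated [sroi_scenario()].
#' @param mode `"simple"` or `"npv"`.
#' @param use_override Logical; set `FALSE` to force the computed sum even
#'   when an override is present.
#' @return A single numeric (AUD).
#' @export
benefit_basis <- function(s, mode = c("simple", "npv"), use_override = TRUE) {
  mode <- match.arg(mode)
  if (mode == "simple") {
    if (use_override && !is.null(s$total_benefit_override)) {
      s$total_benefit_override
    } else {
      total_annual_benefit(s)
    }
  } else {
    sum(outcome_npv(s)$npv)
  }
}

#' Per-outcome net present values
#'
#' Builds each outcome's benefit stream over its own duration with the
#' scenario drop-off and discounts it at the scenario rate.
#'
#' @param s A validated [sroi_scenario()].
#' @return A tibble with columns `name`, `annual_benefit`, `duration_years`,
#'   `npv`.
#' @export
outcome_npv <- function(s) {
  ab <- annual_benefit(s$outcomes, s$population, s$adjustments,
                       breastfeeding_rate = effective_bf_rate(s))
  npvs <- purrr::map2_dbl(
    ab$annual_benefit, s$outcomes$duration_years,
    function(a, d) npv(benefit_stream(a, d, s$adjustments$drop_off),
                       s$discount_rate)
  )
  tibble::tibble(
    name = ab$name,
    annual_benefit = ab$annual_benefit,
    duration_years = s$outcomes$duration_years,
    npv = npvs
  )
}

#' SROI ratio from a benefit basis and an investment
#'
#' `ratio_raw = (benefit_basis - investment) / investment`; the reported
#' ratio is the raw ratio truncated toward zero (the "AU$ N : 1" headline
#' convention).
#'
#' @param benefit_basis Monetary benefit basis (AUD).
#' @param investment Annual investment (AUD), strictly positive.
#' @return A list with `ratio_raw` (numeric) and `ratio_reported` (integer).
#' @export
#' @examples
#' sroi_ratio(1375050, 24433.80)
sroi_ratio <- function(benefit_basis, investment) {
  if (is.na(investment) || investment <= 0) {
    rlang::abort("investment must be strictly positive",
                 class = "sroikit_domain_error")
  }
  raw <- (benefit_basis - investment) / investment
  list(ratio_raw = raw, ratio_reported = as.integer(trunc(raw)))
}

#' Payback period in months
#'
#' Months until cumulative benefits equal the investment, under uniform
#' within-year accrual: `12 * investment / total_annual_benefit`.
#'
#' @param investment Annual investment (AUD).
#' @param total_annual_benefit Annual benefit total (AUD), strictly positive.
#' @return A single numeric (months).
#' @export
payback_months <- function(investment, total_annual_benefit) {
  if (is.na(total_annual_benefit) || total_annual_benefit <= 0) {
    rlang::abort("total_annual_benefit must be strictly positive",
                 class = "sroikit_domain_error")
  }
  12 * investment / total_annual_benefit
}

#' Evaluate a scenario
#'
#' Runs the full valuation: per-outcome annual benefits, the benefit basis
#' for the declared mode, the SROI ratio (raw and reported), net yield, and
#' payback period. Mode `simple` uses the annual benefit total (override if
#' present) as the ratio basis; mode `npv` uses the sum of per-outcome net
#' present values of the drop-off-decayed streams.
#'
#' @param s A [sroi_scenario()]; validated before evaluation.
#' @param mode `"simple"` or `"npv"`.
#' @param use_override Logical; set `FALSE` to ignore a
#'   `total_benefit_override`.
#' @return An object of class `sroi_result`. Access tidily with [tidy()]
#'   (per-outcome table) and [glance()] (one-row summary).
#' @export
#' @examples
#' res <- sroi_evaluate(calvary_fixture())
#' glance(res)
sroi_evaluate <- function(s, mode = c("simple", "npv"), use_override = TRUE) {
  mode <- match.arg(mode)
  stop_if_invalid(s)

  per <- outcome_npv(s)
  computed_sum <- sum(per$annual_benefit)
  basis <- benefit_basis(s, mode, use_override = use_override)
  annual_basis <- if (use_override) {
    s$total_benefit_override %||% computed_sum
  } else {
    computed_sum
  }
  ratio <- sroi_ratio(basis, s$investment)

  structure(
    list(
      mode = mode,
      per_outcome = tibble::tibble(
        name = per$name,
        beneficiary = s$outcomes$beneficiary,
        annual_benefit = per$annual_benefit,
        printed_value = s$outcomes$printed_value,
        duration_years = per$duration_years,
        npv = per$npv
      ),
      total_annual_benefit = computed_sum,
      npv_total = sum(per$npv),
      benefit_basis = basis,
      investment = s$investment,
      ratio_raw = ratio$ratio_raw,
      ratio_reported = ratio$ratio_reported,
      net_yield = basis - s$investment,
      payback_months = payback_months(s$investment, annual_basis)
    ),
    class = "sroi_result"
  )
}

#' @export
print.sroi_result <- function(x, ...) {
  cat("<sroi_result> mode:", x$mode, "\n")
  cat("  benefit basis:       AUD", fmt_money(x$benefit_basis, 2), "\n")
  cat("  computed annual sum: AUD", fmt_money(x$total_annual_benefit, 2), "\n")
  cat("  investment:          AUD", fmt_money(x$investment, 2), "\n")
  cat(sprintf("  SROI ratio:          %.2f (reported %d:1)\n",
              x$ratio_raw, x$ratio_reported))
  cat("  net yield:           AUD", fmt_money(x$net_yield, 2), "\n")
  cat(sprintf("  payback:             %.2f months\n", x$payback_months))
  invisible(x)
}

#' Tidy the per-outcome valuation of an SROI result
#'
#' @param x An `sroi_result` from [sroi_evaluate()].
#' @param ... Unused.
#' @return A tibble with one row per outcome: `name`, `beneficiary`,
#'   `annual_benefit` (full precision), `annual_benefit_reported` (nearest
#'   AUD), `printed_value`, `duration_years`, `npv`.
#' @method tidy sroi_result
#' @export
tidy.sroi_result <- function(x, ...) {
  dplyr::mutate(
    x$per_outcome,
    annual_benefit_reported = round(.data$annual_benefit),
    .after = "annual_benefit"
  )
}

#' One-row summary of an SROI result
#'
#' @param x An `sroi_result` from [sroi_evaluate()].
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `total_annual_benefit`, `npv_total`,
#'   `benefit_basis`, `investment`, `ratio_raw`, `ratio_reported`,
#'   `net_yield`, `payback_months`.
#' @method glance sroi_result
#' @export
glance.sroi_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    total_annual_benefit = x$total_annual_benefit,
    npv_total = x$npv_total,
    benefit_basis = x$benefit_basis,
    investment = x$investment,
    ratio_raw = x$ratio_raw,
    ratio_reported = x$ratio_reported,
    net_yield = x$net_yield,
    payback_months = x$payback_months
  )
}

#' Bar chart of per-outcome annual benefits
#'
#' @param object An `sroi_result` from [sroi_evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sroi_result
#' @export
autoplot.sroi_result <- function(object, ...) {
  df <- tidy(object)
  df$name <- stats::reorder(df$name, df$annual_benefit)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$annual_benefit, y = .data$name, fill = .data$beneficiary
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Annual benefit (AUD)", y = NULL, fill = "Beneficiary",
      title = "Annual benefit by outcome"
    ) +
    ggplot2::theme_minimal()
}
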