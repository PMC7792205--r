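#' Impact adjustments applied to gross outcome values
#'
#' In SROI accounting the gross value of an outcome is reduced by the fraction
#' that would have occurred anyway (deadweight), the fraction that merely
#' displaced other beneficial activity (displacement) and the fraction caused
#' by other actors (attribution). Drop-off is the annual rate at which the
#' benefit decays in years after the first.
#'
#' @param deadweight Fraction in `[0, 1)` of the outcome that would have
#'   happened without the program.
#' @param displacement Fraction in `[0, 1)` of the outcome that displaced
#'   other activity.
#' @param attribution Fraction in `[0, 1)` of the outcome attributable to
#'   other interventions.
#' @param drop_off Annual decay fraction in `[0, 1)` applied from year 2
#'   onward of a benefit stream.
#'
#' @return An object of class `impact_adjustments` (a named list).
#' @export
#' @examples
#' impact_adjustments(deadweight = 0.05, displacement = 0.2, attribution = 0.25)
impact_adjustments <- function(deadweight = 0, displacement = 0,
                               attribution = 0, drop_off = 0) {
  adj <- list(
    deadweight = as.numeric(deadweight),
    displacement = as.numeric(displacement),
    attribution = as.numeric(attribution),
    drop_off = as.numeric(drop_off)
  )
  structure(adj, class = "impact_adjustments")
}

#' Combined retention factor
#'
#' The fraction of gross outcome value retained after subtracting deadweight,
#' displacement and attribution:
#' `(1 - deadweight) * (1 - displacement) * (1 - attribution)`.
#'
#' @param adjustments An [impact_adjustments()] object.
#' @return A single numeric in `(0, 1]` for valid adjustments.
#' @export
retention_factor <- function(adjustments) {
  (1 - adjustments$deadweight) *
    (1 - adjustments$displacement) *
    (1 - adjustments$attribution)
}

#' Build an outcome table
#'
#' One row per preventable-condition benefit line: who benefits, how common
#' the condition is, what fraction of cases the program averts, the financial
#' proxy per case, and how many years the benefit persists. The optional
#' `printed_value` column carries an externally reported annual value for the
#' row (used when reproducing a published analysis whose row arithmetic cannot
#' be reconstructed); it never replaces the engine's computed value, which is
#' always reported alongside.
#'
#' @param name Short outcome label.
#' @param beneficiary `"infant"` or `"mother"`.
#' @param incidence Condition prevalence/incidence in the reference
#'   population, fraction in `[0, 1]`.
#' @param risk_reduction Relative risk reduction attributable to the program,
#'   fraction in `[0, 1]`.
#' @param unit_value Financial proxy in AUD per affected case (or per
#'   person-year for earnings proxies); non-negative.
#' @param duration_years Positive integer, years the benefit stream persists.
#' @param printed_value Optional externally reported annual value (AUD).
#'
#' @return A tibble with one row per outcome.
#' @export
#' @examples
#' outcome_table(
#'   name = "diarrhea", beneficiary = "infant",
#'   incidence = 1, risk_reduction = 0.26, unit_value = 20.27,
#'   duration_years = 3
#' )
outcome_table <- function(name, beneficiary, incidence, risk_reduction,
                          unit_value, duration_years,
                          printed_value = NA_real_) {
  tibble::tibble(
    name = as.character(name),
    beneficiary = as.character(beneficiary),
    incidence = as.numeric(incidence),
    risk_reduction = as.numeric(risk_reduction),
    unit_value = as.numeric(unit_value),
    duration_years = as.integer(duration_years),
    printed_value = as.numeric(printed_value)
  )
}

#' Assemble an SROI scenario
#'
#' A scenario bundles everything needed to value a program for one annual
#' cohort: the cohort size, the outcome table, the annual investment, the
#' discount rate and the impact adjustments.
#'
#' @param population Count of beneficiary units (e.g. mother-infant dyads)
#'   per year; at least 1.
#' @param outcomes A tibble as built by [outcome_table()]; at least one row.
#' @param investment Annual monetary investment in AUD; strictly positive.
#' @param discount_rate Annual discount rate as a fraction, `>= 0`.
#' @param adjustments An [impact_adjustments()] object.
#' @param breastfeeding_rate Descriptive cohort metadata, fraction in
#'   `[0, 1]`; multiplied into valuations only when
#'   `apply_breastfeeding_rate = TRUE`.
#' @param total_benefit_override Optional total annual benefit (AUD) that
#'   replaces the computed outcome sum as the basis of ratio calculations
#'   (used to reproduce a published headline total that differs from its own
#'   row sum). The computed sum remains inspectable.
#' @param apply_breastfeeding_rate Logical; scale valuations by
#'   `breastfeeding_rate`.
#'
#' @return An object of class `sroi_scenario`.
#' @seealso [validate_scenario()], [sroi_evaluate()], [calvary_fixture()]
#' @export
sroi_scenario <- function(population, outcomes, investment,
                          discount_rate = 0.04,
                          adjustments = impact_adjustments(),
                          breastfeeding_rate = NA_real_,
                          total_benefit_override = NULL,
                          apply_breastfeeding_rate = FALSE) {
  outcomes <- tibble::as_tibble(outcomes)
  if (!"printed_value" %in% names(outcomes)) {
    outcomes$printed_value <- NA_real_
  }
  outcomes$duration_years <- as.integer(outcomes$duration_years)
  s <- structure(
    list(
      population = as.numeric(population),
      breastfeeding_rate = as.numeric(breastfeeding_rate),
      outcomes = outcomes,
      investment = as.numeric(investment),
      discount_rate = as.numeric(discount_rate),
      adjustments = adjustments,
      total_benefit_override = if (is.null(total_benefit_override)) {
        NULL
      } else {
        as.numeric(total_benefit_override)
      },
      apply_breastfeeding_rate = isTRUE(apply_breastfeeding_rate)
    ),
    class = "sroi_scenario"
  )
  s
}

#' @export
print.sroi_scenario <- function(x, ...) {
  cat("<sroi_scenario>\n")
  cat("  population:   ", format(x$population, big.mark = ","), "\n", sep = "")
  cat("  outcomes:     ", nrow(x$outcomes), "\n", sep = "")
  cat("  investment:   AUD ", format(x$investment, big.mark = ","), "\n", sep = "")
  cat("  discount rate:", format(x$discount_rate), "\n")
  adj <- x$adjustments
  cat(sprintf(
    "  adjustments:  deadweight %.2f, displacement %.2f, attribution %.2f, drop-off %.2f\n",
    adj$deadweight, adj$displacement, adj$attribution, adj$drop_off
  ))
  if (!is.null(x$total_benefit_override)) {
    cat("  total benefit override: AUD ",
        format(x$total_benefit_override, big.mark = ","), "\n", sep = "")
  }
  invisible(x)
}

fraction_violation <- function(value, field, lo = 0, hi = 1,
                               hi_open = FALSE) {
  bad <- is.na(value) | value < lo | (if (hi_open) value >= hi else value > hi)
  if (any(bad)) {
    msg <- if (hi_open) {
      sprintf("must be a fraction in [%g, %g)", lo, hi)
    } else {
      sprintf("must be a fraction in [%g, %g]", lo, hi)
    }
    tibble::tibble(field = field[bad], message = msg)
  } else {
    tibble::tibble(field = character(), message = character())
  }
}

#' Validate a scenario against the domain invariants
#'
#' Checks every structural invariant of the scenario: fractions in range,
#' non-negative money, positive durations, positive investment, at least one
#' outcome, and a combined retention factor in `(0, 1]`. Violations are
#' returned as data, never raised; the input is never mutated.
#'
#' @param s An [sroi_scenario()].
#' @return An object of class `sroi_validation`: a list with `ok` (logical)
#'   and `violations` (tibble of `field`, `message`). `ok` is `TRUE` iff
#'   `violations` is empty.
#' @export
#' @examples
#' validate_scenario(calvary_fixture())$ok
validate_scenario <- function(s) {
  v <- list()
  oc <- s$outcomes

  if (nrow(oc) < 1) {
    v[[length(v) + 1]] <- tibble::tibble(
      field = "outcomes", message = "at least one outcome is required"
    )
  }
  if (is.na(s$population) || s$population < 1) {
    v[[length(v) + 1]] <- tibble::tibble(
      field = "population", message = "must be at least 1"
    )
  }
  if (is.na(s$investment) || s$investment <= 0) {
    v[[length(v) + 1]] <- tibble::tibble(
      field = "investment", message = "must be strictly positive"
    )
  }
  if (is.na(s$discount_rate) || s$discount_rate < 0) {
    v[[length(v) + 1]] <- tibble::tibble(
      field = "discount_rate", message = "must be non-negative"
    )
  }
  if (!is.na(s$breastfeeding_rate)) {
    v[[length(v) + 1]] <- fraction_violation(
      s$breastfeeding_rate, "breastfeeding_rate"
    )
  }

  if (nrow(oc) > 0) {
    v[[length(v) + 1]] <- fraction_violation(
      oc$incidence, paste0("outcomes[", oc$name, "].incidence")
    )
    v[[length(v) + 1]] <- fraction_violation(
      oc$risk_reduction, paste0("outcomes[", oc$name, "].risk_reduction")
    )
    bad_uv <- is.na(oc$unit_value) | oc$unit_value < 0
    if (any(bad_uv)) {
      v[[length(v) + 1]] <- tibble::tibble(
        field = paste0("outcomes[", oc$name[bad_uv], "].unit_value"),
        message = "must be non-negative"
      )
    }
    bad_dur <- is.na(oc$duration_years) | oc$duration_years < 1
    if (any(bad_dur)) {
      v[[length(v) + 1]] <- tibble::tibble(
        field = paste0("outcomes[", oc$name[bad_dur], "].duration_years"),
        message = "must be a positive integer"
      )
    }
    bad_ben <- !oc$beneficiary %in% c("infant", "mother")
    if (any(bad_ben)) {
      v[[length(v) + 1]] <- tibble::tibble(
        field = paste0("outcomes[", oc$name[bad_ben], "].beneficiary"),
        message = "must be 'infant' or 'mother'"
      )
    }
  }

  adj <- s$adjustments
  for (f in c("deadweight", "displacement", "attribution", "drop_off")) {
    v[[length(v) + 1]] <- fraction_violation(
      adj[[f]], paste0("adjustments.", f), hi = 1, hi_open = TRUE
    )
  }
  ret <- retention_factor(adj)
  if (!is.na(ret) && (ret <= 0 || ret > 1)) {
    v[[length(v) + 1]] <- tibble::tibble(
      field = "adjustments",
      message = "combined retention factor must lie in (0, 1]"
    )
  }

  violations <- dplyr::bind_rows(v)
  structure(
    list(ok = nrow(violations) == 0, violations = violations),
    class = "sroi_validation"
  )
}

#' @export
print.sroi_validation <- function(x, ...) {
  if (x$ok) {
    cat("<sroi_validation> ok: no violations\n")
  } else {
    cat("<sroi_validation>", nrow(x$violations), "violation(s):\n")
    print(x$violations)
  }
  invisible(x)
}

#' @rdname validate_scenario
#' @param x An `sroi_validation` object.
#' @param ... Unused.
#' @method tidy sroi_validation
#' @export
tidy.sroi_validation <- function(x, ...) {
  x$violations
}

stop_if_invalid <- function(s) {
  report <- validate_scenario(s)
  if (!report$ok) {
    msgs <- paste0(report$violations$field, ": ", report$violations$message)
    rlang::abort(c("invalid scenario", msgs), class = "sroikit_validation_error")
  }
  invisible(s)
}
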