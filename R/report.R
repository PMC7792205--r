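#' Render an SROI result as a human-readable benefit table
#'
#' Mirrors the published layout: a "Benefits" header, infant then mother
#' outcome rows in scenario order with whole-AUD values and thousands
#' separators, the total benefit, investment, net yield and the SROI ratio.
#'
#' @param result An `sroi_result` from [sroi_evaluate()].
#' @return A character vector of lines.
#' @export
render_benefit_table <- function(result) {
  per <- result$per_outcome
  width <- 58
  line <- function(label, value) {
    sprintf("%-*s %s", width, label, value)
  }
  rows <- c(
    line("Benefits", "Annual amount in AUD"),
    "Babies",
    vapply(which(per$beneficiary == "infant"), function(i) {
      line(paste0("  ", per$name[i]), fmt_money(per$annual_benefit[i]))
    }, character(1)),
    "Mothers",
    vapply(which(per$beneficiary == "mother"), function(i) {
      line(paste0("  ", per$name[i]), fmt_money(per$annual_benefit[i]))
    }, character(1)),
    line("Total value of benefits", fmt_money(result$benefit_basis)),
    "Investments",
    line("Total value of investments", fmt_money(result$investment, 2)),
    line("Net Yield (benefits less investments)",
         fmt_money(result$net_yield, 2)),
    line("Social Return on Investment (SROI)",
         sprintf("%.2f (reported %d:1)", result$ratio_raw,
                 result$ratio_reported))
  )
  rows
}

result_to_list <- function(result) {
  per <- result$per_outcome
  list(
    mode = result$mode,
    per_outcome_annual = stats::setNames(
      as.list(round(per$annual_benefit, 2)), per$name
    ),
    total_annual_benefit = round(result$total_annual_benefit, 2),
    npv_total = round(result$npv_total, 2),
    benefit_basis = round(result$benefit_basis, 2),
    investment = round(result$investment, 2),
    ratio = list(raw = result$ratio_raw, reported = result$ratio_reported),
    net_yield = round(result$net_yield, 2),
    payback_months = result$payback_months
  )
}

#' Serialize an SROI result
#'
#' Writes the result as JSON (nested, `per_outcome_annual` as a name-value
#' map) or CSV (long form with `section,name,value` columns). Money fields
#' carry 2 decimal places; the ratio is written both raw (full precision)
#' and reported (integer). Both formats contain identical numeric values.
#'
#' @param result An `sroi_result` from [sroi_evaluate()].
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_sroi_result <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  lst <- result_to_list(result)
  if (format == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    per <- tibble::tibble(
      section = "per_outcome_annual",
      name = names(lst$per_outcome_annual),
      value = unlist(lst$per_outcome_annual, use.names = FALSE)
    )
    summ <- tibble::tibble(
      section = "summary",
      name = c("total_annual_benefit", "npv_total", "benefit_basis",
               "investment", "ratio_raw", "ratio_reported", "net_yield",
               "payback_months"),
      value = c(lst$total_annual_benefit, lst$npv_total, lst$benefit_basis,
                lst$investment, lst$ratio$raw, lst$ratio$reported,
                lst$net_yield, lst$payback_months)
    )
    df <- dplyr::bind_rows(per, summ)
    df$value <- fmt_full(df$value)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Serialize a sensitivity table to CSV
#'
#' Columns: `parameter`, `base`, `new`, `ratio_reported`, `ratio_raw`,
#' `delta`.
#'
#' @param rows A sensitivity table from [one_way_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(rows, path) {
  df <- data.frame(
    parameter = rows$target,
    base = fmt_full(rows$base_value),
    new = fmt_full(rows$new_value),
    ratio_reported = rows$ratio_reported,
    ratio_raw = fmt_full(rows$ratio_raw),
    delta = fmt_full(rows$delta_vs_base)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

resolve_scenario_source <- function(source) {
  if (identical(source, "calvary") || identical(source, "fixture")) {
    s <- calvary_fixture()
    disc <- fixture_discrepancies(s)
    if (nrow(disc) > 0) {
      log_warn(sprintf(
        "%d outcome row(s) carry printed values that differ from the computed valuation: %s",
        nrow(disc), paste(disc$name, collapse = ", ")
      ))
    }
    if (!is.null(s$total_benefit_override)) {
      log_warn(sprintf(
        "published total benefit %s differs from the computed row sum %s; headline ratios use the published total",
        fmt_money(s$total_benefit_override), fmt_money(total_annual_benefit(s))
      ))
    }
    s
  } else {
    load_scenario(source)
  }
}

command_wrapper <- function(expr) {
  tryCatch(
    {
      expr
      invisible(0L)
    },
    error = function(e) {
      message("ERROR: ", conditionMessage(e))
      invisible(1L)
    }
  )
}

#' Evaluate a scenario and write the result (command-style entry point)
#'
#' Thin command wrapper over [load_scenario()], [sroi_evaluate()] and the
#' serializers: loads the scenario (or the built-in `"calvary"` fixture,
#' with WARN log lines surfacing its known printed-value discrepancies),
#' evaluates it, and writes the result. Diagnostics go to the message
#' stream, never into the data output.
#'
#' @param scenario `"calvary"` for the built-in fixture, or a file path
#'   accepted by [load_scenario()].
#' @param mode `"simple"` or `"npv"`.
#' @param format `"text"`, `"json"` or `"csv"`.
#' @param out Output file path; `NULL` writes text to standard output.
#' @return Exit status, invisibly: 0 on success, 1 on failure.
#' @export
run_command <- function(scenario = "calvary", mode = "simple",
                        format = c("text", "json", "csv"), out = NULL) {
  format <- match.arg(format)
  command_wrapper({
    s <- resolve_scenario_source(scenario)
    report <- validate_scenario(s)
    if (!report$ok) {
      rlang::abort(paste0(
        "scenario failed validation: ",
        paste0(report$violations$field, ": ", report$violations$message,
               collapse = "; ")
      ))
    }
    res <- sroi_evaluate(s, mode)
    if (format == "text") {
      lines <- render_benefit_table(res)
      if (is.null(out)) cat(lines, sep = "\n") else writeLines(lines, out)
    } else {
      if (is.null(out)) {
        rlang::abort("an output path is required for json/csv output")
      }
      write_sroi_result(res, out, format)
    }
  })
}

#' Run a one-way sensitivity analysis (command-style entry point)
#'
#' @param scenario As in [run_command()].
#' @param perturbations `"builtin"` for the case study's published one-way
#'   set ([calvary_perturbations()]), a CSV file path with columns
#'   `target,new_value[,label]`, or a list of [perturbation()] objects.
#' @param out Output CSV path; `NULL` prints the table.
#' @return Exit status, invisibly: 0 on success, 1 on failure.
#' @export
sensitivity_command <- function(scenario = "calvary",
                                perturbations = "builtin", out = NULL) {
  command_wrapper({
    s <- resolve_scenario_source(scenario)
    ps <- if (is.character(perturbations) &&
              identical(perturbations, "builtin")) {
      calvary_perturbations()
    } else if (is.character(perturbations)) {
      df <- utils::read.csv(perturbations, colClasses = "character",
                            strip.white = TRUE)
      if (nrow(df) == 0) {
        list()
      } else {
        purrr::pmap(df, function(target, new_value, ...) {
          dots <- list(...)
          perturbation(target, parse_fraction(new_value),
                       label = dots$label)
        })
      }
    } else {
      perturbations
    }
    rows <- one_way_table(s, ps)
    if (is.null(out)) {
      print(rows)
    } else {
      write_sensitivity_csv(rows, out)
    }
  })
}

#' Generate scenario files (command-style entry point)
#'
#' Writes `count` generated scenarios to `out_dir` as
#' `scenario_<seed>.<ext>`, logging the seeds used.
#'
#' @param spec A [generator_spec()].
#' @param count Number of scenarios (`>= 1`).
#' @param out_dir Output directory (created if missing).
#' @param format `"yaml"`, `"json"` or `"csv_bundle"`.
#' @return Exit status, invisibly: 0 on success, 1 on failure.
#' @export
generate_command <- function(spec = generator_spec(), count = 1,
                             out_dir = ".", format = c("yaml", "json",
                                                       "csv_bundle")) {
  format <- match.arg(format)
  command_wrapper({
    if (length(count) != 1 || is.na(count) || count < 1) {
      rlang::abort("usage: count must be at least 1")
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir)) {
      rlang::abort(sprintf("cannot create output directory '%s'", out_dir))
    }
    scenarios <- generate_suite(spec, count)
    seeds <- spec$seed + seq_len(count) - 1L
    ext <- switch(format, yaml = ".yaml", json = ".json", csv_bundle = "")
    for (i in seq_len(count)) {
      path <- file.path(out_dir, sprintf("scenario_%d%s", seeds[i], ext))
      write_scenario(scenarios[[i]], path, format)
    }
    log_info("wrote ", count, " scenario(s) with seeds ",
             paste(seeds, collapse = ", "))
  })
}

#' Validate a scenario source (command-style entry point)
#'
#' @param scenario As in [run_command()].
#' @return Exit status, invisibly: 0 when valid, 1 when invalid or
#'   unreadable.
#' @export
validate_command <- function(scenario) {
  status <- command_wrapper({
    s <- resolve_scenario_source(scenario)
    report <- validate_scenario(s)
    if (!report$ok) {
      print(report)
      rlang::abort("scenario failed validation")
    }
    log_info("scenario is valid")
  })
  status
}
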