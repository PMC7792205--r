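required_scenario_fields <- c("population", "investment", "outcomes")
required_outcome_fields <- c("name", "beneficiary", "incidence",
                             "risk_reduction", "unit_value", "duration_years")

schema_error <- function(field) {
  rlang::abort(sprintf("schema error: missing required field '%s'", field),
               class = "sroikit_schema_error")
}

outcome_from_list <- function(o, idx) {
  for (f in required_outcome_fields) {
    if (is.null(o[[f]])) {
      schema_error(sprintf("outcomes[%d].%s", idx, f))
    }
  }
  outcome_table(
    name = o$name,
    beneficiary = o$beneficiary,
    incidence = parse_fraction(o$incidence),
    risk_reduction = parse_fraction(o$risk_reduction),
    unit_value = as.numeric(o$unit_value),
    duration_years = as.integer(o$duration_years),
    printed_value = if (is.null(o$printed_value)) NA_real_ else
      as.numeric(o$printed_value)
  )
}

scenario_from_list <- function(lst) {
  for (f in required_scenario_fields) {
    if (is.null(lst[[f]])) schema_error(f)
  }
  if (length(lst$outcomes) == 0) schema_error("outcomes")
  outcomes <- dplyr::bind_rows(
    purrr::imap(lst$outcomes, function(o, i) outcome_from_list(o, i))
  )
  adj <- lst$adjustments %||% list()
  sroi_scenario(
    population = as.numeric(lst$population),
    outcomes = outcomes,
    investment = as.numeric(lst$investment),
    discount_rate = parse_fraction(lst$discount_rate %||% 0.04),
    adjustments = impact_adjustments(
      deadweight = parse_fraction(adj$deadweight %||% 0),
      displacement = parse_fraction(adj$displacement %||% 0),
      attribution = parse_fraction(adj$attribution %||% 0),
      drop_off = parse_fraction(adj$drop_off %||% 0)
    ),
    breastfeeding_rate = if (is.null(lst$breastfeeding_rate)) NA_real_ else
      parse_fraction(lst$breastfeeding_rate),
    total_benefit_override = lst$total_benefit_override,
    apply_breastfeeding_rate = isTRUE(lst$apply_breastfeeding_rate)
  )
}

scenario_to_list <- function(s) {
  lst <- list(
    population = s$population,
    investment = s$investment,
    discount_rate = s$discount_rate,
    adjustments = unclass(s$adjustments),
    outcomes = purrr::pmap(s$outcomes, function(name, beneficiary, incidence,
                                                risk_reduction, unit_value,
                                                duration_years,
                                                printed_value) {
      o <- list(
        name = name, beneficiary = beneficiary, incidence = incidence,
        risk_reduction = risk_reduction, unit_value = unit_value,
        duration_years = duration_years
      )
      if (!is.na(printed_value)) o$printed_value <- printed_value
      o
    })
  )
  if (!is.na(s$breastfeeding_rate)) {
    lst$breastfeeding_rate <- s$breastfeeding_rate
  }
  if (isTRUE(s$apply_breastfeeding_rate)) {
    lst$apply_breastfeeding_rate <- TRUE
  }
  if (!is.null(s$total_benefit_override)) {
    lst$total_benefit_override <- s$total_benefit_override
  }
  lst
}

detect_format <- function(path) {
  if (dir.exists(path)) return("csv_bundle")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = "yaml", yml = "yaml", json = "json",
    rlang::abort(
      sprintf("cannot infer format from '%s'; pass format explicitly", path),
      class = "sroikit_schema_error"
    )
  )
}

#' Load an outcome table from CSV
#'
#' Reads a CSV with header
#' `name,beneficiary,incidence,risk_reduction,unit_value,duration_years`
#' (an optional `printed_value` column is honoured). Fractions may be
#' decimals or percent strings such as `"26%"`.
#'
#' @param path CSV file path.
#' @return A tibble as built by [outcome_table()].
#' @export
load_outcomes_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE, check.names = TRUE)
  for (f in required_outcome_fields) {
    if (!f %in% names(df)) schema_error(paste0("outcomes.", f))
  }
  outcome_table(
    name = df$name,
    beneficiary = df$beneficiary,
    incidence = parse_fraction(df$incidence),
    risk_reduction = parse_fraction(df$risk_reduction),
    unit_value = as.numeric(df$unit_value),
    duration_years = as.integer(df$duration_years),
    printed_value = if ("printed_value" %in% names(df)) {
      as.numeric(df$printed_value)
    } else {
      NA_real_
    }
  )
}

#' Load a scenario from a configuration file
#'
#' Accepts the same schema in three dialects: a YAML file, a JSON file, or a
#' CSV bundle (a directory containing `scenario.csv` with `field,value` rows
#' and `outcomes.csv` with the outcome table). All fractions may be written
#' as decimals (`0.26`) or percent strings (`"26%"`). The schema is published
#' at [scenario_schema_path()].
#'
#' @param path File (YAML/JSON) or directory (CSV bundle) path.
#' @param format `"auto"` (from the extension), `"yaml"`, `"json"` or
#'   `"csv_bundle"`.
#' @return An [sroi_scenario()].
#' @export
load_scenario <- function(path, format = c("auto", "yaml", "json",
                                           "csv_bundle")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("scenario source not found: '%s'", path),
                 class = "sroikit_io_error")
  }
  if (format == "auto") format <- detect_format(path)

  if (format == "yaml") {
    lst <- yaml::read_yaml(path)
  } else if (format == "json") {
    lst <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    sc_path <- file.path(path, "scenario.csv")
    oc_path <- file.path(path, "outcomes.csv")
    if (!file.exists(sc_path) || !file.exists(oc_path)) {
      rlang::abort(
        sprintf("csv bundle '%s' must contain scenario.csv and outcomes.csv",
                path),
        class = "sroikit_io_error"
      )
    }
    kv <- utils::read.csv(sc_path, colClasses = "character",
                          strip.white = TRUE)
    vals <- stats::setNames(as.list(kv$value), kv$field)
    lst <- list(
      population = if (!is.null(vals$population))
        as.numeric(vals$population),
      investment = if (!is.null(vals$investment))
        as.numeric(vals$investment),
      discount_rate = vals$discount_rate,
      breastfeeding_rate = vals$breastfeeding_rate,
      apply_breastfeeding_rate =
        identical(tolower(vals$apply_breastfeeding_rate %||% "false"), "true"),
      total_benefit_override = if (!is.null(vals$total_benefit_override))
        as.numeric(vals$total_benefit_override),
      adjustments = list(
        deadweight = vals$adjustments.deadweight,
        displacement = vals$adjustments.displacement,
        attribution = vals$adjustments.attribution,
        drop_off = vals$adjustments.drop_off
      )
    )
    for (f in c("population", "investment")) {
      if (is.null(lst[[f]])) schema_error(f)
    }
    s <- scenario_from_list(c(lst, list(outcomes = list(list(
      name = "placeholder", beneficiary = "infant", incidence = 0,
      risk_reduction = 0, unit_value = 0, duration_years = 1
    )))))
    s$outcomes <- load_outcomes_csv(oc_path)
    return(s)
  }
  scenario_from_list(lst)
}

#' Write a scenario to a configuration file
#'
#' Inverse of [load_scenario()]: the written file loads back to a scenario
#' with identical values (numbers are serialized with 17 significant digits
#' so IEEE doubles round-trip exactly).
#'
#' @param s An [sroi_scenario()].
#' @param path Output file (YAML/JSON) or directory (CSV bundle).
#' @param format `"auto"`, `"yaml"`, `"json"` or `"csv_bundle"`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(s, path, format = c("auto", "yaml", "json",
                                               "csv_bundle")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in%
                  c("yaml", "yml", "json")) {
      detect_format(path)
    } else {
      "csv_bundle"
    }
  }
  lst <- scenario_to_list(s)

  if (format == "yaml") {
    # emit doubles verbatim at 17 significant digits so they parse back
    # bit-identically (yaml's own precision tops out below round-trip)
    yaml::write_yaml(lst, path, handlers = list(
      numeric = function(x) structure(sprintf("%.17g", x),
                                      class = "verbatim")
    ))
  } else if (format == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    fields <- c(
      population = fmt_full(s$population),
      investment = fmt_full(s$investment),
      discount_rate = fmt_full(s$discount_rate),
      breastfeeding_rate = if (!is.na(s$breastfeeding_rate))
        fmt_full(s$breastfeeding_rate),
      apply_breastfeeding_rate = if (isTRUE(s$apply_breastfeeding_rate))
        "true",
      total_benefit_override = if (!is.null(s$total_benefit_override))
        fmt_full(s$total_benefit_override),
      adjustments.deadweight = fmt_full(s$adjustments$deadweight),
      adjustments.displacement = fmt_full(s$adjustments$displacement),
      adjustments.attribution = fmt_full(s$adjustments$attribution),
      adjustments.drop_off = fmt_full(s$adjustments$drop_off)
    )
    utils::write.csv(
      data.frame(field = names(fields), value = unname(fields)),
      file.path(path, "scenario.csv"), row.names = FALSE, quote = FALSE
    )
    oc <- s$outcomes
    oc$incidence <- fmt_full(oc$incidence)
    oc$risk_reduction <- fmt_full(oc$risk_reduction)
    oc$unit_value <- fmt_full(oc$unit_value)
    oc$printed_value <- fmt_full(oc$printed_value)
    utils::write.csv(oc, file.path(path, "outcomes.csv"),
                     row.names = FALSE, quote = TRUE, na = "")
  }
  invisible(path)
}

#' Path to the published scenario JSON schema
#'
#' @return File path of the JSON-schema document describing the YAML/JSON
#'   scenario dialects.
#' @export
scenario_schema_path <- function() {
  system.file("extdata", "scenario-schema.json", package = "sroikit",
              mustWork = TRUE)
}
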