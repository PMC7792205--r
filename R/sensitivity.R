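#' Describe a one-at-a-time parameter perturbation
#'
#' A perturbation names one scenario parameter and the value it takes in a
#' "new case". Recognised target paths:
#' * `"adjustments.deadweight"`, `"adjustments.displacement"`,
#'   `"adjustments.attribution"`, `"adjustments.drop_off"`
#' * `"discount_rate"`, `"investment"`, `"population"`
#' * `"benefit_multiplier"` — a global multiplier on every unit value
#'   (base value 1)
#' * `"outcome:<name>:<field>"` with field one of `incidence`,
#'   `risk_reduction`, `unit_value`, `duration_years`
#'
#' @param target Parameter path (see above).
#' @param new_value Replacement value; must satisfy the same range
#'   constraints as the base field.
#' @param label Optional human-readable row label.
#' @return An object of class `sroi_perturbation`.
#' @export
#' @examples
#' perturbation("adjustments.attribution", 0.5)
perturbation <- function(target, new_value, label = NULL) {
  structure(
    list(target = target, new_value = new_value,
         label = label %||% target),
    class = "sroi_perturbation"
  )
}

parse_target <- function(target) {
  adj_fields <- c("deadweight", "displacement", "attribution", "drop_off")
  if (grepl("^adjustments\\.", target)) {
    field <- sub("^adjustments\\.", "", target)
    if (!field %in% adj_fields) {
      rlang::abort(sprintf("unknown adjustment field '%s'", field),
                   class = "sroikit_domain_error")
    }
    return(list(kind = "adjustment", field = field))
  }
  if (target %in% c("discount_rate", "investment", "population")) {
    return(list(kind = "scalar", field = target))
  }
  if (target == "benefit_multiplier") {
    return(list(kind = "multiplier"))
  }
  if (grepl("^outcome:", target)) {
    parts <- strsplit(target, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3 ||
        !parts[3] %in% c("incidence", "risk_reduction", "unit_value",
                         "duration_years")) {
      rlang::abort(sprintf("malformed outcome target '%s'", target),
                   class = "sroikit_domain_error")
    }
    return(list(kind = "outcome", name = parts[2], field = parts[3]))
  }
  rlang::abort(sprintf("unknown parameter path '%s'", target),
               class = "sroikit_domain_error")
}

#' Base value of a perturbation target in a scenario
#'
#' @param s An [sroi_scenario()].
#' @param target A parameter path (see [perturbation()]).
#' @return The current value of that parameter (`1` for
#'   `benefit_multiplier`).
#' @export
base_value <- function(s, target) {
  t <- parse_target(target)
  switch(t$kind,
    adjustment = s$adjustments[[t$field]],
    scalar = s[[t$field]],
    multiplier = 1,
    outcome = {
      i <- match(t$name, s$outcomes$name)
      if (is.na(i)) {
        rlang::abort(sprintf("no outcome named '%s'", t$name),
                     class = "sroikit_domain_error")
      }
      s$outcomes[[t$field]][i]
    }
  )
}

# annual value of one outcome row used when shifting an override:
# the printed value when the fixture carries one, else the computed value
row_reference_value <- function(s, i) {
  pv <- s$outcomes$printed_value[i]
  if (!is.na(pv)) {
    return(pv)
  }
  annual_benefit(s$outcomes[i, ], s$population, s$adjustments,
                 breastfeeding_rate = effective_bf_rate(s))$annual_benefit
}

#' Apply a perturbation to a scenario
#'
#' Returns a new scenario differing from the input only at the target
#' parameter; the input is never modified. When the scenario carries a
#' `total_benefit_override`, the override is kept coherent with the change:
#' * deadweight/displacement/attribution: rescaled by `(1-new)/(1-old)`
#' * `benefit_multiplier` k: rescaled by k; every unit value is multiplied
#'   by k
#' * `population`: rescaled by `new/old`
#' * an outcome's `incidence`, `risk_reduction` or `unit_value`: shifted by
#'   that outcome's reference annual value (its printed value when present,
#'   else its computed value) times `(new/old - 1)`
#' * `drop_off`, `discount_rate`, `investment`, `duration_years`: the
#'   override (an annual-total quantity) is unchanged
#'
#' @param s An [sroi_scenario()].
#' @param p An [perturbation()].
#' @return A new [sroi_scenario()].
#' @export
#' @examples
#' perturb(calvary_fixture(), perturbation("adjustments.attribution", 0.5))
perturb <- function(s, p) {
  t <- parse_target(p$target)
  old <- base_value(s, p$target)
  new <- p$new_value
  out <- s

  override_factor <- 1
  override_shift <- 0

  if (t$kind == "adjustment") {
    out$adjustments[[t$field]] <- as.numeric(new)
    if (t$field != "drop_off") {
      override_factor <- (1 - new) / (1 - old)
    }
  } else if (t$kind == "scalar") {
    out[[t$field]] <- as.numeric(new)
    if (t$field == "population") {
      override_factor <- new / old
    }
  } else if (t$kind == "multiplier") {
    out$outcomes$unit_value <- s$outcomes$unit_value * new
    out$outcomes$printed_value <- s$outcomes$printed_value * new
    override_factor <- new
  } else if (t$kind == "outcome") {
    i <- match(t$name, s$outcomes$name)
    out$outcomes[[t$field]][i] <-
      if (t$field == "duration_years") as.integer(new) else as.numeric(new)
    if (t$field != "duration_years") {
      if (old == 0) {
        rlang::abort(
          sprintf("cannot rescale outcome '%s': base %s is zero",
                  t$name, t$field),
          class = "sroikit_domain_error"
        )
      }
      override_shift <- row_reference_value(s, i) * (new / old - 1)
    }
  }

  if (!is.null(out$total_benefit_override)) {
    out$total_benefit_override <-
      out$total_benefit_override * override_factor + override_shift
  }
  stop_if_invalid(out)
  out
}

#' One-way deterministic sensitivity table
#'
#' Evaluates each perturbation independently from the base scenario (strict
#' one-at-a-time, no compounding) and reports the resulting SROI ratio and
#' its change from base. Rows appear in input order. By default each row is
#' evaluated in `simple` mode except `drop_off` and `discount_rate` targets,
#' which only act on discounted streams and are therefore evaluated in `npv`
#' mode (against an `npv`-mode base ratio).
#'
#' @param s A validated base [sroi_scenario()]; unchanged by the call.
#' @param perturbations A list of [perturbation()] objects (possibly empty).
#' @param mode `"auto"` (default, as above), `"simple"` or `"npv"` to force
#'   one mode for every row.
#' @return A tibble of class `sroi_sensitivity`: one row per perturbation
#'   with columns `target`, `label`, `base_value`, `new_value`, `mode`,
#'   `ratio_raw`, `ratio_reported`, `delta_vs_base`.
#' @export
#' @examples
#' one_way_table(calvary_fixture(),
#'               list(perturbation("adjustments.displacement", 0)))
one_way_table <- function(s, perturbations, mode = c("auto", "simple", "npv")) {
  mode <- match.arg(mode)
  stop_if_invalid(s)

  empty <- tibble::tibble(
    target = character(), label = character(),
    base_value = numeric(), new_value = numeric(), mode = character(),
    ratio_raw = numeric(), ratio_reported = integer(),
    delta_vs_base = numeric()
  )
  if (length(perturbations) == 0) {
    return(structure(empty, class = c("sroi_sensitivity", class(empty))))
  }

  base_ratio <- list(
    simple = sroi_evaluate(s, "simple")$ratio_raw,
    npv = sroi_evaluate(s, "npv")$ratio_raw
  )

  rows <- purrr::map(perturbations, function(p) {
    row_mode <- if (mode == "auto") {
      if (p$target %in% c("adjustments.drop_off", "discount_rate")) {
        "npv"
      } else {
        "simple"
      }
    } else {
      mode
    }
    res <- sroi_evaluate(perturb(s, p), row_mode)
    tibble::tibble(
      target = p$target,
      label = p$label,
      base_value = base_value(s, p$target),
      new_value = as.numeric(p$new_value),
      mode = row_mode,
      ratio_raw = res$ratio_raw,
      ratio_reported = res$ratio_reported,
      delta_vs_base = res$ratio_raw - base_ratio[[row_mode]]
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("sroi_sensitivity", class(empty)))
}

#' Rank sensitivity rows by influence (tornado ordering)
#'
#' Sorts rows by the absolute change in the raw ratio, descending; ties keep
#' input order.
#'
#' @param rows A sensitivity table from [one_way_table()].
#' @return The same tibble, reordered.
#' @export
tornado_rank <- function(rows) {
  idx <- order(-abs(rows$delta_vs_base))
  rows[idx, ]
}

#' Tornado plot of a sensitivity table
#'
#' @param object A sensitivity table from [one_way_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sroi_sensitivity
#' @export
autoplot.sroi_sensitivity <- function(object, ...) {
  df <- tornado_rank(object)
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  df$base_ratio <- df$ratio_raw - df$delta_vs_base
  ggplot2::ggplot(df, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$base_ratio, xend = .data$ratio_raw, yend = .data$label
    ), linewidth = 3, colour = "steelblue") +
    ggplot2::geom_vline(
      ggplot2::aes(xintercept = .data$base_ratio), linetype = "dashed"
    ) +
    ggplot2::labs(x = "SROI ratio (raw)", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' The built-in one-way sensitivity set for the BFHI case study
#'
#' The published new-case scenarios: attribution to 50%, deadweight to 50%,
#' displacement to 0%, drop-off to 50%, discount rate to 6%, obesity risk
#' reduction to 22% and 30%, SIDS risk reduction to 18% and 56%, breast
#' cancer risk reduction to 2.9% and 5.8%, and the total outcome value
#' halved and doubled.
#'
#' @return A list of [perturbation()] objects.
#' @export
calvary_perturbations <- function() {
  list(
    perturbation("adjustments.attribution", 0.50, "Attribution 25% to 50%"),
    perturbation("adjustments.deadweight", 0.50, "Deadweight 5% to 50%"),
    perturbation("adjustments.displacement", 0.00, "Displacement 20% to 0%"),
    perturbation("adjustments.drop_off", 0.50, "Drop off 20% to 50%"),
    perturbation("discount_rate", 0.06, "Discount rate 4% to 6%"),
    perturbation("outcome:obesity:risk_reduction", 0.22,
                 "Obesity risk reduction 26% to 22%"),
    perturbation("outcome:obesity:risk_reduction", 0.30,
                 "Obesity risk reduction 26% to 30%"),
    perturbation("outcome:SIDS:risk_reduction", 0.18,
                 "SIDS risk reduction 40% to 18%"),
    perturbation("outcome:SIDS:risk_reduction", 0.56,
                 "SIDS risk reduction 40% to 56%"),
    perturbation("outcome:breast cancer:risk_reduction", 0.029,
                 "Breast cancer risk reduction to 2.9%"),
    perturbation("outcome:breast cancer:risk_reduction", 0.058,
                 "Breast cancer risk reduction to 5.8%"),
    perturbation("benefit_multiplier", 0.5, "Value divided by 2"),
    perturbation("benefit_multiplier", 2, "Value multiplied by 2")
  )
}

target_bounds <- function(target) {
  t <- parse_target(target)
  switch(t$kind,
    adjustment = c(0, 1 - 1e-12),
    multiplier = c(1e-12, Inf),
    scalar = switch(t$field,
      discount_rate = c(0, Inf),
      investment = c(1e-12, Inf),
      population = c(1, Inf)
    ),
    outcome = switch(t$field,
      incidence = c(0, 1),
      risk_reduction = c(0, 1),
      unit_value = c(0, Inf),
      duration_years = c(1, Inf)
    )
  )
}

sample_spec <- function(spec, n) {
  b <- target_bounds(spec$target)
  if (identical(spec$dist, "uniform")) {
    if (is.null(spec$min) || is.null(spec$max) || spec$min > spec$max ||
        spec$min < b[1] || spec$max > b[2]) {
      rlang::abort(
        sprintf("uniform bounds for '%s' outside valid range [%g, %g]",
                spec$target, b[1], b[2]),
        class = "sroikit_domain_error"
      )
    }
    stats::runif(n, spec$min, spec$max)
  } else if (identical(spec$dist, "point")) {
    if (is.null(spec$value) || spec$value < b[1] || spec$value > b[2]) {
      rlang::abort(
        sprintf("point value for '%s' outside valid range [%g, %g]",
                spec$target, b[1], b[2]),
        class = "sroikit_domain_error"
      )
    }
    rep(spec$value, n)
  } else {
    rlang::abort(
      sprintf("unsupported distribution '%s' (use 'uniform' or 'point')",
              spec$dist %||% "<missing>"),
      class = "sroikit_domain_error"
    )
  }
}

#' Seeded Monte Carlo probabilistic sensitivity analysis
#'
#' Draws every listed parameter independently from its distribution, jointly
#' applies one draw per iteration, and evaluates the raw SROI ratio in
#' `simple` mode from the computed outcome sum (any
#' `total_benefit_override` is ignored: a fixed published total cannot stay
#' coherent under joint random perturbation). Identical `(seed, n, specs)`
#' give identical output.
#'
#' @param s A validated base [sroi_scenario()].
#' @param specs A list of distribution specs, each a list with `target` (a
#'   [perturbation()] path), `dist` (`"uniform"` or `"point"`), and either
#'   `min`/`max` or `value`.
#' @param n Number of draws (`>= 1`).
#' @param seed Integer seed.
#' @return An object of class `sroi_psa`: a list with `summary` (one-row
#'   tibble: `n`, `mean`, `sd`, `q025`, `median`, `q975`,
#'   `prob_ratio_above_1`) and `draws` (tibble of `draw`, `ratio_raw`).
#' @export
monte_carlo_psa <- function(s, specs, n, seed) {
  stop_if_invalid(s)
  if (length(n) != 1 || is.na(n) || n < 1) {
    rlang::abort("n must be at least 1", class = "sroikit_domain_error")
  }
  n <- as.integer(n)

  inc <- s$outcomes$incidence
  rr <- s$outcomes$risk_reduction
  uv <- s$outcomes$unit_value
  adj <- s$adjustments
  bf <- effective_bf_rate(s)

  draws_mat <- withr::with_seed(
    seed,
    lapply(specs, function(sp) sample_spec(sp, n))
  )
  parsed <- lapply(specs, function(sp) parse_target(sp$target))

  ratio <- vapply(seq_len(n), function(k) {
    inc_k <- inc; rr_k <- rr; uv_k <- uv
    dw <- adj$deadweight; disp <- adj$displacement; attr <- adj$attribution
    pop <- s$population; inv <- s$investment; mult <- 1
    for (j in seq_along(parsed)) {
      t <- parsed[[j]]
      val <- draws_mat[[j]][k]
      if (t$kind == "adjustment") {
        if (t$field == "deadweight") dw <- val
        if (t$field == "displacement") disp <- val
        if (t$field == "attribution") attr <- val
        # drop_off has no effect on the simple-mode annual valuation
      } else if (t$kind == "scalar") {
        if (t$field == "investment") inv <- val
        if (t$field == "population") pop <- val
        # discount_rate has no effect on the simple-mode annual valuation
      } else if (t$kind == "multiplier") {
        mult <- val
      } else {
        i <- match(t$name, s$outcomes$name)
        if (is.na(i)) {
          rlang::abort(sprintf("no outcome named '%s'", t$name),
                       class = "sroikit_domain_error")
        }
        if (t$field == "incidence") inc_k[i] <- val
        if (t$field == "risk_reduction") rr_k[i] <- val
        if (t$field == "unit_value") uv_k[i] <- val
      }
    }
    basis <- pop * bf * mult * sum(inc_k * rr_k * uv_k) *
      (1 - dw) * (1 - disp) * (1 - attr)
    (basis - inv) / inv
  }, numeric(1))

  qs <- stats::quantile(ratio, c(0.025, 0.5, 0.975), names = FALSE)
  structure(
    list(
      summary = tibble::tibble(
        n = n,
        mean = mean(ratio),
        sd = stats::sd(ratio),
        q025 = qs[1],
        median = qs[2],
        q975 = qs[3],
        prob_ratio_above_1 = mean(ratio > 1)
      ),
      draws = tibble::tibble(draw = seq_len(n), ratio_raw = ratio)
    ),
    class = "sroi_psa"
  )
}

#' @export
print.sroi_psa <- function(x, ...) {
  cat("<sroi_psa>", x$summary$n, "draws\n")
  print(x$summary)
  invisible(x)
}

#' @rdname monte_carlo_psa
#' @param x An `sroi_psa` object.
#' @param ... Unused.
#' @method tidy sroi_psa
#' @export
tidy.sroi_psa <- function(x, ...) {
  x$draws
}

#' @rdname monte_carlo_psa
#' @method glance sroi_psa
#' @export
glance.sroi_psa <- function(x, ...) {
  x$summary
}
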