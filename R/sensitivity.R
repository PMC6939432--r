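#' Parameter specifications for sensitivity analyses
#'
#' Builds the table of sensitivity ranges and sampling families for the
#' model parameters. Ranges default to the published input table (costs at
#' +/-20% of base; utilities and transition probabilities at their printed
#' intervals); `pct` replaces them with symmetric +/-pct bounds, clamped to
#' \[0, 1\] for probability-type parameters. Families follow standard
#' health-economics practice: gamma for costs, beta for probabilities and
#' utilities; the discount rate is varied deterministically only
#' (`family = "none"`).
#'
#' `psa_specs()` selects the stochastic set (four costs, two utilities,
#' three transition probabilities) and `tornado_specs()` the seven
#' parameters of the one-way analysis (utilities, the four costs, and the
#' discount rate).
#'
#' @param inputs A [model_inputs()] object supplying base values.
#' @param pct Optional half-width of symmetric bounds as a fraction of the
#'   base value (e.g. 0.2); `NULL` (default) keeps the published ranges.
#' @param parameters Which parameters to include (default: all with a
#'   range).
#' @return A tibble: `parameter`, `base`, `low`, `high`, `family`.
#' @export
param_specs <- function(inputs = model_inputs(), pct = NULL,
                        parameters = NULL) {
  ranges <- tibble(
    parameter = c(
      "cost_surgery_initial", "cost_surgery_cycle",
      "cost_medication_initial", "cost_medication_cycle",
      "u_t2dm", "u_remission",
      "p_relapse", "mu_t2dm", "mu_remission",
      "rate",
      "init_remission_surgery", "init_remission_medication"
    ),
    low = c(
      37123.28, 2213.13, 10065.17, 6139.39,
      0.62, 0.76,
      0.0020, 0.0163, 0.0050,
      0.04,
      NA, NA
    ),
    high = c(
      55684.92, 3319.69, 15097.75, 9209.09,
      0.92, 1.00,
      0.0031, 0.0245, 0.0074,
      0.06,
      NA, NA
    ),
    family = c(
      rep("gamma", 4), rep("beta", 5), "none", "beta", "beta"
    )
  )
  if (is.null(parameters)) {
    parameters <- head(ranges$parameter, 10L)
  }
  unknown <- setdiff(parameters, ranges$parameter)
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown parameter(s): ", paste(unknown, collapse = ", "),
      "; valid names: ", paste(ranges$parameter, collapse = ", ")
    ))
  }
  out <- ranges %>%
    filter(.data$parameter %in% parameters) %>%
    mutate(base = purrr::map_dbl(.data$parameter, ~ inputs[[.x]]), .after = "parameter")

  prob_like <- out$family == "beta" | out$parameter == "rate"
  if (!is.null(pct)) {
    out <- out %>% mutate(
      low = .data$base * (1 - pct),
      high = .data$base * (1 + pct)
    )
  }
  out <- out %>% mutate(
    low = dplyr::if_else(is.na(.data$low), .data$base * 0.8, .data$low),
    high = dplyr::if_else(is.na(.data$high), .data$base * 1.2, .data$high),
    low = dplyr::if_else(prob_like, pmax(.data$low, 0), .data$low),
    high = dplyr::if_else(.data$family == "beta", pmin(.data$high, 1), .data$high)
  )
  bad <- out$low > out$base | out$high < out$base
  if (any(bad)) {
    abort(paste0("range excludes base value for: ", paste(out$parameter[bad], collapse = ", ")))
  }
  out[match(parameters, out$parameter), ]
}

#' @rdname param_specs
#' @export
psa_specs <- function(inputs = model_inputs(), pct = NULL) {
  param_specs(inputs, pct, parameters = c(
    "cost_surgery_initial", "cost_surgery_cycle",
    "cost_medication_initial", "cost_medication_cycle",
    "u_remission", "u_t2dm",
    "p_relapse", "mu_remission", "mu_t2dm"
  ))
}

#' @rdname param_specs
#' @export
tornado_specs <- function(inputs = model_inputs(), pct = NULL) {
  param_specs(inputs, pct, parameters = c(
    "u_remission", "cost_medication_cycle", "u_t2dm",
    "cost_surgery_initial", "rate", "cost_surgery_cycle",
    "cost_medication_initial"
  ))
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full deterministic model with each parameter set to its low
#' and high bound in turn, all others held at base, and records the
#' incremental outcome of surgery versus medication at each bound. Two
#' metrics are reported per bound: the signed ICER (the classical tornado
#' axis; well defined here because dominance holds across the whole input
#' ranges, so its sign is stable) and the incremental net monetary benefit
#' (INMB) at the willingness-to-pay threshold, which stays usable if a
#' parameter change ever breaks dominance. Entries come back sorted by
#' descending spread of the chosen metric.
#'
#' @param inputs A [model_inputs()] object (the base case).
#' @param specs Parameter table from [param_specs()] /
#'   [tornado_specs()].
#' @param metric Which spread orders the entries: `"icer"` (default) or
#'   `"inmb"`.
#' @return A `tornado` tibble: `parameter`, `low`, `high`, `inmb_low`,
#'   `inmb_high`, `icer_low`, `icer_high`, `spread_inmb`, `spread_icer`,
#'   and `spread` (the chosen metric's spread), sorted descending;
#'   base-case INMB, ICER and verdict are attached as attributes
#'   `base_inmb`, `base_icer` and `base_verdict`.
#' @export
one_way <- function(inputs = model_inputs(), specs = tornado_specs(inputs),
                    metric = c("icer", "inmb")) {
  stopifnot(inherits(inputs, "model_inputs"))
  metric <- match.arg(metric)
  eval_at <- function(param, value) {
    cmp <- run_base_case(do.call(set_inputs, c(list(inputs), setNames(list(value), param))))$comparison
    c(
      inmb = cmp$wtp * cmp$delta_qaly - cmp$delta_cost,
      icer = if (cmp$delta_qaly != 0) cmp$delta_cost / cmp$delta_qaly else NA_real_
    )
  }
  base_cmp <- run_base_case(inputs)$comparison

  out <- purrr::pmap_dfr(
    specs[, c("parameter", "low", "high")],
    function(parameter, low, high) {
      lo <- eval_at(parameter, low)
      hi <- eval_at(parameter, high)
      tibble(
        parameter = parameter, low = low, high = high,
        inmb_low = lo[["inmb"]], inmb_high = hi[["inmb"]],
        icer_low = lo[["icer"]], icer_high = hi[["icer"]],
        spread_inmb = abs(hi[["inmb"]] - lo[["inmb"]]),
        spread_icer = abs(hi[["icer"]] - lo[["icer"]])
      )
    }
  ) %>%
    mutate(spread = if (metric == "icer") .data$spread_icer else .data$spread_inmb) %>%
    arrange(dplyr::desc(.data$spread))
  attr(out, "metric") <- metric
  attr(out, "base_inmb") <- base_cmp$wtp * base_cmp$delta_qaly - base_cmp$delta_cost
  attr(out, "base_icer") <- if (base_cmp$delta_qaly != 0) {
    base_cmp$delta_cost / base_cmp$delta_qaly
  } else {
    NA_real_
  }
  attr(out, "base_verdict") <- base_cmp$verdict
  class(out) <- c("tornado", class(out))
  out
}

# moment-matched hyperparameters from a base value and a 95% range
psa_hyper <- function(parameter, base, low, high, family) {
  sdev <- (high - low) / (2 * 1.96)
  if (sdev == 0 || family == "none") {
    return(list(family = "degenerate", base = base))
  }
  v <- sdev^2
  if (family == "gamma") {
    if (base <= 0) abort(sprintf("`%s`: gamma family needs a positive base value", parameter))
    list(family = "gamma", shape = base^2 / v, rate = base / v)
  } else if (family == "beta") {
    if (base <= 0 || base >= 1) {
      abort(sprintf("`%s`: beta family needs a base value inside (0, 1)", parameter))
    }
    if (v >= base * (1 - base)) {
      abort(sprintf("`%s`: SD %.4g too large for a beta distribution with mean %.4g", parameter, sdev, base))
    }
    k <- base * (1 - base) / v - 1
    list(family = "beta", shape1 = base * k, shape2 = (1 - base) * k)
  } else {
    abort(sprintf("`%s`: unknown family '%s'", parameter, family))
  }
}

#' Sample parameter vectors for probabilistic sensitivity analysis
#'
#' Draws independent parameter values with means at the base values: gamma
#' for costs, beta for probabilities and utilities, with the SD derived by
#' treating each parameter's range as a 95% interval
#' (`SD = (high - low) / 3.92`) and matching moments. A zero-width range
#' collapses to the base value.
#'
#' @param specs Parameter table from [param_specs()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A tibble with `.draw` plus one column per parameter.
#' @export
sample_params <- function(specs, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 1) abort("`n` must be at least 1")
  cols <- purrr::pmap(
    specs[, c("parameter", "base", "low", "high", "family")],
    function(parameter, base, low, high, family) {
      h <- psa_hyper(parameter, base, low, high, family)
      switch(h$family,
        degenerate = rep(h$base, n),
        gamma = rgamma(n, shape = h$shape, rate = h$rate),
        beta = rbeta(n, h$shape1, h$shape2)
      )
    }
  )
  names(cols) <- specs$parameter
  tibble(.draw = seq_len(n), !!!cols)
}

#' Run the probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: for each of `n` draws the sampled parameters
#' replace their base values, the Markov model runs for both strategies,
#' and the discounted incremental cost and QALYs are recorded. Draws
#' producing an invalid model (e.g. a non-stochastic transition row) are
#' rejected and redrawn; the count is reported.
#'
#' @param inputs A [model_inputs()] base case.
#' @param specs Parameter table, default [psa_specs()].
#' @param n Number of retained draws (default 1,000).
#' @param seed Integer seed.
#' @return A `psa_result`: `draws` tibble (`.draw`, sampled parameters,
#'   `cost_surgery`, `qaly_surgery`, `cost_medication`, `qaly_medication`,
#'   `delta_cost`, `delta_qaly`), plus `wtp`, `n_rejected`, and `seed`.
#'   [glance()] summarises means, the cost-effective fraction at `wtp`, and
#'   the cost-effectiveness-plane quadrant shares.
#' @export
run_psa <- function(inputs = model_inputs(), specs = psa_specs(inputs),
                    n = 1000, seed = NULL) {
  stopifnot(inherits(inputs, "model_inputs"))
  if (!is.null(seed)) set.seed(seed)

  draws <- sample_params(specs, n)
  rejected <- 0L
  results <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      row <- as.list(draws[i, specs$parameter])
      bc <- tryCatch(
        run_base_case(do.call(set_inputs, c(list(inputs), row))),
        error = function(e) NULL
      )
      if (!is.null(bc)) break
      rejected <- rejected + 1L
      redraw <- sample_params(specs, 1L)
      draws[i, specs$parameter] <- redraw[, specs$parameter]
    }
    cmp <- bc$comparison
    results[[i]] <- tibble(
      cost_surgery = cmp$cost_a, qaly_surgery = cmp$qaly_a,
      cost_medication = cmp$cost_b, qaly_medication = cmp$qaly_b,
      delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly
    )
  }

  structure(
    list(
      draws = dplyr::bind_cols(draws, bind_rows(results)),
      wtp = inputs$wtp,
      n_rejected = rejected,
      seed = seed
    ),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "PSA with %d draws (%d rejected): P(cost-effective at WTP %s) = %.1f%%\n",
    nrow(x$draws), x$n_rejected, format(x$wtp, big.mark = ","),
    100 * g$p_cost_effective
  ))
  invisible(x)
}

#' @rdname run_psa
#' @param x,object A `psa_result`.
#' @param ... Unused.
#' @export
tidy.psa_result <- function(x, ...) {
  x$draws
}

#' @rdname run_psa
#' @export
glance.psa_result <- function(object, ...) {
  d <- object$draws
  tibble(
    n = nrow(d),
    n_rejected = object$n_rejected,
    mean_delta_cost = mean(d$delta_cost),
    mean_delta_qaly = mean(d$delta_qaly),
    p_cost_effective = mean(object$wtp * d$delta_qaly - d$delta_cost > 0),
    p_dominant = mean(d$delta_cost < 0 & d$delta_qaly > 0),
    p_ne = mean(d$delta_cost >= 0 & d$delta_qaly > 0),
    p_sw = mean(d$delta_cost < 0 & d$delta_qaly <= 0),
    p_dominated = mean(d$delta_cost >= 0 & d$delta_qaly <= 0),
    wtp = object$wtp
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on the grid, the probability that
#' surgery is cost-effective is the fraction of PSA draws with positive
#' incremental net monetary benefit, `lambda * delta_qaly - delta_cost > 0`.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay grid in CNY/QALY (default 0 to
#'   400,000 in steps of 10,000).
#' @return A `ceac` tibble: `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 400000, by = 10000)) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0) abort("`wtp_grid` must be non-empty")
  d <- psa$draws
  out <- tibble(
    wtp = wtp_grid,
    probability = purrr::map_dbl(wtp_grid, ~ mean(.x * d$delta_qaly - d$delta_cost > 0))
  )
  class(out) <- c("ceac", class(out))
  out
}
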