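#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Values a [run_markov()] trace under a cost schedule and utility weights.
#' Cycle 0 (the treatment year) accrues the strategy's initial cost for every
#' alive patient and is not discounted; each later cycle accrues the cycle
#' (maintenance) cost per alive patient and the utility-weighted occupancy,
#' discounted at `rate` per year. Death carries neither cost nor utility.
#'
#' @param trace A `cohort_trace` from [run_markov()].
#' @param cost_initial Cost applied at cycle 0 per alive patient (CNY).
#' @param cost_cycle Cost per alive patient per later cycle (CNY).
#' @param utilities Named vector of QALY weights for `remission`, `t2dm`,
#'   `dead`.
#' @param rate Annual discount rate (default 0.05); costs and benefits beyond
#'   the first year are discounted.
#' @param discount_exponent Discounting convention: `"cycle"` (default)
#'   divides cycle t by (1 + rate)^t so the first year is undiscounted;
#'   `"cycle_plus_one"` divides by (1 + rate)^(t + 1), discounting from the
#'   first year onward.
#' @param strategy Label attached to the result.
#' @return A `strategy_result`: per-cycle tibble (`cycle`, `cost`, `qaly`,
#'   `disc_cost`, `disc_qaly` and their cumulative series) with the strategy
#'   label and totals retrievable via [glance()].
#' @export
accrue <- function(trace, cost_initial, cost_cycle,
                   utilities = c(remission = 0.95, t2dm = 0.77, dead = 0),
                   rate = 0.05,
                   discount_exponent = c("cycle", "cycle_plus_one"),
                   strategy = "strategy") {
  discount_exponent <- match.arg(discount_exponent)
  if (cost_initial < 0 || cost_cycle < 0) abort("costs must be nonnegative")
  if (rate < 0) abort("`rate` must be nonnegative")
  u <- utilities[c("remission", "t2dm", "dead")]
  if (anyNA(u)) abort("`utilities` must name remission, t2dm and dead")
  if (u[["dead"]] != 0) abort("the dead state carries no utility")

  trace <- as_tibble(trace)
  cyc <- trace$cycle
  alive <- trace$remission + trace$t2dm
  cost <- ifelse(cyc == 0, cost_initial * alive, cost_cycle * alive)
  qaly <- trace$remission * u[["remission"]] + trace$t2dm * u[["t2dm"]]
  expo <- if (discount_exponent == "cycle") cyc else cyc + 1
  disc <- ifelse(cyc == 0, 1, (1 + rate)^(-expo))

  cycles <- tibble(
    cycle = cyc,
    cost = cost,
    qaly = qaly,
    disc_cost = cost * disc,
    disc_qaly = qaly * disc,
    cum_cost = cumsum(cost),
    cum_qaly = cumsum(qaly),
    cum_disc_cost = cumsum(cost * disc),
    cum_disc_qaly = cumsum(qaly * disc)
  )
  structure(
    list(strategy = strategy, rate = rate, cycles = cycles),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "%s over %d cycles: cost %.2f (discounted %.2f), QALYs %.2f (discounted %.2f)\n",
    x$strategy, max(x$cycles$cycle), g$cost, g$disc_cost, g$qaly, g$disc_qaly
  ))
  invisible(x)
}

#' @rdname accrue
#' @param x,object A `strategy_result`.
#' @param ... Unused.
#' @export
tidy.strategy_result <- function(x, ...) {
  mutate(x$cycles, strategy = x$strategy, .before = 1)
}

#' @rdname accrue
#' @export
glance.strategy_result <- function(object, ...) {
  last <- object$cycles[nrow(object$cycles), ]
  tibble(
    strategy = object$strategy,
    cost = last$cum_cost,
    disc_cost = last$cum_disc_cost,
    qaly = last$cum_qaly,
    disc_qaly = last$cum_disc_qaly,
    rate = object$rate
  )
}

#' Compare two strategies on the cost-effectiveness plane
#'
#' Computes per-strategy cost/QALY ratios, incremental cost and QALYs of `a`
#' versus `b`, the ICER where defined, a dominance verdict, and net monetary
#' benefit at the willingness-to-pay threshold. A strategy *dominates* when
#' it is both cheaper and more effective; the ICER is only meaningful when
#' incremental cost and effect share a sign.
#'
#' @param a,b `strategy_result` objects with the same horizon and discount
#'   rate.
#' @param wtp Willingness-to-pay threshold in CNY per QALY (default 193,932,
#'   three times GDP per capita).
#' @return A one-row `ce_comparison` tibble: strategy labels, discounted
#'   cost/QALY per strategy and their ratios, `delta_cost`, `delta_qaly`,
#'   `icer` (NA under dominance or zero QALY difference), `verdict`
#'   (`"a dominant"`, `"b dominant"`, `"icer"`, or `"equivalent"`), and
#'   `nmb_a`, `nmb_b`.
#' @export
compare_strategies <- function(a, b, wtp = 193932) {
  stopifnot(inherits(a, "strategy_result"), inherits(b, "strategy_result"))
  if (nrow(a$cycles) != nrow(b$cycles)) abort("strategies must share a horizon")
  if (a$rate != b$rate) abort("strategies must share a discount rate")
  ga <- glance(a)
  gb <- glance(b)
  dc <- ga$disc_cost - gb$disc_cost
  dq <- ga$disc_qaly - gb$disc_qaly

  verdict <- if (dc < 0 && dq > 0) {
    "a dominant"
  } else if (dc > 0 && dq < 0) {
    "b dominant"
  } else if (dc == 0 && dq == 0) {
    "equivalent"
  } else {
    "icer"
  }
  icer <- if (verdict == "icer" && dq != 0) dc / dq else NA_real_

  out <- tibble(
    strategy_a = a$strategy,
    strategy_b = b$strategy,
    cost_a = ga$disc_cost,
    qaly_a = ga$disc_qaly,
    cost_b = gb$disc_cost,
    qaly_b = gb$disc_qaly,
    ratio_a = ga$disc_cost / ga$disc_qaly,
    ratio_b = gb$disc_cost / gb$disc_qaly,
    delta_cost = dc,
    delta_qaly = dq,
    icer = icer,
    verdict = verdict,
    wtp = wtp,
    nmb_a = wtp * ga$disc_qaly - ga$disc_cost,
    nmb_b = wtp * gb$disc_qaly - gb$disc_cost
  )
  class(out) <- c("ce_comparison", class(out))
  out
}

#' First cycle at which one strategy dominates cumulatively
#'
#' Scans the cumulative discounted series and returns the first cycle at
#' which strategy `a` has accumulated no more cost and no fewer QALYs than
#' strategy `b` — the payback point of an up-front investment.
#'
#' @inheritParams compare_strategies
#' @return Integer cycle index, or `NA_integer_` if the series never cross.
#' @export
crossover_cycle <- function(a, b) {
  stopifnot(inherits(a, "strategy_result"), inherits(b, "strategy_result"))
  if (nrow(a$cycles) != nrow(b$cycles)) abort("strategies must share a horizon")
  ok <- a$cycles$cum_disc_cost <= b$cycles$cum_disc_cost &
    a$cycles$cum_disc_qaly >= b$cycles$cum_disc_qaly
  idx <- which(ok)
  if (length(idx) == 0) {
    return(NA_integer_)
  }
  as.integer(a$cycles$cycle[idx[1]])
}
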