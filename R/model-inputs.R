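#' Bundle all model inputs for the two-strategy analysis
#'
#' Collects every quantity the deterministic model needs — per-strategy
#' initial and cycle costs, state utilities, annual transition
#' probabilities, the first-cycle remission shares observed in the matched
#' arms, discount rate, horizon, and the willingness-to-pay threshold — into
#' a single validated object addressed by flat parameter names (used by the
#' sensitivity machinery).
#'
#' @param cost_surgery_initial,cost_surgery_cycle Surgery arm costs (CNY):
#'   the treatment-year cost and the per-cycle maintenance cost.
#' @param cost_medication_initial,cost_medication_cycle Medication arm costs
#'   (CNY).
#' @param u_remission,u_t2dm Utility weights of the remission and T2DM
#'   states.
#' @param p_relapse Annual probability of relapse from remission to T2DM.
#' @param mu_remission,mu_t2dm Annual mortality in the remission
#'   (non-diabetic) and T2DM states.
#' @param init_remission_surgery,init_remission_medication Fraction of each
#'   arm in remission at cycle 0 (22/41 and 1/41 in the matched cohort).
#' @param rate Annual discount rate.
#' @param horizon Number of transition cycles.
#' @param wtp Willingness-to-pay threshold (CNY/QALY).
#' @return A `model_inputs` object (named list).
#' @export
model_inputs <- function(cost_surgery_initial = 46404.41,
                         cost_surgery_cycle = 2766.41,
                         cost_medication_initial = 12581.46,
                         cost_medication_cycle = 7674.24,
                         u_remission = 0.95,
                         u_t2dm = 0.77,
                         p_relapse = 0.0025,
                         mu_remission = 0.0062,
                         mu_t2dm = 0.0204,
                         init_remission_surgery = 22 / 41,
                         init_remission_medication = 1 / 41,
                         rate = 0.05,
                         horizon = 40,
                         wtp = 193932) {
  x <- list(
    cost_surgery_initial = cost_surgery_initial,
    cost_surgery_cycle = cost_surgery_cycle,
    cost_medication_initial = cost_medication_initial,
    cost_medication_cycle = cost_medication_cycle,
    u_remission = u_remission,
    u_t2dm = u_t2dm,
    p_relapse = p_relapse,
    mu_remission = mu_remission,
    mu_t2dm = mu_t2dm,
    init_remission_surgery = init_remission_surgery,
    init_remission_medication = init_remission_medication,
    rate = rate,
    horizon = horizon,
    wtp = wtp
  )
  validate_inputs(x)
  structure(x, class = "model_inputs")
}

validate_inputs <- function(x) {
  probs <- c(
    "u_remission", "u_t2dm", "p_relapse", "mu_remission", "mu_t2dm",
    "init_remission_surgery", "init_remission_medication"
  )
  for (nm in probs) {
    if (x[[nm]] < 0 || x[[nm]] > 1) {
      abort(sprintf("`%s` = %g must lie in [0, 1]", nm, x[[nm]]))
    }
  }
  costs <- grep("^cost_", names(x), value = TRUE)
  for (nm in costs) {
    if (x[[nm]] < 0) abort(sprintf("`%s` must be nonnegative", nm))
  }
  if (x$rate < 0) abort("`rate` must be nonnegative")
  if (x$horizon < 1) abort("`horizon` must be at least 1")
  if (x$wtp < 0) abort("`wtp` must be nonnegative")
  invisible(x)
}

#' Update named parameters of a model-inputs object
#'
#' @param inputs A [model_inputs()] object.
#' @param ... Name-value pairs of parameters to replace.
#' @return The updated, revalidated `model_inputs`.
#' @export
set_inputs <- function(inputs, ...) {
  stopifnot(inherits(inputs, "model_inputs"))
  upd <- list(...)
  unknown <- setdiff(names(upd), names(inputs))
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown parameter(s): ", paste(unknown, collapse = ", "),
      "; valid names: ", paste(names(inputs), collapse = ", ")
    ))
  }
  out <- modifyList(unclass(inputs), upd)
  validate_inputs(out)
  structure(out, class = "model_inputs")
}

#' Run the deterministic base case for both strategies
#'
#' Builds the shared transition matrix, runs the Markov cohort trace for
#' each strategy from its observed initial remission share, accrues costs
#' and QALYs under the discounting convention, and compares the strategies.
#'
#' @param inputs A [model_inputs()] object.
#' @return A `base_case` list: `surgery` and `medication`
#'   (`strategy_result`s), `comparison` (a [compare_strategies()] row), and
#'   `crossover` (the [crossover_cycle()] index).
#' @examples
#' bc <- run_base_case(model_inputs())
#' bc$comparison[, c("delta_cost", "delta_qaly", "verdict")]
#' @export
run_base_case <- function(inputs = model_inputs()) {
  stopifnot(inherits(inputs, "model_inputs"))
  tmat <- transition_matrix(inputs$p_relapse, inputs$mu_remission, inputs$mu_t2dm)
  u <- c(remission = inputs$u_remission, t2dm = inputs$u_t2dm, dead = 0)

  arm <- function(init_rem, c0, cc, label) {
    run_markov(initial_distribution(init_rem), tmat, inputs$horizon) %>%
      accrue(
        cost_initial = c0, cost_cycle = cc, utilities = u,
        rate = inputs$rate, strategy = label
      )
  }
  surgery <- arm(
    inputs$init_remission_surgery,
    inputs$cost_surgery_initial, inputs$cost_surgery_cycle, "surgery"
  )
  medication <- arm(
    inputs$init_remission_medication,
    inputs$cost_medication_initial, inputs$cost_medication_cycle, "medication"
  )

  structure(
    list(
      surgery = surgery,
      medication = medication,
      comparison = compare_strategies(surgery, medication, wtp = inputs$wtp),
      crossover = crossover_cycle(surgery, medication)
    ),
    class = "base_case"
  )
}

#' @export
print.base_case <- function(x, ...) {
  print(x$surgery)
  print(x$medication)
  cmp <- x$comparison
  cat(sprintf(
    "incremental (surgery - medication): cost %.2f CNY, QALYs %.3f -> %s\n",
    cmp$delta_cost, cmp$delta_qaly,
    if (cmp$verdict == "a dominant") "surgery dominant" else cmp$verdict
  ))
  if (!is.na(x$crossover)) {
    cat("cumulative discounted cost crossover at cycle", x$crossover, "\n")
  }
  invisible(x)
}

#' @rdname run_base_case
#' @param x,object A `base_case`.
#' @param ... Unused.
#' @export
glance.base_case <- function(object, ...) {
  bind_rows(glance(object$surgery), glance(object$medication))
}

#' @rdname run_base_case
#' @export
tidy.base_case <- function(x, ...) {
  bind_rows(tidy(x$surgery), tidy(x$medication))
}
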