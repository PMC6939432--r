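#' Build the three-state annual transition matrix
#'
#' States are ordered `remission`, `t2dm`, `dead`. Remission patients can
#' relapse to T2DM or die at the non-diabetic mortality; T2DM patients can
#' die at the diabetic mortality; re-remission after the first cycle is not
#' modelled by default (`p_reremission = 0`), since sustained remission is
#' only observed during the initial treatment year. Death is absorbing.
#'
#' @param p_relapse Annual probability remission -> t2dm.
#' @param mu_remission Annual mortality in the remission state (non-diabetic
#'   mortality).
#' @param mu_t2dm Annual mortality in the T2DM state.
#' @param p_reremission Annual probability t2dm -> remission (default 0).
#' @return A 3x3 row-stochastic matrix of class `transition_matrix` with
#'   dimnames `remission`, `t2dm`, `dead`.
#' @examples
#' transition_matrix(0.0025, 0.0062, 0.0204)
#' @export
transition_matrix <- function(p_relapse, mu_remission, mu_t2dm, p_reremission = 0) {
  for (p in c(p_relapse, mu_remission, mu_t2dm, p_reremission)) {
    if (p < 0 || p > 1) abort("all transition probabilities must lie in [0, 1]")
  }
  if (p_relapse + mu_remission > 1) {
    abort("p_relapse + mu_remission exceeds 1: remission row would not be stochastic")
  }
  if (p_reremission + mu_t2dm > 1) {
    abort("p_reremission + mu_t2dm exceeds 1: t2dm row would not be stochastic")
  }
  states <- c("remission", "t2dm", "dead")
  m <- rbind(
    c(1 - p_relapse - mu_remission, p_relapse, mu_remission),
    c(p_reremission, 1 - p_reremission - mu_t2dm, mu_t2dm),
    c(0, 0, 1)
  )
  dimnames(m) <- list(states, states)
  class(m) <- c("transition_matrix", class(m))
  m
}

#' Initial state distribution for a strategy
#'
#' The first model cycle carries the observed end-of-follow-up outcome mix:
#' the fraction of the matched arm in remission versus still diabetic
#' (deaths during follow-up were zero).
#'
#' @param remission Fraction starting in remission.
#' @param t2dm Fraction starting with T2DM (default `1 - remission - dead`).
#' @param dead Fraction dead at entry (default 0).
#' @return Named numeric vector over the three states, summing to 1.
#' @export
initial_distribution <- function(remission, t2dm = 1 - remission - dead, dead = 0) {
  v <- c(remission = remission, t2dm = t2dm, dead = dead)
  if (any(v < -1e-12)) abort("state fractions must be nonnegative")
  if (abs(sum(v) - 1) > 1e-9) abort("state fractions must sum to 1")
  v
}

#' Run the Markov cohort model
#'
#' Propagates the cohort occupancy through `tmat` for `horizon` annual
#' cycles. The returned trace has `horizon + 1` rows: cycle 0 is the initial
#' distribution (the treatment year, whose outcome mix is observed), and
#' each later cycle is the previous row multiplied by the transition matrix.
#'
#' @param init Initial distribution (see [initial_distribution()]).
#' @param tmat A [transition_matrix()].
#' @param horizon Number of transition cycles (years) to simulate,
#'   default 40.
#' @return A `cohort_trace` tibble with columns `cycle` (0..horizon),
#'   `remission`, `t2dm`, `dead`, `alive`.
#' @export
run_markov <- function(init, tmat, horizon = 40) {
  stopifnot(inherits(tmat, "transition_matrix"))
  if (horizon < 1) abort("`horizon` must be at least 1")
  init <- initial_distribution(init[["remission"]], init[["t2dm"]], init[["dead"]])

  tr <- matrix(0, nrow = horizon + 1L, ncol = 3L)
  tr[1L, ] <- init
  for (t in seq_len(horizon)) {
    tr[t + 1L, ] <- tr[t, ] %*% unclass(tmat)
  }
  out <- tibble(
    cycle = 0:horizon,
    remission = tr[, 1L],
    t2dm = tr[, 2L],
    dead = tr[, 3L],
    alive = tr[, 1L] + tr[, 2L]
  )
  class(out) <- c("cohort_trace", class(out))
  out
}

#' Individual-level microsimulation of the cohort model
#'
#' Simulates `n` independent patients through the same transition structure
#' and returns the empirical occupancy trace. This is a Monte-Carlo
#' cross-check of the deterministic cohort propagation, not a modelling
#' surface of its own.
#'
#' @inheritParams run_markov
#' @param n Number of simulated patients.
#' @param seed Integer seed.
#' @return A tibble shaped like a [run_markov()] trace.
#' @export
microsimulate <- function(init, tmat, horizon = 40, n = 1e5, seed = NULL) {
  stopifnot(inherits(tmat, "transition_matrix"))
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(tmat)
  state <- sample.int(3L, n, replace = TRUE, prob = init)
  occ <- matrix(0, nrow = horizon + 1L, ncol = 3L)
  occ[1L, ] <- tabulate(state, 3L) / n
  for (t in seq_len(horizon)) {
    u <- stats::runif(n)
    cum <- t(apply(m, 1, cumsum))
    state <- max.col(u <= cum[state, , drop = FALSE], ties.method = "first")
    occ[t + 1L, ] <- tabulate(state, 3L) / n
  }
  tibble(
    cycle = 0:horizon,
    remission = occ[, 1L], t2dm = occ[, 2L], dead = occ[, 3L],
    alive = occ[, 1L] + occ[, 2L]
  )
}
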