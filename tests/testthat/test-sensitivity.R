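test_that("parameter tables carry bases, ranges and families", {
  sp <- param_specs()
  expect_true(all(sp$low <= sp$base & sp$base <= sp$high))
  expect_equal(sp$base[sp$parameter == "cost_surgery_initial"], 46404.41)
  expect_equal(sp$low[sp$parameter == "u_remission"], 0.76)
  expect_equal(sp$high[sp$parameter == "u_remission"], 1.00)
  expect_true(all(sp$family[grepl("^cost_", sp$parameter)] == "gamma"))
  expect_true(all(sp$family[grepl("^(u_|p_|mu_)", sp$parameter)] == "beta"))
  expect_error(param_specs(parameters = "bogus"), "valid names")
  pct <- param_specs(pct = 0.1)
  expect_equal(
    pct$low[pct$parameter == "cost_surgery_cycle"],
    2766.41 * 0.9
  )
  # probability supports are respected when widening
  wide <- param_specs(pct = 0.2)
  expect_lte(max(wide$high[wide$family == "beta"]), 1)
})

test_that("zero-width bounds collapse the tornado to the base case", {
  tor <- one_way(specs = param_specs(pct = 0))
  expect_true(all(tor$spread < 1e-9))
  expect_true(all(abs(tor$inmb_low - attr(tor, "base_inmb")) < 1e-6))
})

test_that("a single linear parameter's spread equals direct reevaluation", {
  inputs <- model_inputs()
  spec1 <- param_specs(parameters = "cost_surgery_initial")
  tor <- one_way(inputs, specs = spec1, metric = "inmb")
  # direct reevaluation: the initial cost enters the incremental cost
  # linearly with weight 1 (full cohort alive at cycle 0, undiscounted)
  f <- function(v) {
    cmp <- run_base_case(set_inputs(inputs, cost_surgery_initial = v))$comparison
    cmp$wtp * cmp$delta_qaly - cmp$delta_cost
  }
  expect_equal(tor$spread, abs(f(spec1$high) - f(spec1$low)), tolerance = 1e-9)
  expect_equal(tor$spread, spec1$high - spec1$low, tolerance = 1e-6)
})

test_that("sampling respects supports and recovers the base-value moments", {
  specs <- psa_specs()
  draws <- sample_params(specs, n = 10000, seed = 71)
  expect_equal(nrow(draws), 10000)
  for (p in specs$parameter) {
    base <- specs$base[specs$parameter == p]
    mc_se <- sd(draws[[p]]) / sqrt(10000)
    expect_lt(abs(mean(draws[[p]]) - base), 3 * mc_se + 0.01 * base)
  }
  expect_true(all(draws$u_remission >= 0 & draws$u_remission <= 1))
  expect_true(all(draws$cost_surgery_initial >= 0))
  # gamma cost mean within 1% of base at this n
  expect_lt(
    abs(mean(draws$cost_surgery_initial) / 46404.41 - 1), 0.01
  )
})

test_that("degenerate ranges collapse draws to the base value", {
  specs <- param_specs(pct = 0)
  draws <- sample_params(specs, n = 50, seed = 72)
  for (p in specs$parameter) {
    expect_true(all(draws[[p]] == specs$base[specs$parameter == p]))
  }
})

test_that("an infeasibly wide beta range is rejected by name", {
  specs <- param_specs(parameters = "u_remission")
  specs$low <- -5
  specs$high <- 6.8 # SD > sqrt(m(1-m))
  specs$base <- 0.95
  expect_error(sample_params(specs, 10), "u_remission")
})

test_that("a degenerate one-draw PSA reproduces the base case exactly", {
  inputs <- model_inputs()
  psa <- run_psa(inputs, specs = param_specs(pct = 0), n = 1, seed = 73)
  bc <- run_base_case(inputs)$comparison
  expect_equal(psa$draws$delta_cost, bc$delta_cost, tolerance = 1e-9)
  expect_equal(psa$draws$delta_qaly, bc$delta_qaly, tolerance = 1e-9)
  expect_equal(psa$n_rejected, 0L)
})

test_that("PSA means converge to the base case and honour the seed", {
  psa <- run_psa(n = 400, seed = 74)
  d <- psa$draws
  bc <- run_base_case()$comparison
  expect_lt(
    abs(mean(d$delta_cost) - bc$delta_cost),
    3 * sd(d$delta_cost) / sqrt(nrow(d))
  )
  expect_lt(
    abs(mean(d$delta_qaly) - bc$delta_qaly),
    3 * sd(d$delta_qaly) / sqrt(nrow(d))
  )
  again <- run_psa(n = 400, seed = 74)
  expect_equal(d, again$draws)
})

test_that("acceptability curves follow their defining identities", {
  fake_psa <- structure(
    list(
      draws = tibble::tibble(
        delta_cost = c(-100, -50, 20, 80),
        delta_qaly = c(1, 2, 0.5, 1)
      ),
      wtp = 100, n_rejected = 0L, seed = NULL
    ),
    class = "psa_result"
  )
  cc <- ceac(fake_psa, wtp_grid = c(0, 40, 200))
  # lambda = 0: fraction of cost-saving draws
  expect_equal(cc$probability[cc$wtp == 0], 0.5)
  expect_equal(cc$probability[cc$wtp == 40], 0.5)
  expect_equal(cc$probability[cc$wtp == 200], 1)
  # all delta_qaly > 0 here, so the curve is monotone non-decreasing
  expect_true(all(diff(cc$probability) >= 0))
  all_dom <- fake_psa
  all_dom$draws <- tibble::tibble(delta_cost = c(-10, -5), delta_qaly = c(1, 2))
  cc2 <- ceac(all_dom, wtp_grid = seq(0, 1e5, 2e4))
  expect_true(all(cc2$probability == 1))
  expect_error(ceac(fake_psa, wtp_grid = numeric()), "non-empty")
})

test_that("two seeds give overlapping acceptability within binomial error", {
  p1 <- glance(run_psa(n = 250, seed = 75))$p_cost_effective
  p2 <- glance(run_psa(n = 250, seed = 76))$p_cost_effective
  se <- sqrt(0.5 * (p1 * (1 - p1) + p2 * (1 - p2)) / 250 + 1e-6)
  expect_lt(abs(p1 - p2), 4 * se + 0.02)
})
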