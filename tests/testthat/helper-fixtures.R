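# shared fixtures built in code

# tiny balanced spec: both arms share covariate moments, so any between-arm
# difference is pure sampling noise
balanced_spec <- function(n = 40, p_rem = c(surgery = 0.5, medication = 0.1)) {
  cohort_spec(
    n = c(surgery = n, medication = n),
    covariates = tibble::tibble(
      variable = c("age", "bmi", "fpg", "hba1c"),
      surgery_mean = c(40, 35, 9, 8),
      surgery_sd = c(12, 6, 2.5, 1.5),
      medication_mean = c(40, 35, 9, 8),
      medication_sd = c(12, 6, 2.5, 1.5)
    ),
    females = c(surgery = round(n / 2), medication = round(n / 2)),
    p_remission = p_rem
  )
}

# spec with a known logistic assignment rule, for coefficient recovery
confounded_spec <- function(n_s, n_m, beta = c(
                              intercept = -2.5, sex = 0.5, age = -0.02,
                              bmi = 0.08, fpg = 0.05, hba1c = 0.05
                            )) {
  sp <- balanced_spec()
  sp$n <- c(surgery = n_s, medication = n_m)
  sp$females <- c(surgery = round(n_s / 2), medication = round(n_m / 2))
  sp$confounding <- beta
  sp
}

# hand-built strategy_result with prescribed discounted totals
fake_result <- function(cost, qaly, strategy = "x", rate = 0.05, cycles = 2) {
  per_cost <- cost / cycles
  per_qaly <- qaly / cycles
  cyc <- tibble::tibble(
    cycle = seq_len(cycles) - 1L,
    cost = rep(per_cost, cycles), qaly = rep(per_qaly, cycles),
    disc_cost = rep(per_cost, cycles), disc_qaly = rep(per_qaly, cycles),
    cum_cost = cumsum(rep(per_cost, cycles)),
    cum_qaly = cumsum(rep(per_qaly, cycles)),
    cum_disc_cost = cumsum(rep(per_cost, cycles)),
    cum_disc_qaly = cumsum(rep(per_qaly, cycles))
  )
  structure(list(strategy = strategy, rate = rate, cycles = cyc),
    class = "strategy_result"
  )
}

# propensity_model wrapper around given scores, for matcher unit tests
fake_propensity <- function(ids, groups, scores) {
  structure(
    list(scores = tibble::tibble(id = ids, group = groups, score = scores)),
    class = "propensity_model"
  )
}

# independent O(n^2) reference matcher: visits surgery patients in
# descending score order and pairs each with the nearest available
# medication score within the calliper, using explicit matrix scans
reference_match <- function(ids, groups, scores, caliper) {
  trt <- order(-scores[groups == "surgery"])
  tid <- ids[groups == "surgery"][trt]
  tsc <- scores[groups == "surgery"][trt]
  # stable tie-break by id
  o <- order(-tsc, tid)
  tid <- tid[o]
  tsc <- tsc[o]
  cid <- ids[groups == "medication"]
  csc <- scores[groups == "medication"]
  used <- logical(length(cid))
  out <- NULL
  for (i in seq_along(tid)) {
    best <- NA
    bestd <- Inf
    for (j in seq_along(cid)) {
      if (used[j]) next
      d <- abs(tsc[i] - csc[j])
      if (d < bestd) {
        bestd <- d
        best <- j
      }
    }
    if (!is.na(best) && bestd <= caliper) {
      used[best] <- TRUE
      out <- rbind(out, data.frame(
        surgery_id = tid[i], medication_id = cid[best],
        distance = bestd
      ))
    }
  }
  out
}
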