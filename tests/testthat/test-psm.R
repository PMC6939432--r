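test_that("null model fits scores near the treatment prevalence", {
  ch <- generate_cohort(balanced_spec(n = 300), seed = 21)
  pm <- fit_propensity(ch)
  expect_s3_class(pm, "propensity_model")
  expect_true(all(pm$scores$score > 0 & pm$scores$score < 1))
  prevalence <- mean(ch$group == "surgery")
  expect_lt(abs(mean(pm$scores$score) - prevalence), 1e-6) # logistic MLE property
  expect_lt(sd(pm$scores$score), 0.1) # no real signal to exploit
})

test_that("fitted scores equal the inverse-logit of the linear predictor", {
  ch <- generate_cohort(cohort_spec_unmatched(), seed = 22)
  pm <- fit_propensity(ch)
  X <- cbind(1, as.matrix(ch[, pm$covariates]))
  expect_equal(pm$scores$score, unname(plogis(drop(X %*% pm$coefficients))),
    tolerance = 1e-10
  )
})

test_that("assignment coefficients are recovered on a large simulated cohort", {
  truth <- c(
    intercept = -2.5, sex = 0.5, age = -0.02,
    bmi = 0.08, fpg = 0.05, hba1c = 0.05
  )
  sp <- confounded_spec(2500, 2500, beta = truth)
  ch <- generate_cohort(sp, seed = 23)
  pm <- fit_propensity(ch)
  est <- tidy(pm)
  # oracle: the generator's own coefficients
  for (term in c("sex", "age", "bmi", "fpg", "hba1c")) {
    row <- est[est$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 2 * row$std.error + 0.01)
  }
})

test_that("missing covariates and rank deficiency are diagnosed", {
  ch <- generate_cohort(balanced_spec(n = 30), seed = 24)
  expect_error(fit_propensity(ch, covariates = c("age", "nope")), "nope")
  ch$bmi2 <- ch$bmi * 2
  expect_error(
    fit_propensity(ch, covariates = c("bmi", "bmi2")),
    "rank deficient"
  )
})

test_that("identical score vectors match everyone at distance zero", {
  n <- 8
  pm <- fake_propensity(
    ids = sprintf("P%02d", 1:(2 * n)),
    groups = rep(c("surgery", "medication"), each = n),
    scores = rep(seq(0.2, 0.8, length.out = n), 2)
  )
  mp <- match_caliper(pm, caliper = 0.03)
  expect_equal(nrow(mp$pairs), n)
  expect_true(all(mp$pairs$distance == 0))
  expect_length(mp$discarded, 0)
})

test_that("a zero calliper with distinct scores yields no pairs", {
  pm <- fake_propensity(
    ids = c("a", "b", "c", "d"),
    groups = c("surgery", "surgery", "medication", "medication"),
    scores = c(0.31, 0.52, 0.40, 0.61)
  )
  mp <- match_caliper(pm, caliper = 0)
  expect_equal(nrow(mp$pairs), 0)
  expect_setequal(mp$discarded, c("a", "b", "c", "d"))
})

test_that("greedy matching agrees with the exhaustive reference matcher", {
  set.seed(31)
  for (rep in 1:25) {
    n_t <- sample(3:10, 1)
    n_c <- sample(3:10, 1)
    ids <- sprintf("P%02d", seq_len(n_t + n_c))
    groups <- rep(c("surgery", "medication"), c(n_t, n_c))
    scores <- round(runif(n_t + n_c, 0.05, 0.95), 3)
    pm <- fake_propensity(ids, groups, scores)
    mp <- match_caliper(pm, caliper = 0.1)
    ref <- reference_match(ids, groups, scores, caliper = 0.1)
    if (is.null(ref)) {
      expect_equal(nrow(mp$pairs), 0)
    } else {
      expect_equal(nrow(mp$pairs), nrow(ref))
      expect_equal(
        mp$pairs[order(mp$pairs$surgery_id), c("surgery_id", "medication_id")],
        tibble::as_tibble(ref[order(ref$surgery_id), c("surgery_id", "medication_id")])
      )
    }
  }
})

test_that("matching respects the calliper and never reuses a patient", {
  set.seed(32)
  for (rep in 1:20) {
    ch <- generate_cohort(cohort_spec_unmatched())
    mp <- match_caliper(fit_propensity(ch), caliper = 0.03)
    p <- mp$pairs
    expect_true(all(p$distance <= 0.03 + 1e-12))
    expect_equal(anyDuplicated(c(p$surgery_id, p$medication_id)), 0)
    expect_lte(nrow(p), 81)
    # discarded + matched partition the cohort
    expect_equal(
      sort(c(mp$discarded, p$surgery_id, p$medication_id)),
      sort(ch$id)
    )
  }
})

test_that("matching is invariant to id relabelling when scores are distinct", {
  set.seed(33)
  ch <- generate_cohort(cohort_spec_unmatched())
  pm <- fit_propensity(ch)
  mp1 <- match_caliper(pm)
  perm <- sample(nrow(ch))
  relabel <- setNames(sprintf("Q%03d", seq_len(nrow(ch))), ch$id[perm])
  pm2 <- fake_propensity(
    unname(relabel[pm$scores$id]), as.character(pm$scores$group), pm$scores$score
  )
  mp2 <- match_caliper(pm2)
  expect_equal(nrow(mp1$pairs), nrow(mp2$pairs))
  expect_equal(
    sort(unname(relabel[mp1$pairs$surgery_id])),
    sort(mp2$pairs$surgery_id)
  )
})

test_that("matching reduces covariate imbalance on confounded cohorts", {
  set.seed(34)
  improved <- logical(100)
  for (rep in seq_len(100)) {
    ch <- generate_cohort(confounded_spec(100, 100))
    mp <- match_caliper(fit_propensity(ch), caliper = 0.05)
    if (nrow(mp$pairs) < 10) {
      improved[rep] <- NA
      next
    }
    bal <- balance_report(ch, mp)
    bal <- bal[bal$type != "outcome", ]
    msd <- tapply(abs(bal$smd), bal$phase, mean)
    improved[rep] <- msd[["after"]] < msd[["before"]]
  }
  expect_gt(mean(improved, na.rm = TRUE), 0.9)
})

test_that("an empty pairing flags the after-matching section as undefined", {
  pm <- fake_propensity(
    ids = c("a", "b", "c", "d"),
    groups = c("surgery", "surgery", "medication", "medication"),
    scores = c(0.9, 0.95, 0.05, 0.1)
  )
  mp <- match_caliper(pm, caliper = 0.01)
  expect_equal(nrow(mp$pairs), 0)
  ch <- generate_cohort(balanced_spec(n = 2), seed = 1)
  ch$id <- c("a", "b", "c", "d")
  bal <- balance_report(ch, mp)
  expect_true(attr(bal, "after_undefined"))
  expect_true(all(is.na(bal$smd[bal$phase == "after"])))
})
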