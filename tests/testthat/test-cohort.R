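test_that("spec validation names the offending field", {
  sp <- cohort_spec_unmatched()
  expect_s3_class(sp, "cohort_spec")
  bad_cov <- sp$covariates
  bad_cov$surgery_sd[1] <- 0
  expect_error(
    cohort_spec(sp$n, bad_cov, sp$females, sp$p_remission),
    "SDs"
  )
  expect_error(
    cohort_spec(sp$n, sp$covariates, c(surgery = 200, medication = 27), sp$p_remission),
    "females"
  )
  expect_error(
    cohort_spec(sp$n, sp$covariates, sp$females, c(surgery = 1.2, medication = 0)),
    "p_remission"
  )
  expect_error(
    cohort_spec(
      c(surgery = 1, medication = 81), sp$covariates,
      c(surgery = 1, medication = 27), sp$p_remission
    ),
    "at least 2"
  )
})

test_that("generated cohorts have exact arm sizes and are seed-reproducible", {
  sp <- cohort_spec_unmatched()
  ch <- generate_cohort(sp, seed = 11)
  expect_equal(nrow(ch), 215)
  expect_equal(sum(ch$group == "surgery"), 134)
  expect_equal(sum(ch$group == "medication"), 81)
  expect_true(all(ch$age > 0 & ch$bmi > 0 & ch$fpg > 0 & ch$hba1c > 0))
  expect_true(all(levels(ch$outcome_2yr) == c("remission", "t2dm", "death")))
  # no deaths at the 2-year outcome under the default spec
  expect_equal(sum(ch$outcome_2yr == "death"), 0)
  expect_identical(ch, generate_cohort(sp, seed = 11))
  expect_false(identical(ch, generate_cohort(sp, seed = 12)))
})

test_that("degenerate remission probability yields all-t2dm outcomes", {
  sp <- balanced_spec(p_rem = c(surgery = 0, medication = 0))
  ch <- generate_cohort(sp, seed = 3)
  expect_true(all(ch$outcome_2yr == "t2dm"))
})

test_that("replicate surgery-arm BMI means converge on the target moment", {
  # oracle: sample-mean convergence; target is the spec mean
  sp <- cohort_spec_unmatched()
  set.seed(101)
  reps <- replicate(200, {
    ch <- generate_cohort(sp)
    mean(ch$bmi[ch$group == "surgery"])
  })
  mc_se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 36.47), 3 * mc_se)
})

test_that("empirical remission fraction converges to the spec probability", {
  sp <- balanced_spec(n = 4000, p_rem = c(surgery = 0.53, medication = 0.049))
  ch <- generate_cohort(sp, seed = 7)
  fr <- tapply(ch$outcome_2yr == "remission", ch$group, mean)
  expect_lt(abs(fr[["surgery"]] - 0.53), 3 * sqrt(0.53 * 0.47 / 4000))
  expect_lt(abs(fr[["medication"]] - 0.049), 3 * sqrt(0.049 * 0.951 / 4000))
})

test_that("with equal arm moments, between-arm tests reject at the nominal rate", {
  set.seed(42)
  pvals <- replicate(200, {
    ch <- generate_cohort(balanced_spec(n = 30))
    summarize_cohort(ch)$p_value[2] # age row
  })
  rate <- mean(pvals < 0.05)
  # binomial(200, 0.05): 3 SE band around the nominal level
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.01)
})

test_that("summaries echo generator targets and report test p-values", {
  sp <- cohort_spec_unmatched()
  sp$n <- c(surgery = 4000, medication = 4000)
  sp$females <- c(surgery = 1940, medication = 1333)
  ch <- generate_cohort(sp, seed = 5)
  sm <- summarize_cohort(ch)
  bmi <- sm[sm$variable == "bmi", ]
  expect_lt(abs(bmi$surgery_mean - 36.47), 3 * 8.15 / sqrt(4000))
  expect_lt(abs(bmi$surgery_sd - 8.15), 0.4)
  expect_lt(abs(bmi$medication_mean - 33.65), 3 * 4.12 / sqrt(4000))
  expect_true(all(c("p_value", "smd", "test") %in% names(sm)))
  expect_equal(attr(sm, "n"), c(surgery = 4000, medication = 4000))
})

test_that("identical copied arms give zero standardized differences", {
  ch <- generate_cohort(balanced_spec(n = 25), seed = 9)
  surg <- ch[ch$group == "surgery", ]
  twin <- surg
  twin$group <- factor("medication", levels = c("surgery", "medication"))
  twin$id <- paste0("M", twin$id)
  sm <- summarize_cohort(rbind(surg, twin))
  expect_true(all(abs(sm$smd) < 1e-12))
})

test_that("remission fraction of 22 in 41 is reported as 0.5366", {
  sm_frac <- 22 / 41
  ch <- generate_cohort(balanced_spec(n = 41), seed = 2)
  ch$outcome_2yr[ch$group == "surgery"] <-
    factor(rep(c("remission", "t2dm"), c(22, 19)), levels = levels(ch$outcome_2yr))
  sm <- summarize_cohort(ch)
  expect_equal(sm$surgery_mean[sm$variable == "remission_2yr"], sm_frac, tolerance = 1e-12)
})

test_that("single-arm input is rejected", {
  ch <- generate_cohort(balanced_spec(n = 10), seed = 1)
  expect_error(summarize_cohort(ch[ch$group == "surgery", ]), "both")
})

test_that("cohort CSV round-trips", {
  ch <- generate_cohort(balanced_spec(n = 15), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(ch), tolerance = 1e-12)
})
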