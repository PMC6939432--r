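#' Fit a propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment (surgery = 1) on the
#' chosen baseline covariates, the standard first stage of propensity-score
#' matching. Perfect separation and rank deficiency are surfaced as errors
#' rather than silently returning a diverged fit.
#'
#' @param cohort Patient tibble (see [generate_cohort()]).
#' @param covariates Character vector of covariate column names; defaults to
#'   the five baseline variables used in the matched analysis.
#' @return A `propensity_model`: the underlying `glm` fit plus a `scores`
#'   tibble (`id`, `group`, `score`) with every fitted score strictly
#'   inside (0, 1). Supports [tidy()] and [glance()].
#' @export
fit_propensity <- function(cohort, covariates = c("sex", "age", "bmi", "fpg", "hba1c")) {
  cohort <- as_tibble(cohort)
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0) {
    abort(paste0("covariates not present in cohort: ", paste(missing_cov, collapse = ", ")))
  }
  treat <- as.integer(as.character(cohort$group) == "surgery")
  if (length(unique(treat)) < 2) abort("both treatment groups must be present")

  X <- stats::model.matrix(
    ~., data = as.data.frame(cohort[, covariates, drop = FALSE])
  )
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank deficient; drop collinear covariates")
  }

  df <- data.frame(.treat = treat, cohort[, covariates, drop = FALSE])
  fit <- glm(
    stats::reformulate(covariates, response = ".treat"),
    family = binomial(), data = df
  )
  scores <- stats::fitted(fit)
  eps <- 1e-8
  if (any(scores < eps | scores > 1 - eps) || !fit$converged) {
    abort("propensity fit did not converge cleanly (possible perfect separation)")
  }

  structure(
    list(
      fit = fit,
      covariates = covariates,
      coefficients = stats::coef(fit),
      scores = tibble(
        id = cohort$id,
        group = cohort$group,
        score = unname(scores)
      )
    ),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model: surgery ~", paste(x$covariates, collapse = " + "), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_propensity
#' @param x,object A `propensity_model`.
#' @param ... Unused.
#' @export
tidy.propensity_model <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    statistic = co[, "z value"],
    p.value = co[, "Pr(>|z|)"]
  )
}

#' @rdname fit_propensity
#' @export
glance.propensity_model <- function(object, ...) {
  fit <- object$fit
  tibble(
    n = length(fit$y),
    logLik = as.numeric(stats::logLik(fit)),
    AIC = stats::AIC(fit),
    deviance = stats::deviance(fit),
    df.residual = fit$df.residual
  )
}

#' Calliper-restricted 1:1 nearest-neighbour matching
#'
#' Greedy matching without replacement on the propensity score: surgery
#' patients are visited in descending score order (ties broken by id), each
#' is paired with the closest still-unmatched medication patient whose score
#' lies within the calliper (on the probability scale by default), and
#' patients left without a counterpart are discarded. An empty pairing is a
#' valid result.
#'
#' @param model A [fit_propensity()] result.
#' @param caliper Maximum |score difference| allowed within a pair
#'   (default 0.03 on the probability scale).
#' @param scale `"probability"` (default) matches on the fitted probability;
#'   `"logit_sd"` interprets `caliper` as a multiple of the SD of the logit
#'   scores and matches on the logit scale.
#' @return A `matched_pairs` object: `pairs` tibble (`surgery_id`,
#'   `medication_id`, `surgery_score`, `medication_score`, `distance`),
#'   `discarded` ids, and the calliper used (in matching-scale units).
#' @export
match_caliper <- function(model, caliper = 0.03,
                          scale = c("probability", "logit_sd")) {
  stopifnot(inherits(model, "propensity_model"))
  scale <- match.arg(scale)
  if (caliper < 0) abort("`caliper` must be nonnegative")

  sc <- model$scores
  if (scale == "logit_sd") {
    sc$match_score <- qlogis(sc$score)
    width <- caliper * sd(sc$match_score)
  } else {
    sc$match_score <- sc$score
    width <- caliper
  }

  trt <- sc %>%
    filter(.data$group == "surgery") %>%
    arrange(dplyr::desc(.data$match_score), .data$id)
  ctl <- sc %>% filter(.data$group == "medication")

  avail <- rep(TRUE, nrow(ctl))
  pairs <- vector("list", nrow(trt))
  for (i in seq_len(nrow(trt))) {
    d <- abs(ctl$match_score - trt$match_score[i])
    d[!avail] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= width) {
      avail[j] <- FALSE
      pairs[[i]] <- tibble(
        surgery_id = trt$id[i],
        medication_id = ctl$id[j],
        surgery_score = trt$score[i],
        medication_score = ctl$score[j],
        distance = d[j]
      )
    }
  }
  pairs <- bind_rows(pairs)
  if (nrow(pairs) == 0) {
    pairs <- tibble(
      surgery_id = character(), medication_id = character(),
      surgery_score = numeric(), medication_score = numeric(),
      distance = numeric()
    )
  }
  matched_ids <- c(pairs$surgery_id, pairs$medication_id)

  structure(
    list(
      pairs = pairs,
      caliper = width,
      scale = scale,
      discarded = setdiff(sc$id, matched_ids)
    ),
    class = "matched_pairs"
  )
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(
    nrow(x$pairs), "matched pairs (calliper", format(x$caliper, digits = 4),
    "on the", x$scale, "scale),", length(x$discarded), "patients discarded\n"
  )
  invisible(x)
}

#' Subset a cohort to its matched patients
#'
#' @param cohort Patient tibble.
#' @param pairs A [match_caliper()] result.
#' @return The rows of `cohort` belonging to a matched pair.
#' @export
matched_cohort <- function(cohort, pairs) {
  stopifnot(inherits(pairs, "matched_pairs"))
  keep <- c(pairs$pairs$surgery_id, pairs$pairs$medication_id)
  as_tibble(cohort) %>% filter(.data$id %in% keep)
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences and between-arm test p-values for every
#' covariate, computed on the full cohort (`before`) and on the matched
#' subset (`after`). With an empty pairing the `after` rows are returned
#' with `NA` values and the result carries attribute
#' `after_undefined = TRUE`.
#'
#' @param cohort Patient tibble.
#' @param pairs A [match_caliper()] result whose ids all occur in `cohort`.
#' @return A tibble: `phase` (before/after), plus the columns of
#'   [summarize_cohort()].
#' @export
balance_report <- function(cohort, pairs) {
  stopifnot(inherits(pairs, "matched_pairs"))
  cohort <- as_tibble(cohort)
  ids <- c(pairs$pairs$surgery_id, pairs$pairs$medication_id)
  if (!all(ids %in% cohort$id)) abort("`pairs` reference ids absent from `cohort`")

  before <- summarize_cohort(cohort) %>% mutate(phase = "before", .before = 1)
  if (nrow(pairs$pairs) >= 2) {
    after <- summarize_cohort(matched_cohort(cohort, pairs)) %>%
      mutate(phase = "after", .before = 1)
    undefined <- FALSE
  } else {
    after <- before %>%
      mutate(
        phase = "after",
        dplyr::across(
          c("surgery_mean", "surgery_sd", "medication_mean", "medication_sd", "smd", "p_value"),
          ~ NA_real_
        )
      )
    undefined <- TRUE
  }
  out <- bind_rows(before, after)
  attr(out, "after_undefined") <- undefined
  out
}
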