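# Final severity prediction. A logistic model of the binary severity label
# (grade <= 4: hospitalized with any respiratory support) on the
# percentile-normalised IPGS, age in decades, and sex, fitted with
# inverse-class-frequency sample weights; the age+sex baseline and the
# IPGS-only variant share the machinery. Evaluation reports the four
# confusion-matrix metrics at a 0.5 probability threshold with the severe
# class positive; significance of the IPGS contribution comes from an
# empirical null built by shuffling the IPGS column in the test set.

.sev_predictors <- c("ipgs_percentile", "age_decades", "sex")

# design matrix for a predictor subset; sex coded 1 = male
.sev_design <- function(data, predictors) {
  d <- as_tibble(data)
  if (!"age_decades" %in% names(d) && "age" %in% names(d)) {
    d$age_decades <- d$age / 10
  }
  cols <- lapply(predictors, function(p) {
    if (!p %in% names(d)) abort(paste0("predictor column missing: ", p),
                                class = "ipgs_config_error")
    if (p == "sex") as.integer(d$sex == "M") else as.numeric(d[[p]])
  })
  mm <- do.call(cbind, cols)
  colnames(mm) <- predictors
  mm
}

.sev_response <- function(data) {
  d <- as_tibble(data)
  if ("severe" %in% names(d)) return(as.integer(d$severe))
  if ("who_grade" %in% names(d)) return(as.integer(d$who_grade <= 4L))
  abort("data needs a `severe` (or `who_grade`) column", class = "ipgs_config_error")
}

#' Fit a weighted logistic severity model
#'
#' Maximum-likelihood logistic regression of the binary severity label on
#' the chosen predictors, penalising misclassification of the minority
#' class with sample weights inversely proportional to the class
#' frequencies (balanced classes get unit weights). Perfect separation is
#' flagged and resolved by a lightly ridge-penalised refit.
#'
#' @param data tibble with a `severe` (or `who_grade`) column and the
#'   predictor columns (`ipgs_percentile`, `age` or `age_decades`, `sex`,
#'   comorbidity indicators).
#' @param predictors character vector of predictors; the default is the
#'   full IPGS + age + sex model. Use `c("age_decades", "sex")` for the
#'   baseline and `"ipgs_percentile"` for the IPGS-only variant.
#' @param class_weighting `"balanced"` (inverse class frequency, default)
#'   or `"none"`.
#' @return A `severity_fit` object: `coefficients` tibble (`term`,
#'   `estimate`, `std.error`), `predictors`, `class_weighting`,
#'   `separation` flag, and the underlying `glm` fit.
#' @export
fit_severity_model <- function(data, predictors = .sev_predictors,
                               class_weighting = c("balanced", "none")) {
  class_weighting <- match.arg(class_weighting)
  y <- .sev_response(data)
  if (length(unique(y)) < 2L) abort("single-class training labels", class = "ipgs_fit_error")
  X <- .sev_design(data, predictors)
  w <- if (class_weighting == "balanced") {
    tab <- table(factor(y, levels = 0:1))
    unname(length(y) / (2 * tab[as.character(y)]))
  } else rep(1, length(y))
  df <- data.frame(y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", predictors), collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = df, family = binomial(), weights = w),
    warning = function(cond) {
      msg <- conditionMessage(cond)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) separation <<- TRUE
      if (grepl("non-integer #successes|fitted probabilities numerically 0 or 1", msg)) {
        invokeRestart("muffleWarning")
      }
    }
  )
  est <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (separation) {
    warn("perfect separation detected; coefficients from a ridge-penalised refit",
         class = "ipgs_separation_warning")
    rf <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                         lambda = 1e-3, weights = w, standardize = FALSE)
    est <- c(`(Intercept)` = as.numeric(rf$a0),
             setNames(as.numeric(rf$beta), rownames(rf$beta)))
    se <- rep(NA_real_, length(est))
  }
  structure(
    list(
      coefficients = tibble(term = names(est), estimate = unname(est),
                            std.error = unname(se)),
      predictors = predictors,
      class_weighting = class_weighting,
      separation = separation,
      glm = fit
    ),
    class = "severity_fit"
  )
}

#' @export
print.severity_fit <- function(x, ...) {
  cat("<severity_fit> severe ~ ", paste(x$predictors, collapse = " + "),
      " (", x$class_weighting, " weights",
      if (x$separation) ", separation-flagged", ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Predicted severity probability
#' @param object a `severity_fit`.
#' @param newdata tibble with the model's predictor columns.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.severity_fit <- function(object, newdata, ...) {
  X <- .sev_design(newdata, object$predictors)
  est <- setNames(object$coefficients$estimate, object$coefficients$term)
  eta <- est[["(Intercept)"]] + as.numeric(X %*% est[object$predictors])
  plogis(eta)
}

#' Evaluate a severity model on held-out data
#'
#' Confusion-matrix metrics at the given probability threshold, severe as
#' the positive class.
#'
#' @param model a `severity_fit`.
#' @param data held-out tibble with response and predictor columns.
#' @param threshold decision threshold on the predicted probability.
#' @return One-row tibble: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_severity_model <- function(model, data, threshold = 0.5) {
  if (!nrow(data)) abort("empty test set", class = "ipgs_domain_error")
  y <- .sev_response(data)
  pred <- as.integer(predict(model, data) >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  tibble(
    accuracy = (tp + tn) / length(y),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Permutation significance of the IPGS contribution
#'
#' Shuffles the IPGS column within the test set `n_shuffles` times,
#' re-evaluates the *fixed* fitted model on each shuffled copy, and returns
#' one-sided upper-tail empirical p-values (add-one corrected): the
#' probability that a model fed no genuine IPGS information matches the
#' observed metric.
#'
#' @param model fitted `severity_fit` including `ipgs_percentile`.
#' @param data held-out tibble.
#' @param n_shuffles number of shuffles (>= 100 recommended).
#' @param seed integer RNG seed.
#' @param ipgs_col name of the IPGS column to shuffle.
#' @return Tibble with `metric`, `observed`, `null_mean`, `p_value`.
#' @export
permutation_significance <- function(model, data, n_shuffles = 1000L, seed = 1L,
                                     ipgs_col = "ipgs_percentile") {
  if (n_shuffles < 1L) abort("n_shuffles must be >= 1", class = "ipgs_config_error")
  if (n_shuffles < 100L) warn("fewer than 100 shuffles gives a coarse p-value")
  if (!ipgs_col %in% model$predictors) {
    abort("model does not include the IPGS predictor", class = "ipgs_config_error")
  }
  obs <- evaluate_severity_model(model, data)
  metrics <- c("accuracy", "precision", "sensitivity", "specificity")
  set.seed(seed)
  null_mat <- matrix(NA_real_, nrow = n_shuffles, ncol = length(metrics),
                     dimnames = list(NULL, metrics))
  d <- as_tibble(data)
  for (b in seq_len(n_shuffles)) {
    d[[ipgs_col]] <- sample(d[[ipgs_col]])
    null_mat[b, ] <- unlist(evaluate_severity_model(model, d)[metrics])
  }
  purrr::map_dfr(metrics, function(m) {
    nv <- null_mat[, m]
    tibble(
      metric = m,
      observed = obs[[m]],
      null_mean = mean(nv, na.rm = TRUE),
      p_value = (1 + sum(nv >= obs[[m]], na.rm = TRUE)) / (n_shuffles + 1)
    )
  })
}

#' Compare IPGS distributions between severity classes
#'
#' Welch two-sample t-test of the IPGS score between severe and non-severe
#' patients, overall and stratified by sex.
#'
#' @param data tibble with the score column, `severe` (or `who_grade`) and
#'   `sex`.
#' @param score_col score column name (default `raw_score`).
#' @return Tibble with `stratum`, `n_severe`, `n_mild`, `mean_severe`,
#'   `mean_mild`, `statistic`, `p_value`.
#' @export
score_distribution_test <- function(data, score_col = "raw_score") {
  d <- as_tibble(data)
  if (!score_col %in% names(d)) abort(paste0("no column ", score_col),
                                      class = "ipgs_config_error")
  d$..y <- .sev_response(d)
  one <- function(dd, stratum) {
    xs <- dd[[score_col]][dd$..y == 1L]
    xm <- dd[[score_col]][dd$..y == 0L]
    if (length(xs) < 2L || length(xm) < 2L) {
      abort(paste0("need >= 2 samples per class in stratum ", stratum),
            class = "ipgs_domain_error")
    }
    tt <- t.test(xs, xm)
    tibble(stratum = stratum, n_severe = length(xs), n_mild = length(xm),
           mean_severe = mean(xs), mean_mild = mean(xm),
           statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  out <- one(d, "all")
  for (s in sort(unique(d$sex))) out <- bind_rows(out, one(d[d$sex == s, ], s))
  out
}

#' Odds-ratio analysis of severity predictors
#'
#' Logistic-regression odds ratios for severe outcome with Wald 95%
#' confidence intervals; age enters in decades. `"univariate"` fits one
#' model per predictor; `"multivariate"` fits IPGS + age + sex jointly;
#' `"multivariate_comorbidities"` additionally adjusts for the comorbidity
#' indicator columns.
#'
#' @param data tibble with `severe` (or `who_grade`), `ipgs_percentile`,
#'   `age` (or `age_decades`), `sex`, and — for the comorbidity mode — the
#'   indicator columns in `comorbidities`.
#' @param mode analysis mode.
#' @param comorbidities names of 0/1 comorbidity columns.
#' @return Tibble with `mode`, `term`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
odds_ratio_analysis <- function(data,
                                mode = c("univariate", "multivariate",
                                         "multivariate_comorbidities"),
                                comorbidities = c("heart_failure",
                                                  "asthma_copd_osas",
                                                  "diabetes", "hypertension",
                                                  "cancer")) {
  mode <- match.arg(mode)
  d <- as_tibble(data)
  y <- .sev_response(d)
  base <- c("ipgs_percentile", "age_decades", "sex")
  preds <- switch(mode,
    univariate = as.list(base),
    multivariate = list(base),
    multivariate_comorbidities = {
      missing_cols <- setdiff(comorbidities, names(d))
      if (length(missing_cols)) {
        abort(paste0("comorbidity column(s) missing: ",
                     paste(missing_cols, collapse = ", ")),
              class = "ipgs_config_error")
      }
      list(c(base, comorbidities))
    }
  )
  purrr::map_dfr(preds, function(p) {
    X <- .sev_design(d, p)
    df <- data.frame(y = y, X, check.names = FALSE)
    fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", p), collapse = " + ")))
    fit <- glm(fml, data = df, family = binomial())
    sm <- summary(fit)$coefficients
    keep <- rownames(sm) != "(Intercept)"
    tibble(
      mode = mode,
      term = gsub("`", "", rownames(sm)[keep]),
      odds_ratio = exp(sm[keep, "Estimate"]),
      ci_low = exp(sm[keep, "Estimate"] - 1.96 * sm[keep, "Std. Error"]),
      ci_high = exp(sm[keep, "Estimate"] + 1.96 * sm[keep, "Std. Error"]),
      p_value = sm[keep, "Pr(>|z|)"]
    )
  })
}
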