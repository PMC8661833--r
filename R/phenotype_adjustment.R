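# Age/sex-adjusted phenotype. Per sex, a proportional-odds (ordinal
# logistic) model predicts the 6-grade outcome from age alone; each sample's
# expected grade is the cutpoint interval containing its linear predictor.
# Samples whose actual grade equals the expected grade are excluded; the
# rest are labelled more_severe / less_severe than expected. Under the
# 1 = death ... 6 = not hospitalized coding, "more severe than expected"
# means actual_grade < expected_grade. This binary label — not the raw
# severity — is the outcome of the LASSO feature selection, which isolates
# patients whose outcome deviates from their age/sex expectation.

#' Fit the per-sex ordinal age model
#'
#' Proportional-odds logistic regression of the 6-grade outcome on age
#' (single predictor), fitted by maximum likelihood. The latent scale
#' follows the convention `logit P(grade <= k) = zeta_k - slope * age`, so
#' with grades ordered 1 (death) < ... < 6 (not hospitalized) a negative
#' slope means older patients are expected to be more severe. Grades absent
#' from the data collapse their cutpoints with a warning. If age carries no
#' information (single distinct age), the slope is set to 0 with a warning.
#'
#' @param phenotypes validated phenotype tibble (see [as_phenotype_table()]).
#' @param sex which stratum to fit, `"M"` or `"F"`.
#' @param age_scale `"years"` (raw, default) or `"decades"`.
#' @return An `ordinal_age_model` object with `sex`, `slope`, `cutpoints`
#'   (named by the grade boundaries present), `grades` (levels present),
#'   and `age_scale`.
#' @export
fit_ordinal_age_model <- function(phenotypes, sex = c("M", "F"),
                                  age_scale = c("years", "decades")) {
  sex <- match.arg(sex)
  age_scale <- match.arg(age_scale)
  p <- as_phenotype_table(phenotypes) %>% filter(.data$sex == !!sex)
  if (!nrow(p)) abort(paste0("no samples of sex ", sex), class = "ipgs_fit_error")
  if (any(!is.finite(p$age))) abort("ages must be finite", class = "ipgs_fit_error")
  grades <- sort(unique(p$who_grade))
  if (length(grades) < 2L) {
    abort("ordinal fit needs >= 2 distinct outcome grades", class = "ipgs_fit_error")
  }
  if (length(grades) < 6L) {
    warn(paste0("grade level(s) ", paste(setdiff(1:6, grades), collapse = ", "),
                " absent for sex ", sex, "; their cutpoints collapse"),
         class = "ipgs_degenerate_warning")
  }
  age <- if (age_scale == "decades") p$age / 10 else p$age
  y <- factor(p$who_grade, levels = grades, ordered = TRUE)
  if (length(unique(age)) < 2L) {
    warn("age is constant; slope unidentifiable, set to 0",
         class = "ipgs_degenerate_warning")
    # cutpoints from the marginal grade distribution
    cum <- cumsum(prop.table(table(y)))
    zeta <- qlogis(pmin(pmax(cum[-length(cum)], 1e-12), 1 - 1e-12))
    fit <- NULL
    slope <- 0
  } else {
    dat <- data.frame(y = y, age = age)
    fit <- tryCatch(
      suppressWarnings(MASS::polr(y ~ age, data = dat, Hess = FALSE)),
      error = function(e) {
        # default starting values can fail on (near-)deterministic grades;
        # restart from the zero-slope marginal solution
        cum <- cumsum(prop.table(table(y)))
        zeta0 <- qlogis(pmin(pmax(cum[-length(cum)], 1e-6), 1 - 1e-6))
        suppressWarnings(MASS::polr(y ~ age, data = dat, Hess = FALSE,
                                    start = c(0, zeta0)))
      }
    )
    slope <- unname(coef(fit)[["age"]])
    zeta <- unname(fit$zeta)
  }
  structure(
    list(sex = sex, slope = slope, cutpoints = zeta, grades = grades,
         age_scale = age_scale, fit = fit),
    class = "ordinal_age_model"
  )
}

#' @export
print.ordinal_age_model <- function(x, ...) {
  cat("<ordinal_age_model sex=", x$sex, "> slope(", x$age_scale, ") = ",
      signif(x$slope, 4), "; cutpoints: ",
      paste(signif(x$cutpoints, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# expected grade = cutpoint interval containing the linear predictor
# (the modal category under proportional odds with a single predictor)
.expected_grade <- function(model, age) {
  a <- if (model$age_scale == "decades") age / 10 else age
  eta <- model$slope * a
  # grade k iff zeta_{k-1} < eta <= zeta_k
  idx <- findInterval(eta, model$cutpoints, left.open = TRUE) + 1L
  model$grades[idx]
}

#' Adjust phenotypes against the per-sex ordinal age expectation
#'
#' Computes each sample's expected outcome grade from its sex's fitted
#' ordinal age model, excludes samples whose actual grade matches the
#' expectation, and labels the rest `more_severe` or `less_severe` than
#' expected (numerically smaller grade = more severe).
#'
#' @param phenotypes validated phenotype tibble.
#' @param models named list of [fit_ordinal_age_model()] fits, one per sex
#'   present (names `"M"`/`"F"`). Fitted automatically when `NULL`.
#' @return Tibble with `sample_id`, `sex`, `age`, `actual_grade`,
#'   `expected_grade`, `label` (`more_severe`/`less_severe`/`excluded`).
#' @export
adjust_phenotypes <- function(phenotypes, models = NULL) {
  p <- as_phenotype_table(phenotypes)
  sexes <- unique(p$sex)
  if (is.null(models)) {
    models <- lapply(setNames(sexes, sexes), function(s) fit_ordinal_age_model(p, s))
  }
  missing_models <- setdiff(sexes, names(models))
  if (length(missing_models)) {
    abort(paste0("no ordinal model for sex ", paste(missing_models, collapse = ", ")),
          class = "ipgs_fit_error")
  }
  out <- p %>%
    group_by(.data$sex) %>%
    mutate(expected_grade = .expected_grade(models[[.data$sex[1]]], .data$age)) %>%
    ungroup() %>%
    mutate(
      actual_grade = .data$who_grade,
      label = dplyr::case_when(
        .data$actual_grade == .data$expected_grade ~ "excluded",
        .data$actual_grade < .data$expected_grade ~ "more_severe",
        TRUE ~ "less_severe"
      )
    ) %>%
    select("sample_id", "sex", "age", "actual_grade", "expected_grade", "label") %>%
    arrange(.data$sample_id)
  out
}

#' Write an adjusted-phenotype table
#' @param adjusted tibble from [adjust_phenotypes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_adjusted_phenotypes <- function(adjusted, path) {
  writeLines(.io_header("adjusted_phenotypes"), path)
  readr::write_tsv(adjusted, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
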