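# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_density geom_col geom_line
#'   geom_point geom_errorbar labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Tidy a severity model fit
#' @param x a `severity_fit`.
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `odds_ratio`.
#' @export
tidy.severity_fit <- function(x, ...) {
  mutate(x$coefficients, odds_ratio = exp(.data$estimate))
}

#' @rdname tidy.severity_fit
#' @return For `glance()`: one-row tibble with the predictor set, weighting
#'   scheme and separation flag.
#' @export
glance.severity_fit <- function(x, ...) {
  tibble(predictors = paste(x$predictors, collapse = "+"),
         class_weighting = x$class_weighting,
         separation = x$separation,
         n = length(x$glm$y),
         deviance = unname(x$glm$deviance))
}

#' Tidy an ordinal age model
#' @param x an `ordinal_age_model`.
#' @param ... unused.
#' @return Tibble with one row per parameter (slope, then cutpoints).
#' @export
tidy.ordinal_age_model <- function(x, ...) {
  bind_rows(
    tibble(term = paste0("age_", x$age_scale), estimate = x$slope),
    tibble(term = paste0("cutpoint_", head(x$grades, -1), "|", x$grades[-1]),
           estimate = x$cutpoints)
  )
}

#' Tidy the IPGS weights
#' @param x an `ipgs_weights` object.
#' @param ... unused.
#' @return Tibble with `weight`, `value`.
#' @export
tidy.ipgs_weights <- function(x, ...) {
  tibble(weight = names(unclass(x)), value = as.numeric(x))
}

#' @rdname run_pipeline
#' @param x an `ipgs_pipeline`.
#' @param ... unused.
#' @export
glance.ipgs_pipeline <- function(x, ...) x$summary

#' Plot IPGS distributions by severity class
#'
#' Density of the IPGS (raw or percentile) for severe versus non-severe
#' patients — the visual companion of [score_distribution_test()].
#'
#' @param data tibble with the score column and `severe` (or `who_grade`).
#' @param score_col score column name.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(data, score_col = "raw_score") {
  d <- as_tibble(data)
  d$severe <- factor(ifelse(.sev_response(d) == 1L, "severe", "non-severe"))
  ggplot(d, aes(x = .data[[score_col]], fill = .data$severe)) +
    geom_density(alpha = 0.4) +
    labs(x = "IPGS", y = "density", fill = NULL) +
    theme_minimal()
}

#' Cross-validation curve of a LASSO fit
#' @param object a `lasso_fit`.
#' @param ... unused.
#' @return A ggplot object: mean CV accuracy against the regularisation
#'   strength, with the chosen strength marked.
#' @export
autoplot.lasso_fit <- function(object, ...) {
  cv <- object$cv
  ggplot(cv, aes(x = .data$lambda, y = .data$mean_accuracy)) +
    geom_line() +
    geom_point(data = cv[which.min(abs(cv$lambda - object$lambda)), ],
               colour = "red", size = 2) +
    ggplot2::scale_x_log10() +
    labs(x = "regularisation strength", y = "CV accuracy") +
    theme_minimal()
}

#' Evaluation metrics of the pipeline's models
#' @param object an `ipgs_pipeline`.
#' @param ... unused.
#' @return A ggplot object comparing accuracy, precision, sensitivity and
#'   specificity across the fitted model variants.
#' @export
autoplot.ipgs_pipeline <- function(object, ...) {
  ev <- object$evaluation %>%
    tidyr::pivot_longer(c("accuracy", "precision", "sensitivity", "specificity"),
                        names_to = "metric", values_to = "value")
  ggplot(ev, aes(x = .data$metric, y = .data$value, fill = .data$model)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = NULL, fill = "model") +
    theme_minimal()
}
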