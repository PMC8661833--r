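# End-to-end orchestration: encode -> adjust -> select (+ null threshold,
# per-iteration weight estimation) -> score -> fit -> evaluate -> rank.
# Feature selection and weight fitting use one sample partition; the final
# logistic model is fitted on a second, disjoint partition and evaluated on
# a third — the partitions are checked for overlap, mirroring a training
# protocol in which the severity model is fitted on samples never seen by
# the feature-engineering steps.

#' Run the full IPGS pipeline
#'
#' @param variants validated variant tibble for the cohort.
#' @param phenotypes validated phenotype tibble (one row per sample).
#' @param config configuration from [ipgs_defaults()].
#' @param n_boot bootstrap iterations for selection and the null run.
#' @param seed master seed; every stage derives its RNG stream from it.
#' @param split named fractions (`select`, `fit`, `test`) partitioning the
#'   cohort into the feature-selection set, the severity-model training
#'   set, and the held-out evaluation set. Must sum to 1.
#' @param n_shuffles IPGS shuffles for the permutation significance test.
#' @param weights fixed IPGS weights; `NULL` (default) estimates them as
#'   the medians of the per-bootstrap silhouette optima.
#' @param out_dir optional directory; when given, stage artifacts are
#'   written there as TSV/rnk files.
#' @return An `ipgs_pipeline` list: `partitions`, `adjusted`, `ledger`,
#'   `thresholds`, `final_features`, `weights`, `scores`, `models`,
#'   `evaluation`, `permutation`, `distribution_test`, `odds_ratios`,
#'   `gene_ranking`, `summary`.
#' @export
run_pipeline <- function(variants, phenotypes,
                         config = ipgs_defaults(),
                         n_boot = config$n_boot,
                         seed = 1L,
                         split = c(select = 0.6, fit = 0.25, test = 0.15),
                         n_shuffles = 200L,
                         weights = NULL,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "ipgs_stage_error")
    })
  }
  if (abs(sum(split) - 1) > 1e-8 || !all(c("select", "fit", "test") %in% names(split))) {
    abort("split must be named fractions (select, fit, test) summing to 1",
          class = "ipgs_config_error")
  }
  ph <- as_phenotype_table(phenotypes)
  v <- as_variant_table(variants)

  # --- partition, stratified by the binary severity label ---------------
  set.seed(seed)
  parts <- list(select = character(), fit = character(), test = character())
  for (sv in c(TRUE, FALSE)) {
    ids <- sample(ph$sample_id[ph$severe == sv])
    k <- length(ids)
    n_sel <- round(split[["select"]] * k)
    n_fit <- round(split[["fit"]] * k)
    parts$select <- c(parts$select, ids[seq_len(n_sel)])
    parts$fit <- c(parts$fit, ids[n_sel + seq_len(min(n_fit, k - n_sel))])
    parts$test <- c(parts$test, ids[-seq_len(min(n_sel + n_fit, k))])
  }
  parts <- lapply(parts, sort)
  if (length(Reduce(intersect, parts)) ||
      length(intersect(parts$select, parts$fit)) ||
      length(intersect(parts$select, parts$test)) ||
      length(intersect(parts$fit, parts$test))) {
    abort("sample partitions overlap", class = "ipgs_integrity_error")
  }

  # --- encode the whole cohort ------------------------------------------
  reps <- stage("encode", encode_cohort(v, ph, samples = ph$sample_id, config = config))

  # --- adjusted phenotype on the selection partition --------------------
  ph_sel <- filter(ph, .data$sample_id %in% parts$select)
  adjusted <- stage("adjust", adjust_phenotypes(ph_sel))

  # --- bootstrap selection + null threshold -----------------------------
  ledger <- stage("select",
    bootstrap_select(reps, adjusted, n_boot = n_boot,
                     subsample_frac = config$subsample_frac,
                     seed = seed + 1L, config = config,
                     estimate_weights = is.null(weights)))
  thresholds <- stage("null",
    null_threshold(reps, adjusted, n_boot = n_boot,
                   subsample_frac = config$subsample_frac,
                   seed = seed + 2L,
                   percentile = config$null_percentile, config = config))
  final_features <- stage("finalize", finalize_features(ledger, thresholds))

  w <- if (!is.null(weights)) .as_weights(weights) else {
    est <- attr(ledger, "weights")
    if (is.null(est) || any(is.na(est))) {
      warn("per-bootstrap weight estimation degenerate; using shipped defaults")
      .as_weights(config$default_weights)
    } else est
  }

  # --- scores for the whole cohort --------------------------------------
  scores <- if (nrow(final_features)) {
    stage("score", ipgs_scores(count_components(reps, final_features), w))
  } else {
    warn("no features survived the null threshold; IPGS is 0 for all samples")
    tibble(sample_id = ph$sample_id,
           !!!setNames(rep(list(0L), length(.component_cols)), .component_cols),
           raw_score = 0, percentile_score = 0.5)
  }
  model_data <- ph %>%
    left_join(select(scores, "sample_id", "raw_score", "percentile_score"),
              by = "sample_id") %>%
    rename(ipgs_percentile = "percentile_score") %>%
    mutate(age_decades = .data$age / 10)

  # --- severity models: full, baseline, IPGS-only -----------------------
  d_fit <- filter(model_data, .data$sample_id %in% parts$fit)
  d_test <- filter(model_data, .data$sample_id %in% parts$test)
  models <- stage("fit", list(
    ipgs_age_sex = fit_severity_model(d_fit),
    age_sex = fit_severity_model(d_fit, predictors = c("age_decades", "sex")),
    ipgs_only = fit_severity_model(d_fit, predictors = "ipgs_percentile")
  ))
  evaluation <- stage("evaluate",
    purrr::map_dfr(names(models), function(nm) {
      mutate(evaluate_severity_model(models[[nm]], d_test), model = nm, .before = 1L)
    }))
  permutation <- stage("permute",
    permutation_significance(models$ipgs_age_sex, d_test,
                             n_shuffles = n_shuffles, seed = seed + 3L))
  dist_test <- stage("t-test", score_distribution_test(model_data))
  ors <- stage("odds-ratios", bind_rows(
    odds_ratio_analysis(model_data, "univariate"),
    odds_ratio_analysis(model_data, "multivariate")
  ))
  ranking <- stage("rank", rank_genes(ledger, rank_f = config$rank_f))

  out <- structure(list(
    partitions = parts, adjusted = adjusted, ledger = ledger,
    thresholds = thresholds, final_features = final_features, weights = w,
    scores = scores, models = models, evaluation = evaluation,
    permutation = permutation, distribution_test = dist_test,
    odds_ratios = ors, gene_ranking = ranking,
    summary = tibble(
      n_samples = nrow(ph),
      n_features_total = nrow(ledger),
      n_features_final = nrow(final_features),
      F_LF = w[["F_LF"]], F_R = w[["F_R"]], F_UR = w[["F_UR"]],
      accuracy_ipgs_age_sex = evaluation$accuracy[evaluation$model == "ipgs_age_sex"],
      accuracy_age_sex = evaluation$accuracy[evaluation$model == "age_sex"],
      permutation_p_accuracy = permutation$p_value[permutation$metric == "accuracy"],
      t_test_p = dist_test$p_value[dist_test$stratum == "all"]
    ),
    seed = seed
  ), class = "ipgs_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_adjusted_phenotypes(adjusted, file.path(out_dir, "adjusted_phenotypes.tsv"))
    write_ledger(ledger, file.path(out_dir, "selection_ledger.tsv"))
    write_ledger(thresholds, file.path(out_dir, "null_thresholds.tsv"))
    write_ledger(final_features, file.path(out_dir, "final_features.tsv"))
    write_scores(scores, file.path(out_dir, "ipgs_scores.tsv"))
    write_ledger(evaluation, file.path(out_dir, "evaluation.tsv"))
    if (nrow(ranking)) write_rnk(ranking, file.path(out_dir, "gene_ranking.rnk"))
  }
  out
}

#' @export
print.ipgs_pipeline <- function(x, ...) {
  cat("<ipgs_pipeline> seed ", x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}
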