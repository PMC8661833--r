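# Bootstrap LASSO feature selection. Per bootstrap iteration a 90% subsample
# (without replacement) is drawn; for each of the 12 Boolean representations
# an L1-regularised logistic model of the adjusted phenotype is fitted, with
# the regularisation strength chosen by 10-fold cross-validation over 50
# log-spaced values in [1e-2, 1e1] under a 0.5-SD parsimony rule, then refit
# on the whole subsample. A feature's selection count is the number of
# iterations in which its coefficient is non-zero; the inclusion threshold
# comes from repeating the whole procedure with permuted labels.

# coerce adjusted-phenotype output (or a named vector) to a named 0/1 vector,
# 1 = more severe than expected
.selection_labels <- function(labels) {
  if (is.data.frame(labels)) {
    keep <- labels$label %in% c("more_severe", "less_severe")
    y <- setNames(as.integer(labels$label[keep] == "more_severe"),
                  labels$sample_id[keep])
  } else {
    vals <- as.character(labels)
    if (all(vals %in% c("more_severe", "less_severe", "excluded"))) {
      keep <- vals != "excluded"
      y <- setNames(as.integer(vals[keep] == "more_severe"), names(labels)[keep])
    } else {
      y <- setNames(as.integer(as.numeric(labels) != 0), names(labels))
    }
  }
  if (is.null(names(y)) || any(!nzchar(names(y)))) {
    abort("labels must be named by sample_id", class = "ipgs_selection_error")
  }
  y
}

#' Fit one cross-validated LASSO logistic model
#'
#' L1-regularised logistic regression of a binary adjusted phenotype on a
#' Boolean feature matrix. The regularisation strength is chosen over
#' `lambda_grid` by `cv_folds`-fold cross-validation on classification
#' accuracy, as the *largest* strength whose mean accuracy lies within
#' `sd_rule` standard deviations (across the best grid point's folds) of the
#' best mean accuracy — trading a little score for a sparser model. The
#' model is then refit on all rows at the chosen strength.
#'
#' @param x numeric 0/1 matrix, samples in rows, features in columns
#'   (column names are feature ids).
#' @param labels binary vector (1 = more severe than expected), length
#'   `nrow(x)`, or a named vector/adjusted tibble matched by row names.
#' @param cv_folds number of cross-validation folds.
#' @param lambda_grid vector of regularisation strengths to scan.
#' @param sd_rule width of the parsimony band in standard deviations.
#' @return A `lasso_fit` list: `beta` (named coefficient vector, intercept
#'   excluded), `lambda` (chosen strength), `cv` (tibble of per-strength
#'   mean/sd accuracy).
#' @export
lasso_fit_one <- function(x, labels, cv_folds = 10L,
                          lambda_grid = ipgs_defaults()$lambda_grid,
                          sd_rule = ipgs_defaults()$sd_rule) {
  y <- if (is.data.frame(labels) || !is.null(names(labels))) {
    yl <- .selection_labels(labels)
    if (is.null(rownames(x))) abort("x needs rownames to match named labels")
    unname(yl[rownames(x)])
  } else {
    as.integer(labels != 0)
  }
  if (length(y) != nrow(x) || any(is.na(y))) {
    abort("labels do not match the rows of x", class = "ipgs_selection_error")
  }
  if (min(table(factor(y, levels = 0:1))) < 2L) {
    abort("need >= 2 samples in each class", class = "ipgs_selection_error")
  }
  p <- ncol(x)
  if (p == 0L) {
    return(structure(list(beta = setNames(numeric(0), character(0)),
                          lambda = NA_real_, cv = tibble()), class = "lasso_fit"))
  }
  feat_ids <- colnames(x)
  pad <- p < 2L  # glmnet requires >= 2 columns
  if (pad) x <- cbind(x, `..pad..` = 0)
  lambdas <- sort(unique(lambda_grid), decreasing = TRUE)
  # stratified fold assignment so every training fold sees both classes
  foldid <- integer(length(y))
  for (cl in 0:1) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  acc <- matrix(NA_real_, nrow = cv_folds, ncol = length(lambdas))
  for (k in seq_len(cv_folds)) {
    tr <- foldid != k
    if (length(unique(y[tr])) < 2L || sum(!tr) == 0L) next
    fit_k <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = 1, lambda = lambdas, standardize = FALSE)
    pr <- predict(fit_k, newx = x[!tr, , drop = FALSE], s = lambdas, type = "class")
    acc[k, ] <- colMeans(matrix(as.numeric(pr), ncol = length(lambdas)) == y[!tr])
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  best <- which.max(mean_acc)
  sd_best <- sd(acc[, best], na.rm = TRUE)
  if (!is.finite(sd_best)) sd_best <- 0
  ok <- mean_acc >= mean_acc[best] - sd_rule * sd_best
  chosen <- lambdas[which(ok)[1]]  # lambdas descend: first ok = strongest
  full <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                         lambda = lambdas, standardize = FALSE)
  b <- as.numeric(predict(full, s = chosen, type = "coefficients"))[-1]
  if (pad) b <- b[1]
  structure(
    list(beta = setNames(b, feat_ids), lambda = chosen,
         cv = tibble(lambda = lambdas, mean_accuracy = mean_acc,
                     sd_accuracy = apply(acc, 2, sd, na.rm = TRUE))),
    class = "lasso_fit"
  )
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("<lasso_fit> lambda = ", signif(x$lambda, 4), "; ",
      sum(x$beta != 0), "/", length(x$beta), " non-zero coefficients\n", sep = "")
  invisible(x)
}

# one bootstrap pass over all representations; returns per-rep counts + sums
# and, when weight grids are supplied, the per-iteration silhouette-optimal
# IPGS weights computed from that iteration's selected features
.bootstrap_pass <- function(representations, y, n_boot, subsample_frac,
                            cv_folds, lambda_grid, sd_rule, permute = FALSE,
                            weight_grids = NULL) {
  samples <- names(y)
  acc <- purrr::map(representations, function(r) {
    list(count = setNames(integer(nrow(r$features)), r$features$feature_id),
         beta_sum = setNames(numeric(nrow(r$features)), r$features$feature_id))
  })
  rep_class <- purrr::map_chr(representations, function(r) {
    if (nrow(r$features)) r$features$class[1] else NA_character_
  })
  weights <- if (!is.null(weight_grids)) {
    matrix(NA_real_, nrow = n_boot, ncol = 3,
           dimnames = list(NULL, c("F_LF", "F_R", "F_UR")))
  }
  n <- length(samples)
  m <- max(2L, floor(subsample_frac * n))
  for (b in seq_len(n_boot)) {
    yb <- if (permute) setNames(sample(unname(y)), samples) else y
    for (try in 1:100) {
      sub <- sort(sample(samples, m, replace = FALSE))
      if (length(unique(yb[sub])) == 2L && min(table(yb[sub])) >= 2L) break
    }
    d <- list(common = numeric(m), low_frequency = numeric(m),
              rare = numeric(m), ultra_rare = numeric(m))
    for (nm in names(representations)) {
      r <- representations[[nm]]
      if (!nrow(r$features)) next
      xs <- r$matrix[sub, , drop = FALSE]
      fit <- lasso_fit_one(xs, unname(yb[sub]), cv_folds = cv_folds,
                           lambda_grid = lambda_grid, sd_rule = sd_rule)
      nz <- fit$beta != 0
      acc[[nm]]$count[nz] <- acc[[nm]]$count[nz] + 1L
      acc[[nm]]$beta_sum[nz] <- acc[[nm]]$beta_sum[nz] + fit$beta[nz]
      if (!is.null(weight_grids) && any(nz)) {
        sev <- names(fit$beta)[nz & fit$beta > 0]
        mil <- names(fit$beta)[nz & fit$beta < 0]
        d[[rep_class[[nm]]]] <- d[[rep_class[[nm]]]] +
          rowSums(xs[, sev, drop = FALSE]) - rowSums(xs[, mil, drop = FALSE])
      }
    }
    if (!is.null(weight_grids)) {
      res <- .silhouette_grid_search(
        d$common, d$low_frequency, d$rare, d$ultra_rare, unname(yb[sub]),
        weight_grids$grid_f_lf, weight_grids$grid_f_r, weight_grids$grid_f_ur
      )
      if (!is.na(res[["silhouette"]])) weights[b, ] <- res[c("F_LF", "F_R", "F_UR")]
    }
  }
  list(acc = acc, weights = weights)
}

#' Bootstrap LASSO selection over all representations
#'
#' Runs `n_boot` bootstrap iterations; in each, a fraction `subsample_frac`
#' of the labelled samples is drawn without replacement and
#' [lasso_fit_one()] is run on every representation. Selection counts and
#' coefficient sums accumulate across iterations. Deterministic under
#' `seed`.
#'
#' @param representations named list of `bool_rep` objects (see
#'   [encode_cohort()]).
#' @param labels adjusted-phenotype tibble from [adjust_phenotypes()] (rows
#'   labelled `excluded` are dropped) or a named binary vector.
#' @param n_boot number of bootstrap iterations.
#' @param subsample_frac fraction of samples drawn per iteration.
#' @param seed integer RNG seed.
#' @param config configuration list ([ipgs_defaults()]) supplying the CV
#'   folds, regularisation grid and SD rule.
#' @param estimate_weights if `TRUE`, also run the silhouette weight grid
#'   search inside every iteration on that iteration's selected features;
#'   the per-iteration estimates and their medians are attached to the
#'   ledger as attributes `weights_per_iteration` and `weights`.
#' @return A selection ledger tibble: `representation`, `feature_id`,
#'   `gene`, `class`, `model`, `selection_count`, `mean_beta` (mean of the
#'   non-zero coefficients over selecting iterations), `direction`
#'   (`severity` for positive mean coefficient, `mildness` for negative).
#'   `n_boot` is carried as an attribute.
#' @export
bootstrap_select <- function(representations, labels,
                             n_boot = ipgs_defaults()$n_boot,
                             subsample_frac = ipgs_defaults()$subsample_frac,
                             seed = 1L, config = ipgs_defaults(),
                             estimate_weights = FALSE) {
  if (n_boot < 1L) abort("n_boot must be >= 1", class = "ipgs_config_error")
  y <- .selection_labels(labels)
  common <- Reduce(intersect, c(list(names(y)),
                                purrr::map(representations, "samples")))
  if (length(common) < 4L) abort("too few labelled samples", class = "ipgs_selection_error")
  y <- y[sort(common)]
  reps <- purrr::map(representations, function(r) {
    keep <- match(sort(common), r$samples)
    new_bool_rep(r$name, r$samples[keep], r$features, r$matrix[keep, , drop = FALSE])
  })
  set.seed(seed)
  wg <- if (estimate_weights) {
    list(grid_f_lf = config$grid_f_lf, grid_f_r = config$grid_f_r,
         grid_f_ur = config$grid_f_ur)
  }
  pass <- .bootstrap_pass(reps, y, n_boot, subsample_frac,
                          config$cv_folds, config$lambda_grid, config$sd_rule,
                          weight_grids = wg)
  acc <- pass$acc
  ledger <- purrr::map_dfr(names(acc), function(nm) {
    r <- representations[[nm]]
    if (!nrow(r$features)) return(NULL)
    cnt <- acc[[nm]]$count
    mb <- ifelse(cnt > 0L, acc[[nm]]$beta_sum / cnt, NA_real_)
    tibble(
      representation = nm,
      feature_id = r$features$feature_id,
      gene = r$features$gene,
      class = r$features$class,
      model = r$features$model,
      selection_count = unname(cnt),
      mean_beta = unname(mb),
      direction = dplyr::case_when(
        cnt == 0L ~ NA_character_,
        mb > 0 ~ "severity",
        mb < 0 ~ "mildness",
        TRUE ~ NA_character_
      )
    )
  })
  attr(ledger, "n_boot") <- n_boot
  if (estimate_weights) {
    w <- pass$weights
    med <- apply(w, 2, median, na.rm = TRUE)
    attr(ledger, "weights_per_iteration") <- as_tibble(w)
    attr(ledger, "weights") <- structure(
      c(F_C = 1, med), silhouette = NA_real_, class = "ipgs_weights"
    )
  }
  ledger
}

#' Null selection threshold from random phenotypes
#'
#' Repeats the bootstrap selection with labels permuted afresh at every
#' iteration. Since no genuine association is expected under permutation,
#' the `percentile`-th percentile of the per-feature null selection counts
#' (upper tail by default) bounds the false-positive selection count at the
#' corresponding confidence level. One threshold per representation.
#'
#' @inheritParams bootstrap_select
#' @param percentile percentile of the null count distribution (default 95,
#'   upper tail; set 5 for the literal lower-tail reading).
#' @return Tibble with `representation`, `threshold_count`,
#'   `percentile_used`.
#' @export
null_threshold <- function(representations, labels,
                           n_boot = ipgs_defaults()$n_boot,
                           subsample_frac = ipgs_defaults()$subsample_frac,
                           seed = 1L,
                           percentile = ipgs_defaults()$null_percentile,
                           config = ipgs_defaults()) {
  if (n_boot < 1L) abort("n_boot must be >= 1", class = "ipgs_config_error")
  y <- .selection_labels(labels)
  common <- Reduce(intersect, c(list(names(y)),
                                purrr::map(representations, "samples")))
  y <- y[sort(common)]
  reps <- purrr::map(representations, function(r) {
    keep <- match(sort(common), r$samples)
    new_bool_rep(r$name, r$samples[keep], r$features, r$matrix[keep, , drop = FALSE])
  })
  set.seed(seed)
  acc <- .bootstrap_pass(reps, y, n_boot, subsample_frac,
                         config$cv_folds, config$lambda_grid, config$sd_rule,
                         permute = TRUE)$acc
  purrr::map_dfr(names(acc), function(nm) {
    cnt <- acc[[nm]]$count
    thr <- if (length(cnt)) unname(quantile(cnt, percentile / 100, type = 1)) else 0
    tibble(representation = nm, threshold_count = as.numeric(thr),
           percentile_used = percentile)
  })
}

#' Finalise the selected feature set
#'
#' Keeps features whose selection count strictly exceeds their
#' representation's null threshold. Features with an exactly zero mean
#' coefficient (direction undefined) are dropped with a warning.
#'
#' @param ledger selection ledger from [bootstrap_select()].
#' @param thresholds tibble from [null_threshold()].
#' @return The retained rows of the ledger (same columns).
#' @export
finalize_features <- function(ledger, thresholds) {
  if (!nrow(ledger)) return(ledger)
  missing_reps <- setdiff(unique(ledger$representation), thresholds$representation)
  if (length(missing_reps)) {
    abort(paste0("no threshold for representation(s): ",
                 paste(missing_reps, collapse = ", ")),
          class = "ipgs_integrity_error")
  }
  out <- ledger %>%
    left_join(select(thresholds, "representation", "threshold_count"),
              by = "representation") %>%
    filter(.data$selection_count > .data$threshold_count)
  undef <- out$selection_count > 0L & !is.na(out$mean_beta) & out$mean_beta == 0
  if (any(undef)) {
    warn(paste0(sum(undef), " feature(s) dropped: mean coefficient exactly 0, ",
                "direction undefined"),
         class = "ipgs_direction_warning")
    out <- out[!undef, , drop = FALSE]
  }
  out <- filter(out, !is.na(.data$direction))
  select(out, -"threshold_count")
}

#' Write a selection ledger or threshold table
#' @param x ledger or thresholds tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(x, path) {
  writeLines(.io_header("selection_ledger"), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
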