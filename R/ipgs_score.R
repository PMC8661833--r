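# The Integrated PolyGenic Score. Per sample, the final selected features
# equal to 1 are counted by frequency class (common, low-frequency, rare,
# ultra-rare) and direction (severity / mildness), aggregating over the
# inheritance models within a class. The score is the weighted sum
#   IPGS = (nC_s - nC_m) + F_LF (nLF_s - nLF_m)
#        + F_R (nR_s - nR_m) + F_UR (nUR_s - nUR_m)
# with F_C fixed at 1. The class weights are chosen by exhaustive integer
# grid search (F_LF in [1,4], F_R in [2,8], F_UR in [5,100]) maximising the
# silhouette coefficient of the 1-D score split by the adjusted-phenotype
# classes; weights model the greater penetrance of rarer variants.

.component_cols <- c("n_C_s", "n_C_m", "n_LF_s", "n_LF_m",
                     "n_R_s", "n_R_m", "n_UR_s", "n_UR_m")

#' Count per-sample IPGS components
#'
#' For every sample, counts the final selected features equal to 1, split by
#' frequency class and direction and aggregated over inheritance models
#' within each class.
#'
#' @param representations named list of `bool_rep` objects covering the
#'   cohort (see [encode_cohort()]).
#' @param final_features finalised feature tibble from [finalize_features()]
#'   (needs `representation`, `feature_id`, `class`, `direction`).
#' @return Tibble with `sample_id` and the eight counts `n_C_s`, `n_C_m`,
#'   `n_LF_s`, `n_LF_m`, `n_R_s`, `n_R_m`, `n_UR_s`, `n_UR_m`.
#' @export
count_components <- function(representations, final_features) {
  if (!nrow(final_features)) abort("final feature set is empty", class = "ipgs_domain_error")
  bad_rep <- setdiff(unique(final_features$representation), names(representations))
  if (length(bad_rep)) {
    abort(paste0("feature references absent representation(s): ",
                 paste(bad_rep, collapse = ", ")),
          class = "ipgs_integrity_error")
  }
  samples <- representations[[1]]$samples
  out <- matrix(0L, nrow = length(samples), ncol = length(.component_cols),
                dimnames = list(samples, .component_cols))
  for (nm in unique(final_features$representation)) {
    ff <- final_features[final_features$representation == nm, ]
    r <- representations[[nm]]
    missing_feats <- setdiff(ff$feature_id, colnames(r$matrix))
    if (length(missing_feats)) {
      abort(paste0("feature(s) absent from representation ", nm, ": ",
                   paste(head(missing_feats, 5), collapse = ", ")),
            class = "ipgs_integrity_error")
    }
    abbrev <- .ipgs_class_abbrev[ff$class]
    dir_sfx <- ifelse(ff$direction == "severity", "s", "m")
    col_of <- paste0("n_", abbrev, "_", dir_sfx)
    for (cc in unique(col_of)) {
      cols <- ff$feature_id[col_of == cc]
      out[, cc] <- out[, cc] +
        as.integer(rowSums(r$matrix[, cols, drop = FALSE]))
    }
  }
  bind_cols(tibble(sample_id = samples), as_tibble(out))
}

#' Evaluate the IPGS formula
#'
#' Exact weighted sum of the direction-signed class counts; integer-valued
#' whenever the weights are integers.
#'
#' @param components tibble from [count_components()].
#' @param weights named weights (`F_LF`, `F_R`, `F_UR`; `F_C` is fixed at 1),
#'   e.g. from [optimize_weights()] or `ipgs_defaults()$default_weights`.
#' @return `components` with an added `raw_score` column.
#' @export
#' @examples
#' comp <- tibble::tibble(sample_id = "s1", n_C_s = 0L, n_C_m = 0L,
#'   n_LF_s = 0L, n_LF_m = 0L, n_R_s = 0L, n_R_m = 0L, n_UR_s = 1L, n_UR_m = 0L)
#' compute_ipgs(comp, c(F_LF = 2, F_R = 4, F_UR = 5))$raw_score  # 5
compute_ipgs <- function(components, weights = ipgs_defaults()$default_weights) {
  w <- .as_weights(weights)
  missing_cols <- setdiff(.component_cols, names(components))
  if (length(missing_cols)) {
    abort(paste0("components missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "ipgs_integrity_error")
  }
  mutate(as_tibble(components),
         raw_score = (.data$n_C_s - .data$n_C_m) +
           w[["F_LF"]] * (.data$n_LF_s - .data$n_LF_m) +
           w[["F_R"]] * (.data$n_R_s - .data$n_R_m) +
           w[["F_UR"]] * (.data$n_UR_s - .data$n_UR_m))
}

.as_weights <- function(weights) {
  w <- unlist(weights)
  if (is.null(names(w))) names(w) <- c("F_LF", "F_R", "F_UR")[seq_along(w)]
  if (!"F_C" %in% names(w)) w <- c(F_C = 1, w)
  need <- c("F_C", "F_LF", "F_R", "F_UR")
  if (!all(need %in% names(w))) {
    abort(paste0("weights must name ", paste(need, collapse = ", ")),
          class = "ipgs_config_error")
  }
  w[need]
}

#' Percentile-normalise scores within a cohort
#'
#' Empirical CDF value using mid-ranks, so ties share a percentile and a
#' single sample maps to 0.5.
#'
#' @param x numeric vector of raw scores.
#' @return Numeric vector in \[0, 1\].
#' @export
percentile_normalize <- function(x) {
  if (!length(x)) return(numeric(0))
  (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Mean silhouette coefficient of 1-D scores under a binary clustering
#'
#' Exact mean silhouette width for one-dimensional points with Euclidean
#' distance and two fixed clusters, computed in O(n log n) via sorted prefix
#' sums (no dissimilarity matrix). Points in a singleton cluster, and points
#' with zero mean distance to both clusters, get silhouette 0.
#'
#' @param x numeric scores.
#' @param cluster binary cluster membership, length of `x`.
#' @return Mean silhouette width, or `NA` if either cluster is empty.
#' @export
silhouette_binary <- function(x, cluster) {
  g <- as.integer(factor(cluster))
  if (length(unique(g)) != 2L) return(NA_real_)
  xs <- lapply(1:2, function(k) sort(x[g == k]))
  ps <- lapply(xs, function(s) c(0, cumsum(s)))
  sumdist <- function(q, k) {
    s <- xs[[k]]; p <- ps[[k]]; n <- length(s)
    i <- findInterval(q, s)
    q * i - p[i + 1L] + (p[n + 1L] - p[i + 1L]) - q * (n - i)
  }
  n1 <- length(xs[[1]]); n2 <- length(xs[[2]])
  sil <- numeric(length(x))
  for (k in 1:2) {
    idx <- g == k
    nk <- if (k == 1L) n1 else n2
    no <- if (k == 1L) n2 else n1
    if (nk == 1L) { sil[idx] <- 0; next }
    a <- sumdist(x[idx], k) / (nk - 1L)
    b <- sumdist(x[idx], 3L - k) / no
    denom <- pmax(a, b)
    sil[idx] <- ifelse(denom > 0, (b - a) / denom, 0)
  }
  mean(sil)
}

#' Optimise the IPGS frequency-class weights
#'
#' Exhaustive integer grid search over `(F_LF, F_R, F_UR)` maximising the
#' mean silhouette coefficient of the 1-D IPGS scores with the two
#' adjusted-phenotype classes as fixed cluster labels (Euclidean distance,
#' raw scores by default). Ties break toward the lexicographically smallest
#' `(F_UR, F_R, F_LF)`.
#'
#' @param components tibble from [count_components()].
#' @param labels adjusted-phenotype tibble (rows labelled `excluded`
#'   dropped) or named binary vector, matched to `components$sample_id`.
#' @param grid_f_lf,grid_f_r,grid_f_ur integer grids to scan.
#' @param score_type optimise on `"raw"` (default) or `"percentile"` scores.
#' @return An `ipgs_weights` object: named weights (`F_C` fixed at 1) with
#'   the achieved silhouette as attribute `silhouette`.
#' @export
optimize_weights <- function(components, labels,
                             grid_f_lf = ipgs_defaults()$grid_f_lf,
                             grid_f_r = ipgs_defaults()$grid_f_r,
                             grid_f_ur = ipgs_defaults()$grid_f_ur,
                             score_type = c("raw", "percentile")) {
  score_type <- match.arg(score_type)
  y <- .selection_labels(labels)
  comp <- filter(as_tibble(components), .data$sample_id %in% names(y))
  if (nrow(comp) < 4L || length(unique(y[comp$sample_id])) < 2L ||
      min(table(y[comp$sample_id])) < 2L) {
    abort("need >= 2 samples in each adjusted-phenotype class",
          class = "ipgs_selection_error")
  }
  yy <- unname(y[comp$sample_id])
  res <- .silhouette_grid_search(
    comp$n_C_s - comp$n_C_m, comp$n_LF_s - comp$n_LF_m,
    comp$n_R_s - comp$n_R_m, comp$n_UR_s - comp$n_UR_m,
    yy, grid_f_lf, grid_f_r, grid_f_ur, score_type
  )
  if (is.na(res[["silhouette"]])) {
    warn("all candidate scores are constant; silhouette undefined, returning grid minima",
         class = "ipgs_degenerate_warning")
  }
  structure(c(F_C = 1, res[c("F_LF", "F_R", "F_UR")]),
            silhouette = res[["silhouette"]], class = "ipgs_weights")
}

# exhaustive grid search over (F_UR, F_R, F_LF), ties to the smallest
# lexicographically in that order; returns named vector incl. silhouette
.silhouette_grid_search <- function(d_c, d_lf, d_r, d_ur, y,
                                    grid_f_lf, grid_f_r, grid_f_ur,
                                    score_type = "raw") {
  best <- c(F_LF = min(grid_f_lf), F_R = min(grid_f_r), F_UR = min(grid_f_ur))
  best_sil <- -Inf
  any_defined <- FALSE
  for (f_ur in sort(grid_f_ur)) {
    for (f_r in sort(grid_f_r)) {
      for (f_lf in sort(grid_f_lf)) {
        sc <- d_c + f_lf * d_lf + f_r * d_r + f_ur * d_ur
        if (score_type == "percentile") sc <- percentile_normalize(sc)
        if (length(unique(sc)) < 2L) next  # silhouette degenerate here
        s <- silhouette_binary(sc, y)
        any_defined <- TRUE
        if (is.finite(s) && s > best_sil) {
          best_sil <- s
          best <- c(F_LF = f_lf, F_R = f_r, F_UR = f_ur)
        }
      }
    }
  }
  c(best, silhouette = if (any_defined) best_sil else NA_real_)
}

#' @export
print.ipgs_weights <- function(x, ...) {
  cat("<ipgs_weights> F_C = ", x[["F_C"]], ", F_LF = ", x[["F_LF"]],
      ", F_R = ", x[["F_R"]], ", F_UR = ", x[["F_UR"]],
      " (silhouette ", signif(attr(x, "silhouette"), 4), ")\n", sep = "")
  invisible(x)
}

#' Compute per-sample IPGS results
#'
#' Convenience wrapper: evaluates the IPGS formula and attaches the
#' within-cohort percentile score.
#'
#' @inheritParams compute_ipgs
#' @return Tibble with `sample_id`, the eight counts, `raw_score`,
#'   `percentile_score`.
#' @export
ipgs_scores <- function(components, weights = ipgs_defaults()$default_weights) {
  compute_ipgs(components, weights) %>%
    mutate(percentile_score = percentile_normalize(.data$raw_score))
}

#' Write a score table
#' @param scores tibble from [ipgs_scores()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  writeLines(.io_header("ipgs_scores"), path)
  readr::write_tsv(scores, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
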