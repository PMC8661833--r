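# IPGS components, the score formula, the silhouette objective, and the
# weight grid search.

random_components <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * 8, 1), n, 8)
    colnames(m) <- c("n_C_s", "n_C_m", "n_LF_s", "n_LF_m",
                     "n_R_s", "n_R_m", "n_UR_s", "n_UR_m")
    dplyr::bind_cols(tibble::tibble(sample_id = sprintf("c%04d", seq_len(n))),
                     tibble::as_tibble(m))
  })
}

test_that("component counting matches a brute-force recount", {
  sim <- small_sim(n = 50, seed = 55)
  reps <- encode_cohort(sim$variants, sim$phenotypes)
  dict <- feature_dictionary(reps)
  # take every feature as "final", alternating directions deterministically
  final <- dict %>%
    dplyr::mutate(selection_count = 1L, mean_beta = 0.1,
                  direction = ifelse(seq_len(dplyr::n()) %% 2 == 0,
                                     "severity", "mildness"))
  comp <- count_components(reps, final)
  abbrev <- c(ultra_rare = "UR", rare = "R", low_frequency = "LF", common = "C")
  for (s in sample(comp$sample_id, 10)) {
    expected <- setNames(integer(8), colnames(comp)[-1])
    for (i in seq_len(nrow(final))) {
      r <- reps[[final$representation[i]]]
      if (r$matrix[s, final$feature_id[i]] == 1L) {
        cc <- paste0("n_", abbrev[[final$class[i]]], "_",
                     if (final$direction[i] == "severity") "s" else "m")
        expected[cc] <- expected[cc] + 1L
      }
    }
    expect_equal(unlist(comp[comp$sample_id == s, -1]), expected)
  }
  # zero active features -> zero counts
  empty <- final[1, ]
  r1 <- reps[[empty$representation]]
  inactive <- r1$samples[r1$matrix[, empty$feature_id] == 0L]
  comp1 <- count_components(reps, empty)
  expect_true(all(unlist(comp1[comp1$sample_id %in% inactive, -1]) == 0L))
  # referencing an unknown representation is an integrity error
  bad <- final[1, ]; bad$representation <- "NOPE"
  expect_error(count_components(reps, bad), class = "ipgs_integrity_error")
})

test_that("the score formula is exact and matches a dual implementation", {
  comp0 <- random_components(1)
  comp0[1, -1] <- as.list(rep(0L, 8))
  expect_equal(compute_ipgs(comp0)$raw_score, 0)
  # one ultra-rare severity feature under weights (2, 4, 5) scores 5
  comp1 <- comp0
  comp1$n_UR_s <- 1L
  expect_equal(compute_ipgs(comp1, c(F_LF = 2, F_R = 4, F_UR = 5))$raw_score, 5)
  # random components against the independently coded formula
  comp <- random_components(200, seed = 9)
  withr::with_seed(10, {
    for (i in 1:20) {
      w <- c(F_LF = sample(1:4, 1), F_R = sample(2:8, 1), F_UR = sample(5:100, 1))
      got <- compute_ipgs(comp, w)$raw_score
      want <- vapply(seq_len(nrow(comp)),
                     function(j) oracle_ipgs(comp[j, ], w[1], w[2], w[3]),
                     numeric(1))
      expect_equal(got, want)
      expect_true(all(got == round(got)))  # integer weights: integer scores
    }
  })
})

test_that("the fast silhouette equals the naive O(n^2) form and cluster::silhouette", {
  withr::with_seed(14, {
    for (i in 1:20) {
      n <- sample(5:60, 1)
      x <- round(rnorm(n, sd = 3), 1)  # ties included
      g <- rbinom(n, 1, 0.5)
      if (length(unique(g)) < 2) next
      expect_equal(silhouette_binary(x, g), oracle_silhouette(x, g))
    }
  })
  skip_if_not_installed("cluster")
  withr::with_seed(15, {
    x <- rnorm(100); g <- rep(1:2, each = 50)
    sil <- cluster::silhouette(g, dist(x))
    expect_equal(silhouette_binary(x, g), mean(sil[, "sil_width"]))
  })
})

test_that("the silhouette objective is invariant to positive affine rescaling", {
  withr::with_seed(16, {
    x <- rnorm(80); g <- rbinom(80, 1, 0.4)
    expect_equal(silhouette_binary(3.7 * x, g), silhouette_binary(x, g))
    # shifts do not change Euclidean gaps either
    expect_equal(silhouette_binary(x + 11, g), silhouette_binary(x, g))
  })
})

test_that("weight optimisation recovers planted ultra-rare separation", {
  withr::with_seed(17, {
    n <- 200
    comp <- random_components(n, seed = 18)
    # make the classes differ only through the ultra-rare counts
    y <- rbinom(n, 1, 0.5)
    comp$n_UR_s <- ifelse(y == 1, 2L, 0L)
    comp$n_UR_m <- 0L
    labels <- setNames(ifelse(y == 1, "more_severe", "less_severe"), comp$sample_id)
    w <- optimize_weights(comp, labels)
    expect_gte(w[["F_UR"]], 50)
    expect_gt(attr(w, "silhouette"), 0.5)
  })
})

test_that("grid search equals brute-force objective evaluation on small grids", {
  comp <- random_components(60, seed = 19)
  labels <- withr::with_seed(20, setNames(
    sample(c("more_severe", "less_severe"), 60, replace = TRUE), comp$sample_id))
  g_lf <- 1:2; g_r <- 2:4; g_ur <- 5:8
  w <- optimize_weights(comp, labels, g_lf, g_r, g_ur)
  # exhaustive brute force with the naive silhouette
  y <- as.integer(labels[comp$sample_id] == "more_severe")
  best <- -Inf; best_w <- NULL
  for (f_ur in g_ur) for (f_r in g_r) for (f_lf in g_lf) {
    sc <- vapply(seq_len(nrow(comp)),
                 function(j) oracle_ipgs(comp[j, ], f_lf, f_r, f_ur), numeric(1))
    s <- oracle_silhouette(sc, y)
    if (s > best + 1e-12) { best <- s; best_w <- c(f_lf, f_r, f_ur) }
  }
  expect_equal(unname(unclass(w)[c("F_LF", "F_R", "F_UR")]), best_w)
  expect_equal(attr(w, "silhouette"), best)
  # a single grid point is returned unchanged
  w1 <- optimize_weights(comp, labels, 3, 4, 9)
  expect_equal(unname(unclass(w1)[c("F_LF", "F_R", "F_UR")]), c(3, 4, 9))
  # constant scores: grid minima with a warning
  comp0 <- comp; comp0[, -1] <- 0L
  expect_warning(w0 <- optimize_weights(comp0, labels, g_lf, g_r, g_ur),
                 class = "ipgs_degenerate_warning")
  expect_equal(unname(unclass(w0)[c("F_LF", "F_R", "F_UR")]), c(1, 2, 5))
})

test_that("percentile normalisation follows the mid-rank convention", {
  expect_equal(percentile_normalize(3.2), 0.5)
  x <- c(5, 1, 9, 7)
  expect_equal(order(percentile_normalize(x)), order(x))
  expect_true(all(diff(sort(percentile_normalize(x))) > 0))
  # ties share a percentile
  p <- percentile_normalize(c(2, 2, 1))
  expect_equal(p[1], p[2])
  expect_lt(p[3], p[1])
  expect_true(all(p >= 0 & p <= 1))
})
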