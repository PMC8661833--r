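# Synthetic cohorts with the statistical structure the pipeline assumes:
# age- and sex-driven ordinal severity on a proportional-odds latent scale,
# background variants in all four frequency classes, and planted gene-level
# effects (severity or mildness, per class and inheritance model) that enter
# the same latent scale — so phenotype adjustment, feature selection, weight
# optimisation and the final predictive model are all exercised by one
# generator, with a ground-truth manifest for recovery testing. Reference
# MAFs are drawn uniformly within each class interval; no linkage
# disequilibrium, population structure, or realistic site-frequency spectrum
# is modelled.

#' Build a simulation configuration
#'
#' Defaults describe a SARS-CoV-2-positive cohort: ages normal(55, 17)
#' truncated to \[18, 95\], balanced sexes, severity increasing with age and
#' male sex on the ordinal latent scale, and one planted severity plus one
#' planted mildness feature in each frequency class with effect log-odds
#' 1.1 (odds ratio ~ 3).
#'
#' @param n_samples cohort size.
#' @param n_genes_autosomal,n_genes_x background gene counts.
#' @param background_rate per-class per-site carrier probabilities for
#'   background variants.
#' @param planted tibble describing the planted effects (`class`, `model`,
#'   `direction`, `effect`, `carrier_rate`); `NULL` uses the default set,
#'   `tibble()` plants nothing.
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param sex_ratio male fraction.
#' @param age_slope latent-scale slope of age, per year, on the mild
#'   direction (negative: older = more severe); age centred at `age_mean`.
#' @param sex_effect latent-scale male effect (negative: more severe).
#' @param cutpoints five increasing latent thresholds separating the six
#'   outcome grades (1 = death ... 6 = not hospitalized).
#' @param noise_scale scale of the logistic latent noise.
#' @param hom_rate probability a background carrier call is homozygous.
#' @param missing_maf_rate fraction of ultra-rare SNP sites reported with a
#'   missing reference MAF.
#' @param seed mandatory integer seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_samples = 1000L,
                              n_genes_autosomal = 60L,
                              n_genes_x = 12L,
                              background_rate = c(ultra_rare = 0.02,
                                                  rare = 0.05,
                                                  low_frequency = 0.15,
                                                  common = NA),
                              planted = NULL,
                              age_mean = 55, age_sd = 17,
                              age_range = c(18, 95),
                              sex_ratio = 0.5,
                              age_slope = -0.04,
                              sex_effect = -0.8,
                              cutpoints = c(-4.6, -3.4, -2.2, -1.0, 0.4),
                              noise_scale = 1,
                              hom_rate = 0.1,
                              missing_maf_rate = 0.1,
                              seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory", class = "ipgs_config_error")
  if (is.null(planted)) {
    planted <- tidyr::expand_grid(
      class = .ipgs_classes,
      direction = c("severity", "mildness")
    ) %>%
      mutate(model = "AD", effect = 1.1,
             carrier_rate = c(ultra_rare = 0.05, rare = 0.08,
                              low_frequency = 0.15, common = 0.3)[.data$class])
  }
  rates <- unlist(planted$carrier_rate)
  if (any(!is.na(rates) & (rates < 0 | rates > 1))) {
    abort("carrier rates must lie in [0, 1]", class = "ipgs_config_error")
  }
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    abort("cutpoints must be strictly increasing", class = "ipgs_config_error")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_genes_autosomal = as.integer(n_genes_autosomal),
         n_genes_x = as.integer(n_genes_x),
         background_rate = background_rate, planted = as_tibble(planted),
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         sex_ratio = sex_ratio, age_slope = age_slope, sex_effect = sex_effect,
         cutpoints = cutpoints, noise_scale = noise_scale, hom_rate = hom_rate,
         missing_maf_rate = missing_maf_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

.class_maf_interval <- function(class) {
  switch(class,
         ultra_rare = c(1e-5, 9e-4),
         rare = c(1e-3, 9.9e-3),
         low_frequency = c(1e-2, 4.9e-2),
         common = c(5e-2, 4e-1))
}

#' Simulate a cohort with planted variant effects
#'
#' Draws genotypes per gene and frequency class, builds the ordinal
#' phenotype from the latent model
#' `mild-latent = age_slope (age - age_mean) + sex_effect male +
#' genetic effects + logistic noise` cut at the configured thresholds, and
#' returns the cohort in the package's native table shapes. Every planted
#' effect corresponds to a feature the Boolean encoder can produce, and
#' every simulated variant's reference MAF is consistent with its class
#' (planted ultra-rare features with a MAF at or above 0.1% are a
#' configuration error). Deterministic under the configured seed.
#'
#' @param config a [simulation_config()].
#' @return List with `variants`, `phenotypes`, `maf_table`, and `manifest`
#'   (planted-feature tibble plus the true ordinal parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%05d", seq_len(n))
  sex <- ifelse(runif(n) < config$sex_ratio, "M", "F")
  age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])

  # gene table: background genes plus one dedicated gene per planted feature
  planted <- config$planted
  if (nrow(planted)) {
    planted$gene <- sprintf("PG%02d", seq_len(nrow(planted)))
    planted$chrom <- ifelse(planted$model == "XL", "X",
                            as.character(1L + (seq_len(nrow(planted)) %% 22L)))
    bad <- purrr::map_lgl(seq_len(nrow(planted)), function(i) {
      iv <- .class_maf_interval(planted$class[i])
      cls <- classify_frequency(mean(iv), FALSE, 1L)
      cls != planted$class[i]
    })
    if (any(bad)) abort("planted class/MAF inconsistency", class = "ipgs_config_error")
  }
  genes <- bind_rows(
    tibble(gene = sprintf("BG%03d", seq_len(config$n_genes_autosomal)),
           chrom = as.character(1L + (seq_len(config$n_genes_autosomal) %% 22L))),
    tibble(gene = sprintf("BX%03d", seq_len(config$n_genes_x)), chrom = "X")
  )

  rows <- list()
  maf_rows <- list()
  pos_counter <- 10000L
  genetic <- numeric(n)
  bases <- c("A", "C", "G", "T")

  emit_site <- function(gene, chrom, class, carriers, hom, maf, maf_missing) {
    pos_counter <<- pos_counter + 1000L
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    key <- paste(chrom, pos_counter, ref, alt, sep = ":")
    maf_rows[[length(maf_rows) + 1L]] <<- tibble(variant_key = key, ref_maf = maf)
    if (length(carriers)) {
      zyg <- ifelse(chrom == "X" & sex[carriers] == "M", "hemizygous",
                    ifelse(hom, "homozygous_alt", "heterozygous"))
      rows[[length(rows) + 1L]] <<- tibble(
        sample_id = samples[carriers], gene = gene, chrom = chrom,
        pos = pos_counter, ref = ref, alt = alt, protein_impacting = TRUE,
        ref_maf = if (maf_missing) NA_real_ else maf, zygosity = zyg
      )
    }
    list(carriers = carriers, key = key)
  }

  # background sites: one per gene per class
  for (i in seq_len(nrow(genes))) {
    for (cls in .ipgs_classes) {
      iv <- .class_maf_interval(cls)
      maf <- runif(1, iv[1], iv[2])
      rate <- if (cls == "common") 2 * maf * (1 - maf) + maf^2 else
        config$background_rate[[cls]]
      carriers <- which(runif(n) < rate)
      hom <- if (cls == "common") {
        runif(length(carriers)) < maf^2 / (2 * maf * (1 - maf) + maf^2)
      } else runif(length(carriers)) < config$hom_rate
      miss <- cls == "ultra_rare" && runif(1) < config$missing_maf_rate
      emit_site(genes$gene[i], genes$chrom[i], cls, carriers, hom, maf, miss)
    }
  }

  # planted sites: the effect follows the encoded feature exactly
  manifest_keys <- character(nrow(planted))
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      iv <- .class_maf_interval(planted$class[i])
      maf <- runif(1, iv[1], iv[2])
      carriers <- which(runif(n) < planted$carrier_rate[i])
      hom <- if (planted$model[i] == "AR") rep(TRUE, length(carriers)) else
        runif(length(carriers)) < config$hom_rate
      got <- emit_site(planted$gene[i], planted$chrom[i], planted$class[i],
                       carriers, hom, maf, FALSE)
      manifest_keys[i] <- got$key
      sign <- if (planted$direction[i] == "severity") -1 else 1
      genetic[got$carriers] <- genetic[got$carriers] + sign * planted$effect[i]
    }
    planted$variant_key <- manifest_keys
  }

  latent <- config$age_slope * (age - config$age_mean) +
    config$sex_effect * (sex == "M") + genetic +
    stats::rlogis(n, 0, config$noise_scale)
  grade <- findInterval(latent, config$cutpoints) + 1L

  variants <- as_variant_table(bind_rows(rows))
  phenotypes <- as_phenotype_table(
    tibble(sample_id = samples, age = age, sex = sex, who_grade = grade)
  )
  list(
    variants = variants,
    phenotypes = phenotypes,
    maf_table = arrange(bind_rows(maf_rows), .data$variant_key),
    manifest = list(
      planted = planted,
      ordinal = list(age_slope = config$age_slope, sex_effect = config$sex_effect,
                     cutpoints = config$cutpoints, age_mean = config$age_mean),
      seed = config$seed
    )
  )
}

#' A tiny hand-checkable cohort
#'
#' Eight samples and six genes covering all four frequency classes, both
#' sexes, autosomal and X genes, compound-heterozygous and homozygous
#' recessive genotypes, a non-protein-impacting call, a variant-free
#' sample, and a gene with two common variants exercising the combination
#' encoding (combinations A, B, AB plus the absence feature). Fully
#' deterministic; no random number generation.
#'
#' @return List with `variants`, `phenotypes`, `maf_table`.
#' @export
make_toy_fixture <- function() {
  variants <- tibble::tribble(
    ~sample_id, ~gene, ~chrom, ~pos, ~ref, ~alt, ~protein_impacting, ~ref_maf, ~zygosity,
    "s01", "GA", "1", 1000L, "A", "G", TRUE, 0.0002, "heterozygous",
    "s01", "GD", "2", 2000L, "C", "T", TRUE, 0.2,    "heterozygous",
    "s02", "GA", "1", 1000L, "A", "G", TRUE, 0.0002, "homozygous_alt",
    "s02", "GD", "2", 2000L, "C", "T", TRUE, 0.2,    "heterozygous",
    "s02", "GD", "2", 2100L, "G", "A", TRUE, 0.3,    "heterozygous",
    "s03", "GB", "3", 3000L, "T", "C", TRUE, 0.005,  "heterozygous",
    "s03", "GB", "3", 3100L, "C", "G", TRUE, 0.002,  "heterozygous",
    "s04", "GC", "4", 4000L, "G", "T", TRUE, 0.02,   "heterozygous",
    "s04", "GD", "2", 2100L, "G", "A", TRUE, 0.3,    "homozygous_alt",
    "s05", "GE", "X", 5000000L, "A", "C", TRUE, 0.0001, "hemizygous",
    "s05", "GF", "X", 6000000L, "G", "A", TRUE, 0.1,  "hemizygous",
    "s06", "GE", "X", 5000000L, "A", "C", TRUE, 0.0001, "heterozygous",
    "s06", "GF", "X", 6000000L, "G", "A", TRUE, 0.1,  "heterozygous",
    "s07", "GA", "1", 1200L, "C", "A", FALSE, 0.0004, "heterozygous"
  )
  phenotypes <- tibble::tribble(
    ~sample_id, ~age, ~sex, ~who_grade,
    "s01", 45, "M", 3L,
    "s02", 52, "F", 2L,
    "s03", 61, "M", 4L,
    "s04", 38, "F", 6L,
    "s05", 70, "M", 1L,
    "s06", 55, "F", 5L,
    "s07", 47, "M", 6L,
    "s08", 66, "F", 4L
  )
  maf_table <- variants %>%
    filter(!is.na(.data$ref_maf)) %>%
    mutate(variant_key = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":")) %>%
    distinct(.data$variant_key, .data$ref_maf) %>%
    arrange(.data$variant_key)
  list(variants = as_variant_table(variants),
       phenotypes = as_phenotype_table(phenotypes),
       maf_table = maf_table)
}
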