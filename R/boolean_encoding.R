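# Gene-level Boolean representations. Protein-impacting variants are
# stratified into four reference-MAF classes (ultra-rare < 0.1%,
# rare 0.1-1%, low-frequency 1-5%, common >= 5%) and collapsed per gene under
# three inheritance models: autosomal dominant (>= 1 variant), autosomal
# recessive (>= 2 variant alleles, a homozygous call counting as 2), and
# X-linked (>= 1 variant in an X gene). Common variants instead get one
# Boolean feature per combination of a gene's variants, plus an "absence"
# feature, to capture alternative haplotypes. The full cohort encoding is 12
# representations: {UR, R, LF, C} x {AD, AR, X}.

#' Classify a variant into a reference-MAF frequency class
#'
#' Thresholds (default "methods" closure, left-closed): ultra-rare
#' `MAF < 0.1%`; rare `0.1% <= MAF < 1%`; low-frequency `1% <= MAF < 5%`;
#' common `MAF >= 5%`. A SNP with no reference MAF is treated as ultra-rare.
#' An INDEL with no reference MAF is treated as ultra-rare when carried by a
#' single cohort sample and otherwise discarded as a possible sequencing
#' artefact. The alternative `"results"` closure uses right-closed intervals
#' (`0.1% < MAF <= 1%` and so on).
#'
#' @param ref_maf numeric vector of reference-population MAFs (`NA` = missing).
#' @param is_indel logical vector: is the variant an INDEL?
#' @param cohort_carrier_count integer vector: number of cohort samples
#'   carrying the variant (used only when `ref_maf` is missing; must be >= 1).
#' @param breaks named upper boundaries of the ultra-rare, rare and
#'   low-frequency classes (fractions).
#' @param boundary `"methods"` (left-closed, default) or `"results"`
#'   (right-closed).
#' @return Character vector over `ultra_rare`, `rare`, `low_frequency`,
#'   `common`, `discarded`.
#' @export
#' @examples
#' classify_frequency(c(0.0005, 0.001, 0.01, 0.2), is_indel = FALSE,
#'                    cohort_carrier_count = 1L)
classify_frequency <- function(ref_maf, is_indel, cohort_carrier_count,
                               breaks = ipgs_defaults()$maf_breaks,
                               boundary = c("methods", "results")) {
  boundary <- match.arg(boundary)
  n <- max(length(ref_maf), length(is_indel), length(cohort_carrier_count))
  ref_maf <- rep_len(as.numeric(ref_maf), n)
  is_indel <- rep_len(as.logical(is_indel), n)
  cnt <- rep_len(as.integer(cohort_carrier_count), n)
  if (any(!is.na(ref_maf) & (ref_maf < 0 | ref_maf > 1))) {
    abort("ref_maf outside [0, 1]", class = "ipgs_domain_error")
  }
  if (any(is.na(ref_maf) & (is.na(cnt) | cnt < 1L))) {
    abort("cohort_carrier_count must be >= 1 when ref_maf is missing",
          class = "ipgs_domain_error")
  }
  out <- character(n)
  miss <- is.na(ref_maf)
  out[miss & !is_indel] <- "ultra_rare"
  out[miss & is_indel] <- ifelse(cnt[miss & is_indel] == 1L, "ultra_rare", "discarded")
  m <- ref_maf[!miss]
  out[!miss] <- if (boundary == "methods") {
    ifelse(m < breaks[["ultra_rare"]], "ultra_rare",
      ifelse(m < breaks[["rare"]], "rare",
        ifelse(m < breaks[["low_frequency"]], "low_frequency", "common")))
  } else {
    ifelse(m <= breaks[["ultra_rare"]], "ultra_rare",
      ifelse(m <= breaks[["rare"]], "rare",
        ifelse(m <= breaks[["low_frequency"]], "low_frequency", "common")))
  }
  out
}

# constructor for a Boolean representation
new_bool_rep <- function(name, samples, features, matrix) {
  stopifnot(nrow(matrix) == length(samples), ncol(matrix) == nrow(features))
  dimnames(matrix) <- list(samples, features$feature_id)
  structure(list(name = name, samples = samples, features = features,
                 matrix = matrix),
            class = "bool_rep")
}

#' @export
print.bool_rep <- function(x, ...) {
  cat("<bool_rep ", x$name, ">  ", length(x$samples), " samples x ",
      nrow(x$features), " features (", sum(x$matrix), " ones)\n", sep = "")
  invisible(x)
}

#' Tidy a Boolean representation into long form
#' @param x a `bool_rep` object.
#' @param ... unused.
#' @return Tibble with `sample_id`, `feature_id`, `value`.
#' @export
tidy.bool_rep <- function(x, ...) {
  if (!ncol(x$matrix)) {
    return(tibble(sample_id = character(), feature_id = character(), value = integer()))
  }
  tibble(
    sample_id = rep(x$samples, times = ncol(x$matrix)),
    feature_id = rep(colnames(x$matrix), each = nrow(x$matrix)),
    value = as.integer(x$matrix)
  ) %>% arrange(.data$sample_id, .data$feature_id)
}

# qualifying allele count per call under a model: AD/XL count presence,
# AR counts alleles (homozygous = 2; hemizygous treated as 2 on X)
.allele_weight <- function(zygosity, model) {
  if (model == "AR") {
    ifelse(zygosity %in% c("homozygous_alt", "hemizygous"), 2L, 1L)
  } else {
    rep(1L, length(zygosity))
  }
}

.check_gene_side <- function(variants, model) {
  if (model == "XL") {
    if (any(!.is_x(variants$chrom))) {
      abort("XL representation admits only X-chromosome variants",
            class = "ipgs_contract_error")
    }
  } else if (any(!.is_autosome(variants$chrom))) {
    abort(paste0(model, " representation admits only autosomal variants"),
          class = "ipgs_contract_error")
  }
}

.rep_name <- function(freq_class, model) {
  paste0(.ipgs_class_abbrev[[freq_class]], "_", if (model == "XL") "X" else model)
}

#' Build a collapsed (presence-count) representation
#'
#' One Boolean feature per gene. Under AD the feature is 1 when the sample
#' carries at least 1 qualifying variant in the gene; under AR at least 2
#' variant alleles (an unphased pair of heterozygous calls counts as
#' compound-heterozygous by proxy, a homozygous call counts as 2); under XL
#' at least 1 variant in an X-linked gene, any zygosity.
#'
#' @param variants variant tibble pre-filtered to protein-impacting calls of
#'   the requested frequency class.
#' @param freq_class one of `"ultra_rare"`, `"rare"`, `"low_frequency"`.
#' @param model `"AD"`, `"AR"`, or `"XL"`.
#' @param samples character vector fixing the cohort sample set and order;
#'   defaults to the samples present in `variants`.
#' @param check if `TRUE`, re-classify the variants (with carrier counts from
#'   `variants`) and raise a contract error on class mismatch.
#' @return A `bool_rep` object.
#' @export
build_collapsed_representation <- function(variants, freq_class,
                                           model = c("AD", "AR", "XL"),
                                           samples = NULL, check = TRUE) {
  model <- match.arg(model)
  freq_class <- match.arg(freq_class, c("ultra_rare", "rare", "low_frequency"))
  v <- as_variant_table(variants)
  v <- filter(v, .data$protein_impacting)
  .check_gene_side(v, model)
  if (check && nrow(v)) {
    cnt <- v %>% count(.data$variant_key, name = "carriers")
    cls <- classify_frequency(v$ref_maf,
                              nchar(v$ref) != nchar(v$alt),
                              cnt$carriers[match(v$variant_key, cnt$variant_key)])
    if (any(cls != freq_class)) {
      abort(paste0("variant(s) of class ", paste(unique(cls[cls != freq_class]), collapse = "/"),
                   " passed to a ", freq_class, " representation"),
            class = "ipgs_contract_error")
    }
  }
  if (is.null(samples)) samples <- sort(unique(v$sample_id))
  samples <- sort(unique(as.character(samples)))
  genes <- sort(unique(v$gene))
  name <- .rep_name(freq_class, model)
  mat <- matrix(0L, nrow = length(samples), ncol = length(genes))
  if (nrow(v) && length(genes)) {
    v$w <- .allele_weight(v$zygosity, model)
    agg <- v %>%
      group_by(.data$sample_id, .data$gene) %>%
      summarise(w = sum(.data$w), .groups = "drop")
    need <- if (model == "AR") 2L else 1L
    i <- match(agg$sample_id, samples)
    j <- match(agg$gene, genes)
    mat[cbind(i, j)] <- as.integer(agg$w >= need)
  }
  feats <- tibble(
    feature_id = if (length(genes)) paste0(name, ":", genes) else character(),
    gene = genes, class = freq_class, model = model, members = NA_character_
  )
  new_bool_rep(name, samples, feats, mat)
}

# all non-empty subsets of a character vector, in size-then-lexical order
.all_subsets <- function(keys) {
  keys <- sort(keys)
  k <- length(keys)
  out <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(keys, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Build the common-variant combination representation
#'
#' For each gene the observed common variants define combination features:
#' one Boolean per enumerated subset of the gene's variants, plus an
#' "absence" feature. Under AD (and the X-linked analogue) a combination is
#' 1 when the sample carries every variant of the subset in any zygosity;
#' under AR every variant of the subset must be homozygous (a hemizygous
#' male X call satisfies the homozygous requirement). The absence feature is
#' 1 when the sample carries no common variant of the gene (AD/X) or none in
#' the homozygous state (AR). For genes with more common variants than
#' `cap`, full subset enumeration is replaced by the genotype patterns
#' actually observed in the cohort, with a warning.
#'
#' @inheritParams build_collapsed_representation
#' @param cap per-gene variant-count cap above which only observed patterns
#'   are enumerated.
#' @return A `bool_rep` object.
#' @export
build_common_representation <- function(variants, model = c("AD", "AR", "XL"),
                                        samples = NULL,
                                        cap = ipgs_defaults()$combination_cap,
                                        check = TRUE) {
  model <- match.arg(model)
  v <- as_variant_table(variants)
  v <- filter(v, .data$protein_impacting)
  .check_gene_side(v, model)
  if (check && nrow(v)) {
    cnt <- v %>% count(.data$variant_key, name = "carriers")
    cls <- classify_frequency(v$ref_maf,
                              nchar(v$ref) != nchar(v$alt),
                              cnt$carriers[match(v$variant_key, cnt$variant_key)])
    if (any(cls != "common")) {
      abort("non-common variant passed to a common representation",
            class = "ipgs_contract_error")
    }
  }
  if (is.null(samples)) samples <- sort(unique(v$sample_id))
  samples <- sort(unique(as.character(samples)))
  name <- .rep_name("common", model)
  genes <- sort(unique(v$gene))
  qualifies <- if (model == "AR") {
    v$zygosity %in% c("homozygous_alt", "hemizygous")
  } else {
    rep(TRUE, nrow(v))
  }
  feat_rows <- list()
  cols <- list()
  for (g in genes) {
    gv <- v[v$gene == g, ]
    keys <- sort(unique(gv$variant_key))
    # per-sample set of qualifying variants of this gene
    gq <- gv[qualifies[v$gene == g], ]
    carried <- split(gq$variant_key, gq$sample_id)
    combos <- if (length(keys) <= cap) {
      .all_subsets(keys)
    } else {
      warn(paste0("gene ", g, " has ", length(keys), " common variants ",
                  "(cap ", cap, "); enumerating observed genotype patterns only"),
           class = "ipgs_cap_warning")
      pats <- unique(purrr::map(carried[lengths(carried) > 0], ~ sort(unique(.x))))
      pats[order(lengths(pats), purrr::map_chr(pats, paste, collapse = "+"))]
    }
    for (cmb in combos) {
      lab <- paste(cmb, collapse = "+")
      val <- vapply(samples, function(s) {
        has <- carried[[s]]
        as.integer(!is.null(has) && all(cmb %in% has))
      }, integer(1))
      feat_rows[[length(feat_rows) + 1L]] <- tibble(
        feature_id = paste0(name, ":", g, ":", lab),
        gene = g, class = "common", model = model, members = lab
      )
      cols[[length(cols) + 1L]] <- val
    }
    # absence feature: no qualifying variant of the gene at all
    val <- vapply(samples, function(s) {
      has <- carried[[s]]
      as.integer(is.null(has) || !length(has))
    }, integer(1))
    feat_rows[[length(feat_rows) + 1L]] <- tibble(
      feature_id = paste0(name, ":", g, ":absence"),
      gene = g, class = "common", model = model, members = "absence"
    )
    cols[[length(cols) + 1L]] <- val
  }
  feats <- if (length(feat_rows)) bind_rows(feat_rows) else
    tibble(feature_id = character(), gene = character(), class = character(),
           model = character(), members = character())
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(0L, nrow = length(samples), ncol = 0L)
  new_bool_rep(name, samples, feats, mat)
}

#' Encode a cohort into the 12 Boolean representations
#'
#' Drops non-protein-impacting variants, excludes Y, MT and pseudo-autosomal
#' X variants, classifies the remainder by reference MAF (missing-MAF SNPs
#' as ultra-rare; missing-MAF INDELs kept only as cohort singletons),
#' validates that hemizygous calls belong to male samples, and builds all 12
#' representations with a consistent sample ordering. All-zero feature
#' columns are removed, except common-representation absence features.
#'
#' @param variants validated variant tibble for the whole cohort.
#' @param sex_map named character vector (or phenotype tibble) mapping
#'   sample id to `"M"`/`"F"`.
#' @param samples optional character vector fixing the cohort sample set
#'   (includes variant-free samples); defaults to `names(sex_map)`.
#' @param config configuration list from [ipgs_defaults()].
#' @return Named list of 12 `bool_rep` objects (`UR_AD` ... `C_X`).
#' @export
encode_cohort <- function(variants, sex_map, samples = NULL,
                          config = ipgs_defaults()) {
  v <- as_variant_table(variants)
  if (!nrow(v)) abort("empty cohort", class = "ipgs_domain_error")
  if (is.data.frame(sex_map)) {
    sex_map <- setNames(sex_map$sex, sex_map$sample_id)
  }
  if (is.null(samples)) samples <- names(sex_map)
  samples <- sort(unique(as.character(samples)))
  if (!length(samples)) abort("empty cohort", class = "ipgs_domain_error")
  unknown <- setdiff(unique(v$sample_id), names(sex_map))
  if (length(unknown)) {
    abort(paste0("sex missing for sample(s): ", paste(head(unknown, 5), collapse = ", ")),
          class = "ipgs_row_error")
  }
  v <- filter(v, .data$sample_id %in% samples)
  # hemizygous only for male samples (chromosome side already checked on read)
  bad_hemi <- v$zygosity == "hemizygous" & sex_map[v$sample_id] != "M"
  if (any(bad_hemi)) {
    abort(paste0("hemizygous call in non-male sample(s): ",
                 paste(head(unique(v$sample_id[bad_hemi]), 5), collapse = ", ")),
          class = "ipgs_integrity_error")
  }
  v <- filter(v, .data$protein_impacting)
  # keep autosomes and non-PAR X only
  in_par <- .is_x(v$chrom) &
    Reduce(`|`, lapply(config$par_regions,
                       function(r) v$pos >= r[1] & v$pos <= r[2]),
           rep(FALSE, nrow(v)))
  v <- filter(v, (.is_autosome(.data$chrom) | .is_x(.data$chrom)) & !in_par)
  # classify on the full cohort
  carriers <- v %>% count(.data$variant_key, name = "carriers")
  v$freq_class <- classify_frequency(
    v$ref_maf, nchar(v$ref) != nchar(v$alt),
    carriers$carriers[match(v$variant_key, carriers$variant_key)],
    breaks = config$maf_breaks, boundary = config$boundary
  )
  v <- filter(v, .data$freq_class != "discarded")
  reps <- list()
  for (cls in c("ultra_rare", "rare", "low_frequency")) {
    vc <- filter(v, .data$freq_class == cls)
    for (model in c("AD", "AR")) {
      sub <- filter(vc, .is_autosome(.data$chrom))
      reps[[.rep_name(cls, model)]] <-
        build_collapsed_representation(sub, cls, model, samples = samples, check = FALSE)
    }
    sub <- filter(vc, .is_x(.data$chrom))
    reps[[.rep_name(cls, "XL")]] <-
      build_collapsed_representation(sub, cls, "XL", samples = samples, check = FALSE)
  }
  vc <- filter(v, .data$freq_class == "common")
  for (model in c("AD", "AR")) {
    sub <- filter(vc, .is_autosome(.data$chrom))
    reps[[.rep_name("common", model)]] <-
      build_common_representation(sub, model, samples = samples,
                                  cap = config$combination_cap, check = FALSE)
  }
  sub <- filter(vc, .is_x(.data$chrom))
  reps[[.rep_name("common", "XL")]] <-
    build_common_representation(sub, "XL", samples = samples,
                                cap = config$combination_cap, check = FALSE)
  # prune invariant all-zero columns (absence features are retained)
  reps <- purrr::map(reps, function(r) {
    if (!ncol(r$matrix)) return(r)
    keep <- colSums(r$matrix) > 0L | r$features$members %in% "absence"
    new_bool_rep(r$name, r$samples, r$features[keep, , drop = FALSE],
                 r$matrix[, keep, drop = FALSE])
  })
  reps[.ipgs_rep_names]
}

#' Combined feature dictionary of an encoded cohort
#' @param representations named list of `bool_rep` objects.
#' @return Tibble with `representation`, `feature_id`, `gene`, `class`,
#'   `model`, `members`.
#' @export
feature_dictionary <- function(representations) {
  purrr::map_dfr(representations, function(r) {
    mutate(r$features, representation = r$name, .before = 1L)
  })
}
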