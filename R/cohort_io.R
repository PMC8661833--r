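# On-disk artifacts: annotated variant tables, phenotype tables, reference MAF
# tables, feature matrices, selection ledgers, ranked gene lists. The native
# exchange format is TSV with a versioned "#" header comment; VCF ingestion is
# a convenience layer, not the canonical store. Coordinates are 1-based
# (VCF convention). A missing reference MAF is an empty field, never 0.

.variant_cols <- c(
  "sample_id", "gene", "chrom", "pos", "ref", "alt",
  "protein_impacting", "ref_maf", "zygosity"
)
.zygosity_levels <- c("heterozygous", "homozygous_alt", "hemizygous")

.io_header <- function(kind) {
  ver <- tryCatch(as.character(utils::packageVersion("ipgs")), error = function(e) "0.0.0")
  paste0("# ipgs ", kind, " v1 (package ", ver, ")")
}

#' Validate an annotated variant table
#'
#' Checks the invariants every downstream stage relies on: positive 1-based
#' positions, `ref != alt`, reference MAFs in \[0, 1\] or `NA`, known zygosity
#' codes, hemizygous calls only on non-autosomal chromosomes, and uniqueness
#' of each (sample, variant) pair. Rows are canonically sorted by
#' `(sample_id, variant_key)` so load order never affects results.
#'
#' @param variants data frame with columns `sample_id`, `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `protein_impacting`, `ref_maf`, `zygosity`.
#' @return A validated, canonically sorted tibble with an added `variant_key`
#'   column (`chrom:pos:ref:alt`).
#' @export
as_variant_table <- function(variants) {
  missing_cols <- setdiff(.variant_cols, names(variants))
  if (length(missing_cols)) {
    abort(paste0("variant table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ipgs_format_error")
  }
  v <- as_tibble(variants) %>%
    mutate(
      sample_id = as.character(.data$sample_id),
      gene = as.character(.data$gene),
      chrom = .norm_chrom(.data$chrom),
      pos = as.integer(.data$pos),
      ref = as.character(.data$ref),
      alt = as.character(.data$alt),
      protein_impacting = as.logical(.data$protein_impacting),
      ref_maf = as.numeric(.data$ref_maf),
      zygosity = as.character(.data$zygosity)
    )
  .row_err <- function(bad, what) {
    if (any(bad)) {
      abort(paste0(what, " (row ", paste(head(which(bad), 5), collapse = ", "), ")"),
            class = "ipgs_row_error")
    }
  }
  .row_err(is.na(v$pos) | v$pos < 1L, "pos must be a 1-based positive integer")
  .row_err(v$ref == v$alt, "ref and alt alleles must differ")
  .row_err(!is.na(v$ref_maf) & (v$ref_maf < 0 | v$ref_maf > 1),
           "ref_maf must lie in [0, 1] when present")
  .row_err(!v$zygosity %in% .zygosity_levels,
           paste0("malformed zygosity (expected one of ",
                  paste(.zygosity_levels, collapse = ", "), ")"))
  .row_err(v$zygosity == "hemizygous" & .is_autosome(v$chrom),
           "hemizygous call on an autosome")
  v <- v %>% mutate(variant_key = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"))
  dup <- duplicated(v[, c("sample_id", "variant_key")])
  if (any(dup)) {
    abort(paste0("duplicate (sample, variant) pair(s): ",
                 paste(head(paste0(v$sample_id[dup], "/", v$variant_key[dup]), 5), collapse = ", ")),
          class = "ipgs_integrity_error")
  }
  arrange(v, .data$sample_id, .data$variant_key)
}

#' Read an annotated variant table
#'
#' Reads the native tab-separated variant dialect (one row per variant call
#' per sample). Lines starting with `#` are treated as provenance comments.
#' Non-protein-impacting rows are retained but flagged; they are dropped at
#' encoding time, not here.
#'
#' @param path path to a TSV with the columns listed in [as_variant_table()].
#'   `ref_maf` may be empty (missing), never 0-filled.
#' @param maf_table optional data frame (`variant_key`, `ref_maf`) emulating a
#'   reference-population (e.g. gnomAD NFE) frequency table; when given it
#'   overrides the per-row `ref_maf`.
#' @return A validated tibble of annotated variants; see [as_variant_table()].
#' @export
read_variant_table <- function(path, maf_table = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "ipgs_format_error")
  raw <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  v <- as_variant_table(raw)
  if (!is.null(maf_table)) {
    m <- as_tibble(maf_table)
    if (!all(c("variant_key", "ref_maf") %in% names(m))) {
      abort("maf_table needs columns variant_key and ref_maf", class = "ipgs_format_error")
    }
    m <- distinct(m, .data$variant_key, .keep_all = TRUE)
    idx <- match(v$variant_key, m$variant_key)
    hit <- !is.na(idx)
    v$ref_maf[hit] <- as.numeric(m$ref_maf[idx[hit]])
    v <- as_variant_table(v)  # re-check MAF range after override
  }
  v
}

#' Write an annotated variant table
#'
#' @param variants validated variant tibble (see [as_variant_table()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  v <- as_variant_table(variants)
  writeLines(.io_header("variant_table"), path)
  readr::write_tsv(select(v, dplyr::all_of(.variant_cols)), path, append = TRUE,
                   col_names = TRUE, na = "")
  invisible(path)
}

#' Read a reference MAF table
#'
#' Two-column TSV mapping `variant_key` (`chrom:pos:ref:alt`) to the reference
#' population minor allele frequency.
#'
#' @param path path to the TSV.
#' @return Tibble with `variant_key` and numeric `ref_maf`.
#' @export
read_maf_table <- function(path) {
  m <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!all(c("variant_key", "ref_maf") %in% names(m))) {
    abort("MAF table needs columns variant_key and ref_maf", class = "ipgs_format_error")
  }
  m <- mutate(as_tibble(m), ref_maf = as.numeric(.data$ref_maf))
  if (any(!is.na(m$ref_maf) & (m$ref_maf < 0 | m$ref_maf > 1))) {
    abort("ref_maf outside [0, 1]", class = "ipgs_row_error")
  }
  arrange(m, .data$variant_key)
}

#' Validate a phenotype table
#'
#' Phenotypes use a six-grade ordinal outcome scale (1 = death, 2 = invasive
#' mechanical ventilation, 3 = CPAP/BiPAP, 4 = low-flow oxygen,
#' 5 = hospitalized without oxygen, 6 = not hospitalized). The derived binary
#' label is severe when the grade is 4 or lower, i.e. hospitalized with any
#' form of respiratory support. Sex is mandatory for every sample: both the
#' phenotype adjustment and X-chromosome handling require it.
#'
#' @param phenotypes data frame with `sample_id`, `age`, `sex` (`"M"`/`"F"`),
#'   `who_grade` (integer 1-6).
#' @return Validated tibble with an added logical `severe` column.
#' @export
as_phenotype_table <- function(phenotypes) {
  need <- c("sample_id", "age", "sex", "who_grade")
  missing_cols <- setdiff(need, names(phenotypes))
  if (length(missing_cols)) {
    abort(paste0("phenotype table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ipgs_format_error")
  }
  p <- as_tibble(phenotypes) %>%
    mutate(
      sample_id = as.character(.data$sample_id),
      age = as.numeric(.data$age),
      sex = as.character(.data$sex),
      who_grade = as.integer(.data$who_grade)
    )
  bad_grade <- is.na(p$who_grade) | !p$who_grade %in% 1:6
  if (any(bad_grade)) {
    abort(paste0("who_grade outside 1-6 (row ",
                 paste(head(which(bad_grade), 5), collapse = ", "), ")"),
          class = "ipgs_row_error")
  }
  bad_sex <- is.na(p$sex) | !p$sex %in% c("M", "F")
  if (any(bad_sex)) {
    abort(paste0("unknown or missing sex code (row ",
                 paste(head(which(bad_sex), 5), collapse = ", "), "); sex is required"),
          class = "ipgs_row_error")
  }
  if (any(is.na(p$age) | p$age < 0)) {
    abort("age must be a non-negative number", class = "ipgs_row_error")
  }
  if (anyDuplicated(p$sample_id)) {
    abort("duplicate sample_id in phenotype table", class = "ipgs_integrity_error")
  }
  p %>% mutate(severe = .data$who_grade <= 4L) %>% arrange(.data$sample_id)
}

#' Read a phenotype table
#'
#' @param path TSV with `sample_id`, `age`, `sex`, `who_grade`.
#' @return Validated tibble; see [as_phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  p <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  as_phenotype_table(p)
}

#' Write a phenotype table
#' @param phenotypes validated phenotype tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  p <- as_phenotype_table(phenotypes)
  writeLines(.io_header("phenotype_table"), path)
  readr::write_tsv(select(p, "sample_id", "age", "sex", "who_grade"), path,
                   append = TRUE, col_names = TRUE, na = "")
  invisible(path)
}

#' Read variants from a VCF
#'
#' Convenience ingestion of a standard VCF with per-genotype expansion: one
#' record per (sample, alt allele) with a non-reference genotype. Diploid
#' `0/1` maps to heterozygous and `1/1` to homozygous_alt; a haploid `1`
#' (or male non-PAR X genotype) maps to hemizygous. Each alt allele of a
#' multi-allelic site is treated as an independent variant.
#'
#' @param path VCF path (plain or bgzipped); must carry a GT FORMAT field.
#' @param sample_sex named character vector mapping sample id to `"M"`/`"F"`.
#' @param annotation_field_map named list naming which INFO keys carry the
#'   gene symbol (`gene`), the protein-impact flag or consequence
#'   (`protein_impacting`), and the reference MAF (`ref_maf`).
#' @return A validated variant tibble; see [as_variant_table()].
#' @export
read_vcf <- function(path,
                     sample_sex,
                     annotation_field_map = list(gene = "GENE",
                                                 protein_impacting = "IMPACTING",
                                                 ref_maf = "MAF")) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf requires the vcfR package")
  }
  need <- c("gene", "protein_impacting", "ref_maf")
  if (!all(need %in% names(annotation_field_map))) {
    abort(paste0("annotation_field_map must name the INFO keys for: ",
                 paste(need, collapse = ", ")),
          class = "ipgs_config_error")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_slot <- vcf@gt
  if (is.null(gt_slot) || !ncol(gt_slot) ||
      !any(grepl("(^|:)GT(:|$)", gt_slot[, "FORMAT"]))) {
    abort("VCF has no GT FORMAT field", class = "ipgs_format_error")
  }
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info_get <- function(key) vcfR::extract.info(vcf, element = key)
  genes <- info_get(annotation_field_map$gene)
  if (all(is.na(genes))) {
    abort(paste0("INFO field '", annotation_field_map$gene, "' not found in VCF"),
          class = "ipgs_config_error")
  }
  impact_raw <- info_get(annotation_field_map$protein_impacting)
  mafs <- suppressWarnings(as.numeric(info_get(annotation_field_map$ref_maf)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  missing_sex <- setdiff(samples, names(sample_sex))
  if (length(missing_sex)) {
    abort(paste0("sex missing for sample(s): ", paste(missing_sex, collapse = ", ")),
          class = "ipgs_row_error")
  }
  chrom <- .norm_chrom(fix$CHROM)
  pos <- as.integer(fix$POS)
  recs <- purrr::map(seq_len(nrow(gt)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    purrr::map(samples, function(s) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NULL)
      alleles <- as.integer(strsplit(g, "[/|]")[[1]])
      alleles <- alleles[!is.na(alleles)]
      carried <- unique(alleles[alleles > 0L])
      if (!length(carried)) return(NULL)
      purrr::map(carried, function(a) {
        n_alt <- sum(alleles == a)
        haploid <- length(alleles) == 1L
        male_x <- .is_x(chrom[i]) && sample_sex[[s]] == "M"
        zyg <- if (haploid || male_x) "hemizygous"
          else if (n_alt >= 2L) "homozygous_alt" else "heterozygous"
        tibble(
          sample_id = s, gene = genes[i], chrom = chrom[i], pos = pos[i],
          ref = fix$REF[i], alt = alts[a],
          protein_impacting = isTRUE(toupper(as.character(impact_raw[i])) %in%
                                       c("1", "TRUE", "T", "YES")),
          ref_maf = mafs[i], zygosity = zyg
        )
      })
    })
  })
  out <- bind_rows(purrr::flatten(purrr::flatten(recs)))
  if (!nrow(out)) abort("VCF yielded no non-reference genotypes", class = "ipgs_format_error")
  as_variant_table(out)
}

#' Write a Boolean representation to sparse triplet form
#'
#' Emits two TSVs: `<path>` with the non-zero cells
#' (`sample_id`, `feature_id`, `value`) and `<path>.features.tsv` with the
#' feature dictionary (`feature_id`, `gene`, `class`, `model`, `members`).
#'
#' @param rep a `bool_rep` object from the encoder.
#' @param path output path for the triplet TSV.
#' @return `path`, invisibly.
#' @export
write_representation <- function(rep, path) {
  stopifnot(inherits(rep, "bool_rep"))
  trip <- tidy(rep) %>% filter(.data$value == 1L)
  writeLines(.io_header(paste0("representation_", rep$name)), path)
  readr::write_tsv(trip, path, append = TRUE, col_names = TRUE)
  dict_path <- paste0(path, ".features.tsv")
  writeLines(.io_header(paste0("feature_dictionary_", rep$name)), dict_path)
  readr::write_tsv(rep$features, dict_path, append = TRUE, col_names = TRUE)
  invisible(path)
}
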