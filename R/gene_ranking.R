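# Composite gene weights for pathway analysis. Every Boolean feature found
# associated in at least one bootstrap iteration contributes
# |mean beta| x selection count x F to its gene, where F is the fixed
# frequency-class multiplier (ultra-rare 5, rare 4, low-frequency 2,
# common 1) — not the cohort-optimised IPGS weights. Absolute coefficients
# are used because the sign of a common-variant coefficient depends on which
# allele is the reference. Genes with several contributing features sum
# their scores. The ranked list feeds preranked GSEA as a .rnk file.

#' Rank genes by composite feature weight
#'
#' @param features selection-ledger tibble (from [bootstrap_select()] or
#'   [finalize_features()]) with `gene`, `class`, `mean_beta`,
#'   `selection_count`; features selected in at least one iteration
#'   (`selection_count >= 1`) contribute.
#' @param sex_stratum optional stratum label (`"M"`/`"F"`) recorded on the
#'   output for bookkeeping when ranking sex-specific ledgers.
#' @param rank_f named frequency-class multipliers.
#' @return Tibble ordered by descending `weight` (ties broken by gene
#'   symbol): `gene`, `weight`, `n_features`, and `sex_stratum` if given.
#' @export
#' @examples
#' feats <- tibble::tibble(gene = "G1", class = "ultra_rare",
#'                         mean_beta = 0.5, selection_count = 10L)
#' rank_genes(feats)$weight  # 0.5 * 10 * 5 = 25
rank_genes <- function(features, sex_stratum = NULL,
                       rank_f = ipgs_defaults()$rank_f) {
  f <- as_tibble(features) %>% filter(.data$selection_count >= 1L)
  if (nrow(f) && any(!f$class %in% names(rank_f))) {
    abort(paste0("feature with undefined frequency class: ",
                 paste(unique(setdiff(f$class, names(rank_f))), collapse = ", ")),
          class = "ipgs_integrity_error")
  }
  out <- f %>%
    mutate(contrib = abs(.data$mean_beta) * .data$selection_count *
             unname(rank_f[.data$class])) %>%
    group_by(.data$gene) %>%
    summarise(weight = sum(.data$contrib), n_features = n(), .groups = "drop") %>%
    arrange(dplyr::desc(.data$weight), .data$gene)
  if (!is.null(sex_stratum)) out$sex_stratum <- sex_stratum
  out
}

#' Write a GSEA-preranked .rnk file
#'
#' Two tab-separated columns (gene, weight), descending by weight, no
#' header — the format preranked gene-set enrichment tools consume.
#'
#' @param ranked tibble from [rank_genes()].
#' @param path output `.rnk` path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  if (!nrow(ranked)) abort("empty ranked list", class = "ipgs_domain_error")
  if (anyDuplicated(ranked$gene)) {
    abort("duplicate gene symbols in ranked list", class = "ipgs_integrity_error")
  }
  ord <- order(-ranked$weight, ranked$gene)
  writeLines(paste(ranked$gene[ord], format(ranked$weight[ord], trim = TRUE,
                                            scientific = FALSE), sep = "\t"),
             path)
  invisible(path)
}

#' Read a .rnk file back
#' @param path path to a two-column `.rnk` file.
#' @return Tibble with `gene`, `weight`, descending.
#' @export
read_rnk <- function(path) {
  d <- readr::read_tsv(path, col_names = c("gene", "weight"),
                       col_types = "cd", progress = FALSE)
  arrange(as_tibble(d), dplyr::desc(.data$weight), .data$gene)
}
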